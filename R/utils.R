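# Internal helpers: typed conditions, deterministic seed derivation, RNG scoping.

rl_error <- function(class, message, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "reflexlens_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

rl_value_error <- function(msg) rl_error("rl_value_error", msg)
rl_format_error <- function(msg) rl_error("rl_format_error", msg)
rl_integrity_error <- function(msg) rl_error("rl_integrity_error", msg)
rl_io_error <- function(msg) rl_error("rl_io_error", msg)
rl_config_error <- function(msg) rl_error("rl_config_error", msg)
rl_empty_category_error <- function(msg) rl_error("rl_empty_category_error", msg)
rl_degenerate_error <- function(msg) rl_error("rl_degenerate_error", msg)
rl_stratification_error <- function(msg) rl_error("rl_stratification_error", msg)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a master seed and a label
#'
#' Deterministic 31-bit hash of `(seed, label)`, so that independent stages
#' (or unordered pairs, via a sorted label) get reproducible, distinct
#' substreams from one user-supplied master seed.
#'
#' @param seed Integer master seed.
#' @param label Character vector; concatenated into the hash.
#' @return An integer in `[0, 2^31 - 2]`, suitable for [set.seed()].
#' @export
#' @examples
#' derive_seed(1, "jaccard")
#' derive_seed(1, c("Interpreter", "Manager"))
derive_seed <- function(seed, label) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    rl_value_error("`seed` must be a single non-missing number")
  }
  codes <- utf8ToInt(paste(as.character(label), collapse = ""))
  h <- abs(as.double(seed)) %% 2147483647
  for (cd in codes) h <- (h * 131 + cd) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

is_string <- function(x) is.character(x) && length(x) == 1 && !is.na(x)

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1 && !is.na(x) && x >= min && x == floor(x)
}
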