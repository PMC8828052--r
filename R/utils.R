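#' @importFrom stats dnorm qnorm rnorm runif rbinom integrate median quantile
#'   sd var optim p.adjust t.test setNames complete.cases
#' @importFrom utils read.csv write.csv head
#' @importFrom rlang .data
NULL

nn_stop <- function(...) stop(..., call. = FALSE)

check_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    nn_stop("`", name, "` must be finite and numeric")
  }
  invisible(x)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    nn_stop("`", name, "` must be a positive finite scalar")
  }
  invisible(x)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so simulation helpers do not perturb user code.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", globalenv(), mode = "integer", inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream label; keeps derived
# seeds inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  h <- rlang::hash(list(as.integer(seed), stream))
  (strtoi(substr(h, 1, 7), base = 16L) %% 2147483629L) + 1L
}

#' Hash a configuration object
#'
#' Stable content hash used to stamp outputs so a run can be reproduced
#' exactly from its manifest.
#'
#' @param x Any R object (typically a simulation or fit configuration).
#' @return A character scalar hash.
#' @export
config_hash <- function(x) rlang::hash(x)

# numerically stable log(cosh(u))
log_cosh <- function(u) {
  au <- abs(u)
  au + log1p(exp(-2 * au)) - log(2)
}
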