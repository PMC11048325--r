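#' @keywords internal
"_PACKAGE"

#' @importFrom stats fft rnorm runif sd var quantile
#' @importFrom utils read.csv write.csv
NULL

# Evaluate `code` under a temporary RNG seed, restoring global RNG state on
# exit. All stochastic operations in the package route through this so that
# no function mutates the caller's random stream.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed and a stream label; keeps every
# stage independently reproducible while the user supplies one integer.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 1103 + h * 12289 + 49297) %% 2147483587L)
}

abort2 <- function(msg, class) {
  stop(structure(class = c(class, "eegcaps_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_arg <- function(ok, msg) if (!isTRUE(ok)) abort2(msg, "eegcaps_argument_error")

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Column-wise softmax of a matrix (each column sums to one).
softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max), "-")
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}
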