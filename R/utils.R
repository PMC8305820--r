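#' @useDynLib sonoradiomics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef fft median plogis predict quantile rbinom rnorm
#'   runif sd var
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a named sub-stream seed from a master seed
#'
#' All randomness in the package flows from a single master seed through
#' named sub-streams (e.g. `"masks"`, `"split"`, `"cv"`), so that changing
#' one stage's draws never perturbs another stage. The derivation is a
#' small deterministic string hash folded into the 32-bit integer range.
#'
#' @param master integer master seed.
#' @param stream character stream name.
#' @return a positive integer seed below 2^31.
#' @export
sub_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  s <- as.double(master %% 2147483647)
  for (ch in utf8ToInt(stream)) s <- (s * 31 + ch) %% 2147483647
  as.integer(s) + 1L
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_stage <- function(stage, msg, ...) {
  stop(sprintf("[%s] %s", stage, sprintf(msg, ...)), call. = FALSE)
}

# 0*log2(0) = 0 convention used by every entropy in the package
xlog2x <- function(p) {
  out <- numeric(length(p))
  nz <- p > 0
  out[nz] <- p[nz] * log2(p[nz])
  out
}
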