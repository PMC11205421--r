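# Internal helpers shared across modules.

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

#' Coefficient of variation in percent
#'
#' @param x numeric vector.
#' @return `100 * sd(x) / mean(x)`.
#' @keywords internal
cv_pct <- function(x) {
  m <- mean(x)
  if (m == 0) stop("cannot compute a CV: mean of the values is zero", call. = FALSE)
  100 * stats::sd(x) / m
}

check_hct <- function(hct, max_hct = 0.95) {
  if (!is.numeric(hct) || anyNA(hct) || any(hct < 0) || any(hct > max_hct)) {
    stop(sprintf("hematocrit must lie in [0, %.2f]", max_hct), call. = FALSE)
  }
  invisible(hct)
}

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop(sprintf("%s must be numeric and >= 0", what), call. = FALSE)
  }
  invisible(x)
}

#' Wald-Wolfowitz runs test on residual signs
#'
#' One-sided test for too few sign runs (a systematic bowing pattern in
#' calibration residuals). Residuals indistinguishable from zero at machine
#' scale are dropped before counting runs; with fewer than two signed
#' residuals, or residuals of a single sign class, the p-value is 1 (no
#' evidence of a pattern can exist).
#'
#' @param resid numeric residuals.
#' @param zero_tol absolute magnitude below which a residual counts as zero.
#' @return p-value for the one-sided (too few runs) alternative, normal
#'   approximation with continuity correction.
#' @keywords internal
sign_runs_pvalue <- function(resid, zero_tol = NULL) {
  if (is.null(zero_tol)) {
    zero_tol <- 1e-12 * max(abs(resid), 1e-300)
  }
  s <- sign(resid[abs(resid) > zero_tol])
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  if (n1 == 0 || n2 == 0) return(1)
  runs <- 1L + sum(s[-1] != s[-length(s)])
  n <- n1 + n2
  mu <- 2 * n1 * n2 / n + 1
  sig2 <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (sig2 <= 0) return(1)
  stats::pnorm((runs - mu + 0.5) / sqrt(sig2))
}

# Lognormal parameters (meanlog, sdlog) matching an arithmetic mean and sd.
lnorm_params <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(c(meanlog = log(mean), sdlog = 0))
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  c(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# Truncated normal draws by rejection; bounds are mild so this terminates fast.
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

geom_seq <- function(from, to, length.out) {
  exp(seq(log(from), log(to), length.out = length.out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
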