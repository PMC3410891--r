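#' Expected null chi-square quantiles
#'
#' Quantiles of the 1-df chi-square distribution at the symmetric plotting
#' positions (i - 0.5)/n, ascending. These are the abscissae against which a
#' genome of observed scores is regressed to estimate the inflation factor.
#'
#' @param n number of scores (>= 2).
#' @return strictly increasing numeric vector of length n.
#' @export
null_chi2_quantiles <- function(n) {
  if (n < 2L) stop("need at least 2 scores for null quantiles")
  stats::qchisq((seq_len(n) - 0.5) / n, df = 1)
}

#' Inflation factor by zero-intercept regression
#'
#' Sorts the observed 1-df chi-square scores and regresses them through the
#' origin on the corresponding null quantiles; the slope is the inflation
#' factor lambda. This estimator is exactly scale-equivariant and tends to be
#' at least as conservative as the median ratio on heavy-tailed score sets.
#'
#' @param chi2_obs non-negative numeric vector of observed scores (length >= 2).
#' @return An object of class \code{"gc_result"}: list with \code{lambda},
#'   \code{method}, \code{n_scores}, \code{clamped} (set by
#'   \code{\link{gc_correct}}; NA until then).
#' @export
lambda_regression <- function(chi2_obs) {
  check_chi2(chi2_obs)
  x <- null_chi2_quantiles(length(chi2_obs))
  y <- sort(chi2_obs)
  lam <- sum(x * y) / sum(x * x)
  gc_result(lam, "regression", length(chi2_obs))
}

#' Inflation factor by the median ratio
#'
#' Ratio of the observed median chi-square to the theoretical median of the
#' 1-df chi-square distribution (about 0.4549).
#'
#' @inheritParams lambda_regression
#' @return A \code{"gc_result"} (see \code{\link{lambda_regression}}).
#' @export
lambda_median <- function(chi2_obs) {
  check_chi2(chi2_obs)
  lam <- stats::median(chi2_obs) / stats::qchisq(0.5, df = 1)
  gc_result(lam, "median", length(chi2_obs))
}

check_chi2 <- function(chi2_obs) {
  if (length(chi2_obs) < 2L) stop("need at least 2 chi-square scores")
  if (any(is.na(chi2_obs))) stop("NA chi-square score")
  if (any(chi2_obs < 0)) stop("negative chi-square score")
  invisible(TRUE)
}

gc_result <- function(lambda, method, n_scores) {
  if (!is.finite(lambda) || lambda <= 0) stop("estimated lambda is not positive")
  structure(list(lambda = lambda, method = method, n_scores = n_scores,
                 clamped = NA), class = "gc_result")
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf("Genomic-control inflation factor: lambda = %.4f (%s, %d scores)\n",
              x$lambda, x$method, x$n_scores))
  invisible(x)
}

#' Genomic-control corrected p-values
#'
#' Divides observed 1-df chi-square scores by the (optionally clamped)
#' inflation factor and converts to upper-tail p-values. With
#' \code{clamp = TRUE} (default) lambda below 1 is floored at 1, so apparent
#' deflation is never amplified into smaller p-values.
#'
#' @param chi2_obs non-negative observed scores.
#' @param gc a \code{"gc_result"} (or a bare positive number).
#' @param clamp floor lambda at 1 before correcting.
#' @return numeric p-value vector with attributes \code{lambda_eff},
#'   \code{clamped} and \code{chi2_corrected}.
#' @export
gc_correct <- function(chi2_obs, gc, clamp = TRUE) {
  lam <- if (inherits(gc, "gc_result")) gc$lambda else as.numeric(gc)
  if (!is.finite(lam) || lam <= 0) stop("lambda must be positive")
  if (any(chi2_obs < 0, na.rm = TRUE)) stop("negative chi-square score")
  clamped <- isTRUE(clamp) && lam < 1
  lam_eff <- if (isTRUE(clamp)) max(lam, 1) else lam
  corrected <- chi2_obs / lam_eff
  p <- stats::pchisq(corrected, df = 1, lower.tail = FALSE)
  attr(p, "lambda_eff") <- lam_eff
  attr(p, "clamped") <- clamped
  attr(p, "chi2_corrected") <- corrected
  p
}
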