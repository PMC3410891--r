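#' Absolute deviations from the per-genotype median
#'
#' The Brown--Forsythe transform: each observation is replaced by its absolute
#' deviation from the median of its own genotype group. For groups of even
#' size the median is the midpoint of the two central order statistics.
#'
#' @param y numeric phenotype vector, one value per accession in
#'   \code{groups$calls} order; accessions with a missing call are ignored.
#' @param groups a \code{\link{genotype_groups}} result.
#' @return numeric vector z of the same length as \code{y} (NA where the call
#'   is missing), with an attribute \code{"medians"} holding the group medians.
#' @export
abs_median_deviation <- function(y, groups) {
  stopifnot(inherits(groups, "geno_groups"))
  calls <- groups$calls
  if (length(y) != length(calls)) stop("y and genotype calls differ in length")
  z <- rep(NA_real_, length(y))
  meds <- c()
  for (g in as.integer(names(groups$n))) {
    idx <- which(!is.na(calls) & calls == g)
    m <- stats::median(y[idx])
    meds[as.character(g)] <- m
    z[idx] <- abs(y[idx] - m)
  }
  attr(z, "medians") <- meds
  z
}

#' Brown--Forsythe test of variance heterogeneity between genotypes
#'
#' A Levene-type test: one-way ANOVA on the absolute deviations from the
#' per-genotype medians. With K genotype groups and N observations the
#' statistic follows F(K-1, N-K); for large N, (K-1) F is approximately
#' chi-square with K-1 degrees of freedom, which is the score used for
#' genomic control downstream.
#'
#' Degenerate dispersion patterns are resolved deterministically: if both the
#' between- and within-group sums of squares of z are zero the marker shows no
#' dispersion signal at all (F = 0, p = 1); if only the within-group sum is
#' zero the separation is perfect and the smallest representable positive
#' p-value is returned with \code{degenerate = TRUE}.
#'
#' @param y numeric phenotype vector aligned with \code{groups$calls}.
#' @param groups a \code{\link{genotype_groups}} result with K = 2.
#' @param min_group_size smallest admissible genotype-group size (default 2:
#'   a singleton group contributes no within-group dispersion information).
#' @return An object of class \code{"bf_test"}: list with \code{F},
#'   \code{df1}, \code{df2}, \code{p_F}, \code{chi2} (= df1 * F), \code{p_chi2},
#'   \code{z_bar_by_group}, \code{N} and \code{degenerate}.
#' @export
brown_forsythe <- function(y, groups, min_group_size = 2L) {
  stopifnot(inherits(groups, "geno_groups"))
  if (groups$K < 2L) stop("monomorphic marker: variance heterogeneity undefined")
  if (any(groups$n < min_group_size)) {
    stop("genotype group smaller than min_group_size (", min_group_size, ")")
  }
  if (groups$N < groups$K + 1L) stop("need N >= K + 1 observations")
  z <- abs_median_deviation(y, groups)
  calls <- groups$calls
  use <- !is.na(calls)
  zz <- z[use]
  g <- calls[use]
  K <- groups$K
  N <- groups$N
  zbar <- mean(zz)
  zbar_j <- tapply(zz, as.character(g), mean)
  ss_between <- sum(groups$n * (zbar_j[names(groups$n)] - zbar)^2)
  ss_within <- sum((zz - zbar_j[as.character(g)])^2)
  df1 <- K - 1L
  df2 <- N - K
  degenerate <- FALSE
  if (ss_within <= 0) {
    if (ss_between <= 0) {
      Fstat <- 0; p_F <- 1; p_chi2 <- 1
    } else {
      Fstat <- Inf
      p_F <- .Machine$double.xmin
      p_chi2 <- .Machine$double.xmin
      degenerate <- TRUE
    }
  } else {
    Fstat <- (ss_between / df1) / (ss_within / df2)
    p_F <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
    p_chi2 <- stats::pchisq(df1 * Fstat, df = df1, lower.tail = FALSE)
  }
  structure(list(F = Fstat, df1 = df1, df2 = df2, p_F = p_F,
                 chi2 = df1 * Fstat, p_chi2 = p_chi2,
                 z_bar_by_group = zbar_j, N = N, degenerate = degenerate),
            class = "bf_test")
}

#' @export
print.bf_test <- function(x, ...) {
  cat("Brown-Forsythe variance-heterogeneity test\n")
  cat(sprintf("  F = %.4f on (%d, %d) df, p = %.4g\n", x$F, x$df1, x$df2, x$p_F))
  cat(sprintf("  chi-square score = %.4f (df = %d), p = %.4g\n",
              x$chi2, x$df1, x$p_chi2))
  if (x$degenerate) cat("  [degenerate: zero within-group dispersion]\n")
  invisible(x)
}

#' Wilcoxon rank-sum test of a genotype mean/location effect
#'
#' Two-sided Mann--Whitney test between the two homozygote groups, the
#' mean-effect comparator run alongside the variance scan. The default is the
#' normal approximation with tie correction and continuity correction; for
#' N <= 20 and untied data an exact p-value can be requested. The reported
#' chi-square score is Z squared in all cases (the score fed to genomic
#' control), so \code{chi2 == Z^2} holds by construction.
#'
#' @param y numeric phenotype vector aligned with \code{groups$calls}.
#' @param groups a \code{\link{genotype_groups}} result with K = 2.
#' @param min_group_size smallest admissible group size (default 2).
#' @param exact use exact enumeration (only honoured for N <= 20 with no
#'   ties; otherwise the approximation is used with a warning).
#' @param correct apply the continuity correction in the normal approximation.
#' @return An object of class \code{"wx_test"}: list with \code{rank_sum}
#'   (ranks of the low-coded group), \code{U}, \code{Z}, \code{p},
#'   \code{chi2} (= Z^2), \code{N} and \code{exact}.
#' @export
wilcoxon_rank_sum <- function(y, groups, min_group_size = 2L,
                              exact = FALSE, correct = TRUE) {
  stopifnot(inherits(groups, "geno_groups"))
  if (groups$K < 2L) stop("monomorphic marker: no groups to compare")
  if (any(groups$n < min_group_size)) {
    stop("genotype group smaller than min_group_size (", min_group_size, ")")
  }
  calls <- groups$calls
  use <- !is.na(calls)
  yy <- y[use]
  g <- calls[use]
  y0 <- yy[g == 0L]
  y1 <- yy[g == 2L]
  n0 <- length(y0); n1 <- length(y1); N <- n0 + n1
  r <- rank(yy)  # average ranks for ties
  rank_sum <- sum(r[g == 0L])
  U <- rank_sum - n0 * (n0 + 1) / 2
  mu <- n0 * n1 / 2
  ties <- table(yy)
  sigma2 <- (n0 * n1 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  diffU <- U - mu
  if (sigma2 <= 0) {
    Z <- 0
  } else {
    cc <- if (correct) sign(diffU) * 0.5 else 0
    Z <- (diffU - cc) / sqrt(sigma2)
  }
  has_ties <- any(ties > 1)
  use_exact <- isTRUE(exact)
  if (use_exact && (N > 20L || has_ties)) {
    warning("exact Wilcoxon p-value requires N <= 20 and no ties; using the normal approximation")
    use_exact <- FALSE
  }
  if (use_exact) {
    p <- stats::wilcox.test(y0, y1, exact = TRUE, correct = FALSE)$p.value
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(Z)))
  }
  structure(list(rank_sum = rank_sum, U = U, Z = Z, p = p,
                 chi2 = Z^2, N = N, exact = use_exact),
            class = "wx_test")
}

#' @export
print.wx_test <- function(x, ...) {
  cat("Wilcoxon rank-sum test (genotype mean effect)\n")
  cat(sprintf("  U = %g, Z = %.4f, two-sided p = %.4g%s\n",
              x$U, x$Z, x$p, if (x$exact) " (exact)" else ""))
  cat(sprintf("  chi-square score = %.4f (df = 1)\n", x$chi2))
  invisible(x)
}
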