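#' Per-genotype phenotype moments at one marker
#'
#' Sample size, mean, standard deviation (n - 1 denominator) and median of
#' the phenotype within each homozygote group, labelled \code{low}/\code{high}
#' by sample SD. When the two SDs tie exactly, the \code{allele_a} homozygote
#' (call 0) is labelled low.
#'
#' @param y numeric phenotype vector aligned with \code{groups$calls}.
#' @param groups a \code{\link{genotype_groups}} result with K = 2.
#' @return list with elements \code{low} and \code{high} (each \code{n},
#'   \code{mean}, \code{sd}, \code{median}, \code{call}), and \code{p_low},
#'   the frequency of the low-variance genotype (the LAF in inbred lines).
#' @export
genotype_moments <- function(y, groups) {
  stopifnot(inherits(groups, "geno_groups"))
  if (groups$K != 2L) stop("need both homozygote groups (K = 2)")
  if (any(groups$n < 2L)) stop("each genotype group needs >= 2 observations for an SD")
  calls <- groups$calls
  mom <- lapply(c(0L, 2L), function(g) {
    v <- y[!is.na(calls) & calls == g]
    list(n = length(v), mean = mean(v), sd = stats::sd(v),
         median = stats::median(v), call = g)
  })
  # high-variance genotype = larger sample SD; tie -> allele_a homozygote is low
  if (mom[[1L]]$sd <= mom[[2L]]$sd) {
    low <- mom[[1L]]; high <- mom[[2L]]
  } else {
    low <- mom[[2L]]; high <- mom[[1L]]
  }
  list(low = low, high = high, p_low = low$n / groups$N)
}

#' Single-locus decomposition of the phenotypic variance
#'
#' For a biallelic locus in fully homozygous lines, with low-variance allele
#' frequency p (and q = 1 - p), per-genotype means and standard deviations,
#' the phenotypic variance splits exactly into
#' \deqn{\sigma^2_P = \sigma^2_m + \sigma^2_d + \sigma^2_\epsilon,}
#' where \eqn{\sigma^2_m = p q d_\mu^2} is the variance from the mean shift
#' (the locus's additive variance: no dominance in inbreds),
#' \eqn{\sigma^2_d = p q d_\sigma^2} is the variance of the per-genotype SD
#' (the variance-heterogeneity component) and
#' \eqn{\sigma^2_\epsilon = (p \sigma_{low} + q \sigma_{high})^2} the residual
#' (the squared mean per-genotype SD). The heritability-like ratios are
#' \eqn{h^2_m = \sigma^2_m / \sigma^2_P} and
#' \eqn{h^2_d = \sigma^2_d / \sigma^2_P}.
#'
#' Labels are canonicalised so that the high-variance genotype is the one
#' with the larger SD (\eqn{d_\sigma \ge 0}); supplying exchanged labels with
#' p and q swapped returns the identical decomposition.
#'
#' @param p_low frequency of the low-variance allele (LAF), in (0, 1).
#' @param mean_low,mean_high per-genotype phenotype means.
#' @param sd_low,sd_high per-genotype phenotype standard deviations (>= 0).
#' @return An object of class \code{"vardecomp"}: list with \code{p_low},
#'   \code{q_high}, \code{mean_low}, \code{mean_high}, \code{sd_low},
#'   \code{sd_high}, \code{d_mu}, \code{d_sigma}, \code{s2_m}, \code{s2_d},
#'   \code{s2_eps}, \code{s2_P}, \code{h2_m}, \code{h2_d}.
#' @examples
#' # molybdenum-transporter example: two homozygote classes with means
#' # 0.22 / 1.35 and SDs 0.10 / 0.59 at LAF 0.5
#' decompose_locus(0.5, 0.22, 1.35, 0.10, 0.59)
#' @export
decompose_locus <- function(p_low, mean_low, mean_high, sd_low, sd_high) {
  if (!is.finite(p_low) || p_low <= 0 || p_low >= 1) {
    stop("p_low must lie strictly between 0 and 1")
  }
  if (sd_low < 0 || sd_high < 0) stop("standard deviations must be >= 0")
  if (sd_low > sd_high) {  # canonicalise: 'high' is the high-variance genotype
    tmp <- sd_low; sd_low <- sd_high; sd_high <- tmp
    tmp <- mean_low; mean_low <- mean_high; mean_high <- tmp
    p_low <- 1 - p_low
  }
  q <- 1 - p_low
  d_mu <- mean_high - mean_low
  d_sigma <- sd_high - sd_low
  s2_m <- p_low * q * d_mu^2
  s2_d <- p_low * q * d_sigma^2
  s2_eps <- (p_low * sd_low + q * sd_high)^2
  s2_P <- s2_m + s2_d + s2_eps
  if (s2_P > 0) {
    h2_m <- s2_m / s2_P
    h2_d <- s2_d / s2_P
  } else {
    h2_m <- 0; h2_d <- 0
  }
  structure(list(p_low = p_low, q_high = q,
                 mean_low = mean_low, mean_high = mean_high,
                 sd_low = sd_low, sd_high = sd_high,
                 d_mu = d_mu, d_sigma = d_sigma,
                 s2_m = s2_m, s2_d = s2_d, s2_eps = s2_eps, s2_P = s2_P,
                 h2_m = h2_m, h2_d = h2_d),
            class = "vardecomp")
}

#' @export
print.vardecomp <- function(x, digits = 4, ...) {
  cat("Single-locus variance decomposition (inbred biallelic)\n")
  cat(sprintf("  LAF p = %.4g (HAF q = %.4g); d_mu = %.4g, d_sigma = %.4g\n",
              x$p_low, x$q_high, x$d_mu, x$d_sigma))
  cat(sprintf("  s2_m = %.*g  s2_d = %.*g  s2_eps = %.*g  s2_P = %.*g\n",
              digits, x$s2_m, digits, x$s2_d, digits, x$s2_eps, digits, x$s2_P))
  cat(sprintf("  h2_m = %.1f%%  h2_d = %.1f%%\n", 100 * x$h2_m, 100 * x$h2_d))
  invisible(x)
}

#' Decompose an observed marker
#'
#' Plug-in estimation: sample genotype frequencies and per-genotype sample
#' moments replace the population quantities in \code{\link{decompose_locus}}.
#'
#' @inheritParams genotype_moments
#' @return A \code{"vardecomp"}.
#' @export
decompose_marker <- function(y, groups) {
  m <- genotype_moments(y, groups)
  decompose_locus(m$p_low, m$low$mean, m$high$mean, m$low$sd, m$high$sd)
}

#' Low-variance allele frequency maximising h2_m and h2_d
#'
#' At fixed per-genotype moments both heritability ratios are maximised at
#' LAF = sd_high / (sd_high + sd_low); only without variance heterogeneity
#' does the optimum sit at 0.5. The optimum does not depend on the mean
#' difference.
#'
#' @param sd_high,sd_low per-genotype standard deviations, not both zero.
#' @return optimal LAF in (0, 1).
#' @export
optimal_laf <- function(sd_high, sd_low) {
  if (sd_high < 0 || sd_low < 0) stop("standard deviations must be >= 0")
  if (sd_high + sd_low <= 0) stop("both SDs are zero: optimum undefined")
  sd_high / (sd_high + sd_low)
}

#' Variance-partition curves over allele frequency
#'
#' Evaluates the decomposition across a grid of LAF values at fixed
#' per-genotype moments, tracing how h2_m and h2_d change with allele
#' frequency.
#'
#' @inheritParams decompose_locus
#' @param grid vector of LAF values strictly inside (0, 1).
#' @return data frame with columns \code{laf}, \code{h2_m}, \code{h2_d}.
#' @export
h2_curves <- function(mean_low, mean_high, sd_low, sd_high,
                      grid = seq(0.01, 0.99, by = 0.01)) {
  if (any(grid <= 0 | grid >= 1)) stop("grid must lie strictly inside (0, 1)")
  d_mu <- mean_high - mean_low
  d_sigma <- sd_high - sd_low
  pq <- grid * (1 - grid)
  s2_m <- pq * d_mu^2
  s2_d <- pq * d_sigma^2
  s2_P <- s2_m + s2_d + (grid * sd_low + (1 - grid) * sd_high)^2
  data.frame(laf = grid,
             h2_m = ifelse(s2_P > 0, s2_m / s2_P, 0),
             h2_d = ifelse(s2_P > 0, s2_d / s2_P, 0))
}

#' Coefficient of variation
#'
#' @param mean non-zero mean.
#' @param sd standard deviation.
#' @return sd / mean.
#' @export
coefficient_of_variation <- function(mean, sd) {
  if (any(mean == 0)) stop("CV undefined at mean 0")
  sd / mean
}

#' Rank correlations of median deviations across traits
#'
#' Per trait, subtracts the trait median (optionally taking absolute values),
#' then computes Spearman rank correlations on pairwise complete cases.
#' Used to ask whether accessions that deviate strongly from the median of one
#' trait also deviate in correlated traits (e.g. propagation of variability
#' through an expression pathway).
#'
#' @param traits numeric matrix or data frame, accessions in rows, traits in
#'   columns; NA allowed.
#' @param mode \code{"signed"} (default: raw deviations) or \code{"absolute"}.
#' @return trait-by-trait correlation matrix; cells with fewer than 3
#'   complete pairs are NA.
#' @export
median_deviation_correlation <- function(traits, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  m <- as.matrix(traits)
  if (!is.numeric(m)) stop("traits must be numeric")
  dev <- sweep(m, 2L, apply(m, 2L, stats::median, na.rm = TRUE))
  if (mode == "absolute") dev <- abs(dev)
  rho <- suppressWarnings(
    stats::cor(dev, method = "spearman", use = "pairwise.complete.obs"))
  npairs <- crossprod(!is.na(dev))
  rho[npairs < 3L] <- NA_real_
  rho
}
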