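#' Scan configuration
#'
#' Tuning parameters for \code{\link{vgwas}}. Defaults mirror the
#' conservative inbred-panel workflow: markers with MAF below 10\% are
#' removed, significance is Bonferroni-corrected at alpha = 0.05 over the
#' markers actually tested for the trait, genomic control uses the
#' zero-intercept regression estimator with lambda floored at 1, and traits
#' whose variance-scan inflation exceeds 1.5 are flagged for triage.
#'
#' @param maf_min minimum minor-allele frequency, in [0, 0.5).
#' @param alpha nominal significance level, in (0, 1).
#' @param gc_method \code{"regression"} or \code{"median"}.
#' @param gc_clamp floor lambda at 1 when correcting.
#' @param lambda_max trait-triage threshold on the variance-scan lambda
#'   (flagged when strictly greater).
#' @param min_group_size smallest genotype group admitted to testing.
#' @param bonferroni_m denominator for the Bonferroni threshold:
#'   \code{"tested"} (markers tested for this trait, default) or
#'   \code{"all"} (all markers in the input panel).
#' @param seed integer seed for any stochastic step (the scan itself is
#'   deterministic; recorded for provenance).
#' @return list of class \code{"scan_config"}.
#' @export
scan_config <- function(maf_min = 0.10, alpha = 0.05,
                        gc_method = c("regression", "median"),
                        gc_clamp = TRUE, lambda_max = 1.5,
                        min_group_size = 2L,
                        bonferroni_m = c("tested", "all"),
                        seed = 1L) {
  gc_method <- match.arg(gc_method)
  bonferroni_m <- match.arg(bonferroni_m)
  if (maf_min < 0 || maf_min >= 0.5) stop("maf_min must lie in [0, 0.5)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (lambda_max <= 0) stop("lambda_max must be positive")
  structure(list(maf_min = maf_min, alpha = alpha, gc_method = gc_method,
                 gc_clamp = isTRUE(gc_clamp), lambda_max = lambda_max,
                 min_group_size = as.integer(min_group_size),
                 bonferroni_m = bonferroni_m, seed = as.integer(seed)),
            class = "scan_config")
}

#' Bonferroni-corrected p-value threshold
#'
#' @param m_tests number of tests (>= 1).
#' @param alpha nominal level.
#' @return alpha / m_tests.
#' @export
bonferroni_threshold <- function(m_tests, alpha = 0.05) {
  if (m_tests < 1L) stop("need at least one test")
  alpha / m_tests
}

#' Genome scan for variance-controlling and mean-effect loci
#'
#' Fits, per marker, the Brown--Forsythe variance-heterogeneity test and the
#' Wilcoxon rank-sum mean test for one trait in an inbred panel, applies
#' genomic control to each scan's chi-square scores, Bonferroni-corrects the
#' significance threshold, and decomposes each tested marker's contribution
#' to the phenotypic variance into mean-shift and variance-heterogeneity
#' parts.
#'
#' Markers are filtered before testing and carry a reason code:
#' \code{monomorphic} (one genotype class only), \code{low_maf}
#' (MAF < \code{maf_min}), \code{low_count} (a genotype group smaller than
#' \code{min_group_size}) or \code{tested}. Allele frequencies are computed
#' on the per-trait analysed sample (complete cases). The inflation factor is
#' estimated separately for the two scans over the tested markers; a trait
#' whose variance-scan lambda exceeds \code{lambda_max} is flagged as
#' triaged (results to be interpreted as structure-confounded).
#'
#' @param G a \code{\link{geno_matrix}}.
#' @param P phenotype data frame (see \code{\link{read_phenotypes}}).
#' @param trait trait name in \code{P}.
#' @param config a \code{\link{scan_config}}.
#' @return An object of class \code{"vgwas"}: list with \code{table} (one row
#'   per marker: map fields, \code{maf}, \code{N}, \code{n_low},
#'   \code{n_high}, \code{reason}, \code{bf_F}, \code{bf_chi2}, \code{bf_p},
#'   \code{bf_p_gc}, \code{wx_Z}, \code{wx_p}, \code{wx_p_gc}, \code{laf},
#'   \code{d_mu}, \code{d_sigma}, \code{h2_m}, \code{h2_d}), \code{trait},
#'   \code{n_accessions}, \code{m_tested}, \code{lambda_bf},
#'   \code{lambda_wx}, \code{threshold}, \code{triaged}, \code{config} and
#'   \code{call}.
#' @seealso \code{\link{summary.vgwas}}, \code{\link{plot.vgwas}},
#'   \code{\link{scan_exports}}
#' @export
vgwas <- function(G, P, trait, config = scan_config()) {
  stopifnot(inherits(G, "geno_matrix"), inherits(config, "scan_config"))
  acc <- align_complete_cases(G, P, trait)
  y <- P[[trait]][match(acc, P$accession_id)]
  m <- nrow(G$calls)
  tab <- data.frame(marker_id = G$map$marker_id, chrom = G$map$chrom,
                    pos = G$map$pos, maf = NA_real_, N = NA_integer_,
                    n_low = NA_integer_, n_high = NA_integer_,
                    reason = NA_character_,
                    bf_F = NA_real_, bf_chi2 = NA_real_, bf_p = NA_real_,
                    bf_p_gc = NA_real_,
                    wx_Z = NA_real_, wx_p = NA_real_, wx_p_gc = NA_real_,
                    laf = NA_real_, d_mu = NA_real_, d_sigma = NA_real_,
                    h2_m = NA_real_, h2_d = NA_real_,
                    stringsAsFactors = FALSE)
  calls_sub <- G$calls[, acc, drop = FALSE]
  for (i in seq_len(m)) {
    gr <- groups_from_calls(calls_sub[i, ])
    tab$N[i] <- gr$N
    tab$n_low[i] <- gr$n_low
    tab$n_high[i] <- gr$n_high
    if (gr$N == 0L || gr$K < 2L) {
      tab$reason[i] <- "monomorphic"; tab$maf[i] <- 0
      next
    }
    tab$maf[i] <- maf(gr)
    if (tab$maf[i] < config$maf_min) {
      tab$reason[i] <- "low_maf"
      next
    }
    if (any(gr$n < config$min_group_size) || gr$N < gr$K + 1L) {
      tab$reason[i] <- "low_count"
      next
    }
    tab$reason[i] <- "tested"
    bf <- brown_forsythe(y, gr, min_group_size = config$min_group_size)
    wx <- wilcoxon_rank_sum(y, gr, min_group_size = config$min_group_size)
    tab$bf_F[i] <- bf$F
    tab$bf_chi2[i] <- bf$chi2
    tab$bf_p[i] <- bf$p_chi2
    tab$wx_Z[i] <- wx$Z
    tab$wx_p[i] <- wx$p
    if (all(gr$n >= 2L)) {
      d <- decompose_marker(y, gr)
      tab$laf[i] <- d$p_low
      tab$d_mu[i] <- d$d_mu
      tab$d_sigma[i] <- d$d_sigma
      tab$h2_m[i] <- d$h2_m
      tab$h2_d[i] <- d$h2_d
    }
  }
  tested <- which(tab$reason == "tested")
  if (length(tested) == 0L) {
    stop(sprintf(
      "no marker passed the filters for '%s' (monomorphic: %d, low_maf: %d, low_count: %d)",
      trait, sum(tab$reason == "monomorphic"), sum(tab$reason == "low_maf"),
      sum(tab$reason == "low_count")))
  }
  wx_chi2 <- tab$wx_Z[tested]^2
  if (length(tested) >= 2L) {
    estimator <- if (config$gc_method == "regression") lambda_regression else lambda_median
    gc_bf <- estimator(tab$bf_chi2[tested][is.finite(tab$bf_chi2[tested])])
    gc_wx <- estimator(wx_chi2)
    bf_fin <- is.finite(tab$bf_chi2) & tab$reason == "tested"
    tab$bf_p_gc[bf_fin] <-
      as.numeric(gc_correct(tab$bf_chi2[bf_fin], gc_bf, clamp = config$gc_clamp))
    tab$bf_p_gc[tab$reason == "tested" & !is.finite(tab$bf_chi2)] <- .Machine$double.xmin
    tab$wx_p_gc[tested] <- as.numeric(gc_correct(wx_chi2, gc_wx, clamp = config$gc_clamp))
    lambda_bf <- gc_bf$lambda
    lambda_wx <- gc_wx$lambda
  } else {
    # a one-marker genome carries no information about inflation: report the
    # nominal p-values uncorrected and no lambda
    tab$bf_p_gc[tested] <- tab$bf_p[tested]
    tab$wx_p_gc[tested] <- tab$wx_p[tested]
    lambda_bf <- NA_real_
    lambda_wx <- NA_real_
  }
  m_denom <- if (config$bonferroni_m == "tested") length(tested) else m
  structure(list(table = tab, trait = trait, n_accessions = length(acc),
                 m_tested = length(tested),
                 lambda_bf = lambda_bf, lambda_wx = lambda_wx,
                 threshold = bonferroni_threshold(m_denom, config$alpha),
                 triaged = isTRUE(lambda_bf > config$lambda_max),
                 config = config, call = match.call()),
            class = "vgwas")
}

#' @export
print.vgwas <- function(x, ...) {
  cat(sprintf("vGWAS scan of trait '%s' (%d accessions)\n", x$trait, x$n_accessions))
  cat(sprintf("  markers: %d total, %d tested\n", nrow(x$table), x$m_tested))
  cat(sprintf("  inflation: lambda_bf = %.3f, lambda_wx = %.3f%s\n",
              x$lambda_bf, x$lambda_wx,
              if (x$triaged) "  [TRIAGED: lambda_bf > lambda_max]" else ""))
  cat(sprintf("  Bonferroni threshold: %.3g (alpha = %g)\n",
              x$threshold, x$config$alpha))
  n_sig <- sum(x$table$bf_p_gc <= x$threshold, na.rm = TRUE)
  cat(sprintf("  significant variance-heterogeneity markers: %d\n", n_sig))
  invisible(x)
}

#' Summarise a vGWAS scan
#'
#' @param object a \code{"vgwas"} fit.
#' @param n_top number of top markers to display per scan.
#' @param ... unused.
#' @return invisibly, a list with counts, lambdas, threshold and top-marker
#'   tables.
#' @export
summary.vgwas <- function(object, n_top = 5L, ...) {
  tab <- object$table
  tested <- tab[tab$reason == "tested", ]
  top_bf <- tested[order(tested$bf_p_gc), ][seq_len(min(n_top, nrow(tested))), ]
  top_wx <- tested[order(tested$wx_p_gc), ][seq_len(min(n_top, nrow(tested))), ]
  out <- list(trait = object$trait,
              n_accessions = object$n_accessions,
              counts = table(tab$reason),
              lambda_bf = object$lambda_bf, lambda_wx = object$lambda_wx,
              threshold = object$threshold, triaged = object$triaged,
              n_sig_bf = sum(tested$bf_p_gc <= object$threshold, na.rm = TRUE),
              n_sig_wx = sum(tested$wx_p_gc <= object$threshold, na.rm = TRUE),
              top_bf = top_bf, top_wx = top_wx)
  class(out) <- "summary.vgwas"
  out
}

#' @export
print.summary.vgwas <- function(x, ...) {
  cat(sprintf("vGWAS scan of trait '%s' (%d accessions)\n", x$trait, x$n_accessions))
  cat("  marker disposition: ",
      paste(sprintf("%s %d", names(x$counts), x$counts), collapse = ", "), "\n")
  cat(sprintf("  lambda_bf = %.3f, lambda_wx = %.3f%s\n", x$lambda_bf, x$lambda_wx,
              if (x$triaged) "  [TRIAGED]" else ""))
  cat(sprintf("  Bonferroni threshold %.3g: %d significant (variance), %d (mean)\n",
              x$threshold, x$n_sig_bf, x$n_sig_wx))
  cat("\nTop variance-heterogeneity markers:\n")
  print(x$top_bf[, c("marker_id", "chrom", "pos", "maf", "bf_F", "bf_p_gc",
                     "h2_m", "h2_d")], row.names = FALSE, digits = 4)
  cat("\nTop mean-effect markers:\n")
  print(x$top_wx[, c("marker_id", "chrom", "pos", "maf", "wx_Z", "wx_p_gc",
                     "h2_m", "h2_d")], row.names = FALSE, digits = 4)
  invisible(x)
}

#' Manhattan and QQ plots for a scan
#'
#' @param x a \code{"vgwas"} fit.
#' @param type \code{"manhattan"} or \code{"qq"}.
#' @param which \code{"bf"} (variance scan) or \code{"wx"} (mean scan).
#' @param ... passed to the underlying plot call.
#' @export
plot.vgwas <- function(x, type = c("manhattan", "qq"), which = c("bf", "wx"), ...) {
  type <- match.arg(type)
  which <- match.arg(which)
  ex <- scan_exports(x, which = which)
  if (type == "manhattan") {
    d <- ex$manhattan
    chrf <- factor(d$chrom, levels = unique(d$chrom))
    offs <- c(0, cumsum(tapply(d$pos, chrf, max)))
    xcoord <- d$pos + offs[as.integer(chrf)]
    graphics::plot(xcoord, d$log10p_gc, pch = 20, cex = 0.5,
                   col = c("grey30", "steelblue")[1 + as.integer(chrf) %% 2],
                   xlab = "genome position", ylab = "-log10 p (GC)",
                   main = sprintf("%s scan: %s", toupper(which), x$trait), ...)
    graphics::abline(h = -log10(x$threshold), col = "red", lty = 2)
  } else {
    d <- ex$qq
    graphics::plot(d$expected, d$observed, pch = 20, cex = 0.5,
                   xlab = "expected -log10 p", ylab = "observed -log10 p",
                   main = sprintf("QQ, %s scan: %s", toupper(which), x$trait), ...)
    graphics::abline(0, 1, col = "red")
  }
  invisible(x)
}

#' Tabular exports of a scan (Manhattan and QQ data)
#'
#' @param scan a \code{"vgwas"} fit.
#' @param which \code{"bf"} or \code{"wx"}.
#' @return list with data frames \code{manhattan} (\code{chrom}, \code{pos},
#'   \code{log10p}, \code{log10p_gc}; one row per tested marker) and
#'   \code{qq} (\code{expected}, \code{observed}, ascending expected column).
#' @export
scan_exports <- function(scan, which = c("bf", "wx")) {
  stopifnot(inherits(scan, "vgwas"))
  which <- match.arg(which)
  tab <- scan$table[scan$table$reason == "tested", ]
  p <- if (which == "bf") tab$bf_p else tab$wx_p
  p_gc <- if (which == "bf") tab$bf_p_gc else tab$wx_p_gc
  man <- data.frame(chrom = tab$chrom, pos = tab$pos,
                    log10p = -log10(p), log10p_gc = -log10(p_gc),
                    stringsAsFactors = FALSE)
  n <- nrow(tab)
  qq <- data.frame(expected = -log10((n:1 - 0.5) / n),
                   observed = sort(-log10(p_gc), decreasing = FALSE))
  qq <- qq[order(qq$expected), ]
  rownames(qq) <- NULL
  list(manhattan = man, qq = qq)
}

#' Overlap between a mean scan and a variance scan
#'
#' Counts markers significant in each scan at a common threshold and in both,
#' and reports the joint fraction (both / either) with its per-mille value.
#'
#' @param p_gwas,p_vgwas p-value vectors of equal length (same markers).
#' @param threshold significance threshold.
#' @return list with \code{n_gwas}, \code{n_vgwas}, \code{n_both},
#'   \code{ratio_vgwas_gwas}, \code{joint_fraction}, \code{joint_per_mille}.
#' @export
compare_scans <- function(p_gwas, p_vgwas, threshold) {
  if (length(p_gwas) != length(p_vgwas)) stop("p-value vectors differ in length")
  sg <- !is.na(p_gwas) & p_gwas <= threshold
  sv <- !is.na(p_vgwas) & p_vgwas <= threshold
  n_both <- sum(sg & sv)
  n_either <- sum(sg | sv)
  joint <- if (n_either > 0) n_both / n_either else NA_real_
  list(n_gwas = sum(sg), n_vgwas = sum(sv), n_both = n_both,
       ratio_vgwas_gwas = if (sum(sg) > 0) sum(sv) / sum(sg) else NA_real_,
       joint_fraction = joint,
       joint_per_mille = 1000 * joint)
}

#' Write scan outputs to TSV/JSON files
#'
#' Writes \code{PREFIX.scan.tsv} (full marker table),
#' \code{PREFIX.summary.json} (lambdas, threshold, counts),
#' \code{PREFIX.qq.tsv} and \code{PREFIX.manhattan.tsv} (variance scan).
#'
#' @param scan a \code{"vgwas"} fit.
#' @param prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_scan <- function(scan, prefix) {
  stopifnot(inherits(scan, "vgwas"))
  paths <- paste0(prefix, c(".scan.tsv", ".summary.json", ".qq.tsv", ".manhattan.tsv"))
  utils::write.table(scan$table, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  counts <- table(scan$table$reason)
  jsonlite::write_json(
    list(trait = scan$trait, n_accessions = scan$n_accessions,
         m_tested = scan$m_tested,
         lambda_bf = scan$lambda_bf, lambda_wx = scan$lambda_wx,
         bonferroni_threshold = scan$threshold, triaged = scan$triaged,
         n_significant_bf = sum(scan$table$bf_p_gc <= scan$threshold, na.rm = TRUE),
         n_significant_wx = sum(scan$table$wx_p_gc <= scan$threshold, na.rm = TRUE),
         reason_counts = as.list(stats::setNames(as.integer(counts), names(counts)))),
    paths[2L], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ex <- scan_exports(scan, which = "bf")
  utils::write.table(ex$qq, paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ex$manhattan, paths[4L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
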