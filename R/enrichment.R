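#' Best SNP rank per candidate gene
#'
#' Ranks the tested markers of a scan by ascending GC-corrected p-value
#' (ties receive the average of the tied positions, rounded down, so ranks
#' are deterministic integers) and assigns each candidate gene the best rank
#' among SNPs falling within \code{window} bp of its interval.
#'
#' @param scan a \code{"vgwas"} fit, or a marker table in its \code{table}
#'   layout (e.g. a re-read \code{PREFIX.scan.tsv}).
#' @param genes data frame from \code{\link{read_gene_intervals}} (1-based
#'   inclusive \code{start}/\code{end}).
#' @param window bp added on both sides of each gene (default 20000).
#' @param which rank the variance scan (\code{"bf"}) or mean scan
#'   (\code{"wx"}).
#' @return named integer vector of best ranks, NA for genes with no SNP in
#'   the window.
#' @export
gene_best_ranks <- function(scan, genes, window = 20000L, which = c("bf", "wx")) {
  which <- match.arg(which)
  tab <- if (inherits(scan, "vgwas")) scan$table else as.data.frame(scan)
  tab <- tab[tab$reason == "tested", ]
  if (nrow(tab) == 0L) stop("scan has no tested (ranked) markers")
  p <- if (which == "bf") tab$bf_p_gc else tab$wx_p_gc
  rk <- as.integer(floor(rank(p, ties.method = "average")))
  out <- stats::setNames(rep(NA_integer_, nrow(genes)), genes$gene_id)
  for (i in seq_len(nrow(genes))) {
    hit <- tab$chrom == genes$chrom[i] &
      tab$pos >= genes$start[i] - window &
      tab$pos <= genes$end[i] + window
    if (any(hit)) out[i] <- min(rk[hit])
  }
  out
}

#' Merge GWAS and vGWAS gene ranks
#'
#' Combines two gene rank maps by taking, per gene, the better (smaller) of
#' the mean-scan and variance-scan ranks, and summarises how often the
#' variance scan improves on the mean scan alone. "Improved" means the
#' combined rank is strictly smaller than the GWAS rank.
#'
#' @param gwas_ranks,vgwas_ranks named integer vectors over the same gene
#'   universe (as from \code{\link{gene_best_ranks}}).
#' @return list with \code{table} (data frame: \code{gene_id},
#'   \code{best_rank_gwas}, \code{best_rank_vgwas},
#'   \code{best_rank_combined}, \code{improved}) and \code{summary}
#'   (\code{n_genes}, \code{n_improved}, \code{fraction_improved},
#'   \code{mean_rank_change} over improved genes).
#' @export
merge_and_score <- function(gwas_ranks, vgwas_ranks) {
  if (!setequal(names(gwas_ranks), names(vgwas_ranks))) {
    stop("the two rank maps must cover the same gene universe")
  }
  vg <- vgwas_ranks[names(gwas_ranks)]
  comb <- pmin(gwas_ranks, vg, na.rm = TRUE)
  comb[is.na(gwas_ranks) & is.na(vg)] <- NA_integer_
  both <- !is.na(gwas_ranks) & !is.na(vg)
  improved <- both & comb < gwas_ranks
  tab <- data.frame(gene_id = names(gwas_ranks),
                    best_rank_gwas = as.integer(gwas_ranks),
                    best_rank_vgwas = as.integer(vg),
                    best_rank_combined = as.integer(comb),
                    improved = improved,
                    stringsAsFactors = FALSE, row.names = NULL)
  delta <- gwas_ranks[improved] - comb[improved]
  list(table = tab,
       summary = list(n_genes = sum(both),
                      n_improved = sum(improved),
                      fraction_improved = if (sum(both) > 0)
                        sum(improved) / sum(both) else NA_real_,
                      mean_rank_change = if (any(improved))
                        mean(delta) else 0))
}
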