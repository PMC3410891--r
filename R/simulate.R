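#' Simulation configuration for an inbred biallelic panel
#'
#' Parameters of the standard-deviation model used throughout the simulation
#' studies: each line is fully homozygous, one designated causal marker
#' assigns each line a genotype-specific phenotype mean and standard
#' deviation, and the phenotype is mu_g + sigma_g * epsilon with standardised
#' noise epsilon. Optional population structure draws subpopulation allele
#' frequencies from a Balding--Nichols beta model with differentiation
#' parameter \code{fst} and adds a per-subpopulation phenotype mean offset.
#'
#' Defaults emulate the kind of panel the method targets: about 200
#' homozygous lines, a common causal variant (LAF 0.5), unit baseline
#' environmental SD and no structure.
#'
#' @param n_lines number of inbred lines.
#' @param n_markers number of biallelic markers (marker 1 is the causal one).
#' @param laf low-variance allele frequency of the causal marker (and the
#'   ancestral frequency of every null marker).
#' @param mean_low,mean_high per-genotype phenotype means.
#' @param sd_low,sd_high per-genotype phenotype standard deviations.
#' @param n_subpops number of subpopulations (1 = unstructured).
#' @param fst Balding--Nichols differentiation parameter in [0, 1).
#' @param subpop_shift SD of the per-subpopulation phenotype mean offsets.
#' @param noise \code{"normal"} (standard normal) or \code{"heavy"}
#'   (t with 3 df scaled to unit variance), or a function(n) returning n
#'   standardised draws.
#' @param seed integer seed; the dataset is a deterministic function of the
#'   configuration.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_lines = 200L, n_markers = 1000L, laf = 0.5,
                       mean_low = 0, mean_high = 0, sd_low = 1, sd_high = 1,
                       n_subpops = 1L, fst = 0, subpop_shift = 0,
                       noise = "normal", seed = 1L) {
  if (laf <= 0 || laf >= 1) stop("laf must lie strictly between 0 and 1")
  if (sd_low < 0 || sd_high < 0) stop("SDs must be >= 0")
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (n_subpops < 1L) stop("need at least one subpopulation")
  structure(list(n_lines = as.integer(n_lines),
                 n_markers = as.integer(n_markers), laf = laf,
                 mean_low = mean_low, mean_high = mean_high,
                 sd_low = sd_low, sd_high = sd_high,
                 n_subpops = as.integer(n_subpops), fst = fst,
                 subpop_shift = subpop_shift, noise = noise,
                 seed = as.integer(seed)),
            class = "sim_config")
}

noise_fun <- function(noise) {
  if (is.function(noise)) return(noise)
  switch(noise,
         normal = stats::rnorm,
         heavy = function(n) stats::rt(n, df = 3) / sqrt(3),  # unit variance
         stop("unknown noise model: ", noise))
}

#' Simulate an inbred genotype/phenotype dataset
#'
#' Draws genotypes marker-by-marker (independent markers), assigns the
#' phenotype from the causal marker under the standard-deviation model and
#' returns the truth record alongside. Fully reproducible from the seed in
#' the configuration.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{geno} (a \code{\link{geno_matrix}}), \code{pheno}
#'   (phenotype data frame with trait \code{sim_trait}) and \code{truth}
#'   (causal marker id, model parameters, subpopulation assignment and
#'   offsets).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_lines
  m <- cfg$n_markers
  subpop <- rep(seq_len(cfg$n_subpops), length.out = n)
  subpop <- sort(subpop)
  shifts <- if (cfg$subpop_shift > 0) {
    stats::rnorm(cfg$n_subpops, 0, cfg$subpop_shift)
  } else rep(0, cfg$n_subpops)
  # subpopulation-specific low-allele frequencies, Balding-Nichols style
  freq <- matrix(cfg$laf, m, cfg$n_subpops)
  if (cfg$fst > 0 && cfg$n_subpops > 1L) {
    a <- cfg$laf * (1 - cfg$fst) / cfg$fst
    b <- (1 - cfg$laf) * (1 - cfg$fst) / cfg$fst
    freq[] <- stats::rbeta(m * cfg$n_subpops, a, b)
  }
  calls <- matrix(0L, m, n)
  for (s in seq_len(cfg$n_subpops)) {
    idx <- which(subpop == s)
    low <- matrix(stats::runif(m * length(idx)) < freq[, s], m, length(idx))
    calls[, idx] <- ifelse(low, 0L, 2L)
  }
  g <- calls[1L, ]
  mu <- ifelse(g == 0L, cfg$mean_low, cfg$mean_high)
  sg <- ifelse(g == 0L, cfg$sd_low, cfg$sd_high)
  eps <- noise_fun(cfg$noise)(n)
  y <- mu + sg * eps + shifts[subpop]
  ids <- sprintf("line_%03d", seq_len(n))
  map <- data.frame(marker_id = sprintf("mk_%05d", seq_len(m)),
                    chrom = "1", pos = seq_len(m) * 1000L,
                    allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
  G <- geno_matrix(calls, map, ids)
  P <- data.frame(accession_id = ids, sim_trait = y, stringsAsFactors = FALSE)
  truth <- list(causal_id = map$marker_id[1L], laf = cfg$laf,
                mean_low = cfg$mean_low, mean_high = cfg$mean_high,
                sd_low = cfg$sd_low, sd_high = cfg$sd_high,
                subpop = subpop, shifts = shifts, seed = cfg$seed)
  list(geno = G, pheno = P, truth = truth)
}

# one null/effect replicate of the causal-marker test, used by the studies;
# returns the BF p-value (F reference) or NA when the marker is untestable
bf_replicate <- function(n, laf, mean_low, mean_high, sd_low, sd_high,
                         noise = stats::rnorm) {
  g <- ifelse(stats::runif(n) < laf, 0L, 2L)
  gr <- groups_from_calls(g)
  if (gr$K < 2L || any(gr$n < 2L)) return(NA_real_)
  mu <- ifelse(g == 0L, mean_low, mean_high)
  sg <- ifelse(g == 0L, sd_low, sd_high)
  y <- mu + sg * noise(n)
  brown_forsythe(y, gr)$p_F
}

study_row <- function(n, laf, sd_ratio, d_mu, alpha, p) {
  p <- p[!is.na(p)]
  r <- mean(p <= alpha)
  data.frame(n = n, laf = laf, sd_ratio = sd_ratio, d_mu = d_mu,
             alpha = alpha, rate = r,
             mc_se = sqrt(r * (1 - r) / length(p)), n_reps = length(p))
}

#' False-positive-rate study for the variance-heterogeneity test
#'
#' Simulates null markers (equal per-genotype means and SDs) on a grid of
#' sample sizes and allele frequencies and reports the empirical rejection
#' rate of the Brown--Forsythe test at the stated level, with its Monte-Carlo
#' standard error. Replicates whose marker comes out untestable (a genotype
#' group below 2) are dropped.
#'
#' @param n_values,laf_values grid of sample sizes and LAFs.
#' @param alpha rejection level.
#' @param n_reps replicates per grid cell.
#' @param seed integer seed.
#' @return data frame with one row per cell: \code{n}, \code{laf},
#'   \code{sd_ratio} (1), \code{d_mu} (0), \code{alpha}, \code{rate},
#'   \code{mc_se}, \code{n_reps}.
#' @export
fpr_study <- function(n_values = 200L, laf_values = c(0.1, 0.3, 0.5),
                      alpha = 0.05, n_reps = 10000L, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (n in n_values) for (laf in laf_values) {
    p <- vapply(seq_len(n_reps), function(r)
      bf_replicate(n, laf, 0, 0, 1, 1), numeric(1L))
    out[[length(out) + 1L]] <- study_row(n, laf, 1, 0, alpha, p)
  }
  do.call(rbind, out)
}

#' Power study for the variance-heterogeneity test
#'
#' As \code{\link{fpr_study}} but with a true variance-heterogeneity effect:
#' sd_high = sd_ratio * sd_low (sd_low = 1) and an optional mean shift d_mu.
#'
#' @param n_values,laf_values,sd_ratios,d_mu_values grid.
#' @param alpha rejection level.
#' @param n_reps replicates per cell.
#' @param seed integer seed.
#' @return data frame as in \code{\link{fpr_study}}.
#' @export
power_study <- function(n_values = 200L, laf_values = 0.5,
                        sd_ratios = c(1, 2, 3), d_mu_values = 0,
                        alpha = 0.05, n_reps = 1000L, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (n in n_values) for (laf in laf_values)
    for (sr in sd_ratios) for (dm in d_mu_values) {
      p <- vapply(seq_len(n_reps), function(r)
        bf_replicate(n, laf, 0, dm, 1, sr), numeric(1L))
      out[[length(out) + 1L]] <- study_row(n, laf, sr, dm, alpha, p)
    }
  do.call(rbind, out)
}

#' Genomic control under a structured null genome
#'
#' Simulates genomes with subpopulation structure but no genotype-phenotype
#' effect beyond subpopulation mean offsets, runs the Brown--Forsythe scan on
#' every testable marker passing the MAF filter, and reports the inflation
#' factor before correction and recomputed on the corrected scores.
#'
#' @param cfg a \code{\link{sim_config}} with \code{n_subpops > 1}; its
#'   mean/SD parameters must describe a null effect (equal between
#'   genotypes).
#' @param n_reps number of simulated genomes.
#' @param maf_min MAF filter applied before estimating lambda.
#' @param seed integer seed; replicate r re-seeds the generator at
#'   \code{seed + r}.
#' @return data frame with \code{rep}, \code{lambda_pre}, \code{lambda_post}.
#' @export
gc_structure_study <- function(cfg, n_reps = 100L, maf_min = 0.10, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$mean_low != cfg$mean_high || cfg$sd_low != cfg$sd_high) {
    stop("gc_structure_study expects a null genotype-phenotype effect")
  }
  out <- data.frame(rep = seq_len(n_reps), lambda_pre = NA_real_,
                    lambda_post = NA_real_)
  for (r in seq_len(n_reps)) {
    cfg_r <- cfg
    cfg_r$seed <- as.integer(seed + r)
    d <- simulate_dataset(cfg_r)
    y <- d$pheno$sim_trait
    chi2 <- rep(NA_real_, cfg$n_markers)
    for (i in seq_len(cfg$n_markers)) {
      gr <- groups_from_calls(d$geno$calls[i, ])
      if (gr$K < 2L || any(gr$n < 2L) || maf(gr) < maf_min) next
      chi2[i] <- brown_forsythe(y, gr)$chi2
    }
    chi2 <- chi2[is.finite(chi2)]
    gc <- lambda_regression(chi2)
    out$lambda_pre[r] <- gc$lambda
    corrected <- attr(gc_correct(chi2, gc, clamp = TRUE), "chi2_corrected")
    out$lambda_post[r] <- lambda_regression(corrected)$lambda
  }
  out
}
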