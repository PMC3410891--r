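test_that("Bonferroni threshold arithmetic", {
  expect_equal(bonferroni_threshold(1, 0.05), 0.05)
  expect_equal(bonferroni_threshold(216130, 0.05), 0.05 / 216130)
  expect_equal(-log10(bonferroni_threshold(216130, 0.05)), 6.6357, tolerance = 1e-4)
  expect_error(bonferroni_threshold(0), "at least one")
})

test_that("scan config validates its ranges", {
  expect_error(scan_config(maf_min = 0.6), "maf_min")
  expect_error(scan_config(alpha = 0), "alpha")
  expect_identical(scan_config()$gc_method, "regression")
})

test_that("markers carry exactly one reason code and filters behave", {
  # 30 lines: marker 1 testable, marker 2 monomorphic, marker 3 low MAF,
  # marker 4 low count (one heterozygote group of size 1 via min_group_size)
  n <- 40L
  calls <- rbind(rep(c(0L, 2L), each = n / 2),
                 rep(0L, n),
                 c(rep(0L, 2L), rep(2L, n - 2L)),   # maf 0.05
                 c(0L, 0L, 0L, rep(2L, n - 3L)))    # maf 0.075 < 0.10
  map <- data.frame(marker_id = paste0("m", 1:4), chrom = "1",
                    pos = c(100L, 200L, 300L, 400L),
                    allele_a = "A", allele_b = "G")
  G <- geno_matrix(calls, map, sprintf("a%02d", 1:n))
  set.seed(1)
  P <- data.frame(accession_id = sprintf("a%02d", 1:n), y = rnorm(n))
  fit <- vgwas(G, P, "y", scan_config(maf_min = 0.10))
  expect_identical(fit$table$reason, c("tested", "monomorphic", "low_maf", "low_maf"))
  expect_true(all(!is.na(fit$table$reason)))
  expect_true(is.na(fit$table$bf_p[3]))  # no test run on filtered markers
  # low_count: raise min_group_size above a group
  fit2 <- vgwas(G, P, "y", scan_config(maf_min = 0, min_group_size = 4L))
  expect_identical(fit2$table$reason[3], "low_count")
  # every marker filtered out -> diagnostic error
  G3 <- geno_matrix(calls[2, , drop = FALSE], map[2, ], sprintf("a%02d", 1:n))
  expect_error(vgwas(G3, P, "y"), "monomorphic: 1")
})

test_that("a single strong variance locus is detected at study-like settings", {
  cfg <- sim_config(n_lines = 200L, n_markers = 250L, laf = 0.5,
                    mean_low = 0, mean_high = 0, sd_low = 1, sd_high = 3,
                    seed = 11L)
  d <- simulate_dataset(cfg)
  fit <- vgwas(d$geno, d$pheno, "sim_trait")
  tab <- fit$table
  best <- tab$marker_id[which.min(tab$bf_p)]
  expect_identical(best, d$truth$causal_id)
  expect_lt(tab$bf_p_gc[tab$marker_id == best], fit$threshold)
  # the mean scan shows nothing there: pure variance architecture
  expect_gt(tab$wx_p_gc[tab$marker_id == best], fit$threshold)
})

test_that("null genomes give no Bonferroni-significant marker in most runs", {
  hits <- vapply(1:10, function(s) {
    d <- simulate_dataset(sim_config(n_lines = 120L, n_markers = 150L,
                                     laf = 0.4, seed = 500L + s))
    fit <- vgwas(d$geno, d$pheno, "sim_trait")
    sum(fit$table$bf_p_gc <= fit$threshold, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.9)
})

test_that("scans are deterministic and GC-corrected p respects the clamp direction", {
  d <- simulate_dataset(sim_config(n_lines = 80L, n_markers = 60L, seed = 21L))
  f1 <- vgwas(d$geno, d$pheno, "sim_trait")
  f2 <- vgwas(d$geno, d$pheno, "sim_trait")
  expect_identical(f1$table, f2$table)
  tested <- f1$table$reason == "tested"
  if (f1$lambda_bf > 1) {
    expect_true(all(f1$table$bf_p_gc[tested] >= f1$table$bf_p[tested] - 1e-15))
  }
  # triage flag follows the strict lambda rule
  expect_identical(f1$triaged, f1$lambda_bf > f1$config$lambda_max)
})

test_that("removing a filtered marker leaves other statistics unchanged", {
  d <- simulate_dataset(sim_config(n_lines = 100L, n_markers = 40L, seed = 31L))
  fit_all <- vgwas(d$geno, d$pheno, "sim_trait")
  keep <- 2:40
  G2 <- geno_matrix(d$geno$calls[keep, ], d$geno$map[keep, ],
                    colnames(d$geno$calls))
  fit_sub <- vgwas(G2, d$pheno, "sim_trait")
  # per-marker nominal statistics are marker-local
  expect_equal(fit_sub$table$bf_F, fit_all$table$bf_F[keep])
  expect_equal(fit_sub$table$wx_Z, fit_all$table$wx_Z[keep])
  # but lambda and the Bonferroni denominator see the changed marker set
  expect_equal(fit_sub$threshold,
               bonferroni_threshold(fit_sub$m_tested, fit_sub$config$alpha))
})

test_that("scan overlap summary counts joint significance", {
  cmp <- compare_scans(c(0.001, 0.2, 0.01), c(0.001, 0.2, 0.01), 0.05)
  expect_equal(cmp$joint_fraction, 1)
  cmp2 <- compare_scans(c(0.001, 0.5), c(0.5, 0.001), 0.05)
  expect_equal(cmp2$n_both, 0)
  expect_equal(cmp2$joint_per_mille, 0)
  # pure-variance architecture: more variance hits than mean hits
  d <- simulate_dataset(sim_config(n_lines = 200L, n_markers = 150L,
                                   sd_high = 3, seed = 44L))
  fit <- vgwas(d$geno, d$pheno, "sim_trait")
  tab <- fit$table[fit$table$reason == "tested", ]
  cmp3 <- compare_scans(tab$wx_p_gc, tab$bf_p_gc, fit$threshold)
  expect_gt(cmp3$n_vgwas, cmp3$n_gwas)
  expect_error(compare_scans(1:3 / 10, 1:4 / 10, 0.05), "length")
})

test_that("scan exports are well-formed and round-trip through TSV", {
  d <- simulate_dataset(sim_config(n_lines = 60L, n_markers = 30L, seed = 3L))
  fit <- vgwas(d$geno, d$pheno, "sim_trait")
  ex <- scan_exports(fit, which = "bf")
  expect_identical(nrow(ex$manhattan), fit$m_tested)
  expect_true(all(diff(ex$qq$expected) >= 0))
  expect_identical(nrow(ex$qq), fit$m_tested)
  tmp <- withr::local_tempdir()
  paths <- write_scan(fit, file.path(tmp, "out"))
  expect_true(all(file.exists(paths)))
  back <- utils::read.table(paths[1], header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  expect_equal(back$bf_p, fit$table$bf_p, tolerance = 1e-12)
  summ <- jsonlite::read_json(paths[2])
  expect_equal(summ$lambda_bf, fit$lambda_bf, tolerance = 1e-12)
})

test_that("print and summary methods run quietly and report key figures", {
  d <- simulate_dataset(sim_config(n_lines = 60L, n_markers = 30L, seed = 5L))
  fit <- vgwas(d$geno, d$pheno, "sim_trait")
  expect_output(print(fit), "lambda_bf")
  s <- summary(fit)
  expect_output(print(s), "Top variance-heterogeneity markers")
  expect_identical(sum(s$counts), 30L)
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit, type = "manhattan"))
  expect_silent(plot(fit, type = "qq", which = "wx"))
})
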