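test_that("per-genotype moments label low/high by sample SD", {
  gr <- split_groups(2, 2)
  m <- genotype_moments(c(0, 2, 10, 14), gr)
  expect_equal(m$low$sd, sqrt(2))
  expect_equal(m$high$sd, sqrt(8))
  expect_identical(m$high$call, 2L)
  expect_equal(m$p_low, 0.5)
  # exact SD tie: the allele_a homozygote (call 0) is labelled low
  m2 <- genotype_moments(c(0, 2, 10, 12), gr)
  expect_identical(m2$low$call, 0L)
  expect_error(genotype_moments(c(1, 2, 3), groups_of(c(0L, 0L, 2L))), ">= 2")
})

test_that("the worked two-line decomposition reproduces its closed-form values", {
  d <- decompose_locus(0.5, 0.22, 1.35, 0.10, 0.59)
  expect_equal(d$s2_P, 0.498275, tolerance = 1e-12)
  expect_equal(d$h2_m, 0.6406603, tolerance = 1e-6)
  expect_equal(d$h2_d, 0.1204656, tolerance = 1e-6)
  expect_equal(d$d_mu, 1.13)
  expect_equal(d$d_sigma, 0.49)
})

test_that("the two closed forms of s2_P agree to machine precision", {
  with_seed(21, {
    for (i in 1:500) {
      p <- runif(1, 0.01, 0.99)
      ml <- rnorm(1, 0, 5); mh <- rnorm(1, 0, 5)
      sl <- runif(1, 0, 3); sh <- runif(1, 0, 3)
      d <- decompose_locus(p, ml, mh, sl, sh)
      alt <- d$p_low * d$q_high * d$d_mu^2 +
        d$p_low * d$sd_low^2 + d$q_high * d$sd_high^2
      expect_equal(d$s2_P, alt, tolerance = 1e-12)
      expect_equal(d$s2_P, d$s2_m + d$s2_d + d$s2_eps, tolerance = 1e-15)
      expect_gte(d$h2_m, 0); expect_gte(d$h2_d, 0)
      expect_lte(d$h2_m + d$h2_d, 1 + 1e-12)
      expect_gte(d$d_sigma, 0)
    }
  })
})

test_that("decomposition is invariant to exchanging labels with p <-> q", {
  with_seed(31, {
    for (i in 1:50) {
      p <- runif(1, 0.05, 0.95)
      ml <- rnorm(1); mh <- rnorm(1); sl <- runif(1, 0, 2); sh <- runif(1, 0, 2)
      a <- decompose_locus(p, ml, mh, sl, sh)
      b <- decompose_locus(1 - p, mh, ml, sh, sl)
      expect_equal(a$s2_P, b$s2_P, tolerance = 1e-12)
      expect_equal(a$h2_m, b$h2_m, tolerance = 1e-12)
      expect_equal(a$h2_d, b$h2_d, tolerance = 1e-12)
      expect_equal(a$p_low, b$p_low, tolerance = 1e-12)
    }
  })
})

test_that("limiting cases collapse correctly", {
  # equal SDs: no heterogeneity component
  d <- decompose_locus(0.3, 1, 3, 0.8, 0.8)
  expect_equal(d$h2_d, 0)
  expect_equal(d$h2_m, 0.21 * 4 / (0.21 * 4 + 0.64), tolerance = 1e-12)
  # no mean shift, sd_low = 0
  d2 <- decompose_locus(0.4, 2, 2, 0, 1.5)
  expect_equal(d2$h2_m, 0)
  expect_equal(d2$s2_eps, (0.6 * 1.5)^2, tolerance = 1e-12)
  expect_equal(d2$s2_d, 0.4 * 0.6 * 1.5^2, tolerance = 1e-12)
  # all-zero variance: h2 ratios defined as 0
  d3 <- decompose_locus(0.5, 1, 1, 0, 0)
  expect_equal(d3$h2_m, 0); expect_equal(d3$h2_d, 0)
  expect_error(decompose_locus(0, 1, 2, 1, 1), "strictly between")
  expect_error(decompose_locus(0.5, 1, 2, -1, 1), ">= 0")
})

test_that("the closed-form optimal LAF matches grid maximisation of h2_d", {
  grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  with_seed(41, {
    for (i in 1:100) {
      sl <- runif(1, 0, 2); sh <- sl + runif(1, 0.05, 2)
      dm <- rnorm(1, 0, 2)
      curves <- h2_curves(0, dm, sl, sh, grid)
      p_star <- optimal_laf(sh, sl)
      expect_equal(grid[which.max(curves$h2_d)], p_star, tolerance = 2e-4)
      # optimum does not depend on the mean difference
      curves2 <- h2_curves(0, dm + 3, sl, sh, grid)
      expect_equal(grid[which.max(curves2$h2_d)],
                   grid[which.max(curves$h2_d)], tolerance = 2e-4)
    }
  })
  expect_equal(optimal_laf(1, 1), 0.5)  # no heterogeneity: symmetric optimum
  expect_equal(optimal_laf(0.59, 0.10), 0.8550725, tolerance = 1e-6)
  expect_error(optimal_laf(0, 0), "undefined")
})

test_that("h2 curves are non-negative, vanish at the edges and peak at the optimum", {
  curves <- h2_curves(0.2, 1.1, 0.3, 0.9, grid = seq(0.001, 0.999, by = 0.001))
  expect_true(all(curves$h2_m >= 0 & curves$h2_d >= 0))
  expect_lt(curves$h2_d[1], 0.01)
  expect_lt(curves$h2_d[nrow(curves)], 0.01)
  at_opt <- decompose_locus(optimal_laf(0.9, 0.3), 0.2, 1.1, 0.3, 0.9)$h2_d
  expect_gte(at_opt + 1e-9, max(curves$h2_d))
  expect_error(h2_curves(0, 1, 1, 2, grid = c(0, 0.5)), "strictly inside")
})

test_that("coefficient of variation reproduces printed per-genotype values", {
  expect_equal(round(coefficient_of_variation(1.36, 0.64), 2), 0.47)
  expect_equal(round(coefficient_of_variation(80.3, 68.2), 2), 0.85)
  expect_equal(coefficient_of_variation(3, 0), 0)
  expect_error(coefficient_of_variation(0, 1), "undefined")
})

test_that("median-deviation rank correlations behave as expected", {
  with_seed(61, {
    y <- rnorm(100)
    m <- cbind(a = y, b = -y, c = rnorm(100))
    rho <- median_deviation_correlation(m, mode = "signed")
    expect_equal(diag(rho), c(a = 1, b = 1, c = 1))
    expect_equal(rho["a", "b"], -1)
    # absolute mode: y and -y deviate identically in magnitude
    rho_abs <- median_deviation_correlation(m, mode = "absolute")
    expect_equal(rho_abs["a", "b"], 1)
    # independent traits: near-zero rank correlation at n = 1000
    big <- cbind(x = rnorm(1000), y = rnorm(1000))
    expect_lt(abs(median_deviation_correlation(big)["x", "y"]), 0.1)
    # insufficient complete pairs -> NA cell
    m2 <- cbind(u = c(1, 2, NA, NA, 5), v = c(NA, NA, 3, 4, NA), w = 1:5)
    expect_true(is.na(median_deviation_correlation(m2)["u", "v"]))
  })
})

test_that("plug-in h2_d estimates are consistent on simulated data", {
  # large single dataset: sample decomposition near the theoretical values
  cfg <- sim_config(n_lines = 10000L, n_markers = 2L, laf = 0.5,
                    mean_low = 0, mean_high = 1, sd_low = 1, sd_high = 2,
                    seed = 99L)
  d <- simulate_dataset(cfg)
  gr <- genotype_groups(d$geno, d$truth$causal_id)
  dec <- decompose_marker(d$pheno$sim_trait, gr)
  theo <- decompose_locus(0.5, 0, 1, 1, 2)
  expect_lt(abs(dec$h2_d - theo$h2_d), 0.01)
  expect_lt(abs(dec$h2_m - theo$h2_m), 0.01)
  # per-genotype sample moments within 2% of the generating parameters
  m <- genotype_moments(d$pheno$sim_trait, gr)
  expect_equal(m$high$mean, 1, tolerance = 0.02)
  expect_equal(m$high$sd, 2, tolerance = 0.02)
  expect_equal(m$low$sd, 1, tolerance = 0.02)
})
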