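# independent brute-force oracle for the partial Spearman correlation:
# explicit ranking, two covariate regressions, Pearson on residuals
brute_partial_spearman <- function(x, y, Z = NULL) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (!is.null(Z)) {
    X <- cbind(1, as.matrix(Z))
    rx <- stats::residuals(stats::lm.fit(X, rx))
    ry <- stats::residuals(stats::lm.fit(X, ry))
  }
  cor(rx, ry)
}

# exhaustive all-thresholds BH oracle
brute_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  keep <- which(ps <= seq_len(m) * q / m)
  flags <- rep(FALSE, m)
  if (length(keep)) flags[o[seq_len(max(keep))]] <- TRUE
  flags
}

test_that("adjusted group difference reduces to the t-test when covariates are orthogonal", {
  set.seed(1)
  n <- 40
  g <- rep(c("control", "fracture"), each = n / 2)
  y <- rnorm(n) + (g == "fracture")
  z <- rnorm(n)
  # orthogonalize the covariate against both group and outcome
  z <- stats::residuals(lm(z ~ y + I(g == "fracture")))
  df <- tibble::tibble(group = g, y = y, z = z)
  # with no covariates the regression is exactly the equal-variance t-test
  ad0 <- adjusted_group_difference(df, "y", "group", character(0))
  tt <- t.test(y ~ g, var.equal = TRUE)
  expect_equal(ad0$p, tt$p.value, tolerance = 1e-10)
  expect_equal(ad0$statistic, -tt$statistic[[1]], tolerance = 1e-10)
  # an orthogonal covariate leaves the estimate untouched and matches lm()
  ad <- adjusted_group_difference(df, "y", "group", "z")
  ref <- summary(lm(y ~ I(g == "fracture") + z))$coefficients[2, ]
  expect_equal(ad$estimate, ad0$estimate, tolerance = 1e-10)
  expect_equal(ad$estimate, unname(ref[1]), tolerance = 1e-10)
  expect_equal(ad$p, unname(ref[4]), tolerance = 1e-10)
  # y identical to the group indicator: numerically zero p
  df2 <- tibble::tibble(group = g, y = as.numeric(g == "fracture"),
                        z = rnorm(n))
  expect_lt(adjusted_group_difference(df2, "y", "group", "z")$p, 1e-12)
  # collinear design named
  df3 <- tibble::tibble(group = g, y = y, z1 = z, z2 = 2 * z)
  expect_error(adjusted_group_difference(df3, "y", "group",
                                         c("z1", "z2")), "collinear")
})

test_that("adjusted group difference recovers a planted shift without bias", {
  set.seed(2)
  est <- replicate(1000, {
    g <- rep(c("control", "fracture"), each = 50)
    df <- tibble::tibble(
      group = g, age = rnorm(100, 65, 9), height = rnorm(100, 161, 6),
      weight = rnorm(100, 74, 15),
      y = rnorm(100) + (g == "fracture"))
    adjusted_group_difference(df, "y", "group")$estimate
  })
  expect_lt(abs(mean(est) - 1), 0.05)
})

test_that("partial Spearman equals the brute-force oracle to 1e-12", {
  # fixed instance
  x <- c(1, 2, 3, 4, 5, 6)
  y <- c(2, 1, 4, 3, 6, 5)
  z <- c(1, 1, 2, 2, 3, 3)
  ps <- partial_spearman(x, y, cbind(z))
  expect_equal(ps$rho, brute_partial_spearman(x, y, cbind(z)),
               tolerance = 1e-12)
  # random instances with ties, n <= 30, 0-3 covariates
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(8:30, 1)
    k <- sample(0:3, 1)
    x <- sample(1:6, n, replace = TRUE) + rnorm(n, 0, 0.01)
    y <- round(rnorm(n), 1)
    Z <- if (k) matrix(rnorm(n * k), n, k) else NULL
    got <- partial_spearman(x, y, Z)$rho
    expect_equal(got, brute_partial_spearman(x, y, Z), tolerance = 1e-12)
  }
})

test_that("partial Spearman reduces to Spearman and is rank-invariant", {
  set.seed(3)
  x <- rnorm(25)
  y <- rnorm(25)
  expect_equal(partial_spearman(x, y)$rho,
               cor(x, y, method = "spearman"), tolerance = 1e-12)
  # monotone transforms leave it unchanged; perfect monotone pairs give 1
  expect_equal(partial_spearman(exp(x), y)$rho, partial_spearman(x, y)$rho,
               tolerance = 1e-12)
  expect_equal(partial_spearman(x, x^3)$rho, 1, tolerance = 1e-12)
  # constant input flagged undefined
  expect_false(partial_spearman(rep(1, 25), y)$defined)
})

test_that("Fisher Z comparison matches its arithmetic definition", {
  # published global correlations of homogenized density vs local BV/TV:
  # 0.83 in 98 controls vs 0.93 in 84 fracture cases, 3 covariates
  fz <- fisher_z_compare(0.83, 98, 0.93, 84, n_covariates = 3)
  z_ref <- (atanh(0.83) - atanh(0.93)) / sqrt(1 / (98 - 6) + 1 / (84 - 6))
  expect_equal(fz$z, z_ref, tolerance = 1e-12)
  expect_equal(fz$p, 2 * pnorm(-abs(z_ref)), tolerance = 1e-12)
  expect_lt(fz$p, 0.05) # the published contrast is significant
  # equal correlations: z = 0, p = 1
  fz0 <- fisher_z_compare(0.5, 40, 0.5, 60)
  expect_equal(fz0$z, 0)
  expect_equal(fz0$p, 1)
  # antisymmetry
  fa <- fisher_z_compare(0.3, 50, 0.6, 70)
  fb <- fisher_z_compare(0.6, 70, 0.3, 50)
  expect_equal(fa$z, -fb$z, tolerance = 1e-12)
  expect_equal(fa$p, fb$p, tolerance = 1e-12)
  # degenerate input
  expect_error(fisher_z_compare(1, 50, 0.5, 50), "infinite")
  # classic n - 3 when the covariate correction is disabled
  fz2 <- fisher_z_compare(0.83, 98, 0.93, 84, 3, df_correction = FALSE)
  expect_equal(fz2$z, (atanh(0.83) - atanh(0.93)) /
                 sqrt(1 / 95 + 1 / 81), tolerance = 1e-12)
})

test_that("BH-FDR flags match the exhaustive oracle", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03), 0.05), rep(TRUE, 3))
  expect_equal(fdr_correct(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_equal(fdr_correct(numeric(0)), logical(0))
  set.seed(21)
  for (rep in 1:60) {
    m <- sample(c(3, 10, 50, 200), 1)
    p <- c(runif(m), runif(m %/% 3, 0, 0.01))
    expect_identical(fdr_correct(p, 0.05), brute_bh(p, 0.05))
  }
  # NA p-values are never flagged and do not enter the family
  p <- c(0.001, NA, 0.8)
  fl <- fdr_correct(p, 0.05)
  expect_false(fl[2])
  expect_true(fl[1])
})

test_that("correlation maps are uniform when built from a shared latent field", {
  set.seed(31)
  n <- 60
  m <- 300
  lat <- matrix(rnorm(n * m), n, m)
  a <- lat + matrix(rnorm(n * m, 0, 0.8), n, m)
  b <- lat + matrix(rnorm(n * m, 0, 0.8), n, m)
  cm <- correlation_map(a, b)
  expect_s3_class(cm, "stat_map")
  # rho spatially uniform: spread consistent with sampling error
  expect_lt(sd(cm$rho), 2 * (1 - mean(cm$rho)^2) / sqrt(n - 3))
  expect_gt(mean(cm$significant), 0.95) # strong shared signal everywhere
})

test_that("independent maps keep the flagged fraction near the FDR level", {
  set.seed(32)
  frac <- replicate(8, {
    a <- matrix(rnorm(50 * 400), 50, 400)
    b <- matrix(rnorm(50 * 400), 50, 400)
    glance(correlation_map(a, b))$flagged_fraction
  })
  expect_lte(mean(frac), 0.05 + 0.02)
})

test_that("clone cohorts give rho = 1 and the minimum-n rule masks sparse locations", {
  set.seed(33)
  base <- rnorm(30)
  a <- matrix(base, 30, 50) + matrix(rnorm(30 * 50, 0, 1e-6), 30, 50)
  cm <- correlation_map(a, a)
  expect_true(all(cm$rho > 0.999))
  # poke missingness below the 90 % rule at some locations
  b <- a
  b[1:6, 1:5] <- NA # 80 % defined < 90 %
  cm2 <- correlation_map(a, b, min_frac = 0.9)
  expect_true(all(is.na(cm2$rho[1:5])))
  expect_true(all(!is.na(cm2$rho[6:50])))
})

test_that("difference maps detect planted correlation contrasts", {
  set.seed(34)
  m <- 400
  region <- 1:80
  make_group <- function(n, rho_in, rho_out) {
    rho <- rep(rho_out, m)
    rho[region] <- rho_in
    lat <- matrix(rnorm(n * m), n, m)
    e1 <- matrix(rnorm(n * m), n, m)
    e2 <- matrix(rnorm(n * m), n, m)
    a <- sweep(lat, 2, sqrt(rho), "*") + sweep(e1, 2, sqrt(1 - rho), "*")
    b <- sweep(lat, 2, sqrt(rho), "*") + sweep(e2, 2, sqrt(1 - rho), "*")
    list(a = a, b = b)
  }
  ctl <- make_group(100, 0.2, 0.5)
  fx <- make_group(100, 0.8, 0.5)
  cm_c <- correlation_map(ctl$a, ctl$b)
  cm_f <- correlation_map(fx$a, fx$b)
  dm <- correlation_difference_map(cm_c, cm_f)
  flagged <- which(dm$significant)
  dice <- 2 * length(intersect(flagged, region)) /
    (length(flagged) + length(region))
  expect_gt(dice, 0.5)
  # the reported difference is fracture minus control
  expect_gt(mean(dm$delta_rho[region]), 0)
  # identical group maps: no flags, zero differences
  dm0 <- correlation_difference_map(cm_c, cm_c)
  expect_true(all(dm0$delta_rho == 0))
  expect_false(any(dm0$significant))
  expect_error(correlation_difference_map(
    cm_c, correlation_map(fx$a[, 1:10], fx$b[, 1:10])), "mismatch")
})

test_that("cohort-level tables assemble correlations and comparisons", {
  set.seed(35)
  co <- make_cohort(cohort_spec(n_control = 30, n_fracture = 30, seed = 8),
                    generate_volumes = FALSE)
  co$m1 <- co$gt_bvtv_nominal + rnorm(60, 0, 0.01)
  co$m2 <- co$gt_bmd_bone + rnorm(60, 0, 10)
  tab <- correlation_table(co, c("m1", "m2"))
  expect_equal(nrow(tab), 1)
  expect_true(all(c("rho_control", "rho_fracture", "p_between") %in%
                  names(tab)))
  cmp <- group_comparison_table(co, c("m1", "m2"))
  expect_equal(cmp$metric, c("m1", "m2"))
  expect_lt(cmp$p[1], 0.01) # BV/TV effect is planted
  expect_lt(cmp$mean_fracture[1], cmp$mean_control[1])
})
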