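test_that("study tables round-trip through CSV and reject invalid rows", {
  sim <- simulate_population(default_study_configs()$PVp, seed = 42)
  dir <- withr::local_tempdir()

  write_table(sim$fish, file.path(dir, "fish.csv"), "fish")
  expect_equal(read_table(file.path(dir, "fish.csv"), "fish"), sim$fish)
  write_table(sim$guts, file.path(dir, "gut.csv"), "gut")
  expect_equal(read_table(file.path(dir, "gut.csv"), "gut"), sim$guts)
  iso <- sim$isotopes[, setdiff(names(sim$isotopes), "fish_length_cm")]
  write_table(iso, file.path(dir, "iso.csv"), "isotope")
  expect_equal(read_table(file.path(dir, "iso.csv"), "isotope"), iso)
  write_table(sim$community, file.path(dir, "comm.csv"), "community")
  expect_equal(read_table(file.path(dir, "comm.csv"), "community"),
               sim$community)

  # schema error names the missing column
  bad <- sim$fish[, -4]
  utils::write.csv(bad, file.path(dir, "bad.csv"), row.names = FALSE)
  expect_error(read_table(file.path(dir, "bad.csv"), "fish"),
               "total_length_cm")

  # row-level invariant violations
  f2 <- sim$fish; f2$weight_g[3] <- -1
  expect_error(validate_records(f2, "fish"), "row 3")
  g2 <- make_guts(list(c(A = 50, B = 30)))
  g2$volume_pct[g2$category == FULLNESS_CATEGORY] <- 70  # items sum to 80
  expect_error(validate_records(g2, "gut"), "sum to 80")
})

test_that("Shannon diversity matches direct evaluation and is permutation/scale invariant", {
  expect_equal(shannon_diversity(c(10, 0, 0)), 0)
  expect_equal(shannon_diversity(c(5, 5, 5, 5)), log(4))
  expect_equal(shannon_diversity(c(60, 30, 10)), 0.8979457, tolerance = 1e-6)
  expect_equal(shannon_diversity(c(4, 4), base = 2), 1)
  expect_error(shannon_diversity(c(0, 0)), "all-zero")

  set.seed(1)
  for (i in 1:50) {
    x <- stats::rgamma(sample(3:12, 1), 1)
    H <- shannon_diversity(x)
    expect_equal(H, shannon_diversity(sample(x)))
    expect_equal(H, shannon_diversity(3.7 * x))
    expect_lte(H, log(length(x)) + 1e-12)
    expect_equal(H, vegan::diversity(x, index = "shannon"),
                 ignore_attr = TRUE)
  }
})

test_that("Bray-Curtis dissimilarity has the right range, symmetry and reference values", {
  expect_equal(bray_curtis(c(2, 5, 1), c(2, 5, 1)), 0)
  expect_equal(bray_curtis(c(3, 0), c(0, 7)), 1)
  expect_equal(bray_curtis(c(3, 1), c(1, 3)), 0.5)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")

  set.seed(2)
  for (i in 1:200) {
    a <- stats::rpois(6, 4); b <- stats::rpois(6, 4)
    if (sum(a) + sum(b) == 0) next
    d <- bray_curtis(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, bray_curtis(b, a))
    expect_equal(d, as.numeric(vegan::vegdist(rbind(a, b))))
  }
})

test_that("one-way ANOVA equals the squared two-sample t and holds its type-I rate", {
  set.seed(3)
  x <- stats::rnorm(15); y <- stats::rnorm(12, 0.4)
  a <- anova_oneway(list(x, y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p, tt$p.value, tolerance = 1e-10)
  expect_error(anova_oneway(list(x, 1)), ">= 2 observations")

  rej <- mean(replicate(1000, {
    g <- lapply(1:3, function(i) stats::rnorm(8))
    anova_oneway(g)$p < 0.05
  }))
  expect_gt(rej, 0.028); expect_lt(rej, 0.075)
})

test_that("Tukey HSD flags a separated group and never reports less than the unadjusted p", {
  set.seed(4)
  g <- list(a = stats::rnorm(12), b = stats::rnorm(12), c = stats::rnorm(12) + 10)
  tk <- tukey_hsd(g)
  expect_lt(max(tk$p_adj[grepl("c", tk$pair)]), 0.001)
  expect_gt(tk$p_adj[tk$pair == "b-a"], 0.05)

  # adjusted p >= pooled-variance pairwise p, for every pair
  d <- data.frame(y = unlist(g), grp = rep(names(g), each = 12))
  fit <- stats::aov(y ~ grp, data = d)
  s2 <- sum(stats::residuals(fit)^2) / fit$df.residual
  for (r in seq_len(nrow(tk))) {
    pp <- strsplit(tk$pair[r], "-")[[1]]
    tstat <- abs(mean(g[[pp[1]]]) - mean(g[[pp[2]]])) / sqrt(2 * s2 / 12)
    p_unadj <- 2 * stats::pt(-tstat, fit$df.residual)
    expect_gte(tk$p_adj[r] + 1e-12, p_unadj)
  }
})

test_that("Pillai MANOVA matches the reference implementation and reduces to ANOVA", {
  set.seed(5)
  Y <- cbind(stats::rnorm(60, rep(c(0, 0.6, 1.2), each = 20)), stats::rnorm(60))
  g <- rep(letters[1:3], each = 20)
  mine <- manova_pillai(Y, g)
  ref <- summary(stats::manova(Y ~ factor(g)), test = "Pillai")$stats
  expect_equal(mine$pillai, ref[1, "Pillai"], tolerance = 1e-12)
  expect_equal(mine$F_approx, ref[1, "approx F"], tolerance = 1e-12)
  expect_equal(mine$p, ref[1, "Pr(>F)"], tolerance = 1e-12)

  y <- stats::rnorm(45, rep(c(0, 0.8, 0.2), each = 15))
  uni <- manova_pillai(matrix(y, ncol = 1), rep(1:3, each = 15))
  av <- anova_oneway(split(y, rep(1:3, each = 15)))
  expect_equal(uni$F_approx, av$F, tolerance = 1e-12)
  expect_equal(uni$p, av$p, tolerance = 1e-12)

  # strongly separated bivariate means
  Y2 <- cbind(stats::rnorm(45, rep(c(0, 4, 8), each = 15)), stats::rnorm(45))
  expect_lt(manova_pillai(Y2, rep(1:3, each = 15))$p, 0.001)
  # one observation per group: singular within-group matrix
  expect_error(manova_pillai(cbind(1:4, c(1, 1, 2, 2)), 1:4), "singular|need n")
})

test_that("linear regression is exact on a line and calibrated under the null", {
  x <- 1:10
  lr <- suppressWarnings(linear_regression(x, 2 * x + 1))  # perfect fit
  expect_equal(lr$slope, 2, tolerance = 1e-12)
  expect_equal(lr$intercept, 1, tolerance = 1e-12)
  expect_equal(lr$r_squared, 1, tolerance = 1e-12)
  expect_equal(sum(lr$residuals), 0, tolerance = 1e-10)
  expect_error(linear_regression(rep(1, 5), stats::rnorm(5)), "constant")

  set.seed(6)
  # bootstrap SE of the slope agrees with the analytic SE
  x <- stats::runif(200); y <- 1 + 0.5 * x + stats::rnorm(200, 0, 0.3)
  lr <- linear_regression(x, y)
  bs <- replicate(400, {
    i <- sample(200, replace = TRUE)
    linear_regression(x[i], y[i])$slope
  })
  expect_equal(stats::sd(bs), lr$se_slope, tolerance = 0.1)

  # p-value of the slope is uniform under independence
  p <- replicate(500, linear_regression(stats::rnorm(20), stats::rnorm(20))$p_slope)
  expect_gt(mean(p < 0.05), 0.02); expect_lt(mean(p < 0.05), 0.09)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})
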