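test_that("vacuity and mean fullness follow their counting definitions", {
  guts <- make_guts(c(rep(list(c(Chironomidae = 40, Simuliidae = 20)), 15),
                      rep(list(numeric(0)), 4)))
  expect_equal(vacuity_index(guts), 100 * 4 / 19)
  expect_equal(round(vacuity_index(guts)), 21)

  g2 <- make_guts(list(numeric(0), c(A = 100)))
  expect_equal(mean_fullness(g2, include_empty = TRUE)$mean, 50)
  expect_equal(mean_fullness(g2, include_empty = FALSE)$mean, 100)
  g3 <- make_guts(rep(list(c(A = 30, B = 20)), 5))
  expect_equal(mean_fullness(g3)$mean, 50)
  expect_equal(mean_fullness(g3)$sd, 0)
  expect_equal(vacuity_index(make_guts(rep(list(numeric(0)), 3))), 100)
})

test_that("the diet matrix holds only non-empty guts with rows summing to fullness", {
  guts <- make_guts(list(c(A = 30, B = 30), c(A = 10, C = 50), numeric(0)))
  m <- diet_matrix(guts)
  expect_equal(nrow(m), 2)
  expect_equal(unname(rowSums(m)), unname(attr(m, "fullness")))
  # adding an empty gut changes vacuity but not the composition matrix
  guts2 <- rbind(guts, make_guts(list(numeric(0)), population_id = "P9"))
  expect_equal(unclass(diet_matrix(guts2))[, colnames(m)], unclass(m)[, ],
               ignore_attr = TRUE)
  expect_error(diet_matrix(guts, categories = c("A", "B")), "C")
})

test_that("occurrence frequency and prey-specific abundance match hand counts", {
  guts <- make_guts(list(c(X = 30, Y = 30), c(X = 10, Y = 50)))
  m <- diet_matrix(guts)
  expect_equal(occurrence_frequency(m, "X"), 100)
  expect_equal(prey_specific_abundance(m, "X"), 100 * 40 / 120)

  # Pi is invariant to adding guts that lack the category
  guts3 <- rbind(guts, make_guts(list(c(Y = 80)), population_id = "P2"))
  m3 <- diet_matrix(guts3)
  expect_equal(prey_specific_abundance(m3, "X"),
               prey_specific_abundance(m, "X"))
  expect_equal(occurrence_frequency(m3, "X"), 100 * 2 / 3)
  expect_error(occurrence_frequency(m, "Z"), "unknown")
  expect_error(prey_specific_abundance(m3, "Z"), "unknown")

  # 3 of 12 fish hold the category
  g12 <- make_guts(c(rep(list(c(A = 20, B = 20)), 9),
                     rep(list(c(A = 20, C = 20)), 3)))
  expect_equal(occurrence_frequency(diet_matrix(g12), "C"), 25)

  pts <- amundsen_points(m3)
  expect_equal(nrow(pts), sum(colSums(m3 > 0) > 0))
  expect_true(all(pts$Fi > 0 & pts$Fi <= 100))
  expect_true(all(pts$Pi > 0 & pts$Pi <= 100))
  # exclusive heavy consumption by one fish: low Fi, high Pi
  gsp <- make_guts(c(rep(list(c(A = 50)), 9), list(c(B = 90))))
  sp <- amundsen_points(diet_matrix(gsp))
  expect_equal(sp$Fi[sp$category == "B"], 10)
  expect_equal(sp$Pi[sp$category == "B"], 100)
})

test_that("the arcsine square-root transform maps endpoints and midpoints exactly", {
  expect_equal(transform_arcsine_sqrt(0), 0)
  expect_equal(transform_arcsine_sqrt(1), pi / 2)
  expect_equal(transform_arcsine_sqrt(0.25), asin(0.5))
  expect_error(transform_arcsine_sqrt(1.2), "proportions")
  m <- matrix(c(0, 0.25, 0.5, 1), 2)
  expect_equal(dim(transform_arcsine_sqrt(m)), dim(m))
  expect_true(all(diff(transform_arcsine_sqrt(seq(0, 1, 0.1))) > 0))
})

test_that("per-fish dietary diversity is zero for monophagy and log S for even diets", {
  guts <- make_guts(list(c(A = 60), c(A = 15, B = 15, C = 15, D = 15)))
  dv <- diet_diversity(diet_matrix(guts))
  expect_equal(dv$per_fish$H, c(0, log(4)))
  expect_equal(dv$summary$n, 2)
})

test_that("nMDS embeds planar configurations with near-zero stress and is scale-free", {
  set.seed(7)
  pts <- matrix(stats::rnorm(24), ncol = 2)
  d <- stats::dist(pts)
  fit <- suppressWarnings(nmds(d, seed = 3))   # vegan warns on ~zero stress
  expect_lt(fit$stress, 0.01)
  fit2 <- suppressWarnings(nmds(2 * d, seed = 3))
  expect_equal(fit$stress, fit2$stress, tolerance = 1e-6)
  expect_warning(nmds(stats::dist(matrix(1, 5, 2)), seed = 1), "zero")
})

test_that("core ellipses have area pi for whitened clouds and scale with the determinant", {
  set.seed(8)
  X <- matrix(stats::rnorm(200), ncol = 2)
  # whiten so the sample covariance is exactly the identity
  X <- scale(X, scale = FALSE) %*%
    solve(chol(stats::cov(X)))
  e <- core_ellipse(X)
  expect_equal(e$area, pi, tolerance = 1e-9)
  e2 <- core_ellipse(X * sqrt(3))
  expect_equal(e2$area, 3 * pi, tolerance = 1e-9)
  expect_error(core_ellipse(cbind(1:5, 2 * (1:5))), "singular")
})

test_that("PERMANOVA matches vegan and gives the minimal p under complete separation", {
  set.seed(9)
  m <- matrix(stats::rgamma(20 * 6, 2), nrow = 20)
  g <- rep(c("a", "b"), each = 10)
  m[g == "b", 1] <- m[g == "b", 1] + 3
  d <- vegan::vegdist(m)
  mine <- permanova(d, g, n_perm = 999, seed = 1)
  ref <- vegan::adonis2(d ~ g, permutations = 999)
  expect_equal(mine$pseudo_F, ref$F[1], tolerance = 1e-9)
  expect_equal(mine$R2, ref$R2[1], tolerance = 1e-9)
  expect_equal(mine$df1, ref$Df[1])

  # identical rows within groups, groups far apart: p at its floor (up to
  # permutations that exactly swap the two labels and so tie the observed F)
  m2 <- rbind(matrix(1, 8, 3), matrix(100, 8, 3)) +
    matrix(stats::rnorm(48, 0, 1e-4), 16)
  p <- permanova(stats::dist(m2), rep(1:2, each = 8), n_perm = 199, seed = 2)
  expect_lte(p$p_perm, 2 / 200)
  expect_equal(p$p_perm * 200, round(p$p_perm * 200))
})

test_that("SIMPER decomposes the average dissimilarity and matches vegan", {
  # groups differing in exactly one category
  m <- rbind(matrix(c(10, 5, 0), 4, 3, byrow = TRUE),
             matrix(c(10, 5, 8), 4, 3, byrow = TRUE))
  colnames(m) <- c("A", "B", "C")
  g <- rep(c("g1", "g2"), each = 4)
  s <- simper(m, g)[[1]]
  expect_equal(s$contributions$pct[s$contributions$category == "C"], 100)
  expect_equal(s$overall, bray_curtis(c(10, 5, 0), c(10, 5, 8)))

  set.seed(10)
  for (i in 1:20) {
    m <- matrix(stats::rgamma(12 * 5, 1.5), nrow = 12)
    colnames(m) <- paste0("sp", 1:5)
    g <- rep(c("x", "y", "z"), each = 4)
    res <- simper(m, g)
    dmat <- as.matrix(bray_curtis_matrix(m))
    for (pair in names(res)) {
      gr <- strsplit(pair, "_vs_")[[1]]
      avg <- mean(dmat[g == gr[1], g == gr[2]])
      expect_equal(res[[pair]]$overall, avg, tolerance = 1e-9)
      expect_equal(sum(res[[pair]]$contributions$average), avg,
                   tolerance = 1e-9)
    }
    # vegan oracle on one pair
    vs <- vegan::simper(m, g)
    v1 <- vs[[1]]
    mine1 <- res[[gsub("_", "_vs_", names(vs)[1], fixed = TRUE)]]
    ord <- match(v1$species, mine1$contributions$category)
    expect_equal(mine1$contributions$average[ord], unname(v1$average),
                 tolerance = 1e-9)
  }
})

test_that("exact prey accumulation matches its endpoint, mean and vegan identities", {
  set.seed(11)
  pres <- matrix(stats::rbinom(15 * 8, 1, 0.4), nrow = 15)
  colnames(pres) <- paste0("c", 1:8)
  curve <- prey_accumulation(pres)
  S_obs <- sum(colSums(pres) > 0)
  expect_equal(curve$expected_categories[nrow(curve)], S_obs)
  expect_equal(curve$expected_categories[1], mean(rowSums(pres)))
  expect_true(all(diff(curve$expected_categories) >= -1e-12))
  ref <- vegan::specaccum(pres, method = "exact")
  expect_equal(curve$expected_categories, unname(ref$richness),
               tolerance = 1e-9)
  expect_error(prey_accumulation(pres, m = 16), "out of range")
})
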