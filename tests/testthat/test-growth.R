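test_that("the growth curve evaluates exactly, including at the published parameters", {
  p <- list(Linf = 40, K = 0.3, t0 = -0.5)
  expect_equal(predict_vb(p, -0.5), 0)
  expect_equal(predict_vb(p, 1000), 40)
  # PVi parameter set at age 3
  expect_equal(predict_vb(list(Linf = 45.7, K = 0.24, t0 = 0.03), 3),
               45.7 * (1 - exp(-0.24 * 2.97)), tolerance = 1e-12)
  expect_equal(predict_vb(list(Linf = 45.7, K = 0.24, t0 = 0.03), 3),
               23.3, tolerance = 0.005)
})

test_that("mean length-at-age aggregates, excludes old ages, and counts rows", {
  fish <- data.frame(
    fish_id = paste0("F", 1:7), population_id = c(rep("A", 4), rep("B", 3)),
    status = "purebred",
    total_length_cm = c(10, 20, 18, 30, 12, 14, 40),
    weight_g = 1, age = c(2L, 2L, 3L, 5L, 1L, 1L, 2L), pass_number = 1L,
    stringsAsFactors = FALSE)
  m <- mean_length_at_age(fish, max_age = 4)
  expect_equal(m$mean_tl[m$population_id == "A" & m$age == 2], 15)
  expect_equal(m$sd_tl[m$population_id == "A" & m$age == 2],
               stats::sd(c(10, 20)))
  expect_false(any(m$age == 5))                        # 5+ fish dropped
  # row count = sum over populations of distinct retained ages
  expect_equal(nrow(m), 2 + 2)
  expect_true(is.na(m$sd_tl[m$n == 1][1]))
  expect_true("A" %in% attr(m, "unfittable"))          # 2 distinct ages only
})

test_that("noiseless growth data are recovered exactly and beat a grid search", {
  truth <- list(P1 = list(Linf = 40, K = 0.25, t0 = -0.4))
  mlaa <- make_mlaa(truth, ages = 0:5)
  set.seed(1)
  fit <- fit_vb(mlaa, vb_spec())
  expect_lt(fit$SSE, 1e-10)
  expect_equal(fit$params$Linf, 40, tolerance = 1e-3)
  expect_equal(fit$params$K, 0.25, tolerance = 1e-3)
  expect_equal(fit$params$t0, -0.4, tolerance = 1e-2)

  # coarse grid over the parameter box never undercuts the optimizer
  grid <- expand.grid(Linf = seq(30, 60, 2), K = seq(0.05, 0.6, 0.02),
                      t0 = seq(-1, 1, 0.1))
  sse_grid <- vapply(seq_len(nrow(grid)), function(i) {
    pr <- grid[i, ]
    sum((mlaa$mean_tl - pr$Linf * (1 - exp(-pr$K * (mlaa$age - pr$t0))))^2)
  }, 0)
  expect_gte(min(sse_grid), fit$SSE - 1e-9)
})

test_that("sharing more parameters never reduces the residual sum of squares", {
  set.seed(2)
  mlaa <- make_mlaa(study_vb_params(), ages = 0:4, noise_sd = 1)
  specs <- all_vb_specs()
  fits <- lapply(specs, function(sp) fit_vb(mlaa, sp))
  for (i in seq_along(specs)) for (j in seq_along(specs)) {
    if (i != j && spec_nested_in(specs[[i]], specs[[j]]))
      expect_gte(fits[[i]]$SSE, fits[[j]]$SSE - 1e-6 * (1 + fits[[j]]$SSE))
  }
  # identical populations: the fully shared model wins the AIC ranking
  mlaa2 <- make_mlaa(list(A = study_vb_params()$PVp, B = study_vb_params()$PVp),
                     ages = 0:4, noise_sd = 0.5)
  sel <- vb_model_selection(mlaa2)
  expect_equal(sel$table$model[1], "Linf/K/t0")
})

test_that("model selection recovers the generating sharing structure as noise vanishes", {
  set.seed(7)
  wins <- replicate(10, {
    mlaa <- make_mlaa(study_vb_params(), ages = 0:4, noise_sd = 0.1)
    vb_model_selection(mlaa)$table$model[1]
  })
  expect_true(all(wins == "Linf*/K/t0*"))
})

test_that("the least-squares AIC obeys its identities and ranks like the Gaussian likelihood", {
  expect_equal(aic_ls(5, 20, 3) - aic_ls(10, 20, 3), 20 * log(0.5))
  expect_equal(aic_ls(10, 20, 4) - aic_ls(10, 20, 3), 2)
  expect_warning(expect_equal(aic_ls(0, 10, 2), -Inf), "zero")

  # ranking agrees with lm's Gaussian AIC on nested polynomial fits
  set.seed(3)
  x <- stats::runif(40); y <- 1 + 2 * x + stats::rnorm(40, 0, 0.3)
  fits <- lapply(1:3, function(k) stats::lm(y ~ poly(x, k)))
  mine <- vapply(seq_along(fits), function(i)
    aic_ls(sum(stats::residuals(fits[[i]])^2), 40, i + 1), 0)
  ref <- vapply(fits, stats::AIC, 0)
  expect_equal(order(mine), order(ref))
  expect_equal(diff(mine), diff(ref), tolerance = 1e-9)
})

test_that("length-weight fits recover exact power laws and keep slope under rescaling", {
  fish <- make_exact_fish(vb = list(Linf = 36, K = 0.24, t0 = -0.5),
                          lwr = list(a = 0.011, b = 2.99), ages = 1:5)
  fit <- suppressWarnings(fit_lwr(fish))  # perfect fit
  expect_equal(fit$b, 2.99, tolerance = 1e-9)
  expect_equal(fit$a, 0.011, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  fish2 <- fish; fish2$weight_g <- 2 * fish2$weight_g
  fit2 <- suppressWarnings(fit_lwr(fish2))
  expect_equal(fit2$b, fit$b, tolerance = 1e-9)
  expect_equal(fit2$a, 2 * fit$a, tolerance = 1e-9)
  set.seed(41)
  fish3 <- fish
  fish3$weight_g <- fish3$weight_g * 10^stats::rnorm(nrow(fish3), 0, 0.02)
  fish3$weight_g[1] <- -5
  expect_warning(fit_lwr(fish3), "rejected")
})

test_that("isometry testing is exact at b = 3 and detects negative allometry", {
  iso <- test_isometry(list(b = 3, se_b = 0.05, n = 100))
  expect_equal(iso$t, 0)
  expect_equal(iso$df, 98)
  expect_equal(iso$p, 1)
  expect_equal(iso$verdict, "isometric")

  set.seed(4)
  # simulated b = 2.8 with n = 141, sigma_log10 = 0.02: detected as negative
  verdicts <- replicate(50, {
    tl <- stats::runif(141, 7, 28)
    w <- 10^(log10(0.014) + 2.8 * log10(tl) + stats::rnorm(141, 0, 0.02))
    f <- data.frame(fish_id = paste0("F", 1:141), population_id = "P",
                    status = "purebred", total_length_cm = tl, weight_g = w,
                    age = 2L, pass_number = 1L)
    test_isometry(fit_lwr(f))$verdict
  })
  expect_true(all(verdicts == "allometric_negative"))
})

test_that("the LWR ANCOVA matches the interaction t-test and separates distinct slopes", {
  set.seed(5)
  make_pop <- function(id, b, n = 80) {
    tl <- stats::runif(n, 7, 28)
    data.frame(fish_id = sprintf("%s%03d", id, 1:n), population_id = id,
               status = "purebred", total_length_cm = tl,
               weight_g = 10^(log10(0.013) + b * log10(tl) +
                                stats::rnorm(n, 0, 0.02)),
               age = 2L, pass_number = 1L)
  }
  fish <- rbind(make_pop("A", 2.8), make_pop("B", 3.0))
  an <- ancova_lwr(fish)
  d <- data.frame(lw = log10(fish$weight_g), ll = log10(fish$total_length_cm),
                  pop = factor(fish$population_id))
  tstat <- summary(stats::lm(lw ~ ll * pop, data = d))$coefficients["ll:popB", "t value"]
  expect_equal(an$F, tstat^2, tolerance = 1e-9)
  expect_lt(an$p, 0.001)

  fish_same <- rbind(make_pop("A", 2.9), make_pop("B", 2.9))
  expect_gt(ancova_lwr(fish_same)$p, 0.01)
})

test_that("per-population condition residuals centre at zero and pooled fits expose inflated weights", {
  set.seed(6)
  mk <- function(id, infl = 1) {
    tl <- stats::runif(60, 8, 30)
    data.frame(fish_id = sprintf("%s%03d", id, 1:60), population_id = id,
               status = "purebred", total_length_cm = tl,
               weight_g = infl * 10^(log10(0.013) + 2.9 * log10(tl) +
                                       stats::rnorm(60, 0, 0.03)),
               age = 2L, pass_number = 1L)
  }
  fish <- rbind(mk("A"), mk("B", infl = 1.1))
  bc <- body_condition(fish, pooled = FALSE)
  expect_true(all(abs(bc$summary$mean) < 1e-10))   # OLS orthogonality

  bp <- body_condition(fish, pooled = TRUE)
  mB <- bp$summary$mean[bp$summary$population_id == "B"]
  expect_gt(mB, 0)
  expect_lt(bp$anova$p, 0.01)
})
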