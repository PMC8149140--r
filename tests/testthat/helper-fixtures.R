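# Fixture builders shared across the test files. Everything is generated in
# code; no stored data.

# long-format gut table from a list of named item vectors (fullness = sum)
make_guts <- function(items_per_fish, population_id = "P1", length_cm = 15) {
  rows <- lapply(seq_along(items_per_fish), function(i) {
    it <- items_per_fish[[i]]
    id <- sprintf("%s_F%02d", population_id, i)
    data.frame(
      fish_id = id, population_id = population_id,
      total_length_cm = length_cm,
      category = c(FULLNESS_CATEGORY, names(it)),
      volume_pct = c(sum(it), unname(it)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# fish table exactly on a von Bertalanffy curve and length-weight line
make_exact_fish <- function(vb, lwr, ages, population_id = "P1",
                            status = "purebred", n_per_age = 3) {
  age <- rep(ages, each = n_per_age)
  tl <- predict_vb(vb, age)
  w <- lwr$a * tl^lwr$b
  data.frame(
    fish_id = sprintf("%s_F%03d", population_id, seq_along(age)),
    population_id = population_id, status = status,
    total_length_cm = tl, weight_g = w, age = age,
    pass_number = 1L, stringsAsFactors = FALSE)
}

# mean length-at-age table generated from known parameters plus noise
make_mlaa <- function(params_by_pop, ages = 0:4, noise_sd = 0) {
  do.call(rbind, lapply(names(params_by_pop), function(p) {
    data.frame(population_id = p, age = ages,
               mean_tl = predict_vb(params_by_pop[[p]], ages) +
                 stats::rnorm(length(ages), 0, noise_sd),
               sd_tl = NA_real_, n = 5L, stringsAsFactors = FALSE)
  }))
}

# the four growth-parameter sets of the bundled study configuration
study_vb_params <- function() {
  list(PVp = list(Linf = 34.4, K = 0.24, t0 = -0.60),
       PVi = list(Linf = 45.7, K = 0.24, t0 = 0.03),
       TLp = list(Linf = 35.9, K = 0.24, t0 = -0.50),
       TLi = list(Linf = 41.1, K = 0.24, t0 = -0.55))
}

# TRUE when every parameter shared in `sub` is also shared in `super`
spec_nested_in <- function(super, sub) {
  all(vapply(c("Linf", "K", "t0"),
             function(f) sub[[f]] != "shared" || super[[f]] == "shared", TRUE))
}
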