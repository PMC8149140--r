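# Synthetic-data generator: emits fish, gut, isotope and community tables with
# the statistical structure the downstream analyses assume, so every stage is
# testable without the (undeposited) field data.

.dirichlet1 <- function(alpha) {
  # one Dirichlet draw; zero concentrations are structural zeros
  g <- numeric(length(alpha))
  pos <- alpha > 0
  g[pos] <- stats::rgamma(sum(pos), shape = alpha[pos])
  g / sum(g)
}

.check_field <- function(ok, field) {
  if (!isTRUE(ok)) stop("invalid simulation config: field '", field, "'",
                        call. = FALSE)
}

#' Build a population simulation configuration
#'
#' One object per population, describing demographic structure (age-class
#' probabilities), growth (von Bertalanffy mean length-at-age with
#' multiplicative Gaussian length noise), length-weight allometry on the
#' log10 scale, gut contents (vacuity probability, Beta-distributed fullness,
#' Dirichlet-distributed composition), bulk isotope distributions (bivariate
#' normal consumers above a normal macroinvertebrate baseline), and two-pass
#' electrofishing capture.
#'
#' @param population_id,status population label and `"purebred"` /
#'   `"introgressed"`.
#' @param n_fish closed-population size exposed to electrofishing.
#' @param age_probs probability vector over age classes `0..(length-1)`
#'   (must sum to 1).
#' @param vb list `(Linf, K, t0)`: cm, 1/yr, yr. Mean length of an age-`a`
#'   fish is the curve evaluated at `a + 0.5` (spring spawning, mid-summer
#'   sampling).
#' @param length_cv coefficient of variation of individual length about the
#'   age-class mean.
#' @param lwr list `(a, b, sigma_log10)`: `W = a * TL^b` with Gaussian noise
#'   of SD `sigma_log10` on `log10 W`.
#' @param vacuity_prob probability of an empty gut.
#' @param fullness_beta list `(alpha, beta)`: non-empty fullness is
#'   `100 * Beta(alpha, beta)` percent.
#' @param diet_alpha named Dirichlet concentration vector over food
#'   categories; zero entries are structural zeros (category never eaten).
#' @param iso_consumer list `(mean, cov)`: bivariate normal for consumer
#'   `(d13C, d15N)`, per-mil.
#' @param baseline list `(n, d13C_mean, d13C_sd, d15N_mean, d15N_sd)` for the
#'   pooled benthic-macroinvertebrate baseline samples.
#' @param capture_prob per-pass electrofishing capture probability in (0, 1].
#' @param transect_area sampled area, m^2.
#' @param n_guts number of captured fish subsampled for gut-content analysis.
#' @param n_iso number of captured fish subsampled for stable isotopes.
#' @param community_taxa named vector of expected counts for the non-barbel
#'   fish community at the site (Poisson draws).
#' @return a `pop_sim_config` list.
#' @export
sim_config <- function(population_id, status, n_fish, age_probs, vb,
                       length_cv, lwr, vacuity_prob, fullness_beta,
                       diet_alpha, iso_consumer, baseline,
                       capture_prob = 0.6, transect_area = 500,
                       n_guts = 20, n_iso = 10, community_taxa = NULL) {
  .check_field(is.character(population_id) && nzchar(population_id), "population_id")
  .check_field(status %in% c("purebred", "introgressed"), "status")
  .check_field(is.numeric(n_fish) && n_fish >= 1, "n_fish")
  .check_field(abs(sum(age_probs) - 1) < 1e-9 && all(age_probs >= 0), "age_probs")
  .check_field(all(c("Linf", "K", "t0") %in% names(vb)) && vb$Linf > 0 && vb$K > 0, "vb")
  .check_field(length_cv >= 0, "length_cv")
  .check_field(all(c("a", "b", "sigma_log10") %in% names(lwr)) && lwr$a > 0, "lwr")
  .check_field(vacuity_prob >= 0 && vacuity_prob <= 1, "vacuity_prob")
  .check_field(fullness_beta$alpha > 0 && fullness_beta$beta > 0, "fullness_beta")
  .check_field(!is.null(names(diet_alpha)) && all(diet_alpha >= 0) &&
                 any(diet_alpha > 0), "diet_alpha")
  cov <- iso_consumer$cov
  .check_field(is.matrix(cov) && all(dim(cov) == 2) &&
                 isTRUE(all(eigen(cov, symmetric = TRUE, only.values = TRUE)$values > 0)),
               "iso_consumer")
  .check_field(baseline$n >= 2 && baseline$d13C_sd >= 0 && baseline$d15N_sd >= 0,
               "baseline")
  .check_field(capture_prob > 0 && capture_prob <= 1, "capture_prob")
  .check_field(transect_area > 0, "transect_area")
  structure(list(
    population_id = population_id, status = status, n_fish = as.integer(n_fish),
    age_probs = age_probs, vb = vb, length_cv = length_cv, lwr = lwr,
    vacuity_prob = vacuity_prob, fullness_beta = fullness_beta,
    diet_alpha = diet_alpha, iso_consumer = iso_consumer, baseline = baseline,
    capture_prob = capture_prob, transect_area = transect_area,
    n_guts = as.integer(n_guts), n_iso = as.integer(n_iso),
    community_taxa = community_taxa), class = "pop_sim_config")
}

#' Default food-category set
#'
#' The nine-category grouping used by the bundled study configurations:
#' dominant aquatic insect larvae kept separate, rarer items grouped.
#' @export
default_diet_categories <- function() {
  c("Chironomidae", "Simuliidae", "Hydropsychidae", "Trichoptera_other",
    "Mollusca", "terrestrial_organisms", "aquatic_BMI_other", "fish_bones",
    "plants")
}

#' Study configurations for the four-population comparison
#'
#' Two purebred (PVp, TLp) and two introgressed (PVi, TLi) populations with
#' population-specific von Bertalanffy asymptotic lengths (34.4, 45.7, 35.9,
#' 41.1 cm), a shared growth coefficient K = 0.24 1/yr, population-specific
#' t0, length-weight allometry per population, introgressed populations
#' truncated at age 4+ (PVi) and 3+ (TLi), population-specific vacuity and
#' fullness, Dirichlet diet compositions (with a piscivory component only in
#' the TLi-like population), and bivariate-normal consumer isotope
#' distributions above pooled macroinvertebrate baselines.
#'
#' @return named list of four [sim_config()] objects (`PVp`, `PVi`, `TLp`,
#'   `TLi`).
#' @export
default_study_configs <- function() {
  cats <- default_diet_categories()
  al <- function(x) stats::setNames(x, cats)
  mk_cov <- function(sd1, sd2, rho = 0.2)
    matrix(c(sd1^2, rho * sd1 * sd2, rho * sd1 * sd2, sd2^2), 2)
  list(
    PVp = sim_config(
      population_id = "PVp", status = "purebred", n_fish = 49,
      age_probs = c(0.10, 0.22, 0.28, 0.20, 0.10, 0.06, 0.04),
      vb = list(Linf = 34.4, K = 0.24, t0 = -0.60),
      length_cv = 0.08, lwr = list(a = 0.015, b = 2.83, sigma_log10 = 0.04),
      vacuity_prob = 0.10, fullness_beta = list(alpha = 1.72, beta = 1.05),
      diet_alpha = al(c(8, 4, 3, 2, 2.5, 1.5, 1.5, 0, 0.5)),
      iso_consumer = list(mean = c(-26.1, 8.9), cov = mk_cov(0.9, 1.1)),
      baseline = list(n = 15, d13C_mean = -28.1, d13C_sd = 1.8,
                      d15N_mean = 3.0, d15N_sd = 0.5),
      capture_prob = 0.6, transect_area = 420, n_guts = 20, n_iso = 10,
      community_taxa = c(Telestes_muticellus = 500, Cottus_gobio = 300,
                         Salmo_trutta = 40, Padogobius_sp = 60,
                         Squalius_squalus = 80)),
    PVi = sim_config(
      population_id = "PVi", status = "introgressed", n_fish = 86,
      age_probs = c(0.15, 0.35, 0.25, 0.15, 0.10),
      vb = list(Linf = 45.7, K = 0.24, t0 = 0.03),
      length_cv = 0.08, lwr = list(a = 0.016, b = 2.78, sigma_log10 = 0.04),
      vacuity_prob = 0.10, fullness_beta = list(alpha = 1.24, beta = 0.82),
      diet_alpha = al(c(7, 4, 2.5, 1.5, 2, 1.5, 1.5, 0.3, 0.2)),
      iso_consumer = list(mean = c(-24.8, 10.8), cov = mk_cov(0.8, 0.7)),
      baseline = list(n = 15, d13C_mean = -26.8, d13C_sd = 0.8,
                      d15N_mean = 6.6, d15N_sd = 0.5),
      capture_prob = 0.6, transect_area = 1600, n_guts = 20, n_iso = 10,
      community_taxa = c(Gobio_gobio = 900, Barbus_barbus = 120,
                         Telestes_muticellus = 150, Squalius_squalus = 200,
                         Padogobius_sp = 100, Alburnus_sp = 250,
                         Salmo_trutta = 30)),
    TLp = sim_config(
      population_id = "TLp", status = "purebred", n_fish = 52,
      age_probs = c(0.10, 0.22, 0.28, 0.20, 0.10, 0.06, 0.04),
      vb = list(Linf = 35.9, K = 0.24, t0 = -0.50),
      length_cv = 0.08, lwr = list(a = 0.011, b = 2.99, sigma_log10 = 0.04),
      vacuity_prob = 0, fullness_beta = list(alpha = 4.68, beta = 0.83),
      diet_alpha = al(c(6, 5, 4, 3, 3, 2, 2, 0, 1)),
      iso_consumer = list(mean = c(-22.6, 8.3), cov = mk_cov(0.4, 1.0)),
      baseline = list(n = 15, d13C_mean = -24.6, d13C_sd = 1.2,
                      d15N_mean = 4.9, d15N_sd = 0.5),
      capture_prob = 0.6, transect_area = 300, n_guts = 22, n_iso = 10,
      community_taxa = c(Telestes_muticellus = 60, Oncorhynchus_mykiss = 15,
                         Squalius_squalus = 50, Padogobius_nigricans = 40)),
    TLi = sim_config(
      population_id = "TLi", status = "introgressed", n_fish = 168,
      age_probs = c(0.20, 0.40, 0.25, 0.15),
      vb = list(Linf = 41.1, K = 0.24, t0 = -0.55),
      length_cv = 0.08, lwr = list(a = 0.014, b = 2.80, sigma_log10 = 0.04),
      vacuity_prob = 0.21, fullness_beta = list(alpha = 0.64, beta = 1.35),
      diet_alpha = al(c(1.0, 0.5, 0, 0, 0, 0.3, 0.4, 0.6, 0.5)),
      iso_consumer = list(mean = c(-24.0, 12.4), cov = mk_cov(0.9, 1.2)),
      baseline = list(n = 15, d13C_mean = -26.0, d13C_sd = 0.5,
                      d15N_mean = 10.7, d15N_sd = 0.5),
      capture_prob = 0.6, transect_area = 1870, n_guts = 19, n_iso = 10,
      community_taxa = c(Padogobius_nigricans = 4000, Gobio_gobio = 800,
                         Alburnus_sp = 1200, Barbus_barbus = 300,
                         Squalius_squalus = 600, Carassius_sp = 150,
                         Pseudorasbora_parva = 400))
  )
}

#' Simulate one population
#'
#' Draws the closed population (ages multinomial, lengths from the von
#' Bertalanffy mean with multiplicative Gaussian noise, weights from the
#' log10 length-weight line plus Gaussian noise), applies two-pass binomial
#' capture (pass 2 on the survivors of pass 1), then subsamples captured fish
#' for gut contents (empty with probability `vacuity_prob`, otherwise
#' Beta-distributed fullness apportioned by a Dirichlet composition) and for
#' isotopes (bivariate-normal consumers; normal baseline samples).
#'
#' @param cfg a [sim_config()] object.
#' @param seed integer seed; identical `(cfg, seed)` yields identical tables.
#' @return list of data frames: `fish` (captured fish, `fish` schema), `guts`
#'   (long `gut` schema), `isotopes` (`isotope` schema), `catches` (one row:
#'   `population_id`, `C1`, `C2`, `area_m2`), `community` (`community`
#'   schema, barbel plus configured taxa).
#' @export
simulate_population <- function(cfg, seed) {
  stopifnot(inherits(cfg, "pop_sim_config"))
  set.seed(as.integer(seed))
  n <- cfg$n_fish
  ages <- sample(seq_along(cfg$age_probs) - 1L, n, replace = TRUE,
                 prob = cfg$age_probs)
  mean_len <- predict_vb(cfg$vb, ages + 0.5)
  tl <- mean_len * (1 + stats::rnorm(n, 0, cfg$length_cv))
  tl <- pmax(tl, 0.1 * mean_len)
  w <- 10^(log10(cfg$lwr$a) + cfg$lwr$b * log10(tl) +
             stats::rnorm(n, 0, cfg$lwr$sigma_log10))

  p1 <- stats::runif(n) < cfg$capture_prob
  p2 <- !p1 & stats::runif(n) < cfg$capture_prob
  pass <- ifelse(p1, 1L, ifelse(p2, 2L, NA_integer_))
  caught <- which(!is.na(pass))

  fish <- data.frame(
    fish_id = sprintf("%s_F%03d", cfg$population_id, seq_along(caught)),
    population_id = cfg$population_id, status = cfg$status,
    total_length_cm = round(tl[caught], 3), weight_g = round(w[caught], 3),
    age = ages[caught], pass_number = pass[caught],
    stringsAsFactors = FALSE)

  # gut subsample: prefer age classes 1..4, the GCA design
  pool <- which(fish$age >= 1 & fish$age <= 4)
  if (length(pool) < cfg$n_guts) pool <- seq_len(nrow(fish))
  gi <- sort(sample(pool, min(cfg$n_guts, length(pool))))
  cats <- names(cfg$diet_alpha)
  gut_rows <- lapply(gi, function(i) {
    empty <- stats::runif(1) < cfg$vacuity_prob
    full <- if (empty) 0 else
      100 * stats::rbeta(1, cfg$fullness_beta$alpha, cfg$fullness_beta$beta)
    comp <- if (empty) numeric(0) else .dirichlet1(cfg$diet_alpha) * full
    keep <- which(comp > 0)
    data.frame(
      fish_id = rep(fish$fish_id[i], length(keep) + 1L),
      population_id = cfg$population_id,
      total_length_cm = fish$total_length_cm[i],
      category = c(FULLNESS_CATEGORY, cats[keep]),
      volume_pct = c(full, comp[keep]),
      stringsAsFactors = FALSE)
  })
  guts <- do.call(rbind, gut_rows)

  ii <- sort(sample(seq_len(nrow(fish)), min(cfg$n_iso, nrow(fish))))
  cons <- MASS::mvrnorm(length(ii), mu = cfg$iso_consumer$mean,
                        Sigma = cfg$iso_consumer$cov)
  bmi_fams <- c("Baetidae", "Chironomidae", "Hydropsychidae", "Leuctridae",
                "Simuliidae")
  nb <- cfg$baseline$n
  isotopes <- rbind(
    data.frame(
      sample_id = sprintf("%s_C%02d", cfg$population_id, seq_along(ii)),
      group = "consumer", taxon = "Barbus", population_id = cfg$population_id,
      d13C = round(cons[, 1], 3), d15N = round(cons[, 2], 3),
      c_to_n = round(stats::runif(length(ii), 3.0, 3.4), 3),
      stringsAsFactors = FALSE),
    data.frame(
      sample_id = sprintf("%s_B%02d", cfg$population_id, seq_len(nb)),
      group = "baseline_bmi",
      taxon = rep_len(bmi_fams, nb), population_id = cfg$population_id,
      d13C = round(stats::rnorm(nb, cfg$baseline$d13C_mean, cfg$baseline$d13C_sd), 3),
      d15N = round(stats::rnorm(nb, cfg$baseline$d15N_mean, cfg$baseline$d15N_sd), 3),
      c_to_n = round(stats::runif(nb, 3.0, 3.4), 3),
      stringsAsFactors = FALSE))
  # record the fish each consumer sample came from (for ontogeny regressions)
  isotopes$fish_length_cm <- NA_real_
  isotopes$fish_length_cm[seq_along(ii)] <- fish$total_length_cm[ii]

  catches <- data.frame(population_id = cfg$population_id,
                        C1 = sum(fish$pass_number == 1),
                        C2 = sum(fish$pass_number == 2),
                        area_m2 = cfg$transect_area)

  comm_taxa <- c(stats::setNames(cfg$n_fish, "Barbus_sp"), cfg$community_taxa)
  community <- data.frame(
    site_id = cfg$population_id, taxon = names(comm_taxa),
    count = as.integer(stats::rpois(length(comm_taxa), comm_taxa)),
    area_m2 = cfg$transect_area, stringsAsFactors = FALSE)

  list(fish = fish, guts = guts, isotopes = isotopes, catches = catches,
       community = community)
}

#' Simulate a multi-population study
#'
#' Runs [simulate_population()] for each configuration with a per-population
#' seed derived deterministically from `seed`, and row-binds the tables.
#'
#' @param configs list of [sim_config()] objects (default
#'   [default_study_configs()]).
#' @param seed integer master seed.
#' @return list of combined data frames `fish`, `guts`, `isotopes`,
#'   `catches`, `community`.
#' @export
simulate_study <- function(configs = default_study_configs(), seed = 1) {
  sims <- lapply(seq_along(configs), function(k)
    simulate_population(configs[[k]], derive_seed(seed, names(configs)[k])))
  out <- lapply(c("fish", "guts", "isotopes", "catches", "community"),
                function(tb) do.call(rbind, lapply(sims, `[[`, tb)))
  names(out) <- c("fish", "guts", "isotopes", "catches", "community")
  out
}

#' Derive a stage- or population-specific seed from a master seed
#'
#' Deterministic, label-keyed derivation so that enabling or disabling one
#' consumer of randomness never perturbs another's stream.
#'
#' @param seed master integer seed.
#' @param label character stream label.
#' @return integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_len(nchar(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Write the simulated study tables as CSV
#'
#' @param sim output of [simulate_study()] or [simulate_population()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    write_table(sim$fish, file.path(dir, "fish.csv"), "fish"),
    write_table(sim$guts, file.path(dir, "gut.csv"), "gut"),
    write_table(sim$isotopes[names(.schemas$isotope$cols)],
                file.path(dir, "isotope.csv"), "isotope"),
    write_table(sim$community, file.path(dir, "community.csv"), "community"))
  utils::write.csv(sim$catches, file.path(dir, "catches.csv"), row.names = FALSE)
  invisible(paths)
}
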