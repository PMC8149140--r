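# Orchestration: configuration-driven end-to-end run
# (simulate -> growth -> diet -> isotope -> community -> report).

#' Growth-stage analysis
#'
#' Mean length-at-age, the 8-model von Bertalanffy selection, per-population
#' length-weight fits with isometry tests, the across-population ANCOVA and
#' residual body condition.
#'
#' @param fish data frame in the `fish` schema.
#' @param max_age oldest age class used for growth fitting (default 4).
#' @param condition_pooled use one pooled LWR for condition residuals
#'   (default `FALSE`: per-population fits; both are standard, the default
#'   centres every population's residuals).
#' @return list with `mlaa`, `selection`, `best` (best fit), `lwr`
#'   (per-population), `isometry`, `ancova`, `condition`,
#'   `condition_pooled` (residuals under one common LWR, whose ANOVA is the
#'   across-population condition comparison), `manova` (length/age MANOVA
#'   across populations), and `table` (one row per population: N, a, b, SE,
#'   R2, condition mean/SD, Linf, t0, K).
#' @export
analyze_growth <- function(fish, max_age = 4, condition_pooled = FALSE) {
  mlaa <- mean_length_at_age(fish, max_age = max_age)
  sel <- vb_model_selection(mlaa)
  best <- sel$fits[[1]]
  pops <- sort(unique(fish$population_id))
  lwr <- lapply(stats::setNames(pops, pops),
                function(p) fit_lwr(fish[fish$population_id == p, ]))
  iso <- lapply(lwr, test_isometry)
  cond <- body_condition(fish, pooled = condition_pooled)
  # the across-population condition ANOVA is informative only under a common
  # reference line, so the pooled-fit version is always reported alongside
  cond_pooled <- if (condition_pooled) cond else body_condition(fish, pooled = TRUE)
  aged <- fish[!is.na(fish$age) & fish$age >= 1 & fish$age <= max_age, ]
  man <- manova_pillai(cbind(aged$total_length_cm, aged$age),
                       aged$population_id)
  tab <- do.call(rbind, lapply(pops, function(p) {
    bp <- best$params[best$params$population_id == p, ]
    cs <- cond$summary[cond$summary$population_id == p, ]
    data.frame(population_id = p, N = sum(fish$population_id == p),
               a = lwr[[p]]$a, b = lwr[[p]]$b, se_b = lwr[[p]]$se_b,
               r_squared = lwr[[p]]$r_squared,
               isometry = iso[[p]]$verdict,
               condition_mean = cs$mean, condition_sd = cs$sd,
               Linf = bp$Linf, K = bp$K, t0 = bp$t0,
               stringsAsFactors = FALSE)
  }))
  list(mlaa = mlaa, selection = sel, best = best, lwr = lwr, isometry = iso,
       ancova = ancova_lwr(fish), condition = cond,
       condition_pooled = cond_pooled, manova = man, table = tab)
}

#' Diet-stage analysis
#'
#' Vacuity, mean fullness and dietary diversity per population; arcsine
#' square-root transformed proportions, Bray-Curtis distances, nMDS with
#' per-population core-niche ellipses, PERMANOVA, SIMPER and exact prey
#' accumulation curves.
#'
#' @param guts data frame in the `gut` schema.
#' @param categories food-category universe (default: observed categories).
#' @param n_perm PERMANOVA permutations (default 999).
#' @param seed integer seed for ordination and permutation streams.
#' @param include_empty_fullness whether empty guts enter mean fullness
#'   (default `TRUE`).
#' @return list with `vacuity`, `fullness`, `diversity`, `diversity_anova`,
#'   `diversity_tukey`, `matrix`, `nmds`, `ellipses` (per population, on the
#'   ordination plane), `permanova`, `simper`, `accumulation`, `amundsen`
#'   (per population), and Table-3-shaped `table`.
#' @export
analyze_diet <- function(guts, categories = NULL, n_perm = 999, seed = 1,
                         include_empty_fullness = TRUE) {
  pops <- unique(guts$population_id)
  per_pop_guts <- lapply(stats::setNames(pops, pops),
                         function(p) guts[guts$population_id == p, ])
  vac <- vapply(per_pop_guts, vacuity_index, 0)
  fullness <- lapply(per_pop_guts, mean_fullness,
                     include_empty = include_empty_fullness)
  m <- diet_matrix(guts, categories = categories)
  pop_of <- attr(m, "population")
  div <- diet_diversity(m)
  div_groups <- split(div$per_fish$H, div$per_fish$population_id)
  div_anova <- anova_oneway(div_groups)
  div_tukey <- tukey_hsd(div_groups)
  prop <- m / attr(m, "fullness")
  tm <- transform_arcsine_sqrt(prop)
  d <- bray_curtis_matrix(tm)
  ord <- nmds(d, k = 2, seed = derive_seed(seed, "nmds"))
  ell <- lapply(stats::setNames(pops, pops), function(p)
    core_ellipse(ord$points[pop_of == p, , drop = FALSE]))
  perm <- permanova(d, pop_of, n_perm = n_perm,
                    seed = derive_seed(seed, "permanova"))
  simp <- simper(tm, pop_of)
  accum <- lapply(stats::setNames(pops, pops), function(p)
    prey_accumulation(m[pop_of == p, , drop = FALSE] > 0))
  amund <- lapply(stats::setNames(pops, pops), function(p)
    amundsen_points(m[pop_of == p, , drop = FALSE]))
  tab <- do.call(rbind, lapply(pops, function(p) {
    ds <- div$summary[div$summary$population_id == p, ]
    data.frame(population_id = p,
               N = sum(guts$category == FULLNESS_CATEGORY &
                         guts$population_id == p),
               vacuity_pct = vac[[p]],
               fullness_mean = fullness[[p]]$mean,
               fullness_sd = fullness[[p]]$sd,
               H_mean = ds$mean, H_sd = ds$sd,
               nmds_ellipse_area = ell[[p]]$area,
               stringsAsFactors = FALSE)
  }))
  list(vacuity = vac, fullness = fullness, diversity = div,
       diversity_anova = div_anova, diversity_tukey = div_tukey,
       matrix = m, nmds = ord, ellipses = ell, permanova = perm,
       simper = simp, accumulation = accum, amundsen = amund, table = tab)
}

#' Isotope-stage analysis
#'
#' C:N screening, per-site baseline pooling, deterministic TP and corrected
#' carbon per fish, Bayesian TP per population, maximum-likelihood and
#' Bayesian standard ellipse areas on the corrected (C_corr, TP) plane,
#' pairwise posterior comparisons, niche overlap, and ontogenetic
#' regressions.
#'
#' @param isotopes data frame in the `isotope` schema; consumer rows may
#'   carry `fish_length_cm` for the ontogenetic regressions.
#' @param tdf_obj a [tdf()] with `dC_mean` set.
#' @param iters MCMC iterations per chain / posterior draws (default 10000).
#' @param seed integer seed.
#' @return list with `screen`, `baselines`, `per_fish` (TP and C_corr),
#'   `tp` (per population [tp_bayes()] results), `sea` (per population
#'   [sea_bayes()] on corrected data), `tp_comparison` and `sea_comparison`
#'   (pairwise exceedance probabilities), `overlap` (pairwise core-niche
#'   overlap, % of the smaller ellipse pair member), `ontogeny`, `ccorr_anova`,
#'   and Table-4-shaped `table`.
#' @export
analyze_isotope <- function(isotopes, tdf_obj, iters = 10000, seed = 1) {
  if (is.null(tdf_obj$dC_mean))
    stop("carbon discrimination factor (dC_mean) is required", call. = FALSE)
  scr <- screen_cn(isotopes)
  pops <- unique(isotopes$population_id[isotopes$group == "consumer"])
  baselines <- lapply(stats::setNames(pops, pops), function(p)
    pool_baseline(isotopes[isotopes$population_id == p, ]))
  cons <- isotopes[isotopes$group == "consumer", ]
  per_fish <- do.call(rbind, lapply(pops, function(p) {
    s <- cons[cons$population_id == p, ]
    data.frame(sample_id = s$sample_id, population_id = p,
               d13C = s$d13C, d15N = s$d15N,
               TP = tp_point(s$d15N, baselines[[p]], tdf_obj),
               C_corr = c_corr(s$d13C, baselines[[p]], tdf_obj),
               fish_length_cm = if ("fish_length_cm" %in% names(s))
                 s$fish_length_cm else NA_real_,
               stringsAsFactors = FALSE)
  }))
  tp <- lapply(stats::setNames(pops, pops), function(p)
    tp_bayes(cons$d15N[cons$population_id == p], baselines[[p]], tdf_obj,
             iters = iters, seed = derive_seed(seed, paste0("tp_", p))))
  sea <- lapply(stats::setNames(pops, pops), function(p) {
    s <- per_fish[per_fish$population_id == p, ]
    sea_bayes(s$C_corr, s$TP, iters = iters,
              seed = derive_seed(seed, paste0("sea_", p)))
  })
  pair_probs <- function(draws_list) {
    out <- list()
    nm <- names(draws_list)
    for (i in seq_along(nm)) for (j in seq_along(nm)) if (i < j)
      out[[paste0(nm[i], "_vs_", nm[j])]] <-
        posterior_prob_greater(draws_list[[i]], draws_list[[j]])
    unlist(out)
  }
  tp_cmp <- pair_probs(lapply(tp, function(r) r$draws$TP))
  sea_cmp <- pair_probs(lapply(sea, `[[`, "draws"))
  ells <- lapply(stats::setNames(pops, pops), function(p) {
    s <- per_fish[per_fish$population_id == p, ]
    core_ellipse(cbind(s$C_corr, s$TP))
  })
  overlap <- matrix(0, length(pops), length(pops),
                    dimnames = list(pops, pops))
  for (i in seq_along(pops)) for (j in seq_along(pops)) if (i < j) {
    ov <- ellipse_overlap(ells[[i]], ells[[j]])
    overlap[i, j] <- ov$pct_e1
    overlap[j, i] <- ov$pct_e2
  }
  onto <- ontogeny_regression(per_fish)
  ccorr_anova <- anova_oneway(split(per_fish$C_corr, per_fish$population_id))
  tab <- do.call(rbind, lapply(pops, function(p) {
    s <- cons[cons$population_id == p, ]
    data.frame(population_id = p, N = nrow(s),
               d15N_mean = mean(s$d15N), d15N_sd = stats::sd(s$d15N),
               TP_median = tp[[p]]$median,
               TP_lo = tp[[p]]$ci[1], TP_hi = tp[[p]]$ci[2],
               d13C_mean = mean(s$d13C), d13C_sd = stats::sd(s$d13C),
               Ccorr_mean = mean(per_fish$C_corr[per_fish$population_id == p]),
               Ccorr_sd = stats::sd(per_fish$C_corr[per_fish$population_id == p]),
               SEA_ml = sea[[p]]$sea_ml, SEAB_median = sea[[p]]$median,
               SEAB_lo = sea[[p]]$ci[1], SEAB_hi = sea[[p]]$ci[2],
               stringsAsFactors = FALSE)
  }))
  list(screen = scr, baselines = baselines, per_fish = per_fish, tp = tp,
       sea = sea, tp_comparison = tp_cmp, sea_comparison = sea_cmp,
       ellipses = ells, overlap = overlap, ontogeny = onto,
       ccorr_anova = ccorr_anova, table = tab)
}

#' Community-stage analysis
#'
#' Two-pass removal abundance and density for the focal species plus
#' site-level community metrics and dissimilarity.
#'
#' @param community data frame in the `community` schema.
#' @param catches optional data frame `population_id`/`site_id`, `C1`, `C2`,
#'   `area_m2` of two-pass catches for the focal species.
#' @return list with `metrics`, `dissimilarity`, and (when catches are
#'   given) `removal` (per site: N_hat, SE, p_hat, density).
#' @export
analyze_community <- function(community, catches = NULL) {
  metrics <- community_metrics(community)
  diss <- community_dissimilarity(community)
  removal <- NULL
  if (!is.null(catches)) {
    site_col <- if ("site_id" %in% names(catches)) "site_id" else "population_id"
    removal <- do.call(rbind, lapply(seq_len(nrow(catches)), function(i) {
      z <- zippin_two_pass(catches$C1[i], catches$C2[i])
      data.frame(site_id = catches[[site_col]][i], C1 = z$C1, C2 = z$C2,
                 N_hat = z$N_hat, SE = z$SE, p_hat = z$p_hat,
                 degenerate = z$degenerate,
                 density = density_per_m2(z$N_hat, catches$area_m2[i]),
                 stringsAsFactors = FALSE)
    }))
  }
  list(metrics = metrics, dissimilarity = diss, removal = removal)
}

#' Build a validated pipeline run configuration
#'
#' Validation happens here, before any computation: an enabled isotope stage
#' without a carbon discrimination factor is a configuration error.
#'
#' @param simulate if `TRUE` (default) the input tables come from
#'   [simulate_study()] with `sim_configs`; otherwise `paths` must name
#'   existing CSVs (`fish`, `gut`, `isotope`, `community`, optionally
#'   `catches`).
#' @param sim_configs list of [sim_config()] objects.
#' @param paths named list of input CSV paths when `simulate = FALSE`.
#' @param stages character subset of
#'   `c("growth", "diet", "isotope", "community")`.
#' @param max_age oldest age class for growth fitting.
#' @param categories diet category universe (`NULL`: observed).
#' @param n_perm PERMANOVA permutations.
#' @param tdf_n,tdf_n_sd nitrogen TDF mean and SD (per-mil).
#' @param tdf_c carbon TDF (per-mil); required when the isotope stage is
#'   enabled, no default.
#' @param mcmc_iters MCMC iterations / posterior draws.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param outdir optional output directory for the report tables.
#' @return a `run_config` list.
#' @export
run_config <- function(simulate = TRUE, sim_configs = default_study_configs(),
                       paths = NULL,
                       stages = c("growth", "diet", "isotope", "community"),
                       max_age = 4, categories = NULL, n_perm = 999,
                       tdf_n = 4.2, tdf_n_sd = 0.2, tdf_c = NULL,
                       mcmc_iters = 10000, seed = 1, outdir = NULL) {
  stages <- match.arg(stages, c("growth", "diet", "isotope", "community"),
                      several.ok = TRUE)
  if ("isotope" %in% stages && is.null(tdf_c))
    stop("configuration error: the isotope stage requires 'tdf_c' ",
         "(carbon trophic discrimination factor, per-mil); it has no default",
         call. = FALSE)
  if (!simulate) {
    need <- c("fish", "gut", "isotope", "community")
    missing_p <- setdiff(need, names(paths))
    if (length(missing_p))
      stop("configuration error: missing input path(s): ",
           paste(missing_p, collapse = ", "), call. = FALSE)
    for (p in unlist(paths)) if (!file.exists(p))
      stop("configuration error: input file not found: ", p, call. = FALSE)
  }
  structure(list(simulate = simulate, sim_configs = sim_configs,
                 paths = paths, stages = stages, max_age = max_age,
                 categories = categories, n_perm = n_perm, tdf_n = tdf_n,
                 tdf_n_sd = tdf_n_sd, tdf_c = tdf_c,
                 mcmc_iters = mcmc_iters, seed = seed, outdir = outdir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Simulates or loads the four input tables, runs the enabled stages with
#' deterministic per-stage seeds derived from the global seed, and (when
#' `outdir` is set) writes the four report tables plus a machine-readable
#' manifest. Re-running with the same configuration reproduces all outputs.
#'
#' @param cfg a [run_config()].
#' @return a `report_bundle` list with elements `data`, `growth`, `diet`,
#'   `isotope`, `community`, `manifest`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t_start <- Sys.time()
  if (cfg$simulate) {
    data <- simulate_study(cfg$sim_configs, seed = derive_seed(cfg$seed, "simulate"))
  } else {
    data <- list(fish = read_table(cfg$paths$fish, "fish"),
                 guts = read_table(cfg$paths$gut, "gut"),
                 isotopes = read_table(cfg$paths$isotope, "isotope"),
                 community = read_table(cfg$paths$community, "community"),
                 catches = if (!is.null(cfg$paths$catches))
                   utils::read.csv(cfg$paths$catches) else NULL)
  }
  bundle <- list(data = data)
  timings <- list()
  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }
  if ("growth" %in% cfg$stages)
    bundle$growth <- run_stage("growth",
      analyze_growth(data$fish, max_age = cfg$max_age))
  if ("diet" %in% cfg$stages)
    bundle$diet <- run_stage("diet",
      analyze_diet(data$guts, categories = cfg$categories,
                   n_perm = cfg$n_perm, seed = derive_seed(cfg$seed, "diet")))
  if ("isotope" %in% cfg$stages)
    bundle$isotope <- run_stage("isotope",
      analyze_isotope(data$isotopes,
                      tdf(cfg$tdf_n, cfg$tdf_n_sd, cfg$tdf_c),
                      iters = cfg$mcmc_iters,
                      seed = derive_seed(cfg$seed, "isotope")))
  if ("community" %in% cfg$stages)
    bundle$community <- run_stage("community",
      analyze_community(data$community, data$catches))
  bundle$manifest <- list(
    package_version = as.character(utils::packageVersion("introtroph")),
    seed = cfg$seed, stages = cfg$stages, n_perm = cfg$n_perm,
    mcmc_iters = cfg$mcmc_iters, tdf = list(dN = cfg$tdf_n,
                                            dN_sd = cfg$tdf_n_sd,
                                            dC = cfg$tdf_c),
    timings_sec = timings,
    total_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  class(bundle) <- "report_bundle"
  if (!is.null(cfg$outdir)) write_bundle(bundle, cfg$outdir)
  bundle
}

#' Write a report bundle's tables and manifest
#'
#' @param bundle a [run_all()] bundle.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  if (!is.null(bundle$growth)) {
    wr(bundle$growth$table, "growth_table.csv")
    wr(bundle$growth$selection$table, "growth_model_selection.csv")
  }
  if (!is.null(bundle$diet)) {
    wr(bundle$diet$table, "diet_table.csv")
    wr(data.frame(bundle$diet$nmds$points), "diet_nmds_coordinates.csv")
  }
  if (!is.null(bundle$isotope)) wr(bundle$isotope$table, "isotope_table.csv")
  if (!is.null(bundle$community)) {
    wr(bundle$community$metrics, "community_table.csv")
    if (!is.null(bundle$community$removal))
      wr(bundle$community$removal, "community_removal.csv")
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' One-page human-readable summary of a report bundle
#'
#' @param bundle a [run_all()] bundle.
#' @return character vector of markdown lines (also printable with `cat`).
#' @export
report_summary <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  missing_st <- setdiff(c("growth", "diet", "isotope", "community"),
                        names(bundle))
  out <- c("# Pipeline summary", "")
  if (length(missing_st))
    out <- c(out, paste("Missing stages:", paste(missing_st, collapse = ", ")),
             "")
  fm <- function(x, d = 3) formatC(x, digits = d, format = "fg")
  if (!is.null(bundle$growth)) {
    st <- bundle$growth$selection$table
    out <- c(out, "## Growth model selection (dAIC)",
             sprintf("- %s  (k=%d, SSE=%.3f, dAIC=%.2f)%s", st$model, st$k,
                     st$SSE, st$dAIC,
                     ifelse(st$dAIC < 2 & st$dAIC > 0, "  [indistinguishable]",
                            "")),
             "", "## Length-weight and condition")
    gt <- bundle$growth$table
    out <- c(out, sprintf(
      "- %s: N=%d, b=%.2f (%s), Linf=%.1f cm, K=%.2f, t0=%.2f, cond=%.3f",
      gt$population_id, gt$N, gt$b, gt$isometry, gt$Linf, gt$K, gt$t0,
      gt$condition_mean), "")
  }
  if (!is.null(bundle$diet)) {
    dt <- bundle$diet$table
    out <- c(out, "## Diet",
             sprintf("- %s: N=%d, vacuity=%.0f%%, fullness=%.0f +/- %.0f%%, H=%.2f +/- %.2f, nMDS ellipse=%.2f",
                     dt$population_id, dt$N, dt$vacuity_pct, dt$fullness_mean,
                     dt$fullness_sd, dt$H_mean, dt$H_sd, dt$nmds_ellipse_area),
             sprintf("- PERMANOVA: F%d,%d = %.2f, R2 = %.2f, p = %.4g",
                     bundle$diet$permanova$df1, bundle$diet$permanova$df2,
                     bundle$diet$permanova$pseudo_F, bundle$diet$permanova$R2,
                     bundle$diet$permanova$p_perm), "")
  }
  if (!is.null(bundle$isotope)) {
    it <- bundle$isotope$table
    out <- c(out, "## Isotopes",
             sprintf("- %s: d15N=%.1f +/- %.1f, TP=%.1f (%.1f-%.1f), SEA_B=%.2f (%.2f-%.2f)",
                     it$population_id, it$d15N_mean, it$d15N_sd, it$TP_median,
                     it$TP_lo, it$TP_hi, it$SEAB_median, it$SEAB_lo,
                     it$SEAB_hi),
             "### Core-niche overlap (% of row ellipse)")
    ov <- bundle$isotope$overlap
    for (i in seq_len(nrow(ov)))
      out <- c(out, paste0("- ", rownames(ov)[i], ": ",
                           paste(sprintf("%s=%.1f%%", colnames(ov), ov[i, ]),
                                 collapse = ", ")))
    out <- c(out, "")
  }
  if (!is.null(bundle$community)) {
    cm <- bundle$community$metrics
    out <- c(out, "## Community",
             sprintf("- %s: density=%.2f /m2, richness=%d, H=%.2f",
                     cm$site_id, cm$total_density, cm$richness, cm$shannon_H))
    if (!is.null(bundle$community$removal)) {
      rv <- bundle$community$removal
      out <- c(out, sprintf("- removal %s: N=%.0f +/- %.1f (p=%.2f), %.3f /m2",
                            rv$site_id, rv$N_hat, rv$SE, rv$p_hat, rv$density))
    }
  }
  out
}
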