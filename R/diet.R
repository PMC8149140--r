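# Gut-content analysis: vacuity/fullness, Amundsen-Costello feeding-strategy
# statistics, dietary diversity, Bray-Curtis ordination with core-niche
# ellipses, PERMANOVA, SIMPER and exact prey accumulation curves.

#' Per-fish fullness from the long gut table
#'
#' @param guts data frame in the `gut` schema.
#' @return data frame `fish_id`, `population_id`, `total_length_cm`,
#'   `fullness` (one row per fish).
#' @export
gut_fullness <- function(guts) {
  f <- guts[guts$category == FULLNESS_CATEGORY, ]
  data.frame(fish_id = f$fish_id, population_id = f$population_id,
             total_length_cm = f$total_length_cm, fullness = f$volume_pct,
             stringsAsFactors = FALSE)
}

#' Diet matrix (fish x food category volumes)
#'
#' Rows are fish with non-empty guts; cells are volume percents, so each row
#' sums to that fish's fullness. Population labels are carried in attribute
#' `population` (and fullness in attribute `fullness`).
#'
#' @param guts data frame in the `gut` schema.
#' @param categories optional category universe (column order); defaults to
#'   the categories observed.
#' @return numeric matrix with `fish_id` rownames.
#' @export
diet_matrix <- function(guts, categories = NULL) {
  full <- gut_fullness(guts)
  keep <- full$fish_id[full$fullness > 0]
  items <- guts[guts$category != FULLNESS_CATEGORY & guts$fish_id %in% keep, ]
  if (is.null(categories)) categories <- sort(unique(items$category))
  unknown <- setdiff(unique(items$category), categories)
  if (length(unknown))
    stop("categories absent from the configured set: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  m <- matrix(0, nrow = length(keep), ncol = length(categories),
              dimnames = list(keep, categories))
  m[cbind(match(items$fish_id, keep), match(items$category, categories))] <-
    items$volume_pct
  attr(m, "population") <- full$population_id[match(keep, full$fish_id)]
  attr(m, "fullness") <- full$fullness[match(keep, full$fish_id)]
  m
}

#' Vacuity index
#'
#' Percentage of examined fish with empty guts.
#'
#' @param guts data frame in the `gut` schema (>= 1 fish).
#' @return percent in \[0, 100\].
#' @export
vacuity_index <- function(guts) {
  full <- gut_fullness(guts)
  if (!nrow(full)) stop("no guts", call. = FALSE)
  100 * mean(full$fullness == 0)
}

#' Mean gut fullness
#'
#' @param guts data frame in the `gut` schema.
#' @param include_empty whether empty guts (fullness 0) enter the mean
#'   (default `TRUE`).
#' @return list with `mean`, `sd`, `n`.
#' @export
mean_fullness <- function(guts, include_empty = TRUE) {
  full <- gut_fullness(guts)
  v <- if (include_empty) full$fullness else full$fullness[full$fullness > 0]
  if (!length(v)) stop("no guts retained", call. = FALSE)
  list(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
       n = length(v))
}

#' Frequency of occurrence of a food category
#'
#' `Fi% = 100 * Ni / N`: percentage of fish with the category in their gut,
#' over fish with non-empty guts.
#'
#' @param m diet matrix from [diet_matrix()].
#' @param category column name.
#' @return percent in \[0, 100\].
#' @export
occurrence_frequency <- function(m, category) {
  if (!category %in% colnames(m)) stop("unknown category: ", category,
                                       call. = FALSE)
  100 * mean(m[, category] > 0)
}

#' Prey-specific abundance of a food category
#'
#' `Pi% = 100 * sum(Si) / sum(Sti)`: the category's volume across the guts
#' containing it, divided by the total volume of all items in those same
#' guts.
#'
#' @inheritParams occurrence_frequency
#' @return percent in (0, 100\]; error if the category occurs nowhere.
#' @export
prey_specific_abundance <- function(m, category) {
  if (!category %in% colnames(m)) stop("unknown category: ", category,
                                       call. = FALSE)
  has <- m[, category] > 0
  if (!any(has)) stop("category '", category, "' occurs in no gut",
                      call. = FALSE)
  100 * sum(m[has, category]) / sum(m[has, , drop = FALSE])
}

#' Amundsen-Costello feeding-strategy points
#'
#' One (Fi%, Pi%) point per food category present: frequency of occurrence
#' against prey-specific abundance. Points towards the upper right indicate
#' dominant generalized prey; upper-left points indicate within-phenotype
#' specialization.
#'
#' @param m diet matrix from [diet_matrix()].
#' @return data frame `category`, `Fi`, `Pi`, sorted by decreasing `Fi`.
#' @export
amundsen_points <- function(m) {
  cats <- colnames(m)[colSums(m > 0) > 0]
  out <- data.frame(
    category = cats,
    Fi = vapply(cats, function(ct) occurrence_frequency(m, ct), 0),
    Pi = vapply(cats, function(ct) prey_specific_abundance(m, ct), 0),
    stringsAsFactors = FALSE)
  out <- out[order(-out$Fi, -out$Pi), ]
  rownames(out) <- NULL
  out
}

#' Per-fish dietary Shannon diversity with population summaries
#'
#' H is computed on each fish's volume proportions (volumes divided by the
#' fish's own fullness); the compositional view, so fullness itself does not
#' affect H.
#'
#' @param m diet matrix from [diet_matrix()].
#' @return list with `per_fish` (data frame `fish_id`, `population_id`, `H`)
#'   and `summary` (per-population mean, SD, n).
#' @export
diet_diversity <- function(m) {
  H <- apply(m, 1, shannon_diversity)
  pf <- data.frame(fish_id = rownames(m),
                   population_id = attr(m, "population"), H = unname(H),
                   stringsAsFactors = FALSE)
  sm <- do.call(rbind, lapply(split(pf, pf$population_id), function(s)
    data.frame(population_id = s$population_id[1], mean = mean(s$H),
               sd = stats::sd(s$H), n = nrow(s))))
  rownames(sm) <- NULL
  list(per_fish = pf, summary = sm)
}

#' Arcsine square-root transform
#'
#' `asin(sqrt(x))` elementwise for proportions in \[0, 1\]; the standard
#' variance-stabilizing transform for compositional diet data.
#'
#' @param x matrix or vector of proportions.
#' @return transformed object of the same shape (0 maps to 0, 1 to pi/2).
#' @export
transform_arcsine_sqrt <- function(x) {
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("entries must be proportions in [0, 1]", call. = FALSE)
  out <- asin(sqrt(x))
  attributes(out) <- attributes(x)
  out
}

#' Pairwise Bray-Curtis distance matrix
#'
#' @param m rows = objects, columns = categories.
#' @return a `dist` object.
#' @export
bray_curtis_matrix <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- bray_curtis(m[i, ], m[j, ])
  stats::as.dist(d)
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 (monotone regression of configuration
#' distances on dissimilarity ranks) over random restarts, then centers the
#' best configuration and rotates it to its principal axes so repeated runs
#' are comparable. The ordination engine is vegan's `metaMDS`/`monoMDS`.
#'
#' @param d `dist` object (>= 4 objects).
#' @param k dimensions (default 2).
#' @param n_restarts random restarts (default 20).
#' @param seed integer seed (mandatory for reproducibility).
#' @return list with `points` (n x k), `stress` (Kruskal stress-1, fraction),
#'   `converged`, `n_restarts`, `seed`.
#' @export
nmds <- function(d, k = 2, n_restarts = 20, seed = 1) {
  d <- stats::as.dist(d)
  if (attr(d, "Size") < 4) stop("need >= 4 objects", call. = FALSE)
  set.seed(as.integer(seed))
  if (max(d) == 0) {
    warning("all dissimilarities equal zero: arbitrary configuration")
    pts <- matrix(0, attr(d, "Size"), k,
                  dimnames = list(labels(d), paste0("NMDS", 1:k)))
    return(list(points = pts, stress = 0, converged = TRUE,
                n_restarts = n_restarts, seed = seed))
  }
  fit <- vegan::metaMDS(d, k = k, trymax = n_restarts, trace = 0,
                        maxit = 500, sratmax = 1 - 1e-6)
  pts <- scale(fit$points, center = TRUE, scale = FALSE)
  pts <- pts %*% stats::prcomp(pts)$rotation
  colnames(pts) <- paste0("NMDS", seq_len(k))
  rownames(pts) <- labels(d)
  list(points = pts, stress = fit$stress, converged = fit$converged > 0,
       n_restarts = n_restarts, seed = seed)
}

#' Standard ("core-niche") ellipse of a 2-D point cloud
#'
#' The Mahalanobis radius-1 ellipse of the group's bivariate mean and sample
#' covariance: for bivariate-normal data it encloses `1 - exp(-1/2)` (about
#' 39.35%) of the mass, the conventional "40%" core niche. Its area is
#' `pi * sqrt(det(cov))`.
#'
#' @param coords n x 2 matrix (n >= 3).
#' @param coverage nominal coverage label carried through (the geometry is
#'   the radius-1 standard ellipse; default 0.40).
#' @return list with `center`, `cov`, `semi_axes` (major, minor),
#'   `orientation` (radians of the major axis), `area`, `n`.
#' @export
core_ellipse <- function(coords, coverage = 0.40) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("need >= 3 points", call. = FALSE)
  S <- stats::cov(coords)
  if (det(S) <= 0) stop("singular covariance: points are collinear",
                        call. = FALSE)
  e <- eigen(S, symmetric = TRUE)
  list(center = colMeans(coords), cov = S,
       semi_axes = sqrt(e$values),
       orientation = atan2(e$vectors[2, 1], e$vectors[1, 1]),
       area = pi * sqrt(det(S)), coverage = coverage, n = nrow(coords))
}

.within_ss <- function(D2, f) {
  # sum over groups of (sum of squared within-group distances) / group size
  B <- rowsum(t(rowsum(D2, f)), f)   # group-block sums of D2
  sum(diag(B) / (2 * tabulate(f)))
}

#' Permutational multivariate analysis of variance (one factor)
#'
#' Pseudo-F from the partition of the squared-distance sums (the
#' Gower-centered partition) with an unrestricted permutation test of group
#' labels: `p = (#{permuted F >= observed} + 1) / (n_perm + 1)`.
#'
#' @param d `dist` object.
#' @param groups group labels (length = number of objects, >= 2 groups).
#' @param n_perm number of permutations (default 999, >= 99).
#' @param seed integer seed.
#' @return list with `pseudo_F`, `R2`, `df1`, `df2`, `p_perm`,
#'   `n_permutations`, `seed`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  d <- stats::as.dist(d)
  f <- factor(groups)
  n <- attr(d, "Size")
  if (length(f) != n) stop("labels must match distance size", call. = FALSE)
  if (nlevels(f) < 2) stop("need >= 2 groups", call. = FALSE)
  if (n_perm < 99) stop("need >= 99 permutations", call. = FALSE)
  if (any(tabulate(f) < 2))
    warning("group with a single member: its within-group SS is zero")
  D2 <- as.matrix(d)^2
  a <- nlevels(f)
  SS_T <- sum(D2) / (2 * n)
  SS_W <- .within_ss(D2, as.integer(f))
  SS_A <- SS_T - SS_W
  Fobs <- (SS_A / (a - 1)) / (SS_W / (n - a))
  set.seed(as.integer(seed))
  ge <- 0L
  fi <- as.integer(f)
  for (b in seq_len(n_perm)) {
    fp <- fi[sample.int(n)]
    SW <- .within_ss(D2, fp)
    Fp <- ((SS_T - SW) / (a - 1)) / (SW / (n - a))
    if (Fp >= Fobs) ge <- ge + 1L
  }
  list(pseudo_F = Fobs, R2 = SS_A / SS_T, df1 = a - 1, df2 = n - a,
       p_perm = (ge + 1) / (n_perm + 1), n_permutations = n_perm, seed = seed)
}

#' Similarity percentage breakdown (SIMPER)
#'
#' For each pair of groups, the average over all cross-group pairs of each
#' category's share of the Bray-Curtis numerator; per-pair contributions sum
#' exactly to the pair's overall average dissimilarity.
#'
#' @param m rows = objects, columns = categories.
#' @param groups group labels.
#' @return named list (one element per group pair `"A_vs_B"`), each a list
#'   with `overall` (average dissimilarity) and `contributions` (data frame
#'   `category`, `average`, `pct`, `cum_pct`, ranked by contribution).
#' @export
simper <- function(m, groups) {
  f <- factor(groups)
  if (nlevels(f) < 2) stop("need >= 2 groups", call. = FALSE)
  lv <- levels(f)
  out <- list()
  for (i in seq_len(nlevels(f) - 1)) for (j in (i + 1):nlevels(f)) {
    A <- m[f == lv[i], , drop = FALSE]
    B <- m[f == lv[j], , drop = FALSE]
    contr <- matrix(0, nrow(A) * nrow(B), ncol(m))
    r <- 0
    for (ia in seq_len(nrow(A))) for (ib in seq_len(nrow(B))) {
      r <- r + 1
      denom <- sum(A[ia, ]) + sum(B[ib, ])
      contr[r, ] <- abs(A[ia, ] - B[ib, ]) / denom
    }
    avg <- colMeans(contr)
    cd <- data.frame(category = colnames(m), average = avg,
                     pct = 100 * avg / sum(avg), stringsAsFactors = FALSE)
    cd <- cd[order(-cd$average), ]
    cd$cum_pct <- cumsum(cd$pct)
    rownames(cd) <- NULL
    out[[paste0(lv[i], "_vs_", lv[j])]] <-
      list(overall = sum(avg), contributions = cd)
  }
  out
}

#' Exact sample-based prey accumulation (rarefaction) curve
#'
#' Expected number of food categories observed in a random subsample of `m`
#' guts: `E[S(m)] = S_obs - sum_i C(N - N_i, m) / C(N, m)` with `N_i` the
#' number of guts containing category i. Exact (no resampling), computed with
#' log binomial coefficients.
#'
#' @param presence logical or 0/1 matrix, guts x categories.
#' @param m subsample sizes (default `1:N`).
#' @return data frame `m`, `expected_categories` (monotone non-decreasing).
#' @export
prey_accumulation <- function(presence, m = NULL) {
  presence <- presence > 0
  N <- nrow(presence)
  if (N < 2) stop("need >= 2 guts", call. = FALSE)
  if (is.null(m)) m <- seq_len(N)
  if (any(m < 1 | m > N)) stop("subsample size out of range", call. = FALSE)
  Ni <- colSums(presence)
  Ni <- Ni[Ni > 0]
  S_obs <- length(Ni)
  ES <- vapply(m, function(mm) {
    S_obs - sum(exp(lchoose(N - Ni, mm) - lchoose(N, mm)))
  }, 0)
  data.frame(m = m, expected_categories = ES)
}
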