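# Site-level fish and macroinvertebrate community metrics: two-pass removal
# abundance, density, richness, diversity and between-site dissimilarity.

#' Two-pass removal (Moran-Zippin) abundance estimate
#'
#' Closed-population estimator from successive depletion catches:
#' `N_hat = C1^2 / (C1 - C2)`, `p_hat = (C1 - C2) / C1`, with the standard
#' two-pass variance `Var(N_hat) = C1^2 C2^2 (C1 + C2) / (C1 - C2)^4`.
#' Assumes a closed population and equal catchability across passes. When
#' `C2 >= C1` the estimator is undefined: the minimum-known-alive fallback
#' `C1 + C2` is returned with `degenerate = TRUE` and a warning.
#'
#' @param C1,C2 first- and second-pass catches (non-negative integers).
#' @return list with `N_hat`, `SE`, `p_hat`, `C1`, `C2`, `degenerate`.
#' @export
zippin_two_pass <- function(C1, C2) {
  stopifnot(C1 >= 0, C2 >= 0)
  if (C2 >= C1) {
    warning("C2 >= C1: depletion estimator undefined; ",
            "returning minimum known alive (C1 + C2)")
    return(list(N_hat = C1 + C2, SE = NA_real_, p_hat = NA_real_,
                C1 = C1, C2 = C2, degenerate = TRUE))
  }
  N_hat <- C1^2 / (C1 - C2)
  SE <- sqrt(C1^2 * C2^2 * (C1 + C2)) / (C1 - C2)^2
  list(N_hat = N_hat, SE = SE, p_hat = (C1 - C2) / C1,
       C1 = C1, C2 = C2, degenerate = FALSE)
}

#' Brute-force two-pass removal maximum likelihood
#'
#' Independent oracle for [zippin_two_pass()]: numerically maximizes the
#' conditional removal likelihood of the catch split over the capture
#' probability (captures distributed between passes proportional to
#' `p : (1-p) p`, conditional on capture), then `N = T / (1 - (1-p)^2)`.
#' The general k-pass form of the removal ML.
#'
#' @param catches vector of per-pass catches (k >= 2 passes).
#' @return list with `N_hat`, `p_hat`.
#' @export
removal_ml <- function(catches) {
  k <- length(catches)
  stopifnot(k >= 2, all(catches >= 0))
  Tt <- sum(catches)
  if (Tt == 0) stop("no catches", call. = FALSE)
  negll <- function(p) {
    q <- 1 - p
    cell <- p * q^(seq_len(k) - 1) / (1 - q^k)
    -sum(catches * log(cell))
  }
  opt <- stats::optimize(negll, c(1e-9, 1 - 1e-9), tol = 1e-10)
  p <- opt$minimum
  # polish with the score equation (golden-section precision is too coarse
  # where the abundance surface is steep in p)
  score <- function(p) {
    q <- 1 - p
    S <- sum((seq_len(k) - 1) * catches)
    Tt / p - S / q - Tt * k * q^(k - 1) / (1 - q^k)
  }
  lo <- max(p - 1e-3, 1e-12); hi <- min(p + 1e-3, 1 - 1e-12)
  if (is.finite(score(lo)) && is.finite(score(hi)) &&
      sign(score(lo)) != sign(score(hi))) {
    p <- stats::uniroot(score, c(lo, hi), tol = 1e-14)$root
  }
  list(N_hat = Tt / (1 - (1 - p)^k), p_hat = p)
}

#' Abundance to areal density
#'
#' @param N_hat estimated abundance.
#' @param area sampled area in m^2 (> 0).
#' @return individuals per m^2.
#' @export
density_per_m2 <- function(N_hat, area) {
  if (area <= 0) stop("area must be > 0", call. = FALSE)
  N_hat / area
}

#' Community metrics per site
#'
#' Total density (individuals per m^2), richness (taxa with positive count)
#' and Shannon-Wiener diversity for each site of a community count table.
#'
#' @param counts data frame in the `community` schema.
#' @return data frame `site_id`, `total_density`, `richness`, `shannon_H`.
#' @export
community_metrics <- function(counts) {
  out <- do.call(rbind, lapply(split(counts, counts$site_id), function(s) {
    if (sum(s$count) == 0) stop("site '", s$site_id[1], "': empty community",
                                call. = FALSE)
    data.frame(site_id = s$site_id[1],
               total_density = sum(s$count) / s$area_m2[1],
               richness = sum(s$count > 0),
               shannon_H = shannon_diversity(s$count),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Between-site Bray-Curtis dissimilarity
#'
#' Pairwise compositional dissimilarity of the site count vectors over the
#' shared taxon universe (absent taxa count as zero).
#'
#' @param counts data frame in the `community` schema (>= 2 sites).
#' @return a `dist` object.
#' @export
community_dissimilarity <- function(counts) {
  sites <- unique(counts$site_id)
  if (length(sites) < 2) stop("need >= 2 sites", call. = FALSE)
  taxa <- sort(unique(counts$taxon))
  m <- matrix(0, length(sites), length(taxa), dimnames = list(sites, taxa))
  m[cbind(match(counts$site_id, sites), match(counts$taxon, taxa))] <-
    counts$count
  bray_curtis_matrix(m)
}
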