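# Generic statistical kernel shared by the analysis modules.

#' Shannon-Wiener diversity
#'
#' H = -sum p_i log(p_i) over the positive proportions of `x`. Natural
#' logarithm by default, matching the convention of the ecology software
#' family this pipeline mirrors; change `base` for bits/decits.
#'
#' @param x non-negative abundance (or volume) vector with at least one
#'   positive entry.
#' @param base logarithm base (default `exp(1)`, nats).
#' @return diversity H with `0 <= H <= log(S, base)` for S positive categories.
#' @export
shannon_diversity <- function(x, base = exp(1)) {
  if (any(x < 0) || anyNA(x)) stop("abundances must be non-negative", call. = FALSE)
  if (sum(x) == 0) stop("all-zero abundance vector", call. = FALSE)
  p <- x[x > 0] / sum(x)
  -sum(p * log(p)) / log(base)
}

#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' `1 - 2 * sum(pmin(a, b)) / (sum(a) + sum(b))`: 0 for identical
#' compositions, 1 for disjoint ones.
#'
#' @param a,b equal-length non-negative vectors, not both all-zero.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  if (any(a < 0) || any(b < 0)) stop("abundances must be non-negative", call. = FALSE)
  s <- sum(a) + sum(b)
  if (s == 0) stop("both vectors are all-zero", call. = FALSE)
  1 - 2 * sum(pmin(a, b)) / s
}

.as_group_df <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need a list of >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs >= 2 observations", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  data.frame(
    y = unlist(groups, use.names = FALSE),
    g = factor(rep(names(groups), vapply(groups, length, 1L)))
  )
}

#' One-way analysis of variance
#'
#' Classical fixed-effects ANOVA (between/within mean-square ratio) via
#' [stats::aov()].
#'
#' @param groups list of numeric samples, each of length >= 2.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
anova_oneway <- function(groups) {
  d <- .as_group_df(groups)
  tab <- summary(stats::aov(y ~ g, data = d))[[1]]
  list(F = tab[1, "F value"], df1 = tab[1, "Df"], df2 = tab[2, "Df"],
       p = tab[1, "Pr(>F)"])
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' Studentized-range adjusted pairwise tests after a one-way ANOVA
#' ([stats::TukeyHSD()]).
#'
#' @inheritParams anova_oneway
#' @return data frame with `pair`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  d <- .as_group_df(groups)
  tk <- stats::TukeyHSD(stats::aov(y ~ g, data = d))$g
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"], row.names = NULL)
}

#' MANOVA with Pillai's trace
#'
#' One-way multivariate comparison (here of length and age) across groups.
#' Pillai's trace is `tr(H (H + E)^-1)` with `H` the between-group and `E`
#' the within-group cross-product matrices, with the standard F
#' approximation. Computed from the cross-product matrices directly so the
#' univariate case reduces exactly to the classical ANOVA F.
#'
#' @param responses numeric matrix with n rows and >= 1 response columns.
#' @param groups group labels of length n.
#' @return list with `pillai`, `F_approx`, `df1`, `df2`, `p`.
#' @export
manova_pillai <- function(responses, groups) {
  Y <- as.matrix(responses)
  g <- factor(groups)
  if (nrow(Y) != length(g)) stop("dimension mismatch", call. = FALSE)
  if (nrow(Y) <= nlevels(g) + 2)
    stop("need n > number of groups + 2", call. = FALSE)
  N <- nrow(Y); p <- ncol(Y); a <- nlevels(g)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Tm <- crossprod(Yc)
  E <- matrix(0, p, p)
  for (lv in levels(g)) {
    Yg <- Y[g == lv, , drop = FALSE]
    E <- E + crossprod(scale(Yg, center = TRUE, scale = FALSE))
  }
  if (rcond(E) < 1e-12)
    stop("singular within-group cross-product matrix: add data or drop groups",
         call. = FALSE)
  H <- Tm - E
  V <- sum(diag(H %*% solve(H + E)))          # Pillai's trace
  s <- min(a - 1, p)
  m <- (abs(p - (a - 1)) - 1) / 2
  nn <- (N - a - p - 1) / 2
  df1 <- s * (2 * m + s + 1)
  df2 <- s * (2 * nn + s + 1)
  Fa <- (df2 / df1) * (V / (s - V))
  list(pillai = V, F_approx = Fa, df1 = df1, df2 = df2,
       p = stats::pf(Fa, df1, df2, lower.tail = FALSE))
}

#' Ordinary least-squares simple linear regression
#'
#' Wrapper over [stats::lm()] returning the quantities the analysis modules
#' consume.
#'
#' @param x predictor (>= 3 points, not constant).
#' @param y response.
#' @return list with `intercept`, `slope`, `se_slope`, `r_squared`,
#'   `residuals`, `p_slope`, `n`.
#' @export
linear_regression <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 finite points", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  cf <- summary(fit)$coefficients
  list(intercept = cf["(Intercept)", "Estimate"],
       slope = cf["x", "Estimate"],
       se_slope = cf["x", "Std. Error"],
       r_squared = summary(fit)$r.squared,
       residuals = stats::residuals(fit),
       p_slope = cf["x", "Pr(>|t|)"],
       n = length(x))
}
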