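#' Mixed-model ANOVA of per-photo PC scores
#'
#' Repeated photographs of the same horse are not independent, so the effect
#' of a horse-level factor on a shape score is tested with a random-intercept
#' model, `score = factor + (1 | individual) + residual`, fitted by
#' restricted maximum likelihood (through \pkg{lme4}). The F statistic is the
#' Wald F for the fixed factor; because every tested factor is constant
#' within individual, the denominator degrees of freedom follow the
#' containment rule, `n_individuals - n_levels`.
#'
#' @param scores numeric per-photo scores.
#' @param factor per-photo factor values (character/factor/numeric treated as
#'   categorical); must be constant within each individual.
#' @param individual per-photo individual (horse) identifiers.
#' @param label factor name carried into the result.
#' @param component component index carried into the result (metadata).
#' @return An object of class `anova_result`: list with `factor`,
#'   `component`, `F`, `p`, `df_num`, `df_den`, `n_individuals`, `n_photos`.
#' @export
mixed_anova_pc <- function(scores, factor, individual, label = "factor",
                           component = NA_integer_) {
  stopifnot(length(scores) == length(factor), length(scores) == length(individual))
  individual <- as.character(individual)
  fac <- base::factor(factor)
  per_ind <- tapply(as.character(fac), individual, function(v) length(unique(v)))
  if (any(per_ind > 1)) {
    stop("factor varies within individual(s): ",
         paste(names(per_ind)[per_ind > 1], collapse = ", "), call. = FALSE)
  }
  n_ind <- length(unique(individual))
  n_lev <- nlevels(fac)
  if (n_lev < 2) stop("factor needs at least 2 levels", call. = FALSE)
  ind_per_level <- tapply(individual, fac, function(v) length(unique(v)))
  if (any(ind_per_level < 2)) {
    warning("factor level(s) with a single individual: ",
            paste(names(ind_per_level)[ind_per_level < 2], collapse = ", "),
            "; denominator df reduced accordingly")
  }
  dat <- data.frame(score = scores, fac = fac, ind = individual)
  fit <- suppressMessages(lme4::lmer(
    score ~ fac + (1 | ind), data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore",
                                calc.derivs = FALSE)
  ))
  av <- stats::anova(fit)
  F_val <- av[["F value"]][1]
  df_num <- av[["npar"]][1]
  if (is.null(df_num)) df_num <- av[["Df"]][1]
  df_den <- n_ind - n_lev
  if (df_den < 1) stop("not enough individuals for the containment df", call. = FALSE)
  p <- stats::pf(F_val, df_num, df_den, lower.tail = FALSE)
  structure(list(
    factor = label, component = component, F = F_val, p = p,
    df_num = df_num, df_den = df_den,
    n_individuals = n_ind, n_photos = length(scores)
  ), class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> %s%s: F(%d, %d) = %.4g, p = %.4g  (%d horses, %d photos)\n",
              x$factor,
              if (is.na(x$component)) "" else sprintf(" on PC%d", x$component),
              x$df_num, x$df_den, x$F, x$p, x$n_individuals, x$n_photos))
  invisible(x)
}

#' Kruskal-Wallis test
#'
#' Rank-based comparison of one quantitative variable across the levels of a
#' qualitative one, tie-corrected, with the chi-square reference
#' distribution. When all observations are tied the statistic is undefined
#' and returned as `NA` with `p = 1` (`degenerate = TRUE`).
#'
#' @param values numeric vector, or a list of per-group numeric vectors.
#' @param groups group labels (ignored when `values` is a list).
#' @return list with `statistic`, `p`, `df`, `degenerate`.
#' @export
kruskal_wallis <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values)
  }
  groups <- base::factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (length(values) < 2) stop("need at least 2 observations", call. = FALSE)
  if (length(unique(values)) == 1) {
    return(list(statistic = NA_real_, p = 1, df = nlevels(groups) - 1L,
                degenerate = TRUE))
  }
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), degenerate = FALSE)
}

#' Chi-square test of a contingency table, with Monte Carlo option
#'
#' Pearson chi-square (no continuity correction). When `monte_carlo = TRUE`
#' and any observed or expected count is below 5, the p-value is estimated
#' from `reps` tables resampled conditional on both margins,
#' `p = (1 + #resampled X^2 >= observed) / (reps + 1)`; otherwise the
#' asymptotic chi-square p is used.
#'
#' @param table matrix of non-negative integer counts, at least 2x2.
#' @param monte_carlo enable the Monte Carlo method for sparse tables.
#' @param reps number of resampled tables.
#' @param seed integer seed making the Monte Carlo p reproducible.
#' @return list with `statistic`, `p`, `df` (`NA` for Monte Carlo),
#'   `method` (`"asymptotic"` or `"monte_carlo"`).
#' @export
chi_square <- function(table, monte_carlo = FALSE, reps = 2000, seed = NULL) {
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (nrow(table) < 2 || ncol(table) < 2) stop("table must be at least 2x2", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin", call. = FALSE)
  }
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  sparse <- any(expected < 5) || any(table < 5)
  if (monte_carlo && sparse) {
    if (is.null(seed)) stop("seed required for the Monte Carlo method", call. = FALSE)
    set.seed(seed)
    ct <- stats::chisq.test(table, simulate.p.value = TRUE, B = reps)
    list(statistic = unname(ct$statistic), p = ct$p.value, df = NA_integer_,
         method = "monte_carlo")
  } else {
    ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    list(statistic = unname(ct$statistic), p = ct$p.value,
         df = unname(ct$parameter), method = "asymptotic")
  }
}

#' Pearson correlation test
#'
#' Product-moment correlation between two quantitative variables with the
#' t-distribution p-value.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `r`, `p`, `df`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, df = unname(ct$parameter))
}
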