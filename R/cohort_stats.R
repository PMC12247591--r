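# Group-comparison, trend, adjusted-correlation, FDR, regression and
# sensitivity statistics over per-subject metric tables.

#' Cohen's d (pooled-SD convention)
#'
#' @param x,y Numeric samples.
#' @return Standardized mean difference `(mean(x) - mean(y)) / s_pooled`.
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Welch's two-sample t-test with Cohen's d
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value; the effect size is Cohen's d with the pooled-SD
#' convention.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param contrast Label for the comparison.
#' @return A [stat_result()] row.
#' @export
welch_t <- function(x, y, contrast = "x_vs_y") {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2",
                                           call. = FALSE)
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(stat_result("welch_t", contrast, estimate = 0, effect_size = 0,
                         statistic = 0, df = length(x) + length(y) - 2, p = 1,
                         n = length(x) + length(y)))
    }
    stop("zero variance in both samples", call. = FALSE)
  }
  tt <- t.test(x, y, var.equal = FALSE)
  stat_result("welch_t", contrast,
              estimate = mean(x) - mean(y), effect_size = cohens_d(x, y),
              statistic = unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value, n = length(x) + length(y))
}

#' One-way ANOVA across groups
#'
#' @param groups List of numeric samples (>= 2 groups, each n >= 2).
#' @param contrast Label.
#' @return A [stat_result()] row (`statistic` = F on `k - 1` numerator df;
#'   `df` stores the denominator df).
#' @export
one_way_anova <- function(groups, contrast = "all_groups") {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2)) stop("every group needs n >= 2",
                                     call. = FALSE)
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (var(y) == 0) {
    return(stat_result("anova", contrast, statistic = 0,
                       df = length(y) - length(groups), p = 1, n = length(y)))
  }
  ow <- oneway.test(y ~ g, var.equal = TRUE)
  stat_result("anova", contrast, statistic = unname(ow$statistic),
              df = unname(ow$parameter["denom df"]), p = ow$p.value,
              n = length(y))
}

# build a covariate design (drops constant columns with a message)
covariate_design <- function(covariates, n) {
  if (is.null(covariates) || length(covariates) == 0 ||
      (is.data.frame(covariates) && ncol(covariates) == 0)) {
    return(matrix(nrow = n, ncol = 0))
  }
  covariates <- as.data.frame(covariates)
  keep <- vapply(covariates, function(v) length(unique(v[!is.na(v)])) > 1,
                 TRUE)
  if (!all(keep)) {
    cp_msg("dropping constant covariate(s): ",
           paste(names(covariates)[!keep], collapse = ", "))
  }
  covariates <- covariates[, keep, drop = FALSE]
  if (ncol(covariates) == 0) return(matrix(nrow = n, ncol = 0))
  mm <- model.matrix(~ ., data = covariates)
  mm[, -1, drop = FALSE]
}

#' Covariate-adjusted group contrast by linear modelling
#'
#' Fits `metric ~ group + covariates` (Gaussian, identity link) and reports
#' the group-coefficient test. With three groups, each pairwise contrast is
#' fit on the corresponding subset, mirroring pairwise adjusted comparisons.
#'
#' @param metric Numeric vector.
#' @param group Factor of group labels.
#' @param covariates Data.frame of covariates (may be NULL); constant columns
#'   are dropped, factor columns are indicator-coded, ordered factors are
#'   coded as their level index.
#' @return A results data.frame with one row per pairwise contrast.
#' @export
adjusted_group_contrast <- function(metric, group, covariates = NULL) {
  group <- droplevels(factor(group))
  levs <- levels(group)
  if (length(levs) < 2) stop("need >= 2 groups", call. = FALSE)
  covariates <- prep_covariates(covariates)
  pair_fit <- function(la, lb) {
    sel <- group %in% c(la, lb)
    cv <- if (is.null(covariates)) NULL else
      covariates[sel, , drop = FALSE]
    y <- metric[sel]
    gi <- as.numeric(group[sel] == lb)
    X <- cbind(grp = gi, covariate_design(cv, sum(sel)))
    ok <- complete.cases(X) & !is.na(y)
    if (sum(ok) < ncol(X) + 2) stop("n too small for adjusted contrast",
                                    call. = FALSE)
    X <- X[ok, , drop = FALSE]; y <- y[ok]
    if (qr(cbind(1, X))$rank < ncol(X) + 1) {
      stop("rank-deficient design in adjusted contrast", call. = FALSE)
    }
    fit <- lm(y ~ X)
    sm <- summary(fit)$coefficients
    row <- sm[2, ]  # intercept first, group indicator second
    stat_result("adjusted_lm", paste0(lb, "_vs_", la),
                estimate = unname(row[1]),
                effect_size = unname(row[1]) / sd(y),
                statistic = unname(row[3]), df = fit$df.residual,
                p = unname(row[4]), n = length(y))
  }
  pairs <- utils::combn(levs, 2, simplify = FALSE)
  bind_results(lapply(pairs, function(pr) pair_fit(pr[1], pr[2])))
}

# normalize a covariate frame: ordered factors -> numeric scores,
# characters -> factors
prep_covariates <- function(covariates) {
  if (is.null(covariates)) return(NULL)
  covariates <- as.data.frame(covariates)
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (is.ordered(v)) covariates[[nm]] <- as.numeric(v)
    else if (is.character(v) || is.logical(v)) covariates[[nm]] <- factor(v)
  }
  covariates
}

#' Cuzick's nonparametric test for trend across ordered groups
#'
#' Wilcoxon-type rank statistic with integer group scores, normal
#' approximation with tie correction, two-sided p.
#'
#' @param metric Numeric vector.
#' @param ordered_group Ordered factor (or factor whose level order encodes
#'   the trend).
#' @return A [stat_result()] row (`statistic` = z).
#' @export
trend_test <- function(metric, ordered_group) {
  g <- droplevels(factor(ordered_group, ordered = TRUE))
  if (nlevels(g) < 2) stop("need >= 2 ordered groups", call. = FALSE)
  if (length(unique(metric)) == 1) stop("all values tied", call. = FALSE)
  N <- length(metric)
  l <- as.numeric(g)
  r <- rank(metric)
  T_obs <- sum(l * r)
  n_i <- tabulate(as.integer(g))
  scores <- seq_len(nlevels(g))
  ET <- (N + 1) / 2 * sum(n_i * scores)
  tie <- table(metric)
  tie_corr <- 1 - sum(tie^3 - tie) / (N^3 - N)
  VT <- (N + 1) / 12 * (N * sum(n_i * scores^2) - sum(n_i * scores)^2) *
    tie_corr
  if (VT <= 0) stop("degenerate trend test (no variance)", call. = FALSE)
  z <- (T_obs - ET) / sqrt(VT)
  stat_result("cuzick_trend", paste(levels(g), collapse = "<"),
              estimate = T_obs, statistic = z, df = NA_real_,
              p = 2 * pnorm(-abs(z)), n = N)
}

residualize <- function(v, design) {
  if (ncol(design) == 0) return(v - mean(v))
  lm.fit(cbind(1, design), v)$residuals
}

#' Multivariable-adjusted Spearman correlation
#'
#' Rank-transforms both variables, residualizes each on the covariates by
#' least squares, and correlates the residuals; the p-value uses the t
#' approximation `t = rho * sqrt((n - 2 - q) / (1 - rho^2))` with `q`
#' adjusted-for covariate terms. With no covariates this is the ordinary
#' Spearman rho with t-approximation p.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional covariate data.frame.
#' @param contrast Label.
#' @return A [stat_result()] row (`effect_size` = rho).
#' @export
adjusted_spearman <- function(x, y, covariates = NULL, contrast = "x_vs_y") {
  ok <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) {
    covariates <- prep_covariates(covariates)
    ok <- ok & complete.cases(covariates)
    covariates <- covariates[ok, , drop = FALSE]
  }
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("constant input after ranking", call. = FALSE)
  }
  design <- covariate_design(covariates, n)
  q <- ncol(design)
  if (n < q + 3) stop("n too small for adjusted correlation", call. = FALSE)
  rx <- residualize(rank(x), design)
  ry <- residualize(rank(y), design)
  rho <- cor(rx, ry)
  df <- n - 2 - q
  if (abs(rho) >= 1) {
    p <- 0; tstat <- sign(rho) * Inf
  } else {
    tstat <- rho * sqrt(df / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df)
  }
  stat_result("adjusted_spearman", contrast, estimate = rho,
              effect_size = rho, statistic = tstat, df = df, p = p, n = n)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure over a family of p-values.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level in `(0, 1)`.
#' @return List: `rejected` (logical, input order), `p_adjusted` (BH-adjusted
#'   p-values, monotone in the raw p-values).
#' @export
bh_fdr <- function(pvals, alpha = 0.05) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  adj <- p.adjust(pvals, method = "BH")
  list(rejected = adj <= alpha, p_adjusted = adj)
}

#' Ordinary least squares with standardized coefficients
#'
#' Z-scores the response and the continuous predictors, fits OLS, and
#' reports a standardized beta, t statistic and p-value per non-intercept
#' coefficient.
#'
#' @param y Numeric response.
#' @param X Data.frame of predictors (factors are indicator-coded and left
#'   unscaled).
#' @return A results data.frame, one row per coefficient.
#' @export
ols_standardized <- function(y, X) {
  X <- prep_covariates(as.data.frame(X))
  ok <- !is.na(y) & complete.cases(X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  if (sd(y) == 0) stop("zero-variance response", call. = FALSE)
  for (nm in names(X)) {
    if (is.numeric(X[[nm]])) {
      if (sd(X[[nm]]) == 0) stop("zero-variance column: ", nm, call. = FALSE)
      X[[nm]] <- as.numeric(scale(X[[nm]]))
    }
  }
  mm <- model.matrix(~ ., data = X)
  if (qr(mm)$rank < ncol(mm)) stop("rank-deficient design", call. = FALSE)
  if (nrow(mm) <= ncol(mm)) stop("n too small", call. = FALSE)
  ys <- as.numeric(scale(y))
  fit <- lm(ys ~ mm - 1)
  sm <- summary(fit)$coefficients
  terms <- sub("^mm", "", rownames(sm))
  rows <- lapply(which(terms != "(Intercept)"), function(i) {
    stat_result("ols_standardized", terms[i],
                estimate = sm[i, 1], effect_size = sm[i, 1],
                statistic = sm[i, 3], df = fit$df.residual, p = sm[i, 4],
                n = length(ys))
  })
  bind_results(rows)
}

#' Sample skewness and kurtosis
#'
#' Moment-based diagnostics: skewness `g1 = m3 / m2^(3/2)`, Pearson kurtosis
#' `m4 / m2^2` and its excess form (Pearson minus 3). Both kurtosis
#' conventions are reported because published values often leave the
#' convention unstated.
#'
#' @param x Numeric vector, n >= 3, non-constant.
#' @return List: `skew`, `kurtosis_excess`, `kurtosis_pearson`, `n`.
#' @export
distribution_diagnostics <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) stop("constant vector", call. = FALSE)
  m3 <- mean((x - mean(x))^3)
  m4 <- mean((x - mean(x))^4)
  list(skew = m3 / m2^1.5, kurtosis_excess = m4 / m2^2 - 3,
       kurtosis_pearson = m4 / m2^2, n = n)
}

#' Outlier sensitivity analysis
#'
#' Re-runs an analysis after removing the `k` highest-wCPL subjects within
#' one named group (other groups are untouched), and counts subjects above a
#' reporting threshold.
#'
#' @param data Data.frame holding at least `wcpl` and the grouping column.
#' @param group Group label whose top-wCPL members are trimmed.
#' @param k Number of subjects to remove (0 <= k < group size).
#' @param analysis Function `data -> stat_result` (or results data.frame).
#' @param group_col Name of the grouping column.
#' @param threshold Optional wCPL reporting cutoff; when given, the count of
#'   subjects above it (and how many are in `group`) is reported.
#' @return List: `full`, `trimmed` (analysis outputs), `removed_ids` (row
#'   indices or subject ids removed), `n_above_threshold`,
#'   `n_above_threshold_in_group`.
#' @export
outlier_sensitivity <- function(data, group, k, analysis,
                                group_col = "group", threshold = NULL) {
  in_group <- data[[group_col]] == group
  if (k >= sum(in_group)) stop("k must be smaller than the group size",
                               call. = FALSE)
  drop_idx <- integer(0)
  if (k > 0) {
    gi <- which(in_group)
    drop_idx <- gi[order(data$wcpl[gi], decreasing = TRUE)[seq_len(k)]]
  }
  trimmed_data <- if (length(drop_idx) > 0) data[-drop_idx, , drop = FALSE]
    else data
  out <- list(full = analysis(data), trimmed = analysis(trimmed_data),
              removed_ids = if ("subject_id" %in% names(data))
                data$subject_id[drop_idx] else drop_idx)
  if (!is.null(threshold)) {
    out$n_above_threshold <- sum(data$wcpl > threshold)
    out$n_above_threshold_in_group <- sum(data$wcpl > threshold & in_group)
  }
  out
}
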