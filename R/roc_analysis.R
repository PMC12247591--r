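# ROC discrimination analysis: single-feature AUC with DeLong confidence
# intervals, and logistic combination of imaging features with demographics.

as_binary <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.character(labels)
  u <- sort(unique(labels))
  if (length(u) != 2 && !all(labels %in% c(0, 1))) {
    stop("labels must be binary with both classes present", call. = FALSE)
  }
  if (is.numeric(labels)) return(as.integer(labels != 0))
  as.integer(labels == u[2])
}

#' ROC area under the curve with DeLong confidence interval
#'
#' AUC by the Mann-Whitney construction (ties count one half); the 95%
#' confidence interval uses the DeLong placement-variance estimator, clipped
#' to `[0, 1]`.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary labels (logical, 0/1, or a two-level factor whose
#'   second sorted level is the case).
#' @param model Label stored in the result (`"single_feature"` or
#'   `"combined"`).
#' @param conf_level Confidence level (default 0.95).
#' @return A `roc_result` list: `auc`, `ci_low`, `ci_high`, `se`, `n_pos`,
#'   `n_neg`, `model`.
#' @export
roc_auc <- function(scores, labels, model = "single_feature",
                    conf_level = 0.95) {
  y <- as_binary(labels)
  pos <- scores[y == 1]; neg <- scores[y == 0]
  n_pos <- length(pos); n_neg <- length(neg)
  if (n_pos < 1 || n_neg < 1) stop("both classes must be present",
                                   call. = FALSE)
  if (length(unique(scores)) == 1) {
    warning("all scores tied; AUC = 0.5")
    return(structure(list(auc = 0.5, ci_low = 0.5, ci_high = 0.5, se = 0,
                          n_pos = n_pos, n_neg = n_neg, model = model),
                     class = "roc_result"))
  }
  # placements: P(neg < s) + 0.5 P(neg == s) per positive, and the converse
  v10 <- vapply(pos, function(s) (sum(neg < s) + 0.5 * sum(neg == s)) / n_neg,
                0)
  v01 <- vapply(neg, function(s) (sum(pos > s) + 0.5 * sum(pos == s)) / n_pos,
                0)
  auc <- mean(v10)
  se <- sqrt(var(v10) / n_pos + var(v01) / n_neg)
  zq <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(auc = auc, ci_low = max(0, auc - zq * se),
                 ci_high = min(1, auc + zq * se), se = se, n_pos = n_pos,
                 n_neg = n_neg, model = model), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result %s> AUC = %.3f, 95%% CI [%.3f-%.3f], %d/%d\n",
              x$model, x$auc, x$ci_low, x$ci_high, x$n_pos, x$n_neg))
  invisible(x)
}

#' Logistic combination of features and covariates
#'
#' Fits an in-sample logistic model of the binary label on the imaging
#' features plus demographic covariates and scores subjects by their fitted
#' probabilities. The returned AUC is apparent (same-sample) performance;
#' no resampling correction is applied and the result notes this. Perfect
#' separation triggers a ridge-penalized fallback fit with a warning.
#'
#' @param features Data.frame (or vector) of imaging features.
#' @param labels Binary labels.
#' @param covariates Optional covariate data.frame.
#' @return List: `scores` (fitted probabilities), `roc` (a `roc_result` with
#'   `model = "combined"`), `separation` flag, `note`.
#' @export
combined_score <- function(features, labels, covariates = NULL) {
  y <- as_binary(labels)
  X <- as.data.frame(features)
  if (!is.null(covariates)) X <- cbind(X, as.data.frame(covariates))
  X <- prep_covariates(X)
  ok <- complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  mm <- model.matrix(~ ., data = X)
  if (qr(mm)$rank < ncol(mm)) stop("rank-deficient design", call. = FALSE)
  fit <- suppressWarnings(glm(y ~ mm - 1, family = binomial()))
  separated <- !fit$converged || any(abs(coef(fit)) > 15) ||
    all(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)
  if (separated) {
    warning("(near-)separation detected; using ridge-penalized logistic fit")
    Xr <- mm[, -1, drop = FALSE]
    if (ncol(Xr) < 2) Xr <- cbind(Xr, jitter_col = 0)  # glmnet needs >= 2
    rfit <- glmnet::glmnet(Xr, y, family = "binomial", alpha = 0,
                           lambda = 1e-2)
    scores <- as.numeric(predict(rfit, newx = Xr, type = "response"))
  } else {
    scores <- fit$fitted.values
  }
  list(scores = scores, roc = roc_auc(scores, y, model = "combined"),
       separation = separated,
       note = "apparent (in-sample) AUC; no resampling correction")
}

#' Rank correlation between two features
#'
#' Spearman rho with the t-approximation p-value; a thin wrapper over
#' [adjusted_spearman()] with no covariates.
#'
#' @param f1,f2 Numeric vectors (n >= 3).
#' @param contrast Label.
#' @return A [stat_result()] row.
#' @export
feature_correlation <- function(f1, f2, contrast = "f1_vs_f2") {
  if (length(f1) < 3) stop("need n >= 3", call. = FALSE)
  adjusted_spearman(f1, f2, covariates = NULL, contrast = contrast)
}
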