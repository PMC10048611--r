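# Multivariable logistic risk modelling: parsimonious model building by
# backward selection with a change-in-estimate guard, Nagelkerke pseudo-R2,
# AUROC with a DeLong confidence interval, variance-explained increments,
# and gene-environment multiplicative interaction tests.

#' Fit a binomial logistic regression
#'
#' Maximum-likelihood fit (IRLS via `stats::glm`) on complete cases, with
#' standard errors from the observed information. Rank-deficient designs
#' are an error naming the collinear columns; (quasi-)complete separation
#' is flagged and confidence intervals are suppressed for the affected
#' fit.
#'
#' @param data Data frame.
#' @param formula Model formula with a binary (0/1 or logical) outcome.
#' @return A `logistic_fit`: `predictors`, `coefficients`, `se`,
#'   `loglik_fit`, `loglik_null`, `n`, `converged`, `separation`,
#'   `fitted`, `outcome`, plus the formula and model frame for refits.
#' @export
#' @examples
#' d <- data.frame(y = rbinom(100, 1, 0.4), x = rnorm(100))
#' fit_logistic(d, y ~ x)
fit_logistic <- function(data, formula) {
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% 0:1)) stop("outcome must be binary 0/1")
  n <- length(y)
  p <- ncol(stats::model.matrix(attr(mf, "terms"), mf))
  if (n <= p) stop("need more observations than coefficients")
  fit <- suppressWarnings(glm(formula, data = mf, family = binomial()))
  if (any(is.na(coef(fit)))) {
    stop("rank-deficient design; collinear columns: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  }
  se <- sqrt(diag(vcov(fit)))
  sep <- (max(fit$fitted.values) > 1 - 1e-8 ||
            min(fit$fitted.values) < 1e-8) && max(abs(coef(fit))) > 15
  null_ll <- {
    p0 <- mean(y)
    sum(y * log(p0) + (1 - y) * log(1 - p0))
  }
  structure(
    list(
      predictors = names(coef(fit)), coefficients = unname(coef(fit)),
      se = unname(se), loglik_fit = as.numeric(logLik(fit)),
      loglik_null = null_ll, n = n, converged = fit$converged,
      separation = sep, fitted = unname(fit$fitted.values), outcome = y,
      formula = formula, model_frame = mf
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit: n = %d, logLik = %.3f (null %.3f)\n",
              x$n, x$loglik_fit, x$loglik_null))
  s <- model_summary(x)
  print(round_model_summary(s)$table)
  cat(sprintf("Nagelkerke R2 = %.3f; AUC = %.3f (95%% CI %.3f, %.3f)\n",
              s$nagelkerke_r2, s$auc, s$auc_ci95[1], s$auc_ci95[2]))
  if (x$separation) cat("warning: separation detected; CIs suppressed\n")
  invisible(x)
}

#' Nagelkerke pseudo-R-squared
#'
#' Cox-Snell R2, `1 - exp(2*(loglik_null - loglik_fit)/n)`, rescaled by its
#' maximum attainable value `1 - exp(2*loglik_null/n)` so a saturated model
#' reaches 1.
#'
#' @param fit A [fit_logistic()] result (or any list with `loglik_fit`,
#'   `loglik_null`, `n`).
#' @return Number in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fit) {
  if (fit$n == 0) stop("empty fit")
  r2_cs <- 1 - exp(2 * (fit$loglik_null - fit$loglik_fit) / fit$n)
  r2_max <- 1 - exp(2 * fit$loglik_null / fit$n)
  r2_cs / r2_max
}

#' AUROC with DeLong confidence interval
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic
#' (probability that a random case outscores a random control, ties
#' counted 1/2), with a 95% CI from the DeLong placement variance and a
#' normal approximation, truncated to `[0, 1]`. The AUC is invariant under
#' strictly monotone transformation of the scores.
#'
#' @param scores Numeric predictions (higher = more case-like).
#' @param labels Binary outcomes (1 = case).
#' @return List `auc`, `ci95`, `se`.
#' @export
#' @examples
#' auroc(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  x <- scores[labels == 1]
  y <- scores[labels == 0]
  n1 <- length(x)
  n0 <- length(y)
  if (n1 == 0 || n0 == 0) stop("both outcome classes must be present")
  psi <- function(xi, yj) (xi > yj) + 0.5 * (xi == yj)
  # placements: V10_i = mean_j psi(x_i, y_j); V01_j = mean_i psi(x_i, y_j)
  v10 <- vapply(x, function(xi) mean(psi(xi, y)), 0)
  v01 <- vapply(y, function(yj) mean(psi(x, yj)), 0)
  auc <- mean(v10)
  var_auc <- if (n1 > 1 && n0 > 1) {
    stats::var(v10) / n1 + stats::var(v01) / n0
  } else {
    NA_real_
  }
  se <- sqrt(var_auc)
  ci <- pmin(1, pmax(0, auc + c(-1.96, 1.96) * se))
  list(auc = auc, ci95 = ci, se = se)
}

wald_p <- function(fit) {
  z2 <- (fit$coefficients / fit$se)^2
  setNames(pchisq(z2, 1, lower.tail = FALSE), fit$predictors)
}

#' Backward selection with a change-in-estimate guard
#'
#' Starting from the full model, repeatedly removes the predictor with the
#' highest Wald p-value among those with `p >= p_keep`, unless its removal
#' changes any remaining coefficient by more than `change_tol` (relative)
#' — such confounders are locked in and the next candidate considered.
#' Deterministic; an audit trail of every step is returned.
#'
#' @param data Data frame.
#' @param outcome Name of the binary outcome column.
#' @param predictors Character vector of candidate predictor columns.
#' @param p_keep Retention threshold (default 0.20).
#' @param change_tol Relative coefficient-change threshold above which a
#'   removal counts as a substantive model change (default 0.15, the usual
#'   epidemiologic change-in-estimate heuristic).
#' @return List: `fit` (final [fit_logistic()]), `kept`, `audit` (data
#'   frame of considered removals and their outcomes).
#' @export
backward_select <- function(data, outcome, predictors, p_keep = 0.20,
                            change_tol = 0.15) {
  if (!length(predictors)) stop("empty candidate predictor set")
  current <- predictors
  locked <- character(0)
  audit <- list()
  form <- function(preds) {
    stats::reformulate(if (length(preds)) preds else "1",
                       response = outcome)
  }
  # complete cases on the full variable set, so every candidate model is
  # compared on identical rows
  data <- data[complete.cases(data[, c(outcome, predictors),
                                   drop = FALSE]), , drop = FALSE]
  fit <- fit_logistic(data, form(current))
  repeat {
    p <- wald_p(fit)
    p <- p[setdiff(names(p), "(Intercept)")]
    cand <- names(p)[p >= p_keep & !names(p) %in% locked]
    if (!length(cand)) break
    drop_var <- cand[which.max(p[cand])]
    reduced <- fit_logistic(data, form(setdiff(current, drop_var)))
    # change-in-estimate guard compares predictor coefficients only (the
    # intercept re-centres freely and is not a confounding signal)
    keep_idx <- setdiff(intersect(fit$predictors, reduced$predictors),
                        "(Intercept)")
    old <- fit$coefficients[match(keep_idx, fit$predictors)]
    new <- reduced$coefficients[match(keep_idx, reduced$predictors)]
    rel <- abs(new - old) / pmax(abs(old), 1e-8)
    substantive <- any(rel > change_tol)
    audit[[length(audit) + 1L]] <- data.frame(
      predictor = drop_var, p_value = unname(p[drop_var]),
      max_rel_change = max(rel),
      action = if (substantive) "retained_confounder" else "removed",
      stringsAsFactors = FALSE
    )
    if (substantive) {
      locked <- c(locked, drop_var)
    } else {
      current <- setdiff(current, drop_var)
      fit <- reduced
    }
  }
  list(
    fit = fit, kept = current,
    audit = if (length(audit)) do.call(rbind, audit) else
      data.frame(predictor = character(0), p_value = numeric(0),
                 max_rel_change = numeric(0), action = character(0))
  )
}

#' Increment in Nagelkerke R-squared from added predictors
#'
#' Computes `nagelkerke_r2(model_plus) - nagelkerke_r2(model_base)`. The
#' two fits must rest on identical complete-case rows; differing row sets
#' are an error, forcing the caller to align on common cases first (e.g.
#' subset to rows complete for the larger model).
#'
#' @param fit_base,fit_plus [fit_logistic()] results, nested or not.
#' @return The R2 increment (positive when the additions explain more
#'   variation).
#' @export
delta_r2 <- function(fit_base, fit_plus) {
  if (fit_base$n != fit_plus$n ||
      !isTRUE(all.equal(fit_base$outcome, fit_plus$outcome))) {
    stop("fits rest on different complete-case rows; align on common ",
         "cases before comparing")
  }
  nagelkerke_r2(fit_plus) - nagelkerke_r2(fit_base)
}

#' Multiplicative gene-environment interaction test
#'
#' Fits `outcome ~ snp * env + adjusters` and returns the Wald p-value of
#' the product term (the multiplicative-interaction coefficient).
#'
#' @param data Data frame.
#' @param outcome Binary outcome column name.
#' @param snp Genotype predictor column name (numeric coding, e.g. carrier
#'   indicator or allele count).
#' @param env Non-genetic risk-factor column name.
#' @param adjusters Optional further adjustment columns.
#' @return List: `p_value`, `estimate` (product-term log-OR), `se`,
#'   `estimable` (`FALSE` with `p_value = NA` when an empty cell makes the
#'   product term inestimable).
#' @export
interaction_test <- function(data, outcome, snp, env,
                             adjusters = character(0)) {
  if (length(unique(stats::na.omit(data[[snp]]))) < 2) {
    stop("snp column is constant")
  }
  if (length(unique(stats::na.omit(data[[env]]))) < 2) {
    stop("env column is constant")
  }
  term <- paste0(snp, ":", env)
  rhs <- c(snp, env, adjusters, term)
  formula <- stats::reformulate(rhs, response = outcome)
  mf <- stats::model.frame(formula, data = data,
                           na.action = stats::na.omit)
  mm <- stats::model.matrix(attr(mf, "terms"), mf)
  prod_col <- ncol(mm)
  if (qr(mm)$rank < ncol(mm)) {
    return(list(p_value = NA_real_, estimate = NA_real_, se = NA_real_,
                estimable = FALSE))
  }
  fit <- fit_logistic(data, formula)
  i <- length(fit$coefficients)  # product term enters last
  z2 <- (fit$coefficients[i] / fit$se[i])^2
  list(p_value = pchisq(z2, 1, lower.tail = FALSE),
       estimate = fit$coefficients[i], se = fit$se[i], estimable = TRUE)
}

#' Summarise a logistic fit in the published model-table shape
#'
#' @param fit A [fit_logistic()] result.
#' @return List: `table` (per-predictor aOR, 95% CI, p), `nagelkerke_r2`,
#'   `auc`, `auc_ci95`. CIs are `NA` when separation was flagged.
#' @export
model_summary <- function(fit) {
  p <- wald_p(fit)
  ci_lo <- exp(fit$coefficients - 1.96 * fit$se)
  ci_hi <- exp(fit$coefficients + 1.96 * fit$se)
  if (fit$separation) ci_lo <- ci_hi <- rep(NA_real_, length(ci_lo))
  tab <- data.frame(
    predictor = fit$predictors, aor = exp(fit$coefficients),
    ci_low = ci_lo, ci_high = ci_hi, p_value = unname(p),
    stringsAsFactors = FALSE
  )
  tab <- tab[tab$predictor != "(Intercept)", , drop = FALSE]
  rownames(tab) <- NULL
  roc <- auroc(fit$fitted, fit$outcome)
  list(table = tab, nagelkerke_r2 = nagelkerke_r2(fit), auc = roc$auc,
       auc_ci95 = roc$ci95)
}

#' Round a model summary for report output
#'
#' 2 decimal places for odds ratios and CIs, 3 for p-values and R2/AUC.
#' A `per_k_units` option rescales a continuous predictor's OR to a
#' k-unit contrast (`OR^k`), the usual way per-5-year or per-5-mmol/L
#' effects are reported.
#'
#' @param summary Output of [model_summary()].
#' @param per_k_units Optional named numeric vector, e.g. `c(age = 5)`.
#' @return The summary with a rounded `table`.
#' @export
round_model_summary <- function(summary, per_k_units = NULL) {
  tab <- summary$table
  if (!is.null(per_k_units)) {
    for (v in names(per_k_units)) {
      i <- tab$predictor == v
      k <- per_k_units[[v]]
      tab$aor[i] <- tab$aor[i]^k
      tab$ci_low[i] <- tab$ci_low[i]^k
      tab$ci_high[i] <- tab$ci_high[i]^k
    }
  }
  for (v in c("aor", "ci_low", "ci_high")) tab[[v]] <- round(tab[[v]], 2)
  tab$p_value <- round(tab$p_value, 3)
  summary$table <- tab
  summary$nagelkerke_r2 <- round(summary$nagelkerke_r2, 3)
  summary$auc <- round(summary$auc, 3)
  summary$auc_ci95 <- round(summary$auc_ci95, 3)
  summary
}
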