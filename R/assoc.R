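# Univariable case-control association: crude odds ratios from 2x2
# tables, Wald chi-squared tests, 95% confidence intervals, Bonferroni
# correction, and the cohort-level univariable table.

#' Construct a 2x2 exposure table
#'
#' @param a Exposed cases.
#' @param b Unexposed cases.
#' @param c Exposed controls.
#' @param d Unexposed controls.
#' @return A `two_by_two` object.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = unname(a), b = unname(b), c = unname(c), d = unname(d))
  if (any(cells < 0) || any(!is.finite(cells))) {
    stop("cell counts must be finite and non-negative")
  }
  if (a + b == 0 || c + d == 0) stop("each group needs at least one record")
  structure(as.list(cells), class = "two_by_two")
}

#' Crude odds ratio with Wald test
#'
#' Cross-product odds ratio `(a*d)/(b*c)` with the standard error of the
#' log odds ratio `sqrt(1/a + 1/b + 1/c + 1/d)`, a 95% confidence interval
#' `exp(lnOR +/- 1.96*SE)`, and the Wald chi-squared statistic
#' `(lnOR/SE)^2` on 1 df.
#'
#' @param table A [two_by_two()] (or four counts via `a, b, c, d`).
#' @param alpha_adjusted Optional Bonferroni-adjusted significance
#'   threshold; when given, the result carries a
#'   `significant_after_bonferroni` flag.
#' @param haldane If `TRUE`, apply the Haldane-Anscombe 0.5 correction to
#'   every cell when any cell is zero; by default a zero cell is an error.
#' @return An `assoc_result` object: `or_hat`, `ln_or`, `se_ln_or`,
#'   `wald_chi2`, `df`, `p_value`, `ci95`, and the Bonferroni flag.
#' @export
#' @examples
#' crude_or(two_by_two(102, 228, 70, 260))  # tobacco use: OR 1.66
crude_or <- function(table, alpha_adjusted = NULL, haldane = FALSE) {
  stopifnot(inherits(table, "two_by_two"))
  cells <- unlist(table[c("a", "b", "c", "d")])
  if (any(cells == 0)) {
    if (!haldane) {
      stop("zero cell in 2x2 table; set haldane = TRUE to apply the 0.5 ",
           "correction")
    }
    cells <- cells + 0.5
  }
  ln_or <- log(cells["a"] * cells["d"] / (cells["b"] * cells["c"]))
  se <- sqrt(sum(1 / cells))
  chi2 <- (ln_or / se)^2
  res <- list(
    or_hat = unname(exp(ln_or)), ln_or = unname(ln_or),
    se_ln_or = unname(se), wald_chi2 = unname(chi2), df = 1L,
    p_value = unname(pchisq(chi2, df = 1, lower.tail = FALSE)),
    ci95 = unname(exp(ln_or + c(-1.96, 1.96) * se)),
    significant_after_bonferroni = if (is.null(alpha_adjusted)) NA else
      unname(pchisq(chi2, 1, lower.tail = FALSE) < alpha_adjusted)
  )
  structure(res, class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f, %.2f), Wald chi2 %.2f (%d df), p %s\n",
              x$or_hat, x$ci95[1], x$ci95[2], x$wald_chi2, x$df,
              format.pval(x$p_value, digits = 3, eps = 1e-3)))
  invisible(x)
}

#' Per-genotype odds ratios against a reference genotype
#'
#' Each non-reference genotype category is compared to the reference in
#' its own 2x2 table via [crude_or()] (the published per-SNP layout, e.g.
#' "CT vs. C").
#'
#' @param case_counts,control_counts Named count vectors over genotype
#'   categories (identical names).
#' @param reference Name of the reference category (default: first).
#' @param ... Passed to [crude_or()].
#' @return Named list of `assoc_result`, one per non-reference category.
#' @export
#' @examples
#' genotype_or(c(C = 290, CT = 40, TT = 8), c(C = 320, CT = 16, TT = 3))
genotype_or <- function(case_counts, control_counts,
                        reference = names(case_counts)[1], ...) {
  stopifnot(identical(names(case_counts), names(control_counts)),
            length(case_counts) >= 2L, reference %in% names(case_counts))
  if (case_counts[reference] == 0 || control_counts[reference] == 0) {
    stop("reference category must be populated in both groups")
  }
  cats <- setdiff(names(case_counts), reference)
  out <- lapply(cats, function(g) {
    crude_or(two_by_two(case_counts[g], case_counts[reference],
                        control_counts[g], control_counts[reference]), ...)
  })
  setNames(out, cats)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests.
#' @return `alpha / m` (e.g. 0.05/27 = 0.00185, reported as 0.002).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (m < 1) stop("m must be at least 1")
  alpha / m
}

#' Univariable association table for a cohort
#'
#' For each requested variable, computes the crude association between
#' HLDL/LLDL group and the variable on that variable's complete cases
#' (denominators therefore vary by variable, matching a design with
#' per-item missingness). Binary tristate covariates use [crude_or()] on
#' the yes/no 2x2; continuous covariates use a single-predictor logistic
#' fit reporting the per-unit OR with its Wald test.
#'
#' @param cohort Cohort data frame with a `group` column.
#' @param variables Character vector of cohort columns; default is every
#'   schema covariate.
#' @param alpha_adjusted Optional adjusted threshold passed through.
#' @return Data frame: variable, kind, denominators, OR, CI, Wald
#'   chi-squared, df, p.
#' @export
univariable_table <- function(cohort,
                              variables = c(cohort_continuous_covariates(),
                                            "sex_male",
                                            cohort_binary_covariates()),
                              alpha_adjusted = NULL) {
  stopifnot("group" %in% names(cohort),
            all(cohort$group %in% c("HLDL", "LLDL")))
  case <- cohort$group == "HLDL"
  rows <- lapply(variables, function(v) {
    col <- if (v == "sex_male") {
      ifelse(is.na(cohort$sex), NA,
             ifelse(cohort$sex == "male", "yes", "no"))
    } else if (v %in% names(cohort)) {
      cohort[[v]]
    } else {
      stop("variable absent from cohort: ", v)
    }
    ok <- !is.na(col)
    if (!any(ok)) stop("variable has no non-missing values: ", v)
    n1 <- sum(ok & case)
    n0 <- sum(ok & !case)
    if (is.numeric(col)) {
      fit <- fit_logistic(
        data.frame(y = as.integer(case[ok]), x = col[ok]), y ~ x)
      i <- match("x", fit$predictors)
      chi2 <- (fit$coefficients[i] / fit$se[i])^2
      res <- list(or_hat = exp(fit$coefficients[i]),
                  ci95 = exp(fit$coefficients[i] +
                               c(-1.96, 1.96) * fit$se[i]),
                  wald_chi2 = chi2,
                  p_value = pchisq(chi2, 1, lower.tail = FALSE))
      kind <- "continuous"
    } else {
      res <- crude_or(two_by_two(sum(ok & case & col == "yes"),
                                 sum(ok & case & col == "no"),
                                 sum(ok & !case & col == "yes"),
                                 sum(ok & !case & col == "no")),
                      alpha_adjusted = alpha_adjusted)
      kind <- "binary"
    }
    data.frame(variable = v, kind = kind, n_hldl = n1, n_lldl = n0,
               or = res$or_hat, ci_low = res$ci95[1], ci_high = res$ci95[2],
               wald_chi2 = res$wald_chi2, df = 1L, p_value = res$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Round an association table for report output
#'
#' Report convention: 2 decimal places for odds ratios, confidence limits
#' and chi-squared statistics; 3 for p-values. Full precision is retained
#' in the unrounded table.
#'
#' @param tab Output of [univariable_table()].
#' @return The table with rounded display columns.
#' @export
round_association_table <- function(tab) {
  for (v in c("or", "ci_low", "ci_high", "wald_chi2")) {
    tab[[v]] <- round(tab[[v]], 2)
  }
  tab$p_value <- round(tab$p_value, 3)
  tab
}
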