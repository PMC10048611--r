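test_that("logistic fits maximise the likelihood and match closed forms", {
  # intercept-only: logit of the case fraction
  d <- data.frame(y = rep(c(1L, 0L), c(338, 339)))
  fit <- fit_logistic(d, y ~ 1)
  expect_equal(fit$coefficients, qlogis(338 / 677), tolerance = 1e-8)

  # single binary predictor on the tobacco 2x2: exp(coef) = crude OR
  d2 <- data.frame(
    y = rep(c(1L, 1L, 0L, 0L), c(102, 228, 70, 260)),
    x = rep(c(1L, 0L, 1L, 0L), c(102, 228, 70, 260))
  )
  fit2 <- fit_logistic(d2, y ~ x)
  expect_equal(exp(fit2$coefficients[2]),
               crude_or(two_by_two(102, 228, 70, 260))$or_hat,
               tolerance = 1e-9)

  # 20-row dataset vs coarse grid-search ML
  withr::with_seed(3, {
    x <- rnorm(20)
    y <- rbinom(20, 1, plogis(0.3 + 0.8 * x))
  })
  fit3 <- fit_logistic(data.frame(y = y, x = x), y ~ x)
  bf <- bf_logistic_grid(y, x)
  expect_equal(unname(fit3$coefficients), unname(bf), tolerance = 1e-4)

  # likelihood monotonicity: adding a predictor never lowers logLik
  withr::with_seed(5, {
    d4 <- data.frame(y = rbinom(120, 1, 0.4), a = rnorm(120),
                     b = rnorm(120))
  })
  expect_gte(fit_logistic(d4, y ~ a + b)$loglik_fit,
             fit_logistic(d4, y ~ a)$loglik_fit - 1e-10)

  # rank deficiency names the collinear column
  d5 <- data.frame(y = rbinom(50, 1, 0.5), a = rnorm(50))
  d5$b <- d5$a
  expect_error(fit_logistic(d5, y ~ a + b), "collinear.*b")

  # separation is flagged and CIs suppressed
  d6 <- data.frame(y = rep(c(1L, 0L), each = 20),
                   x = rep(c(1L, 0L), each = 20))
  fit6 <- fit_logistic(d6, y ~ x)
  expect_true(fit6$separation)
  expect_true(all(is.na(model_summary(fit6)$table$ci_low)))
})

test_that("logistic OR equals the cross-product OR on random 2x2 tables", {
  withr::with_seed(10, {
    for (i in 1:100) {
      cells <- sample(3:150, 4)
      d <- data.frame(
        y = rep(c(1L, 1L, 0L, 0L), cells),
        x = rep(c(1L, 0L, 1L, 0L), cells)
      )
      fit <- fit_logistic(d, y ~ x)
      bf <- (cells[1] * cells[4]) / (cells[2] * cells[3])
      expect_equal(exp(fit$coefficients[2]), bf, tolerance = 1e-6)
    }
  })
})

test_that("Nagelkerke R2 spans [0, 1] and matches hand arithmetic", {
  d <- data.frame(y = rep(c(1L, 0L), c(30, 50)))
  null_fit <- fit_logistic(d, y ~ 1)
  expect_equal(nagelkerke_r2(null_fit), 0, tolerance = 1e-12)

  # hand-computed small example
  d2 <- data.frame(y = c(1, 1, 1, 0, 0, 0, 1, 0),
                   x = c(2.0, 1.5, 1.0, -1.0, -0.5, 0.0, 0.5, 0.2))
  fit2 <- fit_logistic(d2, y ~ x)
  n <- 8
  r2_cs <- 1 - exp(2 * (fit2$loglik_null - fit2$loglik_fit) / n)
  r2_expected <- r2_cs / (1 - exp(2 * fit2$loglik_null / n))
  expect_equal(nagelkerke_r2(fit2), r2_expected, tolerance = 1e-12)

  # perfectly separating predictor drives the normalised R2 to 1
  d3 <- data.frame(y = rep(c(1L, 0L), each = 15),
                   x = rep(c(5, -5), each = 15))
  fit3 <- fit_logistic(d3, y ~ x)
  expect_gt(nagelkerke_r2(fit3), 0.99)
})

test_that("AUROC equals brute-force pair counting and honours ties", {
  expect_equal(auroc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(auroc(rep(1, 10), rep(c(1, 0), 5))$auc, 0.5)
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both outcome classes")

  withr::with_seed(14, {
    for (i in 1:30) {
      n <- sample(6:50, 1)
      labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
      scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # forces ties
      expect_equal(auroc(scores, labels)$auc, bf_auc(scores, labels))
      # invariance under strictly monotone transformation
      expect_equal(auroc(exp(3 * scores), labels)$auc,
                   auroc(scores, labels)$auc)
    }
  })
})

test_that("AUROC DeLong interval agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  withr::with_seed(15, {
    labels <- rbinom(120, 1, 0.45)
    labels[1:2] <- c(0, 1)
    scores <- rnorm(120) + labels
  })
  ours <- auroc(scores, labels)
  ref <- pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE),
                      method = "delong")
  expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(ours$ci95[1], as.numeric(ref[1]), tolerance = 1e-3)
  expect_equal(ours$ci95[2], as.numeric(ref[3]), tolerance = 1e-3)
})

test_that("backward selection drops noise and guards confounders", {
  # all predictors strongly associated: model unchanged
  withr::with_seed(16, {
    n <- 500
    a <- rnorm(n); b <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.2 + 0.9 * a - 0.9 * b))
  })
  sel <- backward_select(data.frame(y = y, a = a, b = b), "y", c("a", "b"))
  expect_setequal(sel$kept, c("a", "b"))

  # pure-noise predictor: under the null its Wald p is uniform, so with
  # p_keep = 0.20 the removal rate converges to P(p >= 0.20) = 0.80;
  # assert that rate within binomial error over 200 seeds (n = 600)
  removed <- vapply(1:200, function(s) {
    withr::with_seed(s, {
      n <- 600
      a <- rnorm(n)
      noise <- rnorm(n)
      y <- rbinom(n, 1, plogis(0.8 * a))
    })
    sel <- backward_select(data.frame(y = y, a = a, noise = noise), "y",
                           c("a", "noise"))
    !"noise" %in% sel$kept
  }, logical(1))
  expect_lt(abs(mean(removed) - 0.80), 0.09)

  # constructed confounder: weak own p-value but its removal shifts the
  # exposure coefficient by > 30%, so it must be retained
  withr::with_seed(9, {
    n <- 250
    conf <- rbinom(n, 1, 0.5)
    x <- rbinom(n, 1, 0.1 + 0.8 * conf)
    y <- rbinom(n, 1, plogis(-1 + 1.2 * x - 0.7 * conf))
  })
  d <- data.frame(y = y, x = x, conf = conf)
  fit_full <- fit_logistic(d, y ~ x + conf)
  p_conf <- pchisq((fit_full$coefficients[3] / fit_full$se[3])^2, 1,
                   lower.tail = FALSE)
  expect_gte(p_conf, 0.20)  # fixture precondition: weak marginal evidence
  sel2 <- backward_select(d, "y", c("x", "conf"))
  expect_true("conf" %in% sel2$kept)
  expect_true("retained_confounder" %in% sel2$audit$action)

  expect_error(backward_select(d, "y", character(0)), "empty candidate")
})

test_that("R2 increments require aligned rows and detect signal vs noise", {
  withr::with_seed(18, {
    n <- 400
    x <- rnorm(n)
    g <- rbinom(n, 1, 0.1)
    y <- rbinom(n, 1, plogis(0.5 * x + 2 * g))
    d <- data.frame(y = y, x = x, g = g, noise = rnorm(n))
  })
  base <- fit_logistic(d, y ~ x)
  plus <- fit_logistic(d, y ~ x + g)
  expect_equal(delta_r2(base, base), 0)
  expect_gt(delta_r2(base, plus), 0)
  expect_lt(abs(delta_r2(base, fit_logistic(d, y ~ x + noise))), 0.02)

  # differing complete-case rows are an error
  d2 <- d
  d2$g[1:10] <- NA
  expect_error(delta_r2(base, fit_logistic(d2, y ~ x + g)),
               "complete-case")
})

test_that("interaction test recovers a strong product effect", {
  # power > 0.8 at n = 677 for a strong multiplicative interaction
  rej <- vapply(1:100, function(s) {
    withr::with_seed(7000 + s, {
      n <- 677
      snp <- rbinom(n, 2, 0.3)
      env <- rbinom(n, 1, 0.4)
      y <- rbinom(n, 1, plogis(-1 + 0.2 * snp + 0.2 * env +
                                 log(2.2) * snp * env))
    })
    d <- data.frame(y = y, snp = snp, env = env)
    interaction_test(d, "y", "snp", "env")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.8)

  d <- data.frame(y = rbinom(50, 1, 0.5), snp = rep(1, 50),
                  env = rbinom(50, 1, 0.5))
  expect_error(interaction_test(d, "y", "snp", "env"), "constant")

  # empty exposure cell: product term flagged inestimable
  d2 <- data.frame(y = rbinom(60, 1, 0.5),
                   snp = rep(c(0, 1, 0), 20),
                   env = rep(c(0, 0, 1), 20))
  d2$both <- d2$snp * d2$env  # never 1 together
  res <- interaction_test(d2, "y", "snp", "env")
  expect_false(res$estimable)
  expect_true(is.na(res$p_value))
})
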