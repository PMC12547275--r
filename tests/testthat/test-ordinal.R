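test_that("the cumulative-logit mixed model recovers known effects", {
  rec <- gen_ordinal_records(2000, seed = 4, n_poss = 30, n_event = 500)
  fit <- suppressMessages(fit_ordinal(rec, se = FALSE, rel_tol = 1e-7))
  expect_true(fit$converged)
  truth <- c(-1, 1, -1.2, -2.3, 0, 0, 0)
  est <- c(fit$theta, fit$beta)
  expect_true(all(abs(est - truth) < 0.45))
  # fixed effects within the recovery band
  expect_lt(abs(fit$beta[["social_leveldiff_unit_same_party"]] + 1.2), 0.45)
  expect_lt(abs(fit$beta[["social_leveldiff_unit_diff_party"]] + 2.3), 0.45)
  # monotone tolerance: P(share) decreases unit -> party -> gang
  lv <- c("same_unit_same_party", "diff_unit_same_party", "diff_unit_diff_party")
  nd <- tibble::tibble(
    social_level = factor(lv, levels = lv),
    possessor_sex = 0, recipient_sex = 0
  )
  pshare <- predict(fit, nd)[, 3]
  expect_true(all(diff(pshare) < 0))
})

test_that("zero-variance truth matches a fixed-effects-only fit", {
  rec <- gen_ordinal_records(800, seed = 8, sd_u = 0)
  fit <- suppressMessages(fit_ordinal(rec, se = FALSE))
  pol <- MASS::polr(
    factor(transfer_type, ordered = TRUE) ~
      social_level + possessor_sex * recipient_sex,
    data = rec, Hess = FALSE
  )
  # truth-zero variances: estimates stay near the boundary (sampling
  # noise at ~160 grouping levels leaves a little spread)
  expect_true(all(abs(fit$sigma) < 0.45))
  expect_true(all(abs(fit$beta - pol$coefficients[names(fit$beta)]) < 0.1))
  expect_true(all(abs(fit$theta - pol$zeta) < 0.1))
})

test_that("single-category responses are rejected", {
  rec <- gen_ordinal_records(50, seed = 2)
  rec$transfer_type <- 2L
  expect_error(fit_ordinal(rec), "single category")
})

test_that("Wald summaries carry finite observed-information standard errors", {
  rec <- gen_ordinal_records(400, seed = 6)
  fit <- suppressMessages(fit_ordinal(rec))
  td <- tidy(fit)
  fx <- td[td$type %in% c("threshold", "fixed"), ]
  expect_true(all(is.finite(fx$std_error) & fx$std_error > 0))
  expect_equal(fx$statistic, fx$estimate / fx$std_error)
  expect_true(all(fx$p_value >= 0 & fx$p_value <= 1))
  g <- glance(fit)
  expect_equal(g$n, 400)
  expect_equal(g$n_fixed, 5)
})

test_that("the Laplace marginal likelihood matches numerical integration on small-variance toys", {
  set.seed(33)
  n <- 9
  grp <- rep(c("a", "b", "c"), each = 3)
  x <- stats::rnorm(n)
  y <- sample(1:3, n, replace = TRUE)
  y[1:3] <- 1:3 # all categories present
  X <- matrix(x, ncol = 1)
  re1 <- meatshare:::make_ranef(list(g = grp), n)
  exact_1f <- function(theta, beta, sigma) {
    s <- 0
    for (g in unique(grp)) {
      i <- grp == g
      f <- function(uu) {
        vapply(uu, function(u1) {
          exp(sum(meatshare:::cumlogit_ll(y[i], x[i] * beta + u1, theta)$ll)) *
            stats::dnorm(u1, 0, sigma)
        }, 0)
      }
      s <- s + log(stats::integrate(f, -8 * sigma, 8 * sigma, rel.tol = 1e-11)$value)
    }
    s
  }
  for (sigma in c(0.05, 0.1, 0.2)) {
    for (beta in c(-0.5, 0.4)) {
      lap <- meatshare:::laplace_ll(y, X, re1, c(-0.8, 0.9), beta, sigma)$ll
      expect_equal(lap, exact_1f(c(-0.8, 0.9), beta, sigma), tolerance = 1e-3)
    }
  }

  # crossed toy: two factors with one level each -> 2-d integral
  re2 <- meatshare:::make_ranef(list(f1 = rep("u", n), f2 = rep("v", n)), n)
  exact_2f <- function(theta, beta, s1, s2) {
    outerf <- function(u1v) {
      vapply(u1v, function(u1) {
        inner <- stats::integrate(function(u2v) {
          vapply(u2v, function(u2) {
            exp(sum(meatshare:::cumlogit_ll(y, x * beta + u1 + u2, theta)$ll)) *
              stats::dnorm(u2, 0, s2)
          }, 0)
        }, -8 * s2, 8 * s2, rel.tol = 1e-9)$value
        inner * stats::dnorm(u1, 0, s1)
      }, 0)
    }
    log(stats::integrate(outerf, -8 * s1, 8 * s1, rel.tol = 1e-8)$value)
  }
  lap2 <- meatshare:::laplace_ll(y, X, re2, c(-0.8, 0.9), 0.4, c(0.15, 0.1))$ll
  expect_equal(lap2, exact_2f(c(-0.8, 0.9), 0.4, 0.15, 0.1), tolerance = 1e-3)
})

test_that("full-null and full-reduced tests have the right structure", {
  rec <- gen_ordinal_records(150, seed = 10)
  full <- suppressMessages(fit_ordinal(rec, se = FALSE, rel_tol = 1e-6))
  null <- suppressMessages(fit_ordinal(rec, fixed = ~1, se = FALSE, rel_tol = 1e-6))
  red <- suppressMessages(fit_reduced(rec, se = FALSE, rel_tol = 1e-6))
  lrt <- lrt_full_null(full, null)
  expect_equal(lrt$df, 5)
  expect_gte(lrt$chi2, 0)
  expect_equal(lrt_full_null(full, red)$df, 1)
  # identical models: chi2 = 0, df = 0
  self <- lrt_full_null(full, full)
  expect_equal(self$chi2, 0)
  expect_equal(self$df, 0)
  # non-nested models error
  only_poss <- suppressMessages(
    fit_ordinal(rec, fixed = ~possessor_sex, se = FALSE, rel_tol = 1e-6)
  )
  only_rec <- suppressMessages(
    fit_ordinal(rec, fixed = ~recipient_sex, se = FALSE, rel_tol = 1e-6)
  )
  expect_error(lrt_full_null(only_poss, only_rec), "not nested")
})

test_that("dichotomized logistic fits agree with the ordinal fit under proportional odds", {
  rec <- gen_ordinal_records(2000, seed = 14, sd_u = 0.4, n_poss = 25, n_event = 400)
  po <- suppressMessages(proportional_odds_check(rec, rel_tol = 1e-6))
  lvl_terms <- grep("social_level", po$comparison$term)
  expect_true(all(sign(po$comparison$cut_steal[lvl_terms]) ==
    sign(po$comparison$ordinal[lvl_terms])))
  expect_true(all(sign(po$comparison$cut_share[lvl_terms]) ==
    sign(po$comparison$ordinal[lvl_terms])))
  expect_lt(po$max_abs_discrepancy, 0.5)

  # a category-specific (non-proportional) effect inflates the discrepancy
  set.seed(15)
  n <- 1500
  x <- stats::rbinom(n, 1, 0.5)
  p1 <- stats::plogis(-1.5 - 2.0 * x) # strong effect at the lower cut
  p2 <- stats::plogis(1.5 - 0.1 * x) # almost none at the upper cut
  u <- stats::runif(n)
  recv <- gen_ordinal_records(n, seed = 15, sd_u = 0.2)
  recv$possessor_sex <- x
  recv$transfer_type <- ifelse(u < p1, 1L, ifelse(u < p2, 2L, 3L))
  pov <- suppressMessages(
    proportional_odds_check(recv, fixed = ~possessor_sex, rel_tol = 1e-6)
  )
  expect_gt(pov$max_abs_discrepancy, po$max_abs_discrepancy)

  # dichotomization bookkeeping: the two cuts reproduce the category counts
  y <- rec$transfer_type
  expect_equal(sum(y > 1), sum(y %in% c(2, 3)))
  expect_equal(sum(y > 2), sum(y == 3))
})

test_that("leave-one-level-out refits are stable on balanced data", {
  rec <- gen_ordinal_records(300, seed = 16, sd_u = 0.3,
    n_poss = 6, partners_per = 3, n_event = 12
  )
  st <- suppressMessages(
    stability_check(rec, random = c("possessor_id", "event_id"), rel_tol = 1e-6)
  )
  expect_true(all(st$range < 1.0))
  expect_equal(st$estimate[st$term == "threshold_1"],
    suppressMessages(
      fit_ordinal(rec, random = c("possessor_id", "event_id"), se = FALSE)
    )$theta[[1]],
    tolerance = 1e-3
  )
})

test_that("the parametric bootstrap brackets truth-zero effects", {
  rec <- gen_ordinal_records(200, seed = 18, sd_u = 0.3, betas = c(-1.2, -2.3, 0, 0, 0),
    n_poss = 10, n_event = 30
  )
  fit <- suppressMessages(fit_ordinal(rec, se = FALSE, rel_tol = 1e-6))
  empty <- parametric_bootstrap(fit, rec, n_boot = 0)
  expect_equal(nrow(empty), 0)
  ci <- suppressMessages(parametric_bootstrap(fit, rec, n_boot = 30, seed = 3L))
  expect_gte(attr(ci, "n_boot_used"), 22)
  # truth-zero possessor_sex effect: 95% interval contains 0
  row <- ci[ci$term == "possessor_sex", ]
  expect_true(row$lower < 0 && row$upper > 0)
  # bootstrap is seed-deterministic
  ci2 <- suppressMessages(parametric_bootstrap(fit, rec, n_boot = 30, seed = 3L))
  expect_identical(ci, ci2)
})
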