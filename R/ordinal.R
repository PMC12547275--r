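# Transfer-type tolerance: cumulative-logit (proportional-odds) mixed
# model with crossed random intercepts for possessor, recipient, dyad and
# event identity, fitted by maximizing a Laplace-approximated marginal
# likelihood. Crossed grouping factors rule out quadrature, and the
# full-null likelihood-ratio test needs maximized likelihoods, hence the
# frequentist Laplace route.
#
# Latent scale: P(Y <= k) = logit^-1(theta_k - eta),
# eta = X beta + Z u,  u_r ~ Normal(0, sigma_r^2) stacked over factors.
# With steal as the lowest category, positive effects mean "more tolerant".

# log P(y | eta) for the cumulative logit plus its first two derivatives
# in eta. theta is the full cutpoint vector (K-1 increasing values).
cumlogit_ll <- function(y, eta, theta) {
  K <- length(theta) + 1L
  up <- ifelse(y < K, theta[pmin(y, K - 1L)] - eta, Inf)
  lo <- ifelse(y > 1L, theta[pmax(y - 1L, 1L)] - eta, -Inf)
  Fa <- stats::plogis(up)
  Fb <- stats::plogis(lo)
  fa <- ifelse(is.finite(up), Fa * (1 - Fa), 0)
  fb <- ifelse(is.finite(lo), Fb * (1 - Fb), 0)
  D <- pmax(Fa - Fb, 1e-300)
  dN <- fa * (1 - 2 * Fa) - fb * (1 - 2 * Fb) # d(fa - fb)/d(up-scale)
  list(
    ll = log(D),
    d1 = -(fa - fb) / D,
    d2 = dN / D - ((fa - fb) / D)^2
  )
}

# category probabilities at a vector of linear predictors
cumlogit_probs <- function(eta, theta) {
  cum <- stats::plogis(outer(theta, eta, function(t, e) t - e))
  rbind(cum[1, , drop = FALSE], diff(rbind(cum, 1)))
}

# Build sparse random-effect structures from a named list of factors.
make_ranef <- function(flist, n) {
  flist <- lapply(flist, function(f) factor(f))
  q_r <- vapply(flist, nlevels, 0L)
  offs <- c(0L, cumsum(q_r))
  q <- sum(q_r)
  if (q == 0) {
    return(list(Z = NULL, q = 0L, q_r = q_r, offs = offs, flist = flist))
  }
  j <- unlist(lapply(seq_along(flist), function(r) {
    offs[r] + as.integer(flist[[r]])
  }))
  Z <- Matrix::sparseMatrix(
    i = rep(seq_len(n), times = length(flist)),
    j = j, x = 1, dims = c(n, q)
  )
  list(Z = Z, q = q, q_r = q_r, offs = offs, flist = flist)
}

# Laplace-approximated marginal log-likelihood for fixed parameter values.
# Inner Newton maximization over the stacked random-effect vector with
# sparse curvature. Returns the ll and the inner mode (reused as a warm
# start across outer iterations).
laplace_ll <- function(y, X, re, theta, beta, sigma, u0 = NULL) {
  n <- length(y)
  xb <- if (ncol(X)) drop(X %*% beta) else rep(0, n)
  if (re$q == 0) {
    return(list(ll = sum(cumlogit_ll(y, xb, theta)$ll), u = numeric(0)))
  }
  prec <- rep(1 / pmax(sigma, 1e-8)^2, times = re$q_r)
  u <- u0 %||% numeric(re$q)
  Zt <- Matrix::t(re$Z)
  h_of <- function(u) {
    eta <- xb + drop(re$Z %*% u)
    sum(cumlogit_ll(y, eta, theta)$ll) -
      0.5 * sum(prec * u^2) - 0.5 * sum(log(2 * pi / prec))
  }
  h <- h_of(u)
  for (it in 1:50) {
    eta <- xb + drop(re$Z %*% u)
    d <- cumlogit_ll(y, eta, theta)
    grad <- drop(Zt %*% d$d1) - prec * u
    W <- Matrix::Diagonal(x = pmax(-d$d2, 1e-10))
    Hn <- Matrix::forceSymmetric(Zt %*% W %*% re$Z + Matrix::Diagonal(x = prec))
    step <- as.numeric(Matrix::solve(Hn, grad))
    # backtracking line search on the joint objective
    t <- 1
    repeat {
      u_new <- u + t * step
      h_new <- h_of(u_new)
      if (is.finite(h_new) && h_new >= h - 1e-12) break
      t <- t / 2
      if (t < 1e-8) {
        u_new <- u
        h_new <- h
        break
      }
    }
    conv <- abs(h_new - h) < 1e-9 * (1 + abs(h))
    u <- u_new
    h <- h_new
    if (conv) break
  }
  eta <- xb + drop(re$Z %*% u)
  d <- cumlogit_ll(y, eta, theta)
  W <- Matrix::Diagonal(x = pmax(-d$d2, 1e-10))
  Hn <- Matrix::forceSymmetric(Zt %*% W %*% re$Z + Matrix::Diagonal(x = prec))
  logdet <- as.numeric(Matrix::determinant(Hn, logarithm = TRUE)$modulus)
  list(ll = h + 0.5 * re$q * log(2 * pi) - 0.5 * logdet, u = u)
}

# parameter vector <-> (theta, beta, log sigma) mapping; thresholds are
# kept increasing via (theta1, log diff) coding
par_pack <- function(theta, beta, sigma) {
  c(theta[1], log(diff(theta)), beta, log(pmax(sigma, 1e-8)))
}
par_unpack <- function(par, n_theta, n_beta, n_sigma) {
  theta <- cumsum(c(par[1], exp(par[seq_len(n_theta - 1) + 1])))
  beta <- par[n_theta + seq_len(n_beta)]
  sigma <- exp(par[n_theta + n_beta + seq_len(n_sigma)])
  list(theta = theta, beta = beta, sigma = sigma)
}

#' Cumulative-logit mixed model for transfer-type tolerance
#'
#' Ordinal regression of transfer type (steal < scavenge/succeed <
#' share) on the shared social level of possessor and recipient, their
#' sexes, and the sex interaction, with crossed random intercepts for
#' possessor, recipient, dyad and event identity. The latent-scale model
#' is `P(Y <= k) = logit^-1(theta_k - eta)` with
#' `eta = X beta + sum_r u_r`; the marginal likelihood integrates the
#' stacked random effects out by Laplace approximation and is maximized
#' by quasi-Newton optimization. Positive effects mean more tolerant
#' transfers.
#'
#' @param records Tibble with `transfer_type` (integer 1-3 or ordered
#'   factor, steal lowest), the fixed-effect columns used in `fixed`,
#'   and the grouping columns named in `random`.
#' @param fixed One-sided formula for the fixed effects (default the
#'   full model `~ social_level + possessor_sex * recipient_sex`; the
#'   intercept is absorbed by the thresholds).
#' @param random Character vector of grouping columns (default
#'   possessor, recipient, dyad and event identity). `character(0)`
#'   fits a fixed-effects-only cumulative logit.
#' @param se Compute standard errors from the observed information
#'   (numerical Hessian of the marginal log-likelihood); skip for speed
#'   in resampling loops.
#' @param start Optional named list with `theta`, `beta`, `sigma` warm
#'   starts.
#' @param rel_tol Relative convergence tolerance of the outer
#'   quasi-Newton optimization (default 1e-8; loosen in large
#'   resampling loops where third-decimal accuracy suffices).
#' @return Object of class `ordinal_fit`: `theta` (thresholds), `beta`,
#'   `se` (incl. thresholds), `sigma` (random-intercept s.d. per factor,
#'   clamped at 0 when the optimizer hits the boundary), `loglik`,
#'   `converged`, plus the design kept for downstream refits.
#' @export
fit_ordinal <- function(records,
                        fixed = ~ social_level + possessor_sex * recipient_sex,
                        random = c("possessor_id", "recipient_id", "dyad_id", "event_id"),
                        se = TRUE,
                        start = NULL,
                        rel_tol = 1e-8) {
  y <- records$transfer_type
  if (is.ordered(y) || is.factor(y)) y <- as.integer(y)
  y <- as.integer(y)
  K <- max(y)
  if (length(unique(y)) < 2) {
    stop("response has a single category; nothing to fit", call. = FALSE)
  }
  mf <- stats::model.frame(fixed, data = records)
  X <- stats::model.matrix(fixed, mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  re <- make_ranef(records[random], length(y))
  n_theta <- K - 1L
  n_beta <- ncol(X)
  n_sigma <- length(random)

  # starts: thresholds from marginal cumulative frequencies, beta at 0
  if (is.null(start)) {
    cumfreq <- cumsum(tabulate(y, K) / length(y))[seq_len(n_theta)]
    start <- list(
      theta = logit(pmin(pmax(cumfreq, 0.02), 0.98)),
      beta = rep(0, n_beta), sigma = rep(0.5, n_sigma)
    )
  }
  u_warm <- new.env(parent = emptyenv())
  u_warm$u <- NULL
  negll <- function(par) {
    p <- par_unpack(par, n_theta, n_beta, n_sigma)
    fit <- laplace_ll(y, X, re, p$theta, p$beta, p$sigma, u0 = u_warm$u)
    u_warm$u <- fit$u
    -fit$ll
  }
  par0 <- par_pack(start$theta, start$beta, start$sigma)
  lower <- c(rep(-Inf, n_theta + n_beta), rep(-6, n_sigma))
  upper <- c(rep(Inf, n_theta + n_beta), rep(3, n_sigma))
  opt <- stats::nlminb(par0, negll,
    lower = lower, upper = upper,
    control = list(rel.tol = rel_tol, iter.max = 300)
  )
  p <- par_unpack(opt$par, n_theta, n_beta, n_sigma)
  at_bound <- p$sigma < 0.005
  sigma <- ifelse(at_bound, 0, p$sigma)
  if (any(at_bound)) {
    message(
      "random-intercept variance at boundary, clamped to 0: ",
      paste(random[at_bound], collapse = ", ")
    )
  }
  ses <- rep(NA_real_, n_theta + n_beta)
  if (se && (n_theta + n_beta) > 0) {
    ses <- tryCatch(
      {
        H <- num_hessian(negll, opt$par, idx = seq_len(n_theta + n_beta))
        sqrt(diag(solve(H)))
      },
      error = function(e) rep(NA_real_, n_theta + n_beta)
    )
    # delta method for theta2 = theta1 + exp(par2) is skipped: report the
    # raw-threshold SEs by refitting the Hessian in (theta1, theta2) space
    if (n_theta == 2 && all(is.finite(ses))) {
      negll_theta <- function(q) {
        negll(c(q[1], log(max(q[2] - q[1], 1e-8)), opt$par[-(1:2)]))
      }
      H2 <- tryCatch(
        num_hessian(
          function(v) negll_theta(v),
          c(p$theta[1], p$theta[2]), idx = 1:2
        ),
        error = function(e) NULL
      )
      if (!is.null(H2)) {
        s2 <- tryCatch(sqrt(diag(solve(H2))), error = function(e) c(NA, NA))
        ses[1:2] <- s2
      }
    }
  }
  beta_names <- colnames(X)
  theta_names <- paste0("threshold_", seq_len(n_theta))
  structure(
    list(
      theta = stats::setNames(p$theta, theta_names),
      beta = stats::setNames(p$beta, beta_names),
      se = stats::setNames(ses, c(theta_names, beta_names)),
      sigma = stats::setNames(sigma, random),
      loglik = -opt$objective,
      converged = opt$convergence == 0,
      n = length(y),
      n_categories = K,
      fixed = fixed,
      random = random,
      y = y, X = X, re = re,
      opt = opt
    ),
    class = "ordinal_fit"
  )
}

# central-difference Hessian of f over par[idx], other coords fixed
num_hessian <- function(f, par, idx = seq_along(par), h_rel = 1e-4) {
  m <- length(idx)
  h <- h_rel * (1 + abs(par[idx]))
  H <- matrix(NA_real_, m, m)
  f0 <- f(par)
  for (i in seq_len(m)) {
    for (j in i:m) {
      pp <- par
      if (i == j) {
        pp[idx[i]] <- par[idx[i]] + h[i]
        fp <- f(pp)
        pp[idx[i]] <- par[idx[i]] - h[i]
        fm <- f(pp)
        H[i, i] <- (fp - 2 * f0 + fm) / h[i]^2
      } else {
        val <- 0
        for (si in c(1, -1)) {
          for (sj in c(1, -1)) {
            pp <- par
            pp[idx[i]] <- par[idx[i]] + si * h[i]
            pp[idx[j]] <- par[idx[j]] + sj * h[j]
            val <- val + si * sj * f(pp)
          }
        }
        H[i, j] <- H[j, i] <- val / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' @export
print.ordinal_fit <- function(x, ...) {
  cat("<ordinal_fit> n = ", x$n, ", logLik = ", formatC(x$loglik, digits = 3, format = "f"),
    if (!x$converged) " (NOT converged)", "\n",
    sep = ""
  )
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Tidy an ordinal tolerance fit
#'
#' @param x An `ordinal_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `statistic`
#'   (Wald z), `p_value`, and `type` (threshold / fixed / ranef_sd).
#' @export
tidy.ordinal_fit <- function(x, ...) {
  est <- c(x$theta, x$beta)
  se <- x$se[names(est)]
  z <- est / se
  fixed <- tibble::tibble(
    term = names(est), estimate = unname(est), std_error = unname(se),
    statistic = unname(z), p_value = 2 * stats::pnorm(-abs(unname(z))),
    type = rep(c("threshold", "fixed"), c(length(x$theta), length(x$beta)))
  )
  ranef <- tibble::tibble(
    term = paste0("sd_", names(x$sigma)), estimate = unname(x$sigma),
    std_error = NA_real_, statistic = NA_real_, p_value = NA_real_,
    type = "ranef_sd"
  )
  dplyr::bind_rows(fixed, ranef)
}

#' @export
glance.ordinal_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, logLik = x$loglik, n_fixed = length(x$beta),
    n_thresholds = length(x$theta), converged = x$converged
  )
}

#' Predicted category probabilities at the population level
#'
#' @param object An `ordinal_fit`.
#' @param newdata Tibble of fixed-effect covariates (random effects set
#'   to 0); default the original records.
#' @param ... Unused.
#' @return Matrix (rows = newdata rows, cols = categories) of
#'   probabilities.
#' @export
predict.ordinal_fit <- function(object, newdata = NULL, ...) {
  X <- if (is.null(newdata)) {
    object$X
  } else {
    Xn <- stats::model.matrix(object$fixed, stats::model.frame(object$fixed, newdata))
    Xn[, colnames(object$X), drop = FALSE]
  }
  eta <- if (ncol(X)) drop(X %*% object$beta) else rep(0, nrow(X))
  t(cumlogit_probs(eta, object$theta))
}

#' Reduced tolerance model without the sex interaction
#'
#' @inheritParams fit_ordinal
#' @param ... Passed to [fit_ordinal()].
#' @return An `ordinal_fit`.
#' @export
fit_reduced <- function(records, ...) {
  fit_ordinal(records, fixed = ~ social_level + possessor_sex + recipient_sex, ...)
}

#' Full-null likelihood-ratio test
#'
#' Overall test of the primary predictors guarding against cryptic
#' multiple testing: the null model lacks all fixed predictors but keeps
#' the identical random-intercept structure. `chi2 = 2 (llfull - llnull)`
#' (floored at 0), df = difference in fixed-effect parameter count.
#'
#' @param full,null `ordinal_fit`s on the same data; the null's fixed
#'   terms must be a subset of the full's.
#' @return Tibble `chi2`, `df`, `p_value`.
#' @export
lrt_full_null <- function(full, null) {
  if (full$n != null$n) stop("models were fitted to different data", call. = FALSE)
  if (!all(names(null$beta) %in% names(full$beta))) {
    stop("null model is not nested in the full model", call. = FALSE)
  }
  df <- length(full$beta) - length(null$beta)
  chi2 <- max(0, 2 * (full$loglik - null$loglik))
  tibble::tibble(
    chi2 = chi2, df = df,
    p_value = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else NA_real_
  )
}

#' Proportional-odds diagnostic via dichotomized logistic fits
#'
#' Fits two binary mixed logistic models on the same records, with the
#' response dichotomized once as steal vs scavenge/succeed/share and
#' once as steal/scavenge/succeed vs share (both coded so 1 = the more
#' tolerant side, making the estimates directly comparable to the
#' ordinal fit's), with identical fixed and random structure. Roughly
#' similar fixed-effect estimates across the three fits indicate the
#' proportional-odds assumption is not strongly violated.
#'
#' @inheritParams fit_ordinal
#' @return List with `comparison` (tibble: term, ordinal, cut_steal,
#'   cut_share) and `max_abs_discrepancy`.
#' @export
proportional_odds_check <- function(records,
                                    fixed = ~ social_level + possessor_sex * recipient_sex,
                                    random = c("possessor_id", "recipient_id", "dyad_id", "event_id"),
                                    ...) {
  ord <- fit_ordinal(records, fixed = fixed, random = random, se = FALSE, ...)
  y <- ord$y
  fit_bin <- function(z) {
    dat <- records
    dat$z <- z
    rhs <- paste(c(
      attr(stats::terms(fixed), "term.labels"),
      paste0("(1 | ", random, ")")
    ), collapse = " + ")
    m <- suppressMessages(suppressWarnings(
      lme4::glmer(stats::as.formula(paste("z ~", rhs)),
        data = dat, family = stats::binomial,
        control = lme4::glmerControl(calc.derivs = FALSE)
      )
    ))
    b <- lme4::fixef(m)
    b[names(b) != "(Intercept)"]
  }
  b1 <- fit_bin(as.integer(y > 1)) # steal vs the rest
  b2 <- fit_bin(as.integer(y > 2)) # share vs the rest
  comparison <- tibble::tibble(
    term = names(ord$beta),
    ordinal = unname(ord$beta),
    cut_steal = unname(b1[names(ord$beta)]),
    cut_share = unname(b2[names(ord$beta)])
  )
  disc <- max(abs(c(
    comparison$cut_steal - comparison$ordinal,
    comparison$cut_share - comparison$ordinal
  )), na.rm = TRUE)
  list(comparison = comparison, max_abs_discrepancy = disc)
}

#' Model stability under leave-one-level-out refits
#'
#' Refits the model once per level of each grouping factor with the
#' records of that level removed and reports the range of every fixed
#' estimate across the refits.
#'
#' @param records Records tibble as in [fit_ordinal()].
#' @param ... Passed to [fit_ordinal()] (e.g. `fixed`).
#' @param random Grouping columns.
#' @return Tibble `term`, `estimate` (full fit), `min`, `max`, `range`.
#' @export
stability_check <- function(records,
                            random = c("possessor_id", "recipient_id", "dyad_id", "event_id"),
                            ...) {
  full <- fit_ordinal(records, random = random, se = FALSE, ...)
  ests <- list(c(full$theta, full$beta))
  for (fac in random) {
    for (lev in unique(records[[fac]])) {
      sub <- records[records[[fac]] != lev, , drop = FALSE]
      if (length(unique(sub$transfer_type)) < 2) next
      f <- try(fit_ordinal(sub, random = random, se = FALSE, ...), silent = TRUE)
      if (!inherits(f, "try-error") && f$converged) {
        ests[[length(ests) + 1L]] <- c(f$theta, f$beta)
      }
    }
  }
  nm <- names(ests[[1]])
  m <- do.call(rbind, lapply(ests, function(e) e[nm]))
  tibble::tibble(
    term = nm,
    estimate = unname(m[1, ]),
    min = unname(apply(m[-1, , drop = FALSE], 2, min)),
    max = unname(apply(m[-1, , drop = FALSE], 2, max))
  ) |>
    dplyr::mutate(range = .data$max - .data$min)
}

# simulate a response vector from a fitted ordinal model, redrawing the
# random intercepts from the estimated variances
simulate_ordinal_response <- function(fit) {
  re <- fit$re
  eta <- if (ncol(fit$X)) drop(fit$X %*% fit$beta) else rep(0, fit$n)
  if (re$q > 0) {
    u <- stats::rnorm(re$q, 0, rep(fit$sigma, times = re$q_r))
    eta <- eta + drop(re$Z %*% u)
  }
  pr <- cumlogit_probs(eta, fit$theta)
  apply(pr, 2, function(p) sample.int(length(p), 1, prob = p))
}

#' Parametric bootstrap confidence intervals
#'
#' Simulates responses from the fitted model (fixed effects at their
#' estimates, random intercepts redrawn from the estimated variances),
#' refits, and returns percentile 95% intervals for the thresholds and
#' fixed effects. Non-converged replicates are dropped and counted.
#'
#' @param fit A converged `ordinal_fit`.
#' @param records The records the model was fitted to.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param level Interval level (default 0.95).
#' @return Tibble `term`, `estimate`, `lower`, `upper`, with attributes
#'   `n_boot_used` and `n_failed`.
#' @export
parametric_bootstrap <- function(fit, records, n_boot = 1000, seed = 1L, level = 0.95) {
  if (!fit$converged) stop("refusing to bootstrap a non-converged fit", call. = FALSE)
  est <- c(fit$theta, fit$beta)
  if (n_boot == 0) {
    out <- tibble::tibble(
      term = character(), estimate = numeric(),
      lower = numeric(), upper = numeric()
    )
    attr(out, "n_boot_used") <- 0L
    attr(out, "n_failed") <- 0L
    return(out)
  }
  boot <- with_seed(seed, salt = 23L, expr = {
    res <- vector("list", n_boot)
    for (b in seq_len(n_boot)) {
      rec_b <- records
      rec_b$transfer_type <- simulate_ordinal_response(fit)
      f <- try(
        fit_ordinal(rec_b,
          fixed = fit$fixed, random = fit$random, se = FALSE, rel_tol = 1e-7,
          start = list(
            theta = unname(fit$theta), beta = unname(fit$beta),
            sigma = pmax(unname(fit$sigma), 0.05)
          )
        ),
        silent = TRUE
      )
      if (!inherits(f, "try-error") && f$converged &&
        length(unique(rec_b$transfer_type)) == fit$n_categories) {
        res[[b]] <- c(f$theta, f$beta)
      }
    }
    res
  })
  ok <- !vapply(boot, is.null, TRUE)
  m <- do.call(rbind, boot[ok])
  alpha <- (1 - level) / 2
  out <- tibble::tibble(
    term = names(est),
    estimate = unname(est),
    lower = apply(m[, names(est), drop = FALSE], 2, stats::quantile, alpha),
    upper = apply(m[, names(est), drop = FALSE], 2, stats::quantile, 1 - alpha)
  )
  attr(out, "n_boot_used") <- sum(ok)
  attr(out, "n_failed") <- n_boot - sum(ok)
  out
}
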