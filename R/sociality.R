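# Sociality stage: individual gregariousness and dyadic affinity.
#
# The two axes are estimated jointly from three focal-follow behaviours
# (approaches, grooming, contact sitting) aggregated over the 90 days
# preceding a meat-eating event. The symmetric dyadic score is
#   mu_ij = 0.5 * (g_i + g_j) + a_ij
# with approaches Poisson on the log scale (log-effort offset) and the
# two proportion behaviours Beta in the mean-precision parameterization.

#' MCMC settings
#'
#' @param chains,warmup,iter,thin Number of chains, adaptation+burn-in
#'   iterations, kept iterations per chain, and thinning interval.
#' @param seed Integer seed; chain RNGs are derived from it.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 4, warmup = 1000, iter = 1000, thin = 1, seed = 1L) {
  stopifnot(chains >= 1, warmup >= 0, iter >= 1, thin >= 1)
  structure(
    list(
      chains = as.integer(chains), warmup = as.integer(warmup),
      iter = as.integer(iter), thin = as.integer(thin), seed = as.integer(seed)
    ),
    class = "mcmc_config"
  )
}

jags_inits <- function(mcmc) {
  lapply(seq_len(mcmc$chains), function(ch) {
    list(
      .RNG.name = "base::Mersenne-Twister",
      .RNG.seed = (mcmc$seed + 104729L * ch) %% .Machine$integer.max
    )
  })
}

run_jags <- function(model_string, data, monitor, mcmc, inits_extra = NULL) {
  inits <- jags_inits(mcmc)
  if (!is.null(inits_extra)) {
    inits <- lapply(inits, function(x) c(x, inits_extra))
  }
  con <- textConnection(model_string)
  on.exit(close(con))
  jm <- rjags::jags.model(con,
    data = data, inits = inits, n.chains = mcmc$chains,
    n.adapt = max(100L, mcmc$warmup %/% 2L), quiet = TRUE
  )
  if (mcmc$warmup > 0) stats::update(jm, mcmc$warmup, progress.bar = "none")
  rjags::coda.samples(jm, monitor,
    n.iter = mcmc$iter * mcmc$thin,
    thin = mcmc$thin, progress.bar = "none"
  )
}

# max split-free potential-scale-reduction over monitored columns
rhat_max <- function(samples) {
  if (coda::nchain(samples) < 2) {
    return(NA_real_)
  }
  gd <- try(coda::gelman.diag(samples, multivariate = FALSE, autoburnin = FALSE),
    silent = TRUE
  )
  if (inherits(gd, "try-error")) {
    return(NA_real_)
  }
  max(gd$psrf[, 1], na.rm = TRUE)
}

#' Restrict behaviour records to the window preceding an event
#'
#' Keeps focal-behaviour records with `event_date - window_days <= date <
#' event_date` and aggregates them per unordered dyad: counts and
#' durations are summed, effort is summed, and proportions are recomputed
#' as total duration / total effort.
#'
#' @param records Tibble with columns `date`, `id_a`, `id_b`,
#'   `approach_count`, `groom_hours`, `contact_hours`, `effort_hours`.
#' @param event_date Date of the meat-eating event (strict upper bound).
#' @param window_days Length of the window (default 90).
#' @return Tibble with one row per dyad: `id_a`, `id_b`, `dyad`,
#'   `approach_count`, `obs_effort`, `groom_prop`, `contact_prop`. An
#'   empty result carries attribute `insufficient_focal_data = TRUE`.
#' @export
window_subset <- function(records, event_date, window_days = 90) {
  stopifnot(window_days > 0)
  event_date <- as.Date(event_date)
  w <- records |>
    dplyr::filter(
      .data$date >= event_date - window_days,
      .data$date < event_date
    ) |>
    dplyr::mutate(dyad = dyad_key(.data$id_a, .data$id_b)) |>
    dplyr::group_by(.data$dyad) |>
    dplyr::summarise(
      id_a = pmin(.data$id_a[1], .data$id_b[1]),
      id_b = pmax(.data$id_a[1], .data$id_b[1]),
      approach_count = sum(.data$approach_count),
      obs_effort = sum(.data$effort_hours),
      groom_prop = sum(.data$groom_hours) / sum(.data$effort_hours),
      contact_prop = sum(.data$contact_hours) / sum(.data$effort_hours),
      .groups = "drop"
    ) |>
    dplyr::relocate("id_a", "id_b", "dyad")
  if (nrow(w) == 0) attr(w, "insufficient_focal_data") <- TRUE
  w
}

#' Nudge proportions away from exact zero
#'
#' Adds Uniform(0, epsilon) noise to every grooming and contact
#' proportion so that all values are strictly positive, as the Beta
#' likelihood requires. Applied to all values, not only zeros, so the
#' perturbation is exchangeable across dyads.
#'
#' @param records Output of [window_subset()].
#' @param epsilon Upper bound of the uniform noise (default 1e-6; must be
#'   in (0, 1e-4]).
#' @param seed Integer seed for reproducibility.
#' @return `records` with perturbed `groom_prop` and `contact_prop`,
#'   all strictly inside (0, 1).
#' @export
jitter_proportions <- function(records, epsilon = 1e-6, seed = 1L) {
  if (!(epsilon > 0 && epsilon <= 1e-4)) {
    stop("epsilon must be in (0, 1e-4]", call. = FALSE)
  }
  with_seed(seed, salt = 11L, expr = {
    n <- nrow(records)
    cap <- 1 - 1e-12
    records$groom_prop <- pmin(records$groom_prop + stats::runif(n, 0, epsilon), cap)
    records$contact_prop <- pmin(records$contact_prop + stats::runif(n, 0, epsilon), cap)
    records
  })
}

sociality_model_code <- "
model {
  for (d in 1:D) {
    mu[d] <- 0.5 * (g[ia[d]] + g[ib[d]]) + a[d]
    approach[d] ~ dpois(exp(mu[d] + b0_approach + log_eff[d]))
    m_groom[d] <- ilogit(mu[d] + b0_groom)
    m_contact[d] <- ilogit(mu[d] + b0_contact)
    groom[d] ~ dbeta(m_groom[d] * phi_groom, (1 - m_groom[d]) * phi_groom)
    contact[d] ~ dbeta(m_contact[d] * phi_contact, (1 - m_contact[d]) * phi_contact)
    a[d] ~ dnorm(0, 1 / sa2)
  }
  for (i in 1:N) {
    g[i] ~ dnorm(0, 1 / sg2)
  }
  sg2 ~ dexp(1)
  sa2 ~ dexp(1)
  b0_approach ~ dnorm(0, 1)
  b0_groom ~ dnorm(-6, 0.25)
  b0_contact ~ dnorm(-6, 0.25)
  phi_groom ~ dexp(0.1)
  phi_contact ~ dexp(0.1)
}
"

#' Fit the joint gregariousness/affinity model
#'
#' Joint hierarchical Bayesian model over all three behaviours:
#' `approach ~ Poisson(exp(mu + b0_approach + log(effort)))`,
#' `groom, contact ~ Beta(logit^-1(mu + b0) * phi, (1 - logit^-1(mu + b0)) * phi)`,
#' `mu_ij = 0.5 * (g_i + g_j) + a_ij`, with `g ~ Normal(0, sigma_g^2)`,
#' `a ~ Normal(0, sigma_a^2)` and priors `sigma^2 ~ Exponential(1)`,
#' `b0_approach ~ Normal(0, 1)`, `b0_groom, b0_contact ~ Normal(-6, 2)`
#' (s.d. 2), `phi ~ Exponential(0.1)`. Fitted by Gibbs/Metropolis
#' sampling (JAGS).
#'
#' @param records Jittered output of [window_subset()]: proportions must
#'   be strictly inside (0, 1).
#' @param mcmc An [mcmc_config()].
#' @return Object of class `sociality_fit`: matrices of posterior draws
#'   for `g` (draws x individuals) and `a` (draws x dyads), a tibble of
#'   scalar draws (intercepts, precisions, variance components), and a
#'   diagnostics list (`rhat_max`, `converged`).
#' @export
fit_sociality <- function(records, mcmc = mcmc_config()) {
  ids <- sort(unique(c(records$id_a, records$id_b)))
  if (length(ids) < 2) stop("need at least 2 individuals", call. = FALSE)
  if (any(records$obs_effort <= 0)) stop("non-positive observation effort", call. = FALSE)
  if (any(records$groom_prop <= 0 | records$groom_prop >= 1) ||
    any(records$contact_prop <= 0 | records$contact_prop >= 1)) {
    stop("proportions must lie strictly in (0, 1); run jitter_proportions() first",
      call. = FALSE
    )
  }
  dyads <- dyad_key(records$id_a, records$id_b)
  if (anyDuplicated(dyads)) {
    stop("one record per dyad expected; aggregate with window_subset() first",
      call. = FALSE
    )
  }
  data <- list(
    D = nrow(records), N = length(ids),
    ia = match(pmin(records$id_a, records$id_b), ids),
    ib = match(pmax(records$id_a, records$id_b), ids),
    approach = records$approach_count,
    log_eff = log(records$obs_effort),
    groom = records$groom_prop,
    contact = records$contact_prop
  )
  monitor <- c(
    "g", "a", "b0_approach", "b0_groom", "b0_contact",
    "phi_groom", "phi_contact", "sg2", "sa2"
  )
  samples <- run_jags(sociality_model_code, data, monitor, mcmc)
  mat <- as.matrix(samples)
  gi <- grep("^g\\[", colnames(mat))
  ai <- grep("^a\\[", colnames(mat))
  scalars <- tibble::as_tibble(mat[, c(
    "b0_approach", "b0_groom", "b0_contact",
    "phi_groom", "phi_contact", "sg2", "sa2"
  ), drop = FALSE])
  rh <- rhat_max(samples[, c(
    "b0_approach", "b0_groom", "b0_contact",
    "phi_groom", "phi_contact", "sg2", "sa2"
  ), drop = FALSE])
  conv <- is.na(rh) || rh < 1.1
  if (!conv) {
    warning("sociality model may not have converged (max Rhat = ",
      round(rh, 3), ")",
      call. = FALSE
    )
  }
  structure(
    list(
      g = mat[, gi, drop = FALSE],
      a = mat[, ai, drop = FALSE],
      scalars = scalars,
      ids = ids,
      dyads = dyads,
      diagnostics = list(rhat_max = rh, converged = conv, mcmc = mcmc)
    ),
    class = "sociality_fit"
  )
}

#' @export
print.sociality_fit <- function(x, ...) {
  cat(
    "<sociality_fit> ", length(x$ids), " individuals, ", length(x$dyads),
    " dyads, ", nrow(x$g), " posterior draws\n",
    sep = ""
  )
  cat(
    "  max Rhat: ", formatC(x$diagnostics$rhat_max, digits = 3, format = "f"),
    if (isTRUE(x$diagnostics$converged)) " (converged)" else " (NOT converged)", "\n",
    sep = ""
  )
  invisible(x)
}

#' Tidy posterior summaries of a sociality fit
#'
#' @param x A `sociality_fit`.
#' @param interval_mass Credible-interval mass (default 0.89).
#' @param ... Unused.
#' @return Tibble with one row per parameter (`g:<id>`, `a:<dyad>` and
#'   scalars), posterior median and equal-tailed interval.
#' @export
tidy.sociality_fit <- function(x, interval_mass = 0.89, ...) {
  summ <- function(m, prefix, names) {
    purrr::map2_dfr(
      asplit(m, 2), names,
      function(col, nm) {
        dplyr::mutate(summarize_posterior(as.numeric(col), interval_mass),
          term = paste0(prefix, nm), .before = 1
        )
      }
    )
  }
  dplyr::bind_rows(
    summ(x$g, "g:", x$ids),
    summ(x$a, "a:", x$dyads),
    summ(as.matrix(x$scalars), "", colnames(x$scalars))
  )
}

#' @export
glance.sociality_fit <- function(x, ...) {
  tibble::tibble(
    n_individuals = length(x$ids), n_dyads = length(x$dyads),
    n_draws = nrow(x$g), rhat_max = x$diagnostics$rhat_max,
    converged = x$diagnostics$converged
  )
}

#' Posterior means of dyadic affinity
#'
#' @param fit A `sociality_fit`.
#' @return Tibble `dyad`, `a_mean`.
#' @export
affinity_means <- function(fit) {
  tibble::tibble(dyad = fit$dyads, a_mean = colMeans(fit$a))
}

# indexes of K approximately evenly spaced posterior draws
thin_index <- function(n_draws, k) {
  unique(round(seq(1, n_draws, length.out = min(k, n_draws))))
}
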