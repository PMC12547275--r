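# Meat-transfer sub-models: audience size (zero-truncated Poisson),
# audience composition (multinomial softmax over the party roster) and
# transfer choice (categorical softmax over the audience), each taking
# its sociality predictor with full posterior uncertainty propagated by
# multiple imputation over thinned sociality draws.

#' Apply the transfer exclusion rules
#'
#' Removes, in order and with one logged reason per transfer: transfers
#' of unknown type, steal transfers (they do not reflect the possessor's
#' motivation to share), cross-party dyads (no affinity can be
#' estimated), and transfers whose preceding 90-day window lacks focal
#' observations.
#'
#' @param transfers Tibble with at least `type` plus either
#'   `possessor_party` / `recipient_party` columns or a `roster` to
#'   derive them, and either a logical `has_focal` column or a
#'   `focal_available` lookup.
#' @param roster Optional roster tibble (`id`, `party_id`) used to
#'   resolve party membership.
#' @param focal_available Optional tibble (`event_id`, `has_focal`)
#'   flagging events whose window holds focal data.
#' @return List with `transfers` (the retained subset) and `exclusions`
#'   (tibble `reason`, `n`, in application order).
#' @export
filter_transfers <- function(transfers, roster = NULL, focal_available = NULL) {
  tr <- transfers
  if (!is.null(roster)) {
    party <- stats::setNames(roster$party_id, roster$id)
    tr$possessor_party <- unname(party[tr$possessor_id])
    tr$recipient_party <- unname(party[tr$recipient_id])
  }
  if (!is.null(focal_available)) {
    tr <- dplyr::left_join(tr, focal_available, by = "event_id")
  }
  if (is.null(tr$has_focal)) tr$has_focal <- TRUE
  if (nrow(tr) == 0) {
    return(list(
      transfers = tr,
      exclusions = tibble::tibble(reason = character(), n = integer())
    ))
  }
  known_types <- c("share", "scavenge", "succeed", "steal")
  reason <- dplyr::case_when(
    !(tr$type %in% known_types) ~ "unknown_type",
    tr$type == "steal" ~ "steal",
    tr$possessor_party != tr$recipient_party ~ "cross_party",
    !tr$has_focal ~ "no_focal",
    TRUE ~ NA_character_
  )
  excl <- tibble::tibble(reason = reason[!is.na(reason)]) |>
    dplyr::count(.data$reason, name = "n") |>
    dplyr::arrange(match(.data$reason, c("unknown_type", "steal", "cross_party", "no_focal")))
  list(transfers = tr[is.na(reason), , drop = FALSE], exclusions = excl)
}

#' Keep transfers with a minimum audience size
#'
#' The transfer-choice model needs at least two candidates, so events
#' with a singleton audience carry no information about who is chosen.
#'
#' @param transfers Transfers tibble keyed by (`event_id`, `order`).
#' @param audiences Audience membership tibble (`event_id`, `order`,
#'   `member_id`); if `NULL`, `transfers` must carry an `audience_size`
#'   column.
#' @param min_size Minimum audience size retained (default 2).
#' @return The retained subset of `transfers` (with an `audience_size`
#'   column attached).
#' @export
prune_min_audience <- function(transfers, audiences = NULL, min_size = 2) {
  stopifnot(min_size >= 1)
  if (!is.null(audiences)) {
    sizes <- audiences |>
      dplyr::count(.data$event_id, .data$order, name = "audience_size")
    transfers <- transfers |>
      dplyr::select(-dplyr::any_of("audience_size")) |>
      dplyr::left_join(sizes, by = c("event_id", "order")) |>
      dplyr::mutate(audience_size = dplyr::coalesce(.data$audience_size, 0L))
  }
  if (is.null(transfers$audience_size)) {
    stop("provide `audiences` or an `audience_size` column", call. = FALSE)
  }
  dplyr::filter(transfers, .data$audience_size >= min_size)
}

# ---- uncertainty propagation over sociality draws -------------------------

# Normalize a sociality predictor into a draws matrix (n_draw_sets x n_keys).
# Accepts a sociality_fit (thinned to k sets), a pre-built draws matrix
# with key colnames (thinned to k rows), or a fixed tibble (key, value)
# treated as a single draw set.
predictor_draws <- function(x, kind = c("a", "g"), k = 50) {
  kind <- match.arg(kind)
  if (inherits(x, "sociality_fit")) {
    m <- if (kind == "a") x$a else x$g
    keys <- if (kind == "a") x$dyads else x$ids
    idx <- thin_index(nrow(m), k)
    m <- m[idx, , drop = FALSE]
    colnames(m) <- keys
    return(m)
  }
  if (is.matrix(x)) {
    return(x[thin_index(nrow(x), k), , drop = FALSE])
  }
  stopifnot(is.data.frame(x), ncol(x) >= 2)
  matrix(x[[2]], nrow = 1, dimnames = list(NULL, x[[1]]))
}

# per-imputation MCMC settings: one chain, same warmup, kept draws so the
# pooled posterior has about chains*iter draws in total
imputation_mcmc <- function(mcmc, n_sets, s) {
  mcmc_config(
    chains = 1, warmup = mcmc$warmup,
    iter = max(50L, ceiling(mcmc$iter * mcmc$chains / n_sets)),
    thin = mcmc$thin,
    seed = (mcmc$seed + 6553L * s) %% .Machine$integer.max
  )
}

pool_imputations <- function(draws_list) {
  dplyr::bind_rows(draws_list, .id = "draw_set")
}

audience_size_code <- "
model {
  for (i in 1:T) {
    log(lambda[i]) <- c0 + c0_party[party[i]] + c0_poss[poss[i]] + c1 * g[i]
    size[i] ~ dpois(lambda[i]) T(1,)
  }
  for (p in 1:P) { c0_party[p] ~ dnorm(0, 1 / sparty2) }
  for (q in 1:Q) { c0_poss[q] ~ dnorm(0, 1 / sposs2) }
  sparty2 ~ dexp(1)
  sposs2 ~ dexp(1)
  c0 ~ dnorm(0, 1)
  c1 ~ dnorm(0, 1)
}
"

#' Audience size as a function of possessor gregariousness
#'
#' Zero-truncated Poisson regression of audience size on the possessor's
#' gregariousness, with varying intercepts for possessor and party
#' identity: `size ~ Poisson+(exp(c0 + c0_possessor + c0_party + c1 * g))`,
#' priors `c0, c1 ~ Normal(0, 1)`, `sigma^2 ~ Exponential(1)`.
#' Gregariousness enters with propagated posterior uncertainty: the model
#' is refitted once per thinned sociality draw set and the posteriors are
#' pooled by concatenation.
#'
#' @param observations Tibble with `size` (>= 1), `possessor_id`,
#'   `party_id`, and optionally `g_key` (the column of the
#'   gregariousness draws to use as predictor; defaults to
#'   `possessor_id`).
#' @param gregariousness A `sociality_fit` (posterior draws of `g` are
#'   propagated) or a tibble (`id`, `g`) of fixed values.
#' @param mcmc An [mcmc_config()]; the pooled posterior has about
#'   `chains * iter` draws regardless of `k`.
#' @param k Number of imputation draw sets (default 50; ignored for
#'   fixed-value predictors).
#' @return Object of class `audience_size_fit` with a tibble of pooled
#'   draws (`c0`, `c1`, `sparty2`, `sposs2`) and diagnostics.
#' @export
fit_audience_size <- function(observations, gregariousness,
                              mcmc = mcmc_config(), k = 50) {
  if (any(observations$size < 1)) {
    stop("audience sizes must be >= 1 (zero-truncated)", call. = FALSE)
  }
  gd <- predictor_draws(gregariousness, "g", k)
  g_key <- if ("g_key" %in% names(observations)) {
    observations$g_key
  } else {
    observations$possessor_id
  }
  missing_ids <- setdiff(unique(g_key), colnames(gd))
  if (length(missing_ids)) {
    stop("no gregariousness for: ", paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  poss <- factor(observations$possessor_id)
  party <- factor(observations$party_id)
  base_data <- list(
    T = nrow(observations), P = nlevels(party), Q = nlevels(poss),
    size = as.integer(observations$size),
    party = as.integer(party), poss = as.integer(poss)
  )
  n_sets <- nrow(gd)
  draws <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    data <- c(base_data, list(g = unname(gd[s, g_key])))
    samp <- run_jags(
      audience_size_code, data, c("c0", "c1", "sparty2", "sposs2"),
      imputation_mcmc(mcmc, n_sets, s)
    )
    draws[[s]] <- tibble::as_tibble(as.matrix(samp))
  }
  new_transfer_fit(
    pool_imputations(draws), "audience_size_fit",
    slope = "c1", n_obs = nrow(observations), n_sets = n_sets
  )
}

audience_comp_code <- "
model {
  for (j in 1:M) {
    eta[j] <- caffi * a[j]
    e[j] <- exp(eta[j])
  }
  for (t in 1:T) {
    ll[t] <- inprod(y[start[t]:end[t]], eta[start[t]:end[t]]) -
             naud[t] * log(sum(e[start[t]:end[t]]))
    zeros[t] ~ dpois(BIG - ll[t])
  }
  caffi ~ dnorm(0, 1)
}
"

#' Audience composition as a function of affinity with the possessor
#'
#' Multinomial softmax model of which party members are present in the
#' audience: for each transfer the candidate pool is the adult party
#' roster, membership counts follow
#' `Multinomial(softmax(c_affi * a), size = audience size)`, prior
#' `c_affi ~ Normal(0, 1)`. Affinity uncertainty is propagated as in
#' [fit_audience_size()].
#'
#' @param candidates Long tibble with one row per (transfer, candidate):
#'   `choice_id`, `member_id`, `dyad` (possessor-member key),
#'   `in_audience` (0/1).
#' @param affinity A `sociality_fit` or tibble (`dyad`, `a`).
#' @inheritParams fit_audience_size
#' @return Object of class `audience_comp_fit` with pooled draws of
#'   `caffi`.
#' @export
fit_audience_composition <- function(candidates, affinity,
                                     mcmc = mcmc_config(), k = 50) {
  ad <- predictor_draws(affinity, "a", k)
  missing <- setdiff(unique(candidates$dyad), colnames(ad))
  if (length(missing)) {
    stop("no affinity for dyads: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  candidates <- dplyr::arrange(candidates, .data$choice_id)
  grp <- factor(candidates$choice_id, levels = unique(candidates$choice_id))
  len <- as.integer(table(grp))
  end <- cumsum(len)
  start <- end - len + 1L
  naud <- as.numeric(tapply(candidates$in_audience, grp, sum))
  if (any(naud > len)) stop("audience larger than candidate pool", call. = FALSE)
  base_data <- list(
    M = nrow(candidates), T = nlevels(grp),
    y = as.numeric(candidates$in_audience),
    start = start, end = end, naud = naud,
    zeros = rep(0, nlevels(grp)), BIG = 1e4
  )
  n_sets <- nrow(ad)
  draws <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    data <- c(base_data, list(a = unname(ad[s, candidates$dyad])))
    samp <- run_jags(
      audience_comp_code, data, "caffi",
      imputation_mcmc(mcmc, n_sets, s)
    )
    draws[[s]] <- tibble::as_tibble(as.matrix(samp))
  }
  new_transfer_fit(
    pool_imputations(draws), "audience_comp_fit",
    slope = "caffi", n_obs = nlevels(grp), n_sets = n_sets
  )
}

transfer_choice_code <- "
model {
  for (j in 1:M) {
    mu[j] <- b_affi * a[j] + b_sex * sexk[j] + b0p[pid[j]]
    e[j] <- exp(mu[j])
  }
  for (t in 1:T) {
    ll[t] <- mu[rec[t]] - log(sum(e[start[t]:end[t]]))
    zeros[t] ~ dpois(BIG - ll[t])
  }
  for (p in 1:P) { b0p[p] ~ dnorm(0, 1 / spartner2) }
  spartner2 ~ dexp(1)
  b_affi ~ dnorm(0, 1)
  b_sex ~ dnorm(0, 1)
}
"

#' Who in the audience receives the meat
#'
#' The primary sub-model: a categorical softmax choice over the ragged
#' audience of each transfer,
#' `recipient ~ Multinomial(softmax(b_affi * a + b_sex * sex + b0_partner), 1)`,
#' with a varying intercept per candidate identity
#' (`b0_partner ~ Normal(0, sigma_partner^2)`) and priors
#' `b_affi, b_sex ~ Normal(0, 1)`, `sigma_partner^2 ~ Exponential(1)`.
#' A positive `b_affi` means audience members with a stronger dyadic
#' affinity to the possessor are more likely to receive meat. Affinity
#' uncertainty is propagated as in [fit_audience_size()].
#'
#' @param choices Long tibble with one row per (transfer, candidate):
#'   `choice_id`, `member_id`, `dyad` (possessor-candidate key), `sex`
#'   (0 = female, 1 = male), `is_recipient` (exactly one TRUE per
#'   choice). Audiences must have >= 2 candidates.
#' @param affinity A `sociality_fit` or tibble (`dyad`, `a`).
#' @inheritParams fit_audience_size
#' @return Object of class `transfer_choice_fit` with pooled draws of
#'   `b_affi`, `b_sex`, `spartner2`.
#' @export
fit_transfer_choice <- function(choices, affinity,
                                mcmc = mcmc_config(), k = 50) {
  choices <- dplyr::arrange(choices, .data$choice_id)
  grp <- factor(choices$choice_id, levels = unique(choices$choice_id))
  len <- as.integer(table(grp))
  if (any(len < 2)) {
    stop("every choice needs an audience of >= 2 candidates; run prune_min_audience()",
      call. = FALSE
    )
  }
  nrec <- tapply(choices$is_recipient, grp, sum)
  if (any(nrec != 1)) stop("each choice must have exactly one recipient", call. = FALSE)
  ad <- predictor_draws(affinity, "a", k)
  missing <- setdiff(unique(choices$dyad), colnames(ad))
  if (length(missing)) {
    stop("no affinity for dyads: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  end <- cumsum(len)
  start <- end - len + 1L
  partner <- factor(choices$member_id)
  base_data <- list(
    M = nrow(choices), T = nlevels(grp), P = nlevels(partner),
    sexk = as.numeric(choices$sex), pid = as.integer(partner),
    rec = which(choices$is_recipient),
    start = start, end = end,
    zeros = rep(0, nlevels(grp)), BIG = 1e4
  )
  n_sets <- nrow(ad)
  draws <- vector("list", n_sets)
  for (s in seq_len(n_sets)) {
    data <- c(base_data, list(a = unname(ad[s, choices$dyad])))
    samp <- run_jags(
      transfer_choice_code, data, c("b_affi", "b_sex", "spartner2"),
      imputation_mcmc(mcmc, n_sets, s)
    )
    draws[[s]] <- tibble::as_tibble(as.matrix(samp))
  }
  new_transfer_fit(
    pool_imputations(draws), "transfer_choice_fit",
    slope = "b_affi", n_obs = nlevels(grp), n_sets = n_sets
  )
}

new_transfer_fit <- function(draws, class, slope, n_obs, n_sets) {
  structure(
    list(draws = draws, slope = slope, n_obs = n_obs, n_sets = n_sets),
    class = c(class, "transfer_fit")
  )
}

#' @export
print.transfer_fit <- function(x, ...) {
  s <- summarize_posterior(x$draws[[x$slope]])
  cat("<", class(x)[1], "> ", x$n_obs, " observations, ",
    nrow(x$draws), " pooled draws over ", x$n_sets, " imputation set(s)\n",
    sep = ""
  )
  cat(sprintf(
    "  %s: median %.3f, %d%% CI [%.3f, %.3f]\n",
    x$slope, s$median, round(100 * s$mass), s$lower, s$upper
  ))
  invisible(x)
}

#' Tidy posterior summaries of a transfer sub-model fit
#'
#' @param x An `audience_size_fit`, `audience_comp_fit` or
#'   `transfer_choice_fit`.
#' @param interval_mass Credible-interval mass (default 0.89).
#' @param ... Unused.
#' @return Tibble with one row per monitored parameter.
#' @export
tidy.transfer_fit <- function(x, interval_mass = 0.89, ...) {
  nms <- setdiff(names(x$draws), "draw_set")
  purrr::map_dfr(nms, function(nm) {
    dplyr::mutate(summarize_posterior(x$draws[[nm]], interval_mass),
      term = nm, .before = 1
    )
  })
}

#' @export
glance.transfer_fit <- function(x, ...) {
  s <- summarize_posterior(x$draws[[x$slope]])
  tibble::tibble(
    slope_term = x$slope, slope_median = s$median,
    slope_lower = s$lower, slope_upper = s$upper,
    n_obs = x$n_obs, n_draws = nrow(x$draws), n_imputation_sets = x$n_sets
  )
}

#' Predicted choice probabilities for one audience
#'
#' The softmax choice rule of the transfer model applied to a single
#' audience, at fixed parameter values.
#'
#' @param affinities Numeric vector of candidate affinities with the
#'   possessor.
#' @param slope Affinity slope (`b_affi`).
#' @param sexes Candidate sexes (0/1), default all 0.
#' @param b_sex Sex effect, default 0.
#' @param intercepts Per-candidate varying intercepts, default 0.
#' @return Probability vector over the candidates.
#' @export
choice_probs <- function(affinities, slope, sexes = 0, b_sex = 0, intercepts = 0) {
  softmax(slope * affinities + b_sex * rep_len(sexes, length(affinities)) +
    rep_len(intercepts, length(affinities)))
}
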