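# Synthetic multi-level society with known ground truth.
#
# The generator mirrors the generative assumptions of the inference stages:
# gregariousness and affinity are i.i.d. Normal, approach counts are Poisson
# with a log-effort offset, grooming / contact-sitting proportions are Beta
# in the mean-precision parameterization, audience sizes are zero-truncated
# Poisson, and audience composition / transfer choice are softmax-weighted.
# Transfer types are graded by tolerance through a cumulative-logit model
# stratified by the shared social level of possessor and recipient.

#' Configuration of a synthetic multi-level society
#'
#' Builds and validates the full parameter set for the synthetic-data
#' generator. Defaults describe a society of 2 gangs x 2 parties x 3
#' one-male units with 2 females each, and generative parameters on the
#' scale of the estimates reported for wild Guinea baboons: unit-level
#' sociality variation of 1 s.d., rare grooming (logit-scale intercepts
#' near -6), a weak positive gregariousness effect on audience size and
#' weak positive affinity effects on audience composition and transfer
#' choice.
#'
#' @param n_gangs,parties_per_gang,units_per_party,females_per_unit
#'   Society structure counts; each unit holds exactly one male plus
#'   `females_per_unit` adult females.
#' @param sigma_g,sigma_a S.d. of individual gregariousness and dyadic
#'   affinity (both Normal(0, sigma^2); `sigma_a = 0` gives a society with
#'   no dyad-specific preferences).
#' @param b0_approach,b0_groom,b0_contact Behaviour intercepts on the log
#'   (approaches) and logit (proportions) scales.
#' @param phi_groom,phi_contact Beta precisions of the proportion behaviours.
#' @param c0,c1 Audience-size intercept and gregariousness slope (log scale).
#' @param sigma_party,sigma_possessor S.d. of the audience-size varying
#'   intercepts for party and possessor identity.
#' @param c_affi Affinity slope of the audience-composition softmax.
#' @param b_affi,b_sex Affinity slope and candidate-sex effect of the
#'   transfer-choice softmax (sex coded female = 0, male = 1).
#' @param sigma_partner S.d. of the per-individual propensity to receive
#'   meat irrespective of affinity.
#' @param ordinal_thresholds Two increasing cutpoints of the latent
#'   tolerance scale separating steal | scavenge/succeed | share.
#' @param ordinal_betas Named vector of latent-tolerance effects:
#'   `level_party` and `level_gang` (relative to same-unit transfers),
#'   `possessor_sex`, `recipient_sex`, `sex_interaction`.
#' @param ordinal_ranef_sd S.d. shared by the possessor / recipient /
#'   dyad / event random intercepts on the latent tolerance scale.
#' @param n_events Number of meat-eating events to simulate.
#' @param p_no_transfer Probability an event is consumed whole with no
#'   transfer (small prey); matches the observed 22/109 rate by default.
#' @param transfer_rate Rate of the zero-truncated Poisson for the number
#'   of transfers per event (1.6 gives mean very near 2, the observed
#'   median).
#' @param p_cross_party Probability that a given audience slot is open to
#'   same-gang members outside the possessor's party (cross-party dyads
#'   have no focal data, so no defined affinity; their sampling weight
#'   uses affinity 0).
#' @param effort_per_dyad Total focal observation effort per within-party
#'   dyad over a 90-day window, in hours.
#' @param start_date Date of the first meat-eating event.
#' @param event_span_days Events are spread uniformly over this many days.
#' @param seed Integer seed; every stochastic step flows from it.
#' @return A validated list of class `society_config`.
#' @export
society_config <- function(n_gangs = 2,
                           parties_per_gang = 2,
                           units_per_party = 3,
                           females_per_unit = 2,
                           sigma_g = 1,
                           sigma_a = 1,
                           b0_approach = -1,
                           b0_groom = -6,
                           b0_contact = -6,
                           phi_groom = 10,
                           phi_contact = 10,
                           c0 = 0.7,
                           c1 = 0.15,
                           sigma_party = 0.3,
                           sigma_possessor = 0.3,
                           c_affi = 0.15,
                           b_affi = 0.3,
                           b_sex = 0,
                           sigma_partner = 0.3,
                           ordinal_thresholds = c(-1, 1),
                           ordinal_betas = c(
                             level_party = -1.2, level_gang = -2.3,
                             possessor_sex = 0, recipient_sex = 0,
                             sex_interaction = 0
                           ),
                           ordinal_ranef_sd = 0.5,
                           n_events = 109,
                           p_no_transfer = 22 / 109,
                           transfer_rate = 1.6,
                           p_cross_party = 0.1,
                           effort_per_dyad = 30,
                           start_date = as.Date("2020-04-01"),
                           event_span_days = 60,
                           seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "society_config"
  validate_society_config(cfg)
  cfg
}

validate_society_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid society_config field '", field, "': ", msg, call. = FALSE)
  }
  for (f in c("n_gangs", "parties_per_gang", "units_per_party", "females_per_unit", "n_events")) {
    chk(length(cfg[[f]]) == 1 && cfg[[f]] >= 1 && cfg[[f]] == round(cfg[[f]]), f, "must be a count >= 1")
  }
  for (f in c("sigma_g", "sigma_a", "sigma_party", "sigma_possessor", "sigma_partner", "ordinal_ranef_sd")) {
    chk(cfg[[f]] >= 0, f, "must be >= 0")
  }
  for (f in c("phi_groom", "phi_contact", "transfer_rate", "effort_per_dyad")) {
    chk(cfg[[f]] > 0, f, "must be > 0")
  }
  chk(length(cfg$ordinal_thresholds) == 2 && diff(cfg$ordinal_thresholds) > 0,
    "ordinal_thresholds", "must be 2 strictly increasing cutpoints"
  )
  chk(all(c("level_party", "level_gang", "possessor_sex", "recipient_sex", "sex_interaction")
  %in% names(cfg$ordinal_betas)), "ordinal_betas", "missing named effects")
  for (f in c("p_no_transfer", "p_cross_party")) {
    chk(cfg[[f]] >= 0 && cfg[[f]] < 1, f, "must be in [0, 1)")
  }
  invisible(cfg)
}

# run `expr` under a seed derived from (seed, salt) and restore RNG state
with_seed <- function(seed, expr, salt = 0L) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((as.integer(seed) + 7919L * as.integer(salt)) %% .Machine$integer.max)
  expr
}

#' Generate a multi-level society roster with ground-truth sociality
#'
#' Builds the nested unit-in-party-in-gang roster (one male and
#' `females_per_unit` females per unit) and draws the true gregariousness
#' of every individual and the true affinity of every within-party dyad
#' from Normal(0, sigma_g^2) and Normal(0, sigma_a^2).
#'
#' @param config A [society_config()].
#' @return A list with `roster` (tibble: id, sex, unit_id, party_id,
#'   gang_id) and `truth` (list with tibbles `g` (id, g) and
#'   `a` (id_a, id_b, dyad, a), `a` keyed on unordered within-party dyads).
#' @export
generate_society <- function(config) {
  validate_society_config(config)
  with_seed(config$seed, salt = 1L, expr = {
    rows <- list()
    k <- 0L
    for (gg in seq_len(config$n_gangs)) {
      for (pp in seq_len(config$parties_per_gang)) {
        party <- sprintf("G%dP%d", gg, pp)
        for (uu in seq_len(config$units_per_party)) {
          unit <- sprintf("%sU%d", party, uu)
          sexes <- c("male", rep("female", config$females_per_unit))
          for (sx in sexes) {
            k <- k + 1L
            rows[[k]] <- tibble::tibble(
              id = sprintf("ind%03d", k), sex = sx,
              unit_id = unit, party_id = party, gang_id = sprintf("G%d", gg)
            )
          }
        }
      }
    }
    roster <- dplyr::bind_rows(rows)

    g <- tibble::tibble(
      id = roster$id,
      g = stats::rnorm(nrow(roster), 0, config$sigma_g)
    )
    a <- roster |>
      dplyr::group_by(.data$party_id) |>
      dplyr::reframe({
        ids <- sort(.data$id)
        if (length(ids) < 2) {
          tibble::tibble(id_a = character(), id_b = character())
        } else {
          cmb <- utils::combn(ids, 2)
          tibble::tibble(id_a = cmb[1, ], id_b = cmb[2, ])
        }
      }) |>
      dplyr::select(-dplyr::any_of("party_id"))
    a$dyad <- dyad_key(a$id_a, a$id_b)
    a$a <- stats::rnorm(nrow(a), 0, config$sigma_a)
    list(roster = roster, truth = list(g = g, a = a))
  })
}

# symmetric lookup of mu_ij = 0.5 * (g_i + g_j) + a_ij for dyad tables
dyad_mu <- function(id_a, id_b, truth) {
  g <- stats::setNames(truth$g$g, truth$g$id)
  a <- stats::setNames(truth$a$a, truth$a$dyad)
  0.5 * (g[id_a] + g[id_b]) + a[dyad_key(id_a, id_b)]
}

#' Simulate focal-follow behaviour for every within-party dyad
#'
#' For each dyad the symmetric sociality score is
#' `mu_ij = 0.5 * (g_i + g_j) + a_ij`. Approach counts are
#' `Poisson(exp(mu_ij + b0_approach + log(effort)))`; grooming and
#' contact-sitting proportions are Beta with mean `logit^-1(mu_ij + b0)`
#' and precision `phi` (mean-precision parameterization).
#'
#' @param roster,truth As returned by [generate_society()].
#' @param config A [society_config()].
#' @param dates Optional vector of observation dates; the per-dyad effort
#'   is split evenly across them (one record per dyad per date). Default
#'   is a single record dated 45 days before `config$start_date`.
#' @return Tibble of dyad behaviour records: `id_a`, `id_b`, `dyad`,
#'   `party_id`, `date`, `approach_count`, `obs_effort` (hours),
#'   `groom_prop`, `contact_prop`.
#' @export
simulate_behavior <- function(roster, truth, config, dates = NULL) {
  validate_society_config(config)
  if (is.null(dates)) dates <- config$start_date - 45L
  if (config$effort_per_dyad <= 0) stop("non-positive observation effort", call. = FALSE)
  with_seed(config$seed, salt = 2L, expr = {
    base <- truth$a |>
      dplyr::left_join(
        dplyr::select(roster, "id", party_id = "party_id"),
        by = c("id_a" = "id")
      )
    base$mu <- dyad_mu(base$id_a, base$id_b, truth)
    effort <- config$effort_per_dyad / length(dates)
    out <- tidyr::crossing(base, date = dates)
    n <- nrow(out)
    out$obs_effort <- effort
    out$approach_count <- stats::rpois(
      n, exp(out$mu + config$b0_approach + log(effort))
    )
    m_groom <- inv_logit(out$mu + config$b0_groom)
    m_contact <- inv_logit(out$mu + config$b0_contact)
    clamp01 <- function(x) pmin(pmax(x, 1e-12), 1 - 1e-12)
    out$groom_prop <- clamp01(
      stats::rbeta(n, m_groom * config$phi_groom, (1 - m_groom) * config$phi_groom)
    )
    out$contact_prop <- clamp01(
      stats::rbeta(n, m_contact * config$phi_contact, (1 - m_contact) * config$phi_contact)
    )
    dplyr::select(
      out, "id_a", "id_b", "dyad", "party_id", "date",
      "approach_count", "obs_effort", "groom_prop", "contact_prop"
    )
  })
}

# sequential sampling without replacement with softmax renormalization
sample_softmax_norepl <- function(ids, scores, size) {
  picked <- character(0)
  avail <- seq_along(ids)
  for (k in seq_len(min(size, length(ids)))) {
    p <- softmax(scores[avail])
    j <- sample(length(avail), 1, prob = p)
    picked <- c(picked, ids[avail[j]])
    avail <- avail[-j]
  }
  picked
}

shared_level <- function(roster_row_a, roster_row_b) {
  if (roster_row_a$unit_id == roster_row_b$unit_id) {
    "same_unit_same_party"
  } else if (roster_row_a$party_id == roster_row_b$party_id) {
    "diff_unit_same_party"
  } else {
    "diff_unit_diff_party"
  }
}

#' Simulate meat-eating events, transfers, audiences and transfer types
#'
#' Each event starts with a uniformly chosen adult catcher in a uniformly
#' chosen party. A fraction of events (small prey) have no transfers; the
#' rest draw a zero-truncated-Poisson number of transfers, the recipient
#' of transfer k becoming the possessor of transfer k+1. Per transfer:
#' audience size is zero-truncated Poisson on
#' `exp(c0 + c0_party + c0_possessor + c1 * g_possessor)` (truncated at
#' the candidate-pool size when the draw exceeds it); audience membership
#' is sampled sequentially without replacement with
#' `softmax(c_affi * a)` weights; the recipient is drawn from the
#' audience with `softmax(b_affi * a + b_sex * sex + b0_partner)`
#' weights; and the transfer type (steal < scavenge/succeed < share) is
#' drawn from a cumulative-logit tolerance model with shared-social-level
#' and sex effects plus possessor / recipient / dyad / event random
#' intercepts.
#'
#' @param roster,truth As returned by [generate_society()].
#' @param config A [society_config()].
#' @return A list of tibbles: `meat_events` (event_id, date, party_id,
#'   catcher_id, prey, n_transfers), `transfers` (event_id, order,
#'   possessor_id, recipient_id, type), `audiences` (event_id, order,
#'   member_id), plus `ranef` (the drawn varying intercepts, part of the
#'   ground truth) and `n_truncated_audiences` (count of audience-size
#'   draws truncated at the candidate-pool size).
#' @export
simulate_meat_events <- function(roster, truth, config) {
  validate_society_config(config)
  if (nrow(roster) == 0) stop("empty roster", call. = FALSE)
  with_seed(config$seed, salt = 3L, expr = {
    g <- stats::setNames(truth$g$g, truth$g$id)
    a <- stats::setNames(truth$a$a, truth$a$dyad)
    aff <- function(x, ys) {
      v <- a[dyad_key(x, ys)]
      v[is.na(v)] <- 0 # cross-party dyads carry no affinity
      unname(v)
    }
    parties <- unique(roster$party_id)
    sexnum <- stats::setNames(as.integer(roster$sex == "male"), roster$id)
    rostersplit <- split(roster, roster$party_id)
    gang_of <- stats::setNames(roster$gang_id, roster$id)
    party_of <- stats::setNames(roster$party_id, roster$id)
    unit_of <- stats::setNames(roster$unit_id, roster$id)

    ran <- list(
      c0_party = stats::setNames(stats::rnorm(length(parties), 0, config$sigma_party), parties),
      c0_possessor = stats::setNames(stats::rnorm(nrow(roster), 0, config$sigma_possessor), roster$id),
      b0_partner = stats::setNames(stats::rnorm(nrow(roster), 0, config$sigma_partner), roster$id),
      tol_possessor = stats::setNames(stats::rnorm(nrow(roster), 0, config$ordinal_ranef_sd), roster$id),
      tol_recipient = stats::setNames(stats::rnorm(nrow(roster), 0, config$ordinal_ranef_sd), roster$id)
    )
    tol_dyad <- new.env(parent = emptyenv())
    tol_event <- stats::rnorm(config$n_events, 0, config$ordinal_ranef_sd)

    bt <- config$ordinal_betas
    th <- config$ordinal_thresholds
    draw_type <- function(possessor, recipient, event_i) {
      lvl <- shared_level(
        list(unit_id = unit_of[[possessor]], party_id = party_of[[possessor]]),
        list(unit_id = unit_of[[recipient]], party_id = party_of[[recipient]])
      )
      dk <- dyad_key(possessor, recipient)
      if (is.null(tol_dyad[[dk]])) {
        tol_dyad[[dk]] <- stats::rnorm(1, 0, config$ordinal_ranef_sd)
      }
      eta <- switch(lvl,
        same_unit_same_party = 0,
        diff_unit_same_party = bt[["level_party"]],
        diff_unit_diff_party = bt[["level_gang"]]
      ) +
        bt[["possessor_sex"]] * sexnum[[possessor]] +
        bt[["recipient_sex"]] * sexnum[[recipient]] +
        bt[["sex_interaction"]] * sexnum[[possessor]] * sexnum[[recipient]] +
        ran$tol_possessor[[possessor]] + ran$tol_recipient[[recipient]] +
        tol_dyad[[dk]] + tol_event[event_i]
      # cumulative logit: P(Y <= k) = logit^-1(theta_k - eta); high eta -> tolerant
      pcum <- inv_logit(th - eta)
      p <- c(pcum[1], pcum[2] - pcum[1], 1 - pcum[2])
      k <- sample(3, 1, prob = p)
      switch(k, "steal", sample(c("scavenge", "succeed"), 1), "share")
    }

    events <- list()
    transfers <- list()
    audiences <- list()
    n_trunc <- 0L
    dates <- sort(config$start_date +
      sample(0:config$event_span_days, config$n_events, replace = TRUE))
    for (e in seq_len(config$n_events)) {
      eid <- sprintf("ev%04d", e)
      party <- sample(parties, 1)
      members <- rostersplit[[party]]$id
      catcher <- sample(members, 1)
      no_transfer <- stats::runif(1) < config$p_no_transfer
      n_tr <- if (no_transfer) 0L else rztpois(1, config$transfer_rate)
      events[[e]] <- tibble::tibble(
        event_id = eid, date = dates[e], party_id = party, catcher_id = catcher,
        prey = if (no_transfer) "small bird" else "bushbuck", n_transfers = n_tr
      )
      possessor <- catcher
      for (k in seq_len(n_tr)) {
        pool <- setdiff(members, possessor)
        if (config$p_cross_party > 0 && stats::runif(1) < config$p_cross_party) {
          gangmates <- roster$id[roster$gang_id == gang_of[[possessor]] &
            roster$party_id != party_of[[possessor]]]
          pool <- c(pool, gangmates)
        }
        lam <- exp(config$c0 + ran$c0_party[[party_of[[possessor]]]] +
          ran$c0_possessor[[possessor]] + config$c1 * g[[possessor]])
        size <- rztpois(1, lam)
        if (size > length(pool)) {
          size <- length(pool)
          n_trunc <- n_trunc + 1L
        }
        aud <- sample_softmax_norepl(pool, config$c_affi * aff(possessor, pool), size)
        audiences[[length(audiences) + 1L]] <- tibble::tibble(
          event_id = eid, order = k, member_id = aud
        )
        sc <- config$b_affi * aff(possessor, aud) +
          config$b_sex * sexnum[aud] + ran$b0_partner[aud]
        recipient <- aud[sample(length(aud), 1, prob = softmax(sc))]
        transfers[[length(transfers) + 1L]] <- tibble::tibble(
          event_id = eid, order = k, possessor_id = possessor,
          recipient_id = recipient, type = draw_type(possessor, recipient, e)
        )
        possessor <- recipient
        members <- unique(c(members, recipient)) # recipient may be cross-party
      }
    }
    list(
      meat_events = dplyr::bind_rows(events),
      transfers = dplyr::bind_rows(transfers),
      audiences = dplyr::bind_rows(audiences),
      ranef = ran,
      n_truncated_audiences = n_trunc
    )
  })
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: generates the society, the focal behaviour spread
#' over three observation dates preceding the event span (so every
#' event's 90-day window contains data), and the meat-eating events.
#'
#' @param config A [society_config()].
#' @return A list with the five pipeline tables (`roster` gains
#'   `start_date` / `end_date` columns), `focal_behavior`, `meat_events`,
#'   `transfers`, `audiences`, plus `truth`.
#' @export
simulate_dataset <- function(config = society_config()) {
  soc <- generate_society(config)
  dates <- config$start_date - c(80L, 50L, 20L)
  beh <- simulate_behavior(soc$roster, soc$truth, config, dates = dates)
  ev <- simulate_meat_events(soc$roster, soc$truth, config)
  roster <- soc$roster
  roster$start_date <- config$start_date - 365L
  roster$end_date <- config$start_date + 365L
  list(
    roster = roster,
    focal_behavior = tibble::tibble(
      date = beh$date, id_a = beh$id_a, id_b = beh$id_b,
      approach_count = beh$approach_count,
      groom_hours = beh$groom_prop * beh$obs_effort,
      contact_hours = beh$contact_prop * beh$obs_effort,
      effort_hours = beh$obs_effort
    ),
    meat_events = ev$meat_events,
    transfers = ev$transfers,
    audiences = ev$audiences,
    truth = c(soc$truth, list(ranef = ev$ranef)),
    n_truncated_audiences = ev$n_truncated_audiences
  )
}
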