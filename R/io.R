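# Data contracts and the end-to-end pipeline.
#
# Five CSV tables tie the pipeline together: roster, focal_behavior,
# meat_events, transfers and audiences (schemas below). Validation
# failures are collected and reported together, never one at a time.

dataset_schemas <- list(
  roster = c("id", "sex", "unit_id", "party_id", "gang_id", "start_date", "end_date"),
  focal_behavior = c(
    "date", "id_a", "id_b", "approach_count",
    "groom_hours", "contact_hours", "effort_hours"
  ),
  meat_events = c("event_id", "date", "party_id", "catcher_id", "prey", "n_transfers"),
  transfers = c("event_id", "order", "possessor_id", "recipient_id", "type"),
  audiences = c("event_id", "order", "member_id")
)

#' Pipeline run configuration
#'
#' @param window_days Length of the behaviour window preceding each
#'   event (default 90 days).
#' @param epsilon Uniform-noise bound for [jitter_proportions()].
#' @param mcmc An [mcmc_config()] used by every Bayesian stage.
#' @param k_propagation Number of thinned sociality draw sets propagated
#'   into the transfer sub-models (default 50).
#' @param interval_mass Credible-interval mass (default 0.89).
#' @param bootstrap_n Parametric bootstrap replicates for the ordinal
#'   model (default 1000; 0 skips the bootstrap).
#' @param min_audience Minimum audience size for the choice model
#'   (default 2).
#' @param seed Master seed; all pipeline randomness derives from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(window_days = 90, epsilon = 1e-6,
                       mcmc = mcmc_config(), k_propagation = 50,
                       interval_mass = 0.89, bootstrap_n = 1000,
                       min_audience = 2, seed = 1L) {
  stopifnot(
    window_days > 0, epsilon > 0, epsilon <= 1e-4,
    k_propagation >= 1, interval_mass > 0, interval_mass < 1,
    bootstrap_n >= 0, min_audience >= 1
  )
  mcmc$seed <- as.integer(seed)
  structure(
    list(
      window_days = window_days, epsilon = epsilon, mcmc = mcmc,
      k_propagation = as.integer(k_propagation),
      interval_mass = interval_mass, bootstrap_n = as.integer(bootstrap_n),
      min_audience = min_audience, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read and validate the five pipeline tables
#'
#' @param paths Named character vector or list with elements `roster`,
#'   `focal_behavior`, `meat_events`, `transfers`, `audiences`, or a
#'   single directory containing `<name>.csv` files.
#' @return A validated list of tibbles of class `meatshare_dataset`.
#'   Schema or referential-integrity failures raise one error listing
#'   every issue found.
#' @export
read_dataset <- function(paths) {
  if (length(paths) == 1 && is.null(names(paths)) && dir.exists(paths[[1]])) {
    paths <- stats::setNames(
      file.path(paths[[1]], paste0(names(dataset_schemas), ".csv")),
      names(dataset_schemas)
    )
  }
  missing <- setdiff(names(dataset_schemas), names(paths))
  if (length(missing)) {
    stop("missing tables: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  issues <- character(0)
  tabs <- list()
  for (nm in names(dataset_schemas)) {
    tab <- readr::read_csv(paths[[nm]], show_col_types = FALSE, progress = FALSE)
    bad <- setdiff(dataset_schemas[[nm]], names(tab))
    if (length(bad)) {
      issues <- c(issues, paste0(nm, ": missing columns ", paste(bad, collapse = ", ")))
      next
    }
    for (dc in intersect(c("date", "start_date", "end_date"), names(tab))) {
      tab[[dc]] <- as.Date(tab[[dc]])
      if (anyNA(tab[[dc]])) issues <- c(issues, paste0(nm, ": unparseable dates in ", dc))
    }
    tabs[[nm]] <- tab
  }
  if (!length(issues)) {
    ids <- tabs$roster$id
    ref <- function(vals, what) {
      orphan <- setdiff(stats::na.omit(unique(vals)), ids)
      if (length(orphan)) {
        issues <<- c(issues, paste0(
          what, ": unknown individual(s) ",
          paste(orphan, collapse = ", ")
        ))
      }
    }
    ref(c(tabs$focal_behavior$id_a, tabs$focal_behavior$id_b), "focal_behavior")
    ref(tabs$meat_events$catcher_id, "meat_events.catcher_id")
    ref(tabs$transfers$possessor_id, "transfers.possessor_id")
    ref(tabs$transfers$recipient_id, "transfers.recipient_id")
    ref(tabs$audiences$member_id, "audiences.member_id")
    ev <- tabs$meat_events$event_id
    for (nm in c("transfers", "audiences")) {
      orphan <- setdiff(unique(tabs[[nm]]$event_id), ev)
      if (length(orphan)) {
        issues <- c(issues, paste0(
          nm, ": unknown event(s) ",
          paste(orphan, collapse = ", ")
        ))
      }
    }
  }
  if (length(issues)) {
    stop("dataset validation failed:\n  ", paste(issues, collapse = "\n  "), call. = FALSE)
  }
  structure(tabs, class = "meatshare_dataset")
}

#' Write a dataset (or simulation) to CSV fixtures
#'
#' Writes the five pipeline tables; ground-truth values of a simulated
#' dataset go to separate `truth_*.csv` files that the inference stages
#' never read.
#'
#' @param dataset A `meatshare_dataset` or the output of
#'   [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(dataset_schemas)) {
    readr::write_csv(dataset[[nm]], file.path(dir, paste0(nm, ".csv")))
  }
  if (!is.null(dataset$truth)) {
    readr::write_csv(dataset$truth$g, file.path(dir, "truth_g.csv"))
    readr::write_csv(dataset$truth$a, file.path(dir, "truth_a.csv"))
  }
  invisible(dir)
}

# window key: party plus the exact set of focal records in the window,
# so windows with identical content share one cached sociality fit
window_key <- function(party, win) {
  paste0(party, "#", paste(sort(win$dyad), collapse = ","), "#", nrow(win))
}

#' Run the full analysis pipeline
#'
#' Executes the complete chain on a validated dataset: per-event focal
#' windows, exclusion funnel, sociality fits (one per unique
#' party-window, cached), the three transfer sub-models with propagated
#' affinity/gregariousness uncertainty, the ordinal tolerance model with
#' full-null LRT (plus reduced model), and the descriptive tallies.
#' Deterministic given `config$seed`.
#'
#' @param dataset A `meatshare_dataset` (or [simulate_dataset()] output).
#' @param config A [run_config()].
#' @return A report bundle (list of class `meatshare_report`) with
#'   sections `funnel`, `sociality`, `transfer_models`, `ordinal`,
#'   `descriptives`.
#' @export
run_pipeline <- function(dataset, config = run_config()) {
  roster <- dataset$roster
  events <- dataset$meat_events
  party_of <- stats::setNames(roster$party_id, roster$id)
  sex_of <- stats::setNames(as.integer(roster$sex == "male"), roster$id)
  unit_of <- stats::setNames(roster$unit_id, roster$id)
  focal <- dataset$focal_behavior
  focal$party_id <- unname(party_of[focal$id_a])

  # ---- windows and focal availability -------------------------------------
  win_of_event <- list()
  keys <- character(nrow(events))
  for (e in seq_len(nrow(events))) {
    fb <- focal[focal$party_id == events$party_id[e], , drop = FALSE]
    win <- window_subset(fb, events$date[e], config$window_days)
    win_of_event[[events$event_id[e]]] <- win
    keys[e] <- window_key(events$party_id[e], win)
  }
  focal_available <- tibble::tibble(
    event_id = events$event_id,
    has_focal = vapply(win_of_event[events$event_id], nrow, 0L) > 0
  )

  # ---- exclusion funnel ---------------------------------------------------
  ft <- filter_transfers(dataset$transfers, roster, focal_available)
  choice_transfers <- prune_min_audience(ft$transfers, dataset$audiences,
    min_size = config$min_audience
  )
  funnel <- list(
    n_events = nrow(events),
    n_transfers_total = nrow(dataset$transfers),
    exclusions = ft$exclusions,
    n_transfers_bayes = nrow(ft$transfers),
    n_transfers_choice = nrow(choice_transfers)
  )

  # ---- sociality fits, one per unique window ------------------------------
  ukeys <- unique(keys[vapply(win_of_event[events$event_id], nrow, 0L) > 0])
  soc_fits <- list()
  for (kk in ukeys) {
    e <- which(keys == kk)[1]
    win <- win_of_event[[events$event_id[e]]]
    win <- jitter_proportions(win, config$epsilon, seed = config$seed)
    soc_fits[[kk]] <- fit_sociality(win, config$mcmc)
  }
  key_of_event <- stats::setNames(keys, events$event_id)

  # combined, thinned predictor matrices with window-scoped keys
  K <- config$k_propagation
  bind_pred <- function(kind) {
    mats <- lapply(names(soc_fits), function(kk) {
      m <- predictor_draws(soc_fits[[kk]], kind, K)
      colnames(m) <- paste0(kk, "|", colnames(m))
      m
    })
    nr <- min(vapply(mats, nrow, 0L))
    do.call(cbind, lapply(mats, function(m) m[seq_len(nr), , drop = FALSE]))
  }
  a_draws <- bind_pred("a")
  g_draws <- bind_pred("g")

  # ---- sub-model inputs ---------------------------------------------------
  aud_sizes <- dataset$audiences |>
    dplyr::count(.data$event_id, .data$order, name = "size")
  tb <- ft$transfers
  tb$size <- aud_sizes$size[match(
    paste(tb$event_id, tb$order),
    paste(aud_sizes$event_id, aud_sizes$order)
  )]
  size_obs <- tibble::tibble(
    size = tb$size,
    possessor_id = tb$possessor_id,
    party_id = unname(party_of[tb$possessor_id]),
    g_key = paste0(key_of_event[tb$event_id], "|", tb$possessor_id)
  ) |> dplyr::filter(!is.na(.data$size), .data$g_key %in% colnames(g_draws))

  comp_candidates <- build_comp_candidates(
    tb, dataset$audiences, roster, key_of_event, a_draws
  )
  choices <- build_choices(
    choice_transfers, dataset$audiences, roster,
    key_of_event, a_draws, sex_of
  )

  mcmc <- config$mcmc
  size_fit <- fit_audience_size(size_obs, g_draws, mcmc, k = K)
  comp_fit <- fit_audience_composition(comp_candidates, a_draws, mcmc, k = K)
  choice_fit <- fit_transfer_choice(choices$choices, a_draws, mcmc, k = K)

  # ---- ordinal tolerance model --------------------------------------------
  known <- dataset$transfers$type %in% c("share", "scavenge", "succeed", "steal") &
    dataset$transfers$possessor_id %in% roster$id &
    dataset$transfers$recipient_id %in% roster$id
  ot <- dataset$transfers[known, , drop = FALSE]
  ordinal_records <- tibble::tibble(
    transfer_type = dplyr::case_when(
      ot$type == "steal" ~ 1L, ot$type == "share" ~ 3L, TRUE ~ 2L
    ),
    social_level = factor(
      dplyr::case_when(
        unit_of[ot$possessor_id] == unit_of[ot$recipient_id] ~ "same_unit_same_party",
        party_of[ot$possessor_id] == party_of[ot$recipient_id] ~ "diff_unit_same_party",
        TRUE ~ "diff_unit_diff_party"
      ),
      levels = c("same_unit_same_party", "diff_unit_same_party", "diff_unit_diff_party")
    ),
    possessor_sex = unname(sex_of[ot$possessor_id]),
    recipient_sex = unname(sex_of[ot$recipient_id]),
    possessor_id = ot$possessor_id,
    recipient_id = ot$recipient_id,
    dyad_id = dyad_key(ot$possessor_id, ot$recipient_id),
    event_id = ot$event_id
  )
  ord_full <- fit_ordinal(ordinal_records)
  ord_null <- fit_ordinal(ordinal_records, fixed = ~1)
  ord_reduced <- fit_reduced(ordinal_records)
  lrt <- lrt_full_null(ord_full, ord_null)
  boot <- if (config$bootstrap_n > 0) {
    parametric_bootstrap(ord_full, ordinal_records,
      n_boot = config$bootstrap_n, seed = config$seed
    )
  }

  structure(
    list(
      funnel = funnel,
      sociality = list(
        fits = soc_fits,
        summary = purrr::map_dfr(soc_fits, glance, .id = "window")
      ),
      transfer_models = list(
        audience_size = size_fit,
        audience_composition = comp_fit,
        transfer_choice = choice_fit,
        n_cross_party_audience_members = choices$n_excluded_members,
        summary = dplyr::bind_rows(
          audience_size = glance(size_fit),
          audience_composition = glance(comp_fit),
          transfer_choice = glance(choice_fit),
          .id = "model"
        )
      ),
      ordinal = list(
        full = ord_full, null = ord_null, reduced = ord_reduced,
        lrt = lrt, bootstrap = boot, records = ordinal_records
      ),
      descriptives = list(
        tally = tally_transfers(
          dplyr::left_join(dataset$transfers,
            dplyr::select(dataset$meat_events, "event_id", "date"),
            by = "event_id"
          ),
          roster
        ),
        events = event_summaries(dataset$meat_events)
      ),
      config = config
    ),
    class = "meatshare_report"
  )
}

# candidate pools for the audience-composition model: the possessor's
# adult party roster (minus the possessor), within-party only
build_comp_candidates <- function(transfers, audiences, roster, key_of_event, a_draws) {
  party_of <- stats::setNames(roster$party_id, roster$id)
  rows <- list()
  for (i in seq_len(nrow(transfers))) {
    poss <- transfers$possessor_id[i]
    eid <- transfers$event_id[i]
    ord <- transfers$order[i]
    if (is.na(party_of[poss])) next
    pool <- roster$id[roster$party_id == party_of[[poss]] & roster$id != poss]
    keys <- paste0(key_of_event[eid], "|", dyad_key(poss, pool))
    ok <- keys %in% colnames(a_draws)
    if (sum(ok) < 2) next
    aud <- audiences$member_id[audiences$event_id == eid & audiences$order == ord]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      choice_id = paste(eid, ord, sep = ":"),
      member_id = pool[ok], dyad = keys[ok],
      in_audience = as.integer(pool[ok] %in% aud)
    )
  }
  dplyr::bind_rows(rows)
}

# choice-model input: audience candidates with affinity keys; audience
# members from other parties (no affinity) are excluded with a count
build_choices <- function(choice_transfers, audiences, roster, key_of_event, a_draws, sex_of) {
  rows <- list()
  n_excluded <- 0L
  for (i in seq_len(nrow(choice_transfers))) {
    eid <- choice_transfers$event_id[i]
    ord <- choice_transfers$order[i]
    poss <- choice_transfers$possessor_id[i]
    aud <- audiences$member_id[audiences$event_id == eid & audiences$order == ord]
    keys <- paste0(key_of_event[eid], "|", dyad_key(poss, aud))
    ok <- keys %in% colnames(a_draws)
    n_excluded <- n_excluded + sum(!ok)
    aud <- aud[ok]
    keys <- keys[ok]
    if (length(aud) < 2 || !(choice_transfers$recipient_id[i] %in% aud)) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      choice_id = paste(eid, ord, sep = ":"),
      member_id = aud, dyad = keys,
      sex = unname(sex_of[aud]),
      is_recipient = aud == choice_transfers$recipient_id[i]
    )
  }
  list(choices = dplyr::bind_rows(rows), n_excluded_members = n_excluded)
}

#' Write a report bundle to JSON summaries
#'
#' @param report A `meatshare_report`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- list(
    funnel = report$funnel,
    sociality = report$sociality$summary,
    transfer_models = report$transfer_models$summary,
    ordinal = list(
      full = tidy(report$ordinal$full),
      lrt = report$ordinal$lrt
    ),
    descriptives = list(
      tally = report$descriptives$tally,
      median_transfers = report$descriptives$events$median_transfers,
      range_transfers = report$descriptives$events$range_transfers,
      n_zero_transfer = report$descriptives$events$n_zero_transfer
    )
  )
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = 10, pretty = TRUE
  )
  readr::write_csv(sankey_table(report$descriptives$tally), file.path(dir, "sankey.csv"))
  if (!is.null(report$ordinal$bootstrap)) {
    readr::write_csv(report$ordinal$bootstrap, file.path(dir, "bootstrap_ci.csv"))
  }
  invisible(dir)
}

#' @export
print.meatshare_report <- function(x, ...) {
  cat("<meatshare_report>\n")
  cat(
    "  funnel: ", x$funnel$n_transfers_total, " transfers -> ",
    x$funnel$n_transfers_bayes, " (sub-models) -> ",
    x$funnel$n_transfers_choice, " (choice model)\n",
    sep = ""
  )
  s <- summarize_posterior(
    x$transfer_models$transfer_choice$draws$b_affi,
    x$config$interval_mass
  )
  cat(sprintf(
    "  b_affi: median %.3f, %d%% CI [%.3f, %.3f]\n",
    s$median, round(100 * s$mass), s$lower, s$upper
  ))
  cat(sprintf(
    "  ordinal LRT: chi2 = %.3f, df = %d, p = %.4g\n",
    x$ordinal$lrt$chi2, x$ordinal$lrt$df, x$ordinal$lrt$p_value
  ))
  invisible(x)
}
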