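# Descriptive surfaces: transfer tallies by sex pair and shared social
# level (the Sankey-diagram input) and per-event transfer summaries.

#' Tally transfers by sex pair and shared social level
#'
#' Classifies every transfer into exactly one (possessor sex x recipient
#' sex x shared social level) cell. Transfers whose unit membership
#' cannot be resolved from the roster go to a separate `unknown` bucket,
#' never silently dropped, so cells + unknown always equals the input
#' size.
#'
#' @param transfers Tibble with `possessor_id`, `recipient_id`.
#' @param roster Tibble with `id`, `sex`, `unit_id`, `party_id` (and
#'   optionally `start_date` / `end_date` for date-aware membership; a
#'   transfer `date` column is then matched against them).
#' @return Tibble `possessor_sex`, `recipient_sex`, `social_level`, `n`,
#'   `pct` (of total known), with attributes `total_known` and
#'   `n_unknown`.
#' @export
tally_transfers <- function(transfers, roster) {
  date_aware <- all(c("start_date", "end_date") %in% names(roster))
  lookup <- function(ids, dates) {
    idx <- match(ids, roster$id)
    if (date_aware && !is.null(dates)) {
      ok <- !is.na(idx) &
        dates >= roster$start_date[idx] & dates <= roster$end_date[idx]
      idx[!ok] <- NA_integer_
    }
    idx
  }
  dates <- if ("date" %in% names(transfers)) transfers$date
  pi <- lookup(transfers$possessor_id, dates)
  ri <- lookup(transfers$recipient_id, dates)
  known <- !is.na(pi) & !is.na(ri)
  level <- dplyr::case_when(
    !known ~ NA_character_,
    roster$unit_id[pi] == roster$unit_id[ri] ~ "same_unit_same_party",
    roster$party_id[pi] == roster$party_id[ri] ~ "diff_unit_same_party",
    TRUE ~ "diff_unit_diff_party"
  )
  cells <- tibble::tibble(
    possessor_sex = roster$sex[pi][known],
    recipient_sex = roster$sex[ri][known],
    social_level = level[known]
  ) |>
    dplyr::count(.data$possessor_sex, .data$recipient_sex, .data$social_level)
  total_known <- sum(cells$n)
  cells$pct <- if (total_known > 0) 100 * cells$n / total_known else numeric(nrow(cells))
  attr(cells, "total_known") <- total_known
  attr(cells, "n_unknown") <- sum(!known)
  cells
}

#' Shape a transfer tally for Sankey plotting
#'
#' @param tally Output of [tally_transfers()].
#' @return Tibble `source` (possessor sex), `target`
#'   (recipient sex : social level), `value`.
#' @export
sankey_table <- function(tally) {
  tibble::tibble(
    source = tally$possessor_sex,
    target = paste(tally$recipient_sex, tally$social_level, sep = ":"),
    value = tally$n
  )
}

#' Per-event transfer summaries
#'
#' @param events Meat-events tibble with an `n_transfers` column (events
#'   whose prey was consumed whole have 0).
#' @return List with `per_event` (tibble `event_id`, `n_transfers`),
#'   `median_transfers`, `range_transfers` (over events with >= 1
#'   transfer), and `n_zero_transfer`.
#' @export
event_summaries <- function(events) {
  per_event <- dplyr::select(events, "event_id", "n_transfers")
  pos <- per_event$n_transfers[per_event$n_transfers > 0]
  list(
    per_event = per_event,
    median_transfers = if (length(pos)) stats::median(pos) else NA_real_,
    range_transfers = if (length(pos)) range(pos) else c(NA_real_, NA_real_),
    n_zero_transfer = sum(per_event$n_transfers == 0)
  )
}
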