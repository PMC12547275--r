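test_that("generated rosters match the configured structure", {
  cfg <- society_config(
    n_gangs = 1, parties_per_gang = 2, units_per_party = 3,
    females_per_unit = 1, seed = 5L
  )
  soc <- generate_society(cfg)
  expect_equal(nrow(soc$roster), 12)
  expect_equal(sum(soc$roster$sex == "male"), 6)
  expect_equal(sum(soc$roster$sex == "female"), 6)
  # exactly one male per unit, units nested in parties nested in gangs
  per_unit <- table(soc$roster$unit_id, soc$roster$sex)
  expect_true(all(per_unit[, "male"] == 1))
  expect_equal(dplyr::n_distinct(soc$roster$party_id), 2)
})

test_that("degenerate affinity variance yields exactly zero affinities", {
  cfg <- society_config(sigma_a = 0, seed = 3L)
  soc <- generate_society(cfg)
  expect_true(all(soc$truth$a$a == 0))
})

test_that("generation is deterministic under a fixed seed", {
  cfg <- society_config(seed = 11L, n_events = 15)
  s1 <- generate_society(cfg)
  s2 <- generate_society(cfg)
  expect_identical(s1, s2)
  e1 <- simulate_meat_events(s1$roster, s1$truth, cfg)
  e2 <- simulate_meat_events(s2$roster, s2$truth, cfg)
  expect_identical(e1$transfers, e2$transfers)
  expect_identical(e1$audiences, e2$audiences)
  b1 <- simulate_behavior(s1$roster, s1$truth, cfg)
  b2 <- simulate_behavior(s2$roster, s2$truth, cfg)
  expect_identical(b1, b2)
})

test_that("invalid configurations name the offending field", {
  expect_error(society_config(n_gangs = 0), "n_gangs")
  expect_error(society_config(phi_groom = -1), "phi_groom")
  expect_error(society_config(ordinal_thresholds = c(1, -1)), "ordinal_thresholds")
  expect_error(society_config(females_per_unit = 0), "females_per_unit")
})

test_that("behaviour follows the Poisson/Beta generative model", {
  # vanishing rate: mu + b0 -> -inf gives all-zero approach counts
  cfg0 <- society_config(
    sigma_g = 0, sigma_a = 0, b0_approach = -20,
    n_gangs = 1, parties_per_gang = 1, seed = 2L
  )
  soc0 <- generate_society(cfg0)
  beh0 <- simulate_behavior(soc0$roster, soc0$truth, cfg0)
  expect_true(all(beh0$approach_count == 0))

  # Beta mean: b0_groom = 0 and mu = 0 give mean logit^-1(0) = 0.5
  cfg1 <- society_config(
    sigma_g = 0, sigma_a = 0, b0_groom = 0, phi_groom = 10,
    n_gangs = 4, parties_per_gang = 4, units_per_party = 4,
    females_per_unit = 3, seed = 8L
  )
  soc1 <- generate_society(cfg1)
  beh1 <- simulate_behavior(soc1$roster, soc1$truth, cfg1)
  expect_gt(nrow(beh1), 1500)
  se <- sqrt(0.25 / (10 + 1)) / sqrt(nrow(beh1)) # Beta(5,5) sd / sqrt(n)
  expect_lt(abs(mean(beh1$groom_prop) - 0.5), 3 * se)

  # offset property: doubling effort doubles the mean approach count
  cfg2a <- society_config(
    sigma_g = 0, sigma_a = 0, b0_approach = 0, effort_per_dyad = 10,
    n_gangs = 4, parties_per_gang = 4, units_per_party = 4,
    females_per_unit = 3, seed = 9L
  )
  cfg2b <- society_config(
    sigma_g = 0, sigma_a = 0, b0_approach = 0, effort_per_dyad = 20,
    n_gangs = 4, parties_per_gang = 4, units_per_party = 4,
    females_per_unit = 3, seed = 10L
  )
  soc2 <- generate_society(cfg2a)
  m1 <- mean(simulate_behavior(soc2$roster, soc2$truth, cfg2a)$approach_count)
  m2 <- mean(simulate_behavior(soc2$roster, soc2$truth, cfg2b)$approach_count)
  n <- nrow(soc2$truth$a)
  se_ratio <- 3 * sqrt(20 / n + 4 * 10 / n) / 10 # delta-method-ish bound
  expect_lt(abs(m2 - 2 * m1), 10 * se_ratio + 0.5)
  expect_gt(m2 / m1, 1.8)
  expect_lt(m2 / m1, 2.2)
})

test_that("audience sizes are zero-truncated with the analytic mean", {
  cfg <- society_config(
    n_events = 400, p_no_transfer = 0, p_cross_party = 0,
    sigma_party = 0, sigma_possessor = 0, sigma_g = 0,
    c0 = 0, c1 = 0, seed = 21L,
    n_gangs = 1, parties_per_gang = 1, units_per_party = 4, females_per_unit = 2
  )
  soc <- generate_society(cfg)
  ev <- simulate_meat_events(soc$roster, soc$truth, cfg)
  sizes <- dplyr::count(ev$audiences, event_id, order)$n
  expect_gte(min(sizes), 1)
  # lambda = exp(0) = 1: truncated mean 1/(1-e^-1), party of 12 never truncates
  se <- stats::sd(sizes) / sqrt(length(sizes))
  expect_lt(abs(mean(sizes) - ztpois_mean(1)), 3 * se)

  # rate -> 0: every audience has exactly one member
  cfg0 <- society_config(
    n_events = 60, p_no_transfer = 0, c0 = -20,
    sigma_party = 0, sigma_possessor = 0, sigma_g = 0, seed = 22L
  )
  soc0 <- generate_society(cfg0)
  ev0 <- simulate_meat_events(soc0$roster, soc0$truth, cfg0)
  expect_true(all(dplyr::count(ev0$audiences, event_id, order)$n == 1))
})

test_that("recipient choice is uniform without affinity effects and saturates with them", {
  # flat choice model: recipients uniform over the audience
  cfg <- society_config(
    c_affi = 0, b_affi = 0, b_sex = 0, sigma_partner = 0,
    p_no_transfer = 0, p_cross_party = 0, n_events = 1200,
    transfer_rate = 0.5, seed = 31L,
    n_gangs = 1, parties_per_gang = 1, units_per_party = 4, females_per_unit = 2
  )
  soc <- generate_society(cfg)
  ev <- simulate_meat_events(soc$roster, soc$truth, cfg)
  aud2 <- dplyr::add_count(ev$audiences, event_id, order)
  aud2 <- dplyr::filter(aud2, n == 2)
  aud2$position <- stats::ave(seq_len(nrow(aud2)), paste(aud2$event_id, aud2$order),
    FUN = seq_along
  )
  rec <- dplyr::left_join(ev$transfers, aud2,
    by = c("event_id", "order", "recipient_id" = "member_id")
  )
  pos <- rec$position[!is.na(rec$position)]
  expect_gt(stats::chisq.test(table(pos))$p.value, 0.01)

  # saturated slope: the top-affinity audience member nearly always receives
  cfgS <- society_config(
    b_affi = 10, b_sex = 0, sigma_partner = 0, p_no_transfer = 0,
    p_cross_party = 0, n_events = 600, transfer_rate = 0.5, seed = 32L,
    n_gangs = 1, parties_per_gang = 1, units_per_party = 4, females_per_unit = 2
  )
  socS <- generate_society(cfgS)
  evS <- simulate_meat_events(socS$roster, socS$truth, cfgS)
  a <- stats::setNames(socS$truth$a$a, socS$truth$a$dyad)
  # condition on a clear affinity gap: near-ties are decided by a coin
  # flip no matter how steep the slope
  hit <- vapply(seq_len(nrow(evS$transfers)), function(i) {
    tr <- evS$transfers[i, ]
    aud <- evS$audiences$member_id[
      evS$audiences$event_id == tr$event_id & evS$audiences$order == tr$order
    ]
    if (length(aud) < 2) {
      return(NA)
    }
    affs <- sort(a[dyad_key(tr$possessor_id, aud)], decreasing = TRUE)
    if (affs[1] - affs[2] < 0.5) {
      return(NA)
    }
    tr$recipient_id == aud[which.max(a[dyad_key(tr$possessor_id, aud)])]
  }, NA)
  expect_gt(mean(hit, na.rm = TRUE), 0.99)
})

test_that("transfer tolerance stratifies by social level as generated", {
  cfg <- society_config(
    n_events = 2500, p_no_transfer = 0, p_cross_party = 0.3,
    ordinal_ranef_sd = 0.3, seed = 41L
  )
  soc <- generate_society(cfg)
  ev <- simulate_meat_events(soc$roster, soc$truth, cfg)
  unit_of <- stats::setNames(soc$roster$unit_id, soc$roster$id)
  party_of <- stats::setNames(soc$roster$party_id, soc$roster$id)
  lvl <- dplyr::case_when(
    unit_of[ev$transfers$possessor_id] == unit_of[ev$transfers$recipient_id] ~ "unit",
    party_of[ev$transfers$possessor_id] == party_of[ev$transfers$recipient_id] ~ "party",
    TRUE ~ "gang"
  )
  ratio <- vapply(c("unit", "party", "gang"), function(l) {
    tt <- ev$transfers$type[lvl == l]
    sum(tt == "share") / max(sum(tt == "steal"), 1)
  }, 0)
  expect_true(ratio["unit"] > ratio["party"])
  expect_true(ratio["party"] > ratio["gang"])
})
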