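test_that("transfer exclusion rules reproduce hand-counted funnels", {
  tr <- tibble::tibble(
    event_id = paste0("e", 1:6),
    type = c("steal", "share", "share", "succeed", "scavenge", "share"),
    possessor_party = c("P1", "P1", "P1", "P1", "P1", "P1"),
    recipient_party = c("P1", "P2", "P1", "P1", "P1", "P1"),
    has_focal = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
  )
  out <- filter_transfers(tr)
  expect_equal(nrow(out$transfers), 3)
  expect_equal(
    tibble::deframe(out$exclusions),
    c(steal = 1L, cross_party = 1L, no_focal = 1L)
  )

  # empty input and all-valid input
  e <- filter_transfers(tr[0, ])
  expect_equal(nrow(e$transfers), 0)
  expect_equal(nrow(e$exclusions), 0)
  ok <- filter_transfers(tr[4:6, ])
  expect_equal(nrow(ok$transfers), 3)
  expect_equal(nrow(ok$exclusions), 0)

  # unknown type is its own exclusion reason
  tr2 <- tr[2:3, ]
  tr2$type <- c("unknown", "mystery")
  tr2$recipient_party <- "P1"
  tr2$has_focal <- TRUE
  out2 <- filter_transfers(tr2)
  expect_equal(tibble::deframe(out2$exclusions), c(unknown_type = 2L))
})

test_that("audience pruning matches the truncated-Poisson retention rate", {
  tr <- tibble::tibble(
    event_id = "e1", order = 1:3,
    audience_size = c(1L, 2L, 3L)
  )
  expect_equal(nrow(prune_min_audience(tr, min_size = 2)), 2)
  expect_equal(nrow(prune_min_audience(tr, min_size = 1)), 3)

  # retention at lambda = 1.5 approaches 1 - P(size = 1)
  set.seed(13)
  n <- 2000
  sizes <- rztpois(n, 1.5)
  tr2 <- tibble::tibble(event_id = "e", order = seq_len(n), audience_size = sizes)
  kept <- nrow(prune_min_audience(tr2, min_size = 2)) / n
  p_keep <- 1 - dztpois(1, 1.5)
  expect_lt(abs(kept - p_keep), 3 * sqrt(p_keep * (1 - p_keep) / n))

  # join path: sizes derived from the audiences table
  aud <- tibble::tibble(
    event_id = "e1", order = c(1L, 2L, 2L, 3L, 3L, 3L),
    member_id = c("a", "a", "b", "a", "b", "c")
  )
  got <- prune_min_audience(tr[, c("event_id", "order")], aud, min_size = 2)
  expect_equal(got$order, 2:3)
})

test_that("choice probabilities equal brute-force enumeration on small audiences", {
  set.seed(9)
  for (sz in 2:4) {
    for (r in 1:20) {
      a <- stats::rnorm(sz)
      sex <- stats::rbinom(sz, 1, 0.5)
      b0 <- stats::rnorm(sz, 0, 0.4)
      p <- choice_probs(a, slope = 0.3, sexes = sex, b_sex = -0.2, intercepts = b0)
      # independent enumeration: raw exponentials, no max-subtraction
      mu <- 0.3 * a - 0.2 * sex + b0
      oracle <- exp(mu) / sum(exp(mu))
      expect_equal(p, oracle, tolerance = 1e-10)
    }
  }
  # symmetric two-member audience
  expect_equal(choice_probs(c(0.7, 0.7), 2, sexes = c(1, 1), b_sex = 1), c(0.5, 0.5))
})

test_that("the audience-size model recovers null and non-null gregariousness slopes", {
  set.seed(17)
  n <- 1200
  ids <- sprintf("p%02d", 1:20)
  g <- stats::rnorm(20)
  names(g) <- ids
  poss <- sample(ids, n, replace = TRUE)
  party <- rep(c("A", "B"), 10)[match(poss, ids)]
  obs0 <- tibble::tibble(
    size = rztpois(n, exp(0.7 + 0 * g[poss])),
    possessor_id = poss, party_id = party
  )
  f0 <- fit_audience_size(obs0, tibble::tibble(id = ids, g = unname(g)),
    test_mcmc(seed = 2L)
  )
  s0 <- summarize_posterior(f0$draws$c1)
  expect_lt(abs(s0$median), 0.08)
  expect_true(s0$lower < 0 && s0$upper > 0)

  obs1 <- tibble::tibble(
    size = rztpois(n, exp(0.7 + 0.3 * g[poss])),
    possessor_id = poss, party_id = party
  )
  f1 <- fit_audience_size(obs1, tibble::tibble(id = ids, g = unname(g)),
    test_mcmc(seed = 3L)
  )
  s1 <- summarize_posterior(f1$draws$c1)
  expect_true(s1$lower < 0.3 && s1$upper > 0.3)
  expect_gt(s1$median, 0.1)
  expect_error(
    fit_audience_size(
      tibble::tibble(size = 0L, possessor_id = "p01", party_id = "A"),
      tibble::tibble(id = ids, g = unname(g))
    ),
    "zero-truncated"
  )
})

test_that("the composition model is centred on truth and flat without information", {
  set.seed(19)
  rows <- lapply(1:250, function(t) {
    a <- stats::rnorm(8)
    aud <- sample(8, 3, prob = softmax(0.15 * a))
    tibble::tibble(
      choice_id = t, member_id = sprintf("m%d", 1:8),
      dyad = sprintf("d%03d_%d", t, 1:8),
      in_audience = as.integer(1:8 %in% aud), a = a
    )
  })
  cc <- dplyr::bind_rows(rows)
  f <- fit_audience_composition(
    dplyr::select(cc, -a),
    tibble::tibble(dyad = cc$dyad, a = cc$a), test_mcmc(seed = 4L)
  )
  s <- summarize_posterior(f$draws$caffi)
  expect_true(s$lower < 0.15 && s$upper > 0.15)

  # single-candidate pools carry no information: posterior ~ prior N(0, 1)
  cc1 <- tibble::tibble(
    choice_id = 1:40, member_id = "m1",
    dyad = sprintf("d%02d", 1:40), in_audience = 1L
  )
  f1 <- fit_audience_composition(
    cc1, tibble::tibble(dyad = cc1$dyad, a = stats::rnorm(40)),
    test_mcmc(seed = 5L, warmup = 600, iter = 1000)
  )
  ks <- stats::ks.test(f1$draws$caffi, "pnorm")$statistic
  expect_lt(unname(ks), 0.1)
})

test_that("the transfer-choice model recovers null effects and enforces contracts", {
  sim <- gen_choice_data(300, seed = 23, b_affi = 0, b_sex = 0, sigma_partner = 0)
  f <- fit_transfer_choice(sim$choices, sim$affinity, test_mcmc(seed = 6L))
  sa <- summarize_posterior(f$draws$b_affi)
  ss <- summarize_posterior(f$draws$b_sex)
  expect_lt(abs(sa$median), 0.2)
  expect_lt(abs(ss$median), 0.35)
  expect_true(sa$lower < 0 && sa$upper > 0)

  bad <- sim$choices
  bad$is_recipient[1] <- !bad$is_recipient[1]
  expect_error(
    fit_transfer_choice(bad, sim$affinity, test_mcmc()),
    "exactly one recipient"
  )
  single <- tibble::tibble(
    choice_id = "c1", member_id = "m1", dyad = "d1",
    sex = 0, is_recipient = TRUE
  )
  expect_error(
    fit_transfer_choice(single, tibble::tibble(dyad = "d1", a = 0)),
    "audience"
  )
})

test_that("propagating affinity uncertainty widens the slope posterior", {
  sim <- gen_choice_data(150, seed = 29, b_affi = 0.3)
  # posterior-mean predictor: a single imputation set
  fixed <- fit_transfer_choice(sim$choices, sim$affinity,
    test_mcmc(seed = 7L, chains = 2, warmup = 400, iter = 500)
  )
  # noisy draw sets around the same values emulate sociality uncertainty
  set.seed(31)
  k <- 10
  amat <- matrix(
    rep(sim$affinity$a, each = k) + stats::rnorm(k * nrow(sim$affinity), 0, 0.5),
    nrow = k,
    dimnames = list(NULL, sim$affinity$dyad)
  )
  prop <- fit_transfer_choice(sim$choices, amat,
    test_mcmc(seed = 7L, chains = 2, warmup = 400, iter = 500),
    k = k
  )
  expect_gte(
    stats::sd(prop$draws$b_affi) + 0.02,
    stats::sd(fixed$draws$b_affi)
  )
  expect_equal(prop$n_sets, k)
})
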