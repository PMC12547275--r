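# Simulators used across test files. All take explicit seeds so every
# test is reproducible in isolation.

# Ordinal tolerance records with crossed possessor/recipient/dyad/event
# grouping. Social level is a property of the dyad; each possessor has a
# small fixed set of partners so clusters carry real information.
gen_ordinal_records <- function(n, seed, sd_u = 0.5,
                                betas = c(-1.2, -2.3, 0, 0, 0),
                                th = c(-1, 1),
                                n_poss = 15, partners_per = 4,
                                n_event = round(n / 5)) {
  set.seed(seed)
  poss_pool <- sprintf("P%02d", 1:n_poss)
  partner <- lapply(poss_pool, function(p) sample(sprintf("R%02d", 1:n_poss), partners_per))
  names(partner) <- poss_pool
  lv <- c("same_unit_same_party", "diff_unit_same_party", "diff_unit_diff_party")
  possessor <- sample(poss_pool, n, TRUE)
  recipient <- vapply(possessor, function(p) sample(partner[[p]], 1), "")
  dyad <- paste(possessor, recipient)
  event <- sample(sprintf("E%03d", 1:n_event), n, TRUE)
  dl <- sample(lv, length(unique(dyad)), TRUE)
  names(dl) <- unique(dyad)
  rec <- tibble::tibble(
    social_level = factor(dl[dyad], levels = lv),
    possessor_sex = stats::rbinom(n, 1, .5),
    recipient_sex = stats::rbinom(n, 1, .5),
    possessor_id = possessor, recipient_id = recipient,
    dyad_id = dyad, event_id = event
  )
  mku <- function(ids) {
    u <- stats::rnorm(length(unique(ids)), 0, sd_u)
    names(u) <- unique(ids)
    u[ids]
  }
  eta <- betas[1] * (rec$social_level == lv[2]) +
    betas[2] * (rec$social_level == lv[3]) +
    betas[3] * rec$possessor_sex + betas[4] * rec$recipient_sex +
    betas[5] * rec$possessor_sex * rec$recipient_sex +
    mku(possessor) + mku(recipient) + mku(dyad) + mku(event)
  pc <- stats::plogis(outer(th, eta, "-"))
  pr <- rbind(pc[1, ], pc[2, ] - pc[1, ], 1 - pc[2, ])
  rec$transfer_type <- apply(pr, 2, function(p) sample(3, 1, prob = p))
  rec
}

# Transfer-choice data at known affinities: n choices over audiences of
# 2-4 candidates drawn from a limited partner pool (so the partner
# varying intercept is estimable), softmax recipient choice.
gen_choice_data <- function(n, seed, b_affi = 0.3, b_sex = 0,
                            sigma_partner = 0.3, n_partners = 30) {
  set.seed(seed)
  pool <- sprintf("p%02d", seq_len(n_partners))
  b0 <- stats::rnorm(n_partners, 0, sigma_partner)
  names(b0) <- pool
  sex_of <- stats::rbinom(n_partners, 1, 0.5)
  names(sex_of) <- pool
  rows <- lapply(seq_len(n), function(t) {
    sz <- sample(2:4, 1, prob = c(.5, .35, .15))
    ids <- sample(pool, sz)
    a <- stats::rnorm(sz)
    p <- softmax(b_affi * a + b_sex * sex_of[ids] + b0[ids])
    rec <- sample(sz, 1, prob = p)
    tibble::tibble(
      choice_id = sprintf("c%04d", t), member_id = ids,
      dyad = sprintf("d%04d_%s", t, ids), sex = unname(sex_of[ids]),
      is_recipient = seq_len(sz) == rec, a = a
    )
  })
  ch <- dplyr::bind_rows(rows)
  list(
    choices = dplyr::select(ch, -"a"),
    affinity = tibble::tibble(dyad = ch$dyad, a = ch$a)
  )
}

# fast MCMC settings for unit tests
test_mcmc <- function(seed = 1L, chains = 2, warmup = 400, iter = 400) {
  mcmc_config(chains = chains, warmup = warmup, iter = iter, seed = seed)
}
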