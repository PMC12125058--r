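# Unit semantics of the ORL and VSE update/choice rules, and agreement
# between the R reference implementations and the compiled engines.

test_that("one-step ORL updates match hand-derived values", {
  p <- orl_params(A_rew = 0.5, A_pun = 0.2, K_prime = 1, beta_F = 1,
                  beta_P = 1)
  # zero net outcome: only perseverance moves (K' = 0 -> K = 0 -> PS_chosen 1)
  p0 <- orl_params(0.5, 0.2, 0, 1, 1)
  st <- orl_update(orl_state(), p0, "A", list(gain = 1, loss = 1))
  expect_equal(unname(st$EV), rep(0, 4))
  expect_equal(unname(st$EF), rep(0, 4))
  expect_equal(unname(st$PS), c(1, 0, 0, 0))
  # positive unit net: EV/EF of chosen move by A_rew; fictive EF moves the
  # unchosen decks toward -sgn/3 with the opposite rate (A_pun); K = 2
  st <- orl_update(orl_state(), p, "B", list(gain = 1, loss = 0))
  expect_equal(st$EV[["B"]], 0.5)
  expect_equal(st$EF[["B"]], 0.5)
  expect_equal(unname(st$EF[c("A", "C", "D")]), rep(0.2 * (-1 / 3), 3))
  expect_equal(st$PS[["B"]], 1 / 3)
  expect_equal(unname(st$V), unname(st$EV + st$EF + st$PS))
  # negative net from a non-zero starting EV: 0.5 + 0.2 * (-1.5 - 0.5) = 0.1
  st2 <- st
  st2$EV[] <- c(0, 0.5, 0, 0)
  st2 <- orl_update(st2, p, "B", list(gain = 1, loss = 2.5))
  expect_equal(st2$EV[["B"]], 0.1)
  # unchosen EV untouched
  expect_equal(unname(st2$EV[c("A", "C", "D")]), rep(0, 3))
})

test_that("ORL choice rule is a unit-sensitivity softmax on V", {
  st <- orl_state()
  expect_equal(unname(orl_choice_probs(st)), rep(0.25, 4))
  st$V[] <- c(1, 0, 0, 0)
  expect_equal(orl_choice_probs(st)[["A"]], exp(1) / (exp(1) + 3),
               tolerance = 1e-12)
  expect_equal(sum(orl_choice_probs(st)), 1, tolerance = 1e-12)
})

test_that("ORL decay transform spans [0, 242]", {
  expect_equal(orl_decay_K(0), 0)
  expect_equal(orl_decay_K(5), 242)
})

test_that("VSE utility follows gain^theta - loss^theta on magnitudes", {
  expect_equal(vse_utility(100, 0, 1), 100)
  expect_equal(vse_utility(100, 50, 0.5), 10 - sqrt(50), tolerance = 1e-12)
  expect_equal(vse_utility(7, 7, 0.33), 0)
  expect_error(vse_utility(-1, 0, 0.5), "non-negative")
  expect_error(vse_utility(1, 0, 1.5), "theta")
})

test_that("one-step VSE updates match hand-derived values", {
  p <- vse_params(theta = 1, delta = 1, alpha = 0.5, phi = 2, beta = 1)
  # delta = 1 and zero utility leave exploitation unchanged
  st <- vse_state()
  st$exploit[] <- c(1, 2, 3, 4)
  st2 <- vse_update(st, p, "A", list(gain = 1, loss = 1))
  expect_equal(st2$exploit, st$exploit)
  # unchosen exploration: 0 + 0.5 * (2 - 0) = 1; chosen resets to zero
  expect_equal(unname(st2$explore), c(0, 1, 1, 1))
  st3 <- vse_update(st2, p, "C", list(gain = 0.5, loss = 0))
  expect_equal(st3$explore[["C"]], 0)
  expect_equal(st3$exploit[["C"]], 3.5)
})

test_that("VSE choice rule uses consistency c = 3^beta - 1", {
  p0 <- vse_params(0.5, 0.5, 0.5, 1, 0)
  st <- vse_state()
  st$exploit[] <- c(5, -3, 1, 0)
  expect_equal(unname(vse_choice_probs(st, p0)), rep(0.25, 4))
  p1 <- vse_params(0.5, 0.5, 0.5, 1, 1)
  st1 <- vse_state()
  st1$exploit[] <- c(1, 0, 0, 0)
  expect_equal(vse_choice_probs(st1, p1)[["A"]], exp(2) / (exp(2) + 3),
               tolerance = 1e-12)
  expect_equal(vse_consistency(5), 242)
})

test_that("simulation conserves counts and is reproducible", {
  p <- vse_params(0.5, 0.8, 0.3, 0.5, 1)
  tr <- simulate_agent(p, n_trials = 100, seed = 31)
  expect_equal(nrow(tr), 100)
  expect_true(all(tr$deck %in% DECK_IDS))
  expect_equal(sum(count_choices(tr)[, c("nA", "nB", "nC", "nD")]), 100)
  tr2 <- simulate_agent(p, n_trials = 100, seed = 31)
  expect_identical(tr, tr2)
  tr3 <- simulate_agent(p, n_trials = 100, seed = 32)
  expect_false(identical(tr$deck, tr3$deck))
})

test_that("a zero-consistency VSE agent chooses uniformly", {
  p <- vse_params(0.5, 0.8, 0.3, 0.5, 0)
  tr <- simulate_agent(p, n_trials = 1000, seed = 77)
  counts <- as.numeric(count_choices(tr)[, c("nA", "nB", "nC", "nD")])
  # 3.9-sigma binomial band around n/4
  band <- 3.9 * sqrt(1000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 250) < band))
})

test_that("log-likelihoods match forced uniform values", {
  tr <- withr::with_seed(5, random_trials("u1", 100, seed = 6))
  expect_equal(log_lik(vse_params(0.5, 0.8, 0.3, 0.5, 0), tr), 100 * log(0.25),
               tolerance = 1e-10)
  one <- tr[1, ]
  expect_equal(log_lik(orl_params(0.3, 0.1, 1, 1, 1), one), log(0.25),
               tolerance = 1e-12)
  pw <- log_lik(orl_params(0.3, 0.1, 1, 1, 1), tr, pointwise = TRUE)
  expect_length(pw, 100)
  expect_true(all(exp(pw) > 0 & exp(pw) <= 1))
  expect_lte(sum(pw), 0)
})

test_that("compiled likelihoods equal the R reference stepping", {
  tr <- simulate_agent(orl_params(0.4, 0.15, 1.2, 0.8, -0.5), seed = 91)
  p_orl <- orl_params(0.3, 0.2, 2, 1.5, 0.7)
  expect_equal(log_lik(p_orl, tr), r_loglik(p_orl, tr), tolerance = 1e-9)
  p_vse <- vse_params(0.6, 0.7, 0.4, -1, 1.3)
  expect_equal(log_lik(p_vse, tr), r_loglik(p_vse, tr), tolerance = 1e-9)
})

test_that("repeated identical outcomes drive ORL EV along the closed form", {
  a <- 0.3
  p <- orl_params(a, a, 1, 0, 0)
  st <- orl_state()
  x <- 0.8
  for (k in 1:12) {
    st <- orl_update(st, p, "C", list(gain = x, loss = 0))
    expect_equal(st$EV[["C"]], x * (1 - (1 - a)^k), tolerance = 1e-12)
  }
})

test_that("VSE weights follow their geometric closed forms", {
  p <- vse_params(0.5, 0.6, 0.25, 1.5, 1)
  st <- vse_state()
  st$exploit[["B"]] <- 2
  prev <- 0
  for (k in 1:15) {
    st <- vse_update(st, p, "A", list(gain = 0, loss = 0))
    # never-chosen deck D: explore converges monotonically toward phi
    expect_equal(st$explore[["D"]], 1.5 * (1 - 0.75^k), tolerance = 1e-12)
    expect_gt(st$explore[["D"]], prev)
    prev <- st$explore[["D"]]
    # unselected deck B: exploit decays geometrically
    expect_equal(st$exploit[["B"]], 2 * 0.6^k, tolerance = 1e-12)
  }
})

test_that("simulated choice frequencies match the model probabilities", {
  # agents share trial-1 uniformity; conditional trial-2 frequencies must
  # match the probabilities implied by stepping the reference update
  p <- orl_params(0.6, 0.3, 0.5, 1.2, 0.8)
  sch <- igt_schedule(2, seed = 1, loss_policy = "fixed_canonical")
  n <- 2000
  first <- character(n)
  second <- character(n)
  for (i in seq_len(n)) {
    tr <- simulate_agent(p, schedule = sch, n_trials = 2, seed = 10000 + i)
    first[i] <- tr$deck[1]
    second[i] <- tr$deck[2]
  }
  expect_true(max(abs(table(factor(first, levels = DECK_IDS)) / n - 0.25)) <
                3.9 * sqrt(0.25 * 0.75 / n))
  for (d in DECK_IDS) {
    idx <- first == d
    out <- igt_draw(sch, d)$outcome
    st <- orl_update(orl_state(), p, d,
                     list(gain = out$gain * 0.01, loss = out$loss * 0.01))
    probs <- orl_choice_probs(st)
    emp <- table(factor(second[idx], levels = DECK_IDS)) / sum(idx)
    tol <- 4.2 * sqrt(0.25 / sum(idx))
    expect_true(all(abs(as.numeric(emp) - unname(probs)) < tol))
  }
})

test_that("the generating parameters beat perturbed ones in likelihood", {
  truth <- vse_params(0.5, 0.8, 0.3, 0.5, 1)
  pert <- vse_params(0.8, 0.5, 0.3, -0.5, 0.4)
  ll_t <- ll_p <- 0
  for (i in 1:50) {
    tr <- simulate_agent(truth, seed = 400 + i, subjID = paste0("s", i))
    ll_t <- ll_t + log_lik(truth, tr)
    ll_p <- ll_p + log_lik(pert, tr)
  }
  expect_gt(ll_t, ll_p)
  truth_o <- orl_params(0.3, 0.1, 1, 1.5, 1)
  pert_o <- orl_params(0.8, 0.6, 3, -1.5, -1)
  ll_t <- ll_p <- 0
  for (i in 1:50) {
    tr <- simulate_agent(truth_o, seed = 700 + i, subjID = paste0("s", i))
    ll_t <- ll_t + log_lik(truth_o, tr)
    ll_p <- ll_p + log_lik(pert_o, tr)
  }
  expect_gt(ll_t, ll_p)
})

test_that("parameter containers validate ranges", {
  expect_error(orl_params(1.2, 0.1, 1, 0, 0), "A_rew")
  expect_error(orl_params(0.5, 0.1, 6, 0, 0), "K_prime")
  expect_error(vse_params(0.5, 0.5, 0.5, 0, 7), "beta")
  expect_error(orl_update(orl_state(), orl_params(.5, .5, 1, 0, 0), "A",
                          list(gain = Inf, loss = 0)), "finite")
})
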