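# Shared fixtures and independent oracles used across test files.

DECK_IDS <- c("A", "B", "C", "D")

# brute-force sliding-window / chunk enumerators, independent of the package
oracle_de_sliding <- function(ch, w) {
  n <- length(ch)
  if (n < w) return(0L)
  s <- 0L
  for (i in 1:(n - w + 1)) {
    if (length(unique(ch[i:(i + w - 1)])) == w) s <- s + 1L
  }
  s
}

oracle_de_chunks <- function(ch, w) {
  k <- length(ch) %/% w
  s <- 0L
  for (b in seq_len(k)) {
    if (length(unique(ch[((b - 1) * w + 1):(b * w)])) == w) s <- s + 1L
  }
  s
}

# independent broad-classification oracle via the max pair-sum formulation:
# the four named patterns correspond to the largest of the pair sums
# C+D, A+B, B+D, A+C, with the value pair winning magnitude ties
oracle_broad <- function(nA, nB, nC, nD) {
  sums <- c(GOB = nC + nD, BOG = nA + nB, IOF = nB + nD, FOI = nA + nC)
  n <- nA + nB + nC + nD
  if (sums["GOB"] == sums["BOG"] && sums["IOF"] == sums["FOI"]) {
    return("Remaining")
  }
  value_max <- max(sums["GOB"], sums["BOG"])
  freq_max <- max(sums["IOF"], sums["FOI"])
  if (value_max >= freq_max) {
    if (sums["GOB"] > sums["BOG"]) "GOB" else "BOG"
  } else {
    if (sums["IOF"] > sums["FOI"]) "IOF" else "FOI"
  }
}

# uniform-random chooser on a standard schedule
random_trials <- function(subjID, n_trials = 100, seed = 1) {
  sch <- igt_schedule(n_trials, seed = seed)
  decks <- DECK_IDS[sample.int(4, n_trials, replace = TRUE)]
  gain <- loss <- numeric(n_trials)
  cur <- c(A = 0, B = 0, C = 0, D = 0)
  for (t in seq_len(n_trials)) {
    d <- decks[t]
    cur[d] <- cur[d] + 1
    row <- sch$cards[sch$cards$deck == d & sch$cards$index == cur[d], ]
    gain[t] <- row$gain
    loss[t] <- row$loss
  }
  tibble::tibble(subjID = subjID, trial = seq_len(n_trials), deck = decks,
                 gain = gain, loss = loss)
}

trials_from_decks <- function(decks, subjID = "s1") {
  n <- length(decks)
  tibble::tibble(subjID = subjID, trial = seq_len(n), deck = decks,
                 gain = 100, loss = 0)
}

# R-side teacher-forced log-likelihood by stepping the reference updates
r_loglik <- function(params, trials, outcome_scale = 0.01) {
  model <- igtrl:::model_name(params)
  ll <- 0
  if (model == "orl") {
    st <- orl_state()
    for (t in seq_len(nrow(trials))) {
      p <- orl_choice_probs(st)
      ll <- ll + log(p[[trials$deck[t]]])
      st <- orl_update(st, params, trials$deck[t],
                       list(gain = trials$gain[t] * outcome_scale,
                            loss = trials$loss[t] * outcome_scale))
    }
  } else if (model == "vse") {
    st <- vse_state()
    for (t in seq_len(nrow(trials))) {
      p <- vse_choice_probs(st, params)
      ll <- ll + log(p[[trials$deck[t]]])
      st <- vse_update(st, params, trials$deck[t],
                       list(gain = trials$gain[t] * outcome_scale,
                            loss = trials$loss[t] * outcome_scale))
    }
  } else {
    st <- legacy_state()
    for (t in seq_len(nrow(trials))) {
      p <- legacy_choice_probs(params, st, t)
      ll <- ll + log(p[[trials$deck[t]]])
      st <- legacy_update(params, st, trials$deck[t],
                          list(gain = trials$gain[t] * outcome_scale,
                               loss = trials$loss[t] * outcome_scale))
    }
  }
  unname(ll)
}
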