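# Classical EV / PVL / EV-PU / PVL-Delta models: transcription oracles and
# qualitative parameter-space structure.

test_that("one-step legacy updates match hand computation", {
  out <- list(gain = 1, loss = 0.5)
  # EV: u = (1-w) W - w L = 0.7*1 - 0.3*0.5 = 0.55; delta rule, chosen only
  ev <- legacy_params("ev", loss_aversion = 0.3, rate = 0.2, cons = 1)
  st <- legacy_update(ev, legacy_state(), "A", out)
  expect_equal(unname(st), c(0.2 * 0.55, 0, 0, 0))
  # PVL: u = x^shape = 0.5^0.5; decay rule shrinks all decks
  pvl <- legacy_params("pvl", shape = 0.5, loss_aversion = 2, rate = 0.9,
                       cons = 1)
  st <- legacy_state()
  st[] <- c(1, 1, 1, 1)
  st <- legacy_update(pvl, st, "B", out)
  expect_equal(unname(st), c(0.9, 0.9 + sqrt(0.5), 0.9, 0.9))
  # PVL loss branch: u = -w * |x|^shape
  st <- legacy_update(pvl, legacy_state(), "B", list(gain = 1, loss = 3))
  expect_equal(st[["B"]], -2 * sqrt(2))
  # PVL-Delta: delta rule on chosen deck only
  pvld <- legacy_params("pvldelta", shape = 0.5, loss_aversion = 1,
                        rate = 0.4, cons = 2)
  st <- legacy_state()
  st[] <- c(0, 0, 1, 0)
  st <- legacy_update(pvld, st, "C", out)
  expect_equal(st[["C"]], 1 + 0.4 * (sqrt(0.5) - 1))
  expect_equal(unname(st[c("A", "B", "D")]), rep(0, 3))
  # EV-PU combines prospect utility with the delta rule
  evpu <- legacy_params("evpu", shape = 0.5, loss_aversion = 1, rate = 1,
                        cons = -2)
  st <- legacy_update(evpu, legacy_state(), "D", out)
  expect_equal(st[["D"]], sqrt(0.5))
})

test_that("frozen and uniform limits behave as identities", {
  out <- list(gain = 1, loss = 0)
  ev0 <- legacy_params("ev", loss_aversion = 0.5, rate = 0, cons = 1)
  st <- legacy_state(); st[] <- c(1, 2, 3, 4)
  expect_equal(legacy_update(ev0, st, "A", out), st)
  pvld0 <- legacy_params("pvldelta", shape = 0.5, loss_aversion = 1,
                         rate = 0, cons = 1)
  expect_equal(legacy_update(pvld0, st, "A", out), st)
  # equal expectancies -> uniform choice, any trial
  expect_equal(unname(legacy_choice_probs(ev0, legacy_state(), 1)),
               rep(0.25, 4))
  # PVL-style consistency 0 -> sensitivity 3^0 - 1 = 0 -> uniform regardless
  pvl0 <- legacy_params("pvl", shape = 0.5, loss_aversion = 1, rate = 0.5,
                        cons = 0)
  expect_equal(unname(legacy_choice_probs(pvl0, st, 7)), rep(0.25, 4))
})

test_that("legacy simulation and likelihood agree with the R stepping", {
  p <- legacy_params("pvl", shape = 0.6, loss_aversion = 1.5, rate = 0.7,
                     cons = 1.2)
  tr <- simulate_agent(p, seed = 55)
  expect_equal(nrow(tr), 100)
  expect_equal(log_lik(p, tr), r_loglik(p, tr), tolerance = 1e-9)
  p2 <- legacy_params("ev", loss_aversion = 0.4, rate = 0.3, cons = 1)
  expect_equal(log_lik(p2, tr), r_loglik(p2, tr), tolerance = 1e-9)
})

test_that("legacy parameter spaces show the expected qualitative skew", {
  # all four classical models devote the largest share of their parameter
  # space to Good-Over-Bad; EV generates more BOG than IOF, while the
  # prospect-utility models generate more IOF than BOG
  props <- list()
  for (m in c("ev", "pvl", "evpu", "pvldelta")) {
    pts <- if (m == "ev") 16 else 10
    r <- run_psp(psp_grid(m, points = pts), seed = 3, definition = "broad")
    p <- r$proportions$proportion
    names(p) <- r$proportions$label
    props[[m]] <- p
    expect_equal(names(which.max(p[1:4])), "GOB", label = m)
  }
  expect_gt(props$ev[["BOG"]], props$ev[["IOF"]])
  expect_gt(min(props$ev[["BOG"]], props$ev[["FOI"]]), props$ev[["IOF"]])
  expect_gt(props$pvl[["IOF"]], props$pvl[["BOG"]])
  expect_gt(props$evpu[["IOF"]], props$evpu[["BOG"]])
})

test_that("legacy parameter validation enforces model-specific ranges", {
  expect_error(legacy_params("ev", shape = 0.5, loss_aversion = 0.5,
                             rate = 0.5, cons = 1), "shape")
  expect_error(legacy_params("ev", loss_aversion = 2, rate = 0.5, cons = 1),
               "loss_aversion")
  expect_error(legacy_params("pvl", shape = 0.5, loss_aversion = 1,
                             rate = 0.5, cons = -1), "cons")
  expect_silent(legacy_params("evpu", shape = 0.5, loss_aversion = 1,
                              rate = 0.5, cons = -1))
})
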