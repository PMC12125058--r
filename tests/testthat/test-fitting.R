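# Information criteria, the comparison rule, and the estimation backends.

test_that("AIC/BIC/WAIC formulas evaluate correctly", {
  ic <- information_criteria(-100, k = 5, n = 100)
  expect_equal(ic$AIC, 210)
  expect_equal(ic$BIC, 200 + 5 * log(100), tolerance = 1e-9)
  # degenerate posterior: all draws identical -> p_waic = 0, WAIC = -2 lppd
  ll <- matrix(rep(c(-1.1, -0.7, -2.0), each = 4), nrow = 4)
  ic2 <- information_criteria(-100, k = 2, n = 3, ll_pointwise = ll)
  expect_equal(ic2$p_waic, 0)
  expect_equal(ic2$WAIC, -2 * sum(ll[1, ]))
  expect_gte(ic2$WAIC_SE, 0)
  expect_error(information_criteria(-10, k = 1, n = 5,
                                    ll_pointwise = ll[1, , drop = FALSE]),
               "2 posterior draws")
})

test_that("p_waic is non-negative and WAIC_SE positive for varied draws", {
  withr::with_seed(3, {
    ll <- matrix(rnorm(200, -1.4, 0.3), nrow = 20)
  })
  w <- igtrl:::waic_from_pointwise(ll)
  expect_gte(w$p_waic, 0)
  expect_gt(w$waic_se, 0)
  expect_equal(w$waic, -2 * (w$lppd - w$p_waic), tolerance = 1e-12)
})

test_that("the comparison verdict follows the printed decision rule", {
  a <- fit_stub(aic = 1010, bic = 1020, waic = 1000, waic_se = 10)
  b <- fit_stub(aic = 1210, bic = 1220, waic = 1200, waic_se = 15)
  expect_equal(compare_models(a, b)$verdict, "A_superior")
  expect_equal(compare_models(b, a)$verdict, "B_superior")
  # WAIC gap inside the larger standard error -> inconclusive
  c1 <- fit_stub(aic = 1000, bic = 1000, waic = 1000, waic_se = 10)
  c2 <- fit_stub(aic = 1006, bic = 1006, waic = 1005, waic_se = 15)
  expect_equal(compare_models(c1, c2)$verdict, "inconclusive")
  # identical fits -> inconclusive
  expect_equal(compare_models(c1, c1)$verdict, "inconclusive")
  # disagreeing criteria -> inconclusive even with a large WAIC gap
  d1 <- fit_stub(aic = 900, bic = 1100, waic = 1000, waic_se = 5)
  d2 <- fit_stub(aic = 1000, bic = 1000, waic = 1100, waic_se = 5)
  expect_equal(compare_models(d1, d2)$verdict, "inconclusive")
  expect_error(compare_models(a, fit_stub(1, 1, 1, 1, n_obs = 7)),
               "same dataset")
})

test_that("the analytic likelihood gradients match finite differences", {
  coh <- generate_cohort(cohort_spec(n_subjects = 3), seed = 12)
  hd <- igtrl:::hier_data(coh$data)
  withr::with_seed(4, eta <- c(rnorm(10, 0, 0.3), rnorm(15, 0, 0.5)))
  for (mid in c(1L, 2L)) {
    an <- igtrl:::cpp_hier_lp_grad(mid, eta, hd$off, hd$choices, hd$gain,
                                   hd$loss, 0.01)
    num <- vapply(seq_along(eta), function(j) {
      h <- 1e-5
      ep <- em <- eta
      ep[j] <- ep[j] + h
      em[j] <- em[j] - h
      (igtrl:::cpp_hier_nlp(mid, em, hd$off, hd$choices, hd$gain, hd$loss,
                            0.01) -
         igtrl:::cpp_hier_nlp(mid, ep, hd$off, hd$choices, hd$gain, hd$loss,
                              0.01)) / (2 * h)
    }, numeric(1))
    expect_equal(an$gradient, num, tolerance = 1e-5)
  }
})

test_that("fits are deterministic given a seed and reject degenerate data", {
  coh <- generate_cohort(cohort_spec(n_subjects = 5), seed = 21)
  f1 <- fit_hierarchical(coh$data, "vse", draws = 150, seed = 3,
                         warmup = 150)
  f2 <- fit_hierarchical(coh$data, "vse", draws = 150, seed = 3,
                         warmup = 150)
  expect_identical(f1$draws, f2$draws)
  expect_identical(glance(f1), glance(f2))
  expect_gt(f1$waic_se, 0)
  expect_true(all(is.finite(c(f1$aic, f1$bic, f1$waic))))
  one <- coh$data[coh$data$subjID == coh$data$subjID[1], ][1, ]
  expect_error(fit_hierarchical(one, "vse"), "fewer than 2")
  tiny <- coh$data[0, ]
  expect_error(fit_hierarchical(tiny, "vse"))
})

test_that("criteria are stable under subject reordering (up to MC error)", {
  coh <- generate_cohort(cohort_spec(n_subjects = 8), seed = 33)
  perm <- coh$data |> dplyr::arrange(dplyr::desc(.data$subjID), .data$trial)
  f1 <- fit_hierarchical(coh$data, "vse", draws = 400, seed = 5,
                         warmup = 300)
  f2 <- fit_hierarchical(perm, "vse", draws = 400, seed = 5, warmup = 300)
  expect_lt(abs(f1$waic - f2$waic), 0.03 * abs(f1$waic))
  expect_lt(abs(f1$aic - f2$aic), 0.03 * abs(f1$aic))
  expect_lt(abs(f1$bic - f2$bic), 0.03 * abs(f1$bic))
})

test_that("uniform-random choosers yield a consistency estimate near zero", {
  withr::with_seed(17, {
    dat <- dplyr::bind_rows(lapply(1:8, function(i) {
      random_trials(sprintf("u%02d", i), 100, seed = 500 + i)
    }))
  })
  f <- fit_hierarchical(dat, "vse", draws = 400, seed = 2, warmup = 400)
  td <- tidy(f)
  beta_row <- td[td$parameter == "beta", ]
  expect_lt(beta_row$estimate, 0.5)
  # and the fit is close to the forced-uniform likelihood bound
  expect_lt(abs(f$loglik_hat - 800 * log(0.25)), 40)
})

test_that("the ADVI backend satisfies the same contract", {
  coh <- generate_cohort(cohort_spec(n_subjects = 5), seed = 21)
  f1 <- fit_hierarchical(coh$data, "orl", draws = 200, seed = 9,
                         backend = "advi", iters = 2000)
  f2 <- fit_hierarchical(coh$data, "orl", draws = 200, seed = 9,
                         backend = "advi", iters = 2000)
  expect_identical(f1$draws, f2$draws)
  expect_equal(dim(f1$pointwise_ll), c(200, nrow(coh$data)))
  expect_true(is.finite(f1$waic))
  td <- tidy(f1)
  expect_equal(td$parameter, c("A_rew", "A_pun", "K_prime", "beta_F",
                               "beta_P"))
  expect_true(all(td$conf.low <= td$conf.high))
})

test_that("glance and autoplot expose the fit summary", {
  coh <- generate_cohort(cohort_spec(n_subjects = 4), seed = 2)
  f <- fit_hierarchical(coh$data, "vse", draws = 120, seed = 1, warmup = 120)
  g <- glance(f)
  expect_equal(g$n_obs, 400)
  expect_equal(g$WAIC, f$waic)
  pl <- ggplot2::autoplot(f)
  expect_s3_class(pl, "ggplot")
})
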