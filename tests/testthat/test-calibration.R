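# Concurrent MML-EM calibration: identification, recovery, model
# comparison and respecification with subgroup parameters.

w_small <- one_group_world(n = 1500L, J = 8L, seed = 101)
fit_small <- concurrent_calibrate(w_small$data, opts = quick_opts())

test_that("calibration enforces its contracts", {
  # reference group fixed exactly at (0, 1)
  expect_identical(fit_small$dists$mean[1], 0)
  expect_identical(fit_small$dists$sd[1], 1)
  # AIC bookkeeping and convergence flags
  expect_equal(fit_small$aic, 2 * fit_small$n_params - 2 * fit_small$loglik)
  expect_true(fit_small$converged)
  # EM marginal log-likelihood is nondecreasing
  expect_true(all(diff(fit_small$ll_trace) > -1e-6))
  # PCM constrains all discriminations to 1
  fp <- concurrent_calibrate(w_small$data, model = "PCM",
                             opts = quick_opts())
  expect_true(all(bank_a(fp$bank) == 1))
  # disconnected designs refuse to calibrate
  X <- cbind(w_small$data$responses,
             iso = rep(NA_integer_, nrow(w_small$data$responses)))
  X[1:10, "iso"] <- 1L; X[1:10, 1:8] <- NA_integer_
  pers <- w_small$data$persons
  pers$dataset[1:10] <- "D9"
  items <- rbind(w_small$data$items,
                 data.frame(item_id = "iso", instrument = "I9", n_cat = 4L))
  expect_error(concurrent_calibrate(response_data(X, pers, items)),
               "linkage error")
})

test_that("parameters are recovered and improve with n", {
  a_err <- sqrt(mean((bank_a(fit_small$bank) - bank_a(w_small$bank))^2))
  b_err <- sqrt(mean((bank_b(fit_small$bank) - bank_b(w_small$bank))^2))
  expect_lt(a_err, 0.20)
  expect_lt(b_err, 0.20)
  # matched-seed comparison: RMSE at the larger n must not be worse
  w_lo <- one_group_world(n = 400L, J = 8L, seed = 303)
  w_hi <- one_group_world(n = 3200L, J = 8L, seed = 303)
  f_lo <- concurrent_calibrate(w_lo$data, opts = quick_opts())
  f_hi <- concurrent_calibrate(w_hi$data, opts = quick_opts())
  rmse <- function(f, w) sqrt(mean(c(bank_a(f$bank) - bank_a(w$bank),
                                     bank_b(f$bank) - bank_b(w$bank))^2))
  expect_lt(rmse(f_hi, w_hi), rmse(f_lo, w_lo))
})

test_that("model comparison obeys nesting and AIC algebra", {
  fg <- fit_small
  fp <- concurrent_calibrate(w_small$data, model = "PCM",
                             opts = quick_opts())
  cmp <- compare_models(fp, fg)
  expect_gte(cmp$lr_stat, 0)
  expect_equal(cmp$df, length(w_small$bank$items))
  expect_equal(cmp$delta_aic, cmp$lr_stat - 2 * cmp$df, tolerance = 1e-8)
  # mismatched data are refused
  w2 <- one_group_world(n = 300L, J = 8L, seed = 999)
  f2 <- concurrent_calibrate(w2$data, opts = quick_opts())
  expect_error(compare_models(f2, fg), "comparison error")
})

test_that("LR test holds its size under the PCM null", {
  # type-I simulation at desk scale: tiny PCM worlds, GPCM vs PCM LR test
  n_rep <- 120L
  rej <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    spec <- sim_spec(n_datasets = 1L, n_instruments = 1L,
                     items_per_instrument = 3L, n_cat = 3L,
                     n_per_dataset = 150L, a_sdlog = 0, a_meanlog = 0,
                     seed = 5000L + r)
    dat <- simulate_responses(generate_bank(spec),
                              link_design(list(D1 = "I1")),
                              group_dist("D1", 0, 1), spec)
    fp <- suppressWarnings(concurrent_calibrate(dat, model = "PCM",
                                                opts = tiny_opts()))
    fg <- suppressWarnings(concurrent_calibrate(dat, model = "GPCM",
                                                opts = tiny_opts()))
    rej[r] <- compare_models(fp, fg)$p < 0.05
  }
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.10)
})

test_that("subgroup respecification removes DIF from the flagged item", {
  # a replicate in which the injected DIF is flagged (true ~90% of
  # replicates), so the respecification path can be exercised
  w <- dif_world(seed = 7001)
  fit <- concurrent_calibrate(w$data, opts = quick_opts())
  fl <- lm_dif_test(fit, w$data)
  expect_true(fl$flagged[fl$item_id == "I1_01"])
  # empty flags: identity
  none <- fl; none$flagged <- FALSE
  expect_identical(assign_group_parameters(fit, none, w$data), fit)
  refit <- assign_group_parameters(fit, fl, w$data)
  # nesting: more free parameters cannot reduce the likelihood
  expect_gte(refit$loglik, fit$loglik - 1e-3)
  ov <- refit$bank$items[["I1_01"]]$overrides
  expect_true(length(ov) >= 1L)
  # after respecification the freed item's ES_DIF collapses
  fl2 <- lm_dif_test(refit, w$data)
  expect_lt(fl2$es_dif[fl2$item_id == "I1_01"],
            fl$es_dif[fl$item_id == "I1_01"] / 2)
  expect_false(fl2$flagged[fl2$item_id == "I1_01"])
})
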