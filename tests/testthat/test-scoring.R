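# EAP scoring, the standardized metric, reliabilities, correlation
# summaries and the congruence report.

test_that("EAP scoring: edge cases and fine-grid oracle", {
  bank <- toy_bank()
  # all-missing pattern returns the prior
  e0 <- eap_score(bank, c(a1 = NA_integer_))
  expect_true(e0$all_missing)
  expect_equal(c(e0$theta, e0$se), c(0, 1))
  # single symmetric item answered in the middle: theta 0 by symmetry
  es <- eap_score(item_bank(list(item_params("s", 1, c(-1, 1)))),
                  c(s = 1L))
  expect_equal(es$theta, 0, tolerance = 1e-10)
  # brute-force 10,001-point trapezoid oracle
  pat <- c(a1 = 2L, a2 = 0L, a3 = 3L, b1 = 1L, b2 = 1L)
  e <- eap_score(bank, pat)
  fine <- quad_grid(10001L)
  lp <- log(fine$weights)
  for (id in names(pat))
    lp <- lp + log(gpcm_probs(bank$items[[id]], fine$nodes)[, pat[[id]] + 1L])
  p <- exp(lp - max(lp)); p <- p / sum(p)
  oracle <- sum(p * fine$nodes)
  expect_lt(abs(e$theta - oracle), 1e-4)
  # invalid category refused
  expect_error(eap_score(bank, c(a1 = 9L)), "invalid category")
  # EAP shrinks toward the prior mean relative to ML
  nll <- function(t) -sum(vapply(names(pat), function(id)
    log(gpcm_probs(bank$items[[id]], t)[, pat[[id]] + 1L]), 0))
  ml <- optimize(nll, c(-8, 8))$minimum
  expect_lte(abs(e$theta), abs(ml) + 1e-8)
})

test_that("metric origin and standardized scores follow the 10/logit rule", {
  bank <- toy_bank()
  th0 <- locate_metric_origin(bank)
  grid <- quad_grid()
  # definitional: every instrument's mean expected item score <= epsilon
  for (s in bank_instruments(bank)) {
    k <- length(instrument_items(bank, s))
    expect_lte(scale_characteristic(bank, s, th0) / k, 0.01)
  }
  bank <- set_metric_origin(bank, th0)
  expect_equal(standardize_score(th0, bank), 0)
  expect_equal(standardize_score(th0 + 1, bank), 10)
  expect_equal(standardize_score(th0 + 7, bank), 70)
  expect_error(standardize_score(0, toy_bank()), "configuration error")
  # translation: shifting all steps by +1 shifts theta0 by +1 (grid res.)
  shifted <- item_bank(lapply(toy_bank()$items, function(it)
    item_params(it$item_id, it$a, it$b + 1, instrument_ids =
                  it$instrument_ids)))
  step <- diff(grid$nodes[1:2])
  expect_equal(locate_metric_origin(shifted), th0 + 1, tolerance = step + 1e-9)
  # epsilon = 0 is unattainable: warning + grid floor
  expect_warning(t0 <- locate_metric_origin(bank, epsilon = 0),
                 "unreachable")
  expect_equal(as.numeric(t0), grid$nodes[1])
  # grid refinement moves theta0 by less than the coarse step
  t_fine <- locate_metric_origin(bank, grid = quad_grid(121L))
  expect_lt(abs(as.numeric(t_fine) - th0), step)
})

test_that("reliability coefficients behave", {
  w <- one_group_world(n = 2000L, J = 10L, seed = 23)
  sc <- eap_scores(w$data, w$bank, "I1")
  mr <- marginal_reliability(sc)
  # identity under the unit-variance prior
  expect_equal(mr, 1 - mean(sc$se^2), tolerance = 0.03)
  # conditional reliability: near-zero-information instrument
  weak <- item_bank(list(item_params("w", 0.05, 0, instrument_ids = "W")))
  crw <- conditional_reliability(weak, "W")
  expect_true(all(crw$curve$cr < 0.01))
  expect_true(all(is.na(crw$range)))
  # adding items never decreases CR (this bank's flattest item keeps the
  # 0.01 origin epsilon unattainable on the default grid: expected warning)
  b10 <- suppressWarnings(set_metric_origin(w$bank))
  half <- item_bank(w$bank$items[1:5], theta0 = b10$theta0)
  cr_half <- conditional_reliability(half, "I1")
  cr_full <- conditional_reliability(b10, "I1")
  expect_true(all(cr_full$curve$cr >= cr_half$curve$cr - 1e-12))
  expect_true(diff(cr_full$range) > 0)
})

test_that("GLB approximation dominates alpha and matches it when parallel", {
  # parallel items: equal loadings and uniquenesses -> GLB == alpha
  set.seed(31)
  n <- 1500L; p <- 6L
  f <- rnorm(n)
  Xp <- sapply(seq_len(p), function(j) 0.7 * f + sqrt(1 - 0.49) * rnorm(n))
  expect_equal(glb_reliability(Xp), cronbach_alpha(Xp), tolerance = 0.02)
  # tau-inequivalent items: GLB >= alpha
  for (s in 1:5) {
    set.seed(100 + s)
    lam <- runif(p, 0.3, 0.9)
    X <- sapply(seq_len(p), function(j)
      lam[j] * f + sqrt(1 - lam[j]^2) * rnorm(n))
    expect_gte(glb_reliability(X), cronbach_alpha(X) - 1e-8)
  }
  expect_error(glb_reliability(Xp[, 1, drop = FALSE]), "single item")
  expect_error(glb_reliability(Xp[1:10, ]), "too few")
})

test_that("score correlations with overlap handling", {
  spec <- sim_spec(n_datasets = 1L, n_instruments = 2L,
                   items_per_instrument = 10L, n_per_dataset = 800L,
                   seed = 33)
  bank <- generate_bank(spec)
  dat <- simulate_responses(bank, link_design(list(D1 = c("I1", "I2"))),
                            group_dist("D1", 0, 1), spec)
  sc <- score_correlations(dat, bank)
  # observed/IRT correlations near one for multi-item scales
  expect_true(all(sc$observed_irt$r > 0.95))
  # disjoint scales measuring one trait correlate strongly, uncorrected
  expect_equal(sc$overlap["I1", "I2"], 0L)
  expect_identical(sc$note["I1", "I2"], "")
  expect_gt(sc$between["I1", "I2"], 0.70)
  # overlapping scales: shared items excluded from the larger member
  scales <- list(S1 = paste0("I1_0", 1:8), S2 = c(paste0("I1_0", 7:8),
                                                  paste0("I2_0", 1:6)))
  sc2 <- score_correlations(dat, bank, scales = scales)
  expect_identical(sc2$note["S1", "S2"], "corrected")
  expect_equal(sc2$overlap["S1", "S2"], 2L)
  # nested scales are labelled, not corrected
  scales3 <- list(long = paste0("I1_0", 1:8), short = paste0("I1_0", 1:4))
  sc3 <- score_correlations(dat, bank, scales = scales3)
  expect_identical(sc3$note["long", "short"], "nested")
  expect_true(is.na(sc3$between["long", "short"]))
})

test_that("rescaled summed scores span 0-100", {
  bank <- item_bank(lapply(1:8, function(j)
    item_params(paste0("q", j), 1, c(-1, 0, 1), instrument_ids = "Q")))
  X <- rbind(rep(0L, 8), rep(3L, 8), rep(c(1L, 2L), 4), c(rep(1L, 7), NA))
  colnames(X) <- paste0("q", 1:8)
  r <- rescale_summed(X, bank, "Q")
  expect_equal(r[1:3], c(0, 100, 50))
  expect_equal(100 * 12 / 24, 50)                 # 8-item 0-3, summed 12
  expect_true(is.na(r[4]))                        # incomplete person
})

test_that("congruence report: self-comparison is null", {
  spec <- sim_spec(n_datasets = 1L, n_instruments = 2L,
                   items_per_instrument = 6L, n_per_dataset = 150L,
                   seed = 88)
  bank <- generate_bank(spec)
  dat <- simulate_responses(bank, link_design(list(D1 = c("I1", "I2"))),
                            group_dist("D1", 0, 1), spec)
  bank <- set_metric_origin(bank)
  rep <- congruence_report(dat, bank, c("I1", "I1"))
  expect_equal(rep$pairs$d, c(0, 0))
  expect_equal(rep$pairs$p_bonf, c(1, 1))
  expect_error(congruence_report(dat, bank, "I1"), "two instruments")
})
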