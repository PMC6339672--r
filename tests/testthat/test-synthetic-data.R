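# Synthetic multi-registry generator: linking designs, banks, response
# simulation and sparse-category collapsing.

test_that("link designs enforce connectivity", {
  expect_s3_class(link_design(list(D1 = "I1", D2 = "I1")), "link_design")
  expect_s3_class(link_design(list(D1 = c("I1", "I2"), D2 = c("I2", "I3"),
                                   D3 = "I3")), "link_design")
  expect_error(link_design(list(D1 = "I1", D2 = "I2")), "design error")
  # generated designs are always connected, across shapes
  for (nd in c(2L, 5L, 10L)) for (ni in c(2L, 6L)) {
    d <- generate_link_design(sim_spec(n_datasets = nd, n_instruments = ni))
    expect_true(promlink:::design_connected(d$instrument_map))
    sizes <- lengths(d$instrument_map)
    expect_true(all(sizes >= 1L & sizes <= 4L))
  }
})

test_that("bank generation is deterministic and bookkept", {
  spec <- sim_spec(seed = 77)
  expect_identical(generate_bank(spec), generate_bank(spec))
  # 97 items over 10 instruments
  spec97 <- sim_spec(n_instruments = 10L,
                     items_per_instrument = c(10, 3, 18, 20, 10, 8, 1, 10,
                                              10, 7),
                     n_datasets = 5L)
  expect_equal(length(generate_bank(spec97)$items), 97L)
  # degenerate discrimination distribution gives a PCM-type bank
  b <- generate_bank(sim_spec(a_sdlog = 0, a_meanlog = 0))
  expect_true(all(bank_a(b) == 1))
})

test_that("simulated responses honor design, DIF and missingness", {
  w <- one_group_world(n = 200L, J = 4L, seed = 5)
  expect_true(all(!is.na(w$data$responses)))     # no structural missing
  # identical spec -> bitwise identical data
  d2 <- simulate_responses(w$bank, link_design(list(D1 = "I1")),
                           group_dist("D1", 0, 1), w$spec)
  expect_identical(w$data, d2)
  # MCAR missingness rate approximately honoured
  specm <- sim_spec(n_datasets = 1L, n_instruments = 1L,
                    items_per_instrument = 4L, n_per_dataset = 2000L,
                    missing_rate = 0.2, seed = 5)
  dm <- simulate_responses(w$bank, link_design(list(D1 = "I1")),
                           group_dist("D1", 0, 1), specm)
  expect_equal(mean(is.na(dm$responses)), 0.2, tolerance = 0.02)
  # items of non-administered instruments are missing by design
  spec2 <- sim_spec(n_datasets = 2L, n_instruments = 2L,
                    items_per_instrument = 3L, n_per_dataset = 50L, seed = 6)
  des2 <- link_design(list(D1 = c("I1", "I2"), D2 = "I1"))
  b2 <- generate_bank(spec2)
  dat2 <- simulate_responses(b2, des2, group_dist(c("D1", "D2"), c(0, 0.3),
                                                  c(1, 1)), spec2)
  i2 <- dat2$items$item_id[dat2$items$instrument == "I2"]
  expect_true(all(is.na(dat2$responses[dat2$persons$dataset == "D2", i2])))
  expect_true(all(!is.na(dat2$responses[dat2$persons$dataset == "D1", i2])))
})

test_that("latent draws recover the group distributions", {
  spec <- sim_spec(n_datasets = 3L, n_instruments = 2L,
                   items_per_instrument = 2L, n_per_dataset = 4000L,
                   group_means = c(0, 0.6, -0.4), group_sds = c(1, 1.3, 0.8),
                   seed = 9)
  dists <- group_dist(spec$datasets, spec$group_means, spec$group_sds)
  dat <- simulate_responses(generate_bank(spec), generate_link_design(spec),
                            dists, spec)
  for (g in seq_len(3)) {
    th <- dat$persons$theta_true[dat$persons$dataset == spec$datasets[g]]
    tol <- 3 * dists$sd[g] / sqrt(length(th))
    expect_equal(mean(th), dists$mean[g], tolerance = tol * 1.5)
    expect_equal(sd(th), dists$sd[g], tolerance = 0.05)
  }
})

test_that("empirical category frequencies match the quadrature oracle", {
  # Monte-Carlo at n = 50,000 vs gpcm_probs integrated over N(mu, sd)
  spec <- sim_spec(n_datasets = 1L, n_instruments = 1L,
                   items_per_instrument = 2L, n_per_dataset = 50000L,
                   group_means = 0.3, group_sds = 1.1, seed = 17)
  bank <- generate_bank(spec)
  dists <- group_dist("D1", 0.3, 1.1, reference = NULL)
  dat <- simulate_responses(bank, link_design(list(D1 = "I1")), dists, spec)
  it <- bank$items[[1]]
  emp <- tabulate(dat$responses[, 1] + 1L, it$n_cat) / nrow(dat$responses)
  th <- seq(-8, 8, length.out = 401)
  w <- dnorm(th, 0.3, 1.1); w <- w / sum(w)
  theo <- colSums(gpcm_probs(it, th) * w)
  expect_equal(emp, unname(theo), tolerance = 0.01)
})

test_that("sparse categories collapse toward the interior", {
  mk <- function(counts) {
    x <- rep(seq_along(counts) - 1L, counts)
    response_data(matrix(x, ncol = 1, dimnames = list(NULL, "it")),
                  persons = data.frame(person_id = as.character(seq_along(x)),
                                       dataset = "D1"),
                  items = data.frame(item_id = "it", instrument = "I1",
                                     n_cat = length(counts)))
  }
  # spec'd arithmetic: (300, 15, 685) with min_count 20 -> (315, 685)
  cs <- collapse_sparse_categories(mk(c(300, 15, 685)))
  expect_equal(unname(table(cs$data$responses)), c(315, 685),
               ignore_attr = TRUE)
  expect_equal(cs$data$items$n_cat, 2L)
  expect_equal(cs$log$new, c(0L, 0L, 1L))
  # sparse floor category merges upward (toward the interior)
  cs2 <- collapse_sparse_categories(mk(c(5, 300, 300)))
  expect_equal(cs2$log$new, c(0L, 0L, 1L))
  # all heavy -> unchanged, empty log
  cs3 <- collapse_sparse_categories(mk(c(100, 100, 100)))
  expect_equal(nrow(cs3$log), 0L)
  expect_identical(cs3$data$responses, mk(c(100, 100, 100))$responses)
  # degenerate item errors by name
  expect_error(collapse_sparse_categories(mk(c(4, 5)), min_count = 20),
               "degenerate.*it")
  # default threshold is 20 responses
  expect_equal(formals(collapse_sparse_categories)$min_count, 20L)
})
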