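# GPCM/PCM mathematical core: category probabilities, expected scores,
# information, scale characteristic curves and their inversion.

test_that("GPCM category probabilities match the closed form", {
  # 2PL symmetry point
  it <- item_params("x", 1, 0)
  expect_equal(drop(gpcm_probs(it, 0)), c("0" = 0.5, "1" = 0.5))
  # hand evaluation: m=2, a=1, b=(-1,1), theta=0 -> unnormalized (1, e, 1)
  it2 <- item_params("y", 1, c(-1, 1))
  p <- drop(gpcm_probs(it2, 0))
  expect_equal(unname(p), c(1, exp(1), 1) / (2 + exp(1)), tolerance = 1e-12)
  expect_equal(round(unname(p), 4), c(0.2119, 0.5761, 0.2119))
  # normalization for arbitrary parameters and thetas
  set.seed(1)
  for (r in 1:20) {
    m <- sample(1:8, 1)
    it <- item_params("z", rlnorm(1, 0, 0.4), rnorm(m, 0, 1.5))
    th <- runif(7, -8, 8)
    expect_equal(rowSums(gpcm_probs(it, th)), rep(1, 7), tolerance = 1e-12)
  }
  expect_error(item_params("bad", -1, 0), "positive")
  expect_error(gpcm_probs(item_params("x", 1, 0), Inf), "finite")
})

test_that("GPCM reduces to the PCM closed form when a = 1", {
  # independent PCM oracle written directly from the adjacent-logit form
  pcm_oracle <- function(b, theta) {
    num <- exp(cumsum(c(0, theta - b)))
    num / sum(num)
  }
  set.seed(2)
  for (r in 1:10) {
    b <- rnorm(sample(1:5, 1), 0, 1.2)
    th <- runif(1, -4, 4)
    expect_equal(drop(gpcm_probs(item_params("p", 1, b), th)),
                 pcm_oracle(b, th), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("expected item score is bounded, symmetric and monotone", {
  it <- item_params("y", 1, c(-1, 1))
  expect_equal(expected_score(it, 0), 1)          # m/2 by symmetry
  expect_lt(expected_score(it, -8), 1e-3)
  expect_gt(expected_score(it, 8), 2 - 1e-3)
  # nondecreasing on a 201-point grid for random items
  set.seed(3)
  th <- seq(-8, 8, length.out = 201)
  for (r in 1:10) {
    it <- item_params("z", rlnorm(1, 0, 0.3), rnorm(sample(1:6, 1), 0, 1.5))
    expect_true(all(diff(expected_score(it, th)) >= -1e-12))
  }
})

test_that("item information matches the finite-difference oracle", {
  it <- item_params("x", 2, 0)
  expect_equal(item_information(it, 0), 1)        # 2^2 * 0.25
  set.seed(4)
  for (r in 1:8) {
    it <- item_params("z", rlnorm(1, 0, 0.3), rnorm(sample(1:5, 1)))
    th <- runif(1, -3, 3)
    expect_gte(item_information(it, th), 0)
    # -d2/dtheta2 of the expected log-likelihood at the true theta
    h <- 1e-4
    f <- function(t) sum(gpcm_probs(it, th) * log(gpcm_probs(it, t)))
    oracle <- -(f(th + h) - 2 * f(th) + f(th - h)) / h^2
    expect_equal(item_information(it, th), oracle, tolerance = 1e-4)
  }
})

test_that("scale characteristic curve sums items and respects transforms", {
  bank <- toy_bank()
  th <- seq(-6, 6, length.out = 41)
  # single-item instrument equals the item's expected score
  b1 <- item_bank(list(item_params("solo", 1.2, c(-0.5, 0.5),
                                   instrument_ids = "S")))
  expect_equal(scale_characteristic(b1, "S", th),
               expected_score(b1$items$solo, th))
  # additivity over disjoint instruments
  scc_ab <- scale_characteristic(bank, "A", th) +
    scale_characteristic(bank, "B", th)
  bank_u <- item_bank(lapply(bank$items, function(it)
    item_params(it$item_id, it$a, it$b, instrument_ids = "U")))
  expect_equal(scale_characteristic(bank_u, "U", th), scc_ab,
               tolerance = 1e-12)
  # ceiling at the grid top
  mtot <- sum(vapply(instrument_items(bank, "A"), function(i) i$n_cat - 1L,
                     0L))
  expect_equal(scale_characteristic(bank, "A", 8), mtot, tolerance = 1e-3)
  # invariance: SCC(theta; bank) == SCC(A theta + B; transformed bank)
  tb <- apply_transform(bank, list(A = 1.7, B = -0.6))
  expect_equal(scale_characteristic(bank, "A", th),
               scale_characteristic(tb, "A", 1.7 * th - 0.6),
               tolerance = 1e-10)
  expect_error(scale_characteristic(bank, "nope", 0), "unknown instrument")
})

test_that("invert_scc inverts the SCC with boundary flagging", {
  bank <- toy_bank()
  r <- invert_scc(bank, "A", scale_characteristic(bank, "A", 0.7))
  expect_false(r$boundary)
  expect_equal(r$theta, 0.7, tolerance = 1e-6)
  r0 <- invert_scc(bank, "A", 0)
  expect_true(r0$boundary)
  expect_equal(r0$theta, -8)
  # grid-search oracle at step 1e-4
  target <- 3.1
  grid <- seq(-8, 8, by = 1e-4)
  oracle <- grid[which.min(abs(scale_characteristic(bank, "A", grid) -
                                 target))]
  expect_lt(abs(invert_scc(bank, "A", target)$theta - oracle), 2e-4)
  expect_error(invert_scc(bank, "A", 99), "outside")
})

test_that("subgroup overrides resolve by exact label", {
  it <- item_params("d", 1, c(0, 1),
                    overrides = list(G2 = list(a = 1.5, b = c(0.5, 1.5))))
  expect_equal(gpcm_probs(it, 0.3, group = "G1"), gpcm_probs(it, 0.3))
  expect_false(isTRUE(all.equal(gpcm_probs(it, 0.3, group = "G2"),
                                gpcm_probs(it, 0.3))))
  expect_equal(gpcm_probs(it, 0.3, group = "G2"),
               gpcm_probs(item_params("d", 1.5, c(0.5, 1.5)), 0.3))
})
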