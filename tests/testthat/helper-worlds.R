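# Shared fixtures: small simulated "worlds" and fast estimation options.

quick_opts <- function(n_quad = 41L, tol = 1e-3, ...) {
  calib_opts(n_quad = n_quad, tol = tol, ...)
}

tiny_opts <- function() calib_opts(n_quad = 15L, tol = 1e-3, range = c(-6, 6))

# a deterministic small bank for closed-form checks
toy_bank <- function() {
  item_bank(list(
    item_params("a1", 1.0, c(-1, 1),    instrument_ids = "A"),
    item_params("a2", 1.4, c(-0.5, 0.8), instrument_ids = "A"),
    item_params("a3", 0.8, c(0, 0.5, 1.2), instrument_ids = "A"),
    item_params("b1", 1.1, c(-2, -1, 0), instrument_ids = "B"),
    item_params("b2", 0.9, c(0.3),       instrument_ids = "B")))
}

# single-dataset world used by several estimation tests
one_group_world <- function(n = 1500L, J = 8L, seed = 101L, ...) {
  spec <- sim_spec(n_datasets = 1L, n_instruments = 1L,
                   items_per_instrument = J, n_per_dataset = n,
                   seed = seed, ...)
  bank <- generate_bank(spec)
  data <- simulate_responses(bank, link_design(list(D1 = "I1")),
                             group_dist("D1", 0, 1), spec)
  list(spec = spec, bank = bank, data = data)
}

# DIF world: one focal registry among three reference registries, all
# administering the same 10-item instrument; uniform DIF on item 1
dif_world <- function(seed, delta = 0.5, n = 1000L) {
  dif <- if (delta != 0)
    data.frame(item = "I1_01", group = "D4", delta = delta) else NULL
  spec <- sim_spec(n_datasets = 4L, n_instruments = 1L,
                   items_per_instrument = 10L, n_per_dataset = n,
                   seed = seed, dif = dif,
                   group_means = rep(0, 4), group_sds = rep(1, 4))
  design <- link_design(setNames(rep(list("I1"), 4), paste0("D", 1:4)))
  bank <- generate_bank(spec)
  dists <- group_dist(paste0("D", 1:4), rep(0, 4), rep(1, 4))
  data <- simulate_responses(bank, design, dists, spec)
  list(spec = spec, bank = bank, data = data)
}

# local-dependence world: high-discrimination 5-category items typical of
# physical-function short forms; the testlet is a triplet of near-duplicate
# items (matched high discrimination, adjacent central difficulty - the
# walking/stair-climbing situation that produces LD flags in practice)
# sharing a nuisance factor with loading gamma = 0.8
ld_world <- function(seed, gamma = 0.8, n = 2000L) {
  tl <- if (gamma != 0)
    list(list(items = c("I1_01", "I1_02", "I1_03"), gamma = gamma)) else NULL
  spec <- sim_spec(n_datasets = 1L, n_instruments = 1L,
                   items_per_instrument = 12L, n_cat = 5L,
                   a_meanlog = log(2), a_sdlog = 0.2,
                   n_per_dataset = n, seed = seed, testlets = tl)
  bank <- generate_bank(spec)
  for (k in 1:3) {
    id <- sprintf("I1_%02d", k)
    loc <- c(-0.3, 0, 0.3)[k]
    bank$items[[id]] <- item_params(id, 2, loc + seq(-0.7, 0.7,
                                                     length.out = 4L),
                                    instrument_ids = "I1")
  }
  data <- simulate_responses(bank, link_design(list(D1 = "I1")),
                             group_dist("D1", 0, 1), spec)
  list(spec = spec, bank = bank, data = data)
}

bank_a <- function(bank) vapply(bank$items, `[[`, 0, "a")
bank_b <- function(bank) unlist(lapply(bank$items, `[[`, "b"))
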