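# Synthetic multi-registry response data with a common-item linking
# structure: several datasets, each administering a subset of instruments,
# joined by anchor instruments so that all items can be calibrated
# concurrently.  Supports injected uniform DIF, testlet local dependence,
# sparse extreme categories and MCAR missingness.

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulation specification
#'
#' Describes the "world" the generator draws from: the linking design shape,
#' item pool, dataset-specific latent normal distributions, and optional
#' perturbations (uniform DIF, testlet local dependence, MCAR missingness).
#' Defaults emulate a multi-registry physical-function calibration study:
#' six registries each administering two to four instruments out of six,
#' eight 4-category items per instrument, about a thousand respondents per
#' registry, lognormal discriminations and item locations spread over
#' \[-2, 2\] logits.
#'
#' @param n_datasets Number of datasets (registries).
#' @param n_instruments Number of instruments in the pool.
#' @param items_per_instrument Items per instrument (scalar or vector).
#' @param n_cat Categories per item (scalar, or vector recycled over items).
#' @param n_per_dataset Respondents per dataset.
#' @param a_meanlog,a_sdlog Lognormal parameters for discriminations;
#'   `a_sdlog = 0, a_meanlog = 0` gives a PCM-type bank (all `a = 1`).
#' @param b_range Range over which item locations are spread (logits).
#' @param b_step_sd Random jitter of step difficulties around the location.
#' @param group_means,group_sds Latent means/SDs per dataset; the first
#'   dataset is the reference and is forced to (0, 1).  Defaults alternate
#'   moderate shifts, emulating registries of differing severity.
#' @param dif Optional data.frame `item`, `group`, `delta`: uniform DIF, the
#'   focal group's step difficulties are shifted by `delta` logits.
#' @param testlets Optional list of `list(items=, gamma=)`: items sharing a
#'   testlet draw a common N(0,1) nuisance factor weighted by `gamma`.
#' @param missing_rate MCAR missingness rate in `[0, 1]` applied on top of
#'   the by-design missingness (items not administered in a dataset).
#' @param seed Integer seed; all generator functions are deterministic
#'   functions of the spec.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(n_datasets = 6L, n_instruments = 6L,
                     items_per_instrument = 8L, n_cat = 4L,
                     n_per_dataset = 1000L,
                     a_meanlog = 0, a_sdlog = 0.25,
                     b_range = c(-2, 2), b_step_sd = 0.2,
                     group_means = NULL, group_sds = NULL,
                     dif = NULL, testlets = NULL,
                     missing_rate = 0, seed = 1L) {
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0,1]")
  if (!is.null(dif) && any(!is.finite(dif$delta))) stop("DIF shifts must be finite")
  if (!is.null(testlets) &&
      any(!vapply(testlets, function(t) is.finite(t$gamma), TRUE)))
    stop("testlet loadings must be finite")
  if (any(n_cat < 2)) stop("items need at least 2 categories")
  datasets <- paste0("D", seq_len(n_datasets))
  if (is.null(group_means)) {
    group_means <- c(0, rep_len(c(0.4, -0.4, 0.8, -0.2, 0.2), n_datasets - 1L))
  }
  if (is.null(group_sds)) {
    group_sds <- c(1, rep_len(c(1.2, 0.9, 1.1, 1, 0.8), n_datasets - 1L))
  }
  structure(list(n_datasets = as.integer(n_datasets),
                 n_instruments = as.integer(n_instruments),
                 items_per_instrument = items_per_instrument,
                 n_cat = n_cat, n_per_dataset = n_per_dataset,
                 a_meanlog = a_meanlog, a_sdlog = a_sdlog,
                 b_range = b_range, b_step_sd = b_step_sd,
                 datasets = datasets,
                 group_means = group_means, group_sds = group_sds,
                 dif = dif, testlets = testlets,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Dataset-specific latent distributions
#'
#' Latent normal mean/SD per dataset.  The reference dataset is constrained
#' to mean 0 and SD 1 exactly; this is the identification constraint of the
#' concurrent calibration.
#'
#' @param datasets Character vector of dataset labels.
#' @param means,sds Numeric vectors, one per dataset.
#' @param reference Reference dataset label (default the first); `NULL`
#'   leaves all distributions unconstrained (e.g. to simulate an external
#'   population expressed on an already-fixed common metric).
#' @return Object of class `group_dist` (data.frame with attributes).
#' @export
group_dist <- function(datasets, means, sds, reference = datasets[1]) {
  stopifnot(length(means) == length(datasets), length(sds) == length(datasets))
  if (any(sds <= 0)) stop("latent SDs must be positive")
  if (!is.null(reference)) {
    i <- match(reference, datasets)
    if (is.na(i)) stop("reference dataset not among datasets")
    means[i] <- 0; sds[i] <- 1
  }
  structure(data.frame(dataset = datasets, mean = means, sd = sds,
                       stringsAsFactors = FALSE),
            reference = reference, class = c("group_dist", "data.frame"))
}

#' Common-item linking design
#'
#' Maps datasets to the instruments they administer.  Validates the central
#' linking requirement of a non-equivalent-groups common-items design: the
#' dataset/instrument bipartite graph must be connected, i.e. every pair of
#' datasets must be joined through shared (anchor) instruments.
#'
#' @param instrument_map Named list: dataset label -> character vector of
#'   instrument ids administered there.
#' @return Object of class `link_design`.
#' @export
link_design <- function(instrument_map) {
  datasets <- names(instrument_map)
  if (length(datasets) < 1L) stop("at least one dataset required")
  if (!design_connected(instrument_map))
    stop("design error: datasets are not connected by shared instruments")
  structure(list(datasets = datasets, instrument_map = instrument_map),
            class = "link_design")
}

# connectivity of the dataset graph (edge = shared instrument), by BFS
design_connected <- function(instrument_map) {
  n <- length(instrument_map)
  if (n == 1L) return(TRUE)
  seen <- c(TRUE, rep(FALSE, n - 1L))
  frontier <- 1L
  while (length(frontier)) {
    nxt <- integer()
    for (i in frontier) for (j in which(!seen)) {
      if (length(intersect(instrument_map[[i]], instrument_map[[j]]))) {
        seen[j] <- TRUE; nxt <- c(nxt, j)
      }
    }
    frontier <- nxt
  }
  all(seen)
}

#' Generate a connected linking design from a simulation spec
#'
#' Every dataset receives one global anchor instrument plus a rotating block
#' of the remaining instruments (2-4 instruments per dataset), which
#' guarantees connectivity.
#'
#' @param spec A [sim_spec()].
#' @return A [link_design()].
#' @export
generate_link_design <- function(spec) {
  K <- spec$n_instruments
  instr <- paste0("I", seq_len(K))
  if (spec$n_datasets >= 2L && K < 1L)
    stop("design error: cannot connect datasets without instruments")
  im <- vector("list", spec$n_datasets)
  names(im) <- spec$datasets
  for (d in seq_len(spec$n_datasets)) {
    extra <- 1L + (d - 1L) %% 3L                 # 1..3 extras -> 2..4 total
    others <- setdiff(seq_len(K), 1L)
    if (length(others)) {
      rot <- ((d - 1L) * 2L + seq_len(extra) - 1L) %% length(others) + 1L
      sel <- c(1L, others[unique(rot)])
    } else sel <- 1L
    im[[d]] <- instr[sort(unique(sel))]
  }
  link_design(im)
}

#' Generate an item bank from a simulation spec
#'
#' Discriminations are lognormal, step difficulties are an item location
#' drawn uniformly over `b_range` plus spread-out, jittered step offsets.
#' Deterministic under the spec's seed.
#'
#' @param spec A [sim_spec()].
#' @return An [item_bank()].
#' @export
generate_bank <- function(spec) {
  with_seed(spec$seed + 1L, {
    ipi <- rep_len(spec$items_per_instrument, spec$n_instruments)
    items <- list()
    ix <- 0L
    for (k in seq_len(spec$n_instruments)) {
      for (j in seq_len(ipi[k])) {
        ix <- ix + 1L
        m <- rep_len(spec$n_cat, sum(ipi))[ix] - 1L
        a <- if (spec$a_sdlog == 0) exp(spec$a_meanlog) else
          stats::rlnorm(1, spec$a_meanlog, spec$a_sdlog)
        loc <- stats::runif(1, spec$b_range[1], spec$b_range[2])
        off <- if (m == 1L) 0 else seq(-0.7, 0.7, length.out = m)
        b <- loc + off + stats::rnorm(m, 0, spec$b_step_sd)
        items[[ix]] <- item_params(sprintf("I%d_%02d", k, j), a, b,
                                   instrument_ids = paste0("I", k))
      }
    }
    item_bank(items)
  })
}

#' Simulate item responses under the GPCM
#'
#' Each person in dataset `g` draws a latent value from N(mu_g, sd_g^2);
#' testlet items add a shared nuisance draw weighted by gamma; DIF items use
#' shifted step difficulties in their focal group; responses to items not
#' administered in the person's dataset are missing by design; an MCAR mask
#' is applied on top.
#'
#' @param bank An [item_bank()].
#' @param design A [link_design()].
#' @param dists A [group_dist()].
#' @param spec A [sim_spec()] (sample sizes, DIF/testlet/missingness, seed).
#' @return A `response_data` object: integer matrix `responses` (persons x
#'   items, NA = missing), `persons` data.frame (person_id, dataset,
#'   theta_true), `items` data.frame (item_id, instrument, n_cat).
#' @export
simulate_responses <- function(bank, design, dists, spec) {
  with_seed(spec$seed + 2L, {
    ids <- names(bank$items)
    J <- length(ids)
    item_instr <- vapply(bank$items, function(it) it$instrument_ids[1], "")
    n_cat <- vapply(bank$items, `[[`, 0L, "n_cat")
    n_g <- rep_len(spec$n_per_dataset, length(design$datasets))
    n <- sum(n_g)
    dataset <- rep(design$datasets, n_g)
    mu <- dists$mean[match(dataset, dists$dataset)]
    sd <- dists$sd[match(dataset, dists$dataset)]
    theta <- stats::rnorm(n, mu, sd)
    # shared testlet nuisance draws
    tl_of <- setNames(rep(NA_integer_, J), ids)
    tl_u <- NULL
    if (length(spec$testlets)) {
      tl_u <- matrix(stats::rnorm(n * length(spec$testlets)), n)
      for (t in seq_along(spec$testlets))
        tl_of[spec$testlets[[t]]$items] <- t
    }
    X <- matrix(NA_integer_, n, J, dimnames = list(NULL, ids))
    for (j in seq_len(J)) {
      admin_ds <- design$datasets[vapply(design$instrument_map,
                                         function(s) item_instr[j] %in% s,
                                         TRUE)]
      idx <- which(dataset %in% admin_ds)
      if (!length(idx)) next
      th <- theta[idx]
      if (!is.na(tl_of[j])) {
        t <- tl_of[j]
        th <- th + spec$testlets[[t]]$gamma * tl_u[idx, t]
      }
      it <- bank$items[[j]]
      # uniform DIF: shift steps for focal-group persons
      difrows <- if (is.null(spec$dif)) integer() else
        which(spec$dif$item == ids[j])
      grp_delta <- setNames(rep(0, length(design$datasets)), design$datasets)
      for (r in difrows) grp_delta[spec$dif$group[r]] <- spec$dif$delta[r]
      u <- stats::runif(length(idx))
      x <- integer(length(idx))
      for (g in design$datasets) {
        gi <- which(dataset[idx] == g)
        if (!length(gi)) next
        itg <- if (grp_delta[g] != 0)
          item_params(it$item_id, it$a, it$b + grp_delta[g]) else it
        p <- gpcm_probs(itg, th[gi])
        cp <- t(apply(p, 1L, cumsum))
        x[gi] <- rowSums(u[gi] > cp)          # inverse-CDF draw
      }
      X[idx, j] <- x
    }
    if (spec$missing_rate > 0) {
      mask <- matrix(stats::runif(n * J) < spec$missing_rate, n)
      X[mask] <- NA_integer_
    }
    response_data(X,
                  persons = data.frame(person_id = sprintf("P%05d", seq_len(n)),
                                       dataset = dataset,
                                       theta_true = theta,
                                       stringsAsFactors = FALSE),
                  items = data.frame(item_id = ids,
                                     instrument = unname(item_instr),
                                     n_cat = unname(n_cat),
                                     stringsAsFactors = FALSE))
  })
}

#' Response data container
#'
#' @param responses Integer matrix, persons x items, categories `0..m_j`,
#'   `NA` = missing; columns named by item id.
#' @param persons data.frame with at least `person_id` and `dataset`.
#' @param items data.frame with `item_id`, `instrument`, `n_cat`; derived
#'   from the data when omitted.
#' @return Object of class `response_data`.
#' @export
response_data <- function(responses, persons, items = NULL) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  if (is.null(colnames(responses))) stop("responses must have item-id columns")
  if (nrow(persons) != nrow(responses))
    stop("persons table must match response rows")
  if (is.null(items)) {
    items <- data.frame(item_id = colnames(responses),
                        instrument = NA_character_,
                        n_cat = apply(responses, 2L, function(x)
                          max(x, 0L, na.rm = TRUE) + 1L),
                        stringsAsFactors = FALSE)
  }
  if (!all(colnames(responses) == items$item_id))
    stop("item metadata must align with response columns")
  bad <- which(sweep(responses, 2L, items$n_cat - 1L, `>`) | responses < 0L,
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("validation error: out-of-range category at person %d, item %s",
                 bad[1, 1], items$item_id[bad[1, 2]]))
  structure(list(responses = responses, persons = persons, items = items),
            class = "response_data")
}

#' @export
print.response_data <- function(x, ...) {
  cat(sprintf("<response_data> %d persons x %d items, %d datasets, %.1f%% observed\n",
              nrow(x$responses), ncol(x$responses),
              length(unique(x$persons$dataset)),
              100 * mean(!is.na(x$responses))))
  invisible(x)
}

#' @export
dim.response_data <- function(x) dim(x$responses)

#' Collapse sparsely used response categories
#'
#' Any observed category that attracted fewer than `min_count` responses is
#' merged into its adjacent category nearer the scale interior, iteratively
#' (sparsest first, ties to the lower category), and the item is recoded to
#' contiguous codes `0..m'`.  The default threshold of 20 responses reflects
#' common practice for stabilizing step-parameter estimation.
#'
#' @param data A `response_data`.
#' @param min_count Minimum responses per category (default 20).
#' @return List: `data` (recoded `response_data`) and `log`, a data.frame
#'   with columns `item_id`, `old`, `new` for every recoded item.
#' @export
collapse_sparse_categories <- function(data, min_count = 20L) {
  stopifnot(min_count >= 1L)
  X <- data$responses
  items <- data$items
  logs <- list()
  for (j in seq_len(ncol(X))) {
    m1 <- items$n_cat[j]
    counts <- tabulate(X[, j] + 1L, nbins = m1)
    if (sum(counts) == 0L) next
    # groups of original categories, merged pairwise until all heavy enough
    groups <- as.list(seq_len(m1))
    gcounts <- counts
    while (length(groups) > 1L && min(gcounts) < min_count) {
      i <- which.min(gcounts)
      center <- (length(groups) + 1) / 2
      target <- if (i == 1L) 2L
        else if (i == length(groups)) i - 1L
        else if (i < center) i + 1L
        else i - 1L
      lo <- min(i, target); hi <- max(i, target)
      groups[[lo]] <- c(groups[[lo]], groups[[hi]])
      gcounts[lo] <- gcounts[lo] + gcounts[hi]
      groups[[hi]] <- NULL
      gcounts <- gcounts[-hi]
    }
    if (length(groups) < 2L)
      stop("degenerate item after collapsing: ", items$item_id[j])
    if (length(groups) == m1) next
    map <- integer(m1)
    for (g in seq_along(groups)) map[groups[[g]]] <- g - 1L
    X[, j] <- map[X[, j] + 1L]
    items$n_cat[j] <- length(groups)
    logs[[length(logs) + 1L]] <-
      data.frame(item_id = items$item_id[j], old = seq_len(m1) - 1L,
                 new = map, stringsAsFactors = FALSE)
  }
  log <- if (length(logs)) do.call(rbind, logs) else
    data.frame(item_id = character(), old = integer(), new = integer(),
               stringsAsFactors = FALSE)
  list(data = response_data(X, data$persons, items), log = log)
}
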