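#' Item parameters for a polytomous (G)PCM item
#'
#' Bundles the generalized partial credit parameters of a single item: a
#' discrimination `a` (logit units, strictly positive) and `m` step
#' difficulties `b` for an item with `m + 1` ordered response categories
#' scored `0..m`.  Steps are stored in step order and are *not* required to
#' be sorted: GPCM steps may legitimately be disordered.  Items flagged for
#' differential item functioning can carry subgroup-specific parameter
#' overrides that are resolved by exact group-label match.
#'
#' @param item_id Character scalar, unique within a bank.
#' @param a Discrimination, > 0.
#' @param b Numeric vector of step difficulties `b_1..b_m`.
#' @param instrument_ids Character vector of instruments the item belongs to.
#' @param overrides Named list (group label -> `list(a=, b=)`) of subgroup
#'   parameters for DIF-affected items.
#' @return An object of class `item_params`.
#' @export
item_params <- function(item_id, a, b, instrument_ids = character(),
                        overrides = list()) {
  if (!is.character(item_id) || length(item_id) != 1L)
    stop("item_id must be a single string")
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("invalid parameter: discrimination 'a' must be a positive finite number")
  b <- as.numeric(b)
  if (length(b) < 1L || any(!is.finite(b)))
    stop("step difficulties 'b' must be finite and non-empty")
  for (ov in overrides) {
    if (!is.finite(ov$a) || ov$a <= 0 || length(ov$b) != length(b))
      stop("invalid subgroup override for item ", item_id)
  }
  structure(list(item_id = item_id,
                 instrument_ids = as.character(instrument_ids),
                 a = as.numeric(a), b = b, n_cat = length(b) + 1L,
                 overrides = overrides),
            class = "item_params")
}

#' @export
print.item_params <- function(x, ...) {
  cat(sprintf("<item %s> a = %.3f, b = (%s), %d categories",
              x$item_id, x$a, paste(sprintf("%.3f", x$b), collapse = ", "),
              x$n_cat))
  if (length(x$overrides))
    cat(", overrides:", paste(names(x$overrides), collapse = ", "))
  cat("\n")
  invisible(x)
}

# Resolve the (a, b) pair that applies to a group: exact label match on the
# overrides, otherwise the default parameters.
resolve_params <- function(item, group = NULL) {
  if (!is.null(group) && length(item$overrides) &&
      !is.na(group) && group %in% names(item$overrides)) {
    ov <- item$overrides[[group]]
    list(a = ov$a, b = as.numeric(ov$b))
  } else {
    list(a = item$a, b = item$b)
  }
}

#' Item bank
#'
#' A collection of [item_params()] objects with unique ids, plus an optional
#' metric origin `theta0` (the latent value mapped to 0 on the standardized
#' reporting metric, see [locate_metric_origin()]).
#'
#' @param items List of `item_params`.
#' @param theta0 Optional numeric scalar, the metric origin on the logit scale.
#' @return An object of class `item_bank`.
#' @export
item_bank <- function(items, theta0 = NULL) {
  if (inherits(items, "item_params")) items <- list(items)
  ids <- vapply(items, `[[`, "", "item_id")
  if (anyDuplicated(ids)) stop("item ids must be unique")
  names(items) <- ids
  structure(list(items = items, theta0 = theta0), class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank> %d items, %d instruments", length(x$items),
              length(bank_instruments(x))))
  if (!is.null(x$theta0)) cat(sprintf(", theta0 = %.3f", x$theta0))
  cat("\n")
  invisible(x)
}

#' @export
length.item_bank <- function(x) length(x$items)

#' Instruments represented in a bank
#' @param bank An `item_bank`.
#' @return Character vector of instrument ids.
#' @export
bank_instruments <- function(bank) {
  sort(unique(unlist(lapply(bank$items, `[[`, "instrument_ids"))))
}

#' Items belonging to an instrument
#' @param bank An `item_bank`.
#' @param instrument_id Instrument label.
#' @return List of `item_params` making up the instrument.
#' @export
instrument_items <- function(bank, instrument_id) {
  sel <- Filter(function(it) instrument_id %in% it$instrument_ids, bank$items)
  if (!length(sel)) stop("unknown instrument: ", instrument_id)
  sel
}

#' Quadrature grid over the latent scale
#'
#' Equally spaced nodes on a bounded support with normalized nonnegative
#' weights.  The default 61 nodes on \[-8, 8\] with standard-normal weights
#' serve all marginal-likelihood, EAP and Stocking-Lord integrations; both
#' the node count and the support are configurable.
#'
#' @param n Number of nodes (default 61).
#' @param range Support (default `c(-8, 8)`).
#' @param weights Optional nonnegative weights; default standard normal
#'   density at the nodes.  Normalized to sum to one.
#' @return Object of class `quad_grid` with fields `nodes`, `weights`.
#' @export
quad_grid <- function(n = 61L, range = c(-8, 8), weights = NULL) {
  stopifnot(n >= 2L, range[2] > range[1])
  nodes <- seq(range[1], range[2], length.out = n)
  if (is.null(weights)) weights <- stats::dnorm(nodes)
  if (length(weights) != n || any(weights < 0))
    stop("weights must be nonnegative, one per node")
  structure(list(nodes = nodes, weights = weights / sum(weights)),
            class = "quad_grid")
}

# normal density weights on an existing grid, renormalized
grid_normal_weights <- function(grid, mean = 0, sd = 1) {
  w <- stats::dnorm(grid$nodes, mean, sd)
  s <- sum(w)
  if (s <= 0) w <- rep(1 / length(w), length(w)) else w <- w / s
  w
}
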