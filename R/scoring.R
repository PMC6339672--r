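# EAP scoring, the standardized reporting metric (10 points per logit above
# the metric origin), reliability coefficients, score-level correlation
# summaries and the cross-instrument congruence report.

#' Expected a posteriori (EAP) score for one response pattern
#'
#' Posterior mean and SD of the latent value over a quadrature grid, given
#' the observed responses and a normal prior (default N(0, 1)).  Missing
#' responses are simply omitted; an all-missing pattern returns the prior
#' mean and SD with `all_missing = TRUE`.
#'
#' @param bank An [item_bank()].
#' @param pattern Named integer vector (names = item ids, values =
#'   categories `0..m`, NA = missing).
#' @param prior `c(mean, sd)` of the normal prior (default `c(0, 1)`).
#' @param grid A [quad_grid()].
#' @param group Optional group label for subgroup override resolution.
#' @return List: `theta`, `se`, `all_missing`.
#' @export
eap_score <- function(bank, pattern, prior = c(0, 1), grid = quad_grid(),
                      group = NULL) {
  ids <- intersect(names(pattern), names(bank$items))
  obs <- ids[!is.na(pattern[ids])]
  w <- grid_normal_weights(grid, prior[1], prior[2])
  if (!length(obs))
    return(list(theta = prior[1], se = prior[2], all_missing = TRUE))
  lp <- log(w)
  for (id in obs) {
    item <- bank$items[[id]]
    k <- pattern[[id]]
    if (k < 0 || k > item$n_cat - 1L)
      stop("invalid category ", k, " for item ", id)
    lp <- lp + log(gpcm_probs(item, grid$nodes, group)[, k + 1L])
  }
  lp <- lp - max(lp)
  p <- exp(lp); p <- p / sum(p)
  th <- sum(p * grid$nodes)
  se <- sqrt(max(sum(p * grid$nodes^2) - th^2, 0))
  list(theta = th, se = se, all_missing = FALSE)
}

#' EAP scores for all persons on one instrument
#'
#' Vectorized scoring of a response matrix restricted to an instrument's
#' items.  Returns one score record per person: the EAP estimate and its
#' posterior SD, the standardized metric score (if the bank's metric origin
#' is set), and the number of items answered.
#'
#' @param data A `response_data` or numeric matrix with item-id columns.
#' @param bank An [item_bank()].
#' @param instrument_id Instrument to score; `NULL` scores on all bank
#'   items present in the data.
#' @inheritParams eap_score
#' @return data.frame: `person_id`, `instrument_id`, `theta_eap`, `se`,
#'   `standardized` (NA when no origin is set), `n_items_answered`,
#'   `all_missing`.
#' @export
eap_scores <- function(data, bank, instrument_id = NULL, prior = c(0, 1),
                       grid = quad_grid()) {
  X <- if (inherits(data, "response_data")) data$responses else as.matrix(data)
  pid <- if (inherits(data, "response_data")) data$persons$person_id else
    rownames(X) %||% as.character(seq_len(nrow(X)))
  ids <- if (is.null(instrument_id)) intersect(colnames(X), names(bank$items))
    else intersect(colnames(X),
                   vapply(instrument_items(bank, instrument_id), `[[`, "",
                          "item_id"))
  if (!length(ids)) stop("no scorable items in the data")
  Xs <- X[, ids, drop = FALSE]
  pars <- lapply(bank$items[ids], function(it) list(a = it$a, b = it$b))
  LL <- conditional_loglik(pars, Xs, grid$nodes)
  lw <- log(grid_normal_weights(grid, prior[1], prior[2]))
  ep <- posterior_from_loglik(LL, matrix(lw, nrow(Xs), length(lw),
                                         byrow = TRUE))
  th <- drop(ep$post %*% grid$nodes)
  se <- sqrt(pmax(drop(ep$post %*% grid$nodes^2) - th^2, 0))
  n_ans <- rowSums(!is.na(Xs))
  all_missing <- n_ans == 0L
  th[all_missing] <- prior[1]; se[all_missing] <- prior[2]
  std <- if (!is.null(bank$theta0)) 10 * (th - bank$theta0) else NA_real_
  data.frame(person_id = pid,
             instrument_id = instrument_id %||% NA_character_,
             theta_eap = th, se = se, standardized = std,
             n_items_answered = n_ans, all_missing = all_missing,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate the metric origin
#'
#' The origin of the standardized metric is the largest grid value at which
#' every instrument's expected *mean* item score is at most `epsilon`
#' (default 0.01 score units): a standardized score of zero then represents
#' the lower bound of what the linked instruments can measure.  An exactly
#' zero expected score is only attained asymptotically, hence the epsilon.
#'
#' @param bank An [item_bank()].
#' @param epsilon Tolerance on the mean expected item score (default 0.01).
#' @param grid A [quad_grid()].
#' @return The origin `theta0` (logits); the grid floor, with a warning,
#'   when `epsilon` is unattainable on the grid.
#' @export
locate_metric_origin <- function(bank, epsilon = 0.01, grid = quad_grid()) {
  instr <- bank_instruments(bank)
  if (!length(instr)) stop("bank has no instruments")
  worst <- rep(0, length(grid$nodes))
  for (s in instr) {
    items <- instrument_items(bank, s)
    worst <- pmax(worst,
                  scale_characteristic(bank, s, grid$nodes) / length(items))
  }
  ok <- which(worst <= epsilon)
  if (!length(ok)) {
    warning("epsilon unreachable on the grid; using the grid floor")
    return(grid$nodes[1])
  }
  grid$nodes[max(ok)]
}

#' Set the metric origin on a bank
#' @param bank An [item_bank()].
#' @param theta0 Origin (logits); default computed by
#'   [locate_metric_origin()].
#' @param ... Passed on to [locate_metric_origin()].
#' @return The bank with `theta0` set.
#' @export
set_metric_origin <- function(bank, theta0 = locate_metric_origin(bank, ...),
                              ...) {
  bank$theta0 <- as.numeric(theta0)
  bank
}

#' Standardized metric score
#'
#' `S = 10 (theta - theta0)`: increments of 10 points on the reporting
#' metric correspond to one logit on the latent scale, and the metric
#' origin maps to zero.
#'
#' @param theta Latent values (logits).
#' @param bank An [item_bank()] with its metric origin set.
#' @return Numeric vector of standardized scores.
#' @export
standardize_score <- function(theta, bank) {
  if (is.null(bank$theta0))
    stop("configuration error: metric origin not set (see set_metric_origin)")
  10 * (theta - bank$theta0)
}

#' Marginal reliability of EAP scores
#'
#' `var(theta_hat) / (var(theta_hat) + mean(se^2))`.
#'
#' @param scores data.frame from [eap_scores()] (needs `theta_eap`, `se`).
#' @return Reliability in `[0, 1]`.
#' @export
marginal_reliability <- function(scores) {
  if (nrow(scores) < 2L) stop("need at least two scored persons")
  v <- stats::var(scores$theta_eap)
  if (v <= 0) { warning("degenerate score variance"); return(0) }
  v / (v + mean(scores$se^2))
}

#' Conditional reliability curve
#'
#' `CR(theta) = I(theta) / (I(theta) + 1)` with `I` the summed item
#' information of the instrument, evaluated on the grid; also reports the
#' standardized-metric range over which CR exceeds `threshold` (0.70 by
#' convention), rounded to grid resolution.
#'
#' @param bank An [item_bank()].
#' @param instrument_id Instrument label.
#' @param grid A [quad_grid()].
#' @param threshold CR cutoff for the reported range (default 0.70).
#' @return List: `curve` (data.frame `theta`, `standardized`, `info`,
#'   `cr`) and `range` (standardized metric; `c(NA, NA)` if never reached).
#' @export
conditional_reliability <- function(bank, instrument_id, grid = quad_grid(),
                                    threshold = 0.70) {
  items <- instrument_items(bank, instrument_id)
  info <- Reduce(`+`, lapply(items, item_information, theta = grid$nodes))
  cr <- info / (info + 1)
  std <- if (!is.null(bank$theta0)) 10 * (grid$nodes - bank$theta0) else
    NA_real_
  ok <- which(cr > threshold)
  rng <- if (length(ok) && !is.null(bank$theta0))
    c(std[min(ok)], std[max(ok)]) else c(NA_real_, NA_real_)
  list(curve = data.frame(theta = grid$nodes, standardized = std,
                          info = info, cr = cr),
       range = rng)
}

#' Cronbach's alpha of a complete item score matrix
#' @param X Numeric matrix (persons x items), no missing values.
#' @return Alpha coefficient.
#' @export
cronbach_alpha <- function(X) {
  S <- stats::cov(X)
  p <- ncol(S)
  p / (p - 1) * (1 - sum(diag(S)) / sum(S))
}

#' Greatest lower bound reliability (factor-analytic approximation)
#'
#' Approximates the GLB by substituting iterated factor-analytic
#' communalities for the observed variances on the covariance diagonal:
#' error variance is bounded by the unique variances, so
#' `GLB = 1 - sum(sigma_i^2 (1 - h_i^2)) / var(total)`.
#'
#' @param data A `response_data` or numeric matrix; complete cases on the
#'   selected columns are used.
#' @param items Optional character vector of columns (default all).
#' @param min_n Minimum complete cases required (default 30).
#' @return GLB estimate in `[0, 1]`.
#' @export
glb_reliability <- function(data, items = NULL, min_n = 30L) {
  X <- if (inherits(data, "response_data")) data$responses else as.matrix(data)
  if (!is.null(items)) X <- X[, items, drop = FALSE]
  if (ncol(X) < 2L) stop("GLB is undefined for a single item")
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) < min_n)
    stop("too few complete cases (", nrow(X), " < ", min_n, ") for the GLB")
  S <- stats::cov(X)
  R <- stats::cov2cor(S)
  k <- max(1L, sum(eigen(R, symmetric = TRUE, only.values = TRUE)$values > 1))
  h <- pmin(pmax(1 - 1 / diag(tryCatch(solve(R), error = function(e)
    diag(ncol(R)))), 0.1), 0.99)
  for (i in seq_len(200L)) {
    Rh <- R; diag(Rh) <- h
    e <- eigen(Rh, symmetric = TRUE)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
    h_new <- pmin(rowSums(L^2), 1)
    if (max(abs(h_new - h)) < 1e-6) { h <- h_new; break }
    h <- h_new
  }
  vt <- sum(S)
  min(max(1 - sum(diag(S) * (1 - h)) / vt, 0), 1)
}

#' Observed-vs-IRT and overlap-corrected inter-scale correlations
#'
#' For each scale: the Pearson correlation between raw summed scores and
#' EAP scores (complete cases on the scale).  Between scales: summed-score
#' correlations with shared items excluded from the larger member of the
#' pair (ties: the second), the overlap noted per cell.  A scale fully
#' nested within another is marked `"nested"`: exclusion is impossible and
#' no corrected value is reported.
#'
#' @param data A `response_data` or numeric matrix.
#' @param bank An [item_bank()].
#' @param scales Named list: scale label -> character vector of item ids;
#'   default, the bank's instruments.
#' @param grid A [quad_grid()] for the EAP scores.
#' @return List: `observed_irt` (data.frame `scale`, `r`, `n`),
#'   `between` (correlation matrix), `overlap` (shared item counts),
#'   `note` (character matrix: "", "corrected", "nested").
#' @export
score_correlations <- function(data, bank, scales = NULL,
                               grid = quad_grid()) {
  X <- if (inherits(data, "response_data")) data$responses else as.matrix(data)
  if (is.null(scales)) {
    scales <- lapply(bank_instruments(bank), function(s)
      intersect(vapply(instrument_items(bank, s), `[[`, "", "item_id"),
                colnames(X)))
    names(scales) <- bank_instruments(bank)
    scales <- Filter(length, scales)
  }
  oi <- do.call(rbind, lapply(names(scales), function(s) {
    cols <- scales[[s]]
    cc <- stats::complete.cases(X[, cols, drop = FALSE])
    summed <- rowSums(X[cc, cols, drop = FALSE])
    sc <- eap_scores(X[cc, cols, drop = FALSE], bank, grid = grid)
    data.frame(scale = s, r = stats::cor(summed, sc$theta_eap),
               n = sum(cc), stringsAsFactors = FALSE)
  }))
  ns <- length(scales)
  between <- matrix(NA_real_, ns, ns, dimnames = list(names(scales),
                                                      names(scales)))
  overlap <- matrix(0L, ns, ns, dimnames = dimnames(between))
  note <- matrix("", ns, ns, dimnames = dimnames(between))
  diag(between) <- 1
  for (i in seq_len(ns - 1L)) for (j in (i + 1L):ns) {
    si <- scales[[i]]; sj <- scales[[j]]
    shared <- intersect(si, sj)
    overlap[i, j] <- overlap[j, i] <- length(shared)
    if (all(si %in% sj) || all(sj %in% si)) {
      note[i, j] <- note[j, i] <- "nested"
      next
    }
    if (length(shared)) {
      if (length(si) >= length(sj)) si <- setdiff(si, shared) else
        sj <- setdiff(sj, shared)
      note[i, j] <- note[j, i] <- "corrected"
    }
    cc <- stats::complete.cases(X[, c(si, sj), drop = FALSE])
    between[i, j] <- between[j, i] <-
      stats::cor(rowSums(X[cc, si, drop = FALSE]),
                 rowSums(X[cc, sj, drop = FALSE]))
  }
  list(observed_irt = oi, between = between, overlap = overlap, note = note)
}

#' Rescale summed scores to 0-100
#'
#' `100 (summed - min) / (max - min)` over an instrument; persons with any
#' missing response within the instrument get NA.
#'
#' @param data A `response_data` or numeric matrix.
#' @param bank An [item_bank()].
#' @param instrument_id Instrument label.
#' @return Numeric vector of rescaled scores, NA for incomplete persons.
#' @export
rescale_summed <- function(data, bank, instrument_id) {
  X <- if (inherits(data, "response_data")) data$responses else as.matrix(data)
  items <- instrument_items(bank, instrument_id)
  ids <- intersect(vapply(items, `[[`, "", "item_id"), colnames(X))
  if (!length(ids)) stop("unknown instrument or no items in data")
  maxs <- sum(vapply(bank$items[ids], function(it) it$n_cat - 1L, 0L))
  if (maxs == 0) stop("zero-range instrument")
  Xi <- X[, ids, drop = FALSE]
  summed <- rowSums(Xi)                       # NA when any item missing
  100 * summed / maxs
}

#' Cross-instrument congruence of standardized scores
#'
#' The validation exercise of a common metric: persons who answered several
#' instruments are scored per instrument (standardized EAP scores and
#' rescaled 0-100 summed scores), and all instrument pairs are compared by
#' paired t-tests with Bonferroni correction (divisor = number of pairs per
#' scoring method) and paired Cohen's d (mean difference / SD of
#' differences).  On a well-linked metric the IRT-score effect sizes should
#' be trivial (|d| < 0.20) even where summed-score effects are large.
#'
#' @param data A `response_data` or numeric matrix.
#' @param bank An [item_bank()] with its metric origin set.
#' @param instruments Character vector (>= 2) of instruments to compare.
#' @param alpha Significance level after Bonferroni correction.
#' @param grid A [quad_grid()].
#' @return List: `summary` (per instrument: n, means and SDs of both
#'   scores), `pairs` (per pair and scoring method: n, mean_diff, d,
#'   p_raw, p_bonf, significant), `d_range` (per method range of |d|).
#' @export
congruence_report <- function(data, bank, instruments, alpha = 0.05,
                              grid = quad_grid()) {
  if (length(instruments) < 2L) stop("need at least two instruments")
  X <- if (inherits(data, "response_data")) data$responses else as.matrix(data)
  n <- nrow(X)
  irt <- summed <- matrix(NA_real_, n, length(instruments),
                          dimnames = list(NULL, instruments))
  for (s in instruments) {
    sc <- eap_scores(X, bank, instrument_id = s, grid = grid)
    irt[, s] <- ifelse(sc$all_missing, NA, standardize_score(sc$theta_eap,
                                                             bank))
    summed[, s] <- rescale_summed(X, bank, s)
  }
  summary <- data.frame(
    instrument = instruments,
    n_irt = colSums(!is.na(irt)), n_summed = colSums(!is.na(summed)),
    irt_mean = colMeans(irt, na.rm = TRUE),
    irt_sd = apply(irt, 2L, stats::sd, na.rm = TRUE),
    summed_mean = colMeans(summed, na.rm = TRUE),
    summed_sd = apply(summed, 2L, stats::sd, na.rm = TRUE),
    stringsAsFactors = FALSE, row.names = NULL)
  cmb <- utils::combn(instruments, 2L)
  n_pairs <- ncol(cmb)
  rows <- list()
  for (method in c("irt", "summed")) {
    M <- if (method == "irt") irt else summed
    for (q in seq_len(n_pairs)) {
      a <- cmb[1, q]; b <- cmb[2, q]
      cc <- stats::complete.cases(M[, c(a, b)])
      dd <- M[cc, a] - M[cc, b]
      if (identical(a, b) || stats::sd(dd) == 0) {
        d <- 0; p <- 1
      } else {
        tt <- stats::t.test(dd)
        d <- mean(dd) / stats::sd(dd)
        p <- tt$p.value
      }
      rows[[length(rows) + 1L]] <- data.frame(
        instrument_1 = a, instrument_2 = b, method = method, n = sum(cc),
        mean_diff = mean(dd), d = d, p_raw = p,
        p_bonf = min(1, p * n_pairs), stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  pairs$significant <- pairs$p_bonf < alpha
  d_range <- vapply(c("irt", "summed"), function(m)
    range(abs(pairs$d[pairs$method == m])), numeric(2))
  list(summary = summary, pairs = pairs, d_range = d_range)
}
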