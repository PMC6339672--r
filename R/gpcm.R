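#' GPCM category response probabilities
#'
#' Computes, for one item, the generalized partial credit probabilities
#' \deqn{P(X = k \mid \theta) = \frac{\exp\{\sum_{v=1}^{k} a(\theta - b_v)\}}
#'   {\sum_{c=0}^{m} \exp\{\sum_{v=1}^{c} a(\theta - b_v)\}},}
#' with the empty sum (category 0) equal to zero.  The partial credit model
#' is the special case `a = 1`.  If `group` matches a subgroup override on
#' the item, the override parameters are used.
#'
#' @param item An [item_params()] object.
#' @param theta Numeric vector of latent values (logits).
#' @param group Optional group label for subgroup parameter resolution.
#' @return A `length(theta) x n_cat` matrix of probabilities; rows sum to 1.
#' @export
gpcm_probs <- function(item, theta, group = NULL) {
  if (any(!is.finite(theta))) stop("theta must be finite")
  pr <- resolve_params(item, group)
  if (pr$a <= 0) stop("invalid parameter: non-positive discrimination")
  m <- length(pr$b)
  k <- 0:m
  # eta_k(theta) = a * (k*theta - B_k), B_k = sum_{v<=k} b_v
  Bk <- c(0, cumsum(pr$b))
  eta <- pr$a * (outer(theta, k) - matrix(Bk, length(theta), m + 1L,
                                          byrow = TRUE))
  eta <- eta - apply(eta, 1L, max)           # log-sum-exp stabilization
  e <- exp(eta)
  p <- e / rowSums(e)
  dimnames(p) <- list(NULL, as.character(k))
  p
}

#' Expected item score \eqn{T_j(\theta) = \sum_k k P_k(\theta)}
#'
#' Monotonically nondecreasing in `theta`, with range \eqn{[0, m]}.
#'
#' @inheritParams gpcm_probs
#' @return Numeric vector, one value per `theta`.
#' @export
expected_score <- function(item, theta, group = NULL) {
  p <- gpcm_probs(item, theta, group)
  drop(p %*% (seq_len(ncol(p)) - 1))
}

#' Fisher information of a GPCM item
#'
#' For the GPCM with common slope across steps, the item information equals
#' \eqn{a^2 \mathrm{Var}(X \mid \theta)}.
#'
#' @inheritParams gpcm_probs
#' @return Nonnegative numeric vector.
#' @export
item_information <- function(item, theta, group = NULL) {
  pr <- resolve_params(item, group)
  p <- gpcm_probs(item, theta, group)
  k <- seq_len(ncol(p)) - 1
  mu <- drop(p %*% k)
  v <- drop(p %*% k^2) - mu^2
  pr$a^2 * pmax(v, 0)
}

#' Scale characteristic curve (SCC)
#'
#' Expected summed score of an instrument as a function of the latent value:
#' the sum of [expected_score()] over the instrument's items.  Its inverse
#' ([invert_scc()]) is the raw-summed-score-to-theta crosswalk.
#'
#' @param bank An [item_bank()].
#' @param instrument_id Instrument label (must exist in the bank).
#' @param theta Numeric vector of latent values.
#' @param group Optional group label.
#' @return Numeric vector of expected summed scores.
#' @export
scale_characteristic <- function(bank, instrument_id, theta, group = NULL) {
  items <- instrument_items(bank, instrument_id)
  Reduce(`+`, lapply(items, expected_score, theta = theta, group = group))
}

#' Invert a scale characteristic curve
#'
#' Finds the `theta` at which the SCC equals a given summed score by
#' monotone root bracketing (`uniroot`) on the grid support.  Scores at the
#' exact floor or ceiling of the scale map to the support endpoints and are
#' flagged as boundary solutions.
#'
#' @inheritParams scale_characteristic
#' @param summed_score Raw summed score in `[0, sum(m_j)]`.
#' @param range Latent support searched (default `c(-8, 8)`).
#' @param tol Root tolerance.
#' @return List with `theta` and logical `boundary`.
#' @export
invert_scc <- function(bank, instrument_id, summed_score, range = c(-8, 8),
                       tol = 1e-8, group = NULL) {
  items <- instrument_items(bank, instrument_id)
  max_score <- sum(vapply(items, function(it) it$n_cat - 1L, 0L))
  if (summed_score < 0 || summed_score > max_score)
    stop("summed score outside [0, ", max_score, "]")
  f <- function(th) scale_characteristic(bank, instrument_id, th, group) -
    summed_score
  lo <- f(range[1]); hi <- f(range[2])
  if (summed_score <= 0 || lo >= 0)
    return(list(theta = range[1], boundary = TRUE))
  if (summed_score >= max_score || hi <= 0)
    return(list(theta = range[2], boundary = TRUE))
  r <- stats::uniroot(f, interval = range, tol = tol)
  list(theta = r$root, boundary = FALSE)
}
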