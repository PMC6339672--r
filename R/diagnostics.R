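# Pre-calibration assumption checks: kernel-smoothed monotonicity of item
# score curves, a mixed polychoric/polyserial/Pearson correlation matrix,
# and an essential-unidimensionality screen via hierarchical exploratory
# factor analysis (Schmid-Leiman orthogonalization, omega-hierarchical and
# explained common variance).

# ---- Gauss-Legendre nodes (Golub-Welsch), cached -------------------------
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n = 48L) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  i <- seq_len(n - 1L)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- beta
  J[cbind(i + 1L, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  res <- list(nodes = rev(e$values), weights = rev(2 * e$vectors[1L, ]^2))
  .gl_cache[[key]] <- res
  res
}

# standard bivariate normal CDF P(X <= a, Y <= b) by one-dimensional
# Gauss-Legendre quadrature of dnorm(x) * pnorm((b - rho x)/s)
pbvn <- function(a, b, rho, gl = gauss_legendre()) {
  if (a <= -8 || b <= -8) return(0)
  if (a >= 8) return(stats::pnorm(min(b, 8)))
  if (b >= 8) return(stats::pnorm(a))
  if (abs(rho) > 0.9999) {
    return(if (rho > 0) stats::pnorm(min(a, b)) else
      max(0, stats::pnorm(a) + stats::pnorm(b) - 1))
  }
  s <- sqrt(1 - rho^2)
  # for strong correlations the inner pnorm has a sharp transition around
  # x = b/rho; split the integration interval there so fixed-order
  # Gauss-Legendre stays accurate
  cuts <- -8
  if (abs(rho) > 0.5) {
    ctr <- b / rho
    cuts <- c(cuts, max(-8, min(a, ctr - 6 * s)), max(-8, min(a, ctr + 6 * s)))
  }
  cuts <- sort(unique(c(cuts, a)))
  tot <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    lo <- cuts[i]; hi <- cuts[i + 1L]
    if (hi <= lo) next
    x <- 0.5 * (hi - lo) * gl$nodes + 0.5 * (hi + lo)
    w <- 0.5 * (hi - lo) * gl$weights
    tot <- tot + sum(w * stats::dnorm(x) * stats::pnorm((b - rho * x) / s))
  }
  tot
}

# two-step polychoric: thresholds from the margins, rho by ML on the table
polychoric_rho <- function(x, y) {
  tab <- table(factor(x), factor(y))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
  tabc <- tab
  tabc[tabc == 0] <- 0.5                          # continuity correction
  n <- sum(tabc)
  tx <- stats::qnorm(cumsum(rowSums(tabc) / n))[-nrow(tab)]
  ty <- stats::qnorm(cumsum(colSums(tabc) / n))[-ncol(tab)]
  tx <- c(-Inf, tx, Inf); ty <- c(-Inf, ty, Inf)
  negll <- function(rho) {
    C <- outer(seq_along(tx), seq_along(ty), Vectorize(function(i, j)
      pbvn(tx[i], ty[j], rho)))
    P <- C[-1, -1] - C[-length(tx), -1] - C[-1, -length(ty)] +
      C[-length(tx), -length(ty)]
    -sum(tabc * log(pmax(P, 1e-12)))
  }
  stats::optimize(negll, c(-0.999, 0.999))$minimum
}

# two-step polyserial: thresholds from the ordinal margins, rho by ML
polyserial_rho <- function(cont, ord) {
  z <- (cont - mean(cont)) / stats::sd(cont)
  lev <- sort(unique(ord))
  if (length(lev) < 2L) return(NA_real_)
  k <- match(ord, lev)
  pr <- tabulate(k, length(lev)) / length(k)
  tau <- c(-Inf, stats::qnorm(cumsum(pr))[-length(lev)], Inf)
  negll <- function(rho) {
    s <- sqrt(1 - rho^2)
    up <- stats::pnorm((tau[k + 1L] - rho * z) / s)
    lo <- stats::pnorm((tau[k] - rho * z) / s)
    -sum(log(pmax(up - lo, 1e-12)))
  }
  stats::optimize(negll, c(-0.999, 0.999))$minimum
}

#' Mixed polychoric/polyserial/Pearson correlation matrix
#'
#' Items with at most `category_threshold` observed response options are
#' treated as ordinal; items with more are treated as continuous.  Pairs of
#' ordinal items get a two-step maximum-likelihood polychoric correlation
#' (normal thresholds from the margins, empty cells handled by a 0.5
#' continuity correction); ordinal-continuous pairs get a polyserial
#' correlation; continuous pairs a product-moment correlation.  A
#' non-convergent or undefined estimate falls back to the product-moment
#' value with a log entry.
#'
#' @param data A `response_data` or a numeric persons-by-items matrix.
#' @param category_threshold Maximum number of response options for an item
#'   to be treated as categorical (default 10).
#' @return List: `rho` (correlation matrix), `method` (matrix of
#'   "polychoric"/"polyserial"/"pearson" tags), `log` (character).
#' @export
mixed_correlation_matrix <- function(data, category_threshold = 10L) {
  X <- if (inherits(data, "response_data")) data$responses else as.matrix(data)
  p <- ncol(X)
  if (p < 2L) stop("need at least 2 items")
  nlev <- apply(X, 2L, function(v) length(unique(stats::na.omit(v))))
  ordinal <- nlev <= category_threshold
  rho <- diag(1, p)
  meth <- matrix("", p, p, dimnames = list(colnames(X), colnames(X)))
  logs <- character()
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    cc <- stats::complete.cases(X[, c(i, j)])
    xi <- X[cc, i]; xj <- X[cc, j]
    tag <- if (ordinal[i] && ordinal[j]) "polychoric"
      else if (ordinal[i] || ordinal[j]) "polyserial" else "pearson"
    r <- tryCatch(switch(tag,
      polychoric = polychoric_rho(xi, xj),
      polyserial = if (ordinal[j]) polyserial_rho(xi, xj) else
        polyserial_rho(xj, xi),
      pearson = stats::cor(xi, xj)), error = function(e) NA_real_)
    if (!is.finite(r)) {
      r <- stats::cor(xi, xj)
      logs <- c(logs, sprintf("%s x %s: %s failed, product-moment fallback",
                              colnames(X)[i], colnames(X)[j], tag))
      tag <- "pearson"
    }
    rho[i, j] <- rho[j, i] <- r
    meth[i, j] <- meth[j, i] <- tag
  }
  dimnames(rho) <- dimnames(meth)
  list(rho = rho, method = meth, log = logs)
}

# clip eigenvalues to make a correlation matrix positive semi-definite
psd_smooth <- function(R, eps = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eps) return(list(R = R, smoothed = FALSE))
  v <- pmax(e$values, eps)
  S <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(S))
  list(R = S / tcrossprod(d), smoothed = TRUE)
}

# minres (ULS) exploratory factoring: optimize uniquenesses, loadings from
# the truncated eigendecomposition of the reduced correlation matrix
minres_efa <- function(R, k) {
  p <- ncol(R)
  loadings_from <- function(psi) {
    e <- eigen(R - diag(psi, p), symmetric = TRUE)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
    L
  }
  off <- upper.tri(R)
  obj <- function(psi) {
    L <- loadings_from(psi)
    sum((R - tcrossprod(L))[off]^2)
  }
  smc <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, p))
  psi0 <- pmin(pmax(1 - smc, 0.05), 0.95)
  fit <- stats::nlminb(psi0, obj, lower = 0.005, upper = 0.995)
  L <- loadings_from(fit$par)
  pmin(pmax(L, -0.999), 0.999)
}

#' Hierarchical omega and explained common variance
#'
#' Screens item response data (or a correlation matrix) for essential
#' unidimensionality: extract `n_group_factors` factors by maximum
#' likelihood (minres fallback), rotate obliquely (promax), factor the
#' factor correlations with a single second-order factor, and apply the
#' Schmid-Leiman orthogonalization.  Reports omega-hierarchical
#' \eqn{\omega_h = (\sum g_i)^2 / \mathbf{1}'R\mathbf{1}} (general-factor
#' saturation of the summed score) and the explained common variance
#' \eqn{ECV = \sum g_i^2 / (\sum g_i^2 + \sum \lambda_{group}^2)}, plus the
#' per-group-factor ECVs.  Conventional cutoffs for declaring essential
#' unidimensionality are omega >= 0.70 and ECV >= 0.60.
#'
#' @param data A `response_data`, persons-by-items matrix, or correlation
#'   matrix (square, unit diagonal).
#' @param n_group_factors Number of group factors to extract (default 3).
#' @param category_threshold Passed to [mixed_correlation_matrix()] when
#'   raw data are supplied.
#' @return List: `omega_h`, `ecv_general`, `ecv_group_factors`,
#'   `general_loadings`, `group_loadings`, `phi` (factor correlations),
#'   `n_factors_used`, `smoothed`, `correlation` (the matrix analysed),
#'   `method` (correlation method tags, if computed here).
#' @export
hierarchical_omega_ecv <- function(data, n_group_factors = 3L,
                                   category_threshold = 10L) {
  meth <- NULL
  if (is.matrix(data) && nrow(data) == ncol(data) &&
      all(abs(diag(data) - 1) < 1e-8)) {
    R <- data
  } else {
    mc <- mixed_correlation_matrix(data, category_threshold)
    R <- mc$rho; meth <- mc$method
  }
  p <- ncol(R)
  sm <- psd_smooth(R)
  R <- sm$R
  k <- min(n_group_factors, p - 1L)
  extract <- function(k) tryCatch({
    fa <- stats::factanal(covmat = R, factors = k, rotation = "none")
    matrix(fa$loadings, p, k)
  }, error = function(e) minres_efa(R, k))
  L <- extract(k)
  # drop null factors (SS loadings < 0.1) and re-extract: a rank-deficient
  # structure otherwise leaves arbitrary noise factors behind
  k_used <- max(1L, sum(colSums(L^2) > 0.1))
  if (k_used < k) L <- extract(k_used)
  if (k_used <= 1L) {
    g <- L[, 1]
    if (sum(g) < 0) g <- -g
    Gm <- matrix(0, p, 0)
    phi <- matrix(1, 1, 1)
  } else {
    pm <- stats::promax(L)
    P <- matrix(pm$loadings, p, k_used)
    phi <- solve(crossprod(pm$rotmat))
    phi <- phi / tcrossprod(sqrt(diag(phi)))
    # column signs: orient each factor positively
    sgn <- sign(colSums(P)); sgn[sgn == 0] <- 1
    P <- sweep(P, 2L, sgn, `*`)
    phi <- phi * tcrossprod(sgn)
    gamma <- if (k_used == 2L) {
      rep(sqrt(max(phi[1, 2], 0)), 2L)
    } else {
      as.numeric(minres_efa(psd_smooth(phi)$R, 1L))
    }
    if (sum(gamma) < 0) gamma <- -gamma      # eigen sign is arbitrary
    gamma <- pmin(pmax(gamma, 0), 0.999)
    g <- drop(P %*% gamma)
    Gm <- P %*% diag(sqrt(pmax(1 - gamma^2, 0)), k_used)
    if (sum(g) < 0) g <- -g
  }
  vt <- sum(R)
  omega_h <- (sum(g))^2 / vt
  if (omega_h > 1) { warning("omega_h > 1, clipped"); omega_h <- 1 }
  common <- sum(g^2) + sum(Gm^2)
  ecv_general <- sum(g^2) / common
  ecv_groups <- if (ncol(Gm)) colSums(Gm^2) / common else numeric()
  list(omega_h = omega_h, ecv_general = ecv_general,
       ecv_group_factors = ecv_groups, general_loadings = g,
       group_loadings = Gm, phi = phi, n_factors_used = k_used,
       smoothed = sm$smoothed, correlation = R, method = meth)
}

#' Kernel-smoothed monotonicity check of item score curves
#'
#' For every item, plots (numerically) the Nadaraya-Watson Gaussian-kernel
#' smooth of the item score against the rest score (instrument total minus
#' the item) over complete cases, evaluated on `n_grid` points, and flags
#' the item if the smooth decreases by more than `tol` score units anywhere
#' along the continuum.  Bandwidth defaults to Silverman's rule on the rest
#' scores.
#'
#' @param data A `response_data` or numeric matrix (persons x items);
#'   restrict the columns to co-administered items before calling.
#' @param bandwidth Kernel bandwidth; default Silverman's rule.
#' @param tol Maximum tolerated decrease of the smooth (default 0.05).
#' @param n_grid Evaluation points (default 50).
#' @param min_n Minimum complete observations per item (default 50); items
#'   below are skipped with a log entry.
#' @return List: `curves` (named list of data.frames `rest`, `smooth`),
#'   `flags` (named logical), `skipped` (character).
#' @export
monotonicity_curves <- function(data, bandwidth = NULL, tol = 0.05,
                                n_grid = 50L, min_n = 50L) {
  X <- if (inherits(data, "response_data")) data$responses else as.matrix(data)
  curves <- list(); flags <- logical(); skipped <- character()
  for (j in seq_len(ncol(X))) {
    id <- colnames(X)[j]
    cc <- stats::complete.cases(X)
    y <- X[cc, j]
    rest <- rowSums(X[cc, -j, drop = FALSE])
    if (length(y) < min_n) {
      skipped <- c(skipped, sprintf("%s: only %d complete observations",
                                    id, length(y)))
      next
    }
    # Silverman's density rule undersmooths a regression curve: at registry-
    # typical n the raw rule leaves sampling wiggles of the same order as
    # `tol`.  Doubling it keeps the smooth's noise amplitude well below the
    # flag tolerance while preserving real reversals (which are global).
    h <- if (is.null(bandwidth)) max(2 * stats::bw.nrd0(rest), 1e-6) else
      bandwidth
    # evaluate only where the rest-score distribution has support: kernel
    # estimates outside the central 99% are dominated by a handful of persons
    qs <- stats::quantile(rest, c(0.005, 0.995), names = FALSE)
    grid <- seq(qs[1], qs[2], length.out = n_grid)
    sm <- vapply(grid, function(g) {
      w <- stats::dnorm((rest - g) / h)
      sum(w * y) / sum(w)
    }, 0)
    curves[[id]] <- data.frame(rest = grid, smooth = sm)
    flags[id] <- max(cummax(sm) - sm) > tol
  }
  list(curves = curves, flags = flags, skipped = skipped)
}
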