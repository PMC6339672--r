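# Concurrent marginal-maximum-likelihood calibration of PCM/GPCM item
# parameters across several linked datasets.  All datasets enter one person
# by item matrix with structurally missing entries; each dataset has its own
# latent normal distribution, re-estimated each EM cycle, with the reference
# dataset fixed at N(0, 1) for identification.

#' Estimation options for [concurrent_calibrate()]
#'
#' @param n_quad Number of quadrature nodes (default 61).
#' @param range Latent support (default `c(-8, 8)`).
#' @param tol Absolute log-likelihood convergence tolerance (default 1e-5).
#' @param max_iter Maximum EM cycles (default 500).
#' @param a_bounds Box bounds for discriminations (default `c(0.05, 5)`).
#' @param b_bounds Box bounds for step difficulties (default `c(-10, 10)`).
#' @param sd_floor Lower bound for group SDs (default 0.05).
#' @param verbose Print the log-likelihood each cycle.
#' @return List of options.
#' @export
calib_opts <- function(n_quad = 61L, range = c(-8, 8), tol = 1e-5,
                       max_iter = 500L, a_bounds = c(0.05, 5),
                       b_bounds = c(-10, 10), sd_floor = 0.05,
                       verbose = FALSE) {
  list(n_quad = n_quad, range = range, tol = tol, max_iter = max_iter,
       a_bounds = a_bounds, b_bounds = b_bounds, sd_floor = sd_floor,
       verbose = verbose)
}

# log GPCM category probabilities on the grid: K x Q matrix
logprob_grid <- function(a, b, nodes) {
  m <- length(b)
  k <- 0:m
  eta <- a * (outer(k, nodes) - c(0, cumsum(b)))
  mx <- apply(eta, 2L, max)
  eta <- sweep(eta, 2L, mx)
  sweep(eta, 2L, log(colSums(exp(eta))))
}

# n x Q matrix of per-person conditional log-likelihoods log f(x_i | theta_q).
# `pars` is a list per item: list(a, b, overrides = list(group -> list(a,b)));
# `gid_label` gives each person's group label for override resolution.
conditional_loglik <- function(pars, X, nodes, gid_label = NULL) {
  n <- nrow(X); Q <- length(nodes)
  LL <- matrix(0, n, Q)
  for (j in seq_along(pars)) {
    obs <- which(!is.na(X[, j]))
    if (!length(obs)) next
    xc <- X[obs, j] + 1L
    ov <- pars[[j]]$overrides
    if (is.null(ov) || !length(ov) || is.null(gid_label)) {
      lp <- logprob_grid(pars[[j]]$a, pars[[j]]$b, nodes)
      LL[obs, ] <- LL[obs, ] + lp[xc, , drop = FALSE]
    } else {
      gl <- gid_label[obs]
      rest <- !(gl %in% names(ov))
      if (any(rest)) {
        lp <- logprob_grid(pars[[j]]$a, pars[[j]]$b, nodes)
        LL[obs[rest], ] <- LL[obs[rest], ] + lp[xc[rest], , drop = FALSE]
      }
      for (g in names(ov)) {
        sel <- gl == g
        if (!any(sel)) next
        lp <- logprob_grid(ov[[g]]$a, ov[[g]]$b, nodes)
        LL[obs[sel], ] <- LL[obs[sel], ] + lp[xc[sel], , drop = FALSE]
      }
    }
  }
  LL
}

# posterior over the grid given conditional log-likelihoods and per-person
# log prior weights; returns posterior matrix and the marginal log-likelihood
posterior_from_loglik <- function(LL, log_prior) {
  A <- LL + log_prior
  mx <- apply(A, 1L, max)
  E <- exp(A - mx)
  s <- rowSums(E)
  list(post = E / s, loglik = sum(mx + log(s)))
}

# maximize the expected complete-data likelihood of one item.
# rmat: K x Q expected counts; returns updated list(a, b)
mstep_item <- function(rmat, nodes, a0, b0, est_a, opts) {
  K <- nrow(rmat); m <- K - 1L
  k <- 0:m
  nq <- colSums(rmat)
  kth <- outer(k, nodes)
  negll <- function(par) {
    a <- if (est_a) exp(par[1]) else 1
    b <- if (est_a) par[-1] else par
    eta <- a * (kth - c(0, cumsum(b)))
    mx <- apply(eta, 2L, max)
    logZ <- mx + log(colSums(exp(sweep(eta, 2L, mx))))
    -(sum(rmat * eta) - sum(nq * logZ))
  }
  grad <- function(par) {
    a <- if (est_a) exp(par[1]) else 1
    b <- if (est_a) par[-1] else par
    eta <- a * (kth - c(0, cumsum(b)))
    mx <- apply(eta, 2L, max)
    P <- exp(sweep(eta, 2L, mx))
    P <- sweep(P, 2L, colSums(P), `/`)
    D <- rmat - sweep(P, 2L, nq, `*`)
    gb <- numeric(m)
    cs <- apply(D, 2L, function(col) rev(cumsum(rev(col))))  # K x Q
    for (v in seq_len(m)) gb[v] <- -a * sum(cs[v + 1L, ])
    if (est_a) -c(sum(D * eta), gb) else -gb
  }
  par0 <- if (est_a) c(log(a0), b0) else b0
  lower <- if (est_a) c(log(opts$a_bounds[1]), rep(opts$b_bounds[1], m)) else
    rep(opts$b_bounds[1], m)
  upper <- if (est_a) c(log(opts$a_bounds[2]), rep(opts$b_bounds[2], m)) else
    rep(opts$b_bounds[2], m)
  fit <- stats::optim(par0, negll, grad, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 60L))
  if (est_a) list(a = exp(fit$par[1]), b = fit$par[-1])
  else list(a = 1, b = fit$par)
}

# starting step values from adjacent-category count ratios
start_steps <- function(x, m) {
  counts <- tabulate(x + 1L, nbins = m + 1L) + 0.5
  b <- log(counts[-(m + 1L)] / counts[-1L])
  pmin(pmax(b, -3), 3)
}

# connectivity of datasets through items observed in more than one dataset
data_connected <- function(X, dataset) {
  ds <- unique(dataset)
  if (length(ds) <= 1L) return(TRUE)
  inc <- vapply(ds, function(g)
    colSums(!is.na(X[dataset == g, , drop = FALSE])) > 0L,
    logical(ncol(X)))
  inc <- t(inc)                                   # dataset x item
  seen <- c(TRUE, rep(FALSE, length(ds) - 1L))
  frontier <- 1L
  while (length(frontier)) {
    nxt <- integer()
    for (i in frontier) for (j in which(!seen))
      if (any(inc[i, ] & inc[j, ])) { seen[j] <- TRUE; nxt <- c(nxt, j) }
    frontier <- nxt
  }
  all(seen)
}

data_fingerprint <- function(data) {
  X <- data$responses
  sprintf("%dx%d|%d|%d", nrow(X), ncol(X), sum(X, na.rm = TRUE), sum(is.na(X)))
}

#' Concurrent MML-EM calibration across linked datasets
#'
#' Fits the partial credit model (`"PCM"`, all discriminations fixed at 1)
#' or the generalized partial credit model (`"GPCM"`) to all items of all
#' datasets jointly by an EM algorithm over a quadrature grid.  Latent
#' distributions are normal per dataset; the reference dataset (the first
#' level encountered) is fixed at N(0, 1) and the remaining means/SDs are
#' re-estimated each cycle.  The marginal log-likelihood is checked to be
#' nondecreasing across cycles.
#'
#' @param data A `response_data`.
#' @param design Optional [link_design()]; connectivity is always
#'   re-verified from the observed data.
#' @param model `"GPCM"` (default) or `"PCM"`.
#' @param opts See [calib_opts()].
#' @return Object of class `calibration_result`: fields `bank`, `dists`,
#'   `loglik`, `n_params`, `aic`, `n_iter`, `converged`, `ll_trace`,
#'   `model`, `opts`, `se_table` (NULL; not computed).
#' @export
concurrent_calibrate <- function(data, design = NULL,
                                 model = c("GPCM", "PCM"),
                                 opts = calib_opts()) {
  model <- match.arg(model)
  X <- data$responses
  dataset <- data$persons$dataset
  if (!data_connected(X, dataset))
    stop("linkage error: datasets are not connected by common items")
  J <- ncol(X)
  n_obs_cat <- vapply(seq_len(J), function(j)
    length(unique(stats::na.omit(X[, j]))), 0L)
  if (any(n_obs_cat < 2L))
    stop("items with fewer than 2 observed categories: ",
         paste(colnames(X)[n_obs_cat < 2L], collapse = ", "),
         " (collapse or drop them first)")
  ds <- unique(dataset)
  gid <- match(dataset, ds)
  G <- length(ds)
  grid <- quad_grid(opts$n_quad, opts$range)
  nodes <- grid$nodes
  m <- data$items$n_cat - 1L
  est_a <- model == "GPCM"
  pars <- lapply(seq_len(J), function(j)
    list(a = 1, b = start_steps(stats::na.omit(X[, j]), m[j])))
  mu <- rep(0, G); sd <- rep(1, G)
  obs_idx <- lapply(seq_len(J), function(j) which(!is.na(X[, j])))
  xcat <- lapply(seq_len(J), function(j) X[obs_idx[[j]], j] + 1L)
  ll_trace <- numeric()
  converged <- FALSE
  ll_prev <- -Inf
  for (iter in seq_len(opts$max_iter)) {
    LL <- conditional_loglik(pars, X, nodes)
    lw <- t(vapply(seq_len(G), function(g)
      log(grid_normal_weights(grid, mu[g], sd[g])), numeric(length(nodes))))
    ep <- posterior_from_loglik(LL, lw[gid, , drop = FALSE])
    ll <- ep$loglik
    ll_trace <- c(ll_trace, ll)
    if (ll < ll_prev - max(1e-8, 1e-10 * abs(ll)))
      warning(sprintf("EM log-likelihood decreased at cycle %d (%.6g -> %.6g)",
                      iter, ll_prev, ll))
    if (opts$verbose) message(sprintf("cycle %3d  loglik %.4f", iter, ll))
    if (is.finite(ll_prev) && abs(ll - ll_prev) < opts$tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    post <- ep$post
    # group distribution updates (reference group stays (0, 1))
    for (g in seq_len(G)[-1L]) {
      wq <- colSums(post[gid == g, , drop = FALSE])
      tot <- sum(wq)
      mu[g] <- sum(wq * nodes) / tot
      sd[g] <- max(sqrt(sum(wq * (nodes - mu[g])^2) / tot), opts$sd_floor)
    }
    # item updates
    for (j in seq_len(J)) {
      pj <- post[obs_idx[[j]], , drop = FALSE]
      rmat <- matrix(0, m[j] + 1L, length(nodes))
      for (k in seq_len(m[j] + 1L)) {
        sel <- xcat[[j]] == k
        if (any(sel)) rmat[k, ] <- colSums(pj[sel, , drop = FALSE])
      }
      pars[[j]] <- mstep_item(rmat, nodes, pars[[j]]$a, pars[[j]]$b,
                              est_a, opts)
    }
  }
  if (!converged)
    warning("EM did not converge within ", opts$max_iter, " cycles")
  items <- lapply(seq_len(J), function(j)
    item_params(data$items$item_id[j], pars[[j]]$a, pars[[j]]$b,
                instrument_ids = if (is.na(data$items$instrument[j]))
                  character() else data$items$instrument[j]))
  bank <- item_bank(items)
  dists <- group_dist(ds, mu, sd, reference = ds[1])
  n_params <- sum(m) + if (est_a) J else 0L
  n_params <- n_params + 2L * (G - 1L)
  ll <- ll_trace[length(ll_trace)]
  structure(list(bank = bank, dists = dists, loglik = ll,
                 n_params = n_params, aic = 2 * n_params - 2 * ll,
                 n_iter = length(ll_trace), converged = converged,
                 ll_trace = ll_trace, model = model, opts = opts,
                 grid = grid, fingerprint = data_fingerprint(data),
                 se_table = NULL),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %s, %d items, %d datasets\n", x$model,
              length(x$bank$items), nrow(x$dists)))
  cat(sprintf("  loglik %.2f, AIC %.2f (%d params), %d cycles, converged: %s\n",
              x$loglik, x$aic, x$n_params, x$n_iter, x$converged))
  invisible(x)
}

#' Likelihood-ratio and AIC comparison of nested PCM/GPCM fits
#'
#' @param fit_pcm,fit_gpcm `calibration_result`s fitted to the same data.
#' @return List: `lr_stat`, `df`, `p`, `delta_aic` (AIC_PCM - AIC_GPCM;
#'   positive favours the GPCM).
#' @export
compare_models <- function(fit_pcm, fit_gpcm) {
  if (fit_pcm$fingerprint != fit_gpcm$fingerprint)
    stop("comparison error: fits are not based on the same data")
  lr <- 2 * (fit_gpcm$loglik - fit_pcm$loglik)
  df <- fit_gpcm$n_params - fit_pcm$n_params
  list(lr_stat = lr, df = df,
       p = stats::pchisq(max(lr, 0), df, lower.tail = FALSE),
       delta_aic = fit_pcm$aic - fit_gpcm$aic)
}

# posterior grid matrix + EAP/SD for each person under a fitted model,
# using the fitted group distributions as priors
fit_posterior <- function(fit, data) {
  X <- data$responses
  ds <- fit$dists$dataset
  gid <- match(data$persons$dataset, ds)
  pars <- lapply(fit$bank$items[colnames(X)], function(it)
    list(a = it$a, b = it$b, overrides = it$overrides))
  nodes <- fit$grid$nodes
  LL <- conditional_loglik(pars, X, nodes, gid_label = data$persons$dataset)
  lw <- t(vapply(seq_along(ds), function(g)
    log(grid_normal_weights(fit$grid, fit$dists$mean[g], fit$dists$sd[g])),
    numeric(length(nodes))))
  ep <- posterior_from_loglik(LL, lw[gid, , drop = FALSE])
  eap <- drop(ep$post %*% nodes)
  se <- sqrt(pmax(drop(ep$post %*% nodes^2) - eap^2, 0))
  list(post = ep$post, nodes = nodes, eap = eap, se = se)
}
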