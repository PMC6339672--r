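# Item fit and differential item functioning screening via observed-versus-
# expected item score contrasts (a score-type Lagrange-multiplier-style
# statistic), plus Yen's Q3 local-dependence diagnostics.  Items are flagged
# only when the statistic is significant AND the effect size exceeds a
# threshold, which guards against the high false-alarm rates of pure
# significance tests in large samples.

# Observed-vs-expected contrast for every item, cells = group x EAP bin.
# The item's own response is removed from the posterior (rest-pattern
# posterior): with the item left in, the observed response contaminates its
# own expectation and the statistic is anti-conservative.  Returns one row
# per item with the chi-square-referenced statistic, the effect size ES
# (size-weighted mean absolute observed-expected gap in the worst group,
# divided by the item score range) and the flag.
lm_flag_table <- function(fit, data, grouping, n_bins, alpha, es_threshold,
                          min_group_n, require_groups = 2L) {
  X <- data$responses
  ds <- fit$dists$dataset
  gid <- match(data$persons$dataset, ds)
  nodes <- fit$grid$nodes
  pars <- lapply(fit$bank$items[colnames(X)], function(it)
    list(a = it$a, b = it$b, overrides = it$overrides))
  LL <- conditional_loglik(pars, X, nodes,
                           gid_label = data$persons$dataset)
  lw <- t(vapply(seq_along(ds), function(g)
    log(grid_normal_weights(fit$grid, fit$dists$mean[g], fit$dists$sd[g])),
    numeric(length(nodes))))
  base <- LL + lw[gid, , drop = FALSE]
  ids <- colnames(X)
  rest_quartiles <- identical(grouping, "rest_quartiles")
  skip_row <- function(id, reason)
    data.frame(item_id = id, statistic = NA_real_, df = NA_integer_,
               p = NA_real_, es_dif = NA_real_, focal_group = NA_character_,
               flagged = FALSE, skipped = TRUE, reason = reason,
               stringsAsFactors = FALSE)
  out <- vector("list", length(ids))
  for (j in seq_along(ids)) {
    item <- fit$bank$items[[ids[j]]]
    m <- item$n_cat - 1L
    obs <- which(!is.na(X[, j]))
    skipped_groups <- character()
    if (!rest_quartiles) {
      gl <- as.character(grouping[obs])
      keep_groups <- names(which(table(gl) >= min_group_n))
      skipped_groups <- setdiff(unique(gl), keep_groups)
      sel <- gl %in% keep_groups
      if (length(keep_groups) < require_groups || sum(sel) == 0L) {
        out[[j]] <- skip_row(ids[j], "too few groups with enough respondents")
        next
      }
      obs <- obs[sel]; gl <- gl[sel]
    } else if (length(obs) < require_groups * min_group_n) {
      out[[j]] <- skip_row(ids[j], "too few respondents for trait intervals")
      next
    }
    x <- X[obs, j]
    xc <- x + 1L
    # rest-pattern posterior: subtract the item's own likelihood term,
    # resolved against each person's dataset for subgroup overrides
    dsl <- data$persons$dataset[obs]
    C <- matrix(0, length(obs), length(nodes))
    ovg <- intersect(unique(dsl), names(item$overrides))
    restg <- !(dsl %in% ovg)
    if (any(restg)) {
      lp <- logprob_grid(item$a, item$b, nodes)
      C[restg, ] <- lp[xc[restg], , drop = FALSE]
    }
    for (g in ovg) {
      gi <- dsl == g
      lp <- logprob_grid(item$overrides[[g]]$a, item$overrides[[g]]$b, nodes)
      C[gi, ] <- lp[xc[gi], , drop = FALSE]
    }
    A <- base[obs, , drop = FALSE] - C
    mx <- apply(A, 1L, max)
    E <- exp(A - mx)
    post <- E / rowSums(E)
    # per-person expected item score and variance under the rest posterior
    eexp <- evar <- numeric(length(obs))
    for (g in unique(dsl)) {
      gi <- dsl == g
      tg <- expected_score(item, nodes, group = g)
      t2 <- drop(gpcm_probs(item, nodes, group = g) %*% (0:m)^2)
      pg <- post[gi, , drop = FALSE]
      eexp[gi] <- drop(pg %*% tg)
      evar[gi] <- pmax(drop(pg %*% t2) - eexp[gi]^2, 1e-10)
    }
    theta <- drop(post %*% nodes)
    if (rest_quartiles) {
      # groups are equal-count intervals of the rest-pattern EAP; binning
      # by the full EAP would reintroduce the own-item selection bias
      br <- unique(stats::quantile(theta, seq(0, 1, length.out = n_bins + 1L)))
      gl <- if (length(br) > 2L)
        paste0("Q", as.integer(cut(theta, br, include.lowest = TRUE))) else
        rep("Q1", length(theta))
    }
    n_bins_g <- if (rest_quartiles) 1L else n_bins
    stat <- 0; n_cells <- 0L
    es_g <- setNames(numeric(length(unique(gl))), unique(gl))
    for (g in unique(gl)) {
      gi <- which(gl == g)
      nb <- max(1L, min(n_bins_g, length(unique(theta[gi]))))
      br <- unique(stats::quantile(theta[gi], probs = seq(0, 1, length.out =
                                                           nb + 1L)))
      bins <- if (length(br) > 2L)
        cut(theta[gi], breaks = br, include.lowest = TRUE) else
        factor(rep(1L, length(gi)))
      acc <- 0
      for (b in levels(bins)) {
        bi <- gi[bins == b]
        if (!length(bi)) next
        o <- sum(x[bi]); e <- sum(eexp[bi]); v <- sum(evar[bi])
        stat <- stat + (o - e)^2 / v
        n_cells <- n_cells + 1L
        acc <- acc + length(bi) * abs(mean(x[bi]) - mean(eexp[bi]))
      }
      es_g[g] <- acc / length(gi) / m
    }
    df <- max(n_cells - 1L, 1L)
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
    es <- max(es_g)
    out[[j]] <- data.frame(item_id = ids[j], statistic = stat, df = df,
                           p = p, es_dif = es,
                           focal_group = names(which.max(es_g)),
                           flagged = p < alpha && es > es_threshold,
                           skipped = FALSE,
                           reason = if (length(skipped_groups))
                             paste("groups below minimum n:",
                                   paste(skipped_groups, collapse = ","))
                           else "", stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Differential item functioning screen (observed-vs-expected LM-type test)
#'
#' For every item, compares observed with model-expected item scores across
#' person groups, with respondents binned by their EAP estimate within group
#' to control for trait level.  The statistic is referred to a chi-square
#' distribution; the accompanying effect size `ES_DIF` is the sample-size
#' weighted mean absolute observed-expected gap in the most deviant group,
#' normalized by the item's score range.  An item is flagged only if the
#' test is significant at `alpha` *and* `ES_DIF > es_threshold`.
#'
#' @param fit A `calibration_result`.
#' @param data The `response_data` used for the fit.
#' @param grouping Person-level group labels (default: dataset).
#' @param alpha Significance level (default 0.05).
#' @param es_threshold Effect-size threshold (default 0.05).
#' @param n_bins EAP bins per group (default 4).
#' @param min_group_n Minimum respondents per group per item (default 50);
#'   smaller groups are dropped and logged in `reason`.
#' @return Flag table: one row per item with `statistic`, `df`, `p`,
#'   `es_dif`, `focal_group`, `flagged`, `skipped`, `reason`.
#' @export
lm_dif_test <- function(fit, data, grouping = data$persons$dataset,
                        alpha = 0.05, es_threshold = 0.05, n_bins = 4L,
                        min_group_n = 50L) {
  lm_flag_table(fit, data, grouping, n_bins, alpha, es_threshold,
                min_group_n, require_groups = 2L)
}

#' Item fit screen (observed-vs-expected across trait levels)
#'
#' Same machinery as [lm_dif_test()] with the grouping replaced by
#' equal-count EAP-score intervals over all respondents (default 4), so the
#' contrast is between the empirical and model-implied item score curves:
#' the statistic has `bins - 1` degrees of freedom and the effect size is
#' the largest absolute observed-expected gap across the intervals,
#' normalized by the item's score range.
#'
#' @inheritParams lm_dif_test
#' @return Flag table with one row per item.
#' @export
item_fit_lm <- function(fit, data, alpha = 0.05, es_threshold = 0.05,
                        n_bins = 4L, min_group_n = 50L) {
  lm_flag_table(fit, data, grouping = "rest_quartiles",
                n_bins = n_bins, alpha = alpha, es_threshold = es_threshold,
                min_group_n = min_group_n, require_groups = 2L)
}

#' Assign subgroup item parameters to flagged items and refit
#'
#' Every flagged item receives free parameters for its focal group: the
#' focal group's responses are split into a virtual item, the whole model is
#' recalibrated, and the virtual item's estimates are folded back as a
#' subgroup override.  The flagged item thereby stops acting as an anchor
#' for its focal group.
#'
#' @param fit A `calibration_result`.
#' @param flags Flag table from [lm_dif_test()]; only `flagged` rows are used.
#' @param grouping Person-level group labels (default: dataset).
#' @param data The `response_data` used for the fit.
#' @return A new `calibration_result` whose bank carries subgroup overrides.
#' @export
assign_group_parameters <- function(fit, flags, data,
                                    grouping = data$persons$dataset) {
  fl <- flags[!is.na(flags$flagged) & flags$flagged, , drop = FALSE]
  if (!nrow(fl)) return(fit)
  X <- data$responses
  items <- data$items
  for (r in seq_len(nrow(fl))) {
    id <- fl$item_id[r]; g <- fl$focal_group[r]
    j <- match(id, colnames(X))
    vcol <- matrix(NA_integer_, nrow(X), 1L,
                   dimnames = list(NULL, paste0(id, "@", g)))
    focal <- grouping == g & !is.na(X[, j])
    vcol[focal, 1L] <- X[focal, j]
    X[focal, j] <- NA_integer_
    X <- cbind(X, vcol)
    items <- rbind(items, data.frame(item_id = colnames(vcol),
                                     instrument = items$instrument[j],
                                     n_cat = items$n_cat[j],
                                     stringsAsFactors = FALSE))
  }
  data2 <- response_data(X, data$persons, items)
  refit <- concurrent_calibrate(data2, model = fit$model, opts = fit$opts)
  bank_items <- refit$bank$items
  for (r in seq_len(nrow(fl))) {
    id <- fl$item_id[r]; g <- fl$focal_group[r]
    vid <- paste0(id, "@", g)
    ov <- bank_items[[vid]]
    bank_items[[id]]$overrides[[g]] <- list(a = ov$a, b = ov$b)
    bank_items[[vid]] <- NULL
  }
  refit$bank <- item_bank(unname(bank_items))
  refit
}

#' Yen's Q3 local-dependence matrix
#'
#' Residuals `x_ij - T_j(theta_hat_i)` (EAP point estimates under the fitted
#' model, subgroup overrides resolved by dataset) are correlated across
#' items over the persons observed on both items of a pair.  Pairs with
#' `|Q3|` above the threshold are flagged; pairs with too little overlap are
#' set missing and logged.
#'
#' @param fit A `calibration_result`.
#' @param data The `response_data` used for the fit.
#' @param threshold Flagging threshold (default 0.25, i.e. 6.25% shared
#'   residual variance).
#' @param min_n Minimum pairwise-complete persons per pair (default 50).
#' @return List: `q3` (symmetric matrix, NA diagonal), `n` (pairwise
#'   overlap counts), `flagged` (data.frame `item_i`, `item_j`, `q3`, `n`),
#'   `low_overlap` (pairs set missing).
#' @export
q3_matrix <- function(fit, data, threshold = 0.25, min_n = 50L) {
  X <- data$responses
  fp <- fit_posterior(fit, data)
  gl <- data$persons$dataset
  E <- X * NA_real_
  for (j in seq_len(ncol(X))) {
    item <- fit$bank$items[[colnames(X)[j]]]
    obs <- which(!is.na(X[, j]))
    if (!length(obs)) next
    gset <- if (length(item$overrides))
      intersect(unique(gl[obs]), names(item$overrides)) else character()
    e <- expected_score(item, fp$eap[obs])
    for (g in gset) {
      gi <- gl[obs] == g
      e[gi] <- expected_score(item, fp$eap[obs][gi], group = g)
    }
    E[obs, j] <- X[obs, j] - e
  }
  q3 <- suppressWarnings(stats::cor(E, use = "pairwise.complete.obs"))
  nmat <- crossprod(!is.na(E))
  low <- which(nmat < min_n & upper.tri(nmat), arr.ind = TRUE)
  q3[nmat < min_n] <- NA_real_
  diag(q3) <- NA_real_
  up <- which(upper.tri(q3) & !is.na(q3) & abs(q3) > threshold, arr.ind = TRUE)
  flagged <- data.frame(item_i = colnames(X)[up[, 1]],
                        item_j = colnames(X)[up[, 2]],
                        q3 = q3[up], n = nmat[up], stringsAsFactors = FALSE)
  low_overlap <- data.frame(item_i = colnames(X)[low[, 1]],
                            item_j = colnames(X)[low[, 2]],
                            n = nmat[low], stringsAsFactors = FALSE)
  list(q3 = q3, n = nmat, flagged = flagged, low_overlap = low_overlap)
}
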