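# File formats: wide response CSV, item metadata CSV, parameter-bank JSON
# and flat CSV, group-distribution CSV, crosswalk CSVs, JSON run configs
# and JSON-lines logs.

#' Write / read wide-format response data
#'
#' One row per person: `person_id`, `dataset`, then one column per item;
#' blank cells are missing.  The roundtrip is lossless, including missing
#' cells.  On reading, categories are validated against the item metadata
#' (`item_id`, `instrument`, `n_cat`), when provided.
#'
#' @param data A `response_data`.
#' @param path CSV path.
#' @export
write_responses <- function(data, path) {
  df <- data.frame(person_id = data$persons$person_id,
                   dataset = data$persons$dataset,
                   data$responses, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_responses
#' @param metadata Optional item metadata data.frame or CSV path with
#'   columns `item_id`, `instrument`, `n_cat`.
#' @return `read_responses` returns a `response_data`.
#' @export
read_responses <- function(path, metadata = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("person_id", "dataset")
  if (!all(need %in% names(df)))
    stop("response CSV must have person_id and dataset columns")
  items_df <- NULL
  if (!is.null(metadata)) {
    items_df <- if (is.character(metadata))
      utils::read.csv(metadata, stringsAsFactors = FALSE) else metadata
    unknown <- setdiff(setdiff(names(df), need), items_df$item_id)
    if (length(unknown))
      stop("unknown item column(s): ", paste(unknown, collapse = ", "))
    items_df <- items_df[match(setdiff(names(df), need), items_df$item_id), ]
  }
  X <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  storage.mode(X) <- "integer"
  response_data(X, persons = df[need], items = items_df)
}

#' Write item metadata
#' @param data A `response_data`.
#' @param path CSV path.
#' @export
write_item_metadata <- function(data, path) {
  utils::write.csv(data$items, path, row.names = FALSE)
  invisible(path)
}

#' Serialize an item bank as JSON
#'
#' @param bank An [item_bank()].
#' @param path JSON path.
#' @export
write_bank_json <- function(bank, path) {
  items <- lapply(bank$items, function(it) list(
    item_id = it$item_id, instrument_ids = as.list(it$instrument_ids),
    a = it$a, b = it$b,
    overrides = lapply(it$overrides, function(o) list(a = o$a, b = o$b))))
  jsonlite::write_json(list(theta0 = bank$theta0, items = unname(items)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_bank_json
#' @return `read_bank_json` returns an [item_bank()].
#' @export
read_bank_json <- function(path) {
  x <- jsonlite::read_json(path)
  items <- lapply(x$items, function(it)
    item_params(it$item_id, it$a, unlist(it$b),
                instrument_ids = unlist(it$instrument_ids),
                overrides = lapply(it$overrides, function(o)
                  list(a = o$a, b = unlist(o$b)))))
  item_bank(items, theta0 = x$theta0)
}

#' Serialize an item bank as a flat CSV
#'
#' One row per item (and one extra row per subgroup override, keyed by the
#' `group` column): `item_id`, `group` (empty = default parameters),
#' `instruments` (semicolon-separated), `a`, `b_1..b_m`.
#'
#' @inheritParams write_bank_json
#' @export
write_bank_csv <- function(bank, path) {
  mmax <- max(vapply(bank$items, function(it) it$n_cat - 1L, 0L))
  rows <- list()
  for (it in bank$items) {
    pad <- function(b) c(b, rep(NA_real_, mmax - length(b)))
    rows[[length(rows) + 1L]] <-
      data.frame(item_id = it$item_id, group = "",
                 instruments = paste(it$instrument_ids, collapse = ";"),
                 a = it$a, t(pad(it$b)), stringsAsFactors = FALSE)
    for (g in names(it$overrides)) {
      o <- it$overrides[[g]]
      rows[[length(rows) + 1L]] <-
        data.frame(item_id = it$item_id, group = g,
                   instruments = paste(it$instrument_ids, collapse = ";"),
                   a = o$a, t(pad(o$b)), stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  names(df)[-(1:4)] <- paste0("b_", seq_len(mmax))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_bank_csv
#' @param theta0 Optional metric origin to attach.
#' @export
read_bank_csv <- function(path, theta0 = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  bcols <- grep("^b_", names(df))
  main <- df[is.na(df$group) | df$group == "", , drop = FALSE]
  items <- lapply(seq_len(nrow(main)), function(i) {
    r <- main[i, ]
    b <- as.numeric(r[bcols]); b <- b[!is.na(b)]
    ovr <- df[df$item_id == r$item_id & !is.na(df$group) & df$group != "", ,
              drop = FALSE]
    overrides <- list()
    for (k in seq_len(nrow(ovr))) {
      ob <- as.numeric(ovr[k, bcols]); ob <- ob[!is.na(ob)]
      overrides[[ovr$group[k]]] <- list(a = ovr$a[k], b = ob)
    }
    item_params(r$item_id, r$a, b,
                instrument_ids = strsplit(r$instruments, ";")[[1]],
                overrides = overrides)
  })
  item_bank(items, theta0 = theta0)
}

#' Write group latent distributions as CSV
#' @param dists A [group_dist()].
#' @param path CSV path.
#' @export
write_group_dists <- function(dists, path) {
  utils::write.csv(as.data.frame(dists), path, row.names = FALSE)
  invisible(path)
}

#' Summed-score-to-metric crosswalk table
#'
#' One row per attainable raw summed score of the instrument, with the
#' corresponding latent value (SCC inverse) and, when the metric origin is
#' set, the standardized score.
#'
#' @param bank An [item_bank()].
#' @param instrument_id Instrument label.
#' @param range Latent support for the inversion.
#' @return data.frame: `summed_score`, `theta`, `standardized`, `boundary`.
#' @export
crosswalk_table <- function(bank, instrument_id, range = c(-8, 8)) {
  items <- instrument_items(bank, instrument_id)
  maxs <- sum(vapply(items, function(it) it$n_cat - 1L, 0L))
  rows <- lapply(0:maxs, function(s) {
    r <- invert_scc(bank, instrument_id, s, range = range)
    data.frame(summed_score = s, theta = r$theta,
               standardized = if (!is.null(bank$theta0))
                 10 * (r$theta - bank$theta0) else NA_real_,
               boundary = r$boundary)
  })
  do.call(rbind, rows)
}

# ---- run configuration ----------------------------------------------------

default_thresholds <- function() {
  list(min_count = 20, q3 = 0.25, es_dif = 0.05, alpha = 0.05,
       omega = 0.70, ecv = 0.60, cr = 0.70, congruence_es = 0.20)
}

#' Read a JSON run configuration
#'
#' Merges the file over the package defaults: decision thresholds
#' (`min_count` 20, `q3` 0.25, `es_dif` 0.05, `alpha` 0.05, `omega` 0.70,
#' `ecv` 0.60, `cr` 0.70, `congruence_es` 0.20), model `"GPCM"`, a 61-node
#' quadrature on \[-8, 8\], and `seed` 1.  (YAML configs are not supported;
#' use JSON.)
#'
#' @param path JSON path, or `NULL` for pure defaults.
#' @return Config list with elements `seed`, `model`, `quad`, `thresholds`,
#'   `sim`, `paths`, ... and a `hash` of the merged config.
#' @export
read_config <- function(path = NULL) {
  cfg <- list(seed = 1L, model = "GPCM",
              quad = list(n = 61L, range = c(-8, 8)),
              thresholds = default_thresholds(),
              sim = list(), paths = list())
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (nm in names(user)) {
      if (is.list(cfg[[nm]]) && is.list(user[[nm]]))
        cfg[[nm]] <- utils::modifyList(cfg[[nm]], user[[nm]])
      else cfg[[nm]] <- user[[nm]]
    }
  }
  th <- cfg$thresholds
  if (th$q3 < 0 || th$q3 > 1 || th$alpha <= 0 || th$alpha >= 1 ||
      th$min_count < 1)
    stop("thresholds outside valid ranges")
  cfg$hash <- config_hash(cfg)
  cfg
}

# polynomial rolling hash of the serialized config, for provenance stamping
# (kept in doubles below 2^53 so the arithmetic is exact)
config_hash <- function(cfg) {
  cfg$hash <- NULL
  bytes <- utf8ToInt(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA))
  h <- 5381
  for (b in bytes) h <- (h * 127 + b) %% 2147483647
  sprintf("%08x", h)
}

# append one JSON line to a log file
log_line <- function(path, event, ...) {
  if (is.null(path)) return(invisible())
  rec <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                event = event), list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
      file = path, append = TRUE, sep = "")
  invisible()
}
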