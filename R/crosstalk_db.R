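# Complete device x inducer crosstalk parameter database: schema, validation,
# CSV/JSON persistence, an import adapter for externally deposited parameter
# sets, and cognate-normalised summaries.

#' Identifiers of the six characterised quorum-sensing receiver devices
#' @export
ahl_devices <- c("rhl", "lux", "tra", "las", "cin", "rpa")

#' Identifiers of the six AHL inducers
#' @export
ahl_inducers <- c("C4_HSL", "3OC6_HSL", "3OC8_HSL", "3OC12_HSL",
                  "3OHC14_HSL", "pC_HSL")

#' Cognate device-to-inducer map of the characterised systems
#'
#' Each receiver device's natural AHL partner, following the systems' source
#' organisms: rhl/C4 HSL, lux/3OC6 HSL, tra/3OC8 HSL, las/3OC12 HSL,
#' cin/3OHC14 HSL, rpa/pC HSL. Any conflicting pairing in an imported
#' parameter file is flagged at import time rather than silently overridden.
#'
#' @return Named character vector, names = device ids, values = inducer ids.
#' @export
ahl_cognate_map <- function() {
  stats::setNames(ahl_inducers, ahl_devices)
}

db_param_cols <- c("a", "b", "ec50_M", "h")

#' Construct a crosstalk parameter database
#'
#' The database is COMPLETE by construction: it must hold exactly one fitted
#' transfer-function record for every (device, inducer) pair — cognate and
#' non-cognate alike — so a 6-device, 6-inducer library carries 36 records.
#'
#' @param params Data frame with one row per pair and columns `device_id`,
#'   `inducer_id`, `a`, `b`, `ec50_M`, `h`, and logical/0-1 `saturated`
#'   (optionally `converged`, `fit_residual`).
#' @param cognate Named character vector mapping each device to its cognate
#'   inducer.
#' @param devices,inducers Optional identifier orderings; default to order of
#'   first appearance in `params`.
#' @return An object of class `crosstalk_db`.
#' @export
crosstalk_db <- function(params, cognate, devices = NULL, inducers = NULL) {
  need <- c("device_id", "inducer_id", db_param_cols, "saturated")
  missing_cols <- setdiff(need, names(params))
  if (length(missing_cols) > 0L) {
    stop(sprintf("database lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  params$device_id <- as.character(params$device_id)
  params$inducer_id <- as.character(params$inducer_id)
  params$saturated <- as.logical(params$saturated)
  if (is.null(devices)) devices <- unique(params$device_id)
  if (is.null(inducers)) inducers <- unique(params$inducer_id)
  if (anyDuplicated(devices) || anyDuplicated(inducers)) {
    stop("device/inducer identifiers must be unique", call. = FALSE)
  }

  key <- paste(params$device_id, params$inducer_id, sep = ":")
  dup <- key[duplicated(key)]
  if (length(dup) > 0L) {
    stop(sprintf("duplicate (device, inducer) record(s): %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  expect_keys <- as.vector(outer(devices, inducers, paste, sep = ":"))
  miss <- setdiff(expect_keys, key)
  if (length(miss) > 0L) {
    stop(sprintf("database incomplete, missing pair(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(key, expect_keys)
  if (length(extra) > 0L) {
    stop(sprintf("record(s) outside the device/inducer lists: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }

  cognate <- stats::setNames(as.character(cognate), names(cognate))
  if (!setequal(names(cognate), devices)) {
    stop("cognate map must name every device exactly once", call. = FALSE)
  }
  unknown <- setdiff(unname(cognate), inducers)
  if (length(unknown) > 0L) {
    stop(sprintf("cognate inducer(s) not in inducer list: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }

  bad <- which(!is.finite(params$ec50_M) | params$ec50_M <= 0 |
                 !is.finite(params$h) | params$h <= 0 |
                 !is.finite(params$a) | !is.finite(params$b))
  if (length(bad) > 0L) {
    stop(sprintf("invalid parameter values for pair(s): %s",
                 paste(key[bad], collapse = ", ")), call. = FALSE)
  }

  ord <- order(match(params$device_id, devices),
               match(params$inducer_id, inducers))
  params <- params[ord, , drop = FALSE]
  rownames(params) <- NULL
  structure(list(devices = devices, inducers = inducers,
                 params = params, cognate = cognate[devices]),
            class = "crosstalk_db")
}

#' @export
print.crosstalk_db <- function(x, ...) {
  cat(sprintf("Crosstalk database: %d devices x %d inducers = %d records\n",
              length(x$devices), length(x$inducers), nrow(x$params)))
  cat("devices:", paste(x$devices, collapse = ", "), "\n")
  cat("inducers:", paste(x$inducers, collapse = ", "), "\n")
  invisible(x)
}

#' Retrieve one pair's fitted parameters from a database
#'
#' @param db A [crosstalk_db()].
#' @param device,inducer Identifiers.
#' @return A [dr_params()].
#' @export
db_params <- function(db, device, inducer) {
  i <- which(db$params$device_id == device & db$params$inducer_id == inducer)
  if (length(i) != 1L) {
    stop(sprintf("unknown (device, inducer) pair: (%s, %s)", device, inducer),
         call. = FALSE)
  }
  row <- db$params[i, ]
  dr_params(a = row$a, b = row$b, ec50 = row$ec50_M, h = row$h,
            saturated = row$saturated,
            fit_residual = if ("fit_residual" %in% names(row))
              row$fit_residual else NA_real_,
            converged = if ("converged" %in% names(row))
              row$converged else NA)
}

db_df_from_any <- function(params) {
  params <- as.data.frame(params, stringsAsFactors = FALSE)
  for (col in c(db_param_cols, "fit_residual")) {
    if (col %in% names(params)) params[[col]] <- as.numeric(params[[col]])
  }
  for (col in c("saturated", "converged", "cognate")) {
    if (col %in% names(params)) {
      v <- params[[col]]
      params[[col]] <- if (is.character(v)) {
        toupper(v) %in% c("1", "TRUE", "T", "YES")
      } else as.logical(as.numeric(v) != 0 | (is.logical(v) & v))
    }
  }
  params
}

cognate_from_column <- function(params) {
  cg <- params[params$cognate, , drop = FALSE]
  dup <- cg$device_id[duplicated(cg$device_id)]
  if (length(dup) > 0L) {
    stop(sprintf("device(s) with more than one cognate inducer: %s",
                 paste(unique(dup), collapse = ", ")), call. = FALSE)
  }
  no_cog <- setdiff(unique(params$device_id), cg$device_id)
  if (length(no_cog) > 0L) {
    stop(sprintf("device(s) without a cognate inducer: %s",
                 paste(no_cog, collapse = ", ")), call. = FALSE)
  }
  stats::setNames(cg$inducer_id, cg$device_id)
}

#' Load a crosstalk database from CSV or JSON
#'
#' CSV schema: header `device_id, inducer_id, cognate (0/1), a, b, ec50_M, h,
#' saturated (0/1)` (optional `converged`, `fit_residual`), one row per pair.
#' JSON schema: object with `devices`, `inducers`, `cognate` (device -> inducer
#' map) and `params` (array of the same records). Completeness is enforced:
#' a missing or duplicated pair is an error naming the pair, not a warning.
#'
#' @param path File path; format chosen by `.json` extension, else CSV.
#' @return A validated [crosstalk_db()].
#' @export
load_db <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    params <- db_df_from_any(obj$params)
    cognate <- unlist(obj$cognate)
    db <- crosstalk_db(params, cognate,
                       devices = obj$devices, inducers = obj$inducers)
  } else {
    params <- db_df_from_any(utils::read.csv(path, stringsAsFactors = FALSE))
    if (!"cognate" %in% names(params)) {
      stop("CSV database lacks the cognate column", call. = FALSE)
    }
    db <- crosstalk_db(params, cognate_from_column(params))
  }
  db
}

#' Save a crosstalk database to CSV or JSON
#'
#' Numeric fields are written at full precision so that
#' `load_db(save_db(db, path))` reproduces `db` bit-identically.
#'
#' @param db A [crosstalk_db()].
#' @param path Output path; `.json` selects the JSON variant, else CSV.
#' @return `path`, invisibly.
#' @export
save_db <- function(db, path) {
  stopifnot(inherits(db, "crosstalk_db"))
  p <- db$params
  p$cognate <- as.integer(db$cognate[p$device_id] == p$inducer_id)
  cols <- c("device_id", "inducer_id", "cognate", db_param_cols, "saturated")
  if ("converged" %in% names(p)) cols <- c(cols, "converged")
  if ("fit_residual" %in% names(p)) cols <- c(cols, "fit_residual")
  p <- p[, cols, drop = FALSE]
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(devices = db$devices, inducers = db$inducers,
                cognate = as.list(db$cognate), params = p)
    # I(17) significant digits: doubles survive the write/read cycle exactly
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else {
    out <- p
    for (col in intersect(c(db_param_cols, "fit_residual"), names(out))) {
      out[[col]] <- fmt_num(out[[col]])
    }
    out$saturated <- as.integer(out$saturated)
    if ("converged" %in% names(out)) out$converged <- as.integer(out$converged)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Import an externally deposited parameter set via a column mapping
#'
#' Adapter for parameter tables that do not follow the native schema (for
#' example a hand-converted export of a deposited fitted-parameter set): a
#' column map translates the file's headers into the native `device_id`,
#' `inducer_id`, `a`, `b`, `ec50_M`, `h`, `saturated` (and optionally
#' `cognate`) columns. When the file carries no cognate column, the pairing is
#' taken from `cognate` (default [ahl_cognate_map()]); a cognate column that
#' conflicts with that map triggers an error rather than a silent override.
#'
#' @param path Delimited text file (CSV, or TSV by extension).
#' @param column_map Named character vector `c(native_name = file_column)`, or
#'   a path to a YAML/JSON file holding that mapping. Identity mapping if
#'   `NULL`.
#' @param cognate Named device -> inducer map used when the file has no
#'   cognate column.
#' @return A validated [crosstalk_db()].
#' @export
import_db <- function(path, column_map = NULL, cognate = ahl_cognate_map()) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (is.character(column_map) && length(column_map) == 1L &&
      file.exists(column_map)) {
    column_map <- unlist(
      if (grepl("\\.json$", column_map, ignore.case = TRUE))
        jsonlite::read_json(column_map, simplifyVector = TRUE)
      else yaml::read_yaml(column_map))
  }
  if (!is.null(column_map)) {
    absent <- setdiff(unname(column_map), names(raw))
    if (length(absent) > 0L) {
      stop(sprintf("column map refers to absent column(s): %s",
                   paste(absent, collapse = ", ")), call. = FALSE)
    }
    for (native in names(column_map)) {
      raw[[native]] <- raw[[column_map[[native]]]]
    }
  }
  params <- db_df_from_any(raw)
  if ("cognate" %in% names(params)) {
    file_map <- cognate_from_column(params)
    conflict <- names(cognate)[
      names(cognate) %in% names(file_map) &
        cognate[names(cognate) %in% names(file_map)] !=
        file_map[names(cognate)[names(cognate) %in% names(file_map)]]]
    if (length(conflict) > 0L) {
      stop(sprintf(
        "cognate pairing in file conflicts with the expected map for: %s",
        paste(conflict, collapse = ", ")), call. = FALSE)
    }
    cognate <- file_map
  }
  crosstalk_db(params, cognate[unique(params$device_id)])
}

#' Predicted fold change of a device's output at a given inducer concentration
#'
#' Pointwise fold change in GFP output: the transfer-function prediction for
#' the (device, inducer) pair at `conc`, divided by the device's basal output.
#' The basal divisor defaults to the `b` fitted for the device's COGNATE
#' record — basal leak is a property of the device, not of which inducer is
#' present — with `basal = "pair"` available to divide by the pair's own `b`.
#'
#' @param db A [crosstalk_db()].
#' @param device,inducer Identifiers (any pair in the database).
#' @param conc Concentration(s), molar, > 0.
#' @param basal `"cognate"` (default) or `"pair"`.
#' @return Dimensionless fold change(s) (>= 0); 1 at vanishing concentration
#'   for a cognate pair, approaching `a/b` at saturation.
#' @export
predicted_fold <- function(db, device, inducer, conc,
                           basal = c("cognate", "pair")) {
  basal <- match.arg(basal)
  p <- db_params(db, device, inducer)
  b0 <- if (basal == "cognate") {
    db_params(db, device, db$cognate[[device]])$b
  } else {
    p$b
  }
  if (!is.finite(b0) || b0 <= 0) {
    stop(sprintf("basal output for device %s is not positive", device),
         call. = FALSE)
  }
  eval_4pl(p, conc) / b0
}

#' Cognate-normalised output matrix
#'
#' Evaluates every pair's transfer function on a concentration grid and
#' normalises per device against the maximal output of that device's cognate
#' pair over the grid — the cognate row therefore peaks at 1 (up to grid
#' resolution), and crosstalk rows read directly as fractions of cognate
#' activation.
#'
#' @param db A [crosstalk_db()].
#' @param grid Strictly increasing concentration grid (molar), non-empty.
#' @return Data frame of class `cognate_norm_matrix` with columns `device_id`,
#'   `inducer_id`, `concentration_M`, `value`.
#' @export
normalise_to_cognate <- function(db, grid = default_conc_grid()) {
  stopifnot(length(grid) >= 1L, all(grid > 0), !is.unsorted(grid,
                                                            strictly = TRUE))
  rows <- list()
  for (d in db$devices) {
    cog_max <- max(eval_4pl(db_params(db, d, db$cognate[[d]]), grid))
    if (!is.finite(cog_max) || cog_max <= 0) {
      stop(sprintf("cognate maximum for device %s is not positive", d),
           call. = FALSE)
    }
    for (i in db$inducers) {
      rows[[paste(d, i)]] <- data.frame(
        device_id = d, inducer_id = i, concentration_M = grid,
        value = eval_4pl(db_params(db, d, i), grid) / cog_max,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cognate_norm_matrix", "data.frame")
  out
}
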