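# Four-parameter logistic transfer functions for AHL-receiver devices:
# model evaluation, constrained fitting, and the derived metrics used in
# device characterisation (fold activation, relative promoter activity,
# low/high expression states).

#' Construct a titration series for one device x inducer pair
#'
#' A titration series holds background-subtracted mean GFP fluorescence
#' (arbitrary units) measured over an increasing inducer concentration grid,
#' with one value per biological replicate at each concentration.
#'
#' @param device_id Device identifier (e.g. `"lux"`).
#' @param inducer_id Inducer identifier (e.g. `"3OC6_HSL"`).
#' @param concentration Numeric vector of inducer concentrations (molar), one
#'   entry per measurement (long format). Must be strictly positive and cover
#'   at least 4 distinct concentrations.
#' @param response Numeric vector of background-subtracted mean fluorescence
#'   values, same length as `concentration`. Negative values are allowed
#'   (background subtraction can over-shoot) but must be finite.
#' @param replicate Optional replicate labels (defaults to a running index
#'   within each concentration).
#'
#' @return An object of class `titration_series`: a data frame with columns
#'   `concentration_M`, `replicate`, `response_au`, sorted by concentration,
#'   carrying `device_id` / `inducer_id` attributes.
#' @export
titration_series <- function(device_id, inducer_id, concentration, response,
                             replicate = NULL) {
  stopifnot(length(device_id) == 1L, length(inducer_id) == 1L,
            length(concentration) == length(response))
  if (!all(is.finite(concentration)) || any(concentration <= 0)) {
    stop("concentrations must be finite and strictly positive", call. = FALSE)
  }
  if (!all(is.finite(response))) {
    stop("responses must be finite", call. = FALSE)
  }
  concs <- sort(unique(concentration))
  if (length(concs) < 4L) {
    stop("a titration series needs at least 4 distinct concentrations",
         call. = FALSE)
  }
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(concentration), concentration,
                            FUN = seq_along)
  }
  df <- data.frame(concentration_M = concentration,
                   replicate = replicate,
                   response_au = response)
  df <- df[order(df$concentration_M, df$replicate), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            device_id = as.character(device_id),
            inducer_id = as.character(inducer_id),
            class = c("titration_series", "data.frame"))
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series: device %s, inducer %s (%d points, %d rows)\n",
              attr(x, "device_id"), attr(x, "inducer_id"),
              length(unique(x$concentration_M)), nrow(x)))
  print(as.data.frame(x), ...)
  invisible(x)
}

series_concentrations <- function(series) sort(unique(series$concentration_M))

# Locate a concentration in a series, robust to decimal-representation jitter.
match_conc <- function(series, conc) {
  hit <- which(abs(log10(series$concentration_M) - log10(conc)) < 1e-9)
  if (length(hit) == 0L) {
    stop(sprintf("concentration %g M is not present in the series", conc),
         call. = FALSE)
  }
  hit
}

mean_response_at <- function(series, conc) {
  mean(series$response_au[match_conc(series, conc)])
}

#' Fitted four-parameter logistic transfer-function parameters
#'
#' @param a Maximal output (arbitrary units).
#' @param b Basal output (arbitrary units).
#' @param ec50 Inducer concentration of half-maximal activation (molar).
#' @param h Hill slope (dimensionless, > 0 for activators).
#' @param saturated Logical; whether the output plateau was reached within the
#'   tested concentration range.
#' @param fit_residual Sum of squared residuals of the fit (NA if the
#'   parameters were not obtained by fitting).
#' @param converged Logical; whether the optimiser reported convergence.
#'
#' @return An object of class `dr_params`.
#' @export
dr_params <- function(a, b, ec50, h, saturated = NA, fit_residual = NA_real_,
                      converged = NA) {
  stopifnot(is.finite(a), is.finite(b), is.finite(ec50), is.finite(h))
  if (ec50 <= 0) stop("ec50 must be positive", call. = FALSE)
  if (h <= 0) stop("h must be positive (activator sign convention)",
                   call. = FALSE)
  structure(list(a = a, b = b, ec50 = ec50, h = h,
                 saturated = saturated, fit_residual = fit_residual,
                 converged = converged),
            class = "dr_params")
}

#' @export
print.dr_params <- function(x, ...) {
  cat(sprintf(
    "4PL params: a=%.6g, b=%.6g, EC50=%.4g M, h=%.4g (saturated=%s, converged=%s)\n",
    x$a, x$b, x$ec50, x$h, x$saturated, x$converged))
  invisible(x)
}

#' Evaluate the four-parameter logistic transfer function
#'
#' The receiver-device transfer function on a log10 concentration axis:
#' \deqn{GFP(c) = b + \frac{a - b}{1 + 10^{(\log_{10} EC50 - \log_{10} c)\,h}}}
#' At `conc = ec50` the value is exactly `(a + b) / 2`; for `a > b`, `h > 0`
#' the curve rises monotonically from the basal asymptote `b` to the maximal
#' asymptote `a`.
#'
#' @param params A [dr_params()] object (or a list with fields `a`, `b`,
#'   `ec50`, `h`).
#' @param conc Inducer concentration(s), molar, strictly positive.
#' @return Numeric response(s), arbitrary units.
#' @export
#' @examples
#' p <- dr_params(a = 1000, b = 10, ec50 = 1e-7, h = 1)
#' eval_4pl(p, 1e-7)   # (a+b)/2 = 505
eval_4pl <- function(params, conc) {
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("conc must be finite and strictly positive", call. = FALSE)
  }
  params$b + (params$a - params$b) /
    (1 + 10^((log10(params$ec50) - log10(conc)) * params$h))
}

# Sum of squared residuals of the 4PL with b fixed, over pooled points.
ssr_4pl <- function(par, b, conc, resp) {
  pred <- b + (par[1] - b) / (1 + 10^((par[2] - log10(conc)) * par[3]))
  sum((pred - resp)^2)
}

#' Fit the four-parameter logistic model with a fixed basal constraint
#'
#' Least-squares fit of the transfer function to pooled replicate measurements,
#' in linear response space over log10 concentration. The basal output `b` is
#' not free: it is fixed to the mean observed response at
#' `basal_constraint_conc` (by default the lowest characterised concentration,
#' 1e-15 M, where the inducer is effectively absent). Bounds enforce the
#' activator convention: `a >= max(b, 0)`, `ec50` in [1e-16, 1e-2] M,
#' `h` in (0, 10].
#'
#' @param series A [titration_series()].
#' @param basal_constraint_conc Concentration (molar) whose mean response fixes
#'   `b`; must be present in the series. Default `1e-15`.
#' @param sat_frac,sat_decades Saturation criterion: the fit is flagged
#'   `saturated` when the device activates (`a > b`), the mean observed
#'   response at the highest tested concentration reaches at least `sat_frac`
#'   of the fitted `a`, AND the fitted EC50 lies at least `sat_decades`
#'   decades below the highest tested concentration.
#' @return A [dr_params()] object with `saturated`, `converged` and
#'   `fit_residual` filled in. Non-convergence returns best-effort parameters
#'   with `converged = FALSE` (never silently).
#' @export
fit_4pl <- function(series, basal_constraint_conc = 1e-15,
                    sat_frac = 0.9, sat_decades = 1) {
  stopifnot(inherits(series, "titration_series"))
  b <- mean_response_at(series, basal_constraint_conc)

  conc <- series$concentration_M
  resp <- series$response_au
  n_free <- 3L  # a, log10(ec50), h
  if (nrow(series) < n_free + 1L) {
    stop("fewer data points than free parameters", call. = FALSE)
  }

  lg <- log10(range(conc))
  lower <- c(a = max(b, 0), lec50 = -16, h = 1e-6)
  upper <- c(a = Inf, lec50 = -2, h = 10)
  start <- c(a = max(max(resp), max(b, 0) + 1e-9),
             lec50 = min(max(mean(lg), -16), -2),
             h = 1)

  resid_fn <- function(par) {
    b + (par[1] - b) / (1 + 10^((par[2] - log10(conc)) * par[3])) - resp
  }

  fit <- tryCatch({
    out <- minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14))
    list(par = out$par, converged = out$info %in% 1:4)
  }, error = function(e) NULL)

  if (is.null(fit)) {
    # Fall back to bounded quasi-Newton on the same objective.
    out <- tryCatch(
      stats::optim(start, ssr_4pl, b = b, conc = conc, resp = resp,
                   method = "L-BFGS-B",
                   lower = lower, upper = pmin(upper, 1e12),
                   control = list(maxit = 2000, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(out)) {
      fit <- list(par = start, converged = FALSE)
    } else {
      fit <- list(par = out$par, converged = out$convergence == 0)
    }
  }

  par <- as.numeric(fit$par)
  a <- par[1]; ec50 <- 10^par[2]; h <- max(par[3], .Machine$double.eps)
  ssr <- ssr_4pl(c(a, log10(ec50), h), b, conc, resp)

  top_conc <- max(conc)
  top_mean <- mean_response_at(series, top_conc)
  # A plateau presupposes activation: a flat (a == b) curve never saturates.
  saturated <- isTRUE(a > b && a > 0 && top_mean >= sat_frac * a &&
                        ec50 * 10^sat_decades <= top_conc)

  dr_params(a = a, b = b, ec50 = ec50, h = h,
            saturated = saturated, fit_residual = ssr,
            converged = isTRUE(fit$converged))
}

#' Fold activation of a receiver device
#'
#' Maximal output divided by basal output. When the fitted curve reached its
#' plateau within the tested range (`saturated`), the ratio of fitted
#' parameters `a / b` is used; otherwise the fallback is the mean observed
#' response at the highest soluble test concentration (default 1e-4 M, i.e.
#' 100 uM) divided by `b`.
#'
#' @param params Fitted [dr_params()] for the series.
#' @param series The [titration_series()] the parameters were fitted to.
#' @param max_test_conc Highest tested concentration used in the unsaturated
#'   fallback (molar); must be present in the series. Default `1e-4`.
#' @return Dimensionless fold change (>= 0).
#' @export
fold_activation <- function(params, series, max_test_conc = 1e-4) {
  if (!is.finite(params$b) || params$b <= 0) {
    stop("fold activation is undefined for basal output b <= 0",
         call. = FALSE)
  }
  if (isTRUE(params$saturated)) {
    params$a / params$b
  } else {
    mean_response_at(series, max_test_conc) / params$b
  }
}

#' Reference standard promoter
#'
#' A constitutive promoter whose measured output defines relative promoter
#' activity 1 (conventionally Bba_J23101 from the Anderson library), on the
#' same measurement scale as the titration responses.
#'
#' @param output Measured output of the reference promoter (arbitrary units,
#'   > 0).
#' @param name Identifier, default `"J23101"`.
#' @return An object of class `reference_standard`.
#' @export
reference_standard <- function(output, name = "J23101") {
  stopifnot(is.finite(output))
  if (output <= 0) stop("reference output must be positive", call. = FALSE)
  structure(list(name = as.character(name), output = output),
            class = "reference_standard")
}

#' Relative promoter activity
#'
#' Calibrates an output against the reference standard promoter:
#' `output / reference$output`. The reference itself maps to 1, and the
#' measure is linear in the output.
#'
#' @param output Output value(s), arbitrary units (same scale as the
#'   reference).
#' @param reference A [reference_standard()].
#' @return Dimensionless relative promoter activity.
#' @export
relative_activity <- function(output, reference) {
  stopifnot(inherits(reference, "reference_standard"))
  output / reference$output
}

#' Low and high expression states in relative promoter units
#'
#' The low (uninduced) and high (fully induced) expression states of a
#' receiver device, as relative promoter activities of the mean observed
#' responses at two concentrations — conventionally 1e-15 M (inducer
#' effectively absent) and 1e-4 M (highest soluble concentration).
#'
#' @param params Fitted [dr_params()] (used to sanity-check the activator
#'   ordering of the two states).
#' @param series The [titration_series()].
#' @param reference A [reference_standard()].
#' @param low_conc,high_conc Concentrations (molar) present in the series.
#' @param tol Relative tolerance for the `high >= low` check on activating
#'   devices (warns, never errors: noise can invert a flat device).
#' @return Named numeric vector `c(low = ..., high = ...)`.
#' @export
low_high_states <- function(params, series, reference,
                            low_conc = 1e-15, high_conc = 1e-4, tol = 0.05) {
  low <- relative_activity(mean_response_at(series, low_conc), reference)
  high <- relative_activity(mean_response_at(series, high_conc), reference)
  if (params$a > params$b && high < low * (1 - tol)) {
    warning("high state below low state for an activating device",
            call. = FALSE)
  }
  c(low = low, high = high)
}

#' Read titration measurements from delimited text
#'
#' Expects columns `device_id`, `inducer_id`, `concentration_M` (scientific
#' notation accepted), `replicate`, `response_au`; one row per replicate
#' measurement. Comma- or tab-delimited (by extension: `.tsv`/`.txt` is tab).
#'
#' @param path File path.
#' @return A named list of [titration_series()], one per device x inducer
#'   pair, names `"<device>:<inducer>"`.
#' @export
read_titrations <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("device_id", "inducer_id", "concentration_M", "replicate",
            "response_au")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("titration file lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!is.finite(df$concentration_M) | df$concentration_M <= 0 |
                 !is.finite(df$response_au))
  if (length(bad) > 0L) {
    stop(sprintf("invalid concentration/response at data row(s): %s",
                 paste(utils::head(bad, 10), collapse = ", ")), call. = FALSE)
  }
  key <- paste(df$device_id, df$inducer_id, sep = ":")
  out <- lapply(split(df, key), function(s) {
    titration_series(s$device_id[1], s$inducer_id[1],
                     s$concentration_M, s$response_au, s$replicate)
  })
  out[order(names(out))]
}

#' Write a titration list to CSV
#'
#' Inverse of [read_titrations()].
#'
#' @param series_list Named list of [titration_series()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_titrations <- function(series_list, path) {
  rows <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(device_id = attr(s, "device_id"),
               inducer_id = attr(s, "inducer_id"),
               concentration_M = fmt_num(s$concentration_M),
               replicate = s$replicate,
               response_au = fmt_num(s$response_au),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit every device x inducer pair in a titration set
#'
#' @param series_list Named list of [titration_series()] (as from
#'   [read_titrations()]).
#' @param ... Passed to [fit_4pl()].
#' @return Data frame with one row per pair: `device_id`, `inducer_id`, `a`,
#'   `b`, `ec50_M`, `h`, `saturated`, `converged`, `fit_residual`.
#' @export
fit_all <- function(series_list, ...) {
  rows <- lapply(series_list, function(s) {
    p <- fit_4pl(s, ...)
    data.frame(device_id = attr(s, "device_id"),
               inducer_id = attr(s, "inducer_id"),
               a = p$a, b = p$b, ec50_M = p$ec50, h = p$h,
               saturated = p$saturated, converged = p$converged,
               fit_residual = p$fit_residual,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Full-precision numeric formatting so CSV round-trips are bit-identical.
fmt_num <- function(x) sprintf("%.17g", x)
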