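# Synthetic-data generators: crosstalk databases with planted orthogonality
# structure (known feasible channels, decoy crosstalk with known feasibility
# boundaries) and noisy titration datasets emulating replicate flow-cytometry
# characterisation, so the full pipeline is testable without external data.

with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Multiplicative replicate-noise model for titration data
#'
#' Population-mean fluorescence from flow cytometry has roughly constant
#' coefficient of variation across the dynamic range, so replicates are
#' modelled as the true curve value times a lognormal factor with mean 1 and
#' the given CV.
#'
#' @param replicate_count Biological replicates per concentration (default 3,
#'   the usual characterisation design).
#' @param cv Coefficient of variation of the multiplicative factor (>= 0;
#'   0 reproduces the curve exactly).
#' @param seed Optional integer seed for reproducible draws.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(replicate_count = 3L, cv = 0.05, seed = NULL) {
  stopifnot(replicate_count >= 1L, cv >= 0)
  structure(list(replicate_count = as.integer(replicate_count),
                 cv = cv, seed = seed),
            class = "noise_model")
}

#' Generate a noisy titration series from known transfer-function parameters
#'
#' @param params A [dr_params()] (the ground truth).
#' @param grid Concentration grid (molar), strictly increasing, >= 4 points.
#' @param noise A [noise_model()].
#' @param device_id,inducer_id Identifiers stamped on the series.
#' @return A [titration_series()] with `noise$replicate_count` responses per
#'   grid point; identical for identical seeds.
#' @export
generate_titration <- function(params, grid = default_conc_grid(),
                               noise = noise_model(),
                               device_id = "D1", inducer_id = "I1") {
  stopifnot(inherits(noise, "noise_model"))
  truth <- eval_4pl(params, grid)
  nrep <- noise$replicate_count
  resp <- with_local_seed(noise$seed, {
    if (noise$cv == 0) {
      rep(truth, each = nrep)
    } else {
      sdlog <- sqrt(log(1 + noise$cv^2))
      factor <- stats::rlnorm(length(grid) * nrep,
                              meanlog = -sdlog^2 / 2, sdlog = sdlog)
      rep(truth, each = nrep) * factor
    }
  })
  titration_series(device_id, inducer_id,
                   concentration = rep(grid, each = nrep),
                   response = resp,
                   replicate = rep(seq_len(nrep), times = length(grid)))
}

#' Specification of a database with planted orthogonal structure
#'
#' Describes a synthetic crosstalk database in which a chosen set of channels
#' is feasible with a safety margin on the activation and crosstalk
#' thresholds, and optional decoy cross pairs are forced infeasible inside
#' given concentration ranges (their fold crosses `fold_off` at a known grid
#' point, giving known window boundaries).
#'
#' @param n_devices,n_inducers Board dimensions (devices `D1..`, inducers
#'   `I1..`; `n_devices <= n_inducers`; cognate map is the identity
#'   `Dk -> Ik`).
#' @param planted_channels List of channels, each
#'   `list(device = <index>, inducer = <index>, window = c(lo, hi))` with the
#'   window endpoints on `grid`; must satisfy the rook condition.
#' @param fold_on,fold_off The thresholds the planted system is built for.
#' @param fold_on_margin,fold_off_margin Safety margins (> 1): planted
#'   activation is at least `fold_on * fold_on_margin` in-window, planted
#'   crosstalk at most `fold_off / fold_off_margin`.
#' @param decoy_crosstalk List of
#'   `list(device = <index>, inducer = <index>, range = c(lo, hi))` cross
#'   pairs whose fold exceeds `fold_off` within `range`.
#' @param grid Concentration grid (molar).
#' @param seed Integer seed controlling the randomised curve parameters.
#' @return An object of class `planted_design_spec`.
#' @export
planted_design_spec <- function(n_devices, n_inducers,
                                planted_channels = list(),
                                fold_on = 2, fold_off = 2,
                                fold_on_margin = 2, fold_off_margin = 2,
                                decoy_crosstalk = list(),
                                grid = default_conc_grid(), seed = 1L) {
  stopifnot(n_devices >= 1L, n_inducers >= n_devices,
            fold_on_margin > 1, fold_off_margin > 1)
  if (fold_off / fold_off_margin < 1) {
    stop("fold_off_margin too large: the tightened crosstalk bound would ",
         "fall below 1, which even a silent (flat) pair cannot satisfy",
         call. = FALSE)
  }
  pd <- vapply(planted_channels, function(ch) ch$device, 0L)
  pi_ <- vapply(planted_channels, function(ch) ch$inducer, 0L)
  if (anyDuplicated(pd) || anyDuplicated(pi_)) {
    stop("planted channels violate the rook condition", call. = FALSE)
  }
  if (length(pd) > 0L && (max(pd) > n_devices || max(pi_) > n_inducers)) {
    stop("planted channel index out of range", call. = FALSE)
  }
  structure(list(n_devices = as.integer(n_devices),
                 n_inducers = as.integer(n_inducers),
                 planted_channels = planted_channels,
                 fold_on = fold_on, fold_off = fold_off,
                 fold_on_margin = fold_on_margin,
                 fold_off_margin = fold_off_margin,
                 decoy_crosstalk = decoy_crosstalk,
                 grid = grid, seed = as.integer(seed)),
            class = "planted_design_spec")
}

# Fold along a 4PL curve with shared basal: fold(c) = 1 + (A-1)/(1+(ec50/c)^h)
# where A = a/b. Solving fold(c*) = F for ec50 gives the decoy construction.
ec50_for_fold_at <- function(A, F, h, conc) {
  stopifnot(A > F, F > 1)
  conc * ((A - F) / (F - 1))^(1 / h)
}

#' Generate a crosstalk database with planted orthogonal channels
#'
#' Builds a complete `n_devices x n_inducers` database (basal output 100 au
#' for every device) in which:
#' \itemize{
#'   \item each planted (device, inducer) pair gets a strongly activating
#'     curve whose fold exceeds `fold_on * fold_on_margin` across its window;
#'   \item cross pairs between a planted inducer and any other planted device
#'     are kept flat (fold 1, far below `fold_off / fold_off_margin`);
#'   \item each decoy cross pair gets a curve whose fold equals `fold_off`
#'     exactly at a grid point drawn inside its range (so concentrations above
#'     it violate the crosstalk constraint under the default strict
#'     comparison);
#'   \item remaining cognate pairs get randomised activating curves and all
#'     other pairs stay flat.
#' }
#' The construction is verified before returning: planted channels must pass
#' [point_feasible()] with their margins at every in-window grid point, and a
#' decoy whose curve would break a planted channel raises a construction
#' error.
#'
#' @param pspec A [planted_design_spec()].
#' @return A validated [crosstalk_db()]; identical for identical seeds.
#' @export
generate_db <- function(pspec) {
  stopifnot(inherits(pspec, "planted_design_spec"))
  nd <- pspec$n_devices; ni <- pspec$n_inducers
  devices <- paste0("D", seq_len(nd))
  inducers <- paste0("I", seq_len(ni))
  grid <- pspec$grid
  b <- 100

  planted <- pspec$planted_channels
  pdev <- vapply(planted, function(ch) ch$device, 0L)
  pind <- vapply(planted, function(ch) ch$inducer, 0L)

  # Pairs that must stay quiet: a planted inducer hitting any OTHER planted
  # device (these are exactly the crosstalk constraints of the planted
  # system). Overrides any randomised cognate activation.
  quiet <- unique(do.call(rbind, lapply(seq_along(planted), function(i) {
    others <- setdiff(pdev, pdev[i])
    if (length(others) == 0L) return(NULL)
    cbind(device = others, inducer = pind[i])
  })))

  with_local_seed(pspec$seed, {
    flat <- function() c(a = b, b = b, ec50 = stats::runif(1, 1e-9, 1e-6),
                         h = stats::runif(1, 0.8, 2))
    A_on <- 2 * pspec$fold_on * pspec$fold_on_margin

    par_mat <- array(NA_real_, dim = c(nd, ni, 4),
                     dimnames = list(devices, inducers,
                                     c("a", "b", "ec50", "h")))
    for (d in seq_len(nd)) for (i in seq_len(ni)) {
      par_mat[d, i, ] <- flat()
    }

    # Randomised activating cognate curves (identity pairing) where free.
    for (d in seq_len(nd)) {
      fold_act <- 10^stats::runif(1, 1.2, 2.3)
      ec50 <- 10^stats::runif(1, log10(min(grid)) + 3, log10(max(grid)) - 2)
      par_mat[d, d, ] <- c(b * fold_act, b, ec50, stats::runif(1, 0.8, 2))
    }

    # Planted channels: activation comfortably above threshold across the
    # window (EC50 more than a decade below the window start).
    for (ch in planted) {
      win <- ch$window
      par_mat[ch$device, ch$inducer, ] <-
        c(b * A_on, b, win[1] / 15, 1.2)
    }

    # Quiet cross pairs forced flat (even if cognate).
    if (!is.null(quiet)) {
      for (r in seq_len(nrow(quiet))) {
        par_mat[as.integer(quiet[r, "device"]),
                as.integer(quiet[r, "inducer"]), ] <- flat()
      }
    }

    # Decoys: fold crosses fold_off exactly at a seeded grid point inside the
    # requested range.
    for (dec in pspec$decoy_crosstalk) {
      d <- dec$device; i <- dec$inducer
      if (length(pdev) > 0L && any(pdev == d & pind == i)) {
        stop("decoy coincides with a planted channel: contradictory spec",
             call. = FALSE)
      }
      in_range <- which(grid >= dec$range[1] & grid <= dec$range[2])
      if (length(in_range) == 0L) {
        stop("decoy range contains no grid point", call. = FALSE)
      }
      cross_at <- grid[sample(in_range, 1L)]
      A_dec <- 4 * pspec$fold_off
      par_mat[d, i, ] <- c(b * A_dec, b,
                           ec50_for_fold_at(A_dec, pspec$fold_off, 1, cross_at),
                           1)
    }

    params <- expand.grid(device_id = devices, inducer_id = inducers,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    idx <- cbind(match(params$device_id, devices),
                 match(params$inducer_id, inducers))
    params$a <- par_mat[cbind(idx, 1L)]
    params$b <- par_mat[cbind(idx, 2L)]
    params$ec50_M <- par_mat[cbind(idx, 3L)]
    params$h <- par_mat[cbind(idx, 4L)]
    params$saturated <- TRUE

    db <- crosstalk_db(params,
                       cognate = stats::setNames(inducers[seq_len(nd)],
                                                 devices),
                       devices = devices, inducers = inducers)

    # Verify the plant: every in-window grid point must be feasible with the
    # stated margins under the tightened specification.
    if (length(planted) > 0L) {
      tight <- design_spec(n_channels = length(planted),
                           fold_on = pspec$fold_on * pspec$fold_on_margin,
                           fold_off = pspec$fold_off / pspec$fold_off_margin,
                           grid = grid, off_strict = FALSE)
      asg <- list(devices = devices[pdev], inducers = inducers[pind])
      win_idx <- lapply(planted, function(ch) {
        which(grid >= ch$window[1] & grid <= ch$window[2])
      })
      if (any(vapply(win_idx, length, 0L) == 0L)) {
        stop("planted window contains no grid point", call. = FALSE)
      }
      for (pt in seq_len(max(vapply(win_idx, length, 0L)))) {
        concs <- vapply(win_idx, function(w) grid[w[min(pt, length(w))]], 0)
        if (!point_feasible(db, asg, concs, tight)) {
          stop(paste("contradictory planted specification:",
                     "a decoy or random curve blocks a planted channel"),
               call. = FALSE)
        }
      }
      # Exhaustive in-window check via the per-channel feasible sets.
      feas <- channel_feasible_idx(db, asg, tight)
      for (i in seq_along(planted)) {
        if (!all(win_idx[[i]] %in% feas[[i]])) {
          stop(paste("contradictory planted specification:",
                     "planted window not fully feasible with margins"),
               call. = FALSE)
        }
      }
    }
    db
  })
}

#' Generate a fully random crosstalk database
#'
#' Unstructured random 4PL parameter sets (no planted feasibility) over a
#' given board, used to exercise the search against the brute-force oracle on
#' arbitrary instances: basal outputs vary per device, every pair gets a
#' random maximal output between basal (flat) and ~100-fold activation, with
#' log-uniform EC50 spanning the grid and Hill slopes in [0.5, 3].
#'
#' @param n_devices,n_inducers Board dimensions (`n_devices <= n_inducers`).
#' @param grid Concentration grid (molar).
#' @param seed Integer seed.
#' @return A validated [crosstalk_db()] with identity cognate pairing.
#' @export
random_db <- function(n_devices = 3L, n_inducers = 3L,
                      grid = default_conc_grid(), seed = 1L) {
  stopifnot(n_devices <= n_inducers)
  devices <- paste0("D", seq_len(n_devices))
  inducers <- paste0("I", seq_len(n_inducers))
  with_local_seed(seed, {
    params <- expand.grid(device_id = devices, inducer_id = inducers,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    n <- nrow(params)
    basal <- stats::setNames(stats::runif(n_devices, 20, 200), devices)
    params$b <- basal[params$device_id]
    params$a <- params$b * 10^stats::runif(n, 0, 2)
    params$ec50_M <- 10^stats::runif(n, log10(min(grid)), log10(max(grid)))
    params$h <- stats::runif(n, 0.5, 3)
    params$saturated <- TRUE
    crosstalk_db(params,
                 cognate = stats::setNames(inducers[seq_len(n_devices)],
                                           devices),
                 devices = devices, inducers = inducers)
  })
}

#' Generate titration data for every pair of a database
#'
#' @param db A [crosstalk_db()].
#' @param grid Concentration grid (molar).
#' @param noise A [noise_model()]; per-pair seeds are derived from its seed.
#' @return Named list of [titration_series()] (names `"<device>:<inducer>"`).
#' @export
generate_titration_set <- function(db, grid = default_conc_grid(),
                                   noise = noise_model()) {
  out <- list()
  pair_id <- 0L
  for (d in db$devices) {
    for (i in db$inducers) {
      pair_id <- pair_id + 1L
      nm <- noise
      if (!is.null(noise$seed)) nm$seed <- noise$seed + pair_id
      out[[paste(d, i, sep = ":")]] <-
        generate_titration(db_params(db, d, i), grid, nm,
                           device_id = d, inducer_id = i)
    }
  }
  out[order(names(out))]
}
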