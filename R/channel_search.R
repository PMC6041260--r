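# Automated identification of orthogonal communication channels: exhaustive
# search over non-attacking-rook placements of (device, inducer) pairs,
# intersected with per-channel concentration windows that satisfy activation
# and crosstalk fold-change constraints.

#' Default characterisation concentration grid
#'
#' Decade-spaced inducer concentrations from 1e-15 M (inducer effectively
#' absent) to 1e-4 M (highest soluble concentration), 12 points.
#'
#' @return Numeric vector of molar concentrations.
#' @export
default_conc_grid <- function() 10^seq(-15, -4)

#' Design specification for an orthogonal channel search
#'
#' @param n_channels Number of simultaneous communication channels required
#'   (>= 1).
#' @param fold_on Minimal fold change for specific activation (>= 1): each
#'   channel's inducer, at an in-window concentration, must activate its own
#'   device at least this much over basal.
#' @param fold_off Maximal fold change tolerated as crosstalk (>= 1): each
#'   channel's inducer, at an in-window concentration, must not activate any
#'   OTHER selected device beyond this.
#' @param grid Strictly increasing concentration grid (molar) the windows are
#'   drawn from.
#' @param on_strict,off_strict Comparison strictness. Defaults follow the
#'   usual reading of "more than x-fold activation, less than y-fold
#'   crosstalk" while avoiding float-equality fragility on the activation
#'   side: activation `fold >= fold_on` (non-strict), crosstalk
#'   `fold < fold_off` (strict).
#' @param window_mode `"joint"` (default) or `"per-channel"`. Under this fold
#'   model the two coincide (each constraint depends on a single channel's
#'   concentration), so the flag is interface sugar; see the methods vignette.
#' @param basal `"cognate"` or `"pair"` basal divisor, see [predicted_fold()].
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_channels, fold_on, fold_off,
                        grid = default_conc_grid(),
                        on_strict = FALSE, off_strict = TRUE,
                        window_mode = c("joint", "per-channel"),
                        basal = c("cognate", "pair")) {
  stopifnot(length(n_channels) == 1L, n_channels >= 1,
            n_channels == as.integer(n_channels),
            is.finite(fold_on), fold_on >= 1,
            is.finite(fold_off), fold_off >= 1,
            length(grid) >= 1L, all(grid > 0))
  if (length(grid) > 1L && is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly increasing", call. = FALSE)
  }
  structure(list(n_channels = as.integer(n_channels),
                 fold_on = fold_on, fold_off = fold_off, grid = grid,
                 on_strict = isTRUE(on_strict),
                 off_strict = isTRUE(off_strict),
                 window_mode = match.arg(window_mode),
                 basal = match.arg(basal)),
            class = "design_spec")
}

meets_on <- function(fold, spec) {
  if (spec$on_strict) fold > spec$fold_on else fold >= spec$fold_on
}
meets_off <- function(fold, spec) {
  if (spec$off_strict) fold < spec$fold_off else fold <= spec$fold_off
}

# Permutations of 1:k in lexicographic order (k <= 7 at the scales used here).
permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in permutations_of(k - 1L)) {
      rest <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

#' Enumerate non-attacking-rook assignments of devices to inducers
#'
#' All placements of `k` rooks on the |devices| x |inducers| board such that
#' no device and no inducer is used twice: choose `k` devices, choose `k`
#' inducers, and match them in every order — `C(nd, k) * C(ni, k) * k!`
#' assignments in total.
#'
#' @param devices,inducers Character vectors of identifiers.
#' @param k Number of channels (1 <= k <= min(|devices|, |inducers|)).
#' @return List of assignments, each a list with character vectors `devices`
#'   and `inducers` of length `k` (position i pairs `devices[i]` with
#'   `inducers[i]`).
#' @export
enumerate_assignments <- function(devices, inducers, k) {
  nd <- length(devices); ni <- length(inducers)
  k <- as.integer(k)
  if (k < 1L || k > min(nd, ni)) {
    stop(sprintf("k must be between 1 and min(%d, %d)", nd, ni),
         call. = FALSE)
  }
  dev_sets <- utils::combn(devices, k, simplify = FALSE)
  ind_sets <- utils::combn(inducers, k, simplify = FALSE)
  perms <- permutations_of(k)
  out <- vector("list", length(dev_sets) * length(ind_sets) * length(perms))
  n <- 0L
  for (ds in dev_sets) {
    for (is_ in ind_sets) {
      for (p in perms) {
        n <- n + 1L
        out[[n]] <- list(devices = ds, inducers = is_[p])
      }
    }
  }
  out
}

#' Test feasibility of one concentration point per channel
#'
#' An assignment with one concentration per channel is feasible when (i) every
#' channel's inducer activates its own device by at least `fold_on` at its
#' concentration, and (ii) every channel's inducer, at its own concentration,
#' activates every OTHER selected device by less than `fold_off`.
#'
#' @param db A [crosstalk_db()].
#' @param assignment One element of [enumerate_assignments()].
#' @param concs Numeric vector, one concentration per channel, each in
#'   `spec$grid`.
#' @param spec A [design_spec()].
#' @return Logical scalar.
#' @export
point_feasible <- function(db, assignment, concs, spec) {
  k <- length(assignment$devices)
  stopifnot(length(concs) == k)
  for (i in seq_len(k)) {
    f_on <- predicted_fold(db, assignment$devices[i], assignment$inducers[i],
                           concs[i], basal = spec$basal)
    if (!meets_on(f_on, spec)) return(FALSE)
    for (j in seq_len(k)[-i]) {
      f_off <- predicted_fold(db, assignment$devices[j],
                              assignment$inducers[i], concs[i],
                              basal = spec$basal)
      if (!meets_off(f_off, spec)) return(FALSE)
    }
  }
  TRUE
}

# Precompute predicted folds for every (device, inducer) pair over the grid,
# so the exhaustive search does array lookups instead of per-call data-frame
# scans. Returns an nd x ni x ngrid array with device/inducer dimnames.
precompute_folds <- function(db, spec) {
  nd <- length(db$devices); ni <- length(db$inducers)
  arr <- array(NA_real_, dim = c(nd, ni, length(spec$grid)),
               dimnames = list(db$devices, db$inducers, NULL))
  for (d in db$devices) {
    for (i in db$inducers) {
      arr[d, i, ] <- predicted_fold(db, d, i, spec$grid, basal = spec$basal)
    }
  }
  arr
}

# Per-channel feasible grid indices for a fixed assignment. Separable: channel
# i's constraints (own activation + its inducer's crosstalk onto the other
# selected devices) depend only on channel i's own concentration, so the
# jointly feasible set is the product of these sets.
channel_feasible_idx <- function(db, assignment, spec, folds = NULL) {
  if (is.null(folds)) folds <- precompute_folds(db, spec)
  k <- length(assignment$devices)
  lapply(seq_len(k), function(i) {
    ok <- meets_on(folds[assignment$devices[i], assignment$inducers[i], ],
                   spec)
    for (j in seq_len(k)[-i]) {
      ok <- ok & meets_off(folds[assignment$devices[j],
                                 assignment$inducers[i], ], spec)
    }
    which(ok)
  })
}

contiguous_runs <- function(idx) {
  if (length(idx) == 0L) return(list())
  breaks <- c(0L, which(diff(idx) != 1L), length(idx))
  lapply(seq_len(length(breaks) - 1L), function(r) {
    idx[(breaks[r] + 1L):breaks[r + 1L]]
  })
}

make_design <- function(assignment, runs, spec) {
  grid <- spec$grid
  ch <- data.frame(device = assignment$devices,
                   inducer = assignment$inducers,
                   conc_min = vapply(runs, function(r) grid[min(r)], 0),
                   conc_max = vapply(runs, function(r) grid[max(r)], 0),
                   stringsAsFactors = FALSE)
  ch <- ch[order(ch$device, ch$inducer), , drop = FALSE]
  rownames(ch) <- NULL
  structure(list(channels = ch, spec = spec), class = "system_design")
}

#' @export
print.system_design <- function(x, ...) {
  cat(sprintf("System design: %d channel(s), fold_on=%g, fold_off=%g\n",
              nrow(x$channels), x$spec$fold_on, x$spec$fold_off))
  print(x$channels, ...)
  invisible(x)
}

design_key <- function(design) {
  ch <- design$channels
  paste(sprintf("%s|%s|%.17g|%.17g", ch$device, ch$inducer,
                ch$conc_min, ch$conc_max), collapse = ";")
}

#' Maximal feasible concentration windows for one rook assignment
#'
#' For each channel, the grid concentrations at which the assignment is
#' jointly feasible (every combination of one in-window concentration per
#' channel passes [point_feasible()]) are reported as maximal contiguous runs
#' on the grid. One [design_spec()]-conforming system design is emitted per
#' combination of runs across channels; the empty list means no feasible
#' point exists.
#'
#' @inheritParams point_feasible
#' @param folds Optional precomputed fold array (internal fast path).
#' @return List of `system_design` objects (possibly empty).
#' @export
find_windows <- function(db, assignment, spec, folds = NULL) {
  feas <- channel_feasible_idx(db, assignment, spec, folds)
  if (any(vapply(feas, length, 0L) == 0L)) return(list())
  runs_per_channel <- lapply(feas, contiguous_runs)
  combos <- expand.grid(lapply(runs_per_channel, seq_along),
                        KEEP.OUT.ATTRS = FALSE)
  designs <- vector("list", nrow(combos))
  for (r in seq_len(nrow(combos))) {
    runs <- lapply(seq_along(runs_per_channel), function(i) {
      runs_per_channel[[i]][[combos[r, i]]]
    })
    designs[[r]] <- make_design(assignment, runs, spec)
  }
  designs
}

sort_designs <- function(designs) {
  if (length(designs) == 0L) return(list())
  keys <- vapply(designs, design_key, "")
  designs <- designs[!duplicated(keys)]
  keys <- keys[!duplicated(keys)]
  designs[order(keys, method = "radix")]
}

#' Search for all feasible orthogonal communication systems
#'
#' Exhaustive depth over all rook assignments of `spec$n_channels`
#' (device, inducer) pairs, pruning an assignment as soon as any channel has
#' no feasible concentration, then aggregating feasible concentrations into
#' maximal contiguous windows. Deterministic: results are deduplicated and
#' ordered lexicographically by device ids, inducer ids and window bounds.
#'
#' @param db A [crosstalk_db()].
#' @param spec A [design_spec()].
#' @return List of `system_design` objects; an empty list is a valid
#'   "no feasible design" result.
#' @export
search_designs <- function(db, spec) {
  stopifnot(inherits(db, "crosstalk_db"), inherits(spec, "design_spec"))
  if (spec$n_channels > min(length(db$devices), length(db$inducers))) {
    stop("n_channels exceeds the number of available devices or inducers",
         call. = FALSE)
  }
  assignments <- enumerate_assignments(db$devices, db$inducers,
                                       spec$n_channels)
  folds <- precompute_folds(db, spec)
  out <- list()
  for (asg in assignments) {
    designs <- find_windows(db, asg, spec, folds)
    if (length(designs) > 0L) out <- c(out, designs)
  }
  sort_designs(out)
}

#' Largest number of simultaneously feasible orthogonal channels
#'
#' The maximal `k` for which [search_designs()] returns at least one system
#' design. Feasibility is monotone (dropping a channel only removes
#' constraints), so the scan stops at the first infeasible `k`.
#'
#' @param db A [crosstalk_db()].
#' @param spec A [design_spec()]; its `n_channels` is ignored.
#' @return Integer >= 0 (0 when even one channel is infeasible).
#' @export
max_channels <- function(db, spec) {
  kmax <- 0L
  for (k in seq_len(min(length(db$devices), length(db$inducers)))) {
    spec_k <- spec
    spec_k$n_channels <- k
    if (length(search_designs(db, spec_k)) == 0L) break
    kmax <- k
  }
  kmax
}

#' Brute-force reference search (test oracle)
#'
#' Exhaustively enumerates every rook assignment and every combination of one
#' grid concentration per channel, classifies each combination with
#' [point_feasible()], and aggregates passing combinations into window
#' designs. No pruning, small instances only — this is the reference
#' implementation the fast search is validated against.
#'
#' @inheritParams search_designs
#' @param max_board,max_grid Instance-size guards (defaults 4 and 6).
#' @return List of `system_design` objects, ordered as in [search_designs()].
#' @export
brute_force_oracle <- function(db, spec, max_board = 4L, max_grid = 6L) {
  nd <- length(db$devices); ni <- length(db$inducers)
  if (nd > max_board || ni > max_board || length(spec$grid) > max_grid) {
    stop("instance too large for the brute-force oracle", call. = FALSE)
  }
  assignments <- enumerate_assignments(db$devices, db$inducers,
                                       spec$n_channels)
  k <- spec$n_channels
  combos <- as.matrix(expand.grid(rep(list(seq_along(spec$grid)), k),
                                  KEEP.OUT.ATTRS = FALSE))
  out <- list()
  for (asg in assignments) {
    pass <- apply(combos, 1L, function(ix) {
      point_feasible(db, asg, spec$grid[ix], spec)
    })
    if (!any(pass)) next
    # Feasible combinations form a product set (constraints are separable);
    # recover each channel's feasible concentrations and confirm the product.
    feas <- lapply(seq_len(k), function(i) sort(unique(combos[pass, i])))
    expected <- prod(vapply(feas, length, 0L))
    if (sum(pass) != expected) {
      stop("feasible set is not a product set; oracle aggregation invalid",
           call. = FALSE)
    }
    runs_per_channel <- lapply(feas, contiguous_runs)
    run_combos <- expand.grid(lapply(runs_per_channel, seq_along),
                              KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(run_combos))) {
      runs <- lapply(seq_len(k), function(i) {
        runs_per_channel[[i]][[run_combos[r, i]]]
      })
      out[[length(out) + 1L]] <- make_design(asg, runs, spec)
    }
  }
  sort_designs(out)
}

#' Per-concentration feasibility matrix for an assignment
#'
#' The green/red rendering of a candidate system: for every channel and every
#' grid concentration, whether all constraints (own activation and crosstalk
#' onto the other selected devices) hold at that concentration.
#'
#' @inheritParams point_feasible
#' @return Data frame with columns `device`, `inducer`, one column per grid
#'   concentration holding `"green"` or `"red"`.
#' @export
feasibility_matrix <- function(db, assignment, spec) {
  feas <- channel_feasible_idx(db, assignment, spec)
  k <- length(assignment$devices)
  m <- matrix("red", nrow = k, ncol = length(spec$grid))
  for (i in seq_len(k)) m[i, feas[[i]]] <- "green"
  out <- data.frame(device = assignment$devices,
                    inducer = assignment$inducers,
                    stringsAsFactors = FALSE)
  grid_cols <- as.data.frame(m, stringsAsFactors = FALSE)
  names(grid_cols) <- sprintf("conc_%.0e", spec$grid)
  cbind(out, grid_cols)
}

#' Check a parameter database against the published channel designs
#'
#' Given a characterised 6x6 AHL crosstalk database (e.g. an import of the
#' deposited fitted-parameter set), verifies the three headline design
#' results: (i) at >= 2-fold specific activation and < 2-fold crosstalk the
#' library supports a maximum of four orthogonal channels; (ii) a stricter
#' 10-fold / 3-fold two-channel specification admits the rhl + C4 HSL
#' (1e-6 to 1e-5 M) / lux + 3OC6 HSL (1e-9 to 1e-7 M) system; and (iii) the
#' experimentally validated three-channel operating point (rhl, lux and las
#' devices driven by C4 HSL at 1e-5 M, 3OC8 HSL at 1e-8 M and 3OHC14 HSL at
#' 1e-7 M) is predicted >= 2-fold specific and < 2-fold crosstalk.
#'
#' @param db A 6x6 [crosstalk_db()] using the canonical identifiers.
#' @param grid Concentration grid for the searches.
#' @return Named list with elements `max_channels_2_2`,
#'   `strict_two_channel_found` (logical), `validated_point_feasible`
#'   (logical), plus the underlying fold values.
#' @export
check_published_designs <- function(db, grid = default_conc_grid()) {
  spec22 <- design_spec(n_channels = 1L, fold_on = 2, fold_off = 2,
                        grid = grid)
  kmax <- max_channels(db, spec22)

  spec103 <- design_spec(n_channels = 2L, fold_on = 10, fold_off = 3,
                         grid = grid)
  designs2 <- search_designs(db, spec103)
  target <- vapply(designs2, function(d) {
    ch <- d$channels
    rhl <- ch[ch$device == "rhl" & ch$inducer == "C4_HSL", , drop = FALSE]
    lux <- ch[ch$device == "lux" & ch$inducer == "3OC6_HSL", , drop = FALSE]
    nrow(rhl) == 1L && nrow(lux) == 1L &&
      rhl$conc_min <= 1e-6 && rhl$conc_max >= 1e-5 &&
      lux$conc_min <= 1e-9 && lux$conc_max >= 1e-7
  }, logical(1))

  # Experimentally validated 3-channel operating point: devices rhl, lux, las
  # driven by C4 HSL (1e-5 M), 3OC8 HSL (1e-8 M) and 3OHC14 HSL (1e-7 M).
  asg3 <- list(devices = c("rhl", "lux", "las"),
               inducers = c("C4_HSL", "3OC8_HSL", "3OHC14_HSL"))
  concs3 <- c(1e-5, 1e-8, 1e-7)
  spec3 <- design_spec(n_channels = 3L, fold_on = 2, fold_off = 2,
                       grid = grid)
  folds_on <- vapply(1:3, function(i) {
    predicted_fold(db, asg3$devices[i], asg3$inducers[i], concs3[i])
  }, 0)
  folds_off <- unlist(lapply(1:3, function(i) {
    vapply(setdiff(1:3, i), function(j) {
      predicted_fold(db, asg3$devices[j], asg3$inducers[i], concs3[i])
    }, 0)
  }))

  list(max_channels_2_2 = kmax,
       strict_two_channel_found = any(target),
       validated_point_feasible = point_feasible(db, asg3, concs3, spec3),
       validated_folds_on = folds_on,
       validated_folds_off = folds_off)
}
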