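# Rook enumeration, feasibility, window construction, exhaustive search.

test_that("rook enumeration yields each placement exactly once", {
  d6 <- paste0("D", 1:6); i6 <- paste0("I", 1:6)
  expect_length(enumerate_assignments(d6, i6, 1), 36)
  expect_length(enumerate_assignments(d6, i6, 2), 450)
  expect_length(enumerate_assignments(c("a", "b"), c("x", "y"), 2), 2)
  expect_error(enumerate_assignments(d6, i6[1:3], 4), "between 1 and")

  asg <- enumerate_assignments(paste0("D", 1:3), paste0("I", 1:4), 2)
  keys <- vapply(asg, function(a) {
    paste(sort(paste(a$devices, a$inducers)), collapse = ";")
  }, "")
  expect_false(any(duplicated(keys)))
  for (a in asg) {
    expect_false(anyDuplicated(a$devices) > 0)
    expect_false(anyDuplicated(a$inducers) > 0)
  }
})

test_that("rook counts match exhaustive cell-subset generation on small boards", {
  for (nd in 2:4) {
    for (ni in 2:4) {
      for (k in 1:min(nd, ni)) {
        cells <- expand.grid(d = seq_len(nd), i = seq_len(ni))
        subsets <- utils::combn(nrow(cells), k, simplify = FALSE)
        valid <- sum(vapply(subsets, function(ix) {
          !anyDuplicated(cells$d[ix]) && !anyDuplicated(cells$i[ix])
        }, logical(1)))
        # each assignment lists devices in sorted order, so one entry per
        # unordered non-attacking placement of k cells
        expect_equal(length(enumerate_assignments(paste0("D", 1:nd),
                                                  paste0("I", 1:ni), k)),
                     valid,
                     info = sprintf("nd=%d ni=%d k=%d", nd, ni, k))
      }
    }
  }
})

test_that("point feasibility enforces activation and pairwise crosstalk", {
  db <- diagonal_db(3, fold = 100, ec50 = 1e-8)
  spec <- design_spec(2, fold_on = 2, fold_off = 2,
                      grid = default_conc_grid())
  asg <- list(devices = c("D1", "D2"), inducers = c("I1", "I2"))
  expect_true(point_feasible(db, asg, c(1e-5, 1e-5), spec))   # saturating
  expect_false(point_feasible(db, asg, c(1e-12, 1e-5), spec)) # D1 not on

  # single channel: no cross pairs to check
  spec1 <- design_spec(1, 2, 2)
  expect_true(point_feasible(db, list(devices = "D1", inducers = "I1"),
                             1e-5, spec1))

  # planted crossing: D2 responds to I1 above a known concentration
  p <- db$params
  sel <- p$device_id == "D2" & p$inducer_id == "I1"
  p$a[sel] <- 800; p$ec50_M[sel] <- 1e-6; p$h[sel] <- 1
  db2 <- crosstalk_db(p, db$cognate)
  cross_at <- fold_crossing_conc(800, 100, 1e-6, 1, F = 2)
  expect_false(point_feasible(db2, asg, c(cross_at * 10, 1e-5), spec))
  expect_true(point_feasible(db2, asg, c(cross_at / 10, 1e-5), spec))
})

test_that("windows follow the closed-form activation crossing on a diagonal db", {
  db <- diagonal_db(2, fold = 100, b = 100, ec50 = 1e-8, h = 1.2)
  grid <- default_conc_grid()
  spec <- design_spec(2, fold_on = 2, fold_off = 2, grid = grid)
  asg <- list(devices = c("D1", "D2"), inducers = c("I1", "I2"))
  designs <- find_windows(db, asg, spec)
  expect_length(designs, 1)

  crossing <- fold_crossing_conc(100 * 100, 100, 1e-8, 1.2, F = 2)
  expected_lo <- min(grid[grid >= crossing])
  ch <- designs[[1]]$channels
  expect_equal(ch$conc_min, rep(expected_lo, 2))
  expect_equal(ch$conc_max, rep(max(grid), 2))  # suffix window: monotone curve

  # infeasible everywhere: crosstalk at/above fold_off on the whole grid
  p <- db$params
  sel <- p$device_id == "D2" & p$inducer_id == "I1"
  p[sel, c("a", "b")] <- c(100 * 400, 100)
  p$ec50_M[sel] <- 1e-16  # activated from the lowest grid point on
  db_bad <- crosstalk_db(p, db$cognate)
  expect_length(find_windows(db_bad, asg, spec), 0)
})

test_that("search equals the brute-force oracle on random instances", {
  grid5 <- 10^seq(-12, -4, length.out = 5)
  n_nonempty <- 0
  for (seed in 1:30) {
    db <- random_db(3, 3, grid = grid5, seed = seed)
    for (k in 1:3) {
      spec <- design_spec(k, fold_on = 2, fold_off = 2, grid = grid5)
      fast <- search_designs(db, spec)
      slow <- brute_force_oracle(db, spec)
      expect_identical(design_channels(fast), design_channels(slow),
                       info = sprintf("seed=%d k=%d", seed, k))
      n_nonempty <- n_nonempty + (length(fast) > 0)
    }
  }
  expect_gt(n_nonempty, 10)  # the comparison is not vacuous
  db_small <- random_db(2, 2, grid = grid5, seed = 99)
  spec2 <- design_spec(2, 2, 2, grid = grid5)
  expect_identical(design_channels(search_designs(db_small, spec2)),
                   design_channels(brute_force_oracle(db_small, spec2)))
  expect_error(brute_force_oracle(diagonal_db(6), spec2), "too large")
})

test_that("diagonal db at k=3 admits exactly the 20 cognate-only triples", {
  db <- diagonal_db(6, fold = 100)
  spec <- design_spec(3, fold_on = 2, fold_off = 2)
  designs <- search_designs(db, spec)
  # C(6,3) device triples, identity pairing only, one contiguous window each
  expect_length(designs, choose(6, 3))
  for (d in designs) {
    expect_identical(sub("D", "", d$channels$device),
                     sub("I", "", d$channels$inducer))
  }
})

test_that("solution set shrinks as constraints tighten (monotonicity)", {
  grid <- default_conc_grid()
  db <- random_db(4, 4, grid = grid, seed = 8)
  keyset <- function(designs) {
    vapply(designs, function(d) {
      paste(sprintf("%s|%s|%g|%g", d$channels$device, d$channels$inducer,
                    d$channels$conc_min, d$channels$conc_max),
            collapse = ";")
    }, "")
  }
  # point-level inclusion: compare feasible grid points per assignment
  feas_points <- function(fold_on, fold_off) {
    spec <- design_spec(2, fold_on, fold_off, grid = grid)
    unlist(lapply(enumerate_assignments(db$devices, db$inducers, 2),
                  function(a) {
      f <- ahldesign:::channel_feasible_idx(db, a, spec)
      tags <- c(paste0("ch1:", f[[1]], recycle0 = TRUE),
                paste0("ch2:", f[[2]], recycle0 = TRUE))
      if (length(tags) == 0L) return(NULL)
      paste(paste(a$devices, collapse = ","),
            paste(a$inducers, collapse = ","), tags)
    }))
  }
  base <- feas_points(2, 2)
  expect_true(all(feas_points(4, 2) %in% base))    # raise fold_on
  expect_true(all(feas_points(2, 1.5) %in% base))  # lower fold_off
  # max_channels is non-increasing in fold_on
  mc <- vapply(c(1.5, 3, 10, 50),
               function(f_on) max_channels(db, design_spec(1, f_on, 2,
                                                           grid = grid)),
               0L)
  expect_true(all(diff(mc) <= 0))
})

test_that("max_channels: full board on diagonal db, 0 on an all-flat db", {
  spec <- design_spec(1, 2, 2)
  expect_equal(max_channels(diagonal_db(6), spec), 6)
  expect_equal(max_channels(diagonal_db(4, fold = 1e6), spec), 4)
  flat <- diagonal_db(3, fold = 1)  # a == b everywhere: nothing activates
  expect_equal(max_channels(flat, spec), 0)
})

test_that("search output is deterministic and respects the rook condition", {
  db <- random_db(4, 4, seed = 33)
  spec <- design_spec(2, 2, 2)
  r1 <- search_designs(db, spec)
  r2 <- search_designs(db, spec)
  expect_identical(design_channels(r1), design_channels(r2))
  for (d in r1) {
    expect_false(anyDuplicated(d$channels$device) > 0)
    expect_false(anyDuplicated(d$channels$inducer) > 0)
  }
})

test_that("strictness flags govern threshold boundary behaviour", {
  # a flat pair's fold is exactly 1, giving an exact threshold boundary
  grid <- 10^seq(-12, -4, length.out = 5)
  params <- expand.grid(device_id = c("D1", "D2"),
                        inducer_id = c("I1", "I2"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  params$a <- ifelse(params$device_id == "D1" & params$inducer_id == "I1",
                     400, 100)
  params$b <- 100; params$ec50_M <- 1e-7; params$h <- 1
  params$saturated <- TRUE
  db <- crosstalk_db(params, c(D1 = "I1", D2 = "I2"))

  # activation boundary: D2's flat cognate sits exactly at fold_on = 1
  asg_flat <- list(devices = "D2", inducers = "I2")
  on_ge <- design_spec(1, 1, 2, grid = grid, on_strict = FALSE)
  on_gt <- design_spec(1, 1, 2, grid = grid, on_strict = TRUE)
  expect_true(point_feasible(db, asg_flat, 1e-4, on_ge))
  expect_false(point_feasible(db, asg_flat, 1e-4, on_gt))

  # crosstalk boundary: flat cross pairs sit exactly at fold_off = 1
  asg2 <- list(devices = c("D1", "D2"), inducers = c("I1", "I2"))
  off_le <- design_spec(2, 1, 1, grid = grid, off_strict = FALSE)
  off_lt <- design_spec(2, 1, 1, grid = grid, off_strict = TRUE)
  expect_true(point_feasible(db, asg2, c(1e-4, 1e-4), off_le))
  expect_false(point_feasible(db, asg2, c(1e-4, 1e-4), off_lt))
})

test_that("feasibility matrix marks exactly the feasible concentrations", {
  db <- diagonal_db(2, fold = 100, ec50 = 1e-8, h = 1.2)
  grid <- default_conc_grid()
  spec <- design_spec(2, 2, 2, grid = grid)
  asg <- list(devices = c("D1", "D2"), inducers = c("I1", "I2"))
  fm <- feasibility_matrix(db, asg, spec)
  expect_equal(nrow(fm), 2)
  crossing <- fold_crossing_conc(100 * 100, 100, 1e-8, 1.2, F = 2)
  greens <- grid >= crossing
  expect_identical(unlist(fm[1, -(1:2)], use.names = FALSE),
                   ifelse(greens, "green", "red"))
})
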