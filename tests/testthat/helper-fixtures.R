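# Fixtures built in code: small hand-specified databases and series used
# across test files.

# Database with activating cognate (diagonal) curves and flat (a == b)
# off-diagonal pairs: fully orthogonal by construction.
diagonal_db <- function(n = 6, fold = 100, b = 100, ec50 = 1e-8, h = 1.2) {
  devices <- paste0("D", seq_len(n))
  inducers <- paste0("I", seq_len(n))
  params <- expand.grid(device_id = devices, inducer_id = inducers,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  diag_pair <- match(params$device_id, devices) ==
    match(params$inducer_id, inducers)
  params$a <- ifelse(diag_pair, b * fold, b)
  params$b <- b
  params$ec50_M <- ec50
  params$h <- h
  params$saturated <- diag_pair
  crosstalk_db(params, cognate = stats::setNames(inducers, devices),
               devices = devices, inducers = inducers)
}

# Long-format series from exact 4PL values, n replicates, no noise.
exact_series <- function(params, grid, nrep = 1,
                         device = "dev", inducer = "ind") {
  titration_series(device, inducer,
                   concentration = rep(grid, each = nrep),
                   response = rep(eval_4pl(params, grid), each = nrep),
                   replicate = rep(seq_len(nrep), times = length(grid)))
}

# Closed-form concentration where the fold curve (shared basal) crosses F:
# fold(c) = 1 + (a/b - 1) / (1 + (ec50/c)^h) = F.
fold_crossing_conc <- function(a, b, ec50, h, F) {
  A <- a / b
  ec50 * ((F - 1) / (A - F))^(1 / h)
}

# Extract channel tables for design-list comparisons.
design_channels <- function(designs) lapply(designs, function(d) d$channels)
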