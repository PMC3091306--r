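# shared fixtures, built in code

sc_pc_head <- function() parse_sum_composition("C5 H15 O4 N1 P1", charge = 1L)
sc_pc361 <- function() parse_sum_composition("C44 H87 N1 O8 P1", charge = 1L)

pc_constraint <- function() parse_sc_constraint("C[30..48]H[30..200]N[1]O[8]P[1]",
                                                charge = 1L, dbr_range = c(1.5, 7.5))

pc_query_path <- function() {
  p <- system.file("extdata", "phosphatidylcholine.mfql", package = "lipidscan")
  if (!nzchar(p)) p <- test_path("..", "..", "inst", "extdata",
                                 "phosphatidylcholine.mfql")
  p
}

# positive-mode mixture: one genuine PC plus decoys that must not satisfy the
# PC query (a PE-like species matching the precursor constraint but lacking
# the head-group fragment, and a neutral-loss-free DAG-like ion)
pc_decoy_truth <- function() {
  lipid_ground_truth(list(
    list(name = "PC 36:1", chemsc = sc_pc361(), amount = 5,
         fragments = list(head = sc_pc_head())),
    list(name = "PE 36:1",
         chemsc = parse_sum_composition("C41 H81 N1 O8 P1", charge = 1L),
         amount = 3,
         fragments = list(gly = parse_sum_composition("C3 H9 O4 N1 P1", charge = 1L))),
    list(name = "DAG-like",
         chemsc = parse_sum_composition("C43 H81 O5", charge = 1L),
         amount = 2,
         fragments = list(f = parse_sum_composition("C20 H37 O2", charge = 1L)))
  ), polarity = "+")
}

pc_decoy_masterscan <- function(seed = 11L) {
  acqs <- simulate_acquisitions(pc_decoy_truth(), n_acquisitions = 3L,
                                n_scans = 2L, seed = seed,
                                jitter_ms1 = 2e5, jitter_ms2 = 2e5, cv = 0.05)
  model <- resolution_model(1e5, 400, 0)
  build_masterscan(acqs, model, model, min_sn = 0)
}

# brute-force oracle for composition enumeration: plain nested grid
brute_force_enumeration <- function(constraint, target_mz, tol) {
  grid <- do.call(expand.grid, lapply(constraint$ranges, function(r) r[1]:r[2]))
  out <- list()
  for (i in seq_len(nrow(grid))) {
    cnt <- unlist(grid[i, , drop = TRUE])
    names(cnt) <- names(constraint$ranges)
    if (all(cnt == 0)) next
    sc <- sum_composition(cnt[cnt > 0], charge = constraint$charge)
    d <- dbr(sc)
    if (d < constraint$dbr_range[1] || d > constraint$dbr_range[2]) next
    if (abs(monoisotopic_mz(sc) - target_mz) <= tol_width(tol, target_mz))
      out[[length(out) + 1L]] <- sc
  }
  out
}

# direct polynomial-convolution oracle for isotope abundances (no mass
# bookkeeping, no truncation tricks: full-length products, trimmed at the end)
brute_force_pattern <- function(counts, n_peaks) {
  tab <- lipidscan:::.isotope_table
  mult <- function(p, q) {
    r <- numeric(length(p) + length(q) - 1L)
    for (i in seq_along(p)) r[i:(i + length(q) - 1L)] <-
        r[i:(i + length(q) - 1L)] + p[i] * q
    r
  }
  poly <- 1
  for (sym in names(counts)) {
    iso <- tab[[sym]]
    offs <- as.integer(round(iso$mass - iso$mass[1]))
    ep <- numeric(max(offs) + 1L)
    ep[offs + 1L] <- iso$abundance
    for (a in seq_len(counts[[sym]])) poly <- mult(poly, ep)
  }
  poly <- c(poly, numeric(n_peaks))[seq_len(n_peaks)]
  poly / poly[1]
}
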