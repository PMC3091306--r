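.C13_SHIFT <- 1.0033548378  # 13C - 12C, the dominant isotopologue spacing

# resolution-determined overlap half-window: an isotopologue contributes to a
# peak when the two cannot be resolved, i.e. |dm| <= m / (2 R(m)). At unit
# resolution this merges the M+2 of a species with the monoisotopic peak of
# its +1-double-bond neighbor; at R = 100,000 it does not.
.overlap_halfwidth <- function(model, m) m / (2 * resolution_at(model, m))

#' Isotopic correction of MS precursor intensities
#'
#' Peaks of lipid species 1-2 Da apart sit inside each other's isotopic
#' clusters: the M+1/M+2 isotopologues of a lighter species add to the
#' monoisotopic peak of a heavier one whenever the instrument cannot resolve
#' them. Given the identified species (each with a bound sum composition and
#' a per-acquisition intensity vector), the expected isotopologue intensities
#' are computed from the composition's natural isotope pattern and subtracted
#' in a single light-to-heavy sweep; already-corrected intensities feed the
#' subtraction cascade, so chains of overlapping clusters unwind correctly.
#'
#' @param entries list of identified species; each a list with `name`,
#'   `chemsc` (a `sum_composition`), `mz` (observed m/z) and `intensity`
#'   (named per-acquisition vector). Entries without a composition are
#'   skipped with a warning.
#' @param model `resolution_model` of the MS level being corrected.
#' @param depth number of isotopologue peaks subtracted (default 2:
#'   M+1 and M+2, which covers glycerophospholipids).
#' @return list with `entries` (corrected intensity vectors, input order),
#'   `ledger` (data.frame: one row per subtraction and acquisition with the
#'   requested and applied amounts; corrected intensities are floored at 0
#'   and `clipped` records the difference).
#' @export
correct_ms <- function(entries, model, depth = 2L) {
  stopifnot(length(entries) > 0L)
  has_sc <- vapply(entries, function(e) inherits(e$chemsc, "sum_composition"),
                   logical(1))
  if (any(!has_sc))
    warning("skipping ", sum(!has_sc), " species without a bound composition")
  ord <- order(vapply(entries, function(e) e$mz, numeric(1)))
  cur <- lapply(entries, function(e) e$intensity)
  ledger <- list()
  for (i in ord) {
    if (!has_sc[i]) next
    pat <- isotope_pattern(entries[[i]]$chemsc, n_peaks = depth + 1L)
    for (k in seq_len(depth)) {
      iso_mz <- pat$mz[k + 1L]
      ratio <- pat$abundance[k + 1L]
      if (!is.finite(iso_mz) || ratio <= 0) next
      for (j in ord) {
        if (entries[[j]]$mz <= entries[[i]]$mz || j == i) next
        if (abs(entries[[j]]$mz - iso_mz) >
            .overlap_halfwidth(model, entries[[j]]$mz)) next
        amount <- cur[[i]] * ratio
        applied <- pmin(amount, cur[[j]])
        cur[[j]] <- cur[[j]] - applied
        ledger[[length(ledger) + 1L]] <- data.frame(
          target = entries[[j]]$name, source = entries[[i]]$name,
          offset = k, acquisition = names(amount) %||% seq_along(amount),
          requested = unname(amount), applied = unname(applied),
          clipped = unname(amount - applied))
      }
    }
  }
  out <- entries
  for (i in seq_along(out)) out[[i]]$intensity <- cur[[i]]
  list(entries = out,
       ledger = if (length(ledger)) do.call(rbind, ledger) else
         data.frame(target = character(0), source = character(0),
                    offset = integer(0), acquisition = character(0),
                    requested = numeric(0), applied = numeric(0),
                    clipped = numeric(0)))
}

# probability that j of the k heavy isotopes of an isolated precursor
# isotopologue end up on a released fragment carrying C_f of the precursor's
# C_p carbons (carbon-only transfer; 13C dominates lipid envelopes)
.fragment_transfer <- function(j, k, c_frag, c_prec) {
  stats::dhyper(j, c_frag, c_prec - c_frag, k)
}

#' Isotopic correction of MS/MS fragment intensities
#'
#' In tandem spectra the contamination is indirect: the precursor isolation
#' window of a heavier species co-isolates isotopologues of lighter
#' precursors, whose fragments (carrying 0..k of the heavy isotopes,
#' hypergeometrically distributed over the carbon skeleton) then overlap the
#' heavier species' own fragments -- at unit resolution the M+2 acyl anion of
#' a fatty acid overlaps the acyl anion of its saturated-by-one counterpart.
#' The sweep runs light to heavy over identified precursors: for every
#' heavier fragment block whose isolation window contains an isotopologue of
#' a lighter precursor, the expected fragment isotopologue intensities
#' (corrected own-block fragment intensity x precursor isotopologue
#' abundance x carbon transfer probability) are subtracted from overlapping
#' peaks of that block.
#'
#' @param species list of identified species: each a list with `name`,
#'   `chemsc` (precursor ion `sum_composition`), `block` (index into
#'   `blocks`), `fragments` (named list of fragment `sum_composition`s).
#' @param blocks list of MS2 blocks: each a list with `precursor_mz`
#'   (recorded), `mz` (fragment masses) and `intensities` (fragments x
#'   acquisitions matrix).
#' @param model MS2 `resolution_model` (sets the fragment overlap window).
#' @param isolation_width precursor isolation window in Da.
#' @param depth precursor isotopologue depth considered (default 2).
#' @param tol fragment matching tolerance (default: the resolution window).
#' @return list with `blocks` (corrected), `species_intensity` (per species:
#'   named list of corrected per-acquisition fragment intensity vectors) and
#'   `ledger` as in [correct_ms()].
#' @export
correct_msms <- function(species, blocks, model, isolation_width = 1.0,
                         depth = 2L, tol = NULL) {
  stopifnot(length(species) > 0L, length(blocks) > 0L)
  half <- isolation_width / 2
  frag_window <- function(m) if (is.null(tol)) .overlap_halfwidth(model, m)
                             else tol_width(tol, m)
  match_frag <- function(block, target_mz) {
    d <- abs(block$mz - target_mz)
    j <- which.min(d)
    if (length(j) == 1L && d[j] <= frag_window(block$mz[j])) j else NA_integer_
  }
  ord <- order(vapply(species, function(s) monoisotopic_mz(s$chemsc), numeric(1)))
  ledger <- list()
  for (si in ord) {
    s <- species[[si]]
    prec_pat <- isotope_pattern(s$chemsc, n_peaks = depth + 1L)
    c_prec <- sc_count(s$chemsc, "C")
    z <- max(1L, abs(s$chemsc$charge))
    own <- blocks[[s$block]]
    for (bi in seq_along(blocks)) {
      blk <- blocks[[bi]]
      for (k in seq_len(depth)) {
        if (prec_pat$abundance[k + 1L] <= 0) next
        if (abs(prec_pat$mz[k + 1L] - blk$precursor_mz) > half) next
        for (fn in names(s$fragments)) {
          fsc <- s$fragments[[fn]]
          f_theo <- monoisotopic_mz(fsc)
          fj_own <- match_frag(own, f_theo)
          if (is.na(fj_own)) next
          src <- blocks[[s$block]]$intensities[fj_own, ]  # current (corrected)
          for (j in 0:k) {
            h <- .fragment_transfer(j, k, sc_count(fsc, "C"), c_prec)
            if (h <= 0) next
            target <- f_theo + j * .C13_SHIFT / z
            gj <- match_frag(blk, target)
            if (is.na(gj)) next
            if (bi == s$block && gj == fj_own) next  # never reduce a peak by itself
            amount <- src * prec_pat$abundance[k + 1L] * h
            applied <- pmin(amount, blocks[[bi]]$intensities[gj, ])
            ledger[[length(ledger) + 1L]] <- data.frame(
              target = sprintf("block%d@%.4f", bi, blk$mz[gj]),
              source = paste0(s$name, ":", fn), offset = k,
              acquisition = colnames(blocks[[bi]]$intensities) %||%
                as.character(seq_along(applied)),
              requested = unname(amount), applied = unname(applied),
              clipped = unname(amount - applied))
            blocks[[bi]]$intensities[gj, ] <-
              blocks[[bi]]$intensities[gj, ] - applied
          }
        }
      }
    }
  }
  species_intensity <- lapply(species, function(s) {
    blk <- blocks[[s$block]]
    out <- list()
    for (fn in names(s$fragments)) {
      j <- match_frag(blk, monoisotopic_mz(s$fragments[[fn]]))
      out[[fn]] <- if (is.na(j)) NULL else blk$intensities[j, ]
    }
    out
  })
  names(species_intensity) <- vapply(species, function(s) s$name, character(1))
  list(blocks = blocks, species_intensity = species_intensity,
       ledger = if (length(ledger)) do.call(rbind, ledger) else
         data.frame(target = character(0), source = character(0),
                    offset = integer(0), acquisition = character(0),
                    requested = numeric(0), applied = numeric(0),
                    clipped = numeric(0)))
}
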