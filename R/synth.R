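#' Template spectrum for alignment validation
#'
#' Builds the deterministic template used to validate the binning/alignment
#' algorithm: starting at the lower mass bound, each successive mass is one
#' resolution-determined bin width above the previous one,
#' `m[k+1] = m[k] + m[k] / R_template`. With the defaults (R = 500 over
#' 500-945 Da, the range covering most lipid precursors) the template holds
#' 319 masses spaced on average by 1.4 Da.
#'
#' @param R_template resolution defining the spacing (default 500).
#' @param lo,hi mass range in Da (defaults 500 and 945).
#' @return numeric vector of template masses.
#' @export
make_template <- function(R_template = 500, lo = 500, hi = 945) {
  if (lo >= hi) stop("lo must be below hi")
  if (R_template <= 0) stop("R_template must be positive")
  out <- numeric(0)
  m <- lo
  while (m <= hi) {
    out <- c(out, m)
    nxt <- m + m / R_template
    if (nxt == m) break   # R_template -> Inf degenerates to a single mass
    m <- nxt
  }
  out
}

#' Simulated repeated acquisitions of a template spectrum
#'
#' Generates `n_spectra` single-scan spectra: each has one unit-intensity
#' peak per template mass, drawn from a Gaussian centered on the template
#' mass with the instrument's mass imprecision `sigma = m / (2 R_instrument)`
#' (half the FWHM-resolution bin width, so one ideally centered bin captures
#' 68% of the draws). At the default parameters neighboring template
#' positions never overlap.
#'
#' @param template template masses (see [make_template()]).
#' @param n_spectra number of simulated spectra (default 256).
#' @param R_instrument instrument resolution governing the jitter
#'   (default 100000).
#' @param seed mandatory RNG seed -- generation is a pure function of
#'   (parameters, seed).
#' @return list of `scan` objects (MS1, positive, unit intensities).
#' @export
generate_template_spectra <- function(template, n_spectra = 256L,
                                      R_instrument = 1e5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  sigma <- template / (2 * R_instrument)
  withr::with_seed(seed, {
    lapply(seq_len(n_spectra), function(i) {
      scan(mz = stats::rnorm(length(template), template, sigma),
           intensity = rep(1, length(template)),
           ms_level = 1L, polarity = "+", index = i)
    })
  })
}

#' Alignment accuracy against a known template
#'
#' For each template mass, the nearest aligned entry is taken as its aligned
#' counterpart; returns per-position occupancy and mass deviations plus their
#' means -- the quantities used to validate the alignment algorithm.
#'
#' @param template template masses.
#' @param mz aligned representative masses.
#' @param occupancy aligned per-entry occupancy.
#' @return list: `n_entries`, `mean_occupancy`, `mean_abs_mda`,
#'   `mean_abs_ppm`, and the per-position vectors.
#' @export
template_alignment_stats <- function(template, mz, occupancy) {
  idx <- vapply(template, function(m) which.min(abs(mz - m)), integer(1))
  dev <- mz[idx] - template
  list(n_entries = length(mz),
       mean_occupancy = mean(occupancy[idx]),
       mean_abs_mda = mean(abs(dev)) * 1e3,
       mean_abs_ppm = mean(abs(dev) / template * 1e6),
       occupancy = occupancy[idx], deviation = dev)
}

#' Run the template alignment experiment
#'
#' Generates the simulated spectra, aligns them with 1..`n_passes` binning
#' passes and reports the template-matched statistics after each pass.
#'
#' @inheritParams generate_template_spectra
#' @param align_model `resolution_model` used for binning (default constant
#'   R = 100000, matching the simulated imprecision).
#' @param n_passes maximum number of passes evaluated (default 3).
#' @return data.frame: one row per pass with `n_entries`, `mean_occupancy`,
#'   `mean_abs_mda`, `mean_abs_ppm`.
#' @export
run_template_experiment <- function(seed, template = make_template(),
                                    n_spectra = 256L, R_instrument = 1e5,
                                    align_model = resolution_model(1e5, 0, 0),
                                    n_passes = 3L) {
  spectra <- generate_template_spectra(template, n_spectra, R_instrument, seed)
  specs <- lapply(spectra, function(s) data.frame(mz = s$mz, intensity = s$intensity))
  names(specs) <- sprintf("sim%03d", seq_along(specs))
  out <- vector("list", n_passes)
  for (p in seq_len(n_passes)) {
    al <- align_spectra(specs, align_model, n_passes = p)
    st <- template_alignment_stats(template, al$mz, al$occupancy)
    out[[p]] <- data.frame(passes = p, n_entries = st$n_entries,
                           mean_occupancy = st$mean_occupancy,
                           mean_abs_mda = st$mean_abs_mda,
                           mean_abs_ppm = st$mean_abs_ppm)
  }
  do.call(rbind, out)
}

# ---- lipid mixture ground truth ---------------------------------------------

#' Ground-truth lipid mixtures for end-to-end simulation
#'
#' A ground truth lists ion species (name, ion sum composition, molar
#' amount) and, per species, the MS2 fragment rules: named fragment ion
#' compositions with an integer yield (2 for an acyl anion occurring twice in
#' a di-18:1 species). Fragment compositions must be sub-formulas of the
#' precursor.
#'
#' @param species list of species; each a list with `name`, `chemsc`
#'   (`sum_composition` of the ion), `amount` (> 0), `fragments` (named list
#'   of `sum_composition`), `yields` (named numeric, defaults to 1 per
#'   fragment).
#' @param polarity `"+"` or `"-"`.
#' @return object of class `lipid_ground_truth`.
#' @export
lipid_ground_truth <- function(species, polarity) {
  stopifnot(length(species) > 0L, polarity %in% c("+", "-"))
  for (s in species) {
    stopifnot(inherits(s$chemsc, "sum_composition"), s$amount > 0)
    for (f in s$fragments) {
      stopifnot(inherits(f, "sum_composition"))
      if (monoisotopic_mz(f) >= monoisotopic_mz(s$chemsc) + 1)
        stop("fragment heavier than precursor in species ", s$name)
    }
  }
  species <- lapply(species, function(s) {
    if (is.null(s$yields))
      s$yields <- stats::setNames(rep(1, length(s$fragments)), names(s$fragments))
    s
  })
  structure(list(species = species, polarity = polarity),
            class = "lipid_ground_truth")
}

#' The four-standard phosphatidic acid mixture
#'
#' Ground truth emulating the classic isotopic-correction validation sample:
#' PA 18:0/18:2 and PA 18:1/18:1 are exactly isobaric (the MS precursor peak
#' pools them 1+9), with PA 18:0/18:1 and PA 18:0/18:0 each one and two
#' double bonds down, so at unit resolution the isotopic clusters overlap
#' pairwise. Deprotonated ions, negative mode; acyl anions as MS2 fragments.
#'
#' @param amounts molar amounts of (18:0/18:2, 18:1/18:1, 18:0/18:1,
#'   18:0/18:0); default the validation ratio 1:9:1:1.
#' @return a `lipid_ground_truth`.
#' @export
pa_mixture_truth <- function(amounts = c(1, 9, 1, 1)) {
  stopifnot(length(amounts) == 4L)
  acyl <- list(  # fatty-acid carboxylate anions
    `FA18:2` = parse_sum_composition("C18 H31 O2", charge = -1L),
    `FA18:1` = parse_sum_composition("C18 H33 O2", charge = -1L),
    `FA18:0` = parse_sum_composition("C18 H35 O2", charge = -1L))
  pa <- function(h) parse_sum_composition(sprintf("C39 H%d O8 P1", h), charge = -1L)
  lipid_ground_truth(list(
    list(name = "PA 18:0/18:2", chemsc = pa(72), amount = amounts[1],
         fragments = acyl[c("FA18:0", "FA18:2")]),
    list(name = "PA 18:1/18:1", chemsc = pa(72), amount = amounts[2],
         fragments = acyl["FA18:1"],
         yields = c(`FA18:1` = 2)),
    list(name = "PA 18:0/18:1", chemsc = pa(74), amount = amounts[3],
         fragments = acyl[c("FA18:0", "FA18:1")]),
    list(name = "PA 18:0/18:0", chemsc = pa(76), amount = amounts[4],
         fragments = acyl["FA18:0"],
         yields = c(`FA18:0` = 2))
  ), polarity = "-")
}

#' Simulate a multi-acquisition shotgun dataset from a ground truth
#'
#' MS1 scans contain the isotope envelopes of all species (via
#' [isotope_pattern()]) scaled by molar amounts, with multiplicative
#' log-normal intensity noise and Gaussian mass jitter
#' `sigma = m / (2 R_jitter)`. One MS2 spectrum is generated per distinct
#' monoisotopic precursor mass (data-dependent acquisition): every species
#' isotopologue inside the isolation window contributes its fragment rules,
#' with the co-isolated heavy isotopes distributed hypergeometrically over
#' the carbon skeleton -- so isobaric precursors are co-fragmented and
#' isotopologue-contaminated fragment blocks arise exactly as on the
#' instrument.
#'
#' @param truth a `lipid_ground_truth`.
#' @param n_acquisitions technical replicates to simulate.
#' @param n_scans scans per spectrum and acquisition.
#' @param seed mandatory RNG seed.
#' @param jitter_ms1,jitter_ms2 resolutions governing mass jitter (sigma =
#'   m/(2R)); these describe the simulated instrument's centroid scatter and
#'   are independent of the resolution model later used for binning.
#' @param isolation_width precursor isolation window in Da (default 1).
#' @param cv coefficient of variation of the log-normal intensity noise
#'   (default 0.1); 0 disables intensity noise.
#' @param isotope_depth isotopologue peaks generated per species (default 3:
#'   M+0..M+2; 1 generates monoisotopic-only spectra).
#' @param base_intensity intensity of one molar unit (default 1e5).
#' @param chemical_noise number of uniform random low-intensity noise peaks
#'   per MS1 scan (default 0).
#' @return list of `acquisition` objects.
#' @export
simulate_acquisitions <- function(truth, n_acquisitions = 4L, n_scans = 3L,
                                  seed, jitter_ms1 = 1e5, jitter_ms2 = 1e5,
                                  isolation_width = 1.0, cv = 0.1,
                                  isotope_depth = 3L, base_intensity = 1e5,
                                  chemical_noise = 0L) {
  stopifnot(inherits(truth, "lipid_ground_truth"))
  if (missing(seed)) stop("seed is mandatory")
  pol <- truth$polarity
  sdlog <- if (cv > 0) sqrt(log(1 + cv^2)) else 0
  rln <- function(n) if (sdlog > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else rep(1, n)

  # theoretical MS1 peak list: every species isotopologue
  ms1_theo <- do.call(rbind, lapply(truth$species, function(s) {
    pat <- isotope_pattern(s$chemsc, n_peaks = isotope_depth)
    keep <- is.finite(pat$mz) & pat$abundance > 0
    data.frame(mz = pat$mz[keep],
               intensity = s$amount * base_intensity * pat$abundance[keep])
  }))
  mz_lo <- min(ms1_theo$mz) - 50; mz_hi <- max(ms1_theo$mz) + 50

  # distinct recorded precursors: monoisotopic m/z of each species, grouped
  prec_mz <- vapply(truth$species, function(s) monoisotopic_mz(s$chemsc), numeric(1))
  pg <- .group_by_width(prec_mz, isolation_width / 2)
  recorded <- vapply(split(prec_mz, pg), mean, numeric(1))

  # theoretical fragment list per recorded precursor (co-isolation included)
  ms2_theo <- lapply(recorded, function(p) {
    rows <- list()
    for (s in truth$species) {
      pat <- isotope_pattern(s$chemsc, n_peaks = isotope_depth)
      cp <- sc_count(s$chemsc, "C")
      z <- max(1L, abs(s$chemsc$charge))
      for (k in which(abs(pat$mz - p) <= isolation_width / 2) - 1L) {
        for (fn in names(s$fragments)) {
          fsc <- s$fragments[[fn]]
          f0 <- monoisotopic_mz(fsc)
          for (j in 0:k) {
            h <- .fragment_transfer(j, k, sc_count(fsc, "C"), cp)
            if (h <= 0) next
            rows[[length(rows) + 1L]] <- data.frame(
              mz = f0 + j * .C13_SHIFT / z,
              intensity = s$amount * base_intensity *
                pat$abundance[k + 1L] * h * s$yields[[fn]])
          }
        }
      }
    }
    if (length(rows) == 0L) return(NULL)
    df <- do.call(rbind, rows)
    # pool entries closer than the jitter scale (identical theoretical masses)
    g <- .group_by_width(df$mz, 1e-6)
    o <- order(df$mz)
    data.frame(mz = rowsum(df$mz[o], g[o])[, 1] / tabulate(g[o]),
               intensity = rowsum(df$intensity[o], g[o])[, 1])
  })

  withr::with_seed(seed, {
    lapply(seq_len(n_acquisitions), function(a) {
      acq_scale <- rln(1)
      scans <- list()
      for (sc_i in seq_len(n_scans)) {
        mzj <- stats::rnorm(nrow(ms1_theo), ms1_theo$mz,
                            ms1_theo$mz / (2 * jitter_ms1))
        ij <- ms1_theo$intensity * acq_scale * rln(nrow(ms1_theo))
        if (chemical_noise > 0L) {
          mzj <- c(mzj, stats::runif(chemical_noise, mz_lo, mz_hi))
          ij <- c(ij, stats::runif(chemical_noise, 0,
                                   0.005 * max(ms1_theo$intensity)))
        }
        scans[[length(scans) + 1L]] <- scan(mzj, ij, ms_level = 1L,
                                            polarity = pol, index = length(scans) + 1L)
      }
      for (pi in seq_along(recorded)) {
        theo <- ms2_theo[[pi]]
        if (is.null(theo)) next
        for (sc_i in seq_len(n_scans)) {
          mzj <- stats::rnorm(nrow(theo), theo$mz, theo$mz / (2 * jitter_ms2))
          ij <- theo$intensity * acq_scale * rln(nrow(theo))
          scans[[length(scans) + 1L]] <- scan(
            mzj, ij, ms_level = 2L, polarity = pol,
            precursor_mz = recorded[pi], index = length(scans) + 1L)
        }
      }
      acquisition(sprintf("sim-acq%02d", a), scans)
    })
  })
}

# ---- mzXML writing ----------------------------------------------------------

.encode_peaks <- function(mz, intensity) {
  vals <- as.numeric(rbind(mz, intensity))
  jsonlite::base64_enc(writeBin(vals, raw(), size = 8L, endian = "big"))
}

#' Write an acquisition as mzXML
#'
#' Minimal standards-conforming mzXML: centroided scans, 64-bit network-
#' byte-order uncompressed peak arrays; MS2 scans carry their recorded
#' precursor. Acquisitions written here re-read identically (to float64
#' precision) with [read_mzxml()].
#'
#' @param acq an `acquisition`.
#' @param path output file.
#' @export
write_mzxml <- function(acq, path) {
  stopifnot(inherits(acq, "acquisition"))
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  lines <- c('<?xml version="1.0" encoding="ISO-8859-1"?>',
             '<mzXML xmlns="http://sashimi.sourceforge.net/schema_revision/mzXML_3.2">',
             sprintf(' <msRun scanCount="%d">', length(acq$scans)))
  for (i in seq_along(acq$scans)) {
    s <- acq$scans[[i]]
    lines <- c(lines, sprintf(
      '  <scan num="%d" msLevel="%d" polarity="%s" peaksCount="%d" centroided="1">',
      i, s$ms_level, esc(s$polarity), length(s$mz)))
    if (s$ms_level == 2L)
      lines <- c(lines, sprintf('   <precursorMz precursorIntensity="0">%.8f</precursorMz>',
                                s$precursor_mz))
    lines <- c(lines, paste0(
      '   <peaks precision="64" byteOrder="network" contentType="m/z-int" compressionType="none">',
      .encode_peaks(s$mz, s$intensity), '</peaks>'),
      '  </scan>')
  }
  lines <- c(lines, ' </msRun>', '</mzXML>')
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write a simulated dataset plus manifest to a directory
#' @param acquisitions list of `acquisition` objects.
#' @param dir output directory (created if needed).
#' @param groups optional named list of acquisition-id vectors.
#' @return path of the written manifest.
#' @export
write_dataset <- function(acquisitions, dir, groups = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(acquisitions, function(a) a$id, character(1))
  files <- file.path(dir, paste0(ids, ".mzXML"))
  for (i in seq_along(acquisitions)) write_mzxml(acquisitions[[i]], files[i])
  lines <- c("[files]", sprintf("%s = %s", ids, basename(files)))
  if (length(groups) > 0L)
    lines <- c(lines, "[groups]",
               vapply(names(groups), function(g)
                 sprintf("%s = %s", g, paste(groups[[g]], collapse = ", ")),
                 character(1)))
  manifest <- file.path(dir, "manifest.ini")
  writeLines(lines, manifest)
  invisible(manifest)
}

#' Run the PA-mixture isotopic-correction experiment
#'
#' End-to-end validation of the isotopic correction: simulates the
#' four-standard PA dataset, imports it at the given (unit-type) resolution,
#' matches the known species to precursor entries and MS2 blocks, and
#' quantifies them before and after correction. MS quantification uses the
#' precursor peak (the two isobaric standards pool into one peak, expected
#' 10:1:1); MS/MS quantification sums each species' acyl-anion intensities
#' within its own fragment block (expected 1:9:1:1).
#'
#' @param seed RNG seed for the simulation.
#' @param amounts molar amounts (default 1:9:1:1).
#' @param n_acquisitions,n_scans simulation size.
#' @param analysis_resolution FWHM resolution assumed during import and
#'   correction (default 800, at which the overlapping clusters merge).
#' @param cv intensity noise (default 0.05).
#' @return list with `ms_ratio`/`ms_ratio_raw` (pool, 36:1, 36:0 normalized
#'   to the smaller components) and `msms_ratio`/`msms_ratio_raw` (per
#'   species, normalized to species 1), each averaged over acquisitions.
#' @export
run_pa_experiment <- function(seed, amounts = c(1, 9, 1, 1),
                              n_acquisitions = 4L, n_scans = 3L,
                              analysis_resolution = 800, cv = 0.05) {
  truth <- pa_mixture_truth(amounts)
  acqs <- simulate_acquisitions(truth, n_acquisitions, n_scans, seed = seed,
                                jitter_ms1 = 1e4, jitter_ms2 = 1e4, cv = cv)
  model <- resolution_model(analysis_resolution, 400, 0)
  ms <- build_masterscan(acqs, ms1_model = model, ms2_model = model,
                         n_passes = 3L, min_sn = 0, isolation_width = 1.0)

  sp_mz <- vapply(truth$species, function(s) monoisotopic_mz(s$chemsc), numeric(1))
  entry_of <- vapply(sp_mz, function(m) which.min(abs(ms$mz - m)), integer(1))

  # MS level: one entry per distinct precursor mass (isobaric standards pool)
  uniq <- !duplicated(entry_of)
  entries <- lapply(which(uniq), function(i) list(
    name = truth$species[[i]]$name, chemsc = truth$species[[i]]$chemsc,
    mz = ms$mz[entry_of[i]],
    intensity = ms$intensities[entry_of[i], ]))
  raw_ms <- t(vapply(entries, function(e) e$intensity,
                     numeric(length(ms$acquisitions))))
  cor_ms <- correct_ms(entries, model, depth = 2L)
  corrected_ms <- t(vapply(cor_ms$entries, function(e) e$intensity,
                           numeric(length(ms$acquisitions))))
  ms_ratio_raw <- rowMeans(sweep(raw_ms, 2, colMeans(raw_ms[-1, , drop = FALSE]), "/"))
  ms_ratio <- rowMeans(sweep(corrected_ms, 2, colMeans(corrected_ms[-1, , drop = FALSE]), "/"))

  # MS/MS level: correct fragment blocks, then sum acyl anions per species
  blocks <- lapply(which(uniq), function(i) ms$msms[[entry_of[i]]])
  block_of <- match(entry_of, entry_of[uniq])
  species <- lapply(seq_along(truth$species), function(i) {
    s <- truth$species[[i]]
    list(name = s$name, chemsc = s$chemsc, block = block_of[i],
         fragments = s$fragments)
  })
  acyl_sum <- function(spint) t(vapply(spint, function(fr)
    Reduce(`+`, fr), numeric(length(ms$acquisitions))))
  raw_species <- lapply(species, function(s) {
    blk <- blocks[[s$block]]
    out <- list()
    for (fn in names(s$fragments)) {
      j <- which.min(abs(blk$mz - monoisotopic_mz(s$fragments[[fn]])))
      out[[fn]] <- blk$intensities[j, ]
    }
    out
  })
  names(raw_species) <- vapply(species, function(s) s$name, character(1))
  cor2 <- correct_msms(species, blocks, model, isolation_width = 1.0, depth = 2L)
  msms_raw <- acyl_sum(raw_species)
  msms_cor <- acyl_sum(cor2$species_intensity)
  msms_ratio_raw <- rowMeans(sweep(msms_raw, 2, msms_raw[1, ], "/"))
  msms_ratio <- rowMeans(sweep(msms_cor, 2, msms_cor[1, ], "/"))
  list(ms_ratio = unname(ms_ratio), ms_ratio_raw = unname(ms_ratio_raw),
       msms_ratio = unname(msms_ratio), msms_ratio_raw = unname(msms_ratio_raw),
       masterscan = ms, ledger_ms = cor_ms$ledger, ledger_msms = cor2$ledger)
}

#' An E. coli-style diacyl-PE mixture
#'
#' Negative-mode ground truth of common diacyl phosphatidylethanolamine
#' species (deprotonated ions) with their acyl anions and lyso-PE fragments
#' (precursor minus fatty-acid ketene). PE species are near-isobaric with
#' ether-linked PE-O species of other classes: exchanging O for CH4 shifts
#' the exact mass by only 36.4 mDa, the classic high-resolution
#' discrimination problem.
#'
#' @param amounts molar amounts for the five species (recycled).
#' @return a `lipid_ground_truth`.
#' @export
pe_mixture_truth <- function(amounts = c(5, 8, 3, 4, 2)) {
  fa <- function(c, d)  # fatty-acid carboxylate anion
    sum_composition(c(C = c, H = 2 * c - 2 * d - 1, O = 2), charge = -1L)
  ketene <- function(c, d)  # neutral loss forming the lyso-PE fragment
    sum_composition(c(C = c, H = 2 * c - 2 * d - 2, O = 1), charge = 0L)
  pe_ion <- function(c, d)  # deprotonated diacyl PE c:d
    sum_composition(c(C = c + 5, H = 2 * (c + 5) - 2 * d - 6, N = 1, O = 8, P = 1),
                    charge = -1L)
  mk <- function(c, d, acyls, amount) {
    frs <- list(); yl <- numeric(0)
    prec <- pe_ion(c, d)
    for (a in acyls) {
      fn <- sprintf("FA%d:%d", a[1], a[2])
      frs[[fn]] <- fa(a[1], a[2])
      yl[fn] <- 1
      ln <- sprintf("LPE%d:%d", a[1], a[2])
      frs[[ln]] <- prec - ketene(a[1], a[2])
      yl[ln] <- 0.5
    }
    list(name = sprintf("PE %d:%d", c, d), chemsc = prec, amount = amount,
         fragments = frs, yields = yl)
  }
  amounts <- rep_len(amounts, 5L)
  lipid_ground_truth(list(
    mk(32, 1, list(c(16, 0), c(16, 1)), amounts[1]),
    mk(34, 1, list(c(16, 0), c(18, 1)), amounts[2]),
    mk(34, 2, list(c(16, 1), c(18, 1)), amounts[3]),
    mk(36, 2, list(c(18, 1), c(18, 1)), amounts[4]),
    mk(38, 4, list(c(18, 1), c(20, 3)), amounts[5])
  ), polarity = "-")
}

#' Count false ether-lipid (PE-O) assignments in a PE dataset
#'
#' Probes every precursor entry of a MasterScan built from a diacyl-PE
#' dataset for assignments to ether-linked PE-O compositions (one O fewer,
#' one CH4 more). A precursor is misassigned when (1) a PE-O composition
#' matches its mass within the resolution-determined tolerance `m/R(m)` of
#' the MS survey spectra, and (2) the entry's MS2 block appears to confirm
#' the assignment: some fragment matches a lyso-PE-O fragment mass implied by
#' the candidate composition (candidate m/z minus a standard fatty-acid
#' ketene) within `tol_ms2`. With low-resolution matching both gates pass for
#' abundant PE peaks (their true lyso-PE fragments sit only 36.4 mDa from the
#' expected ether fragments); at R = 100,000 in MS and a few mDa in MS/MS
#' both fail.
#'
#' @param ms a `master_scan` of a PE-only dataset.
#' @param ms1_model resolution model assumed when matching precursor masses
#'   (tolerance `m/R(m)`).
#' @param tol_ms2 fragment confirmation tolerance (`mass_tol`).
#' @param constraint PE-O sc-constraint (default C[30..48] H[30..200] N[1]
#'   O[7] P[1], charge -1, DBR 1.5-7.5).
#' @return number of precursor entries falsely assignable to PE-O.
#' @export
count_ether_misassignments <- function(ms, ms1_model, tol_ms2 = tol_da(0.3),
                                       constraint = NULL) {
  stopifnot(inherits(ms, "master_scan"))
  if (is.null(constraint))
    constraint <- parse_sc_constraint("C[30..48]H[30..200]N[1]O[7]P[1]",
                                      charge = -1L, dbr_range = c(1.5, 7.5))
  ketene_mass <- function(c, d)
    monoisotopic_mz(sum_composition(c(C = c, H = 2 * c - 2 * d - 2, O = 1)))
  chains <- expand.grid(c = seq(14L, 22L, 2L), d = 0:6)
  ketenes <- mapply(ketene_mass, chains$c, chains$d)
  n_bad <- 0L
  for (e in seq_along(ms$mz)) {
    m <- ms$mz[e]
    cands <- enumerate_compositions(constraint, m,
                                    tol_da(m / resolution_at(ms1_model, m)))
    if (length(cands) == 0L) next
    blk <- ms$msms[[e]]
    if (is.null(blk)) next
    confirmed <- FALSE
    for (sc in cands) {
      expected <- monoisotopic_mz(sc) - ketenes
      expected <- expected[expected > min(blk$mz) - 1]
      for (f in expected)
        if (any(abs(blk$mz - f) <= tol_width(tol_ms2, f))) { confirmed <- TRUE; break }
      if (confirmed) break
    }
    if (confirmed) n_bad <- n_bad + 1L
  }
  n_bad
}
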