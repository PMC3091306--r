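#' Cross-acquisition spectra alignment
#'
#' Aligns one representative spectrum per acquisition into shared mass bins.
#' The sweep is the same resolution-dependent binning used for scan
#' averaging, but representative bin masses are the plain (unweighted) mean
#' of the member peak masses, and every acquisition's member intensities are
#' summed into its own slot of a per-bin intensity vector (0 when the
#' acquisition contributed no peak).
#'
#' @param spectra named list (one element per acquisition) of data.frames
#'   with columns `mz`, `intensity` (e.g. [average_scans()] output).
#' @param model `resolution_model` for the spectra's MS level.
#' @param n_passes successive binning passes (default 3).
#' @return list with `mz` (representative masses, ascending), `occupancy`,
#'   `intensities` (matrix entries x acquisitions, acquisition ids as
#'   colnames), `n_members`.
#' @export
align_spectra <- function(spectra, model, n_passes = 3L) {
  if (length(spectra) == 0L) stop("no spectra to align")
  ids <- names(spectra)
  if (is.null(ids)) ids <- sprintf("acq%03d", seq_along(spectra))
  pieces <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    data.table::data.table(mz = s$mz, intensity = s$intensity, acq = i)
  })
  members <- data.table::rbindlist(pieces)
  members[, entry := .I]

  for (pass in seq_len(n_passes)) {
    reps <- members[, .(rep = mean(mz)), by = entry]   # unweighted
    data.table::setorder(reps, rep)
    g <- .bin_group_ids(reps$rep, model)
    map <- reps[, .(entry, new = g)]
    members <- merge(members, map, by = "entry", sort = FALSE)
    members[, entry := new][, new := NULL]
  }

  out <- members[, .(mz = mean(mz), n_members = .N), by = entry]
  data.table::setorder(out, mz)
  iv <- members[, .(si = sum(intensity)), by = .(entry, acq)]
  mat <- matrix(0, nrow = nrow(out), ncol = length(spectra),
                dimnames = list(NULL, ids))
  mat[cbind(match(iv$entry, out$entry), iv$acq)] <- iv$si
  list(mz = out$mz,
       occupancy = rowMeans(mat > 0),
       intensities = mat,
       n_members = out$n_members)
}

# greedy fixed-width grouping of sorted values (used for collecting MS2
# spectra that share a recorded precursor)
.group_by_width <- function(values, width) {
  o <- order(values)
  v <- values[o]
  g <- integer(length(v)); gi <- 0L; i <- 1L
  while (i <= length(v)) {
    gi <- gi + 1L
    k <- findInterval(v[i] + width, v, left.open = TRUE)
    if (k < i) k <- i
    g[i:k] <- gi
    i <- k + 1L
  }
  out <- integer(length(values)); out[o] <- g
  out
}

#' The MasterScan: a flat-file database of aligned shotgun spectra
#'
#' A MasterScan stores, for one polarity, the aligned precursor masses of all
#' acquisitions of an experiment, each with a per-acquisition intensity
#' vector, an occupancy (fraction of acquisitions in which the peak was
#' observed) and an attached block of aligned MS2 fragment entries.
#'
#' @param acquisitions character vector of acquisition ids (column order of
#'   all intensity matrices).
#' @param polarity `"+"` or `"-"`.
#' @param mz,occupancy,intensities aligned precursor table as returned by
#'   [align_spectra()].
#' @param ms1_model,ms2_model resolution models used at each level.
#' @param groups named list of acquisition-id vectors.
#' @param msms list (same length as `mz`) of fragment blocks or `NULL`s.
#' @param orphans MS2 blocks with no matching precursor entry.
#' @param provenance named list of thresholds/settings for the record.
#' @return object of class `master_scan`.
#' @export
master_scan <- function(acquisitions, polarity, mz, occupancy, intensities,
                        ms1_model, ms2_model = ms1_model,
                        groups = list(), msms = NULL, orphans = list(),
                        provenance = list()) {
  n <- length(mz)
  stopifnot(length(occupancy) == n, nrow(intensities) == n,
            ncol(intensities) == length(acquisitions),
            !is.unsorted(mz))
  if (is.null(msms)) msms <- vector("list", n)
  colnames(intensities) <- acquisitions
  if (length(groups) == 0L) groups <- list(all = acquisitions)
  structure(list(acquisitions = as.character(acquisitions),
                 polarity = polarity,
                 mz = as.numeric(mz), occupancy = as.numeric(occupancy),
                 intensities = intensities,
                 ms1_model = ms1_model, ms2_model = ms2_model,
                 groups = groups, msms = msms, orphans = orphans,
                 provenance = provenance),
            class = "master_scan")
}

#' @export
print.master_scan <- function(x, ...) {
  nms2 <- sum(!vapply(x$msms, is.null, logical(1)))
  cat(sprintf("<master_scan> polarity %s: %d precursor entries, %d acquisitions, %d MS2 blocks\n",
              x$polarity, length(x$mz), length(x$acquisitions), nms2))
  invisible(x)
}

#' Attach aligned MS2 blocks to precursor entries
#'
#' Each MS2 block is keyed by its recorded precursor m/z and attached to
#' every precursor entry whose representative m/z lies within half the
#' precursor isolation width of that recorded value -- several neighboring
#' precursor entries can therefore legitimately share one MS2 block. Blocks
#' matching no entry are kept in the `orphans` bucket.
#'
#' @param ms a `master_scan`.
#' @param msms_blocks list of blocks: each a list with `precursor_mz`
#'   (recorded), `mz`, `occupancy`, `intensities` (fragments x acquisitions).
#' @param isolation_width isolation window in Da (default 1.0).
#' @return the updated `master_scan`.
#' @export
associate_msms <- function(ms, msms_blocks, isolation_width = 1.0) {
  stopifnot(inherits(ms, "master_scan"), isolation_width > 0)
  half <- isolation_width / 2
  for (blk in msms_blocks) {
    hit <- which(abs(ms$mz - blk$precursor_mz) <= half)
    if (length(hit) == 0L) {
      ms$orphans[[length(ms$orphans) + 1L]] <- blk
      next
    }
    for (i in hit) {
      if (is.null(ms$msms[[i]])) {
        ms$msms[[i]] <- blk
      } else {
        # merge two blocks mapping to one entry: re-align their fragments
        a <- ms$msms[[i]]
        spl <- list(data.frame(mz = a$mz, intensity = rowSums(a$intensities)),
                    data.frame(mz = blk$mz, intensity = rowSums(blk$intensities)))
        # align on the fragment level, then rebuild the acquisition matrix
        comb_mz <- sort(c(a$mz, blk$mz))
        g <- .bin_group_ids(comb_mz, ms$ms2_model)
        src <- rbind(cbind(seq_along(a$mz), 1L), cbind(seq_along(blk$mz), 2L))
        src <- src[order(c(a$mz, blk$mz)), , drop = FALSE]
        nmz <- rowsum(comb_mz, g)[, 1] / tabulate(g)
        mat <- matrix(0, nrow = max(g), ncol = length(ms$acquisitions),
                      dimnames = list(NULL, ms$acquisitions))
        for (r in seq_along(g)) {
          from <- if (src[r, 2] == 1L) a$intensities[src[r, 1], ] else blk$intensities[src[r, 1], ]
          mat[g[r], ] <- mat[g[r], ] + from
        }
        ms$msms[[i]] <- list(precursor_mz = (a$precursor_mz + blk$precursor_mz) / 2,
                             mz = nmz, occupancy = rowMeans(mat > 0),
                             intensities = mat)
      }
    }
  }
  ms
}

#' Recalibrate masses against reference (lock) masses
#'
#' Matches each reference mass to the nearest precursor entry within
#' `match_tol`, fits the observed mass shift as a linear function of mass
#' (a constant offset when only one reference matches) and subtracts the
#' fitted shift from all precursor masses. Fragment masses are corrected
#' only when MS2-level references are supplied.
#'
#' @param ms a `master_scan`.
#' @param reference_masses numeric vector of MS1 reference m/z values.
#' @param match_tol `mass_tol` for matching references (default 20 ppm).
#' @param ms2_references optional fragment-level reference masses.
#' @return the recalibrated `master_scan` (coefficients in `provenance`).
#' @export
recalibrate <- function(ms, reference_masses, match_tol = tol_ppm(20),
                        ms2_references = NULL) {
  stopifnot(inherits(ms, "master_scan"))
  fit_shift <- function(obs_mz, refs) {
    matched_obs <- numeric(0); matched_ref <- numeric(0)
    for (r in refs) {
      d <- abs(obs_mz - r)
      j <- which.min(d)
      if (d[j] <= tol_width(match_tol, r)) {
        matched_obs <- c(matched_obs, obs_mz[j])
        matched_ref <- c(matched_ref, r)
      }
    }
    if (length(matched_obs) == 0L) stop("no reference mass matched")
    err <- matched_obs - matched_ref
    if (length(matched_obs) == 1L) c(intercept = err, slope = 0)
    else {
      cf <- stats::coef(stats::lm(err ~ matched_obs))
      c(intercept = unname(cf[1]), slope = unname(cf[2]))
    }
  }
  cf <- fit_shift(ms$mz, reference_masses)
  ms$mz <- ms$mz - (cf["intercept"] + cf["slope"] * ms$mz)
  ms$provenance$recalibration_ms1 <- as.list(cf)
  if (!is.null(ms2_references)) {
    all_frag <- sort(unique(unlist(lapply(ms$msms, function(b) if (is.null(b)) NULL else b$mz))))
    cf2 <- fit_shift(all_frag, ms2_references)
    ms$msms <- lapply(ms$msms, function(b) {
      if (is.null(b)) return(NULL)
      b$mz <- b$mz - (cf2["intercept"] + cf2["slope"] * b$mz)
      b
    })
    ms$provenance$recalibration_ms2 <- as.list(cf2)
  }
  ms
}

#' Occupancy and intensity pre-filtering
#'
#' Intensities below the per-level thresholds are set to 0 first; occupancy
#' is then recomputed (over the named acquisition group if given, else all
#' acquisitions) and entries below the occupancy threshold are removed.
#' Fragment rows whose intensity vector becomes all-zero are dropped from
#' MS2 blocks.
#'
#' @param ms a `master_scan`.
#' @param min_occupancy fraction in `[0, 1]`.
#' @param min_intensity_ms1,min_intensity_ms2 absolute intensity floors.
#' @param scope optional group name over which occupancy is computed.
#' @return the filtered `master_scan`.
#' @export
filter_entries <- function(ms, min_occupancy = 0, min_intensity_ms1 = 0,
                           min_intensity_ms2 = 0, scope = NULL) {
  stopifnot(inherits(ms, "master_scan"))
  cols <- ms$acquisitions
  if (!is.null(scope)) {
    if (!scope %in% names(ms$groups)) stop("unknown group: ", scope)
    cols <- ms$groups[[scope]]
  }
  ms$intensities[ms$intensities < min_intensity_ms1] <- 0
  occ <- rowMeans(ms$intensities[, cols, drop = FALSE] > 0)
  keep <- occ >= min_occupancy
  ms$mz <- ms$mz[keep]
  ms$occupancy <- rowMeans(ms$intensities[keep, , drop = FALSE] > 0)
  ms$intensities <- ms$intensities[keep, , drop = FALSE]
  ms$msms <- lapply(ms$msms[keep], function(b) {
    if (is.null(b)) return(NULL)
    b$intensities[b$intensities < min_intensity_ms2] <- 0
    fk <- rowSums(b$intensities) > 0
    if (!any(fk)) return(NULL)
    b$mz <- b$mz[fk]
    b$intensities <- b$intensities[fk, , drop = FALSE]
    b$occupancy <- rowMeans(b$intensities > 0)
    b
  })
  ms$provenance$filter <- list(min_occupancy = min_occupancy,
                               min_intensity_ms1 = min_intensity_ms1,
                               min_intensity_ms2 = min_intensity_ms2,
                               scope = scope)
  ms
}

.MASTERSCAN_FORMAT_VERSION <- "1"

#' Persist and reload a MasterScan
#'
#' The on-disk format is a versioned JSON flat file with full-precision
#' numbers; saving is deterministic (two saves of the same object are
#' byte-identical) and `load_masterscan(save_masterscan(x))` reproduces the
#' object exactly.
#'
#' @param ms a `master_scan`.
#' @param path output file (conventionally `*.sc`).
#' @return `path`, invisibly (`save_masterscan`); a `master_scan`
#'   (`load_masterscan`).
#' @export
save_masterscan <- function(ms, path) {
  stopifnot(inherits(ms, "master_scan"))
  ser_block <- function(b) {
    if (is.null(b)) return(NULL)
    list(precursor_mz = b$precursor_mz, mz = b$mz, occupancy = b$occupancy,
         intensities = unname(apply(b$intensities, 1, as.numeric, simplify = FALSE)))
  }
  obj <- list(
    format = "lipidscan-masterscan",
    version = .MASTERSCAN_FORMAT_VERSION,
    acquisitions = ms$acquisitions,
    polarity = ms$polarity,
    groups = ms$groups,
    ms1_model = unclass(ms$ms1_model),
    ms2_model = unclass(ms$ms2_model),
    mz = ms$mz,
    occupancy = ms$occupancy,
    intensities = unname(apply(ms$intensities, 1, as.numeric, simplify = FALSE)),
    msms = lapply(ms$msms, ser_block),
    orphans = lapply(ms$orphans, ser_block),
    provenance = ms$provenance
  )
  json <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, null = "null",
                           pretty = FALSE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname save_masterscan
#' @export
load_masterscan <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (!identical(obj$format, "lipidscan-masterscan"))
    stop("not a MasterScan file: ", path)
  if (!identical(obj$version, .MASTERSCAN_FORMAT_VERSION))
    stop("unsupported MasterScan format version: ", obj$version)
  des_mat <- function(rows, ids) {
    m <- if (length(rows) == 0L) matrix(0, 0, length(ids))
         else do.call(rbind, lapply(rows, unlist))
    dimnames(m) <- list(NULL, ids)
    m
  }
  des_block <- function(b) {
    if (is.null(b)) return(NULL)
    list(precursor_mz = b$precursor_mz, mz = unlist(b$mz),
         occupancy = unlist(b$occupancy),
         intensities = des_mat(b$intensities, obj$acquisitions))
  }
  m1 <- obj$ms1_model; m2 <- obj$ms2_model
  msms <- lapply(obj$msms, des_block)
  if (length(msms) == 0L) msms <- vector("list", length(obj$mz))
  master_scan(acquisitions = unlist(obj$acquisitions),
              polarity = obj$polarity,
              mz = unlist(obj$mz), occupancy = unlist(obj$occupancy),
              intensities = des_mat(obj$intensities, unlist(obj$acquisitions)),
              ms1_model = resolution_model(m1$R0, m1$anchor, m1$gradient),
              ms2_model = resolution_model(m2$R0, m2$anchor, m2$gradient),
              groups = lapply(obj$groups, unlist),
              msms = msms,
              orphans = lapply(obj$orphans, des_block),
              provenance = obj$provenance)
}

#' Export the precursor table as CSV
#' @param ms a `master_scan`.
#' @param path output CSV; columns `mz`, `occupancy`, one intensity column
#'   per acquisition id.
#' @export
export_precursor_table <- function(ms, path) {
  df <- data.frame(mz = ms$mz, occupancy = ms$occupancy,
                   ms$intensities, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Build a MasterScan from acquisitions
#'
#' Full import pipeline: per acquisition, MS1 scans are averaged into one
#' representative spectrum and MS2 scans are collected by recorded precursor
#' and averaged; representative spectra are then aligned across acquisitions
#' (MS1 entries, and fragment blocks per recorded precursor), MS2 blocks are
#' attached to precursor entries within the isolation window, and optional
#' recalibration and occupancy/intensity pre-filters are applied.
#'
#' @param acquisitions list of `acquisition` objects (single shared polarity).
#' @param ms1_model,ms2_model resolution models.
#' @param n_passes binning passes (default 3).
#' @param min_sn per-scan signal-to-noise threshold (default 3).
#' @param isolation_width precursor isolation window in Da (default 1).
#' @param min_occupancy,min_intensity_ms1,min_intensity_ms2 pre-filters
#'   (defaults keep everything).
#' @param groups named list of acquisition-id vectors.
#' @param reference_masses optional recalibration lock masses.
#' @return a `master_scan`.
#' @export
build_masterscan <- function(acquisitions, ms1_model, ms2_model = ms1_model,
                             n_passes = 3L, min_sn = 3.0,
                             isolation_width = 1.0,
                             min_occupancy = 0, min_intensity_ms1 = 0,
                             min_intensity_ms2 = 0, groups = list(),
                             reference_masses = NULL) {
  if (length(acquisitions) == 0L) stop("no acquisitions")
  stopifnot(all(vapply(acquisitions, inherits, logical(1), "acquisition")))
  ids <- vapply(acquisitions, function(a) a$id, character(1))
  if (anyDuplicated(ids)) stop("duplicate acquisition identifiers")
  pol <- unique(unlist(lapply(acquisitions, function(a)
    vapply(a$scans, function(s) s$polarity, character(1)))))
  if (length(pol) != 1L)
    stop("acquisitions mix polarities; split them with split_polarity() first")

  ms1_avg <- list()
  frag_pool <- list()   # one row per (acquisition, recorded precursor group)
  for (a in acquisitions) {
    lvl <- vapply(a$scans, function(s) s$ms_level, integer(1))
    ms1 <- a$scans[lvl == 1L]
    if (length(ms1) == 0L) stop("acquisition ", a$id, " has no MS1 scans")
    ms1_avg[[a$id]] <- average_scans(ms1, ms1_model, n_passes, min_sn)
    ms2 <- a$scans[lvl == 2L]
    if (length(ms2) > 0L) {
      prec <- vapply(ms2, function(s) s$precursor_mz, numeric(1))
      g <- .group_by_width(prec, isolation_width / 2)
      for (gi in unique(g)) {
        avg <- average_scans(ms2[g == gi], ms2_model, n_passes, min_sn)
        frag_pool[[length(frag_pool) + 1L]] <-
          list(acq = a$id, precursor_mz = stats::median(prec[g == gi]), spec = avg)
      }
    }
  }

  al <- align_spectra(ms1_avg, ms1_model, n_passes)
  ms <- master_scan(acquisitions = ids, polarity = pol,
                    mz = al$mz, occupancy = al$occupancy,
                    intensities = al$intensities,
                    ms1_model = ms1_model, ms2_model = ms2_model,
                    groups = groups,
                    provenance = list(n_passes = n_passes, min_sn = min_sn,
                                      isolation_width = isolation_width))

  if (length(frag_pool) > 0L) {
    # group MS2 spectra across acquisitions by recorded precursor
    precs <- vapply(frag_pool, function(x) x$precursor_mz, numeric(1))
    g <- .group_by_width(precs, isolation_width / 2)
    blocks <- lapply(unique(g), function(gi) {
      sel <- frag_pool[g == gi]
      specs <- stats::setNames(vector("list", length(ids)), ids)
      for (x in sel) {
        if (is.null(specs[[x$acq]])) specs[[x$acq]] <- x$spec
        else {  # same acquisition fragmented this precursor more than once
          comb <- rbind(data.frame(mz = specs[[x$acq]]$mz, intensity = specs[[x$acq]]$intensity),
                        data.frame(mz = x$spec$mz, intensity = x$spec$intensity))
          comb <- comb[order(comb$mz), ]
          specs[[x$acq]] <- bin_pass(comb, ms2_model)
        }
      }
      present <- !vapply(specs, is.null, logical(1))
      sub <- align_spectra(specs[present], ms2_model, n_passes)
      mat <- matrix(0, nrow = length(sub$mz), ncol = length(ids),
                    dimnames = list(NULL, ids))
      mat[, colnames(sub$intensities)] <- sub$intensities
      list(precursor_mz = mean(vapply(sel, function(x) x$precursor_mz, numeric(1))),
           mz = sub$mz, occupancy = rowMeans(mat > 0), intensities = mat)
    })
    ms <- associate_msms(ms, blocks, isolation_width)
  }

  if (!is.null(reference_masses)) ms <- recalibrate(ms, reference_masses)
  if (min_occupancy > 0 || min_intensity_ms1 > 0 || min_intensity_ms2 > 0)
    ms <- filter_entries(ms, min_occupancy, min_intensity_ms1, min_intensity_ms2)
  ms
}
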