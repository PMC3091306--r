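#' Linear mass-resolution model
#'
#' FWHM resolution is assumed to change linearly over the working mass range:
#' `R(m) = R0 + gradient * (m - anchor)`. `R0` is the resolution at the
#' anchor mass (typically the lowest mass of the range), the gradient its
#' change per Da; both are instrument properties determined from reference
#' spectra. Bin widths everywhere in the package are `m / R(m)`.
#'
#' @param R0 resolution at `anchor` (dimensionless, > 0).
#' @param anchor anchor mass in Da.
#' @param gradient change of resolution per Da (default 0: constant model).
#' @return object of class `resolution_model`.
#' @export
resolution_model <- function(R0, anchor = 0, gradient = 0) {
  if (R0 <= 0) stop("R0 must be positive")
  structure(list(R0 = as.numeric(R0), anchor = as.numeric(anchor),
                 gradient = as.numeric(gradient)),
            class = "resolution_model")
}

#' @rdname resolution_model
#' @param model a `resolution_model`.
#' @param m mass (Da), vectorized.
#' @return resolution at `m`; error if non-positive anywhere.
#' @export
resolution_at <- function(model, m) {
  stopifnot(inherits(model, "resolution_model"))
  r <- model$R0 + model$gradient * (m - model$anchor)
  if (any(r <= 0)) stop("resolution model non-positive at mass ",
                        signif(m[which(r <= 0)[1]], 8))
  r
}

# Core sweep: group sorted masses into half-open bins [m, m + m/R(m)),
# anchored at the lowest unconsumed mass. Returns an integer group id per
# mass. O(bins * log n) via findInterval jumps.
.bin_group_ids <- function(masses, model) {
  n <- length(masses)
  groups <- integer(n)
  i <- 1L; g <- 0L
  while (i <= n) {
    g <- g + 1L
    m0 <- masses[i]
    end <- m0 + m0 / resolution_at(model, m0)
    # number of masses strictly below the bin's right edge
    k <- findInterval(end, masses, left.open = TRUE)
    if (k < i) k <- i   # degenerate guard (zero-width bin)
    groups[i:k] <- g
    i <- k + 1L
  }
  groups
}

#' One binning pass over a sorted peak list
#'
#' Sweeps the peak list from the lowest mass; all peaks in the half-open bin
#' `[m, m + m/R(m))` are replaced by a single peak at their intensity-weighted
#' mean mass (the weighting of the most-intense-peak normalization cancels,
#' leaving the plain weighted mean); bin intensity is the summed member
#' intensity. The sweep resumes at the first mass beyond the bin.
#'
#' @param peaks data.frame with numeric columns `mz` (ascending) and
#'   `intensity`.
#' @param model a `resolution_model`.
#' @return data.frame `mz`, `intensity`, `n_members`.
#' @export
bin_pass <- function(peaks, model) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (is.unsorted(peaks$mz)) stop("peak list must be sorted ascending by mz")
  g <- .bin_group_ids(peaks$mz, model)
  w <- rowsum(peaks$intensity, g)[, 1]
  wm <- rowsum(peaks$intensity * peaks$mz, g)[, 1]
  nm <- tabulate(g)
  data.frame(mz = wm / w, intensity = w, n_members = nm, row.names = NULL)
}

# Per-scan noise floor: median intensity of the lowest-intensity half of the
# peaks. If the implied threshold would remove even the base peak the
# estimate is deemed unusable (flat synthetic spectra have no noise
# population) and no filtering is applied.
.sn_filter <- function(mz, intensity, min_sn) {
  if (min_sn <= 0 || length(intensity) < 4L) return(seq_along(mz))
  lower <- sort(intensity)[seq_len(max(1L, length(intensity) %/% 2L))]
  thr <- min_sn * stats::median(lower)
  if (thr >= max(intensity)) return(seq_along(mz))
  which(intensity >= thr)
}

#' Average repeated scans into one representative spectrum
#'
#' All scans' peaks are pooled, sorted and noise-filtered, then the
#' resolution-dependent binning pass is applied `n_passes` times (three
#' passes suffice for complete bin separation). Masses within a bin are
#' intensity-weight averaged over the original member peaks; the
#' representative intensity of a bin is the mean, over scans contributing at
#' least one member, of the per-scan summed member intensity. Per-peak
#' occupancy is the fraction of input scans contributing to the bin.
#'
#' @param scans list of `scan` objects (same MS level and polarity).
#' @param model a `resolution_model`.
#' @param n_passes number of successive binning passes (default 3).
#' @param min_sn signal-to-noise threshold applied per scan before binning
#'   (default 3; 0 disables).
#' @return data.frame `mz`, `intensity`, `n_members`, `occupancy`, class
#'   `averaged_spectrum`, with attributes `ms_level`, `polarity`, `n_scans`,
#'   `precursor_mz` (median recorded precursor for MS2).
#' @export
average_scans <- function(scans, model, n_passes = 3L, min_sn = 3.0) {
  if (length(scans) == 0L) stop("no scans to average")
  stopifnot(all(vapply(scans, inherits, logical(1), "scan")))
  lvl <- unique(vapply(scans, function(s) s$ms_level, integer(1)))
  pol <- unique(vapply(scans, function(s) s$polarity, character(1)))
  if (length(lvl) != 1L) stop("cannot average scans of mixed MS level")
  if (length(pol) != 1L) stop("cannot average scans of mixed polarity")

  pieces <- lapply(seq_along(scans), function(i) {
    s <- scans[[i]]
    keep <- .sn_filter(s$mz, s$intensity, min_sn)
    data.table::data.table(mz = s$mz[keep], intensity = s$intensity[keep],
                           scan = i)
  })
  members <- data.table::rbindlist(pieces)
  if (nrow(members) == 0L) stop("all peaks removed by the noise filter")
  members[, entry := .I]

  for (pass in seq_len(n_passes)) {
    # current representative mass per entry: intensity-weighted member mean
    reps <- members[, .(rep = sum(mz * intensity) / sum(intensity)), by = entry]
    data.table::setorder(reps, rep)
    g <- .bin_group_ids(reps$rep, model)
    map <- reps[, .(entry, new = g)]
    members <- merge(members, map, by = "entry", sort = FALSE)
    members[, entry := new][, new := NULL]
  }

  per_scan <- members[, .(si = sum(intensity)), by = .(entry, scan)]
  out <- members[, .(mz = sum(mz * intensity) / sum(intensity),
                     n_members = .N), by = entry]
  stats <- per_scan[, .(intensity = mean(si), occ = .N / length(scans)),
                    by = entry]
  out <- merge(out, stats, by = "entry")
  data.table::setorder(out, mz)
  res <- data.frame(mz = out$mz, intensity = out$intensity,
                    n_members = out$n_members, occupancy = out$occ)
  prec <- vapply(scans, function(s) s$precursor_mz, numeric(1))
  structure(res, class = c("averaged_spectrum", "data.frame"),
            ms_level = lvl, polarity = pol, n_scans = length(scans),
            precursor_mz = if (lvl == 2L) stats::median(prec) else NA_real_)
}
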