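#' Sum compositions: elemental formulas of ions
#'
#' A sum composition is a set of non-negative element counts plus an ion
#' charge state (0 for a neutral molecule). It is the unit of all mass and
#' double-bond-equivalent arithmetic in the package. The formula is always
#' interpreted exactly as written, i.e. for an ion it is the composition of
#' the ion itself including any charge-carrying hydrogens.
#'
#' @param counts named integer vector of element counts (names are element
#'   symbols such as `"C"`, `"H"`); all counts must be non-negative.
#' @param charge integer ion charge state; 0 means neutral.
#' @return an object of class `sum_composition`.
#' @examples
#' sc <- sum_composition(c(C = 5, H = 15, O = 4, N = 1, P = 1), charge = +1)
#' monoisotopic_mz(sc)   # the phosphorylcholine head-group fragment, 184.0733
#' @export
sum_composition <- function(counts, charge = 0L) {
  if (length(counts) == 0L) stop("a sum composition needs at least one element")
  if (is.null(names(counts)) || any(names(counts) == ""))
    stop("element counts must be named by element symbol")
  unknown <- setdiff(names(counts), .known_elements())
  if (length(unknown) > 0L)
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  counts <- round(counts)
  if (any(counts < 0)) stop("element counts must be non-negative")
  counts <- counts[counts > 0]
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, charge = as.integer(charge)),
            class = "sum_composition")
}

#' Parse a formula string into a sum composition
#'
#' Accepts the space-separated dialect used throughout the package's query
#' files, e.g. `"C5 H15 O4 N1 P1"`. An omitted count means 1. Whitespace
#' between tokens is optional (`"C5H15O4N1P1"` parses identically).
#'
#' @param text formula string.
#' @param charge ion charge state attached to the parsed composition.
#' @return a `sum_composition`.
#' @export
parse_sum_composition <- function(text, charge = 0L) {
  s <- gsub("[[:space:]]+", "", text)
  if (!nzchar(s)) stop("empty formula string")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s) || length(tokens) == 0L)
    stop("malformed formula string: '", text, "'")
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Z][a-z]?", "", tokens)
  cnt <- ifelse(cnt == "", 1L, as.integer(cnt))
  counts <- tapply(cnt, sym, sum)
  sum_composition(stats::setNames(as.integer(counts), names(counts)), charge)
}

#' @export
format.sum_composition <- function(x, ...) {
  syms <- names(x$counts)
  # C, H first, remaining elements alphabetical -- the conventional order
  ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste(paste0(ord, x$counts[ord]), collapse = " ")
}

#' @export
print.sum_composition <- function(x, ...) {
  chg <- if (x$charge == 0L) "neutral" else sprintf("charge %+d", x$charge)
  cat("<sum_composition> ", format(x), " (", chg, ")\n", sep = "")
  invisible(x)
}

#' Element count accessor
#'
#' `sc_count(x, "C")` returns the count of an element (0 when absent). The
#' pseudo-element `"db"` returns the double-bond equivalent, mirroring the
#' query-language accessor `chemsc[db]`.
#' @param x a `sum_composition`.
#' @param element element symbol or `"db"`.
#' @export
sc_count <- function(x, element) {
  stopifnot(inherits(x, "sum_composition"))
  if (identical(element, "db")) return(dbr(x))
  n <- x$counts[[element]]
  if (is.null(n)) 0L else n
}

.sc_merge <- function(a, b, op) {
  syms <- union(names(a$counts), names(b$counts))
  ca <- stats::setNames(integer(length(syms)), syms)
  cb <- ca
  ca[names(a$counts)] <- a$counts
  cb[names(b$counts)] <- b$counts
  res <- op(ca, cb)
  if (any(res < 0))
    stop("composition subtraction would produce a negative element count")
  if (all(res == 0)) stop("composition arithmetic produced an empty formula")
  sum_composition(res[res > 0], charge = op(a$charge, b$charge))
}

#' @export
`+.sum_composition` <- function(e1, e2) .sc_merge(e1, e2, `+`)

#' @export
`-.sum_composition` <- function(e1, e2) .sc_merge(e1, e2, `-`)

#' @export
`==.sum_composition` <- function(e1, e2) {
  identical(format(e1), format(e2)) && e1$charge == e2$charge
}

#' Monoisotopic mass-to-charge ratio
#'
#' For a charged composition, `(sum of monoisotopic element masses -
#' charge * electron mass) / |charge|`; for a neutral one, the plain
#' monoisotopic mass. The electron mass is accounted for per charge, which
#' matters at sub-ppm accuracy on high-resolution instruments.
#'
#' @param sc a `sum_composition`.
#' @return m/z (or neutral mass) in Da.
#' @export
monoisotopic_mz <- function(sc) {
  stopifnot(inherits(sc, "sum_composition"))
  if (length(sc$counts) == 0L) stop("empty composition")
  mono <- vapply(names(sc$counts), .monoisotopic_mass, numeric(1))
  m <- sum(sc$counts * mono) - sc$charge * .electron_mass
  if (sc$charge == 0L) m else m / abs(sc$charge)
}

#' Double-bond equivalents of a composition
#'
#' Generalized valence form `1 + sum n_i (v_i - 2) / 2`, i.e.
#' `1 + C - H/2 + (N + P)/2` over C,H,N,O,P (phosphorus taken trivalent).
#' Evaluated on the formula exactly as written: for a protonated ion the
#' charge-carrying proton is part of the formula, so DBR values of even-
#' electron cations are half-integral.
#'
#' @param sc a `sum_composition`.
#' @return double-bond equivalents (real, can be negative for exotic input).
#' @export
dbr <- function(sc) {
  stopifnot(inherits(sc, "sum_composition"))
  v <- .element_valence[names(sc$counts)]
  if (anyNA(v)) stop("no valence defined for: ",
                     paste(names(sc$counts)[is.na(v)], collapse = ", "))
  1 + sum(sc$counts * (v - 2)) / 2
}

#' Sum-composition constraints
#'
#' A constraint gives a closed integer range per element, an ion charge, and
#' a closed range of admissible double-bond equivalents. The text dialect is
#' the bracketed one used in query files: `"C[30..48] H[30..200] N[1] O[8] P[1]"`
#' (`E[n]` is shorthand for `E[n..n]`).
#'
#' @param ranges named list of length-2 integer vectors `c(lo, hi)`.
#' @param charge ion charge the enumerated compositions carry.
#' @param dbr_range closed interval of admissible DBR values.
#' @return an object of class `sc_constraint`.
#' @export
sc_constraint <- function(ranges, charge = 0L, dbr_range = c(-Inf, Inf)) {
  if (length(ranges) == 0L) stop("constraint needs at least one element")
  unknown <- setdiff(names(ranges), .known_elements())
  if (length(unknown) > 0L)
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  ranges <- lapply(ranges, function(r) {
    r <- as.integer(r)
    if (length(r) == 1L) r <- c(r, r)
    if (length(r) != 2L || anyNA(r) || r[1] > r[2] || r[1] < 0)
      stop("element range must be c(lo, hi) with 0 <= lo <= hi")
    r
  })
  if (length(dbr_range) != 2L || dbr_range[1] > dbr_range[2])
    stop("dbr_range must be c(lo, hi) with lo <= hi")
  structure(list(ranges = ranges, charge = as.integer(charge),
                 dbr_range = as.numeric(dbr_range)),
            class = "sc_constraint")
}

#' Parse the bracketed constraint dialect
#' @param text e.g. `"C[30..48]H[30..200]N[1]O[8]P[1]"`.
#' @inheritParams sc_constraint
#' @export
parse_sc_constraint <- function(text, charge = 0L, dbr_range = c(-Inf, Inf)) {
  s <- gsub("[[:space:]]+", "", text)
  m <- gregexpr("[A-Z][a-z]?\\[[0-9]+(\\.\\.[0-9]+)?\\]", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (length(tokens) == 0L || sum(attr(m, "match.length")) != nchar(s))
    stop("malformed sc-constraint: '", text, "'")
  sym <- sub("\\[.*$", "", tokens)
  rng <- lapply(tokens, function(tk) {
    inside <- sub("^.*\\[", "", sub("\\]$", "", tk))
    parts <- strsplit(inside, "..", fixed = TRUE)[[1]]
    as.integer(c(parts[1], parts[length(parts)]))
  })
  names(rng) <- sym
  sc_constraint(rng, charge = charge, dbr_range = dbr_range)
}

#' @export
print.sc_constraint <- function(x, ...) {
  rng <- vapply(names(x$ranges), function(s) {
    r <- x$ranges[[s]]
    if (r[1] == r[2]) sprintf("%s[%d]", s, r[1]) else sprintf("%s[%d..%d]", s, r[1], r[2])
  }, character(1))
  cat("<sc_constraint> ", paste(rng, collapse = ""),
      sprintf(" CHG %+d, DBR (%g, %g)\n", x$charge, x$dbr_range[1], x$dbr_range[2]),
      sep = "")
  invisible(x)
}

#' Mass tolerance specifications
#'
#' Tolerances are given either relative (`tol_ppm(5)`) or absolute
#' (`tol_da(0.3)`); `tol_width()` resolves either to Da at a given m/z.
#' @param x numeric tolerance value.
#' @export
tol_ppm <- function(x) structure(list(value = as.numeric(x), unit = "ppm"), class = "mass_tol")

#' @rdname tol_ppm
#' @export
tol_da <- function(x) structure(list(value = as.numeric(x), unit = "da"), class = "mass_tol")

#' @rdname tol_ppm
#' @param tol a `mass_tol`.
#' @param mz m/z at which a ppm tolerance is converted to Da.
#' @export
tol_width <- function(tol, mz) {
  stopifnot(inherits(tol, "mass_tol"))
  if (tol$unit == "ppm") tol$value * 1e-6 * mz else tol$value
}

#' Exhaustively enumerate compositions matching a mass under a constraint
#'
#' Depth-first search over the element count grid with running lower/upper
#' mass bounds for pruning; every returned composition satisfies all element
#' ranges, the DBR range, and `|monoisotopic_mz - target_mz| <= tol`. The
#' result is sorted by absolute mass error, ties broken by the formula
#' string, so output order is deterministic.
#'
#' @param constraint an `sc_constraint`.
#' @param target_mz target m/z in Da (interpreted at the constraint's charge).
#' @param tol a `mass_tol` (see [tol_ppm()]).
#' @return list of `sum_composition` objects (possibly empty).
#' @export
enumerate_compositions <- function(constraint, target_mz, tol) {
  stopifnot(inherits(constraint, "sc_constraint"))
  if (any(vapply(constraint$ranges, function(r) any(!is.finite(r)), logical(1))))
    stop("constraint ranges must be finite")
  syms <- names(constraint$ranges)
  mono <- vapply(syms, .monoisotopic_mass, numeric(1))
  lo <- vapply(constraint$ranges, `[`, integer(1), 1L)
  hi <- vapply(constraint$ranges, `[`, integer(1), 2L)
  z <- constraint$charge
  width <- tol_width(tol, target_mz)
  # target ion mass window translated to a neutral-atom mass sum window
  tgt <- target_mz * max(1L, abs(z)) + z * .electron_mass
  # suffix bounds: min/max mass attainable from element i..n
  min_suffix <- rev(cumsum(rev(lo * mono)))
  max_suffix <- rev(cumsum(rev(hi * mono)))
  min_suffix <- c(min_suffix, 0)
  max_suffix <- c(max_suffix, 0)

  out <- list()
  counts <- integer(length(syms))
  recurse <- function(i, acc_mass) {
    if (i > length(syms)) {
      if (abs(acc_mass - tgt) <= width) {
        sc <- sum_composition(stats::setNames(counts, syms), charge = z)
        d <- dbr(sc)
        if (d >= constraint$dbr_range[1] && d <= constraint$dbr_range[2])
          out[[length(out) + 1L]] <<- sc
      }
      return(invisible())
    }
    for (n in lo[i]:hi[i]) {
      m <- acc_mass + n * mono[i]
      # prune: even the extreme remaining counts cannot reach the window
      if (m + max_suffix[i + 1L] < tgt - width) next
      if (m + min_suffix[i + 1L] > tgt + width) break
      counts[i] <<- n
      recurse(i + 1L, m)
    }
    counts[i] <<- lo[i]
    invisible()
  }
  recurse(1L, 0)
  if (length(out) == 0L) return(out)
  err <- vapply(out, function(sc) abs(monoisotopic_mz(sc) - target_mz), numeric(1))
  key <- vapply(out, format, character(1))
  out[order(err, key)]
}

#' Theoretical isotope pattern of a composition
#'
#' Convolves the natural isotope distributions of all atoms and aggregates by
#' nominal mass offset (0 = monoisotopic). Abundances are reported relative
#' to the monoisotopic peak; the exact m/z of each isotopologue peak is the
#' abundance-weighted mean mass of the configurations pooled into that
#' nominal offset.
#'
#' @param sc a `sum_composition`.
#' @param n_peaks number of isotopologue peaks to return (>= 1).
#' @return data.frame with columns `offset`, `mz`, `abundance` (class
#'   `isotope_pattern`); `abundance[offset == 0]` is 1.
#' @export
isotope_pattern <- function(sc, n_peaks = 3L) {
  stopifnot(inherits(sc, "sum_composition"))
  if (n_peaks < 1L) stop("n_peaks must be >= 1")
  if (length(sc$counts) == 0L) stop("empty composition")
  np <- as.integer(n_peaks)

  # distribution representation: abundance a[k] and mass moment s[k]
  # (= sum of abundance * exact mass over configurations) per offset k
  unit <- function(sym) {
    tab <- .isotope_table[[sym]]
    off <- as.integer(round(tab$mass - tab$mass[1]))
    a <- numeric(np); s <- numeric(np)
    keep <- off < np
    a[off[keep] + 1L] <- tab$abundance[keep]
    s[off[keep] + 1L] <- tab$abundance[keep] * tab$mass[keep]
    list(a = a, s = s)
  }
  conv <- function(x, y) {
    a <- numeric(np); s <- numeric(np)
    for (k in seq_len(np)) {
      i <- seq_len(k)
      a[k] <- sum(x$a[i] * y$a[k - i + 1L])
      s[k] <- sum(x$s[i] * y$a[k - i + 1L] + x$a[i] * y$s[k - i + 1L])
    }
    list(a = a, s = s)
  }
  acc <- NULL
  for (sym in names(sc$counts)) {
    u <- unit(sym)
    for (j in seq_len(sc$counts[[sym]]))
      acc <- if (is.null(acc)) u else conv(acc, u)
  }
  mass <- ifelse(acc$a > 0, acc$s / acc$a, NA_real_)
  z <- sc$charge
  mz <- if (z == 0L) mass else (mass - z * .electron_mass) / abs(z)
  res <- data.frame(offset = 0:(np - 1L), mz = mz,
                    abundance = acc$a / acc$a[1])
  class(res) <- c("isotope_pattern", "data.frame")
  res
}
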