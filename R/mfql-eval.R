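# ---- expression evaluation over variable bindings ---------------------------

# one binding: list(var -> list(mz, chemsc (sum_composition|NULL), errppm,
# errda, intensity (named vector), occupancy))
.mfql_attr <- function(binding, var, name) {
  b <- binding[[var]]
  if (is.null(b)) stop("variable '", var, "' is not bound in this candidate",
                       call. = FALSE)
  switch(name,
    mass = b$mz,
    chemsc = b$chemsc %||% stop("variable '", var, "' has no bound composition",
                                call. = FALSE),
    errppm = b$errppm,
    errda = b$errda,
    intensity = b$intensity,
    occupation = b$occupancy,
    occupancy = b$occupancy,
    stop("unknown peak attribute: .", name, call. = FALSE))
}

.mfql_eval_expr <- function(node, binding) {
  ev <- function(n) .mfql_eval_expr(n, binding)
  switch(node$kind,
    num = node$value,
    str = node$value,
    var = node$name,   # bare variable: resolves to its name (only meaningful under attr)
    attr = {
      if (!identical(node$obj$kind, "var"))
        stop("attribute access is only defined on variables", call. = FALSE)
      .mfql_attr(binding, node$obj$name, node$name)
    },
    index = {
      obj <- if (identical(node$obj$kind, "var")) {
        .mfql_attr(binding, node$obj$name, "chemsc")
      } else ev(node$obj)
      if (inherits(obj, "sum_composition")) sc_count(obj, as.character(node$key))
      else if (is.numeric(obj)) obj[[as.integer(node$key)]]
      else stop("cannot index a ", class(obj)[1], call. = FALSE)
    },
    call = {
      args <- lapply(node$args, ev)
      fn <- node$fn
      if (fn %in% c("isEven", "isOdd")) {
        x <- args[[1]]
        if (abs(x - round(x)) > 1e-9) return(FALSE)
        if (fn == "isEven") round(x) %% 2 == 0 else round(x) %% 2 == 1
      } else if (fn == "abs") abs(args[[1]])
      else if (fn == "isStandard") TRUE
      else stop("unknown MFQL function: ", fn, call. = FALSE)
    },
    neg = -ev(node$arg),
    binop = {
      l <- ev(node$lhs); r <- ev(node$rhs)
      switch(node$op,
        "+" = l + r, "-" = l - r, "*" = l * r, "/" = l / r,
        "%" = stop("'%' expects two strings (format operator)", call. = FALSE))
    },
    cmp = {
      l <- ev(node$lhs); r <- ev(node$rhs)
      switch(node$op,
        "<" = l < r, ">" = l > r, "<=" = l <= r, ">=" = l >= r,
        "==" = isTRUE(all.equal(l, r, tolerance = 1e-9)),
        "!=" = !isTRUE(all.equal(l, r, tolerance = 1e-9)))
    },
    and = isTRUE(ev(node$lhs)) && isTRUE(ev(node$rhs)),
    or = isTRUE(ev(node$lhs)) || isTRUE(ev(node$rhs)),
    not = !isTRUE(ev(node$arg)),
    format = .mfql_format(node$fmt, lapply(node$args, ev)),
    tuple = lapply(node$items, ev),
    stop("cannot evaluate MFQL node of kind '", node$kind, "'", call. = FALSE)
  )
}

# printf-style formatting; %d truncates toward zero, bare %f prints one
# decimal (so a double-bond count renders as in "PC [36:1]")
.mfql_format <- function(fmt, args) {
  m <- gregexpr("%[-0-9.]*[dfs]", fmt)[[1]]
  if (m[1] == -1) return(fmt)
  specs <- regmatches(fmt, list(m))[[1]]
  if (length(specs) != length(args))
    stop("format '", fmt, "' expects ", length(specs), " argument(s), got ",
         length(args), call. = FALSE)
  rendered <- mapply(function(spec, val) {
    type <- substr(spec, nchar(spec), nchar(spec))
    if (type == "d") sprintf(sub("d$", "d", spec), as.integer(trunc(val)))
    else if (type == "f") {
      if (spec == "%f") spec <- "%.1f"
      sprintf(spec, as.numeric(val))
    } else {
      if (inherits(val, "sum_composition")) val <- format(val)
      sprintf(spec, as.character(val))
    }
  }, specs, args)
  parts <- strsplit(gsub("%[-0-9.]*[dfs]", "\001", fmt), "\001", fixed = TRUE)[[1]]
  parts <- c(parts, rep("", length(rendered) + 1L - length(parts)))
  paste0(paste0(parts[seq_along(rendered)], rendered, collapse = ""),
         parts[length(rendered) + 1L])
}

#' Evaluate a report-column expression against a binding set
#' @param expr parsed expression node (from an [parse_mfql()] AST).
#' @param binding named list of variable bindings.
#' @return a number, string, `sum_composition` or per-acquisition vector.
#' @export
evaluate_report_expression <- function(expr, binding) {
  .mfql_eval_expr(expr, binding)
}

# ---- identification ---------------------------------------------------------

# candidate bindings of one variable against one precursor entry
.match_ms1_var <- function(def, mz_obs, tol) {
  w <- tol_width(tol, mz_obs)
  mk <- function(chemsc, theo) list(
    mz = mz_obs, chemsc = chemsc,
    errda = mz_obs - theo, errppm = (mz_obs - theo) / theo * 1e6)
  if (def$kind == "constraint") {
    lapply(enumerate_compositions(def$value, mz_obs, tol), function(sc)
      mk(sc, monoisotopic_mz(sc)))
  } else if (def$kind == "composition") {
    theo <- monoisotopic_mz(def$value)
    if (abs(mz_obs - theo) <= w) list(mk(def$value, theo)) else list()
  } else {
    if (abs(mz_obs - def$value) <= w) list(mk(NULL, def$value)) else list()
  }
}

.match_ms2_var <- function(def, block, tol, acquisitions) {
  if (is.null(block)) return(list())
  out <- list()
  for (j in seq_along(block$mz)) {
    cands <- .match_ms1_var(def, block$mz[j], tol)
    for (cd in cands) {
      cd$intensity <- stats::setNames(as.numeric(block$intensities[j, ]),
                                      acquisitions)
      cd$occupancy <- block$occupancy[j]
      out[[length(out) + 1L]] <- cd
    }
  }
  if (length(out) > 1L) {
    err <- vapply(out, function(b) abs(b$errda), numeric(1))
    out <- out[order(err)]
  }
  out
}

.identify_clauses <- function(node) {
  if (identical(node$kind, "clause")) return(list(node))
  c(.identify_clauses(node$lhs), .identify_clauses(node$rhs))
}

.identify_satisfied <- function(node, bound) {
  switch(node$kind,
    clause = isTRUE(bound[[node$var]]),
    and = .identify_satisfied(node$lhs, bound) && .identify_satisfied(node$rhs, bound),
    or = .identify_satisfied(node$lhs, bound) || .identify_satisfied(node$rhs, bound),
    stop("bad identify node"))
}

#' Evaluate an MFQL query against a MasterScan
#'
#' For every precursor entry, MS1 variables are bound by matching the entry
#' mass against the variable's composition/constraint within `tol_ms1`
#' (constraint variables via exhaustive composition enumeration, one
#' candidate per matching composition, so ambiguous precursors yield one
#' flagged row each); MS2 variables are bound within the entry's attached
#' fragment block within `tol_ms2`. The IDENTIFY tree decides which
#' combinations of bound/unbound variables constitute an identification;
#' SUCHTHAT then filters candidate binding sets; one report row is emitted
#' per surviving set, sorted by precursor m/z then name. Extra fragment
#' peaks in an MS2 block never prevent a match.
#'
#' @param query an `mfql_query`.
#' @param ms a `master_scan`.
#' @param tol_ms1 MS1 mass tolerance (default 5 ppm).
#' @param tol_ms2 MS2 mass tolerance (default 0.3 Da, suitable for ion
#'   traps; pass [tol_ppm()] for high-resolution MS2).
#' @return data.frame of report rows (class `mfql_report`): `QUERY`,
#'   `PRECURSOR_MZ`, `AMBIGUOUS`, then one column per REPORT column;
#'   intensity-vector values expand to one column per acquisition,
#'   `<column>.<acquisition>`.
#' @export
evaluate <- function(query, ms, tol_ms1 = tol_ppm(5), tol_ms2 = tol_da(0.3)) {
  stopifnot(inherits(query, "mfql_query"), inherits(ms, "master_scan"))
  clauses <- .identify_clauses(query$identify)
  vars <- vapply(clauses, function(cl) cl$var, character(1))
  if (anyDuplicated(vars)) stop("variable appears in more than one IDENTIFY clause")
  levels <- stats::setNames(vapply(clauses, function(cl) cl$level, integer(1)), vars)
  pols <- stats::setNames(vapply(clauses, function(cl) cl$polarity, character(1)), vars)

  rows <- list()
  for (e in seq_along(ms$mz)) {
    cand <- list()
    for (v in vars) {
      def <- query$defines[[v]]
      if (pols[[v]] != ms$polarity) { cand[[v]] <- list(); next }
      cand[[v]] <- if (levels[[v]] == 1L) {
        lapply(.match_ms1_var(def, ms$mz[e], tol_ms1), function(b) {
          b$intensity <- stats::setNames(as.numeric(ms$intensities[e, ]),
                                         ms$acquisitions)
          b$occupancy <- ms$occupancy[e]
          b
        })
      } else {
        .match_ms2_var(def, ms$msms[[e]], tol_ms2, ms$acquisitions)
      }
    }
    bound <- lapply(cand, function(x) length(x) > 0L)
    if (!.identify_satisfied(query$identify, bound)) next

    # cross product over candidates; unmatched variables stay unbound
    idx_space <- lapply(cand, function(x) if (length(x) == 0L) 0L else seq_along(x))
    grid <- expand.grid(idx_space, KEEP.OUT.ATTRS = FALSE)
    ambiguous <- nrow(grid) > 1L
    for (r in seq_len(nrow(grid))) {
      binding <- stats::setNames(vector("list", length(vars)), vars)
      for (v in vars) {
        i <- grid[r, v]
        if (i > 0L) binding[[v]] <- cand[[v]][[i]]
      }
      if (!is.null(query$suchthat)) {
        ok <- tryCatch(isTRUE(.mfql_eval_expr(query$suchthat, binding)),
                       error = function(err) FALSE)
        if (!ok) next
      }
      vals <- tryCatch(
        lapply(query$report, function(ex) .mfql_eval_expr(ex, binding)),
        error = function(err) NULL)
      if (is.null(vals)) next
      rows[[length(rows) + 1L]] <- list(entry_mz = ms$mz[e],
                                        ambiguous = ambiguous, values = vals)
    }
  }
  .report_rows_to_df(query, ms, rows)
}

.report_rows_to_df <- function(query, ms, rows) {
  cols <- names(query$report)
  flatten <- function(val, col) {
    if (inherits(val, "sum_composition")) {
      stats::setNames(list(format(val)), col)
    } else if (is.numeric(val) && length(val) > 1L) {
      stats::setNames(as.list(val), paste0(col, ".", names(val)))
    } else stats::setNames(list(val), col)
  }
  dfs <- lapply(rows, function(rw) {
    flat <- list(QUERY = query$name, PRECURSOR_MZ = rw$entry_mz,
                 AMBIGUOUS = rw$ambiguous)
    for (cl in cols) flat <- c(flat, flatten(rw$values[[cl]], cl))
    as.data.frame(flat, check.names = FALSE, stringsAsFactors = FALSE)
  })
  if (length(dfs) == 0L) {
    out <- data.frame(QUERY = character(0), PRECURSOR_MZ = numeric(0),
                      AMBIGUOUS = logical(0))
    for (cl in cols) out[[cl]] <- character(0)
  } else {
    out <- do.call(rbind, dfs)
    key2 <- if ("NAME" %in% names(out)) as.character(out$NAME) else ""
    out <- out[order(out$PRECURSOR_MZ, key2), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("mfql_report", "data.frame")
  out
}

#' Run a set of queries and write the CSV report
#'
#' @param queries list of `mfql_query` objects (or paths to `.mfql` files).
#' @param ms a `master_scan`.
#' @param path output CSV path (optional).
#' @inheritParams evaluate
#' @return combined report data.frame (rows partitioned by query, in query
#'   order; deterministic column and row ordering, so reruns are
#'   byte-identical).
#' @export
run_queries <- function(queries, ms, path = NULL,
                        tol_ms1 = tol_ppm(5), tol_ms2 = tol_da(0.3)) {
  if (length(queries) == 0L) stop("no queries")
  queries <- lapply(queries, function(q)
    if (inherits(q, "mfql_query")) q else read_mfql(q))
  reps <- lapply(queries, evaluate, ms = ms, tol_ms1 = tol_ms1, tol_ms2 = tol_ms2)
  all_cols <- unique(unlist(lapply(reps, names)))
  reps <- lapply(reps, function(df) {
    for (cl in setdiff(all_cols, names(df))) df[[cl]] <- rep(NA, nrow(df))
    df[, all_cols, drop = FALSE]
  })
  out <- do.call(rbind, reps)
  rownames(out) <- NULL
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
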