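#' The MFQL query dialect
#'
#' The molecular fragmentation query language implemented here is a small
#' declarative language for describing lipid fragmentation patterns. A query
#' has four sections:
#' \preformatted{
#' QUERYNAME = Phosphatidylcholine;
#' DEFINE headPC = 'C5 H15 O4 N1 P1' WITH CHG = +1;
#' DEFINE prPC = 'C[30..48] H[30..200] N[1] O[8] P[1]' WITH CHG = +1, DBR = (1.5, 7.5);
#' IDENTIFY prPC IN MS1+ AND headPC IN MS2+;
#' SUCHTHAT isEven(prPC.chemsc[C]);
#' REPORT
#'   MASS   = prPC.mass;
#'   NAME   = "PC [%d:%d]" % "((prPC.chemsc - headPC.chemsc)[C] - 3, prPC.chemsc[db] - 1.5)";
#'   CHEMSC = prPC.chemsc;
#'   ERROR  = "%dppm" % "(prPC.errppm)";
#'   INTENS = prPC.intensity;
#' }
#' DEFINE binds a name to an explicit sum composition, a bracketed
#' sum-composition constraint, or a plain mass, optionally `WITH CHG = <n>`
#' and `DBR = (lo, hi)`. IDENTIFY places variables in MS1/MS2 spectra of a
#' polarity, combined with AND/OR. SUCHTHAT is an arbitrary boolean
#' expression over peak attributes (`.mass`, `.chemsc`, `.chemsc[C]`,
#' `.chemsc[db]`, `.errppm`, `.errda`, `.intensity`, `.occupation`),
#' arithmetic, comparisons and the builtins `isEven`, `isOdd`, `abs`,
#' `isStandard`. REPORT columns are expressions; `"fmt" % "(args)"` is
#' printf-style formatting (`%d` truncates toward zero, bare `%f` prints one
#' decimal). The full grammar is in the package's methods vignette.
#' @name mfql-dialect
NULL

# ---- lexer -----------------------------------------------------------------

.mfql_keywords <- c("QUERYNAME", "DEFINE", "IDENTIFY", "SUCHTHAT", "REPORT",
                    "WITH", "CHG", "DBR", "IN", "AND", "OR", "NOT")

.mfql_lex <- function(text) {
  toks <- list()
  line <- 1L; col <- 1L; i <- 1L; n <- nchar(text)
  push <- function(type, value) toks[[length(toks) + 1L]] <<- list(
    type = type, value = value, line = line, col = col)
  advance <- function(s) {
    nl <- gregexpr("\n", s, fixed = TRUE)[[1]]
    if (nl[1] != -1) { line <<- line + length(nl); col <<- nchar(s) - max(nl) + 1L }
    else col <<- col + nchar(s)
    i <<- i + nchar(s)
  }
  while (i <= n) {
    rest <- substr(text, i, n)
    if (grepl("^[[:space:]]", rest)) { advance(regmatches(rest, regexpr("^[[:space:]]+", rest))); next }
    if (startsWith(rest, "#")) { advance(sub("\n.*$", "\n", rest)); next }
    m <- regmatches(rest, regexpr("^[0-9]+(\\.[0-9]+)?", rest))
    if (length(m) == 1 && nzchar(m)) { push("number", as.numeric(m)); advance(m); next }
    m <- regmatches(rest, regexpr("^[A-Za-z_][A-Za-z0-9_]*", rest))
    if (length(m) == 1 && nzchar(m)) {
      push(if (toupper(m) %in% .mfql_keywords) toupper(m) else "ident", m)
      advance(m); next
    }
    c1 <- substr(rest, 1, 1)
    if (c1 %in% c("'", "\"")) {
      close <- regexpr(c1, substr(rest, 2, nchar(rest)), fixed = TRUE)
      if (close == -1) stop(sprintf("MFQL syntax error at line %d col %d: unterminated string", line, col))
      s <- substr(rest, 2, close)
      push("string", s); advance(substr(rest, 1, close + 1L)); next
    }
    two <- substr(rest, 1, 2)
    if (two %in% c("<=", ">=", "==", "!=")) { push("op", two); advance(two); next }
    if (c1 %in% c("=", ";", ",", "(", ")", "[", "]", "+", "-", "*", "/", "%",
                  "<", ">", ".")) {
      push("op", c1); advance(c1); next
    }
    stop(sprintf("MFQL syntax error at line %d col %d: unexpected character '%s'",
                 line, col, c1))
  }
  push("eof", "")
  toks
}

# ---- parser ----------------------------------------------------------------

.mfql_parser <- function(tokens) {
  pos <- 1L
  peek <- function(k = 0L) tokens[[pos + k]]
  fail <- function(msg, tok = peek()) stop(sprintf(
    "MFQL syntax error at line %d col %d: %s (got '%s')",
    tok$line, tok$col, msg, tok$value), call. = FALSE)
  accept <- function(type, value = NULL) {
    tk <- peek()
    if (tk$type == type && (is.null(value) || identical(tk$value, value))) {
      pos <<- pos + 1L; tk
    } else NULL
  }
  expect <- function(type, value = NULL, what = NULL) {
    tk <- accept(type, value)
    if (is.null(tk)) fail(paste0("expected ", what %||% value %||% type))
    tk
  }

  # expression grammar (lowest to highest precedence):
  # or -> and (OR and)* ; and -> not (AND not)* ; not -> NOT not | cmp
  # cmp -> add (relop add)? ; add -> mul (("+"|"-") mul)*
  # mul -> unary (("*"|"/"|"%") unary)* ; unary -> "-" unary | postfix
  # postfix -> primary ("." ident | "[" key "]")*
  parse_expr <- function() parse_or()
  parse_or <- function() {
    l <- parse_and()
    while (!is.null(accept("OR"))) l <- list(kind = "or", lhs = l, rhs = parse_and())
    l
  }
  parse_and <- function() {
    l <- parse_not()
    while (!is.null(accept("AND"))) l <- list(kind = "and", lhs = l, rhs = parse_not())
    l
  }
  parse_not <- function() {
    if (!is.null(accept("NOT"))) list(kind = "not", arg = parse_not()) else parse_cmp()
  }
  parse_cmp <- function() {
    l <- parse_add()
    tk <- peek()
    if (tk$type == "op" && tk$value %in% c("<", ">", "<=", ">=", "==", "!=")) {
      pos <<- pos + 1L
      l <- list(kind = "cmp", op = tk$value, lhs = l, rhs = parse_add())
    }
    l
  }
  parse_add <- function() {
    l <- parse_mul()
    repeat {
      tk <- peek()
      if (tk$type == "op" && tk$value %in% c("+", "-")) {
        pos <<- pos + 1L
        l <- list(kind = "binop", op = tk$value, lhs = l, rhs = parse_mul())
      } else break
    }
    l
  }
  parse_mul <- function() {
    l <- parse_unary()
    repeat {
      tk <- peek()
      if (tk$type == "op" && tk$value %in% c("*", "/", "%")) {
        pos <<- pos + 1L
        r <- parse_unary()
        if (tk$value == "%") l <- .make_format_node(l, r, fail)
        else l <- list(kind = "binop", op = tk$value, lhs = l, rhs = r)
      } else break
    }
    l
  }
  parse_unary <- function() {
    if (!is.null(accept("op", "-"))) list(kind = "neg", arg = parse_unary())
    else parse_postfix()
  }
  parse_postfix <- function() {
    e <- parse_primary()
    repeat {
      if (!is.null(accept("op", "."))) {
        attr_tk <- expect("ident", what = "attribute name")
        e <- list(kind = "attr", obj = e, name = attr_tk$value)
      } else if (!is.null(accept("op", "["))) {
        tk <- peek()
        if (tk$type == "ident") { pos <<- pos + 1L; key <- tk$value }
        else if (tk$type == "number") { pos <<- pos + 1L; key <- tk$value }
        else fail("expected element symbol or index inside []")
        expect("op", "]")
        e <- list(kind = "index", obj = e, key = key)
      } else break
    }
    e
  }
  parse_primary <- function() {
    tk <- peek()
    if (tk$type == "number") { pos <<- pos + 1L; return(list(kind = "num", value = tk$value)) }
    if (tk$type == "string") { pos <<- pos + 1L; return(list(kind = "str", value = tk$value)) }
    if (tk$type == "ident") {
      pos <<- pos + 1L
      if (!is.null(accept("op", "("))) {
        args <- list()
        if (is.null(accept("op", ")"))) {
          repeat {
            args[[length(args) + 1L]] <- parse_expr()
            if (is.null(accept("op", ","))) break
          }
          expect("op", ")")
        }
        return(list(kind = "call", fn = tk$value, args = args))
      }
      return(list(kind = "var", name = tk$value))
    }
    if (tk$type == "op" && tk$value == "(") {
      pos <<- pos + 1L
      inner <- list(parse_expr())
      while (!is.null(accept("op", ","))) inner[[length(inner) + 1L]] <- parse_expr()
      expect("op", ")")
      if (length(inner) == 1L) return(inner[[1L]])
      return(list(kind = "tuple", items = inner))
    }
    fail("expected an expression")
  }

  list(peek = peek, accept = accept, expect = expect, fail = fail,
       parse_expr = parse_expr,
       pos = function() pos, set_pos = function(p) pos <<- p)
}

# "fmt" % "(arg, arg)": the right-hand string is itself parsed as an
# expression tuple (the two-string convention of the dialect)
.make_format_node <- function(lhs, rhs, fail) {
  if (!identical(lhs$kind, "str") || !identical(rhs$kind, "str"))
    return(list(kind = "binop", op = "%", lhs = lhs, rhs = rhs))
  sub <- .mfql_parser(.mfql_lex(rhs$value))
  args <- sub$parse_expr()
  if (!identical(sub$peek()$type, "eof")) fail("trailing input in format arguments")
  args <- if (identical(args$kind, "tuple")) args$items else list(args)
  list(kind = "format", fmt = lhs$value, args = args)
}

#' Parse an MFQL query
#'
#' @param text query text (see the dialect description in
#'   [mfql-dialect]); alternatively use [read_mfql()] on a file.
#' @return object of class `mfql_query` with elements `name`, `defines`,
#'   `identify`, `suchthat` (may be `NULL`) and `report`.
#' @export
parse_mfql <- function(text) {
  p <- .mfql_parser(.mfql_lex(text))

  p$expect("QUERYNAME", what = "QUERYNAME")
  p$expect("op", "=")
  name_tk <- p$expect("ident", what = "query name")
  p$expect("op", ";")

  defines <- list()
  while (!is.null(p$accept("DEFINE")) || p$peek()$type == "ident") {
    if (p$peek()$type != "ident") next  # bare DEFINE keyword before each binding
    var_tk <- p$expect("ident", what = "variable name")
    p$expect("op", "=")
    tk <- p$peek()
    if (tk$type == "string") {
      p$accept("string")
      body <- tk$value
      kind <- if (grepl("\\[", body)) "constraint" else "composition"
    } else if (tk$type == "number") {
      p$accept("number")
      body <- tk$value
      kind <- "mass"
    } else p$fail("expected a quoted formula/constraint or a mass")
    charge <- 0L; dbr_range <- NULL
    if (!is.null(p$accept("WITH"))) {
      repeat {
        if (!is.null(p$accept("CHG"))) {
          p$expect("op", "=")
          sgn <- 1L
          if (!is.null(p$accept("op", "+"))) sgn <- 1L
          else if (!is.null(p$accept("op", "-"))) sgn <- -1L
          charge <- sgn * as.integer(p$expect("number", what = "charge")$value)
        } else if (!is.null(p$accept("DBR"))) {
          p$expect("op", "=")
          p$expect("op", "(")
          lo <- as.numeric(p$expect("number", what = "DBR lower bound")$value)
          p$expect("op", ",")
          hi <- as.numeric(p$expect("number", what = "DBR upper bound")$value)
          p$expect("op", ")")
          dbr_range <- c(lo, hi)
        } else p$fail("expected CHG or DBR after WITH")
        if (is.null(p$accept("op", ","))) break
      }
    }
    p$expect("op", ";")
    def <- switch(kind,
      composition = list(kind = "composition",
                         value = parse_sum_composition(body, charge = charge)),
      constraint = list(kind = "constraint",
                        value = parse_sc_constraint(body, charge = charge,
                                                    dbr_range = dbr_range %||% c(-Inf, Inf))),
      mass = list(kind = "mass", value = as.numeric(body), charge = charge))
    if (var_tk$value %in% names(defines))
      p$fail(paste0("variable '", var_tk$value, "' defined twice"), var_tk)
    defines[[var_tk$value]] <- def
    if (p$peek()$type %in% c("IDENTIFY", "eof")) break
  }
  if (length(defines) == 0L) p$fail("query has no DEFINE section")

  if (is.null(p$accept("IDENTIFY"))) p$fail("query has no IDENTIFY section")
  parse_clause <- function() {
    var_tk <- p$expect("ident", what = "variable name")
    p$expect("IN", what = "IN")
    lvl_tk <- p$expect("ident", what = "MS1 or MS2")
    if (!toupper(lvl_tk$value) %in% c("MS1", "MS2"))
      p$fail("spectrum level must be MS1 or MS2", lvl_tk)
    polarity <- "+"
    if (!is.null(p$accept("op", "+"))) polarity <- "+"
    else if (!is.null(p$accept("op", "-"))) polarity <- "-"
    else p$fail("spectrum level needs a polarity sign (MS1+ / MS2-)")
    list(kind = "clause", var = var_tk$value,
         level = if (toupper(lvl_tk$value) == "MS1") 1L else 2L,
         polarity = polarity)
  }
  parse_identify <- function() {
    l <- parse_clause()
    repeat {
      if (!is.null(p$accept("AND"))) l <- list(kind = "and", lhs = l, rhs = parse_clause())
      else if (!is.null(p$accept("OR"))) l <- list(kind = "or", lhs = l, rhs = parse_clause())
      else break
    }
    l
  }
  identify <- parse_identify()
  p$accept("op", ";")

  suchthat <- NULL
  if (!is.null(p$accept("SUCHTHAT"))) {
    suchthat <- p$parse_expr()
    p$expect("op", ";")
  }

  if (is.null(p$accept("REPORT"))) p$fail("query has no REPORT section")
  report <- list()
  while (p$peek()$type == "ident") {
    col_tk <- p$expect("ident")
    p$expect("op", "=")
    report[[col_tk$value]] <- p$parse_expr()
    p$expect("op", ";")
    while (!is.null(p$accept("op", ";"))) NULL   # tolerate ';;'
  }
  if (length(report) == 0L) p$fail("REPORT section is empty")
  if (p$peek()$type != "eof") p$fail("unexpected trailing input")

  q <- structure(list(name = name_tk$value, defines = defines,
                      identify = identify, suchthat = suchthat,
                      report = report),
                 class = "mfql_query")
  .mfql_check_vars(q)
  q
}

#' @rdname parse_mfql
#' @param path an `.mfql` file.
#' @export
read_mfql <- function(path) {
  parse_mfql(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' @export
print.mfql_query <- function(x, ...) {
  cat(sprintf("<mfql_query> %s: %d defines, %d report columns\n",
              x$name, length(x$defines), length(x$report)))
  invisible(x)
}

# collect variables referenced anywhere and check they are all DEFINEd
.expr_vars <- function(node) {
  if (is.null(node) || !is.list(node)) return(character(0))
  if (identical(node$kind, "var")) return(node$name)
  if (identical(node$kind, "clause")) return(node$var)
  unique(unlist(lapply(node[setdiff(names(node), c("kind", "op", "fn", "name",
                                                   "key", "value", "fmt"))],
                       function(ch) {
    if (is.list(ch) && !is.null(ch$kind)) .expr_vars(ch)
    else if (is.list(ch)) unlist(lapply(ch, .expr_vars))
    else character(0)
  })))
}

.mfql_check_vars <- function(q) {
  used <- unique(c(.expr_vars(q$identify), .expr_vars(q$suchthat),
                   unlist(lapply(q$report, .expr_vars))))
  undef <- setdiff(used, names(q$defines))
  if (length(undef) > 0L)
    stop("undefined variable(s) in query '", q$name, "': ",
         paste(undef, collapse = ", "), call. = FALSE)
  invisible(q)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
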