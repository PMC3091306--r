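test_that("formula strings parse to exact element counts", {
  sc <- parse_sum_composition("C5 H15 O4 N1 P1", charge = 1L)
  expect_equal(sc$counts[c("C", "H", "O", "N", "P")],
               c(C = 5L, H = 15L, O = 4L, N = 1L, P = 1L))
  expect_equal(sc$charge, 1L)
  expect_equal(parse_sum_composition("H1")$counts, c(H = 1L))
  expect_equal(parse_sum_composition("CH4")$counts, c(C = 1L, H = 4L))

  expect_error(parse_sum_composition(""), "empty")
  expect_error(parse_sum_composition("Xx3"), "malformed|unknown")
  expect_error(parse_sum_composition("C2 Qq1"), "malformed|unknown")
  expect_error(sum_composition(c(C = -1)), "non-negative")
})

test_that("monoisotopic m/z matches reference ions", {
  expect_equal(monoisotopic_mz(sc_pc_head()), 184.0733, tolerance = 0.0005 / 184)
  expect_equal(monoisotopic_mz(parse_sum_composition("H1", charge = 1L)),
               1.00728, tolerance = 1e-5)
  # protonated PC 36:1
  expect_equal(monoisotopic_mz(sc_pc361()), 788.616, tolerance = 1e-3 / 788)
  # the PE vs ether-PE split: CH4 and O differ by 36.4 mDa
  d <- abs(monoisotopic_mz(parse_sum_composition("C1 H4")) -
           monoisotopic_mz(parse_sum_composition("O1")))
  expect_equal(round(d * 1e3, 1), 36.4)
  expect_error(monoisotopic_mz(structure(list(counts = integer(0), charge = 0L),
                                         class = "sum_composition")), "empty")
})

test_that("m/z is additive over neutral composition sums", {
  set.seed(42)
  syms <- c("C", "H", "N", "O", "P", "S")
  for (i in 1:20) {
    a <- sum_composition(setNames(sample(1:20, 3), sample(syms, 3)))
    b <- sum_composition(setNames(sample(1:20, 3), sample(syms, 3)))
    expect_equal(monoisotopic_mz(a + b),
                 monoisotopic_mz(a) + monoisotopic_mz(b), tolerance = 1e-12)
  }
})

test_that("double-bond equivalents follow the generalized valence formula", {
  expect_equal(dbr(sc_pc361()), 2.5)      # protonated PC 36:1: db = 2.5 - 1.5 = 1
  expect_equal(dbr(parse_sum_composition("C1 H4")), 0)   # methane
  expect_equal(dbr(parse_sum_composition("C6 H6")), 4)   # benzene
  # additivity: the constant "+1" is counted once per molecule
  a <- parse_sum_composition("C6 H6")
  b <- parse_sum_composition("C2 H4 O2")
  expect_equal(dbr(a + b), dbr(a) + dbr(b) - 1)
})

test_that("constraint parsing reads the bracketed dialect", {
  con <- pc_constraint()
  expect_equal(con$ranges$C, c(30L, 48L))
  expect_equal(con$ranges$H, c(30L, 200L))
  expect_equal(con$ranges$N, c(1L, 1L))
  expect_equal(con$charge, 1L)
  expect_equal(con$dbr_range, c(1.5, 7.5))
  expect_error(parse_sc_constraint("C[5..2]"), "lo <= hi")
  expect_error(parse_sc_constraint("C[1..3]junk"), "malformed")
})

test_that("composition enumeration is exhaustive and correctly ordered", {
  # PC 36:1 is the unique constraint solution at 5 ppm
  hits <- enumerate_compositions(pc_constraint(), 788.6164, tol_ppm(5))
  expect_length(hits, 1L)
  expect_true(hits[[1]] == sc_pc361())

  # nothing below the lightest admissible mass
  expect_length(enumerate_compositions(pc_constraint(), 10.0, tol_ppm(1)), 0L)

  # methane is recovered exactly from a tiny neutral constraint
  con <- sc_constraint(list(C = c(1, 2), H = c(1, 6)), charge = 0L,
                       dbr_range = c(-1, 5))
  target <- monoisotopic_mz(parse_sum_composition("C1 H4"))
  hits <- enumerate_compositions(con, target, tol_ppm(1))
  expect_length(hits, 1L)
  expect_true(hits[[1]] == parse_sum_composition("C1 H4"))
})

test_that("enumeration equals the brute-force oracle on random small constraints", {
  set.seed(7)
  for (i in 1:15) {
    con <- sc_constraint(list(C = sort(sample(0:12, 2)),
                              H = sort(sample(0:24, 2)),
                              O = sort(sample(0:4, 2))),
                         charge = sample(c(-1L, 0L, 1L), 1),
                         dbr_range = c(-2, 10))
    target <- runif(1, 50, 250)
    tol <- tol_da(runif(1, 0.001, 0.5))
    got <- enumerate_compositions(con, target, tol)
    want <- brute_force_enumeration(con, target, tol)
    expect_setequal(vapply(got, format, character(1)),
                    vapply(want, format, character(1)))
    # sorted by absolute mass error
    errs <- vapply(got, function(sc) abs(monoisotopic_mz(sc) - target), numeric(1))
    expect_false(is.unsorted(errs))
  }
})

test_that("isotope patterns match known ratios and the convolution oracle", {
  p <- isotope_pattern(parse_sum_composition("C1"), 2)
  expect_equal(p$abundance[2], 0.0107 / 0.9893, tolerance = 0.02)
  p <- isotope_pattern(parse_sum_composition("H2"), 2)
  expect_equal(p$abundance[2], 2 * 0.000115 / 0.999885, tolerance = 0.02)
  p <- isotope_pattern(parse_sum_composition("P1"), 3)
  expect_equal(p$abundance[2:3], c(0, 0))

  # pattern invariants and the oracle, over assorted lipid-scale formulas
  for (f in list(c(C = 39, H = 72, O = 8, P = 1), c(C = 5, H = 15, O = 4, N = 1, P = 1),
                 c(C = 18, H = 33, O = 2), c(S = 2, O = 4), c(C = 100, H = 100))) {
    pat <- isotope_pattern(sum_composition(f), 4)
    expect_equal(pat$abundance[1], 1)
    expect_true(all(pat$abundance >= 0))
    expect_true(all(diff(pat$mz[is.finite(pat$mz)]) > 0))
    want <- brute_force_pattern(as.list(f), 4)
    expect_equal(pat$abundance / sum(pat$abundance),
                 want / sum(want), tolerance = 1e-6)
  }
})

test_that("composition arithmetic guards against negative counts", {
  expect_error(sc_pc_head() - sc_pc361(), "negative")
  diff <- sc_pc361() - sc_pc_head()
  expect_equal(sc_count(diff, "C"), 39L)
  expect_equal(sc_count(diff, "db"), dbr(diff))
})
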