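test_that("the PC query parses into the expected AST", {
  q <- read_mfql(pc_query_path())
  expect_s3_class(q, "mfql_query")
  expect_equal(q$name, "Phosphatidylcholine")
  expect_named(q$defines, c("headPC", "prPC"))
  expect_equal(q$defines$headPC$kind, "composition")
  expect_equal(q$defines$headPC$value$charge, 1L)
  expect_equal(q$defines$prPC$kind, "constraint")
  expect_equal(q$defines$prPC$value$dbr_range, c(1.5, 7.5))
  expect_equal(q$identify$kind, "and")
  expect_equal(q$identify$lhs$var, "prPC")
  expect_equal(q$identify$lhs$level, 1L)
  expect_equal(q$identify$rhs$var, "headPC")
  expect_equal(q$identify$rhs$level, 2L)
  expect_false(is.null(q$suchthat))
  expect_length(q$report, 6L)
})

test_that("malformed queries raise targeted errors", {
  expect_error(parse_mfql("QUERYNAME = x; DEFINE a = 'C1' WITH CHG = +1;
                           REPORT M = a.mass;"),
               "IDENTIFY")
  expect_error(parse_mfql("QUERYNAME = x; DEFINE a = 'C1' WITH CHG = +1;
                           IDENTIFY a IN MS1+; REPORT M = b.mass;"),
               "undefined variable.*b")
  expect_error(parse_mfql("QUERYNAME = x; DEFINE a = 'C1' WITH CHG = +1;
                           IDENTIFY a IN MS3+; REPORT M = a.mass;"),
               "MS1 or MS2")
  expect_error(parse_mfql("QUERYNAME = ;"), "syntax")
})

test_that("report expressions compute composition arithmetic and formatting", {
  binding <- list(
    prPC = list(mz = 788.6161, chemsc = sc_pc361(), errppm = 2.4,
                errda = 0.0019, intensity = c(a = 10, b = 20), occupancy = 1),
    headPC = list(mz = 184.0731, chemsc = sc_pc_head(), errppm = -1.1,
                  errda = -2e-4, intensity = c(a = 1, b = 2), occupancy = 1))
  ev <- function(src) {
    q <- parse_mfql(paste0("QUERYNAME = t; DEFINE prPC = 'C1' WITH CHG = +1;
      DEFINE headPC = 'C1' WITH CHG = +1;
      IDENTIFY prPC IN MS1+ AND headPC IN MS2+; REPORT X = ", src, ";"))
    evaluate_report_expression(q$report$X, binding)
  }
  expect_equal(ev("(prPC.chemsc - headPC.chemsc)[C] - 3"), 36)
  expect_equal(ev("prPC.chemsc[db] - 1.5"), 1)
  expect_equal(ev('"PC [%d:%d]" % "((prPC.chemsc - headPC.chemsc)[C] - 3, prPC.chemsc[db] - 1.5)"'),
               "PC [36:1]")
  expect_equal(ev('"%dppm" % "(prPC.errppm)"'), "2ppm")  # %d truncates toward zero
  expect_equal(ev("prPC.intensity"), c(a = 10, b = 20))
  expect_equal(ev("abs(0 - prPC.errppm)"), 2.4)
  expect_true(ev("isEven(prPC.chemsc[C])"))
  expect_false(ev("isOdd(prPC.chemsc[C])"))
  expect_error(ev("headPC.chemsc - prPC.chemsc"), "negative")
  expect_error(ev('"%d %d" % "(prPC.errppm)"'), "argument")
})

test_that("the PC query finds exactly PC 36:1 among decoys", {
  ms <- pc_decoy_masterscan(seed = 11)
  q <- read_mfql(pc_query_path())
  rep <- evaluate(q, ms, tol_ms1 = tol_ppm(5), tol_ms2 = tol_da(0.01))
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$NAME, "PC [36:1]")
  expect_equal(rep$CHEMSC, "C44 H87 N1 O8 P1")
  expect_lt(abs(rep$PRECURSOR_MZ - monoisotopic_mz(sc_pc361())), 0.01)
  # extra co-isolated fragments in the MS2 block did not block the match:
  # the PC precursor's block contains more than the head-group peak? at least
  # the match survived alongside whatever else aligned into the window
  expect_true(all(rep[, grepl("^FRAGINTENS", names(rep))] > 0))
})

test_that("a fragment-less precursor or odd-carbon solution yields no rows", {
  model <- resolution_model(1e5, 400, 0)
  q <- read_mfql(pc_query_path())
  # precursor present, MS2 block missing entirely: AND unsatisfied
  al <- align_spectra(list(a = data.frame(mz = monoisotopic_mz(sc_pc361()),
                                          intensity = 100)), model)
  ms <- master_scan("a", "+", al$mz, al$occupancy, al$intensities, model)
  expect_equal(nrow(evaluate(q, ms)), 0L)
  # precursor one CH2 up (an odd-chain PC 37:1): only odd-C compositions
  # within 5 ppm -> isEven fails
  al <- align_spectra(list(a = data.frame(mz = monoisotopic_mz(sc_pc361()) + 14.01565,
                                          intensity = 100)), model)
  ms <- master_scan("a", "+", al$mz, al$occupancy, al$intensities, model)
  ms <- associate_msms(ms, list(list(precursor_mz = al$mz[1], mz = 184.0733,
                                     occupancy = 1,
                                     intensities = matrix(5, 1, 1))), 1.0)
  cands <- enumerate_compositions(pc_constraint(), al$mz[1], tol_ppm(5))
  expect_true(length(cands) > 0)
  expect_true(all(vapply(cands, function(sc) sc_count(sc, "C") %% 2 == 1,
                         logical(1))))
  expect_equal(nrow(evaluate(q, ms)), 0L)
})

test_that("identification is sound, AND is a subset of OR, tolerance is monotone", {
  q_and <- read_mfql(pc_query_path())
  q_or <- parse_mfql(gsub("AND", "OR", paste(readLines(pc_query_path()),
                                             collapse = "\n")))
  for (seed in c(11, 12, 13)) {
    ms <- pc_decoy_masterscan(seed = seed)
    r_and <- evaluate(q_and, ms, tol_ppm(5), tol_da(0.01))
    r_or <- evaluate(q_or, ms, tol_ppm(5), tol_da(0.01))
    # soundness: reported ppm errors within tolerance
    if (nrow(r_and)) {
      err <- as.numeric(sub("ppm", "", r_and$ERROR))
      expect_true(all(abs(err) <= 5))
    }
    # AND-identified precursors are a subset of OR-identified ones
    expect_true(all(r_and$PRECURSOR_MZ %in% r_or$PRECURSOR_MZ))
    # growing the precursor tolerance never removes a row
    r_wide <- evaluate(q_and, ms, tol_ppm(50), tol_da(0.01))
    expect_true(all(r_and$PRECURSOR_MZ %in% r_wide$PRECURSOR_MZ))
    expect_gte(nrow(r_wide), nrow(r_and))
  }
})

test_that("run_queries writes a deterministic partitioned CSV", {
  ms <- pc_decoy_masterscan(seed = 11)
  pc_q <- read_mfql(pc_query_path())
  pe_q <- parse_mfql("QUERYNAME = Phosphatidylethanolamine;
    DEFINE prPE = 'C[30..48] H[30..200] N[1] O[8] P[1]' WITH CHG = +1, DBR = (1.5, 7.5);
    DEFINE glyPE = 'C3 H9 O4 N1 P1' WITH CHG = +1;
    IDENTIFY prPE IN MS1+ AND glyPE IN MS2+;
    REPORT MASS = prPE.mass; CHEMSC = prPE.chemsc; INTENS = prPE.intensity;")
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  rep <- run_queries(list(pc_q, pe_q), ms, path = f1, tol_ms2 = tol_da(0.01))
  expect_setequal(unique(rep$QUERY), c("Phosphatidylcholine",
                                       "Phosphatidylethanolamine"))
  expect_equal(sum(rep$QUERY == "Phosphatidylcholine"), 1L)
  expect_gte(sum(rep$QUERY == "Phosphatidylethanolamine"), 1L)
  run_queries(list(pc_q, pe_q), ms, path = f2, tol_ms2 = tol_da(0.01))
  expect_identical(readLines(f1), readLines(f2))
  # zero matches: header-only CSV
  ms_neg <- pc_decoy_masterscan(seed = 11)
  ms_neg$polarity <- "-"
  f3 <- withr::local_tempfile(fileext = ".csv")
  rep0 <- run_queries(list(pc_q), ms_neg, path = f3)
  expect_equal(nrow(rep0), 0L)
  expect_gt(length(readLines(f3)), 0L)
})

test_that("a head-group fragment query emulates a precursor ion scan", {
  # reporting the head fragment intensity across precursors reproduces the
  # precursor-scan profile implied by the simulation's ground truth
  truth <- lipid_ground_truth(list(
    list(name = "PC 34:1",
         chemsc = parse_sum_composition("C42 H83 N1 O8 P1", charge = 1L),
         amount = 4, fragments = list(head = sc_pc_head())),
    list(name = "PC 36:1", chemsc = sc_pc361(), amount = 1,
         fragments = list(head = sc_pc_head()))
  ), polarity = "+")
  acqs <- simulate_acquisitions(truth, 3, 2, seed = 17, jitter_ms1 = 2e5,
                                jitter_ms2 = 2e5, cv = 0.02)
  model <- resolution_model(1e5, 400, 0)
  ms <- build_masterscan(acqs, model, model, min_sn = 0)
  rep <- evaluate(read_mfql(pc_query_path()), ms, tol_ppm(5), tol_da(0.01))
  expect_equal(nrow(rep), 2L)
  frag <- rowMeans(rep[, grepl("^FRAGINTENS", names(rep))])
  expect_equal(frag[1] / frag[2], 4, tolerance = 0.15)
})
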