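model_hi <- resolution_model(1e5, 400, 0)

test_that("alignment uses unweighted means and per-acquisition vectors", {
  sp <- data.frame(mz = c(500.1, 700.2), intensity = c(10, 20))
  al <- align_spectra(list(a = sp, b = sp, c = sp), model_hi)
  expect_equal(al$mz, sp$mz, tolerance = 1e-12)
  expect_equal(dim(al$intensities), c(2L, 3L))
  expect_equal(al$occupancy, c(1, 1))
  expect_equal(unname(al$intensities[, "b"]), c(10, 20))

  # unweighted: intensities must not pull the representative mass
  m <- resolution_model(500, 0, 0)
  a <- data.frame(mz = 500.0, intensity = 1)
  b <- data.frame(mz = 500.5, intensity = 999)
  al <- align_spectra(list(a = a, b = b), m, n_passes = 1)
  expect_equal(al$mz, 500.25)   # plain mean, not 500.4995
  expect_equal(al$occupancy, 0.5 * 2)  # both acquisitions contribute one peak
})

test_that("occupancy is the fraction of acquisitions carrying the peak", {
  specs <- c(
    replicate(3, data.frame(mz = c(500.0, 600.0), intensity = c(1, 1)),
              simplify = FALSE),
    replicate(5, data.frame(mz = 600.0, intensity = 1), simplify = FALSE))
  names(specs) <- sprintf("a%d", 1:8)
  al <- align_spectra(specs, model_hi)
  expect_equal(al$occupancy[match(c(500, 600), round(al$mz))], c(3 / 8, 1))
})

test_that("alignment conserves per-acquisition total intensity and is order-invariant", {
  acqs <- simulate_acquisitions(pc_decoy_truth(), 4, 2, seed = 21,
                                jitter_ms1 = 2e5, jitter_ms2 = 2e5, cv = 0.1)
  avg <- lapply(acqs, function(a) {
    lvl <- vapply(a$scans, function(s) s$ms_level, integer(1))
    average_scans(a$scans[lvl == 1L], model_hi, min_sn = 0)
  })
  names(avg) <- vapply(acqs, function(a) a$id, character(1))
  al <- align_spectra(avg, model_hi)
  for (id in names(avg))
    expect_equal(sum(al$intensities[, id]), sum(avg[[id]]$intensity),
                 tolerance = 1e-9)
  perm <- rev(seq_along(avg))
  al2 <- align_spectra(avg[perm], model_hi)
  expect_equal(al2$mz, al$mz, tolerance = 1e-12)
  expect_equal(al2$intensities[, names(avg)], al$intensities[, names(avg)])
})

test_that("MS2 blocks attach within the isolation window, sharing and orphaning", {
  al <- align_spectra(list(a = data.frame(mz = c(788.6164, 788.9),
                                          intensity = c(5, 7))), model_hi)
  ms <- master_scan("a", "+", al$mz, al$occupancy, al$intensities, model_hi)
  blk <- function(p) list(precursor_mz = p, mz = 184.0733,
                          occupancy = 1, intensities = matrix(3, 1, 1))
  ms <- associate_msms(ms, list(blk(788.6)), isolation_width = 1.0)
  # both entries 0.3 Da apart receive the same block
  expect_false(is.null(ms$msms[[1]]))
  expect_false(is.null(ms$msms[[2]]))
  ms <- associate_msms(ms, list(blk(700.0)), isolation_width = 1.0)
  expect_length(ms$orphans, 1L)
})

test_that("recalibration removes constant and proportional mass errors", {
  refs <- c(400, 900)
  # uniform +2 mDa shift
  al <- align_spectra(list(a = data.frame(mz = refs + 0.002,
                                          intensity = c(1, 1)))[1], model_hi)
  ms <- master_scan("a", "+", al$mz, al$occupancy, al$intensities, model_hi)
  out <- recalibrate(ms, refs, match_tol = tol_ppm(20))
  expect_equal(out$mz, refs, tolerance = 1e-9)

  # 5 ppm proportional error: least squares on an exact linear error is exact
  obs <- c(400, 650, 900) * (1 + 5e-6)
  al <- align_spectra(list(a = data.frame(mz = obs, intensity = rep(1, 3))), model_hi)
  ms <- master_scan("a", "+", al$mz, al$occupancy, al$intensities, model_hi)
  out <- recalibrate(ms, c(400, 900), match_tol = tol_ppm(20))
  expect_lt(abs(out$mz[1] - 400) / 400 * 1e6, 0.1)
  expect_lt(abs(out$mz[3] - 900) / 900 * 1e6, 0.1)
  # zero observed error: identity
  al <- align_spectra(list(a = data.frame(mz = refs, intensity = c(1, 1))), model_hi)
  ms <- master_scan("a", "+", al$mz, al$occupancy, al$intensities, model_hi)
  expect_equal(recalibrate(ms, refs)$mz, refs, tolerance = 1e-12)
  expect_error(recalibrate(ms, 123.456), "no reference")
})

test_that("occupancy filtering implements the replicate-majority rule", {
  ids <- sprintf("r%d", 1:8)
  intens <- rbind(c(rep(10, 4), rep(0, 4)),   # in 4 of 8 -> retained at 0.5
                  c(rep(10, 3), rep(0, 5)),   # in 3 of 8 -> removed
                  rep(10, 8))
  ms <- master_scan(ids, "+", c(500, 600, 700), rowMeans(intens > 0), intens,
                    model_hi)
  out <- filter_entries(ms, min_occupancy = 0.5)
  expect_equal(out$mz, c(500, 700))
  expect_true(all(out$occupancy >= 0.5))
  # threshold 0 is the identity
  expect_equal(filter_entries(ms, 0)$mz, ms$mz)
  expect_error(filter_entries(ms, 0.5, scope = "nope"), "unknown group")
})

test_that("MasterScan persistence round-trips exactly and deterministically", {
  ms <- pc_decoy_masterscan(seed = 31)
  f1 <- withr::local_tempfile(fileext = ".sc")
  f2 <- withr::local_tempfile(fileext = ".sc")
  save_masterscan(ms, f1)
  save_masterscan(ms, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- load_masterscan(f1)
  expect_identical(back$acquisitions, ms$acquisitions)
  expect_identical(back$polarity, ms$polarity)
  expect_equal(back$mz, ms$mz)
  expect_equal(back$occupancy, ms$occupancy)
  expect_equal(back$intensities, ms$intensities)
  for (i in seq_along(ms$msms)) {
    expect_equal(is.null(back$msms[[i]]), is.null(ms$msms[[i]]))
    if (!is.null(ms$msms[[i]])) {
      expect_equal(back$msms[[i]]$mz, ms$msms[[i]]$mz)
      expect_equal(back$msms[[i]]$intensities, ms$msms[[i]]$intensities)
    }
  }
  # corrupt / truncated files are rejected
  txt <- readLines(f1, warn = FALSE)
  writeLines(substr(txt, 1, nchar(txt) %/% 2), f2)
  expect_error(load_masterscan(f2))
  writeLines('{"format":"something-else"}', f2)
  expect_error(load_masterscan(f2), "not a MasterScan")
})

test_that("the MasterScan file is smaller than the concatenated peak lists", {
  acqs <- simulate_acquisitions(pc_decoy_truth(), 6, 4, seed = 33,
                                jitter_ms1 = 2e5, jitter_ms2 = 2e5, cv = 0.1)
  dir <- withr::local_tempdir()
  raw_bytes <- 0
  for (a in acqs) for (s in a$scans) {
    f <- tempfile(tmpdir = dir)
    writeLines(sprintf("%.6f %.2f", s$mz, s$intensity), f)
    raw_bytes <- raw_bytes + file.size(f)
  }
  ms <- build_masterscan(acqs, model_hi, model_hi, min_sn = 0)
  sc_file <- file.path(dir, "out.sc")
  save_masterscan(ms, sc_file)
  expect_lt(file.size(sc_file), raw_bytes)
})
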