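unit_model <- resolution_model(800, 400, 0)
hires_model <- resolution_model(1e5, 400, 0)

test_that("an isolated species is never corrected", {
  e <- list(list(name = "x", chemsc = sc_pc361(), mz = monoisotopic_mz(sc_pc361()),
                 intensity = c(a = 100, b = 200)))
  out <- correct_ms(e, unit_model)
  expect_equal(out$entries[[1]]$intensity, c(a = 100, b = 200))
  expect_equal(nrow(out$ledger), 0L)
})

test_that("a +2 Da neighbor is reduced by the lighter species' M+2 fraction", {
  light <- parse_sum_composition("C39 H72 O8 P1", charge = -1L)  # PA 36:2 ion
  heavy <- parse_sum_composition("C39 H74 O8 P1", charge = -1L)  # PA 36:1 ion
  pat <- isotope_pattern(light, 3)
  r2 <- pat$abundance[3]
  entries <- list(
    list(name = "36:2", chemsc = light, mz = monoisotopic_mz(light),
         intensity = c(a = 9000)),
    list(name = "36:1", chemsc = heavy, mz = monoisotopic_mz(heavy),
         intensity = c(a = 1000 + 9000 * r2)))
  out <- correct_ms(entries, unit_model)
  expect_equal(unname(out$entries[[2]]$intensity), 1000, tolerance = 1e-9)
  expect_equal(sum(out$ledger$applied), 9000 * r2, tolerance = 1e-9)
  # at R = 100,000 the 9 mDa offset is resolved: no subtraction
  out_hi <- correct_ms(entries, hires_model)
  expect_equal(nrow(out_hi$ledger), 0L)
  # subtractions never exceed source intensity x isotopologue ratio
  expect_true(all(out$ledger$applied <= out$ledger$requested + 1e-12))
})

test_that("correction floors at zero and records the clip", {
  light <- parse_sum_composition("C39 H72 O8 P1", charge = -1L)
  heavy <- parse_sum_composition("C39 H74 O8 P1", charge = -1L)
  entries <- list(
    list(name = "big", chemsc = light, mz = monoisotopic_mz(light),
         intensity = c(a = 1e6)),
    list(name = "tiny", chemsc = heavy, mz = monoisotopic_mz(heavy),
         intensity = c(a = 1)))
  out <- correct_ms(entries, unit_model)
  expect_equal(unname(out$entries[[2]]$intensity), 0)
  expect_gt(sum(out$ledger$clipped), 0)
})

test_that("correction is invariant to input order", {
  light <- parse_sum_composition("C39 H72 O8 P1", charge = -1L)
  mid <- parse_sum_composition("C39 H74 O8 P1", charge = -1L)
  heavy <- parse_sum_composition("C39 H76 O8 P1", charge = -1L)
  entries <- list(
    list(name = "a", chemsc = light, mz = monoisotopic_mz(light), intensity = c(x = 900)),
    list(name = "b", chemsc = mid, mz = monoisotopic_mz(mid), intensity = c(x = 300)),
    list(name = "c", chemsc = heavy, mz = monoisotopic_mz(heavy), intensity = c(x = 100)))
  out1 <- correct_ms(entries, unit_model)
  out2 <- correct_ms(entries[c(3, 1, 2)], unit_model)
  got1 <- sapply(out1$entries, function(e) e$intensity)
  got2 <- sapply(out2$entries, function(e) e$intensity)[c(2, 3, 1)]
  expect_equal(unname(got1), unname(got2))
})

test_that("the PA mixture experiment recovers 10:1:1 and 1:9:1:1 after correction", {
  r <- run_pa_experiment(seed = 101)
  expect_equal(r$ms_ratio, c(10, 1, 1), tolerance = 0.05)
  expect_equal(r$msms_ratio, c(1, 9, 1, 1), tolerance = 0.05)
  # without correction the 18:0/18:1 channel is overestimated in both modes
  expect_gt(r$ms_ratio_raw[2], r$ms_ratio[2] * 1.15)
  expect_gt(r$msms_ratio_raw[3], r$msms_ratio[3] * 1.15)
})

test_that("monoisotopic-only simulations are left untouched by MS/MS correction", {
  truth <- pa_mixture_truth()
  acqs <- simulate_acquisitions(truth, 2, 2, seed = 41, jitter_ms1 = 1e4,
                                jitter_ms2 = 1e4, cv = 0, isotope_depth = 1L)
  ms <- build_masterscan(acqs, unit_model, unit_model, min_sn = 0)
  sp_mz <- vapply(truth$species, function(s) monoisotopic_mz(s$chemsc), numeric(1))
  entry_of <- vapply(sp_mz, function(m) which.min(abs(ms$mz - m)), integer(1))
  uniq <- which(!duplicated(entry_of))
  blocks <- lapply(uniq, function(i) ms$msms[[entry_of[i]]])
  species <- lapply(seq_along(truth$species), function(i) {
    s <- truth$species[[i]]
    list(name = s$name, chemsc = s$chemsc,
         block = match(entry_of[i], entry_of[uniq]), fragments = s$fragments)
  })
  before <- lapply(blocks, function(b) b$intensities)
  # correction depth 0 models the no-isotope setting: must be the identity
  out <- correct_msms(species, blocks, unit_model, isolation_width = 1.0,
                      depth = 0L)
  for (i in seq_along(blocks))
    expect_equal(out$blocks[[i]]$intensities, before[[i]], tolerance = 1e-12)
})

test_that("acyl-anion chains correct pairwise in MS/MS mode", {
  # two co-isolated precursor isotopologue sources: block of the mid species
  # receives the M+2-driven fragments of the light one
  r <- run_pa_experiment(seed = 55, amounts = c(2, 6, 2, 1))
  expect_equal(r$msms_ratio, c(1, 3, 1, 0.5), tolerance = 0.06)
})
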