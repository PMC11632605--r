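test_that("dose rates convert to pmol/min with the peptide molecular weight", {
  expect_equal(convert_dose_rate(300, "pmol/min"), 300)
  expect_equal(convert_dose_rate(4, "pmol/kg/min", 70), 280)
  expect_equal(convert_dose_rate(4, "nmol/kg/min", 70), 280000)
  expect_equal(convert_dose_rate(0.5, "ng/kg/min", 70), 14.04, tolerance = 1e-3)
  expect_error(convert_dose_rate(1, "mg/h"), "supported")
})

test_that("built-in protocols carry the published timings, rates and affinities", {
  bg <- builtin_protocol("stepped_biget")
  expect_equal(nrow(bg$segments), 3)
  expect_equal(bg$segments$rate_pmol_min, c(0.75, 15, 300))
  expect_equal(bg$segments$t_end - bg$segments$t_start, rep(30, 3))

  se <- builtin_protocol("stepped_et1")
  expect_equal(se$sampling_times, c(0, 75, 125, 225))
  expect_equal(se$segments$rate_pmol_min,
               c(0.5, 1, 2) * 70 * 1000 / 2492)

  tr <- builtin_protocol("bolus_tracer")
  expect_true(tr$rel_output)
  expect_equal(tr$segments$t_end, 5)
  expect_equal(max(tr$sampling_times), 240)

  b788 <- builtin_protocol("validation_bq788")
  expect_equal(b788$antagonist$K_ia, 1e6)   # 1 uM in pmol/L
  expect_equal(b788$antagonist$K_ib, 9800)  # 9.8 nM in pmol/L
  expect_lt(b788$antagonist$selectivity, 1)
  b123 <- builtin_protocol("validation_bq123")
  expect_equal(b123$antagonist$K_ia, 780)
  expect_equal(b123$antagonist$K_ib, 2.43e7)
  a123 <- b123$segments[b123$segments$species == "antagonist", ]
  expect_equal(c(a123$t_start, a123$t_end), c(0, 50))
  a788 <- b788$segments[b788$segments$species == "antagonist", ]
  expect_equal(c(a788$t_start, a788$t_end), c(0, 15))
  # ET-1 challenge from minute 30 for 20 min in every validation arm
  for (nm in c("validation_placebo", "validation_bq123", "validation_bq788")) {
    pr <- builtin_protocol(nm)
    e <- pr$segments[pr$segments$species == "ET1", ]
    expect_equal(c(e$t_start, e$t_end, e$rate_pmol_min), c(30, 50, 280))
    expect_equal(pr$sampling_times, c(0, 15, 30, 40, 50))
  }
  expect_null(builtin_protocol("validation_placebo")$antagonist)
  expect_error(builtin_protocol("nope"), "available")
})

test_that("protocol validation rejects malformed segment tables", {
  expect_error(et_protocol(data.frame(t_start = 10, t_end = 5,
                                      species = "ET1", rate_pmol_min = 1),
                           sampling_times = 0), "t_start")
  expect_error(et_protocol(data.frame(t_start = c(0, 5), t_end = c(10, 15),
                                      species = "ET1",
                                      rate_pmol_min = c(1, 1)),
                           sampling_times = 0), "overlap")
  expect_error(et_protocol(data.frame(t_start = 0, t_end = 10,
                                      species = "antagonist",
                                      rate_pmol_min = 1),
                           sampling_times = 0), "et_antagonist")
})

test_that("protocols round-trip through YAML unchanged", {
  for (nm in c("stepped_biget", "validation_bq123", "bolus_tracer")) {
    pr <- builtin_protocol(nm)
    f <- tempfile(fileext = ".yaml")
    write_et_protocol(pr, f)
    expect_equal(read_et_protocol(f), pr)
    unlink(f)
  }
})
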