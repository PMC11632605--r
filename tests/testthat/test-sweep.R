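test_that("percent changes are anchored to zero at zero concentration", {
  sw <- run_sweep(default_params, et_antagonist(1, 100), c(0.1, 10))
  z <- sw[sw$conc_mult == 0, grepl("^pct_", names(sw))]
  expect_true(all(unlist(z) == 0))
})

test_that("the antagonized complex is suppressed monotonically", {
  sw <- sweep_perfect(default_params, "ETA", n_per_decade = 10)
  expect_true(all(diff(sw$pct_ET1_RA_p) <= 1e-9))
  expect_true(all(diff(sw$pct_ET1_RA_t) <= 1e-9))
  swb <- sweep_perfect(default_params, "ETB", n_per_decade = 10)
  expect_true(all(diff(swb$pct_ET1_RB_p) <= 1e-9))
})

test_that("both perfect-selectivity encodings give the same sweep", {
  a <- sweep_perfect(default_params, "ETA", n_per_decade = 5, perfect = "inf")
  b <- sweep_perfect(default_params, "ETA", n_per_decade = 5, perfect = "1e20")
  expect_equal(a$pct_ET1_RB_p, b$pct_ET1_RB_p, tolerance = 1e-6)
})

test_that("finite ETA selectivity: transient hump falls below baseline, steady state plateaus", {
  # over a finite exposure the ETB complex rises, peaks, and turns negative
  sw <- run_sweep(default_params, et_antagonist(1, 100),
                  10^seq(-3, 5, length.out = 41), mode = "transient")
  y <- sw$pct_ET1_RB_p[sw$conc_mult > 0]
  expect_gt(max(y), 5)          # a real hump
  expect_lt(y[length(y)], 0)    # ends below baseline
  s <- sign(y[abs(y) > 1e-6])
  expect_equal(sum(diff(s) != 0), 1)  # exactly one sign change
  sm <- summarize_sweep(sw)
  expect_true(all(sm$supp50_mult > 1))  # shifted right of K_ia
  expect_true(all(sm$zero_cross_reached))
  # at the true steady state the flux constraint keeps the plateau positive
  ss <- run_sweep(default_params, et_antagonist(1, 100),
                  10^seq(-3, 5, length.out = 17))
  expect_gt(ss$pct_ET1_RB_p[nrow(ss)], 0)
})

test_that("a non-selective antagonist cannot suppress total complex flux", {
  p <- default_params
  sw <- run_sweep(p, et_antagonist(1, 1), 10^seq(-2, 3, length.out = 21))
  # internalization flux must still carry the production flux, so the
  # complexes return to (nearly) baseline at every concentration
  expect_lt(max(abs(sw$pct_ET1_RA_p)), 5)
  expect_lt(max(abs(sw$pct_ET1_RB_t)), 5)
  # while free ET-1 rises without bound
  expect_gt(max(sw$pct_ET1_free_p), 1000)
})

test_that("receptor-fraction scenarios behave as the clearance split dictates", {
  p <- default_params
  sc5 <- fb_scenario(0.5, p, n_per_decade = 10)
  # equal pools: the non-antagonized complex rises equally under either drug
  expect_equal(max(sc5$ETA$pct_ET1_RB_p), max(sc5$ETB$pct_ET1_RA_p),
               tolerance = 0.01)
  expect_equal(max(sc5$ETA$pct_ET1_RB_t), max(sc5$ETB$pct_ET1_RA_t),
               tolerance = 0.01)
  sc999 <- fb_scenario(0.999, p, n_per_decade = 10)
  # almost no ETA receptors: ETA antagonism does nothing to the ETB complex
  expect_lt(max(abs(sc999$ETA$pct_ET1_RB_p)), 1)
  # but ETB antagonism drives an enormous rise in the ETA complex
  top <- sc999$ETB[nrow(sc999$ETB), ]
  expect_gt(top$pct_ET1_RA_p, 2000)
  # curve shapes are scenario-invariant up to vertical scaling
  dflt <- sweep_perfect(p, "ETA", n_per_decade = 10)
  n1 <- sc5$ETA$pct_ET1_RB_p / max(sc5$ETA$pct_ET1_RB_p)
  n2 <- dflt$pct_ET1_RB_p / max(dflt$pct_ET1_RB_p)
  expect_gt(stats::cor(n1, n2, method = "spearman"), 0.99)
})

test_that("sweep summaries report maxima and crossings coherently", {
  sw <- sweep_perfect(default_params, "ETA", n_per_decade = 10)
  sm <- summarize_sweep(sw)
  expect_equal(sm$compartment, c("plasma", "tissue"))
  expect_equal(sm$max_rise_pct[1], max(sw$pct_ET1_RB_p))
  # saturating perfect-ETA case: the ETB complex never turns negative
  expect_false(any(sm$zero_cross_reached))
  expect_true(all(is.na(sm$zero_cross_mult)))
})

test_that("drug presets are a well-formed ETA-selective table", {
  tab <- et_drug_presets()
  expect_true(all(c("bosentan", "zibotentan") %in% tab$drug))
  expect_true(all(tab$selectivity > 1))
})
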