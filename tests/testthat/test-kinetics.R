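test_that("derived production rates follow the ECE conversion flux", {
  p <- et_params()
  pr98 <- derived_production_rates(p)
  expect_equal(unname(pr98["Prod_BigET"]), 24.06, tolerance = 1e-3)
  expect_equal(unname(pr98["Prod_ET1"]), 24.06 * 2.64, tolerance = 1e-3)
  # linear in ECE
  pr196 <- derived_production_rates(p, ECE = 196)
  expect_equal(unname(pr196["Prod_BigET"]), 2 * unname(pr98["Prod_BigET"]))
})

test_that("steady-state initialization reproduces the published baseline", {
  p <- et_params()
  init <- steady_state_init(p)
  expect_equal(unname(init$free["ET1_p0"]), 3.2)            # by construction
  expect_equal(unname(init$free["ET1_t0"]), 88.3,           # printed value
               tolerance = 0.02)
  # implied baseline ECE lies inside the study-specific range
  expect_gt(init$params$ECE_implied, 27)
  expect_lt(init$params$ECE_implied, 162.6)
  # every ODE right-hand side vanishes at the constructed state
  pp <- etkin:::pack_parms(init$params)
  d <- ode_rhs(0, init$state, pp)[[1]]
  expect_lt(max(abs(d[c("BigET", "Tt", "Tp")])), 1e-8)
})

test_that("ECE-anchored initialization derives the tissue receptor pool", {
  p <- et_params(ECE = 27)
  init <- steady_state_init(p, anchor = "ECE")
  expect_false(init$params$Rtot_t == 7738)
  expect_gt(init$params$Rtot_t, 0)
  pp <- etkin:::pack_parms(init$params)
  d <- ode_rhs(0, init$state, pp)[[1]]
  expect_lt(max(abs(d[c("BigET", "Tt", "Tp")])), 1e-8)
  # production too small to balance distribution: named initialization error
  expect_error(steady_state_init(et_params(ECE = 1), anchor = "ECE"),
               "receptor pool")
})

test_that("compiled and reference right-hand sides agree on random states", {
  p <- et_params()
  init <- steady_state_init(p)
  pp <- etkin:::pack_parms(init$params, antagonist = et_antagonist(500, 2000),
                           inf_ET1 = 20, inf_BigET = 5, inf_antag = 1e4,
                           ke0 = 0.03)
  set.seed(5)
  for (i in 1:50) {
    st <- init$state * exp(rnorm(7, 0, 0.5))
    names(st) <- names(init$state)
    dR <- ode_rhs(0, st, pp)[[1]]
    # a single unit Euler step through deSolve recovers the C derivative
    sol <- deSolve::ode(y = st, times = c(0, 1), func = "etkin_derivs",
                        parms = pp, dllname = "etkin",
                        initfunc = "etkin_init", nout = 6, method = "euler")
    dC <- sol[2, 2:8] - sol[1, 2:8]
    expect_lt(max(abs(dR - dC) / (abs(dR) + 1e-9)), 1e-10)
  }
})

test_that("an ET-1 infusion adds exactly rate/Vp to the plasma derivative", {
  p <- et_params()
  init <- steady_state_init(p)
  st <- init$state
  d0 <- ode_rhs(0, st, etkin:::pack_parms(init$params))[[1]]
  dq <- ode_rhs(0, st, etkin:::pack_parms(init$params, inf_ET1 = 42))[[1]]
  expect_equal(unname(dq["Tp"] - d0["Tp"]), 42 / p$Vp, tolerance = 1e-12)
  expect_equal(unname(dq["Tt"]), unname(d0["Tt"]))
})

test_that("the baseline is a fixed point of the dynamics over 1000 min", {
  p <- et_params()
  null_proto <- et_protocol(
    segments = data.frame(t_start = numeric(0), t_end = numeric(0),
                          species = character(0), rate_pmol_min = numeric(0)),
    sampling_times = c(0, 1000), horizon = 1000, name = "null")
  sim <- et_simulate(null_proto, p, output_times = c(0, 250, 500, 1000))
  for (v in c("BigET", "Tt", "Tp"))
    expect_lt(max(abs(sim[[v]] / sim[[v]][1] - 1)), 1e-3)
})

test_that("stepped ET-1 infusion raises plasma ET-1 across the three plateaus", {
  sim <- et_simulate(builtin_protocol("stepped_et1"), et_params(),
                     output_times = c(0, 55, 115, 175))
  expect_true(all(diff(sim$up) > 0))
})

test_that("ET-1 amount is conserved: infused + produced - cleared", {
  p <- et_params()
  proto <- builtin_protocol("stepped_et1")
  sim <- et_simulate(proto, p, output_times = seq(0, 225, by = 5))
  amt <- p$Vt * sim$Tt + p$Vp * sim$Tp
  seg <- proto$segments
  infused <- vapply(sim$time, function(t)
    sum(pmin(pmax(t - seg$t_start, 0), seg$t_end - seg$t_start) *
          seg$rate_pmol_min), numeric(1))
  balance <- (amt - amt[1]) - (infused + sim$cumPr - sim$cumCl)
  expect_lt(max(abs(balance)) / max(amt), 1e-6)
})

test_that("quasi-equilibrium mass balance holds at every output step", {
  p <- et_params()
  for (nm in c("bolus_tracer", "stepped_et1", "stepped_biget",
               "validation_bq123", "validation_bq788")) {
    sim <- et_simulate(builtin_protocol(nm), p)
    expect_lt(max(abs(sim$ut + sim$CAt + sim$CBt - sim$Tt) / sim$Tt), 1e-9)
    expect_lt(max(abs(sim$up + sim$CAp + sim$CBp - sim$Tp) / sim$Tp), 1e-9)
  }
})

test_that("tracer mode reports a baseline-subtracted, peak-normalized signal", {
  sim <- et_simulate(builtin_protocol("bolus_tracer"), et_params())
  expect_equal(max(sim$rel), 1)
  expect_lt(abs(sim$rel[1]), 1e-6)
  expect_equal(sim$time[which.max(sim$rel)], 5)  # peak at end of the bolus
})

test_that("algebraic antagonist steady state matches long integration", {
  p <- et_params()
  antag <- et_antagonist(K_ia = 1, K_ib = 50)
  for (I in c(0, 2, 200)) {
    ss <- steady_state_with_antagonist(p, antag, I)
    proto <- etkin:::constant_exposure_protocol(I, antag, horizon = 2000)
    sim <- et_simulate(proto, p, output_times = c(0, 2000),
                       exposure = list(mode = "step", t_half = 60))
    end <- sim[nrow(sim), ]
    expect_equal(end$up, unname(ss$free["up"]), tolerance = 1e-3)
    expect_equal(end$ut, unname(ss$free["ut"]), tolerance = 1e-3)
  }
})

test_that("antagonist steady state reduces to baseline at zero exposure", {
  p <- et_params()
  ss0 <- steady_state_with_antagonist(p, et_antagonist(1, 1e20), 0, f_B = NULL)
  init <- steady_state_init(p)
  expect_equal(unname(ss0$free["up"]), unname(init$free["ET1_p0"]),
               tolerance = 1e-9)
  expect_equal(unname(ss0$free["ut"]), unname(init$free["ET1_t0"]),
               tolerance = 1e-9)
})

test_that("a saturating selective ETA antagonist suppresses its complex", {
  p <- et_params()
  ss <- steady_state_with_antagonist(p, et_antagonist(1, Inf), 1000)
  base <- steady_state_with_antagonist(p, et_antagonist(1, Inf), 0)
  expect_lt(ss$plasma$ET1_RA / base$plasma$ET1_RA, 0.01)  # > 99% suppression
})

test_that("ETB clearance dominates: blocking ETB raises plasma ET-1 more", {
  p <- et_params()
  up_eta <- steady_state_with_antagonist(p, et_antagonist(1, Inf), 1e5)$free["up"]
  up_etb <- steady_state_with_antagonist(p, et_antagonist(Inf, 1), 1e5)$free["up"]
  expect_gt(up_etb, up_eta)
})

test_that("the pharmacodynamic delay slows the early antagonist response", {
  p <- et_params()
  s0 <- et_simulate(builtin_protocol("validation_bq788"), p,
                    output_times = c(0, 5, 10, 15))
  s1 <- et_simulate(builtin_protocol("validation_bq788"), p,
                    output_times = c(0, 5, 10, 15), pd_delay_ke0 = 0.05)
  expect_lt(s1$up[s1$time == 10], s0$up[s0$time == 10])
  expect_lt(s1$up[s1$time == 15], s0$up[s0$time == 15])
})
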