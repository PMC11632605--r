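test_that("receptor pool splits by the ETB fraction and conserves the total", {
  expect_equal(split_receptor_pool(460, 0.8),
               c(RA_tot = 92, RB_tot = 368))
  expect_equal(split_receptor_pool(7738, 0.65),
               c(RA_tot = 2708.3, RB_tot = 5029.7))
  expect_equal(split_receptor_pool(0, 0.5), c(RA_tot = 0, RB_tot = 0))
  set.seed(1)
  for (i in 1:50) {
    R <- runif(1, 0, 1e4); f <- runif(1)
    pool <- split_receptor_pool(R, f)
    expect_identical(unname(pool[1] + pool[2]), R)  # exact, not approximate
    expect_true(all(pool >= 0))
  }
  expect_error(split_receptor_pool(-1, 0.5), "R_tot")
  expect_error(split_receptor_pool(100, 1.2), "f_B")
})

test_that("free ligand without antagonist solves the quadratic mass balance", {
  expect_equal(free_ligand(0, 460, 400), 0)
  expect_equal(free_ligand(10, 0, 400), 10)
  # inversion of the forward map at the baseline tissue operating point
  expect_equal(free_ligand(1487.6, 7738, 400), 88.3, tolerance = 0.1 / 88.3)
  set.seed(2)
  for (i in 1:200) {
    Ttot <- 10^runif(1, -3, 7); R <- 10^runif(1, -3, 5); Kd <- 10^runif(1, 0, 5)
    u <- free_ligand(Ttot, R, Kd)
    expect_true(u >= 0 && u <= Ttot)
    resid <- u + R * u / (Kd + u) - Ttot
    expect_lt(abs(resid) / Ttot, 1e-9)
  }
  expect_error(free_ligand(1, 1, 0), "Kd")
})

test_that("bound complex follows receptor occupancy and saturates", {
  expect_equal(bound_complex(460, 400, 400), 230)  # half saturation at Kd
  expect_equal(bound_complex(460, 0, 400), 0)
  expect_equal(bound_complex(460, 3.2, 400), 460 * 3.2 / 403.2)
  u <- seq(0, 1e5, length.out = 50)
  cx <- bound_complex(460, u, 400)
  expect_true(all(diff(cx) > 0))       # monotone in free ligand
  expect_true(all(cx < 460))           # bounded by the pool
})

test_that("inhibited free-ligand cubic reduces correctly in degenerate cases", {
  # no antagonist: equals the lumped quadratic
  expect_equal(free_ligand_inhibited(10, 92, 368, 400, I = 0, K_ia = 1, K_ib = 1),
               free_ligand(10, 460, 400), tolerance = 1e-10)
  # equal affinities collapse to an effective dissociation constant
  for (I in c(5, 50, 500)) {
    expect_equal(free_ligand_inhibited(10, 92, 368, 400, I, K_ia = 20, K_ib = 20),
                 free_ligand(10, 460, 400 * (1 + I / 20)), tolerance = 1e-10)
  }
  # frozen value computed with the bracketed oracle at tolerance 1e-10
  expect_equal(free_ligand_inhibited(10, 92, 368, 400, I = 10,
                                     K_ia = 1, K_ib = 1e20),
               5.19, tolerance = 0.005)
  # infinite-affinity flag agrees with the 1e20 encoding
  expect_equal(free_ligand_inhibited(10, 92, 368, 400, 10, 1, Inf),
               free_ligand_inhibited(10, 92, 368, 400, 10, 1, 1e20),
               tolerance = 1e-9)
  # single-receptor systems (f_B at 0 or 1)
  expect_equal(free_ligand_inhibited(10, 0, 460, 400, 10, 1, 2),
               free_ligand(10, 460, 400 * (1 + 10 / 2)), tolerance = 1e-10)
})

test_that("cubic solver matches a bracketed root-finding oracle on random draws", {
  set.seed(3)
  worst <- 0
  for (i in 1:1000) {
    Ttot <- 10^runif(1, -3, 7)
    RA <- 10^runif(1, -2, 4); RB <- 10^runif(1, -2, 4)
    Kd <- 10^runif(1, 0, 4)
    I <- 10^runif(1, -3, 8)
    Kia <- 10^runif(1, -2, 20); Kib <- 10^runif(1, -2, 20)
    u <- free_ligand_inhibited(Ttot, RA, RB, Kd, I, Kia, Kib)
    uo <- oracle_free(Ttot, RA, RB, Kd, I, Kia, Kib)
    worst <- max(worst, abs(u - uo) / max(uo, 1e-300))
  }
  expect_lt(worst, 1e-8)
})

test_that("binding solution conserves mass and behaves in the antagonist limits", {
  set.seed(4)
  for (i in 1:200) {
    Ttot <- 10^runif(1, -2, 6); RA <- 10^runif(1, 0, 4); RB <- 10^runif(1, 0, 4)
    Kd <- 10^runif(1, 1, 4); I <- 10^runif(1, -2, 6)
    Kia <- 10^runif(1, 0, 6); Kib <- 10^runif(1, 0, 6)
    b <- binding_solution(Ttot, RA, RB, Kd, I, Kia, Kib)
    expect_lt(abs(b$ET1_free + b$ET1_RA + b$ET1_RB - Ttot) / Ttot, 1e-9)
    expect_true(all(unlist(b) >= 0))
    expect_lte(b$RA_free + b$ET1_RA, RA * (1 + 1e-12))
    expect_lte(b$RB_free + b$ET1_RB, RB * (1 + 1e-12))
  }
  # no antagonist bound: receptor pools fully accounted by free + complex
  b0 <- binding_solution(100, 92, 368, 400)
  expect_equal(b0$RA_free + b0$ET1_RA, 92, tolerance = 1e-9)
  expect_equal(b0$RB_free + b0$ET1_RB, 368, tolerance = 1e-9)
  # I -> large: complexes vanish, ligand all free
  bI <- binding_solution(100, 92, 368, 400, I = 1e12, K_ia = 1, K_ib = 1)
  expect_lt(bI$ET1_RA + bI$ET1_RB, 1e-6)
  expect_equal(bI$ET1_free, 100, tolerance = 1e-6)
})

test_that("complexes are monotone in antagonist concentration", {
  Is <- 10^seq(-2, 5, length.out = 40)
  ca <- vapply(Is, function(I)
    binding_solution(50, 92, 368, 400, I, K_ia = 10, K_ib = 1e20)$ET1_RA,
    numeric(1))
  expect_true(all(diff(ca) < 0))  # strictly decreasing at fixed total ligand
})

test_that("closed-form limits hold: vanishing receptors and weak binding", {
  # R_tot -> 0: all ligand free
  expect_equal(free_ligand(25, 1e-12, 400), 25, tolerance = 1e-9)
  # Kd -> large: linear binding regime, complex ~ R*u/Kd
  u <- free_ligand(25, 460, 1e9)
  expect_equal(bound_complex(460, u, 1e9), 460 * u / 1e9, tolerance = 1e-6)
})
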