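# shared fixtures: the calibrated parameter set and the estimation truth
default_params <- et_params()

truth_theta <- c(Vp = 81.6, Vt = 2.64, Kpt = 0.87, Ktp = 0.98,
                 Kint = 0.0095, Rtot_p = 460,
                 ECE.bolus_tracer = 162.6, ECE.stepped_et1 = 98,
                 ECE.stepped_biget = 27)

# independent oracle for the inhibited free-ligand problem: plain bracketed
# root-finding on the mass-balance residual, no Newton step
oracle_free <- function(Ttot, RA, RB, Kd, I, Kia, Kib) {
  if (Ttot == 0) return(0)
  KdA <- if (is.finite(Kia)) Kd * (1 + I / Kia) else Kd
  KdB <- if (is.finite(Kib)) Kd * (1 + I / Kib) else Kd
  g <- function(u) u + RA * u / (KdA + u) + RB * u / (KdB + u) - Ttot
  stats::uniroot(g, c(0, Ttot), tol = 1e-13)$root
}
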