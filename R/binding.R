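#' Split a lumped receptor pool into ETA and ETB pools
#'
#' The model lumps ETA and ETB during calibration (shared dissociation
#' constant) and splits the total pool afterwards by the ETB fraction
#' `f_B`: `RB_tot = f_B * R_tot`, `RA_tot = (1 - f_B) * R_tot`.
#'
#' @param R_tot Total receptor concentration (pmol/L), non-negative.
#' @param f_B Fraction of receptors that are ETB, in [0, 1].
#' @return Named numeric vector `c(RA_tot, RB_tot)`; the two components
#'   sum to `R_tot` exactly.
#' @examples
#' split_receptor_pool(460, 0.8)
#' @export
split_receptor_pool <- function(R_tot, f_B) {
  if (!is.numeric(R_tot) || any(R_tot < 0)) stop("R_tot must be >= 0")
  if (!is.numeric(f_B) || any(f_B < 0 | f_B > 1)) stop("f_B must lie in [0, 1]")
  RB <- f_B * R_tot
  c(RA_tot = R_tot - RB, RB_tot = RB)
}

#' Free ligand at quasi-equilibrium without an antagonist
#'
#' Solves the single-receptor-class quasi-equilibrium mass balance
#' `ET1_tot = u + R_tot * u / (Kd + u)` for the free ligand `u`, using the
#' cancellation-safe form of the quadratic root.
#'
#' @param ET1_tot Total (free + bound) ligand concentration (pmol/L).
#' @param R_tot Total receptor concentration (pmol/L).
#' @param Kd Dissociation constant (pmol/L), positive.
#' @return Free ET-1 concentration, in `[0, ET1_tot]`. Vectorized.
#' @examples
#' free_ligand(1487.6, 7738, 400)  # ~88.3
#' @export
free_ligand <- function(ET1_tot, R_tot, Kd) {
  if (any(Kd <= 0)) stop("Kd must be > 0")
  if (any(ET1_tot < 0) || any(R_tot < 0)) stop("concentrations must be >= 0")
  b <- ET1_tot - R_tot - Kd
  disc <- sqrt(b * b + 4 * Kd * ET1_tot)
  # b >= 0: (b + disc)/2 is safe; b < 0: use the product form to avoid
  # subtracting nearly equal numbers
  u <- ifelse(b >= 0, (b + disc) / 2, 2 * Kd * ET1_tot / (disc - b))
  pmin(pmax(u, 0), ET1_tot)
}

#' Receptor-ligand complex at quasi-equilibrium
#'
#' `R_tot * u / (Kd + u)`: the bound-complex concentration given free
#' ligand `u`. Under a competitive antagonist at concentration `I` the same
#' form applies with `Kd` replaced by `Kd * (1 + I / K_i)`.
#'
#' @inheritParams free_ligand
#' @param ET1_free Free ligand concentration (pmol/L).
#' @return Complex concentration (pmol/L), bounded above by `R_tot`.
#' @export
bound_complex <- function(R_tot, ET1_free, Kd) {
  if (any(Kd <= 0)) stop("Kd must be > 0")
  if (any(ET1_free < 0) || any(R_tot < 0)) stop("concentrations must be >= 0")
  R_tot * ET1_free / (Kd + ET1_free)
}

#' Competitive antagonist specification
#'
#' @param K_ia Antagonist affinity (inhibition constant) for ETA (pmol/L).
#' @param K_ib Antagonist affinity for ETB (pmol/L). `Inf` encodes a
#'   perfectly selective ETA antagonist (no ETB binding), and vice versa;
#'   finite values up to 1e20 are accepted as the conventional
#'   "effectively infinite" encoding.
#' @return An object of class `et_antagonist` with fields `K_ia`, `K_ib`
#'   and `selectivity = K_ib / K_ia` (> 1 means ETA-selective).
#' @examples
#' bq123 <- et_antagonist(K_ia = 780, K_ib = 2.43e7)
#' bq123$selectivity
#' @export
et_antagonist <- function(K_ia, K_ib) {
  if (!(K_ia > 0) || !(K_ib > 0)) stop("K_ia and K_ib must be > 0 (Inf allowed)")
  structure(list(K_ia = K_ia, K_ib = K_ib, selectivity = K_ib / K_ia),
            class = "et_antagonist")
}

# effective dissociation constant under competitive inhibition;
# infinite affinity constants leave Kd unchanged
kd_eff <- function(Kd, I, K_i) {
  if (!is.finite(K_i)) return(rep_len(Kd, length(I)))
  Kd * (1 + I / K_i)
}

#' Free ligand under a competitive antagonist (cubic mass balance)
#'
#' With two receptor classes whose effective dissociation constants differ
#' under a competitive antagonist, the free-ligand mass balance
#' `ET1_tot = u + RA_tot*u/(KdA + u) + RB_tot*u/(KdB + u)` (with
#' `KdX = Kd * (1 + I/K_ix)`) is a cubic in `u`. The unique physical root
#' in `[0, ET1_tot]` is found by safeguarded Newton iteration with a
#' bisection fallback, which remains stable for the extreme affinity
#' constants (up to 1e20, or `Inf`) used to encode perfect selectivity.
#'
#' @inheritParams free_ligand
#' @param RA_tot,RB_tot ETA and ETB receptor pool concentrations (pmol/L).
#' @param I Antagonist concentration (pmol/L), non-negative.
#' @param K_ia,K_ib Antagonist affinities for ETA / ETB (pmol/L; `Inf`
#'   drops the corresponding inhibition term analytically).
#' @param tol Relative convergence tolerance on the mass-balance residual.
#' @return Free ET-1 concentration (scalar).
#' @examples
#' free_ligand_inhibited(10, 92, 368, 400, I = 10, K_ia = 1, K_ib = 1e20)
#' @export
free_ligand_inhibited <- function(ET1_tot, RA_tot, RB_tot, Kd, I, K_ia, K_ib,
                                  tol = 1e-12) {
  if (Kd <= 0 || K_ia <= 0 || K_ib <= 0) stop("Kd, K_ia, K_ib must be > 0")
  if (ET1_tot < 0 || RA_tot < 0 || RB_tot < 0 || I < 0)
    stop("concentrations must be >= 0")
  if (ET1_tot == 0) return(0)
  KdA <- kd_eff(Kd, I, K_ia)
  KdB <- kd_eff(Kd, I, K_ib)
  solve_free(ET1_tot, RA_tot, RB_tot, KdA, KdB, tol)
}

# dispatcher: collapse degenerate cases to the closed-form quadratic,
# otherwise safeguarded Newton on the cubic mass balance
solve_free <- function(Ttot, RA, RB, KdA, KdB, tol = 1e-12) {
  if (Ttot <= 0) return(0)
  if (KdA == KdB) return(free_ligand(Ttot, RA + RB, KdA))
  if (RA == 0) return(free_ligand(Ttot, RB, KdB))
  if (RB == 0) return(free_ligand(Ttot, RA, KdA))
  solve_free_newton(Ttot, RA, RB, KdA, KdB, tol)
}

# safeguarded Newton / bisection on g(u) = u + RA u/(KdA+u) + RB u/(KdB+u) - T
# over [0, T]; g is strictly increasing so the bracket always shrinks
solve_free_newton <- function(Ttot, RA, RB, KdA, KdB, tol = 1e-12) {
  g <- function(u) u + RA * u / (KdA + u) + RB * u / (KdB + u) - Ttot
  lo <- 0; hi <- Ttot
  # start from the lumped-quadratic estimate with the smaller effective Kd
  u <- free_ligand(Ttot, RA + RB, min(KdA, KdB))
  if (u <= lo || u >= hi) u <- Ttot / 2
  for (iter in 1:100) {
    gu <- g(u)
    if (abs(gu) <= tol * Ttot) return(u)
    if (gu > 0) hi <- u else lo <- u
    dg <- 1 + RA * KdA / (KdA + u)^2 + RB * KdB / (KdB + u)^2
    un <- u - gu / dg
    u <- if (un <= lo || un >= hi) (lo + hi) / 2 else un
  }
  if ((hi - lo) > 1e-6 * Ttot + 1e-9)
    stop(sprintf(paste0("free-ligand solve did not converge ",
                        "(ET1_tot=%g, RA=%g, RB=%g, KdA=%g, KdB=%g)"),
                 Ttot, RA, RB, KdA, KdB))
  (lo + hi) / 2
}

#' Full quasi-equilibrium binding solution under an antagonist
#'
#' Solves the inhibited free-ligand cubic and returns the complete binding
#' state: free ET-1, both receptor-ligand complexes, and both free
#' receptor concentrations (which exclude antagonist-bound receptors).
#'
#' @inheritParams free_ligand_inhibited
#' @return A list of class `et_binding` with fields `ET1_free`, `ET1_RA`,
#'   `ET1_RB`, `RA_free`, `RB_free`. The mass balance
#'   `ET1_free + ET1_RA + ET1_RB == ET1_tot` holds to solver tolerance.
#' @export
binding_solution <- function(ET1_tot, RA_tot, RB_tot, Kd, I = 0,
                             K_ia = Inf, K_ib = Inf) {
  u <- free_ligand_inhibited(ET1_tot, RA_tot, RB_tot, Kd, I, K_ia, K_ib)
  KdA <- kd_eff(Kd, I, K_ia)
  KdB <- kd_eff(Kd, I, K_ib)
  structure(list(
    ET1_free = u,
    ET1_RA = RA_tot * u / (KdA + u),
    ET1_RB = RB_tot * u / (KdB + u),
    RA_free = RA_tot / (1 + u / Kd + inh_ratio(I, K_ia)),
    RB_free = RB_tot / (1 + u / Kd + inh_ratio(I, K_ib))
  ), class = "et_binding")
}

inh_ratio <- function(I, K_i) if (is.finite(K_i)) I / K_i else 0
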