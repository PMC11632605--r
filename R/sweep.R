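#' Steady-state antagonist concentration sweep
#'
#' Computes the steady state of the full kinetics model over a grid of
#' antagonist concentrations and reports, for each grid point, the percent
#' change from the drug-free baseline of the four receptor complexes and
#' of free ET-1 in both compartments.
#'
#' By default the sweep applies a single whole-body ETB fraction, the
#' receptor-amount-weighted pool of the per-compartment calibrated values
#' ([pooled_fB()], 0.747 at the default parameters); the antagonism
#' analysis treats the receptor split as one quantity, and this is the
#' configuration under which the published sweep magnitudes are internally
#' consistent. Pass `f_B = NULL` to use the per-compartment fractions
#' instead, or a number to force a scenario value (e.g. 0.5 or 0.999).
#'
#' @param params An [et_params()] object.
#' @param antagonist An [et_antagonist()]; use `Inf` for the off-target
#'   affinity of a perfectly selective drug (the conventional 1e20
#'   encoding is also accepted).
#' @param conc_mult Concentration grid as multiples of `ref`; a value of 0
#'   (the baseline) is always prepended.
#' @param ref Reference affinity for the concentration grid: `"K_ia"` or
#'   `"K_ib"`.
#' @param f_B ETB-fraction mode: `"pooled"` (default), `NULL`
#'   (per-compartment), or a fraction in `[0, 1]` applied to both
#'   compartments.
#' @param anchor Baseline anchoring (see [steady_state_init()]).
#' @param mode `"steady"` (default) solves the algebraic steady state at
#'   each concentration. `"transient"` instead integrates the model for
#'   `horizon` minutes of constant exposure and reports the endpoint.
#'   The two differ materially at high concentrations: at steady state
#'   the total internalization flux must equal the production flux, so
#'   the total complex amount is invariant and the less-antagonized
#'   complex plateaus above baseline; over any finite horizon the ET-1
#'   pool has not yet accumulated enough to offset a strong blockade
#'   (the equilibration time grows with concentration), so the same
#'   complex passes through a maximum and then falls below baseline.
#' @param horizon Exposure duration (min) for the transient mode.
#' @return A data frame of class `et_sweep`: `conc_mult`, `I` (pmol/L),
#'   absolute complex and free concentrations, and percent changes
#'   (`pct_*`) versus baseline. Attribute `baseline` holds the drug-free
#'   solution; `selectivity` the antagonist's `K_ib/K_ia`.
#' @export
run_sweep <- function(params, antagonist, conc_mult, ref = c("K_ia", "K_ib"),
                      f_B = "pooled", anchor = c("Rtot_t", "ECE"),
                      mode = c("steady", "transient"), horizon = 1000) {
  ref <- match.arg(ref)
  anchor <- match.arg(anchor)
  mode <- match.arg(mode)
  if (any(conc_mult < 0)) stop("conc_mult must be >= 0")
  Kref <- antagonist[[ref]]
  if (!is.finite(Kref))
    stop("reference affinity ", ref, " is infinite; pick the on-target side")
  conc_mult <- sort(unique(c(0, conc_mult)))
  solve1 <- if (mode == "steady") {
    function(I) steady_state_with_antagonist(params, antagonist, I,
                                             f_B = f_B, anchor = anchor)
  } else {
    function(I) transient_exposure_endpoint(params, antagonist, I,
                                            f_B = f_B, anchor = anchor,
                                            horizon = horizon)
  }
  sols <- lapply(conc_mult * Kref, solve1)
  base <- sols[[1]]
  pull <- function(s) c(
    ET1_RA_p = s$plasma$ET1_RA, ET1_RB_p = s$plasma$ET1_RB,
    ET1_RA_t = s$tissue$ET1_RA, ET1_RB_t = s$tissue$ET1_RB,
    ET1_free_p = unname(s$free["up"]), ET1_free_t = unname(s$free["ut"]))
  ab <- t(vapply(sols, pull, numeric(6)))
  b <- pull(base)
  pct <- sweep(ab, 2, b, function(x, b0) 100 * (x - b0) / b0)
  colnames(pct) <- paste0("pct_", colnames(ab))
  out <- data.frame(conc_mult = conc_mult, I = conc_mult * Kref, ab, pct)
  attr(out, "baseline") <- base
  attr(out, "selectivity") <- antagonist$selectivity
  attr(out, "f_B") <- f_B
  class(out) <- c("et_sweep", "data.frame")
  out
}

#' Perfectly selective antagonist sweeps
#'
#' The headline simulation: a perfectly selective ETA antagonist
#' (`K_ia = 1`, no ETB binding) swept over 0.001-1000 x K_ia, or a
#' perfectly selective ETB antagonist (`K_ib = 1`, no ETA binding) swept
#' over 0.001-100000 x K_ib, at steady state.
#'
#' @param params An [et_params()] object.
#' @param target Which receptor the drug blocks: `"ETA"` or `"ETB"`.
#' @param f_B ETB-fraction mode (see [run_sweep()]).
#' @param n_per_decade Log-spaced grid resolution.
#' @param perfect How to encode the absent off-target affinity: `"inf"`
#'   (drop the term analytically) or `"1e20"` (the conventional huge
#'   constant); results agree to solver tolerance.
#' @return An `et_sweep` data frame (see [run_sweep()]).
#' @examples
#' \donttest{
#' sw <- sweep_perfect(et_params(), "ETA")
#' max(sw$pct_ET1_RB_p)  # ~ +44% rise of the unantagonized plasma complex
#' }
#' @export
sweep_perfect <- function(params, target = c("ETA", "ETB"), f_B = "pooled",
                          n_per_decade = 25, perfect = c("inf", "1e20")) {
  target <- match.arg(target)
  perfect <- match.arg(perfect)
  off <- if (perfect == "inf") Inf else 1e20
  if (target == "ETA") {
    antag <- et_antagonist(K_ia = 1, K_ib = off)
    grid <- log_grid(1e-3, 1e3, n_per_decade)
    run_sweep(params, antag, grid, ref = "K_ia", f_B = f_B)
  } else {
    antag <- et_antagonist(K_ia = off, K_ib = 1)
    grid <- log_grid(1e-3, 1e5, n_per_decade)
    run_sweep(params, antag, grid, ref = "K_ib", f_B = f_B)
  }
}

# endpoint of a fixed-duration constant-exposure simulation, in the same
# shape steady_state_with_antagonist() returns
transient_exposure_endpoint <- function(params, antagonist, I, f_B, anchor,
                                        horizon) {
  proto <- constant_exposure_protocol(I, antagonist, horizon = horizon)
  sim <- et_simulate(proto, params, output_times = c(0, horizon),
                     f_B = f_B, anchor = anchor,
                     exposure = list(mode = "step", t_half = 60))
  end <- sim[nrow(sim), ]
  list(free = c(up = end$up, ut = end$ut),
       plasma = list(ET1_free = end$up, ET1_RA = end$CAp, ET1_RB = end$CBp),
       tissue = list(ET1_free = end$ut, ET1_RA = end$CAt, ET1_RB = end$CBt),
       state = c(Tt = end$Tt, Tp = end$Tp))
}

log_grid <- function(lo, hi, n_per_decade) {
  10^seq(log10(lo), log10(hi),
         length.out = round(n_per_decade * log10(hi / lo)) + 1)
}

#' Summary metrics of a selectivity sweep
#'
#' For a sweep of an ETA-selective (selectivity > 1) or ETB-selective
#' drug, reports per compartment: the maximum percent rise of the
#' non-antagonized complex, the concentration multiple at which the
#' antagonized complex is suppressed by 50% (log-interpolated), and the
#' concentration multiple at which the non-antagonized complex's change
#' crosses zero from above (`NA` with `zero_cross_reached = FALSE` when
#' the crossing lies beyond the grid).
#'
#' @param result An `et_sweep` from [run_sweep()] / [sweep_perfect()].
#' @return A data frame with one row per compartment (`plasma`,
#'   `tissue`).
#' @export
summarize_sweep <- function(result) {
  stopifnot(inherits(result, "et_sweep"))
  sel <- attr(result, "selectivity")
  eta_selective <- is.na(sel) || sel >= 1
  ant <- if (eta_selective) "ET1_RA" else "ET1_RB"   # antagonized complex
  non <- if (eta_selective) "ET1_RB" else "ET1_RA"
  one <- function(comp) {
    suff <- if (comp == "plasma") "_p" else "_t"
    pa <- result[[paste0("pct_", ant, suff)]]
    pn <- result[[paste0("pct_", non, suff)]]
    cm <- result$conc_mult
    zc <- crossing_mult(cm, pn + 0)      # first + -> - crossing
    data.frame(compartment = comp, selectivity = sel,
               max_rise_pct = max(pn),
               mult_at_max = cm[which.max(pn)],
               supp50_mult = crossing_mult(cm, pa + 50),
               zero_cross_mult = zc,
               zero_cross_reached = !is.na(zc))
  }
  rbind(one("plasma"), one("tissue"))
}

# first downward zero crossing of y(conc_mult), log-interpolated on the grid;
# NA when y never crosses from above
crossing_mult <- function(cm, y) {
  pos <- cm > 0
  cm <- cm[pos]; y <- y[pos]
  idx <- which(y[-length(y)] > 0 & y[-1] <= 0)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  w <- y[i] / (y[i] - y[i + 1])
  exp((1 - w) * log(cm[i]) + w * log(cm[i + 1]))
}

#' Receptor-fraction scenario comparison
#'
#' Repeats both perfectly selective sweeps with the whole-body ETB
#' fraction forced to a scenario value (0.5: equal receptor pools and
#' thus symmetric antagonism; 0.999: almost pure ETB) and returns the two
#' sweeps side by side.
#'
#' @param f_B Scenario ETB fraction in `[0, 1]`, or `"pooled"` for the
#'   default configuration.
#' @param params An [et_params()] object.
#' @param n_per_decade Grid resolution (see [sweep_perfect()]).
#' @return A list with elements `ETA` and `ETB` (each an `et_sweep`) and
#'   `f_B`.
#' @export
fb_scenario <- function(f_B, params = et_params(), n_per_decade = 25) {
  list(ETA = sweep_perfect(params, "ETA", f_B = f_B,
                           n_per_decade = n_per_decade),
       ETB = sweep_perfect(params, "ETB", f_B = f_B,
                           n_per_decade = n_per_decade),
       f_B = f_B)
}

#' Approximate selectivities of marketed ETA antagonists
#'
#' Ships a configurable preset table of ETA-selective drugs with
#' order-of-magnitude selectivity values (K_ib/K_ia) assembled from the
#' secondary literature; the primary study cites but does not print these
#' numbers, so they are placeholders for exploratory sweeps, not
#' reference values.
#'
#' @return Data frame with columns `drug`, `selectivity`.
#' @export
et_drug_presets <- function() {
  data.frame(
    drug = c("bosentan", "ambrisentan", "atrasentan", "sitaxentan",
             "zibotentan"),
    selectivity = c(20, 4000, 1800, 6500, 10000))
}
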