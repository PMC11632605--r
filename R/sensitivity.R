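#' Saltelli sample design for Sobol sensitivity analysis
#'
#' Generates the base matrices A and B and the k radial matrices AB_i (A
#' with column i replaced from B), the standard design for estimating
#' first-order and total-order Sobol indices with N*(k+2) model
#' evaluations. Sampling is uniform within each parameter's range
#' (log-uniform optional for scale parameters), deterministic given the
#' seed.
#'
#' @param ranges Data frame with columns `parameter`, `lower`, `upper`
#'   (positive-width ranges).
#' @param N Base sample size; must be a power of two and >= 64 (balance of
#'   the sampling sequence).
#' @param seed Integer seed.
#' @param log_uniform Logical (scalar or per-parameter): sample
#'   log-uniformly.
#' @return A list with the evaluation matrix `X` (N*(k+2) rows, in the
#'   order A, B, AB_1 ... AB_k), and `N`, `k`, `parameters`.
#' @export
sobol_design <- function(ranges, N, seed = 1, log_uniform = FALSE) {
  stopifnot(all(c("parameter", "lower", "upper") %in% names(ranges)))
  if (any(ranges$upper <= ranges$lower)) stop("ranges must have positive width")
  if (N < 64 || bitwAnd(N, N - 1L) != 0L)
    stop("N must be a power of two and >= 64")
  k <- nrow(ranges)
  lg <- rep_len(log_uniform, k)
  if (any(lg & ranges$lower <= 0))
    stop("log-uniform sampling needs positive lower bounds")
  set.seed(seed)
  # one scrambled Sobol' point set in 2k dimensions supplies both base
  # matrices (A = first k coordinates, B = last k), the standard
  # low-discrepancy construction for Saltelli designs
  P <- sobol_points(N, 2 * k, shift = sobol_shift(2 * k))
  U <- rbind(P[, seq_len(k), drop = FALSE],
             P[, k + seq_len(k), drop = FALSE])
  scale1 <- function(u, i) {
    if (lg[i]) exp(log(ranges$lower[i]) + u * log(ranges$upper[i] / ranges$lower[i]))
    else ranges$lower[i] + u * (ranges$upper[i] - ranges$lower[i])
  }
  A <- vapply(seq_len(k), function(i) scale1(U[1:N, i], i), numeric(N))
  B <- vapply(seq_len(k), function(i) scale1(U[N + (1:N), i], i), numeric(N))
  colnames(A) <- colnames(B) <- ranges$parameter
  ABs <- lapply(seq_len(k), function(i) { M <- A; M[, i] <- B[, i]; M })
  X <- do.call(rbind, c(list(A, B), ABs))
  list(X = X, N = N, k = k, parameters = ranges$parameter)
}

#' Sobol first-order and total-order indices
#'
#' Estimates S_i (a parameter's solo variance contribution) with the
#' Saltelli 2010 estimator and T_i (its contribution including all
#' interactions) with the Jansen estimator, from model outputs evaluated
#' on a [sobol_design()] matrix, with bootstrap confidence intervals from
#' resampling the N design rows.
#'
#' @param y Model outputs over the design rows (length N*(k+2), in design
#'   order).
#' @param design The [sobol_design()] used to generate `y`.
#' @param nboot Bootstrap replicates for the CIs (0 disables).
#' @param conf Confidence level.
#' @return Data frame: `parameter`, `S1`, `S1_CI_low`, `S1_CI_high`,
#'   `ST`, `ST_CI_low`, `ST_CI_high`. A zero-variance output yields all
#'   zeros with a warning.
#' @examples
#' d <- sobol_design(data.frame(parameter = c("x1", "x2"),
#'                              lower = 0, upper = 1), N = 1024)
#' y <- d$X[, 1] + 2 * d$X[, 2]
#' sobol_indices(y, d)  # S1 ~ 0.2, S2 ~ 0.8
#' @export
sobol_indices <- function(y, design, nboot = 100, conf = 0.95) {
  N <- design$N; k <- design$k
  if (length(y) != N * (k + 2)) stop("y length must be N*(k+2)")
  if (!all(is.finite(y))) stop("model outputs must be finite")
  yA <- y[1:N]; yB <- y[N + (1:N)]
  yAB <- matrix(y[-(1:(2 * N))], nrow = N, ncol = k)
  est <- function(idx) {
    a <- yA[idx]; b <- yB[idx]; ab <- yAB[idx, , drop = FALSE]
    V <- stats::var(c(a, b))
    if (V < .Machine$double.eps)
      return(cbind(S1 = rep(0, k), ST = rep(0, k)))
    S1 <- vapply(seq_len(k), function(i) mean(b * (ab[, i] - a)) / V, numeric(1))
    ST <- vapply(seq_len(k), function(i) mean((a - ab[, i])^2) / (2 * V), numeric(1))
    cbind(S1 = S1, ST = ST)
  }
  if (stats::var(c(yA, yB)) < .Machine$double.eps)
    warning("zero-variance output; all indices set to 0")
  point <- est(seq_len(N))
  out <- data.frame(parameter = design$parameters,
                    S1 = point[, "S1"], S1_CI_low = NA, S1_CI_high = NA,
                    ST = point[, "ST"], ST_CI_low = NA, ST_CI_high = NA)
  if (nboot > 0) {
    boots <- array(NA_real_, c(k, 2, nboot))
    for (b in seq_len(nboot))
      boots[, , b] <- est(sample.int(N, N, replace = TRUE))
    al <- (1 - conf) / 2
    out$S1_CI_low <- apply(boots[, 1, , drop = FALSE], 1, stats::quantile, al)
    out$S1_CI_high <- apply(boots[, 1, , drop = FALSE], 1, stats::quantile, 1 - al)
    out$ST_CI_low <- apply(boots[, 2, , drop = FALSE], 1, stats::quantile, al)
    out$ST_CI_high <- apply(boots[, 2, , drop = FALSE], 1, stats::quantile, 1 - al)
  }
  out
}

#' Global sensitivity of the antagonist-sweep output to model parameters
#'
#' Convenience wrapper: Sobol analysis of a scalar functional of the
#' kinetics model — by default the maximum percent rise of the plasma
#' ET1-ETB complex over a perfectly selective ETA antagonist sweep — with
#' parameters varied uniformly over +/- `span` times their reported
#' relative standard errors around the calibrated values.
#'
#' @param params An [et_params()] object (center of the ranges).
#' @param parameters Which parameters to vary (default: all with reported
#'   RSEs, including the two receptor-fraction parameters).
#' @param N Base sample size (power of two).
#' @param seed Integer seed.
#' @param span Half-width of each range in RSE multiples (default 3).
#' @param n_per_decade Sweep grid resolution for the output functional.
#' @param output Functional of the sweep: `"max_rise_CBp"` (default) or
#'   `"max_rise_CBt"`.
#' @return A list with `indices` (the [sobol_indices()] table sorted by
#'   decreasing total-order index) and `design`.
#' @export
et_sobol <- function(params = et_params(), parameters = names(et_params_rse()),
                     N = 128, seed = 1, span = 3, n_per_decade = 8,
                     output = c("max_rise_CBp", "max_rise_CBt")) {
  output <- match.arg(output)
  rse <- et_params_rse()
  if (!all(parameters %in% names(rse)))
    stop("parameters must be among: ", paste(names(rse), collapse = ", "))
  ctr <- vapply(parameters, function(nm) params[[nm]], numeric(1))
  half <- span * rse[parameters] * ctr
  ranges <- data.frame(parameter = parameters,
                       lower = pmax(ctr - half, 1e-12),
                       upper = ctr + half)
  for (nm in c("fB_t", "fB_c")) {
    i <- which(ranges$parameter == nm)
    if (length(i)) ranges$upper[i] <- min(ranges$upper[i], 1)
  }
  design <- sobol_design(ranges, N, seed)
  col <- if (output == "max_rise_CBp") "pct_ET1_RB_p" else "pct_ET1_RB_t"
  y <- apply(design$X, 1, function(row) {
    p <- params
    for (j in seq_along(parameters)) p[[parameters[j]]] <- unname(row[j])
    sw <- sweep_perfect(p, "ETA", f_B = "pooled",
                        n_per_decade = n_per_decade)
    max(sw[[col]])
  })
  idx <- sobol_indices(y, design, nboot = 50)
  list(indices = idx[order(-idx$ST), ], design = design)
}
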