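#' Observation set for model fitting
#'
#' Bundles a protocol with plasma ET-1 measurements at the protocol's
#' sampling times. Tracer-mode sets hold unitless relative values
#' (baseline-subtracted, peak-normalized); all others hold absolute
#' plasma ET-1 in pmol/L.
#'
#' @param study_id Label identifying the study (used to map
#'   study-specific ECE values).
#' @param protocol An [et_protocol()].
#' @param times Observation times (min), within the protocol horizon.
#' @param values Observed plasma ET-1 (pmol/L, or relative units).
#' @param relative Whether values are in relative (tracer) mode.
#' @return An object of class `et_observations`.
#' @export
et_observations <- function(study_id, protocol, times, values,
                            relative = protocol$rel_output) {
  stopifnot(inherits(protocol, "et_protocol"))
  if (length(times) != length(values)) stop("times and values differ in length")
  if (any(times < 0 | times > protocol$horizon))
    stop("observation times outside the protocol horizon")
  if (!relative && any(values < 0)) stop("absolute concentrations must be >= 0")
  structure(list(study_id = study_id, protocol = protocol,
                 times = as.numeric(times), values = as.numeric(values),
                 relative = isTRUE(relative)),
            class = "et_observations")
}

#' Read and write observation sets as CSV
#'
#' Schema: `study_id, time_min, et1_pmol_per_L, relative_flag`. Protocols
#' are matched back by `study_id` on read.
#'
#' @param datasets List of [et_observations()].
#' @param path CSV file path.
#' @param protocols Named list of protocols keyed by study id (for
#'   reading).
#' @return `write_et_observations()` returns `path` invisibly;
#'   `read_et_observations()` a list of observation sets.
#' @export
write_et_observations <- function(datasets, path) {
  df <- do.call(rbind, lapply(datasets, function(d)
    data.frame(study_id = d$study_id, time_min = d$times,
               et1_pmol_per_L = d$values,
               relative_flag = as.integer(d$relative))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_et_observations
#' @export
read_et_observations <- function(path, protocols) {
  df <- utils::read.csv(path)
  lapply(split(df, df$study_id), function(s)
    et_observations(s$study_id[1], protocols[[as.character(s$study_id[1])]],
                    s$time_min, s$et1_pmol_per_L,
                    relative = s$relative_flag[1] == 1))
}

# model-predicted observable for one dataset at one parameter set:
# plasma free ET-1, or its baseline-subtracted peak-normalized form
predict_observable <- function(dataset, params, rtol = 1e-7, atol = 1e-9) {
  sim <- et_simulate(dataset$protocol, params,
                     output_times = sort(unique(c(dataset$times,
                                                  dataset$protocol$sampling_times))),
                     rel_output = dataset$relative, anchor = "ECE",
                     rtol = rtol, atol = atol)
  col <- if (dataset$relative) "rel" else "up"
  sim[[col]][match(dataset$times, sim$time)]
}

#' Least-squares objective over multiple observation sets
#'
#' The unweighted sum over datasets of squared residuals between the
#' observed plasma ET-1 and the model prediction simulated under each
#' dataset's own protocol, with all parameters shared except ECE, which
#' is study-specific. Relative-mode datasets are compared after the same
#' baseline-subtraction and peak normalization is applied to the model
#' output. Simulation failures return a large finite penalty.
#'
#' @param theta Named parameter vector on the natural scale. Shared names
#'   come from [et_params()]; study-specific ECE entries are named
#'   `ECE.<study_id>`.
#' @param datasets List of [et_observations()].
#' @param base_params Parameter values for everything not in `theta`.
#' @param weighting `"none"` (default) or `"proportional"` (residuals
#'   divided by the prediction).
#' @param rtol,atol Integrator tolerances used during fitting.
#' @return Scalar sum of squared errors.
#' @export
et_objective <- function(theta, datasets, base_params = et_params(),
                         weighting = c("none", "proportional"),
                         rtol = 1e-7, atol = 1e-9) {
  weighting <- match.arg(weighting)
  sse <- 0
  for (d in datasets) {
    p <- apply_theta(base_params, theta, d$study_id)
    pred <- tryCatch(predict_observable(d, p, rtol, atol),
                     error = function(e) NULL)
    if (is.null(pred) || anyNA(pred)) return(1e10)
    r <- d$values - pred
    if (weighting == "proportional") r <- r / pmax(abs(pred), 1e-6)
    sse <- sse + sum(r^2)
  }
  sse
}

apply_theta <- function(params, theta, study_id) {
  nm <- names(theta)
  ece_key <- paste0("ECE.", study_id)
  for (i in seq_along(theta)) {
    if (nm[i] == ece_key) params$ECE <- unname(theta[i])
    else if (nm[i] %in% names(params) && !startsWith(nm[i], "ECE."))
      params[[nm[i]]] <- unname(theta[i])
  }
  params
}

#' Fit the kinetics model to observation sets
#'
#' Bound-constrained least-squares estimation over log-transformed
#' parameters (scales span several orders of magnitude), with optional
#' seeded multistart. The default optimizer is Levenberg-Marquardt
#' (`minpack.lm::nls.lm`) on the residual vector with a finite-difference
#' step large enough to sit above the ODE-integration noise floor, which
#' descends the sloppy valleys of this objective reliably; `"l-bfgs-b"`
#' minimizes the scalar SSE instead. Approximate relative standard errors
#' come from a finite-difference Jacobian of the residual vector at the
#' optimum (Gauss-Newton curvature), computed on the log scale so they
#' are relative errors directly; practically unidentifiable parameters
#' show RSEs orders of magnitude above 100%.
#'
#' @param datasets List of [et_observations()].
#' @param init Named vector of starting values (natural scale); names as
#'   in [et_objective()].
#' @param lower,upper Named bounds (natural scale); default init/50 and
#'   init*50.
#' @param base_params Fixed values for parameters not being estimated.
#' @param multistart Number of optimizer starts (>= 1); starts beyond the
#'   first jitter `init` log-normally.
#' @param seed Seed for the multistart jitter.
#' @param maxit Iteration cap per start.
#' @param method `"lm"` (Levenberg-Marquardt, default) or `"l-bfgs-b"`.
#' @param weighting Residual weighting (see [et_objective()]).
#' @param rtol,atol Integrator tolerances during fitting.
#' @return List of class `et_fit`: `estimates` (natural scale), `rse`
#'   (relative standard errors, fractions), `sse`, `convergence` (0 =
#'   converged), `n_obs`, and the per-start SSEs (`start_sse`).
#' @export
et_fit <- function(datasets, init, lower = init / 50, upper = init * 50,
                   base_params = et_params(), multistart = 1, seed = 1,
                   maxit = 300, method = c("lm", "l-bfgs-b"),
                   weighting = "none", rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  stopifnot(length(datasets) >= 1, !is.null(names(init)))
  if (any(lower <= 0) || any(!is.finite(upper)))
    stop("bounds must be finite and positive")
  if (any(init < lower | init > upper)) stop("init must lie within bounds")
  nms <- names(init)
  resfun <- function(lth) {
    r <- fit_residuals(lth, nms, datasets, base_params, weighting, rtol, atol)
    r[!is.finite(r)] <- 1e3  # simulation failure penalty, kept finite
    r
  }
  set.seed(seed)
  starts <- list(log(init))
  if (multistart > 1)
    for (i in 2:multistart)
      starts[[i]] <- pmin(pmax(log(init) + stats::rnorm(length(init), 0, 0.3),
                               log(lower)), log(upper))
  run1 <- function(s) {
    if (method == "lm") {
      r <- minpack.lm::nls.lm(
        par = s, fn = resfun, lower = log(lower), upper = log(upper),
        control = minpack.lm::nls.lm.control(
          maxiter = maxit, ftol = 1e-15, ptol = 1e-15, gtol = 0,
          epsfcn = 1e-8))
      list(par = r$par, value = sum(r$fvec^2),
           convergence = if (r$info %in% 1:4) 0L else 1L)
    } else {
      r <- stats::optim(s, function(lth) sum(resfun(lth)^2),
                        method = "L-BFGS-B",
                        lower = log(lower), upper = log(upper),
                        control = list(maxit = maxit, factr = 1e7))
      list(par = r$par, value = r$value, convergence = r$convergence)
    }
  }
  runs <- lapply(starts, run1)
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  est <- exp(best$par); names(est) <- nms
  n_obs <- sum(vapply(datasets, function(d) length(d$times), integer(1)))
  rse <- fit_rse(best$par, nms, datasets, base_params, weighting,
                 best$value, n_obs, rtol, atol)
  structure(list(estimates = est, rse = rse, sse = best$value,
                 convergence = best$convergence, n_obs = n_obs,
                 start_sse = vapply(runs, `[[`, numeric(1), "value")),
            class = "et_fit")
}

#' @export
print.et_fit <- function(x, ...) {
  cat("<et_fit> SSE =", signif(x$sse, 6), " convergence =", x$convergence, "\n")
  print(data.frame(estimate = signif(x$estimates, 5),
                   rse_pct = signif(100 * x$rse, 3)))
  invisible(x)
}

# residual vector across datasets at log-parameters lth
fit_residuals <- function(lth, nms, datasets, base_params, weighting,
                          rtol, atol) {
  th <- exp(lth); names(th) <- nms
  unlist(lapply(datasets, function(d) {
    p <- apply_theta(base_params, th, d$study_id)
    pred <- tryCatch(predict_observable(d, p, rtol, atol),
                     error = function(e) rep(NA_real_, length(d$times)))
    r <- d$values - pred
    if (weighting == "proportional") r <- r / pmax(abs(pred), 1e-6)
    r
  }))
}

# Gauss-Newton RSEs from a finite-difference Jacobian on the log scale;
# singular directions get effectively infinite RSE via pseudo-inverse
fit_rse <- function(lpar, nms, datasets, base_params, weighting, sse, n_obs,
                    rtol, atol) {
  p <- length(lpar)
  r0 <- fit_residuals(lpar, nms, datasets, base_params, weighting, rtol, atol)
  if (anyNA(r0)) return(stats::setNames(rep(NA_real_, p), nms))
  h <- 1e-4
  J <- vapply(seq_len(p), function(i) {
    lp <- lpar; lp[i] <- lp[i] + h
    (fit_residuals(lp, nms, datasets, base_params, weighting, rtol, atol) - r0) / h
  }, numeric(length(r0)))
  J[!is.finite(J)] <- 0  # failed perturbation: treat direction as uninformative
  dof <- max(n_obs - p, 1)
  sigma2 <- max(sse / dof, .Machine$double.eps)
  sv <- svd(J)
  d <- sv$d
  inv <- ifelse(d > max(d) * 1e-10, 1 / d^2, 1e20)  # singular -> huge variance
  covd <- sv$v %*% (inv * t(sv$v)) * sigma2
  stats::setNames(sqrt(pmax(diag(covd), 0)), nms)
}
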