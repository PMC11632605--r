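#' Model parameters for the endothelin-1 kinetics model
#'
#' Constructs the full parameter set of the two-compartment ET-1 kinetics
#' model. Defaults are the published calibrated values. Units are fixed
#' package-wide: concentrations in pmol/L (except `ECE`, conventionally
#' quoted in nmol/L), volumes in L, times in minutes.
#'
#' @param BigET0 Normal plasma Big ET-1 concentration (pmol/L), initial
#'   condition of the precursor pool.
#' @param ET1p0 Normal plasma free ET-1 concentration (pmol/L).
#' @param Kcat_Km ECE catalytic efficiency (L/min/pmol).
#' @param Kd ET-1 dissociation constant, shared by ETA and ETB (pmol/L).
#' @param Vp Central (plasma) compartment volume (L).
#' @param Vt Tissue compartment volume (L).
#' @param ECE Endothelin converting enzyme concentration (nmol/L). The
#'   calibrated value is study-specific; the default is the Hunter-study
#'   value. See `anchor` in [steady_state_init()] for how the baseline
#'   production flux is reconciled with `Rtot_t`.
#' @param Kpt ET-1 distribution rate, plasma to tissue (/min).
#' @param Ktp ET-1 distribution rate, tissue to plasma (/min).
#' @param Kint First-order internalization rate of the receptor-ligand
#'   complex (/min).
#' @param Rtot_p Total receptor concentration, plasma compartment (pmol/L).
#' @param Rtot_t Total receptor concentration, tissue compartment (pmol/L).
#' @param fB_t Fraction of tissue receptors that are ETB (0-1).
#' @param fB_c Fraction of plasma ("central") receptors that are ETB (0-1).
#' @return An object of class `et_params` (a named list).
#' @examples
#' p <- et_params()
#' p$Kd
#' pooled_fB(p)
#' @export
et_params <- function(BigET0 = 0.93, ET1p0 = 3.2, Kcat_Km = 2.64e-4,
                      Kd = 400, Vp = 81.6, Vt = 2.64, ECE = 98,
                      Kpt = 0.87, Ktp = 0.98, Kint = 0.0095,
                      Rtot_p = 460, Rtot_t = 7738,
                      fB_t = 0.65, fB_c = 0.8) {
  p <- list(BigET0 = BigET0, ET1p0 = ET1p0, Kcat_Km = Kcat_Km, Kd = Kd,
            Vp = Vp, Vt = Vt, ECE = ECE, Kpt = Kpt, Ktp = Ktp, Kint = Kint,
            Rtot_p = Rtot_p, Rtot_t = Rtot_t, fB_t = fB_t, fB_c = fB_c)
  class(p) <- "et_params"
  validate_et_params(p)
  p
}

#' @export
print.et_params <- function(x, ...) {
  cat("<et_params> two-compartment ET-1 kinetics parameters\n")
  for (nm in names(x)) cat(sprintf("  %-8s %g\n", nm, x[[nm]]))
  invisible(x)
}

validate_et_params <- function(p) {
  num <- vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                logical(1))
  if (!all(num)) stop("all parameters must be finite numeric scalars; bad: ",
                      paste(names(p)[!num], collapse = ", "))
  pos <- c("BigET0", "ET1p0", "Kcat_Km", "Kd", "Vp", "Vt", "ECE",
           "Kpt", "Ktp", "Kint", "Rtot_p", "Rtot_t")
  bad <- pos[vapply(pos, function(nm) p[[nm]] <= 0, logical(1))]
  if (length(bad)) stop("parameters must be positive: ", paste(bad, collapse = ", "))
  for (nm in c("fB_t", "fB_c"))
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  invisible(p)
}

#' Receptor-amount-weighted whole-body ETB fraction
#'
#' Pools the per-compartment ETB fractions into a single whole-body value,
#' weighting each compartment by its total receptor amount
#' (concentration times volume). This is the default ETB fraction used by
#' the steady-state selectivity sweeps, where the antagonism analysis
#' treats the receptor split as a single quantity.
#'
#' @param params An [et_params()] object.
#' @return The pooled ETB fraction (dimensionless).
#' @export
pooled_fB <- function(params) {
  wt <- params$Rtot_t * params$Vt
  wp <- params$Rtot_p * params$Vp
  (params$fB_t * wt + params$fB_c * wp) / (wt + wp)
}

#' Relative standard errors of the calibrated parameters
#'
#' The approximate relative standard errors (fractions, not percent)
#' reported for the estimated parameters, used to set default sensitivity
#' ranges. `ECE` carries the Hunter-study RSE.
#'
#' @return Named numeric vector of RSE fractions.
#' @export
et_params_rse <- function() {
  c(Vp = 0.011, Vt = 0.07, ECE = 0.046, Kpt = 0.185, Ktp = 0.023,
    Kint = 0.004, Rtot_p = 0.012, fB_t = 0.11, fB_c = 0.15)
}

#' Read and write parameter sets
#'
#' Parameter sets are serialized as YAML (or JSON via file extension
#' `.json`) keyed by the parameter symbol names.
#'
#' @param params An [et_params()] object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_et_params()` returns `path` invisibly;
#'   `read_et_params()` returns an [et_params()] object.
#' @export
write_et_params <- function(params, path) {
  stopifnot(inherits(params, "et_params"))
  x <- unclass(params)
  x <- x[names(x) %in% names(formals(et_params))]  # drop derived fields
  if (grepl("\\.json$", path)) {
    writeLines(to_json_obj(x), path)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_et_params
#' @export
read_et_params <- function(path) {
  x <- if (grepl("\\.json$", path)) yaml::yaml.load(paste(readLines(path), collapse = "\n"))
       else yaml::read_yaml(path)
  do.call(et_params, x)
}

# minimal flat-object JSON writer (numbers only); avoids a jsonlite dependency
to_json_obj <- function(x) {
  vals <- vapply(x, function(v) format(v, digits = 15, scientific = FALSE),
                 character(1))
  paste0("{", paste(sprintf("\"%s\": %s", names(x), vals), collapse = ", "), "}")
}
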