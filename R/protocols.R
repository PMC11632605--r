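#' Construct an infusion protocol
#'
#' A protocol is a set of non-overlapping (per species) piecewise-constant
#' infusion segments plus a sampling schedule. Exogenous inputs are ET-1
#' (into plasma), Big ET-1 (into the tissue precursor pool), and a
#' competitive antagonist (plasma, via the exposure model of
#' [et_simulate()]).
#'
#' @param segments Data frame with columns `t_start`, `t_end` (min),
#'   `species` (one of `"ET1"`, `"BigET"`, `"antagonist"`), and
#'   `rate_pmol_min` (pmol/min).
#' @param antagonist An [et_antagonist()], required when any segment
#'   infuses an antagonist.
#' @param sampling_times Measurement times (min).
#' @param horizon Simulation horizon (min); defaults to the latest of the
#'   segment ends and sampling times.
#' @param mass_kg Subject body mass used for per-kg dose conversion.
#' @param rel_output Whether observations from this protocol are relative
#'   (baseline-subtracted, peak-normalized), as for radiolabeled tracer.
#' @param name Protocol label.
#' @return An object of class `et_protocol`.
#' @export
et_protocol <- function(segments, antagonist = NULL, sampling_times,
                        horizon = NULL, mass_kg = 70, rel_output = FALSE,
                        name = "custom") {
  segments <- as.data.frame(segments)
  need <- c("t_start", "t_end", "species", "rate_pmol_min")
  if (!all(need %in% names(segments)))
    stop("segments must have columns ", paste(need, collapse = ", "))
  if (nrow(segments)) {
    if (any(!segments$species %in% c("ET1", "BigET", "antagonist")))
      stop("species must be ET1, BigET or antagonist")
    if (any(segments$t_start >= segments$t_end))
      stop("each segment needs t_start < t_end")
    if (any(segments$rate_pmol_min < 0)) stop("rates must be >= 0")
    for (sp in unique(segments$species)) {
      s <- segments[segments$species == sp, , drop = FALSE]
      s <- s[order(s$t_start), , drop = FALSE]
      if (nrow(s) > 1 && any(s$t_start[-1] < s$t_end[-nrow(s)]))
        stop("overlapping segments for species ", sp)
    }
    if (any(segments$species == "antagonist") && is.null(antagonist))
      stop("antagonist segments require an et_antagonist spec")
  }
  if (is.null(horizon)) horizon <- max(c(segments$t_end, sampling_times, 0))
  structure(list(segments = segments, antagonist = antagonist,
                 sampling_times = sort(unique(sampling_times)),
                 horizon = horizon, mass_kg = mass_kg,
                 rel_output = rel_output, name = name),
            class = "et_protocol")
}

#' @export
print.et_protocol <- function(x, ...) {
  cat(sprintf("<et_protocol> %s: %d segment(s), horizon %g min, %d sampling times\n",
              x$name, nrow(x$segments), x$horizon, length(x$sampling_times)))
  if (nrow(x$segments)) print(x$segments)
  invisible(x)
}

#' Convert a published dose rate to model units (pmol/min)
#'
#' Mass-based ET-1 doses use a molecular weight of 2492 g/mol for the
#' 21-residue peptide (a package constant, overridable); molar doses
#' convert exactly.
#'
#' @param rate Dose rate in `unit`.
#' @param unit One of `"pmol/min"`, `"pmol/kg/min"`, `"nmol/kg/min"`,
#'   `"ng/kg/min"`.
#' @param mass_kg Subject body mass (kg), used for per-kg units.
#' @param mw Molecular weight (g/mol) for mass-based units.
#' @return Dose rate in pmol/min.
#' @examples
#' convert_dose_rate(0.5, "ng/kg/min", mass_kg = 70)  # ~14.04
#' @export
convert_dose_rate <- function(rate, unit, mass_kg = 70, mw = 2492) {
  if (rate < 0) stop("rate must be >= 0")
  switch(unit,
    "pmol/min" = rate,
    "pmol/kg/min" = rate * mass_kg,
    "nmol/kg/min" = rate * mass_kg * 1000,
    "ng/kg/min" = rate * mass_kg * 1000 / mw,
    stop("unknown dose unit '", unit, "'; supported: pmol/min, pmol/kg/min, ",
         "nmol/kg/min, ng/kg/min"))
}

#' Built-in study protocols
#'
#' The four study designs used to calibrate and validate the model, with
#' the published timings and dose rates:
#'
#' * `bolus_tracer`: radiolabeled ET-1 bolus (a tracer dose of 0.1% of the
#'   plasma ET-1 pool over 5 min; the published dose is unknown and tiny),
#'   dense sampling to 240 min, relative output.
#' * `stepped_et1`: ET-1 at 0.5 / 1.0 / 2.0 ng/kg/min over three 60-min
#'   steps; sampling at 0, 75, 125, 225 min.
#' * `stepped_biget`: Big ET-1 at 0.75 / 15 / 300 pmol/min over three
#'   30-min steps; sampling every 30 min to 150 min.
#' * `validation_placebo` / `validation_bq123` / `validation_bq788`:
#'   saline, the ETA antagonist BQ123 (4 nmol/kg/min, 0-50 min; affinities
#'   K_ia 0.78 nM, K_ib 24.3 uM), or the ETB antagonist BQ788
#'   (4 nmol/kg/min, 0-15 min; K_ia 1 uM, K_ib 9.8 nM), each followed by
#'   ET-1 at 4 pmol/kg/min from minute 30 for 20 min; sampling at
#'   0, 15, 30, 40, 50 min.
#'
#' @param name Protocol name (see above).
#' @param mass_kg Subject body mass for per-kg dose conversion.
#' @return An [et_protocol()] object.
#' @export
builtin_protocol <- function(name = c("bolus_tracer", "stepped_et1",
                                      "stepped_biget", "validation_placebo",
                                      "validation_bq123", "validation_bq788"),
                             mass_kg = 70) {
  if (length(name) != 1 || !name %in% c("bolus_tracer", "stepped_et1",
                                        "stepped_biget", "validation_placebo",
                                        "validation_bq123", "validation_bq788"))
    stop("unknown protocol '", paste(name, collapse = ","),
         "'; available: bolus_tracer, stepped_et1, stepped_biget, ",
         "validation_placebo, validation_bq123, validation_bq788")
  dflt <- et_params()
  switch(name,
    bolus_tracer = {
      dose <- 0.001 * dflt$ET1p0 * dflt$Vp  # 0.1% of the plasma pool, pmol
      et_protocol(
        segments = data.frame(t_start = 0, t_end = 5, species = "ET1",
                              rate_pmol_min = dose / 5),
        sampling_times = c(0:6, 8, 10, 12, 14, 16, 18, 20, 25, 30, 35, 40,
                           45, 50, 60, 70, 80, 100, 120, 150, 180, 210, 240),
        horizon = 240, mass_kg = mass_kg, rel_output = TRUE,
        name = "bolus_tracer")
    },
    stepped_et1 = et_protocol(
      segments = data.frame(
        t_start = c(0, 60, 120), t_end = c(60, 120, 180), species = "ET1",
        rate_pmol_min = vapply(c(0.5, 1, 2), convert_dose_rate,
                               numeric(1), unit = "ng/kg/min",
                               mass_kg = mass_kg)),
      sampling_times = c(0, 75, 125, 225), horizon = 225,
      mass_kg = mass_kg, name = "stepped_et1"),
    stepped_biget = et_protocol(
      segments = data.frame(
        t_start = c(0, 30, 60), t_end = c(30, 60, 90), species = "BigET",
        rate_pmol_min = c(0.75, 15, 300)),
      sampling_times = seq(0, 150, by = 30), horizon = 150,
      mass_kg = mass_kg, name = "stepped_biget"),
    validation_placebo = et_protocol(
      segments = validation_et1_segment(mass_kg),
      sampling_times = c(0, 15, 30, 40, 50), horizon = 60,
      mass_kg = mass_kg, name = "validation_placebo"),
    validation_bq123 = et_protocol(
      segments = rbind(
        data.frame(t_start = 0, t_end = 50, species = "antagonist",
                   rate_pmol_min = convert_dose_rate(4, "nmol/kg/min", mass_kg)),
        validation_et1_segment(mass_kg)),
      antagonist = et_antagonist(K_ia = 780, K_ib = 2.43e7),
      sampling_times = c(0, 15, 30, 40, 50), horizon = 60,
      mass_kg = mass_kg, name = "validation_bq123"),
    validation_bq788 = et_protocol(
      segments = rbind(
        data.frame(t_start = 0, t_end = 15, species = "antagonist",
                   rate_pmol_min = convert_dose_rate(4, "nmol/kg/min", mass_kg)),
        validation_et1_segment(mass_kg)),
      antagonist = et_antagonist(K_ia = 1e6, K_ib = 9800),
      sampling_times = c(0, 15, 30, 40, 50), horizon = 60,
      mass_kg = mass_kg, name = "validation_bq788"))
}

validation_et1_segment <- function(mass_kg) {
  data.frame(t_start = 30, t_end = 50, species = "ET1",
             rate_pmol_min = convert_dose_rate(4, "pmol/kg/min", mass_kg))
}

#' Read and write protocols as YAML
#'
#' @param protocol An [et_protocol()] object.
#' @param path File path (YAML).
#' @return `write_et_protocol()` returns `path` invisibly;
#'   `read_et_protocol()` returns the protocol. A written-then-read
#'   protocol is identical to the original.
#' @export
write_et_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "et_protocol"))
  x <- unclass(protocol)
  x$segments <- lapply(seq_len(nrow(x$segments)), function(i)
    as.list(x$segments[i, , drop = FALSE]))
  if (!is.null(x$antagonist)) x$antagonist <- unclass(x$antagonist)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_et_protocol
#' @export
read_et_protocol <- function(path) {
  x <- yaml::read_yaml(path)
  seg <- do.call(rbind, lapply(x$segments, as.data.frame))
  antag <- if (!is.null(x$antagonist))
    et_antagonist(x$antagonist$K_ia, x$antagonist$K_ib)
  et_protocol(segments = seg, antagonist = antag,
              sampling_times = unlist(x$sampling_times),
              horizon = x$horizon, mass_kg = x$mass_kg,
              rel_output = x$rel_output, name = x$name)
}
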