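#' Liver-MPS stage kinetics for the coupled drug-drug interaction model
#'
#' The conversion time course measured in conventional 2-D dishes (~9 %
#' metabolized by 24 h, [cisapride_metabolism_data()]) does not transfer to
#' the perfused liver chip: the chip holds ~10^4 hepatocytes against a
#' 0.32 uL media channel (a physiological medium-to-cell ratio, orders of
#' magnitude below a dish) and acts as a first-pass organ. Consistent with
#' that, efflux from the uninhibited chip produced no cardiac response at a
#' dose well above the cardiac EC50 — near-complete parent clearance. The
#' default liver-stage kinetics therefore use a high first-pass extraction
#' (plateau 95 %, time constant 2 h, so ~93 % of parent is cleared over an
#' 8-h perfusion) with the inhibition constant derived from the chip's own
#' CYP3A4 activity assay: the seven-fold drop in luminescence under 10 uM
#' ketoconazole gives an inhibition factor of 361/2640 = 0.137, i.e.
#' Ki = 10 * 0.137 / (1 - 0.137) = 1.58 uM.
#'
#' @param A_pct,tau_h Extraction plateau (%) and time constant (h) of the
#'   liver-MPS stage.
#' @param reference Reference measurement list providing the CYP3A4
#'   activity ratio (default [mps_reference_values()]).
#' @return A [metabolism_params()] object.
#' @export
mps_liver_kinetics <- function(A_pct = 95, tau_h = 2,
                               reference = mps_reference_values()) {
  rlu <- reference$cyp3a4_rlu
  fac <- unname(rlu["ketoconazole"] / rlu["control"]) # 1/(1 + I/Ki) at 10 uM
  ki <- 10 * fac / (1 - fac)
  metabolism_params(A_pct = A_pct, tau_h = tau_h, Ki_uM = ki)
}

#' Configuration of an in-silico functional-coupling experiment
#'
#' Describes one drug-drug interaction run: a nominal drug dose that is
#' corrected for PDMS absorption, passed through the liver stage with or
#' without a CYP inhibitor, and finally mapped through a cardiac
#' dose-response curve to a predicted normalized cAPD90. Kinetic and
#' dose-response parameters must be supplied explicitly (no silent
#' defaults for kinetics); [mps_liver_kinetics()] provides the package's
#' documented liver-chip parameterization.
#'
#' @param drug Drug name (label only).
#' @param nominal_dose_nM Nominal dose (nM, >= 0).
#' @param absorbed_fraction PDMS-absorbed fraction in `[0, 1)`.
#' @param liver_duration_h Liver-stage exposure (h).
#' @param inhibitor_uM Inhibitor concentration in the inhibited arm (uM).
#' @param metabolism A [metabolism_params()] object (required).
#' @param hill Cardiac dose-response of the normalized cAPD90: a list with
#'   `ec50_nM`, `emax` (saturating normalized response, vehicle = 1),
#'   and optionally `slope` (default 1). Required.
#' @param prolongation_threshold Fractional cAPD90 increase over vehicle
#'   that counts as prolongation (default 0.10).
#' @param triangulation_threshold Triangulation increase flagged as
#'   proarrhythmic in trace-based comparisons (default 0.1).
#' @param etpc_nM Estimated therapeutic plasma concentration (nM), used
#'   for the margin of safety.
#' @return An object of class `mps_ddi_config`.
#' @export
ddi_config <- function(drug = "cisapride", nominal_dose_nM = 50,
                       absorbed_fraction = 0.64, liver_duration_h = 8,
                       inhibitor_uM = 10, metabolism = NULL, hill = NULL,
                       prolongation_threshold = 0.10,
                       triangulation_threshold = 0.1,
                       etpc_nM = 2.6) {
  if (is.null(metabolism) || !inherits(metabolism, "mps_metab_params")) {
    stop("configuration error: `metabolism` must be a metabolism_params ",
         "object (e.g. mps_liver_kinetics()); kinetics are never defaulted ",
         "silently", call. = FALSE)
  }
  if (is.null(hill) || !all(c("ec50_nM", "emax") %in% names(hill))) {
    stop("configuration error: `hill` must be a list with ec50_nM and emax",
         call. = FALSE)
  }
  if (is.null(hill$slope)) hill$slope <- 1
  if (nominal_dose_nM < 0 || prolongation_threshold <= 0 ||
      triangulation_threshold <= 0) {
    stop("doses must be >= 0 and thresholds > 0", call. = FALSE)
  }
  structure(list(
    drug = drug, nominal_dose_nM = nominal_dose_nM,
    absorbed_fraction = absorbed_fraction,
    liver_duration_h = liver_duration_h, inhibitor_uM = inhibitor_uM,
    metabolism = metabolism, hill = hill,
    prolongation_threshold = prolongation_threshold,
    triangulation_threshold = triangulation_threshold,
    etpc_nM = etpc_nM
  ), class = "mps_ddi_config")
}

# normalized cAPD90 predicted at an effective cardiac dose
.hill_response <- function(dose_nM, hill) {
  occ <- ifelse(dose_nM > 0,
                1 / (1 + 10^(hill$slope *
                               (log10(hill$ec50_nM) - log10(dose_nM)))),
                0)
  1 + (hill$emax - 1) * occ
}

#' Run the in-silico drug-drug interaction experiment
#'
#' Evaluates the three arms of the functional-coupling study:
#' \describe{
#'   \item{direct}{the PDMS-corrected dose applied straight to the cardiac
#'     stage;}
#'   \item{liver}{the same dose first passed through the liver stage
#'     without inhibitor;}
#'   \item{liver+inhibitor}{the liver stage with the CYP inhibitor
#'     present.}
#' }
#' Each arm's effective cardiac dose is mapped through the configured Hill
#' curve to a predicted normalized cAPD90; an arm is flagged as prolonging
#' when the predicted increase over vehicle exceeds the configured
#' threshold. The report records the provenance of every parameter.
#'
#' @param config An [ddi_config()] object.
#' @return An object of class `mps_ddi_report`: a list with `arms` (tibble:
#'   arm, effective dose, predicted normalized cAPD90, prolongation flag),
#'   `margin_of_safety`, and `provenance`.
#' @examples
#' cfg <- ddi_config(metabolism = mps_liver_kinetics(),
#'                   hill = list(ec50_nM = 9.63, emax = 1.5))
#' run_ddi(cfg)
#' @export
run_ddi <- function(config) {
  stopifnot(inherits(config, "mps_ddi_config"))
  d_eff <- effective_dose(config$nominal_dose_nM, config$absorbed_fraction)
  arm_b <- liver_stage(d_eff, config$liver_duration_h, config$metabolism,
                       inhibitor_uM = 0)
  arm_c <- liver_stage(d_eff, config$liver_duration_h, config$metabolism,
                       inhibitor_uM = config$inhibitor_uM)
  doses <- c(direct = d_eff, liver = arm_b$parent_nM,
             `liver+inhibitor` = arm_c$parent_nM)
  pred <- .hill_response(doses, config$hill)
  arms <- tibble::tibble(
    arm = names(doses),
    effective_dose_nM = unname(doses),
    predicted_capd90_ratio = unname(pred),
    prolongation = unname(pred - 1 > config$prolongation_threshold)
  )
  structure(list(
    arms = arms,
    margin_of_safety = margin_of_safety(config$hill$ec50_nM, config$etpc_nM),
    provenance = list(
      absorbed_fraction = "PDMS absorption constant (dose-response figures)",
      metabolism = config$metabolism,
      hill = config$hill,
      thresholds = c(prolongation = config$prolongation_threshold,
                     triangulation = config$triangulation_threshold)
    ),
    config = config
  ), class = "mps_ddi_report")
}

#' @export
print.mps_ddi_report <- function(x, ...) {
  cat("In-silico liver-heart DDI report\n")
  print(x$arms)
  cat(sprintf("Margin of safety (EC50/ETPC): %.2f-fold\n",
              x$margin_of_safety))
  invisible(x)
}

#' Compare treated and vehicle beat metrics
#'
#' Ratio of median cAPD90 between a treated and a vehicle recording (the
#' per-device normalization used for coupled-experiment readouts), with a
#' standard two-sample Welch t-test for significance.
#'
#' @param treated,vehicle Beat-metric tables from [beat_metrics()] (or any
#'   data frame with a `capd90` column), at least 3 beats each.
#' @return A list with `capd90_ratio`, `p_value`, `n_treated`,
#'   `n_vehicle`.
#' @export
compare_to_vehicle <- function(treated, vehicle) {
  for (nm in c("treated", "vehicle")) {
    x <- get(nm)
    if (!is.data.frame(x) || !"capd90" %in% names(x) ||
        sum(is.finite(x$capd90)) < 3) {
      stop(nm, " must provide >= 3 finite cAPD90 values", call. = FALSE)
    }
  }
  tv <- treated$capd90[is.finite(treated$capd90)]
  vv <- vehicle$capd90[is.finite(vehicle$capd90)]
  p <- if (stats::sd(tv) == 0 && stats::sd(vv) == 0) {
    if (stats::median(tv) == stats::median(vv)) 1 else 0
  } else {
    stats::t.test(tv, vv)$p.value
  }
  list(capd90_ratio = stats::median(tv) / stats::median(vv),
       p_value = p, n_treated = length(tv), n_vehicle = length(vv))
}
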