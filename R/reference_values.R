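#' Reported wet-lab reference measurements
#'
#' The small set of headline measurements from the liver-heart MPS
#' characterization that the package uses for calibration and consistency
#' checks: hepatocyte synthetic function in the device versus conventional
#' 2-D culture, CYP3A4 activity with and without ketoconazole, the cardiac
#' cisapride potency, and the hepatocyte oxygen consumption rate.
#'
#' @return A named list:
#' \describe{
#'   \item{albumin_ug_per_1e6_per_day}{c(mps = 41.41, dish2d = 12.47)}
#'   \item{urea_ug_per_1e6_per_day}{c(mps = 49.75, dish2d = 7.37)}
#'   \item{cyp3a4_rlu}{c(control = 2640, ketoconazole = 361) — relative
#'     luminescence units of the CYP3A4 activity assay in the liver MPS}
#'   \item{ec50_nM}{9.63 — cisapride cAPD80 potency in the cardiac MPS}
#'   \item{etpc_nM}{c(2.6, 4.9) — estimated therapeutic plasma
#'     concentration range of cisapride}
#'   \item{ocr_nmol_s_per_1e6}{0.1 — measured hepatocyte oxygen
#'     consumption rate}
#' }
#' @export
mps_reference_values <- function() {
  list(
    albumin_ug_per_1e6_per_day = c(mps = 41.41, dish2d = 12.47),
    urea_ug_per_1e6_per_day = c(mps = 49.75, dish2d = 7.37),
    cyp3a4_rlu = c(control = 2640, ketoconazole = 361),
    ec50_nM = 9.63,
    etpc_nM = c(2.6, 4.9),
    ocr_nmol_s_per_1e6 = 0.1
  )
}
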