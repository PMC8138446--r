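#' Liver MPS device geometry
#'
#' Constructs the geometric description of the membrane-bilayer liver chip:
#' a rectangular cell chamber and a media channel of equal footprint, stacked
#' and separated by an isoporous polymer membrane, the whole device cast in a
#' gas-permeable PDMS slab. Defaults are the as-fabricated dimensions of the
#' device (5,560 um x 560 um footprint; 100 um chamber and channel heights;
#' 15 um membrane with 5.6 % porosity and 3 um pores; 3.5 mm PDMS slab).
#'
#' @param chamber_length_um Footprint length of both chambers (um).
#' @param chamber_width_um Footprint width of both chambers (um).
#' @param cell_chamber_height_um Height of the cell chamber (um).
#' @param media_channel_height_um Height of the media channel (um).
#' @param membrane_thickness_um Membrane thickness (um).
#' @param membrane_porosity Open-area fraction of the membrane, in (0, 1).
#' @param membrane_pore_diameter_um Mean membrane pore diameter (um).
#' @param pdms_slab_thickness_mm Thickness of the PDMS slab above the media
#'   channel (mm).
#' @return An object of class `mps_geometry` (a named list, all lengths in
#'   the stated units).
#' @examples
#' geo <- device_geometry()
#' chamber_volume(geo, "cell")
#' @export
device_geometry <- function(chamber_length_um = 5560,
                            chamber_width_um = 560,
                            cell_chamber_height_um = 100,
                            media_channel_height_um = 100,
                            membrane_thickness_um = 15,
                            membrane_porosity = 0.056,
                            membrane_pore_diameter_um = 3,
                            pdms_slab_thickness_mm = 3.5) {
  geo <- list(
    chamber_length_um = chamber_length_um,
    chamber_width_um = chamber_width_um,
    cell_chamber_height_um = cell_chamber_height_um,
    media_channel_height_um = media_channel_height_um,
    membrane_thickness_um = membrane_thickness_um,
    membrane_porosity = membrane_porosity,
    membrane_pore_diameter_um = membrane_pore_diameter_um,
    pdms_slab_thickness_mm = pdms_slab_thickness_mm
  )
  lengths <- geo[grepl("_um$|_mm$", names(geo))]
  if (any(!vapply(lengths, is.numeric, logical(1))) ||
      any(unlist(lengths) <= 0) || any(!is.finite(unlist(lengths)))) {
    stop("invalid geometry: all lengths must be finite and > 0", call. = FALSE)
  }
  if (!is.numeric(membrane_porosity) || membrane_porosity <= 0 ||
      membrane_porosity >= 1) {
    stop("invalid geometry: membrane_porosity must lie in (0, 1)", call. = FALSE)
  }
  structure(geo, class = "mps_geometry")
}

#' Transport and uptake parameters of the liver MPS
#'
#' Physical constants used by the hydraulics and transport solver. Defaults
#' are the values used for the device's design simulations: 20 uL/h media
#' flow; O2 diffusivity 3.0e-9 m^2/s in media and 3.25e-9 m^2/s in PDMS;
#' generic small-molecule diffusivity 1.0e-9 m^2/s; inlet O2 0.173 mol/m^3
#' (medium saturated against incubator air, 18.7 % O2); PDMS O2 saturation
#' 1.11 mM; Michaelis-Menten uptake with VO2max = 1.04e-16 mol/s/cell,
#' Km = 5.6 mmHg, cellular O2 solubility 1.049 mM/atm, and a cell density of
#' 6.44e13 cells/m^3 (about 9,812 cells per chip).
#'
#' @param flow_rate_ul_per_h Media flow rate Q (uL/h).
#' @param fluid_density_kg_m3 Media density (kg/m^3).
#' @param dynamic_viscosity_mPa_s Media dynamic viscosity at 37 C (mPa s).
#' @param D_O2_media_m2_s O2 diffusivity in culture media (m^2/s).
#' @param D_O2_pdms_m2_s O2 diffusivity in PDMS (m^2/s).
#' @param D_small_molecule_m2_s diffusivity of a generic small molecule in
#'   media (m^2/s).
#' @param c_inlet_O2_mol_m3 inlet / air-saturated media O2 (mol/m^3).
#' @param c_sat_pdms_mM O2 saturation concentration in PDMS (mM).
#' @param VO2max_mol_s_cell maximal per-cell O2 consumption (mol/s/cell).
#' @param Km_mmHg Michaelis constant as an O2 partial pressure (mmHg).
#' @param S_cell_mM_atm O2 solubility in cells (mM per atm O2).
#' @param rho_cell_per_m3 cell density in the cell chamber (cells/m^3).
#' @param n_cells cell count per chip.
#' @param ambient_O2_fraction O2 fraction of humidified incubator gas.
#' @return An object of class `mps_transport_params`.
#' @export
transport_params <- function(flow_rate_ul_per_h = 20,
                             fluid_density_kg_m3 = 1000,
                             dynamic_viscosity_mPa_s = 0.78,
                             D_O2_media_m2_s = 3.0e-9,
                             D_O2_pdms_m2_s = 3.25e-9,
                             D_small_molecule_m2_s = 1.0e-9,
                             c_inlet_O2_mol_m3 = 0.173,
                             c_sat_pdms_mM = 1.11,
                             VO2max_mol_s_cell = 1.04e-16,
                             Km_mmHg = 5.6,
                             S_cell_mM_atm = 1.049,
                             rho_cell_per_m3 = 6.44e13,
                             n_cells = 9812,
                             ambient_O2_fraction = 0.187) {
  par <- list(
    flow_rate_ul_per_h = flow_rate_ul_per_h,
    fluid_density_kg_m3 = fluid_density_kg_m3,
    dynamic_viscosity_mPa_s = dynamic_viscosity_mPa_s,
    D_O2_media_m2_s = D_O2_media_m2_s,
    D_O2_pdms_m2_s = D_O2_pdms_m2_s,
    D_small_molecule_m2_s = D_small_molecule_m2_s,
    c_inlet_O2_mol_m3 = c_inlet_O2_mol_m3,
    c_sat_pdms_mM = c_sat_pdms_mM,
    VO2max_mol_s_cell = VO2max_mol_s_cell,
    Km_mmHg = Km_mmHg,
    S_cell_mM_atm = S_cell_mM_atm,
    rho_cell_per_m3 = rho_cell_per_m3,
    n_cells = n_cells,
    ambient_O2_fraction = ambient_O2_fraction
  )
  v <- unlist(par)
  # Q = 0 (stopped flow) is a legitimate state; everything else must be > 0
  if (any(!is.finite(v)) || any(v[names(v) != "flow_rate_ul_per_h"] <= 0) ||
      flow_rate_ul_per_h < 0) {
    stop("invalid transport parameters: values must be finite and positive ",
         "(flow rate may be zero)", call. = FALSE)
  }
  structure(par, class = "mps_transport_params")
}

# -- internal SI conversions ------------------------------------------------
# printed mixed units (uL/h, um, mmHg, mM/atm) are converted on ingest;
# everything downstream is m, s, mol/m^3.

.q_m3_s <- function(params) params$flow_rate_ul_per_h * 1e-9 / 3600

.geo_m <- function(geometry) {
  list(
    L = geometry$chamber_length_um * 1e-6,
    W = geometry$chamber_width_um * 1e-6,
    h_cell = geometry$cell_chamber_height_um * 1e-6,
    h_media = geometry$media_channel_height_um * 1e-6,
    h_mem = geometry$membrane_thickness_um * 1e-6,
    h_pdms = geometry$pdms_slab_thickness_mm * 1e-3
  )
}

#' Read a device configuration file
#'
#' Reads a flat key-value (DCF) parameter file whose keys carry their units
#' in the name (e.g. `flow_rate_ul_per_h`) and splits the entries into a
#' geometry and a transport-parameter object. The bundled default file
#' reproduces every as-designed value.
#'
#' @param path Path to a DCF file; defaults to the bundled
#'   `liver_chip_defaults.dcf`.
#' @return A list with `geometry` ([device_geometry()]) and `params`
#'   ([transport_params()]).
#' @export
read_device_config <- function(path = system.file("extdata",
                                                  "liver_chip_defaults.dcf",
                                                  package = "mpsddi")) {
  raw <- read.dcf(path)[1, ]
  vals <- as.list(as.numeric(raw))
  names(vals) <- names(raw)
  geo_args <- intersect(names(vals), names(formals(device_geometry)))
  par_args <- intersect(names(vals), names(formals(transport_params)))
  unknown <- setdiff(names(vals), c(geo_args, par_args))
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  list(geometry = do.call(device_geometry, vals[geo_args]),
       params = do.call(transport_params, vals[par_args]))
}

#' Michaelis constant in concentration units
#'
#' The uptake law is written with the Michaelis constant as a partial
#' pressure (Km, mmHg) multiplied by the cellular O2 solubility
#' (S_cell, mM/atm). This returns the product Km * S_cell converted to
#' mol/m^3 (760 mmHg = 1 atm; 1 mM = 1 mol/m^3), i.e. the half-saturation
#' concentration of the Michaelis-Menten sink.
#'
#' @param params An `mps_transport_params` object.
#' @return Half-saturation O2 concentration (mol/m^3). Defaults give
#'   5.6 * 1.049 / 760 = 7.73e-3 mol/m^3.
#' @export
km_in_concentration_units <- function(params) {
  params$Km_mmHg * params$S_cell_mM_atm / 760
}

#' Analytic hydraulics of the media channel
#'
#' Plane-Poiseuille reduction of the channel flow: at the device's Reynolds
#' number (<< 1) the media channel carries fully developed laminar flow, so
#' mean velocity, wall shear stress and residence time follow in closed form
#' and no numerical flow solve is needed. Flow across the low-porosity
#' membrane and within the cell chamber is neglected (transport there is
#' diffusive).
#'
#' @param geometry An `mps_geometry` object.
#' @param params An `mps_transport_params` object.
#' @param D_m2_s Diffusivity used for the Peclet number (m^2/s); defaults to
#'   the O2 diffusivity in media.
#' @return An object of class `mps_hydraulics` with fields
#'   `mean_velocity_m_s`, `wall_shear_dyn_cm2` (6 mu Q / (w h^2)),
#'   `residence_time_s` (`Inf` with `no_flow = TRUE` when Q = 0), and
#'   `peclet`.
#' @examples
#' channel_hydraulics(device_geometry(), transport_params())
#' @export
channel_hydraulics <- function(geometry, params,
                               D_m2_s = params$D_O2_media_m2_s) {
  stopifnot(inherits(geometry, "mps_geometry"),
            inherits(params, "mps_transport_params"))
  g <- .geo_m(geometry)
  Q <- .q_m3_s(params)
  mu <- params$dynamic_viscosity_mPa_s * 1e-3 # Pa s
  v_mean <- Q / (g$W * g$h_media)
  shear_pa <- 6 * mu * Q / (g$W * g$h_media^2)
  structure(list(
    mean_velocity_m_s = v_mean,
    wall_shear_dyn_cm2 = shear_pa * 10, # 1 Pa = 10 dyn/cm^2
    residence_time_s = if (v_mean > 0) g$L / v_mean else Inf,
    peclet = v_mean * g$h_media / D_m2_s,
    no_flow = v_mean == 0
  ), class = "mps_hydraulics")
}

#' @export
print.mps_hydraulics <- function(x, ...) {
  cat("Media channel hydraulics (plane Poiseuille)\n")
  cat(sprintf("  mean velocity   : %.3g m/s\n", x$mean_velocity_m_s))
  cat(sprintf("  wall shear      : %.3g dyn/cm^2\n", x$wall_shear_dyn_cm2))
  cat(sprintf("  residence time  : %.3g s%s\n", x$residence_time_s,
              if (x$no_flow) " (no flow)" else ""))
  cat(sprintf("  Peclet number   : %.3g\n", x$peclet))
  invisible(x)
}

#' Chamber volume
#'
#' Volume of the selected chamber, `length * width * height`, in uL. The
#' default dimensions give 0.311 uL for either chamber, consistent with the
#' nominal 0.32 uL media-channel fill volume to within rounding.
#'
#' @param geometry An `mps_geometry` object.
#' @param which `"cell"` or `"media"`.
#' @return Volume in uL.
#' @export
chamber_volume <- function(geometry, which = c("cell", "media")) {
  stopifnot(inherits(geometry, "mps_geometry"))
  which <- match.arg(which)
  h <- switch(which,
              cell = geometry$cell_chamber_height_um,
              media = geometry$media_channel_height_um)
  geometry$chamber_length_um * geometry$chamber_width_um * h / 1e9
}

#' Per-cell oxygen consumption scaled to a standard cell count
#'
#' Converts the maximal per-cell uptake VO2max into the oxygen consumption
#' rate (OCR) conventionally reported per 10^6 cells, in nmol/s.
#'
#' @param params An `mps_transport_params` object.
#' @return OCR in nmol/s per 10^6 cells (defaults give 0.104).
#' @export
ocr_per_million_cells <- function(params) {
  params$VO2max_mol_s_cell * 1e6 * 1e9
}
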