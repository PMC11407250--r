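# Tissue optical properties: absorption from chromophore content, power-law
# reduced scattering, and per-element property fields at a cardiac phase.
#
# Conventions: mu_a and mu_s' in cm^-1, wavelengths in nm, hemoglobin
# concentrations in uM, extinction coefficients in cm^-1 uM^-1 (decadic,
# ln 10 folded in). The scattering reference wavelength is 500 nm.

.LAMBDA0 <- 500

.fetalnirs_env <- new.env(parent = emptyenv())

#' Load the embedded chromophore table
#'
#' A 1-nm table over 700-900 nm of hemoglobin extinction coefficients
#' (cm^-1 uM^-1) and water/fat/melanin absorption (cm^-1), shipped in
#' `inst/extdata/chromophores.csv`. Cached after first load.
#'
#' @param path optional path to an alternative table with the same columns.
#' @return data frame with columns `wavelength_nm`, `eps_HbO`, `eps_Hb`,
#'   `mua_water`, `mua_fat`, `mua_melanin`.
#' @export
load_chromophores <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.fetalnirs_env$chromophores)) return(.fetalnirs_env$chromophores)
    path <- system.file("extdata", "chromophores.csv", package = "fetalnirs")
    tab <- utils::read.csv(path, comment.char = "#")
    .fetalnirs_env$chromophores <- tab
    return(tab)
  }
  utils::read.csv(path, comment.char = "#")
}

# Linear interpolation lookup; errors rather than extrapolates.
chromophores_at <- function(lambda, table = load_chromophores()) {
  rng <- range(table$wavelength_nm)
  if (any(lambda < rng[1] | lambda > rng[2]))
    stop(sprintf("wavelength %s nm outside table range [%g, %g]",
                 paste(lambda, collapse = ", "), rng[1], rng[2]))
  look <- function(col) stats::approx(table$wavelength_nm, table[[col]],
                                      xout = lambda, rule = 1)$y
  list(eps_HbO = look("eps_HbO"), eps_Hb = look("eps_Hb"),
       mua_water = look("mua_water"), mua_fat = look("mua_fat"),
       mua_melanin = look("mua_melanin"))
}

#' Default tissue parameter database
#'
#' Hemoglobin content, saturations, water/fat fractions, scattering power-law
#' coefficients and refractive indices for the seven phantom tissues.
#' Maternal tissues carry a single tissue saturation `StO2` and are never
#' pulsed; fetal tissues carry arterial/venous saturations (`SaO2`, `SvO2`)
#' split 25%/75% (`Va`/`Vv`) with a 5% systolic arterial volume increase
#' (`Vp`) applied to brain and scalp muscle only. Amniotic fluid and CSF are
#' water-like: mu_a of water, mu_s' = 0.1 cm^-1, n = 1.33.
#'
#' @return Named list keyed by [tissue_labels()].
#' @export
default_tissue_params <- function() {
  list(
    maternal_fat = list(kind = "maternal", HbT = 12.2, StO2 = 0.75,
                        Vwater = 0.23, Vfat = 0.72, Vmelanin = 0,
                        a = 9.69, b = 0.81, n = 1.4),
    maternal_muscle_uterus = list(kind = "maternal", HbT = 26.2, StO2 = 0.75,
                                  Vwater = 0.76, Vfat = 0, Vmelanin = 0,
                                  a = 15.42, b = 0.89, n = 1.4),
    amniotic_fluid = list(kind = "fluid", a = 0.1, n = 1.33),
    fetal_muscle = list(kind = "fetal", HbT = 33.5, SaO2 = 0.50, SvO2 = 0.40,
                        Va = 0.25, Vv = 0.75, Vp = 0.05, pulsatile = TRUE,
                        Vwater = 0.76, Vfat = 0, Vmelanin = 0,
                        a = 15.42, b = 0.89, n = 1.3),
    fetal_skull_spinal = list(kind = "fetal", HbT = 39.7, SaO2 = 0.50, SvO2 = 0.40,
                              Va = 0.25, Vv = 0.75, Vp = 0.05, pulsatile = FALSE,
                              Vwater = 0.16, Vfat = 0, Vmelanin = 0,
                              a = 22.90, b = 0.72, n = 1.3),
    fetal_csf = list(kind = "fluid", a = 0.1, n = 1.33),
    fetal_brain = list(kind = "fetal", HbT = 39.7, SaO2 = 0.50, SvO2 = 0.40,
                       Va = 0.25, Vv = 0.75, Vp = 0.05, pulsatile = TRUE,
                       Vwater = 0.76, Vfat = 0, Vmelanin = 0,
                       a = 22.52, b = 1.56, n = 1.3)
  )
}

#' Static tissue absorption coefficient
#'
#' `mu_a = HbT*StO2*eps_HbO + HbT*(1-StO2)*eps_Hb + Vwater*mua_water +
#' Vfat*mua_fat + Vmelanin*mua_melanin`, linear in the hemoglobin
#' concentration and each background volume fraction.
#'
#' @param params list with `HbT` (uM), `StO2`, `Vwater`, `Vfat`, `Vmelanin`.
#' @param lambda wavelength in nm (scalar or vector).
#' @param table chromophore table (see [load_chromophores()]).
#' @return mu_a in cm^-1.
#' @export
mua_static <- function(params, lambda, table = load_chromophores()) {
  ch <- chromophores_at(lambda, table)
  params$HbT * params$StO2 * ch$eps_HbO +
    params$HbT * (1 - params$StO2) * ch$eps_Hb +
    params$Vwater * ch$mua_water + params$Vfat * ch$mua_fat +
    params$Vmelanin * ch$mua_melanin
}

#' Pulsatile (fetal) tissue absorption coefficient
#'
#' Splits total hemoglobin into arterial and venous compartments
#' (`[HbO]a = HbT*Va*SaO2` etc.); at systole the arterial compartment is
#' scaled by `1 + Vp` to model the cardiac volume pulse, so
#' `mu_a,systole - mu_a,diastole = Vp*([HbO]a*eps_HbO + [Hb]a*eps_Hb) >= 0`.
#'
#' @param params list with `HbT`, `SaO2`, `SvO2`, `Va`, `Vv`, `Vp` and
#'   background fractions `Vwater`, `Vfat`, `Vmelanin`.
#' @param lambda wavelength in nm.
#' @param phase `"diastole"` or `"systole"`.
#' @param table chromophore table.
#' @return mu_a in cm^-1.
#' @export
mua_pulsatile <- function(params, lambda, phase = c("diastole", "systole"),
                          table = load_chromophores()) {
  phase <- match.arg(phase)
  req <- c("HbT", "SaO2", "SvO2", "Va", "Vv")
  miss <- req[!vapply(req, function(f) !is.null(params[[f]]), logical(1))]
  if (length(miss)) stop("missing fetal parameters: ", paste(miss, collapse = ", "))
  ch <- chromophores_at(lambda, table)
  hbo_a <- params$HbT * params$Va * params$SaO2
  hb_a <- params$HbT * params$Va * (1 - params$SaO2)
  hbo_v <- params$HbT * params$Vv * params$SvO2
  hb_v <- params$HbT * params$Vv * (1 - params$SvO2)
  gain <- if (phase == "systole") 1 + (params$Vp %||% 0) else 1
  (hbo_a * gain + hbo_v) * ch$eps_HbO + (hb_a * gain + hb_v) * ch$eps_Hb +
    params$Vwater * ch$mua_water + params$Vfat * ch$mua_fat +
    params$Vmelanin * ch$mua_melanin
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Power-law reduced scattering
#'
#' `mu_s'(lambda) = a * (lambda/500)^(-b)` with `a` the reduced scattering at
#' the 500 nm reference wavelength and `b` the scattering power.
#'
#' @param a mu_s' at 500 nm, cm^-1 (> 0).
#' @param b scattering power (dimensionless).
#' @param lambda wavelength in nm.
#' @return mu_s' in cm^-1.
#' @export
musp_power_law <- function(a, b, lambda) {
  if (any(a <= 0)) stop("scattering amplitude a must be positive")
  if (any(lambda <= 0)) stop("wavelength must be positive")
  a * (lambda / .LAMBDA0)^(-b)
}

#' Assign optical properties to every mesh element
#'
#' Fluids (amniotic fluid, CSF) get water absorption, mu_s' = 0.1 cm^-1 and
#' n = 1.33. Maternal tissues use the static absorption model; fetal brain and
#' muscle use the pulsatile model at the requested phase; fetal skull/spinal
#' uses the fetal compartment model but is never pulsed. Phase `"static"` is
#' an alias for the diastolic baseline.
#'
#' @param mesh a [tet_mesh()].
#' @param lambda wavelength in nm.
#' @param phase `"static"`, `"diastole"` or `"systole"`.
#' @param param_db tissue database, see [default_tissue_params()].
#' @param table chromophore table.
#' @return Object of class `property_field`: per-element `mua`, `musp`, `n`
#'   (cm^-1 / unitless) plus `kappa` = 1/(3(mua+musp)) in cm, `lambda`,
#'   `phase`.
#' @export
assign_properties <- function(mesh, lambda, phase = "static",
                              param_db = default_tissue_params(),
                              table = load_chromophores()) {
  phase <- match.arg(phase, c("static", "diastole", "systole"))
  eff_phase <- if (phase == "systole") "systole" else "diastole"
  labs <- unique(mesh$labels)
  mua_by <- musp_by <- n_by <- stats::setNames(numeric(length(labs)), labs)
  for (lab in labs) {
    p <- param_db[[lab]]
    if (is.null(p)) stop("no parameters for tissue label '", lab, "'")
    if (identical(p$kind, "fluid")) {
      mua_by[lab] <- chromophores_at(lambda, table)$mua_water
      musp_by[lab] <- p$a
      n_by[lab] <- p$n
    } else if (identical(p$kind, "maternal")) {
      mua_by[lab] <- mua_static(p, lambda, table)
      musp_by[lab] <- musp_power_law(p$a, p$b, lambda)
      n_by[lab] <- p$n
    } else {
      ph <- if (isTRUE(p$pulsatile)) eff_phase else "diastole"
      mua_by[lab] <- mua_pulsatile(p, lambda, ph, table)
      musp_by[lab] <- musp_power_law(p$a, p$b, lambda)
      n_by[lab] <- p$n
    }
  }
  property_field(mesh, mua = unname(mua_by[mesh$labels]),
                 musp = unname(musp_by[mesh$labels]),
                 n = unname(n_by[mesh$labels]),
                 lambda = lambda, phase = phase)
}

#' Construct a per-element property field
#'
#' @param mesh a [tet_mesh()].
#' @param mua,musp per-element (or scalar) absorption / reduced scattering in
#'   cm^-1.
#' @param n per-element (or scalar) refractive index.
#' @param lambda wavelength in nm (metadata).
#' @param phase cardiac phase tag (metadata).
#' @return `property_field` object.
#' @export
property_field <- function(mesh, mua, musp, n = 1.4, lambda = NA_real_,
                           phase = "static") {
  m <- nrow(mesh$elements)
  mua <- rep_len(mua, m); musp <- rep_len(musp, m); n <- rep_len(n, m)
  if (any(mua < 0)) stop("mu_a must be non-negative")
  if (any(musp <= 0)) stop("mu_s' must be positive")
  structure(list(mua = mua, musp = musp, n = n,
                 kappa = 1 / (3 * (mua + musp)),
                 lambda = lambda, phase = phase),
            class = "property_field")
}

#' Uniform property field (test/validation helper)
#'
#' @inheritParams property_field
#' @export
uniform_properties <- function(mesh, mua, musp, n = 1.4, lambda = NA_real_) {
  property_field(mesh, mua, musp, n, lambda)
}

#' Volume-weighted nodal absorption
#'
#' The forward solver's absorption term uses a P1 (nodal) interpolation of
#' mu_a; this is the canonical element-to-node conversion: the volume-weighted
#' mean of the values of the elements sharing each node.
#'
#' @param mesh a [tet_mesh()].
#' @param props a [property_field()].
#' @return numeric vector, nodal mu_a in cm^-1.
#' @export
nodal_mua <- function(mesh, props) {
  w <- rep(mesh$volumes / 4, 4L)
  num <- as.vector(rowsum(w * rep(props$mua, 4L), as.vector(mesh$elements)))
  num / mesh$node_volumes
}
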