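#' Kinetic parameter set for the chelatase model
#'
#' Bundles every enzyme-side constant used by the rate law and the progress
#' curve simulator. All values are SI (molar, seconds). The defaults encode
#' the Synechocystis enzyme: a turnover number of 1/75 s^-1, an uncatalyzed
#' dechelation constant of 3.17e-5 s^-1, and substrate half-saturation
#' constants whose product (Km_DIX * K05_Mg = 1.4e-8 M^2) pins the catalytic
#' proficiency at 3e16 M^-1; the individual split between the two constants
#' is a documented convention, not a measured pair.
#'
#' @param kcat_per_s Turnover number (s^-1).
#' @param Km_DIX_M Michaelis constant for the porphyrin substrate (M).
#' @param K05_Mg_M Half-saturation constant for free Mg2+ (M).
#' @param hill_Mg Hill coefficient for the Mg2+ saturation term (>= 1).
#' @param K05_ATP_M Half-saturation constant for MgATP2- (M).
#' @param n_ATP ATP hydrolyzed per Mg porphyrin formed (>= 1).
#' @param k_basal_ATPase_per_s Uncoupled (chelation-independent) ATPase
#'   turnover per ChlI (s^-1).
#' @param Ki_product_M Competitive product-inhibition constant (M);
#'   `Inf` disables inhibition (the default).
#' @param k_dechel_per_s First-order uncatalyzed dechelation constant (s^-1).
#' @param k_photolysis_per_s Optional first-order photolysis loss of the
#'   magnesium porphyrin, modeled as an extra MgD -> D channel; 0 by default
#'   (controls show photolysis is negligible in the dark-adapted assay).
#' @return An object of class `kinetic_params` (a validated named list).
#' @examples
#' p <- chela_params()
#' p$kcat_per_s * 75  # 1
#' @export
chela_params <- function(kcat_per_s = 1 / 75,
                         Km_DIX_M = 2.0e-6,
                         K05_Mg_M = 7.0e-3,
                         hill_Mg = 2,
                         K05_ATP_M = 1.0e-4,
                         n_ATP = 15,
                         k_basal_ATPase_per_s = 0.7,
                         Ki_product_M = Inf,
                         k_dechel_per_s = 3.17e-5,
                         k_photolysis_per_s = 0) {
  p <- list(
    kcat_per_s = kcat_per_s, Km_DIX_M = Km_DIX_M, K05_Mg_M = K05_Mg_M,
    hill_Mg = hill_Mg, K05_ATP_M = K05_ATP_M, n_ATP = n_ATP,
    k_basal_ATPase_per_s = k_basal_ATPase_per_s,
    Ki_product_M = Ki_product_M, k_dechel_per_s = k_dechel_per_s,
    k_photolysis_per_s = k_photolysis_per_s
  )
  validate_params(p)
  structure(p, class = "kinetic_params")
}

validate_params <- function(p) {
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    }
    if (nm != "Ki_product_M" && !is.finite(v)) {
      stop("parameter '", nm, "' must be finite", call. = FALSE)
    }
    if (v < 0) stop("parameter '", nm, "' must be >= 0", call. = FALSE)
  }
  if (p$n_ATP < 1) stop("n_ATP must be >= 1", call. = FALSE)
  if (p$hill_Mg < 1) stop("hill_Mg must be >= 1", call. = FALSE)
  invisible(p)
}

#' Gun4-activated parameter set
#'
#' Alternative [chela_params()] describing the chelatase in the presence of
#' the activator protein Gun4. Gun4 is represented purely as a parameter
#' change, not a mechanism: `kcat` is back-computed from the reported
#' 550e6 M rate enhancement (k_cat = 550e6 * k_uncat = 1.744e-2 s^-1) and
#' `Km_DIX` is rescaled so the catalytic proficiency is 3e17 M^-1, ten-fold
#' above the basal enzyme. Both numbers are calibrations, labeled as such.
#'
#' @param ... Overrides forwarded to [chela_params()].
#' @return A `kinetic_params` object.
#' @export
gun4_params <- function(...) {
  kcat <- 1.744e-2
  prof <- 3e17                       # target proficiency, M^-1
  k_uncat <- 1e-6 * 3.17e-5          # K_eq * k_dechel
  K05 <- 7.0e-3
  Km <- kcat / (prof * k_uncat) / K05
  chela_params(kcat_per_s = kcat, Km_DIX_M = Km, K05_Mg_M = K05, ...)
}

#' Assay conditions
#'
#' Concentrations and switches describing one chelatase assay. Defaults are
#' the base plate-reader conditions: 0.1 uM ChlI, 0.1 uM ChlD, 0.4 uM ChlH,
#' 8 uM deuteroporphyrin IX, 10 mM free Mg2+, 34 C, with a
#' phosphoenolpyruvate/pyruvate-kinase ATP-regeneration system holding a
#' 2 mM PEP pool.
#'
#' @param ChlI_M,ChlD_M,ChlH_M Subunit concentrations (M).
#' @param D_total_M Total porphyrin (free + chelated, M).
#' @param Mg_free_M Free Mg2+ (M); treated as clamped (buffered by the
#'   10 mM pool, never depleted by the ~uM porphyrin turnover).
#' @param ATP0_M Initial MgATP2- (M).
#' @param PEP0_M Phosphoenolpyruvate pool (M); `Inf` models an ideal,
#'   inexhaustible ATP clamp.
#' @param regeneration_on Logical; when `TRUE` and PEP remains, ATP is held
#'   at its initial value and the PEP pool is debited 1:1 for every ATP
#'   hydrolyzed.
#' @param temperature_K Assay temperature (K); default 307.15 (34 C).
#' @return An object of class `assay_conditions`.
#' @export
chela_conditions <- function(ChlI_M = 1e-7,
                             ChlD_M = 1e-7,
                             ChlH_M = 4e-7,
                             D_total_M = 8e-6,
                             Mg_free_M = 1e-2,
                             ATP0_M = 5e-4,
                             PEP0_M = 2e-3,
                             regeneration_on = TRUE,
                             temperature_K = 307.15) {
  cond <- list(
    ChlI_M = ChlI_M, ChlD_M = ChlD_M, ChlH_M = ChlH_M,
    D_total_M = D_total_M, Mg_free_M = Mg_free_M, ATP0_M = ATP0_M,
    PEP0_M = PEP0_M, regeneration_on = isTRUE(regeneration_on),
    temperature_K = temperature_K
  )
  num <- setdiff(names(cond), "regeneration_on")
  for (nm in num) {
    v <- cond[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0) {
      stop("condition '", nm, "' must be a single number >= 0", call. = FALSE)
    }
    if (nm != "PEP0_M" && !is.finite(v)) {
      stop("condition '", nm, "' must be finite", call. = FALSE)
    }
  }
  if (cond$temperature_K <= 0) stop("temperature_K must be > 0", call. = FALSE)
  structure(cond, class = "assay_conditions")
}

#' Thermodynamic context
#'
#' Equilibrium constant for the uncoupled chelation reaction
#' Mg2+ + D_IX <-> MgD_IX (association convention, units M^-1), the gas
#' constant and the temperature. The default K_eq of 1e-6 M^-1 makes the
#' uncatalyzed reaction strongly unfavorable.
#'
#' @param K_eq_per_M Association equilibrium constant (M^-1), > 0.
#' @param T_K Temperature (K), > 0.
#' @return An object of class `thermo_context`; the gas constant is fixed at
#'   8.314 J mol^-1 K^-1.
#' @export
thermo_context <- function(K_eq_per_M = 1e-6, T_K = 307.15) {
  if (!is.numeric(K_eq_per_M) || length(K_eq_per_M) != 1L ||
      is.na(K_eq_per_M) || K_eq_per_M <= 0) {
    stop("K_eq_per_M must be a single number > 0", call. = FALSE)
  }
  if (!is.numeric(T_K) || length(T_K) != 1L || is.na(T_K) || T_K <= 0) {
    stop("T_K must be a single number > 0", call. = FALSE)
  }
  structure(list(K_eq_per_M = K_eq_per_M, R_J_per_mol_K = 8.314, T_K = T_K),
            class = "thermo_context")
}

# Effective active-complex concentration: the assembled I/D/H complex cannot
# exceed the scarcest subunit.
enzyme_conc <- function(cond) {
  min(cond$ChlI_M, cond$ChlD_M, cond$ChlH_M)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.assay_conditions <- function(x, ...) {
  cat("<assay_conditions>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
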