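#' Catalytic rate enhancement
#'
#' Ratio of the enzyme's turnover number to the uncatalyzed second-order
#' chelation constant, k_cat / k_uncat. The result carries units of molarity
#' because the catalyzed reaction is first-order in enzyme-saturated turnover
#' while the uncatalyzed reaction is second-order.
#'
#' @param kcat_per_s Turnover number (s^-1, >= 0).
#' @param k_uncat_per_M_s Uncatalyzed second-order constant (M^-1 s^-1, > 0).
#' @return Rate enhancement in M.
#' @examples
#' rate_enhancement(1 / 75, 3.17e-11)  # ~4.2e8 M
#' @export
rate_enhancement <- function(kcat_per_s, k_uncat_per_M_s) {
  if (!is.numeric(k_uncat_per_M_s) || is.na(k_uncat_per_M_s) ||
      k_uncat_per_M_s <= 0) {
    stop("k_uncat must be > 0", call. = FALSE)
  }
  if (!is.numeric(kcat_per_s) || is.na(kcat_per_s) || kcat_per_s < 0) {
    stop("kcat must be >= 0", call. = FALSE)
  }
  kcat_per_s / k_uncat_per_M_s
}

#' Catalytic proficiency
#'
#' The second-order specificity constant of the enzyme, normalized by both
#' substrate half-saturation constants, over the uncatalyzed constant:
#' (k_cat / (K_m_DIX * K_0.5_Mg)) / k_uncat. This is the factor by which the
#' enzyme stabilizes the transition state relative to the uncatalyzed
#' bimolecular reaction; its reciprocal is the transition-state dissociation
#' constant.
#'
#' @param kcat_per_s Turnover number (s^-1, > 0).
#' @param Km_DIX_M Porphyrin Michaelis constant (M, > 0).
#' @param K05_Mg_M Magnesium half-saturation constant (M, > 0).
#' @param k_uncat_per_M_s Uncatalyzed second-order constant (M^-1 s^-1, > 0).
#' @return Proficiency in M^-1.
#' @examples
#' catalytic_proficiency(1 / 75, 2e-6, 7e-3, 3.17e-11)  # ~3e16 M^-1
#' @export
catalytic_proficiency <- function(kcat_per_s, Km_DIX_M, K05_Mg_M,
                                  k_uncat_per_M_s) {
  vals <- c(kcat_per_s, Km_DIX_M, K05_Mg_M, k_uncat_per_M_s)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all inputs must be finite and > 0", call. = FALSE)
  }
  (kcat_per_s / (Km_DIX_M * K05_Mg_M)) / k_uncat_per_M_s
}

#' Transition-state dissociation constant
#'
#' Reciprocal of the catalytic proficiency: the formal dissociation constant
#' of the enzyme-transition-state complex, K_TX. For magnesium chelatase this
#' lands in the attomolar decade band.
#'
#' @param proficiency_per_M Catalytic proficiency (M^-1, > 0).
#' @return K_TX in M.
#' @export
transition_state_kd <- function(proficiency_per_M) {
  if (!is.numeric(proficiency_per_M) || is.na(proficiency_per_M) ||
      proficiency_per_M <= 0) {
    stop("proficiency must be > 0", call. = FALSE)
  }
  1 / proficiency_per_M
}

#' Standard free energy of uncatalyzed chelation
#'
#' Delta-G-standard-prime = -R T ln(K_eq * c0) with standard state c0 = 1 M,
#' reported in kJ mol^-1. Positive for the chelatase reaction (the uncoupled
#' chelation is thermodynamically unfavorable).
#'
#' @param thermo A [thermo_context()].
#' @return Standard free energy in kJ mol^-1.
#' @examples
#' standard_free_energy(thermo_context(1e-6, 307.15))  # ~ +35.3
#' @export
standard_free_energy <- function(thermo) {
  stopifnot(inherits(thermo, "thermo_context"))
  -thermo$R_J_per_mol_K * thermo$T_K * log(thermo$K_eq_per_M * 1) / 1000
}

#' Free energy of displacement from equilibrium
#'
#' R T ln(ratio / K_eq): the free-energy distance between the ATP-maintained
#' steady-state product:substrate ratio, \[MgD\]/(\[D\]\[Mg2+\]), and the
#' equilibrium constant of the uncoupled reaction.
#'
#' @param ratio_over_Mg_per_M Steady-state MgD/(D*Mg) ratio (M^-1, > 0).
#' @param thermo A [thermo_context()].
#' @return Displacement free energy in kJ mol^-1.
#' @examples
#' displacement_free_energy(1e2, thermo_context(1e-6, 307.15))  # ~47
#' @export
displacement_free_energy <- function(ratio_over_Mg_per_M, thermo) {
  stopifnot(inherits(thermo, "thermo_context"))
  if (!is.numeric(ratio_over_Mg_per_M) || is.na(ratio_over_Mg_per_M) ||
      ratio_over_Mg_per_M <= 0) {
    stop("ratio_over_Mg must be > 0", call. = FALSE)
  }
  thermo$R_J_per_mol_K * thermo$T_K *
    log(ratio_over_Mg_per_M / thermo$K_eq_per_M) / 1000
}

#' Full catalytic-power report
#'
#' Assembles every derived catalytic-power quantity from a kinetic parameter
#' set and a thermodynamic context: the uncatalyzed second-order constant,
#' rate enhancement, catalytic proficiency, transition-state dissociation
#' constant, the pseudo-first-order half-life of the uncatalyzed reaction at
#' a reference Mg2+ concentration, the standard free energy, and — when assay
#' conditions are supplied — the steady-state displacement factor and free
#' energy. Values are stored at full precision; the print method renders them
#' at `sig_figs` significant figures (default 1, the "circa" reporting style
#' used for order-of-magnitude quantities). Rendering never alters the stored
#' values.
#'
#' @param params A [chela_params()] object.
#' @param thermo A [thermo_context()].
#' @param mg_ref_M Reference free Mg2+ for the uncatalyzed half-life (M);
#'   default 1e-3.
#' @param cond Optional [chela_conditions()]; when given, the ATP-clamped
#'   steady state is solved and the displacement quantities filled in.
#' @param sig_figs Significant figures for the rendered report (default 1).
#' @return An object of class `derived_power`.
#' @examples
#' power_report(chela_params(), thermo_context())
#' @export
power_report <- function(params, thermo, mg_ref_M = 1e-3, cond = NULL,
                         sig_figs = 1) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(thermo, "thermo_context"))
  k_uncat <- chelation_second_order_constant(thermo$K_eq_per_M,
                                             params$k_dechel_per_s)
  prof <- catalytic_proficiency(params$kcat_per_s, params$Km_DIX_M,
                                params$K05_Mg_M, k_uncat)
  halflife <- pseudo_first_order_halflife(k_uncat, mg_ref_M)
  disp_factor <- NA_real_
  dG_disp <- NA_real_
  ss <- NULL
  if (!is.null(cond)) {
    ss <- find_steady_state(params, cond)
    if (is.finite(ss$ratio_over_Mg_per_M) && ss$ratio_over_Mg_per_M > 0) {
      disp_factor <- displacement_factor(ss, thermo)
      dG_disp <- displacement_free_energy(ss$ratio_over_Mg_per_M, thermo)
    }
  }
  rep <- list(
    k_uncat_per_M_s = k_uncat,
    rate_enhancement_M = rate_enhancement(params$kcat_per_s, k_uncat),
    proficiency_per_M = prof,
    K_TX_M = transition_state_kd(prof),
    halflife_s = halflife,
    halflife_yr = seconds_to_years(halflife),
    mg_ref_M = mg_ref_M,
    dG_standard_kJ_per_mol = standard_free_energy(thermo),
    displacement_factor = disp_factor,
    dG_displacement_kJ_per_mol = dG_disp,
    steady_state = ss,
    sig_figs = sig_figs
  )
  rep$rendered <- render_power(rep, sig_figs)
  structure(rep, class = "derived_power")
}

render_power <- function(rep, sig_figs) {
  num <- c("k_uncat_per_M_s", "rate_enhancement_M", "proficiency_per_M",
           "K_TX_M", "halflife_s", "halflife_yr", "dG_standard_kJ_per_mol",
           "displacement_factor", "dG_displacement_kJ_per_mol")
  out <- lapply(rep[num], function(v) {
    if (is.na(v)) NA_character_ else format(signif(v, sig_figs))
  })
  names(out) <- num
  out
}

#' @export
print.derived_power <- function(x, ...) {
  r <- x$rendered
  cat("Catalytic power report (rendered at", x$sig_figs, "sig. fig.)\n")
  cat("  k_uncat          ", r$k_uncat_per_M_s, "M^-1 s^-1\n")
  cat("  rate enhancement ", r$rate_enhancement_M, "M\n")
  cat("  proficiency      ", r$proficiency_per_M, "M^-1\n")
  cat("  K_TX             ", r$K_TX_M, "M\n")
  cat(sprintf("  t1/2 (at %g M Mg) %s yr\n", x$mg_ref_M, r$halflife_yr))
  cat("  dG standard      ", r$dG_standard_kJ_per_mol, "kJ/mol\n")
  if (!is.na(x$displacement_factor)) {
    cat("  displacement     ", r$displacement_factor, "fold,",
        r$dG_displacement_kJ_per_mol, "kJ/mol\n")
  }
  invisible(x)
}
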