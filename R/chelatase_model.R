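#' Chelation velocity
#'
#' Saturation-kinetics rate law for ATP-coupled magnesium insertion:
#' independent saturating factors in porphyrin (Michaelis), Mg2+ (Hill,
#' cooperative metal activation) and MgATP2- (Michaelis), an optional
#' competitive product-inhibition factor, and an active-complex concentration
#' equal to the scarcest subunit:
#'
#' v = kcat * E0 * D/(Km + D) * Mg^h/(K05^h + Mg^h) * ATP/(K05ATP + ATP)
#'     * 1/(1 + MgD/Ki)
#'
#' The separable form is the simplest rate law consistent with treating
#' Km_DIX and K05_Mg as independent factors in the catalytic-proficiency
#' expression; all constants are configuration, not code.
#'
#' @param state Named list or vector with `D_M` (free porphyrin), `MgD_M`
#'   (magnesium porphyrin) and `ATP_M` (MgATP2-), all in M.
#' @param params A [chela_params()] object.
#' @param cond A [chela_conditions()] object (supplies subunit concentrations
#'   and the clamped free Mg2+).
#' @return Chelation flux in M s^-1.
#' @examples
#' v <- chelation_velocity(list(D_M = 8e-6, MgD_M = 0, ATP_M = 5e-3),
#'                         chela_params(), chela_conditions())
#' @export
chelation_velocity <- function(state, params, cond) {
  D <- state[["D_M"]]
  MgD <- state[["MgD_M"]]
  ATP <- state[["ATP_M"]]
  E0 <- enzyme_conc(cond)
  if (E0 <= 0 || D <= 0 || ATP <= 0) return(0)
  Mg <- cond$Mg_free_M
  h <- params$hill_Mg
  inhib <- if (is.finite(params$Ki_product_M)) {
    1 / (1 + MgD / params$Ki_product_M)
  } else 1
  params$kcat_per_s * E0 *
    (D / (params$Km_DIX_M + D)) *
    (Mg^h / (params$K05_Mg_M^h + Mg^h)) *
    (ATP / (params$K05_ATP_M + ATP)) *
    inhib
}

#' ATP consumption flux
#'
#' Total hydrolysis flux: the coupled term (n_ATP hydrolysis events per
#' magnesium porphyrin formed) plus a chelation-independent basal ATPase on
#' the ChlI motor subunit with the same nucleotide saturation. When the
#' regeneration system is active this flux is paid from the PEP pool (1:1)
#' and the net d[ATP]/dt is zero.
#'
#' @inheritParams chelation_velocity
#' @return ATP consumption flux in M s^-1 (non-negative).
#' @export
atp_flux <- function(state, params, cond) {
  ATP <- state[["ATP_M"]]
  if (ATP <= 0) return(0)
  sat <- ATP / (params$K05_ATP_M + ATP)
  params$n_ATP * chelation_velocity(state, params, cond) +
    params$k_basal_ATPase_per_s * cond$ChlI_M * sat
}

ode_rhs <- function(t, y, parms) {
  st <- list(D_M = y[[1L]], MgD_M = y[[2L]], ATP_M = y[[3L]])
  v <- chelation_velocity(st, parms$params, parms$cond)
  loss <- (parms$params$k_dechel_per_s + parms$params$k_photolysis_per_s) *
    y[[2L]]
  f <- atp_flux(st, parms$params, parms$cond)
  if (parms$regen) {
    dATP <- 0
    dPEP <- -f
  } else {
    dATP <- -f
    dPEP <- 0
  }
  list(c(dD = -v + loss, dMgD = v - loss, dATP = dATP, dPEP = dPEP))
}

#' Simulate a chelatase assay progress curve
#'
#' Integrates the coupled system
#' dD/dt = -v + k_dechel*MgD, dMgD/dt = v - k_dechel*MgD, with ATP and PEP
#' bookkeeping from [atp_flux()]: while the regeneration system is on and PEP
#' remains, ATP is clamped and PEP is debited; once PEP exhausts (located by
#' the integrator's root finder, so the regime switch is exact) ATP itself is
#' consumed. Uses a stiff-capable solver (`deSolve::lsodar`) at rtol 1e-8 /
#' atol 1e-12 with output on a fixed grid independent of solver steps.
#'
#' @param params A [chela_params()] object.
#' @param cond A [chela_conditions()] object.
#' @param t_end_s End of the simulation (s, > 0).
#' @param n_out Number of output points (>= 2), evenly spaced on [0, t_end_s].
#' @param MgD0_M Initial magnesium porphyrin (M), default 0; the free
#'   porphyrin starts at `D_total_M - MgD0_M`.
#' @return A `progress_curve`: a data frame with columns `time_s`, `D_M`,
#'   `MgD_M`, `ATP_M`, `PEP_M` and attributes `params` and `conditions`.
#' @examples
#' pc <- simulate_progress(chela_params(), chela_conditions(), 3600, 61)
#' head(pc)
#' @export
simulate_progress <- function(params, cond, t_end_s, n_out = 601,
                              MgD0_M = 0) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(cond, "assay_conditions"))
  if (!is.numeric(t_end_s) || t_end_s <= 0) stop("t_end_s must be > 0",
                                                 call. = FALSE)
  if (n_out < 2L) stop("n_out must be >= 2", call. = FALSE)
  if (MgD0_M < 0 || MgD0_M > cond$D_total_M) {
    stop("MgD0_M must lie in [0, D_total_M]", call. = FALSE)
  }
  grid <- seq(0, t_end_s, length.out = n_out)
  y0 <- c(D = cond$D_total_M - MgD0_M, MgD = MgD0_M, ATP = cond$ATP0_M,
          PEP = if (cond$regeneration_on) cond$PEP0_M else 0)

  regen_active <- cond$regeneration_on && y0[["PEP"]] > 0 &&
    y0[["ATP"]] > 0
  rows <- NULL
  t0 <- 0

  if (regen_active && is.finite(y0[["PEP"]])) {
    out <- deSolve::lsodar(
      y = y0, times = grid, func = ode_rhs,
      parms = list(params = params, cond = cond, regen = TRUE),
      rootfunc = function(t, y, p) y[[4L]],
      rtol = 1e-8, atol = 1e-12
    )
    diagn <- attr(out, "istate")
    if (is.null(diagn) || diagn[1L] < 0) {
      stop("integrator failed during the regeneration phase", call. = FALSE)
    }
    troot <- attr(out, "troot")
    if (length(troot) == 1L && troot < t_end_s) {
      rows <- out[out[, "time"] < troot, , drop = FALSE]
      y0 <- out[nrow(out), c("D", "MgD", "ATP", "PEP")]
      y0[["PEP"]] <- 0
      t0 <- troot
      regen_active <- FALSE
    } else {
      rows <- out
      t0 <- NA  # whole horizon covered by the clamp phase
    }
  } else if (regen_active) {
    # infinite PEP pool: ideal clamp for the whole horizon
    out <- deSolve::lsoda(
      y = y0, times = grid, func = ode_rhs,
      parms = list(params = params, cond = cond, regen = TRUE),
      rtol = 1e-8, atol = 1e-12
    )
    rows <- out
    t0 <- NA
  }

  if (!is.na(t0)) {
    times2 <- c(t0, grid[grid > t0])
    out2 <- deSolve::lsoda(
      y = y0, times = times2, func = ode_rhs,
      parms = list(params = params, cond = cond, regen = FALSE),
      rtol = 1e-8, atol = 1e-12
    )
    diagn <- attr(out2, "istate")
    if (is.null(diagn) || diagn[1L] < 0) {
      stop("integrator failed after nucleotide-regeneration exhaustion",
           call. = FALSE)
    }
    # drop the stitching point unless it is a grid point
    keep2 <- out2[, "time"] > t0 | out2[, "time"] %in% grid
    rows <- rbind(rows, out2[keep2, , drop = FALSE])
  }

  res <- data.frame(time_s = rows[, "time"], D_M = pmax(rows[, "D"], 0),
                    MgD_M = pmax(rows[, "MgD"], 0),
                    ATP_M = pmax(rows[, "ATP"], 0),
                    PEP_M = pmax(rows[, "PEP"], 0))
  res <- res[!duplicated(res$time_s), , drop = FALSE]
  rownames(res) <- NULL
  structure(res, params = params, conditions = cond,
            class = c("progress_curve", "data.frame"))
}

#' Algebraic steady state of the chelatase assay
#'
#' With ATP clamped at its initial value (the regeneration idealization) the
#' porphyrin subsystem is one-dimensional and its steady state solves
#' v(D) = k_dechel * (D_total - D). The left side is increasing in D and the
#' right side decreasing, so the root is unique; it is located by bracketed
#' root-finding ([stats::uniroot]) at relative tolerance 1e-10. Degenerate
#' cases (no enzyme, no nucleotide, no porphyrin, or zero dechelation) are
#' returned as the exact boundary solutions.
#'
#' @inheritParams simulate_progress
#' @return A `steady_state` object: list with `D_ss_M`, `MgD_ss_M`,
#'   `ratio_ss` (MgD/D), `ratio_over_Mg_per_M` (MgD/(D*Mg), M^-1),
#'   `velocity_ss_M_per_s` and a `boundary` flag.
#' @examples
#' find_steady_state(chela_params(),
#'                   chela_conditions(D_total_M = 2.5e-6, ATP0_M = 5e-3))
#' @export
find_steady_state <- function(params, cond) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(cond, "assay_conditions"))
  Dtot <- cond$D_total_M
  kloss <- params$k_dechel_per_s + params$k_photolysis_per_s
  vfun <- function(D) {
    chelation_velocity(list(D_M = D, MgD_M = Dtot - D, ATP_M = cond$ATP0_M),
                       params, cond)
  }
  mk <- function(D_ss, boundary = FALSE) {
    MgD <- Dtot - D_ss
    structure(list(
      D_ss_M = D_ss, MgD_ss_M = MgD,
      ratio_ss = if (D_ss > 0) MgD / D_ss else Inf,
      ratio_over_Mg_per_M = if (D_ss > 0 && cond$Mg_free_M > 0) {
        MgD / (D_ss * cond$Mg_free_M)
      } else NA_real_,
      velocity_ss_M_per_s = kloss * MgD,
      boundary = boundary
    ), class = "steady_state")
  }
  if (Dtot <= 0) return(mk(0, boundary = TRUE))
  if (enzyme_conc(cond) <= 0 || cond$ATP0_M <= 0) {
    return(mk(Dtot, boundary = TRUE))      # no formation path: MgD_ss = 0
  }
  if (kloss <= 0) return(mk(0, boundary = TRUE))  # no loss path: MgD_ss = Dtot
  g <- function(D) vfun(D) - kloss * (Dtot - D)
  root <- stats::uniroot(g, lower = Dtot * 1e-14, upper = Dtot,
                         tol = Dtot * 1e-10, extendInt = "no")
  mk(root$root)
}

#' @export
print.steady_state <- function(x, ...) {
  cat("<steady_state>\n")
  cat(sprintf("  D_ss   = %.4g M\n  MgD_ss = %.4g M\n", x$D_ss_M, x$MgD_ss_M))
  cat(sprintf("  MgD/D  = %.4g   MgD/(D*Mg) = %.4g M^-1\n",
              x$ratio_ss, x$ratio_over_Mg_per_M))
  cat(sprintf("  flux   = %.4g M/s%s\n", x$velocity_ss_M_per_s,
              if (x$boundary) "   [boundary solution]" else ""))
  invisible(x)
}

#' Displacement of the steady state from chemical equilibrium
#'
#' The dimensionless factor by which the ATP-driven steady-state
#' product:substrate ratio, \[MgD\]/(\[D\]\[Mg2+\]), exceeds the equilibrium
#' constant of the uncoupled reaction — the thermodynamic benefit purchased
#' by ATP hydrolysis.
#'
#' @param ss A `steady_state` from [find_steady_state()], or a single
#'   positive number taken directly as the ratio MgD/(D*Mg) in M^-1.
#' @param thermo A [thermo_context()].
#' @return Dimensionless displacement factor.
#' @export
displacement_factor <- function(ss, thermo) {
  ratio <- if (inherits(ss, "steady_state")) ss$ratio_over_Mg_per_M else ss
  if (!is.numeric(ratio) || is.na(ratio) || ratio <= 0) {
    stop("ratio_over_Mg must be > 0", call. = FALSE)
  }
  ratio / thermo$K_eq_per_M
}

#' Duration for which a progress curve holds its plateau
#'
#' Length of the maximal contiguous interval during which the magnesium
#' porphyrin concentration stays within `tolerance_fraction` of the plateau.
#' The plateau defaults to the curve's maximum (the last point before decline
#' in a rise-and-fall trace); an algebraic steady-state value can be supplied
#' instead. Durations are resolved on the curve's own time grid.
#'
#' @param curve A `progress_curve` (or data frame with `time_s` and `MgD_M`).
#' @param tolerance_fraction Relative band half-width around the plateau;
#'   default 0.10.
#' @param plateau_M Optional plateau value (M); default the curve maximum.
#' @return A list with `duration_s`, `plateau_M`, `no_plateau` (TRUE for a
#'   curve that never rises) and `censored` (TRUE when the curve is still
#'   inside the band — e.g. still rising — at the final time point).
#' @export
steady_state_maintenance_time <- function(curve, tolerance_fraction = 0.10,
                                          plateau_M = NULL) {
  curve <- as.data.frame(curve)
  t <- curve$time_s
  y <- curve$MgD_M
  if (is.null(t) || is.null(y)) {
    stop("curve must have 'time_s' and 'MgD_M' columns", call. = FALSE)
  }
  n <- length(y)
  never_rises <- all(diff(y) <= 0) && y[n] < y[1L]
  if (never_rises) {
    return(list(duration_s = 0, plateau_M = NA_real_, no_plateau = TRUE,
                censored = FALSE))
  }
  plateau <- if (is.null(plateau_M)) max(y) else plateau_M
  ok <- abs(y - plateau) <= tolerance_fraction * plateau
  if (!any(ok)) {
    return(list(duration_s = 0, plateau_M = plateau, no_plateau = FALSE,
                censored = FALSE))
  }
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  durations <- t[ends[runs]] - t[starts[runs]]
  best <- runs[which.max(durations)]
  list(duration_s = max(durations),
       plateau_M = plateau,
       no_plateau = FALSE,
       censored = ends[best] == n)
}
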