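#' Read a time-series CSV
#'
#' Reads the package's time-series dialect: comma-separated, UTF-8, `.`
#' decimal, mandatory header whose column names carry unit suffixes
#' (`time_s`, `conc_M`, `fluor_au`, ...). The first column must be a strictly
#' increasing time grid; every cell must be numeric. CRLF and LF files parse
#' identically.
#'
#' @param path Path to a CSV file.
#' @return A data frame; parse errors name the first offending line.
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tbl <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         fileEncoding = "UTF-8")
  if (ncol(tbl) < 2L) {
    stop("time-series CSV needs a header with >= 2 columns: ", path,
         call. = FALSE)
  }
  if (names(tbl)[1L] != "time_s") {
    stop("first column must be 'time_s' (got '", names(tbl)[1L], "')",
         call. = FALSE)
  }
  for (j in seq_along(tbl)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tbl[[j]]))))
    if (length(bad)) {
      stop("non-numeric or missing cell in column '", names(tbl)[j],
           "', line ", bad[1L] + 1L, call. = FALSE)  # +1 for the header line
    }
    tbl[[j]] <- as.numeric(tbl[[j]])
  }
  dt <- diff(tbl$time_s)
  if (any(dt <= 0)) {
    stop("time_s must be strictly increasing; first violation at line ",
         which(dt <= 0)[1L] + 2L, call. = FALSE)
  }
  tbl
}

#' Write a time-series CSV
#'
#' Companion writer for [read_timeseries_csv()]; round-trips exactly.
#'
#' @param tbl Data frame whose first column is `time_s`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_timeseries_csv <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# Read a flat JSON document with unit-suffixed keys and validate against a
# constructor's formals; unknown keys are errors, "Inf" strings are accepted
# for unbounded constants.
read_config_json <- function(path, constructor, what) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(constructor))
  unknown <- setdiff(names(doc), allowed)
  if (length(unknown)) {
    stop("unknown ", what, " key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  doc <- lapply(doc, function(v) {
    if (identical(v, "Inf")) Inf else v
  })
  do.call(constructor, doc)
}

#' Read parameter, condition and thermodynamic JSON documents
#'
#' Flat JSON objects with unit-suffixed keys matching the arguments of
#' [chela_params()], [chela_conditions()] and [thermo_context()]
#' respectively (e.g. `{"kcat_per_s": 0.0133, "Km_DIX_M": 2e-6}`). Unknown
#' keys are rejected; omitted keys take the package defaults; the string
#' `"Inf"` is accepted for unbounded constants such as `Ki_product_M`.
#'
#' @param path Path to a JSON file.
#' @return The validated object.
#' @export
read_params_json <- function(path) {
  read_config_json(path, chela_params, "parameter")
}

#' @rdname read_params_json
#' @export
read_conditions_json <- function(path) {
  read_config_json(path, chela_conditions, "condition")
}

#' @rdname read_params_json
#' @export
read_thermo_json <- function(path) {
  read_config_json(path, thermo_context, "thermo")
}

#' Run the full analysis pipeline
#'
#' End-to-end composition of the package's stages: generate the synthetic
#' dechelation initial-rate experiment, fit the first-order dechelation
#' constant, derive the uncatalyzed second-order constant and the full
#' catalytic-power report (including the ATP-clamped steady state and its
#' displacement from equilibrium under the supplied conditions), and write
#' the artifacts — the rate table, fitted constants and a `report.json`
#' holding every derived quantity at full precision plus a `rendered` block —
#' into `out_dir`. Progress is logged to standard error; all randomness flows
#' through `seed`.
#'
#' @param params A [chela_params()] object (or path to a params JSON).
#' @param thermo A [thermo_context()] (or path to a thermo JSON).
#' @param cond A [chela_conditions()] for the displacement stage (or path to
#'   a conditions JSON); default the low-porphyrin steady-state conditions.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed for the synthetic stage.
#' @param mg_ref_M Reference Mg2+ for the uncatalyzed half-life (M).
#' @param sig_figs Rendering precision of the report.
#' @param quiet Suppress log messages.
#' @return Invisibly, a list with the `report` (list), the `fit` and the
#'   paths written.
#' @export
run_pipeline <- function(params = chela_params(),
                         thermo = thermo_context(),
                         cond = chela_conditions(D_total_M = 2.5e-6,
                                                 ATP0_M = 5e-3),
                         out_dir = ".",
                         seed = 42,
                         mg_ref_M = 1e-3,
                         sig_figs = 1,
                         quiet = FALSE) {
  log_info <- function(...) if (!quiet) message("[chelapower] ", ...)
  if (is.character(params)) params <- read_params_json(params)
  if (is.character(thermo)) thermo <- read_thermo_json(thermo)
  if (is.character(cond)) cond <- read_conditions_json(cond)
  stopifnot(inherits(params, "kinetic_params"),
            inherits(thermo, "thermo_context"),
            inherits(cond, "assay_conditions"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  log_info("stage 1/4: synthetic dechelation experiment (seed ", seed, ")")
  ex <- generate_dechelation_experiment(k_true = params$k_dechel_per_s,
                                        seed = seed)
  rates_path <- file.path(out_dir, "dechelation_rates.csv")
  utils::write.csv(ex$rates, rates_path, row.names = FALSE, quote = FALSE)

  log_info("stage 2/4: through-origin first-order fit")
  fit <- fit_first_order_constant(ex$rates)

  log_info("stage 3/4: catalytic-power derivation")
  fitted_params <- do.call(chela_params,
                           utils::modifyList(unclass(params),
                                             list(k_dechel_per_s =
                                                    fit$k_dechel_per_s)))
  report <- power_report(fitted_params, thermo, mg_ref_M = mg_ref_M,
                         cond = cond, sig_figs = sig_figs)

  log_info("stage 4/4: writing report")
  out <- unclass(report)
  out$steady_state <- if (!is.null(report$steady_state)) {
    unclass(report$steady_state)
  }
  out$fit <- list(k_dechel_per_s = fit$k_dechel_per_s,
                  k_se_per_s = fit$k_se_per_s, n_points = fit$n_points)
  out$seed <- seed
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(out, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(report = out, fit = fit,
                 paths = c(rates = rates_path, report = report_path)))
}
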