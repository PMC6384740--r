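#' Run configuration for the end-to-end analyses
#'
#' Collects the inputs and settings of an orchestrated run. Series may be
#' given as [titration_series()] objects or as manifest paths (resolved
#' through [read_titration_series()]).
#'
#' @param series a [titration_series()], a manifest path, or a list of
#'   them (one per temperature for mechanism classification).
#' @param ternary_series optional second series (or list) for ternary
#'   comparison runs.
#' @param corrections a [correction_settings()].
#' @param buffer optional buffer blank [spectrum()] or CSV path.
#' @param n_points Stern-Volmer truncation (NULL = first seven points rule).
#' @param tau_0 fluorophore lifetime, s.
#' @param mechanism_tolerance relative K_sv flatness tolerance.
#' @param comparison_threshold relative K_D change for [compare_systems()].
#' @param out_dir optional output directory for JSON/CSV reports.
#' @param seed integer recorded in every report.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(series, ternary_series = NULL,
                       corrections = correction_settings(),
                       buffer = NULL, n_points = NULL, tau_0 = 1e-8,
                       mechanism_tolerance = 0.05,
                       comparison_threshold = 0.10,
                       out_dir = NULL, seed = 1L) {
  structure(list(series = series, ternary_series = ternary_series,
                 corrections = corrections, buffer = buffer,
                 n_points = n_points, tau_0 = tau_0,
                 mechanism_tolerance = mechanism_tolerance,
                 comparison_threshold = comparison_threshold,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

# normalise a series argument to a list of titration_series
resolve_series <- function(x, what = "series") {
  if (inherits(x, "titration_series")) return(list(x))
  if (is.character(x)) x <- as.list(x)
  if (!is.list(x) || length(x) == 0L)
    stop("config error: '", what, "' must be a titration_series, a ",
         "manifest path, or a non-empty list of them", call. = FALSE)
  lapply(x, function(e) {
    if (inherits(e, "titration_series")) return(e)
    if (is.character(e) && length(e) == 1L) {
      if (!file.exists(e))
        stop("config error: '", what, "' manifest not found: ", e,
             call. = FALSE)
      return(read_titration_series(e))
    }
    stop("config error: '", what, "' entries must be titration_series ",
         "objects or manifest paths", call. = FALSE)
  })
}

resolve_buffer <- function(b) {
  if (is.null(b) || inherits(b, "spectrum")) return(b)
  if (is.character(b) && length(b) == 1L) return(read_spectrum(b, "emission"))
  stop("config error: 'buffer' must be a spectrum or a CSV path",
       call. = FALSE)
}

with_stage <- function(stage, input, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s (input: %s)", stage, conditionMessage(e), input),
         call. = FALSE)
  })
}

#' End-to-end binary titration analysis
#'
#' Composes the full single-titrant workflow: corrected quenching curves,
#' Stern-Volmer fits (one per temperature), mechanism classification when
#' several temperatures are supplied, the equilibrium K_D / Gibbs-energy
#' fit on the highest-temperature series, and an emission peak-shift
#' summary. The report embeds the settings and seed so a rerun with the
#' same configuration reproduces it exactly.
#'
#' @param config a [run_config()].
#' @return An object of class `"binding_report"`: a list with `quenching`
#'   (data frame: temperature, K_sv, K_sv_se, intercept, pearson_r, k_q,
#'   curvature, n_points_used), `mechanism` (a `mechanism_call` or NULL),
#'   `binding` (the [binding_fit()]), `binding_table` (one-row data frame
#'   with K_D, dG), `peak_shift` (nm, first vs last point), `settings`.
#'   When `config$out_dir` is set, `report.json`, `quenching_table.csv`
#'   and `binding_table.csv` are written there.
#' @export
run_binary_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  series_list <- resolve_series(config$series, "series")
  buffer <- resolve_buffer(config$buffer)

  sv_fits <- lapply(series_list, function(ser) {
    curve <- with_stage("quenching", ser$label,
                        build_quenching_curve(ser, config$corrections, buffer))
    with_stage("stern_volmer", ser$label,
               sv_fit(curve, n_points = config$n_points, tau_0 = config$tau_0))
  })
  qtab <- do.call(rbind, lapply(sv_fits, function(f)
    data.frame(temperature = f$temperature, K_sv = f$K_sv,
               K_sv_se = f$K_sv_se, intercept = f$intercept,
               pearson_r = f$pearson_r, k_q = f$k_q,
               curvature = f$curvature_flag,
               n_points_used = f$n_points_used)))

  mech <- NULL
  temps <- vapply(series_list, function(s) s$temperature, numeric(1))
  if (length(unique(temps)) >= 2L)
    mech <- with_stage("mechanism", "temperature series",
                       classify_mechanism(sv_fits,
                                          tolerance = config$mechanism_tolerance,
                                          tau_0 = config$tau_0))

  main <- series_list[[which.max(temps)]]
  main_curve <- build_quenching_curve(main, config$corrections, buffer)
  bfit <- with_stage("binding", main$label,
                     binding_fit(as_binding_system(main_curve,
                                                   main$fixed_total,
                                                   label = main$label)))
  btab <- data.frame(temperature = bfit$temperature,
                     K_D = bfit$k_d, K_D_se = bfit$k_d_se,
                     ratio_at_saturation = bfit$ratio_at_saturation,
                     delta_g_kJ_mol = bfit$delta_g,
                     residual_norm = bfit$residual_norm)

  pk0 <- peak_position(main$points[[1L]]$spectrum)
  pk1 <- peak_position(main$points[[length(main$points)]]$spectrum)
  peak_shift <- as.numeric(pk1) - as.numeric(pk0)

  report <- structure(list(
    quenching = qtab, mechanism = mech, binding = bfit,
    binding_table = btab, peak_shift = peak_shift,
    settings = list(
      n_points = config$n_points, tau_0 = config$tau_0,
      apply_background = config$corrections$apply_background,
      apply_inner_filter = config$corrections$apply_inner_filter,
      mechanism_tolerance = config$mechanism_tolerance,
      seed = config$seed)),
    class = "binding_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Binary versus ternary affinity comparison
#'
#' Fits the equilibrium binding model to a binary and a ternary titration
#' recorded at the same temperature and judges whether the competitor
#' changed the titrant's affinity.
#'
#' @param config a [run_config()] whose `series` is the binary titration
#'   and `ternary_series` the competitor-preincubated one.
#' @return An object of class `"comparison_report"` with `binary_fit`,
#'   `ternary_fit`, `interaction` (an [compare_systems()] report),
#'   `settings`.
#' @export
run_ternary_comparison <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$ternary_series))
    stop("config error: 'ternary_series' is required for a ternary ",
         "comparison", call. = FALSE)
  buffer <- resolve_buffer(config$buffer)
  fit_one <- function(x, what) {
    ser <- resolve_series(x, what)[[1L]]
    curve <- with_stage("quenching", ser$label,
                        build_quenching_curve(ser, config$corrections, buffer))
    with_stage("binding", ser$label,
               binding_fit(as_binding_system(curve, ser$fixed_total,
                                             label = ser$label)))
  }
  bfit <- fit_one(config$series, "series")
  tfit <- fit_one(config$ternary_series, "ternary_series")
  rep <- with_stage("comparison", "binary vs ternary",
                    compare_systems(bfit, tfit,
                                    threshold = config$comparison_threshold))
  report <- structure(list(binary_fit = bfit, ternary_fit = tfit,
                           interaction = rep,
                           settings = list(
                             threshold = config$comparison_threshold,
                             apply_inner_filter =
                               config$corrections$apply_inner_filter,
                             seed = config$seed)),
                      class = "comparison_report")
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir))
      dir.create(config$out_dir, recursive = TRUE)
    jsonlite::write_json(comparison_report_json(report),
                         file.path(config$out_dir, "comparison_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_json <- function(report) {
  list(
    quenching = report$quenching,
    mechanism = if (is.null(report$mechanism)) NULL else
      list(label = report$mechanism$label,
           diffusion_limit_exceeded = report$mechanism$diffusion_limit_exceeded,
           relative_trend = report$mechanism$relative_trend),
    binding = list(K_D = report$binding$k_d,
                   K_D_se = report$binding$k_d_se,
                   ratio_at_saturation = report$binding$ratio_at_saturation,
                   delta_g_kJ_mol = report$binding$delta_g,
                   free_ligand_at_half = report$binding$free_ligand_at_half,
                   residual_norm = report$binding$residual_norm,
                   saturation_flag = report$binding$saturation_flag),
    peak_shift_nm = report$peak_shift,
    settings = report$settings)
}

comparison_report_json <- function(report) {
  list(binary = list(K_D = report$binary_fit$k_d,
                     delta_g_kJ_mol = report$binary_fit$delta_g),
       ternary = list(K_D = report$ternary_fit$k_d,
                      delta_g_kJ_mol = report$ternary_fit$delta_g),
       interaction = list(call = report$interaction$call,
                          ratio = report$interaction$ratio),
       settings = report$settings)
}

write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  jsonlite::write_json(report_json(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  qt <- report$quenching
  num <- vapply(qt, is.numeric, TRUE)
  qt[num] <- lapply(qt[num], signif, digits = 4L)
  utils::write.csv(qt, file.path(out_dir, "quenching_table.csv"),
                   row.names = FALSE)
  bt <- report$binding_table
  bt$K_D <- signif(bt$K_D, 4L)
  bt$K_D_se <- signif(bt$K_D_se, 4L)
  bt$ratio_at_saturation <- signif(bt$ratio_at_saturation, 4L)
  bt$delta_g_kJ_mol <- round(bt$delta_g_kJ_mol, 3L)
  utils::write.csv(bt, file.path(out_dir, "binding_table.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.binding_report <- function(x, ...) {
  cat("== Binary titration analysis ==\n\nStern-Volmer fits:\n")
  print(x$quenching, row.names = FALSE)
  if (!is.null(x$mechanism)) {
    cat("\n"); print(x$mechanism)
  }
  cat("\n"); print(x$binding)
  cat(sprintf("\nEmission peak shift (last vs first point): %+g nm\n",
              x$peak_shift))
  invisible(x)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("== Binary vs ternary comparison ==\n\nBinary:\n")
  print(x$binary_fit)
  cat("\nTernary:\n")
  print(x$ternary_fit)
  cat("\n")
  print(x$interaction)
  invisible(x)
}
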