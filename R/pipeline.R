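#' Analysis configuration
#'
#' Collects and validates every tunable parameter of the pipeline. Defaults
#' are the canonical protocol values: 1,000 dots per cm resampling, 0.005 cm
#' smoothing half-window, 20 trimmed dots per end, 50 cm^-1 exceedance
#' threshold, compartment breaks at 0.5 and 1.0 cm, 0.5% trimming per side
#' for the mean curvature index, 0.05 cm tip window, 20 degree angle classes
#' and alpha = 0.05.
#'
#' @param density Resampling density, dots per cm.
#' @param half_window_cm Moving-average half window, cm.
#' @param n_trim Dots trimmed at each profile end.
#' @param threshold Curvature exceedance threshold, cm^-1.
#' @param breaks Compartment break points, cm.
#' @param trim_fraction Trim fraction per side for the mean curvature index.
#' @param tip_window_cm Tip secant window, cm.
#' @param class_width_deg Angle class width, degrees.
#' @param alpha Significance level for letter displays.
#' @param gravity Gravity vector.
#' @param denominator Curvature denominator convention.
#' @param abs_hgi Report |HGI| instead of signed HGI.
#' @param smoothing Resampling smoothing mode, `"gcv"` or `"none"`.
#' @param seed Seed recorded for any stochastic step.
#' @return A validated list of class `posture_config`.
#' @export
posture_config <- function(density = 1000, half_window_cm = 0.005,
                           n_trim = 20, threshold = 50, breaks = c(0.5, 1),
                           trim_fraction = 0.005, tip_window_cm = 0.05,
                           class_width_deg = 20, alpha = 0.05,
                           gravity = c(0, -1), denominator = "mean_chord",
                           abs_hgi = FALSE, smoothing = "gcv", seed = NULL) {
  stopifnot(density > 0, half_window_cm >= 0, n_trim >= 0, threshold > 0,
            !is.unsorted(breaks, strictly = TRUE), trim_fraction >= 0,
            trim_fraction < 0.5, tip_window_cm > 0, 360 %% class_width_deg == 0,
            alpha > 0, alpha < 1)
  denominator <- match.arg(denominator, c("mean_chord", "endpoint_chord"))
  smoothing <- match.arg(smoothing, c("gcv", "none"))
  structure(list(density = density, half_window_cm = half_window_cm,
                 n_trim = n_trim, threshold = threshold, breaks = breaks,
                 trim_fraction = trim_fraction, tip_window_cm = tip_window_cm,
                 class_width_deg = class_width_deg, alpha = alpha,
                 gravity = unit_gravity(gravity), denominator = denominator,
                 abs_hgi = abs_hgi, smoothing = smoothing, seed = seed),
            class = "posture_config")
}

#' Measure every root in a collection
#'
#' Runs the full per-root pipeline over a collection. Roots failing a
#' precondition (too short, degenerate) are skipped with a warning and
#' reported in the `skipped` element — never silently dropped.
#'
#' @param collection A [trace_collection()].
#' @param config A [posture_config()].
#' @return List with `indices` (per-root tibble), `profiles` (per-point
#'   tibble from [profile_table()]), and `skipped` (tibble: root_id,
#'   reason).
#' @export
measure_collection <- function(collection, config = posture_config()) {
  stopifnot(inherits(collection, "trace_collection"),
            inherits(config, "posture_config"))
  g <- collection$gravity_direction
  indices <- list(); profiles <- list(); skipped <- list()
  for (tr in collection$traces) {
    res <- tryCatch({
      row <- measure_root(tr, gravity_direction = g,
                          density = config$density,
                          half_window_cm = config$half_window_cm,
                          n_trim = config$n_trim,
                          denominator = config$denominator,
                          threshold = config$threshold,
                          breaks = config$breaks,
                          trim_fraction = config$trim_fraction,
                          tip_window_cm = config$tip_window_cm,
                          abs_hgi = config$abs_hgi,
                          smoothing = config$smoothing)
      prof <- curvature_profile(tr, density = config$density,
                                half_window_cm = config$half_window_cm,
                                n_trim = config$n_trim,
                                denominator = config$denominator,
                                smoothing = config$smoothing)
      list(row = row, prof = profile_table(prof))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      warning("Skipping root '", tr$root_id, "': ", res, call. = FALSE)
      skipped[[tr$root_id]] <- tibble::tibble(root_id = tr$root_id,
                                              reason = res)
    } else {
      indices[[tr$root_id]] <- res$row
      profiles[[tr$root_id]] <- res$prof
    }
  }
  list(indices = dplyr::bind_rows(indices),
       profiles = dplyr::bind_rows(profiles),
       skipped = dplyr::bind_rows(skipped))
}

#' Measure traces and write result files
#'
#' End-to-end batch entry point: reads (or accepts) a trace collection,
#' measures every root, and writes `results.csv` (one row per root),
#' `profiles.csv` (per-point curvature) and optional figures into
#' `out_dir`. Output is deterministic for a given input and configuration.
#'
#' @param input A [trace_collection()] or the path of a long-format trace
#'   table CSV.
#' @param out_dir Output directory (created if needed).
#' @param config A [posture_config()].
#' @param figures Write posture and curvature-coloured figures (default
#'   TRUE).
#' @param scale_cm_per_unit Scale used when `input` is a path.
#' @return Invisibly, the [measure_collection()] result.
#' @export
run_measure <- function(input, out_dir, config = posture_config(),
                        figures = TRUE, scale_cm_per_unit = 1) {
  collection <- if (inherits(input, "trace_collection")) input else
    read_trace_table(input, scale_cm_per_unit = scale_cm_per_unit,
                     gravity_direction = config$gravity)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- measure_collection(collection, config)
  if (nrow(res$indices) == 0) {
    stop("No roots could be measured.", call. = FALSE)
  }
  write_results(res$indices, file.path(out_dir, "results.csv"))
  readr::write_csv(res$profiles, file.path(out_dir, "profiles.csv"))
  if (nrow(res$skipped) > 0) {
    readr::write_csv(res$skipped, file.path(out_dir, "skipped.csv"))
  }
  message(sprintf("Measured %d root(s), skipped %d.",
                  nrow(res$indices), nrow(res$skipped)))
  if (figures) {
    ggplot2::ggsave(file.path(out_dir, "posture.png"),
                    plot_posture(res$profiles), width = 7, height = 5,
                    dpi = 150)
    ggplot2::ggsave(file.path(out_dir, "posture_ci.png"),
                    plot_posture(res$profiles, color_ci = TRUE,
                                 vmax = config$threshold),
                    width = 8, height = 5, dpi = 150)
  }
  invisible(res)
}

#' Compare groups across indices and write a report
#'
#' Runs [compare_groups()] for each requested index and writes a CSV of
#' pairwise p-values/letters plus a JSON report with the full matrices and
#' the Bonferroni family metadata.
#'
#' @param results Per-root results tibble (or CSV path) with a `group`
#'   column.
#' @param out_dir Output directory; `NULL` to skip writing.
#' @param indices Character vector of index columns to compare.
#' @param method,alpha,family_size Passed to [compare_groups()].
#' @return Named list of `group_comparison` objects, invisibly when writing.
#' @export
run_compare <- function(results, out_dir = NULL,
                        indices = c("L", "HGI", "VGI", "SI", "ci_mean",
                                    "ci_max", "n_exceed"),
                        method = "steel_dwass", alpha = 0.05,
                        family_size = NULL) {
  if (is.character(results)) results <- read_results(results)
  stopifnot(is.data.frame(results), "group" %in% names(results))
  indices <- intersect(indices, names(results))
  if (length(indices) == 0) stop("No requested index column present.",
                                 call. = FALSE)
  comps <- lapply(indices, function(ix) {
    compare_groups(results, ix, method = method, alpha = alpha,
                   family_size = family_size)
  })
  names(comps) <- indices
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    rows <- dplyr::bind_rows(lapply(comps, function(cc) {
      tibble::tibble(index = cc$index_name, group = names(cc$letters),
                     letters = unname(cc$letters), omnibus_p = cc$omnibus_p,
                     method = cc$method, alpha = cc$alpha,
                     family_size = cc$family_size)
    }))
    readr::write_csv(rows, file.path(out_dir, "comparison_letters.csv"))
    payload <- lapply(comps, function(cc) {
      list(index = cc$index_name, omnibus_p = cc$omnibus_p, H = cc$H,
           method = cc$method, alpha = cc$alpha,
           family_size = cc$family_size,
           groups = names(cc$letters), letters = unname(cc$letters),
           pairwise = cc$pairwise)
    })
    jsonlite::write_json(payload, file.path(out_dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         matrix = "rowmajor", na = "null")
    invisible(comps)
  } else {
    comps
  }
}
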