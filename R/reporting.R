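#' Aggregate per-structure gamma pass rates
#'
#' Per group and mode: the mean and population standard deviation of the
#' pass rates, and — for every non-global mode — how many structures score
#' *strictly below* their own global-mode pass rate (the comparison that
#' exposes where a tolerance-based normalisation is more, or less,
#' forgiving than the conventional global gamma).  Structures skipped in a
#' mode (no tolerance) are excluded from that mode's aggregate and counted
#' in `n_skipped`.
#'
#' @param results tibble with columns `structure`, `mode`, `pass_rate`
#'   (e.g. `tidy()` of a [structural_gamma()] result); optionally a
#'   grouping column named by `group`.
#' @param group name of the grouping column (e.g. treatment site); when
#'   absent a single group `"all"` is used.
#' @return A tibble with one row per group x mode: `group`, `mode`,
#'   `n_structures`, `mean_pass_rate`, `sd_pass_rate`, `n_skipped`,
#'   `n_below_global`, `pct_below_global` (NA for the global mode itself).
#' @export
summarize_gamma <- function(results, group = NULL) {
  if (nrow(results) == 0L) {
    return(tibble(group = character(0), mode = character(0),
                  n_structures = integer(0), mean_pass_rate = numeric(0),
                  sd_pass_rate = numeric(0), n_skipped = integer(0),
                  n_below_global = integer(0),
                  pct_below_global = numeric(0)))
  }
  results <- as_tibble(results)
  results$group <- if (is.null(group)) "all" else results[[group]]
  gl <- results[results$mode == "global", c("group", "structure", "pass_rate")]
  if (any(is.na(gl$pass_rate)) ||
      !all(unique(results$structure) %in% gl$structure)) {
    stop_validation(
      "every structure needs a global-mode pass rate as the comparison baseline")
  }
  names(gl)[3] <- "global_pass_rate"
  joined <- dplyr::left_join(results, gl, by = c("group", "structure"))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- joined |>
    dplyr::group_by(.data$group, .data$mode) |>
    dplyr::summarise(
      n_structures = sum(!is.na(.data$pass_rate)),
      mean_pass_rate = mean(.data$pass_rate[!is.na(.data$pass_rate)]),
      sd_pass_rate = pop_sd(.data$pass_rate[!is.na(.data$pass_rate)]),
      n_skipped = sum(is.na(.data$pass_rate)),
      n_below_global = sum(!is.na(.data$pass_rate) &
                             .data$pass_rate < .data$global_pass_rate),
      .groups = "drop")
  out$pct_below_global <- ifelse(out$mode == "global", NA_real_,
                                 100 * out$n_below_global /
                                   pmax(out$n_structures, 1L))
  out$n_below_global[out$mode == "global"] <- NA_integer_
  out
}

# Signed-gamma display classification shared by the renderer and its tests:
# white at 0, saturating red at >= +2, blue at <= -2, NA transparent.
classify_gamma_pixels <- function(gamma, saturate = 2) {
  cls <- character(length(gamma))
  cls[is.na(gamma)] <- "transparent"
  cls[!is.na(gamma) & abs(gamma) < 1e-9] <- "white"
  cls[!is.na(gamma) & gamma >= 1e-9] <- "red"
  cls[!is.na(gamma) & gamma <= -1e-9] <- "blue"
  array(cls, dim = dim(gamma) %||% length(gamma))
}

#' Render a signed gamma map for one axial slice
#'
#' Diverging colour map centred at zero: white where the distributions
#' agree, saturating red at signed gamma >= +2 (evaluated hotter than
#' reference), saturating blue at <= -2 (evaluated colder).  Voxels outside
#' the evaluated set are transparent over the background (a CT/phantom
#' slice in greyscale, or neutral grey when absent).
#'
#' @param result a `gamma_result` from [compute_gamma()].
#' @param slice_index axial slice (1-based, third grid axis).
#' @param background optional numeric matrix (same in-plane shape as the
#'   gamma slice) drawn in greyscale under the map, e.g. from
#'   [read_ct_slice()].
#' @param file optional output path; when given the plot is saved with
#'   [ggplot2::ggsave()] (PNG or PDF by extension).
#' @param saturate |gamma| at which the colour scale saturates.
#' @return The ggplot object, invisibly when writing to `file`.
#' @export
plot_gamma_map <- function(result, slice_index, background = NULL,
                           file = NULL, saturate = 2) {
  d <- dim(result$signed_gamma)
  if (slice_index < 1 || slice_index > d[3]) {
    stop_validation(sprintf("slice %d out of range (grid has %d slices)",
                            slice_index, d[3]))
  }
  sl <- result$signed_gamma[, , slice_index]
  df <- tidyr::expand_grid(j = seq_len(d[2]), i = seq_len(d[1]))
  df$gamma <- as.vector(sl)[(df$j - 1) * d[1] + df$i]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j))
  if (!is.null(background)) {
    bg <- background
    rng <- range(bg)
    grey <- if (diff(rng) > 0) (bg - rng[1]) / diff(rng) else bg * 0 + 0.5
    # annotation raster rows run top-down
    cols <- matrix(grDevices::grey(t(grey)[rev(seq_len(ncol(grey))), ]),
                   nrow = ncol(grey))
    p <- p + ggplot2::annotation_raster(cols, xmin = 0.5, xmax = d[1] + 0.5,
                                        ymin = 0.5, ymax = d[2] + 0.5)
  } else {
    p <- p + ggplot2::theme(
      panel.background = ggplot2::element_rect(fill = "grey60"))
  }
  p <- p +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$gamma)) +
    ggplot2::scale_fill_gradient2(
      low = "blue", mid = "white", high = "red", midpoint = 0,
      limits = c(-saturate, saturate), oob = scales::squish,
      na.value = NA, name = expression(gamma)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("Signed gamma: %s (%s normalisation)",
                      result$structure_name, result$normalization$mode),
      subtitle = sprintf(
        "%g%% / %g mm, threshold %g Gy, slice %d; pass rate %s",
        result$criteria$dose_percent, result$criteria$dta_mm,
        result$criteria$low_dose_threshold, slice_index,
        if (is.na(result$pass_rate)) "undefined"
        else sprintf("%.1f%%", result$pass_rate)),
      x = "x voxel", y = "y voxel")
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 5, dpi = 120)
    return(invisible(p))
  }
  p
}

#' @rdname plot_gamma_map
#' @param object a `gamma_result`.
#' @param ... passed to [plot_gamma_map()].
#' @export
autoplot.gamma_result <- function(object, slice_index = NULL, ...) {
  if (is.null(slice_index)) {
    # default to the slice with the most evaluated voxels
    counts <- apply(!is.na(object$signed_gamma), 3, sum)
    slice_index <- which.max(counts)
  }
  plot_gamma_map(object, slice_index, ...)
}

#' Export per-structure and summary tables as CSV
#'
#' Writes `structures.csv` (one row per structure x mode: canonical name,
#' normalisation dose used, evaluated voxels, pass rate to one decimal,
#' skip reason) and `summary.csv` (the [summarize_gamma()] table), plus a
#' plain-text run log of every skip and exclusion.
#'
#' @param sg a [structural_gamma()] result.
#' @param directory output directory (created if needed).
#' @param group optional group label recorded on the summary.
#' @return Named character vector of file paths, invisibly.
#' @export
export_report <- function(sg, directory, group = NULL) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  per <- tidy(sg)
  per$pass_rate <- round(per$pass_rate, 1)
  # only structures with a global baseline can enter the summary
  with_baseline <- per$structure %in%
    per$structure[per$mode == "global" & !is.na(per$pass_rate)]
  tallies <- summarize_gamma(per[with_baseline, , drop = FALSE])
  tallies$mean_pass_rate <- round(tallies$mean_pass_rate, 1)
  tallies$sd_pass_rate <- round(tallies$sd_pass_rate, 1)
  tallies$pct_below_global <- round(tallies$pct_below_global, 1)
  if (!is.null(group)) tallies$group <- group
  paths <- c(structures = file.path(directory, "structures.csv"),
             summary = file.path(directory, "summary.csv"),
             log = file.path(directory, "run_log.txt"))
  readr::write_csv(per, paths[["structures"]], na = "")
  readr::write_csv(tallies, paths[["summary"]], na = "")
  log_lines <- c(
    sprintf("structural gamma run: %d structure-mode evaluations",
            nrow(per)),
    sprintf("excluded structure: %s (reason: %s)",
            sg$exclusions$raw_name[!sg$exclusions$kept],
            sg$exclusions$reason[!sg$exclusions$kept]),
    sprintf("skipped: %s [%s] (%s)",
            per$structure[!is.na(per$skip_reason)],
            per$mode[!is.na(per$skip_reason)],
            per$skip_reason[!is.na(per$skip_reason)]),
    sprintf("normalisation: %s [%s] = %s Gy",
            per$structure[!is.na(per$norm_dose)],
            per$mode[!is.na(per$norm_dose)],
            format(per$norm_dose[!is.na(per$norm_dose)], digits = 6))
  )
  writeLines(log_lines, paths[["log"]])
  invisible(paths)
}
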