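#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Choropleth of a per-ward layer
#'
#' ggplot2 map of a ward-level quantity over the ward geometry. Three break
#' styles: `"quantile"` (default, five classes — used for relative-rate
#' maps), `"equal"` (equal-width classes), and `"exceedance"` (binary
#' emphasis at the 0.8 high-certainty threshold, the convention for
#' exceedance-probability maps). Every ward in the geometry must appear in
#' the layer (`NA` values are drawn as an explicit missing class), and every
#' ward in the layer must exist in the geometry.
#'
#' @param geo A `ward_geography`.
#' @param layer Data frame with `ward_id` and the value column.
#' @param fill Name of the value column in `layer`.
#' @param breaks `"quantile"`, `"equal"` or `"exceedance"`.
#' @param n_breaks Number of classes for quantile/equal breaks.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_choropleth <- function(geo, layer, fill, breaks = c("quantile", "equal",
                                                         "exceedance"),
                            n_breaks = 5, title = NULL) {
  breaks <- match.arg(breaks)
  if (!fill %in% names(layer)) abort(sprintf("Column `%s` not found in `layer`.", fill))
  extra <- setdiff(layer$ward_id, geo$wards$ward_id)
  if (length(extra)) {
    abort(sprintf("Ward(s) in layer but not in geometry: %s.",
                  paste(extra, collapse = ", ")))
  }
  values <- layer[[fill]][match(geo$wards$ward_id, layer$ward_id)]
  classed <- classify_layer(values, breaks, n_breaks)
  df <- dplyr::left_join(
    geo$polygons,
    tibble::tibble(ward_id = geo$wards$ward_id, .class = classed),
    by = "ward_id"
  )
  centroids <- geo$polygons |>
    dplyr::group_by(.data$ward_id) |>
    dplyr::summarise(x = mean(.data$x[-1]), y = mean(.data$y[-1]),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$ward_id,
                                   fill = .data$.class)) +
    ggplot2::geom_polygon(colour = "grey25", linewidth = 0.3) +
    ggplot2::geom_text(data = centroids,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$ward_id),
                       inherit.aes = FALSE, size = 3) +
    ggplot2::scale_fill_brewer(palette = if (breaks == "exceedance") "OrRd" else "YlGnBu",
                               na.value = "grey85", drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = fill, title = title) +
    ggplot2::theme_void()
}

classify_layer <- function(values, breaks, n_breaks) {
  finite <- values[!is.na(values)]
  if (breaks == "exceedance") {
    return(cut(values, breaks = c(-Inf, 0.8 - 1e-12, Inf),
               labels = c("< 0.8", ">= 0.8")))
  }
  if (length(unique(finite)) <= 1) {
    return(factor(ifelse(is.na(values), NA, format(signif(values, 4)))))
  }
  brk <- if (breaks == "quantile") {
    unique(quantile(finite, probs = seq(0, 1, length.out = n_breaks + 1)))
  } else {
    seq(min(finite), max(finite), length.out = n_breaks + 1)
  }
  cut(values, breaks = brk, include.lowest = TRUE, dig.lab = 3)
}

#' Render a choropleth to file with a sidecar CSV
#'
#' Writes the map as PNG and the plotted values as a `ward_id,value` CSV
#' sidecar next to it, so every mapped value is traceable to (and
#' re-parseable from) a text file.
#'
#' @inheritParams plot_choropleth
#' @param out_path PNG output path; the sidecar CSV replaces the extension.
#' @param width,height Device size in inches.
#' @return Invisible named character vector of the two paths.
#' @export
render_choropleth <- function(geo, layer, fill, out_path,
                              breaks = "quantile", n_breaks = 5,
                              title = NULL, width = 6, height = 5) {
  p <- plot_choropleth(geo, layer, fill, breaks = breaks,
                       n_breaks = n_breaks, title = title)
  ggplot2::ggsave(out_path, p, width = width, height = height, dpi = 150)
  csv_path <- sub("\\.[A-Za-z]+$", ".csv", out_path)
  utils::write.csv(
    data.frame(ward_id = layer$ward_id, value = layer[[fill]]),
    csv_path, row.names = FALSE)
  invisible(c(image = out_path, sidecar = csv_path))
}

#' Ward RR and exceedance maps for a fitted model
#'
#' Draws the presentation-layer panels for a fit: the ward relative rates
#' (quantile classes) and the exceedance probabilities (binary emphasis at
#' 0.8).
#'
#' @param object A `dm_fit` or `ml_fit`.
#' @param geo The `ward_geography` the data were simulated from / mapped to.
#' @param type `"rr"` or `"exceedance"`.
#' @param ... Passed to [plot_choropleth()].
#' @return A ggplot object.
#' @export
autoplot.dm_fit <- function(object, geo, type = c("rr", "exceedance"), ...) {
  plot_fit_map(object, geo, match.arg(type), ...)
}

#' @rdname autoplot.dm_fit
#' @export
autoplot.ml_fit <- function(object, geo, type = c("rr", "exceedance"), ...) {
  plot_fit_map(object, geo, match.arg(type), ...)
}

plot_fit_map <- function(fit, geo, type, ...) {
  rr <- rr_summaries(fit, force = TRUE)
  wards <- rr[rr$type == "ward", ]
  layer <- tibble::tibble(
    ward_id = as.integer(sub("ward_", "", wards$term)),
    rr = wards$rr, exceedance = wards$exceedance
  )
  if (type == "rr") {
    plot_choropleth(geo, layer, "rr", breaks = "quantile",
                    title = "Ward relative rate", ...)
  } else {
    plot_choropleth(geo, layer, "exceedance", breaks = "exceedance",
                    title = "Pr(RR > 1)", ...)
  }
}

#' Assemble a Markdown report from a pipeline run directory
#'
#' Collates the descriptive table, both models' RR tables and DIC ledgers,
#' the diagnostics summary and the rendered maps into one self-contained
#' Markdown report. Every number in the report is read back from the run's
#' CSV/JSON outputs, never recomputed, so the report is traceable to the
#' artifacts; a missing input produces an explicit gap notice instead of a
#' failure. Output is byte-identical across re-runs on identical inputs.
#'
#' @param run_dir Pipeline output directory.
#' @param out_file Report path (default `report.md` inside `run_dir`).
#' @return The report path, invisibly.
#' @export
build_report <- function(run_dir, out_file = file.path(run_dir, "report.md")) {
  lines <- c("# SDQ spatiotemporal analysis report", "")
  add_csv <- function(lines, path, heading) {
    lines <- c(lines, paste("##", heading), "")
    full <- file.path(run_dir, path)
    if (!file.exists(full)) {
      return(c(lines, sprintf("*Gap: expected output `%s` was not found.*", path), ""))
    }
    df <- utils::read.csv(full, check.names = FALSE)
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 5))
    c(lines, df_to_markdown(df), "")
  }
  lines <- add_csv(lines, "descriptives.csv", "Descriptive table")
  lines <- add_csv(lines, "exclusions.csv", "Exclusion tally")
  lines <- add_csv(lines, "dm_rr.csv", "Disease-mapping model: relative rates (adjusted)")
  lines <- add_csv(lines, "dm_rr_unadjusted.csv", "Disease-mapping model: relative rates (unadjusted)")
  lines <- add_csv(lines, "dm_dic_ledger.csv", "Disease-mapping model: DIC ledger")
  lines <- add_csv(lines, "ml_rr.csv", "Multilevel model: relative rates (adjusted)")
  lines <- add_csv(lines, "ml_rr_unadjusted.csv", "Multilevel model: relative rates (unadjusted)")
  lines <- add_csv(lines, "ml_variances.csv", "Multilevel model: variance components")
  lines <- add_csv(lines, "ml_dic_ledger.csv", "Multilevel model: DIC ledger")

  lines <- c(lines, "## Diagnostics", "")
  diag_path <- file.path(run_dir, "diagnostics.json")
  if (file.exists(diag_path)) {
    d <- jsonlite::read_json(diag_path)
    lines <- c(lines, vapply(names(d), function(k) {
      sprintf("- %s: %s", k, paste(format(unlist(d[[k]])), collapse = ", "))
    }, character(1)), "")
  } else {
    lines <- c(lines, "*Gap: diagnostics.json not found.*", "")
  }

  maps <- sort(list.files(run_dir, pattern = "^map_.*\\.png$"))
  lines <- c(lines, "## Maps", "")
  if (length(maps)) {
    lines <- c(lines, sprintf("![%s](%s)", sub("\\.png$", "", maps), maps), "")
  } else {
    lines <- c(lines, "*Gap: no rendered maps found.*", "")
  }
  writeLines(lines, out_file)
  invisible(out_file)
}

df_to_markdown <- function(df) {
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(trimws(r), collapse = " | "), " |"))
  c(hdr, sep, rows)
}
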