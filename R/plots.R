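# Bullseye and cross-correlation figures. All figure data is tabular and
# attached to the ggplot object so tests assert numbers, not pixels.

# wedge geometry: 9 angular sectors of 40 degrees in the fixed lobe order,
# ring edges at the depth-layer bin boundaries (0, .25, .5, .75, 1)
bullseye_geometry <- function(values, value_col = "rho",
                              significant_col = NULL, n_layers = 4L) {
  lookup <- bullseye_region_lookup(n_layers)
  if (!"region_id" %in% names(values)) {
    if ("region" %in% names(values)) {
      values <- dplyr::left_join(values,
                                 lookup[, c("region", "region_id")], by = "region")
    } else {
      rlang::abort("values need a region_id or region column",
                   class = "bullseye_parameter_error")
    }
  }
  if (nrow(values) != nrow(lookup) ||
      !setequal(values$region_id, lookup$region_id)) {
    rlang::abort(sprintf("expected exactly %d region values", nrow(lookup)),
                 class = "bullseye_parameter_error")
  }
  sig <- if (is.null(significant_col)) rep(TRUE, nrow(values)) else values[[significant_col]]
  lookup |>
    dplyr::left_join(
      tibble::tibble(region_id = values$region_id,
                     value = values[[value_col]],
                     significant = sig),
      by = "region_id") |>
    dplyr::mutate(
      sector = match(.data$lobe, .lobe_levels),
      xmin = (.data$sector - 1) * 360 / 9,
      xmax = .data$sector * 360 / 9,
      ymin = (.data$layer - 1) / n_layers,
      ymax = .data$layer / n_layers
    )
}

#' Bullseye plot of 36 regional values
#'
#' Polar plot with nine 40-degree angular sectors in the fixed order
#' FR, FL, TR, TL, PR, PL, OR, OL, BG and four concentric rings whose radii
#' are the depth-layer bin edges; the innermost ring is the most
#' periventricular layer. Non-significant cells are rendered in a neutral
#' beige.
#'
#' @param values Tibble with `region_id` (or `region`) and the value column.
#' @param value_col Column to colour by (default `"rho"`).
#' @param significant_col Optional logical column; FALSE cells are neutral.
#' @param limits Colour scale limits (default symmetric around 0).
#' @param neutral_colour Fill for non-significant cells.
#' @param title Plot title.
#' @return A ggplot object; its `data` holds the wedge geometry.
#' @export
plot_bullseye <- function(values, value_col = "rho", significant_col = NULL,
                          limits = NULL, neutral_colour = "#f2e8cf",
                          title = NULL) {
  geo <- bullseye_geometry(values, value_col, significant_col)
  if (is.null(limits)) {
    m <- max(abs(geo$value[geo$significant]), 0.01, na.rm = TRUE)
    limits <- c(-m, m)
  }
  geo$fill_value <- ifelse(geo$significant, geo$value, NA_real_)
  lab <- tibble::tibble(
    x = (seq_len(9) - 0.5) * 40, y = 1.12, lobe = .lobe_levels)
  ggplot2::ggplot(geo) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                                    ymin = .data$ymin, ymax = .data$ymax,
                                    fill = .data$fill_value),
                       colour = "white", linewidth = 0.3) +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$lobe),
                       size = 3) +
    ggplot2::coord_polar(theta = "x", start = 0) +
    ggplot2::scale_x_continuous(limits = c(0, 360), breaks = NULL) +
    ggplot2::scale_y_continuous(limits = c(0, 1.15), breaks = NULL) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = limits, na.value = neutral_colour,
                                  name = value_col) +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Render a bullseye figure to disk
#'
#' Writes SVG and PNG versions plus a CSV of the wedge data, so downstream
#' checks can assert numbers rather than pixels.
#'
#' @inheritParams plot_bullseye
#' @param file Output path without extension.
#' @return The ggplot, invisibly.
#' @export
render_bullseye <- function(values, file, value_col = "rho",
                            significant_col = NULL, ...) {
  p <- plot_bullseye(values, value_col, significant_col, ...)
  ggplot2::ggsave(paste0(file, ".svg"), p, width = 6, height = 6,
                  device = grDevices::svg)
  ggplot2::ggsave(paste0(file, ".png"), p, width = 6, height = 6, dpi = 150)
  utils::write.csv(p$data, paste0(file, ".csv"), row.names = FALSE)
  invisible(p)
}

#' Plot a cognitive cross-correlation matrix
#'
#' Lower triangle shows Pearson r, upper triangle shows p-values with
#' non-significant cells greyed out, diagonal is labelled.
#'
#' @param x A `wmh_xcor` from [cross_correlation()].
#' @param alpha Significance threshold for greying the upper triangle.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wmh_xcor
#' @export
autoplot.wmh_xcor <- function(x, alpha = 0.05, ...) {
  cn <- x$columns
  k <- length(cn)
  grid <- expand.grid(i = seq_len(k), j = seq_len(k))
  dat <- tibble::tibble(
    row = grid$i, col = grid$j,
    measure_row = cn[grid$i], measure_col = cn[grid$j],
    r = x$r[cbind(grid$i, grid$j)],
    p = x$p[cbind(grid$i, grid$j)]
  ) |>
    dplyr::mutate(
      panel = dplyr::case_when(row > col ~ "r", row < col ~ "p", TRUE ~ "diag"),
      shown = dplyr::case_when(
        panel == "r" ~ .data$r,
        panel == "p" & .data$p < alpha ~ .data$p,
        TRUE ~ NA_real_)
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(data = ~ dplyr::filter(.x, .data$panel == "r"),
                       ggplot2::aes(fill = .data$shown), colour = "grey90") +
    ggplot2::geom_tile(data = ~ dplyr::filter(.x, .data$panel == "p"),
                       ggplot2::aes(alpha = -log10(pmax(.data$shown, 1e-16))),
                       fill = "#d7301f", colour = "grey90", na.rm = TRUE) +
    ggplot2::geom_tile(data = ~ dplyr::filter(.x, .data$panel == "p" & is.na(.data$shown)),
                       fill = "grey80", colour = "grey90") +
    ggplot2::geom_text(data = ~ dplyr::filter(.x, .data$panel == "diag"),
                       ggplot2::aes(label = .data$measure_row),
                       size = 2, angle = 45) +
    ggplot2::scale_y_reverse(breaks = seq_len(k), labels = cn) +
    ggplot2::scale_x_continuous(breaks = NULL) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", high = "#b2182b",
                                  limits = c(-1, 1), name = "r") +
    ggplot2::scale_alpha_continuous(range = c(0.2, 1), name = "-log10 p") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 6))
}

#' Render a cross-correlation figure from raw matrices
#'
#' @param r_matrix,p_matrix Square symmetric matrices of identical shape
#'   with matching dimnames.
#' @param file Output path without extension.
#' @return The ggplot, invisibly.
#' @export
render_cross_correlation <- function(r_matrix, p_matrix, file) {
  if (!isTRUE(all.equal(dim(r_matrix), dim(p_matrix))) ||
      nrow(r_matrix) != ncol(r_matrix) ||
      !isTRUE(all.equal(r_matrix, t(r_matrix), tolerance = 1e-8,
                        check.attributes = FALSE))) {
    rlang::abort("matrices must be square, symmetric and of identical shape",
                 class = "bullseye_parameter_error")
  }
  x <- structure(list(r = r_matrix, p = p_matrix,
                      n = matrix(NA_integer_, nrow(r_matrix), ncol(r_matrix)),
                      columns = colnames(r_matrix) %||% paste0("m", seq_len(ncol(r_matrix))),
                      flagged = character()),
                 class = "wmh_xcor")
  p <- autoplot(x)
  ggplot2::ggsave(paste0(file, ".svg"), p, width = 7, height = 6,
                  device = grDevices::svg)
  ggplot2::ggsave(paste0(file, ".png"), p, width = 7, height = 6, dpi = 150)
  utils::write.csv(tidy(x), paste0(file, ".csv"), row.names = FALSE)
  invisible(p)
}

#' Bullseye panel for one outcome of an association map
#'
#' @param x A `wmh_association`.
#' @param outcome Outcome column to display (default first present).
#' @param ... Passed to [plot_bullseye()].
#' @return A ggplot object.
#' @method autoplot wmh_association
#' @export
autoplot.wmh_association <- function(x, outcome = NULL, ...) {
  tb <- tibble::as_tibble(x) |>
    dplyr::filter(grepl("^load_region_", .data$predictor))
  if (is.null(outcome)) outcome <- tb$outcome[1]
  tb <- tb |>
    dplyr::filter(.data$outcome == !!outcome) |>
    dplyr::mutate(region_id = as.integer(sub("^load_region_", "", .data$predictor)))
  plot_bullseye(tb, value_col = "rho", significant_col = "significant",
                title = outcome, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
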