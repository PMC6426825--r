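# Cross-taxa karyotype asymmetry comparison plot.

scatter_markers <- c(echiuran = "circle", sipunculid = "square",
                     polychaete = "triangle", oligochaete = "triangle_open")

#' Karyotype asymmetry scatter across taxa
#'
#' Builds the plot data for a comparative karyotype asymmetry scatter: one
#' point per species, by default L/S ratio on the x axis and mean arm ratio
#' on the y axis (the two quantitative columns of published comparison
#' tables; configurable to any pair of numeric columns, e.g. a Stebbins-style
#' `pct_ar_gt2` vs `ls_ratio` plot when such a column is available). Marker
#' shapes follow the taxon category: filled circle (echiurans), filled square
#' (sipunculids), filled triangle (polychaetes), open triangle (oligochaetes).
#' Species missing either axis value are skipped with a warning.
#'
#' @param summaries data frame of species karyotype summaries, e.g.
#'   [annelid_karyotypes()]; needs `species`, `category` and the two axis
#'   columns.
#' @param x,y names of the axis columns.
#' @param svg optional path; when given the scatter is also rendered to a
#'   deterministic SVG file.
#' @param csv optional path for the plot-data CSV
#'   (`species,category,x,y,marker`).
#' @return An object of class `"asymmetry_scatter"`: the plot-data frame with
#'   columns `species`, `category`, `x`, `y`, `marker` and the axis names in
#'   attribute `"axes"`.
#' @examples
#' sc <- asymmetry_scatter(annelid_karyotypes())
#' head(sc)
#' @export
asymmetry_scatter <- function(summaries, x = "ls_ratio", y = "mean_ar",
                              svg = NULL, csv = NULL) {
  s <- as.data.frame(summaries)
  if (nrow(s) == 0L)
    stop_input("no species summaries supplied")
  for (col in c("species", "category", x, y))
    if (!col %in% names(s))
      stop_input("column '%s' not found in the species summaries", col)
  bad_cat <- setdiff(unique(s$category), names(scatter_markers))
  if (length(bad_cat))
    stop_input("unknown category: %s (expected %s)",
               paste(bad_cat, collapse = ", "),
               paste(names(scatter_markers), collapse = ", "))
  xv <- suppressWarnings(as.numeric(s[[x]]))
  yv <- suppressWarnings(as.numeric(s[[y]]))
  keep <- is.finite(xv) & is.finite(yv)
  if (!any(keep))
    stop_input("no species has both axis values ('%s', '%s')", x, y)
  if (any(!keep))
    warning(sprintf("skipping %d species missing an axis value: %s",
                    sum(!keep), paste(s$species[!keep], collapse = ", ")),
            call. = FALSE)
  out <- data.frame(
    species = s$species[keep],
    category = s$category[keep],
    x = xv[keep], y = yv[keep],
    marker = unname(scatter_markers[s$category[keep]]),
    stringsAsFactors = FALSE
  )
  attr(out, "axes") <- c(x = x, y = y)
  class(out) <- c("asymmetry_scatter", "data.frame")
  if (!is.null(csv)) {
    tab <- out
    names(tab)[3:4] <- c(x, y)
    utils::write.csv(tab, csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(svg))
    write_scatter_svg(out, svg)
  out
}

# map data coordinates to SVG pixels and emit a deterministic scatter plot
write_scatter_svg <- function(sc, path, width = 460, height = 360) {
  axes <- attr(sc, "axes")
  margin <- c(left = 56, right = 18, top = 18, bottom = 48)
  pw <- width - margin["left"] - margin["right"]
  ph <- height - margin["top"] - margin["bottom"]
  xt <- pretty(sc$x); xt <- xt[xt >= min(sc$x) - diff(range(sc$x)) * 0.2 &
                              xt <= max(sc$x) + diff(range(sc$x)) * 0.2]
  yt <- pretty(sc$y); yt <- yt[yt >= min(sc$y) - diff(range(sc$y)) * 0.2 &
                              yt <= max(sc$y) + diff(range(sc$y)) * 0.2]
  xr <- range(c(sc$x, xt)); yr <- range(c(sc$y, yt))
  pad <- function(r) r + c(-1, 1) * diff(r) * 0.06
  xr <- pad(xr); yr <- pad(yr)
  px <- function(v) margin["left"] + (v - xr[1]) / diff(xr) * pw
  py <- function(v) margin["top"] + (yr[2] - v) / diff(yr) * ph

  el <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            width, height, width, height),
    '<rect width="100%" height="100%" fill="white"/>',
    sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="none" stroke="black"/>',
            fmt_px(margin["left"]), fmt_px(margin["top"]), fmt_px(pw), fmt_px(ph))
  )
  for (v in xt)
    el <- c(el,
            sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
                    fmt_px(px(v)), fmt_px(margin["top"] + ph),
                    fmt_px(px(v)), fmt_px(margin["top"] + ph + 5)),
            sprintf('<text x="%s" y="%s" font-size="11" font-family="sans-serif" text-anchor="middle">%s</text>',
                    fmt_px(px(v)), fmt_px(margin["top"] + ph + 18), format(v)))
  for (v in yt)
    el <- c(el,
            sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black"/>',
                    fmt_px(margin["left"] - 5), fmt_px(py(v)),
                    fmt_px(margin["left"]), fmt_px(py(v))),
            sprintf('<text x="%s" y="%s" font-size="11" font-family="sans-serif" text-anchor="end">%s</text>',
                    fmt_px(margin["left"] - 8), fmt_px(py(v) + 4), format(v)))
  el <- c(el,
          sprintf('<text x="%s" y="%s" font-size="12" font-family="sans-serif" text-anchor="middle">%s</text>',
                  fmt_px(margin["left"] + pw / 2), fmt_px(height - 12), axes[["x"]]),
          sprintf('<text x="%s" y="%s" font-size="12" font-family="sans-serif" text-anchor="middle" transform="rotate(-90 14 %s)">%s</text>',
                  "14", fmt_px(margin["top"] + ph / 2),
                  fmt_px(margin["top"] + ph / 2), axes[["y"]]))
  for (i in seq_len(nrow(sc))) {
    cx <- px(sc$x[i]); cy <- py(sc$y[i])
    el <- c(el, switch(
      sc$marker[i],
      circle = sprintf('<circle cx="%s" cy="%s" r="5" fill="black"/>',
                       fmt_px(cx), fmt_px(cy)),
      square = sprintf('<rect x="%s" y="%s" width="9" height="9" fill="black"/>',
                       fmt_px(cx - 4.5), fmt_px(cy - 4.5)),
      triangle = sprintf('<path d="M %s %s L %s %s L %s %s Z" fill="black"/>',
                         fmt_px(cx), fmt_px(cy - 5.5), fmt_px(cx - 5),
                         fmt_px(cy + 4.5), fmt_px(cx + 5), fmt_px(cy + 4.5)),
      triangle_open = sprintf('<path d="M %s %s L %s %s L %s %s Z" fill="white" stroke="black"/>',
                              fmt_px(cx), fmt_px(cy - 5.5), fmt_px(cx - 5),
                              fmt_px(cy + 4.5), fmt_px(cx + 5), fmt_px(cy + 4.5))
    ))
  }
  el <- c(el, "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(el, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Plot method for the asymmetry scatter
#'
#' @param x an `"asymmetry_scatter"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.asymmetry_scatter <- function(x, ...) {
  axes <- attr(x, "axes")
  pch_map <- c(circle = 19, square = 15, triangle = 17, triangle_open = 2)
  graphics::plot(x$x, x$y, pch = pch_map[x$marker],
                 xlab = axes[["x"]], ylab = axes[["y"]],
                 main = "Karyotype asymmetry", ...)
  graphics::legend("topright", pch = pch_map[names(scatter_markers)],
                   legend = names(scatter_markers), bty = "n")
  invisible(x)
}
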