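# Idiogram construction and rendering.

#' Build an idiogram model from a karyotype
#'
#' Lays out one bar per homolog pair, scaled to relative length and split at
#' the centromere: the short arm is drawn above the centromere line (dark)
#' and the long arm below (grey). Bars are grouped by Levan class (m, sm, st,
#' t) and ordered within a class by pair label (`order = "label"`, the
#' published-table order) or by descending length (`order = "length"`).
#'
#' @param x a `"karyotype"` object (or its `per_chromosome` data frame).
#' @param order within-class ordering, `"label"` or `"length"`.
#' @return An object of class `"idiogram"`: a data frame with one row per
#'   pair (`pair_index`, `label`, `levan_type`, `rl_total`, `rl_short`,
#'   `rl_long`, `position`), arm extents in relative-length units.
#' @examples
#' build_idiogram(karyotype(urechis_arms(), input = "pairs"))
#' @export
build_idiogram <- function(x, order = c("label", "length")) {
  order <- match.arg(order)
  pc <- if (inherits(x, "karyotype")) x$per_chromosome else as.data.frame(x)
  needed <- c("mean_p", "mean_q", "mean_rl_pct", "levan_type")
  if (is.null(pc) || nrow(pc) == 0L || !all(needed %in% names(pc)))
    stop_input("per-chromosome statistics are missing; run karyotype() first")
  frac_short <- pc$mean_p / (pc$mean_p + pc$mean_q)
  model <- data.frame(
    pair_index = pc$pair_index,
    label = pc$label %||% as.character(pc$pair_index),
    levan_type = pc$levan_type,
    rl_total = pc$mean_rl_pct,
    rl_short = pc$mean_rl_pct * frac_short,
    rl_long = pc$mean_rl_pct * (1 - frac_short),
    stringsAsFactors = FALSE
  )
  key <- if (order == "label") order(factor(model$levan_type, levels = levan_types),
                                     model$pair_index)
         else order(factor(model$levan_type, levels = levan_types),
                    -model$rl_total)
  model <- model[key, , drop = FALSE]
  model$position <- seq_len(nrow(model))
  rownames(model) <- NULL
  class(model) <- c("idiogram", "data.frame")
  model
}

#' Render an idiogram to SVG
#'
#' Writes a deterministic, self-contained SVG: identical models produce
#' byte-identical files. Short arms are drawn in near-black above the
#' centromere line, long arms in mid-grey below; bars are labelled with the
#' pair label and grouped by Levan class.
#'
#' @param model an `"idiogram"` model from [build_idiogram()].
#' @param path output file path.
#' @param px_per_rl vertical scale in pixels per relative-length percent.
#' @param short_fill,long_fill bar colours.
#' @return Invisibly, `path`.
#' @export
write_idiogram_svg <- function(model, path, px_per_rl = 28,
                               short_fill = "#1a1a1a", long_fill = "#8c8c8c") {
  if (!inherits(model, "idiogram") || nrow(model) == 0L)
    stop_input("'model' must be a non-empty idiogram model")
  slot <- 34; bar <- 18; margin <- 46; label_space <- 34
  y0 <- margin + max(model$rl_short) * px_per_rl  # centromere line
  width <- 2 * margin + nrow(model) * slot
  height <- y0 + max(model$rl_long) * px_per_rl + label_space + margin

  el <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%s" height="%s" viewBox="0 0 %s %s">',
            fmt_px(width), fmt_px(height), fmt_px(width), fmt_px(height)),
    '<rect width="100%" height="100%" fill="white"/>',
    sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#cccccc" stroke-dasharray="4,3"/>',
            fmt_px(margin - 10), fmt_px(y0), fmt_px(width - margin + 10), fmt_px(y0))
  )
  for (i in seq_len(nrow(model))) {
    x <- margin + (model$position[i] - 1) * slot + (slot - bar) / 2
    hs <- model$rl_short[i] * px_per_rl
    hl <- model$rl_long[i] * px_per_rl
    if (hs > 0)
      el <- c(el, sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
                          fmt_px(x), fmt_px(y0 - hs), fmt_px(bar), fmt_px(hs),
                          short_fill))
    el <- c(el, sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"/>',
                        fmt_px(x), fmt_px(y0), fmt_px(bar), fmt_px(hl), long_fill))
    el <- c(el, sprintf('<text x="%s" y="%s" font-size="11" font-family="sans-serif" text-anchor="middle">%s</text>',
                        fmt_px(x + bar / 2),
                        fmt_px(y0 + max(model$rl_long) * px_per_rl + 16),
                        model$label[i]))
  }
  # one group caption per Levan class present
  for (tp in unique(model$levan_type)) {
    pos <- model$position[model$levan_type == tp]
    xc <- margin + (mean(range(pos)) - 0.5) * slot
    el <- c(el, sprintf('<text x="%s" y="%s" font-size="12" font-family="sans-serif" font-style="italic" text-anchor="middle">%s</text>',
                        fmt_px(xc),
                        fmt_px(y0 + max(model$rl_long) * px_per_rl + 30), tp))
  }
  el <- c(el, "</svg>")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(el, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Plot an idiogram with base graphics
#'
#' @param x an `"idiogram"` model.
#' @param short_col,long_col arm colours.
#' @param ... further arguments passed to [graphics::plot()].
#' @export
plot.idiogram <- function(x, short_col = "grey10", long_col = "grey55", ...) {
  n <- nrow(x)
  ymax <- max(x$rl_short)
  ymin <- -max(x$rl_long)
  graphics::plot(NA, xlim = c(0.5, n + 0.5), ylim = c(ymin * 1.25, ymax * 1.1),
                 xlab = "", ylab = "relative length (%)", xaxt = "n",
                 main = "Idiogram", ...)
  graphics::abline(h = 0, col = "grey70", lty = 3)
  for (i in seq_len(n)) {
    if (x$rl_short[i] > 0)
      graphics::rect(i - 0.3, 0, i + 0.3, x$rl_short[i], col = short_col,
                     border = NA)
    graphics::rect(i - 0.3, -x$rl_long[i], i + 0.3, 0, col = long_col,
                   border = NA)
  }
  graphics::axis(1, at = seq_len(n), labels = x$label, cex.axis = 0.8)
  graphics::mtext(x$levan_type, side = 1, line = 2.2, at = seq_len(n),
                  cex = 0.7, font = 3)
  invisible(x)
}
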