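#' 10-20 head layout for the seven-channel frontoparietal montage
#'
#' 2D projection of the standard electrode positions onto a unit head
#' circle (nose up, +y anterior, +x right). Coordinates are the usual
#' schematic 10-20 projection values; homologous left/right pairs are
#' mirror-symmetric.
#'
#' @return data frame with `channel`, `x`, `y`.
#' @export
head_layout_1020 <- function() {
  data.frame(
    channel = c("Fp1", "Fp2", "F3", "F4", "P3", "P4", "Cz"),
    x = c(-0.27, 0.27, -0.35, 0.35, -0.35, 0.35, 0),
    y = c(0.83, 0.83, 0.45, 0.45, -0.45, -0.45, 0))
}

svg_num <- function(v) sprintf("%.4f", v)

#' Render a dominant information flow on a 2D head map
#'
#' Draws the head outline, marks source-group channels in blue and
#' target-group channels in red, and draws one arrow from the source
#' centroid to the target centroid whose stroke width is proportional to
#' the transfer-entropy value (`width = scale * value`); a zero value
#' omits the arrow. Output is deterministic SVG text: identical inputs
#' give byte-identical files.
#'
#' @param source,target character vectors of channel names (disjoint).
#' @param value transfer entropy in nats (>= 0).
#' @param path output SVG path.
#' @param layout head layout data frame (default [head_layout_1020()]).
#' @param scale arrow width per nat (default 0.2 head-radius units).
#' @return `path`, invisibly.
#' @export
render_flow <- function(source, target, value, path,
                        layout = head_layout_1020(), scale = 0.2) {
  miss <- setdiff(c(source, target), layout$channel)
  if (length(miss)) stop("unknown channels: ", paste(miss, collapse = ", "))
  if (value < 0) stop("value must be non-negative")
  pos <- function(ch) layout[match(ch, layout$channel), c("x", "y")]
  lines <- c(
    '<svg xmlns="http://www.w3.org/2000/svg" width="400" height="440" viewBox="-1.3 -1.4 2.6 2.8">',
    '<g transform="scale(1,-1)">',
    '<circle cx="0" cy="0" r="1" fill="none" stroke="black" stroke-width="0.02"/>',
    '<path d="M -0.12 0.993 L 0 1.12 L 0.12 0.993" fill="none" stroke="black" stroke-width="0.02"/>')
  for (i in seq_len(nrow(layout))) {
    ch <- layout$channel[i]
    fill <- if (ch %in% source) "#4575b4"
            else if (ch %in% target) "#d73027" else "#cccccc"
    lines <- c(lines, sprintf(
      '<circle cx="%s" cy="%s" r="0.11" fill="%s" stroke="black" stroke-width="0.01"/>',
      svg_num(layout$x[i]), svg_num(layout$y[i]), fill))
  }
  if (value > 0) {
    cs <- colMeans(pos(source))
    ct <- colMeans(pos(target))
    # shorten the arrow so the head does not sit inside an electrode disc
    v <- ct - cs
    len <- sqrt(sum(v^2))
    if (len > 0) {
      ct_draw <- cs + v * max(0, (len - 0.14)) / len
      u <- v / len
      n_ <- c(-u[2], u[1])
      h1 <- ct_draw - 0.1 * u + 0.06 * n_
      h2 <- ct_draw - 0.1 * u - 0.06 * n_
      lines <- c(lines, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="black" stroke-width="%s"/>',
        svg_num(cs[1]), svg_num(cs[2]), svg_num(ct_draw[1]),
        svg_num(ct_draw[2]), svg_num(scale * value)),
        sprintf('<path d="M %s %s L %s %s L %s %s Z" fill="black"/>',
                svg_num(h1[1]), svg_num(h1[2]), svg_num(ct_draw[1]),
                svg_num(ct_draw[2]), svg_num(h2[1]), svg_num(h2[2])))
    }
  }
  for (i in seq_len(nrow(layout))) {
    lines <- c(lines, sprintf(
      '<text x="%s" y="%s" transform="scale(1,-1)" font-size="0.09" text-anchor="middle">%s</text>',
      svg_num(layout$x[i]), svg_num(-(layout$y[i] + 0.16)),
      layout$channel[i]))
  }
  lines <- c(lines, "</g>", "</svg>")
  writeLines(lines, path)
  invisible(path)
}
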