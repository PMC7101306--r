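# Pixel geometry of the colour-block canvas.
#
# The published design fixes the canvas (871 x 494 px), the content (two
# bilaterally symmetrical hand panels of 15 cruciform joint blocks each,
# plus 14 numbered clinical squares) and the cruciform sub-square labels
# a-e, but shows the exact pixel coordinates only graphically. The default
# layout below is therefore an explicit, versioned stand-in: right-hand
# panel laid out site-by-site, left-hand panel its exact horizontal mirror,
# clinical squares in two rows of seven beneath. Every block is at least
# 14 px wide so it survives nearest-neighbour downscaling to the default
# classifier input resolution.

#' Default canvas layout
#'
#' Builds the shipped 871 x 494 layout: for each side, 15 cruciform joint
#' blocks (3x3 arrangement of 26 px sub-squares: channel a on top, b left,
#' c centre, d right, e bottom; b/d mirrored on the left hand), and the 14
#' clinical squares (60 px) in two rows of seven in the published field
#' order. The left-hand panel is the pixel-exact horizontal mirror of the
#' right-hand panel.
#'
#' @return A list of class `tda_layout` with elements `canvas`
#'   (named width/height), `blocks` (data.frame `field, kind, x0, y0, x1,
#'   y1`, 1-based inclusive pixel bounds) and `version`.
#' @seealso [validate_layout()], [render_tda()]
#' @export
default_layout <- function() {
  W <- 871L; H <- 494L
  s <- 26L          # cruciform sub-square edge
  gap <- 8L         # gap between cruciform blocks
  block <- 3L * s   # cruciform bounding box

  sites <- tda_sites()
  rows <- list(sites[1:5], sites[6:10], sites[11:15])

  # right-hand panel; the left is its mirror about the canvas centre
  panel_w <- 5L * block + 4L * gap             # 422
  x_right <- W - 6L - panel_w + 1L             # 444
  y_top <- 10L

  sub_offsets <- list(a = c(s, 0L), b = c(0L, s), c = c(s, s),
                      d = c(2L * s, s), e = c(s, 2L * s))

  out <- list()
  for (r in seq_along(rows)) {
    for (cidx in seq_along(rows[[r]])) {
      site <- rows[[r]][cidx]
      bx <- x_right + (cidx - 1L) * (block + gap)
      by <- y_top + (r - 1L) * (block + gap)
      for (letter in names(sub_offsets)) {
        off <- sub_offsets[[letter]]
        x0 <- bx + off[1]; y0 <- by + off[2]
        out[[length(out) + 1L]] <- data.frame(
          field = paste("J", "right", site, letter, sep = "_"),
          kind = "joint", x0 = x0, y0 = y0,
          x1 = x0 + s - 1L, y1 = y0 + s - 1L)
        # mirror for the left hand: x' = W + 1 - x
        out[[length(out) + 1L]] <- data.frame(
          field = paste("J", "left", site, letter, sep = "_"),
          kind = "joint", x0 = W + 1L - (x0 + s - 1L), y0 = y0,
          x1 = W + 1L - x0, y1 = y0 + s - 1L)
      }
    }
  }

  sq <- 60L; sq_gap <- 10L
  row_w <- 7L * sq + 6L * sq_gap               # 480
  x_sq <- (W - row_w) %/% 2L + 1L              # 196
  y_rows <- c(306L, 396L)
  fields <- tda_clinical_fields()
  for (i in seq_along(fields)) {
    rr <- if (i <= 7) 1L else 2L
    cc <- if (i <= 7) i else i - 7L
    x0 <- x_sq + (cc - 1L) * (sq + sq_gap)
    y0 <- y_rows[rr]
    out[[length(out) + 1L]] <- data.frame(
      field = fields[i], kind = "clinical", x0 = x0, y0 = y0,
      x1 = x0 + sq - 1L, y1 = y0 + sq - 1L)
  }

  blocks <- do.call(rbind, out)
  rownames(blocks) <- blocks$field
  structure(list(canvas = c(width = W, height = H), blocks = blocks,
                 version = "default-1"),
            class = "tda_layout")
}

#' Validate a layout
#'
#' Checks that all rectangles lie within the canvas, that no two overlap,
#' and that the left-hand joint blocks are the exact horizontal mirror of
#' the right-hand ones.
#'
#' @param layout a `tda_layout`.
#' @return Character vector of violations (empty if valid).
#' @export
validate_layout <- function(layout) {
  v <- character(0)
  b <- layout$blocks
  W <- layout$canvas[["width"]]; H <- layout$canvas[["height"]]
  bad_bounds <- b$x0 < 1 | b$y0 < 1 | b$x1 > W | b$y1 > H | b$x0 > b$x1 |
    b$y0 > b$y1
  for (f in b$field[bad_bounds]) {
    v <- c(v, sprintf("block %s outside canvas or degenerate", f))
  }
  n <- nrow(b)
  for (i in seq_len(n - 1)) {
    ov <- b$x0[i] <= b$x1[(i + 1):n] & b$x1[i] >= b$x0[(i + 1):n] &
      b$y0[i] <= b$y1[(i + 1):n] & b$y1[i] >= b$y0[(i + 1):n]
    for (j in which(ov)) {
      v <- c(v, sprintf("blocks %s and %s overlap", b$field[i],
                        b$field[i + j]))
    }
  }
  jr <- b[b$kind == "joint" & grepl("^J_right_", b$field), ]
  for (i in seq_len(nrow(jr))) {
    lf <- sub("^J_right_", "J_left_", jr$field[i])
    lb <- b[b$field == lf, ]
    if (nrow(lb) != 1 ||
        lb$x0 != W + 1 - jr$x1[i] || lb$x1 != W + 1 - jr$x0[i] ||
        lb$y0 != jr$y0[i] || lb$y1 != jr$y1[i]) {
      v <- c(v, sprintf("%s is not the mirror of %s", lf, jr$field[i]))
    }
  }
  v
}

#' Read or write a layout as a versioned YAML file
#'
#' @param path YAML file.
#' @return `read_layout()`: a `tda_layout`; `write_layout()`: the path,
#'   invisibly.
#' @export
read_layout <- function(path) {
  y <- yaml::read_yaml(path)
  blocks <- do.call(rbind, lapply(y$blocks, function(r) {
    data.frame(field = r$field, kind = r$kind, x0 = r$x0, y0 = r$y0,
               x1 = r$x1, y1 = r$y1)
  }))
  rownames(blocks) <- blocks$field
  structure(list(canvas = c(width = y$canvas$width,
                            height = y$canvas$height),
                 blocks = blocks, version = as.character(y$version)),
            class = "tda_layout")
}

#' @rdname read_layout
#' @param layout a `tda_layout`.
#' @export
write_layout <- function(layout, path) {
  y <- list(version = layout$version,
            canvas = list(width = unname(layout$canvas[["width"]]),
                          height = unname(layout$canvas[["height"]])),
            blocks = lapply(seq_len(nrow(layout$blocks)), function(i) {
              as.list(layout$blocks[i, ])
            }))
  yaml::write_yaml(y, path)
  invisible(path)
}
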