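# Rendering patient records as colour-block rasters and decoding them back.
#
# A rendered image is an integer array (height x width x 3, values 0-255)
# and a pure function of (record, rules, palette, layout): byte-identical
# across runs. The decoder inverts the renderer block-by-block by nearest
# palette colour, which makes render/decode round trips a testable property
# of the whole encoder.

#' Render a patient record as a colour-block image
#'
#' Every layout block is filled with the palette colour of its field's
#' category under `rules`; all other pixels take the background colour.
#'
#' @param record a validated [patient_record()].
#' @param rules discretization rules ([default_rules()]).
#' @param palette colour palette ([default_palette()]).
#' @param layout canvas layout ([default_layout()]).
#' @param missing_policy what to do when a field value is `NA`: `"error"`
#'   (default) or `"grey"` (fill with the missing colour and warn).
#' @return An integer array of class `tda_image`, dim `c(height, width, 3)`,
#'   with `patient_id`, `layout_version` and `rules_version` attributes.
#' @export
render_tda <- function(record, rules = default_rules(),
                       palette = default_palette(),
                       layout = default_layout(),
                       missing_policy = c("error", "grey")) {
  missing_policy <- match.arg(missing_policy)
  W <- layout$canvas[["width"]]; H <- layout$canvas[["height"]]
  cats <- discretize_record(record, rules)
  if (missing_policy == "error" && any(cats == "missing")) {
    stop("missing value in field(s): ",
         paste(names(cats)[cats == "missing"], collapse = ", "))
  }
  if (any(cats == "missing")) {
    warning("missing value(s) rendered grey: ",
            paste(names(cats)[cats == "missing"], collapse = ", "),
            call. = FALSE)
  }
  bg <- as.integer(palette$background)
  img <- array(rep(bg, each = H * W), dim = c(H, W, 3))
  b <- layout$blocks
  for (i in seq_len(nrow(b))) {
    col <- palette[[cats[[b$field[i]]]]]
    for (d in 1:3) {
      img[b$y0[i]:b$y1[i], b$x0[i]:b$x1[i], d] <- col[d]
    }
  }
  structure(img, class = "tda_image",
            patient_id = record$patient_id,
            layout_version = layout$version,
            rules_version = attr(rules, "version"))
}

#' @export
print.tda_image <- function(x, ...) {
  cat(sprintf("<tda_image %s> %d x %d px (layout %s, rules %s)\n",
              attr(x, "patient_id"), dim(x)[2], dim(x)[1],
              attr(x, "layout_version"), attr(x, "rules_version")))
  invisible(x)
}

#' Decode a colour-block image back to field categories
#'
#' For each layout block, takes the mean colour of the block's centre
#' region (the middle half in each dimension) and assigns the nearest
#' palette colour (Euclidean RGB). A block whose colour is farther than
#' half the minimum pairwise palette distance from every palette colour is
#' an error: the image does not come from this palette/layout.
#'
#' @param image a `tda_image` or any height x width x 3 array (0-255).
#' @param layout canvas layout; dimensions must match the image.
#' @param palette colour palette.
#' @return Named character vector: one category per layout block field.
#' @export
decode_tda <- function(image, layout = default_layout(),
                       palette = default_palette()) {
  H <- dim(image)[1]; W <- dim(image)[2]
  if (W != layout$canvas[["width"]] || H != layout$canvas[["height"]]) {
    stop(sprintf("image is %d x %d but layout canvas is %d x %d",
                 W, H, layout$canvas[["width"]], layout$canvas[["height"]]))
  }
  # blocks are never filled with the background colour: a block that
  # decodes nearest to background is an empty/unrecognized block
  pm <- palette_matrix(palette[setdiff(names(palette), "background")])
  tol <- palette_min_distance(palette) / 2
  b <- layout$blocks
  out <- stats::setNames(character(nrow(b)), b$field)
  for (i in seq_len(nrow(b))) {
    # centre region: middle half of the block in each dimension
    qx <- (b$x1[i] - b$x0[i] + 1) %/% 4
    qy <- (b$y1[i] - b$y0[i] + 1) %/% 4
    xs <- (b$x0[i] + qx):(b$x1[i] - qx)
    ys <- (b$y0[i] + qy):(b$y1[i] - qy)
    mu <- c(mean(image[ys, xs, 1]), mean(image[ys, xs, 2]),
            mean(image[ys, xs, 3]))
    d2 <- sqrt(colSums((t(pm) - mu)^2))
    j <- which.min(d2)
    if (d2[j] > tol) {
      stop(sprintf("unrecognized colour in block %s (distance %.1f)",
                   b$field[i], d2[j]))
    }
    out[i] <- rownames(pm)[j] %||% names(palette)[j]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split an image (or record) into its ablation variants
#'
#' Reproduces the two-image ablation: `cruciform_only` keeps the 30 joint
#' blocks and fills the 14 clinical squares with background;
#' `clinical_only` does the reverse. The two variants partition the
#' non-background content of the full image.
#'
#' @param x a `tda_image` or a [patient_record()] (which is rendered first).
#' @param mode `"cruciform_only"` or `"clinical_only"`.
#' @param rules,palette,layout encoder configuration (used when `x` is a
#'   record; `palette`/`layout` also drive the masking).
#' @return A `tda_image` of the same canvas size.
#' @export
split_ablation <- function(x, mode = c("cruciform_only", "clinical_only"),
                           rules = default_rules(),
                           palette = default_palette(),
                           layout = default_layout()) {
  mode <- match.arg(mode)
  img <- if (inherits(x, "tda_patient")) {
    render_tda(x, rules, palette, layout)
  } else if (is.array(x) && length(dim(x)) == 3) {
    x
  } else {
    stop("x must be a tda_image or a patient record")
  }
  drop_kind <- if (mode == "cruciform_only") "clinical" else "joint"
  b <- layout$blocks[layout$blocks$kind == drop_kind, ]
  bg <- palette$background
  for (i in seq_len(nrow(b))) {
    for (d in 1:3) img[b$y0[i]:b$y1[i], b$x0[i]:b$x1[i], d] <- bg[d]
  }
  img
}

#' Write an image to a lossless TIFF or PNG file
#'
#' @param image a `tda_image` (integer array 0-255).
#' @param path destination; extension chooses the format when `format` is
#'   `"auto"`.
#' @param format `"tiff"`, `"png"`, or `"auto"`.
#' @return The path, invisibly.
#' @export
write_image <- function(image, path, format = c("auto", "tiff", "png")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png"
              else "tiff"
  }
  arr <- unclass(image) / 255
  attributes(arr) <- list(dim = dim(image))
  if (format == "tiff") {
    tiff::writeTIFF(arr, path, compression = "none")
  } else {
    png::writePNG(arr, path)
  }
  invisible(path)
}

#' Read an image written by [write_image()]
#'
#' @param path a TIFF or PNG file.
#' @return Integer array (height x width x 3, 0-255) of class `tda_image`.
#' @export
read_image <- function(path) {
  arr <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(arr)) == 3 && dim(arr)[3] > 3) arr <- arr[, , 1:3]
  out <- array(as.integer(round(arr * 255)), dim = dim(arr))
  class(out) <- "tda_image"
  out
}

#' Downscale an image by nearest-neighbour sampling
#'
#' Nearest-neighbour (rather than interpolating) resizing keeps every
#' sampled pixel an exact palette colour, which preserves the block
#' structure the classifier consumes.
#'
#' @param image height x width x 3 array.
#' @param width,height target size in pixels.
#' @return Integer array `c(height, width, 3)`.
#' @export
downscale_tda <- function(image, width, height) {
  H <- dim(image)[1]; W <- dim(image)[2]
  ys <- pmin(H, pmax(1, ceiling((seq_len(height) - 0.5) * H / height)))
  xs <- pmin(W, pmax(1, ceiling((seq_len(width) - 0.5) * W / width)))
  out <- unclass(image)[ys, xs, , drop = FALSE]
  class(out) <- "tda_image"
  out
}
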