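# Category -> RGB palette.
#
# The published figure names colours only (green, yellow, orange, red on a
# white background); the shipped RGB values are package defaults chosen so
# that every pair of used colours is at least 100 apart in Euclidean RGB
# distance, which is what lets the decoder identify block colours
# unambiguously even after downscaling or lossless re-encoding.

#' Default colour palette
#'
#' @return Named list of RGB integer triples (0-255) with class
#'   `tda_palette`: the four severity colours plus `background` (white) and
#'   `missing` (grey).
#' @export
default_palette <- function() {
  structure(list(green = c(0L, 176L, 80L),
                 yellow = c(255L, 255L, 0L),
                 orange = c(255L, 140L, 0L),
                 red = c(255L, 0L, 0L),
                 background = c(255L, 255L, 255L),
                 missing = c(128L, 128L, 128L)),
            class = "tda_palette")
}

palette_matrix <- function(palette) {
  do.call(rbind, lapply(palette, as.numeric))
}

#' Minimum pairwise RGB distance of a palette
#'
#' @param palette a `tda_palette`.
#' @return The smallest Euclidean distance between any two palette colours.
#' @export
palette_min_distance <- function(palette) {
  m <- palette_matrix(palette)
  min(stats::dist(m))
}

#' Validate a palette
#'
#' @param palette a named list of RGB triples.
#' @param min_distance required minimum pairwise colour distance (the
#'   decoder needs well-separated colours; default 100).
#' @return Character vector of violations (empty if valid).
#' @export
validate_palette <- function(palette, min_distance = 100) {
  v <- character(0)
  need <- c("green", "yellow", "orange", "red", "background", "missing")
  miss <- setdiff(need, names(palette))
  if (length(miss) > 0) {
    v <- c(v, paste("missing colours:", paste(miss, collapse = ", ")))
  }
  for (nm in names(palette)) {
    x <- palette[[nm]]
    if (length(x) != 3 || any(is.na(x)) || any(x < 0) || any(x > 255)) {
      v <- c(v, sprintf("%s: not an RGB triple in 0-255", nm))
    }
  }
  if (length(v) == 0 && palette_min_distance(palette) < min_distance) {
    v <- c(v, sprintf("minimum pairwise colour distance %.1f below %g",
                      palette_min_distance(palette), min_distance))
  }
  v
}
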