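#' Structuring elements
#'
#' `disk_se()` builds a flat disk-shaped structuring element containing every
#' pixel whose centre lies within Euclidean distance `radius` of the centre
#' pixel. `line_se()` builds a flat 1-pixel-thick line; its length is rounded
#' up to the nearest odd integer so the element is centred.
#'
#' @param radius Disk radius in pixels (integer, >= 1).
#' @param length Line length in pixels (>= 1).
#' @param orientation `"horizontal"` or `"vertical"`.
#' @return A logical matrix usable with the morphological operators.
#' @examples
#' disk_se(2)
#' line_se(5)
#' @export
disk_se <- function(radius) {
  radius <- as.integer(radius)
  if (is.na(radius) || radius < 1L) sf_stop("argument", "disk radius must be >= 1")
  d <- -radius:radius
  outer(d, d, function(r, c) r * r + c * c <= radius * radius)
}

#' @rdname disk_se
#' @export
line_se <- function(length, orientation = c("horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  length <- as.integer(length)
  if (is.na(length) || length < 1L) sf_stop("argument", "line length must be >= 1")
  if (length %% 2L == 0L) length <- length + 1L
  se <- matrix(TRUE, nrow = 1L, ncol = length)
  if (orientation == "vertical") t(se) else se
}

check_morph_input <- function(x, se) {
  if (!is.matrix(x) || !is.numeric(x)) sf_stop("argument", "image must be a numeric matrix")
  if (anyNA(x)) sf_stop("argument", "image passed to morphology must be NaN-free; pre-fill NaN pixels")
  if (!is.matrix(se) || !is.logical(se)) sf_stop("argument", "structuring element must be a logical matrix")
  if (!se[nrow(se) %/% 2L + 1L, ncol(se) %/% 2L + 1L])
    sf_stop("argument", "structuring element must contain its centre pixel")
  invisible(TRUE)
}

#' Grayscale morphological operators
#'
#' Flat grayscale erosion, dilation, opening, closing and white top-hat with
#' an arbitrary structuring element (each SE row must be a contiguous run, as
#' in disks, lines and boxes). At image borders the neighbourhood shrinks to
#' the in-bounds pixels, so results match a brute-force sliding-window
#' min/max exactly.
#'
#' @param x Numeric matrix without NaN/Inf.
#' @param se Logical structuring element (see [disk_se()], [line_se()]).
#' @return Numeric matrix of the same shape.
#' @seealso [texture_map()], [tophat_baseline()]
#' @export
morph_erode <- function(x, se) {
  check_morph_input(x, se)
  morph_extreme_cpp(x, se, FALSE)
}

#' @rdname morph_erode
#' @export
morph_dilate <- function(x, se) {
  check_morph_input(x, se)
  morph_extreme_cpp(x, se, TRUE)
}

#' @rdname morph_erode
#' @export
morph_open <- function(x, se) morph_dilate(morph_erode(x, se), se)

#' @rdname morph_erode
#' @export
morph_close <- function(x, se) morph_erode(morph_dilate(x, se), se)

#' @rdname morph_erode
#' @export
morph_tophat <- function(x, se) x - morph_open(x, se)
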