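# Shared low-level helpers: 8-bit quantization, connected components,
# Feret diameter, roundness.

#' Quantize intensities to 256 levels
#'
#' Maps intensities on \[0, 1\] to the integer levels `0:255`, clipping out-of
#' range values.  All entropy and histogram computations operate on these
#' levels so that "unique pixel values" is well defined for 8-bit data.
#'
#' @param img numeric matrix with values (nominally) on \[0, 1\].
#' @return integer matrix of the same shape with values in `0:255`.
#' @export
quantize256 <- function(img) {
  stopifnot(is.matrix(img))
  q <- round(pmin(pmax(img, 0), 1) * 255)
  storage.mode(q) <- "integer"
  q
}

#' Label connected components
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 8 (default, foreground convention) or 4 (background
#'   convention).
#' @return integer matrix of component labels, 0 for background; labels are
#'   assigned in raster order of each component's first pixel.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  cpp_label(m, as.integer(connectivity))
}

#' Maximum (Feret) diameter of a pixel set
#'
#' The maximum pairwise distance between pixel centers, plus one pixel width
#' so that a single pixel has diameter 1 and a 1 x n run of pixels has
#' diameter n.  Computed on the convex hull for large sets.
#'
#' @param rows,cols integer pixel coordinates.
#' @return diameter in pixel units.
#' @export
feret_diameter <- function(rows, cols) {
  n <- length(rows)
  if (n == 0) return(0)
  if (n == 1) return(1)
  pts <- cbind(rows, cols)
  if (n > 3) {
    hull <- grDevices::chull(pts)
    pts <- pts[hull, , drop = FALSE]
  }
  d2 <- 0
  for (k in seq_len(nrow(pts))) {
    dd <- (pts[, 1] - pts[k, 1])^2 + (pts[, 2] - pts[k, 2])^2
    d2 <- max(d2, dd)
  }
  sqrt(d2) + 1
}

#' Roundness of a structure
#'
#' `4 * pi * A / (pi * D)^2`, i.e. `4 A / (pi D^2)`: 1 for a perfect disc and
#' approaching 0 for elongated shapes.  `A` is the pixel count and `D` the
#' maximum (Feret) diameter.
#'
#' @param area pixel count.
#' @param diameter maximum diameter in pixels.
#' @return dimensionless roundness; values slightly above 1 can occur for
#'   tiny structures through discretization.
#' @export
roundness <- function(area, diameter) {
  4 * area / (pi * diameter^2)
}

# per-component pixel index list for a label matrix (0 = unlabeled)
split_labels <- function(labels) {
  idx <- which(labels > 0)
  split(idx, labels[idx])
}

# base-2 Shannon entropy of the value distribution of `v`
shannon_entropy <- function(v) {
  p <- tabulate(match(v, unique(v)))
  p <- p / sum(p)
  -sum(p * log2(p))
}

# entropy standardized by the maximum obtainable for n values
standardized_entropy <- function(v) {
  n <- length(v)
  if (n <= 1) return(0)
  shannon_entropy(v) / log2(n)
}

stop_if_not_gray <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a numeric matrix of grayscale intensities")
  invisible(img)
}
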