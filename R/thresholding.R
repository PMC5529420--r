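# Foreground/background separation: local entropy filtering, Otsu and Tsai
# global threshold selection, and five-step mask post-processing
# (threshold, bright-pixel rescue, thinning, small-object removal, hole
# filling).

#' Local entropy filter
#'
#' For each pixel, the base-2 Shannon entropy of the empirical distribution
#' of unique 8-bit pixel values in a square window around it, divided by the
#' maximum obtainable entropy `log2(#w)` for the `#w` pixels actually inside
#' the image (windows are clipped at the borders, not padded).  Values land
#' on \[0, 1\]: near 0 on flat background, high on textured tissue.
#' Intensities are re-quantized to 256 levels first so that "unique pixel
#' values" is well defined.
#'
#' @param image grayscale matrix on \[0, 1\].
#' @param window odd window size in pixels (default 7, suited to
#'   low-resolution confocal projections).
#' @return matrix of standardized entropies on \[0, 1\] with attribute
#'   `window`.
#' @export
local_entropy <- function(image, window = 7L) {
  stop_if_not_gray(image)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  e <- cpp_local_entropy(quantize256(image), window)
  attr(e, "window") <- window
  e
}

# 256-level histogram of an image on [0, 1]
hist256 <- function(image) {
  tabulate(quantize256(image) + 1L, nbins = 256L)
}

#' Otsu's threshold
#'
#' Exhaustively evaluates the 256 candidate gray levels and picks the one
#' minimizing the weighted within-class variance of the two classes (equal to
#' maximizing the between-class variance).  Foreground is defined as pixels
#' strictly greater than the returned threshold.
#'
#' @param image grayscale or entropy matrix on \[0, 1\] with at least two
#'   distinct quantized values.
#' @return scalar threshold on \[0, 1\] (a multiple of 1/255).
#' @export
otsu_threshold <- function(image) {
  h <- hist256(image)
  if (sum(h > 0) < 2) stop("Otsu threshold undefined for a constant image")
  p <- h / sum(h)
  lev <- (0:255) / 255
  w0 <- cumsum(p)
  mu <- cumsum(p * lev)
  mu_t <- mu[256]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- -Inf
  k <- which.max(between[-256]) # threshold below the top level
  lev[k]
}

#' Tsai's moment-preserving threshold
#'
#' Finds the threshold for which a two-level image preserves the first three
#' moments of the input gray-level distribution as closely as the discrete
#' histogram allows.  The two representative levels are the roots of the
#' moment-determined quadratic and the below-threshold fraction `p0` follows
#' from the first moment; the threshold is the gray level where the
#' cumulative histogram comes closest to `p0`.  Foreground is `pixels > t`.
#'
#' @inheritParams otsu_threshold
#' @return scalar threshold on \[0, 1\].
#' @export
tsai_threshold <- function(image) {
  h <- hist256(image)
  if (sum(h > 0) < 2) stop("Tsai threshold undefined for a constant image")
  p <- h / sum(h)
  lev <- (0:255) / 255
  m1 <- sum(p * lev); m2 <- sum(p * lev^2); m3 <- sum(p * lev^3)
  cd <- m2 - m1^2
  c0 <- (m1 * m3 - m2^2) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- sqrt(max(c1^2 - 4 * c0, 0))
  z0 <- (-c1 - disc) / 2
  z1 <- (-c1 + disc) / 2
  p0 <- if (z1 > z0) (z1 - m1) / (z1 - z0) else 0.5
  cdf <- cumsum(p)
  k <- which.min(abs(cdf - p0))
  lev[k]
}

#' Topology-preserving thinning
#'
#' Peels up to `iterations` one-pixel boundary layers from a binary mask,
#' removing a pixel only when it is a simple point, i.e. when its removal
#' changes neither the number of 8-connected foreground components nor the
#' number of 4-connected background holes.  Used to counteract the boundary
#' expansion of the entropy filter (about half a window in every direction).
#'
#' @param mask binary matrix.
#' @param iterations number of one-pixel peels.
#' @return binary integer matrix.
#' @export
topology_preserving_thin <- function(mask, iterations) {
  stopifnot(is.matrix(mask), iterations >= 0)
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (iterations == 0) return(m)
  cpp_thin(m, as.integer(iterations))
}

#' Thresholding configuration
#'
#' @param method `"otsu"` or `"tsai"`.
#' @param use_entropy apply the local entropy filter before thresholding
#'   (recommended; thresholding the raw intensities is retained for
#'   comparison).
#' @param window entropy window size (odd).
#' @param rescue_level original-intensity level above which pixels are always
#'   foreground (default 0.2; bright pixels always belong to tissue).
#' @param min_structure_diameter components with maximum (Feret) diameter
#'   strictly below this are deleted (default 10 px; cell debris).
#' @param min_hole_area background holes strictly smaller than this are
#'   filled (default 100 px; holes inside organoids).
#' @param thinning_iterations boundary peels after entropy-based
#'   thresholding; defaults to half the entropy window.
#' @param min_foreground_contrast empty-well guard: a global threshold always
#'   splits its histogram somewhere, so on an image with no tissue the
#'   nominal "foreground" class is just the brighter half of the noise.
#'   Since tissue is bright on a dark background, the candidate foreground
#'   must exceed the background by at least this much in mean original
#'   intensity, or the thresholding step yields an empty mask (bright-pixel
#'   rescue still applies).
#' @return a `threshold_config` list.
#' @export
threshold_config <- function(method = c("otsu", "tsai"),
                             use_entropy = TRUE,
                             window = 7L,
                             rescue_level = 0.2,
                             min_structure_diameter = 10,
                             min_hole_area = 100,
                             thinning_iterations = NULL,
                             min_foreground_contrast = 0.02) {
  method <- match.arg(method)
  if (is.null(thinning_iterations)) thinning_iterations <- window %/% 2L
  stopifnot(rescue_level > 0, rescue_level < 1,
            min_structure_diameter > 0, min_hole_area > 0,
            thinning_iterations >= 0, min_foreground_contrast >= 0)
  structure(list(method = method, use_entropy = use_entropy,
                 window = as.integer(window), rescue_level = rescue_level,
                 min_structure_diameter = min_structure_diameter,
                 min_hole_area = min_hole_area,
                 thinning_iterations = as.integer(thinning_iterations),
                 min_foreground_contrast = min_foreground_contrast),
            class = "threshold_config")
}

# fill background holes smaller than min_area whose surrounding foreground
# is a single component (so filling never merges components)
fill_small_holes <- function(mask, min_area) {
  nr <- nrow(mask); nc <- ncol(mask)
  bg <- label_components(mask == 0, connectivity = 4)
  if (max(bg) == 0) return(mask)
  border_labels <- unique(c(bg[1, ], bg[nr, ], bg[, 1], bg[, nc]))
  fglab <- label_components(mask, connectivity = 8)
  sizes <- tabulate(bg[bg > 0])
  for (lab in seq_along(sizes)) {
    if (lab %in% border_labels || sizes[lab] >= min_area) next
    idx <- which(bg == lab)
    rows <- (idx - 1) %% nr + 1
    cols <- (idx - 1) %/% nr + 1
    nb_labels <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- rows + dr; cc <- cols + dc
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      nb <- fglab[cbind(rr[ok], cc[ok])]
      nb_labels <- union(nb_labels, nb[nb > 0])
    }
    if (length(nb_labels) == 1) mask[idx] <- 1L
  }
  mask
}

# delete 8-connected components with Feret diameter below min_diameter
remove_small_structures <- function(mask, min_diameter) {
  lab <- label_components(mask, connectivity = 8)
  if (max(lab) == 0) return(mask)
  nr <- nrow(mask)
  for (px in split_labels(lab)) {
    rows <- (px - 1) %% nr + 1
    cols <- (px - 1) %/% nr + 1
    if (feret_diameter(rows, cols) < min_diameter) mask[px] <- 0L
  }
  mask
}

#' Threshold a well image into a foreground mask
#'
#' Applies, in order: (i) the configured global threshold on the (optionally
#' entropy-filtered) image, foreground being pixels strictly above the
#' threshold; (ii) rescue of pixels whose original intensity exceeds
#' `rescue_level`, which always belong to tissue; (iii) topology-preserving
#' thinning, only when the entropy filter was used (to undo its boundary
#' expansion); (iv) deletion of components with maximum diameter below
#' `min_structure_diameter`; (v) filling of enclosed background holes
#' smaller than `min_hole_area`.
#'
#' @param image grayscale matrix on \[0, 1\].
#' @param cfg a [threshold_config()] object.
#' @return binary integer mask with attribute `threshold` (the global
#'   threshold used).
#' @export
threshold_mask <- function(image, cfg = threshold_config()) {
  stop_if_not_gray(image)
  stopifnot(inherits(cfg, "threshold_config"))
  base <- if (cfg$use_entropy) local_entropy(image, cfg$window) else image
  t <- switch(cfg$method, otsu = otsu_threshold(base), tsai = tsai_threshold(base))
  m <- matrix(as.integer(base > t), nrow(image), ncol(image))
  # empty-well guard: the thresholded class must actually be brighter than
  # the background in the original image
  fg <- m > 0
  if (!any(fg) || !any(!fg) ||
      mean(image[fg]) - mean(image[!fg]) < cfg$min_foreground_contrast)
    m[] <- 0L
  m[image > cfg$rescue_level] <- 1L                        # (ii)
  if (cfg$use_entropy && cfg$thinning_iterations > 0)
    m <- cpp_thin(m, cfg$thinning_iterations)              # (iii)
  m <- remove_small_structures(m, cfg$min_structure_diameter) # (iv)
  m <- fill_small_holes(m, cfg$min_hole_area)              # (v)
  attr(m, "threshold") <- t
  m
}
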