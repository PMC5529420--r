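# Image input/output, maximum projection, grayscale conversion, and
# collation of the four overlapping per-well tiles by FFT phase correlation.

#' Read a grayscale image
#'
#' Reads TIFF or PNG (by file extension).  RGB images are converted with the
#' luminance transform of [to_grayscale()].
#'
#' @param path file path ending in `.tif`, `.tiff` or `.png`.
#' @return numeric matrix with intensities on \[0, 1\].
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop(sprintf("unsupported image format '%s'", ext))
  )
  if (length(dim(img)) == 3) {
    if (dim(img)[3] >= 3) img <- to_grayscale(img[, , 1:3]) else img <- img[, , 1]
  }
  img
}

#' Write a grayscale image
#'
#' Writes 8-bit grayscale TIFF or PNG depending on the file extension.
#'
#' @param img numeric matrix on \[0, 1\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gray <- function(img, path) {
  stop_if_not_gray(img)
  img <- pmin(pmax(img, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    png = png::writePNG(img, path),
    stop(sprintf("unsupported image format '%s'", ext))
  )
  invisible(path)
}

#' Read a multi-layer TIFF stack
#'
#' @param path TIFF file with one or more pages.
#' @return list of grayscale matrices (the layers).
#' @export
read_stack <- function(path) {
  img <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(img)) img <- list(img)
  lapply(img, function(x) if (length(dim(x)) == 3) to_grayscale(x[, , 1:3]) else x)
}

#' Maximum projection of an image stack
#'
#' Per-pixel maximum over the layers of a confocal stack, collapsing 3D
#' information to a single 2D image.
#'
#' @param stack list of equally shaped grayscale matrices, or a 3D array
#'   with layers along the third dimension.
#' @return grayscale matrix of the common layer shape.
#' @export
max_project <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(k) stack[, , k])
  stopifnot(is.list(stack), length(stack) >= 1)
  shp <- dim(stack[[1]])
  for (l in stack)
    if (!identical(dim(l), shp)) stop("all stack layers must have the same shape")
  Reduce(pmax, stack)
}

#' Luminance grayscale transform
#'
#' `0.2126 R + 0.7152 G + 0.0722 B`, the luminance-preserving weights for
#' converting color fluorescence images to grayscale.
#'
#' @param rgb array of dimension `(rows, cols, 3)` with channels on \[0, 1\].
#' @return grayscale matrix.
#' @export
to_grayscale <- function(rgb) {
  if (length(dim(rgb)) != 3 || dim(rgb)[3] != 3)
    stop("expected an array with exactly 3 channels")
  0.2126 * rgb[, , 1] + 0.7152 * rgb[, , 2] + 0.0722 * rgb[, , 3]
}

#' Integer translation between two images by phase correlation
#'
#' Computes the normalized cross-power spectrum of the two images' fast
#' Fourier transforms and returns the integer shift `(dy, dx)` at its peak:
#' the translation such that `b` is (circularly) `a` shifted down by `dy`
#' rows and right by `dx` columns.  Shifts are reported in
#' `(-n/2, n/2]`-wrapped signed form.
#'
#' @param a,b equal-shaped grayscale matrices; must not be constant.
#' @return integer vector `c(dy, dx)`.
#' @export
phase_correlation_shift <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  if (sd(a) == 0 || sd(b) == 0)
    stop("phase correlation is undefined for constant images")
  fa <- fft(a); fb <- fft(b)
  cross <- fa * Conj(fb)
  mag <- Mod(cross)
  mag[mag < .Machine$double.eps] <- 1
  r <- Re(fft(cross / mag, inverse = TRUE))
  peak <- arrayInd(which.max(r), dim(r)) - 1L
  wrap <- function(d, n) if (d > n / 2) d - n else d
  # peak of ifft(Fa * conj(Fb)) sits at the shift taking b onto a
  c(dy = -wrap(peak[1], nrow(a)), dx = -wrap(peak[2], ncol(a)))
}

# evaluate candidate placements of b at offset (dy, dx) relative to a and
# return the normalized cross-correlation over the overlap (NA if the
# overlap is smaller than min_pixels)
overlap_ncc <- function(a, b, dy, dx, min_pixels = 64) {
  nr <- nrow(a); nc <- ncol(a)
  if (abs(dy) >= nr || abs(dx) >= nc) return(NA_real_)
  ys_a <- max(1, 1 + dy):min(nr, nr + dy)
  xs_a <- max(1, 1 + dx):min(nc, nc + dx)
  if (length(ys_a) * length(xs_a) < min_pixels) return(NA_real_)
  pa <- a[ys_a, xs_a]
  pb <- b[ys_a - dy, xs_a - dx]
  if (sd(pa) == 0 || sd(pb) == 0) return(NA_real_)
  stats::cor(as.vector(pa), as.vector(pb))
}

# phase-correlation shift with the circular-wrap ambiguity resolved by the
# candidate placement with the best overlap correlation
estimate_tile_shift <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0)
    stop("cannot register constant tiles")
  fa <- fft(a); fb <- fft(b)
  cross <- fa * Conj(fb)
  mag <- Mod(cross)
  mag[mag < .Machine$double.eps] <- 1
  r <- Re(fft(cross / mag, inverse = TRUE))
  peak <- arrayInd(which.max(r), dim(r)) - 1L
  # the placement offset of b relative to a is the negative of the content
  # shift, i.e. the raw (unwrapped) peak index
  dy0 <- peak[1]; dx0 <- peak[2]
  cand_y <- unique(c(dy0, dy0 - nrow(a)))
  cand_x <- unique(c(dx0, dx0 - ncol(a)))
  best <- NULL; best_ncc <- -Inf
  for (dy in cand_y) for (dx in cand_x) {
    ncc <- overlap_ncc(a, b, dy, dx)
    if (!is.na(ncc) && ncc > best_ncc) {
      best_ncc <- ncc
      best <- c(dy, dx)
    }
  }
  if (is.null(best)) stop("tile registration failed: no overlapping placement")
  as.integer(best)
}

#' Bundle the four tiles of a well
#'
#' @param tiles list of 4 equally shaped grayscale matrices in row-major 2x2
#'   order: top-left, top-right, bottom-left, bottom-right.
#' @param shifts optional list with integer offsets (rows, cols) of each tile
#'   relative to the top-left tile, named `tr`, `bl`, `br`.  When omitted,
#'   [collate_well()] estimates them by phase correlation.
#' @return object of class `well_tiles`.
#' @export
well_tiles <- function(tiles, shifts = NULL) {
  stopifnot(is.list(tiles), length(tiles) == 4)
  shp <- dim(tiles[[1]])
  for (t in tiles) if (!identical(dim(t), shp)) stop("all tiles must have the same shape")
  structure(list(tiles = tiles, shifts = shifts), class = "well_tiles")
}

#' Collate four overlapping tiles into one well-wide image
#'
#' Tile offsets are taken from the `well_tiles` object or estimated by phase
#' correlation (top-left vs top-right, top-left vs bottom-left, top-right vs
#' bottom-right).  Registration is integer-pixel only; in overlap regions
#' the earlier tile in raster order keeps its pixels, so no interpolation or
#' averaging ever touches the 8-bit data.
#'
#' @param tiles a [well_tiles()] object.
#' @return grayscale matrix of the collated well, with attributes
#'   `overlap_fraction` (duplicated tile pixels / total tile pixels) and
#'   `positions` (top-left corner of each tile, 0-based).
#' @export
collate_well <- function(tiles) {
  stopifnot(inherits(tiles, "well_tiles"))
  tl <- tiles$tiles[[1]]; tr <- tiles$tiles[[2]]
  bl <- tiles$tiles[[3]]; br <- tiles$tiles[[4]]
  if (is.null(tiles$shifts)) {
    s_tr <- estimate_tile_shift(tl, tr)
    s_bl <- estimate_tile_shift(tl, bl)
    s_br <- s_tr + estimate_tile_shift(tr, br)
  } else {
    s_tr <- as.integer(tiles$shifts$tr)
    s_bl <- as.integer(tiles$shifts$bl)
    s_br <- as.integer(tiles$shifts$br)
  }
  pos <- rbind(tl = c(0L, 0L), tr = s_tr, bl = s_bl, br = s_br)
  pos[, 1] <- pos[, 1] - min(pos[, 1])
  pos[, 2] <- pos[, 2] - min(pos[, 2])
  nr <- max(pos[, 1]) + nrow(tl)
  nc <- max(pos[, 2]) + ncol(tl)
  canvas <- matrix(NA_real_, nr, nc)
  dup <- 0L
  for (k in 1:4) {
    t <- tiles$tiles[[k]]
    ys <- (pos[k, 1] + 1):(pos[k, 1] + nrow(t))
    xs <- (pos[k, 2] + 1):(pos[k, 2] + ncol(t))
    patch <- canvas[ys, xs]
    written <- !is.na(patch)
    dup <- dup + sum(written)
    patch[!written] <- t[!written]
    canvas[ys, xs] <- patch
  }
  canvas[is.na(canvas)] <- 0
  attr(canvas, "overlap_fraction") <- dup / (4 * length(tl))
  attr(canvas, "positions") <- pos
  canvas
}
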