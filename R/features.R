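# Per-region texture features: standardized entropy, SD, rotation-invariant
# uniform local binary patterns, and co-occurrence (Haralick) statistics,
# followed by standardization and PCA reduction to 95% explained variance.

# circular order of the 8 neighbors for LBP (E, NE, N, NW, W, SW, S, SE):
# a 90-degree patch rotation permutes these cyclically by two positions.
LBP_DR <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
LBP_DC <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)

#' Rotation-invariant uniform LBP histogram of a region
#'
#' For every region pixel with a full 8-neighborhood inside the image, the
#' local binary pattern compares each neighbor with the center
#' (`neighbor >= center`).  Patterns with at most two circular 0/1
#' transitions ("uniform") are labeled by their number of set bits (0-8);
#' all non-uniform patterns share one label, which is dropped as redundant.
#' The 9 uniform labels are reported as relative frequencies over the
#' considered region pixels, so entries are in \[0, 1\] and sum to at most 1.
#' The encoding is invariant to 90-degree rotations, reflections, and to
#' adding a constant to the image.
#'
#' @param image grayscale matrix.
#' @param region_idx linear indices of the region's pixels.
#' @return numeric vector of length 9 (counts of set bits 0-8).
#' @export
lbp_features <- function(image, region_idx) {
  nr <- nrow(image); nc <- ncol(image)
  if (length(region_idx) == 0) return(numeric(9))
  rows <- (region_idx - 1) %% nr + 1
  cols <- (region_idx - 1) %/% nr + 1
  ok <- rows > 1 & rows < nr & cols > 1 & cols < nc
  if (!any(ok)) return(numeric(9))
  rows <- rows[ok]; cols <- cols[ok]
  center <- image[cbind(rows, cols)]
  bits <- matrix(0L, length(rows), 8)
  for (k in 1:8)
    bits[, k] <- as.integer(image[cbind(rows + LBP_DR[k], cols + LBP_DC[k])] >= center)
  transitions <- rowSums(bits != bits[, c(2:8, 1)])
  nset <- rowSums(bits)
  uniform <- transitions <= 2
  counts <- tabulate(nset[uniform] + 1L, nbins = 9L)
  counts / length(rows)
}

# the 13 classic co-occurrence statistics of a normalized symmetric GLCM
haralick_stats <- function(P) {
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P)
  mu <- sum((1:ng) * px)
  sig2 <- sum(((1:ng) - mu)^2 * px)
  sig <- sqrt(sig2)
  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sig2 > 0) (sum(i * j * P) - mu^2) / sig2 else 0
  variance <- sig2
  idm <- sum(P / (1 + (i - j)^2))
  # sum / difference distributions
  sums <- i + j
  diffs <- abs(i - j)
  psum <- tapply(P, sums, sum)
  pdiff <- tapply(P, diffs, sum)
  ks <- as.numeric(names(psum))
  kd <- as.numeric(names(pdiff))
  sav <- sum(ks * psum)
  sva <- sum((ks - sav)^2 * psum)
  sen <- -sum(ifelse(psum > 0, psum * log2(psum), 0))
  ent <- -sum(ifelse(P > 0, P * log2(P), 0))
  dav <- sum(kd * pdiff)
  dva <- sum((kd - dav)^2 * pdiff)
  den <- -sum(ifelse(pdiff > 0, pdiff * log2(pdiff), 0))
  # information measures of correlation
  py <- colSums(P)
  hx <- -sum(ifelse(px > 0, px * log2(px), 0))
  hy <- -sum(ifelse(py > 0, py * log2(py), 0))
  pxpy <- outer(px, py)
  hxy1 <- -sum(ifelse(P > 0 & pxpy > 0, P * log2(pxpy), 0))
  hxy2 <- -sum(ifelse(pxpy > 0, pxpy * log2(pxpy), 0))
  f12 <- if (max(hx, hy) > 0) (ent - hxy1) / max(hx, hy) else 0
  f13 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - ent))))
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sav = sav, sva = sva, sen = sen,
    ent = ent, dva = dva, den = den, imc1 = f12, imc2 = f13)
}

HARALICK_FALLBACK <- local({
  v <- rep(0, 13)
  names(v) <- c("asm", "contrast", "correlation", "variance", "idm", "sav",
                "sva", "sen", "ent", "dva", "den", "imc1", "imc2")
  v["asm"] <- 1 # energy of a one-level distribution; all other stats 0
  v
})

#' Co-occurrence (Haralick) features of a region
#'
#' Region intensities are min-max normalized and quantized to `n_levels`
#' gray levels (making the features independent of the region's overall
#' brightness), then symmetric co-occurrence matrices are accumulated at
#' distance 1 along the 4 canonical directions, restricted to pixel pairs
#' that both lie inside the region.  The 13 classic statistics (angular
#' second moment, contrast, correlation, variance, inverse difference
#' moment, sum average/variance/entropy, entropy, difference
#' variance/entropy, and the two information measures of correlation) are
#' summarized by their mean and range over the 4 directions, giving 26
#' values.  A constant region returns the defined fallback (energy 1, all
#' other statistics and all ranges 0).
#'
#' @param image grayscale matrix.
#' @param region_idx linear indices of the region's pixels.
#' @param n_levels gray levels for quantization (default 32).
#' @return numeric vector of length 26 (`*_mean` then `*_range`).
#' @export
haralick_features <- function(image, region_idx, n_levels = 32) {
  nm <- c(paste0(names(HARALICK_FALLBACK), "_mean"),
          paste0(names(HARALICK_FALLBACK), "_range"))
  v <- image[region_idx]
  rng <- range(v)
  if (length(region_idx) < 2 || rng[1] == rng[2]) {
    out <- c(HARALICK_FALLBACK, rep(0, 13))
    names(out) <- nm
    return(out)
  }
  g <- pmin(floor((v - rng[1]) / (rng[2] - rng[1]) * n_levels) + 1L, n_levels)
  nr <- nrow(image); nc <- ncol(image)
  level <- matrix(NA_integer_, nr, nc)
  level[region_idx] <- g
  dirs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  per_dir <- matrix(NA_real_, 4, 13)
  rows <- (region_idx - 1) %% nr + 1
  cols <- (region_idx - 1) %/% nr + 1
  for (d in seq_along(dirs)) {
    dr <- dirs[[d]][1]; dc <- dirs[[d]][2]
    ok <- rows + dr >= 1 & rows + dr <= nr & cols + dc >= 1 & cols + dc <= nc
    a <- level[cbind(rows[ok], cols[ok])]
    b <- level[cbind(rows[ok] + dr, cols[ok] + dc)]
    keep <- !is.na(b)
    a <- a[keep]; b <- b[keep]
    if (length(a) == 0) {
      per_dir[d, ] <- HARALICK_FALLBACK
      next
    }
    C <- matrix(0, n_levels, n_levels)
    tab <- table(factor(a, levels = 1:n_levels), factor(b, levels = 1:n_levels))
    C <- unclass(tab) + t(unclass(tab)) # symmetric accumulation
    P <- C / sum(C)
    per_dir[d, ] <- haralick_stats(P)
  }
  means <- colMeans(per_dir)
  ranges <- apply(per_dir, 2, function(x) diff(range(x)))
  out <- c(means, ranges)
  names(out) <- nm
  out
}

#' Full 37-feature texture vector of a region
#'
#' Concatenates the standardized entropy of the region's pixel values
#' (entropy of the 8-bit value distribution divided by `log2` of the region
#' size), the standard deviation of the pixel values, the 9 LBP frequencies
#' and the 26 co-occurrence features.  All 37 features are invariant to
#' region translation, to axis/diagonal reflections, and to adding a
#' constant to the image (as long as no quantization levels merge).
#'
#' @param image grayscale matrix on \[0, 1\].
#' @param region_idx linear indices of the region's pixels.
#' @param culture_method categorical covariate attached (not a numeric
#'   feature).
#' @return numeric vector of length 37 with attribute `culture_method`.
#' @export
region_feature_vector <- function(image, region_idx, culture_method = "freezer") {
  q <- quantize256(image)
  vals <- q[region_idx]
  ent <- standardized_entropy(vals)
  sdev <- sd(image[region_idx])
  if (is.na(sdev)) sdev <- 0
  f <- c(entropy = ent, sd = sdev,
         setNames(lbp_features(image, region_idx), paste0("lbp", 0:8)),
         haralick_features(image, region_idx))
  attr(f, "culture_method") <- culture_method
  f
}

#' Feature table for all regions of a well
#'
#' @param image grayscale matrix.
#' @param regions integer region label matrix from [propagate_regions()].
#' @param culture_method covariate recorded for every region.
#' @param well_id identifier recorded for every region.
#' @return data.frame with `well_id`, `region_id`, `culture_method`, the 37
#'   feature columns, and `n_pixels`.
#' @export
region_features <- function(image, regions, culture_method = "freezer",
                            well_id = "well") {
  px <- split_labels(regions)
  if (length(px) == 0) {
    return(data.frame())
  }
  rows <- lapply(names(px), function(id) {
    f <- region_feature_vector(image, px[[id]], culture_method)
    data.frame(well_id = well_id, region_id = as.integer(id),
               culture_method = culture_method, t(f),
               n_pixels = length(px[[id]]))
  })
  do.call(rbind, rows)
}

#' Fit a standardize-then-PCA feature reducer
#'
#' Columns are standardized to mean 0 and variance 1 (constant columns map
#' to 0), then the smallest number of leading principal components whose
#' cumulative explained variance reaches `variance_target` is retained.
#' The number of retained components is always data driven, never fixed.
#'
#' @param X numeric matrix or data.frame of feature rows.
#' @param variance_target fraction of variance to retain (default 0.95).
#' @return a `feature_reducer` with means, SDs, loadings and the retained
#'   component count.
#' @export
fit_reducer <- function(X, variance_target = 0.95) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows to fit a reducer")
  mu <- colMeans(X)
  sds <- apply(X, 2, sd)
  sds[sds == 0 | is.na(sds)] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sds, "/")
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ev) >= variance_target)[1]
  if (is.na(k)) k <- length(ev)
  structure(list(mean = mu, sd = sds, rotation = pc$rotation[, 1:k, drop = FALSE],
                 n_components = k, explained = ev,
                 variance_target = variance_target),
            class = "feature_reducer")
}

#' Apply a fitted feature reducer
#'
#' @param reducer a [fit_reducer()] result.
#' @param X numeric matrix or data.frame with the training columns.
#' @return matrix of principal component scores (columns `PC1..PCk`).
#' @export
apply_reducer <- function(reducer, X) {
  stopifnot(inherits(reducer, "feature_reducer"))
  X <- as.matrix(X)
  Z <- sweep(sweep(X, 2, reducer$mean), 2, reducer$sd, "/")
  Z %*% reducer$rotation
}

# names of the 37 numeric feature columns in a region_features() table
feature_columns <- function(df) {
  setdiff(names(df), c("well_id", "region_id", "culture_method", "n_pixels",
                       "label", "vote_fraction"))
}
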