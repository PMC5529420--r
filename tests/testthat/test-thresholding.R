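brute_entropy <- function(img, window = 7) {
  q <- quantize256(img)
  nr <- nrow(q); nc <- ncol(q); h <- window %/% 2
  out <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    ys <- max(1, i - h):min(nr, i + h)
    xs <- max(1, j - h):min(nc, j + h)
    v <- as.vector(q[ys, xs])
    p <- as.vector(table(v)) / length(v)
    out[i, j] <- -sum(p * log2(p)) / log2(length(v))
  }
  out
}

test_that("local entropy matches a brute-force histogram loop, borders included", {
  for (s in 1:20) {
    set.seed(s)
    img <- matrix(runif(16 * 16), 16, 16)
    e <- local_entropy(img, 7)
    expect_equal(unclass(e), brute_entropy(img, 7), ignore_attr = TRUE,
                 tolerance = 1e-12)
  }
})

test_that("local entropy hits its defined extremes", {
  img <- matrix(0.5, 15, 15)
  expect_equal(local_entropy(img, 7)[8, 8], 0)
  img[5:11, 5:11] <- (1:49) / 50 # 49 distinct quantized values
  expect_equal(local_entropy(img, 7)[8, 8], 1)
})

test_that("entropy is invariant to a constant offset without level merging", {
  set.seed(9)
  img <- quantize256(matrix(runif(20 * 20, 0, 0.5), 20, 20)) / 255
  shifted <- img + 50 / 255
  expect_equal(local_entropy(img, 7), local_entropy(shifted, 7))
})

test_that("Otsu matches exhaustive search and is histogram-only", {
  brute_otsu <- function(img) {
    q <- quantize256(img)
    lev <- (0:255) / 255
    best <- Inf; bestt <- 0
    for (k in 0:254) {
      t <- lev[k + 1]
      lo <- q[q <= k]; hi <- q[q > k]
      if (length(lo) == 0 || length(hi) == 0) next
      wv <- length(lo) * pvar(lo) + length(hi) * pvar(hi)
      if (wv < best) { best <- wv; bestt <- t }
    }
    bestt
  }
  pvar <- function(x) if (length(x) < 2) 0 else mean((x - mean(x))^2)
  for (s in 1:20) {
    set.seed(s)
    img <- matrix(c(rnorm(200, 0.3, 0.05), rnorm(150, 0.7, 0.08)), 25, 14)
    expect_equal(otsu_threshold(img), brute_otsu(img))
  }
  img <- matrix(c(rep(0.2, 50), rep(0.8, 50)), 10, 10)
  t <- otsu_threshold(img)
  expect_gte(t, 0.2); expect_lt(t, 0.8)
  set.seed(1)
  shuf <- matrix(sample(img), 10, 10)
  expect_equal(otsu_threshold(shuf), t)
  expect_error(otsu_threshold(matrix(0.4, 5, 5)), "constant")
})

test_that("Tsai threshold preserves the first three moments", {
  # independent oracle: numeric solve for the below-threshold fraction from
  # the moment-preserving equations via root finding on the quadratic
  tsai_oracle <- function(img) {
    q <- quantize256(img) / 255
    m1 <- mean(q); m2 <- mean(q^2); m3 <- mean(q^3)
    f <- function(z) z^2 + ((m1 * m2 - m3) / (m2 - m1^2)) * z +
      (m1 * m3 - m2^2) / (m2 - m1^2)
    # bracketed roots of the quadratic on [min, max]
    lo <- uniroot(f, c(min(q) - 1, m1), tol = 1e-12)$root
    hi <- uniroot(f, c(m1, max(q) + 1), tol = 1e-12)$root
    p0 <- (hi - m1) / (hi - lo)
    lev <- sort(unique(q))
    cdf <- vapply(lev, function(l) mean(q <= l), numeric(1))
    lev[which.min(abs(cdf - p0))]
  }
  for (s in 1:20) {
    set.seed(s)
    img <- matrix(c(rnorm(400, 0.3, 0.06), rnorm(100, 0.75, 0.1)), 25, 20)
    expect_equal(tsai_threshold(img), tsai_oracle(img), tolerance = 1e-9)
  }
  # binarized two-level reconstruction preserves the first moment to a bin
  set.seed(5)
  img <- matrix(c(rnorm(300, 0.3, 0.1), rnorm(300, 0.7, 0.1)), 30, 20)
  t <- tsai_threshold(img)
  q <- quantize256(img) / 255
  z0 <- mean(q[q <= t]); z1 <- mean(q[q > t]); p0 <- mean(q <= t)
  expect_lt(abs((p0 * z0 + (1 - p0) * z1) - mean(q)), 1 / 255)
  img2 <- matrix(c(rep(0.2, 50), rep(0.8, 50)), 10, 10)
  t2 <- tsai_threshold(img2)
  expect_gte(t2, 0.2); expect_lt(t2, 0.8)
})

test_that("thinning preserves topology and tightens dilated boundaries", {
  disc <- disc_mask(40, 40, 20, 20, 12)
  th <- topology_preserving_thin(disc, 3)
  expect_equal(n_components(th), 1)
  # at most 3 one-pixel layers are peeled (Chebyshev depth > 3 survives)
  expect_true(all(th[disc_mask(40, 40, 20, 20, 12 - 3 * sqrt(2)) > 0] == 1))

  ring <- disc_mask(50, 50, 25, 25, 18) - disc_mask(50, 50, 25, 25, 9)
  th <- topology_preserving_thin(ring, 3)
  expect_equal(n_components(th), 1)
  expect_equal(count_holes(th), 1)

  # dilating then thinning recovers the original disc better; the peel is
  # bounded by three box erosions (one layer per iteration, never deeper)
  dil <- as.matrix(EBImage::dilate(disc, EBImage::makeBrush(7, "box")))
  th <- topology_preserving_thin(dil, 3)
  iou <- function(a, b) sum(a & b) / sum(a | b)
  expect_gt(iou(th > 0, disc > 0), iou(dil > 0, disc > 0))
  core <- dil
  for (k in 1:3)
    core <- matrix(as.integer(as.matrix(EBImage::erode(core, EBImage::makeBrush(3, "box")))), 40, 40)
  expect_true(all(th[core > 0] == 1)) # pixels deeper than 3 are untouched
  expect_true(all(th <= dil))
})

test_that("thinning never changes component or hole counts (50 random masks)", {
  set.seed(77)
  for (k in 1:50) {
    m <- random_blob_mask()
    th <- topology_preserving_thin(m, 3)
    expect_equal(n_components(th), n_components(m))
    expect_equal(count_holes(th), count_holes(m))
    expect_true(all(th <= m)) # thinning only removes pixels
  }
})

test_that("mask post-processing follows the five steps in order", {
  # single bright pixel: rescued by step ii, deleted by step iv
  img <- matrix(0, 64, 64)
  img[30, 30] <- 0.9
  m <- threshold_mask(img, threshold_config(use_entropy = FALSE))
  expect_equal(sum(m), 0)

  # noise-only image below the rescue level gives an empty mask
  set.seed(2)
  img <- matrix(pmin(abs(rnorm(64 * 64, 0, 0.01)), 0.19), 64, 64)
  m <- threshold_mask(img, threshold_config())
  expect_equal(sum(m), 0)

  # hole filling: a small enclosed hole is filled, component count unchanged
  img <- matrix(0.01, 64, 64)
  img[disc_mask(64, 64, 32, 32, 15) == 1] <- 0.6
  img[disc_mask(64, 64, 32, 32, 4) == 1] <- 0.01
  m <- threshold_mask(img, threshold_config(use_entropy = FALSE))
  expect_equal(count_holes(m), 0)
  expect_equal(n_components(m), 1)
})

test_that("entropy+Otsu masks are accurate on synthetic wells", {
  for (s in 1:3) {
    w <- generate_well(small_well_params(s))
    m <- threshold_mask(w$image, threshold_config(method = "otsu"))
    r <- matrix(as.numeric(w$truth > 0), nrow(w$truth))
    rates <- fpr_fnr(m, r)
    expect_lt(rates["FPR"], 0.10)
    expect_lt(rates["FNR"], 0.10)
  }
})
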