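# Synthetic well images with per-pixel ground truth.
#
# Emulates confocal maximum projections of calcein-stained 3D co-cultures:
# a dark background, bright compact organoids with smooth interior texture,
# thin branching fibroblast strokes with high local edge density, small
# rounded single cells, strong object-to-object brightness variation, and
# final 8-bit quantization.  Truth classes: 0 background, 1 tumor,
# 2 fibroblast, 3 rounded single cell.

TRUTH_BACKGROUND <- 0L
TRUTH_TUMOR <- 1L
TRUTH_FIBROBLAST <- 2L
TRUTH_SINGLE <- 3L

#' Parameters for synthetic well generation
#'
#' Defaults reflect a moderately populated screening well imaged at low
#' resolution: a handful of organoids tens of pixels across, a loose meshwork
#' of fibroblasts, and a sprinkling of small rounded (dead/dying) cells, with
#' per-object peak brightness varying several-fold and a nearly black
#' background whose noise is below one 8-bit gray level.
#'
#' @param image_shape integer `(rows, cols)` of the generated image.
#' @param n_organoids number of tumor organoids.
#' @param organoid_radius_range radius range in pixels.
#' @param organoid_aspect_range axis-ratio range of the elliptical organoid
#'   outline; 1 is a perfect disc, larger values are more elongated.
#' @param n_fibroblasts number of fibroblast strokes.
#' @param fibroblast_length_range stroke length range in pixels.
#' @param n_single_cells number of rounded single cells.
#' @param brightness_range per-object peak intensity range, a subset of
#'   (0, 1].
#' @param background_noise_sd standard deviation of additive background
#'   noise, in intensity units.
#' @param seed integer seed; generation is fully deterministic given the
#'   seed.
#' @return a `synthetic_well_params` list.
#' @export
synthetic_well_params <- function(image_shape = c(512L, 672L),
                                  n_organoids = 8,
                                  organoid_radius_range = c(18, 42),
                                  organoid_aspect_range = c(1, 1.4),
                                  n_fibroblasts = 14,
                                  fibroblast_length_range = c(80, 200),
                                  n_single_cells = 25,
                                  brightness_range = c(0.35, 0.9),
                                  background_noise_sd = 0.004,
                                  seed = 1L) {
  stopifnot(
    length(image_shape) == 2, all(image_shape >= 16),
    n_organoids >= 0, n_fibroblasts >= 0, n_single_cells >= 0,
    length(organoid_radius_range) == 2, all(organoid_radius_range > 0),
    diff(organoid_radius_range) >= 0,
    length(fibroblast_length_range) == 2, all(fibroblast_length_range > 0),
    all(organoid_aspect_range >= 1),
    length(brightness_range) == 2,
    brightness_range[1] > 0, brightness_range[2] <= 1,
    diff(brightness_range) >= 0,
    background_noise_sd >= 0
  )
  structure(list(
    image_shape = as.integer(image_shape),
    n_organoids = as.integer(n_organoids),
    organoid_radius_range = organoid_radius_range,
    organoid_aspect_range = organoid_aspect_range,
    n_fibroblasts = as.integer(n_fibroblasts),
    fibroblast_length_range = fibroblast_length_range,
    n_single_cells = as.integer(n_single_cells),
    brightness_range = brightness_range,
    background_noise_sd = background_noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_well_params")
}

# smooth random field with unit sd: white noise blurred with a Gaussian
# whose kernel is clamped to the field size (small object patches)
smooth_field <- function(nr, nc, sigma = 3) {
  f <- matrix(rnorm(nr * nc), nr, nc)
  s <- 2L * ceiling(2 * sigma) + 1L
  s <- min(s, nr, nc)
  if (s %% 2L == 0L) s <- s - 1L
  if (s >= 3L)
    f <- EBImage::filter2(f, EBImage::makeBrush(s, "Gaussian", sigma = sigma))
  sdv <- sd(f)
  if (!is.na(sdv) && sdv > 0) f <- f / sdv
  f
}

# paint an elliptical organoid-like blob; returns its updated canvases
paint_blob <- function(intensity, truth, cy, cx, r, aspect, theta, peak,
                       class_id, edge_drop = 0.3, mult_amp = 0.18,
                       fine_sd = 0.015) {
  nr <- nrow(intensity); nc <- ncol(intensity)
  rx <- r * sqrt(aspect); ry <- r / sqrt(aspect)
  ext <- ceiling(max(rx, ry)) + 1
  r0 <- max(1, floor(cy - ext)); r1 <- min(nr, ceiling(cy + ext))
  c0 <- max(1, floor(cx - ext)); c1 <- min(nc, ceiling(cx + ext))
  ys <- r0:r1; xs <- c0:c1
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- (dy * cos(theta) + dx * sin(theta)) / ry
  v <- (-dy * sin(theta) + dx * cos(theta)) / rx
  rho2 <- u^2 + v^2
  inside <- rho2 <= 1
  if (!any(inside)) return(list(intensity = intensity, truth = truth))
  tex <- 1 + mult_amp * smooth_field(length(ys), length(xs), sigma = 3)
  val <- peak * (1 - edge_drop * rho2) * tex +
    matrix(rnorm(length(rho2), sd = fine_sd), nrow(rho2))
  patch <- intensity[ys, xs]
  patch[inside] <- pmax(patch[inside], val[inside])
  intensity[ys, xs] <- patch
  tpatch <- truth[ys, xs]
  tpatch[inside] <- class_id
  truth[ys, xs] <- tpatch
  list(intensity = intensity, truth = truth)
}

# random-walk polyline for a fibroblast stroke, with optional branches;
# returns a matrix of (row, col, arclen) sampled at ~1 px spacing
fibroblast_path <- function(nr, nc, length_px) {
  p <- c(runif(1, 3, nr - 2), runif(1, 3, nc - 2))
  ang <- runif(1, 0, 2 * pi)
  n <- ceiling(length_px)
  out <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    ang <- ang + rnorm(1, sd = 0.18)
    p <- p + c(sin(ang), cos(ang))
    # reflect at image borders
    if (p[1] < 3 || p[1] > nr - 2) { ang <- pi - ang; p[1] <- min(max(p[1], 3), nr - 2) }
    if (p[2] < 3 || p[2] > nc - 2) { ang <- -ang; p[2] <- min(max(p[2], 3), nc - 2) }
    out[k, ] <- c(p, k)
  }
  out
}

# paint an anti-aliased stroke along a path; width in pixels
paint_stroke <- function(intensity, truth, path, width, peak) {
  nr <- nrow(intensity); nc <- ncol(intensity)
  half <- width / 2
  phase <- runif(1, 0, 2 * pi)
  rad <- ceiling(half) + 1
  for (k in seq_len(nrow(path))) {
    py <- path[k, 1]; px <- path[k, 2]
    b <- peak * (1 + 0.15 * sin(2 * pi * path[k, 3] / 40 + phase))
    ys <- max(1, floor(py - rad)):min(nr, ceiling(py + rad))
    xs <- max(1, floor(px - rad)):min(nc, ceiling(px + rad))
    dd <- sqrt(outer((ys - py)^2, rep(1, length(xs))) +
                 outer(rep(1, length(ys)), (xs - px)^2))
    alpha <- pmin(pmax(half + 0.5 - dd, 0), 1)
    patch <- intensity[ys, xs]
    upd <- alpha * b
    sel <- upd > patch
    patch[sel] <- upd[sel]
    intensity[ys, xs] <- patch
    tpatch <- truth[ys, xs]
    core <- alpha > 0.5 & tpatch != TRUTH_TUMOR
    tpatch[core] <- TRUTH_FIBROBLAST
    truth[ys, xs] <- tpatch
  }
  list(intensity = intensity, truth = truth)
}

#' Generate a synthetic well image with ground truth
#'
#' Renders rounded single cells, then fibroblasts, then organoids.  At
#' overlapping pixels the intensity is the maximum of the contributions and
#' the truth class follows tumor precedence (tumor over fibroblast over
#' single cell).  Additive background noise is applied first and the final
#' image is quantized to 256 levels on \[0, 1\] last, mirroring 8-bit
#' acquisition.
#'
#' @param params a [synthetic_well_params()] object.
#' @return list with `image` (numeric matrix on \[0,1\], 8-bit quantized) and
#'   `truth` (integer matrix, classes 0-3).
#' @export
generate_well <- function(params) {
  stopifnot(inherits(params, "synthetic_well_params"))
  set.seed(params$seed)
  nr <- params$image_shape[1]; nc <- params$image_shape[2]

  rmax <- params$organoid_radius_range[2] * sqrt(max(params$organoid_aspect_range))
  if (params$n_organoids > 0 && 2 * rmax + 4 > min(nr, nc))
    stop(sprintf("image_shape %d x %d too small to place organoid 1 (max extent %.0f px)",
                 nr, nc, 2 * rmax))

  intensity <- matrix(0.015, nr, nc) +
    matrix(rnorm(nr * nc, sd = params$background_noise_sd), nr, nc)
  truth <- matrix(TRUTH_BACKGROUND, nr, nc)

  # rounded single cells (lowest truth precedence)
  for (k in seq_len(params$n_single_cells)) {
    r <- runif(1, 3, 7.5)
    cy <- runif(1, r + 2, nr - r - 1); cx <- runif(1, r + 2, nc - r - 1)
    b <- runif(1, params$brightness_range[1], params$brightness_range[2])
    res <- paint_blob(intensity, truth, cy, cx, r, aspect = runif(1, 1, 1.15),
                      theta = runif(1, 0, pi), peak = b,
                      class_id = TRUTH_SINGLE, edge_drop = 0.25)
    intensity <- res$intensity; truth <- res$truth
  }

  # fibroblast strokes
  for (k in seq_len(params$n_fibroblasts)) {
    len <- runif(1, params$fibroblast_length_range[1], params$fibroblast_length_range[2])
    b <- runif(1, params$brightness_range[1], params$brightness_range[2])
    width <- runif(1, 2, 4)
    path <- fibroblast_path(nr, nc, len)
    res <- paint_stroke(intensity, truth, path, width, b)
    intensity <- res$intensity; truth <- res$truth
    if (runif(1) < 0.6) { # one branch point
      at <- sample(seq_len(nrow(path)), 1)
      bpath <- fibroblast_path(nr, nc, len * 0.5)
      bpath[, 1] <- pmin(pmax(bpath[, 1] - bpath[1, 1] + path[at, 1], 2), nr - 1)
      bpath[, 2] <- pmin(pmax(bpath[, 2] - bpath[1, 2] + path[at, 2], 2), nc - 1)
      res <- paint_stroke(intensity, truth, bpath, width, b)
      intensity <- res$intensity; truth <- res$truth
    }
  }

  # tumor organoids (highest truth precedence)
  for (k in seq_len(params$n_organoids)) {
    r <- runif(1, params$organoid_radius_range[1], params$organoid_radius_range[2])
    aspect <- runif(1, params$organoid_aspect_range[1], params$organoid_aspect_range[2])
    ext <- r * sqrt(aspect)
    if (2 * ext + 4 > min(nr, nc))
      stop(sprintf("image_shape %d x %d too small to place organoid %d (extent %.0f px)",
                   nr, nc, k, 2 * ext))
    cy <- runif(1, ext + 2, nr - ext - 1); cx <- runif(1, ext + 2, nc - ext - 1)
    b <- runif(1, params$brightness_range[1], params$brightness_range[2])
    res <- paint_blob(intensity, truth, cy, cx, r, aspect,
                      theta = runif(1, 0, pi), peak = b,
                      class_id = TRUTH_TUMOR)
    intensity <- res$intensity; truth <- res$truth
  }

  image <- quantize256(intensity) / 255
  list(image = image, truth = truth)
}

#' Simulate expert foreground annotations
#'
#' Each simulated expert mask is the true foreground perturbed near its
#' boundary: a smooth random field is added to the signed Euclidean distance
#' from the boundary and the result re-thresholded at zero, so perturbations
#' are boundary-localized dilations/erosions whose magnitude grows with
#' `disagreement`.
#'
#' @param truth truth matrix from [generate_well()] (or any binary mask).
#' @param n_experts number of simulated annotators (>= 1).
#' @param disagreement scalar in \[0, 1\]; 0 reproduces the true foreground
#'   exactly, 1 corresponds to boundary displacements of a few pixels.
#' @param seed integer seed.
#' @return list of `n_experts` binary masks (0/1 integer matrices).
#' @export
generate_expert_masks <- function(truth, n_experts, disagreement, seed = 1L) {
  stopifnot(n_experts >= 1)
  if (disagreement < 0 || disagreement > 1)
    stop("disagreement must be in [0, 1]")
  fg <- matrix(as.numeric(truth > 0), nrow(truth), ncol(truth))
  set.seed(seed)
  if (disagreement == 0)
    return(replicate(n_experts, matrix(as.integer(fg > 0), nrow(fg), ncol(fg)),
                     simplify = FALSE))
  dsigned <- as.matrix(EBImage::distmap(fg)) - as.matrix(EBImage::distmap(1 - fg))
  amp <- 3 * disagreement
  lapply(seq_len(n_experts), function(e) {
    eta <- smooth_field(nrow(fg), ncol(fg), sigma = 6)
    matrix(as.integer(dsigned + amp * eta > 0), nrow(fg), ncol(fg))
  })
}

#' Construct a plate design
#'
#' @param wells data.frame with columns `well_id`, `patient`, `treatment`,
#'   `concentration`, `replicate`; `well_id` must be unique.
#' @param effects data.frame with columns `treatment`, `area_effect`
#'   (multiplicative on organoid area), `roundness_shift` (added to the
#'   organoid axis-ratio range; positive values elongate organoids and lower
#'   their roundness), and `single_cell_rate` (multiplicative on the rounded
#'   single-cell count).  Effects scale linearly with concentration up to the
#'   maximum concentration used for that treatment.
#' @param control name of the vehicle control treatment (default `"DMSO"`);
#'   must appear in `wells`.
#' @return a `plate_design` object.
#' @export
plate_design <- function(wells, effects, control = "DMSO") {
  need <- c("well_id", "patient", "treatment", "concentration", "replicate")
  stopifnot(all(need %in% names(wells)))
  if (anyDuplicated(wells$well_id)) stop("well_id values must be unique")
  if (!control %in% wells$treatment)
    stop(sprintf("control treatment '%s' not present in the design", control))
  treated <- setdiff(unique(wells$treatment), control)
  missing <- setdiff(treated, effects$treatment)
  if (length(missing))
    stop(sprintf("unknown treatment in effects table: no entry for %s",
                 paste(missing, collapse = ", ")))
  structure(list(wells = wells, effects = effects, control = control),
            class = "plate_design")
}

#' Full-factorial screening design
#'
#' Builds the standard layout of a screening plate: every
#' patient x treatment x concentration combination in `replicates` wells,
#' plus control wells (concentration 0) in the same number of replicates per
#' patient x treated-concentration cell, mirroring a vehicle column on each
#' plate.
#'
#' @param patients character vector of patient/sample ids.
#' @param effects effects table as in [plate_design()]; its `treatment`
#'   column defines the treated arms.
#' @param concentrations numeric vector of treated concentrations.
#' @param replicates wells per combination.
#' @param control control treatment name.
#' @param control_wells number of control wells per patient; defaults to
#'   `replicates * length(concentrations)` so the control arm is as large as
#'   each treated arm's full dose range.
#' @return a `plate_design` object.
#' @export
screen_design <- function(patients, effects, concentrations, replicates = 2,
                          control = "DMSO",
                          control_wells = replicates * length(concentrations)) {
  rows <- list()
  for (p in patients) {
    for (r in seq_len(control_wells))
      rows[[length(rows) + 1]] <- data.frame(
        patient = p, treatment = control, concentration = 0, replicate = r)
    for (tr in effects$treatment)
      for (cc in concentrations)
        for (r in seq_len(replicates))
          rows[[length(rows) + 1]] <- data.frame(
            patient = p, treatment = tr, concentration = cc, replicate = r)
  }
  wells <- do.call(rbind, rows)
  wells <- cbind(well_id = sprintf("W%03d", seq_len(nrow(wells))), wells)
  plate_design(wells, effects, control)
}

#' Generate a synthetic plate
#'
#' One well image per design row.  Treatment effects modify the generation
#' parameters before rendering: the organoid area effect scales the organoid
#' radius range by its square root, the roundness shift is added to the
#' organoid axis-ratio range, and the single-cell rate scales the rounded
#' single-cell count.  Effect strength scales linearly with concentration
#' relative to the maximum concentration of that treatment.
#'
#' @param design a [plate_design()] object.
#' @param base_params [synthetic_well_params()] used for control wells; each
#'   well receives a seed derived deterministically from `base_params$seed`
#'   and its row index.
#' @return list of wells, each `list(well_id, image, truth, params)`.
#' @export
generate_plate <- function(design, base_params) {
  stopifnot(inherits(design, "plate_design"),
            inherits(base_params, "synthetic_well_params"))
  wells <- design$wells
  out <- vector("list", nrow(wells))
  for (i in seq_len(nrow(wells))) {
    p <- base_params
    tr <- wells$treatment[i]
    if (tr != design$control) {
      eff <- design$effects[design$effects$treatment == tr, ]
      cmax <- max(wells$concentration[wells$treatment == tr])
      s <- if (cmax > 0) wells$concentration[i] / cmax else 1
      area_mult <- 1 + s * (eff$area_effect - 1)
      p$organoid_radius_range <- p$organoid_radius_range * sqrt(area_mult)
      p$organoid_aspect_range <- p$organoid_aspect_range + s * eff$roundness_shift
      rate <- 1 + s * (eff$single_cell_rate - 1)
      p$n_single_cells <- as.integer(round(p$n_single_cells * rate))
    }
    p$seed <- as.integer((as.numeric(base_params$seed) * 7919 + i * 104729) %% 2147483647)
    w <- generate_well(p)
    out[[i]] <- list(well_id = wells$well_id[i], image = w$image,
                     truth = w$truth, params = p)
  }
  out
}

#' Write synthetic plate artifacts to disk
#'
#' Images as 8-bit grayscale PNG, truth maps as single-channel label PNG
#' (0 = background, 1 = tumor, 2 = fibroblast, 3 = single cell; stored as
#' label/255 gray values), and the design as CSV.
#'
#' @param plate result of [generate_plate()].
#' @param design the matching [plate_design()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_plate <- function(plate, design, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (w in plate) {
    write_gray(w$image, file.path(dir, paste0(w$well_id, ".png")))
    png::writePNG(w$truth / 255, file.path(dir, paste0(w$well_id, "_truth.png")))
  }
  write.csv(design$wells, file.path(dir, "plate_design.csv"), row.names = FALSE)
  invisible(dir)
}
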