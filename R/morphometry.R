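# Structure-level morphometrics: watershed splitting of each class's
# foreground and per-structure area, maximum diameter and roundness.

#' Split a class mask into structures by watershed
#'
#' Applies the watershed transform to the Euclidean distance transform of
#' the mask, which separates structures that are connected only by a narrow
#' neck of pixels.  Nearby regional maxima of the distance map (within
#' `merge_radius` pixels, or shallower than `tolerance`) are merged to
#' suppress over-segmentation from distance-transform plateaus.
#'
#' @param class_mask binary mask of one cell class.
#' @param tolerance minimum depth separating two catchment basins.
#' @param merge_radius neighborhood radius for regional-maximum detection.
#' @return integer label matrix partitioning the mask (0 outside).
#' @export
watershed_split <- function(class_mask, tolerance = 1, merge_radius = 2) {
  m <- matrix(as.numeric(class_mask != 0), nrow(class_mask), ncol(class_mask))
  if (!any(m > 0)) return(matrix(0L, nrow(m), ncol(m)))
  d <- as.matrix(EBImage::distmap(m))
  w <- EBImage::watershed(d, tolerance = tolerance, ext = merge_radius)
  matrix(as.integer(round(as.matrix(w))), nrow(m), ncol(m))
}

#' Morphometrics of labeled structures
#'
#' Per structure: area `A` (pixel count), maximum diameter `D` (Feret
#' diameter over the convex hull), and roundness `4 pi A / (pi D)^2` (1 for
#' a perfect disc).
#'
#' @param labels integer structure label matrix.
#' @param class class name recorded for all structures (optional).
#' @param well_id well identifier recorded for all structures (optional).
#' @return data.frame with `well_id`, `structure_id`, `class`, `area_px`,
#'   `max_diameter_px`, `roundness`.
#' @export
structure_morphometrics <- function(labels, class = NA_character_,
                                    well_id = NA_character_) {
  px <- split_labels(labels)
  nr <- nrow(labels)
  rows <- lapply(names(px), function(id) {
    idx <- px[[id]]
    r <- (idx - 1) %% nr + 1
    cc <- (idx - 1) %/% nr + 1
    d <- feret_diameter(r, cc)
    data.frame(well_id = well_id, structure_id = as.integer(id),
               class = class, area_px = length(idx), max_diameter_px = d,
               roundness = roundness(length(idx), d))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(well_id = character(), structure_id = integer(),
                      class = character(), area_px = numeric(),
                      max_diameter_px = numeric(), roundness = numeric())
  out
}

#' Structure table of a classified well
#'
#' Splits the tumor and fibroblast class masks by [watershed_split()] and
#' computes [structure_morphometrics()] for each; rounded single cells
#' bypass the watershed (each connected component is one structure by
#' definition).
#'
#' @param classmap class matrix from [classify_well()] (values 0-3).
#' @param well_id recorded in all rows.
#' @return data.frame of structure records for the three classes.
#' @export
well_structures <- function(classmap, well_id = "well") {
  cls <- if (is.list(classmap)) classmap$class else classmap
  parts <- list()
  for (spec in list(list(v = TRUTH_TUMOR, name = "tumor", ws = TRUE),
                    list(v = TRUTH_FIBROBLAST, name = "fibroblast", ws = TRUE),
                    list(v = TRUTH_SINGLE, name = "rounded_single", ws = FALSE))) {
    m <- cls == spec$v
    lab <- if (spec$ws) watershed_split(m) else label_components(m, 8)
    parts[[spec$name]] <- structure_morphometrics(lab, spec$name, well_id)
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}


#' Well-level summary
#'
#' Total area per class and the count of rounded single cells (connected
#' components of that class).  Class areas sum to the total foreground area
#' of the class map.
#'
#' @param classmap class matrix from [classify_well()] (or the list it
#'   returns).
#' @param well_id well identifier.
#' @return one-row data.frame with `well_id`, `tumor_area`,
#'   `fibroblast_area`, `single_cell_area`, `single_cell_count`.
#' @export
well_summary <- function(classmap, well_id = "well") {
  cls <- if (is.list(classmap)) classmap$class else classmap
  data.frame(
    well_id = well_id,
    tumor_area = sum(cls == TRUTH_TUMOR),
    fibroblast_area = sum(cls == TRUTH_FIBROBLAST),
    single_cell_area = sum(cls == TRUTH_SINGLE),
    single_cell_count = max(label_components(cls == TRUTH_SINGLE, 8))
  )
}
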