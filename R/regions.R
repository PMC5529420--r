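# Splitting the foreground into classification units: rounded-single-cell
# exclusion, hexagonal seeding, and seeded geodesic (Voronoi) propagation.

#' Rounded single-cell rule
#'
#' Small round structures are dead or dying cells of either type; they are
#' excluded from texture classification and reported as a third class.
#'
#' @param max_diameter structures with maximum (Feret) diameter strictly
#'   below this qualify (default 30 px).
#' @param min_roundness minimum roundness (default 0.5).
#' @return a `single_cell_rule` list.
#' @export
single_cell_rule <- function(max_diameter = 30, min_roundness = 0.5) {
  stopifnot(max_diameter > 0, min_roundness > 0)
  structure(list(max_diameter = max_diameter, min_roundness = min_roundness),
            class = "single_cell_rule")
}

#' Extract rounded single cells from a foreground mask
#'
#' Moves every 8-connected component with Feret diameter below
#' `rule$max_diameter` and roundness of at least `rule$min_roundness` into a
#' separate mask.  The two returned masks are disjoint and their union is
#' the input mask; re-applying the rule to `remaining` extracts nothing.
#'
#' @param mask binary foreground mask.
#' @param rule a [single_cell_rule()].
#' @return list with binary masks `single_cells` and `remaining`.
#' @export
extract_rounded_single_cells <- function(mask, rule = single_cell_rule()) {
  stopifnot(inherits(rule, "single_cell_rule"))
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  singles <- matrix(0L, nrow(m), ncol(m))
  lab <- label_components(m, connectivity = 8)
  nr <- nrow(m)
  for (px in split_labels(lab)) {
    rows <- (px - 1) %% nr + 1
    cols <- (px - 1) %/% nr + 1
    d <- feret_diameter(rows, cols)
    if (d < rule$max_diameter && roundness(length(px), d) >= rule$min_roundness) {
      singles[px] <- 1L
      m[px] <- 0L
    }
  }
  list(single_cells = singles, remaining = m)
}

#' Hexagonal seed lattice over a mask
#'
#' Seed points on a hexagonal lattice whose Voronoi cells have approximately
#' `target_area` pixels; seeds falling on background are dropped, and any
#' foreground component left without a seed receives one at its
#' interior-most pixel (maximum of the distance transform), so that every
#' component can be propagated.
#'
#' @param mask binary foreground mask.
#' @param target_area intended region area in pixels (default 350, about one
#'   large cell or a small multicellular structure).
#' @return integer matrix of seed labels (0 elsewhere), labels consecutive
#'   in raster order.
#' @export
hex_seeds <- function(mask, target_area = 350) {
  stopifnot(target_area >= 10)
  nr <- nrow(mask); nc <- ncol(mask)
  m <- mask != 0
  d <- sqrt(2 * target_area / sqrt(3))  # lattice spacing for hex cell area
  dy <- d * sqrt(3) / 2
  seeds <- matrix(0L, nr, nc)
  label <- 0L
  rowpos <- seq(1 + dy / 2, nr, by = dy)
  for (k in seq_along(rowpos)) {
    offset <- if (k %% 2 == 0) d / 2 else 0
    colpos <- seq(1 + d / 2 + offset, nc, by = d)
    for (x in colpos) {
      i <- round(rowpos[k]); j <- round(x)
      if (i >= 1 && i <= nr && j >= 1 && j <= nc && m[i, j]) {
        label <- label + 1L
        seeds[i, j] <- label
      }
    }
  }
  # fallback: one seed at the interior-most pixel of unseeded components
  comp <- label_components(m, connectivity = 8)
  if (max(comp) > 0) {
    seeded <- unique(comp[seeds > 0])
    todo <- setdiff(seq_len(max(comp)), seeded)
    if (length(todo)) {
      dm <- as.matrix(EBImage::distmap(matrix(as.numeric(m), nr, nc)))
      for (lab in todo) {
        px <- which(comp == lab)
        label <- label + 1L
        seeds[px[which.max(dm[px])]] <- label
      }
    }
  }
  seeds
}

#' Propagate Voronoi-style regions from seeds
#'
#' Assigns every foreground pixel to its geodesically nearest seed, distance
#' being measured within the mask so regions never cross background gaps.
#' Region shape is controlled purely by the seeds (no intensity weighting).
#' Regions smaller than `min_region_area` pixels (clipped lattice remnants at
#' mask borders) are merged into their largest adjacent region, as texture
#' features are meaningless on a handful of pixels.
#'
#' @param mask binary foreground mask.
#' @param seeds integer seed label matrix, e.g. from [hex_seeds()]; every
#'   mask component must contain at least one seed.
#' @param min_region_area regions below this size are merged (default 20).
#' @return integer region label matrix partitioning the mask, with a
#'   `sizes` attribute (named pixel counts).
#' @export
propagate_regions <- function(mask, seeds, min_region_area = 20) {
  m <- mask != 0
  comp <- label_components(m, connectivity = 8)
  if (max(comp) > 0) {
    seeded <- unique(comp[seeds > 0 & m])
    if (length(setdiff(seq_len(max(comp)), seeded)))
      stop("unseeded foreground component; generate seeds with hex_seeds()")
  }
  lab <- EBImage::propagate(matrix(0, nrow(mask), ncol(mask)),
                            seeds = seeds, mask = m, lambda = 1)
  lab <- matrix(as.integer(round(as.matrix(lab))), nrow(mask), ncol(mask))

  # merge tiny clipped regions into their largest neighboring region
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes > 0 & sizes < min_region_area)
  nr <- nrow(lab)
  for (s in small) {
    px <- which(lab == s)
    rows <- (px - 1) %% nr + 1
    cols <- (px - 1) %/% nr + 1
    nb <- integer(0)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- rows + dr; cc <- cols + dc
      ok <- rr >= 1 & rr <= nr & cc <= ncol(lab) & cc >= 1
      v <- lab[cbind(rr[ok], cc[ok])]
      nb <- c(nb, v[v > 0 & v != s])
    }
    if (length(nb)) {
      target <- unique(nb)[which.max(sizes[unique(nb)])] # largest neighbor
      lab[px] <- target
      sizes[target] <- sizes[target] + length(px)
      sizes[s] <- 0L
    }
  }
  sizes <- tabulate(lab[lab > 0])
  attr(lab, "sizes") <- setNames(sizes[sizes > 0],
                                 which(sizes > 0))
  lab
}
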