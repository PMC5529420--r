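# shared fixtures: geometric masks and downsized synthetic wells

disc_mask <- function(nr, nc, cy, cx, r) {
  d <- sqrt(outer((1:nr) - cy, rep(1, nc))^2 +
              outer(rep(1, nr), (1:nc) - cx)^2)
  matrix(as.integer(d <= r), nr, nc)
}

ellipse_mask <- function(nr, nc, cy, cx, ry, rx) {
  u <- outer((1:nr) - cy, rep(1, nc)) / ry
  v <- outer(rep(1, nr), (1:nc) - cx) / rx
  matrix(as.integer(u^2 + v^2 <= 1), nr, nc)
}

# number of enclosed background holes (4-connected background duality)
count_holes <- function(mask) {
  bg <- label_components(mask == 0, connectivity = 4)
  nr <- nrow(mask); nc <- ncol(mask)
  border <- unique(c(bg[1, ], bg[nr, ], bg[, 1], bg[, nc]))
  length(setdiff(unique(bg[bg > 0]), border))
}

n_components <- function(mask) max(label_components(mask, connectivity = 8))

# random blob mask: union of discs, possibly with punched holes
random_blob_mask <- function(nr = 60, nc = 60, n_blobs = 4, punch = TRUE) {
  m <- matrix(0L, nr, nc)
  for (k in seq_len(n_blobs)) {
    r <- runif(1, 4, 12)
    m <- m | disc_mask(nr, nc, runif(1, r + 2, nr - r - 1),
                       runif(1, r + 2, nc - r - 1), r)
  }
  m <- matrix(as.integer(m), nr, nc)
  if (punch && runif(1) < 0.5) {
    idx <- which(m == 1)
    if (length(idx) > 50) {
      c0 <- idx[sample(length(idx), 1)]
      cy <- (c0 - 1) %% nr + 1; cx <- (c0 - 1) %/% nr + 1
      m[disc_mask(nr, nc, cy, cx, runif(1, 1, 3)) == 1] <- 0L
    }
  }
  m
}

# downsized well parameters used throughout the tests; same object mix and
# intensity regime as the full-size defaults
small_well_params <- function(seed, ...) {
  args <- list(image_shape = c(224, 288), n_organoids = 3,
               organoid_radius_range = c(16, 32), n_fibroblasts = 8,
               fibroblast_length_range = c(60, 140), n_single_cells = 8,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_well_params, args)
}

feature_cols <- function(df) {
  setdiff(names(df), c("well_id", "region_id", "culture_method", "n_pixels",
                       "label", "vote_fraction"))
}

# region feature table + majority labels for a list of wells
labeled_features <- function(seeds, params_fun = small_well_params) {
  out <- list()
  for (s in seeds) {
    w <- generate_well(params_fun(s))
    m <- threshold_mask(w$image)
    sp <- extract_rounded_single_cells(m)
    if (!any(sp$remaining > 0)) next
    r <- propagate_regions(sp$remaining, hex_seeds(sp$remaining))
    f <- region_features(w$image, r, well_id = paste0("w", s))
    lab <- majority_vote_labels(r, w$truth)
    out[[length(out) + 1]] <- merge(f, lab, by = "region_id")
  }
  do.call(rbind, out)
}

reduced_design <- function(feats, reducer = NULL) {
  X <- feats[, feature_cols(feats)]
  if (is.null(reducer)) reducer <- fit_reducer(X)
  list(X = data.frame(apply_reducer(reducer, X),
                      culture_method = feats$culture_method),
       y = factor(feats$label, levels = c("fibroblast", "tumor")),
       reducer = reducer)
}
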