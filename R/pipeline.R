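# End-to-end orchestration: simulate (or load) -> threshold -> classify ->
# segment -> statistics, with plain-file handoff between stages and a
# machine-readable run log.

#' Pipeline configuration
#'
#' @param out_dir output directory for all per-well artifacts and tables.
#' @param design a [plate_design()] describing the plate to simulate.
#' @param base_params [synthetic_well_params()] for control wells.
#' @param threshold a [threshold_config()].
#' @param rule a [single_cell_rule()].
#' @param target_area region seed area in pixels.
#' @param classifier a [classifier_spec()].
#' @param n_training_wells wells (taken from the start of the design) whose
#'   ground truth is used to train the region classifier.
#' @param variance_target PCA explained-variance target.
#' @param seed global seed; the run is fully reproducible given the
#'   configuration and seed.
#' @param verbose print stage progress.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, design, base_params = synthetic_well_params(),
                            threshold = threshold_config(),
                            rule = single_cell_rule(), target_area = 350,
                            classifier = classifier_spec("svm_gaussian"),
                            n_training_wells = 6, variance_target = 0.95,
                            seed = 1L, verbose = FALSE) {
  stopifnot(inherits(design, "plate_design"))
  structure(list(out_dir = out_dir, design = design, base_params = base_params,
                 threshold = threshold, rule = rule, target_area = target_area,
                 classifier = classifier, n_training_wells = n_training_wells,
                 variance_target = variance_target, seed = as.integer(seed),
                 verbose = verbose),
            class = "pipeline_config")
}

stage_guard <- function(stage, well_id, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed for well '%s': %s", stage, well_id,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the five stages (simulate, threshold, classify, segment,
#' statistics) over the configured plate, writes per-well masks and class
#' maps, the well summary / structure / test tables as CSV, and a run log
#' with per-stage timings and the effective parameter set.  Two runs with
#' identical configuration and seed produce byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the plate, model, reducer, summaries,
#'   structures, tests and the log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "masks"), showWarnings = FALSE)
  dir.create(file.path(config$out_dir, "classmaps"), showWarnings = FALSE)
  log <- list()
  tick <- function(stage, t0) {
    log[[length(log) + 1]] <<- list(stage = stage,
                                    seconds = round(as.numeric(Sys.time()) - t0, 2))
    if (config$verbose) message(sprintf("stage %-10s %6.1fs", stage,
                                        log[[length(log)]]$seconds))
  }

  # 1. simulate
  t0 <- as.numeric(Sys.time())
  p <- config$base_params; p$seed <- config$seed
  plate <- stage_guard("simulate", "*", generate_plate(config$design, p))
  tick("simulate", t0)

  # 2. threshold
  t0 <- as.numeric(Sys.time())
  masks <- lapply(plate, function(w)
    stage_guard("threshold", w$well_id, threshold_mask(w$image, config$threshold)))
  names(masks) <- vapply(plate, `[[`, "", "well_id")
  for (i in seq_along(plate))
    write_gray(masks[[i]] * 1, file.path(config$out_dir, "masks",
                                         paste0(plate[[i]]$well_id, ".png")))
  tick("threshold", t0)

  # 3. classify: train on the ground truth of the first wells, then apply
  t0 <- as.numeric(Sys.time())
  set.seed(config$seed)
  ntrain <- min(config$n_training_wells, length(plate))
  train <- training_table(plate[seq_len(ntrain)], masks[seq_len(ntrain)],
                          config$rule, config$target_area)
  reducer <- fit_reducer(train$features[, feature_columns(train$features)],
                         config$variance_target)
  Z <- apply_reducer(reducer, train$features[, feature_columns(train$features)])
  Xtr <- data.frame(Z, culture_method = train$features$culture_method)
  cv <- cross_validate(config$classifier, Xtr, train$labels,
                       k = min(10, floor(nrow(Xtr) / 2)), seed = config$seed)
  model <- train_classifier(config$classifier, Xtr, train$labels)
  model$threshold <- cv$threshold
  classmaps <- lapply(seq_along(plate), function(i)
    stage_guard("classify", plate[[i]]$well_id,
                classify_well(plate[[i]]$image, model, reducer,
                              mask = masks[[i]], rule = config$rule,
                              cfg = config$threshold,
                              target_area = config$target_area)))
  for (i in seq_along(plate))
    write_gray(classmaps[[i]]$class / 255,
               file.path(config$out_dir, "classmaps",
                         paste0(plate[[i]]$well_id, "_class.png")))
  tick("classify", t0)

  # 4. segment
  t0 <- as.numeric(Sys.time())
  summaries <- do.call(rbind, lapply(seq_along(plate), function(i)
    stage_guard("segment", plate[[i]]$well_id,
                well_summary(classmaps[[i]], plate[[i]]$well_id))))
  structures <- do.call(rbind, lapply(seq_along(plate), function(i)
    stage_guard("segment", plate[[i]]$well_id,
                well_structures(classmaps[[i]], plate[[i]]$well_id))))
  write.csv(summaries, file.path(config$out_dir, "summaries.csv"),
            row.names = FALSE)
  write.csv(structures, file.path(config$out_dir, "structures.csv"),
            row.names = FALSE)
  tick("segment", t0)

  # 5. statistics
  t0 <- as.numeric(Sys.time())
  set.seed(config$seed + 1L)
  tests <- stage_guard("statistics", "*",
                       treatment_tests(summaries, structures, config$design))
  write.csv(tests, file.path(config$out_dir, "tests.csv"), row.names = FALSE)
  tick("statistics", t0)

  log_df <- do.call(rbind, lapply(log, as.data.frame))
  yaml::write_yaml(list(seed = config$seed,
                        parameters = config_echo(config),
                        stages = log_df$stage,
                        cv_metrics = as.list(round(cv$metrics, 4))),
                   file.path(config$out_dir, "run_log.yaml"))
  write.csv(log_df, file.path(config$out_dir, "timings.csv"), row.names = FALSE)
  invisible(list(plate = plate, masks = masks, classmaps = classmaps,
                 model = model, reducer = reducer, cv = cv,
                 summaries = summaries, structures = structures,
                 tests = tests, log = log_df))
}

# flatten the effective parameter set for the run log
config_echo <- function(config) {
  list(threshold = unclass(config$threshold),
       single_cell_rule = unclass(config$rule),
       target_area = config$target_area,
       classifier = unclass(config$classifier),
       n_training_wells = config$n_training_wells,
       base_params = lapply(unclass(config$base_params), function(x) x))
}

# region features + majority-vote labels for a set of truth-bearing wells
training_table <- function(wells, masks, rule, target_area) {
  feats <- list(); labels <- list()
  for (i in seq_along(wells)) {
    w <- wells[[i]]
    split <- extract_rounded_single_cells(masks[[i]], rule)
    if (!any(split$remaining > 0)) next
    seeds <- hex_seeds(split$remaining, target_area)
    regions <- propagate_regions(split$remaining, seeds)
    f <- region_features(w$image, regions, well_id = w$well_id)
    lab <- majority_vote_labels(regions, w$truth)
    keep <- merge(f, lab, by = "region_id")
    feats[[length(feats) + 1]] <- keep
  }
  all <- do.call(rbind, feats)
  if (is.null(all) || nrow(all) < 10)
    stop("not enough labeled training regions")
  list(features = all, labels = factor(all$label, levels = CLASS_LEVELS))
}
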