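test_that("well generation is deterministic and honors object counts", {
  p <- small_well_params(11)
  w1 <- generate_well(p)
  w2 <- generate_well(p)
  expect_identical(w1$image, w2$image)
  expect_identical(w1$truth, w2$truth)
  expect_true(all(w1$image >= 0 & w1$image <= 1))
  # 8-bit quantization: every value is a multiple of 1/255
  expect_true(all(abs(w1$image * 255 - round(w1$image * 255)) < 1e-9))

  w0 <- generate_well(small_well_params(3, n_fibroblasts = 0))
  expect_equal(sum(w0$truth == 2), 0)
  wo <- generate_well(small_well_params(3, n_organoids = 0, n_single_cells = 0,
                                        n_fibroblasts = 5))
  expect_equal(sum(wo$truth %in% c(1, 3)), 0)
  expect_gt(sum(wo$truth == 2), 0)
})

test_that("foreground fraction matches the analytic object-area expectation", {
  p <- small_well_params(5)
  w <- generate_well(p)
  set.seed(p$seed) # replay the generator's object draws analytically
  observed <- sum(w$truth > 0)
  # generous bound from summed expected object areas (overlap reduces it)
  exp_org <- p$n_organoids * pi * mean(p$organoid_radius_range)^2
  exp_fib <- p$n_fibroblasts * mean(p$fibroblast_length_range) * 3 * 1.3
  exp_sng <- p$n_single_cells * pi * mean(c(3, 7.5))^2
  expected <- exp_org + exp_fib + exp_sng
  expect_lt(abs(observed - expected) / expected, 0.20)
})

test_that("too-small images fail naming the unplaceable object", {
  p <- small_well_params(1, image_shape = c(24, 24))
  expect_error(generate_well(p), "organoid")
})

test_that("expert masks reproduce the truth at zero disagreement", {
  w <- generate_well(small_well_params(2, image_shape = c(128, 160),
                                       n_organoids = 2, n_fibroblasts = 3,
                                       n_single_cells = 4,
                                       organoid_radius_range = c(12, 20)))
  ms <- generate_expert_masks(w$truth, 4, disagreement = 0, seed = 7)
  expect_length(ms, 4)
  for (m in ms) expect_equal(m, matrix(as.integer(w$truth > 0), nrow(w$truth)))
  av <- average_masks(generate_expert_masks(w$truth, 4, 0.4, seed = 9))
  expect_true(all(av %in% c(0, 0.25, 0.5, 0.75, 1)))
  expect_error(generate_expert_masks(w$truth, 4, 1.5), "disagreement")
})

test_that("expert-mask agreement decreases monotonically with disagreement", {
  w <- generate_well(small_well_params(4, image_shape = c(128, 160),
                                       n_organoids = 2, n_fibroblasts = 3,
                                       n_single_cells = 4,
                                       organoid_radius_range = c(12, 20)))
  iou <- function(a, b) sum(a & b) / sum(a | b)
  mean_iou <- function(dg, seed) {
    ms <- generate_expert_masks(w$truth, 4, dg, seed = seed)
    pr <- combn(4, 2)
    mean(apply(pr, 2, function(p) iou(ms[[p[1]]] > 0, ms[[p[2]]] > 0)))
  }
  levels <- c(0, 0.3, 0.6)
  curves <- sapply(1:20, function(s) sapply(levels, mean_iou, seed = s))
  avg <- rowMeans(curves)
  expect_true(all(diff(avg) < 0))
})

test_that("plate generation applies effects and yields one image per well", {
  eff <- data.frame(treatment = "drugA", area_effect = 0.5,
                    roundness_shift = 0, single_cell_rate = 1)
  des <- screen_design(patients = "P1", effects = eff, concentrations = 10,
                       replicates = 5, control_wells = 5)
  base <- small_well_params(5, n_organoids = 4, n_fibroblasts = 4,
                            n_single_cells = 5)
  plate <- generate_plate(des, base)
  expect_length(plate, nrow(des$wells))
  expect_setequal(vapply(plate, `[[`, "", "well_id"), des$wells$well_id)

  # a 0.5x area effect halves the median true organoid area within 15%
  areas <- vapply(plate, function(w) sum(w$truth == 1), numeric(1))
  trt <- des$wells$treatment == "drugA"
  ratio <- median(areas[trt]) / median(areas[!trt])
  expect_lt(abs(ratio - 0.5), 0.15)

  # unknown treated arm in the wells table is rejected
  bad_wells <- des$wells
  bad_wells$treatment[1] <- "mystery"
  expect_error(plate_design(bad_wells, eff), "unknown treatment")
})

test_that("a 60-well factorial design produces 60 wells", {
  eff <- data.frame(treatment = c("cisplatin", "docetaxel", "gemcitabine"),
                    area_effect = c(0.9, 0.5, 0.8),
                    roundness_shift = c(0, 0.4, 0),
                    single_cell_rate = c(1, 3, 1))
  des <- screen_design(patients = c("P1", "P2"), effects = eff,
                       concentrations = c(1, 10), replicates = 2,
                       control_wells = 3)
  # 2 patients x (3 control + 3 treatments x 2 concentrations x 2 reps) = 30
  expect_equal(nrow(des$wells), 30)
  des2 <- screen_design(patients = c("P1", "P2"), effects = eff,
                        concentrations = c(0.1, 1, 10), replicates = 2,
                        control_wells = 12)
  expect_equal(nrow(des2$wells), 60)
  base <- synthetic_well_params(image_shape = c(48, 64), n_organoids = 1,
                                organoid_radius_range = c(6, 9),
                                n_fibroblasts = 1,
                                fibroblast_length_range = c(15, 25),
                                n_single_cells = 1, seed = 1)
  plate <- generate_plate(des2, base)
  expect_length(plate, 60)
})

test_that("control wells are statistically indistinguishable across replicates", {
  base <- synthetic_well_params(image_shape = c(96, 128), n_organoids = 2,
                                organoid_radius_range = c(8, 14),
                                n_fibroblasts = 2,
                                fibroblast_length_range = c(30, 60),
                                n_single_cells = 3, seed = 0)
  eff <- data.frame(treatment = "drug", area_effect = 1,
                    roundness_shift = 0, single_cell_rate = 1)
  rejections <- 0
  for (s in 1:20) {
    des <- screen_design(patients = "P1", effects = eff, concentrations = 1,
                         replicates = 6, control_wells = 6)
    b <- base; b$seed <- s
    plate <- generate_plate(des, b)
    areas <- vapply(plate, function(w) sum(w$truth == 1), numeric(1))
    ctrl <- des$wells$treatment == "DMSO"
    # the treated arm has neutral effects: both groups are control draws
    v <- van_der_waerden(areas[ctrl], areas[!ctrl])
    if (v$p <= 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 1) # p > 0.01 in at least 19/20 seeds
})
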