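# Rank-based treatment-effect testing: two-sample Van der Waerden
# normal-scores test against the vehicle control, with starred summary
# tables for well totals and structure morphologies.

#' Two-sample Van der Waerden normal-scores test
#'
#' Pooled mid-ranks `r_i` are mapped to normal scores
#' `qnorm(r_i / (n + 1))`; the statistic is the squared standardized
#' difference of the group mean scores,
#' `sum_j n_j * mean(A_j)^2 / s^2` with `s^2 = sum(a_i^2) / (n - 1)`,
#' referred to the chi-square distribution with 1 degree of freedom.  For
#' small samples an exact/Monte-Carlo permutation p-value is available and
#' is the default below 15 observations per group; the statistic is
#' invariant under any strictly monotone transform of the pooled data.
#'
#' @param x,y numeric samples (each of length >= 2).
#' @param method `"auto"` (permutation if `min(n_x, n_y) < 15`, else
#'   asymptotic), `"asymptotic"`, or `"permutation"`.
#' @param n_perm Monte-Carlo permutations when full enumeration exceeds
#'   `n_perm` (the permutation p-value uses the add-one estimator).
#' @return list with `statistic`, `p`, `method`, and the group sizes.
#' @export
van_der_waerden <- function(x, y, method = c("auto", "asymptotic", "permutation"),
                            n_perm = 10000) {
  method <- match.arg(method)
  stopifnot(length(x) >= 2, length(y) >= 2)
  pooled <- c(x, y)
  n <- length(pooled)
  if (length(unique(pooled)) == 1)
    return(list(statistic = 0, p = 1, method = "degenerate",
                n_x = length(x), n_y = length(y)))
  if (method == "auto")
    method <- if (min(length(x), length(y)) < 15) "permutation" else "asymptotic"
  scores <- qnorm(rank(pooled, ties.method = "average") / (n + 1))
  stat_fun <- function(g1) {
    a1 <- scores[g1]; a2 <- scores[-g1]
    s2 <- sum(scores^2) / (n - 1)
    (length(a1) * mean(a1)^2 + length(a2) * mean(a2)^2) / s2
  }
  g1 <- seq_along(x)
  stat <- stat_fun(g1)
  if (method == "asymptotic") {
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    n1 <- length(x)
    n_total <- choose(n, n1)
    if (n_total <= n_perm) {
      combs <- combn(n, n1)
      stats <- apply(combs, 2, stat_fun)
      p <- mean(stats >= stat - 1e-12)
    } else {
      stats <- replicate(n_perm, stat_fun(sample(n, n1)))
      p <- (1 + sum(stats >= stat - 1e-12)) / (n_perm + 1)
    }
  }
  list(statistic = stat, p = p, method = method,
       n_x = length(x), n_y = length(y))
}

#' Significance stars
#'
#' @param p p-value(s).
#' @return `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#'   `""` otherwise.
#' @export
p_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) "" else if (pp < 0.001) "***" else if (pp < 0.01) "**"
    else if (pp < 0.05) "*" else ""
  }, character(1))
}

#' Treatment-effect tests against the vehicle control
#'
#' One Van der Waerden test per endpoint x treatment x concentration against
#' the pooled control wells.  Well-level endpoints (`tumor_area`,
#' `fibroblast_area`, `single_cell_count`) use one observation per well;
#' structure-level endpoints (`structure_area`, `structure_roundness`,
#' tumor structures only) pool structures across the replicate wells of a
#' condition, so their sample sizes are structure counts.
#'
#' @param summaries data.frame from [well_summary()] rows, one per well.
#' @param structures data.frame from [well_structures()] rows (may be
#'   `NULL` to skip structure endpoints).
#' @param design a [plate_design()]; tests are computed within each patient.
#' @param control control treatment name (defaults to the design's).
#' @return data.frame with endpoint, patient, treatment, concentration,
#'   group sizes, medians, statistic, p and stars.
#' @export
treatment_tests <- function(summaries, structures, design,
                            control = design$control) {
  wells <- design$wells
  if (!control %in% wells$treatment) stop("control wells missing from design")
  s <- merge(summaries, wells, by = "well_id")
  out <- list()
  well_endpoints <- c("tumor_area", "fibroblast_area", "single_cell_count")
  struct <- NULL
  if (!is.null(structures) && nrow(structures)) {
    struct <- merge(structures[structures$class == "tumor", ], wells,
                    by = "well_id")
  }
  for (patient in unique(wells$patient)) {
    sp <- s[s$patient == patient, ]
    ctrl <- sp[sp$treatment == control, ]
    conds <- unique(sp[sp$treatment != control, c("treatment", "concentration")])
    for (ci in seq_len(nrow(conds))) {
      tr <- conds$treatment[ci]; cc <- conds$concentration[ci]
      grp <- sp[sp$treatment == tr & sp$concentration == cc, ]
      for (ep in well_endpoints) {
        tst <- van_der_waerden(grp[[ep]], ctrl[[ep]])
        out[[length(out) + 1]] <- data.frame(
          endpoint = ep, patient = patient, treatment = tr,
          concentration = cc, n_treated = nrow(grp), n_control = nrow(ctrl),
          median_treated = median(grp[[ep]]), median_control = median(ctrl[[ep]]),
          statistic = tst$statistic, p = tst$p, stars = p_stars(tst$p))
      }
      if (!is.null(struct)) {
        stp <- struct[struct$patient == patient, ]
        gs <- stp[stp$treatment == tr & stp$concentration == cc, ]
        cs <- stp[stp$treatment == control, ]
        struct_eps <- c(structure_area = "area_px",
                        structure_roundness = "roundness")
        for (k in seq_along(struct_eps)) {
          ep <- struct_eps[[k]]; epname <- names(struct_eps)[k]
          if (nrow(gs) < 2 || nrow(cs) < 2) next
          tst <- van_der_waerden(gs[[ep]], cs[[ep]])
          out[[length(out) + 1]] <- data.frame(
            endpoint = epname, patient = patient, treatment = tr,
            concentration = cc, n_treated = nrow(gs), n_control = nrow(cs),
            median_treated = median(gs[[ep]]), median_control = median(cs[[ep]]),
            statistic = tst$statistic, p = tst$p, stars = p_stars(tst$p))
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
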