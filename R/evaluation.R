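# Continuous evaluation of thresholding results against multi-expert
# reference masks.

#' Average expert masks into a continuous reference
#'
#' Per-pixel arithmetic mean over binary expert annotations; values are
#' multiples of `1/n`, with gray shades marking expert disagreement.
#'
#' @param masks list of equally shaped binary masks.
#' @return numeric matrix on \[0, 1\].
#' @export
average_masks <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1)
  shp <- dim(masks[[1]])
  for (m in masks)
    if (!identical(dim(m), shp)) stop("all masks must have the same shape")
  Reduce(`+`, lapply(masks, function(m) (m != 0) * 1)) / length(masks)
}

#' Continuous false positive and false negative rates
#'
#' `FPR = mean(pmax(f - r, 0))` and `FNR = mean(pmax(r - f, 0))`: the
#' average amount of excess and missing foreground relative to a (possibly
#' continuous) reference.  With binary `f` and `r` these reduce to the
#' classic confusion-matrix rates FP/N and FN/N.
#'
#' @param f thresholded image, values on \[0, 1\] (typically binary).
#' @param r reference mask, values on \[0, 1\] (typically an expert
#'   average).
#' @return named numeric vector `c(FPR =, FNR =)`.
#' @export
fpr_fnr <- function(f, r) {
  if (!identical(dim(f), dim(r))) stop("f and r must have the same shape")
  d <- f - r
  c(FPR = mean(pmax(d, 0)), FNR = mean(pmax(-d, 0)))
}
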