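# Tissue vs non-tissue quantification from the raw NeuN + GFAP signal.

#' Combined squared tissue signal
#'
#' Adds the raw NeuN and GFAP intensities of one ROI pixel-wise (in a
#' widened numeric range, no 8-bit overflow) and squares the sum,
#' emphasizing true tissue over background noise. Range 0..260100.
#'
#' @param neun_roi,gfap_roi same-shape 8-bit matrices of one ROI.
#' @return Numeric matrix of squared sums.
#' @export
combined_tissue_signal <- function(neun_roi, gfap_roi) {
  if (!all(dim(neun_roi) == dim(gfap_roi))) {
    stop("NeuN and GFAP ROIs must have identical shape", call. = FALSE)
  }
  out <- (as.numeric(neun_roi) + as.numeric(gfap_roi))^2
  matrix(out, nrow(neun_roi), ncol(neun_roi))
}

#' Tissue-loss map of one ROI
#'
#' Pixels whose combined squared signal falls below the threshold (default
#' 50, applied to the squared intensities) are classified as non-tissue.
#' The binary non-tissue image is downsampled to the 11 x 10 grid, so a
#' cell's value is 255 x the fraction of lost tissue in that cell.
#'
#' @param combined output of [combined_tissue_signal()].
#' @param threshold non-tissue cutoff on the squared signal.
#' @param region optional region label.
#' @return A `tissue_loss_map` (a `downsampled_map` whose high intensities
#'   mean tissue loss).
#' @export
tissue_loss_map <- function(combined, threshold = 50, region = NULL) {
  nontissue <- combined < threshold
  attr(nontissue, "region") <- region
  attr(nontissue, "stain") <- "TissueLoss"
  out <- downsample(nontissue)
  class(out) <- c("tissue_loss_map", class(out))
  out
}

#' Delta tissue loss against control cortex
#'
#' Cell-wise difference between an experimental tissue-loss map and the
#' control map for the same region; higher values mean more tissue loss
#' than in non-implanted cortex.
#'
#' @param experimental,control `tissue_loss_map`s of the same region.
#' @return List with `map` (10 x 11 signed grid) and `scalar` (mean over
#'   cells).
#' @export
delta_tissue_loss <- function(experimental, control) {
  if (!is.null(experimental$region) && !is.null(control$region) &&
      !identical(experimental$region, control$region)) {
    stop("experimental and control maps are from different regions",
         call. = FALSE)
  }
  d <- experimental$grid - control$grid
  list(map = d, scalar = mean(d))
}
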