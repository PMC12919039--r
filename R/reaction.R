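# Delta signals against control cortex, exclusion rules, depth profiles and
# the tissue-reaction index.

#' Cell-wise mean of control occupancy maps
#'
#' @param controls list of `downsampled_map`s of one stain and region.
#' @param stain,region optional labels enforced on the inputs when given.
#' @return A `downsampled_map` with the cell-wise arithmetic mean.
#' @export
control_mean_map <- function(controls, stain = NULL, region = NULL) {
  if (length(controls) == 0L) stop("no control maps given", call. = FALSE)
  for (m in controls) {
    if (!inherits(m, "downsampled_map")) {
      stop("controls must be downsampled_map objects", call. = FALSE)
    }
    if (!is.null(stain) && !is.null(m$stain) && !identical(m$stain, stain)) {
      stop("control map stain mismatch", call. = FALSE)
    }
    if (!is.null(region) && !is.null(m$region) &&
        !identical(m$region, region)) {
      stop("control map region mismatch", call. = FALSE)
    }
  }
  g <- Reduce(`+`, lapply(controls, `[[`, "grid")) / length(controls)
  structure(list(grid = g,
                 region = region %||% controls[[1]]$region,
                 stain = stain %||% controls[[1]]$stain),
            class = "downsampled_map")
}

#' Experimental-minus-control delta map with tissue-loss exclusion
#'
#' Computes the cell-wise difference between an experimental occupancy map
#' and the control mean. Cells whose tissue-loss intensity exceeds
#' `loss_threshold` (default 190, i.e. more than 75% lost tissue) carry no
#' interpretable stain signal and are marked excluded; they are omitted
#' from every downstream mean. The threshold value itself is not excluded.
#'
#' @param exp,control_mean `downsampled_map`s of the same stain and region.
#' @param loss a `tissue_loss_map` of the experimental image, or `NULL` for
#'   no exclusion.
#' @param loss_threshold exclusion cutoff on the 0..255 loss intensity.
#' @return A `delta_map`: list with `grid` (10 x 11 signed values in
#'   \[-255, 255\]), logical `excluded` mask, `stain`, `region`.
#' @export
delta_map <- function(exp, control_mean, loss = NULL, loss_threshold = 190) {
  if (!all(dim(exp$grid) == dim(control_mean$grid))) {
    stop("map shapes differ", call. = FALSE)
  }
  if (!is.null(exp$region) && !is.null(control_mean$region) &&
      !identical(exp$region, control_mean$region)) {
    stop("experimental and control maps are from different regions",
         call. = FALSE)
  }
  excl <- matrix(FALSE, nrow(exp$grid), ncol(exp$grid))
  if (!is.null(loss)) {
    if (!all(dim(loss$grid) == dim(exp$grid))) {
      stop("loss map shape differs", call. = FALSE)
    }
    excl <- loss$grid > loss_threshold
  }
  structure(
    list(grid = exp$grid - control_mean$grid,
         excluded = excl,
         stain = exp$stain,
         region = exp$region),
    class = "delta_map"
  )
}

#' Exclude layer 1 from an upper-cortex NeuN delta map
#'
#' Layer 1 contains few neurons, so the first 3 of the 10 depth rows of the
#' upper-cortex grid (about the top 210 px of the ROI) are excluded from
#' NeuN averages in experimental and control conditions alike. Idempotent.
#'
#' @param neun_delta a `delta_map` with `stain == "NeuN"` and
#'   `region == "upper_cortex"`.
#' @param n_rows number of top grid rows to exclude.
#' @return The `delta_map` with rows 1..`n_rows` marked excluded.
#' @export
strip_layer1 <- function(neun_delta, n_rows = 3L) {
  stopifnot(inherits(neun_delta, "delta_map"))
  if (!identical(neun_delta$stain, "NeuN") ||
      !identical(neun_delta$region, "upper_cortex")) {
    stop("layer-1 stripping applies only to upper-cortex NeuN maps",
         call. = FALSE)
  }
  neun_delta$excluded[seq_len(n_rows), ] <- TRUE
  neun_delta
}

#' Mean delta over the non-excluded cells of an ROI
#'
#' @param dmap a `delta_map`.
#' @return Signed scalar mean; `NA` (with a warning) when every cell is
#'   excluded.
#' @export
roi_mean_delta <- function(dmap) {
  stopifnot(inherits(dmap, "delta_map"))
  vals <- dmap$grid[!dmap$excluded]
  if (length(vals) == 0L) {
    warning("all cells excluded; region mean undefined")
    return(NA_real_)
  }
  mean(vals)
}

#' Tissue-reaction index
#'
#' Combines neuronal loss with astrocytic reactivity:
#' \deqn{Idx = (|\min(\Delta NeuN, 0)| + \max(\Delta GFAP, 0)) / 510}
#' Positive delta-NeuN and negative delta-GFAP reflect biological variation
#' rather than a reaction and are zeroed before the addition; the
#' denominator 510 is the sum of the two 0..255 channel ranges, so the
#' index runs from 0 (no reaction) to 1 (complete neuronal loss plus
#' maximal astrocytic response). The normative form takes the two region
#' means as scalars; matrices are evaluated cell-wise and averaged.
#'
#' @param dneun,dgfap scalar region-mean deltas in \[-255, 255\], or
#'   equal-shape matrices.
#' @return Index in \[0, 1\] (scalar; cell-wise mean for matrix input).
#' @export
#' @examples
#' tissue_reaction_index(-255, 255)  # maximal reaction: 1
#' tissue_reaction_index(0, 0)       # no reaction: 0
#' tissue_reaction_index(-51, 51)    # 102/510 = 0.2
tissue_reaction_index <- function(dneun, dgfap) {
  if (any(abs(dneun) > 255, na.rm = TRUE) ||
      any(abs(dgfap) > 255, na.rm = TRUE)) {
    stop("delta inputs must lie in [-255, 255]", call. = FALSE)
  }
  idx <- (abs(pmin(dneun, 0)) + pmax(dgfap, 0)) / 510
  if (is.matrix(idx)) mean(idx) else idx
}

#' Depth profile of a delta map
#'
#' Per-row means over non-excluded cells (row 1 is the shallow edge of the
#' ROI), plus the top-half (rows 1-5) and bottom-half (rows 6-10) means
#' used for within-ROI depth comparisons.
#'
#' @param dmap a `delta_map`.
#' @return List with `profile` (10-vector, `NA` for fully excluded rows),
#'   `top_mean`, `bottom_mean`.
#' @export
depth_profile <- function(dmap) {
  stopifnot(inherits(dmap, "delta_map"))
  g <- dmap$grid
  g[dmap$excluded] <- NA
  prof <- rowMeans(g, na.rm = TRUE)
  prof[is.nan(prof)] <- NA
  nr <- nrow(dmap$grid)
  top <- g[seq_len(nr / 2), , drop = FALSE]
  bot <- g[(nr / 2 + 1L):nr, , drop = FALSE]
  list(profile = prof,
       top_mean = mean(top, na.rm = TRUE),
       bottom_mean = mean(bot, na.rm = TRUE))
}
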