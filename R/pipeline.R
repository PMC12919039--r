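# End-to-end histology pipeline: section -> per-shank ROIs -> occupancy and
# tissue-loss maps -> delta summaries against control cortex.

REGIONS <- c("upper_cortex", "lower_cortex", "white_matter")
STAINS <- c("NeuN", "GFAP", "IBA1")

#' Quantify one shank image
#'
#' Runs the segmentation chain (Moments binarization, stain-specific mask
#' filtering, 11 x 10 downsampling) for the requested stains and computes
#' the tissue-loss map per depth region from the raw NeuN + GFAP signal.
#'
#' @param shank a `shank_image` from [crop_shank()].
#' @param profiles named list of [stain_filter_profile()]s.
#' @param stains stains to segment (tissue loss always uses raw NeuN and
#'   GFAP).
#' @return List with `maps` (`maps[[stain]][[region]]`, `downsampled_map`s)
#'   and `loss` (`loss[[region]]`, `tissue_loss_map`s); absent white matter
#'   yields `NULL` entries.
#' @export
quantify_shank <- function(shank, profiles = default_stain_profiles(),
                           stains = STAINS) {
  stains <- match.arg(stains, STAINS, several.ok = TRUE)
  rois <- lapply(stats::setNames(nm = unique(c(stains, "NeuN", "GFAP"))),
                 function(s) extract_rois(shank, s))
  maps <- lapply(stats::setNames(nm = stains), function(s) {
    lapply(rois[[s]], function(roi) {
      if (is.null(roi)) return(NULL)
      downsample(filter_mask(binarize(roi), profiles[[s]]))
    })
  })
  loss <- lapply(stats::setNames(nm = REGIONS), function(rg) {
    n_roi <- rois[["NeuN"]][[rg]]
    g_roi <- rois[["GFAP"]][[rg]]
    if (is.null(n_roi) || is.null(g_roi)) return(NULL)
    tissue_loss_map(combined_tissue_signal(n_roi, g_roi), region = rg)
  })
  list(maps = maps, loss = loss)
}

#' Build the control reference from control sections
#'
#' Each control section is cropped at its centre column (no lesion) and
#' quantified like an implanted shank; the reference is the cell-wise mean
#' occupancy map per stain and region plus the mean tissue-loss map per
#' region.
#'
#' @param controls list of `list(section, truth)` as produced by
#'   [generate_control_section()], or of bare `section_image`s.
#' @param profiles named list of [stain_filter_profile()]s.
#' @param stains stains to include.
#' @return List with `maps[[stain]][[region]]` and `loss[[region]]` mean
#'   maps.
#' @export
control_reference <- function(controls, profiles = default_stain_profiles(),
                              stains = STAINS) {
  if (length(controls) == 0L) stop("no control sections", call. = FALSE)
  qs <- lapply(controls, function(ctl) {
    sec <- if (inherits(ctl, "section_image")) ctl else ctl$section
    W <- ncol(sec$channels[[1]])
    quantify_shank(crop_shank(sec, round(W / 2)), profiles, stains)
  })
  maps <- lapply(stats::setNames(nm = stains), function(s) {
    lapply(stats::setNames(nm = REGIONS), function(rg) {
      ms <- Filter(Negate(is.null), lapply(qs, function(q) q$maps[[s]][[rg]]))
      if (length(ms) == 0L) return(NULL)
      control_mean_map(ms, stain = s, region = rg)
    })
  })
  loss <- lapply(stats::setNames(nm = REGIONS), function(rg) {
    ls <- Filter(Negate(is.null), lapply(qs, function(q) q$loss[[rg]]))
    if (length(ls) == 0L) return(NULL)
    g <- Reduce(`+`, lapply(ls, `[[`, "grid")) / length(ls)
    structure(list(grid = g, region = rg, stain = "TissueLoss"),
              class = c("tissue_loss_map", "downsampled_map"))
  })
  list(maps = maps, loss = loss)
}

#' Delta maps of one quantified shank against the control reference
#'
#' @param q output of [quantify_shank()].
#' @param ctrl output of [control_reference()].
#' @param loss_threshold tissue-loss exclusion cutoff (see [delta_map()]).
#' @return List `dmaps[[stain]][[region]]` of `delta_map`s (layer 1
#'   stripped for upper-cortex NeuN) and `dloss[[region]]` of
#'   [delta_tissue_loss()] results.
#' @export
shank_delta_maps <- function(q, ctrl, loss_threshold = 190) {
  stains <- names(q$maps)
  dmaps <- lapply(stats::setNames(nm = stains), function(s) {
    lapply(stats::setNames(nm = REGIONS), function(rg) {
      em <- q$maps[[s]][[rg]]
      cm <- ctrl$maps[[s]][[rg]]
      if (is.null(em) || is.null(cm)) return(NULL)
      dm <- delta_map(em, cm, q$loss[[rg]], loss_threshold = loss_threshold)
      if (s == "NeuN" && rg == "upper_cortex") dm <- strip_layer1(dm)
      dm
    })
  })
  dloss <- lapply(stats::setNames(nm = REGIONS), function(rg) {
    if (is.null(q$loss[[rg]]) || is.null(ctrl$loss[[rg]])) return(NULL)
    delta_tissue_loss(q$loss[[rg]], ctrl$loss[[rg]])
  })
  list(dmaps = dmaps, dloss = dloss)
}

#' Summarize a synthetic cohort as a tidy delta-summary table
#'
#' Crops one shank image per implanted section, quantifies it and the
#' control reference, and emits one row per section x region with the mean
#' delta signals, the delta tissue loss, and the tissue-reaction index
#' computed from the two region-mean deltas. White-matter rows are flagged
#' `statistical = FALSE`: NeuN is non-informative there, so the index is
#' reported but not meant for group statistics.
#'
#' @param cohort a `probe_cohort` from [generate_cohort()].
#' @param profiles named list of [stain_filter_profile()]s.
#' @param stains stains to quantify; the index needs NeuN and GFAP.
#' @param loss_threshold tissue-loss exclusion cutoff.
#' @return Data frame: manifest columns plus `region`, `delta_neun`,
#'   `delta_gfap`, `delta_iba1`, `delta_tissue_loss`,
#'   `idx_tissue_reaction`, `statistical`.
#' @export
summarize_cohort <- function(cohort, profiles = default_stain_profiles(),
                             stains = STAINS, loss_threshold = 190) {
  stopifnot(inherits(cohort, "probe_cohort"))
  ctrl <- control_reference(cohort$controls, profiles, stains)
  rows <- lapply(cohort$sections, function(sec) {
    shank <- crop_shank(sec$section, sec$section$lesion_columns[1],
                        shank_width_um = sec$meta$width_um)
    q <- quantify_shank(shank, profiles, stains)
    d <- shank_delta_maps(q, ctrl, loss_threshold)
    mean_or_na <- function(dm) if (is.null(dm)) NA_real_ else {
      suppressWarnings(roi_mean_delta(dm))
    }
    per_region <- lapply(REGIONS, function(rg) {
      dn <- mean_or_na(d$dmaps[["NeuN"]][[rg]])
      dg <- mean_or_na(d$dmaps[["GFAP"]][[rg]])
      di <- mean_or_na(d$dmaps[["IBA1"]][[rg]])
      dl <- if (is.null(d$dloss[[rg]])) NA_real_ else d$dloss[[rg]]$scalar
      idx <- if (is.na(dn) || is.na(dg)) NA_real_ else {
        tissue_reaction_index(dn, dg)
      }
      cbind(sec$meta,
            data.frame(region = rg, delta_neun = dn, delta_gfap = dg,
                       delta_iba1 = di, delta_tissue_loss = dl,
                       idx_tissue_reaction = idx,
                       statistical = rg != "white_matter",
                       stringsAsFactors = FALSE))
    })
    do.call(rbind, per_region)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
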