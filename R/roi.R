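# ROI geometry is defined in pixels: per-shank crops are 800 px wide and the
# three depth regions of interest are 800 x 700 px each, anchored at the pia
# and at the cortex/white-matter boundary. Row 1 is the pial side; rows
# increase with depth.

ROI_WIDTH <- 800L
ROI_DEPTH <- 700L

#' Orient a section so that the narrowest shank lies on the left
#'
#' Multi-shank sections are normalized so that the 35 um shank track is the
#' leftmost lesion. If the shank widths run widest-to-narrowest from left to
#' right, the image and the lesion columns are mirrored horizontally;
#' otherwise the section is returned unchanged. The operation is idempotent.
#'
#' @param section a `section_image` with non-empty `lesion_columns`.
#' @param shank_widths shank widths (um) in current left-to-right order of
#'   `lesion_columns`.
#' @param override allow orientation when the width order is ambiguous
#'   (equal widths); the section is then returned unchanged.
#' @return The oriented `section_image`; `lesion_columns` remapped and kept
#'   sorted left to right, with the matching width order in attribute
#'   `shank_widths`.
#' @export
orient_section <- function(section, shank_widths, override = FALSE) {
  stopifnot(inherits(section, "section_image"))
  if (length(section$lesion_columns) == 0L) {
    stop("section has no annotated lesion columns", call. = FALSE)
  }
  if (length(shank_widths) != length(section$lesion_columns)) {
    stop("`shank_widths` must match `lesion_columns` in length", call. = FALSE)
  }
  n <- length(shank_widths)
  if (n > 1L && shank_widths[1] == shank_widths[n]) {
    if (!override) {
      stop("ambiguous shank order (equal outer widths); ",
           "pass `override = TRUE` to keep the section as is", call. = FALSE)
    }
    attr(section, "shank_widths") <- shank_widths
    return(section)
  }
  if (n > 1L && shank_widths[1] > shank_widths[n]) {
    W <- ncol(section$channels[[1]])
    section$channels <- lapply(section$channels, function(ch) ch[, W:1])
    section$lesion_columns <- rev(W + 1L - section$lesion_columns)
    shank_widths <- rev(shank_widths)
  }
  attr(section, "shank_widths") <- shank_widths
  section
}

#' Crop an 800-px-wide per-shank image
#'
#' Cuts a crop centred on the lesion column, spanning columns
#' `lesion_col - 400` to `lesion_col + 399` and rows from the pial surface
#' down to 700 px below the cortex/white-matter boundary. Areas outside the
#' source image are zero-padded and flagged.
#'
#' @param section a `section_image`.
#' @param lesion_col column index of the shank-track centre.
#' @param shank_width_um optional shank width carried as metadata.
#' @return A `shank_image`: list with `channels` (each
#'   `(cortex depth + 700) x 800`), local `pia_row` (always 1),
#'   `wm_boundary_row`, `shank_width_um`, `pixel_size_um`, logical `padded`
#'   and `wm_absent` flags.
#' @export
crop_shank <- function(section, lesion_col, shank_width_um = NA_real_) {
  stopifnot(inherits(section, "section_image"))
  stopifnot_scalar(lesion_col, "lesion_col", 1)
  if (is.null(section$pia_row) || is.null(section$wm_boundary_row)) {
    stop("section lacks pia/white-matter annotations", call. = FALSE)
  }
  H <- nrow(section$channels[[1]]); W <- ncol(section$channels[[1]])
  cols <- (lesion_col - ROI_WIDTH / 2):(lesion_col + ROI_WIDTH / 2 - 1L)
  rows <- section$pia_row:(section$wm_boundary_row + ROI_DEPTH - 1L)
  in_c <- cols >= 1L & cols <= W
  in_r <- rows >= 1L & rows <= H
  padded <- !all(in_c) || !all(in_r)
  crop_one <- function(ch) {
    out <- matrix(0, length(rows), length(cols))
    out[which(in_r), which(in_c)] <- ch[rows[in_r], cols[in_c]]
    out
  }
  wm_local <- section$wm_boundary_row - section$pia_row + 1L
  wm_rows_missing <- sum(rows[wm_local:length(rows)] > H)
  structure(
    list(
      channels = lapply(section$channels, crop_one),
      pia_row = 1L,
      wm_boundary_row = wm_local,
      shank_width_um = shank_width_um,
      pixel_size_um = section$pixel_size_um,
      padded = padded,
      wm_absent = wm_rows_missing > ROI_DEPTH / 2
    ),
    class = "shank_image"
  )
}

#' Extract the three anatomically anchored depth ROIs
#'
#' From an 800-px-wide shank image, cuts three 800 x 700 px regions of
#' interest for one channel: *upper cortex* starting at the pial surface,
#' *lower cortex* ending at the cortex/white-matter boundary, and *white
#' matter* starting at that boundary. When the cortical depth is below
#' 700 px the two cortical ROIs overlap; both are still returned and the
#' overlap is signalled with a warning. If the shank image was flagged as
#' lacking white matter, the `white_matter` entry is `NULL`.
#'
#' @param shank a `shank_image` from [crop_shank()].
#' @param channel channel name (`"NeuN"`, `"GFAP"` or `"IBA1"`).
#' @return Named list `upper_cortex`, `lower_cortex`, `white_matter`; each a
#'   700 x 800 matrix with attributes `region` and `stain` (class
#'   `roi_image`), or `NULL` for absent white matter.
#' @export
extract_rois <- function(shank, channel = c("NeuN", "GFAP", "IBA1")) {
  stopifnot(inherits(shank, "shank_image"))
  channel <- match.arg(channel)
  ch <- shank$channels[[channel]]
  wm <- shank$wm_boundary_row
  if (wm - 1L < 2L * ROI_DEPTH) {
    warning(sprintf(
      "cortical depth %d px < %d px: upper and lower cortex ROIs overlap",
      wm - 1L, ROI_DEPTH))
  }
  take <- function(r0, region) {
    rows <- r0:(r0 + ROI_DEPTH - 1L)
    if (any(rows < 1L)) {
      pad <- sum(rows < 1L)
      block <- rbind(matrix(0, pad, ncol(ch)), ch[rows[rows >= 1L], ])
    } else {
      block <- ch[rows, ]
    }
    structure(block, region = region, stain = channel, class = "roi_image")
  }
  upper <- take(1L, "upper_cortex")
  lower <- take(wm - ROI_DEPTH, "lower_cortex")
  white <- if (isTRUE(shank$wm_absent)) NULL else take(wm, "white_matter")
  list(upper_cortex = upper, lower_cortex = lower, white_matter = white)
}

#' Split an ROI or downsampled map into depth halves
#'
#' Top half = first half of the rows (towards the pia), bottom half = second
#' half; row-binding the two halves restores the input.
#'
#' @param x a matrix with an even number of rows (700-row ROI or 10-row
#'   downsampled grid, or a `downsampled_map`).
#' @return List with `top` and `bottom` matrices.
#' @export
split_roi_halves <- function(x) {
  m <- if (inherits(x, "downsampled_map")) x$grid else x
  if (!is.matrix(m)) stop("input must be a matrix or downsampled_map",
                          call. = FALSE)
  nr <- nrow(m)
  if (nr %% 2L != 0L) stop("row count must be even", call. = FALSE)
  list(top = m[seq_len(nr / 2), , drop = FALSE],
       bottom = m[(nr / 2 + 1L):nr, , drop = FALSE])
}
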