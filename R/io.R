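# On-disk interchange: multi-page TIFF + JSON sidecar for sections,
# float32 binary + JSON header for recordings, CSV manifests for cohorts.

#' Write a section as a multi-page TIFF with a JSON sidecar
#'
#' One 8-bit page per channel in the order NeuN, GFAP, IBA1. Annotations
#' (pixel size, pia row, white-matter boundary row, lesion columns) and,
#' when given, the ground truth (neuron centres, per-row occupancy levels,
#' run-length-encoded lesion mask) go into `<path>.json`.
#'
#' @param section a `section_image`.
#' @param path output TIFF path.
#' @param truth optional `ground_truth` to embed in the sidecar.
#' @return `path`, invisibly.
#' @export
write_section_tiff <- function(section, path, truth = NULL) {
  stopifnot(inherits(section, "section_image"))
  pages <- lapply(section$channels, function(ch) ch / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  side <- list(
    channels = names(section$channels),
    pixel_size_um = section$pixel_size_um,
    pia_row = section$pia_row,
    wm_boundary_row = section$wm_boundary_row,
    lesion_columns = section$lesion_columns
  )
  if (!is.null(truth)) {
    mask <- truth$lesion_mask
    runs <- apply(mask, 1, function(r) {
      w <- which(r)
      if (length(w) == 0L) c(0L, 0L) else c(min(w), max(w))
    })
    side$truth <- list(
      neuron_centers = unname(truth$neuron_centers),
      per_row_gfap_level = truth$per_row_gfap_level,
      per_row_iba1_level = truth$per_row_iba1_level,
      lesion_mask_runs = t(runs)
    )
  }
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a section written by [write_section_tiff()]
#'
#' @param path TIFF path; annotations are read from `<path>.json` unless an
#'   `annotations` list is supplied.
#' @param annotations optional list with `pixel_size_um`, `pia_row`,
#'   `wm_boundary_row`, `lesion_columns`.
#' @return A `section_image`.
#' @export
read_section_tiff <- function(path, annotations = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.null(annotations)) {
    annotations <- jsonlite::read_json(paste0(path, ".json"),
                                       simplifyVector = TRUE)
  }
  nm <- annotations$channels %||% c("NeuN", "GFAP", "IBA1")
  channels <- stats::setNames(lapply(pages, function(p) round(p * 255)), nm)
  structure(
    list(
      channels = channels,
      pixel_size_um = annotations$pixel_size_um,
      pia_row = as.integer(annotations$pia_row),
      wm_boundary_row = as.integer(annotations$wm_boundary_row),
      lesion_columns = as.integer(annotations$lesion_columns %||% integer())
    ),
    class = "section_image"
  )
}

#' Write a raw recording as float32 binary plus JSON header
#'
#' Samples are stored channel-major (electrode 1 first). The header
#' records rate, channel count, onsets and week.
#'
#' @param rec a `raw_recording`.
#' @param path output path for the binary; the header goes to
#'   `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$samples)), con, size = 4L)
  jsonlite::write_json(
    list(rate_hz = rec$rate_hz, n_channels = nrow(rec$samples),
         n_samples = ncol(rec$samples), onsets_s = rec$onsets_s,
         week = rec$week),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path binary path with `<path>.json` header alongside.
#' @return A `raw_recording`.
#' @export
read_recording <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = hdr$n_channels * hdr$n_samples, size = 4L)
  structure(
    list(samples = matrix(x, hdr$n_channels, hdr$n_samples, byrow = TRUE),
         rate_hz = hdr$rate_hz, onsets_s = hdr$onsets_s,
         week = as.integer(hdr$week)),
    class = "raw_recording"
  )
}

#' Write a cohort to disk
#'
#' Sections as TIFF + JSON sidecars and the manifest as CSV (columns:
#' `file`, `material`, `tether`, `width_um`, `thickness_um`, `group`).
#'
#' @param cohort a `probe_cohort`.
#' @param dir output directory (created if missing).
#' @return Manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "probe_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- cohort$manifest
  files <- character(0)
  for (i in seq_along(cohort$sections)) {
    f <- file.path(dir, paste0(man$id[i], ".tif"))
    write_section_tiff(cohort$sections[[i]]$section, f,
                       cohort$sections[[i]]$truth)
    files <- c(files, basename(f))
  }
  for (j in seq_along(cohort$controls)) {
    f <- file.path(dir, sprintf("CTL%03d.tif", j))
    write_section_tiff(cohort$controls[[j]]$section, f,
                       cohort$controls[[j]]$truth)
  }
  out <- if (nrow(man) > 0) {
    cbind(file = files,
          man[c("material", "tether", "width_um", "thickness_um", "group")])
  } else {
    data.frame(file = character(), material = character(),
               tether = character(), width_um = numeric(),
               thickness_um = numeric(), group = character())
  }
  mp <- file.path(dir, "manifest.csv")
  utils::write.csv(out, mp, row.names = FALSE)
  invisible(mp)
}
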