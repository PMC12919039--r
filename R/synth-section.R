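#' Parameters of the synthetic tissue model
#'
#' Describes one simulated coronal section of visual cortex as imaged in a
#' three-channel immunofluorescence preparation. Rows index depth (row 1 is
#' the pial surface side of the image), columns the medio-lateral axis.
#'
#' Densities are expressed per 100 x 100 pixel tile, occupancies as area
#' fractions in \[0, 1\]. Defaults emulate a healthy adult mouse cortex at
#' 0.576 um/pixel: a neuron-dense cortex with a sparse layer 1, and
#' astrocyte-rich white matter below the cortex--callosum boundary.
#'
#' @param image_width_px image width in pixels.
#' @param pia_row row index (1-based) of the pial surface.
#' @param wm_boundary_row row index of the cortex/white-matter boundary.
#' @param image_height_px image height; defaults to `wm_boundary_row + 720`
#'   so a full white-matter region of interest fits below the boundary.
#' @param pixel_size_um micrometres per pixel (isotropic).
#' @param neuron_density_cortex,neuron_density_layer1 NeuN somata per
#'   100 x 100 px in cortex proper and in layer 1.
#' @param neuron_radius_px soma radius in pixels.
#' @param gfap_baseline,gfap_wm_level GFAP occupancy fraction in cortex and
#'   in white matter.
#' @param iba1_baseline IBA1 occupancy fraction.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (8-bit units).
#' @param seed integer RNG seed; generators are pure functions of
#'   (parameters, seed).
#' @return An object of class `tissue_model_params`.
#' @export
tissue_model_params <- function(image_width_px = 850,
                                pia_row = 11,
                                wm_boundary_row = pia_row + 1400,
                                image_height_px = wm_boundary_row + 720,
                                pixel_size_um = 0.576,
                                neuron_density_cortex = 15,
                                neuron_density_layer1 = 2,
                                neuron_radius_px = 4,
                                gfap_baseline = 0.12,
                                gfap_wm_level = 0.30,
                                iba1_baseline = 0.05,
                                noise_sd = 4,
                                seed = 1L) {
  stopifnot_scalar(image_width_px, "image_width_px", 1)
  stopifnot_scalar(image_height_px, "image_height_px", 1)
  stopifnot_scalar(pia_row, "pia_row", 1)
  stopifnot_scalar(wm_boundary_row, "wm_boundary_row", 1)
  if (pia_row >= wm_boundary_row) {
    stop("`pia_row` must lie above `wm_boundary_row`", call. = FALSE)
  }
  stopifnot_scalar(neuron_density_cortex, "neuron_density_cortex", 0)
  stopifnot_scalar(neuron_density_layer1, "neuron_density_layer1", 0)
  if (neuron_density_layer1 > neuron_density_cortex) {
    stop("layer-1 neuron density must not exceed the cortical density",
         call. = FALSE)
  }
  stopifnot_scalar(gfap_baseline, "gfap_baseline", 0, 1)
  stopifnot_scalar(gfap_wm_level, "gfap_wm_level", 0, 1)
  stopifnot_scalar(iba1_baseline, "iba1_baseline", 0, 1)
  stopifnot_scalar(noise_sd, "noise_sd", 0)
  p <- list(
    image_width_px = as.integer(image_width_px),
    image_height_px = as.integer(image_height_px),
    pia_row = as.integer(pia_row),
    wm_boundary_row = as.integer(wm_boundary_row),
    pixel_size_um = pixel_size_um,
    neuron_density_cortex = neuron_density_cortex,
    neuron_density_layer1 = neuron_density_layer1,
    neuron_radius_px = neuron_radius_px,
    gfap_baseline = gfap_baseline,
    gfap_wm_level = gfap_wm_level,
    iba1_baseline = iba1_baseline,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  )
  class(p) <- "tissue_model_params"
  p
}

#' Parameters of the synthetic implant lesion model
#'
#' Parameterizes the tissue reaction rendered around a single vertical shank
#' track: a lesion void whose width scales with the shank, peri-track
#' neuronal depletion, a GFAP depth profile elevated at the pial entry point
#' and at the cortex/white-matter boundary, and an IBA1 elevation at that
#' boundary.
#'
#' @param shank_width_um shank width in micrometres (35, 70 or 105 in the
#'   probe designs emulated here, but any positive value is accepted).
#' @param lesion_scale void width as a multiple of the shank width (>= 0).
#' @param depletion_radius_um radius of peri-track neuronal depletion.
#' @param gfap_entry_gain,gfap_wm_gain amplitudes of the astrocytic
#'   reactivity bumps at the pial entry and at the white-matter boundary
#'   (multiples of baseline occupancy).
#' @param gfap_uniform_gain depth-uniform astrocytic gain.
#' @param iba1_wm_gain microglial gain at the white-matter boundary.
#' @param upper_loss_prob probability that the upper cortex shows a widened
#'   through-lesion (complete local tissue loss).
#' @return An object of class `lesion_model_params`.
#' @export
lesion_model_params <- function(shank_width_um = 70,
                                lesion_scale = 1.2,
                                depletion_radius_um = 40,
                                gfap_entry_gain = 1.2,
                                gfap_wm_gain = 1.2,
                                gfap_uniform_gain = 0.4,
                                iba1_wm_gain = 1.5,
                                upper_loss_prob = 0.1) {
  stopifnot_scalar(shank_width_um, "shank_width_um", 0)
  stopifnot_scalar(lesion_scale, "lesion_scale", 0)
  stopifnot_scalar(depletion_radius_um, "depletion_radius_um", 0)
  stopifnot_scalar(gfap_entry_gain, "gfap_entry_gain", 0)
  stopifnot_scalar(gfap_wm_gain, "gfap_wm_gain", 0)
  stopifnot_scalar(gfap_uniform_gain, "gfap_uniform_gain", 0)
  stopifnot_scalar(iba1_wm_gain, "iba1_wm_gain", 0)
  stopifnot_scalar(upper_loss_prob, "upper_loss_prob", 0, 1)
  p <- list(
    shank_width_um = shank_width_um,
    lesion_scale = lesion_scale,
    depletion_radius_um = depletion_radius_um,
    gfap_entry_gain = gfap_entry_gain,
    gfap_wm_gain = gfap_wm_gain,
    gfap_uniform_gain = gfap_uniform_gain,
    iba1_wm_gain = iba1_wm_gain,
    upper_loss_prob = upper_loss_prob
  )
  class(p) <- "lesion_model_params"
  p
}

# GFAP depth gain: uniform term plus Gaussian bumps at the pial entry and at
# the white-matter boundary, each with width 1/6 of the cortical depth.
gfap_depth_gain <- function(rows, pia_row, wm_boundary_row, lesion) {
  sigma <- (wm_boundary_row - pia_row) / 6
  1 + lesion$gfap_uniform_gain +
    lesion$gfap_entry_gain * exp(-(rows - pia_row)^2 / (2 * sigma^2)) +
    lesion$gfap_wm_gain * exp(-(rows - wm_boundary_row)^2 / (2 * sigma^2))
}

iba1_depth_gain <- function(rows, pia_row, wm_boundary_row, lesion) {
  sigma <- (wm_boundary_row - pia_row) / 6
  1 + lesion$iba1_wm_gain * exp(-(rows - wm_boundary_row)^2 / (2 * sigma^2))
}

# Baseline per-row occupancy targets of the control tissue.
control_row_levels <- function(params) {
  rows <- seq_len(params$image_height_px)
  gfap <- ifelse(rows < params$wm_boundary_row,
                 params$gfap_baseline, params$gfap_wm_level)
  iba1 <- rep(params$iba1_baseline, length(rows))
  list(gfap = gfap, iba1 = iba1)
}

# ---- rendering primitives (all vectorized over objects) ---------------------

# Sample soma centres: layer 1 (top 10% of cortical depth) is sparse, cortex
# proper dense, white matter nearly neuron-free.
sample_neurons <- function(params) {
  H <- params$image_height_px; W <- params$image_width_px
  l1_bottom <- params$pia_row +
    round(0.1 * (params$wm_boundary_row - params$pia_row))
  zones <- list(
    list(r0 = params$pia_row, r1 = l1_bottom - 1L,
         d = params$neuron_density_layer1),
    list(r0 = l1_bottom, r1 = params$wm_boundary_row - 1L,
         d = params$neuron_density_cortex),
    list(r0 = params$wm_boundary_row, r1 = H,
         d = params$neuron_density_cortex / 30)
  )
  out <- lapply(zones, function(z) {
    nrows <- z$r1 - z$r0 + 1L
    if (nrows <= 0 || z$d <= 0) return(NULL)
    n <- rpois(1L, z$d * nrows * W / 1e4)
    if (n == 0L) return(NULL)
    cbind(row = z$r0 + floor(runif(n) * nrows),
          col = 1L + floor(runif(n) * W))
  })
  centers <- do.call(rbind, out)
  if (is.null(centers)) centers <- matrix(integer(), 0, 2,
                                          dimnames = list(NULL, c("row", "col")))
  centers
}

# Stamp soft-edged disks of radius r at the given centres.
render_somata <- function(H, W, centers, r) {
  img <- matrix(0, H, W)
  n <- nrow(centers)
  if (n == 0L) return(img)
  span <- ceiling(r + 1)
  off <- expand.grid(dr = -span:span, dc = -span:span)
  d <- sqrt(off$dr^2 + off$dc^2)
  prof <- pmin(1, pmax(0, (r + 1 - d)))   # hard core, 1-px soft edge
  keep <- prof > 0
  off <- off[keep, ]; prof <- prof[keep]
  k <- length(prof)
  inten <- pmin(240, pmax(120, rnorm(n, 175, 20)))
  rr <- rep(centers[, "row"], each = k) + off$dr
  cc <- rep(centers[, "col"], each = k) + off$dc
  vv <- rep(inten, each = k) * prof
  ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  assign_max(img, (cc[ok] - 1L) * H + rr[ok], vv[ok])
}

# Short curvilinear strokes as an astrocytic-process proxy. `lambda` is the
# per-row target coverage intensity; the realized occupancy approaches
# 1 - exp(-lambda) under random overlap.
render_strokes <- function(H, W, level_row, len = 18L, px_per_stroke = 27) {
  img <- matrix(0, H, W)
  lambda <- -log(pmax(1e-9, 1 - pmin(0.95, level_row)))
  n <- round(sum(lambda) * W / px_per_stroke)
  if (n <= 0) return(img)
  r0 <- sample.int(H, n, replace = TRUE, prob = lambda)
  c0 <- 1 + floor(runif(n) * W)
  theta <- matrix(rnorm(n * len, 0, 0.35), n, len)
  theta[, 1] <- runif(n, 0, 2 * pi)
  for (j in 2:len) theta[, j] <- theta[, j - 1] + theta[, j]
  dr <- sin(theta); dc <- cos(theta)
  rows <- matrix(r0, n, len); cols <- matrix(c0, n, len)
  for (j in 2:len) {
    rows[, j] <- rows[, j - 1] + dr[, j]
    cols[, j] <- cols[, j - 1] + dc[, j]
  }
  inten <- pmin(250, pmax(110, rnorm(n, 180, 25)))
  rr <- round(as.vector(rows)); cc <- round(as.vector(cols))
  vv <- rep(inten, times = len)
  # thicken roughly every other point by one perpendicular pixel
  half <- seq(1, length(rr), by = 2)
  rr <- c(rr, rr[half] + 1L); cc <- c(cc, cc[half]); vv <- c(vv, vv[half])
  ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  assign_max(img, (cc[ok] - 1L) * H + rr[ok], vv[ok])
}

# Small irregular blobs as a microglial soma proxy.
render_blobs <- function(H, W, level_row, px_per_blob = 7) {
  img <- matrix(0, H, W)
  lambda <- -log(pmax(1e-9, 1 - pmin(0.95, level_row)))
  n <- round(sum(lambda) * W / px_per_blob)
  if (n <= 0) return(img)
  r0 <- sample.int(H, n, replace = TRUE, prob = lambda)
  c0 <- 1 + floor(runif(n) * W)
  off <- expand.grid(dr = -1:1, dc = -1:1)
  k <- nrow(off)
  keep <- matrix(runif(n * k) < 0.75, n, k)
  keep[, 5] <- TRUE                       # centre pixel always present
  inten <- pmin(240, pmax(100, rnorm(n, 160, 25)))
  rr <- rep(r0, each = k) + off$dr
  cc <- rep(c0, each = k) + off$dc
  vv <- rep(inten, each = k)
  sel <- as.vector(t(keep)) & rr >= 1 & rr <= H & cc >= 1 & cc <= W
  assign_max(img, (cc[sel] - 1L) * H + rr[sel], vv[sel])
}

# ---- generators -------------------------------------------------------------

new_section_image <- function(channels, params, lesion_columns = integer()) {
  structure(
    list(
      channels = channels,
      pixel_size_um = params$pixel_size_um,
      pia_row = params$pia_row,
      wm_boundary_row = params$wm_boundary_row,
      lesion_columns = as.integer(lesion_columns)
    ),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<section_image> %d x %d px, %.3f um/px, pia row %d, WM boundary row %d\n",
    d[1], d[2], x$pixel_size_um, x$pia_row, x$wm_boundary_row))
  if (length(x$lesion_columns)) {
    cat("  lesion columns:", paste(x$lesion_columns, collapse = ", "), "\n")
  }
  invisible(x)
}

# Shared renderer. `lesion` = NULL renders control tissue. Returns the
# section plus ground truth.
render_section <- function(params, lesion = NULL, lesion_col = NULL) {
  H <- params$image_height_px; W <- params$image_width_px
  base <- control_row_levels(params)
  rows <- seq_len(H)

  gfap_level <- base$gfap
  iba1_level <- base$iba1
  if (!is.null(lesion)) {
    gfap_level <- pmin(0.9, gfap_level *
                         gfap_depth_gain(rows, params$pia_row,
                                         params$wm_boundary_row, lesion))
    iba1_level <- pmin(0.9, iba1_level *
                         iba1_depth_gain(rows, params$pia_row,
                                         params$wm_boundary_row, lesion))
  }

  centers <- sample_neurons(params)

  lesion_mask <- matrix(FALSE, H, W)
  if (!is.null(lesion)) {
    if (is.null(lesion_col)) lesion_col <- as.integer(round(W / 2))
    w_px <- lesion$lesion_scale * lesion$shank_width_um / params$pixel_size_um
    if (w_px > W) stop("lesion wider than the image", call. = FALSE)
    r_lo <- params$pia_row
    r_hi <- min(H, params$wm_boundary_row + 300L)
    if (w_px >= 1) {
      c_lo <- max(1L, ceiling(lesion_col - w_px / 2))
      c_hi <- min(W, floor(lesion_col + w_px / 2))
      lesion_mask[r_lo:r_hi, c_lo:c_hi] <- TRUE
    }
    # occasional complete loss of upper cortex around the track
    widened <- runif(1) < lesion$upper_loss_prob
    if (widened && w_px >= 1) {
      wu <- min(W, 3 * w_px)
      c_lo <- max(1L, ceiling(lesion_col - wu / 2))
      c_hi <- min(W, floor(lesion_col + wu / 2))
      r_hi_u <- min(H, params$pia_row + 699L)
      lesion_mask[r_lo:r_hi_u, c_lo:c_hi] <- TRUE
    }
    # peri-track neuronal depletion: neuron i is lost when its column
    # distance to the track is below radius * u_i, u_i ~ U(0,1); loss count
    # is therefore non-decreasing in the depletion radius.
    if (nrow(centers) > 0) {
      u <- runif(nrow(centers))
      r_px <- lesion$depletion_radius_um / params$pixel_size_um
      d <- abs(centers[, "col"] - lesion_col)
      keep <- d >= r_px * u
      centers <- centers[keep, , drop = FALSE]
    }
  }

  neun <- render_somata(H, W, centers, params$neuron_radius_px)
  gfap <- render_strokes(H, W, gfap_level)
  iba1 <- render_blobs(H, W, iba1_level)

  if (!is.null(lesion)) {
    # drop ground-truth somata whose centre fell inside the void
    if (nrow(centers) > 0) {
      inside <- lesion_mask[(centers[, "col"] - 1L) * H + centers[, "row"]]
      centers <- centers[!inside, , drop = FALSE]
    }
    neun[lesion_mask] <- 0
    gfap[lesion_mask] <- 0
    iba1[lesion_mask] <- 0
  }

  bgd <- 12
  add_noise <- function(ch) {
    ch <- pmax(ch, bgd * !lesion_mask)
    round(clip255(ch + rnorm(length(ch), 0, params$noise_sd)))
  }
  channels <- list(
    NeuN = add_noise(neun),
    GFAP = add_noise(gfap),
    IBA1 = add_noise(iba1)
  )

  truth <- structure(
    list(
      lesion_mask = lesion_mask,
      neuron_centers = centers,
      per_row_gfap_level = gfap_level,
      per_row_iba1_level = iba1_level
    ),
    class = "ground_truth"
  )
  list(
    section = new_section_image(channels, params,
                                if (is.null(lesion)) integer() else lesion_col),
    truth = truth
  )
}

#' Generate a synthetic control (non-implanted) section
#'
#' Renders a three-channel 8-bit section of healthy cortex: NeuN somata as
#' soft-edged disks at the configured densities (sparse in layer 1), GFAP as
#' short curvilinear strokes with higher occupancy in white matter, IBA1 as
#' sparse irregular blobs, plus additive Gaussian noise clipped to
#' \[0, 255\]. The same parameters and seed always produce bit-identical
#' output.
#'
#' @param params a [tissue_model_params()] object.
#' @return A list with elements `section` (a `section_image`: channels
#'   `NeuN`, `GFAP`, `IBA1` as height x width matrices) and `truth` (a
#'   `ground_truth`: `lesion_mask`, `neuron_centers`, `per_row_gfap_level`,
#'   `per_row_iba1_level`).
#' @export
#' @examples
#' p <- tissue_model_params(image_width_px = 200, pia_row = 5,
#'                          wm_boundary_row = 145, image_height_px = 220,
#'                          seed = 7)
#' ctl <- generate_control_section(p)
#' dim(ctl$section$channels$NeuN)
generate_control_section <- function(params) {
  stopifnot(inherits(params, "tissue_model_params"))
  with_seed(params$seed, render_section(params, lesion = NULL))
}

#' Generate a synthetic implanted section
#'
#' As [generate_control_section()] plus a vertical lesion void (all channels
#' suppressed), peri-track neuronal depletion, a GFAP depth profile with
#' reactivity bumps at the pial entry and at the cortex/white-matter
#' boundary, and an IBA1 elevation at that boundary.
#'
#' @param params a [tissue_model_params()] object.
#' @param lesion a [lesion_model_params()] object.
#' @param lesion_col column of the track centre; defaults to the image
#'   centre.
#' @return A list with `section` and `truth` as in
#'   [generate_control_section()]; `truth$lesion_mask` marks the void.
#' @export
generate_implanted_section <- function(params, lesion, lesion_col = NULL) {
  stopifnot(inherits(params, "tissue_model_params"),
            inherits(lesion, "lesion_model_params"))
  with_seed(params$seed, render_section(params, lesion, lesion_col))
}
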