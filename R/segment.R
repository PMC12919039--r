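# Binarization and occupancy summarization of single-stain ROIs.

#' Moment-preserving (Tsai) automatic threshold
#'
#' Computes the gray level that splits a 256-bin intensity histogram so that
#' a two-level image carrying the below/above-threshold populations
#' preserves the first three moments of the input image. The returned level
#' `t` assigns its own bin to the background: pixels with intensity
#' strictly greater than `t` are foreground. When the cumulative-fraction
#' cut falls inside a histogram bin, that bin's gray level is returned.
#'
#' @param histogram integer vector of 256 counts for gray levels 0..255.
#' @return Threshold gray level in 0..255.
#' @export
#' @examples
#' h <- integer(256); h[1] <- 400; h[256] <- 100   # levels 0 and 255
#' moments_threshold(h)
moments_threshold <- function(histogram) {
  if (length(histogram) != 256L || any(histogram < 0)) {
    stop("`histogram` must be 256 non-negative counts", call. = FALSE)
  }
  total <- sum(histogram)
  if (total <= 0) stop("empty histogram", call. = FALSE)
  p <- histogram / total
  z <- 0:255
  m1 <- sum(z * p)
  m2 <- sum(z^2 * p)
  m3 <- sum(z^3 * p)
  cd <- m2 - m1^2
  if (cd < 1e-9) {
    # (near-)single-valued histogram: all mass at one level; return it and
    # leave everything background
    lvl <- z[which.max(p)]
    warning("degenerate single-valued histogram; returning that gray level")
    return(lvl)
  }
  c0 <- (m1 * m3 - m2^2) / cd
  c1 <- (m1 * m2 - m3) / cd
  disc <- max(0, c1^2 - 4 * c0)
  z0 <- 0.5 * (-c1 - sqrt(disc))
  z1 <- 0.5 * (-c1 + sqrt(disc))
  p0 <- (z1 - m1) / (z1 - z0)    # background fraction of the two-level image
  cum <- cumsum(p)
  th <- which(cum >= p0 - 1e-9)[1L]
  if (is.na(th)) th <- 256L
  z[th]
}

#' Binarize an ROI with its own Moments threshold
#'
#' @param roi 8-bit matrix (values 0..255), e.g. a `roi_image`.
#' @return Logical matrix of the same shape; `TRUE` = foreground (cell
#'   signal). Attributes `threshold`, `region` and `stain` are carried
#'   along. Class `binary_map`.
#' @export
binarize <- function(roi) {
  if (!is.matrix(roi) || length(roi) == 0L) {
    stop("`roi` must be a non-empty matrix", call. = FALSE)
  }
  h <- tabulate(as.integer(roi) + 1L, nbins = 256L)
  th <- moments_threshold(h)
  structure(unclass(roi) > th,
            threshold = th,
            region = attr(roi, "region"),
            stain = attr(roi, "stain"),
            class = c("binary_map", "matrix", "array"))
}

#' Morphology criteria of a stain-specific mask filter
#'
#' Connected components (8-connectivity) of a binary mask that fail any
#' active criterion are removed. Criteria left `NULL` are inactive. The
#' numeric defaults per stain are free parameters of this pipeline,
#' reflecting the compact somata of NeuN, the thin filaments of GFAP and
#' the small blobs of IBA1; see [default_stain_profiles()].
#'
#' @param min_area_px,max_area_px component pixel-count bounds.
#' @param min_eccentricity,max_eccentricity bounds on the component's
#'   ellipse eccentricity in \[0, 1\].
#' @param min_solidity lower bound on area / convex-hull area.
#' @return An object of class `stain_filter_profile`.
#' @export
stain_filter_profile <- function(min_area_px = NULL, max_area_px = NULL,
                                 min_eccentricity = NULL,
                                 max_eccentricity = NULL,
                                 min_solidity = NULL) {
  chk <- function(x, name, lo, hi) {
    if (!is.null(x)) stopifnot_scalar(x, name, lo, hi)
    x
  }
  p <- list(
    min_area_px = chk(min_area_px, "min_area_px", 0, Inf),
    max_area_px = chk(max_area_px, "max_area_px", 0, Inf),
    min_eccentricity = chk(min_eccentricity, "min_eccentricity", 0, 1),
    max_eccentricity = chk(max_eccentricity, "max_eccentricity", 0, 1),
    min_solidity = chk(min_solidity, "min_solidity", 0, 1)
  )
  if (!is.null(p$min_area_px) && !is.null(p$max_area_px) &&
      p$min_area_px > p$max_area_px) {
    stop("min_area_px > max_area_px", call. = FALSE)
  }
  class(p) <- "stain_filter_profile"
  p
}

#' Default mask-filter profiles per stain
#'
#' NeuN keeps compact somata (area >= 20 px, solidity >= 0.7); GFAP keeps
#' filaments but drops near-single-pixel noise (area >= 5 px); IBA1 keeps
#' small blobs (area >= 8 px). All values are config-overridable.
#'
#' @return Named list of [stain_filter_profile()] objects.
#' @export
default_stain_profiles <- function() {
  list(
    NeuN = stain_filter_profile(min_area_px = 20, min_solidity = 0.7),
    GFAP = stain_filter_profile(min_area_px = 5),
    IBA1 = stain_filter_profile(min_area_px = 8)
  )
}

#' Read stain-filter profiles from a YAML config
#'
#' The file maps stain names to criterion fields of
#' [stain_filter_profile()].
#'
#' @param path YAML file path.
#' @return Named list of [stain_filter_profile()] objects.
#' @export
read_stain_profiles <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read profile configs",
         call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  lapply(cfg, function(x) do.call(stain_filter_profile, x))
}

# 8-connectivity labeling: EBImage::bwlabel is 4-connected, so labels that
# touch diagonally are merged with a union-find pass.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]      # down-right diagonal
  a2 <- lab[-nr, -1];  b2 <- lab[-1, -nc]     # down-left diagonal
  sel1 <- a1 > 0L & b1 > 0L & a1 != b1
  sel2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2])))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(pairs))) {
    ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(n), find, integer(1))
  remap <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0L] <- remap[lab[lab > 0L]]
  out
}

component_eccentricity <- function(rows, cols, labs, n) {
  cnt <- tabulate(labs, n)
  sr <- rowsum(rows, labs)[, 1]
  sc <- rowsum(cols, labs)[, 1]
  srr <- rowsum(rows^2, labs)[, 1]
  scc <- rowsum(cols^2, labs)[, 1]
  src <- rowsum(rows * cols, labs)[, 1]
  mr <- sr / cnt; mc <- sc / cnt
  # central second moments with the 1/12 pixel-extent term, as in common
  # region-properties implementations
  vrr <- srr / cnt - mr^2 + 1 / 12
  vcc <- scc / cnt - mc^2 + 1 / 12
  vrc <- src / cnt - mr * mc
  tr2 <- (vrr + vcc) / 2
  det <- vrr * vcc - vrc^2
  disc <- pmax(0, tr2^2 - det)
  l1 <- tr2 + sqrt(disc)
  l2 <- tr2 - sqrt(disc)
  sqrt(pmax(0, 1 - l2 / pmax(l1, 1e-12)))
}

component_solidity <- function(rows, cols, labs, n) {
  cnt <- tabulate(labs, n)
  sol <- rep(1, n)
  members <- split(seq_along(labs), labs)
  for (i in which(cnt >= 3L)) {
    sel <- members[[as.character(i)]]
    pts <- cbind(cols[sel], rows[sel])
    h <- chull(pts)
    hp <- pts[h, , drop = FALSE]
    m <- nrow(hp)
    if (m < 3L) next
    # shoelace area of hull through pixel centres, plus boundary correction
    # approximating the pixelated hull area (Pick-style)
    x <- hp[, 1]; y <- hp[, 2]
    area <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
    per <- sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
    hull_area <- area + per / 2 + 1
    sol[i] <- min(1, cnt[i] / hull_area)
  }
  sol
}

#' Filter a binary mask by stain-specific morphology criteria
#'
#' Labels 8-connected components and removes every component failing any
#' active criterion of the profile; surviving pixels are unchanged.
#'
#' @param mask logical matrix (`binary_map`).
#' @param profile a [stain_filter_profile()].
#' @return Filtered mask of the same shape and attributes.
#' @export
filter_mask <- function(mask, profile) {
  stopifnot(inherits(profile, "stain_filter_profile"))
  m <- mask
  active <- !vapply(profile, is.null, logical(1))
  if (!any(active) || !any(m)) return(mask)
  lab <- label_components8(m)
  n <- max(lab)
  idx <- which(lab > 0L)
  labs <- lab[idx]
  nr <- nrow(m)
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  keep <- rep(TRUE, n)
  area <- tabulate(labs, n)
  if (!is.null(profile$min_area_px)) keep <- keep & area >= profile$min_area_px
  if (!is.null(profile$max_area_px)) keep <- keep & area <= profile$max_area_px
  if (!is.null(profile$min_eccentricity) || !is.null(profile$max_eccentricity)) {
    ecc <- component_eccentricity(rows, cols, labs, n)
    if (!is.null(profile$min_eccentricity)) {
      keep <- keep & ecc >= profile$min_eccentricity
    }
    if (!is.null(profile$max_eccentricity)) {
      keep <- keep & ecc <= profile$max_eccentricity
    }
  }
  if (!is.null(profile$min_solidity)) {
    # solidity only needs computing for components still alive
    sol <- rep(1, n)
    alive <- keep
    if (any(alive)) {
      sub <- alive[labs]
      sol_sub <- component_solidity(rows[sub], cols[sub], labs[sub], n)
      sol[alive] <- sol_sub[alive]
    }
    keep <- keep & sol >= profile$min_solidity
  }
  out <- m
  out[idx] <- keep[labs]
  attributes(out) <- attributes(mask)
  out
}

# Exact area-weighted partition of n_src pixels into n_bin bins: entry
# (i, j) is the overlap length of pixel i (covering [i-1, i)) with bin j.
bin_weights <- function(n_src, n_bin) {
  e <- n_src * (0:n_bin) / n_bin
  W <- matrix(0, n_src, n_bin)
  for (j in seq_len(n_bin)) {
    lo <- e[j]; hi <- e[j + 1]
    for (i in (floor(lo) + 1L):min(ceiling(hi), n_src)) {
      ov <- min(hi, i) - max(lo, i - 1)
      if (ov > 0) W[i, j] <- ov
    }
  }
  W
}

.downsample_cache <- new.env(parent = emptyenv())

downsample_weights <- function(n_src, n_bin) {
  key <- paste0(n_src, "x", n_bin)
  if (is.null(.downsample_cache[[key]])) {
    .downsample_cache[[key]] <- bin_weights(n_src, n_bin)
  }
  .downsample_cache[[key]]
}

#' Downsample a 700 x 800 binary mask to an 11 x 10 occupancy grid
#'
#' Partitions the 800 columns into 11 bins and the 700 rows into 10 bins by
#' exact (non-integer) area weighting and stores, per output cell,
#' 255 x the area-weighted foreground fraction. Total foreground mass is
#' conserved: `sum(grid) / 255 * (800*700) / (11*10)` equals the foreground
#' pixel count.
#'
#' @param mask logical (or 0/1 numeric) 700 x 800 matrix; `TRUE`/1 =
#'   foreground.
#' @return A `downsampled_map`: list with `grid` (10 rows x 11 columns,
#'   depth by width, values in \[0, 255\]), `region`, `stain`.
#' @export
downsample <- function(mask) {
  if (!is.matrix(mask) || nrow(mask) != ROI_DEPTH || ncol(mask) != ROI_WIDTH) {
    stop(sprintf("`mask` must be %d x %d", ROI_DEPTH, ROI_WIDTH),
         call. = FALSE)
  }
  Wr <- downsample_weights(ROI_DEPTH, 10L)   # 700 x 10
  Wc <- downsample_weights(ROI_WIDTH, 11L)   # 800 x 11
  m <- matrix(as.numeric(mask), ROI_DEPTH, ROI_WIDTH)
  cell_area <- (ROI_DEPTH / 10) * (ROI_WIDTH / 11)
  grid <- 255 * (t(Wr) %*% m %*% Wc) / cell_area
  grid[grid < 0] <- 0
  grid[grid > 255] <- 255
  structure(
    list(grid = grid,
         region = attr(mask, "region"),
         stain = attr(mask, "stain")),
    class = "downsampled_map"
  )
}

#' @export
print.downsampled_map <- function(x, ...) {
  cat(sprintf("<downsampled_map> %s / %s, 10 x 11, mean %.1f\n",
              x$stain %||% "?", x$region %||% "?", mean(x$grid)))
  invisible(x)
}
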