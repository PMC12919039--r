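#' Default mapping from probe design to lesion-model parameters
#'
#' Encodes the qualitative phenomenology the generator emulates as effect
#' sizes: silicon probes provoke a stronger glial reaction, wider neuronal
#' depletion and more frequent complete upper-cortex loss than polyimide;
#' untethered probes react somewhat more than tethered ones; the lesion void
#' scales with shank width.
#'
#' @param material_gain named multipliers applied to the glial gains and the
#'   depletion radius per material.
#' @param tether_gain named multipliers per tethering condition.
#' @param lesion_scale void width as a multiple of shank width.
#' @param base_entry,base_wm,base_uniform,base_iba1 baseline gains (see
#'   [lesion_model_params()]).
#' @param base_depletion_um baseline peri-track depletion radius.
#' @param base_upper_loss baseline probability of complete upper-cortex loss.
#' @return A function mapping one design row (with columns `material`,
#'   `tether`, `width_um`) to a [lesion_model_params()] object.
#' @export
default_effect_map <- function(material_gain = c(PI = 1, Si = 2.5),
                               tether_gain = c(T = 1, U = 1.3),
                               lesion_scale = 1.2,
                               base_entry = 1.2,
                               base_wm = 1.2,
                               base_uniform = 0.4,
                               base_iba1 = 1.5,
                               base_depletion_um = 40,
                               base_upper_loss = 0.08) {
  force(material_gain); force(tether_gain)
  function(design_row) {
    m <- unname(material_gain[[design_row$material]])
    t <- unname(tether_gain[[design_row$tether]])
    g <- m * t
    lesion_model_params(
      shank_width_um = design_row$width_um,
      lesion_scale = lesion_scale,
      depletion_radius_um = base_depletion_um * m,
      gfap_entry_gain = base_entry * g,
      gfap_wm_gain = base_wm * g,
      gfap_uniform_gain = base_uniform * g,
      iba1_wm_gain = base_iba1 * g,
      upper_loss_prob = min(0.9, base_upper_loss * m)
    )
  }
}

#' Generate a labeled synthetic cohort of sections
#'
#' One implanted section is generated per design row, with lesion and
#' reactivity parameters mapped from the design factors through
#' `effect_map`, plus `n_control` control sections emulating non-implanted
#' hemispheres. A fixed master seed yields an identical cohort.
#'
#' @param design data frame with columns `material` (`"PI"` or `"Si"`),
#'   `tether` (`"T"` or `"U"`), `width_um` (35, 70 or 105) and
#'   `thickness_um` (positive). May have zero rows, in which case only
#'   controls are generated.
#' @param params a [tissue_model_params()] object; its `seed` is ignored in
#'   favour of per-section seeds derived from `seed`.
#' @param effect_map function from design row to [lesion_model_params()];
#'   defaults to [default_effect_map()].
#' @param n_control number of control sections.
#' @param seed master seed.
#' @return A list with `sections` (list of `list(section, truth, meta)`),
#'   `controls` (list of `list(section, truth)`), and `manifest` (data frame
#'   with one row per implanted section: `id`, `material`, `tether`,
#'   `width_um`, `thickness_um`, `cross_section_um2`, `group`, `seed`).
#' @export
generate_cohort <- function(design, params = tissue_model_params(),
                            effect_map = default_effect_map(),
                            n_control = 5, seed = 1L) {
  design <- as.data.frame(design)
  if (nrow(design) > 0) {
    req <- c("material", "tether", "width_um", "thickness_um")
    miss <- setdiff(req, names(design))
    if (length(miss)) {
      stop("design table lacks columns: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    if (!all(design$material %in% c("PI", "Si"))) {
      stop("unknown material level (expected \"PI\" or \"Si\")", call. = FALSE)
    }
    if (!all(design$tether %in% c("T", "U"))) {
      stop("unknown tether level (expected \"T\" or \"U\")", call. = FALSE)
    }
    if (!all(design$width_um %in% c(35, 70, 105))) {
      stop("shank width must be one of 35, 70, 105 um", call. = FALSE)
    }
    if (!all(design$thickness_um > 0)) {
      stop("thickness_um must be positive", call. = FALSE)
    }
  }

  sections <- vector("list", nrow(design))
  if (nrow(design) > 0) {
    for (i in seq_len(nrow(design))) {
      row <- design[i, , drop = FALSE]
      p_i <- params
      p_i$seed <- as.integer(seed + i)
      lesion <- effect_map(as.list(row))
      out <- generate_implanted_section(p_i, lesion)
      out$meta <- data.frame(
        id = sprintf("S%03d", i),
        material = row$material,
        tether = row$tether,
        width_um = row$width_um,
        thickness_um = row$thickness_um,
        cross_section_um2 = row$width_um * row$thickness_um,
        group = paste(row$material, row$tether, row$width_um, sep = "-"),
        seed = p_i$seed,
        stringsAsFactors = FALSE
      )
      sections[[i]] <- out
    }
  }

  controls <- vector("list", n_control)
  for (j in seq_len(n_control)) {
    p_j <- params
    p_j$seed <- as.integer(seed + 100000L + j)
    controls[[j]] <- generate_control_section(p_j)
  }

  manifest <- if (nrow(design) > 0) {
    do.call(rbind, lapply(sections, `[[`, "meta"))
  } else {
    data.frame()
  }
  structure(list(sections = sections, controls = controls,
                 manifest = manifest, params = params, seed = seed),
            class = "probe_cohort")
}

#' @export
print.probe_cohort <- function(x, ...) {
  cat(sprintf("<probe_cohort> %d implanted section(s), %d control(s)\n",
              length(x$sections), length(x$controls)))
  invisible(x)
}
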