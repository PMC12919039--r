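# Shared synthetic cohorts for the end-to-end recovery tests. Built once
# per test run and memoized; every replicate processes 10 polyimide and 10
# silicon shanks (tethered, 70 x 15 um) against a shared pool of 5 control
# sections, mirroring the study's fixed control pool.

.cohort_cache <- new.env(parent = emptyenv())

small_tissue_params <- function(seed = 1L) {
  tissue_model_params(seed = seed)
}

# Per-shank quantification of n_rep replicate cohorts. Returns, per
# replicate, the delta-summary rows (NeuN/GFAP based) and the GFAP
# depth-half means per cortical region.
recovery_cohorts <- function(n_rep = 6, n_per_group = 10, master_seed = 2024) {
  key <- paste(n_rep, n_per_group, master_seed, sep = "_")
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  params <- small_tissue_params()
  profiles <- default_stain_profiles()
  stains <- c("NeuN", "GFAP")
  controls <- lapply(1:5, function(j) {
    p <- params
    p$seed <- as.integer(master_seed + 900000L + j)
    generate_control_section(p)
  })
  ctrl <- control_reference(controls, profiles, stains)
  effect <- default_effect_map()
  reps <- lapply(seq_len(n_rep), function(rep) {
    design <- data.frame(
      material = rep(c("PI", "Si"), each = n_per_group),
      tether = "T", width_um = 70, thickness_um = 15,
      stringsAsFactors = FALSE
    )
    rows <- lapply(seq_len(nrow(design)), function(i) {
      p <- params
      p$seed <- as.integer(master_seed + rep * 1000L + i)
      lesion <- effect(as.list(design[i, ]))
      sec <- generate_implanted_section(p, lesion)
      shank <- crop_shank(sec$section, sec$section$lesion_columns[1])
      q <- quantify_shank(shank, profiles, stains)
      d <- shank_delta_maps(q, ctrl)
      summary_row <- data.frame(
        material = design$material[i],
        rep = rep,
        stringsAsFactors = FALSE
      )
      for (rg in c("upper_cortex", "lower_cortex")) {
        dn <- suppressWarnings(roi_mean_delta(d$dmaps$NeuN[[rg]]))
        dg <- suppressWarnings(roi_mean_delta(d$dmaps$GFAP[[rg]]))
        dp <- depth_profile(d$dmaps$GFAP[[rg]])
        summary_row[[paste0("idx_", rg)]] <- tissue_reaction_index(dn, dg)
        summary_row[[paste0("gfap_top_", rg)]] <- dp$top_mean
        summary_row[[paste0("gfap_bottom_", rg)]] <- dp$bottom_mean
      }
      summary_row
    })
    do.call(rbind, rows)
  })
  .cohort_cache[[key]] <- reps
  reps
}
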