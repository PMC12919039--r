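# Generator contracts: determinism, ground-truth consistency, and the
# constructed lesion phenomenology.

tiny_params <- function(seed = 1L, ...) {
  tissue_model_params(image_width_px = 240, pia_row = 6,
                      wm_boundary_row = 186, image_height_px = 280,
                      seed = seed, ...)
}

test_that("control generation is deterministic and respects densities", {
  p <- tiny_params(seed = 11)
  a <- generate_control_section(p)
  b <- generate_control_section(p)
  expect_identical(a$section$channels, b$section$channels)
  expect_identical(a$truth$neuron_centers, b$truth$neuron_centers)

  # zero neuron density: NeuN is background noise only, no somata
  p0 <- tiny_params(seed = 12, neuron_density_cortex = 0,
                    neuron_density_layer1 = 0)
  z <- generate_control_section(p0)
  expect_equal(nrow(z$truth$neuron_centers), 0)
  expect_lt(max(z$section$channels$NeuN), 60)  # background + noise only

  # invalid geometry rejected
  expect_error(tissue_model_params(pia_row = 100, wm_boundary_row = 50),
               "pia_row")
})

test_that("ground-truth somata match the rendered noiseless NeuN layer", {
  # seed chosen so that no two somata touch (distinct components)
  p <- tiny_params(seed = 5, noise_sd = 0, neuron_density_cortex = 3,
                   neuron_density_layer1 = 0.5)
  ctl <- generate_control_section(p)
  expect_gt(min(dist(ctl$truth$neuron_centers)), 12)
  # with sparse somata and no noise, components above background = somata
  mask <- ctl$section$channels$NeuN > 60
  lab <- oracle_label8(mask)
  expect_equal(max(lab), nrow(ctl$truth$neuron_centers))
})

test_that("GFAP occupancy is higher in white matter than in cortex", {
  wins <- vapply(1:10, function(s) {
    p <- tiny_params(seed = s, gfap_baseline = 0.1, gfap_wm_level = 0.4)
    ctl <- generate_control_section(p)
    g <- ctl$section$channels$GFAP
    th <- moments_threshold(tabulate(as.integer(g) + 1L, 256L))
    fg <- g > th
    cortex <- mean(fg[p$pia_row:(p$wm_boundary_row - 1L), ])
    wm <- mean(fg[p$wm_boundary_row:nrow(fg), ])
    wm > cortex
  }, logical(1))
  expect_true(all(wins))
})

test_that("null lesion reproduces control statistics; lesion area grows with width", {
  p <- tiny_params(seed = 31)
  null_lesion <- lesion_model_params(shank_width_um = 35, lesion_scale = 0,
                                     depletion_radius_um = 0,
                                     gfap_entry_gain = 0, gfap_wm_gain = 0,
                                     gfap_uniform_gain = 0, iba1_wm_gain = 0,
                                     upper_loss_prob = 0)
  imp <- generate_implanted_section(p, null_lesion)
  ctl <- generate_control_section(p)
  expect_equal(sum(imp$truth$lesion_mask), 0)
  expect_identical(imp$truth$per_row_gfap_level, ctl$truth$per_row_gfap_level)
  for (ch in c("NeuN", "GFAP", "IBA1")) {
    expect_lt(abs(mean(imp$section$channels[[ch]]) -
                    mean(ctl$section$channels[[ch]])), 2)
  }

  areas <- vapply(c(35, 70, 105), function(w) {
    les <- lesion_model_params(shank_width_um = w, upper_loss_prob = 0)
    sum(generate_implanted_section(p, les)$truth$lesion_mask)
  }, numeric(1))
  expect_true(all(diff(areas) > 0))

  les_widest <- lesion_model_params(shank_width_um = 105, lesion_scale = 10)
  expect_error(generate_implanted_section(p, les_widest), "wider")
})

test_that("neuron loss is non-decreasing in the depletion radius", {
  p <- tiny_params(seed = 41)
  counts <- vapply(c(0, 20, 60, 120), function(r) {
    les <- lesion_model_params(shank_width_um = 35, lesion_scale = 0,
                               depletion_radius_um = r, upper_loss_prob = 0)
    nrow(generate_implanted_section(p, les)$truth$neuron_centers)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("GFAP depth-gain profile is U-shaped over the cortex", {
  p <- tiny_params(seed = 51)
  les <- lesion_model_params(shank_width_um = 35, gfap_entry_gain = 2,
                             gfap_wm_gain = 2, gfap_uniform_gain = 0)
  imp <- generate_implanted_section(p, les)
  cortex_rows <- p$pia_row:p$wm_boundary_row
  prof <- imp$truth$per_row_gfap_level[cortex_rows]
  i_min <- which.min(prof)
  expect_gt(i_min, 1)
  expect_lt(i_min, length(cortex_rows))
  expect_gt(prof[1], prof[i_min])
  expect_gt(prof[length(prof)], prof[i_min])
})

test_that("cohort generation validates designs and is reproducible", {
  p <- tiny_params()
  empty <- generate_cohort(data.frame(), p, n_control = 2, seed = 5)
  expect_length(empty$sections, 0)
  expect_length(empty$controls, 2)

  design <- data.frame(material = c("PI", "Si"), tether = c("T", "U"),
                       width_um = c(35, 105), thickness_um = c(15, 25))
  a <- generate_cohort(design, p, n_control = 1, seed = 9)
  b <- generate_cohort(design, p, n_control = 1, seed = 9)
  expect_identical(a$sections[[2]]$section$channels,
                   b$sections[[2]]$section$channels)
  expect_equal(a$manifest$cross_section_um2, c(35 * 15, 105 * 25))

  bad <- design; bad$material[1] <- "steel"
  expect_error(generate_cohort(bad, p, seed = 9), "material")
})

test_that("evoked recordings decay over weeks and carry a common artifact", {
  ep <- ephys_model_params(n_electrodes = 2, n_trials = 8,
                           evoked_amplitude = 6, weekly_decay = 0.75,
                           noise_sd = 0.5, artifact_amp = 1, seed = 3)
  r0 <- generate_mua_recording(ep, week = 0)
  expect_identical(dim(r0$samples), c(2L, ncol(r0$samples)))
  expect_length(r0$onsets_s, 8)
  # determinism
  expect_identical(generate_mua_recording(ep, week = 0)$samples, r0$samples)

  snr_by_week <- vapply(c(0, 4, 8), function(w) {
    median(process_recording(generate_mua_recording(ep, week = w))$snr)
  }, numeric(1))
  expect_true(all(diff(snr_by_week) < 0))

  # amplitude-free recording: SNR near the null level, far below the evoked one
  ep0 <- ep; ep0$evoked_amplitude <- 0
  s0 <- process_recording(generate_mua_recording(ep0, week = 0))
  expect_lt(median(s0$snr), snr_by_week[1] / 2)
})
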