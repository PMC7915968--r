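test_that("rendered cylinders carry the analytic optical volume", {
  cfg <- sim_config(counts_u = 1, counts_v = 1, cylinders_per_trap = 1,
                    margin = 15, pixel_size = 0.25,
                    trap_cv = 0, occupancy_prob = 0, seed = 1)
  fld <- render_trap_field(cfg)
  v <- sum(fld$phase$optical_thickness) * cfg$pixel_size^2
  analytic <- pi * 7.5^2 * 9.8 * 0.0241
  expect_lt(abs(v / analytic - 1), 0.01)
  expect_equal(fld$truth$trap_volume_um3, analytic, tolerance = 1e-9)
  expect_equal(round(analytic, 2), 41.74)
})

test_that("index matching zeroes the field; resolution refines the integral", {
  cfg0 <- sim_config(counts_u = 1, counts_v = 1, margin = 15,
                     n_material = 1.33, n_medium = 1.33,
                     trap_cv = 0, occupancy_prob = 0)
  expect_equal(max(abs(render_trap_field(cfg0)$phase$optical_thickness)), 0)
  # discretization error of the area integral shrinks at least linearly
  errs <- vapply(c(0.5, 0.25), function(px) {
    cfg <- sim_config(counts_u = 1, counts_v = 1, cylinders_per_trap = 1,
                      margin = 12, pixel_size = px, trap_cv = 0,
                      occupancy_prob = 0)
    fld <- render_trap_field(cfg)
    abs(sum(fld$phase$optical_thickness) * px^2 / fld$truth$trap_volume_um3 - 1)
  }, numeric(1))
  expect_lte(errs[2], errs[1] / 2 + 1e-12)
})

test_that("cells add exactly their target optical volume and mass", {
  cfg <- small_config()
  fld0 <- render_trap_field(cfg)
  fld <- add_cells(fld0, cfg, occupied_ids = 5L, cell_volumes = 54)
  added <- sum(fld$phase$optical_thickness - fld0$phase$optical_thickness) *
    cfg$pixel_size^2
  expect_equal(added, 54, tolerance = 1e-9)
  expect_equal(fld$truth$cell_mass_pg[5], 300)
  # zero occupancy leaves the field untouched
  fld_none <- add_cells(fld0, cfg, occupied_ids = integer(0))
  expect_identical(fld_none$phase$optical_thickness,
                   fld0$phase$optical_thickness)
  # occupancy probability 1 fills every trap
  cfg_full <- small_config(occupancy_prob = 1)
  fld_full <- add_cells(fld0, cfg_full)
  expect_true(all(fld_full$truth$occupied))
})

test_that("forward DPC model is linear in gain and zero on flat fields", {
  flat <- phase_image(matrix(0.3, 32, 32), 0.5)
  sig <- forward_dpc(flat, recon_params())
  expect_equal(max(abs(sig$sig_x$values)), 0)
  expect_equal(max(abs(sig$sig_y$values)), 0)
  f <- phase_image(smooth_field(32, seed = 2), 0.5)
  s1 <- forward_dpc(f, recon_params(gradient_gain = 0.5))
  s2 <- forward_dpc(f, recon_params(gradient_gain = 1.0))
  expect_equal(2 * s1$sig_x$values, s2$sig_x$values, tolerance = 1e-12)
})

test_that("intensity pairs reproduce the signal and clip at zero", {
  cfg <- small_config()
  fld <- render_trap_field(cfg)
  pairs <- forward_dpc_pairs(fld$phase, cfg)
  sig <- forward_dpc(fld$phase, recon_params(cfg$gradient_gain))
  rec_sig <- compute_dpc_signal(pairs$horizontal)
  expect_equal(rec_sig$values, sig$sig_x$values, tolerance = 1e-12)
  expect_true(all(pairs$vertical$intensity_a >= 0))
})

test_that("time lapse: exponential truth masses, static traps, seeded", {
  cfg <- small_config(frames = 5, growth_rate = 0.021, dt_min = 5 * 60)
  sim <- simulate_timelapse(cfg, occupied_ids = 5L, cell_volumes = 54)
  truth5 <- sim$truth[sim$truth$trap_id == 5L, ]
  # 18 h of growth at 0.021 1/h : final/initial mass ratio exp(0.378)
  expect_equal(truth5$time_h, c(0, 5, 10, 15, 20))
  ratio <- truth5$cell_mass_pg[4] / truth5$cell_mass_pg[1]
  expect_equal(ratio, exp(0.021 * 15), tolerance = 1e-12)
  expect_equal(round(exp(0.021 * 18), 4), 1.4594)
  # trap truth is static
  expect_equal(length(unique(sim$truth$trap_volume_um3[sim$truth$trap_id == 1])), 1L)
  # zero rate keeps truth masses constant
  sim0 <- simulate_timelapse(small_config(frames = 3, growth_rate = 0),
                             occupied_ids = 5L, cell_volumes = 54)
  expect_equal(length(unique(sim0$truth$cell_mass_pg[sim0$truth$trap_id == 5L])), 1L)
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- small_config(trap_cv = 0.042, frame_jitter_cv = 0.018,
                      occupancy_prob = 0.3, frames = 2)
  s1 <- simulate_timelapse(cfg)
  s2 <- simulate_timelapse(cfg)
  expect_identical(s1$phases[[2]]$optical_thickness,
                   s2$phases[[2]]$optical_thickness)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_timelapse(small_config(trap_cv = 0.042, occupancy_prob = 0.3,
                                        frames = 2, seed = 43L))
  expect_false(identical(s1$phases[[1]]$optical_thickness,
                         s3$phases[[1]]$optical_thickness))
})

test_that("quantification closes on noise-free simulator output", {
  # generator/estimator closure: volumes and masses recovered within 1%
  cfg <- small_config(trap_cv = 0)
  fld <- render_trap_field(cfg)
  fld <- add_cells(fld, cfg, occupied_ids = c(2L, 7L), cell_volumes = c(54, 70))
  mk <- render_mask(fld$lattice, dim(fld$phase$optical_thickness))
  ph <- background_correct(fld$phase, mk$labels == 0L)
  tab <- measure_traps(ph, mk)
  m <- merge(tab, fld$truth, by = "trap_id")
  expect_true(all(abs(m$optical_volume_um3 /
                        (m$trap_volume_um3 +
                           ifelse(is.na(m$cell_volume_um3), 0,
                                  m$cell_volume_um3)) - 1) < 0.01))
  occ <- m[m$occupied.x, ]
  expect_equal(occ$cell_mass_pg.x, occ$cell_mass_pg.y, tolerance = 0.01)
})
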