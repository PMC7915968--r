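test_that("background correction removes exactly the region mean", {
  set.seed(4)
  base <- matrix(rnorm(400, sd = 0.01), 20, 20)
  reg <- matrix(FALSE, 20, 20); reg[1:10, 1:10] <- TRUE
  ph <- phase_image(base, 0.5)
  out1 <- background_correct(ph, reg)
  # shift invariance: adding a constant changes nothing
  out2 <- background_correct(phase_image(base + 3.7, 0.5), reg)
  expect_equal(out1$optical_thickness, out2$optical_thickness,
               tolerance = 1e-12)
  expect_lt(abs(mean(out1$optical_thickness[reg])), 1e-12)
  # uniform image -> all zero
  u <- background_correct(phase_image(matrix(0.7, 8, 8), 1), matrix(TRUE, 8, 8))
  expect_equal(u$optical_thickness, matrix(0, 8, 8))
  expect_error(background_correct(ph, matrix(FALSE, 20, 20)), "empty")
})

test_that("only the mean is removed: tilted plane keeps object contrast", {
  plane <- outer(seq(0, 0.1, length.out = 40), seq(0, 0.05, length.out = 40), "+")
  obj <- matrix(0, 40, 40); obj[18:22, 18:22] <- 0.3
  reg <- matrix(TRUE, 40, 40); reg[15:25, 15:25] <- FALSE
  out <- background_correct(phase_image(plane + obj, 0.5), reg)
  # oracle: subtract the region mean by hand (no plane fit happens)
  oracle <- (plane + obj) - mean((plane + obj)[reg])
  expect_equal(out$optical_thickness, oracle, tolerance = 1e-12)
})

test_that("optical volume is the thickness sum times pixel area", {
  th <- matrix(0, 20, 20); th[1:10, 1:10] <- 0.2362
  ph <- phase_image(th, 0.5)
  reg <- th > 0
  expect_equal(optical_volume(ph, reg), 0.2362 * 100 * 0.25)
  expect_equal(optical_volume(phase_image(matrix(0, 5, 5), 2),
                              matrix(TRUE, 5, 5)), 0)
  # single pixel: t * s^2
  expect_equal(optical_volume(phase_image(matrix(1.3, 3, 3), 0.7),
                              cbind(1, 1)), 1.3 * 0.49)
  expect_error(optical_volume(ph, cbind(25, 3)), "outside")
  # additivity over disjoint regions
  set.seed(8)
  ph2 <- phase_image(matrix(rnorm(100), 10, 10), 0.5)
  a <- matrix(FALSE, 10, 10); a[1:5, ] <- TRUE
  b <- !a
  expect_equal(optical_volume(ph2, a) + optical_volume(ph2, b),
               optical_volume(ph2, matrix(TRUE, 10, 10)))
})

test_that("theoretical trap volume follows the cylinder formula", {
  geom <- trap_geometry(radius = 7.5, height = 9.8, cylinders_per_trap = 1)
  opt <- material_optics(n_material = 1.330 + 0.0241, n_medium = 1.330)
  v <- theoretical_trap_volume(geom, opt)
  expect_equal(v, pi * 7.5^2 * 9.8 * 0.0241, tolerance = 1e-10)
  expect_equal(round(v, 2), 41.74)
  # delta_n = 0 -> 0
  expect_equal(theoretical_trap_volume(geom, material_optics(1.33, 1.33)), 0)
  # two cylinders double one
  geom2 <- trap_geometry(7.5, 9.8, 2)
  expect_equal(theoretical_trap_volume(geom2, opt), 2 * v)
})

test_that("refractive-index difference from phase over a known height", {
  ph <- phase_image(matrix(0.23618, 10, 10), 0.5)
  reg <- matrix(TRUE, 10, 10)
  expect_equal(delta_n_from_phase(ph, reg, 9.8), 0.0241, tolerance = 1e-12)
  expect_equal(delta_n_from_phase(phase_image(matrix(0, 4, 4), 1),
                                  matrix(TRUE, 4, 4), 9.8), 0)
  # thickness equal to height -> ratio identity 1
  expect_equal(delta_n_from_phase(phase_image(matrix(9.8, 4, 4), 1),
                                  matrix(TRUE, 4, 4), 9.8), 1)
  expect_error(delta_n_from_phase(ph, reg, -1), "positive")
})

test_that("absolute refractive index is medium plus difference", {
  expect_equal(round(refractive_index(0.0241, 1.330), 3), 1.354)
  expect_equal(refractive_index(0, 1.41), 1.41)
  expect_equal(refractive_index(-0.01, 1.33), 1.32)
})

test_that("mass conversion uses alpha = 0.18 um^3/pg exactly", {
  cal <- mass_calibration()
  expect_equal(cal$alpha_um3_per_pg, 0.18)
  expect_equal(mass_from_optical_volume(0.18, cal), 1)
  expect_equal(mass_from_optical_volume(98, cal), 98 / 0.18)
  expect_equal(round(mass_from_optical_volume(98, cal), 1), 544.4)
  expect_equal(mass_from_optical_volume(0, cal), 0)
})

test_that("trap measurement subtracts the mean empty-trap reference", {
  cfg <- small_config()
  fld <- render_trap_field(cfg)
  fld <- add_cells(fld, cfg, occupied_ids = 5L, cell_volumes = 54)
  mk <- render_mask(fld$lattice, dim(fld$phase$optical_thickness))
  tab <- measure_traps(fld$phase, mk)
  expect_equal(sum(tab$occupied), 1L)
  expect_true(tab$occupied[tab$trap_id == 5L])
  # empty traps all identical: reference subtraction is exact
  expect_equal(tab$cell_optical_volume_um3[tab$trap_id == 5L], 54,
               tolerance = 1e-9)
  expect_equal(tab$cell_mass_pg[tab$trap_id == 5L], 300, tolerance = 1e-9)
  expect_true(all(is.na(tab$cell_mass_pg[!tab$occupied])))
  v0 <- tab$optical_volume_um3[!tab$occupied]
  expect_lt(diff(range(v0)), 1e-9)
})

test_that("all-empty frames report no cells; manual override wins", {
  cfg <- small_config()
  fld <- render_trap_field(cfg)
  mk <- render_mask(fld$lattice, dim(fld$phase$optical_thickness))
  tab <- measure_traps(fld$phase, mk)
  expect_true(all(!tab$occupied))
  expect_true(all(is.na(tab$cell_optical_volume_um3)))
  # manual empty list: everything not listed is treated as occupied
  tab2 <- measure_traps(fld$phase, mk, empty_ids = c(1:4, 6:9))
  expect_true(tab2$occupied[tab2$trap_id == 5L])
  expect_equal(tab2$cell_optical_volume_um3[tab2$trap_id == 5L], 0,
               tolerance = 1e-9)
})

test_that("fewer than 3 empty traps is an error", {
  cfg <- small_config()
  fld <- render_trap_field(cfg)
  mk <- render_mask(fld$lattice, dim(fld$phase$optical_thickness))
  expect_error(measure_traps(fld$phase, mk, empty_ids = c(1L, 2L)),
               "at least 3 empty")
})

test_that("rendered cylinder integral converges to the analytic volume", {
  # discrete area integral vs pi r^2 h delta_n, within 1% at >= 20 px/radius
  analytic <- pi * 7.5^2 * 9.8 * 0.0241
  for (px in c(7.5 / 20, 7.5 / 40)) {
    n <- ceiling(20 / px)
    th <- trapmass:::add_disc(matrix(0, n, n), px, 10, 10, 7.5, 9.8 * 0.0241)
    v <- sum(th) * px^2
    expect_lt(abs(v / analytic - 1), 0.01)
  }
})
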