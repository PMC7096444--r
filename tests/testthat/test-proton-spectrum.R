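test_that("zero-weight companion peaks contribute nothing", {
  m <- range_energy_model()
  b1 <- beam_config(50, 60, c(55, 60), c(1, 0), model = m)
  b2 <- beam_config(50, 60, 55, 1, model = m)
  tum <- tumor_spec(depth_interval = c(1.6, 3.0), boron_isotope = "11B")
  expect_equal(proton_spectrum_in_tumor(b1, tum)$flux,
               proton_spectrum_in_tumor(b2, tum)$flux)
})

test_that("constant stopping power toy gives a flat 0.05 cm^-2 spectrum", {
  # R = 0.5 E^(1+eps): S ~ 2 MeV/cm; 10-MeV proton stopping in a 1-cm^3 tumor
  m <- range_energy_model(alpha = 0.5, p = 1 + 1e-9, density = 1,
                          e_valid_max = 1000)
  b <- beam_config(10, 10, 10, 1, model = m)
  tum <- tumor_spec(radius = (3 / (4 * pi))^(1/3), volume = 1,
                    depth_interval = c(0, 5.05), boron_isotope = "11B")
  grid <- energy_grid(0.1, 0L, 100L)
  sp <- proton_spectrum_in_tumor(b, tum, grid)
  mid <- grid_midpoints(grid)
  expect_equal(sp$flux[mid < 10], rep(0.05, sum(mid < 10)), tolerance = 1e-6)
  expect_equal(sp$flux[mid > 10], rep(0, sum(mid > 10)))
})

test_that("spectrum matches a brute-force depth-marching oracle", {
  m <- range_energy_model()
  e0 <- 58
  b <- beam_config(e0, e0, e0, 1, model = m)
  tum <- tumor_spec(depth_interval = c(1.6, 3.0), boron_isotope = "11B")
  grid <- energy_grid(0.1, 0L, 599L)
  sp <- proton_spectrum_in_tumor(b, tum, grid)
  oracle <- track_length_oracle(e0, 1.6, 3.0, m, grid, dz = 2e-5)
  # total in-tumor track length agrees to 1%
  expect_equal(sum(sp$flux) * tum$volume, sum(oracle), tolerance = 0.01)
  # and so does the energy distribution where the flux is appreciable
  big <- sp$flux * tum$volume > 0.005
  expect_equal(sp$flux[big] * tum$volume, oracle[big], tolerance = 0.02)
})

test_that("track-length closure holds for full SOBP beams", {
  for (d in list(shallow_case, deep_case)) {
    b <- build_sobp(d[1], d[2])
    tum <- tumor_spec(depth_interval = d, boron_isotope = "11B")
    sp <- proton_spectrum_in_tumor(b, tum)
    r_pk <- range_from_energy(b$peak_energies, b$model)
    path <- sum(b$peak_weights * (pmin(r_pk, d[2]) - d[1]))
    expect_equal(sum(sp$flux) * tum$volume, path, tolerance = 1e-9)
    expect_true(all(sp$flux >= 0))
  }
})

test_that("sub-600-keV bins are flagged and grid coverage is enforced", {
  b <- build_sobp(1.6, 3.0)
  tum <- tumor_spec(depth_interval = c(1.6, 3.0), boron_isotope = "11B")
  sp <- proton_spectrum_in_tumor(b, tum)
  flag <- attr(sp, "sub_threshold")
  expect_identical(flag, grid_midpoints(sp$grid) < 0.6)
  expect_error(proton_spectrum_in_tumor(b, tum, energy_grid(0.1, 0L, 100L)),
               "does not cover")
  expect_error(
    proton_spectrum_in_tumor(b,
      tumor_spec(depth_interval = c(5, 6), boron_isotope = "11B")),
    "reach the tumor")
})
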