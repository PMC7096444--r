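test_that("boron inventory matches the printed 9e18 benchmark", {
  t11 <- tumor_spec(boron_isotope = "11B", ppm = 100)
  expect_lt(abs(boron_atom_count(t11) - 9e18) / 9e18, 0.01)
  t10 <- tumor_spec(boron_isotope = "10B", ppm = 100)
  # (4/3 pi 0.71^3 * 1.1) g * 1e-4 / 10.013 g/mol * N_A = 9.918e18 (~9.9e18)
  expect_equal(boron_atom_count(t10), 9.9184e18, tolerance = 1e-4)
  expect_lt(abs(boron_atom_count(t10) - 9.9e18) / 9.9e18, 0.01)
  expect_equal(boron_atom_count(tumor_spec(ppm = 0)), 0)
  # integer molar mass changes the inventory by < 0.1%
  expect_lt(abs(boron_atom_count(t11, 11) / boron_atom_count(t11) - 1), 1e-3)
})

test_that("folding sum: toys and window conventions", {
  g2 <- energy_grid(1, 0L, 1L)
  sp <- particle_spectrum("proton", g2, c(1, 2))
  expect_equal(fold_flux_xs(sp, c(1000, 500)), 2000)
  expect_equal(fold_flux_xs(particle_spectrum("proton", g2, c(0, 0)),
                            c(1000, 500)), 0)
  # window endpoints act on bin midpoints, inclusive at both ends
  g <- energy_grid(0.1, 0L, 9L)
  one <- particle_spectrum("proton", g, rep(1, 10))
  sig <- rep(1, 10)
  expect_equal(fold_flux_xs(one, sig, 0.05, 0.25), 3)   # mids 0.05,0.15,0.25
  expect_error(fold_flux_xs(one, rep(1, 5)), "does not match")
})

test_that("vectorized folding equals the naive loop oracle exactly", {
  set.seed(42)
  g <- energy_grid(0.1, 0L, 399L)
  mid <- grid_midpoints(g)
  for (rep in 1:5) {
    flux <- rexp(400) * 1e-4
    sig <- runif(400, 0, 1400)
    sp <- particle_spectrum("proton", g, flux)
    # agreement to 1 ulp-scale tolerance: sum() accumulates in extended
    # precision, the sequential loop in double
    expect_equal(fold_flux_xs(sp, sig, 0.6, 40),
                 fold_loop(flux, sig, mid, 0.6, 40), tolerance = 1e-12)
    expect_equal(fold_flux_xs(sp, sig), fold_loop(flux, sig, mid),
                 tolerance = 1e-12)
  }
})

test_that("fusion rate combines the printed factors of the folding identity", {
  # folded 70.52 mb cm^-2 s^-1 with n = 9e18 atoms -> 6.347e-7 s^-1
  r <- reaction_rate_result(70.52, 9e18, c(0.6, 40))
  expect_equal(r$rate, 6.3468e-7, tolerance = 1e-4)
})

test_that("fusion rate is linear in ppm and guards its inputs", {
  b <- build_sobp(1.6, 3.0)
  sp <- proton_spectrum_in_tumor(
    b, tumor_spec(depth_interval = c(1.6, 3), boron_isotope = "11B"))
  xs <- b11_fusion_xs()
  mk <- function(ppm) fusion_reaction_rate(
    sp, xs, tumor_spec(depth_interval = c(1.6, 3),
                       boron_isotope = "11B", ppm = ppm))
  expect_equal(mk(1000)$rate, 10 * mk(100)$rate)
  expect_equal(mk(0)$rate, 0)
  expect_error(
    fusion_reaction_rate(sp, xs,
      tumor_spec(depth_interval = c(1.6, 3), boron_isotope = "10B")),
    "11B")
})

test_that("capture rate: single-bin hand product and isotope guard", {
  # phi = 1e-5 at 0.0253 eV, sigma = 3837 b, n(10B at 100 ppm) = 9.918e18
  g1 <- log_energy_grid(c(2.53e-8 / 1.1, 2.53e-8 * 1.1), 1L)
  sp <- particle_spectrum("neutron", g1, 1e-5)
  t10 <- tumor_spec(depth_interval = c(10, 11.3), boron_isotope = "10B")
  r <- capture_reaction_rate(sp, one_over_v_model(), t10)
  expect_equal(r$rate, 9.9184e18 * 1e-5 * 3837e-24, tolerance = 1e-4)
  expect_equal(r$rate, 3.808e-7, tolerance = 1e-3)
  expect_error(
    capture_reaction_rate(sp, one_over_v_model(),
      tumor_spec(depth_interval = c(10, 11.3), boron_isotope = "11B")),
    "10B")
})

test_that("rates scale linearly with the spectrum", {
  cal <- neutron_field_calibration("mcnpx-like")
  sp <- neutron_spectrum(11.3, cal)
  t10 <- tumor_spec(depth_interval = c(10, 11.3), boron_isotope = "10B")
  r1 <- capture_reaction_rate(sp, one_over_v_model(), t10)$rate
  sp3 <- particle_spectrum("neutron", sp$grid, 3 * sp$flux)
  expect_equal(capture_reaction_rate(sp3, one_over_v_model(), t10)$rate,
               3 * r1)
  expect_gte(r1, 0)
})

test_that("percent increase reproduces the published comparison statistic", {
  expect_equal(round(percent_increase(9.5e-8, 1.09e-6), 1), 91.3)
  expect_equal(round(percent_increase(8.14e-8, 7.6e-7), 1), 89.3)
  expect_equal(percent_increase(5, 5), 0)
  expect_error(percent_increase(1, 0), "> 0")
})

test_that("reaction-rate JSON carries all fields and a config hash", {
  r <- reaction_rate_result(70.52, 9e18, c(0.6, 40), "11B(p,aa)a")
  txt <- rate_to_json(r)
  obj <- jsonlite::fromJSON(txt)
  expect_equal(obj$folded_sum, 70.52)
  expect_equal(obj$n_atoms, 9e18)
  expect_equal(obj$rate, r$rate)
  expect_equal(obj$energy_window, c(0.6, 40))
  expect_match(obj$config_hash, "^[0-9a-f]{8}$")
})
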