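test_that("excess-dose conversion reproduces hand arithmetic", {
  expect_equal(equivalent_dose_rate_eq2(0, 2.3, 1.65e-3), 0)
  # deep-tumor capture rate 1.09e-6 s^-1, 2.3 MeV, 1.65e-3 kg, Q = 20
  expect_equal(equivalent_dose_rate_eq2(1.09e-6, 2.3, 1.65e-3, 20),
               4.86206e-15, tolerance = 1e-5)
  # fusion: 6.35e-7 s^-1 at 8.67 MeV clears the 1e-14 EGy/s order bound
  expect_gte(equivalent_dose_rate_eq2(6.35e-7, 8.67, 1.65e-3, 20), 1e-14)
  expect_error(equivalent_dose_rate_eq2(1, 1, 0), "mass")
})

test_that("excess dose is linear in rate, e_dep, q and inverse in mass", {
  base <- equivalent_dose_rate_eq2(1e-6, 2.3, 1.65e-3, 20)
  expect_equal(equivalent_dose_rate_eq2(3e-6, 2.3, 1.65e-3, 20), 3 * base)
  expect_equal(equivalent_dose_rate_eq2(1e-6, 6.9, 1.65e-3, 20), 3 * base)
  expect_equal(equivalent_dose_rate_eq2(1e-6, 2.3, 1.65e-3, 60), 3 * base)
  expect_equal(equivalent_dose_rate_eq2(1e-6, 2.3, 4.95e-3, 20), base / 3)
})

test_that("energy-deposition chain matches the printed baseline", {
  expect_equal(dose_from_edep(14), 2.24e-9)
  expect_lt(abs(dose_from_edep(14) - 2.2e-9) / 2.2e-9, 0.02)
  expect_equal(dose_from_edep(0), 0)
  expect_equal(dose_from_edep(1), 1.6e-10)
})

test_that("ICRP chain and Sv->Gy conversion match the printed pair", {
  expect_equal(icrp_equiv_dose(0, 2.5, 1.45), 0)
  expect_equal(icrp_equiv_dose(1, 1, 1), 1e-5 / 3600)   # 1 mrem/h
  sv <- icrp_equiv_dose(0.5, 2.5, 1.45)
  expect_equal(sv, 5.0347e-9, tolerance = 1e-4)
  expect_lt(abs(sv - 4.8e-9) / 4.8e-9, 0.10)
  expect_equal(sv_to_gy(4.8e-9, 5), 9.6e-10)
  expect_equal(sv_to_gy(7, 1), 7)
  expect_equal(sv_to_gy(0, 3), 0)
  expect_error(sv_to_gy(1, 0), "> 0")
})

test_that("conversion-factor table is valid and fast exceeds thermal", {
  cf <- icrp21_factors()
  expect_true(all(cf$cf_mrem_h_per_flux > 0))
  expect_gt(cf_lookup(cf, 1), cf_lookup(cf, 2.5e-8))
  expect_error(cf_lookup(cf, 0), "> 0")
})

test_that("group doses: zero spectrum, Sv/Gy identity, fast dominance", {
  cal <- neutron_field_calibration("mcnpx-like")
  zero <- particle_spectrum("neutron", neutron_grid(cal),
                            numeric(grid_n_bins(neutron_grid(cal))))
  d0 <- neutron_group_doses(zero, calib = cal)
  expect_equal(d0$sv_per_s, rep(0, 3))
  sp <- neutron_spectrum(11.3, cal)
  d <- neutron_group_doses(sp, calib = cal)
  expect_equal(d$gy_per_s, d$sv_per_s / d$w_r)
  expect_gte(d$sv_per_s[d$group == "fast"],
             1e3 * d$sv_per_s[d$group == "thermal"])
})

test_that("fast-group quality factor interpolates across the 6-11 band", {
  w <- radiation_weights()
  expect_equal(q_fast_at(0.1, w), 6)
  expect_equal(q_fast_at(100, w), 11)
  expect_true(all(diff(q_fast_at(10 ^ seq(-1, 2, 0.5), w)) >= 0))
})

test_that("absorption competition stays below 1% at 1000 ppm", {
  ph <- phantom_spec()
  f1000 <- boron_capture_fraction(ph, tumor_spec(ppm = 1000))
  expect_lt(f1000, 0.01)
  expect_equal(f1000, 0.005, tolerance = 0.25)
  expect_equal(boron_capture_fraction(ph, tumor_spec(ppm = 0)), 0)
})

test_that("absorption competition is monotone and saturates toward 1", {
  ph <- phantom_spec()
  f <- vapply(c(10, 100, 1e3, 1e4, 1e5, 1e6),
              function(p) boron_capture_fraction(ph, tumor_spec(ppm = p)),
              numeric(1))
  expect_true(all(diff(f) > 0))
  expect_gt(f[6], 0.8)
  # the 10% crossing falls in the tens-of-thousands-ppm range
  ppm10 <- uniroot(function(p)
    boron_capture_fraction(ph, tumor_spec(ppm = p)) - 0.1,
    c(1e3, 1e6))$root
  expect_gt(ppm10, 1e4)
  expect_lt(ppm10, 1e5)
})

test_that("competition estimator guards its inputs", {
  expect_error(boron_capture_fraction(phantom_spec(),
                                      tumor_spec(boron_isotope = "11B")),
               "10B")
  expect_error(boron_capture_fraction(phantom_spec(radius = 0.5),
                                      tumor_spec()),
               "inside")
  expect_error(boron_capture_fraction(phantom_spec(), tumor_spec(),
                                      thermal_xs = c(H = 0.332)),
               "cross-section for element")
})
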