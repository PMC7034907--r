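test_that("bending-magnet spectral function peaks near y = 0.29 and decays", {
  # brute-force maximisation of the quadrature-evaluated G1
  ys <- seq(0.05, 1.5, by = 0.01)
  g <- synchrotron_g1(ys)
  expect_true(all(g > 0))
  expect_equal(ys[which.max(g)], 0.29, tolerance = 0.05)
  # exponential tail: flux -> 0 as E -> infinity
  tail_val <- synchrotron_g1(c(10, 20, 40))
  expect_true(all(diff(tail_val) < 0))
  expect_lt(tail_val[3] / max(g), 1e-10)
})

test_that("doubling the critical energy rescales the spectrum", {
  e <- c(20, 40, 80, 160)
  f1 <- bending_magnet_flux(e / 2, 20)
  f2 <- bending_magnet_flux(e, 40)
  # flux(E; 2Ec) = flux(E/2; Ec)/2 holds exactly on flux ratios
  expect_equal(f2 / f2[1], f1 / f1[1], tolerance = 1e-8)
})

test_that("filter transmission follows Beer-Lambert algebra", {
  e <- seq(50, 300, by = 5)
  expect_equal(filter_transmission(list(), e), rep(1, length(e)))
  cu6 <- list(list(material = "copper", thickness_mm = 6))
  cu6x2 <- c(cu6, cu6)
  cu12 <- list(list(material = "copper", thickness_mm = 12))
  t1 <- filter_transmission(cu6, e)
  expect_equal(filter_transmission(cu6x2, e), t1^2, tolerance = 1e-12)
  expect_equal(filter_transmission(cu12, e), t1^2, tolerance = 1e-12)
  # mu_Cu decreases over 50-300 keV, so transmission rises
  expect_true(all(diff(filter_transmission(cu12, e)) > 0))
  # order invariance
  mix1 <- list(list(material = "copper", thickness_mm = 6),
               list(material = "molybdenum", thickness_mm = 0.4))
  expect_equal(filter_transmission(mix1, e),
               filter_transmission(rev(mix1), e), tolerance = 1e-14)
})

test_that("scintillator response is monotone in thickness and absorption falls with energy", {
  e <- seq(50, 300, by = 5)
  expect_equal(scintillator_response(list(material = "luag", thickness_um = 0), e),
               rep(0, length(e)))
  r200 <- scintillator_response(list(material = "luag", thickness_um = 200), e)
  r2000 <- scintillator_response(list(material = "luag", thickness_um = 2000), e)
  expect_true(all(r2000 >= r200))
  # absorbed fraction (response / E) decreases with E: no Lu edge in 64-300
  frac <- r2000 / e
  e_noedge <- e > 64
  expect_true(all(diff(frac[e_noedge]) < 0))
})

test_that("detected spectra are normalised and harden under filtration", {
  bl_soft <- beamline(critical_energy_keV = 20.55,
                      scintillator = list(material = "luag", thickness_um = 200))
  bl_hard <- beamline(critical_energy_keV = 20.55,
                      filters = list(list(material = "copper", thickness_mm = 12)),
                      scintillator = list(material = "luag", thickness_um = 200))
  s_soft <- detected_spectrum(bl_soft)
  s_hard <- detected_spectrum(bl_hard)
  for (s in list(s_soft, s_hard)) {
    expect_equal(sum(s$weight), 1, tolerance = 1e-9)
    expect_true(all(s$weight >= 0))
  }
  expect_lt(average_energy(s_soft), average_energy(s_hard))
})

test_that("adding any filter never decreases the average detected energy", {
  base <- beamline(critical_energy_keV = 20.55,
                   scintillator = list(material = "luag", thickness_um = 2000))
  avg0 <- average_energy(detected_spectrum(base))
  for (mat in c("aluminium", "copper", "molybdenum")) {
    for (th in c(0.1, 1, 5, 20)) {
      bl <- beamline(critical_energy_keV = 20.55,
                     filters = list(list(material = mat, thickness_mm = th)),
                     scintillator = list(material = "luag", thickness_um = 2000))
      expect_gte(average_energy(detected_spectrum(bl)), avg0 - 1e-9)
    }
  }
})

test_that("an opaque filter stack raises a degenerate-spectrum error", {
  bl <- beamline(critical_energy_keV = 20.55,
                 filters = list(list(material = "copper", thickness_mm = 1e6)),
                 scintillator = list(material = "luag", thickness_um = 2000))
  expect_error(detected_spectrum(bl), "degenerate|opaque")
})

test_that("monochromatic spectra do not harden; filtration makes water hardening negligible", {
  e <- seq(10, 400, by = 0.5)
  w <- rep(0, length(e)); w[which.min(abs(e - 146))] <- 1
  mono <- structure(list(energy = e, weight = w), class = "detected_spectrum")
  bh <- beam_hardening_curve(mono, water_mat(), seq(0, 6, by = 0.5))
  expect_lt(attr(bh, "max_rel_dev"), 1e-12)
  # the heavily filtered overview-body configuration: < 3% over 0-6 cm of water
  s_body <- detected_spectrum(beamline_preset("body_24um"))
  bh_body <- beam_hardening_curve(s_body, water_mat(), seq(0, 6, by = 0.5))
  expect_lt(attr(bh_body, "max_rel_dev"), 0.03)
  # unfiltered beam at the same source: > 10%
  s_raw <- detected_spectrum(
    beamline(critical_energy_keV = 20.55,
             scintillator = list(material = "luag", thickness_um = 2000)))
  bh_raw <- beam_hardening_curve(s_raw, water_mat(), seq(0, 6, by = 0.5))
  expect_gt(attr(bh_raw, "max_rel_dev"), 0.10)
})

test_that("beamline presets resolve and fail fast on unknown names", {
  p <- beamline_preset()
  expect_setequal(names(p), c("head_53um", "body_24um", "detail_6um", "plants_4um"))
  bl <- beamline_preset("body_24um")
  expect_s3_class(bl, "beamline")
  expect_length(bl$filters, 2)
  expect_error(beamline_preset("nope"), "unknown preset")
})

test_that("spectrum CSV export round-trips", {
  s <- detected_spectrum(beamline_preset("body_24um"))
  f <- tempfile(fileext = ".csv")
  write_spectrum(s, f)
  d <- read.csv(f)
  expect_equal(d$weight, s$weight, tolerance = 1e-12)
  expect_equal(sum(d$weight), 1, tolerance = 1e-9)
})
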