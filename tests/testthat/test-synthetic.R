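test_that("every generator is seed-deterministic", {
  expect_identical(gen_curves("kinetics", preset = "s-DMPC-folding", seed = 3),
                   gen_curves("kinetics", preset = "s-DMPC-folding", seed = 3))
  expect_identical(gen_zeta_table(n = 50, seed = 4)$table,
                   gen_zeta_table(n = 50, seed = 4)$table)
  c1 <- gen_membrane_cohort(n_structures = 5, seed = 5)
  c2 <- gen_membrane_cohort(n_structures = 5, seed = 5)
  expect_identical(c1$structures, c2$structures)
  expect_identical(c1$records, c2$records)
  t1 <- gen_trajectory(n_frames = 20, f = 0.5, seed = 6)
  t2 <- gen_trajectory(n_frames = 20, f = 0.5, seed = 6)
  expect_identical(t1$trajectory, t2$trajectory)
  # different seeds differ
  expect_false(identical(
    gen_curves("kinetics", preset = "s-DMPC-folding", seed = 1)$data$signal,
    gen_curves("kinetics", preset = "s-DMPC-folding", seed = 2)$data$signal))
})

test_that("every curve preset is recovered by its fitter at default noise", {
  presets <- asymfold_presets()
  for (nm in names(presets)) {
    p <- presets[[nm]]
    curve <- gen_curves(p$kind, preset = nm, seed = 17)
    if (p$kind == "kinetics") {
      fit <- fit_folding_kinetics(curve$data)
      expect_equal(length(fit$k_obs), length(p$k_obs), info = nm)
      expect_true(all(abs(fit$k_obs - p$k_obs) / p$k_obs < p$tolerance),
                  info = nm)
    } else if (p$kind == "titration") {
      fit <- fit_urea_titration(curve$data)
      expect_lt(abs(fit$Pm - p$Pm), p$tolerance)
    } else if (p$kind == "laurdan") {
      mm <- melting_midpoint(curve$data$temp_C, curve$data$gp)
      expect_lt(abs(mm$tm - p$tm), p$tolerance)
    } else if (p$kind == "spectrum") {
      refs <- asymfold:::reference_spectra()
      d <- deconvolute_spectrum(
        data.frame(wavelength_nm = curve$data$wavelength_nm,
                   absorbance = curve$data$absorbance), refs)
      expect_true(all(abs(d$concentrations - p$components) /
                        p$components < p$tolerance))
    }
  }
})

test_that("zeta tables carry their planted linear truth", {
  z <- gen_zeta_table(n = 100, effects = list(mean_charge = 30),
                      noise_sd = 0, seed = 8)
  expect_equal(z$table$zeta_mV, 30 * z$table$mean_charge)
  expect_warning(gen_zeta_table(n = 50, effects = list(mean_charge = 0),
                                seed = 9), "degenerate")
  expect_error(gen_zeta_table(n = 5, seed = 1), "n >= 20")
})

test_that("membrane cohorts plant the patch only where requested", {
  coh <- gen_membrane_cohort(n_structures = 3, seed = 10,
                             patch = list(centre = 8, width = 4, excess = 3))
  expect_equal(coh$truth$band_z, c(21, 25))
  s <- coh$structures[[1]]
  expect_s3_class(s, "membrane_structure")
  res <- s$residues
  # strands span the membrane; loops above, turns below
  expect_true(all(abs(res$ca_z[res$region == "TM"]) <= 15))
  expect_true(all(res$ca_z[res$side == "extracellular"] > 15))
  expect_true(all(res$ca_z[res$side == "periplasmic"] < -15))
  # matched sequence records share length and topology with the structure
  expect_equal(nchar(coh$records[[1]]$sequence), nrow(res))
  expect_equal(strsplit(coh$records[[1]]$topology, "")[[1]] == "S",
               res$region == "TM")

  expect_error(gen_membrane_cohort(n_strands = 7), "even")
  expect_error(gen_membrane_cohort(
    patch = list(centre = 40, width = 4, excess = 3)), "loop reach")
})

test_that("trajectory generator hits its planted bound fraction exactly", {
  tr1 <- gen_trajectory(n_frames = 50, f = 1, seed = 11)
  expect_equal(site_occupancy(tr1$trajectory, tr1$site, "DMPG"), 1.0)
  tr0 <- gen_trajectory(n_frames = 50, f = 0, seed = 12)
  expect_equal(site_occupancy(tr0$trajectory, tr0$site, "DMPG"), 0.0)
  # occupancy equals the realized bound-any fraction by construction
  tr <- gen_trajectory(n_frames = 400, f = 0.4, seed = 13)
  expect_equal(site_occupancy(tr$trajectory, tr$site, "DMPG"),
               tr$truth$bound_any)
  expect_error(gen_trajectory(f = 1.5), "\\[0, 1\\]")
  expect_error(gen_trajectory(box = c(1, 1, 1)), "too small")
})
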