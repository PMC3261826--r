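test_that("history-by-history dose reduction matches the hand formula", {
  # two histories depositing 0 and 2 J in a 1 kg water region
  J <- 1 / 1.602176634e-19            # eV per joule
  tally <- structure(list(n = 2, sum_tot = 2 * J, ssq_tot = 4 * J^2,
                          sum_ch = NULL, ssq_ch = NULL, mass_g = 1000,
                          region = "chamber", depths = 1,
                          beam_area_cm2 = 81, kind = "neutron"),
                     class = "dose_tally")
  d <- finalize_dose(tally)
  expect_equal(d$dose_Gy, 1)          # mean (0 + 2)/2 J/kg
  expect_equal(d$se_Gy, 1)            # s = sqrt((2 - 1)/1) J/kg
  expect_equal(d$dose_per_fluence, 81)
  # identical deposits give zero standard error
  t2 <- tally; t2$n <- 4; t2$sum_tot <- 4 * J; t2$ssq_tot <- 4 * J^2
  expect_equal(finalize_dose(t2)$se_Gy, 0)
  expect_error(finalize_dose(structure(list(n = 1), class = "dose_tally")),
               "at least 2")
})

test_that("total dose equals the sum of the particle-tagged doses exactly", {
  run <- fixture_solid_neutron_run(2e4)
  expect_equal(run$tally$sum_tot, unname(rowSums(run$tally$sum_ch)),
               tolerance = 1e-12)
  d <- finalize_dose(run, by = "channel")
  tot <- finalize_dose(run, by = "total")
  agg <- tapply(d$dose_Gy, d$region, sum)
  expect_equal(as.numeric(agg), tot$dose_Gy, tolerance = 1e-12)
  # single-kind run: lineage view equals the total
  lin <- finalize_dose(run, by = "lineage")
  expect_equal(lin$dose_Gy, tot$dose_Gy)
  expect_true(all(lin$channel == "neutron_lineage"))
})

test_that("track-length fluence equals planar fluence in a collision-free medium", {
  tab <- read.delim(np_extdata("materials.tsv"))
  # water, Perspex and aluminum window all effectively interaction-free
  tab$density_g_cm3[tab$id %in% c(1, 2, 3)] <- 1e-30
  f <- tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
  db <- load_materials(f)
  run <- run_simulation(solid_box_phantom(), default_beam(),
                        mono_spectrum(1e6), transport_config(4e3, seed = 2,
                                                             fluence = TRUE),
                        db = db)
  fl <- finalize_fluence(run)
  tot <- tapply(fl$fluence_per_primary, fl$region, sum)
  se <- sqrt(tapply(fl$se^2, fl$region, sum))
  planar <- 1 / 81
  for (r in c(1, 20, 40))
    expect_lt(abs(tot[[r]] - planar), 4 * se[[r]])
  # all track length lands in the bin containing 1 MeV; other bins are 0 +- 0
  nonzero <- fl[fl$fluence_per_primary > 0, ]
  expect_true(all(nonzero$E_lo_eV <= 1e6 & nonzero$E_hi_eV >= 1e6))
  empty <- fl[fl$fluence_per_primary == 0, ]
  expect_true(all(empty$se == 0))
})

test_that("dose rate and absolute dose conversions track units", {
  expect_equal(to_dose_rate(1.0e-11, 3.2e8), 3.2e-3)
  expect_equal(to_dose_rate(1.0e-11, 0), 0)
  expect_equal(to_absolute(3.2e-3, 0), 0)
  expect_equal(to_absolute(3.2e-3, 180), 0.576)
  expect_error(to_dose_rate(-1, 1))
})

test_that("voxel-block pooling reproduces the stated collection volume", {
  dim <- c(10, 8, 6)
  run <- fake_voxel_run(rep(2e-13, prod(dim)), dim)  # uniform field
  a <- aggregate_voxels(run)
  expect_equal(unique(a$volume_cm3), 8 * 0.02)       # 0.16 cm^3 from 8 voxels
  g <- dose_grid(run)
  expect_equal(a$dose_per_fluence, rep(g[1], nrow(a)), tolerance = 1e-9)
  # pooled SE below the largest single-voxel SE for equal-mass voxels
  set.seed(12)
  d2 <- 2e-13 * runif(prod(dim), 0.5, 1.5)
  run2 <- fake_voxel_run(d2, dim, se_frac = 0.1)
  a2 <- aggregate_voxels(run2)
  S <- dose_grid(run2, statistic = "se")
  expect_true(all(a2$se < apply(S, 1, max)))
  expect_error(aggregate_voxels(run, n_lateral = 50), "exceeds")
})

test_that("selecting a zero-mass region for dose reduction is an error", {
  ph <- synthetic_head_phantom(seed = 4)
  run <- run_simulation(ph, beam_config(4, 4, center = c(-1, 0, 20)),
                        mono_spectrum(1e6),
                        transport_config(200, seed = 1, score_channels = FALSE))
  vac <- which(ph$ids == 0L)[1]
  expect_error(finalize_dose(run, regions = vac), "zero mass")
})
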