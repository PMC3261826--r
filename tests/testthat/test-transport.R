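test_that("voxel traversal yields exact chords", {
  ph <- small_water_grid(c(20, 10, 10), c(0.5, 0.5, 0.5))
  tr <- traverse(c(-1, 0.13, 0.21), c(1, 0, 0), ph)
  expect_equal(nrow(tr), 40)
  expect_true(all(abs(tr$length - 0.5) < 1e-9))
  # chord sums equal the analytic box chord for random oblique rays
  box_chord <- function(p, d) {
    d <- d / sqrt(sum(d^2))
    lo <- ph$origin; hi <- ph$origin + ph$dim * ph$voxel_size
    t0 <- -Inf; t1 <- Inf
    for (ax in 1:3) {
      if (d[ax] == 0) { if (p[ax] <= lo[ax] || p[ax] >= hi[ax]) return(0) }
      else {
        ta <- sort(c((lo[ax] - p[ax]) / d[ax], (hi[ax] - p[ax]) / d[ax]))
        t0 <- max(t0, ta[1]); t1 <- min(t1, ta[2])
      }
    }
    max(t1 - max(t0, 0), 0)
  }
  set.seed(8)
  for (i in 1:1000) {
    p <- c(runif(1, -25, -1), runif(1, -8, 8), runif(1, -8, 8))
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    if (d[1] <= 0) d[1] <- -d[1]
    tr <- traverse(p, d, ph)
    expect_equal(sum(tr$length), box_chord(p, d), tolerance = 1e-7)
  }
  # a ray that misses the grid
  expect_equal(nrow(traverse(c(-1, 50, 0), c(1, 0, 0), ph)), 0)
})

test_that("free-flight sampling is exponential with mean 1/Sigma", {
  set.seed(9)
  s <- free_flight(2.5, 1e5)
  expect_lt(abs(mean(s) - 0.4), 3 * 0.4 / sqrt(1e5))
  expect_true(all(free_flight(0, 5) == Inf))
  expect_error(free_flight(-1), ">= 0")
})

test_that("collision depths across a two-slab medium follow the piecewise-exponential law", {
  # 15 cm water then 15 cm cortical bone, 1 MeV photon pencil beam
  ph <- voxelise_box(c(30, 10, 10), c(0.5, 0.5, 0.5))
  a <- array(ph$ids, ph$dim); a[31:60, , ] <- 13L
  ph$ids <- as.integer(a)
  E <- 1e6
  run <- run_simulation(ph, beam_config(0.5, 0.5, center = c(-1, 0, 0)),
                        mono_spectrum(E, "photon"),
                        transport_config(2e4, seed = 21, first_interaction = TRUE,
                                         score_channels = FALSE))
  x <- first_interaction_depths(run)
  x <- x[!is.na(x)]
  phys <- physics_tables()
  s1 <- macroscopic_xs(phys, 1, E, "photon")$total
  s2 <- macroscopic_xs(phys, 13, E, "photon")$total
  cdf <- function(q) {
    tau <- ifelse(q <= 15, s1 * q, 15 * s1 + s2 * pmin(q - 15, 15))
    (1 - exp(-tau)) / (1 - exp(-(15 * s1 + 15 * s2)))
  }
  ks <- suppressWarnings(ks.test(x, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("runs are bit-reproducible under a fixed seed and consistent across seeds", {
  r1 <- run_simulation(solid_box_phantom(), default_beam(),
                       synthetic_medapp_spectrum("neutron", 3.2e8),
                       transport_config(5e3, seed = 31))
  r2 <- run_simulation(solid_box_phantom(), default_beam(),
                       synthetic_medapp_spectrum("neutron", 3.2e8),
                       transport_config(5e3, seed = 31))
  expect_identical(r1$tally$sum_tot, r2$tally$sum_tot)
  expect_identical(r1$tally$ssq_ch, r2$tally$ssq_ch)
  # different seeds: pooled shallow-chamber dose agrees within 3 combined SE
  r3 <- run_simulation(solid_box_phantom(), default_beam(),
                       synthetic_medapp_spectrum("neutron", 3.2e8),
                       transport_config(5e3, seed = 32))
  expect_false(identical(r1$tally$sum_tot, r3$tally$sum_tot))
  d1 <- depth_dose(r1); d3 <- depth_dose(r3)
  sel <- 1:10
  z <- (sum(d1$dose_per_fluence[sel]) - sum(d3$dose_per_fluence[sel])) /
    sqrt(sum(d1$se[sel]^2) + sum(d3$se[sel]^2))
  expect_lt(abs(z), 3)
})

test_that("every history conserves energy and off-beam primaries deposit nothing", {
  run <- fixture_solid_neutron_run(2e4)
  expect_lt(run$audit$max_rel_imbalance, 1e-6)
  bal <- with(run$audit, abs(E_source_eV + E_released_eV -
                               E_deposited_eV - E_escaped_eV) /
                (E_source_eV + E_released_eV))
  expect_lt(bal, 1e-6)
  # beam aimed past the phantom: no deposits anywhere
  ph <- small_water_grid()
  miss <- run_simulation(ph, beam_config(2, 2, center = c(-1, 40, 0)),
                         mono_spectrum(1e6), transport_config(500, seed = 33))
  expect_equal(sum(miss$tally$sum_tot), 0)
  expect_equal(miss$audit$E_deposited_eV, 0)
})

test_that("standard errors shrink as one over the square root of n", {
  ns <- c(2e4, 1e5, 5e5)
  mean_se <- vapply(ns, function(n) {
    r <- fixture_solid_neutron_run(n, seed = 101)
    mean(depth_dose(r)$se[1:10])
  }, numeric(1))
  fit <- lm(log10(mean_se) ~ log10(ns))
  expect_lt(abs(coef(fit)[2] + 0.5), 0.15)
})

test_that("Woodcock tracking is statistically equivalent to surface tracking", {
  # heterogeneous grid: water with a bone slab
  ph <- voxelise_box(c(20, 10, 10), c(0.5, 0.5, 0.5))
  a <- array(ph$ids, ph$dim); a[15:24, , ] <- 13L
  ph$ids <- as.integer(a)
  beam <- beam_config(4, 4, center = c(-1, 0, 0))
  sp <- synthetic_medapp_spectrum("neutron", 3.2e8)
  rs <- run_simulation(ph, beam, sp,
                       transport_config(3e4, seed = 61, score_channels = FALSE))
  rw <- run_simulation(ph, beam, sp,
                       transport_config(3e4, seed = 62, score_channels = FALSE,
                                        tracking = "woodcock"))
  ds <- depth_dose(rs, n_lateral = 8, n_vertical = 8)
  dw <- depth_dose(rw, n_lateral = 8, n_vertical = 8)
  z <- (ds$dose_per_fluence - dw$dose_per_fluence) / sqrt(ds$se^2 + dw$se^2)
  expect_lt(max(abs(z)), 4)        # 40 depths compared
  # and the pooled curve-wide dose agrees tightly
  zt <- (sum(ds$dose_per_fluence) - sum(dw$dose_per_fluence)) /
    sqrt(sum(ds$se^2) + sum(dw$se^2))
  expect_lt(abs(zt), 3)
})

test_that("lowering the neutron cutoff lets more captures happen", {
  sp <- synthetic_medapp_spectrum("neutron", 3.2e8)
  hi_cut <- run_simulation(solid_box_phantom(), default_beam(), sp,
                           transport_config(4e3, seed = 41, cut_n = 1000))
  lo_cut <- run_simulation(solid_box_phantom(), default_beam(), sp,
                           transport_config(4e3, seed = 41, cut_n = 0.01))
  # capture gammas release binding energy; with a high cutoff neutrons are
  # killed before they can thermalise and be captured
  expect_gt(lo_cut$audit$E_released_eV, 2 * hi_cut$audit$E_released_eV)
})
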