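test_that("depth-dose extraction covers the chamber array and recovers a known attenuation", {
  run <- fixture_solid_neutron_run(2e4)
  dd <- depth_dose(run)
  expect_equal(dd$depth_cm, chamber_depths(0.5, 1.0, 40))
  # constructed exponential dose field: fitted attenuation length within 2%
  dim <- c(50, 8, 6)
  x <- (seq_len(dim[1]) - 0.5) * 0.2
  lambda <- 7.3
  field <- rep(1e-12 * exp(-x / lambda), times = prod(dim[2:3]))
  run_exp <- fake_voxel_run(field, dim)
  dd2 <- depth_dose(run_exp)
  fit <- lm(log(dd2$dose_per_fluence) ~ dd2$depth_cm)
  expect_equal(-1 / coef(fit)[[2]], lambda, tolerance = 0.02)
  # uniform field gives a flat curve
  flat <- depth_dose(fake_voxel_run(rep(1e-12, prod(dim)), dim))
  expect_lt(diff(range(flat$dose_per_fluence)) / mean(flat$dose_per_fluence), 1e-9)
})

test_that("lateral profiles expose the field edges", {
  dim <- c(10, 21, 5)
  set.seed(3)
  field <- rep(1e-13, prod(dim))
  run <- fake_voxel_run(field, dim)
  pr <- lateral_profile(run, x_index = 5, z_index = 3)
  expect_equal(nrow(pr), 21)
  expect_lt(diff(range(pr$dose_per_fluence)), 1e-20)   # flat for uniform field
  expect_error(lateral_profile(run, 99, 3), "out of range")
  expect_error(lateral_profile(run, 5, 99), "out of range")
  # relative decrease definition
  p <- data.frame(y_index = c(39, 41), dose_per_fluence = c(0.07, 1.0))
  expect_equal(edge_decrease(p, y_in = 41, y_out = 39), 93)
  expect_equal(edge_decrease(p, 39, 39), 0)
})

test_that("cumulative DVH is a proper survival curve of the organ dose", {
  # uniform 2 Gy organ: step from 1 to 0 at 2 Gy
  dvh <- cumulative_dvh(rep(2, 50), rep(TRUE, 50), bin_width = 0.5)
  expect_equal(dvh$volume_fraction[dvh$dose == 0], 1)
  expect_equal(dvh$volume_fraction[dvh$dose == 2], 1)
  expect_equal(dvh$volume_fraction[dvh$dose == 2.5], 0)
  dvh2 <- cumulative_dvh(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, TRUE),
                         bin_width = 0.5)
  expect_equal(dvh2$volume_fraction[dvh2$dose == 2.5], 0.5)
  expect_equal(dvh2$volume_fraction[1], 1)
  expect_true(all(diff(dvh2$volume_fraction) <= 0))
  expect_true(all(dvh2$volume_fraction >= 0 & dvh2$volume_fraction <= 1))
  # mean organ dose = integral of V(D) dD (numerically, to binning accuracy)
  set.seed(4)
  d <- runif(500, 0, 6)
  dvh3 <- cumulative_dvh(d, rep(TRUE, 500), bin_width = 0.01)
  expect_equal(sum(dvh3$volume_fraction) * 0.01, mean(d), tolerance = 0.01)
  expect_error(cumulative_dvh(d, rep(FALSE, 500)), "empty")
})

test_that("RBE weighting is the stated linear combination", {
  n <- array(runif(24), dim = c(2, 3, 4))
  p <- array(runif(24), dim = c(2, 3, 4))
  comp <- list(neutron_lineage = n, photon_lineage = p)
  expect_equal(apply_rbe(comp, c(neutron_lineage = 1, photon_lineage = 1)), n + p)
  expect_equal(apply_rbe(list(neutron_lineage = n), c(neutron_lineage = 3)), 3 * n)
  # 60/40 mixed field with weights (3, 1): factor 2.2 on the total
  tot <- apply_rbe(list(neutron_lineage = 0.6 * (n * 0 + 1),
                        photon_lineage = 0.4 * (n * 0 + 1)))
  expect_equal(unique(as.vector(tot)), 2.2)
  # linearity in the weights
  w1 <- c(neutron_lineage = 1.5, photon_lineage = 0.5)
  w2 <- c(neutron_lineage = 1.5, photon_lineage = 0.5)
  expect_equal(apply_rbe(comp, w1 + w2),
               apply_rbe(comp, w1) + apply_rbe(comp, w2))
  expect_error(apply_rbe(list(photon_lineage = p)), "missing")
  expect_error(apply_rbe(comp, c(neutron_lineage = -1)), "positive")
})

test_that("photon renormalisation solves the least-squares match", {
  depth <- seq(0.5, 20, by = 1)
  P <- exp(-depth / 15); S <- 0.1 * exp(-depth / 8)
  expect_equal(renormalize_photons(P, S, P + S, depth), 1)
  expect_equal(renormalize_photons(P, S, 2 * P + S, depth), 2)
  # invariant to a common rescaling of all three curves
  s <- renormalize_photons(P, S, 1.7 * P + S, depth)
  expect_equal(renormalize_photons(5 * P, 5 * S, 5 * (1.7 * P + S), depth), s)
  expect_error(renormalize_photons(0 * P, S, P, depth), "zero")
  expect_error(renormalize_photons(P, S, P, depth, window = c(100, 200)),
               "empty")
})

test_that("isodose contours behave on constant, ramp and radial fields", {
  const <- matrix(1, 10, 10)
  iso <- isodose_contours(const, prescribed = 2, levels = c(10, 90))
  expect_true(all(vapply(iso, function(l) length(l$contours), integer(1)) == 0))
  # linear ramp: the mid-level contour sits at the mid position
  ramp <- matrix(rep(seq(0, 2, length.out = 21), 15), 21, 15)
  isor <- isodose_contours(ramp, prescribed = 2, levels = 50)
  xs <- unlist(lapply(isor[[1]]$contours, function(p) p$x))
  expect_true(all(abs(xs - 11) < 0.1))      # value 1 at row index 11
  # radially symmetric dose: closed contours, enclosed area ordered by level
  g <- expand.grid(x = 1:41, y = 1:41)
  r2 <- (g$x - 21)^2 + (g$y - 21)^2
  rad <- matrix(2 * exp(-r2 / 120), 41, 41)
  isoc <- isodose_contours(rad, prescribed = 2, levels = c(30, 60, 90))
  areas <- vapply(isoc, function(l) {
    expect_length(l$contours, 1)
    p <- l$contours[[1]]
    expect_lt((p$x[1] - p$x[nrow(p)])^2 + (p$y[1] - p$y[nrow(p)])^2, 1e-9)
    abs(sum(p$x * c(p$y[-1], p$y[1]) - p$y * c(p$x[-1], p$x[1]))) / 2
  }, numeric(1))
  expect_true(all(diff(areas) < 0))
  expect_error(isodose_contours(const, prescribed = -1), "positive")
  expect_error(isodose_contours(matrix(1, 1, 5), prescribed = 1), "2 x 2")
})

test_that("wall-influence comparison reports relative differences", {
  dd <- data.frame(depth_cm = 1:5, dose_per_fluence = c(1, 2, 3, 4, 5),
                   se = rep(0.01, 5))
  expect_equal(wall_influence(dd, dd)$rel_diff, rep(0, 5))
  up <- dd; up$dose_per_fluence <- dd$dose_per_fluence * 1.05
  expect_equal(wall_influence(up, dd)$rel_diff, rep(0.05, 5), tolerance = 1e-9)
  z <- dd; z$dose_per_fluence[3] <- 0
  expect_error(wall_influence(dd, z), "zero free-field")
})
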