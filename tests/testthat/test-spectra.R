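test_that("CDF construction integrates and normalises the spectrum", {
  sp <- energy_spectrum(c(0, 1, 2), c(3, 1), "neutron")
  cdf <- build_cdf(sp)
  expect_equal(cdf$cum, c(0.75, 1.0))
  one <- build_cdf(energy_spectrum(c(0, 5), 4, "photon"))
  expect_equal(one$cum, 1.0)
  expect_error(build_cdf(energy_spectrum(c(0, 1), 0, "neutron")), "zero total")
  expect_error(energy_spectrum(c(1, 1), 1, "neutron"), "increasing")
  expect_error(energy_spectrum(c(0, 1), -1, "neutron"), ">= 0")
})

test_that("inverse-CDF sampling reproduces the bin probabilities", {
  sp <- energy_spectrum(c(0, 1, 3, 6, 10, 20), c(5, 1, 3, 0.5, 2), "neutron")
  cdf <- build_cdf(sp)
  beam <- beam_config(9, 9, center = c(-1, 0, 0))
  set.seed(5)
  p <- sample_primary(beam, cdf, n = 1e5)
  counts <- table(cut(p$energy, sp$edges))
  cs <- chisq.test(counts, p = sp$rate / sum(sp$rate))
  expect_gt(cs$p.value, 0.01)
  expect_true(all(p$energy >= 0 & p$energy <= 20))  # inside support
})

test_that("primaries fill the rectangular aperture as a parallel beam", {
  beam <- beam_config(9, 9, center = c(-100, 1, -2))
  cdf <- build_cdf(mono_spectrum(1e6))
  set.seed(6)
  p <- sample_primary(beam, cdf, n = 1e4)
  expect_true(all(abs(p$y - 1) <= 4.5) && all(abs(p$z + 2) <= 4.5))
  expect_true(all(p$ux == 1 & p$uy == 0 & p$uz == 0))
  # empirical mean at beam centre within 3 sigma (sd of uniform = w/sqrt(12))
  se <- 9 / sqrt(12) / sqrt(1e4)
  expect_lt(abs(mean(p$y) - 1), 3 * se)
  expect_lt(abs(mean(p$z) + 2), 3 * se)
})

test_that("synthetic beam spectrum is normalised, positive, Watt-shaped", {
  sp <- synthetic_medapp_spectrum("neutron", 3.2e8)
  expect_equal(sum(sp$rate), 3.2e8, tolerance = 1e-9)
  expect_true(all(sp$rate >= 0))
  expect_equal(length(sp$rate), 58)
  # mean energy of the fast (Watt) component: <E> = 3a/2 + a^2 b / 4 ~ 2.03 MeV
  mid <- sqrt(head(sp$edges, -1) * tail(sp$edges, -1))
  fast <- sp$edges[-59] > 1e3
  mean_fast <- sum((sp$rate * mid)[fast]) / sum(sp$rate[fast])
  expect_equal(mean_fast / 1e6, 1.5 * 0.988 + 0.988^2 * 2.249 / 4,
               tolerance = 0.05)
  spg <- synthetic_medapp_spectrum("photon", 2.9e8)
  expect_equal(sum(spg$rate), 2.9e8, tolerance = 1e-9)
  expect_true(min(spg$edges) >= 1e5 && max(spg$edges) <= 8e6)
})

test_that("spectrum files round-trip and sampling is seed-reproducible", {
  sp <- synthetic_medapp_spectrum("neutron", 3.2e8)
  f <- tempfile(fileext = ".txt")
  write_spectrum(sp, f)
  sp2 <- read_spectrum(f)
  expect_equal(sp2$edges, sp$edges, tolerance = 1e-12)
  expect_equal(sp2$rate, sp$rate, tolerance = 1e-12)
  expect_equal(sp2$particle, "neutron")
  expect_error(read_spectrum(tempfile()), "not found")
  cdf <- build_cdf(sp)
  beam <- beam_config(9, 9)
  set.seed(77); a <- sample_primary(beam, cdf, 100)
  set.seed(77); b <- sample_primary(beam, cdf, 100)
  expect_identical(a, b)
})
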