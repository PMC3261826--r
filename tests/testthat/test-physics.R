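phys <- physics_tables()

test_that("macroscopic cross sections combine number densities and sigma", {
  # vacuum
  expect_equal(macroscopic_xs(phys, 0, 1e3, "neutron")$total, 0)
  # water at thermal: hand multiplication of packaged anchors
  db <- load_materials()
  N <- number_densities(get_material(db, 1))
  xs <- load_xs()
  sigH <- approx(log(xs$elastic$E_eV[xs$elastic$symbol == "H"]),
                 log(xs$elastic$sigma_b[xs$elastic$symbol == "H"]),
                 log(0.0253))$y
  sigO <- approx(log(xs$elastic$E_eV[xs$elastic$symbol == "O"]),
                 log(xs$elastic$sigma_b[xs$elastic$symbol == "O"]),
                 log(0.0253))$y
  by_hand <- (N[["H"]] * exp(sigH) + N[["O"]] * exp(sigO)) * 1e-24
  got <- macroscopic_xs(phys, 1, 0.0253, "neutron")
  expect_equal(got$elastic, unname(by_hand), tolerance = 0.01)
  cap_hand <- (N[["H"]] * 0.3326 + N[["O"]] * 0.00019) * 1e-24
  expect_equal(got$capture, unname(cap_hand), tolerance = 1e-3)
  # doubling density doubles Sigma
  tab <- read.delim(np_extdata("materials.tsv"))
  tab$density_g_cm3[tab$id == 1] <- 2
  f <- tempfile(fileext = ".tsv")
  write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
  phys2 <- physics_tables(load_materials(f))
  expect_equal(macroscopic_xs(phys2, 1, 1e6, "neutron")$total,
               2 * macroscopic_xs(phys, 1, 1e6, "neutron")$total,
               tolerance = 1e-9)
  expect_error(macroscopic_xs(phys, 1, 1e9, "neutron"), "outside")
})

test_that("channel sampling follows the cross-section ratios", {
  expect_true(all(sample_channel(c(a = 0, b = 2), 50) == "b"))
  set.seed(1)
  x <- sample_channel(c(a = 1, b = 1), 1e4)
  k <- sum(x == "a")
  expect_lt(abs(k - 5000), 3 * sqrt(1e4 * 0.25))
  set.seed(2)
  sig <- c(el = 3, cap = 1, oth = 0.5)
  x <- sample_channel(sig, 1e5)
  cs <- chisq.test(table(factor(x, names(sig))), p = sig / sum(sig))
  expect_gt(cs$p.value, 1e-3)
  expect_error(sample_channel(c(a = 0, b = 0)), "zero")
})

test_that("elastic scattering kinematics match the isotropic-CM closed form", {
  s <- elastic_scatter(1e6, A = 1, n = 1e5, seed = 7)
  r <- s$E_out / 1e6
  expect_true(all(r >= 0 & r <= 1 + 1e-12))
  expect_lt(abs(mean(r) - 0.5), 3 * sd(r) / sqrt(length(r)))
  expect_lt(min(r), 1e-3)   # full backscatter on hydrogen drives E' to 0
  # A = 16: minimum energy ratio is alpha = (15/17)^2
  s16 <- elastic_scatter(1e6, A = 16, n = 1e5, seed = 8)
  a <- (15 / 17)^2
  expect_gte(min(s16$E_out) / 1e6, a - 1e-9)
  expect_lt(min(s16$E_out) / 1e6, a + 0.002)
})

test_that("free-gas scattering thermalises towards the gas temperature", {
  # far below kT the neutron gains energy on average; far above it loses
  lo <- elastic_scatter(1e-3, A = 1, n = 2e4, seed = 9)
  expect_gt(mean(lo$E_out), 1e-3)
  hi <- elastic_scatter(3.9, A = 1, n = 2e4, seed = 10)
  expect_lt(mean(hi$E_out), 3.9 / 2 * 1.2)
})

test_that("capture secondaries: hydrogen gamma, local deposit otherwise", {
  set.seed(3)
  uz <- replicate(2000, {
    s <- capture_secondaries(0.02, "H")
    expect_equal(s$photons$E_eV, 2.2246e6)
    expect_equal(s$local_deposit_eV, 0.02)
    s$photons$uz
  })
  expect_lt(abs(mean(uz)), 3 / sqrt(3 * length(uz)))  # sd of uniform cos = 1/sqrt(3)
  s <- capture_secondaries(0.02, "O")
  expect_equal(nrow(s$photons), 0)
  expect_equal(s$local_deposit_eV, 0.02 + 4.143e6)
})

test_that("Compton sampling respects Klein-Nishina kinematics", {
  E <- 2.2246
  s <- compton_sample(E, n = 2e4, seed = 11)
  expect_equal(s$E_out + s$T_electron, rep(E, nrow(s)), tolerance = 1e-12)
  k <- E / 0.51099895
  edge <- E * 2 * k / (1 + 2 * k)
  expect_lte(max(s$T_electron), edge + 1e-9)
  expect_gt(max(s$T_electron), edge - 0.01)   # the edge is reached
  expect_gt(max(s$E_out), E - 0.01)           # theta ~ 0 keeps E' ~ E
  # consistency of sampled E' with the scattering angle
  expect_equal(s$E_out, E / (1 + k * (1 - s$cos_theta)), tolerance = 1e-9)
})

test_that("Klein-Nishina total cross section has the Thomson limit", {
  expect_equal(klein_nishina_total(1e-6), 0.6652, tolerance = 0.01)
  expect_true(all(diff(klein_nishina_total(c(0.1, 0.5, 1, 2, 5, 8))) < 0))
})
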