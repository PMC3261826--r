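# Shared fixtures. Heavier Monte Carlo runs are memoised so several test
# files can reuse them without re-running the kernel.

.fixtures <- new.env()

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

default_beam <- function() beam_config(9, 9, center = c(-100, 0, 0))

mono_spectrum <- function(E_eV, particle = "neutron")
  energy_spectrum(c(E_eV * 0.999, E_eV * 1.001), 1, particle)

fixture_solid_neutron_run <- function(n = 2e4, seed = 101, ...) {
  memo(paste0("solid_n_", n, "_", seed), {
    run_simulation(solid_box_phantom(), default_beam(),
                   synthetic_medapp_spectrum("neutron", 3.2e8),
                   transport_config(n, seed, ...))
  })
}

# small all-water voxel grid for cheap voxel-geometry tests
small_water_grid <- function(extent = c(20, 10, 10), voxel = c(0.5, 0.5, 0.5))
  voxelise_box(extent, voxel)

# a fabricated voxel-geometry run with a prescribed per-voxel dose field and
# negligible statistical error, for testing the reduction/analysis stages
fake_voxel_run <- function(dose_Gy_per_hist, dim, voxel = c(0.2, 0.2, 0.5),
                           se_frac = 1e-6, n = 1000, beam_area = 81,
                           mass = NULL) {
  stopifnot(length(dose_Gy_per_hist) == prod(dim))
  if (is.null(mass)) mass <- rep(prod(voxel), prod(dim))  # water
  ev2gy <- 1.602176634e-16
  xbar <- dose_Gy_per_hist * mass / ev2gy
  se <- xbar * se_frac
  ssq <- n * (se^2 * (n - 1) + xbar^2)
  tally <- structure(list(n = n, sum_tot = xbar * n, ssq_tot = ssq,
                          sum_ch = NULL, ssq_ch = NULL, mass_g = mass,
                          region = "voxel", beam_area_cm2 = beam_area,
                          kind = "neutron", dim = as.integer(dim),
                          voxel_size = voxel,
                          origin = c(0, -dim[2] * voxel[2] / 2,
                                     -dim[3] * voxel[3] / 2)),
                     class = "dose_tally")
  structure(list(tally = tally, audit = list(max_rel_imbalance = 0),
                 config = transport_config(n, 1), seed = 1L,
                 geometry_type = "voxel", elapsed_s = 0),
            class = "mc_run")
}
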