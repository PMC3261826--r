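# Monte Carlo transport driver.
#
# The compiled kernel uses one counter-based RNG stream per history
# (splitmix64-seeded xoshiro256++), so runs are bit-reproducible under
# (seed, n_histories, config) and independent of execution order; two runs
# with the same seed are correlated history-by-history, which the room-
# influence comparison exploits.

#' Transport configuration
#'
#' @param n_histories Number of primary histories (>= 1).
#' @param seed Integer RNG seed (one derived stream per history).
#' @param cut_n Neutron energy cutoff, eV: below it the remaining kinetic
#'   energy is deposited locally as neutron dose (default 0.01 eV).
#' @param cut_g Photon cutoff, eV: below it the photon energy is deposited
#'   locally as electron dose (default 10 keV).
#' @param thermal_cutoff Energy below which free-gas target motion is sampled
#'   in elastic scattering, eV.
#' @param kT Free-gas temperature, eV (default 300 K).
#' @param score_channels Score per-particle-type channels in addition to the
#'   total (costs 8 doubles per region instead of 2).
#' @param fluence Track-length cell-fluence tally in the chambers of the
#'   solid-box geometry, binned in energy.
#' @param flu_nbins,flu_range Fluence binning (58 log bins, 1e-3 eV - 20 MeV).
#' @param first_interaction Record the x-position of each primary's first
#'   interaction (for attenuation checks).
#' @param log_in_bin Sample energies log-uniformly within a spectrum bin.
#' @param tracking Voxel-grid flight sampling: "surface" (exact face-by-face
#'   traversal, the reference) or "woodcock" (delta tracking with a grid-wide
#'   majorant; statistically equivalent, cheaper on fine heterogeneous grids).
#' @return A `transport_config` list.
#' @export
transport_config <- function(n_histories, seed, cut_n = 0.01, cut_g = 1e4,
                             thermal_cutoff = 4, kT = .KT_300K_EV,
                             score_channels = TRUE, fluence = FALSE,
                             flu_nbins = 58, flu_range = c(1e-3, 2e7),
                             first_interaction = FALSE, log_in_bin = FALSE,
                             tracking = c("surface", "woodcock")) {
  stopifnot(n_histories >= 1, cut_n >= 0, cut_g >= 0)
  tracking <- match.arg(tracking)
  structure(list(n_histories = n_histories, seed = as.integer(seed),
                 cut_n = cut_n, cut_g = cut_g, thermal_cutoff = thermal_cutoff,
                 kT = kT, score_channels = score_channels, fluence = fluence,
                 flu_nbins = flu_nbins, flu_range = flu_range,
                 first_interaction = first_interaction,
                 log_in_bin = log_in_bin, tracking = tracking),
            class = "transport_config")
}

kernel_solid_geometry <- function(ph, phys, beam_x0) {
  inner <- ph$inner
  ch <- ph$chambers
  g <- list(type = "solid",
            wx0 = 0, wx1 = inner[1], wyh = inner[2] / 2, wzh = inner[3] / 2,
            ox0 = -ph$wall, ox1 = inner[1] + ph$wall,
            oyh = ph$outer[2] / 2, ozh = ph$outer[3] / 2,
            win_yh = ph$window[1] / 2, win_zh = ph$window[2] / 2,
            al_x1 = -ph$wall + ph$al_thickness,
            room = !is.null(ph$room),
            nch = as.integer(ch$count), ch_first = ch$first,
            ch_pitch = ch$pitch, ch_r = ch$radius, ch_height = ch$height,
            mat_water = mat_index0(phys, 1L), mat_perspex = mat_index0(phys, 2L),
            mat_al = mat_index0(phys, 3L),
            mat_concrete = mat_index0(phys, if (is.null(ph$room)) 4L else
                                              ph$room$material_id),
            mat_air = mat_index0(phys, 5L))
  if (g$room) {
    r <- ph$room
    g$rx0 <- -r$upstream; g$rx1 <- g$ox1 + r$downstream
    g$ryh <- r$lateral; g$rzh <- r$floor_dist
    g$rwx0 <- g$rx0 - r$exit_wall; g$rwx1 <- g$rx1 + r$wall
    g$rwyh <- g$ryh + r$wall; g$rwzh <- g$rzh + r$wall
    g$rwin_yh <- r$window[1] / 2; g$rwin_zh <- r$window[2] / 2
    g$wb_x0 <- g$rwx0; g$wb_x1 <- g$rwx1
    g$wb_yh <- g$rwyh; g$wb_zh <- g$rwzh
    if (beam_x0 <= g$rx0)
      stop("beam source plane lies inside or behind the room entry wall")
  } else {
    g$wb_x0 <- min(g$ox0, beam_x0) - 1
    g$wb_x1 <- g$ox1 + 1
    g$wb_yh <- g$oyh + 1; g$wb_zh <- g$ozh + 1
  }
  g
}

kernel_voxel_geometry <- function(ph, phys) {
  ids <- material_ids(ph)
  u <- sort(unique(ids))
  lut <- integer(max(u) + 1L)
  lut[u + 1L] <- ifelse(u == 0L, mat_index0(phys, 0L), mat_index0(phys, u))
  list(type = "voxel", dim = ph$dim, voxsize = ph$voxel_size,
       origin = ph$origin, mats = lut[ids + 1L])
}

#' Run a Monte Carlo simulation
#'
#' Transports `config$n_histories` primaries sampled from `spectrum` through
#' `geometry` and returns the raw dose tallies (per-history sums and sums of
#' squares per scoring region and particle channel) plus an energy audit.
#'
#' @param geometry A `solid_phantom` or `voxel_phantom`.
#' @param beam A `beam_config`; `center[1]` is the source-plane x (upstream of
#'   the phantom).
#' @param spectrum An `energy_spectrum` (single particle kind per run; runs
#'   for mixed beams are combined at the analysis stage).
#' @param config A `transport_config`.
#' @param db Material database.
#' @return An `mc_run` object.
#' @export
run_simulation <- function(geometry, beam, spectrum, config,
                           db = load_materials()) {
  stopifnot(inherits(beam, "beam_config"), inherits(spectrum, "energy_spectrum"),
            inherits(config, "transport_config"))
  phys <- physics_tables(db)
  cdf <- build_cdf(spectrum)
  kind <- if (spectrum$particle == "neutron") 0L else 1L

  if (inherits(geometry, "solid_phantom")) {
    glist <- kernel_solid_geometry(geometry, phys, beam$center[1])
    nreg <- geometry$chambers$count
    mass_g <- rep(chamber_volume(geometry$chambers$radius,
                                 geometry$chambers$height) *
                    get_material(db, 1L)$density, nreg)
    region <- "chamber"
  } else if (inherits(geometry, "voxel_phantom")) {
    glist <- kernel_voxel_geometry(geometry, phys)
    nreg <- prod(geometry$dim)
    dens <- numeric(length(db$ids))
    names(dens) <- as.character(db$ids)
    for (m in db$materials) dens[as.character(m$id)] <- m$density
    mass_g <- dens[as.character(material_ids(geometry))] * prod(geometry$voxel_size)
    names(mass_g) <- NULL
    region <- "voxel"
    if (beam$center[1] >= geometry$origin[1])
      stop("beam source plane must be upstream of the voxel grid")
  } else stop("geometry must be a solid_phantom or voxel_phantom")

  blist <- list(kind = kind, x0 = beam$center[1], cy = beam$center[2],
                cz = beam$center[3], width = beam$width, height = beam$height,
                edges = cdf$edges, cum = cdf$cum)
  clist <- list(n_histories = as.numeric(config$n_histories),
                seed = as.numeric(config$seed),
                cut_n = config$cut_n, cut_g = config$cut_g,
                thermal_E = config$thermal_cutoff, kT = config$kT,
                score_channels = config$score_channels,
                fluence = config$fluence, flu_nbins = as.integer(config$flu_nbins),
                flu_emin = config$flu_range[1], flu_emax = config$flu_range[2],
                first_x = config$first_interaction,
                log_in_bin = config$log_in_bin,
                woodcock = identical(config$tracking, "woodcock"))

  t0 <- proc.time()[["elapsed"]]
  res <- cpp_run_transport(unclass(phys), glist, blist, clist)
  elapsed <- proc.time()[["elapsed"]] - t0

  tally <- list(n = res$n_histories, sum_tot = res$sum_tot,
                ssq_tot = res$ssq_tot,
                sum_ch = if (!is.null(res$sum_ch))
                  matrix(res$sum_ch, nreg, 4, byrow = TRUE,
                         dimnames = list(NULL, .np_channels)),
                ssq_ch = if (!is.null(res$ssq_ch))
                  matrix(res$ssq_ch, nreg, 4, byrow = TRUE,
                         dimnames = list(NULL, .np_channels)),
                mass_g = mass_g, region = region,
                beam_area_cm2 = beam$area_cm2, kind = spectrum$particle)
  if (region == "chamber") {
    tally$depths <- geometry$depths
  } else {
    tally$dim <- geometry$dim
    tally$voxel_size <- geometry$voxel_size
    tally$origin <- geometry$origin
  }
  fl <- NULL
  if (config$fluence && !is.null(res$flu_sum)) {
    fl <- list(sum = matrix(res$flu_sum, nreg, config$flu_nbins, byrow = TRUE),
               ssq = matrix(res$flu_ssq, nreg, config$flu_nbins, byrow = TRUE),
               edges = exp(seq(log(config$flu_range[1]),
                               log(config$flu_range[2]),
                               length.out = config$flu_nbins + 1)),
               volume_cm3 = mass_g / get_material(db, 1L)$density,
               n = res$n_histories)
  }
  structure(list(tally = structure(tally, class = "dose_tally"),
                 fluence = fl, audit = res$audit,
                 first_x = res$first_x,
                 config = config, beam = beam,
                 spectrum_total_rate = spectrum$total_rate,
                 geometry_type = region, seed = config$seed,
                 elapsed_s = elapsed),
            class = "mc_run")
}

.np_channels <- c("proton", "neutron", "electron_n", "electron_p")

#' @export
print.mc_run <- function(x, ...) {
  cat(sprintf("<mc_run> %s beam, %g histories, %s geometry, %.1f s\n",
              x$tally$kind, x$tally$n, x$geometry_type, x$elapsed_s))
  cat(sprintf("  energy balance: max per-history imbalance %.2e\n",
              x$audit$max_rel_imbalance))
  inv <- x$audit$E_deposited_eV /
    (x$audit$E_source_eV + x$audit$E_released_eV)
  cat(sprintf("  deposited fraction of available energy: %.3f\n", inv))
  invisible(x)
}

#' @export
summary.mc_run <- function(object, ...) {
  d <- finalize_dose(object)
  cat(sprintf("Dose summary (%s, %g histories):\n", object$tally$kind,
              object$tally$n))
  nz <- d[d$dose_per_fluence > 0, ]
  cat(sprintf("  scored regions with dose: %d of %d\n", nrow(nz), nrow(d)))
  if (nrow(nz)) {
    cat(sprintf("  max dose per unit fluence: %.3e Gy cm^2 (median rel. SE %.1f%%)\n",
                max(nz$dose_per_fluence),
                100 * stats::median(nz$se_per_fluence / nz$dose_per_fluence)))
  }
  invisible(d)
}

#' Walk a ray through a voxel grid
#'
#' Amanatides-Woo traversal: the ordered sequence of voxels a ray crosses and
#' the chord length in each; lengths sum to the total chord through the grid.
#'
#' @param origin,direction Ray origin and direction (cm; direction need not be
#'   normalised but must be nonzero).
#' @param phantom A `voxel_phantom` (or a list with dim, voxel_size, origin).
#' @return data.frame ix, iy, iz (1-based voxel indices), length (cm); zero
#'   rows if the ray misses the grid.
#' @export
traverse <- function(origin, direction, phantom) {
  r <- cpp_traverse(as.numeric(origin), as.numeric(direction),
                    as.integer(phantom$dim), as.numeric(phantom$voxel_size),
                    as.numeric(phantom$origin))
  data.frame(ix = r$ix + 1L, iy = r$iy + 1L, iz = r$iz + 1L, length = r$length)
}

#' Sample exponential free-flight path lengths
#'
#' @param sigma_total Macroscopic total cross section, cm^-1 (>= 0).
#' @param n Number of samples.
#' @return Path lengths (cm); `Inf` when sigma_total is zero. Uses R's RNG.
#' @export
free_flight <- function(sigma_total, n = 1) {
  if (sigma_total < 0) stop("sigma_total must be >= 0")
  if (sigma_total == 0) return(rep(Inf, n))
  rexp(n, sigma_total)
}

#' Depths of first interaction of the primaries
#'
#' Requires `first_interaction = TRUE` in the transport config.
#'
#' @param run An `mc_run`.
#' @param entry_x x-coordinate of the phantom entry face (depth reference).
#' @return Numeric vector, NA for histories whose primary never interacted.
#' @export
first_interaction_depths <- function(run, entry_x = 0) {
  if (is.null(run$first_x))
    stop("run was not configured with first_interaction = TRUE")
  run$first_x - entry_x
}
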