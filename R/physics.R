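# Simplified neutron/photon interaction model.
#
# Neutrons: elastic scattering from smooth per-element log-log anchor tables
# (resonances omitted) with isotropic centre-of-mass kinematics, free-gas
# 300 K target motion below a thermal cutoff, and 1/v radiative capture
# (hydrogen emits the 2.2246 MeV capture gamma; other elements deposit their
# Q-value locally).  Photons: Klein-Nishina Compton scattering, a parametric
# photoelectric cross section ~ Z^4.5/E^3, and parametric pair production.
# Charged secondaries are not tracked (kerma approximation): their kinetic
# energy is deposited at the interaction site, tagged by particle type.

#' Load neutron cross-section tables
#'
#' Reads the packaged anchor tables by default; users can point either
#' argument at their own table in the same plain-text format to swap in
#' different data.
#'
#' @param elastic_path,capture_path Optional paths to replacement tables.
#' @return list with `elastic` (data.frame symbol, E_eV, sigma_b) and
#'   `capture` (data.frame symbol, sigma_thermal_b, E_gamma_MeV, Q_MeV).
#' @export
load_xs <- function(elastic_path = NULL, capture_path = NULL) {
  custom <- !is.null(elastic_path) || !is.null(capture_path)
  if (!custom && !is.null(the$xs)) return(the$xs)
  xs <- list(
    elastic = read.delim(if (is.null(elastic_path)) np_extdata("xs_elastic.tsv")
                         else elastic_path, stringsAsFactors = FALSE),
    capture = read.delim(if (is.null(capture_path)) np_extdata("xs_capture.tsv")
                         else capture_path, stringsAsFactors = FALSE))
  if (!custom) the$xs <- xs
  xs
}

#' Build the physics tables used by the transport kernel
#'
#' Combines the element table, elastic/capture cross-section tables and the
#' material compositions into the structure consumed by the compiled kernel.
#' Material ids are mapped to 0-based kernel indices; the mapping is kept as
#' an attribute so voxel grids can be translated.
#'
#' @param db A `material_db` (default: packaged table).
#' @param xs Cross-section tables from [load_xs()].
#' @return A `physics_db` object.
#' @export
physics_tables <- function(db = load_materials(), xs = load_xs()) {
  el <- element_table()
  elements <- lapply(seq_len(nrow(el)), function(i) {
    sym <- el$symbol[i]
    tab <- xs$elastic[xs$elastic$symbol == sym, ]
    cap <- xs$capture[xs$capture$symbol == sym, ]
    if (!nrow(tab)) stop("no elastic table for element ", sym)
    list(Ar = el$A_r[i], Z = el$Z[i],
         cap_th = if (nrow(cap)) cap$sigma_thermal_b else 0,
         Egam_eV = if (nrow(cap)) cap$E_gamma_MeV * 1e6 else 0,
         Q_eV = if (nrow(cap)) cap$Q_MeV * 1e6 else 0,
         logE = log(tab$E_eV), logS = log(tab$sigma_b))
  })
  names(elements) <- el$symbol
  materials <- lapply(db$materials, function(m) {
    if (m$density <= 0) {
      list(elem = 0L, N = 0, vacuum = TRUE)
    } else {
      N <- number_densities(m)
      list(elem = match(names(N), el$symbol) - 1L, N = unname(N), vacuum = FALSE)
    }
  })
  structure(list(elements = elements, materials = materials,
                 mat_ids = db$ids),
            class = "physics_db")
}

mat_index0 <- function(phys, id) {
  i <- match(id, phys$mat_ids)
  if (any(is.na(i))) stop("material id(s) not in physics tables: ",
                          paste(unique(id[is.na(i)]), collapse = ", "))
  i - 1L
}

#' Macroscopic cross sections of a material
#'
#' Per-channel macroscopic cross sections Sigma = sum_i N_i sigma_i(E)
#' (cm^-1), interpolated on the same energy grid the transport kernel uses.
#'
#' @param phys A `physics_db` from [physics_tables()].
#' @param material_id Material id (as in the material table).
#' @param energy Energy in eV.
#' @param particle "neutron" or "photon".
#' @return List of per-channel Sigma (cm^-1) and `total`.
#' @export
macroscopic_xs <- function(phys, material_id, energy,
                           particle = c("neutron", "photon")) {
  particle <- match.arg(particle)
  if (energy < .E_GRID_MIN || energy > .E_GRID_MAX)
    stop("energy ", energy, " eV outside tabulated range [",
         .E_GRID_MIN, ", ", .E_GRID_MAX, "] eV")
  cpp_macro_xs(unclass(phys), mat_index0(phys, material_id), energy,
               if (particle == "neutron") 0L else 1L)
}

#' Sample an interaction channel
#'
#' Draws a channel with probability proportional to its macroscopic cross
#' section. Uses R's RNG (set.seed() applies).
#'
#' @param sigma Named numeric vector of per-channel Sigma (>= 0).
#' @param n Number of draws.
#' @return Character vector of channel labels.
#' @export
sample_channel <- function(sigma, n = 1) {
  stopifnot(is.numeric(sigma), !is.null(names(sigma)), all(sigma >= 0))
  if (sum(sigma) <= 0) stop("all channel cross sections are zero")
  names(sigma)[sample.int(length(sigma), n, replace = TRUE, prob = sigma)]
}

rng_seed_from_R <- function() sample.int(2147483647L, 1)

#' Sample neutron elastic scattering
#'
#' Isotropic scattering in the centre-of-mass frame off a nucleus of mass
#' number A. Above `thermal_cutoff` the target is at rest and
#' E'/E in [alpha, 1] with alpha = ((A-1)/(A+1))^2; below it the target moves
#' with a free-gas Maxwellian at temperature kT.
#'
#' @param energy Incident energy, eV.
#' @param A Target mass number.
#' @param n Number of samples.
#' @param thermal_cutoff Free-gas threshold, eV (default 4).
#' @param kT Gas temperature, eV (default 300 K).
#' @param seed Optional integer; default drawn from R's RNG.
#' @return data.frame with `E_out` (eV) and `mu_lab` (lab-frame cosine).
#' @export
elastic_scatter <- function(energy, A, n = 1, thermal_cutoff = 4,
                            kT = .KT_300K_EV, seed = NULL) {
  stopifnot(energy > 0, A >= 1)
  if (is.null(seed)) seed <- rng_seed_from_R()
  m <- cpp_sample_elastic(energy, A, as.integer(n), seed,
                          energy < thermal_cutoff, kT)
  data.frame(E_out = m[, 1], mu_lab = m[, 2])
}

#' Secondaries from radiative neutron capture
#'
#' Hydrogen emits a single isotropic 2.2246 MeV capture gamma and the
#' neutron's remaining kinetic energy is deposited locally; all other elements
#' deposit kinetic energy plus their capture Q-value locally (a documented
#' simplification).
#'
#' @param energy Neutron kinetic energy at capture, eV.
#' @param element Chemical symbol of the capturing element.
#' @return list with `photons` (data.frame E_eV, ux, uy, uz) and
#'   `local_deposit_eV`.
#' @export
capture_secondaries <- function(energy, element) {
  xs <- load_xs()$capture
  row <- xs[xs$symbol == element, ]
  if (!nrow(row)) stop("no capture data for element ", element)
  if (row$E_gamma_MeV > 0) {
    mu <- runif(1, -1, 1); phi <- runif(1, 0, 2 * pi)
    s <- sqrt(1 - mu^2)
    list(photons = data.frame(E_eV = row$E_gamma_MeV * 1e6,
                              ux = s * cos(phi), uy = s * sin(phi), uz = mu),
         local_deposit_eV = energy)
  } else {
    list(photons = data.frame(E_eV = numeric(0), ux = numeric(0),
                              uy = numeric(0), uz = numeric(0)),
         local_deposit_eV = energy + row$Q_MeV * 1e6)
  }
}

#' Sample Compton scattering (Klein-Nishina)
#'
#' @param energy Incident photon energy, MeV.
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @return data.frame with `E_out` (MeV), `T_electron` (MeV), `cos_theta`.
#' @export
compton_sample <- function(energy, n = 1, seed = NULL) {
  stopifnot(energy > 0)
  if (is.null(seed)) seed <- rng_seed_from_R()
  m <- cpp_sample_compton(energy * 1e6, as.integer(n), seed)
  data.frame(E_out = m[, 1] / 1e6, T_electron = m[, 2] / 1e6, cos_theta = m[, 3])
}

#' Total Klein-Nishina cross section per electron
#' @param energy Photon energy, MeV.
#' @return Cross section in barns.
#' @export
klein_nishina_total <- function(energy) {
  cpp_kn_total(energy * 1e6) / 1e-24
}
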