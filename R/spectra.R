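# Source spectra: binned fluence-rate representation, inverse-CDF sampling,
# rectangular parallel beam, synthetic reactor-beam spectrum generator.

#' Default fluence-tally energy binning
#'
#' 58 log-spaced bins between 1e-3 eV and 20 MeV (the tally gives the bin
#' count; the edges are this engine's choice).
#'
#' @param n Number of bins.
#' @param emin,emax Range in eV.
#' @return Numeric vector of n + 1 bin edges, eV.
#' @export
fluence_bins <- function(n = 58, emin = 1e-3, emax = 2e7) {
  exp(seq(log(emin), log(emax), length.out = n + 1))
}

#' Construct a binned energy spectrum
#'
#' @param edges Bin edges in eV, strictly increasing, length nbins + 1.
#' @param rate Fluence rate per bin, cm^-2 s^-1, non-negative.
#' @param particle "neutron" or "photon".
#' @return An `energy_spectrum` object.
#' @export
energy_spectrum <- function(edges, rate, particle = c("neutron", "photon")) {
  particle <- match.arg(particle)
  stopifnot(length(edges) == length(rate) + 1)
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  if (any(rate < 0)) stop("per-bin rates must be >= 0")
  structure(list(edges = as.numeric(edges), rate = as.numeric(rate),
                 particle = particle, total_rate = sum(rate)),
            class = "energy_spectrum")
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("<energy_spectrum: %s>  %d bins, %.4g - %.4g eV, total %.4g cm^-2 s^-1\n",
              x$particle, length(x$rate), min(x$edges), max(x$edges), x$total_rate))
  invisible(x)
}

#' @export
plot.energy_spectrum <- function(x, ...) {
  mid <- sqrt(head(x$edges, -1) * tail(x$edges, -1))
  wid <- diff(x$edges)
  plot(mid, x$rate / wid, log = "xy", type = "s",
       xlab = "energy (eV)", ylab = "fluence rate density (cm^-2 s^-1 eV^-1)",
       main = paste(x$particle, "spectrum"), ...)
  invisible(x)
}

#' Build the inverse-CDF sampling table of a spectrum
#'
#' Integrates and normalises the binned spectrum; the cumulative probabilities
#' end exactly at 1. Within-bin sampling is uniform in energy by default
#' (log-uniform available at sampling time for wide thermal bins).
#'
#' @param spectrum An `energy_spectrum`.
#' @return list with `edges` and `cum` (cumulative probability per bin).
#' @export
build_cdf <- function(spectrum) {
  if (spectrum$total_rate <= 0) stop("spectrum has zero total fluence rate")
  cum <- cumsum(spectrum$rate) / sum(spectrum$rate)
  cum[length(cum)] <- 1
  list(edges = spectrum$edges, cum = cum)
}

#' Rectangular parallel beam
#'
#' Uniform rectangular profile (no decrease towards the edges), directed along
#' the +x axis; beam divergence and penumbra are not modelled.
#'
#' @param width,height Beam cross section, cm (width along y, height along z).
#' @param center Position of the beam centre at the source plane, cm (x, y, z).
#' @return A `beam_config` object; `area_cm2` is the aperture area.
#' @export
beam_config <- function(width, height, center = c(0, 0, 0)) {
  stopifnot(width > 0, height > 0, length(center) == 3)
  structure(list(width = width, height = height, center = as.numeric(center),
                 axis = c(1, 0, 0), area_cm2 = width * height),
            class = "beam_config")
}

#' Sample primary particle states from a beam
#'
#' Position uniform over the rectangular aperture, direction exactly the beam
#' axis, energy by inverse CDF. Uses R's RNG.
#'
#' @param beam A `beam_config`.
#' @param cdf From [build_cdf()].
#' @param n Number of primaries.
#' @param particle Particle kind label carried through.
#' @param log_in_bin Sample log-uniformly within a bin instead of uniformly.
#' @return data.frame of particle states with weight 1.
#' @export
sample_primary <- function(beam, cdf, n = 1, particle = "neutron",
                           log_in_bin = FALSE) {
  u <- runif(n)
  b <- findInterval(u, c(0, cdf$cum), rightmost.closed = TRUE)
  b <- pmin(b, length(cdf$cum))
  lo <- cdf$edges[b]; hi <- cdf$edges[b + 1]
  uu <- runif(n)
  E <- if (log_in_bin) lo * (hi / lo)^uu else lo + uu * (hi - lo)
  data.frame(kind = particle,
             x = rep(beam$center[1], n),
             y = beam$center[2] + (runif(n) - 0.5) * beam$width,
             z = beam$center[3] + (runif(n) - 0.5) * beam$height,
             ux = 1, uy = 0, uz = 0, energy = E, weight = 1)
}

watt_density <- function(E_MeV, a = 0.988, b = 2.249) {
  exp(-E_MeV / a) * sinh(sqrt(b * E_MeV))
}

#' Synthetic reactor therapy-beam spectrum
#'
#' A stand-in for the (unpublished) measured converter-plate beam spectrum.
#' Neutrons: a Watt fission shape (a = 0.988 MeV, b = 2.249 MeV^-1) carrying
#' 95% of the fluence plus a 300 K thermal Maxwellian tail carrying 5%, binned
#' onto the 58 fluence-tally bins. Photons: a broad fission-gamma-like shape,
#' exp(-E/1.5 MeV) with a soft roll-off below ~0.2 MeV, spanning 0.1-8 MeV.
#' Absolute depth-dose magnitudes obtained with these spectra are therefore
#' stand-ins as well.
#'
#' @param particle "neutron" or "photon".
#' @param total_rate Total fluence rate to normalise to, cm^-2 s^-1
#'   (the study values are 3.2e8 for neutrons, 2.9e8 for photons).
#' @param thermal_fraction Fluence fraction in the thermal tail (neutrons).
#' @return An `energy_spectrum`.
#' @export
synthetic_medapp_spectrum <- function(particle = c("neutron", "photon"),
                                      total_rate = 3.2e8,
                                      thermal_fraction = 0.05) {
  particle <- match.arg(particle)
  stopifnot(total_rate > 0)
  bin_integral <- function(edges, dens) {
    # trapezoid on a log-spaced refinement of each bin
    vapply(seq_len(length(edges) - 1), function(i) {
      x <- exp(seq(log(edges[i]), log(edges[i + 1]), length.out = 33))
      y <- dens(x)
      sum((y[-1] + y[-length(x)]) / 2 * diff(x))
    }, numeric(1))
  }
  if (particle == "neutron") {
    edges <- fluence_bins()
    watt <- bin_integral(edges, function(E) watt_density(E / 1e6) / 1e6)
    kT <- .KT_300K_EV
    maxw <- bin_integral(edges, function(E) E / kT^2 * exp(-E / kT))
    rate <- (1 - thermal_fraction) * watt / sum(watt) +
      thermal_fraction * maxw / sum(maxw)
  } else {
    edges <- exp(seq(log(1e5), log(8e6), length.out = 59))
    rate <- bin_integral(edges, function(E)
      exp(-E / 1.5e6) * (1 - exp(-E / 2e5)))
  }
  energy_spectrum(edges, rate / sum(rate) * total_rate, particle)
}

#' Write a spectrum to a plain-text file
#'
#' Format: header lines `# particle: <kind>` and `# total_rate_cm2s: <rate>`,
#' then one `E_low E_high rate` row per bin.
#'
#' @param spectrum An `energy_spectrum`.
#' @param file Output path.
#' @export
write_spectrum <- function(spectrum, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste("# particle:", spectrum$particle),
               paste("# total_rate_cm2s:", format(spectrum$total_rate, digits = 15))),
             con)
  nb <- length(spectrum$rate)
  write.table(data.frame(format(spectrum$edges[-(nb + 1)], digits = 15),
                         format(spectrum$edges[-1], digits = 15),
                         format(spectrum$rate, digits = 15)),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a spectrum file
#' @param file Path to a spectrum file written by [write_spectrum()].
#' @return An `energy_spectrum`.
#' @export
read_spectrum <- function(file) {
  if (!file.exists(file)) stop("spectrum file not found: ", file)
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  particle <- sub(".*particle:\\s*", "", hdr[grepl("particle:", hdr)])
  body <- read.table(text = lines[!grepl("^#", lines)])
  edges <- c(body[[1]], body[nrow(body), 2])
  if (any(abs(body[[2]][-nrow(body)] - body[[1]][-1]) >
          1e-9 * abs(body[[2]][-nrow(body)])))
    stop("spectrum bins are not contiguous")
  energy_spectrum(edges, body[[3]], particle)
}
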