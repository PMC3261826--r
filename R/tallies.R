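# Dose and fluence tally reduction.
#
# Accumulation is history-by-history: per region and particle channel the
# kernel returns Sum(x) and Sum(x^2) of the *per-history* deposited energy,
# which keeps the statistics of correlated secondaries correct. The standard
# error of the mean is s = sqrt((Sum(x^2)/n - xbar^2)/(n-1)).

hist_mean_se <- function(sum, ssq, n) {
  xbar <- sum / n
  v <- pmax(ssq / n - xbar^2, 0) / (n - 1)
  list(mean = xbar, se = sqrt(v))
}

#' Reduce a dose tally to dose per primary fluence
#'
#' Converts per-history deposited energy to absorbed dose (Gy) per history and
#' to dose per unit primary planar fluence (Gy cm^2: the per-history dose
#' divided by the planar fluence of one primary, 1/beam area), with the
#' one-standard-deviation history-by-history error.
#'
#' @param run An `mc_run` (or its `dose_tally`).
#' @param by "total" for total dose, "channel" for the per-particle-type
#'   split (proton / neutron / electron), "lineage" for grouping by primary
#'   lineage (for a single-kind run the lineage dose equals the total and is
#'   labelled with the primary kind).
#' @param regions Optional integer vector of region indices to report
#'   (1-based). Selecting a zero-mass region is an error; by default,
#'   zero-mass (vacuum) regions report NA.
#' @return data.frame with region, channel, mass_g, dose_Gy, se_Gy,
#'   dose_per_fluence, se_per_fluence (+ depth_cm for chamber tallies).
#' @export
finalize_dose <- function(run, by = c("total", "channel", "lineage"),
                          regions = NULL) {
  by <- match.arg(by)
  t <- if (inherits(run, "mc_run")) run$tally else run
  if (t$n < 2) stop("need at least 2 histories for an error estimate")
  sel <- if (is.null(regions)) seq_along(t$sum_tot) else as.integer(regions)
  mass <- t$mass_g[sel]
  if (!is.null(regions) && any(mass <= 0))
    stop("selected region(s) have zero mass: ",
         paste(head(sel[mass <= 0], 5), collapse = ", "))
  ev_to_gy <- .EV_TO_J * 1e3 / pmax(mass, .Machine$double.xmin)  # eV -> Gy
  ev_to_gy[mass <= 0] <- NA_real_
  A <- t$beam_area_cm2

  one <- function(sum, ssq, label) {
    ms <- hist_mean_se(sum[sel], ssq[sel], t$n)
    out <- data.frame(region = sel, channel = label,
                      mass_g = mass,
                      dose_Gy = ms$mean * ev_to_gy,
                      se_Gy = ms$se * ev_to_gy)
    out$dose_per_fluence <- out$dose_Gy * A
    out$se_per_fluence <- out$se_Gy * A
    out
  }
  res <- switch(by,
    total = one(t$sum_tot, t$ssq_tot, "total"),
    lineage = one(t$sum_tot, t$ssq_tot,
                  paste0(t$kind, "_lineage")),
    channel = {
      if (is.null(t$sum_ch))
        stop("run was not configured with score_channels = TRUE")
      do.call(rbind, lapply(colnames(t$sum_ch), function(ch)
        one(t$sum_ch[, ch], t$ssq_ch[, ch], ch)))
    })
  if (!is.null(t$depths)) res$depth_cm <- t$depths[res$region]
  res
}

#' Reduce the cell-fluence tally
#'
#' Track-length estimate: fluence per primary = accumulated track length /
#' (region volume x histories), per energy bin, with history-by-history error.
#'
#' @param run An `mc_run` with a fluence tally.
#' @return data.frame region, bin, E_lo_eV, E_hi_eV, fluence_per_primary,
#'   se (both cm^-2).
#' @export
finalize_fluence <- function(run) {
  fl <- run$fluence
  if (is.null(fl)) stop("run has no fluence tally")
  if (fl$n < 2) stop("need at least 2 histories")
  nb <- ncol(fl$sum)
  nreg <- nrow(fl$sum)
  if (any(fl$volume_cm3 <= 0)) stop("zero-volume scoring region")
  ms <- hist_mean_se(fl$sum, fl$ssq, fl$n)
  data.frame(region = rep(seq_len(nreg), nb),
             bin = rep(seq_len(nb), each = nreg),
             E_lo_eV = rep(fl$edges[-(nb + 1)], each = nreg),
             E_hi_eV = rep(fl$edges[-1], each = nreg),
             fluence_per_primary = as.vector(ms$mean) / fl$volume_cm3,
             se = as.vector(ms$se) / fl$volume_cm3)
}

#' Dose per fluence to dose rate
#' @param dose_per_fluence Gy cm^2.
#' @param fluence_rate Primary fluence rate, cm^-2 s^-1.
#' @return Dose rate, Gy/s.
#' @export
to_dose_rate <- function(dose_per_fluence, fluence_rate) {
  stopifnot(all(dose_per_fluence >= 0, na.rm = TRUE), fluence_rate >= 0)
  dose_per_fluence * fluence_rate
}

#' Dose rate to absorbed dose for an irradiation time
#' @param dose_rate Gy/s.
#' @param seconds Irradiation time, s.
#' @return Absorbed dose, Gy.
#' @export
to_absolute <- function(dose_rate, seconds) {
  stopifnot(all(dose_rate >= 0, na.rm = TRUE), seconds >= 0)
  dose_rate * seconds
}

#' Per-voxel dose grid from a run
#'
#' @param run An `mc_run` on a voxel geometry.
#' @param channel "total" or one of the particle channels.
#' @param statistic "dose" or "se".
#' @param value "per_fluence" (Gy cm^2) or "per_history" (Gy).
#' @return Numeric array of dim = grid shape; NA in zero-mass (vacuum) voxels.
#' @export
dose_grid <- function(run, channel = "total",
                      statistic = c("dose", "se"),
                      value = c("per_fluence", "per_history")) {
  statistic <- match.arg(statistic); value <- match.arg(value)
  t <- run$tally
  if (t$region != "voxel") stop("dose_grid needs a voxel-geometry run")
  if (channel == "total") {
    s <- t$sum_tot; q <- t$ssq_tot
  } else {
    if (is.null(t$sum_ch)) stop("run was not configured with score_channels = TRUE")
    if (!channel %in% colnames(t$sum_ch)) stop("unknown channel: ", channel)
    s <- t$sum_ch[, channel]; q <- t$ssq_ch[, channel]
  }
  ms <- hist_mean_se(s, q, t$n)
  conv <- .EV_TO_J * 1e3 / pmax(t$mass_g, .Machine$double.xmin)
  conv[t$mass_g <= 0] <- NA_real_
  if (value == "per_fluence") conv <- conv * t$beam_area_cm2
  array((if (statistic == "dose") ms$mean else ms$se) * conv, dim = t$dim)
}

#' Pool voxel doses over a small block around the beam axis
#'
#' At every depth (x index) the dose is pooled mass-weighted over a block of
#' `n_lateral` voxels in y times `n_vertical` voxels in z centred on
#' `center` (the defaults pool 8 voxels: for 0.2 x 0.2 x 0.5 cm^3 voxels a
#' collection volume of 0.16 cm^3). Pooled errors combine the per-voxel
#' standard errors in quadrature, treating voxels as independent.
#'
#' @param run An `mc_run` on a voxel geometry.
#' @param center Physical (y, z) of the beam axis, cm.
#' @param n_lateral,n_vertical Block size in voxels (y, z).
#' @param channel Dose channel.
#' @return data.frame depth_cm (voxel-centre x), dose_per_fluence, se,
#'   volume_cm3.
#' @export
aggregate_voxels <- function(run, center = c(0, 0), n_lateral = 4,
                             n_vertical = 2, channel = "total") {
  t <- run$tally
  if (t$region != "voxel") stop("aggregate_voxels needs a voxel-geometry run")
  dim <- t$dim; vs <- t$voxel_size; org <- t$origin
  if (n_lateral > dim[2] || n_vertical > dim[3])
    stop("aggregation block exceeds the grid")
  cy <- org[2] + (seq_len(dim[2]) - 0.5) * vs[2]
  cz <- org[3] + (seq_len(dim[3]) - 0.5) * vs[3]
  iy <- order(abs(cy - center[1]))[seq_len(n_lateral)]
  iz <- order(abs(cz - center[2]))[seq_len(n_vertical)]
  if (length(iy) < n_lateral || length(iz) < n_vertical)
    stop("aggregation block exceeds the grid")
  D <- dose_grid(run, channel = channel, statistic = "dose")
  S <- dose_grid(run, channel = channel, statistic = "se")
  M <- array(t$mass_g, dim = dim)
  nx <- dim[1]
  out <- data.frame(depth_cm = org[1] + (seq_len(nx) - 0.5) * vs[1],
                    dose_per_fluence = NA_real_, se = NA_real_,
                    volume_cm3 = n_lateral * n_vertical * prod(vs))
  for (ix in seq_len(nx)) {
    m <- M[ix, iy, iz]; d <- D[ix, iy, iz]; s <- S[ix, iy, iz]
    if (all(m > 0)) {
      out$dose_per_fluence[ix] <- sum(m * d) / sum(m)
      out$se[ix] <- sqrt(sum((m * s)^2)) / sum(m)
    }
  }
  out
}
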