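# Planning outputs: depth-dose curves, lateral profiles, cumulative DVHs,
# RBE weighting, photon-fluence renormalisation, isodose contours and the
# treatment-room (wall) influence comparison.

#' Depth-dose curve along the beam axis
#'
#' For a chamber-array (solid box) run: the chamber doses ordered by depth.
#' For a voxel run: voxel doses pooled over a small block around the beam
#' axis at every depth (see [aggregate_voxels()]).
#'
#' @param run An `mc_run`.
#' @param channel Dose channel ("total", "proton", ...).
#' @param center Beam-axis (y, z) for the voxel variant, cm.
#' @param n_lateral,n_vertical Pooling block for the voxel variant.
#' @return A `depth_dose` data.frame: depth_cm, dose_per_fluence (Gy cm^2),
#'   se.
#' @export
depth_dose <- function(run, channel = "total", center = c(0, 0),
                       n_lateral = 4, n_vertical = 2) {
  t <- run$tally
  if (t$region == "chamber") {
    by <- if (channel == "total") "total" else "channel"
    d <- finalize_dose(run, by = by)
    if (channel != "total") d <- d[d$channel == channel, ]
    out <- data.frame(depth_cm = d$depth_cm,
                      dose_per_fluence = d$dose_per_fluence, se = d$se_per_fluence)
  } else {
    a <- aggregate_voxels(run, center = center, n_lateral = n_lateral,
                          n_vertical = n_vertical, channel = channel)
    out <- data.frame(depth_cm = a$depth_cm,
                      dose_per_fluence = a$dose_per_fluence, se = a$se)
  }
  out <- out[order(out$depth_cm), ]
  if (!nrow(out)) stop("empty depth-dose selection")
  rownames(out) <- NULL
  class(out) <- c("depth_dose", "data.frame")
  out
}

#' Scale a depth-dose curve to absolute dose rate or dose
#' @param dd A `depth_dose` (dose per fluence, Gy cm^2).
#' @param fluence_rate Primary fluence rate, cm^-2 s^-1.
#' @param seconds Irradiation time; if given, returns absorbed dose in Gy,
#'   otherwise dose rate in Gy/s.
#' @return A data.frame with `dose` and `se` rescaled.
#' @export
scale_depth_dose <- function(dd, fluence_rate, seconds = NULL) {
  f <- fluence_rate * (if (is.null(seconds)) 1 else seconds)
  data.frame(depth_cm = dd$depth_cm, dose = dd$dose_per_fluence * f,
             se = dd$se * f)
}

#' @export
plot.depth_dose <- function(x, ...) {
  plot(x$depth_cm, x$dose_per_fluence, type = "b", pch = 16,
       xlab = "depth (cm)", ylab = "dose per fluence (Gy cm^2)", log = "y", ...)
  arr_up <- x$dose_per_fluence + x$se
  arr_dn <- pmax(x$dose_per_fluence - x$se, .Machine$double.xmin)
  suppressWarnings(graphics::arrows(x$depth_cm, arr_dn, x$depth_cm, arr_up,
                                    angle = 90, code = 3, length = 0.02))
  invisible(x)
}

#' Lateral dose profile at fixed depth and slice
#'
#' Extracts the dose along a row (y) of a voxel grid at a given x column and
#' z slice, with statistical errors.
#'
#' @param run An `mc_run` on a voxel geometry.
#' @param x_index Column index (1-based, depth direction).
#' @param z_index Slice index (1-based, vertical).
#' @param channel Dose channel.
#' @return data.frame y_index, y_cm, dose_per_fluence, se.
#' @export
lateral_profile <- function(run, x_index, z_index, channel = "total") {
  t <- run$tally
  if (t$region != "voxel") stop("lateral_profile needs a voxel-geometry run")
  dim <- t$dim
  if (x_index < 1 || x_index > dim[1]) stop("x_index out of range")
  if (z_index < 1 || z_index > dim[3]) stop("z_index out of range")
  D <- dose_grid(run, channel = channel, statistic = "dose")
  S <- dose_grid(run, channel = channel, statistic = "se")
  data.frame(y_index = seq_len(dim[2]),
             y_cm = t$origin[2] + (seq_len(dim[2]) - 0.5) * t$voxel_size[2],
             dose_per_fluence = D[x_index, , z_index],
             se = S[x_index, , z_index])
}

#' Relative edge decrease between two rows of a lateral profile
#'
#' 100 * (D(y_in) - D(y_out)) / D(y_in): how much the dose drops from a row
#' inside the beam to a row outside it.
#'
#' @param profile data.frame from [lateral_profile()].
#' @param y_in,y_out Row indices inside / outside the field edge.
#' @return Percent decrease.
#' @export
edge_decrease <- function(profile, y_in, y_out) {
  din <- profile$dose_per_fluence[match(y_in, profile$y_index)]
  dout <- profile$dose_per_fluence[match(y_out, profile$y_index)]
  100 * (din - dout) / din
}

#' Cumulative dose-volume histogram
#'
#' V(D): the fraction of the organ's volume receiving at least dose D.
#' Voxels are assumed equal-volume (uniform grid).
#'
#' @param dose Numeric array/vector of voxel doses (Gy).
#' @param mask Logical mask or integer voxel indices selecting the organ.
#' @param bin_width Dose bin width; default max dose / 200.
#' @return A `dvh_curve` data.frame: dose, volume_fraction, starting at
#'   V(0) = 1 and reaching 0 beyond the maximum dose.
#' @export
cumulative_dvh <- function(dose, mask, bin_width = NULL) {
  d <- dose[mask]
  if (!length(d)) stop("empty organ mask")
  if (anyNA(d)) stop("mask selects voxels with undefined dose")
  dmax <- max(d)
  if (is.null(bin_width)) bin_width <- if (dmax > 0) dmax / 200 else 1
  edges <- seq(0, dmax + bin_width, by = bin_width)
  vf <- vapply(edges, function(x) mean(d >= x), numeric(1))
  vf[1] <- 1
  structure(data.frame(dose = edges, volume_fraction = vf),
            class = c("dvh_curve", "data.frame"),
            n_voxels = length(d), mean_dose = mean(d))
}

#' @export
plot.dvh_curve <- function(x, ...) {
  plot(x$dose, 100 * x$volume_fraction, type = "s", ylim = c(0, 100),
       xlab = "dose (Gy)", ylab = "volume (%)", ...)
  invisible(x)
}

#' Apply RBE weights to per-lineage dose components
#'
#' Weighted dose = sum over tags of w_tag * D_tag. The clinical choice here is
#' a factor 3 for the neutron lineage (neutrons and all their secondaries,
#' applied after the Monte Carlo calculation) and 1 for primary photons.
#'
#' @param components Named list of dose arrays (same shape), one per lineage
#'   tag.
#' @param weights Named numeric weights (> 0); names must be present in
#'   `components`.
#' @return Weighted dose array.
#' @export
apply_rbe <- function(components, weights = c(neutron_lineage = 3,
                                              photon_lineage = 1)) {
  if (any(weights <= 0)) stop("RBE weights must be positive")
  missing <- setdiff(names(weights), names(components))
  if (length(missing)) stop("missing dose component(s): ",
                            paste(missing, collapse = ", "))
  out <- 0
  for (tag in names(weights)) out <- out + weights[[tag]] * components[[tag]]
  out
}

#' Least-squares renormalisation of the primary-photon curve
#'
#' Finds the scale s minimising sum over the depth window of
#' (s * primary + secondary - reference)^2; closed form
#' s = sum(P (R - S)) / sum(P^2). Used to renormalise a primary photon
#' fluence rate so that primary + secondary photon depth-dose matches a
#' reference in the first centimeters.
#'
#' @param primary,secondary,reference Dose values on a common depth grid.
#' @param depth_cm Depths of the curves.
#' @param window Depth window (cm) used for the fit.
#' @return The scale factor s.
#' @export
renormalize_photons <- function(primary, secondary, reference, depth_cm,
                                window = c(0, 10)) {
  sel <- depth_cm >= window[1] & depth_cm <= window[2]
  if (!any(sel)) stop("empty depth window")
  P <- primary[sel]; S <- secondary[sel]; R <- reference[sel]
  if (all(P == 0)) stop("primary curve is zero everywhere in the window")
  sum(P * (R - S)) / sum(P * P)
}

#' Isodose contours of a dose slice
#'
#' Upsamples the slice with separable cubic splines (factor `upsample`), then
#' extracts level contours with marching squares. Levels are percentages of
#' the prescribed dose.
#'
#' @param slice Dose matrix (e.g. one z-slice of a dose grid).
#' @param x,y Coordinates of the rows/columns of `slice`; defaults to indices.
#' @param prescribed Prescribed dose (> 0), same units as `slice`.
#' @param levels Percent levels relative to the prescribed dose.
#' @param upsample Spline upsampling factor.
#' @return List per level: list(level_percent, dose, contours = list of
#'   data.frames x, y). Levels outside the data range get empty contour sets.
#' @export
isodose_contours <- function(slice, x = NULL, y = NULL, prescribed,
                             levels = c(10, 30, 50, 70, 90, 95),
                             upsample = 4) {
  if (!is.matrix(slice) || nrow(slice) < 2 || ncol(slice) < 2)
    stop("slice must be at least a 2 x 2 matrix")
  if (prescribed <= 0) stop("prescribed dose must be positive")
  if (is.null(x)) x <- seq_len(nrow(slice))
  if (is.null(y)) y <- seq_len(ncol(slice))
  slice[is.na(slice)] <- 0
  xf <- seq(min(x), max(x), length.out = (nrow(slice) - 1) * upsample + 1)
  yf <- seq(min(y), max(y), length.out = (ncol(slice) - 1) * upsample + 1)
  tmp <- matrix(0, length(xf), ncol(slice))
  for (j in seq_len(ncol(slice)))
    tmp[, j] <- spline(x, slice[, j], xout = xf)$y
  fine <- matrix(0, length(xf), length(yf))
  for (i in seq_len(length(xf)))
    fine[i, ] <- spline(y, tmp[i, ], xout = yf)$y
  lapply(levels, function(lv) {
    dose <- lv / 100 * prescribed
    cl <- suppressWarnings(contourLines(xf, yf, fine, levels = dose))
    list(level_percent = lv, dose = dose,
         contours = lapply(cl, function(p) data.frame(x = p$x, y = p$y)))
  })
}

#' Relative influence of the treatment-room walls
#'
#' Per-depth relative difference |D_room - D_free| / D_free between two
#' depth-dose curves, with the combined statistical error of the difference
#' (quadrature; an overestimate when the runs are seed-correlated).
#'
#' @param with_room,without `depth_dose` curves on a common depth grid.
#' @return data.frame depth_cm, rel_diff, se (both as fractions).
#' @export
wall_influence <- function(with_room, without) {
  if (!isTRUE(all.equal(with_room$depth_cm, without$depth_cm)))
    stop("curves are not on a common depth grid")
  if (any(without$dose_per_fluence <= 0))
    stop("zero free-field dose at some depth")
  rel <- abs(with_room$dose_per_fluence - without$dose_per_fluence) /
    without$dose_per_fluence
  se <- sqrt(with_room$se^2 + without$se^2) / without$dose_per_fluence
  data.frame(depth_cm = with_room$depth_cm, rel_diff = rel, se = se)
}

#' Room-influence study on the solid-box water phantom
#'
#' Runs the phantom inside the treatment room with concrete walls and with the
#' walls removed (vacuum walls, identical air cavity), using the same seed.
#' With one RNG stream per history the two runs are identical except for
#' particles returned by the walls, so the difference isolates the
#' wall-scattered dose component (correlated sampling).
#'
#' @param beam,spectrum,config As for [run_simulation()].
#' @param room A `room_shell`.
#' @param max_depth Report the maximum relative difference up to this depth.
#' @return list(table, max_rel_diff_percent, runs).
#' @export
room_influence_study <- function(beam, spectrum, config, room = room_shell(),
                                 max_depth = 10) {
  room_off <- room; room_off$material_id <- 0L
  ph_free <- solid_box_phantom(room = room_off)
  ph_room <- solid_box_phantom(room = room)
  r_free <- run_simulation(ph_free, beam, spectrum, config)
  r_room <- run_simulation(ph_room, beam, spectrum, config)
  dd_room <- depth_dose(r_room); dd_free <- depth_dose(r_free)
  sel <- dd_free$depth_cm <= max_depth
  tab <- wall_influence(dd_room[sel, ], dd_free[sel, ])
  list(table = tab,
       max_rel_diff_percent = 100 * max(tab$rel_diff),
       runs = list(with_room = r_room, without = r_free))
}
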