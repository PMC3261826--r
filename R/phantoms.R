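# Phantom and room geometry.
#
# Coordinate convention: continuous cm, origin at the centre of the beam-entry
# face of the water (x = 0 at the inner surface of the front wall), beam along
# +x. Voxel indices are 0-based in the kernel, 1-based at the R surface; voxel
# i covers the half-open interval [origin + i*d, origin + (i+1)*d).

#' Depths of the measurement-chamber array
#'
#' Arithmetic sequence of chamber depths: first chamber at `first` cm in
#' water, one every `pitch` cm.
#'
#' @param first Depth of the first chamber, cm.
#' @param pitch Spacing, cm (> 0).
#' @param count Number of chambers (>= 1).
#' @return Numeric vector of depths, cm.
#' @export
chamber_depths <- function(first = 0.5, pitch = 1.0, count = 40) {
  stopifnot(count >= 1)
  if (pitch <= 0) stop("pitch must be positive")
  first + (seq_len(count) - 1) * pitch
}

#' Volume of a tube-shaped chamber
#' @param radius,height Chamber radius and height, cm.
#' @return Volume pi r^2 h, cm^3.
#' @export
chamber_volume <- function(radius = 0.38, height = 1.21) {
  stopifnot(radius >= 0, height >= 0)
  pi * radius^2 * height
}

#' Schematic concrete treatment-room shell
#'
#' Six concrete slabs around an air cavity, with a beam window through the
#' entry wall. Wall thickness 83 cm (50 cm for the wall the beam exits the
#' reactor through), beam window 20 x 30 cm^2, floor/ceiling 145 cm from the
#' beam axis. Lateral distances are schematic.
#'
#' @param wall Thickness of the regular walls, cm.
#' @param exit_wall Thickness of the beam entry/exit wall, cm.
#' @param window Beam window width (y) and height (z), cm.
#' @param floor_dist Distance from beam axis to floor and ceiling, cm.
#' @param upstream Distance from the phantom front face to the entry wall, cm.
#' @param downstream Distance behind the phantom to the far wall, cm.
#' @param lateral Distance from the beam axis to the side walls, cm.
#' @param material_id Wall material (default 4 = concrete). Setting it to 0
#'   (vacuum) keeps the room's air cavity but removes the walls, which gives a
#'   "walls removed" reference run whose histories stay correlated with the
#'   concrete run.
#' @return A `room_shell` object.
#' @export
room_shell <- function(wall = 83, exit_wall = 50, window = c(20, 30),
                       floor_dist = 145, upstream = 101, downstream = 150,
                       lateral = 200, material_id = 4L) {
  stopifnot(window[1] > 0, window[2] > 0)
  if (window[1] / 2 > lateral || window[2] / 2 > floor_dist)
    stop("beam window does not fit inside the exit wall")
  structure(list(wall = wall, exit_wall = exit_wall, window = window,
                 floor_dist = floor_dist, upstream = upstream,
                 downstream = downstream, lateral = lateral,
                 material_id = as.integer(material_id)),
            class = "room_shell")
}

#' Solid-box water phantom with chamber array
#'
#' A Perspex container (outer 63.5 x 63.5 x 52 cm^3, 2.0 cm walls) filled
#' with water, with a 12 x 34 cm^2 entrance window sealed by two 1.5 mm
#' aluminum plates, and an array of water-equivalent tube-shaped scoring
#' chambers along the beam axis (radius 0.38 cm, height 1.21 cm, first at
#' 0.5 cm depth, one per cm). The chambers are water like their surroundings,
#' so they score without disturbing transport.
#'
#' @param outer Outer box dimensions (x depth, y, z), cm.
#' @param wall Perspex wall thickness, cm.
#' @param window Entrance window width (y) and height (z), cm.
#' @param al_plates Number and thickness (cm) of aluminum window plates.
#' @param chambers list(first, pitch, count, radius, height).
#' @param room Optional `room_shell` (NULL = free field).
#' @return A `solid_phantom` object.
#' @export
solid_box_phantom <- function(outer = c(63.5, 63.5, 52), wall = 2.0,
                              window = c(34, 12),
                              al_plates = c(n = 2, thickness = 0.15),
                              chambers = list(first = 0.5, pitch = 1.0,
                                              count = 40, radius = 0.38,
                                              height = 1.21),
                              room = NULL) {
  inner <- outer - 2 * wall
  depths <- chamber_depths(chambers$first, chambers$pitch, chambers$count)
  if (max(depths) + chambers$radius > inner[1] ||
      chambers$height / 2 > inner[3] / 2)
    stop("chamber array does not fit inside the water volume")
  structure(list(outer = outer, wall = wall, inner = inner, window = window,
                 al_thickness = unname(al_plates["n"] * al_plates["thickness"]),
                 chambers = chambers, depths = depths, room = room),
            class = "solid_phantom")
}

#' @export
print.solid_phantom <- function(x, ...) {
  cat(sprintf("<solid_phantom> %g x %g x %g cm^3 Perspex box, %g cm walls, %d chambers at %g..%g cm%s\n",
              x$outer[1], x$outer[2], x$outer[3], x$wall,
              x$chambers$count, min(x$depths), max(x$depths),
              if (is.null(x$room)) "" else ", with room shell"))
  invisible(x)
}

new_voxel_phantom <- function(dim, voxel_size, origin, ids, organ_map = NULL,
                              rois = NULL) {
  stopifnot(length(ids) == prod(dim))
  structure(list(dim = as.integer(dim), voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin), ids = as.integer(ids),
                 organ_map = organ_map, rois = rois),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("<voxel_phantom> %d x %d x %d voxels of %g x %g x %g cm^3 (%.3g total)\n",
              x$dim[1], x$dim[2], x$dim[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], prod(x$dim)))
  if (!is.null(x$organ_map))
    cat("  ", nrow(x$organ_map), "organ ids ->",
        length(unique(x$organ_map$material_id)), "materials\n")
  if (!is.null(x$rois)) cat("  ROIs:", paste(names(x$rois), collapse = ", "), "\n")
  invisible(x)
}

#' Voxelise a homogeneous box
#'
#' @param extent Physical box extent (x, y, z), cm.
#' @param voxel Voxel size (x, y, z), cm; must divide the extent exactly.
#' @param material_id Material id to fill with (default 1 = water).
#' @param origin Position of the grid corner, cm; default centres the box on
#'   the beam axis with its front face at x = 0.
#' @return A `voxel_phantom` whose ids are material ids directly.
#' @export
voxelise_box <- function(extent, voxel, material_id = 1L, origin = NULL) {
  n <- extent / voxel
  if (any(abs(n - round(n)) > 1e-9))
    stop("voxel size does not divide the extent exactly (",
         paste(format(n), collapse = " x "), " voxels)")
  n <- as.integer(round(n))
  if (is.null(origin)) origin <- c(0, -extent[2] / 2, -extent[3] / 2)
  new_voxel_phantom(n, voxel, origin, rep(as.integer(material_id), prod(n)))
}

#' Voxelised water phantom matching the solid-box setup
#'
#' The container is voxelised together with the water: the box is enlarged to
#' 64 x 64 x 52 cm^3 so that 0.2 x 0.2 x 0.5 cm^3 voxels divide it exactly,
#' the 2 cm Perspex walls and the aluminum entrance window are painted into
#' the grid by voxel-centre membership, and the interior is water.
#'
#' @param extent Enlarged box extent, cm.
#' @param voxel Voxel size, cm.
#' @param wall Wall thickness, cm.
#' @param window Entrance window (y, z), cm.
#' @param al_thickness Total aluminum plate thickness, cm.
#' @return A `voxel_phantom` (material ids), front water face at x = 0.
#' @export
voxelised_water_phantom <- function(extent = c(64, 64, 52),
                                    voxel = c(0.2, 0.2, 0.5), wall = 2.0,
                                    window = c(34, 12), al_thickness = 0.3) {
  ph <- voxelise_box(extent, voxel, material_id = 1L,
                     origin = c(-wall, -extent[2] / 2, -extent[3] / 2))
  n <- ph$dim
  cx <- ph$origin[1] + (seq_len(n[1]) - 0.5) * voxel[1]
  cy <- ph$origin[2] + (seq_len(n[2]) - 0.5) * voxel[2]
  cz <- ph$origin[3] + (seq_len(n[3]) - 0.5) * voxel[3]
  inner <- extent - 2 * wall
  ids <- array(ph$ids, dim = n)
  in_wall <- outer(abs(cy) > inner[2] / 2, abs(cz) > inner[3] / 2, "|")
  for (i in seq_len(n[1])) {
    if (cx[i] < 0 || cx[i] > inner[1]) {
      sl <- matrix(2L, n[2], n[3])  # perspex
      if (cx[i] < 0) {
        win <- outer(abs(cy) <= window[1] / 2, abs(cz) <= window[2] / 2, "&")
        sl[win] <- if (cx[i] < -wall + al_thickness) 3L else 1L
      }
      ids[i, , ] <- sl
    } else {
      ids[i, , ][in_wall] <- 2L
    }
  }
  new_voxel_phantom(n, voxel, ph$origin, ids)
}

#' Write a voxel phantom to disk
#'
#' Grid file: three text header lines (shape; voxel size in mm; integer
#' width in bytes) followed by the raw little-endian unsigned integer grid,
#' x fastest. Organ map: text rows `organ_id material_id name`.
#'
#' @param phantom A `voxel_phantom`.
#' @param grid_file,map_file Output paths (map written only if the phantom
#'   has an organ map).
#' @export
write_voxel_phantom <- function(phantom, grid_file, map_file = NULL) {
  con <- file(grid_file, "wb")
  on.exit(close(con))
  bytes <- if (max(phantom$ids) > 65535L) 4L else 2L
  hdr <- c(paste(phantom$dim, collapse = " "),
           paste(format(phantom$voxel_size * 10, digits = 10), collapse = " "),
           as.character(bytes))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(phantom$ids, con, size = bytes, endian = "little")
  if (!is.null(phantom$organ_map) && !is.null(map_file))
    write.table(phantom$organ_map, map_file, row.names = FALSE, quote = FALSE)
  invisible(grid_file)
}

#' Load a voxel phantom from disk
#'
#' @param grid_file Grid file as written by [write_voxel_phantom()].
#' @param map_file Optional organ map; if given, every id in the grid must be
#'   present (unmapped ids are an error naming the id). Id 0 is the
#'   surrounding vacuum and needs no mapping.
#' @return A `voxel_phantom`.
#' @export
load_voxel_phantom <- function(grid_file, map_file = NULL) {
  if (!file.exists(grid_file)) stop("phantom grid file not found: ", grid_file)
  con <- file(grid_file, "rb")
  on.exit(close(con))
  hdr <- character(3)
  for (i in 1:3) {
    ch <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1)
      if (!length(b) || b == as.raw(10)) break
      ch <- c(ch, b)
    }
    hdr[i] <- rawToChar(ch)
  }
  dim <- as.integer(strsplit(hdr[1], " ")[[1]])
  vox_mm <- as.numeric(strsplit(hdr[2], " ")[[1]])
  bytes <- as.integer(hdr[3])
  ids <- readBin(con, "integer", prod(dim), size = bytes, signed = bytes == 4,
                 endian = "little")
  if (length(ids) != prod(dim))
    stop("grid payload has ", length(ids), " voxels, header says ", prod(dim))
  map <- NULL
  if (!is.null(map_file)) {
    map <- read.table(map_file, header = TRUE, stringsAsFactors = FALSE)
    missing <- setdiff(unique(ids), c(0L, map$organ_id))
    if (length(missing))
      stop("organ id(s) not in map: ", paste(missing, collapse = ", "))
  }
  new_voxel_phantom(dim, vox_mm / 10, c(0, -dim[2] * vox_mm[2] / 20,
                                        -dim[3] * vox_mm[3] / 20), ids, map)
}

#' Crop a voxel phantom to its top slices
#'
#' Keeps the `n_slices` highest-z slices (e.g. the head-and-neck upper quarter
#' of a whole-body phantom) and adjusts the origin.
#'
#' @param phantom A `voxel_phantom`.
#' @param n_slices Number of top slices to keep (1..nz).
#' @return A `voxel_phantom`.
#' @export
crop_upper <- function(phantom, n_slices) {
  nz <- phantom$dim[3]
  if (n_slices <= 0) stop("n_slices must be positive")
  if (n_slices > nz) stop("n_slices exceeds the grid (", nz, " slices)")
  a <- array(phantom$ids, dim = phantom$dim)
  keep <- (nz - n_slices + 1):nz
  new_voxel_phantom(c(phantom$dim[1:2], n_slices), phantom$voxel_size,
                    phantom$origin + c(0, 0, (nz - n_slices) * phantom$voxel_size[3]),
                    a[, , keep, drop = FALSE], phantom$organ_map, phantom$rois)
}

#' Resolve a phantom's organ ids to material ids
#' @param phantom A `voxel_phantom`.
#' @return Integer vector of material ids (0 = vacuum) per voxel.
#' @export
material_ids <- function(phantom) {
  if (is.null(phantom$organ_map)) return(phantom$ids)
  map <- phantom$organ_map
  lut <- integer(max(phantom$ids, map$organ_id) + 1L)
  lut[map$organ_id + 1L] <- as.integer(map$material_id)
  unmapped <- setdiff(unique(phantom$ids), c(0L, map$organ_id))
  if (length(unmapped))
    stop("organ id(s) not in map: ", paste(unmapped, collapse = ", "))
  lut[phantom$ids + 1L]
}

# ------------------------------------------------------------------------
# Synthetic anthropomorphic head phantom (stand-in for the unavailable
# reference female voxel phantom). Layered ellipsoidal head and neck with
# skin shell, subcutaneous adipose, muscle, cortical-bone skull and mandible,
# cervical spine with cord, air trachea, eyes, brain, and six salivary glands
# (right/left parotid, submandibular, sublingual) as labelled ROI masks.

head_organs <- data.frame(
  organ_id = c(101L, 102L, 103L, 104L, 105L, 106L, 107L, 108L, 109L,
               111L, 112L, 113L, 114L, 115L, 116L),
  material_id = c(19L, 28L, 21L, 13L, 11L, 14L, 38L, 5L, 18L,
                  22L, 22L, 22L, 22L, 22L, 22L),
  name = c("skin", "adipose", "muscle", "bone_cortical", "brain", "spongiosa",
           "spinal_cord", "trachea_air", "eye",
           "parotid_r", "parotid_l", "submandibular_r", "submandibular_l",
           "sublingual_r", "sublingual_l"),
  stringsAsFactors = FALSE)

#' Synthetic voxel head phantom with salivary-gland ROIs
#'
#' Deterministic under `seed` (the seed jitters gland centres by up to 2 mm to
#' emulate anatomical variability). Grid convention matches the engine:
#' x = columns increasing right to left of the phantom, y = rows front to
#' back, z = slices upward; the grid stores organ ids that the bundled organ
#' map projects onto the packaged tissue materials.
#'
#' @param seed Integer seed.
#' @param shape Grid shape (nx, ny, nz) in voxels.
#' @param voxel_size Voxel size, cm (default 1.775 x 1.775 x 4.84 mm).
#' @return A `voxel_phantom` with `organ_map` and `rois` (named list of voxel
#'   indices for the six salivary glands).
#' @export
synthetic_head_phantom <- function(seed = 1L,
                                   shape = c(112L, 136L, 87L),
                                   voxel_size = c(0.1775, 0.1775, 0.484)) {
  stopifnot(all(shape > 0))
  ext <- shape * voxel_size
  if (ext[1] < 16 || ext[2] < 18 || ext[3] < 34)
    stop("shape too small to fit the anatomical layers")
  set.seed(seed)
  jit <- function() runif(1, -0.2, 0.2)

  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  # voxel centre coordinates relative to the head axis
  cxv <- (seq_len(nx) - 0.5) * voxel_size[1] - ext[1] / 2
  cyv <- (seq_len(ny) - 0.5) * voxel_size[2] - ext[2] / 2
  czv <- (seq_len(nz) - 0.5) * voxel_size[3]
  X <- array(rep(cxv, times = ny * nz), dim = shape)
  Y <- array(rep(rep(cyv, each = nx), times = nz), dim = shape)
  Z <- array(rep(czv, each = nx * ny), dim = shape)

  zc_head <- ext[3] - 13         # head ellipsoid centre height
  in_ellip <- function(cx, cy, cz, a, b, c)
    ((X - cx) / a)^2 + ((Y - cy) / b)^2 + ((Z - cz) / c)^2 <= 1
  head_shrunk <- function(t) in_ellip(0, 0, zc_head, 8 - t, 10 - t, 11.5 - t)
  neck_shrunk <- function(t)
    (X / (5.5 - t))^2 + (Y / (6.5 - t))^2 <= 1 & Z <= zc_head

  # skin shell thicker than the largest voxel dimension so the outermost
  # occupied voxel along every grid line is skin
  body   <- head_shrunk(0) | neck_shrunk(0)
  fat    <- head_shrunk(0.6) | neck_shrunk(0.6)      # inside the skin shell
  muscle <- head_shrunk(1.2) | neck_shrunk(1.2)      # inside the adipose layer

  ids <- array(0L, dim = shape)
  ids[body] <- 101L                                   # skin
  ids[fat] <- 102L                                    # adipose
  ids[muscle] <- 103L                                 # muscle
  skull_out <- in_ellip(0, 0, zc_head, 6.6, 8.6, 10.1)
  skull_in  <- in_ellip(0, 0, zc_head, 5.9, 7.9, 9.4)
  ids[skull_out & muscle] <- 104L                     # cortical skull
  ids[skull_in] <- 105L                               # brain
  # mandible: bone bar low in the face
  ids[in_ellip(0, -6, zc_head - 9, 4.5, 2.2, 1.4) & muscle] <- 104L
  # cervical spine: cortical shell with spongiosa core and cord
  spine_r2 <- X^2 + (Y - 3.2)^2
  spine <- spine_r2 <= 1.4^2 & Z <= zc_head - 6
  ids[spine] <- 104L
  ids[spine & spine_r2 <= 0.9^2] <- 106L              # spongiosa
  ids[spine & spine_r2 <= 0.45^2] <- 107L             # spinal cord
  # trachea air column up the front of the neck
  ids[X^2 + (Y + 2.8)^2 <= 0.9^2 & Z <= zc_head - 8 & body] <- 108L
  # eyes
  for (s in c(-1, 1))
    ids[in_ellip(3.1 * s, -6.8, zc_head + 2.5, 1.15, 1.15, 1.15) & muscle] <- 109L

  glands <- list(
    parotid_r       = c(+4.6 + jit(), +0.5 + jit(), zc_head - 5.0, 1.0, 1.8, 2.2),
    parotid_l       = c(-4.6 + jit(), +0.5 + jit(), zc_head - 5.0, 1.0, 1.8, 2.2),
    submandibular_r = c(+2.4 + jit(), -2.6 + jit(), zc_head - 10.8, 1.4, 1.2, 1.5),
    submandibular_l = c(-2.4 + jit(), -2.6 + jit(), zc_head - 10.8, 1.4, 1.2, 1.5),
    sublingual_r    = c(+1.0 + jit(), -3.4 + jit(), zc_head - 9.6, 0.8, 0.8, 0.9),
    sublingual_l    = c(-1.0 + jit(), -3.4 + jit(), zc_head - 9.6, 0.8, 0.8, 0.9))
  gland_ids <- c(111L, 112L, 113L, 114L, 115L, 116L)
  rois <- list()
  taken <- array(FALSE, dim = shape)   # keep gland masks pairwise disjoint
  for (i in seq_along(glands)) {
    g <- glands[[i]]
    m <- in_ellip(g[1], g[2], g[3], g[4], g[5], g[6]) & muscle & !taken
    taken <- taken | m
    ids[m] <- gland_ids[i]
    rois[[names(glands)[i]]] <- which(m)
  }
  if (any(vapply(rois, length, integer(1)) == 0))
    stop("shape too small: a salivary gland mask is empty")
  # close the neck's inferior cut plane with skin so every grid line starts
  # and ends on the skin shell
  ids[body & Z <= 0.6] <- 101L

  origin <- c(0, -ext[2] / 2, 0)
  new_voxel_phantom(shape, voxel_size, origin, ids, head_organs, rois)
}
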