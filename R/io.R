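# File formats, run manifests, configuration and the command-line interface.

fnv1a <- function(s) {
  # tiny polynomial content hash for provenance stamping (not cryptographic)
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", h)
}

config_hash <- function(config) {
  fnv1a(paste(deparse(config[order(names(config))]), collapse = ""))
}

#' Run manifest
#'
#' Provenance record of a run: configuration, seed, config hash, package
#' version, wall time.
#'
#' @param run An `mc_run`.
#' @return A list (serialisable to JSON).
#' @export
run_manifest <- function(run) {
  list(package = "neutronplan",
       version = as.character(utils::packageVersion("neutronplan")),
       seed = run$seed,
       n_histories = run$tally$n,
       geometry = run$geometry_type,
       particle = run$tally$kind,
       config = unclass(run$config),
       config_hash = config_hash(unclass(run$config)),
       beam = unclass(run$beam),
       elapsed_s = run$elapsed_s,
       audit = run$audit,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write a dose grid container
#'
#' Binary array container with a JSON metadata header: line 1 the magic
#' "NPDOSE1", line 2 the metadata (shape, voxel size, units, channel,
#' n_histories, seed, config hash), then the raw little-endian doubles.
#'
#' @param run An `mc_run` on a voxel geometry.
#' @param file Output path.
#' @param channel Dose channel to export.
#' @export
write_dose_grid <- function(run, file, channel = "total") {
  g <- dose_grid(run, channel = channel)
  s <- dose_grid(run, channel = channel, statistic = "se")
  meta <- list(shape = run$tally$dim, voxel_size_cm = run$tally$voxel_size,
               origin_cm = run$tally$origin, units = "Gy_cm2_per_primary_fluence",
               channel = channel, n_histories = run$tally$n, seed = run$seed,
               config_hash = config_hash(unclass(run$config)))
  con <- file(file, "wb")
  on.exit(close(con))
  writeChar(paste0("NPDOSE1\n",
                   jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA),
                   "\n"), con, eos = NULL)
  g[is.na(g)] <- -1
  s[is.na(s)] <- -1
  writeBin(as.vector(g), con, size = 8, endian = "little")
  writeBin(as.vector(s), con, size = 8, endian = "little")
  invisible(file)
}

read_text_line <- function(con) {
  ch <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (!length(b) || b == as.raw(10)) break
    ch <- c(ch, b)
  }
  rawToChar(ch)
}

#' Read a dose grid container
#' @param file Path written by [write_dose_grid()].
#' @return list(meta, dose (array), se (array)); NA where undefined.
#' @export
read_dose_grid <- function(file) {
  if (!file.exists(file)) stop("dose grid file not found: ", file)
  con <- file(file, "rb")
  on.exit(close(con))
  magic <- read_text_line(con)
  if (magic != "NPDOSE1") stop("not a dose grid container: ", file)
  meta <- jsonlite::fromJSON(read_text_line(con))
  n <- prod(meta$shape)
  g <- readBin(con, "numeric", n, size = 8, endian = "little")
  s <- readBin(con, "numeric", n, size = 8, endian = "little")
  g[g < 0] <- NA; s[s < 0] <- NA
  list(meta = meta, dose = array(g, dim = meta$shape),
       se = array(s, dim = meta$shape))
}

#' Read a run configuration file (YAML)
#'
#' Declarative run description: geometry (water-solid | water-voxel |
#' head-phantom), room on/off, beam, spectrum (path or synthetic), histories,
#' seed, irradiation time and fluence rate.
#'
#' @param path YAML file.
#' @return Validated list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  defaults <- list(geometry = "water-solid", room = FALSE,
                   beam = list(width = 9, height = 9, center = c(-100, 0, 0)),
                   spectrum = "synthetic", particle = "neutron",
                   fluence_rate = 3.2e8, n_histories = 1e4, seed = 1,
                   irradiation_s = 180, score_channels = TRUE)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (!cfg$geometry %in% c("water-solid", "water-voxel", "head-phantom"))
    stop("unknown geometry: ", cfg$geometry)
  if (is.character(cfg$spectrum) && cfg$spectrum != "synthetic" &&
      !file.exists(cfg$spectrum))
    stop("spectrum file not found: ", cfg$spectrum)
  cfg
}

cli_usage <- function() {
  cat("usage: neutronplan <command> [options]\n",
      "commands:\n",
      "  make-spectrum --particle neutron|photon --rate R --out FILE\n",
      "  make-phantom  --seed N --grid FILE --map FILE\n",
      "  simulate      --config FILE [--out DIR]\n",
      "  depthdose     --config FILE --out FILE.csv\n",
      "  dvh           --grid FILE --phantom FILE --map FILE --roi NAME --out FILE.csv\n",
      "  isodose       --grid FILE --slice K --prescribed GY --out FILE.json\n",
      "  compare       --config FILE --out FILE.csv   (room vs free field)\n",
      sep = "")
}

cli_opt <- function(args, name, default = NULL) {
  i <- which(args == paste0("--", name))
  if (!length(i)) return(default)
  args[i[1] + 1]
}

cli_run_from_config <- function(cfg) {
  spectrum <- if (identical(cfg$spectrum, "synthetic"))
    synthetic_medapp_spectrum(cfg$particle, cfg$fluence_rate)
  else read_spectrum(cfg$spectrum)
  beam <- beam_config(cfg$beam$width, cfg$beam$height, unlist(cfg$beam$center))
  geometry <- switch(cfg$geometry,
    "water-solid" = solid_box_phantom(room = if (isTRUE(cfg$room)) room_shell() else NULL),
    "water-voxel" = voxelised_water_phantom(),
    "head-phantom" = synthetic_head_phantom(seed = cfg$seed))
  config <- transport_config(cfg$n_histories, cfg$seed,
                             score_channels = isTRUE(cfg$score_channels))
  list(run = run_simulation(geometry, beam, spectrum, config),
       geometry = geometry, cfg = cfg)
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher over the package functions; see
#' `inst/cli/neutronplan.R` for the executable wrapper.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  status <- tryCatch({
    if (!length(args)) { cli_usage(); return(invisible(1L)) }
    cmd <- args[1]; rest <- args[-1]
    switch(cmd,
      "make-spectrum" = {
        sp <- synthetic_medapp_spectrum(
          cli_opt(rest, "particle", "neutron"),
          as.numeric(cli_opt(rest, "rate", "3.2e8")))
        write_spectrum(sp, cli_opt(rest, "out", "spectrum.txt"))
        0L
      },
      "make-phantom" = {
        ph <- synthetic_head_phantom(seed = as.integer(cli_opt(rest, "seed", "1")))
        write_voxel_phantom(ph, cli_opt(rest, "grid", "head.vox"),
                            cli_opt(rest, "map", "head.map"))
        0L
      },
      "simulate" = {
        cfg <- read_run_config(cli_opt(rest, "config"))
        out <- cli_opt(rest, "out", ".")
        r <- cli_run_from_config(cfg)
        if (r$run$geometry_type == "voxel")
          write_dose_grid(r$run, file.path(out, "dose.npd"))
        else
          write.csv(finalize_dose(r$run), file.path(out, "chambers.csv"),
                    row.names = FALSE)
        jsonlite::write_json(run_manifest(r$run),
                             file.path(out, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
        0L
      },
      "depthdose" = {
        cfg <- read_run_config(cli_opt(rest, "config"))
        r <- cli_run_from_config(cfg)
        write.csv(depth_dose(r$run), cli_opt(rest, "out", "depthdose.csv"),
                  row.names = FALSE)
        0L
      },
      "dvh" = {
        gr <- read_dose_grid(cli_opt(rest, "grid"))
        ph <- load_voxel_phantom(cli_opt(rest, "phantom"), cli_opt(rest, "map"))
        roi_name <- cli_opt(rest, "roi")
        organ <- ph$organ_map[ph$organ_map$name == roi_name, ]
        if (!nrow(organ)) stop("no ROI named ", roi_name)
        mask <- which(ph$ids == organ$organ_id)
        dvh <- cumulative_dvh(gr$dose, mask)
        write.csv(dvh, cli_opt(rest, "out", "dvh.csv"), row.names = FALSE)
        0L
      },
      "isodose" = {
        gr <- read_dose_grid(cli_opt(rest, "grid"))
        k <- as.integer(cli_opt(rest, "slice", "1"))
        iso <- isodose_contours(gr$dose[, , k],
                                prescribed = as.numeric(cli_opt(rest, "prescribed", "2")))
        jsonlite::write_json(iso, cli_opt(rest, "out", "isodose.json"),
                             auto_unbox = TRUE, digits = NA)
        0L
      },
      "compare" = {
        cfg <- read_run_config(cli_opt(rest, "config"))
        spectrum <- if (identical(cfg$spectrum, "synthetic"))
          synthetic_medapp_spectrum(cfg$particle, cfg$fluence_rate)
        else read_spectrum(cfg$spectrum)
        beam <- beam_config(cfg$beam$width, cfg$beam$height, unlist(cfg$beam$center))
        st <- room_influence_study(beam, spectrum,
                                   transport_config(cfg$n_histories, cfg$seed))
        write.csv(st$table, cli_opt(rest, "out", "compare.csv"), row.names = FALSE)
        message(sprintf("max relative wall influence (<=10 cm): %.2f%%",
                        st$max_rel_diff_percent))
        0L
      },
      { message("unknown command: ", cmd); cli_usage(); 1L })
  }, error = function(e) { message("error: ", conditionMessage(e)); 1L })
  invisible(status)
}
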