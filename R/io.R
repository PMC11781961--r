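#' Load a simulation configuration file
#'
#' Reads a YAML configuration and builds a validated [sim_config], filling
#' every missing entry with the reference defaults (geometry table,
#' material table, 50 x 50 x 150 grid, dt = 1e-5 s).  Unknown keys are
#' rejected.  An empty file yields the full default configuration.
#'
#' @param path path to a YAML file.
#' @return A [sim_config].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  config_from_list(raw)
}

#' Build a configuration from a nested list
#'
#' @param raw nested list with optional sections `geometry`, `materials`,
#'   `fluid`, `pressure`, `numerics`, and scalar `scenario`, `seed`,
#'   `jitter`.
#' @return A [sim_config].
#' @export
config_from_list <- function(raw) {
  known <- c("geometry", "materials", "fluid", "pressure", "numerics",
             "scenario", "seed", "jitter", "preset")
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  take <- function(section, keys) {
    s <- raw[[section]]
    if (is.null(s)) return(list())
    ubad <- setdiff(names(s), keys)
    if (length(ubad))
      stop("unknown key(s) in '", section, "': ",
           paste(ubad, collapse = ", "))
    s
  }
  geo <- do.call(geometry_params,
                 take("geometry", names(formals(geometry_params))))
  mats_raw <- take("materials", c("wall", "sinus", "leaflet", "beta"))
  beta <- if (!is.null(mats_raw$beta)) mats_raw$beta else 500
  mats <- default_materials(beta = beta)
  for (reg in c("wall", "sinus", "leaflet")) {
    m <- mats_raw[[reg]]
    if (is.null(m)) next
    m$beta <- if (is.null(m$beta)) beta else m$beta
    mats[[reg]] <- do.call(material_params, m)
  }
  fl <- take("fluid", c("grid_n", "box", "rho", "mu"))
  pr <- take("pressure", c("amplitude", "P0", "period", "eps", "ramp",
                           "P0_ramp"))
  nu <- take("numerics", c("dt", "cycles", "struct_resolution",
                           "tether_kappa", "kernel", "rk_stages",
                           "output_every", "hypertension_P0"))
  args <- c(list(geometry = geo, materials = mats,
                 profile = do.call(pressure_profile, pr)),
            fl, nu)
  if (!is.null(raw$scenario)) args$scenario <- raw$scenario
  if (!is.null(raw$seed)) args$seed <- raw$seed
  if (!is.null(raw$jitter)) args$jitter <- raw$jitter
  if (!is.null(raw$preset))
    do.call(preset_config, c(list(name = raw$preset), args["scenario"]))
  else
    do.call(sim_config, args)
}

#' Save a configuration to YAML
#'
#' Writes the configuration so that [load_config] round-trips it.
#'
#' @param cfg a [sim_config].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  mat_list <- function(m) {
    out <- unclass(m)
    out
  }
  lst <- list(
    geometry = unclass(cfg$geometry),
    materials = list(wall = mat_list(cfg$materials_base$wall),
                     sinus = mat_list(cfg$materials_base$sinus),
                     leaflet = mat_list(cfg$materials_base$leaflet)),
    fluid = list(grid_n = cfg$grid_n, box = cfg$box, rho = cfg$rho,
                 mu = cfg$mu),
    pressure = list(amplitude = cfg$profile$A, P0 = cfg$profile$P0,
                    period = cfg$profile$T, eps = cfg$profile$eps,
                    ramp = cfg$profile$ramp, P0_ramp = cfg$profile$P0_ramp),
    numerics = list(dt = cfg$dt, cycles = cfg$cycles,
                    struct_resolution = cfg$struct_resolution,
                    tether_kappa = cfg$tether_kappa, kernel = cfg$kernel,
                    rk_stages = cfg$rk_stages,
                    output_every = cfg$output_every),
    scenario = cfg$scenario)
  if (!is.null(cfg$seed)) lst$seed <- cfg$seed
  if (cfg$jitter > 0) lst$jitter <- cfg$jitter
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical (recursively key-sorted) JSON serialisation, so
#' the hash does not depend on key order.
#'
#' @param cfg a [sim_config] (or any nested list).
#' @return Character hash.
#' @export
config_hash <- function(cfg) {
  sort_rec <- function(x) {
    if (is.list(x)) {
      x <- lapply(x, sort_rec)
      if (!is.null(names(x))) x <- x[order(names(x))]
    }
    x
  }
  js <- jsonlite::toJSON(sort_rec(rapply(unclass(cfg), unclass,
                                         how = "replace")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}

#' Write the structural mesh (and fields) as VTK XML unstructured grid
#'
#' ASCII VTU with region tags as integer cell data and fixed/free-edge
#' flags as point data; re-readable by standard VTK tools and by
#' [read_vtu_points].
#'
#' @param mesh a [structural_mesh].
#' @param file output path (`.vtu`).
#' @param x node positions to write (defaults to reference coordinates).
#' @param cell_data optional named list of per-element numeric vectors.
#' @param point_data optional named list of per-node numeric vectors.
#' @return `file`, invisibly.
#' @export
write_vtu <- function(mesh, file, x = mesh$nodes, cell_data = list(),
                      point_data = list()) {
  nn <- nrow(x); ne <- nrow(mesh$elements)
  region_code <- c(wall = 1L, sinus = 2L, leaflet = 3L)[mesh$region]
  fixed_flag <- integer(nn); fixed_flag[mesh$fixed] <- 1L
  fe_flag <- integer(nn)
  fe_flag[mesh$free_edges[[1]]] <- 1L
  fe_flag[mesh$free_edges[[2]]] <- 2L
  cell_data <- c(list(region = region_code), cell_data)
  point_data <- c(list(fixed = fixed_flag, free_edge = fe_flag), point_data)
  con <- file(file, "w"); on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  num <- function(v) paste(formatC(v, format = "g", digits = 9),
                           collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', nn, ne))
  w('<Points><DataArray type="Float32" NumberOfComponents="3" format="ascii">')
  w(num(as.vector(t(x))))
  w('</DataArray></Points>')
  w('<Cells>')
  w('<DataArray type="Int32" Name="connectivity" format="ascii">')
  w(paste(as.vector(t(mesh$elements)) - 1L, collapse = " "))
  w('</DataArray>')
  w('<DataArray type="Int32" Name="offsets" format="ascii">')
  w(paste(seq_len(ne) * 4L, collapse = " "))
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(10L, ne), collapse = " "))
  w('</DataArray>')
  w('</Cells>')
  w('<CellData>')
  for (nmv in names(cell_data)) {
    w(sprintf('<DataArray type="Float32" Name="%s" format="ascii">', nmv))
    w(num(cell_data[[nmv]]))
    w('</DataArray>')
  }
  w('</CellData>')
  w('<PointData>')
  for (nmv in names(point_data)) {
    w(sprintf('<DataArray type="Float32" Name="%s" format="ascii">', nmv))
    w(num(point_data[[nmv]]))
    w('</DataArray>')
  }
  w('</PointData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(file)
}

#' Read point coordinates back from a VTU file
#'
#' Minimal reader for the ASCII VTU files written by [write_vtu] (points
#' section only), for round-trip checks.
#'
#' @param file path to a `.vtu` file.
#' @return n x 3 matrix of coordinates.
#' @export
read_vtu_points <- function(file) {
  txt <- readLines(file)
  i <- grep("<Points>", txt, fixed = TRUE)
  vals <- as.numeric(strsplit(trimws(txt[i + 1L]), "\\s+")[[1]])
  matrix(vals, ncol = 3, byrow = TRUE)
}

#' Write the fluid state as VTK XML image data
#'
#' Cell-centred pressure and cell-averaged velocity on the uniform grid.
#'
#' @param state a [fluid_state].
#' @param file output path (`.vti`).
#' @return `file`, invisibly.
#' @export
write_vti <- function(state, file) {
  g <- state$grid; n <- g$n
  sp <- cell_speed(state)
  con <- file(file, "w"); on.exit(close(con))
  w <- function(...) cat(..., "\n", sep = "", file = con)
  num <- function(v) paste(formatC(v, format = "g", digits = 9),
                           collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="ImageData" version="0.1" byte_order="LittleEndian">')
  w(sprintf('<ImageData WholeExtent="0 %d 0 %d 0 %d" Origin="0 0 0" Spacing="%g %g %g">',
            n[1], n[2], n[3], g$h, g$h, g$h))
  w(sprintf('<Piece Extent="0 %d 0 %d 0 %d">', n[1], n[2], n[3]))
  w('<CellData>')
  w('<DataArray type="Float32" Name="pressure" format="ascii">')
  w(num(as.vector(state$p)))
  w('</DataArray>')
  w('<DataArray type="Float32" Name="speed" format="ascii">')
  w(num(as.vector(sp)))
  w('</DataArray>')
  w('</CellData>')
  w('</Piece></ImageData></VTKFile>')
  invisible(file)
}

#' Write a simulation snapshot
#'
#' Emits the structure (VTU), the fluid (VTI) and the metrics table (CSV)
#' into a directory; partially written files are removed on failure.
#'
#' @param st an `fsi_state`.
#' @param metrics metrics data frame (see [run_simulation]).
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Character vector of the written paths.
#' @export
write_snapshot <- function(st, metrics, dir, prefix = "snapshot") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- file.path(dir, paste0(prefix, c(".vtu", ".vti", "_metrics.csv")))
  ok <- FALSE
  on.exit(if (!ok) unlink(files))
  write_vtu(st$mesh, files[1], x = st$x)
  write_vti(st$fluid, files[2])
  utils::write.csv(metrics, files[3], row.names = FALSE)
  ok <- TRUE
  files
}

#' Run manifest
#'
#' Records the configuration hash, package version, wall-clock interval
#' and output inventory of a run; written as JSON next to the outputs.
#'
#' @param cfg the [sim_config] of the run.
#' @param files character vector of produced files.
#' @param started,finished POSIXct timestamps.
#' @param path output path for the JSON manifest (optional).
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(cfg, files, started, finished, path = NULL) {
  man <- list(
    package = "valvefsi",
    version = as.character(utils::packageVersion("valvefsi")),
    config_hash = config_hash(cfg),
    scenario = cfg$scenario,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
    files = as.list(basename(files)))
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("manifest lists files that do not exist: ",
         paste(missing, collapse = ", "))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
    return(invisible(man))
  }
  man
}
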