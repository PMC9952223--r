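# Readers, writers and configuration: legacy-ASCII VTK export of the
# hexahedral mesh (no VTK bindings are required), labeled-volume import,
# and YAML/JSON configuration with schema validation.

#' Export a voxel model to a VTK unstructured grid
#'
#' Writes a legacy-ASCII VTK file (`UNSTRUCTURED_GRID`, cell type 12 =
#' hexahedron) with per-cell `material` (integer code), `fragment` and
#' `inert` data and, when fields are supplied, per-point `msc` and `cho`
#' concentrations. Values are written with full precision so a read-back
#' recovers them exactly.
#'
#' @param model A [voxel_model()].
#' @param fields Optional [concentration_fields()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_vtk <- function(model, fields = NULL, path) {
  if (!is.null(fields) &&
      (length(fields$msc) != n_nodes(model) ||
         length(fields$cho) != n_nodes(model)))
    stop("field/node mismatch")
  con <- file(path, open = "wt")
  on.exit(close(con))
  wl <- function(...) writeLines(..., con = con)
  n <- n_nodes(model); m <- n_elements(model)
  wl("# vtk DataFile Version 3.0")
  wl("callusim voxel model")
  wl("ASCII")
  wl("DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d double", n))
  xyz <- sweep(model$node_xyz * model$lattice$L, 2L, model$lattice$origin, "+")
  wl(apply(format(xyz, digits = 17, trim = TRUE, scientific = FALSE), 1L,
           paste, collapse = " "))
  wl(sprintf("CELLS %d %d", m, m * 9L))
  if (m > 0L)
    wl(apply(cbind(8L, model$conn - 1L), 1L, paste, collapse = " "))
  wl(sprintf("CELL_TYPES %d", m))
  if (m > 0L) wl(rep("12", m))
  mat_levels <- default_materials()$name
  mat_code <- match(model$material, mat_levels)
  mat_code[is.na(mat_code)] <- 0L
  wl(sprintf("CELL_DATA %d", m))
  wl("SCALARS material int 1"); wl("LOOKUP_TABLE default")
  if (m > 0L) wl(as.character(mat_code))
  wl("SCALARS fragment int 1"); wl("LOOKUP_TABLE default")
  if (m > 0L) wl(as.character(model$fragment))
  wl("SCALARS inert int 1"); wl("LOOKUP_TABLE default")
  if (m > 0L) wl(as.character(as.integer(model$inert)))
  if (!is.null(fields)) {
    wl(sprintf("POINT_DATA %d", n))
    for (sp in c("msc", "cho")) {
      wl(sprintf("SCALARS %s double 1", sp)); wl("LOOKUP_TABLE default")
      wl(format(fields[[sp]], digits = 17, trim = TRUE))
    }
  }
  invisible(path)
}

#' Read back a VTK file written by [export_vtk()]
#'
#' Minimal legacy-ASCII reader for round-trip verification: recovers point
#' coordinates, hexahedron connectivity, cell data and point data.
#'
#' @param path File path.
#' @return A list with `points`, `cells` (m x 8, 1-based), `cell_data` and
#'   `point_data`.
#' @export
read_vtk <- function(path) {
  lines <- readLines(path)
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1L]])
  i_pts <- grep("^POINTS", lines)[1L]
  n <- as.integer(strsplit(lines[i_pts], "\\s+")[[1L]][2L])
  pts <- matrix(unlist(lapply(lines[i_pts + seq_len(n)], num)),
                ncol = 3L, byrow = TRUE)
  i_cells <- grep("^CELLS", lines)[1L]
  m <- as.integer(strsplit(lines[i_cells], "\\s+")[[1L]][2L])
  cells <- if (m > 0L)
    matrix(unlist(lapply(lines[i_cells + seq_len(m)], num)),
           ncol = 9L, byrow = TRUE)[, -1L, drop = FALSE] + 1L
  else matrix(integer(0), 0L, 8L)
  read_scalars <- function(start, count) {
    out <- list()
    i <- start
    while (i <= length(lines) && grepl("^SCALARS", lines[i])) {
      nm <- strsplit(lines[i], "\\s+")[[1L]][2L]
      vals <- as.numeric(lines[(i + 2L):(i + 1L + count)])
      out[[nm]] <- vals
      i <- i + 2L + count
    }
    out
  }
  cell_data <- point_data <- list()
  i_cd <- grep("^CELL_DATA", lines)
  if (length(i_cd)) cell_data <- read_scalars(i_cd[1L] + 1L, m)
  i_pd <- grep("^POINT_DATA", lines)
  if (length(i_pd)) point_data <- read_scalars(i_pd[1L] + 1L, n)
  list(points = pts, cells = cells, cell_data = cell_data,
       point_data = point_data)
}

#' Import a labeled voxel volume as a voxel model
#'
#' Builds one element per nonzero voxel of an integer-labeled 3-D volume
#' (label 0 = empty), mapping labels to materials through `label_map`.
#' Nodes are created on the lattice with exact deduplication, and fragment
#' ids are assigned by connected components of the bone materials. Accepts
#' an integer array or the path of a NIfTI file (read with the RNifti
#' package); only cubic voxels are supported.
#'
#' @param x Integer 3-D array, or path to a NIfTI file.
#' @param label_map Named list or vector mapping label values (as names) to
#'   material names, e.g. `c("1" = "cortical", "2" = "nail")`. Must cover
#'   every nonzero label present.
#' @param L Voxel edge length in mm (for arrays; NIfTI files supply their
#'   own spacing, which must be isotropic).
#' @return A [voxel_model()].
#' @export
import_labeled_volume <- function(x, label_map, L = 1) {
  if (is.character(x)) {
    if (!requireNamespace("RNifti", quietly = TRUE))
      stop("reading NIfTI files requires the RNifti package")
    img <- RNifti::readNifti(x)
    pd <- RNifti::pixdim(img)[1:3]
    if (max(pd) - min(pd) > 1e-6 * max(pd))
      stop("anisotropic voxel spacing is not supported (cubic voxels only)")
    L <- pd[1L]
    x <- as.array(img)
  }
  if (length(dim(x)) != 3L) stop("expected a 3-D volume")
  if (any(x != round(x))) stop("volume must be integer-labeled")
  lat <- voxel_lattice(dim(x), L = L)
  nz <- which(x != 0)
  if (!length(nz)) return(voxel_model(lat, matrix(integer(0), 0L, 3L)))
  sites <- arrayInd(nz, dim(x)) - 1L
  labels <- as.character(x[nz])
  unknown <- setdiff(unique(labels), names(label_map))
  if (length(unknown))
    stop("unknown label(s) in volume: ", paste(unknown, collapse = ", "))
  material <- unlist(label_map)[labels]
  model <- voxel_model(lat, sites, material = material)
  bone <- which(material_property(default_materials(), model$material,
                                  "growable") &
                  model$material != "callus")
  comp <- connected_components(model, bone)
  model$fragment <- comp
  model
}

#' Load a simulation configuration file
#'
#' Parses a YAML or JSON configuration, validates it against the schema and
#' fills defaults (material diffusivities in um^2/min are converted to the
#' internal mm^2/day on use). Unknown keys are rejected with the offending
#' key path.
#'
#' @param path Configuration file (`.yaml`/`.yml`/`.json`); `NULL` or an
#'   empty file yields the full default configuration.
#' @param ... Named configuration sections overriding the file's values
#'   (passed to [simulation_config()]).
#' @return A [simulation_config()].
#' @export
load_config <- function(path = NULL, ...) {
  from_file <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    from_file <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(from_file)) from_file <- list()
  }
  overrides <- list(...)
  for (key in names(overrides)) {
    if (is.list(overrides[[key]]) && is.list(from_file[[key]]))
      from_file[[key]] <- utils::modifyList(from_file[[key]], overrides[[key]])
    else from_file[[key]] <- overrides[[key]]
  }
  simulation_config(from_file)
}

#' Serialize a configuration to YAML
#'
#' @param config A [simulation_config()].
#' @return A YAML string (the `model`/explicit-boundary slots, which are not
#'   file-representable, are omitted).
#' @export
dump_config <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  keep <- intersect(names(default_config()), names(config))
  yaml::as.yaml(config[keep])
}

#' Write the outputs and manifest of a simulation run
#'
#' Writes the per-day summary CSV, the final model (plus concentration
#' fields) as VTK, and a JSON run manifest echoing the configuration and
#' listing every output file with its MD5 checksum.
#'
#' @param result A [run_simulation()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
save_run <- function(result, dir) {
  stopifnot(inherits(result, "callus_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "summary.csv")
  utils::write.csv(result$days, csv, row.names = FALSE)
  vtk <- file.path(dir, "final_model.vtk")
  export_vtk(result$model, result$fields, vtk)
  files <- c(csv, vtk)
  manifest <- list(
    package = "callusim",
    version = as.character(utils::packageVersion("callusim")),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = yaml::yaml.load(dump_config(result$config)),
    events = result$events,
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
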