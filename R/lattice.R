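# Voxel lattice data model and idealized fractured-diaphysis geometries.
#
# All geometry lives on an integer lattice of cubic voxels with edge L (mm).
# An element is identified by the integer triple of its minimum corner
# ("site", 0-based); its 8 nodes are the corners of the unit cube at that
# site, ordered in the standard VTK hexahedron convention. Node identity is
# keyed exactly by the integer lattice triple, so deduplication needs no
# floating-point tolerance.

# VTK_HEXAHEDRON corner ordering: bottom face counter-clockwise, then top.
CORNER_OFFSETS <- rbind(
  c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L),
  c(0L, 0L, 1L), c(1L, 0L, 1L), c(1L, 1L, 1L), c(0L, 1L, 1L)
)

# Axial direction table: +x, -x, +y, -y, +z, -z.
DIRECTIONS <- rbind(
  c(1L, 0L, 0L), c(-1L, 0L, 0L),
  c(0L, 1L, 0L), c(0L, -1L, 0L),
  c(0L, 0L, 1L), c(0L, 0L, -1L)
)
DIRECTION_LABELS <- c("+x", "-x", "+y", "-y", "+z", "-z")

# Corner indices (into CORNER_OFFSETS rows) of the face normal to each
# direction, i.e. the 4 element nodes lying on that face.
FACE_CORNERS <- rbind(
  c(2L, 3L, 6L, 7L),  # +x
  c(1L, 4L, 5L, 8L),  # -x
  c(3L, 4L, 7L, 8L),  # +y
  c(1L, 2L, 5L, 6L),  # -y
  c(5L, 6L, 7L, 8L),  # +z
  c(1L, 2L, 3L, 4L)   # -z
)

#' Create a voxel lattice
#'
#' Defines the integer lattice that hosts every node and element of a
#' [voxel_model()]. Element sites are integer triples `(i, j, k)` with
#' `0 <= i < nx` (etc.); node positions are integer triples with
#' `0 <= i <= nx`. Physical coordinates are `origin + L * triple`.
#'
#' @param extents Integer vector `c(nx, ny, nz)`, the number of voxels per
#'   axis. All entries must be >= 1.
#' @param L Edge length of the cubic voxel in mm (default 1).
#' @param origin Physical coordinate (mm) of lattice site `(0, 0, 0)`.
#' @return An object of class `voxel_lattice`.
#' @export
voxel_lattice <- function(extents, L = 1, origin = c(0, 0, 0)) {
  extents <- as.integer(extents)
  if (length(extents) != 3L || any(is.na(extents)) || any(extents < 1L))
    stop("`extents` must be three integers >= 1")
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("voxel edge length `L` must be a positive number")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite length-3 coordinate")
  structure(list(extents = extents, L = as.numeric(L),
                 origin = as.numeric(origin)),
            class = "voxel_lattice")
}

#' @export
print.voxel_lattice <- function(x, ...) {
  cat(sprintf("<voxel_lattice> %d x %d x %d voxels, L = %g mm\n",
              x$extents[1], x$extents[2], x$extents[3], x$L))
  invisible(x)
}

# Linear key of element sites (1-based; sites are 0-based triples).
site_key <- function(lattice, sites) {
  n <- lattice$extents
  1L + sites[, 1L] + n[1L] * (sites[, 2L] + n[2L] * sites[, 3L])
}

# Linear key of node lattice triples (node coordinates run 0..n).
node_key <- function(lattice, triples) {
  n <- lattice$extents + 1L
  1L + triples[, 1L] + n[1L] * (triples[, 2L] + n[2L] * triples[, 3L])
}

sites_in_bounds <- function(lattice, sites) {
  n <- lattice$extents
  sites[, 1L] >= 0L & sites[, 1L] < n[1L] &
    sites[, 2L] >= 0L & sites[, 2L] < n[2L] &
    sites[, 3L] >= 0L & sites[, 3L] < n[3L]
}

as_site_matrix <- function(sites) {
  if (is.null(dim(sites))) sites <- matrix(as.integer(sites), ncol = 3L)
  sites <- as.matrix(sites)
  storage.mode(sites) <- "integer"
  dimnames(sites) <- NULL
  sites
}

#' Build a voxel model from explicit element sites
#'
#' Constructs the hexahedral mesh for a set of occupied lattice sites:
#' nodes are created at the distinct corner lattice points (exact
#' deduplication by integer triple) and each element receives its 8 corner
#' node ids in VTK hexahedron order.
#'
#' @param lattice A [voxel_lattice()].
#' @param sites Integer matrix (m x 3) of element sites (0-based minimum
#'   corners), one row per element. Duplicate sites are an error.
#' @param material Character vector of material names (recycled).
#' @param fragment Integer fragment ids (0 = unassigned; recycled).
#' @param inert Logical flags for inert fragments (recycled).
#' @return An object of class `voxel_model`.
#' @seealso [generate_diaphysis()], [apply_fracture()], [spawn_elements()]
#' @export
voxel_model <- function(lattice, sites, material = "cortical",
                        fragment = 0L, inert = FALSE) {
  stopifnot(inherits(lattice, "voxel_lattice"))
  sites <- as_site_matrix(sites)
  m <- nrow(sites)
  model <- list(
    lattice  = lattice,
    node_xyz = matrix(integer(0), 0L, 3L),
    node_at  = integer(prod(lattice$extents + 1L)),
    elem_site = matrix(integer(0), 0L, 3L),
    material = character(0),
    fragment = integer(0),
    inert    = logical(0),
    conn     = matrix(integer(0), 0L, 8L),
    elem_at  = integer(prod(lattice$extents)),
    meta     = list()
  )
  class(model) <- "voxel_model"
  if (m == 0L) return(model)
  if (!all(sites_in_bounds(lattice, sites)))
    stop("element site outside lattice extents")
  if (anyDuplicated(site_key(lattice, sites)))
    stop("duplicate element sites")
  add_elements(model, sites,
               material = rep_len(as.character(material), m),
               fragment = rep_len(as.integer(fragment), m),
               inert    = rep_len(as.logical(inert), m))$model
}

#' @export
print.voxel_model <- function(x, ...) {
  cat(sprintf("<voxel_model> %d elements, %d nodes on %d x %d x %d lattice (L = %g mm)\n",
              n_elements(x), n_nodes(x), x$lattice$extents[1],
              x$lattice$extents[2], x$lattice$extents[3], x$lattice$L))
  if (n_elements(x) > 0L) {
    tab <- table(x$material)
    cat("  materials:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
    fr <- unique(x$fragment[x$fragment > 0L])
    if (length(fr)) cat("  fragments:", paste(sort(fr), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of elements / nodes in a voxel model
#' @param model A [voxel_model()].
#' @return Integer count.
#' @export
n_elements <- function(model) nrow(model$elem_site)

#' @rdname n_elements
#' @export
n_nodes <- function(model) nrow(model$node_xyz)

# Append elements (and any missing corner nodes) to a model. Internal batch
# primitive shared by the constructor and the mesh-growth phase. Sites must
# be in bounds, mutually distinct and unoccupied. Returns the updated model
# plus bookkeeping needed to initialize fields on the new nodes.
add_elements <- function(model, sites, material, fragment = 0L, inert = FALSE) {
  lattice <- model$lattice
  m_new <- nrow(sites)
  corners_i <- rep(sites[, 1L], each = 8L) + rep(CORNER_OFFSETS[, 1L], m_new)
  corners_j <- rep(sites[, 2L], each = 8L) + rep(CORNER_OFFSETS[, 2L], m_new)
  corners_k <- rep(sites[, 3L], each = 8L) + rep(CORNER_OFFSETS[, 3L], m_new)
  corners <- cbind(corners_i, corners_j, corners_k)
  dimnames(corners) <- NULL
  keys <- node_key(lattice, corners)

  ids <- model$node_at[keys]
  missing <- which(ids == 0L)
  created <- integer(0)
  if (length(missing)) {
    umiss <- missing[!duplicated(keys[missing])]
    created <- nrow(model$node_xyz) + seq_along(umiss)
    model$node_xyz <- rbind(model$node_xyz, corners[umiss, , drop = FALSE])
    model$node_at[keys[umiss]] <- created
    ids <- model$node_at[keys]
  }
  conn_new <- matrix(ids, nrow = m_new, ncol = 8L, byrow = TRUE)

  first_new <- nrow(model$elem_site) + 1L
  model$elem_site <- rbind(model$elem_site, sites)
  model$material <- c(model$material, rep_len(as.character(material), m_new))
  model$fragment <- c(model$fragment, rep_len(as.integer(fragment), m_new))
  model$inert <- c(model$inert, rep_len(as.logical(inert), m_new))
  model$conn <- rbind(model$conn, conn_new)
  model$elem_at[site_key(lattice, sites)] <- first_new:(first_new + m_new - 1L)

  list(model = model,
       element_ids = first_new:(first_new + m_new - 1L),
       conn_new = conn_new,
       created_nodes = created,
       is_new_node = matrix(ids %in% created, nrow = m_new, ncol = 8L, byrow = TRUE))
}

#' Element centroid coordinates
#'
#' @param model A [voxel_model()].
#' @param elements Optional element ids (default all).
#' @return Numeric matrix (m x 3) of centroid coordinates in mm.
#' @export
element_centroids <- function(model, elements = NULL) {
  s <- if (is.null(elements)) model$elem_site else
    model$elem_site[elements, , drop = FALSE]
  sweep((s + 0.5) * model$lattice$L, 2L, model$lattice$origin, "+")
}

#' Build the centroid occupancy index
#'
#' The centroid index maps every occupied lattice site to its element id and
#' is the backbone of free-face detection and overlap checks: growth looks
#' for missing neighbour centroids instead of inverting node connectivity.
#'
#' @param model A [voxel_model()].
#' @return An object of class `centroid_index`.
#' @export
build_centroid_index <- function(model) {
  m <- n_elements(model)
  occ <- integer(prod(model$lattice$extents))
  if (m > 0L) {
    keys <- site_key(model$lattice, model$elem_site)
    if (anyDuplicated(keys)) stop("integrity error: duplicate element sites")
    occ[keys] <- seq_len(m)
  }
  structure(list(occupancy = occ, extents = model$lattice$extents, n = m),
            class = "centroid_index")
}

#' Look up lattice sites in a centroid index
#'
#' @param index A [build_centroid_index()] result.
#' @param sites Integer matrix (or length-3 vector) of lattice sites.
#' @return Integer element ids; `0` marks an unoccupied (or out-of-lattice)
#'   site.
#' @export
index_lookup <- function(index, sites) {
  sites <- as_site_matrix(sites)
  n <- index$extents
  inb <- sites[, 1L] >= 0L & sites[, 1L] < n[1L] &
    sites[, 2L] >= 0L & sites[, 2L] < n[2L] &
    sites[, 3L] >= 0L & sites[, 3L] < n[3L]
  out <- integer(nrow(sites))
  if (any(inb)) {
    keys <- 1L + sites[inb, 1L] + n[1L] * (sites[inb, 2L] + n[2L] * sites[inb, 3L])
    out[inb] <- index$occupancy[keys]
  }
  out
}

#' Material table
#'
#' Default material properties: diffusion coefficients (given in um^2/min
#' and converted to the internal mm^2/day unit system), whether the material
#' participates in the diffusion problem (the nail does not), whether callus
#' may grow from its free faces, and which prescribed-concentration class the
#' material belongs to under region boundary conditions (`"high"` for the
#' well-perfused marrow/trabecular/periosteal compartments, `"low"` for
#' cortical bone, `NA` for free materials).
#'
#' @param D_um2_min Named numeric vector of diffusion coefficients in
#'   um^2/min overriding the defaults (marrow 100, trabecular 100,
#'   periosteum 100, callus 50, cortical 1, nail 0).
#' @return A data.frame with columns `name`, `D_um2_min`, `D` (mm^2/day),
#'   `diffusive`, `growable`, `bc_group`.
#' @export
default_materials <- function(D_um2_min = NULL) {
  tab <- data.frame(
    name = c("nail", "cortical", "trabecular", "periosteum", "marrow", "callus"),
    D_um2_min = c(0, 1, 100, 100, 100, 50),
    diffusive = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    growable = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    bc_group = c(NA, "low", "high", "high", "high", NA),
    stringsAsFactors = FALSE
  )
  if (!is.null(D_um2_min)) {
    if (is.null(names(D_um2_min)) || !all(names(D_um2_min) %in% tab$name))
      stop("unknown material in `D_um2_min` override")
    tab$D_um2_min[match(names(D_um2_min), tab$name)] <- D_um2_min
  }
  tab$D <- convert_diffusivity(tab$D_um2_min)
  tab
}

material_property <- function(materials, names, column) {
  idx <- match(names, materials$name)
  if (anyNA(idx)) stop("element with unknown material: ",
                       paste(unique(names[is.na(idx)]), collapse = ", "))
  materials[[column]][idx]
}

#' Generate an idealized fractured-diaphysis substrate
#'
#' Builds a concentric-cylinder stand-in for a diaphyseal femur section
#' treated with an intramedullary nail: a nail core, a marrow/trabecular
#' annulus, a cortical annulus and a one-voxel-deep periosteal shell on the
#' outer surface, aligned with the z axis and centred in the lattice
#' cross-section. An element belongs to a region iff its centroid satisfies
#' the region's radial inequality. Free growth space (empty lattice sites)
#' surrounds the bone out to `margin` mm so callus can form without a
#' pre-meshed domain.
#'
#' @param lattice Optional [voxel_lattice()]. When `NULL` a lattice of edge
#'   `L` just large enough for `outer_radius + margin` laterally and `length`
#'   axially is created.
#' @param outer_radius Outer (periosteal) radius of the bone in mm.
#' @param cortical_thickness Thickness of the cortical annulus in mm
#'   (the outermost `periosteum_thickness` of it is labelled periosteum).
#' @param periosteum_thickness Thickness of the periosteal shell in mm
#'   (default one voxel).
#' @param nail_diameter Diameter of the intramedullary nail in mm.
#' @param length Axial length of the modeled section in mm.
#' @param L Voxel edge length in mm (used when `lattice` is `NULL`).
#' @param margin Free radial growth margin around the bone in mm.
#' @return A [voxel_model()] with materials `nail`, `marrow`, `cortical`,
#'   `periosteum` and metadata describing the axis and radii.
#' @export
generate_diaphysis <- function(lattice = NULL, outer_radius = 15,
                               cortical_thickness = 5.25,
                               periosteum_thickness = 1,
                               nail_diameter = 11, length = 43,
                               L = 1, margin = 7) {
  if (!is.numeric(outer_radius) || outer_radius <= 0)
    stop("sizing error: `outer_radius` must be positive")
  nail_radius <- nail_diameter / 2
  canal_radius <- outer_radius - cortical_thickness
  if (nail_radius >= canal_radius)
    stop("nail radius must be smaller than the inner cortical radius")
  if (periosteum_thickness < 0 || periosteum_thickness >= cortical_thickness)
    stop("`periosteum_thickness` must lie in [0, cortical_thickness)")
  if (is.null(lattice)) {
    nxy <- ceiling(2 * (outer_radius + margin) / L)
    lattice <- voxel_lattice(c(nxy, nxy, ceiling(length / L)), L = L)
  }
  Lv <- lattice$L
  n <- lattice$extents
  if (min(n[1L], n[2L]) * Lv < 2 * (outer_radius + margin))
    stop("sizing error: lattice too small for outer_radius plus growth margin")
  nlay <- floor(length / Lv)
  if (nlay < 1L || nlay > n[3L])
    stop("sizing error: section length does not fit the lattice axially")

  axis <- c(n[1L] / 2, n[2L] / 2) * Lv  # lattice-centred axis (lattice units from origin)
  ij <- expand.grid(i = 0:(n[1L] - 1L), j = 0:(n[2L] - 1L))
  cx <- (ij$i + 0.5) * Lv
  cy <- (ij$j + 0.5) * Lv
  r <- sqrt((cx - axis[1L])^2 + (cy - axis[2L])^2)
  region <- rep(NA_character_, nrow(ij))
  region[r < nail_radius] <- "nail"
  region[r >= nail_radius & r < canal_radius] <- "marrow"
  region[r >= canal_radius & r < outer_radius - periosteum_thickness] <- "cortical"
  region[r >= outer_radius - periosteum_thickness & r < outer_radius] <- "periosteum"
  keep <- which(!is.na(region))
  if (!length(keep)) stop("sizing error: no bone voxels generated")

  sites <- cbind(
    rep(ij$i[keep], times = nlay),
    rep(ij$j[keep], times = nlay),
    rep(0:(nlay - 1L), each = length(keep))
  )
  model <- voxel_model(lattice, sites,
                       material = rep(region[keep], times = nlay),
                       fragment = 0L, inert = FALSE)
  model$meta$geometry <- list(
    axis = axis, outer_radius = outer_radius,
    canal_radius = canal_radius, nail_radius = nail_radius,
    periosteum_thickness = periosteum_thickness,
    length = nlay * Lv, margin = margin
  )
  model
}

#' Describe a fracture
#'
#' @param kind One of `"transverse"`, `"oblique"`, `"comminuted"`,
#'   `"spiral"`.
#' @param gap Interfragmentary gap in mm, measured along the cut normal
#'   (axially for a transverse cut). Must be >= 0; `0` leaves the model
#'   unchanged.
#' @param slope_deg Obliquity angle in degrees from the transverse plane
#'   (used for oblique/comminuted/spiral), `0 <= slope_deg < 90`.
#' @param center Axial position (mm) of the fracture centre; defaults to the
#'   mid-section.
#' @param offset For `"comminuted"`: axial half-distance (mm) between the
#'   transverse cut (at `center - offset`) and the oblique cut (at
#'   `center + offset`); the bone between the two cuts becomes the inert
#'   intermediate fragment.
#' @param pitch For `"spiral"`: axial advance per turn in mm.
#' @return An object of class `fracture_spec`.
#' @export
fracture_spec <- function(kind = c("transverse", "oblique", "comminuted", "spiral"),
                          gap = 6, slope_deg = 30, center = NULL,
                          offset = 6.5, pitch = 30) {
  kind <- match.arg(kind)
  if (!is.numeric(gap) || gap < 0) stop("`gap` must be >= 0")
  if (slope_deg < 0 || slope_deg >= 90) stop("`slope_deg` must be in [0, 90)")
  structure(list(kind = kind, gap = as.numeric(gap),
                 slope_deg = as.numeric(slope_deg),
                 center = center, offset = offset, pitch = pitch),
            class = "fracture_spec")
}

# Signed distance bands used by the analytic cutters. Returns a logical
# "remove" mask over centroid coordinates (mm, lattice frame).
cut_mask <- function(kind, cx, cy, cz, axis, center, gap, slope_deg, pitch = 30) {
  if (gap == 0) return(rep(FALSE, length(cz)))
  switch(kind,
    transverse = abs(cz - center) < gap / 2,
    oblique = {
      phi <- slope_deg * pi / 180
      d <- sin(phi) * (cx - axis[1L]) + cos(phi) * (cz - center)
      abs(d) < gap / 2
    },
    spiral = {
      theta <- atan2(cy - axis[2L], cx - axis[1L])
      zc <- center + pitch * theta / (2 * pi)
      d <- (cz - zc) %% pitch
      pmin(d, pitch - d) < gap / 2
    },
    stop("unsupported cut kind: ", kind)
  )
}

#' Apply a fracture to a voxel model
#'
#' Removes (does not remesh) every bone element whose centroid lies between
#' the two analytic fracture surfaces: parallel transverse planes, tilted
#' planes for an oblique cut, a helicoid band for a spiral cut, or a
#' transverse plus an oblique cut for a comminuted fracture. Nail elements
#' are never removed. The surviving bone is relabelled by connected
#' component (6-connectivity) into fragments numbered by increasing axial
#' position; for a comminuted fracture the intermediate fragment between the
#' two cuts is retained, given its own fragment id and flagged inert (no
#' concentration and no growth, but a substrate that callus may bridge
#' across).
#'
#' @param model A [voxel_model()] from [generate_diaphysis()] (or any model
#'   whose metadata provides an axis; defaults to the lattice centre).
#' @param spec A [fracture_spec()].
#' @return The fractured [voxel_model()]; metadata records the removed
#'   sites and the axial extent of the cut for closure analysis.
#' @export
apply_fracture <- function(model, spec) {
  stopifnot(inherits(model, "voxel_model"), inherits(spec, "fracture_spec"))
  if (spec$gap == 0) return(model)
  lat <- model$lattice
  geom <- model$meta$geometry
  axis <- if (!is.null(geom)) geom$axis else (lat$extents[1:2] / 2) * lat$L
  zlen <- if (!is.null(geom)) geom$length else lat$extents[3L] * lat$L
  # default centre on a node plane so a transverse gap removes whole layers
  center <- if (!is.null(spec$center)) spec$center else floor(zlen / 2)

  cen <- element_centroids(model)
  cx <- cen[, 1L] - lat$origin[1L]
  cy <- cen[, 2L] - lat$origin[2L]
  cz <- cen[, 3L] - lat$origin[3L]

  if (spec$kind == "comminuted") {
    m1 <- cut_mask("transverse", cx, cy, cz, axis, center - spec$offset,
                   spec$gap, 0)
    m2 <- cut_mask("oblique", cx, cy, cz, axis, center + spec$offset,
                   spec$gap, spec$slope_deg)
    remove <- m1 | m2
  } else {
    remove <- cut_mask(spec$kind, cx, cy, cz, axis, center, spec$gap,
                       spec$slope_deg, spec$pitch)
  }
  is_bone <- model$material != "nail"
  remove <- remove & is_bone
  if (!any(remove))
    stop("fracture surfaces lie outside the model span (nothing removed)")
  zr <- range(cz[remove])
  if (zr[1L] < 0 || zr[2L] > zlen)
    stop("fracture surfaces outside model span")

  keep <- which(!remove)
  removed_sites <- model$elem_site[remove & is_bone, , drop = FALSE]
  out <- voxel_model(lat, model$elem_site[keep, , drop = FALSE],
                     material = model$material[keep],
                     fragment = 0L, inert = model$inert[keep])
  out$meta <- model$meta
  out$lattice <- lat

  bone <- which(out$material != "nail")
  comp <- connected_components(out, bone)
  ids <- sort(unique(comp[comp > 0L]))
  # order fragments by increasing minimum axial position
  minz <- vapply(ids, function(id) min(out$elem_site[comp == id, 3L]), numeric(1))
  ord <- order(minz)
  frag <- integer(n_elements(out))
  for (i in seq_along(ord)) frag[comp == ids[ord[i]]] <- i
  out$fragment <- frag

  if (spec$kind == "comminuted") {
    if (length(ids) != 3L)
      stop("comminuted fracture must yield exactly 3 bone fragments, got ",
           length(ids), " (empty or merged intermediate fragment)")
    out$inert[out$fragment == 2L] <- TRUE
  }
  out$meta$fracture <- list(
    spec = spec, center = center,
    removed_sites = removed_sites,
    z_range = zr,
    n_fragments = length(ids)
  )
  out
}

# Connected components (6-connectivity over element sites) of the element
# subset `elems`; returns a component id per element (0 outside the subset).
connected_components <- function(model, elems) {
  m <- n_elements(model)
  comp <- integer(m)
  if (!length(elems)) return(comp)
  in_set <- logical(m)
  in_set[elems] <- TRUE
  lat <- model$lattice
  next_id <- 0L
  pending <- elems
  while (length(pending)) {
    seed <- pending[1L]
    next_id <- next_id + 1L
    comp[seed] <- next_id
    frontier <- seed
    while (length(frontier)) {
      sites <- model$elem_site[frontier, , drop = FALSE]
      nb <- integer(0)
      for (d in seq_len(6L)) {
        tgt <- sweep(sites, 2L, DIRECTIONS[d, ], "+")
        ok <- sites_in_bounds(lat, tgt)
        if (!any(ok)) next
        ids <- model$elem_at[site_key(lat, tgt[ok, , drop = FALSE])]
        ids <- ids[ids > 0L]
        nb <- c(nb, ids[in_set[ids] & comp[ids] == 0L])
      }
      nb <- unique(nb)
      comp[nb] <- next_id
      frontier <- nb
    }
    pending <- pending[comp[pending] == 0L]
  }
  comp
}
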