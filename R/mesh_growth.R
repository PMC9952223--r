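# Free mesh growth: create new callus elements at spawn requests. The new
# centroid is placed one edge length L from the parent centroid in the free
# direction; the path vectors (centroid-to-corner offsets) then locate the
# 8 corner positions, where existing nodes are reused and missing nodes are
# created, so no node is ever repeated at one lattice position and the mesh
# stays watertight.

#' Centroid-to-corner path vectors
#'
#' The fixed offsets from an element centroid to its 8 corner nodes, in the
#' canonical (VTK hexahedron) corner order. They are identical for every
#' element of the cubic lattice: all components are +/- L/2 and the offsets
#' sum to the zero vector.
#'
#' @param L Voxel edge length in mm.
#' @return An 8 x 3 numeric matrix of offsets (mm).
#' @export
path_vectors <- function(L = 1) {
  (CORNER_OFFSETS - 0.5) * L
}

#' Apply a batch of spawn requests
#'
#' Creates one callus element per distinct requested target site. Requests
#' are first put in canonical (parent element id, direction) order and
#' deduplicated by target site, so the outcome is independent of request
#' order within a step; requests whose target site is already occupied (by
#' bone, nail, callus or a fragment) are rejected without changing the
#' model. For each created element the 8 corner lattice positions reuse an
#' existing node id when present and create a node otherwise.
#'
#' @param model A [voxel_model()].
#' @param requests A data.frame with columns `element` (parent id) and `dir`
#'   (1..6), e.g. from [accrue_and_select()].
#' @return A list with the updated `model` and a `report` containing
#'   `created` (data.frame: new element id, parent, dir, site), `rejected`
#'   (occupied-target requests), `created_nodes` (new node ids), `conn_new`
#'   and `is_new_node` (per created element), and `parent_face` (the 4
#'   parent-face node ids per created element).
#' @export
spawn_elements <- function(model, requests) {
  stopifnot(inherits(model, "voxel_model"))
  empty_report <- list(
    created = data.frame(element = integer(0), parent = integer(0),
                         dir = integer(0)),
    rejected = data.frame(parent = integer(0), dir = integer(0)),
    created_nodes = integer(0),
    conn_new = matrix(integer(0), 0L, 8L),
    is_new_node = matrix(logical(0), 0L, 8L),
    parent_face = matrix(integer(0), 0L, 4L)
  )
  if (is.null(requests) || nrow(requests) == 0L)
    return(list(model = model, report = empty_report))

  parent <- as.integer(requests$element)
  dir <- as.integer(requests$dir)
  if (any(parent < 1L | parent > n_elements(model)))
    stop("spawn request references an unknown parent element")
  if (any(dir < 1L | dir > 6L)) stop("invalid growth direction")

  ord <- order(parent, dir)
  parent <- parent[ord]; dir <- dir[ord]
  tgt <- model$elem_site[parent, , drop = FALSE] + DIRECTIONS[dir, , drop = FALSE]
  if (!all(sites_in_bounds(model$lattice, tgt)))
    stop("spawn target outside the lattice")
  keys <- site_key(model$lattice, tgt)
  first <- !duplicated(keys)
  parent <- parent[first]; dir <- dir[first]
  tgt <- tgt[first, , drop = FALSE]

  occupied <- model$elem_at[site_key(model$lattice, tgt)] > 0L
  rejected <- data.frame(parent = parent[occupied], dir = dir[occupied])
  parent <- parent[!occupied]; dir <- dir[!occupied]
  tgt <- tgt[!occupied, , drop = FALSE]
  if (!nrow(tgt)) {
    empty_report$rejected <- rejected
    return(list(model = model, report = empty_report))
  }

  res <- add_elements(model, tgt, material = "callus", fragment = 0L,
                      inert = FALSE)
  parent_face <- matrix(0L, nrow(tgt), 4L)
  for (d in seq_len(6L)) {
    rows <- which(dir == d)
    if (length(rows))
      parent_face[rows, ] <- model$conn[parent[rows], FACE_CORNERS[d, ],
                                        drop = FALSE]
  }
  # integrity: the target face of the new element must reuse exactly the
  # parent's face nodes (lattice adjacency)
  opp <- c(2L, 1L, 4L, 3L, 6L, 5L)
  for (d in seq_len(6L)) {
    rows <- which(dir == d)
    if (!length(rows)) next
    shared <- res$conn_new[rows, FACE_CORNERS[opp[d], ], drop = FALSE]
    if (!all(sort_rows(shared) == sort_rows(parent_face[rows, , drop = FALSE])))
      stop("integrity error: inconsistent node ids on a shared face")
  }
  report <- list(
    created = data.frame(element = res$element_ids, parent = parent,
                         dir = dir),
    rejected = rejected,
    created_nodes = res$created_nodes,
    conn_new = res$conn_new,
    is_new_node = res$is_new_node,
    parent_face = parent_face
  )
  list(model = res$model, report = report)
}

sort_rows <- function(m) {
  t(apply(m, 1L, sort))
}

#' Apply a single spawn request
#'
#' Convenience wrapper over [spawn_elements()] for one `(parent, direction)`
#' request; validates the centroid index first.
#'
#' @param model A [voxel_model()].
#' @param index A current [build_centroid_index()].
#' @param req A list or one-row data.frame with `element` and `dir`.
#' @return As [spawn_elements()].
#' @export
spawn_element <- function(model, index, req) {
  if (index$n != n_elements(model)) stop("integrity error: stale centroid index")
  spawn_elements(model, data.frame(element = req$element, dir = req$dir))
}

#' Initialize concentration fields on newly created nodes
#'
#' Gives every node created by a spawn, per species, the mean of the parent
#' face's 4 nodal values (a smooth continuation of the field into the new
#' element); reused nodes are untouched. When several new elements created
#' the same node in one batch, the first creating element (in report order)
#' provides the value.
#'
#' @param fields [concentration_fields()] extended to cover the new nodes.
#' @param report Spawn report from [spawn_elements()].
#' @param model The updated [voxel_model()].
#' @return The updated fields.
#' @export
init_new_nodes <- function(fields, report, model) {
  if (!length(report$created_nodes)) return(fields)
  if (max(report$conn_new) > n_nodes(model) ||
      max(report$parent_face) > n_nodes(model))
    stop("report references unknown nodes")
  for (sp in c("msc", "cho")) {
    vals <- fields[[sp]]
    if (length(vals) < n_nodes(model))
      vals <- c(vals, numeric(n_nodes(model) - length(vals)))
    face_mean <- rowMeans(matrix(vals[report$parent_face],
                                 nrow = nrow(report$parent_face)))
    seen <- logical(length(vals))
    for (e in seq_len(nrow(report$conn_new))) {
      nn <- report$conn_new[e, report$is_new_node[e, ]]
      nn <- nn[!seen[nn]]
      vals[nn] <- face_mean[e]
      seen[nn] <- TRUE
    }
    fields[[sp]] <- vals
  }
  fields
}
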