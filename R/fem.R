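# Finite-element solution of Fick's second law, dc/dt = D * Laplacian(c),
# on the voxel mesh: trilinear (8-node) hexahedral elements, consistent mass
# matrix, backward-Euler time stepping
#   (M/dt + N) c_{t+dt} = f + (M/dt) c_t
# with essential (Dirichlet) conditions enforced by exact row/column
# elimination with right-hand-side correction.

#' Convert a diffusion coefficient from um^2/min to mm^2/day
#'
#' Material diffusivities are conventionally tabulated in um^2/min; the
#' internal unit system is mm and day, so the conversion factor is
#' `1440 * 1e-6`.
#'
#' @param value Diffusion coefficient(s) in um^2/min; must be >= 0.
#' @return The coefficient(s) in mm^2/day.
#' @examples
#' convert_diffusivity(100)  # bone marrow: 0.144 mm^2/day
#' @export
convert_diffusivity <- function(value) {
  if (any(!is.finite(value)) || any(value < 0))
    stop("diffusion coefficients must be finite and >= 0")
  value * 1440 * 1e-6
}

# 2-point Gauss abscissae on [-1, 1]; exact for the (per-axis quadratic)
# products of trilinear shape functions and their gradients.
GAUSS_2 <- c(-1, 1) / sqrt(3)

# Trilinear shape functions and local-coordinate gradients at local point
# (xi, eta, zeta) in [-1,1]^3, in VTK corner order.
shape_hex8 <- function(xi, eta, zeta) {
  sg <- 2 * CORNER_OFFSETS - 1   # corner signs (+/-1) per axis
  Nf <- (1 + sg[, 1L] * xi) * (1 + sg[, 2L] * eta) * (1 + sg[, 3L] * zeta) / 8
  dN <- cbind(
    sg[, 1L] * (1 + sg[, 2L] * eta) * (1 + sg[, 3L] * zeta),
    sg[, 2L] * (1 + sg[, 1L] * xi) * (1 + sg[, 3L] * zeta),
    sg[, 3L] * (1 + sg[, 1L] * xi) * (1 + sg[, 2L] * eta)
  ) / 8
  list(N = Nf, dN = dN)
}

#' Elemental mass and diffusion matrices for a cubic hexahedron
#'
#' Computes the 8x8 consistent mass matrix `Me` (integrals of shape-function
#' products over the cube of side `L`) and the diffusion/stiffness matrix
#' `Ne = D * integral(grad phi_i . grad phi_j)` by full 2x2x2 Gauss
#' quadrature, which is exact for trilinear shape-function products. The
#' boundary-flux load `fe` is zero under natural (zero-flux) conditions.
#'
#' @param L Element edge length in mm (> 0).
#' @param D Diffusion coefficient in mm^2/day (>= 0).
#' @return A list with `Me` (mm^3), `Ne` (mm^3/day) and `fe` (zero 8-vector).
#' @export
element_matrices <- function(L, D = 1) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("element edge length `L` must be positive")
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D < 0)
    stop("diffusion coefficient `D` must be >= 0")
  Me <- matrix(0, 8L, 8L)
  Ke <- matrix(0, 8L, 8L)
  detJ <- (L / 2)^3          # cube Jacobian determinant
  gscale <- 2 / L            # local-to-physical gradient scaling
  for (xi in GAUSS_2) for (eta in GAUSS_2) for (zeta in GAUSS_2) {
    s <- shape_hex8(xi, eta, zeta)
    Me <- Me + tcrossprod(s$N) * detJ
    G <- s$dN * gscale
    Ke <- Ke + tcrossprod(G) * detJ
  }
  list(Me = Me, Ne = D * Ke, fe = numeric(8L))
}

#' Assemble the global diffusion system on a voxel model
#'
#' Sums elemental mass and diffusion contributions over all diffusive,
#' non-inert elements (the nail and inert fragments carry no concentration
#' and are excluded from the domain). All non-essential boundaries are
#' natural zero-flux surfaces, so the load vector is zero. The system is
#' expressed on the active node set -- the nodes of the assembled elements
#' -- with a `dof_map` from node id to local equation index.
#'
#' @param model A [voxel_model()].
#' @param materials Material table from [default_materials()].
#' @param dirichlet A list with integer `nodes` (global node ids with
#'   prescribed concentration) and numeric `values` (recycled to the same
#'   length), e.g. from [boundary_from_regions()]. Prescribed nodes must
#'   belong to the diffusive domain.
#' @param elements Optional subset of element ids to assemble. Restricting
#'   to the elements that own at least one unconstrained node yields an
#'   identical reduced system when every excluded diffusive element has all
#'   its nodes prescribed (the situation under region boundary conditions);
#'   the simulation loop uses this to keep per-step assembly proportional to
#'   the callus size.
#' @return An object of class `global_system` with sparse `M`, `N`, dense
#'   `f`, the active `nodes`, `dof_map`, and the free/prescribed partition.
#' @export
assemble <- function(model, materials = default_materials(), dirichlet,
                     elements = NULL) {
  stopifnot(inherits(model, "voxel_model"))
  diffusive <- material_property(materials, model$material, "diffusive") &
    !model$inert
  elems <- if (is.null(elements)) which(diffusive) else {
    elements <- as.integer(elements)
    elements[diffusive[elements]]
  }
  if (!length(elems))
    stop("no diffusive domain: model has no diffusive, non-inert elements")

  conn <- model$conn[elems, , drop = FALSE]
  nodes <- sort(unique(as.vector(conn)))
  n_active <- length(nodes)
  dof_map <- integer(n_nodes(model))
  dof_map[nodes] <- seq_len(n_active)

  base <- element_matrices(model$lattice$L, 1)
  Me64 <- as.vector(base$Me)
  Ke64 <- as.vector(base$Ne)
  D_e <- material_property(materials, model$material[elems], "D")

  li <- matrix(dof_map[conn], nrow = length(elems))  # local node indices
  ii <- li[, rep(seq_len(8L), times = 8L), drop = FALSE]
  jj <- li[, rep(seq_len(8L), each = 8L), drop = FALSE]
  xM <- matrix(Me64, nrow = length(elems), ncol = 64L, byrow = TRUE)
  xN <- matrix(Ke64, nrow = length(elems), ncol = 64L, byrow = TRUE) * D_e
  M <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(xM), dims = c(n_active, n_active))
  N <- Matrix::sparseMatrix(i = as.vector(ii), j = as.vector(jj),
                            x = as.vector(xN), dims = c(n_active, n_active))

  dn <- as.integer(dirichlet$nodes)
  dv <- rep_len(as.numeric(dirichlet$values), length(dn))
  if (anyDuplicated(dn)) stop("prescribed node sets must be disjoint")
  if (any(dn < 1L | dn > n_nodes(model))) stop("Dirichlet node id out of range")
  inside <- dof_map[dn] > 0L
  if (is.null(elements) && !all(inside))
    stop("Dirichlet node belongs only to excluded (nail/inert) elements")
  # under reduced assembly, prescribed nodes not touching any assembled
  # element do not enter the system at all
  dn <- dn[inside]
  dv <- dv[inside]
  presc_local <- dof_map[dn]
  free_local <- setdiff(seq_len(n_active), presc_local)

  structure(list(
    M = M, N = N, f = numeric(n_active),
    nodes = nodes, dof_map = dof_map,
    presc_local = presc_local, presc_values = dv,
    presc_keep = which(inside), presc_n_orig = length(inside),
    free_local = free_local,
    cache = new.env(parent = emptyenv())
  ), class = "global_system")
}

#' @export
print.global_system <- function(x, ...) {
  cat(sprintf("<global_system> %d active nodes (%d free, %d prescribed)\n",
              length(x$nodes), length(x$free_local), length(x$presc_local)))
  invisible(x)
}

#' Advance one implicit diffusion step
#'
#' Solves `(M/dt + N) c_{t+dt} = f + (M/dt) c_t` with prescribed values
#' enforced exactly by elimination. The backward-Euler scheme is
#' unconditionally stable, so `dt` may span the diffusive time scale.
#' The sparse Cholesky factorization of the constrained operator is cached
#' on the system and reused while `dt` is unchanged.
#'
#' @param system A [assemble()]d `global_system`.
#' @param c_t Full-length nodal concentration vector (length
#'   `n_nodes(model)`); entries outside the active node set are ignored.
#' @param dt Time step in days (> 0).
#' @param values Optional override of the prescribed values (same order as
#'   the Dirichlet nodes passed to [assemble()]); used to share one
#'   assembled system between species with different boundary levels.
#' @return The updated full-length nodal vector: free active nodes advanced
#'   by one step, prescribed nodes set to their values, other entries
#'   unchanged.
#' @export
fem_step <- function(system, c_t, dt, values = NULL) {
  stopifnot(inherits(system, "global_system"))
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("time step `dt` must be positive")
  v <- if (is.null(values)) system$presc_values else
    rep_len(as.numeric(values), system$presc_n_orig)[system$presc_keep]
  nodes <- system$nodes
  c_loc <- c_t[nodes]
  c_loc[system$presc_local] <- v
  free <- system$free_local
  if (length(free)) {
    key <- paste0("chol_", format(dt, digits = 17))
    if (is.null(system$cache[[key]])) {
      A <- system$M / dt + system$N
      A_ff <- Matrix::forceSymmetric(A[free, free, drop = FALSE])
      system$cache[[key]] <- list(
        ch = Matrix::Cholesky(A_ff, LDL = FALSE),
        A_fp = A[free, system$presc_local, drop = FALSE]
      )
    }
    fac <- system$cache[[key]]
    b <- (system$M %*% c_loc) / dt + system$f
    rhs <- b[free]
    if (length(system$presc_local))
      rhs <- rhs - as.numeric(fac$A_fp %*% v)
    sol <- as.numeric(Matrix::solve(fac$ch, rhs, system = "A"))
    if (any(!is.finite(sol)))
      stop("diffusion solve produced non-finite concentrations")
    c_loc[free] <- sol
  }
  c_t[nodes] <- c_loc
  c_t
}

#' Prescribed-concentration node sets from material regions
#'
#' Builds the essential boundary conditions of the healing simulations: the
#' well-perfused high-diffusivity compartments (marrow/trabecular shaft
#' content and the periosteal shell) act as a cell reservoir held at the
#' high dimensionless concentration, while the cortical region is held at a
#' lower level; every remaining surface is a natural zero-flux boundary, so
#' no cells leave the bone through the outer surface. Nodes incident to
#' inert fragments are excluded (an inert fragment has no concentration and
#' no cell production). With `mode = "ends"` the same material split is
#' prescribed only on the two end cross-sections of the section, leaving the
#' shaft interior free.
#'
#' @param model A [voxel_model()].
#' @param materials Material table (provides the `bc_group` split).
#' @param c_high Dimensionless concentration on the high (reservoir) nodes.
#' @param c_low Dimensionless concentration on cortical nodes
#'   (`0 <= c_low <= c_high`).
#' @param scale Single calibration scale multiplying both prescribed values.
#' @param mode `"regions"` (default) or `"ends"`.
#' @return A list with `nodes`, `values` (a list per species would carry the
#'   same nodes; values here are a single numeric vector), and the node
#'   counts per group.
#' @export
boundary_from_regions <- function(model, materials = default_materials(),
                                  c_high = 1, c_low = 0.3, scale = 1,
                                  mode = c("regions", "ends")) {
  mode <- match.arg(mode)
  if (c_low < 0 || c_low > c_high)
    stop("`c_low` must satisfy 0 <= c_low <= c_high")
  grp <- material_property(materials, model$material, "bc_group")
  sel_hi <- which(grp %in% "high" & !model$inert)
  sel_lo <- which(grp %in% "low" & !model$inert)
  nodes_hi <- unique(as.vector(model$conn[sel_hi, , drop = FALSE]))
  nodes_lo <- unique(as.vector(model$conn[sel_lo, , drop = FALSE]))
  k <- model$elem_site[, 3L]
  kz <- model$node_xyz[, 3L]
  on_ends <- kz == min(k) | kz == max(k) + 1L
  # cortical concentration is prescribed only on the end cross-sections;
  # the cortical volume itself diffuses freely (so bone surfaces uncovered
  # by the fracture can be charged by the callus that envelops them)
  nodes_lo <- nodes_lo[on_ends[nodes_lo]]
  if (mode == "ends") nodes_hi <- nodes_hi[on_ends[nodes_hi]]
  nodes_lo <- setdiff(nodes_lo, nodes_hi)
  list(nodes = c(nodes_hi, nodes_lo),
       values = c(rep(c_high * scale, length(nodes_hi)),
                  rep(c_low * scale, length(nodes_lo))),
       n_high = length(nodes_hi), n_low = length(nodes_lo))
}
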