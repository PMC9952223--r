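# Independent oracles used by the tests. Everything here is written from
# first principles (closed forms, dense linear algebra, exhaustive scans)
# and deliberately shares no code path with the package implementation.

# --- closed-form hexahedral element matrices (tensor products) -------------

# 1-D linear-element mass and stiffness on [0, L]:
#   M1 = L/6 [[2,1],[1,2]],  K1 = 1/L [[1,-1],[-1,1]]
# The 3-D trilinear matrices are tensor products over the axes, evaluated
# per corner pair in the VTK ordering.
oracle_element_matrices <- function(L, D = 1) {
  corners <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
  )
  M1 <- L / 6 * rbind(c(2, 1), c(1, 2))
  K1 <- 1 / L * rbind(c(1, -1), c(-1, 1))
  Me <- matrix(0, 8, 8)
  Ke <- matrix(0, 8, 8)
  for (p in 1:8) for (q in 1:8) {
    mm <- vapply(1:3, function(d) M1[corners[p, d] + 1, corners[q, d] + 1],
                 numeric(1))
    kk <- vapply(1:3, function(d) K1[corners[p, d] + 1, corners[q, d] + 1],
                 numeric(1))
    Me[p, q] <- prod(mm)
    Ke[p, q] <- sum(vapply(1:3, function(d) kk[d] * prod(mm[-d]), numeric(1)))
  }
  list(Me = Me, Ne = D * Ke)
}

# --- direct transcription of the sigmoid law -------------------------------

oracle_phi <- function(a, b, alpha0, beta0, alpha, beta) {
  k <- 1 / ((1 + exp(-a * (1 - alpha0))) * (1 + exp(-b * (1 - beta0))))
  A <- 1 / (4 * k - 1)
  4 * A / ((1 + exp(-a * (alpha - alpha0))) * (1 + exp(-b * (beta - beta0)))) - A
}

# --- exhaustive lattice scans ----------------------------------------------

# Count of distinct corner lattice points of a set of element sites.
oracle_lattice_point_union <- function(sites) {
  off <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
  )
  corners <- do.call(rbind, lapply(seq_len(nrow(sites)), function(e)
    sweep(off, 2, sites[e, ], "+")))
  nrow(unique(corners))
}

# Brute-force classification of every lattice site of an idealized
# diaphysis by the centroid radial inequalities.
oracle_diaphysis_regions <- function(extents, L, outer_radius,
                                     cortical_thickness,
                                     periosteum_thickness, nail_radius,
                                     length) {
  axis <- c(extents[1] / 2, extents[2] / 2) * L
  canal <- outer_radius - cortical_thickness
  nlay <- floor(length / L)
  counts <- c(nail = 0, marrow = 0, cortical = 0, periosteum = 0)
  for (i in 0:(extents[1] - 1)) for (j in 0:(extents[2] - 1)) {
    r <- sqrt(((i + 0.5) * L - axis[1])^2 + ((j + 0.5) * L - axis[2])^2)
    reg <- if (r < nail_radius) "nail"
    else if (r < canal) "marrow"
    else if (r < outer_radius - periosteum_thickness) "cortical"
    else if (r < outer_radius) "periosteum"
    else NA
    if (!is.na(reg)) counts[reg] <- counts[reg] + nlay
  }
  counts
}

# Brute-force transverse-cutter scan: which bone element centroids fall
# strictly between the two planes.
oracle_transverse_removed <- function(model, center, gap) {
  cz <- (model$elem_site[, 3] + 0.5) * model$lattice$L
  which(abs(cz - center) < gap / 2 & model$material != "nail")
}

# --- dense assembly and one implicit step ----------------------------------

# Dense global matrices by naive per-element accumulation (independent of
# the package's sparse triplet assembly), over the diffusive elements.
oracle_dense_system <- function(model, D_by_material) {
  n <- n_nodes(model)
  M <- matrix(0, n, n)
  N <- matrix(0, n, n)
  for (e in seq_len(n_elements(model))) {
    D <- D_by_material[[model$material[e]]]
    if (is.null(D) || is.na(D)) next
    em <- oracle_element_matrices(model$lattice$L, D)
    idx <- model$conn[e, ]
    M[idx, idx] <- M[idx, idx] + em$Me
    N[idx, idx] <- N[idx, idx] + em$Ne
  }
  list(M = M, N = N)
}

# One backward-Euler step with Dirichlet elimination, dense algebra.
oracle_dense_step <- function(M, N, c_t, dt, presc_nodes, presc_values,
                              active = NULL) {
  n <- length(c_t)
  act <- if (is.null(active)) seq_len(n) else active
  free <- setdiff(act, presc_nodes)
  A <- M / dt + N
  c_new <- c_t
  c_new[presc_nodes] <- presc_values
  b <- (M %*% c_new) / dt
  rhs <- b[free] - A[free, presc_nodes, drop = FALSE] %*% presc_values
  c_new[free] <- solve(A[free, free, drop = FALSE], rhs)
  c_new
}

# --- hand-stepped trace of the three-phase loop on the toy instance --------

# Independent re-implementation of the whole iteration for the two-block
# bar: dense FEM on the occupancy grid, min-over-face-nodes triggering,
# volume accrual, element addition with zero-initialized new nodes.
# Returns the first day on which every gap site is occupied (with the two
# blocks necessarily in contact), i.e. the closure day.
oracle_toy_closure_day <- function(gap = 2, block = 3, dt = 0.25,
                                   horizon = 60, D_trab = 100 * 1440e-6,
                                   D_callus = 50 * 1440e-6,
                                   a = 5, b = 5, alpha0 = 1/32,
                                   beta0 = 1/16, v_max = 5) {
  nz <- 2 * block + gap
  dims <- c(block, block, nz)
  occ <- array("", dim = dims)          # material per site ("" = empty)
  occ[, , 1:block] <- "trabecular"
  occ[, , (block + gap + 1):nz] <- "trabecular"
  gap_k <- (block + 1):(block + gap)

  node_id <- array(0L, dim = dims + 1L) # node ids on the (0-based) corners
  nxyz <- matrix(0L, 0, 3)
  get_node <- function(i, j, k) {       # 0-based corner triple
    if (node_id[i + 1, j + 1, k + 1] == 0L) {
      nxyz <<- rbind(nxyz, c(i, j, k))
      node_id[i + 1, j + 1, k + 1] <<- nrow(nxyz)
    }
    node_id[i + 1, j + 1, k + 1]
  }
  corner_off <- rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
  )
  elem_sites <- which(occ != "", arr.ind = TRUE) - 1L
  elem_sites <- elem_sites[order(elem_sites[, 3], elem_sites[, 2],
                                 elem_sites[, 1]), , drop = FALSE]
  conn <- t(apply(elem_sites, 1, function(s)
    vapply(1:8, function(c8) get_node(s[1] + corner_off[c8, 1],
                                      s[2] + corner_off[c8, 2],
                                      s[3] + corner_off[c8, 3]), integer(1))))

  # sigmoid (independent transcription)
  phi_fun <- function(al, be) oracle_phi(a, b, alpha0, beta0,
                                         pmin(al, 1), pmin(be, 1))

  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  face_corners <- list(c(2, 3, 6, 7), c(1, 4, 5, 8), c(3, 4, 7, 8),
                       c(1, 2, 5, 6), c(5, 6, 7, 8), c(1, 2, 3, 4))

  conc <- numeric(nrow(nxyz))           # same field traced for both species
  presc <- which(nxyz[, 3] == 0 | nxyz[, 3] == nz)
  conc[presc] <- 1
  acc <- new.env(parent = emptyenv())

  steps_per_day <- round(1 / dt)
  for (day in seq_len(horizon)) {
    for (s in seq_len(steps_per_day)) {
      # phase 1: dense implicit diffusion step on the current mesh
      D_map <- list(trabecular = D_trab, callus = D_callus)
      n <- nrow(nxyz)
      M <- matrix(0, n, n); N <- matrix(0, n, n)
      for (e in seq_len(nrow(elem_sites))) {
        mat <- occ[elem_sites[e, 1] + 1, elem_sites[e, 2] + 1,
                   elem_sites[e, 3] + 1]
        em <- oracle_element_matrices(1, D_map[[mat]])
        idx <- conn[e, ]
        M[idx, idx] <- M[idx, idx] + em$Me
        N[idx, idx] <- N[idx, idx] + em$Ne
      }
      conc <- as.numeric(oracle_dense_step(M, N, conc, dt, presc,
                                           rep(1, length(presc))))
      # phase 2: triggers and accrual; phase 3: growth
      requests <- list()
      for (e in seq_len(nrow(elem_sites))) {
        se <- elem_sites[e, ]
        for (d in 1:6) {
          t3 <- se + dirs[d, ]
          if (any(t3 < 0) || any(t3 >= dims)) next
          if (occ[t3[1] + 1, t3[2] + 1, t3[3] + 1] != "") next
          fv <- conc[conn[e, face_corners[[d]]]]
          al <- min(fv)
          if (al < alpha0 || al < beta0) next
          v <- v_max * min(max(phi_fun(al, al), 0), 1)
          key <- paste(e, d)
          cur <- if (is.null(acc[[key]])) 0 else acc[[key]]
          cur <- cur + v * dt
          if (cur >= 1) {
            cur <- cur - 1
            requests[[length(requests) + 1]] <- c(e, d)
          }
          acc[[key]] <- cur
        }
      }
      for (rq in requests) {
        se <- elem_sites[rq[1], ]
        t3 <- se + dirs[rq[2], ]
        if (occ[t3[1] + 1, t3[2] + 1, t3[3] + 1] != "") next
        occ[t3[1] + 1, t3[2] + 1, t3[3] + 1] <- "callus"
        newc <- vapply(1:8, function(c8) get_node(t3[1] + corner_off[c8, 1],
                                                  t3[2] + corner_off[c8, 2],
                                                  t3[3] + corner_off[c8, 3]),
                       integer(1))
        elem_sites <- rbind(elem_sites, t3)
        conn <- rbind(conn, newc)
        if (nrow(nxyz) > length(conc))
          conc <- c(conc, numeric(nrow(nxyz) - length(conc)))
      }
    }
    if (all(occ[, , gap_k] != "")) return(day)
  }
  NA_integer_
}

# --- misc test utilities ---------------------------------------------------

# Occupy the given empty sites with callus via the public spawning API,
# growing inward from whatever faces can reach them.
spawnfill <- function(model, sites) {
  remaining <- sites
  repeat {
    idx <- build_centroid_index(model)
    ids <- index_lookup(idx, remaining)
    remaining <- remaining[ids == 0L, , drop = FALSE]
    if (!nrow(remaining)) break
    faces <- detect_free_faces(model, idx)
    key <- paste(remaining[, 1], remaining[, 2], remaining[, 3])
    hit <- faces[paste(faces$ti, faces$tj, faces$tk) %in% key, ]
    if (!nrow(hit)) stop("cannot reach remaining sites")
    model <- spawn_elements(model, hit)$model
  }
  model
}
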