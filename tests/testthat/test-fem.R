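# Finite-element diffusion: element matrices, assembly, implicit stepping.

test_that("element matrices match the closed-form tensor-product oracle", {
  for (L in c(1, 0.5, 2)) for (D in c(1, 0.144)) {
    em <- element_matrices(L, D)
    or <- oracle_element_matrices(L, D)
    expect_equal(em$Me, or$Me, tolerance = 1e-14)
    expect_equal(em$Ne, or$Ne, tolerance = 1e-14)
  }
})

test_that("element matrices satisfy partition of unity and zero row sums", {
  em <- element_matrices(1, 3)
  expect_equal(sum(em$Me), 1)                      # element volume
  expect_equal(em$Me[1, 1], 1 / 27)                # symbolic diagonal value
  expect_equal(max(abs(rowSums(em$Ne))), 0, tolerance = 1e-13)
  expect_equal(em$fe, numeric(8))
  expect_true(isSymmetric(em$Me) && isSymmetric(em$Ne))
  # Me positive definite, Ne positive semidefinite
  expect_true(all(eigen(em$Me, symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_true(min(eigen(em$Ne, symmetric = TRUE, only.values = TRUE)$values) > -1e-12)
  expect_error(element_matrices(0), "positive")
  expect_error(element_matrices(1, -1), ">= 0")
})

test_that("unit conversion from um^2/min to mm^2/day is exact", {
  expect_equal(convert_diffusivity(100), 0.144)    # bone marrow
  expect_equal(convert_diffusivity(1), 0.00144)    # cortical bone
  expect_equal(convert_diffusivity(0), 0)
  expect_error(convert_diffusivity(-1), ">= 0")
})

test_that("assembly reproduces element matrices and the dense oracle", {
  lat <- voxel_lattice(c(2, 1, 1))
  one <- voxel_model(voxel_lattice(c(1, 1, 1)), rbind(c(0, 0, 0)),
                     material = "marrow")
  mats <- default_materials()
  sys1 <- assemble(one, mats, dirichlet = list(nodes = 1L, values = 0))
  em <- element_matrices(1, mats$D[mats$name == "marrow"])
  expect_equal(as.matrix(sys1$M), em$Me, tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_equal(as.matrix(sys1$N), em$Ne, tolerance = 1e-14,
               ignore_attr = TRUE)

  bar <- voxel_model(lat, rbind(c(0, 0, 0), c(1, 0, 0)), material = "marrow")
  sys <- assemble(bar, mats, dirichlet = list(nodes = 1L, values = 0))
  oracle <- oracle_dense_system(bar, setNames(as.list(mats$D), mats$name))
  expect_equal(as.matrix(sys$M), oracle$M, tolerance = 1e-13,
               ignore_attr = TRUE)
  expect_equal(as.matrix(sys$N), oracle$N, tolerance = 1e-13,
               ignore_attr = TRUE)
  # symmetry of the assembled operators
  expect_equal(as.matrix(sys$M), t(as.matrix(sys$M)))
  expect_equal(as.matrix(sys$N), t(as.matrix(sys$N)))
})

test_that("a nail-only model has no diffusive domain", {
  m <- voxel_model(voxel_lattice(c(2, 1, 1)),
                   rbind(c(0, 0, 0), c(1, 0, 0)), material = "nail")
  expect_error(assemble(m, dirichlet = list(nodes = 1L, values = 0)),
               "no diffusive domain")
})

test_that("a uniform field at the prescribed value is a steady state", {
  m <- voxel_model(voxel_lattice(c(3, 1, 1)),
                   cbind(0:2, 0L, 0L), material = "marrow")
  ends <- which(m$node_xyz[, 1] == 0L)
  sys <- assemble(m, dirichlet = list(nodes = ends, values = 0.7))
  c0 <- rep(0.7, n_nodes(m))
  c1 <- fem_step(sys, c0, dt = 0.5)
  c2 <- fem_step(sys, c1, dt = 0.5)
  expect_equal(c2, c0, tolerance = 1e-12)
})

test_that("the 1-D bar converges to the analytic linear profile", {
  n <- 50L
  m <- voxel_model(voxel_lattice(c(1, 1, n)),
                   cbind(0L, 0L, 0:(n - 1L)), material = "marrow")
  lo <- which(m$node_xyz[, 3] == 0L)
  hi <- which(m$node_xyz[, 3] == n)
  sys <- assemble(m, dirichlet = list(nodes = c(lo, hi),
                                      values = c(rep(0, 4), rep(1, 4))))
  cc <- numeric(n_nodes(m))
  for (i in 1:80) cc <- fem_step(sys, cc, dt = 1e5)
  expect_lt(max(abs(cc - m$node_xyz[, 3] / n)), 1e-8)
})

test_that("one implicit step equals the dense constrained solve", {
  m <- voxel_model(voxel_lattice(c(2, 2, 2)),
                   as.matrix(expand.grid(0:1, 0:1, 0:1)),
                   material = "marrow")
  mats <- default_materials()
  presc <- which(m$node_xyz[, 3] == 0L)
  vals <- rep(1, length(presc))
  sys <- assemble(m, mats, dirichlet = list(nodes = presc, values = vals))
  set.seed(42)
  c0 <- runif(n_nodes(m))
  c0[presc] <- 1
  got <- fem_step(sys, c0, dt = 0.25)
  oracle <- oracle_dense_system(m, setNames(as.list(mats$D), mats$name))
  want <- oracle_dense_step(oracle$M, oracle$N, c0, 0.25, presc, vals)
  expect_equal(got, as.numeric(want), tolerance = 1e-10)
})

test_that("implicit stepping is stable over four orders of magnitude in dt", {
  n <- 10L
  m <- voxel_model(voxel_lattice(c(1, 1, n)),
                   cbind(0L, 0L, 0:(n - 1L)), material = "marrow")
  lo <- which(m$node_xyz[, 3] == 0L)
  hi <- which(m$node_xyz[, 3] == n)
  sys <- assemble(m, dirichlet = list(nodes = c(lo, hi),
                                      values = c(rep(0, 4), rep(1, 4))))
  for (dt in c(0.01, 0.1, 1, 10, 100)) {
    cc <- numeric(n_nodes(m))
    worst <- 0
    for (i in 1:30) {
      cc <- fem_step(sys, cc, dt = dt)
      worst <- max(worst, -min(cc), max(cc) - 1)
    }
    # the consistent mass matrix admits small transient over/undershoots at
    # low Fourier number; the scheme stays bounded and decays to steady
    expect_lt(worst, 0.05, label = paste("dt", dt))
    expect_false(any(!is.finite(cc)))
  }
})

test_that("time-stepping error on the transient bar is first order in dt", {
  # 1-D diffusion with ends 0/1 from a zero start: compare against a
  # fine-step reference at t = 10 days and check the error ratio when dt
  # halves (backward Euler is O(dt))
  n <- 10L
  m <- voxel_model(voxel_lattice(c(1, 1, n)),
                   cbind(0L, 0L, 0:(n - 1L)), material = "marrow")
  lo <- which(m$node_xyz[, 3] == 0L)
  hi <- which(m$node_xyz[, 3] == n)
  sys <- assemble(m, dirichlet = list(nodes = c(lo, hi),
                                      values = c(rep(0, 4), rep(1, 4))))
  run_to <- function(dt, t_end = 10) {
    cc <- numeric(n_nodes(m))
    for (i in seq_len(round(t_end / dt))) cc <- fem_step(sys, cc, dt = dt)
    cc
  }
  ref <- run_to(0.03125)
  e1 <- max(abs(run_to(0.5) - ref))
  e2 <- max(abs(run_to(0.25) - ref))
  expect_gt(e1 / e2, 1.6)   # halving dt roughly halves the error
  expect_lt(e1 / e2, 2.6)
})

test_that("re-assembly on a grown mesh preserves old interior entries", {
  m <- voxel_model(voxel_lattice(c(3, 1, 1)),
                   rbind(c(0, 0, 0), c(1, 0, 0)), material = "marrow")
  bc <- list(nodes = 1L, values = 0)
  sys0 <- assemble(m, dirichlet = bc)
  grown <- spawn_elements(m, data.frame(element = 2L, dir = 1L))$model
  sys1 <- assemble(grown, dirichlet = bc)
  old_nodes <- sys0$nodes
  untouched <- setdiff(old_nodes, grown$conn[3, ])
  i0 <- sys0$dof_map[untouched]
  i1 <- sys1$dof_map[untouched]
  expect_equal(as.matrix(sys0$M)[i0, i0], as.matrix(sys1$M)[i1, i1],
               ignore_attr = TRUE)
  expect_equal(as.matrix(sys0$N)[i0, i0], as.matrix(sys1$N)[i1, i1],
               ignore_attr = TRUE)
})

test_that("region boundary sets split by material and respect inert fragments", {
  m <- generate_diaphysis(outer_radius = 8, cortical_thickness = 3,
                          nail_diameter = 5, length = 8, margin = 3)
  bc <- boundary_from_regions(m)
  expect_gt(bc$n_high, 0)
  expect_gt(bc$n_low, 0)
  expect_false(anyDuplicated(bc$nodes) > 0)
  # high set contains every marrow/periosteum-incident node
  hi_nodes <- unique(as.vector(m$conn[m$material %in% c("marrow", "periosteum"), ]))
  expect_setequal(bc$nodes[seq_len(bc$n_high)], hi_nodes)
  # "ends" mode prescribes only on the two end cross-sections
  bce <- boundary_from_regions(m, mode = "ends")
  kz <- m$node_xyz[bce$nodes, 3]
  expect_true(all(kz == 0L | kz == max(m$elem_site[, 3]) + 1L))
  expect_error(boundary_from_regions(m, c_low = 2), "c_low")
})
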