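# Sigmoid growth law, free-face detection, candidate selection, accrual.

test_that("sigmoid normalization satisfies both corner conditions exactly", {
  gf <- growth_function(a = 5, b = 5, alpha0 = 1/32, beta0 = 1/16, v_max = 5)
  expect_equal(phi(gf, gf$alpha0, gf$beta0), 0, tolerance = 1e-12)
  expect_equal(phi(gf, 1, 1), 1, tolerance = 1e-12)
  # also away from the tabulated parameters
  for (ab in list(c(1, 2), c(10, 3), c(100, 100))) {
    g2 <- growth_function(a = ab[1], b = ab[2], alpha0 = 0.2, beta0 = 0.1)
    expect_lt(abs(phi(g2, 0.2, 0.1)), 1e-12)
    expect_lt(abs(phi(g2, 1, 1) - 1), 1e-12)
  }
  expect_error(growth_function(a = -1), "positive")
  expect_error(growth_function(alpha0 = 1.2), "thresholds")
})

test_that("phi matches a direct formula transcription and is monotone/bounded", {
  gf <- growth_function()
  expect_equal(phi(gf, 0.5, 0.5),
               oracle_phi(5, 5, 1/32, 1/16, 0.5, 0.5), tolerance = 1e-14)
  grid <- seq(gf$alpha0, 1, length.out = 50)
  gridb <- seq(gf$beta0, 1, length.out = 50)
  for (ab in list(c(1, 1), c(2, 5), c(5, 5), c(10, 2), c(100, 10))) {
    g2 <- growth_function(a = ab[1], b = ab[2])
    vals <- outer(grid, gridb, function(x, y) phi(g2, x, y))
    expect_true(all(vals >= -1e-12 & vals <= 1 + 1e-12))
    # nondecreasing in each argument on the domain grid
    expect_true(all(diff(vals) >= -1e-12))
    expect_true(all(t(diff(t(vals))) >= -1e-12))
  }
  # increasing a steepens the alpha response: the maximum slope of
  # phi(., 1) over the domain grows with a
  slope_prev <- 0
  xs <- seq(1/32, 1, length.out = 400)
  for (a in c(1, 2, 5, 10, 100)) {
    ga <- growth_function(a = a, b = 5)
    slope <- max(diff(phi(ga, xs, 1)) / diff(xs))
    expect_gt(slope, slope_prev)
    slope_prev <- slope
  }
})

test_that("growth velocity obeys the threshold cutoff and the v_max cap", {
  gf <- growth_function()
  expect_equal(growth_velocity(gf, 1, 1), 5)       # v_max at saturation
  expect_equal(growth_velocity(gf, gf$alpha0 / 2, 1), 0)
  expect_equal(growth_velocity(gf, 1, gf$beta0 / 2), 0)
  v <- growth_velocity(gf, 0.5, 0.5)
  expect_equal(v, 5 * oracle_phi(5, 5, 1/32, 1/16, 0.5, 0.5),
               tolerance = 1e-12)
  expect_true(all(growth_velocity(gf, runif(20), runif(20)) <= 5))
  expect_equal(growth_velocity(gf, 2, 2), 5)       # clamped above 1
  expect_error(growth_velocity(gf, -0.1, 0.5), "non-negative")
})

test_that("free-face detection counts exposed faces correctly", {
  lat <- voxel_lattice(c(5, 5, 5))
  one <- voxel_model(lat, rbind(c(2, 2, 2)), material = "callus")
  f1 <- detect_free_faces(one, build_centroid_index(one))
  expect_equal(nrow(f1), 6L)
  two <- voxel_model(lat, rbind(c(2, 2, 2), c(3, 2, 2)), material = "callus")
  f2 <- detect_free_faces(two, build_centroid_index(two))
  expect_equal(nrow(f2), 10L)
  expect_equal(sum(f2$element == 1L), 5L)
  # centre of a full 3x3x3 block has no free faces
  block <- voxel_model(lat, as.matrix(expand.grid(1:3, 1:3, 1:3)),
                       material = "callus")
  fb <- detect_free_faces(block, build_centroid_index(block))
  centre <- index_lookup(build_centroid_index(block), c(2, 2, 2))
  expect_false(centre %in% fb$element)
  # nail elements never grow; stale index is an integrity error
  nail <- voxel_model(lat, rbind(c(2, 2, 2)), material = "nail")
  expect_equal(nrow(detect_free_faces(nail, build_centroid_index(nail))), 0L)
  expect_error(detect_free_faces(two, build_centroid_index(one)), "stale")
})

test_that("free-face detection equals the inverse-connectivity method", {
  # the node-sharing oracle: a face is free iff no other element shares all
  # 4 of its face nodes
  lat <- voxel_lattice(c(4, 4, 4))
  set.seed(7)
  all_sites <- as.matrix(expand.grid(0:3, 0:3, 0:3))
  sites <- all_sites[sample(64, 30), ]
  m <- voxel_model(lat, sites, material = "callus")
  got <- detect_free_faces(m, build_centroid_index(m))
  got_keys <- sort(paste(got$element, got$dir))
  want <- character(0)
  for (e in seq_len(n_elements(m))) for (d in 1:6) {
    fn <- m$conn[e, callusim:::FACE_CORNERS[d, ]]
    shared <- vapply(seq_len(n_elements(m)), function(o)
      o != e && all(fn %in% m$conn[o, ]), logical(1))
    tgt <- m$elem_site[e, ] + callusim:::DIRECTIONS[d, ]
    inside <- all(tgt >= 0) && all(tgt < 4)
    if (!any(shared) && inside) want <- c(want, paste(e, d))
  }
  expect_equal(got_keys, sort(want))
})

test_that("candidate selection matches per-face recomputation for both rules", {
  lat <- voxel_lattice(c(4, 4, 4))
  m <- voxel_model(lat, rbind(c(1, 1, 1), c(2, 1, 1)), material = "callus")
  gf <- growth_function()
  set.seed(11)
  fields <- concentration_fields(m)
  fields$msc <- runif(n_nodes(m))
  fields$cho <- runif(n_nodes(m))
  faces <- detect_free_faces(m, build_centroid_index(m))
  for (rule in c("min", "mean")) {
    cands <- eligible_candidates(faces, fields, gf, m, aggregate = rule)
    for (i in seq_len(nrow(faces))) {
      fn <- m$conn[faces$element[i], callusim:::FACE_CORNERS[faces$dir[i], ]]
      agg <- if (rule == "min") min else mean
      al <- agg(fields$msc[fn]); be <- agg(fields$cho[fn])
      hit <- which(cands$element == faces$element[i] & cands$dir == faces$dir[i])
      if (al >= gf$alpha0 && be >= gf$beta0) {
        expect_length(hit, 1L)
        expect_equal(cands$velocity[hit], growth_velocity(gf, al, be))
      } else {
        expect_length(hit, 0L)
      }
    }
  }
  # all-zero fields yield no candidates; saturated fields yield all at v_max
  z <- concentration_fields(m)
  expect_equal(nrow(eligible_candidates(faces, z, gf, m)), 0L)
  s <- concentration_fields(m, init = 1)
  cs <- eligible_candidates(faces, s, gf, m)
  expect_equal(nrow(cs), nrow(faces))
  expect_true(all(cs$velocity == gf$v_max))
})

test_that("candidate selection is invariant under element reordering", {
  lat <- voxel_lattice(c(4, 4, 4))
  sites <- rbind(c(1, 1, 1), c(2, 1, 1), c(1, 2, 1))
  gf <- growth_function()
  key_set <- function(perm) {
    m <- voxel_model(lat, sites[perm, ], material = "callus")
    f <- concentration_fields(m, init = 1)
    cands <- eligible_candidates(detect_free_faces(m, build_centroid_index(m)),
                                 f, gf, m)
    sort(paste(cands$ti, cands$tj, cands$tk))
  }
  expect_equal(key_set(1:3), key_set(c(3, 1, 2)))
})

test_that("volume accrual spawns at L^3 and carries the remainder", {
  gf <- growth_function()
  cand <- data.frame(element = 1L, dir = 1L, ti = 1L, tj = 0L, tk = 0L,
                     alpha = 1, beta = 1, velocity = 5)
  acc <- numeric(6)
  r1 <- accrue_and_select(cand, dt = 0.1, acc)      # 0.5 accrued
  expect_equal(nrow(r1$requests), 0L)
  r2 <- accrue_and_select(cand, dt = 0.1, r1$acc)   # reaches 1.0
  expect_equal(nrow(r2$requests), 1L)
  expect_equal(r2$acc[1], 0)
  # velocity 0 never spawns
  cand0 <- transform(cand, velocity = 0)
  r <- list(acc = numeric(6))
  for (i in 1:50) r <- accrue_and_select(cand0, dt = 1, r$acc)
  expect_equal(r$acc[1], 0)
  # remainder carry: v = 3, dt = 0.25 spawns on step 2 with 0.5 left
  cand3 <- transform(cand, velocity = 3)
  r <- accrue_and_select(cand3, dt = 0.25, numeric(6))
  expect_equal(nrow(r$requests), 0L)
  r <- accrue_and_select(cand3, dt = 0.25, r$acc)
  expect_equal(nrow(r$requests), 1L)
  expect_equal(r$acc[1], 0.5)
})
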