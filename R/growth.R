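# Growth trigger and control: which free faces may grow, and how fast.
#
# The dimensionless concentrations alpha (MSC) and beta (chondrocyte) gate
# growth through thresholds (alpha0, beta0); above threshold the face grows
# with volumetric velocity v = v_max * phi(alpha, beta), where phi is a
# normalized sigmoid-like surface on [alpha0, 1] x [beta0, 1] whose slopes a
# and b summarize the levels of the signalling molecules (TNF-alpha,
# BMP-2) that modulate healing rate.

#' Construct the normalized sigmoid growth function
#'
#' Builds the growth-velocity law
#' \deqn{v = v_{max}\,\varphi(\alpha,\beta), \qquad
#'   \varphi(\alpha,\beta) = \frac{4A}{[1+e^{-a(\alpha-\alpha_0)}]
#'   [1+e^{-b(\beta-\beta_0)}]} + B}
#' with the normalization constants chosen so that
#' \eqn{\varphi(\alpha_0,\beta_0) = 0} and \eqn{\varphi(1,1) = 1} hold
#' exactly: with \eqn{k = 1/([1+e^{-a(1-\alpha_0)}][1+e^{-b(1-\beta_0)}])}
#' this gives \eqn{A = 1/(4k - 1)} and \eqn{B = -A}.
#'
#' @param a,b Positive slope constants (dimensionless); larger values steepen
#'   the response to the MSC and chondrocyte concentrations respectively.
#' @param alpha0,beta0 Dimensionless trigger thresholds in (0, 1).
#' @param v_max Maximum growth velocity in mm^3/day.
#' @return An object of class `growth_function` holding `a`, `b`, `alpha0`,
#'   `beta0`, `k`, `A`, `B`, `v_max`.
#' @examples
#' gf <- growth_function()           # defaults: a = b = 5, 1/32, 1/16, 5
#' phi(gf, gf$alpha0, gf$beta0)      # 0
#' phi(gf, 1, 1)                     # 1
#' @export
growth_function <- function(a = 5, b = 5, alpha0 = 1/32, beta0 = 1/16,
                            v_max = 5) {
  if (!is.numeric(a) || !is.numeric(b) || a <= 0 || b <= 0)
    stop("slope constants `a` and `b` must be positive")
  if (alpha0 <= 0 || alpha0 >= 1 || beta0 <= 0 || beta0 >= 1)
    stop("thresholds `alpha0`, `beta0` must lie in (0, 1)")
  if (!is.numeric(v_max) || v_max < 0)
    stop("`v_max` must be >= 0")
  k <- 1 / ((1 + exp(-a * (1 - alpha0))) * (1 + exp(-b * (1 - beta0))))
  A <- 1 / (4 * k - 1)
  structure(list(a = a, b = b, alpha0 = alpha0, beta0 = beta0,
                 k = k, A = A, B = -A, v_max = v_max),
            class = "growth_function")
}

#' @export
print.growth_function <- function(x, ...) {
  cat(sprintf("<growth_function> a=%g b=%g alpha0=%g beta0=%g v_max=%g mm^3/day (A=%.6f)\n",
              x$a, x$b, x$alpha0, x$beta0, x$v_max, x$A))
  invisible(x)
}

#' Evaluate the normalized sigmoid surface
#'
#' Vectorized over `alpha` and `beta`; arguments above 1 are clamped to 1
#' (the dimensionless concentrations are defined relative to their maxima).
#'
#' @param gf A [growth_function()].
#' @param alpha,beta Dimensionless concentrations (>= 0).
#' @return phi values; 0 at `(alpha0, beta0)` and 1 at `(1, 1)`.
#' @export
phi <- function(gf, alpha, beta) {
  stopifnot(inherits(gf, "growth_function"))
  alpha <- pmin(alpha, 1)
  beta <- pmin(beta, 1)
  4 * gf$A / ((1 + exp(-gf$a * (alpha - gf$alpha0))) *
                (1 + exp(-gf$b * (beta - gf$beta0)))) + gf$B
}

#' Growth velocity for given dimensionless concentrations
#'
#' Returns 0 below either trigger threshold; above both thresholds returns
#' `v_max * phi(alpha, beta)`, clamped to `[0, v_max]`.
#'
#' @inheritParams phi
#' @return Velocity in mm^3/day (vectorized).
#' @export
growth_velocity <- function(gf, alpha, beta) {
  if (any(alpha < 0) || any(beta < 0))
    stop("concentrations must be non-negative")
  v <- gf$v_max * pmin(pmax(phi(gf, alpha, beta), 0), 1)
  v[alpha < gf$alpha0 | beta < gf$beta0] <- 0
  v
}

#' Detect free element faces
#'
#' Using the centroid index, a face is free when the neighbouring lattice
#' site in one of the six axial directions holds no element centroid and
#' lies inside the lattice. Only growable, non-inert elements (bone
#' substrate and callus; never the nail) whose centroid lies inside the
#' axial growth region of interest are examined, so remote surfaces far
#' from the fracture do not sprout callus.
#'
#' @param model A [voxel_model()].
#' @param index A current [build_centroid_index()]; a stale index (size
#'   mismatch with the model) is an integrity error.
#' @param roi Optional axial band `c(z_min, z_max)` in mm on element
#'   centroids; `NULL` considers every element.
#' @param materials Material table (provides the `growable` flag).
#' @return A data.frame with columns `element`, `dir` (1..6 for +x, -x,
#'   +y, -y, +z, -z) and the target site `ti`, `tj`, `tk`.
#' @export
detect_free_faces <- function(model, index, roi = NULL,
                              materials = default_materials()) {
  stopifnot(inherits(index, "centroid_index"))
  if (index$n != n_elements(model) ||
      !identical(index$extents, model$lattice$extents))
    stop("integrity error: centroid index is stale")
  growable <- material_property(materials, model$material, "growable") &
    !model$inert
  elems <- which(growable)
  if (!is.null(roi) && length(elems)) {
    cz <- (model$elem_site[elems, 3L] + 0.5) * model$lattice$L +
      model$lattice$origin[3L]
    elems <- elems[cz >= roi[1L] & cz <= roi[2L]]
  }
  out <- vector("list", 6L)
  for (d in seq_len(6L)) {
    tgt <- sweep(model$elem_site[elems, , drop = FALSE], 2L,
                 DIRECTIONS[d, ], "+")
    free <- index_lookup(index, tgt) == 0L & sites_in_bounds(model$lattice, tgt)
    out[[d]] <- data.frame(element = elems[free], dir = rep.int(d, sum(free)),
                           ti = tgt[free, 1L], tj = tgt[free, 2L],
                           tk = tgt[free, 3L])
  }
  do.call(rbind, out)
}

# Aggregate per-species nodal values over the 4 nodes of each listed face.
face_aggregate <- function(model, faces, values, aggregate) {
  k <- nrow(faces)
  out <- numeric(k)
  for (d in seq_len(6L)) {
    rows <- which(faces$dir == d)
    if (!length(rows)) next
    idx <- model$conn[faces$element[rows], FACE_CORNERS[d, ], drop = FALSE]
    vals <- matrix(values[idx], nrow = length(rows))
    out[rows] <- if (aggregate == "min") do.call(pmin, asplit(vals, 2L))
    else rowMeans(vals)
  }
  out
}

#' Turn free faces into growth candidates
#'
#' For each free face the dimensionless concentrations of the two species
#' are aggregated over the 4 face nodes and compared with the trigger
#' thresholds; faces with `alpha >= alpha0` and `beta >= beta0` become
#' candidates with velocity [growth_velocity()]. The default aggregation is
#' the minimum over the face nodes, so a face only grows once cells have
#' actually reached its whole front; the mean is available as an
#' alternative.
#'
#' @param faces Free-face table from [detect_free_faces()].
#' @param fields Concentration fields from [concentration_fields()].
#' @param gf A [growth_function()].
#' @param model The [voxel_model()] the faces refer to.
#' @param aggregate `"min"` (default) or `"mean"`.
#' @return `faces` augmented with `alpha`, `beta`, `velocity`, restricted to
#'   eligible candidates.
#' @export
eligible_candidates <- function(faces, fields, gf, model,
                                aggregate = c("min", "mean")) {
  aggregate <- match.arg(aggregate)
  if (is.null(faces) || nrow(faces) == 0L) {
    return(cbind(faces, alpha = numeric(0), beta = numeric(0),
                 velocity = numeric(0)))
  }
  need <- max(model$conn[faces$element, ])
  if (length(fields$msc) < need || length(fields$cho) < need)
    stop("missing nodal values for listed elements")
  alpha <- face_aggregate(model, faces, fields$msc / fields$c_max[["msc"]],
                          aggregate)
  beta <- face_aggregate(model, faces, fields$cho / fields$c_max[["cho"]],
                         aggregate)
  ok <- alpha >= gf$alpha0 & beta >= gf$beta0
  faces <- faces[ok, , drop = FALSE]
  faces$alpha <- alpha[ok]
  faces$beta <- beta[ok]
  faces$velocity <- growth_velocity(gf, faces$alpha, faces$beta)
  faces
}

#' Accrue face growth and select spawn requests
#'
#' Maps the volumetric growth velocity (mm^3/day) to discrete element
#' additions: each candidate face accrues `velocity * dt` toward the element
#' volume `L^3`; a face whose accumulator reaches `L^3` emits one spawn
#' request and retains the remainder. Accumulators of faces that cease to be
#' candidates persist (the concentration may return), and stale accumulators
#' of faces that later become occupied simply never trigger.
#'
#' @param candidates Candidate table from [eligible_candidates()].
#' @param dt Time step in days.
#' @param acc Numeric accumulator vector indexed by `(element - 1) * 6 +
#'   dir`; grown as needed.
#' @param L Voxel edge length (mm).
#' @return A list with `requests` (rows of `candidates` that spawn) and the
#'   updated `acc`.
#' @export
accrue_and_select <- function(candidates, dt, acc, L = 1) {
  if (dt <= 0) stop("`dt` must be positive")
  vol <- L^3
  if (nrow(candidates)) {
    key <- (candidates$element - 1L) * 6L + candidates$dir
    if (max(key) > length(acc)) acc <- c(acc, numeric(max(key) - length(acc)))
    acc[key] <- acc[key] + candidates$velocity * dt
    fire <- acc[key] >= vol
    acc[key[fire]] <- acc[key[fire]] - vol
    requests <- candidates[fire, , drop = FALSE]
  } else {
    requests <- candidates
  }
  list(requests = requests, acc = acc)
}
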