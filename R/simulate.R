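# Orchestration of the three-phase healing iteration: (1) advance both
# species' diffusion by dt on the current mesh, (2) detect free faces,
# evaluate triggers and velocities and accrue growth, (3) apply spawn
# requests and initialize the new nodes. Per-day records track callus size,
# fragment bridging and interfragmentary-gap closure.

#' Per-species nodal concentration fields
#'
#' Holds the MSC (`msc`) and chondrocyte (`cho`) nodal concentration
#' vectors together with the per-species maxima used for
#' nondimensionalization (`alpha = msc / c_max["msc"]`,
#' `beta = cho / c_max["cho"]`).
#'
#' @param model A [voxel_model()].
#' @param init Initial nodal value (default 0).
#' @param c_max Named per-species maxima (default 1 for both).
#' @return An object of class `concentration_fields`.
#' @export
concentration_fields <- function(model, init = 0, c_max = c(msc = 1, cho = 1)) {
  n <- n_nodes(model)
  structure(list(msc = rep(init, n), cho = rep(init, n), c_max = c_max),
            class = "concentration_fields")
}

default_config <- function() {
  list(
    geometry = list(outer_radius = 15, cortical_thickness = 5.25,
                    periosteum_thickness = 1, nail_diameter = 11,
                    length = 43, voxel = 1, margin = 7),
    fracture = list(kind = "transverse", gap = 6, slope_deg = 30,
                    center = NULL, offset = 6.5),
    materials = list(D_um2_min = NULL),
    boundary = list(mode = "regions", c_high = 1, c_low = 0.3, scale = 0.16),
    growth = list(a = 5, b = 5, alpha0 = 1/32, beta0 = 1/16, v_max = 5,
                  aggregate = "min", new_node_init = "zero",
                  roi_halfwidth = 5),
    time = list(dt = 0.25, horizon = 100, stop_at_closure = TRUE)
  )
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    if (!key %in% names(base))
      stop("unknown configuration key: ", paste0(path, key))
    if (is.list(base[[key]]) && !is.null(base[[key]])) {
      if (!is.list(override[[key]]))
        stop("configuration section must be a mapping: ", paste0(path, key))
      base[[key]] <- merge_config(base[[key]], override[[key]],
                                  paste0(path, key, "$"))
    } else {
      base[key] <- list(override[[key]])  # preserves explicit NULLs
    }
  }
  base
}

#' Build a validated simulation configuration
#'
#' Fills every unspecified setting with the model defaults (Tables of
#' material diffusivities and sigmoid parameters, 1 mm voxels, dt = 0.25
#' day) and validates the result. Unknown keys are rejected. Geometry units
#' are mm, diffusivities um^2/min, times days, velocities mm^3/day.
#'
#' @param ... Nested configuration sections (`geometry`, `fracture`,
#'   `materials`, `boundary`, `growth`, `time`) overriding the defaults.
#' @param model Optional prebuilt [voxel_model()] that replaces the
#'   generated geometry (its metadata supplies the fracture information).
#' @param boundary_nodes,boundary_values Optional explicit Dirichlet node
#'   ids and values, replacing the region-derived boundary sets.
#' @param roi Optional explicit axial growth band `c(z_min, z_max)` in mm.
#' @return An object of class `sim_config`.
#' @export
simulation_config <- function(..., model = NULL, boundary_nodes = NULL,
                              boundary_values = NULL, roi = NULL) {
  override <- list(...)
  if (length(override) == 1L && is.null(names(override)) &&
      is.list(override[[1L]]))
    override <- override[[1L]]
  cfg <- merge_config(default_config(), override)
  with(cfg$time, {
    if (!is.numeric(dt) || dt <= 0) stop("time step `dt` must be > 0")
    if (!is.numeric(horizon) || horizon < 0) stop("`horizon` must be >= 0")
  })
  with(cfg$growth, {
    if (alpha0 <= 0 || alpha0 >= 1 || beta0 <= 0 || beta0 >= 1)
      stop("trigger thresholds must lie in (0, 1)")
    if (!aggregate %in% c("min", "mean"))
      stop("`growth$aggregate` must be \"min\" or \"mean\"")
    if (!new_node_init %in% c("zero", "parent_mean"))
      stop("`growth$new_node_init` must be \"zero\" or \"parent_mean\"")
  })
  if (!cfg$boundary$mode %in% c("regions", "ends"))
    stop("`boundary$mode` must be \"regions\" or \"ends\"")
  cfg$model <- model
  cfg$boundary_nodes <- boundary_nodes
  cfg$boundary_values <- boundary_values
  cfg$roi <- roi
  class(cfg) <- "sim_config"
  cfg
}

#' Scenario preset configurations
#'
#' The three diaphyseal fracture scenarios: `"transverse"` (6 mm gap),
#' `"oblique"` (30 degree slope, 3 mm gap) and `"comminuted"` (transverse
#' plus 30 degree oblique cuts, 3 mm gaps, inert intermediate fragment), all
#' on a 43 mm section with an 11 mm intramedullary nail and 1 mm voxels.
#' Presets are shipped as YAML files under
#' `system.file("extdata", "presets", package = "callusim")` and loaded via
#' [load_config()].
#'
#' @param name Preset name.
#' @param ... Further overrides passed to [simulation_config()].
#' @return A `sim_config`.
#' @export
preset_config <- function(name = c("transverse", "oblique", "comminuted"), ...) {
  name <- match.arg(name)
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "callusim")
  if (!nzchar(path)) stop("preset file not found: ", name)
  load_config(path, ...)
}

build_config_model <- function(cfg) {
  if (!is.null(cfg$model)) return(cfg$model)
  g <- cfg$geometry
  model <- generate_diaphysis(outer_radius = g$outer_radius,
                              cortical_thickness = g$cortical_thickness,
                              periosteum_thickness = g$periosteum_thickness,
                              nail_diameter = g$nail_diameter,
                              length = g$length, L = g$voxel,
                              margin = g$margin)
  f <- cfg$fracture
  if (!is.null(f$kind) && f$gap > 0) {
    spec <- fracture_spec(kind = f$kind, gap = f$gap,
                          slope_deg = f$slope_deg, center = f$center,
                          offset = f$offset)
    model <- apply_fracture(model, spec)
  }
  model
}

#' Lattice sites of the interfragmentary-gap region of interest
#'
#' The sites removed by the fracture cutter plus the surrounding growth
#' band: every lattice site whose axial position lies within
#' `halfwidth` mm of the removed region, excluding sites occupied by the
#' nail. This is the region inspected for interior voids by
#' [closure_state()].
#'
#' @param model A fractured [voxel_model()].
#' @param halfwidth Band half-width in mm beyond the removed region.
#' @return Integer site matrix (m x 3).
#' @export
gap_roi <- function(model, halfwidth = 5) {
  fr <- model$meta$fracture
  if (is.null(fr)) stop("model has no fracture metadata")
  lat <- model$lattice
  k0 <- max(0L, floor((fr$z_range[1L] - halfwidth) / lat$L))
  k1 <- min(lat$extents[3L] - 1L, ceiling((fr$z_range[2L] + halfwidth) / lat$L) - 1L)
  sites <- as.matrix(expand.grid(i = 0:(lat$extents[1L] - 1L),
                                 j = 0:(lat$extents[2L] - 1L),
                                 k = k0:k1))
  dimnames(sites) <- NULL
  storage.mode(sites) <- "integer"
  ids <- model$elem_at[site_key(lat, sites)]
  nail <- ids > 0L & model$material[pmax(ids, 1L)] == "nail"
  sites[!nail, , drop = FALSE]
}

#' Are two fragments bridged?
#'
#' `TRUE` iff a 6-connected path of non-nail elements (bone of either
#' fragment, inert fragments, or callus) joins an element of `fragA` to an
#' element of `fragB`.
#'
#' @param model A [voxel_model()].
#' @param fragA,fragB Fragment ids present in the model.
#' @return Logical flag.
#' @export
bridged <- function(model, fragA = 1L, fragB = NULL) {
  frags <- unique(model$fragment[model$fragment > 0L])
  if (is.null(fragB)) fragB <- max(frags)
  if (!fragA %in% frags || !fragB %in% frags)
    stop("unknown fragment id")
  lat <- model$lattice
  non_nail <- model$material != "nail"
  target <- model$fragment == fragB
  visited <- logical(n_elements(model))
  frontier <- which(model$fragment == fragA)
  visited[frontier] <- TRUE
  while (length(frontier)) {
    if (any(target[frontier])) return(TRUE)
    sites <- model$elem_site[frontier, , drop = FALSE]
    nb <- integer(0)
    for (d in seq_len(6L)) {
      tgt <- sweep(sites, 2L, DIRECTIONS[d, ], "+")
      ok <- sites_in_bounds(lat, tgt)
      if (!any(ok)) next
      ids <- model$elem_at[site_key(lat, tgt[ok, , drop = FALSE])]
      ids <- ids[ids > 0L]
      nb <- c(nb, ids[non_nail[ids] & !visited[ids]])
    }
    nb <- unique(nb)
    visited[nb] <- TRUE
    frontier <- nb
  }
  FALSE
}

#' Gap closure state and interior-void count
#'
#' The gap is `"open"` until the main fragments are bridged, `"bridged"`
#' while the interfragmentary gap still contains empty sites, and
#' `"closed"` once it is bridged and every site removed by the fracture
#' cutter is occupied again (the gap is filled seamlessly). Alongside the
#' state, the number of interior voids is reported: empty
#' region-of-interest sites that are not 6-connected, through empty sites,
#' to the outside of the region (computed by flood fill from the region's
#' outer boundary) -- the sealed cavities that remain inside the callus
#' shortly before closure.
#'
#' @param model A [voxel_model()].
#' @param roi Site matrix from [gap_roi()] (must be non-empty): the removed
#'   sites plus the surrounding growth band, inspected for sealed voids.
#' @param core Optional site matrix of the cutter-removed (non-nail) sites
#'   whose complete refill defines closure; defaults to `roi`.
#' @param fragA,fragB Fragment ids whose bridging defines the bridged state.
#' @return A list with `state` (`"open"`, `"bridged"` or `"closed"`),
#'   `voids` (interior-void count), `unfilled` (empty core sites) and
#'   `bridged` (logical).
#' @export
closure_state <- function(model, roi, core = NULL, fragA = 1L, fragB = NULL) {
  if (is.null(roi) || nrow(roi) == 0L) stop("empty region of interest")
  if (is.null(core)) core <- roi
  lat <- model$lattice
  keys <- site_key(lat, roi)
  in_roi <- logical(prod(lat$extents))
  in_roi[keys] <- TRUE
  empty <- model$elem_at[keys] == 0L
  esites <- roi[empty, , drop = FALSE]
  voids <- 0L
  if (nrow(esites)) {
    ekeys <- keys[empty]
    pos <- integer(prod(lat$extents))
    pos[ekeys] <- seq_len(nrow(esites))
    reached <- logical(nrow(esites))
    # seeds: empty roi sites adjacent to the outside of the roi (an
    # out-of-lattice face or an empty non-roi site)
    seed <- logical(nrow(esites))
    nbr_empty <- vector("list", 6L)
    for (d in seq_len(6L)) {
      tgt <- sweep(esites, 2L, DIRECTIONS[d, ], "+")
      inb <- sites_in_bounds(lat, tgt)
      esc <- !inb
      nbr <- integer(nrow(esites))
      if (any(inb)) {
        tk <- site_key(lat, tgt[inb, , drop = FALSE])
        occ <- model$elem_at[tk] > 0L
        esc[inb][!occ & !in_roi[tk]] <- TRUE
        nbr[inb] <- ifelse(!occ & in_roi[tk], pos[tk], 0L)
      }
      seed <- seed | esc
      nbr_empty[[d]] <- nbr
    }
    frontier <- which(seed)
    reached[frontier] <- TRUE
    while (length(frontier)) {
      nb <- unlist(lapply(nbr_empty, function(v) v[frontier]), use.names = FALSE)
      nb <- unique(nb[nb > 0L])
      nb <- nb[!reached[nb]]
      reached[nb] <- TRUE
      frontier <- nb
    }
    voids <- sum(!reached)
  }
  br <- bridged(model, fragA, fragB)
  unfilled <- sum(model$elem_at[site_key(lat, core)] == 0L)
  state <- if (!br) "open" else if (unfilled > 0L) "bridged" else "closed"
  list(state = state, voids = as.integer(voids),
       unfilled = as.integer(unfilled), bridged = br)
}

#' Run the three-phase callus-growth simulation
#'
#' Iterates, with time step `dt`, the cycle of diffusion advance for both
#' cell species, growth-trigger evaluation with volume accrual, and free
#' mesh growth, recording per-day metrics until the gap closes or the
#' horizon is reached. Fully deterministic for a fixed configuration.
#'
#' @param config A [simulation_config()] or [preset_config()].
#' @return An object of class `callus_sim`: `days` (per-day data.frame with
#'   callus element count and volume, bridged/closed flags and interior-void
#'   count), `events` (`bridging_day`, `closure_day`), the final `model` and
#'   `fields`, and the `config`.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  materials <- default_materials(config$materials$D_um2_min)
  gf <- with(config$growth,
             growth_function(a = a, b = b, alpha0 = alpha0, beta0 = beta0,
                             v_max = v_max))
  model <- build_config_model(config)
  lat <- model$lattice

  if (!is.null(config$boundary_nodes)) {
    bc <- list(nodes = as.integer(config$boundary_nodes),
               values = rep_len(as.numeric(config$boundary_values),
                                length(config$boundary_nodes)))
  } else {
    bc <- boundary_from_regions(model, materials,
                                c_high = config$boundary$c_high,
                                c_low = config$boundary$c_low,
                                scale = config$boundary$scale,
                                mode = config$boundary$mode)
  }

  roi <- config$roi
  roi_sites <- NULL
  if (!is.null(model$meta$fracture)) {
    hw <- config$growth$roi_halfwidth
    if (is.null(roi))
      roi <- c(model$meta$fracture$z_range[1L] - hw,
               model$meta$fracture$z_range[2L] + hw)
    roi_sites <- gap_roi(model, hw)
  }
  core_sites <- model$meta$fracture$removed_sites
  frags <- unique(model$fragment[model$fragment > 0L])
  track_bridge <- length(frags) >= 2L

  fields <- concentration_fields(model)
  node_presc <- logical(n_nodes(model))
  node_presc[bc$nodes] <- TRUE
  fields$msc[bc$nodes] <- bc$values
  fields$cho[bc$nodes] <- bc$values

  steps_per_day <- max(1L, round(1 / config$time$dt))
  dt <- 1 / steps_per_day
  acc <- numeric(6L * n_elements(model))
  n0 <- n_elements(model)
  L <- lat$L

  diffusive_flag <- function()
    material_property(materials, model$material, "diffusive") & !model$inert
  record <- function(day) {
    callus <- model$material == "callus"
    br <- FALSE; st <- "open"; voids <- NA_integer_; unfilled <- NA_integer_
    if (track_bridge && !is.null(roi_sites)) {
      cs <- closure_state(model, roi_sites, core_sites)
      br <- cs$bridged; st <- cs$state
      voids <- cs$voids; unfilled <- cs$unfilled
    } else if (track_bridge) {
      br <- bridged(model)
      st <- if (br) "bridged" else "open"
    }
    wrap <- NA_real_; max_r <- NA_real_
    if (!is.null(model$meta$geometry) && !is.null(model$meta$fracture)) {
      mo <- callus_morphology(model)
      wrap <- mo$nail_wrap_fraction
      max_r <- mo$max_callus_radius
    }
    data.frame(day = day, elements = n_elements(model),
               callus_elements = sum(callus),
               callus_volume = sum(callus) * L^3,
               bridged = br, closed = identical(st, "closed"),
               voids = voids, unfilled = unfilled,
               nail_wrap = wrap, max_callus_radius = max_r)
  }

  days <- list(record(0))
  bridging_day <- NA_integer_
  closure_day <- NA_integer_
  system <- NULL
  mesh_changed <- TRUE

  if (config$time$horizon >= 1) {
    for (day in seq_len(ceiling(config$time$horizon))) {
      for (s in seq_len(steps_per_day)) {
        if (mesh_changed || is.null(system)) {
          dflag <- diffusive_flag()
          free_node <- !node_presc
          has_free <- matrix(free_node[model$conn], nrow = n_elements(model))
          active <- which(dflag & rowSums(has_free) > 0L)
          system <- if (length(active))
            assemble(model, materials, bc, elements = active) else NULL
          mesh_changed <- FALSE
        }
        if (!is.null(system)) {
          fields$msc <- fem_step(system, fields$msc, dt)
          fields$cho <- fem_step(system, fields$cho, dt)
        }
        idx <- build_centroid_index(model)
        faces <- detect_free_faces(model, idx, roi, materials)
        cands <- eligible_candidates(faces, fields, gf, model,
                                     aggregate = config$growth$aggregate)
        sel <- accrue_and_select(cands, dt, acc, L)
        acc <- sel$acc
        if (nrow(sel$requests)) {
          sp <- spawn_elements(model, sel$requests)
          model <- sp$model
          nn <- n_nodes(model)
          if (length(fields$msc) < nn) {
            fields$msc <- c(fields$msc, numeric(nn - length(fields$msc)))
            fields$cho <- c(fields$cho, numeric(nn - length(fields$cho)))
            node_presc <- c(node_presc, logical(nn - length(node_presc)))
          }
          if (config$growth$new_node_init == "parent_mean")
            fields <- init_new_nodes(fields, sp$report, model)
          mesh_changed <- nrow(sp$report$created) > 0L
        }
      }
      rec <- record(day)
      days[[length(days) + 1L]] <- rec
      if (is.na(bridging_day) && isTRUE(rec$bridged)) bridging_day <- day
      if (is.na(closure_day) && isTRUE(rec$closed)) closure_day <- day
      if (!is.na(closure_day) && isTRUE(config$time$stop_at_closure)) break
    }
  }
  days <- do.call(rbind, days)
  structure(list(days = days,
                 events = list(bridging_day = bridging_day,
                               closure_day = closure_day,
                               initial_elements = n0),
                 model = model, fields = fields, config = config),
            class = "callus_sim")
}

#' @export
print.callus_sim <- function(x, ...) {
  last <- x$days[nrow(x$days), ]
  cat(sprintf("<callus_sim> %d days simulated, %d callus elements (%.0f mm^3)\n",
              last$day, last$callus_elements, last$callus_volume))
  cat(sprintf("  bridging day: %s, closure day: %s\n",
              format(x$events$bridging_day), format(x$events$closure_day)))
  invisible(x)
}

#' Summarize a simulation result
#'
#' @param object A `callus_sim` result.
#' @param ... Unused.
#' @return A list with the per-day table and the headline events
#'   (first bridging day, closure day, total callus volume).
#' @export
summary.callus_sim <- function(object, ...) {
  last <- object$days[nrow(object$days), ]
  out <- list(per_day = object$days,
              events = object$events,
              final_callus_volume = last$callus_volume)
  class(out) <- "summary.callus_sim"
  out
}

#' @export
print.summary.callus_sim <- function(x, ...) {
  cat("Per-day record (first and last rows):\n")
  n <- nrow(x$per_day)
  print(x$per_day[unique(c(1L, min(2L, n), n - 1L, n)), ], row.names = FALSE)
  cat(sprintf("First bridging day: %s\nClosure day: %s\nFinal callus volume: %.0f mm^3\n",
              format(x$events$bridging_day), format(x$events$closure_day),
              x$final_callus_volume))
  invisible(x)
}

#' Callus morphology descriptors
#'
#' Voxel-occupancy measures of the callus shape used to check the expected
#' qualitative morphology: at bridging the callus should wrap around the
#' nail inside the gap and the largest radial extent should occur at the
#' periosteal surface (an external collar overtopping the bone).
#'
#' @param model A fractured, grown [voxel_model()] with diaphysis metadata.
#' @param n_sectors Number of azimuthal sectors for the wrap check.
#' @return A list: `nail_wrap_fraction` (fraction of azimuthal sectors of
#'   the gap band that contain endosteal callus, i.e. callus radially inside
#'   the canal), `max_callus_radius` (mm), `outer_radius` (mm), and
#'   `collar_overtops` (`TRUE` when the radially outermost callus lies at or
#'   beyond the periosteal surface).
#' @export
callus_morphology <- function(model, n_sectors = 8L) {
  geom <- model$meta$geometry
  fr <- model$meta$fracture
  if (is.null(geom) || is.null(fr))
    stop("model lacks diaphysis geometry or fracture metadata")
  callus <- which(model$material == "callus")
  if (!length(callus))
    return(list(nail_wrap_fraction = 0, max_callus_radius = NA_real_,
                outer_radius = geom$outer_radius, collar_overtops = FALSE))
  cen <- element_centroids(model, callus)
  lat <- model$lattice
  cx <- cen[, 1L] - lat$origin[1L] - geom$axis[1L]
  cy <- cen[, 2L] - lat$origin[2L] - geom$axis[2L]
  cz <- cen[, 3L] - lat$origin[3L]
  r <- sqrt(cx^2 + cy^2)
  in_gap <- cz > fr$z_range[1L] & cz < fr$z_range[2L]
  endosteal <- in_gap & r < geom$canal_radius
  sector <- floor((atan2(cy, cx) + pi) / (2 * pi) * n_sectors)
  sector <- pmin(sector, n_sectors - 1L)
  wrap <- length(unique(sector[endosteal])) / n_sectors
  list(nail_wrap_fraction = wrap,
       max_callus_radius = max(r),
       outer_radius = geom$outer_radius,
       collar_overtops = max(r) >= geom$outer_radius)
}

#' Deterministic two-block toy scenario
#'
#' A miniature instance of the healing problem used for exact traceability:
#' two 3 x 3 x 3 trabecular blocks separated by a 2-voxel axial gap on a
#' 3 x 3 x 8 lattice. Cells enter from the two outer end cross-sections,
#' which are held at the prescribed concentration. The whole loop on this
#' instance can be traced by hand (or by an independent dense
#' re-implementation) in a few dozen elements.
#'
#' @param gap Gap height in voxels (default 2).
#' @param block Block edge in voxels (default 3).
#' @return A list with the `model`, the Dirichlet `nodes` and `values`, and
#'   the gap `roi` sites.
#' @export
toy_two_block_model <- function(gap = 2L, block = 3L) {
  nz <- 2L * block + gap
  lat <- voxel_lattice(c(block, block, nz))
  g <- expand.grid(i = 0:(block - 1L), j = 0:(block - 1L))
  lower <- cbind(g$i, g$j, rep(0:(block - 1L), each = nrow(g)))
  upper <- cbind(g$i, g$j, rep((block + gap):(nz - 1L), each = nrow(g)))
  sites <- rbind(lower[order(lower[, 3L]), ], upper[order(upper[, 3L]), ])
  model <- voxel_model(lat, sites, material = "trabecular",
                       fragment = rep(c(1L, 2L), each = nrow(g) * block))
  model$meta$fracture <- list(
    spec = fracture_spec("transverse", gap = gap),
    center = nz / 2,
    removed_sites = cbind(g$i, g$j, rep(block:(block + gap - 1L),
                                        each = nrow(g)))[, c(1, 2, 3)],
    z_range = c(block, block + gap),
    n_fragments = 2L
  )
  ends <- which(model$node_xyz[, 3L] == 0L | model$node_xyz[, 3L] == nz)
  list(model = model, nodes = ends, values = rep(1, length(ends)),
       roi = gap_roi(model, halfwidth = nz))
}
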