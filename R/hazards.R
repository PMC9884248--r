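#' Hazard layer
#'
#' A set of hazard footprints of one kind. Floods are polygons carrying a
#' water depth in cm; faults are linestrings (buffered before use) or
#' polygons (used as affected areas directly) carrying a return-period
#' label.
#'
#' @param id layer identifier.
#' @param kind `"flood"` or `"fault"`.
#' @param geometries list of geometries: a polygon is a list of rings
#'   (n x 2 matrices, first outer); a fault linestring is a single n x 2
#'   matrix.
#' @param intensity per-geometry intensity: flood depth in cm (numeric,
#'   >= 0) or fault return-period label (character).
#' @return an object of class `hazard_layer`.
#' @export
hazard_layer <- function(id, kind, geometries, intensity) {
  kind <- match.arg(kind, c("flood", "fault"))
  if (!is.list(geometries)) geometries <- list(geometries)
  if (length(intensity) == 1 && length(geometries) > 1) {
    intensity <- rep(intensity, length(geometries))
  }
  if (length(intensity) != length(geometries)) {
    stop("one intensity per geometry required", call. = FALSE)
  }
  if (kind == "flood") {
    depth <- as.numeric(intensity)
    if (any(!is.finite(depth)) || any(depth < 0)) {
      stop("flood depths must be finite and >= 0", call. = FALSE)
    }
    intensity <- depth
    geometries <- lapply(geometries, function(g) if (is.matrix(g)) list(g) else g)
  }
  structure(list(id = as.character(id), kind = kind,
                 geometries = geometries, intensity = intensity),
            class = "hazard_layer")
}

#' Hazard disruption rule
#'
#' Parameters translating hazard exposure into network damage: flood
#' depths above `penalize_cm` (strict) divide the affected edge's speed by
#' `rho`; depths of at least `disrupt_cm` (inclusive) fully disrupt the
#' link; every link within `fault_buffer_m` of a fault line is fully
#' disrupted. Defaults follow common practice for off-peak urban driving:
#' rho = 3 (speed reduced to one-third), penalize above 5 cm, disrupt at
#' 15 cm, 500 m fault buffer.
#'
#' @param rho speed penalization factor (> 1).
#' @param penalize_cm flood depth threshold (cm) above which speed is
#'   penalized.
#' @param disrupt_cm flood depth threshold (cm) at/above which the link is
#'   disrupted; must be >= `penalize_cm`.
#' @param fault_buffer_m buffer radius (m) around fault lines.
#' @return an object of class `hazard_rule`.
#' @export
hazard_rule <- function(rho = 3, penalize_cm = 5, disrupt_cm = 15,
                        fault_buffer_m = 500) {
  if (!is.finite(rho) || rho <= 1) stop("`rho` must be > 1", call. = FALSE)
  if (disrupt_cm < penalize_cm) {
    stop("`disrupt_cm` must be >= `penalize_cm`", call. = FALSE)
  }
  if (!is.finite(fault_buffer_m) || fault_buffer_m <= 0) {
    stop("`fault_buffer_m` must be > 0", call. = FALSE)
  }
  structure(list(rho = rho, penalize_cm = penalize_cm,
                 disrupt_cm = disrupt_cm, fault_buffer_m = fault_buffer_m),
            class = "hazard_rule")
}

#' Buffer fault lines into affected-area polygons
#'
#' Planar buffer of radius `radius_m` around each fault linestring. The
#' returned polygons discretize the circular caps with 32 segments per
#' semicircle; containment tests elsewhere in the package use the exact
#' segment-to-polyline distance, so the discretization only affects
#' exported shapes and area reports.
#'
#' @param geometries list of fault linestrings (n x 2 matrices).
#' @param radius_m buffer radius in meters (> 0).
#' @return a list, one element per input geometry, each of class
#'   `fault_buffer` holding `line`, `radius_m`, and `polygons` (list of
#'   rings, one stadium per line segment; overlapping parts at joints are
#'   union semantics).
#' @export
buffer_fault_lines <- function(geometries, radius_m) {
  if (!is.finite(radius_m) || radius_m <= 0) {
    stop("`radius_m` must be > 0", call. = FALSE)
  }
  if (!is.list(geometries)) geometries <- list(geometries)
  lapply(geometries, function(line) {
    stopifnot(is.matrix(line), ncol(line) == 2)
    n <- nrow(line)
    polys <- list()
    if (n == 1) {
      polys <- list(.segment_stadium(line[1, 1], line[1, 2],
                                     line[1, 1], line[1, 2], radius_m))
    } else {
      for (i in seq_len(n - 1)) {
        polys[[i]] <- .segment_stadium(line[i, 1], line[i, 2],
                                       line[i + 1, 1], line[i + 1, 2],
                                       radius_m)
      }
    }
    structure(list(line = line, radius_m = radius_m, polygons = polys),
              class = "fault_buffer")
  })
}

#' Area of a fault buffer polygon
#'
#' Shoelace area summed over the buffer's parts. Exact only when parts do
#' not overlap (single-segment faults); multi-segment buffers overlap at
#' joints and the sum overstates the union.
#'
#' @param buffer a `fault_buffer` from [buffer_fault_lines()].
#' @return area in square meters.
#' @export
buffer_area <- function(buffer) {
  stopifnot(inherits(buffer, "fault_buffer"))
  sum(vapply(buffer$polygons, .ring_area, numeric(1)))
}

# does geometry g (rings list or fault_buffer) touch segment (p1,p2)?
.geom_hits_segment <- function(g, p1x, p1y, p2x, p2y) {
  if (inherits(g, "fault_buffer")) {
    .seg_polyline_dist(p1x, p1y, p2x, p2y, g$line) <= g$radius_m + 1e-9
  } else {
    .seg_intersects_rings(p1x, p1y, p2x, p2y, g)
  }
}

# edge geometry (possibly a polyline) vs one hazard geometry
.geom_hits_edge <- function(g, coords) {
  for (i in seq_len(nrow(coords) - 1)) {
    if (.geom_hits_segment(g, coords[i, 1], coords[i, 2],
                           coords[i + 1, 1], coords[i + 1, 2])) {
      return(TRUE)
    }
  }
  FALSE
}

#' Intersect network edges with hazard geometries
#'
#' An edge is affected iff its geometry (stored shape, else the straight
#' chord between its endpoints) touches any hazard geometry; boundary
#' contact counts. The reported intensity is the maximum over intersecting
#' flood geometries; for fault layers the intensity column carries the
#' return-period label of the first intersecting geometry.
#'
#' @param network a `road_network`.
#' @param layer a `hazard_layer`, with fault linestrings already buffered
#'   via [prepare_hazard_geometries()] or [buffer_fault_lines()].
#' @return data.frame with columns `edge_id` and `intensity` (numeric for
#'   floods, character for faults), one row per affected edge.
#' @export
intersect_edges <- function(network, layer) {
  stopifnot(inherits(network, "road_network"), inherits(layer, "hazard_layer"))
  geoms <- layer$geometries
  hit_id <- character(0)
  hit_int <- if (layer$kind == "flood") numeric(0) else character(0)
  for (i in seq_len(nrow(network$edges))) {
    coords <- .edge_coords(network, i)
    best <- NULL
    for (gi in seq_along(geoms)) {
      if (.geom_hits_edge(geoms[[gi]], coords)) {
        if (layer$kind == "flood") {
          v <- layer$intensity[[gi]]
          if (is.null(best) || v > best) best <- v
        } else if (is.null(best)) {
          best <- layer$intensity[[gi]]
        }
      }
    }
    if (!is.null(best)) {
      hit_id <- c(hit_id, network$edges$edge_id[i])
      hit_int <- c(hit_int, best)
    }
  }
  data.frame(edge_id = hit_id, intensity = hit_int, stringsAsFactors = FALSE)
}

#' Prepare hazard geometries for edge intersection
#'
#' Fault linestrings are replaced by their buffered footprints using the
#' rule's `fault_buffer_m`; flood polygons and fault polygons pass through
#' unchanged.
#'
#' @param layer a `hazard_layer`.
#' @param rule a [hazard_rule()].
#' @return a `hazard_layer` whose geometries are ready for
#'   [intersect_edges()].
#' @export
prepare_hazard_geometries <- function(layer, rule) {
  stopifnot(inherits(layer, "hazard_layer"), inherits(rule, "hazard_rule"))
  if (layer$kind != "fault") return(layer)
  geoms <- lapply(layer$geometries, function(g) {
    if (is.matrix(g)) buffer_fault_lines(list(g), rule$fault_buffer_m)[[1]]
    else g
  })
  layer$geometries <- geoms
  layer
}

# per-edge status for one (layer, rule): factors = applied rho (NA intact)
.layer_status <- function(network, layer, rule) {
  prepped <- prepare_hazard_geometries(layer, rule)
  hits <- intersect_edges(network, prepped)
  status <- stats::setNames(rep("intact", nrow(network$edges)),
                            network$edges$edge_id)
  if (nrow(hits) > 0) {
    if (layer$kind == "fault") {
      status[hits$edge_id] <- "disrupted"
    } else {
      depth <- as.numeric(hits$intensity)
      status[hits$edge_id[depth >= rule$disrupt_cm]] <- "disrupted"
      pen <- depth > rule$penalize_cm & depth < rule$disrupt_cm
      status[hits$edge_id[pen]] <- "penalized"
    }
  }
  status
}

# build a scenario from a per-edge status vector + per-edge rho
.make_scenario <- function(network, name, status, rho_applied, layer_status) {
  disrupted <- names(status)[status == "disrupted"]
  penalized <- names(status)[status == "penalized"]
  net <- network
  idx_p <- match(penalized, net$edges$edge_id)
  if (length(idx_p)) {
    net$edges$speed_kph[idx_p] <-
      net$edges$speed_kph[idx_p] / rho_applied[penalized]
    net$edges$travel_time_min[idx_p] <-
      .travel_time_min(net$edges$length_m[idx_p], net$edges$speed_kph[idx_p])
  }
  idx_d <- match(disrupted, net$edges$edge_id)
  if (length(idx_d)) net$edges$travel_time_min[idx_d] <- Inf
  edge_status <- data.frame(
    edge_id = names(status),
    status = unname(status),
    factor = unname(ifelse(status == "penalized", rho_applied[names(status)], NA_real_)),
    stringsAsFactors = FALSE
  )
  structure(list(name = name, baseline = network, network = net,
                 edge_status = edge_status, layer_status = layer_status),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  tab <- table(x$edge_status$status)
  cat(sprintf("<scenario> '%s': %d intact, %d penalized, %d disrupted edges\n",
              x$name,
              if ("intact" %in% names(tab)) tab[["intact"]] else 0,
              if ("penalized" %in% names(tab)) tab[["penalized"]] else 0,
              if ("disrupted" %in% names(tab)) tab[["disrupted"]] else 0))
  invisible(x)
}

#' Baseline (undisrupted) scenario
#'
#' Wraps a network as a scenario with every edge intact, so baseline and
#' disrupted cases share one interface downstream.
#'
#' @param network a `road_network`.
#' @param name scenario name.
#' @return a `scenario`.
#' @export
baseline_scenario <- function(network, name = "baseline") {
  status <- stats::setNames(rep("intact", nrow(network$edges)),
                            network$edges$edge_id)
  .make_scenario(network, name, status,
                 stats::setNames(numeric(0), character(0)), list())
}

#' Apply a hazard rule to a set of affected edges
#'
#' Translates flood depths / fault exposure into the disrupted network:
#' flood depth in (penalize_cm, disrupt_cm) divides the edge speed by rho
#' and recomputes the travel time; depth >= disrupt_cm or fault exposure
#' disrupts the link (infinite travel time; the edge stays addressable for
#' criticality reporting). The baseline network is never mutated.
#'
#' @param network a `road_network` (the baseline).
#' @param affected data.frame from [intersect_edges()].
#' @param rule a [hazard_rule()].
#' @param kind `"flood"` or `"fault"` (how to read `intensity`).
#' @param name scenario name.
#' @return a `scenario`.
#' @export
apply_rule <- function(network, affected, rule, kind = c("flood", "fault"),
                       name = "hazard") {
  kind <- match.arg(kind)
  stopifnot(inherits(network, "road_network"), inherits(rule, "hazard_rule"))
  if (nrow(affected) > 0 && !all(affected$edge_id %in% network$edges$edge_id)) {
    stop("affected edges must belong to the network", call. = FALSE)
  }
  status <- stats::setNames(rep("intact", nrow(network$edges)),
                            network$edges$edge_id)
  if (nrow(affected) > 0) {
    if (kind == "fault") {
      status[affected$edge_id] <- "disrupted"
    } else {
      depth <- as.numeric(affected$intensity)
      status[affected$edge_id[depth >= rule$disrupt_cm]] <- "disrupted"
      pen <- depth > rule$penalize_cm & depth < rule$disrupt_cm
      status[affected$edge_id[pen]] <- "penalized"
    }
  }
  rho <- stats::setNames(rep(rule$rho, length(status)), names(status))
  .make_scenario(network, name, status, rho, list())
}

#' Compose several hazard layers into one scenario
#'
#' Per edge the most severe status wins (disrupted > penalized > intact);
#' an edge penalized by several layers is penalized once with the largest
#' applicable rho — penalties never compound multiplicatively. Per-layer
#' statuses are retained for reporting.
#'
#' @param network a `road_network`.
#' @param layers list of `hazard_layer` objects.
#' @param rules a single [hazard_rule()] applied to all layers, or a list
#'   of rules parallel to `layers`.
#' @param name scenario name.
#' @return a `scenario`; `$layer_status` maps layer id to its per-edge
#'   status vector.
#' @export
compose_hazards <- function(network, layers, rules = hazard_rule(),
                            name = "compound") {
  stopifnot(inherits(network, "road_network"), length(layers) >= 1)
  if (inherits(rules, "hazard_rule")) {
    rules <- rep(list(rules), length(layers))
  }
  stopifnot(length(rules) == length(layers))
  edge_ids <- network$edges$edge_id
  status <- stats::setNames(rep("intact", length(edge_ids)), edge_ids)
  rho_applied <- stats::setNames(rep(NA_real_, length(edge_ids)), edge_ids)
  layer_status <- list()
  rank <- c(intact = 0, penalized = 1, disrupted = 2)
  for (i in seq_along(layers)) {
    st <- .layer_status(network, layers[[i]], rules[[i]])
    layer_status[[layers[[i]]$id]] <- st
    upgrade <- rank[st] > rank[status]
    status[upgrade] <- st[upgrade]
    pen <- names(st)[st == "penalized"]
    rho_applied[pen] <- pmax(rho_applied[pen], rules[[i]]$rho, na.rm = TRUE)
  }
  .make_scenario(network, name, status, rho_applied, layer_status)
}

#' Single-hazard scenario from a layer
#'
#' Convenience wrapper: prepare geometries, intersect, apply the rule.
#'
#' @inheritParams compose_hazards
#' @param layer a `hazard_layer`.
#' @param rule a [hazard_rule()].
#' @return a `scenario`.
#' @export
hazard_scenario <- function(network, layer, rule = hazard_rule(),
                            name = layer$id) {
  compose_hazards(network, list(layer), rule, name = name)
}
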