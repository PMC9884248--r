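# Synthetic cities: a lattice road network, a tiling population grid,
# randomly placed facilities and parametric hazard bands, so the whole
# pipeline is testable without any external data.

#' Specification of a synthetic city
#'
#' A rows x cols lattice of intersections with 4-neighbour streets.
#' Every `arterial_every`-th row/column line is an arterial (faster
#' class); population cells tile the lattice in square blocks; facility
#' footprint areas are lognormal, the usual shape for building-size
#' distributions.
#'
#' @param rows,cols lattice dimensions (>= 2).
#' @param spacing_m distance between neighbouring intersections, meters.
#' @param speeds a [speed_table()]; the default maps `arterial` to 60 and
#'   `local` to 30 km/h.
#' @param arterial_every every k-th grid line is arterial; 0 disables the
#'   two-class mixture (all edges `local`).
#' @param cell_span population-cell side length, in lattice steps.
#' @param pop_range uniform range for per-cell population counts.
#' @param n_facilities number of service facilities (>= 0).
#' @param area_meanlog,area_sdlog lognormal parameters for facility areas
#'   (m^2).
#' @param seed integer seed; all generation is deterministic under it.
#' @return a `city_spec` object.
#' @export
city_spec <- function(rows = 8, cols = 8, spacing_m = 500,
                      speeds = speed_table(c(arterial = 60, local = 30),
                                           default = 30),
                      arterial_every = 3, cell_span = 2,
                      pop_range = c(100, 1000), n_facilities = 3,
                      area_meanlog = log(2000), area_sdlog = 0.5,
                      seed = 1L) {
  if (rows < 2 || cols < 2) stop("rows and cols must be >= 2", call. = FALSE)
  if (!is.finite(spacing_m) || spacing_m <= 0) {
    stop("`spacing_m` must be > 0", call. = FALSE)
  }
  if (cell_span < 1) stop("`cell_span` must be >= 1", call. = FALSE)
  if (n_facilities < 0) stop("`n_facilities` must be >= 0", call. = FALSE)
  if (!all(is.finite(c(pop_range, area_meanlog, area_sdlog)))) {
    stop("distribution parameters must be finite", call. = FALSE)
  }
  structure(list(rows = rows, cols = cols, spacing_m = spacing_m,
                 speeds = speeds, arterial_every = arterial_every,
                 cell_span = cell_span, pop_range = pop_range,
                 n_facilities = n_facilities, area_meanlog = area_meanlog,
                 area_sdlog = area_sdlog, seed = as.integer(seed)),
            class = "city_spec")
}

.rect_ring <- function(xmin, ymin, xmax, ymax) {
  cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
}

#' Generate a synthetic city
#'
#' Builds the lattice road network (rows*(cols-1) + cols*(rows-1) edges),
#' the tiling population grid, and seeded-random facilities snapped to
#' lattice nodes.
#'
#' @param spec a [city_spec()].
#' @return list with `network` (`road_network`), `cells`
#'   (`population_cells`), `facilities` (`amenities`), `spec`.
#' @export
generate_city <- function(spec = city_spec()) {
  stopifnot(inherits(spec, "city_spec"))
  r <- spec$rows; cc <- spec$cols; s <- spec$spacing_m
  grid <- expand.grid(row = seq_len(r), col = seq_len(cc))
  nodes <- data.frame(
    id = sprintf("n%03d_%03d", grid$row, grid$col),
    x = (grid$col - 1) * s,
    y = (grid$row - 1) * s,
    stringsAsFactors = FALSE
  )
  is_art <- function(k) spec$arterial_every > 0 && k %% spec$arterial_every == 0
  eu <- character(0); ev <- character(0); ecl <- character(0)
  for (i in seq_len(r)) {
    for (j in seq_len(cc)) {
      if (j < cc) {  # horizontal edge along row i
        eu <- c(eu, sprintf("n%03d_%03d", i, j))
        ev <- c(ev, sprintf("n%03d_%03d", i, j + 1))
        ecl <- c(ecl, if (is_art(i)) "arterial" else "local")
      }
      if (i < r) {   # vertical edge along column j
        eu <- c(eu, sprintf("n%03d_%03d", i, j))
        ev <- c(ev, sprintf("n%03d_%03d", i + 1, j))
        ecl <- c(ecl, if (is_art(j)) "arterial" else "local")
      }
    }
  }
  edges <- data.frame(u = eu, v = ev, length_m = s, road_class = ecl,
                      stringsAsFactors = FALSE)
  network <- build_network(nodes, edges, spec$speeds)

  # population cells: square blocks of cell_span lattice steps, expanded
  # by half a spacing so boundary nodes are covered
  half <- s / 2
  span <- spec$cell_span * s
  nx <- max(1, ceiling(((cc - 1) * s + s) / span))
  ny <- max(1, ceiling(((r - 1) * s + s) / span))
  ids <- character(0); geoms <- list()
  for (iy in seq_len(ny)) {
    for (ix in seq_len(nx)) {
      ids <- c(ids, sprintf("c%02d_%02d", iy, ix))
      geoms[[length(geoms) + 1]] <- list(.rect_ring(
        -half + (ix - 1) * span, -half + (iy - 1) * span,
        -half + ix * span, -half + iy * span
      ))
    }
  }
  pops <- .with_seed(spec$seed, {
    round(stats::runif(length(ids), spec$pop_range[1], spec$pop_range[2]))
  })
  cells <- population_cells(ids, pops, geoms)

  facilities <- NULL
  if (spec$n_facilities > 0) {
    fac <- .with_seed(spec$seed + 1L, {
      node <- sample(sort(nodes$id), spec$n_facilities)
      area <- stats::rlnorm(spec$n_facilities, spec$area_meanlog,
                            spec$area_sdlog)
      list(node = node, area = area)
    })
    idx <- match(fac$node, nodes$id)
    facilities <- snap_facilities(network, data.frame(
      id = sprintf("f%02d", seq_len(spec$n_facilities)),
      name = sprintf("facility %02d", seq_len(spec$n_facilities)),
      x = nodes$x[idx], y = nodes$y[idx],
      area_m2 = fac$area, service_type = "health",
      stringsAsFactors = FALSE
    ))
  } else {
    facilities <- structure(
      data.frame(id = character(0), name = character(0), x = numeric(0),
                 y = numeric(0), node = character(0),
                 snap_dist_m = numeric(0), area_m2 = numeric(0),
                 service_type = character(0), stringsAsFactors = FALSE),
      class = c("amenities", "data.frame"))
  }
  list(network = network, cells = cells, facilities = facilities,
       spec = spec)
}

#' Generate a hazard band across a synthetic city
#'
#' A flood band is a rectangle of the given width crossing the whole city
#' perpendicular to `axis` at `position`; a fault band is a straight
#' linestring at `position`. Which lattice edges the band touches is
#' predictable from the geometry, which makes downstream assertions easy.
#'
#' @param city a [generate_city()] result.
#' @param kind `"flood"` or `"fault"`.
#' @param axis `"vertical"` (band of constant x) or `"horizontal"`.
#' @param position band center coordinate (x if vertical, y if
#'   horizontal), meters.
#' @param width_m band width (floods; > 0).
#' @param depth_cm flood depth.
#' @param return_period fault label.
#' @param id layer id.
#' @return a `hazard_layer`; empty (with a warning) when the band lies
#'   outside the city bounds.
#' @export
generate_hazard_band <- function(city, kind = c("flood", "fault"),
                                 axis = c("vertical", "horizontal"),
                                 position, width_m = 100, depth_cm = 8,
                                 return_period = "100y",
                                 id = paste0(kind, "_band")) {
  kind <- match.arg(kind)
  axis <- match.arg(axis)
  if (kind == "flood" && (!is.finite(width_m) || width_m <= 0)) {
    stop("`width_m` must be > 0", call. = FALSE)
  }
  bx <- range(city$network$nodes$x)
  by <- range(city$network$nodes$y)
  pad <- city$spec$spacing_m / 2
  lim <- if (axis == "vertical") bx else by
  if (position < lim[1] - pad || position > lim[2] + pad) {
    warning("hazard band lies outside the city bounds; empty layer")
    return(hazard_layer(id, kind, list(),
                        if (kind == "flood") numeric(0) else character(0)))
  }
  if (kind == "flood") {
    g <- if (axis == "vertical") {
      .rect_ring(position - width_m / 2, by[1] - pad,
                 position + width_m / 2, by[2] + pad)
    } else {
      .rect_ring(bx[1] - pad, position - width_m / 2,
                 bx[2] + pad, position + width_m / 2)
    }
    hazard_layer(id, "flood", list(list(g)), depth_cm)
  } else {
    g <- if (axis == "vertical") {
      cbind(c(position, position), c(by[1] - pad, by[2] + pad))
    } else {
      cbind(c(bx[1] - pad, bx[2] + pad), c(position, position))
    }
    hazard_layer(id, "fault", list(g), return_period)
  }
}

#' Hand-coded illustration city
#'
#' A small city with nodes A..K, two health facilities at H and J, four
#' population cells Gr11..Gr22, one flood footprint and one fault
#' footprint whose overlap covers edge E--F. Node A hangs off the single
#' edge A--D, so disrupting that edge isolates A's population. The
#' fixture reproduces topology and hazard incidence (which edges each
#' hazard touches), not any metric distances, and backs the package
#' tutorial and worked-example tests.
#'
#' @return list with `network`, `cells`, `facilities`, `flood`, `fault`
#'   (two `hazard_layer`s).
#' @export
demo_city <- function() {
  nodes <- data.frame(
    id = c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K"),
    x  = c(0, 1000, 2000, 0, 1000, 2000, 0, 1000, 2000, 3000, 3000),
    y  = c(2000, 2000, 2000, 1000, 1000, 1000, 0, 0, 0, 0, 1000),
    stringsAsFactors = FALSE
  )
  edges <- data.frame(
    u = c("A", "D", "E", "E", "C", "F", "F", "G", "H", "I", "K"),
    v = c("D", "E", "B", "F", "F", "K", "H", "H", "I", "J", "J"),
    length_m = NA_real_, road_class = "local", stringsAsFactors = FALSE
  )
  iu <- match(edges$u, nodes$id); iv <- match(edges$v, nodes$id)
  edges$length_m <- sqrt((nodes$x[iu] - nodes$x[iv])^2 +
                         (nodes$y[iu] - nodes$y[iv])^2)
  network <- build_network(nodes, edges, speed_table(c(local = 30), 30))
  cells <- population_cells(
    id = c("Gr11", "Gr12", "Gr21", "Gr22"),
    pop = c(300, 200, 100, 100),
    geometry = list(
      list(.rect_ring(-500, 500, 1500, 2500)),    # A, B, D, E
      list(.rect_ring(1500, 500, 3500, 2500)),    # C, F, K
      list(.rect_ring(-500, -500, 1500, 500)),    # G, H
      list(.rect_ring(1500, -500, 3500, 500))     # I, J
    )
  )
  facilities <- snap_facilities(network, data.frame(
    id = c("H", "J"), name = c("hospital H", "hospital J"),
    x = c(1000, 3000), y = c(0, 0),
    area_m2 = c(2000, 1000), service_type = "health",
    stringsAsFactors = FALSE
  ))
  flood <- hazard_layer("flood", "flood", list(list(cbind(
    c(600, 1850, 2350, 2100, 1300, 500),
    c(-200, -200, 800, 1300, 1050, 300)
  ))), intensity = 8)
  fault <- hazard_layer("fault", "fault", list(list(cbind(
    c(-300, 700, 1600, 1500, 600, -200),
    c(900, 700, 950, 1400, 1500, 1600)
  ))), intensity = "100y")
  list(network = network, cells = cells, facilities = facilities,
       flood = flood, fault = fault)
}
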