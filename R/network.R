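#' Free-flow speed lookup by road class
#'
#' Maps road-class labels (OSM-style `highway` values or any categorical
#' scheme) to free-flow speeds in km/h, with a default for classes missing
#' from the table. Unknown classes falling back to a default rather than
#' erroring keeps messy open data usable.
#'
#' @param speeds named numeric vector, road class -> speed in km/h (all > 0).
#' @param default speed in km/h applied to unmapped classes (> 0).
#' @return an object of class `speed_table`.
#' @examples
#' speed_table(c(primary = 60, residential = 30), default = 30)
#' @export
speed_table <- function(speeds = c(arterial = 60, local = 30), default = 30) {
  speeds <- unlist(speeds)
  if (length(speeds) && (is.null(names(speeds)) || any(!nzchar(names(speeds))))) {
    stop("`speeds` must be a named vector of road classes", call. = FALSE)
  }
  speeds <- stats::setNames(as.numeric(speeds), names(speeds))
  if (any(!is.finite(speeds)) || any(speeds <= 0)) {
    stop("all speeds must be finite and > 0", call. = FALSE)
  }
  if (!is.finite(default) || default <= 0) {
    stop("`default` speed must be finite and > 0", call. = FALSE)
  }
  structure(list(speeds = speeds, default = default), class = "speed_table")
}

.lookup_speed <- function(table, road_class) {
  out <- unname(table$speeds[road_class])
  out[is.na(out)] <- table$default
  out
}

# travel time in minutes for a length in meters at a speed in km/h
.travel_time_min <- function(length_m, speed_kph) {
  length_m / (speed_kph * 1000 / 60)
}

.edge_id <- function(u, v, directed = FALSE) {
  if (directed) paste(u, v, sep = "--")
  else paste(pmin(u, v), pmax(u, v), sep = "--")
}

#' Build an annotated road network graph
#'
#' Constructs the road graph G(V, E): vertices are street intersections,
#' edges are street segments carrying length, road class, free-flow speed
#' and the derived travel time in minutes. The graph is undirected by
#' default. Connectivity is not required.
#'
#' @param nodes data.frame with columns `id`, `x`, `y` (projected meters).
#' @param edges data.frame with columns `u`, `v`, `length_m` and optionally
#'   `road_class` (default `"unclassified"`) and `geometry` (list column of
#'   n x 2 coordinate matrices; edges without a stored shape use the
#'   straight chord between their endpoints).
#' @param speeds a [speed_table()] giving free-flow speeds per road class.
#' @param directed logical; keep `FALSE` to match the default undirected
#'   road-network model.
#' @return an object of class `road_network` with elements `nodes`,
#'   `edges` (including `edge_id`, `speed_kph`, `travel_time_min`),
#'   `directed`, and `geometry` (named list keyed by `edge_id`).
#' @examples
#' nodes <- data.frame(id = c("a", "b"), x = c(0, 1000), y = 0)
#' edges <- data.frame(u = "a", v = "b", length_m = 1000, road_class = "arterial")
#' net <- build_network(nodes, edges, speed_table(c(arterial = 60)))
#' net$edges$travel_time_min  # 1 minute
#' @export
build_network <- function(nodes, edges, speeds = speed_table(),
                          directed = FALSE) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (!all(c("id", "x", "y") %in% names(nodes))) {
    stop("`nodes` needs columns id, x, y", call. = FALSE)
  }
  if (!all(c("u", "v", "length_m") %in% names(edges))) {
    stop("`edges` needs columns u, v, length_m", call. = FALSE)
  }
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (any(!is.finite(nodes$x)) || any(!is.finite(nodes$y))) {
    stop("node coordinates must be finite", call. = FALSE)
  }
  edges$u <- as.character(edges$u)
  edges$v <- as.character(edges$v)
  missing_u <- !(edges$u %in% nodes$id)
  missing_v <- !(edges$v %in% nodes$id)
  if (any(missing_u | missing_v)) {
    bad <- which(missing_u | missing_v)[1]
    stop(sprintf("edge %s--%s references a node not present in `nodes`",
                 edges$u[bad], edges$v[bad]), call. = FALSE)
  }
  if (any(!is.finite(edges$length_m)) || any(edges$length_m <= 0)) {
    stop("edge lengths must be finite and > 0", call. = FALSE)
  }
  if (any(edges$u == edges$v)) {
    stop("self-loop edges are rejected", call. = FALSE)
  }
  if (is.null(edges$road_class)) edges$road_class <- "unclassified"
  edges$road_class <- as.character(edges$road_class)

  geom <- NULL
  if (!is.null(edges$geometry)) {
    geom <- edges$geometry
    edges$geometry <- NULL
  }
  edge_id <- .edge_id(edges$u, edges$v, directed)
  if (anyDuplicated(edge_id)) stop("duplicate (parallel) edges", call. = FALSE)
  speed_kph <- .lookup_speed(speeds, edges$road_class)
  out_edges <- data.frame(
    edge_id = edge_id,
    u = edges$u, v = edges$v,
    length_m = edges$length_m,
    road_class = edges$road_class,
    speed_kph = speed_kph,
    travel_time_min = .travel_time_min(edges$length_m, speed_kph),
    stringsAsFactors = FALSE
  )
  geometry <- stats::setNames(vector("list", nrow(out_edges)), edge_id)
  if (!is.null(geom)) {
    for (i in seq_along(geom)) {
      if (!is.null(geom[[i]])) geometry[[edge_id[i]]] <- geom[[i]]
    }
  }
  structure(
    list(nodes = nodes[, c("id", "x", "y")], edges = out_edges,
         directed = directed, geometry = geometry),
    class = "road_network"
  )
}

#' @export
print.road_network <- function(x, ...) {
  cat(sprintf("<road_network> %d nodes, %d edges (%s)\n",
              nrow(x$nodes), nrow(x$edges),
              if (x$directed) "directed" else "undirected"))
  invisible(x)
}

# coordinates of an edge: stored shape or straight chord u -> v
.edge_coords <- function(network, i) {
  g <- network$geometry[[network$edges$edge_id[i]]]
  if (!is.null(g)) return(g)
  ui <- match(network$edges$u[i], network$nodes$id)
  vi <- match(network$edges$v[i], network$nodes$id)
  rbind(c(network$nodes$x[ui], network$nodes$y[ui]),
        c(network$nodes$x[vi], network$nodes$y[vi]))
}

#' Snap points to their nearest network node
#'
#' Maps each point to the Euclidean-nearest vertex of the road graph, the
#' standard preprocessing step before facilities become routing
#' destinations. Ties within 1e-9 m go to the smallest node id so results
#' are reproducible.
#'
#' @param network a [build_network()] result.
#' @param points data.frame with columns `id`, `x`, `y`.
#' @return data.frame with columns `id`, `node`, `snap_dist_m`.
#' @export
snap_points <- function(network, points) {
  stopifnot(inherits(network, "road_network"))
  if (nrow(network$nodes) == 0) stop("network has no nodes", call. = FALSE)
  if (!all(c("id", "x", "y") %in% names(points))) {
    stop("`points` needs columns id, x, y", call. = FALSE)
  }
  if (any(!is.finite(points$x)) || any(!is.finite(points$y))) {
    stop("point coordinates must be finite", call. = FALSE)
  }
  nx <- network$nodes$x
  ny <- network$nodes$y
  nid <- network$nodes$id
  node <- character(nrow(points))
  dist <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    d <- sqrt((nx - points$x[i])^2 + (ny - points$y[i])^2)
    dmin <- min(d)
    cand <- nid[d <= dmin + 1e-9]
    node[i] <- sort(cand)[1]
    dist[i] <- dmin
  }
  data.frame(id = as.character(points$id), node = node, snap_dist_m = dist,
             stringsAsFactors = FALSE)
}

#' Population grid cells
#'
#' Wraps polygonal population-grid cells (projected meters) with their
#' population counts.
#'
#' @param id character vector of cell ids.
#' @param pop numeric vector of population counts (>= 0).
#' @param geometry list of polygons; each polygon is a list of rings and
#'   each ring an n x 2 coordinate matrix (first ring outer, rest holes).
#' @return an object of class `population_cells` (a data.frame with a
#'   `geometry` list column).
#' @export
population_cells <- function(id, pop, geometry) {
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate cell ids", call. = FALSE)
  if (any(!is.finite(pop)) || any(pop < 0)) {
    stop("cell populations must be finite and >= 0", call. = FALSE)
  }
  if (length(geometry) != length(id)) {
    stop("`geometry` must have one polygon per cell", call. = FALSE)
  }
  geometry <- lapply(geometry, function(g) {
    if (is.matrix(g)) list(g) else g
  })
  out <- data.frame(id = id, pop = pop, stringsAsFactors = FALSE)
  out$geometry <- geometry
  class(out) <- c("population_cells", "data.frame")
  out
}

# node -> covering cell id (NA when uncovered); boundary-inclusive, first
# cell in input order wins, so the assignment is deterministic
.assign_nodes_to_cells <- function(network, cells) {
  out <- rep(NA_character_, nrow(network$nodes))
  for (ci in seq_len(nrow(cells))) {
    rings <- cells$geometry[[ci]]
    todo <- which(is.na(out))
    for (ni in todo) {
      if (.point_in_rings(network$nodes$x[ni], network$nodes$y[ni], rings)) {
        out[ni] <- cells$id[ci]
      }
    }
  }
  stats::setNames(out, network$nodes$id)
}

.ORIGIN_STRATEGIES <- c("FIXED_GRID_1KM", "CELL_CENTROIDS", "NEAREST_10PCT",
                        "RANDOM_10PCT", "RANDOM_5PCT")

#' Sample origin nodes from the population grid
#'
#' Implements the five origin-subsampling strategies used to represent the
#' population distribution on the road graph:
#' \describe{
#'   \item{FIXED_GRID_1KM}{nearest network node to each vertex of a
#'     1 km x 1 km lattice covering the network bounding box.}
#'   \item{CELL_CENTROIDS}{nearest in-cell node to each cell centroid.}
#'   \item{NEAREST_10PCT}{per cell, the 10\% of in-cell nodes closest
#'     (Euclidean) to the centroid-nearest node; at least 1.}
#'   \item{RANDOM_10PCT / RANDOM_5PCT}{per cell, a seeded uniform sample of
#'     10\% / 5\% of in-cell nodes; at least 1.}
#' }
#' Percentages round up with a minimum of one origin per non-empty cell, so
#' no populated cell silently loses representation. Cells containing no
#' network node contribute no origins and are reported in the
#' `empty_cells` attribute. Nodes on cell boundaries belong to the first
#' covering cell in input order.
#'
#' @param network a `road_network`.
#' @param cells a [population_cells()] object.
#' @param strategy one of the five strategy names above.
#' @param seed integer seed, required for the random strategies.
#' @return an `origin_set`: data.frame with columns `origin` (node id),
#'   `cell`, `weight` (NA until [allocate_population()] runs), plus
#'   attributes `strategy`, `seed`, `empty_cells`, and for FIXED_GRID_1KM
#'   `uncovered_origins` (lattice origins snapped to nodes outside every
#'   cell, which are dropped).
#' @export
sample_origins <- function(network, cells, strategy, seed = NULL) {
  stopifnot(inherits(network, "road_network"),
            inherits(cells, "population_cells"))
  if (!strategy %in% .ORIGIN_STRATEGIES) {
    stop(sprintf("unknown strategy '%s'; expected one of %s", strategy,
                 paste(.ORIGIN_STRATEGIES, collapse = ", ")), call. = FALSE)
  }
  random <- strategy %in% c("RANDOM_10PCT", "RANDOM_5PCT")
  if (random && is.null(seed)) {
    stop("random strategies require `seed`", call. = FALSE)
  }
  node_cell <- .assign_nodes_to_cells(network, cells)
  in_cell <- split(names(node_cell)[!is.na(node_cell)],
                   node_cell[!is.na(node_cell)])
  empty_cells <- setdiff(cells$id, names(in_cell))
  uncovered <- character(0)

  pick <- list()  # per cell: character vector of node ids
  if (strategy == "FIXED_GRID_1KM") {
    bx <- range(network$nodes$x)
    by <- range(network$nodes$y)
    gx <- seq(bx[1], by = 1000, length.out = max(2, ceiling(diff(bx) / 1000) + 1))
    gy <- seq(by[1], by = 1000, length.out = max(2, ceiling(diff(by) / 1000) + 1))
    lattice <- expand.grid(x = gx, y = gy)
    lattice$id <- sprintf("g%d", seq_len(nrow(lattice)))
    snapped <- snap_points(network, lattice)
    nodes <- unique(snapped$node)
    cell_of <- node_cell[nodes]
    uncovered <- nodes[is.na(cell_of)]
    keep <- !is.na(cell_of)
    pick <- split(nodes[keep], cell_of[keep])
  } else {
    for (ci in seq_len(nrow(cells))) {
      cid <- cells$id[ci]
      cand <- in_cell[[cid]]
      if (is.null(cand) || length(cand) == 0) next
      if (strategy == "CELL_CENTROIDS") {
        cen <- .ring_centroid(cells$geometry[[ci]][[1]])
        idx <- match(cand, network$nodes$id)
        d <- sqrt((network$nodes$x[idx] - cen[1])^2 +
                  (network$nodes$y[idx] - cen[2])^2)
        sel <- sort(cand[d <= min(d) + 1e-9])[1]
      } else if (strategy == "NEAREST_10PCT") {
        cen <- .ring_centroid(cells$geometry[[ci]][[1]])
        idx <- match(cand, network$nodes$id)
        d <- sqrt((network$nodes$x[idx] - cen[1])^2 +
                  (network$nodes$y[idx] - cen[2])^2)
        cen_node <- sort(cand[d <= min(d) + 1e-9])[1]
        ci2 <- match(cen_node, network$nodes$id)
        d2 <- sqrt((network$nodes$x[idx] - network$nodes$x[ci2])^2 +
                   (network$nodes$y[idx] - network$nodes$y[ci2])^2)
        k <- max(1L, ceiling(0.10 * length(cand)))
        ord <- order(d2, cand)  # ties by node id for determinism
        sel <- cand[ord][seq_len(k)]
      } else {
        frac <- if (strategy == "RANDOM_10PCT") 0.10 else 0.05
        k <- max(1L, ceiling(frac * length(cand)))
        # per-cell substream so sampling is independent of cell order
        cell_seed <- (as.integer(seed) + ci * 10007L) %% .Machine$integer.max
        sel <- .with_seed(cell_seed, sample(sort(cand), k))
      }
      pick[[cid]] <- sel
    }
  }

  cells_with <- names(pick)
  out <- data.frame(
    origin = unlist(pick, use.names = FALSE),
    cell = rep(cells_with, lengths(pick)),
    weight = NA_real_,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$cell, out$origin), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("origin_set", "data.frame"),
            strategy = strategy, seed = seed,
            empty_cells = empty_cells,
            uncovered_origins = uncovered)
}

# evaluate expr under a temporary seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Distribute cell populations over their sampled origins
#'
#' Within each cell holding population P and k selected origins, every
#' origin receives weight P / k, so the cell population is conserved
#' exactly for every cell that contributed at least one origin.
#'
#' @param cells a [population_cells()] object.
#' @param origins an `origin_set` from [sample_origins()].
#' @return the origin set with `weight` filled in.
#' @export
allocate_population <- function(cells, origins) {
  stopifnot(inherits(cells, "population_cells"),
            inherits(origins, "origin_set"))
  if (any(is.na(origins$cell)) || !all(origins$cell %in% cells$id)) {
    stop("every origin must be attributed to a known cell", call. = FALSE)
  }
  k <- table(origins$cell)
  pop <- stats::setNames(cells$pop, cells$id)
  origins$weight <- pop[origins$cell] / as.numeric(k[origins$cell])
  origins$weight <- unname(origins$weight)
  origins
}

#' Snap service facilities to the road network
#'
#' Facilities (points with a footprint area used as the attractivity proxy
#' in the Huff model) become routing destinations once snapped to their
#' nearest network node.
#'
#' @param network a `road_network`.
#' @param facilities data.frame with columns `id`, `x`, `y`, `area_m2`
#'   (> 0) and optionally `name`, `service_type` (default `"health"`).
#' @return an `amenities` data.frame with columns `id`, `name`, `x`, `y`,
#'   `node`, `snap_dist_m`, `area_m2`, `service_type`.
#' @export
snap_facilities <- function(network, facilities) {
  need <- c("id", "x", "y", "area_m2")
  if (!all(need %in% names(facilities))) {
    stop("`facilities` needs columns id, x, y, area_m2", call. = FALSE)
  }
  if (any(!is.finite(facilities$area_m2)) || any(facilities$area_m2 <= 0)) {
    stop("facility areas must be finite and > 0", call. = FALSE)
  }
  if (is.null(facilities$name)) facilities$name <- as.character(facilities$id)
  if (is.null(facilities$service_type)) facilities$service_type <- "health"
  sn <- snap_points(network, facilities)
  out <- data.frame(
    id = as.character(facilities$id),
    name = as.character(facilities$name),
    x = facilities$x, y = facilities$y,
    node = sn$node, snap_dist_m = sn$snap_dist_m,
    area_m2 = facilities$area_m2,
    service_type = as.character(facilities$service_type),
    stringsAsFactors = FALSE
  )
  class(out) <- c("amenities", "data.frame")
  out
}
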