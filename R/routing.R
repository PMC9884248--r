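# Shortest-path routing on the (possibly disrupted) road graph.
# igraph's Dijkstra provides distances; path reconstruction is a greedy
# walk over the shortest-path DAG choosing, at each step, the smallest
# node id consistent with the total distance — this makes tie-broken paths
# (and hence criticality imputation) reproducible.

# accept a road_network or a scenario
.as_network <- function(x) {
  if (inherits(x, "scenario")) x$network
  else if (inherits(x, "road_network")) x
  else stop("expected a road_network or scenario", call. = FALSE)
}

# igraph over routable (finite travel time) edges, plus bookkeeping
.routing_graph <- function(network, weight = c("time", "length")) {
  weight <- match.arg(weight)
  e <- network$edges
  keep <- is.finite(e$travel_time_min)
  e <- e[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("u", "v")], directed = network$directed,
    vertices = data.frame(name = network$nodes$id)
  )
  w <- if (weight == "time") e$travel_time_min else e$length_m
  list(graph = g, weights = w, edges = e)
}

# adjacency list: node -> data.frame(nbr, w_min, len_m, edge_id)
.adjacency <- function(network) {
  e <- network$edges
  keep <- is.finite(e$travel_time_min)
  e <- e[keep, , drop = FALSE]
  if (network$directed) {
    from <- e$u; to <- e$v
    w <- e$travel_time_min; len <- e$length_m; id <- e$edge_id
  } else {
    from <- c(e$u, e$v); to <- c(e$v, e$u)
    w <- rep(e$travel_time_min, 2); len <- rep(e$length_m, 2)
    id <- rep(e$edge_id, 2)
  }
  split(data.frame(nbr = to, w = w, len = len, edge_id = id,
                   stringsAsFactors = FALSE), from)
}

# Dijkstra distances (minutes) from `from` nodes to `to` nodes
.dists <- function(network, from, to, mode = "out") {
  rg <- .routing_graph(network)
  d <- igraph::distances(rg$graph, v = from, to = to, weights = rg$weights,
                         mode = mode, algorithm = "dijkstra")
  rownames(d) <- from
  colnames(d) <- to
  d
}

#' Origin-destination travel-time matrix
#'
#' Dijkstra shortest-path travel times (minutes) from every origin to
#' every facility on the scenario's network; +Inf encodes unreachability.
#' Disrupted edges are excluded from routing. Optionally the length (km)
#' of the tie-broken shortest path is reported per reachable pair.
#'
#' @param x a `road_network` or `scenario`.
#' @param origins an `origin_set`, or a character vector of node ids.
#' @param destinations an `amenities` data.frame, or a character vector of
#'   node ids.
#' @param with_km also compute path lengths in km along the tie-broken
#'   time-shortest paths (slower; reconstructs every path).
#' @return an `od_matrix`: list with `minutes` (origins x destinations
#'   matrix), optional `km`, `origins` (data.frame with node, weight),
#'   `destinations` (data.frame with id, node).
#' @export
travel_times <- function(x, origins, destinations, with_km = FALSE) {
  network <- .as_network(x)
  o <- .origin_frame(origins)
  d <- .dest_frame(destinations)
  unknown <- setdiff(unique(c(o$node, d$node)), network$nodes$id)
  if (length(unknown)) {
    stop(sprintf("unknown node id(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  dm <- .dists(network, unique(o$node), unique(d$node))
  minutes <- dm[o$node, d$node, drop = FALSE]
  rownames(minutes) <- o$id
  colnames(minutes) <- d$id
  km <- NULL
  if (with_km) {
    km <- matrix(NA_real_, nrow(minutes), ncol(minutes),
                 dimnames = dimnames(minutes))
    adj <- .adjacency(network)
    all_ids <- network$nodes$id
    dist_to <- .dists(network, unique(d$node), all_ids, mode = "in")
    for (ii in seq_len(nrow(o))) {
      if (!any(is.finite(minutes[ii, ]))) next
      dist_from <- .dists(network, o$node[ii], all_ids)[1, ]
      for (jj in seq_len(nrow(d))) {
        if (!is.finite(minutes[ii, jj])) next
        if (o$node[ii] == d$node[jj]) { km[ii, jj] <- 0; next }
        p <- .walk_path(adj, o$node[ii], d$node[jj], dist_from,
                        dist_to[d$node[jj], ])
        km[ii, jj] <- sum(p$len) / 1000
      }
    }
  }
  structure(list(minutes = minutes, km = km, origins = o, destinations = d),
            class = "od_matrix")
}

.origin_frame <- function(origins) {
  if (inherits(origins, "origin_set")) {
    data.frame(id = origins$origin, node = origins$origin,
               weight = origins$weight, stringsAsFactors = FALSE)
  } else {
    data.frame(id = as.character(origins), node = as.character(origins),
               weight = NA_real_, stringsAsFactors = FALSE)
  }
}

.dest_frame <- function(destinations) {
  if (inherits(destinations, "amenities") ||
      (is.data.frame(destinations) && all(c("id", "node") %in% names(destinations)))) {
    out <- data.frame(id = destinations$id, node = destinations$node,
                      stringsAsFactors = FALSE)
    if (!is.null(destinations$area_m2)) out$area_m2 <- destinations$area_m2
    if (!is.null(destinations$service_type)) out$service_type <- destinations$service_type
    out
  } else {
    data.frame(id = as.character(destinations),
               node = as.character(destinations), stringsAsFactors = FALSE)
  }
}

# greedy lexicographic walk over the shortest-path DAG.
# dist_from: distances origin -> all nodes; dist_to: all nodes -> dest.
.walk_path <- function(adj, from, to, dist_from, dist_to) {
  total <- dist_from[[to]]
  if (!is.finite(total)) return(NULL)
  tol <- 1e-9 * max(1, total)
  cur <- from
  nodes <- from
  edge_ids <- character(0)
  lens <- numeric(0)
  while (cur != to) {
    nb <- adj[[cur]]
    ok <- abs(dist_from[[cur]] + nb$w - dist_from[nb$nbr]) <= tol &
      abs(dist_from[nb$nbr] + dist_to[nb$nbr] - total) <= tol
    cand <- nb[ok, , drop = FALSE]
    if (nrow(cand) == 0) stop("internal: shortest-path walk stuck")
    nxt <- cand[order(cand$nbr), , drop = FALSE][1, ]
    nodes <- c(nodes, nxt$nbr)
    edge_ids <- c(edge_ids, nxt$edge_id)
    lens <- c(lens, nxt$len)
    cur <- nxt$nbr
  }
  list(nodes = nodes, edges = edge_ids, len = lens)
}

#' Edge sequence of the tie-broken shortest path
#'
#' Returns the ordered edges of the shortest path whose node sequence is
#' lexicographically smallest among all time-minimal paths — the same
#' tie-break used throughout, so travel times and imputed paths are
#' mutually consistent.
#'
#' @param x a `road_network` or `scenario`.
#' @param from,to node ids.
#' @return `NULL` when no path exists (an explicit no-path signal, not an
#'   error); otherwise a list with `nodes`, `edges` (edge ids in order),
#'   `minutes`, `km`.
#' @export
shortest_path_edges <- function(x, from, to) {
  network <- .as_network(x)
  from <- as.character(from); to <- as.character(to)
  if (!all(c(from, to) %in% network$nodes$id)) {
    stop("unknown node id", call. = FALSE)
  }
  dist_from <- .dists(network, from, network$nodes$id)[1, ]
  if (!is.finite(dist_from[[to]])) return(NULL)
  if (from == to) {
    return(list(nodes = from, edges = character(0), minutes = 0, km = 0))
  }
  dist_to <- .dists(network, to, network$nodes$id, mode = "in")[1, ]
  adj <- .adjacency(network)
  p <- .walk_path(adj, from, to, dist_from, dist_to)
  e <- network$edges
  idx <- match(p$edges, e$edge_id)
  list(nodes = p$nodes, edges = p$edges,
       minutes = sum(e$travel_time_min[idx]), km = sum(p$len) / 1000)
}

#' Partition the network into amenity-centred subgraphs
#'
#' Every node within network (shortest-path) distance `lambda_km` of an
#' amenity's node joins that amenity's subgraph; subgraphs sharing at
#' least `delta` of their nodes (overlap divided by the smaller subgraph)
#' are merged, repeatedly, until no pair crosses the threshold. Nodes in
#' no subgraph are reported as out of coverage.
#'
#' @param network a `road_network` or `scenario`.
#' @param amenities an `amenities` data.frame.
#' @param lambda_km influence radius in km (> 0); distances are measured
#'   along the network in edge length, not Euclidean.
#' @param delta merge threshold, fraction in (0, 1].
#' @return a `partition`: list with `subgraphs` (each a list with `nodes`
#'   and `amenities`), `out_of_coverage` node ids, `lambda_km`, `delta`.
#' @export
partition_network <- function(network, amenities, lambda_km, delta = 0.5) {
  network <- .as_network(network)
  if (!is.finite(lambda_km) || lambda_km <= 0) {
    stop("`lambda_km` must be > 0", call. = FALSE)
  }
  if (!(delta > 0 && delta <= 1)) {
    stop("`delta` must be in (0, 1]", call. = FALSE)
  }
  d <- .dest_frame(amenities)
  rg <- .routing_graph(network, weight = "length")
  dm <- igraph::distances(rg$graph, v = unique(d$node), to = network$nodes$id,
                          weights = rg$weights, algorithm = "dijkstra")
  balls <- lapply(seq_len(nrow(d)), function(i) {
    network$nodes$id[dm[d$node[i], ] <= lambda_km * 1000 + 1e-9]
  })
  groups <- as.list(seq_len(nrow(d)))  # each group: amenity indices
  nodesets <- balls
  repeat {
    merged <- FALSE
    n <- length(groups)
    for (a in seq_len(n - 1)) {
      if (is.null(groups[[a]])) next
      for (b in seq((a + 1), n)) {
        if (is.null(groups[[b]])) next
        ov <- length(intersect(nodesets[[a]], nodesets[[b]]))
        denom <- min(length(nodesets[[a]]), length(nodesets[[b]]))
        if (denom > 0 && ov / denom >= delta) {
          groups[[a]] <- c(groups[[a]], groups[[b]])
          nodesets[[a]] <- union(nodesets[[a]], nodesets[[b]])
          groups[b] <- list(NULL)
          merged <- TRUE
        }
      }
    }
    keep <- !vapply(groups, is.null, logical(1))
    groups <- groups[keep]
    nodesets <- nodesets[keep]
    if (!merged) break
  }
  subgraphs <- lapply(seq_along(groups), function(i) {
    list(nodes = sort(nodesets[[i]]), amenities = d$id[sort(groups[[i]])])
  })
  covered <- unique(unlist(nodesets))
  structure(list(subgraphs = subgraphs,
                 out_of_coverage = setdiff(network$nodes$id, covered),
                 lambda_km = lambda_km, delta = delta,
                 network = network, destinations = d),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d subgraphs (lambda = %g km, delta = %g), %d nodes out of coverage\n",
              length(x$subgraphs), x$lambda_km, x$delta,
              length(x$out_of_coverage)))
  invisible(x)
}

#' Travel times through the subgraph partition
#'
#' For destinations whose amenity belongs to one of the origin's
#' subgraphs the time is the exact Dijkstra time; for every other
#' destination the trip is composed as time(origin -> gateway) +
#' time(gateway -> destination), where the gateway is the time-nearest
#' amenity in the origin's subgraph and amenity-to-amenity times are
#' precomputed on the full network. Composed entries are upper bounds on
#' the exact times, with equality whenever origin, gateway and
#' destination lie on one shortest path. Origins outside every subgraph
#' get all-infinite rows and are flagged.
#'
#' @param partition a [partition_network()] result.
#' @param origins an `origin_set` or character vector of node ids.
#' @param destinations an `amenities` data.frame or node-id vector;
#'   defaults to the amenities the partition was built with.
#' @return an `od_matrix` with an extra `out_of_coverage` attribute.
#' @export
partitioned_travel_times <- function(partition, origins,
                                     destinations = partition$destinations) {
  stopifnot(inherits(partition, "partition"))
  network <- partition$network
  o <- .origin_frame(origins)
  d <- .dest_frame(destinations)
  amat <- .dists(network, unique(d$node), unique(d$node))  # amenity-amenity
  # origin node -> indices of subgraphs containing it
  minutes <- matrix(Inf, nrow(o), nrow(d), dimnames = list(o$id, d$id))
  out_flag <- logical(nrow(o))
  dest_by_id <- stats::setNames(d$node, d$id)
  for (ii in seq_len(nrow(o))) {
    sgs <- which(vapply(partition$subgraphs,
                        function(sg) o$node[ii] %in% sg$nodes, logical(1)))
    if (length(sgs) == 0) { out_flag[ii] <- TRUE; next }
    local_ids <- unique(unlist(lapply(partition$subgraphs[sgs],
                                      function(sg) sg$amenities)))
    local_ids <- intersect(local_ids, d$id)
    if (length(local_ids) == 0) { out_flag[ii] <- TRUE; next }
    t_local <- .dists(network, o$node[ii], dest_by_id[local_ids])[1, ]
    names(t_local) <- local_ids
    minutes[ii, local_ids] <- t_local
    ext <- setdiff(d$id, local_ids)
    if (length(ext)) {
      reach <- local_ids[is.finite(t_local)]
      if (length(reach)) {
        gw <- reach[order(t_local[reach], reach)][1]
        minutes[ii, ext] <- t_local[[gw]] +
          amat[dest_by_id[[gw]], dest_by_id[ext]]
      }
    }
  }
  structure(list(minutes = minutes, km = NULL, origins = o, destinations = d),
            class = "od_matrix", out_of_coverage = o$id[out_flag])
}

#' @export
print.od_matrix <- function(x, ...) {
  cat(sprintf("<od_matrix> %d origins x %d destinations; %d unreachable pairs\n",
              nrow(x$minutes), ncol(x$minutes), sum(!is.finite(x$minutes))))
  invisible(x)
}
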