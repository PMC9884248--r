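# Fixture builders and independent oracles. Everything is generated in
# code; oracles are deliberately naive (triple-loop Floyd-Warshall,
# exhaustive path enumeration) and share no code with the implementation.

# a chain a-b-c-... with given per-edge travel times (minutes), encoded
# as lengths at 60 km/h (1 km per minute)
line_network <- function(times_min) {
  n <- length(times_min) + 1
  ids <- letters[seq_len(n)]
  nodes <- data.frame(id = ids, x = c(0, cumsum(times_min)) * 1000, y = 0,
                      stringsAsFactors = FALSE)
  edges <- data.frame(u = ids[-n], v = ids[-1],
                      length_m = times_min * 1000, road_class = "r",
                      stringsAsFactors = FALSE)
  build_network(nodes, edges, speed_table(c(r = 60), 60))
}

# connected random network: spanning tree over random points + extra
# chords, random speeds per edge class
random_network <- function(n_nodes, extra = n_nodes, seed = 1) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n_nodes))
  x <- runif(n_nodes, 0, 5000)
  y <- runif(n_nodes, 0, 5000)
  u <- character(0); v <- character(0)
  for (i in 2:n_nodes) {       # random spanning tree
    j <- sample(i - 1, 1)
    u <- c(u, ids[j]); v <- c(v, ids[i])
  }
  tries <- 0
  while (extra > 0 && tries < 50 * extra) {
    ij <- sample(n_nodes, 2)
    e <- paste(sort(ids[ij]), collapse = "-")
    if (!e %in% paste(pmin(u, v), pmax(u, v), sep = "-")) {
      u <- c(u, ids[ij[1]]); v <- c(v, ids[ij[2]])
      extra <- extra - 1
    }
    tries <- tries + 1
  }
  iu <- match(u, ids); iv <- match(v, ids)
  len <- pmax(1, sqrt((x[iu] - x[iv])^2 + (y[iu] - y[iv])^2))
  cls <- sample(c("fast", "slow"), length(u), replace = TRUE)
  nodes <- data.frame(id = ids, x = x, y = y, stringsAsFactors = FALSE)
  edges <- data.frame(u = u, v = v, length_m = len, road_class = cls,
                      stringsAsFactors = FALSE)
  build_network(nodes, edges, speed_table(c(fast = 60, slow = 25), 30))
}

# independent all-pairs shortest-path oracle (undirected travel times)
floyd_warshall <- function(network) {
  ids <- network$nodes$id
  n <- length(ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  e <- network$edges
  for (i in seq_len(nrow(e))) {
    w <- e$travel_time_min[i]
    if (!is.finite(w)) next
    iu <- match(e$u[i], ids); iv <- match(e$v[i], ids)
    D[iu, iv] <- min(D[iu, iv], w)
    D[iv, iu] <- min(D[iv, iu], w)
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# exhaustive tie-broken shortest path: enumerate all simple paths, keep
# the minimal-time ones, break ties on the lexicographically smallest
# node sequence
enumerate_shortest_path <- function(network, from, to) {
  e <- network$edges[is.finite(network$edges$travel_time_min), , drop = FALSE]
  g <- igraph::graph_from_data_frame(e[, c("u", "v")], directed = FALSE,
                                     vertices = network$nodes$id)
  wt <- stats::setNames(e$travel_time_min, e$edge_id)
  paths <- igraph::all_simple_paths(g, from, to)
  if (length(paths) == 0) return(NULL)
  best <- NULL; best_t <- Inf
  for (p in paths) {
    nm <- igraph::as_ids(p)
    tt <- 0
    for (i in seq_len(length(nm) - 1)) {
      eid <- paste(sort(c(nm[i], nm[i + 1])), collapse = "--")
      tt <- tt + wt[[eid]]
    }
    if (tt < best_t - 1e-9) {
      best <- list(nm); best_t <- tt
    } else if (abs(tt - best_t) <= 1e-9) {
      best <- c(best, list(nm))
    }
  }
  key <- vapply(best, paste, character(1), collapse = "\r")
  list(nodes = best[[order(key)[1]]], minutes = best_t)
}

# brute-force criticality oracle: for every origin/facility pair, find
# the tie-broken shortest path by enumeration and accumulate
# alpha * w * P over its edges
criticality_oracle <- function(network, od, P, weights, alpha = 1) {
  score <- stats::setNames(rep(0, nrow(network$edges)),
                           network$edges$edge_id)
  onodes <- od$origins$node
  dnodes <- od$destinations$node
  for (i in seq_along(onodes)) {
    for (j in seq_along(dnodes)) {
      if (!is.finite(od$minutes[i, j])) next
      contrib <- alpha * weights[i] * P[i, j]
      if (contrib == 0 || onodes[i] == dnodes[j]) next
      p <- enumerate_shortest_path(network, onodes[i], dnodes[j])
      nm <- p$nodes
      for (k in seq_len(length(nm) - 1)) {
        eid <- paste(sort(c(nm[k], nm[k + 1])), collapse = "--")
        score[eid] <- score[eid] + contrib
      }
    }
  }
  score
}

# small city bundle used across metric tests
toy_city <- function(seed = 1, rows = 5, cols = 5, n_facilities = 3) {
  generate_city(city_spec(rows = rows, cols = cols, spacing_m = 500,
                          n_facilities = n_facilities, seed = seed))
}

weighted_origins <- function(city, strategy = "CELL_CENTROIDS", seed = 11) {
  allocate_population(city$cells,
                      sample_origins(city$network, city$cells, strategy,
                                     seed = seed))
}
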