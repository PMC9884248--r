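test_that("edge travel times derive from length and class speed", {
  nodes <- data.frame(id = c("a", "b", "c"), x = c(0, 1000, 3000), y = 0)
  edges <- data.frame(u = c("a", "b"), v = c("b", "c"),
                      length_m = c(1000, 2000),
                      road_class = c("arterial", "weird"))
  net <- build_network(nodes, edges, speed_table(c(arterial = 60), default = 30))
  e <- net$edges
  expect_equal(e$travel_time_min[e$u == "a"], 1)          # 1 km at 60 km/h
  expect_equal(e$speed_kph[e$u == "b"], 30)               # default fallback
  expect_equal(e$travel_time_min[e$u == "b"], 2000 / (30 * 1000 / 60))
  # consistency invariant at tight tolerance
  expect_equal(e$travel_time_min, e$length_m / (e$speed_kph * 1000 / 60),
               tolerance = 1e-9)
})

test_that("structural and validation errors are raised on bad graphs", {
  nodes <- data.frame(id = c("a", "b"), x = c(0, 100), y = 0)
  expect_error(
    build_network(nodes, data.frame(u = "a", v = "zz", length_m = 10)),
    "zz")
  expect_error(
    build_network(nodes, data.frame(u = "a", v = "b", length_m = -5)),
    "length")
  expect_error(
    build_network(nodes, data.frame(u = "a", v = "a", length_m = 5)),
    "self-loop")
  expect_error(speed_table(c(x = -10)), "speeds")
  expect_error(
    build_network(data.frame(id = c("a", "a"), x = 0, y = 0),
                  data.frame(u = "a", v = "a", length_m = 1)),
    "duplicate")
})

test_that("points snap to the Euclidean-nearest node with id tie-break", {
  nodes <- data.frame(id = c("B", "A", "C"), x = c(0, 100, 200), y = 0)
  edges <- data.frame(u = c("B", "A"), v = c("A", "C"), length_m = 100)
  net <- build_network(nodes, edges)
  # identity: a point exactly on a node
  s <- snap_points(net, data.frame(id = "p", x = 100, y = 0))
  expect_equal(s$node, "A")
  expect_equal(s$snap_dist_m, 0)
  # nearest with reported distance
  s <- snap_points(net, data.frame(id = "p", x = 5, y = 0))
  expect_equal(s$node, "B")
  expect_equal(s$snap_dist_m, 5)
  # exact tie at x = 50 between B (0) and A (100): smaller id wins
  s <- snap_points(net, data.frame(id = "p", x = 50, y = 0))
  expect_equal(s$node, "A")
  # idempotence: snapping the snapped location returns the same node
  idx <- match(s$node, net$nodes$id)
  s2 <- snap_points(net, data.frame(id = "p", x = net$nodes$x[idx],
                                    y = net$nodes$y[idx]))
  expect_equal(s2$node, s$node)
  expect_equal(s2$snap_dist_m, 0)
  expect_error(snap_points(net, data.frame(id = "p", x = NaN, y = 0)),
               "finite")
})

test_that("origin sampling follows the per-strategy counting rules", {
  city <- toy_city(seed = 3, rows = 6, cols = 6)
  net <- city$network
  cells <- city$cells

  # CELL_CENTROIDS: one origin per cell containing nodes
  oc <- sample_origins(net, cells, "CELL_CENTROIDS")
  covered <- setdiff(cells$id, attr(oc, "empty_cells"))
  expect_equal(sort(unique(oc$cell)), sort(covered))
  expect_equal(nrow(oc), length(covered))

  # RANDOM_5PCT: ceil(0.05 * k) with minimum 1 per cell
  o5 <- sample_origins(net, cells, "RANDOM_5PCT", seed = 9)
  per_cell_nodes <- table(oc$cell)  # at least these cells have nodes
  cnt <- table(o5$cell)
  expect_true(all(cnt >= 1))
  # a cell of a 6x6 city with cell_span 2 holds <= 9 nodes -> exactly 1
  expect_true(all(cnt == 1))

  # NEAREST_10PCT: ceil(0.10 * k), minimum 1
  o10 <- sample_origins(net, cells, "NEAREST_10PCT")
  expect_true(all(table(o10$cell) >= 1))

  # determinism: same inputs and seed give identical origin sets
  o5b <- sample_origins(net, cells, "RANDOM_5PCT", seed = 9)
  expect_identical(o5$origin, o5b$origin)
  o10b <- sample_origins(net, cells, "RANDOM_10PCT", seed = 4)
  o10c <- sample_origins(net, cells, "RANDOM_10PCT", seed = 4)
  expect_identical(o10b$origin, o10c$origin)

  expect_error(sample_origins(net, cells, "KMEANS"), "unknown strategy")
  expect_error(sample_origins(net, cells, "RANDOM_10PCT"), "seed")
})

test_that("the minimum-one rule keeps small cells represented", {
  # one cell with 20 in-cell nodes: ceil(0.05 * 20) = 1 origin
  nodes <- data.frame(id = sprintf("n%02d", 1:20),
                      x = rep(c(0, 100, 200, 300, 400), 4),
                      y = rep(c(0, 100, 200, 300), each = 5))
  edges <- data.frame(u = nodes$id[-20], v = nodes$id[-1], length_m = 100)
  net <- build_network(nodes, edges)
  cells <- population_cells("only", 500,
                            list(list(cbind(c(-50, 450, 450, -50),
                                            c(-50, -50, 350, 350)))))
  o <- sample_origins(net, cells, "RANDOM_5PCT", seed = 2)
  expect_equal(nrow(o), 1)
})

test_that("fixed 1 km lattice origins land on network nodes", {
  city <- generate_city(city_spec(rows = 5, cols = 5, spacing_m = 1000,
                                  seed = 2))
  o <- sample_origins(city$network, city$cells, "FIXED_GRID_1KM")
  expect_true(all(o$origin %in% city$network$nodes$id))
  expect_true(nrow(o) >= 1)
  # with 1 km node spacing every lattice vertex snaps exactly onto a node
  expect_equal(sort(unique(o$origin)), sort(city$network$nodes$id))
})

test_that("population allocation conserves cell populations", {
  city <- demo_city()
  # three origins in a 300-person cell get one third each
  o <- structure(data.frame(origin = c("A", "B", "D"), cell = "Gr11",
                            weight = NA_real_, stringsAsFactors = FALSE),
                 class = c("origin_set", "data.frame"))
  o <- allocate_population(city$cells, o)
  expect_equal(o$weight, c(100, 100, 100))

  # zero-population cell gives zero weights
  cells0 <- population_cells("z", 0, list(list(cbind(c(0, 10, 10, 0),
                                                     c(0, 0, 10, 10)))))
  o0 <- structure(data.frame(origin = c("p", "q"), cell = "z",
                             weight = NA_real_, stringsAsFactors = FALSE),
                  class = c("origin_set", "data.frame"))
  expect_equal(allocate_population(cells0, o0)$weight, c(0, 0))

  # conservation across cells: (100, 2 origins) + (50, 1 origin) -> 150
  cells2 <- population_cells(c("a", "b"), c(100, 50), list(
    list(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))),
    list(cbind(c(20, 30, 30, 20), c(0, 0, 10, 10)))))
  o2 <- structure(data.frame(origin = c("p", "q", "r"),
                             cell = c("a", "a", "b"),
                             weight = NA_real_, stringsAsFactors = FALSE),
                  class = c("origin_set", "data.frame"))
  expect_equal(sum(allocate_population(cells2, o2)$weight), 150)

  # property: for sampled origins of random cities, per-cell sums equal
  # cell populations exactly
  for (seed in 1:3) {
    city <- toy_city(seed = seed)
    o <- weighted_origins(city, "RANDOM_10PCT", seed = seed)
    sums <- tapply(o$weight, o$cell, sum)
    pops <- stats::setNames(city$cells$pop, city$cells$id)
    expect_equal(as.numeric(sums), as.numeric(pops[names(sums)]))
  }

  expect_error(allocate_population(city$cells, structure(
    data.frame(origin = "x", cell = "nope", weight = NA_real_),
    class = c("origin_set", "data.frame"))), "cell")
})

test_that("boundary nodes join the first covering cell in input order", {
  nodes <- data.frame(id = c("m"), x = 100, y = 0)
  nodes <- rbind(nodes, data.frame(id = "n", x = 150, y = 0))
  edges <- data.frame(u = "m", v = "n", length_m = 50)
  net <- build_network(nodes, edges)
  # node m sits exactly on the shared boundary x = 100
  left <- list(cbind(c(0, 100, 100, 0), c(-50, -50, 50, 50)))
  right <- list(cbind(c(100, 200, 200, 100), c(-50, -50, 50, 50)))
  cells_lr <- population_cells(c("L", "R"), c(10, 20), list(left, right))
  o <- sample_origins(net, cells_lr, "CELL_CENTROIDS")
  expect_true("L" %in% o$cell[o$origin == "m"] ||
              !"m" %in% o$origin ||
              o$cell[o$origin == "m"] == "L")
  cells_rl <- population_cells(c("R", "L"), c(20, 10), list(right, left))
  # flipping input order flips the assignment of the boundary node
  a1 <- roadaccess:::.assign_nodes_to_cells(net, cells_lr)
  a2 <- roadaccess:::.assign_nodes_to_cells(net, cells_rl)
  expect_equal(unname(a1["m"]), "L")
  expect_equal(unname(a2["m"]), "R")
})

test_that("facility snapping validates areas and attaches nodes", {
  city <- toy_city(seed = 5)
  fac <- data.frame(id = "h1", x = 260, y = 240, area_m2 = 1500)
  am <- snap_facilities(city$network, fac)
  expect_true(am$node %in% city$network$nodes$id)
  expect_error(snap_facilities(city$network,
                               transform(fac, area_m2 = 0)), "area")
})
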