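test_that("Huff probabilities reproduce direct evaluations", {
  net <- line_network(c(10, 10))          # a-b-c at 10 min per edge
  fac <- snap_facilities(net, data.frame(id = c("F1", "F2"),
                                         x = c(0, 20000), y = 0,
                                         area_m2 = c(200, 100)))
  od <- travel_times(net, "b", fac)       # both 10 min from b
  p <- huff_probabilities(od, "b")
  # areas (200, 100) at equal times: (2/3, 1/3)
  expect_equal(unname(p), c(2 / 3, 1 / 3))
  # equal areas, equal times: symmetry
  fac$area_m2 <- c(100, 100)
  od2 <- travel_times(net, "b", fac)
  expect_equal(unname(huff_probabilities(od2, "b")), c(0.5, 0.5))
  # single reachable facility: probability one
  od1 <- travel_times(net, "b", fac[1, ])
  expect_equal(unname(huff_probabilities(od1, "b")), 1)
  expect_error(huff_probabilities(od, "b", areas = c(F1 = -5, F2 = 1)),
               "area")
})

test_that("choice rows are normalized, scale-invariant, and clamp t = 0", {
  for (seed in 1:3) {
    city <- toy_city(seed = seed, rows = 5, cols = 5, n_facilities = 4)
    origins <- weighted_origins(city, "RANDOM_10PCT", seed = seed)
    od <- travel_times(city$network, origins, city$facilities)
    ch <- choice_matrix(od)
    reach <- apply(od$minutes, 1, function(r) any(is.finite(r)))
    expect_equal(unname(rowSums(ch$P)[reach]),
                 rep(1, sum(reach)), tolerance = 1e-12)
    expect_true(all(ch$P >= 0))
    # multiplying all areas by a constant changes nothing
    big <- stats::setNames(od$destinations$area_m2 * 1e4,
                           od$destinations$id)
    ch2 <- choice_matrix(od, areas = big)
    expect_equal(ch2$P, ch$P, tolerance = 1e-12)
  }
  # origin co-located with a facility: finite probabilities, co-located
  # facility strongly preferred
  net <- line_network(c(1))
  fac <- snap_facilities(net, data.frame(id = c("here", "there"),
                                         x = c(0, 1000), y = 0,
                                         area_m2 = c(100, 100)))
  od <- travel_times(net, "a", fac)
  p <- huff_probabilities(od, "a")
  expect_true(all(is.finite(p)))
  expect_gt(p[["here"]], 0.9)  # 1/0.1 min floor vs 1 min
})

test_that("accessibility is the probability-weighted expected time", {
  net <- line_network(c(10, 10))
  fac <- snap_facilities(net, data.frame(id = c("F1", "F2"),
                                         x = c(0, 20000), y = 0,
                                         area_m2 = c(100, 100)))
  # from a: t = (~0, 20) -> use b: t = (10, 10), P = (.5, .5) -> 10
  od <- travel_times(net, c("a", "b"), fac)
  ch <- choice_matrix(od)
  acc <- accessibility(od, ch)
  expect_equal(acc$accessibility_min[acc$origin == "b"], 10)
  # t = (10, 20) with forced P = (.5, .5) -> 15
  P <- matrix(c(0.5, 0.5), 1, dimnames = list("a", c("F1", "F2")))
  odx <- od
  odx$minutes <- matrix(c(10, 20), 1, dimnames = list("a", c("F1", "F2")))
  odx$origins <- odx$origins[1, ]
  chx <- structure(list(P = P, od = odx), class = "choice_matrix")
  expect_equal(accessibility(odx, chx)$accessibility_min, 15)
  # single facility: accessibility equals its travel time; bounds hold
  od1 <- travel_times(net, "b", fac[2, ])
  expect_equal(accessibility(od1)$accessibility_min, od1$minutes[1, 1])
  for (seed in 4:5) {
    city <- toy_city(seed = seed)
    origins <- weighted_origins(city)
    od <- travel_times(city$network, origins, city$facilities)
    acc <- accessibility(od)
    fin <- !acc$isolated
    tmin <- apply(od$minutes, 1, min)
    tmax <- apply(od$minutes, 1, function(r) max(r[is.finite(r)]))
    expect_true(all(acc$accessibility_min[fin] >= tmin[fin] - 1e-9))
    expect_true(all(acc$accessibility_min[fin] <= tmax[fin] + 1e-9))
  }
})

test_that("criticality accumulates per-trip contributions on path edges", {
  city <- demo_city()
  # two origins A and C reaching facility H share edge F--H: its score is
  # the sum of both trip contributions c1 + c2
  o <- structure(data.frame(origin = c("A", "C"), cell = c("Gr11", "Gr12"),
                            weight = c(300, 200), stringsAsFactors = FALSE),
                 class = c("origin_set", "data.frame"))
  facH <- city$facilities[city$facilities$id == "H", ]
  class(facH) <- class(city$facilities)
  od <- travel_times(city$network, o, facH)
  ch <- choice_matrix(od)   # single facility: P = 1 for both
  cr <- criticality(city$network, od, ch)
  sc <- stats::setNames(cr$score, cr$edge_id)
  c1 <- 1 * 300 * 1
  c2 <- 1 * 200 * 1
  expect_equal(unname(sc["F--H"]), c1 + c2)
  expect_equal(unname(sc["A--D"]), c1)
  expect_equal(unname(sc["C--F"]), c2)
  # edges on no used path score zero
  expect_equal(unname(sc["I--J"]), 0)

  # doubling alpha doubles every score
  cr2 <- criticality(city$network, od, ch,
                     service_importance(c(health = 2)))
  expect_equal(cr2$score, 2 * cr$score)
})

test_that("criticality matches the path-enumeration oracle", {
  for (seed in 21:23) {
    net <- random_network(8, extra = 4, seed = seed)
    fac <- snap_facilities(net, data.frame(
      id = c("g1", "g2"), x = c(1000, 4000), y = c(1000, 4000),
      area_m2 = c(3000, 1000)))
    o <- structure(data.frame(origin = net$nodes$id[1:4],
                              cell = "c", weight = c(120, 80, 50, 10),
                              stringsAsFactors = FALSE),
                   class = c("origin_set", "data.frame"))
    od <- travel_times(net, o, fac)
    ch <- choice_matrix(od)
    got <- criticality(net, od, ch)
    want <- criticality_oracle(net, od, ch$P, o$weight)
    expect_equal(stats::setNames(got$score, got$edge_id), want,
                 tolerance = 1e-9)
    # conservation: total score equals sum over trips of
    # contribution x path length in edges
    total <- 0
    for (i in 1:4) {
      for (j in 1:2) {
        if (!is.finite(od$minutes[i, j])) next
        p <- shortest_path_edges(net, o$origin[i], od$destinations$node[j])
        total <- total + o$weight[i] * ch$P[i, j] * length(p$edges)
      }
    }
    expect_equal(sum(got$score), total, tolerance = 1e-9)
  }
})

test_that("isolation totals the population that can reach nothing", {
  city <- demo_city()
  origins <- weighted_origins(city)  # centroid origins with weights
  od <- travel_times(city$network, origins, city$facilities)
  expect_equal(isolation(od)$total, 0)  # fully connected city
  # cutting the only edge into A isolates exactly A's population
  cut <- city$network
  cut$edges$travel_time_min[cut$edges$edge_id == "A--D"] <- Inf
  oA <- structure(data.frame(origin = c("A", "C"),
                             cell = c("Gr11", "Gr12"),
                             weight = c(300, 200), stringsAsFactors = FALSE),
                  class = c("origin_set", "data.frame"))
  odc <- travel_times(cut, oA, city$facilities)
  iso <- isolation(odc)
  expect_equal(iso$total, 300)
  expect_equal(iso$isolated_origins, "A")
  # all facilities disrupted: everyone is isolated
  dead <- city$network
  dead$edges$travel_time_min[] <- Inf
  odd <- travel_times(dead, oA, city$facilities)
  expect_equal(isolation(odd)$total, 500)
})

test_that("compound aggregation follows sum/max semantics", {
  city <- toy_city(seed = 7)
  origins <- weighted_origins(city)
  b1 <- generate_hazard_band(city, "flood", "vertical", 750, 200, 8,
                             id = "h1")
  b2 <- generate_hazard_band(city, "flood", "horizontal", 750, 200, 20,
                             id = "h2")
  res <- lapply(list(b1, b2), function(b) {
    scn <- compose_hazards(city$network, list(b), hazard_rule())
    od <- travel_times(scn, origins, city$facilities)
    ch <- choice_matrix(od)
    list(crit = criticality(scn, od, ch), acc = accessibility(od, ch))
  })
  crits <- lapply(res, `[[`, "crit")
  s <- compound_aggregate(crits, "sum")
  m <- compound_aggregate(crits, "max")
  # identical inputs: sum doubles, max preserves
  ss <- compound_aggregate(list(crits[[1]], crits[[1]]), "sum")
  mm <- compound_aggregate(list(crits[[1]], crits[[1]]), "max")
  expect_equal(ss$score, 2 * crits[[1]]$score)
  expect_equal(mm$score, crits[[1]]$score)
  # single result: both modes are the identity
  expect_equal(compound_aggregate(crits[1], "sum")$score, crits[[1]]$score)
  expect_equal(compound_aggregate(crits[1], "max")$score, crits[[1]]$score)
  # elementwise max never exceeds the sum
  expect_true(all(m$score <= s$score + 1e-12))
  # accessibility combines by max only
  accs <- lapply(res, `[[`, "acc")
  cacc <- compound_aggregate(accs, "max")
  expect_equal(cacc$accessibility_min,
               pmax(accs[[1]]$accessibility_min, accs[[2]]$accessibility_min))
  expect_error(compound_aggregate(accs, "sum"), "max")
  # compound isolation contains each constituent's isolated set
  expect_true(all(accs[[1]]$isolated <= cacc$isolated))
  expect_true(all(accs[[2]]$isolated <= cacc$isolated))
})

test_that("comparing a scenario with itself gives the null comparison", {
  city <- toy_city(seed = 9)
  origins <- weighted_origins(city)
  od <- travel_times(city$network, origins, city$facilities)
  acc <- accessibility(od)
  cmp <- compare_scenarios(acc, acc)
  expect_equal(cmp$js_divergence, 0)
  expect_equal(cmp$changed_fraction, 0)
  expect_equal(nrow(cmp$preference_shift), 0)
  expect_equal(cmp$mean_time_delta_min, 0)
  # the binned population shares always total 100%
  expect_equal(sum(cmp$access_table_baseline$share_pct), 100)
})

test_that("preference shifts count origins switching their top choice", {
  # hand-built 5-origin comparison: switch counts equal direct argmax diff
  mk_acc <- function(top) {
    structure(data.frame(origin = sprintf("o%d", 1:5), weight = 10,
                         accessibility_min = c(10, 20, 30, 40, 50),
                         isolated = FALSE, top_choice = top,
                         stringsAsFactors = FALSE),
              class = c("access_result", "data.frame"))
  }
  base <- mk_acc(c("H", "H", "J", "J", "H"))
  dis <- mk_acc(c("H", "J", "J", "H", "J"))
  cmp <- compare_scenarios(base, dis)
  expect_equal(cmp$changed_fraction, 3 / 5)
  sh <- cmp$preference_shift
  expect_equal(sh$count[sh$from == "H" & sh$to == "J"], 2)
  expect_equal(sh$count[sh$from == "J" & sh$to == "H"], 1)
  # one switching origin gives a single unit-weight shift edge
  one <- mk_acc(c("H", "H", "J", "J", "H"))
  one$top_choice[1] <- "H"
  dis1 <- mk_acc(c("J", "H", "J", "J", "H"))
  cmp1 <- compare_scenarios(one, dis1)
  expect_equal(cmp1$preference_shift$count, 1)
  expect_equal(cmp1$preference_shift$from, "H")
  expect_equal(cmp1$preference_shift$to, "J")
  # mismatched origin sets are rejected
  other <- mk_acc(c("H", "H", "J", "J", "H"))
  other$origin <- sprintf("x%d", 1:5)
  expect_error(compare_scenarios(base, other), "origin")
  # isolated origins are excluded from the change fraction
  dis2 <- mk_acc(c("H", "J", "J", "H", "J"))
  dis2$isolated[5] <- TRUE
  dis2$accessibility_min[5] <- Inf
  cmp2 <- compare_scenarios(base, dis2)
  expect_equal(cmp2$n_compared, 4)
  expect_equal(cmp2$changed_fraction, 2 / 4)
  expect_equal(cmp2$n_isolated_any, 1)
})
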