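# Core measures: Huff facility-choice probabilities, expected access time,
# preference-weighted edge criticality, isolated population, compound
# aggregation and scenario comparison.

#' Huff choice probabilities for one origin
#'
#' Gravity-type destination choice: the probability of visiting facility j
#' from origin i is proportional to its attractivity (footprint area A_j,
#' the capacity proxy) divided by the travel time t_ij, normalized over
#' the reachable facilities. Unreachable facilities are excluded from both
#' numerator and denominator and get probability 0; an origin with no
#' reachable facility gets an all-zero row (isolated). A travel time of 0
#' (origin co-located with the facility) is clamped to `t_floor_min` to
#' avoid division by zero while preserving near-certain choice.
#'
#' @param od an `od_matrix`.
#' @param origin origin id (a row of the matrix).
#' @param areas named vector of facility areas (m^2); defaults to the
#'   `area_m2` column captured in the od matrix destinations.
#' @param t_floor_min floor for zero travel times, minutes.
#' @return named probability vector over facilities.
#' @export
huff_probabilities <- function(od, origin, areas = NULL, t_floor_min = 0.1) {
  stopifnot(inherits(od, "od_matrix"))
  if (is.null(areas)) {
    if (is.null(od$destinations$area_m2)) {
      stop("`areas` required when od matrix has no area_m2", call. = FALSE)
    }
    areas <- stats::setNames(od$destinations$area_m2, od$destinations$id)
  }
  t <- od$minutes[origin, ]
  areas <- areas[colnames(od$minutes)]
  if (any(!is.finite(areas)) || any(areas <= 0)) {
    stop("facility areas must be finite and > 0", call. = FALSE)
  }
  p <- stats::setNames(rep(0, length(t)), colnames(od$minutes))
  reach <- is.finite(t)
  if (!any(reach)) return(p)
  tt <- pmax(t[reach], t_floor_min)
  a <- areas[reach] / tt
  p[reach] <- a / sum(a)
  p
}

#' Huff choice matrix over all origins
#'
#' Row-wise [huff_probabilities()] for every origin of the od matrix.
#'
#' @inheritParams huff_probabilities
#' @return a `choice_matrix`: list with `P` (origins x facilities matrix,
#'   rows of reachable origins summing to 1) and `od`.
#' @export
choice_matrix <- function(od, areas = NULL, t_floor_min = 0.1) {
  P <- matrix(0, nrow(od$minutes), ncol(od$minutes),
              dimnames = dimnames(od$minutes))
  for (i in rownames(od$minutes)) {
    P[i, ] <- huff_probabilities(od, i, areas, t_floor_min)
  }
  structure(list(P = P, od = od), class = "choice_matrix")
}

#' Expected access time per origin
#'
#' Accessibility of origin i is the choice-probability-weighted sum of
#' travel times over reachable facilities — the expected time to access
#' the whole service system, not just the closest facility. Origins with
#' no reachable facility are flagged isolated and excluded from the
#' summary statistics.
#'
#' @param od an `od_matrix`.
#' @param choice a [choice_matrix()]; computed from `od` if omitted.
#' @return an `access_result`: data.frame with `origin`, `weight`,
#'   `accessibility_min`, `isolated`, `top_choice`; attributes `mean`,
#'   `median` over non-isolated origins.
#' @export
accessibility <- function(od, choice = choice_matrix(od)) {
  stopifnot(inherits(od, "od_matrix"), inherits(choice, "choice_matrix"))
  P <- choice$P
  t <- od$minutes
  acc <- numeric(nrow(t))
  top <- character(nrow(t))
  iso <- logical(nrow(t))
  for (i in seq_len(nrow(t))) {
    reach <- is.finite(t[i, ]) & P[i, ] > 0
    if (!any(is.finite(t[i, ]))) {
      iso[i] <- TRUE
      acc[i] <- Inf
      top[i] <- NA_character_
    } else {
      acc[i] <- sum(t[i, reach] * P[i, reach])
      top[i] <- colnames(P)[which.max(P[i, ])]
    }
  }
  out <- data.frame(origin = rownames(t), weight = od$origins$weight,
                    accessibility_min = acc, isolated = iso,
                    top_choice = top, stringsAsFactors = FALSE)
  structure(out, class = c("access_result", "data.frame"),
            mean = mean(acc[!iso]), median = stats::median(acc[!iso]))
}

#' Service-importance weights
#'
#' Per-service-type importance factors alpha supplied by the analyst
#' (e.g. health vs. education); they scale criticality contributions.
#'
#' @param alpha named non-negative numeric vector, service type -> alpha.
#' @param default alpha for types missing from the map.
#' @return a `service_importance` object.
#' @export
service_importance <- function(alpha = c(health = 1), default = 1) {
  alpha <- unlist(alpha)
  if (any(!is.finite(alpha)) || any(alpha < 0)) {
    stop("alpha values must be finite and >= 0", call. = FALSE)
  }
  structure(list(alpha = alpha, default = default),
            class = "service_importance")
}

.lookup_alpha <- function(imp, service_type) {
  out <- unname(imp$alpha[service_type])
  out[is.na(out)] <- imp$default
  out
}

#' Preference-weighted road-segment criticality
#'
#' For every origin i (population weight w) and reachable facility j, the
#' trip contributes alpha * w * P[i, j] to each edge on the tie-broken
#' shortest path from i to j; an edge's criticality is the sum over all
#' trips — a population- and preference-weighted edge betweenness. Edges
#' on no used path score 0. The scaled score is min-max over edges with
#' nonzero score; ranking is by descending score with ties broken by edge
#' id.
#'
#' @param x a `road_network` or `scenario`.
#' @param od an `od_matrix` built on `x` (origins must carry weights).
#' @param choice a [choice_matrix()] for `od`.
#' @param importance a [service_importance()]; facilities' `service_type`
#'   (when present in the od destinations) selects each alpha.
#' @return a `criticality_result` data.frame: `edge_id`, `score`,
#'   `scaled`, `rank`.
#' @export
criticality <- function(x, od, choice = choice_matrix(od),
                        importance = service_importance()) {
  network <- .as_network(x)
  stopifnot(inherits(od, "od_matrix"), inherits(choice, "choice_matrix"))
  w <- od$origins$weight
  if (any(is.na(w))) {
    stop("origins must carry population weights (run allocate_population)",
         call. = FALSE)
  }
  st <- od$destinations$service_type
  if (is.null(st)) st <- rep("health", nrow(od$destinations))
  alpha <- .lookup_alpha(importance, st)

  score <- stats::setNames(rep(0, nrow(network$edges)),
                           network$edges$edge_id)
  adj <- .adjacency(network)
  all_ids <- network$nodes$id
  dnodes <- unique(od$destinations$node)
  dist_to <- .dists(network, dnodes, all_ids, mode = "in")
  for (ii in seq_len(nrow(od$minutes))) {
    t_row <- od$minutes[ii, ]
    if (!any(is.finite(t_row))) next
    onode <- od$origins$node[ii]
    dist_from <- .dists(network, onode, all_ids)[1, ]
    for (jj in seq_len(ncol(od$minutes))) {
      if (!is.finite(t_row[jj])) next
      contrib <- alpha[jj] * w[ii] * choice$P[ii, jj]
      if (contrib == 0) next
      jnode <- od$destinations$node[jj]
      if (onode == jnode) next  # zero-length trip touches no edge
      p <- .walk_path(adj, onode, jnode, dist_from, dist_to[jnode, ])
      score[p$edges] <- score[p$edges] + contrib
    }
  }
  nz <- score > 0
  scaled <- rep(0, length(score))
  if (any(nz)) {
    rng <- range(score[nz])
    scaled[nz] <- if (diff(rng) == 0) 1 else (score[nz] - rng[1]) / diff(rng)
  }
  ord <- order(-score, names(score))
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  out <- data.frame(edge_id = names(score), score = unname(score),
                    scaled = scaled, rank = rank, stringsAsFactors = FALSE)
  structure(out, class = c("criticality_result", "data.frame"))
}

#' Isolated population
#'
#' An origin is isolated when no facility is reachable from it; the
#' isolation total is the summed population weight of isolated origins.
#'
#' @param od an `od_matrix` whose origins carry weights.
#' @return an `isolation_result`: list with `total` (persons),
#'   `isolated_origins` (ids), `n_origins`.
#' @export
isolation <- function(od) {
  stopifnot(inherits(od, "od_matrix"))
  iso <- !apply(od$minutes, 1, function(r) any(is.finite(r)))
  w <- od$origins$weight
  total <- sum(w[iso], na.rm = FALSE)
  if (length(w[iso]) == 0) total <- 0
  structure(list(total = total,
                 isolated_origins = od$origins$id[iso],
                 n_origins = nrow(od$minutes)),
            class = "isolation_result")
}

#' @export
print.isolation_result <- function(x, ...) {
  cat(sprintf("<isolation> %g persons isolated at %d of %d origins\n",
              x$total, length(x$isolated_origins), x$n_origins))
  invisible(x)
}

#' Combine per-hazard results into a compound result
#'
#' Per-edge criticality from several single-hazard scenarios is combined
#' elementwise by sum or max; per-origin accessibility is always combined
#' by max (requesting sum for accessibility is an error). Elementwise max
#' never exceeds the sum for non-negative scores.
#'
#' @param results list of `criticality_result` or `access_result` objects
#'   over identical edges / origins.
#' @param mode `"sum"` or `"max"`; ignored (forced to max) for
#'   accessibility.
#' @return a combined object of the same class.
#' @export
compound_aggregate <- function(results, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  stopifnot(length(results) >= 1)
  first <- results[[1]]
  if (inherits(first, "access_result")) {
    if (mode == "sum") {
      stop("accessibility combines only by max across hazards", call. = FALSE)
    }
    out <- first
    for (r in results[-1]) {
      stopifnot(identical(r$origin, out$origin))
      out$accessibility_min <- pmax(out$accessibility_min, r$accessibility_min)
      out$isolated <- out$isolated | r$isolated
    }
    out$top_choice <- NULL  # undefined for an aggregated scenario
    attr(out, "mean") <- mean(out$accessibility_min[!out$isolated])
    attr(out, "median") <- stats::median(out$accessibility_min[!out$isolated])
    return(out)
  }
  if (!inherits(first, "criticality_result")) {
    stop("results must be criticality_result or access_result objects",
         call. = FALSE)
  }
  score <- stats::setNames(first$score, first$edge_id)
  for (r in results[-1]) {
    stopifnot(identical(r$edge_id, first$edge_id))
    s <- stats::setNames(r$score, r$edge_id)
    score <- if (mode == "sum") score + s else pmax(score, s)
  }
  nz <- score > 0
  scaled <- rep(0, length(score))
  if (any(nz)) {
    rng <- range(score[nz])
    scaled[nz] <- if (diff(rng) == 0) 1 else (score[nz] - rng[1]) / diff(rng)
  }
  ord <- order(-score, names(score))
  rank <- integer(length(score))
  rank[ord] <- seq_along(score)
  out <- data.frame(edge_id = names(score), score = unname(score),
                    scaled = scaled, rank = rank, stringsAsFactors = FALSE)
  structure(out, class = c("criticality_result", "data.frame"))
}

# Jensen-Shannon divergence (natural log) between two samples, via shared
# equal-width histogram bins over the pooled finite range
.js_divergence <- function(a, b, bins = 256) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  rng <- range(c(a, b))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  p <- tabulate(findInterval(a, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), bins) / length(a)
  q <- tabulate(findInterval(b, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), bins) / length(b)
  m <- (p + q) / 2
  kl <- function(x, y) {
    i <- x > 0
    sum(x[i] * log(x[i] / y[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

# population-weighted shares of access time in hour bins + unreachable
.access_share_table <- function(res, breaks_h = 0:4) {
  w <- res$weight
  if (all(is.na(w))) w <- rep(1, nrow(res))
  tot <- sum(w)
  hrs <- res$accessibility_min / 60
  shares <- numeric(length(breaks_h) - 1)
  for (i in seq_along(shares)) {
    inbin <- !res$isolated & hrs >= breaks_h[i] & hrs < breaks_h[i + 1]
    shares[i] <- 100 * sum(w[inbin]) / tot
  }
  over <- !res$isolated & hrs >= breaks_h[length(breaks_h)]
  data.frame(
    bin = c(paste(utils::head(breaks_h, -1), utils::tail(breaks_h, -1),
                  sep = " - "),
            paste0(">= ", breaks_h[length(breaks_h)]), "unreachable"),
    share_pct = c(shares, 100 * sum(w[over]) / tot,
                  100 * sum(w[res$isolated]) / tot),
    stringsAsFactors = FALSE
  )
}

#' Compare a disrupted scenario with the baseline
#'
#' Computes the Jensen-Shannon divergence between the two accessibility
#' distributions (shared equal-width bins over the pooled finite range,
#' natural log), the fraction of origins whose top-choice facility
#' changed (origins isolated in either scenario are counted separately),
#' the facility-to-facility preference-shift graph, mean time (and, when
#' available, distance) deltas over origins finite in both, and the
#' population-share table of access times in hour bins.
#'
#' @param baseline,disrupted `access_result` objects over the same origin
#'   set.
#' @param od_baseline,od_disrupted optional `od_matrix` objects with `km`
#'   filled, enabling the mean distance delta.
#' @param bins histogram bin count for the JS divergence.
#' @return a `scenario_comparison` list.
#' @export
compare_scenarios <- function(baseline, disrupted,
                              od_baseline = NULL, od_disrupted = NULL,
                              bins = 256) {
  stopifnot(inherits(baseline, "access_result"),
            inherits(disrupted, "access_result"))
  if (!identical(baseline$origin, disrupted$origin)) {
    stop("scenarios must share one origin set", call. = FALSE)
  }
  js <- .js_divergence(baseline$accessibility_min[!baseline$isolated],
                       disrupted$accessibility_min[!disrupted$isolated],
                       bins = bins)
  both <- !baseline$isolated & !disrupted$isolated
  changed <- both & baseline$top_choice != disrupted$top_choice
  frac <- if (any(both)) sum(changed) / sum(both) else NA_real_
  shift <- data.frame(from = character(0), to = character(0),
                      count = integer(0), stringsAsFactors = FALSE)
  if (any(changed)) {
    tab <- table(from = baseline$top_choice[changed],
                 to = disrupted$top_choice[changed])
    shift <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(shift) <- c("from", "to", "count")
    shift <- shift[shift$count > 0, , drop = FALSE]
    shift <- shift[order(-shift$count, shift$from, shift$to), , drop = FALSE]
    rownames(shift) <- NULL
  }
  mean_dt <- mean(disrupted$accessibility_min[both] -
                  baseline$accessibility_min[both])
  mean_dkm <- NA_real_
  if (!is.null(od_baseline) && !is.null(od_disrupted) &&
      !is.null(od_baseline$km) && !is.null(od_disrupted$km)) {
    mk <- function(od, ch) {
      # expected trip distance per origin under the scenario's choices
      P <- ch$P
      km <- od$km
      km[!is.finite(od$minutes)] <- 0
      rowSums(km * P)
    }
    kb <- mk(od_baseline, choice_matrix(od_baseline))
    kd <- mk(od_disrupted, choice_matrix(od_disrupted))
    mean_dkm <- mean(kd[both] - kb[both])
  }
  structure(list(
    js_divergence = js,
    changed_fraction = frac,
    n_compared = sum(both),
    n_isolated_any = sum(baseline$isolated | disrupted$isolated),
    preference_shift = shift,
    mean_time_delta_min = mean_dt,
    mean_km_delta = mean_dkm,
    access_table_baseline = .access_share_table(baseline),
    access_table_disrupted = .access_share_table(disrupted)
  ), class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat(sprintf("<scenario_comparison> JS = %.3g; %.1f%% of origins changed top choice; mean delta = %.2f min\n",
              x$js_divergence, 100 * x$changed_fraction,
              x$mean_time_delta_min))
  invisible(x)
}

#' Top-k most critical segments
#'
#' The ranked table of road segments by criticality, the form used to
#' prioritize resilience investments.
#'
#' @param crit a `criticality_result`.
#' @param network optional `road_network` to attach segment names (road
#'   class and endpoints).
#' @param k number of segments.
#' @return data.frame `rank`, `edge_id`, `name`, `score`, `scaled`.
#' @export
top_critical_segments <- function(crit, network = NULL, k = 10) {
  stopifnot(inherits(crit, "criticality_result"))
  out <- crit[order(crit$rank), , drop = FALSE][seq_len(min(k, nrow(crit))), ]
  name <- out$edge_id
  if (!is.null(network)) {
    idx <- match(out$edge_id, network$edges$edge_id)
    name <- paste0(network$edges$road_class[idx], " ",
                   network$edges$u[idx], "-", network$edges$v[idx])
  }
  data.frame(rank = out$rank, edge_id = out$edge_id, name = name,
             score = out$score, scaled = out$scaled,
             stringsAsFactors = FALSE, row.names = NULL)
}
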