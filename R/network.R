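#' Road network
#'
#' Builds a weighted graph representation of a road network from an edge
#' list.  Edge weights are travel times in minutes and must be strictly
#' positive and finite.  Vertices may carry roles (\code{"origin"},
#' \code{"destination"}, \code{"station"}, \code{"junction"}); any vertex
#' not listed in \code{vertices} is treated as a junction.
#'
#' @param edges data frame with columns \code{from}, \code{to},
#'   \code{travel_time} (minutes).
#' @param vertices optional data frame with columns \code{id}, \code{role}.
#' @param directed logical; roads are undirected by default (flows are
#'   still reported per driving direction downstream).
#' @return An object of class \code{road_network}.
#' @export
road_network <- function(edges, vertices = NULL, directed = FALSE) {
  edges <- as.data.frame(edges)
  need <- c("from", "to", "travel_time")
  if (!all(need %in% names(edges)))
    stop("edges must have columns from, to, travel_time")
  w <- as.numeric(edges$travel_time)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("all travel times must be strictly positive and finite")
  el <- cbind(as.character(edges$from), as.character(edges$to))
  g <- igraph::graph_from_edgelist(el, directed = directed)
  igraph::E(g)$weight <- w

  roles <- rep("junction", igraph::vcount(g))
  names(roles) <- igraph::V(g)$name
  if (!is.null(vertices)) {
    vertices <- as.data.frame(vertices)
    if (!all(c("id", "role") %in% names(vertices)))
      stop("vertices must have columns id, role")
    vid <- as.character(vertices$id)
    unknown <- setdiff(vid, names(roles))
    if (length(unknown))
      stop("vertex ids not present in the edge list: ",
           paste(unknown, collapse = ", "))
    if (anyDuplicated(vid))
      stop("duplicated vertex ids in the role table")
    roles[vid] <- as.character(vertices$role)
  }
  structure(list(graph = g, roles = roles, directed = directed,
                 cache = new.env(parent = emptyenv())),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  tab <- table(x$roles)
  cat("Road network:", igraph::vcount(x$graph), "vertices,",
      igraph::ecount(x$graph), "edges",
      if (x$directed) "(directed)" else "(undirected)", "\n")
  cat("Roles:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Vertices of a road network holding a given role
#' @param network a \code{road_network}
#' @param role one of "origin", "destination", "station", "junction"
#' @return character vector of vertex names
#' @export
network_vertices <- function(network, role = NULL) {
  if (is.null(role)) return(names(network$roles))
  names(network$roles)[network$roles == role]
}

# All-pairs shortest travel times, cached on the network object.
.all_distances <- function(network) {
  if (is.null(network$cache$D)) {
    D <- igraph::distances(network$graph, weights = igraph::E(network$graph)$weight)
    network$cache$D <- D
  }
  network$cache$D
}

#' Shortest travel times between vertex sets
#'
#' @param network a \code{road_network}
#' @param origins,destinations character vectors of vertex names
#' @return matrix of travel times (minutes); \code{Inf} marks unreachable
#'   pairs (downstream these get mean flow 0).
#' @export
shortest_distance <- function(network, origins, destinations) {
  origins <- as.character(origins); destinations <- as.character(destinations)
  miss <- setdiff(c(origins, destinations), names(network$roles))
  if (length(miss)) stop("unknown vertices: ", paste(miss, collapse = ", "))
  D <- .all_distances(network)
  D[origins, destinations, drop = FALSE]
}

# Next-hop matrix for deterministic shortest-path reconstruction: entry
# (u, t) is the vertex index that follows u on the (lexicographically
# tie-broken) shortest path from u to t.  Computed once per network and
# cached; any shortest path is then reconstructed by pointer walking.
.next_hops <- function(network) {
  if (!is.null(network$cache$NH)) return(network$cache$NH)
  D <- .all_distances(network)
  g <- network$graph
  nms <- igraph::V(g)$name
  n <- length(nms)
  NH <- matrix(NA_integer_, n, n, dimnames = list(nms, nms))
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::E(g)$weight
  if (!network$directed) {
    el <- rbind(el, el[, 2:1])
    w <- c(w, w)
  }
  # minimal parallel-edge weight per ordered neighbour pair
  adj <- split(data.frame(to = el[, 2], w = w), el[, 1])
  for (u in seq_len(n)) {
    a <- adj[[as.character(u)]]
    if (is.null(a)) next
    a <- stats::aggregate(w ~ to, data = a, FUN = min)
    ord <- order(nms[a$to])           # lexicographic tie-break
    nb <- a$to[ord]; wt <- a$w[ord]
    slack <- wt + D[nb, , drop = FALSE] -
      matrix(D[u, ], length(nb), n, byrow = TRUE)
    tol <- 1e-9 * pmax(1, abs(D[u, ]))
    ok <- sweep(slack, 2, tol, `<=`)
    pick <- apply(ok, 2, which.max)   # first TRUE = smallest name
    found <- apply(ok, 2, any) & is.finite(D[u, ])
    NH[u, found] <- nb[pick[found]]
    NH[u, u] <- NA_integer_
  }
  network$cache$NH <- NH
  NH
}

# Deterministic shortest-path reconstruction between two vertices, breaking
# ties by lexicographic vertex name so enumerated path sets are reproducible.
.reconstruct_sp <- function(network, a, b, D = NULL) {
  if (is.null(D)) D <- .all_distances(network)
  if (!is.finite(D[a, b])) return(NULL)
  NH <- .next_hops(network)
  nms <- rownames(NH)
  ai <- match(a, nms); bi <- match(b, nms)
  path <- ai
  cur <- ai
  while (cur != bi) {
    cur <- NH[cur, bi]
    if (is.na(cur)) stop("shortest-path reconstruction failed from ", a)
    path <- c(path, cur)
  }
  nms[path]
}

.path_length <- function(network, path) {
  if (length(path) < 2) return(0)
  g <- network$graph
  ids <- igraph::get_edge_ids(g, rbind(path[-length(path)], path[-1]))
  sum(igraph::E(g)$weight[ids])
}

# Local-optimality test: every along-path subpath shorter than delta * l_P
# must itself be a shortest path in the network (relative tolerance 1e-9).
# idx are vertex indices into D, cum the cumulative along-path distances.
.locally_optimal <- function(idx, cum, D, delta) {
  n <- length(idx)
  lim <- delta * cum[n] + 1e-12
  for (a in seq_len(n - 1L)) {
    sep <- cum[(a + 1L):n] - cum[a]
    upper <- sum(sep <= lim)      # cum is nondecreasing along the path
    if (upper == 0L) next
    b <- a + seq_len(upper)
    if (any(sep[seq_len(upper)] > D[idx[a], idx[b]] * (1 + 1e-9) + 1e-12))
      return(FALSE)
  }
  TRUE
}

#' Enumerate admissible paths between an origin and a destination
#'
#' Admissible paths are single-via paths (shortest path constrained through
#' one intermediate vertex) whose length is at most \code{gamma} times the
#' shortest travel time and that contain no local detour: every subpath
#' shorter than \code{delta} times the path length must itself be a
#' shortest path.  The shortest path is always admissible.
#'
#' @param network a \code{road_network}
#' @param i,j origin and destination vertex names (\code{i != j})
#' @param gamma stretch bound, >= 1
#' @param delta local-optimality scale, in [0, 1]
#' @param .to_i,.to_j internal: memoized shortest-path trees toward i / j,
#'   shared across pairs by \code{\link{admissible_path_sets}}
#' @return An object of class \code{admissible_paths} with elements
#'   \code{origin}, \code{dest}, \code{paths} (list of vertex sequences),
#'   \code{lengths} (minutes), \code{unreachable}.
#' @export
enumerate_admissible_paths <- function(network, i, j, gamma = 1.4, delta = 0.2,
                                       .to_i = NULL, .to_j = NULL) {
  i <- as.character(i); j <- as.character(j)
  if (i == j) stop("origin and destination must differ")
  if (gamma < 1) stop("gamma must be >= 1")
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1]")
  D <- .all_distances(network)
  out <- structure(list(origin = i, dest = j, gamma = gamma, delta = delta,
                        paths = list(), lengths = numeric(0),
                        unreachable = FALSE),
                   class = "admissible_paths")
  lstar <- D[i, j]
  if (!is.finite(lstar)) {
    out$unreachable <- TRUE
    return(out)
  }
  NH <- .next_hops(network)
  nms <- rownames(D)
  ii <- match(i, nms); jj <- match(j, nms)
  if (is.null(.to_i)) .to_i <- .path_tree(NH, ii)
  if (is.null(.to_j)) .to_j <- .path_tree(NH, jj)
  tol <- 1e-9 * max(1, lstar)
  tot <- D[ii, ] + D[, jj]
  cand <- which(is.finite(tot) & tot <= gamma * lstar + tol)
  cand <- setdiff(cand, c(ii, jj))
  cand <- cand[order(tot[cand])]

  sp0 <- .to_j(ii)               # forward path i -> j
  # cumulative along-path distances come from D: both legs of a single-via
  # path are shortest paths, and prefixes of shortest paths are shortest
  paths <- list(list(idx = sp0, cum = D[ii, sp0]))
  covered <- rep(FALSE, length(tot))
  covered[sp0] <- TRUE           # vias on the shortest path reproduce it
  for (v in cand) {
    if (covered[v]) next
    p1 <- if (network$directed) .walk_nh(NH, ii, v) else rev(.to_i(v))
    p2 <- .to_j(v)
    p <- c(p1, p2[-1])
    # other in-budget vertices on this path are vias of this same path
    on_p <- p[abs(tot[p] - tot[v]) <= tol]
    covered[on_p] <- TRUE
    if (anyDuplicated(p)) next   # not a simple path
    paths[[length(paths) + 1L]] <-
      list(idx = p, cum = c(D[ii, p1], D[ii, v] + D[v, p2[-1]]))
  }
  keys <- vapply(paths, function(p) paste(p$idx, collapse = "\r"), character(1))
  paths <- paths[!duplicated(keys)]

  keep <- list(); lens <- numeric(0)
  for (p in paths) {
    lP <- p$cum[length(p$cum)]
    if (lP > gamma * lstar + tol) next
    if (!.locally_optimal(p$idx, p$cum, D, delta)) next
    keep[[length(keep) + 1L]] <- nms[p$idx]
    lens <- c(lens, lP)
  }
  ord <- order(lens, vapply(keep, paste, character(1), collapse = "\r"))
  out$paths <- lapply(keep[ord], unname)
  out$lengths <- unname(lens[ord])
  out
}

# plain pointer walk a -> b along the next-hop matrix
.walk_nh <- function(NH, a, b) {
  p <- integer(64); p[1] <- a; n <- 1L; cur <- a
  while (cur != b) {
    cur <- NH[cur, b]
    if (is.na(cur)) stop("next-hop walk failed")
    n <- n + 1L
    if (n > length(p)) p <- c(p, integer(length(p)))
    p[n] <- cur
  }
  p[seq_len(n)]
}

# memoized shortest-path tree toward a fixed target: returns a function
# mapping a vertex index to the index path u -> target; paths into the
# target share suffixes, so total work is linear in the tree size
.path_tree <- function(NH, target) {
  memo <- vector("list", nrow(NH))
  memo[[target]] <- target
  function(u) {
    if (!is.null(memo[[u]])) return(memo[[u]])
    pre <- integer(0); cur <- u
    while (is.null(memo[[cur]])) {
      pre <- c(pre, cur)
      cur <- NH[cur, target]
      if (is.na(cur)) stop("next-hop walk failed")
    }
    full <- c(pre, memo[[cur]])
    for (s in seq_along(pre)) memo[[pre[s]]] <<- full[s:length(full)]
    full
  }
}

#' @export
print.admissible_paths <- function(x, ...) {
  cat("Admissible paths", x$origin, "->", x$dest,
      sprintf("(gamma=%.3g, delta=%.3g):", x$gamma, x$delta),
      if (x$unreachable) "unreachable" else paste(length(x$paths), "paths"), "\n")
  invisible(x)
}

#' Enumerate admissible paths for every origin-destination pair
#'
#' Paths are enumerated once per pair and intended to be cached by the
#' caller; keys are \code{"origin|destination"}.
#'
#' @inheritParams enumerate_admissible_paths
#' @param origins,destinations character vectors of vertex names
#' @return A named list of \code{admissible_paths} objects, class
#'   \code{path_set_list}.
#' @export
admissible_path_sets <- function(network, origins, destinations,
                                 gamma = 1.4, delta = 0.2) {
  origins <- as.character(origins); destinations <- as.character(destinations)
  D <- .all_distances(network)
  NH <- .next_hops(network)  # warm the caches once
  nms <- rownames(D)
  to_i <- lapply(match(origins, nms), function(t) .path_tree(NH, t))
  names(to_i) <- origins
  to_j <- lapply(match(destinations, nms), function(t) .path_tree(NH, t))
  names(to_j) <- destinations
  sets <- list()
  for (i in origins) for (j in destinations) {
    if (i == j) next
    sets[[paste(i, j, sep = "|")]] <-
      enumerate_admissible_paths(network, i, j, gamma, delta,
                                 .to_i = to_i[[i]], .to_j = to_j[[j]])
  }
  structure(sets, class = "path_set_list",
            origins = origins, destinations = destinations,
            gamma = gamma, delta = delta)
}

#' Station-path incidence
#'
#' For each origin-destination pair, a logical matrix (paths x stations)
#' saying whether the station vertex lies on the path.  Stations that
#' coincide with the pair's endpoints are excluded: agents are surveyed en
#' route, not at their origin or destination.
#'
#' @param path_sets a \code{path_set_list}
#' @param stations character vector of station vertex names
#' @return named list of logical matrices, class \code{station_incidence}
#' @export
station_incidence <- function(path_sets, stations) {
  stations <- as.character(stations)
  inc <- lapply(path_sets, function(ps) {
    m <- matrix(FALSE, nrow = length(ps$paths), ncol = length(stations),
                dimnames = list(NULL, stations))
    for (q in seq_along(ps$paths)) {
      inner <- ps$paths[[q]]
      inner <- setdiff(inner, c(ps$origin, ps$dest))
      m[q, stations %in% inner] <- TRUE
    }
    m
  })
  structure(inc, class = "station_incidence", stations = stations)
}
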