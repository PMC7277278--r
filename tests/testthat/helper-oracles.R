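# Independent brute-force oracles and small fixtures, built in code.

# random connected undirected graph as an edge data frame
rand_graph <- function(n, extra_edges = n, wmax = 10) {
  # spanning tree guarantees connectivity
  from <- to <- integer(0)
  for (v in 2:n) {
    from <- c(from, sample(v - 1, 1)); to <- c(to, v)
  }
  for (e in seq_len(extra_edges)) {
    uv <- sample(n, 2)
    from <- c(from, uv[1]); to <- c(to, uv[2])
  }
  el <- cbind(pmin(from, to), pmax(from, to))
  keep <- !duplicated(el) & el[, 1] != el[, 2]
  el <- el[keep, , drop = FALSE]
  data.frame(from = paste0("n", sprintf("%02d", el[, 1])),
             to = paste0("n", sprintf("%02d", el[, 2])),
             travel_time = stats::runif(nrow(el), 0.5, wmax))
}

# all simple paths between two vertices by depth-first search
all_simple_paths_bf <- function(edges, s, t) {
  verts <- unique(c(edges$from, edges$to))
  adj <- lapply(stats::setNames(verts, verts), function(v) {
    i <- edges$from == v; j <- edges$to == v
    rbind(data.frame(to = edges$to[i], w = edges$travel_time[i]),
          data.frame(to = edges$from[j], w = edges$travel_time[j]))
  })
  out <- list()
  recurse <- function(path, len) {
    cur <- path[length(path)]
    if (cur == t) {
      out[[length(out) + 1L]] <<- list(path = path, len = len)
      return()
    }
    a <- adj[[cur]]
    for (r in seq_len(nrow(a))) {
      if (a$to[r] %in% path) next
      recurse(c(path, a$to[r]), len + a$w[r])
    }
  }
  recurse(s, 0)
  out
}

# brute-force shortest distance via exhaustive path enumeration
shortest_bf <- function(edges, s, t) {
  if (s == t) return(0)
  ap <- all_simple_paths_bf(edges, s, t)
  if (!length(ap)) return(Inf)
  min(vapply(ap, `[[`, numeric(1), "len"))
}

# brute-force shortest distances between all pairs of a vertex vector
dist_bf <- function(edges, verts) {
  D <- matrix(Inf, length(verts), length(verts),
              dimnames = list(verts, verts))
  for (a in seq_along(verts)) for (b in seq_along(verts))
    D[a, b] <- shortest_bf(edges, verts[a], verts[b])
  D
}

# brute-force admissible single-via paths: every single-via candidate,
# exhaustive stretch and local-optimality filters
admissible_bf <- function(edges, s, t, gamma, delta) {
  verts <- unique(c(edges$from, edges$to))
  D <- dist_bf(edges, verts)
  lstar <- D[s, t]
  if (!is.finite(lstar)) return(list())
  # edge weight lookup
  wkey <- c(stats::setNames(edges$travel_time, paste(edges$from, edges$to)),
            stats::setNames(edges$travel_time, paste(edges$to, edges$from)))
  sp_between <- function(a, b) {     # unique shortest path (random weights)
    ap <- all_simple_paths_bf(edges, a, b)
    lens <- vapply(ap, `[[`, numeric(1), "len")
    ap[[which.min(lens)]]$path
  }
  cands <- list(sp_between(s, t))
  for (v in setdiff(verts, c(s, t))) {
    if (!is.finite(D[s, v]) || !is.finite(D[v, t])) next
    p <- c(sp_between(s, v), sp_between(v, t)[-1])
    if (anyDuplicated(p)) next
    cands[[length(cands) + 1L]] <- p
  }
  keys <- vapply(cands, paste, character(1), collapse = ">")
  cands <- cands[!duplicated(keys)]
  keep <- list()
  for (p in cands) {
    ew <- wkey[paste(p[-length(p)], p[-1])]
    cum <- c(0, cumsum(ew))
    lP <- cum[length(cum)]
    if (lP > gamma * lstar * (1 + 1e-9)) next
    ok <- TRUE
    for (a in seq_len(length(p) - 1)) for (b in (a + 1):length(p)) {
      sep <- cum[b] - cum[a]
      if (sep <= delta * lP + 1e-12 &&
          sep > D[p[a], p[b]] * (1 + 1e-9) + 1e-12) ok <- FALSE
    }
    if (ok) keep[[length(keep) + 1L]] <- p
  }
  keep
}

path_key_set <- function(paths) {
  sort(vapply(paths, paste, character(1), collapse = ">"))
}

# the admissibility illustration topology: a direct road, a locally
# optimal alternative via u and v, and a local detour via w between u and v
fig_topology <- function() {
  data.frame(
    from = c("s", "s", "u", "v", "u", "w"),
    to = c("t", "u", "v", "t", "w", "v"),
    travel_time = c(3.5, 1, 2, 1, 1.5, 1.5))
}

# observation times from the daily pattern conditioned on shift windows:
# each observation is assigned a shift and its time is drawn from the von
# Mises day density restricted to that shift's window (batch rejection)
sample_conditional_times <- function(n, theta, kappa, shifts) {
  sid <- sample(shifts$shift, n, replace = TRUE)
  idx <- match(sid, shifts$shift)
  tt <- rep(NA_real_, n)
  pending <- seq_len(n)
  while (length(pending)) {
    cand <- gravroute:::.rvm24(length(pending), theta, kappa)
    ok <- cand >= shifts$start[idx[pending]] &
      cand < shifts$end[idx[pending]]
    tt[pending[ok]] <- cand[ok]
    pending <- pending[!ok]
  }
  data.frame(shift = sid, time = tt)
}

# tiny but fully exercised synthetic system for pipeline tests: a small
# dense subsystem with large, popular lakes so traffic is informative
tiny_config <- function(seed = 42, n_shifts = 120) {
  scenario_config(n_origins = 5, n_destinations = 15, n_junctions = 35,
                  n_stations = 5, n_shifts = n_shifts,
                  minutes_per_unit = 120, feeder_range = c(150, 500),
                  covariates = list(area_meanlog = log(800), area_sdlog = 1,
                                    lpop_meanlog = log(30), p_mar = 0.4),
                  seed = seed)
}
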