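#' Scenario configuration for the synthetic-data generator
#'
#' Defines a synthetic road network, covariates, true submodel parameters
#' and a survey design.  The defaults emulate the surveyed system the
#' reference parameters (\code{\link{bc_boater_params}}) were estimated
#' for: a sparse long-distance road network where origin-destination
#' travel times span a few hundred to a couple of thousand minutes,
#' populations and lake areas are heavy-tailed, and roadside stations sit
#' on high-betweenness vertices so most long-distance routes cross at
#' least one of them.  Each survey shift runs during daytime on its own
#' day, so count cells are independent across shifts.
#'
#' @param n_origins,n_destinations,n_junctions numbers of origin vertices
#'   (external jurisdictions), destination vertices (lakes) and pure
#'   junction vertices of the internal road network
#' @param n_stations number of survey stations
#' @param n_shifts number of survey shifts
#' @param k_nearest connectivity of the k-nearest-neighbour road graph
#' @param minutes_per_unit travel-time scale of the unit-square geometry
#' @param feeder_range range (minutes) of the long feeder roads attaching
#'   origin jurisdictions to border vertices of the internal network;
#'   together with \code{minutes_per_unit} this puts origin-destination
#'   travel times in the multi-hour long-distance band
#' @param true true parameter set (a list like
#'   \code{\link{bc_boater_params}})
#' @param shift_starts,shift_durations pools the survey design samples
#'   from (hours; durations on a grid keeps the likelihood grouping
#'   effective)
#' @param covariates distribution settings for the covariate draws
#'   (log-normal meanlog/sdlog for populations in 1e6, lake areas in km^2
#'   and near-lake populations in 1e3; Bernoulli rates for the facility
#'   indicators); partial lists are merged into the defaults.  Busier
#'   settings emulate a small, dense, high-traffic subsystem
#' @param seed random seed; a fixed seed reproduces the scenario exactly
#' @return object of class \code{scenario_config}
#' @export
scenario_config <- function(n_origins = 20, n_destinations = 100,
                            n_junctions = 180, n_stations = 12,
                            n_shifts = 500, k_nearest = 3,
                            minutes_per_unit = 300,
                            feeder_range = c(300, 1500),
                            true = bc_boater_params(),
                            shift_starts = seq(7, 12, by = 0.5),
                            shift_durations = c(4, 5, 6, 8),
                            covariates = list(),
                            seed = 1L) {
  stopifnot(n_origins >= 1, n_destinations >= 1, n_stations >= 1,
            n_shifts >= 1)
  cov_def <- list(pop_meanlog = log(2), pop_sdlog = 1, p_CA = 0.5,
                  area_meanlog = log(150), area_sdlog = 1.5,
                  lpop_meanlog = log(3), lpop_sdlog = 1.5,
                  p_camp = 0.4, p_fac = 0.5, p_mar = 0.25)
  cov_def[names(covariates)] <- covariates
  structure(list(n_origins = n_origins, n_destinations = n_destinations,
                 n_junctions = n_junctions, n_stations = n_stations,
                 n_shifts = n_shifts, k_nearest = k_nearest,
                 minutes_per_unit = minutes_per_unit,
                 feeder_range = feeder_range, true = true,
                 shift_starts = shift_starts,
                 shift_durations = shift_durations,
                 covariates = cov_def, seed = seed),
            class = "scenario_config")
}

# connected planar-ish random road graph on the unit square:
# k-nearest-neighbour edges plus the Euclidean minimum spanning tree
.random_road_graph <- function(n, k, minutes_per_unit) {
  xy <- cbind(stats::runif(n), stats::runif(n))
  D <- as.matrix(stats::dist(xy))
  el <- NULL
  for (v in seq_len(n)) {
    nb <- order(D[v, ])[2:(k + 1)]
    el <- rbind(el, cbind(v, nb))
  }
  g_full <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                                weighted = TRUE)
  mst <- igraph::mst(g_full)
  el <- rbind(el, igraph::as_edgelist(mst, names = FALSE))
  el <- t(apply(el, 1, sort))
  el <- el[!duplicated(el), , drop = FALSE]
  list(edges = data.frame(from = paste0("v", el[, 1]),
                          to = paste0("v", el[, 2]),
                          travel_time = D[el] * minutes_per_unit,
                          stringsAsFactors = FALSE),
       xy = xy)
}

#' Generate a synthetic scenario
#'
#' Draws a connected road network with positive travel times, covariates
#' on the scales the gravity parameters are defined on (populations
#' log-normal in 1e6 persons, lake areas heavy-tailed in km^2, near-lake
#' populations log-normal in 1e3 persons, facility indicators Bernoulli),
#' places stations on the highest-betweenness junctions, and precomputes
#' travel times, admissible path sets and station incidence under the
#' true route-choice parameters.
#'
#' @param config a \code{\link{scenario_config}}
#' @return object of class \code{scenario}
#' @export
generate_scenario <- function(config = scenario_config()) {
  .with_seed(config$seed, {
    n_int <- config$n_destinations + config$n_junctions
    rg <- .random_road_graph(n_int, config$k_nearest, config$minutes_per_unit)
    edges <- rg$edges
    ids <- paste0("v", seq_len(n_int))
    # origins are external jurisdictions far from the destination region,
    # each attached by one or two long feeder roads to border vertices
    # (the eastmost strip of the internal network)
    org <- paste0("o", seq_len(config$n_origins))
    border <- ids[order(rg$xy[, 1], decreasing = TRUE)][
      seq_len(max(4, config$n_origins %/% 3))]
    feeder <- do.call(rbind, lapply(seq_along(org), function(k) {
      nf <- sample(1:2, 1)
      data.frame(from = org[k], to = sample(border, nf),
                 travel_time = stats::runif(nf, config$feeder_range[1],
                                            config$feeder_range[2]))
    }))
    edges <- rbind(edges, feeder)
    dst <- sample(ids, config$n_destinations)
    rest <- setdiff(ids, dst)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    btw <- igraph::betweenness(g, weights = igraph::E(g)$travel_time)
    names(btw) <- igraph::V(g)$name
    stations <- names(sort(btw[rest], decreasing = TRUE))[seq_len(config$n_stations)]
    roles <- data.frame(id = c(org, dst, stations),
                        role = rep(c("origin", "destination", "station"),
                                   c(length(org), length(dst), length(stations))))
    net <- road_network(edges, roles)
    cv <- config$covariates
    origins <- data.frame(id = org,
                          pop = stats::rlnorm(length(org), cv$pop_meanlog,
                                              cv$pop_sdlog),
                          CA = stats::rbinom(length(org), 1, cv$p_CA))
    destinations <- data.frame(id = dst,
                               A = stats::rlnorm(length(dst), cv$area_meanlog,
                                                 cv$area_sdlog),
                               camp = stats::rbinom(length(dst), 1, cv$p_camp),
                               fac = stats::rbinom(length(dst), 1, cv$p_fac),
                               mar = stats::rbinom(length(dst), 1, cv$p_mar),
                               lpop = stats::rlnorm(length(dst),
                                                    cv$lpop_meanlog,
                                                    cv$lpop_sdlog))
    dmat <- shortest_distance(net, org, dst)
    rp <- config$true$route
    path_sets <- admissible_path_sets(net, org, dst, rp$gamma, rp$delta)
    incidence <- station_incidence(path_sets, stations)
    mu <- mean_flow_matrix(config$true$gravity, origins, destinations, dmat)
    structure(list(network = net, origins = origins,
                   destinations = destinations, stations = stations,
                   dmat = dmat, path_sets = path_sets, incidence = incidence,
                   mu = mu, true = config$true, config = config),
              class = "scenario")
  })
}

#' @export
print.scenario <- function(x, ...) {
  cat("Synthetic scenario:", nrow(x$origins), "origins,",
      nrow(x$destinations), "destinations,", length(x$stations),
      "stations\n")
  cat(sprintf("Total true flow: %.3f agents/day\n", sum(x$mu)))
  invisible(x)
}

# sample from the 24h von Mises daily pattern by rejection
.rvm24 <- function(n, theta, kappa) {
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2 * (n - length(out)), 16)
    t <- stats::runif(m, 0, 24)
    u <- stats::runif(m)
    acc <- u < exp(kappa * (cos(2 * pi * (t - theta) / 24) - 1))
    out <- c(out, t[acc])
  }
  out[seq_len(n)]
}

#' Simulate roadside surveys from a scenario
#'
#' Event-level simulation of the hierarchical observation process: per
#' day and origin-destination pair a negative binomial number of agents
#' travels; each agent samples an actual route (an admissible path by the
#' route-choice probabilities, or an inadmissible route with probability
#' \code{eta_c} that passes any given station with probability
#' \code{eta_o}); agents passing the surveyed station draw a passage time
#' from the daily pattern, and those inside the shift window stop and
#' yield complete data with the compliance probabilities.  Each shift is
#' run on its own day.
#'
#' @param scenario a \code{\link{generate_scenario}} result
#' @param n_shifts number of shifts (defaults to the scenario config)
#' @param seed random seed
#' @return list with \code{counts} (a \code{\link{count_data}}),
#'   \code{compliance} (per-shift counts data frame) and
#'   \code{survey_times} (data frame of observation times)
#' @export
simulate_surveys <- function(scenario, n_shifts = scenario$config$n_shifts,
                             seed = scenario$config$seed + 1L) {
  cfg <- scenario$config
  true <- scenario$true
  gp <- true$gravity; rp <- true$route; tp <- true$temporal; cp <- true$compliance
  .with_seed(seed, {
    shifts <- data.frame(
      shift = paste0("s", seq_len(n_shifts)),
      station = rep_len(scenario$stations, n_shifts),
      start = sample(cfg$shift_starts, n_shifts, replace = TRUE),
      day = seq_len(n_shifts))
    shifts$end <- shifts$start +
      sample(cfg$shift_durations, n_shifts, replace = TRUE)
    shifts$end <- pmin(shifts$end, 23.5)

    keys <- names(scenario$path_sets)
    muv <- .mu_vector(scenario$mu, keys)
    n_od <- length(keys)
    # per od: choice probabilities and station incidence of each path
    choice <- lapply(scenario$path_sets, function(ps)
      if (length(ps$paths)) .choice_probs(ps$lengths, rp$lambda) else numeric(0))

    counts <- vector("list", n_shifts)
    comp <- data.frame(shift = shifts$shift, stopped = 0L, bypassed = 0L,
                       highrisk_stopped = 0L, highrisk_complete = 0L)
    times <- vector("list", n_shifts)
    for (s in seq_len(n_shifts)) {
      k <- shifts$station[s]
      N <- rnbmv(n_od, muv, gp$p)
      nz <- which(N > 0)
      if (!length(nz)) { counts[[s]] <- NULL; next }
      pass <- integer(0)   # od index per passing agent
      for (u in nz) {
        inadm <- stats::rbinom(1, N[u], rp$eta_c)
        n_pass <- if (inadm > 0) stats::rbinom(1, inadm, rp$eta_o) else 0L
        adm <- N[u] - inadm
        if (adm > 0 && length(choice[[u]])) {
          routes <- sample.int(length(choice[[u]]), adm, replace = TRUE,
                               prob = choice[[u]])
          on_k <- scenario$incidence[[u]][routes, k]
          n_pass <- n_pass + sum(on_k)
        }
        if (n_pass > 0) pass <- c(pass, rep.int(u, n_pass))
      }
      if (!length(pass)) next
      t_pass <- .rvm24(length(pass), tp$theta, tp$kappa)
      inwin <- t_pass >= shifts$start[s] & t_pass < shifts$end[s]
      n_in <- sum(inwin)
      if (n_in == 0) next
      stopped <- stats::runif(n_in) < cp$xi_p
      complete <- stopped & (stats::runif(n_in) < cp$xi_c)
      comp$stopped[s] <- sum(stopped)
      comp$bypassed[s] <- n_in - sum(stopped)
      comp$highrisk_stopped[s] <- sum(stopped)
      comp$highrisk_complete[s] <- sum(complete)
      if (any(complete)) {
        od <- pass[inwin][complete]
        tt <- t_pass[inwin][complete]
        tab <- table(od)
        parts <- strsplit(keys[as.integer(names(tab))], "|", fixed = TRUE)
        counts[[s]] <- data.frame(
          shift = shifts$shift[s],
          origin = vapply(parts, `[`, character(1), 1),
          destination = vapply(parts, `[`, character(1), 2),
          count = as.integer(tab))
        times[[s]] <- data.frame(shift = shifts$shift[s], time = tt)
      }
    }
    cdf <- do.call(rbind, counts)
    if (is.null(cdf))
      cdf <- data.frame(shift = character(0), origin = character(0),
                        destination = character(0), count = integer(0))
    tdf <- do.call(rbind, times)
    if (is.null(tdf))
      tdf <- data.frame(shift = character(0), time = numeric(0))
    tdf$obs <- if (nrow(tdf)) paste0("o", seq_len(nrow(tdf))) else character(0)
    list(counts = count_data(shifts, cdf, scenario$origins$id,
                             scenario$destinations$id),
         compliance = comp,
         survey_times = tdf[, c("obs", "shift", "time")])
  })
}
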