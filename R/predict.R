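#' Predict origin outflows, destination inflows and road-edge flows
#'
#' Destination inflow means are sums of the gravity means over origins;
#' their 95th percentiles use the negative binomial law with the common
#' mean-to-variance ratio (the shared-p family is closed under summation
#' over origins).  Edge flows allocate the admissible share
#' \code{(1 - eta_c)} of each pair's mean over its admissible paths by the
#' route-choice probabilities; traffic on inadmissible routes is
#' location-free in the model and is reported only as an unallocated
#' total.
#'
#' @param gravity a \code{gravity_params} (or \code{gravity_fit})
#' @param route a \code{route_choice_params} (or \code{route_choice_fit})
#' @param origins,destinations covariate data frames with \code{id}
#'   columns
#' @param dmat travel-time matrix (minutes)
#' @param path_sets admissible path sets for all pairs
#' @return object of class \code{flow_summary} with \code{origin_outflow},
#'   \code{dest_inflow} (mean and \code{q95}), \code{edge_flows} (directed,
#'   agents/day) and \code{unallocated}
#' @export
predict_flows <- function(gravity, route, origins, destinations, dmat,
                          path_sets) {
  gpar <- if (inherits(gravity, "gravity_fit")) gravity$params else gravity
  rpar <- if (inherits(route, "route_choice_fit")) route$params else route
  origins <- as.data.frame(origins); destinations <- as.data.frame(destinations)
  rownames(dmat) <- as.character(origins$id)
  colnames(dmat) <- as.character(destinations$id)
  mu <- mean_flow_matrix(gpar, origins, destinations, dmat)

  outflow <- data.frame(origin = rownames(mu), outflow = rowSums(mu))
  inflow_mean <- colSums(mu)
  inflow <- data.frame(destination = colnames(mu), mean = inflow_mean,
                       q95 = qnbmv(0.95, inflow_mean, gpar$p))

  acc <- new.env(parent = emptyenv())
  add_edge <- function(u, v, f) {
    k <- paste(u, v, sep = "\r")
    acc[[k]] <- (if (is.null(acc[[k]])) 0 else acc[[k]]) + f
  }
  for (u in names(path_sets)) {
    ps <- path_sets[[u]]
    if (ps$unreachable || !length(ps$paths)) next
    m <- mu[ps$origin, ps$dest]
    if (m == 0) next
    pr <- .choice_probs(ps$lengths, rpar$lambda)
    fl <- m * (1 - rpar$eta_c) * pr
    for (q in seq_along(ps$paths)) {
      p <- ps$paths[[q]]
      if (fl[q] == 0) next
      for (e in seq_len(length(p) - 1)) add_edge(p[e], p[e + 1], fl[q])
    }
  }
  keys <- ls(acc)
  ef <- if (length(keys)) {
    parts <- strsplit(keys, "\r", fixed = TRUE)
    data.frame(from = vapply(parts, `[`, character(1), 1),
               to = vapply(parts, `[`, character(1), 2),
               flow = vapply(keys, function(k) acc[[k]], numeric(1)),
               row.names = NULL)
  } else data.frame(from = character(0), to = character(0), flow = numeric(0))
  ef <- ef[order(-ef$flow, ef$from, ef$to), ]
  rownames(ef) <- NULL
  structure(list(origin_outflow = outflow, dest_inflow = inflow,
                 edge_flows = ef,
                 unallocated = rpar$eta_c * sum(mu), total = sum(mu)),
            class = "flow_summary")
}

#' @export
print.flow_summary <- function(x, ...) {
  cat(sprintf("Predicted flows: total %.4g agents/day over %d origins, %d destinations\n",
              x$total, nrow(x$origin_outflow), nrow(x$dest_inflow)))
  cat(sprintf("Unallocated (inadmissible-route) share: %.4g agents/day\n",
              x$unallocated))
  invisible(x)
}

#' Cumulative share curve of flows
#'
#' Sorts destinations (or origins) by predicted flow and reports the
#' cumulative fraction of the total, e.g. to read off how many sites
#' receive half of the total pressure.
#'
#' @param flows a \code{\link{predict_flows}} result
#' @param which \code{"destination"} or \code{"origin"}
#' @return data frame with \code{id}, \code{flow}, \code{share},
#'   \code{cum_share}, sorted descending
#' @export
share_table <- function(flows, which = c("destination", "origin")) {
  which <- match.arg(which)
  df <- if (which == "destination")
    data.frame(id = flows$dest_inflow$destination,
               flow = flows$dest_inflow$mean)
  else data.frame(id = flows$origin_outflow$origin,
                  flow = flows$origin_outflow$outflow)
  df <- df[order(-df$flow, df$id), ]
  tot <- sum(df$flow)
  df$share <- if (tot > 0) df$flow / tot else 0
  df$cum_share <- cumsum(df$share)
  rownames(df) <- NULL
  df
}

#' Variance-corrected R-squared of station mean counts
#'
#' Compares observed and predicted mean counts per station over midday
#' shifts (fully inside the reference window, 11.00-16.00 by default, so
#' that per-station counts are comparably distributed), after dividing
#' both by the model-predicted standard deviation of the station mean.
#' The per-shift predicted variance sums the thinned negative binomial
#' cell variances over all origin-destination pairs.
#'
#' @param data a \code{\link{count_data}}
#' @param mu mean-flow matrix (origins x destinations)
#' @param p mean-to-variance ratio of daily counts
#' @param rho passage-probability matrix (od pairs x stations)
#' @param temporal \code{temporal_params} (or fit)
#' @param xi compliance rate
#' @param window reference time window (hours)
#' @return scalar R-squared with attribute \code{stations} (the per-station
#'   normalized observed and predicted means)
#' @export
variance_corrected_r2 <- function(data, mu, p, rho, temporal, xi,
                                  window = c(11, 16)) {
  tpar <- if (inherits(temporal, "temporal_fit")) temporal$params else temporal
  shifts <- data$shifts
  keep <- shifts$start >= window[1] & shifts$end <= window[2] &
    shifts$end > shifts$start
  shifts <- shifts[keep, , drop = FALSE]
  if (length(unique(shifts$station)) < 2)
    stop("need counts at >= 2 stations inside the reference window")
  tau <- .vm_tau(tpar$theta, tpar$kappa, shifts$start, shifts$end)
  muv <- .mu_vector(mu, rownames(rho))
  cnts <- data$counts[data$counts$shift %in% shifts$shift, , drop = FALSE]
  obs_shift <- tapply(cnts$count, factor(cnts$shift, levels = shifts$shift),
                      sum, default = 0)

  per_station <- lapply(split(seq_len(nrow(shifts)), shifts$station),
    function(ix) {
      m_shift <- numeric(length(ix)); v_shift <- numeric(length(ix))
      for (a in seq_along(ix)) {
        s <- ix[a]
        tvec <- rho[, as.character(shifts$station[s])] * tau[s] * xi
        m_shift[a] <- sum(muv * tvec)
        v_shift[a] <- sum(.varnbthin(muv, p, tvec))
      }
      m <- length(ix)
      sd_mean <- sqrt(sum(v_shift)) / m
      c(obs = mean(obs_shift[ix]) / sd_mean,
        pred = mean(m_shift) / sd_mean)
    })
  tab <- do.call(rbind, per_station)
  sse <- sum((tab[, "obs"] - tab[, "pred"])^2)
  sst <- sum((tab[, "obs"] - mean(tab[, "obs"]))^2)
  structure(1 - sse / sst, stations = tab)
}

#' Nagelkerke's pseudo R-squared
#'
#' \deqn{R^2 = \frac{1 - (L_0/L_1)^{2/n}}{1 - L_0^{2/n}}}
#' computed from composite log-likelihoods of the fitted and the null
#' model over the same \code{n} likelihood cells.  Equals 0 when the
#' model does not improve on the null; a warning is issued (and a
#' negative value returned) if the fitted model is worse than the null.
#'
#' @param logL1 composite log-likelihood of the fitted model
#' @param logL0 composite log-likelihood of the null model
#' @param n number of likelihood cells (shift x od pairs)
#' @return pseudo R-squared
#' @export
nagelkerke_pseudo_r2 <- function(logL1, logL0, n) {
  if (logL1 < logL0)
    warning("fitted model has lower likelihood than the null model")
  (1 - exp(2 * (logL0 - logL1) / n)) / (1 - exp(2 * logL0 / n))
}
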