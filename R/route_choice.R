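#' Route choice parameters
#'
#' Agents choose among the admissible paths with probability inversely
#' proportional to a power \code{lambda} of travel time.  A small fraction
#' \code{eta_c} of agents drives inadmissible routes instead; such an agent
#' passes any given survey location with probability \code{eta_o}.  The
#' probabilities \code{eta_c} and \code{eta_o} are not jointly estimable
#' from station data, so \code{eta_c} is bounded above by 0.05.
#'
#' @param lambda travel-time exponent, >= 0
#' @param eta_c probability of choosing an inadmissible route, in [0, 0.05]
#' @param eta_o probability that a given survey location lies on an
#'   inadmissible route, in [0, 1]
#' @param gamma,delta admissibility parameters the path sets were built
#'   with (kept for bookkeeping)
#' @return object of class \code{route_choice_params}
#' @export
route_choice_params <- function(lambda, eta_c = 0, eta_o = 0,
                                gamma = 1.4, delta = 0.2) {
  if (lambda < 0) stop("lambda must be >= 0")
  if (eta_c < 0 || eta_c > 0.05)
    stop("eta_c must lie in [0, 0.05]")
  if (eta_o < 0 || eta_o > 1) stop("eta_o must be in [0, 1]")
  structure(list(lambda = lambda, eta_c = eta_c, eta_o = eta_o,
                 gamma = gamma, delta = delta),
            class = "route_choice_params")
}

#' @export
print.route_choice_params <- function(x, ...) {
  cat(sprintf(
    "Route choice: lambda=%.3f, eta_c=%.4f, eta_o=%.4f (gamma=%.2f, delta=%.2f)\n",
    x$lambda, x$eta_c, x$eta_o, x$gamma, x$delta))
  invisible(x)
}

# choice weights from path lengths, overflow-safe via scaling by the
# shortest length
.choice_probs <- function(lengths, lambda) {
  w <- (lengths / min(lengths))^(-lambda)
  w / sum(w)
}

#' Route choice probabilities over an admissible path set
#'
#' @param paths an \code{\link{admissible_paths}} object (or a numeric
#'   vector of path lengths)
#' @param lambda travel-time exponent
#' @return probability per path; sums to 1, weakly larger for shorter paths
#' @export
choice_probabilities <- function(paths, lambda) {
  lengths <- if (inherits(paths, "admissible_paths")) paths$lengths else paths
  if (length(lengths) == 0)
    stop("empty admissible path set (unreachable origin-destination pair)")
  if (any(lengths <= 0)) stop("path lengths must be > 0")
  .choice_probs(lengths, lambda)
}

#' Probability of passing a survey location
#'
#' \eqn{\rho_{ijk} = (1-\eta_c)\sum_{P \ni k} P(P) + \eta_c \eta_o}: the
#' admissible-route mass through station k plus the location-free
#' inadmissible-route noise.
#'
#' @param paths an \code{\link{admissible_paths}} object
#' @param on_path logical vector: does station k lie on each path (see
#'   \code{\link{station_incidence}})
#' @param params a \code{route_choice_params}
#' @return probability rho in [eta_c*eta_o, (1-eta_c) + eta_c*eta_o]
#' @export
station_probability <- function(paths, on_path, params) {
  pr <- choice_probabilities(paths, params$lambda)
  (1 - params$eta_c) * sum(pr[on_path]) + params$eta_c * params$eta_o
}

# rho matrix for all OD pairs x stations (rows keyed like the path list)
.rho_matrix <- function(path_sets, incidence, params) {
  stations <- attr(incidence, "stations")
  out <- matrix(params$eta_c * params$eta_o,
                nrow = length(path_sets), ncol = length(stations),
                dimnames = list(names(path_sets), stations))
  for (u in seq_along(path_sets)) {
    ps <- path_sets[[u]]
    if (ps$unreachable || length(ps$paths) == 0) { out[u, ] <- 0; next }
    pr <- .choice_probs(ps$lengths, params$lambda)
    out[u, ] <- (1 - params$eta_c) * as.numeric(crossprod(incidence[[u]], pr)) +
      params$eta_c * params$eta_o
  }
  out
}

#' Fit the route choice model by conditional maximum likelihood
#'
#' The likelihood conditions on which stations were monitored for how
#' long: given that an agent travelling from i to j was surveyed
#' somewhere, the probability that it was surveyed at station k is
#' \eqn{\rho_{ijk} w_k / \sum_{k'} \rho_{ijk'} w_{k'}}, where \code{w_k}
#' is station k's monitoring effort (by default the sum of its shift
#' window probabilities under the fitted temporal model).  \code{eta_c}
#' is estimated on [0, 0.05].
#'
#' @param obs data frame of surveyed agents aggregated per (origin,
#'   destination, station): columns \code{origin}, \code{destination},
#'   \code{station}, \code{count}
#' @param path_sets a \code{\link{admissible_path_sets}} result
#' @param incidence a \code{\link{station_incidence}} result
#' @param effort named vector of monitoring effort per station; stations
#'   with zero effort are treated as unmonitored
#' @param gamma,delta admissibility parameters recorded in the result
#' @param level confidence level for profile intervals
#' @param ci logical: compute profile confidence intervals?
#' @param n_starts number of optimizer starts
#' @return object of class \code{route_choice_fit} with \code{params},
#'   \code{logLik}, \code{ci}, \code{identifiable}
#' @export
fit_route_choice <- function(obs, path_sets, incidence, effort,
                             gamma = attr(path_sets, "gamma"),
                             delta = attr(path_sets, "delta"),
                             level = 0.95, ci = TRUE, n_starts = 3) {
  obs <- as.data.frame(obs)
  stations <- attr(incidence, "stations")
  mon <- names(effort)[effort > 0]
  mon <- intersect(stations, mon)
  if (length(mon) < 2)
    stop("need at least two monitored stations to identify the route model")
  w <- effort[mon]
  key <- paste(obs$origin, obs$destination, sep = "|")
  miss <- setdiff(unique(key), names(path_sets))
  if (length(miss))
    stop("no admissible path set for pairs: ", paste(miss, collapse = ", "))
  ods <- unique(key)
  # per unique OD: path lengths and incidence restricted to monitored stations
  str <- lapply(ods, function(u) {
    ps <- path_sets[[u]]
    list(len = ps$lengths, inc = incidence[[u]][, mon, drop = FALSE])
  })
  names(str) <- ods
  cnt <- matrix(0, nrow = length(ods), ncol = length(mon),
                dimnames = list(ods, mon))
  ok <- obs$station %in% mon
  if (!all(ok)) stop("observations at unmonitored stations: ",
                     paste(unique(obs$station[!ok]), collapse = ", "))
  for (r in seq_len(nrow(obs)))
    cnt[key[r], as.character(obs$station[r])] <-
      cnt[key[r], as.character(obs$station[r])] + obs$count[r]

  multi <- vapply(str, function(s) length(s$len) > 1, logical(1))
  identifiable <- any(multi[rowSums(cnt) > 0])

  nll <- function(par) {
    lambda <- par[1]; eta_c <- par[2]; eta_o <- par[3]
    if (!all(is.finite(par)) || lambda < 0 || lambda > 100 ||
        eta_c < 0 || eta_c > 0.05 || eta_o < 0 || eta_o > 1)
      return(1e12)
    ll <- 0
    for (u in seq_along(str)) {
      nu <- cnt[u, ]
      tot <- sum(nu)
      if (tot == 0) next
      s <- str[[u]]
      pr <- .choice_probs(s$len, lambda)
      rho <- (1 - eta_c) * as.numeric(crossprod(s$inc, pr)) + eta_c * eta_o
      rw <- rho * w
      den <- sum(rw)
      if (den <= 0) return(1e12)
      pos <- nu > 0
      if (any(rw[pos] <= 0)) return(1e12)
      ll <- ll + sum(nu[pos] * log(rw[pos])) - tot * log(den)
    }
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  lower <- c(0, 0, 1e-8); upper <- c(100, 0.05, 1)
  starts <- list(c(5, 0.02, 0.1))
  if (n_starts > 1) {
    extra <- lapply(seq_len(n_starts - 1), function(s)
      c(stats::runif(1, 0.5, 20), stats::runif(1, 0, 0.05),
        stats::runif(1, 0.01, 0.9)))
    starts <- c(starts, extra)
  }
  best <- NULL
  for (s0 in starts) {
    o <- stats::optim(s0, nll, method = "L-BFGS-B", lower = lower,
                      upper = upper, control = list(maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  est <- best$par
  cimat <- NULL
  if (ci) {
    cimat <- rbind(
      lambda = if (identifiable)
        .profile_ci(nll, est, 1, level = level, lower = 0, upper = 100)
      else c(NA_real_, NA_real_),
      eta_c = .profile_ci(nll, est, 2, level = level, lower = 0, upper = 0.05),
      eta_o = .profile_ci(nll, est, 3, level = level, lower = 0, upper = 1))
    colnames(cimat) <- c("lower", "upper")
  }
  if (!identifiable)
    warning("every surveyed pair has a single admissible route: ",
            "lambda is unidentifiable")
  structure(list(params = route_choice_params(est[1], est[2], est[3],
                                              gamma = gamma, delta = delta),
                 logLik = -best$value, ci = cimat,
                 identifiable = identifiable, effort = w,
                 convergence = best$convergence, nll = nll, estimate = est),
            class = "route_choice_fit")
}

#' @export
print.route_choice_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("Conditional log-likelihood: %.3f\n", x$logLik))
  if (!x$identifiable) cat("NOTE: lambda unidentifiable (single routes)\n")
  if (!is.null(x$ci)) print(signif(x$ci, 4))
  invisible(x)
}
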