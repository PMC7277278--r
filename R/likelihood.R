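#' Survey count dataset
#'
#' Sparse container for roadside survey counts.  Every survey shift is
#' listed in \code{shifts}; only nonzero counts are stored in
#' \code{counts}, all other (shift, origin-destination) cells are implicit
#' zeros.
#'
#' @param shifts data frame with columns \code{shift}, \code{station},
#'   \code{start}, \code{end} (times of day, hours) and optionally
#'   \code{day}
#' @param counts data frame with columns \code{shift}, \code{origin},
#'   \code{destination}, \code{count}
#' @param origins,destinations character vectors naming the full
#'   origin/destination universe (implicit zeros range over these)
#' @return object of class \code{count_data}
#' @export
count_data <- function(shifts, counts, origins, destinations) {
  shifts <- as.data.frame(shifts); counts <- as.data.frame(counts)
  origins <- as.character(origins); destinations <- as.character(destinations)
  if (anyDuplicated(shifts$shift)) stop("duplicated shift ids")
  if (nrow(counts)) {
    if (any(counts$count < 0) ||
        any(abs(counts$count - round(counts$count)) > 1e-9))
      stop("counts must be nonnegative integers")
    bad <- !counts$shift %in% shifts$shift
    if (any(bad)) stop("count records reference unknown shifts: ",
                       paste(unique(counts$shift[bad]), collapse = ", "))
    bad <- !(counts$origin %in% origins) | !(counts$destination %in% destinations)
    if (any(bad)) stop("count records reference unknown origins/destinations")
  }
  structure(list(shifts = shifts, counts = counts,
                 origins = origins, destinations = destinations),
            class = "count_data")
}

#' @export
print.count_data <- function(x, ...) {
  cat("Survey count data:", nrow(x$shifts), "shifts,",
      nrow(x$counts), "nonzero count records,",
      length(x$origins), "origins x", length(x$destinations),
      "destinations\n")
  invisible(x)
}

.od_keys <- function(origins, destinations) {
  as.vector(outer(origins, destinations, paste, sep = "|"))
}

# flatten a mu matrix (origins x destinations) into a vector aligned with
# the od keys of a rho matrix
.mu_vector <- function(mu, keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  i <- vapply(parts, `[`, character(1), 1L)
  j <- vapply(parts, `[`, character(1), 2L)
  mu[cbind(match(i, rownames(mu)), match(j, colnames(mu)))]
}

#' Count law for one survey shift and origin-destination pair
#'
#' The daily count NB(mu, p) is thinned by the route-choice probability
#' \code{rho}, the window probability \code{tau} and the compliance rate
#' \code{xi}.  Binomial thinning preserves the negative binomial shape
#' parameter, so the surveyed count is negative binomial with mean
#' \code{mu * rho * tau * xi}, size \code{mu p / (1-p)} and success
#' parameter \code{p / (p + t(1-p))} where \code{t = rho * tau * xi}.
#'
#' @param mu mean daily flow of the pair
#' @param p mean-to-variance ratio of the daily counts
#' @param rho station passage probability
#' @param tau shift window probability
#' @param xi compliance rate
#' @return a count-law list as in \code{\link{nb_count_law}}
#' @export
shift_count_law <- function(mu, p, rho, tau, xi) {
  .check_p(p)
  t <- rho * tau * xi
  if (t < 0 || t > 1) stop("thinning probability outside [0, 1]")
  m <- mu * t
  if (m == 0 || p >= 1) {
    if (m == 0)
      return(list(d = function(x, log = FALSE)
        if (log) ifelse(x == 0, 0, -Inf) else as.numeric(x == 0),
        p = function(q) as.numeric(q >= 0),
        q = function(prob) rep(0, length(prob)),
        r = function(n) integer(n), mean = 0, var = 0))
    return(list(d = function(x, log = FALSE) stats::dpois(x, m, log = log),
                p = function(q) stats::ppois(q, m),
                q = function(prob) stats::qpois(prob, m),
                r = function(n) stats::rpois(n, m), mean = m, var = m))
  }
  size <- mu * p / (1 - p)
  prob <- p / (p + t * (1 - p))
  list(d = function(x, log = FALSE)
         stats::dnbinom(x, size = size, prob = prob, log = log),
       p = function(q) stats::pnbinom(q, size = size, prob = prob),
       q = function(pr) stats::qnbinom(pr, size = size, prob = prob),
       r = function(n) stats::rnbinom(n, size = size, prob = prob),
       mean = m, var = m / prob)
}

#' Composite log-likelihood of a survey count dataset
#'
#' Sums the log-probability of the observed count over every (shift,
#' origin-destination) cell, treating cells as independent.  Implicit
#' zeros are included: zero-count blocks are evaluated in closed form and
#' cells sharing the same (mean, shape) are grouped, which makes the
#' computation linear in the number of distinct (station, window) groups
#' rather than in the number of shifts.
#'
#' @param data a \code{\link{count_data}}
#' @param mu matrix of mean daily flows (origins x destinations)
#' @param p mean-to-variance ratio of daily counts
#' @param rho matrix of station passage probabilities with rows keyed
#'   \code{"origin|destination"} and columns keyed by station
#' @param tau numeric vector of window probabilities, one per shift (in
#'   the order of \code{data$shifts})
#' @param xi compliance rate
#' @return scalar log-likelihood with attribute \code{n_cells}
#' @export
composite_log_likelihood <- function(data, mu, p, rho, tau, xi) {
  .check_p(p)
  shifts <- data$shifts
  n_od <- nrow(rho)
  n_cells <- nrow(shifts) * n_od
  if (nrow(shifts) == 0)
    return(structure(0, n_cells = 0))
  if (length(tau) != nrow(shifts))
    stop("tau must have one entry per shift")
  muv <- .mu_vector(mu, rownames(rho))
  if (any(!is.finite(muv)) || any(muv < 0)) stop("invalid mean flows")

  # group shifts by (station, quantized tau): cells within a group share
  # the whole (mean, shape) vector over od pairs
  gkey <- paste(shifts$station, signif(tau, 12))
  grp <- split(seq_len(nrow(shifts)), gkey)

  ll <- 0
  one_minus_p <- 1 - p
  r <- if (p < 1) muv * p / one_minus_p else NULL
  for (g in grp) {
    k <- as.character(shifts$station[g[1]])
    tg <- tau[g[1]]
    tvec <- rho[, k] * tg * xi
    if (p < 1) {
      logq <- log(p) - log(p + tvec * one_minus_p)
      ll <- ll + length(g) * sum(r * logq)
    } else {
      ll <- ll - length(g) * sum(muv * tvec)
    }
  }
  # replace the zero-cell contribution of observed nonzero records
  cnts <- data$counts
  if (nrow(cnts)) {
    if (any(abs(cnts$count - round(cnts$count)) > 1e-9))
      stop("counts must be integers")
    si <- match(cnts$shift, shifts$shift)
    keys <- paste(cnts$origin, cnts$destination, sep = "|")
    oi <- match(keys, rownames(rho))
    if (anyNA(oi)) stop("count records outside the od universe of rho")
    k <- as.character(shifts$station[si])
    tcell <- rho[cbind(oi, match(k, colnames(rho)))] * tau[si] * xi
    mucell <- muv[oi]
    lp0 <- if (p < 1) mucell * p / one_minus_p *
      (log(p) - log(p + tcell * one_minus_p)) else -mucell * tcell
    lp <- .dnbthin(cnts$count, mucell, p, tcell, log = TRUE)
    nonzero <- cnts$count > 0
    ll <- ll - sum(lp0[nonzero]) + sum(lp[nonzero])
  }
  structure(as.numeric(ll), n_cells = n_cells)
}

# --- profile likelihood machinery ------------------------------------------

# Profile-likelihood confidence interval by stepping out and bisection.
# nll: function of the full parameter vector; par: the optimum; idx: which
# component.  Sides that stay inside the chi-square threshold all the way
# to a finite box bound are reported at the bound; infinite bounds give an
# open (infinite) endpoint.
.profile_ci <- function(nll, par, idx, level = 0.95,
                        lower = -Inf, upper = Inf, max_steps = 40L) {
  f0 <- nll(par)
  thr <- f0 + stats::qchisq(level, 1) / 2
  rest_start <- par[-idx]
  pf <- function(v) {
    if (length(par) == 1L) return(nll(v))
    full <- function(th) { x <- par; x[idx] <- v; x[-idx] <- th; nll(x) }
    o <- if (length(rest_start) == 1L)
      stats::optim(rest_start, full, method = "BFGS",
                   control = list(maxit = 200))
    else stats::optim(rest_start, full, method = "Nelder-Mead",
                      control = list(maxit = 500))
    rest_start <<- o$par
    o$value
  }
  side <- function(dir, bound) {
    rest_start <<- par[-idx]
    step <- max(abs(par[idx]) * 0.1, 0.1)
    prev <- par[idx]
    for (s in seq_len(max_steps)) {
      v <- par[idx] + dir * step
      hit_bound <- (dir < 0 && v <= bound) || (dir > 0 && v >= bound)
      if (hit_bound) v <- bound
      fv <- pf(v)
      if (is.finite(fv) && fv > thr) {
        root <- stats::uniroot(function(z) pf(z) - thr,
                               lower = min(prev, v), upper = max(prev, v),
                               tol = max(abs(par[idx]), 1) * 1e-3)
        return(root$root)
      }
      if (hit_bound) return(bound)
      prev <- v
      step <- step * 2
    }
    dir * Inf
  }
  c(side(-1, lower), side(+1, upper))
}

#' Profile-likelihood confidence interval
#'
#' Endpoints are the parameter values where the profile log-likelihood
#' drops by \code{qchisq(level, 1) / 2} (1.92 at the 95\% level) below its
#' maximum, found by stepping out and bisection while re-optimizing the
#' remaining parameters.  A side whose profile never crosses the threshold
#' before a finite box bound is reported at that bound; an infinite bound
#' gives an open (\code{Inf}) endpoint.
#'
#' @param object a fitted model (\code{temporal_fit},
#'   \code{route_choice_fit} or \code{gravity_fit}) or a list with fields
#'   \code{nll} (function of the parameter vector), \code{estimate},
#'   \code{lower}, \code{upper}
#' @param parameter index or name of the parameter to profile
#' @param level confidence level
#' @param ... unused
#' @return numeric vector \code{c(lower, upper)}
#' @export
profile_confidence_interval <- function(object, parameter, level = 0.95, ...) {
  UseMethod("profile_confidence_interval")
}

#' @export
profile_confidence_interval.default <- function(object, parameter,
                                                level = 0.95, ...) {
  idx <- if (is.character(parameter))
    match(parameter, names(object$estimate)) else parameter
  lo <- if (!is.null(object$lower)) rep_len(object$lower,
                                            length(object$estimate))[idx] else -Inf
  hi <- if (!is.null(object$upper)) rep_len(object$upper,
                                            length(object$estimate))[idx] else Inf
  .profile_ci(object$nll, object$estimate, idx, level = level,
              lower = lo, upper = hi)
}

#' @export
profile_confidence_interval.temporal_fit <- function(object, parameter,
                                                     level = 0.95, ...) {
  idx <- if (is.character(parameter))
    match(parameter, c("theta", "kappa")) else parameter
  bounds <- rbind(c(object$estimate[1] - 12, object$estimate[1] + 12),
                  c(0, 50))
  ci <- .profile_ci(object$nll, object$estimate, idx, level = level,
                    lower = bounds[idx, 1], upper = bounds[idx, 2])
  if (idx == 1) ci <- ci %% 24
  ci
}

#' @export
profile_confidence_interval.route_choice_fit <- function(object, parameter,
                                                         level = 0.95, ...) {
  idx <- if (is.character(parameter))
    match(parameter, c("lambda", "eta_c", "eta_o")) else parameter
  bounds <- rbind(c(0, 100), c(0, 0.05), c(0, 1))
  .profile_ci(object$nll, object$estimate, idx, level = level,
              lower = bounds[idx, 1], upper = bounds[idx, 2])
}

#' @export
profile_confidence_interval.gravity_fit <- function(object, parameter,
                                                    level = 0.95, ...) {
  idx <- if (is.character(parameter))
    match(parameter, object$free) else parameter
  if (is.na(idx)) stop("parameter was not free in this fit")
  ci_t <- .profile_ci(object$nll, object$estimate, idx, level = level)
  sort(object$back_transform[[object$free[idx]]](ci_t))
}

# --- gravity fit ------------------------------------------------------------

.grav_free_names <- c("c", "p", "alpha_d", "pop0", "beta_CA", "A0",
                      "beta_camp", "beta_fac", "beta_mar", "beta_lpop",
                      "lpop0")

.grav_transforms <- function(free) {
  to <- list(); from <- list()
  for (nm in free) {
    if (nm == "p") {
      to[[nm]] <- function(x) stats::qlogis(pmin(x, 1 - 1e-9))
      from[[nm]] <- function(y) stats::plogis(y)
    } else {
      to[[nm]] <- log
      from[[nm]] <- exp
    }
  }
  list(to = to, from = from)
}

# evaluate expr with a temporary RNG seed, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Fit the gravity model by composite maximum likelihood
#'
#' The last stage of the fitting pipeline: with compliance, temporal and
#' route-choice submodels already fitted (upstream arguments are
#' mandatory), maximizes the composite log-likelihood of the count data
#' over the free gravity parameters with multi-start local optimization on
#' log/logit-transformed scales.
#'
#' @param data a \code{\link{count_data}}
#' @param dmat travel-time matrix (minutes, origins x destinations)
#' @param origins,destinations covariate data frames with an \code{id}
#'   column matching \code{data$origins} / \code{data$destinations}
#' @param route a \code{route_choice_fit} or \code{route_choice_params}
#' @param temporal a \code{temporal_fit} or \code{temporal_params}
#' @param compliance a \code{compliance_fit} or \code{compliance_params}
#' @param start a \code{\link{gravity_params}} giving fixed values and
#'   starting values for the free parameters
#' @param free character vector of parameter names to estimate (subset of
#'   c, p, alpha_d, pop0, beta_CA, A0, beta_camp, beta_fac, beta_mar,
#'   beta_lpop, lpop0)
#' @param path_sets,incidence admissible path sets and station incidence
#'   (used to build the passage-probability matrix; alternatively pass
#'   \code{rho} directly)
#' @param rho optional precomputed passage-probability matrix
#' @param n_starts number of optimizer restarts (jittered starts)
#' @param seed seed for the start jitter (the caller's RNG stream is
#'   restored afterwards)
#' @param ci logical: compute profile confidence intervals for the free
#'   parameters?
#' @param level confidence level
#' @return object of class \code{gravity_fit}
#' @export
fit_gravity <- function(data, dmat, origins, destinations,
                        route, temporal, compliance,
                        start, free = c("c", "p", "alpha_d"),
                        path_sets = NULL, incidence = NULL, rho = NULL,
                        n_starts = 10, seed = 0, ci = TRUE, level = 0.95) {
  if (missing(route) || missing(temporal) || missing(compliance) ||
      is.null(route) || is.null(temporal) || is.null(compliance))
    stop("staged fit: compliance, temporal and route-choice submodels ",
         "must be fitted before the gravity model")
  rpar <- if (inherits(route, "route_choice_fit")) route$params else route
  tpar <- if (inherits(temporal, "temporal_fit")) temporal$params else temporal
  cpar <- if (inherits(compliance, "compliance_fit")) compliance$params else compliance
  if (!inherits(start, "gravity_params")) stop("start must be gravity_params")
  bad <- setdiff(free, .grav_free_names)
  if (length(bad)) stop("unknown free parameters: ", paste(bad, collapse = ", "))

  if (is.null(rho)) {
    if (is.null(path_sets) || is.null(incidence))
      stop("supply either rho or path_sets + incidence")
    rho <- .rho_matrix(path_sets, incidence, rpar)
  }
  tau <- .vm_tau(tpar$theta, tpar$kappa, data$shifts$start, data$shifts$end)
  xi <- cpar$xi

  origins <- as.data.frame(origins); destinations <- as.data.frame(destinations)
  rownames(dmat) <- origins$id <- as.character(origins$id)
  colnames(dmat) <- destinations$id <- as.character(destinations$id)

  tr <- .grav_transforms(free)
  base <- unclass(start)
  par0 <- vapply(free, function(nm) tr$to[[nm]](base[[nm]]), numeric(1))
  if (any(!is.finite(par0)))
    stop("free parameters need positive starting values")

  make_params <- function(theta) {
    pl <- base
    for (i in seq_along(free)) pl[[free[i]]] <- tr$from[[free[i]]](theta[i])
    pl
  }
  nll <- function(theta) {
    pl <- make_params(theta)
    if (pl$p <= 0 || pl$p > 1) return(1e12)
    mu <- pl$c * outer((origins$pop / (origins$pop + pl$pop0))^pl$alpha_pop *
                         pl$beta_CA^origins$CA,
                       (destinations$A / (destinations$A + pl$A0))^pl$alpha_A *
                         (1 + pl$beta_camp * destinations$camp +
                            pl$beta_fac * destinations$fac +
                            pl$beta_mar * destinations$mar +
                            pl$beta_lpop *
                              (destinations$lpop /
                                 (destinations$lpop + pl$lpop0))^pl$alpha_lpop)) *
      (dmat / 1e4)^(-pl$alpha_d)
    mu[!is.finite(dmat)] <- 0
    dimnames(mu) <- dimnames(dmat)
    if (any(!is.finite(mu)) || any(mu < 0)) return(1e12)
    v <- composite_log_likelihood(data, mu, pl$p, rho, tau, xi)
    if (!is.finite(v)) 1e12 else -as.numeric(v)
  }

  starts <- list(par0)
  if (n_starts > 1)
    starts <- c(starts, .with_seed(seed, lapply(seq_len(n_starts - 1),
      function(s) par0 + stats::rnorm(length(par0), 0, 0.4))))
  best <- NULL
  for (s0 in starts) {
    o <- if (length(par0) == 1L)
      stats::optim(s0, nll, method = "BFGS", control = list(maxit = 300))
    else stats::optim(s0, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (length(par0) > 1L) {  # polish
    o <- stats::optim(best$par, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
    if (o$value < best$value) best <- o
  }
  if (best$value >= 1e12)
    stop("gravity fit failed to find a finite likelihood; best point: ",
         paste(signif(best$par, 4), collapse = ", "))

  est_t <- best$par
  names(est_t) <- free
  pl <- make_params(est_t)
  params <- do.call(gravity_params,
                    pl[intersect(names(pl), names(formals(gravity_params)))])
  n_cells <- nrow(data$shifts) * nrow(rho)
  logLik <- -best$value
  k <- length(free)
  cimat <- NULL
  fit <- structure(list(params = params, free = free, estimate = est_t,
                        logLik = logLik, AIC = 2 * k - 2 * logLik,
                        n_cells = n_cells, nll = nll,
                        back_transform = tr$from,
                        convergence = best$convergence,
                        rho = rho, tau = tau, xi = xi),
                   class = "gravity_fit")
  if (ci) {
    cimat <- t(vapply(free, function(nm)
      profile_confidence_interval(fit, nm, level = level), numeric(2)))
    dimnames(cimat) <- list(free, c("lower", "upper"))
    fit$ci <- cimat
  }
  fit
}

#' @export
print.gravity_fit <- function(x, ...) {
  cat("Gravity model fit (composite likelihood)\n")
  est <- vapply(x$free, function(nm)
    x$back_transform[[nm]](x$estimate[nm]), numeric(1))
  tab <- data.frame(estimate = signif(est, 4))
  if (!is.null(x$ci)) {
    tab$lower <- signif(x$ci[, 1], 4); tab$upper <- signif(x$ci[, 2], 4)
  }
  print(tab)
  cat(sprintf("logLik = %.3f over %d cells; AIC = %.2f\n",
              x$logLik, x$n_cells, x$AIC))
  invisible(x)
}

#' AIC-based selection among candidate gravity models
#'
#' Fits each candidate covariate structure and ranks by
#' \eqn{AIC = 2k - 2\log L} with the composite log-likelihood.  Ties are
#' ordered stably by candidate name.
#'
#' @param candidates named list; each element is a list with components
#'   \code{start} (a \code{gravity_params}) and \code{free} (character)
#' @param ... arguments passed on to \code{\link{fit_gravity}} (data,
#'   matrices, upstream fits, ...)
#' @return data frame with columns \code{name}, \code{k}, \code{logLik},
#'   \code{AIC}, \code{dAIC}, ascending in AIC, with the fitted models in
#'   attribute \code{fits}
#' @export
aic_select <- function(candidates, ...) {
  if (is.null(names(candidates)) || any(names(candidates) == ""))
    stop("candidates must be a named list")
  fits <- lapply(names(candidates), function(nm) {
    cand <- candidates[[nm]]
    fit_gravity(..., start = cand$start, free = cand$free, ci = FALSE)
  })
  names(fits) <- names(candidates)
  tab <- data.frame(name = names(candidates),
                    k = vapply(fits, function(f) length(f$free), numeric(1)),
                    logLik = vapply(fits, function(f) f$logLik, numeric(1)),
                    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$AIC, tab$name), ]
  tab$dAIC <- tab$AIC - tab$AIC[1]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  tab
}

#' Fit the non-informative null model
#'
#' The null counterpart used for Nagelkerke's pseudo R-squared: uniform
#' temporal traffic (window probability proportional to duration), a
#' route-choice model carrying no route information, and a gravity model
#' with one constant mean for all pairs.  The observed cell counts are
#' modelled as negative binomial with mean \code{M * duration/24} and a
#' fitted mean-to-variance ratio; \code{M} absorbs the constant passage
#' and compliance factors.
#'
#' @param data a \code{\link{count_data}}
#' @return list with \code{M}, \code{p}, \code{logLik}, \code{n_cells}
#' @export
fit_null_model <- function(data) {
  shifts <- data$shifts
  n_od <- length(data$origins) * length(data$destinations)
  dur <- (shifts$end - shifts$start) %% 24
  dur[dur == 0] <- 24
  cnts <- data$counts
  si <- match(cnts$shift, shifts$shift)
  nz_per_shift <- tabulate(si, nbins = nrow(shifts))
  nll <- function(par) {
    M <- exp(par[1]); p <- stats::plogis(par[2])
    m_s <- M * dur / 24
    lp0 <- dnbmv(0, m_s, p, log = TRUE)
    ll <- sum((n_od - nz_per_shift) * lp0)
    if (nrow(cnts))
      ll <- ll + sum(dnbmv(cnts$count, m_s[si], p, log = TRUE))
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  m0 <- max(sum(cnts$count) / max(sum(dur / 24), 1) / n_od, 1e-12)
  o <- stats::optim(c(log(m0), 0), nll, method = "Nelder-Mead",
                    control = list(maxit = 1000, reltol = 1e-10))
  list(M = exp(o$par[1]), p = stats::plogis(o$par[2]),
       logLik = -o$value, n_cells = nrow(shifts) * n_od)
}
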