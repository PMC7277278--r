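#' Daily traffic pattern parameters
#'
#' The daily traffic density is a von Mises distribution rescaled to a
#' 24-hour period: \eqn{f(t) = \exp(\kappa \cos(2\pi(t-\theta)/24)) /
#' (24 I_0(\kappa))}.  \code{theta} is the traffic peak time (hours,
#' circular on [0, 24)); \code{kappa} controls how sharp the peak is
#' (\code{kappa = 0} gives uniform traffic; the midday-to-night density
#' ratio is \eqn{e^{2\kappa}}).
#'
#' @param theta peak time of day in hours
#' @param kappa concentration, >= 0
#' @return object of class \code{temporal_params}
#' @export
temporal_params <- function(theta, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  structure(list(theta = theta %% 24, kappa = kappa),
            class = "temporal_params")
}

#' @export
print.temporal_params <- function(x, ...) {
  cat(sprintf("Daily traffic pattern: peak at %.2f h, concentration %.3f\n",
              x$theta, x$kappa))
  invisible(x)
}

#' Daily traffic density
#'
#' @param params a \code{temporal_params}
#' @param t time of day in hours (values are taken modulo 24)
#' @return density per hour; integrates to 1 over a day
#' @export
daily_density <- function(params, t) {
  k <- params$kappa
  # exp(k (cos - 1)) / (24 I0(k) e^-k) stays finite for large k
  exp(k * (cos(2 * pi * (t - params$theta) / 24) - 1)) /
    (24 * besselI(k, 0, expon.scaled = TRUE))
}

# split a (start, end) window into non-wrapping segments on [0, 24]
.window_segments <- function(start, end) {
  if (start < 0 || start >= 24) stop("start must be in [0, 24)")
  if (end <= start) {               # wraps midnight
    list(c(start, 24), c(0, end))
  } else if (end <= 24) {
    list(c(start, end))
  } else {                          # written as start + duration
    if (end - start > 24) stop("window longer than 24 h")
    if (end - 24 >= start) list(c(0, 24))
    else list(c(start, 24), c(0, end - 24))
  }
}

#' Probability of passing within a survey window
#'
#' Integral of the daily density over the shift window.  Windows may wrap
#' midnight (either \code{end < start} or \code{end > 24}); a full-day
#' window has probability 1.  The integral is computed by adaptive
#' quadrature with absolute tolerance 1e-10.
#'
#' @param params a \code{temporal_params}
#' @param start,end shift start and end times of day (hours)
#' @return probability tau in [0, 1]
#' @export
window_probability <- function(params, start, end) {
  n <- max(length(start), length(end))
  start <- rep_len(start, n); end <- rep_len(end, n)
  vapply(seq_len(n), function(i) {
    segs <- .window_segments(start[i], end[i])
    if (params$kappa == 0)
      return(sum(vapply(segs, function(s) (s[2] - s[1]) / 24, numeric(1))))
    tot <- sum(vapply(segs, function(s) {
      if (s[2] <= s[1]) return(0)
      stats::integrate(function(t) daily_density(params, t), s[1], s[2],
                       abs.tol = 1e-10, rel.tol = 1e-10,
                       subdivisions = 200L)$value
    }, numeric(1)))
    min(tot, 1)
  }, numeric(1))
}

# --- fast fixed-order quadrature used inside likelihood loops --------------

# Gauss-Legendre nodes/weights on [-1, 1] via the Golub-Welsch eigenproblem
.gauss_legendre <- function(n) {
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = rev(e$values), w = rev(2 * e$vectors[1, ]^2))
}

.gl64 <- NULL
.gl_nodes <- function() {
  if (is.null(.gl64)) {
    gl <- .gauss_legendre(64L)
    utils::assignInMyNamespace(".gl64", gl)
  }
  .gl64
}

# vectorized window probabilities for many (start, end) windows at once;
# windows must already be split so that end > start (callers pre-split
# wrapping windows).  Accurate to ~1e-10 for kappa <= 50.
.vm_window_prob <- function(theta, kappa, start, end) {
  gl <- .gl_nodes()
  half <- (end - start) / 2
  mid <- (end + start) / 2
  tt <- outer(half, gl$x) + mid            # n_windows x 64
  dens <- exp(kappa * (cos(2 * pi * (tt - theta) / 24) - 1)) /
    (24 * besselI(kappa, 0, expon.scaled = TRUE))
  pmin(as.numeric((dens %*% gl$w) * half), 1)
}

# tau for windows that may wrap midnight, vectorized
.vm_tau <- function(theta, kappa, start, end) {
  wrap <- end <= start
  out <- numeric(length(start))
  if (any(!wrap))
    out[!wrap] <- .vm_window_prob(theta, kappa, start[!wrap],
                                  pmin(end[!wrap], 24)) +
      ifelse(end[!wrap] > 24,
             .vm_window_prob(theta, kappa, rep(0, sum(!wrap)),
                             pmax(end[!wrap] - 24, 0)), 0)
  if (any(wrap))
    out[wrap] <- .vm_window_prob(theta, kappa, start[wrap],
                                 rep(24, sum(wrap))) +
      .vm_window_prob(theta, kappa, rep(0, sum(wrap)), end[wrap])
  pmin(out, 1)
}

#' Fit the daily traffic pattern by conditional maximum likelihood
#'
#' Observation times are censored by the survey schedule: an agent can only
#' be recorded while its shift was running.  Each observation therefore
#' contributes the density at its time divided by the probability mass of
#' its own shift window, which removes the bias introduced by unevenly
#' scheduled shifts.
#'
#' @param times observation times of day (decimal hours)
#' @param shift_id shift identifier per observation
#' @param shifts data frame with columns \code{shift}, \code{start},
#'   \code{end}
#' @param level confidence level for profile intervals
#' @param kappa_max upper cap for the concentration (degenerate samples
#'   would otherwise drive it to infinity)
#' @param ci logical: compute profile confidence intervals?
#' @return object of class \code{temporal_fit} with \code{params},
#'   \code{logLik}, \code{ci} and \code{convergence}
#' @export
fit_temporal <- function(times, shift_id, shifts, level = 0.95,
                         kappa_max = 50, ci = TRUE) {
  if (length(times) < 2 || length(unique(times)) < 2)
    stop("need at least two distinct observation times")
  shifts <- as.data.frame(shifts)
  idx <- match(as.character(shift_id), as.character(shifts$shift))
  if (anyNA(idx)) stop("observation references unknown shift")
  ws <- shifts$start[idx]; we <- shifts$end[idx]
  # unique windows with multiplicities: the conditional likelihood only
  # involves windows of shifts that contain observations
  key <- paste(ws, we)
  uk <- !duplicated(key)
  ustart <- ws[uk]; uend <- we[uk]
  mult <- as.numeric(table(factor(key, levels = key[uk])))
  w <- 2 * pi * times / 24

  nll <- function(par) {
    theta <- par[1]; kappa <- par[2]
    if (kappa < 0 || kappa > kappa_max) return(1e12)
    logf <- kappa * (cos(w - 2 * pi * theta / 24) - 1) -
      log(24 * besselI(kappa, 0, expon.scaled = TRUE))
    tau <- .vm_tau(theta, kappa, ustart, uend)
    if (any(tau <= 0)) return(1e12)
    -(sum(logf) - sum(mult * log(tau)))
  }

  # moment-based start: circular mean and a standard concentration inverse
  C <- mean(cos(w)); S <- mean(sin(w))
  theta0 <- (atan2(S, C) * 24 / (2 * pi)) %% 24
  R <- sqrt(C^2 + S^2)
  kappa0 <- if (R < 0.53) 2 * R + R^3 + 5 * R^5 / 6
  else if (R < 0.85) -0.4 + 1.39 * R + 0.43 / (1 - R)
  else 1 / (R^3 - 4 * R^2 + 3 * R)
  kappa0 <- min(max(kappa0, 0.01), kappa_max)

  # the conditional likelihood can be multimodal in theta when all shift
  # windows sit on one side of the day, so start from several peak offsets
  starts <- list(c(theta0, kappa0), c(theta0 + 6, kappa0),
                 c(theta0 - 6, kappa0), c(theta0 + 12, kappa0),
                 c(theta0, 0.25))
  opt <- NULL
  for (s0 in starts) {
    o <- stats::optim(s0, nll, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  o <- stats::optim(opt$par, nll, method = "L-BFGS-B",
                    lower = c(opt$par[1] - 2, 0),
                    upper = c(opt$par[1] + 2, kappa_max),
                    control = list(maxit = 200))
  if (o$value < opt$value) opt <- o
  est <- opt$par
  est[1] <- est[1] %% 24
  if (est[2] >= kappa_max - 1e-6)
    warning("concentration estimate capped at kappa_max = ", kappa_max)
  cimat <- NULL
  if (ci) {
    cimat <- rbind(
      theta = .profile_ci(nll, est, 1, level = level,
                          lower = est[1] - 12, upper = est[1] + 12),
      kappa = .profile_ci(nll, est, 2, level = level,
                          lower = 0, upper = kappa_max))
    cimat[1, ] <- cimat[1, ] %% 24
  }
  structure(list(params = temporal_params(est[1], est[2]),
                 logLik = -opt$value, ci = cimat,
                 convergence = opt$convergence, nll = nll, estimate = est),
            class = "temporal_fit")
}

#' @export
print.temporal_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("Conditional log-likelihood: %.3f\n", x$logLik))
  if (!is.null(x$ci)) {
    cat("Profile confidence intervals:\n")
    print(signif(x$ci, 4))
  }
  invisible(x)
}
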