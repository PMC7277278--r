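#' Negative binomial count law in mean / mean-to-variance parametrization
#'
#' The daily origin-destination counts follow a negative binomial
#' distribution parametrized by its mean \code{mu} and the ratio \code{p}
#' of mean to variance, shared across all pairs.  In the classical
#' (size, prob) parametrization this is \code{size = mu p / (1 - p)},
#' \code{prob = p}: the shared success probability makes the family closed
#' under addition of independent counts with common \code{p}, so the model
#' is invariant to how individual origins or destinations are pooled into
#' regions.  \code{p = 1} is the Poisson limit (variance equal to the
#' mean); \code{mu = 0} is a point mass at zero.
#'
#' @param x,q counts (nonnegative integers)
#' @param prob probabilities
#' @param n number of draws
#' @param mu mean (>= 0)
#' @param p mean-to-variance ratio, in (0, 1]
#' @param log,log.p,lower.tail as in \code{\link[stats]{dnbinom}}
#' @name nbmv
NULL

.check_p <- function(p) {
  if (any(p <= 0) || any(p > 1)) stop("p must be in (0, 1]")
}

#' @rdname nbmv
#' @export
dnbmv <- function(x, mu, p, log = FALSE) {
  .check_p(p)
  n <- max(length(x), length(mu), length(p))
  x <- rep_len(x, n); mu <- rep_len(mu, n); p <- rep_len(p, n)
  out <- numeric(n)
  pois <- p >= 1
  zero <- mu == 0
  out[zero] <- ifelse(x[zero] == 0, 0, -Inf)
  i <- pois & !zero
  out[i] <- stats::dpois(x[i], mu[i], log = TRUE)
  i <- !pois & !zero
  out[i] <- stats::dnbinom(x[i], size = mu[i] * p[i] / (1 - p[i]),
                           prob = p[i], log = TRUE)
  if (log) out else exp(out)
}

#' @rdname nbmv
#' @export
pnbmv <- function(q, mu, p, lower.tail = TRUE, log.p = FALSE) {
  .check_p(p)
  n <- max(length(q), length(mu), length(p))
  q <- rep_len(q, n); mu <- rep_len(mu, n); p <- rep_len(p, n)
  out <- numeric(n)
  pois <- p >= 1
  zero <- mu == 0
  out[zero] <- as.numeric(q[zero] >= 0)
  i <- pois & !zero
  out[i] <- stats::ppois(q[i], mu[i])
  i <- !pois & !zero
  out[i] <- stats::pnbinom(q[i], size = mu[i] * p[i] / (1 - p[i]), prob = p[i])
  if (!lower.tail) out <- 1 - out
  if (log.p) log(out) else out
}

#' @rdname nbmv
#' @export
qnbmv <- function(prob, mu, p) {
  .check_p(p)
  n <- max(length(prob), length(mu), length(p))
  prob <- rep_len(prob, n); mu <- rep_len(mu, n); p <- rep_len(p, n)
  out <- numeric(n)
  pois <- p >= 1
  zero <- mu == 0
  out[zero] <- 0
  i <- pois & !zero
  out[i] <- stats::qpois(prob[i], mu[i])
  i <- !pois & !zero
  out[i] <- stats::qnbinom(prob[i], size = mu[i] * p[i] / (1 - p[i]), prob = p[i])
  out
}

#' @rdname nbmv
#' @export
rnbmv <- function(n, mu, p) {
  .check_p(p)
  mu <- rep_len(mu, n); p <- rep_len(p, n)
  out <- integer(n)
  pois <- p >= 1
  zero <- mu == 0
  i <- pois & !zero
  out[i] <- stats::rpois(sum(i), mu[i])
  i <- !pois & !zero
  out[i] <- stats::rnbinom(sum(i), size = mu[i] * p[i] / (1 - p[i]), prob = p[i])
  out
}

#' Count distribution object
#'
#' Bundles pmf, cdf, quantile function and sampler for the negative
#' binomial law with mean \code{mu} and mean-to-variance ratio \code{p}.
#'
#' @inheritParams nbmv
#' @return list with functions \code{d}, \code{p}, \code{q}, \code{r} and
#'   fields \code{mean}, \code{var}
#' @export
nb_count_law <- function(mu, p) {
  if (mu < 0) stop("mu must be >= 0")
  .check_p(p)
  list(d = function(x, log = FALSE) dnbmv(x, mu, p, log = log),
       p = function(q) pnbmv(q, mu, p),
       q = function(prob) qnbmv(prob, mu, p),
       r = function(n) rnbmv(n, mu, p),
       mean = mu, var = if (mu == 0) 0 else mu / p)
}

# --- Thinned law -----------------------------------------------------------
# Binomial thinning of NB(size r, prob p) with retention t yields
# NB(size r, prob p / (p + t (1 - p))): the size is preserved, the success
# parameter grows toward 1 as the thinning gets stronger.  In mean /
# mean-to-variance terms: a daily count NB(mu, p) observed through the
# route (rho), time window (tau) and compliance (xi) filters has mean
# t * mu with t = rho * tau * xi, size mu p / (1 - p) and mean-to-variance
# ratio p / (p + t (1 - p)).  The Poisson case (p = 1) stays Poisson.

# log-pmf of the thinned count; vectorized over all arguments
.dnbthin <- function(x, mu, p, t, log = FALSE) {
  n <- max(length(x), length(mu), length(t))
  x <- rep_len(x, n); mu <- rep_len(mu, n); t <- rep_len(t, n)
  out <- numeric(n)
  m <- mu * t
  zero <- m == 0
  out[zero] <- ifelse(x[zero] == 0, 0, -Inf)
  if (p >= 1) {
    out[!zero] <- stats::dpois(x[!zero], m[!zero], log = TRUE)
  } else {
    q <- p / (p + t * (1 - p))
    i <- !zero
    out[i] <- stats::dnbinom(x[i], size = mu[i] * p / (1 - p),
                             prob = q[i], log = TRUE)
  }
  if (log) out else exp(out)
}

# variance of the thinned count (mean / ratio form)
.varnbthin <- function(mu, p, t) {
  m <- mu * t
  if (p >= 1) return(m)
  q <- p / (p + t * (1 - p))
  ifelse(m == 0, 0, m / q)
}
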