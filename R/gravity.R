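#' Covariate building blocks
#'
#' A building block maps one covariate to a dimensionless factor.  Two
#' forms are supported: the power form \eqn{f_0(x) = x^{\alpha_1}} and the
#' saturating form \eqn{f_1(x) = (x / (x + \alpha_0))^{\alpha_1}}.  The
#' saturating form is appropriate when differences between large covariate
#' values matter little; \code{alpha0} is the half-saturation constant in
#' covariate units.
#'
#' @param covariate name of the covariate the block reads
#' @param form \code{"power"} or \code{"saturating"}
#' @param alpha1 exponent (dimensionless)
#' @param alpha0 half-saturation constant (saturating form only, > 0)
#' @return an object of class \code{building_block}
#' @export
building_block <- function(covariate, form = c("power", "saturating"),
                           alpha1 = 1, alpha0 = NULL) {
  form <- match.arg(form)
  if (form == "saturating") {
    if (is.null(alpha0) || alpha0 <= 0)
      stop("saturating form requires alpha0 > 0")
  } else {
    alpha0 <- NULL
  }
  structure(list(covariate = covariate, form = form,
                 alpha1 = alpha1, alpha0 = alpha0),
            class = "building_block")
}

#' Evaluate a building block
#'
#' @param block a \code{building_block}
#' @param x covariate values (>= 0)
#' @return numeric vector of factors; the saturating form lies in [0, 1)
#'   for positive exponents
#' @export
eval_building_block <- function(block, x) {
  if (any(x < 0)) stop("covariate values must be nonnegative")
  if (block$form == "power") x^block$alpha1
  else (x / (x + block$alpha0))^block$alpha1
}

#' Gravity model parameters
#'
#' Parameters of the applied gravity mean model
#' \deqn{\mu_{ij} = c \left(\frac{pop_i}{pop_i + pop_0}\right)^{\alpha_{pop}}
#'   \beta_{CA}^{CA_i}
#'   \left(\frac{A_j}{A_j + A_0}\right)^{\alpha_A}
#'   \left(1 + \beta_{camp} camp_j + \beta_{fac} fac_j + \beta_{mar} mar_j
#'     + \beta_{lpop} \left(\frac{lpop_j}{lpop_j + lpop_0}\right)^{\alpha_{lpop}}\right)
#'   d_{ij}^{-\alpha_d}.}
#' Units follow the conventions under which the parameters are meaningful:
#' populations \code{pop} in 1e6 persons, near-lake populations \code{lpop}
#' in 1e3 persons, lake areas \code{A} in km^2, and travel times \code{d}
#' in 1e4 minutes.  \code{p} is the common mean-to-variance ratio of the
#' daily origin-destination counts.
#'
#' @param c scaling factor (> 0), agents per day per unit product
#' @param p mean-to-variance ratio, in (0, 1]
#' @param alpha_d travel-time exponent (> 0)
#' @param pop0,A0,lpop0 half-saturation constants (> 0)
#' @param alpha_pop,alpha_A,alpha_lpop block exponents (default 1, usually
#'   fixed)
#' @param beta_CA origin nation weight (>= 0)
#' @param beta_camp,beta_fac,beta_mar,beta_lpop additive attractiveness
#'   weights (>= 0)
#' @return object of class \code{gravity_params}
#' @export
gravity_params <- function(c, p, alpha_d,
                           pop0, alpha_pop = 1, beta_CA,
                           A0, alpha_A = 1,
                           beta_camp = 0, beta_fac = 0, beta_mar = 0,
                           beta_lpop = 0, lpop0 = 1, alpha_lpop = 1) {
  if (c <= 0) stop("c must be > 0")
  if (p <= 0 || p > 1) stop("p must be in (0, 1]")
  if (alpha_d <= 0) stop("alpha_d must be > 0")
  if (pop0 <= 0 || A0 <= 0 || lpop0 <= 0)
    stop("half-saturation constants must be > 0")
  betas <- c(beta_CA, beta_camp, beta_fac, beta_mar, beta_lpop)
  if (any(betas < 0)) stop("beta coefficients must be >= 0")
  structure(list(c = c, p = p, alpha_d = alpha_d,
                 pop0 = pop0, alpha_pop = alpha_pop, beta_CA = beta_CA,
                 A0 = A0, alpha_A = alpha_A,
                 beta_camp = beta_camp, beta_fac = beta_fac,
                 beta_mar = beta_mar, beta_lpop = beta_lpop,
                 lpop0 = lpop0, alpha_lpop = alpha_lpop),
            class = "gravity_params")
}

#' @export
print.gravity_params <- function(x, ...) {
  v <- unlist(x)
  cat("Gravity parameters:\n")
  print(signif(v, 4))
  invisible(x)
}

#' Origin repulsiveness
#'
#' @param params a \code{gravity_params}
#' @param origins data frame with columns \code{pop} (1e6 persons) and
#'   \code{CA} (1 for Canadian jurisdictions, else 0)
#' @return numeric vector of repulsiveness values m_i
#' @export
repulsiveness <- function(params, origins) {
  pop <- origins$pop
  if (any(pop < 0)) stop("pop must be >= 0")
  (pop / (pop + params$pop0))^params$alpha_pop * params$beta_CA^origins$CA
}

#' Destination attractiveness
#'
#' Lake size gates a facility term: a sufficient area and the presence of
#' facilities act together ("and"), while the facility types substitute for
#' one another ("or", additive).
#'
#' @param params a \code{gravity_params}
#' @param destinations data frame with columns \code{A} (km^2),
#'   \code{camp}, \code{fac}, \code{mar} (0/1 indicators) and \code{lpop}
#'   (1e3 persons within 5 km)
#' @return numeric vector of attractiveness values a_j
#' @export
attractiveness <- function(params, destinations) {
  d <- destinations
  if (any(d$A < 0) || any(d$lpop < 0)) stop("covariates must be >= 0")
  size <- (d$A / (d$A + params$A0))^params$alpha_A
  fac_term <- 1 + params$beta_camp * d$camp + params$beta_fac * d$fac +
    params$beta_mar * d$mar +
    params$beta_lpop * (d$lpop / (d$lpop + params$lpop0))^params$alpha_lpop
  size * fac_term
}

#' Mean daily origin-destination flow
#'
#' @param params a \code{gravity_params}
#' @param origins,destinations covariate data frames (see
#'   \code{\link{repulsiveness}}, \code{\link{attractiveness}}); both of
#'   length 1 or of equal length
#' @param d travel time in minutes (> 0); \code{Inf} (unreachable) yields 0
#' @return mean flows \eqn{\mu_{ij}} in agents per day
#' @export
mean_flow <- function(params, origins, destinations, d) {
  if (any(d <= 0, na.rm = TRUE)) stop("travel times must be > 0")
  m <- repulsiveness(params, origins)
  a <- attractiveness(params, destinations)
  mu <- params$c * m * a * (d / 1e4)^(-params$alpha_d)
  mu[!is.finite(d)] <- 0
  mu
}

#' Mean-flow matrix over all origin-destination pairs
#'
#' @param params a \code{gravity_params}
#' @param origins,destinations covariate data frames with rownames or an
#'   \code{id} column
#' @param dmat matrix of travel times in minutes (origins x destinations)
#' @return matrix of mean daily flows
#' @export
mean_flow_matrix <- function(params, origins, destinations, dmat) {
  m <- repulsiveness(params, origins)
  a <- attractiveness(params, destinations)
  mu <- params$c * outer(m, a) * (dmat / 1e4)^(-params$alpha_d)
  mu[!is.finite(dmat)] <- 0
  dimnames(mu) <- dimnames(dmat)
  mu
}

#' Reference parameter set: high-risk boater traffic into British Columbia
#'
#' Parameter values estimated for the traffic of potentially
#' mussel-infested trailered boats from North American jurisdictions to
#' British Columbian lakes, as surveyed by roadside watercraft inspection
#' stations.  Useful as a realistic default for the synthetic-data
#' generator and for worked examples.
#'
#' @return a list with components \code{gravity}
#'   (\code{\link{gravity_params}}), \code{route}
#'   (\code{\link{route_choice_params}}), \code{temporal}
#'   (\code{\link{temporal_params}}) and \code{compliance}
#'   (\code{\link{compliance_params}})
#' @export
bc_boater_params <- function() {
  list(
    gravity = gravity_params(c = 3.73e-8, p = 0.23, alpha_d = 3.45,
                             pop0 = 0.16, beta_CA = 14.79,
                             A0 = 1236,
                             beta_camp = 6.55, beta_fac = 4.51,
                             beta_mar = 26.4, beta_lpop = 1011,
                             lpop0 = 888),
    route = route_choice_params(lambda = 7.4, eta_c = 0.049, eta_o = 0.062,
                                gamma = 1.4, delta = 0.2),
    temporal = temporal_params(theta = 14.0, kappa = 1.34),
    compliance = compliance_params(xi_p = 0.80, xi_c = 0.93)
  )
}
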