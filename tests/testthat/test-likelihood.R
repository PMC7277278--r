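test_that("count datasets validate their records", {
  shifts <- data.frame(shift = c("s1", "s2"), station = "k1",
                       start = 9, end = 15)
  good <- data.frame(shift = "s1", origin = "a", destination = "b",
                     count = 2)
  expect_s3_class(count_data(shifts, good, "a", "b"), "count_data")
  expect_error(count_data(shifts, transform(good, shift = "zz"), "a", "b"),
               "unknown shifts")
  expect_error(count_data(shifts, transform(good, count = 1.5), "a", "b"),
               "integers")
  expect_error(count_data(shifts, transform(good, origin = "zz"), "a", "b"),
               "unknown origins")
})

test_that("the shift count law is the thinned negative binomial", {
  law <- shift_count_law(6, 0.23, 0.7, 0.45, 0.744)
  t <- 0.7 * 0.45 * 0.744
  expect_equal(law$mean, 6 * t)
  # zero-length window: point mass at zero
  law0 <- shift_count_law(6, 0.23, 0.7, 0, 0.744)
  expect_equal(law0$d(0), 1)
  expect_equal(law0$mean, 0)
  # expectation linear in the compliance rate
  expect_equal(shift_count_law(6, 0.23, 0.7, 0.45, 0.6)$mean,
               2 * shift_count_law(6, 0.23, 0.7, 0.45, 0.3)$mean)
  # mean additivity over disjoint windows of one shift
  expect_equal(shift_count_law(6, 0.23, 0.7, 0.2 + 0.25, 0.744)$mean,
               shift_count_law(6, 0.23, 0.7, 0.2, 0.744)$mean +
                 shift_count_law(6, 0.23, 0.7, 0.25, 0.744)$mean)
})

test_that("the shift count law matches the simulated hierarchy", {
  set.seed(31)
  mu <- 6; p <- 0.23; rho <- 0.7; tau <- 0.45; xi <- 0.744
  n <- 2e4
  N <- rnbmv(n, mu, p)
  N1 <- rbinom(n, N, rho)
  N2 <- rbinom(n, N1, tau)
  N3 <- rbinom(n, N2, xi)
  law <- shift_count_law(mu, p, rho, tau, xi)
  se <- sqrt(law$var / n)
  expect_lt(abs(mean(N3) - law$mean), 3 * se)
  # the variance of the thinned count exceeds Poisson and matches the law
  expect_equal(var(N3), law$var, tolerance = 0.1)
  expect_equal(mean(N3 == 0), law$d(0), tolerance = 0.02)
})

test_that("grouped composite likelihood equals the naive double loop", {
  set.seed(32)
  org <- c("a", "b"); dst <- c("x", "y")
  shifts <- data.frame(shift = paste0("s", 1:3),
                       station = c("k1", "k2", "k1"),
                       start = c(9, 9, 11), end = c(15, 15, 16))
  keys <- as.vector(outer(org, dst, paste, sep = "|"))
  rho <- matrix(runif(8, 0.05, 0.9), 4, 2, dimnames = list(keys, c("k1", "k2")))
  mu <- matrix(runif(4, 0.5, 8), 2, 2, dimnames = list(org, dst))
  tau <- c(0.3, 0.3, 0.25)
  p <- 0.23; xi <- 0.744
  counts <- data.frame(shift = c("s1", "s1", "s3"),
                       origin = c("a", "b", "a"),
                       destination = c("x", "y", "y"),
                       count = c(2, 1, 4))
  data <- count_data(shifts, counts, org, dst)
  got <- composite_log_likelihood(data, mu, p, rho, tau, xi)

  naive <- 0   # independent reimplementation of the thinned NB log-pmf
  for (s in 1:3) for (k in keys) {
    i <- sub("\\|.*", "", k); j <- sub(".*\\|", "", k)
    n_obs <- 0
    hit <- counts$shift == shifts$shift[s] & counts$origin == i &
      counts$destination == j
    if (any(hit)) n_obs <- counts$count[hit]
    t <- rho[k, shifts$station[s]] * tau[s] * xi
    size <- mu[i, j] * p / (1 - p)
    prob <- p / (p + t * (1 - p))
    naive <- naive + dnbinom(n_obs, size = size, prob = prob, log = TRUE)
  }
  expect_equal(as.numeric(got), naive, tolerance = 1e-8)
  expect_equal(attr(got, "n_cells"), 12)

  # record order is irrelevant
  data2 <- count_data(shifts[c(3, 1, 2), ], counts[c(3, 1, 2), ], org, dst)
  expect_equal(as.numeric(composite_log_likelihood(data2, mu, p, rho,
                                                   tau[c(3, 1, 2)], xi)),
               naive, tolerance = 1e-10)

  # an extra all-zero shift strictly decreases the log-likelihood
  shifts3 <- rbind(shifts, data.frame(shift = "s4", station = "k2",
                                      start = 10, end = 14))
  data3 <- count_data(shifts3, counts, org, dst)
  expect_lt(as.numeric(composite_log_likelihood(data3, mu, p, rho,
                                                c(tau, 0.2), xi)), naive)

  # empty dataset has log-likelihood zero
  empty <- count_data(shifts[0, ], counts[0, ], org, dst)
  expect_equal(as.numeric(composite_log_likelihood(empty, mu, p, rho,
                                                   numeric(0), xi)), 0)
})

test_that("scale confounding of c and xi holds exactly in the Poisson limit", {
  org <- "a"; dst <- c("x", "y")
  shifts <- data.frame(shift = paste0("s", 1:2), station = "k1",
                       start = 9, end = 15)
  keys <- paste("a", dst, sep = "|")
  rho <- matrix(c(0.6, 0.4), 2, 1, dimnames = list(keys, "k1"))
  mu <- matrix(c(2, 3), 1, 2, dimnames = list(org, dst))
  counts <- data.frame(shift = "s1", origin = "a", destination = "x",
                       count = 3)
  data <- count_data(shifts, counts, org, dst)
  # Poisson daily counts: thinning confounds the overall scale with the
  # compliance rate, only the product c * xi is identified
  l1 <- composite_log_likelihood(data, mu, 1, rho, c(0.4, 0.4), 0.8)
  l2 <- composite_log_likelihood(data, 2 * mu, 1, rho, c(0.4, 0.4), 0.4)
  expect_equal(as.numeric(l1), as.numeric(l2), tolerance = 1e-12)
  # overdispersed daily counts break the exact confounding: the thinned
  # law keeps the daily shape parameter, which scales with mu
  l3 <- composite_log_likelihood(data, mu, 0.3, rho, c(0.4, 0.4), 0.8)
  l4 <- composite_log_likelihood(data, 2 * mu, 0.3, rho, c(0.4, 0.4), 0.4)
  expect_false(isTRUE(all.equal(as.numeric(l3), as.numeric(l4))))
  # the cell means still agree, so first-moment fits cannot separate them
  expect_equal(shift_count_law(2, 0.3, 0.6, 0.4, 0.8)$mean,
               shift_count_law(4, 0.3, 0.6, 0.4, 0.4)$mean)
})

test_that("profile intervals are exact for quadratic log-likelihoods", {
  # quadratic nll in two parameters: CI = estimate +/- 1.96 se
  nll <- function(th) 0.5 * ((th[1] - 3) / 0.5)^2 + 0.5 * ((th[2] - 1) / 2)^2
  obj <- list(nll = nll, estimate = c(a = 3, b = 1))
  ci_a <- profile_confidence_interval(obj, 1)
  expect_equal(ci_a, 3 + c(-1, 1) * 1.96 * 0.5, tolerance = 1e-3)
  ci_b <- profile_confidence_interval(obj, 2)
  expect_equal(ci_b, 1 + c(-1, 1) * 1.96 * 2, tolerance = 1e-3)
  # monotone profile: open side
  obj2 <- list(nll = function(th) exp(-th[1]), estimate = c(a = 0))
  ci <- profile_confidence_interval(obj2, 1)
  expect_equal(ci[2], Inf)
})

test_that("gravity fitting enforces the staged order", {
  shifts <- data.frame(shift = "s1", station = "k1", start = 9, end = 15)
  data <- count_data(shifts, data.frame(shift = character(0),
                                        origin = character(0),
                                        destination = character(0),
                                        count = integer(0)), "a", "x")
  expect_error(fit_gravity(data, matrix(1e4, 1, 1), NULL, NULL,
                           route = NULL, temporal = NULL, compliance = NULL,
                           start = bc_boater_params()$gravity),
               "staged")
})

test_that("c is recovered exactly from noise-free counts near the Poisson limit", {
  org <- data.frame(id = "o", pop = 10, CA = 0)
  dst <- data.frame(id = "d", A = 1e9, camp = 0, fac = 0, mar = 0, lpop = 0)
  dmat <- matrix(1e4, 1, 1, dimnames = list("o", "d"))
  m <- 40
  shifts <- data.frame(shift = paste0("s", 1:m), station = "k",
                       start = 0, end = 24)
  counts <- data.frame(shift = shifts$shift, origin = "o",
                       destination = "d", count = 5L)
  data <- count_data(shifts, counts, "o", "d")
  rho <- matrix(1, 1, 1, dimnames = list("o|d", "k"))
  start <- gravity_params(c = 1, p = 1 - 1e-9, alpha_d = 3.45, pop0 = 0.16,
                          beta_CA = 1, A0 = 1236)
  fit <- fit_gravity(data, dmat, org, dst,
                     route = route_choice_params(7.4, 0, 0),
                     temporal = temporal_params(12, 0),
                     compliance = compliance_params(1, 1),
                     start = start, free = "c", rho = rho,
                     n_starts = 1, ci = FALSE)
  mu_hat <- unname(mean_flow(fit$params, org, dst, 1e4))
  expect_equal(mu_hat, 5, tolerance = 1e-4)
})

test_that("AIC selection ranks candidates and prefers the generating structure", {
  scen <- generate_scenario(tiny_config(seed = 71))
  surv <- simulate_surveys(scen)
  upstream <- list(route = scen$true$route, temporal = scen$true$temporal,
                   compliance = scen$true$compliance)
  start <- scen$true$gravity
  no_camp <- gravity_params(c = start$c, p = start$p, alpha_d = start$alpha_d,
                            pop0 = start$pop0, beta_CA = start$beta_CA,
                            A0 = start$A0, beta_camp = 0,
                            beta_fac = start$beta_fac,
                            beta_mar = start$beta_mar,
                            beta_lpop = start$beta_lpop, lpop0 = start$lpop0)
  cands <- list(with_camp = list(start = start, free = c("c", "p", "beta_camp")),
                no_camp = list(start = no_camp, free = c("c", "p")))
  tab <- aic_select(cands, data = surv$counts, dmat = scen$dmat,
                    origins = scen$origins, destinations = scen$destinations,
                    route = upstream$route, temporal = upstream$temporal,
                    compliance = upstream$compliance,
                    path_sets = scen$path_sets, incidence = scen$incidence,
                    n_starts = 2)
  expect_equal(tab$AIC, 2 * tab$k - 2 * tab$logLik)
  expect_equal(tab$dAIC[1], 0)
  # the candidate with the generating campground effect wins
  expect_equal(tab$name[1], "with_camp")
  # identical candidates tie with a stable name order
  same <- list(b_copy = list(start = start, free = "c"),
               a_copy = list(start = start, free = "c"))
  tab2 <- aic_select(same, data = surv$counts, dmat = scen$dmat,
                     origins = scen$origins, destinations = scen$destinations,
                     route = upstream$route, temporal = upstream$temporal,
                     compliance = upstream$compliance,
                     path_sets = scen$path_sets, incidence = scen$incidence,
                     n_starts = 1)
  expect_equal(tab2$AIC[1], tab2$AIC[2], tolerance = 1e-6)
  expect_equal(tab2$name, c("a_copy", "b_copy"))
})
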