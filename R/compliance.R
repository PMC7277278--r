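#' Compliance parameters
#'
#' @param xi_p participation rate (probability a passing agent stops)
#' @param xi_c complete/consistent-data rate among stopped high-risk agents
#' @return object of class \code{compliance_params} with the overall rate
#'   \code{xi = xi_p * xi_c}
#' @export
compliance_params <- function(xi_p, xi_c) {
  if (xi_p < 0 || xi_p > 1 || xi_c < 0 || xi_c > 1)
    stop("rates must be in [0, 1]")
  structure(list(xi_p = xi_p, xi_c = xi_c, xi = xi_p * xi_c),
            class = "compliance_params")
}

#' @export
print.compliance_params <- function(x, ...) {
  cat(sprintf("Compliance: participation %.3f x complete-data %.3f = %.3f\n",
              x$xi_p, x$xi_c, x$xi))
  invisible(x)
}

.clopper_pearson <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  c(lo, hi)
}

#' Estimate the compliance model
#'
#' The participation rate is the fraction of passing agents who stopped;
#' the complete-data rate is the fraction of stopped high-risk agents who
#' provided complete and consistent information.  A single rate is shared
#' across stations and shifts.  Shifts where bypassing agents were not
#' counted (missing \code{bypassed}) contribute only to the complete-data
#' rate.
#'
#' @param data either a data frame with per-shift columns \code{stopped},
#'   \code{bypassed} (may be \code{NA}), \code{highrisk_stopped},
#'   \code{highrisk_complete}, or \code{NULL} if pooled counts are given
#'   directly
#' @param n_stopped,n_bypassed,n_highrisk_stopped,n_highrisk_complete
#'   pooled counts (used when \code{data} is \code{NULL})
#' @param level confidence level for the Clopper-Pearson intervals
#' @return object of class \code{compliance_fit} with \code{params} and a
#'   \code{ci} matrix (rows \code{xi_p}, \code{xi_c}, \code{xi}; the
#'   interval for the product multiplies the endpoints and is approximate)
#' @export
estimate_compliance <- function(data = NULL, n_stopped = NULL,
                                n_bypassed = NULL, n_highrisk_stopped = NULL,
                                n_highrisk_complete = NULL, level = 0.95) {
  if (!is.null(data)) {
    data <- as.data.frame(data)
    has_bp <- !is.na(data$bypassed)
    n_stopped <- sum(data$stopped[has_bp])
    n_bypassed <- sum(data$bypassed[has_bp])
    n_highrisk_stopped <- sum(data$highrisk_stopped, na.rm = TRUE)
    n_highrisk_complete <- sum(data$highrisk_complete, na.rm = TRUE)
  }
  if (n_highrisk_complete > n_highrisk_stopped)
    stop("complete-data count exceeds stopped high-risk count")
  np <- n_stopped + n_bypassed
  if (is.na(np) || np <= 0)
    stop("no shifts with bypass counts: supply pooled counts of stopped ",
         "and bypassed agents")
  if (n_highrisk_stopped <= 0)
    stop("no stopped high-risk agents: supply pooled high-risk counts")
  xi_p <- n_stopped / np
  xi_c <- n_highrisk_complete / n_highrisk_stopped
  ci_p <- .clopper_pearson(n_stopped, np, level)
  ci_c <- .clopper_pearson(n_highrisk_complete, n_highrisk_stopped, level)
  ci <- rbind(xi_p = ci_p, xi_c = ci_c, xi = ci_p * ci_c)
  colnames(ci) <- c("lower", "upper")
  structure(list(params = compliance_params(xi_p, xi_c), ci = ci,
                 counts = c(stopped = n_stopped, bypassed = n_bypassed,
                            highrisk_stopped = n_highrisk_stopped,
                            highrisk_complete = n_highrisk_complete)),
            class = "compliance_fit")
}

#' @export
print.compliance_fit <- function(x, ...) {
  print(x$params)
  cat("Clopper-Pearson intervals:\n")
  print(signif(x$ci, 4))
  invisible(x)
}
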