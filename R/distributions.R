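#' Discrete service-duration distribution
#'
#' A `service_distribution` is a probability mass function over a strictly
#' increasing support of positive integer examination durations (minutes).
#'
#' @param support Integer vector of durations in minutes, strictly increasing,
#'   all positive.
#' @param probs Numeric vector of probabilities, same length as `support`,
#'   nonnegative and summing to 1 (within `1e-9`).
#'
#' @return An object of class `service_distribution` with elements `support`
#'   and `probs`.
#' @seealso [gp_duration_dist()], [ep_duration_dist()], [sample_duration()]
#' @export
#' @examples
#' d <- service_distribution(c(2L, 4L), c(0.5, 0.5))
#' dist_mean(d)
service_distribution <- function(support, probs) {
  if (length(support) != length(probs) || length(support) == 0L)
    stop("support and probs must be nonempty and of equal length")
  if (any(support <= 0) || any(support != round(support)))
    stop("support must consist of positive integer minutes")
  if (any(diff(support) <= 0))
    stop("support must be strictly increasing")
  if (any(probs < 0))
    stop("probs must be nonnegative")
  if (abs(sum(probs) - 1) > 1e-9)
    stop("probs must sum to 1")
  structure(list(support = as.integer(support), probs = as.numeric(probs)),
            class = "service_distribution")
}

#' @export
print.service_distribution <- function(x, ...) {
  cat("service_distribution on {", paste(x$support, collapse = ", "),
      "} min, mean", format(dist_mean(x), digits = 4), "min\n")
  invisible(x)
}

#' Mean of a service-duration distribution
#'
#' @param dist A [service_distribution()].
#' @return The expectation, in minutes.
#' @export
dist_mean <- function(dist) {
  stopifnot(inherits(dist, "service_distribution"))
  sum(dist$support * dist$probs)
}

#' Built-in examination-duration distributions
#'
#' Empirical duration tables for the two patient streams of the CT
#' examination queue.  General patients take 1--4 minutes (mean 2.26 min);
#' the emergency stream (urgent and emergency patients alike, who share one
#' arrival stream) takes 1--7 minutes (mean 3.195 min).
#'
#' @return A [service_distribution()].
#' @export
gp_duration_dist <- function() {
  service_distribution(1:4, c(0.111, 0.579, 0.249, 0.061))
}

#' @rdname gp_duration_dist
#' @export
ep_duration_dist <- function() {
  service_distribution(1:7, c(0.024, 0.341, 0.320, 0.155, 0.075, 0.061, 0.024))
}

#' Sample examination durations
#'
#' Draws from the discrete duration distribution using the current R random
#' number stream (seed with [set.seed()] for reproducibility).
#'
#' @param dist A [service_distribution()].
#' @param n Number of draws.
#' @return Integer vector of durations in minutes.
#' @export
sample_duration <- function(dist, n = 1L) {
  stopifnot(inherits(dist, "service_distribution"))
  if (n == 0L) return(integer(0))
  dist$support[findInterval(stats::runif(n), cumsum(dist$probs),
                            left.open = TRUE) + 1L]
}
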