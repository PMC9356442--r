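#' Beta posterior for one arm's mortality rate
#'
#' A uniform Beta(1, 1) prior on the 28-day mortality probability updated by
#' the binomial likelihood of the observed deaths and survivors gives a
#' Beta(deaths + 1, survivors + 1) posterior.
#'
#' @param deaths observed deaths (>= 0).
#' @param survivors observed survivors (>= 0).
#' @return An object of class `arm_posterior` with elements `deaths`,
#'   `survivors`, `alpha` (= deaths + 1) and `beta` (= survivors + 1).
#' @export
arm_posterior <- function(deaths, survivors) {
  deaths <- as.numeric(deaths); survivors <- as.numeric(survivors)
  if (length(deaths) != 1L || length(survivors) != 1L ||
      deaths < 0 || survivors < 0 || deaths != round(deaths) ||
      survivors != round(survivors))
    stop("deaths and survivors must be single non-negative counts")
  structure(list(deaths = deaths, survivors = survivors,
                 alpha = deaths + 1, beta = survivors + 1),
            class = "arm_posterior")
}

#' Posterior probability that one arm has lower mortality (two arms)
#'
#' Computes \eqn{P(p_1 < p_0)} for independent beta posteriors by
#' deterministic one-dimensional quadrature of arm 1's density against arm
#' 0's upper distribution function,
#' \eqn{\int_0^1 f_1(u)\,(1 - F_0(u))\,du}, to absolute accuracy 1e-8.
#'
#' @param p1 `arm_posterior` for the arm whose superiority is assessed.
#' @param p0 `arm_posterior` for the comparator.
#' @return Probability in `[0, 1]`.
#' @export
prob_best_two <- function(p1, p0) {
  stopifnot(inherits(p1, "arm_posterior"), inherits(p0, "arm_posterior"))
  # restrict to where either density has mass; avoids adaptive-quadrature
  # failures for very concentrated posteriors
  lo <- min(stats::qbeta(1e-12, p1$alpha, p1$beta),
            stats::qbeta(1e-12, p0$alpha, p0$beta))
  hi <- max(stats::qbeta(1e-12, p1$alpha, p1$beta, lower.tail = FALSE),
            stats::qbeta(1e-12, p0$alpha, p0$beta, lower.tail = FALSE))
  val <- stats::integrate(
    function(u) stats::dbeta(u, p1$alpha, p1$beta) *
      stats::pbeta(u, p0$alpha, p0$beta, lower.tail = FALSE),
    lower = lo, upper = hi, rel.tol = 1e-10, abs.tol = 1e-10,
    subdivisions = 500L
  )$value
  min(1, max(0, val))
}

#' Posterior probability of being the best arm (Monte Carlo, any number of arms)
#'
#' \eqn{\theta(l)}: joint Monte-Carlo samples are drawn from every arm's beta
#' posterior; \eqn{\theta(l)} is the fraction of draws in which arm `l`
#' attains the minimum mortality rate (ties, a measure-zero event for
#' continuous posteriors, broken uniformly at random). The returned vector
#' sums to 1 exactly.
#'
#' @param posteriors list of `arm_posterior` objects (>= 2 arms).
#' @param n_draws number of Monte-Carlo draws (default 10000, giving a
#'   standard error on each \eqn{\theta(l)} of at most 0.005).
#' @param rng an [rng_stream()] dedicated to posterior sampling.
#' @return Probability vector over arms.
#' @export
prob_best_multi <- function(posteriors, n_draws = 10000L, rng) {
  if (!is.list(posteriors) || length(posteriors) < 2L ||
      !all(vapply(posteriors, inherits, TRUE, "arm_posterior")))
    stop("posteriors must be a list of >= 2 arm_posterior objects")
  n_draws <- as.integer(n_draws)
  if (n_draws < 1L) stop("n_draws must be >= 1")
  L <- length(posteriors)
  a <- vapply(posteriors, `[[`, 0, "alpha")
  b <- vapply(posteriors, `[[`, 0, "beta")
  winners <- stream_eval(rng, {
    draws <- matrix(stats::rbeta(n_draws * L, rep(a, each = n_draws),
                                 rep(b, each = n_draws)),
                    nrow = n_draws, ncol = L)
    max.col(-draws, ties.method = "random")
  })
  tabulate(winners, nbins = L) / n_draws
}

#' @export
print.arm_posterior <- function(x, ...) {
  cat("<arm_posterior> Beta(", x$alpha, ", ", x$beta, ") from ",
      x$deaths, " deaths / ", x$survivors, " survivors; mean ",
      signif(x$alpha / (x$alpha + x$beta), 4), "\n", sep = "")
  invisible(x)
}
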