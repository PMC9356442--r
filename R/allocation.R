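#' Construct a randomisation policy
#'
#' Ten named strategies are available. Two-arm (standard care vs
#' dexamethasone):
#' \describe{
#'   \item{FeR}{1:1 fixed equal randomisation.}
#'   \item{FuR}{2:1 standard care : dexamethasone fixed unequal randomisation.}
#'   \item{T_f, T_s}{Tuning-algorithm response-adaptive randomisation,
#'     \eqn{\theta^s / (\theta^s + (1-\theta)^s)} with s the fraction of the
#'     trial completed, at cohort (`_f`) or subgroup (`_s`) scope.}
#'   \item{RMC_f, RMC_s}{REMAP-CAP-style rule
#'     \eqn{\sqrt{\theta(l)/(n_l + 1)}} normalised over arms, at cohort or
#'     subgroup scope.}
#' }
#' Two-arm adaptive probabilities are clipped to `[clip_lo, clip_hi]`
#' (default 0.1–0.9). Four-arm strategies `FeR4` (1:1:1:1), `FuR4` (2:1:1:1),
#' `T_f4` and `RMC_f4` apply the same adaptive rules across the three
#' experimental arms only, scaled to an experimental budget (default 0.6)
#' with control fixed at `control_fraction` (default 0.4); experimental
#' probabilities below `floor` (default 0.05) are raised to the floor with
#' the deficit taken from the largest arm.
#'
#' @param name one of `"FeR"`, `"FuR"`, `"T_f"`, `"RMC_f"`, `"T_s"`,
#'   `"RMC_s"`, `"FeR4"`, `"FuR4"`, `"T_f4"`, `"RMC_f4"`.
#' @param clip_lo,clip_hi two-arm clip bounds.
#' @param floor four-arm minimum experimental-arm probability.
#' @param control_fraction fixed four-arm control probability.
#' @param experimental_budget total probability shared by four-arm
#'   experimental arms.
#' @param n_draws Monte-Carlo draws used for the multi-arm
#'   probability-of-best computation.
#' @return An object of class `rar_policy`.
#' @export
rar_policy <- function(name, clip_lo = 0.1, clip_hi = 0.9, floor = 0.05,
                       control_fraction = 0.4, experimental_budget = 0.6,
                       n_draws = 10000L) {
  registry <- list(
    FeR     = list(n_arms = 2L, type = "fixed",    scope = "cohort",
                   fixed_probs = c(1/2, 1/2)),
    FuR     = list(n_arms = 2L, type = "fixed",    scope = "cohort",
                   fixed_probs = c(2/3, 1/3)),
    T_f     = list(n_arms = 2L, type = "tuning",   scope = "cohort"),
    RMC_f   = list(n_arms = 2L, type = "remapcap", scope = "cohort"),
    T_s     = list(n_arms = 2L, type = "tuning",   scope = "subgroup"),
    RMC_s   = list(n_arms = 2L, type = "remapcap", scope = "subgroup"),
    FeR4    = list(n_arms = 4L, type = "fixed",    scope = "cohort",
                   fixed_probs = c(1/4, 1/4, 1/4, 1/4)),
    FuR4    = list(n_arms = 4L, type = "fixed",    scope = "cohort",
                   fixed_probs = c(2/5, 1/5, 1/5, 1/5)),
    T_f4    = list(n_arms = 4L, type = "tuning",   scope = "cohort"),
    RMC_f4  = list(n_arms = 4L, type = "remapcap", scope = "cohort")
  )
  if (!name %in% names(registry))
    stop("unknown policy '", name, "'; available: ",
         paste(names(registry), collapse = ", "))
  if (!(clip_lo >= 0 && clip_lo < clip_hi && clip_hi <= 1))
    stop("need 0 <= clip_lo < clip_hi <= 1")
  if (floor < 0) stop("floor must be >= 0")
  if (control_fraction <= 0 || control_fraction >= 1)
    stop("control_fraction must be in (0, 1)")
  p <- registry[[name]]
  p$name <- name
  p$adaptive <- p$type != "fixed"
  p$clip_lo <- clip_lo; p$clip_hi <- clip_hi
  p$floor <- floor
  p$control_fraction <- control_fraction
  p$experimental_budget <- experimental_budget
  p$n_draws <- as.integer(n_draws)
  p$theta_fn <- NULL  # optional override for harness testing (see run_replicate)
  class(p) <- "rar_policy"
  p
}

#' All policies for a given arm count
#'
#' @param n_arms 2 or 4.
#' @return Named list of `rar_policy` objects in the order reported by the
#'   study (FuR/FeR first, then cohort RAR, then subgroup RAR).
#' @export
default_policies <- function(n_arms) {
  nm <- switch(as.character(n_arms),
               "2" = c("FuR", "FeR", "T_f", "RMC_f", "T_s", "RMC_s"),
               "4" = c("FuR4", "FeR4", "T_f4", "RMC_f4"),
               stop("n_arms must be 2 or 4"))
  stats::setNames(lapply(nm, rar_policy), nm)
}

#' Fixed two-arm dexamethasone probability
#'
#' @param policy a fixed two-arm `rar_policy` (`FeR` or `FuR`).
#' @return The experimental-arm (dexamethasone) allocation probability:
#'   1/2 for FeR, 1/3 for FuR.
#' @export
fixed_prob_two <- function(policy) {
  stopifnot(inherits(policy, "rar_policy"))
  if (policy$adaptive || policy$n_arms != 2L)
    stop("fixed_prob_two applies to fixed two-arm policies only")
  policy$fixed_probs[2L]
}

#' Tuning-algorithm allocation probability (two arms, unclipped)
#'
#' \eqn{\theta^s / (\theta^s + (1 - \theta)^s)}: at s = 0 (trial start) the
#' rule allocates 1:1 regardless of \eqn{\theta}; at s = 1 it allocates with
#' probability \eqn{\theta} itself, growing more exploitative as the trial
#' progresses.
#'
#' @param theta1 posterior probability that the experimental arm is best.
#' @param s fraction of trial completed at the adaptation point, `j / J`.
#' @return Unclipped experimental-arm probability.
#' @export
tuning_prob_two <- function(theta1, s) {
  stopifnot(theta1 >= 0, theta1 <= 1, s >= 0, s <= 1)
  w1 <- theta1^s
  w0 <- (1 - theta1)^s
  w1 / (w1 + w0)
}

#' REMAP-CAP-style allocation probability (two arms, unclipped)
#'
#' \eqn{\sqrt{\theta(1)/(n_1 + 1)} / (\sqrt{\theta(1)/(n_1+1)} +
#' \sqrt{\theta(0)/(n_0+1)})}: arms that have already accrued more observed
#' patients are discounted, so allocation imbalance is self-limiting.
#'
#' @param theta1,theta0 probability-of-best for the experimental and
#'   standard-care arm (need not both be zero).
#' @param n1,n0 observed patient counts on each arm within the adaptation
#'   window.
#' @return Unclipped experimental-arm probability.
#' @export
remapcap_prob_two <- function(theta1, theta0, n1, n0) {
  stopifnot(theta1 >= 0, theta1 <= 1, theta0 >= 0, theta0 <= 1,
            n1 >= 0, n0 >= 0)
  if (theta1 == 0 && theta0 == 0)
    stop("remapcap_prob_two undefined when both probabilities are zero")
  w1 <- sqrt(theta1 / (n1 + 1))
  w0 <- sqrt(theta0 / (n0 + 1))
  w1 / (w1 + w0)
}

#' Clip a two-arm allocation probability
#'
#' @param alpha unclipped probability.
#' @param lo,hi bounds (defaults 0.1 and 0.9).
#' @return `min(hi, max(lo, alpha))`.
#' @export
clip_two <- function(alpha, lo = 0.1, hi = 0.9) {
  stopifnot(lo >= 0, lo < hi, hi <= 1)
  pmin(hi, pmax(lo, alpha))
}

#' Tuning-algorithm allocation (experimental arms of a multi-arm trial)
#'
#' Per-arm tuning weights \eqn{\theta_l^s / (\theta_l^s + (1-\theta_l)^s)}
#' are normalised over the experimental arms and scaled by the experimental
#' budget (0.6 by default, the remainder being the fixed control fraction).
#'
#' @param thetas probability-of-best values for the experimental arms.
#' @param s fraction of trial completed.
#' @param experimental_budget total probability given to experimental arms.
#' @return Unclipped probability vector over experimental arms summing to the
#'   budget.
#' @export
tuning_prob_multi <- function(thetas, s, experimental_budget = 0.6) {
  stopifnot(all(thetas >= 0), all(thetas <= 1), s >= 0, s <= 1,
            experimental_budget > 0, experimental_budget < 1)
  w <- thetas^s / (thetas^s + (1 - thetas)^s)
  if (all(w == 0)) stop("all tuning weights are zero")
  experimental_budget * w / sum(w)
}

#' REMAP-CAP-style allocation (experimental arms of a multi-arm trial)
#'
#' Weights \eqn{\sqrt{\theta_l / (n_l + 1)}} normalised over experimental
#' arms and scaled by the experimental budget.
#'
#' @param thetas probability-of-best values for the experimental arms.
#' @param arm_counts observed patient counts per experimental arm within the
#'   adaptation window.
#' @param experimental_budget total probability given to experimental arms.
#' @return Unclipped probability vector over experimental arms summing to the
#'   budget.
#' @export
remapcap_prob_multi <- function(thetas, arm_counts, experimental_budget = 0.6) {
  stopifnot(all(thetas >= 0), all(thetas <= 1), all(arm_counts >= 0),
            length(thetas) == length(arm_counts),
            experimental_budget > 0, experimental_budget < 1)
  w <- sqrt(thetas / (arm_counts + 1))
  if (all(w == 0)) stop("all REMAP-CAP weights are zero")
  experimental_budget * w / sum(w)
}

#' Floor-clip a multi-arm experimental allocation vector
#'
#' Every experimental-arm probability below `floor` is raised to the floor
#' and the total deficit is subtracted from the single largest arm (ties
#' broken toward the lowest arm index), preserving the vector's sum exactly.
#' Errors if the largest arm would itself fall below the floor.
#'
#' @param alphas probability vector over experimental arms (sums to the
#'   experimental budget).
#' @param floor minimum per-arm probability (default 0.05).
#' @return Clipped probability vector with unchanged sum.
#' @export
clip_multi <- function(alphas, floor = 0.05) {
  stopifnot(all(is.finite(alphas)), floor >= 0)
  low <- alphas < floor
  if (!any(low)) return(alphas)
  deficit <- sum(floor - alphas[low])
  out <- alphas
  out[low] <- floor
  imax <- which.max(alphas)  # which.max breaks ties toward the lowest index
  out[imax] <- out[imax] - deficit
  if (out[imax] < floor - 1e-12)
    stop("floor ", floor, " infeasible: maximum arm would drop to ",
         format(out[imax]))
  out
}

#' Assemble the full allocation vector over all arms
#'
#' Applies the policy's rule, clipping, and (four-arm) the fixed control
#' fraction, returning a probability vector over every arm (control first).
#'
#' @param policy a `rar_policy`.
#' @param inputs list with elements `theta` (probability-of-best vector over
#'   all arms), `arm_counts` (observed patient counts per arm within the
#'   adaptation window) and `s` (fraction of trial completed). Ignored for
#'   fixed policies.
#' @param scen the `rar_scenario` (used to check dimensions).
#' @return Probability vector over all arms, summing to 1. Two-arm adaptive
#'   probabilities are clipped to `[clip_lo, clip_hi]`; four-arm experimental
#'   probabilities are floored at `floor` with control exactly
#'   `control_fraction`.
#' @export
full_allocation_vector <- function(policy, inputs = NULL, scen = NULL) {
  stopifnot(inherits(policy, "rar_policy"))
  L <- policy$n_arms
  if (!is.null(scen) && length(scen$arm_names) != L)
    stop("policy '", policy$name, "' expects ", L, " arms; scenario has ",
         length(scen$arm_names))
  if (!policy$adaptive) return(policy$fixed_probs)
  theta <- inputs$theta
  counts <- inputs$arm_counts
  s <- inputs$s
  if (length(theta) != L || length(counts) != L)
    stop("theta and arm_counts must have one entry per arm")
  if (L == 2L) {
    raw <- switch(policy$type,
      tuning   = tuning_prob_two(theta[2L], s),
      remapcap = remapcap_prob_two(theta[2L], theta[1L], counts[2L], counts[1L])
    )
    a <- clip_two(raw, policy$clip_lo, policy$clip_hi)
    c(1 - a, a)
  } else {
    raw <- switch(policy$type,
      tuning   = tuning_prob_multi(theta[-1L], s, policy$experimental_budget),
      remapcap = remapcap_prob_multi(theta[-1L], counts[-1L],
                                     policy$experimental_budget)
    )
    c(policy$control_fraction, clip_multi(raw, policy$floor))
  }
}

# allocation vector in force during burn-in
burn_in_vector <- function(policy) {
  if (!policy$adaptive) return(policy$fixed_probs)
  if (policy$n_arms == 2L) c(0.5, 0.5)
  else c(policy$control_fraction,
         rep(policy$experimental_budget / (policy$n_arms - 1L),
             policy$n_arms - 1L))
}

#' @export
print.rar_policy <- function(x, ...) {
  cat("<rar_policy>", x$name, "-", x$n_arms, "arms,", x$type, "rule,",
      x$scope, "scope\n")
  if (!x$adaptive) {
    cat("  fixed probabilities:", paste(signif(x$fixed_probs, 4), collapse = ", "), "\n")
  } else if (x$n_arms == 2L) {
    cat("  clip bounds: [", x$clip_lo, ",", x$clip_hi, "]\n")
  } else {
    cat("  control", x$control_fraction, "| experimental budget",
        x$experimental_budget, "| floor", x$floor, "\n")
  }
  invisible(x)
}
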