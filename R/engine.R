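#' Blocks at which allocation is adapted
#'
#' The first adaptation happens at block `burn_in + 1`, immediately after the
#' burn-in period, and then every `cadence` blocks until the end of the
#' trial. With the default schedule (burn-in 34, cadence 7) over 100 blocks
#' this gives blocks 35, 42, ..., 98.
#'
#' @param schedule an [adaptation_schedule()].
#' @param n_blocks total number of blocks.
#' @return Integer vector of adaptation block indices (possibly empty).
#' @export
adaptation_blocks <- function(schedule, n_blocks) {
  stopifnot(inherits(schedule, "rar_schedule"))
  first <- schedule$burn_in + 1L
  if (first > n_blocks) return(integer(0))
  as.integer(seq.int(first, n_blocks, by = schedule$cadence))
}

#' Blocks whose outcomes are observable at block j
#'
#' At an adaptation in block `j`, only patients from blocks `1..j - lag` have
#' reached the 28-day endpoint. The window is additionally capped at `j - 1`
#' (the current block has not been allocated yet), which only matters for
#' lag-free harness configurations.
#'
#' @param j current block index (>= 1).
#' @param lag outcome lag in blocks.
#' @return Integer vector `1..min(j - lag, j - 1)`; empty if no block has
#'   matured.
#' @export
observed_window <- function(j, lag) {
  j <- as.integer(j); lag <- as.integer(lag)
  if (j < 1L) stop("j must be >= 1")
  end <- min(j - lag, j - 1L)
  if (end < 1L) integer(0) else seq_len(end)
}

# probability-of-best vector from windowed deaths/counts for all arms
compute_theta <- function(policy, obs_deaths, obs_counts, po_stream) {
  if (!is.null(policy$theta_fn))
    return(policy$theta_fn(obs_deaths, obs_counts))
  posts <- lapply(seq_along(obs_counts), function(l)
    arm_posterior(obs_deaths[l], obs_counts[l] - obs_deaths[l]))
  if (length(posts) == 2L) {
    th1 <- prob_best_two(posts[[2L]], posts[[1L]])
    c(1 - th1, th1)
  } else {
    prob_best_multi(posts, n_draws = policy$n_draws, rng = po_stream)
  }
}

#' Simulate one trial replicate
#'
#' Runs a full trial block by block: subgroup membership, allocation-count
#' realisation under the probability vector currently in force, 28-day
#' mortality outcomes, and — for adaptive policies — scheduled allocation
#' updates computed from the outcome-lagged observed window. Allocation
#' vectors are piecewise-constant between adaptations; during burn-in,
#' adaptive two-arm policies allocate 1:1 and adaptive four-arm policies use
#' (control_fraction, equal experimental split). Subgroup-scope policies
#' maintain one allocation vector per subgroup, each adapting on its own
#' subgroup's observed window.
#'
#' The entire replicate is reproducible from `(scenario, policy, schedule,
#' seed)`: subgroup draws, allocation draws, outcome draws and posterior
#' Monte Carlo each use a dedicated named stream derived from `seed`.
#'
#' @param scen a `rar_scenario`.
#' @param policy a `rar_policy` with the same number of arms.
#' @param schedule an [adaptation_schedule()]; defaults to the scenario's.
#' @param seed integer replicate seed.
#' @return An object of class `rar_history` with elements `counts`, `deaths`
#'   and `alloc` (block x subgroup x arm arrays of allocated patients, deaths
#'   and the allocation probabilities in force) and `adaptations` (a data
#'   frame of per-adaptation snapshots: block, scope, arm, theta,
#'   alloc_prob).
#' @export
run_replicate <- function(scen, policy, schedule = scen$schedule, seed = 1L) {
  stopifnot(inherits(scen, "rar_scenario"), inherits(policy, "rar_policy"),
            inherits(schedule, "rar_schedule"))
  J <- scen$n_blocks
  K <- length(scen$subgroup_names)
  L <- length(scen$arm_names)
  if (policy$n_arms != L)
    stop("policy '", policy$name, "' expects ", policy$n_arms,
         " arms; scenario has ", L)

  sg_stream <- rng_stream(seed, "subgroups")
  al_stream <- rng_stream(seed, "allocation")
  oc_stream <- rng_stream(seed, "outcomes")
  po_stream <- rng_stream(seed, "posterior")

  counts <- array(0L, dim = c(J, K, L))
  deaths <- array(0L, dim = c(J, K, L))
  alloc  <- array(NA_real_, dim = c(J, K, L))
  dimnames(counts) <- dimnames(deaths) <- dimnames(alloc) <-
    list(NULL, scen$subgroup_names, scen$arm_names)

  current <- matrix(burn_in_vector(policy), nrow = K, ncol = L, byrow = TRUE)
  adapt_set <- if (policy$adaptive) adaptation_blocks(schedule, J) else integer(0)
  snaps <- vector("list", length(adapt_set) * K)
  n_snap <- 0L

  for (j in seq_len(J)) {
    if (j %in% adapt_set) {
      w <- observed_window(j, schedule$lag)
      s <- j / J
      if (policy$scope == "cohort") {
        obs_counts <- colSums(colSums(counts[w, , , drop = FALSE]))
        obs_deaths <- colSums(colSums(deaths[w, , , drop = FALSE]))
        theta <- compute_theta(policy, obs_deaths, obs_counts, po_stream)
        vec <- full_allocation_vector(
          policy, list(theta = theta, arm_counts = obs_counts, s = s), scen)
        current <- matrix(vec, nrow = K, ncol = L, byrow = TRUE)
        n_snap <- n_snap + 1L
        snaps[[n_snap]] <- data.frame(
          block = j, scope = "cohort", arm = scen$arm_names,
          theta = theta, alloc_prob = vec, stringsAsFactors = FALSE)
      } else {
        for (k in seq_len(K)) {
          obs_counts <- colSums(matrix(counts[w, k, ], ncol = L))
          obs_deaths <- colSums(matrix(deaths[w, k, ], ncol = L))
          theta <- compute_theta(policy, obs_deaths, obs_counts, po_stream)
          vec <- full_allocation_vector(
            policy, list(theta = theta, arm_counts = obs_counts, s = s), scen)
          current[k, ] <- vec
          n_snap <- n_snap + 1L
          snaps[[n_snap]] <- data.frame(
            block = j, scope = scen$subgroup_names[k], arm = scen$arm_names,
            theta = theta, alloc_prob = vec, stringsAsFactors = FALSE)
        }
      }
    }
    n_k <- tabulate(
      draw_block_subgroups(scen$subgroup_mix, scen$block_size, sg_stream),
      nbins = K)
    cnt <- matrix(0L, K, L)
    for (k in seq_len(K)) {
      if (n_k[k] > 0L)
        cnt[k, ] <- allocate_counts(current[k, ], n_k[k], al_stream)
    }
    counts[j, , ] <- cnt
    deaths[j, , ] <- draw_cell_deaths(cnt, scen$mortality, oc_stream)
    alloc[j, , ] <- current
  }

  structure(list(
    scenario = scen, policy = policy, schedule = schedule, seed = seed,
    counts = counts, deaths = deaths, alloc = alloc,
    adaptations = if (n_snap > 0L) do.call(rbind, snaps[seq_len(n_snap)])
                  else data.frame(block = integer(), scope = character(),
                                  arm = character(), theta = numeric(),
                                  alloc_prob = numeric())
  ), class = "rar_history")
}

#' Simulate a batch of independent replicates
#'
#' Each replicate's seed is derived deterministically from
#' `(base_seed, replicate index)`, so results are independent of execution
#' order and replicate `i` is unchanged when `n_reps` grows.
#'
#' @param scen a `rar_scenario`.
#' @param policy a `rar_policy`.
#' @param schedule an [adaptation_schedule()]; defaults to the scenario's.
#' @param n_reps number of replicates (the study design uses 1000).
#' @param base_seed integer batch seed.
#' @return An object of class `rar_batch`: a list of `rar_history` objects.
#' @export
run_batch <- function(scen, policy, schedule = scen$schedule, n_reps = 1000L,
                      base_seed = 1L) {
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  histories <- lapply(seq_len(n_reps), function(i)
    run_replicate(scen, policy, schedule,
                  seed = derive_seed(base_seed, paste0("replicate:", i))))
  structure(histories, class = "rar_batch",
            policy = policy$name, base_seed = base_seed)
}

#' @export
print.rar_history <- function(x, ...) {
  cat("<rar_history>", x$policy$name, "replicate, seed", x$seed, "\n")
  cat("  ", sum(x$counts), "patients in", dim(x$counts)[1L], "blocks;",
      sum(x$deaths), "deaths (",
      round(100 * sum(x$deaths) / sum(x$counts), 1), "%)\n")
  cat("  per-arm patients:",
      paste(colSums(colSums(x$counts)), collapse = " / "), "\n")
  n_adapt <- length(unique(x$adaptations$block))
  cat("  adaptations:", n_adapt, "\n")
  invisible(x)
}

#' @export
print.rar_batch <- function(x, ...) {
  cat("<rar_batch>", length(x), "replicates of policy", attr(x, "policy"),
      "(base seed", paste0(attr(x, "base_seed"), ")"), "\n")
  invisible(x)
}
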