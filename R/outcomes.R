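#' Draw subgroup membership for one block
#'
#' Each of the `block_size` patients in a block is assigned a subgroup
#' independently with probabilities `mix` (the 24/60/16% respiratory-support
#' mix in the default scenarios). Membership is sampled per patient rather
#' than fixed at rounded per-block counts, since the target proportions of a
#' block are non-integer.
#'
#' @param mix probability vector over subgroups (sums to 1).
#' @param block_size number of patients in the block.
#' @param rng an [rng_stream()].
#' @return Integer vector of length `block_size` with subgroup indices.
#' @export
draw_block_subgroups <- function(mix, block_size, rng) {
  mix <- as.numeric(mix)
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9)
    stop("mix must be non-negative and sum to 1")
  block_size <- as.integer(block_size)
  if (block_size < 1L) stop("block_size must be >= 1")
  stream_eval(rng, sample.int(length(mix), block_size, replace = TRUE, prob = mix))
}

#' Realise arm counts from an allocation probability vector
#'
#' Allocation probabilities are turned into realised patient counts by a
#' random draw (rather than deterministic rounding), creating the sampling
#' variation of patient-level randomisation: two arms use a binomial draw on
#' the experimental-arm probability; three or more arms use a single
#' multinomial draw.
#'
#' @param alloc_probs probability vector over arms (sums to 1).
#' @param n number of patients to allocate (>= 0).
#' @param rng an [rng_stream()].
#' @return Integer vector of per-arm counts summing to `n`.
#' @export
allocate_counts <- function(alloc_probs, n, rng) {
  alloc_probs <- as.numeric(alloc_probs)
  if (any(alloc_probs < 0)) stop("allocation probabilities must be non-negative")
  if (abs(sum(alloc_probs) - 1) > 1e-9)
    stop("allocation probabilities must sum to 1 (got ", format(sum(alloc_probs)), ")")
  n <- as.integer(n)
  if (n < 0L) stop("n must be >= 0")
  L <- length(alloc_probs)
  if (L < 2L) stop("need at least two arms")
  if (n == 0L) return(integer(L))
  if (L == 2L) {
    x1 <- stream_eval(rng, stats::rbinom(1L, n, alloc_probs[2L]))
    c(n - x1, x1)
  } else {
    as.integer(stream_eval(rng, stats::rmultinom(1L, n, alloc_probs))[, 1L])
  }
}

#' Draw a single 28-day mortality outcome
#'
#' \eqn{Y \sim \mathrm{bern}(P_{k,l})} for a patient in subgroup `k` on arm `l`.
#'
#' @param scen a `rar_scenario`.
#' @param k subgroup index.
#' @param l arm index.
#' @param rng an [rng_stream()].
#' @return 0 (survived) or 1 (died by 28 days).
#' @export
draw_outcome <- function(scen, k, l, rng) {
  stopifnot(inherits(scen, "rar_scenario"))
  K <- length(scen$subgroup_names); L <- length(scen$arm_names)
  if (k < 1 || k > K || l < 1 || l > L) stop("invalid subgroup or arm index")
  stream_eval(rng, stats::rbinom(1L, 1L, scen$mortality[k, l]))
}

# death counts for a whole block's (subgroup x arm) cell counts in one stream
# evaluation; equals iid bernoulli draws per patient in distribution.
draw_cell_deaths <- function(cell_counts, mortality, rng) {
  stream_eval(rng, stats::rbinom(length(cell_counts), as.vector(cell_counts),
                                 as.vector(mortality)))
}

#' Export a replicate's patients as a data frame
#'
#' Expands the per-block cell counts of a [run_replicate()] history into one
#' row per patient, ordered by block, then subgroup, then arm, with deaths
#' listed before survivors within a cell.
#'
#' @param history a `rar_history`.
#' @param replicate optional replicate id recorded in the first column.
#' @return A data frame with columns `replicate`, `block`, `subgroup`, `arm`,
#'   `outcome`.
#' @export
patient_table <- function(history, replicate = 1L) {
  stopifnot(inherits(history, "rar_history"))
  cnt <- history$counts; dth <- history$deaths
  J <- dim(cnt)[1L]; K <- dim(cnt)[2L]; L <- dim(cnt)[3L]
  idx <- which(cnt > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L], idx[, 3L]), , drop = FALSE]
  n <- cnt[idx]; d <- dth[idx]
  data.frame(
    replicate = replicate,
    block = rep.int(idx[, 1L], n),
    subgroup = history$scenario$subgroup_names[rep.int(idx[, 2L], n)],
    arm = history$scenario$arm_names[rep.int(idx[, 3L], n)],
    outcome = unlist(lapply(seq_along(n), function(i)
      rep.int(c(1L, 0L), c(d[i], n[i] - d[i])))),
    stringsAsFactors = FALSE
  )
}
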