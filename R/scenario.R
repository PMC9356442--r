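#' Define a trial scenario
#'
#' A scenario fixes the data-generating model of the simulated trial: the
#' arms (standard care always first), the patient subgroups and their mix,
#' the matrix of true 28-day mortality probabilities \eqn{P_{k,l}} (subgroup
#' k in rows, arm l in columns), the block structure, and the fraction of the
#' trial at which single-point operating characteristics are taken.
#'
#' @param arm_names character vector of arm identifiers; index 1 must be
#'   standard care.
#' @param subgroup_names character vector of subgroup identifiers.
#' @param mortality numeric matrix of death probabilities, `length(subgroup_names)`
#'   rows by `length(arm_names)` columns, all entries in `[0, 1]`.
#' @param subgroup_mix probability vector over subgroups (sums to 1).
#' @param block_size patients recruited per block (one block = one day).
#' @param n_blocks total number of blocks J.
#' @param metric_cut_fraction fraction of total patients at which single-point
#'   metrics are computed (default 0.80, i.e. 6400 of 8000 patients two-arm).
#' @param schedule an [adaptation_schedule()] giving burn-in, update cadence
#'   and outcome lag in blocks.
#' @return An object of class `rar_scenario`.
#' @seealso [recovery_two_arm()], [recovery_four_arm()], [null_variant()]
#' @export
scenario <- function(arm_names, subgroup_names, mortality, subgroup_mix,
                     block_size, n_blocks, metric_cut_fraction = 0.8,
                     schedule = adaptation_schedule()) {
  arm_names <- as.character(arm_names)
  subgroup_names <- as.character(subgroup_names)
  mortality <- as.matrix(mortality)
  subgroup_mix <- as.numeric(subgroup_mix)
  K <- length(subgroup_names)
  L <- length(arm_names)
  if (L < 2L) stop("scenario needs at least two arms")
  if (!identical(dim(mortality), c(K, L)))
    stop("mortality must be a ", K, " x ", L,
         " matrix (subgroups x arms); got ", nrow(mortality), " x ", ncol(mortality))
  if (any(!is.finite(mortality)) || any(mortality < 0) || any(mortality > 1))
    stop("mortality: all entries must be probabilities in [0, 1]")
  if (length(subgroup_mix) != K)
    stop("subgroup_mix must have one entry per subgroup")
  if (any(subgroup_mix < 0) || abs(sum(subgroup_mix) - 1) > 1e-12)
    stop("subgroup_mix must be non-negative and sum to 1 (got sum ",
         format(sum(subgroup_mix)), ")")
  block_size <- as.integer(block_size)
  n_blocks <- as.integer(n_blocks)
  if (block_size < 1L || n_blocks < 1L)
    stop("block_size and n_blocks must be positive integers")
  if (!is.numeric(metric_cut_fraction) || metric_cut_fraction <= 0 ||
      metric_cut_fraction > 1)
    stop("metric_cut_fraction must be in (0, 1]")
  stopifnot(inherits(schedule, "rar_schedule"))
  dimnames(mortality) <- list(subgroup_names, arm_names)
  structure(list(
    arm_names = arm_names,
    subgroup_names = subgroup_names,
    mortality = mortality,
    subgroup_mix = subgroup_mix,
    block_size = block_size,
    n_blocks = n_blocks,
    metric_cut_fraction = metric_cut_fraction,
    schedule = schedule
  ), class = "rar_scenario")
}

#' Adaptation schedule (burn-in, cadence, outcome lag)
#'
#' Controls when allocation probabilities are updated. The first adaptation
#' happens at block `burn_in + 1` and then every `cadence` blocks. At an
#' adaptation in block j, only outcomes from blocks `1..j - lag` have reached
#' the 28-day endpoint and may inform the posterior. The schedule must leave
#' the first adaptation a non-empty observed window
#' (`burn_in + 1 - lag >= 1`).
#'
#' @param burn_in number of initial blocks with fixed allocation (default 34).
#' @param cadence blocks between successive allocation updates (default 7).
#' @param lag outcome follow-up lag in blocks (default 28).
#' @return An object of class `rar_schedule`.
#' @export
adaptation_schedule <- function(burn_in = 34, cadence = 7, lag = 28) {
  burn_in <- as.integer(burn_in)
  cadence <- as.integer(cadence)
  lag <- as.integer(lag)
  if (burn_in < 0L || cadence < 1L || lag < 0L)
    stop("burn_in >= 0, cadence >= 1, lag >= 0 required")
  if (burn_in + 1L - lag < 1L)
    stop("first adaptation (block ", burn_in + 1L,
         ") would have an empty observed window with lag ", lag)
  structure(list(burn_in = burn_in, cadence = cadence, lag = lag),
            class = "rar_schedule")
}

#' RECOVERY-calibrated two-arm scenario
#'
#' Standard care vs dexamethasone, with the stratified 28-day mortality rates
#' observed in the RECOVERY trial (no oxygen 14.0% vs 17.8%; oxygen-only
#' 26.2% vs 23.3%; invasive ventilation 41.4% vs 29.3%), a 24/60/16% subgroup
#' mix, 100 blocks of 80 patients (8000 total), and single-point metrics at
#' 80% completion (6400 patients).
#'
#' @return A `rar_scenario`.
#' @export
recovery_two_arm <- function() {
  scenario(
    arm_names = c("standard_care", "dexamethasone"),
    subgroup_names = c("no_oxygen", "oxygen_only", "ventilated"),
    mortality = rbind(
      no_oxygen   = c(0.140, 0.178),
      oxygen_only = c(0.262, 0.233),
      ventilated  = c(0.414, 0.293)
    ),
    subgroup_mix = c(0.24, 0.60, 0.16),
    block_size = 80,
    n_blocks = 100,
    metric_cut_fraction = 0.80
  )
}

#' RECOVERY-calibrated four-arm scenario
#'
#' Standard care, dexamethasone, hydroxychloroquine and lopinavir-ritonavir
#' with the stratified RECOVERY mortality rates, 100 blocks of 120 patients
#' (12000 total), metrics at 80% completion (9600 patients).
#'
#' @return A `rar_scenario`.
#' @export
recovery_four_arm <- function() {
  scenario(
    arm_names = c("standard_care", "dexamethasone", "hydroxychloroquine",
                  "lopinavir"),
    subgroup_names = c("no_oxygen", "oxygen_only", "ventilated"),
    mortality = rbind(
      no_oxygen   = c(0.140, 0.178, 0.160, 0.167),
      oxygen_only = c(0.262, 0.233, 0.270, 0.247),
      ventilated  = c(0.414, 0.293, 0.421, 0.400)
    ),
    subgroup_mix = c(0.24, 0.60, 0.16),
    block_size = 120,
    n_blocks = 100,
    metric_cut_fraction = 0.80
  )
}

#' Null variant of a scenario (no treatment effect)
#'
#' Returns a copy of `s` in which, within every subgroup, each arm's mortality
#' equals the standard-care rate \eqn{P_{k,0}}. Used for type-I-error and
#' familywise-error simulations. Idempotent; all other fields unchanged.
#'
#' @param s a `rar_scenario`.
#' @return A `rar_scenario` with equal rates across arms.
#' @export
null_variant <- function(s) {
  stopifnot(inherits(s, "rar_scenario"))
  s$mortality[] <- s$mortality[, 1L]
  s
}

#' Total planned patients and the single-point metric cut
#'
#' @param s a `rar_scenario`.
#' @return `total_patients()`: `block_size * n_blocks`. `metric_cut()`: the
#'   patient count `metric_cut_fraction * total_patients`, rounded to nearest.
#' @export
total_patients <- function(s) {
  stopifnot(inherits(s, "rar_scenario"))
  s$block_size * s$n_blocks
}

#' @rdname total_patients
#' @export
metric_cut <- function(s) {
  stopifnot(inherits(s, "rar_scenario"))
  as.integer(round(s$metric_cut_fraction * total_patients(s)))
}

#' Load a scenario from a YAML configuration
#'
#' The configuration carries keys `arms`, `subgroups`, `mortality`
#' (subgroup-major list of rows), `mix`, `block_size`, `n_blocks`, and
#' optionally `metric_cut_fraction` and `schedule: {burn_in, cadence, lag}`
#' (defaults applied when omitted). All scenario invariants are checked.
#'
#' @param path path to a YAML file, or `text =` a YAML string.
#' @param text YAML string (alternative to `path`).
#' @return A `rar_scenario`.
#' @export
load_scenario <- function(path = NULL, text = NULL) {
  if (is.null(path) == is.null(text))
    stop("supply exactly one of path or text")
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else yaml::yaml.load(text)
  required <- c("arms", "subgroups", "mortality", "mix", "block_size", "n_blocks")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("scenario config is missing key(s): ", paste(missing, collapse = ", "))
  mort <- cfg$mortality
  if (is.list(mort)) mort <- do.call(rbind, lapply(mort, as.numeric))
  sched <- if (is.null(cfg$schedule)) adaptation_schedule() else
    adaptation_schedule(
      burn_in = cfg$schedule$burn_in %||% 34,
      cadence = cfg$schedule$cadence %||% 7,
      lag = cfg$schedule$lag %||% 28
    )
  scenario(
    arm_names = cfg$arms,
    subgroup_names = cfg$subgroups,
    mortality = mort,
    subgroup_mix = cfg$mix,
    block_size = cfg$block_size,
    n_blocks = cfg$n_blocks,
    metric_cut_fraction = cfg$metric_cut_fraction %||% 0.8,
    schedule = sched
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rar_scenario <- function(x, ...) {
  cat("Trial scenario:", length(x$arm_names), "arms,",
      length(x$subgroup_names), "subgroups\n")
  cat("  arms:", paste(x$arm_names, collapse = ", "), "\n")
  cat("  blocks:", x$n_blocks, "x", x$block_size, "patients =",
      total_patients(x), "total; metrics at n =", metric_cut(x), "\n")
  cat("  subgroup mix:", paste(format(x$subgroup_mix), collapse = " / "), "\n")
  cat("  28-day mortality P[k, l]:\n")
  print(round(x$mortality, 3))
  cat("  schedule: burn-in", x$schedule$burn_in, "blocks, update every",
      x$schedule$cadence, "blocks, outcome lag", x$schedule$lag, "blocks\n")
  invisible(x)
}

#' @export
print.rar_schedule <- function(x, ...) {
  cat("<rar_schedule> burn-in", x$burn_in, "| cadence", x$cadence,
      "| lag", x$lag, "blocks\n")
  invisible(x)
}
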