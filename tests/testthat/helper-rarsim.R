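# shared fixtures, built in code

# small fast trial for engine/metrics unit tests: 12 blocks of 20 patients,
# burn-in 4, update every 2 blocks, outcome lag 3
tiny_scenario <- function(n_arms = 2L) {
  mort <- if (n_arms == 2L) {
    rbind(a = c(0.2, 0.1), b = c(0.4, 0.3))
  } else {
    rbind(a = c(0.2, 0.1, 0.25, 0.22), b = c(0.4, 0.3, 0.45, 0.42))
  }
  scenario(
    arm_names = paste0("arm", seq_len(n_arms) - 1L),
    subgroup_names = c("a", "b"),
    mortality = mort,
    subgroup_mix = c(0.5, 0.5),
    block_size = 20,
    n_blocks = 12,
    metric_cut_fraction = 0.75,
    schedule = adaptation_schedule(burn_in = 4, cadence = 2, lag = 3)
  )
}

# cohort-level (mix-weighted) true mortality per arm
mixture_rates <- function(scen) {
  as.numeric(scen$subgroup_mix %*% scen$mortality)
}

# hand-built deterministic history for metric arithmetic tests
fake_history <- function(scen, counts, deaths) {
  pol <- rar_policy(if (length(scen$arm_names) == 2L) "FeR" else "FeR4")
  structure(list(
    scenario = scen, policy = pol, schedule = scen$schedule, seed = 0L,
    counts = counts, deaths = deaths,
    alloc = array(1 / length(scen$arm_names), dim = dim(counts)),
    adaptations = data.frame()
  ), class = "rar_history")
}
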