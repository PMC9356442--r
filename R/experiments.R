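#' Run a full simulation suite and write result tables
#'
#' Wires scenario, policies, schedule and replicate batches into the two
#' study suites. For each policy the batch is simulated and operating
#' characteristics are aggregated at the scenario's single-point cut;
#' type-I/familywise error is always measured on the null variant of the
#' scenario (equal mortality across arms). Results are written as a tidy CSV
#' plus wide-format tables (operating characteristics by policy; deaths and
#' deaths prevented versus FuR) and a JSON manifest recording the
#' specification and seeds.
#'
#' @param scenario `"two_arm"`, `"four_arm"`, a `rar_scenario`, or a path to
#'   a YAML scenario config.
#' @param policies character vector of policy names (default: every policy
#'   for the scenario's arm count) or a list of `rar_policy` objects.
#' @param n_reps replicates per batch (the study design uses 1000).
#' @param seed base seed; per-policy and per-replicate seeds are derived
#'   from it.
#' @param out_dir output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param trajectory if `TRUE`, also compute operating characteristics at
#'   every block-end cut and write them as `trajectory.csv`.
#' @param null_only if `TRUE`, only run the null-variant batches (error-rate
#'   study).
#' @return Invisibly, a list with `oc` (list of `rar_oc` per policy),
#'   `null_oc`, `tables` (from [table_report()]), and `trajectory` (long
#'   data frame or `NULL`).
#' @export
run_suite <- function(scenario = "two_arm", policies = NULL, n_reps = 1000L,
                      seed = 1L, out_dir = NULL, trajectory = FALSE,
                      null_only = FALSE) {
  scen <- if (inherits(scenario, "rar_scenario")) scenario
    else if (identical(scenario, "two_arm")) recovery_two_arm()
    else if (identical(scenario, "four_arm")) recovery_four_arm()
    else load_scenario(scenario)
  L <- length(scen$arm_names)
  if (is.null(policies)) policies <- default_policies(L)
  if (is.character(policies))
    policies <- stats::setNames(lapply(policies, rar_policy), policies)
  for (p in policies)
    if (p$n_arms != L)
      stop("policy '", p$name, "' is incompatible with a ", L, "-arm scenario")
  null_scen <- null_variant(scen)

  oc <- null_oc <- stats::setNames(vector("list", length(policies)),
                                   names(policies))
  traj <- NULL
  for (nm in names(policies)) {
    pol <- policies[[nm]]
    null_batch <- run_batch(null_scen, pol, n_reps = n_reps,
                            base_seed = derive_seed(seed, paste0("null:", nm)))
    null_oc[[nm]] <- operating_characteristics(null_batch)
    if (!null_only) {
      batch <- run_batch(scen, pol, n_reps = n_reps,
                         base_seed = derive_seed(seed, paste0("main:", nm)))
      oc[[nm]] <- operating_characteristics(batch)
      if (trajectory) {
        cuts <- seq_len(scen$n_blocks) * scen$block_size
        for (ct in cuts) {
          occ <- suppressWarnings(operating_characteristics(batch, n_cut = ct))
          m <- occ$metrics
          m$policy <- nm; m$n_cut <- ct
          traj <- rbind(traj, m)
        }
      }
    }
  }
  if (null_only) oc <- NULL
  tables <- if (!null_only) table_report(oc, null_oc, scen) else NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    tidy <- NULL
    for (nm in names(policies)) {
      for (set in list(c("main", nm), c("null", nm))) {
        o <- if (set[1L] == "main") oc[[nm]] else null_oc[[nm]]
        if (is.null(o)) next
        m <- o$metrics
        m$policy <- nm; m$variant <- set[1L]
        m$n_cut <- o$n_cut; m$n_reps <- o$n_reps
        tidy <- rbind(tidy, m)
      }
    }
    utils::write.csv(tidy, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    if (!is.null(tables)) {
      utils::write.csv(tables$operating, file.path(out_dir, "table_oc.csv"),
                       row.names = FALSE)
      utils::write.csv(tables$deaths, file.path(out_dir, "table_deaths.csv"),
                       row.names = FALSE)
    }
    if (!is.null(traj))
      utils::write.csv(traj, file.path(out_dir, "trajectory.csv"),
                       row.names = FALSE)
    manifest <- list(
      scenario = if (is.character(scenario)) scenario else "custom",
      arms = scen$arm_names, policies = names(policies),
      n_reps = n_reps, seed = seed, null_only = null_only,
      trajectory = trajectory,
      package_version = as.character(utils::packageVersion("rarsim")))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(oc = oc, null_oc = null_oc, tables = tables,
                 trajectory = traj))
}

#' Wide-format report tables
#'
#' Builds the study's two table shapes: an operating-characteristics table
#' (allocation %, mortality, power, error rate, bias on the 1e-2 scale, MSE
#' on the 1e-4 scale; one column block per policy) and a deaths table
#' (mean deaths +/- SE with percentage, and deaths prevented versus the FuR
#' reference, left blank for FuR itself). Missing metrics render as `NA`,
#' never fabricated.
#'
#' @param oc named list of `rar_oc` from the main scenario.
#' @param null_oc named list of `rar_oc` from the null variant (error rates).
#' @param scen the `rar_scenario`.
#' @return List with data frames `operating` and `deaths`.
#' @export
table_report <- function(oc, null_oc = NULL, scen = NULL) {
  stopifnot(is.list(oc), length(oc) > 0)
  if (is.null(scen)) scen <- oc[[1L]]$scenario
  pol_names <- names(oc)
  L <- length(scen$arm_names)

  num <- function(x, d = 1) ifelse(is.na(x), NA, round(x, d))
  rows <- list()
  arow <- function(characteristic, scope, arm, values) {
    rows[[length(rows) + 1L]] <<- cbind(
      data.frame(characteristic = characteristic, scope = scope, arm = arm,
                 stringsAsFactors = FALSE),
      as.data.frame(as.list(stats::setNames(values, pol_names))))
  }
  for (l in seq_len(L)) {
    arow(paste0("allocation_pct"), "cohort", scen$arm_names[l],
         num(100 * vapply(oc, oc_value, 0, "alloc_prop", "cohort",
                          scen$arm_names[l])))
  }
  if (L == 2L) {
    for (k in seq_along(scen$subgroup_names))
      arow("allocation_pct", scen$subgroup_names[k], scen$arm_names[2L],
           num(100 * vapply(oc, oc_value, 0, "alloc_prop",
                            scen$subgroup_names[k], scen$arm_names[2L])))
  }
  arow("deaths", "cohort", NA, num(vapply(oc, oc_value, 0, "deaths")))
  arow("mortality_pct", "cohort", NA,
       num(100 * vapply(oc, function(o) oc_value(o, "deaths") / o$n_cut, 0)))
  power_scopes <- if (L == 2L)
    c("cohort",
      scen$subgroup_names[intersect(2:3, seq_along(scen$subgroup_names))])
  else "cohort"
  power_arms <- if (L == 2L) scen$arm_names[2L]
                else scen$arm_names[c(2L, L)]
  for (sc in power_scopes) for (ar in power_arms)
    arow("power_pct", sc, ar,
         num(100 * vapply(oc, oc_value, 0, "reject", sc, ar)))
  if (!is.null(null_oc)) {
    if (L == 2L) {
      arow("type1_error_pct", "cohort", scen$arm_names[2L],
           num(100 * vapply(null_oc, function(o) {
             v <- oc_value(o, "reject", "cohort", scen$arm_names[2L])
             if (is.na(v)) mean(vapply(scen$subgroup_names[2:3], function(s)
               oc_value(o, "reject", s, scen$arm_names[2L]), 0))
             else v
           }, 0)))
    } else {
      arow("fwer_pct", "cohort", NA,
           num(100 * vapply(null_oc, oc_value, 0, "fwer", "cohort", NA)))
    }
  }
  bias_scopes <- if (L == 2L) c("cohort", scen$subgroup_names) else "cohort"
  bias_arms <- if (L == 2L) scen$arm_names[2L] else scen$arm_names[-1L]
  for (sc in bias_scopes) for (ar in bias_arms) {
    arow("bias_x1e2", sc, ar,
         num(100 * vapply(oc, oc_value, 0, "bias", sc, ar), 2))
    arow("mse_x1e4", sc, ar,
         num(1e4 * vapply(oc, oc_value, 0, "mse", sc, ar), 2))
  }
  operating <- do.call(rbind, rows)

  deaths_mean <- vapply(oc, oc_value, 0, "deaths")
  deaths_se <- vapply(oc, oc_value, 0, "deaths", what = "se")
  ref <- grep("^FuR", pol_names, value = TRUE)[1L]
  prevented <- if (!is.na(ref)) deaths_mean[ref] - deaths_mean
               else rep(NA_real_, length(oc))
  if (!is.na(ref)) prevented[ref] <- NA  # reference policy: rendered as dash
  deaths <- data.frame(
    policy = pol_names,
    deaths_mean = round(deaths_mean, 1),
    deaths_se = round(deaths_se, 2),
    mortality_pct = round(100 * deaths_mean / oc[[1L]]$n_cut, 1),
    deaths_prevented_vs_FuR = round(prevented, 1),
    row.names = NULL, stringsAsFactors = FALSE)

  list(operating = operating, deaths = deaths)
}
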