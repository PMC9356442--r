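#' Per-cell patients and deaths among the first n_cut patients
#'
#' Patients are counted in block order. The study's cut points (6400 of 8000
#' two-arm, 9600 of 12000 four-arm) fall exactly on block boundaries; a cut
#' inside a block contributes that block's cells pro rata (fractional
#' counts), which preserves expectations for trajectory metrics at arbitrary
#' cuts.
#'
#' @param history a `rar_history`.
#' @param n_cut number of patients (<= total).
#' @return List with `counts` and `deaths`, subgroup x arm matrices.
#' @export
cut_cells <- function(history, n_cut) {
  stopifnot(inherits(history, "rar_history"))
  bs <- history$scenario$block_size
  total <- sum(history$counts)
  n_cut <- as.numeric(n_cut)
  if (n_cut < 0 || n_cut > total) stop("n_cut must be in [0, ", total, "]")
  full <- floor(n_cut / bs)
  frac <- (n_cut - full * bs) / bs
  K <- dim(history$counts)[2L]; L <- dim(history$counts)[3L]
  take <- function(a) {
    m <- if (full > 0L) colSums(a[seq_len(full), , , drop = FALSE], dims = 1L)
         else matrix(0, K, L)
    if (frac > 0) m <- m + frac * a[full + 1L, , ]
    dimnames(m) <- list(history$scenario$subgroup_names,
                        history$scenario$arm_names)
    m
  }
  list(counts = take(history$counts), deaths = take(history$deaths))
}

#' Deaths among the first n_cut patients of a replicate
#'
#' Counts the eventual 28-day outcomes of the first `n_cut` allocated
#' patients; the outcome lag constrains adaptation, not metric computation.
#'
#' @inheritParams cut_cells
#' @return Number of deaths.
#' @export
deaths_at <- function(history, n_cut) {
  sum(cut_cells(history, n_cut)$deaths)
}

#' Proportion of the first n_cut patients allocated to an arm
#'
#' @inheritParams cut_cells
#' @param arm arm index or name.
#' @param scope `NULL` (whole cohort) or a subgroup index/name, in which case
#'   the proportion is among that subgroup's patients within the cut.
#' @return Fraction in `[0, 1]`.
#' @export
allocation_proportion <- function(history, arm, n_cut, scope = NULL) {
  cc <- cut_cells(history, n_cut)$counts
  arm <- resolve_index(arm, history$scenario$arm_names, "arm")
  if (is.null(scope)) {
    sum(cc[, arm]) / sum(cc)
  } else {
    k <- resolve_index(scope, history$scenario$subgroup_names, "subgroup")
    cc[k, arm] / sum(cc[k, ])
  }
}

resolve_index <- function(x, names, what) {
  if (is.character(x)) {
    i <- match(x, names)
    if (is.na(i)) stop("unknown ", what, " '", x, "'")
    i
  } else {
    x <- as.integer(x)
    if (x < 1L || x > length(names)) stop("invalid ", what, " index ", x)
    x
  }
}

#' Test an experimental arm against standard care
#'
#' Fits the maximum-likelihood binomial log-odds (logistic regression) model
#' of death on an indicator of arm `arm` versus standard care, using the
#' first `n_cut` patients (other arms excluded), and performs a two-sided
#' Wald test of the arm coefficient at level `level / n_comparisons`
#' (Bonferroni). With a single binary covariate the ML fit is the saturated
#' 2x2 model, so the coefficient is the sample log odds ratio with standard
#' error \eqn{\sqrt{1/a + 1/b + 1/c + 1/d}}; a zero cell (no deaths or no
#' survivors on an arm) makes the Wald statistic degenerate, and the test
#' falls back to the two-proportion score test (flagged in the result).
#'
#' Also returns the risk-difference estimate
#' \eqn{\hat P_{0} - \hat P_{arm}} from raw cell proportions, the quantity
#' used by the bias and MSE metrics.
#'
#' @inheritParams cut_cells
#' @param arm experimental arm index or name.
#' @param level nominal significance level (default 0.05).
#' @param n_comparisons Bonferroni divisor (1 two-arm; 3 four-arm).
#' @param scope `NULL` for the whole cohort or a subgroup index/name.
#' @param mature_only if `TRUE`, restrict to patients in blocks whose 28-day
#'   outcome has matured by the cut block (blocks `1..cut_block - lag`).
#' @return List with `reject` (logical), `estimate` (risk difference),
#'   `p_value`, and `method` (`"wald"` or `"score"`).
#' @export
treatment_test <- function(history, n_cut, arm, level = 0.05,
                           n_comparisons = 1L, scope = NULL,
                           mature_only = FALSE) {
  scen <- history$scenario
  arm <- resolve_index(arm, scen$arm_names, "arm")
  if (arm == 1L) stop("arm must be an experimental arm, not standard care")
  if (mature_only) {
    cut_block <- floor(n_cut / scen$block_size)
    n_cut <- max(0L, (cut_block - history$schedule$lag)) * scen$block_size
    if (n_cut == 0L) stop("no matured outcomes before the cut")
  }
  cc <- cut_cells(history, n_cut)
  rows <- if (is.null(scope)) seq_len(nrow(cc$counts))
          else resolve_index(scope, scen$subgroup_names, "subgroup")
  n0 <- round(sum(cc$counts[rows, 1L])); d0 <- round(sum(cc$deaths[rows, 1L]))
  n1 <- round(sum(cc$counts[rows, arm])); d1 <- round(sum(cc$deaths[rows, arm]))
  if (n0 == 0L || n1 == 0L)
    stop("both arms must be present among the first n_cut patients")
  estimate <- d0 / n0 - d1 / n1
  a <- d1; b <- n1 - d1; cc0 <- d0; dd <- n0 - d0
  if (min(a, b, cc0, dd) > 0) {
    beta <- log((a / b) / (cc0 / dd))
    se <- sqrt(1 / a + 1 / b + 1 / cc0 + 1 / dd)
    p <- 2 * stats::pnorm(-abs(beta / se))
    method <- "wald"
  } else if (d0 + d1 == 0L || (b + dd) == 0L) {
    p <- 1  # no information on a difference
    method <- "score"
  } else {
    p <- suppressWarnings(
      stats::prop.test(c(d1, d0), c(n1, n0), correct = FALSE)$p.value)
    method <- "score"
  }
  list(reject = p < level / n_comparisons, estimate = estimate,
       p_value = p, method = method)
}

#' Relative bias of replicate treatment-effect estimates
#'
#' \eqn{E[((\hat P_0 - \hat P_1) - (P_0 - P_1)) / (P_0 - P_1)]}: the mean
#' over replicates of the risk-difference estimation error as a fraction of
#' the true risk difference.
#'
#' @param estimates vector of per-replicate risk-difference estimates
#'   \eqn{\hat P_0 - \hat P_1}.
#' @param p0,p1 true mortality rates on standard care and the experimental
#'   arm (must differ).
#' @return Relative bias (unitless fraction).
#' @export
relative_bias <- function(estimates, p0, p1) {
  true_diff <- p0 - p1
  if (abs(true_diff) < 1e-12)
    stop("relative bias undefined when the true difference is zero")
  mean((estimates - true_diff) / true_diff)
}

#' Mean squared error of replicate treatment-effect estimates
#'
#' \eqn{\frac{1}{N}\sum_n ((\hat P_0 - \hat P_1)_n - (P_0 - P_1))^2}.
#'
#' @param estimates vector of per-replicate risk-difference estimates.
#' @param true_diff true risk difference \eqn{P_0 - P_1}.
#' @return Mean squared error.
#' @export
mse <- function(estimates, true_diff) {
  if (!length(estimates)) stop("need at least one estimate")
  mean((estimates - true_diff)^2)
}

#' Neyman allocation for a two-arm binary outcome
#'
#' The power-optimal standard-care allocation fraction
#' \eqn{\sqrt{p_0 q_0} / (\sqrt{p_0 q_0} + \sqrt{p_1 q_1})}, proportional to
#' each arm's outcome standard deviation. On the cohort-weighted mortality
#' rates of the default two-arm scenario this is a 51%/49% split.
#'
#' @param p0,p1 mortality rates in (0, 1).
#' @return Standard-care allocation fraction.
#' @export
neyman_allocation <- function(p0, p1) {
  if (p0 <= 0 || p0 >= 1 || p1 <= 0 || p1 >= 1)
    stop("rates must be strictly inside (0, 1)")
  s0 <- sqrt(p0 * (1 - p0)); s1 <- sqrt(p1 * (1 - p1))
  s0 / (s0 + s1)
}

#' Aggregate operating characteristics over a replicate batch
#'
#' Computes, per replicate and summarised as mean +/- standard error
#' (sample SD / sqrt(N)) across replicates: deaths at the cut; allocation
#' proportion per arm (cohort, and per subgroup for two-arm trials);
#' rejection rates (cohort Wald test at 5% for cohort-scope two-arm
#' policies; subgroup tests for the oxygen-only and ventilated subgroups for
#' subgroup-scope policies; dexamethasone and lopinavir tests at Bonferroni
#' 0.05/3 plus the familywise error over all three comparisons for four-arm
#' trials); relative bias and MSE of the risk-difference estimates at cohort
#' scope (two-arm also per subgroup; four-arm per experimental arm). Bias is
#' skipped where the true difference is zero (null scenarios).
#'
#' @param batch a `rar_batch` (or list of `rar_history`, >= 2 replicates).
#' @param n_cut patient cut; defaults to the scenario's [metric_cut()].
#' @param mature_only passed to [treatment_test()].
#' @return An object of class `rar_oc` with a tidy `metrics` data frame
#'   (metric, scope, arm, mean, se) and metadata.
#' @export
operating_characteristics <- function(batch, n_cut = NULL,
                                      mature_only = FALSE) {
  if (inherits(batch, "rar_history")) batch <- list(batch)
  N <- length(batch)
  if (N < 2L) stop("need >= 2 replicates to estimate standard errors")
  scen <- batch[[1L]]$scenario
  policy <- batch[[1L]]$policy
  if (is.null(n_cut)) n_cut <- metric_cut(scen)
  K <- length(scen$subgroup_names); L <- length(scen$arm_names)
  mix <- scen$subgroup_mix
  p_true <- as.numeric(mix %*% scen$mortality)  # cohort-level true rates

  per_rep <- lapply(batch, function(h) {
    cc <- cut_cells(h, n_cut)
    out <- list(deaths = sum(cc$deaths))
    out$alloc_cohort <- colSums(cc$counts) / sum(cc$counts)
    if (L == 2L)
      out$alloc_sub <- cc$counts[, 2L] / rowSums(cc$counts)
    # risk-difference estimates, control minus experimental arm
    phat <- cc$deaths / cc$counts
    p_coh <- colSums(cc$deaths) / colSums(cc$counts)
    out$est_cohort <- p_coh[1L] - p_coh[-1L]
    if (L == 2L) out$est_sub <- phat[, 1L] - phat[, 2L]
    if (L == 2L) {
      if (policy$scope == "subgroup") {
        ks <- intersect(2:3, seq_len(K))
        out$reject_sub <- vapply(ks, function(k)
          treatment_test(h, n_cut, 2L, level = 0.05, scope = k,
                         mature_only = mature_only)$reject, TRUE)
      } else {
        out$reject_cohort <- treatment_test(h, n_cut, 2L, level = 0.05,
                                            mature_only = mature_only)$reject
      }
    } else {
      rej <- vapply(2:L, function(l)
        treatment_test(h, n_cut, l, level = 0.05, n_comparisons = L - 1L,
                       mature_only = mature_only)$reject, TRUE)
      out$reject_arms <- rej
      out$fwer <- any(rej)
    }
    out
  })

  rows <- list()
  add <- function(metric, scope, arm, x) {
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, scope = scope, arm = arm,
      mean = mean(x), se = stats::sd(x) / sqrt(N), stringsAsFactors = FALSE)
  }
  g <- function(field, i = NULL) {
    vapply(per_rep, function(r) if (is.null(i)) r[[field]] else r[[field]][i],
           numeric(1))
  }

  add("deaths", "cohort", NA_character_, g("deaths"))
  for (l in seq_len(L))
    add("alloc_prop", "cohort", scen$arm_names[l], g("alloc_cohort", l))
  if (L == 2L)
    for (k in seq_len(K))
      add("alloc_prop", scen$subgroup_names[k], scen$arm_names[2L],
          g("alloc_sub", k))
  if (L == 2L) {
    if (policy$scope == "subgroup") {
      ks <- intersect(2:3, seq_len(K))
      for (i in seq_along(ks))
        add("reject", scen$subgroup_names[ks[i]], scen$arm_names[2L],
            as.numeric(g("reject_sub", i)))
    } else {
      add("reject", "cohort", scen$arm_names[2L],
          as.numeric(g("reject_cohort")))
    }
  } else {
    for (i in seq_len(L - 1L))
      add("reject", "cohort", scen$arm_names[i + 1L],
          as.numeric(g("reject_arms", i)))
    add("fwer", "cohort", NA_character_, as.numeric(g("fwer")))
  }

  # bias and MSE of the risk-difference estimates
  for (l in 2:L) {
    est <- g("est_cohort", l - 1L)
    td <- p_true[1L] - p_true[l]
    if (abs(td) > 1e-12)
      add("bias", "cohort", scen$arm_names[l],
          rep(relative_bias(est, p_true[1L], p_true[l]), N))
    add("mse", "cohort", scen$arm_names[l], (est - td)^2)
  }
  if (L == 2L) {
    for (k in seq_len(K)) {
      est <- g("est_sub", k)
      td <- scen$mortality[k, 1L] - scen$mortality[k, 2L]
      if (abs(td) > 1e-12)
        add("bias", scen$subgroup_names[k], scen$arm_names[2L],
            rep(relative_bias(est, scen$mortality[k, 1L],
                              scen$mortality[k, 2L]), N))
      add("mse", scen$subgroup_names[k], scen$arm_names[2L], (est - td)^2)
    }
  }

  metrics <- do.call(rbind, rows)
  # bias rows carry a replicated constant; recover the real SE of the mean
  bias_rows <- metrics$metric == "bias"
  if (any(bias_rows)) {
    for (i in which(bias_rows)) {
      sc <- metrics$scope[i]; ar <- metrics$arm[i]
      if (sc == "cohort") {
        l <- match(ar, scen$arm_names)
        est <- g("est_cohort", l - 1L)
        td <- p_true[1L] - p_true[l]
      } else {
        k <- match(sc, scen$subgroup_names)
        est <- g("est_sub", k)
        td <- scen$mortality[k, 1L] - scen$mortality[k, 2L]
      }
      metrics$se[i] <- stats::sd((est - td) / td) / sqrt(N)
    }
  }
  rownames(metrics) <- NULL
  structure(list(policy = policy$name, n_cut = n_cut, n_reps = N,
                 scenario = scen, metrics = metrics),
            class = "rar_oc")
}

#' Extract one summarised metric from an `rar_oc` object
#'
#' @param oc a `rar_oc`.
#' @param metric metric name (`"deaths"`, `"alloc_prop"`, `"reject"`,
#'   `"fwer"`, `"bias"`, `"mse"`).
#' @param scope `"cohort"` or a subgroup name (default `"cohort"`).
#' @param arm arm name, or `NA` for scalar metrics.
#' @param what `"mean"` or `"se"`.
#' @return A single number (`NA` if the cell is absent).
#' @export
oc_value <- function(oc, metric, scope = "cohort", arm = NA_character_,
                     what = "mean") {
  stopifnot(inherits(oc, "rar_oc"))
  m <- oc$metrics
  sel <- m$metric == metric & m$scope == scope &
    (if (is.na(arm)) is.na(m$arm) else !is.na(m$arm) & m$arm == arm)
  if (!any(sel)) return(NA_real_)
  m[[what]][sel][1L]
}

#' @export
print.rar_oc <- function(x, digits = 3, ...) {
  cat("Operating characteristics:", x$policy, "|", x$n_reps,
      "replicates | cut at n =", x$n_cut, "\n")
  m <- x$metrics
  m$mean <- signif(m$mean, digits + 2)
  m$se <- signif(m$se, 2)
  print(m, row.names = FALSE)
  invisible(x)
}

#' @export
summary.rar_oc <- function(object, ...) {
  d <- oc_value(object, "deaths")
  cat(object$policy, ": ", round(d, 1), " deaths (",
      round(100 * d / object$n_cut, 1), "%) at n = ", object$n_cut,
      " over ", object$n_reps, " replicates\n", sep = "")
  invisible(object)
}
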