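#' Speed-accuracy performance ratio
#'
#' The behavioral criterion for group formation: the percentage of correct
#' inhibitions in the Nogo condition (100% minus the false-alarm rate)
#' divided by the mean Go hit reaction time. Larger values mean better
#' performance (fewer false alarms and/or faster responses); the unit
#' convention is percent per millisecond, under which typical values are
#' around 0.25.
#'
#' @param fa_rate false-alarm rate, proportion of Nogo trials in \[0, 1\].
#' @param mean_go_rt_ms mean correct-Go reaction time in ms (> 0).
#' @return ratio in percent/ms.
#' @examples
#' compute_ratio(0.1212, 348)  # ~0.2525
#' @export
compute_ratio <- function(fa_rate, mean_go_rt_ms) {
  if (any(!is.finite(fa_rate)) || any(fa_rate < 0) || any(fa_rate > 1))
    stop("fa_rate must lie in [0, 1]")
  if (any(!is.finite(mean_go_rt_ms)) || any(mean_go_rt_ms <= 0))
    stop("mean_go_rt_ms must be positive")
  100 * (1 - fa_rate) / mean_go_rt_ms
}

#' Assemble a behavior table with ratios
#'
#' @param behavior data.frame with columns `subject_id`, `mean_go_rt_ms`,
#'   `fa_rate`, `miss_rate` (e.g. from [generate_cohort()]).
#' @return the table with a `ratio` column appended.
#' @export
behavior_table <- function(behavior) {
  need <- c("subject_id", "mean_go_rt_ms", "fa_rate", "miss_rate")
  miss <- setdiff(need, names(behavior))
  if (length(miss)) stop("behavior table lacks columns: ",
                         paste(miss, collapse = ", "))
  behavior$ratio <- compute_ratio(behavior$fa_rate, behavior$mean_go_rt_ms)
  behavior
}

#' Flag subjects violating the performance exclusion rules
#'
#' A subject is excluded when their mean Go RT exceeds the cohort mean by
#' more than 3 cohort SDs (reason `"slow_rt"`), or when false alarms or
#' misses reach 50% (reasons `"fa_rate"` / `"miss_rate"`). Cohort RT mean
#' and SD are computed over all subjects before any exclusion.
#'
#' @param table behavior table (see [behavior_table()]).
#' @return the table with logical `excluded` and character
#'   `exclusion_reason` columns (comma-separated when several rules fire).
#' @export
apply_exclusions <- function(table) {
  if (nrow(table) == 0) stop("empty behavior table")
  mu <- mean(table$mean_go_rt_ms)
  sdv <- stats::sd(table$mean_go_rt_ms)
  if (nrow(table) < 2 || !is.finite(sdv)) sdv <- 0
  reasons <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    r <- character(0)
    if (sdv > 0 && table$mean_go_rt_ms[i] > mu + 3 * sdv) r <- c(r, "slow_rt")
    if (is.finite(table$fa_rate[i]) && table$fa_rate[i] >= 0.5)
      r <- c(r, "fa_rate")
    if (is.finite(table$miss_rate[i]) && table$miss_rate[i] >= 0.5)
      r <- c(r, "miss_rate")
    reasons[[i]] <- r
  }
  table$excluded <- lengths(reasons) > 0
  table$exclusion_reason <- vapply(reasons, paste, "", collapse = ",")
  table
}

#' Median-split group assignment
#'
#' Ranks the non-excluded subjects by their speed-accuracy ratio and assigns
#' the lower half to the "low" (bad performers) and the upper half to the
#' "high" (good performers) group. Ties at the median are broken by stable
#' subject-ID order, which guarantees equal group sizes for even N (for odd
#' N the low group receives the middle subject).
#'
#' @param table behavior table with `ratio` (and optionally `excluded`).
#' @return list of class `group_assignment`: data.frame `assignment`
#'   (`subject_id`, `ratio`, `group` factor low/high) and `split_value`
#'   (the median ratio).
#' @export
median_split <- function(table) {
  if (!"ratio" %in% names(table)) table <- behavior_table(table)
  if ("excluded" %in% names(table)) table <- table[!table$excluded, ]
  if (nrow(table) < 2) stop("need at least 2 non-excluded subjects")
  if (length(unique(table$ratio)) == 1)
    stop("degenerate split: all ratios identical")
  ord <- order(table$ratio, table$subject_id)
  n <- nrow(table)
  n_low <- ceiling(n / 2)
  group <- character(n)
  group[ord[seq_len(n_low)]] <- "low"
  group[ord[(n_low + 1):n]] <- "high"
  out <- data.frame(subject_id = table$subject_id, ratio = table$ratio,
                    group = factor(group, levels = c("low", "high")))
  structure(list(assignment = out,
                 split_value = stats::median(table$ratio)),
            class = "group_assignment")
}
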