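#' Baseline distributions of choroidal metrics by cohort
#'
#' Mean and SD of each choroidal metric at baseline for the adult and child
#' myopic cohorts (adults n = 30, aged 18-28; children n = 30, aged 8-12),
#' on the reporting scales: SFCT in um, LA/SA/TCA in 10^3 um^2, CVI and CcFD
#' in percent.
#'
#' @return data.frame with columns `group`, `metric`, `mean`, `sd`.
#' @export
default_baseline_stats <- function() {
  rbind(
    data.frame(group = "adult",
               metric = c("SFCT", "LA", "SA", "TCA", "CVI", "CcFD"),
               mean = c(267.2, 990.0, 589.4, 1579.4, 62.45, 8.41),
               sd = c(68.6, 229.3, 113.7, 331.8, 3.08, 2.20)),
    data.frame(group = "child",
               metric = c("SFCT", "LA", "SA", "TCA", "CVI", "CcFD"),
               mean = c(255.9, 919.6, 587.8, 1507.4, 61.06, 7.05),
               sd = c(52.8, 167.6, 115.4, 269.6, 2.90, 1.33)))
}

#' Near-work induced changes of choroidal metrics by cohort and duration
#'
#' Mean and SD of the post-minus-pre change of each metric after 20, 40 and
#' 60 minutes of reading at 33 cm, on the reporting scales (SFCT um,
#' LA/SA/TCA 10^3 um^2, CVI and CcFD percentage points). Cells in which no
#' significant change was observed carry a zero mean with the metric's
#' typical change SD.
#'
#' @return data.frame with columns `group`, `metric`, `visit_min`,
#'   `delta_mean`, `delta_sd`.
#' @export
default_group_effects <- function() {
  g <- expand.grid(metric = c("SFCT", "LA", "SA", "TCA", "CVI", "CcFD"),
                   visit_min = c(20L, 40L, 60L),
                   group = c("adult", "child"),
                   stringsAsFactors = FALSE)
  g$delta_mean <- 0
  typical_sd <- c(SFCT = 6.5, LA = 18.6, SA = 12.6, TCA = 24.9,
                  CVI = 0.70, CcFD = 0.75)
  g$delta_sd <- typical_sd[g$metric]
  set_cell <- function(g, grp, met, vm, m, s) {
    i <- g$group == grp & g$metric == met & g$visit_min == vm
    g$delta_mean[i] <- m
    g$delta_sd[i] <- s
    g
  }
  g <- set_cell(g, "adult", "SFCT", 20L, -5.1, 6.5)
  g <- set_cell(g, "adult", "LA", 20L, -19.2, 18.6)
  g <- set_cell(g, "adult", "SA", 20L, -8.2, 12.6)
  g <- set_cell(g, "adult", "TCA", 20L, -27.4, 24.9)
  g <- set_cell(g, "adult", "LA", 40L, -9.4, 18.3)
  g <- set_cell(g, "adult", "CVI", 40L, -0.39, 0.70)
  g <- set_cell(g, "adult", "CcFD", 40L, 0.30, 0.78)
  g <- set_cell(g, "adult", "CVI", 60L, -0.28, 0.59)
  g <- set_cell(g, "adult", "CcFD", 60L, 0.37, 0.75)
  g <- set_cell(g, "child", "CcFD", 20L, 0.55, 0.64)
  g <- set_cell(g, "child", "SA", 60L, 7.2, 13.0)
  g <- set_cell(g, "child", "TCA", 60L, 9.7, 25.3)
  g <- set_cell(g, "child", "CVI", 60L, -0.28, 0.72)
  g[, c("group", "metric", "visit_min", "delta_mean", "delta_sd")]
}

#' Parameters for the longitudinal cohort simulator
#'
#' @param n_per_group subjects per cohort (>= 2; the study used 30).
#' @param visit_durations near-work durations in minutes.
#' @param group_effects data.frame as [default_group_effects()]:
#'   per-(group, metric, duration) mean and SD of the post-pre change.
#' @param baseline_stats data.frame as [default_baseline_stats()].
#' @param al_distribution data.frame with columns `group`, `mean`, `sd`
#'   giving the axial-length distribution (mm) per cohort.
#' @param seed integer seed.
#' @return validated parameter list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_per_group = 30L,
                              visit_durations = c(20L, 40L, 60L),
                              group_effects = default_group_effects(),
                              baseline_stats = default_baseline_stats(),
                              al_distribution = data.frame(
                                group = c("adult", "child"),
                                mean = c(25.00, 24.56),
                                sd = c(1.05, 0.67)),
                              seed = 1L) {
  p <- list(n_per_group = as.integer(n_per_group),
            visit_durations = as.integer(visit_durations),
            group_effects = group_effects,
            baseline_stats = baseline_stats,
            al_distribution = al_distribution,
            seed = as.integer(seed))
  if (p$n_per_group < 2L) stopf("n_per_group must be >= 2")
  if (length(p$visit_durations) < 1L || any(p$visit_durations <= 0))
    stopf("visit_durations must be positive")
  need <- c("group", "metric", "visit_min", "delta_mean", "delta_sd")
  if (!all(need %in% names(p$group_effects)))
    stopf("group_effects must have columns %s", paste(need, collapse = ", "))
  if (any(p$group_effects$delta_sd < 0) || any(p$baseline_stats$sd < 0) ||
      any(p$al_distribution$sd < 0))
    stopf("all SDs must be >= 0")
  class(p) <- "cohort_sim_params"
  p
}

#' Simulate a two-cohort longitudinal table of choroidal metrics
#'
#' For each subject, a baseline value of every metric is drawn from the
#' cohort's baseline distribution and reused as the pre-near-work value of
#' every visit; the post value at each duration adds a change drawn from the
#' per-(group, metric, duration) change distribution. Axial length is drawn
#' once per subject.
#'
#' @param params a [cohort_sim_params()] object.
#' @return long-format data.frame with columns `subject`, `group`,
#'   `visit_min`, `phase` (pre/post), `metric`, `value`, `al_mm`.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  p <- params
  set.seed(p$seed)
  metrics <- unique(p$baseline_stats$metric)
  groups <- unique(p$baseline_stats$group)
  n <- p$n_per_group
  blocks <- list()
  for (grp in groups) {
    al_row <- p$al_distribution[p$al_distribution$group == grp, ]
    if (nrow(al_row) != 1L) stopf("al_distribution must have one row per group")
    sid <- sprintf("%s_%02d", grp, seq_len(n))
    al <- rnorm(n, al_row$mean, al_row$sd)
    for (met in metrics) {
      b <- p$baseline_stats[p$baseline_stats$group == grp &
                              p$baseline_stats$metric == met, ]
      if (nrow(b) != 1L)
        stopf("baseline_stats has no row for (%s, %s)", grp, met)
      baseline <- rnorm(n, b$mean, b$sd)
      for (vm in p$visit_durations) {
        e <- p$group_effects[p$group_effects$group == grp &
                               p$group_effects$metric == met &
                               p$group_effects$visit_min == vm, ]
        if (nrow(e) != 1L)
          stopf("group_effects has no row for (%s, %s, %d)", grp, met, vm)
        delta <- rnorm(n, e$delta_mean, e$delta_sd)
        blocks[[length(blocks) + 1L]] <- data.frame(
          subject = rep(sid, 2L), group = grp, visit_min = vm,
          phase = rep(c("pre", "post"), each = n), metric = met,
          value = c(baseline, baseline + delta), al_mm = rep(al, 2L))
      }
    }
  }
  out <- do.call(rbind, blocks)
  out <- out[order(out$group, out$subject, out$metric, out$visit_min,
                   out$phase, method = "radix"), ]
  rownames(out) <- NULL
  out
}
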