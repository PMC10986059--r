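#' Assemble and validate a pipeline run configuration
#'
#' A run configuration bundles every tunable of the simulate - quantify -
#' analyze pipeline. Sub-lists override the defaults of the corresponding
#' parameter constructors ([scene_params()], [angio_params()],
#' [cohort_sim_params()], [niblack_params()], [fd_threshold_spec()],
#' [slab_spec()]); everything is validated here so a bad field fails before
#' any stage runs. One master seed drives all stochastic stages: per-file
#' seeds are derived from it sequentially and recorded in the manifest.
#'
#' @param seed master integer seed.
#' @param out_dir output directory of the run.
#' @param n_imaging_subjects_per_group subjects per cohort for which images
#'   are simulated (the imaging track is the expensive one).
#' @param visit_durations near-work durations, minutes.
#' @param scene,angio,cohort,niblack,fd_threshold,slab named lists of
#'   overrides for the respective parameter constructors.
#' @param despeckle_radius median-filter radius applied before binarization
#'   (0 disables).
#' @param roi_width_mm submacular ROI width for choroidal metrics.
#' @param circle_diameter_mm analysis circle for the flow-deficit metric.
#' @param reference_al_mm device-assumed axial length, mm.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       out_dir = "chorovasc_run",
                       n_imaging_subjects_per_group = 2L,
                       visit_durations = c(20L, 40L, 60L),
                       scene = list(),
                       angio = list(),
                       cohort = list(),
                       niblack = list(),
                       fd_threshold = list(),
                       slab = list(),
                       despeckle_radius = 1L,
                       roi_width_mm = 6.0,
                       circle_diameter_mm = 2.5,
                       reference_al_mm = 24.385) {
  cfg <- list(seed = as.integer(seed),
              out_dir = out_dir,
              n_imaging_subjects_per_group = as.integer(n_imaging_subjects_per_group),
              visit_durations = as.integer(visit_durations),
              scene = scene, angio = angio, cohort = cohort,
              niblack = niblack, fd_threshold = fd_threshold, slab = slab,
              despeckle_radius = as.integer(despeckle_radius),
              roi_width_mm = roi_width_mm,
              circle_diameter_mm = circle_diameter_mm,
              reference_al_mm = reference_al_mm)
  if (!is_count(cfg$n_imaging_subjects_per_group))
    stopf("config field n_imaging_subjects_per_group must be a positive integer")
  if (cfg$despeckle_radius < 0) stopf("config field despeckle_radius must be >= 0")
  # validate all sub-configs up front
  do.call(scene_params, c(cfg$scene, list(reference_al_mm = cfg$reference_al_mm)))
  do.call(angio_params, c(cfg$angio, list(reference_al_mm = cfg$reference_al_mm)))
  do.call(cohort_sim_params,
          c(cfg$cohort, list(visit_durations = cfg$visit_durations)))
  do.call(niblack_params, cfg$niblack)
  do.call(fd_threshold_spec, cfg$fd_threshold)
  do.call(slab_spec, cfg$slab)
  class(cfg) <- "run_config"
  cfg
}

#' Load a pipeline configuration from a YAML file
#'
#' @param path YAML file; top-level keys are the arguments of
#'   [run_config()].
#' @return validated `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L)
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

config_hash <- function(cfg, dir) {
  path <- file.path(dir, "config_used.yaml")
  plain <- rapply(unclass(cfg), identity, how = "replace")
  yaml::write_yaml(plain, path)
  unname(tools::md5sum(path))
}

log_line <- function(run_dir, ...) {
  msg <- sprintf(...)
  cat(msg, "\n", sep = "", file = file.path(run_dir, "run.log"), append = TRUE)
  message(msg)
}

#' Simulate a full synthetic dataset
#'
#' Writes, under `<out_dir>/dataset/`: one B-scan scene per imaging subject
#' x visit x phase x meridian, one en-face angiogram per imaging subject x
#' visit x phase, the longitudinal cohort table `cohort.csv`, and
#' `manifest.json` listing every file with the seed that produced it.
#'
#' @param config a [run_config()].
#' @return invisibly, the dataset directory.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  run_dir <- config$out_dir
  ds <- file.path(run_dir, "dataset")
  dir.create(ds, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(ds)) stopf("cannot create dataset directory %s", ds)
  t0 <- Sys.time()
  hash <- config_hash(config, run_dir)

  cohort_p <- do.call(cohort_sim_params,
                      c(config$cohort,
                        list(visit_durations = config$visit_durations,
                             seed = config$seed)))
  cohort <- generate_cohort(cohort_p)
  write_csv_strict(cohort, file.path(ds, "cohort.csv"))

  baselines <- cohort_p$baseline_stats
  al_dist <- cohort_p$al_distribution
  entries <- list()
  counter <- 0L
  set.seed(config$seed)
  for (grp in unique(al_dist$group)) {
    alr <- al_dist[al_dist$group == grp, ]
    cvi_b <- baselines[baselines$group == grp & baselines$metric == "CVI", ]
    fd_b <- baselines[baselines$group == grp & baselines$metric == "CcFD", ]
    for (s in seq_len(config$n_imaging_subjects_per_group)) {
      sid <- sprintf("%s_%02d", grp, s)
      al <- round(rnorm(1, alr$mean, alr$sd), 3)
      cvi_t <- min(0.80, max(0.45, rnorm(1, cvi_b$mean / 100, cvi_b$sd / 100)))
      fd_t <- min(0.20, max(0.02, rnorm(1, fd_b$mean / 100, fd_b$sd / 100)))
      for (vm in config$visit_durations) for (ph in c("pre", "post")) {
        for (mer in c("vertical", "horizontal")) {
          counter <- counter + 1L
          sp <- do.call(scene_params,
                        c(config$scene,
                          list(target_lumen_fraction = round(cvi_t, 3),
                               al_mm = al,
                               reference_al_mm = config$reference_al_mm,
                               seed = config$seed + 1000L * counter)))
          scene <- generate_bscan_scene(sp, roi_width_mm = config$roi_width_mm)
          stem <- sprintf("scene_%s_v%02d_%s_%s", sid, vm, ph, mer)
          write_bscan_scene(scene, file.path(ds, stem))
          entries[[length(entries) + 1L]] <-
            list(file = paste0(stem, ".png"), kind = "bscan_scene",
                 subject = sid, group = grp, visit_min = vm, phase = ph,
                 meridian = mer, al_mm = al, seed = sp$seed)
        }
        counter <- counter + 1L
        ap <- do.call(angio_params,
                      c(config$angio,
                        list(target_fd_fraction = round(fd_t, 3),
                             al_mm = al,
                             reference_al_mm = config$reference_al_mm,
                             seed = config$seed + 1000L * counter)))
        angio <- generate_cc_enface(ap, circle_diameter_mm = config$circle_diameter_mm)
        stem <- sprintf("angio_%s_v%02d_%s", sid, vm, ph)
        write_cc_enface(angio, file.path(ds, stem))
        entries[[length(entries) + 1L]] <-
          list(file = paste0(stem, ".png"), kind = "cc_enface",
               subject = sid, group = grp, visit_min = vm, phase = ph,
               meridian = NA, al_mm = al, seed = ap$seed)
      }
    }
  }
  manifest <- list(config_hash = hash,
                   seed = config$seed,
                   n_files = length(entries) + 1L,
                   cohort_csv = "cohort.csv",
                   entries = entries)
  jsonlite::write_json(manifest, file.path(ds, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(run_dir, "simulate: %d files, config %s, %.1f s",
           manifest$n_files, hash, as.numeric(Sys.time() - t0, units = "secs"))
  invisible(ds)
}

#' Quantify a simulated dataset
#'
#' Runs the structural pipeline (despeckle, masked Niblack binarization,
#' submacular metrics, meridian averaging) on every B-scan of the dataset
#' and the perfusion pipeline (artifact compensation, 1.5 x SD flow-deficit
#' thresholding in the 2.5-mm circle) on every angiogram. Missing files
#' fail fast, naming the file.
#'
#' @param config a [run_config()].
#' @param dataset_dir directory written by [run_simulate()].
#' @return invisibly, the metrics directory containing
#'   `choroid_metrics.csv` and `ccfd_metrics.csv`.
#' @export
run_quantify <- function(config, dataset_dir = file.path(config$out_dir, "dataset")) {
  stopifnot(inherits(config, "run_config"))
  run_dir <- config$out_dir
  t0 <- Sys.time()
  man_path <- file.path(dataset_dir, "manifest.json")
  if (!file.exists(man_path)) stopf("missing manifest: %s", man_path)
  manifest <- jsonlite::read_json(man_path, simplifyVector = FALSE)
  nib <- do.call(niblack_params, config$niblack)
  fd <- do.call(fd_threshold_spec, config$fd_threshold)
  met_dir <- file.path(run_dir, "metrics")
  dir.create(met_dir, recursive = TRUE, showWarnings = FALSE)

  ch_rows <- list()
  fd_rows <- list()
  for (e in manifest$entries) {
    stem <- file.path(dataset_dir, sub("\\.png$", "", e$file))
    if (e$kind == "bscan_scene") {
      sc <- read_bscan_scene(stem)
      img <- despeckle(sc$image, config$despeckle_radius)
      band <- boundaries_to_mask(sc$boundaries, nrow(img))
      lum <- niblack_binarize(img, band, nib)
      m <- compute_choroid_metrics(sc$boundaries, sc$geometry, lum,
                                   roi_width_mm = config$roi_width_mm,
                                   meridian = e$meridian)
      ch_rows[[length(ch_rows) + 1L]] <- data.frame(
        subject = e$subject, visit_min = e$visit_min, phase = e$phase,
        meridian = e$meridian, SFCT_um = m$SFCT, LA_um2 = m$LA, SA_um2 = m$SA,
        TCA_um2 = m$TCA, CVI_pct = m$CVI, group = e$group, al_mm = e$al_mm)
    } else if (e$kind == "cc_enface") {
      an <- read_cc_enface(stem)
      comp <- compensate_enface(an, an$truth$reference, an$truth$projection_mask)
      r <- compute_ccfd(comp, fd, circle_diameter_mm = config$circle_diameter_mm)
      fd_rows[[length(fd_rows) + 1L]] <- data.frame(
        subject = e$subject, visit_min = e$visit_min, phase = e$phase,
        ccfd_pct = r$ccfd_pct, n_roi_px = r$n_roi_px,
        group = e$group, al_mm = e$al_mm)
    }
  }
  ch <- do.call(rbind, ch_rows)
  # meridian averages per subject x visit x phase
  key <- interaction(ch$subject, ch$visit_min, ch$phase, drop = TRUE)
  avg_rows <- lapply(split(ch, key), function(d) {
    mv <- choroid_metrics(d$SFCT_um[d$meridian == "vertical"],
                          d$LA_um2[d$meridian == "vertical"],
                          d$SA_um2[d$meridian == "vertical"], "vertical")
    mv$CVI <- d$CVI_pct[d$meridian == "vertical"]
    mh <- choroid_metrics(d$SFCT_um[d$meridian == "horizontal"],
                          d$LA_um2[d$meridian == "horizontal"],
                          d$SA_um2[d$meridian == "horizontal"], "horizontal")
    mh$CVI <- d$CVI_pct[d$meridian == "horizontal"]
    a <- average_meridians(mv, mh)
    data.frame(subject = d$subject[1], visit_min = d$visit_min[1],
               phase = d$phase[1], meridian = "averaged", SFCT_um = a$SFCT,
               LA_um2 = a$LA, SA_um2 = a$SA, TCA_um2 = a$TCA, CVI_pct = a$CVI,
               group = d$group[1], al_mm = d$al_mm[1])
  })
  ch <- rbind(ch, do.call(rbind, avg_rows))
  ord <- order(ch$subject, ch$visit_min, ch$phase, ch$meridian)
  write_csv_strict(ch[ord, ], file.path(met_dir, "choroid_metrics.csv"))
  fdt <- do.call(rbind, fd_rows)
  write_csv_strict(fdt[order(fdt$subject, fdt$visit_min, fdt$phase), ],
                   file.path(met_dir, "ccfd_metrics.csv"))
  log_line(run_dir, "quantify: %d B-scans, %d angiograms, %.1f s",
           length(ch_rows), length(fd_rows),
           as.numeric(Sys.time() - t0, units = "secs"))
  invisible(met_dir)
}

# long cohort-format table from the two imaging metrics CSVs
imaging_metrics_to_long <- function(met_dir) {
  ch <- read_csv_checked(file.path(met_dir, "choroid_metrics.csv"),
                         c("subject", "visit_min", "phase", "meridian",
                           "SFCT_um", "LA_um2", "SA_um2", "TCA_um2",
                           "CVI_pct", "group", "al_mm"))
  ch <- ch[ch$meridian == "averaged", ]
  long <- do.call(rbind, lapply(seq_len(nrow(ch)), function(i) {
    d <- ch[i, ]
    data.frame(subject = d$subject, group = d$group, visit_min = d$visit_min,
               phase = d$phase,
               metric = c("SFCT", "LA", "SA", "TCA", "CVI"),
               value = c(d$SFCT_um, d$LA_um2 / 1e3, d$SA_um2 / 1e3,
                         d$TCA_um2 / 1e3, d$CVI_pct),
               al_mm = d$al_mm)
  }))
  fd <- read_csv_checked(file.path(met_dir, "ccfd_metrics.csv"),
                         c("subject", "visit_min", "phase", "ccfd_pct",
                           "n_roi_px", "group", "al_mm"))
  rbind(long,
        data.frame(subject = fd$subject, group = fd$group,
                   visit_min = fd$visit_min, phase = fd$phase,
                   metric = "CcFD", value = fd$ccfd_pct, al_mm = fd$al_mm))
}

#' Run the cohort statistics on a metrics table
#'
#' Consumes either the simulated cohort table (`cohort.csv`) or the long
#' table assembled from the two imaging metrics CSVs, and produces: paired
#' pre/post change tests per group x metric x duration with Bonferroni
#' adjustment over durations, Shapiro-Wilk normality screening (reported,
#' never gating), a Greenhouse-Geisser-corrected repeated-measures ANOVA of
#' the percent changes over durations per metric, and the AL-adjusted
#' between-group contrast of percent changes.
#'
#' @param config a [run_config()].
#' @param metrics_path path to a long-format cohort CSV, or a metrics
#'   directory written by [run_quantify()].
#' @return invisibly, the analysis directory.
#' @export
run_analyze <- function(config,
                        metrics_path = file.path(config$out_dir, "dataset", "cohort.csv")) {
  stopifnot(inherits(config, "run_config"))
  run_dir <- config$out_dir
  t0 <- Sys.time()
  long <- if (dir.exists(metrics_path)) {
    imaging_metrics_to_long(metrics_path)
  } else {
    read_csv_checked(metrics_path, c("subject", "group", "visit_min", "phase",
                                     "metric", "value", "al_mm"))
  }
  ana_dir <- file.path(run_dir, "analysis")
  dir.create(ana_dir, recursive = TRUE, showWarnings = FALSE)

  wide <- merge(
    long[long$phase == "pre",
         c("subject", "group", "visit_min", "metric", "value", "al_mm")],
    long[long$phase == "post", c("subject", "visit_min", "metric", "value")],
    by = c("subject", "visit_min", "metric"), suffixes = c("_pre", "_post"))
  wide <- wide[complete.cases(wide), ]
  wide$delta <- wide$value_post - wide$value_pre
  wide$pct_change <- percent_change(wide$value_pre, wide$value_post)

  metrics <- unique(wide$metric)
  groups <- unique(wide$group)
  durations <- sort(unique(wide$visit_min))
  m_comp <- length(durations)

  test_rows <- list()
  for (grp in groups) for (met in metrics) for (vm in durations) {
    d <- wide[wide$group == grp & wide$metric == met & wide$visit_min == vm, ]
    if (nrow(d) < 2L) next
    tt <- paired_change_test(d$delta)
    sw <- if (nrow(d) >= 3L && sd(d$delta) > 0) shapiro.test(d$delta)$p.value else NA
    p_adj <- bonferroni_adjust(tt$p, m_comp)
    test_rows[[length(test_rows) + 1L]] <- data.frame(
      group = grp, metric = met, visit_min = vm, n = tt$n,
      mean_change = tt$mean, sd_change = tt$sd, t = tt$t,
      p_raw = tt$p, p_bonferroni = p_adj, m_comparisons = m_comp,
      shapiro_p = sw,
      direction = ifelse(tt$mean < 0, "down", "up"),
      signif = if (p_adj < 0.001) "***" else if (p_adj < 0.01) "**"
               else if (p_adj < 0.05) "*" else "ns")
  }
  tests <- do.call(rbind, test_rows)
  write_csv_strict(tests, file.path(ana_dir, "change_tests.csv"))

  anova_rows <- list()
  contrast_rows <- list()
  for (met in metrics) {
    d <- wide[wide$metric == met, ]
    if (length(durations) >= 2L) {
      w <- reshape(d[, c("subject", "visit_min", "pct_change")],
                   idvar = "subject", timevar = "visit_min", direction = "wide")
      w <- w[complete.cases(w), , drop = FALSE]
      if (nrow(w) > length(durations)) {
        rm <- rm_anova_gg(w[, -1, drop = FALSE])
        anova_rows[[length(anova_rows) + 1L]] <- data.frame(
          metric = met, F = rm$F, df1 = rm$df1, df2 = rm$df2,
          epsilon_gg = rm$epsilon_gg, p = rm$p, n = rm$n)
      }
    }
    if (length(groups) == 2L && nrow(d) >= 4L) {
      gc <- group_contrast_ancova(d$pct_change, d$group, d$al_mm,
                                  duration = d$visit_min, subject = d$subject)
      contrast_rows[[length(contrast_rows) + 1L]] <- data.frame(
        metric = met, estimate_pct = gc$estimate, se = gc$se, t = gc$t,
        p = gc$p, contrast = paste(gc$groups[2], "-", gc$groups[1]))
    }
  }
  if (length(anova_rows) > 0L)
    write_csv_strict(do.call(rbind, anova_rows),
                     file.path(ana_dir, "duration_anova.csv"))
  if (length(contrast_rows) > 0L)
    write_csv_strict(do.call(rbind, contrast_rows),
                     file.path(ana_dir, "group_contrasts.csv"))

  # plain-text trend report in the layout of a metric x duration x group grid
  rep_path <- file.path(ana_dir, "report.txt")
  con <- file(rep_path, "w")
  writeLines(sprintf("Near-work choroidal response report (seed %d)", config$seed), con)
  writeLines(sprintf("%d subjects/group (cohort table), durations: %s min",
                     length(unique(wide$subject)) %/% max(1L, length(groups)),
                     paste(durations, collapse = "/")), con)
  writeLines("", con)
  for (grp in groups) {
    writeLines(sprintf("-- %s --", grp), con)
    header <- sprintf("%-6s %s", "metric",
                      paste(sprintf("%12s", paste0(durations, " min")), collapse = " "))
    writeLines(header, con)
    for (met in metrics) {
      cells <- vapply(durations, function(vm) {
        r <- tests[tests$group == grp & tests$metric == met &
                     tests$visit_min == vm, ]
        if (nrow(r) == 0L) return(sprintf("%12s", "-"))
        mark <- if (r$signif == "ns") "" else paste0(if (r$direction == "down") "v" else "^",
                                                     r$signif)
        sprintf("%12s", sprintf("%+.2f%s", r$mean_change, mark))
      }, character(1))
      writeLines(sprintf("%-6s %s", met, paste(cells, collapse = " ")), con)
    }
    writeLines("", con)
  }
  writeLines("v/^ = significant decrease/increase after Bonferroni; * p<0.05, ** p<0.01, *** p<0.001", con)
  close(con)
  log_line(run_dir, "analyze: %d tests, %.1f s", nrow(tests),
           as.numeric(Sys.time() - t0, units = "secs"))
  invisible(ana_dir)
}

#' Run simulate, quantify and analyze end to end
#'
#' @param config a [run_config()].
#' @return invisibly, the run directory.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ds <- run_simulate(config)
  run_quantify(config, ds)
  run_analyze(config, file.path(ds, "cohort.csv"))
  invisible(config$out_dir)
}
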