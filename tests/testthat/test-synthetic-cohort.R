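test_that("zero-SD simulation reproduces the specified changes exactly", {
  eff <- default_group_effects()
  eff$delta_sd <- 0
  base <- default_baseline_stats()
  base$sd <- 0
  al <- data.frame(group = c("adult", "child"), mean = c(25, 24.56), sd = c(0, 0))
  co <- generate_cohort(cohort_sim_params(n_per_group = 3, group_effects = eff,
                                          baseline_stats = base,
                                          al_distribution = al, seed = 1))
  pre <- co[co$phase == "pre", ]
  post <- co[co$phase == "post", ]
  key <- c("subject", "metric", "visit_min")
  m <- merge(pre, post, by = key, suffixes = c("_pre", "_post"))
  m <- merge(m, eff, by.x = c("group_pre", "metric", "visit_min"),
             by.y = c("group", "metric", "visit_min"))
  expect_equal(m$value_post - m$value_pre, m$delta_mean, tolerance = 1e-12)
  expect_equal(m$value_pre,
               base$mean[match(paste(m$group_pre, m$metric),
                               paste(base$group, base$metric))])
})

test_that("the cohort table is seed-deterministic and well-formed", {
  a <- generate_cohort(cohort_sim_params(n_per_group = 5, seed = 11))
  b <- generate_cohort(cohort_sim_params(n_per_group = 5, seed = 11))
  expect_identical(a, b)
  expect_setequal(names(a), c("subject", "group", "visit_min", "phase",
                              "metric", "value", "al_mm"))
  # exactly one pre and one post per subject x visit x metric
  tab <- table(a$subject, a$visit_min, a$metric, a$phase)
  expect_true(all(tab == 1L))
})

test_that("large-sample mean change converges to the specified effect", {
  eff <- expand.grid(metric = "SFCT", visit_min = 20L,
                     group = c("adult", "child"), stringsAsFactors = FALSE)
  eff$delta_mean <- c(-5.1, 0)
  eff$delta_sd <- 6.5
  base <- default_baseline_stats()
  base <- base[base$metric == "SFCT", ]
  co <- generate_cohort(cohort_sim_params(
    n_per_group = 10000, visit_durations = 20L, group_effects = eff,
    baseline_stats = base, seed = 4))
  d <- co[co$group == "adult", ]
  deltas <- d$value[d$phase == "post"] - d$value[d$phase == "pre"]
  expect_lt(abs(mean(deltas) - (-5.1)), 0.2)
})

test_that("invalid cohort parameters are rejected", {
  expect_error(cohort_sim_params(n_per_group = 1), ">= 2")
  eff <- default_group_effects()
  eff$delta_sd[1] <- -1
  expect_error(cohort_sim_params(group_effects = eff), "SDs")
  expect_error(generate_cohort(cohort_sim_params(visit_durations = 35L)),
               "group_effects has no row")
})
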