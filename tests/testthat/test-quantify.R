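test_that("median_fluorescence matches definition and sort-based oracle", {
  expect_equal(median_fluorescence(c(5, 5, 5)), 5)
  expect_equal(median_fluorescence(c(1, 2, 3, 10)), 2.5)
  withr::local_seed(11)
  v <- stats::runif(10001)
  expect_equal(median_fluorescence(v), oracle_median(v))
  expect_error(median_fluorescence(numeric(0)), class = "lucflow_contract_error")
})

test_that("percentile_84 uses linear interpolation between order statistics", {
  expect_equal(percentile_84(rep(3.7, 10)), 3.7)
  expect_equal(percentile_84(c(0, 100)), 84)
  withr::local_seed(12)
  v <- stats::rnorm(5000)
  expect_equal(percentile_84(v), oracle_p84(v))
  expect_error(percentile_84(5), class = "lucflow_contract_error")
})

test_that("separation_index matches the defining formula", {
  expect_equal(separation_index(100, 100, 200), 0)
  expect_equal(separation_index(1000, 100, 200), 8.955)
  expect_equal(separation_index(10000, 1000, 2000),
               separation_index(1000, 100, 200))  # scale invariance
  expect_error(separation_index(10, 5, 5),
               class = "lucflow_degenerate_spread_error")
})

test_that("fold_change_scheme_A implements the background-subtracted ratio", {
  expect_equal(fold_change_scheme_A(500, 100, 500, 100)$L_sample, 1)
  expect_equal(fold_change_scheme_A(500, 100, 100, 100)$L_sample, 0)
  fc <- fold_change_scheme_A(500, 100, 900, 100)
  expect_equal(fc$L_sample, 2)
  expect_equal(fc$scheme, "A_puer_spike")
  expect_true(is.na(fc$b_sample))

  expect_error(fold_change_scheme_A(100, 100, 500, 100),
               class = "lucflow_reference_background_error")
  expect_warning(neg <- fold_change_scheme_A(500, 100, 80, 100),
                 class = "lucflow_negative_signal_warning")
  expect_true(neg$negative)
  expect_equal(neg$L_sample, -0.05)   # flagged, not clipped
})

test_that("fold_change_scheme_B estimates background and cancels tube factors", {
  fc <- fold_change_scheme_B(400, 400, 100, 400)
  expect_equal(fc$b_sample, 100)
  expect_equal(fc$L_sample, 1)

  fc2 <- fold_change_scheme_B(1600, 800, 100, 400)
  expect_equal(fc2$b_sample, 200)
  expect_equal(fc2$L_sample, 1400 / 600)

  fc3 <- fold_change_scheme_B(1600 * 3.7, 800 * 3.7, 100, 400)
  expect_equal(fc3$L_sample, fc2$L_sample)

  expect_error(fold_change_scheme_B(100, 100, 400, 400),
               class = "lucflow_degenerate_spike_error")
  expect_error(fold_change_scheme_B(400, 400, 100, 0),
               class = "lucflow_contract_error")
})

test_that("coefficient_of_variation uses the n-1 sample SD in percent", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 2, 3)), 50)
  expect_equal(coefficient_of_variation(7.3 * c(1, 2, 3)), 50)
  expect_error(coefficient_of_variation(5), class = "lucflow_contract_error")
  expect_error(coefficient_of_variation(c(-1, 1)), class = "lucflow_contract_error")
})

test_that("analyze_tube recovers the live-sample Luciferase median", {
  sim <- simulate_tube(synthetic_tube_spec(n_events = 20000,
                                           expression_level = 3000, seed = 21))
  s <- analyze_tube(sim$table)
  true_median <- 100 + 3000   # autofluorescence + expression
  expect_lt(abs(s$f_sample - true_median) / true_median, 0.02)
  expect_gte(s$p84_sample, s$f_sample)
  expect_gte(s$p84_control, s$f_control)

  g <- gate_tube(sim$table, gate_config())
  live_singlets <- sum(g$counts[c("control_spike", "sample")])
  expect_equal(s$n_sample + s$n_control, live_singlets)
})

test_that("analyze_tube propagates a degenerate spike split", {
  sim <- simulate_tube(synthetic_tube_spec(n_events = 3000, frac_spike = 0,
                                           seed = 22))
  expect_error(suppressWarnings(analyze_tube(sim$table)),
               class = "lucflow_degenerate_split_error")
})

test_that("analyze_tube attaches low-count warnings", {
  sim <- simulate_tube(synthetic_tube_spec(n_events = 400, seed = 23))
  expect_warning(s <- analyze_tube(sim$table),
                 class = "lucflow_low_count_warning")
  expect_true(length(s$warnings) > 0)
})

test_that("precision_report computes hand-checkable CVs and ranges", {
  rec <- data.frame(construct = rep(c("A", "B"), each = 3),
                    replicate = rep(1:3, 2),
                    fold_change = c(1.0, 1.1, 0.9, 2.0, 2.2, 1.8))
  rep <- precision_report(rec)
  expect_equal(rep$per_construct$cv, c(10, 10), tolerance = 1e-12)
  expect_equal(rep$ranges$min_cv, 10)
  expect_equal(rep$ranges$max_cv, 10)

  one <- data.frame(construct = "A", replicate = 1, fold_change = 2)
  expect_warning(empty <- precision_report(one),
                 class = "lucflow_skipped_group_warning")
  expect_equal(nrow(empty$per_construct), 0)
})

test_that("precision_report is invariant to per-construct scaling", {
  withr::local_seed(31)
  rec <- data.frame(construct = rep(c("A", "B"), each = 4), replicate = rep(1:4, 2),
                    mfi = stats::rlnorm(8), si = stats::rlnorm(8),
                    fold_change = stats::rlnorm(8))
  scaled <- rec
  for (col in c("mfi", "si", "fold_change"))
    scaled[[col]] <- scaled[[col]] * ifelse(scaled$construct == "A", 3, 0.2)
  expect_equal(precision_report(scaled)$per_construct$cv,
               precision_report(rec)$per_construct$cv)
})

test_that("compare_to_bulk returns r^2 over matched construct/time means", {
  bulk <- data.frame(construct = rep(c("P", "X"), c(3, 2)),
                     replicate = 1, time_hours = c(-48, 0, 24, 0, 24),
                     luminescence = c(100, 300, 200, 500, 400))
  flow <- data.frame(construct = bulk$construct, time_hours = bulk$time_hours,
                     fold_change = 2 * bulk$luminescence / 100)
  r2 <- compare_to_bulk(bulk, flow, reference_construct = "P")
  expect_equal(as.numeric(r2), 1)
  expect_equal(nrow(attr(r2, "points")), 5)

  const <- bulk; const$luminescence <- 100
  expect_error(compare_to_bulk(const, flow, reference_construct = "P"),
               class = "lucflow_undefined_correlation_error")
  expect_error(compare_to_bulk(bulk[1:2, ], flow[1:2, ],
                               reference_construct = "P"),
               class = "lucflow_contract_error")
})

test_that("compare_to_bulk matches the covariance-formula oracle", {
  withr::local_seed(32)
  n <- 10
  bulk <- data.frame(construct = paste0("c", 1:n), replicate = 1,
                     time_hours = 0, luminescence = stats::rlnorm(n, 5, 1))
  bulk <- rbind(bulk, data.frame(construct = "Promoter", replicate = 1,
                                 time_hours = -48, luminescence = 100))
  flow <- data.frame(construct = c(paste0("c", 1:n), "Promoter"),
                     time_hours = c(rep(0, n), -48),
                     fold_change = c(stats::rlnorm(n, 1, 0.5), 1))
  r2 <- compare_to_bulk(bulk, flow)
  pts <- attr(r2, "points")
  expect_equal(as.numeric(r2), oracle_r2(pts$bulk_fold, pts$flow_fold))
})
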