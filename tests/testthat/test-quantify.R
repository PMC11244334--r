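test_that("gating applies the strictly-greater convention", {
  rec <- data.frame(ratio = c(10, 1, 0.5, 2),
                    integrated_marker = c(0, 1e5, 2e5, 5))
  g <- gate_cells(rec, gate_config(1, 1e5))
  expect_equal(g$is_gfp_pos, c(TRUE, FALSE, FALSE, TRUE))  # tie -> negative
  expect_equal(g$is_marker_pos, c(FALSE, FALSE, TRUE, FALSE))

  rec$integrated_marker <- 0
  g0 <- gate_cells(rec, gate_config(1, 1e5))
  expect_false(any(g0$is_marker_pos))

  expect_error(gate_cells(data.frame(ratio = 1), gate_config(1, 1)),
               "integrated_marker")
  expect_error(gate_config(-1, 5), "gfp_ratio_cutoff")
})

test_that("gating is monotone in the ratio cutoff", {
  cells <- simulate_cell_table(gating_config(n_cells = 400, seed = 17))
  rec <- records_from_truth(cells)
  n_pos <- vapply(c(0.1, 0.5, 1, 5, 50), function(cut) {
    sum(gate_cells(rec, gate_config(cut, 1e5))$is_gfp_pos)
  }, numeric(1))
  expect_true(all(diff(n_pos) <= 0))
})

test_that("gating on well-separated mixtures recovers ground truth", {
  cells <- simulate_cell_table(gating_config(n_cells = 1000, seed = 3))
  rec <- records_from_truth(cells)
  g <- gate_cells(rec, default_gate())
  acc_gfp <- mean(g$is_gfp_pos == cells$is_gfp_pos)
  acc_marker <- mean(g$is_marker_pos == cells$is_marker_pos)
  expect_gte(acc_gfp, 0.99)
  expect_gte(acc_marker, 0.99)
})

test_that("suggested cutoffs fall in the valley between the two modes", {
  vals <- c(rep(0.1, 200), rep(10, 300))
  for (method in c("auto_log_valley", "auto_otsu")) {
    cut <- suggest_cutoff(vals, method)
    expect_gt(cut, 0.1)
    expect_lt(cut, 10)
  }
  expect_error(suggest_cutoff(rep(2, 50)), "manual cutoff")
  expect_error(suggest_cutoff(c(-1, 2)), "positive")
})

test_that("valley cutoff is near-optimal for a log-normal mixture", {
  set.seed(42)
  n <- 2000
  lo <- rlnorm(n / 2, log(0.1), 0.5)
  hi <- rlnorm(n / 2, log(10), 0.5)
  vals <- c(lo, hi)
  truth <- rep(c(FALSE, TRUE), each = n / 2)
  cut <- suggest_cutoff(vals, "auto_log_valley")
  # analytic equal-likelihood boundary: equal weights and sdlog -> midpoint
  # of the meanlogs, i.e. sqrt(0.1 * 10) = 1
  boundary <- sqrt(0.1 * 10)
  err_at <- function(cutoff) mean((vals > cutoff) != truth)
  expect_lte(err_at(cut), err_at(boundary) + 0.02)
})

test_that("well summaries reproduce count arithmetic and flag undefined fractions", {
  # 27 GFP+ of 440; 8 of 204 GFP- cells marker+; 0 of 27 GFP+ marker+
  rec <- data.frame(
    well = "W01", timepoint = 0, condition = "control",
    ratio = c(rep(10, 27), rep(0.1, 413)),
    integrated_marker = c(rep(0, 27), rep(2e5, 8), rep(0, 405))
  )
  g <- gate_cells(rec, gate_config(1, 1e5))
  s <- summarize_wells(g)
  expect_equal(s$n_total, 440)
  expect_equal(s$n_gfp_pos, 27)
  expect_equal(s$pct_gfp_pos, 100 * 27 / 440)
  expect_equal(s$n_marker_pos_in_gfp_neg, 8)
  expect_equal(s$pct_marker_in_gfp_neg, 100 * 8 / 413)
  expect_equal(s$pct_marker_in_gfp_pos, 0)
  # counts stay consistent and fractions recompute from counts
  expect_equal(s$n_gfp_pos + s$n_gfp_neg, s$n_total)

  # no GFP+ cells: the within-GFP+ fraction is undefined, not zero
  rec2 <- data.frame(well = "W02", timepoint = 0, condition = "control",
                     ratio = rep(0.1, 204),
                     integrated_marker = c(rep(2e5, 8), rep(0, 196)))
  s2 <- summarize_wells(gate_cells(rec2, gate_config(1, 1e5)))
  expect_true(is.na(s2$pct_marker_in_gfp_pos))
  expect_equal(s2$pct_marker_in_gfp_neg, 100 * 8 / 204)

  expect_error(summarize_wells(rec), "gated")
})

test_that("mean_sem matches hand arithmetic and flags n = 1", {
  expect_equal(mean_sem(c(5, 5, 5)), c(mean = 5, sem = 0, n = 3))
  ms <- mean_sem(c(1, 2, 3))
  expect_equal(ms[["mean"]], 2)
  expect_equal(ms[["sem"]], 1 / sqrt(3), tolerance = 1e-12)
  one <- mean_sem(7)
  expect_equal(one[["mean"]], 7)
  expect_true(is.na(one[["sem"]]))
  expect_error(mean_sem(numeric(0)), "at least one")
})

test_that("pooled t test matches the explicit formula oracle", {
  cases <- list(
    list(a = c(1, 2, 3), b = c(2, 3, 4)),
    list(a = c(5.7, 6.1, 4.9), b = c(94.3, 93.9, 95.1)),
    list(a = rnorm(8, 0, 1), b = rnorm(5, 1, 2))
  )
  set.seed(7)
  for (cs in cases) {
    got <- two_sample_t_test(cs$a, cs$b)
    want <- oracle_pooled_t(cs$a, cs$b)
    expect_equal(got$t_statistic, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
})

test_that("t test handles identical and degenerate groups as defined", {
  same <- two_sample_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t_statistic, 0)
  expect_equal(same$p_value, 1)

  flat <- two_sample_t_test(c(2, 2, 2), c(2, 2, 2))
  expect_equal(flat$t_statistic, 0)
  expect_equal(flat$p_value, 1)

  apart <- two_sample_t_test(c(2, 2), c(5, 5))
  expect_equal(apart$p_value, 0)
  expect_true(is.infinite(apart$t_statistic))
  expect_match(apart$note, "unequal means")

  expect_error(two_sample_t_test(1, c(1, 2)), "at least 2")

  # Welch option reproduces stats::t.test's Welch df
  w <- two_sample_t_test(c(1, 2, 3, 9), c(2, 3, 4), var_equal = FALSE)
  ref <- t.test(c(1, 2, 3, 9), c(2, 3, 4))
  expect_equal(w$df, unname(ref$parameter))
})

test_that("small-sample t test p agrees with an exhaustive permutation test", {
  a <- c(1.2, 2.1, 3.3)
  b <- c(2.8, 3.9, 4.1)
  got <- two_sample_t_test(a, b)
  pool <- c(a, b)
  combs <- combn(6, 3)
  t_abs <- apply(combs, 2, function(ix) {
    abs(oracle_pooled_t(pool[ix], pool[-ix])$t)
  })
  p_perm <- mean(t_abs >= abs(got$t_statistic) - 1e-12)
  # permutation p and t p agree to within the resolution of 20 permutations
  expect_lt(abs(p_perm - got$p_value), 0.1)
})

test_that("time-course table reduces to mean_sem over replicate wells", {
  s <- data.frame(
    well = c("A", "B", "C"), timepoint = 24, condition = "control",
    pct_marker_in_gfp_pos = c(NA, 2, 4),
    pct_marker_in_gfp_neg = c(10, 20, 30)
  )
  tc <- timecourse_table(s)
  neg <- tc[tc$population == "gfp_neg", ]
  expect_equal(neg$n_wells, 3)
  expect_equal(neg$mean_pct_marker_pos, 20)
  expect_equal(neg$sem_pct_marker_pos, sd(c(10, 20, 30)) / sqrt(3))
  pos <- tc[tc$population == "gfp_pos", ]
  expect_equal(pos$n_wells, 2)  # NA well dropped, not counted

  # sorted by timepoint; empty input gives an empty table
  s2 <- rbind(s, within(s, timepoint <- 0))
  expect_equal(timecourse_table(s2)$timepoint[1], 0)
  expect_equal(nrow(timecourse_table(s[0, ])), 0)
})

test_that("recovered time profile tracks the configured marker probabilities", {
  profile <- data.frame(timepoint = c(0, 24, 48), p = c(0.05, 0.5, 0.25))
  summaries <- do.call(rbind, lapply(seq_len(nrow(profile)), function(i) {
    do.call(rbind, lapply(1:3, function(wi) {
      cfg <- gating_config(n_cells = 300, seed = 1000 + 10 * i + wi,
                           frac_gfp_pos = 0.06,
                           p_marker_pos_given_gfp_neg = profile$p[i])
      rec <- records_from_truth(simulate_cell_table(cfg))
      rec$well <- paste0("W", wi)
      rec$timepoint <- profile$timepoint[i]
      summarize_wells(gate_cells(rec, default_gate()))
    }))
  }))
  tc <- timecourse_table(summaries)
  neg <- tc[tc$population == "gfp_neg", ]
  expect_equal(neg$timepoint, profile$timepoint)
  dev <- abs(neg$mean_pct_marker_pos - 100 * profile$p)
  expect_true(all(dev <= pmax(3 * neg$sem_pct_marker_pos, 2)))
})
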