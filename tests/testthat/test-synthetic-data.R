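test_that("nucleus placement respects count, spacing and determinism", {
  cfg <- simulation_config(n_cells = 0)
  expect_equal(nrow(place_nuclei(cfg)), 0)

  cfg <- simulation_config(image_height = 512, image_width = 512,
                           n_cells = 10, min_center_distance = 40, seed = 9)
  pl <- place_nuclei(cfg)
  expect_equal(nrow(pl), 10)
  d <- as.matrix(dist(pl[, c("x", "y")]))
  expect_true(all(d[upper.tri(d)] >= 40))
  expect_true(all(pl$x > pl$radius & pl$x < 512 - pl$radius + 1))

  expect_identical(place_nuclei(cfg), place_nuclei(cfg))

  # impossible density errors out with an informative message
  dense <- simulation_config(image_height = 64, image_width = 64,
                             n_cells = 60, min_center_distance = 30)
  expect_error(place_nuclei(dense), "placement failed")
})

test_that("clumped placement produces close pairs", {
  cfg <- simulation_config(n_cells = 20, clump_frac = 0.3,
                           min_center_distance = 40, seed = 5)
  pl <- place_nuclei(cfg)
  d <- as.matrix(dist(pl[, c("x", "y")]))
  diag(d) <- Inf
  expect_true(any(d < 40))  # some pairs violate the spacing on purpose
})

test_that("simulated fields are deterministic and conserve the population", {
  cfg <- simulation_config(n_cells = 25, seed = 21,
                           noise = list(read_sd = 40, poisson = TRUE))
  a <- simulate_field(cfg)
  b <- simulate_field(cfg)
  expect_identical(a$field$channels, b$field$channels)
  expect_identical(a$truth, b$truth)

  cells <- a$truth$cells
  expect_equal(sum(cells$is_gfp_pos) + sum(!cells$is_gfp_pos), 25)
  expect_equal(anyDuplicated(cells$cell_id), 0)

  # label raster and cell table agree exactly
  expect_setequal(setdiff(unique(as.vector(a$truth$labels)), 0L),
                  cells$cell_id)
  vmax <- 2^cfg$bit_depth - 1
  for (ch in a$field$channels) {
    expect_true(all(ch >= 0 & ch <= vmax))
  }
})

test_that("an empty field is pure background", {
  cfg <- noiseless_config(n_cells = 0)
  sim <- simulate_field(cfg)
  expect_true(all(sim$field$channels$nuclear == 200))
  expect_true(all(sim$field$channels$gfp == 120))
  expect_equal(nrow(sim$truth$cells), 0)
  expect_true(all(sim$truth$labels == 0L))
})

test_that("noiseless rendering is exact inside every nucleus", {
  cfg <- noiseless_config(n_cells = 10, gfp_fg_pos = 200, seed = 4,
                          frac_gfp_pos = 1)  # all cells GFP+
  sim <- simulate_field(cfg)
  for (id in sim$truth$cells$cell_id) {
    mask <- sim$truth$labels == id
    expect_identical(mean(sim$field$channels$gfp[mask]), 200)
    expect_identical(mean(sim$field$channels$nuclear[mask]), 3000)
  }
  # background untouched outside nuclei
  expect_true(all(sim$field$channels$gfp[sim$truth$labels == 0] == 120))
})

test_that("GFP+ assignment follows the configured binomial fraction", {
  cfg <- gating_config(n_cells = 1000, seed = 33, frac_gfp_pos = 0.5)
  cells <- simulate_cell_table(cfg)
  expect_lt(abs(sum(cells$is_gfp_pos) - 500), 3 * sqrt(1000 * 0.25))
})

test_that("label raster regions are disks assigned to the nearest centre", {
  cfg <- noiseless_config(n_cells = 8, seed = 13)
  sim <- simulate_field(cfg)
  cells <- sim$truth$cells
  for (i in seq_len(nrow(cells))) {
    idx <- which(sim$truth$labels == cells$cell_id[i])
    rows <- (idx - 1) %% nrow(sim$truth$labels) + 1
    cols <- (idx - 1) %/% nrow(sim$truth$labels) + 1
    d <- sqrt((cols - cells$x[i])^2 + (rows - cells$y[i])^2)
    expect_true(all(d <= cells$radius[i]))
    # area close to the analytic disk area (pixelation error only)
    expect_lt(abs(length(idx) - pi * cells$radius[i]^2),
              0.15 * pi * cells$radius[i]^2 + 10)
  }
})

test_that("membrane mode keeps reporter signal off the nucleus", {
  cfg <- noiseless_config(n_cells = 6, seed = 8,
                          reporter_mode = "membrane", frac_gfp_pos = 1)
  sim <- simulate_field(cfg)
  on_nuc <- sim$truth$labels > 0
  expect_true(all(sim$field$channels$gfp[on_nuc] == 120))  # background only
  expect_true(any(sim$field$channels$gfp[!on_nuc] > 120))  # ring exists
})

test_that("experiment simulation propagates metadata and forbids duplicates", {
  base <- simulation_config(n_cells = 5, image_height = 128,
                            image_width = 128, min_center_distance = 15)
  design <- list()
  for (tp in c(0, 24, 48, 72, 96, 120)) {
    for (cond in c("control", "tgfb")) {
      design[[length(design) + 1]] <- list(
        well = paste0("W", tp, cond), timepoint = tp, condition = cond,
        config = base)
    }
  }
  sims <- simulate_experiment(design)
  expect_length(sims, 12)
  md <- t(vapply(sims, function(s) {
    c(s$field$metadata$well, s$field$metadata$condition)
  }, character(2)))
  expect_equal(sort(unique(md[, 2])), c("control", "tgfb"))
  expect_equal(anyDuplicated(md[, 1]), 0)

  expect_identical(simulate_experiment(list()), list())

  dup <- list(list(well = "A", timepoint = 0, condition = "c", config = base),
              list(well = "A", timepoint = 0, condition = "d", config = base))
  expect_error(simulate_experiment(dup), "duplicate")
})

test_that("a configured marker profile over time is recovered in ground truth", {
  profile <- c(0.1, 0.5, 0.2)  # rise then fall
  design <- lapply(seq_along(profile), function(i) {
    cfg <- gating_config(n_cells = 500, seed = 100 + i, frac_gfp_pos = 0,
                         p_marker_pos_given_gfp_neg = profile[i])
    list(well = paste0("W", i), timepoint = 24 * (i - 1),
         condition = "control", config = cfg)
  })
  # ground truth only; no rendering needed
  fracs <- vapply(seq_along(design), function(i) {
    cells <- simulate_cell_table(design[[i]]$config)
    mean(cells$is_marker_pos)
  }, numeric(1))
  binom_tol <- 3 * sqrt(profile * (1 - profile) / 500)
  expect_true(all(abs(fracs - profile) <= binom_tol))
  expect_gt(fracs[2], fracs[1])
  expect_gt(fracs[2], fracs[3])
})

test_that("config validation names the offending field", {
  expect_error(simulation_config(frac_gfp_pos = 1.5), "frac_gfp_pos")
  expect_error(simulation_config(n_cells = -1), "n_cells")
  expect_error(simulation_config(bit_depth = 12), "bit_depth")
  expect_error(simulation_config(nucleus_radius_mean = 0),
               "nucleus_radius_mean")
})
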