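# shared fixtures: all synthetic, generated at test time

# noiseless config: every foreground renders its configured level exactly
noiseless_config <- function(n_cells = 10, seed = 4, gfp_fg_pos = 200,
                             ...) {
  simulation_config(
    n_cells = n_cells, seed = seed,
    channels = list(
      nuclear = list(background = 200, fg = 3000, sdlog = 0),
      gfp = list(background = 120, fg_pos = gfp_fg_pos, fg_neg = 60,
                 sdlog = 0),
      rfp = list(background = 120, fg_pos = 60, fg_neg = 2500, sdlog = 0),
      marker = list(background = 100, fg_pos = 4000, fg_neg = 30, sdlog = 0)
    ),
    noise = list(read_sd = 0, poisson = FALSE),
    ...
  )
}

# cell-level records built from ground truth (no rendering/segmentation):
# the gating module's contract only needs ratio and integrated_marker
records_from_truth <- function(cells) {
  eps <- 1e-6 * max(c(cells$fg_gfp, cells$fg_rfp))
  area <- pi * cells$radius^2
  data.frame(
    nucleus_id = cells$cell_id,
    well = "W01", field_id = 1L, timepoint = 0, condition = "control",
    area = area, x = cells$x, y = cells$y,
    mean_gfp = cells$fg_gfp, mean_rfp = cells$fg_rfp,
    integrated_marker = cells$fg_marker * area,
    ratio = (cells$fg_gfp + eps) / (cells$fg_rfp + eps)
  )
}

# config for gating studies at large n: placement only constrains centres
# loosely since no pixels are rendered
gating_config <- function(n_cells = 1000, seed = 1, frac_gfp_pos = 0.06,
                          ...) {
  simulation_config(
    image_height = 1024, image_width = 1024, n_cells = n_cells,
    min_center_distance = 10, frac_gfp_pos = frac_gfp_pos, seed = seed, ...
  )
}

default_gate <- function() gate_config(gfp_ratio_cutoff = 1,
                                       marker_cutoff = 1e5)

# independent popmodel oracle: spreadsheet-style iteration written without
# reference to the package implementation
oracle_iterate_composition <- function(adipocyte0, other0, survival,
                                       division_time, n_days) {
  a <- adipocyte0; o <- other0
  for (i in seq_len(n_days)) {
    a <- a * survival
    o <- o * survival * (1 + 24 / division_time)
  }
  100 * o / (o + a)
}

# independent pooled-variance Student t oracle
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df))
}
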