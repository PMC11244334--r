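#' Configuration for a synthetic reporter-microscopy field
#'
#' Describes one simulated field of an *Adipoq:Cre* reporter culture: nuclear
#' counterstain (Hoechst-like), GFP and RFP (tdTomato) reporter channels, and
#' one proliferation-marker channel (EdU- or phospho-H3-like). A minority of
#' cells is adipocyte-derived (GFP-positive); marker positivity is drawn
#' conditionally on GFP status, so a "proliferation restricted to
#' non-adipocyte cells" population is the default.
#'
#' Nuclei are disks with normally distributed radii, placed by dart throwing
#' with a minimum centre distance (a configurable fraction of placements may
#' deliberately violate it, to exercise watershed splitting). Foreground
#' intensities are log-normal per population: each channel entry gives the
#' median foreground level(s) on the linear scale and a log-scale standard
#' deviation `sdlog` (0 means every cell renders the level exactly, which is
#' what the noiseless-fidelity tests rely on). Rendered values replace the
#' background inside a nucleus, then Gaussian read noise (and optionally
#' Poisson shot noise) is added and values are clipped to
#' `[0, 2^bit_depth - 1]`.
#'
#' @param image_height,image_width Field size in pixels.
#' @param n_cells Number of cells to place (>= 0).
#' @param nucleus_radius_mean,nucleus_radius_sd Nuclear radius distribution,
#'   pixels.
#' @param min_center_distance Minimum pairwise centre distance, pixels.
#' @param clump_frac Fraction of cells placed deliberately close to an
#'   existing nucleus (centre distance about 1.5 radii), violating
#'   `min_center_distance`. Default 0.
#' @param frac_gfp_pos Probability a cell is adipocyte-derived (GFP+).
#' @param p_marker_pos_given_gfp_pos,p_marker_pos_given_gfp_neg Conditional
#'   probabilities of marker positivity by GFP status.
#' @param channels Per-channel intensity model; see Defaults. `nuclear` and
#'   `marker` carry `background`, `fg` (or `fg_pos`/`fg_neg`), `sdlog`;
#'   `gfp`/`rfp` carry `background`, `fg_pos`, `fg_neg`, `sdlog`, where
#'   "pos"/"neg" refer to the GFP (for marker: marker) status of the cell.
#' @param noise List with `read_sd` (Gaussian read-noise sd, intensity units)
#'   and `poisson` (logical; Poisson shot noise on the pre-noise intensity).
#' @param reporter_mode `"nuclear_ratio"` (nT/nG: nuclear GFP vs nuclear
#'   tdTomato) or `"membrane"` (mT/mG: a ~2 px fluorescent ring at the cell
#'   boundary, nuclei dark in the reporter channels).
#' @param membrane_radius_factor Cell (ring) radius as a multiple of the
#'   nuclear radius, membrane mode only.
#' @param bit_depth 8 or 16.
#' @param seed Integer seed; identical configurations give bit-identical
#'   fields and ground truth.
#'
#' @return Object of class `simulation_config`.
#' @export
#' @examples
#' cfg <- simulation_config(n_cells = 20, seed = 7)
simulation_config <- function(image_height = 512, image_width = 512,
                              n_cells = 80,
                              nucleus_radius_mean = 8, nucleus_radius_sd = 1,
                              min_center_distance = 28, clump_frac = 0,
                              frac_gfp_pos = 0.06,
                              p_marker_pos_given_gfp_pos = 0,
                              p_marker_pos_given_gfp_neg = 0.04,
                              channels = list(
                                nuclear = list(background = 200, fg = 3000,
                                               sdlog = 0.15),
                                gfp = list(background = 120, fg_pos = 2500,
                                           fg_neg = 60, sdlog = 0.25),
                                rfp = list(background = 120, fg_pos = 60,
                                           fg_neg = 2500, sdlog = 0.25),
                                marker = list(background = 100, fg_pos = 4000,
                                              fg_neg = 30, sdlog = 0.30)
                              ),
                              noise = list(read_sd = 40, poisson = FALSE),
                              reporter_mode = c("nuclear_ratio", "membrane"),
                              membrane_radius_factor = 2.2,
                              bit_depth = 16, seed = 1L) {
  reporter_mode <- match.arg(reporter_mode)
  cfg <- list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    n_cells = as.integer(n_cells),
    nucleus_radius_mean = nucleus_radius_mean,
    nucleus_radius_sd = nucleus_radius_sd,
    min_center_distance = min_center_distance,
    clump_frac = clump_frac,
    frac_gfp_pos = frac_gfp_pos,
    p_marker_pos_given_gfp_pos = p_marker_pos_given_gfp_pos,
    p_marker_pos_given_gfp_neg = p_marker_pos_given_gfp_neg,
    channels = channels,
    noise = noise,
    reporter_mode = reporter_mode,
    membrane_radius_factor = membrane_radius_factor,
    bit_depth = as.integer(bit_depth),
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  bad <- character(0)
  frac_ok <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  if (!(cfg$image_height >= 1 && cfg$image_width >= 1)) {
    bad <- c(bad, "image_height/image_width")
  }
  if (is.na(cfg$n_cells) || cfg$n_cells < 0) bad <- c(bad, "n_cells")
  if (!(cfg$nucleus_radius_mean > 0)) bad <- c(bad, "nucleus_radius_mean")
  if (!(cfg$nucleus_radius_sd >= 0)) bad <- c(bad, "nucleus_radius_sd")
  if (!(cfg$min_center_distance >= 0)) bad <- c(bad, "min_center_distance")
  if (!frac_ok(cfg$clump_frac)) bad <- c(bad, "clump_frac")
  if (!frac_ok(cfg$frac_gfp_pos)) bad <- c(bad, "frac_gfp_pos")
  if (!frac_ok(cfg$p_marker_pos_given_gfp_pos)) {
    bad <- c(bad, "p_marker_pos_given_gfp_pos")
  }
  if (!frac_ok(cfg$p_marker_pos_given_gfp_neg)) {
    bad <- c(bad, "p_marker_pos_given_gfp_neg")
  }
  if (!all(c("nuclear", "gfp", "rfp", "marker") %in% names(cfg$channels))) {
    bad <- c(bad, "channels")
  }
  if (!(cfg$noise$read_sd >= 0)) bad <- c(bad, "noise$read_sd")
  if (!cfg$bit_depth %in% c(8L, 16L)) bad <- c(bad, "bit_depth")
  if (length(bad) > 0) {
    stop("invalid simulation_config field(s): ", paste(bad, collapse = ", "))
  }
  invisible(cfg)
}

# run expr with a private, restored RNG stream seeded from `seed`
with_sim_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Place nuclei by dart throwing
#'
#' Samples nucleus centres uniformly inside the field (with a margin of one
#' radius, so disks are fully contained) and rejects candidates closer than
#' `min_center_distance` to an accepted centre. A `clump_frac` fraction of
#' cells is instead placed about 1.5 radii from a random accepted centre to
#' create touching pairs. Deterministic given `config$seed` (or an explicit
#' `seed`).
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return Data frame with columns `x`, `y`, `radius` (one row per cell).
#' @export
place_nuclei <- function(config, seed = config$seed) {
  validate_simulation_config(config)
  with_sim_seed(seed, place_nuclei_impl(config))
}

place_nuclei_impl <- function(config) {
  n <- config$n_cells
  if (n == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), radius = numeric(0)))
  }
  h <- config$image_height; w <- config$image_width
  radii <- pmax(2, stats::rnorm(n, config$nucleus_radius_mean,
                                config$nucleus_radius_sd))
  n_clumped <- floor(config$clump_frac * n)
  # clumped cells are placed last, next to an already accepted centre
  xs <- ys <- numeric(n)
  max_tries <- 200L * n + 200L
  tries <- 0L
  accepted <- 0L
  while (accepted < n - n_clumped) {
    tries <- tries + 1L
    if (tries > max_tries) {
      density_note <- sprintf(
        "placed %d of %d nuclei; min_center_distance = %g is too large for a %dx%d field (achievable density ~ %.0f cells)",
        accepted, n, config$min_center_distance, w, h,
        floor(0.5 * h * w / max(1, config$min_center_distance)^2))
      stop("nucleus placement failed: ", density_note)
    }
    i <- accepted + 1L
    r <- radii[i]
    if (w - 2 * r < 1 || h - 2 * r < 1) {
      stop("nucleus placement failed: nucleus radius ", round(r, 1),
           " does not fit a ", w, "x", h, " field")
    }
    cx <- stats::runif(1, r + 1, w - r)
    cy <- stats::runif(1, r + 1, h - r)
    if (accepted > 0) {
      d2 <- (xs[seq_len(accepted)] - cx)^2 + (ys[seq_len(accepted)] - cy)^2
      if (min(d2) < config$min_center_distance^2) next
    }
    xs[i] <- cx; ys[i] <- cy
    accepted <- i
  }
  if (n_clumped > 0) {
    for (i in (n - n_clumped + 1L):n) {
      anchor <- sample.int(accepted, 1)
      theta <- stats::runif(1, 0, 2 * pi)
      d <- 1.5 * radii[i]
      cx <- min(max(xs[anchor] + d * cos(theta), radii[i] + 1),
                w - radii[i])
      cy <- min(max(ys[anchor] + d * sin(theta), radii[i] + 1),
                h - radii[i])
      xs[i] <- cx; ys[i] <- cy
      accepted <- i
    }
  }
  data.frame(x = xs, y = ys, radius = radii)
}

# draw one log-normal foreground intensity per cell; sdlog = 0 renders the
# median level exactly
draw_fg <- function(level, sdlog, n) {
  if (sdlog == 0) rep(level, n)
  else stats::rlnorm(n, meanlog = log(level), sdlog = sdlog)
}

#' Sample the per-cell ground-truth table for a field
#'
#' Performs placement, population assignment (GFP status, marker status) and
#' per-cell foreground intensity draws without rendering pixels. This is the
#' cell-level half of [simulate_field()]; it is useful on its own to study
#' gating behaviour at large cell numbers.
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return Data frame with one row per cell: `cell_id`, `x`, `y`, `radius`,
#'   `is_gfp_pos`, `is_marker_pos`, and true foreground intensities
#'   `fg_nuclear`, `fg_gfp`, `fg_rfp`, `fg_marker`.
#' @export
simulate_cell_table <- function(config, seed = config$seed) {
  validate_simulation_config(config)
  with_sim_seed(seed, {
    pl <- place_nuclei_impl(config)
    n <- nrow(pl)
    ch <- config$channels
    is_gfp_pos <- stats::runif(n) < config$frac_gfp_pos
    p_marker <- ifelse(is_gfp_pos,
                       config$p_marker_pos_given_gfp_pos,
                       config$p_marker_pos_given_gfp_neg)
    is_marker_pos <- stats::runif(n) < p_marker
    fg_nuclear <- draw_fg(ch$nuclear$fg, ch$nuclear$sdlog, n)
    fg_gfp <- ifelse(is_gfp_pos,
                     draw_fg(ch$gfp$fg_pos, ch$gfp$sdlog, n),
                     draw_fg(ch$gfp$fg_neg, ch$gfp$sdlog, n))
    fg_rfp <- ifelse(is_gfp_pos,
                     draw_fg(ch$rfp$fg_pos, ch$rfp$sdlog, n),
                     draw_fg(ch$rfp$fg_neg, ch$rfp$sdlog, n))
    fg_marker <- ifelse(is_marker_pos,
                        draw_fg(ch$marker$fg_pos, ch$marker$sdlog, n),
                        draw_fg(ch$marker$fg_neg, ch$marker$sdlog, n))
    data.frame(
      cell_id = seq_len(n), x = pl$x, y = pl$y, radius = pl$radius,
      is_gfp_pos = is_gfp_pos, is_marker_pos = is_marker_pos,
      fg_nuclear = fg_nuclear, fg_gfp = fg_gfp,
      fg_rfp = fg_rfp, fg_marker = fg_marker
    )
  })
}

# paint disks into a label raster; overlapping pixels go to the nearest centre
rasterize_cells <- function(cells, h, w) {
  labels <- matrix(0L, h, w)
  if (nrow(cells) == 0) return(labels)
  best_d2 <- matrix(Inf, h, w)
  for (i in seq_len(nrow(cells))) {
    cx <- cells$x[i]; cy <- cells$y[i]; r <- cells$radius[i]
    x0 <- max(1L, floor(cx - r)); x1 <- min(w, ceiling(cx + r))
    y0 <- max(1L, floor(cy - r)); y1 <- min(h, ceiling(cy + r))
    xs <- x0:x1; ys <- y0:y1
    d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
    inside <- d2 <= r^2
    sub_best <- best_d2[ys, xs, drop = FALSE]
    take <- inside & d2 < sub_best
    if (any(take)) {
      sub_lab <- labels[ys, xs, drop = FALSE]
      sub_lab[take] <- cells$cell_id[i]
      sub_best[take] <- d2[take]
      labels[ys, xs] <- sub_lab
      best_d2[ys, xs] <- sub_best
    }
  }
  labels
}

# 2-px ring mask at the cell boundary (membrane reporter mode)
ring_mask_add <- function(raster, cx, cy, rad, value, ring_width = 2) {
  h <- nrow(raster); w <- ncol(raster)
  x0 <- max(1L, floor(cx - rad - 1)); x1 <- min(w, ceiling(cx + rad + 1))
  y0 <- max(1L, floor(cy - rad - 1)); y1 <- min(h, ceiling(cy + rad + 1))
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  ring <- d <= rad & d > rad - ring_width
  sub <- raster[ys, xs, drop = FALSE]
  sub[ring] <- value
  raster[ys, xs] <- sub
  raster
}

#' Simulate one multi-channel reporter field with ground truth
#'
#' Renders the four channels (nuclear, GFP, RFP, marker) for the cell
#' population drawn by [simulate_cell_table()]. In `nuclear_ratio` mode
#' GFP-positive cells have bright nuclear GFP and dim nuclear tdTomato and
#' GFP-negative cells the converse; in `membrane` mode the reporter signal is
#' a ~2 px ring at the cell boundary instead. The marker channel is bright
#' only inside marker-positive nuclei. With `sdlog = 0` everywhere and noise
#' disabled, pixel values inside each nucleus equal the configured foreground
#' levels exactly.
#'
#' @param config A [simulation_config()].
#' @param well,field_id,timepoint,condition Acquisition metadata carried on
#'   the returned field.
#' @return List with elements `field` (a `field_image`: named channel
#'   matrices + metadata) and `truth` (a `ground_truth`: per-cell table +
#'   reference label raster).
#' @export
#' @examples
#' sim <- simulate_field(simulation_config(n_cells = 12, seed = 3))
#' dim(sim$field$channels$nuclear)
#' head(sim$truth$cells)
simulate_field <- function(config, well = "W01", field_id = 1L,
                           timepoint = 0, condition = "control") {
  validate_simulation_config(config)
  cells <- simulate_cell_table(config)
  h <- config$image_height; w <- config$image_width
  labels <- rasterize_cells(cells, h, w)
  ch <- config$channels
  vmax <- 2^config$bit_depth - 1

  fill_channel <- function(background, fg_values) {
    m <- matrix(background, h, w)
    idx <- which(labels > 0)
    if (length(idx) > 0) m[idx] <- fg_values[labels[idx]]
    m
  }

  nuclear <- fill_channel(ch$nuclear$background, cells$fg_nuclear)
  marker <- fill_channel(ch$marker$background, cells$fg_marker)
  if (config$reporter_mode == "nuclear_ratio") {
    gfp <- fill_channel(ch$gfp$background, cells$fg_gfp)
    rfp <- fill_channel(ch$rfp$background, cells$fg_rfp)
  } else {
    gfp <- matrix(ch$gfp$background, h, w)
    rfp <- matrix(ch$rfp$background, h, w)
    if (nrow(cells) > 0) {
      for (i in seq_len(nrow(cells))) {
        rad <- config$membrane_radius_factor * cells$radius[i]
        if (cells$is_gfp_pos[i]) {
          gfp <- ring_mask_add(gfp, cells$x[i], cells$y[i], rad,
                               cells$fg_gfp[i])
        } else {
          rfp <- ring_mask_add(rfp, cells$x[i], cells$y[i], rad,
                               cells$fg_rfp[i])
        }
      }
    }
  }

  add_noise <- function(m) {
    with_noise <- m
    if (isTRUE(config$noise$poisson)) {
      with_noise <- matrix(
        as.numeric(stats::rpois(length(m), lambda = pmax(m, 0))), h, w)
    }
    if (config$noise$read_sd > 0) {
      with_noise <- with_noise +
        stats::rnorm(length(m), 0, config$noise$read_sd)
    }
    pmin(pmax(with_noise, 0), vmax)
  }
  # noise drawn channel by channel in a fixed order, seeded separately from
  # the cell draws so the ground truth is unchanged by the noise model
  channels <- with_sim_seed(config$seed + 1L, list(
    nuclear = add_noise(nuclear), gfp = add_noise(gfp),
    rfp = add_noise(rfp), marker = add_noise(marker)
  ))

  field <- structure(list(
    channels = channels,
    metadata = list(well = well, field_id = field_id,
                    timepoint = timepoint, condition = condition,
                    bit_depth = config$bit_depth)
  ), class = "field_image")
  truth <- structure(list(cells = cells, labels = labels),
                     class = "ground_truth")
  list(field = field, truth = truth)
}

#' Simulate a multi-well, multi-timepoint experiment
#'
#' Takes a design — one entry per (well, timepoint) with a condition label
#' and a [simulation_config()] — and simulates `n_fields` fields per entry,
#' propagating the metadata into every field. Field-level seeds are derived
#' stably from each entry's config seed, so the whole experiment is
#' reproducible from the design alone.
#'
#' @param design List of entries, each a list with elements `well`,
#'   `timepoint`, `condition`, `config` and optionally `n_fields` (default 1).
#' @return List of `list(field =, truth =)` simulations, one per field.
#' @export
simulate_experiment <- function(design) {
  if (length(design) == 0) return(list())
  keys <- vapply(design, function(e) {
    paste(e$well, e$timepoint, sep = "@")
  }, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate (well, timepoint) keys in design: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  out <- list()
  for (e in design) {
    n_fields <- if (is.null(e$n_fields)) 1L else as.integer(e$n_fields)
    for (f in seq_len(n_fields)) {
      cfg <- e$config
      cfg$seed <- (cfg$seed + 7919L * f) %% .Machine$integer.max
      out[[length(out) + 1]] <- simulate_field(
        cfg, well = e$well, field_id = f,
        timepoint = e$timepoint, condition = e$condition
      )
    }
  }
  out
}
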