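#' Nuclear segmentation parameters
#'
#' Controls the Hoechst-channel segmentation pipeline: background
#' subtraction, Gaussian smoothing, thresholding (Otsu by default, or a fixed
#' intensity), hole filling, distance-transform watershed to split touching
#' nuclei, an area filter and optional border exclusion.
#'
#' @param smoothing_sigma Gaussian smoothing scale, pixels (>= 0; 0 disables).
#' @param threshold `"otsu"` or `"fixed"`.
#' @param threshold_value Intensity threshold (background-subtracted units),
#'   required when `threshold = "fixed"`.
#' @param min_area,max_area Allowed nucleus area range, pixels^2
#'   (0 < min < max).
#' @param seed_separation Neighbourhood radius (pixels) used when detecting
#'   watershed seeds as local maxima of the distance transform; set to about
#'   0.8x the expected nuclear radius.
#' @param watershed_tolerance Minimum distance-transform height separating two
#'   seeds, pixels.
#' @param exclude_border Drop nuclei touching the field border (their areas
#'   and integrals are truncated). Default TRUE.
#' @return Object of class `segmentation_params`.
#' @export
segmentation_params <- function(smoothing_sigma = 2,
                                threshold = c("otsu", "fixed"),
                                threshold_value = NULL,
                                min_area = 50, max_area = 2000,
                                seed_separation = 6,
                                watershed_tolerance = 0.3,
                                exclude_border = TRUE) {
  threshold <- match.arg(threshold)
  stopifnot(
    "smoothing_sigma must be >= 0" = smoothing_sigma >= 0,
    "need 0 < min_area < max_area" = min_area > 0 && min_area < max_area,
    "seed_separation must be >= 1" = seed_separation >= 1,
    "watershed_tolerance must be > 0" = watershed_tolerance > 0
  )
  if (threshold == "fixed" && (is.null(threshold_value) ||
                               !is.numeric(threshold_value))) {
    stop("threshold = 'fixed' requires a numeric threshold_value")
  }
  structure(list(
    smoothing_sigma = smoothing_sigma, threshold = threshold,
    threshold_value = threshold_value, min_area = min_area,
    max_area = max_area, seed_separation = seed_separation,
    watershed_tolerance = watershed_tolerance,
    exclude_border = exclude_border
  ), class = "segmentation_params")
}

#' Segment nuclei from the nuclear-counterstain channel
#'
#' Pipeline: subtract the median background, Gaussian-smooth, threshold
#' (Otsu on the smoothed image, or a fixed value), fill holes, compute the
#' distance transform, and split touching objects by watershed seeded at
#' distance-transform maxima. Objects outside `[min_area, max_area]` and
#' (optionally) objects touching the border are removed and the survivors
#' relabelled densely `1..K`. A blank or constant image yields an empty label
#' map, not an error. The procedure is deterministic.
#'
#' @param nuclear 2-D numeric intensity matrix (the Hoechst/DAPI channel).
#' @param params A [segmentation_params()].
#' @return Integer label matrix (0 = background) of the same shape.
#' @export
#' @examples
#' sim <- simulate_field(simulation_config(n_cells = 10, seed = 2))
#' labels <- segment_nuclei(sim$field$channels$nuclear, segmentation_params())
#' max(labels)
segment_nuclei <- function(nuclear, params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"))
  if (!is.matrix(nuclear) || !is.numeric(nuclear)) {
    stop("nuclear channel must be a 2-D numeric matrix")
  }
  h <- nrow(nuclear); w <- ncol(nuclear)
  x <- nuclear - stats::median(nuclear)
  x[x < 0] <- 0
  rng <- max(x)
  if (rng <= 0) return(matrix(0L, h, w))  # blank/constant field

  img <- EBImage::Image(x / rng)
  if (params$smoothing_sigma > 0) {
    img <- EBImage::gblur(img, sigma = params$smoothing_sigma)
  }
  thr <- if (params$threshold == "otsu") {
    EBImage::otsu(img, range = c(0, 1), levels = 256)
  } else {
    params$threshold_value / rng
  }
  bin <- EBImage::fillHull(img > thr)
  if (sum(bin) == 0) return(matrix(0L, h, w))
  dm <- EBImage::distmap(bin)
  labs <- EBImage::watershed(dm, tolerance = params$watershed_tolerance,
                             ext = params$seed_separation)
  labels <- matrix(as.integer(EBImage::imageData(labs)), h, w)
  filter_labels(labels, params)
}

# area filter + border exclusion + dense relabelling
filter_labels <- function(labels, params) {
  if (max(labels) == 0) return(labels)
  areas <- tabulate(labels, nbins = max(labels))
  keep <- areas >= params$min_area & areas <= params$max_area
  if (params$exclude_border) {
    border_labs <- unique(c(labels[1, ], labels[nrow(labels), ],
                            labels[, 1], labels[, ncol(labels)]))
    keep[border_labs[border_labs > 0]] <- FALSE
  }
  remap <- integer(length(keep))
  remap[keep] <- seq_len(sum(keep))
  out <- labels
  pos <- labels > 0
  out[pos] <- remap[labels[pos]]
  out
}

#' Measure per-nucleus signals over a label map
#'
#' For each labelled nucleus: pixel area, intensity-independent centroid,
#' the mean of the GFP and RFP channels over the nucleus pixels, the
#' integrated (summed) marker signal over the nucleus, and the GFP/RFP
#' ratio `(mean_gfp + eps) / (mean_rfp + eps)` with
#' `eps = 1e-6 * max(gfp, rfp channel maxima)` guarding against division by
#' zero.
#'
#' @param labels Integer label matrix from [segment_nuclei()] (or a
#'   ground-truth raster).
#' @param field A `field_image` (channels `nuclear`, `gfp`, `rfp`, `marker`
#'   of the same shape, plus metadata).
#' @return Data frame with one row per nucleus: `nucleus_id`, `well`,
#'   `field_id`, `timepoint`, `condition`, `area`, `x`, `y`, `mean_gfp`,
#'   `mean_rfp`, `integrated_marker`, `ratio`.
#' @export
measure_nuclei <- function(labels, field) {
  for (role in c("nuclear", "gfp", "rfp", "marker")) {
    if (is.null(field$channels[[role]])) {
      stop("field is missing the '", role, "' channel")
    }
    if (!all(dim(field$channels[[role]]) == dim(labels))) {
      stop("shape mismatch between labels and the '", role, "' channel")
    }
  }
  md <- field$metadata
  empty <- data.frame(
    nucleus_id = integer(0), well = character(0), field_id = integer(0),
    timepoint = numeric(0), condition = character(0), area = integer(0),
    x = numeric(0), y = numeric(0), mean_gfp = numeric(0),
    mean_rfp = numeric(0), integrated_marker = numeric(0), ratio = numeric(0)
  )
  if (max(labels) == 0) return(empty)

  idx <- which(labels > 0)
  lab <- labels[idx]
  ids <- sort(unique(lab))
  area <- as.vector(rowsum(rep(1L, length(lab)), lab)[, 1])
  rows <- (idx - 1) %% nrow(labels) + 1   # y
  cols <- (idx - 1) %/% nrow(labels) + 1  # x
  cy <- as.vector(rowsum(as.numeric(rows), lab)[, 1]) / area
  cx <- as.vector(rowsum(as.numeric(cols), lab)[, 1]) / area
  mean_gfp <- as.vector(rowsum(field$channels$gfp[idx], lab)[, 1]) / area
  mean_rfp <- as.vector(rowsum(field$channels$rfp[idx], lab)[, 1]) / area
  integrated_marker <- as.vector(rowsum(field$channels$marker[idx], lab)[, 1])
  eps <- 1e-6 * max(field$channels$gfp, field$channels$rfp)
  data.frame(
    nucleus_id = ids,
    well = md$well, field_id = md$field_id,
    timepoint = md$timepoint, condition = md$condition,
    area = area, x = cx, y = cy,
    mean_gfp = mean_gfp, mean_rfp = mean_rfp,
    integrated_marker = integrated_marker,
    ratio = (mean_gfp + eps) / (mean_rfp + eps)
  )
}

#' Match detected nuclei to ground-truth cells
#'
#' Greedy one-to-one nearest-centroid matching: repeatedly pair the globally
#' closest (record, truth cell) under `max_distance`. Reports detection
#' recall (matched / truth cells) and precision (matched / records).
#'
#' @param records Data frame from [measure_nuclei()].
#' @param truth A `ground_truth` from [simulate_field()].
#' @param max_distance Maximum centroid distance for a match, pixels (> 0).
#' @return List with `matches` (data frame: `nucleus_id`, `cell_id`,
#'   `distance`), `unmatched_records`, `unmatched_cells`, `recall`,
#'   `precision`.
#' @export
match_to_ground_truth <- function(records, truth, max_distance = 5) {
  stopifnot("max_distance must be > 0" = max_distance > 0)
  nr <- nrow(records); nc <- nrow(truth$cells)
  if (nr == 0 || nc == 0) {
    return(list(
      matches = data.frame(nucleus_id = integer(0), cell_id = integer(0),
                           distance = numeric(0)),
      unmatched_records = records$nucleus_id,
      unmatched_cells = truth$cells$cell_id,
      recall = if (nc == 0) NA_real_ else 0,
      precision = if (nr == 0) NA_real_ else 0
    ))
  }
  d <- sqrt(outer(records$x, truth$cells$x, `-`)^2 +
            outer(records$y, truth$cells$y, `-`)^2)
  d[d > max_distance] <- Inf
  matches <- data.frame(nucleus_id = integer(0), cell_id = integer(0),
                        distance = numeric(0))
  while (any(is.finite(d))) {
    k <- arrayInd(which.min(d), dim(d))
    i <- k[1]; j <- k[2]
    matches <- rbind(matches, data.frame(
      nucleus_id = records$nucleus_id[i],
      cell_id = truth$cells$cell_id[j],
      distance = d[i, j]
    ))
    d[i, ] <- Inf
    d[, j] <- Inf
  }
  list(
    matches = matches,
    unmatched_records = setdiff(records$nucleus_id, matches$nucleus_id),
    unmatched_cells = setdiff(truth$cells$cell_id, matches$cell_id),
    recall = nrow(matches) / nc,
    precision = nrow(matches) / nr
  )
}
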