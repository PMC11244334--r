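#' Write a field as a multi-page TIFF with a JSON sidecar
#'
#' Channels are written as pages in the fixed order nuclear, GFP, RFP,
#' marker, at the field's bit depth; acquisition metadata and the channel
#' order go into `<path>.json` next to the TIFF. Intensities are rounded to
#' integers on write.
#'
#' @param field A `field_image`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  bit_depth <- field$metadata$bit_depth
  if (is.null(bit_depth)) bit_depth <- 16L
  vmax <- 2^bit_depth - 1
  order <- c("nuclear", "gfp", "rfp", "marker")
  pages <- lapply(order, function(role) {
    m <- field$channels[[role]]
    if (is.null(m)) stop("field is missing the '", role, "' channel")
    round(pmin(pmax(m, 0), vmax)) / vmax
  })
  tiff::writeTIFF(pages, path, bits.per.sample = bit_depth)
  sidecar <- c(field$metadata, list(channel_order = order))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a field from TIFF
#'
#' Reads either a multi-page TIFF written by [write_field()] (channel order
#' from the JSON sidecar, or nuclear/GFP/RFP/marker when absent) or a named
#' list of single-channel TIFF paths keyed by role. All channels must agree
#' in shape.
#'
#' @param path One multi-page TIFF path, or a named list/vector of per-role
#'   paths with names among nuclear, gfp, rfp, marker.
#' @param metadata Optional metadata list overriding the sidecar.
#' @return A `field_image`.
#' @export
read_field <- function(path, metadata = list()) {
  read_one <- function(p) {
    m <- tiff::readTIFF(p, as.is = TRUE)
    storage.mode(m) <- "double"
    m
  }
  if (length(path) > 1 || !is.null(names(path))) {
    roles <- names(path)
    if (!all(roles %in% c("nuclear", "gfp", "rfp", "marker"))) {
      stop("per-channel paths must be named by role ",
           "(nuclear, gfp, rfp, marker)")
    }
    channels <- lapply(path, read_one)
    names(channels) <- roles
  } else {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    sidecar_path <- paste0(path, ".json")
    order <- c("nuclear", "gfp", "rfp", "marker")
    if (file.exists(sidecar_path)) {
      sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
      order <- sc$channel_order
      metadata <- utils::modifyList(
        sc[setdiff(names(sc), "channel_order")], metadata)
    }
    if (length(pages) != length(order)) {
      stop("expected ", length(order), " channel pages, found ",
           length(pages))
    }
    channels <- lapply(pages, function(m) {
      storage.mode(m) <- "double"; m
    })
    names(channels) <- order
  }
  shapes <- vapply(channels, function(m) paste(dim(m), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1) {
    stop("channel shape mismatch: ", paste(shapes, collapse = ", "))
  }
  defaults <- list(well = NA_character_, field_id = NA_integer_,
                   timepoint = NA_real_, condition = NA_character_,
                   bit_depth = 16L)
  structure(list(channels = channels,
                 metadata = utils::modifyList(defaults, metadata)),
            class = "field_image")
}

#' Write / read a label map as 16-bit TIFF
#'
#' @param labels Integer label matrix.
#' @param path TIFF path.
#' @return `path` (write) or the integer label matrix (read).
#' @export
write_label_map <- function(labels, path) {
  if (max(labels) > 65535) stop("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Write ground truth as label TIFF + per-cell CSV
#'
#' @param truth A `ground_truth`.
#' @param label_path TIFF path for the reference label raster.
#' @param table_path CSV path for the per-cell table.
#' @return Invisibly, the two paths.
#' @export
write_ground_truth <- function(truth, label_path, table_path) {
  write_label_map(truth$labels, label_path)
  utils::write.csv(truth$cells, table_path, row.names = FALSE)
  invisible(c(label_path, table_path))
}

#' QC overlay of segmentation outlines on the nuclear channel
#'
#' Writes a PNG with the nuclear channel in grey and detected nucleus
#' outlines in red.
#'
#' @param nuclear Nuclear-channel matrix.
#' @param labels Label matrix from [segment_nuclei()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_qc_overlay <- function(nuclear, labels, path) {
  g <- nuclear / max(nuclear, 1)
  edge <- labels > 0 &
    (rbind(labels[-1, ], 0L) != labels | rbind(0L, labels[-nrow(labels), ]) != labels |
     cbind(labels[, -1], 0L) != labels | cbind(0L, labels[, -ncol(labels)]) != labels)
  rgb <- array(g, dim = c(dim(g), 3))
  rgb[, , 1][edge] <- 1
  rgb[, , 2][edge] <- 0
  rgb[, , 3][edge] <- 0
  png::writePNG(rgb, path)
  invisible(path)
}
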