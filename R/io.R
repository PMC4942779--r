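# On-disk formats: multi-page TIFF images + JSON sidecars, 16-bit mask
# rasters, CSV feature tables and label sheets.
#
# Image storage convention: one multi-page 32-bit TIFF per sample, page order
# fixed as channel_names(); each channel is scaled by its own intensity
# maximum (recorded in the sidecar) into [0,1] before quantisation to 2^32-1
# levels, so the on-disk representation is lossless to ~2.3e-10 relative.
# Masks are unscaled 16-bit integers (lossless).

sidecar_path <- function(image_path) paste0(image_path, ".json")

#' Write / read a multimodal sample as multi-page TIFF + JSON sidecar
#'
#' Pages are stored in the fixed order given by \code{\link{channel_names}};
#' the sidecar records channel names, per-channel intensity scale, pixel
#' size, tile geometry and a \code{grid} tag (\code{"acquired"} before
#' downsampling, \code{"downsampled"} after).
#'
#' @param sample a \code{\link{multimodal_sample}}.
#' @param image_path path of the TIFF to write; the sidecar is written next
#'   to it as \code{<image_path>.json}.
#' @param grid_tag provenance tag stored in the sidecar.
#' @return \code{write_sample}: the image path, invisibly.
#' @export
write_sample <- function(sample, image_path, grid_tag = "acquired") {
  stopifnot(inherits(sample, "multimodal_sample"))
  scales <- vapply(sample$channels, function(ch) max(ch, 1e-300), 0)
  pages <- lapply(channel_names(),
                  function(nm) sample$channels[[nm]] / scales[[nm]])
  tiff::writeTIFF(pages, image_path, bits.per.sample = 32L,
                  compression = "deflate", reduce = FALSE)
  meta <- list(sample_id = sample$sample_id,
               channels = channel_names(),
               intensity_scale = as.list(scales),
               pixel_size_um = sample$pixel_size_um,
               tile_grid = sample$tile_grid,
               tile_shape_px = sample$tile_shape_px,
               grid = grid_tag)
  jsonlite::write_json(meta, sidecar_path(image_path),
                       auto_unbox = TRUE, digits = NA)
  invisible(image_path)
}

#' @rdname write_sample
#' @param meta_path sidecar path; defaults to \code{<image_path>.json}.
#' @return \code{read_sample}: a validated \code{\link{multimodal_sample}}.
#'   Integer pixel data are promoted to double on read.
#' @export
read_sample <- function(image_path, meta_path = NULL) {
  meta_path <- meta_path %||% sidecar_path(image_path)
  if (!file.exists(image_path))
    iq_stop("file-missing", paste0("no such image: ", image_path))
  if (!file.exists(meta_path))
    iq_stop("file-missing", paste0("no such sidecar: ", meta_path))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(image_path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != 5L)
    iq_stop("channel-missing",
            sprintf("expected 5 channel pages, found %d", length(pages)))
  want <- channel_names()
  if (!identical(as.character(meta$channels), want))
    iq_stop("channel-missing", "sidecar channel list does not match the canonical order")
  scales <- unlist(meta$intensity_scale)[want]
  channels <- setNames(vector("list", 5L), want)
  for (i in seq_len(5L)) {
    p <- pages[[i]]
    if (length(dim(p)) == 3L) p <- p[, , 1L]   # tolerate grey-stored-as-RGB
    channels[[want[i]]] <- p * scales[[i]]
  }
  multimodal_sample(as.character(meta$sample_id), channels,
                    pixel_size_um = meta$pixel_size_um,
                    tile_grid = meta$tile_grid,
                    tile_shape_px = meta$tile_shape_px)
}

write_mask_tiff <- function(m, path) {
  storage.mode(m) <- "integer"
  if (max(m) > 65535L)
    iq_stop("bad-argument", "mask labels exceed 16-bit range")
  tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L,
                  compression = "deflate", reduce = FALSE)
  invisible(path)
}

read_mask_tiff <- function(path) {
  if (!file.exists(path)) iq_stop("file-missing", paste0("no such mask: ", path))
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  storage.mode(m) <- "integer"
  m
}

#' Write / read an ROI set (crypt label raster + mucosa raster)
#'
#' Both masks are stored as 16-bit integer TIFFs on the grid of the image
#' they annotate; the mucosa raster uses 0/1.
#'
#' @param roi a \code{\link{roi_set}}.
#' @param crypt_path,mucosa_path raster file paths.
#' @param policy passed to \code{\link{roi_set}} on read: \code{"error"}
#'   rejects crypt pixels outside the mucosa, \code{"clip"} drops them.
#' @return \code{read_roi_set}: a validated \code{\link{roi_set}} with
#'   labels relabelled to contiguous \code{1..K}.
#' @export
write_roi_set <- function(roi, crypt_path, mucosa_path) {
  stopifnot(inherits(roi, "roi_set"))
  write_mask_tiff(roi$crypt_labels, crypt_path)
  write_mask_tiff(roi$mucosa_mask + 0L, mucosa_path)
  invisible(crypt_path)
}

#' @rdname write_roi_set
#' @export
read_roi_set <- function(crypt_path, mucosa_path, policy = c("error", "clip")) {
  crypts <- read_mask_tiff(crypt_path)
  mucosa <- read_mask_tiff(mucosa_path)
  roi_set(crypts, mucosa > 0L, policy = match.arg(policy))
}

#' Write / read a feature table (CSV + JSON metadata sidecar)
#'
#' The CSV has one header row (\code{sample_id} followed by feature names)
#' and one row per sample; values are written with full double precision.
#' Per-feature metadata tags travel in \code{<path>.json}.
#'
#' @param table a \code{\link{feature_table}}.
#' @param path CSV path.
#' @return \code{read_feature_table}: a \code{\link{feature_table}}.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(sample_id = table$sample_ids, check.names = FALSE)
  vals <- table$values
  for (j in seq_len(ncol(vals))) df[[colnames(vals)[j]]] <- vals[, j]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  jsonlite::write_json(table$feature_meta, sidecar_path(path),
                       auto_unbox = FALSE, digits = NA, na = "string")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) iq_stop("file-missing", paste0("no such file: ", path))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1L] != "sample_id")
    iq_stop("bad-argument", "first column must be sample_id")
  fn <- names(df)[-1L]
  if (anyDuplicated(fn))
    iq_stop("duplicate-feature", "duplicate feature column names")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (length(vals) && !is.numeric(vals))
    iq_stop("bad-argument", "non-numeric cells in feature table")
  storage.mode(vals) <- "double"
  colnames(vals) <- fn
  meta_file <- sidecar_path(path)
  meta <- if (file.exists(meta_file)) {
    m <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    m[match(fn, m$feature), , drop = FALSE]
  } else NULL
  if (!is.null(meta)) rownames(meta) <- NULL
  feature_table(vals, df$sample_id, meta)
}

#' Read / write per-sample histological index labels
#'
#' CSV with columns \code{sample_id}, \code{architecture}, \code{chronicity},
#' \code{activity}. Levels are validated against the allowed sets
#' (architecture, chronicity in \{0,2\}; activity in \{0,1\}).
#'
#' @param path CSV path.
#' @return \code{read_labels}: a named list of \code{\link{index_labels}},
#'   one entry per sample_id.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) iq_stop("file-missing", paste0("no such file: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", index_names())
  if (!all(need %in% names(df)))
    iq_stop("bad-argument", paste0("labels CSV needs columns: ",
                                   paste(need, collapse = ", ")))
  out <- lapply(seq_len(nrow(df)), function(i)
    index_labels(df$architecture[i], df$chronicity[i], df$activity[i]))
  names(out) <- df$sample_id
  out
}

#' @rdname read_labels
#' @param labels named list of \code{\link{index_labels}}.
#' @export
write_labels <- function(labels, path) {
  df <- labels_to_df(labels)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# named list of index_labels -> data.frame
labels_to_df <- function(labels) {
  data.frame(sample_id = names(labels),
             architecture = vapply(labels, `[[`, 0L, "architecture"),
             chronicity = vapply(labels, `[[`, 0L, "chronicity"),
             activity = vapply(labels, `[[`, 0L, "activity"),
             row.names = NULL)
}
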