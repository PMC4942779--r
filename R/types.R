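# Core S3 containers: multimodal_sample, roi_set, index_labels, feature_table.

#' Construct a multimodal microscopy sample
#'
#' A sample holds the five co-registered nonlinear-optical channels of one
#' tissue section (CARS at 2850 and 2930 cm^-1, TPEF at 458 and 525 nm, SHG)
#' as non-negative intensity matrices on a common pixel grid, together with
#' the mosaic tile geometry and the physical pixel size.
#'
#' @param sample_id character scalar identifying the section.
#' @param channels named list of five numeric matrices, one per entry of
#'   \code{\link{channel_names}}, all with identical dimensions, finite and
#'   non-negative.
#' @param pixel_size_um physical edge length of one pixel in micrometres.
#' @param tile_grid integer vector \code{c(rows, cols)} of the mosaic layout.
#' @param tile_shape_px integer vector \code{c(h, w)}: pixel size of one tile.
#'   The image must be an exact tiling: \code{nrow = rows * h},
#'   \code{ncol = cols * w}.
#' @return an object of class \code{multimodal_sample}.
#' @examples
#' ch <- setNames(replicate(5, matrix(1, 64, 64), simplify = FALSE),
#'                channel_names())
#' s <- multimodal_sample("s1", ch, pixel_size_um = 1.76,
#'                        tile_grid = c(1, 1), tile_shape_px = c(64, 64))
#' @export
multimodal_sample <- function(sample_id, channels, pixel_size_um,
                              tile_grid = c(1L, 1L),
                              tile_shape_px = NULL) {
  if (!is.character(sample_id) || length(sample_id) != 1L)
    iq_stop("bad-argument", "sample_id must be a single string")
  want <- channel_names()
  if (!is.list(channels) || is.null(names(channels)))
    iq_stop("channel-missing", "channels must be a named list")
  miss <- setdiff(want, names(channels))
  if (length(miss))
    iq_stop("channel-missing",
            paste0("missing channel(s): ", paste(miss, collapse = ", ")))
  channels <- channels[want]
  d <- dim(channels[[1L]])
  for (nm in want) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !is.numeric(ch))
      iq_stop("shape-mismatch", paste0("channel ", nm, " is not a numeric matrix"))
    if (!identical(dim(ch), d))
      iq_stop("shape-mismatch", paste0("channel ", nm, " shape differs"))
    if (anyNA(ch) || any(!is.finite(ch)))
      iq_stop("bad-intensity", paste0("channel ", nm, " has non-finite values"))
    if (any(ch < 0))
      iq_stop("bad-intensity", paste0("channel ", nm, " has negative values"))
    storage.mode(channels[[nm]]) <- "double"
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    iq_stop("bad-argument", "pixel_size_um must be a positive number")
  tile_grid <- as.integer(tile_grid)
  if (length(tile_grid) != 2L || any(tile_grid < 1L))
    iq_stop("bad-argument", "tile_grid must be two integers >= 1")
  if (is.null(tile_shape_px)) tile_shape_px <- d %/% tile_grid
  tile_shape_px <- as.integer(tile_shape_px)
  if (!identical(as.integer(tile_grid * tile_shape_px), as.integer(d)))
    iq_stop("shape-mismatch",
            "image dimensions are not an exact tiling of tile_grid x tile_shape_px")
  structure(list(sample_id = sample_id, channels = channels,
                 pixel_size_um = as.numeric(pixel_size_um),
                 tile_grid = tile_grid, tile_shape_px = tile_shape_px),
            class = "multimodal_sample")
}

#' @export
print.multimodal_sample <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("<multimodal_sample> %s: %d x %d px (%.3g um/px), %d x %d tiles\n",
              x$sample_id, d[1L], d[2L], x$pixel_size_um,
              x$tile_grid[1L], x$tile_grid[2L]))
  invisible(x)
}

#' Construct a region-of-interest set (crypt labels + mucosa mask)
#'
#' Holds the labelled crypt mask (0 = background, k > 0 = crypt object k) and
#' the mucosa mask on the same pixel grid. Labels are relabelled to a
#' contiguous 1..K on construction. The derived "mucosa without crypts"
#' region is available through \code{\link{mucosa_wo_crypts}}.
#'
#' @param crypt_labels integer matrix of crypt object labels (>= 0).
#' @param mucosa_mask logical (or 0/1) matrix, same dimensions.
#' @param policy what to do when a crypt pixel falls outside the mucosa:
#'   \code{"error"} (default) raises \code{ibdq_roi_inconsistent};
#'   \code{"clip"} removes the offending pixels from the crypt mask.
#' @return an object of class \code{roi_set} with elements
#'   \code{crypt_labels}, \code{mucosa_mask}, \code{n_crypts}.
#' @export
roi_set <- function(crypt_labels, mucosa_mask, policy = c("error", "clip")) {
  policy <- match.arg(policy)
  if (!is.matrix(crypt_labels) || !is.numeric(crypt_labels))
    iq_stop("shape-mismatch", "crypt_labels must be a numeric matrix")
  if (!is.matrix(mucosa_mask))
    iq_stop("shape-mismatch", "mucosa_mask must be a matrix")
  if (!identical(dim(crypt_labels), dim(mucosa_mask)))
    iq_stop("shape-mismatch", "crypt_labels and mucosa_mask shapes differ")
  if (anyNA(crypt_labels) || any(crypt_labels < 0))
    iq_stop("negative-label", "crypt labels must be non-negative integers")
  if (any(crypt_labels != round(crypt_labels)))
    iq_stop("negative-label", "crypt labels must be integer-valued")
  storage.mode(crypt_labels) <- "integer"
  mucosa_mask <- matrix(as.logical(mucosa_mask), nrow(mucosa_mask))
  if (anyNA(mucosa_mask))
    iq_stop("shape-mismatch", "mucosa_mask has NA entries")
  out <- crypt_labels > 0L & !mucosa_mask
  if (any(out)) {
    if (policy == "error")
      iq_stop("roi-inconsistent",
              sprintf("%d crypt pixel(s) lie outside the mucosa mask", sum(out)))
    crypt_labels[out] <- 0L
  }
  # relabel to contiguous 1..K, preserving label order
  lev <- sort(unique(crypt_labels[crypt_labels > 0L]))
  if (length(lev) && !identical(lev, seq_along(lev))) {
    map <- integer(max(lev)); map[lev] <- seq_along(lev)
    pos <- crypt_labels > 0L
    crypt_labels[pos] <- map[crypt_labels[pos]]
  }
  structure(list(crypt_labels = crypt_labels, mucosa_mask = mucosa_mask,
                 n_crypts = length(lev)),
            class = "roi_set")
}

#' Mucosa-without-crypts region
#'
#' The epithelial mucosa excluding every crypt object: the second ROI class
#' over which intensity-related properties are evaluated. Disjoint from the
#' crypt region by construction.
#'
#' @param roi a \code{\link{roi_set}}.
#' @return logical matrix.
#' @export
mucosa_wo_crypts <- function(roi) {
  stopifnot(inherits(roi, "roi_set"))
  roi$mucosa_mask & roi$crypt_labels == 0L
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d x %d px, %d crypt(s), mucosa %.1f%% of frame\n",
              nrow(x$crypt_labels), ncol(x$crypt_labels), x$n_crypts,
              100 * mean(x$mucosa_mask)))
  invisible(x)
}

#' Histological index labels for one sample
#'
#' The three pathologist-assigned IBD indices. Architecture (degree of crypt
#' distortion) and chronicity (lymphocyte/plasma-cell infiltration) are
#' scored 0 or 2; activity (neutrophil presence / epithelial damage) is
#' scored 0 or 1.
#'
#' @param architecture 0 or 2.
#' @param chronicity 0 or 2.
#' @param activity 0 or 1.
#' @return object of class \code{index_labels}.
#' @export
index_labels <- function(architecture, chronicity, activity) {
  chk <- function(v, allowed, nm) {
    if (length(v) != 1L || is.na(v) || !(v %in% allowed))
      iq_stop("invalid-level",
              sprintf("%s must be one of {%s}, got %s", nm,
                      paste(allowed, collapse = ","), format(v)))
    as.integer(v)
  }
  structure(list(architecture = chk(architecture, c(0L, 2L), "architecture"),
                 chronicity   = chk(chronicity,  c(0L, 2L), "chronicity"),
                 activity     = chk(activity,    c(0L, 1L), "activity")),
            class = "index_labels")
}

#' Names of the three histological indices
#' @return character vector
#' @export
index_names <- function() c("architecture", "chronicity", "activity")

# Allowed level sets per index.
index_levels <- function(index_name) {
  switch(index_name,
         architecture = c(0L, 2L), chronicity = c(0L, 2L),
         activity = c(0L, 1L),
         iq_stop("bad-argument", paste0("unknown index: ", index_name)))
}

#' Construct a feature table
#'
#' Samples-by-features matrix with per-feature metadata tags (family,
#' region of interest, modality) used by the ranking and classification
#' stages.
#'
#' @param values numeric matrix, rows = samples, columns = features; must
#'   carry unique column names.
#' @param sample_ids character vector, one per row.
#' @param feature_meta data frame with columns \code{feature}, \code{family}
#'   (\code{"geometry"} or \code{"irp"}), \code{roi}, \code{modality},
#'   \code{modality_b}, \code{stat}; row order must match the columns of
#'   \code{values}. Defaults to the matching rows of
#'   \code{\link{default_catalogue}}.
#' @return object of class \code{feature_table}.
#' @export
feature_table <- function(values, sample_ids, feature_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    iq_stop("bad-argument", "values must be a numeric matrix")
  fn <- colnames(values)
  if (is.null(fn) || anyDuplicated(fn))
    iq_stop("duplicate-feature", "feature (column) names must exist and be unique")
  if (length(sample_ids) != nrow(values))
    iq_stop("bad-argument", "one sample_id per row required")
  if (anyDuplicated(sample_ids))
    iq_stop("bad-argument", "sample_ids must be unique")
  rownames(values) <- sample_ids
  if (is.null(feature_meta)) {
    cat_ <- default_catalogue()
    feature_meta <- cat_[match(fn, cat_$feature), , drop = FALSE]
    feature_meta$feature <- fn
    rownames(feature_meta) <- NULL
  }
  if (!identical(feature_meta$feature, fn))
    iq_stop("bad-argument", "feature_meta rows must match value columns")
  structure(list(values = values, sample_ids = as.character(sample_ids),
                 feature_names = fn, feature_meta = feature_meta),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d sample(s) x %d feature(s)\n",
              nrow(x$values), ncol(x$values)))
  fam <- table(x$feature_meta$family)
  cat("  families:", paste(names(fam), fam, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.feature_table` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  meta <- x$feature_meta[match(colnames(v), x$feature_meta$feature), ,
                         drop = FALSE]
  rownames(meta) <- NULL
  feature_table(v, rownames(v), meta)
}
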