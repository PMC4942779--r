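# Preprocessing chain, applied in fixed order:
# median filter -> downsample x4 -> mosaic illumination correction ->
# contrast adjustment. Masks follow the image through downsampling
# (crypt labels by block majority, mucosa by block-any).

#' Preprocessing configuration
#'
#' @param median_kernel odd integer edge length of the median filter window
#'   (default 3: the smallest denoising kernel that preserves crypt borders
#'   at the downsampled resolution).
#' @param downsample_factor integer block size for block-mean downsampling
#'   (default 4).
#' @param flatfield_model \code{"quadratic"} (default): the flat field is a
#'   least-squares quadratic surface fitted to the pixel-wise tile average,
#'   matching the radially symmetric illumination falloff of laser-scanning
#'   acquisition; \code{"smooth"}: non-parametric Gaussian-smoothed tile
#'   average.
#' @param flatfield_sigma_px Gaussian smoothing sigma for the
#'   \code{"smooth"} flat-field model, in pixels of the corrected image;
#'   \code{NULL} (default) means tile_width / 8.
#' @param contrast_percentiles length-2 vector (low, high) in [0,100];
#'   intensities between these percentiles are mapped linearly to [0,1].
#' @param stages character vector of enabled stages, a subset of
#'   \code{c("median", "downsample", "mosaic", "contrast")}; order of
#'   application is always the canonical order above.
#' @return object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(median_kernel = 3L, downsample_factor = 4L,
                              flatfield_model = c("quadratic", "smooth"),
                              flatfield_sigma_px = NULL,
                              contrast_percentiles = c(1, 99),
                              stages = c("median", "downsample",
                                         "mosaic", "contrast")) {
  flatfield_model <- match.arg(flatfield_model)
  if (!is_count(median_kernel) || median_kernel %% 2 == 0)
    iq_stop("even-kernel", "median_kernel must be an odd integer >= 1")
  if (!is_count(downsample_factor))
    iq_stop("bad-argument", "downsample_factor must be an integer >= 1")
  stopifnot(length(contrast_percentiles) == 2L,
            contrast_percentiles[1L] < contrast_percentiles[2L],
            all(contrast_percentiles >= 0), all(contrast_percentiles <= 100))
  stages <- if (length(stages)) match.arg(stages, several.ok = TRUE)
            else character(0)
  structure(list(median_kernel = as.integer(median_kernel),
                 downsample_factor = as.integer(downsample_factor),
                 flatfield_model = flatfield_model,
                 flatfield_sigma_px = flatfield_sigma_px,
                 contrast_percentiles = as.numeric(contrast_percentiles),
                 stages = stages),
            class = "preprocess_config")
}

#' Median filter a channel
#'
#' Each pixel is replaced by the median of its kernel x kernel
#' neighbourhood; borders are handled by mirror reflection. The 3x3 case
#' uses a vectorised selection network; other kernel sizes fall back to a
#' per-pixel median.
#'
#' @param channel numeric matrix.
#' @param kernel odd integer window edge.
#' @return filtered matrix, same shape.
#' @export
median_filter <- function(channel, kernel = 3L) {
  if (!is_count(kernel) || kernel %% 2 == 0)
    iq_stop("even-kernel", "kernel must be an odd integer >= 1")
  if (kernel == 1L) return(channel)
  nr <- nrow(channel); nc <- ncol(channel)
  pad <- (kernel - 1L) %/% 2L
  ri <- reflect_index(nr, pad); ci <- reflect_index(nc, pad)
  padded <- channel[ri, ci]
  k2 <- kernel * kernel
  planes <- vector("list", k2)
  m <- 0L
  for (dc in seq_len(kernel)) for (dr in seq_len(kernel)) {
    m <- m + 1L
    planes[[m]] <- padded[seq_len(nr) + dr - 1L, seq_len(nc) + dc - 1L]
  }
  if (kernel == 3L) return(median9(planes))
  arr <- do.call(cbind, lapply(planes, as.vector))
  matrix(apply(arr, 1L, stats::median), nr, nc)
}

# Vectorised median of nine matrices via a 19-exchange selection network.
median9 <- function(v) {
  sw <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6); sw(5, 8); sw(5, 3); sw(7, 5); sw(5, 3)
  v[[5]]
}

#' Downsample a channel by block averaging
#'
#' Reduces each factor x factor block to its mean, preserving the global
#' mean exactly for divisible shapes (non-divisible trailing rows/columns
#' are cropped). The caller is responsible for scaling the pixel size.
#'
#' @param channel numeric matrix.
#' @param factor integer >= 1.
#' @return downsampled matrix.
#' @export
downsample <- function(channel, factor = 4L) {
  if (!is_count(factor))
    iq_stop("bad-argument", "factor must be an integer >= 1")
  if (factor == 1L) return(channel)
  nr <- nrow(channel) - nrow(channel) %% factor
  nc <- ncol(channel) - ncol(channel) %% factor
  m <- channel[seq_len(nr), seq_len(nc), drop = FALSE]
  ridx <- (seq_len(nr) - 1L) %/% factor
  cidx <- (seq_len(nc) - 1L) %/% factor
  s <- rowsum(m, ridx)
  out <- t(rowsum(t(s), cidx)) / factor^2
  dimnames(out) <- NULL
  out
}

# Block-majority downsampling of an integer label image; ties broken toward
# the lower label (background 0 participates in the vote).
downsample_labels <- function(lab, factor) {
  if (factor == 1L) return(lab)
  nr <- nrow(lab) - nrow(lab) %% factor
  nc <- ncol(lab) - ncol(lab) %% factor
  m <- lab[seq_len(nr), seq_len(nc), drop = FALSE]
  nbr <- nr %/% factor; nbc <- nc %/% factor
  rb <- (seq_len(nr) - 1L) %/% factor
  cb <- (seq_len(nc) - 1L) %/% factor
  block <- outer(rb, cb * nbr, "+") + 1L          # 1..nbr*nbc, column-major
  lev <- sort(unique(as.vector(m)))
  counts <- unclass(table(factor(as.vector(block), levels = seq_len(nbr * nbc)),
                          factor(as.vector(m), levels = lev)))
  # lev is ascending and ties.method = "first", so ties go to the lower label
  win <- lev[max.col(counts, ties.method = "first")]
  out <- matrix(win, nbr, nbc)
  storage.mode(out) <- "integer"
  out
}

# Block-any downsampling of a logical mask.
downsample_any <- function(mask, factor) {
  if (factor == 1L) return(mask)
  downsample(mask + 0, factor) > 0
}

#' Correct mosaic illumination (flat-field) artifacts
#'
#' Retrospective tile-average flat-field correction: the per-tile
#' illumination field is estimated from the pixel-wise mean over all mosaic
#' tiles -- by default as a least-squares quadratic surface (matching the
#' radially symmetric falloff of laser-scanning illumination and immune to
#' boundary bias), alternatively as a Gaussian-smoothed tile average --
#' normalised to mean one and floored at 1e-3 of its mean; every tile is
#' divided by it. The per-channel mean is preserved exactly (a final global
#' rescale), and applying the correction twice is close to applying it once.
#'
#' @param sample a \code{\link{multimodal_sample}}.
#' @param model \code{"quadratic"} or \code{"smooth"}, see
#'   \code{\link{preprocess_config}}.
#' @param sigma Gaussian sigma (px) for the \code{"smooth"} model; default
#'   tile_width / 8.
#' @return corrected \code{\link{multimodal_sample}}.
#' @export
correct_mosaic_illumination <- function(sample,
                                        model = c("quadratic", "smooth"),
                                        sigma = NULL) {
  stopifnot(inherits(sample, "multimodal_sample"))
  model <- match.arg(model)
  th <- sample$tile_shape_px[1L]; tw <- sample$tile_shape_px[2L]
  gr <- sample$tile_grid[1L]; gc <- sample$tile_grid[2L]
  sigma <- sigma %||% (tw / 8)
  qbasis <- NULL
  if (model == "quadratic") {
    x <- rep((seq_len(tw) - (tw + 1) / 2) / tw, each = th)
    y <- rep((seq_len(th) - (th + 1) / 2) / th, times = tw)
    qbasis <- cbind(1, x, y, x * y, x^2, y^2)
  }
  channels <- lapply(sample$channels, function(ch) {
    acc <- matrix(0, th, tw)
    for (i in seq_len(gr)) for (j in seq_len(gc))
      acc <- acc + ch[(i - 1L) * th + seq_len(th), (j - 1L) * tw + seq_len(tw)]
    acc <- acc / (gr * gc)
    F <- if (model == "quadratic")
      matrix(qbasis %*% stats::lm.fit(qbasis, as.vector(acc))$coefficients,
             th, tw)
    else gaussian_smooth(acc, sigma)
    mF <- mean(F)
    if (mF <= 0) return(ch)                   # fully dark channel: no-op
    F <- F / mF
    F <- pmax(F, 1e-3)
    Ffull <- F[(seq_len(nrow(ch)) - 1L) %% th + 1L,
               (seq_len(ncol(ch)) - 1L) %% tw + 1L]
    out <- ch / Ffull
    mo <- mean(out)
    if (mo > 0) out <- out * (mean(ch) / mo)  # preserve the channel mean
    out
  })
  multimodal_sample(sample$sample_id, channels, sample$pixel_size_um,
                    sample$tile_grid, sample$tile_shape_px)
}

#' Tile-seam step metric
#'
#' Mean absolute gradient discontinuity across internal tile borders: for a
#' border between positions b and b+1 (perpendicular to it), the step is
#' |(x[b+1] - x[b]) - (x[b] - x[b-1])|. A diagnostic for mosaicking
#' artifacts: a per-tile illumination field bends the intensity profile at
#' every border, even when the field is mirror-symmetric across the seam
#' (in which case a plain first difference would vanish). Large before
#' flat-field correction, near zero after.
#'
#' @param channel numeric matrix.
#' @param tile_grid mosaic layout \code{c(rows, cols)}.
#' @return non-negative scalar (0 if there are no internal borders).
#' @export
seam_metric <- function(channel, tile_grid) {
  d <- dim(channel)
  th <- d[1L] %/% tile_grid[1L]; tw <- d[2L] %/% tile_grid[2L]
  diffs <- numeric(0)
  if (tile_grid[1L] > 1L) {
    rows <- th * seq_len(tile_grid[1L] - 1L)
    diffs <- c(diffs, abs(channel[rows + 1L, ] - 2 * channel[rows, ] +
                            channel[rows - 1L, ]))
  }
  if (tile_grid[2L] > 1L) {
    cols <- tw * seq_len(tile_grid[2L] - 1L)
    diffs <- c(diffs, abs(channel[, cols + 1L] - 2 * channel[, cols] +
                            channel[, cols - 1L]))
  }
  if (!length(diffs)) return(0)
  mean(diffs)
}

#' Contrast adjustment by percentile stretch
#'
#' Linearly maps the (low, high) percentile interval of the channel to
#' [0,1], clipping values outside. A constant channel (equal percentiles)
#' returns all zeros with a warning.
#'
#' @param channel numeric matrix.
#' @param percentiles length-2 vector (low, high) in [0,100].
#' @return matrix with values in [0,1].
#' @export
adjust_contrast <- function(channel, percentiles = c(1, 99)) {
  stopifnot(length(percentiles) == 2L, percentiles[1L] < percentiles[2L])
  q <- stats::quantile(channel, percentiles / 100, names = FALSE)
  if (q[2L] <= q[1L]) {
    iq_warn("constant channel: contrast adjustment returns all zeros")
    return(channel * 0)
  }
  pmin(pmax((channel - q[1L]) / (q[2L] - q[1L]), 0), 1)
}

#' Run the full preprocessing chain on a sample and its ROI set
#'
#' Stages are applied in the fixed order median filter, block-mean
#' downsampling, mosaic flat-field correction, contrast adjustment
#' (whichever of them are enabled in the config). Masks are downsampled
#' alongside the image -- crypt labels by block majority (ties toward the
#' lower label), the mucosa mask by block-any -- and relabelled to stay
#' contiguous; pixel size and tile shape metadata are updated.
#'
#' @param sample a \code{\link{multimodal_sample}}.
#' @param roi a \code{\link{roi_set}} on the same grid (or NULL).
#' @param config a \code{\link{preprocess_config}}.
#' @return list with elements \code{sample} and \code{roi}.
#' @export
preprocess_sample <- function(sample, roi = NULL, config = preprocess_config()) {
  stopifnot(inherits(sample, "multimodal_sample"),
            inherits(config, "preprocess_config"))
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "roi_set"))
    if (!identical(dim(roi$crypt_labels), dim(sample$channels[[1L]])))
      iq_stop("shape-mismatch", "ROI grid does not match the image grid")
  }
  channels <- sample$channels
  px <- sample$pixel_size_um
  tile_shape <- sample$tile_shape_px

  if ("median" %in% config$stages)
    channels <- lapply(channels, median_filter, kernel = config$median_kernel)

  if ("downsample" %in% config$stages && config$downsample_factor > 1L) {
    f <- config$downsample_factor
    if (any(tile_shape %% f != 0L))
      iq_stop("shape-mismatch",
              "tile shape is not divisible by the downsampling factor")
    channels <- lapply(channels, downsample, factor = f)
    px <- px * f
    tile_shape <- tile_shape %/% f
    if (!is.null(roi))
      roi <- roi_set(downsample_labels(roi$crypt_labels, f),
                     downsample_any(roi$mucosa_mask, f), policy = "clip")
  }

  out <- multimodal_sample(sample$sample_id, channels, px,
                           sample$tile_grid, tile_shape)

  if ("mosaic" %in% config$stages)
    out <- correct_mosaic_illumination(out, model = config$flatfield_model,
                                       sigma = config$flatfield_sigma_px)

  if ("contrast" %in% config$stages)
    out <- multimodal_sample(out$sample_id,
                             lapply(out$channels, adjust_contrast,
                                    percentiles = config$contrast_percentiles),
                             out$pixel_size_um, out$tile_grid, out$tile_shape_px)

  list(sample = out, roi = roi)
}
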