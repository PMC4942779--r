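# Feature extraction: crypt morphometry, first-order intensity statistics
# and inter-modality contrasts over two ROI classes (all crypts; epithelial
# mucosa without crypts). The default catalogue has exactly 87 entries:
# 15 geometry + 6 statistics x 5 modalities x 2 ROIs (60) + 6 modality-pair
# contrasts x 2 ROIs (12). SHG enters the per-modality statistics but not
# the contrast pairs.

roi_short <- c(crypts = "crypts", mucosa_wo_crypts = "mucosa")

#' The default 87-feature catalogue
#'
#' @return data frame with columns \code{feature}, \code{family}
#'   (\code{"geometry"}/\code{"irp"}), \code{kind} (\code{"geometry"},
#'   \code{"texture"}, \code{"contrast"}), \code{roi}, \code{modality},
#'   \code{modality_b} and \code{stat}; exactly 87 rows.
#' @export
default_catalogue <- function() {
  meas <- c("area", "perimeter", "equivalent_diameter", "radius",
            "eccentricity", "solidity")
  geom <- data.frame(
    feature = c(paste0(rep(meas, each = 2L), "_", c("mean", "sd")),
                "crypt_density", "nn_distance_mean", "nn_distance_sd"),
    family = "geometry", kind = "geometry", roi = "crypts",
    modality = NA_character_, modality_b = NA_character_,
    stat = c(rep(c("mean", "sd"), 6L), "density", "mean", "sd"))

  stats_ <- c("mean", "std", "smoothness", "third_moment", "uniformity",
              "entropy")
  tex <- expand.grid(stat = stats_, modality = channel_names(),
                     roi = names(roi_short), stringsAsFactors = FALSE,
                     KEEP.OUT.ATTRS = FALSE)
  tex <- data.frame(
    feature = paste(tex$modality, tex$stat, roi_short[tex$roi], sep = "_"),
    family = "irp", kind = "texture", roi = tex$roi,
    modality = tex$modality, modality_b = NA_character_, stat = tex$stat)

  prs <- utils::combn(contrast_channels(), 2L)
  con <- expand.grid(pair = seq_len(ncol(prs)), roi = names(roi_short),
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  con <- data.frame(
    feature = paste0("contrast_", prs[1L, con$pair], "_", prs[2L, con$pair],
                     "_", roi_short[con$roi]),
    family = "irp", kind = "contrast", roi = con$roi,
    modality = prs[1L, con$pair], modality_b = prs[2L, con$pair],
    stat = "contrast")

  out <- rbind(geom, tex, con)
  rownames(out) <- NULL
  out
}

# ---- crypt geometry ------------------------------------------------------

# Clockwise Moore-neighbourhood ring offsets: W NW N NE E SE S SW.
.ring <- cbind(dr = c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L),
               dc = c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L))

# Perimeter of one connected object by boundary tracing: steps between
# consecutive 8-connected boundary pixels, axial steps weighted 1 and
# diagonal steps sqrt(2). A single-pixel object has perimeter 4 (its
# outline). `mask` is a logical matrix containing exactly one object.
trace_perimeter <- function(mask) {
  npix <- sum(mask)
  if (npix == 0L) return(0)
  if (npix == 1L) return(4)
  nr <- nrow(mask)
  start <- which(mask)[1L]                 # column-major: min col, then row
  p <- c((start - 1L) %% nr + 1L, (start - 1L) %/% nr + 1L)
  at <- function(q) q[1L] >= 1L && q[1L] <= nr && q[2L] >= 1L &&
    q[2L] <= ncol(mask) && mask[q[1L], q[2L]]
  b_dir <- 1L                              # backtrack is west of the start
  p0 <- p; b0 <- b_dir
  per <- 0; first <- TRUE
  for (it in seq_len(8L * npix + 8L)) {
    found <- FALSE
    for (k in seq_len(8L)) {
      d <- (b_dir + k - 1L) %% 8L + 1L     # clockwise from backtrack
      q <- p + .ring[d, ]
      if (at(q)) {
        step <- if (sum(abs(.ring[d, ])) == 2L) sqrt(2) else 1
        per <- per + step
        # new backtrack: the neighbour examined just before q, as seen from q
        prev <- (b_dir + k - 2L) %% 8L + 1L
        bq <- p + .ring[prev, ]
        rel <- bq - q
        b_dir <- which(.ring[, 1L] == rel[1L] & .ring[, 2L] == rel[2L])
        p <- q
        found <- TRUE
        break
      }
    }
    if (!found) return(4)                  # isolated pixel (defensive)
    if (!first && all(p == p0) && b_dir == b0) return(per)
    first <- FALSE
  }
  per                                       # defensive: bounded walk
}

# Pixel count of the convex hull of a set of pixel centres.
hull_pixel_count <- function(rows, cols) {
  n <- length(rows)
  if (n <= 3L) return(n)
  h <- grDevices::chull(cols, rows)
  hx <- cols[h]; hy <- rows[h]
  m <- length(h)
  if (m < 3L) return(n)
  # signed area fixes orientation for the half-plane tests
  s <- sum(hx * hy[c(2:m, 1L)] - hx[c(2:m, 1L)] * hy)
  gr <- seq(min(rows), max(rows)); gc <- seq(min(cols), max(cols))
  py <- rep(gr, times = length(gc)); px <- rep(gc, each = length(gr))
  inside <- rep(TRUE, length(px))
  for (i in seq_len(m)) {
    j <- if (i == m) 1L else i + 1L
    cr <- (hx[j] - hx[i]) * (py - hy[i]) - (hy[j] - hy[i]) * (px - hx[i])
    inside <- inside & (if (s > 0) cr >= -1e-9 else cr <= 1e-9)
  }
  max(sum(inside), n)
}

#' Measure geometrical properties of every crypt
#'
#' Per-object measurements in physical units: area, perimeter (boundary-step
#' counting, diagonal steps weighted sqrt(2)), equivalent diameter
#' \eqn{\sqrt{4A/\pi}}, radius (half of it), eccentricity (from the second
#' central moments of the pixel coordinates), solidity (area / convex hull
#' area, both in pixel counts) and centroid.
#'
#' @param roi a \code{\link{roi_set}}.
#' @param pixel_size_um physical pixel size.
#' @return data frame with one row per crypt label (zero rows when the field
#'   is empty): columns \code{label}, \code{area_um2}, \code{perimeter_um},
#'   \code{equivalent_diameter_um}, \code{radius_um}, \code{eccentricity},
#'   \code{solidity}, \code{centroid_row_um}, \code{centroid_col_um}.
#' @export
measure_crypts <- function(roi, pixel_size_um) {
  stopifnot(inherits(roi, "roi_set"), pixel_size_um > 0)
  lab <- roi$crypt_labels
  K <- roi$n_crypts
  out <- data.frame(label = integer(0), area_um2 = numeric(0),
                    perimeter_um = numeric(0),
                    equivalent_diameter_um = numeric(0), radius_um = numeric(0),
                    eccentricity = numeric(0), solidity = numeric(0),
                    centroid_row_um = numeric(0), centroid_col_um = numeric(0))
  if (K == 0L) return(out)
  nr <- nrow(lab)
  idx <- which(lab > 0L)
  by_crypt <- split(idx, lab[idx])
  rows_l <- lapply(by_crypt, function(i) (i - 1L) %% nr + 1L)
  cols_l <- lapply(by_crypt, function(i) (i - 1L) %/% nr + 1L)
  px2 <- pixel_size_um^2
  res <- lapply(seq_len(K), function(k) {
    rows <- rows_l[[k]]; cols <- cols_l[[k]]
    n <- length(rows)
    area <- n * px2
    eqd <- sqrt(4 * area / pi)
    # eccentricity from the pixel-coordinate covariance eigenvalues
    ecc <- 0
    if (n > 1L) {
      cv <- stats::cov(cbind(rows, cols)) * (n - 1) / n
      ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
      if (ev[1L] > 0) ecc <- sqrt(max(0, 1 - max(0, ev[2L]) / ev[1L]))
    }
    r0 <- min(rows); c0 <- min(cols)
    sub <- matrix(FALSE, max(rows) - r0 + 1L, max(cols) - c0 + 1L)
    sub[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
    per <- trace_perimeter(sub) * pixel_size_um
    sol <- min(1, n / hull_pixel_count(rows, cols))
    c(area, per, eqd, eqd / 2, ecc, sol,
      mean(rows) * pixel_size_um, mean(cols) * pixel_size_um)
  })
  res <- do.call(rbind, res)
  data.frame(label = seq_len(K), area_um2 = res[, 1L], perimeter_um = res[, 2L],
             equivalent_diameter_um = res[, 3L], radius_um = res[, 4L],
             eccentricity = res[, 5L], solidity = res[, 6L],
             centroid_row_um = res[, 7L], centroid_col_um = res[, 8L])
}

#' Crypt density
#'
#' Number of crypt objects per square millimetre of mucosa.
#'
#' @param roi a \code{\link{roi_set}}.
#' @param pixel_size_um physical pixel size.
#' @return crypts per mm^2.
#' @export
crypt_density <- function(roi, pixel_size_um) {
  stopifnot(inherits(roi, "roi_set"))
  area_mm2 <- sum(roi$mucosa_mask) * (pixel_size_um / 1000)^2
  if (area_mm2 <= 0) iq_stop("empty-roi", "mucosa mask is empty")
  roi$n_crypts / area_mm2
}

#' Aggregate per-crypt measurements into the 15 geometry features
#'
#' Mean and standard deviation over crypts of area, perimeter, equivalent
#' diameter, radius, eccentricity and solidity (12 features), plus crypt
#' density and the mean and standard deviation of the nearest-neighbour
#' centroid distance (arrangement regularity). With fewer than two crypts
#' the undefined entries are set to 0 and a QC flag is attached.
#'
#' @param measures data frame from \code{\link{measure_crypts}}.
#' @param density crypt density from \code{\link{crypt_density}}.
#' @return named numeric vector of 15 features with attribute \code{qc}
#'   (character vector of quality flags, possibly empty).
#' @export
aggregate_geometry <- function(measures, density) {
  cols <- c(area = "area_um2", perimeter = "perimeter_um",
            equivalent_diameter = "equivalent_diameter_um",
            radius = "radius_um", eccentricity = "eccentricity",
            solidity = "solidity")
  K <- nrow(measures)
  qc <- character(0)
  out <- numeric(0)
  for (nm in names(cols)) {
    v <- measures[[cols[[nm]]]]
    out[paste0(nm, "_mean")] <- if (K >= 1L) mean(v) else 0
    out[paste0(nm, "_sd")] <- if (K >= 2L) stats::sd(v) else 0
  }
  out["crypt_density"] <- density
  if (K >= 2L) {
    d <- as.matrix(stats::dist(measures[, c("centroid_row_um",
                                            "centroid_col_um")]))
    diag(d) <- Inf
    nn <- apply(d, 1L, min)
    out["nn_distance_mean"] <- mean(nn)
    out["nn_distance_sd"] <- if (K >= 3L) stats::sd(nn) else 0
  } else {
    out["nn_distance_mean"] <- 0
    out["nn_distance_sd"] <- 0
  }
  if (K < 2L) qc <- c(qc, sprintf("geometry-degenerate: %d crypt(s)", K))
  attr(out, "qc") <- qc
  out
}

# ---- first-order (histogram) statistics ----------------------------------

#' First-order texture statistics of a masked region
#'
#' The [0,1]-normalised intensities inside the mask are binned into
#' \code{n_bins} equal levels \eqn{z_i = i/(L-1)}, \eqn{i = 0..L-1}, with
#' relative frequencies \eqn{p_i}. Reported statistics are the histogram
#' mean \eqn{m = \sum z_i p_i}, standard deviation
#' \eqn{\sigma = \sqrt{\sum (z_i-m)^2 p_i}}, smoothness
#' \eqn{1 - 1/(1+\sigma^2)}, third central moment \eqn{\sum (z_i-m)^3 p_i},
#' uniformity \eqn{\sum p_i^2} and entropy \eqn{-\sum p_i \log_2 p_i}.
#' A constant region therefore has zero std, smoothness, third moment and
#' entropy, and uniformity one. Values outside [0,1] are clamped into the
#' end bins.
#'
#' @param channel numeric matrix, expected pre-normalised to [0,1].
#' @param mask logical matrix, same shape, at least one TRUE pixel.
#' @param n_bins number of histogram levels (default 256).
#' @return object of class \code{first_order_stats}: a list with elements
#'   \code{mean}, \code{std}, \code{smoothness}, \code{third_moment},
#'   \code{uniformity}, \code{entropy_bits}.
#' @export
first_order_stats <- function(channel, mask, n_bins = 256L) {
  v <- channel[mask]
  if (!length(v)) iq_stop("empty-roi", "mask selects no pixels")
  L <- as.integer(n_bins)
  b <- floor(pmin(pmax(v, 0), 1) * L)
  b[b == L] <- L - 1L
  p <- tabulate(b + 1L, nbins = L) / length(b)
  z <- (seq_len(L) - 1L) / (L - 1L)
  m <- sum(z * p)
  varz <- sum((z - m)^2 * p)
  pp <- p[p > 0]
  structure(list(mean = m,
                 std = sqrt(varz),
                 smoothness = 1 - 1 / (1 + varz),
                 third_moment = sum((z - m)^3 * p),
                 uniformity = sum(p^2),
                 entropy_bits = -sum(pp * log2(pp))),
            class = "first_order_stats")
}

#' Inter-modality contrast of two channels over a mask
#'
#' Michelson-type contrast \eqn{(m_a - m_b)/(m_a + m_b)} of the two ROI
#' mean intensities; defined as 0 when both means are 0. Antisymmetric in
#' its channel arguments.
#'
#' @param channel_a,channel_b numeric matrices on the same grid.
#' @param mask logical matrix with at least one TRUE pixel.
#' @return scalar in [-1, 1].
#' @export
intermodality_contrast <- function(channel_a, channel_b, mask) {
  if (!any(mask)) iq_stop("empty-roi", "mask selects no pixels")
  ma <- mean(channel_a[mask]); mb <- mean(channel_b[mask])
  if (ma + mb == 0) return(0)
  (ma - mb) / (ma + mb)
}

# ---- catalogue evaluation ------------------------------------------------

#' Extract the feature catalogue for one sample
#'
#' Evaluates every catalogue entry on a preprocessed sample (channels in
#' [0,1]) and its ROI set. Degenerate regions never produce NaN: an empty
#' ROI sets the affected features to 0 and records a QC flag.
#'
#' @param sample a preprocessed \code{\link{multimodal_sample}}.
#' @param roi a \code{\link{roi_set}} on the same grid.
#' @param catalogue feature catalogue (default \code{\link{default_catalogue}}).
#' @return single-row \code{\link{feature_table}} with attribute \code{qc}.
#' @export
extract_features <- function(sample, roi, catalogue = default_catalogue()) {
  stopifnot(inherits(sample, "multimodal_sample"), inherits(roi, "roi_set"))
  if (!identical(dim(roi$crypt_labels), dim(sample$channels[[1L]])))
    iq_stop("shape-mismatch", "ROI grid does not match the image grid")
  qc <- character(0)
  geom <- NULL
  if (any(catalogue$kind == "geometry")) {
    meas <- measure_crypts(roi, sample$pixel_size_um)
    geom <- aggregate_geometry(meas, crypt_density(roi, sample$pixel_size_um))
    qc <- c(qc, attr(geom, "qc"))
  }
  masks <- list(crypts = roi$crypt_labels > 0L,
                mucosa_wo_crypts = mucosa_wo_crypts(roi))
  stat_pool <- list()
  for (rn in names(masks)) {
    if (!any(masks[[rn]])) {
      qc <- c(qc, paste0("empty-roi: ", rn))
      next
    }
    for (ch in channel_names())
      stat_pool[[paste(ch, rn, sep = ".")]] <-
        first_order_stats(sample$channels[[ch]], masks[[rn]])
  }
  vals <- numeric(nrow(catalogue))
  for (i in seq_len(nrow(catalogue))) {
    e <- catalogue[i, ]
    vals[i] <- switch(e$kind,
      geometry = unname(geom[[e$feature]]),
      texture = {
        s <- stat_pool[[paste(e$modality, e$roi, sep = ".")]]
        if (is.null(s)) 0
        else switch(e$stat, mean = s$mean, std = s$std,
                    smoothness = s$smoothness, third_moment = s$third_moment,
                    uniformity = s$uniformity, entropy = s$entropy_bits)
      },
      contrast = {
        if (!any(masks[[e$roi]])) 0
        else intermodality_contrast(sample$channels[[e$modality]],
                                    sample$channels[[e$modality_b]],
                                    masks[[e$roi]])
      })
  }
  if (anyNA(vals))
    iq_stop("bad-feature-value", "feature extraction produced NA")
  v <- matrix(vals, nrow = 1L, dimnames = list(NULL, catalogue$feature))
  ft <- feature_table(v, sample$sample_id, catalogue)
  attr(ft, "qc") <- qc
  ft
}

#' Extract features for a whole cohort
#'
#' @param cohort list of per-sample lists with elements \code{sample} and
#'   \code{roi} (the layout produced by \code{\link{generate_cohort}},
#'   typically after \code{\link{preprocess_sample}}).
#' @param catalogue feature catalogue.
#' @return multi-row \code{\link{feature_table}}.
#' @export
extract_feature_table <- function(cohort, catalogue = default_catalogue()) {
  rows <- lapply(cohort, function(it)
    extract_features(it$sample, it$roi, catalogue))
  vals <- do.call(rbind, lapply(rows, function(r) r$values))
  ft <- feature_table(vals, vapply(rows, function(r) r$sample_ids, ""),
                      catalogue)
  attr(ft, "qc") <- unlist(lapply(rows, attr, "qc"))
  ft
}
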