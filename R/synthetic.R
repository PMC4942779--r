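# Synthetic multimodal mosaic generator.
#
# Emulates the healthy-vs-inflamed contrasts seen in nonlinear multimodal
# imaging of colonic mucosa: regular vs. distorted/branched crypts, loss of
# crypt density, elevated TPEF autofluorescence background, bright
# lymphocyte-like TPEF spots, SHG-positive fibrosis patches, per-tile
# vignetting and Poisson + Gaussian acquisition noise. Ground-truth crypt
# and mucosa masks and per-sample index labels are emitted alongside the
# images so every downstream stage can be validated without patient data.

#' Crypt-field morphology parameters
#'
#' @param crypt_density_per_mm2 target density of crypt objects per mm^2 of
#'   mucosa.
#' @param crypt_radius_um named vector \code{c(mean=, cv=)}: mean equivalent
#'   radius in micrometres and its coefficient of variation across crypts.
#' @param shape_irregularity in [0,1]; amplitude of elliptical distortion and
#'   radial boundary perturbation (0 = perfect circles).
#' @param spacing_cv relative jitter of crypt centres around a regular
#'   lattice (0 = perfectly regular arrangement).
#' @param branch_prob probability that a crypt is branched (rendered as two
#'   fused lobes, giving a non-convex outline).
#' @return object of class \code{morphology_spec}.
#' @export
morphology_spec <- function(crypt_density_per_mm2 = 100,
                            crypt_radius_um = c(mean = 30, cv = 0.08),
                            shape_irregularity = 0.08,
                            spacing_cv = 0.08,
                            branch_prob = 0.02) {
  stopifnot(crypt_density_per_mm2 >= 0,
            crypt_radius_um[["mean"]] > 0, crypt_radius_um[["cv"]] >= 0,
            shape_irregularity >= 0, shape_irregularity <= 1,
            spacing_cv >= 0, branch_prob >= 0, branch_prob <= 1)
  structure(list(crypt_density_per_mm2 = crypt_density_per_mm2,
                 crypt_radius_um = crypt_radius_um,
                 shape_irregularity = shape_irregularity,
                 spacing_cv = spacing_cv, branch_prob = branch_prob),
            class = "morphology_spec")
}

#' Built-in morphology presets
#'
#' \code{healthy_morphology()}: dense, regularly shaped, evenly spaced,
#' essentially unbranched crypts. \code{diseased_morphology()}: lower
#' density (mucosal atrophy), larger and more variable radii, distorted
#' outlines, irregular spacing and frequent branching.
#' @return a \code{\link{morphology_spec}}.
#' @export
healthy_morphology <- function() morphology_spec()

#' @rdname healthy_morphology
#' @export
diseased_morphology <- function() {
  morphology_spec(crypt_density_per_mm2 = 55,
                  crypt_radius_um = c(mean = 36, cv = 0.25),
                  shape_irregularity = 0.5,
                  spacing_cv = 0.35,
                  branch_prob = 0.3)
}

#' Channel intensity parameters
#'
#' Baseline (lamina propria) and crypt-epithelium intensity levels per
#' channel are in arbitrary detector units; channel semantics follow the
#' modality-to-structure mapping of the five channels (CARS: lipids/protein,
#' TPEF: NAD(P)H / flavins + elastin, SHG: fibrillar collagen).
#'
#' @param baseline,crypt_level named numeric vectors over
#'   \code{\link{channel_names}()}: mucosal background and crypt-epithelium
#'   levels.
#' @param goblet_dark_fraction fraction of each crypt's area occupied by a
#'   dark mucin/lumen core (mucin is dark in CARS and TPEF).
#' @param goblet_core_level multiplicative attenuation inside the core.
#' @param lymphocyte_spot_density bright immune-cell-like spots per mm^2 of
#'   mucosa-without-crypts, rendered in the TPEF channels (strongest at
#'   525 nm).
#' @param spot_brightness peak additive amplitude of one spot in TPEF525.
#' @param tpef_background_gain multiplicative elevation (>= 1) of both TPEF
#'   channels in the mucosa-without-crypts region; inflammation elevates the
#'   TPEF background.
#' @param shg_fibrosis_patch_fraction fraction of the mucosa covered by
#'   SHG-bright fibrotic collagen patches (about 0 in healthy mucosa).
#' @param shg_patch_level SHG intensity of fibrosis patches.
#' @param membrane_ring_level optional SHG level of a thin basement-membrane
#'   ring around each crypt (default 0 = off).
#' @param outside_level_frac intensity outside the mucosa, as a fraction of
#'   each channel's baseline.
#' @return object of class \code{intensity_spec}.
#' @export
intensity_spec <- function(baseline = c(CARS2850 = 0.25, CARS2930 = 0.30,
                                        TPEF458 = 0.15, TPEF525 = 0.15,
                                        SHG = 0.002),
                           crypt_level = c(CARS2850 = 0.55, CARS2930 = 0.60,
                                           TPEF458 = 0.35, TPEF525 = 0.40,
                                           SHG = 0.003),
                           goblet_dark_fraction = 0.35,
                           goblet_core_level = 0.15,
                           lymphocyte_spot_density = 30,
                           spot_brightness = 0.45,
                           tpef_background_gain = 1,
                           shg_fibrosis_patch_fraction = 0,
                           shg_patch_level = 0.5,
                           membrane_ring_level = 0,
                           outside_level_frac = 0.05) {
  want <- channel_names()
  stopifnot(all(want %in% names(baseline)), all(want %in% names(crypt_level)),
            all(baseline >= 0), all(crypt_level >= 0),
            goblet_dark_fraction >= 0, goblet_dark_fraction <= 1,
            goblet_core_level >= 0, lymphocyte_spot_density >= 0,
            spot_brightness >= 0, tpef_background_gain >= 1,
            shg_fibrosis_patch_fraction >= 0, shg_fibrosis_patch_fraction <= 1,
            shg_patch_level >= 0, membrane_ring_level >= 0,
            outside_level_frac >= 0)
  structure(list(baseline = baseline[want], crypt_level = crypt_level[want],
                 goblet_dark_fraction = goblet_dark_fraction,
                 goblet_core_level = goblet_core_level,
                 lymphocyte_spot_density = lymphocyte_spot_density,
                 spot_brightness = spot_brightness,
                 tpef_background_gain = tpef_background_gain,
                 shg_fibrosis_patch_fraction = shg_fibrosis_patch_fraction,
                 shg_patch_level = shg_patch_level,
                 membrane_ring_level = membrane_ring_level,
                 outside_level_frac = outside_level_frac),
            class = "intensity_spec")
}

#' Built-in intensity presets
#'
#' \code{healthy_intensity()}: quiet TPEF background, sparse immune spots,
#' no fibrosis. \code{diseased_intensity()}: elevated TPEF background,
#' dense lymphocyte-like spots, SHG fibrosis patches, partial mucin (dark
#' core) depletion and reduced epithelial lipid (CARS2850) signal.
#' @return an \code{\link{intensity_spec}}.
#' @export
healthy_intensity <- function() intensity_spec()

#' @rdname healthy_intensity
#' @export
diseased_intensity <- function() {
  intensity_spec(crypt_level = c(CARS2850 = 0.45, CARS2930 = 0.60,
                                 TPEF458 = 0.35, TPEF525 = 0.40, SHG = 0.003),
                 goblet_dark_fraction = 0.15,
                 lymphocyte_spot_density = 500,
                 tpef_background_gain = 1.8,
                 shg_fibrosis_patch_fraction = 0.25)
}

#' Cohort specification for the synthetic generator
#'
#' The defaults model a scaled-down mosaic acquisition: 2 x 2 tiles of
#' 256 x 256 px at 1.76 um/px, i.e. a 450 um tile field of view (full-scale
#' acquisitions use up to 10 x 15 tiles of 2048 x 2048 px and can be
#' requested through these arguments).
#'
#' @param n_samples number of tissue sections to simulate (>= 2).
#' @param class_mix fraction of healthy samples; with 0 < class_mix < 1 both
#'   classes are guaranteed to be represented.
#' @param seed master seed; every sample's randomness is derived from it.
#' @param tile_grid,tile_shape_px mosaic layout and per-tile pixel size.
#' @param pixel_size_um physical pixel size.
#' @param healthy,diseased per-class lists with elements \code{morphology}
#'   (\code{\link{morphology_spec}}) and \code{intensity}
#'   (\code{\link{intensity_spec}}).
#' @param noise list with \code{poisson_scale} (photon-count scaling of the
#'   Poisson shot noise; \code{Inf} disables) and \code{gaussian_sd}
#'   (additive read noise).
#' @param vignette_strength per-tile radial illumination falloff in [0,1).
#' @return object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_samples = 20, class_mix = 0.5, seed = 1,
                        tile_grid = c(2L, 2L), tile_shape_px = c(256L, 256L),
                        pixel_size_um = 1.76,
                        healthy = list(morphology = healthy_morphology(),
                                       intensity = healthy_intensity()),
                        diseased = list(morphology = diseased_morphology(),
                                        intensity = diseased_intensity()),
                        noise = list(poisson_scale = 200, gaussian_sd = 0.01),
                        vignette_strength = 0.25) {
  if (!is_count(n_samples) || n_samples < 2)
    iq_stop("bad-argument", "n_samples must be an integer >= 2")
  stopifnot(class_mix >= 0, class_mix <= 1, pixel_size_um > 0,
            vignette_strength >= 0, vignette_strength < 1,
            noise$poisson_scale > 0, noise$gaussian_sd >= 0)
  structure(list(n_samples = as.integer(n_samples), class_mix = class_mix,
                 seed = as.integer(seed), tile_grid = as.integer(tile_grid),
                 tile_shape_px = as.integer(tile_shape_px),
                 pixel_size_um = pixel_size_um,
                 healthy = healthy, diseased = diseased, noise = noise,
                 vignette_strength = vignette_strength),
            class = "cohort_spec")
}

# ---- crypt rasterisation -------------------------------------------------

# Conservative outer extent (px) of one parameterised crypt.
crypt_extent <- function(p) {
  base <- max(p$r_major, p$r_minor) * (1 + abs(p$a3) + abs(p$a4))
  if (!is.na(p$lobe_r)) base <- max(base, sqrt(p$lobe_dr^2 + p$lobe_dc^2) + p$lobe_r)
  base
}

# Pixel indices (matrix row/col) covered by one crypt. The outline is an
# ellipse (semi-axes r_major/r_minor, orientation `angle`) whose radius is
# modulated by 3rd and 4th harmonic perturbations in the body frame, so that
# the whole shape rotates rigidly with `angle`; branched crypts add a fused
# circular lobe at a body-frame offset.
rasterize_one <- function(p, shape_px) {
  ext <- ceiling(crypt_extent(p)) + 1L
  r0 <- max(1L, floor(p$row - ext)); r1 <- min(shape_px[1L], ceiling(p$row + ext))
  c0 <- max(1L, floor(p$col - ext)); c1 <- min(shape_px[2L], ceiling(p$col + ext))
  if (r0 > r1 || c0 > c1) return(matrix(integer(), 0L, 2L))
  rr <- seq.int(r0, r1); cc <- seq.int(c0, c1)
  dy <- rep(rr - p$row, times = length(cc))
  dx <- rep(cc - p$col, each = length(rr))
  ca <- cos(p$angle); sa <- sin(p$angle)
  xb <- ca * dx + sa * dy          # body-frame coordinates
  yb <- -sa * dx + ca * dy
  th <- atan2(yb, xb)
  g <- 1 + p$a3 * cos(3 * th + p$p3) + p$a4 * cos(4 * th + p$p4)
  g <- pmax(g, 0.2)
  inside <- (xb / p$r_major)^2 + (yb / p$r_minor)^2 <= g^2
  if (!is.na(p$lobe_r)) {
    lx <- xb - p$lobe_dr; ly <- yb - p$lobe_dc
    inside <- inside | (lx^2 + ly^2 <= p$lobe_r^2)
  }
  cbind(rep(rr, times = length(cc))[inside],
        rep(cc, each = length(rr))[inside])
}

#' Rasterise a table of parameterised crypts into a label image
#'
#' Low-level geometry kernel shared by the generator and by validation code.
#' Crypts are painted in row order; a crypt whose pixels would overlap an
#' already painted one is skipped (recorded in the \code{placed} attribute).
#'
#' @param params data frame with one row per crypt and columns \code{row},
#'   \code{col} (centre, px, 1-based, may be fractional), \code{r_major},
#'   \code{r_minor} (px), \code{angle} (radians), \code{a3}, \code{p3},
#'   \code{a4}, \code{p4} (radial harmonic amplitudes/phases), and
#'   \code{lobe_dr}, \code{lobe_dc}, \code{lobe_r} (body-frame offset and
#'   radius of a fused branch lobe; \code{NA} for unbranched crypts).
#' @param shape_px canvas dimensions \code{c(nrow, ncol)}.
#' @return integer label matrix with attribute \code{placed} (logical per
#'   input row).
#' @export
rasterize_crypts <- function(params, shape_px) {
  lab <- matrix(0L, shape_px[1L], shape_px[2L])
  placed <- logical(nrow(params))
  k <- 0L
  for (i in seq_len(nrow(params))) {
    px <- rasterize_one(params[i, ], shape_px)
    if (nrow(px) == 0L) next
    if (any(lab[px] != 0L)) next
    k <- k + 1L
    lab[px] <- k
    placed[i] <- TRUE
  }
  attr(lab, "placed") <- placed
  lab
}

#' Render a ground-truth crypt field
#'
#' Places crypts on a jittered square lattice whose spacing matches the
#' requested density; the mucosa mask is the interior of the canvas (a
#' margin wide enough for the largest crypt is excluded so that every crypt
#' lies fully inside the mucosa).
#'
#' @param morph a \code{\link{morphology_spec}}.
#' @param canvas_shape_px canvas dimensions \code{c(nrow, ncol)}.
#' @param pixel_size_um physical pixel size.
#' @param seed optional integer; if given, \code{set.seed} is called first.
#' @param mucosa_margin_um width of the frame band excluded from the mucosa
#'   mask, in micrometres. Deliberately independent of the morphology, so
#'   that the ROI extent (and with it the image composition entering the
#'   contrast stretch) does not encode the disease class; crypts whose
#'   outline would cross into the band are constrained inward instead.
#' @return a \code{\link{roi_set}} with attribute \code{params} (the table
#'   of placed crypt parameters, as taken by \code{\link{rasterize_crypts}}).
#' @export
render_crypt_field <- function(morph, canvas_shape_px, pixel_size_um,
                               seed = NULL, mucosa_margin_um = 45) {
  stopifnot(inherits(morph, "morphology_spec"))
  if (!is.null(seed)) set.seed(seed)
  nr <- canvas_shape_px[1L]; nc <- canvas_shape_px[2L]
  rmean_px <- morph$crypt_radius_um[["mean"]] / pixel_size_um
  margin <- ceiling(mucosa_margin_um / pixel_size_um) + 2L
  mucosa <- matrix(FALSE, nr, nc)
  i0 <- margin + 1L; i1 <- nr - margin; j0 <- margin + 1L; j1 <- nc - margin
  if (i1 < i0 || j1 < j0)
    iq_stop("packing-failure", "canvas too small for any mucosa interior")
  mucosa[i0:i1, j0:j1] <- TRUE
  empty <- function() {
    r <- roi_set(matrix(0L, nr, nc), mucosa)
    attr(r, "params") <- crypt_param_frame(0L)
    r
  }
  if (morph$crypt_density_per_mm2 <= 0) return(empty())

  s_px <- (1000 / sqrt(morph$crypt_density_per_mm2)) / pixel_size_um
  ih <- i1 - i0 + 1L; iw <- j1 - j0 + 1L
  n_r <- floor(ih / s_px); n_c <- floor(iw / s_px)
  if (n_r < 1 || n_c < 1)
    iq_stop("packing-failure",
            "requested crypt density gives no lattice site inside the canvas")
  # centred lattice
  row0 <- i0 + (ih - n_r * s_px) / 2 + s_px / 2
  col0 <- j0 + (iw - n_c * s_px) / 2 + s_px / 2
  lab <- matrix(0L, nr, nc)
  placed <- list()
  k <- 0L; n_sites <- n_r * n_c
  for (gi in seq_len(n_r)) for (gj in seq_len(n_c)) {
    base_r <- row0 + (gi - 1) * s_px
    base_c <- col0 + (gj - 1) * s_px
    for (attempt in seq_len(25L)) {
      p <- draw_crypt_params(morph, base_r, base_c, s_px, rmean_px)
      ext <- crypt_extent(p)
      if (p$row - ext < i0 || p$row + ext > i1 ||
          p$col - ext < j0 || p$col + ext > j1) next
      px <- rasterize_one(p, c(nr, nc))
      if (nrow(px) == 0L || any(lab[px] != 0L)) next
      k <- k + 1L
      lab[px] <- k
      placed[[k]] <- p
      break
    }
  }
  if (k < 0.75 * n_sites)
    iq_stop("packing-failure",
            sprintf("placed only %d of %d crypts; density infeasible without overlap",
                    k, n_sites))
  roi <- roi_set(lab, mucosa)
  attr(roi, "params") <- do.call(rbind, placed)
  roi
}

crypt_param_frame <- function(n) {
  data.frame(row = numeric(n), col = numeric(n), r_major = numeric(n),
             r_minor = numeric(n), angle = numeric(n), a3 = numeric(n),
             p3 = numeric(n), a4 = numeric(n), p4 = numeric(n),
             lobe_dr = numeric(n), lobe_dc = numeric(n), lobe_r = numeric(n))
}

draw_crypt_params <- function(morph, base_r, base_c, s_px, rmean_px) {
  irr <- morph$shape_irregularity
  jit <- stats::rnorm(2L, sd = morph$spacing_cv * s_px)
  r <- rmean_px * max(0.25, 1 + stats::rnorm(1L, sd = morph$crypt_radius_um[["cv"]]))
  q <- 1 + stats::runif(1L) * irr          # axis ratio r_major/r_minor = q
  branched <- stats::runif(1L) < morph$branch_prob
  lobe_r <- lobe_dr <- lobe_dc <- NA_real_
  if (branched) {
    lobe_r <- 0.75 * r
    phi <- stats::runif(1L, 0, 2 * pi)
    d <- 1.15 * r
    lobe_dr <- d * cos(phi); lobe_dc <- d * sin(phi)
  }
  data.frame(row = base_r + jit[1L], col = base_c + jit[2L],
             r_major = r * sqrt(q), r_minor = r / sqrt(q),
             angle = stats::runif(1L, 0, 2 * pi),
             a3 = irr * 0.22 * stats::runif(1L), p3 = stats::runif(1L, 0, 2 * pi),
             a4 = irr * 0.13 * stats::runif(1L), p4 = stats::runif(1L, 0, 2 * pi),
             lobe_dr = lobe_dr, lobe_dc = lobe_dc, lobe_r = lobe_r)
}

# ---- channel rendering ---------------------------------------------------

#' Render the noiseless five-channel stack for a crypt field
#'
#' Deterministic piecewise-smooth rendering: per-channel baseline in the
#' lamina propria, crypt-epithelium level inside crypts with a dark
#' mucin/lumen core (CARS and TPEF only), additive lymphocyte-like Gaussian
#' spots in the TPEF channels, SHG fibrosis patches, and a final
#' multiplicative TPEF background gain over the mucosa-without-crypts
#' region. No acquisition noise is applied here (see
#' \code{\link{apply_acquisition}}).
#'
#' @param roi a \code{\link{roi_set}}.
#' @param intens an \code{\link{intensity_spec}}.
#' @param pixel_size_um physical pixel size (sets spot/patch sizes).
#' @param seed optional integer seed.
#' @return named list of five non-negative matrices (one per channel).
#' @export
render_channels <- function(roi, intens, pixel_size_um, seed = NULL) {
  stopifnot(inherits(roi, "roi_set"), inherits(intens, "intensity_spec"))
  if (!is.null(seed)) set.seed(seed)
  lab <- roi$crypt_labels
  mucosa <- roi$mucosa_mask
  crypts <- lab > 0L
  lam_prop <- mucosa & !crypts           # lamina propria between crypts
  nr <- nrow(lab); nc <- ncol(lab)
  want <- channel_names()

  stack <- lapply(want, function(nm) {
    ch <- matrix(intens$baseline[[nm]] * intens$outside_level_frac, nr, nc)
    ch[lam_prop] <- intens$baseline[[nm]]
    ch[crypts] <- intens$crypt_level[[nm]]
    ch
  })
  names(stack) <- want

  # dark mucin / lumen cores inside crypts (CARS + TPEF, not SHG)
  if (intens$goblet_dark_fraction > 0 && any(crypts)) {
    idx <- which(crypts)
    by_crypt <- split(idx, lab[idx])
    core <- rep(FALSE, nr * nc)
    for (pxs in by_crypt) {
      rows <- (pxs - 1L) %% nr + 1L
      cols <- (pxs - 1L) %/% nr + 1L
      cr <- mean(rows); cc <- mean(cols)
      r_core <- sqrt(intens$goblet_dark_fraction) * sqrt(length(pxs) / pi)
      core[pxs[(rows - cr)^2 + (cols - cc)^2 <= r_core^2]] <- TRUE
    }
    core <- matrix(core, nr, nc)
    for (nm in setdiff(want, "SHG"))
      stack[[nm]][core] <- stack[[nm]][core] * intens$goblet_core_level
  }

  # optional SHG basement-membrane ring: one-pixel-dilated crypt boundary
  if (intens$membrane_ring_level > 0 && any(crypts)) {
    dil <- binary_dilate3(crypts)
    ring <- dil & !crypts & mucosa
    stack$SHG[ring] <- stack$SHG[ring] + intens$membrane_ring_level
  }

  # SHG fibrosis patches covering ~shg_fibrosis_patch_fraction of the mucosa
  if (intens$shg_fibrosis_patch_fraction > 0) {
    P <- matrix(0, nr, nc)
    muc_idx <- which(mucosa)
    target <- intens$shg_fibrosis_patch_fraction
    for (it in seq_len(300L)) {
      if (mean(P[muc_idx] > 0.2) >= target) break
      ctr <- muc_idx[sample.int(length(muc_idx), 1L)]
      pr <- (ctr - 1L) %% nr + 1L; pc <- (ctr - 1L) %/% nr + 1L
      rad <- stats::runif(1L, 30, 80) / pixel_size_um
      r0 <- max(1L, floor(pr - rad)); r1 <- min(nr, ceiling(pr + rad))
      c0 <- max(1L, floor(pc - rad)); c1 <- min(nc, ceiling(pc + rad))
      rr <- r0:r1; cc <- c0:c1
      d2 <- outer((rr - pr)^2, (cc - pc)^2, "+")
      fall <- pmax(0, 1 - d2 / rad^2)      # soft-edged patch
      P[rr, cc] <- pmax(P[rr, cc], fall)
    }
    P[!mucosa] <- 0
    stack$SHG <- stack$SHG + intens$shg_patch_level * P
  }

  # bright lymphocyte-like spots in the TPEF channels
  if (intens$lymphocyte_spot_density > 0 && any(lam_prop)) {
    area_mm2 <- sum(lam_prop) * (pixel_size_um / 1000)^2
    n_spots <- stats::rpois(1L, intens$lymphocyte_spot_density * area_mm2)
    if (n_spots > 0) {
      cand <- which(lam_prop)
      pos <- cand[sample.int(length(cand), n_spots, replace = TRUE)]
      sig <- max(0.8, 2.5 / pixel_size_um)      # ~5 um FWHM cell body
      ext <- ceiling(3 * sig)
      off <- seq.int(-ext, ext)
      stamp <- exp(-outer(off^2, off^2, "+") / (2 * sig^2))
      w <- c(CARS2850 = 0.10, CARS2930 = 0.25, TPEF458 = 0.70,
             TPEF525 = 1.00, SHG = 0)
      for (pidx in pos) {
        pr <- (pidx - 1L) %% nr + 1L; pc <- (pidx - 1L) %/% nr + 1L
        rr <- pmax(1L, pr - ext):pmin(nr, pr + ext)
        cc <- pmax(1L, pc - ext):pmin(nc, pc + ext)
        st <- stamp[rr - pr + ext + 1L, cc - pc + ext + 1L, drop = FALSE]
        for (nm in want[w[want] > 0])
          stack[[nm]][rr, cc] <- stack[[nm]][rr, cc] +
            intens$spot_brightness * w[[nm]] * st
      }
    }
  }

  # inflammation: general elevation of the TPEF background outside crypts.
  # Applied last (and deterministically), so the same seed with a different
  # gain scales the mucosal TPEF signal exactly multiplicatively.
  if (intens$tpef_background_gain != 1) {
    for (nm in c("TPEF458", "TPEF525"))
      stack[[nm]][lam_prop] <- stack[[nm]][lam_prop] * intens$tpef_background_gain
  }
  stack
}

# 3x3 binary dilation (used for the optional basement-membrane ring)
binary_dilate3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  out <- m
  ri <- reflect_index(nr, 1L); ci <- reflect_index(nc, 1L)
  for (dr in 0:2) for (dc in 0:2) {
    if (dr == 1 && dc == 1) next
    out <- out | m[ri[seq_len(nr) + dr], ci[seq_len(nc) + dc]]
  }
  out
}

# ---- acquisition ---------------------------------------------------------

# Radial vignette profile of one tile: v(r) = 1 - strength * (r/rmax)^2,
# r measured from the tile centre, rmax = centre-to-corner distance.
vignette_tile <- function(th, tw, strength) {
  cr <- (th + 1) / 2; cc <- (tw + 1) / 2
  r2 <- outer((seq_len(th) - cr)^2, (seq_len(tw) - cc)^2, "+")
  1 - strength * r2 / max(r2)
}

#' Apply mosaic acquisition effects: vignetting and shot/read noise
#'
#' Each tile of the mosaic is multiplied by a radially symmetric vignette
#' field \eqn{v(r) = 1 - s (r/r_{max})^2}; then Poisson shot noise (the
#' pixel value is treated as an expected photon count after multiplication
#' by \code{poisson_scale}) and additive Gaussian read noise are applied.
#' Negative values from read noise are clamped to zero.
#'
#' @param stack named list of five channel matrices (noiseless rendering).
#' @param tile_grid mosaic layout \code{c(rows, cols)}; the stack dimensions
#'   must be divisible accordingly.
#' @param vignette_strength in [0,1); 0 disables.
#' @param noise list with \code{poisson_scale} (\code{Inf} disables) and
#'   \code{gaussian_sd} (0 disables).
#' @param pixel_size_um physical pixel size recorded in the output sample.
#' @param sample_id identifier for the output sample.
#' @param seed optional integer seed.
#' @return a \code{\link{multimodal_sample}}.
#' @export
apply_acquisition <- function(stack, tile_grid, vignette_strength = 0.25,
                              noise = list(poisson_scale = 200,
                                           gaussian_sd = 0.01),
                              pixel_size_um = 1.76, sample_id = "synthetic",
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- dim(stack[[1L]])
  tile_grid <- as.integer(tile_grid)
  if (any(d %% tile_grid != 0L))
    iq_stop("shape-mismatch", "stack shape is not divisible into the tile grid")
  th <- d[1L] %/% tile_grid[1L]; tw <- d[2L] %/% tile_grid[2L]
  vfull <- NULL
  if (vignette_strength > 0) {
    v <- vignette_tile(th, tw, vignette_strength)
    vfull <- v[(seq_len(d[1L]) - 1L) %% th + 1L,
               (seq_len(d[2L]) - 1L) %% tw + 1L]
  }
  ps <- noise$poisson_scale %||% Inf
  gs <- noise$gaussian_sd %||% 0
  out <- lapply(stack, function(ch) {
    if (!is.null(vfull)) ch <- ch * vfull
    if (is.finite(ps) && ps > 0)
      ch <- matrix(stats::rpois(length(ch), lambda = ch * ps) / ps, d[1L], d[2L])
    if (gs > 0)
      ch <- ch + matrix(stats::rnorm(length(ch), sd = gs), d[1L], d[2L])
    pmax(ch, 0)
  })
  multimodal_sample(sample_id, out, pixel_size_um = pixel_size_um,
                    tile_grid = tile_grid, tile_shape_px = c(th, tw))
}

# ---- cohort --------------------------------------------------------------

#' Generate a synthetic cohort with ground truth
#'
#' Simulates \code{n_samples} tissue sections. Class labels follow the
#' two-class contrast the pipeline predicts: healthy sections get index
#' labels (architecture 0, chronicity 0, activity 0) and diseased sections
#' (2, 2, 1). Output is deterministic for a fixed spec (all per-sample seeds
#' are derived from \code{spec$seed}).
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return list with one element per sample, each a list with components
#'   \code{sample} (\code{\link{multimodal_sample}}), \code{roi}
#'   (ground-truth \code{\link{roi_set}}), \code{labels}
#'   (\code{\link{index_labels}}) and \code{class}
#'   (\code{"healthy"}/\code{"diseased"}).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_samples
  n_h <- round(spec$class_mix * n)
  if (spec$class_mix > 0 && spec$class_mix < 1)
    n_h <- min(max(n_h, 1L), n - 1L)
  classes <- rep(c("healthy", "diseased"), c(n_h, n - n_h))
  seeds <- derive_seeds(spec$seed, n)
  canvas <- spec$tile_grid * spec$tile_shape_px
  lapply(seq_len(n), function(i) {
    cls <- classes[i]
    preset <- spec[[cls]]
    set.seed(seeds[i])
    roi <- render_crypt_field(preset$morphology, canvas, spec$pixel_size_um)
    stack <- render_channels(roi, preset$intensity, spec$pixel_size_um)
    sid <- sprintf("S%03d_%s", i, cls)
    sample <- apply_acquisition(stack, spec$tile_grid,
                                vignette_strength = spec$vignette_strength,
                                noise = spec$noise,
                                pixel_size_um = spec$pixel_size_um,
                                sample_id = sid)
    labels <- if (cls == "healthy") index_labels(0, 0, 0) else index_labels(2, 2, 1)
    list(sample = sample, roi = roi, labels = labels, class = cls)
  })
}

#' Write a generated cohort to disk
#'
#' Writes, per sample, the multi-page image TIFF + sidecar and the two mask
#' rasters, plus a cohort-level \code{labels.csv} and the resolved spec as
#' YAML.
#'
#' @param cohort result of \code{\link{generate_cohort}}.
#' @param dir output directory (created if needed).
#' @param spec the \code{\link{cohort_spec}} used (serialised alongside).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labels <- list()
  for (item in cohort) {
    sid <- item$sample$sample_id
    write_sample(item$sample, file.path(dir, paste0(sid, ".tif")))
    write_roi_set(item$roi, file.path(dir, paste0(sid, "_crypts.tif")),
                  file.path(dir, paste0(sid, "_mucosa.tif")))
    labels[[sid]] <- item$labels
  }
  write_labels(labels, file.path(dir, "labels.csv"))
  if (!is.null(spec))
    yaml::write_yaml(spec_to_list(spec), file.path(dir, "cohort_spec.yaml"))
  invisible(dir)
}

spec_to_list <- function(spec) {
  rapply(unclass(spec), function(x) if (is.numeric(x)) as.numeric(x) else x,
         how = "replace")
}
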