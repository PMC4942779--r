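# Shared fixtures, built in code and memoised across test files.

.fix <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fix[[key]])) .fix[[key]] <- force(expr)
  .fix[[key]]
}

# Flat five-channel stack at a given level.
flat_stack <- function(level = 0.5, d = c(64L, 64L)) {
  setNames(replicate(5L, matrix(level, d[1L], d[2L]), simplify = FALSE),
           channel_names())
}

flat_sample <- function(level = 0.5, d = c(64L, 64L), tile_grid = c(1L, 1L),
                        id = "flat") {
  multimodal_sample(id, flat_stack(level, d), pixel_size_um = 1,
                    tile_grid = tile_grid)
}

# Binary disk rasterised on pixel centres.
disk_mask <- function(shape, center, r) {
  outer((seq_len(shape[1L]) - center[1L])^2,
        (seq_len(shape[2L]) - center[2L])^2, "+") <= r^2
}

# Parameter row for rasterize_crypts().
crypt_par <- function(row, col, a, b = a, angle = 0, a3 = 0, p3 = 0,
                      a4 = 0, p4 = 0, lobe = NULL) {
  data.frame(row = row, col = col, r_major = a, r_minor = b, angle = angle,
             a3 = a3, p3 = p3, a4 = a4, p4 = p4,
             lobe_dr = if (is.null(lobe)) NA_real_ else lobe[1L],
             lobe_dc = if (is.null(lobe)) NA_real_ else lobe[2L],
             lobe_r = if (is.null(lobe)) NA_real_ else lobe[3L])
}

# Small default-scale cohort shared by several files (one 512x512 mosaic
# per sample). Built once.
mini_cohort <- function() memo("mini_cohort", {
  spec <- cohort_spec(n_samples = 10, seed = 101)
  coh <- generate_cohort(spec)
  pp <- lapply(coh, function(it)
    preprocess_sample(it$sample, it$roi, preprocess_config()))
  list(cohort = coh,
       features = extract_feature_table(pp),
       labels = setNames(lapply(coh, `[[`, "labels"),
                         vapply(coh, function(it) it$sample$sample_id, "")))
})

# Full-scale study cohorts for the acceptance checks (seed 1 throughout).
extract_cohort <- function(spec) {
  coh <- generate_cohort(spec)
  pp <- lapply(coh, function(it)
    preprocess_sample(it$sample, it$roi, preprocess_config()))
  list(features = extract_feature_table(pp),
       labels = setNames(lapply(coh, `[[`, "labels"),
                         vapply(coh, function(it) it$sample$sample_id, "")),
       cohort = coh)
}

# default mixed cohort: both morphology and intensity differ between classes
acc_mixed_cohort <- function() memo("acc_mixed",
  extract_cohort(cohort_spec(n_samples = 40, seed = 1)))

# classes differ only in intensity properties (shared healthy morphology)
acc_intensity_cohort <- function() memo("acc_intensity",
  extract_cohort(cohort_spec(n_samples = 40, seed = 1,
                             diseased = list(morphology = healthy_morphology(),
                                             intensity = diseased_intensity()))))

# classes differ only in crypt geometry (shared healthy intensity)
acc_geometry_cohort <- function() memo("acc_geometry",
  extract_cohort(cohort_spec(n_samples = 20, seed = 1,
                             diseased = list(morphology = diseased_morphology(),
                                             intensity = healthy_intensity()))))

# Independent brute-force recomputation of the six first-order statistics
# (deliberately written differently from the package implementation).
brute_first_order <- function(channel, mask, L = 256L) {
  v <- channel[mask]
  v <- pmin(pmax(v, 0), 1)
  idx <- as.integer(floor(v * L))
  idx[idx >= L] <- L - 1L
  counts <- vapply(0:(L - 1L), function(k) sum(idx == k), 0L)
  p <- counts / sum(counts)
  z <- (0:(L - 1L)) / (L - 1L)
  m <- sum(z * p)
  va <- sum((z - m)^2 * p)
  ent <- 0
  for (k in seq_len(L)) if (p[k] > 0) ent <- ent - p[k] * log2(p[k])
  list(mean = m, std = sqrt(va), smoothness = 1 - 1 / (1 + va),
       third_moment = sum((z - m)^3 * p), uniformity = sum(p^2),
       entropy_bits = ent)
}

# Independent two-pass Fisher-discriminant-ratio recomputation.
brute_fdr <- function(values, labels) {
  lev <- sort(unique(labels))
  g1 <- values[labels == lev[1L]]; g2 <- values[labels == lev[2L]]
  m1 <- sum(g1) / length(g1); m2 <- sum(g2) / length(g2)
  s1 <- sum((g1 - m1)^2) / (length(g1) - 1L)
  s2 <- sum((g2 - m2)^2) / (length(g2) - 1L)
  if (s1 + s2 == 0) return(if (m1 == m2) 0 else Inf)
  (m1 - m2)^2 / (s1 + s2)
}
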