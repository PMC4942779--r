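test_that("the default catalogue has the documented structure", {
  cat_ <- default_catalogue()
  expect_identical(nrow(cat_), 87L)
  expect_identical(anyDuplicated(cat_$feature), 0L)
  expect_identical(sum(cat_$family == "geometry"), 15L)
  expect_identical(sum(cat_$kind == "texture"), 60L)
  expect_identical(sum(cat_$kind == "contrast"), 12L)
  # SHG has texture entries but enters no contrast pair
  expect_identical(sum(cat_$kind == "contrast" &
                         (cat_$modality == "SHG" | cat_$modality_b == "SHG")),
                   0L)
  # both ROI classes are covered for every modality
  expect_identical(sum(cat_$kind == "texture" & cat_$roi == "crypts"), 30L)
  expect_identical(sum(cat_$kind == "texture" & cat_$roi == "mucosa_wo_crypts"),
                   30L)
})

test_that("first-order statistics obey the histogram definitions", {
  # constant region identities
  ch <- matrix(0.7, 10, 10)
  s <- first_order_stats(ch, matrix(TRUE, 10, 10))
  expect_equal(s$mean, 0.7, tolerance = 1 / 255)
  expect_identical(s$std, 0)
  expect_identical(s$smoothness, 0)
  expect_identical(s$third_moment, 0)
  expect_identical(s$uniformity, 1)
  expect_identical(s$entropy_bits, 0)

  # half 0 / half 1: exact hand values
  ch2 <- matrix(c(0, 1), 8, 8)
  s2 <- first_order_stats(ch2, matrix(TRUE, 8, 8))
  expect_equal(s2$mean, 0.5)
  expect_equal(s2$std, 0.5)
  expect_equal(s2$smoothness, 1 - 1 / 1.25)
  expect_equal(s2$third_moment, 0)
  expect_equal(s2$uniformity, 0.5)
  expect_equal(s2$entropy_bits, 1)

  # brute-force oracle on random masked regions
  set.seed(7)
  for (i in 1:10) {
    ch3 <- matrix(runif(64 * 64), 64, 64)
    mask <- matrix(runif(64 * 64) < 0.6, 64, 64)
    got <- first_order_stats(ch3, mask)
    want <- brute_first_order(ch3, mask)
    for (f in names(want))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-10)
  }
  expect_error(first_order_stats(ch3, matrix(FALSE, 64, 64)),
               class = "ibdq_empty_roi")
})

test_that("crypt measurements match closed-form shapes", {
  # disk r = 20 px at 1 um/px
  shape <- c(64L, 64L)
  lab <- matrix(0L, shape[1], shape[2])
  lab[disk_mask(shape, c(32, 32), 20)] <- 1L
  roi <- roi_set(lab, matrix(TRUE, shape[1], shape[2]))
  m <- measure_crypts(roi, 1)
  expect_equal(m$area_um2, pi * 400, tolerance = 0.02)
  expect_equal(m$equivalent_diameter_um, 40, tolerance = 0.02)
  expect_equal(m$radius_um, m$equivalent_diameter_um / 2)
  expect_lt(m$eccentricity, 0.1)
  expect_gt(m$solidity, 0.97)

  # 10x10 filled square: area exactly 100
  lab2 <- matrix(0L, 32, 32); lab2[11:20, 11:20] <- 1L
  m2 <- measure_crypts(roi_set(lab2, matrix(TRUE, 32, 32)), 1)
  expect_identical(m2$area_um2, 100)
  expect_equal(m2$equivalent_diameter_um, sqrt(400 / pi), tolerance = 1e-10)
  expect_equal(m2$perimeter_um, 4 * 9)      # boundary steps around the square

  # ellipse with a = 2b: eccentricity sqrt(3)/2
  par <- crypt_par(40, 40, 24, 12, angle = 0.4)
  lab3 <- rasterize_crypts(par, c(80L, 80L))
  m3 <- measure_crypts(roi_set(lab3, matrix(TRUE, 80, 80)), 1)
  expect_equal(m3$eccentricity, sqrt(1 - 1 / 4), tolerance = 0.02)

  # empty field: empty frame, density zero
  roi0 <- roi_set(matrix(0L, 16, 16), matrix(TRUE, 16, 16))
  expect_identical(nrow(measure_crypts(roi0, 1)), 0L)
  expect_identical(crypt_density(roi0, 1000), 0)
})

test_that("geometry features are rotation invariant within tolerance", {
  # a non-overlapping parametric field inside the inscribed circle of a
  # generous canvas, so both orientations rasterise every crypt
  n <- 12
  ang <- 2 * pi * (seq_len(n) - 1) / n
  rad <- rep(c(60, 95), length.out = n)
  pars0 <- do.call(rbind, lapply(seq_len(n), function(i)
    crypt_par(128 + rad[i] * cos(ang[i]), 128 + rad[i] * sin(ang[i]),
              a = 11, b = 8, angle = ang[i], a3 = 0.1, p3 = 1.1)))
  rot <- 30 * pi / 180
  pars1 <- pars0
  pars1$row <- 128 + (pars0$row - 128) * cos(rot) - (pars0$col - 128) * sin(rot)
  pars1$col <- 128 + (pars0$row - 128) * sin(rot) + (pars0$col - 128) * cos(rot)
  pars1$angle <- pars0$angle + rot
  muc <- matrix(TRUE, 256, 256)
  g0 <- aggregate_geometry(
    measure_crypts(roi_set(rasterize_crypts(pars0, c(256L, 256L)), muc), 1),
    1)
  g1 <- aggregate_geometry(
    measure_crypts(roi_set(rasterize_crypts(pars1, c(256L, 256L)), muc), 1),
    1)
  for (f in c("area_mean", "perimeter_mean", "equivalent_diameter_mean",
              "eccentricity_mean", "solidity_mean", "nn_distance_mean"))
    expect_equal(g1[[f]], g0[[f]], tolerance = 0.02, label = f)
})

test_that("geometry aggregation handles degenerate fields", {
  lab <- matrix(0L, 32, 32); lab[10:14, 10:14] <- 1L
  roi <- roi_set(lab, matrix(TRUE, 32, 32))
  g <- aggregate_geometry(measure_crypts(roi, 1), crypt_density(roi, 1))
  expect_identical(unname(g["area_sd"]), 0)
  expect_identical(unname(g["nn_distance_mean"]), 0)
  expect_match(attr(g, "qc"), "geometry-degenerate")

  # two identical crypts 100 um apart
  lab2 <- matrix(0L, 64, 128)
  lab2[disk_mask(c(64, 128), c(32, 14), 5)] <- 1L
  lab2[disk_mask(c(64, 128), c(32, 114), 5)] <- 2L
  roi2 <- roi_set(lab2, matrix(TRUE, 64, 128))
  g2 <- aggregate_geometry(measure_crypts(roi2, 1), crypt_density(roi2, 1))
  expect_equal(unname(g2["nn_distance_mean"]), 100)
  expect_identical(unname(g2["nn_distance_sd"]), 0)

  # jittered lattices have larger nn-distance spread than regular ones
  reg <- render_crypt_field(morphology_spec(spacing_cv = 0,
                                            shape_irregularity = 0,
                                            crypt_radius_um = c(mean = 30, cv = 0),
                                            branch_prob = 0),
                            c(512L, 512L), 1.76, seed = 12)
  jit <- render_crypt_field(morphology_spec(spacing_cv = 0.3,
                                            shape_irregularity = 0,
                                            crypt_radius_um = c(mean = 30, cv = 0),
                                            branch_prob = 0),
                            c(512L, 512L), 1.76, seed = 12)
  gr <- aggregate_geometry(measure_crypts(reg, 1.76), crypt_density(reg, 1.76))
  gj <- aggregate_geometry(measure_crypts(jit, 1.76), crypt_density(jit, 1.76))
  expect_gt(gj[["nn_distance_sd"]], gr[["nn_distance_sd"]])
})

test_that("inter-modality contrast follows its definition", {
  mask <- matrix(TRUE, 4, 4)
  a <- matrix(0.6, 4, 4); b <- matrix(0.2, 4, 4)
  expect_equal(intermodality_contrast(a, b, mask), 0.5)
  expect_identical(intermodality_contrast(a, a, mask), 0)
  expect_equal(intermodality_contrast(b, a, mask),
               -intermodality_contrast(a, b, mask))
  expect_identical(intermodality_contrast(a * 0, b * 0, mask), 0)
  expect_error(intermodality_contrast(a, b, mask & FALSE),
               class = "ibdq_empty_roi")
})

test_that("extraction is deterministic and normalisation-invariant", {
  it <- mini_cohort()$cohort[[1]]
  cfg <- preprocess_config()
  pp <- preprocess_sample(it$sample, it$roi, cfg)
  f1 <- extract_features(pp$sample, pp$roi)
  f2 <- extract_features(pp$sample, pp$roi)
  expect_identical(f1$values, f2$values)
  expect_identical(ncol(f1$values), 87L)
  expect_false(anyNA(f1$values))

  # global pre-normalisation rescaling is absorbed by contrast adjustment
  half <- multimodal_sample(it$sample$sample_id,
                           lapply(it$sample$channels, function(ch) ch * 0.5),
                           it$sample$pixel_size_um, it$sample$tile_grid,
                           it$sample$tile_shape_px)
  pph <- preprocess_sample(half, it$roi, cfg)
  fh <- extract_features(pph$sample, pph$roi)
  irp <- f1$feature_meta$family == "irp"
  expect_equal(fh$values[, irp], f1$values[, irp], tolerance = 1e-10)
})
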