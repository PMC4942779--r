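test_that("cohort generation is deterministic and honours the class mix", {
  spec <- cohort_spec(n_samples = 2, seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)

  all_h <- generate_cohort(cohort_spec(n_samples = 3, class_mix = 1, seed = 5))
  for (it in all_h) {
    expect_identical(it$class, "healthy")
    expect_identical(unclass(it$labels),
                     unclass(index_labels(0, 0, 0)))
  }
  # strictly mixed specs represent both classes even at skewed mixes
  mixed <- generate_cohort(cohort_spec(n_samples = 4, class_mix = 0.95,
                                       seed = 5, tile_grid = c(1L, 1L)))
  expect_setequal(unique(vapply(mixed, `[[`, "", "class")),
                  c("healthy", "diseased"))
  expect_error(cohort_spec(n_samples = 1), class = "ibdq_bad_argument")
})

test_that("rendered crypt fields match the requested morphology", {
  # realized density close to the request
  roi <- render_crypt_field(healthy_morphology(), c(512L, 512L), 1.76,
                            seed = 7)
  d <- crypt_density(roi, 1.76)
  expect_lt(abs(d - 100) / 100, 0.15)
  # ground truth consistency: every crypt pixel inside the mucosa
  expect_true(all(roi$mucosa_mask[roi$crypt_labels > 0L]))

  # cv = 0, irregularity = 0: equal-area circles up to rasterisation error
  morph <- morphology_spec(crypt_radius_um = c(mean = 30, cv = 0),
                           shape_irregularity = 0, spacing_cv = 0,
                           branch_prob = 0)
  roi0 <- render_crypt_field(morph, c(512L, 512L), 1.76, seed = 8)
  areas <- measure_crypts(roi0, 1.76)$area_um2
  expect_gt(length(areas), 10)
  expect_lt(max(abs(areas - mean(areas))) / mean(areas), 0.02)

  # branching makes every object non-convex
  morphb <- morphology_spec(branch_prob = 1)
  roib <- render_crypt_field(morphb, c(512L, 512L), 1.76, seed = 9)
  sol <- measure_crypts(roib, 1.76)$solidity
  expect_true(all(sol < 0.98))

  # zero density: valid empty field
  roi_e <- render_crypt_field(morphology_spec(crypt_density_per_mm2 = 0),
                              c(256L, 256L), 1.76, seed = 1)
  expect_identical(roi_e$n_crypts, 0L)

  # infeasible packing is a typed error
  expect_error(
    render_crypt_field(morphology_spec(crypt_density_per_mm2 = 2000,
                                       crypt_radius_um = c(mean = 30, cv = 0)),
                       c(256L, 256L), 1.76, seed = 1),
    class = "ibdq_packing_failure")
})

test_that("channel rendering realises the intensity contrasts", {
  roi <- render_crypt_field(healthy_morphology(), c(256L, 256L), 1.76,
                            seed = 11)
  lam <- mucosa_wo_crypts(roi)

  # TPEF background gain scales the mucosal TPEF signal multiplicatively
  base <- healthy_intensity()
  gain2 <- do.call(intensity_spec,
                   modifyList(lapply(unclass(base), identity),
                              list(tpef_background_gain = 2)))
  s1 <- render_channels(roi, base, 1.76, seed = 21)
  s2 <- render_channels(roi, gain2, 1.76, seed = 21)
  expect_equal(mean(s2$TPEF525[lam]) / mean(s1$TPEF525[lam]), 2,
               tolerance = 1e-10)

  # no fibrosis: mucosal SHG stays below 1% of the crypt CARS level
  expect_lt(mean(s1$SHG[roi$mucosa_mask]),
            0.01 * base$crypt_level[["CARS2850"]])
  # fibrosis patches raise it markedly
  s3 <- render_channels(roi, diseased_intensity(), 1.76, seed = 21)
  expect_gt(mean(s3$SHG[roi$mucosa_mask]), 5 * mean(s1$SHG[roi$mucosa_mask]))

  # without lymphocyte spots the TPEF channels have no significant local
  # maxima above the mucosal background
  quiet <- do.call(intensity_spec,
                   modifyList(lapply(unclass(base), identity),
                              list(lymphocyte_spot_density = 0)))
  sq <- render_channels(roi, quiet, 1.76, seed = 22)
  ch <- sq$TPEF525
  thr <- mean(ch[lam]) + 3 * max(stats::sd(ch[lam]), 1e-12)
  inner <- ch[2:(nrow(ch) - 1), 2:(ncol(ch) - 1)]
  is_max <- rep(TRUE, length(inner))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- ch[2:(nrow(ch) - 1) + dr, 2:(ncol(ch) - 1) + dc]
    is_max <- is_max & (inner > nb)
  }
  expect_identical(sum(is_max & inner > thr), 0L)
})

test_that("acquisition applies vignette and noise with the stated moments", {
  stack <- flat_stack(0.5, c(256L, 256L))
  # identity when everything is disabled
  s0 <- apply_acquisition(stack, c(1L, 1L), vignette_strength = 0,
                          noise = list(poisson_scale = Inf, gaussian_sd = 0))
  expect_identical(s0$channels$CARS2850, stack$CARS2850)

  # vignette: corner/centre ratio = 1 - strength at the corner pixel
  sv <- apply_acquisition(stack, c(2L, 2L), vignette_strength = 0.3,
                          noise = list(poisson_scale = Inf, gaussian_sd = 0))
  ch <- sv$channels$TPEF458
  expect_equal(ch[1, 1] / ch[64, 64], 0.7, tolerance = 0.02)

  # Poisson-only noise at unit scale: per-pixel variance tracks the mean
  sp <- apply_acquisition(flat_stack(50, c(256L, 256L)), c(1L, 1L),
                          vignette_strength = 0,
                          noise = list(poisson_scale = 1, gaussian_sd = 0),
                          seed = 33)
  v <- sp$channels$SHG
  expect_lt(abs(stats::var(as.vector(v)) - mean(v)) / mean(v), 0.1)

  # non-divisible shape is rejected
  expect_error(apply_acquisition(flat_stack(1, c(63L, 64L)), c(2L, 2L)),
               class = "ibdq_shape_mismatch")
})

test_that("default presets separate the two classes in the expected directions", {
  coh <- mini_cohort()$cohort
  cls <- vapply(coh, `[[`, "", "class")
  px <- coh[[1]]$sample$pixel_size_um
  dens <- vapply(coh, function(it) crypt_density(it$roi, px), 0)
  eqd <- vapply(coh, function(it)
    mean(measure_crypts(it$roi, px)$equivalent_diameter_um), 0)
  tpef <- vapply(coh, function(it)
    mean(it$sample$channels$TPEF525[mucosa_wo_crypts(it$roi)]), 0)
  h <- cls == "healthy"
  expect_gt(mean(dens[h]), mean(dens[!h]))        # density loss
  expect_lt(mean(eqd[h]), mean(eqd[!h]))          # dilated, distorted crypts
  expect_lt(mean(tpef[h]), mean(tpef[!h]))        # elevated TPEF background
})
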