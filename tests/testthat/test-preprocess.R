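test_that("median filter matches a brute-force neighbourhood median", {
  # brute force with the same mirror-reflection convention
  brute_median <- function(m, k) {
    pad <- (k - 1L) %/% 2L
    refl <- function(n) c(rev(seq_len(pad)), seq_len(n), n + 1L - seq_len(pad))
    p <- m[refl(nrow(m)), refl(ncol(m))]
    out <- m
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
      out[i, j] <- sort(p[i:(i + k - 1L), j:(j + k - 1L)])[(k * k + 1L) %/% 2L]
    out
  }
  set.seed(4)
  m <- matrix(runif(256), 16, 16)
  expect_equal(median_filter(m, 3L), brute_median(m, 3L))
  expect_equal(median_filter(m, 5L), brute_median(m, 5L))

  # constant image unchanged; isolated impulse removed
  cst <- matrix(2, 10, 10)
  expect_identical(median_filter(cst, 3L), cst)
  imp <- matrix(0, 11, 11); imp[6, 6] <- 100
  expect_identical(median_filter(imp, 3L), matrix(0, 11, 11))

  expect_error(median_filter(m, 4L), class = "ibdq_even_kernel")
})

test_that("block-mean downsampling preserves means and handles masks", {
  m <- matrix(rep(c(0, 1), 32), 8, 8)        # checkerboard columns
  chk <- outer(1:8, 1:8, function(i, j) (i + j) %% 2)
  expect_equal(downsample(chk, 4L), matrix(0.5, 2, 2))
  expect_identical(downsample(m, 1L), m)
  set.seed(5)
  r <- matrix(runif(64 * 64), 64, 64)
  expect_equal(mean(downsample(r, 4L)), mean(r))
  expect_error(downsample(r, 0L), class = "ibdq_bad_argument")
})

test_that("contrast adjustment is an exact percentile stretch", {
  v <- matrix(as.numeric(0:100), 1)
  out <- adjust_contrast(v, c(0, 100))
  expect_equal(out, v / 100)
  # channel already spanning (1,99) at (0,1): near identity
  set.seed(6)
  u <- matrix(runif(10000), 100, 100)
  adj <- adjust_contrast(u, c(1, 99))
  expect_lt(max(abs(adj - u)), 0.02)
  # constant channel: zeros and a warning
  expect_warning(z <- adjust_contrast(matrix(3, 5, 5)), class = "ibdq_warning")
  expect_identical(z, matrix(0, 5, 5))
})

test_that("flat-field correction removes vignette seams and spares clean input", {
  stack <- flat_stack(0.5, c(512L, 512L))
  noise0 <- list(poisson_scale = Inf, gaussian_sd = 0)
  vig <- apply_acquisition(stack, c(2L, 2L), vignette_strength = 0.3,
                           noise = noise0)
  corr <- correct_mosaic_illumination(vig)
  for (nm in c("CARS2850", "TPEF525")) {
    before <- seam_metric(vig$channels[[nm]], c(2L, 2L))
    after <- seam_metric(corr$channels[[nm]], c(2L, 2L))
    expect_gt(before / max(after, .Machine$double.eps), 5)
    # corrected image is flat again
    cc <- corr$channels[[nm]]
    expect_lt(stats::sd(cc) / mean(cc), 0.02)
    # channel mean preserved
    expect_equal(mean(cc), mean(vig$channels[[nm]]), tolerance = 0.01)
  }
  # clean input: near identity
  clean <- apply_acquisition(stack, c(2L, 2L), vignette_strength = 0,
                             noise = noise0)
  ccl <- correct_mosaic_illumination(clean)
  expect_lt(sqrt(mean((ccl$channels$SHG - 0.5)^2)) / 0.5, 0.005)
  # idempotence
  corr2 <- correct_mosaic_illumination(corr)
  expect_lt(sqrt(mean((corr2$channels$SHG - corr$channels$SHG)^2)) /
              mean(corr$channels$SHG), 0.01)
  # the smooth (non-parametric) model removes most of the vignette
  # amplitude (its mirror-padded estimate keeps some border curvature,
  # which is why the quadratic surface is the default)
  corr_s <- correct_mosaic_illumination(vig, model = "smooth")
  amp <- function(ch) stats::sd(ch) / mean(ch)
  expect_gt(amp(vig$channels$SHG) / amp(corr_s$channels$SHG), 2)
})

test_that("the full chain keeps masks aligned and counts intact", {
  # disabled chain is the identity
  s <- flat_sample(0.4, c(64L, 64L))
  lab <- matrix(0L, 64, 64); lab[10:20, 10:20] <- 1L
  roi <- roi_set(lab, matrix(TRUE, 64, 64))
  idp <- preprocess_sample(s, roi, preprocess_config(stages = character(0)))
  expect_identical(idp$sample$channels, s$channels)
  expect_identical(idp$roi$crypt_labels, roi$crypt_labels)

  # after x4 the mask grid still matches the image grid
  it <- mini_cohort()$cohort[[1]]
  pp <- preprocess_sample(it$sample, it$roi, preprocess_config())
  expect_identical(dim(pp$roi$crypt_labels), dim(pp$sample$channels[[1]]))
  expect_equal(pp$sample$pixel_size_um, it$sample$pixel_size_um * 4)
  expect_true(all(vapply(pp$sample$channels,
                         function(ch) all(ch >= 0 & ch <= 1), TRUE)))

  # crypt objects of >= 8 px diameter survive block-majority downsampling
  lab2 <- matrix(0L, 64, 64)
  k <- 0L
  for (cr in c(10, 30, 50)) for (cc in c(10, 30, 50)) {
    k <- k + 1L
    lab2[disk_mask(c(64, 64), c(cr, cc), 4.5)] <- k
  }
  roi2 <- roi_set(lab2, matrix(TRUE, 64, 64))
  s2 <- flat_sample(0.4, c(64L, 64L))
  pp2 <- preprocess_sample(s2, roi2,
                           preprocess_config(stages = c("downsample")))
  expect_identical(pp2$roi$n_crypts, roi2$n_crypts)

  # tie-break toward the lower label keeps labels contiguous and valid
  expect_true(all(sort(unique(as.vector(pp2$roi$crypt_labels))) ==
                    0:pp2$roi$n_crypts))
})
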