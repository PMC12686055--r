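cal <- calibration(5 / 95)

test_that("gaussian smoothing uses a unit-sum kernel evaluated on the grid", {
  const <- matrix(0.37, 20, 20)
  expect_equal(gaussian_smooth(const, 51, 0.8), const)

  # unit impulse reproduces the normalized kernel values
  img <- matrix(0, 31, 31); img[16, 16] <- 1
  out <- gaussian_smooth(img, 11, 2)
  g <- exp(-((-5:5)^2) / (2 * 2^2))
  k <- outer(g, g); k <- k / sum(k)
  expect_equal(out[11:21, 11:21], k, tolerance = 1e-10)

  # interior-supported intensity is conserved by a unit-sum kernel
  img2 <- matrix(0, 40, 40); img2[18:22, 18:22] <- runif(25)
  expect_equal(sum(gaussian_smooth(img2, 7, 1.2)), sum(img2), tolerance = 1e-10)

  expect_error(gaussian_smooth(const, 10, 1), "odd")
})

test_that("global threshold is an inclusive minimum and not shift-invariant", {
  img <- matrix(0.5, 4, 4)
  expect_true(all(global_threshold_mask(img, 0.4)))
  expect_true(all(global_threshold_mask(img, 0.5)))   # inclusive at boundary
  expect_false(any(global_threshold_mask(img * 0 + 0.39, 0.4)))
  withr::local_seed(1)
  img2 <- matrix(runif(100, 0, 0.6), 10, 10)
  m1 <- global_threshold_mask(img2, 0.4)
  m2 <- global_threshold_mask(img2 + 0.2, 0.4)
  expect_false(identical(m1, m2))                     # global mode shifts
})

test_that("adaptive threshold equals the brute-force window-mean loop", {
  withr::local_seed(2)
  for (i in 1:6) {
    img <- matrix(runif(16 * 16), 16, 16)
    h <- sample(1:5, 1); off <- runif(1, 0, 0.2)
    got <- adaptive_threshold_mask(img, h, off)
    want <- img >= bf_window_mean(img, h) + off
    expect_identical(got, want)
  }
  # 5x5 printed-scale check
  img5 <- matrix(seq(0, 1, length.out = 25), 5, 5)
  expect_identical(adaptive_threshold_mask(img5, 2, 0.05),
                   img5 >= bf_window_mean(img5, 2) + 0.05)
})

test_that("adaptive mask is invariant under additive brightness shifts", {
  withr::local_seed(7)
  img <- matrix(runif(400, 0, 0.5), 20, 20)
  base <- adaptive_threshold_mask(img, 10, 0.1)
  for (c in c(0.1, 0.3, -0.05)) {
    expect_identical(adaptive_threshold_mask(img + c, 10, 0.1), base)
  }
  # constant image with positive offset has no bright pixels
  expect_false(any(adaptive_threshold_mask(matrix(0.5, 30, 30), 10, 0.01)))
})

test_that("cluster labeling matches flood fill, respects the ROI and converts areas", {
  roi <- full_frame_roi(20, 30, cal)
  mask <- matrix(FALSE, 20, 30)
  mask[3:5, 3:5] <- TRUE
  mask[3:5, 10:12] <- TRUE
  res <- label_clusters(mask, roi)
  expect_equal(res$n_clusters, 2L)
  expect_equal(res$areas_px, c(9L, 9L))
  expect_equal(res$areas_um2, rep(9 * (5 / 95)^2, 2))
  expect_equal(res$total_area_um2, sum(res$areas_um2))
  expect_equal(res$area_per_length, res$total_area_um2 / roi$length_um)

  # blob outside the ROI is excluded
  narrow <- grow_skeleton(horizontal_skeleton(20, 30, row = 10, cal = cal), 2)
  outside <- matrix(FALSE, 20, 30); outside[1:2, 1:4] <- TRUE
  inside <- matrix(FALSE, 20, 30); inside[9:11, 5:7] <- TRUE
  res2 <- label_clusters(outside | inside, narrow)
  expect_equal(res2$n_clusters, 1L)
  expect_equal(sum(res2$areas_px), sum(inside))

  # random masks against the flood-fill oracle, both connectivities
  withr::local_seed(31)
  for (i in 1:8) {
    m <- matrix(runif(16 * 16) < 0.35, 16, 16)
    for (conn in c(4L, 8L)) {
      res <- label_clusters(m, full_frame_roi(16, 16, cal), connectivity = conn)
      oracle <- bf_flood_label(m, conn)
      expect_equal(res$n_clusters, max(oracle))
      expect_equal(sort(res$areas_px), sort(tabulate(oracle[oracle > 0])))
      expect_equal(res$labels > 0, oracle > 0)
    }
  }
})

test_that("4-connectivity never merges what 8-connectivity splits", {
  withr::local_seed(5)
  roi <- full_frame_roi(16, 16, cal)
  for (i in 1:5) {
    m <- matrix(runif(256) < 0.3, 16, 16)
    r4 <- label_clusters(m, roi, connectivity = 4L)
    r8 <- label_clusters(m, roi, connectivity = 8L)
    expect_gte(r4$n_clusters, r8$n_clusters)
    expect_equal(sum(r4$areas_px), sum(r8$areas_px))  # same bright set
  }
})

test_that("labeling agrees with EBImage's 4-connected bwlabel", {
  withr::local_seed(17)
  m <- matrix(runif(24 * 24) < 0.3, 24, 24)
  res <- label_clusters(m, full_frame_roi(24, 24, cal), connectivity = 4L)
  eb <- EBImage::bwlabel(matrix(as.numeric(m), 24, 24))
  expect_equal(res$n_clusters, max(eb))
  expect_equal(sort(res$areas_px), sort(tabulate(eb[eb > 0])))
})

test_that("pipeline recovers planted puncta counts in both modes' valid regimes", {
  for (k in c(0L, 3L, 12L)) {
    sp <- scene_params(n_puncta = k, punctum_peak = 0.8, noise_sd = 0)
    sc <- make_puncta_image(sp, seed = 100 + k)
    roi <- full_frame_roi(256, 256, cal)
    for (mode in c("adaptive", "global")) {
      res <- run_cluster_pipeline(sc$image, roi, cluster_params(mode))
      expect_equal(res$n_clusters, k)
    }
  }
})

test_that("gradient backgrounds defeat the global threshold but not the adaptive one", {
  sp <- scene_params(n_puncta = 12L, background = "linear-gradient",
                     gradient_range = c(0, 0.5), punctum_peak = 0.8)
  sc <- make_puncta_image(sp, seed = 11)
  roi <- full_frame_roi(256, 256, cal)
  ra <- run_cluster_pipeline(sc$image, roi, cluster_params("adaptive"))
  rg <- run_cluster_pipeline(sc$image, roi, cluster_params("global"))
  expect_equal(ra$n_clusters, 12L)
  expect_false(rg$n_clusters == 12L)
  # the failure mode: the gradient itself crosses 0.4, so an empty scene
  # already yields a spurious global cluster while adaptive mode stays clean
  empty <- make_puncta_image(scene_params(n_puncta = 0L,
                                          background = "linear-gradient",
                                          gradient_range = c(0, 0.5)), seed = 1)
  re_g <- run_cluster_pipeline(empty$image, roi, cluster_params("global"))
  re_a <- run_cluster_pipeline(empty$image, roi, cluster_params("adaptive"))
  expect_gt(re_g$n_clusters, 0L)
  expect_equal(re_a$n_clusters, 0L)
})

test_that("raising the global threshold never grows the clustered area", {
  withr::local_seed(23)
  img <- gaussian_smooth(matrix(runif(40 * 40), 40, 40), 5, 1)
  roi <- full_frame_roi(40, 40, cal)
  areas <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th) {
    label_clusters(global_threshold_mask(img, th), roi)$total_area_um2
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("every labeled pixel is inside the ROI and areas sum consistently", {
  withr::local_seed(41)
  m <- matrix(runif(30 * 30) < 0.4, 30, 30)
  roi <- grow_skeleton(horizontal_skeleton(30, 30, cal = cal), 6)
  res <- label_clusters(m, roi)
  expect_true(all(roi$mask[res$labels > 0]))
  expect_equal(sum(res$areas_px), sum(m & roi$mask))
  expect_equal(res$n_clusters, length(unique(res$labels[res$labels > 0])))
})

test_that("baseline normalization divides by the pre-treatment mean", {
  expect_equal(normalize_timeseries(c(2, 2, 2, 2, 1))[5], 0.5)
  expect_equal(normalize_timeseries(rep(3, 8)), rep(1, 8))
  expect_equal(normalize_timeseries(c(1, 2, 3, 4, 5))[5], 2)
  expect_error(normalize_timeseries(c(1, 2, 3)), "baseline")
  expect_error(normalize_timeseries(c(0, 0, 0, 0, 1)), "zero")
})

test_that("cluster_table reports per-cluster centroids and areas", {
  roi <- full_frame_roi(12, 12, cal)
  m <- matrix(FALSE, 12, 12); m[2:3, 2:3] <- TRUE; m[8:10, 8] <- TRUE
  tab <- cluster_table(label_clusters(m, roi))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$area_px, c(4L, 3L))
  expect_equal(tab$centroid_row, c(2.5, 9))
  expect_equal(tab$centroid_col, c(2.5, 8))
})
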