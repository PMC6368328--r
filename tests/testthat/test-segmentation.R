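# Segmentation and per-nucleus feature extraction.

spec1 <- acquisition_spec(pixel_size_um = 1, height_px = 200, width_px = 200)

test_that("disjoint disks are labelled one nucleus each", {
  img <- matrix(0, 200, 200)
  centers <- expand.grid(cy = c(40, 100, 160), cx = c(40, 100, 160))
  centers <- centers[1:9, ]
  for (i in seq_len(9))
    img <- img + draw_disk(200, 200, centers$cy[i], centers$cx[i], 10)
  img <- img + draw_disk(200, 200, 100, 70, 6)  # a 10th, smaller one
  labels <- segment_nuclei(img, spec1, segmentation_params())
  expect_equal(max(labels), 10)
  expect_true(all(sort(unique(as.vector(labels))) == 0:10))
})

test_that("a blank image yields zero labels, not an error", {
  labels <- segment_nuclei(matrix(0, 50, 50), spec1, segmentation_params())
  expect_equal(max(labels), 0)
  expect_error(segment_nuclei(array(0, c(4, 4, 2)), spec1,
                              segmentation_params()),
               "2D")
})

test_that("a fused disk pair splits under watershed but not without it", {
  # centres 1.5 r apart: one connected blob with two distance-transform
  # maxima (verified directly on the distance map)
  r <- 10
  img <- pmax(draw_disk(120, 120, 60, 50, r), draw_disk(120, 120, 60, 65, r))
  dm <- as.matrix(EBImage::distmap(EBImage::Image(img > 0)))
  left_max <- max(dm[, 1:57]); right_max <- max(dm[, 58:120])
  saddle <- min(dm[60, 55:60])
  expect_true(left_max > saddle + 2 && right_max > saddle + 2)

  labels_split <- segment_nuclei(img, spec1, segmentation_params())
  labels_merge <- segment_nuclei(img, spec1,
                                 segmentation_params(split_touching = FALSE))
  expect_equal(max(labels_split), 2)
  expect_equal(max(labels_merge), 1)
})

test_that("small objects and edge-touching objects are filtered", {
  img <- draw_disk(200, 200, 100, 100, 8) +
    draw_disk(200, 200, 50, 50, 0.9) +     # 1 px, below 5 um^2 at 1 um/px
    draw_disk(200, 200, 3, 100, 10)        # clipped by the border
  labels <- segment_nuclei(img, spec1, segmentation_params())
  expect_equal(max(labels), 1)
  labels2 <- segment_nuclei(img, spec1,
                            segmentation_params(exclude_edge = FALSE))
  expect_equal(max(labels2), 2)
})

test_that("circle and ellipse morphometry match closed forms", {
  img <- draw_disk(64, 64, 32, 32, 10, value = 7)
  labels <- segment_nuclei(img, spec1, segmentation_params())
  rec <- extract_features(labels, list(hoechst = img), spec1)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$area_um2, pi * 100, tolerance = 0.02)
  expect_equal(rec$equivalent_radius_um, 10, tolerance = 0.01)
  expect_equal(rec$mean_hoechst, 7)              # constant field: exact
  expect_gt(rec$elongation, 0.97)

  ell <- draw_ellipse(80, 80, 40, 40, a = 20, b = 10)
  lab2 <- segment_nuclei(ell, spec1, segmentation_params())
  rec2 <- extract_features(lab2, list(hoechst = ell), spec1)
  expect_equal(rec2$elongation, 0.5, tolerance = 0.05)
})

test_that("integrated intensity equals brute-force pixel summation", {
  fld <- make_noiseless_field(seed = 21, n_nuclei = 30, side_px = 500)
  hoechst <- fld$image[, , "hoechst"]
  labels <- segment_nuclei(hoechst, fld$spec, segmentation_params())
  rec <- extract_features(labels, list(hoechst = hoechst), fld$spec)
  oracle <- brute_label_stats(labels, hoechst)
  expect_equal(rec$integrated_hoechst, oracle$sum, tolerance = 1e-9)
  expect_equal(rec$mean_hoechst, oracle$mean, tolerance = 1e-9)
  expect_equal(rec$area_um2 / fld$spec$pixel_size_um^2, oracle$npx,
               tolerance = 1e-9)
})

test_that("elongation is rotation invariant", {
  ell <- draw_ellipse(100, 100, 50, 50, a = 18, b = 12)
  rec0 <- extract_features(segment_nuclei(ell, spec1, segmentation_params()),
                           list(hoechst = ell), spec1)
  # 90 degree rotation (transpose + flip): exact
  ell90 <- t(ell)[, rev(seq_len(100))]
  rec90 <- extract_features(
    segment_nuclei(ell90, spec1, segmentation_params()),
    list(hoechst = ell90), spec1)
  expect_equal(rec90$elongation, rec0$elongation, tolerance = 1e-12)
  # arbitrary angle: small discretisation drift only
  ell37 <- draw_ellipse(100, 100, 50, 50, a = 18, b = 12, theta = 37 * pi / 180)
  rec37 <- extract_features(
    segment_nuclei(ell37, spec1, segmentation_params()),
    list(hoechst = ell37), spec1)
  expect_lt(abs(rec37$elongation - rec0$elongation), 0.02)
})

test_that("extract_features rejects shape mismatches", {
  labels <- matrix(0L, 10, 10)
  expect_error(extract_features(labels, list(hoechst = matrix(0, 5, 5)),
                                spec1),
               "shape")
})

test_that("HNF4a classification thresholds per-nucleus means", {
  rec <- data.frame(nucleus_id = 1:2, mean_hnf4a = c(100, 5))
  out <- classify_hnf4a(rec, threshold = 50)
  expect_identical(out$hnf4a_positive, c(TRUE, FALSE))

  rec2 <- data.frame(nucleus_id = 1:3, mean_hnf4a = rep(20, 3))
  out2 <- classify_hnf4a(rec2, threshold = 30)
  expect_identical(out2$hnf4a_positive, rep(FALSE, 3))
  expect_error(classify_hnf4a(rec2, threshold = "otsu"), "distinct")
})

test_that("noiseless fields classify HNF4a status identically to ground truth", {
  fld <- make_noiseless_field(seed = 17, n_nuclei = 80)
  labels <- segment_nuclei(fld$image[, , "hoechst"], fld$spec,
                           segmentation_params())
  rec <- extract_features(labels, fld$image, fld$spec)
  rec <- classify_hnf4a(rec, "otsu")
  m <- match_to_truth(rec, fld$truth)
  expect_equal(nrow(m), nrow(fld$truth))
  truth_status <- fld$truth$hnf4a_positive[match(m$truth_id,
                                                 fld$truth$nucleus_id)]
  seg_status <- rec$hnf4a_positive[match(m$nucleus_id, rec$nucleus_id)]
  expect_identical(seg_status, truth_status)
})

test_that("vector Otsu separates two well-spread groups at their gap", {
  set.seed(2)
  x <- c(rnorm(50, 10, 1), rnorm(50, 50, 2))
  t <- otsu_threshold(x)
  expect_gt(t, 15); expect_lt(t, 45)
  expect_error(otsu_threshold(rep(3, 10)), "distinct")
})
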