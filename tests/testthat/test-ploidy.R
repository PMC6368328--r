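# DNA-content interpolation, 2n calibration, class assignment, gates.

# Build a calibration from fabricated HNF4a-negative records.
make_calibration <- function(contents, cfg = gate_config(min_reference_n = 1)) {
  rec <- data.frame(nucleus_id = seq_along(contents),
                    area_um2 = rep(30, length(contents)),
                    elongation = 1,
                    hnf4a_positive = FALSE,
                    dna_content = contents)
  calibrate_2n(rec, cfg)
}

test_that("circularity gate keeps strictly > 0.8 and preserves order", {
  rec <- data.frame(nucleus_id = 1:3, elongation = c(0.85, 0.80, 0.79))
  out <- circularity_gate(rec, gate_config())
  expect_equal(out$nucleus_id, 1L)

  rec2 <- data.frame(nucleus_id = 5:1, elongation = rep(1, 5))
  expect_equal(circularity_gate(rec2)$nucleus_id, 5:1)
  expect_equal(nrow(circularity_gate(rec[0, ])), 0)
})

test_that("spherical volume interpolation matches closed forms", {
  expect_equal(interpolate_volume(pi), 4 * pi / 3, tolerance = 1e-12)
  expect_equal(interpolate_volume(4 * pi), 32 * pi / 3, tolerance = 1e-12)
  expect_error(interpolate_volume(0), "positive")
  expect_error(interpolate_volume(-3), "positive")
})

test_that("DNA content is mean intensity times interpolated volume", {
  rec <- data.frame(nucleus_id = 1:2, mean_hoechst = c(10, 20),
                    area_um2 = c(pi, pi))
  out <- compute_dna_content(rec)
  expect_equal(out$dna_content[1], 10 * 4 * pi / 3, tolerance = 1e-12)
  expect_equal(out$dna_content[2], 2 * out$dna_content[1],
               tolerance = 1e-12)  # linear in intensity
  expect_error(compute_dna_content(data.frame(area_um2 = 1)), "hoechst")
})

test_that("2n calibration is the median of gated HNF4a-negative contents", {
  cal <- make_calibration(c(38, 40, 42),
                          gate_config(min_reference_n = 3))
  expect_equal(cal$reference_content, 40)
  expect_equal(cal$n_reference, 3L)
  expect_equal(cal$statistic, "median")

  rec_pos <- data.frame(nucleus_id = 1, area_um2 = 30, elongation = 1,
                        hnf4a_positive = TRUE, dna_content = 50)
  expect_error(calibrate_2n(rec_pos, gate_config(min_reference_n = 1)),
               "reference")
})

test_that("the NPC area cap excludes oversized reference candidates", {
  rec <- data.frame(nucleus_id = 1:4, area_um2 = c(30, 30, 30, 90),
                    elongation = 1, hnf4a_positive = FALSE,
                    dna_content = c(38, 40, 42, 1000))
  cal <- calibrate_2n(rec, gate_config(min_reference_n = 3))
  expect_equal(cal$reference_content, 40)
  expect_equal(cal$n_reference, 3L)
})

test_that("ploidy classes follow the nearest log2 doubling with a half-open window", {
  cal <- make_calibration(100)
  rec <- data.frame(nucleus_id = 1:3, dna_content = c(100, 200, 145))
  est <- estimate_ploidy(rec, cal, gate_config())
  expect_equal(est$ploidy_c, c(2, 4, 2.9))
  expect_equal(as.character(est$class), c("2c", "4c", "4c"))
  # 2.9: log2 = 1.536, distance to 4c (log2 = 2) is 0.464 < 0.5

  # exhaustive check of the assignment rule on a dense ploidy grid
  grid <- 2^seq(0.2, 4.8, by = 0.013)
  rec_g <- data.frame(nucleus_id = seq_along(grid),
                      dna_content = 100 * grid / 2)
  est_g <- estimate_ploidy(rec_g, cal, gate_config())
  oracle <- vapply(grid, function(p) {
    d <- log2(p) - log2(c(2, 4, 8, 16))
    j <- which.min(abs(d))
    if (d[j] >= -0.5 && d[j] < 0.5) c("2c", "4c", "8c", "16c")[j]
    else "unassigned"
  }, "")
  expect_identical(as.character(est_g$class), oracle)
})

test_that("shrinking the class window only turns assignments into unassigned", {
  cal <- make_calibration(100)
  set.seed(42)
  rec <- data.frame(nucleus_id = 1:500,
                    dna_content = 100 * 2^runif(500, -0.8, 3.8) / 2)
  wide <- estimate_ploidy(rec, cal, gate_config(class_window_log2 = 0.5))
  narrow <- estimate_ploidy(rec, cal, gate_config(class_window_log2 = 0.2))
  moved <- which(as.character(wide$class) != as.character(narrow$class))
  expect_true(all(narrow$class[moved] == "unassigned"))
})

test_that("peak detection resolves unimodal and too-small inputs", {
  set.seed(5)
  x <- rlnorm(1500, log(120), 0.12)
  pk <- detect_content_peaks(x, k_max = 4)
  expect_length(pk, 1)
  # histogram oracle on the same sample
  h <- hist(log2(x), breaks = 40, plot = FALSE)
  mode_oracle <- 2^h$mids[which.max(h$counts)]
  expect_lt(abs(pk / mode_oracle - 1), 0.1)
  expect_error(detect_content_peaks(rlnorm(10, 1, 1)), "100")
  expect_error(detect_content_peaks(rep(c(1, -1), 100)), "positive")
})

test_that("2c and small-hepatocyte gates honour their printed bounds", {
  rec <- data.frame(
    nucleus_id = 1:6,
    hnf4a_positive = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    area_um2 = c(30, 19.5, 19.99, 34.99, 30, 74.9),
    elongation = c(0.9, 0.9, 0.9, 0.9, 0.9, 0.9))
  g <- gate_2c(rec, gate_config())
  expect_equal(g$records$nucleus_id, c(1L, 3L, 4L))  # inclusive bounds
  expect_equal(g$count, 3)

  s <- gate_small_hepatocytes(rec, gate_config())
  expect_equal(s$records$nucleus_id, c(1L, 2L, 3L, 4L, 6L))
  rec$area_um2[6] <- 75.0                              # strict bound
  expect_equal(gate_small_hepatocytes(rec, gate_config())$count, 4)
})

test_that("the 2c gate is always a subset of the small-hepatocyte gate", {
  set.seed(8)
  rec <- data.frame(nucleus_id = 1:300,
                    hnf4a_positive = runif(300) < 0.6,
                    area_um2 = runif(300, 5, 120),
                    elongation = runif(300, 0.5, 1))
  ids2c <- gate_2c(rec)$records$nucleus_id
  ids_small <- gate_small_hepatocytes(rec)$records$nucleus_id
  expect_true(all(ids2c %in% ids_small))
})

test_that("population densities divide counts by tissue area", {
  rec <- data.frame(nucleus_id = 1:150,
                    hnf4a_positive = rep(c(TRUE, FALSE), c(100, 50)))
  d <- population_densities(rec, tissue_area_mm2 = 2)
  expect_equal(d$density_per_mm2[d$population == "hnf4a_positive"], 50)
  expect_equal(d$density_per_mm2[d$population == "hnf4a_negative"], 25)
  d0 <- population_densities(rec[0, ], 2)
  expect_true(all(d0$density_per_mm2 == 0))
  expect_error(population_densities(rec, 0), "positive")
})

test_that("size distribution bins HNF4a+ areas and conserves counts", {
  rec <- data.frame(nucleus_id = 1:4,
                    hnf4a_positive = c(TRUE, TRUE, TRUE, FALSE),
                    area_um2 = c(10, 20, 30, 25))
  h <- size_distribution(rec, c(0, 15, 35))
  expect_equal(h$count, c(1, 2))
  expect_equal(sum(h$count), 3)
  expect_equal(sum(size_distribution(rec[0, ], c(0, 15, 35))$count), 0)
  expect_error(size_distribution(rec, c(10, 5)), "increasing")
})
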