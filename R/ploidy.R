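## In-situ ploidy estimation.
##
## Per-nucleus DNA content is modelled as mean nuclear Hoechst intensity
## (DNA density) multiplied by an interpolated spherical nuclear volume,
## where the sphere radius is the equivalent radius of the projected 2D
## nuclear area. The content scale is calibrated internally against the
## circular HNF4a-negative nonparenchymal nuclei of the same field, which
## are taken to be diploid (2n): their median content defines 2c. Ploidy
## classes are then assigned by nearest DNA-content doubling in log2
## space.

#' Circularity gate
#'
#' Keeps the records whose fitted-ellipse elongation is strictly greater
#' than `cfg$elongation_min` (default 0.8), removing elongated and
#' bilobular nuclei whose projected-area-to-volume interpolation would be
#' biased. Input order is preserved.
#'
#' @param records Feature data frame with an `elongation` column.
#' @param cfg A [gate_config()].
#' @return The gated subset of `records` (possibly empty).
#' @export
circularity_gate <- function(records, cfg = gate_config()) {
  stopifnot(inherits(cfg, "gate_config"))
  if (!"elongation" %in% names(records))
    stop("records must contain an 'elongation' column")
  records[records$elongation > cfg$elongation_min, , drop = FALSE]
}

#' Interpolate nuclear volume from projected area
#'
#' Treats the nucleus as a sphere whose radius is the equivalent radius
#' of the projected area: `r = sqrt(area/pi)`, `V = (4/3) pi r^3`.
#'
#' @param area_um2 Numeric vector of projected nuclear areas, um^2 (> 0).
#' @return Nuclear volumes in um^3.
#' @examples
#' interpolate_volume(pi)      # unit sphere: 4*pi/3
#' interpolate_volume(4 * pi)  # r = 2: 32*pi/3
#' @export
interpolate_volume <- function(area_um2) {
  if (!is.numeric(area_um2) || any(!is.finite(area_um2)) ||
      any(area_um2 <= 0))
    stop("'area_um2' must be positive and finite")
  r <- sqrt(area_um2 / pi)
  (4 / 3) * pi * r^3
}

#' Per-nucleus DNA content
#'
#' `dna_content = mean Hoechst intensity x interpolated spherical volume`,
#' in intensity x um^3 units. This is the uncalibrated quantity; dividing
#' by the 2n reference content (x2) converts it to c units.
#'
#' @param records Feature data frame with `mean_hoechst` and `area_um2`.
#' @return `records` with a `dna_content` column appended.
#' @export
compute_dna_content <- function(records) {
  if (!all(c("mean_hoechst", "area_um2") %in% names(records)))
    stop("records must contain 'mean_hoechst' and 'area_um2' ",
         "(is the Hoechst channel present?)")
  records$dna_content <- records$mean_hoechst *
    interpolate_volume(records$area_um2)
  records
}

#' Calibrate the 2n reference from HNF4a-negative nuclei
#'
#' The HNF4a-negative (nonparenchymal) nuclei within the gated population
#' serve as an internal diploid control: the median of their DNA contents
#' is taken as the 2n (= 2c) reference content. Candidates may be further
#' restricted by an area cap (`cfg$npc_area_max_um2`, default 40 um^2)
#' to guard against missegmented clumps.
#'
#' @param records Circularity-gated feature data frame with
#'   `hnf4a_positive` set and `dna_content` computed (computed on the fly
#'   if absent).
#' @param cfg A [gate_config()].
#' @return An object of class `ploidy_calibration` with fields
#'   `reference_content`, `n_reference`, `statistic`.
#' @export
calibrate_2n <- function(records, cfg = gate_config()) {
  stopifnot(inherits(cfg, "gate_config"))
  if (!"hnf4a_positive" %in% names(records) ||
      any(is.na(records$hnf4a_positive)))
    stop("HNF4a statuses must be set before calibration")
  if (!"dna_content" %in% names(records))
    records <- compute_dna_content(records)
  ref <- records[!records$hnf4a_positive &
                   records$area_um2 <= cfg$npc_area_max_um2, , drop = FALSE]
  if (nrow(ref) < cfg$min_reference_n)
    stop(sprintf(paste0("2n calibration needs >= %d HNF4a-negative ",
                        "reference nuclei but only %d are available"),
                 cfg$min_reference_n, nrow(ref)))
  structure(list(reference_content = stats::median(ref$dna_content),
                 n_reference = nrow(ref),
                 statistic = "median"),
            class = "ploidy_calibration")
}

#' @export
print.ploidy_calibration <- function(x, ...) {
  cat(sprintf("ploidy_calibration: 2n reference content %.4g (%s of %d nuclei)\n",
              x$reference_content, x$statistic, x$n_reference))
  invisible(x)
}

#' Estimate per-nucleus ploidy
#'
#' Converts DNA content to continuous c units,
#' `ploidy_c = 2 * dna_content / reference_content`, and assigns the
#' discrete class whose log2 distance to `ploidy_c` is smallest among
#' {2c, 4c, 8c, 16c}, provided that distance falls inside the half-open
#' window `[-class_window_log2, class_window_log2)`; otherwise the
#' nucleus is `unassigned`. With the default window of 0.5 the class
#' boundaries sit at the geometric midpoints between adjacent doublings.
#'
#' @param records Feature data frame with `dna_content` (computed on the
#'   fly if absent).
#' @param calibration A `ploidy_calibration` from [calibrate_2n()].
#' @param cfg A [gate_config()].
#' @return A data frame with `nucleus_id`, `dna_content`, `ploidy_c`,
#'   `class` (factor with levels `2c`, `4c`, `8c`, `16c`, `unassigned`).
#' @export
estimate_ploidy <- function(records, calibration, cfg = gate_config()) {
  stopifnot(inherits(calibration, "ploidy_calibration"),
            inherits(cfg, "gate_config"))
  if (calibration$reference_content <= 0)
    stop("calibration reference_content must be positive")
  if (!"dna_content" %in% names(records))
    records <- compute_dna_content(records)
  ploidy_c <- 2 * records$dna_content / calibration$reference_content
  lev <- c("2c", "4c", "8c", "16c", "unassigned")
  cls_val <- c(2, 4, 8, 16)
  lp <- log2(ploidy_c)
  # signed distance to each class centre; half-open window [-w, w)
  cls <- rep("unassigned", length(ploidy_c))
  if (length(ploidy_c)) {
    d <- outer(lp, log2(cls_val), `-`)
    j <- max.col(-abs(d), ties.method = "first")
    dj <- d[cbind(seq_along(j), j)]
    ok <- dj >= -cfg$class_window_log2 & dj < cfg$class_window_log2
    cls[ok] <- c("2c", "4c", "8c", "16c")[j[ok]]
  }
  data.frame(nucleus_id = records$nucleus_id,
             dna_content = records$dna_content,
             ploidy_c = ploidy_c,
             class = factor(cls, levels = lev))
}

#' Detect ploidy peaks in a DNA-content distribution
#'
#' Finds the local maxima of a Gaussian kernel-density estimate of
#' log2(content) (bandwidth by Silverman's rule-of-thumb, the default of
#' [stats::density()]), returned in ascending order on the content scale.
#' If more than `k_max` maxima exist, the `k_max` highest are kept.
#'
#' @param contents Numeric vector of positive DNA contents, length >= 100.
#' @param k_max Maximum number of peaks to report (1--5).
#' @param min_rel_height Local maxima below this fraction of the tallest
#'   peak are discarded as density-estimate ripple (default 0.05).
#' @return Numeric vector of peak locations in content units.
#' @export
detect_content_peaks <- function(contents, k_max = 4L,
                                 min_rel_height = 0.05) {
  if (length(contents) < 100L)
    stop("peak detection needs >= 100 content values")
  if (any(contents <= 0)) stop("contents must be positive")
  k_max <- as.integer(k_max)
  stopifnot(k_max >= 1L, k_max <= 5L)
  d <- stats::density(log2(contents))
  y <- d$y
  i <- which(y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf))
  i <- i[y[i] >= min_rel_height * max(y)]
  if (length(i) > k_max)
    i <- sort(i[order(y[i], decreasing = TRUE)[seq_len(k_max)]])
  2^d$x[i]
}

#' The 2c hepatocyte gate
#'
#' The 2c hepatocyte population is defined as the HNF4a-positive nuclei
#' within the 19.99--34.99 um^2 nuclear size range (inclusive bounds)
#' with elongation strictly above 0.8.
#'
#' @param records Feature data frame with `hnf4a_positive`, `area_um2`
#'   and `elongation` set.
#' @param cfg A [gate_config()].
#' @return A list with `count` and `records` (the gated subset).
#' @export
gate_2c <- function(records, cfg = gate_config()) {
  stopifnot(inherits(cfg, "gate_config"))
  keep <- records$hnf4a_positive %in% TRUE &
    records$area_um2 >= cfg$area_2c_min_um2 &
    records$area_um2 <= cfg$area_2c_max_um2 &
    records$elongation > cfg$elongation_min
  list(count = sum(keep), records = records[keep, , drop = FALSE])
}

#' The small-hepatocyte gate
#'
#' Small hepatocytes are HNF4a-positive nuclei with area strictly below
#' 75 um^2.
#'
#' @inheritParams gate_2c
#' @return A list with `count` and `records`.
#' @export
gate_small_hepatocytes <- function(records, cfg = gate_config()) {
  stopifnot(inherits(cfg, "gate_config"))
  keep <- records$hnf4a_positive %in% TRUE &
    records$area_um2 < cfg$small_area_max_um2
  list(count = sum(keep), records = records[keep, , drop = FALSE])
}

#' Hepatocyte and NPC nuclear densities
#'
#' @param records Feature data frame with `hnf4a_positive` set.
#' @param tissue_area_mm2 Analysed tissue area in mm^2 (> 0).
#' @return A data frame with one row per HNF4a status
#'   (`hnf4a_positive`, `hnf4a_negative`): `count` and `density_per_mm2`.
#' @export
population_densities <- function(records, tissue_area_mm2) {
  if (!is.numeric(tissue_area_mm2) || tissue_area_mm2 <= 0)
    stop("'tissue_area_mm2' must be positive")
  pos <- sum(records$hnf4a_positive %in% TRUE)
  neg <- sum(records$hnf4a_positive %in% FALSE)
  data.frame(population = c("hnf4a_positive", "hnf4a_negative"),
             count = c(pos, neg),
             density_per_mm2 = c(pos, neg) / tissue_area_mm2)
}

#' Size distribution of hepatocyte nuclei
#'
#' Histogram of HNF4a-positive nuclear areas over caller-supplied bin
#' edges (left-closed, right-open bins; values outside the edge span are
#' not counted).
#'
#' @param records Feature data frame with `hnf4a_positive` and `area_um2`.
#' @param bin_edges_um2 Strictly increasing numeric vector of bin edges.
#' @return A data frame with `bin_lo`, `bin_hi`, `count`.
#' @export
size_distribution <- function(records, bin_edges_um2) {
  if (length(bin_edges_um2) < 2L || is.unsorted(bin_edges_um2, strictly = TRUE))
    stop("'bin_edges_um2' must be strictly increasing with >= 2 edges")
  areas <- records$area_um2[records$hnf4a_positive %in% TRUE]
  k <- length(bin_edges_um2) - 1L
  idx <- findInterval(areas, bin_edges_um2, rightmost.closed = FALSE)
  idx <- idx[idx >= 1L & idx <= k]
  data.frame(bin_lo = bin_edges_um2[-length(bin_edges_um2)],
             bin_hi = bin_edges_um2[-1],
             count = tabulate(idx, nbins = k))
}
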