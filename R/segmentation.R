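## Nuclear segmentation and per-nucleus feature extraction.
##
## Pipeline: optional Gaussian smoothing -> global threshold (Otsu or
## fixed) -> hole filling -> optional distance-transform watershed to
## split touching nuclei -> minimum-area filter -> optional removal of
## edge-touching objects. Morphometry is computed from second central
## moments of each binary mask; intensities are summarised over the mask
## per channel.

#' Segment nuclei from a Hoechst image
#'
#' @param hoechst 2D numeric matrix (the Hoechst/DNA channel),
#'   non-negative.
#' @param spec An [acquisition_spec()] (supplies the pixel size for the
#'   minimum-area filter).
#' @param params A [segmentation_params()].
#' @return Integer label matrix of the same shape: 0 is background,
#'   labels `1..N` are contiguous.
#' @examples
#' spec <- acquisition_spec(height_px = 64, width_px = 64, pixel_size_um = 1)
#' img <- matrix(0, 64, 64); img[20:30, 20:30] <- 100
#' labels <- segment_nuclei(img, spec, segmentation_params())
#' max(labels)
#' @export
segment_nuclei <- function(hoechst, spec, params = segmentation_params()) {
  if (!is.matrix(hoechst) || length(dim(hoechst)) != 2L)
    stop("'hoechst' must be a 2D matrix")
  if (any(hoechst < 0)) stop("'hoechst' must be non-negative")
  stopifnot(inherits(spec, "acquisition_spec"),
            inherits(params, "segmentation_params"))

  img <- hoechst
  if (params$smoothing_sigma_px > 0)
    img <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                    sigma = params$smoothing_sigma_px))
  if (max(img) == 0)
    return(matrix(0L, nrow(img), ncol(img)))

  thr <- if (params$threshold_method == "otsu") {
    # Otsu on square-root intensities: DNA staining spans a wide dynamic
    # range (per-pixel density falls as ploidy rises under the density x
    # volume model), and a linear-domain Otsu can land between dim
    # polyploid nuclei and bright diploid ones instead of at the
    # background. The sqrt transform compresses that spread (and
    # stabilises shot-noise variance) while remaining exactly
    # equivariant under rescaling of the channel, so the mask is
    # invariant to any positive intensity scale factor. The exact
    # (unbinned) Otsu cut sits at a midpoint between observed values.
    work <- if (params$otsu_sqrt_domain) sqrt(img) else img
    if (length(unique(as.vector(work))) < 2L) {
      max(img)  # constant image: nothing above threshold
    } else {
      t <- otsu_threshold(as.vector(work))
      if (params$otsu_sqrt_domain) t^2 else t
    }
  } else params$fixed_threshold

  mask <- EBImage::Image(ifelse(img > thr, 1, 0))
  mask <- EBImage::fillHull(mask)

  labels <- if (params$split_touching) {
    EBImage::watershed(EBImage::distmap(mask),
                       tolerance = params$watershed_tolerance, ext = 1)
  } else {
    EBImage::bwlabel(mask)
  }
  lab <- as.matrix(EBImage::imageData(labels))
  storage.mode(lab) <- "integer"

  min_px <- params$min_area_um2 / spec$pixel_size_um^2
  sizes <- tabulate(lab[lab > 0L])
  drop <- which(sizes < min_px)
  if (params$exclude_edge) {
    edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    drop <- union(drop, edge[edge > 0L])
  }
  if (length(drop)) lab[lab %in% drop] <- 0L

  # relabel 1..N contiguous
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids)) {
    map <- integer(max(ids)); map[ids] <- seq_along(ids)
    pos <- lab > 0L
    lab[pos] <- map[lab[pos]]
  }
  lab
}

#' Extract per-nucleus morphometry and intensity features
#'
#' For every label, reports area and equivalent radius in physical units,
#' fitted-ellipse elongation (minor/major axis ratio from second central
#' moments of the binary mask; 1 for a circle), the centroid in um, and
#' per-channel mean and integrated intensity over the mask.
#'
#' @param labels Integer label matrix from [segment_nuclei()].
#' @param channels Named list of 2D matrices, or a 3D array with channel
#'   names in `dimnames(...)[[3]]`, sharing the spatial shape of `labels`.
#' @param spec An [acquisition_spec()].
#' @return A data frame with one row per label: `nucleus_id`, `area_um2`,
#'   `equivalent_radius_um`, `elongation`, `centroid_x_um`,
#'   `centroid_y_um`, then `mean_<channel>` and `integrated_<channel>`
#'   per channel, and an `hnf4a_positive` column initialised to `NA`
#'   (set by [classify_hnf4a()]).
#' @export
extract_features <- function(labels, channels, spec) {
  stopifnot(inherits(spec, "acquisition_spec"))
  if (is.array(channels) && length(dim(channels)) == 3L) {
    nm <- dimnames(channels)[[3]]
    if (is.null(nm)) nm <- spec$channels[seq_len(dim(channels)[3])]
    channels <- stats::setNames(
      lapply(seq_along(nm), function(i) channels[, , i]), nm)
  }
  if (!length(channels) || is.null(names(channels)))
    stop("'channels' must be a named list of matrices or a named 3D array")
  for (ch in channels)
    if (!identical(dim(ch), dim(labels)))
      stop("channel and label images must share spatial shape")

  n <- max(labels, 0L)
  px <- spec$pixel_size_um
  pos <- which(labels > 0L)
  if (n == 0L || !length(pos)) return(.empty_features(names(channels)))
  lab <- labels[pos]
  rows <- ((pos - 1L) %% nrow(labels)) + 1L
  cols <- ((pos - 1L) %/% nrow(labels)) + 1L

  npx <- tabulate(lab, nbins = n)
  sum_r <- .by_label(rows, lab, n); sum_c <- .by_label(cols, lab, n)
  cen_r <- sum_r / npx; cen_c <- sum_c / npx
  dr <- rows - cen_r[lab]; dc <- cols - cen_c[lab]
  mu_rr <- .by_label(dr * dr, lab, n) / npx
  mu_cc <- .by_label(dc * dc, lab, n) / npx
  mu_rc <- .by_label(dr * dc, lab, n) / npx
  tr <- mu_rr + mu_cc
  det <- mu_rr * mu_cc - mu_rc^2
  disc <- sqrt(pmax(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  elongation <- ifelse(l1 > 0, sqrt(pmax(l2, 0) / l1), 1)
  elongation <- pmin(elongation, 1)

  out <- data.frame(
    nucleus_id = seq_len(n),
    area_um2 = npx * px^2,
    equivalent_radius_um = sqrt(npx * px^2 / pi),
    elongation = elongation,
    centroid_x_um = (cen_c - 0.5) * px,
    centroid_y_um = (cen_r - 0.5) * px
  )
  for (ch in names(channels)) {
    v <- channels[[ch]][pos]
    s <- .by_label(v, lab, n)
    out[[paste0("mean_", ch)]] <- s / npx
    out[[paste0("integrated_", ch)]] <- s
  }
  out$hnf4a_positive <- NA
  out
}

.by_label <- function(values, labels, n) {
  out <- numeric(n)
  s <- rowsum(values, labels)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

.empty_features <- function(channel_names) {
  out <- data.frame(nucleus_id = integer(0), area_um2 = numeric(0),
                    equivalent_radius_um = numeric(0),
                    elongation = numeric(0),
                    centroid_x_um = numeric(0), centroid_y_um = numeric(0))
  for (ch in channel_names) {
    out[[paste0("mean_", ch)]] <- numeric(0)
    out[[paste0("integrated_", ch)]] <- numeric(0)
  }
  out$hnf4a_positive <- logical(0)
  out
}

#' Classify nuclei as HNF4a-positive by threshold
#'
#' Sets `hnf4a_positive` on a feature table: a nucleus is positive when
#' its mean HNF4a intensity exceeds the threshold. With `threshold =
#' "otsu"` the threshold is computed by Otsu's method over the per-nucleus
#' mean intensities themselves (not over pixels).
#'
#' @param records Feature data frame from [extract_features()] with a
#'   `mean_hnf4a` column.
#' @param threshold Numeric intensity threshold, or `"otsu"`.
#' @return `records` with `hnf4a_positive` set; the threshold used is
#'   stored in `attr(, "hnf4a_threshold")`.
#' @export
classify_hnf4a <- function(records, threshold = "otsu") {
  if (!"mean_hnf4a" %in% names(records))
    stop("records must contain a 'mean_hnf4a' column")
  x <- records$mean_hnf4a
  thr <- if (identical(threshold, "otsu")) {
    if (length(unique(x)) < 2L)
      stop("Otsu thresholding needs >= 2 distinct per-nucleus means; ",
           "supply an explicit threshold")
    otsu_threshold(x)
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    threshold
  }
  records$hnf4a_positive <- x > thr
  attr(records, "hnf4a_threshold") <- thr
  records
}

#' Otsu threshold of a numeric vector
#'
#' Exhaustive between-class-variance maximisation over the midpoints of
#' consecutive distinct values. Values strictly above the returned
#' threshold form the upper class.
#'
#' @param x Numeric vector with at least two distinct values.
#' @return The threshold (a midpoint between two observed values).
#' @export
otsu_threshold <- function(x) {
  r <- rle(sort(x))
  v <- r$values; cnt <- r$lengths
  U <- length(v)
  if (U < 2L) stop("need >= 2 distinct values")
  n <- sum(cnt)
  cw <- cumsum(cnt)
  cs <- cumsum(cnt * v)
  w0 <- cw[-U] / n
  m0 <- cs[-U] / cw[-U]
  m1 <- (cs[U] - cs[-U]) / (n - cw[-U])
  bcv <- w0 * (1 - w0) * (m0 - m1)^2
  i <- which.max(bcv)  # first maximum: deterministic tie-break
  (v[i] + v[i + 1]) / 2
}
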