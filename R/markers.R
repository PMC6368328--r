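## Threshold-based marker quantification: positive-cell fractions,
## staining-area fractions (incl. collagen morphometry), co-staining
## fractions, and modal pixel intensity. Every result records the
## thresholds actually used so that per-image Otsu runs stay auditable.

.marker_result <- function(metric, numerator, denominator, fraction, roi,
                           threshold = NULL, undefined = FALSE) {
  structure(list(metric = metric, numerator = numerator,
                 denominator = denominator, fraction = fraction,
                 roi = roi, threshold = threshold, undefined = undefined),
            class = "marker_quant_result")
}

#' @export
print.marker_quant_result <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("%s: undefined (empty denominator) [roi: %s]\n",
                x$metric, x$roi))
  } else {
    cat(sprintf("%s: %.4g (%g / %g) [roi: %s]\n", x$metric, x$fraction,
                x$numerator, x$denominator, x$roi))
  }
  invisible(x)
}

#' @export
as.data.frame.marker_quant_result <- function(x, ...) {
  data.frame(metric = x$metric,
             numerator = ifelse(x$undefined, NA_real_, x$numerator),
             denominator = ifelse(x$undefined, NA_real_, x$denominator),
             fraction = ifelse(x$undefined, NA_real_, x$fraction),
             roi = x$roi,
             threshold = if (is.null(x$threshold)) NA_real_ else
               paste(signif(unlist(x$threshold), 6), collapse = ";"),
             undefined = x$undefined)
}

.resolve_threshold <- function(thr, values) {
  stopifnot(inherits(thr, "threshold_spec"))
  if (thr$method == "fixed") return(thr$value)
  if (length(unique(values)) < 2L)
    stop("Otsu thresholding needs >= 2 distinct values; ",
         "supply a fixed threshold")
  otsu_threshold(values)
}

#' Marker-positive cell fraction
#'
#' Fraction of cells whose per-cell marker intensity exceeds a threshold,
#' optionally restricted to the cells positive for a conditioning marker
#' (e.g. the Ki67+ fraction among Spp1+ progenitor cells).
#'
#' @param records Feature data frame with a `mean_<marker>` column per
#'   marker used.
#' @param marker Marker channel name (looks up `mean_<marker>`).
#' @param thr A [threshold_spec()]. Otsu is computed over the per-cell
#'   means of the cells in the denominator.
#' @param within Optional conditioning: either the name of a logical
#'   column of `records` (e.g. `"hnf4a_positive"` or a previously set
#'   `marker_<name>_positive`), or a list `list(marker=, thr=)` that is
#'   itself thresholded first.
#' @return A `marker_quant_result`; `fraction` is `NA` with
#'   `undefined = TRUE` when no cell satisfies the conditioning.
#' @export
positive_cell_fraction <- function(records, marker, thr = threshold_spec(),
                                   within = NULL) {
  col <- paste0("mean_", marker)
  if (!col %in% names(records))
    stop(sprintf("records lack per-cell intensities for marker '%s'", marker))
  sel <- rep(TRUE, nrow(records))
  roi <- "all cells"
  thr_used <- list()
  if (!is.null(within)) {
    if (is.character(within)) {
      if (!within %in% names(records))
        stop(sprintf("conditioning column '%s' not found", within))
      st <- records[[within]]
      if (any(is.na(st))) stop("conditioning statuses contain NA")
      sel <- st %in% TRUE
      roi <- paste0(within, " cells")
    } else {
      wcol <- paste0("mean_", within$marker)
      if (!wcol %in% names(records))
        stop(sprintf("records lack per-cell intensities for marker '%s'",
                     within$marker))
      wt <- .resolve_threshold(within$thr, records[[wcol]])
      sel <- records[[wcol]] > wt
      thr_used[[within$marker]] <- wt
      roi <- paste0(within$marker, "+ cells")
    }
  }
  denom <- sum(sel)
  if (denom == 0L)
    return(.marker_result(paste0(marker, "+ fraction"), 0, 0, NA_real_,
                          roi, thr_used, undefined = TRUE))
  t <- .resolve_threshold(thr, records[[col]][sel])
  thr_used[[marker]] <- t
  num <- sum(records[[col]][sel] > t)
  .marker_result(paste0(marker, "+ fraction"), num, denom, num / denom,
                 roi, thr_used)
}

#' Staining-area fraction
#'
#' Fraction of region-of-interest pixels whose intensity exceeds a
#' threshold — the readout used for stain morphometry such as collagen
#' (Sirius-Red-style) area quantification.
#'
#' @param channel 2D intensity matrix.
#' @param thr A [threshold_spec()]; Otsu is computed over the roi pixels.
#' @param roi Logical matrix of the same shape (`NULL` = whole field).
#' @return A `marker_quant_result`.
#' @export
staining_area_fraction <- function(channel, thr = threshold_spec(),
                                   roi = NULL) {
  if (is.null(roi)) roi <- matrix(TRUE, nrow(channel), ncol(channel))
  if (!identical(dim(roi), dim(channel)))
    stop("roi and channel must share shape")
  npx <- sum(roi)
  if (npx == 0L) stop("roi is empty")
  vals <- channel[roi]
  t <- .resolve_threshold(thr, vals)
  num <- sum(vals > t)
  .marker_result("staining area fraction", num, npx, num / npx,
                 sprintf("%d px", npx), list(threshold = t))
}

#' Co-staining fraction
#'
#' Area mode: the fraction of A-positive pixels that are also B-positive.
#' Cell mode: the fraction of A-positive cells that are B-positive (used
#' e.g. for apoptotic cleaved-caspase-3+ cells within Fgf7-expressing
#' stroma).
#'
#' @param a,b In area mode, 2D intensity matrices of equal shape; in cell
#'   mode, marker channel names looked up as `mean_<name>` in `records`.
#' @param thr_a,thr_b [threshold_spec()]s for the two markers.
#' @param roi Optional logical matrix restricting area mode.
#' @param mode `"area"` or `"cell"`.
#' @param records Feature data frame (cell mode only).
#' @return A `marker_quant_result`; undefined when A has no positive
#'   support.
#' @export
costain_fraction <- function(a, b, thr_a = threshold_spec(),
                             thr_b = threshold_spec(), roi = NULL,
                             mode = c("area", "cell"), records = NULL) {
  mode <- match.arg(mode)
  if (mode == "area") {
    if (!identical(dim(a), dim(b))) stop("channels must share shape")
    if (is.null(roi)) roi <- matrix(TRUE, nrow(a), ncol(a))
    if (!identical(dim(roi), dim(a))) stop("roi must share channel shape")
    va <- a[roi]; vb <- b[roi]
    ta <- .resolve_threshold(thr_a, va)
    tb <- .resolve_threshold(thr_b, vb)
    apos <- va > ta
    if (!any(apos))
      return(.marker_result("costain fraction (area)", 0, 0, NA_real_,
                            "no A-positive pixels", list(a = ta, b = tb),
                            undefined = TRUE))
    num <- sum(apos & (vb > tb))
    .marker_result("costain fraction (area)", num, sum(apos),
                   num / sum(apos), sprintf("%d A+ px", sum(apos)),
                   list(a = ta, b = tb))
  } else {
    if (is.null(records)) stop("cell mode requires 'records'")
    ca <- paste0("mean_", a); cb <- paste0("mean_", b)
    if (!all(c(ca, cb) %in% names(records)))
      stop("records lack per-cell intensities for one of the markers")
    ta <- .resolve_threshold(thr_a, records[[ca]])
    apos <- records[[ca]] > ta
    if (!any(apos))
      return(.marker_result(sprintf("%s+ fraction among %s+ cells", b, a),
                            0, 0, NA_real_, "no A-positive cells",
                            list(a = ta), undefined = TRUE))
    tb <- .resolve_threshold(thr_b, records[[cb]][apos])
    num <- sum(records[[cb]][apos] > tb)
    .marker_result(sprintf("%s+ fraction among %s+ cells", b, a),
                   num, sum(apos), num / sum(apos),
                   sprintf("%d %s+ cells", sum(apos), a),
                   list(a = ta, b = tb))
  }
}

#' Modal pixel intensity
#'
#' The most frequent integer intensity bin within a region of interest
#' (the histogram-mode readout used e.g. for membrane beta-catenin
#' remodelling). Intensities are floored to integer bins; ties are broken
#' toward the lowest intensity.
#'
#' @param image 2D intensity matrix.
#' @param roi Logical matrix of the same shape (`NULL` = whole image).
#' @return The modal intensity bin (integer-valued numeric).
#' @examples
#' modal_pixel_intensity(matrix(7, 3, 3))          # 7
#' modal_pixel_intensity(matrix(c(1, 1, 2, 2, 3))) # tie 1 vs 2 -> 1
#' @export
modal_pixel_intensity <- function(image, roi = NULL) {
  if (is.null(roi)) roi <- array(TRUE, dim(image))
  if (!identical(dim(roi), dim(image)))
    stop("roi and image must share shape")
  vals <- image[roi]
  if (!length(vals)) stop("roi is empty")
  bins <- floor(vals)
  tab <- table(bins)
  cand <- as.numeric(names(tab)[tab == max(tab)])
  min(cand)
}
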