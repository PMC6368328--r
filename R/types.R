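#' Image acquisition specification
#'
#' Describes the geometry and channel semantics of a multi-channel
#' fluorescence image: physical pixel size, field dimensions, the ordered
#' channel names, and the detector bit depth. Every physical-unit
#' conversion in the package goes through this object.
#'
#' @param pixel_size_um Pixel edge length in micrometres (> 0). Tissue
#'   sections are typically imaged at 0.3--1 um/px; the default of 0.5
#'   um/px is representative of a 20x high-content objective.
#' @param height_px,width_px Field dimensions in pixels (>= 1).
#' @param channels Character vector of unique channel names, in the order
#'   the image planes are stored. Must contain `"hoechst"` (DNA) and
#'   `"hnf4a"` (hepatocyte nuclear marker).
#' @param bit_depth Integer detector bit depth; intensities live in
#'   `[0, 2^bit_depth - 1]`.
#'
#' @return An object of class `acquisition_spec`.
#' @examples
#' acquisition_spec(pixel_size_um = 0.5, height_px = 512, width_px = 512)
#' @export
acquisition_spec <- function(pixel_size_um = 0.5,
                             height_px = 512L, width_px = 512L,
                             channels = c("hoechst", "hnf4a"),
                             bit_depth = 16L) {
  stopifnot(is.numeric(pixel_size_um), length(pixel_size_um) == 1L,
            is.finite(pixel_size_um), pixel_size_um > 0)
  height_px <- as.integer(height_px)
  width_px <- as.integer(width_px)
  bit_depth <- as.integer(bit_depth)
  stopifnot(height_px >= 1L, width_px >= 1L, bit_depth >= 1L)
  channels <- as.character(channels)
  if (anyDuplicated(channels))
    stop("channel names must be unique")
  for (req in c("hoechst", "hnf4a"))
    if (!req %in% channels)
      stop(sprintf("channels must include '%s'", req))
  structure(list(pixel_size_um = pixel_size_um,
                 height_px = height_px, width_px = width_px,
                 channels = channels, bit_depth = bit_depth),
            class = "acquisition_spec")
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf("acquisition_spec: %d x %d px @ %.3g um/px, %d-bit\n",
              x$height_px, x$width_px, x$pixel_size_um, x$bit_depth))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Nuclear population composition for the synthetic generator
#'
#' Defines the mixture of nuclear classes a synthetic tissue field should
#' contain. The class set mirrors the populations resolvable in liver
#' sections: diploid nonparenchymal nuclei (`NPC_2n`) and hepatocyte
#' nuclei of DNA content 2c, 4c, 8c and 16c.
#'
#' @param fractions Named numeric vector over
#'   `c("NPC_2n","HEP_2c","HEP_4c","HEP_8c","HEP_16c")` (missing names
#'   default to 0) summing to 1.
#' @param n_nuclei Total number of nuclei to place (>= 0).
#' @param bilobular_fraction Fraction of hepatocyte nuclei rendered as two
#'   fused lobes. Such nuclei have low fitted-ellipse elongation and are
#'   meant to be removed by the downstream circularity gate.
#' @param touching_fraction Fraction of nuclei placed as touching pairs
#'   (adjacent but non-overlapping masks), exercising the watershed
#'   splitting step of segmentation.
#'
#' @return An object of class `population_composition`.
#' @examples
#' population_composition(c(NPC_2n = 0.4, HEP_2c = 0.3, HEP_4c = 0.2,
#'                          HEP_8c = 0.07, HEP_16c = 0.03), n_nuclei = 500)
#' @export
population_composition <- function(fractions, n_nuclei,
                                   bilobular_fraction = 0,
                                   touching_fraction = 0) {
  classes <- ploidy_class_labels()
  if (is.null(names(fractions)) || any(!names(fractions) %in% classes))
    stop("fractions must be named with labels among: ",
         paste(classes, collapse = ", "))
  full <- stats::setNames(numeric(length(classes)), classes)
  full[names(fractions)] <- as.numeric(fractions)
  if (any(full < 0) || abs(sum(full) - 1) > 1e-9)
    stop("fractions must be non-negative and sum to 1")
  n_nuclei <- as.integer(n_nuclei)
  stopifnot(n_nuclei >= 0L,
            bilobular_fraction >= 0, bilobular_fraction <= 1,
            touching_fraction >= 0, touching_fraction <= 1)
  structure(list(fractions = full, n_nuclei = n_nuclei,
                 bilobular_fraction = bilobular_fraction,
                 touching_fraction = touching_fraction),
            class = "population_composition")
}

#' Class labels used by the synthetic generator
#' @return Character vector of the five nuclear class labels.
#' @export
ploidy_class_labels <- function() {
  c("NPC_2n", "HEP_2c", "HEP_4c", "HEP_8c", "HEP_16c")
}

#' Acquisition noise model for the synthetic generator
#'
#' Noise is applied after signal rendering: optional Poisson resampling of
#' the signal, then additive Gaussian noise, then a constant background
#' offset. The Gaussian sigma may be given in absolute intensity units or
#' as a fraction of the mean nuclear signal of the channel.
#'
#' @param background_level Constant background offset, intensity units (>= 0).
#' @param gaussian_sigma Additive Gaussian standard deviation in intensity
#'   units, or `NA` to use `gaussian_sigma_frac`.
#' @param gaussian_sigma_frac Gaussian sigma as a fraction of the mean
#'   within-nucleus signal of each channel (used when `gaussian_sigma` is
#'   `NA`; default 0.02, i.e. 2\% noise).
#' @param poisson_enabled Apply Poisson (shot) noise to the rendered signal.
#'
#' @return An object of class `noise_model`.
#' @examples
#' noise_model()                       # 2% Gaussian noise, background 10
#' noise_model(0, gaussian_sigma = 0)  # noiseless
#' @export
noise_model <- function(background_level = 10, gaussian_sigma = NA,
                        gaussian_sigma_frac = 0.02, poisson_enabled = FALSE) {
  stopifnot(background_level >= 0,
            is.na(gaussian_sigma) || gaussian_sigma >= 0,
            gaussian_sigma_frac >= 0)
  structure(list(background_level = background_level,
                 gaussian_sigma = gaussian_sigma,
                 gaussian_sigma_frac = gaussian_sigma_frac,
                 poisson_enabled = isTRUE(poisson_enabled)),
            class = "noise_model")
}

#' Gating configuration for ploidy estimation
#'
#' Holds the morphometric gates and class-assignment parameters of the
#' ploidy pipeline.
#'
#' @param elongation_min Circularity gate: only nuclei with fitted-ellipse
#'   elongation strictly above this value are analysed (default 0.8).
#' @param area_2c_min_um2,area_2c_max_um2 Inclusive nuclear-area bounds of
#'   the 2c hepatocyte gate, um^2 (defaults 19.99 and 34.99).
#' @param small_area_max_um2 Strict upper area bound of the
#'   small-hepatocyte gate, um^2 (default 75).
#' @param class_window_log2 Half-width, in log2 c-units, of the window
#'   around each ploidy class centre inside which a nucleus is assigned to
#'   that class (default 0.5, i.e. boundaries at the log2 midpoints).
#' @param min_reference_n Minimum number of gated HNF4a-negative nuclei
#'   required to calibrate the 2n reference (default 50).
#' @param npc_area_max_um2 Area cap applied to candidate reference nuclei
#'   (default 40 um^2); `Inf` disables it.
#'
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(elongation_min = 0.8,
                        area_2c_min_um2 = 19.99, area_2c_max_um2 = 34.99,
                        small_area_max_um2 = 75,
                        class_window_log2 = 0.5,
                        min_reference_n = 50L,
                        npc_area_max_um2 = 40) {
  stopifnot(elongation_min > 0, elongation_min <= 1,
            area_2c_min_um2 < area_2c_max_um2,
            area_2c_max_um2 < small_area_max_um2,
            class_window_log2 > 0, class_window_log2 <= 0.5,
            min_reference_n >= 1, npc_area_max_um2 > 0)
  structure(list(elongation_min = elongation_min,
                 area_2c_min_um2 = area_2c_min_um2,
                 area_2c_max_um2 = area_2c_max_um2,
                 small_area_max_um2 = small_area_max_um2,
                 class_window_log2 = class_window_log2,
                 min_reference_n = as.integer(min_reference_n),
                 npc_area_max_um2 = npc_area_max_um2),
            class = "gate_config")
}

#' Intensity threshold specification
#'
#' @param method `"fixed"` or `"otsu"`. With `"otsu"` the threshold is
#'   computed from the data it is applied to.
#' @param value Threshold in intensity units (required iff `method = "fixed"`).
#' @return An object of class `threshold_spec`.
#' @examples
#' threshold_spec("fixed", 50)
#' threshold_spec("otsu")
#' @export
threshold_spec <- function(method = c("otsu", "fixed"), value = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value) || !is.numeric(value) || value < 0)
      stop("fixed threshold requires a non-negative numeric 'value'")
  } else if (!is.null(value)) {
    stop("'value' is only meaningful with method = 'fixed'")
  }
  structure(list(method = method, value = value), class = "threshold_spec")
}

#' Segmentation parameters
#'
#' @param threshold_method `"otsu"` (global Otsu on the Hoechst channel) or
#'   `"fixed"`.
#' @param otsu_sqrt_domain Compute the Otsu threshold on square-root
#'   transformed intensities (default `TRUE`): DNA staining spans a wide
#'   per-pixel dynamic range across ploidy classes, and the sqrt domain
#'   keeps the threshold at the background/foreground boundary rather
#'   than inside the foreground, while staying exactly equivariant under
#'   intensity rescaling.
#' @param fixed_threshold Intensity threshold used iff
#'   `threshold_method = "fixed"`.
#' @param min_area_um2 Minimum object area retained, um^2 (default 5;
#'   removes debris below any plausible nucleus).
#' @param split_touching Split touching nuclei by watershed on the
#'   distance transform (default `TRUE`).
#' @param smoothing_sigma_px Gaussian pre-smoothing sigma in pixels
#'   (0 disables).
#' @param exclude_edge Drop nuclei touching the field border, whose
#'   morphometry is biased (default `TRUE`).
#' @param watershed_tolerance Minimum depth, in distance-transform units
#'   (pixels), separating two watershed seeds (default 2: deep enough to
#'   leave strongly fused bilobular lobes intact while still splitting
#'   adjacent touching nuclei, whose saddle depth approaches a full
#'   nuclear radius).
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(threshold_method = c("otsu", "fixed"),
                                fixed_threshold = 0,
                                min_area_um2 = 5,
                                split_touching = TRUE,
                                smoothing_sigma_px = 0,
                                exclude_edge = TRUE,
                                watershed_tolerance = 2,
                                otsu_sqrt_domain = TRUE) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(fixed_threshold >= 0, min_area_um2 >= 0, smoothing_sigma_px >= 0,
            watershed_tolerance > 0)
  structure(list(threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 min_area_um2 = min_area_um2,
                 split_touching = isTRUE(split_touching),
                 smoothing_sigma_px = smoothing_sigma_px,
                 exclude_edge = isTRUE(exclude_edge),
                 watershed_tolerance = watershed_tolerance,
                 otsu_sqrt_domain = isTRUE(otsu_sqrt_domain)),
            class = "segmentation_params")
}
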