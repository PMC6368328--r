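## End-to-end orchestration: segment -> features -> HNF4a classification
## -> circularity gate -> 2n calibration -> ploidy estimation -> gates
## and per-field summaries. Also provides centroid matching of segmented
## nuclei to a synthetic ground-truth table for validation studies.

#' Run the full ploidy pipeline on a multi-channel field
#'
#' @param image 3D array `height x width x channels` with channel names in
#'   `dimnames(...)[[3]]` (must include `hoechst` and `hnf4a`), or a
#'   `synthetic_field`.
#' @param spec An [acquisition_spec()] (taken from the field if omitted).
#' @param seg_params A [segmentation_params()].
#' @param cfg A [gate_config()].
#' @param hnf4a_threshold Threshold for HNF4a positivity (`"otsu"` or
#'   numeric).
#' @param k_max Maximum number of DNA-content peaks reported.
#' @return A list of class `ploidy_run`: `labels`, `records` (all
#'   segmented nuclei with features, HNF4a status, DNA content), `gated`
#'   (circularity-gated records), `calibration`, `estimates` (per gated
#'   nucleus), `peaks` (content units; `NULL` when too few gated nuclei),
#'   `summary` (one-row data frame: counts, densities, gate counts, class
#'   fractions).
#' @export
run_ploidy_pipeline <- function(image, spec = NULL,
                                seg_params = segmentation_params(),
                                cfg = gate_config(),
                                hnf4a_threshold = "otsu",
                                k_max = 4L) {
  if (inherits(image, "synthetic_field")) {
    if (is.null(spec)) spec <- image$spec
    image <- image$image
  }
  stopifnot(inherits(spec, "acquisition_spec"))
  if (length(dim(image)) != 3L)
    stop("'image' must be a height x width x channels array")
  chn <- dimnames(image)[[3]]
  if (is.null(chn)) chn <- spec$channels[seq_len(dim(image)[3])]
  if (!all(c("hoechst", "hnf4a") %in% chn))
    stop("image must carry 'hoechst' and 'hnf4a' channels")

  labels <- segment_nuclei(image[, , which(chn == "hoechst")], spec,
                           seg_params)
  chlist <- stats::setNames(
    lapply(seq_along(chn), function(i) image[, , i]), chn)
  records <- extract_features(labels, chlist, spec)
  if (nrow(records))
    records <- classify_hnf4a(records, hnf4a_threshold)
  records <- compute_dna_content(records)

  gated <- circularity_gate(records, cfg)
  calibration <- calibrate_2n(gated, cfg)
  gated_hep <- gated[gated$hnf4a_positive %in% TRUE, , drop = FALSE]
  estimates <- estimate_ploidy(gated_hep, calibration, cfg)

  peaks <- if (nrow(gated_hep) >= 100L)
    detect_content_peaks(gated_hep$dna_content, k_max) else NULL

  tissue_area_mm2 <- spec$height_px * spec$width_px *
    spec$pixel_size_um^2 / 1e6
  dens <- population_densities(records, tissue_area_mm2)
  g2c <- gate_2c(records, cfg)
  gsm <- gate_small_hepatocytes(records, cfg)
  frac <- prop.table(table(estimates$class))

  summary <- data.frame(
    n_nuclei = nrow(records),
    n_gated = nrow(gated),
    n_gated_hep = nrow(gated_hep),
    n_reference = calibration$n_reference,
    reference_content = calibration$reference_content,
    density_hep_per_mm2 = dens$density_per_mm2[1],
    density_npc_per_mm2 = dens$density_per_mm2[2],
    n_2c_gate = g2c$count,
    n_small_hep = gsm$count,
    frac_2c = as.numeric(frac["2c"]),
    frac_4c = as.numeric(frac["4c"]),
    frac_8c = as.numeric(frac["8c"]),
    frac_16c = as.numeric(frac["16c"]),
    frac_unassigned = as.numeric(frac["unassigned"])
  )
  structure(list(labels = labels, records = records, gated = gated,
                 calibration = calibration, estimates = estimates,
                 peaks = peaks, summary = summary, spec = spec,
                 cfg = cfg),
            class = "ploidy_run")
}

#' @export
print.ploidy_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("ploidy_run: %d nuclei (%d gated, %d hepatocyte)\n",
              s$n_nuclei, s$n_gated, s$n_gated_hep))
  cat(sprintf("  2n reference: %.4g (n = %d)\n",
              s$reference_content, s$n_reference))
  cat(sprintf("  class fractions: 2c %.3f, 4c %.3f, 8c %.3f, 16c %.3f, unassigned %.3f\n",
              s$frac_2c, s$frac_4c, s$frac_8c, s$frac_16c,
              s$frac_unassigned))
  if (!is.null(x$peaks))
    cat("  content peaks:", paste(signif(x$peaks, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Match segmented nuclei to ground-truth nuclei by centroid
#'
#' Greedy nearest-centroid matching between a feature table and a
#' synthetic-truth table, within a distance cap. Used to validate
#' segmentation and ploidy recovery against known ground truth.
#'
#' @param records Feature data frame with `centroid_x_um`, `centroid_y_um`.
#' @param truth Truth data frame from [generate_field()].
#' @param max_dist_um Maximum centroid distance for a valid match.
#' @return A data frame with `nucleus_id` (segmented), `truth_id`, and
#'   `dist_um`, one row per matched pair.
#' @export
match_to_truth <- function(records, truth, max_dist_um = 3) {
  if (!nrow(records) || !nrow(truth))
    return(data.frame(nucleus_id = integer(0), truth_id = integer(0),
                      dist_um = numeric(0)))
  d <- outer(records$centroid_x_um, truth$centroid_x_um, `-`)^2 +
    outer(records$centroid_y_um, truth$centroid_y_um, `-`)^2
  d <- sqrt(d)
  d[d > max_dist_um] <- Inf
  out <- list()
  repeat {
    m <- which.min(d)
    if (!length(m) || !is.finite(d[m])) break
    i <- ((m - 1L) %% nrow(d)) + 1L
    j <- ((m - 1L) %/% nrow(d)) + 1L
    out[[length(out) + 1L]] <- data.frame(
      nucleus_id = records$nucleus_id[i],
      truth_id = truth$nucleus_id[j],
      dist_um = d[m])
    d[i, ] <- Inf
    d[, j] <- Inf
  }
  if (!length(out))
    return(data.frame(nucleus_id = integer(0), truth_id = integer(0),
                      dist_um = numeric(0)))
  do.call(rbind, out)
}

#' Read a generator configuration from YAML
#'
#' Expects top-level keys `spec`, `composition`, `noise`, and optionally
#' `seed`, `content_scale`, `marker_prevalence`, each mapping to the
#' arguments of the corresponding constructor.
#'
#' @param path Path to a YAML file.
#' @return A list with `spec`, `comp`, `noise`, `seed`, `content_scale`,
#'   `marker_prevalence`.
#' @export
read_generator_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  spec <- do.call(acquisition_spec, c(
    y$spec[setdiff(names(y$spec), "channels")],
    if (!is.null(y$spec$channels)) list(channels = unlist(y$spec$channels))))
  comp <- population_composition(
    fractions = unlist(y$composition$fractions),
    n_nuclei = y$composition$n_nuclei,
    bilobular_fraction = y$composition$bilobular_fraction %||% 0,
    touching_fraction = y$composition$touching_fraction %||% 0)
  noise <- do.call(noise_model, y$noise %||% list())
  list(spec = spec, comp = comp, noise = noise,
       seed = y$seed %||% 1L,
       content_scale = y$content_scale %||% 20000,
       marker_prevalence = y$marker_prevalence)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
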