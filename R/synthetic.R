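## Synthetic tissue-field generator.
##
## Renders seeded, ground-truthed multi-channel fields of elliptical nuclei
## whose Hoechst signal follows the density x spherical-volume model that
## the ploidy pipeline inverts: each nucleus is filled with a uniform
## density d chosen so that d * (4/3) pi r_eq^3 = k * true_content_c for a
## single global constant k, with r_eq the equivalent radius of the
## rendered mask. On noiseless fields the pipeline therefore recovers the
## true DNA content up to mask discretization.

# Default class geometry: mean projected nuclear area per class (um^2).
# The 2c mean sits at the centre of the 19.99-34.99 um^2 2c gate window and
# area doubles with each ploidy doubling; NPC nuclei are slightly smaller
# than 2c hepatocytes.
.class_area_um2 <- c(NPC_2n = 22, HEP_2c = 27.49, HEP_4c = 54.98,
                     HEP_8c = 109.96, HEP_16c = 219.92)
.class_content_c <- c(NPC_2n = 2, HEP_2c = 2, HEP_4c = 4,
                      HEP_8c = 8, HEP_16c = 16)
.area_cv <- 0.08           # lognormal CV of within-class nuclear area
.elong_range <- c(0.85, 1) # axis-ratio range of regular (non-bilobular) nuclei
# Bilobular lobe-centre separation as a multiple of the lobe radius:
# close enough that the waist between lobes stays shallow (distance-
# transform saddle depth ~0.13 r, so watershed keeps the nucleus whole)
# while the fitted-ellipse elongation stays well below the 0.8 gate.
.lobe_sep_factor <- 1.0
.marker_level <- 150       # rendered intensity inside marker-positive nuclei

#' Generate a ground-truthed synthetic tissue field
#'
#' Places `comp$n_nuclei` non-overlapping nuclei (filled ellipses;
#' optionally two fused circular lobes for bilobular nuclei) on a dark
#' field and renders one image plane per channel in `spec$channels`. The
#' Hoechst plane encodes DNA content exactly: each nucleus is filled with
#' a uniform density `d` such that `d * (4/3)*pi*r_eq^3 =
#' content_scale * true_content_c`, where `r_eq` is the equivalent radius
#' of the rendered mask. The HNF4a plane (and any additional marker
#' planes) is filled at a constant level inside positive nuclei only.
#' Noise is applied per channel after rendering: optional Poisson on the
#' signal, then additive Gaussian, then a constant background.
#'
#' @param spec An [acquisition_spec()].
#' @param comp A [population_composition()].
#' @param noise A [noise_model()].
#' @param seed Non-negative integer seed; the same seed yields
#'   bit-identical output. The generator uses its own RNG stream and does
#'   not disturb the global one.
#' @param content_scale Global constant `k` linking DNA content in c units
#'   to integrated Hoechst signal (intensity x um^3 per c). The default
#'   keeps per-pixel densities well inside a 16-bit range for all classes.
#' @param marker_prevalence Optional named list describing marker channels
#'   beyond hoechst/hnf4a, e.g.
#'   `list(spp1 = list(prevalence = 0.2), ki67 = list(prevalence = 0.2,
#'   within = "spp1"))`. A marker with `within` can only be positive in
#'   nuclei positive for the conditioning marker.
#' @param quantize Round intensities to integers and clamp to the bit
#'   depth, emulating a digital detector (default `TRUE`; required for
#'   exact TIFF round-trips).
#' @param max_tries Placement attempts per nucleus before the packing is
#'   declared infeasible.
#'
#' @return A list of class `synthetic_field` with elements `image` (array
#'   `height x width x n_channels`, channel names in `dimnames`), `truth`
#'   (data frame, one row per nucleus), `spec`, and `content_scale`.
#'   Truth columns: `nucleus_id`, `class`, `centroid_x_um`,
#'   `centroid_y_um`, `major_axis_um`, `minor_axis_um`, `orientation_rad`,
#'   `area_um2` (rendered mask area), `true_content_c`, `hoechst_density`,
#'   `bilobular`, `touching`, `hnf4a_positive`, and one `marker_<name>`
#'   logical column per entry of `marker_prevalence`.
#' @examples
#' spec <- acquisition_spec(height_px = 256, width_px = 256)
#' comp <- population_composition(c(HEP_2c = 1), n_nuclei = 20)
#' fld <- generate_field(spec, comp, noise_model(0, gaussian_sigma = 0), seed = 1)
#' nrow(fld$truth)
#' @export
generate_field <- function(spec, comp, noise = noise_model(), seed,
                           content_scale = 20000,
                           marker_prevalence = NULL,
                           quantize = TRUE, max_tries = 500L) {
  stopifnot(inherits(spec, "acquisition_spec"),
            inherits(comp, "population_composition"),
            inherits(noise, "noise_model"))
  if (missing(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stop("'seed' must be a single non-negative integer")
  marker_names <- names(marker_prevalence)
  extra <- setdiff(spec$channels, c("hoechst", "hnf4a"))
  if (!is.null(marker_prevalence)) {
    bad <- setdiff(marker_names, extra)
    if (length(bad))
      stop("marker_prevalence names not in spec$channels: ",
           paste(bad, collapse = ", "))
  }

  H <- spec$height_px; W <- spec$width_px
  px <- spec$pixel_size_um
  field_area_um2 <- H * W * px^2

  n <- comp$n_nuclei
  counts <- .largest_remainder_counts(comp$fractions, n)
  classes <- rep(names(counts), counts)
  demanded <- sum(.class_area_um2[classes])
  if (n > 0 && demanded > 0.4 * field_area_um2)
    stop(sprintf(paste0("infeasible packing: demanded nuclear area ",
                        "%.0f um^2 exceeds 40%% of the %.0f um^2 field; ",
                        "enlarge the field or reduce n_nuclei"),
                 demanded, field_area_um2))

  res <- with_local_seed(seed, {
    .generate_field_impl(spec, comp, noise, classes, content_scale,
                         marker_prevalence, quantize, max_tries)
  })
  res$spec <- spec
  res$content_scale <- content_scale
  class(res) <- "synthetic_field"
  res
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf("synthetic_field: %d x %d px, %d channels, %d nuclei\n",
              dim(x$image)[1], dim(x$image)[2], dim(x$image)[3],
              nrow(x$truth)))
  if (nrow(x$truth)) print(table(x$truth$class))
  invisible(x)
}

## Evaluate expr under set.seed(seed) while preserving the caller's RNG
## state (single private stream per call).
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

.largest_remainder_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(rem)]] <- base[order_idx[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

.generate_field_impl <- function(spec, comp, noise, classes, k,
                                 marker_prevalence, quantize, max_tries) {
  H <- spec$height_px; W <- spec$width_px
  px <- spec$pixel_size_um
  n <- length(classes)
  marker_names <- names(marker_prevalence)

  ## Per-nucleus draws (before placement, so composition order does not
  ## leak into geometry).
  area_um2 <- .class_area_um2[classes] *
    stats::rlnorm(n, -0.5 * log(1 + .area_cv^2), sqrt(log(1 + .area_cv^2)))
  axis_ratio <- stats::runif(n, .elong_range[1], .elong_range[2])
  orientation <- stats::runif(n, 0, pi)
  is_hep <- classes != "NPC_2n"
  bilobular <- is_hep & (stats::runif(n) < comp$bilobular_fraction)

  ## Touching pairs: pair consecutive nuclei of a random subset.
  touching_partner <- rep(NA_integer_, n)
  n_pairs <- floor(comp$touching_fraction * n / 2)
  if (n_pairs > 0) {
    cand <- sample(which(!bilobular), min(2 * n_pairs, sum(!bilobular)))
    cand <- cand[seq_len(length(cand) - length(cand) %% 2)]
    if (length(cand) >= 2) {
      a <- cand[seq(1, length(cand), 2)]; b <- cand[seq(2, length(cand), 2)]
      touching_partner[a] <- b; touching_partner[b] <- a
    }
  }

  ## Place large nuclei first (packing is easier), but pairs together.
  order_idx <- order(area_um2, decreasing = TRUE)
  placed <- rep(FALSE, n)
  occupancy <- matrix(0L, H, W)
  geo <- vector("list", n)  # per nucleus: rows, cols, centre (px)

  for (i in order_idx) {
    if (placed[i]) next
    partner <- touching_partner[i]
    g <- .place_nucleus(occupancy, H, W, px, area_um2[i], axis_ratio[i],
                        orientation[i], bilobular[i], max_tries)
    occupancy[cbind(g$rows, g$cols)] <- i
    geo[[i]] <- g; placed[i] <- TRUE
    if (!is.na(partner) && !placed[partner]) {
      g2 <- .place_touching(occupancy, H, W, px, area_um2[partner],
                            axis_ratio[partner], orientation[partner],
                            g, i, max_tries)
      occupancy[cbind(g2$rows, g2$cols)] <- partner
      geo[[partner]] <- g2; placed[partner] <- TRUE
    }
  }

  npix <- tabulate(occupancy[occupancy > 0L], nbins = n)
  area_render_um2 <- npix * px^2
  r_eq_um <- sqrt(area_render_um2 / pi)
  content_c <- .class_content_c[classes]
  density <- (k * content_c) / ((4 / 3) * pi * r_eq_um^3)
  if (n == 0) density <- numeric(0)

  ## Marker statuses.
  hnf4a_positive <- is_hep
  marker_status <- matrix(FALSE, n, length(marker_names),
                          dimnames = list(NULL, marker_names))
  for (m in .marker_eval_order(marker_prevalence)) {
    mp <- marker_prevalence[[m]]
    eligible <- rep(TRUE, n)
    if (!is.null(mp$within)) {
      w <- mp$within
      eligible <- if (w == "hnf4a") hnf4a_positive else marker_status[, w]
    }
    marker_status[, m] <- eligible & (stats::runif(n) < mp$prevalence)
  }

  ## Render channels.
  nch <- length(spec$channels)
  img <- array(0, dim = c(H, W, nch),
               dimnames = list(NULL, NULL, spec$channels))
  for (i in seq_len(n)) {
    idx <- cbind(geo[[i]]$rows, geo[[i]]$cols)
    plane <- img[, , "hoechst"]; plane[idx] <- density[i]
    img[, , "hoechst"] <- plane
    if (hnf4a_positive[i]) {
      plane <- img[, , "hnf4a"]; plane[idx] <- .marker_level
      img[, , "hnf4a"] <- plane
    }
    for (m in marker_names) {
      if (marker_status[i, m]) {
        plane <- img[, , m]; plane[idx] <- .marker_level
        img[, , m] <- plane
      }
    }
  }

  ## Noise: Poisson on signal -> additive Gaussian -> constant background.
  for (ch in spec$channels) {
    plane <- img[, , ch]
    if (noise$poisson_enabled)
      plane[] <- stats::rpois(length(plane), plane)
    sigma <- noise$gaussian_sigma
    if (is.na(sigma)) {
      nuc <- plane[occupancy > 0L]
      sigma <- if (length(nuc)) noise$gaussian_sigma_frac * mean(nuc) else 0
    }
    if (sigma > 0)
      plane <- plane + stats::rnorm(length(plane), 0, sigma)
    plane <- plane + noise$background_level
    img[, , ch] <- plane
  }
  if (quantize) {
    img <- round(img)
    img[img < 0] <- 0
    img[img > 2^spec$bit_depth - 1] <- 2^spec$bit_depth - 1
  }

  truth <- data.frame(
    nucleus_id = seq_len(n),
    class = classes,
    centroid_x_um = vapply(geo, function(g) (g$cx - 0.5) * px, 0),
    centroid_y_um = vapply(geo, function(g) (g$cy - 0.5) * px, 0),
    major_axis_um = vapply(geo, function(g) g$major_um, 0),
    minor_axis_um = vapply(geo, function(g) g$minor_um, 0),
    orientation_rad = orientation,
    area_um2 = area_render_um2,
    true_content_c = unname(content_c),
    hoechst_density = density,
    bilobular = bilobular,
    touching = !is.na(touching_partner),
    hnf4a_positive = hnf4a_positive,
    stringsAsFactors = FALSE
  )
  if (n == 0) truth <- truth[0, ]
  for (m in marker_names)
    truth[[paste0("marker_", m)]] <- marker_status[, m]
  rownames(truth) <- NULL
  list(image = img, truth = truth)
}

.marker_eval_order <- function(marker_prevalence) {
  nm <- names(marker_prevalence)
  deps <- vapply(marker_prevalence, function(x)
    if (is.null(x$within)) "" else x$within, "")
  ord <- character(0)
  remaining <- nm
  while (length(remaining)) {
    ready <- remaining[deps[remaining] %in% c("", "hnf4a", ord)]
    if (!length(ready))
      stop("circular 'within' dependency among markers: ",
           paste(remaining, collapse = ", "))
    ord <- c(ord, ready)
    remaining <- setdiff(remaining, ready)
  }
  ord
}

## Pixel-centre membership of an ellipse (axes in um, centre in px coords).
.ellipse_pixels <- function(cx, cy, a_um, b_um, theta, px, H, W) {
  a <- a_um / px; b <- b_um / px
  ext <- ceiling(max(a, b)) + 1L
  rows <- max(1L, floor(cy) - ext):min(H, ceiling(cy) + ext)
  cols <- max(1L, floor(cx) - ext):min(W, ceiling(cx) + ext)
  gr <- expand.grid(r = rows, c = cols)
  dx <- gr$c - cx; dy <- gr$r - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  keep <- u^2 + v^2 <= 1
  list(rows = gr$r[keep], cols = gr$c[keep])
}

## Two fused circular lobes approximating total area A (union closed form
## at the default centre separation 1.2 * lobe radius).
.bilobular_pixels <- function(cx, cy, area_um2, theta, px, H, W) {
  f <- .lobe_sep_factor
  lens <- 2 * acos(f / 2) - (f / 2) * sqrt(4 - f^2)
  r_um <- sqrt(area_um2 / (2 * pi - lens))
  s_um <- f * r_um
  dx <- (s_um / 2) * cos(theta) / px; dy <- (s_um / 2) * sin(theta) / px
  p1 <- .ellipse_pixels(cx - dx, cy - dy, r_um, r_um, 0, px, H, W)
  p2 <- .ellipse_pixels(cx + dx, cy + dy, r_um, r_um, 0, px, H, W)
  key <- c(p1$rows + p1$cols * 1e6, p2$rows + p2$cols * 1e6)
  keep <- !duplicated(key)
  list(rows = c(p1$rows, p2$rows)[keep], cols = c(p1$cols, p2$cols)[keep],
       r_lobe_um = r_um, s_um = s_um)
}

.nucleus_pixels <- function(cx, cy, area_um2, axis_ratio, theta, bilobular,
                            px, H, W) {
  if (bilobular) {
    g <- .bilobular_pixels(cx, cy, area_um2, theta, px, H, W)
    list(rows = g$rows, cols = g$cols,
         major_um = g$s_um + 2 * g$r_lobe_um, minor_um = 2 * g$r_lobe_um)
  } else {
    a_um <- sqrt(area_um2 / (pi * axis_ratio))  # semi-major
    b_um <- a_um * axis_ratio
    g <- .ellipse_pixels(cx, cy, a_um, b_um, theta, px, H, W)
    list(rows = g$rows, cols = g$cols,
         major_um = 2 * a_um, minor_um = 2 * b_um)
  }
}

## TRUE when the candidate mask plus a 1-pixel clearance ring is free
## (occupied only by labels in `allow`): independent nuclei must not
## touch, so that fused blobs arise only from deliberate touching pairs.
.clearance_ok <- function(occupancy, rows, cols, H, W, allow = 0L) {
  for (dr in -1:1) for (dc in -1:1) {
    rr <- pmin(pmax(rows + dr, 1L), H)
    cc <- pmin(pmax(cols + dc, 1L), W)
    if (!all(occupancy[cbind(rr, cc)] %in% allow)) return(FALSE)
  }
  TRUE
}

.place_nucleus <- function(occupancy, H, W, px, area_um2, axis_ratio,
                           theta, bilobular, max_tries) {
  margin <- ceiling(sqrt(area_um2 / pi) / px *
                      (if (bilobular) 2.3 else 1.6)) + 2L
  if (2 * margin >= min(H, W))
    stop("infeasible packing: nucleus larger than the field")
  for (t in seq_len(max_tries)) {
    cy <- stats::runif(1, margin, H - margin)
    cx <- stats::runif(1, margin, W - margin)
    g <- .nucleus_pixels(cx, cy, area_um2, axis_ratio, theta, bilobular,
                         px, H, W)
    if (.clearance_ok(occupancy, g$rows, g$cols, H, W)) {
      g$cx <- cx; g$cy <- cy
      return(g)
    }
  }
  stop(sprintf(paste0("infeasible packing: could not place a %.0f um^2 ",
                      "nucleus after %d tries (coverage constraint); ",
                      "enlarge the field or reduce n_nuclei"),
               area_um2, max_tries))
}

## Place a nucleus adjacent to (touching, not overlapping) an anchor.
.place_touching <- function(occupancy, H, W, px, area_um2, axis_ratio,
                            theta, anchor, anchor_id, max_tries) {
  r1 <- (anchor$minor_um / 2) / px
  r2 <- sqrt(area_um2 / pi) / px
  for (t in seq_len(max_tries)) {
    ang <- stats::runif(1, 0, 2 * pi)
    sep <- r1 + r2 + 0.2  # boundaries adjacent; masks disjoint
    cy <- anchor$cy + sep * sin(ang)
    cx <- anchor$cx + sep * cos(ang)
    ext <- r2 + 2
    if (cy < ext || cy > H - ext || cx < ext || cx > W - ext) next
    # render round-ish so the pair forms one fused blob of two convex lobes
    g <- .nucleus_pixels(cx, cy, area_um2, max(axis_ratio, 0.95), ang,
                         FALSE, px, H, W)
    if (all(occupancy[cbind(g$rows, g$cols)] == 0L) &&
        .clearance_ok(occupancy, g$rows, g$cols, H, W,
                      allow = c(0L, anchor_id))) {
      g$cx <- cx; g$cy <- cy
      return(g)
    }
  }
  stop("infeasible packing: could not place touching partner (coverage constraint)")
}

#' Write a synthetic field to disk as TIFF + CSV + YAML metadata
#'
#' The image is written as a multi-page TIFF (one 16-bit page per channel,
#' in the channel order of the acquisition spec, recorded in the YAML
#' sidecar), the ground truth as CSV with full floating-point precision,
#' and the acquisition metadata (pixel size, channels, bit depth, content
#' scale) as YAML.
#'
#' @param field A `synthetic_field` from [generate_field()].
#' @param dir Existing writable directory.
#' @param prefix File-name prefix (default `"field"`).
#' @return Named character vector of the three file paths
#'   (`image`, `truth`, `meta`).
#' @seealso [read_fixture()]
#' @export
write_fixture <- function(field, dir, prefix = "field") {
  stopifnot(inherits(field, "synthetic_field"))
  if (!dir.exists(dir))
    stop(sprintf("directory does not exist: %s", dir))
  spec <- field$spec
  maxval <- 2^spec$bit_depth - 1
  img <- field$image
  if (any(img != round(img)) || any(img < 0) || any(img > maxval))
    stop("image intensities must be integers within the bit depth for ",
         "lossless TIFF storage; generate with quantize = TRUE")
  paths <- c(image = file.path(dir, paste0(prefix, "_image.tif")),
             truth = file.path(dir, paste0(prefix, "_truth.csv")),
             meta = file.path(dir, paste0(prefix, "_meta.yaml")))
  pages <- lapply(seq_along(spec$channels),
                  function(i) img[, , i] / maxval)
  ok <- try(tiff::writeTIFF(pages, paths[["image"]],
                            bits.per.sample = 16L, reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop(sprintf("failed to write TIFF: %s", paths[["image"]]))
  truth <- field$truth
  num <- vapply(truth, is.double, TRUE)
  truth[num] <- lapply(truth[num], function(x) format(x, digits = 17))
  utils::write.csv(truth, paths[["truth"]], row.names = FALSE)
  meta <- list(pixel_size_um = spec$pixel_size_um,
               height_px = spec$height_px, width_px = spec$width_px,
               channels = as.list(spec$channels),
               bit_depth = spec$bit_depth,
               content_scale = field$content_scale)
  yaml::write_yaml(meta, paths[["meta"]])
  paths
}

#' Read a synthetic fixture written by [write_fixture()]
#'
#' @param dir Directory containing the fixture.
#' @param prefix File-name prefix used when writing.
#' @return A `synthetic_field` list with `image`, `truth`, `spec`,
#'   `content_scale`.
#' @export
read_fixture <- function(dir, prefix = "field") {
  paths <- c(image = file.path(dir, paste0(prefix, "_image.tif")),
             truth = file.path(dir, paste0(prefix, "_truth.csv")),
             meta = file.path(dir, paste0(prefix, "_meta.yaml")))
  for (p in paths)
    if (!file.exists(p)) stop(sprintf("fixture file missing: %s", p))
  meta <- yaml::read_yaml(paths[["meta"]])
  spec <- acquisition_spec(pixel_size_um = meta$pixel_size_um,
                           height_px = meta$height_px,
                           width_px = meta$width_px,
                           channels = unlist(meta$channels),
                           bit_depth = meta$bit_depth)
  pages <- tiff::readTIFF(paths[["image"]], all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  maxval <- 2^spec$bit_depth - 1
  img <- array(0, dim = c(spec$height_px, spec$width_px,
                          length(spec$channels)),
               dimnames = list(NULL, NULL, spec$channels))
  for (i in seq_along(pages)) img[, , i] <- round(pages[[i]] * maxval)
  truth <- utils::read.csv(paths[["truth"]], stringsAsFactors = FALSE)
  structure(list(image = img, truth = truth, spec = spec,
                 content_scale = meta$content_scale),
            class = "synthetic_field")
}
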