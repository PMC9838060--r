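# Protoplast and nucleus segmentation.

#' Segmentation and gating parameters
#'
#' @param smoothing_sigma Gaussian sigma (px) applied to the chlorophyll
#'   channel before thresholding.
#' @param cell_threshold `"otsu"` or a fixed intensity value.
#' @param roundness_cutoff Minimum roundness `4*pi*Area/Perimeter^2` for a
#'   region to be kept as a protoplast (default 0.8).
#' @param min_cell_area,max_cell_area Area bounds (px^2) for protoplasts.
#' @param nucleus_threshold `"otsu"` or a fixed intensity value, applied to
#'   the pixelwise max of the mCherry and GFP projections.
#' @param min_nucleus_area,max_nucleus_area Area bounds (px^2) for nuclei.
#' @param gate_method Gate-threshold derivation: `"negative_control_quantile"`
#'   (default; GFP gate from control wells), `"otsu"`, or `"fixed"`.
#' @param gate_quantile Quantile of the negative-control nuclear-GFP
#'   distribution used as the GFP gate (default 0.999).
#' @param mcherry_gate,gfp_gate Fixed gate thresholds (used when
#'   `gate_method = "fixed"`; `mcherry_gate` may also be given to override
#'   the Otsu-derived mCherry gate).
#' @param mode `"wheat_chlorophyll"` (cells segmented from chlorophyll,
#'   nuclei assigned to cells) or `"maize_etiolated"` (nuclei are the
#'   analysis units).
#' @return List of class `"segmentation_params"`.
#' @export
segmentation_params <- function(smoothing_sigma = 2,
                                cell_threshold = "otsu",
                                roundness_cutoff = 0.8,
                                min_cell_area = 100,
                                max_cell_area = 4000,
                                nucleus_threshold = "otsu",
                                min_nucleus_area = 6,
                                max_nucleus_area = 500,
                                gate_method = c("negative_control_quantile",
                                                "otsu", "fixed"),
                                gate_quantile = 0.999,
                                mcherry_gate = NULL,
                                gfp_gate = NULL,
                                mode = c("wheat_chlorophyll", "maize_etiolated")) {
  gate_method <- match.arg(gate_method)
  mode <- match.arg(mode)
  assert_number(roundness_cutoff, "roundness_cutoff", lower = 1e-9, upper = 1)
  if (min_cell_area <= 0 || min_cell_area >= max_cell_area)
    stop_pq("cell area bounds must be positive with min < max",
            class = "protoquant_input_error")
  if (min_nucleus_area <= 0 || min_nucleus_area >= max_nucleus_area)
    stop_pq("nucleus area bounds must be positive with min < max",
            class = "protoquant_input_error")
  structure(list(smoothing_sigma = smoothing_sigma,
                 cell_threshold = cell_threshold,
                 roundness_cutoff = roundness_cutoff,
                 min_cell_area = min_cell_area, max_cell_area = max_cell_area,
                 nucleus_threshold = nucleus_threshold,
                 min_nucleus_area = min_nucleus_area,
                 max_nucleus_area = max_nucleus_area,
                 gate_method = gate_method, gate_quantile = gate_quantile,
                 mcherry_gate = mcherry_gate, gfp_gate = gfp_gate,
                 mode = mode),
            class = "segmentation_params")
}

# Threshold an image. Otsu is computed on the [0, 1]-normalized image; a
# contrast guard returns NA (no foreground) when the image is essentially
# flat, where Otsu would split noise.
resolve_threshold <- function(image, method, guard_mads = 3) {
  if (is.numeric(method)) return(method)
  if (!identical(method, "otsu"))
    stop_pq("threshold method must be 'otsu' or a fixed value",
            class = "protoquant_config_error")
  rng <- range(image)
  med <- median(image)
  spread <- mad(image)
  if (rng[2] - rng[1] < 1e-9) return(NA_real_)
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  thr <- thr * (rng[2] - rng[1]) + rng[1]
  # flat image guard: threshold must clear the background noise floor
  if (thr <= med + guard_mads * max(spread, 1e-9)) return(NA_real_)
  thr
}

# Region properties from a label matrix: area, perimeter, roundness,
# centroid, border contact. The perimeter is the chain-code length of the
# traced boundary (diagonal steps count sqrt(2)); pixel-edge counts
# underestimate smooth boundaries enough to let elongated objects through
# a 4*pi*A/P^2 filter.
region_stats <- function(labels) {
  n <- max(labels)
  if (n == 0L)
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0), perimeter = numeric(0),
                      roundness = numeric(0), on_border = logical(0)))
  area <- tabulate(labels[labels > 0], nbins = n)
  idx <- which(labels > 0)
  rr <- ((idx - 1L) %% nrow(labels)) + 1L
  cc <- ((idx - 1L) %/% nrow(labels)) + 1L
  lab <- labels[idx]
  cx <- as.numeric(rowsum(rr, lab)) / area
  cy <- as.numeric(rowsum(cc, lab)) / area
  contours <- EBImage::ocontour(labels)
  per <- vapply(seq_len(n), function(i) {
    ct <- contours[[i]]
    if (is.null(ct) || nrow(ct) < 2) return(4)  # single pixel
    d <- rbind(diff(ct), ct[1, ] - ct[nrow(ct), ])
    sum(sqrt(rowSums(d^2)))
  }, numeric(1))
  border_labels <- unique(c(labels[1, ], labels[nrow(labels), ],
                            labels[, 1], labels[, ncol(labels)]))
  data.frame(label = seq_len(n),
             x = cx, y = cy,
             area = area, perimeter = per,
             roundness = pmin(4 * pi * area / pmax(per, 1e-9)^2, 1),
             on_border = seq_len(n) %in% border_labels)
}

#' Segment protoplasts from the chlorophyll channel
#'
#' Smooths and thresholds the (flatfield-corrected) chlorophyll projection,
#' fills holes, splits touching cells by distance-transform watershed, and
#' computes shape metrics. Regions failing the roundness cutoff or the
#' area bounds, or touching the field border, are flagged (not deleted):
#' `is_protoplast` is `TRUE` only for round, in-bounds, interior regions.
#'
#' @param image Chlorophyll projection (2-d matrix).
#' @param params [segmentation_params()]; must be wheat mode.
#' @param watershed_tolerance Minimum height between distance-map peaks for
#'   a split (px).
#' @return List with `labels` (integer matrix) and `regions` (data.frame of
#'   per-region metrics with flags `round_enough`, `in_bounds`,
#'   `on_border`, `is_protoplast`).
#' @export
segment_protoplasts <- function(image, params = segmentation_params(),
                                watershed_tolerance = 2) {
  if (params$mode != "wheat_chlorophyll")
    stop_pq("segment_protoplasts requires wheat_chlorophyll mode",
            class = "protoquant_config_error")
  sm <- gaussian_smooth(image, params$smoothing_sigma)
  thr <- resolve_threshold(sm, params$cell_threshold)
  if (is.na(thr)) {
    labels <- matrix(0L, nrow(image), ncol(image))
    return(list(labels = labels, regions = cbind(region_stats(labels),
                                                 round_enough = logical(0),
                                                 in_bounds = logical(0),
                                                 is_protoplast = logical(0))))
  }
  mask <- sm > thr
  mask <- EBImage::fillHull(EBImage::Image(mask * 1))
  dm <- EBImage::distmap(mask)
  labels <- EBImage::watershed(dm, tolerance = watershed_tolerance, ext = 1)
  labels <- matrix(as.integer(EBImage::imageData(labels)),
                   nrow(image), ncol(image))
  regions <- region_stats(labels)
  regions$round_enough <- regions$roundness >= params$roundness_cutoff
  regions$in_bounds <- regions$area >= params$min_cell_area &
    regions$area <= params$max_cell_area
  regions$is_protoplast <- regions$round_enough & regions$in_bounds &
    !regions$on_border
  list(labels = labels, regions = regions)
}

#' Segment nuclei from the reporter channels
#'
#' Nuclei are connected regions of the thresholded pixelwise maximum of the
#' mCherry and GFP projections (union semantics: a nucleus showing either
#' reporter is detected), filtered by the nucleus area bounds. In
#' `maize_etiolated` mode these regions are the analysis units.
#'
#' @param mcherry,gfp Projections (2-d matrices); either may be `NULL`.
#' @param params [segmentation_params()].
#' @return List with `labels` and `regions` (per-nucleus centroid, area,
#'   `mean_mcherry`, `mean_gfp`).
#' @export
segment_nuclei <- function(mcherry, gfp, params = segmentation_params()) {
  if (is.null(mcherry) && is.null(gfp))
    stop_pq("at least one of mCherry/GFP must be present",
            class = "protoquant_input_error")
  comb <- if (is.null(mcherry)) gfp else if (is.null(gfp)) mcherry
  else pmax(mcherry, gfp)
  thr <- resolve_threshold(comb, params$nucleus_threshold)
  empty <- list(labels = matrix(0L, nrow(comb), ncol(comb)),
                regions = data.frame(label = integer(0), x = numeric(0),
                                     y = numeric(0), area = numeric(0),
                                     mean_mcherry = numeric(0),
                                     mean_gfp = numeric(0)))
  if (is.na(thr)) return(empty)
  mask <- EBImage::fillHull(EBImage::Image((comb > thr) * 1))
  labels <- EBImage::bwlabel(mask)
  labels <- matrix(as.integer(EBImage::imageData(labels)),
                   nrow(comb), ncol(comb))
  n <- max(labels)
  if (n == 0L) return(empty)
  st <- region_stats(labels)
  keep <- st$area >= params$min_nucleus_area &
    st$area <= params$max_nucleus_area
  mean_by_label <- function(img) {
    if (is.null(img)) return(rep(NA_real_, n))
    as.numeric(tapply(img[labels > 0], labels[labels > 0], mean))
  }
  regions <- data.frame(label = st$label, x = st$x, y = st$y, area = st$area,
                        mean_mcherry = mean_by_label(mcherry),
                        mean_gfp = mean_by_label(gfp))
  regions <- regions[keep, , drop = FALSE]
  # relabel compactly so labels match row order
  labels[!labels %in% regions$label] <- 0L
  relut <- integer(n)
  relut[regions$label] <- seq_len(nrow(regions))
  labels[labels > 0] <- relut[labels[labels > 0]]
  regions$label <- seq_len(nrow(regions))
  rownames(regions) <- NULL
  list(labels = labels, regions = regions)
}
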