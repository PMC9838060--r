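# Field-level simulation: renders one field of view (4 channels x Z planes)
# plus its ground-truth object table.

# Linear pixel indices of a filled disc, clipped to the image.
disc_pixels <- function(dims, r0, c0, radius) {
  rr <- max(1L, floor(r0 - radius)):min(dims[1], ceiling(r0 + radius))
  cc <- max(1L, floor(c0 - radius)):min(dims[2], ceiling(c0 + radius))
  if (!length(rr) || !length(cc)) return(integer(0))
  g <- expand.grid(r = rr, c = cc)
  keep <- (g$r - r0)^2 + (g$c - c0)^2 <= radius^2
  (g$c[keep] - 1L) * dims[1] + g$r[keep]
}

# Linear pixel indices of a filled rotated ellipse (debris streaks).
ellipse_pixels <- function(dims, r0, c0, a, b, theta) {
  ext <- ceiling(max(a, b))
  rr <- max(1L, floor(r0 - ext)):min(dims[1], ceiling(r0 + ext))
  cc <- max(1L, floor(c0 - ext)):min(dims[2], ceiling(c0 + ext))
  if (!length(rr) || !length(cc)) return(integer(0))
  g <- expand.grid(r = rr, c = cc)
  dr <- g$r - r0; dc <- g$c - c0
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  (g$c[keep] - 1L) * dims[1] + g$r[keep]
}

# Radially symmetric multiplicative vignetting gain field.
vignetting_gain <- function(dims, strength) {
  if (strength <= 0) return(matrix(1, dims[1], dims[2]))
  r0 <- (dims[1] + 1) / 2; c0 <- (dims[2] + 1) / 2
  d2 <- outer((seq_len(dims[1]) - r0)^2, (seq_len(dims[2]) - c0)^2, `+`)
  1 - strength * d2 / max(d2)
}

# Rejection-sample non-overlapping object centers (min pairwise distance
# `min_dist`, margin `margin` from the border).
sample_centers <- function(n, dims, margin, min_dist, max_tries = 400L) {
  centers <- matrix(numeric(0), ncol = 2)
  lo_r <- 1 + margin; hi_r <- dims[1] - margin
  lo_c <- 1 + margin; hi_c <- dims[2] - margin
  if (hi_r <= lo_r || hi_c <= lo_c) return(centers)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- c(runif(1, lo_r, hi_r), runif(1, lo_c, hi_c))
      if (!nrow(centers) ||
          min((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >= min_dist^2) {
        centers <- rbind(centers, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) break  # field saturated; caller may warn
  }
  centers
}

# Positive truncated normal draw (resampled, never clamped).
rnorm_pos <- function(n, mean, sd, floor = 0.5) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < floor)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < floor)
  }
  x
}

# Number of cells allocated to each field of a well (even split, remainder
# on the leading fields; deterministic).
field_cell_counts <- function(n_cells, fields_per_well) {
  base <- n_cells %/% fields_per_well
  extra <- n_cells %% fields_per_well
  base + as.integer(seq_len(fields_per_well) <= extra)
}

#' Simulate one field of view
#'
#' Renders a four-channel (brightfield, chlorophyll, GFP, mCherry) Z stack
#' of round protoplasts with known ground truth. Transfected cells carry a
#' nuclear mCherry disc; edited cells additionally a nuclear GFP disc; in
#' `wheat_chlorophyll` mode cell bodies fluoresce in the chlorophyll
#' channel. Debris objects are elongated streaks with chlorophyll-like
#' intensity and no nuclear signal. Object intensity follows a Gaussian
#' profile across Z (peak at a random focal plane) and the whole field is
#' attenuated by a radial vignetting gain.
#'
#' @param config A [simulation_config()].
#' @param well Well id present in `config$wells`.
#' @param field_index Field index in `1..fields_per_well`.
#' @param render If `FALSE`, only the ground-truth table is produced (the
#'   truth RNG stream is identical either way).
#' @return List with elements `stack` (a [channel_stack()], or `NULL` when
#'   `render = FALSE`) and `truth` (data.frame: `well`, `field`, `x`, `y`
#'   (pixel row/column), `radius`, `is_transfected`, `is_edited`,
#'   `is_debris`).
#' @export
simulate_field <- function(config, well, field_index, render = TRUE) {
  w <- config$wells[config$wells$well == well, , drop = FALSE]
  if (!nrow(w))
    stop_pq(paste0("well not present in layout: ", well),
            class = "protoquant_layout_error")
  if (field_index < 1 || field_index > config$fields_per_well)
    stop_pq(sprintf("field_index %d outside 1..%d", field_index,
                    config$fields_per_well),
            class = "protoquant_input_error")

  dims <- config$field_size_px
  n_here <- field_cell_counts(w$n_cells, config$fields_per_well)[field_index]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(substream_seed(config$seed, well, field_index))

  # --- ground truth (drawn first so render = FALSE shares the stream) ---
  mean_r <- config$cell_radius[1]
  # margin covers a 3-sd radius draw so cells never touch the field border
  centers <- sample_centers(n_here, dims,
                            margin = mean_r + 3 * config$cell_radius[2] + 2,
                            min_dist = 2.2 * mean_r)
  if (nrow(centers) < n_here)
    warning(sprintf("field %s/%d saturated: placed %d of %d cells",
                    well, field_index, nrow(centers), n_here))
  n <- nrow(centers)
  radii <- if (n) rnorm_pos(n, mean_r, config$cell_radius[2]) else numeric(0)
  if (n > 1) {
    # cells are non-overlapping by contract: cap each radius so neighbours
    # keep a clear gap (smoothing in the analysis dilates masks by ~1-2 px)
    d2 <- as.matrix(dist(centers))
    diag(d2) <- Inf
    nnd <- apply(d2, 1, min)
    radii <- pmin(radii, nnd / 2 - 1.5)
  }
  transfected <- if (n) rbinom(n, 1, w$transfection_rate) == 1 else logical(0)
  edited <- if (n) transfected & (rbinom(n, 1, w$editing_rate) == 1) else logical(0)

  n_debris <- config$debris_count
  debris <- NULL
  if (n_debris > 0) {
    rows <- vector("list", n_debris)
    placed <- centers
    for (i in seq_len(n_debris)) {
      a <- runif(1, 1.5, 2.0) * mean_r
      dmargin <- a + 2
      # debris must not overlap cells (or other debris): truth matching
      # downstream needs unambiguous objects
      for (t in seq_len(500L)) {
        cand <- c(runif(1, 1 + dmargin, dims[1] - dmargin),
                  runif(1, 1 + dmargin, dims[2] - dmargin))
        if (!nrow(placed) ||
            min((placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2) >=
              (a + 1.5 * mean_r)^2) break
      }
      placed <- rbind(placed, cand)
      rows[[i]] <- data.frame(r = cand[1], c = cand[2], a = a,
                              ratio = runif(1, 3, 4),
                              theta = runif(1, 0, pi))
    }
    debris <- do.call(rbind, rows)
  }

  truth <- data.frame(
    well = rep(well, n + n_debris),
    field = rep(field_index, n + n_debris),
    x = c(centers[, 1], if (n_debris) debris$r),
    y = c(centers[, 2], if (n_debris) debris$c),
    radius = c(radii, if (n_debris) debris$a),
    is_transfected = c(transfected, rep(FALSE, n_debris)),
    is_edited = c(edited, rep(FALSE, n_debris)),
    is_debris = c(rep(FALSE, n), rep(TRUE, n_debris)),
    stringsAsFactors = FALSE
  )

  if (!render)
    return(list(stack = NULL, truth = truth))

  # --- rendering ---
  im <- config$intensity_model
  nz <- config$z_planes
  sigma_z <- max(1, nz / 4)
  gain <- vignetting_gain(dims, config$vignetting_strength)
  wheat <- config$species_mode == "wheat_chlorophyll"

  # per-object focal planes and drawn intensities
  focal <- if (n + n_debris) sample.int(nz, n + n_debris, replace = TRUE) else integer(0)
  zscale <- function(obj, z) exp(-0.5 * ((z - focal[obj]) / sigma_z)^2)

  cell_px <- lapply(seq_len(n), function(i)
    disc_pixels(dims, centers[i, 1], centers[i, 2], radii[i]))
  nuc_r <- if (n) rnorm_pos(n, config$nucleus_radius[1], config$nucleus_radius[2],
                            floor = 1) else numeric(0)
  # nucleus sits near the cell center (offset < 0.25 cell radius)
  nuc_off <- if (n) matrix(runif(2 * n, -0.25, 0.25) * radii, ncol = 2) else NULL
  nuc_px <- lapply(seq_len(n), function(i)
    disc_pixels(dims, centers[i, 1] + nuc_off[i, 1],
                centers[i, 2] + nuc_off[i, 2], nuc_r[i]))
  debris_px <- lapply(seq_len(n_debris), function(i)
    ellipse_pixels(dims, debris$r[i], debris$c[i], debris$a[i],
                   debris$a[i] / debris$ratio[i], debris$theta[i]))

  chl_int <- if (n) rnorm_pos(n, im$chlorophyll$fg_mean, im$chlorophyll$fg_sd, 1) else numeric(0)
  bf_int  <- if (n) rnorm_pos(n, im$brightfield$fg_mean, im$brightfield$fg_sd, 1) else numeric(0)
  mch_int <- if (n) rnorm_pos(n, im$mCherry$fg_mean, im$mCherry$fg_sd, 1) else numeric(0)
  gfp_int <- if (n) rnorm_pos(n, im$GFP$fg_mean, im$GFP$fg_sd, 1) else numeric(0)
  deb_int <- if (n_debris) rnorm_pos(n_debris, im$chlorophyll$fg_mean,
                                     im$chlorophyll$fg_sd, 1) else numeric(0)

  channels <- list()
  for (ch in PQ_CHANNELS) {
    mod <- im[[ch]]
    arr <- array(0, dim = c(dims[1], dims[2], nz))
    for (z in seq_len(nz)) {
      plane <- matrix(mod$bg, dims[1], dims[2])
      if (ch == "brightfield") {
        for (i in seq_len(n))
          plane[cell_px[[i]]] <- plane[cell_px[[i]]] +
            (bf_int[i] - mod$bg) * zscale(i, z)
        for (i in seq_len(n_debris))
          plane[debris_px[[i]]] <- plane[debris_px[[i]]] +
            (mod$fg_mean - mod$bg) * 0.5 * zscale(n + i, z)
      } else if (ch == "chlorophyll") {
        if (wheat)
          for (i in seq_len(n))
            plane[cell_px[[i]]] <- plane[cell_px[[i]]] + chl_int[i] * zscale(i, z)
        for (i in seq_len(n_debris))
          plane[debris_px[[i]]] <- plane[debris_px[[i]]] +
            deb_int[i] * zscale(n + i, z)
      } else if (ch == "mCherry") {
        for (i in which(transfected))
          plane[nuc_px[[i]]] <- plane[nuc_px[[i]]] + mch_int[i] * zscale(i, z)
      } else if (ch == "GFP") {
        for (i in which(edited))
          plane[nuc_px[[i]]] <- plane[nuc_px[[i]]] + gfp_int[i] * zscale(i, z)
      }
      plane <- plane * gain
      if (mod$noise_sd > 0)
        plane <- plane + rnorm(length(plane), 0, mod$noise_sd)
      arr[, , z] <- pmin(pmax(round(plane), 0), 65535)
    }
    channels[[ch]] <- arr
  }

  list(stack = channel_stack(channels, well = well, field = field_index),
       truth = truth)
}

# Save/restore the global RNG state so simulation substreams do not
# perturb a caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Simulate per-cell reporter records without rendering pixels
#'
#' Draws ground-truth transfection/editing flags and nuclear reporter
#' intensities for every cell of every well, producing the same record
#' shape as the imaging pipeline ([analyze_field()]) emits. This is the
#' fast path for studying the statistical behaviour of gating and plate
#' statistics at realistic cell numbers (thousands of cells per well),
#' where rendering and re-segmenting pixels adds nothing but runtime.
#'
#' Non-transfected cells carry no detectable nucleus; their "nuclear"
#' intensities are background draws. Edited (GFP-positive) cells are a
#' subset of transfected cells.
#'
#' @param config A [simulation_config()].
#' @return data.frame of cell records with measurement columns
#'   (`has_nucleus`, `mean_mcherry`, `mean_gfp`, ...) plus ground-truth
#'   columns `truth_transfected` / `truth_edited` which analysis functions
#'   ignore.
#' @export
simulate_cell_records <- function(config) {
  im <- config$intensity_model
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  out <- vector("list", nrow(config$wells))
  for (i in seq_len(nrow(config$wells))) {
    w <- config$wells[i, ]
    set.seed(substream_seed(config$seed, w$well, "records"))
    n <- w$n_cells
    if (n == 0) next
    transfected <- rbinom(n, 1, w$transfection_rate) == 1
    edited <- transfected & (rbinom(n, 1, w$editing_rate) == 1)
    mch <- ifelse(transfected,
                  rnorm(n, im$mCherry$fg_mean, im$mCherry$fg_sd),
                  rnorm(n, im$mCherry$bg, pmax(im$mCherry$noise_sd, 1)))
    gfp <- ifelse(edited,
                  rnorm(n, im$GFP$fg_mean, im$GFP$fg_sd),
                  rnorm(n, im$GFP$bg, pmax(im$GFP$noise_sd, 1)))
    out[[i]] <- data.frame(
      well = w$well,
      field = rep_len(seq_len(config$fields_per_well), n),
      label = seq_len(n),
      x = NA_real_, y = NA_real_,
      area = pi * config$cell_radius[1]^2,
      roundness = 1,
      is_protoplast = TRUE,
      on_border = FALSE,
      has_nucleus = transfected,
      mean_mcherry = pmax(mch, 0),
      mean_gfp = pmax(gfp, 0),
      truth_transfected = transfected,
      truth_edited = edited,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Match analyzed cell records against a ground-truth table
#'
#' Greedy nearest-centroid matching between detected protoplast records and
#' simulated ground truth (one-to-one, within `max_dist` pixels), giving
#' detection precision, recall and F1 over non-debris truth cells, and the
#' fraction of debris objects correctly rejected (not claimed as
#' protoplasts).
#'
#' @param records Cell records of one field ([analyze_field()]); only rows
#'   with `is_protoplast` count as detections.
#' @param truth Ground-truth table of the same field ([simulate_field()]).
#' @param max_dist Maximum centroid distance (px) for a match.
#' @return List with `f1`, `precision`, `recall`, `debris_rejection`
#'   (proportions), and counts `n_matched`, `n_detected`, `n_truth`.
#' @export
match_truth <- function(records, truth, max_dist = 8) {
  det <- records[records$is_protoplast, , drop = FALSE]
  cells <- truth[!truth$is_debris, , drop = FALSE]
  debris <- truth[truth$is_debris, , drop = FALSE]
  used <- rep(FALSE, nrow(det))
  matched <- 0L
  for (i in seq_len(nrow(cells))) {
    if (!nrow(det)) break
    d2 <- (det$x - cells$x[i])^2 + (det$y - cells$y[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= max_dist^2) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  debris_hit <- 0L
  for (i in seq_len(nrow(debris))) {
    if (!nrow(det)) break
    d2 <- (det$x - debris$x[i])^2 + (det$y - debris$y[i])^2
    if (min(d2) <= max_dist^2) debris_hit <- debris_hit + 1L
  }
  precision <- if (nrow(det)) matched / nrow(det) else NA_real_
  recall <- if (nrow(cells)) matched / nrow(cells) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(f1 = f1, precision = precision, recall = recall,
       debris_rejection = if (nrow(debris)) 1 - debris_hit / nrow(debris)
       else NA_real_,
       n_matched = matched, n_detected = nrow(det), n_truth = nrow(cells))
}
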