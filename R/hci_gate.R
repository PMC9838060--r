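# Gating: from segmented objects to per-cell records and per-well counts.

# Otsu threshold of a numeric vector (histogram formulation).
otsu_vector <- function(x, levels = 512L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) < 1e-12) return(NA_real_)
  h <- hist(x, breaks = seq(min(x), max(x), length.out = levels + 1L),
            plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Measure per-cell records for one field
#'
#' Combines cell labels, nucleus regions and the projected images into one
#' record per analysis unit. In wheat mode the units are chlorophyll-
#' segmented cells: each cell is assigned at most one nucleus by centroid
#' containment (the nucleus whose centroid falls inside the cell region;
#' ties broken by the higher mean nuclear mCherry), and cells without an
#' assigned nucleus get their reporter means measured over the cell body
#' (background level). In maize mode the nuclei themselves are the
#' analysis units.
#'
#' @param cells Result of [segment_protoplasts()] (ignored in maize mode).
#' @param nuclei Result of [segment_nuclei()].
#' @param projections Named list of projected channel images.
#' @param params [segmentation_params()].
#' @param well,field Identity attached to the records.
#' @return data.frame of cell records (one row per cell / nucleus) with
#'   measurement columns; gate flags are added by [gate_cells()].
#' @export
measure_cells <- function(cells, nuclei, projections, params,
                          well = NA_character_, field = NA_integer_) {
  nr <- nuclei$regions
  if (params$mode == "maize_etiolated") {
    n <- nrow(nr)
    return(data.frame(
      well = rep(well, n), field = rep(field, n),
      label = nr$label, x = nr$x, y = nr$y, area = nr$area,
      roundness = NA_real_, is_protoplast = rep(TRUE, n),
      on_border = rep(FALSE, n), has_nucleus = rep(TRUE, n),
      mean_mcherry = nr$mean_mcherry, mean_gfp = nr$mean_gfp,
      stringsAsFactors = FALSE))
  }
  cr <- cells$regions
  n <- nrow(cr)
  if (n == 0L)
    return(data.frame(well = character(0), field = integer(0),
                      label = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0), roundness = numeric(0),
                      is_protoplast = logical(0), on_border = logical(0),
                      has_nucleus = logical(0), mean_mcherry = numeric(0),
                      mean_gfp = numeric(0), stringsAsFactors = FALSE))
  # nucleus -> cell by centroid containment
  cell_of_nuc <- rep(NA_integer_, nrow(nr))
  if (nrow(nr)) {
    ri <- pmin(pmax(round(nr$x), 1), nrow(cells$labels))
    ci <- pmin(pmax(round(nr$y), 1), ncol(cells$labels))
    cell_of_nuc <- cells$labels[cbind(ri, ci)]
    cell_of_nuc[cell_of_nuc == 0L] <- NA_integer_
  }
  nuc_of_cell <- rep(NA_integer_, n)
  if (nrow(nr)) {
    ord <- order(-nr$mean_mcherry)  # brightest nucleus wins ties
    for (k in ord) {
      cl <- cell_of_nuc[k]
      if (!is.na(cl) && is.na(nuc_of_cell[cl])) nuc_of_cell[cl] <- k
    }
  }
  mch_img <- projections$mCherry
  gfp_img <- projections$GFP
  mean_mch <- mean_gfp <- numeric(n)
  for (i in seq_len(n)) {
    if (!is.na(nuc_of_cell[i])) {
      mean_mch[i] <- nr$mean_mcherry[nuc_of_cell[i]]
      mean_gfp[i] <- nr$mean_gfp[nuc_of_cell[i]]
    } else {
      px <- cells$labels == i
      mean_mch[i] <- if (is.null(mch_img)) NA_real_ else mean(mch_img[px])
      mean_gfp[i] <- if (is.null(gfp_img)) NA_real_ else mean(gfp_img[px])
    }
  }
  data.frame(
    well = rep(well, n), field = rep(field, n),
    label = cr$label, x = cr$x, y = cr$y, area = cr$area,
    roundness = cr$roundness, is_protoplast = cr$is_protoplast,
    on_border = cr$on_border, has_nucleus = !is.na(nuc_of_cell),
    mean_mcherry = mean_mch, mean_gfp = mean_gfp,
    stringsAsFactors = FALSE)
}

#' Analyze one field end to end
#'
#' Projection, chlorophyll flatfield correction (wheat mode), protoplast
#' and nucleus segmentation, and per-cell measurement.
#'
#' @param stack A [channel_stack()].
#' @param params [segmentation_params()].
#' @param flatfield_sigma Sigma of the pseudo-flatfield estimate.
#' @return data.frame of ungated cell records (see [measure_cells()]).
#' @export
analyze_field <- function(stack, params = segmentation_params(),
                          flatfield_sigma = 50) {
  proj <- project_stack(stack)
  cells <- NULL
  if (params$mode == "wheat_chlorophyll") {
    if (is.null(proj$chlorophyll))
      stop_pq("wheat mode requires a chlorophyll channel",
              class = "protoquant_config_error")
    chl <- flatfield_correct(proj$chlorophyll, flatfield_sigma)
    cells <- segment_protoplasts(chl, params)
  }
  nuclei <- segment_nuclei(proj$mCherry, proj$GFP, params)
  measure_cells(cells, nuclei, proj, params,
                well = stack$well, field = stack$field)
}

#' Resolve gate thresholds for a plate of cell records
#'
#' The mCherry (transfection) gate separates nucleus-bearing transfected
#' cells from background and is derived by Otsu over all per-cell nuclear
#' mCherry means (the non-transfected cells of every well form the
#' background mode). The GFP (editing) gate defaults to the
#' `gate_quantile` (99.9th percentile) of nuclear GFP among transfected
#' cells in negative-control wells of the same plate; `"otsu"` and
#' `"fixed"` are available when no controls exist.
#'
#' @param records Cell records (rbind of [analyze_field()] /
#'   [simulate_cell_records()] output).
#' @param layout [plate_layout()] resolving control wells.
#' @param params [segmentation_params()].
#' @return List with numeric `mcherry` and `gfp` thresholds.
#' @export
resolve_gates <- function(records, layout, params = segmentation_params()) {
  mch_thr <- params$mcherry_gate %||% otsu_vector(records$mean_mcherry)
  if (is.na(mch_thr))
    stop_pq("could not derive an mCherry gate (degenerate intensities)",
            class = "protoquant_config_error")
  gfp_thr <- switch(
    params$gate_method,
    fixed = params$gfp_gate %||%
      stop_pq("gate_method 'fixed' requires gfp_gate",
              class = "protoquant_config_error"),
    otsu = otsu_vector(records$mean_gfp[records$has_nucleus &
                                          records$mean_mcherry >= mch_thr]),
    negative_control_quantile = {
      ctrl_wells <- layout$well[layout$control_role != "none"]
      if (!length(ctrl_wells))
        stop_pq("gate_method 'negative_control_quantile' requires control wells in the layout",
                class = "protoquant_config_error")
      pool <- records$mean_gfp[records$well %in% ctrl_wells &
                                 records$has_nucleus &
                                 records$mean_mcherry >= mch_thr]
      if (!length(pool))
        stop_pq("no transfected cells found in control wells",
                class = "protoquant_config_error")
      as.numeric(quantile(pool, params$gate_quantile, names = FALSE))
    })
  if (is.na(gfp_thr))
    stop_pq("could not derive a GFP gate", class = "protoquant_config_error")
  list(mcherry = mch_thr, gfp = gfp_thr)
}

#' Apply gate thresholds to cell records
#'
#' `is_transfected` requires a detected nucleus with mean nuclear mCherry
#' at or above the mCherry gate; `is_gfp_positive` additionally requires
#' mean nuclear GFP at or above the GFP gate (nested gating, so
#' GFP-positive implies transfected). `gfp_any` is the independent
#' (non-nested) GFP gate used for co-transfection measurements.
#'
#' @param records Cell records.
#' @param gates List with `mcherry` and `gfp` thresholds
#'   (see [resolve_gates()]).
#' @return `records` with logical columns `is_transfected`,
#'   `is_gfp_positive`, `gfp_any` added.
#' @export
gate_cells <- function(records, gates) {
  records$is_transfected <- records$has_nucleus &
    !is.na(records$mean_mcherry) & records$mean_mcherry >= gates$mcherry
  records$is_gfp_positive <- records$is_transfected &
    !is.na(records$mean_gfp) & records$mean_gfp >= gates$gfp
  records$gfp_any <- records$has_nucleus &
    !is.na(records$mean_gfp) & records$mean_gfp >= gates$gfp
  records
}

#' Summarize gated records per well
#'
#' Counts analysis units (`is_protoplast` and off-border in wheat mode),
#' transfected cells, GFP-positive transfected cells, and the independent
#' GFP count; computes mean nuclear GFP among transfected cells. Counts
#' always nest: `n_gfp_positive <= n_transfected <= n_cells`.
#'
#' @param records Gated cell records ([gate_cells()]).
#' @param layout [plate_layout()] supplying condition labels; wells listed
#'   in the layout but absent from `records` yield zero-count rows with a
#'   warning.
#' @return data.frame with one row per well: `well`, `condition`,
#'   `control_role`, `n_cells`, `n_transfected`, `n_gfp_positive`,
#'   `n_gfp_any`, `mean_gfp_transfected`.
#' @export
summarize_well <- function(records, layout) {
  counted <- records[records$is_protoplast & !records$on_border, , drop = FALSE]
  rows <- lapply(layout$well, function(w) {
    rc <- counted[counted$well == w, , drop = FALSE]
    data.frame(
      well = w,
      n_cells = nrow(rc),
      n_transfected = sum(rc$is_transfected),
      n_gfp_positive = sum(rc$is_gfp_positive),
      n_gfp_any = sum(rc$gfp_any),
      mean_gfp_transfected = if (any(rc$is_transfected))
        mean(rc$mean_gfp[rc$is_transfected]) else NA_real_,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  empty <- out$well[out$n_cells == 0]
  if (length(empty))
    warning("well(s) with zero counted cells: ", paste(empty, collapse = ", "))
  out$condition <- layout$condition[match(out$well, layout$well)]
  out$control_role <- layout$control_role[match(out$well, layout$well)]
  stopifnot(all(out$n_gfp_positive <= out$n_transfected),
            all(out$n_transfected <= out$n_cells))
  out
}
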