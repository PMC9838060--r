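# Image pipeline: projection, flatfield, segmentation, gating, summaries.

test_that("maximum projection matches the elementwise oracle", {
  a <- matrix(runif(64, 0, 100), 8, 8)
  b <- matrix(runif(64, 0, 100), 8, 8)
  st <- channel_stack(list(GFP = array(c(a, b), c(8, 8, 2))))
  proj <- project_stack(st)
  expect_equal(proj$GFP, pmax(a, b))

  one <- channel_stack(list(GFP = a))
  expect_equal(project_stack(one)$GFP, a)

  zero <- channel_stack(list(GFP = array(0, c(4, 4, 3))))
  expect_true(all(project_stack(zero)$GFP == 0))
})

test_that("flatfield correction is a no-op on flat images and removes known gain", {
  flat <- matrix(500, 60, 60)
  out <- flatfield_correct(flat, 15)
  expect_lt(max(abs(out - flat)) / 500, 1e-6)

  # known radial gain applied to a constant image: recovered to within 5%
  gain <- protoquant:::vignetting_gain(c(200, 200), 0.35)
  img <- 1000 * gain
  corr <- flatfield_correct(img, 8)
  expect_lt(max(abs(corr - mean(corr))) / mean(corr), 0.05)

  # coefficient of variation shrinks by > 90%
  cv_before <- sd(img) / mean(img)
  cv_after <- sd(corr) / mean(corr)
  expect_lt(cv_after, 0.1 * cv_before)

  expect_error(flatfield_correct(numeric(0)), "matrix",
               class = "protoquant_input_error")
})

test_that("a synthetic disc segments as one round protoplast", {
  img <- matrix(100, 120, 120)
  img[protoquant:::disc_pixels(c(120, 120), 60, 60, 20)] <- 8000
  seg <- segment_protoplasts(img, segmentation_params())
  expect_equal(nrow(seg$regions), 1)
  expect_gte(seg$regions$roundness, 0.95)
  expect_true(seg$regions$is_protoplast)
  expect_equal(seg$regions$x, 60, tolerance = 0.05)
})

test_that("elongated regions fail the roundness cutoff 4*pi*A/P^2", {
  # 100 x 4 px rectangle: A = 400, P = 208 -> roundness ~ 0.116... by the
  # analytic formula; any perimeter estimator keeps it far below 0.8
  img <- matrix(100, 140, 140)
  img[20:23, 20:119] <- 8000
  seg <- segment_protoplasts(img, segmentation_params(min_cell_area = 10))
  expect_equal(nrow(seg$regions), 1)
  expect_lt(seg$regions$roundness, 0.8)
  expect_false(seg$regions$is_protoplast)
  expect_equal(4 * pi * 400 / 208^2, 0.1161, tolerance = 1e-3)
})

test_that("touching discs are split by the distance-transform watershed", {
  img <- matrix(100, 160, 160)
  r <- 20
  img[protoquant:::disc_pixels(c(160, 160), 70, 80, r)] <- 8000
  img[protoquant:::disc_pixels(c(160, 160), 100, 80, r)] <- 8000  # 1.5 r apart
  seg <- segment_protoplasts(img, segmentation_params())
  expect_equal(nrow(seg$regions), 2)
})

test_that("empty images yield zero regions without error", {
  img <- matrix(100, 60, 60)
  seg <- segment_protoplasts(img, segmentation_params())
  expect_equal(nrow(seg$regions), 0)
  nuc <- segment_nuclei(img, img, segmentation_params())
  expect_equal(nrow(nuc$regions), 0)
})

test_that("nucleus detection uses union semantics over the reporter channels", {
  base <- matrix(100, 100, 100)
  mch <- base; mch[protoquant:::disc_pixels(c(100, 100), 30, 30, 4)] <- 12000
  gfp <- base; gfp[protoquant:::disc_pixels(c(100, 100), 70, 70, 4)] <- 9000
  p <- segmentation_params()
  expect_equal(nrow(segment_nuclei(mch, base, p)$regions), 1)
  expect_equal(nrow(segment_nuclei(base, gfp, p)$regions), 1)   # GFP-only
  both <- segment_nuclei(mch, gfp, p)$regions
  expect_equal(nrow(both), 2)
  expect_error(segment_nuclei(NULL, NULL, p), "at least one",
               class = "protoquant_input_error")
})

test_that("nucleus count matches truth on a noise-free field", {
  cfg <- fixture_config(n_cells = 50, field_size = 320, fields_per_well = 1,
                        z_planes = 3, seed = 31,
                        intensity_model = noise_free_model())
  res <- simulate_field(cfg, "A1", 1)
  proj <- project_stack(res$stack)
  nuc <- segment_nuclei(proj$mCherry, proj$GFP, segmentation_params())
  expect_equal(nrow(nuc$regions), sum(res$truth$is_transfected))
})

test_that("gate flags reproduce truth on noise-free fields (F1 >= 0.98)", {
  cfg <- fixture_config(n_cells = 50, field_size = 320, fields_per_well = 1,
                        z_planes = 3, seed = 41, n_rep = 1, n_control = 1,
                        intensity_model = noise_free_model())
  params <- segmentation_params()
  recs <- list(); truths <- list()
  for (w in cfg$wells$well) {
    res <- simulate_field(cfg, w, 1)
    truths[[w]] <- res$truth
    recs[[w]] <- analyze_field(res$stack, params)
  }
  records <- do.call(rbind, recs)
  gates <- resolve_gates(records, cfg$wells, params)
  records <- gate_cells(records, gates)

  # match detected protoplasts of the edited well to its truth
  w <- cfg$wells$well[cfg$wells$condition == "edited"][1]
  det <- records[records$well == w & records$is_protoplast, ]
  truth <- truths[[w]][!truths[[w]]$is_debris, ]
  f1_gate <- function(flag_det, flag_truth) {
    tp <- fp <- fn <- 0
    for (i in seq_len(nrow(det))) {
      d2 <- (truth$x - det$x[i])^2 + (truth$y - det$y[i])^2
      j <- which.min(d2)
      if (d2[j] <= 64) {
        if (flag_det[i] && flag_truth[j]) tp <- tp + 1
        if (flag_det[i] && !flag_truth[j]) fp <- fp + 1
        if (!flag_det[i] && flag_truth[j]) fn <- fn + 1
      }
    }
    if (tp == 0) return(0)
    2 * tp / (2 * tp + fp + fn)
  }
  expect_gte(f1_gate(det$is_transfected, truth$is_transfected), 0.98)
  expect_gte(f1_gate(det$is_gfp_positive, truth$is_edited), 0.98)
  # nesting invariant
  expect_true(all(!records$is_gfp_positive | records$is_transfected))
})

test_that("gate definitions are literal threshold comparisons", {
  recs <- data.frame(
    well = "A1", field = 1, label = 1:3, x = 0, y = 0, area = 100,
    roundness = 1, is_protoplast = TRUE, on_border = FALSE,
    has_nucleus = c(TRUE, TRUE, FALSE),
    mean_mcherry = c(5000, 100, 5000),
    mean_gfp = c(4000, 4000, 4000))
  g <- gate_cells(recs, list(mcherry = 1000, gfp = 1000))
  expect_equal(g$is_transfected, c(TRUE, FALSE, FALSE))
  expect_equal(g$is_gfp_positive, c(TRUE, FALSE, FALSE))
  expect_equal(g$gfp_any, c(TRUE, TRUE, FALSE))
})

test_that("negative-control gating requires control wells", {
  recs <- data.frame(well = "A1", has_nucleus = TRUE,
                     mean_mcherry = c(100, 5000), mean_gfp = c(100, 200))
  lay <- plate_layout(data.frame(well = "A1", condition = "c", replicate = 1,
                                 control_role = "none"))
  expect_error(resolve_gates(recs, lay, segmentation_params()),
               "control wells", class = "protoquant_config_error")
})

test_that("well summaries count and nest correctly", {
  lay <- plate_layout(data.frame(well = c("A1", "A2"), condition = "c",
                                 replicate = 1:2, control_role = "none"))
  recs <- data.frame(
    well = "A1", field = 1, label = 1:10, x = 0, y = 0, area = 100,
    roundness = 1, is_protoplast = TRUE, on_border = FALSE,
    has_nucleus = TRUE,
    mean_mcherry = c(rep(5000, 4), rep(10, 6)),
    mean_gfp = c(8000, rep(10, 9)))
  recs <- gate_cells(recs, list(mcherry = 1000, gfp = 1000))
  expect_warning(ws <- summarize_well(recs, lay), "A2")
  expect_equal(ws$n_cells, c(10, 0))
  expect_equal(ws$n_transfected, c(4, 0))
  expect_equal(ws$n_gfp_positive, c(1, 0))
  expect_true(all(ws$n_gfp_positive <= ws$n_transfected &
                    ws$n_transfected <= ws$n_cells))
})

test_that("quantile gate thresholds are stable in the control sample size", {
  im <- default_intensity_model()
  set.seed(77)
  pool1 <- rnorm(2000, im$GFP$bg, 50)
  pool2 <- c(pool1, rnorm(2000, im$GFP$bg, 50))
  q1 <- quantile(pool1, 0.999, names = FALSE)
  q2 <- quantile(pool2, 0.999, names = FALSE)
  expect_lt(abs(q2 - q1) / q1, 0.05)
})

test_that("maize mode analyses nuclei directly, without chlorophyll", {
  lay <- plate_layout(data.frame(
    well = "A1", condition = "c", replicate = 1, control_role = "none",
    n_cells = 30, transfection_rate = 1, editing_rate = 0.5))
  cfg <- simulation_config(lay, fields_per_well = 1, z_planes = 2,
                           field_size_px = c(260, 260),
                           species_mode = "maize_etiolated", seed = 13,
                           debris_count = 0,
                           intensity_model = noise_free_model())
  res <- simulate_field(cfg, "A1", 1)
  # chlorophyll channel is background-only in etiolated material
  expect_lt(max(res$stack$channels$chlorophyll),
            default_intensity_model()$chlorophyll$bg + 1)
  params <- segmentation_params(mode = "maize_etiolated")
  recs <- analyze_field(res$stack, params)
  expect_equal(nrow(recs), sum(res$truth$is_transfected))
  expect_true(all(recs$has_nucleus))
  # wheat-mode segmentation refuses to run on maize params
  expect_error(segment_protoplasts(matrix(0, 5, 5), params),
               "wheat", class = "protoquant_config_error")
})
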