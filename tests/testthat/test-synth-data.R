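# Synthetic plates and reads: truth conservation, determinism, and
# statistical faithfulness of the generator.

test_that("empty wells give background-only stacks and empty truth", {
  lay <- plate_layout(data.frame(
    well = "A1", condition = "empty", replicate = 1, control_role = "none",
    n_cells = 0, transfection_rate = 0.5, editing_rate = 0.5))
  cfg <- simulation_config(lay, fields_per_well = 1, z_planes = 2,
                           field_size_px = c(80, 80), debris_count = 0,
                           seed = 1)
  res <- simulate_field(cfg, "A1", 1)
  expect_equal(nrow(res$truth), 0)
  im <- default_intensity_model()
  # only background + vignetting + noise: nothing brighter than background
  expect_lt(max(res$stack$channels$GFP), im$GFP$bg + 6 * im$GFP$noise_sd)
  expect_lt(max(res$stack$channels$mCherry),
            im$mCherry$bg + 6 * im$mCherry$noise_sd)
})

test_that("degenerate rates produce fully transfected, fully edited truth", {
  lay <- plate_layout(data.frame(
    well = "A1", condition = "all", replicate = 1, control_role = "none",
    n_cells = 20, transfection_rate = 1, editing_rate = 1))
  cfg <- simulation_config(lay, fields_per_well = 1, z_planes = 2,
                           field_size_px = c(200, 200), debris_count = 0,
                           seed = 3)
  truth <- simulate_field(cfg, "A1", 1, render = FALSE)$truth
  expect_equal(nrow(truth), 20)
  expect_true(all(truth$is_transfected))
  expect_true(all(truth$is_edited))
})

test_that("truth generation is deterministic and render-invariant", {
  cfg <- fixture_config(seed = 11, field_size = 160, n_cells = 24)
  t1 <- simulate_field(cfg, "A1", 1, render = FALSE)$truth
  t2 <- simulate_field(cfg, "A1", 1, render = FALSE)$truth
  t3 <- simulate_field(cfg, "A1", 1, render = TRUE)$truth
  expect_identical(t1, t2)
  expect_identical(t1, t3)
  # edited implies transfected; debris never transfected
  expect_true(all(!t1$is_edited | t1$is_transfected))
  expect_true(all(!t1$is_debris | !t1$is_transfected))
  # a different substream gives different positions
  t4 <- simulate_field(cfg, "A1", 2, render = FALSE)$truth
  expect_false(isTRUE(all.equal(t1$x[1], t4$x[1])))
})

test_that("unknown wells and bad field indices are rejected", {
  cfg <- fixture_config()
  expect_error(simulate_field(cfg, "H12", 1), "well",
               class = "protoquant_layout_error")
  expect_error(simulate_field(cfg, "A1", 99), "field_index",
               class = "protoquant_input_error")
})

test_that("empirical transfection/editing fractions track configured rates", {
  lay <- plate_layout(data.frame(
    well = c("A1", "A2"), condition = "c", replicate = 1:2,
    control_role = "none", n_cells = 1500,
    transfection_rate = 0.5, editing_rate = 0.3))
  cfg <- simulation_config(lay, fields_per_well = 3, z_planes = 1,
                           field_size_px = c(900, 900), seed = 21)
  truth <- do.call(rbind, lapply(c("A1", "A2"), function(w)
    do.call(rbind, lapply(1:3, function(f)
      simulate_field(cfg, w, f, render = FALSE)$truth))))
  cells <- truth[!truth$is_debris, ]
  n <- nrow(cells)
  expect_gte(n, 1000)
  p_hat <- mean(cells$is_transfected)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.5 * 0.5 / n))
  nt <- sum(cells$is_transfected)
  e_hat <- sum(cells$is_edited) / nt
  expect_lt(abs(e_hat - 0.3), 3 * sqrt(0.3 * 0.7 / nt))
})

test_that("simulate_plate writes a complete, reproducible run", {
  cfg <- fixture_config(n_cells = 10, field_size = 120, fields_per_well = 2,
                        z_planes = 2, seed = 5)
  d1 <- withr::local_tempdir()
  man <- simulate_plate(cfg, file.path(d1, "run1"), render = TRUE)
  expect_equal(nrow(man$fields), 4 * 2)  # 4 wells x 2 fields
  expect_true(all(file.exists(file.path(d1, "run1", man$fields$path))))
  # refusal without overwrite
  expect_error(simulate_plate(cfg, file.path(d1, "run1")), "overwrite",
               class = "protoquant_io_error")
  # byte-identical truth on re-run with the same seed
  simulate_plate(cfg, file.path(d1, "run2"), render = FALSE)
  expect_identical(readLines(file.path(d1, "run1", "truth.csv")),
                   readLines(file.path(d1, "run2", "truth.csv")))
  # manifest reader round trip
  back <- read_manifest(file.path(d1, "run1"))
  expect_equal(back$seed, cfg$seed)
  expect_equal(nrow(back$fields), 8)
})

test_that("reference-only error-free reads are exact amplicon copies", {
  tg <- fixture_target()
  spec <- allele_spec(list("reference"), 1)
  reads <- simulate_reads(tg, spec, 50, seed = 2, rc_prob = 0)
  expect_true(all(reads$seq == tg$amplicon))
  expect_true(all(nchar(reads$qual) == nchar(reads$seq)))
})

test_that("deterministic allocation gives exact haplotype counts", {
  tg <- fixture_target()
  sub10 <- proto_substitution(tg, 10, "G")
  spec <- allele_spec(list(list(subs = sub10), "reference"), c(0.4, 0.6))
  reads <- simulate_reads(tg, spec, 1000, seed = 4, rc_prob = 0)
  expect_equal(attr(reads, "hap_counts"), c(400, 600))
  edited_seq <- protoquant:::apply_haplotype(tg$amplicon, list(subs = sub10))
  expect_equal(sum(reads$seq == edited_seq), 400)
  expect_equal(sum(reads$seq == tg$amplicon), 600)
})

test_that("read simulation is deterministic and indices prepend cleanly", {
  tg <- fixture_target()
  spec <- allele_spec(list("reference"), 1, qual = c(35, 3))
  r1 <- simulate_reads(tg, spec, 30, seed = 9, rc_prob = 0.5, index = "ACGTAC")
  r2 <- simulate_reads(tg, spec, 30, seed = 9, rc_prob = 0.5, index = "ACGTAC")
  expect_identical(r1, r2)
  expect_true(all(substr(r1$seq, 1, 6) == "ACGTAC"))
  expect_true(all(nchar(r1$seq) == nchar(tg$amplicon) + 6))
})

test_that("per-base error rate is within the binomial envelope", {
  tg <- fixture_target()
  spec <- allele_spec(list("reference"), 1, error_rate = 0.001)
  reads <- simulate_reads(tg, spec, 400, seed = 6, rc_prob = 0)
  ref <- strsplit(tg$amplicon, "")[[1]]
  mm <- vapply(reads$seq, function(s)
    sum(strsplit(s, "")[[1]] != ref), numeric(1), USE.NAMES = FALSE)
  n_bases <- 400 * nchar(tg$amplicon)
  rate <- sum(mm) / n_bases
  expect_lt(abs(rate - 0.001), 3 * sqrt(0.001 * 0.999 / n_bases))
})

test_that("haplotypes extending past the amplicon are rejected", {
  tg <- fixture_target()
  bad_del <- list(indel = list(type = "del", pos = nchar(tg$amplicon) - 1, len = 5))
  spec <- allele_spec(list(bad_del), 1)
  expect_error(simulate_reads(tg, spec, 10, seed = 1), "past",
               class = "protoquant_spec_error")
  expect_error(allele_spec(list("reference"), 0.9), "sum",
               class = "protoquant_input_error")
})
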