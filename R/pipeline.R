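# End-to-end orchestration: config-driven runs tying the simulation,
# imaging, statistics and amplicon layers together.

#' Write result tables plus a run manifest
#'
#' Every writer is deterministic (stable row order); the manifest records
#' the seed and the files written so any output is traceable to its
#' configuration.
#'
#' @param results Named list of data.frames.
#' @param dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @param config Optional configuration echoed into the manifest.
#' @return The manifest list, invisibly.
#' @export
write_tables <- function(results, dir, seed = NA_integer_, config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(results)) {
    path <- file.path(dir, paste0(nm, ".csv"))
    df <- as.data.frame(results[[nm]])
    utils::write.csv(df, path, row.names = FALSE)
    files <- c(files, basename(path))
  }
  manifest <- list(tool = "protoquant", seed = seed, files = files,
                   config = config)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Build a simulation_config from a plain config list (as parsed from YAML).
config_from_list <- function(cfg) {
  wells <- if (!is.null(cfg$layout_csv)) {
    as.data.frame(read_layout(cfg$layout_csv))
  } else if (!is.null(cfg$conditions)) {
    condition_layout(unlist(cfg$conditions),
                     n_rep = cfg$n_rep %||% 3,
                     n_control = cfg$n_control %||% 3,
                     n_cells = cfg$n_cells %||% 400,
                     transfection_rate = cfg$transfection_rate %||% 0.5)
  } else {
    stop_pq("config needs either `layout_csv` or `conditions`",
            class = "protoquant_config_error")
  }
  simulation_config(
    wells,
    fields_per_well = cfg$fields_per_well %||% 9,
    z_planes = cfg$z_planes %||% 7,
    field_size_px = unlist(cfg$field_size_px %||% c(220, 220)),
    species_mode = cfg$species_mode %||% "wheat_chlorophyll",
    vignetting_strength = cfg$vignetting_strength %||% 0.25,
    debris_count = cfg$debris_count %||% 1,
    seed = cfg$seed %||% 1L
  )
}

#' Run a pipeline stage from a configuration
#'
#' Subcommands: `simulate-plate` (render a plate to disk),
#' `segment` (images + layout -> per-cell records and well summaries),
#' `stats` (well summaries -> condition table and group comparisons),
#' `simulate-reads` (amplicon read simulation to FASTQ),
#' `amplicon` (FASTQ -> editing/allele/zygosity tables) and
#' `demo` (a miniature simulate -> segment -> stats round trip).
#'
#' @param config Either a path to a YAML/JSON config file or a named list.
#'   Must contain `subcommand` plus the stage's keys (see the package
#'   vignette for the full schema).
#' @return A list with `status` (0 on success) and `manifest`, invisibly.
#'   Validation problems raise classed conditions; the `exec/protoquant`
#'   script maps them to exit status 2.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop_pq(paste0("config file not found: ", config),
              class = "protoquant_config_error")
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  sub <- config$subcommand %||%
    stop_pq("config is missing `subcommand`", class = "protoquant_config_error")
  out <- config$out %||%
    stop_pq("config is missing `out`", class = "protoquant_config_error")
  seed <- config$seed %||% 1L

  manifest <- switch(
    sub,
    "simulate-plate" = {
      sc <- config_from_list(config)
      simulate_plate(sc, out, overwrite = isTRUE(config$overwrite),
                     render = !isTRUE(config$no_render))
    },
    "segment" = {
      images_dir <- config$images %||%
        stop_pq("segment needs `images` (a simulated-plate directory)",
                class = "protoquant_config_error")
      layout <- read_layout(config$layout_csv %||% file.path(images_dir, "layout.csv"))
      man <- read_manifest(images_dir)
      params <- segmentation_params(
        mode = config$species_mode %||% man$species_mode %||% "wheat_chlorophyll",
        gate_method = config$gate_method %||% "negative_control_quantile")
      recs <- list()
      for (i in seq_len(nrow(man$fields))) {
        f <- man$fields[i, ]
        stack <- read_stack(file.path(images_dir, f$path),
                            channels = man$channels,
                            well = f$well, field = f$field)
        recs[[i]] <- analyze_field(stack, params)
      }
      records <- do.call(rbind, recs)
      gates <- resolve_gates(records, layout, params)
      records <- gate_cells(records, gates)
      wells <- summarize_well(records, layout)
      write_tables(list(cell_records = records, well_summaries = wells,
                        gates = data.frame(mcherry = gates$mcherry,
                                           gfp = gates$gfp)),
                   out, seed = seed, config = config)
    },
    "stats" = {
      wells <- utils::read.csv(config$summaries %||%
                                 stop_pq("stats needs `summaries`",
                                         class = "protoquant_config_error"))
      layout <- read_layout(config$layout_csv)
      cond <- aggregate_condition(wells, layout)
      wells$efficiency <- suppressWarnings(editing_efficiency(wells))
      ok <- !is.na(wells$efficiency) & wells$control_role == "none"
      cmp <- if (length(unique(wells$condition[ok])) >= 2) {
        res <- compare_groups(wells$efficiency[ok], wells$condition[ok],
                              test = config$test %||% "anova_tukey")
        cbind(res$pairwise, omnibus_p = res$omnibus_p)
      } else data.frame()
      write_tables(list(conditions = cond, pairwise = cmp,
                        well_efficiencies = wells),
                   out, seed = seed, config = config)
    },
    "simulate-reads" = {
      tgt <- config$target %||%
        stop_pq("simulate-reads needs `target` (id, amplicon, protospacer, strand)",
                class = "protoquant_config_error")
      target <- amplicon_target(tgt$id, tgt$amplicon, tgt$protospacer,
                                strand = tgt$strand %||% "+",
                                nuclease = tgt$nuclease %||% "Cas12a")
      haps <- lapply(config$alleles$haplotypes, function(h) {
        if (identical(h, "reference")) "reference" else h
      })
      spec <- allele_spec(haps, unlist(config$alleles$fractions),
                          error_rate = config$alleles$error_rate %||% 0,
                          qual = unlist(config$alleles$qual %||% 40))
      reads <- simulate_reads(target, spec, config$n_reads %||% 1000,
                              seed = seed, rc_prob = config$rc_prob %||% 0.5,
                              index = config$index)
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_fastq(reads, file.path(out, "reads.fastq"))
      write_tables(list(hap_counts = data.frame(
        haplotype = seq_along(attr(reads, "hap_counts")),
        n_reads = attr(reads, "hap_counts"))), out, seed = seed,
        config = config)
    },
    "amplicon" = {
      reads <- read_fastq(config$fastq %||%
                            stop_pq("amplicon needs `fastq`",
                                    class = "protoquant_config_error"))
      tgt <- config$target
      target <- amplicon_target(tgt$id, tgt$amplicon, tgt$protospacer,
                                strand = tgt$strand %||% "+",
                                nuclease = tgt$nuclease %||% "Cas12a")
      et <- quantify_amplicon(reads, target)
      zyg <- data.frame(target = target$id,
                        editing_rate_pct = et$conversion_pct,
                        call = call_zygosity(min(et$conversion_pct, 100)))
      write_tables(list(substitutions = et$substitutions,
                        alleles = et$alleles,
                        zygosity = zyg,
                        summary = data.frame(
                          n_input = et$n_input, n_pass = et$n_pass,
                          n_fail = et$n_fail,
                          n_unalignable = et$n_unalignable,
                          indel_pct = et$indel_pct,
                          conversion_pct = et$conversion_pct)),
                   out, seed = seed, config = config)
    },
    "demo" = {
      lay <- condition_layout(c(edited = 0.3), n_rep = 2, n_control = 2,
                              n_cells = 40)
      sc <- simulation_config(lay, fields_per_well = 2, z_planes = 3,
                              field_size_px = c(220, 220), seed = seed)
      plate_dir <- file.path(out, "plate")
      man <- simulate_plate(sc, plate_dir, overwrite = TRUE)
      seg <- run_pipeline(list(subcommand = "segment", images = plate_dir,
                               out = file.path(out, "segmented"),
                               seed = seed))
      run_pipeline(list(subcommand = "stats",
                        summaries = file.path(out, "segmented",
                                              "well_summaries.csv"),
                        layout_csv = file.path(plate_dir, "layout.csv"),
                        out = file.path(out, "stats"), seed = seed))
      man
    },
    stop_pq(paste0("unknown subcommand: ", sub),
            class = "protoquant_config_error")
  )
  invisible(list(status = 0L, manifest = manifest))
}
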