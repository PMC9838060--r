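# Plate-level simulation: renders every field of every well to disk and
# writes the layout, ground-truth table and run manifest.

#' Simulate a whole plate to disk
#'
#' One multi-page TIFF per field (pages channel-major then Z, see
#' [write_stack()]), plus `layout.csv`, `truth.csv` and `manifest.json`
#' tying the run together. Re-running with the same configuration and seed
#' reproduces a byte-identical truth table.
#'
#' @param config A [simulation_config()].
#' @param dir Output directory.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @param render Render pixel data (`TRUE`) or write only the truth/layout
#'   tables (`FALSE`).
#' @return The manifest, invisibly: a list with `fields` (data.frame of
#'   well/field/path), `layout_csv`, `truth_csv`, `channels`, `z_planes`,
#'   `seed`.
#' @export
simulate_plate <- function(config, dir, overwrite = FALSE, render = TRUE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite)
    stop_pq(paste0("output directory exists and is not empty: ", dir,
                   " (use overwrite = TRUE)"),
            class = "protoquant_io_error")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (render) dir.create(file.path(dir, "images"), showWarnings = FALSE)

  fields <- expand.grid(field = seq_len(config$fields_per_well),
                        well = config$wells$well,
                        stringsAsFactors = FALSE)[, c("well", "field")]
  fields <- fields[order(fields$well, fields$field), , drop = FALSE]
  fields$path <- if (render)
    file.path("images", sprintf("%s_f%02d.tif", fields$well, fields$field))
  else NA_character_

  truth <- vector("list", nrow(fields))
  for (i in seq_len(nrow(fields))) {
    res <- simulate_field(config, fields$well[i], fields$field[i],
                          render = render)
    truth[[i]] <- res$truth
    if (render) write_stack(res$stack, file.path(dir, fields$path[i]))
  }
  truth <- do.call(rbind, truth)

  layout_csv <- file.path(dir, "layout.csv")
  truth_csv <- file.path(dir, "truth.csv")
  write_layout(config$wells, layout_csv)
  utils::write.csv(truth, truth_csv, row.names = FALSE, quote = FALSE)

  manifest <- list(
    tool = "protoquant", kind = "simulated_plate",
    seed = config$seed,
    species_mode = config$species_mode,
    channels = PQ_CHANNELS,
    z_planes = config$z_planes,
    field_size_px = config$field_size_px,
    layout_csv = "layout.csv", truth_csv = "truth.csv",
    fields = fields
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a simulated-plate manifest
#'
#' @param dir Run directory written by [simulate_plate()].
#' @return The manifest list (paths relative to `dir`).
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path))
    stop_pq(paste0("no manifest.json in ", dir), class = "protoquant_io_error")
  jsonlite::read_json(path, simplifyVector = TRUE)
}
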