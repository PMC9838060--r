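# Simulation configuration: the study conditions under which synthetic
# plates are generated.

#' Default per-channel intensity model
#'
#' Foreground means/sds are 16-bit intensities of in-focus objects;
#' `bg` is the camera/background offset and `noise_sd` the additive
#' Gaussian read-noise. Defaults give well-separated nuclear reporter
#' signals over background, as observed for strong constitutive promoters.
#'
#' @return Named list of channel models.
#' @export
default_intensity_model <- function() {
  list(
    brightfield = list(fg_mean = 15000, fg_sd = 1500, bg = 22000, noise_sd = 120),
    chlorophyll = list(fg_mean = 9000,  fg_sd = 1200, bg = 300,   noise_sd = 60),
    GFP         = list(fg_mean = 12000, fg_sd = 2200, bg = 260,   noise_sd = 60),
    mCherry     = list(fg_mean = 15000, fg_sd = 2500, bg = 260,   noise_sd = 60)
  )
}

#' Build a plate-simulation configuration
#'
#' Encodes the acquisition geometry being emulated (96-well plate, 9 fields
#' per well, 7 Z planes, 4 channels) and the per-well biological conditions.
#' `wells` is a simulation layout (see [plate_layout()]) whose per-well
#' columns `n_cells` (cells plated per well, split across fields),
#' `transfection_rate` and `editing_rate` define the ground truth.
#'
#' @param wells A data.frame/[plate_layout()] with columns `well`,
#'   `condition`, `replicate`, `control_role`, `n_cells`,
#'   `transfection_rate`, `editing_rate`.
#' @param plate_shape `c(rows, cols)`; default `c(8, 12)`.
#' @param fields_per_well Fields of view per well (default 9).
#' @param z_planes Z planes per channel (default 7).
#' @param field_size_px `c(height, width)` of a field in pixels.
#' @param species_mode `"wheat_chlorophyll"` (round chlorophyll-filled
#'   protoplasts) or `"maize_etiolated"` (no chlorophyll signal; analysis
#'   proceeds from nuclei).
#' @param cell_radius,nucleus_radius `c(mean, sd)` in pixels.
#' @param intensity_model See [default_intensity_model()].
#' @param vignetting_strength Multiplicative radial falloff in `[0, 1)`.
#' @param debris_count Elongated debris objects rendered per field.
#' @param rc_prob Unused placeholder for symmetry with read simulation.
#' @param seed Master RNG seed; all per-well/per-field substreams derive
#'   from it (see [substream_seed()]).
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(wells,
                              plate_shape = c(8, 12),
                              fields_per_well = 9,
                              z_planes = 7,
                              field_size_px = c(220, 220),
                              species_mode = c("wheat_chlorophyll", "maize_etiolated"),
                              cell_radius = c(11, 1.5),
                              nucleus_radius = c(3.5, 0.5),
                              intensity_model = default_intensity_model(),
                              vignetting_strength = 0.25,
                              debris_count = 1,
                              seed = 1L) {
  species_mode <- match.arg(species_mode)
  assert_number(fields_per_well, "fields_per_well", lower = 1)
  assert_number(z_planes, "z_planes", lower = 1)
  assert_number(vignetting_strength, "vignetting_strength", lower = 0, upper = 1 - 1e-9)
  assert_number(debris_count, "debris_count", lower = 0)
  if (cell_radius[1] <= 0 || nucleus_radius[1] <= 0)
    stop_pq("radii must be positive", class = "protoquant_input_error")
  if (nucleus_radius[1] >= cell_radius[1])
    stop_pq("nucleus radius must be smaller than cell radius",
            class = "protoquant_input_error")
  for (col in c("n_cells", "transfection_rate", "editing_rate")) {
    if (!col %in% names(wells))
      stop_pq(paste0("simulation layout is missing column: ", col),
              class = "protoquant_input_error")
  }
  wells <- plate_layout(as.data.frame(wells),
                        rows = plate_shape[1], cols = plate_shape[2])
  structure(list(
    wells = wells,
    plate_shape = as.integer(plate_shape),
    fields_per_well = as.integer(fields_per_well),
    z_planes = as.integer(z_planes),
    field_size_px = as.integer(field_size_px),
    species_mode = species_mode,
    cell_radius = cell_radius,
    nucleus_radius = nucleus_radius,
    intensity_model = intensity_model,
    vignetting_strength = vignetting_strength,
    debris_count = as.integer(debris_count),
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Simulation layout for a small set of conditions
#'
#' Convenience constructor: assigns `n_rep` replicate wells per condition in
#' plate order, plus `n_control` no-guide control wells (same transfection
#' rate, editing rate 0).
#'
#' @param conditions Named numeric vector: condition label -> true editing
#'   rate in `[0, 1]`.
#' @param n_rep Replicate wells per condition.
#' @param n_control No-guide control wells.
#' @param n_cells Cells plated per well.
#' @param transfection_rate Per-well transfection rate (default 0.5; arrayed
#'   protoplast transfections typically achieve 40-65\%).
#' @param rows,cols Plate shape.
#' @return A simulation [plate_layout()].
#' @export
condition_layout <- function(conditions, n_rep = 3, n_control = 3,
                             n_cells = 400, transfection_rate = 0.5,
                             rows = 8, cols = 12) {
  labels <- c(rep(names(conditions), each = n_rep), rep("control", n_control))
  rates <- c(rep(unname(conditions), each = n_rep), rep(0, n_control))
  roles <- c(rep("none", length(conditions) * n_rep),
             rep("no_guide_control", n_control))
  reps <- c(unlist(lapply(conditions, function(x) seq_len(n_rep)),
                   use.names = FALSE), seq_len(n_control))
  wells <- plate_wells(rows, cols)
  if (length(labels) > length(wells))
    stop_pq("more condition wells than plate positions",
            class = "protoquant_input_error")
  plate_layout(data.frame(
    well = wells[seq_along(labels)],
    condition = labels, replicate = reps, control_role = roles,
    n_cells = n_cells, transfection_rate = transfection_rate,
    editing_rate = rates, stringsAsFactors = FALSE
  ), rows = rows, cols = cols)
}
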