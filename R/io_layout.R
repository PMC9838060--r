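# Plate-layout reading, writing and validation.

#' Well identifiers of a rectangular plate
#'
#' @param rows,cols Plate shape (default 8 x 12, a 96-well plate).
#' @return Character vector `"A1" ... "H12"` in row-major order.
#' @export
plate_wells <- function(rows = 8, cols = 12) {
  if (rows < 1 || rows > 26 || cols < 1)
    stop_pq("plate shape must have 1-26 rows and >= 1 columns",
            class = "protoquant_input_error")
  as.vector(t(outer(LETTERS[seq_len(rows)], seq_len(cols), paste0)))
}

#' Construct and validate a plate layout
#'
#' A layout maps wells to experimental conditions. Required columns are
#' `well`, `condition`, `replicate` and `control_role`
#' (`"none"`, `"no_guide_control"` or `"reporter_only"`). Simulation
#' layouts additionally carry `n_cells`, `transfection_rate` and
#' `editing_rate` per well.
#'
#' @param df A data.frame with at least the required columns.
#' @param rows,cols Plate shape used to validate well ids.
#' @return The validated data.frame with class `"plate_layout"`.
#' @export
plate_layout <- function(df, rows = 8, cols = 12) {
  req <- c("well", "condition", "replicate", "control_role")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop_pq(paste0("layout is missing column(s): ", paste(miss, collapse = ", ")),
            class = "protoquant_format_error")
  valid <- plate_wells(rows, cols)
  bad <- setdiff(df$well, valid)
  if (length(bad))
    stop_pq(paste0("well id(s) outside the ", rows, "x", cols, " plate: ",
                   paste(utils::head(bad, 5), collapse = ", ")),
            class = "protoquant_format_error")
  if (anyDuplicated(df$well))
    stop_pq(paste0("duplicated well id(s): ",
                   paste(unique(df$well[duplicated(df$well)]), collapse = ", ")),
            class = "protoquant_format_error")
  ok_roles <- c("none", "no_guide_control", "reporter_only")
  bad_role <- setdiff(unique(df$control_role), ok_roles)
  if (length(bad_role))
    stop_pq(paste0("unknown control_role: ", paste(bad_role, collapse = ", ")),
            class = "protoquant_format_error")
  for (col in intersect(c("transfection_rate", "editing_rate"), names(df))) {
    if (any(df[[col]] < 0 | df[[col]] > 1, na.rm = TRUE))
      stop_pq(sprintf("`%s` must lie in [0, 1]", col),
              class = "protoquant_format_error")
  }
  attr(df, "plate_shape") <- c(rows = rows, cols = cols)
  class(df) <- c("plate_layout", "data.frame")
  df
}

#' Read or write a plate-layout CSV
#'
#' @param path CSV path (UTF-8, header row).
#' @param rows,cols Plate shape for validation.
#' @return `read_layout()` returns a validated [plate_layout()];
#'   `write_layout()` returns `path` invisibly.
#' @export
read_layout <- function(path, rows = 8, cols = 12) {
  if (!file.exists(path))
    stop_pq(paste0("layout file not found: ", path), class = "protoquant_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  plate_layout(df, rows = rows, cols = cols)
}

#' @rdname read_layout
#' @param layout A [plate_layout()] (or coercible data.frame).
#' @export
write_layout <- function(layout, path) {
  df <- as.data.frame(layout)
  df <- df[order(df$well), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
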