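# Channel stacks: the raw acquisition unit (one field of view) and its
# multi-page TIFF serialization.

PQ_CHANNELS <- c("brightfield", "chlorophyll", "GFP", "mCherry")

#' Construct a channel stack
#'
#' One field's raw acquisition: named channels, each a `height x width x z`
#' array of 16-bit intensities (stored as numerics in `[0, 65535]`).
#'
#' @param channels Named list of 3-d arrays (or matrices, treated as one Z
#'   plane). All planes must share dimensions.
#' @param well,field Field identity.
#' @param pixel_size Optional pixel size in micrometres.
#' @return An object of class `"channel_stack"`.
#' @export
channel_stack <- function(channels, well = NA_character_, field = NA_integer_,
                          pixel_size = NULL) {
  if (is.null(names(channels)) || any(!nzchar(names(channels))))
    stop_pq("channels must be a named list", class = "protoquant_format_error")
  if (anyDuplicated(names(channels)))
    stop_pq("channel names must be unique", class = "protoquant_format_error")
  channels <- lapply(channels, function(ch) {
    if (is.matrix(ch)) ch <- array(ch, dim = c(dim(ch), 1L))
    if (length(dim(ch)) != 3L)
      stop_pq("each channel must be a matrix or 3-d array",
              class = "protoquant_format_error")
    ch
  })
  dims <- lapply(channels, dim)
  if (length(unique(lapply(dims, function(d) d[1:2]))) != 1L)
    stop_pq("all channel planes must share x/y dimensions",
            class = "protoquant_format_error")
  if (length(unique(vapply(dims, `[`, integer(1), 3L))) != 1L)
    stop_pq("all channels must have the same number of Z planes",
            class = "protoquant_format_error")
  structure(list(channels = channels, well = well, field = field,
                 pixel_size = pixel_size),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<channel_stack> well %s field %s: %d channel(s) [%s], %dx%d px, %d Z plane(s)\n",
              x$well, x$field, length(x$channels),
              paste(names(x$channels), collapse = ", "), d[1], d[2], d[3]))
  invisible(x)
}

#' Write / read a channel stack as a multi-page 16-bit TIFF
#'
#' Pages are ordered channel-major then Z (all Z planes of channel 1, then
#' channel 2, ...). The TIFF container itself does not carry the channel
#' names; they are recorded in the run manifest written by
#' [simulate_plate()] and can be overridden with `channels` when reading a
#' file outside a managed run. Pixel values round-trip exactly (16-bit).
#'
#' @param stack A [channel_stack()].
#' @param path TIFF file path.
#' @return `write_stack()` returns `path` invisibly.
#' @export
write_stack <- function(stack, path) {
  pages <- list()
  for (ch in stack$channels) {
    for (z in seq_len(dim(ch)[3])) {
      pages[[length(pages) + 1L]] <- pmin(pmax(ch[, , z], 0), 65535) / 65535
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  invisible(path)
}

#' @rdname write_stack
#' @param channels Channel names, in on-disk page order. The page count must
#'   be a multiple of `length(channels)`.
#' @param well,field Field identity to attach to the result.
#' @export
read_stack <- function(path, channels = PQ_CHANNELS,
                       well = NA_character_, field = NA_integer_) {
  if (!file.exists(path))
    stop_pq(paste0("stack file not found: ", path), class = "protoquant_io_error")
  pages <- tiff::readTIFF(path, all = TRUE)
  n <- length(pages)
  if (n %% length(channels) != 0L)
    stop_pq(sprintf("%d TIFF pages are not divisible by %d channels",
                    n, length(channels)),
            class = "protoquant_format_error")
  nz <- n %/% length(channels)
  chans <- list()
  for (i in seq_along(channels)) {
    planes <- pages[((i - 1L) * nz + 1L):(i * nz)]
    a <- array(0, dim = c(dim(planes[[1]]), nz))
    for (z in seq_len(nz)) a[, , z] <- round(planes[[z]] * 65535)
    chans[[channels[i]]] <- a
  }
  channel_stack(chans, well = well, field = field)
}
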