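# FASTQ reading/writing. Reads are represented as a plain data.frame with
# columns id, seq, qual (Phred+33), which keeps per-record qualities and
# record-level validation trivial for the 4-line records this pipeline
# produces and consumes.

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ path (uncompressed or gzipped, 4 lines per record).
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path))
    stop_pq(paste0("FASTQ file not found: ", path), class = "protoquant_io_error")
  lines <- readLines(path)
  lines <- lines[nzchar(lines) | seq_along(lines) <= (length(lines) %/% 4L) * 4L]
  if (length(lines) %% 4L != 0L)
    stop_pq(sprintf("FASTQ %s is truncated: %d lines is not a multiple of 4",
                    path, length(lines)),
            class = "protoquant_format_error")
  n <- length(lines) %/% 4L
  if (n == 0L) return(data.frame(id = character(), seq = character(),
                                 qual = character(), stringsAsFactors = FALSE))
  idx <- seq_len(n)
  hdr <- lines[4L * idx - 3L]
  seq <- lines[4L * idx - 2L]
  sep <- lines[4L * idx - 1L]
  qual <- lines[4L * idx]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr))
    stop_pq(sprintf("record %d (line %d): header does not start with '@'",
                    bad_hdr[1], 4L * bad_hdr[1] - 3L),
            class = "protoquant_format_error")
  bad_sep <- which(!startsWith(sep, "+"))
  if (length(bad_sep))
    stop_pq(sprintf("record %d (line %d): separator does not start with '+'",
                    bad_sep[1], 4L * bad_sep[1] - 1L),
            class = "protoquant_format_error")
  bad_len <- which(nchar(seq) != nchar(qual))
  if (length(bad_len))
    stop_pq(sprintf("record %d ('%s'): sequence length %d != quality length %d",
                    bad_len[1], sub("^@", "", hdr[bad_len[1]]),
                    nchar(seq[bad_len[1]]), nchar(qual[bad_len[1]])),
            class = "protoquant_format_error")
  data.frame(id = sub("^@", "", hdr), seq = seq, qual = qual,
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) && any(nchar(reads$seq) != nchar(reads$qual)))
    stop_pq("sequence/quality length mismatch", class = "protoquant_format_error")
  out <- character(4L * nrow(reads))
  if (nrow(reads)) {
    idx <- seq_len(nrow(reads))
    out[4L * idx - 3L] <- paste0("@", reads$id)
    out[4L * idx - 2L] <- reads$seq
    out[4L * idx - 1L] <- "+"
    out[4L * idx] <- reads$qual
  }
  writeLines(out, path)
  invisible(path)
}

#' Encode / decode Phred+33 quality strings
#'
#' @param scores Integer vector of Phred scores (one read), or a list of them.
#' @return `phred_encode()` returns quality string(s); `phred_decode()` a
#'   list of integer vectors.
#' @export
phred_encode <- function(scores) {
  if (is.list(scores))
    return(vapply(scores, phred_encode, character(1)))
  intToUtf8(pmin(pmax(as.integer(scores), 0L), 93L) + 33L)
}

#' @rdname phred_encode
#' @param qual Character vector of Phred+33 quality strings.
#' @export
phred_decode <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}
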