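# Internal helpers: argument checking, seed substreams, small formatters.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pq <- function(msg, class = "protoquant_error", ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop_pq(sprintf("`%s` must be a single number in [%s, %s]",
                    name, format(lower), format(upper)),
            class = "protoquant_input_error")
  x
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_pq(sprintf("`%s` must be TRUE or FALSE", name),
            class = "protoquant_input_error")
  x
}

#' Derive a reproducible substream seed
#'
#' One master seed expands into named substreams (per well, per field, per
#' module) through an integer hash, so that regenerating a single field or
#' read set does not depend on how much of the plate was generated before it.
#'
#' @param master Integer master seed.
#' @param ... Integers or strings identifying the substream (e.g. well id,
#'   field index).
#' @return A single integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @export
substream_seed <- function(master, ...) {
  ids <- list(...)
  h <- as.double(master %% 2147483647L)
  for (id in ids) {
    codes <- if (is.character(id)) utf8ToInt(paste(id, collapse = "/")) else as.integer(id)
    for (k in codes) {
      # 31-bit multiplicative hash; kept in double precision (exact < 2^53)
      h <- (h * 48271 + as.double(k) + 11) %% 2147483647
    }
    h <- (h * 16807 + 7) %% 2147483647
  }
  as.integer(h %% 2147483646) + 1L
}

#' Round a percentage for reporting
#'
#' Percentages are reported to one decimal place in screen tables; raw
#' values are kept alongside in all outputs.
#'
#' @param x Numeric vector of percentages.
#' @return `x` rounded to one decimal.
#' @export
report_pct <- function(x) round(x, 1)

# Mean Phred score of "Phred+33"-encoded quality strings.
phred_mean <- function(qual) {
  vapply(qual, function(q) {
    if (nchar(q) == 0L) return(NA_real_)
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(b) {
  c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")[b]
}
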