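# Amplicon targets and the quantification-window parameterization.

#' Define an amplicon target
#'
#' Binds an amplicon sequence to the protospacer it contains and to the
#' quantification parameters used to score reads: window size `w` (default
#' 10), window center `c` relative to the protospacer 3' end (default -12),
#' cleavage offsets for substitution and indel scoring (defaults -1 and -4;
#' -4 matches the staggered Cas12a cut), and the minimum mean read quality
#' (default Q30).
#'
#' @param id Target identifier.
#' @param amplicon Uppercase DNA amplicon sequence.
#' @param protospacer Protospacer sequence, written 5'->3'.
#' @param strand `"+"` if the protospacer matches the amplicon as given,
#'   `"-"` if it matches the reverse complement. Must occur exactly once on
#'   the stated strand.
#' @param nuclease `"Cas12a"` or `"Cas9"` (controls the position-numbering
#'   tag and the seed-region convention, not the arithmetic).
#' @param window_size,window_center Quantification window parameters.
#' @param cleavage_offset,cleavage_offset_indel Cleavage offsets used for
#'   substitution and indel windows respectively.
#' @param min_quality Minimum mean Phred quality for a read to pass.
#' @return An object of class `"amplicon_target"`.
#' @export
amplicon_target <- function(id, amplicon, protospacer, strand = c("+", "-"),
                            nuclease = c("Cas12a", "Cas9"),
                            window_size = 10, window_center = -12,
                            cleavage_offset = -1, cleavage_offset_indel = -4,
                            min_quality = 30) {
  strand <- match.arg(strand)
  nuclease <- match.arg(nuclease)
  amplicon <- toupper(amplicon)
  protospacer <- toupper(protospacer)
  assert_number(window_size, "window_size", lower = 1)
  assert_number(min_quality, "min_quality", lower = 0)
  search_in <- if (strand == "+") amplicon else revcomp(amplicon)
  hits <- gregexpr(protospacer, search_in, fixed = TRUE)[[1]]
  n_hits <- if (hits[1] == -1L) 0L else length(hits)
  if (n_hits != 1L)
    stop_pq(sprintf("protospacer must occur exactly once on strand '%s' (found %d)",
                    strand, n_hits),
            class = "protoquant_input_error")
  # protospacer location in amplicon coordinates (plus strand)
  L <- nchar(protospacer)
  if (strand == "+") {
    start <- as.integer(hits[1])
  } else {
    start <- nchar(amplicon) - as.integer(hits[1]) - L + 2L
  }
  structure(list(
    id = id, amplicon = amplicon, protospacer = protospacer,
    strand = strand, nuclease = nuclease,
    proto_start = start, proto_end = start + L - 1L, proto_len = L,
    window_size = as.integer(window_size),
    window_center = as.integer(window_center),
    cleavage_offset = as.integer(cleavage_offset),
    cleavage_offset_indel = as.integer(cleavage_offset_indel),
    min_quality = min_quality
  ), class = "amplicon_target")
}

#' @export
print.amplicon_target <- function(x, ...) {
  cat(sprintf("<amplicon_target> %s: %d bp amplicon, %d nt %s protospacer on '%s' at %d-%d\n",
              x$id, nchar(x$amplicon), x$proto_len, x$nuclease, x$strand,
              x$proto_start, x$proto_end))
  invisible(x)
}

#' Quantification window positions
#'
#' The window of protospacer positions over which edits are scored. With
#' protospacer length `L`, center offset `c` and size `w`, the center is
#' `p_c = L + c` and the window spans
#' `[p_c - ceiling(w/2) + 1, p_c + floor(w/2)]`, clipped to `[1, L]`.
#' For the canonical `L = 20, w = 10, c = -12` this yields positions 4-13,
#' the classic base-editing window.
#'
#' @param target An [amplicon_target()].
#' @param size,center Override the target's window size / center.
#' @return Integer vector of 1-based protospacer positions (position 1 is
#'   the protospacer's 5' base).
#' @export
quantification_window <- function(target, size = target$window_size,
                                  center = target$window_center) {
  L <- target$proto_len
  if (abs(center) >= L)
    stop_pq(sprintf("|window center| (%d) must be < protospacer length (%d)",
                    abs(center), L),
            class = "protoquant_config_error")
  pc <- L + center
  lo <- pc - ceiling(size / 2) + 1
  hi <- pc + floor(size / 2)
  win <- intersect(seq(lo, hi), seq_len(L))
  if (!length(win))
    stop_pq("empty quantification window", class = "protoquant_config_error")
  as.integer(win)
}

# Indel-scoring window: same span formula, centered at the cleavage
# position L + cleavage_offset_indel.
indel_window <- function(target) {
  quantification_window(target, size = target$window_size,
                        center = target$cleavage_offset_indel)
}

#' Map protospacer positions to amplicon coordinates
#'
#' @param target An [amplicon_target()].
#' @param pos 1-based protospacer positions (5'->3' along the protospacer).
#' @return Integer amplicon positions (plus strand).
#' @export
proto_to_amplicon <- function(target, pos) {
  if (any(pos < 1 | pos > target$proto_len))
    stop_pq("protospacer position out of range", class = "protoquant_input_error")
  if (target$strand == "+") target$proto_start + as.integer(pos) - 1L
  else target$proto_end - as.integer(pos) + 1L
}

#' Describe a substitution given in protospacer coordinates
#'
#' Convenience for building [allele_spec()] haplotypes: converts "base `to`
#' at protospacer position `pos`" into the equivalent amplicon-strand
#' substitution (complemented for minus-strand protospacers).
#'
#' @param target An [amplicon_target()].
#' @param pos 1-based protospacer position.
#' @param to Replacement base, written on the protospacer strand.
#' @return One-row data.frame with columns `pos` (amplicon) and `base`.
#' @export
proto_substitution <- function(target, pos, to) {
  apos <- proto_to_amplicon(target, pos)
  base <- if (target$strand == "+") toupper(to) else unname(comp_base(toupper(to)))
  data.frame(pos = apos, base = base, stringsAsFactors = FALSE)
}

#' Classify an editing rate as WT / heterozygous / homozygous
#'
#' Rates between 25 and 70 percent (inclusive) are called heterozygous,
#' rates above 70 percent homozygous, lower rates wild type.
#'
#' @param rate Editing rate(s) in percent, in `[0, 100]`.
#' @return Character vector of calls in `{"WT", "HZ", "HM"}`.
#' @export
call_zygosity <- function(rate) {
  if (any(is.na(rate)) || any(rate < 0 | rate > 100))
    stop_pq("editing rate must lie in [0, 100]", class = "protoquant_input_error")
  ifelse(rate > 70, "HM", ifelse(rate >= 25, "HZ", "WT"))
}

#' Annotate spacer/locus mismatches with seed or PAM-distal labels
#'
#' Compares a spacer to an equal-length genomic locus (gap-free) and labels
#' each mismatched position as lying in the seed region (where mismatches
#' strongly suppress activity) or the PAM-distal region. For Cas12a the
#' PAM is 5' of the protospacer, so the seed is positions 1-8; for Cas9
#' (3' PAM) the seed is the last 8 positions.
#'
#' @param spacer,locus Equal-length DNA strings, protospacer orientation.
#' @param nuclease `"Cas12a"` or `"Cas9"`.
#' @param seed_length Seed-region length (default 8).
#' @return data.frame with columns `position`, `spacer`, `locus`, `region`
#'   (`"seed"` or `"distal"`); zero rows when the sequences match.
#' @export
annotate_spacer_mismatches <- function(spacer, locus,
                                       nuclease = c("Cas12a", "Cas9"),
                                       seed_length = 8) {
  nuclease <- match.arg(nuclease)
  spacer <- toupper(spacer); locus <- toupper(locus)
  if (nchar(spacer) != nchar(locus))
    stop_pq("spacer and locus must have equal length",
            class = "protoquant_input_error")
  s <- strsplit(spacer, "")[[1]]
  l <- strsplit(locus, "")[[1]]
  pos <- which(s != l)
  L <- length(s)
  seed_pos <- if (nuclease == "Cas12a") seq_len(min(seed_length, L))
  else seq(max(1, L - seed_length + 1), L)
  data.frame(position = pos, spacer = s[pos], locus = l[pos],
             region = ifelse(pos %in% seed_pos, "seed", "distal"),
             stringsAsFactors = FALSE)
}
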