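# Quantification of substitutions, indels and alleles from aligned reads.

# Amplicon coordinates of the substitution window, sorted ascending.
sub_window_amp <- function(target)
  sort(proto_to_amplicon(target, quantification_window(target)))

ind_window_amp <- function(target)
  sort(proto_to_amplicon(target, indel_window(target)))

# Per-read classification against a target. A read is indel-class iff its
# alignment has a deletion at, or an insertion adjacent to, the indel
# window (size w centered at the cleavage position L + indel offset).
classify_reads <- function(aln, target) {
  sw <- sub_window_amp(target)
  iw <- ind_window_amp(target)
  lo <- min(iw); hi <- max(iw)
  n <- length(aln$aligned)
  covered <- del_win <- ins_win <- sub_win <- rep(FALSE, n)
  ref <- strsplit(target$amplicon, "")[[1]]
  for (i in seq_len(n)) {
    if (!aln$aligned[i]) next
    row <- aln$matrix[i, ]
    covered[i] <- all(row[sw] != ".") && all(row[iw] != ".")
    del_win[i] <- any(row[iw] == "-")
    if (!is.null(aln$insertions[[i]]))
      ins_win[i] <- any(aln$insertions[[i]]$pos >= lo - 1L &
                          aln$insertions[[i]]$pos <= hi)
    sub_win[i] <- any(row[sw] != "-" & row[sw] != "." & row[sw] != ref[sw])
  }
  is_indel <- del_win | ins_win
  cls <- rep(NA_character_, n)
  cls[aln$aligned & covered & is_indel] <- "indel"
  cls[aln$aligned & covered & !is_indel & sub_win] <- "substituted"
  cls[aln$aligned & covered & !is_indel & !sub_win] <- "unmodified"
  cls[aln$aligned & !covered] <- "incomplete"
  cls
}

#' Per-position substitution frequencies
#'
#' For every quantification-window position and every base different from
#' the reference, the percent of quantifiable reads carrying that base.
#' Reads with an indel overlapping the indel window are counted in the
#' indel class and excluded from the substitution denominators; the
#' denominator at a position is the number of remaining passing reads that
#' cover the position gap-free. Positions and bases are reported 5'->3'
#' along the protospacer (position 1 is the protospacer's 5' base; for a
#' minus-strand protospacer, base identities are complemented accordingly).
#'
#' @param aln An [align_reads()] result.
#' @param target The matching [amplicon_target()].
#' @return data.frame with columns `position`, `ref`, `pct_A`, `pct_C`,
#'   `pct_G`, `pct_T`, `n_reads` (denominator), plus attributes
#'   `numbering` (figure-style label of position 1) and `class_counts`.
#' @export
quantify_substitutions <- function(aln, target) {
  win <- quantification_window(target)
  amp_pos <- proto_to_amplicon(target, win)
  cls <- classify_reads(aln, target)
  usable <- which(cls %in% c("substituted", "unmodified"))
  ref <- strsplit(target$amplicon, "")[[1]]
  bases <- c("A", "C", "G", "T")
  out <- data.frame(position = win,
                    ref = character(length(win)),
                    pct_A = 0, pct_C = 0, pct_G = 0, pct_T = 0,
                    n_reads = 0L, stringsAsFactors = FALSE)
  minus <- target$strand == "-"
  for (k in seq_along(win)) {
    a <- amp_pos[k]
    col <- aln$matrix[usable, a]
    good <- col %in% bases
    denom <- sum(good)
    ref_amp <- ref[a]
    ref_proto <- if (minus) unname(comp_base(ref_amp)) else ref_amp
    out$ref[k] <- ref_proto
    out$n_reads[k] <- denom
    if (denom > 0) {
      counts <- table(factor(col[good], levels = bases))
      for (b in bases) {
        b_proto <- if (minus) unname(comp_base(b)) else b
        if (b_proto == ref_proto) next
        out[[paste0("pct_", b_proto)]][k] <- 100 * counts[[b]] / denom
      }
    }
  }
  attr(out, "numbering") <- if (target$nuclease == "Cas12a")
    "position 1 = PAM-adjacent (5' of protospacer)"
  else "position 1 = PAM-distal (5' of protospacer)"
  attr(out, "class_counts") <- table(factor(cls, levels = c(
    "indel", "substituted", "unmodified", "incomplete")))
  out
}

#' Indel rate and length spectrum
#'
#' A read counts as an indel read iff its alignment contains an insertion
#' or deletion overlapping the indel window (size `w`, centered at the
#' cleavage position `L + cleavage_offset_indel`). The rate denominator is
#' all quantifiable (passing, window-covering) reads.
#'
#' @inheritParams quantify_substitutions
#' @return List with `pct`, `n_indel`, `n_reads`, `del_lengths` and
#'   `ins_lengths` (tables of event length vs read count).
#' @export
quantify_indels <- function(aln, target) {
  cls <- classify_reads(aln, target)
  n_quant <- sum(cls %in% c("indel", "substituted", "unmodified"))
  idx <- which(cls == "indel")
  iw <- ind_window_amp(target)
  lo <- min(iw); hi <- max(iw)
  del_len <- integer(0); ins_len <- integer(0)
  for (i in idx) {
    row <- aln$matrix[i, ]
    r <- rle(row == "-")
    if (any(r$values)) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        if (starts[k] <= hi && ends[k] >= lo)
          del_len <- c(del_len, r$lengths[k])
      }
    }
    if (!is.null(aln$insertions[[i]])) {
      sel <- aln$insertions[[i]]$pos >= lo - 1L & aln$insertions[[i]]$pos <= hi
      ins_len <- c(ins_len, nchar(aln$insertions[[i]]$seq[sel]))
    }
  }
  list(pct = if (n_quant) 100 * length(idx) / n_quant else 0,
       n_indel = length(idx), n_reads = n_quant,
       del_lengths = table(del_len), ins_lengths = table(ins_len))
}

#' Allele table over the quantification window
#'
#' Groups quantifiable reads by their window haplotype (the read bases
#' across the quantification window, with `-` for deleted bases and any
#' insertions spliced in), reported 5'->3' along the protospacer. Rows are
#' sorted by count descending, ties broken by sequence.
#'
#' @inheritParams quantify_substitutions
#' @return data.frame with columns `haplotype`, `count`, `pct`,
#'   `annotation` (comma-separated deviations from reference, or
#'   `"reference"`).
#' @export
allele_table <- function(aln, target) {
  win <- quantification_window(target)
  amp_pos <- sort(proto_to_amplicon(target, win))
  lo <- min(amp_pos); hi <- max(amp_pos)
  cls <- classify_reads(aln, target)
  usable <- which(cls %in% c("indel", "substituted", "unmodified"))
  minus <- target$strand == "-"
  haps <- vapply(usable, function(i) {
    pieces <- character(0)
    insl <- aln$insertions[[i]]
    for (a in amp_pos) {
      pieces <- c(pieces, aln$matrix[i, a])
      if (!is.null(insl)) {
        sel <- which(insl$pos == a & a < hi)
        if (length(sel)) pieces <- c(pieces, insl$seq[sel])
      }
    }
    h <- paste(pieces, collapse = "")
    if (minus) {
      h_nogap <- chartr("ACGTN-", "TGCAN-", h)
      h <- paste(rev(strsplit(h_nogap, "")[[1]]), collapse = "")
    }
    h
  }, character(1))
  ref_hap <- paste(strsplit(target$amplicon, "")[[1]][amp_pos], collapse = "")
  if (minus) ref_hap <- revcomp(ref_hap)
  tab <- table(haps)
  out <- data.frame(haplotype = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$haplotype), , drop = FALSE]
  rownames(out) <- NULL
  out$pct <- if (length(usable)) 100 * out$count / length(usable) else numeric(0)
  ref_chars <- strsplit(ref_hap, "")[[1]]
  out$annotation <- vapply(out$haplotype, function(h) {
    if (h == ref_hap) return("reference")
    hc <- strsplit(h, "")[[1]]
    if (length(hc) != length(ref_chars))
      return(if (length(hc) > length(ref_chars)) "ins" else "del")
    diffs <- which(hc != ref_chars)
    ann <- character(0)
    for (d in diffs) {
      p <- win[d]
      ann <- c(ann, if (hc[d] == "-") sprintf("p%d:del", p)
               else sprintf("p%d:%s>%s", p, ref_chars[d], hc[d]))
    }
    paste(ann, collapse = ",")
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Quantify one sample against one target
#'
#' End-to-end quantification: quality filter (mean Phred >= `Q`), alignment,
#' per-position substitution table, indel rate, allele table, and the read
#' bookkeeping (`passing + failing = input`;
#' `indel + substituted + unmodified + incomplete = aligned`).
#'
#' @param reads data.frame (`id`, `seq`, `qual`).
#' @param target An [amplicon_target()].
#' @return An object of class `"editing_table"`: list with elements
#'   `substitutions`, `indels`, `alleles`, `class_counts`, `n_input`,
#'   `n_pass`, `n_fail`, `n_unalignable`, `conversion_pct` (maximum
#'   per-position substitution percent, the headline conversion rate), and
#'   `indel_pct`.
#' @export
quantify_amplicon <- function(reads, target) {
  qf <- quality_filter(reads, target$min_quality)
  aln <- align_reads(qf$pass, target)
  subs <- quantify_substitutions(aln, target)
  ind <- quantify_indels(aln, target)
  alle <- allele_table(aln, target)
  cc <- attr(subs, "class_counts")
  pct_cols <- c("pct_A", "pct_C", "pct_G", "pct_T")
  conv <- if (nrow(subs)) max(as.matrix(subs[, pct_cols])) else 0
  structure(list(
    target = target$id,
    substitutions = subs,
    indels = ind,
    alleles = alle,
    class_counts = cc,
    n_input = nrow(reads),
    n_pass = nrow(qf$pass),
    n_fail = nrow(qf$fail),
    n_unalignable = sum(!aln$aligned),
    conversion_pct = conv,
    indel_pct = ind$pct
  ), class = "editing_table")
}

#' @export
print.editing_table <- function(x, ...) {
  cat(sprintf("<editing_table> target %s: %d reads in, %d pass QC, %d unalignable\n",
              x$target, x$n_input, x$n_pass, x$n_unalignable))
  cat(sprintf("  max conversion %.1f%%, indels %.1f%%\n",
              x$conversion_pct, x$indel_pct))
  invisible(x)
}
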