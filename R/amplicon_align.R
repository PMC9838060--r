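# Read-to-amplicon alignment. The aligner is semi-global: the whole read is
# aligned against a substring of the amplicon (free end gaps on the
# amplicon), scored with match +2, mismatch -1, and affine gaps costing
# 5 + length. Both orientations are scored and the better one kept.

#' Demultiplex reads by inline 6-nt index
#'
#' Assigns each read to at most one sample by its 5' 6-nt prefix, trims the
#' index (bases and qualities) from assigned reads, and reports per-sample
#' counts. Assigned + unassigned always equals the input.
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param index_table data.frame with columns `sample`, `index` (6-nt).
#' @param max_mismatch Maximum Hamming distance between prefix and index
#'   (default 0). Indices must be pairwise separated by more than
#'   `2 * max_mismatch` mismatches, otherwise assignment would be ambiguous
#'   and a configuration error is raised.
#' @return List with `samples` (named list of read data.frames, index
#'   trimmed), `unassigned` (read data.frame) and `stats` (data.frame of
#'   per-sample counts including `"unassigned"`).
#' @export
demultiplex <- function(reads, index_table, max_mismatch = 0) {
  idx <- toupper(index_table$index)
  if (any(nchar(idx) != 6L))
    stop_pq("all indices must be 6 nt", class = "protoquant_config_error")
  if (anyDuplicated(index_table$sample))
    stop_pq("duplicate sample names in index table",
            class = "protoquant_config_error")
  n_idx <- length(idx)
  if (n_idx > 1) {
    im <- do.call(rbind, strsplit(idx, ""))
    for (i in seq_len(n_idx - 1)) for (j in (i + 1):n_idx) {
      d <- sum(im[i, ] != im[j, ])
      if (d <= 2 * max_mismatch)
        stop_pq(sprintf("index collision under max_mismatch=%d: %s vs %s (distance %d)",
                        max_mismatch, idx[i], idx[j], d),
                class = "protoquant_config_error")
    }
  }
  prefix <- toupper(substr(reads$seq, 1, 6))
  assign_to <- rep(NA_integer_, nrow(reads))
  if (max_mismatch == 0) {
    assign_to <- match(prefix, idx)
  } else {
    pm <- do.call(rbind, strsplit(prefix, ""))
    for (k in seq_len(n_idx)) {
      d <- rowSums(pm != matrix(strsplit(idx[k], "")[[1]], nrow(reads), 6,
                                byrow = TRUE))
      assign_to[is.na(assign_to) & d <= max_mismatch] <- k
    }
  }
  samples <- stats::setNames(vector("list", n_idx), index_table$sample)
  for (k in seq_len(n_idx)) {
    sel <- which(assign_to == k)
    sub <- reads[sel, , drop = FALSE]
    sub$seq <- substr(sub$seq, 7, nchar(sub$seq))
    sub$qual <- substr(sub$qual, 7, nchar(sub$qual))
    rownames(sub) <- NULL
    samples[[k]] <- sub
  }
  unassigned <- reads[is.na(assign_to), , drop = FALSE]
  rownames(unassigned) <- NULL
  stats <- data.frame(
    sample = c(index_table$sample, "unassigned"),
    n_reads = c(vapply(samples, nrow, integer(1)), nrow(unassigned)),
    stringsAsFactors = FALSE
  )
  list(samples = samples, unassigned = unassigned, stats = stats)
}

#' Filter reads on mean Phred quality
#'
#' A read passes iff its mean Phred score is greater than or equal to `Q`
#' (inclusive).
#'
#' @param reads data.frame with columns `id`, `seq`, `qual` (Phred+33).
#' @param Q Minimum mean quality (default 30).
#' @return List with `pass` and `fail` read data.frames.
#' @export
quality_filter <- function(reads, Q = 30) {
  if (nrow(reads) && any(nchar(reads$seq) != nchar(reads$qual))) {
    bad <- which(nchar(reads$seq) != nchar(reads$qual))[1]
    stop_pq(sprintf("record %d ('%s'): malformed quality string", bad,
                    reads$id[bad]),
            class = "protoquant_format_error")
  }
  mq <- phred_mean(reads$qual)
  keep <- !is.na(mq) & mq >= Q
  list(pass = `rownames<-`(reads[keep, , drop = FALSE], NULL),
       fail = `rownames<-`(reads[!keep, , drop = FALSE], NULL))
}

#' Align reads to an amplicon
#'
#' Semi-global alignment of each read against the target amplicon (free end
#' gaps on the amplicon; match +2, mismatch -1, gap open -5, gap extend -1).
#' Both orientations are scored; the higher-scoring one wins and the
#' orientation is recorded. Reads scoring below `0.4 * 2 * read length`, or
#' shorter than 30 nt, are flagged unalignable and excluded from
#' quantification (but counted).
#'
#' @param reads data.frame with columns `id`, `seq` (and optionally `qual`).
#' @param target An [amplicon_target()].
#' @return An object of class `"amplicon_alignment"`: a list with
#'   \describe{
#'     \item{matrix}{character matrix reads x amplicon positions; `"."` not
#'       covered, `"-"` deleted, otherwise the read base (plus strand).}
#'     \item{insertions}{per-read list of data.frames (`pos`, `seq`): `seq`
#'       inserted after amplicon position `pos`.}
#'     \item{aligned}{logical, read usable for quantification.}
#'     \item{orientation}{`"+"`/`"-"` per read (`NA` if unalignable).}
#'     \item{score}{best alignment score.}
#'   }
#' @export
align_reads <- function(reads, target) {
  n <- nrow(reads)
  amp <- target$amplicon
  La <- nchar(amp)
  M <- matrix(".", nrow = n, ncol = La)
  ins <- vector("list", n)
  orientation <- rep(NA_character_, n)
  score_best <- rep(NA_real_, n)
  aligned <- rep(FALSE, n)
  if (n == 0L)
    return(structure(list(matrix = M, insertions = ins, aligned = aligned,
                          orientation = orientation, score = score_best,
                          ids = character(0), target = target$id),
                     class = "amplicon_alignment"))

  long_enough <- nchar(reads$seq) >= 30L
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                     baseOnly = FALSE)
  aln_one_way <- function(seqs) {
    Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(seqs), Biostrings::DNAString(amp),
      type = "global-local", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 1)
  }
  idx <- which(long_enough)
  if (length(idx)) {
    seqs <- toupper(reads$seq[idx])
    fwd <- aln_one_way(seqs)
    rev <- aln_one_way(revcomp(seqs))
    sf <- Biostrings::score(fwd)
    sr <- Biostrings::score(rev)
    use_rev <- sr > sf
    best <- pmax(sf, sr)
    floorv <- 0.4 * 2 * nchar(seqs)
    ok <- best >= floorv
    score_best[idx] <- best
    orientation[idx] <- ifelse(use_rev, "-", "+")
    orientation[idx][!ok] <- NA_character_
    aligned[idx] <- ok

    pat_f <- as.character(Biostrings::pattern(fwd))
    sub_f <- as.character(Biostrings::subject(fwd))
    st_f <- Biostrings::start(Biostrings::subject(fwd))
    pat_r <- as.character(Biostrings::pattern(rev))
    sub_r <- as.character(Biostrings::subject(rev))
    st_r <- Biostrings::start(Biostrings::subject(rev))

    for (k in seq_along(idx)) {
      if (!ok[k]) next
      i <- idx[k]
      if (use_rev[k]) {
        p <- strsplit(pat_r[k], "")[[1]]
        s <- strsplit(sub_r[k], "")[[1]]
        apos <- st_r[k]
      } else {
        p <- strsplit(pat_f[k], "")[[1]]
        s <- strsplit(sub_f[k], "")[[1]]
        apos <- st_f[k]
      }
      pending_ins <- character(0)
      row_ins <- list()
      for (j in seq_along(s)) {
        if (s[j] == "-") {
          pending_ins <- c(pending_ins, p[j])
        } else {
          if (length(pending_ins)) {
            row_ins[[length(row_ins) + 1L]] <-
              data.frame(pos = apos - 1L,
                         seq = paste(pending_ins, collapse = ""),
                         stringsAsFactors = FALSE)
            pending_ins <- character(0)
          }
          M[i, apos] <- p[j]  # read base or "-" for deletion
          apos <- apos + 1L
        }
      }
      if (length(pending_ins))
        row_ins[[length(row_ins) + 1L]] <-
          data.frame(pos = apos - 1L, seq = paste(pending_ins, collapse = ""),
                     stringsAsFactors = FALSE)
      if (length(row_ins)) ins[[i]] <- do.call(rbind, row_ins)
    }
  }
  structure(list(matrix = M, insertions = ins, aligned = aligned,
                 orientation = orientation, score = score_best,
                 ids = reads$id, target = target$id),
            class = "amplicon_alignment")
}

#' @export
print.amplicon_alignment <- function(x, ...) {
  cat(sprintf("<amplicon_alignment> target %s: %d read(s), %d aligned, %d unalignable\n",
              x$target, length(x$aligned), sum(x$aligned), sum(!x$aligned)))
  invisible(x)
}
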