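# Amplicon read simulation with known allele composition.

#' Specify an allele mixture for read simulation
#'
#' Each haplotype is either the string `"reference"` or a list with
#' elements `subs` (data.frame with columns `pos`, `base`: substitutions in
#' amplicon coordinates) and/or `indel` (list with `type` `"del"`/`"ins"`,
#' `pos` (1-based amplicon position of the first deleted base, or the base
#' after which the insertion occurs), and `len` for deletions or `seq` for
#' insertions). At most one indel per haplotype.
#'
#' @param haplotypes List of haplotype descriptions.
#' @param fractions Numeric vector summing to 1 (tolerance 1e-9).
#' @param error_rate Per-base substitution error probability.
#' @param qual Either a single Phred score (constant quality) or
#'   `c(mean, sd)` for per-base Gaussian qualities (clipped to `[2, 41]`).
#' @param mode `"deterministic_counts"` (exactly `round(fraction * n)` reads
#'   per haplotype) or `"multinomial"`.
#' @return An object of class `"allele_spec"`.
#' @export
allele_spec <- function(haplotypes, fractions, error_rate = 0,
                        qual = 40, mode = c("deterministic_counts", "multinomial")) {
  mode <- match.arg(mode)
  if (length(haplotypes) != length(fractions))
    stop_pq("haplotypes and fractions differ in length",
            class = "protoquant_input_error")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop_pq("fractions must sum to 1", class = "protoquant_input_error")
  if (any(fractions < 0 | fractions > 1))
    stop_pq("fractions must lie in [0, 1]", class = "protoquant_input_error")
  assert_number(error_rate, "error_rate", lower = 0, upper = 1)
  structure(list(haplotypes = haplotypes, fractions = fractions,
                 error_rate = error_rate, qual = qual, mode = mode),
            class = "allele_spec")
}

# Apply one haplotype's edits to an amplicon sequence.
apply_haplotype <- function(amplicon, hap) {
  if (identical(hap, "reference") || is.null(hap)) return(amplicon)
  chars <- strsplit(amplicon, "")[[1]]
  L <- length(chars)
  if (!is.null(hap$subs)) {
    if (any(hap$subs$pos < 1 | hap$subs$pos > L))
      stop_pq("substitution outside amplicon bounds",
              class = "protoquant_spec_error")
    chars[hap$subs$pos] <- toupper(hap$subs$base)
  }
  if (!is.null(hap$indel)) {
    ind <- hap$indel
    if (ind$type == "del") {
      if (ind$pos < 1 || ind$pos + ind$len - 1 > L)
        stop_pq("deletion extends past amplicon", class = "protoquant_spec_error")
      chars <- chars[-(ind$pos:(ind$pos + ind$len - 1))]
    } else if (ind$type == "ins") {
      if (ind$pos < 0 || ind$pos > L)
        stop_pq("insertion position outside amplicon",
                class = "protoquant_spec_error")
      chars <- append(chars, strsplit(toupper(ind$seq), "")[[1]], after = ind$pos)
    } else {
      stop_pq("indel type must be 'del' or 'ins'", class = "protoquant_spec_error")
    }
  }
  paste(chars, collapse = "")
}

#' Simulate amplicon reads
#'
#' Generates single, full-amplicon reads from an allele mixture, with
#' optional per-base sequencing errors, Gaussian or constant Phred+33
#' qualities, optional random reverse-complementation (to exercise strand
#' handling) and an optional 6-nt inline index prefix (for demultiplexing
#' tests). Read ids record the generating haplotype, so generation is its
#' own truth table.
#'
#' @param target An [amplicon_target()] (the amplicon sequence source).
#' @param spec An [allele_spec()].
#' @param n_reads Number of reads (>= 1).
#' @param seed RNG seed for this read set.
#' @param rc_prob Probability that a read is emitted reverse-complemented.
#' @param index Optional 6-nt index prefixed (with Q40 quality) to each read.
#' @param sample Sample name recorded in read ids.
#' @return data.frame with columns `id`, `seq`, `qual` and attribute
#'   `"hap_counts"` (reads generated per haplotype).
#' @export
simulate_reads <- function(target, spec, n_reads, seed = 1L, rc_prob = 0,
                           index = NULL, sample = "s1") {
  if (n_reads < 1)
    stop_pq("n_reads must be >= 1", class = "protoquant_input_error")
  if (!is.null(index) && nchar(index) != 6L)
    stop_pq("inline index must be 6 nt", class = "protoquant_input_error")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(substream_seed(seed, "reads", sample))

  k <- length(spec$haplotypes)
  if (spec$mode == "deterministic_counts") {
    counts <- round(spec$fractions * n_reads)
    # round() can miss the total by a few reads; settle the difference on
    # the most abundant haplotype
    counts[which.max(spec$fractions)] <-
      counts[which.max(spec$fractions)] + (n_reads - sum(counts))
  } else {
    counts <- as.vector(rmultinom(1, n_reads, spec$fractions))
  }

  hap_seqs <- vapply(spec$haplotypes, function(h)
    apply_haplotype(target$amplicon, h), character(1))

  hap_of <- rep(seq_len(k), counts)
  hap_of <- sample(hap_of)  # shuffle so file order is not informative
  seqs <- hap_seqs[hap_of]

  # per-base sequencing errors (uniform among the 3 non-reference bases)
  if (spec$error_rate > 0) {
    seqs <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      hit <- which(runif(length(ch)) < spec$error_rate)
      if (length(hit)) {
        for (j in hit) {
          alt <- setdiff(c("A", "C", "G", "T"), ch[j])
          ch[j] <- alt[sample.int(3, 1)]
        }
      }
      paste(ch, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }

  is_rc <- if (rc_prob > 0) runif(length(seqs)) < rc_prob else rep(FALSE, length(seqs))
  if (any(is_rc)) seqs[is_rc] <- revcomp(seqs[is_rc])

  quals <- vapply(nchar(seqs), function(L) {
    if (length(spec$qual) == 1L) {
      phred_encode(rep(spec$qual, L))
    } else {
      phred_encode(round(pmin(pmax(rnorm(L, spec$qual[1], spec$qual[2]), 2), 41)))
    }
  }, character(1))

  if (!is.null(index)) {
    seqs <- paste0(toupper(index), seqs)
    quals <- paste0(phred_encode(rep(40L, 6L)), quals)
  }

  reads <- data.frame(
    id = sprintf("%s_read%06d hap=%d rc=%d", sample, seq_along(seqs),
                 hap_of, as.integer(is_rc)),
    seq = seqs, qual = quals, stringsAsFactors = FALSE
  )
  attr(reads, "hap_counts") <- counts
  reads
}
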