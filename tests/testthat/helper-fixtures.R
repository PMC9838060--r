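# Shared fixtures: a deterministic amplicon/target pair and small plate
# configurations, all built in code.

# Fixed 240-bp amplicon with a 23-nt Cas12a protospacer on the plus strand
# (positions 101-123). Generated once from a fixed stream and frozen here
# so tests do not depend on sampling order.
fixture_amplicon <- function() {
  set.seed(424242)
  paste(sample(c("A", "C", "G", "T"), 240, replace = TRUE), collapse = "")
}

fixture_target <- function(strand = "+", ...) {
  amp <- fixture_amplicon()
  proto <- substr(amp, 101, 123)
  if (strand == "-") {
    proto <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(proto)))
  }
  amplicon_target("TS1", amp, proto, strand = strand, nuclease = "Cas12a", ...)
}

# Small wheat plate: one edited condition + controls.
fixture_config <- function(editing_rate = 0.4, n_cells = 60, n_rep = 2,
                           n_control = 2, seed = 7L, field_size = 200,
                           fields_per_well = 2, z_planes = 3, ...) {
  lay <- condition_layout(c(edited = editing_rate), n_rep = n_rep,
                          n_control = n_control, n_cells = n_cells)
  simulation_config(lay, fields_per_well = fields_per_well,
                    z_planes = z_planes,
                    field_size_px = c(field_size, field_size),
                    seed = seed, ...)
}

# Noise-free intensity model (additive read noise zeroed; foreground
# spreads kept).
noise_free_model <- function() {
  im <- default_intensity_model()
  for (ch in names(im)) im[[ch]]$noise_sd <- 0
  im
}

# ---- independent oracles -------------------------------------------------

# Brute-force semi-global aligner (full DP, no affine shortcuts beyond the
# same scoring: match +2, mismatch -1, gap of length k costs 5 + k). Free
# end gaps on the subject only. Returns the optimal score.
brute_force_semiglobal_score <- function(read, subject) {
  r <- strsplit(read, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(r); m <- length(s)
  NEG <- -1e9
  # affine DP: M best ending in match/mismatch, X gap in subject (insertion),
  # Y gap in read (deletion)
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, ] <- 0  # free leading gap on subject
  for (i in seq_len(n)) {
    X[i + 1, 1] <- -5 - i  # read overhang before subject start
    for (j in seq_len(m)) {
      sc <- if (r[i] == s[j]) 2 else -1
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + sc
      X[i + 1, j + 1] <- max(M[i, j + 1] - 6, X[i, j + 1] - 1, Y[i, j + 1] - 6)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - 6, X[i + 1, j] - 6, Y[i + 1, j] - 1)
    }
  }
  max(M[n + 1, ], X[n + 1, ], Y[n + 1, ])  # free trailing gap on subject
}

# Brute-force per-column substitution counts over gap-free reads, using
# the generator's own record of orientation (rc flag in the read id) --
# fully independent of the package aligner.
brute_force_column_counts <- function(reads, target) {
  win <- quantification_window(target)
  amp_pos <- proto_to_amplicon(target, win)
  seqs <- reads$seq
  rc <- grepl("rc=1", reads$id, fixed = TRUE)
  seqs[rc] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs[rc])))
  ref <- strsplit(target$amplicon, "")[[1]]
  minus <- target$strand == "-"
  out <- data.frame(position = win, pct_A = 0, pct_C = 0, pct_G = 0, pct_T = 0)
  n <- length(seqs)
  for (k in seq_along(win)) {
    col <- substr(seqs, amp_pos[k], amp_pos[k])
    for (b in c("A", "C", "G", "T")) {
      b_proto <- if (minus) c(A = "T", C = "G", G = "C", T = "A")[[b]] else b
      ref_proto <- if (minus) c(A = "T", C = "G", G = "C", T = "A")[[ref[amp_pos[k]]]]
      else ref[amp_pos[k]]
      if (b_proto == ref_proto) next
      out[[paste0("pct_", b_proto)]][k] <- 100 * sum(col == b) / n
    }
  }
  out
}
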