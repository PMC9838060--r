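# Amplicon quantification: windows, demultiplexing, alignment, tables.

test_that("the quantification window follows the center/size formula", {
  amp <- paste0(strrep("C", 50), "GTGTGTGTGTGTGTGTGTGA", strrep("C", 50))
  tg20 <- amplicon_target("w", amp, "GTGTGTGTGTGTGTGTGTGA", nuclease = "Cas9")
  expect_equal(quantification_window(tg20), 4:13)            # L=20, w=10, c=-12
  expect_equal(quantification_window(tg20, size = 1, center = -1), 19L)
  expect_equal(quantification_window(tg20, size = 40, center = -10), 1:20)
  expect_error(quantification_window(tg20, center = -25), "protospacer length",
               class = "protoquant_config_error")
})

test_that("targets validate protospacer occurrence and map coordinates", {
  amp <- fixture_amplicon()
  proto <- substr(amp, 101, 123)
  expect_error(amplicon_target("x", amp, "ACGT ACGT"), "exactly once",
               class = "protoquant_input_error")
  expect_error(amplicon_target("x", amp, proto, strand = "-"),
               "exactly once", class = "protoquant_input_error")
  tgp <- fixture_target("+")
  expect_equal(proto_to_amplicon(tgp, 1), 101L)
  expect_equal(proto_to_amplicon(tgp, 23), 123L)
  tgm <- fixture_target("-")
  expect_equal(proto_to_amplicon(tgm, 1), 123L)
  expect_equal(proto_to_amplicon(tgm, 23), 101L)
  # minus-strand substitution is complemented on the amplicon
  s <- proto_substitution(tgm, 1, "G")
  expect_equal(s$pos, 123L)
  expect_equal(s$base, "C")
})

test_that("demultiplexing assigns, trims and conserves reads", {
  idx <- data.frame(sample = c("s1", "s2", "s3"),
                    index = c("AAAAAA", "CCCCCC", "GGGGGG"))
  tg <- fixture_target()
  spec <- allele_spec(list("reference"), 1)
  pool <- do.call(rbind, lapply(seq_len(3), function(i)
    simulate_reads(tg, spec, 100, seed = i, index = idx$index[i],
                   sample = idx$sample[i])))
  pool <- pool[sample.int(nrow(pool)), ]  # shuffle
  dm <- demultiplex(pool, idx)
  expect_equal(dm$stats$n_reads, c(100, 100, 100, 0))
  expect_equal(nrow(dm$unassigned) +
                 sum(vapply(dm$samples, nrow, integer(1))), nrow(pool))
  # trimmed reads are the bare amplicon again
  expect_true(all(dm$samples$s1$seq == tg$amplicon))
  # reads generated for s2 all land in s2 (generation record = id prefix)
  expect_true(all(grepl("^s2_", dm$samples$s2$id)))
  # unmatched prefix stays unassigned at max_mismatch 0
  alien <- data.frame(id = "a", seq = paste0("TTTTTT", tg$amplicon),
                      qual = strrep("I", nchar(tg$amplicon) + 6))
  dm2 <- demultiplex(alien, idx)
  expect_equal(nrow(dm2$unassigned), 1)
  # collision detection under mismatch tolerance
  expect_error(demultiplex(alien, data.frame(sample = c("a", "b"),
                                             index = c("AAAAAA", "AAAAAT")),
                           max_mismatch = 1),
               "collision", class = "protoquant_config_error")
})

test_that("quality filter uses an inclusive mean-Phred rule", {
  reads <- data.frame(
    id = c("hi", "lo", "edge"),
    seq = rep(strrep("A", 40), 3),
    qual = c(strrep(rawToChar(as.raw(40 + 33)), 40),   # Q40
             strrep(rawToChar(as.raw(20 + 33)), 40),   # Q20
             paste0(strrep(rawToChar(as.raw(20 + 33)), 20),
                    strrep(rawToChar(as.raw(40 + 33)), 20))))  # mean 30
  qf <- quality_filter(reads, Q = 30)
  expect_equal(qf$pass$id, c("hi", "edge"))
  expect_equal(qf$fail$id, "lo")
  expect_equal(nrow(qf$pass) + nrow(qf$fail), 3)
})

test_that("alignment recovers offsets, strand and indels", {
  tg <- fixture_target()
  amp <- tg$amplicon
  # exact substring -> gap-free at the correct offset
  reads <- data.frame(id = "sub", seq = substr(amp, 41, 140),
                      qual = strrep("I", 100))
  aln <- align_reads(reads, tg)
  expect_true(aln$aligned[1])
  expect_equal(aln$orientation[1], "+")
  row <- aln$matrix[1, ]
  expect_equal(paste(row[41:140], collapse = ""), substr(amp, 41, 140))
  expect_true(all(row[c(1:40, 141:240)] == "."))
  # reverse complement -> same coordinates, orientation flagged
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(amp, 41, 140))))
  aln2 <- align_reads(data.frame(id = "rc", seq = rc, qual = strrep("I", 100)),
                      tg)
  expect_equal(aln2$orientation[1], "-")
  expect_equal(aln2$matrix[1, 41:140], aln$matrix[1, 41:140])
  # single deletion is recovered as exactly one gap run
  del_read <- paste0(substr(amp, 31, 109), substr(amp, 113, 210))
  aln3 <- align_reads(data.frame(id = "del", seq = del_read,
                                 qual = strrep("I", nchar(del_read))), tg)
  gaps <- rle(aln3$matrix[1, ] == "-")
  expect_equal(sum(gaps$values), 1)
  expect_equal(gaps$lengths[gaps$values], 3)
  # too-short and unalignable reads are flagged, not dropped silently
  junk <- data.frame(id = c("short", "junk"),
                     seq = c("ACGTACGT", strrep("AC", 60)),
                     qual = c(strrep("I", 8), strrep("I", 120)))
  aln4 <- align_reads(junk, tg)
  expect_equal(aln4$aligned, c(FALSE, FALSE))
})

test_that("alignment scores match a brute-force dynamic program", {
  tg <- fixture_target()
  amp <- tg$amplicon
  cases <- list(
    substr(amp, 31, 130),                                     # exact
    paste0(substr(amp, 31, 80), substr(amp, 84, 130)),        # deletion
    paste0(substr(amp, 31, 80), "TTAA", substr(amp, 81, 130)),# insertion
    sub("A", "G", substr(amp, 31, 130))                       # mismatch
  )
  reads <- data.frame(id = paste0("c", seq_along(cases)),
                      seq = unlist(cases),
                      qual = vapply(cases, function(s) strrep("I", nchar(s)), ""))
  aln <- align_reads(reads, tg)
  for (i in seq_along(cases)) {
    expect_equal(aln$score[i], brute_force_semiglobal_score(cases[[i]], amp),
                 info = paste("case", i))
  }
})

test_that("substitution quantification equals the brute-force column count", {
  tg <- fixture_target()
  sub10 <- proto_substitution(tg, 10, "G")
  sub12 <- proto_substitution(tg, 12, "G")
  spec <- allele_spec(list(list(subs = sub10),
                           list(subs = rbind(sub10, sub12)),
                           "reference"),
                      c(0.25, 0.15, 0.6))
  reads <- simulate_reads(tg, spec, 400, seed = 8, rc_prob = 0.5)
  qf <- quality_filter(reads, 30)
  aln <- align_reads(qf$pass, tg)
  got <- quantify_substitutions(aln, tg)
  oracle <- brute_force_column_counts(reads, tg)
  for (b in c("pct_A", "pct_C", "pct_G", "pct_T")) {
    expect_equal(got[[b]], oracle[[b]], info = b)
  }
  expect_equal(got$pct_G[got$position == 10], 40)  # 25 + 15
  expect_equal(got$pct_G[got$position == 12], 15)
})

test_that("the same arithmetic holds for a minus-strand protospacer", {
  tg <- fixture_target("-")
  sub7 <- proto_substitution(tg, 7, "G")
  spec <- allele_spec(list(list(subs = sub7), "reference"), c(0.3, 0.7))
  reads <- simulate_reads(tg, spec, 300, seed = 12, rc_prob = 0.5)
  qf <- quality_filter(reads, 30)
  got <- quantify_substitutions(align_reads(qf$pass, tg), tg)
  oracle <- brute_force_column_counts(reads, tg)
  expect_equal(got$pct_G[got$position == 7], 30)
  for (b in c("pct_A", "pct_C", "pct_G", "pct_T"))
    expect_equal(got[[b]], oracle[[b]], info = b)
})

test_that("appending an edited read never lowers its conversion percent", {
  tg <- fixture_target()
  sub10 <- proto_substitution(tg, 10, "G")
  spec <- allele_spec(list(list(subs = sub10), "reference"), c(0.2, 0.8))
  reads <- simulate_reads(tg, spec, 60, seed = 14)
  edited_seq <- protoquant:::apply_haplotype(tg$amplicon, list(subs = sub10))
  extra <- data.frame(id = "extra rc=0", seq = edited_seq,
                      qual = strrep("I", nchar(edited_seq)))
  p_before <- quantify_substitutions(align_reads(reads, tg), tg)
  p_after <- quantify_substitutions(align_reads(rbind(reads, extra), tg), tg)
  expect_gte(p_after$pct_G[p_after$position == 10],
             p_before$pct_G[p_before$position == 10])
})

test_that("indels count only when they overlap the indel window", {
  tg <- fixture_target()
  iw <- protoquant:::ind_window_amp(tg)
  inside <- list(indel = list(type = "del", pos = iw[3], len = 4))
  outside <- list(indel = list(type = "del", pos = 20, len = 4))  # far 5'
  spec_in <- allele_spec(list(inside, "reference"), c(0.2, 0.8))
  spec_out <- allele_spec(list(outside, "reference"), c(0.2, 0.8))
  r_in <- simulate_reads(tg, spec_in, 500, seed = 15, rc_prob = 0.5)
  r_out <- simulate_reads(tg, spec_out, 500, seed = 16, rc_prob = 0.5)
  et_in <- quantify_amplicon(r_in, tg)
  et_out <- quantify_amplicon(r_out, tg)
  expect_equal(et_in$indel_pct, 20)
  expect_equal(as.integer(names(et_in$indels$del_lengths)), 4L)
  expect_equal(et_out$indel_pct, 0)
  # insertion adjacent to the window also counts
  ins <- list(indel = list(type = "ins", pos = iw[1] - 1, seq = "GG"))
  r_ins <- simulate_reads(tg, allele_spec(list(ins, "reference"), c(0.1, 0.9)),
                          200, seed = 17)
  expect_equal(quantify_amplicon(r_ins, tg)$indel_pct, 10)
})

test_that("allele tables match a dictionary count of window substrings", {
  tg <- fixture_target()
  sub10 <- proto_substitution(tg, 10, "G")
  spec <- allele_spec(list(list(subs = sub10), "reference"), c(0.4, 0.6))
  reads <- simulate_reads(tg, spec, 500, seed = 18, rc_prob = 0.5)
  at <- allele_table(align_reads(reads, tg), tg)
  expect_equal(at$count, c(300, 200))
  expect_equal(at$pct, c(60, 40))
  expect_equal(at$annotation[1], "reference")
  expect_match(at$annotation[2], "^p10:")
  expect_equal(sum(at$pct), 100)
  # dictionary oracle on the generator's own sequences
  win_amp <- sort(proto_to_amplicon(tg, quantification_window(tg)))
  seqs <- reads$seq
  rc <- grepl("rc=1", reads$id, fixed = TRUE)
  seqs[rc] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs[rc])))
  dict <- table(substr(seqs, min(win_amp), max(win_amp)))
  expect_equal(sort(as.integer(dict)), sort(at$count))
})

test_that("single-haplotype read sets give one allele row at 100%", {
  tg <- fixture_target()
  reads <- simulate_reads(tg, allele_spec(list("reference"), 1), 50, seed = 19)
  at <- allele_table(align_reads(reads, tg), tg)
  expect_equal(nrow(at), 1)
  expect_equal(at$pct, 100)
})

test_that("zygosity thresholds follow the 25/70 rule inclusively", {
  expect_equal(call_zygosity(c(0, 10, 24.9)), rep("WT", 3))
  expect_equal(call_zygosity(c(25, 50, 70)), rep("HZ", 3))
  expect_equal(call_zygosity(c(70.1, 80, 100)), rep("HM", 3))
  expect_error(call_zygosity(120), "0, 100", class = "protoquant_input_error")
})

test_that("spacer mismatches are labeled seed or distal by nuclease geometry", {
  sp <- "GTGTGCATGCATGCATGCATGCA"
  expect_equal(nrow(annotate_spacer_mismatches(sp, sp)), 0)
  loc <- sp
  substr(loc, 3, 3) <- "A"
  ann <- annotate_spacer_mismatches(sp, loc, "Cas12a")
  expect_equal(ann$position, 3)
  expect_equal(ann$region, "seed")
  substr(loc, 20, 20) <- "C"
  ann2 <- annotate_spacer_mismatches(sp, loc, "Cas12a")
  expect_equal(ann2$region, c("seed", "distal"))
  # Cas9: PAM is 3', seed is the protospacer 3' end
  ann3 <- annotate_spacer_mismatches(sp, loc, "Cas9")
  expect_equal(ann3$region, c("distal", "seed"))
  expect_error(annotate_spacer_mismatches("ACGT", "ACGTA"), "equal length",
               class = "protoquant_input_error")
})

test_that("read bookkeeping is conserved through the full quantifier", {
  tg <- fixture_target()
  sub10 <- proto_substitution(tg, 10, "G")
  del <- list(indel = list(type = "del",
                           pos = protoquant:::ind_window_amp(tg)[4], len = 2))
  spec <- allele_spec(list(list(subs = sub10), del, "reference"),
                      c(0.3, 0.1, 0.6), qual = c(33, 4))
  reads <- simulate_reads(tg, spec, 300, seed = 20, rc_prob = 0.5)
  et <- quantify_amplicon(reads, tg)
  expect_equal(et$n_pass + et$n_fail, et$n_input)
  cc <- et$class_counts
  expect_equal(sum(cc) + et$n_unalignable, et$n_pass)
  n_quant <- sum(cc[c("indel", "substituted", "unmodified")])
  pct_sum <- 100 * cc[["indel"]] / n_quant +
    100 * cc[["substituted"]] / n_quant +
    100 * cc[["unmodified"]] / n_quant
  expect_equal(pct_sum, 100, tolerance = 1e-9)
})
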