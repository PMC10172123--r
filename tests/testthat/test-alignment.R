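# Alignment hygiene: divergence ratio, filtering rules, SNP selection,
# alt-read removal and marker-based re-ranking.

rec_row <- function(qname = "r1", flag = 0L, rname = "c1", pos = 1L,
                    mapq = 60L, cigar = "100=", seq = "*", qual = "*",
                    AS = NA_real_) {
  data.frame(qname = qname, flag = flag, rname = rname, pos = pos,
             mapq = mapq, cigar = cigar, seq = seq, qual = qual, AS = AS,
             stringsAsFactors = FALSE)
}

test_that("gap-compressed mismatch ratio counts each indel run once", {
  expect_equal(gap_compressed_mismatch_ratio("100="), 0)
  # 98 matches, 1 mismatch, one 5-base deletion: 2 events / 100 columns
  expect_equal(gap_compressed_mismatch_ratio("49=1X49=5D"), 2 / 100)
  # splitting a gap run into two separate runs adds an event
  one_run <- gap_compressed_mismatch_ratio("50=6D50=")
  two_runs <- gap_compressed_mismatch_ratio("50=3D10=3D40=")
  expect_equal(one_run, 1 / 101)
  expect_gt(two_runs, one_run)
  # insertions count the same way as deletions
  expect_equal(gap_compressed_mismatch_ratio("50=4I50="),
               gap_compressed_mismatch_ratio("50=4D50="))
  # plain M is unusable: match and mismatch are indistinguishable
  expect_error(gap_compressed_mismatch_ratio("100M"), "--eqx")
})

test_that("alignment filtering applies the length, divergence and chimera rules", {
  recs <- rbind(
    rec_row("short", cigar = "1999="),                       # < 2 kb: drop
    rec_row("exact", cigar = "2000="),                       # = 2 kb: keep
    rec_row("diverged", cigar = paste0("4950=50X")),         # 1%: keep
    rec_row("toodiverged", cigar = paste0("4949=51X")),      # > 1%: drop
    rec_row("mapq0", flag = 0L, mapq = 0L, cigar = "3000="), # MAPQ 0: keep
    rec_row("chim", cigar = "3000="),
    rec_row("chim", flag = 2048L, cigar = "2500="))          # chimeric read
  out <- filter_alignments(recs)
  expect_setequal(out$qname, c("exact", "diverged", "mapq0"))
  # exact boundary: ratio 50/5000 = 0.01 is retained, 51/5000 is not
  expect_equal(gap_compressed_mismatch_ratio("4950=50X"), 0.01)
  expect_gt(gap_compressed_mismatch_ratio("4949=51X"), 0.01)
})

test_that("SNP selection honours the PASS/biallelic/VAF/GQ rules", {
  snps <- data.frame(contig = "c1", pos = c(9, 19, 29, 39, 49),
                     ref = c("A", "C", "G", "T", "A"),
                     alt = c("T", "G", "A", "C", "G"),
                     vaf = c(0.29, 0.30, 0.80, 0.50, 0.50),
                     gq = c(99L, 10L, 9L, 50L, 50L),
                     filter = c("PASS", "PASS", "PASS", "LowQual", "PASS"))
  f <- tempfile(fileext = ".vcf")
  write_snps_vcf(snps, f, c(c1 = 1000))
  out <- select_snps(f)
  # kept: VAF .30 & GQ 10 (boundary inclusive), and the clean PASS record
  expect_equal(out$pos, c(19, 49))

  # multiallelic records are excluded
  lines <- readLines(f)
  lines[length(lines) + 1] <- "c1\t61\t.\tA\tC,G\t30\tPASS\t.\tGT:VAF:GQ\t0/1:0.5:50"
  writeLines(lines, f)
  out2 <- select_snps(f)
  expect_equal(out2$pos, c(19, 49))
})

test_that("alignments carrying alternative alleles are removed, deletions spare", {
  snps <- data.frame(contig = "c1", pos = 4, ref = "A", alt = "T",
                     stringsAsFactors = FALSE)
  ref_match <- rec_row("refread", pos = 1, cigar = "10=",
                       seq = "CCCCACCCCC")           # base A at 0-based 4
  alt_carry <- rec_row("altread", pos = 1, cigar = "4=1X5=",
                       seq = "CCCCTCCCCC")           # base T at the SNP
  del_span <- rec_row("delread", pos = 1, cigar = "4=2D4=",
                      seq = "CCCCCCCC")              # deletion over the SNP
  out <- filter_alt_reads(rbind(ref_match, alt_carry, del_span), snps)
  expect_equal(out$removed$qname, "altread")
  expect_setequal(out$retained$qname, c("refread", "delread"))
  # SNPs on contigs with no alignments warn and are ignored
  expect_warning(
    filter_alt_reads(ref_match, data.frame(contig = "c9", pos = 1,
                                           ref = "A", alt = "T")),
    "no alignments")
})

test_that("marker scores follow the stated quality-sum rule", {
  # candidate A mismatches two markers of quality 30; candidate B
  # mismatches one marker of quality 20: scores -60 vs -20, B wins
  qual <- rawToChar(as.raw(c(30, 30, 20, 25, 25) + 33L))
  recs <- rbind(
    rec_row("r", flag = 0L, rname = "hapA", cigar = "2X3=",
            seq = "AAAAA", qual = qual, AS = 3),      # mismatches q30, q30
    rec_row("r", flag = 256L, rname = "hapB", cigar = "2=1X2=",
            seq = "AAAAA", qual = qual, AS = 4))      # mismatches q20
  out <- secphase_rerank(recs)
  expect_equal(out$markers[["r"]], 1:3)
  expect_equal(nrow(out$records), 1L)
  expect_equal(out$records$rname, "hapB")
  expect_true(asmflag:::sam_is_primary(out$records$flag))
  expect_equal(nrow(out$swapped), 1L)

  # single candidate: unchanged, no markers
  solo <- rec_row("s", cigar = "5=", seq = "AAAAA", qual = qual)
  out2 <- secphase_rerank(solo)
  expect_identical(out2$records$rname, solo$rname)
  expect_length(out2$markers, 0L)
})

test_that("positions mismatched in all candidates are not markers", {
  qual <- rawToChar(as.raw(rep(30, 5) + 33L))
  recs <- rbind(
    rec_row("r", flag = 0L, rname = "hapA", cigar = "1X4=",
            seq = "AAAAA", qual = qual, AS = 4),
    rec_row("r", flag = 256L, rname = "hapB", cigar = "1X4=",
            seq = "AAAAA", qual = qual, AS = 4))
  out <- secphase_rerank(recs)
  # the shared mismatch is no marker; with no markers nothing changes
  expect_length(out$markers, 0L)
  expect_equal(nrow(out$records), 2L)
  expect_equal(out$records$rname[asmflag:::sam_is_primary(out$records$flag)],
               "hapA")
})

test_that("markers and scores agree with a per-column brute-force oracle", {
  sim <- simulate_read_alignments(n_reads = 25, hap_length = 1200,
                                  n_markers = 8, read_length = 180,
                                  error_rate = 0.01, seed = 13)
  out <- secphase_rerank(sim$records, gate = 0)   # consider all secondaries
  for (qn in unique(sim$records$qname)) {
    recs <- sim$records[sim$records$qname == qn, ]
    oracle <- brute_markers(recs$seq[1], recs$qual[1], recs$pos, sim$haps)
    if (length(oracle$markers)) {
      expect_equal(out$markers[[qn]], oracle$markers)
      # the chosen primary maximises the oracle score (primary on ties)
      kept <- out$records[out$records$qname == qn, ]
      pri <- kept$rname[asmflag:::sam_is_primary(kept$flag)]
      best <- which(oracle$scores == max(oracle$scores))
      orig_pri <- which(asmflag:::sam_is_primary(recs$flag))
      pick <- if (orig_pri %in% best) orig_pri else best[1]
      expect_equal(pri, recs$rname[pick])
    } else {
      expect_null(out$markers[[qn]])
    }
  }
})

test_that("reranking recovers the source haplotype and is idempotent", {
  sim <- simulate_read_alignments(n_reads = 80, hap_length = 4000,
                                  n_markers = 24, read_length = 900,
                                  error_rate = 0.002, swap_fraction = 0.5,
                                  seed = 101)
  out <- secphase_rerank(sim$records)
  pri <- out$records[asmflag:::sam_is_primary(out$records$flag), ]
  expect_equal(nrow(pri), 80L)                   # exactly one primary each
  # where markers exist the decision points home to the source haplotype
  with_markers <- pri$qname %in% names(out$markers)
  expect_gte(mean(pri$rname[with_markers] == "hap1"), 0.99)
  again <- secphase_rerank(out$records)
  expect_equal(again$records[order(again$records$qname, again$records$flag),
                             c("qname", "flag", "rname", "pos", "cigar")],
               out$records[order(out$records$qname, out$records$flag),
                           c("qname", "flag", "rname", "pos", "cigar")],
               ignore_attr = TRUE)
  expect_equal(nrow(again$swapped), 0L)
})

test_that("SAM text survives a read/write round trip", {
  sim <- simulate_read_alignments(n_reads = 6, hap_length = 600,
                                  read_length = 150, seed = 2)
  f <- tempfile(fileext = ".sam")
  write_sam(sim$records, f)
  back <- read_sam(f)
  expect_equal(back[, c("qname", "flag", "rname", "pos", "mapq", "cigar",
                        "seq", "qual", "AS")],
               sim$records[, c("qname", "flag", "rname", "pos", "mapq",
                               "cigar", "seq", "qual", "AS")],
               ignore_attr = TRUE)
  expect_equal(attr(back, "header"), attr(sim$records, "header"))
})
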