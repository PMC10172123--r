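# Marker-based re-ranking of near-tied primary/secondary alignments.
#
# In highly homozygous regions the aligner may pick the wrong haplotype as
# primary. For each read whose secondary alignment scores almost as high as
# its primary, the candidates are compared column-by-column in read
# coordinates (a pseudo-multiple alignment of the read against each
# captured assembly block). Read bases mismatched in at least one but not
# all candidates are "single nucleotide markers"; each candidate's
# consistency score is minus the sum of base qualities at the markers it
# mismatches. The best-scoring candidate becomes the primary; on a swap the
# other alignments of the read are dropped.

# Per-read mismatch profile in original-read orientation: TRUE where this
# candidate mismatches the assembly (X), inserts (I) or leaves the base
# unaligned (soft clip); FALSE at aligned matches (=).
mismatch_profile <- function(flag, cigar, read_len) {
  r <- cigar_runs(cigar)
  if (any(r$ops == "M"))
    stop("CIGAR contains 'M': --eqx-style =/X operators are required")
  prof <- rep(NA, read_len)
  qi <- 0
  for (k in seq_along(r$ops)) {
    op <- r$ops[k]; len <- r$lens[k]
    if (op %in% c("=", "X", "I", "S")) {
      prof[qi + seq_len(len)] <- op != "="
      qi <- qi + len
    }
  }
  if (qi != read_len) stop("CIGAR query length does not match read length")
  if (sam_is_reverse(flag)) rev(prof) else prof
}

# Column score fallback when no AS tag is present: aligned matches minus
# mismatches and gap openings.
column_score <- function(cigar) {
  vapply(cigar, function(cg) {
    r <- cigar_runs(cg)
    sum(r$lens[r$ops == "="]) - sum(r$lens[r$ops == "X"]) -
      sum(r$ops %in% c("I", "D"))
  }, 1, USE.NAMES = FALSE)
}

# Rerank the alignments of a single read. Returns list(records, swapped,
# markers).
rerank_one_read <- function(recs, gate) {
  pri <- which(sam_is_primary(recs$flag))
  sec <- which(sam_is_secondary(recs$flag))
  if (length(pri) != 1 || length(sec) == 0)
    return(list(records = recs, swapped = FALSE, markers = integer(0)))
  score <- recs$AS
  if (anyNA(score)) score <- column_score(recs$cigar)
  # gate: secondaries whose aligner score is almost as high as the primary
  gate_ok <- if (score[pri] > 0) score[sec] >= gate * score[pri]
             else rep(TRUE, length(sec))
  cand <- c(pri, sec[gate_ok])
  if (length(cand) < 2)
    return(list(records = recs, swapped = FALSE, markers = integer(0)))
  read_len <- unique(sam_read_len(recs$cigar[cand]))
  if (length(read_len) != 1)
    stop("candidate alignments of read '", recs$qname[1],
         "' disagree on read length")
  profs <- vapply(cand, function(i)
    mismatch_profile(recs$flag[i], recs$cigar[i], read_len),
    logical(read_len))
  if (read_len == 1) profs <- matrix(profs, nrow = 1)
  nmis <- rowSums(profs)
  markers <- which(nmis >= 1 & nmis < ncol(profs))
  if (length(markers) == 0)
    return(list(records = recs, swapped = FALSE, markers = integer(0)))
  # base qualities in original-read orientation, from the primary record
  qual <- qual_to_phred(recs$qual[pri])
  if (sam_is_reverse(recs$flag[pri])) qual <- rev(qual)
  cons <- -colSums(profs[markers, , drop = FALSE] * qual[markers])
  best <- which(cons == max(cons))
  if (1 %in% best)   # ties keep the original primary (candidate 1)
    return(list(records = recs, swapped = FALSE, markers = markers))
  winner <- cand[best[1]]
  rec <- recs[winner, , drop = FALSE]
  rec$flag <- bitwAnd(rec$flag, bitwNot(SAM_FLAG_SECONDARY))
  rec$mapq <- max(rec$mapq, recs$mapq[pri])
  list(records = rec, swapped = TRUE, markers = markers)
}

#' Re-rank near-tied primary/secondary alignments using markers
#'
#' For every read with at least one secondary alignment whose score is
#' within `gate` of the primary's, computes single-nucleotide markers (read
#' bases mismatched in some but not all candidate alignments) and a
#' consistency score per candidate: minus the sum of phred base qualities
#' at the markers that candidate mismatches. If the best candidate is a
#' secondary alignment it is promoted to primary and the read's other
#' alignments are removed; ties keep the original primary. Re-running on
#' the output is a no-op.
#'
#' Scores come from the `AS` tag when present, otherwise from a column
#' score (matches minus mismatches and gap openings).
#'
#' @param records Alignment record data.frame (see [read_sam()]), one or
#'   more reads.
#' @param gate A secondary is considered when its score is at least
#'   `gate` times the primary score (default 0.99).
#' @return List with `records` (re-ranked record table), `swapped`
#'   (data.frame of reads whose primary changed) and `markers` (named list
#'   of 1-based read offsets of markers per inspected read).
#' @export
secphase_rerank <- function(records, gate = 0.99) {
  hdr <- attr(records, "header")
  out <- list(); swapped <- list(); markers <- list()
  for (qn in unique(records$qname)) {
    recs <- records[records$qname == qn, , drop = FALSE]
    res <- rerank_one_read(recs, gate)
    out[[qn]] <- res$records
    if (length(res$markers)) markers[[qn]] <- res$markers
    if (res$swapped) {
      pri <- which(sam_is_primary(recs$flag))
      swapped[[qn]] <- data.frame(
        qname = qn, old_rname = recs$rname[pri], old_pos = recs$pos[pri],
        new_rname = res$records$rname[1], new_pos = res$records$pos[1],
        stringsAsFactors = FALSE)
    }
  }
  recs_out <- do.call(rbind, out)
  rownames(recs_out) <- NULL
  attr(recs_out, "header") <- hdr
  list(records = recs_out,
       swapped = if (length(swapped)) do.call(rbind, c(swapped,
                                                       make.row.names = FALSE))
                 else data.frame(qname = character()),
       markers = markers)
}
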