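# Alignment hygiene: divergence ratio, chimeric/short/divergent filtering,
# and removal of reads supporting alternative SNP alleles.

#' Gap-compressed mismatch ratio of an alignment
#'
#' Divergence measure in which each contiguous indel run counts as a single
#' event: (mismatched columns + gap openings) / (matched columns +
#' mismatched columns + gap openings). Requires extended `=`/`X` CIGAR
#' operators; a plain `M` cannot distinguish match from mismatch.
#'
#' @param cigar Character vector of extended CIGAR strings.
#' @return Numeric vector of ratios in `[0, 1]`.
#' @export
gap_compressed_mismatch_ratio <- function(cigar) {
  vapply(cigar, function(cg) {
    r <- cigar_runs(cg)
    if (any(r$ops == "M"))
      stop("CIGAR contains 'M': run the aligner with --eqx-style output ",
           "so matches (=) and mismatches (X) are distinguishable")
    matched <- sum(r$lens[r$ops == "="])
    mism <- sum(r$lens[r$ops == "X"])
    gaps <- sum(r$ops %in% c("I", "D"))   # one event per run
    denom <- matched + mism + gaps
    if (denom == 0) return(0)
    (mism + gaps) / denom
  }, 1, USE.NAMES = FALSE)
}

#' Filter unreliable alignments
#'
#' Applies the alignment hygiene rules: all alignments of chimeric reads
#' (reads carrying at least one supplementary alignment) are removed, as
#' are alignments whose reference span is shorter than `min_length` or
#' whose gap-compressed mismatch ratio exceeds `max_divergence`. Mapping
#' quality is deliberately *not* a criterion: reads over homozygous regions
#' of a diploid assembly legitimately map with MAPQ 0.
#'
#' @param records Alignment record data.frame (see [read_sam()]).
#' @param min_length Minimum reference span in bases (default 2,000);
#'   shorter alignments are dropped.
#' @param max_divergence Maximum gap-compressed mismatch ratio (default
#'   0.01); alignments strictly above it are dropped.
#' @return The retained records.
#' @export
filter_alignments <- function(records, min_length = 2000,
                              max_divergence = 0.01) {
  if (nrow(records) == 0) return(records)
  hdr <- attr(records, "header")
  chimeric <- unique(records$qname[sam_is_supplementary(records$flag)])
  keep <- !(records$qname %in% chimeric)
  keep <- keep & sam_ref_span(records$cigar) >= min_length
  ratio <- rep(NA_real_, nrow(records))
  ratio[keep] <- gap_compressed_mismatch_ratio(records$cigar[keep])
  keep <- keep & !is.na(ratio) & ratio <= max_divergence
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "header") <- hdr
  out
}

#' Select high-confidence biallelic SNPs from a VCF
#'
#' Keeps records that PASS, are biallelic single-nucleotide substitutions,
#' and are not excluded by `VAF < min_vaf || GQ < min_gq` (so a record with
#' VAF exactly `min_vaf` and GQ exactly `min_gq` is kept). Records missing
#' the VAF or GQ format fields are skipped with a warning.
#'
#' @param vcf_path Path to a VCF file with per-sample `VAF` and `GQ` format
#'   fields (e.g. from a long-read variant caller).
#' @param min_vaf,min_gq Inclusion thresholds (defaults 0.3 and 10).
#' @return data.frame with columns `contig`, `pos` (0-based), `ref`, `alt`.
#' @export
select_snps <- function(vcf_path, min_vaf = 0.3, min_gq = 10) {
  vcf <- VariantAnnotation::readVcf(vcf_path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  filt <- rr$FILTER == "PASS"
  ref <- as.character(rr$REF)
  altl <- rr$ALT
  biallelic <- S4Vectors::elementNROWS(altl) == 1
  alt <- rep(NA_character_, length(rr))
  alt[biallelic] <- as.character(unlist(altl[biallelic]))
  snv <- biallelic & nchar(ref) == 1 & !is.na(alt) & nchar(alt) == 1 &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  g <- VariantAnnotation::geno(vcf)
  get_field <- function(name) {
    if (!name %in% names(g)) return(rep(NA_real_, length(rr)))
    as.numeric(g[[name]][, 1])
  }
  vaf <- get_field("VAF")
  gq <- get_field("GQ")
  missing_fields <- snv & filt & (is.na(vaf) | is.na(gq))
  if (any(missing_fields))
    warning(sum(missing_fields),
            " record(s) missing VAF/GQ were skipped")
  keep <- filt & snv & !is.na(vaf) & !is.na(gq) &
    !(vaf < min_vaf | gq < min_gq)
  data.frame(contig = as.character(GenomicRanges::seqnames(rr))[keep],
             pos = GenomicRanges::start(rr)[keep] - 1,
             ref = ref[keep], alt = alt[keep], stringsAsFactors = FALSE)
}

# Read base aligned over each 0-based reference position, for one record.
# Positions with no aligned read base (deletion, outside the alignment)
# give NA.
aligned_bases_at <- function(rec, positions) {
  r <- cigar_runs(rec$cigar)
  out <- rep(NA_character_, length(positions))
  ref <- rec$pos - 1   # current 0-based reference cursor
  qi <- 0              # read bases consumed so far
  seq_chars <- strsplit(rec$seq, "")[[1]]
  for (k in seq_along(r$ops)) {
    op <- r$ops[k]; len <- r$lens[k]
    if (op %in% c("M", "=", "X")) {
      hit <- which(positions >= ref & positions < ref + len)
      if (length(hit))
        out[hit] <- seq_chars[qi + (positions[hit] - ref) + 1]
      ref <- ref + len
      qi <- qi + len
    } else if (op %in% c("D", "N")) {
      ref <- ref + len
    } else if (op %in% c("I", "S")) {
      qi <- qi + len
    }                                   # H, P consume nothing
  }
  out
}

#' Remove alignments carrying alternative SNP alleles
#'
#' An alignment whose aligned read base equals the alternative allele at
#' one or more SNPs is removed; all other alignments are retained. A
#' deletion spanning a SNP position leaves no base to compare, so it does
#' not count as alternative support. SNPs on contigs absent from the
#' records are ignored with a warning.
#'
#' @param records Alignment record data.frame (see [read_sam()]).
#' @param snps SNP set from [select_snps()].
#' @return List with elements `retained` and `removed` (record
#'   data.frames).
#' @export
filter_alt_reads <- function(records, snps) {
  hdr <- attr(records, "header")
  if (nrow(records) == 0 || nrow(snps) == 0) {
    return(list(retained = records, removed = records[0, , drop = FALSE]))
  }
  orphan <- setdiff(unique(snps$contig), unique(records$rname))
  if (length(orphan))
    warning("SNP contig(s) with no alignments ignored: ",
            paste(orphan, collapse = ", "))
  spans <- sam_ref_span(records$cigar)
  has_alt <- vapply(seq_len(nrow(records)), function(i) {
    s <- snps[snps$contig == records$rname[i], , drop = FALSE]
    if (nrow(s) == 0) return(FALSE)
    p0 <- records$pos[i] - 1
    s <- s[s$pos >= p0 & s$pos < p0 + spans[i], , drop = FALSE]
    if (nrow(s) == 0) return(FALSE)
    base <- aligned_bases_at(records[i, ], s$pos)
    any(!is.na(base) & base == s$alt)
  }, logical(1))
  retained <- records[!has_alt, , drop = FALSE]
  removed <- records[has_alt, , drop = FALSE]
  rownames(retained) <- rownames(removed) <- NULL
  attr(retained, "header") <- hdr
  attr(removed, "header") <- hdr
  list(retained = retained, removed = removed)
}
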