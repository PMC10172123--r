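# Minimal SAM-text reader/writer for the alignment-hygiene steps.
#
# Only the fields the filtering and re-ranking logic needs are kept. CIGAR
# strings must use the extended =/X match/mismatch operators (aligner run
# with --eqx); plain M is rejected where match/mismatch matters.

SAM_FLAG_REVERSE <- 16L
SAM_FLAG_SECONDARY <- 256L
SAM_FLAG_SUPPLEMENTARY <- 2048L

#' Read SAM text into an alignment record table
#'
#' Parses a SAM file (text dialect) into a data.frame of alignment records.
#' Header lines are kept as the `header` attribute so [write_sam()] can
#' round-trip the file. Tag `AS:i` (alignment score) is extracted when
#' present.
#'
#' @param path Path to a SAM text file.
#' @return data.frame with columns `qname`, `flag`, `rname`, `pos`
#'   (1-based), `mapq`, `cigar`, `seq`, `qual`, `AS` (NA when absent), plus
#'   attribute `header`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^@", lines)
  body <- lines[!hdr]
  if (length(body) == 0) {
    rec <- data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(), mapq = integer(),
                      cigar = character(), seq = character(),
                      qual = character(), AS = numeric())
    attr(rec, "header") <- lines[hdr]
    return(rec)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- vapply(parts, length, 1L)
  if (any(nf < 11))
    stop("malformed SAM record at line ", which(!hdr)[which(nf < 11)[1]])
  field <- function(i) vapply(parts, `[[`, "", i)
  as_tag <- vapply(parts, function(p) {
    hit <- grep("^AS:i:", p[-(1:11)], value = TRUE)
    if (length(hit)) as.numeric(sub("^AS:i:", "", hit[1])) else NA_real_
  }, 1)
  rec <- data.frame(qname = field(1), flag = as.integer(field(2)),
                    rname = field(3), pos = as.integer(field(4)),
                    mapq = as.integer(field(5)), cigar = field(6),
                    seq = field(10), qual = field(11), AS = as_tag,
                    stringsAsFactors = FALSE)
  attr(rec, "header") <- lines[hdr]
  rec
}

#' Write alignment records as SAM text
#'
#' @param records Record data.frame as returned by [read_sam()].
#' @param path Output path.
#' @param header Optional character vector of header lines; defaults to the
#'   `header` attribute of `records`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(records, path, header = attr(records, "header")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header) && length(header)) writeLines(header, con)
  if (nrow(records)) {
    as_field <- ifelse(is.na(records$AS), "",
                       sprintf("\tAS:i:%d", as.integer(records$AS)))
    writeLines(paste0(records$qname, "\t", records$flag, "\t",
                      records$rname, "\t", records$pos, "\t", records$mapq,
                      "\t", records$cigar, "\t*\t0\t0\t", records$seq, "\t",
                      records$qual, as_field), con)
  }
  invisible(path)
}

sam_is_secondary <- function(flag) bitwAnd(flag, SAM_FLAG_SECONDARY) != 0L
sam_is_supplementary <- function(flag) {
  bitwAnd(flag, SAM_FLAG_SUPPLEMENTARY) != 0L
}
sam_is_primary <- function(flag) {
  bitwAnd(flag, SAM_FLAG_SECONDARY + SAM_FLAG_SUPPLEMENTARY) == 0L
}
sam_is_reverse <- function(flag) bitwAnd(flag, SAM_FLAG_REVERSE) != 0L

# CIGAR decomposition (ops and run lengths) for one cigar string.
cigar_runs <- function(cigar) {
  list(ops = GenomicAlignments::explodeCigarOps(cigar)[[1]],
       lens = GenomicAlignments::explodeCigarOpLengths(cigar)[[1]])
}

# Reference-consuming span of each alignment, in bases.
sam_ref_span <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

# Full read length implied by each cigar (soft clips included).
sam_read_len <- function(cigar) {
  GenomicAlignments::cigarWidthAlongQuerySpace(cigar,
                                               after.soft.clipping = FALSE)
}

# Phred qualities (integers) from a SAM QUAL string.
qual_to_phred <- function(qual) {
  as.integer(charToRaw(qual)) - 33L
}
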