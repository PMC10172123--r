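# Run-length coverage tracks: the substrate of the whole pipeline.
#
# A cov_track stores, per contig, maximal runs of constant read depth as a
# data.frame with 0-based half-open [start, end) coordinates and an integer
# depth. Runs tile [0, contig_length) exactly.

new_cov_track <- function(contigs, lengths) {
  structure(list(contigs = contigs, lengths = lengths), class = "cov_track")
}

#' Construct a run-length coverage track
#'
#' @param contigs Named list (one element per contig) of data.frames with
#'   columns `start`, `end` (0-based half-open) and `depth` (non-negative
#'   integer). Blocks need not be maximal; adjacent equal-depth blocks are
#'   merged.
#' @param lengths Named numeric vector of contig lengths, covering every
#'   contig in `contigs`.
#' @return An object of class `cov_track`.
#' @export
coverage_track <- function(contigs, lengths) {
  stopifnot(is.list(contigs), !is.null(names(lengths)))
  if (!all(names(contigs) %in% names(lengths)))
    stop("every contig in `contigs` must appear in `lengths`")
  contigs <- lapply(contigs, function(b) {
    b <- as.data.frame(b)[, c("start", "end", "depth")]
    if (any(b$depth != floor(b$depth)))
      stop("depths must be integral (no floating depths)")
    if (any(b$depth > .Machine$integer.max))
      stop("depth exceeds 2^31 - 1")
    b$depth <- as.integer(b$depth)
    rle_pack(b[order(b$start), , drop = FALSE])
  })
  # contigs present in the index but without blocks are all-zero
  missing <- setdiff(names(lengths), names(contigs))
  for (ctg in missing) {
    contigs[[ctg]] <- data.frame(start = 0, end = unname(lengths[ctg]),
                                 depth = 0L)
  }
  x <- new_cov_track(contigs[names(lengths)], lengths)
  validate_cov_track(x)
  x
}

# Merge adjacent blocks with equal depth (maximal run-length form).
rle_pack <- function(blocks) {
  n <- nrow(blocks)
  if (n <= 1) return(blocks)
  new_run <- c(TRUE, blocks$depth[-1] != blocks$depth[-n] |
                     blocks$start[-1] != blocks$end[-n])
  first <- which(new_run)
  data.frame(start = blocks$start[first],
             end   = blocks$end[c(first[-1] - 1, n)],
             depth = blocks$depth[first],
             row.names = NULL)
}

validate_cov_track <- function(x) {
  for (ctg in names(x$contigs)) {
    b <- x$contigs[[ctg]]
    len <- x$lengths[[ctg]]
    if (nrow(b) == 0) stop("contig '", ctg, "' has no blocks")
    if (any(b$depth < 0)) stop("negative depth on contig '", ctg, "'")
    if (b$start[1] != 0 || b$end[nrow(b)] != len ||
        (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)])))
      stop("blocks of contig '", ctg, "' do not tile [0, ", len, ")")
    if (any(b$end <= b$start)) stop("empty block on contig '", ctg, "'")
  }
  invisible(x)
}

#' @export
print.cov_track <- function(x, ...) {
  nb <- sum(vapply(x$contigs, nrow, 1L))
  cat("cov_track:", length(x$contigs), "contig(s),",
      format(sum(x$lengths), big.mark = ","), "bases,",
      nb, "depth runs\n")
  mu <- track_mean_depth(x)
  cat("  mean depth:", round(mu, 2), "\n")
  invisible(x)
}

#' Total number of bases in a track
#' @param track A `cov_track`.
#' @return Number of bases (sum of contig lengths).
#' @export
track_total_bases <- function(track) sum(track$lengths)

#' Length-weighted mean depth of a track
#' @param track A `cov_track`.
#' @return The mean per-base depth.
#' @export
track_mean_depth <- function(track) {
  tot <- 0; bases <- 0
  for (b in track$contigs) {
    tot <- tot + sum((b$end - b$start) * b$depth)
    bases <- bases + sum(b$end - b$start)
  }
  tot / bases
}

# Clip a track to [start, end) of one contig; coordinates stay absolute.
track_slice <- function(track, contig, start, end) {
  b <- track$contigs[[contig]]
  if (is.null(b)) stop("unknown contig '", contig, "'")
  keep <- b$end > start & b$start < end
  b <- b[keep, , drop = FALSE]
  b$start <- pmax(b$start, start)
  b$end <- pmin(b$end, end)
  b
}

#' Read a FASTA index (.fai) file
#'
#' Only the first two columns (sequence name and length) are used.
#'
#' @param path Path to a `.fai` file.
#' @return Named numeric vector of contig lengths.
#' @export
read_fai <- function(path) {
  fai <- data.table::fread(path, header = FALSE, sep = "\t",
                           select = 1:2, data.table = FALSE)
  setNames(as.numeric(fai[[2]]), as.character(fai[[1]]))
}

#' Read a samtools-depth table into a coverage track
#'
#' Parses the three-column tab-separated dialect written by
#' `samtools depth -aa` (contig, 1-based position, depth). Positions absent
#' from the stream but present in the contig index get depth 0, so the
#' result also works for non-`-aa` tables.
#'
#' @param path Path to the depth table.
#' @param contig_lengths Named numeric vector of contig lengths (see
#'   [read_fai()]).
#' @return A `cov_track`.
#' @export
read_depth_table <- function(path, contig_lengths) {
  if (file.exists(path) && file.size(path) == 0) {
    return(coverage_track(list(), contig_lengths))
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("contig", "pos", "depth"),
                          colClasses = list(character = 1),
                          data.table = FALSE)
  if (nrow(dt) == 0) {
    return(coverage_track(list(), contig_lengths))
  }
  unknown <- setdiff(unique(dt$contig), names(contig_lengths))
  if (length(unknown))
    stop("depth table names contig(s) absent from the index: ",
         paste(unknown, collapse = ", "))
  if (any(dt$depth < 0)) stop("negative depth in depth table")
  contigs <- list()
  for (ctg in unique(dt$contig)) {
    rows <- which(dt$contig == ctg)
    pos0 <- dt$pos[rows] - 1          # to 0-based
    dep <- dt$depth[rows]
    len <- contig_lengths[[ctg]]
    bad <- which(diff(pos0) <= 0)
    if (length(bad))
      stop("non-monotone position on contig '", ctg, "' at line ",
           rows[bad[1] + 1])
    if (pos0[length(pos0)] >= len)
      stop("position beyond contig length on '", ctg, "'")
    # reported bases as unit blocks, plus zero-depth gap blocks
    gap_start <- c(0, pos0 + 1)
    gap_end <- c(pos0, len)
    gaps <- gap_end > gap_start
    blocks <- data.frame(
      start = c(pos0, gap_start[gaps]),
      end   = c(pos0 + 1, gap_end[gaps]),
      depth = c(dep, rep(0, sum(gaps))))
    blocks <- blocks[order(blocks$start), , drop = FALSE]
    contigs[[ctg]] <- blocks
  }
  coverage_track(contigs, contig_lengths)
}

#' Write / read the run-length coverage (.cov) dialect
#'
#' The dialect is one header line `>contig length` per contig followed by
#' one `start end depth` line per constant-depth run, with 1-based inclusive
#' start/end. [read_cov()] and [write_cov()] are lossless inverses.
#'
#' @param track A `cov_track`.
#' @param path Output (or input) file path.
#' @return `write_cov()` returns `path` invisibly; `read_cov()` returns a
#'   `cov_track`.
#' @export
write_cov <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(track$contigs)) {
    b <- track$contigs[[ctg]]
    writeLines(sprintf(">%s %.0f", ctg, track$lengths[[ctg]]), con)
    writeLines(sprintf("%.0f %.0f %.0f", b$start + 1, b$end, b$depth), con)
  }
  invisible(path)
}

#' @rdname write_cov
#' @export
read_cov <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!length(lines) || !hdr[1])
    stop("malformed .cov: expected '>contig length' header at line 1")
  contigs <- list(); lengths <- numeric()
  cur <- NULL; buf <- list()
  flush_contig <- function() {
    if (!is.null(cur)) {
      b <- do.call(rbind, buf)
      contigs[[cur]] <<- b
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "") next
    if (hdr[i]) {
      flush_contig()
      parts <- strsplit(sub("^>", "", ln), "[ \t]+")[[1]]
      if (length(parts) != 2 || is.na(suppressWarnings(as.numeric(parts[2]))))
        stop("malformed .cov header at line ", i)
      cur <- parts[1]
      lengths[cur] <- as.numeric(parts[2])
      buf <- list()
    } else {
      v <- suppressWarnings(as.numeric(strsplit(ln, "[ \t]+")[[1]]))
      if (length(v) != 3 || anyNA(v))
        stop("malformed .cov record at line ", i)
      buf[[length(buf) + 1]] <- data.frame(start = v[1] - 1, end = v[2],
                                           depth = v[3])
    }
  }
  flush_contig()
  coverage_track(contigs, lengths)
}

#' Build a coverage track by counting alignments per base
#'
#' Counts, for every base of every contig in `contig_lengths`, the number of
#' retained alignments overlapping it. Used for the auxiliary high-MAPQ
#' track that backs the duplication rescue step.
#'
#' @param alignments data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open reference span) and `mapq`.
#' @param contig_lengths Named numeric vector of contig lengths.
#' @param min_mapq Alignments with MAPQ below this are excluded when
#'   `min_mapq > 0`. Default 0 (keep all).
#' @return A `cov_track`.
#' @export
depth_from_alignments <- function(alignments, contig_lengths, min_mapq = 0) {
  a <- as.data.frame(alignments)
  if (min_mapq > 0) a <- a[a$mapq >= min_mapq, , drop = FALSE]
  unknown <- setdiff(unique(a$contig), names(contig_lengths))
  if (length(unknown)) stop("alignment on unknown contig: ", unknown[1])
  contigs <- list()
  for (ctg in names(contig_lengths)) {
    len <- contig_lengths[[ctg]]
    ai <- a[a$contig == ctg, , drop = FALSE]
    if (any(ai$start < 0 | ai$end > len))
      stop("alignment exceeds bounds of contig '", ctg, "'")
    cov <- IRanges::coverage(IRanges::IRanges(ai$start + 1, ai$end),
                             width = len)
    ends <- cumsum(S4Vectors::runLength(cov))
    contigs[[ctg]] <- data.frame(start = c(0, head(ends, -1)), end = ends,
                                 depth = S4Vectors::runValue(cov))
  }
  coverage_track(contigs, contig_lengths)
}

#' Write a track as a samtools-depth style table
#'
#' One line per base (contig, 1-based position, depth), as produced by
#' `samtools depth -aa`. Intended for small fixtures; run-length `.cov`
#' ([write_cov()]) is the scalable format.
#'
#' @param track A `cov_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(track$contigs)) {
    b <- track$contigs[[ctg]]
    pos <- sequence(b$end - b$start, from = b$start + 1)
    writeLines(paste(ctg, pos, rep(b$depth, b$end - b$start), sep = "\t"),
               con)
  }
  invisible(path)
}
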