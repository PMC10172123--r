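# BED import/export (via rtracklayer) for flag blocks and region sets.

FLAG_COLORS <- c(Err = "#E31A1C", Dup = "#FF7F00", Hap = "#33A02C",
                 Col = "#6A3D9A", Unk = "#808080")

#' Convert flag blocks to a GRanges
#'
#' @param blocks Block data.frame (`contig`, `start`, `end`, `label`) or a
#'   `flagger_result`.
#' @return A [GenomicRanges::GRanges] with a `name` metadata column holding
#'   the label.
#' @export
flags_to_granges <- function(blocks) {
  if (inherits(blocks, "flagger_result")) blocks <- blocks$blocks
  GenomicRanges::GRanges(blocks$contig,
                         IRanges::IRanges(blocks$start + 1, blocks$end),
                         name = as.character(blocks$label))
}

#' Write flag blocks as a 5-label BED file
#'
#' BED9 with the label in column 4 and an RGB colour per label in column 9
#' (red erroneous, orange duplicated, green haploid, purple collapsed, grey
#' unknown).
#'
#' @param result A `flagger_result` or block data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flag_bed <- function(result, path) {
  gr <- flags_to_granges(result)
  gr$score <- 0
  gr$itemRgb <- unname(FLAG_COLORS[gr$name])
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file as a region data.frame
#'
#' Coordinates come back 0-based half-open; BED column 4 (name), when
#' present, is returned both as `name` and as `class`/`label` convenience
#' aliases.
#'
#' @param path Path to a BED file.
#' @return data.frame with columns `contig`, `start`, `end` and, if
#'   present, `name`, `class`, `label`.
#' @export
read_region_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1,
                   end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
  if (!is.null(gr$name)) {
    df$name <- gr$name
    df$class <- gr$name
    df$label <- gr$name
  }
  df
}

#' Write the per-label summary as TSV
#'
#' @param result A `flagger_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_tsv <- function(result, path) {
  s <- result$summary
  df <- data.frame(label = FLAG_LEVELS,
                   bases = unname(s$label_bases[FLAG_LEVELS]),
                   fraction = unname(s$label_fraction[FLAG_LEVELS]))
  extra <- data.frame(label = c("unreliable_total", "unreliable_n50"),
                      bases = c(s$unreliable_bases, s$unreliable_n50),
                      fraction = c(s$unreliable_fraction, NA))
  utils::write.table(rbind(df, extra), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
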