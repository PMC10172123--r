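# Coverage histograms (depth -> number of bases) and windowing.

new_cov_hist <- function(depth, count) {
  o <- order(depth)
  structure(data.frame(depth = depth[o], count = count[o]),
            class = c("cov_hist", "data.frame"))
}

#' Construct a coverage histogram
#'
#' @param depth Integer vector of distinct depths.
#' @param count Number of bases at each depth.
#' @return A `cov_hist` (data.frame with columns `depth`, `count`).
#' @export
coverage_histogram <- function(depth, count) {
  stopifnot(length(depth) == length(count), !anyDuplicated(depth),
            all(count >= 0), all(depth >= 0))
  new_cov_hist(depth, count)
}

#' Total bases in a histogram
#' @param hist A `cov_hist`.
#' @return Sum of counts.
#' @export
hist_total_bases <- function(hist) sum(hist$count)

#' Count-weighted mean depth of a histogram
#' @param hist A `cov_hist`.
#' @return Mean depth.
#' @export
hist_mean_depth <- function(hist) sum(hist$depth * hist$count) / sum(hist$count)

#' Tabulate depth frequencies of a coverage track
#'
#' Computes, for each depth value, the number of bases at that depth,
#' optionally restricted to a region set.
#'
#' @param track A `cov_track`.
#' @param region Optional region restriction: a data.frame with columns
#'   `contig`, `start`, `end` (0-based half-open) or a
#'   [GenomicRanges::GRanges].
#' @return A `cov_hist`.
#' @export
track_to_histogram <- function(track, region = NULL) {
  if (is.null(region)) {
    depth <- unlist(lapply(track$contigs, function(b) b$depth),
                    use.names = FALSE)
    len <- unlist(lapply(track$contigs, function(b) b$end - b$start),
                  use.names = FALSE)
  } else {
    region <- region_df(region)
    unknown <- setdiff(unique(region$contig), names(track$lengths))
    if (length(unknown)) stop("region on unknown contig: ", unknown[1])
    depth <- numeric(); len <- numeric()
    for (i in seq_len(nrow(region))) {
      ctg <- region$contig[i]
      if (region$start[i] < 0 || region$end[i] > track$lengths[[ctg]])
        stop("region [", region$start[i], ",", region$end[i],
             ") off contig '", ctg, "'")
      b <- track_slice(track, ctg, region$start[i], region$end[i])
      depth <- c(depth, b$depth)
      len <- c(len, b$end - b$start)
    }
  }
  agg <- rowsum(len, depth)
  new_cov_hist(as.numeric(rownames(agg)), as.numeric(agg[, 1]))
}

# Accept a data.frame or GRanges region set; normalise to a data.frame with
# 0-based half-open coordinates.
region_df <- function(region) {
  if (methods::is(region, "GRanges")) {
    data.frame(contig = as.character(GenomicRanges::seqnames(region)),
               start = GenomicRanges::start(region) - 1,
               end = GenomicRanges::end(region),
               stringsAsFactors = FALSE)
  } else {
    as.data.frame(region)
  }
}

#' Split a track into fixed-size fitting windows
#'
#' Contigs longer than `min_contig` are tiled into consecutive windows of
#' `window_size` bases (the final window may be shorter). Contigs of at most
#' `min_contig` bases yield no windows; downstream they are labelled by the
#' whole-genome model instead.
#'
#' @param track A `cov_track`.
#' @param window_size Window length in bases (default 5 Mb).
#' @param min_contig Minimum contig length for window-specific fitting
#'   (default 5 Mb).
#' @return List of entries, each `list(window = list(contig, start, end,
#'   source), hist = cov_hist)`.
#' @export
split_track_by_window <- function(track, window_size = 5e6,
                                  min_contig = 5e6) {
  stopifnot(window_size > 0)
  out <- list()
  for (ctg in names(track$contigs)) {
    len <- track$lengths[[ctg]]
    if (len <= min_contig) next
    starts <- seq(0, len - 1, by = window_size)
    ends <- pmin(starts + window_size, len)
    for (i in seq_along(starts)) {
      reg <- data.frame(contig = ctg, start = starts[i], end = ends[i])
      out[[length(out) + 1]] <- list(
        window = list(contig = ctg, start = starts[i], end = ends[i],
                      source = "window"),
        hist = track_to_histogram(track, reg))
    }
  }
  out
}
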