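# Per-base flagging: windowed model fits, label tracks, HSat and high-MAPQ
# corrections, block merging and the final five-label result.

#' Label a coverage track with an assignment table
#'
#' Maps every base's depth to its component label and returns maximal runs
#' of identically labelled bases. The blocks tile each contig.
#'
#' @param track A `cov_track`.
#' @param table An `assignment_table` covering every depth in the track.
#' @param contigs Optional character vector restricting to some contigs.
#' @return data.frame with columns `contig`, `start`, `end`, `label`.
#' @export
flag_track <- function(track, table, contigs = NULL) {
  if (is.null(contigs)) contigs <- names(track$contigs)
  lookup <- as.character(table$label)
  out <- vector("list", length(contigs))
  for (i in seq_along(contigs)) {
    b <- track$contigs[[contigs[i]]]
    if (any(b$depth > length(lookup) - 1))
      stop("depth ", max(b$depth), " on contig '", contigs[i],
           "' outside assignment table (max ", length(lookup) - 1, ")")
    lab <- lookup[b$depth + 1]
    r <- rle(lab)
    ends <- b$end[cumsum(r$lengths)]
    starts <- c(b$start[1], head(ends, -1))
    out[[i]] <- data.frame(contig = contigs[i], start = starts, end = ends,
                           label = r$values, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$label <- flag_factor(res$label)
  rownames(res) <- NULL
  res
}

#' Windowed mixture fitting and labelling
#'
#' Fits one whole-genome model from the pooled histogram, then a distinct
#' model for each window of every contig longer than `min_contig`. Short
#' contigs, and windows whose fit is degenerate (fewer than
#' `fallback_min_bases` covered bases, or an EM failure), are labelled by
#' the whole-genome model.
#'
#' @param track A `cov_track`.
#' @param window_size,min_contig Window tiling parameters in bases (see
#'   [split_track_by_window()]).
#' @param opts [fit_options()] shared by all fits. A `NULL` `init_coverage`
#'   starts every fit at the genome-wide mean depth.
#' @param fallback_min_bases Windows with fewer covered (depth > 0) bases
#'   than this fall back to the whole-genome model.
#' @return List with `labels` (block data.frame as in [flag_track()]),
#'   `genome_model`, `genome_mean`, `window_fits` (per-window metadata and
#'   models), and `n_fallback`.
#' @export
run_windowed_flagging <- function(track, window_size = 5e6, min_contig = 5e6,
                                  opts = fit_options(),
                                  fallback_min_bases = 1e4) {
  genome_hist <- track_to_histogram(track)
  genome_mean <- hist_mean_depth(genome_hist)
  if (is.null(opts$init_coverage)) opts$init_coverage <- genome_mean
  genome_model <- fit_mixture(genome_hist, opts)
  max_depth <- max(genome_hist$depth)
  genome_table <- assign_components(genome_model, max_depth)

  windows <- split_track_by_window(track, window_size, min_contig)
  windowed_contigs <- unique(vapply(windows, function(w) w$window$contig, ""))
  labels <- list()
  window_fits <- list()
  n_fallback <- 0L

  for (w in windows) {
    hist_w <- w$hist
    informative <- sum(hist_w$count[hist_w$depth > 0])
    model_w <- NULL
    if (informative >= fallback_min_bases) {
      model_w <- tryCatch(fit_mixture(hist_w, opts),
                          asmflag_degenerate_fit = function(e) NULL)
    }
    slice <- track_slice(track, w$window$contig, w$window$start, w$window$end)
    if (is.null(model_w)) {
      n_fallback <- n_fallback + 1L
      tab <- genome_table
    } else {
      tab <- assign_components(model_w, max(max_depth, max(hist_w$depth)))
    }
    lab <- label_blocks(slice, tab, w$window$contig)
    labels[[length(labels) + 1]] <- lab
    window_fits[[length(window_fits) + 1]] <-
      list(window = w$window, model = model_w,
           fallback = is.null(model_w))
  }
  # short contigs: whole-genome model
  for (ctg in setdiff(names(track$contigs), windowed_contigs)) {
    labels[[length(labels) + 1]] <-
      label_blocks(track$contigs[[ctg]], genome_table, ctg)
  }
  if (n_fallback > 0)
    message(n_fallback,
            " window(s) fell back to the whole-genome model")
  lab <- do.call(rbind, labels)
  lab <- lab[order(lab$contig, lab$start), , drop = FALSE]
  rownames(lab) <- NULL
  lab <- collapse_adjacent(lab)
  list(labels = lab, genome_model = genome_model, genome_mean = genome_mean,
       genome_table = genome_table, window_fits = window_fits,
       n_fallback = n_fallback)
}

# Label a block slice (data.frame start/end/depth) with a table.
label_blocks <- function(blocks, table, contig) {
  lookup <- as.character(table$label)
  if (any(blocks$depth > length(lookup) - 1))
    stop("depth outside assignment table on contig '", contig, "'")
  lab <- lookup[blocks$depth + 1]
  r <- rle(lab)
  ends <- blocks$end[cumsum(r$lengths)]
  data.frame(contig = contig, start = c(blocks$start[1], head(ends, -1)),
             end = ends, label = r$values, stringsAsFactors = FALSE)
}

# Merge adjacent same-label blocks per contig (keeps tiling).
collapse_adjacent <- function(lab) {
  n <- nrow(lab)
  if (n <= 1) { lab$label <- flag_factor(lab$label); return(lab) }
  same <- c(FALSE, lab$contig[-1] == lab$contig[-n] &
                   as.character(lab$label[-1]) ==
                   as.character(lab$label[-n]) &
                   lab$start[-1] == lab$end[-n])
  first <- which(!same)
  out <- data.frame(contig = lab$contig[first], start = lab$start[first],
                    end = lab$end[c(first[-1] - 1, n)],
                    label = as.character(lab$label)[first],
                    stringsAsFactors = FALSE)
  out$label <- flag_factor(out$label)
  rownames(out) <- NULL
  out
}

#' Re-label satellite regions with bias-aware refits
#'
#' Human satellites HSat1/2/3 show systematic platform-specific coverage
#' biases (HiFi depth drops on HSat1 and rises on HSat2/3) that mislead the
#' genome-wide model. For each satellite class, the mixture is refitted on
#' the coverage histogram of that class's regions with the EM starting
#' coverage set to `multipliers[class]` times the genome-wide mean depth,
#' and the labels inside those regions are replaced by the refit's
#' assignment. Bases outside the regions are untouched.
#'
#' @param labels Label blocks (from [flag_track()] or
#'   [run_windowed_flagging()]), tiling each contig.
#' @param hsat_regions data.frame with columns `contig`, `start`, `end`
#'   (0-based half-open) and `class` in `HSat1`/`HSat2`/`HSat3`, or a
#'   GRanges whose `name` column holds the class.
#' @param track The `cov_track` the labels were derived from.
#' @param genome_mean Genome-wide mean depth (average sequencing coverage).
#' @param opts [fit_options()] for the refits.
#' @param multipliers Named starting-coverage multipliers per class.
#' @return Corrected label blocks.
#' @export
apply_hsat_correction <- function(labels, hsat_regions, track, genome_mean,
                                  opts = fit_options(),
                                  multipliers = c(HSat1 = 0.75, HSat2 = 1.25,
                                                  HSat3 = 1.25)) {
  regions <- region_df(hsat_regions)
  if (!is.null(regions$name) && is.null(regions$class))
    regions$class <- regions$name
  if (nrow(regions) == 0) return(labels)
  bad <- setdiff(unique(regions$class), names(multipliers))
  if (length(bad)) stop("unknown HSat class: ", paste(bad, collapse = ", "))
  for (cls in intersect(names(multipliers), unique(regions$class))) {
    regs <- regions[regions$class == cls, , drop = FALSE]
    hist_c <- track_to_histogram(track, regs)
    if (hist_total_bases(hist_c) == 0) next
    opts_c <- opts
    opts_c$init_coverage <- multipliers[[cls]] * genome_mean
    model_c <- tryCatch(fit_mixture(hist_c, opts_c),
                        asmflag_degenerate_fit = function(e) NULL)
    if (is.null(model_c)) {
      warning("degenerate fit for ", cls, "; labels left unchanged")
      next
    }
    tab <- assign_components(model_c, max(hist_c$depth))
    new_blocks <- do.call(rbind, lapply(seq_len(nrow(regs)), function(i) {
      sl <- track_slice(track, regs$contig[i], regs$start[i], regs$end[i])
      label_blocks(sl, tab, regs$contig[i])
    }))
    labels <- splice_labels(labels, new_blocks, regs)
  }
  labels
}

# Replace the labelling inside `regions` by `new_blocks`, keeping all other
# bases unchanged. Both inputs use 0-based half-open coordinates.
splice_labels <- function(labels, new_blocks, regions) {
  out <- list()
  for (ctg in unique(labels$contig)) {
    old <- labels[labels$contig == ctg, , drop = FALSE]
    regs <- regions[regions$contig == ctg, , drop = FALSE]
    if (nrow(regs) == 0) { out[[ctg]] <- old; next }
    reg_ir <- IRanges::reduce(IRanges::IRanges(regs$start + 1, regs$end))
    old_ir <- IRanges::IRanges(old$start + 1, old$end)
    keep <- as.data.frame(BiocGenerics::setdiff(old_ir, reg_ir))
    # re-attach labels to the kept fragments
    hit <- IRanges::findOverlaps(IRanges::IRanges(keep$start, keep$end),
                                 old_ir, select = "first")
    kept <- data.frame(contig = ctg, start = keep$start - 1, end = keep$end,
                       label = as.character(old$label)[hit],
                       stringsAsFactors = FALSE)
    nb <- new_blocks[new_blocks$contig == ctg, , drop = FALSE]
    nb$label <- as.character(nb$label)
    merged <- rbind(kept, nb[, c("contig", "start", "end", "label")])
    merged <- merged[order(merged$start), , drop = FALSE]
    out[[ctg]] <- merged
  }
  res <- do.call(rbind, out)
  res$label <- flag_factor(res$label)
  rownames(res) <- NULL
  collapse_adjacent(res)
}

#' Rescue duplicated flags contradicted by high-MAPQ alignments
#'
#' Reads map with low MAPQ wherever two near-identical copies exist, so a
#' genuine false duplication should have almost no alignments with
#' MAPQ > 20. Any maximal `Dup` block whose minimum high-quality depth
#' exceeds `min_support` is relabelled `Hap`; all other labels are left
#' untouched. Idempotent.
#'
#' @param labels Label blocks tiling each contig.
#' @param hq_track `cov_track` built from alignments with MAPQ above the
#'   high-quality cutoff (see [depth_from_alignments()]).
#' @param min_support A `Dup` block is rescued only when its minimum
#'   high-quality depth is strictly greater than this (default 5 reads).
#' @return Corrected label blocks.
#' @export
apply_mapq_correction <- function(labels, hq_track, min_support = 5) {
  dup <- which(labels$label == "Dup")
  if (length(dup) == 0) return(labels)
  missing <- setdiff(unique(labels$contig[dup]), names(hq_track$contigs))
  if (length(missing))
    stop("high-quality track lacks contig(s): ",
         paste(missing, collapse = ", "))
  relabel <- vapply(dup, function(i) {
    b <- track_slice(hq_track, labels$contig[i], labels$start[i],
                     labels$end[i])
    min(b$depth) > min_support
  }, logical(1))
  if (any(relabel)) {
    labels$label[dup[relabel]] <- "Hap"
    labels <- collapse_adjacent(labels)
  }
  labels
}

#' Merge nearby same-label blocks and resolve conflicts to Unknown
#'
#' For each label independently, blocks separated by a gap smaller than
#' `merge_dist` are merged, the gap being absorbed into that label. Any base
#' claimed by two or more labels after merging becomes `Unk` ("unknown"):
#' it could not be assigned to a single component. `Unk` itself never
#' absorbs gaps (it marks conflicts rather than spreading), which makes the
#' operation idempotent. Whenever the input labels tile a contig, the
#' output tiles it too.
#'
#' @param labels Label blocks tiling each contig.
#' @param contig_lengths Named numeric vector of contig lengths.
#' @param merge_dist Gap threshold in bases; gaps strictly smaller than this
#'   merge (default 1,000).
#' @return A `flagger_result`: list with `blocks` (five-label data.frame)
#'   and `summary` (per-label base counts and fractions, unreliable total
#'   and N50).
#' @export
merge_and_finalize <- function(labels, contig_lengths, merge_dist = 1000) {
  out <- list()
  for (ctg in unique(labels$contig)) {
    lab <- labels[labels$contig == ctg, , drop = FALSE]
    present <- unique(as.character(lab$label))
    merged <- lapply(present, function(lv) {
      sel <- lab$label == lv
      # Unk never absorbs gaps: it marks conflicts, it does not spread
      gw <- if (lv == "Unk") 1 else merge_dist
      IRanges::reduce(IRanges::IRanges(lab$start[sel] + 1, lab$end[sel]),
                      min.gapwidth = gw)
    })
    names(merged) <- present
    dj <- IRanges::disjoin(do.call(c, unname(merged)))
    claim <- vapply(merged, function(ir)
      IRanges::countOverlaps(dj, ir) > 0, logical(length(dj)))
    if (length(dj) == 1) claim <- matrix(claim, nrow = 1,
                                         dimnames = list(NULL, present))
    nclaim <- rowSums(claim)
    lv <- character(length(dj))
    lv[nclaim >= 2] <- "Unk"
    single <- which(nclaim == 1)
    lv[single] <- present[apply(claim[single, , drop = FALSE], 1, which)]
    out[[ctg]] <- data.frame(contig = ctg,
                             start = IRanges::start(dj) - 1,
                             end = IRanges::end(dj), label = lv,
                             stringsAsFactors = FALSE)
  }
  blocks <- do.call(rbind, out)
  blocks <- blocks[order(blocks$contig, blocks$start), , drop = FALSE]
  blocks$label <- flag_factor(blocks$label)
  rownames(blocks) <- NULL
  blocks <- collapse_adjacent(blocks)
  # tiling check: whenever the input tiled a contig, the output must too
  in_w <- rowsum(labels$end - labels$start, labels$contig)
  out_w <- rowsum(blocks$end - blocks$start, blocks$contig)
  for (ctg in rownames(out_w)) {
    if (in_w[ctg, 1] == contig_lengths[[ctg]] &&
        out_w[ctg, 1] != contig_lengths[[ctg]])
      stop("finalized blocks do not tile contig '", ctg, "'")
  }
  structure(list(blocks = blocks,
                 summary = flag_summary(blocks, contig_lengths),
                 contig_lengths = contig_lengths,
                 merge_dist = merge_dist),
            class = "flagger_result")
}

#' Summary statistics of a flagged assembly
#'
#' @param blocks Five-label block data.frame.
#' @param contig_lengths Named numeric vector of contig lengths.
#' @return List with `label_bases`, `label_fraction` (both named over the
#'   five labels), `unreliable_bases`, `unreliable_fraction` and
#'   `unreliable_n50` (unreliable = any non-`Hap` label).
#' @export
flag_summary <- function(blocks, contig_lengths) {
  total <- sum(contig_lengths)
  w <- blocks$end - blocks$start
  bases <- vapply(FLAG_LEVELS, function(lv) sum(w[blocks$label == lv]), 1)
  unreliable <- blocks$label != "Hap"
  list(label_bases = bases,
       label_fraction = bases / total,
       unreliable_bases = sum(w[unreliable]),
       unreliable_fraction = sum(w[unreliable]) / total,
       unreliable_n50 = n50(w[unreliable]))
}

#' @export
print.flagger_result <- function(x, ...) {
  s <- x$summary
  cat("flagger_result over", length(x$contig_lengths), "contig(s),",
      format(sum(x$contig_lengths), big.mark = ","), "bases\n")
  for (lv in FLAG_LEVELS)
    cat(sprintf("  %-3s %12s bases (%6.3f%%)\n", lv,
                format(s$label_bases[[lv]], big.mark = ","),
                100 * s$label_fraction[[lv]]))
  cat(sprintf("  unreliable: %s bases (%.3f%%), N50 %s\n",
              format(s$unreliable_bases, big.mark = ","),
              100 * s$unreliable_fraction,
              format(s$unreliable_n50, big.mark = ",")))
  invisible(x)
}
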