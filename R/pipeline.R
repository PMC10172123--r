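# End-to-end orchestration: windowed labelling -> satellite correction ->
# high-MAPQ correction -> merge/finalize. The order is fixed.

#' Flag every base of an assembly from its coverage track
#'
#' Runs the full evaluation: a whole-genome mixture fit plus one fit per
#' 5 Mb window of the long contigs, per-base component labelling,
#' optional satellite-bias and high-MAPQ corrections, then merging of
#' nearby same-label blocks with contested bases flagged unknown.
#'
#' @param track A `cov_track` of per-base read depth (from
#'   [read_depth_table()], [read_cov()] or [simulate_coverage()]).
#' @param hsat_regions Optional satellite annotation (data.frame or BED
#'   GRanges with class HSat1/2/3); see [apply_hsat_correction()].
#' @param hq_track Optional `cov_track` from MAPQ > 20 alignments; see
#'   [apply_mapq_correction()].
#' @param window_size,min_contig Window tiling (default 5 Mb each).
#' @param merge_dist Merge gap threshold in bases (default 1,000).
#' @param min_hq_support Minimum high-quality depth (exclusive) rescuing a
#'   duplicated flag (default 5).
#' @param opts [fit_options()] shared by all mixture fits.
#' @param hsat_multipliers Starting-coverage multipliers per satellite
#'   class.
#' @return A `flagger_result` with extra elements `genome_model`,
#'   `genome_mean`, `window_fits` and `n_fallback`.
#' @export
evaluate_assembly <- function(track, hsat_regions = NULL, hq_track = NULL,
                              window_size = 5e6, min_contig = 5e6,
                              merge_dist = 1000, min_hq_support = 5,
                              opts = fit_options(),
                              hsat_multipliers = c(HSat1 = 0.75,
                                                   HSat2 = 1.25,
                                                   HSat3 = 1.25)) {
  wf <- run_windowed_flagging(track, window_size, min_contig, opts)
  labels <- wf$labels
  if (!is.null(hsat_regions))
    labels <- apply_hsat_correction(labels, hsat_regions, track,
                                    wf$genome_mean, opts, hsat_multipliers)
  if (!is.null(hq_track))
    labels <- apply_mapq_correction(labels, hq_track, min_hq_support)
  result <- merge_and_finalize(labels, track$lengths, merge_dist)
  result$genome_model <- wf$genome_model
  result$genome_mean <- wf$genome_mean
  result$window_fits <- wf$window_fits
  result$n_fallback <- wf$n_fallback
  result
}
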