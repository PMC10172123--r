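# Shared fixture builders and brute-force oracles. The oracles work base by
# base (or column by column) on tiny inputs and stay independent of the
# run-length / vectorised code paths they check.

# Expand a track to per-base depth vectors (tiny fixtures only).
perbase_depths <- function(track) {
  lapply(track$contigs, function(b) rep(b$depth, b$end - b$start))
}

# Build a track from explicit per-base depth vectors.
track_from_perbase <- function(depths_by_contig) {
  contigs <- lapply(depths_by_contig, function(d) {
    r <- rle(d)
    ends <- cumsum(r$lengths)
    data.frame(start = c(0, head(ends, -1)), end = ends, depth = r$values)
  })
  coverage_track(contigs,
                 vapply(depths_by_contig, length, 1))
}

random_track <- function(lengths, max_depth = 50, seed = 1) {
  withr::with_seed(seed, {
    track_from_perbase(lapply(lengths, function(n)
      sample(0:max_depth, n, replace = TRUE)))
  })
}

# Hand-built mixture model object (bypasses fitting).
make_model <- function(hap_mean = 40, err_lambda = 1, hap_sd = 6,
                       dup_sd = 5, col_sds = c(col2 = 8, col3 = 10),
                       weights = c(err = 0.02, dup = 0.03, hap = 0.90,
                                   col2 = 0.04, col3 = 0.01)) {
  structure(list(err_lambda = err_lambda, hap_mean = hap_mean,
                 hap_sd = hap_sd, dup_sd = dup_sd, collapsed_sds = col_sds,
                 n_collapsed = length(col_sds),
                 weights = weights / sum(weights),
                 loglik = NA_real_, loglik_trace = numeric(0),
                 iterations = 0L, converged = TRUE,
                 init_coverage = hap_mean, total_bases = 0),
            class = "cov_mixture")
}

# Independent argmax labelling oracle: direct weighted densities with
# dpois/dnorm, collapsed sub-components pooled, ties broken
# Hap > Dup > Col > Err.
brute_label <- function(model, depth) {
  w <- model$weights
  ks <- 2:(model$n_collapsed + 1)
  col_score <- 0
  for (k in ks)
    col_score <- col_score + w[[paste0("col", k)]] *
      dnorm(depth, k * model$hap_mean, model$collapsed_sds[[paste0("col", k)]])
  scores <- c(Hap = w[["hap"]] * dnorm(depth, model$hap_mean, model$hap_sd),
              Dup = w[["dup"]] * dnorm(depth, model$hap_mean / 2,
                                       model$dup_sd),
              Col = unname(col_score),
              Err = w[["err"]] * dpois(depth, model$err_lambda))
  names(scores)[which.max(scores)]
}

# Column-by-column marker/score oracle from the raw sequences: for each
# candidate the aligned assembly base at every read offset is compared
# directly (fixtures have no indels, so alignment coordinates are shared).
brute_markers <- function(read_seq, qual_str, starts, haps) {
  read <- strsplit(read_seq, "")[[1]]
  qual <- as.integer(charToRaw(qual_str)) - 33L
  mism <- vapply(seq_along(haps), function(j) {
    ref <- strsplit(substr(haps[j], starts[j],
                           starts[j] + length(read) - 1), "")[[1]]
    read != ref
  }, logical(length(read)))
  nm <- rowSums(mism)
  markers <- which(nm >= 1 & nm < length(haps))
  scores <- -colSums(mism[markers, , drop = FALSE] * qual[markers])
  list(markers = markers, scores = scores)
}

# Small tiling label fixture helper.
label_df <- function(contig, starts, ends, labels) {
  data.frame(contig = contig, start = starts, end = ends,
             label = asmflag:::flag_factor(labels))
}

# Constant-depth track over named contig lengths.
const_track <- function(lengths, depth) {
  coverage_track(lapply(lengths, function(n)
    data.frame(start = 0, end = n, depth = depth)), lengths)
}
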