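# Seeded generators for coverage tracks, alignment fixtures and SNP sets
# with known truth, so the whole pipeline is testable without external
# data.
#
# Depth model: per-base HiFi depth is strongly autocorrelated at the
# read-length scale, so the generator works at the resolution of
# autocorrelation blocks. The Poisson/negative-binomial noise is applied to
# the number of reads overlapping each block -- N ~ Pois(mean*(B+L)/L) for
# a block of B bases and reads of L bases -- and the block's depth is
# round(N*L/(B+L)). This reproduces the variance of block-averaged coverage
# (~ mean*L/(B+L)) instead of the much larger per-base Poisson variance.

#' Specification of a synthetic diploid coverage simulation
#'
#' @param contigs Named numeric vector of contig lengths.
#' @param hap_depth Haploid-region mean depth in reads (default 40, the
#'   typical HiFi coverage of a human assembly project).
#' @param read_length Read length in bases controlling depth
#'   autocorrelation (default 15,000).
#' @param block_size Autocorrelation block size in bases (default 25,000);
#'   depth is constant within a block.
#' @param plants Optional data.frame of planted misassemblies: columns
#'   `contig`, `start`, `end` (0-based half-open), `label` in
#'   Err/Dup/Col, and optionally `multiplier` (depth multiplier; defaults
#'   0.025 for Err, 0.5 for Dup, 2 for Col). Plants must not overlap.
#' @param hsat Optional data.frame of satellite coverage biases: columns
#'   `contig`, `start`, `end`, `class` in HSat1/2/3 and optionally `bias`
#'   (multiplier on the local mean; defaults 0.75 for HSat1 and 1.25 for
#'   HSat2/3, the directions seen for HiFi data). Must not overlap plants.
#' @param noise `"poisson"` (default) or `"nb"` (negative binomial read
#'   counts, for overdispersed coverage).
#' @param nb_size Negative-binomial size (dispersion) parameter when
#'   `noise = "nb"`.
#' @param seed Integer seed; everything the simulator draws flows from it.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(contigs, hap_depth = 40, read_length = 15000,
                     block_size = 25000, plants = NULL, hsat = NULL,
                     noise = c("poisson", "nb"), nb_size = 10, seed = 1) {
  noise <- match.arg(noise)
  stopifnot(!is.null(names(contigs)), all(contigs > 0), block_size >= 1,
            hap_depth > 0, read_length >= 1)
  default_mult <- c(Err = 0.025, Dup = 0.5, Col = 2)
  default_bias <- c(HSat1 = 0.75, HSat2 = 1.25, HSat3 = 1.25)
  if (!is.null(plants)) {
    plants <- as.data.frame(plants)
    stopifnot(all(plants$label %in% c("Err", "Dup", "Col")))
    if (is.null(plants$multiplier))
      plants$multiplier <- default_mult[plants$label]
    na <- is.na(plants$multiplier)
    plants$multiplier[na] <- default_mult[plants$label[na]]
    if (any(plants$multiplier <= 0)) stop("plant multipliers must be > 0")
  }
  if (!is.null(hsat)) {
    hsat <- as.data.frame(hsat)
    stopifnot(all(hsat$class %in% names(default_bias)))
    if (is.null(hsat$bias)) hsat$bias <- default_bias[hsat$class]
    na <- is.na(hsat$bias)
    hsat$bias[na] <- default_bias[hsat$class[na]]
    if (any(hsat$bias <= 0)) stop("hsat bias must be > 0")
  }
  check_no_overlap(rbind(
    if (!is.null(plants)) plants[, c("contig", "start", "end")],
    if (!is.null(hsat)) hsat[, c("contig", "start", "end")]))
  structure(list(contigs = contigs, hap_depth = hap_depth,
                 read_length = read_length, block_size = block_size,
                 plants = plants, hsat = hsat, noise = noise,
                 nb_size = nb_size, seed = as.integer(seed)),
            class = "sim_spec")
}

check_no_overlap <- function(regs) {
  if (is.null(regs) || nrow(regs) < 2) return(invisible(NULL))
  for (ctg in unique(regs$contig)) {
    r <- regs[regs$contig == ctg, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1 && any(r$start[-1] < r$end[-nrow(r)]))
      stop("overlapping planted regions on contig '", ctg, "'")
  }
  invisible(NULL)
}

# Piecewise-constant mean depth per contig: hap_depth scaled by plant
# multipliers and satellite biases, cut on a block grid.
segment_means <- function(spec, ctg, base_depth) {
  len <- spec$contigs[[ctg]]
  cuts <- seq(0, len, by = spec$block_size)
  if (cuts[length(cuts)] != len) cuts <- c(cuts, len)
  edges <- function(df) if (is.null(df)) numeric(0) else {
    d <- df[df$contig == ctg, , drop = FALSE]; c(d$start, d$end)
  }
  cuts <- sort(unique(c(cuts, edges(spec$plants), edges(spec$hsat))))
  cuts <- cuts[cuts >= 0 & cuts <= len]
  seg <- data.frame(start = head(cuts, -1), end = cuts[-1])
  seg$mean <- base_depth
  apply_mult <- function(df, col) {
    if (is.null(df)) return()
    d <- df[df$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      sel <- seg$start >= d$start[i] & seg$end <= d$end[i]
      seg$mean[sel] <<- seg$mean[sel] * d[[col]][i]
    }
  }
  apply_mult(spec$plants, "multiplier")
  apply_mult(spec$hsat, "bias")
  seg
}

# Draw integer depths for segments under the spec's noise model.
draw_depths <- function(seg, spec) {
  B <- seg$end - seg$start
  L <- spec$read_length
  lam <- seg$mean * (B + L) / L
  nreads <- switch(spec$noise,
    poisson = rpois(length(lam), lam),
    nb = rnbinom(length(lam), mu = lam, size = spec$nb_size))
  pmax(as.integer(round(nreads * L / (B + L))), 0L)
}

#' Simulate a diploid coverage track with planted misassemblies
#'
#' Generates a run-length coverage track whose depth follows the spec's
#' regional means (haploid baseline; ~0 in planted erroneous regions, half
#' depth in falsely duplicated plants, integer multiples in collapsed
#' plants; satellite biases multiply the local mean), with noise applied to
#' block-level read counts. Fully reproducible from `spec$seed`.
#'
#' @param spec A [sim_spec()].
#' @return List with `track` (a `cov_track`) and `truth` (data.frame of
#'   planted blocks: `contig`, `start`, `end`, `label`).
#' @export
simulate_coverage <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  withr::with_seed(spec$seed, {
    contigs <- list()
    for (ctg in names(spec$contigs)) {
      seg <- segment_means(spec, ctg, spec$hap_depth)
      seg$depth <- draw_depths(seg, spec)
      contigs[[ctg]] <- seg[, c("start", "end", "depth")]
    }
    track <- coverage_track(contigs, spec$contigs)
  })
  truth <- if (is.null(spec$plants)) {
    data.frame(contig = character(), start = numeric(), end = numeric(),
               label = character())
  } else {
    spec$plants[, c("contig", "start", "end", "label")]
  }
  list(track = track, truth = truth)
}

#' Simulate the auxiliary high-MAPQ coverage track
#'
#' Emulates the depth of alignments with MAPQ above the high-quality
#' cutoff: near-haploid depth over uniquely mappable sequence, ~0 over
#' genuine false duplications (reads split between the two copies map
#' ambiguously) and over erroneous plants, and restored high-quality depth
#' over `rescue_regions` (regions that look duplicated by total depth but
#' are genuinely haploid, e.g. systematic coverage drops). Deterministic
#' per `spec$seed`.
#'
#' @param spec A [sim_spec()].
#' @param rescue_regions Optional data.frame (`contig`, `start`, `end`) of
#'   regions that must receive high-quality support despite low total
#'   depth.
#' @param hq_fraction Fraction of the local mean retained at MAPQ > 20 in
#'   uniquely mappable sequence (default 0.9).
#' @return A `cov_track`.
#' @export
simulate_hq_track <- function(spec, rescue_regions = NULL,
                              hq_fraction = 0.9) {
  stopifnot(inherits(spec, "sim_spec"))
  hq_spec <- spec
  hq_spec$seed <- spec$seed + 1L
  # high-quality mean: hq_fraction of baseline, ~0 over Dup/Err plants
  plants <- spec$plants
  if (!is.null(plants)) {
    plants$multiplier[plants$label == "Dup"] <- 0.004
    plants$multiplier[plants$label == "Err"] <- 0.004
    # collapsed sequence is unique in the assembly: reads map confidently
    plants$multiplier[plants$label == "Col"] <- 2
  }
  if (!is.null(rescue_regions)) {
    rescue <- as.data.frame(rescue_regions)
    rescue$label <- "Col"       # placeholder label, multiplier is explicit
    rescue$multiplier <- 1
    plants <- rbind(plants, rescue[, c("contig", "start", "end", "label",
                                       "multiplier")])
  }
  hq_spec$plants <- plants
  hq_spec$hsat <- spec$hsat
  withr::with_seed(hq_spec$seed, {
    contigs <- list()
    for (ctg in names(hq_spec$contigs)) {
      seg <- segment_means(hq_spec, ctg, hq_fraction * spec$hap_depth)
      seg$depth <- draw_depths(seg, hq_spec)
      contigs[[ctg]] <- seg[, c("start", "end", "depth")]
    }
    coverage_track(contigs, hq_spec$contigs)
  })
}

#' Sample a coverage histogram directly from mixture components
#'
#' Draws `n` per-base depths i.i.d. from a four-component generating model
#' (Poisson erroneous; Gaussian duplicated, haploid and collapsed rounded
#' to non-negative integers) and tabulates them. Used for parameter
#' recovery checks of [fit_mixture()].
#'
#' @param n Number of bases.
#' @param err_lambda,hap_mean,hap_sd,dup_sd,col_sd Generating parameters;
#'   the duplicated mean is `hap_mean / 2` and the collapsed mean
#'   `col_copy * hap_mean`.
#' @param col_copy Copy number of the collapsed component (default 2).
#' @param weights Mixing weights, in order err/dup/hap/col; must sum to 1.
#' @param seed Integer seed.
#' @return A `cov_hist`.
#' @export
simulate_mixture_histogram <- function(n, err_lambda = 1, hap_mean = 40,
                                       hap_sd = 6, dup_sd = 5, col_sd = 8,
                                       col_copy = 2,
                                       weights = c(err = 0.02, dup = 0.03,
                                                   hap = 0.90, col = 0.05),
                                       seed = 1) {
  stopifnot(abs(sum(weights) - 1) < 1e-9)
  withr::with_seed(seed, {
    comp <- sample(c("err", "dup", "hap", "col"), n, replace = TRUE,
                   prob = weights)
    d <- integer(n)
    d[comp == "err"] <- rpois(sum(comp == "err"), err_lambda)
    d[comp == "dup"] <- pmax(0L, as.integer(round(
      rnorm(sum(comp == "dup"), hap_mean / 2, dup_sd))))
    d[comp == "hap"] <- pmax(0L, as.integer(round(
      rnorm(sum(comp == "hap"), hap_mean, hap_sd))))
    d[comp == "col"] <- pmax(0L, as.integer(round(
      rnorm(sum(comp == "col"), col_copy * hap_mean, col_sd))))
  })
  tab <- table(d)
  new_cov_hist(as.numeric(names(tab)), as.numeric(tab))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Extended =/X cigar from two equal-length aligned strings.
eqx_cigar <- function(read, ref) {
  a <- strsplit(read, "")[[1]]; b <- strsplit(ref, "")[[1]]
  r <- rle(a == b)
  paste0(r$lengths, ifelse(r$values, "=", "X"), collapse = "")
}

#' Simulate a two-haplotype read-alignment fixture
#'
#' Generates two homologous contigs (`hap1`, `hap2`) differing at
#' `n_markers` planted substitution sites, draws reads from `hap1` with
#' seeded substitution errors, and emits, per read, a candidate alignment
#' to each haplotype (equal coordinates; one primary, one secondary). The
#' fraction `swap_fraction` of reads get the *wrong* haplotype as primary,
#' which the marker-based re-ranking should fix. Also returns the planted
#' inter-haplotype differences as a SNP table for alt-read filtering tests.
#'
#' @param n_reads Number of reads.
#' @param hap_length Length of each haplotype contig.
#' @param n_markers Number of planted inter-haplotype differences.
#' @param read_length Read length (reads are exact-length substrings).
#' @param error_rate Per-base substitution error rate in reads.
#' @param swap_fraction Fraction of reads whose primary alignment points at
#'   the wrong haplotype.
#' @param base_qual_range Integer range of phred base qualities.
#' @param seed Integer seed.
#' @return List with `records` (alignment table as from [read_sam()]),
#'   `truth` (per read: source haplotype and whether the primary was
#'   correct), `haps` (named character vector of the two sequences),
#'   `markers` (0-based positions of planted differences) and `snps`
#'   (data.frame usable with [filter_alt_reads()]: hap1 coordinates, ref =
#'   hap1 base, alt = hap2 base).
#' @export
simulate_read_alignments <- function(n_reads = 50, hap_length = 3000,
                                     n_markers = 12, read_length = 800,
                                     error_rate = 0.001,
                                     swap_fraction = 0.5,
                                     base_qual_range = c(20, 40), seed = 1) {
  stopifnot(read_length <= hap_length, n_markers < hap_length)
  withr::with_seed(seed, {
    hap1 <- random_dna(hap_length)
    marker_pos <- sort(sample(hap_length, n_markers))   # 1-based
    h2 <- strsplit(hap1, "")[[1]]
    for (p in marker_pos)
      h2[p] <- sample(setdiff(c("A", "C", "G", "T"), h2[p]), 1)
    hap2 <- paste(h2, collapse = "")
    h1c <- strsplit(hap1, "")[[1]]
    recs <- list(); truth <- list()
    for (i in seq_len(n_reads)) {
      start <- sample(hap_length - read_length + 1, 1)   # 1-based
      read <- h1c[start:(start + read_length - 1)]
      nerr <- rpois(1, error_rate * read_length)
      if (nerr > 0) {
        at <- sample(read_length, min(nerr, read_length))
        for (p in at) read[p] <- sample(setdiff(c("A", "C", "G", "T"),
                                                read[p]), 1)
      }
      read_s <- paste(read, collapse = "")
      quals <- sample(base_qual_range[1]:base_qual_range[2], read_length,
                      replace = TRUE)
      qual_s <- rawToChar(as.raw(quals + 33L))
      cig1 <- eqx_cigar(read_s, substr(hap1, start, start + read_length - 1))
      cig2 <- eqx_cigar(read_s, substr(hap2, start, start + read_length - 1))
      nm1 <- sum(strsplit(read_s, "")[[1]] !=
                 strsplit(substr(hap1, start, start + read_length - 1),
                          "")[[1]])
      nm2 <- sum(strsplit(read_s, "")[[1]] !=
                 strsplit(substr(hap2, start, start + read_length - 1),
                          "")[[1]])
      swap <- runif(1) < swap_fraction
      mk <- function(rname, cigar, nm, primary) {
        data.frame(qname = sprintf("read%04d", i),
                   flag = if (primary) 0L else SAM_FLAG_SECONDARY,
                   rname = rname, pos = start, mapq = if (primary) 60L else 0L,
                   cigar = cigar, seq = read_s, qual = qual_s,
                   AS = read_length - 2 * nm, stringsAsFactors = FALSE)
      }
      recs[[2 * i - 1]] <- mk("hap1", cig1, nm1, primary = !swap)
      recs[[2 * i]] <- mk("hap2", cig2, nm2, primary = swap)
      truth[[i]] <- data.frame(qname = sprintf("read%04d", i),
                               source = "hap1", primary_correct = !swap,
                               stringsAsFactors = FALSE)
    }
  })
  records <- do.call(rbind, recs)
  attr(records, "header") <- c("@HD\tVN:1.6\tSO:unsorted",
                               sprintf("@SQ\tSN:hap1\tLN:%d", hap_length),
                               sprintf("@SQ\tSN:hap2\tLN:%d", hap_length))
  h2c <- strsplit(hap2, "")[[1]]
  list(records = records, truth = do.call(rbind, truth),
       haps = c(hap1 = hap1, hap2 = hap2), markers = marker_pos - 1,
       snps = data.frame(contig = "hap1", pos = marker_pos - 1,
                         ref = h1c[marker_pos], alt = h2c[marker_pos],
                         stringsAsFactors = FALSE))
}

#' Write a minimal VCF of biallelic SNPs
#'
#' Emits a small, valid VCF (one sample, `GT:VAF:GQ` genotype fields) that
#' [select_snps()] can read back. Used by the simulator and tests.
#'
#' @param snps data.frame with columns `contig`, `pos` (0-based), `ref`,
#'   `alt`, and optionally `vaf`, `gq`, `filter`.
#' @param path Output path.
#' @param contig_lengths Optional named lengths for `##contig` header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_snps_vcf <- function(snps, path, contig_lengths = NULL) {
  if (is.null(snps$vaf)) snps$vaf <- 0.5
  if (is.null(snps$gq)) snps$gq <- 50
  if (is.null(snps$filter)) snps$filter <- "PASS"
  hdr <- c("##fileformat=VCFv4.2",
           "##FILTER=<ID=PASS,Description=\"All filters passed\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("##FORMAT=<ID=VAF,Number=1,Type=Float,",
                  "Description=\"Variant allele fraction\">"),
           paste0("##FORMAT=<ID=GQ,Number=1,Type=Integer,",
                  "Description=\"Genotype quality\">"))
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%.0f>",
                          names(contig_lengths), contig_lengths))
  hdr <- c(hdr, paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", "sample", sep = "\t"))
  body <- paste(snps$contig, snps$pos + 1, ".", snps$ref, snps$alt, 30,
                snps$filter, ".", "GT:VAF:GQ",
                sprintf("0/1:%s:%d", format(snps$vaf), as.integer(snps$gq)),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
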