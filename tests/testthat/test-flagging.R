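# Flag tracks, corrections, merging and summaries.

test_that("flag_track emits maximal runs of identically labelled bases", {
  m <- make_model()
  tab <- assign_components(m, 100)
  tr <- coverage_track(list(c1 = data.frame(start = c(0, 5),
                                            end = c(5, 100),
                                            depth = c(0, 40))),
                       c(c1 = 100))
  fl <- flag_track(tr, tab)
  expect_equal(fl$start, c(0, 5))
  expect_equal(fl$end, c(5, 100))
  expect_equal(as.character(fl$label), c("Err", "Hap"))

  # uniform depth: a single block
  fl1 <- flag_track(const_track(c(u = 500), 40), tab)
  expect_equal(nrow(fl1), 1L)
  expect_equal(as.character(fl1$label), "Hap")

  # depth beyond the table errors
  expect_error(flag_track(const_track(c(u = 10), 5000), tab),
               "outside assignment table")
})

test_that("flag_track agrees with a per-base labelling oracle", {
  m <- make_model()
  tab <- assign_components(m, 60)
  for (seed in 1:4) {
    tr <- random_track(c(a = 700, b = 300), max_depth = 60, seed = seed)
    fl <- flag_track(tr, tab)
    # expand blocks back to bases and compare to the direct per-base labels
    for (ctg in c("a", "b")) {
      blocks <- fl[fl$contig == ctg, ]
      expanded <- rep(as.character(blocks$label), blocks$end - blocks$start)
      oracle <- vapply(perbase_depths(tr)[[ctg]],
                       function(d) brute_label(m, d), "")
      expect_equal(expanded, oracle)
      # maximality: consecutive blocks never share a label
      expect_true(all(blocks$label[-1] != blocks$label[-nrow(blocks)]))
    }
  }
})

test_that("short contigs and degenerate windows fall back to the whole-genome model", {
  # long contig: haploid 40x; short contig: depth 80 => collapsed under the
  # whole-genome model even though its own histogram would look haploid
  long_tr <- const_track(c(long = 3e6), 40)$contigs$long
  short_tr <- data.frame(start = 0, end = 4e5, depth = 80)
  zero_win <- data.frame(start = c(0, 1e6),
                         end = c(1e6, 2e6), depth = c(0, 40))
  tr <- coverage_track(list(long = long_tr, short = short_tr,
                            zeroes = zero_win),
                       c(long = 3e6, short = 4e5, zeroes = 2e6))
  expect_message(
    wf <- run_windowed_flagging(tr, window_size = 1e6, min_contig = 5e5,
                                opts = fit_options(init_coverage = 40)),
    "fell back")
  lab <- wf$labels
  expect_equal(as.character(lab$label[lab$contig == "short"]), "Col")
  expect_equal(as.character(lab$label[lab$contig == "long"]), "Hap")
  # the all-zero window is labelled Err under the genome model
  z <- lab[lab$contig == "zeroes", ]
  expect_equal(as.character(z$label), c("Err", "Hap"))
  expect_gte(wf$n_fallback, 1L)
  # windowed contigs carry one model per window unless fallen back
  expect_equal(length(wf$window_fits), 3L + 2L)  # 3 long + 2 zeroes windows
})

test_that("labels tile the contigs after windowed flagging", {
  sim <- simulate_coverage(sim_spec(c(c1 = 2e6, c2 = 3e5), seed = 8))
  wf <- run_windowed_flagging(sim$track, window_size = 1e6, min_contig = 5e5)
  w <- rowsum(wf$labels$end - wf$labels$start, wf$labels$contig)
  expect_equal(w[, 1], c(c1 = 2e6, c2 = 3e5))
})

test_that("satellite correction reflags biased regions and leaves the rest alone", {
  # 4 Mb haploid genome at 40x with a 300 kb HSat2 array whose HiFi
  # coverage rises systematically to 1.5x; the genome-wide model calls the
  # rise collapsed, the class-specific refit re-learns it as haploid
  hsat <- data.frame(contig = "c1", start = 2e6, end = 2.3e6,
                     class = "HSat2")
  spec <- sim_spec(c(c1 = 4e6), hsat = cbind(hsat, bias = 1.5), seed = 5)
  tr <- simulate_coverage(spec)$track
  wf <- run_windowed_flagging(tr, opts = fit_options(init_coverage = 40))
  before <- wf$labels

  frac_in <- function(labels, lv) {
    sel <- labels$end > 2e6 & labels$start < 2.3e6
    b <- labels[sel, ]
    ov <- pmin(b$end, 2.3e6) - pmax(b$start, 2e6)
    sum(ov[as.character(b$label) == lv]) / 3e5
  }
  expect_gte(frac_in(before, "Col"), 0.9)

  after <- apply_hsat_correction(before, hsat, tr, wf$genome_mean,
                                 fit_options(init_coverage = 40))
  expect_gte(frac_in(after, "Hap"), 0.99)
  # bases outside the annotated array keep their labels, base by base
  label_at <- function(labels, pos) {
    as.character(labels$label[labels$start <= pos & labels$end > pos][1])
  }
  probes <- c(seq(0, 2e6 - 1, by = 5e4), seq(2.3e6, 4e6 - 1, by = 5e4))
  expect_equal(vapply(probes, function(p) label_at(after, p), ""),
               vapply(probes, function(p) label_at(before, p), ""))

  # empty annotation: labels unchanged
  none <- apply_hsat_correction(before,
                                data.frame(contig = character(),
                                           start = numeric(),
                                           end = numeric(),
                                           class = character()),
                                tr, wf$genome_mean)
  expect_identical(none, before)

  # unknown class string
  expect_error(apply_hsat_correction(before,
                                     data.frame(contig = "c2", start = 0,
                                                end = 10, class = "HSat9"),
                                     tr, wf$genome_mean), "unknown HSat")
})

test_that("high-MAPQ support above the cutoff rescues duplicated flags only", {
  labels <- label_df("c1", c(0, 1000, 2000, 3000, 4000),
                     c(1000, 2000, 3000, 4000, 5000),
                     c("Dup", "Hap", "Dup", "Err", "Col"))
  hq6 <- const_track(c(c1 = 5000), 6)
  out <- apply_mapq_correction(labels, hq6, min_support = 5)
  # both Dup blocks rescued; Err/Col untouched
  expect_equal(as.character(out$label), c("Hap", "Err", "Col"))
  expect_equal(out$end[1], 3000)   # rescued blocks merged with Hap

  # support of exactly 5 is not enough (strictly more than five required)
  hq5 <- const_track(c(c1 = 5000), 5)
  out5 <- apply_mapq_correction(labels, hq5, min_support = 5)
  expect_identical(out5$label, labels$label)

  # the block minimum decides: one low-support base blocks the rescue
  hqmix <- coverage_track(list(c1 = data.frame(start = c(0, 500, 501),
                                               end = c(500, 501, 5000),
                                               depth = c(6, 5, 6))),
                          c(c1 = 5000))
  outm <- apply_mapq_correction(labels, hqmix, min_support = 5)
  expect_equal(as.character(outm$label)[1], "Dup")

  # idempotence
  expect_identical(apply_mapq_correction(out, hq6, 5), out)
})

test_that("nearby same-label blocks merge below 1,000 bases but not at it", {
  # non-tiling inputs: only the Hap claims exist
  two <- label_df("c1", c(0, 1999), c(1000, 3000), c("Hap", "Hap"))
  res <- merge_and_finalize(two, c(c1 = 3000), merge_dist = 1000)
  expect_equal(nrow(res$blocks), 1L)
  expect_equal(res$blocks$end - res$blocks$start, 3000)

  apart <- label_df("c1", c(0, 2000), c(1000, 3000), c("Hap", "Hap"))
  res2 <- merge_and_finalize(apart, c(c1 = 3000), merge_dist = 1000)
  expect_equal(nrow(res2$blocks), 2L)
})

test_that("bases contested after merging become Unknown", {
  # Hap gap of 500 holds a Dup block that also merges with a Dup neighbour
  labels <- label_df("c1",
                     c(0, 2000, 2500, 3000, 3400),
                     c(2000, 2500, 3000, 3400, 10000),
                     c("Hap", "Dup", "Hap", "Dup", "Hap"))
  res <- merge_and_finalize(labels, c(c1 = 10000), merge_dist = 1000)
  b <- res$blocks
  # Dup spans 2000-3400 after merging; Hap also claims it all
  expect_equal(as.character(b$label), c("Hap", "Unk", "Hap"))
  expect_equal(b$start[2], 2000)
  expect_equal(b$end[2], 3400)
  # tiling preserved
  expect_equal(sum(b$end - b$start), 10000)
})

test_that("merge_and_finalize is idempotent", {
  withr::with_seed(17, {
    for (rep in 1:3) {
      n <- 40
      cuts <- sort(sample(1:9999, n - 1))
      labels <- label_df("c1", c(0, cuts), c(cuts, 10000),
                         sample(c("Err", "Dup", "Hap", "Col"), n, TRUE))
      r1 <- merge_and_finalize(labels, c(c1 = 10000), merge_dist = 300)
      r2 <- merge_and_finalize(r1$blocks, c(c1 = 10000), merge_dist = 300)
      expect_equal(r2$blocks, r1$blocks)
      expect_equal(sum(r1$blocks$end - r1$blocks$start), 10000)
    }
  })
})

test_that("summaries report per-label fractions and the unreliable N50", {
  # all-haploid assembly: nothing unreliable
  all_hap <- label_df("c1", 0, 1e6, "Hap")
  s <- merge_and_finalize(all_hap, c(c1 = 1e6))$summary
  expect_equal(s$unreliable_fraction, 0)
  expect_equal(s$unreliable_n50, 0)

  # one 10 kb erroneous block in 1 Mb: 1% unreliable, N50 10 kb
  one_err <- label_df("c1", c(0, 5e5, 5.1e5), c(5e5, 5.1e5, 1e6),
                      c("Hap", "Err", "Hap"))
  s2 <- merge_and_finalize(one_err, c(c1 = 1e6))$summary
  expect_equal(s2$unreliable_fraction, 0.01)
  expect_equal(s2$unreliable_n50, 1e4)
  expect_equal(unname(s2$label_bases["Err"]), 1e4)
})

test_that("N50 matches a sort-and-accumulate oracle", {
  withr::with_seed(43, {
    for (rep in 1:10) {
      lens <- sample(1:5000, sample(1:50, 1), replace = TRUE)
      s <- sort(lens, decreasing = TRUE)
      oracle <- s[cumsum(s) >= sum(s) / 2][1]
      expect_equal(n50(lens), oracle)
    }
  })
  expect_equal(n50(numeric(0)), 0)
})

test_that("flag BED export writes five-label BED9 that reads back", {
  labels <- label_df("c1", c(0, 100, 300), c(100, 300, 450),
                     c("Err", "Hap", "Col"))
  res <- merge_and_finalize(labels, c(c1 = 450), merge_dist = 50)
  f <- tempfile(fileext = ".bed")
  write_flag_bed(res, f)
  back <- read_region_bed(f)
  expect_equal(back$start, res$blocks$start)
  expect_equal(back$end, res$blocks$end)
  expect_equal(back$label, as.character(res$blocks$label))
  fields <- strsplit(readLines(f)[1], "\t")[[1]]
  expect_length(fields, 9L)   # itemRgb column present
})
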