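# Region discovery: state calls, frequency sweep vs per-base counting,
# frequent-region extraction and cytoband collapsing.

test_that("state calls follow the 2.5 / 1.5 copy-number thresholds", {
  expect_equal(call_state(c(2.6, 2.0, 1.4)), c("gain", "neutral", "loss"))
  # boundary values are not past the threshold
  expect_equal(call_state(c(2.5, 1.5)), c("neutral", "neutral"))
  df <- call_state(data.frame(mean_cn = c(3.2, 1.1)))
  expect_equal(df$state, c("gain", "loss"))
  expect_error(call_state(c(2, Inf)), "finite")
})

make_state_seg <- function(sample, start, end, state) {
  data.frame(sample = sample, chrom = "chr1", start = start, end = end,
             state = state, stringsAsFactors = FALSE)
}

test_that("frequency track counts covering samples per interval", {
  # 1 of 10 samples gained over [100, 200)
  seg <- make_state_seg(sprintf("S%02d", 1:10), 0, 1000, "neutral")
  seg <- rbind(seg, make_state_seg("S01", 100, 200, "gain"))
  tr <- build_frequency_track(seg, n_samples = 10)
  at <- function(pos) tr$gain_count[tr$start <= pos & tr$end > pos]
  expect_equal(at(150), 1)
  expect_equal(at(50), 0)
  expect_equal(at(500), 0)

  # two half-overlapping gains -> counts 1, 2, 1
  seg2 <- rbind(make_state_seg("A", 0, 200, "gain"),
                make_state_seg("B", 100, 300, "gain"))
  tr2 <- build_frequency_track(seg2, n_samples = 2)
  expect_equal(tr2$gain_count, c(1L, 2L, 1L))
  expect_equal(tr2$start, c(0, 100, 200))
  expect_equal(tr2$end, c(100, 200, 300))

  # everyone gained everywhere -> frequency 1 everywhere
  seg3 <- make_state_seg(c("A", "B", "C"), 0, 500, "gain")
  tr3 <- build_frequency_track(seg3, n_samples = 3)
  expect_true(all(tr3$gain_count / tr3$n_samples == 1))

  expect_equal(nrow(build_frequency_track(seg[0, ])), 0)
})

test_that("sweep frequencies equal brute-force per-base counts", {
  set.seed(31)
  for (rep in 1:10) {
    span <- sample(2000:20000, 1)
    segs <- random_state_segments(sample(2:20, 1), span)
    tr <- build_frequency_track(segs)
    for (state in c("gain", "loss")) {
      pb <- pb_state_counts(segs, state, span)
      col <- paste0(state, "_count")
      # expand the track back to per-base and compare exactly
      expanded <- integer(span)
      for (r in seq_len(nrow(tr))) {
        expanded[(tr$start[r] + 1):tr$end[r]] <- tr[[col]][r]
      }
      expect_identical(expanded, pb)
    }
  }
})

test_that("frequent-gain extraction is inclusive at the threshold", {
  seg <- rbind(
    make_state_seg(sprintf("S%02d", 1:29), 100, 200, "gain"),   # 29/72 = 40.3%
    make_state_seg(sprintf("S%02d", 1:28), 400, 500, "gain"),   # 28/72 = 38.9%
    make_state_seg(sprintf("T%02d", 1:72), 0, 1000, "neutral"))
  tr <- build_frequency_track(seg, n_samples = 72)
  reg <- frequent_gain_regions(tr, min_freq = 0.40)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 100)
  expect_equal(reg$end, 200)
  # exactly 40% qualifies (inclusive comparison)
  seg40 <- rbind(make_state_seg(sprintf("S%02d", 1:4), 0, 100, "gain"),
                 make_state_seg(sprintf("T%02d", 1:10), 0, 100, "neutral"))
  tr40 <- build_frequency_track(seg40, n_samples = 10)
  expect_equal(nrow(frequent_gain_regions(tr40, 0.40)), 1)
})

test_that("a sawtooth track crossing the threshold gives two regions", {
  set.seed(32)
  for (rep in 1:10) {
    span <- 5000
    segs <- random_state_segments(12, span)
    tr <- build_frequency_track(segs)
    reg <- frequent_gain_regions(tr, min_freq = 0.4)
    pb <- pb_state_counts(segs, "gain", span) / length(unique(segs$sample))
    runs <- pb_runs(pb >= 0.4)
    expect_equal(nrow(reg), nrow(runs))
    if (nrow(reg)) {
      expect_equal(reg$start, runs$start)
      expect_equal(reg$end, runs$end)
    }
  }
})

test_that("raising the frequency threshold never adds a region", {
  set.seed(34)
  segs <- random_state_segments(15, 8000)
  tr <- build_frequency_track(segs)
  prev <- Inf
  for (f in c(0.2, 0.4, 0.6, 0.8)) {
    n <- nrow(frequent_gain_regions(tr, f))
    expect_lte(n, prev)
    prev <- n
  }
})

demo_bands <- data.frame(
  chrom = "chr1",
  start = c(0, 1000, 2000), end = c(1000, 2000, 3000),
  band = c("q26.1", "q26.2", "q26.3"),
  stain = "gneg", stringsAsFactors = FALSE)

test_that("intervals in one band collapse to min-start / max-end", {
  iv <- data.frame(chrom = "chr1", start = c(1010, 1030), end = c(1020, 1040))
  reg <- collapse_by_cytoband(iv, demo_bands)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 1010)
  expect_equal(reg$end, 1040)
  expect_equal(reg$cytoband, "q26.2")
  expect_equal(reg$n_members, 2)
  expect_equal(reg$region_id, "1_1")
})

test_that("a single interval collapses to itself", {
  iv <- data.frame(chrom = "chr1", start = 1200, end = 1300)
  reg <- collapse_by_cytoband(iv, demo_bands)
  expect_equal(reg$start, 1200)
  expect_equal(reg$end, 1300)
  expect_equal(reg$cytoband, "q26.2")
})

test_that("band-spanning intervals form their own tagged region", {
  iv <- data.frame(chrom = "chr1",
                   start = c(900, 1100, 1300), end = c(1100, 1200, 1400))
  reg <- collapse_by_cytoband(iv, demo_bands)
  # spanning interval kept apart from the q26.1 and q26.2 groups
  expect_equal(nrow(reg), 2)
  spanning <- reg[reg$cytoband == "q26.1-q26.2", ]
  expect_equal(spanning$start, 900)
  expect_equal(spanning$end, 1100)
  grouped <- reg[reg$cytoband == "q26.2", ]
  expect_equal(grouped$start, 1100)
  expect_equal(grouped$end, 1400)
  expect_equal(grouped$n_members, 2)
})

test_that("collapsing never shrinks coverage and ids follow genomic order", {
  set.seed(35)
  for (rep in 1:5) {
    k <- sample(3:10, 1)
    start <- sample(0:2800, k)
    iv <- data.frame(chrom = "chr1", start = start,
                     end = start + sample(10:150, k, replace = TRUE))
    iv$end <- pmin(iv$end, 3000)
    iv <- iv[iv$end > iv$start, ]
    reg <- collapse_by_cytoband(iv, demo_bands)
    for (r in seq_len(nrow(reg))) {
      mem <- reg$members[[r]]
      expect_true(all(mem$start >= reg$start[r] & mem$end <= reg$end[r]))
    }
    expect_false(is.unsorted(reg$start))
    expect_equal(reg$region_id, paste0("1_", seq_len(nrow(reg))))
  }
})

test_that("an interval outside every cytoband is an error", {
  iv <- data.frame(chrom = "chr1", start = 5000, end = 5100)
  expect_error(collapse_by_cytoband(iv, demo_bands), "no cytoband")
})
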