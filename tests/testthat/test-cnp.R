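# Germline CNP detection (strict >5% of normals) and region subtraction
# (interior split, edge trim, full containment), checked against a
# per-base interval-difference oracle.

cnp_norm_segments <- function(n_normals, altered_idx, alt_start, alt_end,
                              alt_state = "gain", span = 10000) {
  ids <- sprintf("N%02d", seq_len(n_normals))
  base <- data.frame(sample = ids, chrom = "chr1", start = 0, end = span,
                     n_markers = 10, mean_cn = 2, state = "neutral",
                     stringsAsFactors = FALSE)
  if (!length(altered_idx)) return(base)
  alt <- data.frame(sample = ids[altered_idx], chrom = "chr1",
                    start = alt_start, end = alt_end, n_markers = 2,
                    mean_cn = if (alt_state == "gain") 3 else 1,
                    state = alt_state, stringsAsFactors = FALSE)
  rbind(base, alt)
}

test_that("the >5% rule is strict: 3 of 57 qualifies, 2 of 57 does not", {
  seg3 <- cnp_norm_segments(57, 1:3, 2000, 3000)
  cnps <- detect_cnps(NULL, segments = seg3)
  expect_equal(nrow(cnps), 1)
  expect_equal(cnps$n_normals_altered, 3)
  expect_equal(cnps$start, 2000)
  expect_equal(cnps$end, 3000)
  expect_equal(cnps$type, "gain")

  seg2 <- cnp_norm_segments(57, 1:2, 2000, 3000)
  expect_equal(nrow(detect_cnps(NULL, segments = seg2)), 0)
})

test_that("gain and loss evidence pool by default but can be separated", {
  seg <- rbind(cnp_norm_segments(57, 1:2, 2000, 3000, "gain"),
               cnp_norm_segments(57, 3:4, 2000, 3000, "loss")[58:59, ])
  pooled <- detect_cnps(NULL, segments = seg, n_normals = 57)
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$type, "both")
  expect_equal(pooled$n_normals_altered, 4)
  separate <- detect_cnps(NULL, segments = seg, n_normals = 57,
                          mode = "separate")
  expect_equal(nrow(separate), 0) # 2/57 gain and 2/57 loss each below 5%
})

test_that("unaltered normals give no CNPs and zero normals error", {
  seg <- cnp_norm_segments(57, integer(0), 0, 0)[1:57, ]
  expect_equal(nrow(detect_cnps(NULL, segments = seg)), 0)
  expect_error(detect_cnps(data.frame()), "no normal samples")
  expect_warning(detect_cnps(NULL, segments = cnp_norm_segments(5, 1, 100, 200)),
                 "unstable")
})

region <- data.frame(chrom = "chr1", start = 100, end = 200)

test_that("an interior CNP splits the region in two", {
  out <- subtract_cnp(region, data.frame(chrom = "chr1", start = 140, end = 160))
  expect_equal(nrow(out), 2)
  expect_equal(out$start, c(100, 160))
  expect_equal(out$end, c(140, 200))
})

test_that("an edge-overlapping CNP trims the region", {
  out <- subtract_cnp(region, data.frame(chrom = "chr1", start = 90, end = 110))
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 110)
  expect_equal(out$end, 200)
  out2 <- subtract_cnp(region, data.frame(chrom = "chr1", start = 190, end = 250))
  expect_equal(out2$start, 100)
  expect_equal(out2$end, 190)
})

test_that("a covering CNP removes the region; a disjoint one leaves it", {
  out <- subtract_cnp(region, data.frame(chrom = "chr1", start = 90, end = 210))
  expect_equal(nrow(out), 0)
  out2 <- subtract_cnp(region, data.frame(chrom = "chr1", start = 300, end = 400))
  expect_equal(out2$start, 100)
  expect_equal(out2$end, 200)
  # different chromosome: untouched
  out3 <- subtract_cnp(region, data.frame(chrom = "chr2", start = 100, end = 200))
  expect_equal(nrow(out3), 1)
})

test_that("iterated subtraction equals the per-base interval difference", {
  set.seed(41)
  for (rep in 1:20) {
    span <- 5000
    reg <- data.frame(region_id = "1_1", chrom = "chr1",
                      start = sample(0:2000, 1))
    reg$end <- reg$start + sample(500:2500, 1)
    k <- sample(0:5, 1)
    cnps <- if (k > 0) {
      st <- sample(0:(span - 300), k)
      data.frame(chrom = sample(c("chr1", "chr2"), k, replace = TRUE),
                 start = st, end = st + sample(50:600, k, replace = TRUE))
    } else {
      data.frame(chrom = character(), start = numeric(), end = numeric())
    }
    out <- subtract_cnps(reg, cnps)
    mask <- pb_interval_difference(reg, cnps, span)
    runs <- pb_runs(mask)
    expect_equal(nrow(out), nrow(runs))
    if (nrow(out)) {
      expect_equal(out$start, runs$start)
      expect_equal(out$end, runs$end)
      # fragments never overlap a CNP nor exceed the parent region
      for (p in seq_len(nrow(out))) {
        expect_gte(out$start[p], reg$start)
        expect_lte(out$end[p], reg$end)
        if (nrow(cnps)) {
          same <- cnps[cnps$chrom == "chr1", , drop = FALSE]
          if (nrow(same)) {
            ov <- pmax(0, pmin(out$end[p], same$end) -
                         pmax(out$start[p], same$start))
            expect_true(all(ov == 0))
          }
        }
      }
    }
  }
})

test_that("the result does not depend on CNP application order", {
  set.seed(42)
  reg <- data.frame(region_id = "1_1", chrom = "chr1", start = 0, end = 4000)
  st <- sample(0:3500, 6)
  cnps <- data.frame(chrom = "chr1", start = st,
                     end = st + sample(100:800, 6, replace = TRUE))
  a <- subtract_cnps(reg, cnps)
  b <- subtract_cnps(reg, cnps[sample(nrow(cnps)), ])
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
})

test_that("split fragments get suffixed ids and keep the parent id", {
  reg <- data.frame(region_id = "3_10", chrom = "chr3", start = 100, end = 200,
                    cytoband = "q26.2")
  out <- subtract_cnps(reg, data.frame(chrom = "chr3", start = 140, end = 160))
  expect_equal(out$region_id, c("3_10.1", "3_10.2"))
  expect_equal(out$parent_region_id, c("3_10", "3_10"))
  expect_equal(out$cytoband, c("q26.2", "q26.2"))
})
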