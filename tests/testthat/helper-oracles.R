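# Independent oracles used across the suite. All are deliberately naive
# (exhaustive search, per-base counting) and share no code with the
# implementation paths they check.

# Exhaustive circular max-|T| arc search in plain R. Arc (i, j) covers
# markers i+1..j; ties resolve to the leftmost, then shortest, arc.
oracle_max_arc <- function(x, min_width = 2L) {
  n <- length(x)
  best <- list(t = -1, i = NA_integer_, j = NA_integer_)
  cs <- c(0, cumsum(x))
  for (i in 0:(n - min_width)) {
    jmax <- if (i == 0) n - 1 else n
    for (j in seq(i + min_width, jmax)) {
      k <- j - i
      if (n - k < min_width) break
      arc <- (cs[j + 1] - cs[i + 1]) / k
      comp <- (cs[n + 1] - cs[j + 1] + cs[i + 1]) / (n - k)
      t <- abs(arc - comp) / sqrt(1 / k + 1 / (n - k))
      if (t > best$t) best <- list(t = t, i = i, j = j)
    }
  }
  best
}

# Recursive exhaustive change-point search. A split is accepted when the
# best arc's |T| exceeds tcut marker-noise sds (noise estimated robustly
# from lag-1 differences of the whole series); with planted shifts of at
# least 10 noise sds this cleanly separates real change points from the
# null max (~ sqrt(2 log n_arcs) ~ 4 sds at n <= 60).
oracle_cbs_breakpoints <- function(x, min_width = 2L, tcut = 5) {
  sigma <- stats::mad(diff(x)) / sqrt(2)
  if (!is.finite(sigma) || sigma == 0) sigma <- stats::sd(x)
  if (!is.finite(sigma) || sigma == 0) return(integer())
  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 2L * min_width) return(integer())
    b <- oracle_max_arc(x[lo:hi], min_width)
    if (!is.finite(b$t) || b$t / sigma <= tcut) return(integer())
    cuts <- integer()
    if (b$i > 0) cuts <- c(cuts, lo - 1L + b$i)
    if (b$j < n) cuts <- c(cuts, lo - 1L + b$j)
    edges <- c(lo - 1L, cuts, hi)
    for (p in seq_len(length(edges) - 1L)) {
      cuts <- c(cuts, recurse(edges[p] + 1L, edges[p + 1L]))
    }
    cuts
  }
  sort(unique(recurse(1L, length(x))))
}

# Per-base sample counts for one state over [0, span): element b+1 counts
# samples whose segment of that state covers base b.
pb_state_counts <- function(segments, state, span) {
  counts <- integer(span)
  sel <- segments[segments$state == state, , drop = FALSE]
  for (s in unique(sel$sample)) {
    covered <- logical(span)
    ss <- sel[sel$sample == s, , drop = FALSE]
    for (r in seq_len(nrow(ss))) {
      lo <- max(0, ss$start[r]); hi <- min(span, ss$end[r])
      if (hi > lo) covered[(lo + 1):hi] <- TRUE
    }
    counts <- counts + covered
  }
  counts
}

# Per-base membership of "region minus union of CNPs" over [0, span)
pb_interval_difference <- function(region, cnps, span) {
  inside <- logical(span)
  inside[(region$start + 1):region$end] <- TRUE
  if (!is.null(cnps) && nrow(cnps)) {
    for (r in seq_len(nrow(cnps))) {
      if (cnps$chrom[r] != region$chrom) next
      lo <- max(0, cnps$start[r]); hi <- min(span, cnps$end[r])
      if (hi > lo) inside[(lo + 1):hi] <- FALSE
    }
  }
  inside
}

# maximal runs of TRUE in a logical per-base vector -> intervals [start, end)
pb_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# random multi-sample state-called segment set tiling [0, span) per sample
random_state_segments <- function(n_samples, span, max_segments = 6) {
  out <- list()
  for (s in seq_len(n_samples)) {
    k <- sample(1:max_segments, 1)
    bks <- sort(unique(c(0, span, sample(seq_len(span - 1), k - 1))))
    st <- sample(c("gain", "loss", "neutral"), length(bks) - 1, replace = TRUE,
                 prob = c(.3, .2, .5))
    out[[s]] <- data.frame(sample = sprintf("S%02d", s), chrom = "chr1",
                           start = bks[-length(bks)], end = bks[-1],
                           state = st, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# tiny deterministic cohort shared by several tests
tiny_cohort_config <- function(seed = 7) {
  cohort_config(
    n_tumours = 16, n_normals = 8,
    chrom_lengths = c(chr1 = 20e6), marker_spacing = 2e5,
    driver_amplicons = list(
      planted_amplicon("chr1", 4e6, 8e6, frequency = 0.6, cn = c(3, 4),
                       beta = 0.5)),
    passenger_rate = 2, noise_sd_cn = 0.2, n_genes = 60, seed = seed)
}
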