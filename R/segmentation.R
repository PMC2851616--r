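# Circular binary segmentation (CBS) of marker-level copy-number series.
# The max-|T| arc search and permutation test live in src/cbs.cpp; this file
# drives the recursion and assembles tiling segments.

#' CBS parameters
#'
#' @param alpha Significance level a split's permutation p-value must beat.
#' @param n_perm Maximum number of permutations per split test. The test
#'   stops early (sequentially) once the decision at `alpha` is settled, so
#'   the effective count adapts to the data.
#' @param min_width Minimum number of markers in any arc or complement.
#' @param trim Winsorisation fraction applied to each series before testing
#'   (0 disables); guards the statistic against single-marker outliers.
#' @param undo_sd If > 0, adjacent segments whose means differ by less than
#'   `undo_sd` times the marker noise sd (MAD of lag-1 differences / sqrt(2))
#'   are merged back after splitting.
#' @return A `cbs_params` list.
#' @export
cbs_params <- function(alpha = 0.01, n_perm = 10000L, min_width = 2L,
                       trim = 0, undo_sd = 0) {
  stop_if(alpha <= 0 || alpha >= 1, "alpha must be in (0, 1)")
  stop_if(n_perm < 100, "n_perm must be >= 100")
  stop_if(min_width < 1, "min_width must be >= 1")
  stop_if(trim < 0 || trim >= 0.5, "trim must be in [0, 0.5)")
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 min_width = as.integer(min_width), trim = trim,
                 undo_sd = undo_sd), class = "cbs_params")
}

#' Segment one marker series by circular binary segmentation
#'
#' Recursively splits the series at the arc maximising the circular
#' two-sample statistic |T| (arc mean vs complement mean, scaled by
#' `sqrt(1/k + 1/(n-k))`); a split is kept iff its permutation p-value is
#' below `params$alpha`. Ties in |T| resolve to the leftmost, then
#' shortest, arc. Segment boundaries are placed at the first marker of each
#' segment so that a sample's segments tile the marker span without gaps
#' (internal 0-based half-open coordinates; the last segment ends at the
#' last marker position).
#'
#' @param series data.frame with columns `chrom` (single value), `pos`
#'   (strictly increasing 1-based bp) and `cn` (finite values).
#' @param params A [cbs_params()] object.
#' @param seed Optional integer seed for the permutation RNG.
#' @return data.frame `chrom, start, end, n_markers, mean_cn`, ordered,
#'   non-overlapping, tiling `[pos[1]-1, pos[n])`.
#' @export
cbs_segment <- function(series, params = cbs_params(), seed = NULL) {
  stop_if(!all(c("chrom", "pos", "cn") %in% names(series)),
          "series needs columns chrom, pos, cn")
  stop_if(length(unique(series$chrom)) != 1, "series must be a single chromosome")
  stop_if(nrow(series) < 1, "series needs at least one marker")
  stop_if(any(is.na(series$cn)) || any(!is.finite(series$cn)),
          "series contains NA or non-finite copy-number values")
  stop_if(any(diff(series$pos) <= 0), "positions must be strictly increasing")
  if (!is.null(seed)) set.seed(as.integer(seed))

  x <- series$cn
  if (params$trim > 0 && length(x) > 2) {
    q <- stats::quantile(x, c(params$trim, 1 - params$trim), names = FALSE)
    x <- pmin(pmax(x, q[1]), q[2])
  }
  bks <- .cbs_recurse(x, 1L, length(x), params)
  bks <- sort(unique(bks))
  if (params$undo_sd > 0 && length(bks)) {
    bks <- .undo_splits(x, bks, params$undo_sd)
  }
  .assemble_segments(series, bks)
}

# returns breakpoints as marker indices b meaning "split after marker b"
.cbs_recurse <- function(x, lo, hi, params) {
  n <- hi - lo + 1L
  if (n < 2L * params$min_width) return(integer())
  res <- cbs_perm_test(x[lo:hi], params$min_width, params$n_perm,
                       params$alpha, as.integer(ceiling(2 / params$alpha)))
  if (is.na(res$p) || res$p >= params$alpha) return(integer())
  i <- res$i; j <- res$j
  cuts <- integer()
  if (i > 0L) cuts <- c(cuts, lo - 1L + i)
  if (j < n) cuts <- c(cuts, lo - 1L + j)
  if (!length(cuts)) return(integer())
  edges <- c(lo - 1L, cuts, hi)
  out <- cuts
  for (p in seq_len(length(edges) - 1L)) {
    out <- c(out, .cbs_recurse(x, edges[p] + 1L, edges[p + 1L], params))
  }
  out
}

.undo_splits <- function(x, bks, undo_sd) {
  sigma <- stats::mad(diff(x)) / sqrt(2)
  if (!is.finite(sigma) || sigma == 0) sigma <- stats::sd(x)
  repeat {
    edges <- c(0L, bks, length(x))
    means <- vapply(seq_len(length(edges) - 1L), function(p) {
      mean(x[(edges[p] + 1L):edges[p + 1L]])
    }, numeric(1))
    gap <- abs(diff(means))
    if (!length(gap) || all(gap >= undo_sd * sigma)) return(bks)
    bks <- bks[-which.min(gap)]
    if (!length(bks)) return(bks)
  }
}

.assemble_segments <- function(series, bks) {
  n <- nrow(series)
  edges <- c(0L, bks, n)
  first <- edges[-length(edges)] + 1L
  last <- edges[-1L]
  # boundaries at first-marker positions; tiling [pos[1]-1, pos[n])
  starts <- series$pos[first] - 1
  ends <- c(series$pos[first[-1]] - 1, series$pos[n])
  data.frame(chrom = series$chrom[1], start = starts, end = ends,
             n_markers = last - first + 1L,
             mean_cn = vapply(seq_along(first), function(p) {
               mean(series$cn[first[p]:last[p]])
             }, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Segment every sample/chromosome series in a marker table
#'
#' @param markers data.frame `sample, chrom, pos, cn` (multiple samples).
#' @param params A [cbs_params()] object.
#' @param seed Integer seed; series are processed in deterministic
#'   (sample, chromosome) order under one RNG stream, so identical inputs
#'   give identical output.
#' @return SEG-shaped data.frame `sample, chrom, start, end, n_markers,
#'   mean_cn`.
#' @export
segment_profiles <- function(markers, params = cbs_params(), seed = 1L) {
  stop_if(!all(c("sample", "chrom", "pos", "cn") %in% names(markers)),
          "markers needs columns sample, chrom, pos, cn")
  set.seed(as.integer(seed))
  samples <- unique(markers$sample)
  chroms <- chrom_order(markers$chrom)
  out <- list()
  for (s in samples) {
    for (ch in chroms) {
      ser <- markers[markers$sample == s & markers$chrom == ch, , drop = FALSE]
      if (!nrow(ser)) next
      ser <- ser[order(ser$pos), ]
      seg <- cbs_segment(ser[, c("chrom", "pos", "cn")], params)
      seg <- cbind(sample = s, seg, stringsAsFactors = FALSE)
      out[[length(out) + 1]] <- seg
    }
  }
  do.call(rbind, out)
}

#' Per-sample alteration burden summary
#'
#' Counts gained/lost segments and the fraction of the profiled genome they
#' cover, per sample. Fractions are summed altered bp over total profiled
#' bp (the span tiled by the sample's segments).
#'
#' @param segments State-called segments: `sample, chrom, start, end,
#'   n_markers, mean_cn, state` (see [call_state()]).
#' @return data.frame `sample, n_gain, n_loss, gain_fraction, loss_fraction`.
#' @export
summarise_profile <- function(segments) {
  stop_if(!("state" %in% names(segments)),
          "segments must be state-called (run call_state first)")
  res <- lapply(split(segments, segments$sample), function(sg) {
    len <- sg$end - sg$start
    tot <- sum(len)
    data.frame(sample = sg$sample[1],
               n_gain = sum(sg$state == "gain"),
               n_loss = sum(sg$state == "loss"),
               gain_fraction = sum(len[sg$state == "gain"]) / tot,
               loss_fraction = sum(len[sg$state == "loss"]) / tot,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
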