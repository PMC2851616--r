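# Recurrent-gain region discovery: segment state calls, breakpoint-sweep
# frequency track, frequent-region extraction and cytoband collapsing.

#' State-call thresholds
#'
#' Absolute copy-number cutoffs for calling a segment gained or lost
#' (diploid = 2): gain above 2.5 copies, loss below 1.5 copies.
#'
#' @param gain_cutoff Copy number a segment mean must exceed to be a gain.
#' @param loss_cutoff Copy number a segment mean must fall below to be a loss.
#' @return A `state_thresholds` list.
#' @export
state_thresholds <- function(gain_cutoff = 2.5, loss_cutoff = 1.5) {
  stop_if(!(loss_cutoff < 2 && 2 < gain_cutoff),
          "need loss_cutoff < 2 < gain_cutoff")
  structure(list(gain_cutoff = gain_cutoff, loss_cutoff = loss_cutoff),
            class = "state_thresholds")
}

#' Call gain/loss/neutral states on segments
#'
#' @param segments Segment data.frame with a `mean_cn` column, or a bare
#'   numeric vector of segment means.
#' @param thresholds A [state_thresholds()] object.
#' @return The input with a `state` column added (or a character vector for
#'   vector input): `"gain"` iff `mean_cn > gain_cutoff`, `"loss"` iff
#'   `mean_cn < loss_cutoff`, else `"neutral"`.
#' @export
call_state <- function(segments, thresholds = state_thresholds()) {
  cn <- if (is.data.frame(segments)) segments$mean_cn else segments
  stop_if(any(!is.finite(cn)), "segment means must be finite")
  st <- ifelse(cn > thresholds$gain_cutoff, "gain",
               ifelse(cn < thresholds$loss_cutoff, "loss", "neutral"))
  if (is.data.frame(segments)) {
    segments$state <- st
    segments
  } else {
    st
  }
}

#' Build a per-base alteration frequency track by breakpoint sweep
#'
#' For every genomic position, counts the samples whose covering segment is
#' gained (and lost). Implemented as a sweep over the union of segment
#' breakpoints, which equals per-base counting everywhere.
#'
#' @param segments State-called segments (`sample, chrom, start, end, state`).
#' @param n_samples Cohort denominator; defaults to the number of distinct
#'   samples present.
#' @return data.frame `chrom, start, end, gain_count, loss_count, n_samples`
#'   whose intervals tile each chromosome's analysed span.
#' @export
build_frequency_track <- function(segments, n_samples = NULL) {
  if (!nrow(segments)) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      gain_count = integer(), loss_count = integer(),
                      n_samples = integer(), stringsAsFactors = FALSE))
  }
  stop_if(!("state" %in% names(segments)), "segments must be state-called")
  check_intervals(segments, "segments")
  n_samples <- n_samples %||% length(unique(segments$sample))
  out <- lapply(split(segments, segments$chrom), function(sg) {
    bks <- sort(unique(c(sg$start, sg$end)))
    starts <- bks[-length(bks)]
    ends <- bks[-1]
    count_state <- function(state) {
      delta <- numeric(length(bks))
      sel <- sg[sg$state == state, , drop = FALSE]
      if (nrow(sel)) {
        si <- match(sel$start, bks)
        ei <- match(sel$end, bks)
        for (r in seq_along(si)) {
          delta[si[r]] <- delta[si[r]] + 1
          delta[ei[r]] <- delta[ei[r]] - 1
        }
      }
      cumsum(delta)[-length(bks)]
    }
    data.frame(chrom = sg$chrom[1], start = starts, end = ends,
               gain_count = as.integer(count_state("gain")),
               loss_count = as.integer(count_state("loss")),
               n_samples = n_samples, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, chrom_order(res$chrom)), res$start), ]
  rownames(res) <- NULL
  res
}

#' Extract maximal intervals of frequent gain
#'
#' Keeps track intervals whose gain frequency reaches `min_freq`
#' (inclusive) and merges adjacent qualifying intervals into maximal runs.
#'
#' @param track A frequency track from [build_frequency_track()].
#' @param min_freq Minimum gain frequency, compared inclusively (>=).
#' @return data.frame `chrom, start, end, frequency` where `frequency` is
#'   the peak per-base gain frequency inside the merged interval.
#' @export
frequent_gain_regions <- function(track, min_freq = 0.40) {
  stop_if(min_freq <= 0 || min_freq > 1, "min_freq must be in (0, 1]")
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      frequency = numeric(), stringsAsFactors = FALSE)
  if (!nrow(track)) return(empty)
  q <- track[track$gain_count / track$n_samples >= min_freq, , drop = FALSE]
  if (!nrow(q)) return(empty)
  out <- lapply(split(q, q$chrom), function(tq) {
    tq <- tq[order(tq$start), ]
    run <- cumsum(c(1, as.integer(tq$start[-1] != tq$end[-nrow(tq)])))
    do.call(rbind, lapply(split(tq, run), function(piece) {
      data.frame(chrom = piece$chrom[1], start = min(piece$start),
                 end = max(piece$end),
                 frequency = max(piece$gain_count / piece$n_samples),
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, chrom_order(res$chrom)), res$start), ]
  rownames(res) <- NULL
  res
}

#' Collapse frequent-gain intervals by cytoband
#'
#' Intervals lying wholly inside one cytoband are grouped per band and the
#' collapsed region spans the members' minimum start to maximum end.
#' Intervals spanning a band boundary are grouped separately under a
#' joined tag (e.g. `"q26.1-q26.2"`) and never merged into either single
#' band's group. Region ids are `<chrom>_<ordinal>` in genomic order (the
#' chromosome label without its "chr" prefix).
#'
#' @param intervals data.frame `chrom, start, end` (optionally `frequency`).
#' @param cytobands Cytoband table `chrom, start, end, band` (0-based
#'   half-open), e.g. from [read_cytoband()] or [make_cytobands()].
#' @return data.frame `region_id, chrom, start, end, cytoband, n_members,
#'   frequency`, with a `members` list-column of member intervals.
#' @export
collapse_by_cytoband <- function(intervals, cytobands) {
  if (!nrow(intervals)) {
    return(data.frame(region_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      cytoband = character(), n_members = integer(),
                      frequency = numeric(), stringsAsFactors = FALSE))
  }
  check_intervals(intervals, "intervals")
  check_intervals(cytobands, "cytobands")
  if (!("frequency" %in% names(intervals))) intervals$frequency <- NA_real_

  tag <- character(nrow(intervals))
  for (r in seq_len(nrow(intervals))) {
    b <- cytobands[cytobands$chrom == intervals$chrom[r] &
                     cytobands$start < intervals$end[r] &
                     cytobands$end > intervals$start[r], , drop = FALSE]
    stop_if(!nrow(b), "interval ", intervals$chrom[r], ":[",
            intervals$start[r], ",", intervals$end[r],
            ") overlaps no cytoband")
    b <- b[order(b$start), ]
    tag[r] <- paste(b$band, collapse = "-")
  }

  key <- paste(intervals$chrom, tag)
  groups <- split(seq_len(nrow(intervals)), key)
  regions <- do.call(rbind, lapply(groups, function(idx) {
    mem <- intervals[idx, , drop = FALSE]
    data.frame(chrom = mem$chrom[1], start = min(mem$start),
               end = max(mem$end), cytoband = tag[idx[1]],
               n_members = length(idx),
               frequency = if (all(is.na(mem$frequency))) NA_real_
                           else max(mem$frequency, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  members <- lapply(groups, function(idx) {
    intervals[idx, c("chrom", "start", "end"), drop = FALSE]
  })
  ord <- order(match(regions$chrom, chrom_order(regions$chrom)), regions$start,
               regions$end)
  regions <- regions[ord, ]
  members <- members[ord]
  ordinal <- stats::ave(seq_len(nrow(regions)), regions$chrom,
                        FUN = seq_along)
  regions <- cbind(
    region_id = paste0(sub("^chr", "", regions$chrom), "_", ordinal),
    regions, stringsAsFactors = FALSE)
  regions$members <- I(unname(members))
  rownames(regions) <- NULL
  regions
}
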