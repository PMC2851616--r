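# Germline copy-number polymorphism (CNP) detection from normal profiles
# and subtraction of CNPs from candidate regions.

#' Detect germline CNPs from normal-sample profiles
#'
#' Segments the normal profiles, calls gain/loss states with the same
#' thresholds used for tumours, counts altered (gain or loss pooled, since
#' CNPs commonly show both states at one locus) samples per base, and emits
#' maximal intervals altered in strictly more than `cnp_freq` of normals.
#'
#' @param normal_markers data.frame `sample, chrom, pos, cn` for the normal
#'   samples, or NULL if `segments` is supplied.
#' @param cnp_freq Population-frequency cutoff; the comparison is strict
#'   (`> cnp_freq`), so 3 of 57 normals (5.26%) qualifies at the default
#'   0.05 and 2 of 57 (3.5%) does not.
#' @param cbs A [cbs_params()] object for segmenting the normals.
#' @param thresholds A [state_thresholds()] object.
#' @param seed Seed for segmentation permutations.
#' @param mode `"pooled"` (default) counts a normal as altered if it shows
#'   either gain or loss; `"separate"` requires gain alone or loss alone to
#'   exceed `cnp_freq`.
#' @param segments Optional pre-computed state-called normal segments
#'   (skips segmentation).
#' @param n_normals Cohort denominator; defaults to the samples present.
#' @return data.frame `chrom, start, end, n_normals_altered, n_normals,
#'   type` with `type` in gain/loss/both.
#' @export
detect_cnps <- function(normal_markers, cnp_freq = 0.05, cbs = cbs_params(),
                        thresholds = state_thresholds(), seed = 1L,
                        mode = c("pooled", "separate"), segments = NULL,
                        n_normals = NULL) {
  mode <- match.arg(mode)
  if (is.null(segments)) {
    stop_if(is.null(normal_markers) || !nrow(normal_markers),
            "no normal samples: cannot detect CNPs")
    segments <- call_state(segment_profiles(normal_markers, cbs, seed),
                           thresholds)
  }
  nn <- n_normals %||% length(unique(segments$sample))
  stop_if(nn == 0, "no normal samples: cannot detect CNPs")
  if (nn < 10) {
    warning("only ", nn, " normal samples; CNP frequencies are unstable ",
            "below ~10 normals")
  }
  track <- build_frequency_track(segments, n_samples = nn)
  if (!nrow(track)) return(.empty_cnps())

  altered <- track$gain_count + track$loss_count
  qual <- if (mode == "pooled") {
    altered / nn > cnp_freq
  } else {
    track$gain_count / nn > cnp_freq | track$loss_count / nn > cnp_freq
  }
  q <- track[qual, , drop = FALSE]
  if (!nrow(q)) return(.empty_cnps())
  out <- lapply(split(q, q$chrom), function(tq) {
    tq <- tq[order(tq$start), ]
    run <- cumsum(c(1, as.integer(tq$start[-1] != tq$end[-nrow(tq)])))
    do.call(rbind, lapply(split(tq, run), function(piece) {
      g <- max(piece$gain_count); l <- max(piece$loss_count)
      data.frame(chrom = piece$chrom[1], start = min(piece$start),
                 end = max(piece$end),
                 n_normals_altered = max(piece$gain_count + piece$loss_count),
                 n_normals = nn,
                 type = if (g > 0 && l > 0) "both" else if (g > 0) "gain" else "loss",
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, chrom_order(res$chrom)), res$start), ]
  rownames(res) <- NULL
  res
}

.empty_cnps <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             n_normals_altered = integer(), n_normals = integer(),
             type = character(), stringsAsFactors = FALSE)
}

#' Subtract one CNP interval from one candidate region
#'
#' Splitting rules: a CNP strictly interior to the region splits it into a
#' left and a right fragment; a CNP overlapping one edge trims that edge; a
#' CNP covering the whole region removes it; a non-overlapping CNP leaves
#' it unchanged. No minimum fragment length is imposed.
#'
#' @param region One-row data.frame (or list) with `chrom, start, end`.
#' @param cnp One-row data.frame (or list) with `chrom, start, end`.
#' @return data.frame of 0, 1 or 2 rows `chrom, start, end`.
#' @export
subtract_cnp <- function(region, cnp) {
  rs <- region$start; re <- region$end
  if (region$chrom != cnp$chrom || cnp$end <= rs || cnp$start >= re) {
    return(data.frame(chrom = region$chrom, start = rs, end = re,
                      stringsAsFactors = FALSE))
  }
  pieces <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), stringsAsFactors = FALSE)
  if (cnp$start > rs) {
    pieces <- rbind(pieces, data.frame(chrom = region$chrom, start = rs,
                                       end = cnp$start, stringsAsFactors = FALSE))
  }
  if (cnp$end < re) {
    pieces <- rbind(pieces, data.frame(chrom = region$chrom, start = cnp$end,
                                       end = re, stringsAsFactors = FALSE))
  }
  pieces
}

#' Subtract all CNPs from all candidate regions
#'
#' Applies [subtract_cnp()] iteratively over every CNP (the result is
#' order-independent: it equals the interval difference region minus the
#' union of CNPs). Fragments inherit their parent's metadata; when a region
#' splits, fragment ids extend the parent id (`"3_10.1"`, `"3_10.2"`).
#'
#' @param regions Collapsed-region data.frame (needs `region_id, chrom,
#'   start, end`; other columns are carried through).
#' @param cnps CNP calls (`chrom, start, end`), e.g. from [detect_cnps()].
#' @return data.frame like `regions` plus `parent_region_id`; regions fully
#'   covered by CNPs are dropped.
#' @export
subtract_cnps <- function(regions, cnps) {
  if (!nrow(regions)) return(cbind(regions, parent_region_id = character(0)))
  keep_cols <- setdiff(names(regions), c("start", "end", "members"))
  out <- list()
  for (r in seq_len(nrow(regions))) {
    pieces <- data.frame(chrom = regions$chrom[r], start = regions$start[r],
                         end = regions$end[r], stringsAsFactors = FALSE)
    if (!is.null(cnps) && nrow(cnps)) {
      for (k in seq_len(nrow(cnps))) {
        if (!nrow(pieces)) break
        pieces <- do.call(rbind, lapply(seq_len(nrow(pieces)), function(p) {
          subtract_cnp(pieces[p, ], cnps[k, ])
        }))
      }
    }
    if (is.null(pieces) || !nrow(pieces)) next
    pieces <- pieces[order(pieces$start), , drop = FALSE]
    meta <- regions[rep(r, nrow(pieces)), keep_cols, drop = FALSE]
    meta$start <- pieces$start
    meta$end <- pieces$end
    meta$parent_region_id <- regions$region_id[r]
    if (nrow(pieces) > 1) {
      meta$region_id <- paste0(regions$region_id[r], ".", seq_len(nrow(pieces)))
    }
    out[[length(out) + 1]] <- meta
  }
  if (!length(out)) {
    res <- regions[0, keep_cols, drop = FALSE]
    res$start <- numeric(0); res$end <- numeric(0)
    res$parent_region_id <- character(0)
    return(res)
  }
  res <- do.call(rbind, out)
  res <- res[, c("region_id", "chrom", "start", "end",
                 setdiff(names(res), c("region_id", "chrom", "start", "end")))]
  rownames(res) <- NULL
  res
}
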