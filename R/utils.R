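# Internal helpers shared across modules. Intervals are 0-based half-open.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

#' Order chromosome labels naturally (chr1, chr2, ..., chr10, chrX)
#' @noRd
chrom_order <- function(chroms) {
  u <- unique(as.character(chroms))
  key <- sub("^chr", "", u)
  num <- suppressWarnings(as.integer(key))
  rank <- ifelse(is.na(num), 1000L + match(key, sort(unique(key[is.na(num)]))), num)
  u[order(rank, u)]
}

#' Normalise chromosome naming to the "chrN" convention
#' @noRd
norm_chrom <- function(chroms) {
  x <- as.character(chroms)
  ifelse(grepl("^chr", x), x, paste0("chr", x))
}

# bp overlap of [s1,e1) with [s2,e2), vectorised
overlap_bp <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# validate an interval table with columns chrom/start/end
check_intervals <- function(df, what = "interval table") {
  stop_if(!all(c("chrom", "start", "end") %in% names(df)),
          what, " must have columns chrom, start, end")
  stop_if(any(!is.finite(df$start)) || any(!is.finite(df$end)),
          what, " has non-finite coordinates")
  stop_if(any(df$end <= df$start), what, " has intervals with end <= start")
  invisible(df)
}

# deterministic child seed for stage `k` of a run seeded with `seed`
child_seed <- function(seed, k) {
  (as.integer(seed) %% 2147480000L + 9973L * as.integer(k)) %% 2147483647L
}
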