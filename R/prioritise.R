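# High-amplitude amplicon detection and the two-branch candidate driver
# prioritisation cascade.

#' Detect high-amplitude amplicon regions
#'
#' Builds the per-base count of samples covered by a segment of mean copy
#' number at least `amp_cn` and emits maximal intervals where that count
#' reaches `amp_support` samples.
#'
#' @param segments Multi-sample segment table (`sample, chrom, start, end,
#'   mean_cn`).
#' @param amp_cn Minimum segment mean copy number (inclusive, default 5).
#' @param amp_support Minimum number of supporting samples (inclusive,
#'   default 5).
#' @return data.frame `chrom, start, end, n_samples_supporting` with a
#'   `samples` list-column of the supporting sample ids.
#' @export
high_amplitude_regions <- function(segments, amp_cn = 5, amp_support = 5) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_samples_supporting = integer(),
                      stringsAsFactors = FALSE)
  amp <- segments[segments$mean_cn >= amp_cn, , drop = FALSE]
  if (!nrow(amp)) { empty$samples <- I(list()); return(empty) }
  amp$state <- "gain"
  track <- build_frequency_track(amp, n_samples = 1L)
  q <- track[track$gain_count >= amp_support, , drop = FALSE]
  if (!nrow(q)) { empty$samples <- I(list()); return(empty) }
  out <- lapply(split(q, q$chrom), function(tq) {
    tq <- tq[order(tq$start), ]
    run <- cumsum(c(1, as.integer(tq$start[-1] != tq$end[-nrow(tq)])))
    do.call(rbind, lapply(split(tq, run), function(piece) {
      data.frame(chrom = piece$chrom[1], start = min(piece$start),
                 end = max(piece$end),
                 n_samples_supporting = max(piece$gain_count),
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, out)
  res <- res[order(match(res$chrom, chrom_order(res$chrom)), res$start), ]
  res$samples <- I(lapply(seq_len(nrow(res)), function(r) {
    sort(unique(amp$sample[amp$chrom == res$chrom[r] &
                             amp$start < res$end[r] &
                             amp$end > res$start[r]]))
  }))
  rownames(res) <- NULL
  res
}

#' Genes within high-amplitude regions (with flank)
#'
#' @param ha_regions Output of [high_amplitude_regions()].
#' @param genes Gene annotation (`gene, chrom, start, end`).
#' @param flank Flank in bp added to each gene before the overlap test
#'   (default 10 kb), so a gene up to 10 kb outside a region boundary is
#'   still assigned to it.
#' @return Character vector of gene ids.
#' @export
genes_in_high_amp <- function(ha_regions, genes, flank = 1e4) {
  if (!nrow(ha_regions)) return(character())
  hit <- rep(FALSE, nrow(genes))
  for (r in seq_len(nrow(ha_regions))) {
    hit <- hit | (genes$chrom == ha_regions$chrom[r] &
                    genes$start - flank < ha_regions$end[r] &
                    genes$end + flank > ha_regions$start[r])
  }
  genes$gene[hit]
}

#' Gene-level gain frequency across the cohort
#'
#' Fraction of cohort samples whose flanked gene copy number exceeds the
#' state gain cutoff. Samples with missing copy number count against the
#' denominator.
#'
#' @param gene_cn Genes x samples copy-number matrix (see
#'   [gene_cn_matrix()]).
#' @param gain_cutoff State gain cutoff (default 2.5, strict >).
#' @param n_samples Denominator; defaults to the number of columns.
#' @return Named numeric vector of frequencies.
#' @export
gene_gain_frequency <- function(gene_cn, gain_cutoff = 2.5, n_samples = NULL) {
  n <- n_samples %||% ncol(gene_cn)
  rowSums(gene_cn > gain_cutoff, na.rm = TRUE) / n
}

#' Prioritisation cascade configuration
#'
#' Branch A selects differentially expressed genes in frequently gained
#' regions with strong over-expression (`logFC > logfc_min` or
#' `r > r_min`), then applies per-chromosome gain-frequency cuts. Branch B
#' selects genes in high-amplitude amplicons with `r` or `logFC` above its
#' (laxer) cuts. The final list is the union.
#'
#' @param freq_min Baseline gain-frequency cut (inclusive) and the fallback
#'   for chromosomes absent from `per_chrom_freq`.
#' @param logfc_min_A,r_min_A Branch A cuts (strict >).
#' @param per_chrom_freq Named per-chromosome frequency cuts (inclusive >=).
#' @param amp_cn,amp_support High-amplitude definition for branch B.
#' @param r_min_B,logfc_min_B Branch B cuts (strict >).
#' @param de_alpha Adjusted-p cutoff defining "differentially expressed"
#'   (strict <).
#' @param gene_flank Gene flank in bp.
#' @return A `priority_config` list with `branchA`, `branchB`, `gene_flank`.
#' @export
priority_config <- function(freq_min = 0.40, logfc_min_A = 0.7, r_min_A = 0.7,
                            per_chrom_freq = c(chr8 = 0.60, chr3 = 0.50,
                                               chr20 = 0.42),
                            amp_cn = 5, amp_support = 5, r_min_B = 0.6,
                            logfc_min_B = 0.6, de_alpha = 0.05,
                            gene_flank = 1e4) {
  vals <- c(freq_min, logfc_min_A, r_min_A, per_chrom_freq, amp_cn,
            amp_support, r_min_B, logfc_min_B, de_alpha)
  stop_if(any(!is.finite(vals)), "all cutoffs must be finite")
  stop_if(any(c(freq_min, per_chrom_freq) <= 0) ||
            any(c(freq_min, per_chrom_freq) > 1),
          "frequency cuts must be in (0, 1]")
  structure(list(
    branchA = list(freq_min = freq_min, logfc_min = logfc_min_A,
                   r_min = r_min_A, per_chrom_freq = per_chrom_freq),
    branchB = list(amp_cn = amp_cn, amp_support = amp_support,
                   r_min = r_min_B, logfc_min = logfc_min_B),
    de_alpha = de_alpha, gene_flank = gene_flank), class = "priority_config")
}

#' Collapse probeset-level integration results to gene level
#'
#' A gene satisfies a cut if any of its probesets does, so the gene-level
#' summary takes the minimum adjusted p, the maximum logFC and the maximum
#' correlation over the gene's probesets.
#'
#' @param results Probeset-level table from [integrate_regions()].
#' @return data.frame `gene, chrom, p_adj, logFC, r` (one row per gene).
#' @export
collapse_probesets <- function(results) {
  rows <- lapply(split(results, results$gene), function(g) {
    data.frame(gene = g$gene[1], chrom = g$chrom[1],
               p_adj = if (all(is.na(g$p_adj))) NA_real_ else
                 min(g$p_adj, na.rm = TRUE),
               logFC = if (all(is.na(g$logFC))) NA_real_ else
                 max(g$logFC, na.rm = TRUE),
               r = if (all(is.na(g$r))) NA_real_ else max(g$r, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-branch candidate driver-gene prioritisation
#'
#' Branch A (high frequency): differentially expressed (`p_adj < de_alpha`)
#' AND (`logFC > logfc_min` OR `r > r_min`) AND gene gain frequency at or
#' above the chromosome's cut (falling back to `freq_min` with a warning
#' for chromosomes without a configured cut). Branch B (high amplitude):
#' membership in the high-amplitude gene set AND (`r > r_min` OR
#' `logFC > logfc_min`). The final list is the union, deduplicated by gene.
#' `NA` values fail every cut.
#'
#' @param gene_stats Gene-level table (`gene, chrom, p_adj, logFC, r`), e.g.
#'   from [collapse_probesets()]; genes without an identifier are dropped.
#' @param gain_freq Named vector of gene gain frequencies
#'   ([gene_gain_frequency()]).
#' @param high_amp_genes Character vector from [genes_in_high_amp()].
#' @param config A [priority_config()] object.
#' @return data.frame with one row per gene: per-criterion flags
#'   (`de, logfcA, rA, chrom_freq, highamp, highamp_r, highamp_logfc`),
#'   branch memberships (`branchA, branchB`) and the `final` flag.
#' @export
prioritise <- function(gene_stats, gain_freq, high_amp_genes = character(),
                       config = priority_config()) {
  stop_if(!inherits(config, "priority_config"), "config must be a priority_config")
  gs <- gene_stats[!is.na(gene_stats$gene) & gene_stats$gene != "", ,
                   drop = FALSE]
  a <- config$branchA; b <- config$branchB
  freq <- unname(gain_freq[gs$gene])

  cut <- a$per_chrom_freq[gs$chrom]
  miss <- is.na(cut)
  if (any(miss)) {
    warning("no per-chromosome frequency cut for ",
            paste(unique(gs$chrom[miss]), collapse = ", "),
            "; falling back to freq_min = ", a$freq_min)
    cut[miss] <- a$freq_min
  }

  de <- !is.na(gs$p_adj) & gs$p_adj < config$de_alpha
  logfcA <- !is.na(gs$logFC) & gs$logFC > a$logfc_min
  rA <- !is.na(gs$r) & gs$r > a$r_min
  chrom_freq <- !is.na(freq) & freq >= unname(cut)
  branchA <- de & (logfcA | rA) & chrom_freq

  highamp <- gs$gene %in% high_amp_genes
  highamp_r <- !is.na(gs$r) & gs$r > b$r_min
  highamp_logfc <- !is.na(gs$logFC) & gs$logFC > b$logfc_min
  branchB <- highamp & (highamp_r | highamp_logfc)

  out <- data.frame(gene = gs$gene, chrom = gs$chrom,
                    gain_freq = freq, p_adj = gs$p_adj, logFC = gs$logFC,
                    r = gs$r, de = de, logfcA = logfcA, rA = rA,
                    chrom_freq = chrom_freq, highamp = highamp,
                    highamp_r = highamp_r, highamp_logfc = highamp_logfc,
                    branchA = branchA, branchB = branchB,
                    final = branchA | branchB, stringsAsFactors = FALSE)
  out <- out[!duplicated(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rule-replay audit of a candidate table
#'
#' Recomputes branch and final membership from the per-criterion flags and
#' checks the stored memberships agree: every final gene is justified by a
#' complete branch path and no justified gene is missing.
#'
#' @param candidates Output of [prioritise()].
#' @return TRUE if consistent, otherwise FALSE with attribute `"bad"`
#'   listing offending genes.
#' @export
audit_candidates <- function(candidates) {
  withA <- candidates$de & (candidates$logfcA | candidates$rA) &
    candidates$chrom_freq
  withB <- candidates$highamp & (candidates$highamp_r | candidates$highamp_logfc)
  ok <- identical(unname(withA), unname(candidates$branchA)) &&
    identical(unname(withB), unname(candidates$branchB)) &&
    identical(unname(withA | withB), unname(candidates$final))
  if (!ok) {
    bad <- candidates$gene[withA != candidates$branchA |
                             withB != candidates$branchB |
                             (withA | withB) != candidates$final]
    attr(ok, "bad") <- bad
  }
  ok
}
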