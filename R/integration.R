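# Copy-number / expression integration: gene-level CN extraction, G/N group
# assignment, empirical-Bayes moderated t differential expression with a
# histotype covariate, BH adjustment, and CN/expression correlation.

#' Length-weighted gene copy number from one sample's segments
#'
#' Extends the gene interval by `flank` on both sides (genes can be smaller
#' than the marker spacing) and returns the bp-weighted mean of the segment
#' means overlapping the flanked interval.
#'
#' @param segments One sample's segments (`chrom, start, end, mean_cn`).
#' @param gene List or one-row data.frame with `chrom, start, end`.
#' @param flank Flank in bp added to both ends (default 10 kb).
#' @return Weighted-mean copy number, or `NA` if no segment overlaps.
#' @export
gene_copy_number <- function(segments, gene, flank = 1e4) {
  qs <- max(0, gene$start - flank)
  qe <- gene$end + flank
  sg <- segments[segments$chrom == gene$chrom & segments$start < qe &
                   segments$end > qs, , drop = FALSE]
  if (!nrow(sg)) return(NA_real_)
  w <- overlap_bp(sg$start, sg$end, qs, qe)
  sum(w * sg$mean_cn) / sum(w)
}

#' Gene (or region) copy-number matrix across samples
#'
#' Vectorised [gene_copy_number()] over every gene and sample.
#'
#' @param segments Multi-sample segment table (`sample, chrom, start, end,
#'   mean_cn`).
#' @param genes Interval table with rownames or a `gene`/`region_id` column
#'   used as row labels.
#' @param flank Flank in bp (use 0 for region-level copy number).
#' @return Numeric matrix intervals x samples; `NA` where nothing overlaps.
#' @export
gene_cn_matrix <- function(segments, genes, flank = 1e4) {
  check_intervals(genes, "genes")
  ids <- genes$gene %||% genes$region_id %||% rownames(genes)
  samples <- unique(segments$sample)
  m <- matrix(NA_real_, nrow = nrow(genes), ncol = length(samples),
              dimnames = list(ids, samples))
  qs <- pmax(0, genes$start - flank)
  qe <- genes$end + flank
  for (s in samples) {
    sg_all <- segments[segments$sample == s, , drop = FALSE]
    for (ch in unique(genes$chrom)) {
      gi <- which(genes$chrom == ch)
      sg <- sg_all[sg_all$chrom == ch, , drop = FALSE]
      if (!nrow(sg) || !length(gi)) next
      ov <- outer(qe[gi], sg$end, pmin) - outer(qs[gi], sg$start, pmax)
      ov[ov < 0] <- 0
      tot <- rowSums(ov)
      val <- as.vector(ov %*% sg$mean_cn) / tot
      val[tot == 0] <- NA_real_
      m[gi, s] <- val
    }
  }
  m
}

#' Assign samples to gain (G) and neutral (N) groups for one region
#'
#' G holds samples whose region copy number exceeds `gain_cutoff` (default
#' strictly more than 3 copies); N holds samples in the neutral band
#' (1.5--2.5 copies inclusive). Everything else is excluded with a reason:
#' `loss` (< 1.5), `intermediate` (between the neutral band and the gain
#' cutoff) or `missing` (no copy-number value).
#'
#' @param region_cn Named numeric vector of per-sample region copy number.
#' @param gain_cutoff Copy number a sample must exceed to enter G.
#' @param neutral_range Two-element inclusive copy-number band for N.
#' @return data.frame `sample, cn, group, reason` where `group` is
#'   `"G"`, `"N"` or `"excluded"`.
#' @export
assign_groups <- function(region_cn, gain_cutoff = 3.0,
                          neutral_range = c(1.5, 2.5)) {
  stop_if(is.null(names(region_cn)), "region_cn must be named by sample")
  stop_if(neutral_range[2] > gain_cutoff,
          "neutral range must not extend past the gain cutoff")
  grp <- rep("excluded", length(region_cn))
  reason <- rep(NA_character_, length(region_cn))
  grp[!is.na(region_cn) & region_cn > gain_cutoff] <- "G"
  inN <- !is.na(region_cn) & region_cn >= neutral_range[1] &
    region_cn <= neutral_range[2]
  grp[inN] <- "N"
  reason[is.na(region_cn)] <- "missing"
  reason[!is.na(region_cn) & region_cn < neutral_range[1]] <- "loss"
  reason[!is.na(region_cn) & region_cn > neutral_range[2] &
           region_cn <= gain_cutoff] <- "intermediate"
  data.frame(sample = names(region_cn), cn = unname(region_cn), group = grp,
             reason = reason, stringsAsFactors = FALSE)
}

#' Invert the trigamma function
#'
#' Newton iteration solving `trigamma(x) = y`, used by the moderation-prior
#' moment equations.
#' @param y Positive values.
#' @return x with `trigamma(x) = y`; `Inf` for `y <= 0`.
#' @export
trigamma_inverse <- function(y) {
  x <- ifelse(y > 1e7, 1 / sqrt(y), 0.5 + 1 / y)
  out <- x
  ok <- is.finite(y) & y > 0
  out[!ok] <- ifelse(y[!ok] <= 0, Inf, NA)
  x <- x[ok]
  yy <- y[ok]
  if (length(x)) {
    for (iter in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yy) / psigamma(x, deriv = 2)
      x <- x + dif
      if (max(-dif / x) < 1e-10) break
    }
    out[ok] <- x
  }
  out
}

#' Estimate the variance-moderation prior (d0, s0^2) by moment matching
#'
#' Matches the first two moments of `log(s2)` against the scaled-inverse-
#' chi-square model for gene-wise residual variances: with
#' `e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)`, the prior satisfies
#' `E[e] = log(s0^2) + digamma(d0/2) - log(d0/2)` and
#' `Var[e] = trigamma(d0/2) + trigamma(d_g/2)`. `d0 = Inf` (no excess
#' variance dispersion) is returned when the moment equation has no
#' positive solution.
#'
#' @param s2 Gene-wise residual variances.
#' @param df Residual degrees of freedom (scalar or per gene).
#' @return list `d0`, `s0_sq`.
#' @export
fit_moderation_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  stop_if(sum(ok) < 2, "need at least 2 positive variances to fit the prior")
  if (any(!ok)) {
    warning(sum(!ok), " gene(s) with zero/invalid residual variance ",
            "excluded from prior estimation")
  }
  s2 <- s2[ok]; df <- df[ok]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion beyond chi-square sampling noise: variances are
    # exchangeable and the scale is their pooled mean
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated t-test for differential expression between G and N groups
#'
#' Fits, per probeset, the linear model `expression ~ group + histotype` by
#' least squares; the group coefficient is the log2 fold change G vs N.
#' Residual variances are shrunk across probesets by empirical Bayes: the
#' prior `(d0, s0^2)` is estimated by [fit_moderation_prior()] (or supplied),
#' the posterior variance is `(d0*s0^2 + d*s2) / (d0 + d)`, and the
#' moderated t has `d0 + d` degrees of freedom. Raw p-values are adjusted
#' by [bh_adjust()].
#'
#' Histotype levels with fewer than 2 samples among the used (G plus N)
#' samples are collapsed into `"other"`; if only one level remains the
#' covariate is dropped. A probeset with zero residual variance and zero
#' fold change gets t = 0, p = 1 by convention.
#'
#' @param expr Probesets x samples log2 matrix (column names = samples).
#' @param groups A data.frame from [assign_groups()], or a list with
#'   elements `G` and `N` of sample ids.
#' @param histotype Named character vector of histotypes (NULL to omit the
#'   covariate).
#' @param prior Optional list `d0, s0_sq` overriding the estimated prior;
#'   `d0 = 0` reproduces the ordinary (unmoderated) covariate-adjusted
#'   t-test, `d0 = Inf` fully pools variances to `s0_sq`.
#' @return list with `table` (`probeset, logFC, t, p_raw, p_adj, n_G, n_N`),
#'   `prior`, `s2` (residual variances) and `df` (residual df).
#' @export
moderated_t_test <- function(expr, groups, histotype = NULL, prior = NULL) {
  if (is.data.frame(groups)) {
    G <- groups$sample[groups$group == "G"]
    N <- groups$sample[groups$group == "N"]
  } else {
    G <- groups$G; N <- groups$N
  }
  G <- intersect(G, colnames(expr))
  N <- intersect(N, colnames(expr))
  stop_if(length(G) < 2 || length(N) < 2,
          "need at least 2 samples in each of G (", length(G), ") and N (",
          length(N), ")")
  used <- c(G, N)
  grp <- factor(rep(c("G", "N"), c(length(G), length(N))), levels = c("N", "G"))

  if (!is.null(histotype)) {
    ht <- as.character(histotype[used])
    ht[is.na(ht)] <- "other"
    rare <- names(which(table(ht) < 2))
    ht[ht %in% rare] <- "other"
    if (length(unique(ht)) < 2) ht <- NULL
  } else {
    ht <- NULL
  }
  design <- if (is.null(ht)) {
    stats::model.matrix(~grp)
  } else {
    stats::model.matrix(~ grp + factor(ht))
  }
  y <- t(expr[, used, drop = FALSE])
  qrX <- qr(design)
  stop_if(qrX$rank < ncol(design), "design matrix is not full rank")
  coefs <- qr.coef(qrX, y)
  res <- y - design %*% coefs
  df_resid <- length(used) - qrX$rank
  stop_if(df_resid < 1, "zero residual degrees of freedom")
  s2 <- colSums(res^2) / df_resid
  logFC <- coefs["grpG", ]

  if (is.null(prior)) prior <- fit_moderation_prior(s2, df_resid)
  d0 <- prior$d0
  st2 <- if (is.infinite(d0)) {
    rep(prior$s0_sq, length(s2))
  } else {
    (d0 * prior$s0_sq + df_resid * s2) / (d0 + df_resid)
  }
  xtx_inv <- solve(crossprod(design))
  v <- xtx_inv["grpG", "grpG"] # unscaled variance of the group coefficient
  se <- sqrt(st2 * v)
  tstat <- ifelse(se > 0, logFC / se, ifelse(logFC == 0, 0, sign(logFC) * Inf))
  # total df cannot exceed what pooling every gene's residuals would give
  df_total <- min(d0 + df_resid, df_resid * length(s2))
  p <- 2 * pt(-abs(tstat), df = df_total)
  p[se == 0 & logFC == 0] <- 1

  list(table = data.frame(probeset = rownames(expr), logFC = unname(logFC),
                          t = unname(tstat), p_raw = unname(p),
                          p_adj = bh_adjust(unname(p)),
                          n_G = length(G), n_N = length(N),
                          stringsAsFactors = FALSE),
       prior = prior, s2 = unname(s2), df = df_resid)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `p_adj_(i) = min_{j >= i} ( m * p_(j) / j )` over the rank order, capped
#' at 1, returned in the original order. `NA` p-values propagate as `NA`
#' and are excluded from `m`.
#'
#' @param p Vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  stop_if(any(p[ok] < 0 | p[ok] > 1), "p-values must be in [0, 1]")
  m <- sum(ok)
  if (m == 0) return(out)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  out[ok] <- adj
  out
}

#' Pearson correlation of copy number with expression
#'
#' @param expr Numeric vector of log2 expression values.
#' @param cn Numeric vector of copy-number values, same samples.
#' @return list `r`, `p_raw` (two-sided, t-based) and `n` (complete pairs).
#'   `r` is `NA` when fewer than 3 complete pairs exist or either vector
#'   has zero variance.
#' @export
cn_expr_correlation <- function(expr, cn) {
  stop_if(length(expr) != length(cn), "expr and cn must have equal length")
  ok <- !is.na(expr) & !is.na(cn)
  n <- sum(ok)
  if (n < 3) return(list(r = NA_real_, p_raw = NA_real_, n = n))
  x <- expr[ok]; y <- cn[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, p_raw = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, p_raw = 0, n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_raw = 2 * pt(-abs(tstat), df = n - 2), n = n)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided unpaired t-test with the Welch-Satterthwaite degrees of
#' freedom.
#'
#' @param a,b Numeric vectors (each of length >= 2).
#' @return list `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  stop_if(length(a) < 2 || length(b) < 2, "each group needs >= 2 values")
  n1 <- length(a); n2 <- length(b)
  v1 <- var(a); v2 <- var(b)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    eq <- isTRUE(all.equal(mean(a), mean(b)))
    return(list(t = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                df = NA_real_, p = if (eq) 1 else 0))
  }
  tstat <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df = df))
}

#' Integrate copy number with expression over candidate regions
#'
#' For each region: derives per-sample region copy number (bp-weighted over
#' `[start, end)`), assigns G/N groups, tests region probesets for
#' differential expression with the moderated t (histotype covariate, BH
#' within region), and correlates each probeset's expression with its
#' gene's flanked copy number across all samples. Regions with fewer than
#' 2 samples in G or N are flagged untestable and skipped.
#'
#' The moderation prior is estimated per region when the region has at
#' least `min_genes_own_prior` probesets; smaller regions borrow a global
#' prior estimated from all regions' residual variances pooled (moment
#' matching is unstable on tiny gene sets).
#'
#' @param regions Region table (`region_id, chrom, start, end`).
#' @param segments Tumour segment table (`sample, chrom, start, end,
#'   mean_cn`).
#' @param expr Probesets x samples log2 expression matrix.
#' @param probe_map data.frame `probeset, gene`.
#' @param genes Gene annotation (`gene, chrom, start, end`).
#' @param histotype Named character vector of tumour histotypes.
#' @param gain_cutoff,neutral_range Passed to [assign_groups()].
#' @param flank Gene flank in bp for copy-number extraction.
#' @param min_genes_own_prior Region size (probesets) needed to estimate
#'   its own moderation prior.
#' @return list with `results` (one row per region x probeset: `region_id,
#'   probeset, gene, chrom, n_G, n_N, logFC, t, p_raw, p_adj, r, r_p, r_n`),
#'   `skipped` (untestable regions and reasons), `gene_cn` (flanked gene
#'   copy-number matrix) and `global_prior`.
#' @export
integrate_regions <- function(regions, segments, expr, probe_map, genes,
                              histotype = NULL, gain_cutoff = 3.0,
                              neutral_range = c(1.5, 2.5), flank = 1e4,
                              min_genes_own_prior = 10) {
  stop_if(!nrow(regions), "no regions to integrate")
  gene_cn <- gene_cn_matrix(segments, genes, flank = flank)
  region_cn <- gene_cn_matrix(segments, regions, flank = 0)
  expr_samples <- colnames(expr)

  region_probes <- lapply(seq_len(nrow(regions)), function(r) {
    g <- genes$gene[genes$chrom == regions$chrom[r] &
                      genes$start < regions$end[r] &
                      genes$end > regions$start[r]]
    probe_map[probe_map$gene %in% g, , drop = FALSE]
  })

  # pass 1: fits without moderation, pooled for the global prior
  fits <- vector("list", nrow(regions))
  skipped <- list()
  all_s2 <- numeric(); all_df <- numeric()
  for (r in seq_len(nrow(regions))) {
    pm <- region_probes[[r]]
    if (!nrow(pm)) {
      skipped[[length(skipped) + 1]] <- data.frame(
        region_id = regions$region_id[r], reason = "no probesets",
        stringsAsFactors = FALSE)
      next
    }
    asg <- assign_groups(region_cn[regions$region_id[r], expr_samples],
                         gain_cutoff, neutral_range)
    nG <- sum(asg$group == "G"); nN <- sum(asg$group == "N")
    if (nG < 2 || nN < 2) {
      skipped[[length(skipped) + 1]] <- data.frame(
        region_id = regions$region_id[r],
        reason = sprintf("untestable: n_G=%d, n_N=%d", nG, nN),
        stringsAsFactors = FALSE)
      next
    }
    fit <- moderated_t_test(expr[pm$probeset, , drop = FALSE], asg, histotype,
                            prior = list(d0 = 0, s0_sq = 1))
    fits[[r]] <- list(fit = fit, asg = asg, pm = pm)
    all_s2 <- c(all_s2, fit$s2)
    all_df <- c(all_df, rep(fit$df, length(fit$s2)))
  }
  tested <- which(!vapply(fits, is.null, logical(1)))
  stop_if(!length(tested), "no testable regions")
  global_prior <- fit_moderation_prior(all_s2, all_df)

  # pass 2: moderated statistics with the appropriate prior
  out <- list()
  for (r in tested) {
    f <- fits[[r]]
    prior <- if (nrow(f$pm) >= min_genes_own_prior) {
      fit_moderation_prior(f$fit$s2, f$fit$df)
    } else {
      global_prior
    }
    mt <- moderated_t_test(expr[f$pm$probeset, , drop = FALSE], f$asg,
                           histotype, prior = prior)
    corr <- lapply(f$pm$probeset, function(ps) {
      g <- f$pm$gene[f$pm$probeset == ps][1]
      cn_samples <- intersect(expr_samples, colnames(gene_cn))
      cn_expr_correlation(expr[ps, cn_samples], gene_cn[g, cn_samples])
    })
    out[[length(out) + 1]] <- data.frame(
      region_id = regions$region_id[r], probeset = mt$table$probeset,
      gene = f$pm$gene[match(mt$table$probeset, f$pm$probeset)],
      chrom = regions$chrom[r],
      n_G = mt$table$n_G, n_N = mt$table$n_N, logFC = mt$table$logFC,
      t = mt$table$t, p_raw = mt$table$p_raw, p_adj = mt$table$p_adj,
      r = vapply(corr, `[[`, numeric(1), "r"),
      r_p = vapply(corr, `[[`, numeric(1), "p_raw"),
      r_n = vapply(corr, function(x) as.numeric(x$n), numeric(1)),
      stringsAsFactors = FALSE)
  }
  list(results = do.call(rbind, out),
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(region_id = character(), reason = character(),
                    stringsAsFactors = FALSE),
       gene_cn = gene_cn, global_prior = global_prior)
}
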