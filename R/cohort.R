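#' Planted amplicon specification
#'
#' Describes a recurrent somatic gain to plant in a simulated cohort: its
#' genomic interval, the fraction of tumours carrying it, the copy-number
#' values a carrier may attain, and the dosage slope given to genes that
#' fall wholly inside it.
#'
#' @param chrom Chromosome label (normalised to `"chrN"`).
#' @param start,end Interval in bp, 0-based half-open.
#' @param frequency Fraction of tumours carrying the amplicon, in (0, 1].
#' @param cn Numeric vector of attainable absolute copy numbers; each
#'   carrier draws one value uniformly. Use e.g. `c(3, 4)` for a low-level
#'   gain or `6` for a high-amplitude amplicon.
#' @param beta Dosage slope in log2 expression units per copy, applied to
#'   every gene contained in the amplicon. `0` plants a pure passenger
#'   amplicon.
#' @return A `planted_amplicon` list.
#' @export
planted_amplicon <- function(chrom, start, end, frequency, cn = c(3, 4), beta = 0.5) {
  stop_if(start >= end, "amplicon start must be < end")
  stop_if(frequency <= 0 || frequency > 1, "amplicon frequency must be in (0, 1]")
  stop_if(!all(is.finite(cn)) || any(cn <= 2), "amplicon cn values must be finite and > 2")
  stop_if(!is.finite(beta), "beta must be finite")
  structure(list(chrom = norm_chrom(chrom), start = start, end = end,
                 frequency = frequency, cn = cn, beta = beta),
            class = "planted_amplicon")
}

#' Planted germline copy-number polymorphism
#'
#' A germline CNP appears in both the tumour and the matched normal of a
#' carrier individual; each carrier shows either a one-copy gain or a
#' one-copy loss (germline CNPs commonly show both states at one locus
#' across a population).
#'
#' @param chrom Chromosome label.
#' @param start,end Interval in bp, 0-based half-open.
#' @param population_frequency Fraction of individuals carrying the CNP.
#' @return A `planted_cnp` list.
#' @export
planted_cnp <- function(chrom, start, end, population_frequency) {
  stop_if(start >= end, "CNP start must be < end")
  stop_if(population_frequency <= 0 || population_frequency > 1,
          "population_frequency must be in (0, 1]")
  structure(list(chrom = norm_chrom(chrom), start = start, end = end,
                 population_frequency = population_frequency),
            class = "planted_cnp")
}

#' Synthetic cohort configuration
#'
#' Defines the study conditions a simulated cohort emulates: cohort sizes,
#' histotype mix, genome layout and marker density, planted driver
#' amplicons, background passenger-alteration rate, germline CNPs, and
#' noise levels. Defaults mirror a typical high-grade epithelial ovarian
#' carcinoma series: 68 tumours (57 with a matched normal) in five
#' histotypes dominated by serous cases, complex backgrounds of segmental
#' gains and losses, and recurrent amplicons carried by roughly half the
#' cohort.
#'
#' @param n_tumours Number of tumour samples (>= 4).
#' @param n_normals Number of matched normals (<= `n_tumours`; normal `i`
#'   matches tumour `i`).
#' @param histotypes Named numeric vector of histotype proportions summing
#'   to 1.
#' @param chrom_lengths Named numeric vector of chromosome lengths in bp.
#' @param marker_spacing Distance between copy-number markers in bp.
#' @param driver_amplicons List of [planted_amplicon()] objects.
#' @param passenger_rate Expected number of background (passenger) segments
#'   per tumour genome; lengths are log-uniform on 50 kb--10 Mb and copy
#'   number is 1 or 3 with equal probability.
#' @param cnp_spec List of [planted_cnp()] objects.
#' @param noise_sd_cn Marker-level Gaussian noise sd, in copy-number units.
#' @param n_genes Number of genes placed uniformly over the genome.
#' @param gene_length_range Two-element range of gene lengths in bp
#'   (log-uniform draw).
#' @param histotype_gene_fraction Fraction of genes given histotype-specific
#'   expression offsets.
#' @param histotype_sd Sd of the per-histotype expression offsets (log2
#'   units) for affected genes.
#' @param expr_baseline_mean,expr_baseline_sd Mean and sd of per-gene
#'   baseline log2 expression.
#' @param histotype_rate_multipliers Optional named vector scaling
#'   `passenger_rate` per histotype (some histotypes carry fewer
#'   alterations); defaults to 1 for all.
#' @param seed Integer seed making the cohort reproducible.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_tumours = 68,
                          n_normals = 57,
                          histotypes = c(serous = 37, endometrioid = 14,
                                         mucinous = 7, clear_cell = 9,
                                         undifferentiated = 1) / 68,
                          chrom_lengths = c(chr1 = 60e6, chr2 = 80e6),
                          marker_spacing = 1e5,
                          driver_amplicons = list(),
                          passenger_rate = 6,
                          cnp_spec = list(),
                          noise_sd_cn = 0.3,
                          n_genes = 500,
                          gene_length_range = c(5e3, 2e5),
                          histotype_gene_fraction = 0.1,
                          histotype_sd = 0.5,
                          expr_baseline_mean = 7,
                          expr_baseline_sd = 1,
                          histotype_rate_multipliers = NULL,
                          seed = 1L) {
  stop_if(n_tumours < 4, "n_tumours must be >= 4")
  stop_if(n_normals < 0 || n_normals > n_tumours,
          "n_normals must be between 0 and n_tumours")
  stop_if(is.null(names(histotypes)) || any(histotypes < 0),
          "histotypes must be a named vector of non-negative proportions")
  stop_if(abs(sum(histotypes) - 1) > 1e-6, "histotype proportions must sum to 1")
  stop_if(marker_spacing <= 0, "marker_spacing must be > 0")
  stop_if(is.null(names(chrom_lengths)) || any(chrom_lengths <= 0),
          "chrom_lengths must be a named vector of positive lengths")
  names(chrom_lengths) <- norm_chrom(names(chrom_lengths))
  stop_if(noise_sd_cn < 0, "noise_sd_cn must be >= 0")
  stop_if(passenger_rate < 0, "passenger_rate must be >= 0")

  for (amp in driver_amplicons) {
    stop_if(!inherits(amp, "planted_amplicon"),
            "driver_amplicons must be a list of planted_amplicon objects")
    stop_if(!(amp$chrom %in% names(chrom_lengths)) ||
              amp$end > chrom_lengths[[amp$chrom]],
            "amplicon [", amp$start, ",", amp$end, ") exceeds ", amp$chrom)
  }
  for (cnp in cnp_spec) {
    stop_if(!inherits(cnp, "planted_cnp"),
            "cnp_spec must be a list of planted_cnp objects")
    stop_if(!(cnp$chrom %in% names(chrom_lengths)) ||
              cnp$end > chrom_lengths[[cnp$chrom]],
            "CNP [", cnp$start, ",", cnp$end, ") exceeds ", cnp$chrom)
  }
  mult <- setNames(rep(1, length(histotypes)), names(histotypes))
  if (!is.null(histotype_rate_multipliers)) {
    stop_if(!all(names(histotype_rate_multipliers) %in% names(histotypes)),
            "histotype_rate_multipliers names must match histotypes")
    mult[names(histotype_rate_multipliers)] <- histotype_rate_multipliers
  }

  structure(list(
    n_tumours = as.integer(n_tumours), n_normals = as.integer(n_normals),
    histotypes = histotypes, chrom_lengths = chrom_lengths,
    marker_spacing = marker_spacing, driver_amplicons = driver_amplicons,
    passenger_rate = passenger_rate, cnp_spec = cnp_spec,
    noise_sd_cn = noise_sd_cn, n_genes = as.integer(n_genes),
    gene_length_range = gene_length_range,
    histotype_gene_fraction = histotype_gene_fraction,
    histotype_sd = histotype_sd,
    expr_baseline_mean = expr_baseline_mean,
    expr_baseline_sd = expr_baseline_sd,
    histotype_rate_multipliers = mult,
    seed = as.integer(seed)), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort config:", x$n_tumours, "tumours /", x$n_normals,
      "matched normals\n")
  cat("  genome:", paste(names(x$chrom_lengths),
                         sprintf("%.0f Mb", x$chrom_lengths / 1e6),
                         collapse = ", "),
      "| marker spacing", x$marker_spacing / 1e3, "kb\n")
  cat("  planted:", length(x$driver_amplicons), "driver amplicons,",
      length(x$cnp_spec), "germline CNPs; passenger rate",
      x$passenger_rate, "/tumour\n")
  cat("  genes:", x$n_genes, "| marker noise sd", x$noise_sd_cn,
      "| seed", x$seed, "\n")
  invisible(x)
}
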