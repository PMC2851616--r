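#' Packaged demonstration cohort
#'
#' The reference synthetic study the package's tests and worked examples
#' run on: 60 tumours and 20 matched normals over two 60/80 Mb chromosomes
#' with markers every 100 kb; three frequent driver amplicons (carrier
#' frequencies 0.55, 0.60, 0.60; attained copy number 3 or 4; dosage slope
#' 0.5 log2 units per copy), one high-amplitude amplicon (copy number 6 in
#' 10% of tumours, 1 Mb), two germline CNPs (population frequencies 0.25 --
#' one placed inside a driver amplicon so the subtraction rules are
#' exercised -- and 0.15), a background of ~6 passenger segments per
#' tumour, marker noise sd 0.3 and 500 genes.
#'
#' @param seed Integer seed for the cohort.
#' @return A [cohort_config()].
#' @export
demo_cohort_config <- function(seed = 101L) {
  cohort_config(
    n_tumours = 60, n_normals = 20,
    chrom_lengths = c(chr1 = 60e6, chr2 = 80e6),
    marker_spacing = 1e5,
    driver_amplicons = list(
      planted_amplicon("chr1", 10e6, 14e6, frequency = 0.55, cn = c(3, 4),
                       beta = 0.5),
      planted_amplicon("chr1", 40e6, 43e6, frequency = 0.60, cn = c(3, 4),
                       beta = 0.5),
      planted_amplicon("chr2", 20e6, 25e6, frequency = 0.60, cn = c(3, 4),
                       beta = 0.5),
      planted_amplicon("chr2", 60e6, 61e6, frequency = 0.10, cn = 6,
                       beta = 0.5)),
    cnp_spec = list(
      planted_cnp("chr2", 22e6, 23e6, population_frequency = 0.25),
      planted_cnp("chr1", 30e6, 31e6, population_frequency = 0.15)),
    passenger_rate = 6, noise_sd_cn = 0.3, n_genes = 500, seed = seed)
}

#' Packaged demonstration pipeline configuration
#'
#' [pipeline_config()] wrapping [demo_cohort_config()] with the default
#' analysis thresholds (gain > 2.5, loss < 1.5, 40% recurrence, CNP > 5%
#' of normals, G group > 3 copies, expression noise sd 0.3).
#'
#' @param seed Master seed (also seeds the cohort).
#' @param out_dir Optional output directory.
#' @return A `pipeline_config`.
#' @export
demo_pipeline_config <- function(seed = 101L, out_dir = NULL) {
  pipeline_config(cohort = demo_cohort_config(seed = seed), sigma_e = 0.3,
                  seed = seed, out_dir = out_dir)
}
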