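# Synthetic cohort generation: matched tumour/normal marker profiles with
# planted amplicons, passenger segments and germline CNPs, plus a matched
# expression matrix with per-gene dosage slopes.

#' Simulate a matched tumour/normal copy-number cohort
#'
#' Generates marker-level absolute copy-number profiles (diploid = 2) for
#' tumours and matched normals. Each tumour carries its planted driver
#' amplicons with the configured probability, a Poisson number of passenger
#' segments, and, for carrier individuals, germline CNPs that also appear in
#' the matched normal. Marker values are the event-resolved copy number plus
#' Gaussian noise. Overlapping events on one sample are resolved by the
#' max-CN rule (the highest attained copy number wins).
#'
#' @param config A [cohort_config()] object.
#' @return A list with elements:
#'   \describe{
#'     \item{tumour_markers}{data.frame `sample, chrom, pos, cn` (pos is the
#'       1-based bp marker position).}
#'     \item{normal_markers}{same shape, for matched normals.}
#'     \item{samples}{sample sheet: `sample, type, histotype, matched_normal`.}
#'     \item{truth}{ground-truth object (see Details).}
#'   }
#' @details The truth object records everything needed to reconstruct the
#'   planted structure: the per-sample event list (`events`), the gene
#'   annotation with dosage slopes (`genes`), the noiseless per-gene
#'   copy-number matrix (`gene_cn`, genes x tumours), per-gene baseline
#'   expression (`mu`), the histotype of each tumour and the gene x
#'   histotype offset matrix (`histotype_offsets`).
#' @export
simulate_cohort <- function(config) {
  stop_if(!inherits(config, "cohort_config"), "config must be a cohort_config")
  set.seed(config$seed)
  nT <- config$n_tumours
  nN <- config$n_normals
  tumour_ids <- sprintf("T%03d", seq_len(nT))
  normal_ids <- sprintf("N%03d", seq_len(nN))

  histo <- sample(names(config$histotypes), nT, replace = TRUE,
                  prob = config$histotypes)

  genes <- .place_genes(config)

  events <- .plant_events(config, tumour_ids, histo)

  # dosage slopes: genes wholly inside a driver amplicon inherit its beta.
  # Genes overlapping a planted germline CNP stay passengers: a locus that
  # is copy-number variable in the germline cannot report a somatic dosage
  # effect and the analysis excises such loci by construction.
  genes$beta <- 0
  in_cnp <- rep(FALSE, nrow(genes))
  for (cnp in config$cnp_spec) {
    in_cnp <- in_cnp | (genes$chrom == cnp$chrom & genes$start < cnp$end &
                          genes$end > cnp$start)
  }
  for (k in seq_along(config$driver_amplicons)) {
    amp <- config$driver_amplicons[[k]]
    inside <- genes$chrom == amp$chrom & genes$start >= amp$start &
      genes$end <= amp$end & !in_cnp
    genes$beta[inside] <- amp$beta
    genes$amplicon[inside] <- paste0("amp", k)
  }

  # marker grids and per-sample marker values
  grid <- .marker_grid(config)
  tum <- .marker_values(grid, events[events$sample %in% tumour_ids, ],
                        tumour_ids, config$noise_sd_cn)
  norm_events <- events[events$class == "cnp" & events$sample %in% tumour_ids[seq_len(nN)], ]
  if (nrow(norm_events)) {
    norm_events$sample <- normal_ids[match(norm_events$sample, tumour_ids)]
  }
  nrm <- .marker_values(grid, norm_events, normal_ids, config$noise_sd_cn)

  gene_cn <- .true_gene_cn(genes, events[events$sample %in% tumour_ids, ], tumour_ids)

  mu <- rnorm(nrow(genes), config$expr_baseline_mean, config$expr_baseline_sd)
  names(mu) <- genes$gene
  offsets <- .histotype_offsets(genes, names(config$histotypes), config)

  samples <- data.frame(
    sample = c(tumour_ids, normal_ids),
    type = rep(c("tumour", "normal"), c(nT, nN)),
    histotype = c(histo, rep(NA_character_, nN)),
    matched_normal = c(ifelse(seq_len(nT) <= nN, normal_ids[pmin(seq_len(nT), nN)], NA),
                       rep(NA_character_, nN)),
    stringsAsFactors = FALSE)

  truth <- structure(list(
    events = events, genes = genes, gene_cn = gene_cn, mu = mu,
    histotype = setNames(histo, tumour_ids),
    histotype_offsets = offsets,
    config = config), class = "synthetic_truth")

  list(tumour_markers = tum, normal_markers = nrm, samples = samples,
       truth = truth)
}

.place_genes <- function(config) {
  lens <- config$chrom_lengths
  chrom <- sample(names(lens), config$n_genes, replace = TRUE,
                  prob = lens / sum(lens))
  lr <- log(config$gene_length_range)
  glen <- round(exp(runif(config$n_genes, lr[1], lr[2])))
  start <- floor(runif(config$n_genes) * (lens[chrom] - glen))
  g <- data.frame(gene = sprintf("g%04d", seq_len(config$n_genes)),
                  chrom = chrom, start = start, end = start + glen,
                  amplicon = NA_character_, stringsAsFactors = FALSE)
  g <- g[order(match(g$chrom, chrom_order(g$chrom)), g$start), ]
  g$gene <- sprintf("g%04d", seq_len(config$n_genes)) # ids in genomic order
  rownames(g) <- g$gene
  g
}

.plant_events <- function(config, tumour_ids, histo) {
  nT <- length(tumour_ids)
  lens <- config$chrom_lengths
  ev <- list()
  for (k in seq_along(config$driver_amplicons)) {
    amp <- config$driver_amplicons[[k]]
    carrier <- rbinom(nT, 1, amp$frequency) == 1
    if (any(carrier)) {
      ev[[length(ev) + 1]] <- data.frame(
        sample = tumour_ids[carrier], chrom = amp$chrom, start = amp$start,
        end = amp$end, cn = sample(rep(amp$cn, 2), sum(carrier), replace = TRUE),
        class = "driver", id = paste0("amp", k), stringsAsFactors = FALSE)
    }
  }
  rate <- config$passenger_rate * config$histotype_rate_multipliers[histo]
  n_pass <- rpois(nT, rate)
  for (i in seq_len(nT)) {
    if (n_pass[i] == 0) next
    chrom <- sample(names(lens), n_pass[i], replace = TRUE, prob = lens / sum(lens))
    plen <- round(exp(runif(n_pass[i], log(5e4), log(1e7))))
    plen <- pmin(plen, lens[chrom] - 1)
    start <- floor(runif(n_pass[i]) * (lens[chrom] - plen))
    ev[[length(ev) + 1]] <- data.frame(
      sample = tumour_ids[i], chrom = chrom, start = start, end = start + plen,
      cn = 2 + sample(c(-1, 1), n_pass[i], replace = TRUE),
      class = "passenger", id = NA_character_, stringsAsFactors = FALSE)
  }
  for (k in seq_along(config$cnp_spec)) {
    cnp <- config$cnp_spec[[k]]
    carrier <- rbinom(nT, 1, cnp$population_frequency) == 1
    if (any(carrier)) {
      ev[[length(ev) + 1]] <- data.frame(
        sample = tumour_ids[carrier], chrom = cnp$chrom, start = cnp$start,
        end = cnp$end, cn = 2 + sample(c(-1, 1), sum(carrier), replace = TRUE),
        class = "cnp", id = paste0("cnp", k), stringsAsFactors = FALSE)
    }
  }
  if (!length(ev)) {
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(), cn = numeric(),
                      class = character(), id = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, ev)
}

.marker_grid <- function(config) {
  lens <- config$chrom_lengths
  do.call(rbind, lapply(names(lens), function(ch) {
    pos <- seq(config$marker_spacing, lens[[ch]], by = config$marker_spacing)
    data.frame(chrom = ch, pos = pos, stringsAsFactors = FALSE)
  }))
}

# resolve events to marker-level CN: baseline 2, covering events combined by
# the max-CN rule, then Gaussian noise. Noise is drawn sample-by-sample in
# sample order so output is reproducible for a fixed RNG state.
.marker_values <- function(grid, events, sample_ids, noise_sd) {
  out <- vector("list", length(sample_ids))
  for (s in seq_along(sample_ids)) {
    id <- sample_ids[s]
    n <- nrow(grid)
    gain_cn <- rep(2, n); loss_cn <- rep(2, n); gain_cov <- rep(FALSE, n)
    ev <- events[events$sample == id, , drop = FALSE]
    for (r in seq_len(nrow(ev))) {
      # marker at 1-based pos p occupies [p-1, p); covered iff start < p <= end
      hit <- grid$chrom == ev$chrom[r] & grid$pos > ev$start[r] &
        grid$pos <= ev$end[r]
      if (ev$cn[r] > 2) {
        gain_cn[hit] <- pmax(gain_cn[hit], ev$cn[r])
        gain_cov[hit] <- TRUE
      } else {
        loss_cn[hit] <- pmin(loss_cn[hit], ev$cn[r])
      }
    }
    cn <- ifelse(gain_cov, gain_cn, loss_cn)
    noise <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    out[[s]] <- data.frame(sample = id, chrom = grid$chrom, pos = grid$pos,
                           cn = cn + noise, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# exact (noiseless) length-weighted gene copy number from the event list
.true_gene_cn <- function(genes, events, tumour_ids) {
  m <- matrix(2, nrow = nrow(genes), ncol = length(tumour_ids),
              dimnames = list(genes$gene, tumour_ids))
  for (id in tumour_ids) {
    ev <- events[events$sample == id, , drop = FALSE]
    if (!nrow(ev)) next
    for (g in seq_len(nrow(genes))) {
      evc <- ev[ev$chrom == genes$chrom[g] & ev$start < genes$end[g] &
                  ev$end > genes$start[g], , drop = FALSE]
      if (!nrow(evc)) next
      m[g, id] <- .piecewise_mean_cn(evc, genes$start[g], genes$end[g])
    }
  }
  m
}

# mean CN over [s, e) given covering events (max-CN rule), baseline 2
.piecewise_mean_cn <- function(ev, s, e) {
  bps <- sort(unique(c(s, e, pmax(s, ev$start), pmin(e, ev$end))))
  vals <- numeric(length(bps) - 1)
  for (p in seq_along(vals)) {
    a <- bps[p]; b <- bps[p + 1]
    cov <- ev$start <= a & ev$end >= b
    vals[p] <- if (any(cov)) {
      cns <- ev$cn[cov]
      if (any(cns > 2)) max(cns) else min(cns)
    } else 2
  }
  sum(vals * diff(bps)) / (e - s)
}

.histotype_offsets <- function(genes, histotypes, config) {
  off <- matrix(0, nrow = nrow(genes), ncol = length(histotypes),
                dimnames = list(genes$gene, histotypes))
  n_aff <- round(config$histotype_gene_fraction * nrow(genes))
  if (n_aff > 0 && config$histotype_sd > 0) {
    aff <- sample(nrow(genes), n_aff)
    off[aff, ] <- rnorm(n_aff * length(histotypes), 0, config$histotype_sd)
  }
  off
}

#' Simulate a log2 expression matrix from a cohort's ground truth
#'
#' Per gene g and tumour s the model is
#' `expr = mu_g + beta_g * (CN_gs - 2) + histotype offset + N(0, sigma_e)`,
#' with CN the noiseless event-resolved gene copy number from the truth
#' object. One probeset per gene by default; with
#' `probesets_per_gene > 1`, replicate probesets share the signal and draw
#' independent noise.
#'
#' @param profiles The list returned by [simulate_cohort()] (used to check
#'   sample consistency), or NULL.
#' @param truth The `synthetic_truth` object from [simulate_cohort()].
#' @param sigma_e Expression noise sd in log2 units (>= 0).
#' @param seed Integer seed.
#' @param probesets_per_gene Number of probesets measuring each gene.
#' @return A list with `expr` (probesets x tumours log2 matrix) and
#'   `probe_map` (data.frame `probeset, gene`).
#' @export
simulate_expression <- function(profiles = NULL, truth, sigma_e = 0.3,
                                seed = 1L, probesets_per_gene = 1L) {
  stop_if(!inherits(truth, "synthetic_truth"), "truth must come from simulate_cohort()")
  stop_if(sigma_e < 0, "sigma_e must be >= 0")
  stop_if(probesets_per_gene < 1, "probesets_per_gene must be >= 1")
  tumours <- colnames(truth$gene_cn)
  if (!is.null(profiles)) {
    stop_if(!all(tumours %in% unique(profiles$tumour_markers$sample)),
            "profiles do not cover the truth object's tumour samples")
  }
  set.seed(as.integer(seed))
  genes <- truth$genes
  ht <- truth$histotype[tumours]
  signal <- truth$mu[genes$gene] +
    genes$beta * (truth$gene_cn[genes$gene, tumours, drop = FALSE] - 2) +
    truth$histotype_offsets[genes$gene, ht, drop = FALSE]
  expr <- signal[rep(seq_len(nrow(genes)), each = probesets_per_gene), ,
                 drop = FALSE]
  if (sigma_e > 0) expr <- expr + rnorm(length(expr), 0, sigma_e)
  probe_map <- data.frame(
    probeset = paste0(rep(genes$gene, each = probesets_per_gene), "_p",
                      rep(seq_len(probesets_per_gene), nrow(genes))),
    gene = rep(genes$gene, each = probesets_per_gene),
    stringsAsFactors = FALSE)
  rownames(expr) <- probe_map$probeset
  colnames(expr) <- tumours
  list(expr = expr, probe_map = probe_map)
}

#' Build a synthetic cytoband table for simulated chromosomes
#'
#' Produces a UCSC-style cytoband table (0-based half-open) with a p arm
#' covering the first 40% of each chromosome and a q arm the rest, split
#' into bands of roughly `band_size` bp with alternating Giemsa stains.
#' Intended for simulated genomes; real analyses should use the genome
#' build's own cytoBand file.
#'
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param band_size Approximate band width in bp.
#' @return data.frame `chrom, start, end, band, stain`.
#' @export
make_cytobands <- function(chrom_lengths, band_size = 5e6) {
  names(chrom_lengths) <- norm_chrom(names(chrom_lengths))
  rows <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    cen <- round(0.4 * len)
    p_bks <- unique(c(seq(0, cen, by = band_size), cen))
    q_bks <- unique(c(seq(cen, len, by = band_size), len))
    np <- length(p_bks) - 1
    nq <- length(q_bks) - 1
    data.frame(
      chrom = ch,
      start = c(p_bks[-length(p_bks)], q_bks[-length(q_bks)]),
      end = c(p_bks[-1], q_bks[-1]),
      # p bands count down toward the centromere, q bands count up
      band = c(paste0("p", rev(seq_len(np))), paste0("q", seq_len(nq))),
      stain = rep_len(c("gneg", "gpos50"), np + nq),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
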