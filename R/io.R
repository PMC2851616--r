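# Readers and writers for the on-disk formats. Internal coordinates are
# 0-based half-open; SEG files are 1-based inclusive on disk and converted
# at this boundary. Readers validate and reject malformed input rather than
# coercing silently.

.seg_header <- c("Sample", "Chromosome", "Start", "End", "Num_Probes",
                 "Segment_Mean")

#' Write segments as a SEG file
#'
#' Standard six-column SEG dialect, tab-separated, 1-based inclusive
#' coordinates, preceded by comment lines stating units and convention.
#' `Segment_Mean` holds absolute copy number (diploid = 2).
#'
#' @param segments data.frame `sample, chrom, start, end, n_markers,
#'   mean_cn` (internal 0-based half-open).
#' @param path Output path.
#' @export
write_seg <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# SEG: coordinates 1-based inclusive",
               "# Segment_Mean: absolute copy number (diploid = 2)",
               paste(.seg_header, collapse = "\t")), con)
  df <- data.frame(segments$sample, segments$chrom, segments$start + 1,
                   segments$end, segments$n_markers,
                   format(segments$mean_cn, digits = 10, trim = TRUE,
                          scientific = FALSE))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a SEG file
#'
#' @param path SEG file with header
#'   `Sample Chromosome Start End Num_Probes Segment_Mean` (leading `#`
#'   comment lines allowed). Malformed rows raise an error naming the line;
#'   unsorted rows are sorted with a warning.
#' @return Segment data.frame `sample, chrom, start, end, n_markers,
#'   mean_cn` in internal 0-based half-open coordinates.
#' @export
read_seg <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines))
  stop_if(!length(body), "empty SEG file: ", path)
  hdr <- strsplit(lines[body[1]], "\t", fixed = TRUE)[[1]]
  stop_if(!identical(hdr, .seg_header),
          "bad SEG header in ", path, ": expected '",
          paste(.seg_header, collapse = " "), "'")
  rows <- body[-1]
  if (!length(rows)) {
    return(data.frame(sample = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      n_markers = integer(), mean_cn = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[rows], "\t", fixed = TRUE)
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    line_no <- rows[k]
    stop_if(length(f) != 6, "SEG line ", line_no, ": expected 6 fields, got ",
            length(f))
    num <- suppressWarnings(as.numeric(f[3:6]))
    stop_if(any(is.na(num)), "SEG line ", line_no, ": non-numeric field")
    stop_if(num[2] < num[1], "SEG line ", line_no, ": End < Start")
    stop_if(num[3] < 1, "SEG line ", line_no, ": Num_Probes < 1")
  }
  df <- data.frame(
    sample = vapply(fields, `[`, character(1), 1),
    chrom = norm_chrom(vapply(fields, `[`, character(1), 2)),
    start = as.numeric(vapply(fields, `[`, character(1), 3)) - 1,
    end = as.numeric(vapply(fields, `[`, character(1), 4)),
    n_markers = as.integer(vapply(fields, `[`, character(1), 5)),
    mean_cn = as.numeric(vapply(fields, `[`, character(1), 6)),
    stringsAsFactors = FALSE)
  ord <- order(df$sample, match(df$chrom, chrom_order(df$chrom)), df$start)
  if (!identical(ord, seq_len(nrow(df)))) {
    warning("SEG rows in ", path, " were not sorted; sorting")
    df <- df[ord, ]
    rownames(df) <- NULL
  }
  df
}

#' Write / read marker-level copy-number tables
#'
#' Tab-separated `sample, chrom, pos, cn` with `pos` the 1-based bp marker
#' position and `cn` absolute copy number.
#' @param markers data.frame `sample, chrom, pos, cn`.
#' @param path File path.
#' @export
write_markers <- function(markers, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# markers: pos 1-based bp; cn absolute copy number (diploid = 2)",
             con)
  write.table(markers[, c("sample", "chrom", "pos", "cn")], con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers
#' @export
read_markers <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stop_if(!identical(names(df), c("sample", "chrom", "pos", "cn")),
          "marker file must have columns sample, chrom, pos, cn")
  stop_if(any(is.na(df$pos)) || any(is.na(df$cn)),
          "marker file contains missing pos/cn values")
  df$chrom <- norm_chrom(df$chrom)
  df
}

#' Read a UCSC-style cytoband file
#'
#' Five tab-separated columns without header: chrom, start, end, band,
#' gieStain; coordinates 0-based half-open. Overlapping bands on one
#' chromosome are an error; gaps are retained with a warning.
#'
#' @param path cytoBand.txt-style file.
#' @return data.frame `chrom, start, end, band, stain`.
#' @export
read_cytoband <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  stop_if(ncol(df) < 4, "cytoband file needs >= 4 columns (chrom, start, end, band)")
  if (ncol(df) == 4) df$V5 <- NA_character_
  names(df)[1:5] <- c("chrom", "start", "end", "band", "stain")
  df$chrom <- norm_chrom(df$chrom)
  check_intervals(df, "cytoband table")
  for (ch in unique(df$chrom)) {
    b <- df[df$chrom == ch, ]
    b <- b[order(b$start), ]
    stop_if(any(b$start[-1] < b$end[-nrow(b)]),
            "overlapping cytobands on ", ch)
    if (any(b$start[-1] > b$end[-nrow(b)])) {
      warning("gap between cytobands on ", ch, "; retained as-is")
    }
  }
  df[order(match(df$chrom, chrom_order(df$chrom)), df$start), ]
}

#' Look up the cytoband containing a position
#'
#' Bands are half-open, so a position exactly on a boundary belongs to the
#' right-hand band.
#' @param cytobands Cytoband table.
#' @param chrom,pos Query position (0-based).
#' @return Band name, or `NA` if the position falls in no band.
#' @export
cytoband_at <- function(cytobands, chrom, pos) {
  hit <- cytobands$chrom == norm_chrom(chrom) & cytobands$start <= pos &
    cytobands$end > pos
  if (!any(hit)) NA_character_ else cytobands$band[which(hit)[1]]
}

#' Write / read a log2 expression matrix as TSV
#'
#' First column `probeset`, remaining columns one per sample; missing
#' values written as `NA`.
#' @param expr Probesets x samples numeric matrix.
#' @param path File path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(probeset = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# expression: log2 units; probesets x samples", con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  stop_if(names(df)[1] != "probeset",
          "expression file must start with a 'probeset' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  stop_if(!is.numeric(m), "expression values must be numeric")
  rownames(m) <- df$probeset
  m
}

#' Write / read gene annotation as BED6
#'
#' Columns: chrom, start (0-based), end, name (gene id), score, strand.
#' @param genes data.frame `gene, chrom, start, end` (optional `strand`).
#' @param path File path.
#' @export
write_gene_bed <- function(genes, path) {
  df <- data.frame(genes$chrom, format(genes$start, scientific = FALSE,
                                       trim = TRUE),
                   format(genes$end, scientific = FALSE, trim = TRUE),
                   genes$gene, 0L, genes$strand %||% ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_bed
#' @export
read_gene_bed <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  stop_if(ncol(df) < 4, "gene BED needs >= 4 columns")
  out <- data.frame(gene = as.character(df[[4]]),
                    chrom = norm_chrom(df[[1]]),
                    start = as.numeric(df[[2]]), end = as.numeric(df[[3]]),
                    strand = if (ncol(df) >= 6) as.character(df[[6]]) else ".",
                    stringsAsFactors = FALSE)
  check_intervals(out, "gene BED")
  rownames(out) <- out$gene
  out
}

#' Write / read the sample sheet
#'
#' Tab-separated `sample, type, histotype, matched_normal` with `type` in
#' tumour/normal.
#' @param samples Sample sheet data.frame.
#' @param path File path.
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stop_if(!all(c("sample", "type", "histotype") %in% names(df)),
          "sample sheet needs columns sample, type, histotype")
  stop_if(!all(df$type %in% c("tumour", "normal")),
          "sample sheet 'type' must be tumour or normal")
  df
}

#' Serialise the synthetic ground truth to JSON
#'
#' Records the planted event list, gene annotation with dosage slopes,
#' per-tumour histotypes, per-gene baselines and histotype offsets --
#' everything needed to reconstruct the planted structure.
#' @param truth `synthetic_truth` object from [simulate_cohort()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  doc <- list(events = truth$events, genes = truth$genes,
              histotype = as.list(truth$histotype),
              mu = as.list(truth$mu),
              histotype_offsets = truth$histotype_offsets,
              gene_cn = truth$gene_cn)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(path)
}
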