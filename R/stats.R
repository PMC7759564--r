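# Descriptive circRNA signature statistics: sequencing QC ratios,
# BSJ-read support categories, chromosome density, length distribution.
# Percentages and densities are rounded to 2 decimals (print precision
# of the tables/figures they mirror).

#' Sequencing QC ratios
#'
#' @param qc List (or one-row data.frame) with `raw_reads`,
#'   `clean_reads` and optionally `mapped_reads`.
#' @return List with `clean_ratio` (clean/raw, percent, 2 decimals) and
#'   `mapping_ratio` (mapped/clean, percent; `NA` when `mapped_reads`
#'   is absent).
#' @export
qc_ratios <- function(qc) {
  raw <- qc$raw_reads; clean <- qc$clean_reads
  mapped <- qc$mapped_reads %||% NA
  if (is.null(raw) || is.na(raw) || raw <= 0) {
    stop("raw_reads must be positive", call. = FALSE)
  }
  if (clean > raw) stop("clean_reads exceeds raw_reads", call. = FALSE)
  if (!is.na(mapped) && mapped > clean) {
    stop("mapped_reads exceeds clean_reads", call. = FALSE)
  }
  list(clean_ratio = round(clean / raw * 100, 2),
       mapping_ratio = if (is.na(mapped)) NA_real_
                       else round(mapped / clean * 100, 2))
}

# ordered BSJ-read support categories; edges chosen as the only
# assignment making the five classes a partition of the non-negative
# integers: >100 means >= 101, the middle classes are inclusive, and
# <2 means <= 1.
BSJ_CATEGORY_LABELS <- c(">100", "10-100", "4-9", "2-3", "<2")

.bsj_category_of <- function(n) {
  ifelse(n >= 101L, ">100",
  ifelse(n >= 10L, "10-100",
  ifelse(n >= 4L, "4-9",
  ifelse(n >= 2L, "2-3", "<2"))))
}

#' BSJ-read support categories
#'
#' Partitions records into the five support classes
#' `>100 / 10-100 / 4-9 / 2-3 / <2` (junction reads).
#'
#' @param records circRNA record data.frame (column `bsj_reads`) or an
#'   integer vector of junction-read counts.
#' @return Data.frame with `category`, `count`, `percent` (2 decimals;
#'   all-zero input gives percent 0).
#' @export
bsj_categories <- function(records) {
  n <- if (is.data.frame(records)) records$bsj_reads else records
  n <- as.integer(n)
  cat <- factor(.bsj_category_of(n), levels = BSJ_CATEGORY_LABELS)
  counts <- as.integer(table(cat))
  total <- length(n)
  pct <- if (total == 0L) rep(0, length(counts))
         else round(counts / total * 100, 2)
  data.frame(category = BSJ_CATEGORY_LABELS, count = counts,
             percent = pct, stringsAsFactors = FALSE)
}

#' Per-chromosome circRNA counts and density
#'
#' Counts circRNAs per chromosome and divides by chromosome size in Mb,
#' for all records and for the high-support subset (`bsj_reads > 4`);
#' also reports the genome-wide count-to-size ratio.
#'
#' @param records circRNA record data.frame (`chrom`, `bsj_reads`).
#' @param chrom_sizes_mb Named numeric vector of chromosome sizes in
#'   Mb.
#' @return List with `per_chrom` (data.frame: `chrom`, `size_mb`,
#'   `count`, `density`, `count_gt4`, `density_gt4`), `genome_ratio`,
#'   and `genome_ratio_gt4`.
#' @export
chromosome_density <- function(records, chrom_sizes_mb) {
  stopifnot(!is.null(names(chrom_sizes_mb)))
  unknown <- setdiff(unique(records$chrom), names(chrom_sizes_mb))
  if (length(unknown)) {
    stop(sprintf("records on unknown chromosome(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  chroms <- names(chrom_sizes_mb)
  cnt <- table(factor(records$chrom, levels = chroms))
  gt4 <- records[records$bsj_reads > 4L, , drop = FALSE]
  cnt4 <- table(factor(gt4$chrom, levels = chroms))
  per <- data.frame(chrom = chroms,
                    size_mb = unname(chrom_sizes_mb),
                    count = as.integer(cnt),
                    density = round(as.integer(cnt) / unname(chrom_sizes_mb), 2),
                    count_gt4 = as.integer(cnt4),
                    density_gt4 = round(as.integer(cnt4) / unname(chrom_sizes_mb), 2),
                    stringsAsFactors = FALSE)
  list(per_chrom = per,
       genome_ratio = round(nrow(records) / sum(chrom_sizes_mb), 2),
       genome_ratio_gt4 = round(nrow(gt4) / sum(chrom_sizes_mb), 2))
}

#' circRNA length distribution
#'
#' Histogram over predicted sequence lengths with the fraction of
#' records longer than 10,000 bp reported separately.
#'
#' @param records circRNA record data.frame (column `length`) or an
#'   integer vector of lengths.
#' @param bin_edges Increasing interior bin edges; bins are
#'   `[0, e1), [e1, e2), ..., [ek, Inf)`.
#' @return List with `histogram` (data.frame: `bin`, `count`) and
#'   `fraction_over_10k`.
#' @export
length_distribution <- function(records,
                                bin_edges = c(100, 200, 400, 700, 1000,
                                              2000, 4000, 10000)) {
  len <- if (is.data.frame(records)) records$length else records
  breaks <- c(0, bin_edges, Inf)
  labs <- c(sprintf("<%d", bin_edges[1]),
            sprintf("%d-%d", bin_edges[-length(bin_edges)],
                    bin_edges[-1]),
            sprintf(">%d", bin_edges[length(bin_edges)]))
  b <- cut(len, breaks = breaks, labels = labs, right = FALSE)
  hist <- data.frame(bin = labs, count = as.integer(table(b)),
                     stringsAsFactors = FALSE)
  over <- if (length(len) == 0L) 0 else mean(len >= 10000)
  list(histogram = hist, fraction_over_10k = over)
}
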