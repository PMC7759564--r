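# Sequence and table I/O, plus the circRNA locus-identifier convention.
#
# A circRNA locus is printed as "<chrom>:<start>-<end><strand>" with
# 1-based, both-ends-inclusive coordinates; the plus strand is written
# with a separating space (" +") and the minus strand glyph is attached
# ("-"), mirroring how such identifiers appear in circRNA catalogs.

#' Construct a circRNA locus
#'
#' @param chrom Chromosome/scaffold identifier.
#' @param start,end 1-based inclusive genomic coordinates, `start <= end`.
#' @param strand `"+"` or `"-"`.
#' @return An object of class `circ_locus`.
#' @export
circ_locus <- function(chrom, start, end, strand) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L) {
    stop("locus coordinates must be positive integers", call. = FALSE)
  }
  if (start > end) {
    stop(sprintf("invalid locus: start (%d) > end (%d)", start, end),
         call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand),
            class = "circ_locus")
}

#' @export
print.circ_locus <- function(x, ...) {
  cat("<circ_locus> ", format_circ_id(x), "  (", circ_length(x), " bp)\n",
      sep = "")
  invisible(x)
}

#' Parse a circRNA locus identifier
#'
#' Accepts identifiers of the form `"chrom:start-end strand"` where the
#' strand glyph may be attached or separated by whitespace, e.g.
#' `"QPFF01524526.1:668-844 +"` or `"CM012988.1:10693863-10694407-"`.
#' A Unicode minus sign is accepted as `-`.
#'
#' @param text A single identifier string.
#' @return A [circ_locus()].
#' @export
parse_circ_id <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- chartr("−", "-", trimws(text))
  m <- regmatches(s, regexec("^(\\S+):([0-9]+)-([0-9]+)\\s*([+-])$", s))[[1]]
  if (length(m) != 5L) {
    stop(sprintf("malformed circRNA identifier: '%s'", text), call. = FALSE)
  }
  start <- as.integer(m[3]); end <- as.integer(m[4])
  if (start > end) {
    stop(sprintf("malformed circRNA identifier '%s': start (%d) > end (%d)",
                 text, start, end), call. = FALSE)
  }
  circ_locus(m[2], start, end, m[5])
}

#' Format a circRNA locus identifier
#'
#' Inverse of [parse_circ_id()]: plus-strand loci get a space before the
#' `+`, minus-strand loci an attached `-`.
#'
#' @param locus A [circ_locus()].
#' @return A single string.
#' @export
format_circ_id <- function(locus) {
  stopifnot(inherits(locus, "circ_locus"))
  sep <- if (locus$strand == "+") " " else ""
  sprintf("%s:%d-%d%s%s", locus$chrom, locus$start, locus$end, sep,
          locus$strand)
}

#' Predicted circRNA sequence length
#'
#' Length in bp of the genomic interval, `end - start + 1` (1-based,
#' both ends inclusive).
#'
#' @param locus A [circ_locus()].
#' @return Integer length in bp.
#' @export
circ_length <- function(locus) {
  stopifnot(inherits(locus, "circ_locus"))
  locus$end - locus$start + 1L
}

#' Extract the (spliced) sequence of a circRNA locus
#'
#' Returns the genomic substring of the locus; minus-strand loci are
#' reverse-complemented so the result is the RNA-sense sequence in DNA
#' alphabet.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param locus A [circ_locus()].
#' @return A single DNA string.
#' @export
circ_sequence <- function(genome, locus) {
  assert_genome(genome)
  if (!locus$chrom %in% names(genome)) {
    stop(sprintf("chromosome '%s' not in genome", locus$chrom), call. = FALSE)
  }
  s <- substr(genome[[locus$chrom]], locus$start, locus$end)
  if (locus$strand == "-") s <- revcomp(s) else s
}

#' Read sequences from FASTA or FASTQ
#'
#' FASTA parsing is delegated to Biostrings; FASTQ records (4-line,
#' Phred+33) are read with per-record validation so a truncated or
#' inconsistent record is reported with its index. Sequence names are
#' truncated at the first whitespace; sequences are uppercased.
#'
#' @param path Input file.
#' @param format `"fasta"` or `"fastq"`.
#' @param rna_to_dna If `TRUE`, map `U` to `T`.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path, format = c("fasta", "fastq"),
                           rna_to_dna = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "fasta") {
    # BStringSet: tolerate RNA alphabet (U) in the input
    x <- Biostrings::readBStringSet(path, format = "fasta")
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
  } else {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L) {
      stop(sprintf("truncated FASTQ: %d lines is not a multiple of 4 (record %d)",
                   length(lines), length(lines) %/% 4L + 1L), call. = FALSE)
    }
    n <- length(lines) %/% 4L
    idx <- seq_len(n)
    hdr <- lines[4L * idx - 3L]; seqs <- lines[4L * idx - 2L]
    plus <- lines[4L * idx - 1L]; qual <- lines[4L * idx]
    bad <- which(substr(hdr, 1L, 1L) != "@" | substr(plus, 1L, 1L) != "+")
    if (length(bad)) {
      stop(sprintf("malformed FASTQ record %d in %s", bad[1], path),
           call. = FALSE)
    }
    bad <- which(nchar(seqs) != nchar(qual))
    if (length(bad)) {
      stop(sprintf("FASTQ record %d: sequence and quality lengths differ",
                   bad[1]), call. = FALSE)
    }
    out <- seqs
    names(out) <- sub("\\s.*$", "", substring(hdr, 2L))
  }
  norm_dna(out, rna_to_dna = rna_to_dna)
}

#' Write sequences to FASTA or FASTQ
#'
#' FASTQ output carries a constant Phred+33 quality of `"I"` (Q40), the
#' convention used by the read simulator.
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (format == "fasta") {
    Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path,
                                format = "fasta", width = 70L)
  } else {
    qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
    out <- character(4L * length(seqs))
    idx <- seq_along(seqs)
    out[4L * idx - 3L] <- paste0("@", names(seqs))
    out[4L * idx - 2L] <- unname(seqs)
    out[4L * idx - 1L] <- "+"
    out[4L * idx] <- qual
    writeLines(out, path)
  }
  invisible(path)
}

#' Write a circRNA record table as TSV
#'
#' Columns: `circ_id`, `bsj_reads`, `length`, `name`, `norm_expr`.
#'
#' @param records circRNA record data.frame (see [call_circrnas()]).
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_circ_table <- function(records, path) {
  cols <- c("circ_id", "bsj_reads", "length", "name", "norm_expr")
  stopifnot(all(cols %in% names(records)))
  df <- records[, cols, drop = FALSE]
  df$norm_expr <- ifelse(is.na(df$norm_expr), "NA",
                         sprintf("%.6f", df$norm_expr))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a circRNA record table written by [write_circ_table()]
#'
#' @param path Input TSV.
#' @return A data.frame with parsed locus columns re-derived from `circ_id`.
#' @export
read_circ_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(circ_id = "character",
                                         name = "character"))
  loci <- lapply(df$circ_id, parse_circ_id)
  df$chrom <- vapply(loci, `[[`, character(1), "chrom")
  df$start <- vapply(loci, `[[`, integer(1), "start")
  df$end <- vapply(loci, `[[`, integer(1), "end")
  df$strand <- vapply(loci, `[[`, character(1), "strand")
  df
}

#' Export circRNA records as BED6
#'
#' The only place where the 1-based inclusive convention is converted to
#' BED's 0-based half-open intervals.
#'
#' @param records circRNA record data.frame.
#' @param path Output BED file.
#' @return `path`, invisibly.
#' @export
circ_table_to_bed <- function(records, path) {
  stopifnot(all(c("chrom", "start", "end", "strand", "bsj_reads", "name")
                %in% names(records)))
  bed <- data.frame(chrom = records$chrom,
                    start = records$start - 1L,
                    end = records$end,
                    name = records$name,
                    score = records$bsj_reads,
                    strand = records$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Dump alignment hits as a minimal SAM subset (inspection only)
#'
#' Writes `@HD`/`@SQ` headers and one line per ungapped hit with a
#' full-length match CIGAR. Not a general SAM implementation.
#'
#' @param hits Data.frame of alignment hits (see [align_full_read()]).
#' @param genome Named character vector of chromosome sequences.
#' @param path Output SAM file.
#' @param seqs Optional named character vector giving each query's sequence.
#' @return `path`, invisibly.
#' @export
write_sam_subset <- function(hits, genome, path, seqs = NULL) {
  assert_genome(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(genome)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(genome[[nm]])), con)
  }
  if (!is.null(hits) && nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      len <- h$end - h$start + 1L
      seq <- if (!is.null(seqs) && h$query_id %in% names(seqs)) {
        if (h$strand == "-") revcomp(seqs[[h$query_id]]) else seqs[[h$query_id]]
      } else "*"
      flag <- if (h$strand == "-") 16L else 0L
      writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                         h$query_id, flag, h$chrom, h$start, len, seq,
                         h$mismatches), con)
    }
  }
  invisible(path)
}
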