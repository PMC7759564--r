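# Back-splice junction (BSJ) detection.
#
# A read that spans the head-to-tail junction of a circRNA fails
# full-length linear alignment but its two terminal anchors align in
# reversed genomic order: the anchor from the read 3' end (A1..A2)
# lands UPSTREAM of the anchor from the read 5' end (A3..A4). Extending
# both anchors toward a split position p reconstructs the junction, and
# the candidate locus (s, e) must carry the canonical splice signal:
# AG immediately before s and GT immediately after e on the plus
# strand, AC/CT (the reverse complement seen in forward genome
# coordinates) on the minus strand.
#
# Reads sequenced in the reverse orientation are handled by running the
# same forward-strand procedure on the reverse complement of the read;
# the strand of the final call is decided by which canonical flank
# matches the genome.

#' Extract terminal anchors from a read
#'
#' @param read Read sequence.
#' @param anchor_length Anchor length in nt (default 20).
#' @return List with `five_prime` (first `anchor_length` bases) and
#'   `three_prime` (last `anchor_length` bases), or `NULL` when the read
#'   is shorter than two anchors.
#' @export
extract_anchors <- function(read, anchor_length = 20L) {
  L <- nchar(read)
  if (L < 2L * anchor_length) return(NULL)
  list(five_prime = substr(read, 1L, anchor_length),
       three_prime = substr(read, L - anchor_length + 1L, L))
}

#' Pair anchor placements into back-splice geometries
#'
#' Emits every same-chromosome, same-strand pair in which the 3'-end
#' anchor lies strictly upstream of the 5'-end anchor (`A2 < A3`) with
#' total span `A4 - A1 + 1 <= max_span`. With `require_unique = TRUE`
#' (the default) a read contributes no geometry unless both anchors
#' place uniquely.
#'
#' @param hits_5p,hits_3p Placement data.frames from [align_anchor()]
#'   for the read's 5' and 3' anchors.
#' @param max_span Maximum genomic span in bp (default 100000).
#' @param require_unique Demand single-placement anchors.
#' @return Data.frame of geometries (`chrom`, `strand`, `A1`..`A4`).
#' @export
pair_anchors <- function(hits_5p, hits_3p, max_span = 100000L,
                         require_unique = TRUE) {
  empty <- data.frame(chrom = character(0), strand = character(0),
                      A1 = integer(0), A2 = integer(0),
                      A3 = integer(0), A4 = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(hits_5p) || is.null(hits_3p) ||
      !nrow(hits_5p) || !nrow(hits_3p)) return(empty)
  if (require_unique && (nrow(hits_5p) != 1L || nrow(hits_3p) != 1L)) {
    return(empty)
  }
  out <- empty
  for (i in seq_len(nrow(hits_3p))) {
    for (j in seq_len(nrow(hits_5p))) {
      h3 <- hits_3p[i, ]; h5 <- hits_5p[j, ]
      if (h3$chrom != h5$chrom || h3$strand != h5$strand) next
      if (!(h3$end < h5$start)) next          # back-splice order only
      if (h5$end - h3$start + 1L > max_span) next
      out <- rbind(out, data.frame(chrom = h3$chrom, strand = h3$strand,
                                   A1 = h3$start, A2 = h3$end,
                                   A3 = h5$start, A4 = h5$end,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Check the canonical back-splice splice signal at a locus
#'
#' Plus strand: `AG` at `[s-2, s-1]` (acceptor) and `GT` at `[e+1, e+2]`
#' (donor). Minus strand: `AC` and `CT` at the same positions — the
#' reverse complement of GT-AG as seen in forward genome coordinates.
#' Loci too close to a contig edge cannot be validated and return
#' `FALSE`.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param chrom Chromosome name.
#' @param s,e 1-based inclusive locus start/end.
#' @param strand `"+"` or `"-"`.
#' @return Logical scalar.
#' @export
splice_signal_ok <- function(genome, chrom, s, e, strand) {
  seq <- genome[[chrom]]
  if (is.null(seq)) stop(sprintf("unknown chromosome '%s'", chrom),
                         call. = FALSE)
  if (s < 3L || e + 2L > nchar(seq)) return(FALSE)
  up <- substr(seq, s - 2L, s - 1L)
  dn <- substr(seq, e + 1L, e + 2L)
  if (strand == "+") up == "AG" && dn == "GT"
  else if (strand == "-") up == "AC" && dn == "CT"
  else stop("strand must be '+' or '-'", call. = FALSE)
}

# splice signal string stored on candidates, e.g. "AGGT" for +
.splice_signal_string <- function(strand) {
  if (strand == "+") "AGGT" else "ACCT"
}

#' Extend a back-splice geometry to the exact breakpoint
#'
#' Scans split positions `p` (from `anchor_length` to
#' `read_length - anchor_length`): the read prefix `read[1..p]` must
#' align ungapped from `A3`, ending at `e = A3 + p - 1`; the suffix
#' `read[p+1..L]` must align ungapped ending at `A2`, starting at
#' `s = A2 - (L - p) + 1`. Among splits within `max_mismatches` whose
#' locus carries a canonical splice signal, the one with the fewest
#' mismatches wins and equal-mismatch ties resolve to the smallest `p`
#' (deterministic); the matching signal decides the strand (`+` checked
#' before `-`).
#'
#' @param read Oriented read sequence (forward-aligned; the caller
#'   reverse-complements reverse-orientation reads beforehand).
#' @param geometry One-row geometry from [pair_anchors()].
#' @param genome Named character vector of chromosome sequences.
#' @param max_mismatches Total substitution budget across both
#'   extensions (default 2).
#' @param anchor_length Anchor length used to produce the geometry.
#' @return A list (`locus`, `splice_signal`, `split`, `mismatches`) or
#'   `NULL` when no split qualifies.
#' @export
extend_to_breakpoint <- function(read, geometry, genome,
                                 max_mismatches = 2L, anchor_length = 20L) {
  stopifnot(nrow(geometry) == 1L)
  chrom <- geometry$chrom
  seq <- genome[[chrom]]
  if (is.null(seq)) stop(sprintf("unknown chromosome '%s'", chrom),
                         call. = FALSE)
  clen <- nchar(seq)
  L <- nchar(read)
  A2 <- geometry$A2; A3 <- geometry$A3
  # p bounds: both anchors intact, flanks inside the contig
  p_min <- max(anchor_length, L - A2 + 2L)        # s = A2-(L-p)+1 >= 3
  p_max <- min(L - anchor_length, clen - 2L - A3 + 1L)  # e+2 <= clen
  if (p_min > p_max) return(NULL)
  rraw <- charToRaw(read)
  # prefix mismatches: read[i] vs genome[A3 + i - 1]
  pre_cmp <- rraw != charToRaw(substr(seq, A3, A3 + L - 1L))[seq_len(L)]
  pre_cum <- cumsum(pre_cmp)
  # suffix mismatches: read[i] vs genome[A2 - L + i]
  suf_lo <- A2 - L + 1L
  suf_cmp <- rraw != charToRaw(substr(seq, max(1L, suf_lo), A2))
  if (suf_lo < 1L) {  # pad out-of-range prefix as mismatches
    suf_cmp <- c(rep(TRUE, 1L - suf_lo), suf_cmp)
  }
  suf_cum <- cumsum(suf_cmp)
  suf_tot <- suf_cum[L]
  best <- NULL
  for (p in p_min:p_max) {
    mm <- pre_cum[p] + (suf_tot - suf_cum[p])
    if (mm > max_mismatches) next
    if (!is.null(best) && mm >= best$mismatches) next
    e <- A3 + p - 1L
    s <- A2 - (L - p) + 1L
    strand <- if (splice_signal_ok(genome, chrom, s, e, "+")) "+"
              else if (splice_signal_ok(genome, chrom, s, e, "-")) "-"
              else next
    best <- list(locus = circ_locus(chrom, s, e, strand),
                 splice_signal = .splice_signal_string(strand),
                 split = as.integer(p), mismatches = as.integer(mm))
    if (mm == 0L) break    # cannot be beaten; smallest such p by scan order
  }
  best
}

#' Call circRNAs from reads
#'
#' The full caller: reads are first partitioned by full-length linear
#' alignment; each unaligned read is tried in both orientations —
#' terminal anchors are aligned exactly, paired into back-splice
#' geometries, and extended to a breakpoint under the GT-AG rule.
#' Candidates are aggregated by locus, distinct supporting reads are
#' counted as `bsj_reads`, loci below `min_reads` are dropped, and the
#' normalized expression is computed as
#' `log2(bsj_reads / total_mapped_reads * 1e6)` where
#' `total_mapped_reads` counts linearly placed reads plus all distinct
#' junction reads. Records are named `"<bsj_reads>-<length>"` and sorted
#' by (chromosome in reference order, start, end).
#'
#' @param reads Named character vector of read sequences, or a
#'   data.frame with columns `read_id` and `seq`.
#' @param genome Named character vector of chromosome sequences.
#' @param config A [pipeline_config()] list; relevant fields:
#'   `anchor_length`, `max_mismatches_linear`, `max_mismatches_anchor`,
#'   `max_mismatches_extend`, `min_reads`, `max_span`,
#'   `require_unique_anchors`.
#' @param index Optional pre-built [build_index()] (must use
#'   `k = anchor_length`); built on the fly when `NULL`.
#' @return Data.frame of circRNA records with columns `circ_id`,
#'   `chrom`, `start`, `end`, `strand`, `bsj_reads`, `length`, `name`,
#'   `norm_expr`, plus attributes `n_mapped`, `n_junction_reads`,
#'   `supporting_reads` (list keyed by `circ_id`, pre-filter loci
#'   included under attribute `all_candidates`).
#' @export
call_circrnas <- function(reads, genome, config = pipeline_config(),
                          index = NULL) {
  assert_genome(genome)
  genome <- toupper(genome)
  rf <- as_read_frame(reads)
  al <- config$anchor_length
  if (is.null(index)) index <- build_index(genome, k = al)
  if (index$k != al) {
    stop("index k must equal config$anchor_length for exact anchor lookup",
         call. = FALSE)
  }

  n_mapped <- 0L
  cand_chrom <- character(0); cand_s <- integer(0); cand_e <- integer(0)
  cand_strand <- character(0); cand_read <- character(0)
  n_short <- 0L

  for (i in seq_len(nrow(rf))) {
    seq_i <- rf$seq[i]
    hit <- align_full_read(index, seq_i, rf$read_id[i],
                           max_mismatches = config$max_mismatches_linear)
    if (!is.null(hit)) {
      n_mapped <- n_mapped + 1L
      next
    }
    found <- FALSE
    for (orient in 1:2) {
      q <- if (orient == 1L) seq_i else revcomp(seq_i)
      an <- extract_anchors(q, al)
      if (is.null(an)) {
        if (orient == 1L) n_short <- n_short + 1L
        break
      }
      h5 <- align_anchor(index, an$five_prime,
                         max_mismatches = config$max_mismatches_anchor)
      h3 <- align_anchor(index, an$three_prime,
                         max_mismatches = config$max_mismatches_anchor)
      # forward-strand placements of the oriented sequence only; the
      # other orientation covers the reverse strand
      h5 <- h5[h5$strand == "+", , drop = FALSE]
      h3 <- h3[h3$strand == "+", , drop = FALSE]
      geos <- pair_anchors(h5, h3, max_span = config$max_span,
                           require_unique = config$require_unique_anchors)
      for (g in seq_len(nrow(geos))) {
        cand <- extend_to_breakpoint(q, geos[g, , drop = FALSE], genome,
                                     max_mismatches = config$max_mismatches_extend,
                                     anchor_length = al)
        if (!is.null(cand)) {
          cand_chrom <- c(cand_chrom, cand$locus$chrom)
          cand_s <- c(cand_s, cand$locus$start)
          cand_e <- c(cand_e, cand$locus$end)
          cand_strand <- c(cand_strand, cand$locus$strand)
          cand_read <- c(cand_read, rf$read_id[i])
          found <- TRUE
          break
        }
      }
      if (found) break
    }
  }

  junction_reads <- unique(cand_read)
  n_junction <- length(junction_reads)
  total_mapped <- n_mapped + n_junction

  empty <- data.frame(circ_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), bsj_reads = integer(0),
                      length = integer(0), name = character(0),
                      norm_expr = numeric(0), stringsAsFactors = FALSE)
  if (!length(cand_read)) {
    attr(empty, "n_mapped") <- n_mapped
    attr(empty, "n_junction_reads") <- 0L
    attr(empty, "n_short_reads") <- n_short
    return(empty)
  }

  key <- paste(cand_chrom, cand_s, cand_e, cand_strand, sep = "\r")
  supp <- lapply(split(cand_read, key), unique)
  ukey <- names(supp)
  parts <- strsplit(ukey, "\r", fixed = TRUE)
  rec <- data.frame(chrom = vapply(parts, `[[`, character(1), 1L),
                    start = as.integer(vapply(parts, `[[`, character(1), 2L)),
                    end = as.integer(vapply(parts, `[[`, character(1), 3L)),
                    strand = vapply(parts, `[[`, character(1), 4L),
                    bsj_reads = vapply(supp, length, integer(1)),
                    stringsAsFactors = FALSE)
  rec$length <- rec$end - rec$start + 1L
  keep <- rec$bsj_reads >= config$min_reads
  supp <- supp[keep]
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec)) {
    rec$name <- sprintf("%d-%d", rec$bsj_reads, rec$length)
    rec$circ_id <- vapply(seq_len(nrow(rec)), function(i) {
      format_circ_id(circ_locus(rec$chrom[i], rec$start[i], rec$end[i],
                                rec$strand[i]))
    }, character(1))
    if (total_mapped == 0L) {
      warning("zero mapped reads: norm_expr left unset", call. = FALSE)
      rec$norm_expr <- NA_real_
    } else {
      rec$norm_expr <- log2(rec$bsj_reads / total_mapped * 1e6)
    }
    ord <- order(match(rec$chrom, names(genome)), rec$start, rec$end)
    supp <- supp[ord]
    rec <- rec[ord, c("circ_id", "chrom", "start", "end", "strand",
                      "bsj_reads", "length", "name", "norm_expr")]
    rownames(rec) <- NULL
    names(supp) <- rec$circ_id
  } else {
    rec <- empty
    supp <- list()
  }
  attr(rec, "n_mapped") <- n_mapped
  attr(rec, "n_junction_reads") <- n_junction
  attr(rec, "n_short_reads") <- n_short
  attr(rec, "supporting_reads") <- supp
  rec
}
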