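# Ungapped short-sequence alignment against the reference.
#
# A k-mer hash index over the forward genome supports two query modes:
# seed-and-extend (a query of length L with at most m mismatches is
# found through one of m+1 disjoint k-mer seeds, by pigeonhole exact
# when L >= (m+1)*k) and a dense per-offset scan fallback for short
# queries. The reverse strand is always handled by reverse-complementing
# the query, never the genome.

#' Build a k-mer index over a genome
#'
#' @param genome Named character vector of chromosome sequences.
#' @param k Seed length; must be at least 8 (shorter seeds are too
#'   unspecific to bound candidate sets).
#' @return An object of class `ref_index`.
#' @export
build_index <- function(genome, k = 20L) {
  assert_genome(genome)
  k <- as.integer(k)
  if (k < 8L) stop("k < 8: seed too unspecific", call. = FALSE)
  genome <- toupper(genome)
  lens <- nchar(genome)
  if (any(lens < k)) stop("k exceeds the shortest chromosome", call. = FALSE)
  offset <- cumsum(c(0L, lens[-length(lens)]))
  names(offset) <- names(genome)
  all_kmers <- character(0)
  all_pos <- integer(0)
  for (i in seq_along(genome)) {
    np <- lens[i] - k + 1L
    km <- substring(genome[[i]], seq_len(np), seq_len(np) + k - 1L)
    all_kmers <- c(all_kmers, km)
    all_pos <- c(all_pos, offset[i] + seq_len(np))
  }
  env <- list2env(split(all_pos, all_kmers), hash = TRUE)
  structure(list(genome = genome, k = k, env = env,
                 chrom_names = names(genome), chrom_len = unname(lens),
                 chrom_offset = unname(offset),
                 graw = lapply(unname(genome), charToRaw)),
            class = "ref_index")
}

#' @export
print.ref_index <- function(x, ...) {
  cat(sprintf("<ref_index> %d chromosome(s), %s bp total, k = %d\n",
              length(x$chrom_names),
              format(sum(x$chrom_len), big.mark = ","), x$k))
  invisible(x)
}

# global position -> (chrom index, 1-based position on chrom)
.global_to_local <- function(index, g) {
  ci <- findInterval(g, index$chrom_offset)
  list(chrom = ci, pos = g - index$chrom_offset[ci])
}

# all placements of query `q` on the forward strand, <= max_mm
# mismatches; returns list(ci, start, mm) of parallel vectors
.hits_fwd <- function(index, q, max_mm) {
  L <- nchar(q)
  k <- index$k
  qraw <- charToRaw(q)
  empty <- list(ci = integer(0), start = integer(0), mm = integer(0))
  nseeds <- max_mm + 1L
  if (L >= nseeds * k) {
    starts_g <- integer(0)
    for (i in seq_len(nseeds)) {
      o <- (i - 1L) * k + 1L
      p <- index$env[[substr(q, o, o + k - 1L)]]
      if (!is.null(p)) starts_g <- c(starts_g, p - o + 1L)
    }
    if (!length(starts_g)) return(empty)
    starts_g <- sort(unique(starts_g))
    loc <- .global_to_local(index, starts_g)
    ok <- loc$pos >= 1L & loc$pos + L - 1L <= index$chrom_len[loc$chrom]
    if (!any(ok)) return(empty)
    ci <- loc$chrom[ok]; pos <- loc$pos[ok]
    mm <- integer(length(pos))
    for (j in seq_along(pos)) {
      mm[j] <- sum(index$graw[[ci[j]]][pos[j]:(pos[j] + L - 1L)] != qraw)
    }
    keep <- mm <= max_mm
    list(ci = ci[keep], start = pos[keep], mm = as.integer(mm[keep]))
  } else {
    # dense scan: accumulate mismatch counts per candidate start, one
    # vectorized pass per query offset
    res <- empty
    for (ci in seq_along(index$graw)) {
      g <- index$graw[[ci]]
      np <- length(g) - L + 1L
      if (np < 1L) next
      mm <- integer(np)
      for (i in seq_len(L)) {
        mm <- mm + (g[i:(np + i - 1L)] != qraw[i])
      }
      hit <- which(mm <= max_mm)
      if (length(hit)) {
        res$ci <- c(res$ci, rep(ci, length(hit)))
        res$start <- c(res$start, hit)
        res$mm <- c(res$mm, as.integer(mm[hit]))
      }
    }
    res
  }
}

.EMPTY_HITS <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), strand = character(0),
                          mismatches = integer(0), query_id = character(0),
                          q_from = integer(0), q_to = integer(0),
                          stringsAsFactors = FALSE)

.hits_to_frame <- function(index, fwd, rev, L, query_id) {
  nf <- length(fwd$ci); nr <- length(rev$ci)
  if (nf + nr == 0L) return(.EMPTY_HITS)
  ci <- c(fwd$ci, rev$ci)
  start <- c(fwd$start, rev$start)
  data.frame(chrom = index$chrom_names[ci],
             start = start, end = start + L - 1L,
             strand = rep(c("+", "-"), c(nf, nr)),
             mismatches = c(fwd$mm, rev$mm),
             query_id = query_id, q_from = 1L, q_to = L,
             stringsAsFactors = FALSE)
}

#' Look up a k-mer in the index on both strands
#'
#' @param index A [build_index()] object.
#' @param kmer A string of the index's seed length.
#' @return Data.frame of placements (`chrom`, `start`, `end`, `strand`).
#' @export
lookup_kmer <- function(index, kmer) {
  stopifnot(inherits(index, "ref_index"))
  kmer <- toupper(kmer)
  if (nchar(kmer) != index$k) {
    stop(sprintf("kmer length %d != index k %d", nchar(kmer), index$k),
         call. = FALSE)
  }
  get1 <- function(q) {
    p <- index$env[[q]]
    if (is.null(p)) {
      list(ci = integer(0), start = integer(0), mm = integer(0))
    } else {
      loc <- .global_to_local(index, p)
      list(ci = loc$chrom, start = loc$pos,
           mm = integer(length(p)))
    }
  }
  h <- .hits_to_frame(index, get1(kmer), get1(revcomp(kmer)), index$k, kmer)
  h[order(h$chrom, h$start, h$strand), , drop = FALSE]
}

#' Align a full read, keeping only the single best placement
#'
#' Searches both strands for full-length ungapped placements with at
#' most `max_mismatches` substitutions. Ties are broken by fewest
#' mismatches, then chromosome order in the reference, then lowest
#' start, then `+` before `-` — a fixed order so runs are bit-identical.
#'
#' @param index A [build_index()] object.
#' @param read Read sequence (length at least the index k).
#' @param query_id Identifier carried into the hit.
#' @param max_mismatches Maximum substitutions (default 2).
#' @return One-row data.frame, or `NULL` when no placement qualifies.
#' @export
align_full_read <- function(index, read, query_id = "query",
                            max_mismatches = 2L) {
  stopifnot(inherits(index, "ref_index"))
  read <- toupper(read)
  L <- nchar(read)
  if (L < index$k) stop("read shorter than index k", call. = FALSE)
  h <- .hits_to_frame(index,
                      .hits_fwd(index, read, max_mismatches),
                      .hits_fwd(index, revcomp(read), max_mismatches),
                      L, query_id)
  if (!nrow(h)) return(NULL)
  ci <- match(h$chrom, index$chrom_names)
  ord <- order(h$mismatches, ci, h$start, h$strand == "-")
  h[ord[1L], , drop = FALSE]
}

#' Align an anchor, returning all placements
#'
#' All placements on both strands with at most `max_mismatches`
#' substitutions (default 0: anchors are exact). The attribute
#' `"unique"` is `TRUE` when exactly one placement exists.
#'
#' @param index A [build_index()] object.
#' @param anchor Anchor sequence.
#' @param max_mismatches Maximum substitutions (default 0).
#' @return Data.frame of placements, sorted deterministically, with
#'   attribute `unique`.
#' @export
align_anchor <- function(index, anchor, max_mismatches = 0L) {
  stopifnot(inherits(index, "ref_index"))
  anchor <- toupper(anchor)
  L <- nchar(anchor)
  h <- .hits_to_frame(index,
                      .hits_fwd(index, anchor, max_mismatches),
                      .hits_fwd(index, revcomp(anchor), max_mismatches),
                      L, anchor)
  ci <- match(h$chrom, index$chrom_names)
  h <- h[order(h$mismatches, ci, h$start, h$strand == "-"), , drop = FALSE]
  rownames(h) <- NULL
  attr(h, "unique") <- nrow(h) == 1L
  h
}
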