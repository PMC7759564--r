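# Independent brute-force oracles. These deliberately share no code
# with the implementation paths they check: character-vector scans
# instead of the raw-byte k-mer index, direct table walking instead of
# the register search, string search instead of the primer picker.

# all exact occurrences of `pat` in `subject` (overlapping), via
# fixed-string regex scan
oracle_exact_positions <- function(subject, pat) {
  out <- integer(0)
  from <- 1L
  repeat {
    m <- regexpr(pat, substr(subject, from, nchar(subject)), fixed = TRUE)
    if (m == -1L) break
    out <- c(out, from + m - 1L)
    from <- from + m       # advance one position: overlapping matches
  }
  out
}

# all placements of `q` within `max_mm` mismatches on one strand of one
# chromosome, by per-offset character comparison
oracle_scan_one <- function(chrom_chars, q, max_mm) {
  L <- nchar(q)
  qc <- strsplit(q, "")[[1]]
  np <- length(chrom_chars) - L + 1L
  if (np < 1L) return(integer(0))
  mm <- integer(np)
  for (i in seq_len(L)) {
    mm <- mm + (chrom_chars[i:(np + i - 1L)] != qc[i])
  }
  which(mm <= max_mm)
}

# full both-strand oracle over a genome: data.frame(chrom, start, end,
# strand, mismatches) sorted like align_anchor output
oracle_scan_genome <- function(genome, q, max_mm) {
  rows <- list()
  gsplit <- lapply(genome, function(s) strsplit(s, "")[[1]])
  for (strand in c("+", "-")) {
    qq <- if (strand == "+") q else circsponge::revcomp(q)
    qc <- strsplit(qq, "")[[1]]
    for (ci in seq_along(genome)) {
      chars <- gsplit[[ci]]
      np <- length(chars) - length(qc) + 1L
      if (np < 1L) next
      mm <- integer(np)
      for (i in seq_along(qc)) {
        mm <- mm + (chars[i:(np + i - 1L)] != qc[i])
      }
      hit <- which(mm <= max_mm)
      if (length(hit)) {
        rows[[length(rows) + 1L]] <-
          data.frame(chrom = names(genome)[ci], start = hit,
                     end = hit + length(qc) - 1L, strand = strand,
                     mismatches = mm[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  ci <- match(out$chrom, names(genome))
  out <- out[order(out$mismatches, ci, out$start, out$strand == "-"), ]
  rownames(out) <- NULL
  out
}

# exhaustive breakpoint enumeration: every split p, character-level
# mismatch counts, ranked (mismatches, p), signal checked + then -
oracle_extend <- function(read, geometry, genome, max_mm = 2L, al = 20L) {
  chrom <- geometry$chrom
  seqc <- strsplit(genome[[chrom]], "")[[1]]
  L <- nchar(read)
  rc <- strsplit(read, "")[[1]]
  A2 <- geometry$A2; A3 <- geometry$A3
  best <- NULL
  for (p in al:(L - al)) {
    e <- A3 + p - 1L
    s <- A2 - (L - p) + 1L
    if (s < 3L || e + 2L > length(seqc)) next
    mm <- sum(rc[1:p] != seqc[A3:(A3 + p - 1L)]) +
      sum(rc[(p + 1L):L] != seqc[s:A2])
    if (mm > max_mm) next
    strand <- NULL
    if (paste(seqc[(s - 2L):(s - 1L)], collapse = "") == "AG" &&
        paste(seqc[(e + 1L):(e + 2L)], collapse = "") == "GT") strand <- "+"
    else if (paste(seqc[(s - 2L):(s - 1L)], collapse = "") == "AC" &&
             paste(seqc[(e + 1L):(e + 2L)], collapse = "") == "CT") strand <- "-"
    if (is.null(strand)) next
    if (is.null(best) || mm < best$mismatches) {
      best <- list(s = s, e = e, strand = strand, split = p,
                   mismatches = mm)
    }
  }
  best
}

# in-silico PCR on the circular template: locate the forward primer
# and the reverse-complemented reverse primer on the doubled sequence,
# take the shortest product no longer than one full circle
oracle_pcr_circular <- function(circ_seq, pair) {
  dbl <- paste0(circ_seq, circ_seq)
  L <- nchar(circ_seq)
  f_pos <- oracle_exact_positions(dbl, pair$forward)
  r_site <- circsponge::revcomp(pair$reverse)
  r_pos <- oracle_exact_positions(dbl, r_site)
  products <- integer(0)
  for (f in f_pos) {
    for (r in r_pos) {
      len <- r + nchar(r_site) - f
      if (len > 0 && len <= L) products <- c(products, len)
    }
  }
  if (!length(products)) NA_integer_ else min(products)
}

# in-silico PCR on the linear (unrotated) template
oracle_pcr_linear <- function(lin_seq, pair) {
  f_pos <- oracle_exact_positions(lin_seq, pair$forward)
  r_site <- circsponge::revcomp(pair$reverse)
  r_pos <- oracle_exact_positions(lin_seq, r_site)
  products <- integer(0)
  for (f in f_pos) {
    for (r in r_pos) {
      len <- r + nchar(r_site) - f
      if (len > 0) products <- c(products, len)
    }
  }
  if (!length(products)) NA_integer_ else min(products)
}

# duplex energy of a FULLY complementary, fixed-register duplex by
# direct table walking over the parameter file (no register search)
oracle_full_duplex_energy <- function(mirna, init = 4.1) {
  path <- system.file("extdata", "rna_stack_energies.tsv",
                      package = "circsponge", mustWork = TRUE)
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  e <- setNames(tab$dG37, tab$dinucleotide)
  m <- chartr("T", "U", toupper(mirna))
  chars <- strsplit(m, "")[[1]]
  din <- paste0(chars[-length(chars)], chars[-1])
  sum(e[din]) + init
}

# closed-form equal-variance two-sample t-test p-value
oracle_t_test_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}

# random DNA helper for tests
rand_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# shared small synthetic world used by several test files (built once
# per test run)
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      g <- circsponge::generate_genome(2, c(30000, 20000), seed = 11)
      pl <- circsponge::plant_circrnas(g, 5, c(200, 800), seed = 12)
      lin <- circsponge::plant_linear(pl$genome, 3, c(400, 1200), seed = 13,
                                      existing = pl$transcripts)
      tx <- rbind(pl$transcripts, lin)
      sim <- circsponge::simulate_reads(pl$genome, tx, read_length = 150,
                                        coverage = 20, seed = 14)
      cache <<- list(genome = pl$genome, transcripts = pl$transcripts,
                     all_tx = tx, sim = sim)
    }
    cache
  }
})
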