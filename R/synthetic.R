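# Synthetic data generation.
#
# Every generator is a pure function of its seed (RNG state is saved
# and restored via withr), so downstream stages can be tested
# deterministically without any external data.

#' Generate a random multi-chromosome genome
#'
#' Chromosomes are i.i.d. base strings at the requested GC fraction,
#' named `chr1` ... `chrN`.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chromosome_lengths Integer vector of lengths (bp), one per
#'   chromosome, each at least 1000.
#' @param gc_fraction GC content in `[0, 1]` (default 0.5).
#' @param seed Integer RNG seed.
#' @return Named character vector of chromosome sequences.
#' @export
generate_genome <- function(n_chromosomes, chromosome_lengths,
                            gc_fraction = 0.5, seed = 1L) {
  if (length(chromosome_lengths) != n_chromosomes) {
    stop("chromosome_lengths must have n_chromosomes entries", call. = FALSE)
  }
  if (any(chromosome_lengths < 1000L)) {
    stop("every chromosome must be at least 1000 bp", call. = FALSE)
  }
  if (gc_fraction < 0 || gc_fraction > 1) {
    stop("gc_fraction must be in [0, 1]", call. = FALSE)
  }
  withr::with_seed(seed, {
    genome <- vapply(chromosome_lengths, random_dna, character(1),
                     gc = gc_fraction)
  })
  names(genome) <- paste0("chr", seq_len(n_chromosomes))
  genome
}

# sample one set of non-overlapping intervals (flank-inclusive) with
# bounded retries
.place_loci <- function(chrom_len, n, length_range, max_tries = 1000L) {
  placed <- list()
  occupied <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      len <- resample(length_range[1]:length_range[2])
      ci <- sample(seq_along(chrom_len), 1L,
                   prob = chrom_len / sum(chrom_len))
      if (chrom_len[ci] < len + 4L) next
      s <- sample(3L:(chrom_len[ci] - len - 1L), 1L)
      e <- s + len - 1L
      # keep the 2-bp flanks of different loci disjoint
      clash <- FALSE
      for (p in placed) {
        if (p$chrom_idx == ci && s - 2L <= p$end + 2L && e + 2L >= p$start - 2L) {
          clash <- TRUE; break
        }
      }
      if (!clash) {
        placed[[i]] <- list(chrom_idx = ci, start = s, end = e)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop(sprintf("could not place %d non-overlapping loci after %d tries",
                   n, max_tries), call. = FALSE)
    }
  }
  placed
}

#' Plant circular transcripts with canonical splice flanks
#'
#' Chooses `n` non-overlapping loci (at least 2 bp from every contig
#' edge), edits the genome so each plus-strand locus is flanked by `AG`
#' at `[start-2, start-1]` and `GT` at `[end+1, end+2]` (and `AC`/`CT`
#' for minus-strand loci), and returns the edited genome together with
#' the ground-truth transcript table.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param n Number of circular transcripts to plant.
#' @param length_range `(min, max)` transcript lengths in bp.
#' @param strand_mix Probability that a transcript is on the plus
#'   strand (default 0.5).
#' @param seed Integer RNG seed.
#' @param abundance Relative copy number assigned to every transcript.
#' @return List with `genome` (edited) and `transcripts` (data.frame:
#'   `id`, `chrom`, `start`, `end`, `strand`, `kind`, `abundance`).
#' @export
plant_circrnas <- function(genome, n, length_range = c(150L, 2000L),
                           strand_mix = 0.5, seed = 1L, abundance = 1) {
  assert_genome(genome)
  if (n == 0L) {
    return(list(genome = genome, transcripts = .empty_transcripts()))
  }
  chrom_len <- nchar(genome)
  withr::with_seed(seed, {
    placed <- .place_loci(chrom_len, n, as.integer(length_range))
    strands <- ifelse(stats::runif(n) < strand_mix, "+", "-")
  })
  tx <- data.frame(id = sprintf("circ_%03d", seq_len(n)),
                   chrom = names(genome)[vapply(placed, `[[`, integer(1), "chrom_idx")],
                   start = vapply(placed, `[[`, integer(1), "start"),
                   end = vapply(placed, `[[`, integer(1), "end"),
                   strand = strands, kind = "circular",
                   abundance = abundance, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ch <- tx$chrom[i]
    up <- if (tx$strand[i] == "+") "AG" else "AC"
    dn <- if (tx$strand[i] == "+") "GT" else "CT"
    genome[[ch]] <- replace_bases(genome[[ch]], tx$start[i] - 2L, up)
    genome[[ch]] <- replace_bases(genome[[ch]], tx$end[i] + 1L, dn)
  }
  list(genome = genome, transcripts = tx)
}

#' Plant linear transcripts (intervals only; no genome editing)
#'
#' @inheritParams plant_circrnas
#' @param existing Optional transcript table whose loci (with flanks)
#'   must not be overlapped.
#' @return Transcript data.frame in the same schema as
#'   [plant_circrnas()], `kind = "linear"`.
#' @export
plant_linear <- function(genome, n, length_range = c(300L, 3000L),
                         strand_mix = 0.5, seed = 2L, abundance = 1,
                         existing = NULL) {
  assert_genome(genome)
  if (n == 0L) return(.empty_transcripts())
  chrom_len <- nchar(genome)
  withr::with_seed(seed, {
    placed <- list()
    pre <- list()
    if (!is.null(existing) && nrow(existing)) {
      pre <- lapply(seq_len(nrow(existing)), function(i) {
        list(chrom_idx = match(existing$chrom[i], names(genome)),
             start = existing$start[i], end = existing$end[i])
      })
    }
    all_placed <- pre
    for (i in seq_len(n)) {
      ok <- FALSE
      for (try in seq_len(1000L)) {
        len <- resample(length_range[1]:length_range[2])
        ci <- sample(seq_along(chrom_len), 1L,
                     prob = chrom_len / sum(chrom_len))
        if (chrom_len[ci] < len + 4L) next
        s <- sample(3L:(chrom_len[ci] - len - 1L), 1L)
        e <- s + len - 1L
        clash <- FALSE
        for (p in all_placed) {
          if (p$chrom_idx == ci && s - 2L <= p$end + 2L &&
              e + 2L >= p$start - 2L) { clash <- TRUE; break }
        }
        if (!clash) {
          placed[[i]] <- list(chrom_idx = ci, start = s, end = e)
          all_placed[[length(all_placed) + 1L]] <- placed[[i]]
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place linear transcripts", call. = FALSE)
    }
    strands <- ifelse(stats::runif(n) < strand_mix, "+", "-")
  })
  data.frame(id = sprintf("lin_%03d", seq_len(n)),
             chrom = names(genome)[vapply(placed, `[[`, integer(1), "chrom_idx")],
             start = vapply(placed, `[[`, integer(1), "start"),
             end = vapply(placed, `[[`, integer(1), "end"),
             strand = strands, kind = "linear",
             abundance = abundance, stringsAsFactors = FALSE)
}

.empty_transcripts <- function() {
  data.frame(id = character(0), chrom = character(0), start = integer(0),
              end = integer(0), strand = character(0), kind = character(0),
              abundance = numeric(0), stringsAsFactors = FALSE)
}

#' Simulate sequencing reads from planted transcripts
#'
#' Circular transcripts are sampled from the doubled (concatenated)
#' unit sequence truncated to one rotation, so read start positions are
#' uniform on the circle and the fraction of junction-spanning reads is
#' `(read_length - 1) / circ_length`. Linear transcripts yield only
#' colinear reads. With `rnase_r = TRUE`, linear abundance is multiplied
#' by `linear_survival` before sampling (RNase R spares circles).
#' Substitution errors are i.i.d. at `error_rate`; no indels. Each read
#' is emitted in a random orientation (strand-agnostic library).
#'
#' @param genome Named character vector of chromosome sequences (after
#'   planting).
#' @param transcripts Transcript table from [plant_circrnas()] /
#'   [plant_linear()].
#' @param read_length Read length in bp (default 150).
#' @param coverage Mean per-base coverage per unit abundance.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param paired Emit read pairs (`/1`, `/2`) from fragments of
#'   `fragment_length`; mates are written as independent records.
#' @param fragment_length Fragment length for paired mode (capped at
#'   the transcript length).
#' @param rnase_r Apply RNase R enrichment.
#' @param linear_survival Fraction of linear molecules surviving
#'   RNase R.
#' @param seed Integer RNG seed.
#' @return List with `reads` (named character vector) and `truth`
#'   (data.frame: `read_id`, `source_id`, `kind`, `spans_junction`).
#' @export
simulate_reads <- function(genome, transcripts, read_length = 150L,
                           coverage = 20, error_rate = 0, paired = FALSE,
                           fragment_length = 300L, rnase_r = FALSE,
                           linear_survival = 0.05, seed = 1L) {
  assert_genome(genome)
  if (error_rate < 0 || error_rate >= 1) {
    stop("error_rate must be in [0, 1)", call. = FALSE)
  }
  if (nrow(transcripts)) {
    tx_len <- transcripts$end - transcripts$start + 1L
    if (read_length > min(tx_len)) {
      stop(sprintf("read_length (%d) exceeds the shortest transcript (%d bp)",
                   read_length, min(tx_len)), call. = FALSE)
    }
  }
  reads <- character(0); ids <- character(0)
  src <- character(0); kind <- character(0); spans <- logical(0)
  withr::with_seed(seed, {
    for (i in seq_len(nrow(transcripts))) {
      t <- transcripts[i, ]
      M <- t$end - t$start + 1L
      unit <- substr(genome[[t$chrom]], t$start, t$end)
      if (t$strand == "-") unit <- revcomp(unit)
      ab <- t$abundance
      if (t$kind == "linear" && rnase_r) ab <- ab * linear_survival
      n_frag <- round(ab * coverage * M /
                        (read_length * (if (paired) 2L else 1L)))
      if (n_frag < 1L) next
      if (t$kind == "circular") {
        dbl <- paste0(unit, unit)
        starts <- sample.int(M, n_frag, replace = TRUE)
        flen <- max(min(fragment_length, M), read_length)
        if (paired) {
          m1 <- substring(dbl, starts, starts + read_length - 1L)
          m2 <- revcomp(substring(dbl, starts + flen - read_length,
                                  starts + flen - 1L))
          sp1 <- starts <= M & starts + read_length - 1L > M
          sp2 <- starts + flen - read_length <= M & starts + flen - 1L > M
          new_reads <- c(rbind(m1, m2))
          new_spans <- c(rbind(sp1, sp2))
          new_ids <- paste0(t$id, "_", rep(seq_len(n_frag), each = 2L),
                            "/", rep(1:2, n_frag))
        } else {
          new_reads <- substring(dbl, starts, starts + read_length - 1L)
          new_spans <- starts + read_length - 1L > M
          new_ids <- paste0(t$id, "_", seq_len(n_frag))
        }
      } else {
        flen <- max(min(fragment_length, M), read_length)
        span_max <- if (paired) flen else read_length
        starts <- sample.int(M - span_max + 1L, n_frag, replace = TRUE)
        if (paired) {
          m1 <- substring(unit, starts, starts + read_length - 1L)
          m2 <- revcomp(substring(unit, starts + flen - read_length,
                                  starts + flen - 1L))
          new_reads <- c(rbind(m1, m2))
          new_ids <- paste0(t$id, "_", rep(seq_len(n_frag), each = 2L),
                            "/", rep(1:2, n_frag))
        } else {
          new_reads <- substring(unit, starts, starts + read_length - 1L)
          new_ids <- paste0(t$id, "_", seq_len(n_frag))
        }
        new_spans <- rep(FALSE, length(new_reads))
      }
      # random sequencing orientation
      flip <- stats::runif(length(new_reads)) < 0.5
      if (any(flip)) new_reads[flip] <- revcomp(new_reads[flip])
      # i.i.d. substitution errors
      if (error_rate > 0) {
        for (j in seq_along(new_reads)) {
          nerr <- stats::rbinom(1L, read_length, error_rate)
          if (nerr > 0L) {
            pos <- sample.int(read_length, nerr)
            chars <- strsplit(new_reads[j], "")[[1]]
            for (p in pos) {
              chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
            }
            new_reads[j] <- paste(chars, collapse = "")
          }
        }
      }
      reads <- c(reads, new_reads); ids <- c(ids, new_ids)
      src <- c(src, rep(t$id, length(new_reads)))
      kind <- c(kind, rep(t$kind, length(new_reads)))
      spans <- c(spans, new_spans)
    }
  })
  names(reads) <- ids
  list(reads = reads,
       truth = data.frame(read_id = ids, source_id = src, kind = kind,
                          spans_junction = spans, stringsAsFactors = FALSE))
}

#' Simulate miRNAs with guaranteed seed sites in target sequences
#'
#' Each simulated miRNA is 21-23 nt; by construction its positions 2-8
#' are the reverse complement of a site inside its designated target
#' (targets are cycled through in order). With
#' `full_complement = TRUE` (default) the entire miRNA is the reverse
#' complement of a target window, so the planted site also carries a
#' strongly hybridizing context for duplex-energy scoring; with
#' `FALSE` only the seed region is planted and the rest of the miRNA is
#' random.
#'
#' @param targets Named character vector of target sequences (e.g.
#'   circRNA sequences).
#' @param n Number of miRNAs.
#' @param seed Integer RNG seed.
#' @param full_complement Plant full-length complementarity.
#' @return List with `mirnas` (named character vector, DNA alphabet)
#'   and `truth` (data.frame: `mirna_id`, `target_id`, `site_start`,
#'   `site_end`).
#' @export
simulate_mirnas <- function(targets, n, seed = 1L, full_complement = TRUE) {
  if (!length(targets)) stop("targets must be non-empty", call. = FALSE)
  if (n == 0L) {
    return(list(mirnas = stats::setNames(character(0), character(0)),
                truth = data.frame(mirna_id = character(0),
                                   target_id = character(0),
                                   site_start = integer(0),
                                   site_end = integer(0),
                                   stringsAsFactors = FALSE)))
  }
  targets <- norm_dna(targets)
  mirnas <- character(0); mid <- character(0)
  tid <- character(0); ss <- integer(0); se <- integer(0)
  withr::with_seed(seed, {
    for (i in seq_len(n)) {
      ti <- ((i - 1L) %% length(targets)) + 1L
      target <- targets[[ti]]
      len <- resample(21:23)
      if (nchar(target) < len) {
        warning(sprintf("target '%s' shorter than miRNA site; skipped",
                        names(targets)[ti]), call. = FALSE)
        next
      }
      a <- sample.int(nchar(target) - len + 1L, 1L)
      window <- substr(target, a, a + len - 1L)
      if (full_complement) {
        m <- revcomp(window)
      } else {
        m <- random_dna(len)
        # positions 2-8 pair target positions (a+len-8)..(a+len-2):
        # m[2..8] <- revcomp(target[a+len-8 .. a+len-2])
        site7 <- substr(target, a + len - 8L, a + len - 2L)
        m <- replace_bases(m, 2L, revcomp(site7))
      }
      mirnas <- c(mirnas, m)
      mid <- c(mid, sprintf("sim-miR-%03d", i))
      tid <- c(tid, names(targets)[ti])
      ss <- c(ss, a); se <- c(se, a + len - 1L)
    }
  })
  names(mirnas) <- mid
  list(mirnas = mirnas,
       truth = data.frame(mirna_id = mid, target_id = tid,
                          site_start = ss, site_end = se,
                          stringsAsFactors = FALSE))
}

#' Synthesize a 3'UTR carrying binding sites for a set of miRNAs
#'
#' Embeds the reverse complement of each miRNA at evenly spaced,
#' non-overlapping positions in a random backbone, so every miRNA has a
#' strongly complementary site in the UTR (emulating a shared mRNA
#' target in a sponge network).
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param length UTR length in bp.
#' @param gc GC fraction of the random backbone.
#' @param seed Integer RNG seed.
#' @return A single named character vector of length 1 (name `"utr"`).
#' @export
simulate_utr <- function(mirnas, length = 1000L, gc = 0.5, seed = 1L) {
  need <- sum(nchar(mirnas)) + 10L * (length(mirnas) + 1L)
  if (length < need) {
    stop(sprintf("UTR length %d too short for %d sites", length,
                 length(mirnas)), call. = FALSE)
  }
  withr::with_seed(seed, {
    utr <- random_dna(length, gc)
    if (base::length(mirnas)) {
      slots <- floor(seq(10L, length - max(nchar(mirnas)) - 10L,
                         length.out = base::length(mirnas)))
      for (i in seq_along(mirnas)) {
        utr <- replace_bases(utr, slots[i], revcomp(mirnas[[i]]))
      }
    }
  })
  c(utr = utr)
}

#' Simulate a dual-luciferase plate
#'
#' Control wells have Firefly/Renilla (F/R) ratios centered at 1.0 and
#' experimental wells at `effect`; noise is multiplicative lognormal
#' with coefficient of variation `cv` (mean exactly the center, so
#' `cv = 0` gives exact ratios).
#'
#' @param effect Experimental F/R center in `(0, 1]` (1 = no
#'   suppression).
#' @param cv Coefficient of variation of the multiplicative noise.
#' @param n_replicates Wells per group (at least 2; assays typically
#'   use 3).
#' @param seed Integer RNG seed.
#' @return An object of class `luciferase_plate`: list with `control`
#'   and `experimental` data.frames (columns `F`, `R`).
#' @export
simulate_luciferase_plate <- function(effect = 0.5, cv = 0.05,
                                      n_replicates = 3L, seed = 1L) {
  if (effect <= 0 || effect > 1) stop("effect must be in (0, 1]", call. = FALSE)
  if (n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  lnoise <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
  }
  withr::with_seed(seed, {
    R_ctrl <- 1e4 * lnoise(n_replicates, cv)
    F_ctrl <- 1.0 * R_ctrl * lnoise(n_replicates, cv)
    R_exp <- 1e4 * lnoise(n_replicates, cv)
    F_exp <- effect * R_exp * lnoise(n_replicates, cv)
  })
  structure(list(control = data.frame(F = F_ctrl, R = R_ctrl),
                 experimental = data.frame(F = F_exp, R = R_exp),
                 labels = c(control = "control",
                            experimental = "experimental")),
            class = "luciferase_plate")
}
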