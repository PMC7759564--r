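test_that("generate_genome honors lengths, GC boundary and determinism", {
  g <- generate_genome(2, c(10000, 5000), gc_fraction = 0.5, seed = 1)
  expect_identical(names(g), c("chr1", "chr2"))
  expect_identical(unname(nchar(g)), c(10000L, 5000L))
  expect_identical(g, generate_genome(2, c(10000, 5000), seed = 1))
  gc1 <- generate_genome(1, 1000, gc_fraction = 1.0, seed = 3)
  expect_true(grepl("^[GC]+$", gc1[[1]]))
  at1 <- generate_genome(1, 1000, gc_fraction = 0, seed = 3)
  expect_true(grepl("^[AT]+$", at1[[1]]))
  expect_error(generate_genome(2, 10000), "n_chromosomes")
  expect_error(generate_genome(1, 500), "1000")
  expect_error(generate_genome(1, 1000, gc_fraction = 1.5), "\\[0, 1\\]")
})

test_that("plant_circrnas writes canonical splice flanks for every locus", {
  g <- generate_genome(1, 50000, seed = 5)
  pl <- plant_circrnas(g, 10, c(150, 400), seed = 6)
  tx <- pl$transcripts
  expect_identical(nrow(tx), 10L)
  for (i in seq_len(nrow(tx))) {
    ch <- pl$genome[[tx$chrom[i]]]
    up <- substr(ch, tx$start[i] - 2, tx$start[i] - 1)
    dn <- substr(ch, tx$end[i] + 1, tx$end[i] + 2)
    if (tx$strand[i] == "+") {
      expect_identical(up, "AG"); expect_identical(dn, "GT")
    } else {
      expect_identical(up, "AC"); expect_identical(dn, "CT")
    }
    expect_true(splice_signal_ok(pl$genome, tx$chrom[i], tx$start[i],
                                 tx$end[i], tx$strand[i]))
  }
  # loci do not overlap
  o <- order(tx$start)
  s <- tx$start[o]; e <- tx$end[o]
  expect_true(all(s[-1] > e[-length(e)]))
})

test_that("plant_circrnas fixed-length and degenerate cases", {
  g <- generate_genome(1, 20000, seed = 7)
  pl <- plant_circrnas(g, 5, c(177, 177), seed = 8)
  expect_true(all(pl$transcripts$end - pl$transcripts$start + 1L == 177L))
  pl0 <- plant_circrnas(g, 0)
  expect_identical(pl0$genome, g)
  expect_identical(nrow(pl0$transcripts), 0L)
  # impossible placement: more circs than fit
  expect_error(plant_circrnas(g, 100, c(15000, 19000), seed = 9),
               "non-overlapping")
})

test_that("simulate_reads constructs junction reads and conserves counts", {
  w <- small_world()
  sim <- w$sim
  expect_identical(length(sim$reads), nrow(sim$truth))
  expect_identical(names(sim$reads), sim$truth$read_id)
  # an error-free junction read equals genome[end-k+1..end]+genome[start..]
  circ <- w$transcripts[w$transcripts$strand == "+", ][1, ]
  jr <- sim$truth$read_id[sim$truth$source_id == circ$id &
                            sim$truth$spans_junction]
  expect_true(length(jr) >= 1)
  ch <- w$genome[[circ$chrom]]
  unit <- substr(ch, circ$start, circ$end)
  dbl <- paste0(unit, unit)
  hit <- FALSE
  for (r in sim$reads[jr]) {
    for (q in c(r, revcomp(r))) {
      if (grepl(q, dbl, fixed = TRUE)) { hit <- TRUE; break }
    }
  }
  expect_true(hit)
  # linear reads never span a junction
  expect_false(any(sim$truth$spans_junction[sim$truth$kind == "linear"]))
})

test_that("RNase R boundary: linear_survival = 0 removes linear reads", {
  w <- small_world()
  sim <- simulate_reads(w$genome, w$all_tx, read_length = 150,
                        coverage = 10, rnase_r = TRUE,
                        linear_survival = 0, seed = 3)
  expect_false(any(sim$truth$kind == "linear"))
  expect_true(any(sim$truth$kind == "circular"))
})

test_that("junction-spanning fraction matches (L-1)/M enumeration", {
  # uniform start positions on a circle of length M: exactly L-1 of
  # the M starts give a junction-spanning read
  g <- generate_genome(1, 10000, seed = 31)
  pl <- plant_circrnas(g, 1, c(1000, 1000), seed = 32)
  M <- 1000L; L <- 150L
  sim <- simulate_reads(pl$genome, pl$transcripts, read_length = L,
                        coverage = 10000 * L / M, seed = 33)
  n <- nrow(sim$truth)
  expect_gt(n, 9000)
  p_hat <- mean(sim$truth$spans_junction)
  p_exp <- (L - 1) / M
  # binomial 4-sigma envelope at n draws
  tol <- 4 * sqrt(p_exp * (1 - p_exp) / n)
  expect_lt(abs(p_hat - p_exp), tol)
})

test_that("read_length longer than the shortest transcript errors", {
  g <- generate_genome(1, 20000, seed = 41)
  pl <- plant_circrnas(g, 2, c(100, 120), seed = 42)
  expect_error(simulate_reads(pl$genome, pl$transcripts,
                              read_length = 150, coverage = 5),
               "shortest transcript")
})

test_that("paired mode emits both mates and keeps the truth table in sync", {
  g <- generate_genome(1, 30000, seed = 51)
  pl <- plant_circrnas(g, 2, c(400, 600), seed = 52)
  sim <- simulate_reads(pl$genome, pl$transcripts, read_length = 100,
                        coverage = 10, paired = TRUE,
                        fragment_length = 250, seed = 53)
  expect_identical(length(sim$reads), nrow(sim$truth))
  expect_true(all(grepl("/[12]$", sim$truth$read_id)))
  expect_identical(sum(grepl("/1$", sim$truth$read_id)),
                   sum(grepl("/2$", sim$truth$read_id)))
})

test_that("simulate_mirnas plants a seed site on its designated target", {
  set.seed(7)
  targets <- c(circA = rand_seq(500), circB = rand_seq(800))
  ms <- simulate_mirnas(targets, 4, seed = 61)
  expect_identical(length(ms$mirnas), 4L)
  expect_true(all(nchar(ms$mirnas) >= 21 & nchar(ms$mirnas) <= 23))
  for (i in seq_len(4)) {
    sites <- find_seed_sites(ms$mirnas[[i]],
                             targets[[ms$truth$target_id[i]]])
    # guaranteed 7mer-m8 or better by construction
    expect_true(any(sites$seed_class %in% c("7mer-m8", "8mer")))
  }
  # seed-only mode satisfies the same guarantee
  ms2 <- simulate_mirnas(targets, 4, seed = 62, full_complement = FALSE)
  for (i in seq_len(4)) {
    sites <- find_seed_sites(ms2$mirnas[[i]],
                             targets[[ms2$truth$target_id[i]]])
    expect_true(any(sites$seed_class %in% c("7mer-m8", "8mer")))
  }
  # determinism and the n = 0 boundary
  expect_identical(ms$mirnas, simulate_mirnas(targets, 4, seed = 61)$mirnas)
  expect_identical(length(simulate_mirnas(targets, 0)$mirnas), 0L)
})

test_that("chance 7mer matches on random sequences follow 994 * 4^-7", {
  # a fixed 7mer planted in the miRNA seed occurs in an unrelated
  # random 1000-nt sequence ~ Binomial(994, 4^-7) times
  set.seed(77)
  m <- simulate_mirnas(c(t = rand_seq(300)), 1, seed = 78)$mirnas[[1]]
  site7 <- revcomp(substr(m, 2, 8))
  counts <- vapply(1:200, function(i) {
    length(oracle_exact_positions(rand_seq(1000), site7))
  }, integer(1))
  expected <- 200 * 994 * 4^-7
  sd_tot <- sqrt(200 * 994 * 4^-7)   # Poisson-scale spread
  expect_lt(abs(sum(counts) - expected), 5 * sd_tot)
})

test_that("luciferase plate centers, noise and determinism behave", {
  p0 <- simulate_luciferase_plate(effect = 1.0, cv = 0, n_replicates = 3,
                                  seed = 1)
  expect_equal(p0$control$F / p0$control$R, rep(1, 3))
  expect_equal(p0$experimental$F / p0$experimental$R, rep(1, 3))
  p1 <- simulate_luciferase_plate(effect = 0.5, cv = 0.1, n_replicates = 3,
                                  seed = 2)
  expect_identical(p1$control,
                   simulate_luciferase_plate(0.5, 0.1, 3, seed = 2)$control)
  expect_error(simulate_luciferase_plate(effect = 0), "\\(0, 1\\]")
  expect_error(simulate_luciferase_plate(n_replicates = 1), ">= 2")
})
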