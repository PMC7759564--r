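# build a target carrying an exact site for `mirna` at position `at`,
# optionally with the A1 anchor adenine
plant_site <- function(backbone, mirna, at, full = TRUE) {
  site <- if (full) revcomp(mirna) else revcomp(substr(mirna, 2, 8))
  replace_bases(backbone, at, site)
}

test_that("seed-site classes follow the TargetScan conventions", {
  m <- "TCACAGTGGTACGTACGTACG"   # positions 2-8: CACAGTG
  core <- revcomp(substr(m, 2, 7))    # matches miRNA 2-7
  m8c <- revcomp(substr(m, 8, 8))
  not_m8 <- setdiff(c("C", "G"), m8c)[1]   # breaks m8 pairing, not an A
  # 8mer: m8 match 5' of core, A across position 1 at its 3' end
  t8 <- paste0("TTTTT", m8c, core, "A", "TTTTT")
  s8 <- find_seed_sites(m, t8)
  expect_identical(s8$seed_class, "8mer")
  # 7mer-m8: m8 match, no A
  t7m8 <- paste0("TTTTT", m8c, core, "C", "TTTTT")
  expect_identical(find_seed_sites(m, t7m8)$seed_class, "7mer-m8")
  # 7mer-A1: A only
  t7a1 <- paste0("TTTTT", not_m8, core, "A", "TTTTT")
  expect_identical(find_seed_sites(m, t7a1)$seed_class, "7mer-A1")
  # 6mer: neither
  t6 <- paste0("TTTTT", not_m8, core, "C", "TTTTT")
  expect_identical(find_seed_sites(m, t6)$seed_class, "6mer")
  # U/T equivalence: an RNA-alphabet miRNA gives identical calls
  expect_identical(find_seed_sites(chartr("T", "U", m), t8)$seed_class,
                   "8mer")
  # target with no complement of the core
  expect_identical(nrow(find_seed_sites(m, strrep("A", 50))), 0L)
})

test_that("site counts agree with a brute-force scan on random targets", {
  set.seed(91)
  m <- "TGAGGTAGTAGGTTGTATAGT"
  core <- revcomp(substr(m, 2, 7))
  for (i in 1:100) {
    tg <- rand_seq(1000)
    got <- find_seed_sites(m, tg)
    exp_pos <- oracle_exact_positions(tg, core)
    expect_identical(nrow(got), length(exp_pos))
  }
})

test_that("duplex_mfe matches the table-walking oracle on perfect duplexes", {
  set.seed(92)
  for (i in 1:25) {
    m <- rand_seq(20)
    target <- revcomp(m)
    expect_equal(duplex_mfe(m, target), oracle_full_duplex_energy(m),
                 tolerance = 1e-9)
  }
  # zero Watson-Crick pairs -> 0 (fails any negative threshold)
  expect_identical(duplex_mfe(strrep("A", 20), strrep("A", 30)), 0)
  # GC-rich perfect duplex is strictly stronger than AU-only
  gc <- strrep("GC", 10); au <- strrep("AT", 10)
  expect_lt(duplex_mfe(gc, revcomp(gc)), duplex_mfe(au, revcomp(au)))
})

test_that("duplex_mfe is register-shift invariant under padding", {
  set.seed(93)
  m <- rand_seq(21)
  site <- revcomp(m)
  base <- duplex_mfe(m, site)
  expect_lt(base, -20)
  for (pad in c(1, 5, 12)) {
    padded <- paste0(strrep("A", pad), site, strrep("A", pad))
    # A-padding could pair with U/T in the miRNA; use C padding against
    # a G-free check instead: assert energy never worsens (padding can
    # only add registers)
    expect_lte(duplex_mfe(m, padded), base + 1e-9)
  }
})

test_that("site_score maps classes and rejects unknown ones", {
  expect_identical(site_score("8mer"), 100)
  expect_identical(site_score("7mer-m8"), 95)
  expect_identical(site_score("7mer-A1"), 90)
  expect_identical(site_score("6mer"), 80)
  expect_error(site_score("9mer"), "unknown seed class")
})

test_that("build_network applies both thresholds and the length filter", {
  set.seed(94)
  m <- rand_seq(22)
  circ_ok <- plant_site(rand_seq(1096), m, 300)
  circ_long <- plant_site(rand_seq(2500), m, 700)
  net <- build_network(c(small = circ_ok, big = circ_long),
                       c(miR1 = m))
  expect_identical(net$edges$source_id, "small")
  expect_identical(net$edges$edge_kind, "circ-miR")
  expect_true(all(net$edges$mfe < -20))
  expect_true(all(net$edges$site_score >= 90))
  # the long circ is excluded before scoring
  expect_false("big" %in% net$edges$source_id)
  # seed-only site (weak context) passes score but fails the energy
  weak <- plant_site(strrep("A", 1000), m, 400, full = FALSE)
  net2 <- build_network(c(w = weak), c(miR1 = m))
  expect_identical(nrow(net2$edges), 0L)
  expect_true(any(net2$hits$site_score >= 90))   # scored, not passed
})

test_that("threshold monotonicity holds", {
  set.seed(95)
  ms <- vapply(1:3, function(i) rand_seq(21 + i %% 3), character(1))
  names(ms) <- paste0("miR", 1:3)
  circs <- c(cA = rand_seq(800), cB = rand_seq(1500), cC = rand_seq(1900))
  for (mi in names(ms)) {
    for (ci in names(circs)) {
      at <- sample(100:500, 1)
      circs[[ci]] <- plant_site(circs[[ci]], ms[[mi]],
                                at + 30 * match(mi, names(ms)))
    }
  }
  base <- build_network(circs, ms)
  # tightening circ_max_len never adds edges
  tight <- build_network(circs, ms, circ_max_len = 1000)
  ek <- function(n) paste(n$edges$source_id, n$edges$target_id)
  expect_true(all(ek(tight) %in% ek(base)))
  # relaxing the energy threshold never removes edges
  relaxed <- build_network(circs, ms, mfe_threshold = -5)
  expect_true(all(ek(base) %in% ek(relaxed)))
  # no emitted edge ever violates a threshold (post-hoc audit)
  for (n in list(base, tight, relaxed)) {
    expect_true(all(n$edges$site_score >= 90))
  }
  expect_true(all(base$edges$mfe < -20))
})

test_that("a three-miRNA, two-circ, one-UTR world yields the sponge topology", {
  set.seed(96)
  ms <- c(miR1 = rand_seq(21), miR2 = rand_seq(22), miR3 = rand_seq(23))
  c1 <- rand_seq(1000); c2 <- rand_seq(1300)
  for (i in seq_along(ms)) {
    c1 <- plant_site(c1, ms[[i]], 100 + 60 * i)
    c2 <- plant_site(c2, ms[[i]], 150 + 60 * i)
  }
  utr <- simulate_utr(ms, 1000, seed = 97)
  net <- build_network(c(circ1 = c1, circ2 = c2), ms, utr)
  expect_identical(sum(net$nodes$kind == "mRNA"), 1L)
  expect_identical(sum(net$nodes$kind == "miRNA"), 3L)
  expect_gte(sum(net$nodes$kind == "circRNA"), 2L)
  # bipartite edges only: circ-miR and miR-mRNA
  expect_setequal(unique(net$edges$edge_kind), c("circ-miR", "miR-mRNA"))
  expect_identical(sum(net$edges$edge_kind == "circ-miR"), 6L)
  expect_identical(sum(net$edges$edge_kind == "miR-mRNA"), 3L)
  # deduplication: one edge per (source, target)
  expect_false(any(duplicated(paste(net$edges$source_id,
                                    net$edges$target_id))))
  # export round-trip
  dir <- withr::local_tempdir()
  write_network(net, dir, graphml = TRUE)
  nodes <- read.table(file.path(dir, "nodes.tsv"), header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE)
  expect_setequal(nodes$id, net$nodes$id)
  expect_true(file.exists(file.path(dir, "network.graphml")))
})
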