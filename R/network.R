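# circRNA-miRNA-mRNA sponge-network construction: miRNA seed-site
# discovery (TargetScan-style site classes), a simplified
# nearest-neighbor RNA duplex energy, site scoring, thresholding, and
# network export.

.pkg_cache <- new.env(parent = emptyenv())

#' Nearest-neighbor RNA stacking parameters
#'
#' The 16 Watson-Crick RNA/RNA dinucleotide stack free energies
#' (kcal/mol at 37 degrees C, Turner/Freier set), shipped as a
#' plain-text table and indexed by the two adjacent top-strand bases
#' read 5' to 3'.
#'
#' @return Named numeric vector (names are RNA dinucleotides).
#' @export
rna_stack_energies <- function() {
  if (is.null(.pkg_cache$stacks)) {
    path <- system.file("extdata", "rna_stack_energies.tsv",
                        package = "circsponge", mustWork = TRUE)
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
    .pkg_cache$stacks <- stats::setNames(df$dG37, df$dinucleotide)
  }
  .pkg_cache$stacks
}

# Watson-Crick partner in RNA alphabet (no wobble)
RNA_WC <- c(A = "U", U = "A", G = "C", C = "G")

#' Find miRNA seed-match sites on a target
#'
#' Scans the target for Watson-Crick complements of miRNA positions 2-7
#' (the 6mer core) and classifies each site: `7mer-m8` adds pairing of
#' position 8 (the target base 5' of the core), `7mer-A1` adds an `A`
#' across from miRNA position 1 (the target base 3' of the core),
#' `8mer` has both. `U` and `T` are treated as equivalent; overlapping
#' sites are all reported.
#'
#' @param mirna miRNA sequence (RNA or DNA alphabet), length >= 8.
#' @param target Target sequence, length >= 8.
#' @return Data.frame with `site_start`, `site_end` (1-based on the
#'   target, spanning the matched pattern) and `seed_class`.
#' @export
find_seed_sites <- function(mirna, target) {
  m <- norm_dna(mirna); tg <- norm_dna(target)
  if (nchar(m) < 8L || nchar(tg) < 8L) {
    stop("miRNA and target must each be at least 8 nt", call. = FALSE)
  }
  core <- revcomp(substr(m, 2L, 7L))             # 6mer core site
  m8c <- complement_base(chartr("U", "T", substr(m, 8L, 8L)))
  hits <- Biostrings::matchPattern(core, Biostrings::DNAString(tg))
  empty <- data.frame(site_start = integer(0), site_end = integer(0),
                      seed_class = character(0), stringsAsFactors = FALSE)
  if (!length(hits)) return(empty)
  t0 <- Biostrings::start(hits)
  L <- nchar(tg)
  out <- lapply(t0, function(t) {
    has_m8 <- t > 1L && substr(tg, t - 1L, t - 1L) == m8c
    has_a1 <- t + 6L <= L && substr(tg, t + 6L, t + 6L) == "A"
    if (has_m8 && has_a1) {
      data.frame(site_start = t - 1L, site_end = t + 6L,
                 seed_class = "8mer", stringsAsFactors = FALSE)
    } else if (has_m8) {
      data.frame(site_start = t - 1L, site_end = t + 5L,
                 seed_class = "7mer-m8", stringsAsFactors = FALSE)
    } else if (has_a1) {
      data.frame(site_start = t, site_end = t + 6L,
                 seed_class = "7mer-A1", stringsAsFactors = FALSE)
    } else {
      data.frame(site_start = t, site_end = t + 5L,
                 seed_class = "6mer", stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Simplified RNA duplex hybridization energy
#'
#' Best ungapped hybridization register of the miRNA against the
#' (antiparallel) target context, scored as the sum of Watson-Crick
#' nearest-neighbor stack energies over consecutively paired positions
#' plus a duplex-initiation penalty of +4.1 kcal/mol; unpaired
#' positions contribute nothing and G:U wobbles are not paired. A
#' duplex with no stacked pair scores 0 (no hybridization), and the
#' returned value is capped at 0 so weak duplexes never score positive.
#'
#' @param mirna miRNA sequence (RNA or DNA alphabet).
#' @param target_context Target region to hybridize against (at least
#'   as long as pairing requires; shorter contexts simply restrict the
#'   registers).
#' @param init Duplex initiation penalty (kcal/mol).
#' @return Free energy in kcal/mol (<= 0).
#' @export
duplex_mfe <- function(mirna, target_context, init = 4.1) {
  stacks <- rna_stack_energies()
  m <- chartr("T", "U", norm_dna(mirna, rna_to_dna = FALSE))
  tg <- chartr("T", "U", norm_dna(target_context, rna_to_dna = FALSE))
  mc <- strsplit(m, "")[[1]]
  tc <- rev(strsplit(tg, "")[[1]])   # antiparallel: reverse the target
  lm <- length(mc); lt <- length(tc)
  best <- Inf
  for (s in (-(lm - 1L)):(lt - 1L)) {
    i0 <- max(1L, 1L - s); i1 <- min(lm, lt - s)
    if (i1 - i0 < 1L) next
    idx <- i0:i1
    paired <- RNA_WC[mc[idx]] == tc[idx + s]
    paired[is.na(paired)] <- FALSE
    np <- length(paired)
    if (np < 2L) next
    stacked <- paired[-np] & paired[-1L]
    if (!any(stacked)) next
    din <- paste0(mc[idx[-np]], mc[idx[-1L]])
    e <- sum(stacks[din[stacked]]) + init
    if (e < best) best <- e
  }
  if (!is.finite(best)) return(0)
  min(0, best)
}

#' Site score for a seed-match class
#'
#' A declared 0-100 stand-in for target-prediction scores:
#' `8mer = 100`, `7mer-m8 = 95`, `7mer-A1 = 90`, `6mer = 80`
#' (configurable).
#'
#' @param seed_class One of `"8mer"`, `"7mer-m8"`, `"7mer-A1"`,
#'   `"6mer"`.
#' @param score_map Named numeric mapping.
#' @return Numeric score in `[0, 100]`.
#' @export
site_score <- function(seed_class,
                       score_map = c(`8mer` = 100, `7mer-m8` = 95,
                                     `7mer-A1` = 90, `6mer` = 80)) {
  if (!all(seed_class %in% names(score_map))) {
    stop(sprintf("unknown seed class: %s",
                 paste(setdiff(seed_class, names(score_map)),
                       collapse = ", ")), call. = FALSE)
  }
  unname(score_map[seed_class])
}

# duplex context window for a core site starting at t on a target of
# length L, covering the full antiparallel footprint of the miRNA
.site_context <- function(target, core_start, mirna_len) {
  L <- nchar(target)
  substr(target, max(1L, core_start + 7L - mirna_len),
         min(L, core_start + 6L))
}

#' Build the circRNA-miRNA-mRNA sponge network
#'
#' Scores every miRNA against every circRNA shorter than
#' `circ_max_len` (longer circles are excluded before scoring) and
#' every supplied mRNA 3'UTR. An edge is emitted iff the best site
#' passes both thresholds: duplex energy strictly below
#' `mfe_threshold` and site score at least `score_threshold`. Edges are
#' deduplicated per (source, target) keeping the lowest energy.
#'
#' @param circ_seqs Named character vector of circRNA sequences.
#' @param mirna_seqs Named character vector of miRNA sequences.
#' @param utr_seqs Optional named character vector of mRNA 3'UTR
#'   sequences.
#' @param mfe_threshold Energy threshold in kcal/mol (default -20;
#'   strict `<`).
#' @param score_threshold Site-score threshold (default 90; inclusive
#'   `>=`).
#' @param circ_max_len circRNAs with length >= this are excluded
#'   (default 2000).
#' @param score_map Passed to [site_score()].
#' @return List with `nodes` (data.frame: `id`, `kind`), `edges`
#'   (data.frame: `source_id`, `target_id`, `edge_kind`, `mfe`,
#'   `site_score`, `seed_class`) and `hits` (all scored sites before
#'   thresholding).
#' @export
build_network <- function(circ_seqs, mirna_seqs, utr_seqs = NULL,
                          mfe_threshold = -20, score_threshold = 90,
                          circ_max_len = 2000L,
                          score_map = c(`8mer` = 100, `7mer-m8` = 95,
                                        `7mer-A1` = 90, `6mer` = 80)) {
  stopifnot(is.character(mirna_seqs), !is.null(names(mirna_seqs)))
  circ_seqs <- norm_dna(circ_seqs)
  mirna_seqs <- norm_dna(mirna_seqs)
  keep <- nchar(circ_seqs) < circ_max_len
  circ_seqs <- circ_seqs[keep]
  if (!is.null(utr_seqs)) utr_seqs <- norm_dna(utr_seqs)

  targets <- c(as.list(circ_seqs), as.list(utr_seqs %||% character(0)))
  target_kind <- c(rep("circRNA", length(circ_seqs)),
                   rep("mRNA_3UTR", length(utr_seqs %||% character(0))))
  names(target_kind) <- names(targets)

  hits <- list()
  for (mi in names(mirna_seqs)) {
    m <- mirna_seqs[[mi]]
    for (ti in names(targets)) {
      sites <- find_seed_sites(m, targets[[ti]])
      if (!nrow(sites)) next
      for (r in seq_len(nrow(sites))) {
        core_start <- if (sites$seed_class[r] %in% c("8mer", "7mer-m8")) {
          sites$site_start[r] + 1L
        } else {
          sites$site_start[r]
        }
        ctx <- .site_context(targets[[ti]], core_start, nchar(m))
        hits[[length(hits) + 1L]] <-
          data.frame(mirna_id = mi, target_id = ti,
                     target_kind = target_kind[[ti]],
                     site_start = sites$site_start[r],
                     site_end = sites$site_end[r],
                     seed_class = sites$seed_class[r],
                     site_score = site_score(sites$seed_class[r], score_map),
                     mfe = duplex_mfe(m, ctx),
                     stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(mirna_id = character(0), target_id = character(0),
               target_kind = character(0), site_start = integer(0),
               site_end = integer(0), seed_class = character(0),
               site_score = numeric(0), mfe = numeric(0),
               stringsAsFactors = FALSE)

  pass <- hits[hits$mfe < mfe_threshold &
                 hits$site_score >= score_threshold, , drop = FALSE]
  edges <- data.frame(source_id = character(0), target_id = character(0),
                      edge_kind = character(0), mfe = numeric(0),
                      site_score = numeric(0), seed_class = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(pass)) {
    key <- paste(pass$mirna_id, pass$target_id, sep = "\r")
    best <- do.call(rbind, lapply(split(pass, key), function(g) {
      g[order(g$mfe, g$site_start)[1L], , drop = FALSE]
    }))
    edges <- data.frame(
      source_id = ifelse(best$target_kind == "circRNA",
                         best$target_id, best$mirna_id),
      target_id = ifelse(best$target_kind == "circRNA",
                         best$mirna_id, best$target_id),
      edge_kind = ifelse(best$target_kind == "circRNA",
                         "circ-miR", "miR-mRNA"),
      mfe = best$mfe, site_score = best$site_score,
      seed_class = best$seed_class, stringsAsFactors = FALSE)
    edges <- edges[order(edges$edge_kind, edges$source_id,
                         edges$target_id), , drop = FALSE]
    rownames(edges) <- NULL
  }
  node_ids <- unique(c(edges$source_id, edges$target_id))
  kind_of <- function(id) {
    if (id %in% names(mirna_seqs)) "miRNA"
    else if (!is.null(utr_seqs) && id %in% names(utr_seqs)) "mRNA"
    else "circRNA"
  }
  nodes <- data.frame(id = node_ids,
                      kind = vapply(node_ids, kind_of, character(1)),
                      stringsAsFactors = FALSE,
                      row.names = NULL)
  list(nodes = nodes, edges = edges, hits = hits)
}

#' Export a sponge network
#'
#' Writes Cytoscape-importable node and edge TSV files and, optionally,
#' GraphML.
#'
#' @param network Result of [build_network()].
#' @param dir Output directory (created if needed).
#' @param graphml Also write `network.graphml`.
#' @return The directory, invisibly.
#' @export
write_network <- function(network, dir, graphml = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(network$nodes, file.path(dir, "nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(network$edges, file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (graphml && nrow(network$nodes)) {
    g <- igraph::graph_from_data_frame(
      network$edges[, c("source_id", "target_id", "edge_kind", "mfe",
                        "site_score")],
      directed = FALSE, vertices = network$nodes)
    igraph::write_graph(g, file.path(dir, "network.graphml"),
                        format = "graphml")
  }
  invisible(dir)
}
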