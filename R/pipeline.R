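# Pipeline orchestration: one configuration object, JSON (de)serialization,
# and subcommands chaining the stages on declared files.

#' Pipeline configuration
#'
#' Returns the full default configuration, with any field overridable
#' by name. Detection defaults: 20-nt anchors aligned exactly, 2
#' mismatches for linear placement and breakpoint extension, at least 2
#' junction reads per call, 100 kb maximum span. Network defaults:
#' duplex energy < -20 kcal/mol, site score >= 90, circRNAs < 2000 bp.
#'
#' @param ... Named overrides of any default field.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # detection
    anchor_length = 20L,
    max_mismatches_linear = 2L,
    max_mismatches_anchor = 0L,
    max_mismatches_extend = 2L,
    min_reads = 2L,
    max_span = 100000L,
    require_unique_anchors = TRUE,
    # network thresholds
    mfe_threshold = -20,
    score_threshold = 90,
    circ_max_len = 2000L,
    # synthetic world
    seed = 1L,
    n_chromosomes = 2L,
    chromosome_lengths = c(120000L, 80000L),
    gc_fraction = 0.5,
    n_circ = 20L,
    circ_length_range = c(150L, 2000L),
    n_linear = 10L,
    linear_length_range = c(300L, 3000L),
    read_length = 150L,
    coverage = 25,
    error_rate = 0,
    paired = FALSE,
    fragment_length = 300L,
    rnase_r = FALSE,
    linear_survival = 0.05,
    n_mirnas = 3L,
    utr_length = 1000L,
    # luciferase
    luc_effect = 0.5,
    luc_cv = 0.05,
    luc_replicates = 3L
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop(sprintf("unknown config field(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read a pipeline configuration from JSON
#'
#' Fields present in the file override the defaults of
#' [pipeline_config()].
#'
#' @param path JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration as JSON
#'
#' @param config A `pipeline_config`.
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

.log <- function(con, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run pipeline stages
#'
#' Subcommands: `simulate` (genome, transcripts, reads, truth, miRNAs,
#' UTR), `detect` (circRNA table + BED), `stats` (QC, categories,
#' density, lengths), `network` (nodes/edges TSV), `primers` (primer
#' report), `luciferase` (plate + report), or `all` (simulate through
#' primers on one config). Every stage reads and writes only files
#' under `outdir`; the configuration and a run log are written next to
#' the artifacts so a run is reproducible from its output directory
#' alone.
#'
#' @param step One of `simulate`, `detect`, `stats`, `network`,
#'   `primers`, `luciferase`, `all`.
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @return Invisibly, a named list of artifact paths written.
#' @export
run_pipeline <- function(step = c("all", "simulate", "detect", "stats",
                                  "network", "primers", "luciferase"),
                         config = pipeline_config(), outdir) {
  step <- match.arg(step)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logcon <- file(file.path(outdir, "run.log"), "a")
  on.exit(close(logcon))
  write_pipeline_config(config, file.path(outdir, "config.json"))
  .log(logcon, "circsponge %s | step=%s seed=%d",
       as.character(utils::packageVersion("circsponge")), step, config$seed)
  artifacts <- list()
  p <- function(f) file.path(outdir, f)

  steps <- if (step == "all") {
    c("simulate", "detect", "stats", "network", "primers")
  } else step

  for (st in steps) {
    if (st == "simulate") {
      genome <- generate_genome(config$n_chromosomes,
                                config$chromosome_lengths,
                                config$gc_fraction, seed = config$seed)
      planted <- plant_circrnas(genome, config$n_circ,
                                config$circ_length_range,
                                seed = config$seed + 1L)
      lin <- plant_linear(planted$genome, config$n_linear,
                          config$linear_length_range,
                          seed = config$seed + 2L,
                          existing = planted$transcripts)
      tx <- rbind(planted$transcripts, lin)
      sim <- simulate_reads(planted$genome, tx,
                            read_length = config$read_length,
                            coverage = config$coverage,
                            error_rate = config$error_rate,
                            paired = config$paired,
                            fragment_length = config$fragment_length,
                            rnase_r = config$rnase_r,
                            linear_survival = config$linear_survival,
                            seed = config$seed + 3L)
      write_sequences(planted$genome, p("genome.fasta"), "fasta")
      utils::write.table(tx, p("transcripts.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      write_sequences(sim$reads, p("reads.fastq"), "fastq")
      utils::write.table(sim$truth, p("truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      circ_tx <- tx[tx$kind == "circular", , drop = FALSE]
      circ_seqs <- stats::setNames(vapply(seq_len(nrow(circ_tx)), function(i) {
        circ_sequence(planted$genome,
                      circ_locus(circ_tx$chrom[i], circ_tx$start[i],
                                 circ_tx$end[i], circ_tx$strand[i]))
      }, character(1)), circ_tx$id)
      mir <- simulate_mirnas(circ_seqs, config$n_mirnas,
                             seed = config$seed + 4L)
      write_sequences(mir$mirnas, p("mirnas.fasta"), "fasta")
      utr <- simulate_utr(mir$mirnas, config$utr_length,
                          seed = config$seed + 5L)
      write_sequences(utr, p("utr.fasta"), "fasta")
      .log(logcon, "simulate: %d chroms, %d circ + %d linear transcripts, %d reads, %d miRNAs",
           config$n_chromosomes, nrow(planted$transcripts), nrow(lin),
           length(sim$reads), length(mir$mirnas))
      artifacts$simulate <- p(c("genome.fasta", "transcripts.tsv",
                                "reads.fastq", "truth.tsv",
                                "mirnas.fasta", "utr.fasta"))
    } else if (st == "detect") {
      genome <- read_sequences(p("genome.fasta"), "fasta")
      reads <- read_sequences(p("reads.fastq"), "fastq")
      rec <- call_circrnas(reads, genome, config)
      write_circ_table(rec, p("circrnas.tsv"))
      circ_table_to_bed(rec, p("circrnas.bed"))
      .log(logcon, "detect: %d reads -> %d mapped, %d junction reads, %d circRNAs (min_reads=%d)",
           length(reads), attr(rec, "n_mapped"),
           attr(rec, "n_junction_reads"), nrow(rec), config$min_reads)
      artifacts$detect <- p(c("circrnas.tsv", "circrnas.bed"))
    } else if (st == "stats") {
      rec <- read_circ_table(p("circrnas.tsv"))
      genome <- read_sequences(p("genome.fasta"), "fasta")
      reads <- read_sequences(p("reads.fastq"), "fastq")
      qc <- qc_ratios(list(raw_reads = length(reads),
                           clean_reads = length(reads)))
      cats <- bsj_categories(rec)
      dens <- chromosome_density(rec, nchar(genome) / 1e6)
      lens <- length_distribution(rec)
      utils::write.table(cats, p("bsj_categories.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(dens$per_chrom, p("chrom_density.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(lens$histogram, p("length_histogram.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      summary <- c(sprintf("n_circ\t%d", nrow(rec)),
                   sprintf("clean_ratio\t%.2f", qc$clean_ratio),
                   sprintf("genome_ratio\t%.2f", dens$genome_ratio),
                   sprintf("fraction_over_10k\t%.4f",
                           lens$fraction_over_10k))
      writeLines(summary, p("stats_summary.tsv"))
      .log(logcon, "stats: %d records summarized", nrow(rec))
      artifacts$stats <- p(c("bsj_categories.tsv", "chrom_density.tsv",
                             "length_histogram.tsv", "stats_summary.tsv"))
    } else if (st == "network") {
      rec <- read_circ_table(p("circrnas.tsv"))
      genome <- read_sequences(p("genome.fasta"), "fasta")
      mirnas <- read_sequences(p("mirnas.fasta"), "fasta",
                               rna_to_dna = TRUE)
      utr <- read_sequences(p("utr.fasta"), "fasta")
      circ_seqs <- stats::setNames(vapply(seq_len(nrow(rec)), function(i) {
        circ_sequence(genome, parse_circ_id(rec$circ_id[i]))
      }, character(1)), rec$circ_id)
      net <- build_network(circ_seqs, mirnas, utr,
                           mfe_threshold = config$mfe_threshold,
                           score_threshold = config$score_threshold,
                           circ_max_len = config$circ_max_len)
      write_network(net, outdir, graphml = TRUE)
      .log(logcon, "network: %d nodes, %d edges", nrow(net$nodes),
           nrow(net$edges))
      artifacts$network <- p(c("nodes.tsv", "edges.tsv",
                               "network.graphml"))
    } else if (st == "primers") {
      rec <- read_circ_table(p("circrnas.tsv"))
      genome <- read_sequences(p("genome.fasta"), "fasta")
      circ_seqs <- stats::setNames(vapply(seq_len(nrow(rec)), function(i) {
        circ_sequence(genome, parse_circ_id(rec$circ_id[i]))
      }, character(1)), rec$circ_id)
      rep <- design_primer_report(circ_seqs)
      utils::write.table(rep, p("primers.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      templates <- stats::setNames(vapply(circ_seqs, rotate_template,
                                          character(1)),
                                   paste0(names(circ_seqs), "|rotated"))
      write_sequences(templates, p("templates.fasta"), "fasta")
      .log(logcon, "primers: %d circRNAs, %d designs ok", length(circ_seqs),
           sum(rep$note == ""))
      artifacts$primers <- p(c("primers.tsv", "templates.fasta"))
    } else if (st == "luciferase") {
      plate <- simulate_luciferase_plate(config$luc_effect, config$luc_cv,
                                         config$luc_replicates,
                                         seed = config$seed + 6L)
      write_plate_csv(plate, p("plate.csv"))
      res <- luciferase_relative_activity(plate)
      out <- c(sprintf("control_mean\t%.6f", res$means[["control"]]),
               sprintf("experimental_mean\t%.6f",
                       res$means[["experimental"]]),
               sprintf("p_value\t%.6g", res$p_value),
               sprintf("significance\t%s", res$significance))
      writeLines(out, p("luciferase_report.tsv"))
      .log(logcon, "luciferase: effect=%.2f p=%.3g %s", config$luc_effect,
           res$p_value, res$significance)
      artifacts$luciferase <- p(c("plate.csv", "luciferase_report.tsv"))
    }
  }
  invisible(artifacts)
}
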