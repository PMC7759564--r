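---
title: "circsponge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circsponge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circsponge)
```

## The problem

Circular RNAs (circRNAs) arise from back-splicing: a downstream splice
donor is joined to an upstream splice acceptor, producing a covalently
closed loop with no free ends. In an RNA-seq library the only direct
evidence for a circle is a *back-splice junction (BSJ) read* — a read
whose 5' part matches the genomic *end* of the circle and whose 3' part
matches its genomic *start*, i.e. the two halves align in reversed
genomic order. circsponge implements the complete desk-side analysis
around this signal: junction calling, catalog statistics, a
circRNA–miRNA–mRNA "sponge" network, validation-primer templates, and
dual-luciferase interaction statistics, together with a synthetic-data
generator so every stage is testable with no downloads.

## The caller

For each read that fails full-length linear alignment (ungapped, at
most `max_mismatches_linear = 2` substitutions) the caller:

1. extracts the first and last `anchor_length = 20` nt as anchors;
2. aligns each anchor exactly (`max_mismatches_anchor = 0`) and keeps
   reads whose 3'-end anchor (positions `A1..A2`) lands strictly
   upstream of the 5'-end anchor (`A3..A4`) on the same chromosome,
   within `max_span = 100` kb — the reversed order that distinguishes a
   back-splice from a linear splice;
3. extends both anchors to a split position `p`: the read prefix
   `read[1..p]` must align from `A3` ending at `e = A3 + p - 1`, the
   suffix must align ending at `A2` starting at `s = A2 - (L - p) + 1`,
   with at most `max_mismatches_extend = 2` substitutions in total;
4. requires the canonical splice signal at the candidate locus
   `(s, e)`: `AG` immediately before `s` and `GT` immediately after `e`
   on the plus strand, or `AC`/`CT` at the same positions for a
   minus-strand circle (the same GT-AG rule read in forward genome
   coordinates). The matching signal decides the reported strand.

Reads sequenced in the reverse orientation are handled by running the
identical forward-strand procedure on the reverse complement of the
read; this is algebraically the same as pairing minus-strand anchor
placements and keeps the extension arithmetic in one coordinate
system.

Candidates are aggregated by locus; distinct supporting reads are
counted as `bsj_reads`; loci with fewer than `min_reads = 2` supporting
reads are dropped (configurable down to 1 — catalogs routinely report
single-read junctions as well, so both behaviors are reachable).
Records are named `"<bsj_reads>-<length>"` with
`length = end - start + 1`, and expression is normalized as
`log2(bsj_reads / total_mapped_reads * 1e6)`, where the denominator
counts linearly placed reads plus all distinct junction reads. No
pseudocount is needed because support is at least 1. Zero mapped reads
is reported as a warning with `norm_expr` unset.

### Breakpoint tie-breaking

Several split positions can satisfy all constraints — genuinely, when
the genome carries two GT-AG-consistent junctions a few bases apart
(alternative back-splicing), and spuriously, when a shifted split with
1–2 tolerated mismatches happens to hit a coincidental `AG`/`GT` pair.
The caller ranks splits by **fewest mismatches first**, breaking exact
ties by smallest `p`. Ranking by position alone lets a coincidental
flank at a smaller `p` beat the true zero-mismatch split often enough
to shift roughly 1 call in 10 by a few bases at error rate 0; ranking
by mismatches first removes this failure mode entirely while still
resolving true ties deterministically.

### What "unmapped" means

The pipeline uses its own ungapped aligner (a k-mer hash index with
pigeonhole seed-and-extend, exact for queries of length at least
`(m + 1) * k` at `m` mismatches, and a dense per-offset scan for
shorter queries). "Unmapped" therefore means: no full-length ungapped
placement within 2 substitutions. This is a declared, reproducible
stand-in for an external aligner's scoring, not a reproduction of it;
every alignment operation is checked against brute-force scans in the
test suite.

## Signature statistics

* `qc_ratios`: clean/raw and mapped/clean percentages, rounded to two
  decimals (the print precision of sequencing QC tables). Q30 is
  accepted as an input column but never recomputed, since raw qualities
  need not be available.
* `bsj_categories`: the five support classes `>100`, `10–100`, `4–9`,
  `2–3`, `<2`. Edges are inclusive on both ends with `>100` meaning
  at least 101 — the only assignment under which the five prose labels
  partition the non-negative integers.
* `chromosome_density`: per-chromosome counts and circRNAs-per-Mb, for
  all records and for the high-support subset (`bsj_reads > 4`), plus
  the genome-wide count-to-size ratio.
* `length_distribution`: histogram over
  `{100, 200, 400, 700, 1000, 2000, 4000, 10000}` with the fraction of
  records of at least 10 kb reported separately.

## The sponge network

Targeting is scored with a deliberately simple, fully specified pair of
models rather than by wrapping external predictors:

* **Seed sites** (TargetScan-style): a 6mer core is a Watson–Crick
  complement of miRNA positions 2–7 on the target; `7mer-m8` adds
  pairing of position 8, `7mer-A1` adds an `A` across from position 1,
  `8mer` has both. U and T are equivalent; overlapping sites are all
  reported; G:U wobble is out of scope.
* **Duplex energy**: the best ungapped antiparallel register of the
  miRNA against the site context, scored as the sum of the 16
  Watson–Crick RNA/RNA nearest-neighbor stack energies (standard
  Turner/Freier values, shipped as a plain-text table) over
  consecutively paired positions, plus a +4.1 kcal/mol initiation
  penalty. Unpaired positions contribute nothing, so adding
  complementarity can only lower the energy. A duplex with no stacked
  pair scores 0, and results are capped at 0. This reproduces the
  *logic* of hybridization screening; published energies from full
  secondary-structure programs (which model loops, bulges and wobbles)
  are not reproducible by this model and are deliberately not
  acceptance targets.
* **Site score**: a declared 0–100 stand-in for target-prediction
  scores (`8mer` 100, `7mer-m8` 95, `7mer-A1` 90, `6mer` 80,
  configurable), since published "score" scales are tool-specific.

Edges require energy strictly below −20 kcal/mol **and** score at
least 90; circRNAs of 2000 bp or longer are excluded before scoring
(sponge prediction on very long circles is dominated by spurious
sites). Edges are deduplicated per (source, target) keeping the lowest
energy. Note the thresholds' practical consequence: a bare seed match
contributes at most ~6 stacks (≈ −15 kcal/mol + 4.1), so only sites
with substantial 3'-supplementary complementarity pass — which is why
the miRNA simulator defaults to planting full-length complements.

## Primer design

The divergent template is the circle rotated at its midpoint
(`h = floor(L/2)`; "half sequence" leaves the split point open — the
midpoint is chosen and parameterized), so the junction sits between
positions `L - h` and `L - h + 1`. Divergent primers are picked
flanking that point; their amplicon contains the junction, maps to the
genome as two blocks, and can never exceed one full circle. Convergent
primers are picked on the unrotated sequence; their amplicon excludes
the junction and also amplifies the linear precursor. The picker
itself is declared plumbing: length 18–27 nt, GC 40–60%, Wallace-rule
melting temperatures within 3 °C — published primer sequences depend on
the underlying genome and are not reproduction targets. Expected
product sizes are verified against in-silico PCR (string search of the
primers on the doubled circle) in the tests.

## Luciferase statistics

Per well, the Firefly/Renilla ratio cancels transfection efficiency.
The mean control ratio ("average1") is the unit: both groups are
divided by it, so the control mean is 1 by construction and the
experimental mean estimates the suppression effect directly. Groups
are compared with a two-sided two-sample t-test; the equal-variance
form is the default because the plain "t-test" convention in reporter
assays is Student's, with the Welch variant exposed
(`var_equal = FALSE`). Annotation: `**` for p ≤ 0.01, `*` for
0.01 < p ≤ 0.05, from the computed p only. A degenerate plate with
zero variance in both groups reports p = 1 when the means agree (the
null is exactly reproduced) — reachable only at `cv = 0`.

## The synthetic world

The generator states one world and the tests live in it:

* genomes: i.i.d. bases at a configurable GC fraction (default 0.5),
  at least 1 kb per chromosome; the default detection scenario is 2
  chromosomes, 200 kb total — a toy-scale stand-in for a multi-Gb,
  51-chromosome genome;
* planted circles: 150–2000 bp (the length band over which both
  detection and network analysis operate), non-overlapping including
  their 2-bp flanks, flanked by the canonical signal of their strand;
* reads: 150 bp (the sequencing design being emulated), coverage 25 per
  planted transcript so every circle carries junction reads with
  margin, substitution errors only (the extension model is ungapped, so
  indel errors would only lower sensitivity, not corrupt calls),
  random read orientation, constant quality;
* circular reads are drawn from the doubled unit sequence truncated to
  one rotation, so start positions are uniform on the circle and the
  junction-spanning fraction is exactly `(L - 1) / M`;
* RNase R is modeled as multiplying linear abundance by a survival
  fraction before sampling;
* miRNAs: 21–23 nt with positions 2–8 reverse-complementary to a site
  in their designated target (guaranteed seed site), full-length
  complementary by default (see above);
* luciferase plates: multiplicative lognormal noise with the stated
  coefficient of variation, mean exactly at the group center, three
  replicates.

What a green test does **not** establish: performance on real
libraries with quality-dependent errors, indels, PCR duplicates,
multi-mapping repeat structure, incomplete genomes, or expression-level
confounding; nor agreement with full-thermodynamics hybridization
tools. The synthetic world is designed to make the *logic* of every
stage falsifiable, not to imitate a sequencer.

## Numerical and engineering choices

* Coordinates are 1-based and inclusive everywhere; `end - start + 1`
  is the printed "predicted length" convention, and BED export is the
  single place where 0-based half-open conversion happens.
* All generators restore the RNG state (`withr::with_seed`), so a
  pipeline run is a pure function of its configuration.
* Alignment ties are broken by (mismatches, reference chromosome
  order, start, `+` before `-`); records are sorted by (chromosome,
  start, end) — runs are byte-identical.
* Mates of a read pair are processed as independent reads; a junction
  supported by both mates counts once per mate.
* The caller's index uses `k = anchor_length` so anchor lookup is a
  single exact hash probe.
* Configuration is JSON; every run writes its configuration and a log
  next to its artifacts.

## Known limitations

Single-sample design (no differential expression); no non-GT-AG
signals; no circular-vs-linear isoform ratio; no gapped alignment; no
dimer/hairpin screening in the primer picker; the duplex model ignores
loops, bulges and G:U pairs by construction.
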