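# Divergent and convergent validation-primer design.
#
# Divergent primers must amplify across the back-splice junction, which
# does not exist in the linear genome; the amplification template is
# therefore built by rotating the circRNA sequence at its midpoint so
# the junction sits in the middle of the template. Convergent primers
# are picked on the unrotated sequence and amplify linear and circular
# templates alike. The picker is deliberately simple plumbing: primer
# length 18-27 nt, GC 40-60%, Wallace-rule melting temperatures within
# 3 degrees C of each other.

#' GC fraction of a sequence
#'
#' @param seq DNA string.
#' @return Fraction of `G`/`C` bases.
#' @export
gc_content <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  mean(chars %in% c("G", "C"))
}

#' Wallace-rule melting temperature
#'
#' `Tm = 2 (A+T) + 4 (G+C)` degrees C — the standard quick
#' approximation for short oligos.
#'
#' @param seq DNA string.
#' @return Temperature in degrees C.
#' @export
primer_tm <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  gc <- sum(chars %in% c("G", "C"))
  2 * (length(chars) - gc) + 4 * gc
}

#' Rotate a circRNA sequence for divergent-primer design
#'
#' Joins the 3' half of the sequence to its 5' end: with
#' `h = floor(L/2)`, returns `seq[h+1..L] + seq[1..h]`. The back-splice
#' junction then sits between positions `L - h` and `L - h + 1` of the
#' rotated template.
#'
#' @param circ_seq circRNA sequence (length >= 2).
#' @return Rotated template string of the same length.
#' @export
rotate_template <- function(circ_seq) {
  L <- nchar(circ_seq)
  if (L < 2L) stop("sequence must be at least 2 nt", call. = FALSE)
  h <- L %/% 2L
  paste0(substr(circ_seq, h + 1L, L), substr(circ_seq, 1L, h))
}

# default picker parameters
.primer_params <- function(params = list()) {
  utils::modifyList(list(len_range = c(18L, 27L), gc_range = c(0.40, 0.60),
                         tm_diff = 3, search_window = 200L,
                         min_product = 60L), params)
}

# first acceptable primer in a window, scanning outward from `from`
# toward `to` (step direction inferred); returns list(start, end, seq)
# on the template top strand, or NULL
.pick_primer <- function(template, from, to, params, partner_tm = NULL) {
  L <- nchar(template)
  starts <- if (from <= to) from:to else from:to
  for (st in starts) {
    for (len in params$len_range[1]:params$len_range[2]) {
      en <- st + len - 1L
      if (st < 1L || en > L) next
      p <- substr(template, st, en)
      gc <- gc_content(p)
      if (gc < params$gc_range[1] || gc > params$gc_range[2]) next
      if (!is.null(partner_tm) &&
          abs(primer_tm(p) - partner_tm) > params$tm_diff) next
      return(list(start = st, end = en, seq = p))
    }
  }
  NULL
}

.design_pair <- function(template, junction, pair_kind, params) {
  p <- .primer_params(params)
  L <- nchar(template)
  if (pair_kind == "divergent") {
    # forward entirely 5' of the junction, reverse binding site
    # entirely 3' of it, so the amplicon contains the junction
    f_lo <- max(1L, junction - p$search_window)
    r_hi <- min(L, junction + p$search_window)
    f_starts <- f_lo:(junction - p$len_range[1] + 1L)
    r_starts <- (junction + 1L):r_hi
  } else {
    # both primers inside the unrotated sequence; the junction (between
    # position L and 1 on the circle) is outside any amplicon
    f_starts <- 1L:min(p$search_window, L)
    r_starts <- max(1L, L - p$search_window):(L - p$len_range[1] + 1L)
  }
  for (fs in f_starts) {
    fwd <- .pick_primer(template, fs, fs, p)
    if (is.null(fwd)) next
    if (pair_kind == "divergent" && fwd$end > junction) next
    for (rs in rev(r_starts)) {
      len_ok <- p$len_range[1]:p$len_range[2]
      for (len in len_ok) {
        re <- rs + len - 1L
        if (re > L) next
        if (pair_kind == "divergent" && rs <= junction) next
        if (re - fwd$start + 1L < p$min_product) next
        site <- substr(template, rs, re)
        gc <- gc_content(site)
        if (gc < p$gc_range[1] || gc > p$gc_range[2]) next
        if (abs(primer_tm(site) - primer_tm(fwd$seq)) > p$tm_diff) next
        return(structure(list(forward = fwd$seq,
                              reverse = revcomp(site),
                              pair_kind = pair_kind,
                              expected_product_bp = re - fwd$start + 1L,
                              spans_junction = pair_kind == "divergent",
                              fwd_start = fwd$start, fwd_end = fwd$end,
                              rev_start = rs, rev_end = re,
                              tm_forward = primer_tm(fwd$seq),
                              tm_reverse = primer_tm(site)),
                         class = "primer_pair"))
      }
    }
  }
  stop(sprintf("%s primer design failed: no primer pair satisfies the ",
               pair_kind),
       "length/GC/Tm constraints in the search window", call. = FALSE)
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s\n  F: %s (Tm %.0f)\n  R: %s (Tm %.0f)\n  product: %d bp%s\n",
              x$pair_kind, x$forward, x$tm_forward, x$reverse,
              x$tm_reverse, x$expected_product_bp,
              if (x$spans_junction) " (spans junction)" else ""))
  invisible(x)
}

#' Design divergent primers for circRNA validation
#'
#' Primers are picked on the rotated template (see [rotate_template()])
#' flanking the junction point, so the expected amplicon contains the
#' back-splice junction and can only be produced from the circular
#' template; the product is always at most the circRNA length.
#'
#' @param circ_seq circRNA sequence.
#' @param params Optional list overriding the picker defaults
#'   (`len_range`, `gc_range`, `tm_diff`, `search_window`,
#'   `min_product`).
#' @return A `primer_pair` (fields `forward`, `reverse`, `pair_kind`,
#'   `expected_product_bp`, `spans_junction`, primer coordinates on the
#'   template).
#' @export
design_divergent <- function(circ_seq, params = list()) {
  circ_seq <- toupper(circ_seq)
  L <- nchar(circ_seq)
  p <- .primer_params(params)
  if (L < 2L * p$len_range[1] + p$min_product) {
    stop("circRNA too short for divergent primer design", call. = FALSE)
  }
  template <- rotate_template(circ_seq)
  junction <- L - L %/% 2L        # junction between J and J+1
  .design_pair(template, junction, "divergent", params)
}

#' Design convergent primers for circRNA validation
#'
#' Primers are picked on the unrotated sequence, so the amplicon never
#' contains the back-splice junction and is also produced from the
#' linear precursor.
#'
#' @inheritParams design_divergent
#' @return A `primer_pair`.
#' @export
design_convergent <- function(circ_seq, params = list()) {
  circ_seq <- toupper(circ_seq)
  L <- nchar(circ_seq)
  p <- .primer_params(params)
  if (L < 2L * p$len_range[1] + p$min_product) {
    stop("circRNA too short for convergent primer design", call. = FALSE)
  }
  .design_pair(circ_seq, NA_integer_, "convergent", params)
}

#' Primer report for a set of circRNAs
#'
#' Designs divergent and convergent pairs per circRNA; failures are
#' reported in the `note` column rather than aborting the batch.
#'
#' @param circ_seqs Named character vector of circRNA sequences.
#' @param params Picker overrides (see [design_divergent()]).
#' @return Data.frame: `circ_id`, `kind`, `forward`, `reverse`,
#'   `product_bp`, `note`.
#' @export
design_primer_report <- function(circ_seqs, params = list()) {
  rows <- list()
  for (id in names(circ_seqs)) {
    for (kind in c("divergent", "convergent")) {
      fn <- if (kind == "divergent") design_divergent else design_convergent
      pr <- tryCatch(fn(circ_seqs[[id]], params), error = function(e) e)
      rows[[length(rows) + 1L]] <- if (inherits(pr, "error")) {
        data.frame(circ_id = id, kind = kind, forward = NA_character_,
                   reverse = NA_character_, product_bp = NA_integer_,
                   note = conditionMessage(pr), stringsAsFactors = FALSE)
      } else {
        data.frame(circ_id = id, kind = kind, forward = pr$forward,
                   reverse = pr$reverse,
                   product_bp = pr$expected_product_bp, note = "",
                   stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
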