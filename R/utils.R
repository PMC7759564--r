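# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")
DNA_COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse-complement DNA strings
#'
#' Vectorized reverse complement over plain character strings
#' (`A`/`C`/`G`/`T`/`N` alphabet).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  if (length(x) == 0L) return(character(0))
  # pure-R on purpose: short-string calls dominate the caller's hot
  # path and XStringSet construction costs more than the work itself
  x <- chartr("ACGTUNacgtun", "TGCAANtgcaan", x)
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(b) unname(DNA_COMP[b])

# sample() without the scalar trap: always samples from the vector
resample <- function(x, n = 1L, ...) x[sample.int(length(x), n, ...)]

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# replace bases of `s` starting at 1-based `start`
replace_bases <- function(s, start, replacement) {
  substr(s, start, start + nchar(replacement) - 1L) <- replacement
  s
}

# uppercase and optionally map RNA U to DNA T
norm_dna <- function(x, rna_to_dna = TRUE) {
  x <- toupper(x)
  if (rna_to_dna) x <- chartr("U", "T", x)
  x
}

assert_genome <- function(genome) {
  if (!is.character(genome) || length(genome) == 0L || is.null(names(genome)) ||
      anyNA(genome) || any(names(genome) == "")) {
    stop("`genome` must be a non-empty named character vector of sequences",
         call. = FALSE)
  }
  invisible(genome)
}

# standardize reads input (named character vector or data.frame) to a
# data.frame with columns read_id, seq
as_read_frame <- function(reads) {
  if (is.data.frame(reads)) {
    if (!all(c("read_id", "seq") %in% names(reads))) {
      stop("reads data.frame needs columns `read_id` and `seq`", call. = FALSE)
    }
    data.frame(read_id = as.character(reads$read_id),
               seq = toupper(as.character(reads$seq)),
               stringsAsFactors = FALSE)
  } else if (is.character(reads)) {
    if (is.null(names(reads))) names(reads) <- sprintf("read_%06d", seq_along(reads))
    data.frame(read_id = names(reads), seq = toupper(unname(reads)),
               stringsAsFactors = FALSE)
  } else {
    stop("reads must be a named character vector or a data.frame", call. = FALSE)
  }
}
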