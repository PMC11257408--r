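#' Construct a reference sequence
#'
#' A reference sequence is the unit every downstream stage works against: a
#' named RNA string (DNA is transcribed on ingest) plus optional features in
#' 0-based half-open coordinates, mimicking e.g. a 47S pre-rRNA with its
#' ETS/ITS/mature-rRNA segments.
#'
#' @param name Identifier for the sequence.
#' @param sequence Character scalar over A/C/G/U (or DNA; T is transcribed).
#' @param features Optional data.frame with columns `label`, `start`, `end`
#'   (0-based half-open) and `strand` ("+", "-" or "*").
#'
#' @return An object of class `ref_seq`: a list with elements `name`,
#'   `sequence` and `features`.
#' @export
reference_sequence <- function(name, sequence, features = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- as_rna(sequence)
  if (nchar(sequence) == 0L) stop("reference sequence must be non-empty", call. = FALSE)
  if (is.null(features)) {
    features <- data.frame(label = character(), start = integer(),
                           end = integer(), strand = character())
  } else {
    stopifnot(all(c("label", "start", "end", "strand") %in% names(features)))
    if (any(features$start < 0) || any(features$end > nchar(sequence)) ||
        any(features$start >= features$end)) {
      stop("feature intervals must lie within [0, length) and be non-empty",
           call. = FALSE)
    }
  }
  structure(list(name = name, sequence = sequence, features = features),
            class = "ref_seq")
}

#' @export
print.ref_seq <- function(x, ...) {
  cat(sprintf("<ref_seq> %s: %d nt, %d feature(s)\n",
              x$name, nchar(x$sequence), nrow(x$features)))
  invisible(x)
}

#' Length of a reference sequence in nucleotides
#' @param x A `ref_seq`.
#' @export
ref_length <- function(x) nchar(x$sequence)

# Bases of a ref_seq as a character vector (1 char per position).
ref_bases <- function(x) strsplit(x$sequence, "", fixed = TRUE)[[1]]

#' Generate a random reference sequence
#'
#' Draws an i.i.d. RNA sequence from the given base composition. Used as the
#' stand-in for a pre-rRNA analog when profiling motif density or planting
#' edit sites.
#'
#' @param length Sequence length in nt (>= 2).
#' @param base_probs Probabilities for A, C, G, U; must sum to 1.
#' @param seed Integer seed; output is deterministic given the seed.
#' @param name Sequence identifier.
#'
#' @return A [reference_sequence()] object.
#' @examples
#' ref <- generate_reference(500, seed = 1)
#' ref_length(ref)
#' @export
generate_reference <- function(length, base_probs = rep(0.25, 4), seed = 1L,
                               name = "synthref") {
  if (!is_count(length) || length < 2) {
    stop("`length` must be an integer >= 2", call. = FALSE)
  }
  base_probs <- check_base_probs(base_probs)
  set.seed(derive_seed(seed))
  seq <- paste(sample(RNA_BASES, length, replace = TRUE, prob = base_probs),
               collapse = "")
  reference_sequence(name, seq)
}

#' Read a reference from a FASTA file
#'
#' DNA input (T) is transcribed to RNA on ingest.
#'
#' @param path FASTA file; the first record is used unless `which` names one.
#' @param which Optional record name.
#' @return A [reference_sequence()] object.
#' @export
read_reference_fasta <- function(path, which = NULL) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path, call. = FALSE)
  idx <- if (is.null(which)) 1L else match(which, names(ss))
  if (is.na(idx)) stop("record '", which, "' not found in ", path, call. = FALSE)
  nm <- sub("\\s.*$", "", names(ss)[idx])
  reference_sequence(nm, as.character(ss[[idx]]))
}

#' Write a reference to FASTA
#'
#' @param ref A `ref_seq`.
#' @param path Output file.
#' @param as_dna Write the DNA form (U -> T); default keeps RNA letters.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(ref, path, as_dna = FALSE) {
  seq <- ref$sequence
  if (as_dna) seq <- chartr("U", "T", seq)
  ss <- Biostrings::BStringSet(stats::setNames(seq, ref$name))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
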