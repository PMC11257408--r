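#' @keywords internal
"_PACKAGE"

# RNA alphabet used everywhere internally; DNA (T) is transcribed on ingest.
RNA_BASES <- c("A", "C", "G", "U")

#' @importFrom stats runif rnorm density pbinom dbinom fisher.test rmultinom p.adjust setNames sd
#' @importFrom utils read.table write.table
NULL

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == floor(x)
}

check_base_probs <- function(base_probs) {
  if (!is.numeric(base_probs) || length(base_probs) != 4L ||
      any(!is.finite(base_probs)) || any(base_probs < 0) ||
      abs(sum(base_probs) - 1) > 1e-8) {
    stop("`base_probs` must be 4 non-negative probabilities (A, C, G, U) summing to 1",
         call. = FALSE)
  }
  stats::setNames(as.numeric(base_probs), RNA_BASES)
}

# Deterministic sub-seed from a master seed and per-stream indices. Kept below
# 2^31 so it is always a valid R integer seed.
derive_seed <- function(master, i = 0L, j = 0L) {
  as.integer((abs(master) * 69069 + i * 7919 + j * 104729) %% 2147483647)
}

# TRUE where the base immediately 5' of a 0-based position is U. Positions at
# the sequence start have no upstream base and are FALSE.
preceded_by_u <- function(pos0, bases) {
  ok <- pos0 >= 1L
  res <- logical(length(pos0))
  res[ok] <- bases[pos0[ok]] == "U"
  res
}

# Transcribe DNA to RNA and validate the alphabet.
as_rna <- function(x) {
  x <- chartr("t", "u", chartr("T", "U", toupper(x)))
  bad <- gsub("[ACGU]", "", x)
  if (any(nzchar(bad))) {
    stop("sequence contains characters outside the A/C/G/U alphabet: ",
         paste(unique(strsplit(paste(bad, collapse = ""), "")[[1]]), collapse = ", "),
         call. = FALSE)
  }
  x
}
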