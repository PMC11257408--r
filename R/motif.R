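#' Count (overlapping) motif occurrences in a sequence
#'
#' Counts every start index i with `seq[i:(i+|motif|-1)] == motif`,
#' including overlapping occurrences.
#'
#' @param seq Sequence string (RNA; DNA is transcribed) or a `ref_seq`.
#' @param motif Motif string (default the UC dinucleotide).
#' @return Integer count.
#' @examples
#' count_motif("UCUC", "UC") # 2
#' @export
count_motif <- function(seq, motif = "UC") {
  if (inherits(seq, "ref_seq")) seq <- seq$sequence
  seq <- as_rna(seq)
  motif <- as_rna(motif)
  if (nchar(motif) < 1L) stop("`motif` must be non-empty", call. = FALSE)
  length(motif_starts(seq, motif))
}

# 0-based start indices of (overlapping) motif occurrences.
motif_starts <- function(seq, motif) {
  m <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

#' Expected motif count in a window of random sequence
#'
#' Uses the window-length convention `L * prod(P(base_j))`: for the UC
#' dinucleotide in a 100-nt window of equiprobable bases this is
#' 100 x 1/16 = 6.25, the analytic baseline drawn on motif-density profiles.
#' (The alternative start-position convention `(L - |motif| + 1) * p` differs
#' by a vanishing edge term and is not used.)
#'
#' @param L Window length in nt.
#' @param base_probs Probabilities for A, C, G, U.
#' @param motif Motif string.
#' @return Expected count (real).
#' @examples
#' expected_motif_count(100, rep(0.25, 4), "UC") # 6.25
#' @export
expected_motif_count <- function(L, base_probs = rep(0.25, 4), motif = "UC") {
  base_probs <- check_base_probs(base_probs)
  motif <- as_rna(motif)
  letters <- strsplit(motif, "", fixed = TRUE)[[1]]
  L * prod(base_probs[letters])
}

#' Motif density profile over non-overlapping windows
#'
#' Tiles the sequence with consecutive windows of `L` nt starting at 0; each
#' motif occurrence is assigned to the window containing its start index, so
#' window counts sum exactly to [count_motif()] on the whole sequence. The
#' final partial window is reported with its true length and a pro-rated
#' expected count.
#'
#' @param seq Sequence string or `ref_seq`.
#' @param motif Motif string.
#' @param L Window length (default 100 nt).
#' @param base_probs Base composition of the random baseline.
#' @return A data.frame with columns `window_start` (0-based), `window_len`,
#'   `observed`, `expected`, `enrichment`.
#' @export
windowed_motif_profile <- function(seq, motif = "UC", L = 100L,
                                   base_probs = rep(0.25, 4)) {
  if (inherits(seq, "ref_seq")) seq <- seq$sequence
  seq <- as_rna(seq)
  n <- nchar(seq)
  if (!is_count(L) || L < nchar(motif)) {
    stop("`L` must be an integer >= motif length", call. = FALSE)
  }
  starts <- motif_starts(seq, motif)
  win_start <- seq(0L, max(0L, n - 1L), by = L)
  win_len <- pmin(L, n - win_start)
  observed <- as.integer(table(factor(starts %/% L, levels = seq_along(win_start) - 1L)))
  p <- expected_motif_count(1, base_probs, motif)
  expected <- win_len * p
  data.frame(window_start = win_start, window_len = win_len,
             observed = observed, expected = expected,
             enrichment = observed / expected)
}

#' Position frequency matrix of edit-site contexts
#'
#' Builds the per-position base counts over a set of equal-length sequence
#' windows centred on candidate edited cytidines (the input to any logo
#' renderer). End-of-sequence gap characters are counted in their own row.
#'
#' @param contexts Character vector of windows of equal odd length with a C
#'   at the centre (as produced by [annotate_context()]).
#' @param gap Gap character used for out-of-sequence padding.
#' @return An object of class `pfm`: an integer matrix with rows A, C, G, U,
#'   gap and one column per position (-flank..+flank); attribute
#'   `n_sequences`.
#' @export
build_pfm <- function(contexts, gap = "-") {
  if (!length(contexts)) stop("no context windows given", call. = FALSE)
  w <- unique(nchar(contexts))
  if (length(w) != 1L) stop("context windows must all have the same length", call. = FALSE)
  if (w %% 2L == 0L) stop("context windows must have odd length", call. = FALSE)
  flank <- (w - 1L) %/% 2L
  chars <- do.call(rbind, strsplit(contexts, "", fixed = TRUE))
  if (any(chars[, flank + 1L] != "C")) {
    stop("every context must have C at its centre", call. = FALSE)
  }
  lev <- c(RNA_BASES, gap)
  bad <- setdiff(unique(as.vector(chars)), lev)
  if (length(bad)) stop("unexpected characters in contexts: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  counts <- apply(chars, 2L, function(col) table(factor(col, levels = lev)))
  dimnames(counts) <- list(lev, as.character(seq_len(w) - flank - 1L))
  structure(counts, class = c("pfm", class(counts)),
            n_sequences = length(contexts))
}

#' Write a position frequency matrix as TSV
#'
#' @param pfm A `pfm` from [build_pfm()].
#' @param path Output file.
#' @export
write_pfm <- function(pfm, path) {
  utils::write.table(cbind(base = rownames(pfm), as.data.frame(unclass(pfm), check.names = FALSE)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Exact test for enrichment of a preceding base
#'
#' Tests whether the base immediately 5' of candidate edited cytidines occurs
#' more often than the random expectation `p0` (1/4 for a uniform
#' composition), via an exact binomial test with the two-sided p-value formed
#' by doubling the smaller tail (capped at 1).
#'
#' @param preceding Character vector of the preceding bases (one per site),
#'   or a vector of context windows from which the -1 base is taken.
#' @param base Base tested for enrichment (default U, the deaminase motif).
#' @param p0 Null probability of the base.
#' @return A list with `count`, `n`, `expected`, `p_value` and `enriched`
#'   (observed fraction above `p0` and p < 0.05).
#' @export
preceding_base_enrichment <- function(preceding, base = "U", p0 = 0.25) {
  if (!length(preceding)) stop("`preceding` must contain at least one site", call. = FALSE)
  if (any(nchar(preceding) > 1L)) {
    w <- unique(nchar(preceding))
    if (length(w) != 1L || w %% 2L == 0L) {
      stop("context windows must have equal odd length", call. = FALSE)
    }
    preceding <- substr(preceding, (w - 1L) %/% 2L, (w - 1L) %/% 2L)
  }
  n <- length(preceding)
  k <- sum(preceding == base)
  lower <- pbinom(k, n, p0)
  upper <- pbinom(k - 1L, n, p0, lower.tail = FALSE)
  p <- min(1, 2 * min(lower, upper))
  list(count = k, n = n, expected = n * p0, p_value = p,
       enriched = (k / n > p0) && p < 0.05)
}
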