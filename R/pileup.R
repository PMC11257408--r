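#' Edit frequency at a pileup site
#'
#' @param site A one-row (or multi-row, vectorised) pileup data.frame with
#'   base-count columns `A`, `C`, `G`, `U` and `depth`.
#' @param alt_base The alternative base whose frequency is wanted.
#'
#' @return `alt_count / depth` per row.
#' @examples
#' compute_site_frequency(data.frame(A = 0, C = 75, G = 0, U = 25, depth = 100))
#' @export
compute_site_frequency <- function(site, alt_base = "U") {
  stopifnot(alt_base %in% RNA_BASES, all(c(RNA_BASES, "depth") %in% names(site)))
  if (any(site$depth <= 0)) {
    stop("edit frequency is undefined at depth 0", call. = FALSE)
  }
  site[[alt_base]] / site$depth
}

#' Call C-to-U edit candidates from a pileup
#'
#' Emits a call at every reference-C position (and, in strand-aware mode,
#' reference-G position with alternative A, the minus-strand signature of the
#' same edit) whose read depth strictly exceeds `min_depth` and whose
#' alternative count is larger than expected under a uniform sequencing-error
#' null: a one-sided exact binomial test of the alt count against
#' Binomial(depth, `error_rate`/3) at level `alpha`. No multiple-testing
#' correction is applied at this stage; replicate concordance downstream is
#' the de facto error control.
#'
#' @param pileup Data.frame from [simulate_pileups()] or [read_pileup()].
#' @param error_rate Total per-base substitution rate of the null; the per-alt
#'   rate is `error_rate/3`.
#' @param min_depth Depth threshold, exclusive (calls require depth >
#'   `min_depth`).
#' @param alpha Significance level (calls require p < `alpha`).
#' @param strand_aware Also test ref-G/alt-A sites (to be oriented later).
#'
#' @return A data.frame of calls: `ref`, `pos` (0-based), `refbase`, `alt`,
#'   `depth`, `alt_count`, `f`, `p`, `edit` ("C>U" or "G>A").
#' @export
call_c_to_u <- function(pileup, error_rate = 0.001, min_depth = 10L,
                        alpha = 0.05, strand_aware = FALSE) {
  if (!is.numeric(error_rate) || error_rate <= 0 || error_rate >= 0.25) {
    stop("`error_rate` must lie in (0, 0.25)", call. = FALSE)
  }
  cols <- c("ref", "pos", "refbase", RNA_BASES, "depth")
  stopifnot(all(cols %in% names(pileup)))
  pairs <- list(c("C", "U"))
  if (strand_aware) pairs <- c(pairs, list(c("G", "A")))
  rate <- error_rate / 3
  out <- lapply(pairs, function(pr) {
    sub <- pileup[pileup$refbase == pr[1] & pileup$depth > min_depth, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    alt_count <- sub[[pr[2]]]
    # Upper-tail exact binomial: P(X >= alt_count) under the error null.
    p <- pbinom(alt_count - 1L, sub$depth, rate, lower.tail = FALSE)
    keep <- p < alpha
    if (!any(keep)) return(NULL)
    data.frame(ref = sub$ref[keep], pos = sub$pos[keep],
               refbase = pr[1], alt = pr[2],
               depth = sub$depth[keep], alt_count = alt_count[keep],
               f = alt_count[keep] / sub$depth[keep], p = p[keep],
               edit = paste0(pr[1], ">", pr[2]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(ref = character(), pos = integer(), refbase = character(),
                      alt = character(), depth = integer(), alt_count = integer(),
                      f = numeric(), p = numeric(), edit = character())
  }
  out[order(out$pos), , drop = FALSE]
}

#' Orient calls into transcript coordinates
#'
#' A C-to-U edit appears as C>U on a plus-strand transcript and as G>A on a
#' minus-strand transcript. Calls consistent with their transcript's strand
#' are relabelled with the canonical oriented edit "C>U"; inconsistent calls
#' are retained but flagged dropped with a reason; calls on sites of unknown
#' strand are routed to an "unoriented" bucket rather than silently removed.
#'
#' @param calls Data.frame from [call_c_to_u()].
#' @param strand Character vector (recycled or per call) of the containing
#'   transcript's strand: "+", "-" or NA/"*" for unknown.
#'
#' @return `calls` with added columns `strand`, `oriented` ("C>U" or NA),
#'   `status` ("oriented", "dropped", "unoriented") and `reason`.
#' @export
orient_strand <- function(calls, strand) {
  strand <- rep_len(as.character(strand), nrow(calls))
  strand[is.na(strand)] <- "*"
  oriented <- rep(NA_character_, nrow(calls))
  status <- character(nrow(calls))
  reason <- rep(NA_character_, nrow(calls))
  ok_plus <- calls$edit == "C>U" & strand == "+"
  ok_minus <- calls$edit == "G>A" & strand == "-"
  unknown <- strand == "*"
  oriented[ok_plus | ok_minus] <- "C>U"
  status[ok_plus | ok_minus] <- "oriented"
  status[unknown] <- "unoriented"
  reason[unknown] <- "strand unknown"
  bad <- !(ok_plus | ok_minus) & !unknown
  status[bad] <- "dropped"
  reason[bad] <- sprintf("edit %s inconsistent with strand %s",
                         calls$edit[bad], strand[bad])
  calls$strand <- strand
  calls$oriented <- oriented
  calls$status <- status
  calls$reason <- reason
  calls
}

#' Read / write the pileup TSV dialect
#'
#' Columns `ref pos refbase A C G U depth` with 0-based positions.
#'
#' @param path File path.
#' @return For `read_pileup`, a pileup data.frame.
#' @export
read_pileup <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("ref", "pos", "refbase", RNA_BASES, "depth")
  if (!all(need %in% names(df))) {
    stop("pileup file lacks columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  if (!all(df$depth == df$A + df$C + df$G + df$U)) {
    stop("pileup depths do not equal the base-count sums", call. = FALSE)
  }
  df
}

#' @rdname read_pileup
#' @param pileup Pileup data.frame.
#' @export
write_pileup <- function(pileup, path) {
  utils::write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write calls as a VCF-like TSV (1-based positions) or BED
#'
#' @param calls Data.frame from [call_c_to_u()].
#' @param path Output file.
#' @export
write_calls <- function(calls, path) {
  out <- data.frame(ref = calls$ref, pos = calls$pos + 1L,
                    refbase = calls$refbase, alt = calls$alt,
                    depth = calls$depth, alt_count = calls$alt_count,
                    f = calls$f, p = calls$p,
                    oriented = if ("oriented" %in% names(calls)) calls$oriented
                               else NA_character_)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
write_calls_bed <- function(calls, path) {
  bed <- data.frame(chrom = calls$ref, start = calls$pos, end = calls$pos + 1L,
                    name = paste0(calls$edit, "_f", signif(calls$f, 3)),
                    score = pmin(1000L, as.integer(round(-10 * log10(pmax(calls$p, 1e-100))))),
                    strand = if ("strand" %in% names(calls)) calls$strand else ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
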