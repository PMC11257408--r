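#' Intersect calls across every replicate of every condition
#'
#' A site enters the consensus only if a call exists at the same (reference,
#' position, edit) in every replicate of every condition in the design — the
#' strictest presence filter, applied before any frequency comparison.
#'
#' @param calls_by_rep Named list keyed `"<condition>:<replicate>"` of call
#'   data.frames ([call_c_to_u()]).
#' @param design A [study_design()].
#'
#' @return A data.frame with `ref`, `pos`, `edit` and one frequency column
#'   `f_<condition>_<replicate>` per library. Empty (0 rows) when no site is
#'   shared, which is not an error.
#' @export
intersect_replicates <- function(calls_by_rep, design) {
  stopifnot(inherits(design, "study_design"))
  keys <- design_keys(design)
  missing <- setdiff(keys, names(calls_by_rep))
  if (length(missing)) {
    stop("calls missing for libraries: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  site_key <- function(df) paste(df$ref, df$pos, df$edit, sep = "\r")
  common <- Reduce(intersect, lapply(calls_by_rep[keys], site_key))
  first <- calls_by_rep[[keys[1]]]
  idx <- match(common, site_key(first))
  out <- data.frame(ref = first$ref[idx], pos = first$pos[idx],
                    edit = first$edit[idx])
  for (k in keys) {
    df <- calls_by_rep[[k]]
    col <- paste0("f_", gsub(":", "_", k))
    out[[col]] <- df$f[match(common, site_key(df))]
  }
  out <- out[order(out$ref, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "design") <- design
  out
}

#' Percent difference of edit frequency between control and knockdown
#'
#' `100 * (f_control - f_kd) / f_control`: the percentage of control editing
#' lost after depletion. 100 means complete loss; negative values mean the
#' knockdown edited more.
#'
#' @param f_control Control edit frequency (> 0).
#' @param f_kd Knockdown edit frequency.
#' @return Percentage (vectorised).
#' @examples
#' percent_difference(0.10, 0.05) # 50
#' @export
percent_difference <- function(f_control, f_kd) {
  if (any(f_control <= 0)) {
    stop("percent difference is undefined for f_control <= 0", call. = FALSE)
  }
  100 * (f_control - f_kd) / f_control
}

#' Filter consensus sites for depletion sensitivity
#'
#' Two concordance rules are supported, matching the two filters applied to
#' different site sets: `"all_replicates_decrease"` keeps a site only if every
#' knockdown replicate's frequency is below the control mean (the per-replicate
#' rule used for the handful of pre-rRNA sites); `"mean_decrease"` keeps a site
#' if each knockdown condition's mean frequency is below the control mean (the
#' rule used transcriptome-wide). Retained sites get a percent difference of
#' the control mean against the unweighted mean of the knockdown condition
#' means.
#'
#' @param consensus Data.frame from [intersect_replicates()].
#' @param design A [study_design()] (defaults to the one attached to
#'   `consensus`).
#' @param mode `"mean_decrease"` or `"all_replicates_decrease"`.
#'
#' @return The retained rows of `consensus` with added columns
#'   `f_control_mean`, `f_kd_mean` and `percent_difference`.
#' @export
classify_targets <- function(consensus, design = attr(consensus, "design"),
                             mode = c("mean_decrease", "all_replicates_decrease")) {
  mode <- match.arg(mode)
  stopifnot(inherits(design, "study_design"))
  reps <- seq_len(design$replicates)
  fcols <- function(s) paste0("f_", s, "_", reps)
  ctrl <- as.matrix(consensus[, fcols(design$control), drop = FALSE])
  f_control_mean <- rowMeans(ctrl)
  kd_cond_means <- sapply(design$kd, function(s)
    rowMeans(as.matrix(consensus[, fcols(s), drop = FALSE])))
  kd_cond_means <- matrix(kd_cond_means, nrow = nrow(consensus),
                          dimnames = list(NULL, design$kd))
  keep <- if (mode == "all_replicates_decrease") {
    kd_all <- as.matrix(consensus[, unlist(lapply(design$kd, fcols)), drop = FALSE])
    rowSums(kd_all < f_control_mean) == ncol(kd_all)
  } else {
    rowSums(kd_cond_means < f_control_mean) == ncol(kd_cond_means)
  }
  out <- consensus[keep, , drop = FALSE]
  out$f_control_mean <- f_control_mean[keep]
  out$f_kd_mean <- rowMeans(kd_cond_means)[keep]
  out$percent_difference <- if (nrow(out)) {
    percent_difference(out$f_control_mean, out$f_kd_mean)
  } else numeric(0)
  rownames(out) <- NULL
  attr(out, "design") <- design
  out
}

#' Tier sites by percent edit change
#'
#' Strict thresholds: `gt66` iff percent difference > 66, `gt33` iff > 33, so
#' the tiers nest (gt66 within gt33 within all).
#'
#' @param sites Data.frame with a `percent_difference` column.
#' @return `sites` with logical columns `gt33`, `gt66` and a `tier` label
#'   ("all", "gt33" or "gt66", the deepest tier the site reaches).
#' @export
tier_sites <- function(sites) {
  stopifnot("percent_difference" %in% names(sites))
  pd <- sites$percent_difference
  sites$gt33 <- pd > 33
  sites$gt66 <- pd > 66
  sites$tier <- ifelse(sites$gt66, "gt66", ifelse(sites$gt33, "gt33", "all"))
  sites
}

#' Sequence context and UC-motif flag at candidate sites
#'
#' Extracts the +/-`flank` nt window around each site (padded with "-" at the
#' sequence ends) and flags the UC dinucleotide context: true iff the base
#' immediately 5' of the edited C is U.
#'
#' @param sites Data.frame with 0-based `pos`.
#' @param ref A [reference_sequence()].
#' @param flank Window half-width in nt.
#' @return `sites` with columns `uc_motif` and `context` (string of length
#'   `2*flank + 1`, centre = edited base).
#' @export
annotate_context <- function(sites, ref, flank = 10L) {
  stopifnot(inherits(ref, "ref_seq"), all(sites$pos >= 0),
            all(sites$pos < ref_length(ref)))
  bases <- ref_bases(ref)
  L <- length(bases)
  ctx <- vapply(sites$pos, function(p) {
    idx <- (p - flank):(p + flank) + 1L
    win <- ifelse(idx >= 1L & idx <= L, bases[pmax(pmin(idx, L), 1L)], "-")
    paste(win, collapse = "")
  }, character(1))
  sites$uc_motif <- preceded_by_u(sites$pos, bases)
  sites$context <- ctx
  sites
}

#' Assign each site a genomic region label and gene
#'
#' When a site overlaps several feature types the label follows the fixed
#' precedence UTR > coding exon > non-coding exon > intron > intergenic.
#'
#' @param sites Data.frame with 0-based `pos`.
#' @param annotation List from [generate_annotation()] or a compatible
#'   `features` data.frame.
#' @return `sites` with columns `region` (one of "5'UTR", "3'UTR",
#'   "coding exon", "non-coding exon", "intron", "intergenic") and `gene`.
#' @export
annotate_region <- function(sites, annotation) {
  feats <- if (is.data.frame(annotation)) annotation else annotation$features
  stopifnot(all(c("gene", "type", "start", "end") %in% names(feats)))
  label_of <- c(five_prime_UTR = "5'UTR", three_prime_UTR = "3'UTR",
                CDS = "coding exon", exon = "non-coding exon",
                intron = "intron")
  precedence <- c("5'UTR" = 1, "3'UTR" = 1, "coding exon" = 2,
                  "non-coding exon" = 3, "intron" = 4)
  region <- character(nrow(sites))
  gene <- rep(NA_character_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    p <- sites$pos[i]
    hit <- feats[feats$start <= p & p < feats$end, , drop = FALSE]
    if (!nrow(hit)) {
      region[i] <- "intergenic"
    } else {
      labs <- label_of[hit$type]
      best <- which.min(precedence[labs])
      region[i] <- labs[best]
      gene[i] <- hit$gene[best]
    }
  }
  sites$region <- region
  sites$gene <- gene
  sites
}

#' Run the full candidate-target filter
#'
#' Convenience wrapper: intersect calls across replicates, apply the selected
#' concordance rule, tier, and annotate sequence context and region.
#'
#' @inheritParams intersect_replicates
#' @inheritParams classify_targets
#' @param ref A [reference_sequence()] for context annotation.
#' @param annotation Optional annotation for region labels.
#' @param flank Context half-width.
#' @return A tiered, annotated candidate-site data.frame.
#' @export
find_candidate_targets <- function(calls_by_rep, design, ref,
                                   mode = c("mean_decrease",
                                            "all_replicates_decrease"),
                                   annotation = NULL, flank = 10L) {
  consensus <- intersect_replicates(calls_by_rep, design)
  sites <- classify_targets(consensus, design, match.arg(mode))
  sites <- tier_sites(sites)
  sites <- annotate_context(sites, ref, flank)
  if (!is.null(annotation)) sites <- annotate_region(sites, annotation)
  sites
}

#' Write candidate sites as TSV or BED
#'
#' @param sites Candidate-site data.frame.
#' @param path Output file.
#' @export
write_candidates <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates
#' @export
write_candidates_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$ref, start = sites$pos, end = sites$pos + 1L,
                    name = paste0("pd", round(sites$percent_difference, 1)),
                    score = 0L, strand = ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
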