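#' Fraction of cells with exactly one nucleolus
#'
#' The primary readout of the nucleolar-number assay: these cells normally
#' carry 2-3 nucleoli, and depletion of ribosome biogenesis factors shifts
#' cells toward a single nucleolus.
#'
#' @param cells Integer vector of per-cell nucleolus counts (>= 1 cell).
#' @return Fraction in [0, 1].
#' @examples
#' one_nucleolus_fraction(c(1, 1, 2, 3)) # 0.5
#' @export
one_nucleolus_fraction <- function(cells) {
  if (!length(cells)) stop("no cells: one-nucleolus fraction undefined", call. = FALSE)
  mean(cells == 1)
}

#' Percent effect relative to control anchors
#'
#' Rescales a treatment readout so the negative control sits at 0\% and the
#' positive control at 100\%: `100 * (x_test - x_neg) / (x_pos - x_neg)`.
#' Values above 100\% mean a stronger phenotype than the positive control.
#' For replicated screens, apply per replicate and average.
#'
#' @param x_test Treatment summary (e.g. one-nucleolus fraction); vectorised.
#' @param x_neg,x_pos Negative/positive control summaries.
#' @return Percentage.
#' @export
percent_effect <- function(x_test, x_neg, x_pos) {
  if (any(x_pos == x_neg)) {
    stop("degenerate controls: positive and negative summaries are equal",
         call. = FALSE)
  }
  100 * (x_test - x_neg) / (x_pos - x_neg)
}

#' Call screen hits against a 3-SD negative-control cutoff
#'
#' A treatment is a hit when its mean percent effect is at least 3 standard
#' deviations above the negative control: within each replicate the SD of the
#' negative-control well-level effects defines a cutoff `3 * SD_r`, and a
#' treatment's mean effect across replicates is compared to the mean of the
#' per-replicate cutoffs (the `>=` is inclusive). Per-replicate pass flags are
#' also returned. An all-identical negative plate (SD = 0) yields a cutoff of
#' 0, so any non-negative effect is a hit — a documented degenerate edge.
#'
#' @param effects_by_replicate Numeric matrix of percent effects, treatments
#'   in rows and replicates in columns (rownames = treatment labels).
#' @param neg_well_effects List (one element per replicate) of numeric vectors
#'   of negative-control well-level percent effects; each needs >= 2 wells.
#' @return A data.frame: `treatment`, `mean_effect`, `cutoff`, `hit`, plus a
#'   logical matrix attribute `"replicate_hits"`.
#' @export
call_hits <- function(effects_by_replicate, neg_well_effects) {
  effects_by_replicate <- as.matrix(effects_by_replicate)
  R <- ncol(effects_by_replicate)
  if (length(neg_well_effects) != R) {
    stop("need one negative-control effect vector per replicate", call. = FALSE)
  }
  if (any(vapply(neg_well_effects, length, 1L) < 2L)) {
    stop("each replicate needs >= 2 negative-control wells", call. = FALSE)
  }
  cutoffs <- 3 * vapply(neg_well_effects, stats::sd, numeric(1))
  rep_hits <- sweep(effects_by_replicate, 2L, cutoffs, `>=`)
  mean_effect <- rowMeans(effects_by_replicate)
  out <- data.frame(
    treatment = rownames(effects_by_replicate) %||% paste0("t", seq_len(nrow(effects_by_replicate))),
    mean_effect = mean_effect,
    cutoff = mean(cutoffs),
    hit = mean_effect >= mean(cutoffs))
  rownames(out) <- NULL
  attr(out, "replicate_hits") <- rep_hits
  attr(out, "replicate_cutoffs") <- cutoffs
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percent inhibition of nucleolar nascent-RNA signal, with class
#'
#' Rescales median nucleolar 5-EU signal between the negative control (0\%
#' inhibition) and a transcription-blocked positive control (100\%):
#' `I = 100 * (eu_neg - eu_test) / (eu_neg - eu_pos)`. The magnitude
#' classifies the mechanism: factors required for pre-rRNA transcription give
#' I > 80\%, factors required only for processing/maturation give
#' 50\% <= I <= 80\%, and I < 50\% indicates no requirement in making
#' ribosomes.
#'
#' @param eu_test Treatment median nucleolar 5-EU signal (vectorised).
#' @param eu_neg,eu_pos Control signals.
#' @return A data.frame with `percent_inhibition` and `class` (one of
#'   "transcription", "processing/maturation", "not required").
#' @export
percent_inhibition <- function(eu_test, eu_neg, eu_pos) {
  if (any(eu_neg == eu_pos)) {
    stop("degenerate controls: negative and positive 5-EU signals are equal",
         call. = FALSE)
  }
  I <- 100 * (eu_neg - eu_test) / (eu_neg - eu_pos)
  cls <- ifelse(I > 80, "transcription",
                ifelse(I >= 50, "processing/maturation", "not required"))
  data.frame(percent_inhibition = I, class = cls)
}

#' Normalize DNA intensities to control G1 = 1, G2 = 2
#'
#' Locates the G1 and G2 peaks of the control population as the two local
#' maxima of a Gaussian-kernel-smoothed density of log2 intensities whose
#' spacing is 1 +/- 0.3 (the G2 peak sits one doubling above G1); among valid
#' peak pairs the one with the greatest summed density is taken. An affine
#' map on the log2 scale then sends the peaks to 1.0 and 2.0 and is applied
#' to all samples.
#'
#' @param raw Numeric vector of raw integrated intensities to normalize.
#' @param control Raw intensities of the negative-control population used to
#'   locate the peaks (defaults to `raw`).
#' @param bandwidth Kernel bandwidth on the log2 scale.
#' @return Normalized log2 intensities; attributes `g1_peak` and `g2_peak`
#'   give the located control peaks (log2 scale).
#' @export
normalize_dna_intensity <- function(raw, control = raw, bandwidth = 0.05) {
  if (any(raw <= 0) || any(control <= 0)) {
    stop("intensities must be positive", call. = FALSE)
  }
  lc <- log2(control)
  d <- stats::density(lc, bw = bandwidth, n = 2048)
  y <- d$y
  peaks <- which(y[-c(1, length(y))] > y[-((length(y) - 1):length(y))] &
                 y[-c(1, length(y))] >= y[-(1:2)]) + 1L
  if (length(peaks) < 2L) {
    stop(sprintf("fewer than 2 modes in the control log2-intensity histogram (found %d peak at %s)",
                 length(peaks),
                 paste(round(d$x[peaks], 2), collapse = ", ")), call. = FALSE)
  }
  locs <- d$x[peaks]; hts <- y[peaks]
  best <- NULL; best_score <- -Inf
  for (i in seq_along(peaks)) {
    for (j in seq_along(peaks)) {
      if (locs[j] - locs[i] >= 0.7 && locs[j] - locs[i] <= 1.3) {
        score <- hts[i] + hts[j]
        if (score > best_score) { best_score <- score; best <- c(i, j) }
      }
    }
  }
  if (is.null(best)) {
    stop("no pair of control histogram modes spaced 1 +/- 0.3 apart on the log2 scale; peaks at ",
         paste(round(locs, 2), collapse = ", "), call. = FALSE)
  }
  g1 <- locs[best[1]]; g2 <- locs[best[2]]
  out <- 1 + (log2(raw) - g1) / (g2 - g1)
  attr(out, "g1_peak") <- g1
  attr(out, "g2_peak") <- g2
  out
}

#' Bin normalized DNA intensities into cell-cycle phases
#'
#' Fixed half-open bins on the normalized log2 scale: sub-G1 < 0.75,
#' G1 = [0.75, 1.25), S = [1.25, 1.75), G2/M = [1.75, 2.5], >4n > 2.5.
#' Left-closed binning puts each value in exactly one phase.
#'
#' @param normalized Normalized log2 intensities from
#'   [normalize_dna_intensity()].
#' @return A list of class `cell_cycle_profile`: `fractions` and `counts`
#'   (named by phase) and `n`.
#' @export
bin_cell_cycle <- function(normalized) {
  x <- as.numeric(normalized)
  if (any(!is.finite(x))) stop("normalized intensities must be finite", call. = FALSE)
  phases <- c("sub-G1", "G1", "S", "G2/M", ">4n")
  bin <- ifelse(x < 0.75, "sub-G1",
         ifelse(x < 1.25, "G1",
         ifelse(x < 1.75, "S",
         ifelse(x <= 2.5, "G2/M", ">4n"))))
  counts <- table(factor(bin, levels = phases))
  structure(list(fractions = as.numeric(counts) / length(x),
                 counts = as.integer(counts), n = length(x),
                 phases = phases),
            class = "cell_cycle_profile")
}

#' @export
print.cell_cycle_profile <- function(x, ...) {
  cat("<cell_cycle_profile>", x$n, "cells\n")
  print(round(stats::setNames(x$fractions, x$phases), 3))
  invisible(x)
}

#' Phase fractions of a cell-cycle profile
#' @param profile A `cell_cycle_profile`.
#' @return Named numeric vector summing to 1.
#' @export
phase_fractions <- function(profile) {
  stats::setNames(profile$fractions, profile$phases)
}

#' Declare a pre-rRNA processing pathway for ratio analysis
#'
#' Each edge links a downstream precursor (or product) to its upstream
#' precursor, e.g. 47S -> 45S -> 30S/32S -> 12S. Ratio analysis of multiple
#' precursors (RAMP) compares each downstream/upstream abundance ratio between
#' a treatment and its control.
#'
#' @param species Ordered character vector of precursor names (consecutive
#'   pairs become edges), or NULL if `edges` is given.
#' @param edges Data.frame with columns `upstream`, `downstream`.
#' @return An object of class `ramp_pathway` (data.frame of edges).
#' @export
ramp_pathway <- function(species = NULL, edges = NULL) {
  if (is.null(edges)) {
    if (is.null(species) || length(species) < 2L) {
      stop("need >= 2 ordered species or an explicit edge table", call. = FALSE)
    }
    edges <- data.frame(upstream = species[-length(species)],
                        downstream = species[-1])
  }
  stopifnot(all(c("upstream", "downstream") %in% names(edges)))
  if (any(edges$upstream == edges$downstream)) {
    stop("self-edges are not allowed", call. = FALSE)
  }
  structure(edges, class = c("ramp_pathway", "data.frame"))
}

#' Read a RAMP pathway from YAML
#'
#' Accepts either `species: [47S, 45S, 32S, 12S]` or an explicit
#' `edges: [{upstream: ..., downstream: ...}, ...]` block.
#'
#' @param path YAML file.
#' @return A [ramp_pathway()].
#' @export
read_ramp_pathway <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$species)) return(ramp_pathway(unlist(y$species)))
  if (!is.null(y$edges)) {
    return(ramp_pathway(edges = do.call(rbind, lapply(y$edges, as.data.frame))))
  }
  stop("YAML pathway needs a `species` list or an `edges` table", call. = FALSE)
}

#' Log2 fold change of precursor ratios (RAMP)
#'
#' For each pathway edge (downstream d, upstream u) computes
#' `log2((d_test / u_test) / (d_control / u_control))`: how much the
#' processing step's product/precursor ratio shifts in the treatment relative
#' to control. A block in the step shows as a positive value on the edge into
#' the accumulating precursor and a negative value on the edge leaving it.
#'
#' @param intensities_test,intensities_control Named numeric vectors of band
#'   (or trace) intensities per species; all species referenced by the
#'   pathway must be present and positive.
#' @param pathway A [ramp_pathway()].
#' @return A data.frame with `upstream`, `downstream`, `log2fc`.
#' @export
ramp_log2fc <- function(intensities_test, intensities_control, pathway) {
  stopifnot(inherits(pathway, "ramp_pathway"))
  species <- unique(c(pathway$upstream, pathway$downstream))
  for (v in list(test = intensities_test, control = intensities_control)) {
    missing <- setdiff(species, names(v))
    if (length(missing)) {
      stop("missing species: ", paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  bad <- species[intensities_test[species] <= 0 | intensities_control[species] <= 0]
  if (length(bad)) {
    stop("non-positive intensity for species: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  lfc <- log2((intensities_test[pathway$downstream] / intensities_test[pathway$upstream]) /
              (intensities_control[pathway$downstream] / intensities_control[pathway$upstream]))
  data.frame(upstream = pathway$upstream, downstream = pathway$downstream,
             log2fc = as.numeric(lfc))
}

#' Summarize a per-cell screen well table
#'
#' Collapses a per-cell table (as from [simulate_screen_wells()]) to per-well
#' one-nucleolus fractions.
#'
#' @param wells Data.frame with columns `well`, `treatment`, `role`,
#'   `nucleoli`.
#' @return A data.frame with one row per well: `well`, `treatment`, `role`,
#'   `n_cells`, `one_nucleolus_fraction`.
#' @export
summarize_wells <- function(wells) {
  stopifnot(all(c("well", "treatment", "role", "nucleoli") %in% names(wells)))
  sp <- split(wells, wells$well)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(well = d$well[1], treatment = d$treatment[1], role = d$role[1],
               n_cells = nrow(d),
               one_nucleolus_fraction = one_nucleolus_fraction(d$nucleoli))
  }))
  rownames(out) <- NULL
  out[order(out$well), , drop = FALSE]
}

#' Percent effects of every well against the plate's control anchors
#'
#' Computes each well's percent effect using the plate's mean negative and
#' positive control one-nucleolus fractions as the 0\% and 100\% anchors.
#'
#' @param well_summary Data.frame from [summarize_wells()].
#' @return `well_summary` with an added `percent_effect` column.
#' @export
well_percent_effects <- function(well_summary) {
  x_neg <- mean(well_summary$one_nucleolus_fraction[well_summary$role == "negative"])
  x_pos <- mean(well_summary$one_nucleolus_fraction[well_summary$role == "positive"])
  if (!is.finite(x_neg) || !is.finite(x_pos)) {
    stop("plate needs negative and positive control wells", call. = FALSE)
  }
  well_summary$percent_effect <- percent_effect(
    well_summary$one_nucleolus_fraction, x_neg, x_pos)
  well_summary
}
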