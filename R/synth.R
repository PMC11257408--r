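#' Describe a knockdown study design
#'
#' @param control_label Name of the control condition (e.g. "siNT").
#' @param kd_labels One or more knockdown condition names.
#' @param replicates Replicates per condition (>= 2).
#'
#' @return An object of class `study_design`.
#' @examples
#' study_design("siNT", c("siKD_pool", "siKD_1"))
#' @export
study_design <- function(control_label = "siNT",
                         kd_labels = c("siKD_pool", "siKD_1"),
                         replicates = 2L) {
  labels <- c(control_label, kd_labels)
  if (anyDuplicated(labels)) stop("condition labels must be unique", call. = FALSE)
  if (!is_count(replicates) || replicates < 2) {
    stop("`replicates` must be an integer >= 2", call. = FALSE)
  }
  structure(list(control = control_label, kd = kd_labels,
                 replicates = as.integer(replicates)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> control=%s; kd=%s; %d replicates each\n",
              x$control, paste(x$kd, collapse = ","), x$replicates))
  invisible(x)
}

design_samples <- function(design) c(design$control, design$kd)

# Keys "sample:rep" enumerating every library in the design.
design_keys <- function(design) {
  samples <- design_samples(design)
  as.vector(vapply(samples, function(s) paste0(s, ":", seq_len(design$replicates)),
                   character(design$replicates)))
}

#' Plant C-to-U edit sites in a reference
#'
#' Chooses distinct eligible C positions (optionally restricted to UC
#' dinucleotide contexts, the deaminase's preferred motif) and assigns each a
#' true control edit frequency and reduced knockdown frequencies. Planted
#' positions are spaced at least `min_spacing` nt apart so the +/-1 motif
#' contexts stay independent.
#'
#' @param ref A [reference_sequence()].
#' @param n_sites Number of sites to plant.
#' @param f_control_range Two-element interval for the true control edit
#'   frequency; frequencies are drawn uniformly from it. The default spans the
#'   low-frequency regime typical of deaminase editing (0.3\%-25\%).
#' @param kd_reduction Named vector of fractional reductions per knockdown
#'   condition; `f_kd = f_control * (1 - kd_reduction)`.
#' @param require_uc Restrict eligible positions to UC contexts.
#' @param seed Integer seed.
#' @param min_spacing Minimum distance (nt) between planted sites.
#'
#' @return A data.frame with columns `position` (0-based), `f_control`,
#'   `uc_context`, and one `f_<label>` column per knockdown condition.
#' @export
plant_edit_sites <- function(ref, n_sites, f_control_range = c(0.003, 0.25),
                             kd_reduction = c(siKD_pool = 0.5, siKD_1 = 0.5),
                             require_uc = FALSE, seed = 1L, min_spacing = 2L) {
  stopifnot(inherits(ref, "ref_seq"), is_count(n_sites), n_sites >= 1)
  if (any(kd_reduction < 0) || any(kd_reduction > 1)) {
    stop("`kd_reduction` values must be fractions in [0, 1]", call. = FALSE)
  }
  if (is.null(names(kd_reduction)) || any(!nzchar(names(kd_reduction)))) {
    stop("`kd_reduction` must be named by knockdown condition", call. = FALSE)
  }
  bases <- ref_bases(ref)
  eligible <- which(bases == "C") - 1L            # 0-based
  if (require_uc) {
    eligible <- eligible[preceded_by_u(eligible, bases)]
  }
  set.seed(derive_seed(seed, 1L))
  if (length(eligible) > 1L) eligible <- sample(eligible)
  picked <- integer(0)
  for (pos in eligible) {
    if (length(picked) == n_sites) break
    if (all(abs(picked - pos) >= min_spacing)) picked <- c(picked, pos)
  }
  if (length(picked) < n_sites) {
    stop(sprintf(
      "cannot plant %d sites: only %d eligible %sC positions at spacing >= %d",
      n_sites, length(picked), if (require_uc) "U-preceded " else "", min_spacing),
      call. = FALSE)
  }
  picked <- sort(picked)
  f_control <- runif(n_sites, f_control_range[1], f_control_range[2])
  out <- data.frame(position = picked, f_control = f_control,
                    uc_context = preceded_by_u(picked, bases))
  for (lab in names(kd_reduction)) {
    out[[paste0("f_", lab)]] <- f_control * (1 - kd_reduction[[lab]])
  }
  attr(out, "kd_labels") <- names(kd_reduction)
  out
}

#' Simulate per-site pileups for a knockdown study
#'
#' For every (condition, replicate) library, draws a multinomial base-count
#' vector at each reference position. Non-reference bases arise at a uniform
#' error rate split equally among the three alternatives; at a planted site
#' the alternative U additionally arises at the site's true frequency for
#' that condition, so the expected observed alt fraction is
#' `f + error_rate/3`.
#'
#' @param ref A [reference_sequence()].
#' @param planted Data.frame from [plant_edit_sites()] (or NULL for a pure
#'   error-only pileup).
#' @param design A [study_design()]; its knockdown labels must match the
#'   `f_<label>` columns of `planted`.
#' @param depth Reads per position.
#' @param error_rate Total per-base substitution rate (default 0.001).
#' @param seed Integer master seed; each (condition, replicate) stream gets an
#'   independent derived sub-seed, so results are bit-reproducible.
#'
#' @return A named list keyed `"<condition>:<replicate>"` of data.frames with
#'   columns `ref`, `pos` (0-based), `refbase`, `A`, `C`, `G`, `U`, `depth`.
#' @export
simulate_pileups <- function(ref, planted, design, depth = 1000L,
                             error_rate = 0.001, seed = 1L) {
  stopifnot(inherits(ref, "ref_seq"), inherits(design, "study_design"))
  if (!is_count(depth) || depth < 1) stop("`depth` must be >= 1", call. = FALSE)
  if (error_rate < 0 || error_rate >= 0.25) {
    stop("`error_rate` must be in [0, 0.25)", call. = FALSE)
  }
  bases <- ref_bases(ref)
  L <- length(bases)
  samples <- design_samples(design)
  planted_pos <- if (is.null(planted)) integer(0) else planted$position
  if (length(planted_pos) && any(bases[planted_pos + 1L] != "C")) {
    stop("planted sites must sit on reference C positions", call. = FALSE)
  }

  out <- list()
  for (si in seq_along(samples)) {
    s <- samples[si]
    for (r in seq_len(design$replicates)) {
      set.seed(derive_seed(seed, si, r))
      counts <- matrix(0L, nrow = L, ncol = 4L,
                       dimnames = list(NULL, RNA_BASES))
      # Error-only draws, grouped by reference base for vectorised rmultinom.
      for (b in RNA_BASES) {
        idx <- which(bases == b)
        if (!length(idx)) next
        p <- rep(error_rate / 3, 4)
        p[match(b, RNA_BASES)] <- 1 - error_rate
        counts[idx, ] <- t(rmultinom(length(idx), depth, p))
      }
      # Overwrite planted sites with the edited base model.
      if (length(planted_pos)) {
        f <- if (s == design$control) planted$f_control else planted[[paste0("f_", s)]]
        if (is.null(f)) {
          stop("planted sites carry no frequency column for condition '", s, "'",
               call. = FALSE)
        }
        for (k in seq_along(planted_pos)) {
          p <- c(A = error_rate / 3, C = 1 - error_rate - f[k],
                 G = error_rate / 3, U = error_rate / 3 + f[k])
          if (p["C"] < 0) stop("f + error_rate exceeds 1 at a planted site",
                               call. = FALSE)
          counts[planted_pos[k] + 1L, ] <- rmultinom(1L, depth, p)[, 1]
        }
      }
      out[[paste0(s, ":", r)]] <- data.frame(
        ref = ref$name, pos = seq_len(L) - 1L, refbase = bases,
        A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
        U = counts[, "U"], depth = as.integer(depth))
    }
  }
  out
}

#' Generate a synthetic transcript annotation and gene sets
#'
#' Packs `n_genes` non-overlapping transcripts along the reference, each a
#' simple gene model (5'UTR, alternating CDS exons and introns, 3'UTR for
#' coding genes; plain exons and introns for non-coding genes), and draws
#' gene-set memberships (e.g. "nucleolar", "TP53_target") as independent
#' Bernoulli trials at configured baseline fractions.
#'
#' @param ref A [reference_sequence()].
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @param set_baselines Named vector of baseline membership fractions. The
#'   defaults mirror a nucleolar-proteome fraction of 17.7\% and a
#'   TP53-target fraction of 0.8\%.
#' @param p_coding Probability a gene is protein coding.
#'
#' @return A list with elements `features` (data.frame: `gene`, `type` in
#'   {five_prime_UTR, CDS, exon, intron, three_prime_UTR}, `start`, `end`
#'   0-based half-open, `strand`, `coding`), `gene_sets` (data.frame `gene`,
#'   `set`), `genes` (character) and `set_baselines`.
#' @export
generate_annotation <- function(ref, n_genes, seed = 1L,
                                set_baselines = c(nucleolar = 0.177,
                                                  TP53_target = 0.008),
                                p_coding = 0.85) {
  stopifnot(inherits(ref, "ref_seq"), is_count(n_genes), n_genes >= 1)
  if (any(set_baselines < 0) || any(set_baselines > 1)) {
    stop("`set_baselines` must be fractions in [0, 1]", call. = FALSE)
  }
  L <- ref_length(ref)
  min_gene <- 30L; gap <- 5L
  if (n_genes * (min_gene + gap) + gap > L) {
    stop(sprintf("cannot pack %d genes of >= %d nt into a %d nt reference",
                 n_genes, min_gene, L), call. = FALSE)
  }
  set.seed(derive_seed(seed, 2L))
  slot <- L %/% n_genes
  rows <- list()
  genes <- sprintf("gene%03d", seq_len(n_genes))
  coding <- runif(n_genes) < p_coding
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)
  for (g in seq_len(n_genes)) {
    lo <- (g - 1L) * slot + gap
    hi <- g * slot - gap
    glen <- hi - lo
    # Segment lengths: coding genes get UTR/CDS/intron/CDS/UTR, non-coding
    # exon/intron/exon; proportions jittered so genes differ.
    if (coding[g] && glen >= 25L) {
      w <- c(0.1, 0.25, 0.3, 0.25, 0.1) * runif(5, 0.7, 1.3)
      lens <- pmax(2L, as.integer(round(glen * w / sum(w))))
      types <- c("five_prime_UTR", "CDS", "intron", "CDS", "three_prime_UTR")
      if (strands[g] == "-") types <- rev(types)
    } else {
      w <- c(0.35, 0.3, 0.35) * runif(3, 0.7, 1.3)
      lens <- pmax(2L, as.integer(round(glen * w / sum(w))))
      types <- c("exon", "intron", "exon")
    }
    ends <- lo + cumsum(lens)
    ends[length(ends)] <- min(ends[length(ends)], hi)
    starts <- c(lo, ends[-length(ends)])
    keep <- starts < ends
    rows[[g]] <- data.frame(gene = genes[g], type = types[keep],
                            start = starts[keep], end = ends[keep],
                            strand = strands[g], coding = coding[g])
  }
  features <- do.call(rbind, rows)
  memberships <- list()
  for (set in names(set_baselines)) {
    member <- runif(n_genes) < set_baselines[[set]]
    if (any(member)) {
      memberships[[set]] <- data.frame(gene = genes[member], set = set)
    }
  }
  gene_sets <- if (length(memberships)) do.call(rbind, memberships) else
    data.frame(gene = character(), set = character())
  rownames(features) <- rownames(gene_sets) <- NULL
  list(features = features, gene_sets = gene_sets, genes = genes,
       set_baselines = set_baselines)
}

#' Simulate per-cell nucleolus counts for a screen plate
#'
#' Each well's cells carry 1 nucleolus with the well's true one-nucleolus
#' fraction and otherwise 2 or 3 (the normal range for these cells), so the
#' observed well fraction is a binomial estimate of the truth. Default control
#' fractions follow the observed negative (19.2\%) and positive (29.2\%)
#' control one-nucleolus percentages.
#'
#' @param treatments Named vector mapping test-treatment label to its true
#'   one-nucleolus fraction.
#' @param n_neg,n_pos Number of negative/positive control wells (the screen
#'   layout uses 16 of each per replicate).
#' @param neg_fraction,pos_fraction True one-nucleolus fractions of the
#'   controls.
#' @param cells_per_well Cells imaged per well.
#' @param seed Integer seed.
#'
#' @return A data.frame with one row per cell: `well`, `treatment`, `role`
#'   ("negative", "positive" or "test") and `nucleoli`.
#' @export
simulate_screen_wells <- function(treatments, n_neg = 16L, n_pos = 16L,
                                  neg_fraction = 0.192, pos_fraction = 0.292,
                                  cells_per_well = 1000L, seed = 1L) {
  if (!is_count(cells_per_well) || cells_per_well < 1) {
    stop("`cells_per_well` must be >= 1", call. = FALSE)
  }
  fracs <- c(rep(neg_fraction, n_neg), rep(pos_fraction, n_pos),
             as.numeric(treatments))
  if (any(fracs < 0) || any(fracs > 1)) {
    stop("one-nucleolus fractions must lie in [0, 1]", call. = FALSE)
  }
  labels <- c(rep("negative_control", n_neg), rep("positive_control", n_pos),
              names(treatments))
  roles <- c(rep("negative", n_neg), rep("positive", n_pos),
             rep("test", length(treatments)))
  wells <- sprintf("W%03d", seq_along(fracs))
  set.seed(derive_seed(seed, 3L))
  rows <- lapply(seq_along(fracs), function(i) {
    one <- runif(cells_per_well) < fracs[i]
    n <- ifelse(one, 1L, sample(2:3, cells_per_well, replace = TRUE))
    data.frame(well = wells[i], treatment = labels[i], role = roles[i],
               nucleoli = as.integer(n))
  })
  do.call(rbind, rows)
}

#' Simulate integrated DNA-staining intensities across the cell cycle
#'
#' Draws raw integrated intensities for a population with the given phase
#' composition: G1 cells centred at `2^g1_log2`, G2/M at twice that, S-phase
#' cells spread between the two, sub-G1 below G1 and >4n above G2/M, all with
#' multiplicative log-normal measurement noise of coefficient of variation
#' `cv`. S-phase intensities are drawn across the interior of the S interval
#' (normalized log2 1.3-1.7) so phases are recoverable after binning.
#'
#' @param phase_fractions 5-vector of fractions for (sub-G1, G1, S, G2/M,
#'   >4n); must sum to 1.
#' @param n_cells Number of cells.
#' @param cv Coefficient of variation of the intensity noise (< 0.3).
#' @param seed Integer seed.
#' @param g1_log2 Location of the G1 peak on the raw log2 scale.
#'
#' @return A data.frame with columns `phase` (true phase) and `intensity`
#'   (raw, linear scale).
#' @export
simulate_dna_intensities <- function(phase_fractions, n_cells, cv = 0.05,
                                     seed = 1L, g1_log2 = 10) {
  if (length(phase_fractions) != 5L || any(phase_fractions < 0) ||
      abs(sum(phase_fractions) - 1) > 1e-8) {
    stop("`phase_fractions` must be 5 non-negative fractions summing to 1",
         call. = FALSE)
  }
  if (cv < 0 || cv >= 0.3) stop("`cv` must be in [0, 0.3)", call. = FALSE)
  if (!is_count(n_cells) || n_cells < 1) stop("`n_cells` must be >= 1", call. = FALSE)
  phases <- c("sub-G1", "G1", "S", "G2/M", ">4n")
  set.seed(derive_seed(seed, 4L))
  counts <- as.vector(rmultinom(1L, n_cells, phase_fractions))
  x <- unlist(mapply(function(ph, k) {
    if (k == 0L) return(numeric(0))
    switch(ph,
           "sub-G1" = runif(k, g1_log2 - 0.6, g1_log2 - 0.4),
           "G1"     = rep(g1_log2, k),
           "S"      = runif(k, g1_log2 + 0.3, g1_log2 + 0.7),
           "G2/M"   = rep(g1_log2 + 1, k),
           ">4n"    = runif(k, g1_log2 + 1.7, g1_log2 + 2.0))
  }, phases, counts, SIMPLIFY = FALSE), use.names = FALSE)
  sigma <- sqrt(log(1 + cv^2))
  noise <- if (sigma > 0) exp(rnorm(length(x), 0, sigma)) else 1
  data.frame(phase = rep(phases, counts), intensity = 2^x * noise)
}
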