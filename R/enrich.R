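#' Baseline percentage of a gene set in a universe
#'
#' @param K Set size.
#' @param N Universe size.
#' @param report Round to 1 decimal (the reporting convention); `FALSE`
#'   returns full precision.
#' @return `100 * K / N`.
#' @examples
#' set_fraction_baseline(3490, 19670) # 17.7 (nucleolar proteome fraction)
#' set_fraction_baseline(343, 43768)  # 0.8  (high-confidence TP53 targets)
#' @export
set_fraction_baseline <- function(K, N, report = TRUE) {
  if (any(K <= 0) || any(N <= 0) || any(K > N)) {
    stop("need 0 < K <= N", call. = FALSE)
  }
  x <- 100 * K / N
  if (report) round(x, 1) else x
}

#' Fisher exact enrichment of a hit list against a set
#'
#' Tests the 2x2 table (in set / not in set) x (hit / not hit) with a
#' two-sided Fisher exact test. Fold enrichment is the hit-list set fraction
#' over the universe set fraction, `(k/n) / (K/N)`.
#'
#' @param k Hits that are set members.
#' @param n Total hits.
#' @param K Set size in the universe.
#' @param N Universe size.
#' @param alpha Significance level for the `enriched` flag.
#' @return A one-row data.frame of class `enrichment_result`: `k`, `n`, `K`,
#'   `N`, `fold`, `odds_ratio`, `p_value`, `baseline_percent`, `enriched`.
#' @export
fisher_enrichment <- function(k, n, K, N, alpha = 0.05) {
  ok <- is_count(k) && is_count(n) && is_count(K) && is_count(N)
  if (!ok || k > n || k > K || n > N || K > N || (n - k) > (N - K)) {
    stop("inconsistent contingency counts (need k <= min(n, K), n <= N, K <= N)",
         call. = FALSE)
  }
  if (K == 0 || n == 0) {
    stop("fold enrichment undefined for an empty set or empty hit list",
         call. = FALSE)
  }
  tab <- matrix(c(k, n - k, K - k, N - n - (K - k)), nrow = 2,
                dimnames = list(hit = c("yes", "no"), set = c("yes", "no")))
  ft <- stats::fisher.test(tab)
  fold <- (k / n) / (K / N)
  out <- data.frame(k = k, n = n, K = K, N = N, fold = fold,
                    odds_ratio = unname(ft$estimate), p_value = ft$p.value,
                    baseline_percent = set_fraction_baseline(K, N, report = FALSE),
                    enriched = fold > 1 && ft$p.value < alpha)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Over-representation analysis of a gene list against gene sets
#'
#' One Fisher exact test per set, with the reporting rule applied on top:
#' a set is flagged `reported` when fold enrichment strictly exceeds
#' `min_fold` and p < `alpha`. All sets are retained in the output regardless.
#'
#' @param genes Character vector of hit genes (must lie in `universe`).
#' @param gene_sets Named list of character vectors, or a data.frame with
#'   columns `gene` and `set`.
#' @param universe Character vector of all genes considered.
#' @param min_fold Reporting threshold on fold enrichment (strict >).
#' @param alpha Reporting threshold on the p-value.
#' @param adjust Multiple-testing adjustment for an additional `p_adjusted`
#'   column; `"none"` (the default, matching the reporting convention) or
#'   `"BH"`.
#' @return A data.frame with one row per set: `set`, the
#'   [fisher_enrichment()] columns, `p_adjusted` and `reported`.
#' @export
ora <- function(genes, gene_sets, universe, min_fold = 2, alpha = 0.05,
                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (is.data.frame(gene_sets)) {
    gene_sets <- split(gene_sets$gene, gene_sets$set)
  }
  if (!length(gene_sets)) stop("no gene sets given", call. = FALSE)
  genes <- unique(genes); universe <- unique(universe)
  if (!all(genes %in% universe)) {
    stop("`genes` must be a subset of `universe`", call. = FALSE)
  }
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(gene_sets[[nm]]), universe)
    if (!length(members)) {
      stop("gene set '", nm, "' has no members in the universe", call. = FALSE)
    }
    res <- fisher_enrichment(k = length(intersect(genes, members)),
                             n = length(genes), K = length(members),
                             N = length(universe), alpha = alpha)
    cbind(set = nm, as.data.frame(res))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (adjust == "BH") p.adjust(out$p_value, "BH") else out$p_value
  out$reported <- out$fold > min_fold & out$p_value < alpha
  rownames(out) <- NULL
  out
}

#' Read / write gene-set TSV files (`gene<TAB>set`)
#'
#' @param path File path.
#' @export
read_gene_sets <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "set") %in% names(df)))
  df
}

#' @rdname read_gene_sets
#' @param gene_sets Data.frame with columns `gene`, `set`.
#' @export
write_gene_sets <- function(gene_sets, path) {
  utils::write.table(gene_sets, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
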