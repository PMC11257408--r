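#' Write an annotation as GFF3
#'
#' Features are stored internally in 0-based half-open coordinates and
#' converted to GFF3's 1-based closed convention on export.
#'
#' @param annotation List from [generate_annotation()] or a compatible
#'   `features` data.frame.
#' @param ref A [reference_sequence()] providing the seqname.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation_gff3 <- function(annotation, ref, path) {
  feats <- if (is.data.frame(annotation)) annotation else annotation$features
  gr <- GenomicRanges::GRanges(
    seqnames = ref$name,
    ranges = IRanges::IRanges(start = feats$start + 1L, end = feats$end),
    strand = feats$strand)
  gr$type <- feats$type
  gr$ID <- sprintf("%s_%s_%d", feats$gene, feats$type, seq_len(nrow(feats)))
  gr$gene_id <- feats$gene
  gr$phase <- ifelse(feats$type == "CDS", 0L, NA_integer_)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read an annotation from GFF3
#'
#' @param path GFF3 file written by [write_annotation_gff3()] or compatible
#'   (feature types five_prime_UTR/CDS/exon/intron/three_prime_UTR, a
#'   `gene_id` attribute).
#' @return A features data.frame in 0-based half-open coordinates usable by
#'   [annotate_region()].
#' @export
read_annotation_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gene <- if (!is.null(gr$gene_id)) gr$gene_id else as.character(gr$ID)
  feats <- data.frame(gene = gene,
                      type = as.character(gr$type),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)))
  coding_genes <- unique(feats$gene[feats$type == "CDS"])
  feats$coding <- feats$gene %in% coding_genes
  feats
}

#' Read / write per-cell screen well tables as TSV
#'
#' Columns `well treatment role nucleoli` (and optionally further per-cell
#' measurements).
#'
#' @param path File path.
#' @export
read_well_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("well", "treatment", "role") %in% names(df)))
  df
}

#' @rdname read_well_table
#' @param wells Data.frame of per-cell rows.
#' @export
write_well_table <- function(wells, path) {
  utils::write.table(wells, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a band-intensity table (`species sample intensity`)
#'
#' @param path TSV file.
#' @return A list of named intensity vectors, one per sample.
#' @export
read_band_intensities <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("species", "sample", "intensity") %in% names(df)))
  lapply(split(df, df$sample),
         function(d) stats::setNames(d$intensity, d$species))
}
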