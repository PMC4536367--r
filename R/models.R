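# Gene models: stranded single- or multi-block transcript structures with
# 5'UTR/CDS/3'UTR segments, stored as a data.frame in 0-based half-open
# (BED) coordinates; converted to GRanges at overlap-query boundaries.

#' Construct/validate a gene-model table
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `strand`
#'   (`+`/`-`), `tx_start`, `tx_end`, `cds_start`, `cds_end` (0-based
#'   half-open; `cds_start == cds_end` marks a non-coding transcript) and
#'   optional `biotype` (`"coding"`/`"ncRNA"`).
#' @return validated data.frame of class `gene_models`.
#' @export
gene_models <- function(df) {
  need <- c("gene_id", "chrom", "strand", "tx_start", "tx_end",
            "cds_start", "cds_end")
  stopifnot(all(need %in% names(df)))
  if (is.null(df$biotype)) {
    df$biotype <- ifelse(df$cds_end > df$cds_start, "coding", "ncRNA")
  }
  stopifnot(all(df$tx_start < df$tx_end),
            all(df$strand %in% c("+", "-")),
            all(df$cds_start >= df$tx_start | df$cds_start == df$cds_end),
            all(df$cds_end <= df$tx_end),
            !anyDuplicated(df$gene_id))
  class(df) <- c("gene_models", "data.frame")
  df
}

bed_to_granges <- function(chrom, start, end, strand, ...) {
  keep <- end > start
  GenomicRanges::GRanges(chrom[keep],
                         IRanges::IRanges(start[keep] + 1L, end[keep]),
                         strand = strand[keep],
                         ...)
}

#' 3'UTR intervals of coding gene models, optionally extended downstream
#'
#' @param models gene-model table.
#' @param extension nt of strand-aware downstream extension (default 0).
#' @return GRanges with metadata column `gene_id`.
#' @export
utr3_ranges <- function(models, extension = 0L) {
  m <- models[models$biotype == "coding", ]
  plus <- m$strand == "+"
  start <- ifelse(plus, m$cds_end, pmax(0L, m$tx_start - extension))
  end <- ifelse(plus, m$tx_end + extension, m$cds_start)
  bed_to_granges(m$chrom, start, end, m$strand, gene_id = m$gene_id)
}

#' @rdname utr3_ranges
#' @export
utr5_ranges <- function(models) {
  m <- models[models$biotype == "coding", ]
  plus <- m$strand == "+"
  start <- ifelse(plus, m$tx_start, m$cds_end)
  end <- ifelse(plus, m$cds_start, m$tx_end)
  bed_to_granges(m$chrom, start, end, m$strand, gene_id = m$gene_id)
}

#' @rdname utr3_ranges
#' @export
cds_ranges <- function(models) {
  m <- models[models$biotype == "coding", ]
  bed_to_granges(m$chrom, m$cds_start, m$cds_end, m$strand,
                 gene_id = m$gene_id)
}

#' @rdname utr3_ranges
#' @export
ncrna_ranges <- function(models) {
  m <- models[models$biotype == "ncRNA", ]
  bed_to_granges(m$chrom, m$tx_start, m$tx_end, m$strand,
                 gene_id = m$gene_id)
}

#' Write/read gene models as BED12
#'
#' Single-block records: the transcript span is one block, thickStart /
#' thickEnd carry the CDS.
#'
#' @param models gene-model table.
#' @param path output file.
#' @export
write_bed12 <- function(models, path) {
  df <- data.frame(models$chrom, models$tx_start, models$tx_end,
                   models$gene_id, 0L, models$strand,
                   models$cds_start, models$cds_end, "0",
                   1L, models$tx_end - models$tx_start, 0L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' @rdname write_bed12
#' @export
read_bed12 <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  gene_models(data.frame(gene_id = df[[4L]], chrom = df[[1L]],
                         strand = df[[6L]],
                         tx_start = df[[2L]], tx_end = df[[3L]],
                         cds_start = df[[7L]], cds_end = df[[8L]],
                         stringsAsFactors = FALSE))
}

#' Write/read stranded intervals as BED6
#'
#' @param df data.frame with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (missing name/score filled with `"."` / 0).
#' @param path file path.
#' @export
write_bed6 <- function(df, path) {
  name <- if (is.null(df$name)) rep(".", nrow(df)) else df$name
  score <- if (is.null(df$score)) rep(0L, nrow(df)) else df$score
  out <- data.frame(df$chrom, df$start, df$end, name, score, df$strand)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' @rdname write_bed6
#' @export
read_bed6 <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  data.frame(chrom = df[[1L]], start = df[[2L]], end = df[[3L]],
             name = df[[4L]], score = df[[5L]], strand = df[[6L]],
             stringsAsFactors = FALSE)
}

#' Read sequences from FASTA into a named character vector (DNA space)
#'
#' U residues (mature miRNA FASTA) are mapped to T on input.
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as_dna(as.character(x)), names(x))
}

#' Write a named character vector of sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(as_dna(seqs)), path)
}

#' Write/read a counts or log2fc table as TSV
#'
#' @param table matrix or data.frame with feature rownames.
#' @param path file path.
#' @param id_col name for the feature-id column (default `"gene_id"`).
#' @export
write_tsv_matrix <- function(table, path, id_col = "gene_id") {
  df <- data.frame(rownames(table), as.data.frame(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_tsv_matrix
#' @export
read_tsv_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}
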