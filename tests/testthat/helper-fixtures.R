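# in-code fixture builders shared across test files

# build an annotation_set from a compact list spec:
#   tx("t1", "chr1", "+", list(c(0, 100), c(200, 300)), gene = "g1")
tx <- function(id, chrom, strand, exons, gene = NA_character_, support = 1L,
               source = "observed") {
  data.frame(transcript_id = id, chrom = chrom, strand = strand,
             start = vapply(exons, `[`, numeric(1), 1),
             end = vapply(exons, `[`, numeric(1), 2),
             gene_id = gene, read_support = support, source = source,
             stringsAsFactors = FALSE)
}

ann <- function(..., source_tag = "observed") {
  rows <- do.call(rbind, list(...))
  annotation_set(rows[, c("transcript_id", "chrom", "strand", "start", "end")],
                 meta = unique(rows[, c("transcript_id", "gene_id",
                                        "read_support", "source")]),
                 source_tag = source_tag)
}

# mirror an exon matrix through a constant (strand reflection helper)
mirror_exons <- function(exons, C) {
  lapply(rev(exons), function(e) c(C - e[2], C - e[1]))
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

# small two-condition count matrix
toy_counts <- function(values, genes = NULL) {
  m <- as.matrix(values)
  colnames(m) <- c("a1", "a2", "a3", "b1", "b2", "b3")[seq_len(ncol(m))]
  if (is.null(rownames(m))) rownames(m) <- paste0("f", seq_len(nrow(m)))
  design <- stats::setNames(rep(c("A", "B"), each = ncol(m) / 2), colnames(m))
  expression_matrix(m, design, unit = "counts")
}
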