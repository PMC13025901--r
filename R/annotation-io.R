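#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom stats setNames
NULL

# All internal coordinates are 0-based half-open [start, end); GTF's 1-based
# inclusive convention is converted only inside the I/O functions.

#' Construct an annotation set
#'
#' An `annotation_set` bundles a table of transcript models with their exon
#' chains. It is the shared container for reference annotations, observed
#' long-read isoform catalogs, and short-read assembled models.
#'
#' @param exons data.frame with columns `transcript_id`, `chrom`, `strand`,
#'   `start`, `end` (0-based half-open), one row per exon.
#' @param meta optional data.frame with one row per transcript: columns
#'   `transcript_id`, and optionally `gene_id` (NA = unassigned),
#'   `read_support` (non-negative integer) and `source` (one of
#'   `"reference"`, `"observed"`, `"assembled"`).
#' @param source_tag default source for transcripts lacking one.
#'
#' @return An object of class `annotation_set` with elements `transcripts`
#'   (per-transcript table incl. strand-aware `tss`/`tes`) and `exons`
#'   (exon table sorted by genomic start within transcript).
#' @export
annotation_set <- function(exons, meta = NULL, source_tag = "reference") {
  stopifnot(is.data.frame(exons))
  req <- c("transcript_id", "chrom", "strand", "start", "end")
  miss <- setdiff(req, names(exons))
  if (length(miss) > 0L) stop("exon table missing columns: ", paste(miss, collapse = ", "))
  exons$transcript_id <- as.character(exons$transcript_id)
  exons$chrom <- as.character(exons$chrom)
  exons$strand <- as.character(exons$strand)
  exons$start <- as.numeric(exons$start)
  exons$end <- as.numeric(exons$end)
  if (any(!exons$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(exons$start < 0) || any(exons$start >= exons$end))
    stop("invalid exon interval: require 0 <= start < end")

  exons <- exons[order(exons$transcript_id, exons$start), req, drop = FALSE]
  if (nrow(exons) == 0L) {
    tx <- data.frame(transcript_id = character(0), chrom = character(0),
                     strand = character(0), start = numeric(0),
                     end = numeric(0), n_exons = integer(0), tss = numeric(0),
                     tes = numeric(0), gene_id = character(0),
                     read_support = integer(0), source = character(0),
                     stringsAsFactors = FALSE)
    return(structure(list(transcripts = tx, exons = exons),
                     class = "annotation_set"))
  }
  ids <- unique(exons$transcript_id)

  # per-transcript validation: one chrom/strand, non-overlapping exons,
  # intron length >= 1
  sp <- split(seq_len(nrow(exons)), exons$transcript_id)
  for (id in names(sp)) {
    i <- sp[[id]]
    if (length(unique(exons$chrom[i])) != 1L || length(unique(exons$strand[i])) != 1L)
      stop("transcript ", id, ": exons on multiple chroms/strands")
    if (length(i) > 1L) {
      s <- exons$start[i]; e <- exons$end[i]
      if (any(s[-1L] - e[-length(e)] < 1))
        stop("transcript ", id, ": overlapping or abutting exons (intron length < 1)")
    }
  }

  first <- exons[!duplicated(exons$transcript_id), c("transcript_id", "chrom", "strand")]
  agg_start <- tapply(exons$start, exons$transcript_id, min)
  agg_end <- tapply(exons$end, exons$transcript_id, max)
  n_ex <- tapply(exons$start, exons$transcript_id, length)
  tx <- data.frame(
    transcript_id = first$transcript_id,
    chrom = first$chrom,
    strand = first$strand,
    start = as.numeric(agg_start[first$transcript_id]),
    end = as.numeric(agg_end[first$transcript_id]),
    n_exons = as.integer(n_ex[first$transcript_id]),
    stringsAsFactors = FALSE
  )
  tx$tss <- ifelse(tx$strand == "+", tx$start, tx$end)
  tx$tes <- ifelse(tx$strand == "+", tx$end, tx$start)

  tx$gene_id <- NA_character_
  tx$read_support <- 0L
  tx$source <- source_tag
  if (!is.null(meta)) {
    meta$transcript_id <- as.character(meta$transcript_id)
    if (anyDuplicated(meta$transcript_id)) stop("duplicate transcript_id in meta")
    m <- match(tx$transcript_id, meta$transcript_id)
    if ("gene_id" %in% names(meta)) tx$gene_id <- as.character(meta$gene_id)[m]
    if ("read_support" %in% names(meta)) {
      rs <- as.integer(meta$read_support)[m]
      rs[is.na(rs)] <- 0L
      if (any(rs < 0)) stop("read_support must be non-negative")
      tx$read_support <- rs
    }
    if ("source" %in% names(meta)) {
      src <- as.character(meta$source)[m]
      src[is.na(src)] <- source_tag
      tx$source <- src
    }
  }
  if (!all(tx$source %in% c("reference", "observed", "assembled")))
    stop("source must be one of reference/observed/assembled")

  rownames(tx) <- tx$transcript_id
  rownames(exons) <- NULL
  structure(list(transcripts = tx, exons = exons), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", nrow(x$transcripts), "transcripts,",
      length(unique(stats::na.omit(x$transcripts$gene_id))), "assigned genes\n")
  invisible(x)
}

#' Number of transcripts in an annotation set
#' @param x annotation_set
#' @export
n_transcripts <- function(x) nrow(x$transcripts)

#' Exon chains as a named list of matrices
#'
#' @param x annotation_set
#' @param ids transcript ids (default: all)
#' @return named list; each element a numeric matrix with columns
#'   `start`, `end`, rows in ascending genomic order.
#' @export
exon_chains <- function(x, ids = NULL) {
  ex <- x$exons
  if (!is.null(ids)) ex <- ex[ex$transcript_id %in% ids, , drop = FALSE]
  sp <- split(seq_len(nrow(ex)), ex$transcript_id)
  lapply(sp, function(i) cbind(start = ex$start[i], end = ex$end[i]))
}

#' Intron chains as a named list of matrices
#'
#' The intron chain of a transcript is the ordered list of (donor, acceptor)
#' coordinate pairs between consecutive exons; empty (0-row) iff mono-exonic.
#'
#' @inheritParams exon_chains
#' @return named list of numeric matrices with columns `start`, `end`
#'   (0-based half-open intron intervals, ascending).
#' @export
intron_chains <- function(x, ids = NULL) {
  lapply(exon_chains(x, ids), chain_introns)
}

# introns of one exon matrix
chain_introns <- function(em) {
  n <- nrow(em)
  if (n < 2L) return(cbind(start = numeric(0), end = numeric(0)))
  cbind(start = em[-n, "end"], end = em[-1L, "start"])
}

# splice sites (internal exon boundaries) of one exon matrix
chain_sites <- function(em) {
  ic <- chain_introns(em)
  sort(unique(c(ic[, "start"], ic[, "end"])))
}

# GRanges of transcript spans, used for overlap queries
tx_span_granges <- function(x) {
  tx <- x$transcripts
  GenomicRanges::GRanges(
    seqnames = tx$chrom,
    ranges = IRanges::IRanges(start = tx$start + 1L, end = tx$end),
    strand = tx$strand,
    transcript_id = tx$transcript_id,
    gene_id = tx$gene_id
  )
}

#' Subset an annotation set by transcript id
#' @param x annotation_set
#' @param ids transcript ids to keep
#' @export
subset_transcripts <- function(x, ids) {
  annotation_set(
    x$exons[x$exons$transcript_id %in% ids, , drop = FALSE],
    meta = x$transcripts[x$transcripts$transcript_id %in% ids,
                         c("transcript_id", "gene_id", "read_support", "source")]
  )
}

#' Gene membership mapping
#' @param x annotation_set
#' @return named list gene_id -> character vector of transcript ids
#' @export
gene_map <- function(x) {
  tx <- x$transcripts
  keep <- !is.na(tx$gene_id)
  split(tx$transcript_id[keep], tx$gene_id[keep])
}

#' Read a GTF/GFF3 annotation
#'
#' Exon records are grouped per transcript and converted from the file's
#' 1-based inclusive coordinates to the internal 0-based half-open convention.
#'
#' @param path GTF or GFF3 file.
#' @param source_tag source to tag transcripts with
#'   (`"reference"`/`"observed"`/`"assembled"`).
#' @return annotation_set
#' @export
read_annotation <- function(path, source_tag = "reference") {
  if (!file.exists(path)) stop("no such file: ", path)
  fmt <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "gtf"
  gr <- tryCatch(rtracklayer::import(path, format = fmt),
                 error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  gr <- gr[!is.na(md$type) & tolower(as.character(md$type)) == "exon"]
  if (length(gr) == 0L) stop("no exon records in ", path)
  md <- S4Vectors::mcols(gr)
  if (is.null(md$transcript_id)) {
    # GFF3 dialect: exon Parent is the transcript
    if (!is.null(md$Parent)) {
      md$transcript_id <- vapply(md$Parent, function(p) sub("^transcript:", "", p[1]), character(1))
    } else stop("exon records carry no transcript_id")
  }
  ex <- data.frame(
    transcript_id = as.character(md$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    stringsAsFactors = FALSE
  )
  gene <- if (!is.null(md$gene_id)) as.character(md$gene_id) else NA_character_
  meta <- unique(data.frame(transcript_id = ex$transcript_id, gene_id = gene,
                            stringsAsFactors = FALSE))
  if (anyDuplicated(meta$transcript_id))
    stop("transcript assigned to multiple gene_ids in ", path)
  annotation_set(ex, meta = meta, source_tag = source_tag)
}

#' Read observed transcript models from BED12
#'
#' blockStarts/blockSizes are expanded to exons; the BED score column, when
#' present, is taken as the long-read support count.
#'
#' @param path BED12 file.
#' @param source_tag source tag, default `"observed"`.
#' @return annotation_set
#' @export
read_bed12 <- function(path, source_tag = "observed") {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  bl <- rtracklayer::blocks(gr)
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- paste0("bed_tx_", seq_along(gr))
  sup <- S4Vectors::mcols(gr)$score
  if (is.null(sup)) sup <- rep(1L, length(gr))
  rows <- lapply(seq_along(gr), function(i) {
    b <- bl[[i]]
    data.frame(
      transcript_id = nm[i],
      chrom = as.character(GenomicRanges::seqnames(gr[i])),
      strand = as.character(GenomicRanges::strand(gr[i])),
      start = GenomicRanges::start(b) - 1,
      end = as.numeric(GenomicRanges::end(b)),
      stringsAsFactors = FALSE
    )
  })
  ex <- do.call(rbind, rows)
  meta <- data.frame(transcript_id = nm, read_support = as.integer(round(sup)),
                     stringsAsFactors = FALSE)
  annotation_set(ex, meta = meta, source_tag = source_tag)
}

#' Write an annotation set as GTF
#'
#' Output ordering is fixed (chrom, start, transcript_id) so that writing the
#' same set twice yields byte-identical files. Round-trips through
#' [read_annotation()] reproduce all exon chains and ids exactly.
#'
#' @param x annotation_set
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_annotation <- function(x, path) {
  con <- tryCatch(file(path, "w"), error = function(e) stop("cannot write ", path))
  on.exit(close(con))
  writeLines("#gtf produced by txdiversity", con)
  if (nrow(x$transcripts) == 0L) return(invisible(path))
  tx <- x$transcripts
  ord <- order(tx$chrom, tx$start, tx$transcript_id)
  for (i in ord) {
    id <- tx$transcript_id[i]
    gid <- tx$gene_id[i]
    ex <- x$exons[x$exons$transcript_id == id, , drop = FALSE]
    attr_str <- sprintf('transcript_id "%s";%s', id,
                        if (is.na(gid)) "" else sprintf(' gene_id "%s";', gid))
    lines <- sprintf("%s\ttxdiversity\texon\t%d\t%d\t.\t%s\t.\t%s",
                     ex$chrom, as.integer(ex$start + 1), as.integer(ex$end),
                     ex$strand, attr_str)
    writeLines(lines, con)
  }
  invisible(path)
}

# ---- expression matrices -------------------------------------------------

#' Construct an expression matrix
#'
#' @param values numeric matrix, features x samples, non-negative.
#' @param design named character vector mapping sample_id -> condition label;
#'   exactly two conditions.
#' @param unit one of `"counts"`, `"cpm"`, `"fpkm"`.
#' @param feature_lengths optional named numeric vector of exonic lengths
#'   (bp), required for FPKM computation.
#' @return object of class `expression_matrix`
#' @export
expression_matrix <- function(values, design, unit = "counts", feature_lengths = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (any(values < 0)) stop("negative expression values")
  if (!all(colnames(values) %in% names(design)))
    stop("samples missing from design: ",
         paste(setdiff(colnames(values), names(design)), collapse = ", "))
  design <- design[colnames(values)]
  conds <- unique(unname(design))
  if (length(conds) != 2L) stop("design must have exactly two conditions")
  unit <- match.arg(unit, c("counts", "cpm", "fpkm"))
  if (!is.null(feature_lengths)) {
    if (!all(rownames(values) %in% names(feature_lengths)))
      stop("feature_lengths missing features")
    feature_lengths <- feature_lengths[rownames(values)]
  }
  structure(list(values = values, design = design, unit = unit,
                 feature_lengths = feature_lengths,
                 conditions = conds),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix [", x$unit, "]: ", nrow(x$values), " features x ",
      ncol(x$values), " samples (", paste(x$conditions, collapse = " vs "), ")\n", sep = "")
  invisible(x)
}

#' Read an expression table (TSV)
#'
#' @param path TSV with a feature-id first column and one numeric column per
#'   sample.
#' @param design named character vector sample -> condition, or the path to a
#'   YAML file containing such a mapping.
#' @inheritParams expression_matrix
#' @export
read_expression <- function(path, design, unit = "counts", feature_lengths = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (anyDuplicated(tab[[1]])) stop("duplicate feature id in ", path)
  v <- as.matrix(tab[, -1, drop = FALSE])
  rownames(v) <- tab[[1]]
  if (is.character(design) && length(design) == 1L && file.exists(design))
    design <- unlist(yaml::read_yaml(design))
  expression_matrix(v, design, unit = unit, feature_lengths = feature_lengths)
}

#' Counts per million
#'
#' `cpm[i,j] = count[i,j] / colsum[j] * 1e6`; every column of the result sums
#' to 1e6.
#'
#' @param m expression_matrix of counts.
#' @export
compute_cpm <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$unit != "counts") stop("compute_cpm requires counts, got ", m$unit)
  cs <- colSums(m$values)
  if (any(cs <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(m$values)[cs <= 0], collapse = ", "))
  v <- sweep(m$values, 2, cs, "/") * 1e6
  expression_matrix(v, m$design, unit = "cpm", feature_lengths = m$feature_lengths)
}

#' Fragments per kilobase per million
#'
#' `fpkm[i,j] = count[i,j] * 1e9 / (colsum[j] * length[i])`, with `length`
#' the annotated exonic length in bp.
#'
#' @param m expression_matrix of counts with `feature_lengths` set.
#' @export
compute_fpkm <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$unit != "counts") stop("compute_fpkm requires counts, got ", m$unit)
  if (is.null(m$feature_lengths)) stop("feature_lengths required for FPKM")
  len <- m$feature_lengths
  if (any(is.na(len) | len <= 0))
    stop("missing/invalid length for feature(s): ",
         paste(rownames(m$values)[is.na(len) | len <= 0], collapse = ", "))
  cs <- colSums(m$values)
  if (any(cs <= 0))
    stop("zero library size for sample(s): ",
         paste(colnames(m$values)[cs <= 0], collapse = ", "))
  v <- sweep(m$values, 2, cs, "/")
  v <- sweep(v, 1, len, "/") * 1e9
  expression_matrix(v, m$design, unit = "fpkm", feature_lengths = m$feature_lengths)
}

#' Per-condition mean expression
#'
#' @param m expression_matrix
#' @return features x 2 matrix of within-condition means, columns named by
#'   condition.
#' @export
condition_means <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  sapply(m$conditions, function(cc) {
    rowMeans(m$values[, names(m$design)[m$design == cc], drop = FALSE])
  })
}

#' Exonic length of each transcript
#' @param x annotation_set
#' @return named numeric vector of summed exon lengths (bp)
#' @export
transcript_lengths <- function(x) {
  len <- tapply(x$exons$end - x$exons$start, x$exons$transcript_id, sum)
  setNames(as.numeric(len), names(len))[x$transcripts$transcript_id]
}
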