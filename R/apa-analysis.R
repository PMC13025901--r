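#' Cluster transcript 3' ends into polyadenylation sites
#'
#' Strand-aware transcript end sites (TES) of a gene's observed transcripts
#' are merged by single-linkage clustering: two ends belong to the same PAS
#' cluster when they are within `cluster_window` nt of each other through a
#' chain of such links. Clusters whose summed long-read support falls below
#' `min_support` are discarded. The representative cleavage position is the
#' support-weighted mode of member ends (ties resolved to the downstream-most
#' position in transcription direction).
#'
#' @param x observed annotation_set with gene assignments and read support.
#' @param cluster_window single-linkage distance (nt, default 24).
#' @param min_support minimum summed read support per reported cluster
#'   (default 2).
#' @param tx_expr optional expression_matrix of transcript FPKM; when given,
#'   per-condition usage of each cluster is the summed condition-mean
#'   expression of its member transcripts.
#' @param genes optional restriction of the genes processed.
#' @return data.frame: gene_id, cluster_id, position, n_members,
#'   read_support, member_ids (comma-joined), plus `usage_<condition>`
#'   columns when `tx_expr` is given.
#' @export
cluster_pas <- function(x, cluster_window = 24, min_support = 2,
                        tx_expr = NULL, genes = NULL) {
  tx <- x$transcripts
  keep <- !is.na(tx$gene_id)
  if (!is.null(genes)) keep <- keep & tx$gene_id %in% genes
  tx <- tx[keep, , drop = FALSE]
  usage <- NULL
  if (!is.null(tx_expr)) {
    cm <- condition_means(tx_expr)
    usage <- cm[match(tx$transcript_id, rownames(cm)), , drop = FALSE]
    usage[is.na(usage)] <- 0
  }
  rows <- list()
  for (g in unique(tx$gene_id)) {
    i <- which(tx$gene_id == g)
    strand <- tx$strand[i[1]]
    ends <- tx$tes[i]
    ord <- order(ends)
    ends_s <- ends[ord]; idx_s <- i[ord]
    # single-linkage: break where adjacent gap exceeds the window
    brk <- c(0, cumsum(diff(ends_s) > cluster_window))
    for (k in unique(brk)) {
      mem <- idx_s[brk == k]
      sup <- sum(tx$read_support[mem])
      if (sup < min_support) next
      e <- tx$tes[mem]
      wt <- tapply(tx$read_support[mem], e, sum)
      best <- as.numeric(names(wt)[wt == max(wt)])
      pos <- if (strand == "+") max(best) else min(best)
      row <- data.frame(
        gene_id = g, cluster_id = NA_character_, position = pos,
        chrom = tx$chrom[i[1]],
        strand = strand, n_members = length(mem), read_support = sup,
        member_ids = paste(sort(tx$transcript_id[mem]), collapse = ","),
        stringsAsFactors = FALSE)
      if (!is.null(usage)) {
        u <- colSums(usage[mem, , drop = FALSE])
        for (cc in colnames(usage)) row[[paste0("usage_", cc)]] <- u[[cc]]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(0), cluster_id = character(0),
                      position = numeric(0), chrom = character(0),
                      strand = character(0),
                      n_members = integer(0), read_support = numeric(0),
                      member_ids = character(0)))
  out <- do.call(rbind, rows)
  # order clusters 5'->3' in transcription direction within gene
  out <- out[order(out$gene_id, ifelse(out$strand == "+", 1, -1) * out$position), ]
  sp <- split(seq_len(nrow(out)), out$gene_id)
  for (g in names(sp)) out$cluster_id[sp[[g]]] <- paste0(g, ":PAS", seq_along(sp[[g]]))
  rownames(out) <- NULL
  out
}

#' Call APA genes and their UTRR geometry
#'
#' A gene is an APA gene when at least two PAS clusters survive both the
#' transcript-end evidence and the read-support threshold. The UTRR is the
#' genomic distance between the first and last PAS; the midpoint lies halfway
#' between them along the transcription direction.
#'
#' @param clusters output of [cluster_pas()].
#' @return data.frame: gene_id, n_pas, first_pas, last_pas (transcription
#'   order), utrr_length, midpoint.
#' @export
call_apa_genes <- function(clusters) {
  sp <- split(seq_len(nrow(clusters)), clusters$gene_id)
  rows <- list()
  for (g in names(sp)) {
    i <- sp[[g]]
    if (length(i) < 2L) next
    pos <- clusters$position[i]          # already in transcription order
    first <- pos[1]; last <- pos[length(pos)]
    utrr <- abs(last - first)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, n_pas = length(i), strand = clusters$strand[i[1]],
      first_pas = first, last_pas = last, utrr_length = utrr,
      midpoint = (first + last) / 2, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(0), n_pas = integer(0),
                      strand = character(0), first_pas = numeric(0),
                      last_pas = numeric(0), utrr_length = numeric(0),
                      midpoint = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# is position p strictly downstream of midpoint mid in transcription
# direction on `strand`?
is_downstream <- function(p, mid, strand) {
  if (strand[1] == "+") p > mid else p < mid
}

#' Classify APA genes as distal (M) or proximal (P) dominated
#'
#' Isoforms whose PAS lies strictly downstream of the UTRR midpoint (in
#' transcription direction) are distal (M) isoforms; strictly upstream,
#' proximal (m). A PAS exactly at the midpoint joins neither sum. Per
#' condition, `mp_status` is M when the M/m expression ratio exceeds 1, P
#' when below 1, and `tie` when equal (including both sums zero); an empty m
#' sum with expressed M isoforms is status M (ratio infinite).
#'
#' @param apa output of [call_apa_genes()].
#' @param clusters output of [cluster_pas()] with usage columns.
#' @param conditions the two condition labels.
#' @return `apa` with added `M_<cond>`, `m_<cond>`, `mp_status_<cond>`
#'   columns.
#' @export
classify_mp <- function(apa, clusters, conditions) {
  ucol <- paste0("usage_", conditions)
  stopifnot(all(ucol %in% names(clusters)))
  for (cc in conditions) {
    Ms <- numeric(nrow(apa)); ms <- numeric(nrow(apa)); st <- character(nrow(apa))
    for (i in seq_len(nrow(apa))) {
      cl <- clusters[clusters$gene_id == apa$gene_id[i], , drop = FALSE]
      u <- cl[[paste0("usage_", cc)]]
      down <- is_downstream(cl$position, apa$midpoint[i], apa$strand[i])
      up <- is_downstream(apa$midpoint[i], cl$position, apa$strand[i])
      Ms[i] <- sum(u[down]); ms[i] <- sum(u[up])
      st[i] <- if (Ms[i] > ms[i]) "M" else if (Ms[i] < ms[i]) "P" else "tie"
    }
    apa[[paste0("M_", cc)]] <- Ms
    apa[[paste0("m_", cc)]] <- ms
    apa[[paste0("mp_status_", cc)]] <- st
  }
  apa
}

#' Major PAS per condition and shift detection
#'
#' The major PAS (mPAS) of a gene in a condition is the cluster with the
#' highest usage (ties resolved to the downstream-most cluster); the shift
#' flag records whether the mPAS identity differs between the two
#' conditions. Zero usage in a condition leaves the mPAS undefined there and
#' the shift flag NA.
#'
#' @inheritParams classify_mp
#' @return data.frame: gene_id, mpas_<cond1>, mpas_<cond2>, mpas_shift.
#' @export
call_mpas <- function(apa, clusters, conditions) {
  res <- data.frame(gene_id = apa$gene_id, stringsAsFactors = FALSE)
  picks <- list()
  for (cc in conditions) {
    pk <- character(nrow(apa))
    for (i in seq_len(nrow(apa))) {
      cl <- clusters[clusters$gene_id == apa$gene_id[i], , drop = FALSE]
      u <- cl[[paste0("usage_", cc)]]
      if (all(u == 0)) { pk[i] <- NA_character_; next }
      cand <- which(u == max(u))
      # downstream-most: clusters are already in transcription order
      pk[i] <- cl$cluster_id[cand[length(cand)]]
    }
    picks[[cc]] <- pk
    res[[paste0("mpas_", cc)]] <- pk
  }
  res$mpas_shift <- ifelse(is.na(picks[[1]]) | is.na(picks[[2]]), NA,
                           picks[[1]] != picks[[2]])
  res
}

#' Scan upstream windows of PAS clusters for poly(A)-signal hexamers
#'
#' For each PAS the `window_up` nt immediately upstream (mRNA sense;
#' reverse-complemented on the minus strand) are extracted and all
#' overlapping hexamers counted across sites.
#'
#' @param genome named DNAStringSet or character vector of contigs.
#' @param clusters output of [cluster_pas()].
#' @param window_up upstream window size in nt (default 50).
#' @return list: `table` (data.frame hexamer, count, rank, sorted), `aataaa_rank`,
#'   `n_truncated` (windows clipped at a contig edge).
#' @export
scan_pas_signal <- function(genome, clusters, window_up = 50) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  gl <- Biostrings::width(genome)
  names(gl) <- names(genome)
  tx_chrom <- clusters$chrom
  if (is.null(tx_chrom)) {
    # fall back to gene_id prefix "chrom|..." if provided, else single contig
    if (length(genome) == 1L) tx_chrom <- rep(names(genome)[1], nrow(clusters))
    else stop("clusters need a chrom column for multi-contig genomes")
  }
  n_trunc <- 0L
  wins <- character(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    pos <- clusters$position[i]
    chrom <- tx_chrom[i]
    if (clusters$strand[i] == "+") {
      s <- max(1, pos - window_up + 1); e <- min(pos, gl[[chrom]])
      if (pos - window_up + 1 < 1) n_trunc <- n_trunc + 1L
      if (s > e) { wins[i] <- ""; next }
      w <- Biostrings::subseq(genome[[chrom]], s, e)
    } else {
      s <- max(1, pos + 1); e <- min(pos + window_up, gl[[chrom]])
      if (pos + window_up > gl[[chrom]]) n_trunc <- n_trunc + 1L
      if (s > e) { wins[i] <- ""; next }
      w <- Biostrings::reverseComplement(Biostrings::subseq(genome[[chrom]], s, e))
    }
    wins[i] <- as.character(w)
  }
  wins <- wins[nchar(wins) >= 6]
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(wins), width = 6)
  tot <- colSums(counts)
  tot <- tot[tot > 0]
  tab <- data.frame(hexamer = names(tot), count = as.integer(tot),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$count, tab$hexamer), ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  list(table = tab,
       aataaa_rank = if ("AATAAA" %in% tab$hexamer)
         tab$rank[tab$hexamer == "AATAAA"] else NA_integer_,
       n_truncated = n_trunc)
}

#' 3'-UTR and UTRR length distributions
#'
#' The 3'-UTR length of an isoform is the distance from its stop codon to
#' its 3' end along the spliced transcript, using the longest predicted ORF.
#' Isoforms without an ORF are excluded (and counted); an ORF ending at or
#' beyond the transcript end marks the isoform invalid for this statistic.
#'
#' @param x observed annotation_set.
#' @param genome contig sequences.
#' @param ids transcripts to measure (default: all with gene assignment).
#' @param bin_width histogram bin width in bp (default 100).
#' @param min_aa minimum ORF length for a coding call.
#' @return list: `per_transcript` (transcript_id, utr3_length),
#'   `histogram` (bin_start, count), `mode_bin`, `n_no_orf`.
#' @export
utr3_length_distribution <- function(x, genome, ids = NULL, bin_width = 100,
                                     min_aa = 50) {
  if (is.null(ids)) ids <- x$transcripts$transcript_id[!is.na(x$transcripts$gene_id)]
  seqs <- spliced_sequences(x, genome, ids)
  n_no_orf <- 0L
  rows <- list()
  for (id in names(seqs)) {
    orf <- predict_orf(seqs[[id]], min_aa = min_aa)
    if (is.null(orf)) { n_no_orf <- n_no_orf + 1L; next }
    utr <- length(seqs[[id]]) - orf$end
    if (utr < 0) next
    rows[[length(rows) + 1L]] <- data.frame(transcript_id = id,
                                            utr3_length = utr,
                                            stringsAsFactors = FALSE)
  }
  per <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(transcript_id = character(0), utr3_length = numeric(0))
  if (nrow(per) > 0) {
    bins <- floor(per$utr3_length / bin_width) * bin_width
    h <- table(bins)
    hist <- data.frame(bin_start = as.numeric(names(h)), count = as.integer(h))
    mode_bin <- hist$bin_start[which.max(hist$count)]
  } else {
    hist <- data.frame(bin_start = numeric(0), count = integer(0))
    mode_bin <- NA_real_
  }
  list(per_transcript = per, histogram = hist, mode_bin = mode_bin,
       n_no_orf = n_no_orf)
}
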