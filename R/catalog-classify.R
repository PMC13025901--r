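#' @importFrom Biostrings DNAString DNAStringSet reverseComplement subseq
NULL

STRUCTURAL_CATEGORIES <- c("FSM", "ISM", "NIC", "NNC", "fusion", "genic",
                           "antisense", "intergenic")

#' Filter alignment summaries
#'
#' Retains transcripts with alignment identity and coverage at or above the
#' thresholds (strictly-below values are removed), then collapses 5'-degraded
#' duplicates: within each `tss_equivalence_group` (same intron chain and 3'
#' end, differing only at the 5' terminus) only the longest member is kept.
#'
#' @param records data.frame with columns `transcript_id`, `identity`,
#'   `coverage`, and optionally `tss_equivalence_group` and `length`.
#' @param min_identity,min_coverage retention thresholds (defaults 0.9, 0.85).
#' @param lengths optional named vector of transcript lengths used to pick
#'   the group representative when `records$length` is absent.
#' @return character vector of retained transcript ids.
#' @export
filter_alignments <- function(records, min_identity = 0.9, min_coverage = 0.85,
                              lengths = NULL) {
  if (nrow(records) == 0L) return(character(0))
  stopifnot(all(c("transcript_id", "identity", "coverage") %in% names(records)))
  if (any(records$identity < 0 | records$identity > 1 |
          records$coverage < 0 | records$coverage > 1))
    stop("identity and coverage must lie in [0, 1]")
  keep <- records$identity >= min_identity & records$coverage >= min_coverage
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0L) return(character(0))
  grp <- rec$tss_equivalence_group
  if (is.null(grp)) return(rec$transcript_id)
  len <- rec$length
  if (is.null(len)) {
    if (is.null(lengths)) stop("need length column or lengths= to collapse 5' duplicates")
    len <- unname(lengths[rec$transcript_id])
  }
  ungrouped <- is.na(grp) | grp == ""
  kept <- rec$transcript_id[ungrouped]
  if (any(!ungrouped)) {
    sp <- split(which(!ungrouped), grp[!ungrouped])
    reps <- vapply(sp, function(i) {
      rec$transcript_id[i][which.max(len[i])]
    }, character(1))
    kept <- c(kept, unname(reps))
  }
  rec$transcript_id[rec$transcript_id %in% kept]
}

# ---- reference index -----------------------------------------------------

# Precomputed per-gene reference structures used by the classifier.
build_reference_index <- function(reference) {
  tx <- reference$transcripts
  if (any(is.na(tx$gene_id))) stop("reference transcripts must all carry gene_id")
  chains <- exon_chains(reference)
  genes <- split(tx$transcript_id, tx$gene_id)
  gene_info <- lapply(names(genes), function(g) {
    ids <- genes[[g]]
    ems <- chains[ids]
    introns <- lapply(ems, chain_introns)
    sites <- sort(unique(unlist(lapply(introns, function(ic) c(ic[, 1], ic[, 2])))))
    junctions <- unique(unlist(lapply(introns, function(ic) {
      if (nrow(ic) == 0L) character(0) else paste(ic[, 1], ic[, 2], sep = "-")
    })))
    ex <- do.call(rbind, ems)
    list(
      gene_id = g,
      chrom = tx$chrom[match(ids[1], tx$transcript_id)],
      strand = tx$strand[match(ids[1], tx$transcript_id)],
      start = min(ex[, "start"]), end = max(ex[, "end"]),
      transcript_ids = ids,
      exon_union = ex,
      sites = sites,
      junctions = junctions,
      introns = introns
    )
  })
  names(gene_info) <- names(genes)
  list(genes = gene_info, chains = chains, tx = tx)
}

# total overlap (bp) between an exon matrix and a set of intervals
exonic_overlap_bp <- function(em, iv) {
  if (nrow(em) == 0L || nrow(iv) == 0L) return(0)
  tot <- 0
  for (i in seq_len(nrow(em))) {
    o <- pmin(em[i, "end"], iv[, "end"]) - pmax(em[i, "start"], iv[, "start"])
    tot <- tot + sum(pmax(o, 0))
  }
  tot
}

chains_equal <- function(a, b, tol = 0) {
  nrow(a) == nrow(b) && nrow(a) > 0 && all(abs(a - b) <= tol)
}

# is chain `a` a contiguous sub-chain of `b`?
is_subchain <- function(a, b, tol = 0) {
  na <- nrow(a); nb <- nrow(b)
  if (na == 0L || na >= nb) return(FALSE)
  for (off in 0:(nb - na)) {
    if (all(abs(a - b[(off + 1):(off + na), , drop = FALSE]) <= tol)) return(TRUE)
  }
  FALSE
}

#' Classify observed transcripts against a reference annotation
#'
#' Each observed transcript is placed into exactly one of eight structural
#' categories by a decision cascade over same-strand overlapping reference
#' genes: fusion (spans exonic sequence of two or more genes), FSM (intron
#' chain identical to a reference transcript), ISM (contiguous sub-chain),
#' NIC (only known splice sites, in a combination absent from the catalog),
#' NNC (at least one novel splice site), genic (mono-exonic within a gene),
#' antisense (overlaps a gene only on the opposite strand) and intergenic.
#' Antisense/intergenic transcripts are grouped into novel gene loci by
#' single-linkage overlap merging on the same strand.
#'
#' @param observed annotation_set of observed transcript models.
#' @param reference annotation_set with gene_id set on every transcript.
#' @param junction_tolerance maximum splice-site offset (nt) still treated as
#'   a match; default 0 (exact).
#' @param mono_fsm_overlap reciprocal-overlap fraction at which a mono-exon
#'   transcript matching a mono-exon reference transcript is called FSM.
#' @return data.frame with one row per observed transcript: `transcript_id`,
#'   `category`, `assigned_gene_id`, `matched_reference_transcript`,
#'   `n_novel_sites`, `junction_match_fraction`.
#' @export
classify_transcripts <- function(observed, reference, junction_tolerance = 0,
                                 mono_fsm_overlap = 0.8) {
  idx <- build_reference_index(reference)
  chains <- exon_chains(observed)
  tx <- observed$transcripts
  if (nrow(tx) == 0L)
    return(data.frame(transcript_id = character(0), category = character(0),
                      assigned_gene_id = character(0),
                      matched_reference_transcript = character(0),
                      n_novel_sites = integer(0),
                      junction_match_fraction = numeric(0)))
  out <- lapply(seq_len(nrow(tx)), function(i) {
    classify_one(tx[i, ], chains[[tx$transcript_id[i]]], idx,
                 tol = junction_tolerance, mono_fsm_overlap = mono_fsm_overlap)
  })
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  assign_novel_loci(calls, observed)
}

classify_one <- function(trow, em, idx, tol, mono_fsm_overlap) {
  cand_same <- Filter(function(g) {
    g$chrom == trow$chrom && g$strand == trow$strand &&
      g$start < trow$end && trow$start < g$end
  }, idx$genes)
  cand_anti <- Filter(function(g) {
    g$chrom == trow$chrom && g$strand != trow$strand &&
      g$start < trow$end && trow$start < g$end
  }, idx$genes)

  mk <- function(category, gene = NA_character_, match_tx = NA_character_,
                 novel_sites = NA_integer_, jmf = NA_real_) {
    data.frame(transcript_id = trow$transcript_id, category = category,
               assigned_gene_id = gene, matched_reference_transcript = match_tx,
               n_novel_sites = novel_sites, junction_match_fraction = jmf,
               stringsAsFactors = FALSE)
  }

  if (length(cand_same) == 0L) {
    if (length(cand_anti) > 0L) return(mk("antisense"))
    return(mk("intergenic"))
  }

  ic <- chain_introns(em)
  sites <- chain_sites(em)
  jkeys <- if (nrow(ic) > 0L) paste(ic[, 1], ic[, 2], sep = "-") else character(0)

  # fusion: exonic sequence of >= 2 distinct same-strand genes covered
  exonic_genes <- Filter(function(g) exonic_overlap_bp(em, g$exon_union) > 0, cand_same)
  # assigned gene: most matched junctions, ties by exonic overlap
  score <- vapply(cand_same, function(g) {
    if (tol == 0) sum(jkeys %in% g$junctions) else {
      sum(vapply(seq_len(nrow(ic)), function(k) {
        any(vapply(g$introns, function(ri) {
          nrow(ri) > 0 && any(abs(ri[, 1] - ic[k, 1]) <= tol & abs(ri[, 2] - ic[k, 2]) <= tol)
        }, logical(1)))
      }, logical(1)))
    }
  }, numeric(1))
  ov <- vapply(cand_same, function(g) exonic_overlap_bp(em, g$exon_union), numeric(1))
  best <- which(score == max(score))
  if (length(best) > 1L) best <- best[which.max(ov[best])]
  gene <- cand_same[[best]]
  jmf <- if (length(jkeys) > 0) max(score) / length(jkeys) else NA_real_

  if (length(exonic_genes) >= 2L)
    return(mk("fusion", gene$gene_id, novel_sites = 0L, jmf = jmf))

  if (nrow(ic) > 0L) {
    # FSM / ISM against every transcript of every overlapping gene
    for (g in cand_same) {
      for (tid in g$transcript_ids) {
        if (chains_equal(ic, g$introns[[tid]], tol))
          return(mk("FSM", g$gene_id, tid, 0L, 1))
      }
    }
    for (g in cand_same) {
      for (tid in g$transcript_ids) {
        if (is_subchain(ic, g$introns[[tid]], tol))
          return(mk("ISM", g$gene_id, tid, 0L, 1))
      }
    }
    if (tol == 0) {
      novel <- sum(!sites %in% gene$sites)
    } else {
      novel <- sum(vapply(sites, function(s) all(abs(gene$sites - s) > tol), logical(1)))
    }
    if (novel == 0L) return(mk("NIC", gene$gene_id, novel_sites = 0L, jmf = jmf))
    return(mk("NNC", gene$gene_id, novel_sites = as.integer(novel), jmf = jmf))
  }

  # mono-exonic over a same-strand gene
  for (g in cand_same) {
    for (tid in g$transcript_ids) {
      rem <- idx$chains[[tid]]
      if (nrow(rem) == 1L) {
        inter <- min(em[1, "end"], rem[1, "end"]) - max(em[1, "start"], rem[1, "start"])
        if (inter > 0 &&
            inter / (em[1, "end"] - em[1, "start"]) >= mono_fsm_overlap &&
            inter / (rem[1, "end"] - rem[1, "start"]) >= mono_fsm_overlap)
          return(mk("FSM", g$gene_id, tid, 0L, NA_real_))
      }
    }
  }
  mk("genic", gene$gene_id, novel_sites = 0L, jmf = NA_real_)
}

# Merge antisense/intergenic transcripts into novel gene loci by
# single-linkage same-strand overlap; assign NOVELG ids ordered by position.
assign_novel_loci <- function(calls, observed) {
  novel <- calls$category %in% c("antisense", "intergenic")
  if (!any(novel)) return(calls)
  tx <- observed$transcripts
  m <- match(calls$transcript_id[novel], tx$transcript_id)
  gr <- GenomicRanges::GRanges(tx$chrom[m],
                               IRanges::IRanges(tx$start[m] + 1L, tx$end[m]),
                               strand = tx$strand[m])
  red <- GenomicRanges::reduce(gr)
  red <- red[order(as.character(GenomicRanges::seqnames(red)),
                   GenomicRanges::start(red))]
  hit <- GenomicRanges::findOverlaps(gr, red)
  locus <- rep(NA_integer_, length(gr))
  locus[S4Vectors::queryHits(hit)] <- S4Vectors::subjectHits(hit)
  calls$assigned_gene_id[novel] <- sprintf("NOVELG_%04d", locus)
  calls
}

#' Catalog summary (Table-1-style tallies)
#'
#' Known transcripts are FSM calls; ISM calls match annotated structures but
#' carry distinct termini, so they are tallied separately
#' (`n_annotated_category` = FSM + ISM) rather than folded into the
#' known/novel split. Percentages are derived at report time, never stored.
#'
#' @param calls output of [classify_transcripts()].
#' @param observed annotation_set of the classified transcripts.
#' @return list of class `catalog_summary`.
#' @export
summarize_catalog <- function(calls, observed) {
  n_tx <- nrow(calls)
  cat_counts <- table(factor(calls$category, levels = STRUCTURAL_CATEGORIES))
  n_known <- sum(calls$category == "FSM")
  annotated_genes <- unique(calls$assigned_gene_id[
    !calls$category %in% c("antisense", "intergenic") & !is.na(calls$assigned_gene_id)])
  novel_genes <- unique(calls$assigned_gene_id[
    calls$category %in% c("antisense", "intergenic")])
  per_gene <- table(calls$assigned_gene_id)
  tx <- observed$transcripts
  m <- match(calls$transcript_id, tx$transcript_id)
  novelty <- ifelse(calls$category == "FSM", "known", "novel")
  len <- transcript_lengths(observed)[calls$transcript_id]
  structure(list(
    n_transcripts = n_tx,
    n_known = n_known,
    n_novel = n_tx - n_known,
    n_annotated_category = sum(calls$category %in% c("FSM", "ISM")),
    n_genes = length(annotated_genes) + length(novel_genes),
    n_annotated_genes = length(annotated_genes),
    n_novel_genes = length(novel_genes),
    genes_with_multiple_isoforms = sum(per_gene > 1),
    genes_with_ge10_isoforms = sum(per_gene >= 10),
    category_counts = as.integer(cat_counts),
    category_names = names(cat_counts),
    mean_length_by_novelty = tapply(len, novelty, mean),
    mean_exons_by_novelty = tapply(tx$n_exons[m], novelty, mean)
  ), class = "catalog_summary")
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("catalog_summary:", x$n_transcripts, "transcripts (",
      x$n_known, "known /", x$n_novel, "novel ),",
      x$n_genes, "genes (", x$n_novel_genes, "novel )\n")
  invisible(x)
}

# ---- ORF prediction ------------------------------------------------------

#' Spliced transcript sequences
#'
#' @param x annotation_set
#' @param genome named DNAStringSet (or character vector) of contig sequences.
#' @param ids transcripts to extract (default all).
#' @return DNAStringSet of mRNA-sense spliced sequences (reverse-complemented
#'   on the minus strand).
#' @export
spliced_sequences <- function(x, genome, ids = NULL) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  chains <- exon_chains(x, ids)
  tx <- x$transcripts
  seqs <- lapply(names(chains), function(id) {
    i <- match(id, tx$transcript_id)
    contig <- genome[[tx$chrom[i]]]
    if (tx$end[i] > length(contig)) stop("transcript ", id, " outside genome bounds")
    em <- chains[[id]]
    parts <- lapply(seq_len(nrow(em)), function(k)
      Biostrings::subseq(contig, em[k, "start"] + 1L, em[k, "end"]))
    s <- do.call(Biostrings::xscat, parts)
    if (tx$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    s
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(chains)
  out
}

#' Longest open reading frame of a spliced sequence
#'
#' Scans the mRNA sense strand in all three frames for the longest ATG-to-stop
#' ORF (the stop codon is required and not counted in the length).
#'
#' @param seq DNAString/character, the spliced mRNA-sense sequence.
#' @param min_aa minimum ORF length (aa) for a coding call (default 100).
#' @return list with `start`, `end` (1-based nt positions of the ORF within
#'   the spliced sequence, stop codon included), `length_aa` and `coding`;
#'   or NULL when no ORF exists.
#' @export
predict_orf <- function(seq, min_aa = 100) {
  s <- toupper(as.character(seq))
  n <- nchar(s)
  best <- NULL
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    len <- n - frame
    ncod <- len %/% 3
    if (ncod < 2) next
    codons <- substring(s, frame + 1 + 3 * (0:(ncod - 1)), frame + 3 + 3 * (0:(ncod - 1)))
    atg <- which(codons == "ATG")
    stp <- which(codons %in% stops)
    for (i in atg) {
      j <- stp[stp > i]
      if (length(j) == 0L) next
      j <- j[1]
      aa <- j - i
      if (is.null(best) || aa > best$length_aa) {
        best <- list(start = frame + 1 + 3 * (i - 1), end = frame + 3 * j,
                     length_aa = aa)
      }
    }
  }
  if (is.null(best)) return(NULL)
  best$coding <- best$length_aa >= min_aa
  best
}
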