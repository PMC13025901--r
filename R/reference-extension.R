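#' Extend reference transcript termini using assembled models
#'
#' Implements the reference-optimisation rule for incomplete annotations:
#' short-read assembled transcript models that overlap a reference
#' transcript's terminal exon on the same strand and protrude beyond its
#' terminus are collected; when at least `min_support` such models agree that
#' the transcript extends, the transcription start site is moved to the
#' *least*-protruding candidate 5' end (the shortest extension, a
#' conservative TSS) and the transcription end site to the *most*-protruding
#' candidate 3' end (the longest extension). Only terminal exon boundaries
#' move; internal splice junctions are never touched. A 5' terminus whose
#' current boundary coincides with some candidate model's 5' end is treated
#' as already evidence-defined and is not moved, which makes the operation
#' idempotent.
#'
#' @param reference annotation_set to extend.
#' @param assembled annotation_set of short-read assembled models.
#' @param min_support minimum number of protruding assembled models required
#'   at a terminus before it is moved (default 2, operationalising "multiple"
#'   overlapping models).
#' @param extend_5prime set FALSE to leave all 5' termini unchanged.
#' @return list with `annotation` (the extended annotation_set) and
#'   `extensions` (data.frame: transcript_id, end, old_boundary,
#'   new_boundary, n_supporting_models).
#' @export
extend_termini <- function(reference, assembled, min_support = 2,
                           extend_5prime = TRUE) {
  rtx <- reference$transcripts
  atx <- assembled$transcripts
  ach <- exon_chains(assembled)
  exons <- reference$exons
  recs <- list()

  for (i in seq_len(nrow(rtx))) {
    id <- rtx$transcript_id[i]
    strand <- rtx$strand[i]
    ex_i <- which(exons$transcript_id == id)
    ex <- exons[ex_i, , drop = FALSE]
    # terminal exons in genomic orientation
    first <- ex_i[which.min(ex$start)]
    last <- ex_i[which.max(ex$end)]
    cand <- which(atx$chrom == rtx$chrom[i] & atx$strand == strand)
    if (length(cand) == 0L) next

    # genomic-left terminus (5' on +, 3' on -)
    lex_s <- exons$start[first]; lex_e <- exons$end[first]
    ends_l <- numeric(0)  # candidate model boundaries at or beyond the terminus
    for (j in cand) {
      am <- ach[[atx$transcript_id[j]]]
      # must overlap the terminal exon
      o <- am[am[, "start"] < lex_e & am[, "end"] > lex_s, , drop = FALSE]
      if (nrow(o) > 0L && min(o[, "start"]) <= lex_s) ends_l <- c(ends_l, min(o[, "start"]))
    }
    prot_l <- ends_l[ends_l < lex_s]
    confirmed_l <- any(ends_l == lex_s)
    # genomic-right terminus (3' on +, 5' on -)
    rex_s <- exons$start[last]; rex_e <- exons$end[last]
    ends_r <- numeric(0)
    for (j in cand) {
      am <- ach[[atx$transcript_id[j]]]
      o <- am[am[, "start"] < rex_e & am[, "end"] > rex_s, , drop = FALSE]
      if (nrow(o) > 0L && max(o[, "end"]) >= rex_e) ends_r <- c(ends_r, max(o[, "end"]))
    }
    prot_r <- ends_r[ends_r > rex_e]
    confirmed_r <- any(ends_r == rex_e)

    left_is_5p <- strand == "+"
    # left boundary: 5' -> shortest protrusion (max candidate, unless the
    # boundary is already confirmed by a coinciding model end), 3' -> longest
    # protrusion (min candidate)
    if (length(prot_l) >= min_support &&
        (!left_is_5p || !confirmed_l)) {
      which_end <- if (left_is_5p) "five_prime" else "three_prime"
      if (which_end != "five_prime" || extend_5prime) {
        newb <- if (left_is_5p) max(prot_l) else min(prot_l)
        exons$start[first] <- newb
        recs[[length(recs) + 1L]] <- data.frame(
          transcript_id = id, end = which_end, old_boundary = lex_s,
          new_boundary = newb, n_supporting_models = length(prot_l),
          stringsAsFactors = FALSE)
      }
    }
    if (length(prot_r) >= min_support &&
        (left_is_5p || !confirmed_r)) {
      which_end <- if (left_is_5p) "three_prime" else "five_prime"
      if (which_end != "five_prime" || extend_5prime) {
        newb <- if (left_is_5p) max(prot_r) else min(prot_r)
        exons$end[last] <- newb
        recs[[length(recs) + 1L]] <- data.frame(
          transcript_id = id, end = which_end, old_boundary = rex_e,
          new_boundary = newb, n_supporting_models = length(prot_r),
          stringsAsFactors = FALSE)
      }
    }
  }

  ext <- if (length(recs) > 0L) do.call(rbind, recs) else
    data.frame(transcript_id = character(0), end = character(0),
               old_boundary = numeric(0), new_boundary = numeric(0),
               n_supporting_models = integer(0))
  ann <- annotation_set(exons,
                        meta = rtx[, c("transcript_id", "gene_id", "read_support", "source")])
  list(annotation = ann, extensions = ext)
}
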