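AS_TYPES <- c("ES", "IR", "A3SS", "A5SS", "MEE")

# Exonic-status segmentation of a transcript pair over their common genomic
# span. Returns a data.frame of segments with columns start, end, inA, inB,
# or NULL when the spans do not overlap.
pair_segments <- function(emA, emB) {
  cs <- max(min(emA[, "start"]), min(emB[, "start"]))
  ce <- min(max(emA[, "end"]), max(emB[, "end"]))
  if (cs >= ce) return(NULL)
  bp <- sort(unique(c(cs, ce,
                      emA[emA[, "start"] > cs & emA[, "start"] < ce, "start"],
                      emA[emA[, "end"] > cs & emA[, "end"] < ce, "end"],
                      emB[emB[, "start"] > cs & emB[, "start"] < ce, "start"],
                      emB[emB[, "end"] > cs & emB[, "end"] < ce, "end"])))
  s <- bp[-length(bp)]
  e <- bp[-1]
  mid <- (s + e) / 2
  in_exons <- function(em, p) {
    vapply(p, function(pp) any(em[, "start"] < pp & pp < em[, "end"]), logical(1))
  }
  data.frame(start = s, end = e, inA = in_exons(emA, mid), inB = in_exons(emB, mid))
}

# Decompose the differences between two exon chains into typed variant
# regions. Returns a data.frame (possibly 0-row) with columns event_type,
# anchor_start, anchor_end, region_start, region_end, inclusion (A/B).
pair_variant_regions <- function(emA, emB, strand) {
  seg <- pair_segments(emA, emB)
  if (is.null(seg)) return(empty_events())
  status <- ifelse(seg$inA & seg$inB, "both",
                   ifelse(!seg$inA & !seg$inB, "neither",
                          ifelse(seg$inA, "Aonly", "Bonly")))
  # groups of consecutive non-"both" segments, flanked by "both" on each side
  isboth <- status == "both"
  grp <- cumsum(isboth)
  out <- list()
  for (gidx in unique(grp[!isboth])) {
    rows <- which(grp == gidx & !isboth)
    if (length(rows) == 0L) next
    # must be flanked by shared-exonic agreement on both sides
    if (rows[1] == 1L || max(rows) == nrow(seg)) next
    if (!all(status[rows] %in% c("neither", "Aonly", "Bonly"))) next
    if (!any(status[rows] %in% c("Aonly", "Bonly"))) next  # shared intron
    gapL <- seg$start[rows[1]]
    gapR <- seg$end[rows[length(rows)]]
    ev <- type_variant_region(emA, emB, seg[rows, , drop = FALSE],
                              status[rows], gapL, gapR, strand)
    out[[length(out) + 1L]] <- ev
  }
  if (length(out) == 0L) return(empty_events())
  do.call(rbind, out)
}

empty_events <- function() {
  data.frame(event_type = character(0), anchor_start = numeric(0),
             anchor_end = numeric(0), region_start = numeric(0),
             region_end = numeric(0), inclusion = character(0))
}

sites_in_gap <- function(em, gapL, gapR) {
  ss <- chain_sites(em)
  ss[ss >= gapL & ss <= gapR]
}

type_variant_region <- function(emA, emB, seg, status, gapL, gapR, strand) {
  diffseg <- seg[status != "neither", , drop = FALSE]
  dstat <- status[status != "neither"]
  vr_start <- min(diffseg$start)
  vr_end <- max(diffseg$end)
  sA <- sites_in_gap(emA, gapL, gapR)
  sB <- sites_in_gap(emB, gapL, gapR)
  exA <- emA[emA[, "start"] >= gapL & emA[, "end"] <= gapR, , drop = FALSE]
  exB <- emB[emB[, "start"] >= gapL & emB[, "end"] <= gapR, , drop = FALSE]

  res <- function(type, inclusion) {
    data.frame(event_type = type, anchor_start = gapL, anchor_end = gapR,
               region_start = vr_start, region_end = vr_end,
               inclusion = inclusion, stringsAsFactors = FALSE)
  }

  # IR: one form spans the whole gap as uninterrupted exon, the other splices
  # it out with a single intron exactly [gapL, gapR)
  a_exonic_all <- all(seg$inA)
  b_exonic_all <- all(seg$inB)
  if (b_exonic_all && length(sB) == 0L &&
      identical(sort(sA), c(gapL, gapR)) && nrow(exA) == 0L &&
      !any(seg$inA))
    return(res("IR", "B"))
  if (a_exonic_all && length(sA) == 0L &&
      identical(sort(sB), c(gapL, gapR)) && nrow(exB) == 0L &&
      !any(seg$inB))
    return(res("IR", "A"))

  # from here on both forms must splice at the gap flanks for the clean types
  flanks_shared <- all(c(gapL, gapR) %in% sA) && all(c(gapL, gapR) %in% sB)

  # ES: one form intronic across the gap, the other carries >= 1 full exon
  if (flanks_shared) {
    if (!any(seg$inB) && nrow(exA) >= 1L &&
        setequal(sA, c(gapL, gapR, exA[, "start"], exA[, "end"])) &&
        length(sB) == 2L)
      return(res("ES", "A"))
    if (!any(seg$inA) && nrow(exB) >= 1L &&
        setequal(sB, c(gapL, gapR, exB[, "start"], exB[, "end"])) &&
        length(sA) == 2L)
      return(res("ES", "B"))
    # MEE: each form contributes exactly one internal exon, non-overlapping
    if (nrow(exA) == 1L && nrow(exB) == 1L &&
        (exA[1, "end"] <= exB[1, "start"] || exB[1, "end"] <= exA[1, "start"]) &&
        sum(seg$inA) >= 1L && sum(seg$inB) >= 1L &&
        setequal(sA, c(gapL, gapR, exA[, "start"], exA[, "end"])) &&
        setequal(sB, c(gapL, gapR, exB[, "start"], exB[, "end"])))
      return(res("MEE", "A"))
  }

  # alternative donor/acceptor: single differing segment adjacent to a shared
  # exonic flank, with the partner splice site shared
  if (nrow(diffseg) == 1L) {
    shared <- intersect(sA, sB)
    nsA <- setdiff(sA, shared)
    nsB <- setdiff(sB, shared)
    if (length(shared) == 1L && length(nsA) == 1L && length(nsB) == 1L &&
        setequal(c(min(nsA, nsB), max(nsA, nsB)),
                 c(diffseg$start[1], diffseg$end[1]))) {
      shared_right <- shared > diffseg$end[1] - 1e-9
      type <- if (shared_right) {
        if (strand == "+") "A5SS" else "A3SS"
      } else {
        if (strand == "+") "A3SS" else "A5SS"
      }
      incl <- if (dstat[1] == "Aonly") "A" else "B"
      return(res(type, incl))
    }
  }

  res("complex", if (any(dstat == "Aonly")) "A" else "B")
}

#' Detect alternative-splicing events within genes
#'
#' For every unordered pair of transcripts of a gene, the structural
#' differences inside their shared span are decomposed into maximal variant
#' regions bounded by positions where both transcripts are exonic, and each
#' region is typed as exon skipping (ES), intron retention (IR), alternative
#' 3'/5' splice site (A3SS/A5SS, relative to the biological strand) or
#' mutually exclusive exons (MEE). Untypable regions are emitted with type
#' `complex`. Events identical in (type, anchors, region) are deduplicated
#' across pairs, so the event multiset does not depend on transcript input
#' order. Mono-exonic transcripts participate only as the retaining form of
#' IR events; alternative-terminus differences are not events.
#'
#' @param x annotation_set with gene_id assigned.
#' @param genes optional character vector restricting the genes scanned.
#' @return data.frame: gene_id, event_type, inclusion_id, exclusion_id,
#'   anchor_start, anchor_end, region_start, region_end.
#' @export
detect_as_events <- function(x, genes = NULL) {
  gm <- gene_map(x)
  if (!is.null(genes)) gm <- gm[intersect(names(gm), genes)]
  chains <- exon_chains(x)
  tx <- x$transcripts
  res <- list()
  for (g in names(gm)) {
    ids <- gm[[g]]
    if (length(ids) < 2L) next
    if (length(unique(tx$strand[match(ids, tx$transcript_id)])) != 1L)
      stop("gene ", g, ": transcripts on different strands")
    strand <- tx$strand[match(ids[1], tx$transcript_id)]
    nex <- tx$n_exons[match(ids, tx$transcript_id)]
    ev_g <- list()
    for (i in seq_along(ids)[-length(ids)]) {
      for (j in (i + 1):length(ids)) {
        if (nex[i] == 1L && nex[j] == 1L) next
        ev <- pair_variant_regions(chains[[ids[i]]], chains[[ids[j]]], strand)
        if (nrow(ev) == 0L) next
        # mono-exon transcripts: keep only IR with the mono form retaining
        if (nex[i] == 1L) ev <- ev[ev$event_type == "IR" & ev$inclusion == "A", , drop = FALSE]
        if (nex[j] == 1L) ev <- ev[ev$event_type == "IR" & ev$inclusion == "B", , drop = FALSE]
        if (nrow(ev) == 0L) next
        ev$inclusion_id <- ifelse(ev$inclusion == "A", ids[i], ids[j])
        ev$exclusion_id <- ifelse(ev$inclusion == "A", ids[j], ids[i])
        ev$inclusion <- NULL
        ev_g[[length(ev_g) + 1L]] <- ev
      }
    }
    if (length(ev_g) == 0L) next
    evs <- do.call(rbind, ev_g)
    key <- paste(evs$event_type, evs$anchor_start, evs$anchor_end,
                 evs$region_start, evs$region_end)
    evs <- evs[!duplicated(key), , drop = FALSE]
    evs$gene_id <- g
    res[[length(res) + 1L]] <- evs
  }
  if (length(res) == 0L) {
    out <- empty_events()
    out$inclusion <- NULL
    out$inclusion_id <- character(0)
    out$exclusion_id <- character(0)
    out$gene_id <- character(0)
  } else out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[, c("gene_id", "event_type", "inclusion_id", "exclusion_id",
          "anchor_start", "anchor_end", "region_start", "region_end")]
}

#' Per-gene AS profiles and genome-wide summary
#'
#' `complex` regions are reported in the input but excluded from the five-way
#' type proportions and from the per-gene pattern sets.
#'
#' @param events output of [detect_as_events()].
#' @return list with `profiles` (gene_id, n_events, n_patterns, patterns),
#'   `type_counts`, `type_proportions` (percent of typed events, NA when no
#'   events), `genes_ge2_events`, `genes_ge2_patterns`, `genes_all5`,
#'   `n_events`, `n_genes`.
#' @export
profile_as_genes <- function(events) {
  typed <- events[events$event_type %in% AS_TYPES, , drop = FALSE]
  type_counts <- table(factor(typed$event_type, levels = AS_TYPES))
  n_events <- nrow(typed)
  props <- if (n_events > 0) as.numeric(type_counts) / n_events * 100 else
    rep(NA_real_, length(AS_TYPES))
  names(props) <- AS_TYPES
  if (n_events == 0L) {
    profiles <- data.frame(gene_id = character(0), n_events = integer(0),
                           n_patterns = integer(0), patterns = character(0))
  } else {
    sp <- split(typed$event_type, typed$gene_id)
    profiles <- data.frame(
      gene_id = names(sp),
      n_events = vapply(sp, length, integer(1)),
      n_patterns = vapply(sp, function(v) length(unique(v)), integer(1)),
      patterns = vapply(sp, function(v) paste(sort(unique(v)), collapse = ","),
                        character(1)),
      stringsAsFactors = FALSE
    )
    rownames(profiles) <- NULL
  }
  list(
    profiles = profiles,
    type_counts = stats::setNames(as.integer(type_counts), AS_TYPES),
    type_proportions = props,
    n_events = n_events,
    n_genes = nrow(profiles),
    genes_ge2_events = sum(profiles$n_events >= 2),
    genes_ge2_patterns = sum(profiles$n_patterns >= 2),
    genes_all5 = sum(profiles$n_patterns == length(AS_TYPES)),
    n_complex = sum(events$event_type == "complex")
  )
}

#' Correlates of transcript diversity
#'
#' Pearson correlations between per-gene transcript number and (a) maximum
#' exon number over the gene's transcripts, over all genes and over highly
#' expressed genes, and (b) gene expression level.
#'
#' @param x observed annotation_set with gene assignments.
#' @param gene_fpkm named numeric vector of gene-level mean FPKM.
#' @param high_expr_threshold FPKM cutoff defining the highly expressed
#'   stratum (default 30).
#' @return data.frame with rows `tx_vs_exons`, `tx_vs_exons_high`,
#'   `tx_vs_expression`: columns r, p, n (r is NA for strata with fewer than
#'   3 genes or zero variance).
#' @export
correlate_diversity <- function(x, gene_fpkm, high_expr_threshold = 30) {
  tx <- x$transcripts
  keep <- !is.na(tx$gene_id)
  ntx <- tapply(tx$transcript_id[keep], tx$gene_id[keep], length)
  mexon <- tapply(tx$n_exons[keep], tx$gene_id[keep], max)
  genes <- names(ntx)
  fpkm <- gene_fpkm[genes]
  strat <- list(
    tx_vs_exons = cbind(as.numeric(ntx), as.numeric(mexon)),
    tx_vs_exons_high = cbind(as.numeric(ntx), as.numeric(mexon))[
      !is.na(fpkm) & fpkm > high_expr_threshold, , drop = FALSE],
    tx_vs_expression = cbind(as.numeric(ntx), as.numeric(fpkm))[
      !is.na(fpkm), , drop = FALSE]
  )
  rows <- lapply(names(strat), function(nm) {
    m <- strat[[nm]]
    if (nrow(m) < 3L || stats::sd(m[, 1]) == 0 || stats::sd(m[, 2]) == 0) {
      data.frame(stratum = nm, r = NA_real_, p = NA_real_, n = nrow(m))
    } else {
      ct <- stats::cor.test(m[, 1], m[, 2], method = "pearson")
      data.frame(stratum = nm, r = unname(ct$estimate), p = ct$p.value, n = nrow(m))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
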