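# Brute-force per-base oracle for AS-event detection. Works on integer base
# vectors over the pair's common span, independently of the package's
# interval/splice-site arithmetic.

# exon matrices -> per-base exonic indicator over [lo, hi)
base_cover <- function(em, lo, hi) {
  v <- rep(FALSE, hi - lo)
  for (i in seq_len(nrow(em))) {
    s <- max(em[i, 1], lo); e <- min(em[i, 2], hi)
    if (s < e) v[(s - lo + 1):(e - lo)] <- TRUE
  }
  v
}

# maximal runs of TRUE, as a matrix of [start, end) offsets relative to lo
true_runs <- function(v, lo) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- c(0, ends[-length(ends)])
  keep <- r$values
  cbind(start = lo + starts[keep], end = lo + ends[keep])
}

oracle_pair_events <- function(emA, emB, strand) {
  lo <- max(min(emA[, 1]), min(emB[, 1]))
  hi <- min(max(emA[, 2]), max(emB[, 2]))
  out <- data.frame(event_type = character(0), anchor_start = numeric(0),
                    anchor_end = numeric(0), region_start = numeric(0),
                    region_end = numeric(0))
  if (lo >= hi) return(out)
  inA <- base_cover(emA, lo, hi)
  inB <- base_cover(emB, lo, hi)
  both <- inA & inB
  diffb <- xor(inA, inB)
  # clusters: maximal runs of !both containing at least one differing base,
  # flanked by `both` bases on each side
  runs <- true_runs(!both, lo)
  for (k in seq_len(nrow(runs))) {
    a <- runs[k, 1]; b <- runs[k, 2]       # [a, b) cluster
    if (a == lo || b == hi) next           # terminal, not an event
    ii <- (a - lo + 1):(b - lo)
    if (!any(diffb[ii])) next
    dpos <- which(diffb[ii]) + a - 1       # absolute differing bases
    rs <- min(dpos); re <- max(dpos) + 1
    cA <- inA[ii]; cB <- inB[ii]
    # exonic runs of each form inside the cluster
    rA <- true_runs(cA, a); rB <- true_runs(cB, a)
    touch <- function(r) r[, 1] == a | r[, 2] == b
    type <- "complex"
    if (all(cB) && nrow(rA) == 0) type <- "IR"
    else if (all(cA) && nrow(rB) == 0) type <- "IR"
    else if (!any(cB) && nrow(rA) >= 1 && !any(touch(rA))) type <- "ES"
    else if (!any(cA) && nrow(rB) >= 1 && !any(touch(rB))) type <- "ES"
    else if (!any(cB) && nrow(rA) == 1 && sum(touch(rA)) == 1) {
      left <- rA[1, 1] == a
      type <- if (left == (strand == "+")) "A5SS" else "A3SS"
    } else if (!any(cA) && nrow(rB) == 1 && sum(touch(rB)) == 1) {
      left <- rB[1, 1] == a
      type <- if (left == (strand == "+")) "A5SS" else "A3SS"
    } else if (nrow(rA) == 1 && nrow(rB) == 1 && !any(touch(rA)) &&
               !any(touch(rB)) &&
               (rA[1, 2] <= rB[1, 1] || rB[1, 2] <= rA[1, 1]))
      type <- "MEE"
    out <- rbind(out, data.frame(event_type = type, anchor_start = a,
                                 anchor_end = b, region_start = rs,
                                 region_end = re))
  }
  out
}

# gene-level oracle: all pairs, dedup on (type, anchors, region); applies the
# same mono-exon rule as the detector (mono forms only retain introns)
oracle_gene_events <- function(ems, strand) {
  out <- list()
  n <- length(ems)
  for (i in seq_len(max(0, n - 1))) {
    for (j in (i + 1):n) {
      if (nrow(ems[[i]]) == 1 && nrow(ems[[j]]) == 1) next
      ev <- oracle_pair_events(ems[[i]], ems[[j]], strand)
      if (nrow(ev) == 0) next
      if (nrow(ems[[i]]) == 1 || nrow(ems[[j]]) == 1)
        ev <- ev[ev$event_type == "IR", , drop = FALSE]
      out[[length(out) + 1]] <- ev
    }
  }
  if (length(out) == 0) return(data.frame(event_type = character(0),
                                          anchor_start = numeric(0),
                                          anchor_end = numeric(0),
                                          region_start = numeric(0),
                                          region_end = numeric(0)))
  ev <- do.call(rbind, out)
  ev[!duplicated(paste(ev$event_type, ev$anchor_start, ev$anchor_end,
                       ev$region_start, ev$region_end)), , drop = FALSE]
}

# random toy gene generator: a skeleton of <=6 exons, transcripts derived by
# random exon drops, boundary shifts and merges; coordinates stay small so
# the per-base oracle is cheap
random_toy_gene <- function(n_tx = 3, max_exons = 5) {
  E <- sample(3:max_exons, 1)
  bounds <- sort(sample(20:400, 2 * E))
  skel <- cbind(bounds[seq(1, 2 * E, 2)], bounds[seq(2, 2 * E, 2)])
  # require gaps >= 2 between exons
  for (i in 2:E) if (skel[i, 1] - skel[i - 1, 2] < 2)
    return(random_toy_gene(n_tx, max_exons))
  make_variant <- function() {
    em <- skel
    if (E >= 3 && stats::runif(1) < 0.5) {      # drop an internal exon
      em <- em[-sample(2:(E - 1), 1), , drop = FALSE]
    }
    if (stats::runif(1) < 0.5 && nrow(em) >= 2) {  # shift one boundary
      i <- sample(nrow(em) - 1, 1)
      d <- sample(c(-8, 8), 1)
      newe <- em[i, 2] + d
      if (newe > em[i, 1] + 2 && newe < em[i + 1, 1] - 2) em[i, 2] <- newe
    }
    if (stats::runif(1) < 0.3 && nrow(em) >= 2) {  # retain an intron
      i <- sample(nrow(em) - 1, 1)
      em[i, 2] <- em[i + 1, 2]
      em <- em[-(i + 1), , drop = FALSE]
    }
    em
  }
  ems <- c(list(skel), replicate(n_tx - 1, make_variant(), simplify = FALSE))
  lapply(ems, function(m) cbind(start = m[, 1], end = m[, 2]))
}

# wrap a list of exon matrices into an annotation_set for one gene
toy_gene_ann <- function(ems, strand = "+", gene = "g1", chrom = "chr1") {
  rows <- do.call(rbind, lapply(seq_along(ems), function(i) {
    data.frame(transcript_id = paste0("t", i), chrom = chrom, strand = strand,
               start = ems[[i]][, 1], end = ems[[i]][, 2],
               stringsAsFactors = FALSE)
  }))
  meta <- data.frame(transcript_id = paste0("t", seq_along(ems)),
                     gene_id = gene, stringsAsFactors = FALSE)
  annotation_set(rows, meta = meta, source_tag = "observed")
}

event_key <- function(ev) {
  sort(paste(ev$event_type, ev$anchor_start, ev$anchor_end,
             ev$region_start, ev$region_end))
}
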