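#' Simulation configuration
#'
#' Collects every tunable of the synthetic-data generator. Defaults describe
#' a two-condition (d30/d90), three-replicate bulk design over multi-isoform
#' genes with tandem-UTR alternative polyadenylation, a long-read catalog
#' mixing all eight structural categories in proportions close to those seen
#' in real spleen Iso-seq catalogs, and negative-binomial expression with
#' planted major-transcript switching and differential expression.
#'
#' @param n_genes number of reference gene loci.
#' @param n_observed number of observed (long-read) transcript models.
#' @param isoform_weights sampling weights for 1..4 reference isoforms per
#'   gene.
#' @param exons_range range of exon counts for the gene backbone.
#' @param exon_len,intron_len ranges (bp).
#' @param category_mix named target proportions over the eight structural
#'   categories.
#' @param as_event_mix named sampling weights over ES/IR/A3SS/A5SS/MEE for
#'   planted reference isoform variants.
#' @param n_replicates replicates per condition (>= 3 for the CPM rule).
#' @param conditions two condition labels.
#' @param lib_size nominal library size (fragments) per sample.
#' @param gene_fpkm_meanlog,gene_fpkm_sdlog lognormal parameters of the
#'   relative gene expression level.
#' @param nb_dispersion negative-binomial dispersion (0 = deterministic
#'   rounded means, the noiseless limit).
#' @param fraction_amt_genes fraction of eligible multi-isoform genes with a
#'   planted major-transcript switch.
#' @param mt_fold fold-dominance planted for the designated major
#'   transcript over the runner-up in each condition.
#' @param fraction_de_genes,log2fc_effect fraction of genes with planted
#'   differential expression and the planted |log2 fold-change|.
#' @param pas_weights sampling weights for 1..4 polyadenylation sites per
#'   gene.
#' @param pas_spacing_range spacing between adjacent PASs (bp); kept well
#'   above the PAS cluster window so planted sites stay separable.
#' @param fraction_mpas_shift_genes fraction of APA genes whose major PAS
#'   switches between conditions.
#' @param distal_bias probability that the dominant PAS of a condition is
#'   the distal-most one (emulating distal preference).
#' @param pas_signal_rate probability an AATAAA signal is planted 20 nt
#'   upstream of each PAS.
#' @param tss_jitter,tes_jitter terminus jitter (nt) applied to observed
#'   transcript copies; TES jitter stays below half the PAS cluster window.
#' @param orf_aa length (aa) of the ORF planted in each gene's terminal
#'   exon, ending 250 nt upstream of the proximal PAS.
#' @param read_support_p geometric parameter of the shifted-geometric
#'   long-read support distribution.
#' @param rng_seed integer seed; every stage derives its own substream.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 100,
                       n_observed = 400,
                       isoform_weights = c(0.35, 0.30, 0.20, 0.15),
                       exons_range = c(5, 8),
                       exon_len = c(100, 300),
                       intron_len = c(250, 800),
                       category_mix = c(FSM = 0.1415, ISM = 0.2539, NIC = 0.2439,
                                        NNC = 0.3224, fusion = 0.0083, genic = 0.01,
                                        antisense = 0.01, intergenic = 0.01),
                       as_event_mix = c(ES = 0.40, IR = 0.30, A3SS = 0.15,
                                        A5SS = 0.10, MEE = 0.05),
                       n_replicates = 3,
                       conditions = c("d30", "d90"),
                       lib_size = 2e6,
                       gene_fpkm_meanlog = log(30),
                       gene_fpkm_sdlog = 0.6,
                       nb_dispersion = 0.05,
                       fraction_amt_genes = 0.2,
                       mt_fold = 2,
                       fraction_de_genes = 0.2,
                       log2fc_effect = 2,
                       pas_weights = c(0.40, 0.30, 0.20, 0.10),
                       pas_spacing_range = c(120, 400),
                       fraction_mpas_shift_genes = 0.3,
                       distal_bias = 0.7,
                       pas_signal_rate = 0.8,
                       tss_jitter = 30,
                       tes_jitter = 10,
                       orf_aa = 199,
                       read_support_p = 0.35,
                       rng_seed = 1L) {
  category_mix <- category_mix / sum(category_mix)
  as_event_mix <- as_event_mix / sum(as_event_mix)
  stopifnot(all(category_mix >= 0), all(as_event_mix >= 0),
            n_replicates >= 1, length(conditions) == 2,
            fraction_amt_genes >= 0, fraction_amt_genes <= 1,
            fraction_de_genes >= 0, fraction_de_genes <= 1,
            fraction_mpas_shift_genes >= 0, fraction_mpas_shift_genes <= 1,
            pas_signal_rate >= 0, pas_signal_rate <= 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

runif_int <- function(n, lo, hi) lo + floor(stats::runif(n) * (hi - lo + 1))

STOPFREE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

random_stopfree_orf <- function(n_aa) {
  paste0("ATG", paste(sample(setdiff(STOPFREE_CODONS, "ATG"), n_aa - 1,
                             replace = TRUE), collapse = ""), "TAA")
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Build one gene in transcription space: backbone exons, PAS layout, planted
# ORF, and AS-variant isoforms. All coordinates are 0-based offsets from the
# gene's transcription start.
build_gene_structure <- function(cfg) {
  E <- runif_int(1, cfg$exons_range[1], cfg$exons_range[2])
  ex_len <- runif_int(E - 1, cfg$exon_len[1], cfg$exon_len[2])
  in_len <- runif_int(E - 1, cfg$intron_len[1], cfg$intron_len[2])
  k <- sample(seq_along(cfg$pas_weights), 1, prob = cfg$pas_weights)
  spacing <- if (k > 1) runif_int(k - 1, cfg$pas_spacing_range[1],
                                  cfg$pas_spacing_range[2]) else integer(0)
  orf_nt <- 3 * (cfg$orf_aa + 1)

  layout_pas <- function(spacing) {
    pas1 <- 50 + orf_nt + 250
    pas <- pas1 + c(0, cumsum(spacing))
    mid <- (pas[1] + pas[length(pas)]) / 2
    list(pas = pas, mid = mid)
  }
  for (try in 1:12) {
    lp <- layout_pas(spacing)
    bad <- which(abs(lp$pas - lp$mid) < 30)
    if (length(bad) == 0L || k <= 2) break
    spacing[min(bad[1], length(spacing))] <- spacing[min(bad[1], length(spacing))] + 80
  }
  pas_off <- lp$pas  # offsets within the terminal exon

  starts <- numeric(E); ends <- numeric(E)
  cur <- 0
  for (i in seq_len(E - 1)) {
    starts[i] <- cur; ends[i] <- cur + ex_len[i]; cur <- ends[i] + in_len[i]
  }
  starts[E] <- cur
  ends[E] <- cur + pas_off[k]           # backbone ends at the distal PAS
  glen <- ends[E] + 60
  pas_t <- starts[E] + pas_off          # transcription-space PAS positions
  orf_t <- c(starts[E] + 50, starts[E] + 50 + orf_nt)

  backbone <- cbind(start = starts, end = ends)
  isos <- list(backbone)
  n_iso <- sample(seq_along(cfg$isoform_weights), 1, prob = cfg$isoform_weights)
  events <- list()
  used_ex <- integer(0); used_in <- integer(0)
  internal <- if (E >= 3) 2:(E - 1) else integer(0)
  for (v in seq_len(n_iso - 1)) {
    placed <- FALSE
    for (attempt in 1:8) {
      type <- sample(names(cfg$as_event_mix), 1, prob = cfg$as_event_mix)
      em <- backbone
      if (type == "ES") {
        cand <- setdiff(internal, used_ex)
        cand <- cand[!(cand - 1) %in% used_in & !cand %in% used_in]
        if (length(cand) == 0L) next
        i <- if (length(cand) == 1L) cand else sample(cand, 1)
        em <- em[-i, , drop = FALSE]
        used_ex <- c(used_ex, i); used_in <- c(used_in, i - 1, i)
      } else if (type == "IR") {
        cand <- setdiff(seq_len(E - 1), used_in)
        if (length(cand) == 0L) next
        j <- if (length(cand) == 1L) cand else sample(cand, 1)
        em[j, "end"] <- em[j + 1, "end"]
        em <- em[-(j + 1), , drop = FALSE]
        used_in <- c(used_in, j); used_ex <- c(used_ex, j, j + 1)
      } else if (type %in% c("A5SS", "A3SS")) {
        cand <- setdiff(seq_len(E - 1), used_in)
        if (length(cand) == 0L) next
        j <- if (length(cand) == 1L) cand else sample(cand, 1)
        delta <- sample(20:50, 1) * sample(c(-1, 1), 1)
        if (type == "A5SS") {   # move the donor = transcription end of exon j
          newe <- em[j, "end"] + delta
          if (newe < em[j, "start"] + 40 || newe > em[j + 1, "start"] - 40) next
          em[j, "end"] <- newe
        } else {                # move the acceptor = start of exon j+1
          news <- em[j + 1, "start"] + delta
          if (news < em[j, "end"] + 40 || news > em[j + 1, "end"] - 40) next
          em[j + 1, "start"] <- news
        }
        used_in <- c(used_in, j)
      } else {                  # MEE: swap internal exon for one in next intron
        cand <- setdiff(internal, used_ex)
        cand <- cand[!(cand - 1) %in% used_in & !cand %in% used_in]
        cand <- cand[cand < E & (backbone[pmin(cand + 1, E), "start"] -
                                   backbone[cand, "end"]) >= 220]
        if (length(cand) == 0L) next
        i <- if (length(cand) == 1L) cand else sample(cand, 1)
        alt <- c(backbone[i, "end"] + 60, backbone[i, "end"] + 160)
        em[i, ] <- alt
        used_ex <- c(used_ex, i); used_in <- c(used_in, i - 1, i)
      }
      # reject duplicates of existing isoform chains
      dup <- any(vapply(isos, function(x) nrow(x) == nrow(em) && all(x == em),
                        logical(1)))
      if (dup) next
      isos[[length(isos) + 1L]] <- em
      events[[length(events) + 1L]] <- type
      placed <- TRUE
      break
    }
    if (!placed) break
  }
  list(isoforms = isos, events = unlist(events), pas_t = pas_t, orf_t = orf_t,
       glen = glen, E = E)
}

# map transcription-space interval matrix to genomic coordinates
t2g <- function(em, locus_start, glen, strand) {
  if (strand == "+") {
    cbind(start = locus_start + em[, "start"], end = locus_start + em[, "end"])
  } else {
    m <- cbind(start = locus_start + glen - em[, "end"],
               end = locus_start + glen - em[, "start"])
    m[order(m[, "start"]), , drop = FALSE]
  }
}

t2g_pos <- function(p, locus_start, glen, strand) {
  if (strand == "+") locus_start + p else locus_start + glen - p
}

#' Simulate a reference annotation and genome
#'
#' Gene loci are laid out without overlap on two synthetic chromosomes, on
#' both strands, each with a multi-exon backbone isoform, optional
#' AS-variant isoforms sharing its termini, 1-4 tandem polyadenylation sites
#' in a long terminal exon, a planted ORF ending 250 nt upstream of the
#' proximal PAS, and AATAAA signals planted 20 nt upstream of each PAS at
#' `pas_signal_rate`. The genome is random sequence elsewhere.
#'
#' @param cfg sim_config
#' @param seed overrides `cfg$rng_seed`.
#' @return list: `annotation` (annotation_set, source reference), `genome`
#'   (DNAStringSet), `genes` (locus table), `pas_table`
#'   (gene/pas_index/position/signal), `as_truth` (planted events),
#'   `gaps` (intergenic gap table used by the catalog simulator).
#' @export
simulate_reference <- function(cfg, seed = cfg$rng_seed) {
  set.seed(seed)
  n_chrom <- 2L
  chroms <- paste0("chrS", seq_len(n_chrom))
  cursor <- stats::setNames(rep(1000, n_chrom), chroms)
  exon_rows <- list(); meta_rows <- list(); gene_rows <- list()
  pas_rows <- list(); as_rows <- list(); plant <- list(); gaps <- list()

  for (gi in seq_len(cfg$n_genes)) {
    g <- sprintf("G%04d", gi)
    chrom <- chroms[(gi - 1L) %% n_chrom + 1L]
    strand <- sample(c("+", "-"), 1)
    gs <- build_gene_structure(cfg)
    locus <- cursor[[chrom]]
    for (v in seq_along(gs$isoforms)) {
      tid <- sprintf("%s.t%d", g, v)
      em <- t2g(gs$isoforms[[v]], locus, gs$glen, strand)
      exon_rows[[length(exon_rows) + 1L]] <- data.frame(
        transcript_id = tid, chrom = chrom, strand = strand,
        start = em[, "start"], end = em[, "end"], stringsAsFactors = FALSE)
      meta_rows[[length(meta_rows) + 1L]] <- data.frame(
        transcript_id = tid, gene_id = g, stringsAsFactors = FALSE)
    }
    pas_g <- vapply(gs$pas_t, t2g_pos, numeric(1), locus_start = locus,
                    glen = gs$glen, strand = strand)
    sig <- stats::runif(length(pas_g)) < cfg$pas_signal_rate
    pas_rows[[length(pas_rows) + 1L]] <- data.frame(
      gene_id = g, pas_index = seq_along(pas_g), position = pas_g,
      chrom = chrom, strand = strand, signal = sig, stringsAsFactors = FALSE)
    if (length(gs$events) > 0)
      as_rows[[length(as_rows) + 1L]] <- data.frame(
        gene_id = g, event_type = gs$events, stringsAsFactors = FALSE)
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene_id = g, chrom = chrom, strand = strand, start = locus,
      end = locus + gs$glen, n_pas = length(pas_g), n_exons = gs$E,
      stringsAsFactors = FALSE)

    # sequence plants, in transcription space
    orf_seq <- random_stopfree_orf(cfg$orf_aa)
    plant[[length(plant) + 1L]] <- list(
      chrom = chrom, strand = strand, locus = locus, glen = gs$glen,
      t_start = gs$orf_t[1], seq = orf_seq)
    for (j in which(sig)) {
      plant[[length(plant) + 1L]] <- list(
        chrom = chrom, strand = strand, locus = locus, glen = gs$glen,
        t_start = gs$pas_t[j] - 26, seq = "AATAAA")
    }

    gap <- runif_int(1, 2000, 5000)
    gaps[[length(gaps) + 1L]] <- data.frame(
      chrom = chrom, start = locus + gs$glen + 200,
      end = locus + gs$glen + gap - 200, stringsAsFactors = FALSE)
    cursor[[chrom]] <- locus + gs$glen + gap
  }

  # assemble genome with planted segments
  genome <- lapply(chroms, function(ch) {
    len <- cursor[[ch]] + 1000
    sample(c("A", "C", "G", "T"), len, replace = TRUE,
           prob = c(0.3, 0.2, 0.2, 0.3))
  })
  names(genome) <- chroms
  for (p in plant) {
    if (p$strand == "+") {
      g0 <- p$locus + p$t_start
      seqc <- strsplit(p$seq, "")[[1]]
    } else {
      g0 <- p$locus + p$glen - (p$t_start + nchar(p$seq))
      seqc <- strsplit(revcomp_chr(p$seq), "")[[1]]
    }
    genome[[p$chrom]][(g0 + 1):(g0 + length(seqc))] <- seqc
  }
  genome <- Biostrings::DNAStringSet(vapply(genome, paste, character(1), collapse = ""))
  names(genome) <- chroms

  ann <- annotation_set(do.call(rbind, exon_rows),
                        meta = do.call(rbind, meta_rows),
                        source_tag = "reference")
  list(annotation = ann, genome = genome,
       genes = do.call(rbind, gene_rows),
       pas_table = do.call(rbind, pas_rows),
       as_truth = if (length(as_rows)) do.call(rbind, as_rows) else
         data.frame(gene_id = character(0), event_type = character(0)),
       gaps = do.call(rbind, gaps))
}

#' Simulate an observed long-read transcript catalog with planted categories
#'
#' Observed transcripts are constructed by per-category recipes against the
#' reference: FSM copies an isoform's intron chain with terminus jitter; ISM
#' drops leading (5') exons; NIC skips an exon whose skip junction is absent
#' from the catalog (known sites, new combination); NNC shifts one splice
#' site to a novel position; fusion concatenates the chains of two adjacent
#' same-strand genes; genic is a mono-exon inside a gene span; antisense
#' lies opposite a gene; intergenic sits in a gap between loci. Transcripts
#' that retain the terminal exon are assigned a PAS (cycling through the
#' gene's sites) and end there, up to `tes_jitter`.
#'
#' @param cfg sim_config
#' @param ref output of [simulate_reference()].
#' @param seed overrides the config seed.
#' @param tss_jitter,tes_jitter override the config jitters (set 0 for the
#'   noiseless limit).
#' @return list: `annotation` (observed annotation_set), `truth`
#'   (transcript_id, category, gene_id, pas_index, read_support).
#' @export
simulate_observed_catalog <- function(cfg, ref, seed = cfg$rng_seed + 1L,
                                      tss_jitter = cfg$tss_jitter,
                                      tes_jitter = cfg$tes_jitter) {
  set.seed(seed)
  genes <- ref$genes
  chains <- exon_chains(ref$annotation)
  rtx <- ref$annotation$transcripts
  gm <- gene_map(ref$annotation)
  pas <- ref$pas_table
  cats <- names(cfg$category_mix)
  draw <- sample(cats, cfg$n_observed, replace = TRUE, prob = cfg$category_mix)
  pas_cycle <- stats::setNames(rep(0L, nrow(genes)), genes$gene_id)

  # same-strand adjacent gene pairs (for fusion)
  pairs <- list()
  for (ch in unique(genes$chrom)) {
    gg <- genes[genes$chrom == ch, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) < 2) next
    for (i in seq_len(nrow(gg) - 1)) {
      if (gg$strand[i] == gg$strand[i + 1])
        pairs[[length(pairs) + 1L]] <- c(gg$gene_id[i], gg$gene_id[i + 1])
    }
  }
  gaps <- ref$gaps[ref$gaps$end - ref$gaps$start > 600, ]

  exon_rows <- list(); truth_rows <- list()
  add_tx <- function(tid, em, chrom, strand, category, gene, pas_index, env) {
    # full-length models carrying PAS evidence get support >= 2 so every
    # planted site clears the default cluster support threshold
    sup <- (if (is.na(pas_index)) 1L else 2L) + stats::rgeom(1, cfg$read_support_p)
    env$exon_rows[[length(env$exon_rows) + 1L]] <- data.frame(
      transcript_id = tid, chrom = chrom, strand = strand,
      start = em[, "start"], end = em[, "end"], stringsAsFactors = FALSE)
    env$truth_rows[[length(env$truth_rows) + 1L]] <- data.frame(
      transcript_id = tid, category = category, gene_id = gene,
      pas_index = pas_index, read_support = sup, stringsAsFactors = FALSE)
  }
  env <- environment()

  # pick the gene's next PAS (cycled) and truncate/extend the 3' terminal
  # exon of `em` to end at it (with jitter)
  apply_pas <- function(em, g, strand) {
    pg <- pas[pas$gene_id == g, ]
    k <- nrow(pg)
    pas_cycle[[g]] <<- pas_cycle[[g]] %% k + 1L
    j <- pas_cycle[[g]]
    jit <- if (tes_jitter > 0) runif_int(1, -tes_jitter, tes_jitter) else 0
    p <- pg$position[pg$pas_index == j] + jit
    n <- nrow(em)
    if (strand == "+") em[n, "end"] <- max(p, em[n, "start"] + 20)
    else em[1, "start"] <- min(p, em[1, "end"] - 20)
    list(em = em, j = j)
  }
  jitter_tss <- function(em, strand) {
    if (tss_jitter == 0) return(em)
    jit <- runif_int(1, -tss_jitter, tss_jitter)
    n <- nrow(em)
    if (strand == "+") em[1, "start"] <- max(1, min(em[1, "start"] + jit, em[1, "end"] - 20))
    else em[n, "end"] <- max(em[n, "end"] + jit, em[n, "start"] + 20)
    em
  }

  multi_iso_genes <- genes$gene_id[genes$gene_id %in% names(gm)]
  for (t in seq_len(cfg$n_observed)) {
    tid <- sprintf("OBS%05d", t)
    cat_t <- draw[t]
    done <- FALSE
    for (attempt in 1:30) {
      g <- sample(genes$gene_id, 1)
      grow <- genes[genes$gene_id == g, ]
      strand <- grow$strand; chrom <- grow$chrom
      ids <- gm[[g]]
      bb <- chains[[ids[1]]]           # backbone isoform
      if (cat_t == "FSM") {
        src <- chains[[sample(ids, 1)]]
        em <- jitter_tss(src, strand)
        ap <- apply_pas(em, g, strand)
        add_tx(tid, ap$em, chrom, strand, "FSM", g, ap$j, env)
      } else if (cat_t == "ISM") {
        if (nrow(bb) < 3) next
        d <- runif_int(1, 1, nrow(bb) - 2)
        em <- if (strand == "+") bb[-(1:d), , drop = FALSE] else
          bb[seq_len(nrow(bb) - d), , drop = FALSE]
        ic <- chain_introns(em)
        clash <- any(vapply(ids, function(x) chains_equal(ic, chain_introns(chains[[x]])),
                            logical(1)))
        if (clash) next
        ap <- apply_pas(em, g, strand)
        add_tx(tid, ap$em, chrom, strand, "ISM", g, ap$j, env)
      } else if (cat_t == "NIC") {
        if (nrow(bb) < 4) next
        # skip an internal exon whose skip-junction is not in the catalog
        gene_j <- unique(unlist(lapply(ids, function(x) {
          ic <- chain_introns(chains[[x]])
          if (nrow(ic)) paste(ic[, 1], ic[, 2], sep = "-") else character(0)
        })))
        ok <- FALSE
        # internal exon index in transcription order is irrelevant: genomic
        internals <- 2:(nrow(bb) - 1)
        for (i in sample(internals)) {
          em <- bb[-i, , drop = FALSE]
          ic <- chain_introns(em)
          newj <- paste(bb[i - 1, "end"], bb[i + 1, "start"], sep = "-")
          if (newj %in% gene_j) next
          clash <- any(vapply(ids, function(x) {
            ric <- chain_introns(chains[[x]])
            chains_equal(ic, ric) || is_subchain(ic, ric)
          }, logical(1)))
          if (clash) next
          ok <- TRUE; break
        }
        if (!ok) next
        ap <- apply_pas(em, g, strand)
        add_tx(tid, ap$em, chrom, strand, "NIC", g, ap$j, env)
      } else if (cat_t == "NNC") {
        if (nrow(bb) < 3) next
        gene_sites <- sort(unique(unlist(lapply(ids, function(x)
          chain_sites(chains[[x]])))))
        ok <- FALSE
        for (i in sample(seq_len(nrow(bb) - 1))) {
          em <- bb
          newe <- em[i, "end"] + 13
          if (newe > em[i + 1, "start"] - 40) newe <- em[i, "end"] - 13
          if (newe < em[i, "start"] + 20) next
          if (newe %in% gene_sites) next
          em[i, "end"] <- newe
          ok <- TRUE; break
        }
        if (!ok) next
        ap <- apply_pas(em, g, strand)
        add_tx(tid, ap$em, chrom, strand, "NNC", g, ap$j, env)
      } else if (cat_t == "fusion") {
        if (length(pairs) == 0L) next
        pr <- pairs[[sample(length(pairs), 1)]]
        emA <- chains[[gm[[pr[1]]][1]]]
        emB <- chains[[gm[[pr[2]]][1]]]
        st <- genes$strand[genes$gene_id == pr[1]]
        ch <- genes$chrom[genes$gene_id == pr[1]]
        em <- rbind(emA, emB)
        add_tx(tid, em, ch, st, "fusion", NA_character_, NA_integer_, env)
      } else if (cat_t == "genic") {
        if (nrow(bb) < 2) next
        s0 <- bb[1, "end"] + 20
        em <- cbind(start = s0, end = s0 + 150)
        if (em[1, "end"] >= bb[2, "start"] + 120) next
        add_tx(tid, em, chrom, strand, "genic", g, NA_integer_, env)
      } else if (cat_t == "antisense") {
        opp <- if (strand == "+") "-" else "+"
        mid <- floor((grow$start + grow$end) / 2)
        em <- cbind(start = c(mid, mid + 500), end = c(mid + 200, mid + 800))
        if (em[2, "end"] >= grow$end) em <- em[1, , drop = FALSE]
        add_tx(tid, em, chrom, opp, "antisense", NA_character_, NA_integer_, env)
      } else { # intergenic
        gp <- gaps[sample(nrow(gaps), 1), ]
        mid <- floor((gp$start + gp$end) / 2)
        em <- cbind(start = mid, end = mid + 300)
        st <- sample(c("+", "-"), 1)
        add_tx(tid, em, gp$chrom, st, "intergenic", NA_character_, NA_integer_, env)
      }
      done <- TRUE
      break
    }
    if (!done) stop("could not place a transcript of category ", cat_t,
                    " -- category mix unsatisfiable for this reference")
  }
  truth <- do.call(rbind, truth_rows)
  ann <- annotation_set(do.call(rbind, exon_rows),
                        meta = data.frame(transcript_id = truth$transcript_id,
                                          gene_id = truth$gene_id,
                                          read_support = truth$read_support,
                                          stringsAsFactors = FALSE),
                        source_tag = "observed")
  list(annotation = ann, truth = truth)
}

#' Simulate two-condition expression with planted MT, DE and APA structure
#'
#' Per-transcript expected FPKM values are constructed per condition:
#' gene-level levels are lognormal, scaled by `2^log2fc` in the second
#' condition for planted DE genes; within APA genes, per-condition PAS usage
#' weights make one site dominant (the distal-most with probability
#' `distal_bias`), switching dominant site between conditions for planted
#' mPAS-shift genes; the designated major transcript of each condition is
#' then forced to dominate by `mt_fold`-fold (switching
#' identity for planted AMT genes). Counts are drawn per replicate from a
#' negative binomial with these means (deterministically rounded when the
#' dispersion is 0), so every planted label is recoverable in the noiseless
#' limit. Ground-truth labels are derived from the final expected values —
#' the same quantities the analysis estimates — and therefore stay
#' consistent with the planted structure.
#'
#' @param cfg sim_config
#' @param obs output of [simulate_observed_catalog()].
#' @param ref output of [simulate_reference()].
#' @param seed overrides the config seed.
#' @return list: `counts` (expression_matrix, transcript level, with
#'   lengths), `truth_gene`, `truth_apa` (per-gene per-PAS expected usage),
#'   `mu_fpkm` (transcripts x conditions expected FPKM).
#' @export
simulate_expression <- function(cfg, obs, ref, seed = cfg$rng_seed + 2L) {
  set.seed(seed)
  truth <- obs$truth
  tx_len <- transcript_lengths(obs$annotation)
  ids <- obs$annotation$transcripts$transcript_id
  mu <- matrix(0, length(ids), 2, dimnames = list(ids, cfg$conditions))

  # background (unassigned) transcripts: low flat expression
  bg <- is.na(truth$gene_id)
  mu[truth$transcript_id[bg], ] <- stats::rlnorm(sum(bg), log(2), 0.5)

  g_ids <- unique(truth$gene_id[!bg])
  de_flag <- stats::setNames(stats::runif(length(g_ids)) < cfg$fraction_de_genes, g_ids)
  de_sign <- stats::setNames(sample(c(-1, 1), length(g_ids), replace = TRUE), g_ids)
  pas <- ref$pas_table

  amt_planted <- character(0); shift_planted <- character(0)
  truth_apa_rows <- list()

  for (g in g_ids) {
    tr <- truth[!bg & truth$gene_id == g, ]
    n_t <- nrow(tr)
    base <- stats::rlnorm(1, cfg$gene_fpkm_meanlog, cfg$gene_fpkm_sdlog)
    gene_level <- c(base, base)  # DE factor applied after MT enforcement

    # PAS usage weights per condition
    pg <- pas[pas$gene_id == g, ]
    supp <- sort(unique(tr$pas_index[!is.na(tr$pas_index)]))
    w <- matrix(1, length(supp), 2, dimnames = list(as.character(supp), NULL))
    is_shift <- FALSE
    if (length(supp) >= 2) {
      is_shift <- stats::runif(1) < cfg$fraction_mpas_shift_genes
      dom1 <- if (stats::runif(1) < cfg$distal_bias) supp[length(supp)] else
        supp[sample(length(supp), 1)]
      dom2 <- if (is_shift) {
        others <- setdiff(supp, dom1)
        others[sample(length(others), 1)]
      } else dom1
      for (ci in 1:2) {
        dom <- c(dom1, dom2)[ci]
        w[, ci] <- 0.4 / (length(supp) - 1)
        w[as.character(dom), ci] <- 0.6
      }
      if (is_shift) shift_planted <- c(shift_planted, g)
    }

    # within-PAS-group isoform weights (shared across conditions)
    v <- stats::rgamma(n_t, 2, 1)
    pidx <- tr$pas_index
    for (ci in 1:2) {
      u <- rep(1, n_t)
      if (length(supp) >= 1) {
        for (j in supp) {
          sel <- which(!is.na(pidx) & pidx == j)
          u[sel] <- w[as.character(j), ci] / sum(v[sel])
        }
      }
      mu[tr$transcript_id, ci] <- gene_level[ci] * u * v
    }

    # designate and enforce the major transcript per condition. For APA
    # genes the MT lives inside the condition's dominant PAS group, and
    # group sums are re-normalised to the planted usage weights afterwards
    # so the M/m balance keeps a clear margin.
    if (n_t >= 2) {
      is_amt <- !is_shift && stats::runif(1) < cfg$fraction_amt_genes
      if (length(supp) >= 2) {
        grp <- function(j) tr$transcript_id[!is.na(pidx) & pidx == j]
        top_in <- function(ids, ci) ids[which.max(mu[ids, ci])]
        m1 <- top_in(grp(dom1), 1)
        m2 <- if (is_shift) top_in(grp(dom2), 2)
        else if (is_amt && length(grp(dom1)) >= 2)
          setdiff(grp(dom1), m1)[which.max(mu[setdiff(grp(dom1), m1), 2])]
        else m1
        for (ci in 1:2) {
          mt <- c(m1, m2)[ci]
          rest <- setdiff(tr$transcript_id, mt)
          mu[mt, ci] <- max(mu[rest, ci]) * cfg$mt_fold
          for (j in supp) {
            sel <- grp(j)
            mu[sel, ci] <- mu[sel, ci] *
              (gene_level[ci] * w[as.character(j), ci] / sum(mu[sel, ci]))
          }
        }
      } else {
        m1 <- tr$transcript_id[which.max(mu[tr$transcript_id, 1])]
        m2 <- if (is_amt) {
          others <- setdiff(tr$transcript_id, m1)
          others[which.max(mu[others, 2])]
        } else m1
        for (ci in 1:2) {
          mt <- c(m1, m2)[ci]
          rest <- setdiff(tr$transcript_id, mt)
          # fold-dominance keeps gene-level fold changes intact after the
          # DE scaling below
          mu[mt, ci] <- max(mu[rest, ci]) * cfg$mt_fold
        }
      }
      if (is_amt) amt_planted <- c(amt_planted, g)
    }
    if (de_flag[[g]])
      mu[tr$transcript_id, 2] <- mu[tr$transcript_id, 2] *
        2^(de_sign[[g]] * cfg$log2fc_effect)
  }

  # pin the FPKM scale: sum(mu * len) per condition ~ 1e9 so that FPKM
  # recomputed from counts matches the planted values
  f <- 1e9 / sum(mu[, 1] * tx_len[ids])
  mu <- mu * f

  # expected counts and sampling
  cm <- mu * tx_len[ids] * cfg$lib_size / 1e9
  samples <- paste0(rep(cfg$conditions, each = cfg$n_replicates), "_r",
                    rep(seq_len(cfg$n_replicates), 2))
  design <- stats::setNames(rep(cfg$conditions, each = cfg$n_replicates), samples)
  counts <- matrix(0, length(ids), length(samples),
                   dimnames = list(ids, samples))
  for (s in seq_along(samples)) {
    muc <- cm[, design[[samples[s]]]]
    counts[, s] <- if (cfg$nb_dispersion <= 0) round(muc) else
      stats::rnbinom(length(muc), mu = muc, size = 1 / cfg$nb_dispersion)
  }

  # ---- truth derivation from the final expected FPKM -----------------
  gene_rows <- list()
  for (g in g_ids) {
    tr <- truth[!bg & truth$gene_id == g, ]
    e1 <- stats::setNames(mu[tr$transcript_id, 1], tr$transcript_id)
    e2 <- stats::setNames(mu[tr$transcript_id, 2], tr$transcript_id)
    c1 <- call_major_transcript(e1, margin = 10, margin_mode = "absolute")
    c2 <- call_major_transcript(e2, margin = 10, margin_mode = "absolute")
    amt <- !is.na(c1$mt_id) && !is.na(c2$mt_id) && c1$mt_id != c2$mt_id

    pg <- pas[pas$gene_id == g, ]
    supp <- sort(unique(tr$pas_index[!is.na(tr$pas_index)]))
    apa_gene <- length(supp) >= 2
    mpas1 <- mpas2 <- NA_integer_; shift <- NA
    mp1 <- mp2 <- NA_character_
    if (apa_gene) {
      us <- sapply(1:2, function(ci) {
        vapply(supp, function(j) sum(mu[tr$transcript_id[!is.na(tr$pas_index) &
                                                           tr$pas_index == j], ci]),
               numeric(1))
      })
      # tie-break downstream-most = larger pas_index (sites are numbered
      # proximal to distal)
      mpas1 <- supp[max(which(us[, 1] == max(us[, 1])))]
      mpas2 <- supp[max(which(us[, 2] == max(us[, 2])))]
      shift <- mpas1 != mpas2
      pos <- pg$position[match(supp, pg$pas_index)]
      strand <- pg$strand[1]
      first <- if (strand == "+") min(pos) else max(pos)
      last <- if (strand == "+") max(pos) else min(pos)
      midp <- (first + last) / 2
      down <- is_downstream(pos, midp, strand)
      up <- is_downstream(midp, pos, strand)
      mp1 <- if (sum(us[down, 1]) > sum(us[up, 1])) "M" else
        if (sum(us[down, 1]) < sum(us[up, 1])) "P" else "tie"
      mp2 <- if (sum(us[down, 2]) > sum(us[up, 2])) "M" else
        if (sum(us[down, 2]) < sum(us[up, 2])) "P" else "tie"
      for (jj in seq_along(supp)) {
        truth_apa_rows[[length(truth_apa_rows) + 1L]] <- data.frame(
          gene_id = g, pas_index = supp[jj], position = pos[jj],
          usage_1 = us[jj, 1], usage_2 = us[jj, 2], stringsAsFactors = FALSE)
      }
    }
    gene_rows[[length(gene_rows) + 1L]] <- data.frame(
      gene_id = g,
      mt_1 = c1$mt_id, mt_2 = c2$mt_id, amt = amt,
      de = de_flag[[g]],
      true_log2fc = log2(sum(e2) / sum(e1)),
      apa_gene = apa_gene, n_pas_supported = length(supp),
      mpas_1 = mpas1, mpas_2 = mpas2, mpas_shift = shift,
      mp_status_1 = mp1, mp_status_2 = mp2,
      stringsAsFactors = FALSE)
  }
  truth_gene <- do.call(rbind, gene_rows)
  em <- expression_matrix(counts, design, unit = "counts",
                          feature_lengths = tx_len[ids])
  list(counts = em, truth_gene = truth_gene,
       truth_apa = if (length(truth_apa_rows)) do.call(rbind, truth_apa_rows) else NULL,
       mu_fpkm = mu)
}

#' Simulate the full synthetic bundle
#'
#' Convenience wrapper running [simulate_reference()],
#' [simulate_observed_catalog()] and [simulate_expression()] under one seed.
#'
#' @param cfg sim_config
#' @param seed overrides `cfg$rng_seed`.
#' @return list: `reference`, `observed`, `expression` (the three stage
#'   outputs), and `cfg`.
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = cfg$rng_seed) {
  cfg$rng_seed <- seed
  ref <- simulate_reference(cfg, seed = seed)
  obs <- simulate_observed_catalog(cfg, ref, seed = seed + 1L)
  expr <- simulate_expression(cfg, obs, ref, seed = seed + 2L)
  list(reference = ref, observed = obs, expression = expr, cfg = cfg)
}

#' Null negative-binomial count matrix
#'
#' Two-group count matrix with identical group means, used for type-I-error
#' calibration of the Wald test.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_per_group replicates per group.
#' @param mean_range gene mean counts drawn log-uniformly in this range.
#' @param dispersion NB dispersion.
#' @param seed RNG seed.
#' @return expression_matrix of counts (conditions `g1`/`g2`).
#' @export
simulate_null_counts <- function(n_genes = 2000, n_per_group = 3,
                                 mean_range = c(20, 2000), dispersion = 0.1,
                                 seed = 1L) {
  set.seed(seed)
  mu <- exp(stats::runif(n_genes, log(mean_range[1]), log(mean_range[2])))
  n <- 2 * n_per_group
  counts <- matrix(stats::rnbinom(n_genes * n, mu = rep(mu, n),
                                  size = 1 / dispersion),
                   nrow = n_genes, ncol = n,
                   dimnames = list(sprintf("g%05d", seq_len(n_genes)),
                                   paste0("s", seq_len(n))))
  design <- stats::setNames(rep(c("g1", "g2"), each = n_per_group),
                            colnames(counts))
  expression_matrix(counts, design, unit = "counts")
}
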