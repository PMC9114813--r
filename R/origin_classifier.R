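# Origin-mechanism classification for orphan genes: five duplication modes
# (via within-genome paralog pairs and collinearity chaining), gene overlap,
# TE exaptation and de novo birth, with Nei-Gojobori (NG86) Ks dating under
# a strict molecular clock.

# ---- NG86 -------------------------------------------------------------------

syn_fraction_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    nts <- c("A", "C", "G", "T")
    res <- matrix(0, length(NONSTOP_CODONS), 3L,
                  dimnames = list(NONSTOP_CODONS, NULL))
    for (cod in NONSTOP_CODONS) {
      aa <- GENETIC_CODE_TABLE[[cod]]
      for (p in 1:3) {
        syn <- 0L
        for (b in setdiff(nts, substr(cod, p, p))) {
          alt <- cod
          substr(alt, p, p) <- b
          # changes to stop codons count as nonsynonymous sites
          if (!alt %in% STOP_CODONS && GENETIC_CODE_TABLE[[alt]] == aa)
            syn <- syn + 1L
        }
        res[cod, p] <- syn / 3
      }
    }
    tab <<- res
    res
  }
})

#' NG86 synonymous/nonsynonymous site counts of one coding sequence
#'
#' Per codon, each position contributes the fraction of its three possible
#' single-nucleotide changes that preserve the amino acid (changes into stop
#' codons count as nonsynonymous). The terminal stop codon and codons with
#' ambiguous bases are skipped.
#'
#' @param cds in-frame coding sequence
#' @return list: S (synonymous sites), N (nonsynonymous sites), codons used
#' @export
ng86_site_count <- function(cds) {
  codons <- split_codons(cds)
  codons <- codons[codons %in% NONSTOP_CODONS]
  ft <- syn_fraction_table()
  S <- sum(ft[codons, , drop = FALSE])
  list(S = S, N = 3 * length(codons) - S, n_codons = length(codons))
}

# pathway-averaged synonymous/nonsynonymous difference counts for one codon
# pair; equal weights over minimal mutation pathways, pathways through stop
# codons excluded (all pathways kept if every one passes through a stop)
codon_pair_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  paths <- if (k == 1L) list(pos) else {
    perms <- list()
    permute <- function(v, acc) {
      if (!length(v)) { perms[[length(perms) + 1L]] <<- acc; return() }
      for (i in seq_along(v)) permute(v[-i], c(acc, v[i]))
    }
    permute(pos, integer())
    perms
  }
  walk <- function(order_vec) {
    cur <- ca; sd <- 0; nd <- 0
    for (p in order_vec) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (nxt %in% STOP_CODONS || cur %in% STOP_CODONS)
        return(NULL)
      if (GENETIC_CODE_TABLE[[nxt]] == GENETIC_CODE_TABLE[[cur]])
        sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(paths, walk))
  if (!length(res)) {                       # all pathways hit a stop
    res <- lapply(paths, function(order_vec) {
      cur <- ca; sd <- 0; nd <- 0
      for (p in order_vec) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        same <- !cur %in% STOP_CODONS && !nxt %in% STOP_CODONS &&
          GENETIC_CODE_TABLE[[nxt]] == GENETIC_CODE_TABLE[[cur]]
        if (same) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd)
    })
  }
  colMeans(do.call(rbind, res))
}

#' Nei-Gojobori (NG86) synonymous and nonsynonymous divergence
#'
#' Takes an equal-length, gap-free, in-frame codon alignment. Site counts
#' are averaged between the two sequences; difference counts average with
#' equal weight over all minimal mutation pathways per codon, excluding
#' pathways through stop codons. Proportions are Jukes-Cantor corrected:
#' Ks = -(3/4) ln(1 - (4/3) pS). pS >= 3/4 is saturated (Ks = NA, flagged).
#' Codons containing ambiguity characters, stops or gaps are skipped.
#'
#' @param cds_a,cds_b aligned coding sequences of equal length (multiple
#'   of 3)
#' @return list: ks, ka, ps, pn, S, N, Sd, Nd, n_codons, saturated
#' @export
nei_gojobori_ks <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b))
    stop("aligned sequences must have equal length")
  if (nchar(cds_a) %% 3L != 0L) stop("alignment length not a multiple of 3")
  ca <- split_codons(cds_a); cb <- split_codons(cds_b)
  ok <- ca %in% NONSTOP_CODONS & cb %in% NONSTOP_CODONS
  ca <- ca[ok]; cb <- cb[ok]
  if (!length(ca)) stop("no usable codons in alignment")
  ft <- syn_fraction_table()
  S <- (sum(ft[ca, , drop = FALSE]) + sum(ft[cb, , drop = FALSE])) / 2
  N <- 3 * length(ca) - S
  d <- rowSums(vapply(seq_along(ca),
                      function(i) codon_pair_diffs(ca[i], cb[i]),
                      c(sd = 0, nd = 0)))
  ps <- if (S > 0) d[["sd"]] / S else NA_real_
  pn <- if (N > 0) d[["nd"]] / N else NA_real_
  saturated <- is.na(ps) || ps >= 0.75
  ks <- if (saturated) NA_real_ else -0.75 * log(1 - 4 / 3 * ps)
  ka <- if (is.na(pn) || pn >= 0.75) NA_real_ else -0.75 * log(1 - 4 / 3 * pn)
  list(ks = ks, ka = ka, ps = ps, pn = pn, S = S, N = N,
       Sd = d[["sd"]], Nd = d[["nd"]], n_codons = length(ca),
       saturated = saturated)
}

#' Codon-align two coding sequences through their proteins
#'
#' Global protein alignment (BLOSUM62, affine gaps) back-threaded onto the
#' nucleotide sequences; codon columns opposite a gap are dropped pairwise.
#'
#' @param cds_a,cds_b in-frame coding sequences (terminal stop tolerated)
#' @return list of two equal-length gap-free codon-aligned sequences
#' @export
codon_align <- function(cds_a, cds_b) {
  pa <- translate_cds(cds_a)
  pb <- translate_cds(cds_b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1,
    type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cod_a <- split_codons(cds_a); cod_b <- split_codons(cds_b)
  ia <- 0L; ib <- 0L; keep_a <- character(); keep_b <- character()
  for (i in seq_along(ap)) {
    ga <- ap[i] == "-"; gb <- as_[i] == "-"
    if (!ga) ia <- ia + 1L
    if (!gb) ib <- ib + 1L
    if (!ga && !gb) {
      keep_a <- c(keep_a, cod_a[ia])
      keep_b <- c(keep_b, cod_b[ib])
    }
  }
  list(a = paste(keep_a, collapse = ""), b = paste(keep_b, collapse = ""))
}

#' Pairwise Ks for two unaligned coding sequences
#'
#' Convenience wrapper: [codon_align()] then [nei_gojobori_ks()].
#'
#' @param cds_a,cds_b coding sequences
#' @return see [nei_gojobori_ks()]
#' @export
ks_pair <- function(cds_a, cds_b) {
  aln <- codon_align(cds_a, cds_b)
  nei_gojobori_ks(aln$a, aln$b)
}

#' Date a duplication event from Ks under a strict molecular clock
#'
#' T = Ks / (2 mu), reported in million years (MYA). The default clock is
#' the universal plant substitution rate mu = 6.5e-9 per site per year.
#'
#' @param ks synonymous divergence (NA propagates: saturated pairs stay
#'   undated)
#' @param mu substitution rate per synonymous site per year
#' @return age in MYA
#' @export
date_duplication <- function(ks, mu = 6.5e-9) {
  stopifnot(mu > 0)
  ifelse(is.na(ks), NA_real_, ks / (2 * mu) / 1e6)
}

# ---- paralog pairs and collinearity ----------------------------------------

#' Within-genome paralog pairs by reciprocal protein search
#'
#' All-against-all protein search at `E <= evalue` (default 1e-8);
#' self-hits are excluded and a pair is kept when each member hits the
#' other. Each gene's best-scoring partner is recorded for mode
#' assignment.
#'
#' @param proteome named character vector of proteins (or list of
#'   [gene_model()])
#' @param evalue reciprocal-hit threshold (inclusive)
#' @return data.frame: gene_a, gene_b (gene_a < gene_b), evalue, raw_score;
#'   attribute `best_partner` is a named vector mapping each paired gene to
#'   its best-scoring partner
#' @export
paralog_pairs <- function(proteome, evalue = 1e-8) {
  if (is.list(proteome) && inherits(proteome[[1L]], "gene_model")) {
    proteome <- stats::setNames(
      vapply(proteome, `[[`, "", "protein_seq"),
      vapply(proteome, `[[`, "", "gene_id"))
  }
  stopifnot(length(proteome) >= 2L)
  db <- reference_db("self_proteome", "protein", proteome)
  params <- search_params("protein", evalue_cutoff = evalue)
  hit_list <- list()
  for (g in names(proteome)) {
    h <- search(proteome[[g]], db, params, query_id = g)
    h <- h[h$subject_id != g, , drop = FALSE]
    if (nrow(h)) hit_list[[g]] <- h
  }
  if (!length(hit_list))
    return(structure(data.frame(gene_a = character(), gene_b = character(),
                                evalue = numeric(), raw_score = numeric(),
                                stringsAsFactors = FALSE),
                     best_partner = character()))
  all_hits <- do.call(rbind, hit_list)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  k <- key(all_hits$query_id, all_hits$subject_id)
  seen <- table(paste(all_hits$query_id, all_hits$subject_id))
  reciprocal <- vapply(seq_len(nrow(all_hits)), function(i) {
    paste(all_hits$subject_id[i], all_hits$query_id[i]) %in% names(seen)
  }, TRUE)
  rec <- all_hits[reciprocal, , drop = FALSE]
  if (!nrow(rec))
    return(structure(data.frame(gene_a = character(), gene_b = character(),
                                evalue = numeric(), raw_score = numeric(),
                                stringsAsFactors = FALSE),
                     best_partner = character()))
  rec$pair_key <- key(rec$query_id, rec$subject_id)
  agg <- rec[order(rec$pair_key, rec$evalue), ]
  agg <- agg[!duplicated(agg$pair_key), ]
  pairs <- data.frame(
    gene_a = pmin(agg$query_id, agg$subject_id),
    gene_b = pmax(agg$query_id, agg$subject_id),
    evalue = agg$evalue, raw_score = agg$raw_score,
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), ]
  rownames(pairs) <- NULL
  # best-scoring partner per gene
  rec2 <- rec[order(rec$query_id, -rec$raw_score), ]
  best <- rec2[!duplicated(rec2$query_id), ]
  structure(pairs,
            best_partner = stats::setNames(best$subject_id, best$query_id))
}

#' Chain anchor pairs into collinear blocks
#'
#' Dynamic-programming chaining on each chromosome-pair plane: a chain
#' extends strictly increasing gene ranks on both axes (or strictly
#' decreasing on the second axis for inverted blocks) with rank gaps of at
#' most `max_gap`; chains with at least `min_anchors` anchors are reported
#' as blocks. The chain score is the anchor count.
#'
#' @param anchors data.frame with columns gene_a, gene_b
#' @param ranks data.frame from [gene_ranks()] (gene_id, chromosome, rank);
#'   for cross-species blocks, concatenate the two species' rank tables
#' @param min_anchors minimum anchors per block (default 5)
#' @param max_gap maximum rank gap between consecutive anchors (default 25)
#' @return list of blocks: chrom_a, chrom_b, n_anchors, orientation,
#'   anchors (data.frame gene_a, gene_b, rank_a, rank_b)
#' @export
collinear_blocks <- function(anchors, ranks, min_anchors = 5L,
                             max_gap = 25L) {
  if (nrow(anchors) == 0L) return(list())
  rk <- stats::setNames(ranks$rank, ranks$gene_id)
  ch <- stats::setNames(ranks$chromosome, ranks$gene_id)
  a <- anchors$gene_a; b <- anchors$gene_b
  known <- a %in% names(rk) & b %in% names(rk)
  a <- a[known]; b <- b[known]
  if (!length(a)) return(list())
  # canonical orientation: first gene on the lexicographically smaller
  # chromosome; same-chromosome anchors ordered by rank
  swap <- ch[a] > ch[b] | (ch[a] == ch[b] & rk[a] > rk[b])
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  plane <- paste(ch[a], ch[b], sep = "\r")
  blocks <- list()
  for (pl in unique(plane)) {
    idx <- which(plane == pl)
    df <- data.frame(gene_a = a[idx], gene_b = b[idx],
                     rank_a = unname(rk[a[idx]]), rank_b = unname(rk[b[idx]]),
                     stringsAsFactors = FALSE)
    df <- df[!duplicated(df[, c("rank_a", "rank_b")]), ]
    for (orientation in c(1, -1)) {
      used <- rep(FALSE, nrow(df))
      repeat {
        chain <- best_chain(df[!used, , drop = FALSE], max_gap, orientation)
        if (length(chain) < min_anchors) break
        sel <- which(!used)[chain]
        blk <- df[sel, , drop = FALSE]
        rownames(blk) <- NULL
        blocks[[length(blocks) + 1L]] <-
          list(chrom_a = ch[[blk$gene_a[1L]]],
               chrom_b = ch[[blk$gene_b[1L]]],
               n_anchors = nrow(blk),
               orientation = if (orientation == 1) "forward" else "inverted",
               anchors = blk)
        used[sel] <- TRUE
      }
    }
  }
  blocks
}

# longest chain (strictly increasing rank_a; rank_b strictly increasing for
# orientation 1, strictly decreasing for -1; gaps <= max_gap on both axes)
best_chain <- function(df, max_gap, orientation) {
  n <- nrow(df)
  if (n == 0L) return(integer())
  o <- order(df$rank_a, orientation * df$rank_b)
  ra <- df$rank_a[o]; rb <- orientation * df$rank_b[o]
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      if (ra[j] < ra[i] && rb[j] < rb[i] &&
          ra[i] - ra[j] <= max_gap && rb[i] - rb[j] <= max_gap &&
          len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  end <- which.max(len)
  chain <- integer()
  while (end != 0L) { chain <- c(end, chain); end <- prev[end] }
  o[chain]
}

#' Ancestral-locus calls against an outgroup genome
#'
#' A focal gene occupies an ancestral locus when its gene rank falls inside
#' the focal span of a collinear block between the focal genome and the
#' outgroup (anchored by cross-species homolog pairs at `E <= evalue`).
#'
#' @param pkg focal [genome_package()]
#' @param outgroup outgroup [genome_package()]
#' @param evalue cross-species anchor threshold
#' @param min_anchors,max_gap chaining parameters (see [collinear_blocks()])
#' @return named logical vector over focal genes
#' @export
ancestral_loci <- function(pkg, outgroup, evalue = 1e-5, min_anchors = 5L,
                           max_gap = 25L) {
  focal_prot <- stats::setNames(
    vapply(pkg$genes, `[[`, "", "protein_seq"), names(pkg$genes))
  out_prot <- stats::setNames(
    vapply(outgroup$genes, `[[`, "", "protein_seq"), names(outgroup$genes))
  anc <- stats::setNames(rep(FALSE, length(focal_prot)), names(focal_prot))
  if (!length(out_prot)) return(anc)
  db <- reference_db("outgroup_proteome", "protein", out_prot)
  params <- search_params("protein", evalue_cutoff = evalue)
  hits <- list()
  for (g in names(focal_prot)) {
    h <- search(focal_prot[[g]], db, params, query_id = g)
    if (nrow(h)) hits[[g]] <- h[1L, c("query_id", "subject_id")]
  }
  if (!length(hits)) return(anc)
  anchors <- do.call(rbind, hits)
  names(anchors) <- c("gene_a", "gene_b")
  ranks <- rbind(gene_ranks(pkg), gene_ranks(outgroup))
  blocks <- collinear_blocks(anchors, ranks, min_anchors, max_gap)
  frk <- gene_ranks(pkg)
  for (blk in blocks) {
    span <- range(blk$anchors$rank_a)
    chrom <- blk$chrom_a
    inside <- frk$gene_id[frk$chromosome == chrom &
                            frk$rank >= span[1L] & frk$rank <= span[2L]]
    anc[inside] <- TRUE
  }
  anc
}

#' Classify the duplication mode of a paralog pair
#'
#' Precedence: WGD (the pair is an anchor of a collinear block) > tandem
#' (same chromosome, adjacent gene ranks) > proximal (rank distance 2 to
#' `proximal_window`) > transposed (exactly one member at an ancestral
#' locus; evaluated only when ancestral calls are supplied) > dispersed.
#'
#' @param gene_a,gene_b pair members
#' @param ranks [gene_ranks()] table of the focal package
#' @param blocks [collinear_blocks()] result on the intragenomic anchors
#' @param proximal_window maximum rank distance for proximal (default 10)
#' @param ancestral optional named logical from [ancestral_loci()]
#' @return one of "wgd", "tandem", "proximal", "transposed", "dispersed",
#'   or "unclassified" when a member has no rank entry
#' @export
classify_duplication <- function(gene_a, gene_b, ranks, blocks,
                                 proximal_window = 10L, ancestral = NULL) {
  rk <- stats::setNames(ranks$rank, ranks$gene_id)
  ch <- stats::setNames(ranks$chromosome, ranks$gene_id)
  if (!gene_a %in% names(rk) || !gene_b %in% names(rk)) {
    warning("pair (", gene_a, ",", gene_b, ") has no chromosome rank")
    return("unclassified")
  }
  for (blk in blocks) {
    an <- blk$anchors
    if (any((an$gene_a == gene_a & an$gene_b == gene_b) |
            (an$gene_a == gene_b & an$gene_b == gene_a)))
      return("wgd")
  }
  if (ch[[gene_a]] == ch[[gene_b]]) {
    dist <- abs(rk[[gene_a]] - rk[[gene_b]])
    if (dist == 1L) return("tandem")
    if (dist <= proximal_window) return("proximal")
  }
  if (!is.null(ancestral) &&
      xor(isTRUE(ancestral[[gene_a]]), isTRUE(ancestral[[gene_b]])))
    return("transposed")
  "dispersed"
}

# ---- single-gene origin rules ----------------------------------------------

#' Gene-overlap origin test
#'
#' True when the union coverage of the orphan CDS by nucleotide hits
#' (E <= `evalue`) against other-species CDS reaches `min_coverage`.
#'
#' @param og a [gene_model()]
#' @param other_species_cds nucleotide [reference_db()]
#' @param evalue significance cutoff (default 1e-5)
#' @param min_coverage union-coverage threshold (default 0.5)
#' @return list: is_overlap, coverage, n_hits
#' @export
overlap_origin <- function(og, other_species_cds, evalue = 1e-5,
                           min_coverage = 0.5) {
  params <- search_params("nucleotide", evalue_cutoff = evalue)
  hits <- search(og$cds_seq, other_species_cds, params, query_id = og$gene_id)
  cov <- coverage_of(hits, nchar(og$cds_seq))
  list(is_overlap = cov >= min_coverage, coverage = cov, n_hits = nrow(hits))
}

#' TE-exaptation origin test
#'
#' True when the orphan CDS has at least one nucleotide hit at
#' E <= `evalue` against the TE library.
#'
#' @param og_cds orphan coding sequence
#' @param te_library named character vector of TE sequences
#' @param evalue significance cutoff (default 1e-5)
#' @return list: is_te, best_te, best_evalue
#' @export
te_origin <- function(og_cds, te_library, evalue = 1e-5) {
  if (length(te_library) == 0L)
    return(list(is_te = FALSE, best_te = NA_character_,
                best_evalue = NA_real_))
  db <- reference_db("te_library", "nucleotide", te_library)
  params <- search_params("nucleotide", evalue_cutoff = evalue)
  hits <- search(og_cds, db, params)
  if (nrow(hits) == 0L)
    return(list(is_te = FALSE, best_te = NA_character_,
                best_evalue = NA_real_))
  list(is_te = TRUE, best_te = hits$subject_id[1L],
       best_evalue = hits$evalue[1L])
}

#' De novo origin test
#'
#' Translated search of the orphan protein against other genomes. A gene is
#' called de novo when some genome carries a hit with identity >=
#' `min_identity`, query coverage >= `min_coverage` and E <= `evalue`, and
#' the open reading frame of the orthologous region (translated in the hit
#' frame from the hit start) terminates prematurely at less than
#' `max_orf_frac` of the orphan protein length.
#'
#' @param og a [gene_model()]
#' @param other_genomes list of [genome_package()]
#' @param evalue significance cutoff (default 1e-6)
#' @param min_identity minimum percent identity (default 60)
#' @param min_coverage minimum query coverage (default 0.8)
#' @param max_orf_frac maximal orthologous ORF length as a fraction of the
#'   orphan protein (default 0.5)
#' @return list: is_de_novo, genome, chromosome, frame, orf_frac, evidence
#' @export
de_novo_origin <- function(og, other_genomes, evalue = 1e-6,
                           min_identity = 60, min_coverage = 0.8,
                           max_orf_frac = 0.5) {
  prot <- og$protein_seq
  params <- search_params("translated", evalue_cutoff = evalue)
  for (gp in other_genomes) {
    db <- reference_db(paste0(gp$species_id, "_genome"), "nucleotide",
                       gp$genome)
    hits <- search(prot, db, params, query_id = og$gene_id)
    if (nrow(hits) == 0L) next
    ok <- hits$percent_identity >= min_identity &
      hits$query_coverage >= min_coverage
    hits <- hits[ok, , drop = FALSE]
    if (nrow(hits) == 0L) next
    for (i in seq_len(nrow(hits))) {
      h <- hits[i, ]
      chrom_seq <- gp$genome[[h$subject_id]]
      fr <- h$frame
      strand_seq <- if (fr > 0) chrom_seq else revcomp(chrom_seq)
      aa <- translate_all(substr(strand_seq, abs(fr), nchar(strand_seq)))
      tail_aa <- substr(aa, h$s_start, nchar(aa))
      stop_at <- regexpr("*", tail_aa, fixed = TRUE)
      orf_len <- if (stop_at > 0) stop_at - 1L else nchar(tail_aa)
      orf_frac <- orf_len / nchar(prot)
      if (orf_frac < max_orf_frac)
        return(list(is_de_novo = TRUE, genome = gp$species_id,
                    chromosome = h$subject_id, frame = fr,
                    orf_frac = orf_frac, evidence = h))
    }
  }
  list(is_de_novo = FALSE, genome = NA_character_,
       chromosome = NA_character_, frame = NA_integer_,
       orf_frac = NA_real_, evidence = NULL)
}

# ---- orchestration ----------------------------------------------------------

#' Classify the origin mechanism of every orphan gene
#'
#' Applies the mechanism tests in precedence order duplication > overlap >
#' TE > de novo > unclassified, so each orphan receives exactly one
#' mechanism. Duplicated orphans are assigned a mode by
#' [classify_duplication()] and dated by NG86 Ks under the molecular clock.
#'
#' @param og_ids orphan gene ids (e.g. [orphan_ids()])
#' @param pkg the focal [genome_package()]
#' @param context list with optional elements `other_cds` (nucleotide
#'   [reference_db()]), `partner_genomes` (list of [genome_package()]),
#'   `outgroup` ([genome_package()]); missing elements disable the
#'   corresponding rule
#' @param paralog_evalue,overlap_evalue,te_evalue,denovo_evalue thresholds
#' @param proximal_window,min_anchors,max_gap duplication-mode parameters
#' @param mu molecular-clock rate for [date_duplication()]
#' @return data.frame of class `origin_calls`: gene_id, mechanism, dup_mode,
#'   partner_id, ks, age_mya, evidence; attribute `mechanism_table` holds
#'   the mechanism x mode count table
#' @export
classify_origins <- function(og_ids, pkg, context = list(),
                             paralog_evalue = 1e-8, overlap_evalue = 1e-5,
                             te_evalue = 1e-5, denovo_evalue = 1e-6,
                             proximal_window = 10L, min_anchors = 5L,
                             max_gap = 25L, mu = 6.5e-9) {
  proteome <- stats::setNames(
    vapply(pkg$genes, `[[`, "", "protein_seq"), names(pkg$genes))
  pairs <- paralog_pairs(proteome, evalue = paralog_evalue)
  best <- attr(pairs, "best_partner")
  ranks <- gene_ranks(pkg)
  blocks <- collinear_blocks(pairs, ranks, min_anchors, max_gap)
  ancestral <- if (!is.null(context$outgroup))
    ancestral_loci(pkg, context$outgroup, max_gap = max_gap,
                   min_anchors = min_anchors) else NULL

  calls <- data.frame(gene_id = og_ids, mechanism = "unclassified",
                      dup_mode = NA_character_, partner_id = NA_character_,
                      ks = NA_real_, age_mya = NA_real_,
                      evidence = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(og_ids)) {
    g <- og_ids[i]
    if (g %in% names(best)) {
      partner <- best[[g]]
      mode <- classify_duplication(g, partner, ranks, blocks,
                                   proximal_window, ancestral)
      ksres <- ks_pair(pkg$genes[[g]]$cds_seq, pkg$genes[[partner]]$cds_seq)
      calls$mechanism[i] <- "duplication"
      calls$dup_mode[i] <- mode
      calls$partner_id[i] <- partner
      calls$ks[i] <- ksres$ks
      calls$age_mya[i] <- date_duplication(ksres$ks, mu)
      calls$evidence[i] <- sprintf("partner=%s;pS=%.4f%s", partner, ksres$ps,
                                   if (ksres$saturated) ";saturated" else "")
      next
    }
    if (!is.null(context$other_cds)) {
      ov <- overlap_origin(pkg$genes[[g]], context$other_cds,
                           evalue = overlap_evalue)
      if (ov$is_overlap) {
        calls$mechanism[i] <- "overlap"
        calls$evidence[i] <- sprintf("coverage=%.3f;n_hits=%d",
                                     ov$coverage, ov$n_hits)
        next
      }
    }
    if (length(pkg$te_library)) {
      te <- te_origin(pkg$genes[[g]]$cds_seq, pkg$te_library,
                      evalue = te_evalue)
      if (te$is_te) {
        calls$mechanism[i] <- "te"
        calls$evidence[i] <- sprintf("te=%s;evalue=%.3g", te$best_te,
                                     te$best_evalue)
        next
      }
    }
    if (!is.null(context$partner_genomes)) {
      dn <- de_novo_origin(pkg$genes[[g]], context$partner_genomes,
                           evalue = denovo_evalue)
      if (dn$is_de_novo) {
        calls$mechanism[i] <- "de_novo"
        calls$evidence[i] <- sprintf("genome=%s;frame=%d;orf_frac=%.3f",
                                     dn$genome, dn$frame, dn$orf_frac)
        next
      }
    }
  }
  mech_levels <- c("duplication", "overlap", "te", "de_novo", "unclassified")
  tab <- table(factor(calls$mechanism, levels = mech_levels))
  mode_tab <- table(factor(calls$dup_mode,
                           levels = c("tandem", "proximal", "dispersed",
                                      "wgd", "transposed")))
  attr(calls, "mechanism_table") <- tab
  attr(calls, "mode_table") <- mode_tab
  class(calls) <- c("origin_calls", "data.frame")
  calls
}

#' @export
print.origin_calls <- function(x, ...) {
  cat("<origin_calls>", nrow(x), "orphan genes\n")
  print(attr(x, "mechanism_table"))
  if (any(attr(x, "mode_table") > 0)) print(attr(x, "mode_table"))
  invisible(x)
}

#' Gaussian kernel density of a Ks distribution
#'
#' Visualization helper for duplicate-age summaries (Silverman bandwidth).
#'
#' @param ks numeric vector of Ks values (NAs dropped)
#' @return stats::density object
#' @export
ks_density <- function(ks) {
  ks <- ks[!is.na(ks)]
  if (length(ks) < 2L) stop("need at least two finite Ks values")
  stats::density(ks, bw = "nrd0")
}
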