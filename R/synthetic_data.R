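# Synthetic genome packages, reference panels and count matrices with planted
# ground truth. The generator defines the study conditions for every
# downstream test: planted no-homolog orphans, duplicate pairs of each mode
# mutated to a target Ks, TE-derived / overlap / de novo cases, and
# negative-binomial counts with planted tissue-specific and DE genes.

ALL_CODONS <- names(Biostrings::GENETIC_CODE)
STOP_CODONS <- c("TAA", "TAG", "TGA")
NONSTOP_CODONS <- setdiff(ALL_CODONS, STOP_CODONS)
AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
          "F","P","S","T","W","Y","V")
# codon families whose third position is fourfold degenerate
FOURFOLD_PREFIX <- c("GC", "CG", "GG", "CT", "CC", "TC", "AC", "GT")

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the standard study conditions used throughout the test
#' suite: 1,000 genes on 4 chromosomes with 50 planted orphans, of which 34
#' arise by duplication (3 tandem, 3 proximal and 3 dispersed pairs, one
#' collinear block of 6 WGD anchor pairs, 2 transposed pairs backed by a
#' generated outgroup), 4 by TE exaptation, 4 by gene overlap, 4 de novo,
#' and 4 unclassified. Non-orphan proteins average 300 aa with Poisson
#' exon counts; orphan proteins average 100 aa with fewer exons (the
#' qualitative structure contrast the pipeline is expected to detect).
#'
#' @param seed integer seed; the same config is guaranteed to reproduce
#'   byte-identical packages
#' @param n_genes,n_chromosomes genome size
#' @param orphan_fraction proportion of genes planted as orphans; the
#'   unclassified-orphan count is derived after the planted categories
#' @param duplication_plan named counts of planted duplicate PAIRS per mode
#'   (`wgd` counts anchor pairs of the single planted collinear block and
#'   must be >= 6; `transposed` pairs trigger outgroup generation)
#' @param te_gene_count,overlap_gene_count,denovo_gene_count planted
#'   single-gene origin cases
#' @param panel_stages number of reference databases in the cascade panel
#' @param homolog_identity target protein identity of planted homologs
#' @param later_stage_prob probability a homolog is also present in each
#'   database after its first (planted) stage
#' @param decoys_per_db unrelated random proteins per database
#' @param ks_range range of planted Ks for duplicate pairs
#' @param nog_protein_mean,og_protein_mean mean protein lengths (aa)
#' @param tissues,replicates expression design
#' @param specific_count,specific_fold planted tissue-specific genes and
#'   their focal-tissue fold elevation
#' @param de_count,de_log2fc planted differentially expressed genes
#'   (condition contrast = first vs second tissue)
#' @param nb_dispersion negative-binomial dispersion of counts
#' @param expr_genes number of genes in a standalone count simulation
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L, n_genes = 1000L, n_chromosomes = 4L,
                       orphan_fraction = 0.05,
                       duplication_plan = c(tandem = 3L, proximal = 3L,
                                            dispersed = 3L, wgd = 6L,
                                            transposed = 2L),
                       te_gene_count = 4L, overlap_gene_count = 4L,
                       denovo_gene_count = 4L,
                       panel_stages = 4L, homolog_identity = 0.8,
                       later_stage_prob = 0.3, decoys_per_db = 50L,
                       ks_range = c(0.1, 0.6),
                       nog_protein_mean = 300L, og_protein_mean = 100L,
                       tissues = c("root", "stem", "leaf", "flower", "fruit"),
                       replicates = 3L,
                       specific_count = 50L, specific_fold = 20,
                       de_count = 100L, de_log2fc = 3,
                       nb_dispersion = 0.05, expr_genes = 1000L) {
  stopifnot(orphan_fraction >= 0, orphan_fraction <= 1,
            all(duplication_plan >= 0L),
            duplication_plan[["wgd"]] == 0L || duplication_plan[["wgd"]] >= 6L)
  n_orphans <- round(orphan_fraction * n_genes)
  planted <- 2L * sum(duplication_plan[c("tandem", "proximal", "dispersed",
                                         "transposed")]) +
    2L * duplication_plan[["wgd"]] +
    te_gene_count + overlap_gene_count + denovo_gene_count
  if (planted > n_orphans)
    stop("planted origin cases (", planted, ") exceed the orphan budget (",
         n_orphans, ")")
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_chromosomes = as.integer(n_chromosomes),
                 orphan_fraction = orphan_fraction,
                 duplication_plan = duplication_plan,
                 te_gene_count = as.integer(te_gene_count),
                 overlap_gene_count = as.integer(overlap_gene_count),
                 denovo_gene_count = as.integer(denovo_gene_count),
                 plain_orphan_count = as.integer(n_orphans - planted),
                 panel_stages = as.integer(panel_stages),
                 homolog_identity = homolog_identity,
                 later_stage_prob = later_stage_prob,
                 decoys_per_db = as.integer(decoys_per_db),
                 ks_range = ks_range,
                 nog_protein_mean = as.integer(nog_protein_mean),
                 og_protein_mean = as.integer(og_protein_mean),
                 tissues = tissues, replicates = as.integer(replicates),
                 specific_count = as.integer(specific_count),
                 specific_fold = specific_fold,
                 de_count = as.integer(de_count), de_log2fc = de_log2fc,
                 nb_dispersion = nb_dispersion,
                 expr_genes = as.integer(expr_genes)),
            class = "sim_config")
}

# ---- sequence builders ------------------------------------------------------

random_cds <- function(n_codons) {
  paste0("ATG", paste(sample(NONSTOP_CODONS, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

split_codons <- function(cds) substring(cds, seq(1L, nchar(cds), 3L),
                                        seq(3L, nchar(cds), 3L))

#' Mutate a CDS to a target synonymous divergence
#'
#' Applies substitutions only at third positions of fourfold-degenerate
#' codons (one per codon), so every change is strictly synonymous and the
#' planted count of synonymous differences is exact. The number of changes
#' is chosen so that the Jukes-Cantor-corrected NG86 estimate of the
#' resulting pair equals `target_ks`. Optionally adds strictly
#' nonsynonymous first-position changes so protein identity stays below 1.
#'
#' @param cds in-frame coding sequence
#' @param target_ks planted synonymous divergence (Ks <= 1 recommended)
#' @param nonsyn_frac fraction of codons receiving a nonsynonymous change
#' @return list: cds (mutated copy), planted_ks (realized target after any
#'   capping), n_syn changes applied
#' @export
mutate_to_ks <- function(cds, target_ks, nonsyn_frac = 0.05) {
  codons <- split_codons(cds)
  ncod <- length(codons)
  sites <- ng86_site_count(cds)           # pathway-free NG86 site totals
  ps_target <- 0.75 * (1 - exp(-4 / 3 * target_ks))
  n_syn <- round(ps_target * sites$S)
  four <- which(substr(codons, 1L, 2L) %in% FOURFOLD_PREFIX)
  four <- setdiff(four, c(1L, ncod))       # keep start/stop intact
  if (n_syn > length(four)) {
    warning("target Ks needs ", n_syn, " fourfold sites, only ",
            length(four), " available; capping")
    n_syn <- length(four)
  }
  mut_syn <- if (n_syn > 0L) sample(four, n_syn) else integer()
  for (i in mut_syn) {
    third <- substr(codons[i], 3L, 3L)
    substr(codons[i], 3L, 3L) <- sample(setdiff(c("A", "C", "G", "T"),
                                                third), 1L)
  }
  # single-nucleotide, strictly nonsynonymous, stop-free changes away from
  # the Ks sites (keeps the planted synonymous-difference count exact)
  n_ns <- round(nonsyn_frac * ncod)
  cand <- setdiff(seq(2L, ncod - 1L), mut_syn)
  mut_ns <- if (n_ns > 0L && length(cand)) sample(cand, min(n_ns, length(cand)))
            else integer()
  for (i in mut_ns) {
    cod <- codons[i]
    aa <- GENETIC_CODE_TABLE[[cod]]
    done <- FALSE
    for (p in c(1L, 2L)) {
      for (b in sample(setdiff(c("A", "C", "G", "T"), substr(cod, p, p)))) {
        alt <- cod
        substr(alt, p, p) <- b
        if (!alt %in% STOP_CODONS && GENETIC_CODE_TABLE[[alt]] != aa) {
          codons[i] <- alt
          done <- TRUE
          break
        }
      }
      if (done) break
    }
  }
  realized_ps <- if (sites$S > 0) n_syn / sites$S else 0
  list(cds = paste(codons, collapse = ""),
       planted_ks = -0.75 * log(1 - 4 / 3 * realized_ps),
       n_syn = n_syn)
}

mutate_protein <- function(protein, identity) {
  aa <- strsplit(protein, "")[[1]]
  n_mut <- round((1 - identity) * length(aa))
  if (n_mut > 0L) {
    idx <- sample(seq_along(aa)[-1L], min(n_mut, length(aa) - 1L))
    for (i in idx) aa[i] <- sample(setdiff(AA20, aa[i]), 1L)
  }
  paste(aa, collapse = "")
}

# codon-wise nonsynonymous mutation of a CDS (no stops introduced)
mutate_cds_codonwise <- function(cds, aa_identity) {
  codons <- split_codons(cds)
  ncod <- length(codons)
  n_mut <- round((1 - aa_identity) * ncod)
  idx <- if (n_mut > 0L) sample(seq(2L, ncod - 1L), min(n_mut, ncod - 2L))
         else integer()
  for (i in idx) {
    aa <- GENETIC_CODE_TABLE[[codons[i]]]
    repl <- sample(NONSTOP_CODONS, 8L)
    repl <- repl[GENETIC_CODE_TABLE[repl] != aa]
    if (length(repl)) codons[i] <- repl[1L]
  }
  paste(codons, collapse = "")
}

strip_inframe_stops <- function(cds) {
  codons <- split_codons(cds)
  inner <- seq(2L, length(codons) - 1L)
  bad <- inner[codons[inner] %in% STOP_CODONS]
  for (i in bad) codons[i] <- sample(NONSTOP_CODONS, 1L)
  paste(codons, collapse = "")
}

protein_len_draw <- function(n, mean_aa) {
  pmax(50L, round(stats::rnorm(n, mean_aa, mean_aa / 5)))
}

# ---- package simulation -----------------------------------------------------

#' Simulate a genome package with planted ground truth
#'
#' Builds chromosomes gene by gene: tandem pairs occupy adjacent gene ranks,
#' proximal pairs are separated by 3 intervening genes, the WGD block is a
#' collinear run of anchor pairs across two chromosomes, dispersed and
#' transposed pairs straddle chromosomes, and TE-derived genes embed a TE
#' fragment covering >= 60\% of their CDS. Orphan genes are random-codon
#' sequences absent (by construction) from every reference database the
#' panel generator emits. When the duplication plan includes transposed
#' pairs an outgroup package is generated whose collinear runs anchor the
#' ancestral copy's neighborhood.
#'
#' @param config a [sim_config()]
#' @return list: `package` (a [genome_package()]), `truth` (per-gene truth
#'   table), `outgroup` (a [genome_package()] or NULL)
#' @export
simulate_package <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  plan <- config$duplication_plan
  n <- config$n_genes
  nchr <- config$n_chromosomes
  per_chr <- diff(round(seq(0, n, length.out = nchr + 1)))

  # ---- gene descriptors -----------------------------------------------------
  # category codes: nog, plain, tandem, proximal, dispersed, wgd, transposed,
  #                 te, overlap, denovo
  desc <- data.frame(slot_chr = integer(), category = character(),
                     pair_id = integer(), member = integer(),
                     stringsAsFactors = FALSE)
  add <- function(chr, category, pair_id = NA_integer_,
                  member = NA_integer_) {
    desc[nrow(desc) + 1L, ] <<- list(chr, category, pair_id, member)
  }
  pair_counter <- 0L
  # chr1: tandem pairs (adjacent ranks), transposed ancestral copies embedded
  # in a run of ordinary neighbours
  for (p in seq_len(plan[["tandem"]])) {
    pair_counter <- pair_counter + 1L
    add(1L, "nog"); add(1L, "nog")
    add(1L, "tandem", pair_counter, 1L); add(1L, "tandem", pair_counter, 2L)
  }
  trans_pairs <- integer()
  for (p in seq_len(plan[["transposed"]])) {
    pair_counter <- pair_counter + 1L
    trans_pairs <- c(trans_pairs, pair_counter)
    for (k in 1:3) add(1L, "nog")            # left neighbours (outgroup run)
    add(1L, "transposed", pair_counter, 1L)  # ancestral copy
    for (k in 1:3) add(1L, "nog")            # right neighbours
  }
  # chr2: proximal pairs (3 intervening genes) then the WGD block side A
  for (p in seq_len(plan[["proximal"]])) {
    pair_counter <- pair_counter + 1L
    add(2L, "proximal", pair_counter, 1L)
    for (k in 1:3) add(2L, "nog")
    add(2L, "proximal", pair_counter, 2L)
    add(2L, "nog")
  }
  wgd_pairs <- integer()
  for (p in seq_len(plan[["wgd"]])) {
    pair_counter <- pair_counter + 1L
    wgd_pairs <- c(wgd_pairs, pair_counter)
    add(2L, "wgd", pair_counter, 1L)
  }
  # chr3: WGD block side B, dispersed member 1
  for (p in wgd_pairs) add(3L, "wgd", p, 2L)
  disp_pairs <- integer()
  for (p in seq_len(plan[["dispersed"]])) {
    pair_counter <- pair_counter + 1L
    disp_pairs <- c(disp_pairs, pair_counter)
    add(3L, "dispersed", pair_counter, 1L)
    add(3L, "nog")
  }
  # chr4: dispersed member 2, transposed novel copies, TE / overlap /
  # de novo / plain orphans
  for (p in disp_pairs) { add(4L, "dispersed", p, 2L); add(4L, "nog") }
  for (p in trans_pairs) { add(4L, "transposed", p, 2L); add(4L, "nog") }
  for (k in seq_len(config$te_gene_count)) add(4L, "te")
  for (k in seq_len(config$overlap_gene_count)) add(4L, "overlap")
  for (k in seq_len(config$denovo_gene_count)) add(4L, "denovo")
  for (k in seq_len(config$plain_orphan_count))
    add(((k - 1L) %% nchr) + 1L, "plain")

  # pad every chromosome with ordinary genes up to its share
  for (chr in seq_len(nchr)) {
    have <- sum(desc$slot_chr == chr)
    if (have > per_chr[chr])
      stop("chromosome ", chr, " overfull: ", have, " planted genes for ",
           per_chr[chr], " slots; raise n_genes")
    for (k in seq_len(per_chr[chr] - have)) add(chr, "nog")
  }

  # ---- sequences ------------------------------------------------------------
  te_library <- stats::setNames(
    vapply(seq_len(10L), function(i) random_dna(sample(500:3000, 1L)), ""),
    paste0("TE", sprintf("%02d", 1:10)))

  n_total <- nrow(desc)
  orphan_cats <- c("plain", "tandem", "proximal", "dispersed", "wgd",
                   "transposed", "te", "overlap", "denovo")
  desc$is_orphan <- desc$category %in% orphan_cats
  prot_len <- ifelse(desc$is_orphan,
                     protein_len_draw(n_total, config$og_protein_mean),
                     protein_len_draw(n_total, config$nog_protein_mean))

  cds <- character(n_total)
  planted_ks <- rep(NA_real_, n_total)
  te_source <- rep(NA_character_, n_total)
  # duplicate pairs share a parent; member 2 is the mutated copy
  pair_rows <- split(seq_len(n_total)[!is.na(desc$pair_id)],
                     desc$pair_id[!is.na(desc$pair_id)])
  for (i in seq_len(n_total)) {
    if (!is.na(desc$pair_id[i])) next     # built below
    L <- prot_len[i] + 2L                 # + start, stop
    if (desc$category[i] == "te") {
      body_len <- prot_len[i]             # codons between start and stop
      frag_cod <- ceiling(0.6 * body_len)
      te_id <- names(te_library)[(match(i, which(desc$category == "te")) - 1L) %%
                                   length(te_library) + 1L]
      te_seq <- te_library[[te_id]]
      off <- sample(nchar(te_seq) - 3L * frag_cod, 1L)
      frag <- substr(te_seq, off, off + 3L * frag_cod - 1L)
      pre <- body_len - frag_cod
      cds[i] <- strip_inframe_stops(
        paste0("ATG",
               paste(sample(NONSTOP_CODONS, pre, replace = TRUE), collapse = ""),
               frag, "TAA"))
      te_source[i] <- te_id
    } else {
      cds[i] <- random_cds(L)
    }
  }
  for (p in names(pair_rows)) {
    rows <- pair_rows[[p]]
    stopifnot(length(rows) == 2L)
    L <- max(prot_len[rows]) + 2L
    parent <- random_cds(L)
    ks <- stats::runif(1L, config$ks_range[1L], config$ks_range[2L])
    mut <- mutate_to_ks(parent, ks)
    cds[rows[1L]] <- parent
    cds[rows[2L]] <- mut$cds
    planted_ks[rows] <- mut$planted_ks
  }

  # ---- assemble chromosomes -------------------------------------------------
  genes <- list(); truth_rows <- list()
  gidx <- 0L
  chrom_seq <- character(nchr)
  names(chrom_seq) <- paste0("chr", seq_len(nchr))
  order_rows <- order(desc$slot_chr)      # keep per-chromosome insertion order
  for (chr in seq_len(nchr)) {
    rows <- which(desc$slot_chr == chr)
    seqparts <- character(); pos <- 0L
    for (i in rows) {
      gidx <- gidx + 1L
      gid <- sprintf("G%04d", gidx)
      gap <- sample(200:600, 1L)
      seqparts <- c(seqparts, random_dna(gap)); pos <- pos + gap
      this_cds <- cds[i]
      strand <- if (stats::runif(1L) < 0.3) "-" else "+"
      n_ex <- if (desc$is_orphan[i]) 1L + stats::rpois(1L, 0.5)
              else 1L + stats::rpois(1L, 3L)
      n_ex <- min(n_ex, max(1L, nchar(this_cds) %/% 60L))
      cuts <- if (n_ex > 1L)
        sort(sample(seq(3L, nchar(this_cds) - 3L, by = 3L), n_ex - 1L))
      else integer()
      bounds <- c(0L, cuts, nchar(this_cds))
      chunks <- substring(this_cds, bounds[-length(bounds)] + 1L,
                          bounds[-1L])
      if (strand == "-") chunks <- rev(vapply(chunks, revcomp, ""))
      exon_rows <- matrix(0L, n_ex, 2L)
      gstart <- pos + 1L
      for (e in seq_len(n_ex)) {
        if (e > 1L) {
          intr <- sample(60:300, 1L)
          seqparts <- c(seqparts, random_dna(intr)); pos <- pos + intr
        }
        exon_rows[e, ] <- c(pos + 1L, pos + nchar(chunks[e]))
        seqparts <- c(seqparts, chunks[e]); pos <- pos + nchar(chunks[e])
      }
      genes[[gid]] <- gene_model(gid, paste0("chr", chr), strand,
                                 gstart, pos, exon_rows, this_cds)
      truth_rows[[gid]] <- data.frame(
        gene_id = gid, chromosome = paste0("chr", chr),
        is_orphan = desc$is_orphan[i], category = desc$category[i],
        pair_id = desc$pair_id[i], pair_member = desc$member[i],
        planted_ks = planted_ks[i], te_source = te_source[i],
        stringsAsFactors = FALSE)
    }
    tail_gap <- sample(500:1000, 1L)
    seqparts <- c(seqparts, random_dna(tail_gap))
    chrom_seq[chr] <- paste(seqparts, collapse = "")
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  # partner ids and origin modes
  truth$partner_id <- NA_character_
  for (p in unique(stats::na.omit(truth$pair_id))) {
    rows <- which(truth$pair_id == p)
    truth$partner_id[rows] <- truth$gene_id[rev(rows)]
  }
  truth$origin_mode <- ifelse(
    truth$category %in% c("tandem", "proximal", "dispersed", "wgd",
                          "transposed"), truth$category, NA_character_)
  truth$mechanism <- ifelse(!truth$is_orphan, NA_character_,
    ifelse(!is.na(truth$origin_mode), "duplication",
    ifelse(truth$category == "te", "te",
    ifelse(truth$category == "overlap", "overlap",
    ifelse(truth$category == "denovo", "de_novo", "unclassified")))))
  # reference panel stage for every non-orphan gene
  truth$planted_stage <- NA_integer_
  nog_rows <- which(!truth$is_orphan)
  truth$planted_stage[nog_rows] <- sample(seq_len(config$panel_stages),
                                          length(nog_rows), replace = TRUE)

  pkg <- genome_package("focal", chrom_seq, genes, te_library)
  outgroup <- if (plan[["transposed"]] > 0L)
    build_outgroup(pkg, truth, config) else NULL
  list(package = pkg, truth = truth, outgroup = outgroup)
}

# Outgroup package for transposed-mode calls: for every transposed pair the
# ancestral copy's flanking run (3 neighbours either side, plus the copy's
# rank position left vacant) appears as a collinear run of homologs on an
# outgroup chromosome; the novel copy's neighbourhood has no outgroup match.
build_outgroup <- function(pkg, truth, config) {
  runs <- list()
  ranks <- gene_ranks(pkg)
  for (p in unique(truth$pair_id[truth$category == "transposed" &
                                 truth$pair_member == 1L])) {
    anc <- truth$gene_id[!is.na(truth$pair_id) & truth$pair_id == p &
                           truth$pair_member == 1L]
    chr <- pkg$genes[[anc]]$chromosome
    ordered <- ranks$gene_id[ranks$chromosome == chr][
      order(ranks$rank[ranks$chromosome == chr])]
    at <- match(anc, ordered)
    neigh <- ordered[setdiff(seq(at - 3L, at + 3L), at)]
    neigh <- neigh[!is.na(neigh)]
    runs[[as.character(p)]] <- neigh
  }
  genes <- list(); chrom <- character(); pos <- 0L; parts <- character()
  gidx <- 0L
  for (run in runs) {
    for (gid in run) {
      gidx <- gidx + 1L
      ogid <- sprintf("OUT%03d", gidx)
      prot <- mutate_protein(pkg$genes[[gid]]$protein_seq, 0.85)
      ocds <- protein_to_cds(prot)
      gap <- sample(200:400, 1L)
      parts <- c(parts, random_dna(gap)); pos <- pos + gap
      gstart <- pos + 1L
      parts <- c(parts, ocds); pos <- pos + nchar(ocds)
      genes[[ogid]] <- gene_model(ogid, "och1", "+", gstart, pos,
                                  matrix(c(gstart, pos), 1L), ocds)
    }
  }
  parts <- c(parts, random_dna(500L)); pos <- pos + 500L
  genome_package("outgroup", c(och1 = paste(parts, collapse = "")), genes)
}

# deterministic reverse translation (first codon of each amino acid)
protein_to_cds <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  back <- vapply(aa, function(a) {
    hits <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE == a]
    if (!length(hits)) "NNN" else hits[1L]
  }, "")
  paste0(paste(back, collapse = ""), "TAA")
}

#' Gene ranks (order along each chromosome)
#'
#' @param pkg a [genome_package()]
#' @return data.frame: gene_id, chromosome, rank (1-based order by start)
#' @export
gene_ranks <- function(pkg) {
  df <- data.frame(gene_id = vapply(pkg$genes, `[[`, "", "gene_id"),
                   chromosome = vapply(pkg$genes, `[[`, "", "chromosome"),
                   start = vapply(pkg$genes, `[[`, 1L, "start"),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chromosome, df$start), ]
  df$rank <- stats::ave(df$start, df$chromosome,
                        FUN = function(x) seq_along(x))
  rownames(df) <- NULL
  df[, c("gene_id", "chromosome", "rank")]
}

# ---- reference panel --------------------------------------------------------

#' Simulate the ordered reference-database panel
#'
#' Every non-orphan gene receives at least one planted homolog (protein
#' identity `homolog_identity`, >= 0.7 by default) in the database of its
#' planted stage, and with probability `later_stage_prob` also in each later
#' database. Orphan genes are present in no database. Each database also
#' carries unrelated decoy proteins.
#'
#' @param sim result of [simulate_package()]
#' @param config the same [sim_config()]
#' @return list of [reference_db()] in stage order
#' @export
simulate_reference_panel <- function(sim, config) {
  set.seed(config$seed + 1000L)
  truth <- sim$truth
  pkg <- sim$package
  dbs <- vector("list", config$panel_stages)
  names(dbs) <- paste0("DB", c("I", "II", "III", "IV",
                               as.character(5:9))[seq_len(config$panel_stages)])
  recs <- lapply(seq_len(config$panel_stages), function(s) character())
  for (i in which(!truth$is_orphan)) {
    gid <- truth$gene_id[i]
    prot <- pkg$genes[[gid]]$protein_seq
    s0 <- truth$planted_stage[i]
    stages <- s0
    if (s0 < config$panel_stages) {
      later <- (s0 + 1L):config$panel_stages
      stages <- c(s0, later[stats::runif(length(later)) < config$later_stage_prob])
    }
    for (s in stages) {
      hom <- mutate_protein(prot, config$homolog_identity)
      recs[[s]][paste0("hom_", gid, "_s", s)] <- hom
    }
  }
  for (s in seq_len(config$panel_stages)) {
    for (d in seq_len(config$decoys_per_db)) {
      recs[[s]][sprintf("decoy_s%d_%03d", s, d)] <-
        translate_cds(random_cds(sample(150:400, 1L)))
    }
    dbs[[s]] <- reference_db(names(dbs)[s], "protein", recs[[s]],
                             stage_rank = s)
  }
  dbs
}

#' Simulate the origin-evidence context
#'
#' Builds the inputs the origin classifier needs beyond the focal package:
#' a nucleotide database of other-species CDS in which each planted
#' overlap-origin gene has a homologous fragment covering >= 60\% of its CDS,
#' and one partner genome per panel in which each planted de novo gene has
#' an orthologous non-coding region (about 88\% amino-acid identity) whose
#' reading frame is interrupted by a premature stop at 40\% of the protein
#' length.
#'
#' @param sim result of [simulate_package()]
#' @param config the same [sim_config()]
#' @return list: `other_cds` ([reference_db()], nucleotide), `partner_genomes`
#'   (list of one [genome_package()])
#' @export
simulate_origin_context <- function(sim, config) {
  set.seed(config$seed + 2000L)
  truth <- sim$truth
  pkg <- sim$package
  # other-species CDS database: planted overlap fragments + decoy CDS
  recs <- character()
  for (gid in truth$gene_id[truth$category == "overlap"]) {
    cds <- pkg$genes[[gid]]$cds_seq
    frag_len <- floor(0.6 * nchar(cds))
    frag <- substr(cds, 1L, frag_len)
    frag <- mutate_nt(frag, 0.95)
    recs[paste0("osp_", gid)] <-
      paste0(random_dna(150L), frag, random_dna(150L))
  }
  for (d in seq_len(40L))
    recs[sprintf("osp_decoy_%03d", d)] <- random_cds(sample(150:400, 1L))
  other_cds <- reference_db("other_species_cds", "nucleotide", recs)

  # partner genome carrying the de novo orthologous regions
  parts <- character(); pos <- 0L
  for (gid in truth$gene_id[truth$category == "denovo"]) {
    cds <- pkg$genes[[gid]]$cds_seq
    region <- mutate_cds_codonwise(cds, 0.88)
    codons <- split_codons(region)
    stop_at <- max(2L, floor(0.4 * length(codons)))
    codons[stop_at] <- "TAA"
    region <- paste(codons, collapse = "")
    parts <- c(parts, random_dna(sample(800:1500, 1L)), region)
    pos <- pos + 1L
  }
  parts <- c(parts, random_dna(1000L))
  partner <- genome_package("partner",
                            c(pch1 = paste(parts, collapse = "")), list())
  list(other_cds = other_cds, partner_genomes = list(partner))
}

mutate_nt <- function(x, identity) {
  nt <- strsplit(x, "")[[1]]
  n_mut <- round((1 - identity) * length(nt))
  if (n_mut > 0L) {
    idx <- sample(seq_along(nt), n_mut)
    for (i in idx) nt[i] <- sample(setdiff(c("A", "C", "G", "T"), nt[i]), 1L)
  }
  paste(nt, collapse = "")
}

# ---- expression simulation --------------------------------------------------

#' Simulate a count matrix with planted tissue-specific and DE genes
#'
#' Counts are negative binomial around gene- and tissue-specific means with
#' common dispersion; library sizes vary at most threefold. Planted
#' tissue-specific genes express `specific_fold`-times higher in one focal
#' tissue; planted DE genes differ by `de_log2fc` between the first two
#' tissues (treated as the contrast conditions).
#'
#' @param config a [sim_config()]
#' @return list of class `expression_matrix`: counts (genes x samples),
#'   gene_lengths (bp), design (sample, tissue, replicate), truth
#'   (is_specific, specific_tissue, true_log2fc)
#' @export
simulate_counts <- function(config) {
  stopifnot(length(config$tissues) >= 2L, config$replicates >= 2L)
  set.seed(config$seed + 3000L)
  n <- config$expr_genes
  tis <- config$tissues
  reps <- config$replicates
  samples <- paste(rep(tis, each = reps), rep(seq_len(reps), length(tis)),
                   sep = "_")
  design <- data.frame(sample = samples,
                       tissue = rep(tis, each = reps),
                       replicate = rep(seq_len(reps), length(tis)),
                       stringsAsFactors = FALSE)
  gene_ids <- sprintf("EG%04d", seq_len(n))
  base <- stats::rlnorm(n, log(100), 1)
  lens <- sample(500:4000, n, replace = TRUE)
  mu <- matrix(base, n, length(tis),
               dimnames = list(gene_ids, tis))

  truth <- data.frame(gene_id = gene_ids, is_specific = FALSE,
                      specific_tissue = NA_character_,
                      true_log2fc = 0, is_de = FALSE,
                      stringsAsFactors = FALSE)
  idx <- sample(n, config$specific_count + config$de_count)
  spec_idx <- idx[seq_len(config$specific_count)]
  de_idx <- setdiff(idx, spec_idx)
  for (i in spec_idx) {
    focal <- sample(tis, 1L)
    mu[i, ] <- pmax(base[i] / config$specific_fold, 0.5)
    mu[i, focal] <- base[i] * config$specific_fold
    truth$is_specific[i] <- TRUE
    truth$specific_tissue[i] <- focal
  }
  for (i in de_idx) {
    sgn <- sample(c(-1, 1), 1L)
    mu[i, tis[1L]] <- mu[i, tis[1L]] * 2^(sgn * config$de_log2fc / 2)
    mu[i, tis[2L]] <- mu[i, tis[2L]] * 2^(-sgn * config$de_log2fc / 2)
    truth$true_log2fc[i] <- sgn * config$de_log2fc
    truth$is_de[i] <- TRUE
  }
  libsize <- stats::runif(length(samples), 0.6, 1.8)
  counts <- matrix(0L, n, length(samples),
                   dimnames = list(gene_ids, samples))
  for (j in seq_along(samples)) {
    m <- mu[, design$tissue[j]] * libsize[j]
    counts[, j] <- if (config$nb_dispersion > 0)
      stats::rnbinom(n, mu = m, size = 1 / config$nb_dispersion)
    else stats::rpois(n, m)
  }
  structure(list(counts = counts, gene_lengths = stats::setNames(lens, gene_ids),
                 design = design, truth = truth),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%d tissues)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$design$tissue))))
  invisible(x)
}
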