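test_that("NG86 gives zero divergence for identical sequences", {
  set.seed(61)
  cds <- orphanforge:::random_cds(50)
  r <- nei_gojobori_ks(cds, cds)
  expect_equal(r$ks, 0)
  expect_equal(r$ka, 0)
  expect_false(r$saturated)
})

test_that("NG86 matches the pathway-enumeration oracle on random alignments", {
  set.seed(62)
  nts <- c("A", "C", "G", "T")
  for (rep_i in 1:30) {
    a <- orphanforge:::random_cds(30)
    b <- a
    # random substitutions anywhere (stops are skipped by both routes)
    for (p in sample(4:87, sample(3:12, 1))) {
      v <- substr(b, p, p)
      substr(b, p, p) <- sample(setdiff(nts, v), 1)
    }
    mine <- nei_gojobori_ks(a, b)
    orc <- ng86_oracle(a, b)
    expect_equal(mine$S, orc$S, tolerance = 1e-9)
    expect_equal(mine$Sd, orc$Sd, tolerance = 1e-9)
    expect_equal(mine$Nd, orc$Nd, tolerance = 1e-9)
    if (!mine$saturated) expect_equal(mine$ks, orc$ks, tolerance = 1e-9)
  }
})

test_that("three synonymous third-position changes recover exactly", {
  set.seed(63)
  a <- paste0("ATG", strrep("GGT", 10), strrep("CTT", 10), "TAA")
  b <- a
  # three fourfold third positions: strictly synonymous changes
  for (p in c(6, 9, 12) + 3) substr(b, p, p) <- "C"
  mine <- nei_gojobori_ks(a, b)
  orc <- ng86_oracle(a, b)
  expect_equal(mine$Sd, 3)
  expect_equal(mine$Nd, 0)
  expect_equal(mine$ks, orc$ks, tolerance = 1e-9)
})

test_that("saturated pairs are flagged with no numeric Ks", {
  # maximally diverged fourfold third positions drive pS toward 1
  a <- paste0("ATG", strrep("GGGGGA", 30), "TAA")
  b <- paste0("ATG", strrep("GGTGGC", 30), "TAA")
  r <- nei_gojobori_ks(a, b)
  expect_true(r$saturated)
  expect_true(is.na(r$ks))
})

test_that("codon alignment drops gap columns pairwise", {
  a <- "ATGAAACCCGGGTTTTGCTAA"          # MKPGFC
  b <- "ATGAAAGGGTTTTGCTAA"             # MKGFC (P deleted)
  aln <- codon_align(a, b)
  expect_equal(nchar(aln$a), nchar(aln$b))
  expect_equal(nchar(aln$a) %% 3, 0)
  r <- nei_gojobori_ks(aln$a, aln$b)
  expect_equal(r$ks, 0)                 # remaining columns identical
})

test_that("the molecular clock maps Ks to age linearly", {
  expect_equal(date_duplication(0.20), 15.38, tolerance = 1e-3)
  expect_equal(date_duplication(0.40), 30.77, tolerance = 1e-3)
  expect_equal(date_duplication(0), 0)
  ks <- seq(0, 1, by = 0.1)
  ages <- date_duplication(ks)
  expect_equal(diff(ages), rep(ages[2], 10), tolerance = 1e-12)
  expect_true(is.na(date_duplication(NA_real_)))
})

test_that("paralog pairs are reciprocal, unique and best-partnered", {
  set.seed(64)
  base <- orphanforge:::random_cds(150)
  mut <- mutate_to_ks(base, 0.2)$cds
  prots <- c(a = translate_cds(base), b = translate_cds(mut),
             c = rand_protein(140), d = rand_protein(140))
  pairs <- paralog_pairs(prots)
  expect_equal(nrow(pairs), 1)
  expect_identical(c(pairs$gene_a, pairs$gene_b), c("a", "b"))
  bp <- attr(pairs, "best_partner")
  expect_identical(unname(bp["a"]), "b")
  # unrelated proteome: empty result
  set.seed(65)
  rnd <- setNames(vapply(rep(120, 6), rand_protein, ""), letters[1:6])
  expect_equal(nrow(paralog_pairs(rnd)), 0)
})

test_that("collinear chains match the exhaustive oracle and the threshold", {
  # planted run of 6 consecutive anchors across two chromosomes
  ranks <- data.frame(
    gene_id = c(paste0("a", 1:10), paste0("b", 1:10)),
    chromosome = rep(c("c1", "c2"), each = 10),
    rank = c(1:10, 1:10))
  anchors6 <- data.frame(gene_a = paste0("a", 2:7),
                         gene_b = paste0("b", 3:8))
  blk <- collinear_blocks(anchors6, ranks, min_anchors = 5)
  expect_length(blk, 1)
  expect_equal(blk[[1]]$n_anchors, 6)
  anchors4 <- anchors6[1:4, ]
  expect_length(collinear_blocks(anchors4, ranks, min_anchors = 5), 0)

  set.seed(66)
  for (rep_i in 1:20) {
    n <- sample(6:12, 1)
    ra <- sample(30, n); rb <- sample(30, n)
    df <- data.frame(gene_a = paste0("a", ra), gene_b = paste0("b", rb))
    rk <- data.frame(gene_id = c(paste0("a", 1:30), paste0("b", 1:30)),
                     chromosome = rep(c("c1", "c2"), each = 30),
                     rank = c(1:30, 1:30))
    got <- collinear_blocks(df, rk, min_anchors = 1L, max_gap = 10L)
    fwd <- Filter(function(b) b$orientation == "forward", got)
    best_len <- if (length(fwd)) max(vapply(fwd, `[[`, 0L, "n_anchors"))
                else 0L
    expect_equal(best_len, chain_oracle(ra, rb, 10L, 1))
  }
})

test_that("duplication modes follow the precedence rules", {
  ranks <- data.frame(gene_id = paste0("g", 1:20),
                      chromosome = rep(c("c1", "c2"), each = 10),
                      rank = c(1:10, 1:10))
  no_blocks <- list()
  expect_identical(
    classify_duplication("g1", "g2", ranks, no_blocks), "tandem")
  expect_identical(
    classify_duplication("g1", "g6", ranks, no_blocks), "proximal")
  expect_identical(
    classify_duplication("g1", "g12", ranks, no_blocks), "dispersed")
  # WGD precedence beats adjacency
  blocks <- list(list(chrom_a = "c1", chrom_b = "c1", n_anchors = 5,
                      orientation = "forward",
                      anchors = data.frame(gene_a = "g1", gene_b = "g2",
                                           rank_a = 1, rank_b = 2)))
  expect_identical(
    classify_duplication("g1", "g2", ranks, blocks), "wgd")
  # transposed requires exactly one ancestral member
  anc <- setNames(rep(FALSE, 20), paste0("g", 1:20))
  anc["g1"] <- TRUE
  expect_identical(
    classify_duplication("g1", "g12", ranks, no_blocks, ancestral = anc),
    "transposed")
  anc["g12"] <- TRUE
  expect_identical(
    classify_duplication("g1", "g12", ranks, no_blocks, ancestral = anc),
    "dispersed")
})

test_that("overlap origin thresholds on union coverage", {
  set.seed(67)
  cds <- orphanforge:::random_cds(100)       # 300 nt
  g <- gene_model("og1", "chr1", "+", 1, 300, matrix(c(1, 300), 1), cds)
  frag60 <- substr(cds, 1, 180)
  frag40 <- substr(cds, 1, 120)
  db60 <- reference_db("osp", "nucleotide",
                       c(x = paste0(rand_dna(50), frag60, rand_dna(50)),
                         pad = rand_dna(300)))
  db40 <- reference_db("osp", "nucleotide",
                       c(x = paste0(rand_dna(50), frag40, rand_dna(50)),
                         pad = rand_dna(300)))
  expect_true(overlap_origin(g, db60)$is_overlap)
  expect_false(overlap_origin(g, db40)$is_overlap)
  # two fragments overlapping 10% union to 50%
  fa <- substr(cds, 1, 90)                    # 30%
  fb <- substr(cds, 61, 150)                  # 30%, union 1..150 = 50%
  db_two <- reference_db("osp", "nucleotide", c(p1 = fa, p2 = fb))
  ov <- overlap_origin(g, db_two)
  expect_equal(ov$coverage, 0.5, tolerance = 0.01)
  expect_true(ov$is_overlap)
})

test_that("TE origin requires a library hit and tolerates an empty library", {
  set.seed(68)
  te <- setNames(rand_dna(800), "TEx")
  cds <- orphanforge:::random_cds(100)
  embedded <- orphanforge:::strip_inframe_stops(
    paste0("ATG", substr(te, 101, 280), substr(cds, 184, 300)))
  expect_true(te_origin(embedded, te)$is_te)
  misses <- 0L
  for (i in 1:20) if (te_origin(orphanforge:::random_cds(100), te)$is_te)
    misses <- misses + 1L
  expect_lte(misses, 1L)
  expect_false(te_origin(cds, character())$is_te)
})

test_that("de novo criteria all gate the call", {
  set.seed(69)
  cds <- orphanforge:::random_cds(120)        # protein 119 aa
  og <- gene_model("ogd", "chr1", "+", 1, 360, matrix(c(1, 360), 1), cds)
  build_partner <- function(aa_identity, stop_frac) {
    region <- orphanforge:::mutate_cds_codonwise(cds, aa_identity)
    codons <- orphanforge:::split_codons(region)
    if (!is.na(stop_frac)) codons[ceiling(stop_frac * length(codons))] <- "TAA"
    genome_package("p", c(c1 = paste0(rand_dna(300),
                                      paste(codons, collapse = ""),
                                      rand_dna(300))), list())
  }
  # enabled case: high identity, stop at 40%
  expect_true(de_novo_origin(og, list(build_partner(0.88, 0.4)))$is_de_novo)
  # identity below 60%: rejected
  expect_false(de_novo_origin(og, list(build_partner(0.45, 0.4)))$is_de_novo)
  # orthologous ORF runs to 80% of the protein: rejected
  expect_false(de_novo_origin(og, list(build_partner(0.88, 0.8)))$is_de_novo)
})

test_that("origin classification partitions the orphan set", {
  cfg <- sim_config(seed = 70L, n_genes = 150L, orphan_fraction = 0.2,
                    duplication_plan = c(tandem = 2L, proximal = 2L,
                                         dispersed = 2L, wgd = 0L,
                                         transposed = 0L),
                    te_gene_count = 2L, overlap_gene_count = 2L,
                    denovo_gene_count = 2L, decoys_per_db = 10L)
  sim <- simulate_package(cfg)
  ctx <- simulate_origin_context(sim, cfg)
  og <- sim$truth$gene_id[sim$truth$is_orphan]
  calls <- classify_origins(og, sim$package, ctx)
  expect_equal(sum(attr(calls, "mechanism_table")), length(og))
  expect_identical(sort(calls$gene_id), sort(og))
  truth_mech <- sim$truth$mechanism[match(calls$gene_id, sim$truth$gene_id)]
  expect_identical(calls$mechanism, truth_mech)
})
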