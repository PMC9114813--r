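# one small configuration reused across this file
small_cfg <- function(seed = 9L)
  sim_config(seed = seed, n_genes = 120L, orphan_fraction = 0.2,
             duplication_plan = c(tandem = 2L, proximal = 2L,
                                  dispersed = 2L, wgd = 0L,
                                  transposed = 0L),
             te_gene_count = 2L, overlap_gene_count = 2L,
             denovo_gene_count = 2L, decoys_per_db = 10L)

test_that("the generator is deterministic for a fixed config", {
  cfg <- small_cfg()
  s1 <- simulate_package(cfg)
  s2 <- simulate_package(cfg)
  expect_identical(s1$package$genome, s2$package$genome)
  expect_identical(s1$truth, s2$truth)
  p1 <- simulate_reference_panel(s1, cfg)
  p2 <- simulate_reference_panel(s2, cfg)
  expect_identical(lapply(p1, `[[`, "records"),
                   lapply(p2, `[[`, "records"))
  e1 <- simulate_counts(cfg)
  e2 <- simulate_counts(cfg)
  expect_identical(e1$counts, e2$counts)
})

test_that("planted categories match the configuration exactly", {
  cfg <- small_cfg()
  sim <- simulate_package(cfg)
  tt <- table(sim$truth$category)
  expect_equal(sum(sim$truth$is_orphan), 24)  # 0.2 * 120
  expect_equal(unname(tt[c("tandem", "proximal", "dispersed")]),
               rep(4L, 3L), ignore_attr = TRUE)
  expect_equal(unname(tt["te"]), 2L, ignore_attr = TRUE)
  expect_equal(unname(tt["denovo"]), 2L, ignore_attr = TRUE)
  expect_error(sim_config(seed = 1, n_genes = 100, orphan_fraction = 0.01),
               "exceed the orphan budget")
})

test_that("planted pairs sit at the right genomic arrangement", {
  cfg <- small_cfg()
  sim <- simulate_package(cfg)
  ranks <- gene_ranks(sim$package)
  rk <- setNames(ranks$rank, ranks$gene_id)
  ch <- setNames(ranks$chromosome, ranks$gene_id)
  tr <- sim$truth
  for (p in unique(na.omit(tr$pair_id))) {
    pair <- tr$gene_id[!is.na(tr$pair_id) & tr$pair_id == p]
    mode <- tr$category[tr$gene_id == pair[1]]
    if (mode == "tandem") {
      expect_identical(unname(ch[pair[1]]), unname(ch[pair[2]]))
      expect_equal(abs(rk[[pair[1]]] - rk[[pair[2]]]), 1)
    } else if (mode == "proximal") {
      expect_identical(unname(ch[pair[1]]), unname(ch[pair[2]]))
      d <- abs(rk[[pair[1]]] - rk[[pair[2]]])
      expect_true(d >= 2 && d <= 10)
    } else if (mode == "dispersed") {
      expect_false(ch[[pair[1]]] == ch[[pair[2]]])
    }
  }
})

test_that("orphans are absent from every panel database, non-orphans planted", {
  cfg <- small_cfg()
  sim <- simulate_package(cfg)
  panel <- simulate_reference_panel(sim, cfg)
  params <- search_params("protein")
  og <- sim$truth$gene_id[sim$truth$is_orphan]
  set.seed(1)
  for (g in sample(og, 6)) {
    for (db in panel) {
      hits <- search(sim$package$genes[[g]]$protein_seq, db, params)
      expect_equal(nrow(hits), 0)
    }
  }
  nog <- sim$truth[!sim$truth$is_orphan, ]
  for (i in sample(nrow(nog), 6)) {
    db <- panel[[nog$planted_stage[i]]]
    hits <- search(sim$package$genes[[nog$gene_id[i]]]$protein_seq, db,
                   params)
    expect_gte(nrow(hits), 1)
  }
})

test_that("planted Ks survives a round trip through the NG86 estimator", {
  set.seed(31)
  for (ks_target in c(0.15, 0.4, 0.8)) {
    parent <- orphanforge:::random_cds(200)
    mut <- mutate_to_ks(parent, ks_target, nonsyn_frac = 0.05)
    est <- ks_pair(parent, mut$cds)
    expect_equal(est$ks, mut$planted_ks, tolerance = 0.06)
    expect_equal(mut$planted_ks, ks_target, tolerance = 0.1)
  }
})

test_that("de novo partner regions truncate below half the orphan protein", {
  cfg <- small_cfg()
  sim <- simulate_package(cfg)
  ctx <- simulate_origin_context(sim, cfg)
  for (g in sim$truth$gene_id[sim$truth$category == "denovo"]) {
    r <- de_novo_origin(sim$package$genes[[g]], ctx$partner_genomes)
    expect_true(r$is_de_novo)
    expect_lt(r$orf_frac, 0.5)
  }
})

test_that("TE genes embed a detectable library fragment", {
  cfg <- small_cfg()
  sim <- simulate_package(cfg)
  for (g in sim$truth$gene_id[sim$truth$category == "te"]) {
    r <- te_origin(sim$package$genes[[g]]$cds_seq, sim$package$te_library)
    expect_true(r$is_te)
    expect_identical(r$best_te,
                     sim$truth$te_source[sim$truth$gene_id == g])
  }
})

test_that("simulated counts respect the planted expression design", {
  cfg <- sim_config(seed = 13L, expr_genes = 400L, specific_count = 20L,
                    de_count = 30L)
  em <- simulate_counts(cfg)
  expect_equal(dim(em$counts),
               c(400L, length(cfg$tissues) * cfg$replicates))
  # planted specific genes reach SPM > 0.99 at 20x specificity in means
  fp <- fpkm(em$counts, em$gene_lengths)
  stab <- spm_table(fp, em$design, threshold = 0.9)
  spec <- em$truth[em$truth$is_specific, ]
  got <- stab$specific_tissue[match(spec$gene_id, stab$gene_id)]
  expect_gte(mean(got == spec$specific_tissue, na.rm = TRUE), 0.9)
  # library sizes within the configured threefold band
  tot <- colSums(em$counts)
  expect_lt(max(tot) / min(tot), 3.5)
})

test_that("zero-dispersion counts approach Poisson variance", {
  cfg <- sim_config(seed = 14L, expr_genes = 2000L, nb_dispersion = 0,
                    specific_count = 0L, de_count = 0L, replicates = 3L,
                    tissues = c("a", "b"))
  em <- simulate_counts(cfg)
  # for Poisson counts, var/mean across genes concentrates near 1 after
  # removing the library-size effect
  norm <- sweep(em$counts, 2L, colSums(em$counts) / mean(colSums(em$counts)),
                "/")
  ratio <- apply(norm, 1L, var) / rowMeans(norm)
  expect_equal(median(ratio, na.rm = TRUE), 1, tolerance = 0.15)
})
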