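test_that("gene statistics follow their definitions", {
  g <- gene_model("g1", "chr1", "+", 1, 9, matrix(c(1, 9), 1), "ATGGGCTAA")
  st <- gene_stats(g)
  expect_equal(st$gc_content, 4 / 9, tolerance = 1e-12)
  expect_equal(st$protein_length, 2)
  g2 <- gene_model("g2", "chr1", "+", 1, 300,
                   matrix(c(1, 100, 201, 300), 2, byrow = TRUE),
                   paste0("ATG", strrep("GGC", 50), "TAA"))
  st2 <- gene_stats(g2)
  expect_equal(st2$exon_count, 2)
  expect_equal(st2$mean_exon_length, 100)
  g3 <- gene_model("g3", "chr1", "+", 1, 9, matrix(c(1, 9), 1), "GGGCCCGGG")
  expect_equal(gene_stats(g3)$gc_content, 1.0)
})

test_that("isoelectric point matches the bisection oracle and is monotone", {
  # independent root of the same charge model via uniroot
  pk <- c(Nterm = 8.6, Cterm = 3.6)
  gg_charge <- function(ph)
    10^pk["Nterm"] / (10^ph + 10^pk["Nterm"]) -
      10^ph / (10^ph + 10^pk["Cterm"])
  oracle <- uniroot(gg_charge, c(0, 14), tol = 1e-10)$root
  expect_equal(isoelectric_point("GG"), oracle, tolerance = 1e-3)
  expect_equal(isoelectric_point("GG"), 6.10, tolerance = 0.01)

  set.seed(51)
  for (i in 1:5) {
    p <- rand_protein(30)
    expect_gt(isoelectric_point(paste0(p, "K")), isoelectric_point(p))
  }
  # acidic peptide carries negative charge at neutral pH
  expect_lt(isoelectric_point("DDDD"), 7)
  expect_warning(isoelectric_point("GGX"), "non-standard")
})

test_that("rank-sum exact p-values come from enumeration", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(r$p_value, wilcox_enum_oracle(c(1, 2), c(3, 4)))
  same <- wilcoxon_rank_sum(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$p_value, 1)
  expect_equal(wilcoxon_rank_sum(rep(2, 3), rep(2, 4))$p_value, 1)
})

test_that("reported p-values track enumeration at and beyond the exact cutoff", {
  # at total n = 10 the reported p IS the enumeration value (exact path)
  set.seed(52)
  vals <- sample(100, 10)
  for (m in 2:8) {
    combs <- utils::combn(10, m)
    for (ci in sample(ncol(combs), min(12, ncol(combs)))) {
      x <- vals[combs[, ci]]
      y <- vals[-combs[, ci]]
      expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                   wilcox_enum_oracle(x, y), tolerance = 1e-10)
    }
  }
  # beyond the cutoff the normal approximation takes over; it stays within
  # 0.02 of enumeration at the sizes where it is actually used
  vals20 <- sample(1000, 20)
  combs <- utils::combn(20, 5)
  worst <- 0
  for (ci in sample(ncol(combs), 60)) {
    x <- vals20[combs[, ci]]
    y <- vals20[-combs[, ci]]
    worst <- max(worst,
                 abs(wilcoxon_rank_sum(x, y, method = "normal")$p_value -
                       wilcox_enum_oracle(x, y)))
  }
  expect_lt(worst, 0.02)
})

test_that("planted shorter orphan proteins give the expected contrast direction", {
  cfg <- sim_config(seed = 53L, n_genes = 400L, orphan_fraction = 0.5,
                    duplication_plan = c(tandem = 0L, proximal = 0L,
                                         dispersed = 0L, wgd = 0L,
                                         transposed = 0L),
                    te_gene_count = 0L, overlap_gene_count = 0L,
                    denovo_gene_count = 0L)
  sim <- simulate_package(cfg)
  og <- sim$truth$gene_id[sim$truth$is_orphan]
  stats_tab <- gene_stats_table(sim$package, og)
  ct <- structure_contrasts(stats_tab)
  pl <- ct[ct$metric == "protein_length", ]
  expect_identical(pl$direction, "x<y")
  expect_lt(pl$p_value, 0.001)
  ec <- ct[ct$metric == "exon_count", ]
  expect_lt(ec$median_x, ec$median_y)
})

test_that("chromosome density windows and telomere summary behave", {
  set.seed(54)
  chr_len <- 1e5
  genes <- lapply(1:200, function(i) {
    s <- sample(chr_len - 200, 1)
    gene_model(sprintf("d%03d", i), "chr1", "+", s, s + 8,
               matrix(c(s, s + 8), 1), "ATGAAATAA")
  })
  pkg <- genome_package("dens", c(chr1 = rand_dna(chr_len)), genes)
  # uniform orphans: terminal/interior ratio near 1
  og_uniform <- names(pkg$genes)[seq(1, 200, by = 4)]
  d1 <- chromosome_density(pkg, og_uniform, window_bp = 1e4)
  expect_equal(sum(d1$windows$n_genes), 200)
  expect_equal(sum(d1$windows$n_og), 50)
  # all orphans in terminal windows: ratio above 1
  pos <- vapply(pkg$genes, function(g) (g$start + g$end) / 2, 0)
  terminal <- names(pos)[pos <= 0.1 * chr_len | pos >= 0.9 * chr_len]
  d2 <- chromosome_density(pkg, terminal, window_bp = 1e4)
  expect_gt(d2$telomere$ratio, 1)
  expect_equal(d2$telomere$interior_fraction, 0)
  # a single window reduces to the chromosome-wide fraction
  d3 <- chromosome_density(pkg, og_uniform, window_bp = chr_len)
  expect_equal(d3$windows$og_fraction[1], 50 / 200)
})

test_that("localization labels tabulate against the OG partition", {
  labels <- data.frame(gene_id = paste0("g", 1:10),
                       localization = rep(c("nucleus", "cytoplasm"), 5))
  tab <- localization_table(labels, og_ids = paste0("g", 1:4))
  expect_equal(sum(tab$n), 10)
  og_rows <- tab[tab$class == "OG", ]
  expect_equal(sum(og_rows$percent_of_class), 100)
})
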