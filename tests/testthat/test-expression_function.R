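test_that("FPKM follows its formula and linearity", {
  counts <- matrix(c(10L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  lens <- c(g1 = 1000, g2 = 500)
  f <- fpkm(counts, lens, totals = 1e6)
  expect_equal(f["g1", 1], 10)
  expect_equal(f["g2", 1], 0)
  f2 <- fpkm(counts, lens, totals = 2e6)
  expect_equal(f2["g1", 1], 5)
  expect_error(fpkm(counts, c(g1 = 0, g2 = 500), totals = 1e6), "positive")
})

test_that("expressed flags respect the threshold boundary and the rule", {
  fl_any <- expressed_flags(matrix(c(0.019, 0.021), 1, 2,
                                   dimnames = list("g", NULL)))
  expect_true(fl_any[["g"]])
  fl_one <- expressed_flags(matrix(c(0.019, 0.019), 1, 2,
                                   dimnames = list("g", NULL)))
  expect_false(fl_one[["g"]])
  fl_mean <- expressed_flags(matrix(c(0.001, 0.3), 1, 2,
                                    dimnames = list("g", NULL)),
                             rule = "mean")
  expect_true(fl_mean[["g"]])
})

test_that("SPM is the profile cosine and scale-invariant", {
  r <- spm(c(t1 = 5, t2 = 0, t3 = 0, t4 = 0, t5 = 0))
  expect_equal(unname(r$spm["t1"]), 1)
  expect_identical(r$specific_tissue, "t1")
  r2 <- spm(c(a = 1, b = 1))
  expect_equal(unname(r2$spm), rep(1 / sqrt(2), 2), tolerance = 1e-12)
  expect_identical(r2$specific_tissue, NA_character_)
  r3 <- spm(c(a = 9, b = 1, c = 1, d = 1, e = 1))
  expect_equal(r3$max_spm, 9 / sqrt(85), tolerance = 1e-12)
  expect_identical(r3$specific_tissue, "a")
  x <- c(a = 3, b = 7, c = 1)
  expect_equal(spm(x)$spm, spm(10 * x)$spm, tolerance = 1e-12)
  expect_true(is.na(spm(c(a = 0, b = 0))$max_spm))
  # sum of squared SPM equals 1 (cosine property)
  expect_equal(sum(spm(x)$spm^2), 1, tolerance = 1e-12)
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.2)), c(0.03, 0.03, 0.2))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  set.seed(81)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
})

test_that("DE screen estimates fold changes and respects its thresholds", {
  set.seed(82)
  n <- 500
  design <- data.frame(sample = paste0("s", 1:6),
                       tissue = rep(c("a", "b"), each = 3))
  mu <- matrix(rep(stats::rlnorm(n, log(200), 0.8), 6), n, 6)
  de_idx <- 1:40
  mu[de_idx, 4:6] <- mu[de_idx, 4:6] * 8   # log2fc = 3
  counts <- matrix(stats::rnbinom(n * 6, mu = mu, size = 20), n, 6,
                   dimnames = list(sprintf("g%03d", 1:n), design$sample))
  res <- de_screen(counts, design, c("a", "b"))
  expect_identical(res$is_de, res$fdr < 0.05 & abs(res$log2fc) > 1)
  expect_gte(mean(res$is_de[de_idx]), 0.9)
  expect_lte(mean(res$is_de[-de_idx]), 0.02)
  expect_equal(median(res$log2fc[de_idx]), 3, tolerance = 0.1)
  bad <- counts; bad[, design$tissue == "a"] <- 0L
  expect_error(de_screen(bad, design, c("a", "b")), "all-zero")
})

test_that("high-count fold changes are barely shrunk by the pseudocount", {
  design <- data.frame(sample = paste0("s", 1:4),
                       tissue = rep(c("a", "b"), each = 2))
  # a stable background so size factors reflect depth, not the DE gene
  set.seed(88)
  bg <- matrix(rep(round(stats::rlnorm(60, log(300), 0.5)), 4), 60, 4)
  counts <- rbind(matrix(c(1000L, 1000L, 250L, 250L), 1, 4), bg)
  dimnames(counts) <- list(c("g1", paste0("bg", 1:60)), design$sample)
  res <- de_screen(counts, design, c("a", "b"))
  expect_equal(res$log2fc[1], -2, tolerance = 0.03)
})

test_that("fuzzy c-means degenerate and symmetric cases", {
  set.seed(83)
  x <- matrix(rnorm(40), 10, 4, dimnames = list(paste0("g", 1:10), NULL))
  one <- fuzzy_cmeans(x, c = 1, seed = 1)
  expect_true(all(abs(one$membership - 1) < 1e-12))
  # a point equidistant from two symmetric centers gets (0.5, 0.5)
  prof <- rbind(a = c(1, 0), b = c(-1, 0), mid = c(0, 1e-6))
  r <- fuzzy_cmeans(rbind(prof, prof + 1e-9), c = 2, seed = 2,
                    standardize = FALSE)
  mid_row <- which(rownames(r$membership) == "mid")[1]
  expect_equal(unname(r$membership[mid_row, ]), c(0.5, 0.5),
               tolerance = 0.05)
})

test_that("fuzzy c-means separates planted trends and matches e1071", {
  skip_if_not_installed("e1071")
  set.seed(84)
  stages <- 6
  up <- t(replicate(60, seq(-1, 1, length.out = stages) +
                      rnorm(stages, 0, 0.1)))
  down <- t(replicate(60, seq(1, -1, length.out = stages) +
                        rnorm(stages, 0, 0.1)))
  prof <- rbind(up, down)
  rownames(prof) <- sprintf("t%03d", 1:120)
  r <- fuzzy_cmeans(prof, c = 2, seed = 3)
  # objective is non-increasing across iterations
  expect_true(all(diff(r$objective) <= 1e-8))
  truth <- rep(1:2, each = 60)
  agree <- max(mean(r$cluster == truth), mean(r$cluster == 3 - truth))
  expect_gte(agree, 0.98)
  # independent route: e1071's implementation on the same standardized data
  z <- t(scale(t(prof)))
  set.seed(5)
  cm <- e1071::cmeans(z, centers = 2, m = 2)
  agree_pkgs <- max(mean(r$cluster == cm$cluster),
                    mean(r$cluster == 3 - cm$cluster))
  expect_gte(agree_pkgs, 0.98)
  expect_equal(unname(rowSums(r$membership)), rep(1, 120),
               tolerance = 1e-9)
})

test_that("module detection recovers planted co-expression blocks", {
  set.seed(85)
  n_samp <- 12
  latent1 <- rnorm(n_samp); latent2 <- rnorm(n_samp)
  block <- function(latent, n) vapply(seq_len(n), function(i)
    latent + rnorm(n_samp, 0, 0.35), numeric(n_samp))
  expr <- cbind(block(latent1, 40), block(latent2, 40))
  colnames(expr) <- sprintf("g%03d", 1:80)
  rownames(expr) <- sprintf("s%02d", 1:n_samp)
  mods <- coexpression_modules(expr, beta = 6, min_module_size = 30)
  asg <- mods$assignments
  expect_true(all(table(asg$module[asg$module != "unassigned"]) >= 30))
  truth <- rep(c("A", "B"), each = 40)
  tab <- table(asg$module, truth)
  # each planted block dominated by one detected module
  purity <- sum(apply(tab, 2, max)) / sum(tab)
  expect_gte(purity, 0.95)
  # identical profiles give MM = 1
  same <- matrix(rep(latent1, 60), n_samp, 60) +
    matrix(rnorm(n_samp * 60, 0, 1e-6), n_samp)
  colnames(same) <- paste0("h", 1:60)
  m2 <- coexpression_modules(same, beta = 6, min_module_size = 30)
  expect_true(all(abs(m2$assignments$MM) > 0.999))
})

test_that("eigengenes maximize explained module variance", {
  set.seed(86)
  expr <- matrix(rnorm(10 * 35), 10, 35,
                 dimnames = list(paste0("s", 1:10), paste0("g", 1:35)))
  labels <- setNames(rep("M1", 35), colnames(expr))
  eig <- orphanforge:::module_eigengenes(expr, labels)
  z <- scale(expr)
  # explained variance of the eigengene equals the top eigenvalue share
  ev <- eigen(crossprod(z), symmetric = TRUE)$values
  expl <- sum((t(z) %*% eig[, 1])^2)
  expect_equal(expl, ev[1], tolerance = 1e-6)
})

test_that("module-trait correlation finds the driving trait and hub rules", {
  set.seed(87)
  n_samp <- 12
  trait <- rep(c(1, 0), each = n_samp / 2)
  latent <- trait * 2 + rnorm(n_samp, 0, 0.1)
  noise_lat <- rnorm(n_samp)
  expr <- cbind(vapply(1:40, function(i) latent + rnorm(n_samp, 0, 0.2),
                       numeric(n_samp)),
                vapply(1:40, function(i) noise_lat + rnorm(n_samp, 0, 0.2),
                       numeric(n_samp)))
  colnames(expr) <- paste0("g", 1:80)
  rownames(expr) <- paste0("s", 1:n_samp)
  mods <- coexpression_modules(expr, beta = 6, min_module_size = 30)
  traits <- cbind(driver = trait, junk = rnorm(n_samp))
  rownames(traits) <- rownames(expr)
  mt <- module_trait_and_hubs(mods, expr, traits)
  # the module holding genes 1..40 correlates best with the driver trait
  mod1 <- mods$assignments$module[1]
  sub <- mt$module_trait[mt$module_trait$module == mod1, ]
  expect_identical(sub$trait[which.max(abs(sub$r))], "driver")
  # the hub flag is exactly the MM/GS conjunction (boundary cases like
  # MM 0.96 with GS 0.80 stay out)
  expect_identical(mt$hubs$is_hub,
                   mt$hubs$MM > 0.95 & mt$hubs$GS > 0.85)
})

test_that("hypergeometric enrichment matches the combinatorial count", {
  universe <- paste0("u", 1:20)
  term_map <- data.frame(term_id = "T1", gene_id = paste0("u", 1:5))
  res <- enrichment(paste0("u", 1:5), universe, term_map)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  # selected = universe: every term has p = 1
  res_all <- enrichment(universe, universe, term_map)
  expect_equal(res_all$p_value, 1)
  # zero overlap of a small term: p near 1
  res0 <- enrichment(paste0("u", 6:10), universe, term_map)
  expect_gt(res0$p_value, 0.2)
  expect_error(enrichment(c("zzz"), universe, term_map))
})
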