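# Expression-based function inference: FPKM, expressed-gene calls, a
# negative-binomial DE screen, SPM tissue specificity, fuzzy c-means trend
# clustering, weighted co-expression modules and hypergeometric enrichment.

#' FPKM normalization
#'
#' fpkm[g, s] = counts[g, s] * 1e9 / (length_bp[g] * total[s]).
#'
#' @param counts genes x samples integer matrix
#' @param gene_lengths named vector of gene lengths in bp (> 0)
#' @param totals per-sample totals; defaults to column sums of `counts`
#' @return FPKM matrix with the dimensions of `counts`
#' @export
fpkm <- function(counts, gene_lengths, totals = colSums(counts)) {
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(is.na(gene_lengths)) || any(gene_lengths <= 0))
    stop("every gene needs a positive length")
  if (any(totals <= 0)) stop("per-sample totals must be positive")
  sweep(sweep(counts * 1e9, 1L, gene_lengths, "/"), 2L, totals, "/")
}

#' Expressed-gene flags
#'
#' A gene counts as expressed when its FPKM exceeds `threshold` in at least
#' one sample (`rule = "any"`), or on average (`rule = "mean"`).
#'
#' @param fpkm_mat FPKM matrix from [fpkm()]
#' @param threshold expression floor (default 0.02)
#' @param rule aggregation rule across samples
#' @return named logical vector over genes
#' @export
expressed_flags <- function(fpkm_mat, threshold = 0.02,
                            rule = c("any", "mean")) {
  rule <- match.arg(rule)
  v <- if (rule == "any") apply(fpkm_mat, 1L, max)
       else rowMeans(fpkm_mat)
  stats::setNames(v > threshold, rownames(fpkm_mat))
}

#' SPM tissue-specificity profile
#'
#' SPM_i = x_i / sqrt(sum_j x_j^2): the cosine of the mean-expression
#' profile against the unit vector of tissue i. A gene is tissue-specific
#' when its maximal SPM reaches `threshold`.
#'
#' @param x non-negative per-tissue mean expression vector (named)
#' @param threshold specificity call threshold (default 0.9)
#' @return list: spm (vector), specific_tissue (name or NA), max_spm
#' @export
spm <- function(x, threshold = 0.9) {
  if (any(x < 0)) stop("negative expression")
  norm <- sqrt(sum(x^2))
  if (norm == 0) return(list(spm = NULL, specific_tissue = NA_character_,
                             max_spm = NA_real_))
  s <- x / norm
  top <- which.max(s)
  list(spm = s,
       specific_tissue = if (s[top] >= threshold) names(x)[top]
                         else NA_character_,
       max_spm = unname(s[top]))
}

#' Per-tissue mean expression and SPM table for a whole matrix
#'
#' @param fpkm_mat FPKM matrix
#' @param design data.frame with columns sample, tissue
#' @param threshold SPM specificity threshold (default 0.9)
#' @return data.frame: gene_id, per-tissue SPM columns, max_spm,
#'   specific_tissue (all-zero genes are skipped)
#' @export
spm_table <- function(fpkm_mat, design, threshold = 0.9) {
  stopifnot(all(colnames(fpkm_mat) %in% design$sample))
  tis <- unique(design$tissue)
  means <- vapply(tis, function(t) {
    cols <- design$sample[design$tissue == t]
    rowMeans(fpkm_mat[, cols, drop = FALSE])
  }, numeric(nrow(fpkm_mat)))
  keep <- rowSums(means) > 0
  out <- lapply(which(keep), function(i) {
    r <- spm(means[i, ], threshold)
    c(list(gene_id = rownames(fpkm_mat)[i]),
      as.list(stats::setNames(r$spm, paste0("spm_", tis))),
      list(max_spm = r$max_spm, specific_tissue = r$specific_tissue))
  })
  df <- do.call(rbind, lapply(out, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(df) <- NULL
  df
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]).
#'
#' @param p p-values in [0, 1]
#' @return adjusted values, each >= the raw p
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Negative-binomial differential-expression screen
#'
#' A lightweight DE stand-in: median-of-ratios size factors, log2 fold
#' change of normalized means with pseudocount 1, a per-gene Wald test with
#' pooled method-of-moments NB dispersion, and BH adjustment. A gene is
#' called DE at `fdr < alpha` and `|log2fc| > lfc_cutoff`.
#'
#' @param counts genes x samples matrix
#' @param design data.frame with columns sample, tissue (or condition)
#' @param contrast length-2 character: (reference, treatment) tissue levels
#' @param alpha FDR threshold (default 0.05)
#' @param lfc_cutoff absolute log2 fold-change threshold (default 1)
#' @return data.frame: gene_id, base_mean, log2fc, p_value, fdr, is_de
#' @export
de_screen <- function(counts, design, contrast, alpha = 0.05,
                      lfc_cutoff = 1) {
  stopifnot(length(contrast) == 2L)
  cond <- design$tissue %||% design$condition
  sel <- design$sample[cond %in% contrast]
  if (length(sel) < 4L) stop("need >= 2 replicates per condition")
  cnt <- counts[, sel, drop = FALSE]
  grp <- cond[match(sel, design$sample)]
  if (any(tapply(colSums(cnt), grp, max) == 0))
    stop("one condition has all-zero libraries")
  # median-of-ratios size factors over genes expressed everywhere
  logs <- log(cnt)
  ref <- rowMeans(logs)
  usable <- is.finite(ref)
  sf <- apply(cnt, 2L, function(col)
    exp(stats::median(log(col[usable]) - ref[usable], na.rm = TRUE)))
  norm <- sweep(cnt, 2L, sf, "/")
  a_cols <- grp == contrast[1L]; b_cols <- grp == contrast[2L]
  na <- sum(a_cols); nb <- sum(b_cols)
  mean_a <- rowMeans(norm[, a_cols, drop = FALSE])
  mean_b <- rowMeans(norm[, b_cols, drop = FALSE])
  log2fc <- log2((mean_b + 1) / (mean_a + 1))
  # pooled method-of-moments dispersion
  var_a <- apply(norm[, a_cols, drop = FALSE], 1L, stats::var)
  var_b <- apply(norm[, b_cols, drop = FALSE], 1L, stats::var)
  disp_g <- ((var_a - mean_a) / pmax(mean_a, 1e-8)^2 +
               (var_b - mean_b) / pmax(mean_b, 1e-8)^2) / 2
  expressed <- mean_a + mean_b > 1
  disp <- max(mean(pmax(disp_g[expressed], 0), na.rm = TRUE), 1e-8)
  # Wald test on the log2 ratio (delta method, NB variance mu + disp*mu^2)
  se2 <- (mean_a + disp * mean_a^2) / (na * pmax(mean_a + 1, 1)^2) +
    (mean_b + disp * mean_b^2) / (nb * pmax(mean_b + 1, 1)^2)
  se <- sqrt(se2) / log(2)
  z <- ifelse(se > 0, log2fc / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  fdr <- bh_adjust(p)
  data.frame(gene_id = rownames(counts), base_mean = (mean_a + mean_b) / 2,
             log2fc = log2fc, p_value = p, fdr = fdr,
             is_de = fdr < alpha & abs(log2fc) > lfc_cutoff,
             stringsAsFactors = FALSE)
}

#' Fuzzy c-means clustering of expression trends
#'
#' Bezdek alternating optimization with fuzzifier `m`: memberships
#' u_ij = 1 / sum_k (d_ij / d_kj)^(2/(m-1)), centers as membership^m
#' weighted means. Profiles are z-standardized per gene first (constant
#' profiles are dropped). The objective sum u^m d^2 is verified
#' non-increasing at every iteration; convergence is declared when the
#' largest membership change falls below `tol`.
#'
#' @param profiles genes x stages matrix
#' @param c number of clusters
#' @param m fuzzifier (default 2)
#' @param tol convergence tolerance on memberships (default 1e-6)
#' @param seed RNG seed for center initialization
#' @param max_iter iteration cap
#' @param membership_cutoff screening threshold (default 0.6)
#' @param standardize z-standardize rows first (default TRUE)
#' @return list of class `fuzzy_clustering`: centers, membership (rows sum
#'   to 1), cluster (argmax), screened (named list of gene sets with
#'   membership > cutoff), objective trace
#' @export
fuzzy_cmeans <- function(profiles, c, m = 2, tol = 1e-6, seed = 1L,
                         max_iter = 300L, membership_cutoff = 0.6,
                         standardize = TRUE) {
  stopifnot(c >= 1L, nrow(profiles) >= c)
  x <- as.matrix(profiles)
  if (standardize) {
    sds <- apply(x, 1L, stats::sd)
    keep <- sds > 0
    x <- (x[keep, , drop = FALSE] - rowMeans(x[keep, , drop = FALSE])) /
      sds[keep]
  }
  n <- nrow(x)
  if (n < c) stop("fewer usable profiles than clusters")
  set.seed(seed)
  for (attempt in 1:5) {
    centers <- x[sample(n, c), , drop = FALSE]
    if (nrow(unique(centers)) == c) break
  }
  if (nrow(unique(centers)) < c) stop("could not seed distinct centers")
  u_old <- matrix(0, n, c)
  objective <- numeric()
  for (iter in seq_len(max_iter)) {
    d2 <- vapply(seq_len(c), function(k)
      rowSums(sweep(x, 2L, centers[k, ], "-")^2), numeric(n))
    d2 <- pmax(d2, 1e-12)
    pow <- d2^(-1 / (m - 1))
    u <- pow / rowSums(pow)
    obj <- sum(u^m * d2)
    if (length(objective) && obj > utils::tail(objective, 1L) + 1e-8)
      stop("fuzzy c-means objective increased; numerical failure")
    objective <- c(objective, obj)
    um <- u^m
    centers <- t(um) %*% x / colSums(um)
    delta <- max(abs(u - u_old))
    u_old <- u
    if (delta < tol) break
  }
  rownames(u) <- rownames(x)
  cluster <- apply(u, 1L, which.max)
  screened <- lapply(seq_len(c), function(k)
    rownames(x)[u[, k] > membership_cutoff])
  names(screened) <- paste0("cluster_", seq_len(c))
  structure(list(centers = centers, membership = u, cluster = cluster,
                 screened = screened, objective = objective,
                 iterations = length(objective)),
            class = "fuzzy_clustering")
}

#' @export
print.fuzzy_clustering <- function(x, ...) {
  cat(sprintf("<fuzzy_clustering> %d genes x %d clusters, %d iterations\n",
              nrow(x$membership), ncol(x$membership), x$iterations))
  invisible(x)
}

#' Soft-threshold selection for the co-expression network
#'
#' Picks the smallest integer power in `powers` whose connectivity
#' distribution fits a scale-free law with R^2 >= `target_r2` (log-log
#' regression over connectivity bins, negative slope required); falls back
#' to `fallback` when none qualifies.
#'
#' @param expr samples x genes matrix (genes as columns)
#' @param powers candidate powers (default 1:20)
#' @param target_r2 scale-free fit threshold (default 0.8)
#' @param fallback power when no candidate fits (default 6)
#' @return list: beta, fit (power, r_squared, slope per candidate)
#' @export
pick_soft_threshold <- function(expr, powers = 1:20, target_r2 = 0.8,
                                fallback = 6L) {
  cors <- abs(stats::cor(expr))
  diag(cors) <- 0
  fit <- data.frame(power = powers, r_squared = NA_real_, slope = NA_real_)
  beta <- NA_integer_
  for (i in seq_along(powers)) {
    k <- colSums(cors^powers[i])
    brk <- unique(stats::quantile(k, probs = seq(0, 1, length.out = 11)))
    if (length(brk) < 3L) next
    bins <- cut(k, brk, include.lowest = TRUE)
    dk <- tapply(k, bins, mean)
    pk <- as.numeric(table(bins)) / length(k)
    ok <- pk > 0 & !is.na(dk) & dk > 0
    if (sum(ok) < 3L) next
    lm_fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
    r2 <- summary(lm_fit)$r.squared
    sl <- stats::coef(lm_fit)[2L]
    fit$r_squared[i] <- r2
    fit$slope[i] <- sl
    if (is.na(beta) && r2 >= target_r2 && sl < 0) beta <- powers[i]
  }
  list(beta = if (is.na(beta)) as.integer(fallback) else as.integer(beta),
       fit = fit)
}

#' Weighted co-expression modules
#'
#' Builds a signed-magnitude adjacency |cor|^beta, converts it to the
#' topological overlap measure (TOM), clusters genes by average-linkage
#' hierarchical clustering on 1 - TOM with a fixed-height cut, merges
#' clusters smaller than `min_module_size` into the nearest module by
#' eigengene correlation (or "unassigned" when none correlates), and
#' computes module eigengenes (first principal component of the module's
#' standardized expression, sign-oriented to the module mean).
#'
#' @param expr samples x genes matrix
#' @param beta soft-threshold power; NULL selects via
#'   [pick_soft_threshold()]
#' @param min_module_size minimum genes per module (default 30)
#' @param cut_height fixed cut height on the 1 - TOM dendrogram
#'   (default 0.8)
#' @param merge_cor minimum eigengene correlation for merging a small
#'   cluster (default 0.3)
#' @return list of class `coexpression_modules`: assignments (gene_id,
#'   module, MM), eigengenes (samples x modules), beta, module sizes
#' @export
coexpression_modules <- function(expr, beta = NULL, min_module_size = 30L,
                                 cut_height = 0.8, merge_cor = 0.3) {
  stopifnot(nrow(expr) >= 4L, ncol(expr) >= 2L * min_module_size)
  sds <- apply(expr, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant gene(s)")
    expr <- expr[, sds > 0, drop = FALSE]
  }
  if (is.null(beta)) beta <- pick_soft_threshold(expr)$beta
  adj <- abs(stats::cor(expr))^beta
  diag(adj) <- 0
  k <- colSums(adj)
  num <- adj %*% adj + adj
  den <- outer(k, k, pmin) + 1 - adj
  tom <- num / den
  diag(tom) <- 1
  d <- stats::as.dist(1 - tom)
  hc <- stats::hclust(d, method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_module_size]
  labels <- ifelse(cl %in% as.integer(big),
                   paste0("M", match(cl, as.integer(big))), "unassigned")
  names(labels) <- colnames(expr)
  eig <- module_eigengenes(expr, labels)
  # merge small clusters into the nearest module (by eigengene correlation)
  if (length(big) && any(labels == "unassigned")) {
    for (g in names(labels)[labels == "unassigned"]) {
      cors <- vapply(colnames(eig), function(mod)
        stats::cor(expr[, g], eig[, mod]), 0)
      if (max(abs(cors)) >= merge_cor)
        labels[g] <- colnames(eig)[which.max(abs(cors))]
    }
    eig <- module_eigengenes(expr, labels)
  }
  mods <- setdiff(unique(labels), "unassigned")
  mm <- vapply(names(labels), function(g) {
    if (labels[[g]] == "unassigned") return(NA_real_)
    stats::cor(expr[, g], eig[, labels[[g]]])
  }, 0)
  structure(list(assignments = data.frame(gene_id = names(labels),
                                          module = unname(labels),
                                          MM = unname(mm),
                                          stringsAsFactors = FALSE),
                 eigengenes = eig, beta = beta,
                 sizes = table(labels[labels != "unassigned"])),
            class = "coexpression_modules")
}

module_eigengenes <- function(expr, labels) {
  mods <- setdiff(unique(labels), "unassigned")
  if (!length(mods)) stop("no module reached the minimum size")
  eig <- vapply(mods, function(mod) {
    sub <- scale(expr[, names(labels)[labels == mod], drop = FALSE])
    pc <- stats::prcomp(sub, center = FALSE, scale. = FALSE)$x[, 1L]
    if (stats::cor(pc, rowMeans(sub)) < 0) pc <- -pc
    pc / sqrt(sum(pc^2))
  }, numeric(nrow(expr)))
  colnames(eig) <- mods
  rownames(eig) <- rownames(expr)
  eig
}

#' @export
print.coexpression_modules <- function(x, ...) {
  cat(sprintf("<coexpression_modules> beta=%d, %d modules (+%d unassigned)\n",
              x$beta, ncol(x$eigengenes),
              sum(x$assignments$module == "unassigned")))
  print(x$sizes)
  invisible(x)
}

#' Module-trait correlations and hub genes
#'
#' Correlates each module eigengene with each trait vector (Pearson, with
#' a correlation-test p-value) and flags hub genes by module membership
#' MM > `mm_cutoff` and gene significance GS > `gs_cutoff` against the
#' module's best-correlated trait.
#'
#' @param modules a `coexpression_modules` object
#' @param expr the samples x genes matrix used to build the modules
#' @param traits samples x traits numeric matrix (e.g. tissue indicators)
#' @param mm_cutoff,gs_cutoff hub thresholds (defaults 0.95 / 0.85)
#' @return list: `module_trait` (module, trait, r, p_value),
#'   `hubs` (gene_id, module, MM, GS, is_hub)
#' @export
module_trait_and_hubs <- function(modules, expr, traits,
                                  mm_cutoff = 0.95, gs_cutoff = 0.85) {
  traits <- as.matrix(traits)
  stopifnot(nrow(traits) == nrow(modules$eigengenes))
  const <- apply(traits, 2L, stats::sd) == 0
  if (any(const)) {
    warning("dropping constant trait(s): ",
            paste(colnames(traits)[const], collapse = ", "))
    traits <- traits[, !const, drop = FALSE]
  }
  mt <- expand.grid(module = colnames(modules$eigengenes),
                    trait = colnames(traits), stringsAsFactors = FALSE)
  mt$r <- mapply(function(mod, tr)
    stats::cor(modules$eigengenes[, mod], traits[, tr]),
    mt$module, mt$trait)
  mt$p_value <- mapply(function(mod, tr)
    stats::cor.test(modules$eigengenes[, mod], traits[, tr])$p.value,
    mt$module, mt$trait)
  asg <- modules$assignments[modules$assignments$module != "unassigned", ]
  best_trait <- vapply(unique(asg$module), function(mod) {
    sub <- mt[mt$module == mod, ]
    sub$trait[which.max(abs(sub$r))]
  }, "")
  gs <- vapply(seq_len(nrow(asg)), function(i) {
    tr <- best_trait[[asg$module[i]]]
    stats::cor(expr[, asg$gene_id[i]], traits[, tr])
  }, 0)
  hubs <- data.frame(gene_id = asg$gene_id, module = asg$module,
                     MM = asg$MM, GS = gs,
                     is_hub = asg$MM > mm_cutoff & gs > gs_cutoff,
                     stringsAsFactors = FALSE)
  list(module_trait = mt, hubs = hubs)
}

#' Hypergeometric term enrichment
#'
#' Upper-tail hypergeometric probability of observing at least the overlap
#' between the selected set and each term, BH-adjusted across terms. Terms
#' with no universe genes are skipped.
#'
#' @param selected selected gene ids (must be a subset of `universe`)
#' @param universe background gene ids
#' @param term_map data.frame with columns term_id, gene_id
#' @param alpha significance threshold on the raw p (default 0.05)
#' @return data.frame: term_id, term_size, overlap, expected, p_value, fdr,
#'   significant
#' @export
enrichment <- function(selected, universe, term_map, alpha = 0.05) {
  stopifnot(all(selected %in% universe))
  term_map <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  terms <- split(term_map$gene_id, term_map$term_id)
  if (!length(terms))
    return(data.frame(term_id = character(), term_size = integer(),
                      overlap = integer(), expected = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  N <- length(unique(universe)); n <- length(unique(selected))
  rows <- lapply(names(terms), function(tid) {
    tg <- unique(terms[[tid]])
    K <- length(tg)
    ov <- length(intersect(tg, selected))
    p <- stats::phyper(ov - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, term_size = K, overlap = ov,
               expected = n * K / N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p_value)
  out$significant <- out$p_value < alpha
  out[order(out$p_value), ]
}
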