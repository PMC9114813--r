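# Structural statistics and OG-vs-NOG contrasts, plus chromosome
# distribution summaries.

#' Structural statistics of one gene model
#'
#' GC content is computed on the CDS; exon lengths are genomic; the protein
#' length excludes the stop codon.
#'
#' @param gene a [gene_model()]
#' @return one-row data.frame: gene_id, protein_length, exon_count,
#'   mean_exon_length, gc_content, isoelectric_point
#' @export
gene_stats <- function(gene) {
  if (is.null(gene$cds_seq) || !nzchar(gene$cds_seq))
    stop("gene ", gene$gene_id, " has no CDS")
  nt <- strsplit(gene$cds_seq, "")[[1]]
  gc <- sum(nt %in% c("G", "C")) / length(nt)
  exon_len <- gene$exons[, 2L] - gene$exons[, 1L] + 1L
  prot <- sub("\\*$", "", gene$protein_seq)
  data.frame(gene_id = gene$gene_id,
             protein_length = nchar(prot),
             exon_count = nrow(gene$exons),
             mean_exon_length = mean(exon_len),
             gc_content = gc,
             isoelectric_point = isoelectric_point(prot),
             stringsAsFactors = FALSE)
}

#' Structural statistics for a whole package with OG/NOG labels
#'
#' @param pkg a [genome_package()]
#' @param og_ids orphan gene ids
#' @return data.frame of per-gene stats plus a `class` column (OG/NOG)
#' @export
gene_stats_table <- function(pkg, og_ids) {
  out <- do.call(rbind, lapply(pkg$genes, gene_stats))
  out$class <- ifelse(out$gene_id %in% og_ids, "OG", "NOG")
  rownames(out) <- NULL
  out
}

# EMBOSS pK set; only the OG-vs-NOG contrast matters downstream, so the
# exact table is configurable
EMBOSS_PK <- c(Nterm = 8.6, Cterm = 3.6, K = 10.8, R = 12.5, H = 6.5,
               D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

#' Isoelectric point of a peptide
#'
#' Net charge at pH x sums positive contributions 10^pK/(10^x + 10^pK) over
#' the N-terminus, K, R and H, minus negative contributions
#' 10^x/(10^x + 10^pK) over the C-terminus, D, E, C and Y. The pI is the
#' bisection root of the charge on [0, 14] to |charge| < 1e-4.
#'
#' @param protein amino-acid string; non-standard residues are ignored with
#'   a warning
#' @param pk named pK set (defaults to the EMBOSS values)
#' @return pI in pH units
#' @export
isoelectric_point <- function(protein, pk = EMBOSS_PK) {
  aa <- strsplit(toupper(protein), "")[[1]]
  if (any(!aa %in% AA20)) {
    warning("ignoring ", sum(!aa %in% AA20), " non-standard residue(s)")
    aa <- aa[aa %in% AA20]
  }
  if (!length(aa)) stop("no standard residues in peptide")
  n_pos <- c(Nterm = 1, K = sum(aa == "K"), R = sum(aa == "R"),
             H = sum(aa == "H"))
  n_neg <- c(Cterm = 1, D = sum(aa == "D"), E = sum(aa == "E"),
             C = sum(aa == "C"), Y = sum(aa == "Y"))
  charge <- function(ph) {
    pos <- sum(n_pos * 10^pk[names(n_pos)] / (10^ph + 10^pk[names(n_pos)]))
    neg <- sum(n_neg * 10^ph / (10^ph + 10^pk[names(n_neg)]))
    pos - neg
  }
  lo <- 0; hi <- 14
  if (charge(lo) < 0 || charge(hi) > 0)
    stop("charge does not change sign on [0, 14]")
  repeat {
    mid <- (lo + hi) / 2
    cm <- charge(mid)
    if (abs(cm) < 1e-4 || hi - lo < 1e-10) return(mid)
    if (cm > 0) lo <- mid else hi <- mid
  }
}

#' Wilcoxon rank-sum contrast between two groups
#'
#' Exact two-sided p-value by enumeration for small untied samples
#' (total n <= 10); otherwise the normal approximation with midrank ties,
#' tie-corrected variance and continuity correction. Constant pooled data
#' returns p = 1.
#'
#' @param x,y numeric vectors (each length >= 2)
#' @param metric label carried through to the output
#' @param method "auto" (exact for total n <= 10 without ties, else
#'   normal), or force "exact" / "normal"
#' @return one-row data.frame: metric, n_x, n_y, median_x, median_y,
#'   W (rank-sum U statistic of `x`), p_value, direction
#' @export
wilcoxon_rank_sum <- function(x, y, metric = "metric",
                              method = c("auto", "exact", "normal")) {
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  method <- match.arg(method)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    w <- length(x) * length(y) / 2
    p <- 1
  } else {
    exact <- switch(method,
                    auto = length(pooled) <= 10L && !anyDuplicated(pooled),
                    exact = TRUE, normal = FALSE)
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = TRUE))
    w <- unname(wt$statistic)
    p <- min(1, wt$p.value)
  }
  data.frame(metric = metric, n_x = length(x), n_y = length(y),
             median_x = stats::median(x), median_y = stats::median(y),
             W = w, p_value = p,
             direction = if (stats::median(x) < stats::median(y)) "x<y"
                         else if (stats::median(x) > stats::median(y)) "x>y"
                         else "x=y",
             stringsAsFactors = FALSE)
}

#' OG-vs-NOG contrasts over all structural metrics
#'
#' @param stats_table output of [gene_stats_table()]
#' @return data.frame with one Wilcoxon contrast per metric (OG as `x`)
#' @export
structure_contrasts <- function(stats_table) {
  metrics <- c("protein_length", "exon_count", "mean_exon_length",
               "gc_content", "isoelectric_point")
  og <- stats_table[stats_table$class == "OG", ]
  nog <- stats_table[stats_table$class == "NOG", ]
  out <- do.call(rbind, lapply(metrics, function(m)
    wilcoxon_rank_sum(og[[m]], nog[[m]], metric = m)))
  rownames(out) <- NULL
  out
}

#' Windowed orphan-gene density along chromosomes
#'
#' Counts genes and orphans per fixed-width window and summarizes
#' telomere proximity: the mean orphan fraction in the terminal 10\% of
#' each chromosome (both arms) versus the interior, and their ratio.
#'
#' @param pkg a [genome_package()]
#' @param og_ids orphan gene ids
#' @param window_bp window width in bp (default 1e5)
#' @param terminal_frac chromosome fraction per arm counted as terminal
#'   (default 0.1)
#' @return list: `windows` (chrom, win_start, win_end, n_genes, n_og,
#'   og_fraction), `per_chromosome` (chrom, n_genes, n_og, og_percent),
#'   `telomere` (terminal_fraction, interior_fraction, ratio)
#' @export
chromosome_density <- function(pkg, og_ids, window_bp = 1e5,
                               terminal_frac = 0.1) {
  pos <- data.frame(
    gene_id = names(pkg$genes),
    chrom = vapply(pkg$genes, `[[`, "", "chromosome"),
    mid = vapply(pkg$genes, function(g) (g$start + g$end) / 2, 0),
    stringsAsFactors = FALSE)
  bad <- pos$mid > pkg$chromosome_lengths[pos$chrom]
  if (any(bad)) stop("gene beyond chromosome length: ", pos$gene_id[bad][1L])
  pos$is_og <- pos$gene_id %in% og_ids
  win_rows <- list(); per_chr <- list()
  term_genes <- 0L; term_og <- 0L; int_genes <- 0L; int_og <- 0L
  for (chrom in names(pkg$chromosome_lengths)) {
    len <- pkg$chromosome_lengths[[chrom]]
    p <- pos[pos$chrom == chrom, ]
    starts <- seq(1, len, by = window_bp)
    ends <- pmin(starts + window_bp - 1, len)
    n <- vapply(seq_along(starts), function(i)
      sum(p$mid >= starts[i] & p$mid <= ends[i]), 0L)
    nog_ <- vapply(seq_along(starts), function(i)
      sum(p$is_og & p$mid >= starts[i] & p$mid <= ends[i]), 0L)
    win_rows[[chrom]] <- data.frame(
      chrom = chrom, win_start = starts, win_end = ends,
      n_genes = n, n_og = nog_,
      og_fraction = ifelse(n > 0, nog_ / n, NA_real_),
      stringsAsFactors = FALSE)
    per_chr[[chrom]] <- data.frame(
      chrom = chrom, n_genes = nrow(p), n_og = sum(p$is_og),
      og_percent = if (nrow(p)) 100 * sum(p$is_og) / nrow(p) else NA_real_,
      stringsAsFactors = FALSE)
    cut_lo <- terminal_frac * len
    cut_hi <- (1 - terminal_frac) * len
    terminal <- p$mid <= cut_lo | p$mid >= cut_hi
    term_genes <- term_genes + sum(terminal)
    term_og <- term_og + sum(p$is_og & terminal)
    int_genes <- int_genes + sum(!terminal)
    int_og <- int_og + sum(p$is_og & !terminal)
  }
  tf <- if (term_genes > 0) term_og / term_genes else NA_real_
  inf_ <- if (int_genes > 0) int_og / int_genes else NA_real_
  list(windows = do.call(rbind, c(win_rows, make.row.names = FALSE)),
       per_chromosome = do.call(rbind, c(per_chr, make.row.names = FALSE)),
       telomere = list(terminal_fraction = tf, interior_fraction = inf_,
                       ratio = if (is.na(tf) || is.na(inf_) ||
                                   (tf == 0 && inf_ == 0)) NA_real_
                               else tf / inf_))
}

#' Tabulate precomputed subcellular-localization labels by gene class
#'
#' Localization prediction itself is an external concern; this summarizes a
#' supplied label table against the OG/NOG partition.
#'
#' @param labels data.frame with columns gene_id, localization
#' @param og_ids orphan gene ids
#' @return contingency data.frame: localization, class, n, percent_of_class
#' @export
localization_table <- function(labels, og_ids) {
  stopifnot(all(c("gene_id", "localization") %in% names(labels)))
  labels$class <- ifelse(labels$gene_id %in% og_ids, "OG", "NOG")
  tab <- as.data.frame(table(localization = labels$localization,
                             class = labels$class),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "n"
  totals <- tapply(tab$n, tab$class, sum)
  tab$percent_of_class <- 100 * tab$n / as.numeric(totals[tab$class])
  tab
}
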