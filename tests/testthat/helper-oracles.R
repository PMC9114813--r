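# Independent oracles used across the suite. These deliberately share no
# code with the package: plain quadratic DP for local alignment, direct
# pathway enumeration for NG86, labeling enumeration for the rank-sum test.

# brute-force affine-gap local alignment score (three-state DP, no
# traceback); gap of length L costs open + L * ext
sw_oracle_score <- function(a, b, scoring, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  NEG <- -1e18
  H <- matrix(0, m + 1, n + 1)
  X <- matrix(NEG, m + 1, n + 1)
  Y <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      X[i + 1, j + 1] <- max(H[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(H[i + 1, j] - open - ext, Y[i + 1, j] - ext)
      d <- H[i, j] + scoring[av[i], bv[j]]
      H[i + 1, j + 1] <- max(0, d, X[i + 1, j + 1], Y[i + 1, j + 1])
      best <- max(best, H[i + 1, j + 1])
    }
  }
  best
}

# NG86 oracle: recomputes everything from Biostrings::GENETIC_CODE with its
# own enumeration (site fractions per codon; pathway permutations via
# recursion over differing positions)
ng86_oracle <- function(cds_a, cds_b) {
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  stops <- names(code)[code == "*"]
  nts <- c("A", "C", "G", "T")
  syn_sites <- function(codon) {
    if (codon %in% stops) return(NA_real_)
    s <- 0
    for (p in 1:3) for (b in nts) {
      if (b == substr(codon, p, p)) next
      alt <- codon
      substr(alt, p, p) <- b
      if (!(alt %in% stops) && code[[alt]] == code[[codon]]) s <- s + 1 / 3
    }
    s
  }
  all_orders <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in all_orders(v[-i]))
        out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  pair_diffs <- function(ca, cb) {
    pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    counts <- list()
    for (ord in all_orders(pos)) {
      cur <- ca; sd <- 0; nd <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- cur
        substr(nxt, p, p) <- substr(cb, p, p)
        if (nxt %in% stops) { blocked <- TRUE; break }
        if (code[[nxt]] == code[[cur]]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (!blocked) counts[[length(counts) + 1L]] <- c(sd, nd)
    }
    if (!length(counts)) return(NULL)
    colMeans(do.call(rbind, counts))
  }
  ca <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  cb <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  keep <- !(ca %in% stops) & !(cb %in% stops) &
    grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  ca <- ca[keep]; cb <- cb[keep]
  S <- mean(c(sum(vapply(ca, syn_sites, 0)), sum(vapply(cb, syn_sites, 0))))
  N <- 3 * length(ca) - S
  sd <- 0; nd <- 0
  for (i in seq_along(ca)) {
    d <- pair_diffs(ca[i], cb[i])
    if (is.null(d)) next
    sd <- sd + d[1]; nd <- nd + d[2]
  }
  ps <- sd / S
  list(S = S, N = N, Sd = sd, Nd = nd, ps = ps,
       ks = if (ps < 0.75) -0.75 * log(1 - 4 / 3 * ps) else NA_real_)
}

# exact two-sided rank-sum p by enumeration of all labelings
wilcox_enum_oracle <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(length(pooled), m)
  ws <- apply(combs, 2L, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  p_le <- mean(ws <= obs)
  p_ge <- mean(ws >= obs)
  min(1, 2 * min(p_le, p_ge))
}

# exhaustive best chain over anchor subsets (for <= 14 anchors)
chain_oracle <- function(rank_a, rank_b, max_gap, orientation = 1) {
  n <- length(rank_a)
  rb <- orientation * rank_b
  best <- 0L
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (length(idx) <= best) next
    o <- order(rank_a[idx])
    ra <- rank_a[idx][o]; rr <- rb[idx][o]
    ok <- all(diff(ra) > 0) && all(diff(rr) > 0) &&
      all(diff(ra) <= max_gap) && all(diff(rr) <= max_gap)
    if (ok) best <- length(idx)
  }
  best
}

# small random sequences for fixtures
rand_protein <- function(n, alphabet = c("A","R","N","D","C","Q","E","G",
                                         "H","I","L","K","M","F","P","S",
                                         "T","W","Y","V")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rand_dna <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                              collapse = "")

# small genome package with two genes on one chromosome
toy_package <- function() {
  cds1 <- "ATGAAACCCGGGTTTTAA"
  cds2 <- "ATGCATGATCGATCGTAA"
  chr <- paste0(rand_dna(50), cds1, rand_dna(40),
                as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(cds2))), rand_dna(30))
  g1 <- gene_model("t1", "chrT", "+", 51L, 68L,
                   matrix(c(51L, 68L), 1L), cds1)
  g2s <- 51L + 18L + 40L
  g2 <- gene_model("t2", "chrT", "-", g2s, g2s + 17L,
                   matrix(c(g2s, g2s + 17L), 1L), cds2)
  genome_package("toy", c(chrT = chr), list(g1, g2))
}
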