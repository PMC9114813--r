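#' @useDynLib orphanforge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- sequence utilities -----------------------------------------------------

GENETIC_CODE_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
})

#' Reverse-complement a nucleotide string
#'
#' @param x nucleotide string (ACGTN, case-insensitive)
#' @return reverse complement, uppercase
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(x), "")[[1]]), collapse = ""))
}

#' Translate a coding sequence
#'
#' Standard genetic code. Translation stops at the first stop codon; a
#' trailing partial codon is dropped with a warning. Codons containing an
#' ambiguous base translate to `X` unless the ambiguity cannot change the
#' amino acid.
#'
#' @param cds nucleotide string, length >= 3
#' @param include_stop emit a `*` for the terminating stop codon
#' @return amino-acid string
#' @export
translate_cds <- function(cds, include_stop = FALSE) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n < 3L) stop("CDS shorter than one codon")
  if (n %% 3L != 0L) {
    warning("CDS length not a multiple of 3; trailing partial codon ignored")
    n <- n - (n %% 3L)
  }
  codons <- substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  aa <- GENETIC_CODE_TABLE[codons]
  aa[is.na(aa)] <- "X"
  stop_at <- which(aa == "*")
  if (length(stop_at))
    aa <- aa[seq_len(stop_at[1L] - if (include_stop) 0L else 1L)]
  paste(aa, collapse = "")
}

# ---- FASTA ------------------------------------------------------------------

#' Read a FASTA file into a named character vector
#'
#' Record order is preserved, sequences are uppercased, and duplicated
#' identifiers are rejected. The identifier is the header token up to the
#' first whitespace.
#'
#' @param path FASTA file
#' @return named character vector of sequences
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA parse error in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0L) stop("FASTA parse error in ", path, ": no records")
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicated FASTA ID: ", ids[duplicated(ids)][1L])
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs)))
    stop("FASTA parse error in ", path, ": empty sequence for ",
         ids[!nzchar(seqs)][1L])
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA (wrapped at 60 columns)
#'
#' @param seqs named character vector
#' @param path output file
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

# ---- gene models ------------------------------------------------------------

#' Construct a gene model
#'
#' Coordinates are 1-based inclusive on the genomic forward strand (GFF3
#' convention) everywhere in the package. Exons must be sorted and
#' non-overlapping in forward-strand order.
#'
#' @param gene_id gene identifier
#' @param chromosome chromosome name
#' @param strand "+" or "-"
#' @param start,end gene span
#' @param exons two-column matrix (start, end), forward-strand sorted
#' @param cds_seq spliced, strand-corrected coding sequence
#' @param protein_seq translation (stop stripped); computed when NULL
#' @return object of class `gene_model`
#' @export
gene_model <- function(gene_id, chromosome, strand, start, end, exons,
                       cds_seq, protein_seq = NULL) {
  stopifnot(strand %in% c("+", "-"), start <= end)
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) > 1L) {
    o <- order(exons[, 1L])
    exons <- exons[o, , drop = FALSE]
    if (any(exons[-1L, 1L] <= exons[-nrow(exons), 2L]))
      stop("overlapping exons in ", gene_id)
  }
  if (any(exons[, 1L] > exons[, 2L])) stop("exon start > end in ", gene_id)
  if (is.null(protein_seq)) protein_seq <- translate_cds(cds_seq)
  protein_seq <- sub("\\*$", "", protein_seq)
  structure(list(gene_id = gene_id, chromosome = chromosome, strand = strand,
                 start = as.integer(start), end = as.integer(end),
                 exons = exons, cds_seq = toupper(cds_seq),
                 protein_seq = protein_seq),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) exons=%d cds=%dnt protein=%daa\n",
              x$gene_id, x$chromosome, x$start, x$end, x$strand,
              nrow(x$exons), nchar(x$cds_seq), nchar(x$protein_seq)))
  invisible(x)
}

#' Assemble a genome package
#'
#' Bundles a species' genome sequences, gene models and TE library with
#' consistent coordinates. Every gene must lie on a known chromosome and
#' within its length.
#'
#' @param species_id species label (used to exclude self-hits in panels)
#' @param genome named character vector, chromosome -> sequence
#' @param genes list of [gene_model()] objects
#' @param te_library named character vector of TE nucleotide sequences
#' @return object of class `genome_package`
#' @export
genome_package <- function(species_id, genome, genes, te_library = character()) {
  lens <- nchar(genome)
  for (g in genes) {
    if (!g$chromosome %in% names(genome))
      stop("gene ", g$gene_id, " on unknown chromosome ", g$chromosome)
    if (g$end > lens[[g$chromosome]])
      stop("gene ", g$gene_id, " extends past end of ", g$chromosome)
  }
  names(genes) <- vapply(genes, `[[`, "", "gene_id")
  structure(list(species_id = species_id, genome = genome, genes = genes,
                 te_library = te_library, chromosome_lengths = lens),
            class = "genome_package")
}

#' @export
print.genome_package <- function(x, ...) {
  cat(sprintf("<genome_package> %s: %d chromosomes (%.1f kb), %d genes, %d TEs\n",
              x$species_id, length(x$genome), sum(x$chromosome_lengths) / 1e3,
              length(x$genes), length(x$te_library)))
  invisible(x)
}

#' Construct a reference database for the homology cascade
#'
#' @param name database label (reported as the eliminating stage)
#' @param kind "protein" or "nucleotide"
#' @param records named character vector of sequences
#' @param stage_rank integer order of this database in the panel
#' @return object of class `reference_db`
#' @export
reference_db <- function(name, kind = c("protein", "nucleotide"), records,
                         stage_rank = 1L) {
  kind <- match.arg(kind)
  if (length(records) == 0L) stop("reference_db '", name, "' has no records")
  structure(list(name = name, kind = kind, records = toupper(records),
                 stage_rank = as.integer(stage_rank),
                 cache = new.env(parent = emptyenv())),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> %s (%s, stage %d): %d records, %.0f residues\n",
              x$name, x$kind, x$stage_rank, length(x$records),
              sum(nchar(x$records))))
  invisible(x)
}

# ---- GFF3 -------------------------------------------------------------------

#' Read gene models from a GFF3 annotation
#'
#' Parses gene/mRNA/exon/CDS features (via \pkg{rtracklayer}) and assembles
#' one [gene_model()] per gene. When a gene carries several mRNAs the
#' representative with the longest total CDS is used. CDS segments are
#' spliced in transcription order and reverse-complemented for minus-strand
#' genes before translation.
#'
#' @param path GFF3 file
#' @param genome named character vector of chromosome sequences
#' @return list of `gene_model`
#' @export
read_gff3 <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "gff3")
  co <- as.data.frame(gr)[, c("seqnames", "start", "end", "strand")]
  df <- data.frame(chrom = as.character(co$seqnames),
                   start = co$start, end = co$end,
                   strand = as.character(co$strand),
                   type = as.character(gr$type),
                   id = if (is.null(gr$ID)) NA_character_ else as.character(gr$ID),
                   stringsAsFactors = FALSE)
  par <- gr$Parent
  df$parent <- if (is.null(par)) NA_character_ else
    vapply(as.list(par), function(p) if (length(p)) p[[1]] else NA_character_, "")

  genes <- df[df$type == "gene", , drop = FALSE]
  mrnas <- df[df$type == "mRNA", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  cdss  <- df[df$type == "CDS",  , drop = FALSE]
  if (nrow(genes) == 0L) stop("no gene features in ", path)

  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (!g$chrom %in% names(genome))
      stop("gene ", g$id, " on unknown chromosome ", g$chrom)
    if (g$end > nchar(genome[[g$chrom]]))
      stop("gene ", g$id, " extends past end of chromosome ", g$chrom)
    gm <- mrnas[!is.na(mrnas$parent) & mrnas$parent == g$id, , drop = FALSE]
    if (nrow(gm) == 0L) stop("gene ", g$id, " has no mRNA")
    # longest-CDS representative
    cds_len <- vapply(gm$id, function(mid) {
      seg <- cdss[cdss$parent == mid, , drop = FALSE]
      sum(seg$end - seg$start + 1L)
    }, 0L)
    mid <- gm$id[which.max(cds_len)]
    seg <- cdss[cdss$parent == mid, , drop = FALSE]
    if (nrow(seg) == 0L) stop("mRNA ", mid, " has no CDS")
    seg <- seg[order(seg$start), , drop = FALSE]
    if (max(seg$end) > nchar(genome[[g$chrom]]))
      stop("CDS of ", g$id, " extends past end of chromosome ", g$chrom)
    ex <- exons[exons$parent == mid, , drop = FALSE]
    if (nrow(ex) == 0L) ex <- seg # exon rows optional; fall back to CDS spans
    ex <- ex[order(ex$start), , drop = FALSE]
    cds_fwd <- paste(substring(genome[[g$chrom]], seg$start, seg$end),
                     collapse = "")
    cds <- if (g$strand == "-") revcomp(cds_fwd) else toupper(cds_fwd)
    out[[i]] <- gene_model(g$id, g$chrom, g$strand, g$start, g$end,
                           cbind(ex$start, ex$end), cds)
  }
  names(out) <- vapply(out, `[[`, "", "gene_id")
  out
}

#' Write gene models to a GFF3 file
#'
#' Emits gene/mRNA/exon/CDS rows (one mRNA per gene) in the 9-column GFF3
#' dialect that [read_gff3()] consumes.
#'
#' @param genes list of `gene_model`
#' @param path output file
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    row <- function(type, s, e, attrs)
      paste(g$chromosome, "orphanforge", type, s, e, ".", g$strand, ".",
            attrs, sep = "\t")
    mid <- paste0(g$gene_id, ".1")
    lines <- c(row("gene", g$start, g$end, paste0("ID=", g$gene_id)),
               row("mRNA", g$start, g$end,
                   paste0("ID=", mid, ";Parent=", g$gene_id)))
    for (j in seq_len(nrow(g$exons))) {
      lines <- c(lines,
                 row("exon", g$exons[j, 1L], g$exons[j, 2L],
                     paste0("ID=", mid, ".exon", j, ";Parent=", mid)),
                 row("CDS", g$exons[j, 1L], g$exons[j, 2L],
                     paste0("ID=", mid, ".cds;Parent=", mid)))
    }
    writeLines(lines, con)
  }
  invisible(path)
}
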