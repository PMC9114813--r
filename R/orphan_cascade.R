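# Sequential homology-filter cascade: a gene is eliminated at the first
# reference database in stage order where it has at least one significant
# hit (E <= cutoff, inclusive); survivors of every stage are orphan genes.

#' Run the homology-filter cascade over an ordered database panel
#'
#' Each gene's protein is searched against the panel databases in
#' `stage_rank` order; the gene is eliminated at the first stage with a hit
#' at `E <= evalue_cutoff` and only survivors are queried at later stages.
#' Records whose name contains the focal species id are ignored, so a panel
#' built from proteome files that include the query species never
#' eliminates a gene by self-hit.
#'
#' @param proteome named character vector of protein sequences (or a list
#'   of [gene_model()]; proteins are extracted)
#' @param panel list of [reference_db()]; `stage_rank`s must be unique
#' @param evalue_cutoff significance threshold, inclusive (default 1e-5)
#' @param params optional [search_params()] override (protein mode)
#' @param exclude_species species id whose records are skipped as self-hits
#' @return data.frame of class `cascade_result`: gene_id, is_orphan,
#'   stage_eliminated (NA for orphans), best_evalue, best_subject; attribute
#'   `survivors_per_stage` holds the counts vector (input count followed by
#'   survivors after each stage)
#' @export
run_cascade <- function(proteome, panel, evalue_cutoff = 1e-5,
                        params = NULL, exclude_species = NULL) {
  if (length(panel) == 0L) stop("cascade undefined: empty database panel")
  if (is.list(proteome) && inherits(proteome[[1L]], "gene_model")) {
    proteome <- stats::setNames(
      vapply(proteome, `[[`, "", "protein_seq"),
      vapply(proteome, `[[`, "", "gene_id"))
  }
  stopifnot(is.character(proteome), !is.null(names(proteome)),
            all(nzchar(proteome)))
  ranks <- vapply(panel, `[[`, 1L, "stage_rank")
  if (anyDuplicated(ranks)) stop("panel stage_ranks must be unique")
  panel <- panel[order(ranks)]
  params <- params %||% search_params("protein", evalue_cutoff = evalue_cutoff)
  params$evalue_cutoff <- evalue_cutoff

  res <- data.frame(gene_id = names(proteome), is_orphan = TRUE,
                    stage_eliminated = NA_character_,
                    best_evalue = NA_real_, best_subject = NA_character_,
                    stringsAsFactors = FALSE)
  alive <- rep(TRUE, length(proteome))
  survivors <- c(length(proteome))
  for (db in panel) {
    if (!is.null(exclude_species)) {
      keep <- !grepl(exclude_species, names(db$records), fixed = TRUE)
      if (!any(keep)) {           # whole stage is the query species itself
        survivors <- c(survivors, sum(alive))
        next
      }
      if (!all(keep))
        db <- reference_db(db$name, db$kind, db$records[keep], db$stage_rank)
    }
    for (i in which(alive)) {
      hits <- search(proteome[[i]], db, params, query_id = res$gene_id[i])
      if (nrow(hits) > 0L) {
        alive[i] <- FALSE
        res$is_orphan[i] <- FALSE
        res$stage_eliminated[i] <- db$name
        res$best_evalue[i] <- hits$evalue[1L]
        res$best_subject[i] <- hits$subject_id[1L]
      }
    }
    survivors <- c(survivors, sum(alive))
  }
  attr(res, "survivors_per_stage") <- stats::setNames(
    survivors, c("input", vapply(panel, `[[`, "", "name")))
  class(res) <- c("cascade_result", "data.frame")
  res
}

#' Orphan-gene content of a proteome
#'
#' @param results a `cascade_result` from [run_cascade()]
#' @return list: n_orphan, n_total, percent (orphan share of the proteome,
#'   on the 0-100 scale)
#' @export
orphan_content <- function(results) {
  stopifnot(nrow(results) > 0L)
  n_og <- sum(results$is_orphan)
  list(n_orphan = n_og, n_total = nrow(results),
       percent = 100 * n_og / nrow(results))
}

#' @export
print.cascade_result <- function(x, ...) {
  oc <- orphan_content(x)
  cat(sprintf("<cascade_result> %d genes -> %d orphans (%.2f%%)\n",
              oc$n_total, oc$n_orphan, oc$percent))
  sp <- attr(x, "survivors_per_stage")
  cat("  survivors:", paste(names(sp), sp, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Orphan gene ids from a cascade result
#'
#' @param results a `cascade_result`
#' @return character vector of orphan gene ids
#' @export
orphan_ids <- function(results) results$gene_id[results$is_orphan]
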