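# Resistant-clone variant triage: restrict called variants to non-silent
# changes in a curated gene list above an allele-frequency floor, then
# report genes recurrently hit across clones.

#' Filter clone variants by gene list, effect class and allele frequency
#'
#' Keeps a variant when its gene is on the curated list, its allele
#' frequency strictly exceeds `af_min`, and its effect class is
#' non-silent (`missense`, `nonsense`, `frameshift`, `inframe_indel`,
#' `splice_site`); synonymous and unclassifiable (`other`) variants are
#' dropped.
#'
#' @param variants data.frame from [read_variants()].
#' @param gene_list character vector of curated gene symbols.
#' @param af_min allele-frequency floor, strict (default 0.2).
#' @param keep_effects effect classes to retain (default the non-silent
#'   set).
#' @return The filtered variant data.frame.
#' @export
filter_variants <- function(variants, gene_list, af_min = 0.2,
                            keep_effects = NON_SILENT_EFFECTS) {
  if (length(gene_list) == 0L) stop("empty curated gene list")
  keep <- variants$gene %in% gene_list &
    variants$allele_frequency > af_min &
    variants$effect_class %in% keep_effects
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Report genes recurrently mutated across clones
#'
#' Counts, for each gene in the filtered set, the number of distinct
#' clones carrying at least one variant in it (a clone with several
#' variants in one gene counts once), and keeps genes hit in at least
#' `min_clones` clones.  When clones carry a treatment-arm label
#' (`arm` column, e.g. the selection compound), per-arm clone counts are
#' reported alongside.
#'
#' @param filtered_variants output of [filter_variants()]; must carry
#'   `clone_id` and `gene`, optionally `arm`.
#' @param min_clones recurrence threshold on distinct clones (default 3).
#' @return list of class `recurrence_report`: `genes` (data.frame:
#'   `gene`, `n_clones`, per-arm counts) and `variants` (the supporting
#'   (gene, clone, protein_change) records for reported genes).
#' @export
recurrent_genes <- function(filtered_variants, min_clones = 3L) {
  v <- filtered_variants
  per_gene <- unique(v[, intersect(c("gene", "clone_id", "arm"), names(v)),
                       drop = FALSE])
  counts <- tapply(per_gene$clone_id, per_gene$gene,
                   function(x) length(unique(x)))
  keep_genes <- names(counts)[counts >= min_clones]
  genes <- data.frame(gene = keep_genes,
                      n_clones = as.integer(counts[keep_genes]),
                      stringsAsFactors = FALSE)
  if ("arm" %in% names(v) && nrow(genes) > 0) {
    arms <- sort(unique(v$arm))
    for (a in arms) {
      genes[[paste0("n_clones_", a)]] <- vapply(genes$gene, function(g) {
        length(unique(per_gene$clone_id[per_gene$gene == g & per_gene$arm == a]))
      }, integer(1))
    }
  }
  genes <- genes[order(-genes$n_clones, genes$gene), , drop = FALSE]
  rownames(genes) <- NULL
  support <- v[v$gene %in% keep_genes, , drop = FALSE]
  rownames(support) <- NULL
  structure(list(genes = genes, variants = support, min_clones = min_clones),
            class = "recurrence_report")
}

#' @export
print.recurrence_report <- function(x, ...) {
  cat("Recurrently mutated genes (>=", x$min_clones, "clones):\n")
  if (nrow(x$genes) == 0L) {
    cat("  none\n")
  } else {
    for (i in seq_len(nrow(x$genes))) {
      cat(sprintf("  %s: %d clones\n", x$genes$gene[i], x$genes$n_clones[i]))
    }
  }
  invisible(x)
}

#' Write a recurrence report as TSV
#'
#' @param report a `recurrence_report`.
#' @param path output path.
#' @export
write_recurrence_report <- function(report, path) {
  utils::write.table(report$genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
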