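# ES <-> IR switch comparison across genotypes at shared 3' splice sites.
#
# For each significant exon-skipping site in condition A, the replicate-
# averaged trifurcation PSIs in condition A and condition B are laid side
# by side; a site "switches" when condition B shows strictly lower ES
# PSI and strictly higher IR PSI than condition A.

#' Build the per-site switch table
#'
#' @param sig_sites character vector of significant ES acceptor site
#'   keys (from the condition-A differential test).
#' @param tri_A,tri_B replicate-averaged trifurcation PSIs per condition:
#'   data.frames with `site_key`, `psi_es`, `psi_ir` (e.g. from
#'   [average_replicates()] applied to [trifurcation_matrices()]).
#' @return data.frame with one row per site defined in both conditions:
#'   `site_key`, `es_psi_A`, `ir_psi_A`, `es_psi_B`, `ir_psi_B`,
#'   `is_switch`.  Sites undefined in either condition are excluded and
#'   counted in attribute `n_excluded`.
#' @export
build_switch_table <- function(sig_sites, tri_A, tri_B) {
  ia <- match(sig_sites, tri_A$site_key)
  ib <- match(sig_sites, tri_B$site_key)
  es_A <- tri_A$psi_es[ia]; ir_A <- tri_A$psi_ir[ia]
  es_B <- tri_B$psi_es[ib]; ir_B <- tri_B$psi_ir[ib]
  ok <- !is.na(es_A) & !is.na(ir_A) & !is.na(es_B) & !is.na(ir_B)
  out <- data.frame(
    site_key = sig_sites[ok],
    es_psi_A = es_A[ok], ir_psi_A = ir_A[ok],
    es_psi_B = es_B[ok], ir_psi_B = ir_B[ok],
    stringsAsFactors = FALSE
  )
  # strict inequalities: exact ties never count as a switch
  out$is_switch <- out$es_psi_B < out$es_psi_A & out$ir_psi_B > out$ir_psi_A
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Order the switch table for a waterfall plot
#'
#' Sites are sorted by descending ES PSI in the ordering condition, so
#' both conditions' panels can be drawn in the same order; ties break on
#' the site key for determinism.
#'
#' @param switch_table output of [build_switch_table()].
#' @param order_condition `"A"` or `"B"`: which condition's ES PSI
#'   drives the order (default `"A"`).
#' @return The table sorted, with a `rank` column prepended.
#' @export
waterfall_order <- function(switch_table, order_condition = c("A", "B")) {
  order_condition <- match.arg(order_condition)
  key <- switch_table[[paste0("es_psi_", order_condition)]]
  ord <- order(-key, switch_table$site_key)
  out <- switch_table[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Count ES->IR switches
#'
#' @param switch_table output of [build_switch_table()].
#' @return list with `n_switch`, `n_total` and `fraction`
#'   (`NA` when the table is empty).
#' @export
count_switches <- function(switch_table) {
  n_total <- nrow(switch_table)
  n_switch <- sum(switch_table$is_switch)
  list(n_switch = n_switch, n_total = n_total,
       fraction = if (n_total > 0) n_switch / n_total else NA_real_)
}

#' Write the waterfall table as TSV with a summary line
#'
#' @param switch_table output of [build_switch_table()].
#' @param path output path.
#' @param order_condition forwarded to [waterfall_order()].
#' @export
write_switch_table <- function(switch_table, path, order_condition = "A") {
  tab <- waterfall_order(switch_table, order_condition)
  cnt <- count_switches(switch_table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_switch=%d n_total=%d fraction=%.6f",
                     cnt$n_switch, cnt$n_total,
                     ifelse(is.na(cnt$fraction), NaN, cnt$fraction)), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
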