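# Junction-level PSI and the 3'-splice-site ES/inclusion/IR trifurcation.
#
# PSI (percent spliced in) of a junction is its read count divided by the
# summed counts of all junctions sharing the same splice site.  Donor and
# acceptor sites define separate sharing groups; downstream intron-
# retention / exon-skipping analyses are anchored at the acceptor (3')
# side.

#' Index junctions by shared donor and acceptor splice sites
#'
#' The donor is the 5' end of the intron on the transcript strand and the
#' acceptor its 3' end: on `+` the donor is `intron_first` and the
#' acceptor `intron_last`; on `-` the roles swap.  Junctions of
#' undetermined strand cannot be assigned a 5'/3' side and are excluded.
#'
#' @param junctions junction data.frame ([read_junction_table()]).
#' @return The input restricted to stranded junctions, with added columns
#'   `junction_id`, `donor_key` and `acceptor_key`
#'   (`chrom:pos:strand` site keys).
#' @export
index_shared_sites <- function(junctions) {
  j <- junctions[junctions$strand %in% c("+", "-"), , drop = FALSE]
  plus <- j$strand == "+"
  donor_pos <- ifelse(plus, j$intron_first, j$intron_last)
  acceptor_pos <- ifelse(plus, j$intron_last, j$intron_first)
  j$junction_id <- junction_key(j$chrom, j$intron_first, j$intron_last, j$strand)
  j$donor_key <- site_key(j$chrom, donor_pos, j$strand)
  j$acceptor_key <- site_key(j$chrom, acceptor_pos, j$strand)
  j
}

#' Per-junction PSI at the donor and acceptor sharing groups
#'
#' For one sample, each junction's PSI at a site is its unique read count
#' divided by the total count of all junctions sharing that site.  A
#' group with zero total reads yields an undefined (`NA`) PSI rather than
#' a silent 0/0.
#'
#' @param junctions indexed junctions ([index_shared_sites()]) from one
#'   sample.
#' @return The input with `psi_donor` and `psi_acceptor` columns.
#' @export
compute_junction_psi <- function(junctions) {
  j <- junctions
  if (nrow(j) == 0L) {
    j$psi_donor <- numeric(0)
    j$psi_acceptor <- numeric(0)
    return(j)
  }
  psi_within <- function(key) {
    tot <- stats::ave(j$unique_reads, key, FUN = sum)
    ifelse(tot > 0, j$unique_reads / tot, NA_real_)
  }
  j$psi_donor <- psi_within(j$donor_key)
  j$psi_acceptor <- psi_within(j$acceptor_key)
  j
}

#' Three-way PSI at a shared 3' splice site
#'
#' Reads informative for one acceptor site fall in three classes: the
#' junction skipping the cassette exon (ES), the junction using the
#' cassette exon's own 5' splice site (exon inclusion), and reads
#' crossing the exon-intron boundary (intron retention).  The three PSIs
#' are the class counts as fractions of their sum; a zero total leaves
#' all three undefined.
#'
#' @param es_reads,inclusion_reads,ir_reads non-negative counts (vectors
#'   are recycled jointly).
#' @return data.frame with `psi_es`, `psi_inc`, `psi_ir`, `total_reads`,
#'   and logical `defined`.
#' @export
trifurcate_3ss <- function(es_reads, inclusion_reads, ir_reads) {
  stopifnot(all(es_reads >= 0), all(inclusion_reads >= 0), all(ir_reads >= 0))
  total <- es_reads + inclusion_reads + ir_reads
  defined <- total > 0
  denom <- ifelse(defined, total, NA_real_)
  data.frame(
    psi_es = es_reads / denom,
    psi_inc = inclusion_reads / denom,
    psi_ir = ir_reads / denom,
    total_reads = total,
    defined = defined
  )
}

#' Average per-sample PSI over replicate samples
#'
#' Replicate averaging takes the arithmetic mean of the per-sample PSIs
#' over samples where PSI is defined (no count pooling); the number of
#' contributing samples is reported alongside.
#'
#' @param psi_matrix numeric matrix, events x samples, `NA` for undefined.
#' @param samples character vector naming the columns to average (default
#'   all).
#' @return data.frame with `mean_psi` and `n_defined` per row of
#'   `psi_matrix`.
#' @export
average_replicates <- function(psi_matrix, samples = colnames(psi_matrix)) {
  m <- psi_matrix[, samples, drop = FALSE]
  n_def <- rowSums(!is.na(m))
  mean_psi <- ifelse(n_def > 0, rowMeans(m, na.rm = TRUE), NA_real_)
  data.frame(mean_psi = mean_psi, n_defined = n_def,
             row.names = rownames(psi_matrix))
}

#' Trifurcation PSI table for a set of samples
#'
#' Joins per-sample junction tables and boundary counts into long-format
#' per-site trifurcation PSIs.  For each acceptor site named in
#' `site_table`, ES reads come from the skip junction, inclusion reads
#' from the inclusion junction, and IR reads from the boundary counts at
#' that site.
#'
#' @param site_table data.frame mapping acceptor sites to their member
#'   junctions: columns `site_key`, `es_junction_id`, `inc_junction_id`.
#' @param junctions indexed junction data.frame for all samples (column
#'   `sample` present).
#' @param boundaries boundary-count data.frame ([read_boundary_counts()]).
#' @param samples character vector of sample names to quantify.
#' @return Long data.frame: `sample`, `site_key`, `es_reads`,
#'   `inc_reads`, `ir_reads`, `psi_es`, `psi_inc`, `psi_ir`,
#'   `total_reads`, `defined`.
#' @export
trifurcation_table <- function(site_table, junctions, boundaries, samples) {
  out <- vector("list", length(samples))
  for (k in seq_along(samples)) {
    s <- samples[k]
    js <- junctions[junctions$sample == s, , drop = FALSE]
    bs <- boundaries[boundaries$sample == s, , drop = FALSE]
    es <- js$unique_reads[match(site_table$es_junction_id, js$junction_id)]
    inc <- js$unique_reads[match(site_table$inc_junction_id, js$junction_id)]
    ir <- bs$reads[match(site_table$site_key, bs$site_key)]
    es[is.na(es)] <- 0L; inc[is.na(inc)] <- 0L; ir[is.na(ir)] <- 0L
    tri <- trifurcate_3ss(es, inc, ir)
    out[[k]] <- data.frame(sample = s, site_key = site_table$site_key,
                           es_reads = es, inc_reads = inc, ir_reads = ir,
                           tri, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Reshape a long trifurcation table into per-class PSI matrices
#'
#' @param tri_long long table from [trifurcation_table()].
#' @return list of three matrices (`psi_es`, `psi_inc`, `psi_ir`), sites
#'   x samples, `NA` where undefined.
#' @export
trifurcation_matrices <- function(tri_long) {
  sites <- unique(tri_long$site_key)
  samples <- unique(tri_long$sample)
  shape <- function(col) {
    m <- matrix(NA_real_, length(sites), length(samples),
                dimnames = list(sites, samples))
    idx <- cbind(match(tri_long$site_key, sites),
                 match(tri_long$sample, samples))
    m[idx] <- ifelse(tri_long$defined, tri_long[[col]], NA_real_)
    m
  }
  list(psi_es = shape("psi_es"), psi_inc = shape("psi_inc"),
       psi_ir = shape("psi_ir"))
}
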