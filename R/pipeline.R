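# End-to-end orchestration: PSI -> differential -> event classes -> GC
# profiles -> switch analysis, with the independent variant-filter path.
# Every stage logs its in/out counts; outputs carry the run seed and a
# config hash in a machine-readable manifest.

#' Enumerate cassette 3' splice sites from an annotation
#'
#' For every pair of consecutive introns within a transcript, the shared
#' 3' splice site is the downstream intron's acceptor; its inclusion
#' junction is the downstream intron itself and its skip junction joins
#' the upstream intron's donor to that acceptor.
#'
#' @param annotation an `annotation_model`.
#' @return data.frame with `site_key`, `es_junction_id`,
#'   `inc_junction_id`, `chrom`, `strand`, plus the skip junction's
#'   intron span (`skip_first`, `skip_last`).
#' @export
cassette_site_table <- function(annotation) {
  introns <- annotation$introns
  pieces <- split(introns, introns$transcript_id)
  out <- do.call(rbind, lapply(pieces, function(tx) {
    tx <- tx[order(tx$intron_rank), , drop = FALSE]
    if (nrow(tx) < 2) return(NULL)
    i <- seq_len(nrow(tx) - 1L)
    up <- tx[i, , drop = FALSE]
    dn <- tx[i + 1L, , drop = FALSE]
    skip_first <- pmin(up$donor, dn$acceptor)
    skip_last <- pmax(up$donor, dn$acceptor)
    data.frame(
      site_key = site_key(dn$chrom, dn$acceptor, dn$strand),
      es_junction_id = junction_key(dn$chrom, skip_first, skip_last,
                                    dn$strand),
      inc_junction_id = junction_key(dn$chrom, dn$start, dn$end, dn$strand),
      up_junction_id = junction_key(up$chrom, up$start, up$end, up$strand),
      chrom = dn$chrom, strand = dn$strand,
      skip_first = skip_first, skip_last = skip_last,
      stringsAsFactors = FALSE
    )
  }))
  if (is.null(out)) {
    return(data.frame(site_key = character(), es_junction_id = character(),
                      inc_junction_id = character(),
                      up_junction_id = character(), chrom = character(),
                      strand = character(), skip_first = integer(),
                      skip_last = integer(), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  unique(out)
}

#' Load a study directory written by [simulate_study()]
#'
#' @param dir directory path.
#' @return list with `genome`, `annotation`, `design`, `junctions`,
#'   `boundaries`, `variants`, `gene_list`.
#' @export
load_study <- function(dir) {
  design <- utils::read.table(file.path(dir, "design.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
  junctions <- do.call(rbind, lapply(design$sample, function(s) {
    read_junction_table(file.path(dir, "junctions", paste0(s, ".sj.tab")),
                        sample = s)
  }))
  list(
    genome = read_genome_fasta(file.path(dir, "genome.fa")),
    annotation = read_annotation(file.path(dir, "annotation.bed"), "bed12"),
    design = design,
    junctions = index_shared_sites(junctions),
    boundaries = read_boundary_counts(file.path(dir, "boundary_counts.tsv")),
    variants = cbind(read_variants(file.path(dir, "variants.tsv")),
                     arm = NA_character_),
    gene_list = read_gene_list(file.path(dir, "gene_list.txt"))
  )
}

#' @noRd
condition_samples <- function(design, condition) {
  cond <- paste(design$genotype, design$treatment, sep = "_")
  design$sample[cond == condition]
}

#' Differential trifurcation PSI between two conditions
#'
#' Runs the moderated t-test on one trifurcation PSI class (ES,
#' inclusion or IR) between the samples of two conditions.
#'
#' @param psi_mat sites x samples matrix for one class
#'   ([trifurcation_matrices()]).
#' @param design design data.frame (`sample`, `genotype`, `treatment`).
#' @param condition_control,condition_treated condition labels
#'   (`genotype_treatment`); `delta_psi` = treated - control.
#' @param ... forwarded to [moderated_t_test()].
#' @return [moderated_t_test()] output.
#' @export
differential_psi <- function(psi_mat, design, condition_control,
                             condition_treated, ...) {
  s1 <- condition_samples(design, condition_control)
  s2 <- condition_samples(design, condition_treated)
  if (length(s1) == 0L || length(s2) == 0L) {
    stop("no samples for condition ", condition_control, " or ",
         condition_treated)
  }
  m <- psi_mat[, c(s1, s2), drop = FALSE]
  labels <- rep(c("control", "treated"), c(length(s1), length(s2)))
  moderated_t_test(m, labels, ...)
}

#' Run the full analysis flow on a study
#'
#' Stages, in order: trifurcation PSI at every annotated cassette 3'
#' splice site; moderated-t differential PSI for each requested
#' comparison on the ES, inclusion and IR classes with BH correction;
#' event classification and category summaries; GC metagene profiles
#' (significant-IR foreground, significant-ES triplets, random
#' background); ES/IR switch table across genotypes; and, independently,
#' the resistant-clone variant filter.  All tabular outputs are TSV; a
#' manifest records the seed, thresholds and a config hash.
#'
#' @param study study list ([load_study()] / [simulate_study()] output)
#'   or a directory path.
#' @param out_dir output directory.
#' @param q_max significance threshold (default 0.05).
#' @param epsilon fold-change pseudocount (default 0.01).
#' @param n_boot bootstrap resamples for GC profiles (default 100).
#' @param n_background background pairs for the GC profile (default
#'   10000).
#' @param af_min,min_clones variant-filter thresholds (defaults 0.2, 3).
#' @param seed master seed for the run's stochastic stages (background
#'   sampling, bootstrap, random exon choice).
#' @param genotypes character of length 2: the reference genotype and
#'   the variant genotype (defaults `c("WT", "MUT")`).
#' @return Invisibly, a list with every stage's in-memory result.
#' @export
run_end_to_end <- function(study, out_dir, q_max = 0.05, epsilon = 0.01,
                           n_boot = 100L, n_background = 10000L,
                           af_min = 0.2, min_clones = 3L, seed = 1L,
                           genotypes = c("WT", "MUT")) {
  if (is.character(study)) study <- load_study(study)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- function(...) message("[trisplice] ", sprintf(...))

  # --- stage 1: trifurcation PSI -------------------------------------
  sites <- cassette_site_table(study$annotation)
  logf("psi: %d cassette 3' splice sites, %d samples", nrow(sites),
       nrow(study$design))
  tri_long <- trifurcation_table(sites, study$junctions, study$boundaries,
                                 study$design$sample)
  mats <- trifurcation_matrices(tri_long)
  utils::write.table(tri_long, file.path(out_dir, "trifurcation_psi.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- stage 2: differential PSI per comparison ----------------------
  gA <- genotypes[1]; gB <- genotypes[2]
  comparisons <- list(
    list(name = paste0(gA, "_compound_vs_control"),
         control = paste0(gA, "_control"), treated = paste0(gA, "_compound")),
    list(name = paste0(gB, "_compound_vs_control"),
         control = paste0(gB, "_control"), treated = paste0(gB, "_compound"))
  )
  diffs <- list()
  for (cmp in comparisons) {
    for (cls in c("psi_es", "psi_inc", "psi_ir")) {
      d <- differential_psi(mats[[cls]], study$design, cmp$control,
                            cmp$treated)
      d$class <- sub("psi_", "", cls)
      d$comparison <- cmp$name
      diffs[[paste(cmp$name, cls, sep = ".")]] <- d
      n_sig <- sum(!is.na(d$q) & d$q <= q_max)
      logf("differential %s %s: %d/%d testable, %d significant at q<=%g",
           cmp$name, cls, sum(d$testable), nrow(d), n_sig, q_max)
      utils::write.table(
        d, file.path(out_dir, paste0("diff_", cmp$name, "_",
                                     sub("psi_", "", cls), ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  # --- stage 3: event classification and summaries -------------------
  ev_frame <- function(d, type) {
    key <- d$event_key
    if (type == "boundary") {
      parts <- matrix(unlist(strsplit(key, ":", fixed = TRUE)), ncol = 3,
                      byrow = TRUE)
      data.frame(type = "boundary", chrom = parts[, 1],
                 pos = as.integer(parts[, 2]), strand = parts[, 3],
                 stringsAsFactors = FALSE)
    } else {
      idx <- match(key, sites$site_key)
      data.frame(type = "junction", chrom = sites$chrom[idx],
                 intron_first = sites$skip_first[idx],
                 intron_last = sites$skip_last[idx],
                 strand = sites$strand[idx], stringsAsFactors = FALSE)
    }
  }
  summaries <- list()
  for (cmp in comparisons) {
    d_es <- diffs[[paste(cmp$name, "psi_es", sep = ".")]]
    d_ir <- diffs[[paste(cmp$name, "psi_ir", sep = ".")]]
    d_es$category <- classify_events(ev_frame(d_es, "junction"),
                                     study$annotation)
    d_ir$category <- classify_events(ev_frame(d_ir, "boundary"),
                                     study$annotation)
    both <- rbind(d_es, d_ir)
    summ <- summarize_events(both, q_max = q_max, epsilon = epsilon)
    summaries[[cmp$name]] <- summ
    utils::write.table(summ$counts,
                       file.path(out_dir, paste0("event_summary_", cmp$name,
                                                 ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- stage 4: GC metagene profiles ---------------------------------
  sig_keys <- function(d, direction = +1) {
    ok <- !is.na(d$q) & d$q <= q_max & sign(d$delta_psi) == direction
    d$event_key[ok]
  }
  dA_ir <- diffs[[paste0(gA, "_compound_vs_control.psi_ir")]]
  dB_es <- diffs[[paste0(gB, "_compound_vs_control.psi_es")]]
  sig_ir_sites <- sig_keys(dA_ir)
  sig_es_sites <- sig_keys(dB_es)
  logf("gc: %d significant IR sites (%s), %d significant ES sites (%s)",
       length(sig_ir_sites), comparisons[[1]]$name,
       length(sig_es_sites), comparisons[[2]]$name)
  results_gc <- list()
  if (length(sig_ir_sites) > 0) {
    ir_pairs <- select_ir_pairs(sig_ir_sites, study$annotation,
                                seed = derive_seed(seed, "ir_exon_pick"))
    if (nrow(ir_pairs) > 0) {
      m <- ir_pair_gc_matrix(ir_pairs, study$genome)
      results_gc$ir <- profile_with_bootstrap(
        m, n_boot = n_boot, seed = derive_seed(seed, "boot_ir"))
      write_gc_profile(results_gc$ir, file.path(out_dir, "gc_profile_ir.tsv"))
      logf("gc: IR profile over %d intron/exon pairs", nrow(ir_pairs))
    }
  }
  # untreated-inclusion evidence: introns whose inclusion PSI is
  # significantly higher in the control (untreated) samples; both
  # flanking introns carry the inclusion isoform, so the site-level
  # evidence certifies both junctions
  dB_inc <- diffs[[paste0(gB, "_compound_vs_control.psi_inc")]]
  midx <- match(dB_inc$event_key, sites$site_key)
  inc_q <- ifelse(dB_inc$delta_psi < 0, dB_inc$q, NA_real_)
  inc_evidence <- data.frame(
    event_key = c(sites$inc_junction_id[midx], sites$up_junction_id[midx]),
    q = c(inc_q, inc_q),
    stringsAsFactors = FALSE
  )
  es_j <- sites[match(sig_es_sites, sites$site_key), , drop = FALSE]
  es_junctions <- data.frame(chrom = es_j$chrom,
                             intron_first = es_j$skip_first,
                             intron_last = es_j$skip_last,
                             strand = es_j$strand, stringsAsFactors = FALSE)
  triplets <- select_es_triplets(es_junctions, inc_evidence,
                                 study$annotation)
  if (nrow(triplets) > 0) {
    m <- es_triplet_gc_matrix(triplets, study$genome)
    results_gc$es <- profile_with_bootstrap(
      m, n_boot = n_boot, seed = derive_seed(seed, "boot_es"))
    write_gc_profile(results_gc$es, file.path(out_dir, "gc_profile_es.tsv"))
    logf("gc: ES profile over %d triplets", nrow(triplets))
  }
  bg <- sample_background(study$annotation, n = n_background,
                          seed = derive_seed(seed, "background"))
  m_bg <- ir_pair_gc_matrix(bg, study$genome)
  results_gc$background <- profile_with_bootstrap(
    m_bg, n_boot = n_boot, seed = derive_seed(seed, "boot_bg"))
  write_gc_profile(results_gc$background,
                   file.path(out_dir, "gc_profile_background.tsv"))

  # --- stage 5: ES/IR switch analysis --------------------------------
  tri_avg <- function(condition) {
    s <- condition_samples(study$design, condition)
    data.frame(site_key = rownames(mats$psi_es),
               psi_es = average_replicates(mats$psi_es, s)$mean_psi,
               psi_ir = average_replicates(mats$psi_ir, s)$mean_psi,
               stringsAsFactors = FALSE)
  }
  switch_table <- build_switch_table(sig_es_sites,
                                     tri_avg(paste0(gB, "_compound")),
                                     tri_avg(paste0(gA, "_compound")))
  cnt <- count_switches(switch_table)
  logf("switch: %d/%d sites switch (fraction %.3f; %d excluded undefined)",
       cnt$n_switch, cnt$n_total,
       ifelse(is.na(cnt$fraction), NaN, cnt$fraction),
       attr(switch_table, "n_excluded"))
  write_switch_table(switch_table, file.path(out_dir, "switch_table.tsv"))

  # --- stage 6 (independent path): resistant-clone variant filter ----
  filtered <- filter_variants(study$variants, study$gene_list,
                              af_min = af_min)
  report <- recurrent_genes(filtered, min_clones = min_clones)
  logf("variants: %d/%d kept by filter, %d recurrent genes",
       nrow(filtered), nrow(study$variants), nrow(report$genes))
  write_recurrence_report(report, file.path(out_dir,
                                            "resistance_report.tsv"))

  # --- manifest ------------------------------------------------------
  cfg_path <- file.path(out_dir, "run_config.tsv")
  cfg <- data.frame(
    key = c("q_max", "epsilon", "n_boot", "n_background", "af_min",
            "min_clones", "seed"),
    value = c(q_max, epsilon, n_boot, n_background, af_min, min_clones, seed)
  )
  utils::write.table(cfg, cfg_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  manifest <- data.frame(file = files,
                         md5 = unname(tools::md5sum(file.path(out_dir,
                                                              files))),
                         config_hash = unname(tools::md5sum(cfg_path)),
                         seed = seed, stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(sites = sites, trifurcation = tri_long, matrices = mats,
                 differential = diffs, summaries = summaries,
                 gc_profiles = results_gc, switch_table = switch_table,
                 switch_counts = cnt, filtered_variants = filtered,
                 recurrence = report, manifest = manifest))
}
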