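# Synthetic study generator: genomes with controlled per-feature GC,
# cassette-exon gene models, junction/boundary count tables under a
# 2 (genotype) x 2 (treatment) x replicates design, and clone variant
# tables — all with exported planted truth for recovery testing.
#
# Each locus is a five-feature gene model
#   flank exon - upstream intron - cassette exon - downstream intron - flank exon
# whose shared 3' splice site (the downstream intron's acceptor) supports
# the three read classes: exon skipping (junction spanning both introns
# and the cassette exon), exon inclusion (the downstream intron's own
# junction) and intron retention (reads crossing the exon-intron
# boundary at the acceptor).

#' Default configuration for the synthetic study
#'
#' The defaults emulate the study design this generator models: two
#' genotypes (wild-type and a modulator-resistance point mutant) by two
#' treatments (vehicle control and a splicing modulator) in hexaplicate,
#' with compound-induced intron retention in the wild type and exon
#' skipping in the mutant at GC-rich loci.  Locus labels:
#' \describe{
#'   \item{null}{no treatment response; low-GC introns.}
#'   \item{ir}{intron retention induced by compound in the wild type
#'     (attenuated in the mutant); GC-rich introns.}
#'   \item{es_switch}{exon skipping induced in the mutant while the same
#'     site shifts to intron retention in the treated wild type — an
#'     ES/IR switch; GC-rich introns.}
#'   \item{es_noswitch}{exon skipping induced in both genotypes (no
#'     switch); GC-rich introns.}
#' }
#' Among ES-responsive loci the switch fraction defaults to
#' 0.16/0.25 = 0.64.  Effect sizes move probability mass from the
#' inclusion class; GC-rich introns are the responsive ones, encoding
#' the coupling between intron GC content and modulator sensitivity.
#'
#' @param n_loci number of cassette-exon loci (default 2000).
#' @param n_replicates replicates per condition (default 6).
#' @param ... overrides for any default listed below.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_loci = 2000L, n_replicates = 6L, ...) {
  cfg <- list(
    n_loci = as.integer(n_loci),
    genotypes = c("WT", "MUT"),
    treatments = c("control", "compound"),
    n_replicates = as.integer(n_replicates),
    loci_per_chrom = 250L,
    # locus label mixture
    frac_ir = 0.10, frac_es_switch = 0.16, frac_es_noswitch = 0.09,
    # feature length ranges (uniform integers)
    flank_exon_len = c(120L, 250L),
    cassette_exon_len = c(60L, 180L),
    intron_len = c(150L, 600L),
    spacer_len = 60L,
    # fractions of loci deliberately violating the metagene length
    # filters (short intron < 100 nt, short cassette exon < 50 nt)
    frac_short_intron = 0.03, frac_short_exon = 0.03,
    short_intron_len = c(60L, 99L), short_exon_len = c(30L, 49L),
    # per-feature GC targets
    gc_exon = 0.60, gc_intron_null = 0.40, gc_intron_effect = 0.55,
    gc_spacer = 0.45,
    # baseline trifurcation (es, inclusion, ir) and effect sizes
    p_baseline = c(es = 0.05, inc = 0.90, ir = 0.05),
    delta_ir = 0.40, delta_es = 0.40,
    delta_ir_attenuated = 0.10,   # mutant's residual IR response
    delta_es_noswitch_B = 0.47,   # wild-type ES gain at non-switch loci
    ir_drop_noswitch = 0.04,      # wild-type IR loss at non-switch loci
    # count model
    depth = 200, nb_size = 60, dirichlet_conc = 300,
    # clone variant simulation
    n_clones = 12L,
    clone_arms = rep(c("armA", "armB"), each = 6L),
    drivers = list(
      list(gene = "DRIVER1", protein_change = "R100H",
           clones = c(1L, 2L, 3L, 4L, 5L, 7L, 8L)),
      list(gene = "DRIVER2", protein_change = "Y36C",
           clones = c(6L, 9L, 10L, 11L, 12L))
    ),
    passenger_genes = paste0("PASS", 1:40),
    passenger_rate = 3,
    driver_af = c(0.3, 0.95),
    master_seed = 1L
  )
  dots <- list(...)
  cfg[names(dots)] <- dots
  stopifnot(cfg$n_replicates >= 2L,
            abs(sum(cfg$p_baseline) - 1) < 1e-12,
            cfg$frac_ir + cfg$frac_es_switch + cfg$frac_es_noswitch <= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' @noRd
random_sequence <- function(len, gc) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' @noRd
runif_int <- function(n, range) {
  if (range[1] >= range[2]) return(rep(range[1], n))
  range[1] + floor(stats::runif(n) * (range[2] - range[1] + 1L))
}

#' Generate a synthetic genome, annotation and planted truth
#'
#' Lays the loci left to right along synthetic chromosomes, sampling
#' every feature base-by-base at its GC target; gene strands alternate
#' so both orientations are exercised.  The returned truth table records,
#' per locus, the feature coordinates, GC targets, locus label and the
#' trifurcation probabilities in every condition.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (default derived from the config's master
#'   seed).
#' @return list with `genome` (named character vector), `annotation`
#'   (`annotation_model`) and `truth` (data.frame).
#' @export
make_genome_and_annotation <- function(config,
                                       seed = derive_seed(config$master_seed,
                                                          "genome")) {
  set.seed(seed)
  n <- config$n_loci
  labels <- sample(c(
    rep("ir", round(n * config$frac_ir)),
    rep("es_switch", round(n * config$frac_es_switch)),
    rep("es_noswitch", round(n * config$frac_es_noswitch)),
    rep("null", n)
  )[1:n])
  short_intron <- stats::runif(n) < config$frac_short_intron
  short_exon <- stats::runif(n) < config$frac_short_exon
  gc_intron <- ifelse(labels == "null", config$gc_intron_null,
                      config$gc_intron_effect)
  flank1_len <- runif_int(n, config$flank_exon_len)
  flank2_len <- runif_int(n, config$flank_exon_len)
  cass_len <- ifelse(short_exon, runif_int(n, config$short_exon_len),
                     runif_int(n, config$cassette_exon_len))
  up_len <- ifelse(short_intron, runif_int(n, config$short_intron_len),
                   runif_int(n, config$intron_len))
  dn_len <- runif_int(n, config$intron_len)
  strand <- rep(c("+", "-"), length.out = n)
  chrom <- paste0("simchr", (seq_len(n) - 1L) %/% config$loci_per_chrom + 1L)

  truth <- vector("list", n)
  seqs <- list()
  cursor <- integer(0)  # per-chromosome cursor
  chrom_parts <- list()
  pos <- stats::setNames(rep(0L, length(unique(chrom))), unique(chrom))
  for (i in seq_len(n)) {
    cc <- chrom[i]
    lens <- c(config$spacer_len, flank1_len[i], up_len[i], cass_len[i],
              dn_len[i], flank2_len[i])
    gcs <- c(config$gc_spacer, config$gc_exon, gc_intron[i], config$gc_exon,
             gc_intron[i], config$gc_exon)
    piece <- vapply(seq_along(lens),
                    function(k) random_sequence(lens[k], gcs[k]), character(1))
    chrom_parts[[cc]] <- c(chrom_parts[[cc]], piece)
    start0 <- pos[cc] + config$spacer_len
    # genomic feature boundaries (left to right)
    e1 <- c(start0 + 1L, start0 + flank1_len[i])
    i1 <- c(e1[2] + 1L, e1[2] + up_len[i])
    ce <- c(i1[2] + 1L, i1[2] + cass_len[i])
    i2 <- c(ce[2] + 1L, ce[2] + dn_len[i])
    e2 <- c(i2[2] + 1L, i2[2] + flank2_len[i])
    pos[cc] <- e2[2]
    plus <- strand[i] == "+"
    # transcript-orientation roles: upstream intron borders the cassette
    # exon's 5' side, downstream intron its 3' side
    up <- if (plus) i1 else i2
    dn <- if (plus) i2 else i1
    acceptor <- if (plus) dn[2] else dn[1]
    truth[[i]] <- data.frame(
      locus_id = sprintf("locus%04d", i), chrom = cc, strand = strand[i],
      label = labels[i],
      e1_start = e1[1], e1_end = e1[2], cass_start = ce[1], cass_end = ce[2],
      e2_start = e2[1], e2_end = e2[2],
      up_start = up[1], up_end = up[2], down_start = dn[1], down_end = dn[2],
      gc_intron = gc_intron[i], gc_exon = config$gc_exon,
      short_intron = short_intron[i], short_exon = short_exon[i],
      site_key = site_key(cc, acceptor, strand[i]),
      es_junction = junction_key(cc, i1[1], i2[2], strand[i]),
      inc_junction = junction_key(cc, dn[1], dn[2], strand[i]),
      up_junction = junction_key(cc, up[1], up[2], strand[i]),
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth)
  genome <- vapply(chrom_parts, paste, character(1), collapse = "")
  truth <- cbind(truth, condition_probabilities(truth$label, config))

  exons <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(transcript_id = truth$locus_id[i], gene_id = truth$locus_id[i],
               chrom = truth$chrom[i],
               start = c(truth$e1_start[i], truth$cass_start[i],
                         truth$e2_start[i]),
               end = c(truth$e1_end[i], truth$cass_end[i], truth$e2_end[i]),
               strand = truth$strand[i], stringsAsFactors = FALSE)
  }))
  list(genome = genome, annotation = build_annotation_model(exons),
       truth = truth)
}

#' @noRd
#' Per-condition trifurcation probabilities implied by a locus label.
condition_probabilities <- function(labels, config) {
  p0 <- config$p_baseline
  shift <- function(p, d_es = 0, d_ir = 0) {
    # move mass out of (or into) the inclusion class
    c(es = p[["es"]] + d_es, inc = p[["inc"]] - d_es - d_ir,
      ir = p[["ir"]] + d_ir)
  }
  per_label <- list(
    null = list(WT_compound = p0, MUT_compound = p0),
    ir = list(WT_compound = shift(p0, d_ir = config$delta_ir),
              MUT_compound = shift(p0, d_ir = config$delta_ir_attenuated)),
    es_switch = list(WT_compound = shift(p0, d_ir = config$delta_ir),
                     MUT_compound = shift(p0, d_es = config$delta_es)),
    es_noswitch = list(
      WT_compound = shift(p0, d_es = config$delta_es_noswitch_B,
                          d_ir = -config$ir_drop_noswitch),
      MUT_compound = shift(p0, d_es = config$delta_es))
  )
  conds <- c("WT_control", "WT_compound", "MUT_control", "MUT_compound")
  out <- matrix(NA_real_, length(labels), 3L * length(conds))
  colnames(out) <- as.vector(outer(c("p_es", "p_inc", "p_ir"), conds, paste,
                                   sep = "_"))
  for (lab in unique(labels)) {
    idx <- labels == lab
    for (cond in conds) {
      p <- if (grepl("_control$", cond)) p0 else per_label[[lab]][[cond]]
      out[idx, paste(c("p_es", "p_inc", "p_ir"), cond, sep = "_")] <-
        matrix(p, sum(idx), 3, byrow = TRUE)
    }
  }
  as.data.frame(out)
}

#' Simulate per-sample junction and boundary count tables
#'
#' Per locus and sample, the total informative read count is negative
#' binomial around the configured depth; reads are split among the ES,
#' inclusion and IR classes by a Dirichlet-multinomial around the
#' condition's trifurcation probabilities (biological replicates
#' overdisperse relative to a pure multinomial).  The inclusion isoform
#' also crosses the upstream intron's junction, so that junction receives
#' the inclusion count.
#'
#' @param truth truth table from [make_genome_and_annotation()].
#' @param config the [sim_config()] used to generate it.
#' @param seed integer seed (default derived from the master seed).
#' @return list with `design` (sample, genotype, treatment, replicate),
#'   `junctions` (long junction data.frame across samples, in
#'   [index_shared_sites()] layout) and `boundaries` (long boundary-count
#'   data.frame).
#' @export
simulate_counts <- function(truth, config,
                            seed = derive_seed(config$master_seed, "counts")) {
  set.seed(seed)
  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        treatment = config$treatments,
                        genotype = config$genotypes,
                        stringsAsFactors = FALSE)
  design$sample <- paste(design$genotype, design$treatment, design$replicate,
                         sep = "_")
  n <- nrow(truth)
  conc <- config$dirichlet_conc
  junc_out <- vector("list", nrow(design))
  bound_out <- vector("list", nrow(design))
  for (s in seq_len(nrow(design))) {
    cond <- paste(design$genotype[s], design$treatment[s], sep = "_")
    p <- as.matrix(truth[, paste(c("p_es", "p_inc", "p_ir"), cond, sep = "_")])
    total <- stats::rnbinom(n, mu = config$depth, size = config$nb_size)
    # Dirichlet perturbation of the condition probabilities
    g <- matrix(stats::rgamma(3L * n, shape = pmax(conc * p, 1e-8)), n, 3L)
    pd <- g / rowSums(g)
    es <- stats::rbinom(n, total, pd[, 1])
    rest <- total - es
    p_inc_cond <- ifelse(pd[, 1] < 1, pd[, 2] / (1 - pd[, 1]), 0)
    inc <- stats::rbinom(n, rest, pmin(pmax(p_inc_cond, 0), 1))
    ir <- rest - inc
    sample_id <- design$sample[s]
    parse_j <- function(keys, reads) {
      parts <- matrix(unlist(strsplit(keys, ":", fixed = TRUE)), ncol = 4,
                      byrow = TRUE)
      data.frame(chrom = parts[, 1], intron_first = as.integer(parts[, 2]),
                 intron_last = as.integer(parts[, 3]), strand = parts[, 4],
                 unique_reads = as.integer(reads), strand_known = TRUE,
                 sample = sample_id, stringsAsFactors = FALSE)
    }
    junc_out[[s]] <- rbind(parse_j(truth$up_junction, inc),
                           parse_j(truth$inc_junction, inc),
                           parse_j(truth$es_junction, es))
    bound_out[[s]] <- data.frame(
      sample = sample_id, chrom = truth$chrom,
      pos = as.integer(sub("^[^:]+:([0-9]+):.*$", "\\1", truth$site_key)),
      strand = truth$strand, site_key = truth$site_key,
      reads = as.integer(ir), note = truth$locus_id, stringsAsFactors = FALSE
    )
  }
  junctions <- do.call(rbind, junc_out)
  junctions <- index_shared_sites(junctions)
  list(design = design, junctions = junctions,
       boundaries = do.call(rbind, bound_out))
}

#' Simulate per-clone variant tables
#'
#' Plants recurrent driver mutations in configured clones and adds a
#' Poisson background of passenger variants with uniform allele
#' frequencies and mixed effect classes.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (default derived from the master seed).
#' @return list with `variants` (data.frame in [read_variants()] layout
#'   plus `arm`) and `gene_list` (curated list: drivers plus a subset of
#'   passenger genes).
#' @export
simulate_clone_variants <- function(config,
                                    seed = derive_seed(config$master_seed,
                                                       "variants")) {
  set.seed(seed)
  clones <- sprintf("clone%02d", seq_len(config$n_clones))
  arms <- config$clone_arms
  rows <- list()
  for (d in config$drivers) {
    for (ci in d$clones) {
      rows[[length(rows) + 1L]] <- data.frame(
        clone_id = clones[ci], gene = d$gene,
        protein_change = d$protein_change, effect_class = "missense",
        allele_frequency = stats::runif(1, config$driver_af[1],
                                        config$driver_af[2]),
        arm = arms[ci], stringsAsFactors = FALSE
      )
    }
  }
  effects <- c("missense", "synonymous", "frameshift", "nonsense", "other")
  for (ci in seq_along(clones)) {
    n_pass <- stats::rpois(1, config$passenger_rate)
    if (n_pass == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      clone_id = clones[ci],
      gene = sample(config$passenger_genes, n_pass, replace = TRUE),
      protein_change = sprintf("P%dL", runif_int(n_pass, c(10L, 900L))),
      effect_class = sample(effects, n_pass, replace = TRUE),
      allele_frequency = stats::runif(n_pass, 0.05, 1),
      arm = arms[ci], stringsAsFactors = FALSE
    )
  }
  variants <- do.call(rbind, rows)
  gene_list <- c(vapply(config$drivers, `[[`, character(1), "gene"),
                 config$passenger_genes[1:10])
  list(variants = variants, gene_list = gene_list)
}

#' Generate a complete self-contained synthetic study directory
#'
#' Writes genome FASTA, BED12 annotation, per-sample junction tables,
#' boundary counts, clone variants, curated gene list, the design table,
#' the planted truth and a config echo.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_study <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gen <- make_genome_and_annotation(config)
  counts <- simulate_counts(gen$truth, config)
  vars <- simulate_clone_variants(config)
  write_genome_fasta(gen$genome, file.path(out_dir, "genome.fa"))
  write_annotation_bed12(gen$annotation, file.path(out_dir, "annotation.bed"))
  dir.create(file.path(out_dir, "junctions"), showWarnings = FALSE)
  for (s in counts$design$sample) {
    write_junction_table(
      counts$junctions[counts$junctions$sample == s, , drop = FALSE],
      file.path(out_dir, "junctions", paste0(s, ".sj.tab")))
  }
  write_boundary_counts(counts$boundaries,
                        file.path(out_dir, "boundary_counts.tsv"))
  write_variants(vars$variants, file.path(out_dir, "variants.tsv"))
  writeLines(vars$gene_list, file.path(out_dir, "gene_list.txt"))
  utils::write.table(counts$design, file.path(out_dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gen$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  scalars <- Filter(function(x) is.atomic(x) && length(x) <= 8, unclass(config))
  writeLines(vapply(names(scalars), function(k) {
    paste0(k, "\t", paste(scalars[[k]], collapse = ","))
  }, character(1)), file.path(out_dir, "config_echo.tsv"))
  invisible(list(genome = gen$genome, annotation = gen$annotation,
                 truth = gen$truth, design = counts$design,
                 junctions = counts$junctions,
                 boundaries = counts$boundaries, variants = vars$variants,
                 gene_list = vars$gene_list))
}
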