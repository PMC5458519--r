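# Binned GC-content metagene profiles with bootstrap confidence
# intervals, for retained-intron and skipped-exon junction sets plus
# matched random backgrounds.
#
# Each intron is rescaled to 100 bins and each exon to 50 bins; bins are
# ordered 5' to 3' along the transcript.  Profiles average the per-bin GC
# fraction over intron/exon pairs and attach a percentile bootstrap 95%
# interval obtained by resampling whole pairs.

#' Read a genome FASTA into named sequences
#'
#' @param path FASTA path.
#' @return named character vector, one uppercase sequence per record.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write named sequences as FASTA
#'
#' @param genome named character vector of sequences.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 70L)
  invisible(path)
}

#' @noRd
feature_sequence <- function(genome, chrom, start, end, strand) {
  if (!chrom %in% names(genome)) stop("sequence not in genome: ", chrom)
  s <- substr(genome[[chrom]], start, end)
  if (nchar(s) != end - start + 1L) {
    stop("interval ", chrom, ":", start, "-", end, " exceeds sequence bounds")
  }
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

#' GC fraction of a sequence in equal-length bins
#'
#' The sequence is cut into `n_bins` contiguous bins with boundaries at
#' `floor(k * L / n_bins)`, so bin sizes differ by at most one base.  The
#' GC fraction of a bin is (#G + #C) / (bin length - #N): ambiguous `N`
#' bases count toward neither numerator nor denominator, and an all-`N`
#' bin is undefined (`NaN`).
#'
#' @param sequence character scalar over A/C/G/T/N (case-insensitive).
#' @param n_bins number of bins; requires `nchar(sequence) >= n_bins`.
#' @return numeric vector of length `n_bins`, values in `[0, 1]` or `NaN`.
#' @export
bin_gc <- function(sequence, n_bins) {
  L <- nchar(sequence)
  if (L < n_bins) {
    stop("sequence length ", L, " shorter than n_bins = ", n_bins)
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  bounds <- floor(seq_len(n_bins) * L / n_bins)
  starts <- c(1L, bounds[-n_bins] + 1L)
  vapply(seq_len(n_bins), function(k) {
    b <- chars[starts[k]:bounds[k]]
    informative <- sum(b != "N")
    if (informative == 0L) return(NaN)
    sum(b == "G" | b == "C") / informative
  }, numeric(1))
}

#' Select intron/downstream-exon pairs for significant IR events
#'
#' Restricts a set of significant intron-retention 3' splice sites to
#' those whose intron has length at least `min_intron` and which border
#' at least one exon of length at least `min_exon` at the intron's 3'
#' end.  When several transcripts provide a qualifying downstream exon,
#' one is selected at random (reproducibly under `seed`).
#'
#' @param sig_sites character vector of acceptor site keys
#'   (`chrom:pos:strand`).
#' @param annotation an `annotation_model`.
#' @param seed integer seed for the random exon choice.
#' @param min_intron,min_exon length filters (defaults 100 and 50).
#' @return data.frame of pairs: `site_key`, `chrom`, `strand`,
#'   `intron_start`, `intron_end`, `exon_start`, `exon_end`.  Sites with
#'   no qualifying pair are dropped (reasons in attribute `dropped`).
#' @export
select_ir_pairs <- function(sig_sites, annotation, seed = 1L,
                            min_intron = 100L, min_exon = 50L) {
  universe <- intron_exon_pair_universe(annotation, min_intron, min_exon)
  keep <- universe[universe$site_key %in% sig_sites, , drop = FALSE]
  dropped <- setdiff(sig_sites, universe$site_key)
  pairs <- pick_one_pair_per_site(keep, seed)
  attr(pairs, "dropped") <- dropped
  pairs
}

#' @noRd
#' All (intron, downstream exon) pairs passing the length filters, one
#' row per candidate exon.  The downstream exon is the exon bordering the
#' intron's 3' (acceptor) end within the same transcript.
intron_exon_pair_universe <- function(annotation, min_intron = 100L,
                                      min_exon = 50L) {
  introns <- annotation$introns
  exons <- annotation$exons
  if (nrow(introns) == 0L) {
    return(data.frame(site_key = character(), chrom = character(),
                      strand = character(), intron_start = integer(),
                      intron_end = integer(), exon_start = integer(),
                      exon_end = integer(), stringsAsFactors = FALSE))
  }
  # downstream exon = exon_rank == intron_rank + 1 in the same transcript
  ex_key <- paste(exons$transcript_id, exons$exon_rank)
  idx <- match(paste(introns$transcript_id, introns$intron_rank + 1L), ex_key)
  ok <- !is.na(idx)
  introns <- introns[ok, , drop = FALSE]
  dn <- exons[idx[ok], , drop = FALSE]
  ilen <- introns$end - introns$start + 1L
  elen <- dn$end - dn$start + 1L
  pass <- ilen >= min_intron & elen >= min_exon
  out <- data.frame(
    site_key = site_key(introns$chrom, introns$acceptor, introns$strand),
    chrom = introns$chrom, strand = introns$strand,
    intron_start = introns$start, intron_end = introns$end,
    exon_start = dn$start, exon_end = dn$end,
    stringsAsFactors = FALSE
  )[pass, , drop = FALSE]
  # identical (intron, exon) intervals shared by transcripts collapse
  unique(out)
}

#' @noRd
pick_one_pair_per_site <- function(candidates, seed) {
  if (nrow(candidates) == 0L) return(candidates)
  set.seed(seed)
  sites <- sort(unique(candidates$site_key))
  rows <- vapply(sites, function(s) {
    idx <- which(candidates$site_key == s)
    if (length(idx) == 1L) idx else sample(idx, 1L)
  }, integer(1))
  out <- candidates[rows, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select cassette-exon triplets for significant ES events
#'
#' For each significant exon-skipping junction, locates the transcript
#' where the junction joins the donor of intron *i* to the acceptor of
#' intron *i+1*, giving the cassette exon and its two flanking introns.
#' A triplet is kept when both introns have length at least
#' `min_intron`, both are significantly enriched as exon-inclusion
#' events in the untreated comparison (`q < q_max` in `untreated_diff`),
#' and the intervening annotated exon has length at least `min_exon`
#' (junctions skipping more than one exon never satisfy the annotated
#' single-exon requirement and are excluded).
#'
#' @param es_junctions data.frame of significant ES junctions: `chrom`,
#'   `intron_first`, `intron_last`, `strand`.
#' @param untreated_diff data.frame with `event_key` (intron junction
#'   keys, `chrom:first:last:strand`) and `q` from the untreated
#'   inclusion differential test; `NULL` skips that filter.
#' @param annotation an `annotation_model`.
#' @param min_intron,min_exon,q_max filters (defaults 100, 50, 0.05).
#' @return data.frame of triplets: `chrom`, `strand`, upstream intron,
#'   cassette exon and downstream intron coordinates (`up_start`,
#'   `up_end`, `exon_start`, `exon_end`, `down_start`, `down_end`).
#' @export
select_es_triplets <- function(es_junctions, untreated_diff, annotation,
                               min_intron = 100L, min_exon = 50L,
                               q_max = 0.05) {
  introns <- annotation$introns
  if (nrow(introns) == 0L || nrow(es_junctions) == 0L) {
    return(data.frame(chrom = character(), strand = character(),
                      up_start = integer(), up_end = integer(),
                      exon_start = integer(), exon_end = integer(),
                      down_start = integer(), down_end = integer(),
                      stringsAsFactors = FALSE))
  }
  pieces <- split(introns, introns$transcript_id)
  trips <- do.call(rbind, lapply(pieces, function(tx) {
    tx <- tx[order(tx$intron_rank), , drop = FALSE]
    if (nrow(tx) < 2) return(NULL)
    i <- seq_len(nrow(tx) - 1L)
    up <- tx[i, , drop = FALSE]
    dn <- tx[i + 1L, , drop = FALSE]
    # the skipped junction spans from the upstream intron's donor to the
    # downstream intron's acceptor; the cassette exon is the gap between
    # the two introns
    plus <- tx$strand[1] == "+"
    data.frame(
      chrom = tx$chrom[1], strand = tx$strand[1],
      skip_first = pmin(up$donor, dn$acceptor),
      skip_last = pmax(up$donor, dn$acceptor),
      up_start = up$start, up_end = up$end,
      exon_start = if (plus) up$end + 1L else dn$end + 1L,
      exon_end = if (plus) dn$start - 1L else up$start - 1L,
      down_start = dn$start, down_end = dn$end,
      up_key = junction_key(up$chrom, up$start, up$end, up$strand),
      down_key = junction_key(dn$chrom, dn$start, dn$end, dn$strand),
      stringsAsFactors = FALSE
    )
  }))
  jkey <- junction_key(es_junctions$chrom, es_junctions$intron_first,
                       es_junctions$intron_last, es_junctions$strand)
  trips <- trips[paste(trips$chrom, trips$skip_first, trips$skip_last,
                       trips$strand, sep = ":") %in% jkey, , drop = FALSE]
  up_len <- trips$up_end - trips$up_start + 1L
  dn_len <- trips$down_end - trips$down_start + 1L
  ex_len <- trips$exon_end - trips$exon_start + 1L
  keep <- up_len >= min_intron & dn_len >= min_intron & ex_len >= min_exon
  if (!is.null(untreated_diff)) {
    qs <- untreated_diff$q[match(trips$up_key, untreated_diff$event_key)]
    qd <- untreated_diff$q[match(trips$down_key, untreated_diff$event_key)]
    keep <- keep & !is.na(qs) & qs < q_max & !is.na(qd) & qd < q_max
  }
  out <- trips[keep, c("chrom", "strand", "up_start", "up_end", "exon_start",
                       "exon_end", "down_start", "down_end"), drop = FALSE]
  rownames(out) <- NULL
  unique(out)
}

#' Per-pair GC bin matrix for intron/downstream-exon pairs
#'
#' @param pairs output of [select_ir_pairs()] or [sample_background()].
#' @param genome named sequences ([read_genome_fasta()]).
#' @param intron_bins,exon_bins bin counts (defaults 100 and 50).
#' @return numeric matrix, pairs x (intron_bins + exon_bins), bins
#'   ordered 5' to 3' along the transcript, with a `layout` attribute.
#' @export
ir_pair_gc_matrix <- function(pairs, genome, intron_bins = 100L,
                              exon_bins = 50L) {
  n <- nrow(pairs)
  m <- matrix(NA_real_, n, intron_bins + exon_bins)
  for (i in seq_len(n)) {
    iseq <- feature_sequence(genome, pairs$chrom[i], pairs$intron_start[i],
                             pairs$intron_end[i], pairs$strand[i])
    eseq <- feature_sequence(genome, pairs$chrom[i], pairs$exon_start[i],
                             pairs$exon_end[i], pairs$strand[i])
    m[i, ] <- c(bin_gc(iseq, intron_bins), bin_gc(eseq, exon_bins))
  }
  attr(m, "layout") <- c(intron = intron_bins, exon = exon_bins)
  m
}

#' Per-triplet GC bin matrix for cassette-exon triplets
#'
#' @param triplets output of [select_es_triplets()].
#' @param genome named sequences.
#' @param intron_bins,exon_bins bin counts (defaults 100 and 50).
#' @return numeric matrix, triplets x (2 * intron_bins + exon_bins),
#'   segments ordered upstream intron, cassette exon, downstream intron
#'   along the transcript, with a `layout` attribute.
#' @export
es_triplet_gc_matrix <- function(triplets, genome, intron_bins = 100L,
                                 exon_bins = 50L) {
  n <- nrow(triplets)
  m <- matrix(NA_real_, n, 2L * intron_bins + exon_bins)
  for (i in seq_len(n)) {
    u <- feature_sequence(genome, triplets$chrom[i], triplets$up_start[i],
                          triplets$up_end[i], triplets$strand[i])
    e <- feature_sequence(genome, triplets$chrom[i], triplets$exon_start[i],
                          triplets$exon_end[i], triplets$strand[i])
    d <- feature_sequence(genome, triplets$chrom[i], triplets$down_start[i],
                          triplets$down_end[i], triplets$strand[i])
    m[i, ] <- c(bin_gc(u, intron_bins), bin_gc(e, exon_bins),
                bin_gc(d, intron_bins))
  }
  attr(m, "layout") <- c(upstream_intron = intron_bins, exon = exon_bins,
                         downstream_intron = intron_bins)
  m
}

#' Mean GC profile with percentile bootstrap confidence interval
#'
#' Per-bin mean over pairs, with a 95% interval from the 2.5 and 97.5
#' percentiles of `n_boot` bootstrap means; each bootstrap resamples
#' whole pairs (rows) with replacement, never individual bins.
#'
#' @param gc_matrix pairs x bins matrix
#'   ([ir_pair_gc_matrix()]/[es_triplet_gc_matrix()]), with a `layout`
#'   attribute naming the segments.
#' @param n_boot number of bootstrap resamples (default 100).
#' @param seed integer seed for the resampling.
#' @param conf confidence level (default 0.95).
#' @return data.frame of class `gc_profile`: `segment`, `bin` (index
#'   within segment), `mean`, `ci_lo`, `ci_hi`, with attributes
#'   `n_pairs` and `n_boot`.
#' @export
profile_with_bootstrap <- function(gc_matrix, n_boot = 100L, seed = 1L,
                                   conf = 0.95) {
  n <- nrow(gc_matrix)
  if (is.null(n) || n < 1L) stop("at least one pair required")
  mu <- colMeans(gc_matrix, na.rm = TRUE)
  set.seed(seed)
  boots <- matrix(NA_real_, n_boot, ncol(gc_matrix))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    boots[b, ] <- colMeans(gc_matrix[idx, , drop = FALSE], na.rm = TRUE)
  }
  alpha <- (1 - conf) / 2
  ci <- apply(boots, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              na.rm = TRUE, names = FALSE)
  layout <- attr(gc_matrix, "layout") %||% c(all = ncol(gc_matrix))
  out <- data.frame(
    segment = rep(names(layout), layout),
    bin = unlist(lapply(layout, seq_len), use.names = FALSE),
    mean = mu, ci_lo = ci[1, ], ci_hi = ci[2, ],
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "n_pairs") <- n
  attr(out, "n_boot") <- n_boot
  class(out) <- c("gc_profile", "data.frame")
  out
}

#' Random background intron/exon pairs under the foreground filters
#'
#' Draws `n` pairs uniformly from the universe of annotated
#' (intron, downstream exon) pairs satisfying the same length and
#' boundary requirements as the foreground selector — without
#' replacement when the universe is large enough, otherwise with
#' replacement (with a warning).
#'
#' @param annotation an `annotation_model`.
#' @param n number of background pairs (default 10000).
#' @param seed integer seed.
#' @param min_intron,min_exon the foreground length filters.
#' @return data.frame of pairs in the [select_ir_pairs()] layout.
#' @export
sample_background <- function(annotation, n = 10000L, seed = 1L,
                              min_intron = 100L, min_exon = 50L) {
  universe <- intron_exon_pair_universe(annotation, min_intron, min_exon)
  if (nrow(universe) == 0L) stop("no annotated pair satisfies the filters")
  set.seed(seed)
  replace <- nrow(universe) < n
  if (replace) {
    warning("only ", nrow(universe), " qualifying pairs for a background of ",
            n, "; sampling with replacement")
  }
  idx <- sample.int(nrow(universe), n, replace = replace)
  out <- universe[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a GC profile as TSV
#'
#' @param profile a `gc_profile`.
#' @param path output path.
#' @export
write_gc_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# GC metagene profile; n_pairs=", attr(profile, "n_pairs"),
                    " n_boot=", attr(profile, "n_boot"),
                    "; GC fraction per bin, bins 5'->3' on transcript"), con)
  utils::write.table(as.data.frame(profile), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
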