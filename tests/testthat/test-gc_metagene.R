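# GC metagene machinery: binning oracle, pair/triplet selection filters,
# bootstrap intervals, background parity and strand correctness.

test_that("bin_gc handles degenerate and exact cases", {
  expect_equal(bin_gc(strrep("GC", 30), 10), rep(1, 10))
  expect_equal(bin_gc("ATGCATGCAT", 1), 0.4)   # global GC fraction
  expect_error(bin_gc("ACGT", 5), "shorter")
  # N bases drop out of numerator and denominator
  expect_equal(bin_gc("GNAN", 2), c(1, 0))
  expect_true(is.nan(bin_gc("NN", 1)))
})

test_that("bin_gc matches the per-base counting oracle on random input", {
  set.seed(17)
  for (rep in 1:60) {
    L <- sample(100:400, 1)
    n_bins <- sample(c(7, 50, 100), 1)
    s <- paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                      prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
               collapse = "")
    expect_equal(bin_gc(s, n_bins), bin_gc_oracle(s, n_bins))
  }
  # the stated fixed case: 257 nt into 100 bins (sizes differ by <= 1)
  s <- random_dna(257)
  expect_equal(bin_gc(s, 100), bin_gc_oracle(s, 100))
})

# annotation with tunable intron/exon lengths around one cassette site
length_filter_annotation <- function(intron_len, exon_len) {
  e1 <- c(1L, 100L)
  i1 <- c(101L, 100L + intron_len)
  e2 <- c(i1[2] + 1L, i1[2] + exon_len)
  build_annotation_model(data.frame(
    transcript_id = "t", gene_id = "g", chrom = "c1",
    start = c(e1[1], e2[1]), end = c(e1[2], e2[2]), strand = "+",
    stringsAsFactors = FALSE
  ))
}

test_that("IR pair selection enforces the stated length boundaries", {
  site99 <- site_key("c1", 199L, "+")
  ann99 <- length_filter_annotation(99L, 60L)
  expect_equal(nrow(select_ir_pairs(site99, ann99)), 0L)
  ann100 <- length_filter_annotation(100L, 50L)
  pairs <- select_ir_pairs(site_key("c1", 200L, "+"), ann100)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$intron_start, 101L)
  expect_equal(pairs$exon_end - pairs$exon_start + 1L, 50L)
  ann49 <- length_filter_annotation(100L, 49L)
  expect_equal(nrow(select_ir_pairs(site_key("c1", 200L, "+"), ann49)), 0L)
})

test_that("random exon choice among candidates is seed-reproducible", {
  # two transcripts sharing the acceptor but with different downstream exons
  exons <- rbind(
    data.frame(transcript_id = "tA", gene_id = "g", chrom = "c1",
               start = c(1L, 301L), end = c(100L, 400L), strand = "+",
               stringsAsFactors = FALSE),
    data.frame(transcript_id = "tB", gene_id = "g", chrom = "c1",
               start = c(1L, 301L), end = c(100L, 460L), strand = "+",
               stringsAsFactors = FALSE)
  )
  ann <- build_annotation_model(exons)
  s <- site_key("c1", 300L, "+")
  p1 <- select_ir_pairs(s, ann, seed = 5L)
  p2 <- select_ir_pairs(s, ann, seed = 5L)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 1L)
  picks <- vapply(1:40, function(sd) {
    select_ir_pairs(s, ann, seed = sd)$exon_end
  }, integer(1))
  expect_equal(sort(unique(picks)), c(400L, 460L))
})

test_that("ES triplet selection applies every stated filter", {
  ann <- toy_annotation()
  es_plus <- data.frame(chrom = "chr1", intron_first = 201L,
                        intron_last = 500L, strand = "+",
                        stringsAsFactors = FALSE)
  evidence <- data.frame(event_key = c("chr1:201:300:+", "chr1:401:500:+"),
                         q = c(0.01, 0.01), stringsAsFactors = FALSE)
  t1 <- select_es_triplets(es_plus, evidence, ann)
  expect_equal(nrow(t1), 1L)
  expect_equal(c(t1$up_start, t1$up_end), c(201L, 300L))
  expect_equal(c(t1$exon_start, t1$exon_end), c(301L, 400L))
  expect_equal(c(t1$down_start, t1$down_end), c(401L, 500L))
  # untreated-inclusion filter at q = 0.06 excludes the triplet
  evidence$q[1] <- 0.06
  expect_equal(nrow(select_es_triplets(es_plus, evidence, ann)), 0L)
  # a junction spanning two annotated exons never matches a single-exon
  # skip and is excluded
  multi <- data.frame(chrom = "chr1", intron_first = 201L,
                      intron_last = 700L, strand = "+",
                      stringsAsFactors = FALSE)
  expect_equal(nrow(select_es_triplets(multi, NULL, ann)), 0L)
  # minus-strand triplet: upstream intron is the genomically higher one
  es_minus <- data.frame(chrom = "chr1", intron_first = 1201L,
                         intron_last = 1500L, strand = "-",
                         stringsAsFactors = FALSE)
  tm <- select_es_triplets(es_minus, NULL, ann)
  expect_equal(nrow(tm), 1L)
  expect_equal(c(tm$up_start, tm$up_end), c(1401L, 1500L))
  expect_equal(c(tm$down_start, tm$down_end), c(1201L, 1300L))
})

test_that("bootstrap profile brackets the mean and is seed-deterministic", {
  set.seed(3)
  m <- matrix(runif(200 * 30, 0.3, 0.7), 200, 30)
  attr(m, "layout") <- c(intron = 20L, exon = 10L)
  p1 <- profile_with_bootstrap(m, n_boot = 50, seed = 4)
  p2 <- profile_with_bootstrap(m, n_boot = 50, seed = 4)
  expect_identical(p1, p2)
  expect_true(all(p1$ci_lo <= p1$mean + 1e-12))
  expect_true(all(p1$ci_hi >= p1$mean - 1e-12))
  expect_equal(p1$mean, colMeans(m), ignore_attr = TRUE)
  expect_equal(table(p1$segment)[["intron"]], 20L)
  # identical pairs give zero-width intervals
  m0 <- matrix(0.42, 10, 15)
  p0 <- profile_with_bootstrap(m0, n_boot = 20, seed = 1)
  expect_true(all(p0$ci_hi - p0$ci_lo == 0))
  expect_true(all(p0$mean == 0.42))
})

test_that("bootstrap 95% intervals cover a planted flat truth", {
  set.seed(99)
  truth <- 0.5
  m <- matrix(pmin(pmax(rnorm(200 * 100, truth, 0.05), 0), 1), 200, 100)
  attr(m, "layout") <- c(intron = 100L)
  p <- profile_with_bootstrap(m, n_boot = 100, seed = 12)
  covered <- sum(p$ci_lo <= truth & p$ci_hi >= truth)
  expect_gte(covered, 88)
})

test_that("background sampling matches the foreground filter universe", {
  cfg <- sim_config(n_loci = 60, master_seed = 3)
  gen <- make_genome_and_annotation(cfg)
  expect_warning(bg <- sample_background(gen$annotation, n = 500, seed = 2),
                 "replacement")
  # every background pair passes the foreground selector's filters
  expect_true(all(bg$intron_end - bg$intron_start + 1L >= 100L))
  expect_true(all(bg$exon_end - bg$exon_start + 1L >= 50L))
  keys <- unique(bg$site_key)
  reselected <- select_ir_pairs(keys, gen$annotation, seed = 1)
  expect_setequal(reselected$site_key, keys)
  # degenerate universe errors
  empty <- build_annotation_model(data.frame(
    transcript_id = "t", gene_id = "g", chrom = "c", start = 1L, end = 50L,
    strand = "+", stringsAsFactors = FALSE))
  expect_error(sample_background(empty, 10), "no annotated pair")
})

test_that("profiles follow transcript orientation and GC is strand-symmetric", {
  # plant a 5'->3' GC gradient along a minus-strand intron: the profile
  # must rise along the transcript, i.e. toward lower genomic coordinates
  exon_seq <- flat_seq(60, 0.5)
  low_gc <- flat_seq(100, 0.2)    # genomically right = transcript 5' start
  high_gc <- flat_seq(100, 0.8)   # genomically left = transcript 3' end
  chrom <- paste0(flat_seq(10, 0.5), exon_seq, paste0(high_gc, low_gc),
                  exon_seq, flat_seq(10, 0.5))
  genome <- c(c1 = chrom)
  exons <- data.frame(transcript_id = "t", gene_id = "g", chrom = "c1",
                      start = c(11L, 271L), end = c(70L, 330L), strand = "-",
                      stringsAsFactors = FALSE)
  ann <- build_annotation_model(exons)
  pairs <- select_ir_pairs(site_key("c1", 71L, "-"), ann)
  expect_equal(nrow(pairs), 1L)
  m <- ir_pair_gc_matrix(pairs, genome)
  gc_bins <- m[1, 1:100]
  expect_lt(mean(gc_bins[1:50]), 0.3)    # transcript 5' half is low GC
  expect_gt(mean(gc_bins[51:100]), 0.7)  # transcript 3' half is high GC
  # reverse-complementing the genome and flipping the annotation leaves
  # the profile unchanged
  L <- nchar(chrom)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(chrom)))
  flip <- function(x) L - x + 1L
  exons_rc <- data.frame(transcript_id = "t", gene_id = "g", chrom = "c1",
                         start = flip(exons$end), end = flip(exons$start),
                         strand = "+", stringsAsFactors = FALSE)
  ann_rc <- build_annotation_model(exons_rc)
  pairs_rc <- select_ir_pairs(site_key("c1", flip(71L), "+"), ann_rc)
  m_rc <- ir_pair_gc_matrix(pairs_rc, c(c1 = rc))
  expect_equal(m_rc[1, ], m[1, ])
})
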