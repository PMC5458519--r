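# Shared fixtures: a toy two-gene annotation (one gene per strand) and
# small sequence builders.  All fixtures are constructed in code.

toy_exons <- function() {
  rbind(
    data.frame(transcript_id = "txp", gene_id = "gplus", chrom = "chr1",
               start = c(101L, 301L, 501L), end = c(200L, 400L, 600L),
               strand = "+", stringsAsFactors = FALSE),
    data.frame(transcript_id = "txm", gene_id = "gminus", chrom = "chr1",
               start = c(1101L, 1301L, 1501L), end = c(1200L, 1400L, 1600L),
               strand = "-", stringsAsFactors = FALSE)
  )
}

toy_annotation <- function() build_annotation_model(toy_exons())

# deterministic sequence of given length/GC (no RNG side effects)
flat_seq <- function(len, gc) {
  n_gc <- round(len * gc)
  paste(c(rep(c("G", "C"), length.out = n_gc),
          rep(c("A", "T"), length.out = len - n_gc)), collapse = "")
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# per-base counting oracle for binned GC, using the same floor boundary
# rule but computed base-by-base rather than via the package path
bin_gc_oracle <- function(sequence, n_bins) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  L <- length(chars)
  out <- numeric(n_bins)
  for (k in seq_len(n_bins)) {
    lo <- floor((k - 1) * L / n_bins) + 1
    hi <- floor(k * L / n_bins)
    gc <- 0; informative <- 0
    for (j in lo:hi) {
      if (chars[j] != "N") {
        informative <- informative + 1
        if (chars[j] %in% c("G", "C")) gc <- gc + 1
      }
    }
    out[k] <- if (informative == 0) NaN else gc / informative
  }
  out
}

# small clone-variant fixture shaped like a two-arm resistance screen:
# gene A mutated in 5 arm-1 clones + 2 arm-2 clones, gene B in 1 arm-1
# clone + 4 arm-2 clones, one arm-2 clone carrying both; passengers and
# sub-threshold records included as negative controls
resistance_fixture <- function() {
  v <- rbind(
    data.frame(clone_id = paste0("e", 1:5), gene = "SF3B1",
               protein_change = c("R1074H", "V1078A", "V1078I", "R1074H",
                                  "V1078A"),
               effect_class = "missense", allele_frequency = 0.45,
               arm = "E7107", stringsAsFactors = FALSE),
    data.frame(clone_id = paste0("h", 1:2), gene = "SF3B1",
               protein_change = "K1071E", effect_class = "missense",
               allele_frequency = 0.4, arm = "herboxidiene",
               stringsAsFactors = FALSE),
    data.frame(clone_id = "e6", gene = "PHF5A", protein_change = "Y36C",
               effect_class = "missense", allele_frequency = 0.5,
               arm = "E7107", stringsAsFactors = FALSE),
    data.frame(clone_id = paste0("h", 2:5), gene = "PHF5A",
               protein_change = "Y36C", effect_class = "missense",
               allele_frequency = 0.48, arm = "herboxidiene",
               stringsAsFactors = FALSE),
    # negative controls: low AF, silent, unlisted gene, duplicate in clone
    data.frame(clone_id = c("e1", "e2", "e3", "e1"),
               gene = c("SF3B1", "SF3B1", "TP53", "SF3B1"),
               protein_change = c("A10T", "L20L", "R175H", "G30S"),
               effect_class = c("missense", "synonymous", "missense",
                                "missense"),
               allele_frequency = c(0.15, 0.9, 0.8, 0.3),
               arm = "E7107", stringsAsFactors = FALSE)
  )
  rownames(v) <- NULL
  v
}

spliceosome_gene_list <- c("SF3B1", "PHF5A", "SF3B3", "U2AF1")
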