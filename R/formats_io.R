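# Readers and writers for the external table formats the pipeline touches.
#
# Internal coordinate convention: 1-based, inclusive, everywhere.  BED input
# (0-based, half-open) is shifted at the I/O boundary and nowhere else.

STRAND_CODES <- c("0" = "*", "1" = "+", "2" = "-")
NON_SILENT_EFFECTS <- c("missense", "nonsense", "frameshift",
                        "inframe_indel", "splice_site")

# canonical synonyms for common effect annotations (SO / ANN style terms)
EFFECT_SYNONYMS <- c(
  missense                      = "missense",
  missense_variant              = "missense",
  nonsense                      = "nonsense",
  stop_gained                   = "nonsense",
  stop_lost                     = "nonsense",
  frameshift                    = "frameshift",
  frameshift_variant            = "frameshift",
  inframe_indel                 = "inframe_indel",
  inframe_insertion             = "inframe_indel",
  inframe_deletion              = "inframe_indel",
  splice_site                   = "splice_site",
  splice_acceptor_variant       = "splice_site",
  splice_donor_variant          = "splice_site",
  synonymous                    = "synonymous",
  synonymous_variant            = "synonymous",
  silent                        = "synonymous"
)

#' Read a splice-junction count table
#'
#' Parses the 9-column whitespace-separated junction-table dialect written
#' by the STAR aligner (`SJ.out.tab`): chromosome, first and last intronic
#' base (1-based, inclusive), strand code (0 = undetermined, 1 = `+`,
#' 2 = `-`), intron motif, annotation flag, uniquely-mapping read count,
#' multi-mapping read count, maximum overhang.  Only the unique read count
#' is retained; multi-mapping counts are ignored.
#'
#' @param path path to the junction table.
#' @param sample optional sample label stored in the `sample` column.
#' @return A `data.frame` with columns `chrom`, `intron_first`,
#'   `intron_last`, `strand` (`"+"`, `"-"` or `"*"` for undetermined),
#'   `unique_reads`, `strand_known` (logical flag) and `sample`.
#' @export
read_junction_table <- function(path, sample = NA_character_) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty junction table: ", path)
    return(empty_junction_frame(sample))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  nfield <- lengths(fields)
  if (any(nfield < 7L)) {
    stop("malformed junction row (fewer than 7 columns) at line ",
         which(nfield < 7L)[1L], " of ", path)
  }
  mat <- t(vapply(fields, function(f) f[1:7], character(7)))
  # non-numeric fields surface as NA and are reported with a line number
  intron_first <- suppressWarnings(as.integer(mat[, 2]))
  intron_last <- suppressWarnings(as.integer(mat[, 3]))
  unique_reads <- suppressWarnings(as.integer(mat[, 7]))
  if (anyNA(intron_first) || anyNA(intron_last) || anyNA(unique_reads)) {
    bad <- which(is.na(intron_first) | is.na(intron_last) | is.na(unique_reads))[1L]
    stop("malformed junction row (non-numeric field) at line ", bad, " of ", path)
  }
  if (any(unique_reads < 0L)) {
    stop("negative unique read count at line ", which(unique_reads < 0L)[1L],
         " of ", path)
  }
  if (any(intron_first > intron_last)) {
    stop("intron start exceeds intron end at line ",
         which(intron_first > intron_last)[1L], " of ", path)
  }
  code <- mat[, 4]
  if (!all(code %in% names(STRAND_CODES))) {
    stop("unknown strand code at line ",
         which(!code %in% names(STRAND_CODES))[1L], " of ", path)
  }
  strand <- unname(STRAND_CODES[code])
  data.frame(
    chrom = mat[, 1], intron_first = intron_first, intron_last = intron_last,
    strand = strand, unique_reads = unique_reads,
    strand_known = strand != "*", sample = sample,
    stringsAsFactors = FALSE
  )
}

#' @noRd
empty_junction_frame <- function(sample = NA_character_) {
  data.frame(chrom = character(), intron_first = integer(),
             intron_last = integer(), strand = character(),
             unique_reads = integer(), strand_known = logical(),
             sample = character(), stringsAsFactors = FALSE)
}

#' Write a junction table in the 9-column dialect
#'
#' Inverse of [read_junction_table()]; motif and annotation columns are
#' written as 0 and the multi-mapping count as 0 (they carry no
#' information used by this pipeline).
#'
#' @param junctions junction `data.frame` as returned by
#'   [read_junction_table()].
#' @param path output path.
#' @export
write_junction_table <- function(junctions, path) {
  code <- names(STRAND_CODES)[match(junctions$strand, STRAND_CODES)]
  tab <- data.frame(junctions$chrom, junctions$intron_first,
                    junctions$intron_last, code, 0L, 0L,
                    junctions$unique_reads, 0L, 50L)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a transcript annotation (BED12 or minimal GTF)
#'
#' Builds the internal annotation model: per-transcript exons ordered 5'
#' to 3' on the transcript strand, with introns derived as the genomic
#' gaps between consecutive exons.  BED12 blocks (0-based half-open) are
#' shifted to the internal 1-based inclusive convention on input; GTF
#' `exon` features (already 1-based inclusive) are grouped by their
#' `transcript_id` attribute.
#'
#' @param path annotation file path.
#' @param format `"bed12"` or `"gtf"`; `"auto"` guesses from the
#'   extension.
#' @return An object of class `annotation_model`: a list with `exons` and
#'   `introns` data frames.  Exon rows carry `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `exon_rank` (1 = 5'-most on the
#'   transcript).  Intron rows carry the same keys plus `intron_rank`,
#'   `donor` and `acceptor` genomic positions.
#' @export
read_annotation <- function(path, format = c("auto", "bed12", "gtf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed[0-9]*$", path, ignore.case = TRUE)) "bed12" else "gtf"
  }
  exons <- switch(format,
    bed12 = parse_bed12_exons(path),
    gtf = parse_gtf_exons(path)
  )
  build_annotation_model(exons)
}

#' @noRd
parse_bed12_exons <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 12L) stop("BED12 requires 12 columns, found ", ncol(raw))
  out <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    chrom <- raw[i, 1]; chrom_start <- raw[i, 2]; name <- raw[i, 4]
    strand <- raw[i, 6]; n_blocks <- raw[i, 10]
    sizes <- as.integer(strsplit(sub(",$", "", raw[i, 11]), ",")[[1]])
    starts <- as.integer(strsplit(sub(",$", "", raw[i, 12]), ",")[[1]])
    if (length(sizes) != n_blocks || length(starts) != n_blocks) {
      stop("BED12 block count mismatch for transcript ", name)
    }
    out[[i]] <- data.frame(
      transcript_id = name, gene_id = name, chrom = chrom,
      start = chrom_start + starts + 1L,       # 0-based -> 1-based
      end = chrom_start + starts + sizes,      # half-open -> inclusive
      strand = strand, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' @noRd
parse_gtf_exons <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t")
  keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "exon", logical(1))
  fields <- fields[keep]
  if (length(fields) == 0L) stop("no exon features found in ", path)
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, "[ =]+\"?([^\";]+)\"?"), attrs))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  do.call(rbind, lapply(fields, function(f) {
    tid <- attr_get(f[9], "transcript_id")
    gid <- attr_get(f[9], "gene_id")
    if (is.na(tid)) stop("GTF exon feature without transcript_id attribute")
    data.frame(transcript_id = tid,
               gene_id = if (is.na(gid)) tid else gid,
               chrom = f[1], start = as.integer(f[4]), end = as.integer(f[5]),
               strand = f[7], stringsAsFactors = FALSE)
  }))
}

#' Assemble an annotation model from an exon table
#'
#' Orders exons 5' to 3' on the transcript strand, validates that exons
#' within a transcript do not overlap, and derives introns as the gaps
#' between consecutive exons.
#'
#' @param exons data.frame with `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (1-based inclusive coordinates).
#' @return An `annotation_model` object.
#' @export
build_annotation_model <- function(exons) {
  stopifnot(all(c("transcript_id", "gene_id", "chrom", "start", "end",
                  "strand") %in% names(exons)))
  pieces <- split(exons, exons$transcript_id)
  exon_rows <- vector("list", length(pieces))
  intron_rows <- vector("list", length(pieces))
  for (i in seq_along(pieces)) {
    tx <- pieces[[i]]
    tx <- tx[order(tx$start), ]
    if (nrow(tx) > 1 && any(tx$start[-1] <= tx$end[-nrow(tx)])) {
      stop("overlapping exons in transcript ", tx$transcript_id[1])
    }
    minus <- tx$strand[1] == "-"
    ord <- if (minus) rev(seq_len(nrow(tx))) else seq_len(nrow(tx))
    tx$exon_rank <- NA_integer_
    tx$exon_rank[ord] <- seq_len(nrow(tx))
    exon_rows[[i]] <- tx
    if (nrow(tx) > 1) {
      # genomic gaps between consecutive exons (tx is sorted by start)
      g_first <- tx$end[-nrow(tx)] + 1L
      g_last <- tx$start[-1] - 1L
      if (any(g_last < g_first)) {
        stop("zero-length intron in transcript ", tx$transcript_id[1])
      }
      n_int <- nrow(tx) - 1L
      rank <- if (minus) rev(seq_len(n_int)) else seq_len(n_int)
      intron_rows[[i]] <- data.frame(
        transcript_id = tx$transcript_id[1], gene_id = tx$gene_id[1],
        chrom = tx$chrom[1], start = g_first, end = g_last,
        strand = tx$strand[1], intron_rank = rank,
        donor = if (minus) g_last else g_first,
        acceptor = if (minus) g_first else g_last,
        stringsAsFactors = FALSE
      )
    }
  }
  introns <- do.call(rbind, intron_rows[!vapply(intron_rows, is.null, logical(1))])
  if (is.null(introns)) {
    introns <- data.frame(transcript_id = character(), gene_id = character(),
                          chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          intron_rank = integer(), donor = integer(),
                          acceptor = integer(), stringsAsFactors = FALSE)
  }
  structure(list(exons = do.call(rbind, exon_rows), introns = introns),
            class = "annotation_model")
}

#' @export
print.annotation_model <- function(x, ...) {
  cat("annotation_model:", length(unique(x$exons$transcript_id)),
      "transcripts,", nrow(x$exons), "exons,", nrow(x$introns), "introns\n")
  invisible(x)
}

#' Write an annotation model as BED12
#'
#' Inverse of [read_annotation()] for the BED12 format; coordinates are
#' shifted back to the 0-based half-open convention on output.
#'
#' @param annotation an `annotation_model`.
#' @param path output path.
#' @export
write_annotation_bed12 <- function(annotation, path) {
  pieces <- split(annotation$exons, annotation$exons$transcript_id)
  rows <- vapply(pieces, function(tx) {
    tx <- tx[order(tx$start), ]
    chrom_start <- tx$start[1] - 1L
    chrom_end <- tx$end[nrow(tx)]
    sizes <- paste0(paste(tx$end - tx$start + 1L, collapse = ","), ",")
    starts <- paste0(paste(tx$start - 1L - chrom_start, collapse = ","), ",")
    paste(tx$chrom[1], chrom_start, chrom_end, tx$transcript_id[1], 0,
          tx$strand[1], chrom_start, chrom_end, "0", nrow(tx), sizes, starts,
          sep = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Read per-3'-splice-site boundary read counts
#'
#' Boundary counts quantify intron retention: reads crossing the
#' exon-intron boundary at a 3' splice site.  The format is a 4-column
#' TSV: sample, site key (`chrom:pos:strand`, pos = acceptor genomic
#' position, 1-based), read count, free-text note.
#'
#' @param path TSV path.
#' @return data.frame with `sample`, `chrom`, `pos`, `strand`,
#'   `site_key`, `reads`, `note`.
#' @export
read_boundary_counts <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("sample", "site", "reads", "note"),
                           colClasses = c("character", "character",
                                          "integer", "character"))
  if (nrow(raw) == 0L) {
    return(data.frame(sample = character(), chrom = character(),
                      pos = integer(), strand = character(),
                      site_key = character(), reads = integer(),
                      note = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(raw$site, ":", fixed = TRUE)
  if (any(lengths(parts) != 3L)) {
    stop("malformed site key (expected chrom:pos:strand) at row ",
         which(lengths(parts) != 3L)[1L])
  }
  if (any(raw$reads < 0L)) {
    stop("negative boundary read count at row ", which(raw$reads < 0L)[1L])
  }
  mat <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
  data.frame(sample = raw$sample, chrom = mat[, 1],
             pos = as.integer(mat[, 2]), strand = mat[, 3],
             site_key = raw$site, reads = raw$reads, note = raw$note,
             stringsAsFactors = FALSE)
}

#' Write boundary counts in the 4-column TSV format
#'
#' @param boundaries data.frame as returned by [read_boundary_counts()].
#' @param path output path.
#' @export
write_boundary_counts <- function(boundaries, path) {
  tab <- data.frame(boundaries$sample, boundaries$site_key,
                    boundaries$reads, boundaries$note)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-clone variant table (TSV or minimal VCF)
#'
#' TSV format: 5 columns (clone_id, gene, protein_change, effect,
#' allele_frequency).  Minimal VCF: `AF=`, `GENE=`, `AA=` and `EFFECT=`
#' keys in INFO, clone identity in a `CLONE=` key.  Effect strings are
#' mapped to the canonical classes (`missense`, `nonsense`, `frameshift`,
#' `inframe_indel`, `splice_site`, `synonymous`); unknown strings map to
#' `"other"`.
#'
#' @param path file path.
#' @param format `"tsv"`, `"vcf"` or `"auto"` (guessed from extension).
#' @return data.frame with `clone_id`, `gene`, `protein_change`,
#'   `effect_class`, `allele_frequency`.
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  out <- if (format == "tsv") read_variants_tsv(path) else read_variants_vcf(path)
  if (any(out$allele_frequency < 0 | out$allele_frequency > 1)) {
    bad <- which(out$allele_frequency < 0 | out$allele_frequency > 1)[1L]
    stop("allele frequency outside [0, 1] for variant ", out$gene[bad], " ",
         out$protein_change[bad], " in clone ", out$clone_id[bad])
  }
  out$effect_class <- map_effect_class(out$effect_class)
  out
}

#' @noRd
read_variants_tsv <- function(path) {
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) == 1L) {  # tolerate space-separated tables
    raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  }
  if (ncol(raw) < 5L) stop("variant TSV requires 5 columns, found ", ncol(raw))
  data.frame(clone_id = as.character(raw[, 1]), gene = as.character(raw[, 2]),
             protein_change = as.character(raw[, 3]),
             effect_class = as.character(raw[, 4]),
             allele_frequency = as.numeric(raw[, 5]),
             stringsAsFactors = FALSE)
}

#' @noRd
read_variants_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(clone_id = character(), gene = character(),
                      protein_change = character(), effect_class = character(),
                      allele_frequency = numeric(), stringsAsFactors = FALSE))
  }
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(^|;)", key, "=([^;]+)"), info))[[1]]
    if (length(m) < 3) NA_character_ else m[3]
  }
  do.call(rbind, lapply(lines, function(ln) {
    f <- strsplit(ln, "\t")[[1]]
    if (length(f) < 8) stop("malformed VCF record: ", ln)
    info <- f[8]
    af <- info_get(info, "AF")
    if (is.na(af)) {
      stop("VCF record lacking AF in INFO: ", f[1], ":", f[2])
    }
    data.frame(clone_id = info_get(info, "CLONE"),
               gene = info_get(info, "GENE"),
               protein_change = info_get(info, "AA"),
               effect_class = info_get(info, "EFFECT"),
               allele_frequency = as.numeric(af), stringsAsFactors = FALSE)
  }))
}

#' Map free-text effect strings to canonical effect classes
#'
#' @param effects character vector of effect annotations.
#' @return character vector over `{missense, nonsense, frameshift,
#'   inframe_indel, splice_site, synonymous, other}`.
#' @export
map_effect_class <- function(effects) {
  mapped <- unname(EFFECT_SYNONYMS[tolower(effects)])
  mapped[is.na(mapped)] <- "other"
  mapped
}

#' Write a variant table as 5-column TSV
#'
#' @param variants data.frame as returned by [read_variants()].
#' @param path output path.
#' @export
write_variants <- function(variants, path) {
  tab <- variants[, c("clone_id", "gene", "protein_change", "effect_class",
                      "allele_frequency")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a curated gene list (one symbol per line)
#'
#' @param path file path.
#' @return character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  genes <- trimws(readLines(path))
  genes <- genes[nzchar(genes) & !startsWith(genes, "#")]
  if (length(genes) == 0L) stop("empty gene list: ", path)
  unique(genes)
}
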