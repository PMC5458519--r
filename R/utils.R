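# Internal helpers shared across modules.

#' Derive a stage-specific child seed from a master seed
#'
#' A single master seed drives every stochastic stage of a run; each stage
#' receives its own child seed so that re-running one stage in isolation
#' reproduces its output without replaying the stages before it.
#'
#' @param master integer master seed.
#' @param stage character stage label (e.g. `"genome"`, `"counts"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage),
            length(stage) == 1L)
  chars <- utf8ToInt(stage)
  h <- sum(chars * seq_along(chars))
  val <- (abs(master) %% 65011 + 1) * 32749 + h * 7919
  as.integer(val %% 2147483646)
}

#' @noRd
site_key <- function(chrom, pos, strand) {
  paste(chrom, pos, strand, sep = ":")
}

#' @noRd
junction_key <- function(chrom, intron_first, intron_last, strand) {
  paste(chrom, intron_first, intron_last, strand, sep = ":")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
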