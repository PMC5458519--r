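# Moderated-t differential PSI between sample groups.
#
# Per-event residual variances are shrunk toward a prior estimated across
# events by empirical Bayes: sample variances are modelled as s2 ~
# s0^2 * F(df, d0), and (d0, s0^2) are fitted by matching the mean and
# variance of log(s2) to that scaled-F model through digamma/trigamma
# identities.  The moderated t replaces the per-event variance with the
# posterior value (d0*s0^2 + df*s2)/(d0 + df) and gains d0 degrees of
# freedom.

#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by Newton iteration on a
#' monotone transform; used by the prior moment-matching fit.
#'
#' @param y positive numeric vector.
#' @return numeric vector `x` with `trigamma(x) = y`.
#' @export
trigamma_inverse <- function(y) {
  stopifnot(all(y > 0))
  x <- 0.5 + 1 / y           # asymptotic start: trigamma(x) ~ 1/x + 1/(2x^2)
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

#' Fit the variance-shrinkage prior by moment matching
#'
#' Under the scaled-F model, `log(s2)` has mean
#' `log(s0^2) + digamma(df/2) - log(df/2) - digamma(d0/2) + log(d0/2)`
#' and variance `trigamma(df/2) + trigamma(d0/2)`.  Matching the observed
#' mean and variance of `log(s2)` gives closed-form estimates of the
#' prior degrees of freedom `d0` and prior variance `s0^2`.  When the
#' observed spread of `log(s2)` does not exceed what a common variance
#' would produce, the prior is degenerate: `d0 = Inf` and `s0^2` the mean
#' sample variance.
#'
#' @param sample_variances positive per-event residual variances.
#' @param residual_df residual degrees of freedom (scalar, or one value
#'   per event).
#' @return list with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
estimate_prior <- function(sample_variances, residual_df) {
  s2 <- sample_variances
  if (all(s2 == 0)) stop("all sample variances are zero; no prior can be fit")
  ok <- is.finite(s2) & s2 > 0 & is.finite(residual_df) & residual_df > 0
  if (length(residual_df) == 1L) residual_df <- rep(residual_df, length(s2))
  s2 <- s2[ok]
  df <- residual_df[ok]
  if (length(s2) < 2L) stop("need at least two events with positive variance")
  z <- log(s2)
  e_mean <- mean(z)
  e_var <- stats::var(z) - mean(trigamma(df / 2))
  if (e_var > 0) {
    d0 <- 2 * trigamma_inverse(e_var)
    s0_sq <- exp(e_mean - mean(digamma(df / 2) - log(df / 2)) +
                   digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- mean(s2)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated two-sample t-test on a PSI matrix
#'
#' For each event (row), compares the defined PSI values of the two
#' sample groups.  The per-event pooled residual variance is shrunk
#' toward the empirical-Bayes prior and the t statistic referred to a t
#' distribution with `df + d0` degrees of freedom (the normal limit when
#' `d0 = Inf`).  Events with fewer than `min_samples` defined values in
#' either group are reported as untestable (`NA` statistics).
#'
#' @param psi_matrix numeric matrix, events x samples; `NA` = undefined.
#' @param group_labels character/factor of length `ncol(psi_matrix)` with
#'   exactly two levels; `delta_psi` is mean(level 2) - mean(level 1).
#' @param prior optional list `(d0, s0_sq)`; fitted from the data with
#'   [estimate_prior()] when `NULL`.  `d0 = 0` reproduces the classic
#'   pooled-variance two-sample t-test.
#' @param min_samples minimum defined values per group (default 2).
#' @return data.frame with one row per event: `event_key`, `n1`, `n2`,
#'   `mean1`, `mean2`, `delta_psi`, `s2`, `s2_post`, `t_mod`, `df_total`,
#'   `p`, `q` (BH-adjusted), `testable`, plus the prior as attributes
#'   `d0` and `s0_sq`.
#' @export
moderated_t_test <- function(psi_matrix, group_labels, prior = NULL,
                             min_samples = 2L) {
  glev <- unique(as.character(group_labels))
  if (length(glev) != 2L) stop("exactly two groups required, got ", length(glev))
  m1 <- psi_matrix[, group_labels == glev[1], drop = FALSE]
  m2 <- psi_matrix[, group_labels == glev[2], drop = FALSE]
  if (ncol(m1) == 0L || ncol(m2) == 0L) stop("one group has no samples")
  n1 <- rowSums(!is.na(m1))
  n2 <- rowSums(!is.na(m2))
  mean1 <- ifelse(n1 > 0, rowMeans(m1, na.rm = TRUE), NA_real_)
  mean2 <- ifelse(n2 > 0, rowMeans(m2, na.rm = TRUE), NA_real_)
  ss1 <- rowSums((m1 - mean1)^2, na.rm = TRUE)
  ss2 <- rowSums((m2 - mean2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2L
  testable <- n1 >= min_samples & n2 >= min_samples & df > 0
  s2 <- ifelse(testable, (ss1 + ss2) / df, NA_real_)
  if (is.null(prior)) {
    prior <- estimate_prior(s2[testable], df[testable])
  }
  d0 <- prior$d0
  s0_sq <- prior$s0_sq
  delta <- mean2 - mean1
  if (is.infinite(d0)) {
    s2_post <- ifelse(testable, s0_sq, NA_real_)
  } else {
    s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(testable & se > 0, delta / se,
                  ifelse(testable & delta == 0, 0, NA_real_))
  df_total <- df + d0
  p <- rep(NA_real_, length(t_mod))
  idx <- which(testable & !is.na(t_mod))
  if (is.infinite(d0)) {
    p[idx] <- 2 * stats::pnorm(-abs(t_mod[idx]))
  } else {
    p[idx] <- 2 * stats::pt(-abs(t_mod[idx]), df_total[idx])
  }
  q <- rep(NA_real_, length(p))
  q[idx] <- bh_adjust(p[idx])
  res <- data.frame(
    event_key = rownames(psi_matrix) %||% as.character(seq_along(n1)),
    n1 = n1, n2 = n2, mean1 = mean1, mean2 = mean2, delta_psi = delta,
    s2 = s2, s2_post = s2_post, t_mod = t_mod, df_total = df_total,
    p = p, q = q, testable = testable, stringsAsFactors = FALSE
  )
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0_sq
  res
}

#' Benjamini-Hochberg step-up adjusted values
#'
#' `q_i = min over {j : p_(j) >= p_(i)} of min(1, p_(j) * m / j)`, the
#' step-up construction controlling the false discovery rate.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return q-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Classify splicing events against an annotation
#'
#' Junction events are compared to the annotated splice sites:
#' a junction matching an annotated intron exactly is `canonical`
#' (inclusion); one joining the donor of intron *i* to the acceptor of
#' intron *i+1* of the same transcript (skipping exactly the intervening
#' exon) is `ES`; one sharing only an annotated donor is `alt3`
#' (alternative acceptor) and only an annotated acceptor `alt5`; anything
#' else is `other`.  Boundary-count events at an annotated acceptor are
#' `IR`, elsewhere `other`.
#'
#' @param events data.frame with columns `type` (`"junction"` or
#'   `"boundary"`), `chrom`, `strand`, and either `intron_first` +
#'   `intron_last` (junctions) or `pos` (boundaries).
#' @param annotation an `annotation_model`.
#' @return character vector of categories, one per event row.
#' @export
classify_events <- function(events, annotation) {
  introns <- annotation$introns
  intron_keys <- junction_key(introns$chrom, introns$start, introns$end,
                              introns$strand)
  donor_keys <- site_key(introns$chrom, introns$donor, introns$strand)
  acceptor_keys <- site_key(introns$chrom, introns$acceptor, introns$strand)
  # skip-junction universe: donor of intron i joined to acceptor of
  # intron i+1 within one transcript
  skip_keys <- character(0)
  if (nrow(introns) > 0) {
    pieces <- split(introns, introns$transcript_id)
    skip_keys <- unlist(lapply(pieces, function(tx) {
      tx <- tx[order(tx$intron_rank), , drop = FALSE]
      if (nrow(tx) < 2) return(character(0))
      i <- seq_len(nrow(tx) - 1L)
      d <- tx$donor[i]
      a <- tx$acceptor[i + 1L]
      first <- pmin(d, a)
      last <- pmax(d, a)
      junction_key(tx$chrom[1], first, last, tx$strand[1])
    }), use.names = FALSE)
  }
  out <- character(nrow(events))
  is_j <- events$type == "junction"
  if (any(is_j)) {
    ev <- events[is_j, , drop = FALSE]
    plus <- ev$strand == "+"
    jkey <- junction_key(ev$chrom, ev$intron_first, ev$intron_last, ev$strand)
    dkey <- site_key(ev$chrom, ifelse(plus, ev$intron_first, ev$intron_last),
                     ev$strand)
    akey <- site_key(ev$chrom, ifelse(plus, ev$intron_last, ev$intron_first),
                     ev$strand)
    d_known <- dkey %in% donor_keys
    a_known <- akey %in% acceptor_keys
    cat_j <- ifelse(jkey %in% intron_keys, "canonical",
             ifelse(jkey %in% skip_keys, "ES",
             ifelse(d_known & !a_known, "alt3",
             ifelse(a_known & !d_known, "alt5", "other"))))
    out[is_j] <- cat_j
  }
  if (any(!is_j)) {
    ev <- events[!is_j, , drop = FALSE]
    bkey <- site_key(ev$chrom, ev$pos, ev$strand)
    out[!is_j] <- ifelse(bkey %in% acceptor_keys, "IR", "other")
  }
  out
}

#' Summarize significant differential splicing events by category
#'
#' Counts and fractions of events with `q <= q_max` per category, with
#' the distribution of PSI log2 fold changes
#' `log2((psi_treated + epsilon) / (psi_control + epsilon))` summarized
#' by quartiles and 1.5 x IQR whisker bounds.
#'
#' @param diff_results output of [moderated_t_test()] with an added
#'   `category` column; `mean1` is the control-group PSI and `mean2` the
#'   treated-group PSI.
#' @param q_max significance threshold on the BH-adjusted value (default
#'   0.05).
#' @param epsilon pseudocount on PSI in the fold change (default 0.01).
#' @return list with `counts` (data.frame: category, n, fraction) and
#'   `log2fc` (data.frame: category, q1, median, q3, whisker_lo,
#'   whisker_hi).
#' @export
summarize_events <- function(diff_results, q_max = 0.05, epsilon = 0.01) {
  stopifnot("category" %in% names(diff_results))
  sig <- diff_results[!is.na(diff_results$q) & diff_results$q <= q_max, ,
                      drop = FALSE]
  cats <- sort(unique(diff_results$category))
  n <- vapply(cats, function(cc) sum(sig$category == cc), numeric(1))
  total <- sum(n)
  counts <- data.frame(category = cats, n = n,
                       fraction = if (total > 0) n / total else rep(0, length(n)),
                       row.names = NULL, stringsAsFactors = FALSE)
  l2 <- log2((sig$mean2 + epsilon) / (sig$mean1 + epsilon))
  fc <- do.call(rbind, lapply(cats, function(cc) {
    x <- l2[sig$category == cc]
    if (length(x) == 0L) {
      return(data.frame(category = cc, q1 = NA_real_, median = NA_real_,
                        q3 = NA_real_, whisker_lo = NA_real_,
                        whisker_hi = NA_real_, stringsAsFactors = FALSE))
    }
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- qs[3] - qs[1]
    data.frame(category = cc, q1 = qs[1], median = qs[2], q3 = qs[3],
               whisker_lo = qs[1] - 1.5 * iqr, whisker_hi = qs[3] + 1.5 * iqr,
               stringsAsFactors = FALSE)
  }))
  list(counts = counts, log2fc = fc)
}
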