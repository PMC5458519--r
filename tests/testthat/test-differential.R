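# Moderated-t differential PSI: prior moment matching, reductions to
# classical tests, BH correction, classification and summaries.

sim_psi_matrix <- function(n_events, n1, n2, delta = 0, sd = 0.05,
                           seed = 1) {
  set.seed(seed)
  m <- cbind(matrix(rnorm(n_events * n1, 0.5, sd), n_events),
             matrix(rnorm(n_events * n2, 0.5 + delta, sd), n_events))
  rownames(m) <- paste0("ev", seq_len(n_events))
  colnames(m) <- c(paste0("a", seq_len(n1)), paste0("b", seq_len(n2)))
  m
}

test_that("trigamma_inverse inverts trigamma over a wide range", {
  x <- c(0.01, 0.1, 0.5, 1, 5, 50, 500)
  expect_equal(trigamma_inverse(trigamma(x)), x, tolerance = 1e-8)
})

test_that("identical sample variances give the degenerate infinite prior", {
  prior <- estimate_prior(rep(2.5, 100), residual_df = 10)
  expect_true(is.infinite(prior$d0))
  expect_equal(prior$s0_sq, 2.5)
  expect_error(estimate_prior(rep(0, 10), 10), "zero")
})

test_that("prior recovery from simulated scaled-F variances", {
  set.seed(2024)
  d0 <- 4; s0_sq <- 2; df <- 10
  s2 <- s0_sq * rf(2000, df1 = df, df2 = d0)
  prior <- estimate_prior(s2, residual_df = df)
  expect_lt(abs(prior$d0 - d0) / d0, 0.10)
  expect_lt(abs(prior$s0_sq - s0_sq) / s0_sq, 0.05)
})

test_that("two nearly identical variances yield a large finite or infinite d0", {
  prior <- estimate_prior(c(1, 1 + 1e-6), residual_df = 10)
  expect_true(is.infinite(prior$d0) || prior$d0 > 1e3)
  expect_equal(prior$s0_sq, 1, tolerance = 0.01)
})

test_that("prior fit agrees with the independent limma implementation", {
  skip_if_not_installed("limma")
  set.seed(31)
  s2 <- 1.5 * rf(500, df1 = 8, df2 = 6)
  mine <- estimate_prior(s2, residual_df = 8)
  ref <- limma::fitFDist(s2, df1 = 8)
  expect_equal(mine$d0, ref$df2, tolerance = 1e-6)
  expect_equal(mine$s0_sq, ref$scale, tolerance = 1e-6)
})

test_that("identical groups give t = 0 and p = 1", {
  m <- matrix(rep(c(0.2, 0.4, 0.6), 4), nrow = 1)
  colnames(m) <- paste0("s", 1:12)
  rownames(m) <- "ev1"
  res <- moderated_t_test(rbind(m, m + 0.001), rep(c("g1", "g2"), each = 6),
                          prior = list(d0 = 0, s0_sq = 1))
  expect_equal(res$t_mod[1], 0)
  expect_equal(res$p[1], 1)
})

test_that("d0 = 0 reduces to the classic pooled-variance two-sample t", {
  set.seed(11)
  for (rep in 1:200) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.3)
    m <- matrix(c(x, y), nrow = 1,
                dimnames = list("e", paste0("s", seq_len(n1 + n2))))
    res <- moderated_t_test(m, rep(c("a", "b"), c(n1, n2)),
                            prior = list(d0 = 0, s0_sq = 1),
                            min_samples = 2)
    # independent textbook formula
    sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
    t_ref <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    p_ref <- 2 * pt(-abs(t_ref), n1 + n2 - 2)
    expect_equal(res$t_mod, t_ref, tolerance = 1e-10)
    expect_equal(res$p, p_ref, tolerance = 1e-10)
  }
})

test_that("moderated t matches limma's eBayes on a shared dataset", {
  skip_if_not_installed("limma")
  set.seed(5)
  # heterogeneous per-event variance so the fitted prior is finite
  sds <- runif(300, 0.03, 0.15)
  m <- sim_psi_matrix(300, 4, 4, delta = 0.02, sd = 1) * sds
  labels <- rep(c("a", "b"), each = 4)
  res <- moderated_t_test(m, labels)
  design <- cbind(1, labels == "b")
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_true(is.finite(attr(res, "d0")))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(res, "s0_sq"), fit$s2.prior, tolerance = 1e-6)
  expect_equal(res$t_mod, fit$t[, 2], tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(res$p, fit$p.value[, 2], tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("as d0 grows the statistic approaches the known-variance limit", {
  m <- sim_psi_matrix(50, 4, 4, delta = 0.05, sd = 0.05, seed = 9)
  s0 <- 0.003
  res_inf <- moderated_t_test(m, rep(c("a", "b"), each = 4),
                              prior = list(d0 = Inf, s0_sq = s0))
  res_big <- moderated_t_test(m, rep(c("a", "b"), each = 4),
                              prior = list(d0 = 1e9, s0_sq = s0))
  limit <- res_inf$delta_psi / sqrt(s0 * (1 / 4 + 1 / 4))
  expect_equal(res_inf$t_mod, limit, tolerance = 1e-12)
  expect_equal(res_big$t_mod, limit, tolerance = 1e-4)
})

test_that("sign of t_mod equals sign of delta_psi and q >= p", {
  m <- sim_psi_matrix(400, 5, 5, delta = 0.03, sd = 0.06, seed = 21)
  res <- moderated_t_test(m, rep(c("a", "b"), each = 5))
  ok <- res$testable & res$t_mod != 0
  expect_true(all(sign(res$t_mod[ok]) == sign(res$delta_psi[ok])))
  expect_true(all(res$q[ok] >= res$p[ok] - 1e-15))
  expect_true(all(res$q[ok] >= 0 & res$q[ok] <= 1))
})

test_that("events with too few defined samples are untestable, not imputed", {
  m <- sim_psi_matrix(5, 4, 4, seed = 3)
  m[1, 1:3] <- NA           # one defined value in group a
  m[2, 5:8] <- NA           # group b fully undefined
  res <- moderated_t_test(m, rep(c("a", "b"), each = 4))
  expect_false(res$testable[1])
  expect_false(res$testable[2])
  expect_true(all(is.na(res$p[1:2])))
  expect_true(all(res$testable[3:5]))
  expect_error(moderated_t_test(m, rep("a", 8)), "two groups")
})

test_that("BH adjustment matches the hand-evaluated step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.05, 8)), rep(0.05, 8))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone in sorted-p order and permutation invariant
  set.seed(13)
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  perm <- sample(100)
  expect_equal(bh_adjust(p[perm]), q[perm])
})

test_that("null simulation keeps the q <= 0.05 rejection rate controlled", {
  m <- sim_psi_matrix(5000, 6, 6, delta = 0, sd = 0.05, seed = 77)
  res <- moderated_t_test(m, rep(c("a", "b"), each = 6))
  rate <- mean(res$q <= 0.05)
  # FDR control under a global null bounds the expected rate by alpha
  expect_lte(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / 5000))
})

test_that("event classification is total and follows the definitions", {
  ann <- toy_annotation()
  ev <- data.frame(
    type = c("junction", "junction", "junction", "junction", "junction",
             "boundary", "boundary"),
    chrom = "chr1",
    strand = c("+", "+", "+", "+", "-", "+", "+"),
    intron_first = c(201L, 201L, 201L, 777L, 1201L, NA, NA),
    intron_last = c(300L, 500L, 350L, 888L, 1500L, NA, NA),
    pos = c(NA, NA, NA, NA, NA, 500L, 4444L),
    stringsAsFactors = FALSE
  )
  got <- classify_events(ev, ann)
  # annotated intron; skip of the middle exon; annotated donor with novel
  # acceptor; unannotated; minus-strand skip; boundary at annotated
  # acceptor; boundary elsewhere
  expect_equal(got, c("canonical", "ES", "alt3", "other", "ES", "IR",
                      "other"))
  # novel donor with annotated acceptor
  alt5 <- data.frame(type = "junction", chrom = "chr1", strand = "+",
                     intron_first = 222L, intron_last = 300L, pos = NA,
                     stringsAsFactors = FALSE)
  expect_equal(classify_events(alt5, ann), "alt5")
})

test_that("summaries recover planted category fractions and sum to one", {
  set.seed(55)
  n <- 500
  cat <- sample(c("IR", "ES"), n, replace = TRUE, prob = c(0.8, 0.2))
  d <- data.frame(event_key = paste0("e", 1:n), mean1 = 0.2, mean2 = 0.5,
                  q = 0.01, category = cat, stringsAsFactors = FALSE)
  s <- summarize_events(d)
  expect_equal(sum(s$counts$fraction), 1)
  ir_frac <- s$counts$fraction[s$counts$category == "IR"]
  expect_lt(abs(ir_frac - 0.8), 3 * sqrt(0.8 * 0.2 / n))
  expect_equal(s$log2fc$median[1], log2(0.51 / 0.21), tolerance = 1e-12)
  # empty significant set
  d$q <- 0.5
  s0 <- summarize_events(d)
  expect_true(all(s0$counts$n == 0))
})
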