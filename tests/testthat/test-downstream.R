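test_that("hypergeometric enrichment matches exact combinatorics", {
  universe <- sprintf("g%02d", 1:20)
  ann <- data.frame(term_id = "T1", term_name = "all five",
                    gene_id = universe[1:5], stringsAsFactors = FALSE)
  # drawing all 5 annotated genes in a query of 5: p = 1 / C(20, 5)
  r <- hypergeom_enrich(universe[1:5], ann, universe)
  expect_equal(r$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(r$k, 5); expect_equal(r$K, 5); expect_equal(r$N, 20)

  # no overlap: the certain event has p = 1
  r0 <- hypergeom_enrich(universe[6:10], ann, universe)
  expect_equal(r0$p_value, 1)
  # a term equal to the universe is never enriched
  annU <- data.frame(term_id = "TU", term_name = "everything",
                     gene_id = universe, stringsAsFactors = FALSE)
  expect_equal(hypergeom_enrich(universe[1:4], annU, universe)$p_value, 1)

  expect_error(hypergeom_enrich(c("g01", "nope"), ann, universe), "universe")
})

test_that("hypergeometric tails equal exhaustive enumeration for all small instances", {
  for (N in 4:12) {
    for (K in 1:(N - 1)) {
      for (n in 1:(N - 1)) {
        for (k in 0:min(K, n)) {
          if (n - k > N - K) next
          universe <- sprintf("u%02d", 1:N)
          ann <- data.frame(term_id = "T", term_name = "t",
                            gene_id = universe[1:K], stringsAsFactors = FALSE)
          query <- c(universe[seq_len(k)],
                     universe[K + seq_len(n - k)])
          r <- hypergeom_enrich(query, ann, universe)
          expect_equal(r$p_value, hyper_enum_oracle(k, K, N, n),
                       tolerance = 1e-10,
                       label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
        }
      }
    }
  }
})

test_that("BH adjustment across terms is monotone and bounded", {
  set.seed(40)
  universe <- sprintf("g%03d", 1:200)
  ann <- do.call(rbind, lapply(1:12, function(i) {
    data.frame(term_id = sprintf("T%02d", i), term_name = "t",
               gene_id = sample(universe, sample(10:40, 1)),
               stringsAsFactors = FALSE)
  }))
  r <- hypergeom_enrich(sample(universe, 30), ann, universe)
  expect_true(all(r$fdr <= 1 + 1e-12))
  expect_true(all(diff(r$fdr[order(r$p_value)]) >= -1e-12))
  expect_true(all(r$fdr >= r$p_value - 1e-12))
})

test_that("correlation patterns handle identity, degeneracy and rescaling", {
  set.seed(50)
  cv <- matrix(rnorm(3 * 12), 3, 12,
               dimnames = list(c("c1", "c2", "c3"), sprintf("s%02d", 1:12)))
  mv <- matrix(rnorm(4 * 12), 4, 12,
               dimnames = list(c("g1", "g2", "g3", "g4"), sprintf("s%02d", 1:12)))
  mv[1, ] <- cv[1, ]          # identical vectors: r = 1
  cv[3, ] <- 5                # constant: undefined
  groups <- setNames(rep(c("case", "control"), each = 6), colnames(cv))
  ce <- expression_matrix(cv, groups, unit = "tpm")
  me <- expression_matrix(mv, groups, unit = "tpm")
  p <- correlation_pattern(ce, me, "case")
  expect_equal(p$matrix["c1", "g1"], 1)
  expect_true(all(is.na(p$matrix["c3", ])))
  expect_true(all(abs(p$matrix[is.finite(p$matrix)]) <= 1))

  # invariance to per-feature affine rescaling
  ce2 <- expression_matrix(cv * 3 + 7, groups, unit = "tpm")
  p2 <- correlation_pattern(ce2, me, "case")
  expect_equal(p2$matrix, p$matrix)

  # fewer than three samples is an error
  g2 <- setNames(c("case", "case", rep("control", 10)), colnames(cv))
  expect_error(correlation_pattern(expression_matrix(cv, g2, unit = "tpm"),
                                   expression_matrix(mv, g2, unit = "tpm"),
                                   "case"),
               "3 samples")
})

test_that("pattern divergence contrasts coherent and incoherent groups", {
  # identical group data gives identical patterns: zero differences,
  # matrix correlation 1
  set.seed(61)
  cv8 <- matrix(rnorm(3 * 8), 3, 8, dimnames = list(paste0("c", 1:3), NULL))
  mv8 <- matrix(rnorm(5 * 8), 5, 8, dimnames = list(paste0("g", 1:5), NULL))
  cvals16 <- cbind(cv8, cv8); mvals16 <- cbind(mv8, mv8)
  colnames(cvals16) <- colnames(mvals16) <- sprintf("s%02d", 1:16)
  groups <- setNames(rep(c("case", "control"), each = 8), colnames(cvals16))
  ce <- expression_matrix(cvals16, groups, unit = "tpm")
  me <- expression_matrix(mvals16, groups, unit = "tpm")
  pa <- correlation_pattern(ce, me, "case")
  pb <- correlation_pattern(ce, me, "control")
  d0 <- pattern_divergence(pa, pb)
  expect_equal(d0$coherence_diff, 0)
  expect_equal(d0$frac_positive_diff, 0)
  expect_equal(d0$matrix_correlation, 1)

  # planted shared latent factor in cases only: case coherence exceeds control
  set.seed(62)
  n_s <- 10
  latent <- rnorm(n_s, sd = 2)
  cv2 <- rbind(t(replicate(4, latent + rnorm(n_s, sd = 0.5))),
               deparse.level = 0)
  mv2 <- rbind(t(replicate(6, latent + rnorm(n_s, sd = 0.5))),
               deparse.level = 0)
  cv_ctrl <- matrix(rnorm(4 * n_s), 4, n_s)
  mv_ctrl <- matrix(rnorm(6 * n_s), 6, n_s)
  cvals <- cbind(cv2, cv_ctrl); mvals <- cbind(mv2, mv_ctrl)
  rownames(cvals) <- paste0("c", 1:4); rownames(mvals) <- paste0("g", 1:6)
  colnames(cvals) <- colnames(mvals) <- sprintf("s%02d", 1:(2 * n_s))
  g <- setNames(rep(c("case", "control"), each = n_s), colnames(cvals))
  ce2 <- expression_matrix(cvals, g, unit = "tpm")
  me2 <- expression_matrix(mvals, g, unit = "tpm")
  pc <- correlation_pattern(ce2, me2, "case")
  pk <- correlation_pattern(ce2, me2, "control")
  d <- pattern_divergence(pc, pk)
  expect_gt(d$coherence_diff, 0.3)
  expect_gt(pc$frac_positive, pk$frac_positive - 0.2)

  # constructed half-positive/half-negative contrast
  a <- pc; b <- pc
  a$matrix[] <- 0.8; a$coherence <- 0.8; a$frac_positive <- 1
  b$matrix[] <- rep(c(0.8, -0.8), length.out = length(b$matrix))
  b$coherence <- 0; b$frac_positive <- 0.5
  expect_equal(pattern_divergence(a, b)$frac_positive_diff, 0.5)

  # mismatched grids are rejected
  expect_error(pattern_divergence(pa, pc), "grids")
})
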