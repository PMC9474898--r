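test_that("unit expression vectors return the published coefficients exactly", {
  sig <- published_signature()
  unit_expr <- function(id) {
    m <- matrix(0, nrow = nrow(sig), ncol = 1,
                dimnames = list(sig$lncrna, "s1"))
    m[id, 1] <- 1
    m
  }
  expect_identical(score_samples(unit_expr("MIR4435-1HG"), sig)$score, 0.15)
  expect_identical(score_samples(unit_expr("RP4-568C11.4"), sig)$score, -0.048)
  # identity matrix: each column's score is exactly that lncRNA's coefficient
  ident <- diag(nrow(sig))
  dimnames(ident) <- list(sig$lncrna, sig$lncrna)
  expect_identical(score_samples(ident, sig)$score, sig$weight)
})

test_that("scoring is linear in expression", {
  sig <- published_signature()
  zeros <- matrix(0, nrow = 15, ncol = 2, dimnames = list(sig$lncrna, c("a", "b")))
  expect_equal(score_samples(zeros, sig)$score, c(0, 0))

  dbl <- matrix(0, nrow = 15, ncol = 1, dimnames = list(sig$lncrna, "s"))
  dbl["RP11-383H13.1", 1] <- 2
  expect_equal(score_samples(dbl, sig)$score, 0.32)

  set.seed(2)
  x <- matrix(rexp(30), nrow = 15, dimnames = list(sig$lncrna, c("a", "b")))
  sum_col <- matrix(rowSums(x), nrow = 15, dimnames = list(sig$lncrna, "s"))
  expect_equal(score_samples(sum_col, sig)$score,
               sum(score_samples(x, sig)$score))
})

test_that("missing signature ids follow the chosen policy", {
  sig <- published_signature()
  partial <- matrix(1, nrow = 2, ncol = 1,
                    dimnames = list(c("MIR4435-1HG", "LINC00152"), "s1"))
  expect_error(score_samples(partial, sig), class = "emtlnc_validation_error")
  sc <- suppressMessages(score_samples(partial, sig, missing_policy = "zero"))
  expect_equal(sc$score, 0.15 + 0.13)
})

test_that("log-transform flag changes the scale as documented", {
  sig <- published_signature()
  m <- matrix(3, nrow = 15, ncol = 1, dimnames = list(sig$lncrna, "s1"))
  expect_equal(score_samples(m, sig, log_transform = TRUE)$score,
               log2(4) * sum(sig$weight))
})

test_that("quartile classes partition ordered scores as expected", {
  sc <- tibble::tibble(sample = letters[1:8], score = 1:8)
  c4 <- assign_classes(sc, levels = 4)
  expect_equal(as.vector(table(c4$emt_class)), c(2, 2, 2, 2))
  expect_equal(as.character(c4$emt_class[1:2]), rep("Epithelial", 2))
  expect_equal(as.character(c4$emt_class[7:8]), rep("Mesenchymal", 2))

  c3 <- assign_classes(sc, levels = 3)
  expect_equal(as.vector(table(c3$emt_class)), c(2, 4, 2))

  expect_error(assign_classes(tibble::tibble(sample = "a", score = 1)),
               class = "emtlnc_validation_error")
  expect_error(assign_classes(tibble::tibble(sample = letters[1:8],
                                             score = rep(1, 8))),
               class = "emtlnc_validation_error")
})

test_that("class labels are monotone in score", {
  set.seed(5)
  sc <- tibble::tibble(sample = sprintf("s%03d", 1:200), score = rnorm(200))
  for (lv in c(4, 3)) {
    cl <- assign_classes(sc, levels = lv)
    o <- order(cl$score)
    expect_true(all(diff(as.integer(cl$emt_class[o])) >= 0))
  }
})

test_that("cohort ranking orders by mean score and recovers latent order", {
  sc <- tibble::tibble(sample = c("a", "b", "c", "d"), score = c(0, 0, 1, 1))
  gr <- tibble::tibble(sample = sc$sample, cohort = c("x", "x", "y", "y"))
  rk <- rank_cohorts(sc, gr)
  expect_equal(rk$cohort, c("x", "y"))
  expect_equal(rk$mean_score, c(0, 1))
  expect_equal(rk$rank, c(1L, 2L))

  single <- rank_cohorts(sc, tibble::tibble(sample = sc$sample, cohort = "z"))
  expect_equal(single$rank, 1L)

  spec <- emt_generator_spec(
    n_samples = c(lo = 300L, mid = 300L, hi = 300L),
    latent_means = c(lo = 0.1, mid = 0.5, hi = 0.9),
    planted = tibble::tibble(id = c("LNC_M1", "LNC_M2"),
                             class = "mesenchymal", loading = c(1.8, 1.8)),
    n_decoys = 5L
  )
  coh <- simulate_emt_cohort(spec, seed = 21)
  sig <- tibble::tibble(lncrna = c("LNC_M1", "LNC_M2"),
                        emt_class = "mesenchymal", weight = c(0.2, 0.2))
  scores <- score_samples(coh$expression, sig)
  rk2 <- rank_cohorts(scores,
                      tibble::tibble(sample = coh$truth$latent$sample,
                                     cohort = coh$truth$latent$cancer_type),
                      levels = 3)
  expect_equal(rk2$cohort, c("lo", "mid", "hi"))
})

test_that("differential expression calls direction against an exact rank-sum", {
  feats <- c("f1", "f2")
  vals <- rbind(f1 = c(1, 2, 3, 4, 5, 1, 2, 3, 4, 5),
                f2 = c(1, 2, 3, 4, 5, 101, 102, 103, 104, 105))
  colnames(vals) <- sprintf("s%02d", 1:10)
  groups <- tibble::tibble(sample = colnames(vals),
                           group = rep(c("normal", "tumor"), each = 5))
  res <- differential_expression(vals, groups, feats)

  # identical groups: no change, not significant
  expect_equal(res$log2fc[res$feature == "f1"], 0)
  expect_equal(res$direction[res$feature == "f1"], "ns")

  # complete separation at n=5 per arm: exact two-sided rank-sum p is
  # 2 / choose(10, 5), the two most extreme orderings among all assignments
  expect_equal(res$p.value[res$feature == "f2"], 2 / choose(10, 5))
  expect_equal(res$direction[res$feature == "f2"], "up")
  expect_gt(res$log2fc[res$feature == "f2"], 0)

  expect_error(differential_expression(vals, groups, "absent"),
               class = "emtlnc_validation_error")
  tiny <- groups[c(1:2, 6:10), ]
  expect_warning(differential_expression(vals, tiny, feats), "fewer than 3")
})
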