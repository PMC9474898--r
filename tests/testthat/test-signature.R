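test_that("spearman_rho matches the rank-then-Pearson definition", {
  expect_equal(spearman_rho(c(1, 2, 3), c(10, 20, 30)), 1.0)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 2, 1)), -1.0)

  # tied vectors against the longhand oracle: average ranks, then Pearson
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  oracle <- pearson_by_hand(rank(x), rank(y))
  expect_equal(spearman_rho(x, y), oracle)
  expect_equal(oracle, 3 / sqrt(10))   # frozen hand computation

  set.seed(42)
  for (i in 1:10) {
    a <- sample(20, 12, replace = TRUE)
    b <- rnorm(12)
    expect_equal(spearman_rho(a, b), pearson_by_hand(rank(a), rank(b)))
  }
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(1)
  x <- rnorm(30); y <- rnorm(30)
  r <- spearman_rho(x, y)
  expect_equal(spearman_rho(exp(x), y), r)
  expect_equal(spearman_rho(x, 3 * y - 100), r)
  expect_equal(spearman_rho(x^3, exp(y)), r)
})

test_that("spearman_rho rejects degenerate input", {
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)),
               class = "emtlnc_constant_error")
  expect_error(spearman_rho(1:3, 1:4), class = "emtlnc_validation_error")
  expect_error(spearman_rho(1:2, 2:1), class = "emtlnc_validation_error")
})

test_that("candidate classification applies the directional rules strictly", {
  prof <- function(vim, cdh1, fn1, snai1, snai2) {
    tibble::tibble(rho_vim = vim, rho_cdh1 = cdh1, rho_fn1 = fn1,
                   rho_snai1 = snai1, rho_snai2 = snai2)
  }
  expect_equal(classify_candidate(prof(0.40, -0.25, 0.15, 0.12, -0.05)),
               "mesenchymal")
  # boundary: 0.35 is not "more than 0.35"
  expect_equal(classify_candidate(prof(0.35, -0.25, 0.15, 0.12, 0.2)), "none")
  expect_equal(classify_candidate(prof(-0.25, 0.40, -0.05, -0.3, 0.1)),
               "epithelial")
  # only one secondary above 0.1
  expect_equal(classify_candidate(prof(0.40, -0.25, 0.15, 0.05, 0.08)), "none")
  # vectorised
  multi <- dplyr::bind_rows(prof(0.5, -0.3, 0.2, 0.2, 0.2),
                            prof(-0.3, 0.5, -0.1, -0.1, 0.5))
  expect_equal(classify_candidate(multi), c("mesenchymal", "epithelial"))
})

test_that("the two rule sets are mutually exclusive at default thresholds", {
  set.seed(9)
  prof <- tibble::tibble(
    rho_vim = runif(500, -1, 1), rho_cdh1 = runif(500, -1, 1),
    rho_fn1 = runif(500, -1, 1), rho_snai1 = runif(500, -1, 1),
    rho_snai2 = runif(500, -1, 1)
  )
  cfg <- emt_config()
  cls <- classify_candidate(prof, cfg)
  # a profile can satisfy at most one rule set because each requires the
  # opposite sign of rho_vim; recompute both rules independently
  mes <- prof$rho_vim > cfg$vim_min &
    (prof$rho_fn1 > 0.1) + (prof$rho_snai1 > 0.1) + (prof$rho_snai2 > 0.1) >= 2 &
    prof$rho_cdh1 < cfg$opposite_max
  epi <- prof$rho_cdh1 > cfg$vim_min &
    (prof$rho_fn1 < 0) + (prof$rho_snai1 < 0) + (prof$rho_snai2 < 0) >= 2 &
    prof$rho_vim < cfg$opposite_max
  expect_false(any(mes & epi))
  expect_equal(cls, dplyr::case_when(mes ~ "mesenchymal", epi ~ "epithelial",
                                     .default = "none"))
})

test_that("weights are the sum of the CDH1 and VIM correlations", {
  expect_equal(assign_weight(tibble::tibble(rho_vim = 0.40, rho_cdh1 = -0.24)),
               0.16)
  expect_equal(assign_weight(tibble::tibble(rho_vim = 0.30, rho_cdh1 = -0.30)),
               0.0)
  expect_equal(assign_weight(tibble::tibble(rho_vim = -0.40, rho_cdh1 = 0.352)),
               -0.048)
})

test_that("marker profiles recover perfect and planted correlations", {
  set.seed(4)
  base <- matrix(rexp(5 * 30), nrow = 5,
                 dimnames = list(c("VIM", "CDH1", "FN1", "SNAI1", "SNAI2"),
                                 sprintf("s%02d", 1:30)))
  cand <- rbind(COPY_VIM = base["VIM", ] * 2,            # monotone in VIM
                ANTI_CDH1 = max(base["CDH1", ]) - base["CDH1", ] + 1)
  expr <- rbind(base, cand)
  prof <- profile_markers(expr, marker_panel(), c("COPY_VIM", "ANTI_CDH1"))
  expect_equal(prof$rho_vim[prof$lncrna == "COPY_VIM"], 1.0)
  expect_equal(prof$rho_cdh1[prof$lncrna == "ANTI_CDH1"], -1.0)
  expect_equal(prof$n_pairs, c(30L, 30L))

  expect_error(profile_markers(expr, marker_panel(), "MISSING"),
               class = "emtlnc_validation_error")
  expect_error(profile_markers(expr, marker_panel(), c("VIM", "COPY_VIM")),
               class = "emtlnc_validation_error")
})

test_that("planted lncRNAs profile positively against VIM on a synthetic cohort", {
  coh <- simulate_emt_cohort(lean_spec(n_per_type = 500), seed = 6)
  prof <- profile_markers(coh$expression, marker_panel(),
                          c("LNC_M1", "LNC_M2", "LNC_E1"))
  expect_true(all(prof$rho_vim[prof$lncrna != "LNC_E1"] > 0))
  expect_lt(prof$rho_vim[prof$lncrna == "LNC_E1"], 0)
})

test_that("derive_signature recovers planted truth and rejects decoys", {
  spec <- lean_spec(n_per_type = 1000, n_decoys = 50)
  coh <- simulate_emt_cohort(spec, seed = 8)
  cands <- setdiff(coh$expression$feature, unname(marker_panel()))
  sig <- suppressMessages(derive_signature(coh$expression, candidates = cands))
  expect_setequal(sig$lncrna, spec$planted$id)
  expect_equal(sig$emt_class[match(spec$planted$id, sig$lncrna)],
               spec$planted$class)
  # weights tie out against independently recomputed profiles
  prof <- profile_markers(coh$expression, candidates = sig$lncrna)
  expect_equal(sig$weight,
               (prof$rho_cdh1 + prof$rho_vim)[match(sig$lncrna, prof$lncrna)])
  # ordering by |weight|
  expect_equal(order(abs(sig$weight), decreasing = TRUE), seq_len(nrow(sig)))
})

test_that("an all-decoy candidate set yields an empty signature with warning", {
  spec <- lean_spec(n_per_type = 1000, n_decoys = 60)
  coh <- simulate_emt_cohort(spec, seed = 10)
  decoys <- grep("^DECOY_", coh$expression$feature, value = TRUE)
  expect_warning(
    sig <- suppressMessages(derive_signature(coh$expression, candidates = decoys)),
    "empty signature"
  )
  expect_equal(nrow(sig), 0L)
})

test_that("signatures round-trip through JSON and TSV", {
  sig <- published_signature()
  expect_equal(nrow(sig), 15L)
  for (ext in c(".json", ".tsv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_signature(sig, path)
    expect_equal(read_signature(path), sig)
  }
})
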