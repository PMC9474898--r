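# Shared fixture builders. Everything is generated in code; no binary files.

# tiny feature-by-sample tibble
expr_fixture <- function(values, features, samples) {
  m <- matrix(values, nrow = length(features), byrow = TRUE,
              dimnames = list(features, samples))
  tibble::as_tibble(cbind(tibble::tibble(feature = features),
                          as.data.frame(m, check.names = FALSE)))
}

write_expr_fixture <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

clinical_fixture <- function(n = 4, time = NULL, event = NULL) {
  tibble::tibble(
    sample = sprintf("P%02d", seq_len(n)),
    time_months = if (is.null(time)) seq_len(n) else time,
    event = if (is.null(event)) rep(1L, n) else event,
    age = 50 + seq_len(n),
    gender = rep(c("female", "male"), length.out = n),
    stage = factor(rep(c("I", "II", "III", "IV"), length.out = n),
                   levels = c("I", "II", "III", "IV"), ordered = TRUE),
    cancer_type = "typeA",
    sample_class = "tumor"
  )
}

# small, fast generator spec (used where the full default preset is overkill)
lean_spec <- function(n_per_type = 100L, loading = 1.8, sigma = 0.4,
                      n_decoys = 10L, gamma = 0.7, censoring = 0.3) {
  emtlnc::emt_generator_spec(
    n_samples = c(a = n_per_type, b = n_per_type),
    latent_means = c(a = 0.3, b = 0.7),
    planted = tibble::tibble(
      id = c("LNC_M1", "LNC_M2", "LNC_E1"),
      class = c("mesenchymal", "mesenchymal", "epithelial"),
      loading = c(loading, loading, -loading)
    ),
    n_decoys = n_decoys, sigma = sigma, gamma = gamma, censoring = censoring
  )
}

# Pearson correlation written out longhand, used as the independent half of
# rank-based oracles
pearson_by_hand <- function(a, b) {
  da <- a - mean(a); db <- b - mean(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# hypergeometric two-sided exact p by full enumeration over fixed margins,
# probabilities from choose() directly
fisher_enum_oracle <- function(m) {
  r1 <- sum(m[1, ]); r2 <- sum(m[2, ]); c1 <- sum(m[, 1])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  ks <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- probs[ks == m[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# direct BH step-up formula: min over the sorted tail of p * n / rank
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o] * n / seq_len(n)
  adj_sorted <- rev(cummin(rev(sorted)))
  adj[o] <- pmin(adj_sorted, 1)
  adj
}
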