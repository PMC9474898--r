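#' Compute weighted EMT scores
#'
#' For each sample s, `score_s = sum_g w_g * x_{g,s}` over the signature
#' entries. Expression is used on the scale supplied (FPKM-like) by default; a
#' log2(x + 1) pre-transform is available because published scores do not
#' always state their scale.
#'
#' @param expr Expression tibble or matrix.
#' @param sig An `emt_signature` (see [derive_signature()],
#'   [published_signature()]).
#' @param missing_policy Signature ids absent from `expr`: `"error"` (default)
#'   or `"zero"` (contribute nothing, with a message).
#' @param log_transform Apply log2(x + 1) to expression before weighting.
#' @return A tibble of class `emt_scores` with columns `sample`, `score`.
#' @examples
#' sig <- published_signature()
#' m <- matrix(1, nrow = 15, ncol = 1, dimnames = list(sig$lncrna, "s1"))
#' score_samples(m, sig)  # sum of all published weights
#' @export
score_samples <- function(expr, sig, missing_policy = c("error", "zero"),
                          log_transform = FALSE) {
  missing_policy <- match.arg(missing_policy)
  m <- as_expr_matrix(expr)
  if (!nrow(sig)) {
    abort("signature is empty", class = "emtlnc_validation_error")
  }
  absent <- setdiff(sig$lncrna, rownames(m))
  if (length(absent)) {
    if (missing_policy == "error") {
      abort(paste("signature id(s) absent from expression matrix:",
                  paste(absent, collapse = ", ")),
            class = "emtlnc_validation_error")
    }
    inform(sprintf("%d signature id(s) absent; contributing 0: %s",
                   length(absent), paste(absent, collapse = ", ")))
  }
  present <- sig[sig$lncrna %in% rownames(m), , drop = FALSE]
  xs <- m[present$lncrna, , drop = FALSE]
  if (log_transform) xs <- log2(xs + 1)
  score <- as.numeric(crossprod(xs, present$weight))
  out <- tibble(sample = colnames(m), score = score)
  class(out) <- c("emt_scores", class(out))
  out
}

emt_class_labels <- function(levels) {
  switch(as.character(levels),
         "4" = c("Epithelial", "Epithelial-Mesenchymal",
                 "Mesenchymal-Epithelial", "Mesenchymal"),
         "3" = c("epithelial", "intermediate", "mesenchymal"),
         abort("levels must be 3 or 4", class = "emtlnc_validation_error"))
}

#' Assign EMT classes from score quantiles
#'
#' Partitions samples at score quantiles: the four-level scheme cuts at the
#' quartiles (Epithelial, Epithelial-Mesenchymal, Mesenchymal-Epithelial,
#' Mesenchymal, in increasing score order); the three-level scheme merges the
#' two middle quartile groups into "intermediate", as done when classifying
#' cell-line panels. Labels are ordered factors, monotone in score.
#'
#' @param scores An `emt_scores` tibble (or any tibble with `sample`, `score`).
#' @param levels 4 (default) or 3.
#' @param cuts Quantile cuts for the four-level scheme.
#' @return The input with an `emt_class` ordered-factor column added.
#' @examples
#' sc <- tibble::tibble(sample = letters[1:8], score = 1:8)
#' assign_classes(sc)$emt_class
#' @export
assign_classes <- function(scores, levels = 4, cuts = c(0.25, 0.5, 0.75)) {
  stopifnot(all(c("sample", "score") %in% names(scores)))
  if (!all(is.finite(scores$score))) {
    abort("scores must be finite", class = "emtlnc_validation_error")
  }
  if (nrow(scores) < levels) {
    abort("fewer samples than class levels", class = "emtlnc_validation_error")
  }
  breaks <- unique(c(-Inf, quantile(scores$score, cuts, names = FALSE), Inf))
  if (length(breaks) < length(cuts) + 2) {
    abort("degenerate score distribution: quantile cuts are not distinct",
          class = "emtlnc_validation_error")
  }
  q4 <- cut(scores$score, breaks = breaks, labels = emt_class_labels(4),
            include.lowest = TRUE, right = TRUE)
  out <- scores
  if (levels == 4) {
    out$emt_class <- factor(q4, levels = emt_class_labels(4), ordered = TRUE)
  } else if (levels == 3) {
    lab3 <- emt_class_labels(3)
    map <- c(lab3[1], lab3[2], lab3[2], lab3[3])[as.integer(q4)]
    out$emt_class <- factor(map, levels = lab3, ordered = TRUE)
  } else {
    abort("levels must be 3 or 4", class = "emtlnc_validation_error")
  }
  out
}

#' Rank cohorts (cancer types) by mean EMT score
#'
#' Averages the score within each cohort, ranks cohorts by ascending mean, and
#' classifies the cohort means with the same quantile scheme used for samples.
#'
#' @param scores An `emt_scores` tibble.
#' @param grouping Tibble (`sample`, `cohort`) mapping every scored sample.
#' @param levels Class-scheme levels (4 or 3).
#' @return Tibble (`cohort`, `n`, `mean_score`, `rank`, `emt_class`) ordered by
#'   ascending mean score.
#' @export
rank_cohorts <- function(scores, grouping, levels = 4) {
  stopifnot(all(c("sample", "cohort") %in% names(grouping)))
  joined <- dplyr::inner_join(as_tibble(scores), as_tibble(grouping),
                              by = "sample")
  unmapped <- setdiff(scores$sample, grouping$sample)
  if (length(unmapped)) {
    abort(paste("unmapped sample(s):", paste(unmapped, collapse = ", ")),
          class = "emtlnc_validation_error")
  }
  empty <- setdiff(unique(grouping$cohort), unique(joined$cohort))
  if (length(empty)) {
    warn(paste("excluding empty cohort(s):", paste(empty, collapse = ", ")))
  }
  means <- joined |>
    group_by(.data$cohort) |>
    summarise(n = dplyr::n(), mean_score = mean(.data$score), .groups = "drop") |>
    arrange(.data$mean_score) |>
    mutate(rank = row_number())
  if (nrow(means) >= levels) {
    cls <- assign_classes(tibble(sample = means$cohort, score = means$mean_score),
                          levels = levels)
    means$emt_class <- cls$emt_class
  } else {
    means$emt_class <- factor(NA, levels = emt_class_labels(levels),
                              ordered = TRUE)
  }
  means
}

#' Tumor-vs-normal differential expression of selected features
#'
#' Per feature: log2 fold change `log2((mean_tumor + 1) / (mean_normal + 1))`
#' (pseudocount 1 guards zero means), a two-sided Wilcoxon rank-sum test, and
#' Benjamini-Hochberg adjustment across features. Direction is `ns` unless the
#' adjusted p-value is below `fdr`.
#'
#' @param expr Expression tibble or matrix.
#' @param groups Tibble (`sample`, `group`) with group values `"tumor"` /
#'   `"normal"`.
#' @param features Feature ids to test; must be present in `expr`.
#' @param fdr FDR level for the direction call.
#' @return Tibble (`feature`, `log2fc`, `p.value`, `p.adjusted`, `direction`).
#' @export
differential_expression <- function(expr, groups, features, fdr = 0.05) {
  m <- as_expr_matrix(expr)
  absent <- setdiff(features, rownames(m))
  if (length(absent)) {
    abort(paste("feature(s) absent:", paste(absent, collapse = ", ")),
          class = "emtlnc_validation_error")
  }
  stopifnot(all(c("sample", "group") %in% names(groups)))
  groups <- groups[groups$sample %in% colnames(m), , drop = FALSE]
  tum <- groups$sample[groups$group == "tumor"]
  nor <- groups$sample[groups$group == "normal"]
  if (length(tum) < 3 || length(nor) < 3) {
    warn("a group has fewer than 3 samples; skipping all features")
    return(tibble(feature = character(), log2fc = numeric(),
                  p.value = numeric(), p.adjusted = numeric(),
                  direction = character()))
  }
  res <- purrr::map_dfr(features, function(f) {
    xt <- m[f, tum]; xn <- m[f, nor]
    l2fc <- log2((mean(xt) + 1) / (mean(xn) + 1))
    p <- if (identical(sort(unname(xt)), sort(unname(xn)))) 1 else
      suppressWarnings(wilcox.test(xt, xn)$p.value)
    tibble(feature = f, log2fc = l2fc, p.value = p)
  })
  res$p.adjusted <- p.adjust(res$p.value, method = "BH")
  res$direction <- dplyr::case_when(
    res$p.adjusted >= fdr ~ "ns",
    res$log2fc > 0 ~ "up",
    res$log2fc < 0 ~ "down",
    .default = "ns"
  )
  res
}
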