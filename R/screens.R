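#' Correlate per-sample features with the EMT score
#'
#' Spearman (default) or Pearson correlation of every feature row against the
#' score across shared samples, with Benjamini-Hochberg adjustment across
#' features. A hit is significant when |rho| exceeds the configured cut and
#' the adjusted p-value is below the FDR level — the joint rule used for
#' protein/phosphoprotein screens (|rho| > 0.2, FDR 0.05).
#'
#' @param scores An `emt_scores` tibble (`sample`, `score`).
#' @param features Feature-by-sample tibble or matrix; values may be negative
#'   (RPPA-style centred data).
#' @param config An [emt_config()]; uses `protein_rho_cut` and `fdr`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return Tibble (`feature`, `rho`, `p.value`, `p.adjusted`, `direction`,
#'   `significant`) sorted by descending |rho|.
#' @export
correlate_features <- function(scores, features, config = emt_config(),
                               method = c("spearman", "pearson")) {
  method <- match.arg(method)
  m <- as_expr_matrix(features, allow_negative = TRUE)
  common <- intersect(colnames(m), scores$sample)
  if (length(common) < 10) {
    abort("need at least 10 shared samples", class = "emtlnc_alignment_error")
  }
  m <- m[, common, drop = FALSE]
  sc <- scores$score[match(common, scores$sample)]
  res <- purrr::map_dfr(rownames(m), function(f) {
    ct <- suppressWarnings(cor.test(m[f, ], sc, method = method, exact = FALSE))
    tibble(feature = f, rho = unname(ct$estimate), p.value = ct$p.value)
  })
  res$p.adjusted <- bh_adjust(res$p.value)
  res$direction <- ifelse(res$rho >= 0, "positive", "negative")
  res$significant <- abs(res$rho) > config$protein_rho_cut &
    res$p.adjusted < config$fdr
  arrange(res, desc(abs(.data$rho)))
}

#' Compare feature levels across EMT classes
#'
#' Kruskal-Wallis test of each feature across the classes, with per-class mean
#' levels and BH adjustment across features. Classes below the minimum size are
#' excluded with a message.
#'
#' @param features Feature-by-sample tibble or matrix (negatives allowed).
#' @param classes Tibble (`sample`, `emt_class`).
#' @param fdr FDR level for the significance flag.
#' @param min_n Minimum samples per class (default 3).
#' @return Tibble with one row per feature: per-class means (`mean_<class>`),
#'   `p.value`, `p.adjusted`, `significant`.
#' @export
compare_by_class <- function(features, classes, fdr = 0.05, min_n = 3) {
  m <- as_expr_matrix(features, allow_negative = TRUE)
  stopifnot(all(c("sample", "emt_class") %in% names(classes)))
  classes <- classes[classes$sample %in% colnames(m), , drop = FALSE]
  sizes <- table(as.character(classes$emt_class))
  small <- names(sizes)[sizes < min_n]
  if (length(small)) {
    inform(paste("excluding class(es) below minimum size:",
                 paste(small, collapse = ", ")))
    classes <- classes[!as.character(classes$emt_class) %in% small, , drop = FALSE]
  }
  cls <- as.character(classes$emt_class)
  if (length(unique(cls)) < 2) {
    abort("need at least two classes with enough samples",
          class = "emtlnc_validation_error")
  }
  mm <- m[, classes$sample, drop = FALSE]
  res <- purrr::map_dfr(rownames(mm), function(f) {
    v <- mm[f, ]
    means <- tapply(v, cls, mean)
    p <- if (length(unique(v)) < 2) 1 else
      suppressWarnings(kruskal.test(v, factor(cls))$p.value)
    out <- tibble(feature = f, p.value = p)
    for (g in names(means)) out[[paste0("mean_", g)]] <- unname(means[g])
    out
  })
  res$p.adjusted <- bh_adjust(res$p.value)
  res$significant <- res$p.adjusted < fdr
  res
}

#' Drug-sensitivity screen against the EMT score
#'
#' Correlates each drug's response (log-IC50 by default) with the EMT score
#' across shared cell lines, splits drugs by correlation sign, and retains
#' those with |rho| at or above the configured cut (default 0.15). With a
#' category annotation, builds the 2x2 category-by-sign table over the
#' retained drugs and runs a two-sided Fisher exact test.
#'
#' @param scores An `emt_scores` tibble (cell lines as samples).
#' @param drug_response Tibble with a `sample` column (cell line) and one
#'   numeric column per drug holding IC50 (or already-logged) values.
#' @param annotation Optional tibble (`drug`, `category`) with exactly two
#'   category levels for the enrichment test.
#' @param config An [emt_config()]; uses `drug_rho_cut`.
#' @param log_ic50 Correlate on log-transformed IC50 (default). Values must be
#'   positive for the transform; set `FALSE` for pre-logged data.
#' @return A list of class `emt_drug_screen`: `associations` tibble (`drug`,
#'   `rho`, `group`, `retained`), `enrichment` (list with `table` and
#'   `p.value`, or `NULL` when no annotation is given).
#' @export
drug_screen <- function(scores, drug_response, annotation = NULL,
                        config = emt_config(), log_ic50 = TRUE) {
  stopifnot("sample" %in% names(drug_response))
  common <- intersect(drug_response$sample, scores$sample)
  if (length(common) < 10) {
    abort("need at least 10 shared cell lines", class = "emtlnc_alignment_error")
  }
  dr <- drug_response[match(common, drug_response$sample), , drop = FALSE]
  sc <- scores$score[match(common, scores$sample)]
  drug_ids <- setdiff(names(dr), "sample")
  assoc <- purrr::map_dfr(drug_ids, function(dg) {
    v <- dr[[dg]]
    if (!all(is.finite(v))) {
      abort(paste0("non-finite response for drug '", dg, "'"),
            class = "emtlnc_validation_error")
    }
    if (log_ic50) {
      if (any(v <= 0)) {
        abort(paste0("non-positive IC50 for drug '", dg,
                     "'; use log_ic50 = FALSE for pre-logged data"),
              class = "emtlnc_validation_error")
      }
      v <- log(v)
    }
    tibble(drug = dg, rho = spearman_rho(v, sc))
  })
  assoc$group <- ifelse(assoc$rho >= 0, "positive", "negative")
  assoc$retained <- abs(assoc$rho) >= config$drug_rho_cut
  enrichment <- NULL
  if (!is.null(annotation)) {
    stopifnot(all(c("drug", "category") %in% names(annotation)))
    kept <- dplyr::inner_join(assoc[assoc$retained, , drop = FALSE],
                              as_tibble(annotation), by = "drug")
    cats <- unique(annotation$category)
    if (length(cats) != 2) {
      abort("annotation must have exactly two categories",
            class = "emtlnc_validation_error")
    }
    tab <- table(factor(kept$category, levels = cats),
                 factor(kept$group, levels = c("positive", "negative")))
    enrichment <- list(table = unclass(tab), p.value = fisher_exact(tab))
  }
  structure(list(associations = arrange(assoc, desc(abs(.data$rho))),
                 enrichment = enrichment),
            class = "emt_drug_screen")
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-mass criterion: the sum of
#' hypergeometric probabilities of every table with the observed margins that
#' is no more probable than the observed one. A table with a zero margin
#' carries no information; p = 1 with a warning.
#'
#' @param table 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts.
#' @return Scalar p-value.
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2))
#' @export
fisher_exact <- function(table) {
  m <- generate_contingency(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warn("zero margin in 2x2 table; p = 1 by convention")
    return(1)
  }
  stats::fisher.test(m)$p.value
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (NA passed through).
#' @return Adjusted p-values in the input order; elementwise at least the
#'   input, at most 1.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in [0, 1]", class = "emtlnc_validation_error")
  }
  p.adjust(pvalues, method = "BH")
}
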