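#' Spearman rank correlation of two numeric vectors
#'
#' Pearson correlation of average-rank transforms (ties receive average
#' ranks). Pairs with a missing value in either vector are removed first.
#'
#' @param x,y Numeric vectors of equal length; at least 3 complete pairs and at
#'   least two distinct values in each after pair removal.
#' @return Scalar rho in \[-1, 1\].
#' @examples
#' spearman_rho(1:5, c(2, 4, 6, 8, 10))   # 1
#' spearman_rho(1:5, 5:1)                 # -1
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "emtlnc_validation_error")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) {
    abort("need at least 3 complete pairs", class = "emtlnc_validation_error")
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("correlation undefined for a constant input",
          class = "emtlnc_constant_error")
  }
  cor(x, y, method = "spearman")
}

#' Spearman profiles of candidate lncRNAs against the marker panel
#'
#' Correlates each candidate feature with the five EMT markers across the
#' pooled samples of the expression matrix (the pan-cancer mode the weighted
#' score implies). With `grouping` supplied, rho is computed within each group
#' and aggregated by the median across groups.
#'
#' @param expr Expression tibble or matrix (features x samples).
#' @param panel A [marker_panel()]; all five ids must be present in `expr`.
#' @param candidates Character vector of candidate feature ids, present in
#'   `expr` and disjoint from the panel.
#' @param grouping Optional tibble (`sample`, `cohort`) for per-cohort
#'   correlation with median aggregation.
#' @return A tibble with one row per candidate: `lncrna`, `rho_vim`,
#'   `rho_cdh1`, `rho_fn1`, `rho_snai1`, `rho_snai2`, `n_pairs`.
#' @export
profile_markers <- function(expr, panel = marker_panel(), candidates,
                            grouping = NULL) {
  m <- as_expr_matrix(expr)
  absent <- setdiff(c(unname(panel), candidates), rownames(m))
  if (length(absent)) {
    abort(paste("feature id(s) absent from expression matrix:",
                paste(absent, collapse = ", ")),
          class = "emtlnc_validation_error")
  }
  if (length(intersect(candidates, unname(panel)))) {
    abort("candidates must be disjoint from the marker panel",
          class = "emtlnc_validation_error")
  }
  if (ncol(m) < 3) {
    abort("need at least 3 samples", class = "emtlnc_validation_error")
  }
  rho_block <- function(mm) {
    # candidates x markers matrix of Spearman rho
    cor(t(mm[candidates, , drop = FALSE]),
        t(mm[unname(panel), , drop = FALSE]),
        method = "spearman")
  }
  if (is.null(grouping)) {
    rho <- rho_block(m)
    n_pairs <- ncol(m)
  } else {
    stopifnot(all(c("sample", "cohort") %in% names(grouping)))
    per <- lapply(split(grouping$sample, grouping$cohort), function(s) {
      s <- intersect(s, colnames(m))
      if (length(s) < 3) return(NULL)
      rho_block(m[, s, drop = FALSE])
    })
    per <- per[!vapply(per, is.null, logical(1))]
    if (!length(per)) {
      abort("no cohort has >= 3 samples", class = "emtlnc_validation_error")
    }
    rho <- apply(simplify2array(per), c(1, 2), median)
    n_pairs <- ncol(m)
  }
  colnames(rho) <- names(panel)
  tibble(
    lncrna = candidates,
    rho_vim = unname(rho[, "vim"]), rho_cdh1 = unname(rho[, "cdh1"]),
    rho_fn1 = unname(rho[, "fn1"]), rho_snai1 = unname(rho[, "snai1"]),
    rho_snai2 = unname(rho[, "snai2"]),
    n_pairs = n_pairs
  )
}
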