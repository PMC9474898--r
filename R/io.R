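#' Read a feature-by-sample expression matrix
#'
#' Reads a TSV or CSV table (delimiter chosen by file extension) whose first
#' column holds feature identifiers and whose header row holds sample
#' identifiers, validates it (finite, non-negative values; unique sample ids)
#' and resolves duplicate feature ids according to `id_policy`.
#'
#' @param path Path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file.
#' @param id_policy How to resolve duplicated feature identifiers:
#'   `"max_variance"` keeps the row with the largest variance (the default,
#'   standard practice when collapsing transcript-level duplicates), `"mean"`
#'   averages duplicate rows elementwise, `"error"` fails.
#' @return A tibble with a character `feature` column followed by one numeric
#'   column per sample.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("feature\ts1\ts2", "g1\t1\t2", "g2\t0\t3"), tf)
#' read_expression(tf)
#' @export
read_expression <- function(path,
                            id_policy = c("max_variance", "mean", "error")) {
  id_policy <- match.arg(id_policy)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "emtlnc_io_error")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) < 2) {
    abort("malformed header: need a feature column and at least one sample column",
          class = "emtlnc_parse_error")
  }
  names(raw)[1] <- "feature"
  raw$feature <- as.character(raw$feature)
  if (anyDuplicated(names(raw)[-1])) {
    abort("duplicate sample ids in header", class = "emtlnc_validation_error")
  }
  for (j in seq(2, ncol(raw))) {
    v <- raw[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      abort(sprintf("non-numeric value in column '%s', row %d",
                    names(raw)[j], if (is.na(bad)) 1L else bad),
            class = "emtlnc_validation_error")
    }
  }
  expr <- as_tibble(raw)
  if (anyDuplicated(expr$feature)) {
    dup <- unique(expr$feature[duplicated(expr$feature)])
    if (id_policy == "error") {
      abort(paste("duplicate feature ids:", paste(dup, collapse = ", ")),
            class = "emtlnc_duplicate_id_error")
    }
    inform(sprintf("resolving %d duplicated feature id(s) by %s",
                   length(dup), id_policy))
    expr <- collapse_duplicates(expr, id_policy)
  }
  validate_expression(expr)
  expr
}

collapse_duplicates <- function(expr, id_policy) {
  if (id_policy == "mean") {
    return(expr |>
             group_by(.data$feature) |>
             summarise(across(dplyr::everything(), mean), .groups = "drop") |>
             arrange(match(.data$feature, unique(expr$feature))))
  }
  # max_variance: keep, per feature id, the row with the largest variance
  vr <- apply(as.matrix(expr[-1]), 1, var)
  expr |>
    mutate(.var = vr) |>
    group_by(.data$feature) |>
    dplyr::slice_max(.data$.var, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select(-".var") |>
    arrange(match(.data$feature, unique(expr$feature)))
}

validate_expression <- function(expr, allow_negative = FALSE) {
  m <- as_expr_matrix(expr, allow_negative = allow_negative)
  invisible(m)
}

#' Coerce an expression table to a numeric matrix
#'
#' Internal workhorse shared by every operation: accepts the package's tidy
#' expression layout (character `feature` column + sample columns) or a numeric
#' matrix with feature rownames, and enforces the invariants (finite values,
#' non-negative unless `allow_negative`, unique feature and sample ids).
#'
#' @param expr Expression tibble or numeric matrix.
#' @param allow_negative Permit negative values (RPPA-style centred matrices).
#' @return Numeric matrix, features in rows, samples in columns.
#' @keywords internal
as_expr_matrix <- function(expr, allow_negative = FALSE) {
  if (is.matrix(expr)) {
    m <- expr
    if (is.null(rownames(m))) {
      abort("expression matrix needs feature rownames", class = "emtlnc_validation_error")
    }
  } else if (is.data.frame(expr)) {
    if (!"feature" %in% names(expr)) names(expr)[1] <- "feature"
    m <- as.matrix(expr[setdiff(names(expr), "feature")])
    rownames(m) <- as.character(expr$feature)
    storage.mode(m) <- "double"
  } else {
    abort("expression must be a data frame or a matrix", class = "emtlnc_validation_error")
  }
  if (anyDuplicated(rownames(m))) {
    abort("duplicate feature ids", class = "emtlnc_validation_error")
  }
  if (anyDuplicated(colnames(m))) {
    abort("duplicate sample ids", class = "emtlnc_validation_error")
  }
  if (anyNA(m) || any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    abort(sprintf("non-finite value at feature '%s', sample '%s'",
                  rownames(m)[bad[1]], colnames(m)[bad[2]]),
          class = "emtlnc_validation_error")
  }
  if (!allow_negative && any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative value at feature '%s', sample '%s'",
                  rownames(m)[bad[1]], colnames(m)[bad[2]]),
          class = "emtlnc_validation_error")
  }
  m
}

expr_from_matrix <- function(m) {
  out <- as_tibble(as.data.frame(m, check.names = FALSE))
  tibble(feature = rownames(m)) |> dplyr::bind_cols(out)
}

#' Write an expression table to TSV/CSV
#'
#' Round-trips with [read_expression()] at full precision.
#'
#' @param expr Expression tibble (or matrix with rownames).
#' @param path Output path; `.csv` writes comma-separated, anything else tab.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  m <- as_expr_matrix(expr, allow_negative = TRUE)
  tb <- expr_from_matrix(m)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(tb, path, delim = delim)
  invisible(path)
}

#' Read a clinical table
#'
#' Requires columns `sample`, `time_months` and `event`; the covariates `age`,
#' `gender`, `stage`, `cancer_type` and `sample_class` are read when present
#' and may contain missing values. Rows with non-positive follow-up time are
#' dropped with a message.
#'
#' @param path TSV or CSV file.
#' @return A tibble with one row per subject.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "emtlnc_io_error")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           show_col_types = FALSE, progress = FALSE)
  validate_clinical(as_tibble(raw))
}

#' Validate a clinical tibble
#'
#' @param clin Data frame with at least `sample`, `time_months`, `event`.
#' @return Typed tibble with invalid-time rows dropped.
#' @export
validate_clinical <- function(clin) {
  required <- c("sample", "time_months", "event")
  missing_cols <- setdiff(required, names(clin))
  if (length(missing_cols)) {
    abort(paste("clinical table missing required column(s):",
                paste(missing_cols, collapse = ", ")),
          class = "emtlnc_schema_error")
  }
  clin <- as_tibble(clin)
  clin$sample <- as.character(clin$sample)
  if (anyDuplicated(clin$sample)) {
    abort("duplicate sample ids in clinical table", class = "emtlnc_schema_error")
  }
  if (!is.numeric(clin$time_months)) {
    abort("time_months must be numeric", class = "emtlnc_schema_error")
  }
  ev <- clin$event
  if (!is.numeric(ev) || !all(ev %in% c(0, 1) | is.na(ev))) {
    abort("event must be coded 0/1", class = "emtlnc_schema_error")
  }
  clin$event <- as.integer(ev)
  bad <- !is.finite(clin$time_months) | clin$time_months <= 0
  if (any(bad)) {
    warn(sprintf("dropping %d row(s) with non-positive or non-finite time", sum(bad)))
    clin <- clin[!bad, , drop = FALSE]
  }
  if ("stage" %in% names(clin) && !is.ordered(clin$stage)) {
    clin$stage <- factor(clin$stage, ordered = TRUE)
  }
  clin
}

#' Restrict an expression matrix and a sample table to shared samples
#'
#' Both inputs are subset to the intersection of their sample ids and put in
#' the same sample order. Idempotent: aligning twice equals aligning once.
#'
#' @param expr Expression tibble/matrix (samples in columns).
#' @param tbl Data frame with a `sample` column (clinical table, score table).
#' @return A list with elements `expression` (tibble) and `table` (tibble).
#' @export
align_samples <- function(expr, tbl) {
  m <- as_expr_matrix(expr, allow_negative = TRUE)
  stopifnot("sample" %in% names(tbl))
  common <- intersect(colnames(m), tbl$sample)
  if (!length(common)) {
    abort("no shared samples between expression and table",
          class = "emtlnc_alignment_error")
  }
  inform(sprintf("aligned on %d shared sample(s)", length(common)))
  list(
    expression = expr_from_matrix(m[, common, drop = FALSE]),
    table = as_tibble(tbl)[match(common, tbl$sample), , drop = FALSE]
  )
}
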