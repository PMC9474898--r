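#' Classify candidate lncRNAs from their marker-correlation profile
#'
#' Applies the directional selection rules, with strict inequalities at every
#' threshold:
#' * mesenchymal: rho_vim > 0.35, rho with more than `secondary_count - 1` of
#'   FN1/SNAI1/SNAI2 above 0.1, and rho_cdh1 < -0.2;
#' * epithelial: rho_cdh1 > 0.35, negative rho with at least two of
#'   FN1/SNAI1/SNAI2, and rho_vim < -0.2;
#' * otherwise none.
#'
#' The two rule sets are mutually exclusive whenever the same-class anchor
#' threshold is positive and the opposite-anchor threshold negative (as in the
#' defaults), because each class requires the opposite sign of rho_vim.
#'
#' @param profiles Tibble from [profile_markers()] (columns `rho_vim`,
#'   `rho_cdh1`, `rho_fn1`, `rho_snai1`, `rho_snai2`).
#' @param config An [emt_config()].
#' @return Character vector (`"mesenchymal"`, `"epithelial"` or `"none"`), one
#'   per profile row.
#' @export
classify_candidate <- function(profiles, config = emt_config()) {
  need <- c("rho_vim", "rho_cdh1", "rho_fn1", "rho_snai1", "rho_snai2")
  stopifnot(all(need %in% names(profiles)))
  sec <- cbind(profiles$rho_fn1, profiles$rho_snai1, profiles$rho_snai2)
  n_sec_up <- rowSums(sec > config$secondary_min)
  n_sec_neg <- rowSums(sec < 0)
  mes <- profiles$rho_vim > config$vim_min &
    n_sec_up >= config$secondary_count &
    profiles$rho_cdh1 < config$opposite_max
  epi <- profiles$rho_cdh1 > config$vim_min &
    n_sec_neg >= config$secondary_count &
    profiles$rho_vim < config$opposite_max
  dplyr::case_when(mes ~ "mesenchymal", epi ~ "epithelial", .default = "none")
}

#' Signature weight of a selected lncRNA
#'
#' The weight is the sum of the candidate's Spearman rho with CDH1 and with
#' VIM. Under the selection rules this is positive for mesenchymal lncRNAs
#' (rho_vim > 0.35, rho_cdh1 > -1) and negative for epithelial ones.
#'
#' @param profiles Tibble with `rho_vim` and `rho_cdh1` columns.
#' @return Numeric vector of weights.
#' @examples
#' assign_weight(tibble::tibble(rho_vim = 0.40, rho_cdh1 = -0.24))  # 0.16
#' @export
assign_weight <- function(profiles) {
  stopifnot(all(c("rho_vim", "rho_cdh1") %in% names(profiles)))
  profiles$rho_cdh1 + profiles$rho_vim
}

#' Derive an EMT lncRNA signature from an expression matrix
#'
#' Runs the full correlation screen: Spearman profile of every candidate
#' against the marker panel, directional classification, and weight
#' assignment. Entries are ordered by decreasing absolute weight.
#'
#' @inheritParams profile_markers
#' @param config An [emt_config()].
#' @return A tibble of class `emt_signature` with columns `lncrna`,
#'   `emt_class` and `weight`; empty (with a warning) when nothing passes the
#'   rules.
#' @export
derive_signature <- function(expr, panel = marker_panel(), candidates,
                             config = emt_config(), grouping = NULL) {
  prof <- profile_markers(expr, panel, candidates, grouping = grouping)
  prof$emt_class <- classify_candidate(prof, config)
  sel <- prof[prof$emt_class != "none", , drop = FALSE]
  inform(sprintf("selected %d of %d candidate(s) (%d mesenchymal, %d epithelial)",
                 nrow(sel), nrow(prof),
                 sum(sel$emt_class == "mesenchymal"),
                 sum(sel$emt_class == "epithelial")))
  if (!nrow(sel)) {
    warn("no candidate passed the selection rules; returning an empty signature")
    return(new_signature(tibble(lncrna = character(),
                                emt_class = character(),
                                weight = numeric())))
  }
  sel$weight <- assign_weight(sel)
  out <- sel |>
    select("lncrna", "emt_class", "weight") |>
    arrange(desc(abs(.data$weight)))
  new_signature(out)
}

new_signature <- function(tb) {
  stopifnot(all(c("lncrna", "emt_class", "weight") %in% names(tb)))
  if (anyDuplicated(tb$lncrna)) {
    abort("signature ids must be unique", class = "emtlnc_validation_error")
  }
  class(tb) <- c("emt_signature", class(tibble()))
  tb
}

#' The published 15-coefficient EMT signature
#'
#' The signature shipped with the package: 14 mesenchymal lncRNAs with
#' positive weights and one epithelial lncRNA (RP4-568C11.4) with weight
#' -0.048, exactly as printed in the source formula. Identifiers are the
#' mixed HGNC/clone-style names used there (e.g. "RP11-383H13.1").
#'
#' @return An `emt_signature` tibble with 15 rows.
#' @examples
#' published_signature()
#' @export
published_signature <- function() {
  path <- system.file("extdata", "signature_published.json",
                      package = "emtlnc", mustWork = TRUE)
  read_signature(path)
}

#' Read / write a signature
#'
#' JSON (list of `{id, class, weight}` objects) or TSV (`id`, `class`,
#' `weight`) by file extension.
#'
#' @param path File path ending in `.json` or `.tsv`.
#' @return `read_signature()`: an `emt_signature` tibble. `write_signature()`:
#'   `path`, invisibly.
#' @export
read_signature <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    tb <- tibble(lncrna = raw$id, emt_class = raw$class, weight = raw$weight)
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    tb <- tibble(lncrna = raw$id, emt_class = raw$class, weight = raw$weight)
  }
  new_signature(tb)
}

#' @param sig An `emt_signature` (or tibble with the same columns).
#' @rdname read_signature
#' @export
write_signature <- function(sig, path) {
  out <- data.frame(id = sig$lncrna, class = sig$emt_class, weight = sig$weight)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_tsv(out, path)
  }
  invisible(path)
}
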