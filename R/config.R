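#' Analysis configuration
#'
#' Bundles every tunable threshold of the pipeline with the defaults the
#' analysis was designed around: the marker-correlation selection thresholds
#' (anchor rho > 0.35, secondary rho > 0.1 for at least two of FN1/SNAI1/SNAI2,
#' opposite-anchor rho < -0.2), the class-cut quantiles, the FDR level, and the
#' protein / drug correlation cut-offs.
#'
#' @param vim_min Minimum Spearman rho with the same-class anchor marker (VIM
#'   for mesenchymal candidates, CDH1 for epithelial). Strict inequality.
#' @param secondary_min Minimum rho with the secondary mesenchymal markers
#'   (FN1, SNAI1, SNAI2) for the mesenchymal rule. Strict inequality.
#' @param secondary_count How many of the three secondary markers must pass.
#' @param opposite_max Maximum rho with the opposite anchor (CDH1 for
#'   mesenchymal candidates, VIM for epithelial). Strict inequality.
#' @param class_cuts Quantile cuts for the four-level EMT classification,
#'   strictly increasing within (0, 1).
#' @param fdr False-discovery-rate level for the screens.
#' @param protein_rho_cut Absolute-rho cut for the protein screen.
#' @param drug_rho_cut Absolute-rho cut for the drug screen.
#' @param log_transform Apply log2(x + 1) to expression before scoring.
#' @param seed Default random seed used where a function draws random numbers
#'   and no seed is given explicitly.
#'
#' @return A list of class `emt_config`.
#' @examples
#' cfg <- emt_config()
#' cfg$vim_min
#' @export
emt_config <- function(vim_min = 0.35,
                       secondary_min = 0.1,
                       secondary_count = 2L,
                       opposite_max = -0.2,
                       class_cuts = c(0.25, 0.5, 0.75),
                       fdr = 0.05,
                       protein_rho_cut = 0.2,
                       drug_rho_cut = 0.15,
                       log_transform = FALSE,
                       seed = 1L) {
  stopifnot(is.numeric(vim_min), is.numeric(secondary_min),
            is.numeric(opposite_max), is.numeric(class_cuts))
  if (abs(vim_min) > 1 || abs(secondary_min) > 1 || abs(opposite_max) > 1) {
    abort("correlation thresholds must lie in [-1, 1]", class = "emtlnc_config_error")
  }
  if (any(class_cuts <= 0) || any(class_cuts >= 1) ||
      any(diff(class_cuts) <= 0)) {
    abort("class_cuts must be strictly increasing within (0, 1)",
          class = "emtlnc_config_error")
  }
  if (fdr <= 0 || fdr >= 1) {
    abort("fdr must lie in (0, 1)", class = "emtlnc_config_error")
  }
  structure(
    list(vim_min = vim_min, secondary_min = secondary_min,
         secondary_count = as.integer(secondary_count),
         opposite_max = opposite_max, class_cuts = class_cuts, fdr = fdr,
         protein_rho_cut = protein_rho_cut, drug_rho_cut = drug_rho_cut,
         log_transform = isTRUE(log_transform), seed = as.integer(seed)),
    class = "emt_config"
  )
}

#' Read an analysis configuration from a YAML/JSON-like key-value file
#'
#' Accepts a JSON file whose keys mirror [emt_config()] arguments; absent keys
#' keep their defaults.
#'
#' @param path Path to a JSON configuration file.
#' @return An `emt_config` list.
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(emt_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    warn(paste("ignoring unknown config keys:", paste(extra, collapse = ", ")))
  }
  do.call(emt_config, vals[intersect(names(vals), known)])
}

#' EMT marker panel
#'
#' The five anchor genes of the screen: VIM, FN1, SNAI1 and SNAI2 mark the
#' mesenchymal state, CDH1 (E-cadherin) the epithelial state. Identifiers are
#' opaque strings matched against expression-matrix feature ids, so Ensembl ids
#' or any other nomenclature can be supplied.
#'
#' @param vim,cdh1,fn1,snai1,snai2 Feature identifier of each marker.
#' @return A named character vector of class `emt_marker_panel` with elements
#'   `vim`, `cdh1`, `fn1`, `snai1`, `snai2`.
#' @examples
#' marker_panel()
#' @export
marker_panel <- function(vim = "VIM", cdh1 = "CDH1", fn1 = "FN1",
                         snai1 = "SNAI1", snai2 = "SNAI2") {
  ids <- c(vim = vim, cdh1 = cdh1, fn1 = fn1, snai1 = snai1, snai2 = snai2)
  if (anyDuplicated(ids)) {
    abort("marker panel ids must be distinct", class = "emtlnc_panel_error")
  }
  if (any(!nzchar(ids)) || anyNA(ids)) {
    abort("marker panel ids must be non-empty strings", class = "emtlnc_panel_error")
  }
  structure(ids, class = "emt_marker_panel")
}
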