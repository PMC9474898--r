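#' Specification for the synthetic EMT cohort generator
#'
#' Describes a cohort whose statistical structure matches what the pipeline
#' assumes: a latent EMT level m in [0, 1] per sample (Beta-distributed around
#' a per-cancer-type mean), log-normal expression for every feature with a
#' planted log-linear loading on m (`x = exp(alpha + lambda * m + eps)`),
#' proportional-hazards survival driven by m, a centred protein layer and a
#' log-IC50 drug layer, each with signed loadings on m.
#'
#' @param n_samples Named integer vector: samples per cancer type.
#' @param latent_means Named numeric vector in \[0, 1\]: mean latent EMT level
#'   per cancer type (names must match `n_samples`).
#' @param concentration Beta concentration; larger = tighter around the mean.
#' @param marker_loadings Named numeric vector of log-linear loadings for the
#'   five markers (positive for VIM/FN1/SNAI1/SNAI2, negative for CDH1).
#' @param planted Tibble with columns `id`, `class`
#'   (`"mesenchymal"`/`"epithelial"`) and `loading`: the signal lncRNAs.
#' @param n_decoys Number of null lncRNAs with zero loading.
#' @param sigma Standard deviation of the log-scale expression noise.
#' @param alpha_mean,alpha_sd Mean and sd of the per-feature baseline
#'   log-abundance `alpha`.
#' @param h0 Baseline hazard per month.
#' @param gamma Log-hazard coefficient on the latent EMT level.
#' @param censoring Target censoring fraction in \[0, 1).
#' @param proteins Tibble (`id`, `loading`) for the centred protein layer.
#' @param drugs Tibble (`id`, `loading`) for the log-IC50 drug layer.
#' @return A validated list of class `emt_generator_spec`.
#' @seealso [default_emt_spec()], [simulate_emt_cohort()]
#' @export
emt_generator_spec <- function(n_samples,
                               latent_means,
                               concentration = 10,
                               marker_loadings = c(vim = 2, cdh1 = -1,
                                                   fn1 = 1.5, snai1 = 1.5,
                                                   snai2 = 1.5),
                               planted = tibble(id = character(),
                                                class = character(),
                                                loading = numeric()),
                               n_decoys = 200L,
                               sigma = 0.4,
                               alpha_mean = 2,
                               alpha_sd = 0.5,
                               h0 = 0.02,
                               gamma = 0.7,
                               censoring = 0.3,
                               proteins = NULL,
                               drugs = NULL) {
  if (is.null(names(n_samples)) || is.null(names(latent_means)) ||
      !setequal(names(n_samples), names(latent_means))) {
    abort("n_samples and latent_means must share cancer-type names",
          class = "emtlnc_spec_error")
  }
  if (any(latent_means < 0 | latent_means > 1)) {
    abort("latent_means must lie in [0, 1]", class = "emtlnc_spec_error")
  }
  if (sigma <= 0 || h0 <= 0) {
    abort("sigma and h0 must be positive", class = "emtlnc_spec_error")
  }
  if (censoring < 0 || censoring >= 1) {
    abort("censoring must lie in [0, 1)", class = "emtlnc_spec_error")
  }
  if (!all(c("vim", "cdh1", "fn1", "snai1", "snai2") %in% names(marker_loadings))) {
    abort("marker_loadings must name vim, cdh1, fn1, snai1, snai2",
          class = "emtlnc_spec_error")
  }
  planted <- as_tibble(planted)
  if (nrow(planted)) {
    stopifnot(all(c("id", "class", "loading") %in% names(planted)))
    if (!all(planted$class %in% c("mesenchymal", "epithelial"))) {
      abort("planted class must be mesenchymal or epithelial",
            class = "emtlnc_spec_error")
    }
    if (anyDuplicated(planted$id)) {
      abort("planted ids must be unique", class = "emtlnc_spec_error")
    }
  }
  if (!all(is.finite(c(marker_loadings, planted$loading)))) {
    abort("loadings must be finite", class = "emtlnc_spec_error")
  }
  structure(
    list(n_samples = as.integer(n_samples)[order(names(n_samples))] |>
           setNames(sort(names(n_samples))),
         latent_means = latent_means[sort(names(latent_means))],
         concentration = concentration,
         marker_loadings = marker_loadings,
         planted = planted,
         n_decoys = as.integer(n_decoys),
         sigma = sigma, alpha_mean = alpha_mean, alpha_sd = alpha_sd,
         h0 = h0, gamma = gamma, censoring = censoring,
         proteins = if (is.null(proteins)) default_protein_layer() else as_tibble(proteins),
         drugs = if (is.null(drugs)) default_drug_layer() else as_tibble(drugs)),
    class = "emt_generator_spec"
  )
}

default_protein_layer <- function() {
  tibble(
    id = c(paste0("PROT_POS_", 1:5), paste0("PROT_NEG_", 1:5),
           paste0("PROT_NULL_", 1:20)),
    loading = c(rep(1.5, 5), rep(-1.5, 5), rep(0, 20))
  )
}

default_drug_layer <- function() {
  tibble(
    id = c(paste0("DRUG_POS_", 1:3), paste0("DRUG_NEG_", 1:3)),
    loading = c(rep(1, 3), rep(-1, 3))
  )
}

#' Default generator preset mirroring the published signature structure
#'
#' Four cancer types of 500 samples each (2000 samples) with latent EMT means
#' spread over \[0.2, 0.8\]; one planted lncRNA per entry of the published
#' signature (mesenchymal entries with positive loading, the epithelial entry
#' negative) and 200 null decoys.
#'
#' @param loading Magnitude of the planted lncRNA loadings.
#' @param sigma Log-scale expression noise sd.
#' @return An `emt_generator_spec`.
#' @examples
#' spec <- default_emt_spec()
#' nrow(spec$planted)
#' @export
default_emt_spec <- function(loading = 1.8, sigma = 0.4) {
  sig <- published_signature()
  emt_generator_spec(
    n_samples = c(typeA = 500L, typeB = 500L, typeC = 500L, typeD = 500L),
    latent_means = c(typeA = 0.2, typeB = 0.4, typeC = 0.6, typeD = 0.8),
    planted = tibble(
      id = sig$lncrna,
      class = sig$emt_class,
      loading = ifelse(sig$emt_class == "mesenchymal", loading, -loading)
    ),
    n_decoys = 200L,
    sigma = sigma
  )
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws, deterministically for a given seed, the latent EMT level per sample,
#' the expression of markers, planted lncRNAs and decoys, survival outcomes
#' under a proportional-hazards model, a centred protein layer and a log-IC50
#' drug layer. Censoring times are uniform on \[0, T_max\] and independent of
#' the event times, with T_max solved so the expected censoring fraction equals
#' the requested rate.
#'
#' @param spec An [emt_generator_spec()].
#' @param seed Integer seed; identical (spec, seed) gives identical cohorts.
#' @return A list of class `emt_cohort` with elements `expression`, `clinical`,
#'   `protein`, `drug_response` (all tibbles) and `truth` (list with `latent`
#'   per sample and `loadings` per feature).
#' @examples
#' spec <- emt_generator_spec(
#'   n_samples = c(a = 30, b = 30), latent_means = c(a = 0.3, b = 0.7),
#'   planted = tibble::tibble(id = "LNC1", class = "mesenchymal", loading = 2)
#' )
#' coh <- simulate_emt_cohort(spec, seed = 1)
#' head(coh$truth$latent)
#' @export
simulate_emt_cohort <- function(spec, seed = 1L) {
  if (!inherits(spec, "emt_generator_spec")) {
    abort("spec must be an emt_generator_spec", class = "emtlnc_spec_error")
  }
  withr::with_seed(as.integer(seed), simulate_cohort_impl(spec))
}

simulate_cohort_impl <- function(spec) {
  types <- rep(names(spec$n_samples), spec$n_samples)
  n <- length(types)
  samples <- sprintf("S%04d", seq_len(n))

  mu <- spec$latent_means[types]
  k <- spec$concentration
  m <- rbeta(n, shape1 = mu * k, shape2 = (1 - mu) * k)

  panel <- marker_panel()
  loadings <- tibble(
    feature = c(unname(panel[names(spec$marker_loadings)]),
                spec$planted$id,
                if (spec$n_decoys > 0) sprintf("DECOY_%04d", seq_len(spec$n_decoys))),
    layer = c(rep("marker", length(spec$marker_loadings)),
              rep("lncrna", nrow(spec$planted)),
              rep("decoy", spec$n_decoys)),
    class = c(rep(NA_character_, length(spec$marker_loadings)),
              spec$planted$class, rep(NA_character_, spec$n_decoys)),
    loading = c(unname(spec$marker_loadings), spec$planted$loading,
                rep(0, spec$n_decoys))
  )
  p <- nrow(loadings)
  alpha <- rnorm(p, spec$alpha_mean, spec$alpha_sd)
  eps <- matrix(rnorm(p * n, 0, spec$sigma), nrow = p)
  x <- exp(alpha + outer(loadings$loading, m) + eps)
  dimnames(x) <- list(loadings$feature, samples)

  clinical <- simulate_survival(spec, m, samples, types)

  prot <- spec$proteins
  pe <- matrix(rnorm(nrow(prot) * n, 0, 0.5), nrow = nrow(prot))
  pm <- outer(prot$loading, m) + pe
  dimnames(pm) <- list(prot$id, samples)

  drg <- spec$drugs
  de <- matrix(rnorm(nrow(drg) * n, 0, 0.5), nrow = nrow(drg))
  dm <- outer(drg$loading, m) + de      # log-IC50 scale
  drug_response <- as_tibble(as.data.frame(t(dm), check.names = FALSE))
  names(drug_response) <- drg$id
  drug_response <- dplyr::bind_cols(tibble(sample = samples), drug_response)

  structure(
    list(
      expression = expr_from_matrix(x),
      clinical = clinical,
      protein = expr_from_matrix(pm),
      drug_response = drug_response,
      truth = list(
        latent = tibble(sample = samples, cancer_type = types, latent = m),
        loadings = dplyr::bind_rows(
          loadings,
          tibble(feature = prot$id, layer = "protein",
                 class = NA_character_, loading = prot$loading),
          tibble(feature = drg$id, layer = "drug",
                 class = NA_character_, loading = drg$loading)
        )
      )
    ),
    class = "emt_cohort"
  )
}

simulate_survival <- function(spec, m, samples, types) {
  n <- length(m)
  hazard <- spec$h0 * exp(spec$gamma * m)
  t_event <- rexp(n, rate = hazard)
  if (spec$censoring > 0) {
    t_max <- censoring_horizon(hazard, spec$censoring)
    t_cens <- runif(n, 0, t_max)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  tibble(
    sample = samples,
    time_months = pmax(time, .Machine$double.eps),
    event = event,
    age = round(rnorm(n, 60, 10), 1),
    gender = sample(c("female", "male"), n, replace = TRUE),
    stage = factor(sample(c("I", "II", "III", "IV"), n, replace = TRUE),
                   levels = c("I", "II", "III", "IV"), ordered = TRUE),
    cancer_type = types,
    sample_class = "tumor"
  )
}

# P(C < T) for C ~ U(0, t_max), T ~ Exp(h) is (1 - exp(-h t_max)) / (h t_max);
# solve t_max so the cohort-average censoring probability hits the target.
censoring_horizon <- function(hazard, target) {
  f <- function(t_max) {
    mean((1 - exp(-hazard * t_max)) / (hazard * t_max)) - target
  }
  uniroot(f, lower = 1e-6, upper = 1e9, tol = 1e-8)$root
}

#' Build a 2x2 contingency table from cell counts
#'
#' Fixture helper for exact-test checks.
#'
#' @param counts Length-4 numeric vector or 2x2 matrix of non-negative integer
#'   cell counts (row-major for a vector).
#' @return A 2x2 integer matrix.
#' @examples
#' generate_contingency(c(5, 0, 0, 5))
#' @export
generate_contingency <- function(counts) {
  if (is.matrix(counts) && all(dim(counts) == c(2, 2))) {
    m <- counts
  } else if (length(counts) == 4) {
    m <- matrix(as.vector(counts), 2, 2, byrow = TRUE)
  } else {
    abort("need exactly four cell counts", class = "emtlnc_validation_error")
  }
  if (any(m < 0) || any(m != round(m)) || anyNA(m)) {
    abort("cell counts must be non-negative integers",
          class = "emtlnc_validation_error")
  }
  storage.mode(m) <- "integer"
  m
}
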