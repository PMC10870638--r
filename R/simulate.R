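#' Thresholds from target occurrence rates
#'
#' Inverts the latent-threshold model that underlies tetrachoric
#' correlations: a binary item is "present" when a standard-normal latent
#' exceeds its threshold, so an item with occurrence probability `p` has
#' threshold `qnorm(1 - p)`.
#'
#' @param rates Per-item occurrence proportions, each strictly in (0, 1).
#' @return Numeric vector of thresholds, same length and names as `rates`.
#' @export
#' @examples
#' thresholds_from_rates(c(0.5, 0.845)) # 0 and about -1.015
thresholds_from_rates <- function(rates) {
  if (any(rates <= 0 | rates >= 1)) {
    stop("occurrence rates must be strictly inside (0, 1)")
  }
  stats::qnorm(1 - rates)
}

#' Configuration of the latent-factor symptom generator
#'
#' Bundles and validates the parameters of the thresholded-Gaussian factor
#' model used by [simulate_symptoms()]: latent factor scores are drawn from
#' a multivariate normal with correlation matrix `phi`, each item's latent
#' response is its loading row times the factor scores plus independent
#' noise scaled so the latent has unit variance, and the item is "present"
#' when the latent exceeds its threshold.
#'
#' @param loadings Item-by-factor loading matrix (row names = item codes).
#' @param phi Factor correlation matrix: symmetric, positive definite, unit
#'   diagonal. Scalar shorthand gives that constant off-diagonal.
#' @param thresholds Per-item latent thresholds (see
#'   [thresholds_from_rates()]).
#' @param n Number of patients to simulate.
#' @param age_range Length-2 vector; ages are drawn uniformly from it.
#' @param severity_cutpoints Three increasing cutpoints on the latent excess
#'   `y - tau` mapping it to severity 1-4 for present symptoms.
#' @param distress_cutpoints Four increasing cutpoints mapping the latent
#'   excess to distress 0-4.
#' @param group Free-text tag recorded in the dataset provenance.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(loadings, phi, thresholds, n,
                             age_range = c(30, 85),
                             severity_cutpoints = stats::qnorm(c(0.625, 0.75, 0.875)),
                             distress_cutpoints = stats::qnorm(c(0.6, 0.7, 0.8, 0.9)),
                             group = "simulated") {
  loadings <- as.matrix(loadings)
  k <- ncol(loadings)
  if (length(phi) == 1 && k > 1) {
    phi <- matrix(phi, k, k)
    diag(phi) <- 1
  }
  phi <- as.matrix(phi)
  stopifnot(
    nrow(phi) == k, ncol(phi) == k,
    isTRUE(all.equal(phi, t(phi))),
    isTRUE(all.equal(unname(diag(phi)), rep(1, k))),
    length(thresholds) == nrow(loadings),
    length(severity_cutpoints) == 3, !is.unsorted(severity_cutpoints, strictly = TRUE),
    length(distress_cutpoints) == 4, !is.unsorted(distress_cutpoints, strictly = TRUE),
    n >= 1, length(age_range) == 2, age_range[1] < age_range[2]
  )
  if (min(eigen(phi, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("factor correlation matrix must be positive definite")
  }
  communality <- rowSums((loadings %*% phi) * loadings)
  too_big <- communality > 1 + 1e-12
  if (any(too_big)) {
    stop("communality exceeds 1 for item(s): ",
         paste(rownames(loadings)[too_big], collapse = ", "))
  }
  structure(
    list(
      loadings = loadings, phi = phi, thresholds = thresholds, n = as.integer(n),
      age_range = age_range, severity_cutpoints = severity_cutpoints,
      distress_cutpoints = distress_cutpoints, group = group,
      communality = communality
    ),
    class = "generator_config"
  )
}

#' Default generating model calibrated to the published two-group study
#'
#' Builds a [generator_config()] whose loading pattern places each symptom
#' on its published cluster with the printed rotated loading (values printed
#' above 1, which oblique loadings permit, are clipped to 0.95 so residual
#' variances stay nonnegative under the generating model), zeros elsewhere;
#' factor correlations default to a modest 0.2 off-diagonal (geomin is
#' oblique, so the generator exercises correlated factors); thresholds come
#' from the published per-group occurrence rates. Ages are uniform on
#' [30, 59.9] for the younger group and [60, 85] for the older group.
#'
#' @param group `"younger"` or `"older"`.
#' @param n Sample size; defaults to the published group size (741 younger,
#'   602 older).
#' @param phi_offdiag Constant inter-factor correlation.
#' @return A `"generator_config"`.
#' @export
default_generating_model <- function(group = c("younger", "older"), n = NULL,
                                     phi_offdiag = 0.2) {
  group <- match.arg(group)
  loadings <- pmin(reference_loading_matrix(group), 0.95)
  rates <- reference_occurrence_rates()
  pct <- if (group == "younger") rates$pct_younger else rates$pct_older
  names(pct) <- rates$code
  tau <- thresholds_from_rates(pct[rownames(loadings)] / 100)
  if (is.null(n)) n <- if (group == "younger") 741L else 602L
  age_range <- if (group == "younger") c(30, 59.9) else c(60, 85)
  generator_config(
    loadings = loadings, phi = phi_offdiag, thresholds = tau, n = n,
    age_range = age_range, group = group
  )
}

#' Simulate a patient-level symptom dataset
#'
#' Draws `config$n` patients from the latent thresholded-Gaussian model:
#' factor scores `f ~ MVN(0, phi)`, item latents `y = loadings %*% f + e`
#' with residual variance `1 - communality` (so each latent is standard
#' normal marginally), occurrence `y > tau`. For present symptoms the
#' severity is `1 +` the number of severity cutpoints below the latent
#' excess `y - tau`, and distress analogously with the distress cutpoints;
#' both ratings are missing where the symptom is absent. Ages are uniform
#' on the configured range. The population tetrachoric correlation between
#' items i and j is the (i, j) entry of
#' `loadings %*% phi %*% t(loadings)`.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; identical seed and config give an identical
#'   dataset (the caller's RNG state is untouched).
#' @return A symptom dataset tibble as produced by [read_symptom_data()].
#' @export
simulate_symptoms <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n
  lambda <- config$loadings
  p <- nrow(lambda)
  k <- ncol(lambda)
  codes <- rownames(lambda) %||% paste0("item", seq_len(p))
  withr::with_seed(seed, {
    f <- matrix(stats::rnorm(n * k), n, k) %*% chol(config$phi)
    e <- matrix(stats::rnorm(n * p), n, p) %*%
      diag(sqrt(pmax(1 - config$communality, 0)), p)
    y <- f %*% t(lambda) + e
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
  })
  tau <- matrix(config$thresholds, n, p, byrow = TRUE)
  occ <- (y > tau) * 1L
  excess <- y - tau
  sev <- 1L + (excess > config$severity_cutpoints[1]) +
    (excess > config$severity_cutpoints[2]) +
    (excess > config$severity_cutpoints[3])
  dis <- (excess > config$distress_cutpoints[1]) +
    (excess > config$distress_cutpoints[2]) +
    (excess > config$distress_cutpoints[3]) +
    (excess > config$distress_cutpoints[4])
  sev[occ == 0L] <- NA_integer_
  dis[occ == 0L] <- NA_integer_
  data <- tibble::tibble(
    patient_id = sprintf("%s%05d", substr(config$group, 1, 1), seq_len(n)),
    age = age
  )
  for (j in seq_len(p)) {
    data[[paste0("occ_", codes[j])]] <- as.integer(occ[, j])
    data[[paste0("sev_", codes[j])]] <- as.integer(sev[, j])
    data[[paste0("dis_", codes[j])]] <- as.integer(dis[, j])
  }
  items <- tibble::tibble(code = codes, label = codes,
                          index = seq_along(codes))
  known <- msas_items()
  if (all(codes %in% known$code)) items <- known[match(codes, known$code), ]
  attr(data, "items") <- items
  attr(data, "provenance") <- paste0("simulated:", config$group, ":seed=", seed)
  data
}

#' Model-implied correlation matrix of a generator
#'
#' @param config A [generator_config()].
#' @return The population latent correlation matrix
#'   `loadings %*% phi %*% t(loadings)` with unit diagonal.
#' @export
population_correlations <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  R <- config$loadings %*% config$phi %*% t(config$loadings)
  diag(R) <- 1
  R
}
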