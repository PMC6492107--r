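# Run code with a private RNG stream, restoring the caller's state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministically derive independent sub-seeds from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Specification of a synthetic morphometry cohort
#'
#' Defines a generative model with the statistical structure the normative
#' approach assumes: jointly Gaussian regional features given age and sex,
#' with linear age slopes, additive sex offsets, inter-regional correlation
#' induced by a small number of latent factors, and independent regional
#' noise. Patient groups can differ from controls by regional mean shifts
#' (expressed in units of each feature's healthy marginal SD, so that effect
#' sizes are scale-free across mm and mm^3 features) and/or by a replaced
#' loading matrix (altered inter-regional correlation with no mean change).
#'
#' Default magnitudes emulate adult cortical morphometry: baseline thickness
#' 2.5 mm with ~0.14 mm total SD, baseline volumes 5000 mm^3 with ~540 mm^3
#' total SD, ~60% of variance shared through 12 latent factors, mild cortical
#' thinning with age and larger volumes in males.
#'
#' @param n_reference,n_controls,n_patients Cohort sizes (reference = healthy
#'   training cohort; controls/patients = clinical test cohort).
#' @param schema A `feature_schema`; features and default magnitudes follow it.
#' @param baseline_mean Per-feature mean at the age midpoint (length 1 values
#'   are expanded by feature kind; see details).
#' @param age_slopes Per-feature change per year of age.
#' @param sex_offsets Per-feature additive offset for male subjects.
#' @param n_factors Number of latent factors.
#' @param loadings Optional features x factors loading matrix; by default
#'   drawn once, deterministically from `seed`, with per-kind scale.
#' @param noise_sd Per-feature independent noise SD (scalar or vector).
#' @param age_range Inclusive integer age range (uniform over integers).
#' @param male_fraction Probability of male sex.
#' @param affected_regions Integer indices of regions shifted in patients.
#' @param shift_sizes Shift per affected region, in marginal-SD units.
#' @param loading_perturbation Optional replacement loading matrix for
#'   patients (same dimensions as `loadings`).
#' @param seed Integer seed; generation is fully deterministic given the spec.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_reference = 1000, n_controls = 100, n_patients = 100,
                        schema = default_schema(),
                        baseline_mean = NULL, age_slopes = NULL,
                        sex_offsets = NULL, n_factors = 12, loadings = NULL,
                        noise_sd = NULL, age_range = c(22L, 37L),
                        male_fraction = 0.5,
                        affected_regions = integer(0),
                        shift_sizes = numeric(0),
                        loading_perturbation = NULL, seed = 1L) {
  if (any(c(n_reference, n_controls, n_patients) < 0)) {
    stop("cohort sizes must be non-negative")
  }
  p <- nrow(schema)
  is_thick <- schema$kind == "thickness"
  per_kind <- function(x, thick_val, vol_val) {
    if (is.null(x)) x <- ifelse(is_thick, thick_val, vol_val)
    if (length(x) == 1) x <- rep(x, p)
    stopifnot(length(x) == p)
    as.numeric(x)
  }
  baseline_mean <- per_kind(baseline_mean, 2.5, 5000)
  age_slopes <- per_kind(age_slopes, -0.003, -10)
  sex_offsets <- per_kind(sex_offsets, 0, 400)
  noise_sd <- per_kind(noise_sd, 0.09, 340)
  if (any(noise_sd <= 0)) stop("noise_sd must be positive")
  if (is.null(loadings)) {
    scale_f <- ifelse(is_thick, 0.11, 420)
    loadings <- with_seed(seed, {
      matrix(stats::rnorm(p * n_factors), p, n_factors) / sqrt(max(n_factors, 1)) * scale_f
    })
  }
  loadings <- as.matrix(loadings)
  stopifnot(nrow(loadings) == p, all(is.finite(loadings)))
  n_factors <- ncol(loadings)
  if (length(shift_sizes) == 1 && length(affected_regions) > 1) {
    shift_sizes <- rep(shift_sizes, length(affected_regions))
  }
  if (length(shift_sizes) != length(affected_regions)) {
    stop("shift_sizes must match affected_regions in length")
  }
  if (!is.null(loading_perturbation)) {
    loading_perturbation <- as.matrix(loading_perturbation)
    stopifnot(dim(loading_perturbation) == dim(loadings))
  }
  structure(list(
    n_reference = n_reference, n_controls = n_controls,
    n_patients = n_patients, schema = schema, baseline_mean = baseline_mean,
    age_slopes = age_slopes, sex_offsets = sex_offsets, loadings = loadings,
    noise_sd = noise_sd, age_range = as.integer(age_range),
    male_fraction = male_fraction,
    affected_regions = as.integer(affected_regions),
    shift_sizes = as.numeric(shift_sizes),
    loading_perturbation = loading_perturbation, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Closed-form healthy marginal SD of each feature
#'
#' The total per-feature SD of the healthy generative model, combining factor
#' variance, independent noise, and the variance induced by age and sex
#' mixing: `sqrt(rowSums(L^2) + noise^2 + slope^2 Var(age) + offset^2 m(1-m))`
#' with age uniform over the integers of the range. Used to calibrate
#' patient shifts in scale-free units.
#'
#' @param spec A `cohort_spec`.
#' @return Numeric vector of per-feature SDs.
#' @export
marginal_sd <- function(spec) {
  k <- spec$age_range[2] - spec$age_range[1] + 1
  var_age <- (k^2 - 1) / 12
  m <- spec$male_fraction
  sqrt(rowSums(spec$loadings^2) + spec$noise_sd^2 +
         spec$age_slopes^2 * var_age + spec$sex_offsets^2 * m * (1 - m))
}

draw_subjects <- function(spec, n, prefix, group, dataset, loadings, shift) {
  p <- nrow(spec$schema)
  if (n == 0) {
    x <- matrix(numeric(0), 0, p, dimnames = list(NULL, spec$schema$name))
    return(cbind(data.frame(subject_id = character(0), age = integer(0),
                            sex = character(0), group = character(0),
                            dataset = character(0), stringsAsFactors = FALSE),
                 as.data.frame(x, optional = TRUE)))
  }
  age <- sample(seq.int(spec$age_range[1], spec$age_range[2]), n, replace = TRUE)
  male <- stats::runif(n) < spec$male_fraction
  f <- matrix(stats::rnorm(n * ncol(loadings)), n, ncol(loadings))
  eps <- sweep(matrix(stats::rnorm(n * p), n, p), 2, spec$noise_sd, "*")
  mid <- mean(spec$age_range)
  x <- matrix(spec$baseline_mean, n, p, byrow = TRUE) +
    outer(age - mid, spec$age_slopes) +
    outer(as.numeric(male), spec$sex_offsets) +
    f %*% t(loadings) + eps
  x <- sweep(x, 2, shift, "+")
  colnames(x) <- spec$schema$name
  df <- data.frame(
    subject_id = sprintf("%s%04d", prefix, seq_len(n)),
    age = age, sex = ifelse(male, "M", "F"), group = group, dataset = dataset,
    stringsAsFactors = FALSE
  )
  cbind(df, as.data.frame(x, optional = TRUE))
}

#' Generate a synthetic reference and clinical cohort
#'
#' Draws a healthy reference cohort plus a clinical cohort of healthy controls
#' and patients under the generative model of a [cohort_spec()]. Patients get
#' the spec's mean shifts (in marginal-SD units) on the affected regions and,
#' if given, the perturbed loading matrix. Byte-identical output for the same
#' spec.
#'
#' @param spec A `cohort_spec`.
#' @return List with `reference` and `clinical` morphometry tables; the
#'   clinical table holds groups `"HC"` and `"PAT"` under dataset
#'   `"clinical"`.
#' @export
generate_cohort <- function(spec) {
  msd <- marginal_sd(spec)
  shift <- numeric(nrow(spec$schema))
  shift[spec$affected_regions] <- spec$shift_sizes * msd[spec$affected_regions]
  pat_loadings <- if (is.null(spec$loading_perturbation)) spec$loadings
                  else spec$loading_perturbation
  seeds <- derive_seeds(spec$seed, 3)
  zero <- numeric(nrow(spec$schema))
  reference <- with_seed(seeds[1], draw_subjects(
    spec, spec$n_reference, "ref", "HC", "reference", spec$loadings, zero))
  controls <- with_seed(seeds[2], draw_subjects(
    spec, spec$n_controls, "hc", "HC", "clinical", spec$loadings, zero))
  patients <- with_seed(seeds[3], draw_subjects(
    spec, spec$n_patients, "pt", "PAT", "clinical", pat_loadings, shift))
  list(
    reference = as_morphometry_table(reference, spec$schema,
                                     age_range = spec$age_range),
    clinical = as_morphometry_table(rbind(controls, patients), spec$schema,
                                    age_range = spec$age_range)
  )
}

#' Replace selected regions' loadings by rotated vectors of equal norm
#'
#' Gives each selected region a fresh random loading direction with the same
#' norm, altering its correlation with other regions while leaving its
#' marginal variance (and mean) unchanged. This implements the
#' "covariance-only" alteration mechanism: a region can deviate from the
#' normative inter-regional pattern without any mean difference.
#'
#' @param loadings Features x factors loading matrix.
#' @param regions Integer indices of regions to decorrelate.
#' @param seed Integer seed.
#' @return Modified loading matrix.
#' @export
decorrelate_loadings <- function(loadings, regions, seed = 1L) {
  with_seed(seed, {
    for (r in regions) {
      v <- stats::rnorm(ncol(loadings))
      loadings[r, ] <- v / sqrt(sum(v^2)) * sqrt(sum(loadings[r, ]^2))
    }
    loadings
  })
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(paste0("<cohort_spec> reference n=%d, controls n=%d, patients n=%d\n",
                     "  %d features, %d factors, %d shifted region(s), seed %d\n"),
              x$n_reference, x$n_controls, x$n_patients, nrow(x$schema),
              ncol(x$loadings), length(x$affected_regions), x$seed))
  invisible(x)
}
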