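# Synthetic cohorts with the statistical structure the analysis assumes:
# thresholded-Gaussian ordinal items under a correlated-factor pattern,
# plus sparse missingness, non-scorable answers and a null generator.

#' Configure the synthetic cohort generator
#'
#' Defaults emulate the study conditions: four country strata of four
#' hospitals each, three data-collection rounds of 51 women per hospital
#' (2448 respondents), the published six-factor loading pattern with
#' inter-factor correlation 0.3, equal-probability category thresholds,
#' and sparse completely-at-random missingness at the scale reported for
#' the field study (about 15 affected respondents in 2448, of whom about
#' one exceeds the exclusion threshold).
#'
#' @param schema Questionnaire schema (default the shipped fixture).
#' @param spec Factor specification used as the generating pattern
#'   (default the shipped published loadings). Items outside the spec are
#'   generated as independent noise.
#' @param phi Inter-factor correlation: scalar off-diagonal value or a
#'   full positive-definite matrix.
#' @param n_per_country Named vector of respondents per country.
#' @param rounds,hospitals_per_country Stratum layout.
#' @param thresholds `"equal"` for equal-probability categories or
#'   `"skewed"` for a ceiling-effect preset stressing boundary handling.
#' @param missing_row_rate Fraction of respondents receiving missing
#'   cells.
#' @param missing_count_probs Distribution of the per-affected-row missing
#'   count (names = counts). The default puts most mass at 5 or fewer so
#'   that roughly one affected respondent in fifteen exceeds the
#'   exclusion threshold.
#' @param non_scored_rate Per-cell probability of replacing a response
#'   with a non-scorable answer, for items whose scale declares any.
#' @param max_abs_loading Generating loadings are clipped to this
#'   magnitude: published pattern coefficients above 1 are legal in an
#'   oblique solution but not as standardized generating coefficients.
#' @return A list of class `rrt_simconfig`.
#' @export
simulation_config <- function(schema = rrt_schema_fixture(),
                              spec = rrt_factors_fixture(),
                              phi = 0.3,
                              n_per_country = c(Benin = 612, Malawi = 612,
                                                Tanzania = 612,
                                                Uganda = 612),
                              rounds = 3, hospitals_per_country = 4,
                              thresholds = c("equal", "skewed"),
                              missing_row_rate = 15 / 2448,
                              missing_count_probs = c("1" = 0.35,
                                                      "2" = 0.25,
                                                      "3" = 0.15,
                                                      "4" = 0.10,
                                                      "5" = 0.08,
                                                      "7" = 0.07),
                              non_scored_rate = 0.01,
                              max_abs_loading = 0.95) {
  thresholds <- match.arg(thresholds)
  k <- length(spec$factors)
  if (is.matrix(phi)) {
    Phi <- phi
  } else {
    Phi <- matrix(phi, k, k)
    diag(Phi) <- 1
  }
  if (min(eigen(Phi, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("factor correlation matrix is not positive definite",
         call. = FALSE)
  validate_factor_spec(spec, schema)
  stopifnot(missing_row_rate >= 0, missing_row_rate <= 1,
            non_scored_rate >= 0, non_scored_rate <= 1,
            abs(sum(missing_count_probs) - 1) < 1e-8)
  structure(list(schema = schema, spec = spec, Phi = Phi,
                 n_per_country = n_per_country, rounds = rounds,
                 hospitals_per_country = hospitals_per_country,
                 thresholds = thresholds,
                 missing_row_rate = missing_row_rate,
                 missing_count_probs = missing_count_probs,
                 non_scored_rate = non_scored_rate,
                 max_abs_loading = max_abs_loading),
            class = "rrt_simconfig")
}

config_thresholds <- function(config) {
  nc <- schema_ncat(config$schema)
  lapply(seq_along(nc), function(j) {
    c <- nc[j]
    if (config$thresholds == "equal") {
      qnorm(seq_len(c - 1) / c)
    } else {
      # ceiling preset: most mass in the top category
      p <- 0.6^(rev(seq_len(c)))
      p <- p / sum(p)
      qnorm(cumsum(p)[-c])
    }
  })
}

#' Simulate a cohort from the thresholded-Gaussian factor model
#'
#' Draws correlated standard-normal factor scores, builds each item's
#' latent response as its loading times its factor plus unique noise
#' scaled to unit total variance, and discretizes through the item's
#' thresholds into ordinal codes (worst to best). Items flagged as
#' reverse-coded in the schema are then flipped back to raw orientation,
#' so the output is a raw matrix exactly as the cleaning step expects.
#'
#' @param config An `rrt_simconfig`.
#' @param seed Integer seed; the cohort is reproducible.
#' @return A list of class `rrt_cohort`: `raw` (an `rrt_raw`), `latents`
#'   (factor scores, for recovery tests) and `config`.
#' @export
simulate_latent_ordinal <- function(config, seed = 1) {
  stopifnot(inherits(config, "rrt_simconfig"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  schema <- config$schema
  ids <- schema_ids(schema)
  nc <- schema_ncat(schema)
  n <- sum(config$n_per_country)
  k <- length(config$spec$factors)

  lam <- setNames(numeric(length(ids)), ids)
  fac <- setNames(rep(NA_integer_, length(ids)), ids)
  for (f in seq_len(k)) {
    w <- config$spec$factors[[f]]
    w <- pmax(pmin(w, config$max_abs_loading), -config$max_abs_loading)
    lam[names(w)] <- w
    fac[names(w)] <- f
  }
  uniq <- 1 - lam^2
  if (any(uniq <= 0))
    stop("non-positive uniqueness for item: ",
         paste(ids[uniq <= 0], collapse = ", "), call. = FALSE)

  Fz <- matrix(rnorm(n * k), n, k) %*% chol(config$Phi)
  th <- config_thresholds(config)
  x <- matrix(NA_integer_, n, length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    z <- if (is.na(fac[j])) rnorm(n) else
      lam[j] * Fz[, fac[j]] + sqrt(uniq[j]) * rnorm(n)
    code <- findInterval(z, th[[j]])
    # raw orientation: reverse-coded items are stored flipped
    if (schema$items[[ids[j]]]$reverse) code <- nc[j] - 1L - code
    x[, j] <- as.integer(code)
  }

  country <- rep(names(config$n_per_country), config$n_per_country)
  hospital <- unlist(lapply(seq_along(config$n_per_country), function(ci) {
    nci <- config$n_per_country[ci]
    paste0(substr(names(config$n_per_country)[ci], 1, 2), "_h",
           1 + (seq_len(nci) - 1) %% config$hospitals_per_country)
  }), use.names = FALSE)
  round_id <- unlist(lapply(config$n_per_country, function(nci)
    1 + (seq_len(nci) - 1) %/% ceiling(nci / config$rounds)),
    use.names = FALSE)
  raw <- raw_response_matrix(x, data.frame(country = country,
                                           hospital = hospital,
                                           round = round_id),
                             ids = sprintf("r%05d", seq_len(n)))
  structure(list(raw = raw, latents = Fz, config = config, seed = seed),
            class = "rrt_cohort")
}

#' @export
print.rrt_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", nrow(x$raw$data), " respondents x ",
      ncol(x$raw$data), " items (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Inject missing and non-scorable cells into a cohort
#'
#' Selected rows receive completely-at-random missing cells with a count
#' drawn from the configured distribution; items whose scale declares
#' non-scorable labels additionally receive the non-scored sentinel at
#' the configured per-cell rate. All other cells are untouched.
#'
#' @param cohort An `rrt_cohort`.
#' @param seed Seed for the injection draws.
#' @return The cohort with modified `raw`.
#' @export
inject_missingness <- function(cohort, seed = 1) {
  stopifnot(inherits(cohort, "rrt_cohort"))
  config <- cohort$config
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed + 1L)
  x <- cohort$raw$data
  n <- nrow(x); p <- ncol(x)
  if (config$non_scored_rate > 0) {
    eligible <- vapply(config$schema$items[colnames(x)], function(it)
      length(it$scale$non_scored_labels) > 0, logical(1))
    for (j in which(eligible)) {
      hit <- runif(n) < config$non_scored_rate
      x[hit, j] <- NON_SCORED
    }
  }
  if (config$missing_row_rate > 0) {
    rows <- which(runif(n) < config$missing_row_rate)
    counts <- as.integer(names(config$missing_count_probs))
    for (r in rows) {
      ct <- sample(counts, 1, prob = config$missing_count_probs)
      x[r, sample.int(p, min(ct, p))] <- NA_integer_
    }
  }
  cohort$raw$data <- x
  cohort
}

#' Simulate a structureless null cohort
#'
#' Independent items with the schema's category counts; the reference
#' condition for parallel analysis and sphericity diagnostics.
#'
#' @param n Respondents (at least 2).
#' @param schema Questionnaire schema.
#' @param seed Integer seed.
#' @param marginals Optional list of per-item category probabilities
#'   (default uniform).
#' @return An `rrt_cohort` (no latent structure; `latents = NULL`).
#' @export
simulate_null <- function(n, schema = rrt_schema_fixture(), seed = 1,
                          marginals = NULL) {
  stopifnot(n >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ids <- schema_ids(schema)
  nc <- schema_ncat(schema)
  x <- matrix(NA_integer_, n, length(ids), dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    pr <- if (is.null(marginals)) rep(1 / nc[j], nc[j]) else marginals[[j]]
    x[, j] <- sample.int(nc[j], n, replace = TRUE, prob = pr) - 1L
  }
  raw <- raw_response_matrix(
    x, data.frame(country = rep("Null", n), hospital = rep("h1", n),
                  round = rep(1L, n)),
    ids = sprintf("r%05d", seq_len(n)))
  structure(list(raw = raw, latents = NULL,
                 config = list(schema = schema), seed = seed),
            class = "rrt_cohort")
}

#' Write a canonical demo cohort and its companion files to disk
#'
#' Generates a full synthetic cohort (with injected missingness and
#' non-scorable answers) and writes the response CSV together with the
#' schema, factor-specification and domain-grouping YAML files, enabling
#' the complete simulate / validate / score walkthrough from files alone.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param config An `rrt_simconfig`.
#' @return Named vector of file paths.
#' @export
fixture_cohort <- function(dir, seed = 1, config = simulation_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- inject_missingness(simulate_latent_ordinal(config, seed),
                               seed = seed)
  paths <- c(responses = file.path(dir, "responses.csv"),
             schema = file.path(dir, "schema.yaml"),
             factors = file.path(dir, "factors.yaml"),
             domains = file.path(dir, "domains.yaml"))
  write_responses_csv(cohort$raw, paths[["responses"]])
  write_schema(config$schema, paths[["schema"]])
  write_factor_spec(config$spec, paths[["factors"]])
  write_grouping(rrt_domains_fixture(), paths[["domains"]])
  paths
}
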