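# Polychoric correlation and sampling-adequacy diagnostics.

as_code_matrix <- function(x) {
  if (inherits(x, "rrt_clean")) x <- x$data
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (anyNA(x) || any(x < 0L))
    stop("polychoric estimation needs a complete matrix of scored codes",
         call. = FALSE)
  x
}

# Thresholds from marginal cumulative proportions through the inverse
# normal. Categories are re-indexed to the observed codes so that gaps in
# the code range do not produce empty rows in the pair tables.
item_thresholds <- function(v) {
  tab <- table(v)
  p <- cumsum(tab) / length(v)
  list(levels = as.integer(names(tab)),
       thresholds = qnorm(p[-length(p)]))
}

#' Eigenvalue-smooth a correlation matrix to positive definiteness
#'
#' Negative eigenvalues are raised to a small floor and the matrix is
#' renormalized to unit diagonal.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @param floor Eigenvalue floor.
#' @return List with `R` (smoothed matrix) and `smoothed` flag.
#' @export
smooth_correlation <- function(R, floor = 1e-6) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) > floor)
    return(list(R = R, smoothed = FALSE))
  vals <- pmax(e$values, floor)
  S <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(S))
  S <- S / tcrossprod(d)
  diag(S) <- 1
  dimnames(S) <- dimnames(R)
  list(R = S, smoothed = TRUE)
}

#' Estimate the polychoric correlation matrix of an ordinal item matrix
#'
#' Two-step estimation: per-item thresholds from the marginal cumulative
#' proportions through the inverse normal CDF, then for each pair the
#' latent correlation maximizing the bivariate-normal likelihood of the
#' contingency table (bounded scalar search on (-0.999, 0.999); empty
#' cells receive a 0.5 continuity correction). Near-boundary estimates are
#' clipped to +/-0.999 and non-positive-semidefinite matrices are
#' eigenvalue-smoothed.
#'
#' @param x An `rrt_clean` (factor path) or a complete integer code matrix.
#' @return An object of class `rrt_polychoric`: `rho` (correlations),
#'   `avar` (asymptotic variances of the estimates, used as DWLS weights),
#'   `thresholds`, `n`, `smoothed` and `boundary` flags.
#' @export
estimate_polychoric <- function(x) {
  m <- as_code_matrix(x)
  p <- ncol(m)
  single <- vapply(seq_len(p), function(j) length(unique(m[, j])) < 2L,
                   logical(1))
  if (any(single))
    stop("item with a single observed category: ",
         paste(colnames(m)[single], collapse = ", "), call. = FALSE)
  th <- vector("list", p)
  ncat <- integer(p)
  for (j in seq_len(p)) {
    info <- item_thresholds(m[, j])
    # re-index codes to contiguous 0-based levels
    m[, j] <- match(m[, j], info$levels) - 1L
    th[[j]] <- info$thresholds
    ncat[j] <- length(info$levels)
  }
  res <- .polychoric_matrix_cpp(m, th, ncat)
  rho <- res$rho
  dimnames(rho) <- list(colnames(m), colnames(m))
  boundary <- any(res$boundary > 0)
  sm <- smooth_correlation(rho)
  structure(list(rho = sm$R, raw_rho = rho, avar = res$avar,
                 thresholds = setNames(th, colnames(m)),
                 ncat = ncat, n = nrow(m),
                 smoothed = sm$smoothed || boundary,
                 boundary = boundary),
            class = "rrt_polychoric")
}

#' @export
print.rrt_polychoric <- function(x, ...) {
  cat("Polychoric correlation matrix: ", ncol(x$rho), " items, n = ", x$n,
      if (x$smoothed) " (smoothed)", "\n", sep = "")
  invisible(x)
}

#' Bartlett's test of sphericity
#'
#' Tests whether a correlation matrix is an identity matrix, i.e. whether
#' there is any shared variance to factor.
#'
#' @param R Correlation matrix (or `rrt_polychoric`).
#' @param n Sample size (taken from the polychoric object if omitted).
#' @return List with `chi2`, `df`, `p` and a `smoothed` flag.
#' @export
bartlett_sphericity <- function(R, n = NULL) {
  if (inherits(R, "rrt_polychoric")) {
    if (is.null(n)) n <- R$n
    R <- R$rho
  }
  if (is.null(n)) stop("sample size n required", call. = FALSE)
  p <- ncol(R)
  if (n <= p) stop("Bartlett's test needs n > p", call. = FALSE)
  smoothed <- FALSE
  d <- determinant(R, logarithm = TRUE)
  if (d$sign <= 0 || !is.finite(d$modulus)) {
    R <- smooth_correlation(R)$R
    d <- determinant(R, logarithm = TRUE)
    smoothed <- TRUE
  }
  chi2 <- -(n - 1 - (2 * p + 5) / 6) * as.numeric(d$modulus)
  df <- p * (p - 1) / 2
  list(chi2 = chi2, df = df,
       p = pchisq(chi2, df, lower.tail = FALSE),
       smoothed = smoothed)
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Compares the magnitudes of the observed correlations with those of the
#' anti-image partial correlations computed from the inverse correlation
#' matrix; values near 1 indicate a matrix well suited to factoring.
#'
#' @param R Correlation matrix (or `rrt_polychoric`).
#' @return List with `kmo_overall` and per-item `kmo_per_item`.
#' @export
kmo_msa <- function(R) {
  if (inherits(R, "rrt_polychoric")) R <- R$rho
  p <- ncol(R)
  off <- upper.tri(R)
  if (all(abs(R[off]) < .Machine$double.eps^0.5))
    stop("no common variance: correlation matrix is diagonal",
         call. = FALSE)
  Ri <- tryCatch(solve(R), error = function(e) solve(smooth_correlation(R)$R))
  d <- 1 / sqrt(diag(Ri))
  A <- -Ri * tcrossprod(d)   # anti-image partial correlations
  diag(A) <- 0
  r2 <- R^2; diag(r2) <- 0
  a2 <- A^2
  overall <- sum(r2) / (sum(r2) + sum(a2))
  per_item <- rowSums(r2) / (rowSums(r2) + rowSums(a2))
  names(per_item) <- colnames(R)
  list(kmo_overall = overall, kmo_per_item = per_item)
}

#' Sampling-adequacy report for a cleaned cohort
#'
#' Convenience wrapper computing the polychoric (or Pearson) correlation
#' matrix, Bartlett's sphericity test and the KMO measure. Data are
#' conventionally considered suitable for factor analysis when the
#' Bartlett p-value is at most 0.05 and the overall KMO at least 0.5.
#'
#' @param clean An `rrt_clean` (factor path).
#' @param cor_method `"polychoric"` (default) or `"pearson"`.
#' @return List of class `rrt_adequacy` with the test results, the
#'   correlation object and a `suitable` flag.
#' @export
adequacy_report <- function(clean, cor_method = c("polychoric", "pearson")) {
  cor_method <- match.arg(cor_method)
  n <- nrow(if (inherits(clean, "rrt_clean")) clean$data else clean)
  if (cor_method == "polychoric") {
    pc <- estimate_polychoric(clean)
    R <- pc$rho
  } else {
    m <- as_code_matrix(clean)
    R <- cor(m)
    pc <- NULL
  }
  bt <- bartlett_sphericity(R, n)
  km <- kmo_msa(R)
  structure(list(bartlett_chi2 = bt$chi2, bartlett_df = bt$df,
                 bartlett_p = bt$p,
                 kmo_overall = km$kmo_overall,
                 kmo_per_item = km$kmo_per_item,
                 cor_method = cor_method, n = n,
                 polychoric = pc,
                 suitable = bt$p <= 0.05 && km$kmo_overall >= 0.5),
            class = "rrt_adequacy")
}

#' @export
print.rrt_adequacy <- function(x, ...) {
  cat("Sampling adequacy (", x$cor_method, ", n = ", x$n, ")\n",
      "  Bartlett chi2 = ", round(x$bartlett_chi2, 2), ", df = ",
      x$bartlett_df, ", p = ", format.pval(x$bartlett_p), "\n",
      "  KMO overall = ", round(x$kmo_overall, 3), "\n",
      "  suitable for factor analysis: ", x$suitable, "\n", sep = "")
  invisible(x)
}
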