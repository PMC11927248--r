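# Confirmatory factor analysis by diagonally weighted least squares on
# polychoric correlations, two-stage with thresholds treated as fixed.

#' Build a confirmatory model from an item-to-factor assignment
#'
#' One loading per assigned item, all inter-factor correlations free,
#' unassigned items excluded.
#'
#' @param assignment Either the list returned by [assign_items()], an
#'   `rrt_factors` specification, or a named vector mapping item ids to
#'   factor labels.
#' @return An object of class `rrt_cfa_model`: named list `factors` of
#'   item-id vectors.
#' @export
build_model_from_solution <- function(assignment) {
  if (inherits(assignment, "rrt_factors")) {
    factors <- lapply(assignment$factors, names)
  } else if (is.list(assignment) && !is.null(assignment$assignment)) {
    a <- assignment$assignment
    factors <- split(names(a), paste0("F", a))
  } else {
    a <- assignment
    if (is.null(names(a)) || !length(a))
      stop("empty or unnamed assignment", call. = FALSE)
    factors <- split(names(a), as.character(a))
  }
  if (!length(factors)) stop("empty assignment", call. = FALSE)
  sizes <- lengths(factors)
  if (any(sizes < 2))
    stop("factor with fewer than 2 items: ",
         paste(names(factors)[sizes < 2], collapse = ", "), call. = FALSE)
  structure(list(factors = factors), class = "rrt_cfa_model")
}

#' @export
print.rrt_cfa_model <- function(x, ...) {
  cat("CFA model: ", length(x$factors), " factors, ",
      sum(lengths(x$factors)), " items, ",
      length(x$factors) * (length(x$factors) - 1) / 2,
      " factor correlations\n", sep = "")
  invisible(x)
}

# index helpers for the free parameters: loadings (one per item) then
# factor correlations (lower triangle by column)
cfa_param_info <- function(model, item_order) {
  k <- length(model$factors)
  fac_of <- integer(length(item_order))
  names(fac_of) <- item_order
  for (f in seq_len(k))
    fac_of[model$factors[[f]]] <- f
  pairs <- which(lower.tri(matrix(0, k, k)), arr.ind = TRUE)
  list(k = k, fac_of = fac_of, phi_pairs = pairs,
       n_lambda = length(item_order), n_phi = nrow(pairs))
}

cfa_implied <- function(lambda, phi_vec, info) {
  k <- info$k
  Phi <- diag(k)
  Phi[info$phi_pairs] <- phi_vec
  Phi[info$phi_pairs[, c(2, 1), drop = FALSE]] <- phi_vec
  Lf <- info$fac_of
  S <- (lambda %o% lambda) * Phi[Lf, Lf]
  diag(S) <- 1
  list(S = S, Phi = Phi)
}

#' Fit an ordinal confirmatory factor model by DWLS
#'
#' Two-stage limited-information estimation: the polychoric correlation
#' matrix and the asymptotic variances of its entries are estimated first
#' (thresholds fixed), then the model-implied correlation structure is fit
#' by minimizing the diagonally weighted discrepancy
#' `F = sum_s w_s (r_s - rho_s(theta))^2` with weights the inverse
#' asymptotic variances of the individual estimates at the observed
#' sample size, so the minimized discrepancy is itself the test
#' statistic; no robust correction is applied. The baseline (independence) model for the
#' incremental indices keeps the thresholds and sets all correlations to
#' zero.
#'
#' @param clean An `rrt_clean` (factor path) or complete code matrix
#'   containing at least the model's items.
#' @param model An `rrt_cfa_model`.
#' @return An object of class `rrt_cfa_fit` with `chi2`, `df`,
#'   `baseline_chi2`, `baseline_df`, `CFI`, `TLI`, `RMSEA`, `SRMR`,
#'   parameter estimates, `converged` and `heywood` flags, and `n`.
#' @export
fit_dwls <- function(clean, model) {
  stopifnot(inherits(model, "rrt_cfa_model"))
  m <- as_code_matrix(clean)
  items <- unlist(model$factors, use.names = FALSE)
  absent <- setdiff(items, colnames(m))
  if (length(absent))
    stop("model references absent items: ",
         paste(absent, collapse = ", "), call. = FALSE)
  m <- m[, items, drop = FALSE]
  n <- nrow(m)
  pc <- estimate_polychoric(m)
  R <- pc$raw_rho          # fit raw estimates; weights carry precision
  info <- cfa_param_info(model, items)
  low <- lower.tri(R)
  r_s <- R[low]
  av <- pc$avar[low]
  av[!is.finite(av) | av <= 0] <- (1 - r_s[!is.finite(av) | av <= 0]^2)^2 / n
  w <- 1 / av
  s <- length(r_s)
  idx <- which(low, arr.ind = TRUE)

  obj <- function(theta) {
    lam <- theta[seq_len(info$n_lambda)]
    phi <- theta[info$n_lambda + seq_len(info$n_phi)]
    S <- cfa_implied(lam, phi, info)$S
    e <- r_s - S[low]
    sum(w * e^2)
  }
  grad <- function(theta) {
    lam <- theta[seq_len(info$n_lambda)]
    phi <- theta[info$n_lambda + seq_len(info$n_phi)]
    imp <- cfa_implied(lam, phi, info)
    e <- r_s - imp$S[low]
    Phi <- imp$Phi
    g_lam <- numeric(info$n_lambda)
    g_phi <- numeric(info$n_phi)
    fi <- info$fac_of[idx[, 1]]
    fj <- info$fac_of[idx[, 2]]
    phiff <- Phi[cbind(fi, fj)]
    common <- -2 * w * e
    li <- lam[idx[, 1]]
    lj <- lam[idx[, 2]]
    # dS/dlambda_i = lambda_j * phi, and symmetrically
    for (t in seq_len(s)) {
      g_lam[idx[t, 1]] <- g_lam[idx[t, 1]] + common[t] * lj[t] * phiff[t]
      g_lam[idx[t, 2]] <- g_lam[idx[t, 2]] + common[t] * li[t] * phiff[t]
    }
    same <- fi == fj
    cross <- which(!same)
    if (length(cross)) {
      key <- paste(pmax(fi[cross], fj[cross]), pmin(fi[cross], fj[cross]))
      pkey <- paste(info$phi_pairs[, 1], info$phi_pairs[, 2])
      pos <- match(key, pkey)
      contrib <- common[cross] * li[cross] * lj[cross]
      for (u in seq_along(cross))
        g_phi[pos[u]] <- g_phi[pos[u]] + contrib[u]
    }
    c(g_lam, g_phi)
  }

  start <- c(rep(0.7, info$n_lambda), rep(0.3, info$n_phi))
  opt <- optim(start, obj, grad, method = "L-BFGS-B",
               lower = rep(-0.999, length(start)),
               upper = rep(0.999, length(start)),
               control = list(maxit = 500, factr = 1e4))
  lam <- setNames(opt$par[seq_len(info$n_lambda)], items)
  phi <- opt$par[info$n_lambda + seq_len(info$n_phi)]
  imp <- cfa_implied(lam, phi, info)
  resid <- r_s - imp$S[low]

  # w = 1/avar with avar the finite-sample variance of each polychoric
  # estimate, so the weighted discrepancy is already on the chi-square
  # scale: under a true model each term e_s^2 / avar_s is ~ chi2(1).
  Fmin <- opt$value
  chi2 <- Fmin
  df <- s - info$n_lambda - info$n_phi
  baseline_chi2 <- sum(w * r_s^2)
  baseline_df <- s
  srmr <- sqrt(mean(resid^2))
  heywood <- any(abs(lam) >= 0.999)
  Phi <- imp$Phi
  dimnames(Phi) <- list(names(model$factors), names(model$factors))

  fit <- structure(list(chi2 = chi2, df = df,
                        baseline_chi2 = baseline_chi2,
                        baseline_df = baseline_df,
                        n = n, loadings = lam, Phi = Phi,
                        residuals = resid, SRMR = srmr,
                        converged = opt$convergence == 0,
                        heywood = heywood,
                        model = model),
                   class = "rrt_cfa_fit")
  ix <- compute_fit_indices(fit)
  fit$CFI <- ix$CFI; fit$TLI <- ix$TLI
  fit$RMSEA <- ix$RMSEA; fit$SRMR <- ix$SRMR
  fit
}

#' Compute CFI, TLI, RMSEA and SRMR from a fitted model
#'
#' `CFI = 1 - max(chi2 - df, 0) / max(chi2_b - df_b, chi2 - df, 0)`;
#' `TLI = ((chi2_b/df_b) - (chi2/df)) / ((chi2_b/df_b) - 1)` capped to
#' `[0, 1]`; `RMSEA = sqrt(max(chi2 - df, 0) / (df (n - 1)))`; SRMR is the
#' root mean squared correlation residual over the off-diagonals (the
#' diagonal of the standardized solution is exact).
#'
#' @param fit An `rrt_cfa_fit`, or a list with `chi2`, `df`,
#'   `baseline_chi2`, `baseline_df`, `n` (and optionally `residuals` or
#'   `SRMR`).
#' @return List with `CFI`, `TLI`, `RMSEA`, `SRMR`.
#' @export
compute_fit_indices <- function(fit) {
  chi2 <- fit$chi2; df <- fit$df
  cb <- fit$baseline_chi2; dfb <- fit$baseline_df
  n <- fit$n
  if (df == 0) stop("RMSEA undefined for df = 0", call. = FALSE)
  num <- max(chi2 - df, 0)
  den <- max(cb - dfb, chi2 - df, 0)
  CFI <- if (den == 0) 1 else 1 - num / den
  ratio_b <- cb / dfb
  TLI <- if (ratio_b <= 1) 1 else (ratio_b - chi2 / df) / (ratio_b - 1)
  TLI <- min(max(TLI, 0), 1)
  RMSEA <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))
  SRMR <- if (!is.null(fit$SRMR)) fit$SRMR else
    sqrt(mean(fit$residuals^2))
  CFI <- min(max(CFI, 0), 1)
  list(CFI = CFI, TLI = TLI, RMSEA = RMSEA, SRMR = SRMR)
}

#' @export
print.rrt_cfa_fit <- function(x, ...) {
  cat("DWLS confirmatory fit (n = ", x$n, "): chi2 = ",
      round(x$chi2, 1), ", df = ", x$df, "\n",
      "  CFI = ", round(x$CFI, 3), ", TLI = ", round(x$TLI, 3),
      ", RMSEA = ", round(x$RMSEA, 3), ", SRMR = ", round(x$SRMR, 3),
      "\n", sep = "")
  invisible(x)
}
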