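# Subscale, domain and overall scoring. Two methods share a normalization
# (response code divided by category count minus one, best = 1) and a 0-10
# subscale scale:
#
#   sum score     SS = 10 * ( sum_i sgn(w_i) q_i/(c_i-1) / n
#                             + sum_i 1[w_i < 0] / n )
#   factor score  FS = 10 * ( sum_i w_i q_i/(c_i-1) / sum_j |w_j|
#                             + sum_i 1[w_i < 0] |w_i| / sum_j |w_j| )
#
# with sums over answered items only. The shift terms keep both scores in
# [0, 10] when a subscale contains a negatively loading item. Unanswered
# (missing or non-scorable) items simply drop out; a subscale with no
# answered item receives no score.

score_one <- function(responses, w, method) {
  ids <- names(w)
  q <- responses[ids]
  ans <- !is.na(q)
  n <- sum(ans)
  if (n == 0) return(list(value = NA_real_, n_answered = 0L))
  q <- q[ans]; w <- w[ans]
  if (method == "sum") {
    val <- 10 * (sum(sign(w) * q) / n + sum(w < 0) / n)
  } else {
    denom <- sum(abs(w))
    val <- 10 * (sum(w * q) / denom + sum(abs(w)[w < 0]) / denom)
  }
  list(value = val, n_answered = as.integer(n))
}

check_extra_items <- function(responses, w) {
  extra <- setdiff(names(responses), names(w))
  if (length(extra))
    warning("responses for items outside the subscale ignored: ",
            paste(extra, collapse = ", "), call. = FALSE)
}

#' Sum score of one subscale (simple summation)
#'
#' Unweighted mean of the answered normalized responses, carrying only the
#' sign of each item's pattern loading, shifted so that the score range is
#' 0-10 even with negative loadings. Suited to comparisons across studies
#' because it does not depend on the loading magnitudes.
#'
#' @param responses Named numeric vector of normalized responses in
#'   `[0, 1]`; `NA` = unanswered (missing or non-scorable).
#' @param spec Either an `rrt_factors` with a single factor, or a named
#'   numeric vector of signed loadings.
#' @return List with `value` (score in `[0, 10]`, `NA` if nothing
#'   answered) and `n_answered`.
#' @export
sum_score <- function(responses, spec) {
  w <- spec_loadings(spec)
  check_extra_items(responses, w)
  score_one(responses, w, "sum")
}

#' Factor-weighted score of one subscale
#'
#' Loading-weighted mean of the answered normalized responses divided by
#' the sum of absolute loadings of the answered items, with the analogous
#' 0-10 shift for negative loadings. Gives more weight to items that
#' contributed more to the factor; intended for within-study use.
#'
#' @inheritParams sum_score
#' @return List with `value` and `n_answered`.
#' @export
factor_score <- function(responses, spec) {
  w <- spec_loadings(spec)
  check_extra_items(responses, w)
  score_one(responses, w, "factor")
}

spec_loadings <- function(spec) {
  if (inherits(spec, "rrt_factors")) {
    if (length(spec$factors) != 1)
      stop("single-subscale scoring needs a one-factor specification",
           call. = FALSE)
    return(spec$factors[[1]])
  }
  if (is.numeric(spec) && !is.null(names(spec))) return(spec)
  stop("spec must be an rrt_factors or a named loading vector",
       call. = FALSE)
}

#' Overall score across subscales, as a percentage of best practice
#'
#' Mean of the available subscale scores, times 10: `OS = 10 * sum(s_k)/N`
#' where `N` counts the subscales that received a score. A subscale with
#' all items unanswered contributes nothing.
#'
#' @param subscale_scores Numeric vector of 0-10 subscale scores, `NA` for
#'   absent subscales.
#' @return Percentage in `[0, 100]`, or `NA` if no subscale was scored.
#' @export
overall_score <- function(subscale_scores) {
  s <- subscale_scores[!is.na(subscale_scores)]
  if (!length(s)) return(NA_real_)
  10 * sum(s) / length(s)
}

#' Responsiveness and respectful-treatment domain scores
#'
#' Applies the overall-score formula separately within the two domains.
#'
#' @param subscale_scores Named numeric vector of 0-10 subscale scores
#'   (names = factor names), `NA` for absent.
#' @param grouping An `rrt_domains` grouping.
#' @return List with `responsiveness_pct` and `respectful_pct` (each `NA`
#'   if the domain has no scored subscale).
#' @export
domain_scores <- function(subscale_scores, grouping) {
  stopifnot(inherits(grouping, "rrt_domains"))
  covered <- c(grouping$responsiveness, grouping$respectful)
  missing_f <- setdiff(names(subscale_scores), covered)
  if (length(missing_f))
    stop("factors not covered by the domain grouping: ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  list(
    responsiveness_pct = overall_score(
      subscale_scores[intersect(names(subscale_scores),
                                grouping$responsiveness)]),
    respectful_pct = overall_score(
      subscale_scores[intersect(names(subscale_scores),
                                grouping$respectful)]))
}

#' Score a cohort with both methods
#'
#' Normalizes every answered response, evaluates the sum score and the
#' factor-weighted score for every subscale and respondent, and aggregates
#' to domain and overall percentages. The factor-weighted method is
#' labelled for within-study use and the sum-score method for
#' between-study comparisons.
#'
#' @param clean An `rrt_clean` from the scoring path (`NA` = unanswered).
#' @param spec An `rrt_factors` specification (freshly estimated or the
#'   shipped published fixture).
#' @param grouping An `rrt_domains` grouping covering the spec's factors.
#' @return An object of class `rrt_scores`: `scores` (per-respondent data
#'   frame) and `summary` (per-subscale and per-domain means and SDs for
#'   both methods).
#' @export
score_cohort <- function(clean, spec, grouping) {
  stopifnot(inherits(clean, "rrt_clean"), inherits(spec, "rrt_factors"))
  fnames <- names(spec$factors)
  bad <- setdiff(fnames, c(grouping$responsiveness, grouping$respectful))
  if (length(bad))
    stop("factors not covered by the domain grouping: ",
         paste(bad, collapse = ", "), call. = FALSE)
  norm <- sweep(clean$data, 2, clean$ncat - 1, "/")
  nr <- nrow(norm)
  res <- data.frame(respondent_id = clean$ids, stringsAsFactors = FALSE)
  ss_mat <- fs_mat <- matrix(NA_real_, nr, length(fnames),
                             dimnames = list(NULL, fnames))
  n_mat <- matrix(0L, nr, length(fnames), dimnames = list(NULL, fnames))
  for (f in fnames) {
    w <- spec$factors[[f]]
    miss <- setdiff(names(w), colnames(norm))
    if (length(miss))
      stop("spec items absent from data: ", paste(miss, collapse = ", "),
           call. = FALSE)
    q <- norm[, names(w), drop = FALSE]
    ans <- !is.na(q)
    n_ans <- rowSums(ans)
    sgn_q <- sweep(q, 2, sign(w), "*")
    ss_num <- rowSums(sgn_q, na.rm = TRUE) +
      rowSums(sweep(ans, 2, as.numeric(w < 0), "*"))
    ss <- ifelse(n_ans > 0, 10 * ss_num / n_ans, NA_real_)
    wq <- sweep(q, 2, w, "*")
    denom <- rowSums(sweep(ans, 2, abs(w), "*"))
    fs_num <- rowSums(wq, na.rm = TRUE) +
      rowSums(sweep(ans, 2, abs(w) * (w < 0), "*"))
    fs <- ifelse(n_ans > 0, 10 * fs_num / denom, NA_real_)
    ss_mat[, f] <- ss
    fs_mat[, f] <- fs
    n_mat[, f] <- n_ans
  }
  dom <- function(mat) {
    t(apply(mat, 1, function(s) {
      d <- domain_scores(setNames(s, fnames), grouping)
      c(d$responsiveness_pct, d$respectful_pct, overall_score(s))
    }))
  }
  agg_ss <- dom(ss_mat)
  agg_fs <- dom(fs_mat)
  res[paste0("SS.", fnames)] <- ss_mat
  res[paste0("FS.", fnames)] <- fs_mat
  res[paste0("n.", fnames)] <- n_mat
  res$responsiveness_ss_pct <- agg_ss[, 1]
  res$respectful_ss_pct <- agg_ss[, 2]
  res$overall_ss_pct <- agg_ss[, 3]
  res$responsiveness_fs_pct <- agg_fs[, 1]
  res$respectful_fs_pct <- agg_fs[, 2]
  res$overall_fs_pct <- agg_fs[, 3]

  msd <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = sd(v, na.rm = TRUE))
  subscales <- lapply(fnames, function(f)
    list(subscale = f,
         sum_score = as.list(msd(ss_mat[, f])),
         factor_score = as.list(msd(fs_mat[, f]))))
  domains <- list(
    responsiveness = list(sum_score = as.list(msd(agg_ss[, 1])),
                          factor_score = as.list(msd(agg_fs[, 1]))),
    respectful_treatment = list(sum_score = as.list(msd(agg_ss[, 2])),
                                factor_score = as.list(msd(agg_fs[, 2]))),
    overall = list(sum_score = as.list(msd(agg_ss[, 3])),
                   factor_score = as.list(msd(agg_fs[, 3]))))
  structure(list(scores = res,
                 summary = list(
                   subscales = subscales, domains = domains,
                   methods = list(
                     factor_score = "within-study",
                     sum_score = "comparison across studies"),
                   n = nr)),
            class = "rrt_scores")
}

#' @export
print.rrt_scores <- function(x, ...) {
  cat("Score report: ", nrow(x$scores), " respondents, ",
      length(x$summary$subscales), " subscales\n", sep = "")
  for (s in x$summary$subscales)
    cat(sprintf("  %-40s SS %5.2f (SD %4.2f)  FS %5.2f (SD %4.2f)\n",
                s$subscale, s$sum_score$mean, s$sum_score$sd,
                s$factor_score$mean, s$factor_score$sd))
  ov <- x$summary$domains$overall
  cat(sprintf("  overall %% of best practice: SS %5.2f  FS %5.2f\n",
              ov$sum_score$mean, ov$factor_score$mean))
  invisible(x)
}

#' Write per-respondent scores to CSV
#' @param scores An `rrt_scores` report.
#' @param path Output path.
#' @export
write_scores_csv <- function(scores, path) {
  df <- scores$scores
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 2)   # display rounding only
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
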