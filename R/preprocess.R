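#' Build a raw response matrix
#'
#' @param data Integer matrix, respondents x items, column names = item ids
#'   in schema order. Cells: scored codes `0..c_i-1` in *raw* orientation
#'   (before reverse-coding), `NA` for missing, [NON_SCORED] or
#'   [MEDIAN_IMPUTE] sentinels.
#' @param strata Data frame with columns `country`, `hospital`, `round`,
#'   one row per respondent.
#' @param ids Respondent identifiers (default `r1..rn`).
#' @return An object of class `rrt_raw`.
#' @export
raw_response_matrix <- function(data, strata, ids = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (is.null(colnames(data)))
    stop("response matrix must have item ids as column names", call. = FALSE)
  need <- c("country", "hospital", "round")
  if (!all(need %in% names(strata)))
    stop("strata must contain columns country, hospital, round",
         call. = FALSE)
  if (nrow(strata) != nrow(data))
    stop("strata rows must match respondents", call. = FALSE)
  if (is.null(ids)) ids <- paste0("r", seq_len(nrow(data)))
  rownames(data) <- ids
  structure(list(data = data, strata = as.data.frame(strata), ids = ids),
            class = "rrt_raw")
}

#' @export
print.rrt_raw <- function(x, ...) {
  cat("Raw response matrix: ", nrow(x$data), " respondents x ",
      ncol(x$data), " items\n", sep = "")
  invisible(x)
}

check_raw_against_schema <- function(raw, schema) {
  unknown <- setdiff(colnames(raw$data), schema_ids(schema))
  if (length(unknown))
    stop("items not in schema: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  nc <- schema_ncat(schema)[colnames(raw$data)]
  for (j in seq_len(ncol(raw$data))) {
    v <- raw$data[, j]
    bad <- !is.na(v) & (v > nc[j] - 1L | (v < 0L & v != NON_SCORED &
                                            v != MEDIAN_IMPUTE))
    if (any(bad))
      stop("codes out of range for item ", colnames(raw$data)[j],
           call. = FALSE)
  }
  invisible(TRUE)
}

# Lower-median of an integer vector: for even counts the lower middle order
# statistic, so the imputed value is always a valid category code.
lower_median <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

#' Screen respondents and impute missing responses
#'
#' Applies the data-management rules: respondents with more than
#' `max_missing` missing items are excluded; remaining missing cells (and
#' cells recoded to median imputation) are replaced by the per-item lower
#' median of the observed scored codes. Reverse-coded items are flipped so
#' that higher codes always mean better treatment.
#'
#' Two cleaning paths exist. The factor-analysis path (`path = "factor"`)
#' also imputes non-scorable responses, because factor analysis requires a
#' complete matrix. The scoring path (`path = "scoring"`) leaves both
#' missing and non-scorable cells as `NA`: such answers never receive a
#' value when scores are computed.
#'
#' @param raw An `rrt_raw` matrix.
#' @param schema The questionnaire schema.
#' @param max_missing Exclusion threshold: rows with strictly more missing
#'   items than this are dropped (missing means truly absent cells, not
#'   non-scorable answers). The boundary count itself is imputed.
#' @param path `"factor"` or `"scoring"`.
#' @return A list with `clean` (an `rrt_clean`) and `report` (an
#'   exclusion/imputation report).
#' @export
screen_and_impute <- function(raw, schema, max_missing = 5,
                              path = c("factor", "scoring")) {
  path <- match.arg(path)
  stopifnot(inherits(raw, "rrt_raw"), inherits(schema, "rrt_schema"))
  check_raw_against_schema(raw, schema)
  x <- raw$data
  nc <- schema_ncat(schema)[colnames(x)]
  rev_flag <- vapply(schema$items[colnames(x)], function(i) i$reverse,
                     logical(1))

  miss_count <- rowSums(is.na(x))
  drop <- miss_count > max_missing
  excluded <- data.frame(id = raw$ids[drop],
                         n_missing = miss_count[drop],
                         stringsAsFactors = FALSE)
  x <- x[!drop, , drop = FALSE]
  strata <- raw$strata[!drop, , drop = FALSE]
  ids <- raw$ids[!drop]

  n_imputed <- setNames(integer(ncol(x)), colnames(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    scored <- !is.na(v) & v >= 0L
    if (!any(scored))
      stop("item entirely missing across cohort: ", colnames(x)[j],
           call. = FALSE)
    # reverse-code observed scored cells first; the median is then taken on
    # the final orientation
    if (rev_flag[j]) v[scored] <- reverse_code(v[scored], nc[j])
    med <- lower_median(v[scored])
    fill <- is.na(v) | v == MEDIAN_IMPUTE
    if (path == "factor") fill <- fill | v == NON_SCORED
    n_imputed[j] <- sum(fill)
    v[fill] <- med
    if (path == "scoring") v[v == NON_SCORED] <- NA_integer_
    x[, j] <- v
  }

  clean <- structure(list(data = x, strata = strata, ids = ids,
                          ncat = nc, path = path),
                     class = "rrt_clean")
  report <- list(n_input = length(raw$ids),
                 n_excluded = nrow(excluded),
                 n_retained = length(ids),
                 excluded = excluded,
                 n_imputed = as.list(n_imputed),
                 max_missing = max_missing,
                 path = path)
  list(clean = clean, report = report)
}

#' @export
print.rrt_clean <- function(x, ...) {
  cat("Clean response matrix (", x$path, " path): ", nrow(x$data),
      " respondents x ", ncol(x$data), " items\n", sep = "")
  invisible(x)
}

#' Subset a clean matrix by respondent ids and/or items
#' @param clean An `rrt_clean`.
#' @param ids Respondent ids to keep (default all).
#' @param items Item ids to keep (default all).
#' @export
subset_clean <- function(clean, ids = NULL, items = NULL) {
  keep_r <- if (is.null(ids)) seq_along(clean$ids) else
    match(ids, clean$ids)
  if (anyNA(keep_r)) stop("unknown respondent ids", call. = FALSE)
  keep_c <- if (is.null(items)) seq_len(ncol(clean$data)) else
    match(items, colnames(clean$data))
  if (anyNA(keep_c)) stop("unknown item ids", call. = FALSE)
  structure(list(data = clean$data[keep_r, keep_c, drop = FALSE],
                 strata = clean$strata[keep_r, , drop = FALSE],
                 ids = clean$ids[keep_r],
                 ncat = clean$ncat[keep_c],
                 path = clean$path),
            class = "rrt_clean")
}

#' Normalize ordinal responses to the unit interval
#'
#' A code `q` on a `c`-category item becomes `q / (c - 1)`, so 0 is the
#' worst and 1 the best possible response. `NA` (unanswered, including
#' non-scorable answers on the scoring path) propagates.
#'
#' @param q Integer code(s) in `0..c-1` or `NA`.
#' @param c Category count(s), each at least 2.
#' @return Numeric value(s) in `[0, 1]`.
#' @export
normalize_response <- function(q, c) {
  if (any(c < 2, na.rm = TRUE))
    stop("category count must be >= 2", call. = FALSE)
  bad <- !is.na(q) & (q < 0 | q > c - 1)
  if (any(bad)) stop("response code out of range", call. = FALSE)
  as.numeric(q) / (as.numeric(c) - 1)
}

#' Split a cohort into two halves, randomly but equally per country
#'
#' Within each country the respondents are shuffled with the given seed and
#' assigned alternately to the two halves, guaranteeing per-country balance
#' to one respondent. Half A is intended for the exploratory analysis and
#' half B for the confirmatory analysis.
#'
#' @param clean An `rrt_clean` with a `country` stratum.
#' @param seed Integer seed; the split is reproducible.
#' @return An object of class `rrt_split` with `half_A`, `half_B` id
#'   vectors and the seed.
#' @export
split_half <- function(clean, seed) {
  if (is.null(clean$strata$country) || anyNA(clean$strata$country))
    stop("country stratum required for the half split", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  half_A <- character()
  half_B <- character()
  for (ct in unique(as.character(clean$strata$country))) {
    ids <- clean$ids[clean$strata$country == ct]
    ids <- sample(ids)
    pick_A <- seq_along(ids) %% 2L == 1L
    half_A <- c(half_A, ids[pick_A])
    half_B <- c(half_B, ids[!pick_A])
  }
  structure(list(half_A = half_A, half_B = half_B, seed = seed),
            class = "rrt_split")
}

# ---- CSV interface -------------------------------------------------------

#' Read a respondent-by-item response CSV
#'
#' Expected columns: `respondent_id`, `country`, `hospital`, `round`, then
#' one column per item id holding raw integer codes; empty cells are
#' missing and the token `NS` marks a non-scorable answer (`MI` marks a
#' cell flagged for median imputation).
#'
#' @param path CSV path.
#' @param schema Schema used to validate item columns.
#' @return An `rrt_raw`.
#' @export
read_responses_csv <- function(path, schema) {
  df <- read.csv(path, check.names = FALSE, colClasses = "character")
  meta <- c("respondent_id", "country", "hospital", "round")
  if (!all(meta %in% names(df)))
    stop("response CSV must contain columns ",
         paste(meta, collapse = ", "), call. = FALSE)
  item_cols <- setdiff(names(df), meta)
  x <- matrix(NA_integer_, nrow(df), length(item_cols),
              dimnames = list(NULL, item_cols))
  for (j in item_cols) {
    v <- df[[j]]
    out <- rep(NA_integer_, length(v))
    out[v == "NS"] <- NON_SCORED
    out[v == "MI"] <- MEDIAN_IMPUTE
    plain <- !(v %in% c("", "NS", "MI")) & !is.na(v)
    out[plain] <- as.integer(v[plain])
    x[, j] <- out
  }
  raw <- raw_response_matrix(x, df[meta[-1]], ids = df$respondent_id)
  check_raw_against_schema(raw, schema)
  raw
}

#' Write a raw response matrix to CSV
#' @param raw An `rrt_raw`.
#' @param path Output path.
#' @export
write_responses_csv <- function(raw, path) {
  x <- raw$data
  ch <- matrix("", nrow(x), ncol(x), dimnames = dimnames(x))
  ch[!is.na(x) & x >= 0L] <- as.character(x[!is.na(x) & x >= 0L])
  ch[!is.na(x) & x == NON_SCORED] <- "NS"
  ch[!is.na(x) & x == MEDIAN_IMPUTE] <- "MI"
  df <- data.frame(respondent_id = raw$ids,
                   country = raw$strata$country,
                   hospital = raw$strata$hospital,
                   round = raw$strata$round,
                   ch, check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
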