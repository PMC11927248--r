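# Independent term-by-term oracle for the two scoring equations: literal
# translation of the summation formulas, one term at a time.
oracle_scores <- function(q, w) {
  ans <- names(w)[!is.na(q[names(w)])]
  n <- length(ans)
  if (n == 0) return(list(ss = NA_real_, fs = NA_real_))
  ss1 <- 0; ss2 <- 0; fs1 <- 0; fs2 <- 0; denom <- 0
  for (id in ans) {
    wi <- w[[id]]; qi <- q[[id]]
    sgn <- if (wi < 0) -1 else if (wi > 0) 1 else 0
    ss1 <- ss1 + sgn * qi
    ss2 <- ss2 + as.numeric(wi < 0)
    fs1 <- fs1 + wi * qi
    fs2 <- fs2 + as.numeric(wi < 0) * abs(wi)
    denom <- denom + abs(wi)
  }
  list(ss = 10 * (ss1 / n + ss2 / n),
       fs = 10 * (fs1 / denom + fs2 / denom))
}

social <- c(companion_labour = 0.85, companion_birth = 0.94)
abuse <- c(slapped_pinched = 0.40, negative_comments = 0.66,
           shouted_items = 0.78, asked_bribe = -0.73)

test_that("the sum score hits its printed anchor values", {
  best <- c(companion_labour = 1, companion_birth = 1)
  expect_identical(sum_score(best, social)$value, 10)
  expect_identical(sum_score(c(companion_labour = 1, companion_birth = 0),
                             social)$value, 5)
  all_best <- setNames(rep(1, 4), names(abuse))
  expect_equal(sum_score(all_best, abuse)$value, 7.5, tolerance = 1e-12)
})

test_that("the factor score hits its printed anchor values", {
  expect_equal(factor_score(c(companion_labour = 1, companion_birth = 0),
                            social)$value, 10 * 0.85 / 1.79,
               tolerance = 1e-12)
  expect_equal(factor_score(c(companion_labour = 1, companion_birth = 0),
                            social)$value, 4.749, tolerance = 5e-4)
  all_best <- setNames(rep(1, 4), names(abuse))
  expect_equal(factor_score(all_best, abuse)$value,
               10 * (1.11 + 0.73) / 2.57, tolerance = 1e-12)
  expect_equal(factor_score(all_best, abuse)$value, 7.159,
               tolerance = 5e-4)
})

test_that("with one negative loading the maximum factor score is 10 at q = 0", {
  at0 <- c(slapped_pinched = 1, negative_comments = 1, shouted_items = 1,
           asked_bribe = 0)
  expect_equal(factor_score(at0, abuse)$value, 10, tolerance = 1e-12)
  expect_equal(sum_score(at0, abuse)$value, 10, tolerance = 1e-12)
  # and any worse response on that item lowers the score
  worse <- at0; worse["asked_bribe"] <- 1
  expect_lt(factor_score(worse, abuse)$value, 10)
})

test_that("both scores stay in [0, 10] and agree with the oracle", {
  set.seed(71)
  for (rep in seq_len(2000)) {
    p <- sample(2:8, 1)
    ids <- paste0("i", seq_len(p))
    w <- setNames(round(runif(p, -1.2, 1.2), 2), ids)
    w[w == 0] <- 0.5
    q <- setNames(round(runif(p), 3), ids)
    q[runif(p) < 0.25] <- NA
    if (all(is.na(q))) q[1] <- 0.5
    ss <- sum_score(q, w)$value
    fs <- factor_score(q, w)$value
    expect_gte(ss, 0); expect_lte(ss, 10)
    expect_gte(fs, 0); expect_lte(fs, 10)
    oc <- oracle_scores(q, w)
    expect_equal(ss, oc$ss, tolerance = 1e-12)
    expect_equal(fs, oc$fs, tolerance = 1e-12)
    # permutation invariance
    perm <- sample(p)
    expect_equal(sum_score(q[perm], w[perm])$value, ss,
                 tolerance = 1e-12)
    expect_equal(factor_score(q[perm], w[perm])$value, fs,
                 tolerance = 1e-12)
  }
})

test_that("equal loadings make the two methods coincide", {
  set.seed(72)
  for (rep in 1:50) {
    p <- sample(2:7, 1)
    w <- setNames(rep(round(runif(1, 0.3, 0.9), 2), p),
                  paste0("i", seq_len(p)))
    q <- setNames(runif(p), names(w))
    expect_equal(sum_score(q, w)$value, factor_score(q, w)$value,
                 tolerance = 1e-12)
  }
})

test_that("unanswered items drop out without changing the score", {
  q <- c(i1 = 0.8, i2 = NA, i3 = 0.2)
  w <- c(i1 = 0.7, i2 = 0.5, i3 = -0.6)
  w_red <- w[c("i1", "i3")]
  expect_equal(sum_score(q, w)$value, sum_score(q[c(1, 3)], w_red)$value,
               tolerance = 1e-12)
  expect_equal(factor_score(q, w)$value,
               factor_score(q[c(1, 3)], w_red)$value, tolerance = 1e-12)
  expect_identical(sum_score(c(i1 = NA_real_), c(i1 = 0.5))$n_answered, 0L)
  expect_true(is.na(sum_score(c(i1 = NA_real_), c(i1 = 0.5))$value))
  expect_warning(sum_score(c(i1 = 1, stray = 0.5), c(i1 = 0.5)),
                 "stray")
})

test_that("overall and domain scores aggregate available subscales", {
  expect_equal(overall_score(c(10, 5)), 75)
  expect_equal(overall_score(rep(10, 6)), 100)
  expect_equal(overall_score(c(8, NA, 7, NA, 9, 10)), 85)
  expect_true(is.na(overall_score(c(NA_real_, NA_real_))))

  grouping <- domain_grouping(c("A", "B", "C"), c("D", "E", "F"))
  s <- c(A = 4, B = 6, C = 5, D = 8, E = 9, F = 7)
  d <- domain_scores(s, grouping)
  expect_equal(d$responsiveness_pct, 50)
  expect_equal(d$respectful_pct, 80)
  s2 <- c(A = 4, B = 6, C = 5, D = 8, E = NA, F = 7)
  expect_equal(domain_scores(s2, grouping)$respectful_pct, 75)
  s3 <- c(A = NA, B = NA, C = NA, D = 8, E = 9, F = 7)
  expect_true(is.na(domain_scores(s3, grouping)$responsiveness_pct))
  expect_error(domain_scores(c(G = 5), grouping), "not covered")
})

test_that("cohort scoring matches per-respondent recomputation", {
  cfg <- simulation_config(n_per_country = c(X = 120))
  cohort <- inject_missingness(simulate_latent_ordinal(cfg, seed = 81),
                               seed = 81)
  clean <- screen_and_impute(cohort$raw, cfg$schema,
                             path = "scoring")$clean
  rep_scores <- score_cohort(clean, published_spec, published_grouping)
  norm <- sweep(clean$data, 2, clean$ncat - 1, "/")
  for (i in sample(nrow(norm), 25)) {
    q <- norm[i, ]
    per_f_ss <- per_f_fs <- setNames(
      rep(NA_real_, length(published_spec$factors)),
      names(published_spec$factors))
    for (f in names(published_spec$factors)) {
      oc <- oracle_scores(q, published_spec$factors[[f]])
      per_f_ss[f] <- oc$ss; per_f_fs[f] <- oc$fs
    }
    row <- rep_scores$scores[i, ]
    expect_equal(unname(unlist(row[paste0("SS.",
                                          names(per_f_ss))])),
                 unname(per_f_ss), tolerance = 1e-12)
    expect_equal(unname(unlist(row[paste0("FS.",
                                          names(per_f_fs))])),
                 unname(per_f_fs), tolerance = 1e-12)
    expect_equal(row$overall_ss_pct, overall_score(per_f_ss),
                 tolerance = 1e-12)
    d <- domain_scores(per_f_fs, published_grouping)
    expect_equal(row$responsiveness_fs_pct, d$responsiveness_pct,
                 tolerance = 1e-12)
    expect_equal(row$respectful_fs_pct, d$respectful_pct,
                 tolerance = 1e-12)
  }
  expect_true(all(rep_scores$scores$overall_ss_pct >= 0 &
                    rep_scores$scores$overall_ss_pct <= 100,
                  na.rm = TRUE))
})

test_that("an all-best cohort saturates positive subscales", {
  schema <- rrt_schema_fixture()
  ids <- schema_ids(schema)
  nc <- schema_ncat(schema)
  x <- matrix(rep(nc - 1L, each = 4), nrow = 4,
              dimnames = list(NULL, ids))
  storage.mode(x) <- "integer"
  clean <- fake_clean(x, ncat = nc)
  rep_scores <- score_cohort(clean, published_spec, published_grouping)
  for (f in c("Communication & supportive care", "Hospital environment",
              "Social support")) {
    expect_equal(unique(rep_scores$scores[[paste0("SS.", f)]]), 10)
    expect_equal(unique(rep_scores$scores[[paste0("FS.", f)]]), 10)
  }
  expect_equal(unique(rep_scores$scores$responsiveness_ss_pct), 100)
})
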