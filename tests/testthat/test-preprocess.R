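test_that("respondents over the missing threshold are excluded, the rest imputed", {
  schema <- rrt_schema_fixture()
  cohort <- simulate_latent_ordinal(simulation_config(
    n_per_country = c(X = 40)), seed = 3)
  x <- cohort$raw$data
  x[1, 1:6] <- NA_integer_   # six missing -> excluded
  x[2, 1:5] <- NA_integer_   # boundary five -> imputed (inclusive rule)
  raw <- raw_response_matrix(x, cohort$raw$strata, ids = cohort$raw$ids)
  res <- screen_and_impute(raw, schema, max_missing = 5, path = "factor")
  expect_identical(res$report$n_excluded, 1L)
  expect_identical(res$report$excluded$id, cohort$raw$ids[1])
  expect_identical(res$report$n_input,
                   res$report$n_excluded + nrow(res$clean$data))
  expect_false(anyNA(res$clean$data))
  expect_true(all(res$clean$data >= 0))
})

test_that("median imputation uses the lower median and preserves column medians", {
  schema <- tiny_schema()
  x <- matrix(c(3L, 2L, 2L, 1L, NA,
                1L, 1L, 0L, 1L, 1L,
                0L, 1L, 1L, 2L, NA,
                1L, 1L, 0L, 0L, 1L), ncol = 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  res <- screen_and_impute(tiny_raw(x), schema, path = "factor")
  # column c observed {0,1,1,2}: lower median 1
  expect_identical(res$clean$data[5, "c"], 1L)
  # column a is reverse coded (c=4): raw {3,2,2,1,NA} -> {0,1,1,2,NA},
  # lower median 1
  expect_identical(res$clean$data[5, "a"], 1L)
  for (j in colnames(x)) {
    obs <- res$clean$data[, j]
    pre <- obs[!is.na(x[, j])]
    med <- function(v) unname(sort(v)[floor((length(v) + 1) / 2)])
    expect_identical(med(obs), med(pre))
  }
})

test_that("cleaning is the identity on complete data and idempotent", {
  schema <- tiny_schema()
  set.seed(1)
  x <- cbind(a = sample(0:3, 30, TRUE), b = sample(0:1, 30, TRUE),
              c = sample(0:4, 30, TRUE), d = sample(0:1, 30, TRUE))
  storage.mode(x) <- "integer"
  res <- screen_and_impute(tiny_raw(x), schema, path = "factor")
  expect_identical(res$report$n_excluded, 0L)
  # reverse-coding of column a is the only change
  expect_equal(unname(res$clean$data[, "a"]), unname(3L - x[, "a"]))
  expect_equal(res$clean$data[, c("b", "c", "d")],
               x[, c("b", "c", "d")], ignore_attr = TRUE)
  # idempotence: feeding the cleaned (already reversed) data through a
  # reverse-free schema changes nothing
  schema2 <- questionnaire_schema(list(
    item_definition("a", response_scale("likert", paste0("L", 1:4))),
    item_definition("b", response_scale("binary", c("No", "Yes"))),
    item_definition("c", response_scale("likert", paste0("L", 1:5))),
    item_definition("d", response_scale("categorical", c("No", "Yes"),
                                        non_scored = "Don't know"))))
  res2 <- screen_and_impute(tiny_raw(res$clean$data), schema2,
                            path = "factor")
  expect_identical(res2$clean$data, res$clean$data)
})

test_that("the scoring path keeps non-scorable answers unanswered", {
  schema <- tiny_schema()
  x <- cbind(a = c(0L, 1L), b = c(1L, 0L), c = c(2L, 2L),
             d = c(NON_SCORED, 1L))
  resF <- screen_and_impute(tiny_raw(x), schema, path = "factor")
  resS <- screen_and_impute(tiny_raw(x), schema, path = "scoring")
  expect_false(anyNA(resF$clean$data))
  expect_identical(resF$clean$data[1, "d"], 1L)  # imputed from {1}
  expect_true(is.na(resS$clean$data[1, "d"]))
})

test_that("an item with no observed scored value is an error", {
  schema <- tiny_schema()
  x <- cbind(a = c(0L, 1L), b = c(NA_integer_, NA_integer_),
             c = c(2L, 2L), d = c(1L, 1L))
  expect_error(screen_and_impute(tiny_raw(x), schema, max_missing = 5),
               "entirely missing.*b")
})

test_that("normalization maps codes to the unit interval monotonically", {
  expect_equal(normalize_response(3, 5), 0.75)
  expect_equal(normalize_response(1, 2), 1)
  expect_true(is.na(normalize_response(NA_integer_, 4)))
  expect_error(normalize_response(0, 1), ">= 2")
  for (c in 2:7) {
    v <- normalize_response(0:(c - 1), c)
    expect_equal(v[1], 0)
    expect_equal(v[c], 1)
    expect_true(all(diff(v) > 0))
  }
})

test_that("the half split is seeded, disjoint, exhaustive and balanced", {
  counts <- c(Benin = 606, Malawi = 604, Tanzania = 618, Uganda = 605)
  x <- matrix(0L, sum(counts), 1, dimnames = list(NULL, "a"))
  clean <- fake_clean(x, ncat = c(a = 2L),
                      country = rep(names(counts), counts))
  sp <- split_half(clean, seed = 11)
  expect_length(intersect(sp$half_A, sp$half_B), 0)
  expect_setequal(c(sp$half_A, sp$half_B), clean$ids)
  # one odd country: halves 1217 / 1216
  expect_identical(sort(c(length(sp$half_A), length(sp$half_B))),
                   c(1216L, 1217L))
  for (ct in names(counts)) {
    ids <- clean$ids[clean$strata$country == ct]
    expect_lte(abs(sum(sp$half_A %in% ids) - sum(sp$half_B %in% ids)), 1)
  }
  sp2 <- split_half(clean, seed = 11)
  expect_identical(sp, sp2)
  sp3 <- split_half(clean, seed = 12)
  expect_false(identical(sp$half_A, sp3$half_A))
})

test_that("the response CSV dialect round-trips sentinels and strata", {
  schema <- tiny_schema()
  x <- cbind(a = c(0L, 3L), b = c(1L, NA), c = c(4L, 0L),
             d = c(NON_SCORED, 1L))
  raw <- tiny_raw(x)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_responses_csv(raw, tmp)
  back <- read_responses_csv(tmp, schema)
  expect_identical(back$data, raw$data)
  expect_identical(back$ids, raw$ids)
  expect_identical(back$strata$country, raw$strata$country)
})
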