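# Small in-code fixtures shared across tests.

# minimal 4-item schema: one 4-point likert (reverse), one binary, one
# 5-point likert, one categorical with a non-scored label
tiny_schema <- function() {
  questionnaire_schema(list(
    item_definition("a", response_scale("likert", paste0("L", 1:4)),
                    reverse = TRUE),
    item_definition("b", response_scale("binary", c("No", "Yes"))),
    item_definition("c", response_scale("likert", paste0("L", 1:5))),
    item_definition("d", response_scale("categorical", c("No", "Yes"),
                                        non_scored = "Don't know"))
  ))
}

tiny_raw <- function(x, schema = tiny_schema(), country = NULL) {
  n <- nrow(x)
  raw_response_matrix(
    x, data.frame(country = country %||% rep("X", n),
                  hospital = rep("h1", n), round = rep(1L, n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# clean object without running the pipeline (for split / scoring units)
fake_clean <- function(x, ncat, country = rep("X", nrow(x)),
                       path = "scoring") {
  structure(list(data = x,
                 strata = data.frame(country = country,
                                     hospital = rep("h1", nrow(x)),
                                     round = rep(1L, nrow(x))),
                 ids = rownames(x) %||% paste0("r", seq_len(nrow(x))),
                 ncat = ncat, path = path),
            class = "rrt_clean")
}

# simulate ordinal items from a one-factor model, final orientation,
# equal-probability thresholds
sim_one_factor <- function(n, lambda, ncat, seed = 1) {
  set.seed(seed)
  f <- rnorm(n)
  p <- length(lambda)
  x <- matrix(NA_integer_, n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  for (j in seq_len(p)) {
    z <- lambda[j] * f + sqrt(1 - lambda[j]^2) * rnorm(n)
    x[, j] <- findInterval(z, qnorm(seq_len(ncat[j] - 1) / ncat[j]))
  }
  x
}

published_spec <- rrt_factors_fixture()
published_grouping <- rrt_domains_fixture()
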