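test_that("parallel analysis retains nothing on independent noise", {
  schema <- questionnaire_schema(lapply(paste0("v", 1:10), function(id)
    item_definition(id, response_scale("likert", paste0("L", 1:4)))))
  hits <- 0L
  n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    cohort <- simulate_null(1000, schema, seed = 100 + s)
    pa <- parallel_analysis(cohort$raw$data, n_reps = 100, seed = s)
    if (pa$suggested_k <= 1) hits <- hits + 1L
  }
  expect_gte(hits, n_seeds - 1)
})

test_that("parallel analysis finds a single strong factor", {
  x <- sim_one_factor(2000, rep(0.8, 6), rep(4, 6), seed = 9)
  pa <- parallel_analysis(x, n_reps = 100, seed = 9)
  expect_identical(pa$suggested_k, 1L)
  expect_true(all(diff(pa$reference) < 0))
  pa2 <- parallel_analysis(x, n_reps = 100, seed = 9)
  expect_identical(pa, pa2)
  expect_error(parallel_analysis(x, n_reps = 50, seed = 1), "at least 100")
})

test_that("principal-axis factoring solves the just-identified trio", {
  lam <- c(0.9, 0.8, 0.7)
  R <- tcrossprod(lam); diag(R) <- 1
  ext <- extract_paf(R, 1, tol = 1e-8)
  expect_equal(unname(ext$loadings[, 1]), lam, tolerance = 1e-4)
  expect_equal(unname(ext$communalities), lam^2, tolerance = 1e-4)

  ext0 <- extract_paf(diag(4) + 0, 1)
  expect_lt(max(abs(ext0$loadings)), 1e-3)
  expect_lt(max(ext0$communalities), 1e-3)
})

test_that("an exact two-factor model is reconstructed to numerical precision", {
  L <- cbind(c(0.8, 0.7, 0.6, 0, 0, 0), c(0, 0, 0, 0.75, 0.65, 0.55))
  R <- tcrossprod(L); diag(R) <- 1
  ext <- extract_paf(R, 2, tol = 1e-10)
  Rhat <- tcrossprod(ext$loadings)
  diag(Rhat) <- diag(Rhat) + (1 - ext$communalities)
  expect_equal(Rhat, R, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("promax leaves an orthogonal simple structure essentially fixed", {
  L <- cbind(c(0.8, 0.7, 0.6, 0, 0, 0), c(0, 0, 0, 0.75, 0.65, 0.55))
  rownames(L) <- paste0("v", 1:6)
  rot <- rotate_promax(L)
  cong <- tucker_congruence(L, rot$pattern)
  expect_true(all(cong > 0.999))
  expect_lt(abs(rot$Phi[1, 2]), 0.1)
  expect_equal(diag(rot$Phi), c(1, 1))

  # single factor passes through
  one <- rotate_promax(L[, 1, drop = FALSE])
  expect_identical(one$pattern, L[, 1, drop = FALSE])
  expect_identical(one$Phi, matrix(1, 1, 1))
  expect_error(rotate_promax(cbind(L[, 1], 0)), "all-zero loading column")
})

test_that("an oblique two-factor pipeline recovers the factor correlation", {
  set.seed(31)
  n <- 5000
  phi <- 0.3
  f1 <- rnorm(n); f2 <- phi * f1 + sqrt(1 - phi^2) * rnorm(n)
  L <- c(0.8, 0.75, 0.7, 0.65)
  x <- matrix(NA_integer_, n, 8,
              dimnames = list(NULL, paste0("v", 1:8)))
  for (j in 1:4)
    x[, j] <- findInterval(L[j] * f1 + sqrt(1 - L[j]^2) * rnorm(n),
                           qnorm((1:3) / 4))
  for (j in 5:8)
    x[, j] <- findInterval(L[j - 4] * f2 + sqrt(1 - L[j - 4]^2) * rnorm(n),
                           qnorm((1:3) / 4))
  pc <- estimate_polychoric(x)
  rot <- rotate_promax(extract_paf(pc, 2)$loadings)
  expect_lt(abs(abs(rot$Phi[1, 2]) - phi), 0.1)
})

test_that("McDonald's omega matches its closed form and grows with items", {
  expect_equal(mcdonald_omega(c(0.85, 0.94)), 0.8905, tolerance = 1e-4)
  expect_equal(mcdonald_omega(c(0.85, 0.94)),
               1.79^2 / (1.79^2 + (1 - 0.85^2) + (1 - 0.94^2)),
               tolerance = 1e-12)
  expect_equal(mcdonald_omega(c(0, 0, 0)), 0)
  # absolute loadings: the sign does not change reliability
  expect_equal(mcdonald_omega(c(0.4, 0.66, 0.78, -0.73)),
               mcdonald_omega(c(0.4, 0.66, 0.78, 0.73)))
  oms <- vapply(2:8, function(p) mcdonald_omega(rep(0.7, p)), numeric(1))
  expect_true(all(diff(oms) > 0))
  expect_error(mcdonald_omega(0.9), "at least 2")
  expect_error(mcdonald_omega(c(1.05, 0.7)), ">= 1")
})

test_that("criteria evaluation flags cross-loading, thin and unreliable factors", {
  P <- rbind(x1 = c(0.8, 0.05), x2 = c(0.75, 0.0), x3 = c(0.7, 0.1),
             x4 = c(0.45, 0.42), x5 = c(0.05, 0.85), x6 = c(0, 0.9),
             x7 = c(0.1, 0.6))
  sol <- structure(list(pattern = P, Phi = diag(2),
                        omegas = c(0.88, 0.65),
                        assignment = c(x1 = 1L, x2 = 1L, x3 = 1L, x4 = 1L,
                                       x5 = 2L, x6 = 2L, x7 = 2L),
                        unassigned = character(0), ties = character(0),
                        k = 2L, threshold = 0.4),
                   class = "rrt_efa")
  cr <- evaluate_criteria(sol)
  expect_identical(cr$cross_loading, "x4")
  expect_false(cr$pass[["criterion1"]])
  expect_false(cr$pass[["criterion3"]])  # omega 0.65 < 0.7
  expect_false(cr$accepted)

  # overrides: justified cross-loader plus a near-threshold omega floor
  cr2 <- evaluate_criteria(sol, overrides = list(
    cross_loading_items = "x4", omega_floor = 0.65,
    theory_notes = "both factors interpretable"))
  expect_true(cr2$accepted)
  expect_true(cr2$theory$assessed)

  # a two-item factor warns without failing
  P3 <- rbind(x1 = c(0.8, 0), x2 = c(0.75, 0), x3 = c(0.7, 0),
              y1 = c(0, 0.85), y2 = c(0, 0.94))
  sol3 <- structure(list(pattern = P3, Phi = diag(2),
                         omegas = c(0.8, mcdonald_omega(c(0.85, 0.94))),
                         assignment = c(x1 = 1L, x2 = 1L, x3 = 1L,
                                        y1 = 2L, y2 = 2L),
                         unassigned = character(0), ties = character(0),
                         k = 2L, threshold = 0.4),
                    class = "rrt_efa")
  cr3 <- evaluate_criteria(sol3)
  expect_true(cr3$accepted)
  expect_identical(unname(cr3$two_item_factors), 2L)

  # invariance under item and factor reordering
  perm <- c(4, 2, 5, 1, 3)
  sol_p <- sol3
  sol_p$pattern <- P3[perm, 2:1]
  sol_p$omegas <- rev(sol3$omegas)
  sol_p$assignment <- setNames(3L - sol3$assignment[perm],
                               names(sol3$assignment)[perm])
  cr_p <- evaluate_criteria(sol_p)
  expect_identical(cr_p$accepted, cr3$accepted)
  expect_identical(cr_p$pass, cr3$pass)
})

test_that("items map to their highest-loading factor with documented ties", {
  P <- rbind(a = c(0.50, 0.45), b = c(0.35, 0.2), c = c(0.45, 0.45),
             d = c(0.1, 0.8))
  asg <- assign_items(P)
  expect_identical(asg$assignment[["a"]], 1L)
  expect_identical(asg$unassigned, "b")
  expect_identical(asg$assignment[["c"]], 1L)
  expect_identical(asg$ties, "c")
  expect_identical(asg$assignment[["d"]], 2L)
})

test_that("the acceptance search recovers the generating six-factor pattern", {
  cfg <- simulation_config(n_per_country = c(X = 5000))
  cohort <- simulate_latent_ordinal(cfg, seed = 41)
  clean <- screen_and_impute(cohort$raw, cfg$schema, path = "factor")$clean
  res <- search_solution(clean, k_start = 6,
                         overrides = list(omega_floor = 0.65))
  expect_identical(res$status, "accepted")
  expect_identical(res$solution$k, 6L)
  # congruence against the generating pattern after alignment
  P <- res$solution$pattern
  gen <- rrt_factors_fixture()
  G <- matrix(0, nrow(P), 6,
              dimnames = list(rownames(P), names(gen$factors)))
  for (f in names(gen$factors)) {
    w <- gen$factors[[f]]
    w <- w[names(w) %in% rownames(P)]
    G[names(w), f] <- pmax(pmin(w, 0.95), -0.95)
  }
  expect_true(all(tucker_congruence(G, P) >= 0.95))
  # the seven structureless items stay out of the solution
  expect_true(all(setdiff(schema_ids(cfg$schema),
                          factor_spec_ids(gen)) %in%
                    res$solution$unassigned))
})

test_that("independent noise exhausts the search without acceptance", {
  schema <- questionnaire_schema(lapply(paste0("v", 1:9), function(id)
    item_definition(id, response_scale("likert", paste0("L", 1:4)))))
  cohort <- simulate_null(400, schema, seed = 77)
  res <- search_solution(cohort$raw$data, k_start = 3)
  expect_identical(res$status, "exhausted")
  expect_null(res$solution)
  expect_gt(length(res$trace$steps), 0)
  # k_start 0 (nothing retained) terminates immediately
  res0 <- search_solution(cohort$raw$data, k_start = 0)
  expect_identical(res0$status, "exhausted")
})

test_that("a deliberate cross-loader is eliminated during the search", {
  set.seed(55)
  n <- 1500
  phi <- 0.2
  f1 <- rnorm(n); f2 <- phi * f1 + sqrt(1 - phi^2) * rnorm(n)
  gen <- function(lam1, lam2 = 0) {
    u <- 1 - lam1^2 - lam2^2 - 2 * lam1 * lam2 * phi
    findInterval(lam1 * f1 + lam2 * f2 + sqrt(u) * rnorm(n),
                 qnorm((1:3) / 4))
  }
  x <- cbind(a1 = gen(0.8), a2 = gen(0.75), a3 = gen(0.7),
             b1 = gen(0, 0.8), b2 = gen(0, 0.75), b3 = gen(0, 0.7),
             cross = gen(0.52, 0.52))
  storage.mode(x) <- "integer"
  res <- search_solution(x, k_start = 2)
  expect_true("cross" %in% res$trace$eliminated ||
                "cross" %in% unlist(lapply(res$trace$steps,
                                           `[[`, "cross_loading")))
})

test_that("accepted solutions serialize to the factor-spec format", {
  x <- sim_one_factor(1200, c(0.8, 0.75, 0.7, 0.72), rep(4, 4), seed = 8)
  res <- search_solution(x, k_start = 1)
  expect_identical(res$status, "accepted")
  spec <- solution_to_factor_spec(res$solution)
  expect_s3_class(spec, "rrt_factors")
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_factor_spec(spec, tmp)
  back <- load_factor_spec(tmp)
  expect_equal(back$factors, spec$factors, tolerance = 1e-12)
})
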