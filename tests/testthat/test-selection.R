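# a seeded scenario with one strong active predictor among noise
one_active <- function(seed, n = 2000, beta = 2) {
  simulate_logistic_records(
    n,
    predictors = stats::setNames(
      rep(list(c(l1 = 0.5, l2 = 0.5)), 5), paste0("X", 1:5)),
    beta0 = -0.5, mains = list(X1 = c(l2 = beta)), seed = seed)
}

test_that("forward selection finds the active predictor and stops at noise", {
  d <- one_active(1)
  x <- crosstab(d, dplyr::everything())
  fwd <- mi_forward(x, "T", paste0("X", 1:5))
  expect_identical(fwd$selected[1], "X1")
  expect_lte(length(fwd$selected), 2)  # occasionally one false entry
  expect_true(all(c("step", "kind", "candidate", "p.value", "mir",
                    "chosen") %in% names(fwd$trace)))
})

test_that("forward selection is deterministic and replayable", {
  d <- one_active(7)
  x <- crosstab(d, dplyr::everything())
  a <- mi_forward(x, "T", paste0("X", 1:5))
  b <- mi_forward(x, "T", paste0("X", 1:5))
  expect_identical(a$trace, b$trace)
  expect_identical(a$selected, b$selected)
})

test_that("an all-null scenario mostly yields an empty selection", {
  hits <- vapply(1:20, function(s) {
    d <- simulate_logistic_records(
      400,
      predictors = stats::setNames(
        rep(list(c(l1 = 0.5, l2 = 0.5)), 3), paste0("X", 1:3)),
      beta0 = 0, seed = 5000 + s)
    x <- crosstab(d, dplyr::everything())
    length(mi_forward(x, "T", paste0("X", 1:3))$selected) == 0
  }, logical(1))
  # roughly (1 - alpha)^3 of runs select nothing; 20 runs is a smoke bound
  expect_gte(mean(hits), 0.6)
})

test_that("the mir criterion scores candidates by the joint MI ratio", {
  d <- one_active(3)
  x <- crosstab(d, dplyr::everything())
  cfg <- selection_config(criterion = "mir")
  fwd <- mi_forward(x, "T", paste0("X", 1:5), cfg)
  expect_identical(fwd$selected[1], "X1")
})

test_that("backward deletion removes an appended noise predictor and keeps the signal", {
  d <- one_active(11)
  x <- crosstab(d, dplyr::everything())
  bwd <- mi_backward(x, "T", c("X1", "X4"))
  expect_identical(bwd$retained, "X1")
  expect_identical(unique(bwd$trace$chosen[!is.na(bwd$trace$chosen)]), "X4")
})

test_that("backward deletion never reintroduces factors (retained subset of selected)", {
  for (seed in c(2, 9, 21)) {
    d <- one_active(seed)
    x <- crosstab(d, dplyr::everything())
    fwd <- mi_forward(x, "T", paste0("X", 1:5))
    bwd <- mi_backward(x, "T", fwd$selected)
    expect_true(all(bwd$retained %in% fwd$selected))
  }
})

test_that("strongly associated predictors all survive deletion", {
  d <- simulate_logistic_records(
    4000,
    predictors = list(X1 = c(l1 = 0.5, l2 = 0.5),
                      X2 = c(l1 = 0.5, l2 = 0.5)),
    beta0 = -1, mains = list(X1 = c(l2 = 1.5), X2 = c(l2 = 1.5)),
    seed = 99)
  x <- crosstab(d, dplyr::everything())
  bwd <- mi_backward(x, "T", c("X1", "X2"))
  expect_setequal(bwd$retained, c("X1", "X2"))
})

test_that("rearrangement at m = 2 matches the exhaustive order choice", {
  d <- simulate_logistic_records(
    3000,
    predictors = list(X1 = c(l1 = 0.5, l2 = 0.5),
                      X2 = c(l1 = 0.5, l2 = 0.5)),
    beta0 = -1, mains = list(X1 = c(l2 = 1.2), X2 = c(l2 = 0.8)),
    seed = 17)
  x <- crosstab(d, dplyr::everything())
  re <- mi_rearrange(x, "T", c("X1", "X2"))
  p_int <- function(pred) {
    s <- pythagorean_split(x, pred, "T", setdiff(c("X1", "X2"), pred))
    s$p.value[s$kind == "interaction"]
  }
  outer_pred <- re$order[2]
  expect_gte(p_int(outer_pred), p_int(setdiff(c("X1", "X2"), outer_pred)))
  # the terms table is the machine analogue of a printed decomposition
  expect_setequal(unique(re$terms$kind), c("mi", "cmi", "interaction",
                                           "partial"))
})

test_that("a pure main-effects mechanism yields a model without interactions", {
  d <- simulate_logistic_records(
    6000,
    predictors = list(X1 = c(l1 = 0.5, l2 = 0.5),
                      X2 = c(l1 = 0.5, l2 = 0.5)),
    beta0 = -1, mains = list(X1 = c(l2 = 1.5), X2 = c(l2 = 1.0)),
    seed = 23)
  x <- crosstab(d, dplyr::everything())
  sel <- mi_select(x, "T", c("X1", "X2"))
  expect_setequal(sel$retained, c("X1", "X2"))
  expect_setequal(sel$model$mains, c("X1", "X2"))
  expect_length(sel$model$interactions, 0)
})

test_that("a planted predictor-by-predictor interaction is retained", {
  d <- simulate_logistic_records(
    12000,
    predictors = list(X1 = c(l1 = 0.5, l2 = 0.5),
                      X2 = c(l1 = 0.5, l2 = 0.5)),
    beta0 = -1.2, mains = list(X1 = c(l2 = 1.2), X2 = c(l2 = 1.2)),
    interactions = list(list(
      factors = c("X1", "X2"),
      beta = matrix(c(0, 0, 0, -2), 2, 2,
                    dimnames = list(c("l1", "l2"), c("l1", "l2"))))),
    seed = 31)
  x <- crosstab(d, dplyr::everything())
  sel <- mi_select(x, "T", c("X1", "X2"))
  expect_setequal(sel$retained, c("X1", "X2"))
  expect_true(any(vapply(sel$model$interactions, identical, logical(1),
                         c("X1", "X2"))))
})

test_that("selection handles the single-predictor boundary", {
  d <- one_active(41)
  x <- crosstab(d, X1, T)
  sel <- mi_select(x, "T", "X1")
  expect_identical(sel$retained, "X1")
  expect_identical(sel$model$mains, "X1")
})

test_that("the credit data enters A1 first and drops A9 given {A1, A3}", {
  g <- german_credit()
  x <- crosstab(g, A1, A3, A6, A9, A21)
  fwd <- mi_forward(x, "A21", c("A1", "A3", "A6", "A9"))
  expect_identical(fwd$selected[1], "A1")
  # the known dispensability pattern: A9 adds nothing given {A1, A3}
  bwd <- mi_backward(x, "A21", c("A1", "A3", "A9"))
  expect_setequal(bwd$retained, c("A1", "A3"))
})
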