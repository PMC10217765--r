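test_that("model strings parse in both concatenated and starred notation", {
  m <- loglin_model("{CA, CS, MG, MS, ADG, ADH, SAH, SD}",
                    factors = c("C", "A", "S", "M", "G", "D", "H"))
  expect_length(m$generators, 8)
  expect_identical(m$generators[[5]], c("A", "D", "G"))
  m2 <- loglin_model("{A1*A3, A1*T}", factors = c("A1", "A3", "T"))
  expect_identical(m2$generators, list(c("A1", "A3"), c("A1", "T")))
  # multi-character names concatenated resolve by longest match
  m3 <- loglin_model("{A1A3}", factors = c("A1", "A3"))
  expect_identical(m3$generators[[1]], c("A1", "A3"))
  expect_error(loglin_model("{A1Q}", factors = c("A1", "A3")), "cannot parse")
  # non-maximal generators are absorbed
  m4 <- loglin_model(list(c("X", "Y"), "X"))
  expect_identical(m4$generators, list(c("X", "Y")))
})

test_that("saturated IPF fit reproduces the observed counts with zero deviance", {
  x <- rand_contab(c(2, 3, 2), 400, seed = 5, names = c("X", "Y", "Z"))
  fit <- ipf_fit(x, loglin_model(list(c("X", "Y", "Z"))))
  expect_equal(fit$fitted, x$counts, tolerance = 1e-6)
  expect_equal(fit$deviance, 0, tolerance = 1e-6)
  expect_identical(fit$df, 0L)
  expect_equal(fit$p.value, 1)
})

test_that("independence IPF fit equals the closed-form row*col/N means", {
  x <- rand_contab(c(2, 2), 300, seed = 8, names = c("X", "Y"))
  fit <- ipf_fit(x, loglin_model(list("X", "Y")))
  closed <- outer(rowSums(x$counts), colSums(x$counts)) / x$N
  expect_equal(unname(fit$fitted), unname(closed), tolerance = 1e-8)
  expect_equal(fit$deviance, mi_test(x, "X", "Y")$statistic,
               tolerance = 1e-8)
  expect_identical(fit$df, 1L)
})

test_that("IPF fitted margins match observed margins for every generator", {
  x <- rand_contab(c(3, 2, 2, 2), 1200, seed = 13,
                   names = c("A", "B", "C", "D"))
  model <- loglin_model(list(c("A", "B"), c("B", "C"), c("C", "D")))
  fit <- ipf_fit(x, model)
  expect_true(fit$converged)
  for (g in model$generators) {
    gi <- match(g, ct_factors(x))
    expect_equal(apply(fit$fitted, gi, sum), apply(x$counts, gi, sum),
                 tolerance = 1e-6)
  }
})

test_that("IPF agrees with the stats::loglin reference on random models", {
  for (seed in 1:10) {
    x <- rand_contab(c(2, 3, 2), 500, seed = 100 + seed,
                     names = c("X", "Y", "Z"))
    specs <- list(list(c("X", "Y"), c("X", "Z"), c("Y", "Z")),
                  list(c("X", "Z"), c("Y", "Z")),
                  list("X", c("Y", "Z")))
    for (gen in specs) {
      mine <- ipf_fit(x, loglin_model(gen))
      ref <- stats::loglin(x$counts,
                           margin = lapply(gen, function(g)
                             match(g, ct_factors(x))),
                           fit = FALSE, print = FALSE, eps = 1e-10,
                           iter = 200)
      expect_equal(mine$deviance, ref$lrt, tolerance = 1e-6)
      expect_identical(mine$df, as.integer(ref$df))
    }
  }
})

test_that("adding a generator never increases the deviance", {
  x <- rand_contab(c(2, 2, 3), 700, seed = 31, names = c("X", "Y", "Z"))
  d1 <- ipf_fit(x, loglin_model(list(c("X", "Z"), c("Y", "Z"))))$deviance
  d2 <- ipf_fit(x, loglin_model(list(c("X", "Z"), c("Y", "Z"),
                                     c("X", "Y"))))$deviance
  expect_lte(d2, d1 + 1e-8)
})

test_that("CMI equals the deviance of the conditional-independence model", {
  for (seed in 1:10) {
    x <- rand_contab(c(2, 3, 2), 400, seed = 200 + seed,
                     names = c("X", "Y", "Z"))
    cmi <- cmi_test(x, "X", "Y", "Z")$statistic
    dev <- ipf_fit(x, loglin_model(list(c("X", "Z"), c("Y", "Z"))))$deviance
    expect_equal(cmi, dev, tolerance = 1e-7)
  }
})

test_that("a true homogeneous-association model fits with near-zero deviance", {
  # identical conditional odds ratios in both strata by construction
  base <- matrix(c(30, 10, 10, 30), 2)
  counts <- array(c(base, 2 * base), c(2, 2, 2),
                  dimnames = list(X = c("a", "b"), Y = c("u", "v"),
                                  Z = c("z1", "z2")))
  fit <- ipf_fit(contab(counts),
                 loglin_model(list(c("X", "Y"), c("X", "Z"), c("Y", "Z"))))
  expect_lt(fit$deviance, 1e-8)
})

test_that("the Pythagorean split is exact, non-negative and df-consistent", {
  for (seed in 1:10) {
    x <- rand_contab(c(2, 2, 3), 500, seed = 300 + seed,
                     names = c("X", "Y", "Z"))
    s <- pythagorean_split(x, "X", "Y", "Z")
    stats <- stats::setNames(s$statistic, s$kind)
    dfs <- stats::setNames(s$df, s$kind)
    expect_equal(stats[["interaction"]] + stats[["partial"]],
                 stats[["cmi"]], tolerance = 1e-6)
    expect_true(all(s$statistic >= 0))
    expect_identical(dfs[["interaction"]] + dfs[["partial"]], dfs[["cmi"]])
  }
})

test_that("a conditionally independent table splits into three zeros", {
  counts <- condindep_probs() * 4000
  s <- pythagorean_split(contab(counts), "X", "Y", "Z")
  expect_true(all(s$statistic < 1e-6))
})

test_that("composite conditioning groups are compounded before the split", {
  x <- rand_contab(c(2, 2, 2, 3), 900, seed = 77,
                   names = c("X", "Y", "Z1", "Z2"))
  s <- pythagorean_split(x, "X", "Y", c("Z1", "Z2"))
  dfs <- stats::setNames(s$df, s$kind)
  expect_identical(dfs[["cmi"]], 6L)          # (2-1)(2-1) * 6
  expect_identical(dfs[["interaction"]], 5L)  # (2-1)(2-1)(6-1)
  expect_identical(dfs[["partial"]], 1L)
  # identical whether the caller compounds first or not
  y <- compound(x, c("Z1", "Z2"), "Z")
  s2 <- pythagorean_split(y, "X", "Y", "Z")
  expect_equal(s$statistic, s2$statistic, tolerance = 1e-8)
})

test_that("alpha splits satisfy the exact size identity", {
  eq <- alpha_split(0.05)
  expect_equal(eq$alpha1, 0.025320565519103666, tolerance = 1e-12)
  expect_equal(eq$alpha1 + eq$alpha2 - eq$alpha1 * eq$alpha2, 0.05)
  sp <- alpha_split(0.05, alpha1 = 0.01)
  expect_equal(sp$alpha2, 0.04040404040404041, tolerance = 1e-12)
  expect_equal(sp$alpha1 + sp$alpha2 - sp$alpha1 * sp$alpha2, 0.05)
  z <- alpha_split(0.05, alpha1 = 0)
  expect_equal(z$alpha2, 0.05)
  expect_error(alpha_split(1.2), "in \\(0, 1\\)")
  expect_error(alpha_split(0.05, alpha1 = 0.06), "alpha1")
})

test_that("the two-step decision rule follows the component p-values", {
  # interaction insignificant, partial significant -> rejected
  s <- fake_split(26.110, 16, 15.495, 15, 10.615, 1)
  r <- two_step_test(s, alpha_split(0.05))
  expect_false(r$interaction_significant)
  expect_true(r$partial_significant)
  expect_true(r$rejected)
  expect_equal(r$p_interaction, 0.416, tolerance = 1e-3)
  expect_equal(r$p_partial, 0.001, tolerance = 0.3)
  # both components null -> not rejected
  s0 <- fake_split(0, 2, 0, 1, 0, 1)
  expect_false(two_step_test(s0, alpha_split(0.05))$rejected)
  # alpha1 = 0 degenerates to a single partial-association test
  r0 <- two_step_test(s, alpha_split(0.05, alpha1 = 0))
  expect_false(r0$interaction_significant)
  expect_true(r0$rejected)
})

test_that("model_deviance attaches the validity verdict", {
  x <- rand_contab(c(2, 2), 300, seed = 41, names = c("X", "Y"))
  sat <- model_deviance(x, loglin_model(list(c("X", "Y"))))
  expect_equal(sat$deviance, 0, tolerance = 1e-8)
  expect_identical(sat$df, 0L)
  expect_equal(sat$p.value, 1)
  expect_true(sat$valid)
  prod <- product_contab(c(40, 60), c(30, 70))
  ind <- model_deviance(prod, loglin_model(list("X", "Y")))
  expect_lt(ind$deviance, 1e-8)
  expect_true(ind$valid)
})

test_that("graphical-model extraction lists generator edges and size>=3 cliques", {
  fac <- c("C", "A", "S", "M", "G", "D", "H")
  g <- model_graph("{CA, CS, MG, MS, ADG, ADH, SAH, SD}", factors = fac)
  expect_identical(g$cliques,
                   list(c("A", "D", "G"), c("A", "D", "H"),
                        c("A", "H", "S")))
  pairs <- paste(g$edges$from, g$edges$to)
  expect_true(all(c("A C", "C S", "G M", "M S", "D S", "A D",
                    "A G", "D G", "A H", "D H", "H S", "A S") %in% pairs))
  g2 <- model_graph(loglin_model(list(c("X", "Y"), c("Y", "Z"))))
  expect_length(g2$cliques, 0)
  g3 <- model_graph(loglin_model(list(c("A", "B", "C", "D"))))
  expect_identical(nrow(g3$edges), 6L)
  expect_length(g3$cliques, 1)
})

test_that("IPF reports non-convergence loudly", {
  x <- rand_contab(c(3, 3, 3), 2000, seed = 55, names = c("X", "Y", "Z"))
  expect_warning(
    fit <- ipf_fit(x, loglin_model(list(c("X", "Y"), c("X", "Z"),
                                        c("Y", "Z"))),
                   tol = 1e-12, max_iter = 2L),
    "did not converge")
  expect_false(fit$converged)
})
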