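# Seeded generators of multinomial contingency tables and case-level
# records with specified log-linear or logistic structure.  Every generator
# takes an explicit seed and restores the caller's RNG state afterwards,
# so the package never leaks global randomness.

#' Sample a multinomial contingency table
#'
#' Draws cell counts from `Multinomial(N, f)` where the cell-probability
#' tensor `f` is given either directly (`probs`) or through log-linear
#' `lambda` terms (`exp` of the summed term effects, normalized — the
#' Poisson/multinomial duality makes the two routes equivalent for fixed
#' `N`).
#'
#' @param n total count to distribute.
#' @param probs a probability array with complete named dimnames (cells sum
#'   to 1), or `NULL` when `lambda` is given.
#' @param lambda alternative specification: a list with `levels` (named
#'   list of level labels per factor) and `terms` (named list mapping a
#'   term such as `"X:Y"` to an array of lambda values over those factors'
#'   levels).  An intercept is implied by the normalization.
#' @param seed integer seed; fully determines the draw.
#' @return a [contab].
#' @examples
#' p <- array(0.25, c(2, 2), dimnames = list(X = c("a", "b"),
#'                                           Y = c("u", "v")))
#' simulate_table(100, probs = p, seed = 1)
#' @export
simulate_table <- function(n, probs = NULL, lambda = NULL, seed) {
  if (is.null(probs) == is.null(lambda))
    stop("give exactly one of `probs` or `lambda`")
  if (!is.null(lambda)) probs <- lambda_probs(lambda)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-8)
    stop("`probs` must be a normalized probability tensor")
  counts <- withr::with_seed(seed, {
    as.vector(stats::rmultinom(1L, size = n, prob = as.vector(probs)))
  })
  contab(array(counts, dim = dim(probs), dimnames = dimnames(probs)))
}

#' @rdname simulate_table
#' @export
lambda_probs <- function(lambda) {
  lev <- lambda$levels
  if (is.null(lev)) stop("`lambda$levels` is required")
  logmu <- array(0, dim = lengths(lev), dimnames = lev)
  dims <- names(lev)
  for (term in names(lambda$terms)) {
    fs <- strsplit(term, ":", fixed = TRUE)[[1]]
    if (!all(fs %in% dims))
      stop("lambda term '", term, "' names unknown factors")
    val <- lambda$terms[[term]]
    if (!identical(dim0(val), unname(lengths(lev[fs]))))
      stop("lambda term '", term, "' has the wrong shape")
    # broadcast the term over the remaining axes
    perm <- match(c(fs, setdiff(dims, fs)), dims)
    expanded <- array(as.vector(val),
                      dim = lengths(lev)[perm])
    logmu <- logmu + aperm(expanded, order(perm))
  }
  p <- exp(logmu - max(logmu))
  p / sum(p)
}

dim0 <- function(x) if (is.null(dim(x))) length(x) else unname(dim(x))

#' Sample case-level records from a categorical logistic mechanism
#'
#' Predictors are drawn independently from declared level distributions;
#' the binary target is drawn `Bernoulli(plogis(eta))` with
#' `eta = beta0 + sum of main-effect coefficients + interactions`.
#' Coefficients use reference coding: each factor's coefficient vector has
#' one entry per level with the first level fixed at 0.
#'
#' @param n number of records.
#' @param predictors named list; each element a probability vector over
#'   that predictor's levels (names become the level labels).
#' @param beta0 intercept of the linear predictor.
#' @param mains named list of per-level coefficient vectors (first level is
#'   the reference; entries are matched to levels by name, missing levels
#'   get 0).
#' @param interactions optional list of `list(factors = c("X","Z"),
#'   beta = matrix)` entries, the matrix indexed by the two factors' levels.
#' @param target name of the target column (levels `"0"`/`"1"`,
#'   `"1"` = success).
#' @param seed integer seed.
#' @return a tibble of `n` records.
#' @examples
#' simulate_logistic_records(
#'   100, predictors = list(X = c(a = 0.5, b = 0.5)),
#'   beta0 = -1, mains = list(X = c(b = 2)), seed = 1)
#' @export
simulate_logistic_records <- function(n, predictors, beta0 = 0,
                                      mains = list(),
                                      interactions = list(),
                                      target = "T", seed) {
  stopifnot(length(predictors) > 0, !is.null(names(predictors)))
  if (target %in% names(predictors))
    stop("target name clashes with a predictor")
  withr::with_seed(seed, {
    cols <- purrr::imap(predictors, function(pr, f) {
      if (abs(sum(pr) - 1) > 1e-8)
        stop("level probabilities of '", f, "' must sum to 1")
      lv <- names(pr)
      if (is.null(lv)) lv <- paste0("l", seq_along(pr))
      factor(sample(lv, n, replace = TRUE, prob = pr), levels = lv)
    })
    eta <- rep(beta0, n)
    for (f in names(mains)) {
      if (!f %in% names(cols)) stop("main effect on unknown factor '", f, "'")
      b <- mains[[f]]
      bad <- setdiff(names(b), levels(cols[[f]]))
      if (length(bad)) stop("unknown level(s) in mains$", f, ": ",
                            paste(bad, collapse = ", "))
      eta <- eta + ifelse(is.na(b[as.character(cols[[f]])]), 0,
                          b[as.character(cols[[f]])])
    }
    for (ia in interactions) {
      fs <- ia$factors
      if (length(fs) != 2L || !all(fs %in% names(cols)))
        stop("each interaction needs two known factors")
      eta <- eta + ia$beta[cbind(as.character(cols[[fs[1]]]),
                                 as.character(cols[[fs[2]]]))]
    }
    yv <- stats::rbinom(n, 1L, stats::plogis(eta))
    out <- tibble::as_tibble(cols)
    out[[target]] <- factor(yv, levels = c(0L, 1L))
    out
  })
}
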