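# Grouped-binomial logistic models constructed from a rearranged MI
# identity: dummy-coded categorical mains plus crossings, with the
# likelihood-ratio deviance against the saturated grouped model.

#' Parse a logistic model specification string
#'
#' Dialect: `"T ~ A1 + A3 + A12"`, with a crossing written `"A3*A14"`
#' (the typographic multiplication cross is also accepted).  A crossing is
#' entered as a *compound* factor by default — one factor whose levels are
#' the Cartesian tuples, contributing `L1*L2 - 1` parameters — or as an
#' interaction added to the component mains (`(L1-1)(L2-1)` extra
#' parameters) when `crossing = "interaction"`.
#'
#' @param spec model string.
#' @return a list with `target` and `terms` (list of character vectors).
#' @export
parse_logit_spec <- function(spec) {
  parts <- strsplit(spec, "~", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("spec must have the form 'target ~ terms'")
  target <- trimws(parts[1L])
  toks <- trimws(strsplit(parts[2L], "+", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  if (!length(toks)) stop("no terms on the right-hand side")
  terms <- lapply(toks, function(tok)
    trimws(strsplit(gsub("×", "*", tok), "*", fixed = TRUE)[[1]]))
  if (anyDuplicated(vapply(terms, function(t)
    paste(sort(t), collapse = "*"), "")))
    stop("duplicate terms in spec")
  list(target = target, terms = terms)
}

#' Fit a logistic model on grouped categorical data
#'
#' Fits a binomial logistic regression by iteratively reweighted least
#' squares on the *grouped* data — one row per populated covariate class —
#' with reference (first-level) dummy coding.  The reported deviance is the
#' G-squared statistic against the saturated grouped model; its df is the
#' number of covariate classes minus the parameter count.  Following the
#' field convention for tables specified by nominal level sets, the class
#' count defaults to the *nominal* number of predictor-level combinations
#' (empty classes contribute zero deviance but are not removed from the
#' df); set `class_count = "populated"` to count only observed classes.
#'
#' @param data a data frame of case-level records, or a [contab].
#' @param spec a model string (see [parse_logit_spec()]) or its parsed form.
#' @param crossing how `A*B` terms enter: `"compound"` (one Cartesian-level
#'   factor) or `"interaction"` (component mains plus their interaction).
#' @param ref reference level of the target (the level modelled as
#'   failure); defaults to the target's first declared level.
#' @param class_count `"nominal"` or `"populated"` covariate classes for
#'   the deviance df.
#' @param ... passed to [stats::glm.control()] (`epsilon`, `maxit`).
#' @return an object of class `grouped_logit` wrapping the glm fit, with
#'   `deviance`, `df`, `p.value`, `loglik`, `aic`, `n_params`,
#'   `n_classes`, `converged`.  `tidy()` gives the coefficient table,
#'   `glance()` the fit summary.
#' @examples
#' \dontrun{
#' g <- german_credit()
#' fit_logit(g, "A21 ~ A1 + A3 + A12")
#' }
#' @export
fit_logit <- function(data, spec, crossing = c("compound", "interaction"),
                      ref = NULL, class_count = c("nominal", "populated"),
                      ...) {
  crossing <- match.arg(crossing)
  class_count <- match.arg(class_count)
  if (is.character(spec)) spec <- parse_logit_spec(spec)
  if (inherits(data, "contab")) data <- .ct_cases(data)
  target <- spec$target
  if (!target %in% names(data)) stop("unknown target column '", target, "'")
  base_factors <- unique(unlist(spec$terms))
  if (target %in% base_factors) stop("target cannot appear among the terms")
  missing <- setdiff(base_factors, names(data))
  if (length(missing))
    stop("unknown term columns: ", paste(missing, collapse = ", "))

  mf <- data.frame(row.names = seq_len(nrow(data)))
  tv <- .as_declared_factor(data[[target]])
  if (nlevels(tv) != 2L) stop("target must be binary")
  if (!is.null(ref)) tv <- stats::relevel(tv, ref = ref)
  # success = the non-reference (second) level
  y <- as.integer(tv) - 1L
  for (f in base_factors) mf[[f]] <- .as_declared_factor(data[[f]])

  rhs <- character(0)
  nominal <- prod(vapply(base_factors, function(f) nlevels(mf[[f]]), 0L))
  for (term in spec$terms) {
    if (length(term) == 1L) {
      rhs <- c(rhs, term)
    } else if (crossing == "compound") {
      nm <- paste(term, collapse = ".x.")
      mf[[nm]] <- interaction(mf[term], sep = ":", lex.order = FALSE)
      rhs <- c(rhs, nm)
    } else {
      rhs <- c(rhs, term, paste(term, collapse = ":"))
    }
  }
  grouped <- dplyr::summarise(
    dplyr::group_by(dplyr::mutate(mf, ..y = y),
                    dplyr::across(dplyr::all_of(setdiff(names(mf), "..y")))),
    succ = sum(.data$..y), fail = sum(1 - .data$..y), .groups = "drop")
  fml <- stats::as.formula(paste("cbind(succ, fail) ~",
                                 paste(rhs, collapse = " + ")))
  fit <- stats::glm(fml, family = stats::binomial(), data = grouped,
                    control = stats::glm.control(...))
  if (!fit$converged) warning("IRLS did not converge")
  phat <- stats::fitted(fit)
  sep <- abs(phat) < 1e-8 | abs(1 - phat) < 1e-8
  if (any(sep & abs(stats::coef(fit)[1]) > 0) &&
      any(abs(stats::coef(fit)) > 10, na.rm = TRUE))
    warning("possible complete separation: fitted class probabilities at ",
            sum(sep), " covariate class(es) are within 1e-8 of 0/1")
  n_params <- sum(!is.na(stats::coef(fit)))
  n_classes <- if (class_count == "nominal") nominal else nrow(grouped)
  df <- n_classes - n_params
  loglik <- as.numeric(stats::logLik(fit))
  structure(list(fit = fit, spec = spec, crossing = crossing,
                 grouped = grouped,
                 deviance = stats::deviance(fit), df = as.integer(df),
                 p.value = if (df > 0)
                   stats::pchisq(stats::deviance(fit), df,
                                 lower.tail = FALSE) else 1,
                 loglik = loglik, aic = -2 * loglik + 2 * n_params,
                 n_params = n_params, n_classes = as.integer(n_classes),
                 class_count = class_count,
                 target = target, success_level = levels(tv)[2L],
                 converged = fit$converged),
            class = "grouped_logit")
}

# expand a contab into one row per subject (inverse of crosstab)
.ct_cases <- function(x) {
  tb <- as_tibble(x)
  tb <- tb[tb$n > 0, , drop = FALSE]
  out <- tb[rep(seq_len(nrow(tb)), tb$n), setdiff(names(tb), "n"),
            drop = FALSE]
  # preserve declared level order
  for (f in names(out)) out[[f]] <- factor(out[[f]], levels = ct_levels(x)[[f]])
  tibble::as_tibble(out)
}

.as_declared_factor <- function(v) {
  if (is.factor(v)) v else factor(as.character(v), levels = unique(as.character(v)))
}

#' @export
print.grouped_logit <- function(x, ...) {
  cat("grouped logistic model: ", x$target, " ~ ",
      paste(vapply(x$spec$terms, paste, "", collapse = "*"),
            collapse = " + "),
      "   (success level: ", x$success_level, ")\n", sep = "")
  cat(sprintf("loglik %.2f  deviance %.2f on %d df (p = %.3g)  AIC %.2f\n",
              x$loglik, x$deviance, x$df, x$p.value, x$aic))
  invisible(x)
}

#' @export
tidy.grouped_logit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = unname(s[, 1L]),
                 std.error = unname(s[, 2L]), statistic = unname(s[, 3L]),
                 p.value = unname(s[, 4L]))
}

#' @export
glance.grouped_logit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, deviance = x$deviance, df = x$df,
                 p.value = x$p.value, aic = x$aic,
                 n_params = x$n_params, n_classes = x$n_classes,
                 converged = x$converged)
}

#' Goodness of fit of a grouped logistic model
#'
#' The likelihood-ratio deviance against the saturated grouped model, with
#' the validity verdict used throughout: valid iff the deviance p-value is
#' at or above `alpha`.
#'
#' @param fit a [fit_logit()] result.
#' @param alpha validity threshold.
#' @return a one-row tibble: `deviance`, `df`, `p.value`, `valid`.
#' @export
goodness_of_fit <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "grouped_logit"))
  tibble::tibble(deviance = fit$deviance, df = fit$df,
                 p.value = fit$p.value, valid = fit$p.value >= alpha)
}

#' Translate MI model terms into a logistic specification
#'
#' Mains become main effects; each retained interaction among predictors
#' becomes an interaction term added to the mains.
#'
#' @param terms an `mi_model_terms` object from [mi_build_model()].
#' @return a parsed spec suitable for [fit_logit()] (use
#'   `crossing = "interaction"`).
#' @export
as_logit_spec <- function(terms) {
  stopifnot(inherits(terms, "mi_model_terms"))
  tl <- c(as.list(terms$mains), terms$interactions)
  list(target = terms$target, terms = tl)
}
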