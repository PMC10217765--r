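#' @importFrom rlang .data
NULL

# ---- internal numeric kernels -------------------------------------------

# plug-in joint probability array over a subset of factors
.ct_prob <- function(x, keep = ct_factors(x)) {
  m <- marginalize(x, keep)
  if (m$N == 0) stop("empty table")
  m$counts / m$N
}

# 2N * plug-in MI between two disjoint factor groups, natural log
.mi_stat <- function(x, lhs, rhs) {
  m <- marginalize(x, c(lhs, rhs))
  p <- m$counts / m$N
  # collapse to an (lhs-cells x rhs-cells) matrix
  pm <- matrix(aperm(p, match(c(lhs, rhs), ct_factors(m))),
               nrow = prod(dim(p)[match(lhs, ct_factors(m))]))
  pl <- rowSums(pm)
  pr <- colSums(pm)
  pos <- pm > 0
  stat <- 2 * m$N * sum(pm[pos] * log(pm[pos] / outer(pl, pr)[pos]))
  .clamp0(stat)
}

# round-off guard: tiny negatives (|.| <= 1e-8) are numerical zero
.clamp0 <- function(stat, tol = 1e-8) {
  if (stat < 0) {
    if (stat < -tol)
      stop("negative information statistic (", format(stat),
           "): inconsistent inputs")
    stat <- 0
  }
  stat
}

.nlev <- function(x, group) {
  prod(lengths(ct_levels(x)[group]))
}

.check_groups <- function(x, ...) {
  gs <- list(...)
  all <- unlist(gs)
  .ct_check_factors(x, all)
  if (anyDuplicated(all))
    stop("factor groups must be pairwise disjoint (duplicated: ",
         paste(unique(all[duplicated(all)]), collapse = ", "), ")")
}

.info_row <- function(kind, lhs, rhs, given, stat, df) {
  tibble::tibble(
    kind = kind,
    lhs = paste(lhs, collapse = ","),
    rhs = paste(rhs, collapse = ","),
    given = paste(given, collapse = ","),
    statistic = stat,
    df = as.integer(df),
    p.value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# ---- exported estimators -------------------------------------------------

#' Plug-in Shannon entropy of a contingency table
#'
#' Joint entropy (natural log, nats) of the plug-in cell distribution
#' `counts / N`, with the convention `0 * log 0 = 0`.
#'
#' @param x a [contab].
#' @param margin optional factor subset; defaults to the full joint table.
#' @return entropy in nats.
#' @export
shannon_entropy <- function(x, margin = ct_factors(x)) {
  p <- .ct_prob(x, margin)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mutual information and conditional mutual information tests
#'
#' Plug-in MI / CMI between disjoint factor groups, reported on the
#' `2N * I-hat` scale — the G-squared likelihood-ratio statistic of
#' (conditional) independence — together with its nominal-level degrees of
#' freedom and asymptotic chi-square p-value.
#'
#' Degrees of freedom use *nominal* level counts: for groups with `I` and `J`
#' joint level combinations, MI has `(I-1)(J-1)` df; conditioning on a group
#' with `K` nominal combinations multiplies the df by `K`.  Empty conditioning
#' strata contribute zero to the statistic but are not removed from the df
#' (pass `df_observed = TRUE` to count only populated strata, for sparse
#' tables).
#'
#' @param x a [contab].
#' @param lhs,rhs,given character vectors naming disjoint factor groups;
#'   `given` may be empty (`mi_test`) or is required (`cmi_test`).
#' @param df_observed count only populated conditioning strata in the df.
#' @return a one-row tibble: `kind`, `lhs`, `rhs`, `given`, `statistic`,
#'   `df`, `p.value`.
#' @examples
#' x <- contab(array(c(20, 10, 10, 20), c(2, 2),
#'                   dimnames = list(X = c("a", "b"), Y = c("u", "v"))))
#' mi_test(x, "X", "Y")
#' @export
mi_test <- function(x, lhs, rhs) {
  .check_groups(x, lhs, rhs)
  stat <- .mi_stat(x, lhs, rhs)
  .info_row("mi", lhs, rhs, character(0), stat,
            (.nlev(x, lhs) - 1) * (.nlev(x, rhs) - 1))
}

#' @rdname mi_test
#' @export
cmi_test <- function(x, lhs, rhs, given, df_observed = FALSE) {
  if (!length(given)) return(mi_test(x, lhs, rhs))
  .check_groups(x, lhs, rhs, given)
  # chain rule: I(lhs, rhs | given) = I({lhs, given}, rhs) - I(given, rhs);
  # exact for plug-in estimators, so chain decompositions telescope exactly
  stat <- .clamp0(.mi_stat(x, c(lhs, given), rhs) - .mi_stat(x, given, rhs))
  K <- if (df_observed) {
    sum(marginalize(x, given)$counts > 0)
  } else .nlev(x, given)
  .info_row("cmi", lhs, rhs, given, stat,
            (.nlev(x, lhs) - 1) * (.nlev(x, rhs) - 1) * K)
}

#' Chain-rule decomposition of the joint MI with a target
#'
#' Expands `I({X1..Xm}, T)` as
#' `I(X1,T) + I(X2,T|X1) + ... + I(Xm,T|X1..X(m-1))`.
#' Components are orthogonal: their statistics sum to the joint-MI statistic
#' and their dfs sum to the joint df, for every predictor order.
#'
#' @param x a [contab].
#' @param target target factor name.
#' @param order character vector of predictors, outermost term last.
#' @return an object of class `mi_decomp` with `total` (one-row tibble) and
#'   `components` (tibble, one row per term); supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
chain_decompose <- function(x, target, order) {
  if (anyDuplicated(order)) stop("duplicate predictors in `order`")
  if (target %in% order) stop("target cannot appear among the predictors")
  .check_groups(x, target, order)
  comps <- purrr::map(seq_along(order), function(t) {
    cmi_test(x, order[t], target, given = order[seq_len(t - 1L)])
  })
  structure(list(total = mi_test(x, order, target),
                 components = dplyr::bind_rows(comps),
                 target = target, order = order),
            class = "mi_decomp")
}

#' @export
print.mi_decomp <- function(x, ...) {
  cat("MI chain decomposition of I({", paste(x$order, collapse = ", "),
      "}, ", x$target, ")\n", sep = "")
  print(x$components, ...)
  cat(sprintf("total: statistic %.3f on %d df (p = %.3g)\n",
              x$total$statistic, x$total$df, x$total$p.value))
  invisible(x)
}

#' @export
tidy.mi_decomp <- function(x, ...) x$components

#' @export
glance.mi_decomp <- function(x, ...) x$total

#' @export
autoplot.mi_decomp <- function(object, ...) {
  d <- object$components
  d$term <- factor(sprintf("I(%s,%s%s)", d$lhs, d$rhs,
                           ifelse(nzchar(d$given), paste0("|", d$given), "")),
                   levels = rev(sprintf(
                     "I(%s,%s%s)", d$lhs, d$rhs,
                     ifelse(nzchar(d$given), paste0("|", d$given), ""))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$statistic, y = .data$term,
                                  fill = .data$p.value < 0.05)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "2N * I-hat (G² scale)", y = NULL,
                  fill = "p < 0.05") +
    ggplot2::theme_minimal()
}
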