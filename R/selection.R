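# Stepwise MI variable selection and model construction:
#   step 1  forward selection by MI ratio (MIR) or minimum p,
#   step 2  backward deletion of dispensable predictors,
#   step 3  rearrangement of the MI identity so the outermost interaction
#           terms are least significant,
#   step 4  assembly of the retained main and interaction effects.

#' Configuration for MI variable selection
#'
#' @param alpha overall significance level for entering/keeping a predictor.
#' @param alphas an [alpha_split()] for the interaction / partial-association
#'   sub-tests (defaults to the equal split of `alpha`).
#' @param criterion forward-selection score: `"min_p"` picks the candidate
#'   whose CMI given the current set is most significant; `"mir"` picks the
#'   candidate maximizing the joint MI-to-df ratio.  The two are equivalent
#'   in principle but can disagree under df imbalance; both gate entry on
#'   CMI significance at `alpha`.
#' @param max_predictors optional cap on the number of selected predictors.
#' @param replace_interactions attempt to replace a retained high-order
#'   interaction by a set of significant lower-order interactions whose
#'   statistics sum higher at no larger combined df (see [mi_build_model()]).
#' @return a list with class `selection_config`.
#' @export
selection_config <- function(alpha = 0.05, alphas = alpha_split(alpha),
                             criterion = c("min_p", "mir"),
                             max_predictors = Inf,
                             replace_interactions = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  list(alpha = alpha, alphas = alphas,
       criterion = match.arg(criterion),
       max_predictors = max_predictors,
       replace_interactions = replace_interactions)
}

# score every unselected candidate at one forward step
.score_candidates <- function(x, target, selected, candidates) {
  purrr::map_dfr(candidates, function(cand) {
    cmi <- cmi_test(x, cand, target, given = selected)
    joint <- if (length(selected)) {
      mi_test(x, c(selected, cand), target)
    } else cmi
    tibble::tibble(candidate = cand,
                   statistic = cmi$statistic, df = cmi$df,
                   p.value = cmi$p.value,
                   mir = joint$statistic / joint$df)
  })
}

# deterministic tie-break: smaller p, then larger MIR, then name
.pick <- function(scores, criterion) {
  ord <- if (criterion == "mir") {
    order(-scores$mir, scores$p.value, scores$candidate)
  } else {
    order(scores$p.value, -scores$mir, scores$candidate)
  }
  scores$candidate[ord[1L]]
}

#' Forward selection of predictors by mutual information
#'
#' Step 1 of the selection scheme.  The first predictor maximizes the MI
#' ratio (MI / df) with the target among candidates whose MI is significant
#' at `alpha`; each later step scores every unselected candidate by its CMI
#' with the target given the current set (equivalently the joint-MI ratio)
#' and stops when no candidate's CMI is significant.
#'
#' @param x a [contab] containing the target and all candidates.
#' @param target target factor name.
#' @param candidates character vector of candidate predictor names.
#' @param config a [selection_config()].
#' @return a list with `selected` (character vector, selection order) and
#'   `trace` (tibble of per-step candidate scores and decisions).
#' @export
mi_forward <- function(x, target, candidates,
                       config = selection_config()) {
  if (!length(candidates)) stop("`candidates` must be non-empty")
  if (target %in% candidates) stop("target cannot be a candidate")
  .check_groups(x, target, candidates)
  selected <- character(0)
  trace <- list()
  repeat {
    pool <- setdiff(candidates, selected)
    if (!length(pool) || length(selected) >= config$max_predictors) {
      reason <- if (length(pool)) "max_predictors reached" else
        "candidates exhausted"
      trace <- c(trace, list(tibble::tibble(
        step = length(selected) + 1L, kind = "forward",
        candidate = NA_character_, statistic = NA_real_, df = NA_integer_,
        p.value = NA_real_, mir = NA_real_, chosen = NA_character_,
        note = reason)))
      break
    }
    scores <- .score_candidates(x, target, selected, pool)
    sig <- scores[scores$p.value < config$alpha, , drop = FALSE]
    if (!nrow(sig)) {
      trace <- c(trace, list(dplyr::mutate(
        scores, step = length(selected) + 1L, kind = "forward",
        chosen = NA_character_, note = "no significant candidate")))
      break
    }
    pick <- .pick(sig, config$criterion)
    trace <- c(trace, list(dplyr::mutate(
      scores, step = length(selected) + 1L, kind = "forward",
      chosen = pick, note = "")))
    selected <- c(selected, pick)
  }
  list(selected = selected,
       trace = dplyr::relocate(dplyr::bind_rows(trace), "step", "kind"))
}

#' Backward deletion of dispensable predictors
#'
#' Step 2.  Repeatedly finds the predictor whose leave-one-out CMI with the
#' target, given the remaining predictors, has the largest p-value; if that
#' p-value exceeds `alpha` the predictor is dispensable and is deleted.
#' Stops when every leave-one-out CMI is significant.
#'
#' @inheritParams mi_forward
#' @param selected character vector of currently selected predictors.
#' @return a list with `retained` and `trace`.
#' @export
mi_backward <- function(x, target, selected,
                        config = selection_config()) {
  retained <- selected
  trace <- list()
  while (length(retained)) {
    scores <- purrr::map_dfr(retained, function(f) {
      cmi <- cmi_test(x, f, target, given = setdiff(retained, f))
      tibble::tibble(candidate = f, statistic = cmi$statistic,
                     df = cmi$df, p.value = cmi$p.value,
                     mir = cmi$statistic / cmi$df)
    })
    worst <- scores[order(-scores$p.value, scores$mir,
                          scores$candidate), ][1L, ]
    if (worst$p.value <= config$alpha) {
      trace <- c(trace, list(dplyr::mutate(
        scores, step = length(trace) + 1L, kind = "backward",
        chosen = NA_character_, note = "all leave-one-out CMIs significant")))
      break
    }
    trace <- c(trace, list(dplyr::mutate(
      scores, step = length(trace) + 1L, kind = "backward",
      chosen = worst$candidate, note = "deleted")))
    retained <- setdiff(retained, worst$candidate)
  }
  list(retained = retained,
       trace = if (length(trace))
         dplyr::relocate(dplyr::bind_rows(trace), "step", "kind")
       else tibble::tibble())
}

#' Rearrange the MI identity so outer interactions are least significant
#'
#' Step 3.  Working from the outermost chain position inward, greedily
#' places the predictor whose top-order interaction component (from the
#' Pythagorean split of its CMI term given the others) has the largest
#' p-value.  Returns the chain order (innermost first) together with the
#' full per-term CMI / interaction / partial-association table — the
#' machine analogue of a printed decomposition table.
#'
#' @inheritParams mi_forward
#' @param predictors the final (post-deletion) predictor set.
#' @return a list with `order` (innermost first), `terms` (tibble: per
#'   chain term the CMI and, where defined, Int and Par rows), and
#'   `splits` (list of `pyth_split` objects, outermost first).
#' @export
mi_rearrange <- function(x, target, predictors,
                         config = selection_config()) {
  if (!length(predictors)) stop("`predictors` must be non-empty")
  remaining <- sort(predictors)
  outer_first <- character(0)
  splits <- list()
  while (length(remaining) > 1L) {
    cand <- purrr::map(remaining, function(f)
      pythagorean_split(x, f, target, given = setdiff(remaining, f)))
    p_int <- vapply(cand, function(s)
      s$p.value[s$kind == "interaction"], 0)
    pick <- order(-p_int, remaining)[1L]
    outer_first <- c(outer_first, remaining[pick])
    splits <- c(splits, list(cand[[pick]]))
    remaining <- remaining[-pick]
  }
  ord <- c(remaining, rev(outer_first))  # innermost first
  terms <- dplyr::bind_rows(
    mi_test(x, remaining, target),
    purrr::map_dfr(rev(splits), identity))
  list(order = ord, terms = terms, splits = rev(splits))
}

#' Assemble the final model terms from a rearranged decomposition
#'
#' Step 4.  Every partial-association component significant at `alpha2`
#' is retained as a main effect (as is the innermost predictor when its MI
#' is significant at `alpha`); every interaction component significant at
#' `alpha1` is retained as an interaction among the involved predictors.
#' A retained interaction whose conditioning group is composite may be
#' *replaced* by the set of its single-conditioner sub-interactions when
#' each is significant at `alpha1`, their statistics sum above the original,
#' and their combined df is no larger — the replacement favours several
#' strong low-order effects over one diffuse high-order one.  Disable with
#' `replace_interactions = FALSE` in the config.
#'
#' @param rearranged result of [mi_rearrange()].
#' @inheritParams mi_forward
#' @return an object of class `mi_model_terms`: `target`, `mains`
#'   (character vector), `interactions` (list of character vectors of
#'   predictor names, target implied).
#' @export
mi_build_model <- function(x, target, rearranged,
                           config = selection_config()) {
  a1 <- config$alphas$alpha1
  a2 <- config$alphas$alpha2
  mains <- character(0)
  interactions <- list()
  ord <- rearranged$order
  inner_mi <- rearranged$terms[rearranged$terms$kind == "mi", ][1L, ]
  if (inner_mi$p.value < config$alpha) mains <- ord[1L]
  for (s in rearranged$splits) {
    pred <- s$lhs[1L]
    given <- strsplit(s$given[1L], ",")[[1]]
    if (s$p.value[s$kind == "partial"] < a2)
      mains <- c(mains, pred)
    if (a1 > 0 && s$p.value[s$kind == "interaction"] < a1) {
      term <- sort(c(pred, given))
      repl <- NULL
      if (config$replace_interactions && length(given) >= 2L) {
        subs <- purrr::map(given, function(g)
          pythagorean_split(x, pred, target, given = g))
        sub_stat <- vapply(subs, function(z)
          z$statistic[z$kind == "interaction"], 0)
        sub_p <- vapply(subs, function(z)
          z$p.value[z$kind == "interaction"], 0)
        sub_df <- vapply(subs, function(z)
          z$df[z$kind == "interaction"], 0L)
        ok <- all(sub_p < a1) &&
          sum(sub_stat) > s$statistic[s$kind == "interaction"] &&
          sum(sub_df) <= s$df[s$kind == "interaction"]
        if (ok) repl <- purrr::map(given, function(g) sort(c(pred, g)))
      }
      interactions <- c(interactions, if (is.null(repl)) list(term) else repl)
    }
  }
  if (!length(mains))
    warning("no significant terms retained; the model is empty")
  structure(list(target = target, mains = unique(mains),
                 interactions = unique(interactions)),
            class = "mi_model_terms")
}

#' @export
print.mi_model_terms <- function(x, ...) {
  ints <- if (length(x$interactions)) {
    paste(vapply(x$interactions, paste, "", collapse = "*"), collapse = " + ")
  } else "none"
  cat("MI model for target ", x$target, "\n",
      "  mains:        ", paste(x$mains, collapse = " + "), "\n",
      "  interactions: ", ints, "\n", sep = "")
  invisible(x)
}

#' Full MI selection pipeline
#'
#' Runs forward selection, backward deletion, identity rearrangement, and
#' model construction in sequence.
#'
#' @inheritParams mi_forward
#' @return a list of class `mi_selection`: `selected`, `retained`, `order`,
#'   `terms` (the rearranged Int/Par table), `model` (an `mi_model_terms`),
#'   and `trace` (combined forward/backward trace tibble).
#' @examples
#' \dontrun{
#' g <- german_credit()
#' x <- crosstab(g, A1, A3, A9, A21)
#' mi_select(x, "A21", c("A1", "A3", "A9"))
#' }
#' @export
mi_select <- function(x, target, candidates,
                      config = selection_config()) {
  fwd <- mi_forward(x, target, candidates, config)
  bwd <- mi_backward(x, target, fwd$selected, config)
  trace <- dplyr::bind_rows(fwd$trace, bwd$trace)
  if (!length(bwd$retained)) {
    return(structure(list(selected = fwd$selected, retained = character(0),
                          order = character(0), terms = tibble::tibble(),
                          model = NULL, trace = trace),
                     class = "mi_selection"))
  }
  rearr <- mi_rearrange(x, target, bwd$retained, config)
  model <- mi_build_model(x, target, rearr, config)
  structure(list(selected = fwd$selected, retained = bwd$retained,
                 order = rearr$order, terms = rearr$terms,
                 model = model, trace = trace),
            class = "mi_selection")
}

#' @export
print.mi_selection <- function(x, ...) {
  cat("MI selection: selected {", paste(x$selected, collapse = ", "),
      "} -> retained {", paste(x$retained, collapse = ", "), "}\n", sep = "")
  if (!is.null(x$model)) print(x$model)
  invisible(x)
}

#' @export
tidy.mi_selection <- function(x, ...) x$terms

#' @export
glance.mi_selection <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected),
                 n_retained = length(x$retained),
                 n_mains = if (is.null(x$model)) 0L else length(x$model$mains),
                 n_interactions = if (is.null(x$model)) 0L else
                   length(x$model$interactions))
}

#' @export
autoplot.mi_selection <- function(object, ...) {
  d <- object$terms
  if (!nrow(d)) stop("empty selection; nothing to plot")
  d$label <- sprintf("%s(%s%s)", toupper(substr(d$kind, 1, 3)), d$lhs,
                     ifelse(nzchar(d$given), paste0("|", d$given), ""))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$statistic / .data$df,
                                  y = .data$label,
                                  fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "statistic / df (MIR scale)", y = NULL) +
    ggplot2::theme_minimal()
}
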