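#' Multi-way contingency tables
#'
#' A `contab` is a dense, named count tensor: one axis per categorical factor,
#' axis length equal to the factor's number of levels, with non-negative
#' integer cell counts.  It is the container every estimator in the package
#' operates on.  Plug-in cell probabilities are `counts / N`.
#'
#' @param counts a numeric array (or matrix / vector with names) of
#'   non-negative integral counts.  Must carry complete `dimnames`, with the
#'   names of `dimnames` giving the factor names.
#' @param roles optional named character vector assigning a role
#'   (`"target"`, `"predictor"`) to some factors; purely annotational.
#'
#' @return an object of class `contab`.
#' @examples
#' x <- contab(array(c(20, 10, 10, 20), dim = c(2, 2),
#'                   dimnames = list(X = c("a", "b"), Y = c("u", "v"))))
#' x
#' @export
contab <- function(counts, roles = NULL) {
  if (is.null(dim(counts))) {
    counts <- array(counts, dim = length(counts),
                    dimnames = list(names(counts)))
  }
  dn <- dimnames(counts)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1))))
    stop("`counts` must have complete dimnames (levels for every axis)")
  if (is.null(names(dn)) || any(!nzchar(names(dn))))
    stop("every axis of `counts` must be named after its factor")
  if (anyDuplicated(names(dn)))
    stop("factor names must be unique")
  for (f in names(dn)) {
    if (length(dn[[f]]) < 1L) stop("factor '", f, "' has no levels")
    if (anyDuplicated(dn[[f]]))
      stop("levels of factor '", f, "' are not unique")
  }
  if (any(counts < 0)) stop("cell counts must be non-negative")
  if (max(abs(counts - round(counts))) > 1e-8)
    stop("cell counts must be integral")
  storage.mode(counts) <- "double"
  structure(list(counts = counts, N = sum(counts), roles = roles),
            class = "contab")
}

#' @export
print.contab <- function(x, ...) {
  cat("<contab> ", paste(ct_factors(x), collapse = " x "),
      "  (", paste(dim(x$counts), collapse = "x"), " cells, N = ",
      format(x$N), ")\n", sep = "")
  print(x$counts, ...)
  invisible(x)
}

#' @export
dim.contab <- function(x) dim(x$counts)

# factor names / level sets of a contab
#' @rdname contab
#' @param x a `contab`.
#' @export
ct_factors <- function(x) names(dimnames(x$counts))

#' @rdname contab
#' @export
ct_levels <- function(x) dimnames(x$counts)

#' @export
as_tibble.contab <- function(x, ...) {
  df <- as.data.frame.table(x$counts, responseName = "n",
                            stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

.ct_check_factors <- function(x, nms, arg = "factors") {
  missing <- setdiff(nms, ct_factors(x))
  if (length(missing))
    stop("unknown ", arg, ": ", paste(missing, collapse = ", "))
}

#' Cross-tabulate case-level records
#'
#' Builds a [contab] by tallying exact co-occurrence frequencies of the chosen
#' columns of a data frame, one row per subject.  Level order is order of
#' first appearance in the data unless pre-declared through `levels`, so that
#' degrees of freedom and dummy coding are reproducible run-to-run.
#'
#' Missing values are an error, never a silent extra level: an `NA` in a
#' tabulated column would otherwise corrupt every downstream df computation.
#'
#' @param data a data frame of case-level records.
#' @param ... tidy-select style columns to tabulate (bare names or strings).
#' @param levels optional named list pre-declaring the level order of some
#'   factors (levels observed in the data but absent from the declaration
#'   are an error; declared-but-unobserved levels are kept with zero count).
#' @param roles passed on to [contab()].
#' @return a [contab] with `N = nrow(data)`.
#' @examples
#' d <- data.frame(F1 = c("a", "a", "b", "b"), F2 = c("x", "x", "x", "y"))
#' crosstab(d, F1, F2)
#' @export
crosstab <- function(data, ..., levels = NULL, roles = NULL) {
  sel <- names(tidyselect_cols(data, ...))
  if (!length(sel)) stop("no factor columns selected")
  if (!nrow(data)) stop("empty record set")
  cols <- lapply(sel, function(f) {
    v <- data[[f]]
    if (anyNA(v)) {
      stop("missing value in column '", f, "' at row ",
           which(is.na(v))[1L])
    }
    v <- as.character(v)
    lv <- if (!is.null(levels) && f %in% names(levels)) {
      extra <- setdiff(unique(v), levels[[f]])
      if (length(extra))
        stop("column '", f, "' contains undeclared levels: ",
             paste(extra, collapse = ", "))
      as.character(levels[[f]])
    } else unique(v)
    factor(v, levels = lv)
  })
  names(cols) <- sel
  counts <- table(cols)
  counts <- array(as.numeric(counts), dim = dim(counts),
                  dimnames = stats::setNames(dimnames(counts), sel))
  contab(counts, roles = roles)
}

# resolve `...` column selections against a data frame; returns named list
tidyselect_cols <- function(data, ...) {
  pos <- tryCatch(
    tidyselect::eval_select(rlang::expr(c(...)), data = data),
    error = function(e) stop(conditionMessage(e), call. = FALSE))
  as.list(stats::setNames(names(data)[pos], names(data)[pos]))
}

#' Marginalize a contingency table
#'
#' Sums the count tensor over all axes not listed in `keep`; the total count
#' `N` is preserved.
#'
#' @param x a [contab].
#' @param keep character vector of factor names to retain (result axis order
#'   follows `keep`).
#' @return a [contab] over the `keep` factors.
#' @export
marginalize <- function(x, keep) {
  if (!length(keep)) stop("`keep` must name at least one factor")
  .ct_check_factors(x, keep, "factor in `keep`")
  idx <- match(keep, ct_factors(x))
  if (length(idx) == length(dim(x$counts)) && all(idx == seq_along(idx)))
    return(x)
  m <- apply(x$counts, idx, sum)
  if (length(idx) == 1L) {
    m <- array(m, dim = length(m),
               dimnames = stats::setNames(list(names(m)), keep))
  }
  contab(m, roles = x$roles[names(x$roles) %in% keep])
}

#' Compound several factors into one composite factor
#'
#' Replaces the factors in `merge` by a single factor whose levels are the
#' Cartesian tuples of the original levels — all combinations, including
#' those never observed, so that nominal level counts (and hence degrees of
#' freedom) are preserved.  Counts are preserved cell-by-cell; the operation
#' is a pure reshape and is information-preserving for every MI statistic.
#'
#' @param x a [contab].
#' @param merge character vector (length >= 2) of factors to merge.
#' @param new_name name of the composite factor; defaults to the merged
#'   names joined by `:`.
#' @return a [contab] with the composite factor as its last axis.
#' @export
compound <- function(x, merge, new_name = paste(merge, collapse = ":")) {
  if (length(merge) < 2L) stop("`merge` must contain at least two factors")
  .ct_check_factors(x, merge, "factor in `merge`")
  rest <- setdiff(ct_factors(x), merge)
  if (new_name %in% rest)
    stop("`new_name` ('", new_name, "') clashes with an existing factor")
  perm <- match(c(rest, merge), ct_factors(x))
  a <- aperm(x$counts, perm)
  dn <- dimnames(a)
  merge_lv <- dn[(length(rest) + 1L):length(dn)]
  # expand.grid varies the first factor fastest, matching column-major
  # linearization of the trailing axes
  comp_lv <- do.call(paste, c(expand.grid(merge_lv, stringsAsFactors = FALSE),
                              sep = ":"))
  newdim <- c(dim(a)[seq_along(rest)], length(comp_lv))
  newdn <- c(dn[seq_along(rest)], stats::setNames(list(comp_lv), new_name))
  if (!length(rest)) {
    newdim <- length(comp_lv)
    newdn <- stats::setNames(list(comp_lv), new_name)
  }
  contab(array(as.vector(a), dim = newdim, dimnames = newdn))
}

#' Discretize a numeric column into ordered categorical levels
#'
#' Bins are right-closed: value `v` falls in bin `b` when
#' `cutpoints[b-1] < v <= cutpoints[b]`, with implicit infinite end bins.
#'
#' @param values numeric vector.
#' @param cutpoints strictly increasing numeric breakpoints.
#' @param labels level labels, one more than there are cutpoints.
#' @return a factor with levels `labels`.
#' @examples
#' discretize(c(6, 12, 13, 30), c(12, 24), c("L1", "L2", "L3"))
#' @export
discretize <- function(values, cutpoints, labels) {
  if (!is.numeric(values)) stop("`values` must be numeric")
  if (length(cutpoints) && is.unsorted(cutpoints, strictly = TRUE))
    stop("`cutpoints` must be strictly increasing")
  if (length(labels) != length(cutpoints) + 1L)
    stop("need exactly length(cutpoints) + 1 labels")
  cut(values, breaks = c(-Inf, cutpoints, Inf), labels = labels,
      right = TRUE)
}

#' Read / write the plain-text contingency-table format
#'
#' A self-describing sparse text format: one `factor <name> <levels...>` line
#' per axis (declaring nominal level order), then one
#' `cell <level-tuple...> <count>` line per non-zero cell.
#'
#' @param x a [contab].
#' @param path file path.
#' @return `write_contab()` returns `x` invisibly; `read_contab()` a [contab].
#' @export
write_contab <- function(x, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# contab v1", con)
  dn <- ct_levels(x)
  for (f in names(dn))
    writeLines(paste("factor", f, paste(dn[[f]], collapse = " ")), con)
  tb <- as_tibble(x)
  tb <- tb[tb$n > 0, , drop = FALSE]
  apply(tb, 1L, function(r) {
    writeLines(paste("cell", paste(r[-length(r)], collapse = " "),
                     as.numeric(r[length(r)])), con)
  })
  invisible(x)
}

#' @rdname write_contab
#' @export
read_contab <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  fac <- toks[vapply(toks, `[[`, "", 1L) == "factor"]
  cel <- toks[vapply(toks, `[[`, "", 1L) == "cell"]
  if (!length(fac)) stop("no factor declarations in '", path, "'")
  dn <- stats::setNames(lapply(fac, function(t) t[-(1:2)]),
                        vapply(fac, `[[`, "", 2L))
  counts <- array(0, dim = unname(lengths(dn)), dimnames = dn)
  for (t in cel) {
    lv <- t[2:(1 + length(dn))]
    counts[matrix(mapply(match, lv, dn), nrow = 1L)] <-
      as.numeric(t[length(t)])
  }
  contab(counts)
}
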