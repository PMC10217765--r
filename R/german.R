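#' The Statlog German banking-credit records, in original attribute coding
#'
#' Reconstructs the 1000-row Statlog (German credit) case-level records of
#' the UCI Machine Learning Repository from the one-hot encoded copy
#' shipped in the `caret` package, restoring the original categorical
#' attribute codes (`A11`..`A14` for attribute 1, and so on).  The target
#' `A21` is the binary creditability, coded `1` (creditworthy) / `2` (not
#' creditworthy).  Numerical attributes (duration `A2`, credit amount `A5`,
#' age `A13`) are returned as numeric columns for discretization with
#' [discretize()]; the small ordinal attributes A8, A11, A16 and A18 are
#' returned as factors over their integer codes.
#'
#' @return a 1000-row tibble with columns `A1`..`A20` and the target `A21`;
#'   categorical columns are factors with the full declared level set.
#' @examples
#' \dontrun{
#' g <- german_credit()
#' mi_test(crosstab(g, A1, A21), "A1", "A21")
#' }
#' @export
german_credit <- function() {
  if (!requireNamespace("caret", quietly = TRUE))
    stop("the 'caret' package (which ships the one-hot encoded Statlog ",
         "records) is required for german_credit()")
  e <- new.env()
  utils::data("GermanCredit", package = "caret", envir = e)
  g <- e$GermanCredit

  # codes are given in caret column order; lev declares the code order
  onehot <- function(cols, codes, lev = codes) {
    m <- as.matrix(g[, cols])
    stopifnot(all(rowSums(m) == 1))
    factor(codes[max.col(m)], levels = lev)
  }
  pick <- function(prefix) grep(paste0("^", prefix, "\\."), names(g),
                                value = TRUE)
  ordf <- function(v) factor(v, levels = sort(unique(v)))

  tibble::tibble(
    A1  = onehot(pick("CheckingAccountStatus"), paste0("A1", 1:4)),
    A2  = g$Duration,
    A3  = onehot(pick("CreditHistory"), paste0("A3", 0:4)),
    A4  = onehot(pick("Purpose"),
                 paste0("A4", c(0:9, 10))),
    A5  = g$Amount,
    A6  = onehot(pick("SavingsAccountBonds"), paste0("A6", 1:5)),
    # caret orders employment as (<1, 1-4, 4-7, >=7, unemployed)
    A7  = onehot(pick("EmploymentDuration"),
                 paste0("A7", c(2, 3, 4, 5, 1)), paste0("A7", 1:5)),
    A8  = ordf(g$InstallmentRatePercentage),
    A9  = onehot(pick("Personal"), paste0("A9", 1:5)),
    A10 = onehot(pick("OtherDebtorsGuarantors"), paste0("A10", 1:3)),
    A11 = ordf(g$ResidenceDuration),
    A12 = onehot(pick("Property"), paste0("A12", 1:4)),
    A13 = g$Age,
    A14 = onehot(pick("OtherInstallmentPlans"), paste0("A14", 1:3)),
    A15 = onehot(pick("Housing"), paste0("A15", 1:3)),
    A16 = ordf(g$NumberExistingCredits),
    A17 = onehot(pick("Job"), paste0("A17", 1:4)),
    A18 = ordf(g$NumberPeopleMaintenance),
    A19 = factor(ifelse(g$Telephone == 1, "A191", "A192"),
                 levels = c("A191", "A192")),
    A20 = factor(ifelse(g$ForeignWorker == 1, "A201", "A202"),
                 levels = c("A201", "A202")),
    A21 = factor(ifelse(g$Class == "Good", "1", "2"), levels = c("1", "2"))
  )
}
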