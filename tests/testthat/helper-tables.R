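# shared fixtures: all built in code, seeded

# a random contab: `nlev` levels per factor (vector), counts multinomial
# from a Dirichlet-like random probability tensor
rand_contab <- function(nlev, n, seed, names = paste0("F", seq_along(nlev))) {
  withr::with_seed(seed, {
    p <- stats::rgamma(prod(nlev), shape = 1)
    p <- p / sum(p)
    dn <- stats::setNames(
      lapply(nlev, function(k) paste0("l", seq_len(k))), names)
    counts <- stats::rmultinom(1, n, p)
    contab(array(as.vector(counts), dim = nlev, dimnames = dn))
  })
}

# a product (exact independence) 2-way table from given margins
product_contab <- function(row, col, names = c("X", "Y")) {
  counts <- outer(row, col)
  dn <- stats::setNames(list(paste0("r", seq_along(row)),
                             paste0("c", seq_along(col))), names)
  contab(array(counts, dim = dim(counts), dimnames = dn))
}

# probability tensor with X independent of Y within every level of Z,
# but X and Y both associated with Z (so only the conditional null holds)
condindep_probs <- function() {
  pz <- c(0.4, 0.6)
  px_z <- rbind(c(0.3, 0.7), c(0.6, 0.4))   # P(X | Z = k) by row
  py_z <- rbind(c(0.5, 0.5), c(0.2, 0.8))
  p <- array(0, c(2, 2, 2),
             dimnames = list(X = c("x1", "x2"), Y = c("y1", "y2"),
                             Z = c("z1", "z2")))
  for (k in 1:2) p[, , k] <- pz[k] * outer(px_z[k, ], py_z[k, ])
  p
}

# hand-built pyth_split rows, for testing the two-step decision rule alone
fake_split <- function(cmi, df_cmi, int, df_int, par, df_par) {
  rows <- dplyr::bind_rows(
    midecomp:::.info_row("cmi", "X", "Y", "Z", cmi, df_cmi),
    midecomp:::.info_row("interaction", "X", "Y", "Z", int, df_int),
    midecomp:::.info_row("partial", "X", "Y", "Z", par, df_par))
  structure(rows, class = c("pyth_split", class(rows)))
}
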