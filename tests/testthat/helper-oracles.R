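# Independent oracles operating on plain data frames (states + p), written
# against base R only so they share no code path with the package internals.

# pasted state key for alignment
.okey <- function(df, vars) {
  do.call(paste, c(unname(as.list(df[vars])), sep = "|"))
}

oracle_entropy <- function(df) {
  p <- df$p[df$p > 0]
  -sum(p * log2(p))
}

oracle_marginal <- function(df, vars) {
  agg <- stats::aggregate(df["p"], by = df[vars], FUN = sum)
  agg[agg$p > 0, , drop = FALSE]
}

# direct-sum KL (the defining formula), aligning states by key
oracle_kl <- function(dfP, dfQ, vars) {
  q <- dfQ$p[match(.okey(dfP, vars), .okey(dfQ, vars))]
  stopifnot(!anyNA(q), all(q > 0))
  sum(dfP$p * log2(dfP$p / q))
}

oracle_mutual_information <- function(df, a_vars, b_vars) {
  oracle_entropy(oracle_marginal(df, a_vars)) +
    oracle_entropy(oracle_marginal(df, b_vars)) -
    oracle_entropy(oracle_marginal(df, c(a_vars, b_vars)))
}

# fixed seeded panel of random distributions used by the property suites
random_panel <- function(n_vars, n_dists, first_seed = 100L,
                         alphabet_size = 2L, concentration = 1) {
  lapply(seq_len(n_dists), function(i) {
    random_dist(n_vars, alphabet_size, seed = first_seed + i,
                concentration = concentration)
  })
}

# bits of an atom table keyed by canonical atom label
atom_bits <- function(tab, label) {
  stopifnot(label %in% tab$atom)
  tab$bits[match(label, tab$atom)]
}

expect_atoms_equal <- function(tab, expected, tol = 1e-9) {
  expect_equal(nrow(tab), length(expected))
  for (lab in names(expected)) {
    expect_equal(atom_bits(tab, lab), expected[[lab]], tolerance = tol,
                 ignore_attr = TRUE)
  }
}
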