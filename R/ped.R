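# Partial entropy decomposition -----------------------------------------------
#
# The local entropy h(x) = -log2 P(x) of a realization is split over the
# redundancy lattice: a redundancy function assigns each atom the entropy
# shared by all of its sources, and Moebius inversion turns those cumulative
# values into per-atom partials that sum back to h(x). Expected atoms are the
# P-weighted average of the local tables (decompose locally, then average).

#' Minimum-surprisal redundancy function
#'
#' The reference redundancy function shipped with the package:
#' \eqn{h_{min}(x, \alpha) = \min_i h(a_i)}, the smallest local surprisal
#' among the antichain's source projections. It is localizable, symmetric in
#' its sources, and induces non-negative local partial entropy atoms.
#'
#' Alternative redundancy functions can be supplied wherever an `rf` argument
#' appears: any function with signature `(P, x, alpha)` returning redundant
#' entropy in bits, where `alpha` is a list of integer index vectors. (The
#' co-information-based redundancy is deliberately not shipped: it can return
#' negative local atoms, which breaks the surprisal interpretation of the
#' divergence decomposition.)
#'
#' @param P A `joint_dist`.
#' @param x A full realization (character vector, one symbol per variable).
#' @param alpha An atom: list of integer vectors of variable indices (a bare
#'   integer vector is treated as a single source).
#' @return Redundant entropy in bits.
#' @examples
#' u <- uniform_dist(3)
#' h_min(u, c("0", "0", "0"), list(1L, 2L, 3L))  # 1 bit
#' @export
h_min <- function(P, x, alpha) {
  if (!is.list(alpha)) alpha <- list(alpha)
  min(vapply(alpha, function(src) local_surprisal(P, x, src), numeric(1)))
}

# all distinct sources used by a lattice, as list of index vectors
lattice_sources <- function(lattice) {
  n <- lattice$n
  lapply(seq_len(2L^n - 1L), function(mask) {
    which(bitwAnd(mask, 2L^(seq_len(n) - 1L)) > 0L)
  })
}

# Surprisal matrix: rows = states of `at`, columns = every non-empty source
# of P's variables, entries -log2 of the source projection's marginal
# probability *under P*. Infinite entries mark zero-probability projections.
surprisal_matrix <- function(P, at, sources) {
  out <- matrix(NA_real_, nrow(at), length(sources))
  for (k in seq_along(sources)) {
    idx <- sources[[k]]
    key <- state_keys(P, idx)
    marg <- rowsum(P$p, group = key, reorder = FALSE)
    pr <- marg[match(state_keys(at, idx), rownames(marg)), 1L]
    pr[is.na(pr)] <- 0
    out[, k] <- -log2(pr)
  }
  out
}

# Cumulative h_min values for every lattice atom at every state of `at`,
# evaluated under distribution P. Generic redundancy functions fall back to a
# per-state, per-atom loop.
ped_cumulative <- function(P, lattice, at = P, rf = h_min) {
  if (identical(rf, h_min)) {
    sources <- lattice_sources(lattice)
    surp <- surprisal_matrix(P, at, sources)
    if (any(!is.finite(surp))) {
      bad <- which(!is.finite(surp), arr.ind = TRUE)[1L, ]
      abort_support(sprintf(
        "State (%s) projects onto a zero-probability marginal of (%s).",
        paste(unlist(at[bad[1L], var_names(P)]), collapse = ","),
        paste(var_names(P)[sources[[bad[2L]]]], collapse = ",")
      ))
    }
    src_mask <- vapply(sources, function(s) sum(2L^(s - 1L)), numeric(1))
    atom_cols <- lapply(lattice$atoms, function(atom) {
      match(vapply(atom, function(s) sum(2L^(s - 1L)), numeric(1)), src_mask)
    })
    cum <- vapply(atom_cols, function(cols) {
      if (length(cols) == 1L) surp[, cols] else
        do.call(pmin, lapply(cols, function(cc) surp[, cc]))
    }, numeric(nrow(at)))
    if (nrow(at) == 1L) cum <- matrix(cum, nrow = 1L)
    return(cum)
  }
  vars <- var_names(P)
  cum <- matrix(NA_real_, nrow(at), length(lattice$atoms))
  for (s in seq_len(nrow(at))) {
    x <- stats::setNames(as.character(unlist(at[s, vars])), vars)
    for (j in seq_along(lattice$atoms)) {
      cum[s, j] <- rf(P, x, lattice$atoms[[j]])
    }
  }
  cum
}

#' Local partial entropy decomposition
#'
#' Decomposes the local entropy \eqn{h(x) = -\log_2 P(x)} of one realization
#' into redundancy-lattice atoms under the redundancy function `rf`. The atom
#' values sum to `h(x)`.
#'
#' @param P A `joint_dist` over at most 4 variables.
#' @param x A realization in the support of `P`.
#' @param rf Redundancy function; defaults to [h_min()].
#' @return An `atom_table`.
#' @examples
#' xor <- logic_gate("XOR")
#' local_ped(xor, c("0", "0", "0"))
#' @export
local_ped <- function(P, x, rf = h_min) {
  x <- realization(P, x)
  if (marginal_prob(P, seq_len(n_vars(P)), x) <= 0) {
    abort_support(sprintf("Realization (%s) is outside the support of P.",
                          paste(x, collapse = ",")))
  }
  lattice <- get_lattice(n_vars(P))
  at <- as_tibble(as.list(x))
  cum <- ped_cumulative(P, lattice, at, rf)
  part <- mobius_rows(lattice, cum)
  new_atom_table(part[1L, ], lattice, var_names = var_names(P),
                 measure = "local entropy")
}

#' Expected partial entropy decomposition
#'
#' The probability-weighted average of the local decompositions over the
#' support of `P`. Atom values sum to the Shannon entropy `H(P)`.
#'
#' @inheritParams local_ped
#' @return An `atom_table` whose `bits` sum to [shannon_entropy()] of `P`.
#' @examples
#' expected_ped(logic_gate("XOR"))
#' @export
expected_ped <- function(P, rf = h_min) {
  lattice <- get_lattice(n_vars(P))
  cum <- ped_cumulative(P, lattice, P, rf)
  part <- mobius_rows(lattice, cum)
  new_atom_table(colSums(P$p * part), lattice, var_names = var_names(P),
                 measure = "entropy")
}
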