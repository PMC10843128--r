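# Derived decompositions ------------------------------------------------------
#
# Any information measure expressible as a KL divergence inherits an atomic
# decomposition from the GID by fixing the prior: the product of marginals
# gives the total correlation, the uniform distribution over the declared
# alphabets gives the negentropy, and conditional-vs-marginal priors recover
# the classic single-target PID. The O-information and TSE complexity are
# linear combinations of total correlations, so they expand into fixed linear
# combinations of partial-TC atoms (coefficients known for three variables).

#' Total correlation of a joint distribution
#'
#' \eqn{TC(X) = D(P(X) \| \prod_i P(X_i))}: the divergence of the joint from
#' the independent product of its marginals, i.e. the total deviation from
#' independence, in bits.
#'
#' @param P A `joint_dist`.
#' @return Non-negative scalar, bits.
#' @export
total_correlation <- function(P) {
  if (n_vars(P) < 2L) return(0)
  kl_divergence(P, product_of_marginals(P))
}

#' Atomic decomposition of the total correlation
#'
#' Runs the generalized information decomposition with the product of
#' marginals as the prior. Atom values sum to [total_correlation()]. Because
#' the prior preserves every single-variable marginal, the bottom of the
#' lattice (and every atom built only from singleton sources) carries no
#' partial total correlation; deviation from independence lives in atoms with
#' multi-variable sources.
#'
#' @param P A `joint_dist` (2-4 variables).
#' @param rf Redundancy function; defaults to [h_min()].
#' @return An `atom_table`.
#' @examples
#' tc_decomposition(logic_gate("XOR"))  # one synergistic bit in {X1,X2,T}
#' @export
tc_decomposition <- function(P, rf = h_min) {
  out <- gid(P, product_of_marginals(P), rf)
  attr(out, "measure") <- "total correlation"
  out
}

#' Atomic decomposition of the negentropy
#'
#' Runs the generalized information decomposition against the uniform
#' distribution over the full Cartesian product of the declared alphabets.
#' Atom values sum to \eqn{\sum_i \log_2 |A_i| - H(P)}, the distance from
#' maximum entropy.
#'
#' @inheritParams tc_decomposition
#' @return An `atom_table`.
#' @export
negentropy_decomposition <- function(P, rf = h_min) {
  out <- gid(P, uniform_prior(P), rf)
  attr(out, "measure") <- "negentropy"
  out
}

# total correlation of a marginal, from precomputed marginal entropies
subset_tc <- function(P, idx) {
  if (length(idx) < 2L) return(0)
  sum(vapply(idx, function(i) shannon_entropy(marginalize(P, i)), numeric(1))) -
    shannon_entropy(marginalize(P, idx))
}

#' O-information of a joint distribution
#'
#' \eqn{\Omega(X) = (2 - N)\,TC(X) + \sum_i TC(X^{-i})}: a signed summary of
#' whether the system's higher-order structure is redundancy-dominated
#' (positive) or synergy-dominated (negative), written purely in terms of
#' total correlations of the whole and of the leave-one-out subsystems.
#'
#' @param P A `joint_dist` over at least 3 variables.
#' @return Signed scalar, bits.
#' @examples
#' o_information(logic_gate("XOR"))  # -1: pure synergy
#' o_information(giant_bit(3))       # +1: pure redundancy
#' @export
o_information <- function(P) {
  n <- n_vars(P)
  if (n < 3L) abort_invalid("The O-information needs at least 3 variables.")
  loo <- vapply(seq_len(n), function(i) subset_tc(P, setdiff(seq_len(n), i)),
                numeric(1))
  (2 - n) * total_correlation(P) + sum(loo)
}

#' Tononi-Sporns-Edelman complexity
#'
#' \eqn{TSE(X) = \sum_{i=1}^{N} [\tfrac{i}{N} TC(X) - \langle TC(X^{(i)})
#' \rangle]}, where the bracket averages the total correlation over all
#' subsets of size `i`. High TSE marks systems whose small subsets look
#' independent while the whole is strongly integrated. The total correlation
#' of a single variable is taken as 0 (a one-element system cannot deviate
#' from independence), fixing the size-1 average.
#'
#' @param P A `joint_dist` over at least 2 variables.
#' @return Non-negative scalar, bits.
#' @export
tse_complexity <- function(P) {
  n <- n_vars(P)
  if (n < 2L) abort_invalid("TSE complexity needs at least 2 variables.")
  tc_full <- total_correlation(P)
  sum(vapply(seq_len(n), function(i) {
    subs <- utils::combn(n, i, simplify = FALSE)
    avg <- mean(vapply(subs, function(s) subset_tc(P, s), numeric(1)))
    (i / n) * tc_full - avg
  }, numeric(1)))
}

# Coefficients of the 3-variable atom expansions, classified structurally by
# the multiset of source cardinalities (unambiguous at n = 3).
atom_class_n3 <- function(atom) {
  paste(sort(lengths(atom)), collapse = "")
}

.o_coef_n3 <- c(
  "111" = 2,  # {1}{2}{3}
  "11"  = 2,  # {i}{j}
  "12"  = 2,  # {i}{jk}
  "1"   = 1,  # {i}
  "222" = 2,  # {12}{13}{23}
  "22"  = 1,  # {ij}{ik}
  "2"   = 0,  # {ij}  (bivariate atoms never contribute)
  "3"   = -1  # {123}
)

.tse_coef_n3 <- c(
  "111" = -1,
  "11"  = -2 / 3,
  "12"  = -1 / 3,
  "1"   = 0,
  "222" = 0,
  "22"  = 1 / 3,
  "2"   = 2 / 3,
  "3"   = 1
)

check_n3_atoms <- function(tc_atoms) {
  lattice <- attr(tc_atoms, "lattice")
  if (is.null(lattice) || lattice$n != 3L || nrow(tc_atoms) != 18L) {
    abort_invalid("Expected an 18-atom table from a 3-variable decomposition.")
  }
  lattice
}

#' O-information and TSE complexity from partial-TC atoms
#'
#' Evaluate the fixed linear combinations that express the O-information and
#' the TSE complexity of a three-variable system in terms of its 18 partial
#' total-correlation atoms. `o_information_from_atoms()` uses coefficients
#' (2, 2, 2, 1, 2, 1, 0, -1) down the lattice levels — bivariate atoms
#' `{Xi,Xj}` drop out, reflecting the measure's insensitivity to pairwise
#' structure, and only the top synergy atom counts negatively.
#' `tse_from_atoms()` uses (-1, -2/3, -1/3, 0, 0, +1/3, +2/3, +1):
#' redundancy low in the lattice is penalized in 1/N steps while atoms near
#' the top are increasingly rewarded.
#'
#' @param tc_atoms An `atom_table` from [tc_decomposition()] of a 3-variable
#'   distribution.
#' @return Scalar, bits; matches [o_information()] / [tse_complexity()] of
#'   the decomposed distribution.
#' @export
o_information_from_atoms <- function(tc_atoms) {
  lattice <- check_n3_atoms(tc_atoms)
  cls <- vapply(lattice$atoms, atom_class_n3, character(1))
  sum(.o_coef_n3[cls] * tc_atoms$bits)
}

#' @rdname o_information_from_atoms
#' @export
tse_from_atoms <- function(tc_atoms) {
  lattice <- check_n3_atoms(tc_atoms)
  cls <- vapply(lattice$atoms, atom_class_n3, character(1))
  sum(.tse_coef_n3[cls] * tc_atoms$bits)
}

#' Single-target partial information decomposition
#'
#' Recovers the classic PID of \eqn{I(inputs; T)} from the generalized
#' decomposition via \eqn{I = E_T[D(P(inputs \mid T = t) \| P(inputs))]}: for
#' every target value `t`, the divergence from the input marginal (prior) to
#' the conditional (posterior) is decomposed on the input lattice, and the
#' atom tables averaged under `P(t)`. With [h_min()] this reproduces the
#' pointwise informative/misinformative decomposition; atoms may therefore be
#' negative. Atom values sum to the mutual information, and for two inputs
#' the consistency constraints hold: redundancy plus unique-`Xi` equals
#' \eqn{I(X_i; T)}.
#'
#' @param P A `joint_dist` over the inputs and the target.
#' @param target Name or index of the target variable.
#' @param rf Redundancy function; defaults to [h_min()].
#' @return An `atom_table` over the input-variable lattice (4 atoms for two
#'   inputs: redundancy `{X1}{X2}`, unique `{X1}`, unique `{X2}`, synergy
#'   `{X1,X2}`).
#' @examples
#' pid_single_target(logic_gate("XOR"), "T")  # all mutual information synergistic
#' @export
pid_single_target <- function(P, target, rf = h_min) {
  t_idx <- resolve_vars(P, target)
  if (length(t_idx) != 1L) abort_invalid("Exactly one target variable.")
  in_idx <- setdiff(seq_len(n_vars(P)), t_idx)
  if (length(in_idx) < 1L || length(in_idx) > 3L) {
    abort_invalid("The PID here supports 1-3 input variables.")
  }
  prior <- marginalize(P, in_idx)
  t_marg <- marginalize(P, t_idx)
  lattice <- get_lattice(length(in_idx))
  bits <- numeric(length(lattice$atoms))
  for (r in seq_len(nrow(t_marg))) {
    post <- condition_on(P, t_idx, t_marg[[1L]][r])
    bits <- bits + t_marg$p[r] * gid(post, prior, rf)$bits
  }
  new_atom_table(bits, lattice, var_names = var_names(P)[in_idx],
                 measure = "mutual information (single-target PID)")
}

#' Joint (18-atom) decomposition of a single-target mutual information
#'
#' The same mutual information \eqn{I(inputs; T)} can be written as
#' \eqn{D(P(inputs, T) \| P(inputs) \times P(T))} and decomposed on the full
#' lattice of all variables (18 atoms for two inputs plus a target). The
#' atoms still sum to the mutual information, but the assignment of
#' information to variable combinations differs from
#' [pid_single_target()], and no linear bridge between the two tables is
#' known.
#'
#' @inheritParams pid_single_target
#' @return An `atom_table` over the full lattice.
#' @export
mi_joint_decomposition <- function(P, target, rf = h_min) {
  t_idx <- resolve_vars(P, target)
  if (length(t_idx) != 1L) abort_invalid("Exactly one target variable.")
  in_idx <- setdiff(seq_len(n_vars(P)), t_idx)
  p_in <- marginalize(P, in_idx)
  p_t <- marginalize(P, t_idx)
  vars <- var_names(P)
  rows_in <- as.data.frame(p_in)[rep(seq_len(nrow(p_in)), each = nrow(p_t)),
                                 var_names(p_in), drop = FALSE]
  rows_t <- as.data.frame(p_t)[rep(seq_len(nrow(p_t)), times = nrow(p_in)),
                               var_names(p_t), drop = FALSE]
  q <- cbind(rows_in, rows_t)[, vars, drop = FALSE]
  q$p <- rep(p_in$p, each = nrow(p_t)) * rep(p_t$p, times = nrow(p_in))
  Q <- joint_dist(q, alphabets = alphabets(P))
  out <- gid(P, Q, rf)
  attr(out, "measure") <- "mutual information (joint decomposition)"
  out
}
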