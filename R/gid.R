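# Generalized information decomposition ---------------------------------------
#
# The divergence D(P||Q) = E_P[h_Q(x) - h_P(x)] measures the information
# gained when updating a prior Q to a posterior P. Both local entropies admit
# a partial entropy decomposition, so the divergence itself splits atomwise:
# each atom is the P-expectation of the difference between the prior and
# posterior local partial entropy atoms. Individual atoms may be negative
# (information "lost" in the update); only their total is guaranteed
# non-negative.

# shared preparation: align spaces/support, return the pair plus the
# posterior- and prior-side partial matrices evaluated at supp(P)
gid_parts <- function(P, Q, rf, policy, epsilon) {
  aligned <- apply_support_policy(P, Q, policy, epsilon)
  P <- aligned$P
  Q <- aligned$Q
  lattice <- get_lattice(n_vars(P))
  cum_p <- ped_cumulative(P, lattice, P, rf)
  cum_q <- ped_cumulative(Q, lattice, P, rf)
  list(
    P = P, Q = Q, lattice = lattice,
    part_p = mobius_rows(lattice, cum_p),
    part_q = mobius_rows(lattice, cum_q)
  )
}

#' Local decomposition of an information gain
#'
#' For a single realization `x`, decomposes the log-likelihood ratio
#' \eqn{\log_2 P(x)/Q(x)} into lattice atoms as the difference between the
#' local partial entropy atoms computed under the prior `Q` and under the
#' posterior `P`. Atom values sum to \eqn{h_Q(x) - h_P(x)} and may be
#' negative.
#'
#' @param P,Q Posterior and prior `joint_dist` objects over the same
#'   variables and alphabets.
#' @param x A realization in the support of both (after the policy).
#' @param rf Redundancy function; defaults to [h_min()].
#' @inheritParams apply_support_policy
#' @return An `atom_table`.
#' @export
local_gid <- function(P, Q, x, rf = h_min,
                      policy = c("strict", "pseudocount", "restrict"),
                      epsilon = 1e-6) {
  aligned <- apply_support_policy(P, Q, policy, epsilon)
  ped_q <- local_ped(aligned$Q, x, rf)
  ped_p <- local_ped(aligned$P, x, rf)
  new_atom_table(ped_q$bits - ped_p$bits, attr(ped_p, "lattice"),
                 var_names = var_names(P), measure = "local information gain")
}

#' Generalized information decomposition of a Kullback-Leibler divergence
#'
#' Decomposes \eqn{D(P \| Q)} — the information gained when updating from the
#' prior `Q` to the posterior `P` — into redundancy-lattice atoms: each atom
#' is the expectation, under `P`, of the difference between the prior-side
#' and posterior-side local partial entropy atoms. The atoms sum to
#' [kl_divergence()]`(P, Q)`; individual atoms may be negative.
#'
#' Expectation weights come exclusively from `P` over its support; prior
#' states outside `supp(P)` contribute nothing.
#'
#' @inheritParams local_gid
#' @return An `atom_table` whose `bits` sum to the divergence.
#' @examples
#' xor <- logic_gate("XOR")
#' gid(xor, product_of_marginals(xor))  # 1 bit, all in the top atom
#' @export
gid <- function(P, Q, rf = h_min,
                policy = c("strict", "pseudocount", "restrict"),
                epsilon = 1e-6) {
  parts <- gid_parts(P, Q, rf, policy, epsilon)
  bits <- colSums(parts$P$p * (parts$part_q - parts$part_p))
  new_atom_table(bits, parts$lattice, var_names = var_names(P),
                 measure = "information gain (KL)")
}

#' Decomposition of the cross entropy
#'
#' The cross entropy \eqn{H_{P\|Q} = E_P[-\log_2 Q(x)]} is decomposed by
#' running the local partial entropy decomposition under `Q` and aggregating
#' the local tables with the weights of `P`. Atom values sum to the cross
#' entropy; subtracting [expected_ped()]`(P)` atomwise recovers [gid()].
#'
#' @inheritParams local_gid
#' @return An `atom_table`.
#' @export
cross_entropy_decomposition <- function(P, Q, rf = h_min,
                                        policy = c("strict", "pseudocount", "restrict"),
                                        epsilon = 1e-6) {
  parts <- gid_parts(P, Q, rf, policy, epsilon)
  bits <- colSums(parts$P$p * parts$part_q)
  new_atom_table(bits, parts$lattice, var_names = var_names(P),
                 measure = "cross entropy")
}
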