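# Discrete joint distributions as tibbles -------------------------------------
#
# A `joint_dist` is a tibble with one character column per variable plus a
# numeric column `p`, one row per support state. The full alphabet of each
# variable (which may be larger than its observed support) travels along as an
# attribute, so maximum-entropy priors over the declared state space can be
# constructed even when the distribution itself is degenerate.

# probabilities this close to zero are treated as exactly zero
.zero_tol <- 1e-15
# tolerated deviation of sum(p) from 1 at construction
.sum_tol <- 1e-12

#' Construct a discrete joint distribution
#'
#' Builds a validated joint probability mass function over named,
#' finite-alphabet variables. The input is a data frame with one column per
#' variable (symbols; coerced to character) and a final numeric column `p`
#' holding the probability of each state. States with probability (numerically)
#' zero are dropped from the stored support; duplicated states are an error.
#'
#' @param states A data frame of states: one column per variable plus a
#'   numeric column `p`.
#' @param alphabets Optional named list giving the full symbol set of each
#'   variable. Defaults to the symbols observed in `states`, sorted. Every
#'   observed symbol must belong to the declared alphabet.
#' @param normalize If `TRUE`, rescale `p` to sum to one instead of requiring
#'   it (used by file readers and random generators).
#'
#' @return A `joint_dist`: a tibble of support states with attribute
#'   `alphabets`.
#'
#' @examples
#' xor <- joint_dist(data.frame(
#'   X1 = c("0", "0", "1", "1"),
#'   X2 = c("0", "1", "0", "1"),
#'   T  = c("0", "1", "1", "0"),
#'   p  = rep(0.25, 4)
#' ))
#' shannon_entropy(xor)
#' @export
joint_dist <- function(states, alphabets = NULL, normalize = FALSE) {
  if (!is.data.frame(states) || !"p" %in% names(states)) {
    abort_invalid("`states` must be a data frame with a probability column `p`.")
  }
  vars <- setdiff(names(states), "p")
  if (length(vars) == 0L) {
    abort_invalid("A joint distribution needs at least one variable column.")
  }
  p <- as.numeric(states[["p"]])
  if (anyNA(p) || any(p < -.zero_tol)) {
    abort_invalid("Probabilities must be non-negative numbers.")
  }
  p[p < .zero_tol] <- 0
  if (normalize) {
    tot <- sum(p)
    if (tot <= 0) abort_invalid("Total probability mass is zero.")
    p <- p / tot
  } else if (abs(sum(p) - 1) > .sum_tol) {
    abort_invalid(sprintf(
      "Probabilities must sum to 1 (got %.15g).", sum(p)
    ))
  }
  tab <- as_tibble(states[vars])
  tab[] <- lapply(tab, as.character)
  keep <- p > 0
  tab <- tab[keep, , drop = FALSE]
  p <- p[keep]
  if (normalize) p <- p / sum(p)
  if (anyDuplicated(state_keys(tab, seq_along(vars)))) {
    abort_invalid("Duplicated states in the probability table.")
  }
  if (is.null(alphabets)) {
    alphabets <- lapply(tab, function(col) sort(unique(col)))
  } else {
    if (!all(vars %in% names(alphabets))) {
      abort_invalid("`alphabets` must name every variable.")
    }
    alphabets <- lapply(alphabets[vars], as.character)
    ok <- mapply(function(col, ab) all(col %in% ab), tab, alphabets)
    if (!all(ok)) {
      abort_invalid(sprintf(
        "Symbols outside the declared alphabet for variable(s): %s.",
        paste(vars[!ok], collapse = ", ")
      ))
    }
  }
  names(alphabets) <- vars
  tab$p <- p
  tibble::new_tibble(tab, alphabets = alphabets,
                     class = "joint_dist", nrow = nrow(tab))
}

#' @export
print.joint_dist <- function(x, ...) {
  vars <- var_names(x)
  cat(sprintf("<joint_dist> %d variable(s): %s; %d support state(s)\n",
              length(vars), paste(vars, collapse = ", "), nrow(x)))
  NextMethod()
}

#' Variable names and alphabets of a joint distribution
#' @param P A `joint_dist`.
#' @return `var_names()`: character vector; `alphabets()`: named list of
#'   symbol vectors.
#' @export
var_names <- function(P) setdiff(names(P), "p")

#' @rdname var_names
#' @export
alphabets <- function(P) attr(P, "alphabets")

n_vars <- function(P) length(var_names(P))

# paste projected states into single keys for matching/grouping
state_keys <- function(tab, idx) {
  if (length(idx) == 1L) return(as.character(tab[[idx]]))
  do.call(paste, c(unname(as.list(tab[idx])), sep = "\x1f"))
}

# resolve variable names or indices to validated integer indices
resolve_vars <- function(P, subset, allow_empty = FALSE) {
  vars <- var_names(P)
  if (is.character(subset)) {
    idx <- match(subset, vars)
    if (anyNA(idx)) {
      abort_invalid(sprintf("Unknown variable(s): %s.",
                            paste(subset[is.na(idx)], collapse = ", ")))
    }
  } else {
    idx <- as.integer(subset)
    if (length(idx) && (anyNA(idx) || any(idx < 1L) || any(idx > length(vars)))) {
      abort_invalid("Variable indices out of range.")
    }
  }
  if (!allow_empty && length(idx) == 0L) {
    abort_invalid("The variable subset must be non-empty.")
  }
  if (anyDuplicated(idx)) abort_invalid("Variable subset contains duplicates.")
  idx
}

#' Marginalize a joint distribution onto a subset of variables
#'
#' Sums probability mass over the discarded variables. The returned
#' distribution keeps the requested variable order and the corresponding
#' alphabets.
#'
#' @param P A `joint_dist`.
#' @param subset Variable names or indices (non-empty, distinct).
#' @return A `joint_dist` over `subset`.
#' @export
marginalize <- function(P, subset) {
  idx <- resolve_vars(P, subset)
  vars <- var_names(P)[idx]
  key <- state_keys(P, idx)
  p <- rowsum(P$p, group = key, reorder = FALSE)
  first <- !duplicated(key)
  out <- as_tibble(as.data.frame(P)[first, vars, drop = FALSE])
  out$p <- p[match(key[first], rownames(p)), 1L]
  joint_dist(out, alphabets = alphabets(P)[vars])
}

#' Condition a joint distribution on one variable's value
#'
#' Returns the conditional distribution of the remaining variables given
#' `variable = value`. Conditioning on a value of zero marginal probability is
#' a support error.
#'
#' @param P A `joint_dist` over at least two variables.
#' @param variable Variable name or index to condition on.
#' @param value Symbol (coerced to character) the variable is fixed to.
#' @return A `joint_dist` over the remaining variables.
#' @export
condition_on <- function(P, variable, value) {
  idx <- resolve_vars(P, variable)
  if (length(idx) != 1L) abort_invalid("Condition on exactly one variable.")
  if (n_vars(P) < 2L) abort_invalid("Cannot condition a univariate distribution.")
  value <- as.character(value)
  sel <- P[[idx]] == value
  mass <- sum(P$p[sel])
  if (mass <= .zero_tol) {
    abort_support(sprintf(
      "Conditioning value '%s' for variable '%s' has zero probability.",
      value, var_names(P)[idx]
    ))
  }
  keep <- setdiff(var_names(P), var_names(P)[idx])
  out <- as_tibble(as.data.frame(P)[sel, keep, drop = FALSE])
  out$p <- P$p[sel] / mass
  joint_dist(out, alphabets = alphabets(P)[keep], normalize = TRUE)
}

#' Independence and maximum-entropy priors
#'
#' `product_of_marginals()` returns the distribution in which every variable
#' is independent with its marginal probabilities preserved — the implicit
#' prior of the total correlation. `uniform_prior()` returns the uniform
#' distribution over the full Cartesian product of the declared alphabets —
#' the implicit prior of the negentropy.
#'
#' @param P A `joint_dist`.
#' @return A `joint_dist` over the same variables and alphabets.
#' @export
product_of_marginals <- function(P) {
  vars <- var_names(P)
  margs <- lapply(seq_along(vars), function(i) {
    m <- marginalize(P, i)
    stats::setNames(m$p, m[[1L]])
  })
  grid <- expand.grid(lapply(margs, names),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- vars
  pm <- Reduce(`*`, lapply(seq_along(vars), function(i) {
    unname(margs[[i]][grid[[i]]])
  }))
  grid$p <- pm
  joint_dist(grid, alphabets = alphabets(P))
}

#' @rdname product_of_marginals
#' @export
uniform_prior <- function(P) {
  ab <- alphabets(P)
  grid <- expand.grid(ab, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$p <- rep(1 / nrow(grid), nrow(grid))
  joint_dist(grid, alphabets = ab)
}

#' Local surprisal of a (projected) realization
#'
#' The local entropy \eqn{h(x) = -\log_2 P(x)} of the state `x`, optionally
#' projected onto a subset of variables first (in which case the marginal
#' probability of the projection is used).
#'
#' @param P A `joint_dist`.
#' @param x A full realization: character vector with one symbol per variable
#'   of `P` (optionally named).
#' @param subset Variables to project onto before evaluating; defaults to all.
#' @return Surprisal in bits (non-negative scalar).
#' @export
local_surprisal <- function(P, x, subset = seq_len(n_vars(P))) {
  idx <- resolve_vars(P, subset)
  x <- realization(P, x)
  pr <- marginal_prob(P, idx, x[idx])
  if (pr <= 0) {
    abort_support(sprintf(
      "State (%s) of variables (%s) has zero probability.",
      paste(x[idx], collapse = ","),
      paste(var_names(P)[idx], collapse = ",")
    ))
  }
  -log2(pr)
}

# coerce/validate a full realization against P's variable list
realization <- function(P, x) {
  vars <- var_names(P)
  x <- as.character(unlist(x, use.names = TRUE))
  if (!is.null(names(x)) && all(nzchar(names(x)))) {
    miss <- setdiff(vars, names(x))
    if (length(miss)) {
      abort_invalid(sprintf("Realization lacks variable(s): %s.",
                            paste(miss, collapse = ", ")))
    }
    x <- x[vars]
  }
  if (length(x) != length(vars)) {
    abort_invalid("Realization must supply one symbol per variable.")
  }
  ok <- mapply(function(sym, ab) sym %in% ab, x, alphabets(P))
  if (!all(ok)) {
    abort_invalid(sprintf("Symbol(s) outside alphabet for: %s.",
                          paste(vars[!ok], collapse = ", ")))
  }
  stats::setNames(x, vars)
}

# marginal probability of one projected state (no error on zero)
marginal_prob <- function(P, idx, symbols) {
  key <- state_keys(P, idx)
  target <- paste(symbols, collapse = "\x1f")
  sum(P$p[key == target])
}

#' Shannon entropy of a joint distribution
#'
#' @param P A `joint_dist`.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(P) {
  -sum(P$p * log2(P$p))
}

#' Kullback-Leibler divergence between two distributions
#'
#' Computes \eqn{D(P \| Q) = \sum_x P(x) \log_2 P(x)/Q(x)} in bits, after
#' applying a support policy (see [apply_support_policy()]). `P` plays the
#' role of the posterior and `Q` the prior; both must share variable lists and
#' alphabets. Alignment is by state, never by row order.
#'
#' @param P,Q `joint_dist` objects over the same variables and alphabets.
#' @inheritParams apply_support_policy
#' @return Divergence in bits (non-negative).
#' @export
kl_divergence <- function(P, Q, policy = c("strict", "pseudocount", "restrict"),
                          epsilon = 1e-6) {
  aligned <- apply_support_policy(P, Q, policy, epsilon)
  P <- aligned$P
  Q <- aligned$Q
  q <- lookup_probs(Q, P)
  sum(P$p * (log2(P$p) - log2(q)))
}

# probabilities that `Q` assigns to the support states of `ref`
lookup_probs <- function(Q, ref) {
  idx <- seq_len(n_vars(ref))
  pos <- match(state_keys(ref, idx), state_keys(Q, idx))
  q <- Q$p[pos]
  q[is.na(q)] <- 0
  q
}

check_same_space <- function(P, Q) {
  if (!identical(var_names(P), var_names(Q))) {
    abort_invalid("Distributions are over different variable lists.")
  }
  abP <- lapply(alphabets(P), sort)
  abQ <- lapply(alphabets(Q), sort)
  if (!identical(abP, abQ)) {
    abort_invalid("Distributions declare different alphabets.")
  }
  invisible(TRUE)
}

#' Reconcile the supports of a posterior and a prior
#'
#' The divergence \eqn{D(P\|Q)} is undefined when the posterior `P` has
#' support where the prior `Q` does not. Three policies are offered:
#' `"strict"` (the default everywhere) raises a support error; `"pseudocount"`
#' adds `epsilon` to every state of `Q`'s full alphabet product and
#' renormalizes `Q` — note this biases results, since the inflated prior
#' surprisal of rare states dominates; `"restrict"` drops the offending states
#' from `P` and renormalizes, which discards information held in those states.
#'
#' @param P,Q `joint_dist` objects over the same variables and alphabets
#'   (posterior and prior, respectively).
#' @param policy One of `"strict"`, `"pseudocount"`, `"restrict"`.
#' @param epsilon Pseudocount added to each prior state (must be positive).
#' @return A list with adjusted elements `P` and `Q`.
#' @export
apply_support_policy <- function(P, Q,
                                 policy = c("strict", "pseudocount", "restrict"),
                                 epsilon = 1e-6) {
  policy <- match.arg(policy)
  check_same_space(P, Q)
  q <- lookup_probs(Q, P)
  if (policy == "strict") {
    if (any(q <= 0)) {
      bad <- which(q <= 0)[1L]
      abort_support(sprintf(
        "Posterior state (%s) has zero prior probability under the strict policy.",
        paste(unlist(P[bad, var_names(P)]), collapse = ",")
      ))
    }
    return(list(P = P, Q = Q))
  }
  if (policy == "pseudocount") {
    if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon <= 0) {
      abort_invalid("`epsilon` must be a single positive number.")
    }
    grid <- expand.grid(alphabets(Q), KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    qfull <- lookup_probs(Q, joint_dist(cbind(grid, p = 1 / nrow(grid))))
    grid$p <- qfull + epsilon
    Q2 <- joint_dist(grid, alphabets = alphabets(Q), normalize = TRUE)
    return(list(P = P, Q = Q2))
  }
  # restrict: drop posterior states outside the prior support
  keep <- q > 0
  if (!any(keep)) {
    abort_support("No posterior state lies in the prior support; cannot restrict.")
  }
  out <- as.data.frame(P)[keep, , drop = FALSE]
  P2 <- joint_dist(out, alphabets = alphabets(P), normalize = TRUE)
  list(P = P2, Q = Q)
}
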