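# Deterministic test distributions --------------------------------------------

#' Logic-gate distributions with equiprobable inputs
#'
#' Three binary variables: two independent fair inputs and a deterministic
#' target. `"XOR"` gives the canonical synergy example (support
#' `(0,0,0), (0,1,1), (1,0,1), (1,1,0)`, each 1/4); `"COPY"` sets the target
#' equal to the first input.
#'
#' @param gate One of `"XOR"`, `"AND"`, `"OR"`, `"COPY"`.
#' @param var_names Names for the two inputs and the target.
#' @return A `joint_dist` with 4 support states of probability 1/4 and full
#'   binary alphabets.
#' @export
logic_gate <- function(gate = c("XOR", "AND", "OR", "COPY"),
                       var_names = c("X1", "X2", "T")) {
  gate <- match.arg(gate)
  x1 <- c(0L, 0L, 1L, 1L)
  x2 <- c(0L, 1L, 0L, 1L)
  t <- switch(gate,
    XOR = bitwXor(x1, x2),
    AND = x1 & x2,
    OR = x1 | x2,
    COPY = x1
  )
  tab <- data.frame(as.character(x1), as.character(x2),
                    as.character(as.integer(t)), p = rep(0.25, 4))
  names(tab) <- c(var_names, "p")
  joint_dist(tab, alphabets = stats::setNames(
    rep(list(c("0", "1")), 3L), var_names
  ))
}

#' Uniform (maximum-entropy) distribution
#'
#' All `alphabet_size^n_vars` states equiprobable; symbols are the strings
#' `"0" ... "k-1"`.
#'
#' @param n_vars Number of variables.
#' @param alphabet_size Symbols per variable.
#' @param var_names Variable names; defaults to `X1..Xn`.
#' @return A `joint_dist`.
#' @export
uniform_dist <- function(n_vars, alphabet_size = 2L,
                         var_names = paste0("X", seq_len(n_vars))) {
  if (n_vars < 1L) abort_invalid("`n_vars` must be at least 1.")
  syms <- as.character(seq_len(alphabet_size) - 1L)
  ab <- stats::setNames(rep(list(syms), n_vars), var_names)
  grid <- expand.grid(ab, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$p <- rep(1 / nrow(grid), nrow(grid))
  joint_dist(grid, alphabets = ab)
}

#' Giant-bit distribution
#'
#' All variables copy a single fair coin: two support states (all zeros, all
#' ones) at probability 1/2 — the canonical redundancy-dominated extreme.
#'
#' @inheritParams uniform_dist
#' @return A `joint_dist` with binary alphabets.
#' @export
giant_bit <- function(n_vars, var_names = paste0("X", seq_len(n_vars))) {
  if (n_vars < 2L) abort_invalid("`n_vars` must be at least 2.")
  tab <- as.data.frame(rbind(rep("0", n_vars), rep("1", n_vars)),
                       stringsAsFactors = FALSE)
  names(tab) <- var_names
  tab$p <- c(0.5, 0.5)
  joint_dist(tab, alphabets = stats::setNames(
    rep(list(c("0", "1")), n_vars), var_names
  ))
}

#' Seeded random distribution (symmetric Dirichlet)
#'
#' State probabilities drawn from a symmetric Dirichlet over the full state
#' space, reproducible per seed. States whose drawn mass falls below 1e-15
#' are dropped and the remainder renormalized. Large concentrations approach
#' the uniform distribution; small ones give sparse, spiky distributions.
#'
#' @inheritParams uniform_dist
#' @param seed Integer seed (mandatory; no hidden global state is consumed).
#' @param concentration Dirichlet concentration parameter (default 1 = flat).
#' @return A `joint_dist`.
#' @export
random_dist <- function(n_vars, alphabet_size = 2L, seed,
                        concentration = 1,
                        var_names = paste0("X", seq_len(n_vars))) {
  if (missing(seed)) abort_invalid("`seed` is required for random_dist().")
  if (concentration <= 0) abort_invalid("`concentration` must be positive.")
  syms <- as.character(seq_len(alphabet_size) - 1L)
  ab <- stats::setNames(rep(list(syms), n_vars), var_names)
  grid <- expand.grid(ab, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- withr::with_seed(as.integer(seed),
                        stats::rgamma(nrow(grid), shape = concentration))
  p <- g / sum(g)
  p[p < 1e-15] <- 0
  grid$p <- p / sum(p)
  joint_dist(grid, alphabets = ab, normalize = TRUE)
}

#' Reference decompositions of the XOR system
#'
#' Reproduces the three benchmark columns for the XOR gate system
#' `{X1, X2, T}`: the expected partial entropy decomposition of the
#' maximum-entropy (uniform) prior, the expected PED of the XOR distribution
#' itself, and the partial total-correlation decomposition of XOR — all with
#' [h_min()], over the 18 atoms of the 3-variable lattice in lattice order.
#'
#' @return A tibble with columns `atom`, `H_Q` (uniform PED), `H_P` (XOR
#'   PED), and `TC` (partial total correlation), 18 rows.
#' @export
xor_reference_table <- function() {
  vn <- c("X1", "X2", "T")
  hq <- expected_ped(uniform_dist(3L, var_names = vn))
  hp <- expected_ped(logic_gate("XOR", var_names = vn))
  tc <- tc_decomposition(logic_gate("XOR", var_names = vn))
  tibble(atom = hq$atom, H_Q = hq$bits, H_P = hp$bits, TC = tc$bits)
}
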