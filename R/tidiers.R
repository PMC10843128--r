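# broom-style tidiers ----------------------------------------------------------

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an atom table
#'
#' Augments the `(atom, bits)` table with structural columns: the sources as
#' a list-column of variable-name vectors, the number of sources, the size of
#' the largest source (the atom's synergistic order), and the lattice level
#' (number of atoms strictly below).
#'
#' @param x An `atom_table`.
#' @param ... Unused.
#' @return A tibble with columns `atom`, `sources`, `n_sources`,
#'   `max_order`, `level`, `bits`.
#' @export
tidy.atom_table <- function(x, ...) {
  lattice <- attr(x, "lattice")
  vn <- attr(x, "var_names")
  tibble(
    atom = x$atom,
    sources = lapply(lattice$atoms, function(a) lapply(a, function(s) vn[s])),
    n_sources = lengths(lattice$atoms),
    max_order = vapply(lattice$atoms, function(a) max(lengths(a)), integer(1)),
    level = lengths(lattice$down_sets),
    bits = x$bits
  )
}

#' One-row summary of an atom table
#'
#' @param x An `atom_table`.
#' @param ... Unused.
#' @return A tibble with the measure name, lattice size, total bits, and the
#'   bottom (full redundancy) and top (full synergy) atom values, plus the
#'   count of negative atoms.
#' @export
glance.atom_table <- function(x, ...) {
  lattice <- attr(x, "lattice")
  tibble(
    measure = attr(x, "measure") %||% NA_character_,
    n_variables = lattice$n,
    n_atoms = nrow(x),
    total_bits = sum(x$bits),
    redundancy_bits = x$bits[1L],
    synergy_bits = x$bits[nrow(x)],
    n_negative = sum(x$bits < 0)
  )
}

#' Tidy a joint distribution
#'
#' Returns the support table with an added `surprisal` column
#' (\eqn{-\log_2 p}).
#'
#' @param x A `joint_dist`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.joint_dist <- function(x, ...) {
  out <- as_tibble(as.data.frame(x))
  out$surprisal <- -log2(out$p)
  out
}

#' One-row summary of a joint distribution
#'
#' @param x A `joint_dist`.
#' @param ... Unused.
#' @return A tibble with variable and state counts, entropy, and (for 2+
#'   variables) the total correlation.
#' @export
glance.joint_dist <- function(x, ...) {
  tibble(
    n_variables = n_vars(x),
    n_states = nrow(x),
    n_cells = prod(lengths(alphabets(x))),
    entropy_bits = shannon_entropy(x),
    total_correlation_bits = total_correlation(x)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
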