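# Redundancy (antichain) lattice ----------------------------------------------
#
# A "source" is a non-empty subset of variable indices; an "atom" is an
# antichain of sources (no source contained in another). Atoms are partially
# ordered by: alpha <= beta iff every source of beta contains some source of
# alpha. The bottom atom {1}{2}...{n} is full redundancy, the top atom
# {1,...,n} full synergy. Atom counts for n = 1..4 are 1, 4, 18, 166; larger
# systems are refused because the antichain count grows super-exponentially
# (the Dedekind numbers), which is why decompositions of this kind are
# restricted to systems of four to five elements at most.

check_lattice_n <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n != as.integer(n) || n < 1L || n > 4L) {
    abort_size(paste(
      "Redundancy lattices are supported for 1-4 variables only:",
      "the number of antichains grows super-exponentially with n",
      "(1, 4, 18, 166 atoms for n = 1..4; 7579 for n = 5)."
    ))
  }
  as.integer(n)
}

# canonicalize an atom: each source sorted ascending, sources ordered by
# (cardinality, then index sequence)
canonical_atom <- function(sources) {
  sources <- lapply(sources, function(s) sort(as.integer(s)))
  key <- vapply(sources, function(s) {
    sprintf("%d.%s", length(s), paste(s, collapse = "."))
  }, character(1))
  sources[order(key)]
}

atom_sort_key <- function(atom) {
  paste(vapply(atom, function(s) {
    sprintf("%d.%s", length(s), paste(s, collapse = "."))
  }, character(1)), collapse = "|")
}

#' Render an atom as a canonical label
#'
#' Sources are sorted by (cardinality, index order) and printed as
#' `"{X1}{X2,X3}"` using the supplied variable names.
#'
#' @param atom A list of integer vectors (one per source).
#' @param names Variable names; defaults to `X1..Xn`.
#' @return A single string.
#' @export
atom_label <- function(atom, names = NULL) {
  atom <- canonical_atom(atom)
  n <- max(unlist(atom))
  if (is.null(names)) names <- paste0("X", seq_len(n))
  paste(vapply(atom, function(s) {
    paste0("{", paste(names[s], collapse = ","), "}")
  }, character(1)), collapse = "")
}

#' Enumerate the antichains of non-empty subsets of 1..n
#'
#' Generates every atom of the n-variable redundancy lattice (the empty
#' antichain is excluded). Enumeration is a depth-first search over subset
#' bitmasks with containment pruning, validated against the known atom counts
#' 1, 4, 18, 166 for n = 1..4.
#'
#' @param n Number of variables (1-4).
#' @return A list of atoms, each a list of sorted integer vectors.
#' @export
enumerate_antichains <- function(n) {
  n <- check_lattice_n(n)
  masks <- seq_len(2L^n - 1L)
  m <- length(masks)
  # comparable[i, j]: source i contained in j or vice versa
  comparable <- outer(masks, masks, function(a, b) {
    ab <- bitwAnd(a, b)
    ab == a | ab == b
  })
  acc <- vector("list", 0L)
  stack <- list(list(start = 1L, chosen = integer(0)))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (length(fr$chosen)) acc[[length(acc) + 1L]] <- fr$chosen
    j <- fr$start
    while (j <= m) {
      if (!length(fr$chosen) || !any(comparable[fr$chosen, j])) {
        stack[[length(stack) + 1L]] <- list(start = j + 1L,
                                            chosen = c(fr$chosen, j))
      }
      j <- j + 1L
    }
  }
  lapply(acc, function(ms) {
    canonical_atom(lapply(ms, function(mask) which(bitwAnd(mask, 2L^(seq_len(n) - 1L)) > 0L)))
  })
}

#' Partial order of the redundancy lattice
#'
#' `atom_leq(alpha, beta)` is `TRUE` iff for every source `b` of `beta` there
#' is a source `a` of `alpha` with `a` a subset of `b` — i.e. the redundancy
#' captured by `alpha` is accessible wherever `beta`'s is.
#'
#' @param alpha,beta Atoms: lists of integer vectors.
#' @return Logical scalar.
#' @export
atom_leq <- function(alpha, beta) {
  a_masks <- vapply(alpha, function(s) sum(2L^(s - 1L)), numeric(1))
  all(vapply(beta, function(b) {
    bm <- sum(2L^(b - 1L))
    any(bitwAnd(a_masks, bm) == a_masks)
  }, logical(1)))
}

#' Build the redundancy lattice for n variables
#'
#' Enumerates all antichain atoms, computes the partial order and the strict
#' down-set of every atom, and fixes a deterministic topological order
#' (ascending strict-down-set size, ties broken by canonical label). The
#' bottom atom is the full redundancy `{X1}{X2}...{Xn}`, the top the full
#' synergy `{X1,...,Xn}`.
#'
#' @param n Number of variables (1-4).
#' @return A `redundancy_lattice`: list with elements `n`, `atoms` (list, in
#'   topological order), `labels` (canonical generic labels), `leq` (logical
#'   matrix of the partial order), `down_sets` (strict down-sets as integer
#'   index vectors).
#' @export
build_lattice <- function(n) {
  n <- check_lattice_n(n)
  atoms <- enumerate_antichains(n)
  k <- length(atoms)
  leq <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      leq[i, j] <- atom_leq(atoms[[i]], atoms[[j]])
    }
  }
  down_size <- colSums(leq) - 1L
  ord <- order(down_size, vapply(atoms, atom_sort_key, character(1)))
  atoms <- atoms[ord]
  leq <- leq[ord, ord, drop = FALSE]
  down_sets <- lapply(seq_len(k), function(j) {
    setdiff(which(leq[, j]), j)
  })
  structure(
    list(
      n = n,
      atoms = atoms,
      labels = vapply(atoms, atom_label, character(1)),
      leq = leq,
      down_sets = down_sets
    ),
    class = "redundancy_lattice"
  )
}

#' @export
print.redundancy_lattice <- function(x, ...) {
  cat(sprintf("<redundancy_lattice> n = %d, %d atoms (%s ... %s)\n",
              x$n, length(x$atoms), x$labels[1L], x$labels[length(x$labels)]))
  invisible(x)
}

# cache: lattices are small and rebuilt often in loops
lattice_cache <- new.env(parent = emptyenv())

get_lattice <- function(n) {
  key <- as.character(n)
  if (is.null(lattice_cache[[key]])) {
    lattice_cache[[key]] <- build_lattice(n)
  }
  lattice_cache[[key]]
}

# Atom tables ------------------------------------------------------------------

# An atom table pairs every lattice atom with a value in bits. Stored as a
# tibble (columns `atom`, `bits`) so it pipes into dplyr/ggplot2 directly;
# the lattice and the variable names used for labelling ride along as
# attributes.
new_atom_table <- function(bits, lattice, var_names = NULL, measure = NULL) {
  if (is.null(var_names)) var_names <- paste0("X", seq_len(lattice$n))
  stopifnot(length(bits) == length(lattice$atoms))
  tab <- tibble(
    atom = vapply(lattice$atoms, atom_label, character(1), names = var_names),
    bits = as.numeric(bits)
  )
  tibble::new_tibble(tab, lattice = lattice, var_names = var_names,
                     measure = measure, class = "atom_table", nrow = nrow(tab))
}

#' @export
print.atom_table <- function(x, ...) {
  meas <- attr(x, "measure")
  cat(sprintf("<atom_table>%s n = %d variables, %d atoms, total = %.6g bits\n",
              if (is.null(meas)) "" else paste0(" [", meas, "]"),
              attr(x, "lattice")$n, nrow(x), sum(x$bits)))
  NextMethod()
}

# coerce a user-supplied cumulative table to a numeric vector in lattice order
cumulative_vector <- function(lattice, cumulative) {
  if (inherits(cumulative, "data.frame")) {
    if (!all(c("atom", "bits") %in% names(cumulative))) {
      abort_invalid("A cumulative table needs columns `atom` and `bits`.")
    }
    vn <- attr(cumulative, "var_names")
    labs <- if (is.null(vn)) lattice$labels else
      vapply(lattice$atoms, atom_label, character(1), names = vn)
    pos <- match(labs, cumulative$atom)
    if (anyNA(pos)) {
      abort_invalid(sprintf("Cumulative table is missing atom(s): %s.",
                            paste(labs[is.na(pos)], collapse = " ")))
    }
    return(as.numeric(cumulative$bits[pos]))
  }
  x <- as.numeric(cumulative)
  if (!is.null(names(cumulative))) {
    pos <- match(lattice$labels, names(cumulative))
    if (anyNA(pos)) {
      abort_invalid("Named cumulative vector is missing lattice atoms.")
    }
    return(x[pos])
  }
  if (length(x) != length(lattice$atoms)) {
    abort_invalid("Cumulative values must cover every lattice atom.")
  }
  x
}

#' Moebius inversion of cumulative redundancy values
#'
#' Converts cumulative (redundancy-function) values into partial atom values
#' by recursive subtraction in topological order: each atom's partial value is
#' its cumulative value minus the sum of partial values over its strict
#' down-set. Summing the returned partials over any atom's inclusive down-set
#' reproduces the cumulative input.
#'
#' @param lattice A `redundancy_lattice`.
#' @param cumulative One value per atom: an atom table (columns `atom`,
#'   `bits`), a named numeric vector keyed by canonical label, or a bare
#'   numeric vector in lattice order.
#' @return An `atom_table` of partial values.
#' @export
mobius_inversion <- function(lattice, cumulative) {
  cum <- cumulative_vector(lattice, cumulative)
  if (any(!is.finite(cum))) abort_invalid("Cumulative values must be finite.")
  part <- mobius_rows(lattice, matrix(cum, nrow = 1L))
  new_atom_table(part[1L, ], lattice, measure = "mobius")
}

# vectorized inversion: rows are states, columns atoms (topological order)
mobius_rows <- function(lattice, cum) {
  part <- cum
  for (j in seq_along(lattice$atoms)) {
    ds <- lattice$down_sets[[j]]
    if (length(ds)) {
      part[, j] <- cum[, j] - rowSums(part[, ds, drop = FALSE])
    }
  }
  part
}
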