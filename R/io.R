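# File dialects ---------------------------------------------------------------
#
# TSV/CSV: a header row of variable names plus a final column "p"; one row per
# support state; symbols are strings, probabilities decimal. JSON:
# {"variables": [...], "alphabets": {...}, "pmf": [{"state": [...], "p": ...}]}.
# Atom tables: TSV with columns "atom" and "bits", rows in lattice order.

infer_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(format, c("tsv", "csv", "json")))
  switch(tolower(tools::file_ext(path)),
    tsv = "tsv", txt = "tsv", csv = "csv", json = "json",
    abort_io(sprintf("Cannot infer file format from '%s'; pass `format`.", path))
  )
}

#' Read a joint distribution from TSV, CSV or JSON
#'
#' The tabular dialects carry no alphabet declaration, so alphabets default
#' to the observed symbols unless supplied. Probability mass deviating from 1
#' by more than `1e-6` is rejected; smaller deviations are renormalized with
#' a warning.
#'
#' @param path File path.
#' @param format `"tsv"`, `"csv"` or `"json"`; inferred from the extension
#'   when `NULL`.
#' @param alphabets Optional named list of full symbol sets (tabular formats
#'   only; JSON carries its own).
#' @return A `joint_dist`.
#' @export
read_dist <- function(path, format = NULL, alphabets = NULL) {
  format <- infer_format(path, format)
  if (!file.exists(path)) abort_io(sprintf("No such file: '%s'.", path))
  if (format == "json") {
    obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                    error = function(e) abort_io(conditionMessage(e)))
    vars <- as.character(unlist(obj$variables))
    if (length(vars) == 0L || is.null(obj$pmf)) {
      abort_invalid("JSON distribution needs `variables` and `pmf`.")
    }
    states <- do.call(rbind, lapply(obj$pmf, function(e) {
      as.character(unlist(e$state))
    }))
    tab <- as.data.frame(states, stringsAsFactors = FALSE)
    names(tab) <- vars
    tab$p <- vapply(obj$pmf, function(e) as.numeric(e$p), numeric(1))
    alphabets <- if (!is.null(obj$alphabets)) {
      lapply(obj$alphabets, function(a) as.character(unlist(a)))
    }
  } else {
    delim <- if (format == "tsv") "\t" else ","
    tab <- tryCatch(
      as.data.frame(readr::read_delim(
        path, delim = delim, col_types = readr::cols(
          p = readr::col_double(), .default = readr::col_character()
        ), progress = FALSE
      )),
      error = function(e) abort_io(conditionMessage(e))
    )
    if (!"p" %in% names(tab)) {
      abort_invalid(sprintf("'%s' lacks the probability column `p`.", path))
    }
  }
  tot <- sum(tab$p)
  if (!is.finite(tot) || abs(tot - 1) > 1e-6) {
    abort_invalid(sprintf(
      "Probabilities in '%s' sum to %.8g, outside the ingest tolerance 1e-6.",
      path, tot
    ))
  }
  if (abs(tot - 1) > .sum_tol) {
    warn(sprintf("Renormalizing probabilities in '%s' (sum was %.10g).",
                 path, tot))
  }
  joint_dist(tab, alphabets = alphabets, normalize = TRUE)
}

#' Write a joint distribution to TSV, CSV or JSON
#'
#' @param P A `joint_dist`.
#' @inheritParams read_dist
#' @return `path`, invisibly.
#' @export
write_dist <- function(P, path, format = NULL) {
  format <- infer_format(path, format)
  if (format == "json") {
    vars <- var_names(P)
    obj <- list(
      variables = vars,
      alphabets = alphabets(P),
      pmf = lapply(seq_len(nrow(P)), function(i) {
        list(state = as.character(unlist(P[i, vars])), p = P$p[i])
      })
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    delim <- if (format == "tsv") "\t" else ","
    # readr writes shortest exact decimal representations, so probabilities
    # survive a round trip bit-for-bit
    readr::write_delim(as.data.frame(P), path, delim = delim)
  }
  invisible(path)
}

# 10 significant digits, fixed rendering, for diffable outputs
format_num <- function(x) {
  trimws(vapply(x, function(v) formatC(v, digits = 10, format = "g"),
                character(1)))
}

#' Read and write atom tables
#'
#' Atom tables are TSV files with columns `atom` (canonical label) and `bits`,
#' rows in lattice topological order; values are rendered with 10 significant
#' digits.
#'
#' @param atoms An `atom_table` (or any data frame with `atom` and `bits`).
#' @param path File path.
#' @return `write_atoms()`: `path`, invisibly. `read_atoms()`: a tibble with
#'   columns `atom` and `bits`.
#' @export
write_atoms <- function(atoms, path) {
  if (!all(c("atom", "bits") %in% names(atoms))) {
    abort_invalid("An atom table needs columns `atom` and `bits`.")
  }
  out <- data.frame(atom = atoms$atom, bits = format_num(atoms$bits))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_atoms
#' @export
read_atoms <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("No such file: '%s'.", path))
  as_tibble(readr::read_tsv(path, col_types = readr::cols(
    atom = readr::col_character(), bits = readr::col_double()
  ), progress = FALSE))
}
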