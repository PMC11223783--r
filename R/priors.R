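#' Population-frequency priors for the genotype model
#'
#' The caller's prior over homoplasmic genotypes at a position is the
#' population allele frequency of each base at that position; positions
#' absent from the table (or all positions, when no table is supplied) use
#' a uniform 0.25 per base. `theta_het` is the total prior mass reserved
#' for heteroplasmic (two-allele) hypotheses at a column, shared equally
#' among the candidate pairs.
#'
#' @param table Optional data.frame with columns `pos`, `A`, `C`, `G`, `T`
#'   holding per-position allele frequencies.
#' @param theta_het Prior mass for heteroplasmic hypotheses (default 0.01).
#' @param floor Frequency floor applied before per-row renormalization, so
#'   no base ever has exactly zero prior (default 1e-4).
#' @return An object of class `mito_priors`.
#' @export
mito_priors <- function(table = NULL, theta_het = 0.01, floor = 1e-4) {
  stopifnot(theta_het > 0, theta_het < 1)
  if (!is.null(table)) {
    stopifnot(all(c("pos", "A", "C", "G", "T") %in% names(table)))
    m <- as.matrix(table[, c("A", "C", "G", "T")])
    m[m < floor] <- floor
    m <- m / rowSums(m)
    table <- data.frame(pos = as.integer(table$pos), m)
  }
  structure(
    list(table = table, theta_het = theta_het, floor = floor),
    class = "mito_priors"
  )
}

#' Read a per-position allele-frequency prior table from TSV
#'
#' Expected columns: pos, A, C, G, T (tab-separated, header required).
#'
#' @inheritParams mito_priors
#' @param path Path to the TSV file.
#' @return A `mito_priors` object.
#' @export
read_prior_table <- function(path, theta_het = 0.01, floor = 1e-4) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t")
  mito_priors(tab, theta_het = theta_het, floor = floor)
}

## Dense L x 4 matrix of per-position homoplasmic prior frequencies.
prior_matrix <- function(priors, length) {
  m <- matrix(0.25, nrow = length, ncol = 4L, dimnames = list(NULL, BASES))
  if (!is.null(priors$table)) {
    rows <- priors$table$pos >= 1L & priors$table$pos <= length
    m[priors$table$pos[rows], ] <- as.matrix(priors$table[rows, c("A", "C", "G", "T")])
  }
  m
}

#' @export
print.mito_priors <- function(x, ...) {
  src <- if (is.null(x$table)) "uniform" else sprintf("%d positions from table", nrow(x$table))
  cat(sprintf("<mito_priors> %s; theta_het = %g\n", src, x$theta_het))
  invisible(x)
}
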