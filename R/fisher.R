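#' Create a 2x2 contingency table
#'
#' @param a,b,c,d Non-negative integer counts. `a` is the overlap cell tested
#'   for excess.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stopf("contingency table cells must be non-negative integers")
  }
  if (sum(cells) <= 0) stopf("contingency table total must be positive")
  structure(as.list(cells), class = "contingency_table")
}

# Vectorized right-tail hypergeometric p-value for tables given as vectors.
# P(X >= a) with X ~ Hypergeometric(white = a+b, black = c+d, drawn = a+c).
phyper_right <- function(a, b, c, d) {
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' One-sided (enrichment) Fisher's exact test
#'
#' Right-tail p-value `P(X >= a)` for the hypergeometric distribution with
#' the table's margins -- the shared statistical kernel of all three gene set
#' network builders. Returns exactly 1 when `a` is at the distribution's
#' minimum or a margin is zero.
#'
#' @param table A [contingency_table()], or the count `a` when `b`, `c`, `d`
#'   are supplied.
#' @param b,c,d Optional counts, used when `table` is given as the scalar `a`.
#' @return The right-tail p-value in `[0, 1]`.
#' @export
fisher_right_tail <- function(table, b = NULL, c = NULL, d = NULL) {
  if (inherits(table, "contingency_table")) {
    tb <- table
  } else {
    tb <- contingency_table(table, b, c, d)
  }
  min(1, phyper_right(tb$a, tb$b, tb$c, tb$d))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false discovery rate control, order-aligned with the
#' input and capped at 1. Adjusted values always satisfy `q >= p`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Overlap contingency table for two gene sets
#'
#' Cells: `a = |A intersect B|`, `b = |A| - a`, `c = |B| - a`,
#' `d = |universe| - |A union B|`. The universe must contain both sets; for a
#' collection it is always the union of all member genes.
#'
#' @param set_a,set_b [gene_set()] objects (or plain character vectors).
#' @param universe Character vector of background gene ids.
#' @return A [contingency_table()].
#' @export
overlap_contingency <- function(set_a, set_b, universe) {
  ma <- if (inherits(set_a, "gene_set")) set_a$members else unique(as.character(set_a))
  mb <- if (inherits(set_b, "gene_set")) set_b$members else unique(as.character(set_b))
  if (!all(ma %in% universe) || !all(mb %in% universe)) {
    stopf("gene set members must be contained in the universe")
  }
  a <- length(intersect(ma, mb))
  contingency_table(a, length(ma) - a, length(mb) - a,
                    length(universe) - (length(ma) + length(mb) - a))
}
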