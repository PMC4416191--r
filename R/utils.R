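#' @keywords internal
"_PACKAGE"

# shared input checks; all user-facing errors go through stop(call. = FALSE)
abort_input <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

#' Canonical unordered gene-pair ordering
#'
#' Orders each pair so that `gene_a < gene_b` lexicographically. All pair
#' tables in the package rely on this canonical form for joins and
#' de-duplication.
#'
#' @param gene_a,gene_b character vectors of equal length.
#' @return A data.frame with columns `gene_a`, `gene_b` in canonical order.
#' @export
canonical_pairs <- function(gene_a, gene_b) {
  if (length(gene_a) != length(gene_b)) {
    abort_input("gene_a and gene_b must have equal length")
  }
  gene_a <- as.character(gene_a)
  gene_b <- as.character(gene_b)
  if (any(gene_a == gene_b)) abort_input("self-pairs are not allowed")
  swap <- gene_a > gene_b
  a <- ifelse(swap, gene_b, gene_a)
  b <- ifelse(swap, gene_a, gene_b)
  data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
}

pair_key <- function(gene_a, gene_b) paste(gene_a, gene_b, sep = "\r")

#' Percentage share of a count
#'
#' `100 * part / whole`, unrounded. Used throughout the report tables
#' (core-pair rates, roster shares, hub shares); display rounding happens
#' only at serialization time.
#'
#' @param part,whole numeric; `whole` must be positive.
#' @return numeric percentage(s).
#' @export
pct_share <- function(part, whole) {
  if (!is.numeric(part) || !is.numeric(whole) || any(whole <= 0)) {
    abort_input("pct_share needs numeric inputs with positive denominator")
  }
  100 * part / whole
}

#' Mean degree of a network from its edge and node counts
#'
#' In an undirected simple graph every edge contributes to two node degrees,
#' so the mean number of first-order neighbours is `2 * n_edges / n_nodes`.
#'
#' @param n_edges,n_nodes positive counts.
#' @return numeric mean degree.
#' @export
mean_degree <- function(n_edges, n_nodes) {
  if (!is_count(n_edges) || !is_count(n_nodes) || n_nodes < 1) {
    abort_input("mean_degree needs non-negative integer counts, n_nodes >= 1")
  }
  2 * n_edges / n_nodes
}
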