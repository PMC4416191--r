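#' Call core ceRNA pairs in an expression dataset
#'
#' Re-evaluates a set of optimal ceRNA pairs in another cohort: a pair is a
#' core pair there when both genes are measured and its Pearson correlation
#' is significantly positive (right-tail p below `alpha`). Core ceRNAs are
#' the genes incident to at least one core pair. Pairs with unmeasured or
#' constant genes are dropped and counted.
#'
#' @param optimal_pairs data.frame with canonical `gene_a`, `gene_b`.
#' @param expr gene expression matrix of the dataset (>= 3 samples).
#' @param alpha significance level in (0, 1).
#' @param label dataset label for reports.
#' @return object of class `core_set`: `label`, `alpha`, `n_samples`,
#'   `pairs` (core pairs with `r` and `p_right`), `genes`, and the counts
#'   of evaluable/dropped pairs.
#' @export
call_core_pairs <- function(optimal_pairs, expr, alpha = 0.05, label = "dataset") {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort_input("alpha must be in (0, 1)")
  }
  validate_expression_matrix(expr)
  if (ncol(expr) < 3L) abort_input("need at least 3 samples")
  evaluated <- pair_correlations(optimal_pairs, expr)
  n_dropped <- attr(evaluated, "n_unmeasured") + attr(evaluated, "n_constant")
  if (nrow(evaluated) == 0L) {
    warning("no optimal pair evaluable in ", label, call. = FALSE)
    core <- evaluated
    core$p_right <- numeric(0)
  } else {
    evaluated$p_right <- right_tail_pvalue(evaluated$r, ncol(expr))
    core <- evaluated[evaluated$p_right < alpha, , drop = FALSE]
    rownames(core) <- NULL
  }
  structure(
    list(label = label, alpha = alpha, n_samples = ncol(expr),
         pairs = core,
         genes = sort(unique(c(core$gene_a, core$gene_b))),
         n_evaluated = nrow(evaluated), n_dropped = n_dropped),
    class = "core_set"
  )
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("core_set '%s': %d core pairs (alpha = %g) over %d genes; %d pairs evaluated, %d dropped\n",
              x$label, nrow(x$pairs), x$alpha, length(x$genes),
              x$n_evaluated, x$n_dropped))
  invisible(x)
}

#' Venn membership counts of core ceRNA sets
#'
#' Tallies, for every non-empty intersection region of the datasets' core
#' gene sets, how many genes fall exactly in that region. Region codes are
#' `&`-joined dataset labels (e.g. `"GBM&OV"` holds the genes core in GBM
#' and OV but in no other dataset). Counts over all regions sum to the size
#' of the union.
#'
#' @param core_sets list of `core_set` objects (>= 2), or a named list of
#'   character vectors.
#' @return data.frame `region`, `n`, ordered by decreasing set count then
#'   label order.
#' @export
venn_membership <- function(core_sets) {
  if (length(core_sets) < 2L) abort_input("need at least 2 sets")
  sets <- lapply(core_sets, function(s) {
    if (inherits(s, "core_set")) s$genes else as.character(s)
  })
  labels <- vapply(seq_along(sets), function(i) {
    if (inherits(core_sets[[i]], "core_set")) core_sets[[i]]$label
    else if (!is.null(names(core_sets)) && nzchar(names(core_sets)[i])) names(core_sets)[i]
    else paste0("set", i)
  }, character(1L))
  universe <- sort(unique(unlist(sets)))
  if (length(universe) == 0L) {
    return(data.frame(region = character(), n = integer(),
                      stringsAsFactors = FALSE))
  }
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
  code <- apply(member, 1L, function(row) paste(labels[row], collapse = "&"))
  tab <- table(code)
  out <- data.frame(region = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  n_sets <- lengths(regmatches(out$region, gregexpr("&", out$region))) + 1L
  out <- out[order(-n_sets, out$region), ]
  rownames(out) <- NULL
  out
}

#' Top hub core ceRNAs
#'
#' Ranks the genes of a core network by degree (ties broken by gene id)
#' and returns the minimal prefix whose summed degrees reach `fraction` of
#' the total number of core pairs. Because every pair touches two genes, a
#' degree sum double-counts pairs; the achieved pair coverage of the
#' returned prefix is therefore reported alongside it.
#'
#' @param core a `core_set` (or a pair data.frame).
#' @param fraction target fraction of core pairs in (0, 1].
#' @return character vector of hub genes, with attributes `degrees`,
#'   `coverage` (summed degree / total pairs) and `fraction`.
#' @export
top_hub_core <- function(core, fraction = 0.10) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    abort_input("fraction must be in (0, 1]")
  }
  pairs <- if (inherits(core, "core_set")) core$pairs else core
  if (nrow(pairs) == 0L) abort_input("empty core set")
  net <- build_network(pairs)
  d <- net$degree
  ord <- order(-d, names(d))
  d <- d[ord]
  target <- fraction * net$n_edges
  cum <- cumsum(as.numeric(d))
  k <- which(cum >= target)[1L]
  hubs <- names(d)[seq_len(k)]
  structure(hubs,
            degrees = as.integer(d[seq_len(k)]),
            coverage = cum[k] / net$n_edges,
            fraction = fraction)
}

#' Population coefficient of variation, in percent
#'
#' `100 * sd_pop / mean`, where `sd_pop` divides by the number of values k
#' (not k - 1). This is the stability statistic used to compare
#' intra-function core pair and gene counts across cancer types.
#'
#' @param values numeric vector, length >= 2, positive mean.
#' @return CV in percent.
#' @export
cv_population <- function(values) {
  if (length(values) < 2L) abort_input("need at least 2 values")
  m <- mean(values)
  if (m <= 0) abort_input("mean must be positive")
  100 * sqrt(mean((values - m)^2)) / m
}

#' Cross-dataset ceRNA stability report
#'
#' Summarizes how the optimal ceRNA pair set behaves across expression
#' datasets: per-dataset core pair/gene counts and their share of the
#' optimal set, Venn membership of core ceRNAs, and — per functional gene
#' set — the intra-set core pair and gene counts with their across-dataset
#' coefficients of variation. The characteristic outcome is dynamic pair
#' counts (large CV) over a stable gene roster (small CV).
#'
#' @param optimal_pairs data.frame of optimal pairs (`gene_a`, `gene_b`).
#' @param core_sets list of `core_set` objects, one per dataset.
#' @param gene_sets optional named list of character vectors (e.g. from
#'   [read_gmt()]) for the stability table.
#' @return list of class `pan_cancer_report`: `dataset_summary`, `venn`,
#'   `stability` (NULL when no gene sets given).
#' @export
pan_cancer_report <- function(optimal_pairs, core_sets, gene_sets = NULL) {
  if (length(core_sets) == 0L) abort_input("need at least one core set")
  n_opt_pairs <- nrow(optimal_pairs)
  opt_genes <- sort(unique(c(optimal_pairs$gene_a, optimal_pairs$gene_b)))

  if (n_opt_pairs == 0L) {
    warning("empty optimal pair set: shares reported as NA", call. = FALSE)
  }
  share <- function(part, whole) {
    if (whole > 0) pct_share(part, whole) else NA_real_
  }
  dataset_summary <- do.call(rbind, lapply(core_sets, function(cs) {
    data.frame(dataset = cs$label,
               n_core_pairs = nrow(cs$pairs),
               pct_of_optimal_pairs = share(nrow(cs$pairs), n_opt_pairs),
               n_core_genes = length(cs$genes),
               pct_of_optimal_genes = share(length(cs$genes), length(opt_genes)),
               stringsAsFactors = FALSE)
  }))
  rownames(dataset_summary) <- NULL

  venn <- if (length(core_sets) >= 2L) venn_membership(core_sets) else NULL
  if (length(core_sets) < 2L) {
    warning("single dataset: Venn and CV columns unavailable", call. = FALSE)
  }

  stability <- NULL
  if (!is.null(gene_sets)) {
    stability <- do.call(rbind, lapply(names(gene_sets), function(nm) {
      gs <- gene_sets[[nm]]
      counts <- lapply(core_sets, function(cs) {
        intra <- cs$pairs$gene_a %in% gs & cs$pairs$gene_b %in% gs
        genes <- unique(c(cs$pairs$gene_a[intra], cs$pairs$gene_b[intra]))
        c(pairs = sum(intra), genes = length(genes))
      })
      pair_counts <- vapply(counts, `[[`, numeric(1L), "pairs")
      gene_counts <- vapply(counts, `[[`, numeric(1L), "genes")
      row <- data.frame(gene_set = nm, stringsAsFactors = FALSE)
      for (i in seq_along(core_sets)) {
        row[[paste0("pairs_", core_sets[[i]]$label)]] <- pair_counts[i]
        row[[paste0("genes_", core_sets[[i]]$label)]] <- gene_counts[i]
      }
      row$cv_pairs <- if (length(pair_counts) >= 2L && mean(pair_counts) > 0)
        cv_population(pair_counts) else NA_real_
      row$cv_genes <- if (length(gene_counts) >= 2L && mean(gene_counts) > 0)
        cv_population(gene_counts) else NA_real_
      row
    }))
    rownames(stability) <- NULL
  }

  structure(list(dataset_summary = dataset_summary, venn = venn,
                 stability = stability,
                 n_optimal_pairs = n_opt_pairs,
                 n_optimal_genes = length(opt_genes)),
            class = "pan_cancer_report")
}

#' @export
print.pan_cancer_report <- function(x, ...) {
  cat(sprintf("pan_cancer_report over %d optimal pairs / %d optimal ceRNAs\n",
              x$n_optimal_pairs, x$n_optimal_genes))
  print(x$dataset_summary)
  if (!is.null(x$stability)) {
    cat("stability (CV in percent):\n")
    print(x$stability)
  }
  invisible(x)
}
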