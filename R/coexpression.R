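#' Validate an expression matrix
#'
#' Expression matrices are numeric matrices of log2 expression values with
#' entity ids (genes or miRNAs) as row names and sample ids as column names.
#' Missing values are not allowed: impute or drop entities upstream.
#'
#' @param x numeric matrix.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) abort_input("expression must be a numeric matrix")
  if (nrow(x) == 0L || ncol(x) == 0L) abort_input("empty expression matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort_input("expression matrix needs entity row names and sample column names")
  }
  if (anyDuplicated(rownames(x))) abort_input("duplicate entity ids")
  if (anyDuplicated(colnames(x))) abort_input("duplicate sample ids")
  if (any(!is.finite(x))) abort_input("non-finite expression values")
  invisible(x)
}

#' Pearson correlation of two expression profiles
#'
#' Standard product-moment correlation, the package's measure of ceRNA
#' coexpression.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort_input("need equal-length vectors with at least 3 samples")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_input("undefined correlation: constant profile")
  }
  stats::cor(x, y)
}

#' One-sided (right-tail) p-value for a Pearson correlation
#'
#' Tests positive association under the null of zero correlation via the
#' exact t transform `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2`
#' degrees of freedom. Satisfies `p(r) + p(-r) = 1`.
#'
#' @param r correlation coefficient.
#' @param n number of samples (>= 3).
#' @return right-tail p-value in `[0, 1]`; `|r| = 1` returns the boundary
#'   value 0 (for r = 1) or 1 (for r = -1).
#' @export
right_tail_pvalue <- function(r, n) {
  if (!is.numeric(n) || any(n < 3)) abort_input("need n >= 3")
  if (any(abs(r) > 1)) abort_input("|r| > 1")
  tstat <- ifelse(abs(r) == 1, Inf * sign(r),
                  r * sqrt((n - 2) / (1 - r^2)))
  stats::pt(tstat, df = n - 2, lower.tail = FALSE)
}

#' Two-sample Kolmogorov-Smirnov comparison of correlation distributions
#'
#' Computes the K-S statistic D, the maximum vertical distance between the
#' two empirical cumulative distribution functions, and a two-sided
#' p-value (asymptotic by default; the groups compared here are typically
#' large). A p-value that underflows double precision is reported as 0 with
#' `underflow = TRUE`.
#'
#' @param a,b non-empty numeric vectors.
#' @param exact use the exact small-sample p-value instead of the
#'   asymptotic one.
#' @return list of class `ks_result`: `statistic`, `p_value`, `underflow`.
#' @export
ks_two_sample <- function(a, b, exact = FALSE) {
  if (length(a) == 0L || length(b) == 0L) abort_input("empty input to K-S test")
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  p <- unname(kt$p.value)
  structure(
    list(statistic = unname(kt$statistic),
         p_value = p,
         underflow = p < .Machine$double.xmin),
    class = "ks_result"
  )
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("two-sample K-S: D = %.4g, p = %.4g%s\n", x$statistic, x$p_value,
              if (x$underflow) " (underflow: below double precision)" else ""))
  invisible(x)
}

#' Quartile group labels
#'
#' Splits values into the four quartile strata: Q1 below the 25th
#' percentile, Q2 in [25th, 50th), Q3 in [50th, 75th), Q4 at or above the
#' 75th percentile. Percentiles are computed with linear interpolation
#' between order statistics (`stats::quantile` type 7); a value equal to a
#' boundary goes to the higher group.
#'
#' @param values numeric vector, length >= 4.
#' @param boundaries optional `(q25, q50, q75)` to apply instead of
#'   recomputing (e.g. boundaries from a reference cohort).
#' @return factor with levels `Q1..Q4`; attributes `boundaries` and
#'   `interpolation` record the cut points and convention.
#' @export
quartile_groups <- function(values, boundaries = NULL) {
  if (is.null(boundaries)) {
    if (length(values) < 4L) abort_input("need at least 4 values")
    boundaries <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  }
  if (length(unique(values)) < 4L) {
    warning("fewer than 4 distinct values: some quartile groups will be empty",
            call. = FALSE)
  }
  # direct comparison rather than cut(): boundaries may coincide on
  # discrete values, and ties at a boundary go to the higher group
  idx <- 1L + (values >= boundaries[1L]) + (values >= boundaries[2L]) +
    (values >= boundaries[3L])
  g <- factor(c("Q1", "Q2", "Q3", "Q4")[idx], levels = c("Q1", "Q2", "Q3", "Q4"))
  attr(g, "boundaries") <- boundaries
  attr(g, "interpolation") <- "linear between order statistics (type 7); ties to higher group"
  g
}

#' Mean miRNA-program expression of a ceRNA pair
#'
#' Averages, over the miRNAs of the shared program, each miRNA's mean log2
#' expression across samples. For complete data this equals the grand mean
#' of the miRP-by-sample block. Program members missing from the expression
#' matrix are dropped (their number is reported via the `n_missing`
#' attribute); a program with no measured member yields `NA`.
#'
#' @param mirp character vector of miRNA ids, or a comma-joined string.
#' @param mirna_expr miRNA expression matrix (see
#'   [validate_expression_matrix()]).
#' @return mean log2 expression (scalar), `NA` if no member is measured.
#' @export
mirp_expression <- function(mirp, mirna_expr) {
  validate_expression_matrix(mirna_expr)
  if (length(mirp) == 1L && grepl(",", mirp)) {
    mirp <- strsplit(mirp, ",", fixed = TRUE)[[1L]]
  }
  present <- mirp[mirp %in% rownames(mirna_expr)]
  out <- if (length(present) == 0L) NA_real_ else {
    mean(rowMeans(mirna_expr[present, , drop = FALSE]))
  }
  attr(out, "n_missing") <- length(mirp) - length(present)
  out
}

#' Expression-state labels for genes
#'
#' Labels each gene by its mean log2 expression rank across all genes:
#' low (L) for the 5th-35th percentile band, medium (M) for 35th-65th,
#' high (H) for 65th-95th. Genes in the bottom or top 5% are excluded as
#' likely background or saturation noise. A gene's percentile is
#' `100 * (rank - 1) / n` with ties ranked upward (`ties.method = "max"`),
#' so tied genes fall in the higher band; band intervals are half-open on
#' the right.
#'
#' @param gene_expr gene expression matrix, at least 20 genes.
#' @return named factor (levels `L`, `M`, `H`, `excluded`) over the genes.
#' @export
gene_states <- function(gene_expr) {
  validate_expression_matrix(gene_expr)
  if (nrow(gene_expr) < 20L) abort_input("need at least 20 genes for state bands")
  m <- rowMeans(gene_expr)
  pct <- 100 * (rank(m, ties.method = "max") - 1) / length(m)
  lab <- cut(pct, breaks = c(-Inf, 5, 35, 65, 95, Inf), right = FALSE,
             labels = c("excluded", "L", "M", "H", "excluded_top"))
  lab <- factor(ifelse(lab == "excluded_top", "excluded", as.character(lab)),
                levels = c("L", "M", "H", "excluded"))
  names(lab) <- rownames(gene_expr)
  lab
}

state_pair_label <- function(sa, sb) {
  lv <- c("L", "M", "H")
  ifelse(sa == "excluded" | sb == "excluded" | is.na(sa) | is.na(sb),
         "excluded",
         {
           ia <- match(sa, lv); ib <- match(sb, lv)
           hi <- pmax(ia, ib); lo <- pmin(ia, ib)
           paste(lv[hi], lv[lo], sep = "-")   # H before M before L
         })
}

#' Correlations of ceRNA pairs across samples
#'
#' Computes the Pearson correlation of each pair's gene expression profiles.
#' Pairs with an unmeasured or constant gene are dropped, with the counts
#' recorded in attributes `n_unmeasured` and `n_constant`.
#'
#' @param pairs data.frame with canonical `gene_a`, `gene_b` columns.
#' @param gene_expr gene expression matrix.
#' @return `pairs` with an added `r` column, restricted to computable pairs.
#' @export
pair_correlations <- function(pairs, gene_expr) {
  validate_expression_matrix(gene_expr)
  if (ncol(gene_expr) < 3L) abort_input("need at least 3 samples")
  measured <- pairs$gene_a %in% rownames(gene_expr) &
    pairs$gene_b %in% rownames(gene_expr)
  out <- pairs[measured, , drop = FALSE]
  sds <- apply(gene_expr, 1L, stats::sd)
  ok <- sds[out$gene_a] > 0 & sds[out$gene_b] > 0
  n_constant <- sum(!ok)
  out <- out[ok, , drop = FALSE]
  if (nrow(out) > 0L) {
    genes <- unique(c(out$gene_a, out$gene_b))
    cm <- stats::cor(t(gene_expr[genes, , drop = FALSE]))
    out$r <- cm[cbind(out$gene_a, out$gene_b)]
  } else {
    out$r <- numeric(0)
  }
  rownames(out) <- NULL
  attr(out, "n_unmeasured") <- sum(!measured)
  attr(out, "n_constant") <- n_constant
  out
}

#' Annotate ceRNA pairs with the four regulation-strength factors
#'
#' Attaches, per putative ceRNA pair: the Pearson correlation `r`, the miRP
#' expression level, quartile group labels for miRP size, binding-site count
#' and miRP expression, and the expression-state pair of the two genes
#' (H-H, H-M, ..., L-L, or `excluded` when either gene sits in the trimmed
#' bottom/top 5%). Pairs involving excluded genes keep their factor-1 to -3
#' labels; pairs whose miRP has no measured miRNA get `mirp_expr_group = NA`.
#'
#' @param pair_table a `cerna_pair_table` from [enumerate_cerna_pairs()], or
#'   its `pairs` data.frame.
#' @param gene_expr,mirna_expr expression matrices.
#' @return data.frame of class `factor_annotation`: the computable pairs
#'   with columns `r`, `mirp_expr`, `size_group`, `sites_group`,
#'   `mirp_expr_group`, `state_pair`; the non-ceRNA correlation vector is
#'   attached as attribute `non_cerna_r`.
#' @export
annotate_pairs <- function(pair_table, gene_expr, mirna_expr) {
  pairs <- if (inherits(pair_table, "cerna_pair_table")) pair_table$pairs else pair_table
  req <- c("gene_a", "gene_b", "mirp_size", "n_mirpbs", "mirp")
  if (!all(req %in% names(pairs))) {
    abort_input("pair table must have columns: ", paste(req, collapse = ", "))
  }
  ann <- pair_correlations(pairs, gene_expr)
  if (nrow(ann) == 0L) abort_input("no pair with both genes measured")

  validate_expression_matrix(mirna_expr)
  mir_means <- rowMeans(mirna_expr)
  ann$mirp_expr <- vapply(strsplit(ann$mirp, ",", fixed = TRUE), function(ms) {
    present <- ms[ms %in% names(mir_means)]
    if (length(present) == 0L) NA_real_ else mean(mir_means[present])
  }, numeric(1L))

  ann$size_group <- quartile_groups(ann$mirp_size)
  ann$sites_group <- quartile_groups(ann$n_mirpbs)
  measured_expr <- !is.na(ann$mirp_expr)
  grp <- rep(NA_character_, nrow(ann))
  if (sum(measured_expr) >= 4L) {
    grp[measured_expr] <- as.character(quartile_groups(ann$mirp_expr[measured_expr]))
  }
  ann$mirp_expr_group <- factor(grp, levels = c("Q1", "Q2", "Q3", "Q4"))

  st <- gene_states(gene_expr)
  ann$state_pair <- state_pair_label(as.character(st[ann$gene_a]),
                                     as.character(st[ann$gene_b]))

  non_r <- numeric(0)
  if (inherits(pair_table, "cerna_pair_table") &&
      nrow(pair_table$non_cerna_pairs) > 0L) {
    non <- pair_correlations(pair_table$non_cerna_pairs, gene_expr)
    non_r <- non$r
  }
  attr(ann, "non_cerna_r") <- non_r
  class(ann) <- c("factor_annotation", "data.frame")
  ann
}

#' Stratified K-S comparison of correlation distributions
#'
#' For each regulation-strength factor, partitions the annotated pairs into
#' its groups, and runs a two-sample K-S test between every pair of groups
#' and between each group and the non-ceRNA background. This is the
#' statistical core of the optimal-condition search: a factor matters when
#' the correlation CDFs of its strata separate.
#'
#' @param annotation a `factor_annotation` from [annotate_pairs()].
#' @param non_cerna_r optional numeric vector of non-ceRNA pair
#'   correlations; defaults to the vector attached to `annotation`.
#' @param factors which factors to stratify on.
#' @return data.frame with columns `factor`, `group_a`, `group_b`, `n_a`,
#'   `n_b`, `ks_D`, `ks_p`, `underflow`; group medians and sizes are
#'   attached as attribute `group_summary`.
#' @export
stratify_and_test <- function(annotation, non_cerna_r = NULL,
                              factors = c("mirp_size", "n_mirpbs",
                                          "mirp_expr", "cerna_state")) {
  if (!inherits(annotation, "factor_annotation")) {
    abort_input("annotation must come from annotate_pairs()")
  }
  if (is.null(non_cerna_r)) non_cerna_r <- attr(annotation, "non_cerna_r")
  factors <- match.arg(factors, several.ok = TRUE)
  col_of <- c(mirp_size = "size_group", n_mirpbs = "sites_group",
              mirp_expr = "mirp_expr_group", cerna_state = "state_pair")
  state_levels <- c("H-H", "H-M", "H-L", "M-M", "M-L", "L-L")

  rows <- list()
  summaries <- list()
  for (f in factors) {
    g <- annotation[[col_of[[f]]]]
    if (f == "cerna_state") {
      g <- factor(g, levels = state_levels)   # drops 'excluded'
    }
    keep <- !is.na(g)
    gk <- droplevels(g[keep])
    rk <- annotation$r[keep]
    lv <- levels(gk)
    groups <- split(rk, gk)
    summaries[[f]] <- data.frame(
      factor = f, group = lv,
      n = vapply(groups, length, integer(1L)),
      median_r = vapply(groups, function(v) if (length(v)) stats::median(v) else NA_real_,
                        numeric(1L)),
      row.names = NULL, stringsAsFactors = FALSE
    )
    cmp <- list()
    if (length(lv) >= 2L) {
      idx <- utils::combn(seq_along(lv), 2L)
      cmp <- lapply(seq_len(ncol(idx)), function(j) lv[idx[, j]])
    }
    if (length(non_cerna_r) > 0L) {
      cmp <- c(cmp, lapply(lv, function(l) c(l, "non_ceRNA")))
    }
    for (pr in cmp) {
      va <- groups[[pr[1L]]]
      vb <- if (pr[2L] == "non_ceRNA") non_cerna_r else groups[[pr[2L]]]
      if (length(va) == 0L || length(vb) == 0L) {
        warning(sprintf("empty group in factor %s: %s vs %s skipped",
                        f, pr[1L], pr[2L]), call. = FALSE)
        next
      }
      ks <- ks_two_sample(va, vb)
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, group_a = pr[1L], group_b = pr[2L],
        n_a = length(va), n_b = length(vb),
        ks_D = ks$statistic, ks_p = ks$p_value, underflow = ks$underflow,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "group_summary") <- do.call(rbind, summaries)
  out
}
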