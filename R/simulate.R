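#' Simulation parameters for synthetic ceRNA data
#'
#' Bundles the knobs of the synthetic generator. Genes sharing targeting
#' miRNAs are coupled through the miRNAs' across-sample fluctuations, so
#' shared-program size and site counts translate into pairwise
#' coexpression with a known closed form (see
#' [expected_pair_correlation()]).
#'
#' @param G,M,S gene, miRNA and sample counts.
#' @param density probability that a miRNA targets a gene.
#' @param p_site geometric parameter of the per-edge site-count law
#'   (`1 + rgeom(p_site)`, support >= 1).
#' @param lambda coupling strength per binding site (log2 gene units per
#'   log2 miRNA unit).
#' @param sigma_x miRNA across-sample standard deviation.
#' @param sigma_eps gene residual standard deviation.
#' @param mu_mir,sd_mir miRNA baseline mean and spread (log2).
#' @param mu_gene,sd_gene gene baseline mean and spread (log2).
#' @param seed integer master seed; all generator stages derive their
#'   substreams from it, so a fixed seed gives bit-identical output.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(G = 20L, M = 6L, S = 30L, density = 0.3,
                       p_site = 0.5, lambda = 0.25, sigma_x = 1,
                       sigma_eps = 1, mu_mir = 7, sd_mir = 0.5,
                       mu_gene = 8, sd_gene = 1.5, seed = 1L) {
  if (!is_count(G) || !is_count(M) || !is_count(S) || G < 1 || M < 1 || S < 1) {
    abort_input("G, M, S must be positive integers")
  }
  if (!is.numeric(density) || density < 0 || density > 1) {
    abort_input("density must be in [0, 1]")
  }
  if (p_site <= 0 || p_site > 1) abort_input("p_site must be in (0, 1]")
  if (any(c(sigma_x, sigma_eps, sd_mir, sd_gene) < 0)) {
    abort_input("standard deviations must be >= 0")
  }
  if (!is_count(abs(seed))) abort_input("seed must be an integer")
  structure(
    list(G = as.integer(G), M = as.integer(M), S = as.integer(S),
         density = density, p_site = p_site, lambda = lambda,
         sigma_x = sigma_x, sigma_eps = sigma_eps,
         mu_mir = mu_mir, sd_mir = sd_mir,
         mu_gene = mu_gene, sd_gene = sd_gene, seed = as.integer(seed)),
    class = "sim_params"
  )
}

sim_gene_ids <- function(G) sprintf("g%03d", seq_len(G))
sim_mirna_ids <- function(M) sprintf("mir%02d", seq_len(M))

#' Generate a random miRNA-target matrix
#'
#' Draws each targeting edge independently with probability `density`;
#' where an edge exists the site count follows the shifted geometric law
#' `1 + Geom(p_site)`.
#'
#' @param params a `sim_params`.
#' @return a `target_matrix`.
#' @export
generate_target_matrix <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  if (params$density * params$G * params$M < 1) {
    warning("expected edge count below 1: matrix likely empty", call. = FALSE)
  }
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(params$seed)
  tmat <- matrix(stats::rbinom(params$G * params$M, 1L, params$density),
                 nrow = params$G, ncol = params$M)
  s <- matrix(0L, params$G, params$M)
  n_edge <- sum(tmat)
  if (n_edge > 0L) {
    s[tmat == 1L] <- 1L + stats::rgeom(n_edge, params$p_site)
  }
  dimnames(s) <- list(sim_gene_ids(params$G), sim_mirna_ids(params$M))
  new_target_matrix(rownames(s), colnames(s), s)
}

#' Generate coupled gene and miRNA expression matrices
#'
#' The generative model: each miRNA has profile
#' `x[m, s] = mu_m + u[m, s]` with baseline `mu_m ~ N(mu_mir, sd_mir^2)`
#' and fluctuation `u ~ N(0, sigma_x^2)`; each gene has profile
#' `y[g, s] = b_g - lambda * sum_m s[g, m] * u[m, s] + eps[g, s]` with
#' baseline `b_g ~ N(mu_gene, sd_gene^2)` and noise
#' `eps ~ N(0, sigma_eps^2)`. Coupling acts on the centred miRNA
#' fluctuation, so the miRNA baseline does not shift gene means. Genes
#' sharing miRNAs become positively correlated through the shared `u`
#' terms, while each gene is negatively correlated with its own targeting
#' miRNAs — both the direct repression and the indirect ceRNA coupling of
#' the competition model.
#'
#' @param tm a `target_matrix` (typically from
#'   [generate_target_matrix()]).
#' @param params the same `sim_params`.
#' @return list with `gene_expr`, `mirna_expr` (matrices, entities x
#'   samples) and `truth` (list: `mirna_baseline`, `gene_baseline`, and
#'   `expected_r` for every putative pair).
#' @export
generate_expression <- function(tm, params) {
  stopifnot(inherits(params, "sim_params"))
  validate_target_matrix(tm)
  G <- length(tm$gene_ids); M <- length(tm$mirna_ids); S <- params$S
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(params$seed + 1L)   # expression substream
  mu_m <- stats::rnorm(M, params$mu_mir, params$sd_mir)
  u <- matrix(stats::rnorm(M * S, 0, params$sigma_x), M, S)
  x <- mu_m + u
  b_g <- stats::rnorm(G, params$mu_gene, params$sd_gene)
  eps <- matrix(stats::rnorm(G * S, 0, params$sigma_eps), G, S)
  y <- b_g - params$lambda * (tm$s %*% u) + eps
  sample_ids <- sprintf("s%03d", seq_len(S))
  dimnames(x) <- list(tm$mirna_ids, sample_ids)
  dimnames(y) <- list(tm$gene_ids, sample_ids)
  truth <- list(
    mirna_baseline = stats::setNames(mu_m, tm$mirna_ids),
    gene_baseline = stats::setNames(b_g, tm$gene_ids),
    expected_r = expected_pair_correlation(tm, params)
  )
  list(gene_expr = y, mirna_expr = x, truth = truth)
}

#' Closed-form expected pair correlation under the synthetic model
#'
#' Under the linear generative model the covariance of two gene profiles is
#' `lambda^2 * sigma_x^2 * sum_m s[a, m] * s[b, m]` and each gene's
#' variance is `lambda^2 * sigma_x^2 * sum_m s[g, m]^2 + sigma_eps^2`,
#' giving the expected correlation in closed form. For a pair coupled by a
#' single shared miRNA with one site on each gene and no other targets this
#' reduces to `lambda^2 sigma_x^2 / (lambda^2 sigma_x^2 + sigma_eps^2)`.
#'
#' @param tm a `target_matrix`.
#' @param params a `sim_params`.
#' @param pairs optional data.frame (`gene_a`, `gene_b`); defaults to all
#'   putative ceRNA pairs of `tm`.
#' @return data.frame `gene_a`, `gene_b`, `expected_r`.
#' @export
expected_pair_correlation <- function(tm, params, pairs = NULL) {
  validate_target_matrix(tm)
  if (is.null(pairs)) {
    if (length(tm$gene_ids) < 2L) {
      return(data.frame(gene_a = character(), gene_b = character(),
                        expected_r = numeric(), stringsAsFactors = FALSE))
    }
    pt <- enumerate_cerna_pairs(tm, non_cerna = "none")
    pairs <- pt$pairs[, c("gene_a", "gene_b")]
  }
  if (nrow(pairs) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      expected_r = numeric(), stringsAsFactors = FALSE))
  }
  k2 <- params$lambda^2 * params$sigma_x^2
  var_g <- k2 * rowSums(tm$s^2) + params$sigma_eps^2
  cov_ab <- k2 * rowSums(tm$s[pairs$gene_a, , drop = FALSE] *
                           tm$s[pairs$gene_b, , drop = FALSE])
  data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
             expected_r = cov_ab / sqrt(var_g[pairs$gene_a] * var_g[pairs$gene_b]),
             stringsAsFactors = FALSE)
}

sim_presets <- function() {
  list(
    # fast end-to-end smoke scale
    tiny = sim_params(G = 20L, M = 6L, S = 30L, density = 0.3, p_site = 0.5,
                      lambda = 0.25, seed = 101L),
    # no coupling: null calibration
    null = sim_params(G = 40L, M = 10L, S = 60L, density = 0.3, p_site = 0.5,
                      lambda = 0, seed = 202L),
    # shared-program sizes spanning all four quartiles, coupling on
    graded = sim_params(G = 120L, M = 40L, S = 120L, density = 0.35,
                        p_site = 0.5, lambda = 0.15, seed = 303L)
  )
}

#' Write a synthetic fixture suite to disk
#'
#' Generates a complete input set — target table, gene and miRNA expression
#' matrices, per-pair ground-truth correlations, random "function" gene
#' sets, and the parameters — in the exact dialects the package readers
#' consume. Presets: `tiny` (20 genes x 6 miRNAs x 30 samples, for fast
#' end-to-end runs), `null` (coupling ablated, for calibration) and
#' `graded` (shared-program sizes spanning all four quartiles with coupling
#' on, so factor-stratification trends are recoverable). Reruns with the
#' same preset and seed are byte-identical.
#'
#' @param preset one of `"tiny"`, `"null"`, `"graded"`.
#' @param dir output directory (created if needed).
#' @param seed optional integer overriding the preset's seed.
#' @return named list of file paths, invisibly; the realized `sim_params`
#'   are attached as attribute `params`.
#' @export
make_fixture_suite <- function(preset = c("tiny", "null", "graded"), dir,
                               seed = NULL) {
  preset <- match.arg(preset)
  params <- sim_presets()[[preset]]
  if (!is.null(seed)) params$seed <- as.integer(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  tm <- generate_target_matrix(params)
  sim <- generate_expression(tm, params)

  # split site counts into the two conservation classes deterministically
  edges <- which(tm$s >= 1L, arr.ind = TRUE)
  s_val <- tm$s[edges]
  records <- data.frame(
    gene_id = tm$gene_ids[edges[, 1L]],
    mirna_id = tm$mirna_ids[edges[, 2L]],
    conserved_sites = as.integer(ceiling(s_val / 2)),
    poorly_conserved_sites = as.integer(floor(s_val / 2)),
    stringsAsFactors = FALSE
  )
  records <- records[order(records$gene_id, records$mirna_id), ]

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(params$seed + 2L)   # gene-set substream
  n_sets <- 3L
  gene_sets <- stats::setNames(lapply(seq_len(n_sets), function(i) {
    sort(sample(tm$gene_ids, max(5L, round(length(tm$gene_ids) / 4))))
  }), sprintf("synthetic_function_%d", seq_len(n_sets)))

  paths <- list(
    targets = file.path(dir, "targets.tsv"),
    gene_expr = file.path(dir, "gene_expr.tsv"),
    mirna_expr = file.path(dir, "mirna_expr.tsv"),
    truth = file.path(dir, "truth_pairs.tsv"),
    gene_sets = file.path(dir, "functions.gmt"),
    params = file.path(dir, "params.yaml")
  )
  write_targets(records, paths$targets)
  write_expression(sim$gene_expr, paths$gene_expr)
  write_expression(sim$mirna_expr, paths$mirna_expr)
  write_tsv(sim$truth$expected_r, paths$truth)
  write_gmt(gene_sets, paths$gene_sets)
  yaml::write_yaml(c(list(preset = preset), unclass(params)), paths$params)
  attr(paths, "params") <- params
  invisible(paths)
}
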