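make_coupled_expr <- function(pairs_n = 6L, S = 80L, rho = 0.8, seed = 1L) {
  # pairs of genes sharing a latent factor with coupling sqrt(rho)
  set.seed(seed)
  genes <- character(0); vals <- NULL
  for (i in seq_len(pairs_n)) {
    z <- rnorm(S)
    a <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(S)
    b <- sqrt(rho) * z + sqrt(1 - rho) * rnorm(S)
    genes <- c(genes, sprintf("p%02da", i), sprintf("p%02db", i))
    vals <- rbind(vals, a, b)
  }
  dimnames(vals) <- list(genes, sprintf("s%03d", seq_len(S)))
  vals
}

test_that("core pairs require significantly positive correlation", {
  S <- 100L
  set.seed(2)
  z <- rnorm(S)
  expr <- rbind(
    pos_a = z + 0.3 * rnorm(S),
    pos_b = z + 0.3 * rnorm(S),
    neg_a = z + 0.3 * rnorm(S),
    neg_b = -z + 0.3 * rnorm(S)
  )
  colnames(expr) <- sprintf("s%03d", 1:S)
  pairs <- data.frame(gene_a = c("pos_a", "neg_a"),
                      gene_b = c("pos_b", "neg_b"),
                      stringsAsFactors = FALSE)
  core <- call_core_pairs(pairs, expr, alpha = 0.05, label = "toy")
  expect_equal(nrow(core$pairs), 1L)
  expect_equal(core$pairs$gene_a, "pos_a")     # strong negative r is dropped
  expect_setequal(core$genes, c("pos_a", "pos_b"))
  expect_equal(core$n_evaluated, 2L)

  # unmeasured genes are dropped and counted
  pairs2 <- rbind(pairs, data.frame(gene_a = "ghost", gene_b = "pos_a"))
  core2 <- call_core_pairs(pairs2, expr, label = "toy")
  expect_equal(core2$n_dropped, 1L)
  expect_error(call_core_pairs(pairs, expr, alpha = 1.5), "alpha")
})

test_that("core sets are monotone in alpha", {
  expr <- make_coupled_expr(pairs_n = 10L, rho = 0.2, seed = 8L)
  pairs <- data.frame(gene_a = sprintf("p%02da", 1:10),
                      gene_b = sprintf("p%02db", 1:10),
                      stringsAsFactors = FALSE)
  keys <- function(cs) paste(cs$pairs$gene_a, cs$pairs$gene_b)
  c1 <- call_core_pairs(pairs, expr, alpha = 0.01)
  c2 <- call_core_pairs(pairs, expr, alpha = 0.10)
  expect_true(all(keys(c1) %in% keys(c2)))
})

test_that("venn membership matches the bitmask oracle", {
  simple <- venn_membership(list(A = c("a", "b"), B = c("b", "c")))
  expect_equal(simple$n[simple$region == "A&B"], 1L)
  expect_equal(simple$n[simple$region == "A"], 1L)
  expect_equal(simple$n[simple$region == "B"], 1L)

  same <- venn_membership(list(X = c("a", "b"), Y = c("a", "b")))
  expect_equal(same$region, "X&Y")
  expect_equal(same$n, 2L)

  set.seed(14)
  sets <- lapply(1:4, function(i) sample(letters, sample(5:20, 1L)))
  names(sets) <- paste0("D", 1:4)
  got <- venn_membership(sets)
  expect_equal(sum(got$n), length(unique(unlist(sets))))
  oracle <- oracle_venn(sets)
  # compare region-by-region: translate bitmask to label codes
  for (code in names(oracle)) {
    labs <- paste(names(sets)[strsplit(code, "")[[1]] == "1"], collapse = "&")
    expect_equal(got$n[got$region == labs], unname(oracle[code]),
                 info = labs)
  }
  # permutation invariance of dataset order
  perm <- venn_membership(sets[c(3, 1, 4, 2)])
  expect_equal(sum(perm$n), sum(got$n))
  expect_equal(nrow(perm), nrow(got))
  expect_error(venn_membership(list(A = "a")), "at least 2")
})

test_that("top hub core takes the minimal degree-ranked prefix", {
  star <- data.frame(gene_a = "hub", gene_b = sprintf("leaf%d", 1:9),
                     stringsAsFactors = FALSE)
  hubs <- top_hub_core(star, fraction = 0.10)
  expect_equal(as.character(hubs), "hub")
  expect_equal(attr(hubs, "coverage"), 9 / 9)

  # path a-b-c at fraction 1: b's degree 2 already reaches E = 2
  path <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                     stringsAsFactors = FALSE)
  h2 <- top_hub_core(path, fraction = 1.0)
  expect_equal(as.character(h2), "b")
  expect_equal(attr(h2, "degrees"), 2L)

  # equal degrees: deterministic lexicographic prefix
  ring <- data.frame(gene_a = c("a", "b", "c"), gene_b = c("b", "c", "a"),
                     stringsAsFactors = FALSE)
  h3 <- top_hub_core(ring, fraction = 0.5)
  expect_equal(as.character(h3), "a")
  expect_error(top_hub_core(star, fraction = 0), "fraction")
  expect_error(top_hub_core(star, fraction = 1.2), "fraction")
})

test_that("population CV reproduces the printed stability values", {
  # cross-cancer intra-function counts from the published stability table
  expect_equal(cv_population(c(7152, 6235, 3961, 2755)), 34.85,
               tolerance = 0.005 / 34.85)
  expect_equal(cv_population(c(261, 258, 254, 247)), 2.06,
               tolerance = 0.005 / 2.06)
  expect_equal(cv_population(c(4418, 3836, 2379, 2049)), 31.08,
               tolerance = 0.005 / 31.08)
  expect_equal(cv_population(c(200, 197, 193, 191)), 1.79,
               tolerance = 0.005 / 1.79)

  # divide-by-k oracle written out longhand
  v <- c(7152, 6235, 3961, 2755)
  oracle <- 100 * sqrt(sum((v - mean(v))^2) / length(v)) / mean(v)
  expect_equal(cv_population(v), oracle)

  expect_equal(cv_population(c(5, 5, 5)), 0)
  expect_equal(cv_population(c(10, 20, 30) * 1000),
               cv_population(c(10, 20, 30)))   # scale invariance
  expect_error(cv_population(7), "at least 2")
  expect_error(cv_population(c(-5, 3)), "mean")
})

test_that("pan-cancer report computes shares, venn and stability rows", {
  pairs <- data.frame(gene_a = sprintf("p%02da", 1:10),
                      gene_b = sprintf("p%02db", 1:10),
                      stringsAsFactors = FALSE)
  exprA <- make_coupled_expr(10L, rho = 0.6, seed = 3L)
  exprB <- make_coupled_expr(10L, rho = 0.0, seed = 4L)
  csA <- call_core_pairs(pairs, exprA, label = "A")
  csB <- call_core_pairs(pairs, exprB, label = "B")
  gene_sets <- list(fn1 = c(sprintf("p%02da", 1:5), sprintf("p%02db", 1:5)))
  rep <- pan_cancer_report(pairs, list(csA, csB), gene_sets)

  expect_equal(rep$dataset_summary$pct_of_optimal_pairs,
               100 * c(nrow(csA$pairs), nrow(csB$pairs)) / 10)
  expect_equal(rep$dataset_summary$n_core_genes,
               c(length(csA$genes), length(csB$genes)))
  expect_equal(sum(rep$venn$n), length(union(csA$genes, csB$genes)))
  expect_equal(rep$stability$pairs_A,
               sum(csA$pairs$gene_a %in% gene_sets$fn1 &
                     csA$pairs$gene_b %in% gene_sets$fn1))
  # coupled dataset dominates the ablated one
  expect_gt(nrow(csA$pairs), nrow(csB$pairs))
})

test_that("coupling ablation rewires pairs but keeps the gene roster", {
  # dataset A: every gene coupled to both partners; dataset B: one partner
  # link retained per gene, the rest ablated. Pairs collapse, genes persist.
  S <- 120L
  set.seed(6)
  n_tri <- 8L
  gene_ids <- as.vector(vapply(1:n_tri, function(i)
    sprintf("t%02d%s", i, c("x", "y", "z")), character(3L)))
  mk <- function(keep_all) {
    vals <- NULL
    for (i in 1:n_tri) {
      if (keep_all) {
        # one common factor couples all three pairs of the triple
        w <- rnorm(S)
        x <- w + 0.4 * rnorm(S); y <- w + 0.4 * rnorm(S); z <- w + 0.4 * rnorm(S)
      } else {
        # chain coupling only: x-y and y-z stay, x-z is ablated,
        # yet every gene keeps >= 1 coupled partner
        z1 <- rnorm(S); z2 <- rnorm(S)
        x <- z1 + 0.4 * rnorm(S)
        y <- (z1 + z2) / sqrt(2) + 0.4 * rnorm(S)
        z <- z2 + 0.4 * rnorm(S)
      }
      vals <- rbind(vals, x, y, z)
    }
    dimnames(vals) <- list(gene_ids, sprintf("s%03d", 1:S))
    vals
  }
  # triangle pairs x-y, y-z, x-z per triple
  pairs <- do.call(rbind, lapply(1:n_tri, function(i) {
    g <- sprintf("t%02d%s", i, c("x", "y", "z"))
    data.frame(gene_a = c(g[1], g[2], g[1]), gene_b = c(g[2], g[3], g[3]),
               stringsAsFactors = FALSE)
  }))
  csA <- call_core_pairs(pairs, mk(TRUE), label = "full")
  csB <- call_core_pairs(pairs, mk(FALSE), label = "ablated")
  expect_gt(nrow(csA$pairs), nrow(csB$pairs))
  # roster stability: nearly all genes stay core through >= 1 partner
  expect_gte(length(csB$genes), 0.9 * length(csA$genes))
})
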