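test_that("build_target_matrix accumulates records and sets the indicator", {
  tm <- build_target_matrix(data.frame(
    gene_id = "g1", mirna_id = "m1",
    conserved_sites = 1L, poorly_conserved_sites = 0L))
  expect_equal(unname(tm$t["g1", "m1"]), 1L)
  expect_equal(unname(tm$s["g1", "m1"]), 1L)

  # conserved and poorly conserved rows for the same edge are summed
  tm2 <- build_target_matrix(data.frame(
    gene_id = c("g1", "g1"), mirna_id = c("m1", "m1"),
    conserved_sites = c(1L, 0L), poorly_conserved_sites = c(1L, 2L)))
  expect_equal(unname(tm2$s["g1", "m1"]), 4L)
  expect_equal(unname(tm2$t["g1", "m1"]), 1L)

  # a zero-site record contributes nothing but does not invalidate the table
  tm3 <- build_target_matrix(data.frame(
    gene_id = c("g1", "g2"), mirna_id = c("m1", "m1"),
    conserved_sites = c(0L, 2L), poorly_conserved_sites = c(0L, 0L)))
  expect_equal(unname(tm3$t["g1", "m1"]), 0L)
  expect_equal(unname(tm3$s["g1", "m1"]), 0L)
  expect_silent(validate_target_matrix(tm3))
})

test_that("build_target_matrix rejects invalid input", {
  expect_error(build_target_matrix(data.frame(
    gene_id = "g1", mirna_id = "m1",
    conserved_sites = -1L, poorly_conserved_sites = 0L)), "negative")
  expect_error(build_target_matrix(data.frame(
    gene_id = character(), mirna_id = character(),
    conserved_sites = integer(), poorly_conserved_sites = integer())),
    "empty")
  expect_error(build_target_matrix(data.frame(
    gene_id = "g1", mirna_id = "m1",
    conserved_sites = 0L, poorly_conserved_sites = 0L)),
    "at least one binding site")
})

test_that("pair enumeration matches the targeting structure on worked cases", {
  # g1 and g2 share m1; g3 is targeted only by m2
  s <- matrix(c(1L, 1L, 0L,
                0L, 0L, 1L), nrow = 3L,
              dimnames = list(c("g1", "g2", "g3"), c("m1", "m2")))
  pt <- enumerate_cerna_pairs(tm_from_s(s))
  expect_equal(nrow(pt$pairs), 1L)
  expect_equal(pt$pairs$gene_a, "g1")
  expect_equal(pt$pairs$gene_b, "g2")
  expect_equal(pt$pairs$mirp_size, 1L)
  expect_equal(pt$pairs$mirp, "m1")
  expect_equal(nrow(pt$non_cerna_pairs), 2L)

  # identity targeting: no sharing at all
  s_id <- diag(3L)
  dimnames(s_id) <- list(paste0("g", 1:3), paste0("m", 1:3))
  pt_id <- enumerate_cerna_pairs(tm_from_s(s_id))
  expect_equal(nrow(pt_id$pairs), 0L)
  expect_equal(nrow(pt_id$non_cerna_pairs), 3L)

  expect_error(
    enumerate_cerna_pairs(build_target_matrix(data.frame(
      gene_id = "g1", mirna_id = "m1",
      conserved_sites = 1L, poorly_conserved_sites = 0L))),
    "at least two genes")
})

test_that("pair enumeration equals the brute-force set-intersection oracle", {
  for (seed in c(7L, 23L, 99L, 123L, 2024L)) {
    set.seed(seed)
    rt <- random_target_matrix(G = sample(4:12, 1L), M = sample(2:8, 1L),
                               density = runif(1, 0.2, 0.7), seed = seed)
    if (all(rowSums(rt$s) == 0)) next
    # drop all-zero genes: the record form cannot carry them
    keep <- rowSums(rt$s) > 0
    smat <- rt$s[keep, , drop = FALSE]
    keep_m <- colSums(smat) > 0
    smat <- smat[, keep_m, drop = FALSE]
    if (nrow(smat) < 2L) next
    pt <- enumerate_cerna_pairs(tm_from_s(smat))
    expected <- oracle_enumerate((smat >= 1L) * 1L, smat)
    got <- pt$pairs[, c("gene_a", "gene_b", "mirp_size", "n_mirpbs")]
    rownames(got) <- rownames(expected) <- NULL
    expect_equal(got, expected, info = paste("seed", seed))
    # count conservation over the exhaustive enumeration
    G <- nrow(smat)
    expect_equal(nrow(pt$pairs) + nrow(pt$non_cerna_pairs), G * (G - 1) / 2)
  }
})

test_that("adding a shared miRNA record never decreases pair statistics", {
  s <- matrix(c(2L, 1L, 0L,
                1L, 3L, 0L,
                0L, 0L, 1L), nrow = 3L, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("m1", "m2", "m3")))
  before <- enumerate_cerna_pairs(tm_from_s(s))$pairs
  s_plus <- s
  s_plus["g1", "m3"] <- 2L   # m3 now shared by g1 and g3; (g1,g2) untouched
  after <- enumerate_cerna_pairs(tm_from_s(s_plus))$pairs
  b12 <- before[before$gene_a == "g1" & before$gene_b == "g2", ]
  a12 <- after[after$gene_a == "g1" & after$gene_b == "g2", ]
  expect_gte(a12$mirp_size, b12$mirp_size)
  expect_gte(a12$n_mirpbs, b12$n_mirpbs)
  expect_true("g3" %in% after$gene_b[after$gene_a == "g1"])
})

test_that("non-ceRNA pairs can be reservoir-sampled reproducibly", {
  rt <- random_target_matrix(G = 12L, M = 3L, density = 0.25, seed = 5L)
  keep <- rowSums(rt$s) > 0
  smat <- rt$s[keep, colSums(rt$s[keep, , drop = FALSE]) > 0, drop = FALSE]
  tm <- tm_from_s(smat)
  full <- enumerate_cerna_pairs(tm, non_cerna = "exhaustive")
  n_non <- nrow(full$non_cerna_pairs)
  skip_if(n_non < 3L)
  s1 <- enumerate_cerna_pairs(tm, non_cerna = "sample", n_sample = 2L, seed = 11L)
  s2 <- enumerate_cerna_pairs(tm, non_cerna = "sample", n_sample = 2L, seed = 11L)
  expect_equal(s1$non_cerna_pairs, s2$non_cerna_pairs)
  expect_equal(nrow(s1$non_cerna_pairs), 2L)
  expect_equal(s1$non_cerna_seed, 11L)
  # sampled pairs are a subset of the exhaustive ones
  expect_true(all(paste(s1$non_cerna_pairs$gene_a, s1$non_cerna_pairs$gene_b) %in%
                    paste(full$non_cerna_pairs$gene_a, full$non_cerna_pairs$gene_b)))
})

test_that("compute_mirpbs sums shared-miRNA sites on both genes only", {
  s <- matrix(c(1L, 0L, 0L,
                1L, 0L, 5L), nrow = 2L, byrow = TRUE,
              dimnames = list(c("ga", "gb"), c("m1", "m2", "m3")))
  tm <- tm_from_s(s)
  # single shared miRNA, one site each: the global minimum of 2
  expect_equal(compute_mirpbs("ga", "gb", "m1", tm), 2L)

  s2 <- matrix(c(2L, 1L, 0L,
                 1L, 3L, 5L), nrow = 2L, byrow = TRUE,
               dimnames = list(c("ga", "gb"), c("m1", "m2", "m3")))
  tm2 <- tm_from_s(s2)
  # hand sum 2+1 (ga) + 1+3 (gb) = 7; gb's 5 sites for unshared m3 ignored
  expect_equal(compute_mirpbs("ga", "gb", c("m1", "m2"), tm2), 7L)
  expect_equal(compute_mirpbs("ga", "gb", "m1,m2", tm2), 7L)
  # m3 is not shared: claiming it in the miRP is an inconsistency
  expect_error(compute_mirpbs("ga", "gb", c("m1", "m3"), tm2), "inconsistent")
})

test_that("transcript collapse keeps the max-site transcript, ties by id", {
  rec <- data.frame(
    gene_id = c("g1", "g1", "g1", "g2", "g2"),
    transcript_id = c("t2", "t2", "t1", "tB", "tA"),
    mirna_id = c("m1", "m2", "m1", "m1", "m1"),
    conserved_sites = c(2L, 1L, 1L, 1L, 1L),
    poorly_conserved_sites = 0L,
    stringsAsFactors = FALSE
  )
  out <- collapse_transcripts(rec)
  # g1: t2 has 3 total sites vs t1's 1 -> keep t2's two records
  expect_equal(sum(out$gene_id == "g1"), 2L)
  expect_setequal(out$mirna_id[out$gene_id == "g1"], c("m1", "m2"))
  # g2: tied totals -> lexicographically smallest transcript (tA)
  expect_equal(out$conserved_sites[out$gene_id == "g2"], 1L)
  expect_equal(nrow(out[out$gene_id == "g2", ]), 1L)
})

test_that("co-occurrence symmetry holds on a random fixture", {
  rt <- random_target_matrix(G = 10L, M = 6L, density = 0.5, seed = 77L)
  P <- tcrossprod(rt$t)
  expect_true(isSymmetric(P))
  smat <- rt$s[rowSums(rt$s) > 0, , drop = FALSE]
  smat <- smat[, colSums(smat) > 0, drop = FALSE]
  pt <- enumerate_cerna_pairs(tm_from_s(smat))
  expect_equal(pt$pairs$mirp_size,
               P[cbind(pt$pairs$gene_a, pt$pairs$gene_b)])
  # every pair respects the 2-per-shared-miRNA floor
  expect_true(all(pt$pairs$n_mirpbs >= 2L * pt$pairs$mirp_size))
})
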