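# Independent brute-force oracles used across the suite. These stay naive
# on purpose: double loops and pooled-point scans, never the package's own
# code paths.

# enumerate putative ceRNA pairs by intersecting per-gene target sets
oracle_enumerate <- function(tmat, smat) {
  genes <- rownames(tmat)
  out <- list()
  for (i in seq_len(nrow(tmat) - 1L)) {
    for (j in seq((i + 1L), nrow(tmat))) {
      shared <- which(tmat[i, ] == 1L & tmat[j, ] == 1L)
      if (length(shared) > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          gene_a = min(genes[i], genes[j]),
          gene_b = max(genes[i], genes[j]),
          mirp_size = length(shared),
          n_mirpbs = sum(smat[i, shared] + smat[j, shared]),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      mirp_size = integer(), n_mirpbs = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$gene_a, res$gene_b), , drop = FALSE]
}

# K-S statistic as the maximum ECDF gap over all pooled sample points
oracle_ks_D <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(x) mean(a <= x) - mean(b <= x), numeric(1L))))
}

# Venn region counts by per-element membership bitmask
oracle_venn <- function(sets) {
  universe <- sort(unique(unlist(sets)))
  mask <- vapply(universe, function(g) {
    paste(vapply(sets, function(s) g %in% s, logical(1L)) + 0L, collapse = "")
  }, character(1L))
  table(mask)
}

# random binary target structure with geometric site counts
random_target_matrix <- function(G, M, density = 0.4, seed) {
  set.seed(seed)
  tmat <- matrix(rbinom(G * M, 1L, density), G, M)
  smat <- matrix(0L, G, M)
  smat[tmat == 1L] <- 1L + rgeom(sum(tmat), 0.5)
  dimnames(tmat) <- dimnames(smat) <-
    list(sprintf("g%02d", 1:G), sprintf("m%02d", 1:M))
  list(t = tmat, s = smat)
}

# build a target_matrix from an explicit site-count matrix via records
tm_from_s <- function(smat) {
  edges <- which(smat >= 1L, arr.ind = TRUE)
  rec <- data.frame(gene_id = rownames(smat)[edges[, 1L]],
                    mirna_id = colnames(smat)[edges[, 2L]],
                    conserved_sites = as.integer(smat[edges]),
                    poorly_conserved_sites = 0L,
                    stringsAsFactors = FALSE)
  tm <- build_target_matrix(rec)
  # genes or miRNAs with no sites drop out of the record form; re-add rows
  # only matters when a fixture needs them, so fixtures keep >=1 site per id
  tm
}
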