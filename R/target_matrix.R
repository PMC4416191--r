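#' Build the miRNA-target matrix from prediction records
#'
#' Constructs the gene-by-miRNA targeting structure from a table of
#' miRNA-target predictions. A gene is a target of a miRNA when it carries at
#' least one predicted binding site, conserved or poorly conserved; both site
#' classes count equally. Duplicate (gene, miRNA) records are summed, so
#' summary tables that list conserved and poorly conserved sites on separate
#' rows are handled transparently.
#'
#' @param records data.frame with columns `gene_id`, `mirna_id`,
#'   `conserved_sites`, `poorly_conserved_sites` (non-negative integers).
#' @return An object of class `target_matrix`: a list with `gene_ids`,
#'   `mirna_ids`, the binary indicator matrix `t` (genes x miRNAs) and the
#'   integer site-count matrix `s`. `t[g, m] == 1` exactly when
#'   `s[g, m] >= 1`.
#' @examples
#' rec <- data.frame(gene_id = c("g1", "g1"), mirna_id = c("m1", "m1"),
#'                   conserved_sites = c(1, 0), poorly_conserved_sites = c(1, 2))
#' tm <- build_target_matrix(rec)
#' tm$s  # 4 sites accumulated
#' @export
build_target_matrix <- function(records) {
  req <- c("gene_id", "mirna_id", "conserved_sites", "poorly_conserved_sites")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    abort_input("records must be a data.frame with columns: ",
                paste(req, collapse = ", "))
  }
  if (nrow(records) == 0L) abort_input("empty record list")
  cs <- records$conserved_sites
  ps <- records$poorly_conserved_sites
  if (!is.numeric(cs) || !is.numeric(ps) || anyNA(cs) || anyNA(ps)) {
    abort_input("site counts must be numeric and non-missing")
  }
  if (any(cs < 0) || any(ps < 0)) abort_input("negative site count")
  if (any(cs != floor(cs)) || any(ps != floor(ps))) {
    abort_input("site counts must be integers")
  }
  total <- cs + ps
  if (!any(total >= 1)) abort_input("no record with at least one binding site")

  gene_ids <- sort(unique(as.character(records$gene_id)))
  mirna_ids <- sort(unique(as.character(records$mirna_id)))
  s <- matrix(0L, nrow = length(gene_ids), ncol = length(mirna_ids),
              dimnames = list(gene_ids, mirna_ids))
  gi <- match(as.character(records$gene_id), gene_ids)
  mi <- match(as.character(records$mirna_id), mirna_ids)
  # accumulate duplicates
  acc <- tapply(total, list(gi, mi), sum)
  nz <- which(!is.na(acc), arr.ind = TRUE)
  s[cbind(as.integer(rownames(acc))[nz[, 1]],
          as.integer(colnames(acc))[nz[, 2]])] <- as.integer(acc[nz])
  new_target_matrix(gene_ids, mirna_ids, s)
}

new_target_matrix <- function(gene_ids, mirna_ids, s) {
  storage.mode(s) <- "integer"
  tmat <- (s >= 1L) * 1L
  dimnames(tmat) <- dimnames(s)
  structure(
    list(gene_ids = gene_ids, mirna_ids = mirna_ids, t = tmat, s = s),
    class = "target_matrix"
  )
}

#' Validate a target matrix
#'
#' Checks the structural invariants: unique ids, matching dimensions,
#' non-negative integer site counts, and the indicator/count consistency
#' `t == 1 <=> s >= 1`.
#'
#' @param tm a `target_matrix`.
#' @return `tm`, invisibly; errors on violation.
#' @export
validate_target_matrix <- function(tm) {
  if (!inherits(tm, "target_matrix")) abort_input("not a target_matrix")
  if (anyDuplicated(tm$gene_ids) || anyDuplicated(tm$mirna_ids)) {
    abort_input("gene and miRNA ids must be unique")
  }
  if (length(tm$gene_ids) < 1L || length(tm$mirna_ids) < 1L) {
    abort_input("need at least one gene and one miRNA")
  }
  if (!identical(dim(tm$s), dim(tm$t)) ||
      nrow(tm$s) != length(tm$gene_ids) ||
      ncol(tm$s) != length(tm$mirna_ids)) {
    abort_input("matrix dimensions do not match id vectors")
  }
  if (any(tm$s < 0)) abort_input("negative site count in matrix")
  if (!all((tm$s >= 1L) == (tm$t == 1L))) {
    abort_input("indicator/site-count inconsistency: t must be 1 iff s >= 1")
  }
  invisible(tm)
}

#' @export
print.target_matrix <- function(x, ...) {
  cat(sprintf("target_matrix: %d genes x %d miRNAs, %d targeting edges\n",
              length(x$gene_ids), length(x$mirna_ids), sum(x$t)))
  invisible(x)
}

#' Collapse transcript-level records to gene level
#'
#' When the prediction table is transcript-resolved, one representative
#' transcript is kept per gene: the transcript with the maximum total site
#' count, ties broken by the lexicographically smallest transcript id.
#'
#' @param records data.frame with columns `gene_id`, `transcript_id`,
#'   `mirna_id`, `conserved_sites`, `poorly_conserved_sites`.
#' @return The records of the representative transcripts, without the
#'   `transcript_id` column.
#' @export
collapse_transcripts <- function(records) {
  req <- c("gene_id", "transcript_id", "mirna_id",
           "conserved_sites", "poorly_conserved_sites")
  if (!is.data.frame(records) || !all(req %in% names(records))) {
    abort_input("records must have columns: ", paste(req, collapse = ", "))
  }
  total <- records$conserved_sites + records$poorly_conserved_sites
  per_tx <- aggregate(total,
                      by = list(gene_id = records$gene_id,
                                transcript_id = records$transcript_id),
                      FUN = sum)
  names(per_tx)[3L] <- "total"
  # order: by gene, descending site total, ascending transcript id
  per_tx <- per_tx[order(per_tx$gene_id, -per_tx$total, per_tx$transcript_id), ]
  rep_tx <- per_tx[!duplicated(per_tx$gene_id), c("gene_id", "transcript_id")]
  keep <- paste(records$gene_id, records$transcript_id) %in%
    paste(rep_tx$gene_id, rep_tx$transcript_id)
  out <- records[keep, setdiff(names(records), "transcript_id")]
  rownames(out) <- NULL
  out
}

#' Enumerate putative ceRNA pairs
#'
#' A putative ceRNA pair is an unordered pair of genes sharing at least one
#' predicted targeting miRNA; the shared set is the pair's miRNA program
#' (miRP). Pair counts equal the off-diagonal entries of the co-occurrence
#' product `T %*% t(T)` of the binary targeting matrix. Gene pairs sharing no
#' miRNA form the non-ceRNA background, enumerated exhaustively or
#' reservoir-sampled with a recorded seed.
#'
#' @param tm a `target_matrix` with at least two genes.
#' @param non_cerna one of `"exhaustive"`, `"sample"`, `"none"`: how to
#'   report the zero-sharing background pairs.
#' @param n_sample sample size when `non_cerna = "sample"`.
#' @param seed integer seed recorded and used for the subsample.
#' @return A list of class `cerna_pair_table` with elements
#'   `pairs` (data.frame: `gene_a`, `gene_b`, `mirp_size`, `n_mirpbs`,
#'   `mirp` as comma-joined miRNA ids) and `non_cerna_pairs` (data.frame:
#'   `gene_a`, `gene_b`), plus the sampling metadata.
#' @export
enumerate_cerna_pairs <- function(tm, non_cerna = c("exhaustive", "sample", "none"),
                                  n_sample = NULL, seed = NULL) {
  validate_target_matrix(tm)
  non_cerna <- match.arg(non_cerna)
  G <- length(tm$gene_ids)
  if (G < 2L) abort_input("need at least two genes")

  P <- tcrossprod(tm$t)                  # miRP sizes, genes x genes
  SB <- tcrossprod(tm$s, tm$t)           # SB[a, b] = sum_m s_am * t_bm
  ut <- upper.tri(P)
  hit <- which(ut & P > 0, arr.ind = TRUE)
  if (nrow(hit) > 0L) {
    a <- hit[, 1L]; b <- hit[, 2L]
    # per-gene target index lists for miRP membership
    targets <- lapply(seq_len(G), function(g) which(tm$t[g, ] == 1L))
    mirp <- vapply(seq_along(a), function(i) {
      shared <- intersect(targets[[a[i]]], targets[[b[i]]])
      paste(tm$mirna_ids[shared], collapse = ",")
    }, character(1L))
    pairs <- data.frame(
      gene_a = tm$gene_ids[a],
      gene_b = tm$gene_ids[b],
      mirp_size = as.integer(P[hit]),
      n_mirpbs = as.integer(SB[hit] + t(SB)[hit]),
      mirp = mirp,
      stringsAsFactors = FALSE
    )
    # canonical lexicographic order within and across pairs
    cp <- canonical_pairs(pairs$gene_a, pairs$gene_b)
    pairs$gene_a <- cp$gene_a
    pairs$gene_b <- cp$gene_b
    pairs <- pairs[order(pairs$gene_a, pairs$gene_b), ]
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(gene_a = character(), gene_b = character(),
                        mirp_size = integer(), n_mirpbs = integer(),
                        mirp = character(), stringsAsFactors = FALSE)
  }

  non_df <- data.frame(gene_a = character(), gene_b = character(),
                       stringsAsFactors = FALSE)
  n_non_total <- G * (G - 1) / 2 - nrow(pairs)
  if (non_cerna != "none" && n_non_total > 0) {
    zero <- which(ut & P == 0, arr.ind = TRUE)
    non_df <- data.frame(gene_a = tm$gene_ids[zero[, 1L]],
                         gene_b = tm$gene_ids[zero[, 2L]],
                         stringsAsFactors = FALSE)
    cp <- canonical_pairs(non_df$gene_a, non_df$gene_b)
    non_df <- cp[order(cp$gene_a, cp$gene_b), , drop = FALSE]
    rownames(non_df) <- NULL
    if (non_cerna == "sample") {
      if (is.null(n_sample) || is.null(seed)) {
        abort_input("non_cerna = 'sample' requires n_sample and seed")
      }
      if (n_sample < nrow(non_df)) {
        old <- .Random.seed_get()
        on.exit(.Random.seed_set(old), add = TRUE)
        set.seed(as.integer(seed))
        non_df <- non_df[sort(sample.int(nrow(non_df), n_sample)), , drop = FALSE]
        rownames(non_df) <- NULL
      }
    }
  }

  structure(
    list(pairs = pairs, non_cerna_pairs = non_df,
         n_non_cerna_total = as.integer(n_non_total),
         non_cerna_mode = non_cerna,
         non_cerna_seed = if (non_cerna == "sample") as.integer(seed) else NA_integer_),
    class = "cerna_pair_table"
  )
}

#' @export
print.cerna_pair_table <- function(x, ...) {
  cat(sprintf("cerna_pair_table: %d putative ceRNA pairs, %d non-ceRNA pairs (%s of %d)\n",
              nrow(x$pairs), nrow(x$non_cerna_pairs), x$non_cerna_mode,
              x$n_non_cerna_total))
  invisible(x)
}

# save/restore the global RNG stream so sampling helpers do not perturb it
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Number of miRNA-program binding sites of a ceRNA pair
#'
#' Sums the binding sites of every shared miRNA on both genes of the pair:
#' `sum over m in miRP of (s[a, m] + s[b, m])`. Sites of miRNAs outside the
#' shared program are ignored. The minimum over any valid pair is 2 (one
#' site on each gene for a single shared miRNA).
#'
#' @param gene_a,gene_b gene ids present in `tm`.
#' @param mirp character vector of shared miRNA ids (or a single
#'   comma-joined string as stored in pair tables).
#' @param tm a `target_matrix`.
#' @return integer site count.
#' @export
compute_mirpbs <- function(gene_a, gene_b, mirp, tm) {
  validate_target_matrix(tm)
  if (length(mirp) == 1L && grepl(",", mirp)) {
    mirp <- strsplit(mirp, ",", fixed = TRUE)[[1L]]
  }
  if (!all(mirp %in% tm$mirna_ids)) abort_input("miRP miRNA not in target matrix")
  if (!all(c(gene_a, gene_b) %in% tm$gene_ids)) abort_input("gene not in target matrix")
  sa <- tm$s[gene_a, mirp]
  sb <- tm$s[gene_b, mirp]
  if (any(sa == 0L) || any(sb == 0L)) {
    abort_input("inconsistent miRP: member miRNA has no site on one gene")
  }
  as.integer(sum(sa) + sum(sb))
}
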