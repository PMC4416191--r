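# Shared TSV plumbing. All package tables are tab-separated with a header
# row; lines starting with '#' are provenance comments and are skipped on
# read. Floats are serialized at 6 significant digits. Gzip input is
# handled transparently by R's connections; CRLF files parse like LF.

read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) abort_input("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "")
  if (!is.null(required) && !all(required %in% names(df))) {
    abort_input("file ", path, " is missing required columns: ",
                paste(setdiff(required, names(df)), collapse = ", "))
  }
  df
}

write_tsv <- function(df, path, comment = NULL, digits = 6) {
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample ids; the first column holds entity
#' (gene or miRNA) ids. Gzip-compressed files are decompressed
#' transparently; provenance comment lines starting with `#` are skipped.
#'
#' @param path file path.
#' @param log2_transform set `TRUE` for raw-scale inputs; applies
#'   `log2(x + 1)`.
#' @return numeric matrix, entities x samples.
#' @export
read_expression <- function(path, log2_transform = FALSE) {
  df <- read_tsv(path)
  if (nrow(df) == 0L) abort_input("expression file has no data rows: ", path)
  if (ncol(df) < 2L) abort_input("expression file needs id column plus samples: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    abort_input("duplicate entity ids in ", path, ": ",
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v))[1L]
      abort_input(sprintf("non-numeric cell in %s at row %d (entity '%s'), column '%s': '%s'",
                          path, bad, ids[bad], names(vals)[j], v[bad]))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  storage.mode(m) <- "double"
  if (log2_transform) m <- log2(m + 1)
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix to TSV
#'
#' @param mat numeric matrix with entity row names and sample column names.
#' @param path output path.
#' @param comment optional provenance string written as a leading `#` line.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path, comment = NULL) {
  validate_expression_matrix(mat)
  df <- data.frame(id = rownames(mat), signif(mat, 6), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, comment = comment)
}

#' Read a miRNA-target prediction table
#'
#' Native layout: tab-separated with columns `gene_id`, `mirna_id`,
#' `conserved_sites`, `poorly_conserved_sites`. Summary-count exports from
#' target-prediction tools can be mapped onto this schema by passing
#' `dialect`, a named character vector from native column names to the
#' file's column names.
#'
#' @param path file path.
#' @param dialect optional mapping, e.g.
#'   `c(gene_id = "Gene Symbol", mirna_id = "miRNA family",
#'      conserved_sites = "Total num conserved sites",
#'      poorly_conserved_sites = "Total num nonconserved sites")`.
#' @return data.frame of prediction records.
#' @export
read_targets <- function(path, dialect = NULL) {
  native <- c("gene_id", "mirna_id", "conserved_sites", "poorly_conserved_sites")
  df <- read_tsv(path)
  if (!is.null(dialect)) {
    if (!all(native %in% names(dialect))) {
      abort_input("dialect must map all of: ", paste(native, collapse = ", "))
    }
    missing_cols <- setdiff(unname(dialect[native]), names(df))
    if (length(missing_cols)) {
      abort_input("file ", path, " lacks dialect columns: ",
                  paste(missing_cols, collapse = ", "))
    }
    df <- df[, unname(dialect[native])]
    names(df) <- native
  }
  if (!all(native %in% names(df))) {
    abort_input("target table must have columns: ", paste(native, collapse = ", "))
  }
  df[, native]
}

#' Write a miRNA-target prediction table
#' @param records data.frame of prediction records.
#' @param path output path.
#' @param comment optional provenance line.
#' @return `path`, invisibly.
#' @export
write_targets <- function(records, path, comment = NULL) {
  write_tsv(records, path, comment = comment)
}

#' Write a ceRNA pair table to TSV
#'
#' Columns `gene_a`, `gene_b`, `mirp_size`, `n_mirpbs`, `mirp` (the shared
#' miRNA program, comma-joined), plus any annotation columns present.
#'
#' @param pairs pair data.frame (putative, annotated, or optimal).
#' @param path output path.
#' @param comment optional provenance line.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path, comment = NULL) {
  if (!all(c("gene_a", "gene_b") %in% names(pairs))) {
    abort_input("pair table must have gene_a and gene_b")
  }
  df <- as.data.frame(pairs)
  fac <- vapply(df, is.factor, logical(1L))
  df[fac] <- lapply(df[fac], as.character)
  write_tsv(df, path, comment = comment)
}

#' Read a ceRNA pair table written by [write_pairs()]
#' @param path file path.
#' @return data.frame.
#' @export
read_pairs <- function(path) {
  read_tsv(path, required = c("gene_a", "gene_b"))
}

#' Export a network as a SIF edge list
#'
#' One `gene_a <tab> cerna <tab> gene_b` line per regulation pair, the
#' format Cytoscape imports directly.
#'
#' @param net a `cerna_network` or a pair data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  edges <- if (inherits(net, "cerna_network")) {
    igraph::as_data_frame(net$graph, what = "edges")[, 1:2]
  } else {
    net[, c("gene_a", "gene_b")]
  }
  writeLines(paste(edges[[1L]], "cerna", edges[[2L]], sep = "\t"), path)
  invisible(path)
}

#' Write per-node network attributes
#'
#' Degree and pair-share per node, for import as a Cytoscape node table.
#'
#' @param net a `cerna_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_node_attributes <- function(net, path) {
  if (!inherits(net, "cerna_network")) abort_input("not a cerna_network")
  tab <- if (!is.null(net$node_table)) net$node_table else {
    d <- net$degree
    data.frame(gene = names(d), degree = as.integer(d),
               pct_of_pairs = pct_share(as.numeric(d), max(net$n_edges, 1L)),
               stringsAsFactors = FALSE)
  }
  write_tsv(tab, path)
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member gene ids, tab-separated.
#'
#' @param path file path.
#' @return named list of character vectors; descriptions kept as attribute
#'   `descriptions`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort_input("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) abort_input("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) abort_input("malformed GMT line ", bad[1L], " in ", path)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, character(1L), 2L), names(sets))
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets))) abort_input("gene sets must be named")
  if (is.null(descriptions)) descriptions <- rep("synthetic", length(sets))
  writeLines(vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1L)), path)
  invisible(path)
}

#' Write the stratified K-S results table
#' @param strat output of [stratify_and_test()].
#' @param path output path.
#' @param comment optional provenance line.
#' @return `path`, invisibly.
#' @export
write_stratification <- function(strat, path, comment = NULL) {
  write_tsv(strat, path, comment = comment)
}

#' Read a multi-dataset run configuration
#'
#' YAML mapping with keys `alpha` and `datasets` (label -> expression file
#' path); optional `gmt` path. Referenced files must exist.
#'
#' @param path YAML file.
#' @return validated list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort_input("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$datasets) || length(cfg$datasets) == 0L) {
    abort_input("config needs a non-empty 'datasets' mapping")
  }
  base <- dirname(normalizePath(path))
  cfg$datasets <- lapply(cfg$datasets, function(p) {
    if (!file.exists(p)) {
      p2 <- file.path(base, p)
      if (!file.exists(p2)) abort_input("dataset file not found: ", p)
      p2
    } else p
  })
  if (is.null(cfg$alpha)) cfg$alpha <- 0.05
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1) {
    abort_input("alpha must be in (0, 1)")
  }
  if (!is.null(cfg$gmt) && !file.exists(cfg$gmt)) {
    p2 <- file.path(base, cfg$gmt)
    if (!file.exists(p2)) abort_input("gmt file not found: ", cfg$gmt)
    cfg$gmt <- p2
  }
  cfg
}
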