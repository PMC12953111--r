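#' Construct an expression matrix container
#'
#' A thin container around a genes-by-columns matrix (sparse for cells,
#' dense for bulk samples) carrying gene identifiers, column identifiers
#' and an explicit scale tag. A single genes-by-columns orientation is
#' used throughout the package.
#'
#' @param values numeric matrix or \code{Matrix::sparseMatrix},
#'   genes in rows, cells or samples in columns.
#' @param gene_ids character vector of unique gene identifiers (rows).
#' @param column_ids character vector of unique column identifiers.
#' @param scale_tag one of \code{"counts"}, \code{"lognorm"},
#'   \code{"log2tpm1"}.
#' @return an object of class \code{expression_matrix}.
#' @export
expression_matrix <- function(values, gene_ids, column_ids,
                              scale_tag = c("counts", "lognorm", "log2tpm1")) {
  scale_tag <- match.arg(scale_tag)
  .assert(nrow(values) == length(gene_ids),
          "gene_ids length (%d) does not match matrix rows (%d)",
          length(gene_ids), nrow(values))
  .assert(ncol(values) == length(column_ids),
          "column_ids length (%d) does not match matrix columns (%d)",
          length(column_ids), ncol(values))
  .assert(!anyDuplicated(gene_ids), "duplicate gene identifiers")
  .assert(!anyDuplicated(column_ids), "duplicate column identifiers")
  rownames(values) <- gene_ids
  colnames(values) <- column_ids
  structure(list(values = values,
                 gene_ids = as.character(gene_ids),
                 column_ids = as.character(column_ids),
                 scale_tag = scale_tag),
            class = "expression_matrix")
}

#' @exportS3Method base::print
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d columns [%s, %s]\n",
              length(x$gene_ids), length(x$column_ids), x$scale_tag,
              if (inherits(x$values, "Matrix")) "sparse" else "dense"))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

## Collapse duplicate gene ids: sum for counts, max for log scales.
.collapse_duplicates <- function(values, gene_ids, scale_tag) {
  if (!anyDuplicated(gene_ids)) {
    return(list(values = values, gene_ids = gene_ids))
  }
  n_in <- length(gene_ids)
  f <- factor(gene_ids, levels = unique(gene_ids))
  if (scale_tag == "counts") {
    agg <- Matrix::sparseMatrix(i = as.integer(f), j = seq_along(f), x = 1,
                                dims = c(nlevels(f), length(f)))
    out <- agg %*% values                  # sums within id
  } else {
    dense <- .dense(values)
    out <- do.call(rbind, lapply(split(seq_len(n_in), f), function(i) {
      if (length(i) == 1L) dense[i, , drop = TRUE]
      else apply(dense[i, , drop = FALSE], 2, max)
    }))
  }
  out <- as(out, "CsparseMatrix")
  ids <- levels(f)
  .log_msg("collapsed %d duplicated gene ids into %d unique (%s rule)",
           n_in - length(ids), length(ids),
           if (scale_tag == "counts") "sum" else "max")
  list(values = out, gene_ids = ids)
}

#' Read a sparse expression matrix in Matrix Market format
#'
#' Reads an MTX file with gene and column identifier sidecar files (one
#' identifier per line, first tab-separated field used). Gene identifiers
#' are canonicalized; duplicates are collapsed by sum (counts) or max
#' (log scales) with a log message.
#'
#' @param path_matrix path to the \code{.mtx} file.
#' @param path_genes path to the gene sidecar TSV.
#' @param path_cells path to the column (cell/sample) sidecar TSV.
#' @param scale_tag scale of the stored values (default counts).
#' @return an \code{expression_matrix}.
#' @export
read_expression_mtx <- function(path_matrix, path_genes, path_cells,
                                scale_tag = "counts") {
  for (p in c(path_matrix, path_genes, path_cells))
    .assert(file.exists(p), "file not found: %s", p)
  m <- as(Matrix::readMM(path_matrix), "CsparseMatrix")
  genes <- read.delim(path_genes, header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  cells <- read.delim(path_cells, header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  .assert(nrow(m) == length(genes),
          "MTX rows (%d) do not match gene sidecar %s (%d lines)",
          nrow(m), path_genes, length(genes))
  .assert(ncol(m) == length(cells),
          "MTX columns (%d) do not match column sidecar %s (%d lines)",
          ncol(m), path_cells, length(cells))
  genes <- canonical_gene_ids(genes)
  col <- .collapse_duplicates(m, genes, scale_tag)
  expression_matrix(col$values, col$gene_ids, cells, scale_tag)
}

#' Write a sparse expression matrix in Matrix Market format
#'
#' @param em an \code{expression_matrix}.
#' @param path_matrix,path_genes,path_cells output paths.
#' @return invisibly, the matrix path.
#' @export
write_expression_mtx <- function(em, path_matrix, path_genes, path_cells) {
  Matrix::writeMM(as(Matrix::Matrix(em$values, sparse = TRUE),
                     "generalMatrix"), path_matrix)
  writeLines(em$gene_ids, path_genes)
  writeLines(em$column_ids, path_cells)
  invisible(path_matrix)
}

#' Read a dense bulk expression TSV (genes x samples)
#'
#' First column holds gene identifiers; remaining columns are samples.
#'
#' @param path TSV path.
#' @param scale_tag scale of the stored values (default log2(TPM+1)).
#' @return an \code{expression_matrix}.
#' @export
read_bulk_tsv <- function(path, scale_tag = "log2tpm1") {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  genes <- canonical_gene_ids(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  .assert(!anyDuplicated(genes), "duplicate gene ids in %s", path)
  expression_matrix(m, genes, colnames(m), scale_tag)
}

#' Write a dense bulk expression TSV
#' @param em an \code{expression_matrix}.
#' @param path output TSV path.
#' @export
write_bulk_tsv <- function(em, path) {
  df <- data.frame(gene = em$gene_ids, .dense(em$values),
                   check.names = FALSE)
  colnames(df) <- c("gene", em$column_ids)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Each line is: set name, description, then member genes, tab-separated.
#' Duplicate set names are an error; genes repeated within a set are
#' deduplicated with a warning; empty sets are rejected.
#'
#' @param path GMT path.
#' @return a named list of character vectors (a gene set collection).
#' @export
read_gmt <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[[`, character(1), 1L)
  .assert(!anyDuplicated(names_), "duplicate gene set name in %s", path)
  sets <- lapply(parts, function(p) {
    .assert(length(p) >= 3L, "empty gene set '%s'", p[[1]])
    g <- p[-(1:2)]
    if (anyDuplicated(g)) {
      warning(sprintf("gene repeated within set '%s'; deduplicated", p[[1]]),
              call. = FALSE)
      g <- unique(g)
    }
    g
  })
  names(sets) <- names_
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  .assert(length(names(sets)) == length(sets) && all(nzchar(names(sets))),
          "gene sets must be named")
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- mapply(function(nm, d, g) paste(c(nm, d, g), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table and derive the DE grouping
#'
#' Reads a TSV with at least \code{sample_id} and \code{n_stage} columns
#' and derives the two-group contrast used for differential expression:
#' control = N0 and M0; treatment = N1/N2/N3 and M0; everything else
#' (including M > 0) is excluded.
#'
#' @param path TSV path.
#' @return a data.frame with typed columns plus a derived \code{group}
#'   factor (\code{control}, \code{treatment}, \code{excluded}).
#' @export
read_clinical <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
  .assert(all(c("sample_id", "n_stage") %in% colnames(tab)),
          "clinical table %s lacks mandatory columns sample_id / n_stage",
          path)
  .assert(!anyDuplicated(tab$sample_id), "duplicate sample_id in %s", path)
  if (!"m_stage" %in% colnames(tab)) tab$m_stage <- "M0"
  tab$group <- derive_groups(tab$n_stage, tab$m_stage)
  for (col in c("os_time", "tmb")) {
    if (col %in% colnames(tab)) tab[[col]] <- as.numeric(tab[[col]])
  }
  if ("os_event" %in% colnames(tab)) {
    tab$os_event <- as.integer(tab$os_event)
    .assert(all(tab$os_event %in% c(0L, 1L) | is.na(tab$os_event)),
            "os_event must be 0/1")
  }
  if ("os_time" %in% colnames(tab)) {
    .assert(all(tab$os_time >= 0, na.rm = TRUE), "os_time must be >= 0")
  }
  tab
}

#' Derive the nodal-status DE grouping from N and M stage
#'
#' @param n_stage character vector with values N0..N3 (or NA).
#' @param m_stage character vector with values M0/M1 (or NA).
#' @return factor with levels control, treatment, excluded.
#' @export
derive_groups <- function(n_stage, m_stage) {
  grp <- rep("excluded", length(n_stage))
  m0 <- !is.na(m_stage) & m_stage == "M0"
  grp[!is.na(n_stage) & n_stage == "N0" & m0] <- "control"
  grp[!is.na(n_stage) & n_stage %in% c("N1", "N2", "N3") & m0] <- "treatment"
  factor(grp, levels = c("control", "treatment", "excluded"))
}

#' Read a regulon table (TF, target, importance TSV)
#'
#' @param path TSV path with columns tf, target, importance.
#' @return a named list of \code{regulon} objects (one per TF).
#' @export
read_regulon_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("tf", "target", "importance") %in% colnames(tab)),
          "regulon table %s needs columns tf, target, importance", path)
  lapply(split(tab, tab$tf), function(d) {
    regulon(d$tf[1], d$target, d$importance)
  })
}

#' Write regulons to a TSV
#' @param regulons a list of \code{regulon} objects.
#' @param path output path.
#' @export
write_regulon_tsv <- function(regulons, path) {
  if (inherits(regulons, "regulon")) regulons <- list(regulons)
  tab <- do.call(rbind, lapply(regulons, function(r) {
    data.frame(tf = r$tf, target = r$targets, importance = r$importance)
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
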