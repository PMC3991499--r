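#' Construct an aligned expression dataset
#'
#' Bundles a log2 expression matrix (genes in rows, samples in columns) with
#' its gene and sample identifiers and, optionally, a continuous phenotype
#' value per sample (for instance a disease severity index such as the Duke
#' CAD index). All downstream modelling functions consume this container, so
#' alignment is validated once, here: missing values are an error, identifiers
#' must be unique, and the phenotype (when named) is reordered to the sample
#' order of the matrix.
#'
#' @param values numeric p x n matrix of log2 expression values.
#' @param gene_ids character vector of length p; defaults to `rownames(values)`.
#' @param sample_ids character vector of length n; defaults to `colnames(values)`.
#' @param phenotype optional numeric vector of length n, one value per sample.
#'   If named, names must match `sample_ids` as a set and are used to align.
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `values`, `gene_ids`, `sample_ids`, `phenotype`.
#' @export
#' @examples
#' x <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' ds <- expression_dataset(x, phenotype = c(s1 = 10, s2 = 25, s3 = 40, s4 = 55))
#' ds
expression_dataset <- function(values, gene_ids = rownames(values),
                               sample_ids = colnames(values),
                               phenotype = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("`values` must be a numeric matrix")
  if (anyNA(values)) {
    idx <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value in expression matrix at row %d, column %d; %s",
                 idx[1L], idx[2L],
                 "impute or filter before constructing the dataset"))
  }
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values)) stop("`gene_ids` length must equal nrow(values)")
  if (length(sample_ids) != ncol(values)) stop("`sample_ids` length must equal ncol(values)")
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  if (!is.null(phenotype)) {
    phenotype <- align_phenotype(phenotype, sample_ids)
  }
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, phenotype = phenotype),
            class = "expression_dataset")
}

align_phenotype <- function(phenotype, sample_ids) {
  if (!is.numeric(phenotype)) stop("`phenotype` must be numeric")
  if (anyNA(phenotype)) stop("`phenotype` contains missing values")
  nm <- names(phenotype)
  if (!is.null(nm)) {
    if (anyDuplicated(nm)) {
      stop("duplicate sample ids in phenotype: ",
           paste(unique(nm[duplicated(nm)]), collapse = ", "))
    }
    if (!setequal(nm, sample_ids)) {
      stop(sprintf(paste0("phenotype samples do not match expression samples ",
                          "(%d only in phenotype, %d only in expression); ",
                          "use join_phenotype(..., intersect = TRUE) to keep ",
                          "the common samples"),
                   length(setdiff(nm, sample_ids)),
                   length(setdiff(sample_ids, nm))))
    }
    phenotype <- phenotype[sample_ids]
  } else if (length(phenotype) != length(sample_ids)) {
    stop("`phenotype` must have one value per sample")
  } else {
    names(phenotype) <- sample_ids
  }
  phenotype
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (is.null(x$phenotype)) {
    cat("phenotype: <none>\n")
  } else {
    cat(sprintf("phenotype: continuous, range [%.3g, %.3g]\n",
                min(x$phenotype), max(x$phenotype)))
  }
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$values)

# ---------------------------------------------------------------------------
# Readers / writers.  One dialect everywhere: tab-separated, UTF-8, '#'
# comment lines ignored, header row present unless stated otherwise.
# ---------------------------------------------------------------------------

#' Read an expression matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; the body must be fully numeric (missing or non-numeric cells
#' are an error naming the offending gene and sample). Lines starting with
#' `#` are ignored.
#'
#' @param path path to a tab-separated file.
#' @param transpose if `TRUE` the file is samples x genes and is transposed
#'   after reading.
#' @return An [expression_dataset()] without a phenotype.
#' @seealso [write_expression()], [join_phenotype()]
#' @export
read_expression <- function(path, transpose = FALSE) {
  df <- read_tsv_chr(path, header = TRUE)
  if (ncol(df) < 2L) stop("expression file must have an id column plus >= 1 sample column")
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  body <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value '%s' at row '%s', column '%s' in %s",
                 body[idx[1L], idx[2L]], row_ids[idx[1L]], col_ids[idx[2L]],
                 path))
  }
  dimnames(num) <- list(row_ids, col_ids)
  if (transpose) num <- t(num)
  expression_dataset(num)
}

#' Write an expression matrix to TSV
#'
#' @param x an [expression_dataset()] or a numeric matrix with dimnames.
#' @param path output path.
#' @param id_column name of the identifier column in the header.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, id_column = "gene_id") {
  m <- if (inherits(x, "expression_dataset")) x$values else as.matrix(x)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write_tsv(df, path)
}

#' Read a continuous phenotype from a two-column TSV
#'
#' @param path path to a tab-separated file with columns (sample_id, value).
#' @param header whether the file carries a header row.
#' @return Named numeric vector, one value per sample.
#' @export
read_phenotype <- function(path, header = TRUE) {
  check_two_columns(path)
  df <- read_tsv_chr(path, header = header)
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids in phenotype file: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  vals <- suppressWarnings(as.numeric(df[[2L]]))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1L]
    stop(sprintf("non-numeric phenotype value '%s' for sample '%s' in %s",
                 df[[2L]][bad], ids[bad], path))
  }
  setNames(vals, ids)
}

#' @rdname read_phenotype
#' @param phenotype named numeric vector to write.
#' @export
write_phenotype <- function(phenotype, path) {
  write_tsv(data.frame(sample_id = names(phenotype), value = phenotype,
                       stringsAsFactors = FALSE), path)
}

#' Attach a phenotype vector to an expression dataset
#'
#' Sample sets must match exactly; with `intersect = TRUE` the common samples
#' are kept (in the expression matrix's column order) and the number of
#' dropped samples is reported via a message. Nothing is ever dropped
#' silently.
#'
#' @param ds an [expression_dataset()].
#' @param phenotype named numeric vector, as from [read_phenotype()].
#' @param intersect keep the intersection of the two sample sets instead of
#'   raising an error on mismatch.
#' @return An [expression_dataset()] with aligned phenotype.
#' @export
join_phenotype <- function(ds, phenotype, intersect = FALSE) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(names(phenotype))) stop("`phenotype` must be named by sample id")
  if (intersect && !setequal(names(phenotype), ds$sample_ids)) {
    common <- base::intersect(ds$sample_ids, names(phenotype))
    if (length(common) == 0L) stop("no samples in common between expression and phenotype")
    dropped <- (length(ds$sample_ids) - length(common)) +
      (length(phenotype) - length(common))
    message(sprintf("join_phenotype: keeping %d common samples, dropping %d",
                    length(common), dropped))
    ds <- expression_dataset(ds$values[, common, drop = FALSE],
                             phenotype = phenotype[common])
    return(ds)
  }
  expression_dataset(ds$values, phenotype = phenotype)
}

check_two_columns <- function(path) {
  nf <- count.fields(path, sep = "\t", comment.char = "#",
                     blank.lines.skip = TRUE, quote = "")
  bad <- which(!is.na(nf) & nf != 2L)
  if (length(bad)) {
    stop(sprintf("line %d of %s has %d fields (expected 2)",
                 bad[1L], path, nf[bad[1L]]))
  }
  invisible(TRUE)
}

#' Read a flat gene-to-term annotation
#'
#' Two tab-separated columns (gene, term). Duplicate pairs are collapsed with
#' a message reporting how many were dropped. An empty file yields an empty
#' (valid) table.
#'
#' @param path path to a two-column TSV.
#' @param header whether the file carries a header row.
#' @return data.frame with character columns `gene` and `term`.
#' @export
read_annotation <- function(path, header = TRUE) {
  check_two_columns(path)
  df <- read_tsv_chr(path, header = header)
  if (nrow(df) == 0L) {
    return(data.frame(gene = character(), term = character(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(gene = df[[1L]], term = df[[2L]], stringsAsFactors = FALSE)
  dup <- duplicated(out)
  if (any(dup)) {
    message(sprintf("read_annotation: collapsed %d duplicate gene-term pairs",
                    sum(dup)))
    out <- out[!dup, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' @rdname read_annotation
#' @param annotation data.frame with columns (gene, term) to write.
#' @export
write_annotation <- function(annotation, path) {
  write_tsv(data.frame(gene = annotation$gene, term = annotation$term,
                       stringsAsFactors = FALSE), path)
}

#' Read a gene-gene interaction list
#'
#' Two tab-separated columns (geneA, geneB). Row order is preserved and no
#' deduplication or self-loop removal happens at load time; both are handled
#' when the network is built (see [build_network()]).
#'
#' @inheritParams read_annotation
#' @return data.frame with character columns `geneA` and `geneB`.
#' @export
read_interactions <- function(path, header = TRUE) {
  check_two_columns(path)
  df <- read_tsv_chr(path, header = header)
  if (nrow(df) == 0L) {
    return(data.frame(geneA = character(), geneB = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(geneA = df[[1L]], geneB = df[[2L]], stringsAsFactors = FALSE)
}

#' @rdname read_interactions
#' @param interactions data.frame with columns (geneA, geneB) to write.
#' @export
write_interactions <- function(interactions, path) {
  write_tsv(data.frame(geneA = interactions$geneA, geneB = interactions$geneB,
                       stringsAsFactors = FALSE), path)
}

#' Collapse probe-level rows to gene level
#'
#' Selection runs at the probe level; enrichment and network analysis operate
#' on genes. When a probe-to-gene map is available, the `max-mean` rule keeps,
#' for each gene, the probe with the highest mean expression and renames the
#' row to the gene symbol. Probes absent from the map are dropped.
#'
#' @param ds an [expression_dataset()] whose rows are probes.
#' @param map data.frame with columns `probe` and `gene`.
#' @param method collapsing rule; only `"max-mean"` is implemented.
#' @return An [expression_dataset()] with one row per gene.
#' @export
collapse_probes <- function(ds, map, method = "max-mean") {
  stopifnot(inherits(ds, "expression_dataset"))
  method <- match.arg(method)
  map <- map[map$probe %in% ds$gene_ids, , drop = FALSE]
  if (nrow(map) == 0L) stop("no probes in common between dataset and map")
  means <- rowMeans(ds$values)[map$probe]
  keep <- vapply(split(seq_len(nrow(map)), map$gene), function(i) {
    map$probe[i][which.max(means[i])]
  }, character(1L))
  out <- ds$values[keep, , drop = FALSE]
  rownames(out) <- names(keep)
  expression_dataset(out[order(rownames(out)), , drop = FALSE],
                     phenotype = ds$phenotype)
}
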