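# ---- validation helpers ------------------------------------------------

#' Validate a genes x samples expression matrix
#'
#' Checks the structural invariants every pipeline stage relies on:
#' unique, non-empty gene and sample identifiers matching the matrix
#' dimensions, numeric storage, no all-missing gene rows, and (for
#' count-like data) no negative values.
#'
#' @param values numeric matrix, genes in rows, samples (or cells) in columns,
#'   with rownames and colnames set.
#' @param value_kind one of `"normalized"`, `"counts"`, `"log"`. Count-like
#'   kinds (`counts`, `normalized`) must be non-negative; `log` may be
#'   negative.
#' @return the validated matrix, invisibly unchanged.
#' @export
validate_expression_matrix <- function(values,
                                       value_kind = c("normalized", "counts", "log")) {
  value_kind <- match.arg(value_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression data must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (any(!nzchar(rownames(values))) || any(!nzchar(colnames(values))))
    stop("empty gene or sample identifier")
  all_na <- rowSums(!is.na(values)) == 0L
  if (ncol(values) > 0L && any(all_na))
    stop("gene rows with all values missing: ",
         paste(utils::head(rownames(values)[all_na], 5L), collapse = ", "))
  if (value_kind != "log" && any(values < 0, na.rm = TRUE))
    stop("negative values are not allowed for value_kind = '", value_kind, "'")
  invisible(values)
}

.detect_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# ---- delimited expression tables ---------------------------------------

#' Read a delimited expression table
#'
#' Reads a TSV or CSV table (delimiter auto-detected from the file
#' extension) into a validated genes x samples numeric matrix. The first
#' column holds identifiers; the header row holds the identifiers of the
#' other axis. Identifiers are whitespace-trimmed and matched
#' case-sensitively. `"NA"` and empty cells parse to missing values, never
#' to zero. Duplicate gene rows are collapsed by their mean with a warning;
#' duplicate sample identifiers are an error.
#'
#' @param path path to a `.tsv`/`.txt` (tab) or `.csv` (comma) file.
#' @param orientation `"genes_in_rows"` (default: rows are genes, columns are
#'   samples) or `"genes_in_cols"` (the transpose; the result is always
#'   genes x samples).
#' @param value_kind declared scale of the values; see
#'   [validate_expression_matrix()].
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_table <- function(path,
                                  orientation = c("genes_in_rows", "genes_in_cols"),
                                  value_kind = c("normalized", "counts", "log")) {
  orientation <- match.arg(orientation)
  value_kind <- match.arg(value_kind)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .detect_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "",
                          na.strings = c("NA", ""), colClasses = "character")
  if (ncol(df) < 2L)
    stop("malformed header in ", path, ": need one identifier column plus data columns")
  row_ids <- trimws(df[[1L]])
  col_ids <- trimws(colnames(df)[-1L])
  if (anyDuplicated(col_ids)) {
    dup <- unique(col_ids[duplicated(col_ids)])
    stop("duplicate column identifiers in ", path, ": ", paste(dup, collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric value '", vals[bad[1L, 1L], bad[1L, 2L]], "' at row '",
         row_ids[bad[1L, 1L]], "', column '", col_ids[bad[1L, 2L]], "' in ", path)
  dimnames(num) <- list(row_ids, col_ids)
  if (orientation == "genes_in_cols") num <- t(num)
  if (anyDuplicated(rownames(num))) {
    dup <- unique(rownames(num)[duplicated(rownames(num))])
    warning("collapsing ", length(dup), " duplicated gene row(s) by mean: ",
            paste(utils::head(dup, 5L), collapse = ", "))
    grp <- factor(rownames(num), levels = unique(rownames(num)))
    num <- do.call(rbind, lapply(split(seq_len(nrow(num)), grp), function(idx) {
      colMeans(num[idx, , drop = FALSE], na.rm = TRUE)
    }))
    num[is.nan(num)] <- NA_real_
  }
  validate_expression_matrix(num, value_kind)
  num
}

#' Write an expression matrix as TSV
#'
#' Genes in rows, header row of sample identifiers, first column named
#' `gene_id`. Values round-trip through [read_expression_table()] to at
#' least 1e-9 relative precision.
#'
#' @param expr genes x samples numeric matrix.
#' @param path output path.
#' @export
write_expression_table <- function(expr, path) {
  validate_expression_matrix(expr, "log")
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- GMT signature compendium ------------------------------------------

#' Read an immune cell-type signature compendium from a GMT file
#'
#' Standard GMT dialect: one gene set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. The description field is
#' ignored. Blank lines and `#` comment lines are skipped; trailing tabs
#' are tolerated. Genes are whitespace-trimmed and deduplicated within a
#' signature. Duplicate set names and empty gene lists are errors.
#'
#' @param path path to a `.gmt` file.
#' @return a named list of character vectors (one per cell type), class
#'   `signature_compendium`.
#' @export
read_signatures_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^\\s*#", lines)]
  if (length(lines) == 0L) stop("no gene sets in ", path)
  sets <- lapply(seq_along(lines), function(i) {
    f <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
    if (length(f) < 3L)
      stop("GMT line ", i, ": expected name, description and >=1 gene")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      stop("GMT line ", i, " ('", f[1L], "'): empty gene list")
    list(name = f[1L], genes = genes)
  })
  nms <- vapply(sets, `[[`, character(1L), "name")
  if (anyDuplicated(nms))
    stop("duplicate cell-type name(s) in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  out <- lapply(sets, `[[`, "genes")
  names(out) <- nms
  structure(out, class = "signature_compendium")
}

#' Construct a signature compendium from a named list
#'
#' @param sets named list of character vectors, one per immune cell type.
#' @return validated `signature_compendium`.
#' @export
signature_compendium <- function(sets) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("every cell type needs a name")
  if (anyDuplicated(names(sets))) stop("duplicate cell-type names")
  sets <- lapply(sets, function(g) unique(trimws(as.character(g))))
  if (any(lengths(sets) == 0L)) stop("empty signature")
  structure(sets, class = "signature_compendium")
}

#' @export
print.signature_compendium <- function(x, ...) {
  cat("Signature compendium:", length(x), "cell types,",
      length(unique(unlist(x))), "genes in universe\n")
  invisible(x)
}

#' Gene universe of a compendium
#' @param compendium a `signature_compendium`.
#' @return character vector of all signature genes (unique).
#' @export
compendium_universe <- function(compendium) unique(unlist(compendium, use.names = FALSE))

# ---- centroid tables ---------------------------------------------------

#' Validate a centroid set
#'
#' A centroid set is a genes x clusters numeric matrix: one column per
#' consensus immune cluster, gene identifiers as rownames. At least two
#' clusters are required and every centroid must have at least three
#' finite values.
#'
#' @param centroids genes x clusters numeric matrix.
#' @return the matrix, invisibly.
#' @export
validate_centroid_set <- function(centroids) {
  if (!is.matrix(centroids) || !is.numeric(centroids))
    stop("centroids must be a numeric matrix (genes x clusters)")
  if (ncol(centroids) < 2L) stop("need >= 2 cluster columns")
  if (is.null(rownames(centroids)) || is.null(colnames(centroids)))
    stop("centroid matrix must have gene rownames and cluster colnames")
  if (anyDuplicated(rownames(centroids))) stop("duplicate gene identifiers in centroid set")
  if (anyDuplicated(colnames(centroids))) stop("duplicate cluster labels in centroid set")
  nfin <- colSums(is.finite(centroids))
  if (any(nfin < 3L))
    stop("centroid(s) with fewer than 3 finite values: ",
         paste(colnames(centroids)[nfin < 3L], collapse = ", "))
  invisible(centroids)
}

#' Read a centroid table
#'
#' TSV with a gene identifier column followed by one numeric column per
#' cluster.
#'
#' @param path path to the centroid TSV.
#' @return genes x clusters numeric matrix (see [validate_centroid_set()]).
#' @export
read_centroids <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = .detect_sep(path),
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "", na.strings = c("NA", ""))
  if (ncol(df) < 3L) stop("centroid table needs >= 2 cluster columns")
  ids <- trimws(as.character(df[[1L]]))
  if (anyDuplicated(ids))
    stop("duplicated gene row(s) in centroid table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  colnames(m) <- trimws(colnames(df)[-1L])
  validate_centroid_set(m)
  m
}

#' Write a centroid table
#'
#' Inverse of [read_centroids()]; values are written with enough digits to
#' round-trip to at least 10 significant digits.
#'
#' @param centroids genes x clusters numeric matrix.
#' @param path output path.
#' @export
write_centroids <- function(centroids, path) {
  validate_centroid_set(centroids)
  df <- data.frame(gene_id = rownames(centroids), centroids,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- MatrixMarket triplets ---------------------------------------------

#' Read a single-cell matrix from MatrixMarket triplet files
#'
#' Reads a coordinate-format `.mtx` file plus one-column gene and barcode
#' identifier files (first tab-separated field used if the files have
#' several columns, as in CellRanger output). Cells become samples.
#'
#' @param matrix_path path to the MatrixMarket file.
#' @param genes_path path to the row (gene) identifier file.
#' @param barcodes_path path to the column (cell barcode) identifier file.
#' @return dense genes x cells numeric matrix.
#' @export
read_mtx_triplet <- function(matrix_path, genes_path, barcodes_path) {
  m <- Matrix::readMM(matrix_path)
  read_ids <- function(p) {
    x <- readLines(p, warn = FALSE)
    x <- x[nzchar(trimws(x))]
    trimws(vapply(strsplit(x, "\t", fixed = TRUE), `[[`, character(1L), 1L))
  }
  genes <- read_ids(genes_path)
  cells <- read_ids(barcodes_path)
  if (length(genes) != nrow(m))
    stop("gene file has ", length(genes), " identifiers but matrix has ",
         nrow(m), " rows")
  if (length(cells) != ncol(m))
    stop("barcode file has ", length(cells), " identifiers but matrix has ",
         ncol(m), " columns")
  dense <- as.matrix(m)
  storage.mode(dense) <- "double"  # pattern/logical MTX otherwise stays logical
  dimnames(dense) <- list(genes, cells)
  validate_expression_matrix(dense, "counts")
  dense
}
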