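# TSV contracts: UTF-8, Unix newlines, tab separated, 17 significant digits
# for numeric cells so that read(write(x)) round-trips exactly.

format_num <- function(x) {
  out <- vapply(x, function(v) sprintf("%.17g", v), character(1))
  out[is.na(x)] <- "NA"
  out
}

#' Write a data frame as TSV
#'
#' Numeric columns are serialized with 17 significant digits so that
#' round-trip reads reproduce the values bit for bit. Written atomically:
#' to a temporary file in the target directory, then renamed.
#'
#' @param x data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  y <- x
  for (j in seq_along(y))
    if (is.double(y[[j]])) y[[j]] <- format_num(y[[j]])
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(y, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8", eol = "\n")
  file.rename(tmp, path)
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' @param path input path (plain or gzip-compressed TSV).
#' @return data.frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
}

#' Write an expression set as matrix + design TSVs
#'
#' The matrix TSV has gene ids in the first column (`gene_id`) and one column
#' per sample; the design TSV has columns `sample_id`, `genotype`,
#' `replicate`.
#'
#' @param expr an [expression_set()].
#' @param matrix_path,design_path output paths.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(expr, matrix_path, design_path) {
  stopifnot(inherits(expr, "expression_set"))
  df <- data.frame(gene_id = rownames(expr$values),
                   as.data.frame(expr$values, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table(df, matrix_path)
  write_table(expr$design, design_path)
  invisible(c(matrix_path, design_path))
}

#' Read an expression set from matrix + design TSVs
#'
#' Validates the file contracts: nonempty matrix, unique gene and sample ids,
#' all-numeric expression cells, design covering every sample.
#'
#' @param matrix_path,design_path input paths as written by
#'   [write_expression()].
#' @return an [expression_set()].
#' @export
read_expression <- function(matrix_path, design_path) {
  if (!file.exists(matrix_path))
    stop("matrix file not found: ", matrix_path, call. = FALSE)
  if (file.size(matrix_path) == 0L)
    stop("matrix file is empty: ", matrix_path, call. = FALSE)
  df <- read_table(matrix_path)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("matrix file has no data: ", matrix_path, call. = FALSE)
  if (names(df)[1] != "gene_id")
    stop("first column of the matrix must be gene_id: ", matrix_path,
         call. = FALSE)
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene ids in ", matrix_path, call. = FALSE)
  if (anyDuplicated(names(df)))
    stop("duplicate sample ids in header of ", matrix_path, call. = FALSE)
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals))
    if (!is.numeric(vals[[j]]))
      stop("non-numeric expression values in column '", names(vals)[j],
           "' of ", matrix_path, call. = FALSE)
  m <- as.matrix(vals)
  rownames(m) <- df$gene_id
  design <- read_table(design_path)
  expression_set(m, design)
}

write_json_file <- function(x, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
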