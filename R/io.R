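# Plain-text readers/writers for the package's data interchange formats:
# Matrix Market counts with gene/cell sidecars, dense CSV counts (cells x
# genes), cell metadata CSV, and gene panel lists with JSON provenance.

#' Write a count matrix
#'
#' `format = "mtx"` writes Matrix Market triplets to `<prefix>.mtx` with
#' `<prefix>.genes.tsv` and `<prefix>.cells.tsv` sidecars; `format = "csv"`
#' writes a dense cells x genes CSV (first column `cell_id`, header = gene
#' ids) to `<prefix>.csv`.
#'
#' @param counts genes x cells matrix.
#' @param prefix output path prefix (directories must exist).
#' @param format `"mtx"` or `"csv"`.
#' @return invisibly, the paths written.
#' @export
write_count_matrix <- function(counts, prefix, format = c("mtx", "csv")) {
  counts <- as_count_matrix(counts)
  format <- match.arg(format)
  if (format == "mtx") {
    paths <- paste0(prefix, c(".mtx", ".genes.tsv", ".cells.tsv"))
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(counts,
      sparse = TRUE), "generalMatrix"), "CsparseMatrix"), paths[1])
    writeLines(rownames(counts), paths[2])
    writeLines(colnames(counts), paths[3])
  } else {
    paths <- paste0(prefix, ".csv")
    df <- data.frame(cell_id = colnames(counts), t(counts),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(df, paths, row.names = FALSE)
  }
  invisible(paths)
}

#' Read a count matrix written by [write_count_matrix()]
#'
#' Autodetects the dialect from the file extension: `.mtx` (with sidecars)
#' or `.csv` (dense cells x genes).
#'
#' @param path path to the `.mtx` or `.csv` file.
#' @return genes x cells base matrix with gene/cell id dimnames.
#' @export
read_count_matrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    prefix <- sub("\\.mtx$", "", path)
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(paste0(prefix, ".genes.tsv"))
    colnames(m) <- readLines(paste0(prefix, ".cells.tsv"))
    m
  } else {
    df <- utils::read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    m <- t(as.matrix(df[, -1, drop = FALSE]))
    colnames(m) <- df[[1]]
    m
  }
}

#' Write / read a cell metadata table
#'
#' CSV with columns `cell_id`, `x`, `y`, `subpop`, `z_center`, `volume`,
#' `area` (whichever are present).
#'
#' @param cells cell table.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_cell_table <- function(cells, path) {
  check_cells(cells)
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_cells(cells)
  cells
}

#' Write / read a gene panel
#'
#' The panel is written as a plain-text gene list (one id per line) plus a
#' JSON provenance header at `<path>.json`.
#'
#' @param panel a [gene_panel()].
#' @param path output path for the gene list.
#' @return invisibly, `path`.
#' @export
write_gene_panel <- function(panel, path) {
  stopifnot(inherits(panel, "gene_panel"))
  writeLines(panel$gene_ids, path)
  jsonlite::write_json(
    list(provenance = panel$provenance, size = panel$size,
         seed = if (is.na(panel$seed)) NULL else panel$seed),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_gene_panel
#' @export
read_gene_panel <- function(path) {
  ids <- readLines(path)
  meta_path <- paste0(path, ".json")
  prov <- "full"
  seed <- NA_integer_
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    prov <- meta$provenance %||% "full"
    seed <- meta$seed %||% NA_integer_
  }
  gene_panel(ids, provenance = prov, seed = as.integer(seed))
}

#' Write scaling factors as tidy CSV
#'
#' Columns: `cell_id`, `method`, `panel`, `factor`, `factor_unit_mean`.
#'
#' @param factors named factor vector (see [library_size_factors()]).
#' @param panel panel label.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_factors_csv <- function(factors, panel, path) {
  df <- data.frame(cell_id = names(factors),
                   method = attr(factors, "method") %||% "custom",
                   panel = panel,
                   factor = as.numeric(factors),
                   factor_unit_mean = as.numeric(factors) /
                     mean(as.numeric(factors)),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
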