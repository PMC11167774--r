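# Internal helpers shared across modules.

#' Derive a stream-specific seed from a master seed
#'
#' All randomness in the package flows from one explicit master seed. Each
#' stochastic stage derives its own sub-seed from the master seed plus a
#' string tag, so that stages are statistically decoupled while the whole
#' run stays reproducible. The result is always a valid 32-bit R integer.
#'
#' @param seed integer master seed.
#' @param tag character tag naming the consumer (e.g. "counts", "positions").
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(tag) == 1L)
  ch <- utf8ToInt(as.character(tag))
  # polynomial rolling hash folded into [0, 2^31 - 2]
  h <- 0
  for (c in ch) h <- (h * 131 + c) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h) %% 2147483647)
}

# Evaluate expr with a locally-set RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Coerce a counts container to a base dense matrix (genes x cells) with
# dimnames, validating the CountMatrix invariants.
as_count_matrix <- function(counts) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts)) stop("counts must be a matrix (genes x cells)")
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene ids (rownames) and cell ids (colnames)")
  }
  if (anyDuplicated(rownames(counts))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(counts))) stop("cell ids must be unique")
  counts
}

check_cells <- function(cells, counts = NULL) {
  if (!is.data.frame(cells) || !"cell_id" %in% names(cells)) {
    stop("cells must be a data.frame with a cell_id column")
  }
  if (anyDuplicated(cells$cell_id)) stop("cell ids must be unique")
  if (!is.null(counts)) {
    if (!setequal(colnames(counts), cells$cell_id)) {
      stop("cell table and count matrix disagree on cell ids")
    }
  }
  invisible(cells)
}

# match cells rows to the column order of a matrix
align_cells <- function(cells, counts) {
  check_cells(cells)
  cells[match(colnames(counts), cells$cell_id), , drop = FALSE]
}
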