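# Gene panel construction and panel skew quantification.

#' Construct a gene panel object
#'
#' @param gene_ids ordered unique character vector of gene ids.
#' @param provenance one of `"full"`, `"skewed:<subpop>"`, `"random"`,
#'   `"topk:<k>"`.
#' @param seed integer seed used to draw the panel, or `NA`.
#' @return an object of class `gene_panel`.
#' @export
gene_panel <- function(gene_ids, provenance = "full", seed = NA_integer_) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop("panel gene ids must be unique")
  if (!length(gene_ids)) stop("panel must contain at least one gene")
  structure(list(gene_ids = gene_ids, provenance = provenance,
                 size = length(gene_ids), seed = seed),
            class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat(sprintf("<gene_panel> %d genes, provenance: %s\n", x$size, x$provenance))
  invisible(x)
}

#' Identify the per-subpopulation differentially expressed gene pool
#'
#' Runs one-region-vs-rest differential expression under each requested
#' normalization method (plus whichever are listed, e.g. `"none"`), and pools
#' per subpopulation the genes that under ANY method have adjusted
#' p < `alpha` and |log2 fold change| > `lfc_min`. Skewed panels are sampled
#' from these pools.
#'
#' @param counts genes x cells matrix (full panel).
#' @param cells cell table with `cell_id`, `subpop` (and `volume`/`area` if
#'   those methods are requested).
#' @param methods character vector of normalization methods; any of
#'   `"none"`, `"library_size"`, `"poscounts"`, `"tmm"`, `"volume"`,
#'   `"area"`, `"pearson"`.
#' @param alpha adjusted p-value threshold (default 0.05).
#' @param lfc_min absolute log2 fold change threshold (default 0.25).
#' @return named list: per subpopulation, the character vector of pooled
#'   gene ids.
#' @export
identify_de_pool <- function(counts, cells,
                             methods = c("none", "library_size"),
                             alpha = 0.05, lfc_min = 0.25) {
  counts <- as_count_matrix(counts)
  cells <- align_cells(cells, counts)
  subpops <- sort(unique(cells$subpop))
  if (any(table(cells$subpop) == 0)) stop("empty subpopulation")
  pools <- stats::setNames(vector("list", length(subpops)), subpops)
  for (m in methods) {
    norm <- normalized_matrix(counts, cells, m)
    de <- run_de(norm, cells)
    hit <- !is.na(de$p_adj) & de$p_adj < alpha &
      de$lfc_flag != "undefined" & abs(de$lfc) > lfc_min
    for (sp in subpops) {
      pools[[sp]] <- union(pools[[sp]], de$gene[hit & de$region == sp])
    }
  }
  lapply(pools, function(g) sort(as.character(g)))
}

#' Sample a region-skewed gene panel from a DE pool
#'
#' @param pool character vector of differentially expressed gene ids for the
#'   target subpopulation.
#' @param k panel size; must not exceed `length(pool)`.
#' @param seed integer seed.
#' @param subpop label used in the provenance tag.
#' @return a [gene_panel()] with provenance `"skewed:<subpop>"`.
#' @export
sample_skewed_panel <- function(pool, k, seed = 1L, subpop = "?") {
  if (length(pool) < k) {
    stop("DE pool (", length(pool), " genes) smaller than panel size ", k)
  }
  ids <- with_seed(derive_seed(seed, "skewed_panel"), {
    sample(pool, k)
  })
  gene_panel(ids, provenance = paste0("skewed:", subpop), seed = seed)
}

#' Sample a random gene panel from all genes
#'
#' @param all_genes character vector of the dataset's gene ids.
#' @param k panel size.
#' @param seed integer seed.
#' @return a [gene_panel()] with provenance `"random"`.
#' @export
sample_random_panel <- function(all_genes, k, seed = 1L) {
  if (length(all_genes) < k) stop("panel size exceeds gene count")
  ids <- if (k == length(all_genes)) {
    all_genes
  } else {
    with_seed(derive_seed(seed, "random_panel"), sample(all_genes, k))
  }
  gene_panel(ids, provenance = "random", seed = seed)
}

#' Top-k most significant genes for one subpopulation
#'
#' Ranks the `region == subpop` rows of a differential expression table by
#' adjusted p-value; ties are broken by larger |log2 fold change|, then by
#' gene id, so the selection is deterministic.
#'
#' @param de_results a [run_de()] table.
#' @param subpop target subpopulation label.
#' @param k panel size; must not exceed the number of ranked genes.
#' @return a [gene_panel()] with provenance `"topk:<k>"`.
#' @export
top_k_panel <- function(de_results, subpop, k) {
  d <- de_results[de_results$region == subpop, , drop = FALSE]
  if (!nrow(d)) stop("no DE results for subpopulation '", subpop, "'")
  if (k > nrow(d)) stop("k exceeds the number of genes")
  abs_lfc <- abs(d$lfc)
  abs_lfc[is.na(abs_lfc)] <- -Inf # undefined fold changes rank last
  ord <- order(d$p_adj, -abs_lfc, d$gene)
  gene_panel(d$gene[ord][seq_len(k)], provenance = paste0("topk:", k))
}

#' Subset a count matrix to a gene panel
#'
#' @param counts genes x cells matrix.
#' @param panel a [gene_panel()] or character vector of gene ids.
#' @return the genes x cells matrix restricted to the panel's genes.
#' @export
subset_panel <- function(counts, panel) {
  counts <- as_count_matrix(counts)
  ids <- if (inherits(panel, "gene_panel")) panel$gene_ids else panel
  missing <- setdiff(ids, rownames(counts))
  if (length(missing)) {
    stop("panel genes absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  counts[ids, , drop = FALSE]
}

#' Kullback-Leibler gene panel skew
#'
#' Measures how far the distribution of detected counts across cell
#' subpopulations departs from the distribution of cells:
#' `Skew = sum_i P_i * ln(P_i / Q_i)` in nats, where `P_i` is subpopulation
#' i's share of total detected counts over the panel's genes and `Q_i` its
#' share of cells. Zero iff counts are proportional to cell numbers
#' (Gibbs' inequality); terms with `P_i = 0` contribute 0.
#'
#' @param counts genes x cells matrix already subset to the panel.
#' @param cells cell table with `cell_id` and `subpop`.
#' @return an object of class `skew_score`: list with `skew` (nats),
#'   `p_counts`, `q_cells`.
#' @export
compute_skew <- function(counts, cells) {
  counts <- as_count_matrix(counts)
  cells <- align_cells(cells, counts)
  total <- sum(counts)
  if (total <= 0) stop("total detected counts must be positive")
  per_cell <- colSums(counts)
  p <- tapply(per_cell, cells$subpop, sum) / total
  q <- table(cells$subpop)[names(p)] / nrow(cells)
  q <- as.numeric(q)
  p <- as.numeric(p)
  if (any(q == 0 & p > 0)) stop("subpopulation with counts but no cells")
  terms <- ifelse(p > 0, p * log(p / q), 0)
  structure(list(skew = sum(terms),
                 p_counts = stats::setNames(p, sort(unique(cells$subpop))),
                 q_cells = stats::setNames(q, sort(unique(cells$subpop)))),
            class = "skew_score")
}

#' @export
print.skew_score <- function(x, ...) {
  cat(sprintf("<skew_score> %.4f nats over %d subpopulations\n",
              x$skew, length(x$p_counts)))
  invisible(x)
}
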