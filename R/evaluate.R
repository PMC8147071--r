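#' Summary statistics of a count matrix
#'
#' Computes the benchmarking statistics used to compare a real and a
#' synthetic matrix: per gene the mean, variance (n-1 denominator),
#' coefficient of variation (sd/mean; `NA` for zero-mean genes) and zero
#' proportion; per cell the zero proportion and library size (column sum);
#' and, over the genes whose zero proportion is below `pair_zero_cutoff`,
#' the gene-pair-wise Pearson correlation and Kendall tau-b matrices.
#'
#' @param X Genes-by-cells nonnegative integer count matrix.
#' @param pair_zero_cutoff Zero-proportion filter for the gene-pair
#'   statistics; default 0.5.
#' @param log_scale If `TRUE`, additionally report `log10(1 + x)` versions
#'   of gene mean, gene variance and library size (columns `log_mean`,
#'   `log_var`, `log_libsize`).
#' @return A `count_stats` object: list with tibbles `gene_stats` and
#'   `cell_stats`, matrices `pearson` and `kendall`, and the
#'   `pair_genes` used.
#' @export
summary_statistics <- function(X, pair_zero_cutoff = 0.5, log_scale = FALSE) {
  X <- check_count_matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("gene", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("cell", seq_len(ncol(X)))
  mu <- unname(rowMeans(X))
  v <- unname(apply(X, 1, stats::var))
  gene_stats <- tibble::tibble(
    gene = rownames(X),
    mean = mu,
    var = v,
    cv = ifelse(mu > 0, sqrt(v) / mu, NA_real_),
    zero_prop = unname(rowMeans(X == 0))
  )
  cell_stats <- tibble::tibble(
    cell = colnames(X),
    zero_prop = unname(colMeans(X == 0)),
    libsize = unname(colSums(X))
  )
  if (log_scale) {
    gene_stats$log_mean <- log10(1 + gene_stats$mean)
    gene_stats$log_var <- log10(1 + gene_stats$var)
    cell_stats$log_libsize <- log10(1 + cell_stats$libsize)
  }
  pair_genes <- rownames(X)[gene_stats$zero_prop < pair_zero_cutoff]
  Xp <- X[pair_genes, , drop = FALSE]
  pearson <- if (length(pair_genes) >= 2) {
    safe_cor(Xp)
  } else {
    diag(1, length(pair_genes))
  }
  kendall <- kendall_tau_matrix(Xp)
  structure(
    list(gene_stats = gene_stats, cell_stats = cell_stats,
         pearson = pearson, kendall = kendall, pair_genes = pair_genes,
         pair_zero_cutoff = pair_zero_cutoff),
    class = "count_stats"
  )
}

# Pearson correlation with zero-variance rows mapped to 0 (flagged via
# attribute) instead of NA.
safe_cor <- function(X) {
  sds <- apply(X, 1, stats::sd)
  R <- suppressWarnings(stats::cor(t(X)))
  bad <- sds == 0
  if (any(bad)) {
    R[bad, ] <- 0; R[, bad] <- 0
  }
  diag(R) <- 1
  attr(R, "zero_variance_genes") <- rownames(X)[bad]
  R
}

#' Correlation matrix of selected genes
#'
#' @param X Genes-by-cells count matrix.
#' @param gene_list Genes to include (rownames of `X`); e.g. the top-100
#'   genes by mean expression for heatmap-style comparisons.
#' @param measure `"pearson"` or `"kendall"` (tau-b).
#' @param cluster_order If `TRUE`, attach a gene ordering computed by
#'   complete-linkage hierarchical clustering on `1 - correlation` as the
#'   `"order"` attribute (for heatmap display).
#' @return Symmetric correlation matrix with unit diagonal; pairs
#'   involving a constant gene are set to 0.
#' @export
correlation_matrix <- function(X, gene_list = NULL,
                               measure = c("pearson", "kendall"),
                               cluster_order = FALSE) {
  X <- check_count_matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("gene", seq_len(nrow(X)))
  measure <- match.arg(measure)
  gene_list <- gene_list %||% rownames(X)
  missing <- setdiff(gene_list, rownames(X))
  if (length(missing) > 0) {
    stop("Unknown gene(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  Xs <- X[gene_list, , drop = FALSE]
  R <- if (measure == "pearson") safe_cor(Xs) else kendall_tau_matrix(Xs)
  if (cluster_order && nrow(R) > 2) {
    hc <- stats::hclust(stats::as.dist(1 - R), method = "complete")
    attr(R, "order") <- hc$order
  }
  R
}

#' Genes with the highest mean expression
#'
#' @param X Genes-by-cells count matrix.
#' @param k Number of genes to return.
#' @return Character vector of gene names, decreasing mean expression.
#' @export
top_expressed_genes <- function(X, k) {
  X <- check_count_matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("gene", seq_len(nrow(X)))
  mu <- rowMeans(X)
  rownames(X)[order(mu, decreasing = TRUE)][seq_len(min(k, nrow(X)))]
}

#' Mean-squared error between real and synthetic summary statistics
#'
#' For gene-wise statistics (`mean`, `var`, `cv`, `zero_prop`) the MSE is
#' taken across genes; for cell-wise statistics (`cell_zero_prop`,
#' `libsize`) across sorted per-cell values (cells are unpaired, so each
#' matrix's values are compared by rank); for pair statistics (`pearson`,
#' `kendall`) across unordered gene pairs, optionally restricted to the
#' `top_k` genes with highest mean expression in the real matrix.
#' Genes with undefined cv (zero mean in either matrix) are excluded.
#'
#' @param real_stats,synth_stats `count_stats` objects with identical gene
#'   sets (from [summary_statistics()]).
#' @param statistic One of `"mean"`, `"var"`, `"cv"`, `"zero_prop"`,
#'   `"cell_zero_prop"`, `"libsize"`, `"pearson"`, `"kendall"`.
#' @param top_k For pair statistics, restrict to this many top-expressed
#'   genes (by real mean) before forming pairs; `NULL` uses every gene that
#'   passed the zero-proportion pair filter in both matrices.
#' @return Nonnegative MSE value.
#' @export
stat_mse <- function(real_stats, synth_stats, statistic, top_k = NULL) {
  stopifnot(inherits(real_stats, "count_stats"),
            inherits(synth_stats, "count_stats"))
  if (!identical(real_stats$gene_stats$gene, synth_stats$gene_stats$gene)) {
    stop("Gene sets of the two matrices must be identical and aligned.",
         call. = FALSE)
  }
  gene_cols <- c(mean = "mean", var = "var", cv = "cv",
                 zero_prop = "zero_prop")
  if (statistic %in% names(gene_cols)) {
    a <- real_stats$gene_stats[[gene_cols[[statistic]]]]
    b <- synth_stats$gene_stats[[gene_cols[[statistic]]]]
    ok <- is.finite(a) & is.finite(b)
    return(mean((a[ok] - b[ok])^2))
  }
  if (statistic %in% c("cell_zero_prop", "libsize")) {
    col <- if (statistic == "libsize") "libsize" else "zero_prop"
    a <- sort(real_stats$cell_stats[[col]])
    b <- sort(synth_stats$cell_stats[[col]])
    if (length(a) != length(b)) {
      qs <- seq(0, 1, length.out = 200)
      a <- stats::quantile(a, qs, names = FALSE)
      b <- stats::quantile(b, qs, names = FALSE)
    }
    return(mean((a - b)^2))
  }
  if (statistic %in% c("pearson", "kendall")) {
    genes <- intersect(real_stats$pair_genes, synth_stats$pair_genes)
    if (!is.null(top_k)) {
      ranked <- real_stats$gene_stats$gene[
        order(real_stats$gene_stats$mean, decreasing = TRUE)]
      genes <- intersect(ranked[seq_len(min(top_k, length(ranked)))], genes)
    }
    if (length(genes) < 2) return(NA_real_)
    A <- real_stats[[statistic]][genes, genes]
    B <- synth_stats[[statistic]][genes, genes]
    ut <- upper.tri(A)
    return(mean((A[ut] - B[ut])^2))
  }
  stop("Unknown statistic: ", statistic, call. = FALSE)
}

#' Compare a real and a synthetic count matrix
#'
#' Computes the full suite of summary statistics on both matrices and the
#' MSE between them for each statistic, restricting pair statistics to the
#' `top_k` most highly expressed genes of the real matrix.
#'
#' @param real,synth Genes-by-cells count matrices over the same genes.
#' @param top_k Top-expressed-gene restriction for pair-statistic MSEs;
#'   default 500.
#' @param pair_zero_cutoff Zero-proportion filter for pair statistics;
#'   default 0.5.
#' @return An `eval_report`: list with both `count_stats` bundles and an
#'   `mse` tibble (columns `statistic`, `mse`).
#' @export
compare_counts <- function(real, synth, top_k = 500, pair_zero_cutoff = 0.5) {
  real <- check_count_matrix(real)
  synth <- check_count_matrix(synth)
  if (nrow(real) != nrow(synth) ||
      (!is.null(rownames(real)) && !is.null(rownames(synth)) &&
       !identical(rownames(real), rownames(synth)))) {
    stop("`real` and `synth` must share an identical, aligned gene set.",
         call. = FALSE)
  }
  rs <- summary_statistics(real, pair_zero_cutoff = pair_zero_cutoff)
  ss <- summary_statistics(synth, pair_zero_cutoff = pair_zero_cutoff)
  stats_all <- c("mean", "var", "cv", "zero_prop", "cell_zero_prop",
                 "libsize", "pearson", "kendall")
  mse <- tibble::tibble(
    statistic = stats_all,
    mse = vapply(stats_all, function(s) {
      stat_mse(rs, ss, s, top_k = if (s %in% c("pearson", "kendall")) top_k)
    }, numeric(1), USE.NAMES = FALSE)
  )
  structure(
    list(real_stats = rs, synth_stats = ss, mse = mse, top_k = top_k),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  print(x$mse)
  invisible(x)
}

#' Export an evaluation report to delimited text and JSON
#'
#' Writes `<prefix>_gene_stats.tsv`, `<prefix>_cell_stats.tsv` (both with a
#' `matrix` column distinguishing real from synthetic) and
#' `<prefix>_mse.json`.
#'
#' @param report An `eval_report`.
#' @param prefix Output path prefix.
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(report, prefix) {
  stopifnot(inherits(report, "eval_report"))
  gs <- dplyr::bind_rows(
    dplyr::mutate(report$real_stats$gene_stats, matrix = "real"),
    dplyr::mutate(report$synth_stats$gene_stats, matrix = "synthetic")
  )
  cs <- dplyr::bind_rows(
    dplyr::mutate(report$real_stats$cell_stats, matrix = "real"),
    dplyr::mutate(report$synth_stats$cell_stats, matrix = "synthetic")
  )
  paths <- c(
    gene = paste0(prefix, "_gene_stats.tsv"),
    cell = paste0(prefix, "_cell_stats.tsv"),
    mse = paste0(prefix, "_mse.json")
  )
  utils::write.table(gs, paths[["gene"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cs, paths[["cell"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    stats::setNames(as.list(report$mse$mse), report$mse$statistic),
    paths[["mse"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
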