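#' Partition genes by expression sparsity
#'
#' Splits the genes of one cell type's count matrix into three groups:
#' group 1 (zero proportion below `zero_cutoff`) is modelled jointly with
#' the Gaussian copula; group 2 (sparser, but still expressed in at least
#' three cells) gets an independent marginal per gene; group 3 (expressed
#' in fewer than three cells) is generated as all zeros. A gene that meets
#' both the group-1 and group-3 definitions (possible only at tiny cell
#' numbers) is routed to group 3: genes seen in fewer than three cells are
#' never copula-modelled.
#'
#' @param X Genes-by-cells matrix of nonnegative integer counts.
#' @param zero_cutoff Zero-proportion cutoff in `(0, 1]`; default 0.8.
#' @return A `gene_partition` object with integer index vectors `group1`,
#'   `group2`, `group3` and the `zero_cutoff` used.
#' @examples
#' X <- rbind(a = c(1, 2, 3, 4), b = c(0, 0, 0, 0))
#' partition_genes(X)
#' @export
partition_genes <- function(X, zero_cutoff = 0.8) {
  X <- check_count_matrix(X)
  if (zero_cutoff <= 0 || zero_cutoff > 1) {
    stop("`zero_cutoff` must lie in (0, 1].", call. = FALSE)
  }
  zero_prop <- rowMeans(X == 0)
  n_expressed <- rowSums(X > 0)
  g3 <- unname(which(n_expressed < 3))
  g1 <- setdiff(unname(which(zero_prop < zero_cutoff)), g3)
  g2 <- setdiff(seq_len(nrow(X)), c(g1, g3))
  structure(
    list(group1 = g1, group2 = g2, group3 = g3, zero_cutoff = zero_cutoff,
         gene_names = rownames(X)),
    class = "gene_partition"
  )
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf(
    "<gene_partition> cutoff=%.2f  group1=%d (copula)  group2=%d (marginal)  group3=%d (zero)\n",
    x$zero_cutoff, length(x$group1), length(x$group2), length(x$group3)
  ))
  invisible(x)
}

#' Distributional transform of discrete counts to uniform scores
#'
#' Maps each count through the randomised CDF transform
#' \eqn{u^*_{ij} = v^*_{ij} F_i(x_{ij} - 1) + (1 - v^*_{ij}) F_i(x_{ij})},
#' with `v*` drawn i.i.d. Uniform(0,1) and `F_i(-1) = 0`. If the marginal is
#' correctly specified the transformed values are exactly Uniform(0,1),
#' which makes the Gaussian copula identifiable despite the discreteness of
#' counts. Scores are clipped into `[1e-10, 1 - 1e-10]` so the
#' standard-normal quantile stays finite.
#'
#' @param X Genes-by-cells integer count submatrix (the copula-modelled
#'   genes).
#' @param marginals List of `marginal_fit` objects, one per row of `X`.
#' @param v_star Optional matrix of auxiliary uniforms (same shape as `X`);
#'   drawn from the current RNG stream when `NULL`.
#' @return A `copula_scores` object with matrices `u_star` and `v_star`.
#' @export
distributional_transform <- function(X, marginals, v_star = NULL) {
  X <- check_count_matrix(X)
  if (length(marginals) != nrow(X)) {
    stop("Need exactly one fitted marginal per row of `X`.", call. = FALSE)
  }
  if (is.null(v_star)) {
    v_star <- matrix(stats::runif(length(X)), nrow(X), ncol(X))
  }
  stopifnot(all(dim(v_star) == dim(X)))
  u_star <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
  for (i in seq_len(nrow(X))) {
    Fx <- marginal_cdf(marginals[[i]], X[i, ])
    Fxm1 <- marginal_cdf(marginals[[i]], X[i, ] - 1)
    u_star[i, ] <- v_star[i, ] * Fxm1 + (1 - v_star[i, ]) * Fx
  }
  eps <- 1e-10
  u_star <- pmin(pmax(u_star, eps), 1 - eps)
  structure(list(u_star = u_star, v_star = v_star), class = "copula_scores")
}

#' Convert Kendall's tau to the Gaussian-copula correlation
#'
#' Under a Gaussian copula the latent correlation and the population
#' Kendall's tau of the two variables are linked by
#' \eqn{R = \sin(\pi \tau / 2)}; the map is odd and strictly increasing on
#' `[-1, 1]`.
#'
#' @param tau Kendall's tau value(s) in `[-1, 1]`.
#' @return Copula correlation(s) in `[-1, 1]`.
#' @examples
#' tau_to_copula_corr(1 / 3) # exactly 0.5
#' @export
tau_to_copula_corr <- function(tau) {
  if (any(abs(tau) > 1, na.rm = TRUE)) {
    stop("`tau` must lie in [-1, 1].", call. = FALSE)
  }
  sin(pi * tau / 2)
}

#' Tie-corrected Kendall rank correlation (tau-b)
#'
#' Computes tau-b from the joint contingency table of the two vectors:
#' concordant and discordant pair counts come from two-dimensional
#' cumulative sums, and the denominator applies the standard tie
#' corrections. Exact and fast for count data, where the number of distinct
#' values is small relative to the number of cells.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Kendall's tau-b, or `NA` when either vector is constant.
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  tab <- table(x, y)
  K1 <- nrow(tab); K2 <- ncol(tab)
  if (K1 < 2 || K2 < 2) return(NA_real_)
  tab <- matrix(as.numeric(tab), K1, K2)
  # B[u, v] = count of observations with x-rank strictly above u at y-rank v
  B <- apply(tab, 2, function(col) rev(cumsum(rev(col))) - col)
  B <- matrix(B, K1, K2)
  # concordant partners of cell (u, v): x-rank > u and y-rank > v
  S <- t(apply(B, 1, function(r) rev(cumsum(rev(r))) - r))
  # discordant partners: x-rank > u and y-rank < v
  D <- t(apply(B, 1, function(r) cumsum(r) - r))
  P <- sum(tab * S)
  Q <- sum(tab * D)
  n0 <- n * (n - 1) / 2
  tx <- rowSums(tab); ty <- colSums(tab)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (P - Q) / sqrt((n0 - n1) * (n0 - n2))
}

#' Pairwise Kendall tau-b matrix
#'
#' @param X Observations-in-columns matrix (genes in rows); tau-b is
#'   computed for every unordered row pair.
#' @return Symmetric matrix with unit diagonal; pairs involving a constant
#'   row are set to 0.
#' @export
kendall_tau_matrix <- function(X) {
  p <- nrow(X)
  out <- diag(1, p)
  dimnames(out) <- list(rownames(X), rownames(X))
  if (p < 2) return(out)
  for (h in seq_len(p - 1)) {
    for (l in (h + 1):p) {
      t_hl <- kendall_tau_b(X[h, ], X[l, ])
      out[h, l] <- out[l, h] <- if (is.na(t_hl)) 0 else t_hl
    }
  }
  out
}

# Nearest-PSD repair by eigenvalue clipping at zero, then re-standardise to
# unit diagonal. The sample covariance of Gaussian scores is PSD by
# construction; this only guards floating-point drift.
psd_repair <- function(R, tol = 1e-8) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= -tol && min(e$values) >= 0) return(R)
  vals <- pmax(e$values, 0)
  R2 <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(pmax(diag(R2), .Machine$double.eps))
  R2 <- R2 / tcrossprod(d)
  diag(R2) <- 1
  dimnames(R2) <- dimnames(R)
  (R2 + t(R2)) / 2
}

#' Estimate the Gaussian-copula correlation matrix from uniform scores
#'
#' Applies the standard-normal quantile to the distributional-transform
#' scores and takes the sample covariance across cells, then standardises
#' to correlation form (unit diagonal), symmetrises, and clips any
#' negative eigenvalues introduced by floating-point error.
#'
#' @param scores A `copula_scores` object, or a genes-by-cells matrix of
#'   values strictly inside `(0, 1)`.
#' @return A valid correlation matrix (symmetric, unit diagonal, positive
#'   semidefinite to tolerance).
#' @export
estimate_copula_correlation <- function(scores) {
  u <- if (inherits(scores, "copula_scores")) scores$u_star else scores
  if (any(u <= 0 | u >= 1)) {
    stop("Internal error: uniform scores must lie strictly inside (0, 1).",
         call. = FALSE)
  }
  if (ncol(u) < 2) {
    stop("Need at least 2 cells to estimate a copula correlation.",
         call. = FALSE)
  }
  z <- stats::qnorm(u)
  S <- stats::cov(t(z))
  sd0 <- sqrt(diag(S)) == 0
  R <- suppressWarnings(stats::cov2cor(S))
  if (any(sd0)) { # constant score rows carry no dependence information
    R[sd0, ] <- 0; R[, sd0] <- 0
  }
  diag(R) <- 1
  R[!is.finite(R)] <- 0
  psd_repair(R)
}

#' Estimate the copula correlation by the Kendall-tau plug-in
#'
#' Computes the pairwise tau-b matrix of the raw counts and maps it through
#' `sin(pi tau / 2)`. Faster than the Gaussian-scores route and free of the
#' auxiliary randomisation, but the result is not guaranteed positive
#' semidefinite, so it is repaired by eigenvalue clipping.
#'
#' @param X Genes-by-cells count matrix.
#' @return A valid correlation matrix.
#' @export
estimate_copula_correlation_tau <- function(X) {
  psd_repair(tau_to_copula_corr(kendall_tau_matrix(X)))
}

#' Fit the full generative model for one cell type
#'
#' Partitions the genes by sparsity, selects a marginal count family
#' (Poisson / ZIP / NB / ZINB) for every gene in groups 1 and 2, and
#' estimates the Gaussian-copula correlation over group 1 via the
#' distributional transform. With fewer than 2 cells (or
#' `use_copula = FALSE`) the copula is skipped and group-1 genes are
#' treated as independent, matching the model's no-copula variant.
#'
#' @param X Genes-by-cells nonnegative integer count matrix for one cell
#'   type; rownames are used as gene names.
#' @param cell_type Label for this cell type.
#' @param zero_cutoff Zero-proportion cutoff for the gene partition.
#' @param alpha Significance level of the zero-inflation LRT.
#' @param use_copula Estimate the gene-gene copula correlation? Default
#'   `TRUE`.
#' @param corr_estimator `"gaussian"` (default; sample covariance of
#'   normal scores) or `"tau"` (Kendall plug-in `sin(pi tau / 2)`).
#' @return A `cell_type_model` with the partition, per-gene marginals,
#'   copula correlation `corr`, and the training bookkeeping `n_cells` and
#'   `total_count`.
#' @export
fit_cell_type_model <- function(X, cell_type = "cell_type_1",
                                zero_cutoff = 0.8, alpha = 0.05,
                                use_copula = TRUE,
                                corr_estimator = c("gaussian", "tau")) {
  X <- check_count_matrix(X)
  corr_estimator <- match.arg(corr_estimator)
  if (is.null(rownames(X))) {
    rownames(X) <- paste0("gene", seq_len(nrow(X)))
  }
  part <- partition_genes(X, zero_cutoff)
  fit_one <- function(i) {
    tryCatch(
      select_marginal(X[i, ], alpha = alpha),
      error = function(e) {
        warning(sprintf("marginal fit failed for gene '%s' (%s); using Poisson",
                        rownames(X)[i], conditionMessage(e)), call. = FALSE)
        fit_poisson(X[i, ])
      }
    )
  }
  modeled <- sort(c(part$group1, part$group2))
  marginals <- stats::setNames(lapply(modeled, fit_one), rownames(X)[modeled])
  copula_used <- use_copula && length(part$group1) > 0
  if (copula_used && ncol(X) < 2) {
    warning(sprintf(
      "cell type '%s' has fewer than 2 cells; fitting without copula",
      cell_type), call. = FALSE)
    copula_used <- FALSE
  }
  corr <- if (copula_used) {
    g1_names <- rownames(X)[part$group1]
    if (corr_estimator == "tau") {
      estimate_copula_correlation_tau(X[part$group1, , drop = FALSE])
    } else {
      scores <- distributional_transform(X[part$group1, , drop = FALSE],
                                         marginals[g1_names])
      estimate_copula_correlation(scores)
    }
  } else {
    diag(1, length(part$group1))
  }
  dimnames(corr) <- list(rownames(X)[part$group1], rownames(X)[part$group1])
  structure(
    list(cell_type = cell_type, partition = part, marginals = marginals,
         corr = corr, n_cells = ncol(X), total_count = sum(X),
         gene_names = rownames(X), use_copula = copula_used,
         zero_cutoff = zero_cutoff, alpha = alpha),
    class = "cell_type_model"
  )
}

#' @export
print.cell_type_model <- function(x, ...) {
  cat(sprintf(
    "<cell_type_model> '%s': %d genes (%d copula / %d marginal / %d zero), %d cells, total count %.0f%s\n",
    x$cell_type, length(x$gene_names), length(x$partition$group1),
    length(x$partition$group2), length(x$partition$group3), x$n_cells,
    x$total_count, if (x$use_copula) "" else " [no copula]"
  ))
  invisible(x)
}

#' Fit cell-type models for a labelled count matrix
#'
#' Splits the matrix by cell-type label and fits one generative model per
#' type. The registry order of the types is their order of first appearance
#' in `cell_labels` (or the factor level order when `cell_labels` is a
#' factor); proportions and synthetic output follow that order.
#'
#' @param X Genes-by-cells nonnegative integer count matrix.
#' @param cell_labels Cell-type label per column of `X`.
#' @inheritParams fit_cell_type_model
#' @return A `count_model`: a list of `cell_type_model`s plus the training
#'   cell-type proportions.
#' @export
fit_count_model <- function(X, cell_labels, zero_cutoff = 0.8, alpha = 0.05,
                            use_copula = TRUE,
                            corr_estimator = c("gaussian", "tau")) {
  X <- check_count_matrix(X)
  if (length(cell_labels) != ncol(X)) {
    stop("Need one cell-type label per column of `X`.", call. = FALSE)
  }
  types <- if (is.factor(cell_labels)) {
    levels(droplevels(cell_labels))
  } else {
    unique(as.character(cell_labels))
  }
  cell_labels <- as.character(cell_labels)
  models <- lapply(types, function(ct) {
    fit_cell_type_model(X[, cell_labels == ct, drop = FALSE], cell_type = ct,
                        zero_cutoff = zero_cutoff, alpha = alpha,
                        use_copula = use_copula,
                        corr_estimator = corr_estimator)
  })
  names(models) <- types
  structure(
    list(models = models, cell_types = types,
         proportions = estimate_proportions(cell_labels, levels = types)),
    class = "count_model"
  )
}

#' @export
print.count_model <- function(x, ...) {
  cat(sprintf("<count_model> %d cell type(s): %s\n",
              length(x$models), paste(x$cell_types, collapse = ", ")))
  for (m in x$models) print(m)
  invisible(x)
}
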