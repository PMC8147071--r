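#' Estimate cell-type proportions from labels
#'
#' @param cell_labels Cell-type label per cell.
#' @param levels Optional registry order of the types; defaults to order of
#'   first appearance.
#' @return Named proportion vector summing to 1.
#' @examples
#' estimate_proportions(c("A", "A", "B", "B"))
#' @export
estimate_proportions <- function(cell_labels, levels = NULL) {
  if (length(cell_labels) == 0) {
    stop("`cell_labels` must contain at least one cell.", call. = FALSE)
  }
  cell_labels <- as.character(cell_labels)
  levels <- levels %||% unique(cell_labels)
  if (!all(cell_labels %in% levels)) {
    stop("`cell_labels` contains types absent from `levels`.", call. = FALSE)
  }
  counts <- table(factor(cell_labels, levels = levels))
  stats::setNames(as.numeric(counts) / length(cell_labels), levels)
}

#' Draw per-type synthetic cell numbers from a multinomial
#'
#' @param n_prime Target total number of synthetic cells.
#' @param proportions Valid cell-type proportion vector.
#' @return Named integer vector summing exactly to `n_prime`.
#' @export
draw_cell_type_counts <- function(n_prime, proportions) {
  stopifnot(n_prime >= 1, all(proportions >= 0),
            abs(sum(proportions) - 1) < 1e-8)
  stats::setNames(as.integer(stats::rmultinom(1, n_prime, proportions)),
                  names(proportions))
}

#' Allocate sequencing depth across cell types
#'
#' Given per-type training depth `N^(k)` over `n^(k)` cells and the drawn
#' synthetic cell numbers `n^(k)'`, the unscaled per-type depth is
#' `N^(k)0 = (N^(k) / n^(k)) n^(k)'`. To hit the user's expected total depth
#' `N'`, every type is rescaled by the common factor
#' \eqn{r = N' / \sum_s N^{(s)0}}, so `N^(k)' = r N^(k)0` and the `N^(k)'` sum to
#' `N'`. The same `r` later multiplies every gene's mean parameter.
#'
#' @param models A `count_model` or list of `cell_type_model`s.
#' @param counts_per_type Integer vector `n^(k)'`, one per type.
#' @param N_prime Target expected total count `N'`.
#' @return An `allocation_plan` tibble with one row per type (columns
#'   `cell_type`, `n_train`, `N_train`, `n_out`, `depth_unscaled`,
#'   `depth_scaled`) and the common `scale_factor` as an attribute.
#' @export
make_allocation_plan <- function(models, counts_per_type, N_prime) {
  if (inherits(models, "count_model")) models <- models$models
  stopifnot(length(models) == length(counts_per_type), N_prime > 0,
            all(counts_per_type >= 0))
  if (sum(counts_per_type) == 0) {
    stop("At least one synthetic cell is required (all n^(k)' are 0).",
         call. = FALSE)
  }
  n_train <- vapply(models, function(m) m$n_cells, numeric(1))
  N_train <- vapply(models, function(m) m$total_count, numeric(1))
  depth_unscaled <- N_train / n_train * counts_per_type
  r <- N_prime / sum(depth_unscaled)
  plan <- tibble::tibble(
    cell_type = vapply(models, function(m) m$cell_type, character(1)),
    n_train = n_train,
    N_train = N_train,
    n_out = as.integer(counts_per_type),
    depth_unscaled = depth_unscaled,
    depth_scaled = r * depth_unscaled
  )
  attr(plan, "scale_factor") <- r
  class(plan) <- c("allocation_plan", class(plan))
  plan
}

#' Generate synthetic cells for one cell type
#'
#' Draws counts from the fitted model with every gene's mean rescaled to
#' `scale_factor * mu` (zero-inflation weight and dispersion unchanged).
#' Copula-modelled genes are generated by sampling a latent Gaussian vector
#' with correlation `corr`, mapping each coordinate through the
#' standard-normal CDF and then through the rescaled marginal quantile;
#' marginal-only genes are drawn independently the same way; always-zero
#' genes emit zeros. With `use_copula = FALSE` the copula genes are drawn
#' independently too.
#'
#' Draw order is fixed for reproducibility: the latent Gaussian block
#' first, then the independent-gene uniforms gene by gene.
#'
#' @param model A `cell_type_model`.
#' @param n_cells_out Number of synthetic cells.
#' @param scale_factor Depth scaling factor `r` applied to every mean.
#' @param use_copula Use the fitted gene-gene correlation? Default `TRUE`.
#' @return Genes-by-cells integer matrix over all genes of the model.
#' @export
generate_cell_type <- function(model, n_cells_out, scale_factor = 1,
                               use_copula = TRUE) {
  stopifnot(inherits(model, "cell_type_model"), n_cells_out >= 0)
  if (scale_factor <= 0) {
    stop("`scale_factor` must be positive.", call. = FALSE)
  }
  p <- length(model$gene_names)
  out <- matrix(0L, p, n_cells_out,
                dimnames = list(model$gene_names, NULL))
  if (n_cells_out == 0) return(out)
  part <- model$partition
  g1 <- part$group1
  use_copula <- use_copula && model$use_copula && length(g1) > 1
  if (use_copula) {
    z <- rmvnorm_eigen(n_cells_out, model$corr)
    u <- stats::pnorm(z)
    for (idx in seq_along(g1)) {
      i <- g1[idx]
      out[i, ] <- r_marginal(model$marginals[[model$gene_names[i]]],
                             n_cells_out, scale_factor, u = u[idx, ])
    }
    indep <- part$group2
  } else {
    indep <- sort(c(g1, part$group2))
  }
  for (i in indep) {
    out[i, ] <- r_marginal(model$marginals[[model$gene_names[i]]],
                           n_cells_out, scale_factor)
  }
  out
}

#' Simulate a labelled synthetic count matrix
#'
#' Runs the full generation pipeline: per-type synthetic cell numbers are
#' drawn from Multinomial(`n_prime`, training proportions), the common
#' depth-scaling factor `r` is computed so that the expected grand total
#' count is `N_prime`, and each type's cells are generated from its
#' rescaled model. The realised total varies around `N_prime`, mimicking
#' experimental randomness in sequencing depth.
#'
#' @param model A `count_model` (or single `cell_type_model`).
#' @param n_prime Target number of synthetic cells `n'`.
#' @param N_prime Target expected total count `N'`; defaults to the
#'   depth implied by the training data at `n_prime` cells (scale factor 1).
#' @param seed Optional integer seed (Mersenne-Twister); the same seed and
#'   inputs reproduce the output exactly.
#' @param use_copula Use fitted gene-gene correlations? Default `TRUE`.
#' @return A `sim_counts` object: list with the integer `counts` matrix
#'   (columns named `<type>.<index>`), the `cell_type` label per column,
#'   and the `allocation_plan` used.
#' @export
simulate_counts <- function(model, n_prime, N_prime = NULL, seed = NULL,
                            use_copula = TRUE) {
  if (inherits(model, "cell_type_model")) {
    model <- structure(
      list(models = stats::setNames(list(model), model$cell_type),
           cell_types = model$cell_type,
           proportions = stats::setNames(1, model$cell_type)),
      class = "count_model"
    )
  }
  stopifnot(inherits(model, "count_model"), n_prime >= 1)
  if (!is.null(seed)) set.seed(seed, kind = "Mersenne-Twister")
  n_k <- draw_cell_type_counts(n_prime, model$proportions)
  if (is.null(N_prime)) {
    N_prime <- sum(vapply(model$models, function(m) m$total_count / m$n_cells,
                          numeric(1)) * n_k)
  }
  plan <- make_allocation_plan(model, n_k, N_prime)
  r <- attr(plan, "scale_factor")
  blocks <- lapply(model$cell_types, function(ct) {
    generate_cell_type(model$models[[ct]], n_k[[ct]], scale_factor = r,
                       use_copula = use_copula)
  })
  counts <- do.call(cbind, blocks)
  labels <- rep(model$cell_types, n_k[model$cell_types])
  colnames(counts) <- paste0(labels, ".",
                             unlist(lapply(n_k[model$cell_types], seq_len),
                                    use.names = FALSE))
  structure(list(counts = counts, cell_type = labels, plan = plan),
            class = "sim_counts")
}

#' @export
print.sim_counts <- function(x, ...) {
  cat(sprintf(
    "<sim_counts> %d genes x %d cells, %d type(s), total count %.0f (scale factor %.4g)\n",
    nrow(x$counts), ncol(x$counts), length(unique(x$cell_type)),
    sum(x$counts), attr(x$plan, "scale_factor")
  ))
  invisible(x)
}
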