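#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted cell-type model into a per-gene tibble
#'
#' @param x A `cell_type_model`.
#' @param ... Unused.
#' @return Tibble with one row per gene: `gene`, `group` (1 = copula,
#'   2 = independent marginal, 3 = always zero), `family`, `pi_zero`,
#'   `psi`, `mu`, `loglik`, and the implied marginal `mean` and `var`.
#' @export
tidy.cell_type_model <- function(x, ...) {
  part <- x$partition
  group <- integer(length(x$gene_names))
  group[part$group1] <- 1L
  group[part$group2] <- 2L
  group[part$group3] <- 3L
  rows <- purrr::map2_dfr(x$gene_names, group, function(g, grp) {
    m <- x$marginals[[g]]
    if (is.null(m)) {
      tibble::tibble(gene = g, group = grp, family = NA_character_,
                     pi_zero = NA_real_, psi = NA_real_, mu = NA_real_,
                     loglik = NA_real_, mean = 0, var = 0)
    } else {
      mom <- marginal_moments(m)
      tibble::tibble(gene = g, group = grp, family = m$family,
                     pi_zero = m$pi_zero, psi = m$psi, mu = m$mu,
                     loglik = m$loglik, mean = mom[["mean"]],
                     var = mom[["var"]])
    }
  })
  dplyr::mutate(rows, cell_type = x$cell_type, .before = 1)
}

#' @export
tidy.count_model <- function(x, ...) {
  purrr::map_dfr(x$models, tidy)
}

#' One-row summary of a fitted cell-type model
#'
#' @param x A `cell_type_model`.
#' @param ... Unused.
#' @return One-row tibble with cohort size, total count, group sizes and
#'   family counts.
#' @export
glance.cell_type_model <- function(x, ...) {
  fams <- vapply(x$marginals, function(m) m$family, character(1))
  tibble::tibble(
    cell_type = x$cell_type,
    n_cells = x$n_cells,
    total_count = x$total_count,
    n_genes = length(x$gene_names),
    n_copula = length(x$partition$group1),
    n_marginal_only = length(x$partition$group2),
    n_zero = length(x$partition$group3),
    n_poisson = sum(fams == "POISSON"),
    n_zip = sum(fams == "ZIP"),
    n_nb = sum(fams == "NB"),
    n_zinb = sum(fams == "ZINB"),
    use_copula = x$use_copula
  )
}

#' @export
glance.count_model <- function(x, ...) {
  purrr::map_dfr(x$models, glance)
}

#' @export
tidy.sim_counts <- function(x, ...) {
  tibble::tibble(
    cell = colnames(x$counts),
    cell_type = x$cell_type,
    libsize = colSums(x$counts),
    zero_prop = colMeans(x$counts == 0)
  )
}

#' @export
tidy.eval_report <- function(x, ...) {
  x$mse
}

#' @export
glance.eval_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$mse, names_from = "statistic",
                             values_from = "mse", names_prefix = "mse_")
  dplyr::mutate(wide,
                n_genes = nrow(x$real_stats$gene_stats),
                n_cells_real = nrow(x$real_stats$cell_stats),
                n_cells_synth = nrow(x$synth_stats$cell_stats),
                top_k = x$top_k)
}
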