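ARCHIVE_FORMAT_VERSION <- 1L

#' Read a gene-by-cell count matrix
#'
#' Supports MatrixMarket triplet files with gene/cell-name sidecars
#' (`<stem>.mtx` plus `<stem>.genes.txt` and `<stem>.barcodes.txt`, one
#' name per line, genes as rows) and dense delimited text (gene rows, first
#' column gene names, header of cell names). Entries must be nonnegative
#' integers: the model is defined on raw counts, so normalised matrices
#' are rejected rather than rounded.
#'
#' @param path Path to the `.mtx` file or the dense text file.
#' @param format `"auto"` (by extension), `"mtx"` or `"dense"`.
#' @param sep Field separator for dense files (default tab; `","` for CSV).
#' @return Genes-by-cells integer matrix with unique dimnames.
#' @export
read_counts <- function(path, format = c("auto", "mtx", "dense"),
                        sep = "\t") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "dense"
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    gene_file <- paste0(stem, ".genes.txt")
    cell_file <- paste0(stem, ".barcodes.txt")
    for (f in c(gene_file, cell_file)) {
      if (!file.exists(f)) {
        stop("Missing sidecar file: ", f, call. = FALSE)
      }
    }
    M <- tryCatch(Matrix::readMM(path), error = function(e) {
      stop("Failed to parse MatrixMarket file: ", conditionMessage(e),
           call. = FALSE)
    })
    genes <- readLines(gene_file)
    cells <- readLines(cell_file)
    if (length(genes) != nrow(M) || length(cells) != ncol(M)) {
      stop(sprintf(
        "Sidecar dimensions (%d genes, %d cells) do not match matrix (%d x %d).",
        length(genes), length(cells), nrow(M), ncol(M)), call. = FALSE)
    }
    X <- as.matrix(M)
    dimnames(X) <- list(genes, cells)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, row.names = 1)
    X <- as.matrix(df)
  }
  if (anyNA(X) || any(X < 0) || any(X != floor(X))) {
    stop("Count matrix must contain only nonnegative integers; ",
         "normalised or continuous matrices are not accepted.",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(X)) || anyDuplicated(colnames(X))) {
    stop("Gene and cell names must be unique.", call. = FALSE)
  }
  storage.mode(X) <- "double"
  X
}

#' Write a gene-by-cell count matrix
#'
#' @param X Genes-by-cells integer count matrix with dimnames.
#' @param path Output path (`.mtx` stem rules as in [read_counts()]).
#' @param format `"mtx"` or `"dense"`.
#' @param sep Field separator for dense output.
#' @return Invisibly, the main path written.
#' @export
write_counts <- function(X, path, format = c("mtx", "dense"), sep = "\t") {
  X <- check_count_matrix(X)
  format <- match.arg(format)
  if (is.null(rownames(X)) || is.null(colnames(X))) {
    stop("`X` must carry gene and cell names.", call. = FALSE)
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE), paste0(stem, ".mtx"))
    writeLines(rownames(X), paste0(stem, ".genes.txt"))
    writeLines(colnames(X), paste0(stem, ".barcodes.txt"))
    invisible(paste0(stem, ".mtx"))
  } else {
    df <- data.frame(gene = rownames(X), X, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    invisible(path)
  }
}

#' Read cell-type labels
#'
#' Two-column delimited file (cell name, cell type), no header.
#'
#' @param path Path to the label file.
#' @param sep Field separator.
#' @return Named character vector of cell types.
#' @export
read_cell_labels <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = FALSE, sep = sep,
                          col.names = c("cell", "type"),
                          colClasses = "character")
  stats::setNames(df$type, df$cell)
}

# ---- model archives -------------------------------------------------------

num_out <- function(x) {
  # Inf is not valid JSON; serialised as the string "Inf"
  ifelse(is.finite(x) | is.na(x), x, "Inf")
}

# jsonlite at full precision writes NA/Inf as strings; as.numeric maps
# "NA" -> NA and "Inf" -> Inf, so the coercion warning is spurious.
num_in <- function(x) {
  v <- unlist(x)
  if (is.null(v)) return(NA_real_)
  suppressWarnings(as.numeric(v))
}

marginal_to_list <- function(m) {
  list(family = m$family, pi_zero = m$pi_zero, psi = num_out(m$psi),
       mu = m$mu, loglik = m$loglik, n_obs = m$n_obs,
       degraded = isTRUE(m$degraded))
}

marginal_from_list <- function(l) {
  new_marginal_fit(l$family, num_in(l$pi_zero), num_in(l$psi), num_in(l$mu),
                   num_in(l$loglik), as.integer(l$n_obs),
                   degraded = isTRUE(l$degraded))
}

model_to_list <- function(m) {
  list(
    cell_type = m$cell_type,
    gene_names = m$gene_names,
    partition = list(group1 = m$partition$group1,
                     group2 = m$partition$group2,
                     group3 = m$partition$group3,
                     zero_cutoff = m$partition$zero_cutoff),
    marginals = lapply(m$marginals, marginal_to_list),
    corr = as.vector(m$corr),
    corr_dim = nrow(m$corr),
    n_cells = m$n_cells,
    total_count = m$total_count,
    use_copula = m$use_copula,
    zero_cutoff = m$zero_cutoff,
    alpha = m$alpha
  )
}

model_from_list <- function(l) {
  nrow_corr <- as.integer(l$corr_dim)
  corr <- matrix(num_in(l$corr), nrow_corr, nrow_corr)
  gene_names <- as.character(unlist(l$gene_names))
  g1 <- as.integer(unlist(l$partition$group1))
  dimnames(corr) <- list(gene_names[g1], gene_names[g1])
  part <- structure(
    list(group1 = g1,
         group2 = as.integer(unlist(l$partition$group2)),
         group3 = as.integer(unlist(l$partition$group3)),
         zero_cutoff = num_in(l$partition$zero_cutoff),
         gene_names = gene_names),
    class = "gene_partition"
  )
  marginals <- lapply(l$marginals, marginal_from_list)
  names(marginals) <- names(l$marginals)
  structure(
    list(cell_type = l$cell_type, partition = part, marginals = marginals,
         corr = corr, n_cells = as.integer(l$n_cells),
         total_count = num_in(l$total_count),
         gene_names = gene_names, use_copula = isTRUE(l$use_copula),
         zero_cutoff = num_in(l$zero_cutoff), alpha = num_in(l$alpha)),
    class = "cell_type_model"
  )
}

#' Save a fitted model to a JSON archive
#'
#' Parameters are serialised at 17 significant digits, which round-trips
#' IEEE doubles exactly: a loaded model generates bit-identical synthetic
#' data at a fixed seed. The archive records a format version and the RNG
#' algorithm so seeds stay portable.
#'
#' @param model A `count_model` or `cell_type_model`.
#' @param path Output path for the JSON archive.
#' @param provenance Optional named list stored verbatim (e.g. input
#'   checksum).
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path, provenance = NULL) {
  if (inherits(model, "cell_type_model")) {
    model <- structure(
      list(models = stats::setNames(list(model), model$cell_type),
           cell_types = model$cell_type,
           proportions = stats::setNames(1, model$cell_type)),
      class = "count_model"
    )
  }
  stopifnot(inherits(model, "count_model"))
  payload <- list(
    format_version = ARCHIVE_FORMAT_VERSION,
    rng_kind = "Mersenne-Twister",
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    provenance = provenance,
    cell_types = model$cell_types,
    proportions = as.list(model$proportions),
    models = lapply(model$models, model_to_list)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a fitted model from a JSON archive
#'
#' @param path Path to an archive written by [save_model()].
#' @return A `count_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  payload <- jsonlite::read_json(path)
  ver <- as.integer(payload$format_version %||% -1L)
  if (!identical(ver, ARCHIVE_FORMAT_VERSION)) {
    stop(sprintf("Incompatible model archive version %s (expected %d).",
                 ver, ARCHIVE_FORMAT_VERSION), call. = FALSE)
  }
  types <- as.character(unlist(payload$cell_types))
  models <- lapply(payload$models, model_from_list)
  names(models) <- types
  structure(
    list(models = models, cell_types = types,
         proportions = stats::setNames(num_in(payload$proportions), types)),
    class = "count_model"
  )
}
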