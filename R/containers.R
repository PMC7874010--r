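#' Validate a gene-by-sample expression matrix
#'
#' Expression data are handled throughout the package as a plain numeric
#' matrix with genes in rows and samples in columns, gene identifiers as row
#' names and sample identifiers as column names, on the log2 scale.
#' `expression_matrix()` coerces and validates such a matrix: all values must
#' be finite, identifiers unique and consistent with the matrix dimensions,
#' with at least one gene and two samples.
#'
#' @param values numeric matrix, genes x samples.
#' @param gene_ids character vector of gene identifiers (default: row names).
#' @param sample_ids character vector of sample identifiers (default: column
#'   names).
#' @return the validated numeric matrix with `dimnames` set.
#' @examples
#' x <- expression_matrix(matrix(rnorm(6), 2, 3),
#'                        gene_ids = c("g1", "g2"),
#'                        sample_ids = c("s1", "s2", "s3"))
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  if (length(values) == 0L) stop("empty expression matrix")
  storage.mode(values) <- "double"
  d <- nrow(values)
  n <- ncol(values)
  if (d < 1L || n < 2L) stop("expression matrix needs >= 1 gene and >= 2 samples")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite expression value at gene row %d, sample column %d",
                 bad[1], bad[2]))
  }
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%04d", seq_len(d))
  if (is.null(sample_ids)) sample_ids <- sprintf("sample%04d", seq_len(n))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != d) stop("gene_ids length does not match row count")
  if (length(sample_ids) != n) stop("sample_ids length does not match column count")
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene id: ", gene_ids[duplicated(gene_ids)][1])
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id: ", sample_ids[duplicated(sample_ids)][1])
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Validate a clinical survival table
#'
#' @param sample_id character vector of unique sample identifiers, or a
#'   data.frame holding all three columns.
#' @param time positive follow-up times (days).
#' @param status event indicator, 0 = alive/censored, 1 = dead.
#' @return a `data.frame` with columns `sample_id`, `time`, `status`.
#' @export
clinical_table <- function(sample_id, time = NULL, status = NULL) {
  if (is.data.frame(sample_id)) {
    df <- sample_id
    need <- c("sample_id", "time", "status")
    if (!all(need %in% names(df))) {
      stop("clinical table must have columns sample_id, time, status")
    }
  } else {
    df <- data.frame(sample_id = as.character(sample_id),
                     time = as.numeric(time),
                     status = as.integer(status),
                     stringsAsFactors = FALSE)
  }
  if (nrow(df) == 0L) stop("empty clinical table")
  df$sample_id <- as.character(df$sample_id)
  df$time <- as.numeric(df$time)
  df$status <- as.integer(df$status)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample id: ", df$sample_id[duplicated(df$sample_id)][1])
  }
  if (!all(is.finite(df$time)) || any(df$time <= 0)) {
    stop("survival times must be finite and > 0")
  }
  if (!all(df$status %in% c(0L, 1L))) {
    stop("status must be 0 (alive/censored) or 1 (dead)")
  }
  df
}

#' Build the supervision (label) matrix from clinical data
#'
#' Encodes survival outcomes as the k x n label matrix Y used by
#' [fit_fsor()]. Under `"onehot_status_plus_time"` (default) Y has three rows:
#' an alive indicator, a dead indicator, and follow-up time min-max normalized
#' to \[0, 1\]. Under `"onehot_status_only"` only the two indicator rows are
#' returned. Columns follow the clinical row order.
#'
#' @param clinical a clinical table (see [clinical_table()]).
#' @param scheme label encoding scheme.
#' @return numeric matrix (k x n) with row names describing each row and
#'   sample ids as column names.
#' @examples
#' cl <- clinical_table(c("a", "b"), time = c(100, 300), status = c(0, 1))
#' build_label_matrix(cl)
#' @export
build_label_matrix <- function(clinical,
                               scheme = c("onehot_status_plus_time",
                                          "onehot_status_only")) {
  scheme <- match.arg(scheme)
  clinical <- clinical_table(clinical)
  if (nrow(clinical) < 2L) stop("need >= 2 samples to build a label matrix")
  alive <- as.numeric(clinical$status == 0L)
  dead <- as.numeric(clinical$status == 1L)
  if (scheme == "onehot_status_only") {
    y <- rbind(alive = alive, dead = dead)
  } else {
    rng <- range(clinical$time)
    if (rng[1] == rng[2]) {
      stop("constant survival times: min-max time normalization is degenerate")
    }
    tnorm <- (clinical$time - rng[1]) / (rng[2] - rng[1])
    y <- rbind(alive = alive, dead = dead, time = tnorm)
  }
  colnames(y) <- clinical$sample_id
  y
}

#' Column-centre a matrix (implicit centering operator)
#'
#' Applies the centering operator M = I_n - (1/n) 1 1^T on the right,
#' i.e. returns `A %*% M`, which subtracts each row's mean. The n x n matrix
#' M is never materialized; the operation costs O(dn). M is symmetric and
#' idempotent, so applying twice equals applying once.
#'
#' @param a numeric matrix with n >= 1 columns.
#' @return the row-mean-centred matrix.
#' @examples
#' apply_centering(matrix(c(1, 3), 1))  # -1, 1
#' @export
apply_centering <- function(a) {
  a <- as.matrix(a)
  if (length(a) == 0L) stop("empty matrix")
  storage.mode(a) <- "double"
  a - rowMeans(a)
}
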