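#' Read / write an expression matrix as TSV
#'
#' Expression TSV format: first column `gene` holds gene identifiers, the
#' header row holds sample identifiers, values are log2 expression. Reading
#' validates the matrix (finite values, unique identifiers); writing is the
#' exact inverse so matrices round-trip.
#'
#' @param path file path.
#' @return `read_expression`: the validated genes x samples matrix.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("expression TSV needs a gene column and >= 2 samples")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop(sprintf("missing value at gene '%s', sample '%s'",
                 genes[bad[1]], colnames(m)[bad[2]]))
  }
  expression_matrix(m, gene_ids = genes, sample_ids = colnames(m))
}

#' @rdname read_expression
#' @param x genes x samples matrix with dimnames.
#' @export
write_expression <- function(x, path) {
  x <- expression_matrix(x)
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a clinical table as TSV
#'
#' Clinical TSV format: columns `sample_id`, `time_days`, `status`
#' (0 = alive/censored, 1 = dead); extra columns are preserved.
#'
#' @param path file path.
#' @return `read_clinical`: a validated clinical table (column `time` holds
#'   days).
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time_days", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- data.frame(sample_id = as.character(df$sample_id),
                    time = df$time_days, status = df$status,
                    stringsAsFactors = FALSE)
  extra <- setdiff(names(df), need)
  for (cn in extra) out[[cn]] <- df[[cn]]
  clinical_table(out)
}

#' @rdname read_clinical
#' @param clinical a clinical table.
#' @export
write_clinical <- function(clinical, path) {
  clinical <- clinical_table(clinical)
  df <- data.frame(sample_id = clinical$sample_id,
                   time_days = clinical$time, status = clinical$status,
                   stringsAsFactors = FALSE)
  extra <- setdiff(names(clinical), c("sample_id", "time", "status"))
  for (cn in extra) df[[cn]] <- clinical[[cn]]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a risk model as JSON
#'
#' @param model a [risk_model()].
#' @param path JSON file path.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(inherits(model, "risk_model"))
  obj <- list(genes = model$genes, coefficients = model$coefficients,
              hrs = model$hrs, bic = model$bic, metadata = model$metadata)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_risk_model
#' @export
read_risk_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  risk_model(genes = obj$genes, coefficients = obj$coefficients,
             bic = if (is.null(obj$bic)) NA_real_ else obj$bic,
             metadata = as.list(obj$metadata))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
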