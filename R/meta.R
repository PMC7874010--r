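#' Standardized mean difference (Hedges' g) for one gene in one study
#'
#' Computes the bias-corrected standardized mean difference between two
#' groups: the raw difference in group means divided by the pooled standard
#' deviation, multiplied by the small-sample correction
#' J(m) = 1 - 3/(4m - 1) with m = n1 + n2 - 2. The sampling variance is the
#' usual large-sample form `(n1 + n2)/(n1 n2) + g^2 / (2 (n1 + n2))`.
#'
#' @param x1 numeric expression values of group 1 (e.g. tumor).
#' @param x2 numeric expression values of group 2 (e.g. normal).
#' @return list with `es` (Hedges' g, positive when group 1 is higher) and
#'   `var` (its sampling variance).
#' @export
study_effect_size <- function(x1, x2) {
  x1 <- as.numeric(x1); x2 <- as.numeric(x2)
  n1 <- length(x1); n2 <- length(x2)
  if (n1 < 2 || n2 < 2) stop("each group needs >= 2 samples")
  m <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / m
  if (sp2 <= 0) stop("pooled standard deviation is zero")
  j <- 1 - 3 / (4 * m - 1)
  g <- (mean(x1) - mean(x2)) / sqrt(sp2) * j
  v <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
  list(es = g, var = v)
}

# Vectorized Hedges' g across genes (rows): x1, x2 are genes x samples.
hedges_g_rows <- function(x1, x2) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m <- n1 + n2 - 2
  v1 <- apply(x1, 1, stats::var)
  v2 <- apply(x2, 1, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / m
  j <- 1 - 3 / (4 * m - 1)
  g <- (rowMeans(x1) - rowMeans(x2)) / sqrt(sp2) * j
  v <- (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
  list(es = g, var = v)
}

#' Random-effects pooling of study effect sizes (DerSimonian-Laird)
#'
#' Pools per-study standardized effect sizes under the random-effects model
#' with the DerSimonian-Laird moment estimator of the between-study variance:
#' with fixed-effect weights `w_i = 1/var_i` and Cochran's
#' `Q = sum w_i (es_i - es_bar)^2`,
#' `tau2 = max(0, (Q - (s - 1)) / (sum w - sum w^2 / sum w))`; the combined
#' effect uses weights `1/(var_i + tau2)`. A single study returns its own
#' effect with `tau2 = 0`. The p-value is the two-sided normal approximation.
#'
#' @param es numeric vector of per-study effect sizes.
#' @param var numeric vector of positive per-study sampling variances.
#' @return list with `combined_es`, `combined_var`, `tau2`, `p`.
#' @export
combine_effects_rem <- function(es, var) {
  es <- as.numeric(es); var <- as.numeric(var)
  s <- length(es)
  if (s == 0L) stop("no studies to combine")
  if (length(var) != s) stop("es and var lengths differ")
  if (!all(is.finite(es)) || !all(is.finite(var)) || any(var <= 0)) {
    stop("effect sizes must be finite and variances positive")
  }
  if (s == 1L) {
    tau2 <- 0
  } else {
    w <- 1 / var
    esbar <- sum(w * es) / sum(w)
    q <- sum(w * (es - esbar)^2)
    tau2 <- max(0, (q - (s - 1)) / (sum(w) - sum(w^2) / sum(w)))
  }
  wstar <- 1 / (var + tau2)
  ces <- sum(wstar * es) / sum(wstar)
  cvar <- 1 / sum(wstar)
  z <- ces / sqrt(cvar)
  list(combined_es = ces, combined_var = cvar, tau2 = tau2,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (monotone-enforced, clipped at 1).
#' Input p-values must lie in (0, 1].
#'
#' @param p numeric vector of p-values.
#' @return adjusted q-values in the input order.
#' @export
fdr_adjust <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-gene random-effects meta-analysis across studies
#'
#' For every gene, computes the per-study tumor-vs-normal Hedges' g and its
#' variance, pools them with [combine_effects_rem()], and attaches
#' Benjamini-Hochberg FDR values and an up/down/ns call at the supplied
#' cutoffs. Genes absent from some studies are pooled over the studies that
#' carry them; genes observed in fewer than two studies get `tau2 = 0` by
#' convention.
#'
#' @param studies list of studies; each study is a list with elements
#'   `x` (genes x samples log2 expression matrix with gene row names),
#'   `group` (per-sample labels, values `"normal"`/`"tumor"`), and `id`.
#' @param es_cut absolute combined-effect-size cutoff for the direction call.
#' @param fdr_cut FDR cutoff for the direction call.
#' @return data.frame with one row per gene: per-study `es_*`/`var_*`
#'   columns, `combined_es`, `combined_var`, `tau2`, `p_value`, `fdr`,
#'   `n_studies`, `direction`.
#' @export
meta_effect_table <- function(studies, es_cut = 1.0, fdr_cut = 0.05) {
  if (length(studies) == 0L) stop("need at least one study")
  ids <- vapply(studies, function(s) as.character(s$id), "")
  if (anyDuplicated(ids)) stop("duplicated study ids")
  genes <- sort(unique(unlist(lapply(studies, function(s) rownames(s$x)))),
                method = "radix")
  if (length(genes) == 0L) stop("studies carry no gene identifiers")
  ns <- length(studies)
  es_mat <- matrix(NA_real_, length(genes), ns, dimnames = list(genes, ids))
  var_mat <- es_mat
  for (i in seq_len(ns)) {
    st <- studies[[i]]
    grp <- as.character(st$group)
    if (!all(grp %in% c("normal", "tumor"))) {
      stop("group labels must be 'normal' or 'tumor' (study ", ids[i], ")")
    }
    if (sum(grp == "normal") < 2 || sum(grp == "tumor") < 2) {
      stop("study ", ids[i], " needs >= 2 samples per group")
    }
    hg <- hedges_g_rows(st$x[, grp == "tumor", drop = FALSE],
                        st$x[, grp == "normal", drop = FALSE])
    es_mat[rownames(st$x), i] <- hg$es
    var_mat[rownames(st$x), i] <- hg$var
  }

  # vectorized DerSimonian-Laird across genes
  w <- 1 / var_mat
  w[is.na(es_mat)] <- NA
  sw <- rowSums(w, na.rm = TRUE)
  esbar <- rowSums(w * es_mat, na.rm = TRUE) / sw
  q <- rowSums(w * (es_mat - esbar)^2, na.rm = TRUE)
  s <- rowSums(!is.na(es_mat))
  if (any(s == 0)) stop("gene with no usable study")
  denom <- sw - rowSums(w^2, na.rm = TRUE) / sw
  tau2 <- ifelse(s >= 2, pmax(0, (q - (s - 1)) / denom), 0)
  wstar <- 1 / (var_mat + tau2)
  wstar[is.na(es_mat)] <- NA
  sws <- rowSums(wstar, na.rm = TRUE)
  ces <- rowSums(wstar * es_mat, na.rm = TRUE) / sws
  cvar <- 1 / sws
  p <- 2 * stats::pnorm(-abs(ces / sqrt(cvar)))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  fdr <- fdr_adjust(p)
  direction <- ifelse(fdr <= fdr_cut & ces > es_cut, "up",
                      ifelse(fdr <= fdr_cut & ces < -es_cut, "down", "ns"))

  out <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (i in seq_len(ns)) {
    out[[paste0("es_", ids[i])]] <- es_mat[, i]
    out[[paste0("var_", ids[i])]] <- var_mat[, i]
  }
  out$combined_es <- ces
  out$combined_var <- cvar
  out$tau2 <- tau2
  out$p_value <- p
  out$fdr <- fdr
  out$n_studies <- s
  out$direction <- direction
  rownames(out) <- NULL
  out
}

#' Filter differentially expressed genes from a meta-analysis table
#'
#' Applies the combined-effect-size and FDR cutoffs: up-regulated genes have
#' `combined_es > es_cut` (strict) and `fdr <= fdr_cut`; down-regulated genes
#' mirror this with `combined_es < -es_cut`.
#'
#' @param table a data.frame from [meta_effect_table()] (needs columns
#'   `gene`, `combined_es`, `fdr`).
#' @param es_cut absolute combined-effect-size cutoff (strict inequality).
#' @param fdr_cut FDR cutoff (inclusive).
#' @return list with character vectors `up` and `down`.
#' @export
filter_degs <- function(table, es_cut = 1.0, fdr_cut = 0.05) {
  need <- c("gene", "combined_es", "fdr")
  if (!all(need %in% names(table))) {
    stop("table must have columns gene, combined_es, fdr")
  }
  keep <- table$fdr <= fdr_cut
  list(up = table$gene[keep & table$combined_es > es_cut],
       down = table$gene[keep & table$combined_es < -es_cut])
}

#' Per-batch expression standardization
#'
#' A deliberately simple location/scale batch adjustment: within each batch,
#' every gene is standardized to zero mean and unit variance, then mapped back
#' to that gene's global (across-batch) mean and standard deviation. It
#' removes additive and multiplicative batch offsets per gene; it is not an
#' empirical-Bayes method and makes no attempt to preserve group effects
#' confounded with batch. Genes with zero variance inside some batch are left
#' unadjusted in that batch (with a message).
#'
#' @param x genes x samples expression matrix.
#' @param batch per-sample batch labels (each batch needs >= 2 samples).
#' @return the adjusted matrix, same shape and dimnames.
#' @export
batch_adjust <- function(x, batch) {
  x <- as.matrix(x)
  batch <- as.character(batch)
  if (length(batch) != ncol(x)) stop("one batch label per sample is required")
  tab <- table(batch)
  if (any(tab < 2)) {
    stop("singleton batch: ", paste(names(tab)[tab < 2], collapse = ", "))
  }
  gm <- rowMeans(x)
  gs <- apply(x, 1, stats::sd)
  out <- x
  skipped <- 0L
  for (b in names(tab)) {
    idx <- which(batch == b)
    xb <- x[, idx, drop = FALSE]
    bm <- rowMeans(xb)
    bs <- apply(xb, 1, stats::sd)
    ok <- bs > 0 & gs > 0
    skipped <- skipped + sum(!ok)
    out[ok, idx] <- (xb[ok, , drop = FALSE] - bm[ok]) / bs[ok] * gs[ok] + gm[ok]
  }
  if (skipped > 0) {
    message(skipped, " gene-by-batch cells had zero variance and were left unadjusted")
  }
  out
}
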