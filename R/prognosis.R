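#' Construct a risk model
#'
#' A risk model is the minimal object needed to score samples: a set of genes
#' and one coefficient per gene. Models from [stepwise_cox_bic()],
#' [lasso_cox_baseline()] and [luad_eight_gene_model()] are interchangeable.
#'
#' @param genes character vector of gene identifiers (duplicate-free).
#' @param coefficients numeric coefficients, one per gene.
#' @param bic model BIC if available.
#' @param metadata free-form list of fit information.
#' @return an object of class `risk_model`.
#' @export
risk_model <- function(genes, coefficients, bic = NA_real_, metadata = list()) {
  genes <- as.character(genes)
  coefficients <- as.numeric(coefficients)
  if (length(genes) != length(coefficients)) {
    stop("genes and coefficients lengths differ")
  }
  if (anyDuplicated(genes)) stop("duplicated gene in risk model")
  if (length(coefficients) && !all(is.finite(coefficients))) {
    stop("coefficients must be finite")
  }
  structure(list(genes = genes, coefficients = coefficients,
                 hrs = exp(coefficients), bic = bic, metadata = metadata),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Risk model with %d gene(s)", length(x$genes)))
  if (is.finite(x$bic)) cat(sprintf(", BIC = %.2f", x$bic))
  cat("\n")
  if (length(x$genes)) {
    df <- data.frame(gene = x$genes, coefficient = x$coefficients,
                     HR = x$hrs)
    print(df, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

align_clinical <- function(x, clinical) {
  clinical <- clinical_table(clinical)
  if (!all(clinical$sample_id %in% colnames(x))) {
    miss <- setdiff(clinical$sample_id, colnames(x))
    stop("samples missing from expression matrix: ",
         paste(utils::head(miss, 3), collapse = ", "))
  }
  list(x = x[, clinical$sample_id, drop = FALSE], clinical = clinical)
}

#' Univariate Cox screen over genes
#'
#' Fits one proportional-hazards model per gene with that gene's expression
#' as the single covariate and reports the coefficient, hazard ratio with
#' 95\% confidence interval, and Wald p-value. Ties are handled by the Efron
#' approximation (the `survival::coxph` default). Genes with constant
#' expression are skipped with a message.
#'
#' @param x genes x samples expression matrix.
#' @param clinical clinical table matching the samples.
#' @return data.frame with columns `gene`, `beta`, `hr`, `ci_low`, `ci_high`, `p`.
#' @export
univariate_cox <- function(x, clinical) {
  al <- align_clinical(x, clinical)
  x <- al$x; clinical <- al$clinical
  if (ncol(x) < 10) stop("need >= 10 samples for the Cox screen")
  if (sum(clinical$status) < 1) stop("no events in the clinical table")
  srv <- survival::Surv(clinical$time, clinical$status)
  genes <- rownames(x)
  rows <- vector("list", length(genes))
  skipped <- character(0)
  for (i in seq_along(genes)) {
    e <- x[i, ]
    if (stats::sd(e) == 0) { skipped <- c(skipped, genes[i]); next }
    fit <- tryCatch(survival::coxph(srv ~ e),
                    error = function(err) NULL, warning = function(w) {
                      suppressWarnings(survival::coxph(srv ~ e))
                    })
    if (is.null(fit)) { skipped <- c(skipped, genes[i]); next }
    sm <- summary(fit)
    rows[[i]] <- data.frame(gene = genes[i],
                            beta = unname(stats::coef(fit)[1]),
                            hr = unname(sm$conf.int[1, "exp(coef)"]),
                            ci_low = unname(sm$conf.int[1, "lower .95"]),
                            ci_high = unname(sm$conf.int[1, "upper .95"]),
                            p = unname(sm$coefficients[1, "Pr(>|z|)"]),
                            stringsAsFactors = FALSE)
  }
  if (length(skipped)) {
    message("skipped ", length(skipped), " gene(s) in the Cox screen: ",
            paste(utils::head(skipped, 5), collapse = ", "))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) stop("no gene could be fitted")
  rownames(out) <- NULL
  out
}

#' Select candidate genes by univariate hazard ratio
#'
#' Keeps genes whose univariate hazard ratio is at or above the threshold
#' (higher expression associated with higher mortality hazard). No p-value
#' condition is applied at this stage.
#'
#' @param rows data.frame from [univariate_cox()].
#' @param hr_threshold hazard-ratio threshold (inclusive), default 1.0.
#' @return character vector of selected genes.
#' @export
select_candidates <- function(rows, hr_threshold = 1.0) {
  if (!all(c("gene", "hr") %in% names(rows))) {
    stop("rows must have columns gene and hr")
  }
  if (nrow(rows) == 0L) stop("empty screen table")
  rows$gene[rows$hr >= hr_threshold]
}

cox_bic <- function(loglik, q, n_events) -2 * loglik + q * log(n_events)

#' Bidirectional stepwise multivariate Cox model under BIC
#'
#' Starting from the null model, repeatedly considers adding any unused
#' candidate or dropping any included one, taking the move with the lowest
#' `BIC = -2 logPL + q log(n_events)` (q covariates, partial likelihood at
#' the fitted coefficients) and stopping when no move improves. Moves are
#' scanned in candidate input order; exact BIC ties are broken by gene
#' identifier so the search is deterministic. Covariates whose fit fails to
#' converge at a step are skipped for that step.
#'
#' @param x genes x samples expression matrix.
#' @param clinical matching clinical table.
#' @param candidates character vector of candidate genes (subset of rownames
#'   of `x`).
#' @return a [risk_model()] with the selected genes, Cox coefficients, and
#'   the final BIC (the null model gives an empty gene set).
#' @export
stepwise_cox_bic <- function(x, clinical, candidates) {
  candidates <- as.character(candidates)
  if (length(candidates) == 0L) stop("empty candidate set")
  if (!all(candidates %in% rownames(x))) {
    stop("candidates missing from the expression matrix: ",
         paste(utils::head(setdiff(candidates, rownames(x)), 3), collapse = ", "))
  }
  al <- align_clinical(x, clinical)
  x <- al$x; clinical <- al$clinical
  n_events <- sum(clinical$status)
  if (n_events < 1) stop("no events in the clinical table")
  if (n_events < length(candidates)) {
    warning("fewer events than candidate covariates; stepwise search may be unstable")
  }
  srv <- survival::Surv(clinical$time, clinical$status)
  xmat <- t(x[candidates, , drop = FALSE])   # samples x candidates

  fit_subset <- function(sel) {
    if (length(sel) == 0L) {
      f0 <- survival::coxph(srv ~ 1)
      return(list(loglik = f0$loglik[1], coef = numeric(0)))
    }
    f <- tryCatch(
      withCallingHandlers(
        survival::coxph(srv ~ xmat[, sel, drop = FALSE]),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(f) || any(!is.finite(stats::coef(f)))) return(NULL)
    list(loglik = f$loglik[2], coef = unname(stats::coef(f)))
  }

  current <- character(0)
  f <- fit_subset(current)
  current_bic <- cox_bic(f$loglik, 0L, n_events)
  current_fit <- f
  repeat {
    moves <- c(setdiff(candidates, current), current)  # adds then drops
    best <- NULL
    for (g in moves) {
      sel <- if (g %in% current) setdiff(current, g) else c(current, g)
      fg <- fit_subset(sel)
      if (is.null(fg)) next
      bic <- cox_bic(fg$loglik, length(sel), n_events)
      if (is.null(best) || bic < best$bic - 1e-12 ||
          (abs(bic - best$bic) <= 1e-12 && g < best$gene)) {
        best <- list(gene = g, sel = sel, bic = bic, fit = fg)
      }
    }
    if (is.null(best) || best$bic >= current_bic - 1e-8) break
    current <- best$sel
    current_bic <- best$bic
    current_fit <- best$fit
  }

  risk_model(genes = current, coefficients = current_fit$coef,
             bic = current_bic,
             metadata = list(method = "stepwise_cox_bic",
                             n_events = n_events,
                             n_candidates = length(candidates)))
}

#' Linear risk score of a risk model
#'
#' The per-sample linear predictor `LP = sum_m beta_m * expr_m` over the
#' model's genes; with `type = "hazard"` the relative hazard `exp(LP)` is
#' returned instead. No baseline hazard is estimated: scores are relative,
#' which is all that risk stratification and ROC analysis need.
#'
#' @param model a [risk_model()].
#' @param x genes x samples expression matrix carrying all model genes.
#' @param type `"lp"` (linear predictor, default) or `"hazard"` (`exp(LP)`).
#' @return named numeric vector, one score per sample.
#' @export
risk_score <- function(model, x, type = c("lp", "hazard")) {
  type <- match.arg(type)
  x <- as.matrix(x)
  if (length(model$genes) == 0L) {
    lp <- stats::setNames(rep(0, ncol(x)), colnames(x))
  } else {
    miss <- setdiff(model$genes, rownames(x))
    if (length(miss)) {
      stop("model genes missing from expression matrix: ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
    sub <- x[model$genes, , drop = FALSE]
    if (!all(is.finite(sub))) stop("non-finite expression for a model gene")
    lp <- drop(crossprod(sub, model$coefficients))
    names(lp) <- colnames(x)
  }
  if (type == "hazard") exp(lp) else lp
}

#' Stratify samples into high- and low-risk groups
#'
#' Default rule is a median split with ties assigned to the low-risk group:
#' a sample is `"high"` iff its score strictly exceeds the cut point.
#' `rule = "quantile"` cuts at an arbitrary quantile `q` instead.
#'
#' @param scores numeric risk scores (length >= 2).
#' @param rule `"median"` or `"quantile"`.
#' @param q quantile used when `rule = "quantile"`.
#' @return factor with levels `low`, `high`, named like `scores`.
#' @export
stratify_risk <- function(scores, rule = c("median", "quantile"), q = 0.5) {
  rule <- match.arg(rule)
  nm <- names(scores)
  scores <- as.numeric(scores)
  if (length(scores) < 2L) stop("need >= 2 samples to stratify")
  if (max(scores) == min(scores)) stop("all risk scores identical: stratification is degenerate")
  cut <- if (rule == "median") stats::median(scores) else stats::quantile(scores, q, names = FALSE)
  out <- factor(ifelse(scores > cut, "high", "low"), levels = c("low", "high"))
  names(out) <- nm
  out
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimates per risk group plus the standard log-rank
#' test (chi-square with 1 degree of freedom for two groups).
#'
#' @param clinical clinical table.
#' @param groups per-sample group labels aligned with `clinical` rows.
#' @return list of class `km_logrank` with the `survfit` object (`$fit`),
#'   `$chisq`, `$p`, and the group sizes.
#' @export
km_logrank <- function(clinical, groups) {
  clinical <- clinical_table(clinical)
  groups <- as.factor(groups)
  if (length(groups) != nrow(clinical)) stop("one group label per sample is required")
  if (any(table(groups) == 0)) stop("empty risk group")
  if (sum(clinical$status) < 1) stop("no events")
  df <- data.frame(time = clinical$time, status = clinical$status, group = groups)
  sd <- survival::survdiff(survival::Surv(time, status) ~ group, data = df)
  chisq <- unname(sd$chisq)
  p <- stats::pchisq(chisq, df = length(levels(droplevels(groups))) - 1,
                     lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, status) ~ group, data = df)
  structure(list(fit = fit, chisq = chisq, p = p,
                 n = table(droplevels(groups))),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-square = %.4f, p = %.4g\n", x$chisq, x$p))
  print(x$n)
  invisible(x)
}

#' The published eight-gene LUAD prognostic signature
#'
#' Returns the eight-gene early-stage lung adenocarcinoma risk model with its
#' published per-gene weights. As published, the weights equal the
#' multivariate hazard ratios of the genes rather than their log hazard
#' ratios; `weights = "log_hr"` gives the conventional Cox linear predictor
#' using `log(HR)` instead.
#'
#' @param weights `"hr"` (the published convention, default) or `"log_hr"`.
#' @return a [risk_model()] over RACGAP1, CDCA8, RCC2, PLK1, KIF20B, ALG3,
#'   BRCA1 and CHAF1B.
#' @examples
#' m <- luad_eight_gene_model()
#' sum(m$coefficients)  # score of a sample expressing every gene at 1
#' @export
luad_eight_gene_model <- function(weights = c("hr", "log_hr")) {
  weights <- match.arg(weights)
  w <- c(RACGAP1 = 1.1168, CDCA8 = 0.4740, RCC2 = 1.4432, PLK1 = 1.7456,
         KIF20B = 1.6966, ALG3 = 1.1153, BRCA1 = 0.6784, CHAF1B = 1.3090)
  co <- if (weights == "log_hr") log(w) else w
  risk_model(genes = names(w), coefficients = unname(co),
             metadata = list(source = "published eight-gene LUAD signature",
                             weights = weights))
}
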