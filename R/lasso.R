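#' Cross-validated LASSO-Cox comparator model
#'
#' L1-penalized Cox partial likelihood over all genes with the penalty chosen
#' by seeded k-fold cross-validation of the partial-likelihood deviance.
#' Folds are stratified by vital status so that every fold carries events.
#' Genes with a nonzero coefficient at the selected penalty form the model.
#'
#' @param x genes x samples expression matrix.
#' @param clinical matching clinical table.
#' @param cv_folds number of CV folds (>= 3).
#' @param seed integer seed controlling fold assignment (given the seed the
#'   selection is deterministic).
#' @param lambda `"min"` (deviance-minimizing penalty, default) or `"1se"`.
#' @return a [risk_model()] with the selected genes and coefficients;
#'   metadata records the chosen penalty.
#' @export
lasso_cox_baseline <- function(x, clinical, cv_folds = 5L, seed = 1L,
                               lambda = c("min", "1se")) {
  lambda <- match.arg(lambda)
  al <- align_clinical(x, clinical)
  x <- al$x; clinical <- al$clinical
  cv_folds <- as.integer(cv_folds)
  if (cv_folds < 3L) stop("cv_folds must be >= 3")
  if (ncol(x) < cv_folds) stop("need at least as many samples as folds")
  if (nrow(x) < 2L) stop("the LASSO comparator needs >= 2 genes")
  set.seed(seed)
  foldid <- integer(ncol(x))
  for (st in c(0L, 1L)) {
    idx <- which(clinical$status == st)
    if (length(idx)) {
      foldid[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
  }
  y <- survival::Surv(clinical$time, clinical$status)
  cv <- glmnet::cv.glmnet(t(x), y, family = "cox", foldid = foldid)
  s <- if (lambda == "min") cv$lambda.min else cv$lambda.1se
  co <- as.matrix(stats::coef(cv, s = s))
  nz <- which(co[, 1] != 0)
  risk_model(genes = rownames(co)[nz], coefficients = co[nz, 1],
             metadata = list(method = "lasso_cox", lambda = s,
                             lambda_rule = lambda, cv_folds = cv_folds,
                             seed = seed))
}

eval_auc_horizons <- function(model, x, clinical, horizons, roc_method = "km") {
  scores <- risk_score(model, x)
  vapply(horizons, function(h) {
    tryCatch(time_dependent_roc(scores, clinical, h, method = roc_method)$auc,
             error = function(e) NA_real_)
  }, numeric(1))
}

#' Compare the FSOR-derived and LASSO-Cox prognostic pipelines
#'
#' Runs both arms on the same data split and scores them with time-dependent
#' AUC at the requested horizons. The FSOR arm fits [fit_fsor()] on the
#' training samples, keeps the `top_m` genes by weight, screens them with
#' [univariate_cox()], keeps hazard ratios >= `hr_threshold`, and refines the
#' multivariate model with [stepwise_cox_bic()]. The LASSO arm fits
#' [lasso_cox_baseline()] on the full training gene matrix. With
#' `split = "holdout"` (default) models are built on a seeded
#' status-stratified training fraction and evaluated on the held-out samples;
#' `split = "resubstitution"` evaluates on the training data itself.
#'
#' Horizons at which the ROC is undefined on the evaluation set (no events
#' yet, or nobody still at risk) yield `NA` and are dropped from the means.
#'
#' @param x genes x samples expression matrix.
#' @param clinical matching clinical table.
#' @param horizons numeric vector of horizons in years.
#' @param top_m genes kept from the FSOR ranking.
#' @param hr_threshold univariate hazard-ratio selection threshold.
#' @param split `"holdout"` or `"resubstitution"`.
#' @param train_frac training fraction under `"holdout"`.
#' @param cv_folds folds for the LASSO arm.
#' @param opts [fsor_options()] for the FSOR arm.
#' @param seed integer seed for the split and the LASSO folds.
#' @param roc_method passed to [time_dependent_roc()].
#' @return list of class `pipeline_comparison`: `$table` (method x horizon
#'   AUC rows), `$summary` (per-method mean AUC over horizons <= 3 and over
#'   all horizons), `$models`, `$split`.
#' @export
compare_pipelines <- function(x, clinical, horizons = 1:4, top_m = 20L,
                              hr_threshold = 1.0,
                              split = c("holdout", "resubstitution"),
                              train_frac = 2 / 3, cv_folds = 5L,
                              opts = fsor_options(), seed = 1L,
                              roc_method = "km") {
  split <- match.arg(split)
  al <- align_clinical(x, clinical)
  x <- al$x; clinical <- al$clinical
  n <- ncol(x)
  if (split == "holdout") {
    set.seed(seed + 1L)
    tr <- logical(n)
    for (st in c(0L, 1L)) {
      idx <- which(clinical$status == st)
      tr[sample(idx, max(1L, round(train_frac * length(idx))))] <- TRUE
    }
    x_tr <- x[, tr, drop = FALSE]; cl_tr <- clinical[tr, ]
    x_ev <- x[, !tr, drop = FALSE]; cl_ev <- clinical[!tr, ]
  } else {
    x_tr <- x_ev <- x
    cl_tr <- cl_ev <- clinical
  }

  # FSOR arm
  y <- build_label_matrix(cl_tr)
  fit <- fit_fsor(x_tr, y, opts)
  top <- rank_features(fit, min(top_m, nrow(x_tr)))$gene
  screen <- univariate_cox(x_tr[top, , drop = FALSE], cl_tr)
  cands <- select_candidates(screen, hr_threshold)
  model_fsor <- if (length(cands)) {
    stepwise_cox_bic(x_tr, cl_tr, cands)
  } else {
    risk_model(character(0), numeric(0),
               metadata = list(method = "stepwise_cox_bic", note = "no candidate passed the screen"))
  }
  if (length(model_fsor$genes) == 0L && length(cands)) {
    # BIC kept the null model; fall back to the single best candidate so the
    # arm still produces a usable score
    best <- screen[order(screen$p), ][1, ]
    model_fsor <- stepwise_cox_bic(x_tr, cl_tr, best$gene)
  }

  # LASSO arm
  model_lasso <- lasso_cox_baseline(x_tr, cl_tr, cv_folds = cv_folds, seed = seed)

  auc_f <- eval_auc_horizons(model_fsor, x_ev, cl_ev, horizons, roc_method)
  auc_l <- eval_auc_horizons(model_lasso, x_ev, cl_ev, horizons, roc_method)
  table <- data.frame(method = rep(c("fsor_cox", "lasso_cox"), each = length(horizons)),
                      horizon = rep(horizons, 2),
                      auc = c(auc_f, auc_l),
                      stringsAsFactors = FALSE)
  early <- horizons <= 3
  summary <- data.frame(method = c("fsor_cox", "lasso_cox"),
                        mean_auc_early = c(mean(auc_f[early], na.rm = TRUE),
                                           mean(auc_l[early], na.rm = TRUE)),
                        mean_auc_all = c(mean(auc_f, na.rm = TRUE),
                                         mean(auc_l, na.rm = TRUE)),
                        n_genes = c(length(model_fsor$genes),
                                    length(model_lasso$genes)),
                        stringsAsFactors = FALSE)
  structure(list(table = table, summary = summary,
                 models = list(fsor = model_fsor, lasso = model_lasso),
                 split = split),
            class = "pipeline_comparison")
}

#' @export
print.pipeline_comparison <- function(x, ...) {
  cat("Pipeline comparison (", x$split, " evaluation)\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
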