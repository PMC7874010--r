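#' Simulate a multi-study two-group expression data set
#'
#' Generates several studies of log2-scale tumor/normal expression with known
#' planted differential genes, emulating a multi-cohort microarray design.
#' Gene baseline means are drawn once from Normal(7, 1); each study adds its
#' own batch intercept Normal(0, `batch_shift_sd`) to every gene, and
#' measurement noise is i.i.d. Normal(0, `noise_sd`). Planted genes shift the
#' tumor group by `effect * noise_sd`, where the study-specific standardized
#' effect is drawn from Normal(`effect_mean`, `effect_sd`) (negated for the
#' down-regulated set), so true effects are heterogeneous across studies as a
#' random-effects model assumes. Everything is a pure function of the seed.
#'
#' @param n_studies number of studies.
#' @param n_genes total genes.
#' @param n_up,n_down planted up-/down-regulated gene counts.
#' @param effect_mean,effect_sd mean and SD of the planted standardized
#'   effect across studies.
#' @param samples_per_group per-study samples in each group (recycled to
#'   `n_studies`). The default mirrors a realistic unbalanced multi-study
#'   design with one small cohort.
#' @param batch_shift_sd SD of the per-study additive intercept.
#' @param noise_sd residual SD on the log2 scale.
#' @param seed integer seed.
#' @return list with `studies` (each `list(x, group, id)`, consumable by
#'   [meta_effect_table()]) and `truth` (data.frame `gene`, `direction`,
#'   `true_effect`).
#' @export
simulate_multistudy <- function(n_studies = 4L, n_genes = 1000L,
                                n_up = 30L, n_down = 30L,
                                effect_mean = 1.5, effect_sd = 0.2,
                                samples_per_group = c(59L, 58L, 20L, 83L),
                                batch_shift_sd = 1, noise_sd = 1,
                                seed = 1L) {
  stopifnot(n_up + n_down <= n_genes, n_genes >= 1, n_studies >= 1,
            effect_sd >= 0, batch_shift_sd >= 0, noise_sd > 0)
  samples_per_group <- rep_len(as.integer(samples_per_group), n_studies)
  if (any(samples_per_group < 2)) stop("each group needs >= 2 samples")
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  up_idx <- seq_len(n_up)
  down_idx <- n_up + seq_len(n_down)
  base_mean <- stats::rnorm(n_genes, 7, 1)
  studies <- vector("list", n_studies)
  for (s in seq_len(n_studies)) {
    npg <- samples_per_group[s]
    id <- sprintf("study%02d", s)
    batch <- stats::rnorm(1, 0, batch_shift_sd)
    eff <- numeric(n_genes)
    if (n_up) eff[up_idx] <- stats::rnorm(n_up, effect_mean, effect_sd)
    if (n_down) eff[down_idx] <- -stats::rnorm(n_down, effect_mean, effect_sd)
    grp <- rep(c("normal", "tumor"), each = npg)
    mu <- base_mean + batch + outer(eff * noise_sd, as.numeric(grp == "tumor"))
    xs <- mu + matrix(stats::rnorm(n_genes * 2 * npg, 0, noise_sd),
                      n_genes, 2 * npg)
    rownames(xs) <- genes
    colnames(xs) <- sprintf("%s_s%03d", id, seq_len(2 * npg))
    studies[[s]] <- list(x = xs, group = grp, id = id)
  }
  direction <- rep("null", n_genes)
  direction[up_idx] <- "up"
  direction[down_idx] <- "down"
  true_effect <- numeric(n_genes)
  true_effect[up_idx] <- effect_mean
  true_effect[down_idx] <- -effect_mean
  list(studies = studies,
       truth = data.frame(gene = genes, direction = direction,
                          true_effect = true_effect, stringsAsFactors = FALSE))
}

#' Simulate a survival cohort with a planted Cox signal
#'
#' Expression is drawn as correlated Gaussian blocks (`block_size` genes
#' sharing a latent factor with within-block correlation `block_rho`) and
#' standardized per gene. A planted gene subset carries true log-hazard
#' coefficients (uniform on `beta_range`, or given explicitly via `betas`);
#' event times follow a Weibull baseline hazard scaled by `exp(LP)` via
#' inverse-transform sampling, so the data-generating model is exactly the
#' proportional-hazards risk-score form the downstream Cox stack assumes.
#' Censoring is independent Uniform(0, c_max) with c_max tuned by bisection
#' on the realized event times so the observed censoring fraction matches
#' `censor_rate`.
#'
#' @param n_samples cohort size.
#' @param n_genes gene count.
#' @param n_prognostic planted prognostic gene count (ignored when `betas`
#'   is supplied).
#' @param beta_range interval for the true log-hazard coefficients.
#' @param betas optional named numeric vector of true coefficients keyed by
#'   gene id (genes are `gene0001` ... ), overriding the random draw.
#' @param weibull_shape,weibull_scale baseline Weibull parameters (scale in
#'   days; the defaults give a baseline median around 2.4 years).
#' @param censor_rate target fraction censored, in \[0, 1).
#' @param block_size,block_rho correlation-block structure of the expression.
#' @param seed integer seed.
#' @return list with `x` (genes x samples), `clinical` (see
#'   [clinical_table()]), `truth` (data.frame `gene`, `beta`), and `lp`
#'   (true per-sample linear predictor).
#' @export
simulate_survival_cohort <- function(n_samples = 479L, n_genes = 1000L,
                                     n_prognostic = 5L,
                                     beta_range = c(0.5, 1), betas = NULL,
                                     weibull_shape = 1.2,
                                     weibull_scale = 1200,
                                     censor_rate = 0.4,
                                     block_size = 10L, block_rho = 0.3,
                                     seed = 1L) {
  stopifnot(n_samples >= 2, n_genes >= 1, censor_rate >= 0, censor_rate < 1,
            weibull_shape > 0, weibull_scale > 0,
            block_rho >= 0, block_rho < 1)
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(n_genes))
  samples <- sprintf("s%04d", seq_len(n_samples))

  n_blocks <- ceiling(n_genes / block_size)
  x <- matrix(0, n_genes, n_samples, dimnames = list(genes, samples))
  for (b in seq_len(n_blocks)) {
    rows <- ((b - 1) * block_size + 1):min(b * block_size, n_genes)
    f <- stats::rnorm(n_samples)
    eps <- matrix(stats::rnorm(length(rows) * n_samples), length(rows))
    x[rows, ] <- sqrt(block_rho) * rep(f, each = length(rows)) +
      sqrt(1 - block_rho) * eps
  }
  x <- t(scale(t(x)))  # per-gene standardization
  attributes(x) <- list(dim = c(n_genes, n_samples),
                        dimnames = list(genes, samples))

  if (is.null(betas)) {
    stopifnot(n_prognostic <= n_genes)
    prog <- sort(sample.int(n_genes, n_prognostic))
    beta <- stats::runif(n_prognostic, beta_range[1], beta_range[2])
    names(beta) <- genes[prog]
  } else {
    if (is.null(names(betas)) || !all(names(betas) %in% genes)) {
      stop("betas must be named by gene ids present in the cohort")
    }
    beta <- betas
  }
  lp <- drop(crossprod(x[names(beta), , drop = FALSE], beta))

  u <- stats::runif(n_samples)
  t_event <- weibull_scale * (-log(u) / exp(lp))^(1 / weibull_shape)
  if (censor_rate == 0) {
    time <- t_event
    status <- rep(1L, n_samples)
  } else {
    u2 <- stats::runif(n_samples)
    frac_cens <- function(cmax) mean(u2 * cmax < t_event)
    lo <- min(t_event) * 1e-3
    hi <- max(t_event) * 100
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (frac_cens(mid) > censor_rate) lo <- mid else hi <- mid
    }
    cmax <- (lo + hi) / 2
    cens <- u2 * cmax
    status <- as.integer(t_event <= cens)
    time <- pmin(t_event, cens)
  }
  time <- pmax(time, 1e-3)
  clinical <- clinical_table(samples, time = time, status = status)
  list(x = x, clinical = clinical,
       truth = data.frame(gene = names(beta), beta = unname(beta),
                          stringsAsFactors = FALSE),
       lp = stats::setNames(lp, samples))
}

#' Simulate a two-class testbed for the FSOR solver
#'
#' A balanced two-class cohort in which `n_informative` genes are shifted
#' between classes by 2 residual SDs while all other genes are pure noise.
#' The supervision signal is clinical: vital status is Bernoulli with death
#' probability 0.8 in the poor-outcome class vs 0.2 otherwise, and follow-up
#' time is exponential with mean 300 days (poor) vs 1200 days (good), so the
#' label matrix built by [build_label_matrix()] carries the class signal the
#' informative genes track.
#'
#' @param d gene count.
#' @param n sample count (even).
#' @param n_informative planted informative gene count.
#' @param seed integer seed.
#' @return list with `x`, `y` (label matrix), `clinical`, `truth` (character
#'   vector of informative gene ids), `class` (0/1 per sample).
#' @export
make_fsor_testbed <- function(d = 100L, n = 200L, n_informative = 5L,
                              seed = 1L) {
  stopifnot(n_informative <= d, n >= 4)
  set.seed(seed)
  genes <- sprintf("gene%04d", seq_len(d))
  samples <- sprintf("s%04d", seq_len(n))
  cls <- rep(c(0L, 1L), length.out = n)
  informative <- sort(sample.int(d, n_informative))
  base <- stats::rnorm(d, 7, 1)
  x <- base + matrix(stats::rnorm(d * n), d, n)
  if (n_informative) {
    x[informative, ] <- x[informative, ] +
      2.0 * matrix(rep(cls, each = n_informative), n_informative, n)
  }
  dimnames(x) <- list(genes, samples)
  p_death <- ifelse(cls == 1L, 0.8, 0.2)
  status <- stats::rbinom(n, 1, p_death)
  time <- stats::rexp(n, rate = 1 / ifelse(cls == 1L, 300, 1200))
  time <- pmax(time, 1e-3)
  clinical <- clinical_table(samples, time = time, status = status)
  y <- build_label_matrix(clinical)
  list(x = x, y = y, clinical = clinical,
       truth = genes[informative], class = cls)
}

#' Simulate matched inputs for the full pipeline
#'
#' Couples the two generators on a shared gene universe: a multi-study
#' tumor/normal design whose planted up-regulated genes include the
#' prognostic genes of a survival cohort, so the meta-analysis filter, the
#' FSOR ranking and the Cox stack can all find the same planted biology.
#' Optionally also returns a small interaction network connecting the planted
#' genes (a clique among prognostic genes plus sparse random edges).
#'
#' @param n_genes shared gene count.
#' @param n_up,n_down planted DEG counts for the multi-study design.
#' @param n_prognostic prognostic genes, drawn from the planted up set.
#' @param cohort_n survival cohort size.
#' @param samples_per_group per-study group sizes for the multi-study design.
#' @param beta_range true log-hazard coefficient range.
#' @param censor_rate target censoring fraction.
#' @param with_network if TRUE, also return `edges` (a data.frame usable as
#'   an interaction edge list).
#' @param seed integer seed.
#' @return list with `meta` (from [simulate_multistudy()]), `cohort` (from
#'   [simulate_survival_cohort()]) and optionally `edges`.
#' @export
simulate_pipeline_inputs <- function(n_genes = 300L, n_up = 30L, n_down = 30L,
                                     n_prognostic = 5L, cohort_n = 300L,
                                     samples_per_group = c(30L, 30L, 20L, 40L),
                                     beta_range = c(0.5, 1),
                                     censor_rate = 0.4,
                                     with_network = FALSE, seed = 1L) {
  meta <- simulate_multistudy(n_genes = n_genes, n_up = n_up, n_down = n_down,
                              samples_per_group = samples_per_group,
                              seed = seed)
  up_genes <- meta$truth$gene[meta$truth$direction == "up"]
  set.seed(seed + 1L)
  prog <- sort(sample(up_genes, n_prognostic))
  beta <- stats::runif(n_prognostic, beta_range[1], beta_range[2])
  names(beta) <- prog
  cohort <- simulate_survival_cohort(n_samples = cohort_n, n_genes = n_genes,
                                     betas = beta, censor_rate = censor_rate,
                                     seed = seed + 2L)
  out <- list(meta = meta, cohort = cohort)
  if (with_network) {
    set.seed(seed + 3L)
    cl <- t(utils::combn(prog, 2))
    n_rand <- 3L * n_up
    rnd <- cbind(sample(up_genes, n_rand, replace = TRUE),
                 sample(up_genes, n_rand, replace = TRUE))
    rnd <- rnd[rnd[, 1] != rnd[, 2], , drop = FALSE]
    edges <- data.frame(node1 = c(cl[, 1], rnd[, 1]),
                        node2 = c(cl[, 2], rnd[, 2]),
                        combined_score = round(stats::runif(nrow(cl) + nrow(rnd),
                                                            400, 999)),
                        stringsAsFactors = FALSE)
    out$edges <- edges
  }
  out
}
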