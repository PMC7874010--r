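test_that("univariate Cox recovers a planted log-hazard coefficient", {
  betas <- sapply(1:8, function(s) {
    sim <- simulate_survival_cohort(n_samples = 400, n_genes = 3,
                                    betas = c(gene0001 = 0.7),
                                    censor_rate = 0.4, seed = s)
    scr <- univariate_cox(sim$x, sim$clinical)
    scr$beta[scr$gene == "gene0001"]
  })
  expect_lt(abs(mean(betas) - 0.7), 0.1)
})

test_that("Cox screen is affine-equivariant and skips constant genes", {
  sim <- simulate_survival_cohort(n_samples = 150, n_genes = 4,
                                  betas = c(gene0002 = 0.8),
                                  censor_rate = 0.3, seed = 3)
  scr <- univariate_cox(sim$x, sim$clinical)
  x2 <- sim$x
  x2["gene0002", ] <- 2 * x2["gene0002", ]
  scr2 <- univariate_cox(x2, sim$clinical)
  i <- which(scr$gene == "gene0002")
  expect_equal(scr2$beta[i], scr$beta[i] / 2, tolerance = 1e-6)
  expect_equal(scr2$p[i], scr$p[i], tolerance = 1e-6)
  expect_equal(scr$hr, exp(scr$beta))
  expect_true(all(scr$ci_low <= scr$hr & scr$hr <= scr$ci_high))

  x3 <- rbind(sim$x, flat = 5)
  expect_message(scr3 <- univariate_cox(x3, sim$clinical), "skipped")
  expect_false("flat" %in% scr3$gene)
})

test_that("hazard-ratio selection matches the published univariate screen", {
  rows <- data.frame(gene = names(published_univariate_hrs),
                     hr = unname(published_univariate_hrs))
  kept <- select_candidates(rows, 1.0)
  expect_setequal(setdiff(rows$gene, kept),
                  c("STX1A", "KAT2A", "MTA3", "GTF2IRD1", "HDAC10", "FOXRED1"))
  # boundary is inclusive
  expect_true("x" %in% select_candidates(data.frame(gene = "x", hr = 1.0)))
  expect_length(select_candidates(data.frame(gene = "x", hr = 0.5)), 0)
})

test_that("stepwise BIC keeps strong signals and prunes null candidates", {
  hits <- 0
  for (s in 1:5) {
    sim <- simulate_survival_cohort(n_samples = 400, n_genes = 5,
                                    betas = c(gene0001 = 1),
                                    censor_rate = 0.3, seed = s + 20)
    m <- stepwise_cox_bic(sim$x, sim$clinical, rownames(sim$x))
    if ("gene0001" %in% m$genes) hits <- hits + 1
    # BIC of the chosen model beats the null model
    f0 <- survival::coxph(survival::Surv(sim$clinical$time,
                                         sim$clinical$status) ~ 1)
    expect_lt(m$bic, -2 * f0$loglik[1])
  }
  expect_equal(hits, 5)

  sizes <- sapply(1:5, function(s) {
    sim <- simulate_survival_cohort(n_samples = 200, n_genes = 10,
                                    n_prognostic = 0, censor_rate = 0.3,
                                    seed = s + 50)
    length(stepwise_cox_bic(sim$x, sim$clinical, rownames(sim$x))$genes)
  })
  expect_lte(mean(sizes), 1)
})

test_that("a collinear duplicate adds nothing to the stepwise model", {
  sim <- simulate_survival_cohort(n_samples = 300, n_genes = 4,
                                  betas = c(gene0001 = 1),
                                  censor_rate = 0.3, seed = 77)
  x2 <- rbind(sim$x, dup0001 = sim$x["gene0001", ])
  m1 <- stepwise_cox_bic(sim$x, sim$clinical, rownames(sim$x))
  m2 <- stepwise_cox_bic(x2, sim$clinical, rownames(x2))
  expect_equal(length(m2$genes), length(m1$genes))
})

test_that("stepwise selection is invariant to candidate order", {
  sim <- simulate_survival_cohort(n_samples = 250, n_genes = 8,
                                  n_prognostic = 2, censor_rate = 0.3,
                                  seed = 31)
  base <- stepwise_cox_bic(sim$x, sim$clinical, rownames(sim$x))
  set.seed(1)
  for (i in 1:10) {
    perm <- sample(rownames(sim$x))
    m <- stepwise_cox_bic(sim$x, sim$clinical, perm)
    expect_setequal(m$genes, base$genes)
    expect_equal(m$bic, base$bic, tolerance = 1e-9)
  }
})

test_that("risk scores reproduce the published eight-gene signature", {
  model <- luad_eight_gene_model()
  x0 <- matrix(0, 8, 2, dimnames = list(model$genes, c("s1", "s2")))
  expect_equal(unname(risk_score(model, x0)), c(0, 0))
  expect_equal(unname(risk_score(model, x0, type = "hazard")), c(1, 1))
  x1 <- x0 + 1
  expect_equal(unname(risk_score(model, x1))[1],
               1.1168 + 0.4740 + 1.4432 + 1.7456 + 1.6966 + 1.1153 +
                 0.6784 + 1.3090)
  # one unit of PLK1 adds exactly its coefficient
  x2 <- x1; x2["PLK1", 1] <- 2
  expect_equal(unname(risk_score(model, x2) - risk_score(model, x1))[1],
               1.7456)
  expect_error(risk_score(model, x0[-1, , drop = FALSE]), "missing")
  # log-HR variant
  expect_equal(luad_eight_gene_model("log_hr")$coefficients,
               log(model$coefficients))
})

test_that("median stratification puts ties in the low-risk group", {
  g <- stratify_risk(c(1, 2, 3, 4))
  expect_equal(as.character(g), c("low", "low", "high", "high"))
  g2 <- stratify_risk(c(1, 2, 2, 5))  # median 2: tied samples stay low
  expect_equal(as.character(g2), c("low", "low", "low", "high"))
  expect_error(stratify_risk(3), ">= 2")
  expect_error(stratify_risk(c(1, 1, 1)), "identical")
})

test_that("log-rank statistic matches the hand computation on a toy fixture", {
  time <- c(6, 7, 10, 8, 9, 11)
  status <- rep(1, 6)
  group <- rep(c("A", "B"), each = 3)
  cl <- clinical_table(sprintf("p%d", 1:6), time = time, status = status)
  got <- km_logrank(cl, group)
  ora <- logrank_oracle(time, status, group)
  expect_equal(got$chisq, ora$chisq, tolerance = 1e-9)
  expect_equal(got$p, ora$p, tolerance = 1e-9)
})

test_that("log-rank is null for exchangeable groups and symmetric in labels", {
  cl <- clinical_table(sprintf("p%d", 1:8),
                       time = rep(c(5, 9, 14, 20), 2),
                       status = rep(c(1, 0, 1, 1), 2))
  g <- rep(c("A", "B"), each = 4)
  # each group holds one copy of the same times and statuses
  got <- km_logrank(cl, g)
  expect_equal(got$chisq, 0, tolerance = 1e-12)
  expect_equal(got$p, 1)
  swap <- km_logrank(cl, ifelse(g == "A", "B", "A"))
  expect_equal(km_logrank(cl, g)$chisq, swap$chisq, tolerance = 1e-12)
})

test_that("KM product-limit estimates match the closed form", {
  cl <- clinical_table(c("a", "b"), time = c(5, 10), status = c(1, 1))
  km <- km_logrank(clinical_table(c("a", "b", "c", "d"),
                                  time = c(5, 10, 5, 10),
                                  status = c(1, 1, 1, 1)),
                   rep(c("A", "B"), each = 2))
  s <- summary(km$fit)
  expect_equal(s$surv, c(0.5, 0, 0.5, 0))
})
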