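test_that("Hedges' g matches the corrected standardized mean difference", {
  set.seed(3)
  z <- as.numeric(scale(rnorm(10)))  # exact mean 0, sd 1
  res <- study_effect_size(z + 1, z)
  expect_equal(res$es, 1 - 3 / 71, tolerance = 1e-12)
  expect_equal(res$var, 20 / 100 + res$es^2 / 40, tolerance = 1e-12)

  x1 <- rnorm(8, 5); x2 <- rnorm(12, 5)
  same <- study_effect_size(x1, x1)
  expect_equal(same$es, 0)
  a <- study_effect_size(x1, x2); b <- study_effect_size(x2, x1)
  expect_equal(a$es, -b$es)
  expect_equal(a$var, b$var)
  expect_error(study_effect_size(rep(1, 5), rep(1, 5)), "zero")
  expect_error(study_effect_size(1, rnorm(5)), ">= 2")
})

test_that("DerSimonian-Laird pooling matches textbook formulas and metafor", {
  # hand-checkable two-study case: Q = 3.2, tau2 = 0.22, pooled es = 0.6
  res <- combine_effects_rem(c(1.0, 0.2), c(0.1, 0.1))
  expect_equal(res$tau2, 0.22, tolerance = 1e-12)
  expect_equal(res$combined_es, 0.6, tolerance = 1e-12)
  expect_equal(res$combined_var, 0.32 / 2, tolerance = 1e-12)

  # single study and homogeneous limits
  one <- combine_effects_rem(0.8, 0.05)
  expect_equal(one$combined_es, 0.8)
  expect_equal(one$tau2, 0)
  expect_equal(one$combined_var, 0.05)
  hom <- combine_effects_rem(rep(1, 3), rep(0.1, 3))
  expect_equal(hom$tau2, 0)
  expect_equal(hom$combined_es, 1)
  expect_equal(hom$combined_var, 0.1 / 3)

  for (i in 1:5) {
    set.seed(i)
    es <- rnorm(4); v <- runif(4, 0.05, 0.3)
    got <- combine_effects_rem(es, v)
    ora <- dl_oracle(es, v)
    expect_equal(got$combined_es, ora$mu, tolerance = 1e-10)
    expect_equal(got$tau2, ora$tau2, tolerance = 1e-10)
    expect_equal(got$combined_var, ora$var, tolerance = 1e-10)
    expect_equal(got$p, ora$p, tolerance = 1e-10)
    skip_if_not_installed("metafor")
    mf <- metafor::rma(yi = es, vi = v, method = "DL")
    expect_equal(got$combined_es, as.numeric(mf$beta), tolerance = 1e-8)
    expect_equal(got$tau2, mf$tau2, tolerance = 1e-8)
  }
})

test_that("fixed-effect pooling is recovered when studies are homogeneous", {
  es <- c(0.5, 0.5, 0.5); v <- c(0.2, 0.1, 0.05)
  res <- combine_effects_rem(es, v)
  w <- 1 / v
  expect_equal(res$tau2, 0)
  expect_equal(res$combined_es, sum(w * es) / sum(w))
  expect_equal(res$combined_var, 1 / sum(w))
})

test_that("BH adjustment matches the hand computation and preserves order", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(fdr_adjust(0.2), 0.2)
  set.seed(8)
  p <- runif(50)
  q <- fdr_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_true(all(q <= 1) && all(q >= p - 1e-15))
  expect_error(fdr_adjust(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("the DEG filter applies strict ES and inclusive FDR cutoffs", {
  tab <- data.frame(gene = c("a", "b", "c", "d", "e"),
                    combined_es = c(1.0, 1.5, -1.2, -1.0, 2.0),
                    fdr = c(0.01, 0.01, 0.02, 0.01, 0.2))
  degs <- filter_degs(tab)
  expect_equal(degs$up, "b")       # a excluded: es not > 1; e excluded: fdr
  expect_equal(degs$down, "c")     # d excluded: es not < -1
  expect_length(intersect(degs$up, degs$down), 0)
})

test_that("meta table agrees with the scalar path and flags planted genes", {
  sim <- simulate_multistudy(n_studies = 3, n_genes = 60, n_up = 6, n_down = 6,
                             samples_per_group = c(15, 20, 12), seed = 7)
  tab <- meta_effect_table(sim$studies)
  expect_equal(tab$gene, sort(sim$truth$gene, method = "radix"))
  # scalar recomputation for a few genes
  for (g in tab$gene[c(1, 10, 33)]) {
    es <- v <- numeric(0)
    for (st in sim$studies) {
      r <- study_effect_size(st$x[g, st$group == "tumor"],
                             st$x[g, st$group == "normal"])
      es <- c(es, r$es); v <- c(v, r$var)
    }
    ora <- combine_effects_rem(es, v)
    row <- tab[tab$gene == g, ]
    expect_equal(row$combined_es, ora$combined_es, tolerance = 1e-10)
    expect_equal(row$tau2, ora$tau2, tolerance = 1e-10)
  }
  degs <- filter_degs(tab)
  truth_up <- sim$truth$gene[sim$truth$direction == "up"]
  truth_down <- sim$truth$gene[sim$truth$direction == "down"]
  expect_gte(length(intersect(degs$up, truth_up)) / length(truth_up), 0.8)
  expect_gte(length(intersect(degs$down, truth_down)) / length(truth_down), 0.8)
})

test_that("per-batch standardization removes additive shifts", {
  set.seed(4)
  x <- matrix(rnorm(40 * 30, 7), 40, 30)
  rownames(x) <- sprintf("g%02d", 1:40)
  batch <- rep(c("b1", "b2"), each = 15)
  shifted <- x
  shifted[, batch == "b2"] <- shifted[, batch == "b2"] + 3
  adj <- batch_adjust(shifted, batch)
  m1 <- rowMeans(adj[, batch == "b1"]); m2 <- rowMeans(adj[, batch == "b2"])
  expect_lt(max(abs(m1 - m2)), 1e-9)
  # single batch is the identity
  expect_lt(max(abs(batch_adjust(x, rep("b1", 30)) - x)), 1e-12)
  expect_error(batch_adjust(x, c("a", rep("b", 29))), "singleton")
})

test_that("planted batch variance is suppressed by the adjustment", {
  sim <- simulate_multistudy(n_studies = 3, n_genes = 50, n_up = 0, n_down = 0,
                             samples_per_group = c(20, 20, 20),
                             batch_shift_sd = 2, seed = 12)
  x <- do.call(cbind, lapply(sim$studies, function(s) s$x))
  batch <- rep(sapply(sim$studies, function(s) s$id),
               sapply(sim$studies, function(s) ncol(s$x)))
  between_var <- function(m) {
    mean(apply(m, 1, function(row) var(tapply(row, batch, mean))))
  }
  adj <- batch_adjust(x, batch)
  expect_lt(between_var(adj), 0.05 * between_var(x))
})
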