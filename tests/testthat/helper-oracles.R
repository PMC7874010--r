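# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force or textbook formulas, sharing no code with the
# package implementation.

# Best value of the Stiefel k=1 objective w'Cw - 2 w'd over random unit vectors.
sphere_sample_min <- function(c_mat, d_vec, n_draws = 1e5, seed = 1) {
  set.seed(seed)
  d <- nrow(c_mat)
  w <- matrix(rnorm(n_draws * d), d, n_draws)
  w <- sweep(w, 2, sqrt(colSums(w^2)), "/")
  obj <- colSums(w * (c_mat %*% w)) - 2 * colSums(w * as.numeric(d_vec))
  min(obj)
}

# Dense grid search of phi' H phi - phi' r over the 2-simplex (d = 3).
simplex_grid_min <- function(h_mat, r, step = 0.001) {
  g <- seq(0, 1, by = step)
  pts <- expand.grid(p1 = g, p2 = g)
  pts <- pts[pts$p1 + pts$p2 <= 1 + 1e-12, ]
  p <- rbind(pts$p1, pts$p2, pmax(1 - pts$p1 - pts$p2, 0))
  obj <- colSums(p * (h_mat %*% p)) - colSums(p * as.numeric(r))
  min(obj)
}

# Profiled-bias oracle: numerically minimize the uncentred loss over b.
objective_profile_b <- function(x, y, w, phi) {
  k <- nrow(y)
  f <- function(b) {
    sum((crossprod(w, phi * x) + outer(b, rep(1, ncol(x))) - y)^2)
  }
  opt <- optim(rep(0, k), f, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  opt$value
}

# Textbook DerSimonian-Laird, coded independently.
dl_oracle <- function(es, v) {
  w <- 1 / v
  fixed <- sum(w * es) / sum(w)
  q <- sum(w * (es - fixed)^2)
  s <- length(es)
  c_dl <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - (s - 1)) / c_dl)
  w2 <- 1 / (v + tau2)
  mu <- sum(w2 * es) / sum(w2)
  list(mu = mu, var = 1 / sum(w2), tau2 = tau2,
       p = 2 * pnorm(-abs(mu / sqrt(1 / sum(w2)))))
}

# Hand log-rank for two groups: sum over event times of (O - E) in group 1,
# variance from the hypergeometric form.
logrank_oracle <- function(time, status, group) {
  g1 <- levels(factor(group))[1]
  o_minus_e <- 0
  v <- 0
  for (tt in sort(unique(time[status == 1]))) {
    at_risk <- time >= tt
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == tt & status == 1)
    d1 <- sum(time == tt & status == 1 & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# Brute-force maximal clique centrality for graphs given as an edge matrix
# (2-column character), over all vertex subsets.
mcc_bruteforce <- function(nodes, edges) {
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    adj[cbind(edges[, 1], edges[, 2])] <- TRUE
    adj[cbind(edges[, 2], edges[, 1])] <- TRUE
  }
  is_clique <- function(s) all(adj[s, s][upper.tri(matrix(0, length(s), length(s)))])
  subsets <- unlist(lapply(2:length(nodes), function(k)
    combn(nodes, k, simplify = FALSE)), recursive = FALSE)
  cliques <- Filter(is_clique, subsets)
  maximal <- Filter(function(s) {
    !any(vapply(setdiff(nodes, s), function(v) is_clique(c(s, v)), TRUE))
  }, cliques)
  score <- setNames(rep(0, length(nodes)), nodes)
  for (cl in maximal) score[cl] <- score[cl] + factorial(length(cl) - 1)
  score
}

# Empirical (binary) AUC by the Mann-Whitney statistic.
mw_auc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

random_psd <- function(d, seed) {
  set.seed(seed)
  a <- matrix(rnorm(d * d), d, d)
  crossprod(a) / d
}

random_stiefel <- function(d, k, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(d * k), d, k)))
}

# Published univariate hazard ratios of the 32-gene LUAD candidate screen,
# used as a printed-table fixture for the selection rule.
published_univariate_hrs <- c(
  CPSF3 = 1.1262, UNG = 1.4095, CDCA8 = 1.1656, RCC2 = 1.2477,
  PLK1 = 1.2994, DDX23 = 1.6505, TACO1 = 1.1527, COPB2 = 1.3559,
  STX1A = 0.9996, POU2F1 = 1.0808, SF3B3 = 1.2231, STT3A = 1.1578,
  KAT2A = 0.8785, PSMD4 = 1.1397, MTA3 = 0.9545, KIF20B = 1.477,
  KIFC1 = 1.1626, C1orf112 = 1.3575, RACGAP1 = 1.2801, BRCC3 = 1.0651,
  DONSON = 1.2907, GTF2IRD1 = 0.8124, ALG3 = 1.3626, CHAF1B = 1.2906,
  LIN9 = 1.2842, BCL9 = 1.0935, PUS1 = 1.0632, HDAC10 = 0.8455,
  CHD7 = 1.106, FOXRED1 = 0.8799, BRCA1 = 1.1587, BOLA3 = 1.0905)
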