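#' Solver options for FSOR
#'
#' Tuning knobs for [fit_fsor()] and its two sub-solvers. `outer_tol` is the
#' absolute change in the regression objective between consecutive outer
#' (alternating) iterations below which the fit stops; its default of 0.1 is
#' the conventional stopping rule for this solver and is scale-dependent, so
#' rescale it if your objective lives on a very different scale. `mu0` and
#' `rho` control the augmented-Lagrangian penalty schedule (`mu <- rho * mu`
#' after every multiplier update). `alpha_margin` inflates the spectral shift
#' used by the generalized power iteration so that the shifted curvature
#' matrix is strictly positive definite.
#'
#' @param outer_tol positive; outer-loop objective-change tolerance.
#' @param max_outer_iter positive integer; outer iteration cap.
#' @param gpi_tol positive; Frobenius-change tolerance of the W iterate.
#' @param gpi_max_iter positive integer; GPI iteration cap.
#' @param alm_tol positive; ALM feasibility tolerance (max of the
#'   nonnegativity-split residual and the simplex-sum residual).
#' @param alm_max_iter positive integer; ALM iteration cap.
#' @param mu0 positive; initial augmented-Lagrangian penalty.
#' @param rho penalty inflation factor, > 1.
#' @param alpha_margin small positive relaxation margin for the spectral shift.
#' @param seed integer seed for the W initialization.
#' @return a list of class `fsor_options`.
#' @export
fsor_options <- function(outer_tol = 0.1, max_outer_iter = 1000L,
                         gpi_tol = 1e-8, gpi_max_iter = 500L,
                         alm_tol = 1e-6, alm_max_iter = 200L,
                         mu0 = 1, rho = 1.1, alpha_margin = 1e-6,
                         seed = 1L) {
  stopifnot(outer_tol > 0, gpi_tol > 0, alm_tol > 0,
            max_outer_iter >= 1, gpi_max_iter >= 1, alm_max_iter >= 1,
            mu0 > 0, rho > 1, alpha_margin > 0)
  structure(list(outer_tol = outer_tol,
                 max_outer_iter = as.integer(max_outer_iter),
                 gpi_tol = gpi_tol, gpi_max_iter = as.integer(gpi_max_iter),
                 alm_tol = alm_tol, alm_max_iter = as.integer(alm_max_iter),
                 mu0 = mu0, rho = rho, alpha_margin = alpha_margin,
                 seed = as.integer(seed)),
            class = "fsor_options")
}

#' Weighted orthogonal-regression objective
#'
#' Evaluates `|| W' diag(phi) X M - Y M ||_F^2`, the centred form of the FSOR
#' loss after the bias vector b has been profiled out at its closed-form
#' optimum b = (1/n) (Y 1 - W' diag(phi) X 1).
#'
#' @param x d x n expression matrix.
#' @param y k x n label matrix.
#' @param w d x k projection matrix.
#' @param phi length-d nonnegative weight vector.
#' @return the scalar objective value.
#' @export
fsor_objective <- function(x, y, w, phi) {
  x <- as.matrix(x); y <- as.matrix(y); w <- as.matrix(w)
  phi <- as.numeric(phi)
  if (ncol(x) != ncol(y)) stop("x and y must have the same number of samples")
  if (nrow(w) != nrow(x) || ncol(w) != nrow(y)) stop("w has incompatible shape")
  if (length(phi) != nrow(x)) stop("phi length must equal the gene count")
  if (any(phi < 0)) stop("phi must be elementwise nonnegative")
  resid <- crossprod(w, apply_centering(phi * x)) - apply_centering(y)
  sum(resid^2)
}

stiefel_check <- function(w, tol = 1e-8) {
  k <- ncol(w)
  sqrt(sum((crossprod(w) - diag(k))^2)) <= tol
}

#' Quadratic minimization on the Stiefel manifold by generalized power iteration
#'
#' Minimizes `Tr(W' C W - 2 W' D)` subject to `W' W = I_k` by the generalized
#' power iteration: the problem is recast as maximizing
#' `Tr(W' Ctilde W) + 2 Tr(W' D)` with `Ctilde = alpha I - C` strictly
#' positive definite (`alpha = lambda_max(C) (1 + alpha_margin) +
#' alpha_margin`), and each sweep replaces W by the orthogonal polar factor
#' `U V'` of the ascent direction `G = 2 Ctilde W + 2 D` (thin SVD
#' `G = U S V'`). The relaxed objective is non-decreasing across sweeps; the
#' iteration stops when `||W_{t+1} - W_t||_F <= gpi_tol`.
#'
#' Because the constrained quadratic can own a second, spurious local
#' optimum (the hard case of the trust-region subproblem), the solver also
#' restarts from the Procrustes point `U V'` of the SVD of D — the exact
#' solution when C = 0 — and returns whichever run attains the better
#' objective.
#'
#' @param c_mat d x d symmetric positive semidefinite curvature matrix.
#' @param d_mat d x k linear-term matrix.
#' @param w0 d x k feasible starting point (`w0' w0 = I`).
#' @param opts an [fsor_options()] list.
#' @return the d x k solution W, with attributes `n_iter` and `converged`.
#' @export
solve_w_gpi <- function(c_mat, d_mat, w0, opts = fsor_options()) {
  c_mat <- as.matrix(c_mat); d_mat <- as.matrix(d_mat); w0 <- as.matrix(w0)
  d <- nrow(c_mat)
  k <- ncol(d_mat)
  if (ncol(c_mat) != d) stop("C must be square")
  if (max(abs(c_mat - t(c_mat))) > 1e-8 * max(1, max(abs(c_mat)))) {
    stop("C must be symmetric")
  }
  if (nrow(d_mat) != d) stop("D row count must match C")
  if (k > d) stop("k must not exceed d on the Stiefel manifold")
  if (nrow(w0) != d || ncol(w0) != k) stop("w0 has incompatible shape")
  if (!stiefel_check(w0, 1e-6)) stop("w0 is not on the Stiefel manifold")

  lam_max <- max(eigen(c_mat, symmetric = TRUE, only.values = TRUE)$values, 0)
  alpha <- lam_max * (1 + opts$alpha_margin) + opts$alpha_margin

  # Ctilde = alpha I - C, applied without forming alpha*I explicitly
  run_from <- function(w) {
    converged <- FALSE
    iter <- 0L
    for (iter in seq_len(opts$gpi_max_iter)) {
      g <- 2 * (alpha * w - c_mat %*% w) + 2 * d_mat
      sv <- svd(g, nu = k, nv = k)
      w_new <- sv$u %*% t(sv$v)
      delta <- sqrt(sum((w_new - w)^2))
      w <- w_new
      if (delta <= opts$gpi_tol) { converged <- TRUE; break }
    }
    obj <- alpha * k - sum(diag(crossprod(w, c_mat %*% w))) + 2 * sum(w * d_mat)
    list(w = w, obj = obj, iter = iter, converged = converged)
  }

  # the sphere-constrained quadratic can own a second, spurious local
  # optimum; restarting from the Procrustes point polar(D) (the C = 0
  # solution) covers the basin the warm start can miss
  runs <- list(run_from(w0))
  if (any(d_mat != 0)) {
    sv <- svd(d_mat, nu = k, nv = k)
    if (min(sv$d) > 0) runs <- c(runs, list(run_from(sv$u %*% t(sv$v))))
  }
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "obj"))]]
  w <- best$w
  attr(w, "n_iter") <- best$iter
  attr(w, "converged") <- best$converged
  w
}

#' Nonnegative simplex quadratic program by augmented Lagrangian multipliers
#'
#' Approximately minimizes `phi' H phi - phi' r` over the probability simplex
#' (phi >= 0, sum(phi) = 1). Nonnegativity is handled by a split variable v
#' with multiplier `lambda1`, the sum constraint by a scalar multiplier
#' `lambda2`; each iteration solves the unconstrained phi-subproblem
#' `J phi = g` with `J = 2H + mu I + mu 1 1'` and
#' `g = mu v + mu 1 - lambda2 1 - lambda1 + r`, projects
#' `v = max(phi + lambda1/mu, 0)`, then takes first-order multiplier steps and
#' inflates the penalty `mu <- rho mu`. The linear solves reuse a single
#' eigendecomposition of H through a Sherman-Morrison update, so each
#' iteration costs O(d^2).
#'
#' The returned weights are exactly feasible: the converged iterate is clipped
#' at zero and renormalized to unit sum (a second-order perturbation near the
#' KKT point).
#'
#' @param h_mat d x d symmetric positive semidefinite matrix.
#' @param r length-d linear term.
#' @param opts an [fsor_options()] list.
#' @return length-d weight vector with attributes `converged`, `n_iter`,
#'   `residual` (pre-projection feasibility residual).
#' @export
solve_phi_alm <- function(h_mat, r, opts = fsor_options()) {
  h_mat <- as.matrix(h_mat)
  r <- as.numeric(r)
  d <- nrow(h_mat)
  if (ncol(h_mat) != d) stop("H must be square")
  if (length(r) != d) stop("r length must match H")
  if (max(abs(h_mat - t(h_mat))) > 1e-8 * max(1, max(abs(h_mat)))) {
    stop("H must be symmetric")
  }
  eh <- eigen((h_mat + t(h_mat)) / 2, symmetric = TRUE)
  scale <- max(1, abs(eh$values[1]))
  if (min(eh$values) < -1e-8 * scale) {
    stop("H is not positive semidefinite")
  }
  lam <- pmax(eh$values, 0)
  q <- eh$vectors
  # (2H + mu I)^{-1} x via the cached eigendecomposition
  b_inv <- function(x, mu) q %*% ((crossprod(q, x)) / (2 * lam + mu))

  phi <- rep(1 / d, d)
  v <- phi
  lambda1 <- rep(0, d)
  lambda2 <- 0
  mu <- opts$mu0
  ones <- rep(1, d)
  converged <- FALSE
  residual <- Inf
  best_phi <- phi
  best_res <- Inf
  iter <- 0L
  for (iter in seq_len(opts$alm_max_iter)) {
    g <- mu * v + mu - lambda2 - lambda1 + r
    bg <- b_inv(g, mu)
    bu <- b_inv(ones, mu)
    # Sherman-Morrison for the rank-one mu*11' term
    phi <- as.numeric(bg - (mu * sum(bg) / (1 + mu * sum(bu))) * bu)
    v <- pmax(phi + lambda1 / mu, 0)
    residual <- max(max(abs(phi - v)), abs(sum(phi) - 1))
    if (residual < best_res) { best_res <- residual; best_phi <- phi }
    if (residual <= opts$alm_tol) { converged <- TRUE; break }
    lambda1 <- lambda1 + mu * (phi - v)
    lambda2 <- lambda2 + mu * (sum(phi) - 1)
    mu <- mu * opts$rho
  }
  if (!converged) {
    warning(sprintf(
      "ALM did not reach tolerance %.1e in %d iterations (residual %.2e); returning best iterate",
      opts$alm_tol, opts$alm_max_iter, best_res))
    phi <- best_phi
    residual <- best_res
  }
  phi <- pmax(phi, 0)
  phi <- phi / sum(phi)
  attr(phi, "converged") <- converged
  attr(phi, "n_iter") <- iter
  attr(phi, "residual") <- residual
  phi
}

#' Fit feature selection with orthogonal regression
#'
#' Minimizes `|| W' diag(phi) X + b 1' - Y ||_F^2` subject to `W' W = I_k` and
#' phi on the probability simplex, by alternating minimization: with phi
#' fixed, W solves a quadratic Stiefel-manifold problem with
#' `C = Phi X M X' Phi` and `D = Phi X M Y'` via [solve_w_gpi()]; with W
#' fixed, phi solves the simplex quadratic program with
#' `H = (X M X') o (W W')` (Hadamard product, positive semidefinite by the
#' Schur product theorem) and \code{r = diag(2 X M Y' W')} via
#' [solve_phi_alm()].
#' The bias b is profiled out through the centering operator M and recovered
#' afterwards in closed form. Iteration stops once the objective decreases by
#' no more than `opts$outer_tol`.
#'
#' phi starts uniform at 1/d; W starts from the Q factor of a seeded standard
#' normal draw, so fits are reproducible given `opts$seed`.
#'
#' @param x d x n expression matrix (genes x samples, log2 scale).
#' @param y k x n label matrix, e.g. from [build_label_matrix()].
#' @param opts an [fsor_options()] list.
#' @param keep_path if TRUE, per-iteration W and phi snapshots are stored
#'   under `$path` (for diagnostics; memory grows with iterations).
#' @return an object of class `fsor_model` with elements `W`, `phi`, `b`,
#'   `objective_trace`, `n_outer_iter`, `converged`, `gene_ids`, `options`.
#' @examples
#' tb <- make_fsor_testbed(d = 30, n = 60, n_informative = 3, seed = 1)
#' fit <- fit_fsor(tb$x, tb$y, fsor_options(seed = 1))
#' head(rank_features(fit, 5))
#' @export
fit_fsor <- function(x, y, opts = fsor_options(), keep_path = FALSE) {
  x <- as.matrix(x); y <- as.matrix(y)
  storage.mode(x) <- "double"; storage.mode(y) <- "double"
  d <- nrow(x); n <- ncol(x); k <- nrow(y)
  if (ncol(y) != n) stop("x and y must share the sample dimension")
  if (n < 2) stop("need at least two samples")
  if (k > d) stop("label row count k must not exceed the gene count d")
  gene_ids <- rownames(x)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%04d", seq_len(d))

  xc <- apply_centering(x)            # X M
  yc <- apply_centering(y)            # Y M
  a_mat <- tcrossprod(xc)             # X M X'  (M idempotent)
  xmyt <- tcrossprod(xc, yc)          # X M Y'

  set.seed(opts$seed)
  w <- qr.Q(qr(matrix(stats::rnorm(d * k), d, k)))
  phi <- rep(1 / d, d)

  trace <- fsor_objective(x, y, w, phi)
  path <- if (keep_path) list(list(w = w, phi = phi)) else NULL
  converged <- FALSE
  outer <- 0L
  for (outer in seq_len(opts$max_outer_iter)) {
    c_mat <- a_mat * tcrossprod(phi)
    d_mat <- phi * xmyt
    w <- solve_w_gpi(c_mat, d_mat, w, opts)

    h_mat <- a_mat * tcrossprod(w)
    r <- 2 * rowSums(xmyt * w)
    phi <- as.numeric(solve_phi_alm(h_mat, r, opts))

    obj <- fsor_objective(x, y, w, phi)
    if (!is.finite(obj)) {
      stop(sprintf("objective became non-finite at outer iteration %d", outer))
    }
    trace <- c(trace, obj)
    if (keep_path) path[[outer + 1L]] <- list(w = w, phi = phi)
    if (abs(trace[outer] - obj) <= opts$outer_tol) { converged <- TRUE; break }
  }

  b <- as.numeric(rowMeans(y) - crossprod(w, phi * rowMeans(x)))
  structure(list(W = w, phi = phi, b = b,
                 objective_trace = as.numeric(trace),
                 n_outer_iter = outer, converged = converged,
                 gene_ids = gene_ids, options = opts,
                 path = path),
            class = "fsor_model")
}

#' @export
print.fsor_model <- function(x, ...) {
  cat(sprintf("FSOR model: %d genes, k = %d label rows\n",
              length(x$phi), ncol(x$W)))
  cat(sprintf("  outer iterations: %d (%s), objective %.4f -> %.4f\n",
              x$n_outer_iter,
              if (x$converged) "converged" else "iteration cap reached",
              x$objective_trace[1], utils::tail(x$objective_trace, 1)))
  top <- rank_features(x, min(5L, length(x$phi)))
  cat("  top weights:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %s  %.4g\n", top$gene[i], top$weight[i]))
  }
  invisible(x)
}

#' Rank genes by FSOR weight
#'
#' Sorts genes by their fitted weight phi in decreasing order, breaking ties
#' by gene identifier (C-locale lexicographic order, so rankings are
#' platform-independent), and returns the top `top_m`.
#'
#' @param model an `fsor_model` from [fit_fsor()].
#' @param top_m number of genes to return (1..d).
#' @return data.frame with columns `rank`, `gene`, `weight`.
#' @export
rank_features <- function(model, top_m) {
  phi <- model$phi
  genes <- model$gene_ids
  d <- length(phi)
  top_m <- as.integer(top_m)
  if (top_m < 1L || top_m > d) stop("top_m must be between 1 and the gene count")
  ord <- order(-phi, genes, method = "radix")[seq_len(top_m)]
  data.frame(rank = seq_len(top_m), gene = genes[ord], weight = phi[ord],
             stringsAsFactors = FALSE)
}
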