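## Population structure: genotype PCA (Patterson normalization) and
## maximum-likelihood admixture (frappe-style EM on the binomial dosage
## likelihood) with cross-validation over K.

#' Genotype principal component analysis
#'
#' Missing dosages are mean-imputed per site; each site is centered by twice
#' its allele frequency and scaled by `sqrt(2p(1-p))` (Patterson
#' normalization), then the top principal components of the sample
#' covariance are extracted by SVD. All-missing and monomorphic sites are
#' dropped.
#'
#' @param gm A [genotype_matrix()].
#' @param n_components Number of components to return (default 10, capped by
#'   the data rank).
#' @return List of class `radsweep_pca`: `coords` (samples x components,
#'   column means ~ 0), `eigenvalues` (non-increasing variances),
#'   `loadings` (sites x components), `sites_used`.
#' @export
pca_genotypes <- function(gm, n_components = 10) {
  d <- gm$dosages
  stopifnot(nrow(d) >= 2L)
  p <- colMeans(d, na.rm = TRUE) / 2
  usable <- !is.na(p) & p > 0 & p < 1
  if (sum(usable) < 2L) stop("pca_genotypes needs >= 2 polymorphic sites")
  d <- d[, usable, drop = FALSE]
  p <- p[usable]
  x <- sweep(d, 2L, 2 * p)
  x[is.na(x)] <- 0                              # mean imputation
  x <- sweep(x, 2L, sqrt(2 * p * (1 - p)), "/")
  k <- min(n_components, nrow(x) - 1L, ncol(x))
  sv <- svd(x, nu = k, nv = k)
  eig <- sv$d[seq_len(k)]^2 / (nrow(x) - 1L)
  coords <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  rownames(coords) <- gm$samples
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coords = coords, eigenvalues = eig, loadings = sv$v,
                 sites_used = which(usable)),
            class = "radsweep_pca")
}

## One EM pass for the admixture model. q: n x K, p: K x m; gg/g2 are the
## alt/ref allele-count matrices with missing cells zeroed. Returns updated
## q, p and the loglik of the parameters *before* the update.
admixture_em_step <- function(gg, g2, q, p, eps = 1e-6) {
  f <- q %*% p                                   # n x m expected frequency
  f <- pmin(pmax(f, eps), 1 - eps)
  ll <- sum(gg * log(f) + g2 * log(1 - f))
  ## expected allele-by-ancestry counts, in BLAS form: the alt-allele count
  ## attributable to ancestry k at site j is p_kj * sum_i (g/f)_ij q_ik
  G1 <- gg / f
  G2 <- g2 / (1 - f)
  a_sum_p <- t(crossprod(G1, q)) * p             # K x m alt-ancestry counts
  b_sum_p <- t(crossprod(G2, q)) * (1 - p)       # K x m ref-ancestry counts
  ab_q <- q * (G1 %*% t(p) + G2 %*% t(1 - p))    # n x K total ancestry draws
  p_new <- a_sum_p / (a_sum_p + b_sum_p)
  p_new[!is.finite(p_new)] <- 0.5
  p_new <- pmin(pmax(p_new, eps), 1 - eps)
  denom <- rowSums(ab_q)
  q_new <- ab_q / denom
  list(q = q_new, p = p_new, loglik = ll)
}

admixture_loglik <- function(g, q, p, eps = 1e-6) {
  f <- pmin(pmax(q %*% p, eps), 1 - eps)
  called <- !is.na(g)
  sum(ifelse(called, g, 0) * log(f) + ifelse(called, 2 - g, 0) * log(1 - f))
}

#' Maximum-likelihood admixture by EM
#'
#' Fits the standard admixture model: dosage
#' `g_ij ~ Binomial(2, sum_k q_ik p_kj)` with ancestry fractions Q (rows sum
#' to one) and ancestral allele frequencies P, by EM block updates from a
#' random Dirichlet / uniform initialization. Missing dosages contribute
#' nothing to the likelihood. The log-likelihood is non-decreasing across
#' iterations; iteration stops when the gain drops below `tol` or at
#' `max_iter` (non-convergence returns the last iterate, flagged).
#'
#' @param gm A [genotype_matrix()].
#' @param K Number of ancestral components (>= 1).
#' @param seed Seed for the random initialization.
#' @param max_iter Maximum EM iterations (default 300).
#' @param tol Log-likelihood gain tolerance (default 1e-4).
#' @return List of class `admixture_fit`: `K`, `Q`, `P`, `loglik`,
#'   `loglik_trace` (per-iteration), `converged`, `n_iter`, `seed`.
#' @export
admixture_em <- function(gm, K, seed = 1, max_iter = 300, tol = 1e-4) {
  stopifnot(K >= 1)
  g <- gm$dosages
  n <- nrow(g); m <- ncol(g)
  set.seed(seed)
  if (K == 1L) {
    p <- colMeans(g, na.rm = TRUE) / 2
    p[!is.finite(p)] <- 0.5
    p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
    P <- matrix(p, 1L, m)
    Q <- matrix(1, n, 1L)
    ll <- admixture_loglik(g, Q, P)
    return(structure(list(K = 1L, Q = Q, P = P, loglik = ll,
                          loglik_trace = ll, converged = TRUE, n_iter = 0L,
                          seed = seed),
                     class = "admixture_fit"))
  }
  ## Dirichlet(1,...,1) rows for Q; uniform P
  q <- matrix(stats::rgamma(n * K, 1), n, K)
  q <- q / rowSums(q)
  p <- matrix(stats::runif(K * m, 0.05, 0.95), K, m)
  called <- !is.na(g)
  gg <- ifelse(called, g, 0L) * 1
  g2 <- ifelse(called, 2L - g, 0L) * 1
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    st <- admixture_em_step(gg, g2, q, p)
    q <- st$q; p <- st$p
    trace <- c(trace, st$loglik)
    if (it >= 2L && (trace[it] - trace[it - 1L]) < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
  }
  ll <- admixture_loglik(g, q, p)
  trace <- c(trace, ll)
  rownames(q) <- gm$samples
  structure(list(K = as.integer(K), Q = q, P = p, loglik = ll,
                 loglik_trace = trace, converged = converged, n_iter = it,
                 seed = seed),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("admixture_fit: K=%d, %d samples, %d sites, loglik=%.2f (%s, %d iter)\n",
              x$K, nrow(x$Q), ncol(x$P), x$loglik,
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' Choose K by cross-validation over admixture fits
#'
#' For each K in `k_range`: keep the best of `n_runs` seeded EM restarts on
#' the full data, then estimate a cross-validation error by masking a random
#' fraction of called genotype cells (in `cv_folds` disjoint folds), refitting
#' on the unmasked cells, and scoring the held-out dosages by mean binomial
#' deviance under the refitted model.
#'
#' @param gm A [genotype_matrix()].
#' @param k_range Integer vector of K values (default 2:10).
#' @param n_runs EM restarts per K (default 20).
#' @param cv_folds Number of holdout folds (default 5; holdout fraction is
#'   `1/cv_folds` of called cells per fold).
#' @param seed Master seed; per-run and per-fold seeds derive from it.
#' @param max_iter,tol Passed to [admixture_em()].
#' @return List: `table` (`data.frame` K, loglik, cv_error), `best_k`
#'   (argmin of cv_error), `fits` (best full-data fit per K).
#' @export
choose_k <- function(gm, k_range = 2:10, n_runs = 20, cv_folds = 5,
                     seed = 1, max_iter = 300, tol = 1e-4) {
  g <- gm$dosages
  called_idx <- which(!is.na(g))
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(cv_folds), length(called_idx)))
  fits <- list()
  rows <- lapply(seq_along(k_range), function(ki) {
    K <- k_range[ki]
    runs <- lapply(seq_len(n_runs), function(r) {
      admixture_em(gm, K, seed = seed + 1000L * K + r,
                   max_iter = max_iter, tol = tol)
    })
    best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "loglik"))]]
    fits[[as.character(K)]] <<- best
    dev <- vapply(seq_len(cv_folds), function(fold) {
      hold <- called_idx[fold_of == fold]
      g_train <- g
      g_train[hold] <- NA_integer_
      gm_train <- genotype_matrix(g_train, gm$samples)
      fit <- admixture_em(gm_train, K, seed = seed + 7L * fold + K,
                          max_iter = max_iter, tol = tol)
      f <- pmin(pmax(fit$Q %*% fit$P, 1e-6), 1 - 1e-6)
      gh <- g[hold]
      ## mean binomial deviance of held-out dosages
      -2 * mean(gh * log(f[hold]) + (2 - gh) * log(1 - f[hold]))
    }, numeric(1))
    data.frame(K = K, loglik = best$loglik, cv_error = mean(dev))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, best_k = tab$K[which.min(tab$cv_error)], fits = fits)
}
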