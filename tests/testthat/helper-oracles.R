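# Independent oracles and fixture builders shared across the test files.
# Each oracle takes a different computational route from the implementation
# it checks.

# Graph energy via the full 2n x 2n symmetric bipartite adjacency:
# sum of absolute eigenvalues of [[0, M], [M', 0]].
bipartite_energy_eig <- function(M) {
  z1 <- matrix(0, nrow(M), nrow(M))
  z2 <- matrix(0, ncol(M), ncol(M))
  full <- rbind(cbind(z1, M), cbind(t(M), z2))
  sum(abs(eigen(full, symmetric = TRUE, only.values = TRUE)$values))
}

# AUC by brute-force comparison of every positive/negative score pair
# (ties count 1/2).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Weighted basis pursuit denoising solved by an established, algorithmically
# independent engine: glmnet's coordinate-descent lasso path with the
# Gaussian weights as penalty factors, bisected on lambda until the
# residual constraint ||y - D b|| <= eps is met from below.
wl1_glmnet_oracle <- function(D, y, w, eps) {
  if (sqrt(sum(y^2)) <= eps) {
    return(list(beta = rep(0, ncol(D)), objective = 0))
  }
  refit <- function(l) {
    f <- glmnet::glmnet(D, y, intercept = FALSE, standardize = FALSE,
                        penalty.factor = w, lambda = l * c(8, 4, 2, 1),
                        thresh = 1e-14, maxit = 1e8)
    as.matrix(f$beta)[, 4L]
  }
  lam0 <- max(abs(crossprod(D, y)) / pmax(w, 1e-12)) / nrow(D) * 2
  fit <- glmnet::glmnet(D, y, intercept = FALSE, standardize = FALSE,
                        penalty.factor = w,
                        lambda = lam0 * 10^seq(0, -13, length.out = 60),
                        thresh = 1e-14, maxit = 1e8)
  B <- as.matrix(fit$beta)
  res <- sqrt(colSums((y - D %*% B)^2))
  i <- which(res <= eps)[1L]
  if (is.na(i)) return(NULL)  # eps not reachable along the path
  lam_lo <- fit$lambda[i]
  lam_hi <- if (i > 1L) fit$lambda[i - 1L] else fit$lambda[1L] * 4
  for (it in 1:50) {
    lm <- sqrt(lam_lo * lam_hi)
    if (sqrt(sum((y - D %*% refit(lm))^2)) <= eps) lam_lo <- lm
    else lam_hi <- lm
  }
  b <- refit(lam_lo)
  list(beta = b, objective = sum(w * abs(b)))
}

# Random small WSRC instance with a planted-feasible test vector: y is a
# sparse combination of dictionary atoms plus noise well inside the
# eps-ball, so the constrained problem is feasible for both solvers.
planted_wl1_instance <- function(m = NULL, n = NULL) {
  if (is.null(m)) m <- sample(3:6, 1)
  if (is.null(n)) n <- sample(4:10, 1)
  X <- matrix(rnorm(m * n), n, m)
  lab <- c(0L, 1L, sample(0:1, n - 2L, replace = TRUE))
  eps <- 10^stats::runif(1, -3, -1)
  model <- wsrc_fit(X, lab, epsilon = eps)
  k <- sample(1:min(3L, n), 1)
  b0 <- numeric(n)
  b0[sample(n, k)] <- rnorm(k)
  y <- as.numeric(model$dictionary %*% b0)
  y <- y + rnorm(m) * eps * 0.1 / sqrt(m)
  y <- y / sqrt(sum(y^2))
  list(model = model, y = y,
       weights = stats::runif(n, 0.05, 1), eps = eps)
}

# Random canonical-residue sequence.
rand_seq <- function(len, prob = NULL) {
  paste(sample(aa_order(), len, replace = TRUE, prob = prob), collapse = "")
}

# Small synthetic dataset written to a temp dir; returns proteins + pairs.
small_dataset <- function(n_pos = 25, n_neg = 25, lengths = c(40, 80),
                          delta = 0.5, seed = 7) {
  spec <- synthetic_spec(n_pos = n_pos, n_neg = n_neg,
                         length_range = lengths, delta = delta, seed = seed)
  fa <- tempfile(fileext = ".fasta")
  pr <- tempfile(fileext = ".tsv")
  ds <- generate_dataset(spec, fa, pr)
  list(proteins = ds$proteins, pairs = ds$pairs, fasta = fa, pair_file = pr)
}
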