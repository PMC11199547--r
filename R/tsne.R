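# Exact t-distributed stochastic neighbour embedding, used for qualitative
# inspection of load patterns across lumbar levels. O(n^2) implementation:
# Gaussian input affinities with per-point precision calibrated to the
# target perplexity by bisection, Student-t low-dimensional kernel,
# gradient descent with momentum and early exaggeration.

.tsne_p_matrix <- function(X, perplexity, tol = 1e-5) {
  n <- nrow(X)
  D2 <- as.matrix(stats::dist(X))^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (iter in 1:64) {
      w <- exp(-d * beta)
      s <- sum(w)
      if (s == 0) { h <- 0; p <- w } else {
        p <- w / s
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      diff <- h - target
      if (abs(diff) < tol) break
      if (diff > 0) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, .Machine$double.xmin)
}

.tsne <- function(X, perplexity = 30, n_iter = 400, seed = 1, eta = 100) {
  n <- nrow(X)
  P <- .tsne_p_matrix(X, perplexity)
  Y <- with_seed(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  G <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  exag <- 4
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= 100) P * exag else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), .Machine$double.xmin)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    mom <- if (it <= 250) 0.5 else 0.8
    gains <- pmax(0.01, ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8))
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Two-dimensional t-SNE embedding of scaled load observations
#'
#' Maps the (scaled) high-dimensional load observations to two dimensions
#' while preserving local similarities; used only for qualitative cluster
#' inspection. Deterministic for a fixed seed.
#'
#' @param x numeric matrix or a load matrix data frame (id columns are
#'   carried through to the output).
#' @param perplexity t-SNE perplexity; requires at least
#'   \code{3 * perplexity + 1} rows.
#' @param seed integer seed for the embedding initialization.
#' @param n_iter gradient-descent iterations.
#' @return Data frame with columns \code{dim1, dim2} plus any id columns
#'   of the input.
#' @export
embed_2d <- function(x, perplexity = 30, seed = 1, n_iter = 400) {
  if (is.data.frame(x)) {
    num <- vapply(x, is.numeric, logical(1))
    ids <- x[, !num, drop = FALSE]
    X <- as.matrix(x[, num, drop = FALSE])
  } else {
    ids <- NULL
    X <- as.matrix(x)
  }
  if (nrow(X) < 3 * perplexity + 1) {
    stop("too few rows for perplexity ", perplexity,
         ": need at least ", 3 * perplexity + 1)
  }
  Y <- .tsne(X, perplexity = perplexity, n_iter = n_iter, seed = seed)
  out <- data.frame(dim1 = Y[, 1], dim2 = Y[, 2])
  if (!is.null(ids) && ncol(ids) > 0) out <- cbind(ids, out)
  rownames(out) <- NULL
  out
}
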