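#' Gaussian information measures between channel groups
#'
#' Entropies here are differential Shannon entropies of multivariate
#' Gaussians, in nats, computed from covariance determinants:
#' H = 1/2 ln((2 pi e)^k |Sigma|). Mutual information and transfer entropy
#' between channel groups are linear combinations of such entropies
#' evaluated on sample covariances of (lagged) signal blocks.
#'
#' @name infotheory
NULL

# log-determinant via Cholesky with a small ridge for numerical stability;
# errors if the regularized matrix is still not positive definite.
logdet_reg <- function(S, eps_rel = 1e-10) {
  S <- (S + t(S)) / 2
  if (any(diag(S) <= 0))
    stop("covariance is not positive definite (degenerate channel group?)")
  eps <- eps_rel * mean(diag(S))
  ch <- tryCatch(chol(S + diag(eps, nrow(S))), error = function(e) NULL)
  if (is.null(ch))
    stop("covariance is not positive definite (degenerate channel group?)")
  2 * sum(log(diag(ch)))
}

#' Differential entropy of a multivariate Gaussian
#'
#' @param cov symmetric positive-definite covariance matrix (k x k).
#' @return entropy in nats, \eqn{\frac12 \ln((2\pi e)^k |\Sigma|)}.
#' @examples
#' gaussian_entropy(matrix(1))        # 0.5 * log(2*pi*e)
#' gaussian_entropy(diag(2))          # log(2*pi*e)
#' @export
gaussian_entropy <- function(cov) {
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov)) stop("covariance must be square")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov))))
    stop("covariance must be symmetric")
  k <- nrow(cov)
  0.5 * (k * (log(2 * pi) + 1) + logdet_reg(cov))
}

# ML covariance (divide by N) of already mean-removed columns
cov_ml <- function(x) crossprod(x) / nrow(x)

check_groups <- function(rec, a, b = NULL) {
  miss <- setdiff(c(a, b), rec$channels)
  if (length(miss)) stop("unknown channels: ", paste(miss, collapse = ", "))
  if (!is.null(b) && length(intersect(a, b)))
    stop("channel groups must be disjoint")
  if (length(a) == 0L || (!is.null(b) && length(b) == 0L))
    stop("channel groups must be non-empty")
}

#' Time-embedded signal blocks for transfer entropy
#'
#' Builds the three time-aligned blocks used by the transfer-entropy
#' entropy combination with embedding dimension and delay fixed at 1:
#' `A_next` holds the target group at sample `t + tau`, `A_now` and
#' `B_now` hold target and source at sample `t`. The window is
#' mean-removed per channel before embedding.
#'
#' @param rec an [eeg_recording()].
#' @param target,source character vectors of channel names (disjoint).
#' @param window one row of [make_windows()] output, or `NULL` for the
#'   whole recording.
#' @param tau lag in samples (>= 1, < window length).
#' @return list with matrices `A_next`, `A_now`, `B_now` (each
#'   `N - tau` rows) and `tau`.
#' @export
embed_blocks <- function(rec, target, source, window = NULL, tau = 2L) {
  check_groups(rec, target, source)
  x <- if (is.null(window)) rec$data else window_slice(rec, window)
  n <- nrow(x)
  if (tau < 1L || tau >= n) stop("tau must be in [1, window length)")
  x <- sweep(x, 2L, colMeans(x))
  idx_now <- seq_len(n - tau)
  list(A_next = x[idx_now + tau, target, drop = FALSE],
       A_now  = x[idx_now, target, drop = FALSE],
       B_now  = x[idx_now, source, drop = FALSE],
       tau = as.integer(tau))
}

#' Gaussian mutual information between channel groups
#'
#' MI(X; Y) = H(X) + H(Y) - H(X, Y) with Gaussian entropies from the
#' sample covariance of the (mean-removed) window. Symmetric in its
#' arguments and non-negative up to numerical tolerance.
#'
#' @inheritParams embed_blocks
#' @param x_group,y_group disjoint channel-name vectors.
#' @return mutual information in nats.
#' @export
mutual_information <- function(rec, x_group, y_group, window = NULL) {
  check_groups(rec, x_group, y_group)
  d <- if (is.null(window)) rec$data else window_slice(rec, window)
  d <- sweep(d, 2L, colMeans(d))
  C <- cov_ml(d[, c(x_group, y_group), drop = FALSE])
  ix <- seq_along(x_group)
  iy <- length(x_group) + seq_along(y_group)
  gaussian_entropy(C[ix, ix, drop = FALSE]) +
    gaussian_entropy(C[iy, iy, drop = FALSE]) -
    gaussian_entropy(C)
}

# TE from a pooled 2n x 2n covariance of [x_{t+tau}; x_t]; a/b are column
# indices of target/source within the original n channels. The (2 pi e)^k
# factors cancel, leaving four log-determinants.
te_from_pooled <- function(C2, a, b, n, clip_tol = 1e-9) {
  i_next <- a
  i_now  <- n + a
  i_src  <- n + b
  v <- 0.5 * (logdet_reg(C2[c(i_next, i_now), c(i_next, i_now), drop = FALSE]) -
              logdet_reg(C2[i_now, i_now, drop = FALSE]) -
              logdet_reg(C2[c(i_next, i_now, i_src), c(i_next, i_now, i_src),
                            drop = FALSE]) +
              logdet_reg(C2[c(i_now, i_src), c(i_now, i_src), drop = FALSE]))
  clip_te(v, clip_tol)
}

clip_te <- function(v, clip_tol = 1e-9) {
  if (v < 0) {
    if (-v < clip_tol) v <- 0
    else warning(sprintf("transfer entropy estimate is negative (%.3g)", v))
  }
  v
}

# pooled covariance of [x_{t+tau}; x_t] for a mean-removed window matrix
pooled_lag_cov <- function(x, tau) {
  n <- nrow(x)
  idx <- seq_len(n - tau)
  cov_ml(cbind(x[idx + tau, , drop = FALSE], x[idx, , drop = FALSE]))
}

#' Gaussian transfer entropy between channel groups
#'
#' Directed information flow from a source group B into a target group A:
#' \deqn{T_{B\to A} = H(A_{n+1}, A_n) - H(A_n) - H(A_{n+1}, A_n, B_n) +
#' H(A_n, B_n)} with each term a Gaussian entropy of the corresponding
#' block covariance, embedding dimension and delay fixed at 1, and the
#' "next" sample taken `tau` samples ahead. Small negative estimates
#' (within log-determinant round-off, |value| < 1e-9) are clipped to
#' zero; larger negatives trigger a warning and are returned as computed.
#'
#' @inheritParams embed_blocks
#' @return transfer entropy in nats.
#' @export
transfer_entropy <- function(rec, target, source, window = NULL, tau = 2L) {
  check_groups(rec, target, source)
  x <- if (is.null(window)) rec$data else window_slice(rec, window)
  if (tau < 1L || tau >= nrow(x)) stop("tau must be in [1, window length)")
  x <- sweep(x, 2L, colMeans(x))
  C2 <- pooled_lag_cov(x, tau)
  n <- ncol(x)
  te_from_pooled(C2, match(target, colnames(x)), match(source, colnames(x)), n)
}
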