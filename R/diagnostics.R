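# Convergence diagnostics: rank-normalized split R-hat, bulk and tail ESS
# (the "improved" diagnostics of Vehtari et al.), and the two-sample
# Kolmogorov-Smirnov test used to compare samplers.

split_chains <- function(mat) {
  # mat: chains x draws -> 2*chains x floor(draws/2)
  n <- ncol(mat)
  half <- n %/% 2
  rbind(mat[, seq_len(half), drop = FALSE],
        mat[, seq.int(n - half + 1L, n), drop = FALSE])
}

rank_normalize <- function(mat) {
  r <- rank(as.vector(mat), ties.method = "average")
  z <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(mat), ncol(mat))
}

rhat_basic <- function(mat) {
  m <- nrow(mat); n <- ncol(mat)
  if (n < 2 || m < 2) return(NA_real_)
  chain_means <- rowMeans(mat)
  chain_vars <- apply(mat, 1, stats::var)
  W <- mean(chain_vars)
  B <- n * stats::var(chain_means)
  var_plus <- (n - 1) / n * W + B / n
  if (W <= 0) return(ifelse(B <= 0, 1, Inf))
  sqrt(var_plus / W)
}

ess_basic <- function(mat) {
  m <- nrow(mat); n <- ncol(mat)
  if (n < 4 || m < 1) return(NA_real_)
  chain_vars <- apply(mat, 1, stats::var)
  if (all(chain_vars == 0)) return(NA_real_)
  W <- mean(chain_vars)
  B <- if (m > 1) n * stats::var(rowMeans(mat)) else 0
  var_plus <- (n - 1) / n * W + B / n
  # chain-averaged autocovariances (biased, as in the reference definition)
  acov <- sapply(seq_len(m), function(i) {
    a <- stats::acf(mat[i, ], lag.max = n - 1, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    a
  })
  mean_acov <- rowMeans(acov)
  rho <- 1 - (W - mean_acov) / var_plus  # rho[t+1] = lag-t correlation estimate
  # Geyer initial positive monotone sequence on paired sums (lags 0+1, 2+3, ...)
  P <- numeric(0)
  t <- 1L
  while (t + 1L <= length(rho)) {
    s <- rho[t] + rho[t + 1L]
    if (s <= 0) break
    P <- c(P, s)
    t <- t + 2L
  }
  if (length(P) > 1) P <- cummin(P)
  tau <- max(-1 + 2 * sum(P), 1 / log10(m * n + 10))
  min(m * n / tau, m * n * log10(m * n))
}

fold <- function(mat) abs(mat - stats::median(mat))

#' Rank-normalized split R-hat of one quantity
#'
#' @param mat Chains x draws matrix.
#' @return Scalar R-hat (maximum of the bulk rank-normalized and folded
#'   statistics).
#' @export
rhat <- function(mat) {
  s <- split_chains(mat)
  max(rhat_basic(rank_normalize(s)), rhat_basic(rank_normalize(fold(s))))
}

#' Bulk effective sample size of one quantity
#' @param mat Chains x draws matrix.
#' @export
ess_bulk <- function(mat) {
  ess_basic(rank_normalize(split_chains(mat)))
}

#' Tail effective sample size of one quantity
#'
#' Minimum ESS of the 5 and 95 percent quantile indicator functions.
#' @param mat Chains x draws matrix.
#' @export
ess_tail <- function(mat) {
  q <- stats::quantile(mat, c(0.05, 0.95), names = FALSE)
  s5 <- split_chains((mat <= q[1]) * 1)
  s95 <- split_chains((mat <= q[2]) * 1)
  min(ess_basic(rank_normalize(s5)), ess_basic(rank_normalize(s95)))
}

#' Convergence diagnostics for posterior draws
#'
#' Computes, per parameter, the rank-normalized split R-hat and bulk/tail
#' effective sample sizes, plus the global post-warmup divergence count and
#' number of tree-depth saturations.
#'
#' @param draws A `kin_draws` object, or a chains x draws x parameters array.
#' @return List with `per_parameter` (tibble: parameter, rhat, ess_bulk,
#'   ess_tail), `n_divergent`, `max_tree_depth_hits`.
#' @export
compute_diagnostics <- function(draws) {
  if (inherits(draws, "kin_draws")) {
    a <- draws$theta
    stats_ <- draws$sample_stats
  } else {
    a <- draws
    stats_ <- NULL
  }
  if (length(dim(a)) != 3) stop("need a chains x draws x parameters array", call. = FALSE)
  if (dim(a)[2] < 4) stop("need at least 4 draws per chain", call. = FALSE)
  if (dim(a)[1] < 2) {
    warning("single chain: splitting into 4 segments for R-hat", call. = FALSE)
    n <- dim(a)[2]
    n4 <- (n %/% 4) * 4
    a <- array(aperm(array(a[1, seq_len(n4), , drop = FALSE][1, , ],
                           c(n4 / 4, 4, dim(a)[3])), c(2, 1, 3)),
               c(4, n4 / 4, dim(a)[3]), dimnames = list(NULL, NULL, dimnames(a)[[3]]))
  }
  pn <- dimnames(a)[[3]]
  if (is.null(pn)) pn <- paste0("param", seq_len(dim(a)[3]))
  per <- dplyr::bind_rows(lapply(seq_len(dim(a)[3]), function(j) {
    m <- a[, , j, drop = TRUE]
    if (!is.matrix(m)) m <- matrix(m, nrow = dim(a)[1])
    tibble::tibble(parameter = pn[j], rhat = rhat(m),
                   ess_bulk = ess_bulk(m), ess_tail = ess_tail(m))
  }))
  n_div <- 0; td_hits <- 0
  if (!is.null(stats_)) {
    n_div <- sum(stats_$divergent, na.rm = TRUE)
    if (!is.null(stats_$tree_depth) && inherits(draws, "kin_draws")) {
      td_hits <- sum(stats_$tree_depth >= draws$model$sampler$max_tree_depth,
                     na.rm = TRUE)
    }
  }
  list(per_parameter = per, n_divergent = n_div, max_tree_depth_hits = td_hits)
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Classical statistic \eqn{D = \sup_x |F_x(t) - F_y(t)|} over the empirical
#' CDFs, with the asymptotic p-value.  Used to compare MCMC and Laplace
#' log-density draws.
#'
#' @param x,y Numeric vectors of draws.
#' @return List with `statistic` and `p_value`.
#' @export
ks_two_sample <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  grid <- sort(unique(c(x, y)))
  Fx <- stats::ecdf(x)(grid)
  Fy <- stats::ecdf(y)(grid)
  D <- max(abs(Fx - Fy))
  p <- suppressWarnings(stats::ks.test(x, y)$p.value)
  list(statistic = D, p_value = p)
}
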