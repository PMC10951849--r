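#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif qnorm pnorm dnorm fft mvfft sd var qt pt lm
#'   aov coef pf complete.cases median quantile setNames reshape t.test dist
#'   rpois cor residuals
#' @importFrom utils head tail
NULL

## small shared numerical helpers

#' Symmetric pseudo-inverse via eigendecomposition
#'
#' Moore-Penrose inverse of a symmetric positive semi-definite matrix,
#' truncating eigenvalues below `tol * max(eigenvalue)`.
#' @param A symmetric psd matrix
#' @param tol relative eigenvalue cutoff
#' @return matrix of the same dimension
#' @keywords internal
pinv_sym <- function(A, tol = 1e-12) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  pos <- e$values > tol * max(e$values, 0)
  if (!any(pos)) return(matrix(0, nrow(A), ncol(A)))
  V <- e$vectors[, pos, drop = FALSE]
  V %*% (t(V) / e$values[pos])
}

#' Principal square root of a symmetric psd matrix
#' @keywords internal
sqrtm_psd <- function(A) {
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (t(e$vectors) * sqrt(v))
}

#' Connected components of an undirected graph restricted to a node subset
#'
#' Plain BFS on an adjacency list; used in permutation hot loops where
#' constructing graph objects per permutation would dominate runtime.
#' @param nodes integer vector of active node indices
#' @param adj list: adj[[i]] = integer neighbours of node i
#' @return list of integer vectors (one per component)
#' @keywords internal
graph_components <- function(nodes, adj) {
  if (length(nodes) == 0L) return(list())
  active <- logical(length(adj))
  active[nodes] <- TRUE
  seen <- logical(length(adj))
  out <- vector("list", 0L)
  for (start in nodes) {
    if (seen[start]) next
    comp <- integer(0)
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      comp <- c(comp, v)
      nb <- adj[[v]]
      nb <- nb[active[nb] & !seen[nb]]
      if (length(nb)) {
        seen[nb] <- TRUE
        queue <- c(queue, nb)
      }
    }
    out[[length(out) + 1L]] <- sort(comp)
  }
  out
}

#' Truncated normal sampler (inverse-CDF)
#'
#' Draws from N(mean, sd) truncated to \[lower, upper\]. With sd = 0 the
#' distribution is degenerate at the (clamped) mean.
#' @param n number of draws
#' @param mean,sd location and scale of the parent normal
#' @param lower,upper truncation bounds
#' @return numeric vector of length n
#' @export
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd >= 0, upper >= lower)
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  u <- runif(n, plo, phi)
  q <- qnorm(u, mean, sd)
  pmin(pmax(q, lower), upper) # guard against rounding at extreme quantiles
}

#' 1/f^alpha ("pink") noise via spectral shaping
#'
#' Gaussian noise whose power spectrum falls off as f^-alpha, generated by
#' shaping white Gaussian Fourier coefficients and inverting the FFT. The
#' output is standardised to unit standard deviation.
#' @param n number of samples
#' @param alpha spectral exponent (power ~ 1/f^alpha)
#' @param sfreq sampling frequency in Hz (sets the frequency axis only)
#' @return numeric vector of length n with sd 1
#' @export
pink_noise <- function(n, alpha = 1, sfreq = 250) {
  nfft <- n
  freqs <- seq(0, sfreq / 2, length.out = floor(nfft / 2) + 1L)
  shape <- c(0, freqs[-1]^(-alpha / 2)) # kill DC
  nhalf <- length(freqs)
  re <- rnorm(nhalf) * shape
  im <- rnorm(nhalf) * shape
  spec <- complex(real = re, imaginary = im)
  spec[1] <- 0
  if (nfft %% 2 == 0) {
    spec[nhalf] <- complex(real = re[nhalf], imaginary = 0)
    full <- c(spec, Conj(rev(spec[2:(nhalf - 1L)])))
  } else {
    full <- c(spec, Conj(rev(spec[2:nhalf])))
  }
  x <- Re(fft(full, inverse = TRUE)) / nfft
  x <- x[seq_len(n)]
  s <- sd(x)
  if (s > 0) x <- x / s
  x
}

#' Matrix of independent 1/f^alpha noise columns
#'
#' Vectorised variant of [pink_noise()]: k independent unit-sd columns.
#' @param n samples per column
#' @param k number of columns
#' @inheritParams pink_noise
#' @return n x k matrix
#' @export
pink_noise_matrix <- function(n, k, alpha = 1, sfreq = 250) {
  freqs <- seq(0, sfreq / 2, length.out = floor(n / 2) + 1L)
  shape <- c(0, freqs[-1]^(-alpha / 2))
  nhalf <- length(freqs)
  re <- matrix(rnorm(nhalf * k), nhalf) * shape
  im <- matrix(rnorm(nhalf * k), nhalf) * shape
  spec <- matrix(complex(real = re, imaginary = im), nhalf)
  spec[1, ] <- 0
  if (n %% 2 == 0) {
    spec[nhalf, ] <- complex(real = re[nhalf, ], imaginary = 0)
    full <- rbind(spec, Conj(spec[(nhalf - 1L):2, , drop = FALSE]))
  } else {
    full <- rbind(spec, Conj(spec[nhalf:2, , drop = FALSE]))
  }
  x <- Re(mvfft(full, inverse = TRUE)) / n
  sds <- apply(x, 2, sd)
  sds[sds == 0] <- 1
  sweep(x, 2, sds, "/")
}

#' Hanning taper (periodic convention)
#' @param n window length in samples
#' @keywords internal
hanning_taper <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)
}

#' Derive a bounded child seed from a master seed
#'
#' Deterministic splitting of one integer seed into per-unit seeds that stay
#' below 2^31.
#' @keywords internal
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 * as.numeric(index)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
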