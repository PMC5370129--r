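#' Run an ICA algorithm on an EEG dataset
#'
#' Decomposes channels-by-samples EEG into statistically independent
#' components. The data are centred per channel and whitened by PCA to
#' `n_components` dimensions; the named algorithm then estimates the
#' square rotation:
#'
#' * `infomax`: natural-gradient maximum-likelihood rule with the logistic
#'   nonlinearity (supra-Gaussian sources).
#' * `extended_infomax`: the sign-switching sub-/supra-Gaussian
#'   generalisation (per-component kurtosis-sign estimate).
#' * `jade`: joint approximate diagonalisation of fourth-order cumulant
#'   matrices by Jacobi rotations.
#' * `fastica`: symmetric fixed-point iteration with the kurtosis-family
#'   contrast (`g(u) = u^3`).
#'
#' All algorithms run behind one seeded interface and are deterministic
#' given `seed`. Non-convergence is reported in the result's diagnostics
#' (and as a warning), never silently ignored.
#'
#' @param eeg An [eeg_dataset()] (or bare channels x samples matrix).
#' @param algorithm One of `"infomax"`, `"extended_infomax"`, `"jade"`,
#'   `"fastica"`.
#' @param n_components Number of components (default: all channels; the
#'   in-silico benchmark uses 25). Must not exceed the data rank.
#' @param seed Seed for the random rotation initialisation and block
#'   shuffling.
#' @param max_iter Iteration cap for the algorithm's main loop (default:
#'   500 data passes for infomax variants, 50 Jacobi sweeps for JADE, 200
#'   fixed-point iterations for fastICA).
#' @param tol Convergence tolerance (default: 1e-5 relative unmixing change
#'   for the infomax variants, `1/(100 sqrt(T))` rotation angle for JADE,
#'   1e-6 direction change for fastICA).
#' @param max_train_samples Optionally estimate the rotation on a
#'   contiguous central training window of at most this many samples and
#'   apply it to the full recording (a reduced-training shortcut for very
#'   long recordings). The default `Inf` trains on every sample: shorter
#'   windows measurably increase artifact leakage into the retained
#'   components. A contiguous window (never decimation) preserves the
#'   waveform of pulsatile artifacts.
#' @return An object of class `ica_result`: list with `algorithm`,
#'   `unmixing` (`n_components x n_channels`), `mixing`
#'   (`n_channels x n_components`), `activations`
#'   (`n_components x n_samples`), `scalp_maps` (= `mixing`), `center`,
#'   `n_components`, `seed`, `converged`, `iterations`, `labels`,
#'   `sampling_rate_hz`. Components are ordered by explained variance.
#' @export
run_ica <- function(eeg, algorithm = c("infomax", "extended_infomax",
                                       "jade", "fastica"),
                    n_components = NULL, seed = 1L, max_iter = NULL,
                    tol = NULL, max_train_samples = Inf) {
  algorithm <- match.arg(algorithm)
  if (inherits(eeg, "eeg_dataset")) {
    X <- eeg$data
    labels <- eeg$labels
    fs <- eeg$sampling_rate_hz
  } else {
    X <- as.matrix(eeg)
    labels <- rownames(X) %||% paste0("ch", seq_len(nrow(X)))
    fs <- NA_real_
  }
  nch <- nrow(X)
  n_components <- n_components %||% nch
  if (n_components > nch) {
    stop_assrmix("`n_components` cannot exceed the channel count.")
  }
  ctr <- rowMeans(X)
  Xc <- X - ctr
  cv <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12
  if (sum(pos) < n_components) {
    stop_assrmix(sprintf(
      "Data rank (%d) is below `n_components` (%d).", sum(pos), n_components))
  }
  E <- eg$vectors[, seq_len(n_components), drop = FALSE]
  D <- eg$values[seq_len(n_components)]
  whitener <- t(E) / sqrt(D)          # n_comp x nch
  dewhitener <- E * rep(sqrt(D), each = nch)
  Xw <- whitener %*% Xc
  Xt <- if (is.finite(max_train_samples) && ncol(Xw) > max_train_samples) {
    from <- (ncol(Xw) - max_train_samples) %/% 2L
    Xw[, from + seq_len(max_train_samples), drop = FALSE]
  } else {
    Xw
  }

  mi <- max_iter %||% switch(algorithm, jade = 80L, fastica = 100L, 60L)
  fit <- with_seed_(seed, switch(algorithm,
    infomax = ica_infomax(Xt, extended = FALSE, max_iter = mi,
                          tol = tol %||% 1e-5),
    extended_infomax = ica_infomax(Xt, extended = TRUE, max_iter = mi,
                                   tol = tol %||% 1e-5, anneal = 0.98),
    jade = ica_jade(Xt, max_iter = mi, tol = tol),
    fastica = ica_fastica(Xt, max_iter = mi, tol = tol %||% 1e-6)
  ))
  if (!fit$converged) {
    rlang::warn(sprintf("%s did not converge in %d iterations (delta %.3g).",
                        algorithm, fit$iterations, fit$delta),
                class = "assrmix_convergence_warning")
  }
  W <- fit$W                           # n_comp x n_comp rotation
  unmixing <- W %*% whitener
  mixing <- dewhitener %*% solve(W)
  S <- unmixing %*% Xc
  # order by explained variance in channel space
  ev <- colSums(mixing^2) * apply(S, 1, var)
  ord <- order(ev, decreasing = TRUE)
  unmixing <- unmixing[ord, , drop = FALSE]
  mixing <- mixing[, ord, drop = FALSE]
  S <- S[ord, , drop = FALSE]
  rownames(unmixing) <- rownames(S) <- colnames(mixing) <-
    paste0("IC", seq_len(n_components))
  colnames(unmixing) <- rownames(mixing) <- labels
  structure(
    list(algorithm = algorithm, unmixing = unmixing, mixing = mixing,
         activations = S, scalp_maps = mixing, center = ctr,
         n_components = n_components, seed = seed,
         converged = fit$converged, iterations = fit$iterations,
         delta = fit$delta, labels = labels, sampling_rate_hz = fs),
    class = "ica_result"
  )
}

#' @export
print.ica_result <- function(x, ...) {
  cat(sprintf("<ica_result> %s: %d components over %d channels (%s, %d iterations)\n",
              x$algorithm, x$n_components, length(x$labels),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

# ---- algorithm cores (operate on whitened n x T data) ----------------------

# natural-gradient infomax; extended = Lee/Girolami/Sejnowski sign-switching.
# Learning-rate annealing follows the oscillation heuristic: the rate is
# reduced only when the direction of successive weight updates turns by more
# than `anneal_deg`, so progress is not throttled while descent is steady.
# The block-update loop runs in compiled code.
ica_infomax <- function(Xw, extended = FALSE, max_iter = 500L, tol = 1e-5,
                        block = NULL, lrate = NULL, anneal = 0.9,
                        anneal_deg = 60, max_lrate_reductions = 30L) {
  n <- nrow(Xw)
  T_ <- ncol(Xw)
  block <- block %||% as.integer(max(256L, min(512L, T_ %/% 8L)))
  lrate <- lrate %||% 0.0013 / log(n + 1)
  out <- infomax_cpp(Xw, extended, as.integer(max_iter), tol,
                     as.integer(block), lrate, anneal, anneal_deg,
                     as.integer(max_lrate_reductions))
  return(list(W = out$W, converged = out$converged,
              iterations = out$iterations, delta = out$delta))
}

# symmetric fixed-point fastICA with the kurtosis contrast g(u) = u^3
ica_fastica <- function(Xw, max_iter = 500L, tol = 1e-6) {
  n <- nrow(Xw)
  T_ <- ncol(Xw)
  sym_decor <- function(W) {
    s <- eigen(tcrossprod(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(pmax(s$values, 1e-300)), n) %*%
      t(s$vectors) %*% W
  }
  W <- sym_decor(matrix(rnorm(n * n), n))
  delta <- Inf
  for (iter in seq_len(max_iter)) {
    U <- W %*% Xw
    G <- U^3
    W_new <- G %*% t(Xw) / T_ - diag(rowMeans(3 * U^2), n) %*% W
    W_new <- sym_decor(W_new)
    delta <- max(abs(1 - abs(rowSums(W_new * W))))
    W <- W_new
    if (delta < tol) {
      return(list(W = W, converged = TRUE, iterations = iter, delta = delta))
    }
  }
  list(W = W, converged = FALSE, iterations = max_iter, delta = delta)
}

# JADE: joint approximate diagonalisation of the maximal set of fourth-order
# cumulant matrices by Jacobi rotations (Cardoso & Souloumiac).
ica_jade <- function(Xw, max_iter = 50L, tol = NULL) {
  n <- nrow(Xw)
  T_ <- ncol(Xw)
  tol <- tol %||% (1 / sqrt(T_) / 100)
  # moment accumulation: Z has one column per (i,j) pair, i <= j
  pairs <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  npair <- nrow(pairs)
  # E[x_i x_j x_k x_l] accumulated blockwise to bound memory
  M4 <- matrix(0, npair, npair)
  step <- max(1L, floor(2e6 / npair))
  for (b0 in seq(1, T_, by = step)) {
    idx <- b0:min(T_, b0 + step - 1L)
    Xb <- Xw[, idx, drop = FALSE]
    Z <- Xb[pairs[, 1], , drop = FALSE] * Xb[pairs[, 2], , drop = FALSE]
    M4 <- M4 + tcrossprod(Z)
  }
  M4 <- M4 / T_
  # cumulant matrices Q_{ij}[k,l] = E[xi xj xk xl] - d(ij)d(kl) - d(ik)d(jl)
  #                                 - d(il)d(jk)  (whitened: E[xi xj] = d_ij)
  pk <- matrix(0L, n, n) # (i, j) -> pair index lookup
  pk[cbind(pairs[, 1], pairs[, 2])] <- seq_len(npair)
  pk[cbind(pairs[, 2], pairs[, 1])] <- seq_len(npair)
  moment <- function(i, j, k, l) M4[pk[i, j], pk[k, l]]
  CM <- matrix(0, n, n * npair) # stacked cumulant matrices
  for (p in seq_len(npair)) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    Q <- matrix(0, n, n)
    for (k in seq_len(n)) {
      for (l in k:n) {
        q <- moment(i, j, k, l) -
          (i == j) * (k == l) - (i == k) * (j == l) - (i == l) * (j == k)
        Q[k, l] <- q
        Q[l, k] <- q
      }
    }
    if (i != j) Q <- Q * sqrt(2) # weight for off-diagonal pair set
    CM[, ((p - 1) * n + 1):(p * n)] <- Q
  }
  # joint diagonalisation by Jacobi sweeps
  V <- diag(n)
  max_theta <- Inf
  sweeps <- 0L
  while (max_theta > tol && sweeps < max_iter) {
    max_theta <- 0
    sweeps <- sweeps + 1L
    for (p in 1:(n - 1)) {
      for (q in (p + 1):n) {
        ip <- seq(p, n * npair, by = n)
        iq <- seq(q, n * npair, by = n)
        g1 <- CM[p, ip] - CM[q, iq]
        g2 <- CM[p, iq] + CM[q, ip]
        gg11 <- sum(g1 * g1); gg22 <- sum(g2 * g2); gg12 <- sum(g1 * g2)
        ton <- gg11 - gg22
        toff <- 2 * gg12
        theta <- 0.5 * atan2(toff, ton + sqrt(ton * ton + toff * toff))
        if (abs(theta) > tol) {
          max_theta <- max(max_theta, abs(theta))
          cs <- cos(theta); sn <- sin(theta)
          Vp <- V[, p]; V[, p] <- cs * Vp + sn * V[, q]
          V[, q] <- -sn * Vp + cs * V[, q]
          rp <- CM[p, ]; CM[p, ] <- cs * rp + sn * CM[q, ]
          CM[q, ] <- -sn * rp + cs * CM[q, ]
          cp <- CM[, ip]; cq <- CM[, iq]
          CM[, ip] <- cs * cp + sn * cq
          CM[, iq] <- -sn * cp + cs * cq
        }
      }
    }
  }
  # residual rotations below ~0.05 rad concern noise-dominated cumulants and
  # leave the source subspace settled; treat them as practical convergence
  list(W = t(V), converged = max_theta <= max(tol * 50, 0.05),
       iterations = sweeps, delta = max_theta)
}
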