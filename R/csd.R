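#' Parameters for spherical-spline CSD estimation
#'
#' @param lambda_grid candidate regularization constants (diagonal loading
#'   of the spline kernel)
#' @param stiffness_m spline stiffness order
#' @param n_legendre_terms number of Legendre-polynomial terms in the
#'   kernel expansions
#' @param cv_subset channel labels used for leave-one-out cross-validation
#'   (default: the montage's \code{cv} subset)
#' @param cv_window_s length of each cross-validation window (s)
#' @param cv_window_centers window centres as fractions of the recording
#'   (the middle of the block)
#' @param selected_lambda the chosen constant (filled by
#'   \code{\link{select_lambda}})
#' @return a list of class \code{ckc_csd_params}
#' @export
csd_params <- function(lambda_grid = 10^seq(-7, -3),
                       stiffness_m = 3,
                       n_legendre_terms = 50,
                       cv_subset = NULL,
                       cv_window_s = 0.05,
                       cv_window_centers = c(0.45, 0.48, 0.52, 0.55),
                       selected_lambda = NA_real_) {
  stopifnot(all(lambda_grid > 0), stiffness_m >= 2, n_legendre_terms >= 2)
  structure(list(lambda_grid = sort(lambda_grid), stiffness_m = stiffness_m,
                 n_legendre_terms = n_legendre_terms, cv_subset = cv_subset,
                 cv_window_s = cv_window_s,
                 cv_window_centers = cv_window_centers,
                 selected_lambda = selected_lambda, rmse_per_lambda = NULL),
            class = "ckc_csd_params")
}

## internal: sum_{n=1}^{N} (2n+1) / (n(n+1))^m * P_n(x), elementwise on x,
## by the Legendre three-term recurrence
legendre_kernel <- function(x, m, nterms) {
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  acc <- (2 * 1 + 1) / (1 * 2)^m * p_cur
  for (n in 2:nterms) {
    p_next <- ((2 * n - 1) * x * p_cur - (n - 1) * p_prev) / n
    acc <- acc + (2 * n + 1) / (n * (n + 1))^m * p_next
    p_prev <- p_cur
    p_cur <- p_next
  }
  acc / (4 * pi)
}

## internal: cosine-angle matrix between two sets of unit-sphere positions
cosangle <- function(p, q = p) {
  cs <- tcrossprod(p, q)
  cs[cs > 1] <- 1
  cs[cs < -1] <- -1
  cs
}

#' Spherical-spline CSD operator
#'
#' Builds the linear operator mapping scalp potentials at the montage
#' electrodes to current source density estimates (Perrin-style spherical
#' splines): the spline kernel matrix G (stiffness m) is regularized by
#' adding \code{lambda} to its diagonal, spline coefficients are obtained
#' under the zero-sum constraint, and the CSD kernel H (stiffness m - 1)
#' maps the coefficients to the surface Laplacian. The operator annihilates
#' spatially constant fields (rows sum to zero).
#'
#' @param positions n x 3 unit-sphere electrode positions
#' @param lambda regularization constant
#' @param m stiffness
#' @param nterms Legendre terms
#' @return n x n matrix \code{L}; \code{CSD = L \%*\% voltages}
#' @export
csd_operator <- function(positions, lambda, m = 3, nterms = 50) {
  n <- nrow(positions)
  cs <- cosangle(positions)
  G <- legendre_kernel(cs, m, nterms)
  H <- legendre_kernel(cs, m - 1, nterms)
  A <- rbind(cbind(G + diag(lambda, n), 1), c(rep(1, n), 0))
  Ainv <- solve(A)
  H %*% Ainv[seq_len(n), seq_len(n)]
}

## internal: weights mapping donor-channel voltages to spline-interpolated
## voltages at target positions (constant term included)
spline_interp_weights <- function(donor_pos, target_pos, lambda,
                                  m = 3, nterms = 50) {
  nd <- nrow(donor_pos)
  G <- legendre_kernel(cosangle(donor_pos), m, nterms)
  A <- rbind(cbind(G + diag(lambda, nd), 1), c(rep(1, nd), 0))
  Ainv <- solve(A)
  gt <- legendre_kernel(cosangle(target_pos, donor_pos), m, nterms)
  cbind(gt, 1) %*% Ainv[, seq_len(nd), drop = FALSE]
}

#' Select the CSD regularization constant by leave-one-out cross-validation
#'
#' For each candidate lambda and each channel of the cross-validation
#' subset, the channel is left out and its voltage over four short windows
#' in the middle of the recording is re-estimated by spherical-spline
#' interpolation from all remaining channels; the constant minimizing the
#' global RMSE across channels and windows is selected (ties broken toward
#' the larger, more conservative constant). The procedure is deterministic
#' given the recording.
#'
#' @param rec a \code{ckc_recording} (EEG in voltage domain)
#' @param params a \code{\link{csd_params}}
#' @return \code{params} with \code{selected_lambda} and
#'   \code{rmse_per_lambda} filled
#' @export
select_lambda <- function(rec, params = csd_params()) {
  mont <- rec$montage
  cv_labels <- params$cv_subset
  if (is.null(cv_labels)) cv_labels <- mont$subsets$cv
  cv_labels <- intersect(cv_labels, mont$labels)
  n <- ncol(rec$eeg)
  wlen <- round(params$cv_window_s * rec$fs_hz)
  starts <- round(params$cv_window_centers * n - wlen / 2)
  if (any(starts < 1) || any(starts + wlen - 1 > n))
    stop("cross-validation windows fall outside the recording")
  cols <- unlist(lapply(starts, function(s) s:(s + wlen - 1L)))
  dat <- rec$eeg[, cols, drop = FALSE]

  sse <- stats::setNames(numeric(length(params$lambda_grid)),
                  format(params$lambda_grid, scientific = TRUE))
  n_obs <- 0
  for (li in seq_along(params$lambda_grid)) {
    lam <- params$lambda_grid[li]
    err2 <- 0
    for (lab in cv_labels) {
      i <- match(lab, mont$labels)
      donors <- setdiff(seq_len(nrow(dat)), i)
      w <- spline_interp_weights(mont$positions[donors, , drop = FALSE],
                                 mont$positions[i, , drop = FALSE],
                                 lam, params$stiffness_m,
                                 params$n_legendre_terms)
      est <- as.numeric(w %*% dat[donors, , drop = FALSE])
      err2 <- err2 + sum((est - dat[i, ])^2)
    }
    sse[li] <- err2
  }
  n_obs <- length(cv_labels) * length(cols)
  rmse <- sqrt(sse / n_obs)
  best <- max(which(rmse == min(rmse)))      # tie -> larger lambda
  params$selected_lambda <- params$lambda_grid[best]
  params$rmse_per_lambda <- rmse
  params
}

#' Transform a recording to current source density
#'
#' Applies the spherical-spline CSD operator (see
#' \code{\link{csd_operator}}) built with the selected regularization
#' constant to every sample.
#'
#' @param rec a \code{ckc_recording}
#' @param params a \code{\link{csd_params}} with \code{selected_lambda} set
#' @return the recording with \code{eeg} in CSD units and provenance updated
#' @export
csd_transform <- function(rec, params) {
  if (!is.finite(params$selected_lambda))
    stop("selected_lambda not set; run select_lambda() first")
  L <- csd_operator(rec$montage$positions, params$selected_lambda,
                    params$stiffness_m, params$n_legendre_terms)
  out <- rec
  out$eeg <- L %*% rec$eeg
  dimnames(out$eeg) <- dimnames(rec$eeg)
  out$provenance$csd <- list(lambda = params$selected_lambda,
                             stiffness_m = params$stiffness_m,
                             n_legendre_terms = params$n_legendre_terms,
                             rmse_per_lambda = params$rmse_per_lambda)
  out
}
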