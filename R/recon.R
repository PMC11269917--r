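#' SVD coil compression
#'
#' Compresses multi-coil k-space data onto the dominant singular vectors of
#' the coil covariance. Following common practice the threshold is applied
#' to the eigenvalues of the coil covariance (squared singular values)
#' relative to the largest; a 2% eigenvalue threshold typically keeps on the
#' order of a dozen virtual coils on clinical arrays.
#'
#' @param kdata Complex array with coils on the last dimension.
#' @param threshold Relative threshold in (0, 1]; 0 keeps all coils.
#' @param value_type `"eigen"` (default, threshold on squared singular
#'   values) or `"singular"`.
#' @return List: `kdata` (compressed, virtual coils last), `basis`
#'   (coils x virtual coils), `n_virtual`, `energy_retained`,
#'   `values` (relative eigenvalues).
#' @export
svd_coil_compress <- function(kdata, threshold = 0.02,
                              value_type = c("eigen", "singular")) {
  value_type <- match.arg(value_type)
  d <- dim(kdata)
  nc <- d[length(d)]
  X <- matrix(kdata, ncol = nc)                 # samples x coils
  G <- crossprod(Conj(X), X)                    # coils x coils covariance
  eg <- eigen(G, symmetric = TRUE)
  vals <- pmax(Re(eg$values), 0)
  rel <- vals / max(vals)
  keep <- if (threshold <= 0) rep(TRUE, nc) else {
    if (value_type == "eigen") rel >= threshold else sqrt(rel) >= threshold
  }
  nk <- max(1L, sum(keep))
  V <- eg$vectors[, seq_len(nk), drop = FALSE]
  Xc <- X %*% V
  out <- array(Xc, dim = c(d[-length(d)], nk))
  list(kdata = out, basis = V, n_virtual = nk,
       energy_retained = sum(vals[seq_len(nk)]) / sum(vals), values = rel)
}

# explicit non-uniform DFT operator for small 2D grids: rows = k samples,
# cols = pixels; A x evaluates the image's Fourier transform at the samples
ndft_matrix <- function(k, n, fov_m) {
  xs <- (seq_len(n) - (n + 1) / 2) / n * fov_m
  px <- rep(xs, times = n)
  py <- rep(xs, each = n)
  exp(-2i * pi * (outer(k[, 1], px) + outer(k[, 2], py))) *
    (fov_m / n)^2
}

# radial density compensation: |k| ramp with a flat plateau at the center
# (2D); weights approximate the polar area element per sample. The radial
# sample spacing is estimated from consecutive samples (robust median, since
# samples are stored spoke by spoke).
radial_dcf <- function(k, n_spokes, dk) {
  kr <- sqrt(rowSums(k^2))
  dk_r <- if (nrow(k) > 1L) {
    median(sqrt(rowSums(diff(k)^2)))
  } else dk
  pmax(kr, dk_r / 4) * dk_r * pi / n_spokes
}

#' Adjoint-NUFFT (gridding) reconstruction of radial data
#'
#' Density-compensated adjoint non-uniform DFT: the standard gridding
#' reconstruction `x = A^H (w y)` with a radial ramp (`|k|`, flat plateau at
#' the center) as density compensation. Exact (matrix) NUFFT at desk scale;
#' deterministic.
#'
#' @param y Complex k-space samples (vector, or matrix samples x spokes).
#' @param k Sample positions (n x 2, 1/m), matching `y` in order.
#' @param n Image matrix size.
#' @param fov_m Field of view (m).
#' @param n_spokes Number of spokes the samples came from (for the angular
#'   weight); defaults to `ncol(y)` when `y` is a matrix.
#' @return Complex `n x n` image; all-zero data gives an all-zero image
#'   (empty input gives a zero image with a warning).
#' @export
nufft_gridding_recon <- function(y, k, n, fov_m, n_spokes = NULL) {
  if (is.matrix(y)) {
    if (is.null(n_spokes)) n_spokes <- ncol(y)
    y <- as.vector(y)
  }
  if (length(y) == 0L) {
    warning("empty bin: returning zero image")
    return(matrix(0i, n, n))
  }
  if (is.null(n_spokes)) n_spokes <- 1L
  if (nrow(k) != length(y)) stop("`k` and `y` sizes differ")
  dk <- 1 / fov_m
  w <- radial_dcf(k, n_spokes, dk)
  # adjoint with the pixel-area factor of `ndft_matrix` divided back out:
  # x(r) ~= sum_i w_i y_i exp(+2 pi i k_i . r)
  A <- ndft_matrix(k, n, fov_m)
  img <- Conj(t(A)) %*% (w * y) / (fov_m / n)^2
  matrix(as.complex(img), n, n)
}

# forward/adjoint differences along one dimension of a 4D array
# (clamped boundaries, or cyclic for the cardiac dimension)
diff_forward <- function(x, dim, cyclic = FALSE) {
  n <- dim(x)[dim]
  if (n == 1L) return(array(0i, dim = dim(x)))
  idx <- c(seq(2L, n), if (cyclic) 1L else n)
  shifted <- slice_index(x, dim, idx)
  shifted - x
}

diff_adjoint <- function(g, dim, cyclic = FALSE) {
  n <- dim(g)[dim]
  if (n == 1L) return(array(0i, dim = dim(g)))
  idx <- c(if (cyclic) n else 1L, seq_len(n - 1L))
  prev <- slice_index(g, dim, idx)
  out <- prev - g
  if (!cyclic) {
    # clamped boundary: last forward difference is zero, first has no prev
    out <- assign_slice(out, dim, 1L, -slice_index(g, dim, 1L))
    gl <- slice_index(g, dim, n - 1L)
    out <- assign_slice(out, dim, n, gl)
  }
  out
}

slice_index <- function(x, dim, idx) {
  args <- rep(list(quote(expr = )), 4L)
  args[[dim]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

assign_slice <- function(x, dim, at, value) {
  args <- rep(list(quote(expr = )), 4L)
  args[[dim]] <- at
  do.call(`[<-`, c(list(x), args, list(value)))
}

#' Reconstruction configuration for the motion-resolved CS problem
#'
#' Total-variation weights along spatial (`lambda_s`), cardiac (`lambda_c`)
#' and respiratory (`lambda_r`) dimensions, the ADMM penalty `rho` and the
#' iteration count, with the reference protocol's values as defaults.
#'
#' @param lambda_s,lambda_c,lambda_r TV weights (>= 0).
#' @param rho Augmented-Lagrangian penalty (> 0).
#' @param n_iter ADMM iterations (>= 1).
#' @param cg_iter Cap on inner conjugate-gradient iterations per x-update;
#'   CG exits early on a relative-residual tolerance, so the default solves
#'   the x-subproblem essentially exactly (inexact solves make the ADMM
#'   objective oscillate).
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(lambda_s = 0.0015, lambda_c = 0.0075,
                         lambda_r = 0.005, rho = 0.06, n_iter = 10L,
                         cg_iter = 100L) {
  if (any(c(lambda_s, lambda_c, lambda_r) < 0)) stop("TV weights must be >= 0")
  stop_if_not_scalar_num(rho, "rho", positive = TRUE)
  structure(
    list(lambda_s = lambda_s, lambda_c = lambda_c, lambda_r = lambda_r,
         rho = rho, n_iter = as.integer(n_iter), cg_iter = as.integer(cg_iter)),
    class = "recon_config"
  )
}

#' Motion-resolved compressed-sensing reconstruction (ADMM with TV)
#'
#' Solves `min_x sum_b ||A_b x_b - y_b||^2 + lambda_s TV_s(x) +
#' lambda_c TV_c(x) + lambda_r TV_r(x)` over a cardiac x respiratory binned
#' image series by the alternating direction method of multipliers:
#' variable splitting on the (anisotropic, forward-difference) TV terms,
#' soft-thresholding z-updates, and a conjugate-gradient x-update with the
#' per-bin NUFFT Gram matrices precomputed. The cardiac dimension is cyclic,
#' spatial and respiratory are clamped. The objective is monitored; an
#' increase above 10% between iterations stops early with a warning.
#'
#' @param y_bins List (cardiac bins) of lists (respiratory bins) of complex
#'   sample vectors (possibly length 0 for empty bins).
#' @param k_bins Matching sample positions (n x 2, 1/m).
#' @param n Image matrix size.
#' @param fov_m FOV (m).
#' @param config A [recon_config()].
#' @param spokes_per_frame Nominal fully-sampled spoke count used by the
#'   density weights (defaults per bin from sample counts).
#' @return List of class `cs_recon`: `images` (n x n x n_card x n_resp),
#'   `objective` (per iteration), `converged`.
#' @export
admm_tv_recon <- function(y_bins, k_bins, n, fov_m, config = recon_config(),
                          spokes_per_frame = NULL) {
  nc_bins <- length(y_bins)
  nr_bins <- length(y_bins[[1L]])
  dims <- c(n, n, nc_bins, nr_bins)
  npix <- n * n
  dk <- 1 / fov_m

  # per-bin operators: density-weighted NDFT normalized so that the Gram
  # A^H W A is close to identity (the adjoint-with-DCF of a fully sampled
  # acquisition is then the gridding image); the TV weights are calibrated
  # for unit-normalized operators and images
  px_area <- (fov_m / n)^2
  G_list <- vector("list", nc_bins * nr_bins)
  b_arr <- array(0i, dim = dims)
  ynorm2 <- 0
  for (ci in seq_len(nc_bins)) for (ri in seq_len(nr_bins)) {
    id <- (ri - 1L) * nc_bins + ci
    yb <- y_bins[[ci]][[ri]]
    kb <- k_bins[[ci]][[ri]]
    if (length(yb) == 0L) next
    ns <- if (is.null(spokes_per_frame)) max(1L, round(length(yb) /
                                                         (n))) else spokes_per_frame
    w <- radial_dcf(kb, ns, dk) / px_area
    A <- ndft_matrix(kb, n, fov_m)
    WA <- sqrt(w) * A
    G_list[[id]] <- crossprod(Conj(WA), WA)
    b_arr[, , ci, ri] <- matrix(Conj(t(WA)) %*% (sqrt(w) * yb), n, n)
    ynorm2 <- ynorm2 + sum(w * Mod(yb)^2)
  }
  # unit image scale: the reference regularization weights assume images
  # normalized to about 1; the scale is divided out and restored at the end
  s_norm <- max(Mod(b_arr))
  if (s_norm > 0) {
    b_arr <- b_arr / s_norm
    ynorm2 <- ynorm2 / s_norm^2
  } else s_norm <- 1

  ops <- list(
    list(dim = 1L, cyclic = FALSE, lambda = config$lambda_s),
    list(dim = 2L, cyclic = FALSE, lambda = config$lambda_s),
    list(dim = 3L, cyclic = TRUE, lambda = config$lambda_c),
    list(dim = 4L, cyclic = FALSE, lambda = config$lambda_r)
  )
  ops <- Filter(function(o) o$lambda > 0 && dims[o$dim] > 1L, ops)

  gram_apply <- function(x) {
    out <- array(0i, dim = dims)
    for (ci in seq_len(nc_bins)) for (ri in seq_len(nr_bins)) {
      id <- (ri - 1L) * nc_bins + ci
      if (is.null(G_list[[id]])) next
      out[, , ci, ri] <- matrix(G_list[[id]] %*% as.vector(x[, , ci, ri]),
                                n, n)
    }
    for (o in ops) {
      # x-update of the scaled ADMM: f(x) = ||Ax - y||^2 gives the factor
      # rho/2 against the soft-threshold level lambda/rho in the z-update
      out <- out + (config$rho / 2) *
        diff_adjoint(diff_forward(x, o$dim, o$cyclic), o$dim, o$cyclic)
    }
    out
  }

  cg_solve <- function(rhs, x0) {
    x <- x0
    r <- rhs - gram_apply(x)
    p <- r
    rs <- sum(Mod(r)^2)
    for (i in seq_len(config$cg_iter)) {
      if (rs < 1e-14 * max(sum(Mod(rhs)^2), 1e-30)) break
      Ap <- gram_apply(p)
      alpha <- rs / Re(sum(Conj(p) * Ap))
      x <- x + alpha * p
      r <- r - alpha * Ap
      rs_new <- sum(Mod(r)^2)
      p <- r + (rs_new / rs) * p
      rs <- rs_new
    }
    x
  }

  soft <- function(v, thr) {
    m <- Mod(v)
    scale <- pmax(m - thr, 0) / pmax(m, 1e-30)
    v * scale
  }

  objective <- function(x) {
    data_term <- ynorm2
    for (ci in seq_len(nc_bins)) for (ri in seq_len(nr_bins)) {
      id <- (ri - 1L) * nc_bins + ci
      if (is.null(G_list[[id]])) next
      xv <- as.vector(x[, , ci, ri])
      data_term <- data_term +
        Re(Conj(xv) %*% (G_list[[id]] %*% xv))[1L] -
        2 * Re(Conj(as.vector(b_arr[, , ci, ri])) %*% xv)[1L]
    }
    tv <- 0
    for (o in ops) {
      tv <- tv + o$lambda * sum(Mod(diff_forward(x, o$dim, o$cyclic)))
    }
    Re(data_term) + tv
  }

  x <- array(0i, dim = dims)
  z <- lapply(ops, function(o) array(0i, dim = dims))
  u <- lapply(ops, function(o) array(0i, dim = dims))
  obj <- numeric(config$n_iter)
  converged <- TRUE
  for (it in seq_len(config$n_iter)) {
    rhs <- b_arr
    for (j in seq_along(ops)) {
      rhs <- rhs + (config$rho / 2) *
        diff_adjoint(z[[j]] - u[[j]], ops[[j]]$dim, ops[[j]]$cyclic)
    }
    x <- cg_solve(rhs, x)
    for (j in seq_along(ops)) {
      Dx <- diff_forward(x, ops[[j]]$dim, ops[[j]]$cyclic)
      z[[j]] <- soft(Dx + u[[j]], ops[[j]]$lambda / config$rho)
      u[[j]] <- u[[j]] + Dx - z[[j]]
    }
    obj[it] <- objective(x)
    if (it > 1L && obj[it] > 1.1 * obj[it - 1L]) {
      warning(sprintf("objective increased > 10%% at iteration %d; stopping", it))
      obj <- obj[seq_len(it)]
      converged <- FALSE
      break
    }
  }
  structure(list(images = x * s_norm, objective = obj, converged = converged,
                 scale = s_norm, config = config), class = "cs_recon")
}

#' Even/odd-echo inconsistency metric
#'
#' Normalized magnitude discrepancy between two echo images of a static,
#' water-only phantom: `|| |I2| - |I1| || / || I1 ||`. With consistent
#' trajectories the echo images differ only by decay/noise; trajectory
#' errors that alternate with readout polarity inflate the metric.
#'
#' @param img1,img2 Complex images.
#' @return Scalar inconsistency.
#' @export
echo_inconsistency <- function(img1, img2) {
  sqrt(sum((Mod(img2) - Mod(img1))^2) / sum(Mod(img1)^2))
}

#' Trajectory-correction demonstration on a static water phantom
#'
#' End-to-end desk-scale version of the bipolar trajectory-artifact
#' experiment: a static, water-only disk phantom is "acquired" with a
#' two-echo bipolar radial readout through a distorted gradient chain (the
#' data are sampled at the *actual* k-space positions), then reconstructed
#' by gridding assuming either the nominal trajectory (uncorrected) or the
#' GIRF-predicted one (corrected). Returns the even/odd-echo inconsistency
#' of both reconstructions; correction should reduce it.
#'
#' @param system A `girf_model` for the true gradient chain.
#' @param girf_est The GIRF used for correction (default: `system` itself,
#'   i.e. a perfectly estimated response).
#' @param n_spokes Number of radial spokes.
#' @param n Reconstructed image matrix size; the acquisition uses the full
#'   protocol readout (`design`) and the central `|k| <= n/(2 FOV)` samples
#'   of every echo are reconstructed, so the gradient amplitudes -- and
#'   hence the parity-dependent trajectory distortion in 1/FOV units -- are
#'   those of the actual protocol.
#' @param design A [readout_design()] for the acquisition.
#' @param scheme An [echo_scheme()]; the first two echoes are used.
#' @return List: `metric_nominal`, `metric_corrected`, images per echo and
#'   trajectory choice.
#' @export
trajectory_artifact_demo <- function(system = synth_gradient_system(),
                                     girf_est = NULL,
                                     n_spokes = 64L, n = 24L,
                                     design = readout_design(),
                                     scheme = scheme_preset("bipolar3T")) {
  if (is.null(girf_est)) girf_est <- system
  fov_m <- design$fov_mm * 1e-3
  ph <- generate_dynamic_phantom(fov_m = fov_m, resp_amp_m = 0,
                                 card_amp_frac = 0, water_only = TRUE)
  ro <- build_readout(design, scheme)
  angles <- (seq_len(n_spokes) - 1) * pi * (3 - sqrt(5))
  dirs <- cbind(cos(angles), sin(angles), 0)
  ks_nom <- spoke_kspace(dirs, ro, spokes = seq_len(n_spokes), fov_m = fov_m)
  ks_true <- spoke_kspace(dirs, ro, girf = system,
                          spokes = seq_len(n_spokes), fov_m = fov_m)
  ks_corr <- spoke_kspace(dirs, ro, girf = girf_est,
                          spokes = seq_len(n_spokes), fov_m = fov_m)
  es <- ks_nom$echo_samples
  kmax_small <- n / 2                               # grid-point units (1/FOV)
  recon_echo <- function(ktraj_assumed, e) {
    # central samples of this echo (nominal radius within the small grid)
    k1 <- ks_nom$k[es[[e]], 1:2, 1L]
    idx <- es[[e]][sqrt(rowSums(k1^2)) <= 0.999 * kmax_small]
    y <- k <- NULL
    for (s in seq_len(n_spokes)) {
      kk_true <- ks_true$k[idx, 1:2, s] / fov_m     # grid pts -> 1/m
      y <- c(y, phantom_kspace(ph, kk_true, 0))
      k <- rbind(k, ktraj_assumed$k[idx, 1:2, s] / fov_m)
    }
    nufft_gridding_recon(y, k, n, fov_m, n_spokes = n_spokes)
  }
  img_nom <- lapply(1:2, function(e) recon_echo(ks_nom, e))
  img_cor <- lapply(1:2, function(e) recon_echo(ks_corr, e))
  list(
    metric_nominal = echo_inconsistency(img_nom[[1L]], img_nom[[2L]]),
    metric_corrected = echo_inconsistency(img_cor[[1L]], img_cor[[2L]]),
    images_nominal = img_nom, images_corrected = img_cor
  )
}
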