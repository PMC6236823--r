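#' Total-variation (ROF) denoising of a 2-D field
#'
#' Solves min_u ||u - f||^2/2 + weight * TV(u) with Chambolle's dual
#' projection algorithm at a fixed iteration count. Large weights turn the
#' solver into a structural smoother: features narrower than roughly
#' `2 * weight / contrast` pixels are flattened while wide, smooth fields
#' and strong edges pass through.
#'
#' @param f numeric matrix.
#' @param weight regularization weight (units of f, per pixel).
#' @param n_iter number of dual iterations (default 100).
#' @return Denoised matrix of the same size.
#' @export
tv_denoise2d <- function(f, weight, n_iter = 100) {
  stopifnot(is.matrix(f), weight >= 0)
  if (weight == 0 || n_iter == 0) return(f)
  nr <- nrow(f); nc <- ncol(f)
  px <- matrix(0, nr, nc); py <- matrix(0, nr, nc)
  tau <- 0.25
  divp <- matrix(0, nr, nc)
  for (it in seq_len(n_iter)) {
    u <- divp - f / weight
    # forward differences (Neumann boundary)
    gx <- rbind(u[-1, , drop = FALSE] - u[-nr, , drop = FALSE], rep(0, nc))
    gy <- cbind(u[, -1, drop = FALSE] - u[, -nc, drop = FALSE], rep(0, nr))
    px_n <- px + tau * gx
    py_n <- py + tau * gy
    nrm <- pmax(1, sqrt(px_n^2 + py_n^2))
    px <- px_n / nrm
    py <- py_n / nrm
    # backward-difference divergence (adjoint of the gradient)
    divp <- rbind(px[-nr, , drop = FALSE], rep(0, nc)) -
            rbind(rep(0, nc), px[-nr, , drop = FALSE]) +
            cbind(py[, -nc, drop = FALSE], rep(0, nr)) -
            cbind(rep(0, nr), py[, -nc, drop = FALSE])
  }
  f - weight * divp
}

#' TV denoising applied per view of a projection stack
#'
#' @param ps a [projection_stack()].
#' @inheritParams tv_denoise2d
#' @export
tv_denoise_stack <- function(ps, weight, n_iter = 100) {
  stopifnot(inherits(ps, "projection_stack"))
  out <- ps$values
  for (a in seq_len(dim(out)[3]))
    out[, , a] <- tv_denoise2d(out[, , a], weight, n_iter)
  projection_stack(out, ps$domain, ps$geometry)
}

#' TV in-painting of masked voxels
#'
#' Replaces the values under `mask` with a total-variation interpolation
#' from the surrounding voxels (nonlinear Gauss-Seidel with edge-stopping
#' weights); voxels outside the mask are returned bit-exact. Constant and
#' linear fields are recovered through the masked region.
#'
#' @param values numeric array (2-D or 3-D).
#' @param mask logical array of the same shape; `TRUE` marks voxels to
#'   replace. Must not cover the whole array.
#' @param n_sweeps Gauss-Seidel sweeps (default 400).
#' @param eps edge-stopping regularization (in value units).
#' @export
tv_inpaint <- function(values, mask, n_sweeps = 400, eps = 1e-4) {
  d <- dim(values)
  if (is.null(d)) stop("values must be an array")
  if (length(d) == 2) d <- c(d, 1L)
  if (!identical(dim(values), dim(mask) %||% dim(values)) ||
      length(mask) != length(values))
    stop("mask must match values in shape")
  if (all(mask)) stop("mask covers the entire array; nothing to interpolate from")
  out <- cpp_inpaint_tv(as.numeric(values), as.integer(d),
                        as.logical(mask), as.integer(n_sweeps), eps)
  dim(out) <- dim(values)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
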