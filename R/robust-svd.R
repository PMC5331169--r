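#' Robust singular value decomposition by alternating L1 regression
#'
#' Fits a sequence of rank-one components to a (possibly incomplete) matrix
#' using least-absolute-deviation loss instead of least squares. Each
#' component alternates between regressing the residual's rows on the right
#' vector and its columns on the left vector; both regressions are
#' through-the-origin L1 fits, solved exactly by a weighted median over the
#' observed cells. A converged component is deflated from the residual
#' (`residual - lambda * u %*% t(v)`) and extraction continues.
#'
#' Because the weighted median, not the mean, drives every update, isolated
#' large cells barely move the fitted subspace — which is what makes the
#' decomposition usable on contaminated data. Missing (`NA`) cells are
#' simply excluded from every fit; no pre-imputation happens inside.
#'
#' The component scale `lambda` is the Euclidean norm absorbed when the
#' right vector is normalised, so on a clean complete matrix the fit agrees
#' closely with the classical SVD. Signs are fixed so the largest-magnitude
#' element of each left vector is positive, making output deterministic.
#'
#' @param x numeric matrix; `NA` = unobserved. A [metabolite_matrix] is
#'   also accepted (its `values` are used).
#' @param k maximum number of components to extract. Extraction stops early
#'   when the residual is exhausted (component scale below
#'   `1e-12 * lambda_1`).
#' @param tol convergence tolerance: maximum absolute change in the left and
#'   right vectors between iterations.
#' @param max_iter per-component iteration cap. Hitting the cap marks the
#'   component as not converged (a flag, not an error).
#' @param seed integer used only if a starting vector has to be drawn at
#'   random (degenerate all-zero column medians).
#' @return An object of class `robust_svd`: list with `u` (p x K), `v`
#'   (n x K), `d` (K non-increasing non-negative scales), `iterations`,
#'   `converged`, `dims`.
#' @seealso [select_rank()], [rsvd_approx()]
#' @examples
#' x <- outer(1:5, 1:4) + 0
#' f <- robust_svd(x, k = 2)
#' f$d[1]
#' @export
robust_svd <- function(x, k = NULL, tol = 1e-6, max_iter = 100L, seed = 1L) {
  if (inherits(x, "metabolite_matrix")) x <- x$values
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  p <- nrow(x)
  n <- ncol(x)
  obs <- !is.na(x)
  row_obs <- rowSums(obs)
  col_obs <- colSums(obs)
  if (any(row_obs == 0L))
    stop("row ", which(row_obs == 0L)[1L], " has no observed cells")
  if (any(col_obs == 0L))
    stop("column ", which(col_obs == 0L)[1L], " has no observed cells")
  if (is.null(k)) k <- min(p, n, 10L)
  k <- min(as.integer(k), p, n)
  if (k < 1L) stop("k must be at least 1")

  res <- x
  res[!obs] <- 0  # never read where obs is FALSE; keeps C++ arithmetic finite
  u <- matrix(0, p, k)
  v <- matrix(0, n, k)
  d <- numeric(k)
  iters <- integer(k)
  conv <- logical(k)
  n_fit <- 0L
  for (comp in seq_len(k)) {
    v0 <- vapply(seq_len(n), function(j) {
      cells <- res[obs[, j], j]
      if (length(cells)) median(cells) else 0
    }, 0)
    if (sqrt(sum(v0^2)) < 1e-12) {
      # residual column medians vanish (e.g. symmetric residual): seeded draw
      set.seed(as.integer((as.numeric(seed) + comp) %% 2147483647))
      v0 <- rnorm(n)
    }
    fit <- .l1_component(res, obs, v0, tol, as.integer(max_iter))
    if (fit$lambda <= 0 || (n_fit > 0L && fit$lambda < 1e-12 * max(d[seq_len(n_fit)])))
      break
    n_fit <- comp
    # sign convention: largest-|.| element of u positive
    flip <- sign(fit$u[which.max(abs(fit$u))])
    u[, comp] <- flip * fit$u
    v[, comp] <- flip * fit$v
    d[comp] <- fit$lambda
    iters[comp] <- fit$iterations
    conv[comp] <- fit$converged
    res <- res - fit$lambda * tcrossprod(fit$u, fit$v)
    res[!obs] <- 0
  }
  if (n_fit == 0L) stop("no non-degenerate component could be extracted")
  keep <- seq_len(n_fit)
  ord <- order(d[keep], decreasing = TRUE)
  out <- structure(list(u = u[, keep[ord], drop = FALSE],
                        v = v[, keep[ord], drop = FALSE],
                        d = d[keep][ord],
                        iterations = iters[keep][ord],
                        converged = conv[keep][ord],
                        dims = c(p = p, n = n)),
                   class = "robust_svd")
  if (!all(out$converged))
    warning(sum(!out$converged), " component(s) hit max_iter without converging")
  out
}

#' @export
print.robust_svd <- function(x, ...) {
  cat("robust_svd fit:", x$dims["p"], "x", x$dims["n"], "matrix,",
      length(x$d), "component(s)\n")
  cat("scales:", paste(signif(x$d, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.robust_svd <- function(object, alpha = 0.05, ...) {
  expl <- cumsum(object$d^2) / sum(object$d^2)
  out <- data.frame(component = seq_along(object$d), scale = object$d,
                    explained = expl, iterations = object$iterations,
                    converged = object$converged)
  cat("Robust SVD,", length(object$d), "components; rank at alpha =",
      alpha, "is", select_rank(object$d, alpha), "\n")
  print(out, row.names = FALSE)
  invisible(out)
}

#' Select the approximation rank from singular values
#'
#' Smallest `r` whose leading components explain at least
#' `(1 - alpha) * 100%` of the total variation. Variation is measured as the
#' sum of squared singular values (the explained-variance convention);
#' `total = "sum"` switches to the plain sum of singular values.
#'
#' @param d non-increasing, non-negative singular values.
#' @param alpha tail fraction of variation allowed to be discarded, in
#'   (0, 1).
#' @param total `"square"` (default) or `"sum"`.
#' @return Integer rank (at least 1).
#' @export
select_rank <- function(d, alpha = 0.05, total = c("square", "sum")) {
  total <- match.arg(total)
  if (length(d) == 0L || all(d == 0)) stop("all singular values are zero")
  if (any(d < 0)) stop("singular values must be non-negative")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  mass <- if (total == "square") d^2 else d
  which(cumsum(mass) / sum(mass) >= 1 - alpha)[1L]
}

#' Rank-r approximation from a robust SVD fit
#'
#' @param fit a [robust_svd] fit.
#' @param r rank, `1 <= r <= length(fit$d)`.
#' @return Complete numeric matrix `sum_{k<=r} d_k u_k v_k'`.
#' @export
rsvd_approx <- function(fit, r) {
  stopifnot(inherits(fit, "robust_svd"))
  r <- as.integer(r)
  if (r < 1L) stop("r must be at least 1")
  if (r > length(fit$d))
    stop("r = ", r, " exceeds the ", length(fit$d), " fitted component(s)")
  idx <- seq_len(r)
  fit$u[, idx, drop = FALSE] %*% (fit$d[idx] * t(fit$v[, idx, drop = FALSE]))
}

#' @export
#' @rdname rsvd_approx
#' @param object,... method arguments; `rank` defaults to all components.
#' @param rank approximation rank passed on to [rsvd_approx()].
fitted.robust_svd <- function(object, rank = length(object$d), ...) {
  rsvd_approx(object, rank)
}
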