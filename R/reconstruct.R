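#' Split a matrix by sample group
#'
#' Order-preserving, column-disjoint split of a metabolite matrix into the
#' group-1 and group-2 submatrices. Membership, not file or label order,
#' decides which column lands where.
#'
#' @param x a [metabolite_matrix] or numeric matrix.
#' @param design a [group_design] aligned with the columns of `x`.
#' @param min_per_group smallest admissible group size; quartiles and the
#'   t-test downstream need at least 3.
#' @return List with `group1`, `group2` (numeric matrices, `NA` = missing)
#'   and `index1`, `index2` (column indices into `x`).
#' @export
partition_matrix <- function(x, design, min_per_group = 3L) {
  vals <- if (inherits(x, "metabolite_matrix")) x$values else as.matrix(x)
  if (length(design$labels) != ncol(vals))
    stop("design has ", length(design$labels), " samples, matrix has ",
         ncol(vals), " columns")
  lev <- levels(design$labels)
  idx1 <- which(design$labels == lev[1L])
  idx2 <- which(design$labels == lev[2L])
  if (length(idx1) < min_per_group || length(idx2) < min_per_group)
    stop("each group needs at least ", min_per_group, " samples")
  list(group1 = vals[, idx1, drop = FALSE],
       group2 = vals[, idx2, drop = FALSE],
       index1 = idx1, index2 = idx2)
}

#' Flag outlying cells of one metabolite by the IQR rule
#'
#' A value is flagged when it lies below `Q1 - k * IQR` or above
#' `Q3 + k * IQR`, with quartiles computed on the observed values by linear
#' interpolation between order statistics (`quantile` type 7).
#'
#' @param values numeric vector (one metabolite within one group); `NA` =
#'   missing, never flagged.
#' @param k IQR multiplier, conventionally 1.5.
#' @return Logical vector, `TRUE` = outlying cell. Fewer than 3 observed
#'   values: nothing is flagged and a warning is issued.
#' @export
iqr_outliers <- function(values, k = 1.5) {
  if (k <= 0) stop("k must be positive")
  out <- rep(FALSE, length(values))
  obs <- !is.na(values)
  if (sum(obs) < 3L) {
    warning("fewer than 3 observed values; no outliers flagged")
    return(out)
  }
  q <- quantile(values[obs], c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  out[obs] <- values[obs] < q[1L] - k * iqr | values[obs] > q[2L] + k * iqr
  out
}

#' Groupwise robust-SVD reconstruction
#'
#' The core reconstruction step: within each sample group separately,
#' outlying cells are flagged per metabolite by the IQR rule, a robust SVD
#' is fitted treating missing and flagged cells as unobserved, the rank is
#' chosen so the leading components explain at least `(1 - alpha) * 100%`
#' of the fitted variation, and every missing or flagged cell is replaced
#' by its rank-r approximation value. Clean observed cells are returned
#' bit-identical. The two reconstructed group submatrices are re-assembled
#' in the original sample order.
#'
#' Fitting each group on its own keeps genuine group effects out of the
#' outlier rule and the low-rank fit, so disease/control differences are
#' neither flagged away nor smeared across groups.
#'
#' @param x a [metabolite_matrix] or numeric matrix with `NA` missing cells.
#' @param design a [group_design].
#' @param alpha explained-variation tail for rank selection (default 0.05,
#'   i.e. keep 95%).
#' @param iqr_k IQR multiplier for the outlier rule.
#' @param max_components cap on components fitted per group.
#' @param tol,max_iter,seed passed to [robust_svd()].
#' @param passes outlier-detection passes (default 2). The raw IQR rule
#'   breaks down when more than a quartile's worth of one metabolite's
#'   in-group cells are contaminated (the IQR itself explodes and nothing
#'   is flagged), so by default a second pass applies a Hampel rule
#'   (median +/- `hampel_z` robust standard deviations) to the residuals
#'   from a rank-1 robust baseline fit, where gross cells stand out
#'   against a tight noise spread, and the fit is redone with the
#'   enlarged flag set. `passes = 1` gives the single detect-fit-replace
#'   pass.
#' @param hampel_z cutoff of the second-pass gross-error rule, in robust
#'   standard deviations (`1.4826 * MAD`). The default 3.5 is deliberately
#'   stricter than the IQR rule's normal-theory cutoff (about 2.7 sigma at
#'   `iqr_k = 1.5`): ordinary tail values are already policed by the
#'   quartile rule, and the residual pass only needs to catch gross
#'   contamination that overwhelms it.
#' @param rank_floor `"permutation"` (default) applies a parallel-analysis
#'   noise floor before rank selection: the observed cells of each
#'   metabolite are permuted across samples (which keeps the per-row
#'   baselines and the missingness pattern but destroys any real
#'   across-sample structure), the fit is repeated, and real components
#'   whose scale does not exceed the permuted second component's are
#'   discarded. `"none"` selects the rank from the raw scales.
#' @return Object of class `metab_recon`: list with `reconstructed`
#'   (complete p x n matrix), `outlier_mask`, `replaced_mask` (union of
#'   missing and flagged cells), `missing_mask`, `ranks` (chosen rank per
#'   group), `fits` (the per-group [robust_svd] objects).
#' @export
reconstruct_rsvd <- function(x, design, alpha = 0.05, iqr_k = 1.5,
                             max_components = 10L, tol = 1e-6,
                             max_iter = 100L, seed = 1L, passes = 2L,
                             hampel_z = 3.5,
                             rank_floor = c("permutation", "none")) {
  rank_floor <- match.arg(rank_floor)
  if (!passes %in% 1:2) stop("passes must be 1 or 2")
  vals <- if (inherits(x, "metabolite_matrix")) x$values else as.matrix(x)
  parts <- partition_matrix(vals, design)
  missing_mask <- is.na(vals)
  outlier_mask <- matrix(FALSE, nrow(vals), ncol(vals))
  recon <- vals
  ranks <- integer(2L)
  fits <- vector("list", 2L)
  names(ranks) <- names(fits) <- levels(design$labels)
  for (g in 1:2) {
    idx <- if (g == 1L) parts$index1 else parts$index2
    xg <- vals[, idx, drop = FALSE]
    if (any(rowSums(!is.na(xg)) == 0L))
      stop("metabolite ", which(rowSums(!is.na(xg)) == 0L)[1L],
           " has no observed cells in group ", levels(design$labels)[g])
    keep_fittable <- function(flags) {
      # a metabolite must keep at least one observed cell in the fit
      dead <- rowSums(!is.na(xg) & !flags) == 0L
      flags[dead, ] <- FALSE
      flags
    }
    flags <- keep_fittable(t(apply(xg, 1L, iqr_outliers, k = iqr_k)))
    if (passes == 2L) {
      # Second detection pass against the rank-1 robust baseline. The
      # leading component is the most breakdown-resistant summary of the
      # group (spread loadings, weighted-median fits), so gross cells
      # stand out in its residuals even in metabolites where they
      # overwhelm the raw-value quartiles; the median/MAD rule keeps a
      # 50% breakdown point there.
      xg_fit <- xg
      xg_fit[flags] <- NA_real_
      base <- robust_svd(xg_fit, k = 1L, tol = tol, max_iter = max_iter,
                         seed = seed)
      resid <- xg - rsvd_approx(base, 1L)
      data_scale <- max(abs(xg), na.rm = TRUE)
      hampel <- t(apply(resid, 1L, function(r) {
        out <- rep(FALSE, length(r))
        obs <- !is.na(r)
        if (sum(obs) < 3L) return(out)
        s <- stats::mad(r[obs])
        # floor guards against flagging numerical noise on exact fits
        if (s <= 1e-10 * data_scale) return(out)
        out[obs] <- abs(r[obs] - median(r[obs])) > hampel_z * s
        out
      }))
      flags <- keep_fittable(flags | hampel)
    }
    xg_fit <- xg
    xg_fit[flags] <- NA_real_
    fit <- robust_svd(xg_fit, k = max_components, tol = tol,
                      max_iter = max_iter, seed = seed)
    if (rank_floor == "permutation" && length(fit$d) > 1L) {
      # Parallel-analysis noise floor: permuting the observed cells within
      # each row preserves the per-metabolite baselines (hence the leading
      # component) and the missingness pattern, but destroys any across-
      # sample structure, so the second component of the permuted fit
      # measures the scale at which the alternating-median fit merely
      # co-adapts to noise. Real components at or below that scale carry
      # no evidence of structure and are dropped before rank selection.
      set.seed(as.integer((as.numeric(seed) + 104729 * g) %% 2147483647))
      xp <- xg_fit
      for (i in seq_len(nrow(xp))) {
        o <- which(!is.na(xp[i, ]))
        if (length(o) > 1L) xp[i, o] <- xp[i, sample(o)]
      }
      fitp <- robust_svd(xp, k = 2L, tol = tol, max_iter = max_iter,
                         seed = seed)
      if (length(fitp$d) >= 2L) {
        cut <- which(fit$d <= fitp$d[2L])
        cut <- cut[cut > 1L]
        if (length(cut)) {
          keep <- seq_len(min(cut) - 1L)
          fit$u <- fit$u[, keep, drop = FALSE]
          fit$v <- fit$v[, keep, drop = FALSE]
          fit$d <- fit$d[keep]
          fit$iterations <- fit$iterations[keep]
          fit$converged <- fit$converged[keep]
        }
      }
    }
    r <- select_rank(fit$d, alpha)
    approx <- rsvd_approx(fit, r)
    # A substituted value must stay inside its metabolite's observed clean
    # range within the group: a low-rank extrapolation at an unobserved
    # cell is never allowed to be more extreme than every value actually
    # measured for that metabolite (the averaging imputers share this
    # property by construction).
    row_lo <- apply(xg_fit, 1L, min, na.rm = TRUE)
    row_hi <- apply(xg_fit, 1L, max, na.rm = TRUE)
    approx <- pmin(pmax(approx, row_lo), row_hi)
    replace_g <- is.na(xg) | flags
    xg[replace_g] <- approx[replace_g]
    recon[, idx] <- xg
    outlier_mask[, idx] <- flags
    ranks[g] <- r
    fits[[g]] <- fit
  }
  dimnames(recon) <- dimnames(vals)
  structure(list(reconstructed = recon, outlier_mask = outlier_mask,
                 replaced_mask = missing_mask | outlier_mask,
                 missing_mask = missing_mask, ranks = ranks, fits = fits),
            class = "metab_recon")
}

#' @export
print.metab_recon <- function(x, ...) {
  cat("groupwise robust-SVD reconstruction:",
      nrow(x$reconstructed), "x", ncol(x$reconstructed), "\n")
  cat("  ranks:", paste(names(x$ranks), x$ranks, sep = " = ", collapse = ", "),
      "\n")
  cat("  cells replaced:", sum(x$replaced_mask),
      sprintf("(%d missing, %d flagged as outliers)\n",
              sum(x$missing_mask), sum(x$outlier_mask)))
  invisible(x)
}

#' Zero imputation
#'
#' Replaces every missing cell by zero and leaves everything else untouched.
#'
#' @param x a [metabolite_matrix] or numeric matrix with `NA` missing cells.
#' @return Complete numeric matrix.
#' @export
impute_zero <- function(x) {
  vals <- if (inherits(x, "metabolite_matrix")) x$values else as.matrix(x)
  vals[is.na(vals)] <- 0
  vals
}

#' k-nearest-neighbour imputation
#'
#' Neighbours are other metabolites (rows). Distance between two rows is the
#' Euclidean distance over the coordinates observed in both, rescaled by
#' `sqrt(n / shared)` so rows with few shared coordinates are comparable.
#' A missing cell is filled with the mean of the k nearest rows' observed
#' values in that column; if no neighbour has the column observed, the row's
#' own observed mean is used.
#'
#' @param x a [metabolite_matrix] or numeric matrix with `NA` missing cells.
#' @param k number of neighbours (default 10).
#' @return Complete numeric matrix.
#' @export
impute_knn <- function(x, k = 10L) {
  vals <- if (inherits(x, "metabolite_matrix")) x$values else as.matrix(x)
  p <- nrow(vals)
  n <- ncol(vals)
  if (p < k + 1L) stop("need at least k + 1 = ", k + 1L, " metabolites")
  obs <- !is.na(vals)
  if (any(colSums(obs) == 0L))
    stop("column ", which(colSums(obs) == 0L)[1L], " is missing in every row")
  todo <- which(rowSums(!obs) > 0L)
  if (!length(todo)) return(vals)
  xz <- vals
  xz[!obs] <- 0
  m <- obs * 1
  # squared distance over shared coords via cross products
  sq <- xz^2
  a <- tcrossprod(sq, m)
  shared <- tcrossprod(m)
  d2 <- a + t(a) - 2 * tcrossprod(xz)
  d2[d2 < 0] <- 0  # numerical noise
  dist <- sqrt(d2 * n / pmax(shared, 1))
  dist[shared == 0L] <- Inf
  diag(dist) <- Inf
  out <- vals
  for (i in todo) {
    ord <- order(dist[i, ])
    row_fallback <- mean(vals[i, obs[i, ]])
    for (j in which(!obs[i, ])) {
      donors <- ord[obs[ord, j] & is.finite(dist[i, ord])]
      if (length(donors)) {
        out[i, j] <- mean(vals[head(donors, k), j])
      } else {
        out[i, j] <- row_fallback
      }
    }
  }
  out
}

#' Iterative random-forest imputation
#'
#' missForest-style scheme: missing cells start at their row's observed
#' mean; metabolites are visited in order of increasing missingness, each
#' regressed on all other metabolites with a random forest fitted on the
#' samples where it is observed, and its missing cells replaced by the
#' forest's predictions. Rounds repeat until the normalised change in the
#' imputed values increases (the previous round is then returned) or
#' `max_rounds` is reached.
#'
#' @param x a [metabolite_matrix] or numeric matrix with `NA` missing cells.
#' @param n_trees trees per forest (default 100).
#' @param max_rounds iteration cap (default 10).
#' @param seed integer seed; fixed seed gives identical output.
#' @param mtry predictors tried per split; default `floor(sqrt(p - 1))`.
#' @return Complete numeric matrix.
#' @export
impute_rf <- function(x, n_trees = 100L, max_rounds = 10L, seed = 1L,
                      mtry = NULL) {
  vals <- if (inherits(x, "metabolite_matrix")) x$values else as.matrix(x)
  p <- nrow(vals)
  obs <- !is.na(vals)
  if (any(colSums(obs) == 0L))
    stop("column ", which(colSums(obs) == 0L)[1L], " is missing in every row")
  todo <- which(rowSums(!obs) > 0L)
  if (!length(todo)) return(vals)
  todo <- todo[order(rowSums(!obs)[todo])]
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p - 1L)))
  cur <- vals
  for (i in seq_len(p)) {
    if (any(!obs[i, ])) cur[i, !obs[i, ]] <- mean(vals[i, obs[i, ]])
  }
  set.seed(seed)
  prev <- cur
  prev_diff <- Inf
  for (round in seq_len(max_rounds)) {
    before <- cur
    for (i in todo) {
      train_cols <- which(obs[i, ])
      miss_cols <- which(!obs[i, ])
      xtrain <- t(cur[-i, train_cols, drop = FALSE])
      xpred <- t(cur[-i, miss_cols, drop = FALSE])
      colnames(xtrain) <- colnames(xpred) <- paste0("x", seq_len(p - 1L))
      fit <- ranger::ranger(x = xtrain, y = vals[i, train_cols],
                            num.trees = n_trees, mtry = mtry,
                            num.threads = 1L)
      cur[i, miss_cols] <- predict(fit, data = xpred,
                                   num.threads = 1L)$predictions
    }
    diff <- sum((cur[!obs] - before[!obs])^2) / max(sum(cur[!obs]^2), .Machine$double.eps)
    if (diff >= prev_diff) {
      if (round == max_rounds)
        warning("random-forest imputation did not converge in ", max_rounds,
                " rounds")
      return(before)
    }
    prev_diff <- diff
  }
  cur
}
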