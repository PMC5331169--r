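#' Rank metabolites by SVM importance
#'
#' Features (metabolites) are standardised to zero mean and unit variance,
#' a linear soft-margin SVM is trained on all samples, and recursive
#' feature elimination removes the feature with the smallest squared weight
#' one round at a time. The rank is the reverse elimination order (rank 1 =
#' survived longest); the importance score is the elimination round, so
#' later elimination means a higher score. Ties in the squared weights are
#' broken by eliminating the lower row index first, which together with the
#' fixed seed makes the output deterministic.
#'
#' @param x numeric matrix restricted to the features to rank (features x
#'   samples), typically the DE rows of a reconstructed matrix.
#' @param design a [group_design].
#' @param seed integer seed.
#' @param cost soft-margin cost of the linear SVM.
#' @param method `"rfe"` (recursive elimination, default) or `"weight"`
#'   (single-shot ranking by `|w|` from one fit).
#' @param direction optional per-feature direction labels carried into the
#'   result (e.g. from a [de_table]).
#' @return Data frame of class `svm_ranking` with columns `rank`,
#'   `metabolite_id`, `importance_score`, `direction`, ordered by rank.
#' @export
svm_rank <- function(x, design, seed = 1L, cost = 1, method = c("rfe", "weight"),
                     direction = NULL) {
  method <- match.arg(method)
  x <- as.matrix(x)
  m <- nrow(x)
  if (m < 2L) stop("need at least 2 features to rank")
  if (length(design$labels) != ncol(x)) stop("design does not match columns")
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("m", seq_len(m))
  if (is.null(direction)) direction <- rep(NA_character_, m)
  y <- design$labels
  sds <- apply(x, 1L, sd)
  const <- sds == 0
  if (any(const))
    warning(sum(const), " constant feature(s); eliminated first")
  xs <- (x - rowMeans(x)) / ifelse(const, 1, sds)

  set.seed(seed)
  svm_weights <- function(feat_idx) {
    fit <- e1071::svm(x = t(xs[feat_idx, , drop = FALSE]), y = y,
                      kernel = "linear", cost = cost, scale = FALSE)
    w <- crossprod(fit$coefs, fit$SV)
    as.numeric(w)
  }

  elim_order <- integer(0)
  if (any(const)) elim_order <- which(const)
  active <- setdiff(seq_len(m), elim_order)
  if (method == "weight") {
    w2 <- rep(-Inf, m)
    w2[active] <- svm_weights(active)^2
    # rank by descending squared weight; ties keep lower index first
    ord <- order(-w2, seq_len(m))
    rank <- integer(m)
    rank[ord] <- seq_len(m)
    score <- m - rank + 1L
  } else {
    while (length(active) > 1L) {
      w2 <- svm_weights(active)^2
      drop_pos <- which.min(w2)  # lowest index wins ties
      elim_order <- c(elim_order, active[drop_pos])
      active <- active[-drop_pos]
    }
    elim_order <- c(elim_order, active)
    rank <- integer(m)
    rank[elim_order] <- rev(seq_len(m))
    score <- integer(m)
    score[elim_order] <- seq_len(m)
  }
  out <- data.frame(rank = sort(rank), metabolite_id = ids[order(rank)],
                    importance_score = score[order(rank)],
                    direction = direction[order(rank)],
                    stringsAsFactors = FALSE)
  class(out) <- c("svm_ranking", "data.frame")
  out
}

#' Select a biomarker panel from a ranking
#'
#' Takes the best-ranked `n_up` upregulated and `n_down` downregulated
#' metabolites, preserving rank order. Asks for more than are available on
#' either side: returns all available with a warning.
#'
#' @param ranking an [svm_rank()] result with a `direction` column.
#' @param n_up,n_down panel sizes (defaults 4 and 2).
#' @return List of class `biomarker_panel` with `up_markers`,
#'   `down_markers` (character vectors in rank order).
#' @export
select_panel <- function(ranking, n_up = 4L, n_down = 2L) {
  if (n_up < 0L || n_down < 0L || (n_up == 0L && n_down == 0L))
    stop("panel sizes must be non-negative and not both zero")
  if (!nrow(ranking)) stop("ranking is empty")
  up <- ranking$metabolite_id[ranking$direction %in% "up"]
  down <- ranking$metabolite_id[ranking$direction %in% "down"]
  if (length(up) < n_up || length(down) < n_down)
    warning("fewer metabolites available than requested (",
            length(up), " up, ", length(down), " down); returning all")
  structure(list(up_markers = head(up, n_up), down_markers = head(down, n_down)),
            class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat("biomarker panel:\n  up:  ",
      paste(x$up_markers, collapse = ", "), "\n  down:",
      paste(x$down_markers, collapse = ", "), "\n")
  invisible(x)
}

#' Cross-validated SVM sample classification
#'
#' Stratified k-fold cross validation of a linear SVM on the given feature
#' set. Folds are assigned within each group by a seeded draw applied to
#' samples ordered by their identifier, so the assignment does not depend
#' on column order. Standardisation is fitted on the training folds only.
#' Predictions are pooled over folds into a single confusion matrix;
#' group 2 (disease) is the positive class.
#'
#' @param x numeric matrix restricted to the classifier's features
#'   (features x samples).
#' @param design a [group_design].
#' @param folds number of folds (default 5); each group must have at least
#'   `folds` samples.
#' @param seed integer seed for fold assignment.
#' @param cost linear-SVM cost.
#' @return Object of class `classification_metrics`: list with `confusion`
#'   (named counts nTP, nFP, nTN, nFN) and percentage metrics `accuracy`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `balanced_accuracy`.
#' @export
crossval_classify <- function(x, design, folds = 5L, seed = 1L, cost = 1) {
  x <- as.matrix(x)
  if (nrow(x) < 1L) stop("no features")
  y <- design$labels
  n <- length(y)
  if (ncol(x) != n) stop("design does not match columns")
  lev <- levels(y)
  if (any(table(y) < folds))
    stop("each group needs at least ", folds, " samples for ", folds, "-fold CV")
  sample_ids <- design$sample_ids
  if (is.null(sample_ids)) sample_ids <- sprintf("s%05d", seq_len(n))
  fold_id <- integer(n)
  set.seed(seed)
  for (g in lev) {
    idx <- which(y == g)
    idx <- idx[order(sample_ids[idx])]  # column-order independent
    fold_id[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
  }
  pred <- factor(rep(lev[1L], n), levels = lev)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    mu <- rowMeans(x[, tr, drop = FALSE])
    sdv <- apply(x[, tr, drop = FALSE], 1L, sd)
    sdv[sdv == 0] <- 1
    xs <- (x - mu) / sdv
    fit <- e1071::svm(x = t(xs[, tr, drop = FALSE]), y = y[tr],
                      kernel = "linear", cost = cost, scale = FALSE)
    pred[!tr] <- predict(fit, t(xs[, !tr, drop = FALSE]))
  }
  pos <- lev[2L]
  out <- classification_metrics(nTP = sum(pred == pos & y == pos),
                                nFP = sum(pred == pos & y != pos),
                                nTN = sum(pred != pos & y != pos),
                                nFN = sum(pred != pos & y == pos))
  out$folds <- folds
  out$seed <- seed
  out
}

#' Classification performance metrics from confusion counts
#'
#' Accuracy, sensitivity, specificity, positive and negative predictive
#' value and balanced accuracy, all as percentages.
#'
#' @param nTP,nFP,nTN,nFN non-negative confusion counts.
#' @return Object of class `classification_metrics`.
#' @export
classification_metrics <- function(nTP, nFP, nTN, nFN) {
  counts <- c(nTP = nTP, nFP = nFP, nTN = nTN, nFN = nFN)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  pct <- function(a, b) if (b == 0) NA_real_ else 100 * a / b
  sens <- pct(nTP, nTP + nFN)
  spec <- pct(nTN, nTN + nFP)
  structure(list(confusion = counts,
                 accuracy = pct(nTP + nTN, sum(counts)),
                 sensitivity = sens, specificity = spec,
                 ppv = pct(nTP, nTP + nFP), npv = pct(nTN, nTN + nFN),
                 balanced_accuracy = (sens + spec) / 2,
                 folds = NA_integer_, seed = NA_integer_),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(paste0("%d-fold CV: accuracy %.2f%%, sensitivity %.2f%%, ",
                     "specificity %.2f%%, PPV %.2f%%, NPV %.2f%%, ",
                     "balanced %.2f%%\n"),
              x$folds, x$accuracy, x$sensitivity, x$specificity, x$ppv,
              x$npv, x$balanced_accuracy))
  print(x$confusion)
  invisible(x)
}

#' Correlation network edge list
#'
#' Pearson correlations between feature rows; undirected edges for pairs
#' with `|r| >= threshold`, ordered with `i < j`. Constant features are
#' excluded with a warning.
#'
#' @param x numeric matrix (features x samples), at least 2 features.
#' @param threshold absolute-correlation cut-off (default 0.7).
#' @return Data frame with `id_a`, `id_b`, `pearson_r`.
#' @export
correlation_network <- function(x, threshold = 0.7) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 features")
  ids <- rownames(x)
  if (is.null(ids)) ids <- paste0("m", seq_len(nrow(x)))
  sds <- apply(x, 1L, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant feature(s) excluded")
    x <- x[sds > 0, , drop = FALSE]
    ids <- ids[sds > 0]
  }
  if (nrow(x) < 2L)
    return(data.frame(id_a = character(0), id_b = character(0),
                      pearson_r = numeric(0)))
  r <- cor(t(x))
  pairs <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  data.frame(id_a = ids[pairs[, 1L]], id_b = ids[pairs[, 2L]],
             pearson_r = r[pairs], stringsAsFactors = FALSE)
}
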