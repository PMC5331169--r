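#' Root mean square error between two matrices
#'
#' `sqrt(mean((x - xhat)^2))` over all cells.
#'
#' @param x,xhat numeric matrices of identical shape.
#' @return Non-negative scalar.
#' @export
rmse <- function(x, xhat) {
  x <- as.matrix(x)
  xhat <- as.matrix(xhat)
  if (!identical(dim(x), dim(xhat)))
    stop("shape mismatch: ", paste(dim(x), collapse = "x"), " vs ",
         paste(dim(xhat), collapse = "x"))
  sqrt(mean((x - xhat)^2))
}

#' ROC curve and AUC for DE detection
#'
#' Metabolites are scored by ascending p value (smaller = more confidently
#' DE). The threshold sweeps over all distinct scores — tied scores share a
#' threshold — giving one (FPR, TPR) point per threshold, anchored at
#' (0, 0) and (1, 1). AUC is the trapezoid-rule area, on the percent scale.
#'
#' @param p_values per-metabolite scores (ascending = more significant).
#' @param truth logical or `"de"`/`"ee"` labels; `TRUE`/`"de"` = truly DE.
#' @return List with `roc_points` (data frame `fpr`, `tpr`) and `auc`
#'   (percent scale, 0 to 100).
#' @export
detection_roc <- function(p_values, truth) {
  if (is.character(truth)) truth <- truth == "de"
  if (is.factor(truth)) truth <- as.character(truth) == "de"
  truth <- as.logical(truth)
  if (length(truth) != length(p_values)) stop("labels do not align with scores")
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0L || n_neg == 0L)
    stop("both DE and EE metabolites must be present in the truth")
  ord <- order(p_values)
  ps <- p_values[ord]
  tr <- truth[ord]
  # cumulative counts at each distinct threshold (ties collapse together)
  last_of_tie <- c(ps[-1L] != ps[-length(ps)], TRUE)
  tp <- cumsum(tr)[last_of_tie]
  fp <- cumsum(!tr)[last_of_tie]
  tpr <- c(0, tp / n_pos, 1)
  fpr <- c(0, fp / n_neg, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1L) + tpr[-1L]) / 2) * 100
  list(roc_points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Misclassification error rate from AUC
#'
#' The benchmark's MER is the complement of the AUC on the percent scale.
#'
#' @param auc AUC in percent, between 0 and 100.
#' @return `100 - auc`.
#' @export
mer_from_auc <- function(auc) {
  if (any(auc < 0 | auc > 100)) stop("auc must be in [0, 100]")
  100 - auc
}

#' Complete a contaminated matrix by one of the benchmark methods
#'
#' The three baseline imputers fill missing cells only and leave outlier
#' cells untouched; the `rsvd` method is the groupwise robust-SVD
#' reconstruction, which also replaces cells flagged by the IQR rule.
#'
#' @param sim a [simulate_dataset()] result (or any list with `matrix` and
#'   `design`).
#' @param method `"zero"`, `"knn"`, `"rf"` or `"rsvd"`.
#' @param knn_k,rf_trees,alpha,iqr_k,max_components,seed method options.
#' @return Complete numeric matrix.
#' @export
complete_matrix <- function(sim, method = c("rsvd", "zero", "knn", "rf"),
                            knn_k = 10L, rf_trees = 100L, alpha = 0.05,
                            iqr_k = 1.5, max_components = 10L, seed = 1L) {
  method <- match.arg(method)
  switch(method,
         zero = impute_zero(sim$matrix),
         knn = impute_knn(sim$matrix, k = knn_k),
         rf = impute_rf(sim$matrix, n_trees = rf_trees, seed = seed),
         rsvd = reconstruct_rsvd(sim$matrix, sim$design, alpha = alpha,
                                 iqr_k = iqr_k,
                                 max_components = max_components,
                                 seed = seed)$reconstructed)
}

#' Replicated simulation benchmark
#'
#' For every (missing rate, outlier rate) condition and replicate, a
#' dataset is simulated, completed by each method, and scored by RMSE
#' against the clean matrix and by the t-test p-value ROC against the true
#' DE/EE labels. Per-replicate seeds are derived deterministically from
#' `seed`, so a fixed grid reruns identically. Method failures on a
#' replicate are recorded and excluded from the means.
#'
#' @param methods subset of `c("zero", "knn", "rf", "rsvd")`.
#' @param missing_rates,outlier_rates condition axes.
#' @param n_replicates replicates per condition.
#' @param base_config a [sim_config] supplying everything except the rates
#'   and seed.
#' @param seed grid seed.
#' @param knn_k,rf_trees,alpha,iqr_k,max_components method options passed
#'   to [complete_matrix()].
#' @return Object of class `benchmark_report`: list with `summary` (one
#'   row per method x condition: mean RMSE, mean AUC, mean MER, number of
#'   successful replicates) and `replicates` (per-replicate records).
#' @export
run_benchmark <- function(methods = c("zero", "knn", "rf", "rsvd"),
                          missing_rates = 0.10, outlier_rates = 0,
                          n_replicates = 25L, base_config = sim_config(),
                          seed = 1L, knn_k = 10L, rf_trees = 100L,
                          alpha = 0.05, iqr_k = 1.5, max_components = 10L) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (n_replicates < 1L) stop("n_replicates must be at least 1")
  recs <- list()
  ri <- 0L
  for (mr in missing_rates) for (orate in outlier_rates) {
    for (rep_i in seq_len(n_replicates)) {
      cfg <- base_config
      cfg$missing_rate <- mr
      cfg$outlier_rate <- orate
      cfg$seed <- as.integer((as.numeric(seed) * 10007 + rep_i * 211 +
                                round(1e4 * mr) + round(1e6 * orate)) %%
                               2147483647)
      sim <- simulate_dataset(cfg)
      p_truth <- sim$de_labels != "ee"
      for (method in methods) {
        ri <- ri + 1L
        recs[[ri]] <- tryCatch({
          xhat <- complete_matrix(sim, method, knn_k = knn_k,
                                  rf_trees = rf_trees, alpha = alpha,
                                  iqr_k = iqr_k,
                                  max_components = max_components,
                                  seed = cfg$seed)
          r <- rmse(sim$clean, xhat)
          pv <- two_sample_t(xhat, sim$design)$p_value
          auc <- detection_roc(pv, p_truth)$auc
          data.frame(method = method, missing_rate = mr,
                     outlier_rate = orate, replicate = rep_i,
                     rmse = r, auc = auc, mer = mer_from_auc(auc),
                     error = NA_character_, stringsAsFactors = FALSE)
        }, error = function(e) {
          data.frame(method = method, missing_rate = mr,
                     outlier_rate = orate, replicate = rep_i,
                     rmse = NA_real_, auc = NA_real_, mer = NA_real_,
                     error = conditionMessage(e), stringsAsFactors = FALSE)
        })
      }
    }
  }
  reps <- do.call(rbind, recs)
  ok <- reps[is.na(reps$error), ]
  key <- interaction(ok$method, ok$missing_rate, ok$outlier_rate, drop = TRUE)
  agg <- do.call(rbind, lapply(split(ok, key), function(d) {
    data.frame(method = d$method[1L], missing_rate = d$missing_rate[1L],
               outlier_rate = d$outlier_rate[1L], n_replicates = nrow(d),
               mean_rmse = mean(d$rmse), mean_auc = mean(d$auc),
               mean_mer = mean(d$mer), stringsAsFactors = FALSE)
  }))
  agg <- agg[order(agg$missing_rate, agg$outlier_rate, agg$method), ]
  rownames(agg) <- NULL
  n_failed <- sum(!is.na(reps$error))
  if (n_failed)
    warning(n_failed, " replicate run(s) failed and were excluded")
  structure(list(summary = agg, replicates = reps, seed = seed),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("benchmark_report (seed", x$seed, "):\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}
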