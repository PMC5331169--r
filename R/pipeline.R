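#' End-to-end biomarker identification
#'
#' Runs the full pipeline on a two-group metabolite matrix with missing
#' values and possible outlier cells: groupwise robust-SVD reconstruction,
#' pooled t-test + Bonferroni + fold-change DE calling, SVM recursive
#' feature elimination ranking of the DE set, panel selection, and
#' stratified cross-validated SVM classification of the samples on the
#' panel.
#'
#' @param x a [metabolite_matrix] (or numeric matrix with `NA` missing
#'   cells).
#' @param design a [group_design]; level 1 = control, level 2 = disease.
#' @param alpha familywise level for the Bonferroni threshold (also the
#'   explained-variation tail of the rank selection).
#' @param fc_cut fold-change cut-off (default 2).
#' @param log2_data are intensities on the log2 scale (fold change as mean
#'   difference)?
#' @param iqr_k IQR multiplier for outlier flagging.
#' @param n_up,n_down biomarker panel sizes.
#' @param folds cross-validation folds.
#' @param seed integer seed driving every stochastic step.
#' @param max_components components cap for the robust SVD.
#' @return Object of class `biomarker_fit`: list with `reconstruction`
#'   (a `metab_recon`), `de` (a [de_table]), `ranking`, `panel`,
#'   `cv_metrics` (`NULL` when fewer than 2 DE metabolites or a panel
#'   cannot be classified), and the call parameters.
#' @examples
#' sim <- simulate_dataset(sim_config(p = 60, n1 = 12, n2 = 12,
#'                                    up_indices = 1:4, down_indices = 11:14,
#'                                    missing_rate = 0.1, seed = 7))
#' fit <- identify_biomarkers(sim$matrix, sim$design, log2_data = TRUE,
#'                            n_up = 2, n_down = 2, seed = 7)
#' print(fit)
#' @export
identify_biomarkers <- function(x, design, alpha = 0.05, fc_cut = 2,
                                log2_data = FALSE, iqr_k = 1.5,
                                n_up = 4L, n_down = 2L, folds = 5L,
                                seed = 1L, max_components = 10L) {
  recon <- reconstruct_rsvd(x, design, alpha = alpha, iqr_k = iqr_k,
                            max_components = max_components, seed = seed)
  ids <- if (inherits(x, "metabolite_matrix")) x$metabolite_ids else rownames(recon$reconstructed)
  mz <- if (inherits(x, "metabolite_matrix")) x$mz else NULL
  rt <- if (inherits(x, "metabolite_matrix")) x$rt else NULL
  de <- de_table(recon$reconstructed, design, alpha = alpha, fc_cut = fc_cut,
                 log2_data = log2_data, metabolite_ids = ids, mz = mz, rt = rt)
  out <- list(reconstruction = recon, de = de, ranking = NULL, panel = NULL,
              cv_metrics = NULL,
              params = list(alpha = alpha, fc_cut = fc_cut,
                            log2_data = log2_data, iqr_k = iqr_k,
                            n_up = n_up, n_down = n_down, folds = folds,
                            seed = seed))
  class(out) <- "biomarker_fit"
  de_idx <- which(de$is_de)
  if (length(de_idx) < 2L) {
    message("fewer than 2 DE metabolites (", length(de_idx),
            "); stopping after the DE stage")
    return(out)
  }
  xde <- recon$reconstructed[de_idx, , drop = FALSE]
  rownames(xde) <- ids[de_idx]
  out$ranking <- svm_rank(xde, design, seed = seed,
                          direction = de$direction[de_idx])
  out$panel <- tryCatch(
    withCallingHandlers(select_panel(out$ranking, n_up = n_up, n_down = n_down),
                        warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  panel_ids <- c(out$panel$up_markers, out$panel$down_markers)
  if (length(panel_ids) >= 1L) {
    xp <- recon$reconstructed[match(panel_ids, ids), , drop = FALSE]
    rownames(xp) <- panel_ids
    out$cv_metrics <- tryCatch(
      crossval_classify(xp, design, folds = folds, seed = seed),
      error = function(e) NULL)
  }
  out
}

#' @export
print.biomarker_fit <- function(x, ...) {
  cat("Robust metabolomic biomarker identification\n")
  print(x$reconstruction)
  print(x$de)
  if (!is.null(x$panel)) print(x$panel)
  if (!is.null(x$cv_metrics)) print(x$cv_metrics)
  invisible(x)
}

#' @export
summary.biomarker_fit <- function(object, ...) {
  res <- list(n_de = sum(object$de$is_de),
              n_up = sum(object$de$direction == "up"),
              n_down = sum(object$de$direction == "down"),
              ranks = object$reconstruction$ranks,
              panel = object$panel,
              cv = object$cv_metrics)
  print(object)
  invisible(res)
}
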