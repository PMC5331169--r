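#' Pooled-variance two-sample t-test per metabolite
#'
#' Classical Student's t with pooled variance and `n - 2` degrees of
#' freedom, computed row-wise on a complete matrix. The statistic is
#' `(mean(group1) - mean(group2)) / SE`, so swapping the groups negates it.
#' Degenerate rows (zero pooled variance) give `t = 0, p = 1` when the
#' means agree and `p = 0` with a warning when they do not.
#'
#' @param xhat complete numeric matrix (metabolites x samples).
#' @param design a [group_design] aligned with the columns.
#' @return List with numeric vectors `t_stat` and `p_value`.
#' @export
two_sample_t <- function(xhat, design) {
  xhat <- as.matrix(xhat)
  if (anyNA(xhat)) stop("matrix must be complete (no NA); impute/reconstruct first")
  lev <- levels(design$labels)
  i1 <- design$labels == lev[1L]
  i2 <- design$labels == lev[2L]
  n1 <- sum(i1)
  n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples")
  x1 <- xhat[, i1, drop = FALSE]
  x2 <- xhat[, i2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_stat <- (m1 - m2) / se
  df <- n1 + n2 - 2L
  p_value <- 2 * pt(abs(t_stat), df = df, lower.tail = FALSE)
  degen <- se == 0
  if (any(degen)) {
    same <- degen & (m1 == m2)
    t_stat[same] <- 0
    p_value[same] <- 1
    bad <- degen & (m1 != m2)
    if (any(bad)) {
      warning(sum(bad), " row(s) have zero pooled variance with unequal means")
      t_stat[bad] <- sign(m1[bad] - m2[bad]) * Inf
      p_value[bad] <- 0
    }
  }
  list(t_stat = t_stat, p_value = p_value)
}

#' Fold change per metabolite
#'
#' Fold change is oriented disease over control: `FC = mean(group2) /
#' mean(group1)`, so `log2 FC > 0` means higher abundance in the disease
#' group. On raw-scale intensities the log fold change is `log2(FC)` and is
#' undefined (set `NA`, with a warning) when either group mean is
#' non-positive — such rows are excluded from fold-change-based filtering.
#' With `log2_data = TRUE` the matrix is taken as log2-scale abundances, so
#' `log2_fc` is the plain difference of group means and `FC = 2^log2_fc`;
#' this is the right convention for log-transformed or ANOVA-scale data.
#'
#' @param xhat complete numeric matrix.
#' @param design a [group_design]; level 1 = control, level 2 = disease.
#' @param log2_data are the intensities already on the log2 scale?
#' @return List with `fold_change`, `log2_fc` and `fc_defined` (logical).
#' @export
fold_change <- function(xhat, design, log2_data = FALSE) {
  xhat <- as.matrix(xhat)
  lev <- levels(design$labels)
  m1 <- rowMeans(xhat[, design$labels == lev[1L], drop = FALSE])
  m2 <- rowMeans(xhat[, design$labels == lev[2L], drop = FALSE])
  if (log2_data) {
    log2_fc <- m2 - m1
    return(list(fold_change = 2^log2_fc, log2_fc = log2_fc,
                fc_defined = rep(TRUE, length(m1))))
  }
  ok <- m1 > 0 & m2 > 0
  fc <- ifelse(ok, m2 / m1, NA_real_)
  log2_fc <- ifelse(ok, log2(fc), NA_real_)
  if (any(!ok))
    warning(sum(!ok), " row(s) have a non-positive group mean; ",
            "fold change undefined there")
  list(fold_change = fc, log2_fc = log2_fc, fc_defined = ok)
}

#' Call differentially expressed metabolites
#'
#' A metabolite is called DE when its p value passes the Bonferroni
#' threshold `alpha / p` and its absolute fold change passes the cut
#' (`|log2 FC| >= log2(fc_cut)`). Direction follows the sign of the log
#' fold change. Rows with undefined fold change are never called.
#'
#' @param p_values,log2_fc aligned numeric vectors, one entry per
#'   metabolite.
#' @param alpha familywise error level (default 0.05).
#' @param fc_cut fold-change cut-off (default 2, i.e. `|log2 FC| >= 1`).
#' @return Data frame with `p_value`, `log2_fc`, `is_de`, `direction`
#'   (`"up"`, `"down"`, `"none"`); the Bonferroni threshold is attached as
#'   attribute `bonferroni_threshold`.
#' @export
call_de <- function(p_values, log2_fc, alpha = 0.05, fc_cut = 2) {
  if (length(p_values) != length(log2_fc))
    stop("p_values and log2_fc must be aligned")
  if (fc_cut <= 0) stop("fc_cut must be positive")
  thr <- alpha / length(p_values)
  is_de <- !is.na(log2_fc) & p_values <= thr & abs(log2_fc) >= log2(fc_cut)
  direction <- rep("none", length(p_values))
  direction[is_de & log2_fc > 0] <- "up"
  direction[is_de & log2_fc < 0] <- "down"
  structure(data.frame(p_value = p_values, log2_fc = log2_fc,
                       is_de = is_de, direction = direction,
                       stringsAsFactors = FALSE),
            bonferroni_threshold = thr)
}

#' Differential-expression table
#'
#' Convenience wrapper running [two_sample_t()], [fold_change()] and
#' [call_de()] on a reconstructed (complete) matrix.
#'
#' @inheritParams two_sample_t
#' @inheritParams fold_change
#' @inheritParams call_de
#' @param metabolite_ids optional row identifiers.
#' @param mz,rt optional per-metabolite annotations carried into the table.
#' @return Data frame (class `de_table`) with columns `metabolite_id`,
#'   `mz`, `rt`, `t_stat`, `p_value`, `fold_change`, `log2_fc`,
#'   `direction`, `is_de`; Bonferroni threshold as attribute
#'   `bonferroni_threshold`.
#' @export
de_table <- function(xhat, design, alpha = 0.05, fc_cut = 2,
                     log2_data = FALSE, metabolite_ids = rownames(xhat),
                     mz = NULL, rt = NULL) {
  if (inherits(xhat, "metab_recon")) xhat <- xhat$reconstructed
  xhat <- as.matrix(xhat)
  tt <- two_sample_t(xhat, design)
  fc <- fold_change(xhat, design, log2_data = log2_data)
  calls <- call_de(tt$p_value, fc$log2_fc, alpha = alpha, fc_cut = fc_cut)
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("m", seq_len(nrow(xhat)))
  out <- data.frame(metabolite_id = metabolite_ids,
                    mz = if (is.null(mz)) NA_real_ else mz,
                    rt = if (is.null(rt)) NA_real_ else rt,
                    t_stat = tt$t_stat, p_value = tt$p_value,
                    fold_change = fc$fold_change, log2_fc = fc$log2_fc,
                    direction = calls$direction, is_de = calls$is_de,
                    stringsAsFactors = FALSE)
  attr(out, "bonferroni_threshold") <- attr(calls, "bonferroni_threshold")
  class(out) <- c("de_table", "data.frame")
  out
}

#' @export
print.de_table <- function(x, ...) {
  cat("de_table:", nrow(x), "metabolites,", sum(x$is_de), "called DE (",
      sum(x$direction == "up"), "up,", sum(x$direction == "down"),
      "down); Bonferroni threshold",
      signif(attr(x, "bonferroni_threshold"), 3), "\n")
  if (any(x$is_de)) print(head(as.data.frame(x[x$is_de, ]), 10), row.names = FALSE)
  invisible(x)
}

#' Volcano-plot table
#'
#' Per-metabolite `(log2_fc, -log10 p)` coordinates with the DE call, in
#' input order, ready for plotting or export.
#'
#' @param de a [de_table].
#' @return Data frame with `metabolite_id`, `log2_fc`, `neg_log10_p`,
#'   `is_de`, `direction`.
#' @export
volcano_table <- function(de) {
  data.frame(metabolite_id = de$metabolite_id, log2_fc = de$log2_fc,
             neg_log10_p = -log10(de$p_value), is_de = de$is_de,
             direction = de$direction, stringsAsFactors = FALSE)
}
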