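#' Simulation configuration
#'
#' Parameters of the synthetic two-group metabolomics generator: a one-way
#' ANOVA intensity model `y = mu_i + g + e` on the log2-abundance scale,
#' with per-metabolite baselines `mu_i ~ U(mu_low, mu_high)`, per-cell
#' group effects `g ~ N(effect, 1)` (effect = `effect_mean` in the elevated
#' group of a DE metabolite, 0 otherwise) and noise `e ~ N(0, noise_sd^2)`.
#' Defaults give 500 metabolites (rows 1-15 upregulated, 121-135
#' downregulated, 470 equally expressed) and 80 samples (45 control + 35
#' disease).
#'
#' @param p metabolite count.
#' @param n1,n2 control and disease sample counts.
#' @param up_indices,down_indices row indices of up-/downregulated
#'   metabolites (disjoint).
#' @param mu_low,mu_high uniform bounds of the baseline intensity.
#' @param effect_mean mean group effect of a DE metabolite in its elevated
#'   group.
#' @param noise_sd error standard deviation.
#' @param missing_rate fraction of cells set missing.
#' @param random_missing_fraction share of the missing cells assigned
#'   completely at random; the rest go to the lowest-valued cells
#'   (detection-limit missingness).
#' @param outlier_rate fraction of cells replaced by outliers.
#' @param outlier_mean_multiplier outlier cells in row i are drawn from
#'   `N(multiplier * mu_i, sigma_i^2)` with `mu_i`, `sigma_i^2` the clean
#'   row mean and variance.
#' @param seed integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(p = 500L, n1 = 45L, n2 = 35L,
                       up_indices = 1:15, down_indices = 121:135,
                       mu_low = 4, mu_high = 8, effect_mean = 2,
                       noise_sd = 1, missing_rate = 0.10,
                       random_missing_fraction = 0.5, outlier_rate = 0,
                       outlier_mean_multiplier = 5, seed = 1L) {
  if (length(intersect(up_indices, down_indices)))
    stop("up_indices and down_indices must be disjoint")
  if (length(up_indices) && max(up_indices) > p) stop("up_indices exceed p")
  if (length(down_indices) && max(down_indices) > p) stop("down_indices exceed p")
  if (missing_rate < 0 || missing_rate >= 1 || outlier_rate < 0 || outlier_rate >= 1)
    stop("rates must be in [0, 1)")
  if (missing_rate + outlier_rate >= 1)
    stop("missing_rate + outlier_rate must be below 1")
  if (random_missing_fraction < 0 || random_missing_fraction > 1)
    stop("random_missing_fraction must be in [0, 1]")
  structure(list(p = as.integer(p), n1 = as.integer(n1), n2 = as.integer(n2),
                 up_indices = up_indices, down_indices = down_indices,
                 mu_low = mu_low, mu_high = mu_high,
                 effect_mean = effect_mean, noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 random_missing_fraction = random_missing_fraction,
                 outlier_rate = outlier_rate,
                 outlier_mean_multiplier = outlier_mean_multiplier,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a clean (uncontaminated, complete) dataset
#'
#' Draws the ANOVA model of [sim_config()]. Columns are ordered control
#' first, disease second. Uses the current RNG state when `use_seed =
#' FALSE` (so composite generators can manage one stream).
#'
#' @param config a [sim_config].
#' @param use_seed set the RNG from `config$seed` first?
#' @return List with `clean` (p x n matrix), `de_labels` (`"up"`,
#'   `"down"`, `"ee"` per row), `mu` (baselines), `design` (a
#'   [group_design]).
#' @export
simulate_clean <- function(config, use_seed = TRUE) {
  if (use_seed) set.seed(config$seed)
  p <- config$p
  n1 <- config$n1
  n2 <- config$n2
  n <- n1 + n2
  mu <- runif(p, config$mu_low, config$mu_high)
  de_labels <- rep("ee", p)
  de_labels[config$up_indices] <- "up"
  de_labels[config$down_indices] <- "down"
  # per-(row, group) effect means; the effect itself is drawn per cell
  eff1 <- ifelse(de_labels == "down", config$effect_mean, 0)  # control
  eff2 <- ifelse(de_labels == "up", config$effect_mean, 0)    # disease
  g <- cbind(matrix(rnorm(p * n1, mean = eff1, sd = 1), p, n1),
             matrix(rnorm(p * n2, mean = eff2, sd = 1), p, n2))
  eps <- matrix(rnorm(p * n, sd = config$noise_sd), p, n)
  clean <- mu + g + eps
  rownames(clean) <- paste0("m", seq_len(p))
  colnames(clean) <- c(paste0("ctrl", seq_len(n1)), paste0("dis", seq_len(n2)))
  design <- group_design(rep(c("control", "disease"), c(n1, n2)),
                         levels = c("control", "disease"),
                         sample_ids = colnames(clean))
  list(clean = clean, de_labels = de_labels, mu = mu, design = design)
}

#' Contaminate a matrix with outlier cells
#'
#' Replaces `ceiling(rate * p * n)` uniformly chosen cells of row i by
#' draws from `N(multiplier * mu_i, sigma_i^2)`, where `mu_i` and
#' `sigma_i^2` are the mean and variance of the clean row.
#'
#' @param clean complete numeric matrix (pre-contamination).
#' @param rate fraction of cells to contaminate, below 1.
#' @param multiplier outlier mean multiplier (default 5).
#' @param seed optional seed (`NULL` = use current RNG state).
#' @return List with `matrix` (contaminated) and `outlier_mask`.
#' @export
inject_outliers <- function(clean, rate, multiplier = 5, seed = NULL) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(clean)
  n <- ncol(clean)
  mask <- matrix(FALSE, p, n)
  if (rate == 0) return(list(matrix = clean, outlier_mask = mask))
  m <- ceiling(rate * p * n)
  cells <- sample.int(p * n, m)
  mask[cells] <- TRUE
  row_mu <- rowMeans(clean)
  row_sd <- apply(clean, 1L, sd)
  rows <- (cells - 1L) %% p + 1L
  out <- clean
  out[cells] <- rnorm(m, mean = multiplier * row_mu[rows], sd = row_sd[rows])
  list(matrix = out, outlier_mask = mask)
}

#' Set cells missing (half at random, half at the lowest values)
#'
#' Of the `ceiling(rate * p * n)` missing cells, a `random_fraction` share
#' is chosen uniformly at random among eligible cells and the remainder is
#' assigned to the globally lowest-valued still-unselected cells —
#' emulating detection-limit missingness of mass-spectrometry data. With
#' `per_row = TRUE` the low-value half is instead spread over rows
#' (lowest cells of each row in turn).
#'
#' @param x numeric matrix (possibly already contaminated).
#' @param rate fraction of cells set missing.
#' @param random_fraction share of missing cells assigned at random.
#' @param exclude logical mask of cells never selected (e.g. outlier
#'   cells, to keep the two mechanisms disjoint).
#' @param seed optional seed (`NULL` = current RNG state).
#' @param per_row use per-row lowest values instead of global ones.
#' @return List with `matrix` (`NA` at missing cells) and `missing_mask`.
#' @export
inject_missing <- function(x, rate, random_fraction = 0.5, exclude = NULL,
                           seed = NULL, per_row = FALSE) {
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(x)
  n <- ncol(x)
  mask <- matrix(FALSE, p, n)
  if (rate == 0) return(list(matrix = x, missing_mask = mask))
  if (is.null(exclude)) exclude <- matrix(FALSE, p, n)
  m <- ceiling(rate * p * n)
  n_rand <- ceiling(random_fraction * m)
  eligible <- which(!exclude)
  if (length(eligible) < m) stop("not enough eligible cells")
  rand_cells <- sample(eligible, n_rand)
  mask[rand_cells] <- TRUE
  n_low <- m - n_rand
  if (n_low > 0L) {
    left <- setdiff(eligible, rand_cells)
    if (per_row) {
      # round-robin over rows by ascending value within row
      rows <- (left - 1L) %% p + 1L
      by_row <- split(left[order(x[left])], rows[order(x[left])])
      picked <- integer(0)
      while (length(picked) < n_low) {
        take <- vapply(by_row[lengths(by_row) > 0L], `[`, 0L, 1L)
        picked <- c(picked, take)
        by_row <- lapply(by_row, function(v) v[-1L])
      }
      mask[picked[seq_len(n_low)]] <- TRUE
    } else {
      low_cells <- left[order(x[left])][seq_len(n_low)]
      mask[low_cells] <- TRUE
    }
  }
  x[mask] <- NA_real_
  list(matrix = x, missing_mask = mask)
}

#' Simulate a contaminated two-group metabolomics dataset
#'
#' Composes [simulate_clean()], [inject_outliers()] and [inject_missing()]
#' under one seeded RNG stream; missing selection excludes outlier cells,
#' so the two masks are disjoint.
#'
#' @param config a [sim_config].
#' @return List with `matrix` (a [metabolite_matrix] carrying the `NA`
#'   missing cells), `clean`, `de_labels`, `mu`, `design`,
#'   `missing_mask`, `outlier_mask`.
#' @export
simulate_dataset <- function(config) {
  truth <- simulate_clean(config, use_seed = TRUE)
  contam <- inject_outliers(truth$clean, config$outlier_rate,
                            config$outlier_mean_multiplier)
  miss <- inject_missing(contam$matrix, config$missing_rate,
                         config$random_missing_fraction,
                         exclude = contam$outlier_mask)
  mm <- metabolite_matrix(miss$matrix)
  list(matrix = mm, clean = truth$clean, de_labels = truth$de_labels,
       mu = truth$mu, design = truth$design,
       missing_mask = miss$missing_mask, outlier_mask = contam$outlier_mask,
       config = config)
}
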