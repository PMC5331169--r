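#' Construct a metabolite intensity matrix
#'
#' The basic data container of the package: a real-valued matrix with
#' metabolites in rows and samples in columns, a logical mask of missing
#' cells, per-row metabolite identifiers and optional mass-to-charge (m/z)
#' and retention-time annotations.
#'
#' Missing cells are stored as `NA` in `values`; downstream computations
#' never read them.
#'
#' @param values numeric matrix, p metabolites x n samples. `NA` entries are
#'   taken as missing.
#' @param missing_mask logical matrix of the same shape, `TRUE` = missing.
#'   Defaults to `is.na(values)`.
#' @param metabolite_ids character vector of p unique row identifiers.
#' @param sample_ids character vector of n unique column identifiers.
#' @param mz,rt optional numeric vectors of length p (mass-to-charge ratio,
#'   retention time in minutes).
#' @return An object of class `metabolite_matrix`: a list with elements
#'   `values`, `missing_mask`, `metabolite_ids`, `sample_ids`, `mz`, `rt`.
#' @export
metabolite_matrix <- function(values, missing_mask = is.na(values),
                              metabolite_ids = rownames(values),
                              sample_ids = colnames(values),
                              mz = NULL, rt = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  p <- nrow(values)
  n <- ncol(values)
  if (p < 2L || n < 2L)
    stop("need at least 2 metabolites and 2 samples, got ", p, " x ", n)
  if (!identical(dim(missing_mask), dim(values)))
    stop("missing_mask shape does not match values")
  missing_mask <- missing_mask | is.na(values)
  values[missing_mask] <- NA_real_
  if (is.null(metabolite_ids)) metabolite_ids <- paste0("m", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  metabolite_ids <- as.character(metabolite_ids)
  sample_ids <- as.character(sample_ids)
  if (length(metabolite_ids) != p) stop("metabolite_ids length must equal nrow")
  if (length(sample_ids) != n) stop("sample_ids length must equal ncol")
  if (anyDuplicated(metabolite_ids))
    stop("duplicate metabolite ids: ",
         paste(unique(metabolite_ids[duplicated(metabolite_ids)]), collapse = ", "))
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  if (!is.null(mz) && length(mz) != p) stop("mz length must equal nrow")
  if (!is.null(rt) && length(rt) != p) stop("rt length must equal nrow")
  dimnames(values) <- list(metabolite_ids, sample_ids)
  dimnames(missing_mask) <- dimnames(values)
  structure(list(values = values, missing_mask = missing_mask,
                 metabolite_ids = metabolite_ids, sample_ids = sample_ids,
                 mz = mz, rt = rt),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat("metabolite_matrix:", nrow(x$values), "metabolites x",
      ncol(x$values), "samples;",
      sum(x$missing_mask), "missing cells (",
      sprintf("%.1f%%", 100 * mean(x$missing_mask)), ")\n")
  invisible(x)
}

#' @export
dim.metabolite_matrix <- function(x) dim(x$values)

#' Read a metabolite intensity matrix from a delimited text file
#'
#' Two layouts are supported. `generic`: the first column holds the
#' metabolite identifier and the remaining columns are samples. `hcc`: the
#' first two columns hold retention time (rt) and mass-to-charge ratio
#' (m/z) — the layout of UPLC-MS feature tables where each row is a feature
#' keyed by its (rt, m/z) pair — and the remaining columns are samples.
#'
#' @param path file path. Delimiter is tab for `.tsv`/`.txt`, comma
#'   otherwise; override with `sep`.
#' @param layout `"generic"` or `"hcc"`.
#' @param na_tokens strings parsed as missing (in addition to empty cells).
#' @param sep field delimiter; `NULL` = infer from extension.
#' @return A [metabolite_matrix].
#' @export
read_metabolite_matrix <- function(path, layout = c("generic", "hcc"),
                                   na_tokens = c("", "NA", "NaN", "na"),
                                   sep = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("file has no data rows: ", path)
  # sentinel keeps trailing empty fields, which strsplit would drop
  fields <- lapply(strsplit(paste0(lines, sep, "\x01"), sep, fixed = TRUE),
                   function(f) f[-length(f)])
  ncol_header <- length(fields[[1L]])
  bad <- which(vapply(fields, length, 1L) != ncol_header)
  if (length(bad))
    stop("malformed row: line ", bad[1L], " has ", length(fields[[bad[1L]]]),
         " fields, header has ", ncol_header)
  header <- trimws(fields[[1L]])
  body <- fields[-1L]
  n_id_cols <- if (layout == "hcc") 2L else 1L
  if (ncol_header <= n_id_cols) stop("no sample columns in ", path)
  parse_num <- function(x) {
    x <- trimws(x)
    x[x %in% na_tokens] <- NA
    suppressWarnings(as.numeric(x))
  }
  cells <- t(vapply(body, function(f) parse_num(f[-seq_len(n_id_cols)]),
                    numeric(ncol_header - n_id_cols)))
  sample_ids <- header[-seq_len(n_id_cols)]
  if (layout == "hcc") {
    rt <- as.numeric(vapply(body, `[`, "", 1L))
    mz <- as.numeric(vapply(body, `[`, "", 2L))
    ids <- paste0("mz", mz, "_rt", rt)
  } else {
    rt <- NULL
    mz <- NULL
    ids <- vapply(body, `[`, "", 1L)
  }
  metabolite_matrix(cells, metabolite_ids = ids, sample_ids = sample_ids,
                    mz = mz, rt = rt)
}

#' Write a result table to CSV
#'
#' Plain CSV with a header row; numeric columns keep full double precision
#' (15 significant digits), so a write/read round trip is lossless well past
#' 12 significant digits.
#'
#' @param records data frame (may have zero rows).
#' @param path output file path.
#' @export
write_result_table <- function(records, path) {
  records <- as.data.frame(records)
  out <- records
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 15, trim = TRUE, scientific = NA))
  })
  tryCatch(write.csv(out, path, row.names = FALSE, quote = FALSE, na = ""),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Two-group sample design
#'
#' @param labels per-sample group labels (character or factor with exactly
#'   two levels). The first level is group 1 (control), the second group 2
#'   (disease).
#' @param levels optional explicit level order `c(group1, group2)`.
#' @param sample_ids optional sample identifiers aligned with `labels`.
#' @return An object of class `group_design` with elements `labels`
#'   (factor), `g1` (group-1 count), `sample_ids`.
#' @export
group_design <- function(labels, levels = NULL, sample_ids = NULL) {
  if (is.null(levels)) {
    labels <- as.factor(as.character(labels))
  } else {
    labels <- factor(as.character(labels), levels = levels)
    if (anyNA(labels)) stop("labels contain values outside the given levels")
  }
  if (nlevels(labels) != 2L)
    stop("design must have exactly two groups, got ", nlevels(labels))
  if (any(table(labels) == 0L)) stop("both groups must be non-empty")
  if (!is.null(sample_ids) && length(sample_ids) != length(labels))
    stop("sample_ids length must match labels")
  structure(list(labels = labels, g1 = sum(labels == base::levels(labels)[1L]),
                 sample_ids = sample_ids),
            class = "group_design")
}

#' @export
print.group_design <- function(x, ...) {
  tab <- table(x$labels)
  cat("group_design:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Read a two-column sample design file
#'
#' Expects a CSV with header `sample_id,group`. Rows are reordered to match
#' `sample_ids` when given, so the file's row order never matters.
#'
#' @param path CSV path.
#' @param sample_ids optional sample id order to align to (e.g. the matrix
#'   column order).
#' @param levels optional group level order `c(group1, group2)`.
#' @return A [group_design].
#' @export
read_group_design <- function(path, sample_ids = NULL, levels = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("design file must have columns sample_id, group")
  if (!is.null(sample_ids)) {
    idx <- match(sample_ids, df$sample_id)
    if (anyNA(idx))
      stop("design file is missing samples: ",
           paste(sample_ids[is.na(idx)], collapse = ", "))
    df <- df[idx, ]
  }
  group_design(df$group, levels = levels, sample_ids = df$sample_id)
}

#' Classification rates from a confusion matrix
#'
#' True-positive rate `nTP / (nTP + nFN)` and false-positive rate
#' `nFP / (nTN + nFP)`.
#'
#' @param nTP,nFP,nTN,nFN non-negative counts.
#' @return Named numeric vector `c(tpr =, fpr =)`.
#' @export
confusion_rates <- function(nTP, nFP, nTN, nFN) {
  counts <- c(nTP = nTP, nFP = nFP, nTN = nTN, nFN = nFN)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers")
  if (nTP + nFN == 0) stop("no positive instances: nTP + nFN is zero")
  if (nTN + nFP == 0) stop("no negative instances: nTN + nFP is zero")
  c(tpr = nTP / (nTP + nFN), fpr = nFP / (nTN + nFP))
}
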