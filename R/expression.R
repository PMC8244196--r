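#' Read a sample sheet
#'
#' A sample sheet assigns each expression column to the `control` or
#' `treatment` group. Two samples per group is the hard minimum for a
#' two-group comparison; three or more per group is recommended.
#'
#' @param path Path to a TSV file with columns `sample_id` and `group`.
#' @return A data frame with columns `sample_id` (character) and `group`
#'   (factor with levels `control`, `treatment`).
#' @export
read_sample_sheet <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_sheet(df)
}

#' Validate a sample sheet data frame
#'
#' @param df Data frame with columns `sample_id` and `group`.
#' @return The validated sheet, `group` coerced to a control/treatment factor.
#' @export
validate_sample_sheet <- function(df) {
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("sample sheet needs columns 'sample_id' and 'group'")
  }
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(df$group), c("control", "treatment"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  df$group <- factor(df$group, levels = c("control", "treatment"))
  n <- table(df$group)
  if (any(n < 2)) {
    stop("need at least 2 samples per group (got control=", n[["control"]],
         ", treatment=", n[["treatment"]], "); >=3 per group recommended")
  }
  df[, c("sample_id", "group")]
}

#' Construct an expression matrix object
#'
#' @param values Numeric matrix, rows = probes or genes, columns = samples.
#' @param scale One of `"counts"`, `"intensity"`, `"log2"`.
#' @param sheet A validated sample sheet covering the columns.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `scale` and `sheet`.
#' @export
expr_matrix <- function(values, scale, sheet) {
  scale <- match.arg(scale, c("counts", "intensity", "log2"))
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have row ids and sample column names")
  }
  if (anyDuplicated(colnames(values))) stop("duplicate sample columns")
  if (any(!is.finite(values))) stop("non-finite expression values")
  sheet <- validate_sample_sheet(sheet)
  missing <- setdiff(sheet$sample_id, colnames(values))
  if (length(missing)) {
    stop("sample(s) in sheet absent from matrix: ", paste(missing, collapse = ", "))
  }
  values <- values[, sheet$sample_id, drop = FALSE]
  if (scale == "counts") {
    if (any(values < 0) || any(values != round(values))) {
      stop("scale='counts' requires non-negative integer values")
    }
  }
  structure(list(values = values, scale = scale, sheet = sheet),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d rows x %d samples (%d control, %d treatment), scale=%s\n",
              nrow(x$values), ncol(x$values),
              sum(x$sheet$group == "control"), sum(x$sheet$group == "treatment"),
              x$scale))
  invisible(x)
}

#' Read an expression matrix from TSV
#'
#' The file layout is: first column = probe/gene id, header = sample ids,
#' tab-separated. Columns are restricted and reordered to the sample sheet.
#' When `scale` is omitted it is inferred: an all-integer matrix is treated
#' as counts, otherwise as (linear) intensity.
#'
#' @param path TSV path.
#' @param sheet Sample sheet (data frame or path).
#' @param scale Optional explicit scale tag.
#' @return An `expr_matrix`.
#' @export
read_expression <- function(path, sheet, scale = NULL) {
  stopifnot(file.exists(path))
  if (is.character(sheet)) sheet <- read_sample_sheet(sheet)
  sheet <- validate_sample_sheet(sheet)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) stop("expression TSV needs an id column plus sample columns")
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  missing <- setdiff(sheet$sample_id, colnames(vals))
  if (length(missing)) {
    stop("sample(s) missing from expression file: ", paste(missing, collapse = ", "))
  }
  vals <- vals[, sheet$sample_id, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      if (anyNA(num)) {
        i <- which(is.na(num))[1]
        stop(sprintf("non-numeric cell at row %d (id '%s'), column '%s'",
                     i, ids[i], colnames(vals)[j]))
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (is.null(scale)) {
    scale <- if (all(m >= 0) && all(m == round(m))) "counts" else "intensity"
  }
  expr_matrix(m, scale, sheet)
}

#' Collapse probe rows to gene rows
#'
#' For each gene the probe with the largest mean expression over all
#' samples is retained (ties broken by lexicographically smallest probe
#' id); probes absent from the map are dropped.
#'
#' @param m An `expr_matrix` whose rows are probes (duplicates allowed).
#' @param probe_map Data frame with columns `probe` and `gene`.
#' @return An `expr_matrix` with one row per gene.
#' @export
collapse_probes <- function(m, probe_map) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(probe_map) || nrow(probe_map) == 0) stop("empty probe_map")
  if (!all(c("probe", "gene") %in% names(probe_map))) {
    stop("probe_map needs columns 'probe' and 'gene'")
  }
  probe_map$probe <- as.character(probe_map$probe)
  probe_map$gene <- toupper(trimws(as.character(probe_map$gene)))
  keep <- rownames(m$values) %in% probe_map$probe
  vals <- m$values[keep, , drop = FALSE]
  if (nrow(vals) == 0) stop("no probes map to genes")
  gene <- probe_map$gene[match(rownames(vals), probe_map$probe)]
  means <- rowMeans(vals)
  # max-mean probe per gene; ties -> lexicographically smallest probe id
  ord <- order(gene, -means, rownames(vals))
  vals <- vals[ord, , drop = FALSE]
  gene <- gene[ord]
  sel <- !duplicated(gene)
  out <- vals[sel, , drop = FALSE]
  rownames(out) <- gene[sel]
  out <- out[order(rownames(out)), , drop = FALSE]
  expr_matrix(out, m$scale, m$sheet)
}

#' Filter low-count genes from an RNA-seq count matrix
#'
#' Keeps genes with above-zero counts in at least two samples within the
#' control group or at least two samples within the treatment group.
#'
#' @param m An `expr_matrix` with `scale = "counts"`.
#' @return The filtered `expr_matrix`.
#' @export
filter_low_counts <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "counts") stop("filter_low_counts requires a count matrix")
  ctrl <- m$sheet$sample_id[m$sheet$group == "control"]
  trt <- m$sheet$sample_id[m$sheet$group == "treatment"]
  nz_ctrl <- rowSums(m$values[, ctrl, drop = FALSE] > 0)
  nz_trt <- rowSums(m$values[, trt, drop = FALSE] > 0)
  keep <- nz_ctrl >= 2 | nz_trt >= 2
  expr_matrix(m$values[keep, , drop = FALSE], "counts", m$sheet)
}

#' Log2-transform an expression matrix
#'
#' Counts become `log2(x + 1)`; linear intensities become `log2(max(x, 1))`
#' (a floor of 1 guards against negative logs from background-subtracted
#' values). A matrix already on the log2 scale passes through with a
#' warning.
#'
#' @param m An `expr_matrix`.
#' @return The matrix with `scale = "log2"`.
#' @export
log2_normalize <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale == "log2") {
    warning("matrix already on log2 scale; returning unchanged")
    return(m)
  }
  vals <- if (m$scale == "counts") log2(m$values + 1) else log2(pmax(m$values, 1))
  expr_matrix(vals, "log2", m$sheet)
}

#' PCA quality screen of sample grouping
#'
#' Projects samples onto the first two principal components of the
#' top-variance genes and flags whether control and treatment samples
#' separate: the distance between the two group centroids must exceed the
#' larger of the two within-group mean distances to the own centroid. The
#' flag is advisory and never blocks the pipeline.
#'
#' @param m A log2-scale `expr_matrix` with at least 3 samples.
#' @param n_top Number of top-variance genes used (default 500; capped at
#'   the number of rows).
#' @return A list with `coords` (data frame: sample_id, group, PC1, PC2),
#'   `separated` (logical) and the centroid distances used for the call.
#' @export
pca_qc <- function(m, n_top = 500) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$scale != "log2") stop("pca_qc expects a log2-scale matrix")
  if (ncol(m$values) < 3) stop("pca_qc needs at least 3 samples")
  v <- apply(m$values, 1, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(min(n_top, nrow(m$values)))]
  x <- t(m$values[top, , drop = FALSE])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 2)
  co <- pc$x[, 1:2, drop = FALSE]
  if (ncol(co) < 2) co <- cbind(co, PC2 = 0)
  coords <- data.frame(sample_id = m$sheet$sample_id, group = m$sheet$group,
                       PC1 = co[, 1], PC2 = co[, 2], row.names = NULL)
  cent <- function(g) colMeans(co[m$sheet$group == g, , drop = FALSE])
  cc <- cent("control"); ct <- cent("treatment")
  between <- sqrt(sum((cc - ct)^2))
  within <- function(g, ce) {
    rows <- co[m$sheet$group == g, , drop = FALSE]
    mean(sqrt(rowSums((rows - matrix(ce, nrow(rows), 2, byrow = TRUE))^2)))
  }
  w_ctrl <- within("control", cc)
  w_trt <- within("treatment", ct)
  list(coords = coords, separated = between > max(w_ctrl, w_trt),
       between_centroid = between, within_control = w_ctrl,
       within_treatment = w_trt)
}
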