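#' Two-class expression datasets
#'
#' A genes-by-samples expression matrix with a binary post-MI outcome label
#' per sample. Labels follow the ejection-fraction (EF) rule when EF values
#' are present: `good` iff EF > 40 (%), `poor` iff EF <= 40. Missing values
#' in the matrix are disallowed (fail fast; no imputation policy is
#' assumed).
#'
#' @param matrix numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names.
#' @param labels character/factor vector of `"good"`/`"poor"`, named by
#'   sample or in column order. May be omitted when `ef` is given.
#' @param ef optional numeric vector of ejection fractions (percent), named
#'   by sample or in column order; when both `labels` and `ef` are present
#'   they must agree with the 40% rule.
#' @return An object of class `expression_dataset` with components
#'   `matrix`, `genes`, `samples`, `labels` (factor good/poor), `ef`.
#' @export
expression_dataset <- function(matrix, labels = NULL, ef = NULL) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop("`matrix` must be a numeric matrix")
  if (anyNA(matrix)) stop("expression matrix contains missing values")
  genes <- rownames(matrix); samples <- colnames(matrix)
  if (is.null(genes) || is.null(samples))
    stop("matrix must have gene row names and sample column names")
  if (anyDuplicated(genes)) stop("duplicate gene identifiers")
  if (anyDuplicated(samples)) stop("duplicate sample identifiers")
  align <- function(v, what) {
    if (is.null(v)) return(NULL)
    if (!is.null(names(v))) {
      miss <- setdiff(samples, names(v))
      if (length(miss))
        stop(what, " missing for samples: ", paste(head(miss, 5L), collapse = ", "))
      v <- v[samples]
    } else if (length(v) != length(samples)) {
      stop(what, " must have one entry per sample")
    }
    v
  }
  ef <- align(ef, "EF")
  labels <- align(labels, "labels")
  if (is.null(labels)) {
    if (is.null(ef)) stop("either `labels` or `ef` must be given")
    labels <- ifelse(ef > 40, "good", "poor")
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("good", "poor")))
    stop("labels must be 'good' or 'poor'")
  if (!is.null(ef)) {
    implied <- ifelse(ef > 40, "good", "poor")
    if (any(implied != labels))
      stop("labels inconsistent with the EF > 40% rule for samples: ",
           paste(head(samples[implied != labels], 5L), collapse = ", "))
  }
  structure(
    list(matrix = matrix, genes = genes, samples = samples,
         labels = setNames(factor(labels, levels = c("good", "poor")), samples),
         ef = ef),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", length(x$genes), "genes x", length(x$samples),
      "samples (", sum(x$labels == "good"), "good /",
      sum(x$labels == "poor"), "poor )\n")
  invisible(x)
}

#' Read an expression matrix plus phenotype table
#'
#' The matrix file is tab-delimited with genes in rows (first column gene
#' ids) and a header of sample ids. The phenotype file is tab-delimited
#' with a `sample` column and a `label` and/or `ef` column; labels are
#' derived from EF by the 40% rule when absent.
#'
#' @param matrix_path,phenotype_path file paths.
#' @return An [expression_dataset].
#' @export
read_expression <- function(matrix_path, phenotype_path) {
  mt <- read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(mt) < 2L) stop("matrix file needs gene ids plus >= 1 sample column")
  genes <- as.character(mt[[1L]])
  m <- as.matrix(mt[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in expression matrix")
  rownames(m) <- genes
  ph <- read.delim(phenotype_path, stringsAsFactors = FALSE)
  if (!"sample" %in% names(ph)) stop("phenotype file needs a 'sample' column")
  if (!any(c("label", "ef") %in% names(ph)))
    stop("phenotype file needs a 'label' and/or 'ef' column")
  miss <- setdiff(colnames(m), ph$sample)
  if (length(miss))
    stop("samples absent from phenotype file: ",
         paste(head(miss, 5L), collapse = ", "))
  ph <- ph[match(colnames(m), ph$sample), , drop = FALSE]
  expression_dataset(
    m,
    labels = if ("label" %in% names(ph)) setNames(ph$label, ph$sample),
    ef = if ("ef" %in% names(ph)) setNames(ph$ef, ph$sample)
  )
}

#' Write an expression dataset to matrix + phenotype files
#'
#' @param ds an [expression_dataset].
#' @param matrix_path,phenotype_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(ds, matrix_path, phenotype_path) {
  stopifnot(inherits(ds, "expression_dataset"))
  df <- data.frame(gene = ds$genes, ds$matrix, check.names = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- data.frame(sample = ds$samples, label = as.character(ds$labels))
  if (!is.null(ds$ef)) ph$ef <- ds$ef
  write.table(ph, phenotype_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, phenotype_path))
}

#' Mann-Whitney U test (two-sided)
#'
#' `U` is the number of (x, y) pairs with x > y plus half the tied pairs
#' (equivalently the rank-sum statistic of `x`). The exact null
#' distribution is used for `n1 + n2 <= 20` without ties; otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param x,y numeric vectors, both non-empty.
#' @param mode `"auto"`, `"exact"` (error if ties or too large) or
#'   `"approx"`.
#' @return List with `U` (for `x` vs `y`) and `p` (two-sided).
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  exact_ok <- !ties && (n1 + n2) <= 20L
  if (mode == "exact" && !exact_ok)
    stop("exact mode requires no ties and n1 + n2 <= 20")
  use_exact <- switch(mode, exact = TRUE, approx = FALSE, auto = exact_ok)
  if (use_exact) {
    p <- if (U > n1 * n2 / 2)
      2 * (1 - pwilcox(U - 1, n1, n2))
    else
      2 * pwilcox(U, n1, n2)
    p <- min(1, p)
  } else {
    mu <- n1 * n2 / 2
    nt <- table(c(x, y))
    n <- n1 + n2
    tie_term <- sum(nt^3 - nt) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    if (sigma2 <= 0) return(list(U = U, p = 1))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(U = unname(U), p = unname(p))
}

#' Per-gene differential expression scan
#'
#' Two-sided Mann-Whitney test of each gene's expression between good and
#' poor outcome samples. `direction` is the sign of
#' (median poor - median good).
#'
#' @param ds an [expression_dataset] with both classes present.
#' @param genes subset of genes to test (default all).
#' @param adjust add a Benjamini-Hochberg `p_adj` column (default TRUE).
#' @return Data frame with columns `unit`, `u_stat`, `p_nominal`, `p_adj`
#'   (if requested), `direction`.
#' @export
gene_de_scan <- function(ds, genes = NULL, adjust = TRUE) {
  stopifnot(inherits(ds, "expression_dataset"))
  if (is.null(genes)) genes <- ds$genes
  unknown <- setdiff(genes, ds$genes)
  if (length(unknown))
    stop("unknown genes: ", paste(head(unknown, 10L), collapse = ", "))
  good <- ds$labels == "good"
  poor <- ds$labels == "poor"
  if (!any(good) || !any(poor)) stop("both outcome classes must be present")
  res <- lapply(genes, function(g) {
    xg <- ds$matrix[g, good]
    xp <- ds$matrix[g, poor]
    mw <- mann_whitney(xg, xp)
    data.frame(unit = g, u_stat = mw$U, p_nominal = mw$p,
               direction = sign(median(xp) - median(xg)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjust) out$p_adj <- bh_adjust(out$p_nominal)
  out <- out[, c("unit", "u_stat", "p_nominal",
                 if (adjust) "p_adj", "direction")]
  row.names(out) <- NULL
  out
}

#' Per-sample module mean-expression profile
#'
#' Unweighted mean over the module's genes that are present in the
#' dataset; absent genes are dropped, with the dropped count recorded in
#' the `n_dropped` attribute.
#'
#' @param ds an [expression_dataset].
#' @param module_genes character vector of the module's genes (>= 1 with
#'   expression data).
#' @return Numeric vector, one value per sample.
#' @export
module_mean_profile <- function(ds, module_genes) {
  stopifnot(inherits(ds, "expression_dataset"))
  present <- intersect(ds$genes, module_genes)   # dataset order: order-invariant
  if (!length(present))
    stop("no module gene has expression data")
  n_dropped <- length(setdiff(module_genes, ds$genes))
  if (n_dropped)
    message(n_dropped, " module gene(s) without expression data dropped")
  prof <- colMeans(ds$matrix[present, , drop = FALSE])
  attr(prof, "n_dropped") <- n_dropped
  attr(prof, "genes_used") <- present
  prof
}

#' Module-level differential expression
#'
#' For each module with expression coverage, a two-sided Mann-Whitney test
#' of the per-sample module mean-expression profile between outcome
#' classes, Benjamini-Hochberg corrected across modules. The module-mean
#' summary is this package's definition of gene-set differential
#' expression capability.
#'
#' @param ds an [expression_dataset].
#' @param partition a `module_partition` (or named assignment vector).
#' @return Data frame with `unit` (module id), `n_genes_used`, `u_stat`,
#'   `p_nominal`, `p_adj`, `direction`.
#' @export
module_de <- function(ds, partition) {
  stopifnot(inherits(ds, "expression_dataset"))
  assignment <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  if (is.null(names(assignment))) stop("assignment must be named by gene")
  mods <- split(names(assignment), assignment)
  mods <- lapply(mods, intersect, y = ds$genes)
  mods <- mods[lengths(mods) > 0L]
  if (!length(mods)) stop("no module overlaps the expression data")
  good <- ds$labels == "good"
  poor <- ds$labels == "poor"
  res <- lapply(names(mods), function(mid) {
    prof <- suppressMessages(module_mean_profile(ds, mods[[mid]]))
    mw <- mann_whitney(prof[good], prof[poor])
    data.frame(unit = mid, n_genes_used = length(mods[[mid]]),
               u_stat = mw$U, p_nominal = mw$p,
               direction = sign(median(prof[poor]) - median(prof[good])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p_nominal)
  out <- out[, c("unit", "n_genes_used", "u_stat", "p_nominal", "p_adj",
                 "direction")]
  row.names(out) <- NULL
  out
}

#' qPCR Ct tables
#'
#' Cycle-threshold values, samples in rows and genes in columns, with a
#' designated housekeeping reference gene measured in every sample.
#'
#' @param ct numeric matrix of positive Ct values (samples x genes).
#' @param reference_gene column name of the housekeeping gene.
#' @return An object of class `ct_table`.
#' @export
ct_table <- function(ct, reference_gene) {
  if (!is.matrix(ct) || !is.numeric(ct)) stop("`ct` must be a numeric matrix")
  if (is.null(colnames(ct)) || is.null(rownames(ct)))
    stop("`ct` must have sample row names and gene column names")
  if (!reference_gene %in% colnames(ct))
    stop("reference gene '", reference_gene, "' not measured")
  if (anyNA(ct[, reference_gene]))
    stop("reference gene Ct missing for some samples")
  if (any(ct <= 0, na.rm = TRUE)) stop("Ct values must be positive")
  structure(list(ct = ct, reference_gene = reference_gene),
            class = "ct_table")
}

#' Read a Ct table
#'
#' Tab-delimited, samples in rows (first column sample ids), genes in the
#' header.
#'
#' @param path file path.
#' @param reference_gene housekeeping gene column.
#' @return A [ct_table].
#' @export
read_ct <- function(path, reference_gene) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  ct_table(m, reference_gene)
}

#' Relative expression from Ct values
#'
#' `expression(s, g) = 2^(Ct(s, reference) - Ct(s, g))`: one housekeeping
#' gene per assay, so the reference gene's own value is 1 in every sample,
#' and adding a constant to all Cts of a sample leaves its normalized
#' values unchanged.
#'
#' @param ct a [ct_table].
#' @return Numeric matrix of relative expression (samples x genes).
#' @export
pcr_normalize <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  ref <- ct$ct[, ct$reference_gene]
  2^(ref - ct$ct)
}
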