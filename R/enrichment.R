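#' Annotation collections (GMT gene sets)
#'
#' An `annotation_collection` bundles a namespace (GO biological process
#' `"BP"`, cellular component `"CC"`, miRNA target sets `"MIR"`, or
#' `"other"`), a list of term gene sets, and the gene universe the terms
#' live in.
#'
#' @param terms named list of character vectors (term id -> gene set);
#'   every set non-empty.
#' @param universe character vector of genes; defaults to the union of all
#'   term sets. Every term must be a subset of the universe.
#' @param namespace one of `"BP"`, `"CC"`, `"MIR"`, `"other"`.
#' @param descriptions optional named character vector of term
#'   descriptions.
#' @return An object of class `annotation_collection`.
#' @export
annotation_collection <- function(terms, universe = NULL,
                                  namespace = c("other", "BP", "CC", "MIR"),
                                  descriptions = NULL) {
  namespace <- match.arg(namespace)
  if (!length(terms) || is.null(names(terms)) || any(!nzchar(names(terms))))
    stop("`terms` must be a non-empty named list")
  if (anyDuplicated(names(terms)))
    stop("duplicate term ids: ",
         paste(unique(names(terms)[duplicated(names(terms))]), collapse = ", "))
  terms <- lapply(terms, function(g) unique(as.character(g)))
  if (any(lengths(terms) == 0L)) stop("term gene sets must be non-empty")
  if (is.null(universe)) universe <- sort(unique(unlist(terms, use.names = FALSE)))
  universe <- unique(as.character(universe))
  out_of <- vapply(terms, function(g) any(!(g %in% universe)), logical(1))
  if (any(out_of))
    stop("terms with genes outside the universe: ",
         paste(head(names(terms)[out_of], 5L), collapse = ", "))
  if (is.null(descriptions))
    descriptions <- setNames(rep("", length(terms)), names(terms))
  structure(list(namespace = namespace, terms = terms, universe = universe,
                 descriptions = descriptions[names(terms)]),
            class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat("annotation_collection [", x$namespace, "]: ", length(x$terms),
      " terms over ", length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One term per line: term id, description, then one gene per tab-separated
#' field. The universe defaults to the union of all sets unless
#' `universe` is supplied.
#'
#' @param path GMT file path.
#' @param namespace collection namespace (see [annotation_collection()]).
#' @param universe optional explicit gene universe.
#' @return An [annotation_collection].
#' @export
read_gmt <- function(path, namespace = "other", universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  toks <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(toks) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1L], ": expected >= 3 tab-separated fields")
  ids <- vapply(toks, `[[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate term id: ", ids[duplicated(ids)][1L])
  terms <- lapply(toks, function(tk) tk[-(1:2)])
  names(terms) <- ids
  descs <- setNames(vapply(toks, `[[`, character(1), 2L), ids)
  annotation_collection(terms, universe = universe, namespace = namespace,
                        descriptions = descs)
}

#' Write gene sets in GMT format
#'
#' @param collection an [annotation_collection].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "annotation_collection"))
  lines <- vapply(names(collection$terms), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$terms[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Two-tailed Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by the minimum-likelihood rule: the sum of
#' hypergeometric probabilities, over all tables with the observed margins,
#' that do not exceed the observed table's probability (within relative
#' tolerance 1e-7). A degenerate margin (an empty row or column) gives
#' p = 1.
#'
#' @param a,b,c,d non-negative integer cell counts (`a` = in-module and
#'   in-term, `b` = in-module only, `c` = in-term only, `d` = neither).
#' @return The two-sided p-value.
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || anyNA(counts)) stop("counts must be non-negative")
  if (sum(counts) < 1) stop("table total must be >= 1")
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  probs <- dhyper(lo:hi, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a validated front end to the
#' standard procedure, returning adjusted values in input order.
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  if (!length(pvals)) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Module annotation enrichment
#'
#' One two-tailed Fisher exact test per (module, term) pair over the
#' collection's universe intersected with the clustered network's genes,
#' Benjamini-Hochberg corrected across all pairs within the namespace.
#' Modules whose corrected best term is not below `alpha` have no
#' significant rows; `significant` marks `p_adj < alpha`.
#'
#' @param partition a `module_partition` (or named assignment vector).
#' @param annotations an [annotation_collection].
#' @param alpha significance threshold on the corrected p (default 0.01).
#' @param universe optional explicit background gene set; default is the
#'   intersection of the partition's genes with the collection universe.
#' @return Data frame with columns `module_id`, `namespace`, `term_id`,
#'   `a`, `b`, `c`, `d`, `p_raw`, `p_adj`, `significant`.
#' @export
enrich_modules <- function(partition, annotations, alpha = 0.01,
                           universe = NULL) {
  stopifnot(inherits(annotations, "annotation_collection"))
  assignment <- if (inherits(partition, "module_partition"))
    partition$assignment else partition
  if (is.null(names(assignment)))
    stop("partition assignment must be named by gene")
  if (is.null(universe))
    universe <- intersect(names(assignment), annotations$universe)
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe: modules share no genes with the annotation universe")
  n_u <- length(universe)
  assignment <- assignment[names(assignment) %in% universe]
  mods <- split(names(assignment), assignment)
  terms <- lapply(annotations$terms, intersect, y = universe)
  rows <- list()
  idx <- 0L
  for (mid in names(mods)) {
    mg <- mods[[mid]]
    nm <- length(mg)
    if (nm == 0L) next
    for (tid in names(terms)) {
      tg <- terms[[tid]]
      a <- length(intersect(mg, tg))
      b <- nm - a
      cc <- length(tg) - a
      d <- n_u - a - b - cc
      idx <- idx + 1L
      rows[[idx]] <- data.frame(
        module_id = mid, namespace = annotations$namespace, term_id = tid,
        a = a, b = b, c = cc, d = d,
        p_raw = fisher_two_tailed(a, b, cc, d),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!idx)
    return(data.frame(module_id = character(0), namespace = character(0),
                      term_id = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), p_raw = numeric(0),
                      p_adj = numeric(0), significant = logical(0)))
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p_raw)
  out$significant <- out$p_adj < alpha
  row.names(out) <- NULL
  out
}
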