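#' Planted-partition network generator
#'
#' Random graph with predefined blocks: within-block edges appear with
#' probability `p_in`, between-block edges with `p_out`. With
#' `p_in > p_out` the blocks are planted dense modules, the ground truth
#' for clustering benchmarks. Deterministic per seed.
#'
#' @param block_sizes integer vector of block sizes (each >= 3).
#' @param p_in within-block edge probability, in (0, 1].
#' @param p_out between-block edge probability, in \[0, 1).
#' @param seed integer seed.
#' @return List with `network` (a [ppi_network]; node ids `Gxxxx`) and
#'   `membership` (integer block labels named by node).
#' @export
synth_network <- function(block_sizes, p_in, p_out, seed) {
  block_sizes <- as.integer(block_sizes)
  if (any(block_sizes < 3L)) stop("block sizes must be >= 3")
  if (p_in <= 0 || p_in > 1) stop("`p_in` must be in (0, 1]")
  if (p_out < 0 || p_out >= 1) stop("`p_out` must be in [0, 1)")
  n <- sum(block_sizes)
  nodes <- sprintf("G%04d", seq_len(n))
  block <- rep(seq_along(block_sizes), block_sizes)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  same <- block[pairs[, 1L]] == block[pairs[, 2L]]
  prob <- ifelse(same, p_in, p_out)
  keep <- with_local_seed(seed, runif(nrow(pairs)) < prob)
  edges <- cbind(nodes[pairs[keep, 1L]], nodes[pairs[keep, 2L]])
  list(network = ppi_network(edges, nodes = nodes),
       membership = setNames(block, nodes))
}

#' Two-class expression matrix generator
#'
#' Emulates a blood-transcriptome cohort with a balanced good/poor outcome
#' split: values are `baseline + noise` (Gaussian, sd `noise_sd`, on a
#' log-intensity-like scale), with the per-gene effects in `de_genes`
#' (units of `noise_sd`) added to the poor-outcome samples. Ejection
#' fractions are drawn consistently with the 40% outcome rule: good
#' uniform on (45, 73), poor uniform on (20, 40), matching the reported
#' post-MI cohort ranges.
#'
#' @param n_genes number of genes; ids default to `Gxxxx`.
#' @param n_good,n_poor samples per class (each >= 2; default 16/16).
#' @param de_genes named numeric vector: gene id -> effect size in
#'   noise-sd units (positive = up in poor outcome).
#' @param noise_sd within-class standard deviation (> 0).
#' @param baseline grand mean expression level.
#' @param seed integer seed.
#' @param genes optional explicit gene identifiers (length `n_genes`).
#' @return An [expression_dataset].
#' @export
synth_expression <- function(n_genes, n_good = 16L, n_poor = 16L,
                             de_genes = numeric(0), noise_sd = 1,
                             baseline = 8, seed = 1L, genes = NULL) {
  if (n_good < 2L || n_poor < 2L) stop("need >= 2 samples per class")
  if (noise_sd <= 0) stop("`noise_sd` must be > 0")
  if (is.null(genes)) genes <- sprintf("G%04d", seq_len(n_genes))
  if (length(genes) != n_genes) stop("`genes` must have length `n_genes`")
  if (length(de_genes) && (is.null(names(de_genes)) ||
                           !all(names(de_genes) %in% genes)))
    stop("`de_genes` must be named by generated gene ids")
  samples <- sprintf("S%02d", seq_len(n_good + n_poor))
  labels <- rep(c("good", "poor"), c(n_good, n_poor))
  with_local_seed(seed, {
    m <- matrix(baseline + rnorm(n_genes * length(samples), sd = noise_sd),
                nrow = n_genes, dimnames = list(genes, samples))
    if (length(de_genes))
      m[names(de_genes), labels == "poor"] <-
        m[names(de_genes), labels == "poor"] + de_genes * noise_sd
    ef <- ifelse(labels == "good", runif(length(labels), 45, 73),
                 runif(length(labels), 20, 40))
    expression_dataset(m, labels = labels, ef = setNames(ef, samples))
  })
}

#' Annotation-collection generator
#'
#' Null terms are uniform random subsets of the universe (sizes drawn from
#' 5-50, capped at the universe size); planted terms are included
#' verbatim, giving known-true enrichment signals.
#'
#' @param universe character vector of genes.
#' @param n_null_terms number of random terms.
#' @param planted named list of gene sets (each a subset of `universe`).
#' @param seed integer seed.
#' @param namespace collection namespace.
#' @return An [annotation_collection] over `universe`.
#' @export
synth_annotations <- function(universe, n_null_terms, planted = list(),
                              seed = 1L, namespace = "other") {
  universe <- unique(as.character(universe))
  if (length(planted)) {
    if (is.null(names(planted))) stop("`planted` must be a named list")
    bad <- vapply(planted, function(g) any(!(g %in% universe)), logical(1))
    if (any(bad))
      stop("planted sets outside the universe: ",
           paste(names(planted)[bad], collapse = ", "))
  }
  null_terms <- with_local_seed(seed, {
    out <- vector("list", n_null_terms)
    for (i in seq_len(n_null_terms)) {
      size <- min(sample(5:50, 1L), length(universe))
      out[[i]] <- sample(universe, size)
    }
    names(out) <- sprintf("NULL%03d", seq_len(n_null_terms))
    out
  })
  annotation_collection(c(planted, null_terms), universe = universe,
                        namespace = namespace)
}

#' qPCR Ct table generator
#'
#' Ct values in a plausible 15-35 cycle range, with a low-variance
#' housekeeping reference gene; emulates a small multiplex TaqMan assay
#' table.
#'
#' @param samples number of samples (ids `P01`, ...).
#' @param genes character vector of gene columns.
#' @param reference housekeeping gene (must be in `genes`).
#' @param seed integer seed.
#' @return A [ct_table].
#' @export
synth_ct <- function(samples, genes, reference, seed = 1L) {
  genes <- as.character(genes)
  if (!reference %in% genes) stop("`reference` must be one of `genes`")
  with_local_seed(seed, {
    base <- runif(length(genes), 18, 30)     # per-gene typical Ct
    names(base) <- genes
    m <- matrix(0, nrow = samples, ncol = length(genes),
                dimnames = list(sprintf("P%02d", seq_len(samples)), genes))
    for (g in genes) {
      sdv <- if (g == reference) 0.15 else 1.2
      m[, g] <- pmin(35, pmax(15, rnorm(samples, base[g], sdv)))
    }
    ct_table(m, reference)
  })
}

#' Cohort-scale synthetic scenario (the end-to-end preset)
#'
#' One call producing all inputs for a full pipeline run, shaped like the
#' post-MI study conditions: a ~2500-node planted-partition interactome
#' (one 5-node block — the prognostic module, sized like the smallest
#' informative modules of curated inflammation interactomes — plus 166
#' blocks of 15; `p_in = 0.30`; `p_out` set for ~0.5 expected
#' between-block degree, overall mean degree ~4.7), a 16/16 good/poor
#' expression cohort over the network's genes, annotation sets with the
#' planted module's genes as a verbatim term, and an 11-sample Ct table
#' for the biomarker genes plus a housekeeping reference. Differential
#' effects of +1.5 sd in poor outcome are planted on the prognostic
#' module's 5 genes and on the giant component's three highest-traffic
#' bottleneck genes, emulating the empirical pattern that both a small
#' module's genes and top-traffic bottlenecks carry the outcome signal.
#'
#' @param seed integer seed driving every generator.
#' @return List with `network`, `membership`, `expression`,
#'   `annotations`, `ct`, `planted` (list naming the planted module genes,
#'   module block id, and bottleneck biomarker genes).
#' @export
synth_study_preset <- function(seed = 1L) {
  block_sizes <- c(5L, rep(15L, 166L))
  n <- sum(block_sizes)
  p_out <- 0.5 / (n - 15L)
  sn <- synth_network(block_sizes, p_in = 0.30, p_out = p_out, seed = seed)
  nodes <- sn$network$nodes
  module_genes <- names(sn$membership)[sn$membership == 1L]
  # bottleneck biomarkers: the giant component's top-traffic nodes
  # outside the planted module
  giant <- largest_component(sn$network)
  topo <- node_topology(giant)
  biomarker_genes <- head(setdiff(topo$protein, module_genes), 3L)
  effects <- setNames(rep(1.5, length(c(module_genes, biomarker_genes))),
                      c(module_genes, biomarker_genes))
  ds <- synth_expression(n_genes = length(nodes), n_good = 16L, n_poor = 16L,
                         de_genes = effects, noise_sd = 1, baseline = 8,
                         seed = seed + 1L, genes = nodes)
  ann <- synth_annotations(nodes, n_null_terms = 60L,
                           planted = list(PLANTED_TERM = module_genes),
                           seed = seed + 2L, namespace = "BP")
  ct <- synth_ct(11L, genes = c(biomarker_genes, "REF1"), reference = "REF1",
                 seed = seed + 3L)
  list(network = sn$network, membership = sn$membership, expression = ds,
       annotations = ann, ct = ct,
       planted = list(module_genes = module_genes, module_block = 1L,
                      biomarker_genes = biomarker_genes))
}
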