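#' Hierarchical clustering of log2 profiles
#'
#' Pairwise dissimilarity `1 - Pearson r` over shared probe values, Ward
#' aggregation (`hclust` method `"ward.D2"`). Deterministic; ties are
#' resolved by sample order.
#'
#' @param profiles List of at least three [log2_profile()]s on a shared
#'   probe universe (intersected by `probe_id`).
#' @param on Cluster on per-probe values (default) or on segment-mean
#'   expanded values (each probe replaced by its segment mean; requires
#'   `segmented` to be supplied).
#' @param segmented Optional list of matching [cbs_segment()] results when
#'   `on = "segments"`.
#' @return A `ClusterResult`: `sample_ids`, the `hclust` object, `merge`
#'   records, `distance = "pearson"`, `method = "ward"`.
#' @export
cluster_profiles <- function(profiles, on = c("probes", "segments"),
                             segmented = NULL) {
  on <- match.arg(on)
  stopifnot(length(profiles) >= 3)
  ids <- vapply(profiles, function(p) p$sample_id, "")
  if (anyDuplicated(ids)) stop("duplicate sample_ids among profiles")
  shared <- Reduce(intersect, lapply(profiles, function(p) p$probes$probe_id))
  if (length(shared) < 10) stop("fewer than 10 shared probes")
  mat <- vapply(seq_along(profiles), function(k) {
    p <- profiles[[k]]
    v <- p$values[match(shared, p$probes$probe_id)]
    if (on == "segments") {
      if (is.null(segmented)) stop("on = 'segments' needs segmented profiles")
      s <- segmented[[k]]$segments
      idx <- match(shared, p$probes$probe_id)
      seg_of <- findInterval(idx - 1, s$idx_start)
      v <- s$mean[seg_of]
    }
    v
  }, numeric(length(shared)))
  colnames(mat) <- ids
  sds <- apply(mat, 2, stats::sd)
  if (any(sds < 1e-12)) {
    stop("constant profile (undefined correlation): ",
         paste(ids[sds < 1e-12], collapse = ", "))
  }
  d <- stats::as.dist(1 - stats::cor(mat))
  hc <- stats::hclust(d, method = "ward.D2")
  structure(
    list(sample_ids = ids, hclust = hc, merge = hc$merge,
         heights = hc$height, distance = "pearson", method = "ward"),
    class = "ClusterResult"
  )
}

#' Cut a cluster result into k groups
#'
#' @param x A [cluster_profiles()] result.
#' @param k Number of clusters.
#' @return Named integer vector of cluster memberships.
#' @export
cut_clusters <- function(x, k) {
  stopifnot(inherits(x, "ClusterResult"))
  stats::cutree(x$hclust, k = k)
}

#' Export a cluster result as a Newick tree
#'
#' Leaf names are sample ids; branch lengths derive from merge heights.
#'
#' @param x A [cluster_profiles()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(x, path) {
  stopifnot(inherits(x, "ClusterResult"))
  ape::write.tree(ape::as.phylo(x$hclust), file = path)
  invisible(path)
}

#' Hypergeometric cytoband enrichment of a gene list
#'
#' A transparent stand-in for web-service positional enrichment: each gene
#' maps to every cytoband it overlaps (via the gene coordinates in `ann`),
#' and for every band containing at least one query gene the upper-tail
#' hypergeometric p-value of the query/background overlap is computed,
#' with Benjamini-Hochberg correction across tested bands.
#'
#' @param query Character vector of gene symbols (must be a subset of
#'   `background`).
#' @param background Character vector of background gene symbols.
#' @param ann A [genome_annotation()] with gene coordinates and cytobands.
#' @return data.frame with one row per tested band: `cytoband`, `k` (query
#'   genes in band), `K` (mappable query size), `n` (background genes in
#'   band), `N` (mappable background size), `p`, `p_adj`; sorted by `p`.
#' @export
cytoband_enrichment <- function(query, background, ann) {
  stopifnot(inherits(ann, "GenomeAnnotation"))
  empty <- data.frame(cytoband = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), stringsAsFactors = FALSE)
  if (length(query) == 0) return(empty)
  if (!all(query %in% background)) {
    stop("query genes must be a subset of the background")
  }
  genes <- ann$genes[ann$genes$name %in% background, , drop = FALSE]
  if (nrow(genes) == 0) return(empty)
  g_gr <- .annotation_granges(genes)
  b_gr <- .annotation_granges(ann$cytobands)
  ov <- GenomicRanges::findOverlaps(g_gr, b_gr)
  map <- data.frame(
    gene = genes$name[S4Vectors::queryHits(ov)],
    band = ann$cytobands$name[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE
  )
  map <- unique(map)
  mappable <- unique(map$gene)
  N <- length(intersect(background, mappable))
  qmap <- unique(intersect(query, mappable))
  K <- length(qmap)
  if (K == 0 || N == 0) return(empty)
  n_band <- table(map$band)
  k_band <- table(map$band[map$gene %in% qmap])
  bands <- names(k_band)[k_band > 0]
  if (length(bands) == 0) return(empty)
  k <- as.integer(k_band[bands])
  n <- as.integer(n_band[bands])
  p <- stats::phyper(k - 1, n, N - n, K, lower.tail = FALSE)
  out <- data.frame(cytoband = bands, k = k, K = K, n = n, N = N, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, out$cytoband), , drop = FALSE]
  rownames(out) <- NULL
  out
}
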