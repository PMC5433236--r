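# Co-occurrence network (Spearman + Benjamini-Hochberg) and Bray-Curtis
# NMDS ordination over sample x cluster abundance tables.

#' Co-occurrence network of clusters across samples
#'
#' Relative abundances are computed per sample; only clusters detected in
#' at least `prevalence_min` of samples are tested. Spearman's rho is
#' computed on midranks for every retained pair; p-values use the
#' t-approximation and q-values the Benjamini-Hochberg correction over all
#' tested pairs. Edges must satisfy rho >= `rho_min`, p < `p_max` and
#' q < `q_max`.
#'
#' @param ct a `cluster_table` or a sample x cluster counts matrix.
#' @param prevalence_min minimum detection fraction (default 0.5).
#' @param rho_min minimum Spearman correlation (default 0.5).
#' @param p_max,q_max significance thresholds (default 0.01 each).
#' @return a `cooccurrence_network`: list with `nodes` (tibble:
#'   `cluster_id`, `prevalence`, `mean_rel_abundance`), `edges` (tibble:
#'   `from`, `to`, `rho`, `p`, `q`) and `tested` (all tested pairs).
#' @export
cooccurrence <- function(ct, prevalence_min = 0.5, rho_min = 0.5,
                         p_max = 0.01, q_max = 0.01) {
  m <- if (inherits(ct, "cluster_table")) ct$counts else as.matrix(ct)
  n <- nrow(m)
  if (n < 4) stop("co-occurrence analysis needs at least 4 samples")
  rel <- sweep(m, 1, pmax(rowSums(m), 1), "/")
  prevalence <- colMeans(m > 0)
  keep <- prevalence >= prevalence_min
  nodes <- tibble::tibble(cluster_id = colnames(m)[keep],
                          prevalence = prevalence[keep],
                          mean_rel_abundance = colMeans(rel[, keep, drop = FALSE]))
  rel <- rel[, keep, drop = FALSE]
  k <- ncol(rel)
  if (k < 2) {
    edges <- tibble::tibble(from = character(), to = character(),
                            rho = numeric(), p = numeric(), q = numeric())
    return(structure(list(nodes = nodes, edges = edges, tested = edges),
                     class = "cooccurrence_network"))
  }
  ranks <- apply(rel, 2, rank)  # midranks for ties
  rho_m <- stats::cor(ranks)
  pairs <- which(upper.tri(rho_m), arr.ind = TRUE)
  rho <- rho_m[pairs]
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) >= 1] <- 0
  q <- stats::p.adjust(p, method = "BH")
  tested <- tibble::tibble(from = colnames(rel)[pairs[, 1]],
                           to = colnames(rel)[pairs[, 2]],
                           rho = rho, p = p, q = q)
  edges <- tested[tested$rho >= rho_min & tested$p < p_max & tested$q < q_max, ]
  structure(list(nodes = nodes, edges = edges, tested = tested),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("<cooccurrence_network> ", nrow(x$nodes), " node(s), ", nrow(x$edges),
      " edge(s) of ", nrow(x$tested), " tested pair(s)\n", sep = "")
  invisible(x)
}

#' Export a network as an edge-list TSV (and optionally GraphML)
#' @param net a `cooccurrence_network`.
#' @param path edge-list TSV path.
#' @param graphml optional GraphML path (requires igraph).
#' @export
write_network <- function(net, path, graphml = NULL) {
  write.table(as.data.frame(net$edges), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(graphml)) {
    if (!requireNamespace("igraph", quietly = TRUE))
      stop("GraphML export requires the igraph package")
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = as.data.frame(net$nodes))
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(path)
}

#' Non-metric multidimensional scaling of samples (Bray-Curtis)
#'
#' Relative abundances per sample, Bray-Curtis dissimilarity, and NMDS by
#' iterative stress minimization; a fixed seed makes the configuration
#' reproducible.
#'
#' @param ct a `cluster_table` or counts matrix.
#' @param seed RNG seed.
#' @param k target dimensionality (default 2).
#' @param trymax random restarts (default 20).
#' @return tibble with `sample_id`, `NMDS1`, `NMDS2`; the stress is
#'   attached as attribute `"stress"`.
#' @export
ordinate_nmds <- function(ct, seed = 42, k = 2, trymax = 20) {
  m <- if (inherits(ct, "cluster_table")) ct$counts else as.matrix(ct)
  rel <- sweep(m, 1, pmax(rowSums(m), 1), "/")
  fit <- withr::with_seed(seed,
    vegan::metaMDS(rel, distance = "bray", k = k, trymax = trymax,
                   trace = 0, autotransform = FALSE, wascores = FALSE))
  pts <- vegan::scores(fit, display = "sites")
  out <- tibble::as_tibble(pts)
  names(out) <- paste0("NMDS", seq_len(ncol(out)))
  out <- dplyr::mutate(out, sample_id = rownames(m), .before = 1)
  attr(out, "stress") <- fit$stress
  out
}

#' Plot an NMDS ordination
#' @param ord tibble from [ordinate_nmds()].
#' @return a ggplot object.
#' @export
plot_ordination <- function(ord) {
  ggplot2::ggplot(ord, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2,
                                    label = .data$sample_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(caption = sprintf("stress = %.4f",
                                    attr(ord, "stress") %||% NA_real_)) +
    ggplot2::theme_minimal()
}

#' Plot a co-occurrence network (edge list as a simple layout)
#' @param net a `cooccurrence_network`.
#' @param seed layout seed.
#' @return a ggplot object.
#' @export
plot_network <- function(net, seed = 1) {
  nodes <- net$nodes
  xy <- withr::with_seed(seed, {
    th <- stats::runif(nrow(nodes), 0, 2 * pi)
    r <- sqrt(stats::runif(nrow(nodes)))
    cbind(x = r * cos(th), y = r * sin(th))
  })
  nodes <- dplyr::bind_cols(nodes, tibble::as_tibble(xy))
  ed <- net$edges
  ed$x <- nodes$x[match(ed$from, nodes$cluster_id)]
  ed$y <- nodes$y[match(ed$from, nodes$cluster_id)]
  ed$xend <- nodes$x[match(ed$to, nodes$cluster_id)]
  ed$yend <- nodes$y[match(ed$to, nodes$cluster_id)]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$mean_rel_abundance)) +
    ggplot2::theme_void()
}
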