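## ROI-ROI functional connectivity and node-level graph metrics.
## Graphs are binary and unweighted (unit edge lengths): the metric
## definitions used here (inverse distances, edge counts) presuppose
## unweighted distance. Shortest-path and centrality primitives are
## delegated to igraph; conventions (1/Inf = 0 for efficiency, missing APL
## for isolated nodes, 0 clustering/local efficiency below degree 2,
## Brandes fractional credit for tied shortest paths) are fixed here.

Z_CLIP <- 1 - 1e-7

#' Fisher-z connectivity matrix
#'
#' Pairwise Pearson correlations between ROI timeseries, clipped to
#' `+/-(1 - 1e-7)` and mapped through `atanh` (Fisher z). The diagonal is
#' stored as 0 and never used.
#'
#' @param ts Time x ROI matrix (>= 3 timepoints).
#' @return Symmetric ROI x ROI matrix of class `connectivity_matrix`;
#'   zero-variance ROIs yield `NA` rows/columns with a warning.
#' @export
correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("at least 3 timepoints are required")
  sds <- apply(ts, 2, stats::sd)
  bad <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(stats::cor(ts))
  if (any(bad)) {
    warning("zero-variance ROI(s): ",
            paste(colnames(ts)[bad], collapse = ", "),
            "; their connectivity is set missing")
    r[bad, ] <- NA_real_
    r[, bad] <- NA_real_
  }
  z <- atanh(pmin(pmax(r, -Z_CLIP), Z_CLIP))
  diag(z) <- 0
  class(z) <- c("connectivity_matrix", class(z))
  z
}

#' Threshold a connectivity matrix at fixed cost
#'
#' Builds a binary undirected graph by retaining the `round(cost_target *
#' N(N-1)/2)` largest positive Fisher-z edges; ties are broken by fixed
#' lexicographic (row, column) index order so the result is deterministic.
#'
#' @param cm A `connectivity_matrix`.
#' @param cost_target Fraction of possible edges to keep, in (0, 1);
#'   default 0.15.
#' @return A list of class `binary_graph`: `adjacency` (0/1 matrix),
#'   `n_edges`, `cost_realized`, `cost_target`.
#' @export
threshold_graph <- function(cm, cost_target = 0.15) {
  if (cost_target <= 0 || cost_target >= 1)
    stop("'cost_target' must lie strictly between 0 and 1")
  n <- nrow(cm)
  m_possible <- n * (n - 1) / 2
  k <- round(cost_target * m_possible)
  ut <- which(upper.tri(cm), arr.ind = TRUE)
  z <- cm[ut]
  pos <- which(is.finite(z) & z > 0)
  if (length(pos) < k) {
    warning("only ", length(pos), " positive edges available for ", k,
            " requested; keeping all positive edges")
    keep <- pos
  } else {
    ord <- pos[order(-z[pos], ut[pos, 1], ut[pos, 2])]
    keep <- ord[seq_len(k)]
  }
  adj <- matrix(0L, n, n, dimnames = dimnames(cm))
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  structure(list(adjacency = adj, n_edges = length(keep),
                 cost_realized = length(keep) / m_possible,
                 cost_target = cost_target),
            class = "binary_graph")
}

## all-pairs unweighted shortest-path distances by breadth-first expansion
## of the adjacency matrix (fast for the small neighbour subgraphs LE needs)
bfs_distances <- function(a) {
  k <- nrow(a)
  d <- matrix(Inf, k, k)
  diag(d) <- 0
  a <- (a > 0) + 0
  cur <- a
  step <- 1
  while (step <= k) {
    newly <- cur > 0 & d == Inf
    if (!any(newly)) break
    d[newly] <- step
    cur <- cur %*% a
    step <- step + 1
  }
  d
}

## induced-subgraph global efficiency, averaged over the subgraph's nodes
local_efficiency_node <- function(adj, i) {
  nb <- which(adj[i, ] > 0)
  if (length(nb) < 2) return(0)
  d <- bfs_distances(adj[nb, nb, drop = FALSE])
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  mean(rowSums(inv) / (length(nb) - 1))
}

#' Node-level graph metrics
#'
#' Computes, for every node of a binary graph: global efficiency (GE, mean
#' inverse distance to all other nodes, with unreachable contributing 0),
#' local efficiency (LE, mean within-subgraph GE of the neighbour-induced
#' subgraph; 0 below degree 2), betweenness centrality (BC, Brandes
#' fractional credit, normalised by `(N-1)(N-2)/2`), average path length
#' (APL, mean distance to reachable nodes; missing for isolated nodes),
#' clustering coefficient (CC, fraction of connected neighbour pairs; 0
#' below degree 2), degree and cost (`degree/(N-1)`).
#'
#' @param g A `binary_graph` (or a 0/1 adjacency matrix).
#' @param metrics Which columns to compute (any of `"GE"`, `"LE"`, `"BC"`,
#'   `"APL"`, `"CC"`, `"degree"`, `"cost"`); the default computes all seven.
#'   Restricting the set skips the more expensive shortest-path work when it
#'   is not needed.
#' @return A data frame: `roi` plus one column per requested metric.
#' @export
node_metrics <- function(g, metrics = c("GE", "LE", "BC", "APL", "CC",
                                        "degree", "cost")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  adj <- if (inherits(g, "binary_graph")) g$adjacency else as.matrix(g)
  n <- nrow(adj)
  if (n < 2) stop("graph metrics need at least 2 nodes")
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  deg <- rowSums(adj)
  out <- data.frame(roi = if (!is.null(rownames(adj))) rownames(adj)
                          else as.character(seq_len(n)),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (any(c("GE", "APL") %in% metrics)) {
    d <- igraph::distances(gr)
    if ("GE" %in% metrics) {
      inv <- 1 / d
      diag(inv) <- 0
      inv[!is.finite(inv)] <- 0
      out$GE <- rowSums(inv) / (n - 1)
    }
    if ("APL" %in% metrics)
      out$APL <- apply(d, 1, function(row) {
        reach <- is.finite(row) & row > 0
        if (!any(reach)) NA_real_ else mean(row[reach])
      })
  }
  if ("LE" %in% metrics)
    out$LE <- vapply(seq_len(n), function(i) local_efficiency_node(adj, i),
                     numeric(1))
  if ("BC" %in% metrics)
    out$BC <- igraph::betweenness(gr, directed = FALSE, normalized = TRUE)
  if ("CC" %in% metrics)
    out$CC <- igraph::transitivity(gr, type = "localundirected",
                                   isolates = "zero")
  if ("degree" %in% metrics) out$degree <- as.integer(deg)
  if ("cost" %in% metrics) out$cost <- deg / (n - 1)
  out[, c("roi", intersect(c("GE", "LE", "BC", "APL", "CC", "degree",
                             "cost"), metrics))]
}

#' Graph and spectral node metrics for a whole cohort
#'
#' Runs [correlation_matrix()], [threshold_graph()] and [node_metrics()] for
#' every subject of a BOLD panel and returns a long-format node-metrics
#' table. Optionally adds an ROI-level fALFF column computed directly on the
#' ROI timeseries (the ratio of band-limited to broadband RMS), the
#' voxel-free analogue of the voxel-based fALFF aggregate.
#'
#' @param panel A `bold_panel` (ideally already denoised; fALFF uses the
#'   unfiltered series it is given, so pass regressed-but-unfiltered data
#'   when fALFF is requested).
#' @param atlas An `atlas_table`; ROI order is taken from it.
#' @param cost_target Graph density used by [threshold_graph()].
#' @param metrics Character vector choosing among
#'   `c("GE","LE","BC","APL","CC","degree","cost","fALFF")`.
#' @param band Passband for the fALFF numerator, Hz.
#' @return Long data frame (`subject`, `roi`, `metric`, `value`) of class
#'   `node_metrics_table`.
#' @export
compute_node_metrics <- function(panel, atlas, cost_target = 0.15,
                                 metrics = c("GE", "LE", "BC", "APL", "CC",
                                             "degree", "cost"),
                                 band = c(0.008, 0.09)) {
  stopifnot(inherits(panel, "bold_panel"))
  validate_atlas(atlas)
  graph_metrics <- setdiff(metrics, "fALFF")
  out <- lapply(names(panel$subjects), function(s) {
    ts <- panel$subjects[[s]][, atlas$name, drop = FALSE]
    rows <- NULL
    if (length(graph_metrics)) {
      cm <- correlation_matrix(ts)
      nm <- node_metrics(threshold_graph(cm, cost_target),
                         metrics = graph_metrics)
      rows <- do.call(rbind, lapply(graph_metrics, function(m)
        data.frame(subject = s, roi = nm$roi, metric = m,
                   value = as.numeric(nm[[m]]), stringsAsFactors = FALSE)))
    }
    if ("fALFF" %in% metrics) {
      xm <- sweep(ts, 2, colMeans(ts))
      denom <- sqrt(colMeans(xm^2))
      num <- sqrt(colMeans(bandpass(xm, panel$tr, band[1], band[2])^2))
      fa <- ifelse(denom == 0, NA_real_, num / denom)
      rows <- rbind(rows, data.frame(subject = s, roi = colnames(ts),
                                     metric = "fALFF", value = fa,
                                     stringsAsFactors = FALSE))
    }
    rows
  })
  res <- do.call(rbind, out)
  class(res) <- c("node_metrics_table", "data.frame")
  res
}
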