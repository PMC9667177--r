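## Cluster-based permutation testing of univariate TFR contrasts over
## channel x frequency x time grids, with familywise control via the
## max-cluster-mass randomisation distribution.

#' Dependent-sample t map over a channel x frequency x time grid
#'
#' Paired t per cell across subjects for two within-subject conditions.
#'
#' @param cond_a,cond_b arrays `subjects x channels x frequencies x times` of
#'   per-subject condition means (log-baselined power), identically shaped.
#' @param channel_names,freqs,times axis labels (lengths must match dims).
#' @return a `t_map`: `t` array `channels x frequencies x times`, `df`, axes.
#' @export
dependent_t_map <- function(cond_a, cond_b, channel_names = NULL,
                            freqs = NULL, times = NULL) {
  stopifnot(identical(dim(cond_a), dim(cond_b)), length(dim(cond_a)) == 4)
  n <- dim(cond_a)[1]
  if (n < 3) stop("need at least 3 subjects")
  D <- cond_a - cond_b
  dm <- dim(D)
  Dm <- matrix(D, n, prod(dm[-1]))
  m <- colMeans(Dm)
  s <- sqrt(pmax(colSums(Dm^2) - n * m^2, 0) / (n - 1))
  tv <- m / (s / sqrt(n))
  tv[s == 0] <- sign(m[s == 0]) * 1e6  # zero-variance sentinel
  tv <- array(tv, dm[-1])
  structure(list(t = tv, df = n - 1,
                 channel_names = channel_names %||% seq_len(dm[2]),
                 freqs = freqs %||% seq_len(dm[3]),
                 times = times %||% seq_len(dm[4])),
            class = "t_map")
}

#' Cell adjacency graph for clustering
#'
#' Nodes are (channel, frequency, time) cells; edges join montage channel
#' neighbours at the same (frequency, time) and +/- one grid step along
#' frequency or time at the same channel. A simultaneous step in two axes is
#' not adjacent. With an empty neighbour list the channels are disconnected
#' and clustering reduces to per-channel grids.
#'
#' @param channel_names channels, in array order.
#' @param n_freq,n_time grid sizes.
#' @param neighbors named channel neighbour list (or `NULL`/empty for none).
#' @return an igraph graph with `prod(dims)` vertices in array (column-major)
#'   cell order.
#' @export
build_cell_graph <- function(channel_names, n_freq, n_time,
                             neighbors = NULL) {
  nc <- length(channel_names)
  n_cell <- nc * n_freq * n_time
  id <- function(ch, fr, ti) ch + nc * (fr - 1L) + nc * n_freq * (ti - 1L)
  edges <- list()
  if (n_freq > 1) {
    g <- expand.grid(ch = seq_len(nc), fr = seq_len(n_freq - 1L),
                     ti = seq_len(n_time))
    edges <- c(edges, list(cbind(id(g$ch, g$fr, g$ti),
                                 id(g$ch, g$fr + 1L, g$ti))))
  }
  if (n_time > 1) {
    g <- expand.grid(ch = seq_len(nc), fr = seq_len(n_freq),
                     ti = seq_len(n_time - 1L))
    edges <- c(edges, list(cbind(id(g$ch, g$fr, g$ti),
                                 id(g$ch, g$fr, g$ti + 1L))))
  }
  if (!is.null(neighbors) && length(neighbors)) {
    pairs <- do.call(rbind, lapply(seq_along(channel_names), function(i) {
      nb <- match(intersect(neighbors[[channel_names[i]]], channel_names),
                  channel_names)
      nb <- nb[!is.na(nb) & nb > i]  # undirected, record once
      if (length(nb)) cbind(i, nb) else NULL
    }))
    if (!is.null(pairs) && nrow(pairs)) {
      grid <- expand.grid(fr = seq_len(n_freq), ti = seq_len(n_time))
      np <- nrow(pairs)
      rep_p <- rep(seq_len(np), times = nrow(grid))
      rep_g <- rep(seq_len(nrow(grid)), each = np)
      edges <- c(edges, list(cbind(
        id(pairs[rep_p, 1], grid$fr[rep_g], grid$ti[rep_g]),
        id(pairs[rep_p, 2], grid$fr[rep_g], grid$ti[rep_g]))))
    }
  }
  if (!length(edges))
    return(igraph::make_empty_graph(n_cell, directed = FALSE))
  el <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < n_cell)
    g <- igraph::add_vertices(g, n_cell - igraph::vcount(g))
  g
}

# maximal connected same-sign supra-threshold components; returns a list of
# clusters (cells = cell indices into the flattened array, sign, mass)
supra_clusters <- function(tvec, tcrit, graph) {
  out <- list()
  for (sgn in c(1, -1)) {
    cells <- which(sgn * tvec > tcrit)
    if (!length(cells)) next
    sub <- igraph::induced_subgraph(graph, cells)
    comp <- igraph::components(sub)
    for (k in seq_len(comp$no)) {
      members <- cells[comp$membership == k]
      out[[length(out) + 1L]] <- list(cells = members, sign = sgn,
                                      mass = sum(tvec[members]))
    }
  }
  out
}

#' Supra-threshold clusters of a t map
#'
#' Cells whose |t| exceeds the two-tailed critical paired-t at the map's
#' degrees of freedom are grouped into maximal connected components,
#' separately for positive and negative t, and each cluster's t values are
#' summed into its mass.
#'
#' @param tmap a [dependent_t_map()] result.
#' @param alpha cell-level threshold alpha (two-tailed, default 0.05).
#' @param neighbors channel neighbour list (default none: channels
#'   disconnected).
#' @return list of clusters, each with `cells` (matrix of channel/freq/time
#'   indices), `sign`, `mass`.
#' @export
form_clusters <- function(tmap, alpha = 0.05, neighbors = NULL) {
  dm <- dim(tmap$t)
  graph <- build_cell_graph(tmap$channel_names, dm[2], dm[3], neighbors)
  tcrit <- qt(1 - alpha / 2, tmap$df)
  cl <- supra_clusters(as.vector(tmap$t), tcrit, graph)
  lapply(cl, function(x) {
    idx <- arrayInd(x$cells, dm)
    colnames(idx) <- c("channel", "freq", "time")
    list(cells = idx, sign = x$sign, mass = x$mass)
  })
}

#' Cluster-based permutation test for a paired TFR contrast
#'
#' Builds the observed supra-threshold clusters, then draws the
#' randomisation null of the maximum cluster mass by swapping the two
#' condition labels within subjects (equivalently, flipping the sign of each
#' subject's difference), rebuilding the t map and clusters on each draw.
#' Each observed cluster's Monte-Carlo p is
#' `(1 + #draws with max |mass| >= |observed mass|) / (1 + n_draws)`;
#' positive and negative clusters are each tested against the max-|mass| null
#' at `alpha / 2` per tail.
#'
#' @param cond_a,cond_b per-subject condition arrays as in
#'   [dependent_t_map()].
#' @param neighbors channel neighbour list.
#' @param n_draws random draws (10,000 at full scale; < 100 refused).
#' @param alpha cell-level and (two-tailed) cluster-level alpha.
#' @param seed integer seed.
#' @param channel_names,freqs,times axis labels.
#' @return a `cluster_result`: `clusters` (with Monte-Carlo `p` and
#'   `significant` each), `null_max_mass`, `tmap`, `n_draws`, `alpha`.
#' @export
cluster_permutation_p <- function(cond_a, cond_b, neighbors = NULL,
                                  n_draws = 10000, alpha = 0.05, seed = 1L,
                                  channel_names = NULL, freqs = NULL,
                                  times = NULL) {
  if (n_draws < 100) stop("n_draws below 100 is refused")
  tmap <- dependent_t_map(cond_a, cond_b, channel_names, freqs, times)
  dm <- dim(tmap$t)
  n <- dim(cond_a)[1]
  graph <- build_cell_graph(tmap$channel_names, dm[2], dm[3], neighbors)
  tcrit <- qt(1 - alpha / 2, tmap$df)
  obs <- supra_clusters(as.vector(tmap$t), tcrit, graph)

  D <- matrix(cond_a - cond_b, n, prod(dm))
  SS <- colSums(D^2)
  null_max <- with_seed(seed, vapply(seq_len(n_draws), function(i) {
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    m <- as.vector(crossprod(sgn, D)) / n
    s2 <- pmax(SS - n * m^2, 0) / (n - 1)
    tv <- m / sqrt(s2 / n)
    tv[s2 == 0] <- sign(m[s2 == 0]) * 1e6
    cl <- supra_clusters(tv, tcrit, graph)
    if (!length(cl)) 0 else max(abs(vapply(cl, `[[`, 0, "mass")))
  }, 0))

  clusters <- lapply(obs, function(x) {
    idx <- arrayInd(x$cells, dm)
    colnames(idx) <- c("channel", "freq", "time")
    p <- (1 + sum(null_max >= abs(x$mass))) / (1 + n_draws)
    list(cells = idx, sign = x$sign, mass = x$mass, p = p,
         significant = p <= alpha / 2)
  })
  structure(list(clusters = clusters, null_max_mass = null_max, tmap = tmap,
                 n_draws = n_draws, alpha = alpha),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %d draws\n",
              length(x$clusters), x$n_draws))
  ord <- order(vapply(x$clusters, `[[`, 0, "p"),
               -abs(vapply(x$clusters, `[[`, 0, "mass")))
  show <- head(ord, 8)
  for (cl in x$clusters[show])
    cat(sprintf("  sign %+d  mass %8.2f  cells %4d  p = %.4g%s\n", cl$sign,
                cl$mass, nrow(cl$cells), cl$p,
                if (cl$significant) " *" else ""))
  if (length(ord) > 8)
    cat("  ... and ", length(ord) - 8, " smaller cluster(s)\n", sep = "")
  invisible(x)
}

#' Tabulate a cluster result as tidy delimited text
#' @param x a `cluster_result`.
#' @param file optional output path; when given the table is written there.
#' @return data.frame: cluster id, sign, mass, p, extent per axis.
#' @export
cluster_table <- function(x, file = NULL) {
  tab <- do.call(rbind, lapply(seq_along(x$clusters), function(i) {
    cl <- x$clusters[[i]]
    data.frame(cluster = i, sign = cl$sign, mass = cl$mass, p = cl$p,
               significant = cl$significant, n_cells = nrow(cl$cells),
               n_channels = length(unique(cl$cells[, "channel"])),
               freq_min = min(x$tmap$freqs[cl$cells[, "freq"]]),
               freq_max = max(x$tmap$freqs[cl$cells[, "freq"]]),
               time_min = min(x$tmap$times[cl$cells[, "time"]]),
               time_max = max(x$tmap$times[cl$cells[, "time"]]))
  }))
  if (is.null(tab)) tab <- data.frame()
  if (!is.null(file))
    utils::write.table(tab, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  tab
}
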