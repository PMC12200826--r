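#' Build a channel adjacency graph from montage positions
#'
#' Channels are neighbours iff their Euclidean distance in the flattened
#' montage is at most `radius`.
#'
#' @param montage data.frame with `channel`, `x`, `y`.
#' @param radius neighbourhood radius in montage distance units.
#' @return list of class `adjacency_graph`: `channels`, `edges`
#'   (two-column matrix of channel indices, i < j), `radius`.
#' @export
build_adjacency <- function(montage, radius = 0.8) {
  if (radius <= 0) stop("radius must be positive")
  stopifnot(nrow(montage) >= 2)
  d <- as.matrix(stats::dist(montage[, c("x", "y")]))
  edges <- which(upper.tri(d) & d <= radius, arr.ind = TRUE)
  colnames(edges) <- c("i", "j")
  structure(list(channels = montage$channel, edges = edges,
                 radius = radius),
            class = "adjacency_graph")
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("Adjacency graph:", length(x$channels), "channels,",
      nrow(x$edges), "edges (radius", x$radius, ")\n")
  invisible(x)
}

# Precompute neighbour lists over the (channel, bin) element lattice:
# spatial neighbours at the same bin, plus adjacent bins on the same
# channel (no diagonal hops). Elements are indexed channel-major:
# e = (ch - 1) * n_bins + bin.
.element_neighbours <- function(adjacency, n_ch, n_bins) {
  nb <- vector("list", n_ch * n_bins)
  ch_nb <- vector("list", n_ch)
  for (k in seq_len(nrow(adjacency$edges))) {
    i <- adjacency$edges[k, 1]; j <- adjacency$edges[k, 2]
    ch_nb[[i]] <- c(ch_nb[[i]], j)
    ch_nb[[j]] <- c(ch_nb[[j]], i)
  }
  for (ch in seq_len(n_ch)) {
    for (b in seq_len(n_bins)) {
      e <- (ch - 1L) * n_bins + b
      out <- (ch_nb[[ch]] - 1L) * n_bins + b
      if (b > 1L) out <- c(out, e - 1L)
      if (b < n_bins) out <- c(out, e + 1L)
      nb[[e]] <- out
    }
  }
  nb
}

# Vectorised per-element Welch t statistic (groups of rows of X).
.welch_t <- function(X, g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  m1 <- colMeans(X[g1, , drop = FALSE])
  m2 <- colMeans(X[g2, , drop = FALSE])
  v1 <- (colSums(X[g1, , drop = FALSE]^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(X[g2, , drop = FALSE]^2) - n2 * m2^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(stat = t, df = df)
}

# Vectorised one-way F statistic.
.oneway_f <- function(X, group_idx) {
  k <- length(group_idx)
  n <- nrow(X)
  gm <- colMeans(X)
  ssb <- 0; ssw <- 0
  for (g in group_idx) {
    ng <- length(g)
    mg <- colMeans(X[g, , drop = FALSE])
    ssb <- ssb + ng * (mg - gm)^2
    ssw <- ssw + colSums(X[g, , drop = FALSE]^2) - ng * mg^2
  }
  list(stat = (ssb / (k - 1)) / (ssw / (n - k)),
       df1 = k - 1, df2 = n - k)
}

# Connected components among supra-threshold elements; returns a list of
# integer vectors (element indices).
.components <- function(supra_idx, neighbours) {
  if (length(supra_idx) == 0) return(list())
  in_supra <- logical(length(neighbours))
  in_supra[supra_idx] <- TRUE
  visited <- logical(length(neighbours))
  comps <- list()
  for (seed in supra_idx) {
    if (visited[seed]) next
    stack <- seed
    visited[seed] <- TRUE
    members <- integer(0)
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, v)
      for (w in neighbours[[v]]) {
        if (in_supra[w] && !visited[w]) {
          visited[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    comps[[length(comps) + 1L]] <- members
  }
  comps
}

# One evaluation: stats, threshold, clusters; returns cluster masses
# (signed for t) and optionally the member sets.
.cluster_masses <- function(X, groups, stat, group_idx, neighbours,
                            cluster_alpha, keep_members = FALSE) {
  if (stat == "t") {
    ts <- .welch_t(X, group_idx[[1]], group_idx[[2]])
    crit <- stats::qt(1 - cluster_alpha / 2, ts$df)
    supra <- which(abs(ts$stat) > crit)
    vals <- ts$stat
  } else {
    fs <- .oneway_f(X, group_idx)
    crit <- stats::qf(1 - cluster_alpha, fs$df1, fs$df2)
    supra <- which(fs$stat > crit)
    vals <- fs$stat
  }
  if (length(supra) == 0) {
    return(list(masses = numeric(0), members = list(), values = vals))
  }
  # sign-separated clustering for t: positive and negative elements
  # never join the same cluster
  comps <- if (stat == "t") {
    c(.components(supra[vals[supra] > 0], neighbours),
      .components(supra[vals[supra] < 0], neighbours))
  } else {
    .components(supra, neighbours)
  }
  masses <- vapply(comps, function(m) sum(vals[m]), numeric(1))
  list(masses = masses,
       members = if (keep_members) comps else list(),
       values = vals)
}

#' Cluster-based permutation test over channel x frequency data
#'
#' Element-wise statistics (Welch t for 2 groups, one-way F for 3)
#' are thresholded at the parametric critical value for `cluster_alpha`;
#' supra-threshold elements form clusters via spatial adjacency at the
#' same frequency bin and adjacent bins on the same channel (t clusters
#' are sign-separated). Cluster mass is the sum of element statistics.
#' The null distribution of the maximum absolute cluster mass is built
#' from `n_perm` random relabellings of subjects, and each observed
#' cluster receives p = (number of permutation maxima >= its absolute
#' mass + 1) / (n_perm + 1).
#'
#' @param data numeric array subjects x channels x bins, or a
#'   subjects x channels matrix (treated as a single bin).
#' @param groups factor/character of group labels, one per subject.
#' @param stat "t" (exactly 2 groups) or "F" (exactly 3 groups).
#' @param adjacency an `adjacency_graph` over the channels.
#' @param n_perm number of permutations.
#' @param alpha significance level for flagging clusters (two tails of
#'   `alpha` each for t).
#' @param cluster_alpha element-wise cluster-forming threshold level.
#' @param seed integer seed for the permutation draws.
#' @return list of class `cluster_test_result`: `clusters` (data.frame
#'   with `mass`, `sign`, `p`, `n_elements`), `members` (list of
#'   data.frames channel/bin), `stat`, `n_permutations`, `alpha`,
#'   `cluster_alpha`, `element_stats` (channels x bins matrix).
#' @export
cluster_permutation_test <- function(data, groups, stat = c("t", "F"),
                                     adjacency, n_perm = 1000,
                                     alpha = 0.05, cluster_alpha = 0.05,
                                     seed = 1L) {
  stat <- match.arg(stat)
  if (length(dim(data)) == 2) {
    data <- array(data, c(dim(data), 1L))
  }
  stopifnot(length(dim(data)) == 3,
            dim(data)[1] == length(groups),
            dim(data)[2] == length(adjacency$channels))
  groups <- as.factor(droplevels(as.factor(groups)))
  if (stat == "t" && nlevels(groups) != 2) {
    stop("t statistic requires exactly 2 groups")
  }
  if (stat == "F" && nlevels(groups) != 3) {
    stop("F statistic requires exactly 3 groups")
  }
  if (any(table(groups) < 2)) stop("each group needs at least 2 subjects")
  n_sub <- dim(data)[1]; n_ch <- dim(data)[2]; n_bins <- dim(data)[3]
  # flatten channel-major: column e = (ch-1)*n_bins + bin
  X <- matrix(aperm(data, c(1, 3, 2)), nrow = n_sub)
  neighbours <- .element_neighbours(adjacency, n_ch, n_bins)
  group_idx <- split(seq_len(n_sub), groups)
  obs <- .cluster_masses(X, groups, stat, group_idx, neighbours,
                         cluster_alpha, keep_members = TRUE)
  rng <- local_rng(seed)
  null_max <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    perm <- sample.int(n_sub)
    pidx <- lapply(group_idx, function(ix) perm[ix])
    masses <- .cluster_masses(X, groups, stat, pidx, neighbours,
                              cluster_alpha)$masses
    null_max[p] <- if (length(masses)) max(abs(masses)) else 0
  }
  if (length(obs$masses)) {
    pvals <- vapply(obs$masses, function(m) {
      (sum(null_max >= abs(m)) + 1) / (n_perm + 1)
    }, numeric(1))
    ord <- order(abs(obs$masses), decreasing = TRUE)
    clusters <- data.frame(
      mass = obs$masses[ord],
      sign = if (stat == "t") ifelse(obs$masses[ord] > 0, "+", "-")
             else "F",
      p = pvals[ord],
      n_elements = vapply(obs$members[ord], length, integer(1))
    )
    members <- lapply(obs$members[ord], function(m) {
      data.frame(channel = adjacency$channels[(m - 1L) %/% n_bins + 1L],
                 bin = (m - 1L) %% n_bins + 1L)
    })
  } else {
    clusters <- data.frame(mass = numeric(0), sign = character(0),
                           p = numeric(0), n_elements = integer(0))
    members <- list()
  }
  structure(
    list(clusters = clusters, members = members, stat = stat,
         n_permutations = n_perm, alpha = alpha,
         cluster_alpha = cluster_alpha,
         element_stats = matrix(obs$values, nrow = n_ch, ncol = n_bins,
                                byrow = TRUE,
                                dimnames = list(adjacency$channels, NULL))),
    class = "cluster_test_result"
  )
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat("Cluster permutation test (", x$stat, "-statistic, ",
      x$n_permutations, " permutations)\n", sep = "")
  if (nrow(x$clusters) == 0) {
    cat("No supra-threshold clusters.\n")
  } else {
    print(transform(x$clusters, mass = round(mass, 2),
                    p = round(p, 4)))
  }
  invisible(x)
}

#' Post-hoc pairwise cluster tests between groups
#'
#' Runs the t-variant of [cluster_permutation_test()] for each requested
#' pair of group levels.
#'
#' @param data subjects x channels x bins array (or matrix).
#' @param groups group labels per subject.
#' @param pairs list of length-2 character vectors.
#' @param ... passed to [cluster_permutation_test()] (alpha defaults to
#'   0.025, the two-group convention).
#' @param alpha significance level per pair.
#' @return named list of `cluster_test_result`s ("A_vs_B").
#' @export
posthoc_pairwise <- function(data, groups, pairs, alpha = 0.025, ...) {
  if (length(dim(data)) == 2) data <- array(data, c(dim(data), 1L))
  groups <- as.character(groups)
  out <- list()
  for (pr in pairs) {
    stopifnot(length(pr) == 2, all(pr %in% groups))
    sel <- groups %in% pr
    res <- cluster_permutation_test(
      data[sel, , , drop = FALSE],
      factor(groups[sel], levels = pr), stat = "t",
      alpha = alpha, ...)
    out[[paste(pr, collapse = "_vs_")]] <- res
  }
  out
}
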