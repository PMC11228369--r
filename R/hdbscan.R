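#' Density-based spatial clustering (HDBSCAN)
#'
#' Hierarchical density-based clustering of points: core distances at
#' `min_samples`, mutual-reachability distances, a single-linkage hierarchy
#' (equivalent to the minimum-spanning-tree construction), condensation of
#' the hierarchy at `min_cluster_size`, and excess-of-mass cluster
#' selection on the condensed tree. Points never captured by a selected
#' cluster are noise (label 0). The root is not selectable, so structure
#' must be denser than the background to be reported.
#'
#' @param x Numeric matrix of coordinates (points x dims).
#' @param min_cluster_size Smallest cluster size reported. Default 20.
#' @param min_samples Neighborhood size for core distances; defaults to
#'   `min_cluster_size`.
#' @return Integer vector of labels, 0 = noise, 1..k = clusters (numbered
#'   by decreasing size).
#' @export
hdbscan_points <- function(x, min_cluster_size = 20,
                           min_samples = min_cluster_size) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n == 0L) return(integer(0))
  if (n < min_cluster_size || n < 2L) return(rep(0L, n))

  d <- as.matrix(stats::dist(x))
  k <- min(min_samples, n)
  core <- apply(d, 1, function(r) sort(r)[k])   # self (0) counts as 1st
  mr <- pmax(d, outer(core, core, pmax))
  diag(mr) <- 0
  hc <- stats::hclust(stats::as.dist(mr), method = "single")
  .condense_and_select(hc, n, min_cluster_size)
}

# Condensed-tree construction + excess-of-mass selection on an hclust
# single-linkage hierarchy over mutual reachability distances.
.condense_and_select <- function(hc, n, mcs) {
  merge <- hc$merge
  height <- hc$height
  nm <- nrow(merge)

  # leaves under every merge node
  leaves <- vector("list", nm)
  for (i in seq_len(nm)) {
    l <- merge[i, 1]; r <- merge[i, 2]
    leaves[[i]] <- c(
      if (l < 0) -l else leaves[[l]],
      if (r < 0) -r else leaves[[r]]
    )
  }

  lambda_of <- function(node) 1 / max(height[node], 1e-12)

  # cluster bookkeeping
  parent <- integer(0)       # parent cluster id (0 = none/root)
  birth <- numeric(0)        # lambda at cluster creation
  stability <- numeric(0)
  new_cluster <- function(p, l) {
    parent <<- c(parent, p)
    birth <<- c(birth, l)
    stability <<- c(stability, 0)
    length(parent)
  }
  point_cluster <- integer(n)   # condensed-tree cluster each point fell from

  root <- new_cluster(0L, 0)
  # stack of (merge node, cluster id) pairs
  stack <- list(c(nm, root))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top[1]; cl <- top[2]
    lam <- lambda_of(node)
    ch <- merge[node, ]
    sizes <- ifelse(ch < 0, 1L, lengths(leaves)[pmax(ch, 1L)])
    big <- sizes >= mcs

    drop_points <- function(pts, cl, lam) {
      stability[cl] <<- stability[cl] + length(pts) * (lam - birth[cl])
      point_cluster[pts] <<- cl
    }
    child_points <- function(j) if (ch[j] < 0) -ch[j] else leaves[[ch[j]]]

    if (all(big)) {
      # true split: cluster cl dies here, two children are born
      stability[cl] <- stability[cl] + sum(sizes) * (lam - birth[cl])
      for (j in 1:2) {
        cid <- new_cluster(cl, lam)
        stack[[length(stack) + 1L]] <- c(ch[j], cid)
      }
    } else if (any(big)) {
      # small side falls out, cluster continues into the big side
      small <- which(!big); keep <- which(big)
      drop_points(child_points(small), cl, lam)
      if (ch[keep] < 0) {
        drop_points(-ch[keep], cl, lam)   # cannot happen for big>=mcs>=2
      } else {
        stack[[length(stack) + 1L]] <- c(ch[keep], cl)
      }
    } else {
      # both sides below min size: all points leave, cluster ends
      drop_points(c(child_points(1), child_points(2)), cl, lam)
    }
  }

  # excess-of-mass selection, children before parents (higher ids are
  # created later, hence deeper)
  nc <- length(parent)
  children <- split(seq_len(nc)[-1], parent[-1])
  score <- stability
  selected <- rep(FALSE, nc)
  for (cl in rev(seq_len(nc))) {
    kids <- children[[as.character(cl)]]
    if (cl == root) {
      # the root never competes: subcluster structure always propagates
      selected[cl] <- FALSE
      score[cl] <- if (is.null(kids)) 0 else sum(score[kids])
    } else if (is.null(kids)) {
      selected[cl] <- TRUE
      score[cl] <- stability[cl]
    } else if (stability[cl] >= sum(score[kids])) {
      selected[cl] <- TRUE
      score[cl] <- stability[cl]
    } else {
      score[cl] <- sum(score[kids])
    }
  }
  # deselect descendants of selected clusters
  for (cl in seq_len(nc)) {
    if (selected[cl]) {
      p <- parent[cl]
      while (p != 0L) {
        if (selected[p]) { selected[cl] <- FALSE; break }
        p <- parent[p]
      }
    }
  }

  # label points by their nearest selected ancestor (or self)
  labels <- integer(n)
  sel_ids <- which(selected)
  if (length(sel_ids)) {
    map <- integer(nc)
    for (cl in seq_len(nc)) {
      p <- cl
      while (p != 0L && !selected[p]) p <- parent[p]
      map[cl] <- if (p == 0L) 0L else p
    }
    labels <- map[point_cluster]
    # renumber by decreasing size
    tab <- sort(table(labels[labels > 0]), decreasing = TRUE)
    relabel <- stats::setNames(seq_along(tab), names(tab))
    labels <- ifelse(labels > 0, relabel[as.character(labels)], 0L)
  }
  as.integer(labels)
}
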