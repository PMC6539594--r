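# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths (igraph, lm, nls).

# breadth-first search over an edge list; returns bond-count distance
bfs_bonds <- function(bonds, a, b) {
  adj <- split(c(bonds$to, bonds$from), c(bonds$from, bonds$to))
  if (a == b) return(0L)
  dist <- stats::setNames(Inf, a)
  frontier <- a
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, names(dist))
    if (length(nxt) == 0) return(Inf)
    if (b %in% nxt) return(d)
    dist[nxt] <- d
    frontier <- nxt
  }
  Inf
}

# all-pairs check helper: BFS from each vertex, compared against a matrix
bfs_all_from <- function(bonds, a) {
  adj <- split(c(bonds$to, bonds$from), c(bonds$from, bonds$to))
  dist <- stats::setNames(0L, a)
  frontier <- a
  d <- 0L
  repeat {
    d <- d + 1L
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                   names(dist))
    if (length(nxt) == 0) break
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# graph with triazole C5 atoms removed (nitrogen-side ring traversal)
drop_ring_c5 <- function(g) {
  drop <- g$atoms$id[g$atoms$role == "ring_C5"]
  list(atoms = g$atoms[!g$atoms$id %in% drop, , drop = FALSE],
       bonds = g$bonds[!(g$bonds$from %in% drop | g$bonds$to %in% drop), ,
                       drop = FALSE])
}

# brute-force OLS via the normal equations
ols_oracle <- function(X, y) {
  X <- cbind(1, as.matrix(X))
  n <- nrow(X)
  p <- ncol(X) - 1
  xtx_inv <- solve(t(X) %*% X)
  beta <- drop(xtx_inv %*% t(X) %*% y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / (n - p - 1)
  list(beta = beta,
       se = sqrt(sigma2 * diag(xtx_inv)),
       r.squared = 1 - rss / tss,
       adj.r.squared = 1 - (rss / (n - p - 1)) / (tss / (n - 1)))
}

# two-pass variance oracle
sd_oracle <- function(x) {
  m <- sum(x) / length(x)
  sqrt(sum((x - m)^2) / (length(x) - 1))
}

panel_fixture <- function() triazolopeptide_panel()
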