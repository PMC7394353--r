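# Independent brute-force oracles used to check the package's statistics.

# exhaustive two-sided Mann-Whitney: enumerate every assignment of the pooled
# values into groups of sizes n1/n2 and compare U tail masses
oracle_mw <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  obs <- u_of(x, y)
  idx <- utils::combn(length(pool), n1)
  us <- apply(idx, 2, function(i) u_of(pool[i], pool[-i]))
  p <- min(1, 2 * min(mean(us <= obs), mean(us >= obs)))
  list(U = obs, p = p)
}

# step-up Benjamini-Hochberg from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(1, adj)
  out
}

# pairwise binary distance by direct counting
oracle_binary_dist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      informative <- m[i, ] == 1 | m[j, ] == 1
      if (any(informative)) {
        d[i, j] <- sum(m[i, informative] != m[j, informative]) / sum(informative)
      }
    }
  }
  d
}

# all set partitions of n items as membership vectors
all_partitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_partitions(n - 1)) {
    out <- c(out, lapply(seq_len(max(p) + 1L), function(k) c(p, k)))
  }
  out
}

# --- independent Girvan-Newman oracle -------------------------------------
# adjacency-list graph on nodes 1..n; edges as a 2-column matrix

# edge betweenness by enumerating all shortest paths between all pairs
.oracle_betweenness <- function(n, edges) {
  m <- nrow(edges)
  eb <- numeric(m)
  adj <- lapply(seq_len(n), function(v) {
    rows <- which(edges[, 1] == v | edges[, 2] == v)
    cbind(rows, ifelse(edges[rows, 1] == v, edges[rows, 2], edges[rows, 1]))
  })
  for (s in seq_len(n - 1)) {
    # BFS from s
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      for (k in seq_len(nrow(adj[[v]]))) {
        w <- adj[[v]][k, 2]
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    for (t in (s + 1):n) {
      if (is.infinite(dist[t])) next
      # recursively enumerate all shortest s->t paths (edge-row sequences)
      paths <- list()
      walk <- function(v, used) {
        if (v == s) {
          paths[[length(paths) + 1]] <<- used
          return(invisible())
        }
        for (k in seq_len(nrow(adj[[v]]))) {
          w <- adj[[v]][k, 2]
          if (dist[w] == dist[v] - 1) walk(w, c(used, adj[[v]][k, 1]))
        }
      }
      walk(t, integer(0))
      for (pth in paths) eb[pth] <- eb[pth] + 1 / length(paths)
    }
  }
  eb
}

.oracle_components <- function(n, edges) {
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(edges))) {
      a <- comp[edges[r, 1]]; b <- comp[edges[r, 2]]
      if (a != b) {
        comp[comp == max(a, b)] <- min(a, b)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  as.integer(factor(comp))
}

.oracle_modularity <- function(n, edges, mem) {
  m <- nrow(edges)
  if (m == 0) return(0)
  deg <- tabulate(c(edges[, 1], edges[, 2]), n)
  q <- 0
  for (r in seq_len(m)) {
    if (mem[edges[r, 1]] == mem[edges[r, 2]]) q <- q + 1
  }
  q / m - sum(tapply(deg, mem, sum)^2) / (2 * m)^2
}

# full Girvan-Newman: remove the highest-betweenness edge (ties: first in
# lexicographic edge order), track the component partition, return the best
# modularity over the whole removal sequence (modularity always scored on
# the original graph)
oracle_girvan_newman <- function(n, edges) {
  edges0 <- edges
  best_q <- .oracle_modularity(n, edges0, .oracle_components(n, edges))
  best_mem <- .oracle_components(n, edges)
  work <- edges
  while (nrow(work) > 0) {
    eb <- .oracle_betweenness(n, work)
    drop <- which.max(eb) # which.max takes the first of tied maxima
    work <- work[-drop, , drop = FALSE]
    mem <- .oracle_components(n, work)
    q <- .oracle_modularity(n, edges0, mem)
    if (q > best_q + 1e-12) {
      best_q <- q
      best_mem <- mem
    }
  }
  list(modularity = best_q, membership = best_mem)
}

# small random undirected simple graph as a bait/prey edge data frame
random_small_graph <- function(n, p_edge) {
  repeat {
    pairs <- utils::combn(n, 2)
    keep <- stats::runif(ncol(pairs)) < p_edge
    if (any(keep)) break
  }
  data.frame(bait = paste0("n", pairs[1, keep]),
             prey = paste0("n", pairs[2, keep]),
             stringsAsFactors = FALSE)
}
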