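# Independent brute-force oracles and small fixture builders used across
# the suite.  These deliberately avoid the code paths they check.

# Connected components of an edge list by breadth-first search over an
# adjacency list; returns a set of components, each a sorted vector of
# "i-j" edge keys.
bfs_component_keys <- function(edges, n) {
  if (nrow(edges) == 0L) return(list())
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  visited <- rep(FALSE, n)
  comp_id <- rep(NA_integer_, n)
  cid <- 0L
  for (s in sort(unique(as.vector(edges)))) {
    if (visited[s]) next
    cid <- cid + 1L
    queue <- s; visited[s] <- TRUE
    while (length(queue) > 0L) {
      v <- queue[1L]; queue <- queue[-1L]
      comp_id[v] <- cid
      for (w in adj[[v]]) {
        if (!visited[w]) { visited[w] <- TRUE; queue <- c(queue, w) }
      }
    }
  }
  keys <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]), sep = "-")
  unname(lapply(split(keys, comp_id[edges[, 1]]), sort))
}

# canonical representation of a component list from suprathreshold_components
component_keys <- function(comps) {
  unname(lapply(comps, function(e) {
    sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "-"))
  }))
}

# set equality of two lists of sorted key vectors
same_component_sets <- function(a, b) {
  setequal(vapply(a, paste, "", collapse = ","),
           vapply(b, paste, "", collapse = ","))
}

# Benjamini-Hochberg step-up written straight from the definition
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (k in n:1) {
    prev <- min(prev, p[o[k]] * n / k, 1)
    q[o[k]] <- prev
  }
  q
}

# partial Spearman through lm() residuals (independent of the qr path)
brute_partial_spearman <- function(x, y, cov) {
  rx <- rank(x); ry <- rank(y)
  ex <- stats::resid(stats::lm(rx ~ cov))
  ey <- stats::resid(stats::lm(ry ~ cov))
  sum(ex * ey) / sqrt(sum(ex^2) * sum(ey^2))
}

# Exhaustive hypergeometric upper tail: probability that a random target of
# the given size drawn from the background overlaps the term in at least
# k_obs genes, by enumerating every possible target.
enum_hyper_tail <- function(background, term, target_size, k_obs) {
  memb <- background %in% term
  combos <- utils::combn(length(background), target_size)
  overlap <- colSums(matrix(memb[combos], nrow = target_size))
  mean(overlap >= k_obs)
}

# quick symmetric connectome from an upper-triangular weight spec
make_conn <- function(n, edges, weights, modality = "functional") {
  m <- matrix(0, n, n)
  for (r in seq_along(weights)) {
    m[edges[r, 1], edges[r, 2]] <- weights[r]
    m[edges[r, 2], edges[r, 1]] <- weights[r]
  }
  as_connectome(m, modality)
}

# small fixed atlas reused by several files
tiny_atlas <- function() generate_atlas(20, 4, seed = 11)
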