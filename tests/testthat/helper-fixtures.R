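# Shared fixtures, all built in code.

# small hand-made parcellation: n regions per hemisphere on mirrored circles
toy_parcellation <- function(n_per_hemi = 4, network_id = NULL) {
  theta <- seq(0, pi, length.out = n_per_hemi + 2)[2:(n_per_hemi + 1)]
  right <- cbind(x = rep(0.5, n_per_hemi),
                 y = sqrt(0.75) * cos(theta),
                 z = sqrt(0.75) * sin(theta))
  left <- right; left[, 1] <- -left[, 1]
  xyz <- rbind(left, right)
  hemi <- rep(c("L", "R"), each = n_per_hemi)
  labels <- sprintf("%s%02d", hemi, rep(seq_len(n_per_hemi), 2))
  parcellation(labels, hemi, xyz, sphere_xyz = xyz, network_id = network_id)
}

# network from an explicit edge list on a toy parcellation
toy_network <- function(parc, edges, kind = "structural") {
  n <- parc$n_regions
  m <- matrix(0, n, n)
  for (e in edges) {
    m[e[1], e[2]] <- e[3]
    m[e[2], e[1]] <- e[3]
  }
  network(m, parc, kind = kind)
}

# random connected weighted graph (used against brute-force oracles)
random_connected_network <- function(parc, density = 0.5, seed = 1) {
  n <- parc$n_regions
  set.seed(seed)
  repeat {
    m <- matrix(0, n, n)
    ut <- upper.tri(m)
    present <- stats::runif(sum(ut)) < density
    w <- numeric(sum(ut))
    w[present] <- stats::runif(sum(present), 0.2, 2)
    m[ut] <- w
    m <- m + t(m)
    g <- igraph::graph_from_adjacency_matrix(m != 0, mode = "undirected")
    if (igraph::is_connected(g)) return(network(m, parc, kind = "structural"))
  }
}

# default synthetic study used by several integration tests (built once)
shared_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synth_spec(seed = 42)
      parc <- make_parcellation(spec)
      stack <- make_subject_connectomes(parc, spec)
      cons <- suppressWarnings(group_consensus(stack, parc))
      wcons <- weight_consensus(stack, cons, parc)
      cache <<- list(spec = spec, parc = parc, stack = stack,
                     consensus = cons, weighted = wcons)
    }
    cache
  }
})

# brute-force betweenness/closeness oracle: enumerate all simple paths
# between every pair, find the shortest-length ones, and count traversals
brute_force_paths <- function(w) {
  n <- nrow(w)
  lens <- ifelse(w > 0, 1 / w, Inf)
  btw <- numeric(n)
  dist_mat <- matrix(0, n, n)
  all_paths <- function(a, b) {
    paths <- list()
    walk <- function(path, len) {
      last <- path[length(path)]
      if (last == b) {
        paths[[length(paths) + 1]] <<- list(path = path, len = len)
        return()
      }
      for (v in seq_len(n)) {
        if (lens[last, v] < Inf && !(v %in% path))
          walk(c(path, v), len + lens[last, v])
      }
    }
    walk(a, 0)
    paths
  }
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    ps <- all_paths(a, b)
    best <- min(vapply(ps, function(p) p$len, numeric(1)))
    short <- Filter(function(p) abs(p$len - best) < 1e-12, ps)
    dist_mat[a, b] <- dist_mat[b, a] <- best
    for (p in short) {
      inner <- setdiff(p$path, c(a, b))
      # each unordered pair contributes twice (ordered pairs)
      btw[inner] <- btw[inner] + 2 / length(short)
    }
  }
  list(betweenness = btw / ((n - 1) * (n - 2)),
       closeness = rowSums(dist_mat) / (n - 1))
}

# brute-force dominance oracle: direct definition via lm() on every subset
brute_force_dominance <- function(x, y) {
  p <- ncol(x)
  r2_of <- function(cols) {
    if (length(cols) == 0) return(0)
    summary(stats::lm(y ~ x[, cols, drop = FALSE]))$r.squared
  }
  subsets_of <- function(v) {
    # full power set by bitmask (avoids combn's scalar-expansion trap)
    out <- list(integer(0))
    for (mask in seq_len(max(0, 2^length(v) - 1)))
      out[[mask + 1]] <- v[bitwAnd(mask, bitwShiftL(1L, seq_along(v) - 1L)) > 0]
    out
  }
  vapply(seq_len(p), function(i) {
    others <- setdiff(seq_len(p), i)
    subs <- subsets_of(others)
    sizes <- lengths(subs)
    incs <- vapply(subs, function(s) r2_of(c(s, i)) - r2_of(s), numeric(1))
    mean(vapply(0:(p - 1), function(k) mean(incs[sizes == k]), numeric(1)))
  }, numeric(1))
}
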