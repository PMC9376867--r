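# Independent brute-force oracles, kept deliberately naive: scalar products
# in probability space, flood-fill connectivity via union-find.

# direct product evaluation of the core-model pattern probability
oracle_p_core <- function(m, cw) {
  M <- unclass(m)
  vapply(colnames(M), function(t) {
    p <- 1
    for (g in rownames(M))
      p <- p * if (M[g, t]) cw[g] else 1 - cw[g]
    p
  }, numeric(1))
}

# direct product evaluation of the accessory-model pattern probability
oracle_p_accessory <- function(m, cw, core_size) {
  M <- unclass(m)
  f <- colSums(M) / sum(M)
  vapply(colnames(M), function(t) {
    p <- 1
    for (g in rownames(M)) {
      e <- max(0, sum(M[g, ]) - cw[g] * core_size)
      pbar <- (1 - f[t])^e
      p <- p * if (M[g, t]) 1 - pbar else pbar
    }
    p
  }, numeric(1))
}

random_trait_matrix <- function(n_genomes, n_traits) {
  repeat {
    m <- matrix(stats::runif(n_genomes * n_traits) < 0.5, n_genomes, n_traits,
                dimnames = list(sprintf("g%d", seq_len(n_genomes)),
                                sprintf("t%d", seq_len(n_traits))))
    if (all(colSums(m) > 0) && sum(m) > max(colSums(m))) # no empty or
      return(trait_matrix(m))                            # single-trait pool
  }
}

# connected components by union-find with path compression
oracle_components <- function(vertices, edge_a, edge_b) {
  parent <- stats::setNames(vertices, vertices)
  find <- function(v) {
    while (parent[[v]] != v) {
      parent[[v]] <<- parent[[parent[[v]]]]
      v <- parent[[v]]
    }
    v
  }
  for (i in seq_along(edge_a)) {
    ra <- find(edge_a[i]); rb <- find(edge_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(vertices, find, "")
  unname(lapply(split(vertices, roots), sort))
}

# canonical form for comparing clusterings irrespective of labels/order
canon_clusters <- function(cl) {
  cl <- unname(lapply(cl, sort))
  cl[order(vapply(cl, `[[`, "", 1))]
}
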