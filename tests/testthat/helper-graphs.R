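# shared test helpers: small random graphs and reference computations

# random simple undirected labeled graph with <= max_n vertices
random_labeled_graph <- function(max_n = 6, labels = letters[1:3],
                                 edge_prob = 0.5) {
  n <- sample.int(max_n, 1L)
  labs <- sample(labels, n, replace = TRUE)
  edges <- matrix(integer(0), 0L, 2L)
  if (n > 1L) {
    all_e <- t(utils::combn(n, 2L))
    edges <- all_e[stats::runif(nrow(all_e)) < edge_prob, , drop = FALSE]
  }
  labeled_graph(labs, edges)
}

# geometric tail bound of the truncated kernel series
kernel_tail_bound <- function(params, max_len) {
  ll <- params$lambda1 * params$lambda2
  ll^(max_len + 1) / (1 - ll)
}

# reference joint-walk enumeration by explicit recursion over walk pairs;
# exponential, so only usable for tiny graphs and short walks
enumerate_joint_walks_recursive <- function(g1, g2, m, params, max_len) {
  u1 <- start_distribution(g1)
  u2 <- start_distribution(g2)
  t1 <- as.matrix(transition_matrix(g1))
  t2 <- as.matrix(transition_matrix(g2))
  ll <- params$lambda1 * params$lambda2
  total <- 0
  recurse <- function(i, j, weight, depth) {
    total <<- total + weight
    if (depth == max_len) return(invisible())
    for (i2 in which(t1[, i] > 0)) {
      for (j2 in which(t2[, j] > 0)) {
        w <- weight * ll * t1[i2, i] * t2[j2, j] * m[i2, j2]
        if (w > 0) recurse(i2, j2, w, depth + 1L)
      }
    }
  }
  for (i in seq_along(u1)) {
    for (j in seq_along(u2)) {
      w <- u1[i] * u2[j] * m[i, j]
      if (w > 0) recurse(i, j, w, 0L)
    }
  }
  (1 - params$lambda1) * (1 - params$lambda2) * total
}

# all label sequences of walks of length `len` (edges traversed),
# starting anywhere with positive start weight, on a labeled_graph
walk_label_sequences <- function(g, len) {
  t_ <- as.matrix(transition_matrix(g))
  seqs <- character(0)
  step <- function(v, labs, d) {
    if (d == len) {
      seqs <<- c(seqs, paste(labs, collapse = ","))
      return(invisible())
    }
    for (w in which(t_[, v] > 0)) step(w, c(labs, g$labels[w]), d + 1L)
  }
  starts <- which(start_distribution(g) > 0)
  for (v in starts) step(v, g$labels[v], 0L)
  sort(unique(seqs))
}

# label sequences of non-tottering walks enumerated directly on the
# original undirected graph
non_tottering_label_sequences <- function(g, len) {
  adj <- lapply(seq_len(n_vertices(g)), function(v) {
    nb <- c(g$edges[g$edges[, 1L] == v, 2L], g$edges[g$edges[, 2L] == v, 1L])
    sort(nb)
  })
  seqs <- character(0)
  step <- function(v, prev, labs, d) {
    if (d == len) {
      seqs <<- c(seqs, paste(labs, collapse = ","))
      return(invisible())
    }
    for (w in adj[[v]]) {
      if (!is.na(prev) && w == prev) next
      step(w, v, c(labs, g$labels[w]), d + 1L)
    }
  }
  for (v in seq_len(n_vertices(g))) step(v, NA, g$labels[v], 0L)
  sort(unique(seqs))
}

# tiny two-class fixture used by several reaction-level tests
small_fixture <- function(seed = 7) {
  generate_reaction_classes(fixture_spec(
    seed = seed, n_classes = 2L, reactions_per_class = 3L,
    scaffold_size = c(4L, 6L), decoration_rate = 0.2,
    cofactor_pool = 4L))
}

fast_params <- function() walk_params(0.9, 0.9, 1e-9, 100L)
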