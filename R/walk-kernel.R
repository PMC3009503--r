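#' Random-walk kernel parameters
#'
#' A walk on each graph continues with probability lambda and terminates
#' with probability 1 - lambda at every step, so the joint walk length is
#' geometric and the kernel series converges whenever both lambdas are
#' strictly inside (0, 1). The fixed-point iteration contracts with factor
#' lambda1 * lambda2; with the defaults (0.9, tol 1e-9) a few dozen to
#' ~100 iterations suffice.
#'
#' @param lambda1 continuation probability on the first graph, in (0, 1).
#' @param lambda2 continuation probability on the second graph; defaults
#'   to `lambda1`.
#' @param tol convergence tolerance on the fixed-point residual (sum of
#'   absolute elementwise changes).
#' @param max_iter iteration cap.
#' @return an object of class `walk_params`.
#' @export
walk_params <- function(lambda1 = 0.9, lambda2 = lambda1,
                        tol = 1e-9, max_iter = 100L) {
  if (!is.numeric(lambda1) || lambda1 <= 0 || lambda1 >= 1 ||
      !is.numeric(lambda2) || lambda2 <= 0 || lambda2 >= 1) {
    stop("lambda must lie strictly in (0, 1)")
  }
  if (!is.numeric(tol) || tol <= 0) stop("tol must be positive")
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L) stop("max_iter must be >= 1")
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 tol = tol, max_iter = max_iter),
            class = "walk_params")
}

#' Degree-normalized transition matrix
#'
#' Column-stochastic transition matrix of the simple random walk:
#' entry (i, j) is 1/deg(j) if there is an edge (arc) from j to i, else 0.
#' Columns of isolated vertices (or sinks, in directed graphs) are all
#' zero: a walk that starts there emits one label and then terminates.
#'
#' @param g a [labeled_graph()].
#' @return a sparse column-stochastic (or substochastic) `Matrix`.
#' @export
transition_matrix <- function(g) {
  n <- n_vertices(g)
  if (n_edges(g) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(n, n)))
  }
  if (g$directed) {
    from <- g$edges[, 1L]
    to <- g$edges[, 2L]
  } else {
    from <- c(g$edges[, 1L], g$edges[, 2L])
    to <- c(g$edges[, 2L], g$edges[, 1L])
  }
  outdeg <- tabulate(from, nbins = n)
  Matrix::sparseMatrix(i = to, j = from, x = 1 / outdeg[from],
                       dims = c(n, n))
}

#' Dirac label-match matrix
#'
#' The simplest vertex-match matrix M: entry (i, j) is 1 when the i-th
#' label of the first list equals the j-th label of the second, else 0.
#'
#' @param labels1,labels2 character vectors of vertex labels.
#' @return a binary |V1| x |V2| matrix.
#' @export
dirac_match <- function(labels1, labels2) {
  outer(as.character(labels1), as.character(labels2), "==") * 1
}

.check_match_matrix <- function(m, n1, n2) {
  m <- as.matrix(m)
  if (nrow(m) != n1 || ncol(m) != n2) {
    stop(sprintf("match matrix is %dx%d but graphs have %d and %d vertices",
                 nrow(m), ncol(m), n1, n2))
  }
  if (any(m < -1e-12) || any(m > 1 + 1e-12)) {
    stop("match matrix entries must lie in [0, 1]")
  }
  pmin(pmax(m, 0), 1)
}

#' Random-walk graph kernel between two labeled graphs
#'
#' Similarity of two graphs as the probability that simultaneous,
#' independent random walks on them generate matching label sequences.
#' Matching is gated at every step by the vertex-match matrix `m` (Dirac
#' on labels at the compound level, lower-level kernel values at the
#' reaction level). With U(0) the outer product of the two start
#' distributions and V(0) = M * U(0) (elementwise), the matched joint
#' walk mass solves the fixed point
#'
#'   V = V(0) + M * (lambda1 lambda2 T1 V T2'),
#'
#' iterated from V(0) until the L1 residual drops below `tol`. The kernel
#' value is (1 - lambda1)(1 - lambda2) times the total mass of V, i.e.
#' the probability that both walks terminate having emitted a common,
#' fully matched label sequence. Each update costs two sparse
#' matrix products plus one elementwise mask, i.e.
#' O(|E1||V2| + |E2||V1| + |V1||V2|).
#'
#' @param g1,g2 [labeled_graph()] objects.
#' @param m vertex-match matrix, |V1| x |V2| with entries in \[0, 1\];
#'   defaults to the Dirac kernel on the vertex labels.
#' @param params a [walk_params()].
#' @return the kernel value, with attributes `iterations`, `converged`
#'   and `residual`. A warning is emitted if `max_iter` is reached before
#'   the residual drops below `tol`.
#' @examples
#' g <- labeled_graph(c("a", "b"), rbind(c(1, 2)))
#' walk_kernel(g, g)  # self-similarity of a two-vertex path
#' @export
walk_kernel <- function(g1, g2, m = NULL, params = walk_params()) {
  stopifnot(inherits(g1, "labeled_graph"), inherits(g2, "labeled_graph"),
            inherits(params, "walk_params"))
  if (is.null(m)) m <- dirac_match(g1$labels, g2$labels)
  m <- .check_match_matrix(m, n_vertices(g1), n_vertices(g2))
  u1 <- start_distribution(g1)
  u2 <- start_distribution(g2)
  scale <- (1 - params$lambda1) * (1 - params$lambda2)
  v0 <- m * tcrossprod(u1, u2)
  if (all(v0 == 0)) {
    # no matching start pair: no propagated term can become nonzero either
    return(structure(0, iterations = 0L, converged = TRUE, residual = 0))
  }
  t1 <- transition_matrix(g1)
  t2t <- Matrix::t(transition_matrix(g2))
  ll <- params$lambda1 * params$lambda2
  v <- v0
  iter <- 0L
  residual <- Inf
  while (iter < params$max_iter) {
    iter <- iter + 1L
    v_new <- v0 + m * as.matrix(ll * (t1 %*% v %*% t2t))
    residual <- sum(abs(v_new - v))
    v <- v_new
    if (residual < params$tol) break
  }
  converged <- residual < params$tol
  if (!converged) {
    warning(sprintf(
      "walk_kernel did not converge in %d iterations (residual %.3g)",
      params$max_iter, residual))
  }
  structure(scale * sum(v), iterations = iter, converged = converged,
            residual = residual)
}

#' Truncated joint-walk enumeration (test oracle)
#'
#' Evaluates the defining series of the walk kernel directly: the joint
#' walk over the two graphs is a walk on the Kronecker-product state
#' space, and the length-t term is obtained by applying the dense joint
#' step operator (match mask times lambda1 lambda2 T1 (x) T2) t times to
#' the matched joint start distribution. Summing terms for t = 0..max_len
#' enumerates every joint walk of length at most `max_len` exactly once,
#' so the result differs from the full kernel by at most the geometric
#' tail (lambda1 lambda2)^(max_len + 1) / (1 - lambda1 lambda2).
#'
#' This routine builds the dense |V1||V2| x |V1||V2| operator and is a
#' verification oracle only; it refuses inputs beyond a small guard.
#'
#' @param g1,g2 [labeled_graph()] objects with |V1| * |V2| <= 100.
#' @param m vertex-match matrix (default Dirac on labels).
#' @param params a [walk_params()] (only the lambdas are used).
#' @param max_len maximum joint walk length, at most 30.
#' @return truncated kernel value.
#' @export
walk_kernel_enumerate <- function(g1, g2, m = NULL, params = walk_params(),
                                  max_len = 25L) {
  stopifnot(inherits(g1, "labeled_graph"), inherits(g2, "labeled_graph"))
  n1 <- n_vertices(g1)
  n2 <- n_vertices(g2)
  if (n1 * n2 > 100L || max_len > 30L) {
    stop("walk_kernel_enumerate is a test oracle: requires ",
         "|V1|*|V2| <= 100 and max_len <= 30")
  }
  if (is.null(m)) m <- dirac_match(g1$labels, g2$labels)
  m <- .check_match_matrix(m, n1, n2)
  u1 <- start_distribution(g1)
  u2 <- start_distribution(g2)
  # vec() column-major: vec(T1 V T2') = (T2 (x) T1) vec(V)
  step <- kronecker(as.matrix(transition_matrix(g2)),
                    as.matrix(transition_matrix(g1)))
  ll <- params$lambda1 * params$lambda2
  mvec <- as.vector(m)
  x <- mvec * as.vector(tcrossprod(u1, u2))
  total <- sum(x)
  for (t in seq_len(max_len)) {
    x <- mvec * (ll * (step %*% x))
    total <- total + sum(x)
  }
  (1 - params$lambda1) * (1 - params$lambda2) * total
}

#' Kernel Gram matrix over a list of graphs
#'
#' @param graphs list of [labeled_graph()] objects.
#' @param match_fn function(g1, g2) returning a vertex-match matrix;
#'   defaults to the Dirac kernel on vertex labels.
#' @param params a [walk_params()].
#' @return symmetric matrix of kernel values, with graph ids as dimnames
#'   when available, and an attribute `non_converged` counting kernel
#'   evaluations that hit `max_iter`.
#' @export
gram_matrix <- function(graphs, match_fn = NULL, params = walk_params()) {
  n <- length(graphs)
  if (n == 0L) stop("gram_matrix needs at least one graph")
  if (is.null(match_fn)) {
    match_fn <- function(a, b) dirac_match(a$labels, b$labels)
  }
  k <- matrix(0, n, n)
  non_converged <- 0L
  for (i in seq_len(n)) {
    for (j in i:n) {
      val <- withCallingHandlers(
        tryCatch(
          walk_kernel(graphs[[i]], graphs[[j]],
                      match_fn(graphs[[i]], graphs[[j]]), params),
          error = function(e) {
            stop(sprintf("walk_kernel failed for pair (%d, %d): %s",
                         i, j, conditionMessage(e)), call. = FALSE)
          }),
        warning = function(w) {
          non_converged <<- non_converged + 1L
          invokeRestart("muffleWarning")
        })
      k[i, j] <- k[j, i] <- as.numeric(val)
    }
  }
  ids <- vapply(graphs, function(g) {
    if (is.null(g$id)) NA_character_ else as.character(g$id)
  }, character(1))
  if (!anyNA(ids)) dimnames(k) <- list(ids, ids)
  structure(k, non_converged = non_converged)
}

#' Cosine-normalize a Gram matrix
#'
#' k'(i, j) = k(i, j) / sqrt(k(i, i) k(j, j)), giving unit diagonal and
#' (by Cauchy-Schwarz, for a PSD input) entries in \[0, 1\] -- the range
#' the upper-level kernel requires of its vertex-match matrix.
#'
#' @param k symmetric kernel matrix with strictly positive diagonal.
#' @return normalized matrix with unit diagonal.
#' @export
normalize_gram <- function(k) {
  k <- as.matrix(k)
  d <- diag(k)
  if (any(d <= 0)) {
    who <- which(d <= 0)
    nm <- if (!is.null(rownames(k))) rownames(k)[who] else who
    stop("zero or negative self-kernel for: ", paste(nm, collapse = ", "))
  }
  s <- sqrt(d)
  out <- k / tcrossprod(s, s)
  if (any(out > 1 + 1e-8) || any(out < -1e-8)) {
    stop("normalized entries escape [0, 1] beyond numerical tolerance; ",
         "input is not a valid Gram matrix")
  }
  out <- pmin(pmax(out, 0), 1)
  diag(out) <- 1
  attr(out, "non_converged") <- attr(k, "non_converged")
  out
}

#' Write or read a Gram matrix as TSV
#'
#' Plain-text exchange format: a header row of graph IDs and a leading ID
#' column, with full numeric precision.
#'
#' @param k matrix with dimnames.
#' @param path file path.
#' @return `read_gram_tsv()`: the matrix; `write_gram_tsv()`: `path`,
#'   invisibly.
#' @export
write_gram_tsv <- function(k, path) {
  if (is.null(rownames(k))) {
    dimnames(k) <- list(paste0("g", seq_len(nrow(k))),
                        paste0("g", seq_len(ncol(k))))
  }
  df <- data.frame(id = rownames(k),
                   format(k, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gram_tsv
#' @export
read_gram_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  k <- as.matrix(df[, -1L, drop = FALSE])
  rownames(k) <- df[[1L]]
  storage.mode(k) <- "double"
  k
}
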