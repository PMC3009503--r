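#' Filter a reaction database before evaluation
#'
#' Removes reactions that cannot support supervised EC prediction:
#' (i) reactions without an EC number; (ii) reactions involving a
#' compound whose structure is unavailable; (iv) reactions whose EC
#' contains a 97 or 99 component (the catch-all "other" categories);
#' (v) reactions that are the only member of their EC subsubclass.
#' The numbering deliberately skips (iii): the filter set is the four
#' rules above. Filter (v) runs last and iterates to a fixed point,
#' since removing a reaction can orphan another subsubclass.
#'
#' @param records list of [reaction_record()]s.
#' @param has_structure predicate `function(compound_id) -> logical`;
#'   defaults to accepting everything.
#' @param verbose log per-filter removal counts via `message()`.
#' @return the retained records, with a `removed` attribute: a data frame
#'   of (filter, n_removed).
#' @export
filter_reactions <- function(records, has_structure = NULL,
                             verbose = TRUE) {
  if (is.null(has_structure)) has_structure <- function(id) TRUE
  if (is.null(names(records))) {
    names(records) <- vapply(records, function(r) r$reaction_id,
                             character(1))
  }
  log <- data.frame(filter = character(0), n_removed = integer(0))
  note <- function(name, n) {
    log <<- rbind(log, data.frame(filter = name, n_removed = n))
    if (verbose) message(sprintf("filter %s removed %d reaction(s)",
                                 name, n))
  }
  ecs <- vapply(records, function(r) r$ec, character(1))

  keep <- !is.na(ecs)
  note("i_no_ec", sum(!keep))
  records <- records[keep]

  keep <- vapply(records, function(r) {
    all(vapply(c(r$substrates, r$products), has_structure, logical(1)))
  }, logical(1))
  note("ii_missing_structure", sum(!keep))
  records <- records[keep]

  keep <- vapply(records, function(r) {
    !any(ec_number(r$ec)[1L, 1:3] %in% c("97", "99"))
  }, logical(1))
  note("iv_class_97_99", sum(!keep))
  records <- records[keep]

  removed_v <- 0L
  repeat {
    sub3 <- vapply(records, function(r) ec_prefix(r$ec, 3L), character(1))
    counts <- table(sub3)
    keep <- counts[sub3] >= 2L
    if (all(keep)) break
    removed_v <- removed_v + sum(!keep)
    records <- records[keep]
    if (length(records) == 0L) break
  }
  note("v_singleton_subsubclass", removed_v)

  attr(records, "removed") <- log
  records
}

#' Z-scores of a candidate score list
#'
#' (x - mu) / sigma with the population standard deviation over the
#' candidate scores. A constant list has sigma = 0; it yields an all-zero
#' vector carrying attribute `degenerate = TRUE`.
#'
#' @param scores numeric vector, length >= 2.
#' @return numeric vector of Z-scores.
#' @export
zscore <- function(scores) {
  scores <- as.numeric(scores)
  if (length(scores) < 2L) {
    stop("zscore needs at least 2 scores")
  }
  mu <- mean(scores)
  sigma <- sqrt(mean((scores - mu)^2))
  if (sigma == 0) {
    return(structure(rep(0, length(scores)), degenerate = TRUE))
  }
  (scores - mu) / sigma
}

# rank candidates from a named similarity vector and the matching ECs:
# neighbors sorted by similarity (stable on database order), candidate
# ECs deduplicated by first (= best) occurrence
.candidates_from_sims <- function(sims, ecs, ids, k) {
  no_support <- all(sims == 0)
  ord <- order(-sims)  # stable: ties keep database order
  first <- !duplicated(ecs[ord])
  cand <- data.frame(
    rank = NA_integer_,
    ec = ecs[ord][first],
    score = sims[ord][first],
    neighbor = ids[ord][first],
    stringsAsFactors = FALSE, row.names = NULL)
  cand$zscore <- if (nrow(cand) >= 2L && !no_support) {
    zscore(cand$score)
  } else {
    rep(NA_real_, nrow(cand))
  }
  cand <- utils::head(cand, k)
  cand$rank <- seq_len(nrow(cand))
  attr(cand, "no_support") <- no_support
  cand
}

#' Kernel nearest-neighbor EC prediction
#'
#' Scores the query against every database reaction with the normalized
#' reaction graph kernel, ranks the neighbors, and reports the top-k
#' distinct candidate EC numbers. Each candidate's raw score is the
#' similarity of its best neighbor; Z-scores are computed over the
#' candidate scores so that a saliently strong candidate stands out.
#' Ties are broken by database insertion order (stable sort). If every
#' similarity is zero the prediction is flagged `no_support` and the
#' candidates are emitted in database order with undefined Z-scores.
#'
#' @param query a `reaction_graph` (see [build_reaction_graph()]).
#' @param db list of labeled `reaction_graph`s (their `ec` fields must be
#'   set); must be nonempty.
#' @param compound_gram normalized compound Gram covering query and db
#'   compounds.
#' @param k number of candidate ECs to report.
#' @param params a [walk_params()].
#' @param non_tottering see [reaction_kernel()].
#' @param min_score rejection threshold: if the best similarity falls
#'   below it the predictor abstains (`rejected = TRUE`, no candidates).
#'   Default 0 (never abstain).
#' @return a `prediction` object: list with `query`, `candidates` (data
#'   frame rank/ec/score/zscore/neighbor), `rejected`, `no_support`.
#' @export
knn_predict <- function(query, db, compound_gram, k = 5L,
                        params = walk_params(), non_tottering = TRUE,
                        min_score = 0) {
  if (length(db) == 0L) stop("knn_predict: empty database")
  ecs <- vapply(db, function(r) r$ec, character(1))
  if (anyNA(ecs)) stop("knn_predict: database reactions must carry ECs")
  qg <- .reaction_walk_graph(query, non_tottering)
  qk <- as.numeric(walk_kernel(
    qg, qg, .reaction_match_matrix(qg$labels, qg$labels, compound_gram),
    params))
  sims <- vapply(db, function(r) {
    dg <- .reaction_walk_graph(r, non_tottering)
    dk <- as.numeric(walk_kernel(
      dg, dg, .reaction_match_matrix(dg$labels, dg$labels, compound_gram),
      params))
    as.numeric(reaction_kernel(query, r, compound_gram, params,
                               non_tottering)) / (sqrt(qk) * sqrt(dk))
  }, numeric(1))
  ids <- vapply(db, function(r) r$reaction_id, character(1))
  .prediction(query$reaction_id, sims, ecs, ids, k, min_score)
}

.prediction <- function(query_id, sims, ecs, ids, k, min_score = 0) {
  cand <- .candidates_from_sims(sims, ecs, ids, k)
  rejected <- min_score > 0 && max(sims) < min_score
  structure(
    list(query = query_id,
         candidates = if (rejected) cand[0, ] else cand,
         rejected = rejected,
         no_support = attr(cand, "no_support")),
    class = "prediction")
}

#' @export
print.prediction <- function(x, ...) {
  cat(sprintf("<prediction for %s%s>\n", x$query,
              if (x$rejected) " (rejected)" else ""))
  if (nrow(x$candidates) > 0L) print(x$candidates, row.names = FALSE)
  invisible(x)
}

#' Leave-one-out evaluation of kernel nearest-neighbor EC prediction
#'
#' Withholds each reaction in turn and predicts its EC from all the
#' others. The full normalized reaction Gram matrix is computed once;
#' excluding the held-out reaction amounts to masking its row and column,
#' which is exact because kernel values between the remaining reactions
#' do not depend on the held-out one. A top-1 prediction is correct at
#' level d when it agrees with the truth on the first d EC fields
#' (1 = class, 2 = subclass, 3 = subsubclass).
#'
#' @param reactions list of labeled `reaction_graph`s (>= 2).
#' @param compound_gram normalized compound Gram matrix.
#' @param params a [walk_params()].
#' @param non_tottering see [reaction_kernel()].
#' @param k candidates kept per query (accuracy uses the top-1 only).
#' @param min_score rejection threshold; rejected queries are excluded
#'   from accuracy and counted against coverage.
#' @param gram optionally a precomputed normalized reaction Gram matrix
#'   (indexed like `reactions`) to reuse across modes/levels.
#' @return list with `accuracy` (named vector over levels 1..3, in
#'   percent), `coverage` (percent of queries answered), and `table`
#'   (per-query data frame: query, truth, predicted EC, score, zscore,
#'   neighbor, correct_l1..l3, rejected).
#' @export
loo_evaluate <- function(reactions, compound_gram,
                         params = walk_params(), non_tottering = TRUE,
                         k = 5L, min_score = 0, gram = NULL) {
  n <- length(reactions)
  if (n < 2L) stop("leave-one-out needs at least 2 reactions")
  ecs <- vapply(reactions, function(r) r$ec, character(1))
  if (anyNA(ecs)) stop("all reactions must carry EC numbers")
  ids <- vapply(reactions, function(r) r$reaction_id, character(1))
  if (is.null(gram)) {
    gram <- reaction_gram_matrix(reactions, compound_gram, params,
                                 non_tottering, normalize = TRUE)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sims <- gram[i, -i]
    pred <- .prediction(ids[i], sims, ecs[-i], ids[-i], k, min_score)
    top <- if (nrow(pred$candidates) >= 1L) pred$candidates[1L, ] else NULL
    rows[[i]] <- data.frame(
      query = ids[i],
      truth = ecs[i],
      ec = if (is.null(top)) NA_character_ else top$ec,
      score = if (is.null(top)) NA_real_ else top$score,
      zscore = if (is.null(top)) NA_real_ else top$zscore,
      neighbor = if (is.null(top)) NA_character_ else top$neighbor,
      rejected = pred$rejected,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  lvl <- ifelse(is.na(tab$ec), 0L, ec_match_level(tab$truth, tab$ec))
  for (d in 1:3) tab[[paste0("correct_l", d)]] <- lvl >= d & !tab$rejected
  answered <- !tab$rejected
  acc <- vapply(1:3, function(d) {
    if (!any(answered)) return(NA_real_)
    100 * mean(lvl[answered] >= d)
  }, numeric(1))
  names(acc) <- paste0("level", 1:3)
  list(accuracy = acc, coverage = 100 * mean(answered), table = tab)
}
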