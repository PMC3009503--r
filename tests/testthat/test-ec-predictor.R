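test_that("EC numbers parse and compare hierarchically", {
  p <- ec_number("1.3.3.9")
  expect_equal(unname(p[1, ]), c("1", "3", "3", "9"))
  expect_true(all(is.na(ec_number("?"))))
  expect_true(all(is.na(ec_number(NA))))
  expect_equal(unname(ec_number("1.2.3")[1, "serial"]), "-")
  expect_error(ec_number("1.2"), "malformed")
  expect_error(ec_number("0.1.1.1"), "class")

  expect_equal(ec_match_level("1.3.3.9", "1.3.3.9"), 3L)
  expect_equal(ec_match_level("1.3.3.9", "1.3.11.5"), 2L)
  expect_equal(ec_match_level("1.3.3.9", "1.4.3.9"), 1L)
  expect_equal(ec_match_level("1.3.3.9", "2.3.3.9"), 0L)
  expect_equal(ec_match_level("1.3.3.9", "?"), 0L)
  expect_true(ec_agree("1.3.3.9", "1.3.1.1", 2))
  expect_false(ec_agree("1.3.3.9", "1.3.1.1", 3))
})

make_rec <- function(id, ec) {
  reaction_record(id, ec, "A", "B",
                  data.frame(from = "A", to = "B", type = "main"))
}

test_that("database filters remove the documented reaction groups", {
  recs <- list(
    make_rec("R1", NA),          # (i) no EC
    make_rec("R2", "1.1.1.1"),
    make_rec("R3", "1.1.1.2"),
    make_rec("R4", "1.97.1.1"),  # (iv) 97 component
    make_rec("R5", "2.99.3.1"),  # (iv) 99 component
    make_rec("R6", "3.1.1.1"),   # (v) singleton subsubclass
    make_rec("R7", "4.1.1.1"))   # (v) singleton subsubclass
  out <- suppressMessages(filter_reactions(recs, verbose = FALSE))
  expect_equal(names(out), c("R2", "R3"))
  log <- attr(out, "removed")
  expect_equal(log$n_removed[log$filter == "i_no_ec"], 1L)
  expect_equal(log$n_removed[log$filter == "iv_class_97_99"], 2L)
  expect_equal(log$n_removed[log$filter == "v_singleton_subsubclass"], 2L)
})

test_that("structure filter cascades into subsubclass orphaning", {
  # R2 loses its structure; that orphans R3 in subsubclass 1.1.1
  recs <- list(
    make_rec("R2", "1.1.1.1"),
    make_rec("R3", "1.1.1.2"),
    make_rec("R8", "5.1.1.1"),
    make_rec("R9", "5.1.1.2"))
  recs[[1]]$substrates <- "MISSING"
  out <- filter_reactions(recs,
                          has_structure = function(id) id != "MISSING",
                          verbose = FALSE)
  expect_equal(names(out), c("R8", "R9"))
})

test_that("z-scores follow the population formula", {
  z <- zscore(c(1, 2, 3))
  expect_equal(z, c(-sqrt(1.5), 0, sqrt(1.5)), tolerance = 1e-12)
  # brute-force recomputation on random lists
  set.seed(13)
  for (i in 1:10) {
    x <- stats::rnorm(sample(2:10, 1))
    mu <- sum(x) / length(x)
    sg <- sqrt(sum((x - mu)^2) / length(x))
    expect_equal(zscore(x), (x - mu) / sg, tolerance = 1e-12)
  }
  zc <- zscore(c(5, 5, 5))
  expect_equal(as.numeric(zc), c(0, 0, 0))
  expect_true(attr(zc, "degenerate"))
  expect_error(zscore(7), "at least 2")
})

test_that("nearest neighbor ranks candidates by similarity", {
  fix <- small_fixture()
  cgram <- compound_gram_matrix(fix$compounds, fast_params())
  graphs <- lapply(fix$records, build_reaction_graph, mode = "full_edge")
  # an exact copy of the query sits in the db: top candidate is its EC
  # with normalized score 1
  query <- graphs[[1]]
  pred <- knn_predict(query, graphs, cgram, k = 3, fast_params())
  expect_equal(pred$candidates$ec[1], graphs[[1]]$ec)
  expect_equal(pred$candidates$score[1], 1, tolerance = 1e-9)
  expect_false(pred$rejected)
  expect_false(pred$no_support)
  # candidate scores are sorted and Z-scores are a monotone transform
  expect_true(all(diff(pred$candidates$score) <= 0))
  expect_true(all(diff(pred$candidates$zscore) <= 0))

  # candidate order matches an independent sort of oracle similarities
  # (main-pair graphs keep the promoted state space within the oracle's
  # enumeration guard)
  g_mp <- lapply(fix$records, build_reaction_graph, mode = "main_pair")
  q_mp <- g_mp[[1]]
  db <- g_mp[2:5]
  mk <- function(a, b) {
    ma <- rgk:::.reaction_match_matrix(a$labels, b$labels, cgram)
    walk_kernel_enumerate(a, b, ma, fast_params(), max_len = 25)
  }
  qg <- edge_to_vertex_transform(q_mp)
  sims <- vapply(db, function(d) {
    dg <- edge_to_vertex_transform(d)
    mk(qg, dg) / sqrt(mk(qg, qg) * mk(dg, dg))
  }, numeric(1))
  pred2 <- knn_predict(q_mp, db, cgram, k = 4, fast_params(),
                       non_tottering = FALSE)
  ecs <- vapply(db, function(d) d$ec, character(1))
  oracle_order <- order(-sims)
  expect_equal(pred2$candidates$ec,
               unique(ecs[oracle_order]))
})

test_that("score ties break by database insertion order", {
  cpds <- list(A = compound_graph("A", "C"),
               B = compound_graph("B", "O"))
  cgram <- compound_gram_matrix(cpds, fast_params())
  rec <- reaction_record("Q", "1.1.1.1", "A", "B",
                         data.frame(from = "A", to = "B", type = "main"))
  q <- build_reaction_graph(rec, "main_pair")
  same1 <- q; same1$reaction_id <- "D1"; same1$ec <- "2.1.1.1"
  same2 <- q; same2$reaction_id <- "D2"; same2$ec <- "3.1.1.1"
  pred <- knn_predict(q, list(same1, same2), cgram, k = 2, fast_params())
  expect_equal(pred$candidates$score[1], pred$candidates$score[2])
  expect_equal(pred$candidates$ec, c("2.1.1.1", "3.1.1.1"))
  expect_equal(pred$candidates$neighbor, c("D1", "D2"))
})

test_that("zero similarity everywhere is flagged as unsupported", {
  cpds <- list(A = compound_graph("A", "C"), B = compound_graph("B", "O"),
               X = compound_graph("X", "N"), Y = compound_graph("Y", "S"))
  cgram <- compound_gram_matrix(cpds, fast_params())
  # rpair graphs with different relation labels and non-matching
  # compounds share nothing the joint walk could emit
  q <- build_reaction_graph(
    reaction_record("Q", "1.1.1.1", "A", "B",
                    data.frame(from = "A", to = "B", type = "main")),
    "rpair")
  d <- build_reaction_graph(
    reaction_record("D", "2.1.1.1", "X", "Y",
                    data.frame(from = "X", to = "Y", type = "cofactor")),
    "rpair")
  pred <- knn_predict(q, list(d), cgram, k = 1, fast_params())
  expect_true(pred$no_support)
  expect_true(is.na(pred$candidates$zscore[1]))
  expect_error(knn_predict(q, list(), cgram), "empty database")
})

test_that("leave-one-out recovers well-separated synthetic classes", {
  fix <- small_fixture()
  cgram <- compound_gram_matrix(fix$compounds, fast_params())
  graphs <- lapply(fix$records, build_reaction_graph, mode = "full_edge")
  res <- loo_evaluate(graphs, cgram, fast_params())
  expect_equal(unname(res$accuracy[["level1"]]), 100)
  expect_equal(res$coverage, 100)
  expect_equal(nrow(res$table), length(graphs))
  # level accuracies nest
  expect_true(res$accuracy[["level1"]] >= res$accuracy[["level2"]])
  expect_true(res$accuracy[["level2"]] >= res$accuracy[["level3"]])
})

test_that("all-singleton subsubclasses give level-3 accuracy zero", {
  fix <- small_fixture()
  graphs <- lapply(fix$records, build_reaction_graph, mode = "full_edge")
  # re-label so every reaction is alone in its subsubclass
  for (i in seq_along(graphs)) {
    graphs[[i]]$ec <- sprintf("%d.%d.%d.1", (i %% 6) + 1, i, i)
  }
  cgram <- compound_gram_matrix(fix$compounds, fast_params())
  res <- loo_evaluate(graphs, cgram, fast_params())
  expect_equal(unname(res$accuracy[["level3"]]), 0)
})

test_that("masked-Gram LOO equals naive per-fold recomputation", {
  fix <- small_fixture()
  recs <- fix$records[1:5]
  graphs <- lapply(recs, build_reaction_graph, mode = "full_edge")
  cgram <- compound_gram_matrix(fix$compounds, fast_params())
  masked <- loo_evaluate(graphs, cgram, fast_params())

  # naive: for each fold, recompute every query/db kernel from scratch
  naive_rows <- lapply(seq_along(graphs), function(i) {
    db <- graphs[-i]
    pred <- knn_predict(graphs[[i]], db, cgram, k = 5, fast_params())
    pred$candidates[1, c("ec", "score", "neighbor")]
  })
  naive <- do.call(rbind, naive_rows)
  expect_equal(masked$table$ec, naive$ec)
  expect_equal(masked$table$neighbor, naive$neighbor)
  expect_equal(masked$table$score, naive$score, tolerance = 1e-12)
})

test_that("rejection threshold trades coverage for accuracy", {
  fix <- small_fixture()
  cgram <- compound_gram_matrix(fix$compounds, fast_params())
  graphs <- lapply(fix$records, build_reaction_graph, mode = "full_edge")
  res <- loo_evaluate(graphs, cgram, fast_params(), min_score = 0.999)
  expect_lt(res$coverage, 100)
  expect_true(all(res$table$rejected[res$table$score < 0.999] |
                    is.na(res$table$score)))
})
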