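seco_rxn <- system.file("extdata", "secologanin_synthetic.rxn",
                        package = "rgk")
seco_sdf <- system.file("extdata", "secologanin_synthetic.sdf",
                        package = "rgk")

test_that("reaction records validate pairs and sides", {
  expect_error(
    reaction_record("R1", "1.1.1.1", "A", "B",
                    data.frame(from = "A", to = "B", type = "weird")),
    "unknown pair type")
  expect_error(
    reaction_record("R1", "1.1.1.1", "A", "B",
                    data.frame(from = "A", to = "C", type = "main")),
    "substrate and a product")
  # same-side pair is rejected
  expect_error(
    reaction_record("R1", "1.1.1.1", c("A", "B"), "C",
                    data.frame(from = "A", to = "B", type = "main")),
    "substrate and a product")
  # pairs given product-first are stored substrate-first
  r <- reaction_record("R1", "1.1.1.1", "A", "B",
                       data.frame(from = "B", to = "A", type = "main"))
  expect_equal(r$pairs$from, "A")
  expect_equal(r$pairs$to, "B")
})

test_that("the secologanin stanza parses to the documented record", {
  recs <- read_reaction_list(seco_rxn)
  expect_length(recs, 1L)
  r <- recs$RSECO
  expect_equal(r$ec, "1.3.3.9")
  expect_length(r$substrates, 4L)
  expect_length(r$products, 3L)
  expect_equal(sort(r$pairs$type), c("cofactor", "leave", "main"))
})

test_that("reaction-list parsing handles '?' ECs and empty files", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("reaction: RX", "ec: ?", "substrates: A", "products: B",
               "pair: A B main"), p)
  r <- read_reaction_list(p)$RX
  expect_true(is.na(r$ec))

  writeLines("# only comments", p)
  expect_length(read_reaction_list(p), 0L)
})

test_that("reaction list round-trips through its text format", {
  fix <- small_fixture()
  p <- withr::local_tempfile(fileext = ".txt")
  write_reaction_list(fix$records, p)
  back <- read_reaction_list(p)
  expect_equal(names(back), names(fix$records))
  for (id in names(back)) {
    expect_equal(back[[id]]$substrates, fix$records[[id]]$substrates)
    expect_equal(back[[id]]$products, fix$records[[id]]$products)
    expect_equal(back[[id]]$ec, fix$records[[id]]$ec)
    expect_equal(back[[id]]$pairs, fix$records[[id]]$pairs)
  }
})

test_that("full-edge graph of the worked example has 7 vertices, 12 edges", {
  r <- read_reaction_list(seco_rxn)$RSECO
  g <- build_reaction_graph(r, "full_edge")
  expect_length(g$compound_ids, 7L)
  # group edges: C(4,2) + C(3,2) = 9, plus the 3 typed pairs
  expect_equal(sum(g$edge_labels == "group"), 9L)
  expect_equal(nrow(g$edges), 12L)

  rp <- build_reaction_graph(r, "rpair")
  expect_equal(nrow(rp$edges), 3L)
  expect_length(rp$compound_ids, 7L)

  mp <- build_reaction_graph(r, "main_pair")
  expect_length(mp$compound_ids, 2L)
  expect_equal(nrow(mp$edges), 1L)
  expect_equal(mp$edge_labels, "main")
  expect_setequal(mp$compound_ids, c("LOGANIN", "SECOLOGANIN"))
})

test_that("single main pair reaction is identical across modes", {
  r <- reaction_record("R1", "1.1.1.1", "A", "B",
                       data.frame(from = "A", to = "B", type = "main"))
  gs <- lapply(c("full_edge", "rpair", "main_pair"),
               function(m) build_reaction_graph(r, m))
  for (g in gs) {
    expect_length(g$compound_ids, 2L)
    expect_equal(nrow(g$edges), 1L)
    expect_equal(g$edge_labels, "main")
  }
})

test_that("main_pair mode requires a main pair", {
  r <- reaction_record("R1", "1.1.1.1", "A", "B",
                       data.frame(from = "A", to = "B", type = "cofactor"))
  expect_error(build_reaction_graph(r, "main_pair"), "main")
})

test_that("edge sets nest: main_pair within rpair within full_edge", {
  fix <- small_fixture()
  edge_keys <- function(g) {
    ids <- g$compound_ids
    sides <- g$sides
    paste(ids[g$edges[, 1]], sides[g$edges[, 1]],
          ids[g$edges[, 2]], sides[g$edges[, 2]], g$edge_labels)
  }
  for (r in fix$records) {
    mp <- edge_keys(build_reaction_graph(r, "main_pair"))
    rp <- edge_keys(build_reaction_graph(r, "rpair"))
    fe <- edge_keys(build_reaction_graph(r, "full_edge"))
    expect_true(all(mp %in% rp))
    expect_true(all(rp %in% fe))
  }
})

test_that("promoted reaction graphs use disjoint label namespaces", {
  r <- read_reaction_list(seco_rxn)$RSECO
  g <- edge_to_vertex_transform(build_reaction_graph(r, "rpair"))
  expect_equal(n_vertices(g), 7L + 3L)
  expect_equal(n_edges(g), 6L)
  expect_true(all(grepl("^(cpd|rel):", g$labels)))
})

test_that("reaction kernel matches the enumeration oracle (main_pair)", {
  fix <- small_fixture()
  cgram <- compound_gram_matrix(fix$compounds, fast_params())
  r <- build_reaction_graph(fix$records[[1]], "main_pair")
  # promoted main-pair graph has 3 vertices: enumeration is exact enough
  g <- edge_to_vertex_transform(r)
  m <- rgk:::.reaction_match_matrix(g$labels, g$labels, cgram)
  kf <- as.numeric(walk_kernel(g, g, m, fast_params()))
  ke <- walk_kernel_enumerate(g, g, m, fast_params(), max_len = 25)
  expect_lte(abs(kf - ke), kernel_tail_bound(fast_params(), 25) + 1e-9)

  # and the full reaction_kernel path agrees when tottering is allowed
  kr <- as.numeric(reaction_kernel(r, r, cgram, fast_params(),
                                   non_tottering = FALSE))
  expect_equal(kr, kf, tolerance = 1e-10)
})

test_that("disjoint reactions with no matching labels score zero", {
  # distinct atom AND bond labels everywhere: no vertex can ever match
  cpds <- list(
    A = compound_graph("A", c("C", "C"), rbind(c(1, 2)), "single"),
    B = compound_graph("B", c("N", "N"), rbind(c(1, 2)), "double"),
    X = compound_graph("X", c("O", "O"), rbind(c(1, 2)), "triple"),
    Y = compound_graph("Y", c("S", "S"), rbind(c(1, 2)), "aromatic"))
  cgram <- compound_gram_matrix(cpds, fast_params())
  expect_equal(cgram["A", "B"], 0)
  r1 <- build_reaction_graph(
    reaction_record("R1", "1.1.1.1", "A", "B",
                    data.frame(from = "A", to = "B", type = "main")),
    "main_pair")
  r2 <- build_reaction_graph(
    reaction_record("R2", "2.1.1.1", "X", "Y",
                    data.frame(from = "X", to = "Y", type = "cofactor")),
    "rpair")
  k <- reaction_kernel(r1, r2, cgram, fast_params())
  expect_equal(as.numeric(k), 0)

  # self-kernel is strictly positive
  expect_gt(as.numeric(reaction_kernel(r1, r1, cgram, fast_params())), 0)
})

test_that("missing compounds in the gram matrix are reported by name", {
  r <- build_reaction_graph(
    reaction_record("R1", "1.1.1.1", "A", "B",
                    data.frame(from = "A", to = "B", type = "main")),
    "main_pair")
  cgram <- matrix(1, 1, 1, dimnames = list("A", "A"))
  expect_error(reaction_kernel(r, r, cgram, fast_params()), "B")
})

test_that("consistent compound relabeling leaves kernel values unchanged", {
  fix <- small_fixture()
  sub <- fix$records[1:3]
  ids <- unique(unlist(lapply(sub, function(r) c(r$substrates, r$products))))
  cpds <- fix$compounds[ids]
  cgram <- compound_gram_matrix(cpds, fast_params())
  graphs <- lapply(sub, build_reaction_graph, mode = "full_edge")
  k1 <- reaction_gram_matrix(graphs, cgram, fast_params())

  rename <- function(x) paste0("X_", x)
  cpds2 <- lapply(cpds, function(cg) {
    cg$compound_id <- rename(cg$compound_id)
    cg
  })
  names(cpds2) <- rename(names(cpds))
  sub2 <- lapply(sub, function(r) {
    reaction_record(r$reaction_id, r$ec, rename(r$substrates),
                    rename(r$products),
                    data.frame(from = rename(r$pairs$from),
                               to = rename(r$pairs$to),
                               type = r$pairs$type))
  })
  cgram2 <- compound_gram_matrix(cpds2, fast_params())
  graphs2 <- lapply(sub2, build_reaction_graph, mode = "full_edge")
  k2 <- reaction_gram_matrix(graphs2, cgram2, fast_params())
  expect_equal(unname(k1), unname(k2), tolerance = 1e-12)
})
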