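#' Reaction records and the reaction-list file format
#'
#' A reaction record names its substrates and products (compound IDs) and
#' the reactant pairs connecting them. Pair types follow the KEGG/RPAIR
#' categorization: `main` (the core transformation), `leave`, `cofactor`,
#' `transferase`, `ligase`. An optional EC number annotates the catalyzing
#' enzyme; `"?"` marks a prediction target.
#'
#' The plain-text reaction-list format is one stanza per reaction,
#' stanzas separated by blank lines, `#` starts a comment:
#' \preformatted{
#' reaction: R0001
#' ec: 1.3.3.9
#' substrates: C001 C002
#' products: C003 C004
#' pair: C001 C003 main
#' pair: C002 C004 cofactor
#' }
#'
#' @param reaction_id identifier string.
#' @param ec EC string or `NA`/`"?"` for unannotated reactions.
#' @param substrates,products character vectors of compound IDs.
#' @param pairs data frame with columns `from` (substrate-side compound),
#'   `to` (product-side compound) and `type`.
#' @return an object of class `reaction_record`.
#' @export
reaction_record <- function(reaction_id, ec = NA_character_,
                            substrates, products,
                            pairs = data.frame(from = character(0),
                                               to = character(0),
                                               type = character(0))) {
  reaction_id <- as.character(reaction_id)
  ec <- as.character(ec)
  if (!is.na(ec) && (ec == "?" || !nzchar(ec))) ec <- NA_character_
  if (!is.na(ec)) ec_number(ec)  # validate format
  substrates <- as.character(substrates)
  products <- as.character(products)
  if (length(substrates) < 1L || length(products) < 1L) {
    stop("reaction ", reaction_id, ": needs >= 1 substrate and product")
  }
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (nrow(pairs) > 0L) {
    bad_type <- setdiff(unique(pairs$type), PAIR_TYPES)
    if (length(bad_type) > 0L) {
      stop("reaction ", reaction_id, ": unknown pair type(s) ",
           paste(bad_type, collapse = ", "), "; allowed: ",
           paste(PAIR_TYPES, collapse = ", "))
    }
    # pair endpoints must sit on opposite sides of the reaction
    ok <- (pairs$from %in% substrates & pairs$to %in% products) |
      (pairs$from %in% products & pairs$to %in% substrates)
    if (!all(ok)) {
      stop("reaction ", reaction_id, ": pair endpoints must be a ",
           "substrate and a product of this reaction (offending: ",
           paste(pairs$from[!ok], pairs$to[!ok], collapse = "; "), ")")
    }
    # store with 'from' on the substrate side
    flip <- pairs$from %in% products
    tmp <- pairs$from[flip]
    pairs$from[flip] <- pairs$to[flip]
    pairs$to[flip] <- tmp
  }
  structure(list(reaction_id = reaction_id, ec = ec,
                 substrates = substrates, products = products,
                 pairs = pairs),
            class = "reaction_record")
}

#' @rdname reaction_record
#' @format NULL
#' @export
PAIR_TYPES <- c("main", "leave", "cofactor", "transferase", "ligase")

#' @export
print.reaction_record <- function(x, ...) {
  cat(sprintf("<reaction_record %s [EC %s]: %d substrates, %d products, %d pairs>\n",
              x$reaction_id, ifelse(is.na(x$ec), "?", x$ec),
              length(x$substrates), length(x$products), nrow(x$pairs)))
  invisible(x)
}

#' @rdname reaction_record
#' @param path path to a reaction-list file.
#' @return `read_reaction_list()`: a named list of `reaction_record`s in
#'   file order.
#' @export
read_reaction_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  # split into stanzas at blank lines
  grp <- cumsum(!nzchar(lines))
  stanzas <- split(lines[nzchar(lines)], grp[nzchar(lines)])
  records <- lapply(stanzas, .parse_reaction_stanza)
  names(records) <- vapply(records, function(r) r$reaction_id, character(1))
  if (anyDuplicated(names(records))) {
    stop("duplicate reaction IDs in ", path)
  }
  records
}

.parse_reaction_stanza <- function(lines) {
  kv <- regmatches(lines, regexec("^([a-z]+):\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad) > 0L) {
    stop("cannot parse reaction-list line: ", lines[bad[1L]])
  }
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  get1 <- function(key, required = TRUE) {
    v <- vals[keys == key]
    if (length(v) == 0L) {
      if (required) stop("reaction stanza missing '", key, ":' line")
      return(NA_character_)
    }
    if (length(v) > 1L) stop("duplicate '", key, ":' line in stanza")
    v
  }
  pairs_raw <- vals[keys == "pair"]
  pair_fields <- strsplit(trimws(pairs_raw), "\\s+")
  if (any(lengths(pair_fields) != 3L)) {
    stop("each 'pair:' line needs exactly: <substrate> <product> <type>")
  }
  pairs <- data.frame(
    from = vapply(pair_fields, `[`, character(1), 1L),
    to = vapply(pair_fields, `[`, character(1), 2L),
    type = vapply(pair_fields, `[`, character(1), 3L),
    stringsAsFactors = FALSE)
  reaction_record(
    reaction_id = get1("reaction"),
    ec = get1("ec", required = FALSE),
    substrates = strsplit(trimws(get1("substrates")), "\\s+")[[1L]],
    products = strsplit(trimws(get1("products")), "\\s+")[[1L]],
    pairs = pairs)
}

#' @rdname reaction_record
#' @param records list of `reaction_record`s.
#' @return `write_reaction_list()`: `path`, invisibly.
#' @export
write_reaction_list <- function(records, path) {
  blocks <- vapply(records, function(r) {
    paste(c(
      paste0("reaction: ", r$reaction_id),
      paste0("ec: ", ifelse(is.na(r$ec), "?", r$ec)),
      paste0("substrates: ", paste(r$substrates, collapse = " ")),
      paste0("products: ", paste(r$products, collapse = " ")),
      if (nrow(r$pairs) > 0L) {
        paste("pair:", r$pairs$from, r$pairs$to, r$pairs$type)
      }
    ), collapse = "\n")
  }, character(1))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Build a reaction graph from a record
#'
#' Vertices are the participating compounds (kept separate per side, so a
#' compound occurring on both sides yields two vertices); edges are the
#' typed compound-compound relationships. Three variants:
#'
#' * `full_edge`: all typed pair edges, plus a `group` edge between every
#'   two compounds on the substrate side and every two on the product
#'   side;
#' * `rpair`: the typed pair edges only;
#' * `main_pair`: only the `main` pair edges, with all other compounds
#'   dropped.
#'
#' `group` is a sixth relation label distinct from the five pair types.
#'
#' @param record a [reaction_record()].
#' @param mode one of `"full_edge"`, `"rpair"`, `"main_pair"`.
#' @return an object of class `reaction_graph` with fields `compound_ids`
#'   (per vertex), `sides`, `edges`, `edge_labels`.
#' @export
build_reaction_graph <- function(record,
                                 mode = c("full_edge", "rpair",
                                          "main_pair")) {
  stopifnot(inherits(record, "reaction_record"))
  mode <- match.arg(mode)
  pairs <- record$pairs
  if (mode == "main_pair") {
    pairs <- pairs[pairs$type == "main", , drop = FALSE]
    if (nrow(pairs) == 0L) {
      stop("reaction ", record$reaction_id,
           ": main_pair mode requires at least one 'main' pair")
    }
    ids <- unique(c(pairs$from, pairs$to))
    sides <- ifelse(ids %in% record$substrates, "substrate", "product")
  } else {
    ids <- c(record$substrates, record$products)
    sides <- rep(c("substrate", "product"),
                 c(length(record$substrates), length(record$products)))
  }
  # vertex lookup by (compound, side); pair 'from' is substrate-side
  vkey <- paste(ids, sides)
  idx_of <- function(cid, side) match(paste(cid, side), vkey)
  e_from <- idx_of(pairs$from, "substrate")
  e_to <- idx_of(pairs$to, "product")
  if (anyNA(e_from) || anyNA(e_to)) {
    stop("reaction ", record$reaction_id, ": pair references a compound ",
         "missing from the vertex set")
  }
  edges <- cbind(e_from, e_to)
  edge_labels <- pairs$type
  if (mode == "full_edge") {
    for (s in c("substrate", "product")) {
      v <- which(sides == s)
      if (length(v) >= 2L) {
        grp <- t(utils::combn(v, 2L))
        edges <- rbind(edges, grp)
        edge_labels <- c(edge_labels, rep("group", nrow(grp)))
      }
    }
  }
  dimnames(edges) <- NULL
  structure(list(reaction_id = record$reaction_id, ec = record$ec,
                 mode = mode, compound_ids = ids, sides = sides,
                 edges = edges, edge_labels = edge_labels),
            class = "reaction_graph")
}

#' @export
print.reaction_graph <- function(x, ...) {
  cat(sprintf("<reaction_graph %s (%s): %d compounds, %d edges>\n",
              x$reaction_id, x$mode, length(x$compound_ids),
              nrow(x$edges)))
  invisible(x)
}

#' @export
edge_to_vertex_transform.reaction_graph <- function(g, ...) {
  promote_edges(paste0("cpd:", g$compound_ids), g$edges,
                paste0("rel:", g$edge_labels), id = g$reaction_id)
}

# promoted (and optionally non-tottering) labeled graph for the upper level
.reaction_walk_graph <- function(rg, non_tottering = TRUE) {
  g <- edge_to_vertex_transform(rg)
  if (non_tottering) g <- non_tottering_transform(g)
  g
}

# blockwise vertex-match matrix for the upper level: compound x compound
# entries come from the normalized lower-level Gram, relation x relation
# entries are Dirac on the relation label, cross entries are zero.
.reaction_match_matrix <- function(labels1, labels2, compound_gram) {
  is_cpd1 <- startsWith(labels1, "cpd:")
  is_cpd2 <- startsWith(labels2, "cpd:")
  m <- matrix(0, length(labels1), length(labels2))
  if (any(is_cpd1) && any(is_cpd2)) {
    ids1 <- sub("^cpd:", "", labels1[is_cpd1])
    ids2 <- sub("^cpd:", "", labels2[is_cpd2])
    missing <- setdiff(unique(c(ids1, ids2)), rownames(compound_gram))
    if (length(missing) > 0L) {
      stop("compound(s) missing from the compound Gram matrix: ",
           paste(missing, collapse = ", "))
    }
    m[is_cpd1, is_cpd2] <- compound_gram[ids1, ids2]
  }
  if (any(!is_cpd1) && any(!is_cpd2)) {
    m[!is_cpd1, !is_cpd2] <- dirac_match(labels1[!is_cpd1],
                                         labels2[!is_cpd2])
  }
  m
}

#' Upper-level kernel between two reaction graphs
#'
#' Runs the random-walk kernel on the two edge-promoted reaction graphs.
#' The vertex-match matrix is blockwise: compound-vertex pairs score the
#' normalized lower-level compound kernel of the two compounds; relation
#' vertices (promoted edge labels) match by the Dirac kernel; compound
#' and relation vertices never match each other.
#'
#' @param r1,r2 `reaction_graph` objects (same mode).
#' @param compound_gram normalized compound Gram matrix (unit diagonal,
#'   entries in \[0, 1\]) with compound IDs as dimnames; see
#'   [compound_gram_matrix()].
#' @param params a [walk_params()].
#' @param non_tottering apply [non_tottering_transform()] to the promoted
#'   graphs before walking (default TRUE).
#' @return kernel value (see [walk_kernel()] for attributes).
#' @export
reaction_kernel <- function(r1, r2, compound_gram,
                            params = walk_params(), non_tottering = TRUE) {
  g1 <- .reaction_walk_graph(r1, non_tottering)
  g2 <- .reaction_walk_graph(r2, non_tottering)
  m <- .reaction_match_matrix(g1$labels, g2$labels, compound_gram)
  walk_kernel(g1, g2, m, params)
}

#' Lower-level compound Gram matrix
#'
#' Computes the random-walk kernel between every pair of compounds (after
#' bond-label promotion and, by default, the non-tottering transform) and
#' cosine-normalizes it so that all entries lie in \[0, 1\] with unit
#' diagonal -- the form required for the upper-level vertex-match matrix.
#'
#' @param compounds list of [compound_graph()] objects.
#' @param params a [walk_params()] (`lambda1` is used on both sides).
#' @param non_tottering apply the non-tottering transform (default TRUE).
#' @param normalize cosine-normalize the result (default TRUE).
#' @return matrix indexed by compound ID.
#' @export
compound_gram_matrix <- function(compounds, params = walk_params(),
                                 non_tottering = TRUE, normalize = TRUE) {
  graphs <- lapply(compounds, function(cg) {
    g <- edge_to_vertex_transform(cg)
    if (non_tottering) g <- non_tottering_transform(g)
    g
  })
  k <- gram_matrix(graphs, params = params)
  if (is.null(rownames(k))) {
    ids <- vapply(compounds, function(cg) cg$compound_id, character(1))
    dimnames(k) <- list(ids, ids)
  }
  if (normalize) normalize_gram(k) else k
}

#' Upper-level reaction Gram matrix
#'
#' @param reactions list of `reaction_graph` objects (one mode).
#' @param compound_gram normalized compound Gram matrix covering every
#'   compound occurring in `reactions`.
#' @param params a [walk_params()].
#' @param non_tottering see [reaction_kernel()].
#' @param normalize cosine-normalize (default TRUE; the nearest-neighbor
#'   predictor ranks by normalized similarity).
#' @return matrix indexed by reaction ID.
#' @export
reaction_gram_matrix <- function(reactions, compound_gram,
                                 params = walk_params(),
                                 non_tottering = TRUE, normalize = TRUE) {
  graphs <- lapply(reactions, .reaction_walk_graph,
                   non_tottering = non_tottering)
  k <- gram_matrix(
    graphs,
    match_fn = function(a, b) {
      .reaction_match_matrix(a$labels, b$labels, compound_gram)
    },
    params = params)
  if (normalize) normalize_gram(k) else k
}
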