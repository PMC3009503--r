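#' Chemical compound as a labeled graph
#'
#' Atoms are vertices labeled with their element symbol; bonds are
#' undirected edges labeled `single`, `double`, `triple` or `aromatic`.
#' Charges, isotopes and stereochemistry are ignored on purpose: vertex
#' matching in the kernel is a Dirac kernel on element symbols, so any
#' extra attribute would silently change the match semantics. Hydrogens
#' are kept if the structure file lists them explicitly and are never
#' added.
#'
#' @param compound_id identifier string (KEGG-style IDs, file names, ...).
#' @param atoms character vector of element symbols, one per atom.
#' @param bonds two-column integer matrix of atom indices.
#' @param bond_labels character vector, one per bond, each one of
#'   `single`, `double`, `triple`, `aromatic`.
#' @return an object of class `compound_graph`.
#' @export
compound_graph <- function(compound_id, atoms,
                           bonds = matrix(integer(0), 0, 2),
                           bond_labels = character(0)) {
  atoms <- as.character(atoms)
  if (length(atoms) < 1L) stop("a compound needs at least one atom")
  bonds <- as_edge_matrix(bonds)
  bond_labels <- as.character(bond_labels)
  if (nrow(bonds) != length(bond_labels)) {
    stop("need exactly one bond label per bond")
  }
  bad <- setdiff(unique(bond_labels), BOND_LABELS)
  if (length(bad) > 0L) {
    stop("unknown bond label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(BOND_LABELS, collapse = ", "), ")")
  }
  # reuse labeled_graph validation for endpoints/loops/duplicates
  labeled_graph(atoms, bonds)
  structure(
    list(compound_id = as.character(compound_id), atoms = atoms,
         bonds = bonds, bond_labels = bond_labels),
    class = "compound_graph"
  )
}

#' @rdname compound_graph
#' @format NULL
#' @export
BOND_LABELS <- c("single", "double", "triple", "aromatic")

#' @export
print.compound_graph <- function(x, ...) {
  cat(sprintf("<compound_graph %s: %d atoms, %d bonds>\n",
              x$compound_id, length(x$atoms), nrow(x$bonds)))
  invisible(x)
}

# MDL bond-type code -> label (code 4 is the aromatic flag)
.bond_code_to_label <- function(code) {
  lab <- rep(NA_character_, length(code))
  lab[code == 1] <- "single"
  lab[code == 2] <- "double"
  lab[code == 3] <- "triple"
  lab[code == 4] <- "aromatic"
  lab
}

.bond_label_to_code <- function(label) {
  match(label, BOND_LABELS)
}

#' Read compounds from an SDF or molfile
#'
#' Parses MDL V2000 records via \pkg{ChemmineR} and converts each record
#' into a [compound_graph()]. Atom labels are the element symbols as
#' written; explicit hydrogens become ordinary vertices. Compound IDs are
#' taken from the molfile title line, falling back to the file name (with
#' a record index appended for multi-record files with blank titles).
#'
#' @param path path to a `.mol`/`.sdf` file (one or more records).
#' @return `read_sdf()`: a named list of `compound_graph` objects, in file
#'   order; `read_molfile()`: the single `compound_graph` of the first
#'   record.
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::read.SDFset(path)),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  out <- vector("list", length(sdfset))
  for (i in seq_along(sdfset)) {
    out[[i]] <- .sdf_record_to_compound(sdfset[[i]], path, i,
                                        multi = length(sdfset) > 1L)
  }
  names(out) <- vapply(out, function(cg) cg$compound_id, character(1))
  out
}

#' @rdname read_sdf
#' @export
read_molfile <- function(path) {
  read_sdf(path)[[1L]]
}

.sdf_record_to_compound <- function(sdf, path, index, multi = FALSE) {
  where <- sprintf("%s record %d", path, index)
  ab <- ChemmineR::atomblock(sdf)
  if (is.null(ab) || nrow(ab) == 0L) {
    stop("zero atoms in ", where)
  }
  # atomblock rownames are "<element>_<serial>"
  atoms <- sub("_[0-9]+$", "", rownames(ab))
  bb <- ChemmineR::bondblock(sdf)
  if (is.null(bb) || nrow(bb) == 0L) {
    bonds <- matrix(integer(0), 0L, 2L)
    labels <- character(0)
  } else {
    bonds <- cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]))
    labels <- .bond_code_to_label(as.integer(bb[, 3L]))
    bad <- which(is.na(labels) | is.na(bonds[, 1L]) | is.na(bonds[, 2L]) |
                   bonds[, 1L] < 1L | bonds[, 2L] < 1L |
                   bonds[, 1L] > length(atoms) | bonds[, 2L] > length(atoms))
    if (length(bad) > 0L) {
      stop("malformed bond block line ", bad[1L], " in ", where)
    }
  }
  title <- trimws(ChemmineR::header(sdf)[["Molecule_Name"]])
  if (is.null(title) || is.na(title) || !nzchar(title)) {
    base <- sub("\\.(sdf|mol)$", "", basename(path), ignore.case = TRUE)
    title <- if (multi) sprintf("%s_%d", base, index) else base
  }
  compound_graph(title, atoms, bonds, labels)
}

#' Write compounds to an SDF file
#'
#' Inverse of [read_sdf()] up to coordinates (all-zero, since the kernels
#' are purely topological). Reading the written file back reproduces the
#' same atom and bond multisets.
#'
#' @param compounds a `compound_graph` or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(compounds, path) {
  if (inherits(compounds, "compound_graph")) compounds <- list(compounds)
  lines <- unlist(lapply(compounds, .compound_to_mol_lines))
  writeLines(lines, path)
  invisible(path)
}

.compound_to_mol_lines <- function(cg) {
  n <- length(cg$atoms)
  m <- nrow(cg$bonds)
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m)
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, cg$atoms)
  bond_lines <- if (m > 0L) {
    sprintf("%3d%3d%3d  0", cg$bonds[, 1L], cg$bonds[, 2L],
            .bond_label_to_code(cg$bond_labels))
  } else character(0)
  c(cg$compound_id, "  rgk", "", counts, atom_lines, bond_lines,
    "M  END", "$$$$")
}

#' Promote labeled edges to labeled vertices
#'
#' The walk-kernel engine assumes vertex labels only, so each labeled edge
#' (u, v) with label l is replaced by a fresh vertex carrying l (in a
#' disjoint namespace, e.g. `bond:single`) plus the two edges (u, w) and
#' (w, v). The output therefore has exactly |V| + |E| vertices and 2|E|
#' edges. Keeping the bond/relation namespace disjoint from the original
#' vertex labels guarantees the Dirac kernel never matches an atom against
#' a promoted bond vertex.
#'
#' @param g a [compound_graph()] or `reaction_graph`.
#' @param ... passed to methods.
#' @return a [labeled_graph()].
#' @examples
#' cg <- compound_graph("ethanol-fragment", c("C", "C", "O"),
#'                      rbind(c(1, 2), c(2, 3)), c("single", "single"))
#' g <- edge_to_vertex_transform(cg)
#' n_vertices(g)  # 3 + 2
#' n_edges(g)     # 2 * 2
#' @export
edge_to_vertex_transform <- function(g, ...) {
  UseMethod("edge_to_vertex_transform")
}

#' @export
edge_to_vertex_transform.compound_graph <- function(g, ...) {
  promote_edges(g$atoms, g$bonds, paste0("bond:", g$bond_labels),
                id = g$compound_id)
}

# shared promotion core: vertex labels + labeled edge list -> labeled_graph
promote_edges <- function(labels, edges, edge_labels, id = NULL) {
  n <- length(labels)
  m <- nrow(edges)
  if (m == 0L) {
    return(labeled_graph(labels, id = id))
  }
  new_labels <- c(labels, edge_labels)
  w <- n + seq_len(m)
  new_edges <- rbind(cbind(edges[, 1L], w), cbind(w, edges[, 2L]))
  labeled_graph(new_labels, new_edges, id = id)
}

#' Non-tottering walk transform
#'
#' Rewrites a graph so that random walks on the result correspond exactly
#' to walks on the input that never immediately return to the vertex they
#' came from. This is the classical directed edge-graph construction: the
#' transformed vertex set is V plus one vertex per arc (u, v), labeled
#' with the label of v; arcs go from v to (v, u)-type vertices and from
#' (u, v) to (v, w) whenever w != u. Walks may start only on the original
#' vertices, which the returned graph encodes through its start weights,
#' so label sequences (and hence the length-0 term of the kernel) are
#' preserved.
#'
#' @param g a [labeled_graph()] (undirected).
#' @return a directed `labeled_graph` with start weights concentrated on
#'   the original vertices.
#' @export
non_tottering_transform <- function(g) {
  stopifnot(inherits(g, "labeled_graph"))
  if (g$directed) stop("non_tottering_transform expects an undirected graph")
  n <- n_vertices(g)
  m <- n_edges(g)
  if (m == 0L) {
    return(labeled_graph(g$labels, directed = TRUE, id = g$id))
  }
  # arcs: both orientations of every undirected edge
  arc_from <- c(g$edges[, 1L], g$edges[, 2L])
  arc_to <- c(g$edges[, 2L], g$edges[, 1L])
  n_arc <- length(arc_from)
  labels <- c(g$labels, g$labels[arc_to])
  # v -> (v, u) for every arc (v, u)
  e1 <- cbind(arc_from, n + seq_len(n_arc))
  # (u, v) -> (v, w) for consecutive arcs with w != u
  arcs_out <- split(seq_len(n_arc), arc_from)
  e2_from <- integer(0)
  e2_to <- integer(0)
  for (a in seq_len(n_arc)) {
    nxt <- arcs_out[[as.character(arc_to[a])]]
    nxt <- nxt[arc_to[nxt] != arc_from[a]]
    if (length(nxt) > 0L) {
      e2_from <- c(e2_from, rep(n + a, length(nxt)))
      e2_to <- c(e2_to, n + nxt)
    }
  }
  edges <- rbind(e1, cbind(e2_from, e2_to))
  start <- c(rep(1, n), rep(0, n_arc))
  labeled_graph(labels, edges, directed = TRUE, start = start, id = g$id)
}
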