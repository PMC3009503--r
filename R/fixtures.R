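# run code under a temporary RNG seed, restoring global RNG state after
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# free valence budget per element; bounds the degree of generated atoms
.VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 3L)
.BOND_COST <- c(single = 1L, double = 2L, triple = 3L)

# random connected molecule with valence-plausible degrees; assumes an
# active RNG stream (callers wrap in with_seed)
.random_molecule <- function(size, id = "cpd") {
  elements <- sample(names(.VALENCE), size, replace = TRUE,
                     prob = c(0.55, 0.15, 0.15, 0.08, 0.07))
  cap <- .VALENCE[elements]
  bonds <- matrix(integer(0), 0L, 2L)
  labels <- character(0)
  if (size > 1L) {
    for (v in 2:size) {
      open <- which(cap[seq_len(v - 1L)] > 0L)
      u <- if (length(open) == 0L) v - 1L else
        open[sample.int(length(open), 1L)]
      max_order <- max(1L, min(cap[u], cap[v]))
      ord <- sample(1:3, 1L, prob = c(0.8, 0.15, 0.05))
      ord <- min(ord, max_order)
      bonds <- rbind(bonds, c(u, v))
      labels <- c(labels, names(.BOND_COST)[ord])
      cap[u] <- cap[u] - ord
      cap[v] <- cap[v] - ord
    }
    # a few ring-closing single bonds where valence allows
    n_extra <- stats::rbinom(1L, size, 0.1)
    for (i in seq_len(n_extra)) {
      open <- which(cap > 0L)
      if (length(open) < 2L) break
      uv <- sort(sample(open, 2L))
      if (any(bonds[, 1L] == uv[1L] & bonds[, 2L] == uv[2L])) next
      bonds <- rbind(bonds, uv)
      labels <- c(labels, "single")
      cap[uv] <- cap[uv] - 1L
    }
  }
  list(atoms = unname(elements), bonds = bonds, bond_labels = labels,
       cap = unname(cap), id = id)
}

# first vertex with free valence, falling back to vertex 1
.open_vertex <- function(mol) {
  open <- which(mol$cap > 0L)
  if (length(open) == 0L) 1L else open[1L]
}

# append a chain of atoms to a molecule, starting at vertex `at`
.attach_chain <- function(mol, chain, at) {
  for (el in chain) {
    mol$atoms <- c(mol$atoms, el)
    mol$cap <- c(mol$cap, .VALENCE[[el]] - 1L)
    w <- length(mol$atoms)
    mol$bonds <- rbind(mol$bonds, c(at, w))
    mol$bond_labels <- c(mol$bond_labels, "single")
    mol$cap[at] <- mol$cap[at] - 1L
    at <- w
  }
  mol
}

.as_compound <- function(mol, id) {
  compound_graph(id, mol$atoms, mol$bonds, mol$bond_labels)
}

#' Deterministic random compound
#'
#' Generates a random connected molecular graph with valence-plausible
#' degrees: element labels from C/N/O/S/P, bond labels single/double/
#' triple, built as a random spanning tree plus occasional ring-closing
#' bonds. The same (seed, size) always yields the identical graph.
#'
#' @param seed integer seed.
#' @param size number of atoms (>= 1).
#' @param id compound identifier.
#' @return a [compound_graph()].
#' @export
generate_compound <- function(seed, size, id = sprintf("C%05d", seed)) {
  stopifnot(size >= 1L)
  with_seed(seed, .as_compound(.random_molecule(size), id))
}

#' Synthetic reaction benchmark specification
#'
#' Controls the generator of [generate_reaction_classes()]. Defaults
#' describe the standard benchmark used throughout the test-suite: 3 EC
#' subsubclasses with 6 reactions each, scaffolds of 5-8 atoms, and a
#' decoration rate of 0.2 (each scaffold atom independently sprouts a
#' random substituent with this probability), which leaves within-class
#' reactions clearly more similar than between-class ones without making
#' them identical.
#'
#' @param seed integer; the whole fixture is a pure function of it.
#' @param n_classes number of EC subsubclasses.
#' @param reactions_per_class reactions in each subsubclass.
#' @param scaffold_size integer range (min, max) of scaffold atom counts.
#' @param decoration_rate per-atom probability of a random substituent,
#'   in \[0, 1\]; 0 makes within-class reactions structurally identical.
#' @param cofactor_pool number of shared small cofactor/leave compounds.
#' @return an object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 42L, n_classes = 3L,
                         reactions_per_class = 6L,
                         scaffold_size = c(5L, 8L),
                         decoration_rate = 0.2, cofactor_pool = 4L) {
  stopifnot(n_classes >= 1L, reactions_per_class >= 1L,
            length(scaffold_size) == 2L,
            scaffold_size[1L] >= 1L,
            scaffold_size[2L] >= scaffold_size[1L],
            decoration_rate >= 0, decoration_rate <= 1,
            cofactor_pool >= 2L)
  structure(list(seed = as.integer(seed), n_classes = as.integer(n_classes),
                 reactions_per_class = as.integer(reactions_per_class),
                 scaffold_size = as.integer(scaffold_size),
                 decoration_rate = decoration_rate,
                 cofactor_pool = as.integer(cofactor_pool)),
            class = "fixture_spec")
}

#' Generate a synthetic reaction benchmark with known EC structure
#'
#' Emulates the structural assumption behind similarity-based EC
#' assignment: reactions in the same EC subsubclass share a conserved
#' chemical transformation. Each class owns a substrate scaffold (a base
#' scaffold shared between classes with the same EC class digit, plus a
#' class-specific motif) and a fixed transformation (a class-specific
#' atom chain added to the product). Reactions within a class differ by
#' random decorations applied identically to substrate and product, plus
#' a class-determined cofactor pair (and possibly a leave pair) drawn
#' from a shared pool of small compounds. Synthetic EC numbers use the
#' real 4-field format; classes sharing the first digit get related
#' scaffolds so that level-nesting accuracy is meaningful.
#'
#' @param spec a [fixture_spec()].
#' @return list with `compounds` (named list of [compound_graph()]),
#'   `records` (named list of [reaction_record()]), and `truth`
#'   (data frame reaction_id / ec). Regenerating with the same spec is
#'   byte-identical.
#' @export
generate_reaction_classes <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    pool <- lapply(seq_len(spec$cofactor_pool), function(i) {
      .random_molecule(sample(2:4, 1L), id = sprintf("W%03d", i))
    })
    names(pool) <- vapply(pool, `[[`, character(1), "id")

    n_l1 <- ceiling(spec$n_classes / 2)
    bases <- lapply(seq_len(n_l1), function(i) {
      .random_molecule(sample(spec$scaffold_size[1L]:spec$scaffold_size[2L],
                              1L))
    })

    compounds <- lapply(pool, function(m) .as_compound(m, m$id))
    records <- list()
    truth <- data.frame(reaction_id = character(0), ec = character(0))

    for (cls in seq_len(spec$n_classes)) {
      l1 <- ((cls - 1L) %/% 2L) + 1L
      l2 <- ((cls - 1L) %% 2L) + 1L
      ec <- sprintf("%d.%d.%d.1", l1, l2, cls)
      base <- bases[[l1]]
      # class motif distinguishes classes sharing a base scaffold
      motif <- sample(names(.VALENCE), 1L + (cls %% 2L), replace = TRUE)
      sub_scaffold <- .attach_chain(base, motif, at = .open_vertex(base))
      # conserved transformation: class-specific chain on the product
      trans <- sample(names(.VALENCE), 2L, replace = TRUE)
      prod_scaffold <- .attach_chain(sub_scaffold, trans,
                                     at = .open_vertex(sub_scaffold))
      # class-determined cofactor / leave participants
      cof <- sample(names(pool), 2L)
      # leave pairs need two further pool compounds beyond the cofactors
      has_leave <- (cls %% 2L) == 0L && spec$cofactor_pool >= 4L
      lv <- if (has_leave) sample(setdiff(names(pool), cof), 2L) else NULL

      for (r in seq_len(spec$reactions_per_class)) {
        rid <- sprintf("R%d%02d", cls, r)
        sub <- sub_scaffold
        prod <- prod_scaffold
        # identical decorations on both sides keep the transformation
        deco_at <- which(stats::runif(length(sub$atoms)) <
                           spec$decoration_rate & sub$cap > 0L)
        for (at in deco_at) {
          el <- sample(names(.VALENCE), 1L)
          sub <- .attach_chain(sub, el, at)
          prod <- .attach_chain(prod, el, at)
        }
        sid <- paste0(rid, "S")
        pid <- paste0(rid, "P")
        compounds[[sid]] <- .as_compound(sub, sid)
        compounds[[pid]] <- .as_compound(prod, pid)
        pairs <- data.frame(
          from = c(sid, cof[1L], if (has_leave) lv[1L]),
          to = c(pid, cof[2L], if (has_leave) lv[2L]),
          type = c("main", "cofactor", if (has_leave) "leave"),
          stringsAsFactors = FALSE)
        records[[rid]] <- reaction_record(
          rid, ec,
          substrates = c(sid, cof[1L], if (has_leave) lv[1L]),
          products = c(pid, cof[2L], if (has_leave) lv[2L]),
          pairs = pairs)
        truth <- rbind(truth, data.frame(reaction_id = rid, ec = ec))
      }
    }
    list(compounds = compounds, records = records, truth = truth)
  })
}

#' Write a generated fixture set to disk
#'
#' Writes `compounds.sdf`, `reactions.txt` (reaction-list format) and
#' `truth.tsv` under `dir`. Deterministic: the same spec produces
#' byte-identical files.
#'
#' @param fixture result of [generate_reaction_classes()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_sdf(fixture$compounds, file.path(dir, "compounds.sdf"))
  write_reaction_list(fixture$records, file.path(dir, "reactions.txt"))
  utils::write.table(fixture$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
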