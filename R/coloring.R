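# Atom coloring: canonical labels of the chemical substructure around each
# heavy atom, computed by iterative (Weisfeiler-Lehman style) neighborhood
# refinement over chemistry-aware base labels. A molecule's feature vector is
# the multiset tally of its atom colors.

#' Atom-coloring configuration
#'
#' @param atom_stereo Include the atom stereo parity code in base labels.
#' @param bond_stereo Include the bond stereo code in edge labels.
#' @param max_rounds Number of refinement rounds: a positive integer for a
#'   fixed neighborhood radius (default 1: one-bond environments keep
#'   functional-group chemistry recognizable across the small molecules
#'   typical of metabolite corpora while remaining comparable between
#'   molecules), or `"auto"` to iterate until the induced partition of
#'   atoms stabilizes.
#' @param digest Compress round >= 1 labels with a fixed 128-bit hash
#'   (default). With `FALSE`, labels stay full recursive strings; used by the
#'   collision audit.
#' @return A `coloring_config` list.
#' @export
coloring_config <- function(atom_stereo = TRUE, bond_stereo = TRUE,
                            max_rounds = 1L, digest = TRUE) {
  if (!identical(max_rounds, "auto")) {
    max_rounds <- as.integer(max_rounds)
    if (is.na(max_rounds) || max_rounds < 1L) {
      stop("max_rounds must be a positive integer or \"auto\"")
    }
  }
  structure(list(atom_stereo = isTRUE(atom_stereo),
                 bond_stereo = isTRUE(bond_stereo),
                 max_rounds = max_rounds,
                 digest = isTRUE(digest)),
            class = "coloring_config")
}

# Heavy-atom view: fold explicit hydrogens into heavy-atom H totals so that
# explicit-vs-implicit hydrogen representation cannot change features.
.heavy_view <- function(g) {
  is_h <- g$atoms$element == "H"
  heavy <- which(!is_h)
  if (length(heavy) == 0L) stop("molecule has no heavy atoms")
  idx_map <- integer(nrow(g$atoms))
  idx_map[heavy] <- seq_along(heavy)
  h_total <- g$atoms$h_count[heavy]
  b <- g$bonds
  keep <- logical(nrow(b))
  for (k in seq_len(nrow(b))) {
    ah <- is_h[b$a[k]]; bh <- is_h[b$b[k]]
    if (ah && bh) next            # H-H bond: ignored in the heavy view
    if (ah || bh) {
      hv <- if (ah) b$b[k] else b$a[k]
      if (!is_h[hv]) h_total[idx_map[hv]] <- h_total[idx_map[hv]] + 1L
    } else keep[k] <- TRUE
  }
  bonds <- b[keep, , drop = FALSE]
  if (nrow(bonds) > 0L) {
    bonds$a <- idx_map[bonds$a]
    bonds$b <- idx_map[bonds$b]
  }
  list(
    atoms = data.frame(element = g$atoms$element[heavy],
                       charge = g$atoms$charge[heavy],
                       h_total = h_total,
                       stereo = g$atoms$stereo[heavy],
                       stringsAsFactors = FALSE),
    bonds = bonds
  )
}

.base_labels <- function(hv, config) {
  lab <- paste0(hv$atoms$element, "|c", hv$atoms$charge, "|h", hv$atoms$h_total)
  if (config$atom_stereo) lab <- paste0(lab, "|s", hv$atoms$stereo)
  lab
}

.edge_labels <- function(hv, config) {
  lab <- paste0("o", hv$bonds$order)
  if (config$bond_stereo) lab <- paste0(lab, "s", hv$bonds$stereo)
  lab
}

#' Color the heavy atoms of a molecule
#'
#' Assigns each heavy atom a canonical label describing its surrounding
#' substructure. The base label is (element, formal charge, total attached
#' hydrogens, and the stereo parity when `atom_stereo`); each refinement
#' round replaces an atom's label with a canonical encoding of its previous
#' label plus the sorted multiset of (edge label, neighbor previous label)
#' pairs, where the edge label is the bond order (and the bond stereo code
#' when `bond_stereo`). The result is deterministic and invariant to atom
#' index permutation.
#'
#' @param g A `mol_graph`.
#' @param config A [coloring_config()].
#' @return Character vector of colors, one per heavy atom (in heavy-atom
#'   order), with attribute `rounds` giving the number of refinement rounds
#'   performed.
#' @export
color_atoms <- function(g, config = coloring_config()) {
  validate_mol_graph(g)
  hv <- .heavy_view(g)
  n <- nrow(hv$atoms)
  lab <- .base_labels(hv, config)
  elab <- .edge_labels(hv, config)

  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(nbr = integer(), e = character())
  for (k in seq_len(nrow(hv$bonds))) {
    a <- hv$bonds$a[k]; b <- hv$bonds$b[k]
    adj[[a]]$nbr <- c(adj[[a]]$nbr, b); adj[[a]]$e <- c(adj[[a]]$e, elab[k])
    adj[[b]]$nbr <- c(adj[[b]]$nbr, a); adj[[b]]$e <- c(adj[[b]]$e, elab[k])
  }

  auto <- identical(config$max_rounds, "auto")
  limit <- if (auto) n else config$max_rounds
  rounds <- 0L
  part_prev <- match(lab, unique(lab))
  r <- 0L
  while (r < limit) {
    r <- r + 1L
    new_lab <- character(n)
    for (i in seq_len(n)) {
      nb <- adj[[i]]
      env <- sort(paste0(nb$e, "~", lab[nb$nbr]), method = "radix")
      rec <- c(lab[i], env)
      new_lab[i] <- if (config$digest) rlang::hash(rec)
                    else paste0("(", paste(rec, collapse = ";"), ")")
    }
    part_new <- match(new_lab, unique(new_lab))
    if (auto && identical(.partition_key(part_new), .partition_key(part_prev))) {
      # partition stabilized: labels of this round carry no new splits
      lab <- new_lab
      rounds <- r
      break
    }
    lab <- new_lab
    part_prev <- part_new
    rounds <- r
  }
  attr(lab, "rounds") <- rounds
  lab
}

# canonical key of a set partition given group codes in first-appearance order
.partition_key <- function(codes) paste(codes, collapse = ",")

#' Featurize a molecule as atom-color counts
#'
#' @inheritParams color_atoms
#' @return Named integer vector: counts per color, names sorted. The counts
#'   sum to the number of heavy atoms.
#' @export
featurize <- function(g, config = coloring_config()) {
  cols <- color_atoms(g, config)
  tab <- table(cols)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out), method = "radix")]
}

#' Audit color digests for collisions across a corpus
#'
#' Recolors every graph twice, with digested and with full-string labels,
#' and verifies the mapping between digests and full label strings is a
#' bijection. A detected collision is reported as an error so callers can
#' fall back to `digest = FALSE`.
#'
#' @param graphs List of `mol_graph`s.
#' @param config A [coloring_config()] (its `digest` field is overridden).
#' @return Invisibly, the number of distinct colors audited.
#' @export
audit_color_collisions <- function(graphs, config = coloring_config()) {
  cfg_d <- config; cfg_d$digest <- TRUE
  cfg_f <- config; cfg_f$digest <- FALSE
  map <- new.env(parent = emptyenv())
  n_colors <- 0L
  for (g in graphs) {
    d <- color_atoms(g, cfg_d)
    f <- color_atoms(g, cfg_f)
    for (i in seq_along(d)) {
      prev <- get0(d[i], envir = map, inherits = FALSE)
      if (is.null(prev)) {
        assign(d[i], f[i], envir = map)
        n_colors <- n_colors + 1L
      } else if (!identical(prev, f[i])) {
        stop(sprintf("hash collision detected for color digest %s (graph %s); recolor with digest = FALSE", d[i], g$id))
      }
    }
  }
  invisible(n_colors)
}
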