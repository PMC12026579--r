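# Molecular graph container: the substrate of standardization and coloring.

# Recognized element symbols (periodic table, 1-118).
.elements <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf",
  "Es", "Fm", "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

# Standard valences used to fill in implicit hydrogen counts when a molfile
# omits them. Multi-valent elements list their allowed valences ascending;
# the smallest one accommodating the atom's bond order sum is used.
.valences <- list(
  H = 1L, B = 3L, C = 4L, N = c(3L, 5L), O = 2L, F = 1L, Si = 4L,
  P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L
)

#' Construct a molecular graph
#'
#' A light container for the atoms and bonds parsed from (or destined for) an
#' MDL molfile. Atom stereo parity and bond stereo are carried as the raw
#' molfile codes; implicit hydrogen counts are filled from a standard valence
#' table unless supplied.
#'
#' @param atoms Data frame with columns `element` (symbol), `charge`
#'   (integer formal charge), and optionally `h_count` (implicit hydrogens;
#'   `NA` means compute from the valence table), `stereo` (atom parity code:
#'   0 none, 1 odd, 2 even, 3 either) and `isotope` (mass difference, carried
#'   as an opaque annotation).
#' @param bonds Data frame with columns `a`, `b` (1-based atom indices),
#'   `order` (1 single, 2 double, 3 triple, 4 aromatic) and optionally
#'   `stereo` (molfile bond stereo code).
#' @param id Identifier string.
#' @return An object of class `mol_graph` with components `atoms`, `bonds`
#'   and `id`. Atoms additionally carry `valence_flag`, `TRUE` where the bond
#'   order sum exceeds every allowed valence (such atoms get 0 implicit H and
#'   are flagged rather than rejected).
#' @export
mol_graph <- function(atoms, bonds = NULL, id = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (nrow(atoms) == 0L) stop("mol_graph: molecule must contain at least one atom")
  if (is.null(atoms$charge)) atoms$charge <- 0L
  if (is.null(atoms$h_count)) atoms$h_count <- NA_integer_
  if (is.null(atoms$stereo)) atoms$stereo <- 0L
  if (is.null(atoms$isotope)) atoms$isotope <- 0L
  atoms$element <- as.character(atoms$element)
  atoms$charge <- as.integer(atoms$charge)
  atoms$stereo <- as.integer(atoms$stereo)
  atoms$isotope <- as.integer(atoms$isotope)

  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0L) {
    bonds <- data.frame(a = integer(), b = integer(), order = integer(),
                        stereo = integer())
  } else {
    bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
    if (is.null(bonds$stereo)) bonds$stereo <- 0L
    bonds$a <- as.integer(bonds$a)
    bonds$b <- as.integer(bonds$b)
    bonds$order <- as.integer(bonds$order)
    bonds$stereo <- as.integer(bonds$stereo)
  }

  g <- structure(list(atoms = atoms, bonds = bonds, id = as.character(id)),
                 class = "mol_graph")
  validate_mol_graph(g)
  g$atoms <- .fill_implicit_h(g)
  g
}

#' Validate molecular graph invariants
#'
#' Checks element symbols, bond index ranges, self-bonds and duplicate
#' undirected bonds. Called by [mol_graph()]; exported for reuse on graphs
#' assembled elsewhere.
#'
#' @param g A `mol_graph`.
#' @return `g`, invisibly; errors on violation.
#' @export
validate_mol_graph <- function(g) {
  n <- nrow(g$atoms)
  bad <- !(g$atoms$element %in% .elements)
  if (any(bad)) {
    stop(sprintf("unknown element symbol(s): %s (atom %s)",
                 paste(unique(g$atoms$element[bad]), collapse = ", "),
                 paste(which(bad), collapse = ", ")))
  }
  b <- g$bonds
  if (nrow(b) > 0L) {
    if (any(is.na(b$a)) || any(is.na(b$b)) ||
        any(b$a < 1L | b$a > n) || any(b$b < 1L | b$b > n)) {
      stop(sprintf("bond references atom index outside 1..%d", n))
    }
    if (any(b$a == b$b)) stop("bond with identical endpoints (a == b)")
    key <- paste(pmin(b$a, b$b), pmax(b$a, b$b))
    if (anyDuplicated(key)) stop("duplicate undirected bond")
    if (any(!(b$order %in% 1:4))) {
      stop("unsupported bond order (only 1 single, 2 double, 3 triple, 4 aromatic)")
    }
  }
  invisible(g)
}

# Bond order sum per atom; aromatic bonds count 1.5, and the total is floored
# (so an aromatic carbon in benzene has sum 3).
.bond_order_sums <- function(g) {
  n <- nrow(g$atoms)
  s <- numeric(n)
  b <- g$bonds
  if (nrow(b) > 0L) {
    ord <- ifelse(b$order == 4L, 1.5, as.numeric(b$order))
    for (k in seq_len(nrow(b))) {
      s[b$a[k]] <- s[b$a[k]] + ord[k]
      s[b$b[k]] <- s[b$b[k]] + ord[k]
    }
  }
  as.integer(floor(s + 1e-9))
}

# Effective allowed valences after charge adjustment: N/O/P/S gain a bond
# site per positive charge and lose one per negative; carbon loses |charge|.
.charge_adjusted_valences <- function(element, charge) {
  base <- .valences[[element]]
  if (is.null(base)) return(NULL)
  if (element %in% c("N", "O", "P", "S")) base + charge
  else if (element == "C") base - abs(charge)
  else base
}

.fill_implicit_h <- function(g) {
  atoms <- g$atoms
  sums <- .bond_order_sums(g)
  flag <- logical(nrow(atoms))
  h <- atoms$h_count
  for (i in seq_len(nrow(atoms))) {
    vals <- .charge_adjusted_valences(atoms$element[i], atoms$charge[i])
    if (is.na(h[i])) {
      if (is.null(vals)) {
        h[i] <- 0L  # no valence model for this element: assume none
      } else {
        fit <- vals[vals >= sums[i]]
        if (length(fit) == 0L) {
          h[i] <- 0L
          flag[i] <- TRUE
        } else {
          h[i] <- as.integer(min(fit) - sums[i])
        }
      }
    } else {
      h[i] <- as.integer(h[i])
      if (!is.null(vals) && !any(vals >= sums[i] + h[i])) flag[i] <- TRUE
    }
  }
  atoms$h_count <- h
  atoms$valence_flag <- flag
  atoms
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph %s: %d atoms, %d bonds>\n",
              if (nzchar(x$id)) x$id else "(unnamed)",
              nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}

# Adjacency list: for each atom, data.frame(nbr, order, stereo).
.adjacency <- function(g) {
  n <- nrow(g$atoms)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- list(nbr = integer(), order = integer(), stereo = integer())
  b <- g$bonds
  for (k in seq_len(nrow(b))) {
    a <- b$a[k]; bb <- b$b[k]
    adj[[a]]$nbr <- c(adj[[a]]$nbr, bb)
    adj[[a]]$order <- c(adj[[a]]$order, b$order[k])
    adj[[a]]$stereo <- c(adj[[a]]$stereo, b$stereo[k])
    adj[[bb]]$nbr <- c(adj[[bb]]$nbr, a)
    adj[[bb]]$order <- c(adj[[bb]]$order, b$order[k])
    adj[[bb]]$stereo <- c(adj[[bb]]$stereo, b$stereo[k])
  }
  adj
}

#' Permute atom indices of a molecular graph
#'
#' Relabels atoms by `perm` (atom `i` moves to position `perm[i]`) and remaps
#' bond endpoints accordingly. Used by isomorphism-invariance tests and the
#' synthetic generator's atom-reorder perturbation.
#'
#' @param g A `mol_graph`.
#' @param perm Integer permutation of `seq_len(nrow(g$atoms))`.
#' @return The permuted `mol_graph`.
#' @export
permute_atoms <- function(g, perm) {
  n <- nrow(g$atoms)
  stopifnot(length(perm) == n, all(sort(perm) == seq_len(n)))
  atoms <- g$atoms[order(perm), , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- g$bonds
  if (nrow(bonds) > 0L) {
    bonds$a <- perm[bonds$a]
    bonds$b <- perm[bonds$b]
  }
  out <- g
  out$atoms <- atoms
  out$bonds <- bonds
  out
}
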