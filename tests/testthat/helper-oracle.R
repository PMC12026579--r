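# Independent oracles, kept free of the implementation paths they check.

# Naive rooted unfolding-tree canonicalization: the depth-d tree string of a
# heavy atom, recursing through every neighbor (including the one it came
# from, matching iterative label refinement semantics).
oracle_tree_strings <- function(g, depth, atom_stereo = TRUE, bond_stereo = TRUE) {
  is_h <- g$atoms$element == "H"
  heavy <- which(!is_h)
  idx <- integer(nrow(g$atoms)); idx[heavy] <- seq_along(heavy)
  h_total <- g$atoms$h_count[heavy]
  nb <- rep(list(list(j = integer(), e = character())), length(heavy))
  for (k in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a[k]; b <- g$bonds$b[k]
    if (is_h[a] && is_h[b]) next
    if (is_h[a] || is_h[b]) {
      hv <- if (is_h[a]) b else a
      if (!is_h[hv]) h_total[idx[hv]] <- h_total[idx[hv]] + 1L
      next
    }
    e <- paste0("o", g$bonds$order[k],
                if (bond_stereo) paste0("s", g$bonds$stereo[k]) else "")
    ia <- idx[a]; ib <- idx[b]
    nb[[ia]]$j <- c(nb[[ia]]$j, ib); nb[[ia]]$e <- c(nb[[ia]]$e, e)
    nb[[ib]]$j <- c(nb[[ib]]$j, ia); nb[[ib]]$e <- c(nb[[ib]]$e, e)
  }
  base <- paste0(g$atoms$element[heavy], "|c", g$atoms$charge[heavy],
                 "|h", h_total,
                 if (atom_stereo) paste0("|s", g$atoms$stereo[heavy]) else "")
  tree <- function(i, d) {
    if (d == 0L) return(base[i])
    kids <- sort(vapply(seq_along(nb[[i]]$j), function(t) {
      paste0(nb[[i]]$e[t], "{", tree(nb[[i]]$j[t], d - 1L), "}")
    }, character(1)), method = "radix")
    paste0(base[i], "[", paste(kids, collapse = "+"), "]")
  }
  vapply(seq_along(heavy), tree, character(1), d = depth)
}

# direct-formula confusion metrics, independent of metrics.R internals
oracle_mcc <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}
oracle_prf <- function(tp, tn, fp, fn) {
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  a <- if (tp + tn + fp + fn == 0) 0 else (tp + tn) / (tp + tn + fp + fn)
  c(f1 = f, precision = p, recall = r, accuracy = a)
}

# partition of atoms induced by a label vector, as a canonical string
partition_of <- function(labels) {
  paste(match(labels, unique(labels)), collapse = ",")
}

# does partition b refine partition a (every b-class inside one a-class)?
refines <- function(b, a) {
  all(tapply(a, b, function(v) length(unique(v)) == 1L))
}
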