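# MDL molfile V2000 / SDF reading and writing, and knowledgebase loading.
#
# V2000 is fixed-width: counts line fields are 3 chars each with the version
# stamp in columns 34-39; atom lines carry the element in columns 32-34, the
# legacy charge code in 37-39 and atom stereo parity in 40-42; bond lines are
# four 3-char fields (a, b, order, stereo). "M  CHG"/"M  ISO" property lines
# supersede the legacy atom-block fields.

.substr_int <- function(line, from, to, default = 0L) {
  s <- trimws(substr(line, from, to))
  if (!nzchar(s)) return(default)
  v <- suppressWarnings(as.integer(s))
  if (is.na(v)) NA_integer_ else v
}

# legacy atom-block charge codes: 0 none, 1 +3, 2 +2, 3 +1, 4 doublet
# radical, 5 -1, 6 -2, 7 -3
.charge_code_to_charge <- c(`0` = 0L, `1` = 3L, `2` = 2L, `3` = 1L,
                            `4` = 0L, `5` = -1L, `6` = -2L, `7` = -3L)

#' Parse an MDL molfile (V2000)
#'
#' Reads a single connection table into a [mol_graph()]. Explicit hydrogen
#' atoms are retained as atoms (folding into heavy-atom hydrogen counts
#' happens at featurization). Charges come from `M  CHG` lines when present
#' (which then supersede all atom-block charge codes, per the format),
#' otherwise from the legacy atom-block code. Isotopes and radicals are
#' parsed but carried as opaque annotations.
#'
#' @param text Molfile contents as a single string or character vector of
#'   lines.
#' @param id Identifier for the resulting graph; defaults to the molfile
#'   title line (trimmed), if any.
#' @return A `mol_graph`.
#' @export
parse_molfile <- function(text, id = NULL) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)
  if (length(lines) < 4L) stop("molfile too short: no counts line (line 4)")
  counts <- lines[4]
  version <- trimws(substr(counts, 34, 39))
  if (identical(version, "V3000")) stop("V3000 molfiles are not supported (line 4)")
  if (nzchar(version) && !identical(version, "V2000")) {
    stop(sprintf("unrecognized CTAB version '%s' (line 4)", version))
  }
  n_atoms <- .substr_int(counts, 1, 3, NA_integer_)
  n_bonds <- .substr_int(counts, 4, 6, NA_integer_)
  if (is.na(n_atoms) || is.na(n_bonds) || n_atoms < 1L || n_bonds < 0L) {
    stop("malformed counts line (line 4)")
  }
  if (length(lines) < 4L + n_atoms + n_bonds) {
    stop(sprintf("molfile truncated: expected %d atom and %d bond lines",
                 n_atoms, n_bonds))
  }

  atom_lines <- lines[4L + seq_len(n_atoms)]
  element <- character(n_atoms)
  charge <- integer(n_atoms)
  stereo <- integer(n_atoms)
  radical <- integer(n_atoms)
  for (i in seq_len(n_atoms)) {
    ln <- atom_lines[i]
    el <- trimws(substr(ln, 32, 34))
    if (!nzchar(el)) stop(sprintf("missing element symbol (line %d)", 4L + i))
    if (!(el %in% .elements)) {
      stop(sprintf("unknown element '%s' (line %d)", el, 4L + i))
    }
    element[i] <- el
    cc <- .substr_int(ln, 37, 39, 0L)
    if (is.na(cc) || !(cc %in% 0:7)) {
      stop(sprintf("invalid charge code (line %d)", 4L + i))
    }
    charge[i] <- .charge_code_to_charge[[as.character(cc)]]
    if (cc == 4L) radical[i] <- 2L
    sp <- .substr_int(ln, 40, 42, 0L)
    stereo[i] <- if (is.na(sp) || !(sp %in% 0:3)) 0L else sp
  }

  bond_lines <- if (n_bonds > 0L) lines[4L + n_atoms + seq_len(n_bonds)] else character()
  ba <- integer(n_bonds); bb <- integer(n_bonds)
  bo <- integer(n_bonds); bs <- integer(n_bonds)
  for (k in seq_len(n_bonds)) {
    ln <- bond_lines[k]
    lno <- 4L + n_atoms + k
    a <- .substr_int(ln, 1, 3, NA_integer_)
    b <- .substr_int(ln, 4, 6, NA_integer_)
    o <- .substr_int(ln, 7, 9, NA_integer_)
    s <- .substr_int(ln, 10, 12, 0L)
    if (is.na(a) || is.na(b) || a < 1L || b < 1L || a > n_atoms || b > n_atoms) {
      stop(sprintf("bond references atom outside 1..%d (line %d)", n_atoms, lno))
    }
    if (is.na(o) || !(o %in% 1:4)) {
      stop(sprintf("unsupported bond type %s (line %d)", o, lno))
    }
    ba[k] <- a; bb[k] <- b; bo[k] <- o; bs[k] <- if (is.na(s)) 0L else s
  }

  isotope <- integer(n_atoms)
  prop_lines <- lines[-seq_len(4L + n_atoms + n_bonds)]
  chg_lines <- grep("^M  CHG", prop_lines, value = TRUE)
  rad_lines <- grep("^M  RAD", prop_lines, value = TRUE)
  iso_lines <- grep("^M  ISO", prop_lines, value = TRUE)
  parse_prop <- function(ln) {
    cnt <- .substr_int(ln, 7, 9, 0L)
    out <- matrix(0L, nrow = cnt, ncol = 2L)
    for (j in seq_len(cnt)) {
      off <- 10L + (j - 1L) * 8L
      out[j, 1L] <- .substr_int(ln, off + 1L, off + 3L, NA_integer_)
      out[j, 2L] <- .substr_int(ln, off + 5L, off + 7L, NA_integer_)
    }
    out
  }
  if (length(chg_lines) > 0L || length(rad_lines) > 0L) {
    charge[] <- 0L
    radical[] <- 0L
    for (ln in chg_lines) {
      m <- parse_prop(ln)
      for (j in seq_len(nrow(m))) {
        if (is.na(m[j, 1L]) || m[j, 1L] < 1L || m[j, 1L] > n_atoms) {
          stop("M  CHG references atom outside atom block")
        }
        charge[m[j, 1L]] <- m[j, 2L]
      }
    }
    for (ln in rad_lines) {
      m <- parse_prop(ln)
      for (j in seq_len(nrow(m))) radical[m[j, 1L]] <- m[j, 2L]
    }
  }
  for (ln in iso_lines) {
    m <- parse_prop(ln)
    for (j in seq_len(nrow(m))) {
      if (!is.na(m[j, 1L]) && m[j, 1L] >= 1L && m[j, 1L] <= n_atoms) {
        isotope[m[j, 1L]] <- m[j, 2L]
      }
    }
  }

  if (is.null(id)) id <- trimws(lines[1])
  g <- mol_graph(
    atoms = data.frame(element = element, charge = charge, stereo = stereo,
                       isotope = isotope, stringsAsFactors = FALSE),
    bonds = data.frame(a = ba, b = bb, order = bo, stereo = bs),
    id = id
  )
  g$atoms$radical <- radical
  g
}

#' Write a molecular graph as an MDL molfile (V2000)
#'
#' Coordinates are zeroed (2D flag); formal charges are emitted as `M  CHG`
#' property lines, isotopes as `M  ISO`. The output reparses (via
#' [parse_molfile()]) to a graph with identical per-atom and per-bond fields.
#'
#' @param g A `mol_graph` with at most 999 atoms and 999 bonds (the V2000
#'   limit).
#' @return Molfile text as a single string.
#' @export
write_molfile <- function(g) {
  validate_mol_graph(g)
  n <- nrow(g$atoms); m <- nrow(g$bonds)
  if (n > 999L || m > 999L) {
    stop(sprintf("V2000 supports at most 999 atoms/bonds (got %d atoms, %d bonds)", n, m))
  }
  out <- c(g$id, "  pathcolor", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  for (i in seq_len(n)) {
    out <- c(out, sprintf(
      "%10.4f%10.4f%10.4f %-3s%2d%3d%3d  0  0  0  0  0  0  0  0  0",
      0, 0, 0, g$atoms$element[i], 0L, 0L, g$atoms$stereo[i]))
  }
  for (k in seq_len(m)) {
    out <- c(out, sprintf("%3d%3d%3d%3d  0  0  0",
                          g$bonds$a[k], g$bonds$b[k],
                          g$bonds$order[k], g$bonds$stereo[k]))
  }
  emit_prop <- function(tag, idx, val) {
    res <- character()
    while (length(idx) > 0L) {
      take <- seq_len(min(8L, length(idx)))
      res <- c(res, paste0(sprintf("M  %s%3d", tag, length(take)),
                           paste0(sprintf(" %3d %3d", idx[take], val[take]),
                                  collapse = "")))
      idx <- idx[-take]; val <- val[-take]
    }
    res
  }
  chg <- which(g$atoms$charge != 0L)
  if (length(chg) > 0L) out <- c(out, emit_prop("CHG", chg, g$atoms$charge[chg]))
  iso <- which(g$atoms$isotope != 0L)
  if (length(iso) > 0L) out <- c(out, emit_prop("ISO", iso, g$atoms$isotope[iso]))
  rad <- which((g$atoms$radical %||% integer(n)) != 0L)
  if (length(rad) > 0L) out <- c(out, emit_prop("RAD", rad, g$atoms$radical[rad]))
  paste(c(out, "M  END", ""), collapse = "\n")
}

#' Read a multi-record SDF
#'
#' Splits on `$$$$` delimiters and parses each record with
#' [parse_molfile()]. Record ids come from the title lines.
#'
#' @param text SDF contents (string or lines), or a file path if `file=TRUE`.
#' @param file Interpret `text` as a path.
#' @return List of `mol_graph`s.
#' @export
read_sdf <- function(text, file = FALSE) {
  lines <- if (file) readLines(text, warn = FALSE)
           else if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]]
           else text
  lines <- sub("\r$", "", lines)
  ends <- grep("^\\${4}", lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  if (length(ends) == 0L) { starts <- 1L; ends <- length(lines) + 1L }
  recs <- list()
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:(ends[r] - 1L)]
    block <- block[cumsum(block == "M  END") == 0 | block == "M  END"]
    if (all(!nzchar(trimws(block)))) next
    recs[[length(recs) + 1L]] <- parse_molfile(block)
  }
  recs
}

#' Load a knowledgebase from structure files and an annotation table
#'
#' Structures are read from a directory of `.mol` files (compound id = file
#' name without extension) or a single `.sdf` (compound id = record title).
#' The annotation table is a two-column TSV `(compound_id, pathway_id)`; a
#' header row is detected and skipped if its first field is `compound_id`.
#' Pathway records are derived by inverting the annotation table; compounds
#' without annotations are retained (they still generate negative pairs).
#'
#' @param structures_path Directory of molfiles or path to an SDF file.
#' @param annotations_path Path to the annotation TSV.
#' @param kb_name Knowledgebase name stamped on every record.
#' @param strict If `TRUE` (default) an unparsable structure aborts the
#'   load; if `FALSE` it is skipped with a warning (annotations referencing
#'   only skipped compounds then drop their pathways with a warning).
#' @return List with `compounds` (list of compound records: `compound_id`,
#'   `source_kb`, `graph`, `pathway_ids`) and `pathways` (list of pathway
#'   records: `pathway_id`, `source_kb`, `member_compound_ids`).
#' @export
load_knowledgebase <- function(structures_path, annotations_path, kb_name,
                               strict = TRUE) {
  if (dir.exists(structures_path)) {
    files <- sort(list.files(structures_path, pattern = "\\.mol$", full.names = TRUE))
    graphs <- list()
    for (f in files) {
      cid <- sub("\\.mol$", "", basename(f))
      g <- tryCatch(parse_molfile(readLines(f, warn = FALSE), id = cid),
                    error = function(e) e)
      if (inherits(g, "error")) {
        if (strict) stop(sprintf("failed to parse %s: %s", f, conditionMessage(g)))
        warning(sprintf("skipping unparsable structure %s: %s", f, conditionMessage(g)))
        next
      }
      graphs[[cid]] <- g
    }
  } else if (file.exists(structures_path)) {
    recs <- read_sdf(structures_path, file = TRUE)
    graphs <- list()
    for (g in recs) {
      if (!nzchar(g$id)) stop("SDF record without a title line (needed as compound id)")
      graphs[[g$id]] <- g
    }
  } else {
    stop(sprintf("structures path does not exist: %s", structures_path))
  }
  if (length(graphs) == 0L) stop(sprintf("empty knowledgebase: no structures in %s", structures_path))

  ann <- utils::read.delim(annotations_path, header = FALSE, sep = "\t",
                           colClasses = "character", quote = "",
                           stringsAsFactors = FALSE)
  if (ncol(ann) < 2L) stop("annotation table must have two columns (compound_id, pathway_id)")
  ann <- ann[, 1:2]
  names(ann) <- c("compound_id", "pathway_id")
  if (nrow(ann) > 0L && tolower(ann$compound_id[1]) == "compound_id") {
    ann <- ann[-1L, , drop = FALSE]
  }
  missing <- setdiff(unique(ann$compound_id), names(graphs))
  if (length(missing) > 0L) {
    if (strict) {
      stop(sprintf("annotations reference compounds without structures: %s",
                   paste(missing, collapse = ", ")))
    }
    warning(sprintf("dropping annotations for structureless compounds: %s",
                    paste(missing, collapse = ", ")))
    ann <- ann[ann$compound_id %in% names(graphs), , drop = FALSE]
  }

  compounds <- lapply(names(graphs), function(cid) {
    list(compound_id = cid, source_kb = kb_name, graph = graphs[[cid]],
         pathway_ids = sort(unique(ann$pathway_id[ann$compound_id == cid])))
  })
  names(compounds) <- names(graphs)

  pids <- sort(unique(ann$pathway_id))
  pathways <- lapply(pids, function(pid) {
    list(pathway_id = pid, source_kb = kb_name,
         member_compound_ids = sort(unique(ann$compound_id[ann$pathway_id == pid])))
  })
  names(pathways) <- pids
  keep <- vapply(pathways, function(p) length(p$member_compound_ids) > 0L, logical(1))
  if (any(!keep)) {
    warning(sprintf("dropping pathways with no resolvable members: %s",
                    paste(pids[!keep], collapse = ", ")))
    pathways <- pathways[keep]
  }
  list(compounds = compounds, pathways = pathways)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
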