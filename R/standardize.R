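# Chemical representation standardization: round-trip structures through
# InChI (or canonical SMILES) so that tautomeric/resonance variants of the
# same compound map to one representative structure. Encoding/decoding is
# delegated to the obabel command-line tool (Open Babel), a conformant
# implementation of the published InChI standard; this module owns the
# round-trip orchestration, stereo policy and error handling.

#' Standardization configuration
#'
#' @param mode `"inchi"` (round-trip molfile -> InChI -> molfile; the
#'   default, which canonicalizes tautomeric/resonance forms), `"smiles"`
#'   (round-trip through canonical SMILES) or `"none"` (identity).
#' @param keep_stereo Retain stereo descriptors; with `FALSE`, atom parities
#'   and bond stereo flags are stripped before conversion.
#' @return A `std_config` list.
#' @export
std_config <- function(mode = c("inchi", "none", "smiles"), keep_stereo = TRUE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, keep_stereo = isTRUE(keep_stereo)),
            class = "std_config")
}

.strip_stereo <- function(g) {
  g$atoms$stereo <- 0L
  if (nrow(g$bonds) > 0L) g$bonds$stereo <- 0L
  g
}

.obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) stop("the 'obabel' executable is required but was not found on PATH")
  p
}

# Run obabel on input lines; conversion warnings are discarded (Open Babel
# chatters about undefined stereo on zero-coordinate molfiles).
.obabel <- function(in_fmt, out_fmt, input, extra = character()) {
  tf <- tempfile(fileext = paste0(".", in_fmt))
  on.exit(unlink(tf))
  writeLines(input, tf)
  out <- suppressWarnings(system2(.obabel_path(),
                                  c(paste0("-i", in_fmt), shQuote(tf),
                                    paste0("-o", out_fmt), extra),
                                  stdout = TRUE, stderr = FALSE))
  as.character(out)
}

.split_sdf_records <- function(lines) {
  ends <- grep("^\\${4}", lines)
  if (length(ends) == 0L) return(list())
  starts <- c(1L, head(ends, -1L) + 1L)
  lapply(seq_along(ends), function(r) lines[starts[r]:(ends[r] - 1L)])
}

#' Encode a molecular graph as a standard InChI string
#'
#' Deterministic for isomorphic inputs regardless of atom order; standard
#' InChI flavor (prefix `InChI=1S/`).
#'
#' @param g A `mol_graph`.
#' @param keep_stereo Strip stereo descriptors first when `FALSE`.
#' @return The InChI string.
#' @export
to_inchi <- function(g, keep_stereo = TRUE) {
  validate_mol_graph(g)
  if (!keep_stereo) g <- .strip_stereo(g)
  out <- .obabel("mol", "inchi", strsplit(write_molfile(g), "\n")[[1]])
  inchi <- grep("^InChI=", trimws(out), value = TRUE)
  if (length(inchi) == 0L) {
    stop(sprintf("standardization failed for '%s': no InChI produced", g$id),
         call. = FALSE)
  }
  inchi <- strsplit(inchi[1], " ", fixed = TRUE)[[1]][1]
  if (!startsWith(inchi, "InChI=1S/")) {
    stop(sprintf("standardization failed for '%s': not a standard InChI: %s",
                 g$id, inchi), call. = FALSE)
  }
  inchi
}

#' Decode an InChI string into a molecular graph
#'
#' Returns the canonical structure the InChI algorithm selects for that
#' identifier, i.e. one specific tautomeric/resonance form, so that
#' `to_inchi(from_inchi(x))` reproduces `x`.
#'
#' @param inchi A standard InChI string.
#' @param id Identifier for the resulting graph.
#' @return A `mol_graph`.
#' @export
from_inchi <- function(inchi, id = "") {
  if (!is.character(inchi) || length(inchi) != 1L || !startsWith(inchi, "InChI=")) {
    stop("from_inchi: input is not an InChI string")
  }
  out <- .obabel("inchi", "mol", inchi)
  if (!any(grepl("V2000", out, fixed = TRUE))) {
    stop(sprintf("from_inchi: conversion produced no structure for '%s'", inchi),
         call. = FALSE)
  }
  parse_molfile(out, id = id)
}

.to_smiles <- function(g) {
  out <- .obabel("mol", "can", strsplit(write_molfile(g), "\n")[[1]])
  out <- out[nzchar(trimws(out))]
  if (length(out) == 0L) {
    stop(sprintf("standardization failed for '%s': no SMILES produced", g$id),
         call. = FALSE)
  }
  strsplit(trimws(out[1]), "[\t ]")[[1]][1]
}

.from_smiles <- function(smi, id = "") {
  out <- .obabel("smi", "mol", smi)
  if (!any(grepl("V2000", out, fixed = TRUE))) {
    stop(sprintf("conversion produced no structure for SMILES '%s'", smi),
         call. = FALSE)
  }
  parse_molfile(out, id = id)
}

#' Standardize a molecular graph
#'
#' `mode = "none"` returns the input unchanged; `mode = "inchi"` performs
#' `from_inchi(to_inchi(g))`; `mode = "smiles"` round-trips through canonical
#' SMILES. The operation is idempotent: applying it twice yields a structure
#' with the same downstream feature vector.
#'
#' @param g A `mol_graph`.
#' @param config A [std_config()].
#' @return The standardized `mol_graph` (same `id`).
#' @export
standardize <- function(g, config = std_config()) {
  if (config$mode == "none") return(g)
  if (!config$keep_stereo) g <- .strip_stereo(g)
  out <- switch(config$mode,
    inchi = from_inchi(to_inchi(g, keep_stereo = config$keep_stereo), id = g$id),
    smiles = .from_smiles(.to_smiles(g), id = g$id))
  out$id <- g$id
  out
}

# Batch standardization: one obabel invocation per direction. Records are
# tracked by injected index titles on the forward pass; the backward pass
# converts unique intermediate strings and is re-run per molecule if the
# output count disagrees (a malformed identifier truncates an obabel batch).
.standardize_graphs_batch <- function(graphs, config) {
  n <- length(graphs)
  if (config$mode == "none") {
    return(list(graphs = graphs, error = character(n)))
  }
  res <- vector("list", n)
  err <- character(n)
  tagged <- lapply(seq_len(n), function(i) {
    g <- graphs[[i]]
    if (!config$keep_stereo) g <- .strip_stereo(g)
    g$id <- sprintf("IDX%d", i)
    g
  })
  sdf <- unlist(lapply(tagged, function(g) c(strsplit(write_molfile(g), "\n")[[1]], "$$$$")))
  if (config$mode == "inchi") {
    out <- .obabel("sdf", "inchi", sdf, extra = "-xt")
    out <- grep("^InChI=", trimws(out), value = TRUE)
    inter <- rep(NA_character_, n)
    for (ln in out) {
      parts <- strsplit(ln, " ", fixed = TRUE)[[1]]
      i <- suppressWarnings(as.integer(sub("^IDX", "", parts[length(parts)])))
      if (!is.na(i) && startsWith(parts[1], "InChI=1S/")) inter[i] <- parts[1]
    }
    err[is.na(inter)] <- "no standard InChI produced"
    back_fmt <- "inchi"
  } else {
    out <- trimws(.obabel("sdf", "can", sdf))
    out <- out[nzchar(out)]
    inter <- rep(NA_character_, n)
    for (ln in out) {
      parts <- strsplit(ln, "[\t ]")[[1]]
      i <- suppressWarnings(as.integer(sub("^IDX", "", parts[length(parts)])))
      if (!is.na(i)) inter[i] <- parts[1]
    }
    err[is.na(inter)] <- "no canonical SMILES produced"
    back_fmt <- "smi"
  }
  uniq <- unique(inter[!is.na(inter)])
  if (length(uniq) > 0L) {
    recs <- .split_sdf_records(.obabel(back_fmt, "sdf", uniq))
    back <- list()
    if (length(recs) == length(uniq)) {
      for (u in seq_along(uniq)) {
        back[[uniq[u]]] <- tryCatch(parse_molfile(recs[[u]]), error = function(e) NULL)
      }
    } else {
      # batch truncated by a failing record: recover molecule by molecule
      for (u in uniq) {
        back[[u]] <- tryCatch({
          r1 <- .obabel(back_fmt, "mol", u)
          parse_molfile(r1)
        }, error = function(e) NULL)
      }
    }
    for (i in seq_len(n)) {
      if (is.na(inter[i])) next
      g <- back[[inter[i]]]
      if (is.null(g)) {
        err[i] <- "round-trip decoding failed"
      } else {
        g$id <- graphs[[i]]$id
        res[[i]] <- g
      }
    }
  }
  list(graphs = res, error = err)
}

#' Standardize a set of compound records
#'
#' Applies the configured round-trip to every record's graph (batched
#' through single obabel invocations), collecting a manifest. Structures
#' that fail standardization are excluded (with status recorded) when
#' `on_error = "skip"`, keeping standardized and non-standardized runs
#' comparable on the intersection; with `on_error = "fail"` the first
#' failure aborts.
#'
#' @param records List of compound records (as from [load_knowledgebase()]).
#' @param config A [std_config()].
#' @param on_error `"fail"` or `"skip"`.
#' @return List with `records` (standardized) and `manifest` (data frame:
#'   `compound_id`, `source_kb`, `status`, `detail`).
#' @export
standardize_records <- function(records, config = std_config(),
                                on_error = c("fail", "skip")) {
  on_error <- match.arg(on_error)
  n <- length(records)
  batch <- .standardize_graphs_batch(lapply(records, `[[`, "graph"), config)
  out <- list()
  status <- character(n); detail <- character(n)
  for (i in seq_len(n)) {
    rec <- records[[i]]
    ok <- config$mode == "none" || !is.null(batch$graphs[[i]])
    if (!ok) {
      msg <- sprintf("standardization failed for '%s': %s", rec$compound_id,
                     batch$error[i])
      if (on_error == "fail") stop(msg, call. = FALSE)
      status[i] <- "failed"; detail[i] <- batch$error[i]
      next
    }
    if (config$mode != "none") rec$graph <- batch$graphs[[i]]
    out[[length(out) + 1L]] <- rec
    status[i] <- "ok"
  }
  list(records = out,
       manifest = data.frame(
         compound_id = vapply(records, `[[`, character(1), "compound_id"),
         source_kb = vapply(records, `[[`, character(1), "source_kb"),
         status = status, detail = detail, stringsAsFactors = FALSE))
}
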