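#' Ballesteros-Weinstein residue maps
#'
#' A residue map translates Ballesteros-Weinstein (BW) labels such as
#' `"2.64"` (transmembrane helix 2) or `"45.50"` (the ECL2 loop between TMs
#' 4 and 5) into concrete residue numbers of one receptor construct, as
#' numbered in the topology file. The map is user-supplied configuration:
#' BW assignment from sequence is deliberately out of scope, and the map is
#' the single source of truth for numbering.
#'
#' @param config Either a path to a YAML file or a list with fields
#'   `subtype` (character), optional `chain` (single character), and
#'   `entries`, a list of `{bw, resnum, resname}` records.
#' @return An object of class `residue_map` with fields `subtype`, `chain`,
#'   and `entries` (a data.frame with columns `bw`, `resnum`, `resname`).
#' @examples
#' map <- load_residue_map(list(
#'   subtype = "M1",
#'   entries = list(
#'     list(bw = "2.64", resnum = 85, resname = "TYR"),
#'     list(bw = "45.50", resnum = 178, resname = "CYS")
#'   )
#' ))
#' map_residue(map, "45.50")
#' @export
load_residue_map <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop("residue map config not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stop("residue map config must be a file path or a list", call. = FALSE)
  }
  if (is.null(config$subtype) || !nzchar(config$subtype)) {
    stop("residue map config must declare a 'subtype' name", call. = FALSE)
  }
  entries <- config$entries
  if (is.null(entries) || length(entries) == 0L) {
    stop("residue map config must declare at least one entry", call. = FALSE)
  }
  ent <- do.call(rbind, lapply(entries, function(e) {
    if (is.null(e$bw) || is.null(e$resnum)) {
      stop("each residue map entry needs 'bw' and 'resnum' fields",
        call. = FALSE
      )
    }
    data.frame(
      bw = as.character(e$bw),
      resnum = as.integer(e$resnum),
      resname = toupper(as.character(e$resname %||% NA_character_)),
      stringsAsFactors = FALSE
    )
  }))
  bad <- !grepl("^(?:[1-8]|12|23|34|45|56|67|78)\\.[0-9]{1,2}$", ent$bw)
  if (any(bad)) {
    stop(
      "malformed Ballesteros-Weinstein label(s): ",
      paste(ent$bw[bad], collapse = ", "),
      " (expected helix or loop code followed by '.NN', e.g. 2.64 or 45.50)",
      call. = FALSE
    )
  }
  if (anyDuplicated(ent$bw)) {
    stop(
      "duplicate Ballesteros-Weinstein label(s) in map: ",
      paste(unique(ent$bw[duplicated(ent$bw)]), collapse = ", "),
      call. = FALSE
    )
  }
  chain <- config$chain
  if (!is.null(chain) && (!is.character(chain) || nchar(chain) != 1L)) {
    stop("'chain' must be a single chain identifier character", call. = FALSE)
  }
  structure(
    list(subtype = config$subtype, chain = chain, entries = ent),
    class = "residue_map"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.residue_map <- function(x, ...) {
  cat(
    "Residue map for", x$subtype,
    if (!is.null(x$chain)) paste0("(chain ", x$chain, ")"), "\n"
  )
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Look up one Ballesteros-Weinstein label in a residue map
#'
#' @param map A `residue_map`.
#' @param bw_label A single BW label present in the map.
#' @return A one-row data.frame with `bw`, `resnum`, `resname`.
#' @export
map_residue <- function(map, bw_label) {
  stopifnot(inherits(map, "residue_map"))
  i <- match(bw_label, map$entries$bw)
  if (is.na(i)) {
    stop(
      "label ", bw_label, " is not present in the ", map$subtype,
      " residue map (resolution failures are never silent)",
      call. = FALSE
    )
  }
  map$entries[i, , drop = FALSE]
}

#' Resolve a BW label to a concrete atom selection in a topology
#'
#' Resolves a Ballesteros-Weinstein label through a residue map to atom
#' indices of a `bio3d` PDB topology. By default all non-hydrogen (heavy)
#' atoms of the residue are selected, as the pocket metrics are minimum
#' heavy-atom distances. HETATM records are
#' ignored; multi-chain topologies require the map to name a chain.
#'
#' @param map A `residue_map`.
#' @param topology A `bio3d` `pdb` object (see [bio3d::read.pdb()]).
#' @param bw_label BW label(s) to resolve; with more than one label the
#'   selection is the union over the residues (used e.g. for the
#'   minimum-distance-to-ECL2 metric).
#' @param atom_subset One of `"noh"` (all non-hydrogen atoms, default),
#'   `"backbone-noh"`, `"sidechain-noh"`, or a character vector of atom
#'   names.
#' @param on_name_mismatch What to do when the topology's residue name
#'   disagrees with the map's `resname`: `"warn"` (default) or `"error"`.
#' @return An object of class `atom_selection`: list with `atoms` (data.frame
#'   of the selected atom records), `xyz` indices, `bw_label`, `subset`.
#' @export
resolve_selection <- function(map, topology, bw_label,
                              atom_subset = "noh",
                              on_name_mismatch = c("warn", "error")) {
  stopifnot(inherits(map, "residue_map"))
  on_name_mismatch <- match.arg(on_name_mismatch)
  if (!inherits(topology, "pdb")) {
    stop("topology must be a bio3d 'pdb' object", call. = FALSE)
  }
  atoms <- topology$atom
  atoms$row <- seq_len(nrow(atoms))
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  chains <- unique(atoms$chain[!is.na(atoms$chain)])
  if (length(chains) > 1L && is.null(map$chain)) {
    stop(
      "topology has ", length(chains), " chains (",
      paste(chains, collapse = ", "),
      "); the residue map must name one via its 'chain' field",
      call. = FALSE
    )
  }
  if (!is.null(map$chain)) {
    atoms <- atoms[atoms$chain %in% map$chain, , drop = FALSE]
  }

  rows <- lapply(bw_label, function(lab) {
    ent <- map_residue(map, lab)
    res <- atoms[atoms$resno == ent$resnum, , drop = FALSE]
    if (nrow(res) == 0L) {
      stop(
        "residue ", ent$resnum, " (", lab, ") not found in topology",
        call. = FALSE
      )
    }
    topname <- unique(res$resid)
    if (!is.na(ent$resname) && !identical(topname, ent$resname)) {
      msg <- paste0(
        "residue ", ent$resnum, " (", lab, ") is ", topname,
        " in the topology but ", ent$resname, " in the map"
      )
      if (on_name_mismatch == "error") stop(msg, call. = FALSE)
      warning(msg, call. = FALSE)
    }
    res
  })
  res <- do.call(rbind, rows)

  hyd <- is_hydrogen(res)
  backbone <- res$elety %in% c("N", "CA", "C", "O", "OXT")
  keep <- if (identical(atom_subset, "noh")) {
    !hyd
  } else if (identical(atom_subset, "backbone-noh")) {
    !hyd & backbone
  } else if (identical(atom_subset, "sidechain-noh")) {
    !hyd & !backbone
  } else if (is.character(atom_subset)) {
    res$elety %in% atom_subset
  } else {
    stop("unknown atom_subset", call. = FALSE)
  }
  res <- res[keep, , drop = FALSE]
  if (nrow(res) == 0L) {
    stop(
      "empty atom selection for ", paste(bw_label, collapse = "+"),
      " with subset '", paste(atom_subset, collapse = ","),
      "' (e.g. a glycine has no side-chain heavy atoms)",
      call. = FALSE
    )
  }
  structure(
    list(
      atoms = res,
      atom_rows = res$row,
      xyz = as.vector(t(outer(res$row, 1:3, function(r, k) 3 * (r - 1) + k))),
      bw_label = bw_label,
      subset = atom_subset
    ),
    class = "atom_selection"
  )
}

# Hydrogen detection: element symbol column when present, atom-name
# heuristic (H, 1H.., 2H..) otherwise.
is_hydrogen <- function(atoms) {
  elesy <- atoms$elesy
  if (!is.null(elesy) && any(nzchar(elesy) & !is.na(elesy))) {
    out <- toupper(trimws(elesy)) == "H"
    out[is.na(out)] <- grepl("^[0-9]?H", atoms$elety[is.na(out)])
    return(out)
  }
  grepl("^[0-9]?H", atoms$elety)
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(
    "Atom selection:", paste(x$bw_label, collapse = "+"),
    "/", paste(x$subset, collapse = ","),
    "->", nrow(x$atoms), "atoms\n"
  )
  invisible(x)
}

#' Extract the coordinates of an atom selection from a frame
#'
#' @param sel An `atom_selection`.
#' @param frame_xyz Either a `bio3d` `pdb` object (its first frame is used)
#'   or a numeric xyz vector of length 3 * n_atoms for the full topology.
#' @return An n x 3 coordinate matrix (Angstrom).
#' @export
selection_coords <- function(sel, frame_xyz) {
  stopifnot(inherits(sel, "atom_selection"))
  if (inherits(frame_xyz, "pdb")) frame_xyz <- frame_xyz$xyz[1, ]
  frame_xyz <- as.numeric(frame_xyz)
  matrix(frame_xyz[sel$xyz], ncol = 3, byrow = TRUE)
}
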