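# Tiny hand-built PDB fixtures, written at test time.

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element) {
  name4 <- if (nchar(name) >= 4L) {
    substr(name, 1, 4)
  } else {
    sprintf(" %-3s", name)
  }
  sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    serial, name4, resname, chain, resno, x, y, z, 1.0, 0.0, element
  )
}

# Five-residue toy chain: TYR (12 heavy atoms), GLY (4), CYS (6), ALA (5),
# GLU (9), plus a couple of hydrogens to exercise heavy-atom filtering.
# Residues are spaced ~6 A apart along x; atoms jitter around the residue
# origin.
toy_residues <- function() {
  list(
    list(resno = 1L, resname = "TYR", atoms = c(
      "N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2",
      "CZ", "OH"
    ), hydro = c("HA", "HB2")),
    list(resno = 2L, resname = "GLY", atoms = c("N", "CA", "C", "O"),
      hydro = "HA2"),
    list(resno = 3L, resname = "CYS", atoms = c(
      "N", "CA", "C", "O", "CB", "SG"
    ), hydro = character(0)),
    list(resno = 4L, resname = "ALA", atoms = c(
      "N", "CA", "C", "O", "CB"
    ), hydro = character(0)),
    list(resno = 5L, resname = "GLU", atoms = c(
      "N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"
    ), hydro = character(0))
  )
}

toy_pdb_lines <- function(shift = c(0, 0, 0)) {
  lines <- character(0)
  serial <- 0L
  for (res in toy_residues()) {
    origin <- c((res$resno - 1) * 6, 0, 0)
    k <- 0L
    for (a in res$atoms) {
      serial <- serial + 1L
      k <- k + 1L
      pos <- origin + c(0.4 * k, 0.3 * (k %% 3), 0.2 * (k %% 4)) + shift
      elem <- substr(gsub("[0-9]", "", a), 1, 1)
      lines <- c(lines, pdb_atom_line(
        serial, a, res$resname, "A", res$resno, pos[1], pos[2], pos[3], elem
      ))
    }
    for (h in res$hydro) {
      serial <- serial + 1L
      k <- k + 1L
      pos <- origin + c(0.4 * k, 0.1, 0.1) + shift
      lines <- c(lines, pdb_atom_line(
        serial, h, res$resname, "A", res$resno, pos[1], pos[2], pos[3], "H"
      ))
    }
  }
  lines
}

write_toy_pdb <- function(path) {
  writeLines(c(toy_pdb_lines(), "END"), path)
  path
}

# Multi-model trajectory over the same topology: the whole chain shifts
# along +x by `step` Angstrom per frame.
write_toy_traj_pdb <- function(path, n_frames = 3L, step = 0) {
  lines <- character(0)
  for (i in seq_len(n_frames)) {
    lines <- c(
      lines, sprintf("MODEL     %4d", i),
      toy_pdb_lines(shift = c((i - 1) * step, 0, 0)), "ENDMDL"
    )
  }
  writeLines(c(lines, "END"), path)
  path
}

toy_residue_map <- function() {
  load_residue_map(list(
    subtype = "TOY",
    entries = list(
      list(bw = "2.64", resnum = 1, resname = "TYR"),
      list(bw = "2.61", resnum = 2, resname = "GLY"),
      list(bw = "45.50", resnum = 3, resname = "CYS"),
      list(bw = "45.49", resnum = 4, resname = "ALA"),
      list(bw = "7.36", resnum = 5, resname = "GLU")
    )
  ))
}
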