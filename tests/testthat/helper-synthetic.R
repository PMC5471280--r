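# Synthetic fixtures built in code: structures with exactly known geometry.

# A two-part structure: a long "core" helix (residues 301-340) and a short
# "mobile" helix (residues 489-497) whose placement is controlled by a
# rotation/translation, emulating a repositionable H12 on a rigid LBD core.
makeTwoPartStructure <- function(regionRotation = NULL,
                                 regionTranslation = NULL,
                                 chain = "A") {
  core <- makeSyntheticHelix(40, chain = chain, startRes = 301L)
  helix <- makeSyntheticHelix(9, chain = chain, startRes = 489L,
                              rotation = regionRotation,
                              translation = if (is.null(regionTranslation))
                                c(12, 0, 0) else regionTranslation + c(12, 0, 0))
  atoms <- rbind(structureAtoms(core), structureAtoms(helix))
  atoms$serial <- seq_len(nrow(atoms))
  newStructure(atoms, pdbID = "2PRT")
}

# Hand-placed atoms exercising charge-clamp, contact and hydrogen-bond
# geometry with exactly known distances.
atomRow <- function(serial, name, res_name, res_seq, xyz, chain = "A",
                    element = substr(name, 1, 1), hetero = FALSE) {
  data.frame(serial = serial, name = name, altloc = "",
             res_name = res_name, chain_id = chain, res_seq = res_seq,
             i_code = "", x = xyz[1], y = xyz[2], z = xyz[3],
             occupancy = 1, b_factor = 0, element = element,
             is_hetero = hetero, stringsAsFactors = FALSE)
}

makeClampStructure <- function() {
  atoms <- rbind(
    atomRow(1, "CA", "LYS", 314, c(-2, 0, 0)),
    atomRow(2, "NZ", "LYS", 314, c(0, 0, 0)),
    atomRow(3, "CA", "GLU", 493, c(5, 1, 0)),
    atomRow(4, "OE1", "GLU", 493, c(3, 0, 0)),
    atomRow(5, "OE2", "GLU", 493, c(3, 2, 0)))
  newStructure(atoms, pdbID = "CLMP")
}

# Minimal PDB text with controllable altloc records.
pdbLine <- function(serial, name, res, chain, resno, x, y, z, occ = 1,
                    altloc = " ", record = "ATOM  ", element = NULL) {
  if (is.null(element)) element <- substr(trimws(name), 1, 1)
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, altloc, res, chain, resno, x, y, z, occ,
          0, element)
}
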