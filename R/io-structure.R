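# PDB / mmCIF structure reading and writing. Only the first model block is
# read; alternate locations are resolved to the highest-occupancy copy
# (tie -> first encountered); insertion codes are kept as part of residue
# identity. Residue numbers are author numbering, verbatim from the file.

.parsePdbLines <- function(lines, path) {
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1)]
  sel <- grepl("^(ATOM  |HETATM)", lines)
  rec <- lines[sel]
  if (!length(rec)) stop("empty model: no ATOM/HETATM records in '", path, "'")
  sub <- function(a, b) trimws(substr(rec, a, b))
  x <- suppressWarnings(as.numeric(sub(31, 38)))
  y <- suppressWarnings(as.numeric(sub(39, 46)))
  z <- suppressWarnings(as.numeric(sub(47, 54)))
  resno <- suppressWarnings(as.integer(sub(23, 26)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z) | is.na(resno))
  if (length(bad)) {
    stop("format error in '", path, "': unparseable ATOM record at line ",
         which(sel)[bad[1]], ": ", rec[bad[1]])
  }
  occ <- suppressWarnings(as.numeric(sub(55, 60)))
  occ[is.na(occ)] <- 1
  b <- suppressWarnings(as.numeric(sub(61, 66)))
  b[is.na(b)] <- 0
  element <- sub(77, 78)
  name <- sub(13, 16)
  # infer element from the atom name when column 77-78 is blank
  noel <- element == ""
  if (any(noel)) {
    guess <- gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", name[noel]))
    one <- toupper(substr(guess, 1, 1))
    two <- toupper(substr(guess, 1, 2))
    element[noel] <- ifelse(two %in% names(.BONDI_RADII) &
                              !one %in% c("C", "N", "O", "H", "S", "P"),
                            two, one)
  }
  data.frame(
    chain = substr(rec, 22, 22),
    resno = resno,
    inscode = sub(27, 27),
    resname = sub(18, 20),
    atom = name,
    element = toupper(element),
    x = x, y = y, z = z, occ = occ, b = b,
    altloc = substr(rec, 17, 17),
    stringsAsFactors = FALSE
  )
}

.parseCifTokens <- function(line) {
  scan(text = line, what = "character", quiet = TRUE, quote = "'\"")
}

.parseCif <- function(lines, path) {
  # locate the _atom_site loop
  tagIdx <- grep("^_atom_site\\.", lines)
  if (!length(tagIdx)) stop("format error in '", path, "': no _atom_site loop found")
  first <- tagIdx[1]
  tags <- character()
  i <- first
  while (i <= length(lines) && grepl("^_atom_site\\.", lines[i])) {
    tags <- c(tags, sub("^_atom_site\\.([^ ]+).*$", "\\1", lines[i]))
    i <- i + 1
  }
  rows <- list()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        startsWith(ln, "loop_") || startsWith(ln, "data_")) break
    rows[[length(rows) + 1]] <- .parseCifTokens(ln)
    i <- i + 1
  }
  if (!length(rows)) stop("empty model: _atom_site loop has no rows in '", path, "'")
  nf <- lengths(rows)
  if (any(nf != length(tags))) {
    stop("format error in '", path, "': _atom_site row ", which(nf != length(tags))[1],
         " has ", nf[nf != length(tags)][1], " fields, expected ", length(tags))
  }
  m <- do.call(rbind, rows)
  colnames(m) <- tags
  getcol <- function(prefer, fallback = NULL) {
    for (nmc in c(prefer, fallback)) if (!is.null(nmc) && nmc %in% tags) return(m[, nmc])
    rep(NA_character_, nrow(m))
  }
  modelNum <- getcol("pdbx_PDB_model_num")
  if (!all(is.na(modelNum))) {
    keep <- modelNum == modelNum[1]
    m <- m[keep, , drop = FALSE]
  }
  getcol2 <- function(prefer, fallback = NULL) {
    for (nmc in c(prefer, fallback)) if (!is.null(nmc) && nmc %in% tags) return(m[, nmc])
    rep(NA_character_, nrow(m))
  }
  clean <- function(v, default = "") ifelse(v %in% c("?", ".", NA), default, v)
  data.frame(
    chain = clean(getcol2("auth_asym_id", "label_asym_id"), "A"),
    resno = as.integer(clean(getcol2("auth_seq_id", "label_seq_id"), "0")),
    inscode = clean(getcol2("pdbx_PDB_ins_code")),
    resname = clean(getcol2("auth_comp_id", "label_comp_id")),
    atom = clean(getcol2("auth_atom_id", "label_atom_id")),
    element = toupper(clean(getcol2("type_symbol"))),
    x = as.numeric(m[, "Cartn_x"]),
    y = as.numeric(m[, "Cartn_y"]),
    z = as.numeric(m[, "Cartn_z"]),
    occ = as.numeric(clean(getcol2("occupancy"), "1")),
    b = as.numeric(clean(getcol2("B_iso_or_equiv"), "0")),
    altloc = clean(getcol2("label_alt_id")),
    stringsAsFactors = FALSE
  )
}

.resolveAltloc <- function(at) {
  alt <- at$altloc
  alt[is.na(alt)] <- ""
  if (all(alt %in% c("", " ", "."))) {
    at$altloc <- NULL
    return(at)
  }
  key <- paste(at$chain, at$resno, at$inscode, at$atom)
  # keep highest occupancy per key; tie -> first encountered (stable order)
  ord <- order(factor(key, levels = unique(key)), -at$occ)
  at2 <- at[ord, , drop = FALSE]
  at2 <- at2[!duplicated(paste(at2$chain, at2$resno, at2$inscode, at2$atom)), ,
             drop = FALSE]
  # restore original row order
  at2 <- at2[order(match(paste(at2$chain, at2$resno, at2$inscode, at2$atom),
                         unique(key))), , drop = FALSE]
  at2$altloc <- NULL
  rownames(at2) <- NULL
  at2
}

#' Read an atomic model from PDB or mmCIF
#'
#' Reads all atoms of the first model block. Alternate locations are resolved
#' to the highest-occupancy copy (ties keep the first encountered); insertion
#' codes are preserved as part of residue identity; hydrogens are kept.
#'
#' @param path file path.
#' @param format "pdb", "mmcif" or "auto" (decide from extension/content).
#' @return an [AtomModel-class].
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writeStructure(atomModel(data.frame(chain = "A", resno = 1L, resname = "ALA",
#'   atom = "CA", element = "C", x = 0, y = 0, z = 0)), f)
#' readStructure(f)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else if (any(grepl("^_atom_site\\.", utils::head(lines, 2000)))) "mmcif"
      else "pdb"
  }
  at <- if (format == "pdb") .parsePdbLines(lines, path) else .parseCif(lines, path)
  at <- .resolveAltloc(at)
  atomModel(at, modelId = tools::file_path_sans_ext(basename(path)))
}

.pdbAtomName <- function(name, element) {
  # element right-justified in columns 13-14
  ifelse(nchar(element) == 1 & nchar(name) <= 3,
         sprintf(" %-3s", name), sprintf("%-4s", name))
}

#' Write an atomic model to PDB or mmCIF
#'
#' PDB coordinates are written with 3 decimals (the format's precision).
#'
#' @param model an [AtomModel-class].
#' @param path output file path.
#' @param format "pdb" or "mmcif"; "auto" decides from the extension.
#' @return `path`, invisibly.
#' @export
writeStructure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  at <- atoms(model)
  if (format == "pdb") {
    chain <- substr(ifelse(at$chain == "", "A", at$chain), 1, 1)
    lines <- sprintf(
      "ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      (seq_len(nrow(at)) - 1L) %% 99999L + 1L,
      .pdbAtomName(at$atom, at$element), at$resname, chain, at$resno,
      ifelse(at$inscode == "", " ", at$inscode),
      at$x, at$y, at$z, at$occ, at$b, at$element)
    writeLines(c(lines, "END"), path)
  } else {
    hdr <- c("data_model", "#", "loop_",
             paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                                     "label_atom_id", "label_comp_id",
                                     "label_asym_id", "auth_asym_id",
                                     "auth_seq_id", "pdbx_PDB_ins_code",
                                     "auth_comp_id", "auth_atom_id",
                                     "Cartn_x", "Cartn_y", "Cartn_z",
                                     "occupancy", "B_iso_or_equiv",
                                     "pdbx_PDB_model_num")))
    rows <- sprintf("ATOM %d %s %s %s %s %s %d %s %s %s %.3f %.3f %.3f %.3f %.3f 1",
                    seq_len(nrow(at)), at$element, at$atom, at$resname,
                    at$chain, at$chain, at$resno,
                    ifelse(at$inscode == "", "?", at$inscode),
                    at$resname, at$atom, at$x, at$y, at$z, at$occ, at$b)
    writeLines(c(hdr, rows, "#"), path)
  }
  invisible(path)
}

#' Subset an AtomModel by a Selection
#'
#' Preserves atom order; an empty result is allowed (not an error). Empty
#' selection criteria select everything.
#'
#' @param model an [AtomModel-class].
#' @param sel a [Selection-class] from [atomSelection()].
#' @return the selected [AtomModel-class].
#' @examples
#' m <- atomModel(data.frame(chain = c("A", "B"), resno = 1L, resname = "GLY",
#'   atom = "CA", element = "C", x = 0:1, y = 0, z = 0))
#' nAtoms(selectAtoms(m, atomSelection(chains = "A")))
#' @export
selectAtoms <- function(model, sel = atomSelection()) {
  at <- atoms(model)
  keep <- rep(TRUE, nrow(at))
  if (length(sel@chains)) keep <- keep & at$chain %in% sel@chains
  if (length(sel@residues))
    keep <- keep & at$resno >= sel@residues[1] & at$resno <= sel@residues[2]
  if (length(sel@atomNames)) keep <- keep & at$atom %in% sel@atomNames
  if (length(sel@resnames)) keep <- keep & at$resname %in% sel@resnames
  if (sel@heavyOnly) keep <- keep & toupper(at$element) != "H"
  out <- at[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("AtomModel", atoms = out, modelId = modelId(model))
}
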