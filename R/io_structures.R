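# Reading PDB / mmCIF files (plain or gzipped) into a normalized in-memory
# hierarchy: structure -> chains -> residues -> atoms.
#
# Only heavy atoms are kept: every distance in the scoring definitions is
# over heavy atoms, so hydrogens (and deuteriums) are dropped at parse time.
# Waters are dropped, only the highest-occupancy alternate location is kept,
# and only the first model of multi-model files is read.

# --- constructors ------------------------------------------------------------

new_chain <- function(chain_id, residues, atoms, molecule_class) {
  stopifnot(nrow(residues) >= 1L, nrow(atoms) >= 1L,
            molecule_class %in% MOLECULE_CLASSES)
  structure(list(chain_id = chain_id,
                 residues = residues,
                 atoms = atoms,
                 molecule_class = molecule_class),
            class = "cqa_chain")
}

new_structure <- function(chains, source_path = "<memory>", format = "PDB") {
  ids <- vapply(chains, function(ch) ch$chain_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate chain ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  names(chains) <- ids
  structure(list(chains = chains, source_path = source_path, format = format),
            class = "cqa_structure")
}

#' @export
print.cqa_structure <- function(x, ...) {
  cat("<structure> ", x$source_path, " (", x$format, "), ",
      length(x$chains), " chain(s)\n", sep = "")
  for (ch in x$chains) {
    cat(sprintf("  chain %-4s %-14s %4d residues %5d atoms\n",
                ch$chain_id, ch$molecule_class,
                nrow(ch$residues), nrow(ch$atoms)))
  }
  invisible(x)
}

n_chains <- function(structure) length(structure$chains)

chain_ids <- function(structure) names(structure$chains)

# Coordinates of all (heavy) atoms of a chain as an n x 3 matrix.
chain_coords <- function(chain) {
  as.matrix(chain$atoms[, c("x", "y", "z")])
}

# --- element handling --------------------------------------------------------

# Infer an element symbol from a PDB-style atom name when the element column
# is absent. Leading digits are ignored ("1HB"); two-letter symbols are only
# accepted when the two leading characters form a known symbol that is not a
# plausible one-letter element followed by a remoteness letter (e.g. "CA" in
# a polymer is calcium only when it is a lone het atom; here we take the
# conservative route used by most parsers: two-letter symbols are recognized
# from the padded name field when available, otherwise the first letter wins
# for C/N/O/S/P/H).
infer_element <- function(name, padded = NULL) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  if (nchar(nm) == 0L) return("X")
  first <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  # A name occupying the first column of the 4-char field signals a
  # two-letter element (PDB convention), e.g. "FE  ", "ZN  ", "CL1 ".
  if (!is.null(padded) && nchar(padded) == 4L && substr(padded, 1, 1) != " " &&
      two %in% TWO_LETTER_ELEMENTS && !(first %in% c("H")))
    return(two)
  if (first %in% c("C", "N", "O", "S", "P", "H")) return(first)
  if (two %in% TWO_LETTER_ELEMENTS) return(two)
  first
}

normalize_element <- function(element, name, padded = NULL) {
  el <- toupper(trimws(element))
  ifelse(is.na(el) | el == "" | el == "?" | el == ".",
         mapply(infer_element, name, if (is.null(padded)) vector("list", length(name)) else padded,
                USE.NAMES = FALSE),
         el)
}

# --- raw record parsing ------------------------------------------------------

read_text_lines <- function(path) {
  is_gz <- grepl("\\.gz$", path, ignore.case = TRUE)
  if (!is_gz) {
    # also detect gzip by magic bytes
    con <- file(path, "rb")
    magic <- readBin(con, "raw", 2L)
    close(con)
    is_gz <- length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
  }
  con <- if (is_gz) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

parse_pdb_atoms <- function(lines) {
  rec <- substr(lines, 1, 6)
  model_no <- cumsum(startsWith(lines, "MODEL "))
  keep <- (rec == "ATOM  " | rec == "HETATM") & (model_no <= 1L)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(NULL)
  name_raw <- substr(lines, 13, 16)
  df <- data.frame(
    record  = trimws(substr(lines, 1, 6)),
    name    = trimws(name_raw),
    name_raw = name_raw,
    altloc  = substr(lines, 17, 17),
    resname = trimws(substr(lines, 18, 20)),
    chain   = substr(lines, 22, 22),
    number  = suppressWarnings(as.integer(substr(lines, 23, 26))),
    icode   = trimws(substr(lines, 27, 27)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    occ = suppressWarnings(as.numeric(substr(lines, 55, 60))),
    element = trimws(substr(lines, 77, 78)),
    stringsAsFactors = FALSE
  )
  df$element <- normalize_element(df$element, df$name, df$name_raw)
  df$name_raw <- NULL
  df
}

# Tokenize one mmCIF data line, honoring single/double quotes.
cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  if (m[1] == -1L) return(character(0))
  toks <- regmatches(line, list(m))[[1]]
  gsub("^['\"]|['\"]$", "", toks)
}

parse_cif_atoms <- function(lines) {
  lines <- trimws(lines)
  # locate the atom_site loop
  i <- 1L; n <- length(lines)
  tags <- character(0); data_start <- NA_integer_
  while (i <= n) {
    if (lines[i] == "loop_") {
      j <- i + 1L
      tg <- character(0)
      while (j <= n && startsWith(lines[j], "_")) {
        tg <- c(tg, sub("\\s.*$", "", lines[j]))
        j <- j + 1L
      }
      if (length(tg) > 0L && all(startsWith(tg, "_atom_site."))) {
        tags <- tg; data_start <- j
        break
      }
      i <- j
    } else i <- i + 1L
  }
  if (length(tags) == 0L)
    return(NULL)
  # collect data rows until the loop ends
  rows <- list(); i <- data_start
  while (i <= n) {
    ln <- lines[i]
    if (ln == "" || startsWith(ln, "#") || startsWith(ln, "_") ||
        ln == "loop_" || startsWith(ln, "data_"))
      break
    rows[[length(rows) + 1L]] <- cif_tokens(ln)
    i <- i + 1L
  }
  if (length(rows) == 0L) return(NULL)
  bad <- vapply(rows, length, integer(1)) != length(tags)
  if (any(bad))
    stop("malformed mmCIF atom_site loop: token count mismatch on ",
         sum(bad), " row(s)")
  mat <- do.call(rbind, rows)
  colnames(mat) <- sub("^_atom_site\\.", "", tags)
  col <- function(nm, alt = NULL) {
    if (nm %in% colnames(mat)) {
      v <- mat[, nm]
      v[v %in% c(".", "?")] <- NA
      v
    } else if (!is.null(alt) && alt %in% colnames(mat)) {
      col(alt)
    } else rep(NA_character_, nrow(mat))
  }
  model <- col("pdbx_PDB_model_num")
  if (!all(is.na(model))) {
    first <- model[!is.na(model)][1]
    keep <- is.na(model) | model == first
    mat <- mat[keep, , drop = FALSE]
  }
  chain <- col("auth_asym_id", "label_asym_id")
  number <- col("auth_seq_id", "label_seq_id")
  df <- data.frame(
    record  = col("group_PDB"),
    name    = col("auth_atom_id", "label_atom_id"),
    altloc  = col("label_alt_id"),
    resname = col("auth_comp_id", "label_comp_id"),
    chain   = chain,
    number  = suppressWarnings(as.integer(number)),
    icode   = col("pdbx_PDB_ins_code"),
    x = as.numeric(col("Cartn_x")),
    y = as.numeric(col("Cartn_y")),
    z = as.numeric(col("Cartn_z")),
    occ = suppressWarnings(as.numeric(col("occupancy"))),
    element = col("type_symbol"),
    stringsAsFactors = FALSE
  )
  df$record[is.na(df$record)] <- "ATOM"
  df$altloc[is.na(df$altloc)] <- ""
  df$icode[is.na(df$icode)] <- ""
  df$element <- normalize_element(df$element, df$name)
  df
}

# --- normalization -----------------------------------------------------------

# Residue classification by component code.
residue_kind <- function(resname) {
  ifelse(resname %in% c(names(AA_THREE_TO_ONE), names(AA_MODIFIED_TO_ONE)), "aa",
  ifelse(resname %in% names(NUC_TO_ONE), "nuc", "het"))
}

one_letter_code <- function(resname, kind) {
  out <- rep(NA_character_, length(resname))
  aa <- kind == "aa"
  out[aa] <- unname(c(AA_THREE_TO_ONE, AA_MODIFIED_TO_ONE)[resname[aa]])
  out[aa & is.na(out)] <- "X"
  nc <- kind == "nuc"
  out[nc] <- unname(NUC_TO_ONE[resname[nc]])
  out[nc & is.na(out)] <- "N"
  out[kind == "het"] <- "-"
  out
}

# Turn a raw atom table into a structure: drop waters/hydrogens, resolve
# altlocs, split non-polymer components into their own single-residue chains,
# classify every chain.
atoms_to_structure <- function(df, source_path, format, constants) {
  df <- df[!is.na(df$x) & !is.na(df$y) & !is.na(df$z), , drop = FALSE]
  df <- df[!(df$resname %in% WATER_CODES), , drop = FALSE]
  df <- df[!(df$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(df) == 0L)
    stop("no heavy atoms left after normalization in ", source_path)
  df$occ[is.na(df$occ)] <- 1
  df$icode[is.na(df$icode)] <- ""
  df$altloc[is.na(df$altloc)] <- ""
  df$altloc[df$altloc %in% c(".", "?")] <- ""

  # altloc resolution: keep highest occupancy per atom slot; ties go to the
  # blank altloc, then 'A', then file order (stable sort). File order of the
  # winning rows is preserved.
  key <- paste(df$chain, df$number, df$icode, df$resname, df$name, sep = "\r")
  ord <- order(key, -df$occ, df$altloc != "", df$altloc, seq_len(nrow(df)))
  winners <- ord[!duplicated(key[ord])]
  df <- df[sort(winners), , drop = FALSE]

  df$kind <- residue_kind(df$resname)

  chains <- list()
  for (cid in unique(df$chain)) {
    sub <- df[df$chain == cid, , drop = FALSE]
    rkey <- paste(sub$number, sub$icode, sub$resname, sep = "\r")
    rids <- unique(rkey)
    rinfo <- sub[match(rids, rkey), c("resname", "number", "icode", "kind")]
    poly <- rinfo$kind %in% c("aa", "nuc")
    # polymer part stays one chain
    if (any(poly)) {
      sel <- rkey %in% rids[poly]
      chains[[length(chains) + 1L]] <-
        build_chain(cid, sub[sel, , drop = FALSE], constants)
    }
    # every non-polymer component becomes its own small-molecule chain
    for (rid in rids[!poly]) {
      sel <- rkey == rid
      part <- sub[sel, , drop = FALSE]
      lig_id <- if (any(poly) || sum(!poly) > 1L)
        paste0(cid, "-", part$resname[1], part$number[1]) else cid
      chains[[length(chains) + 1L]] <- build_chain(lig_id, part, constants)
    }
  }
  if (length(chains) == 0L)
    stop("no chains found in ", source_path)
  new_structure(chains, source_path = source_path, format = format)
}

# Build one chain object from its atom rows (single molecule class).
build_chain <- function(chain_id, sub, constants) {
  rkey <- paste(sub$number, sub$icode, sub$resname, sep = "\r")
  rids <- unique(rkey)
  ridx <- match(rkey, rids)
  first <- match(rids, rkey)
  residues <- data.frame(
    name = sub$resname[first],
    number = sub$number[first],
    icode = sub$icode[first],
    seq_id = paste0(sub$number[first], sub$icode[first]),
    stringsAsFactors = FALSE
  )
  residues$one_letter <- one_letter_code(residues$name,
                                         residue_kind(residues$name))
  atoms <- data.frame(
    res_idx = ridx,
    name = sub$name,
    element = sub$element,
    x = sub$x, y = sub$y, z = sub$z,
    stringsAsFactors = FALSE
  )
  cls <- classify_residue_kinds(residue_kind(residues$name), nrow(residues),
                                chain_id, residues$name, constants)
  new_chain(chain_id, residues, atoms, cls)
}

classify_residue_kinds <- function(kinds, n_res, chain_id, resnames, constants) {
  u <- unique(kinds)
  if (all(u == "aa")) {
    if (n_res <= constants$peptide_max_len) "PEPTIDE" else "PROTEIN"
  } else if (all(u == "nuc")) {
    "NUCLEIC"
  } else if (all(u == "het")) {
    if (n_res != 1L)
      stop("chain ", chain_id, ": multi-residue non-polymer entity (",
           paste(unique(resnames), collapse = ","),
           ") is not supported; split components into separate chains")
    "SMALL_MOLECULE"
  } else {
    stop("chain ", chain_id, ": mixed polymer types within one chain (",
         paste(unique(paste0(resnames, "[", kinds, "]")), collapse = ", "), ")")
  }
}

# --- public API --------------------------------------------------------------

#' Parse a structure file
#'
#' Reads a PDB or mmCIF file (plain or gzip-compressed) into a normalized
#' structure. Hydrogens and waters are dropped, only the highest-occupancy
#' alternate location of each atom is kept, and only the first model of a
#' multi-model file is read. Non-polymer components (ligands) are split into
#' their own single-residue chains so that every chain has exactly one
#' molecule class; a ligand sharing a chain id with a polymer gets the
#' derived id `<chain>-<comp><number>`.
#'
#' @param path Path to the file. Gzip input is detected from a `.gz` suffix
#'   or from the gzip magic bytes.
#' @param format_hint Optional `"PDB"` or `"MMCIF"`; by default the format is
#'   inferred from the file extension, falling back to content sniffing.
#' @param constants A [scoring_constants()] object (controls the peptide
#'   length threshold used for chain classification).
#' @return A `cqa_structure`: a named list of chains, each with a residue
#'   table, an atom table (heavy atoms only) and a molecule class
#'   (`PROTEIN`, `PEPTIDE`, `NUCLEIC` or `SMALL_MOLECULE`).
#' @export
parse_structure <- function(path, format_hint = NULL,
                            constants = scoring_constants()) {
  if (!file.exists(path))
    stop("cannot read structure file: ", path)
  lines <- read_text_lines(path)
  fmt <- format_hint
  if (is.null(fmt)) {
    base <- sub("\\.gz$", "", path, ignore.case = TRUE)
    ext <- tolower(tools::file_ext(base))
    fmt <- if (ext %in% c("cif", "mmcif")) "MMCIF"
           else if (ext %in% c("pdb", "ent")) "PDB"
           else if (any(grepl("^_atom_site\\.", trimws(lines))) ||
                    any(startsWith(lines, "data_"))) "MMCIF"
           else "PDB"
  }
  fmt <- toupper(fmt)
  if (!fmt %in% c("PDB", "MMCIF"))
    stop("unknown format hint: ", fmt)
  df <- if (fmt == "PDB") parse_pdb_atoms(lines) else parse_cif_atoms(lines)
  if (is.null(df) || nrow(df) == 0L)
    stop("no atom records found in ", path, " (parsed as ", fmt, ")")
  atoms_to_structure(df, source_path = path, format = fmt,
                     constants = constants)
}

#' Classify a chain by molecule type
#'
#' A chain of standard (or recognized modified) amino acids is `PROTEIN`,
#' or `PEPTIDE` when it has at most `peptide_max_len` residues; a chain of
#' nucleotides is `NUCLEIC`; a single non-polymer component is
#' `SMALL_MOLECULE`. Mixed chains are an error.
#'
#' @param chain A chain from a parsed structure.
#' @param peptide_max_len Maximum length of a peptide (default 20).
#' @return One of `"PROTEIN"`, `"PEPTIDE"`, `"NUCLEIC"`, `"SMALL_MOLECULE"`.
#' @export
classify_chain <- function(chain, peptide_max_len = 20L) {
  kinds <- residue_kind(chain$residues$name)
  cst <- scoring_constants(peptide_max_len = peptide_max_len)
  classify_residue_kinds(kinds, nrow(chain$residues), chain$chain_id,
                         chain$residues$name, cst)
}

#' Extract the one-letter sequence of a polymer chain
#'
#' @param chain A `PROTEIN`, `PEPTIDE` or `NUCLEIC` chain. Unknown amino
#'   acids become `X`, unknown nucleotides `N`.
#' @return A single sequence string.
#' @export
extract_sequence <- function(chain) {
  if (chain$molecule_class == "SMALL_MOLECULE")
    stop("chain ", chain$chain_id,
         ": small-molecule chains have no sequence")
  paste(chain$residues$one_letter, collapse = "")
}

is_polymer <- function(chain) chain$molecule_class != "SMALL_MOLECULE"
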