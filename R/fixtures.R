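# Synthetic test complexes: deterministic generators for idealized
# multimers, nucleic-acid strands and toy ligands, plus minimal PDB/mmCIF
# writers so every module can be exercised without downloading structures.
#
# The geometry is idealized (rigid per-residue templates on a helical CA
# trace), not physically relaxed: it gives exact ground truth for mapping
# recovery and RMSD tests, but does not emulate real side-chain packing.

# Per-subunit-letter sequences, cycled to the requested chain length. Two
# letters never share a sequence, so different subunit types never group.
FIXTURE_SEQS <- c(
  A = "AEKLDWRVFGSTNQH",
  B = "GSHNQYMIPKAVRDE",
  C = "TWLEKFDGARSVNIQ",
  D = "VRPMGAYLSTQEKDN"
)

FIXTURE_ONE_TO_THREE <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

#' Describe a synthetic complex
#'
#' Captures everything needed to build a reference complex and a perturbed
#' model of it deterministically from a seed.
#'
#' @param stoichiometry String like `"A2"`, `"A4"`, `"A2B1"`. Each letter is
#'   a subunit type; the digit is the copy number. Chains are labeled
#'   `A, B, C, ...` in order of creation.
#' @param chain_length Residues per polymer chain (default 24).
#' @param molecule_types Named character vector mapping subunit letters to
#'   `"protein"` (default) or `"nucleic"`.
#' @param ligand `NULL`, or the name of a toy ligand (see [toy_ligand()]),
#'   or a `data.frame(name, element, x, y, z)` of heavy atoms. The ligand is
#'   placed in contact with the first chain.
#' @param n_ligands Number of copies of the ligand to place (default 1).
#' @param noise Standard deviation (Angstrom) of Gaussian coordinate noise
#'   added to every model atom; scalar, or named per model chain.
#' @param transforms Named list (by reference chain id) of rigid transforms
#'   to apply to model chains, each a `list(rotation = 3x3, translation =
#'   length-3)`.
#' @param relabel Named character vector renaming model chains
#'   (`old id -> new id`); ground truth is returned so tests can check
#'   mapping recovery.
#' @param seed RNG seed; the same spec and seed give identical structures.
#' @return A list of class `cqa_fixture_spec`.
#' @export
fixture_spec <- function(stoichiometry = "A2", chain_length = 24L,
                         molecule_types = NULL, ligand = NULL,
                         n_ligands = 1L, noise = 0,
                         transforms = NULL, relabel = NULL, seed = 1L) {
  counts <- parse_stoichiometry(stoichiometry)
  structure(list(stoichiometry = stoichiometry, counts = counts,
                 chain_length = as.integer(chain_length),
                 molecule_types = molecule_types, ligand = ligand,
                 n_ligands = as.integer(n_ligands),
                 noise = noise, transforms = transforms,
                 relabel = relabel, seed = as.integer(seed)),
            class = "cqa_fixture_spec")
}

parse_stoichiometry <- function(s) {
  m <- gregexpr("([A-Z])([0-9]+)", s)[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse stoichiometry: ", s)
  parts <- regmatches(s, list(m))[[1]]
  counts <- as.integer(sub("^[A-Z]", "", parts))
  names(counts) <- sub("[0-9]+$", "", parts)
  if (anyDuplicated(names(counts))) stop("repeated subunit letter in ", s)
  counts
}

# --- idealized chain geometry ------------------------------------------------

# CA trace of an idealized alpha-helix along +z, plus rigid local frames.
helix_trace <- function(n, radius = 2.3, rise = 1.5, turn = 100 * pi / 180) {
  i <- seq_len(n) - 1L
  ca <- cbind(radius * cos(i * turn), radius * sin(i * turn), rise * i)
  e1 <- cbind(cos(i * turn), sin(i * turn), 0)          # radial
  e2 <- cbind(-sin(i * turn), cos(i * turn), 0)         # tangential
  e3 <- matrix(rep(c(0, 0, 1), each = n), n, 3)         # axial
  list(ca = ca, e1 = e1, e2 = e2, e3 = e3)
}

# Backbone + CB atoms for a protein chain of the given one-letter sequence.
protein_chain_atoms <- function(seq1) {
  n <- nchar(seq1)
  tr <- helix_trace(n)
  res <- strsplit(seq1, "")[[1]]
  at <- function(name, element, off1, off2, off3) {
    data.frame(res_i = seq_len(n), name = name, element = element,
               x = tr$ca[, 1] + off1 * tr$e1[, 1] + off2 * tr$e2[, 1] + off3 * tr$e3[, 1],
               y = tr$ca[, 2] + off1 * tr$e1[, 2] + off2 * tr$e2[, 2] + off3 * tr$e3[, 2],
               z = tr$ca[, 3] + off1 * tr$e1[, 3] + off2 * tr$e2[, 3] + off3 * tr$e3[, 3],
               stringsAsFactors = FALSE)
  }
  atoms <- rbind(
    at("N",  "N", -0.45,  1.22, -0.65),
    at("CA", "C",  0.00,  0.00,  0.00),
    at("C",  "C", -0.55, -1.20,  0.70),
    at("O",  "O", -1.25, -1.35,  1.70),
    at("CB", "C",  1.45,  0.20,  0.55)
  )
  # glycine has no CB
  atoms <- atoms[!(atoms$name == "CB" & res[atoms$res_i] == "G"), ]
  atoms <- atoms[order(atoms$res_i, match(atoms$name, c("N", "CA", "C", "O", "CB"))), ]
  resnames <- unname(FIXTURE_ONE_TO_THREE[res])
  list(atoms = atoms, resnames = resnames)
}

# Simplified single-stranded DNA on the same helical trace (wider radius).
nucleic_chain_atoms <- function(n) {
  tr <- helix_trace(n, radius = 3.2, rise = 2.6, turn = 36 * pi / 180)
  codes <- rep(c("DA", "DC", "DG", "DT"), length.out = n)
  offs <- list(
    P    = c("P", -0.8,  1.5, -1.2), OP1 = c("O", -1.9,  1.9, -1.4),
    OP2  = c("O", -0.1,  2.6, -1.6),
    `O5'` = c("O", -0.6,  0.7, -0.9), `C5'` = c("C", -0.2,  0.4, -0.3),
    `C4'` = c("C",  0.0,  0.0,  0.4), `O4'` = c("O",  0.9, -0.6,  0.6),
    `C3'` = c("C", -1.0, -0.7,  0.9), `O3'` = c("O", -1.4, -1.5,  1.4),
    `C2'` = c("C",  0.1, -1.5,  1.2), `C1'` = c("C",  1.1, -1.6,  0.8)
  )
  atoms <- do.call(rbind, lapply(names(offs), function(nm) {
    o <- offs[[nm]]
    off <- as.numeric(o[2:4])
    data.frame(res_i = seq_len(n), name = nm, element = o[1],
               x = tr$ca[, 1] + off[1] * tr$e1[, 1] + off[2] * tr$e2[, 1] + off[3] * tr$e3[, 1],
               y = tr$ca[, 2] + off[1] * tr$e1[, 2] + off[2] * tr$e2[, 2] + off[3] * tr$e3[, 2],
               z = tr$ca[, 3] + off[1] * tr$e1[, 3] + off[2] * tr$e2[, 3] + off[3] * tr$e3[, 3],
               stringsAsFactors = FALSE)
  }))
  atoms <- atoms[order(atoms$res_i, match(atoms$name, names(offs))), ]
  list(atoms = atoms, resnames = codes)
}

#' Toy ligand geometries
#'
#' Small hand-placed heavy-atom molecules at standard bond lengths, used to
#' exercise graph building and symmetry-aware RMSD. `"co2"` is linear
#' O=C=O (one symmetry swap); `"urea"` is a branched C(N)(N)=O;
#' `"square"` is a fictitious symmetric C4 ring with 8 automorphisms.
#'
#' @param name One of `"co2"`, `"urea"`, `"square"`.
#' @param code Component code to give the ligand (default `"LIG"`).
#' @return `data.frame(name, element, x, y, z)` with attribute `code`.
#' @export
toy_ligand <- function(name = c("co2", "urea", "square"), code = "LIG") {
  name <- match.arg(name)
  df <- switch(name,
    co2 = data.frame(
      name = c("O1", "C1", "O2"), element = c("O", "C", "O"),
      x = c(-1.16, 0, 1.16), y = 0, z = 0, stringsAsFactors = FALSE),
    urea = data.frame(
      name = c("C1", "O1", "N1", "N2"), element = c("C", "O", "N", "N"),
      x = c(0, 0, -1.15, 1.15), y = c(0, 1.23, -0.70, -0.70), z = 0,
      stringsAsFactors = FALSE),
    square = data.frame(
      name = paste0("C", 1:4), element = "C",
      x = c(1.1, 0, -1.1, 0), y = c(0, 1.1, 0, -1.1), z = 0,
      stringsAsFactors = FALSE)
  )
  attr(df, "code") <- code
  df
}

# --- assembly ----------------------------------------------------------------

# Minimum heavy-atom distance between two coordinate matrices.
min_cross_dist <- function(a, b) sqrt(min(cross_dist2(a, b)))

# Place n chains evenly on a ring about z, choosing the ring radius by
# bisection so that the minimum distance between adjacent chains is
# `target` Angstrom (contact without clashing).
ring_placement <- function(unit_coords_list, target = 3.5) {
  n <- length(unit_coords_list)
  if (n == 1L)
    return(list(placements = list(list(rot = diag(3), off = c(0, 0, 0)))))
  place <- function(radius) {
    lapply(seq_len(n) - 1L, function(k) {
      ang <- 2 * pi * k / n
      rot <- rotation_about_axis(c(0, 0, 1), ang)
      list(rot = rot, off = c(radius * cos(ang), radius * sin(ang), 0))
    })
  }
  adj_min <- function(radius) {
    pl <- place(radius)
    co <- lapply(seq_len(n), function(k) {
      sweep(unit_coords_list[[k]] %*% t(pl[[k]]$rot), 2, pl[[k]]$off, "+")
    })
    mins <- vapply(seq_len(n), function(k) {
      min_cross_dist(co[[k]], co[[k %% n + 1L]])
    }, numeric(1))
    min(mins)
  }
  lo <- 1; hi <- 80
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (adj_min(mid) < target) lo <- mid else hi <- mid
  }
  pl <- place(hi)
  list(placements = pl)
}

#' Build a synthetic model/reference pair
#'
#' Constructs a reference complex from idealized geometry according to a
#' [fixture_spec()], then derives a model by applying the requested rigid
#' transforms, coordinate noise and chain relabeling. Chains are arranged on
#' a ring so that adjacent chains are in contact (minimum heavy-atom
#' distance about 3.5 Angstrom: inside both contact cutoffs, well
#' outside the 2 Angstrom clash cutoff). The true model-to-reference chain
#' mapping is returned for recovery tests.
#'
#' @param spec A [fixture_spec()] (or arguments forwarded to it).
#' @param ... Forwarded to [fixture_spec()] when `spec` is a string.
#' @return List with `model` and `reference` structures, `mapping` (named
#'   character vector, model chain id -> reference chain id) and `spec`.
#' @export
#' @examples
#' fx <- make_complex(fixture_spec("A2", chain_length = 12))
#' names(fx$reference$chains)
make_complex <- function(spec = fixture_spec(), ...) {
  if (is.character(spec)) spec <- fixture_spec(spec, ...)
  stopifnot(inherits(spec, "cqa_fixture_spec"))
  set.seed(spec$seed)

  # one chain per copy, in stoichiometry order
  letters_out <- rep(names(spec$counts), spec$counts)
  units <- lapply(letters_out, function(lt) {
    type <- if (!is.null(spec$molecule_types) && lt %in% names(spec$molecule_types))
      spec$molecule_types[[lt]] else "protein"
    if (type == "nucleic") {
      nucleic_chain_atoms(spec$chain_length)
    } else {
      base <- FIXTURE_SEQS[[lt]]
      if (is.na(base)) stop("no fixture sequence for subunit letter ", lt)
      seq1 <- paste(rep(strsplit(base, "")[[1]],
                        length.out = spec$chain_length), collapse = "")
      protein_chain_atoms(seq1)
    }
  })

  coords_list <- lapply(units, function(u) as.matrix(u$atoms[, c("x", "y", "z")]))
  ring <- ring_placement(coords_list)
  ids <- LETTERS[seq_along(units)]

  chains <- lapply(seq_along(units), function(k) {
    u <- units[[k]]
    pl <- ring$placements[[k]]
    co <- sweep(coords_list[[k]] %*% t(pl$rot), 2, pl$off, "+")
    atoms <- data.frame(res_idx = u$atoms$res_i, name = u$atoms$name,
                        element = u$atoms$element,
                        x = co[, 1], y = co[, 2], z = co[, 3],
                        stringsAsFactors = FALSE)
    nres <- length(u$resnames)
    residues <- data.frame(name = u$resnames, number = seq_len(nres),
                           icode = "", seq_id = as.character(seq_len(nres)),
                           stringsAsFactors = FALSE)
    residues$one_letter <- one_letter_code(residues$name,
                                           residue_kind(residues$name))
    cls <- if (all(residue_kind(residues$name) == "nuc")) "NUCLEIC"
           else if (nres <= 20L) "PEPTIDE" else "PROTEIN"
    new_chain(ids[k], residues, atoms, cls)
  })

  # optional ligand copies, docked against successive chains
  if (!is.null(spec$ligand)) {
    lig_df <- if (is.character(spec$ligand)) toy_ligand(spec$ligand) else spec$ligand
    code <- attr(lig_df, "code")
    if (is.null(code)) code <- "LIG"
    for (li in seq_len(spec$n_ligands)) {
      host <- chains[[(li - 1L) %% length(chains) + 1L]]
      chains[[length(chains) + 1L]] <-
        place_ligand(lig_df, code, host, id = LETTERS[length(chains) + 1L],
                     slot = li)
    }
  }

  reference <- new_structure(chains, source_path = "<fixture>", format = "PDB")

  # model: perturb copies of the reference chains
  model_chains <- lapply(reference$chains, function(ch) {
    co <- chain_coords(ch)
    tr <- spec$transforms[[ch$chain_id]]
    if (!is.null(tr)) {
      co <- sweep(co %*% tr$rotation, 2, tr$translation, "+")
    }
    sigma <- if (length(spec$noise) > 1L) {
      if (ch$chain_id %in% names(spec$noise)) spec$noise[[ch$chain_id]] else 0
    } else spec$noise
    if (sigma > 0) co <- co + matrix(stats::rnorm(length(co), sd = sigma),
                                     nrow(co), 3)
    ch$atoms$x <- co[, 1]; ch$atoms$y <- co[, 2]; ch$atoms$z <- co[, 3]
    ch
  })

  mapping <- stats::setNames(names(reference$chains), names(reference$chains))
  if (!is.null(spec$relabel)) {
    old <- names(reference$chains)
    if (!all(names(spec$relabel) %in% old))
      stop("relabel refers to unknown chains")
    new_ids <- old
    new_ids[match(names(spec$relabel), old)] <- unname(spec$relabel)
    if (anyDuplicated(new_ids)) stop("relabel is not a bijection")
    model_chains <- lapply(seq_along(model_chains), function(k) {
      ch <- model_chains[[k]]; ch$chain_id <- new_ids[k]; ch
    })
    mapping <- stats::setNames(old, new_ids)  # model id -> reference id
    # present model chains in id order, as a file writer would
    model_chains <- model_chains[order(vapply(model_chains, function(ch)
      ch$chain_id, character(1)))]
  }
  model <- new_structure(model_chains, source_path = "<fixture>", format = "PDB")

  list(model = model, reference = reference,
       mapping = mapping[order(names(mapping))], spec = spec)
}

# Drop a ligand near the host chain: centered `target` Angstrom out from the
# host's outermost midpoint atom, then pushed along that direction until the
# minimum distance to the host is ~3.5 Angstrom.
place_ligand <- function(lig_df, code, host, id, slot = 1L, target = 3.5) {
  hco <- chain_coords(host)
  center <- colMeans(hco)
  mid <- hco[which.max(hco[, 3] * 0 + rowSums(sweep(hco, 2, center)^2)), ]
  dir <- mid - center
  # vary placement direction slightly per ligand copy so copies don't overlap
  dir <- dir + c(0, 0, 2.5 * (slot - 1L))
  dir <- dir / sqrt(sum(dir^2))
  lco0 <- as.matrix(lig_df[, c("x", "y", "z")])
  lco0 <- sweep(lco0, 2, colMeans(lco0))
  place_at <- function(d) sweep(lco0, 2, mid + d * dir, "+")
  lo <- 0; hi <- 30
  for (it in 1:50) {
    mid_d <- (lo + hi) / 2
    if (min_cross_dist(place_at(mid_d), hco) < target) lo <- mid_d else hi <- mid_d
  }
  lco <- place_at(hi)
  atoms <- data.frame(res_idx = 1L, name = lig_df$name,
                      element = lig_df$element,
                      x = lco[, 1], y = lco[, 2], z = lco[, 3],
                      stringsAsFactors = FALSE)
  residues <- data.frame(name = code, number = 1L, icode = "",
                         seq_id = "1", one_letter = "-",
                         stringsAsFactors = FALSE)
  new_chain(id, residues, atoms, "SMALL_MOLECULE")
}

# --- writers -----------------------------------------------------------------

#' Write a structure to PDB or mmCIF
#'
#' Minimal writers producing files that [parse_structure()] reads back with
#' a lossless chain/residue/coordinate round trip (to the 3-decimal
#' precision of the text formats).
#'
#' @param structure A `cqa_structure`.
#' @param path Output path.
#' @param format `"pdb"` or `"mmcif"`.
#' @param gzip Compress the output with gzip.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(structure, path, format = c("pdb", "mmcif"),
                          gzip = FALSE) {
  format <- match.arg(format)
  lines <- if (format == "pdb") render_pdb(structure) else render_cif(structure)
  con <- if (gzip) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

render_pdb <- function(structure) {
  out <- character(0)
  serial <- 0L
  for (ch in structure$chains) {
    hetatm <- ch$molecule_class == "SMALL_MOLECULE"
    for (i in seq_len(nrow(ch$atoms))) {
      a <- ch$atoms[i, ]
      r <- ch$residues[a$res_idx, ]
      serial <- serial + 1L
      nm <- a$name
      # standard name padding: element right-justified in cols 13-14
      padded <- if (nchar(nm) >= 4L) substr(nm, 1, 4)
                else if (nchar(a$element) == 2L) formatC(nm, width = -4)
                else paste0(" ", formatC(nm, width = -3))
      out[length(out) + 1L] <- sprintf(
        "%-6s%5d %s%s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        if (hetatm) "HETATM" else "ATOM", serial %% 100000L, padded, " ",
        r$name, substr(ch$chain_id, 1, 1), r$number %% 10000L, r$icode,
        a$x, a$y, a$z, 1, 0, a$element)
    }
    out[length(out) + 1L] <- "TER"
  }
  c(out, "END")
}

render_cif <- function(structure) {
  head <- c("data_fixture", "#", "loop_",
            paste0("_atom_site.",
                   c("group_PDB", "id", "type_symbol", "label_atom_id",
                     "label_alt_id", "label_comp_id", "label_asym_id",
                     "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x",
                     "Cartn_y", "Cartn_z", "occupancy",
                     "pdbx_PDB_model_num", "auth_seq_id", "auth_comp_id",
                     "auth_asym_id", "auth_atom_id")))
  rows <- character(0)
  serial <- 0L
  qa <- function(s) ifelse(grepl("'", s), paste0('"', s, '"'),
                           ifelse(grepl("[\"' ]", s) | s == "",
                                  paste0("'", s, "'"), s))
  for (ch in structure$chains) {
    hetatm <- ch$molecule_class == "SMALL_MOLECULE"
    for (i in seq_len(nrow(ch$atoms))) {
      a <- ch$atoms[i, ]
      r <- ch$residues[a$res_idx, ]
      serial <- serial + 1L
      rows[length(rows) + 1L] <- paste(
        if (hetatm) "HETATM" else "ATOM", serial, a$element, qa(a$name),
        ".", r$name, qa(ch$chain_id), r$number,
        if (r$icode == "") "?" else r$icode,
        sprintf("%.3f", a$x), sprintf("%.3f", a$y), sprintf("%.3f", a$z),
        "1.00", "1", r$number, r$name, qa(ch$chain_id), qa(a$name))
    }
  }
  c(head, rows, "#")
}
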