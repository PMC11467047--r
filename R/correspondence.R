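# Residue correspondence between model and reference chains, and grouping
# of chains into equivalence classes for the chain-mapping search.
#
# Model and reference are near-identical sequences, so an identity-scored
# global alignment with free end gaps is sufficient: match 1, mismatch 0,
# affine gaps (open 10, extend 0.5). Mismatched residues at aligned columns
# stay paired (models may carry point mutations); the mismatch count is
# reported alongside the pairing.

ALIGN_GAP_OPEN <- 10
ALIGN_GAP_EXTEND <- 0.5

# identity substitution matrix over the full uppercase alphabet; built once
align_submat <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      m <- matrix(0, 27, 27, dimnames = list(c(LETTERS, "*"), c(LETTERS, "*")))
      diag(m) <- 1
      mat <<- m
    }
    mat
  }
})

#' Globally align two sequences
#'
#' End-gap-free global alignment with identity scoring (match 1, mismatch 0,
#' gap open 10, gap extend 0.5). Deterministic for fixed inputs.
#'
#' @param seq_a,seq_b Plain one-letter sequence strings (same polymer type).
#' @return A list with `aligned_a` and `aligned_b` (gapped strings of equal
#'   length covering the full input sequences, `-` for gaps), `identity`
#'   (matches / aligned columns where both are residues) and `score`.
#' @export
#' @examples
#' align_sequences("AGWK", "AGK")$identity
align_sequences <- function(seq_a, seq_b) {
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(seq_a), Biostrings::BString(seq_b),
    substitutionMatrix = align_submat(),
    gapOpening = ALIGN_GAP_OPEN, gapExtension = ALIGN_GAP_EXTEND,
    type = "overlap")
  ap <- as.character(Biostrings::alignedPattern(aln))
  as_ <- as.character(Biostrings::alignedSubject(aln))
  # overlap alignments clip unaligned overhangs; restore them as end gaps so
  # the returned strings always cover the complete input sequences
  sp <- Biostrings::start(Biostrings::pattern(aln))
  ep <- Biostrings::end(Biostrings::pattern(aln))
  ss <- Biostrings::start(Biostrings::subject(aln))
  es <- Biostrings::end(Biostrings::subject(aln))
  pre_a <- substr(seq_a, 1, sp - 1); post_a <- substr(seq_a, ep + 1, nchar(seq_a))
  pre_b <- substr(seq_b, 1, ss - 1); post_b <- substr(seq_b, es + 1, nchar(seq_b))
  gaps <- function(n) strrep("-", n)
  aligned_a <- paste0(pre_a, gaps(nchar(pre_b)), ap,
                      post_a, gaps(nchar(post_b)))
  aligned_b <- paste0(gaps(nchar(pre_a)), pre_b, as_,
                      gaps(nchar(post_a)), post_b)
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  both <- ca != "-" & cb != "-"
  identity <- if (any(both)) mean(ca[both] == cb[both]) else 0
  list(aligned_a = aligned_a, aligned_b = aligned_b,
       identity = identity, score = Biostrings::score(aln))
}

#' Map residues between a model chain and a reference chain
#'
#' In `ALIGNMENT` mode (the default behavior of the tool) residues at
#' aligned non-gap columns are paired, including mismatches; in `NUMBERING`
#' mode residues with equal author numbering (number + insertion code) are
#' paired. Unpaired residues take no part in downstream scoring.
#'
#' @param model_chain,ref_chain Polymer chains of the same molecule class
#'   family (protein/peptide with protein/peptide, nucleic with nucleic).
#' @param mode `"ALIGNMENT"` or `"NUMBERING"`.
#' @return A `cqa_correspondence`: list with `pairs`
#'   (`data.frame(model_idx, ref_idx)` of residue indices), `coverage`
#'   (fraction of reference residues paired), `mismatches` and `mode`.
#' @export
map_residues <- function(model_chain, ref_chain,
                         mode = c("ALIGNMENT", "NUMBERING")) {
  mode <- match.arg(mode)
  if (!is_polymer(model_chain) || !is_polymer(ref_chain))
    stop("map_residues(): both chains must be polymers")
  pc <- function(cl) if (cl == "NUCLEIC") "nuc" else "aa"
  if (pc(model_chain$molecule_class) != pc(ref_chain$molecule_class))
    stop("map_residues(): chains ", model_chain$chain_id, " and ",
         ref_chain$chain_id, " are different polymer types")
  if (mode == "ALIGNMENT") {
    aln <- align_sequences(extract_sequence(model_chain),
                           extract_sequence(ref_chain))
    ca <- strsplit(aln$aligned_a, "")[[1]]
    cb <- strsplit(aln$aligned_b, "")[[1]]
    ia <- cumsum(ca != "-")
    ib <- cumsum(cb != "-")
    both <- ca != "-" & cb != "-"
    pairs <- data.frame(model_idx = ia[both], ref_idx = ib[both])
    mism <- sum(ca[both] != cb[both])
  } else {
    mk <- model_chain$residues$seq_id
    rk <- ref_chain$residues$seq_id
    hit <- match(rk, mk)
    ok <- !is.na(hit)
    pairs <- data.frame(model_idx = hit[ok], ref_idx = which(ok))
    mism <- sum(model_chain$residues$one_letter[pairs$model_idx] !=
                ref_chain$residues$one_letter[pairs$ref_idx])
  }
  if (nrow(pairs) == 0L)
    stop("no residue correspondence between model chain ",
         model_chain$chain_id, " and reference chain ", ref_chain$chain_id,
         " (mode ", mode, ")")
  structure(list(pairs = pairs,
                 coverage = nrow(pairs) / nrow(ref_chain$residues),
                 mismatches = mism, mode = mode),
            class = "cqa_correspondence")
}

#' Group chains into equivalence classes
#'
#' Polymer chains are copies of the same subunit when their pairwise
#' sequence identity over the aligned region reaches `identity_threshold`;
#' small molecules are equivalent when they share a component code. The
#' groups partition the chains and bound the chain-mapping search space.
#'
#' @param structure A parsed structure.
#' @param identity_threshold Fraction in (0, 1]; default 0.9.
#' @return List of groups, each `list(member_chain_ids, representative,
#'   molecule_class)`; `molecule_class` is `"SMALL_MOLECULE"` or the class
#'   of the first member.
#' @export
group_equivalent_chains <- function(structure, identity_threshold = 0.9) {
  groups <- list()
  for (ch in structure$chains) {
    placed <- FALSE
    if (ch$molecule_class == "SMALL_MOLECULE") {
      code <- ch$residues$name[1]
      for (k in seq_along(groups)) {
        g <- groups[[k]]
        if (g$molecule_class == "SMALL_MOLECULE" && g$representative == code) {
          groups[[k]]$member_chain_ids <- c(g$member_chain_ids, ch$chain_id)
          placed <- TRUE; break
        }
      }
      if (!placed)
        groups[[length(groups) + 1L]] <- list(
          member_chain_ids = ch$chain_id, representative = code,
          molecule_class = "SMALL_MOLECULE")
    } else {
      sq <- extract_sequence(ch)
      fam <- if (ch$molecule_class == "NUCLEIC") "nuc" else "aa"
      for (k in seq_along(groups)) {
        g <- groups[[k]]
        if (g$molecule_class == "SMALL_MOLECULE") next
        gfam <- if (g$molecule_class == "NUCLEIC") "nuc" else "aa"
        if (gfam != fam) next
        if (align_sequences(sq, g$representative)$identity >= identity_threshold) {
          groups[[k]]$member_chain_ids <- c(g$member_chain_ids, ch$chain_id)
          placed <- TRUE; break
        }
      }
      if (!placed)
        groups[[length(groups) + 1L]] <- list(
          member_chain_ids = ch$chain_id, representative = sq,
          molecule_class = ch$molecule_class)
    }
  }
  groups
}
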