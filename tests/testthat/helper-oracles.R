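# Independent oracles used to cross-check the implementation, plus small
# builders for hand-made chains. The oracles deliberately share no code
# with the package internals: superposition uses Horn's quaternion method
# instead of SVD, distances are brute-force double loops, and alignment
# scores come from exhaustive path enumeration.

# RMSD of the optimal superposition via Horn's closed-form quaternion
# solution: rmsd^2 = (sum |a|^2 + sum |b|^2 - 2*lambda_max) / n on centered
# coordinates. No rotation matrix is ever built.
oracle_superpose_rmsd <- function(ref, mov) {
  a <- scale(as.matrix(ref), scale = FALSE)
  b <- scale(as.matrix(mov), scale = FALSE)
  s <- crossprod(b, a)  # sum of outer(b_i, a_i)
  sxx <- s[1, 1]; sxy <- s[1, 2]; sxz <- s[1, 3]
  syx <- s[2, 1]; syy <- s[2, 2]; syz <- s[2, 3]
  szx <- s[3, 1]; szy <- s[3, 2]; szz <- s[3, 3]
  n4 <- matrix(c(
    sxx + syy + szz, syz - szy,        szx - sxz,        sxy - syx,
    syz - szy,       sxx - syy - szz,  sxy + syx,        szx + sxz,
    szx - sxz,       sxy + syx,       -sxx + syy - szz,  syz + szy,
    sxy - syx,       szx + sxz,        syz + szy,       -sxx - syy + szz
  ), 4, 4, byrow = TRUE)
  lambda <- max(eigen(n4, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a^2) + sum(b^2) - 2 * lambda) / nrow(a)
  sqrt(max(msd, 0))
}

# Brute-force residue contacts: all atom pairs, double loop.
oracle_contacts <- function(chain_a, chain_b, cutoff) {
  out <- NULL
  for (i in seq_len(nrow(chain_a$residues))) {
    ai <- chain_a$atoms[chain_a$atoms$res_idx == i, c("x", "y", "z")]
    for (j in seq_len(nrow(chain_b$residues))) {
      bj <- chain_b$atoms[chain_b$atoms$res_idx == j, c("x", "y", "z")]
      mind <- Inf
      for (p in seq_len(nrow(ai)))
        for (q in seq_len(nrow(bj)))
          mind <- min(mind, sqrt(sum((as.numeric(ai[p, ]) - as.numeric(bj[q, ]))^2)))
      if (mind <= cutoff) out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) data.frame(res_a = integer(0), res_b = integer(0))
  else data.frame(res_a = out[, 1], res_b = out[, 2])
}

oracle_clashes <- function(chain_a, chain_b, cutoff) {
  ca <- as.matrix(chain_a$atoms[, c("x", "y", "z")])
  cb <- as.matrix(chain_b$atoms[, c("x", "y", "z")])
  n <- 0L
  for (p in seq_len(nrow(ca)))
    for (q in seq_len(nrow(cb)))
      if (sqrt(sum((ca[p, ] - cb[q, ])^2)) < cutoff) n <- n + 1L
  n
}

# Best end-gap-free global alignment score by exhaustive enumeration of all
# monotone alignment paths (feasible for sequences of length <= 5).
# Scoring: match 1, mismatch 0; an internal gap run of length L costs
# open + ext * L; runs at either end of the alignment are free.
oracle_align_best <- function(a, b, open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av); nb <- length(bv)
  best <- -Inf
  recurse <- function(i, j, moves) {
    if (i == na && j == nb) {
      best <<- max(best, score_path(moves))
      return(invisible())
    }
    if (i < na && j < nb) recurse(i + 1L, j + 1L, c(moves, "D"))
    if (i < na) recurse(i + 1L, j, c(moves, "A"))   # consume a: gap in b
    if (j < nb) recurse(i, j + 1L, c(moves, "B"))   # consume b: gap in a
  }
  score_path <- function(moves) {
    i <- 0L; j <- 0L; sc <- 0
    runs <- rle(moves)
    pos <- cumsum(c(1L, runs$lengths))
    for (k in seq_along(runs$values)) {
      v <- runs$values[k]; len <- runs$lengths[k]
      if (v == "D") {
        for (t in seq_len(len)) {
          i <- i + 1L; j <- j + 1L
          if (av[i] == bv[j]) sc <- sc + 1
        }
      } else {
        if (v == "A") i <- i + len else j <- j + len
        internal <- k != 1L && k != length(runs$values)
        if (internal) sc <- sc - (open + ext * len)
      }
    }
    sc
  }
  recurse(0L, 0L, character(0))
  best
}

# All permutations of 1..n as a list (oracle-side, independent of the
# package's enumeration code).
all_perms_oracle <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms_oracle(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# --- hand-made chains --------------------------------------------------------

# Build a chain where residue i has the given atoms. `residues` is a list of
# lists: list(name = "ALA", atoms = data.frame(name, element, x, y, z)).
mk_chain <- function(id, residues, class = NULL) {
  atoms <- do.call(rbind, lapply(seq_along(residues), function(i) {
    df <- residues[[i]]$atoms
    df$res_idx <- i
    df
  }))
  resdf <- data.frame(
    name = vapply(residues, function(r) r$name, character(1)),
    number = seq_along(residues), icode = "",
    seq_id = as.character(seq_along(residues)),
    stringsAsFactors = FALSE)
  resdf$one_letter <- complexqa:::one_letter_code(
    resdf$name, complexqa:::residue_kind(resdf$name))
  if (is.null(class)) class <- complexqa:::classify_residue_kinds(
    complexqa:::residue_kind(resdf$name), nrow(resdf), id, resdf$name,
    scoring_constants())
  complexqa:::new_chain(id, resdf,
                        atoms[, c("res_idx", "name", "element", "x", "y", "z")],
                        class)
}

# Shorthand: one CA atom per residue at the given coordinates.
mk_ca_chain <- function(id, xyz, resname = "ALA", class = NULL) {
  residues <- lapply(seq_len(nrow(xyz)), function(i) {
    list(name = resname,
         atoms = data.frame(name = "CA", element = "C",
                            x = xyz[i, 1], y = xyz[i, 2], z = xyz[i, 3],
                            stringsAsFactors = FALSE))
  })
  mk_chain(id, residues, class = class)
}

# Identity residue correspondence for n residues.
identity_corr <- function(n) {
  structure(list(pairs = data.frame(model_idx = seq_len(n),
                                    ref_idx = seq_len(n)),
                 coverage = 1, mismatches = 0L, mode = "ALIGNMENT"),
            class = "cqa_correspondence")
}

# Random rigid transform (rotation + translation) for invariance tests.
random_rigid <- function() {
  ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
  list(rotation = complexqa:::rotation_about_axis(ax, stats::runif(1, 0, 2 * pi)),
       translation = stats::rnorm(3, sd = 10))
}

# Apply one global rigid transform to every chain of a structure.
transform_structure <- function(structure, tr) {
  chains <- lapply(structure$chains, function(ch) {
    co <- sweep(as.matrix(ch$atoms[, c("x", "y", "z")]) %*% tr$rotation,
                2, tr$translation, "+")
    ch$atoms$x <- co[, 1]; ch$atoms$y <- co[, 2]; ch$atoms$z <- co[, 3]
    ch
  })
  complexqa:::new_structure(chains, structure$source_path, structure$format)
}
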