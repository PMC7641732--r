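# Synthetic-structure generators with known ground truth: ideal A-form RNA
# duplexes and hairpins, toy protein-RNA complexes with planted hydrogen
# bonds / stacking / flipped-out bases, toy crystals, and planted-cluster
# conformational ensembles. All generators are pure functions of
# (spec, seed); every fixture is re-measured at generation time so its
# declared ground truth is consistent with the emitted coordinates.

# Standard base reference-frame coordinates (x, y; base plane z = 0),
# C1' included. In this frame the paired base of the complementary strand
# is obtained by a 180-degree rotation about x (y -> -y, z -> -z), which
# realises Watson-Crick hydrogen-bond distances of 2.85-3.0 A by
# construction.
BASE_TEMPLATE <- list(
  A = rbind(
    `C1'` = c(-2.479, 5.346), N9 = c(-1.291, 4.498), C8 = c(0.024, 4.897),
    N7 = c(0.877, 3.902), C5 = c(0.071, 2.771), C6 = c(0.369, 1.398),
    N6 = c(1.611, 0.909), N1 = c(-0.668, 0.532), C2 = c(-1.912, 1.023),
    N3 = c(-2.320, 2.290), C4 = c(-1.267, 3.124)),
  G = rbind(
    `C1'` = c(-2.477, 5.399), N9 = c(-1.289, 4.551), C8 = c(0.023, 4.962),
    N7 = c(0.870, 3.969), C5 = c(0.071, 2.833), C6 = c(0.424, 1.460),
    O6 = c(1.554, 0.955), N1 = c(-0.700, 0.641), C2 = c(-1.999, 1.087),
    N2 = c(-2.949, 0.139), N3 = c(-2.342, 2.364), C4 = c(-1.265, 3.177)),
  C = rbind(
    `C1'` = c(-2.477, 5.402), N1 = c(-1.285, 4.542), C2 = c(-1.472, 3.158),
    O2 = c(-2.628, 2.709), N3 = c(-0.391, 2.344), C4 = c(0.837, 2.868),
    N4 = c(1.875, 2.027), C5 = c(1.056, 4.275), C6 = c(-0.023, 5.068)),
  U = rbind(
    `C1'` = c(-2.481, 5.354), N1 = c(-1.284, 4.500), C2 = c(-1.462, 3.131),
    O2 = c(-2.563, 2.608), N3 = c(-0.302, 2.397), C4 = c(0.989, 2.884),
    O4 = c(1.935, 2.094), C5 = c(1.089, 4.311), C6 = c(-0.024, 5.053))
)

# schematic ribose/phosphate offsets from C1' (template frame); these give
# the backbone its outside-the-helix placement without a full sugar build
BACKBONE_OFFSETS <- rbind(
  `C2'` = c(-0.9, 0.9, -0.5),
  `O2'` = c(-0.6, 2.2, -0.3),
  `O4'` = c(-1.2, -0.3, 0.9),
  `C4'` = c(-2.0, 0.7, 0.9),
  `C3'` = c(-1.9, 1.4, -0.4),
  `O3'` = c(-2.5, 1.9, -0.9),
  `C5'` = c(-3.0, 0.2, 1.6),
  `O5'` = c(-3.8, -0.6, 1.2),
  P = c(-4.3, -1.6, 1.7),
  OP1 = c(-5.2, -2.4, 2.3),
  OP2 = c(-3.4, -2.6, 2.3)
)

AFORM_RISE <- 2.81    # Angstrom per base-pair step
AFORM_TWIST <- 32.7   # degrees per base-pair step

RNA_COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G")

# run code under a fixed seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}

# full-atom coordinates for one nucleotide in the template frame
nucleotide_template <- function(base, fluoro = FALSE) {
  b <- BASE_TEMPLATE[[base]]
  xyz <- cbind(b, 0)
  rownames(xyz) <- rownames(b)
  bb <- sweep(BACKBONE_OFFSETS, 2, xyz["C1'", ], `+`)
  if (fluoro) rownames(bb)[rownames(bb) == "O2'"] <- "F2'"
  rbind(xyz, bb)
}

# place a nucleotide: optional strand-2 flip (180 deg about x), then helix
# step rotation/translation
place_nucleotide <- function(base, level, strand2 = FALSE, fluoro = FALSE,
                             rise = AFORM_RISE, twist = AFORM_TWIST) {
  xyz <- nucleotide_template(base, fluoro)
  if (strand2) xyz <- xyz %*% diag(c(1, -1, -1))
  xyz <- xyz %*% t(rot_z((level - 1) * twist))
  xyz[, 3] <- xyz[, 3] + (level - 1) * rise
  xyz
}

atom_rows <- function(xyz, resid, chain, resno, type = "ATOM") {
  nm <- rownames(xyz)
  data.frame(
    type = type, eleno = 0L, elety = nm, alt = "", resid = resid,
    chain = chain, resno = resno, insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
    elesy = infer_element(nm), stringsAsFactors = FALSE, row.names = NULL
  )
}

finish_structure <- function(id, rows, cell = NULL, space_group = NULL) {
  rows$eleno <- seq_len(nrow(rows))
  structure3d(id, rows, cell = cell, space_group = space_group)
}

valid_rna_sequence <- function(sequence) {
  seq_chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(seq_chars) < 1L || !all(seq_chars %in% names(RNA_COMPLEMENT))) {
    stop("invalid RNA sequence: ", sequence)
  }
  seq_chars
}

# internal consistency pass on a (possibly noisy) duplex/hairpin: every
# planted pair must retain a Watson-Crick polar contact comfortably inside
# the detection window with near-coplanar geometry, and no unplanted
# residue pair may present a pair-like contact (slightly wider screen than
# the detector, so the detector cannot pick up extras)
pairs_consistent <- function(s, truth_pairs) {
  for (r in seq_len(nrow(truth_pairs))) {
    if (!measure_pair(s, truth_pairs$res_i[r], truth_pairs$res_j[r])) {
      return(FALSE)
    }
  }
  a <- s$atom
  res <- residue_table(a)
  res <- res[!is.na(res$parent_base), , drop = FALSE]
  planted <- paste(truth_pairs$res_i, truth_pairs$res_j)
  n <- nrow(res)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      key <- paste(res$res_key[i], res$res_key[j])
      if (key %in% planted) next
      if (measure_pair(s, res$res_key[i], res$res_key[j],
                       dmin = 2.3, dmax = 3.6, max_plane_angle = 45,
                       max_stagger = 2.2, min_in_plane = 45)) {
        return(FALSE)
      }
    }
  }
  TRUE
}

measure_pair <- function(s, key_i, key_j, dmin = 2.5, dmax = 3.4,
                         max_plane_angle = 30, max_stagger = 1.5,
                         min_in_plane = 60) {
  a <- s$atom
  rk <- res_key(a)
  ai <- a[rk == key_i, , drop = FALSE]
  aj <- a[rk == key_j, , drop = FALSE]
  pi_ <- ai[ai$elety %in% BASE_POLAR_ATOMS[[ai$parent_base[1]]], ,
            drop = FALSE]
  pj <- aj[aj$elety %in% BASE_POLAR_ATOMS[[aj$parent_base[1]]], ,
           drop = FALSE]
  if (nrow(pi_) == 0L || nrow(pj) == 0L) return(FALSE)
  pl_i <- tryCatch(base_plane(ai), error = function(e) NULL)
  pl_j <- tryCatch(base_plane(aj), error = function(e) NULL)
  if (is.null(pl_i) || is.null(pl_j)) return(FALSE)
  if (plane_angle_deg(pl_i$normal, pl_j$normal) > max_plane_angle) {
    return(FALSE)
  }
  if (pair_stagger(pl_i, pl_j) > max_stagger) return(FALSE)
  d <- cross_dist(as.matrix(pi_[, c("x", "y", "z")]),
                  as.matrix(pj[, c("x", "y", "z")]))
  hits <- which(d >= dmin & d <= dmax, arr.ind = TRUE)
  for (h in seq_len(nrow(hits))) {
    v <- as.numeric(pj[hits[h, 2], c("x", "y", "z")]) -
      as.numeric(pi_[hits[h, 1], c("x", "y", "z")])
    to_norm <- min(plane_angle_deg(v, pl_i$normal),
                   plane_angle_deg(v, pl_j$normal))
    if (to_norm >= min_in_plane) return(TRUE)
  }
  FALSE
}

#' Build an ideal A-form RNA duplex with known base pairing
#'
#' Two complementary strands (chains A and B) on ideal A-form helical
#' parameters (rise 2.81 A, twist 32.7 deg per step) built from standard
#' base reference-frame geometry, so every Watson-Crick pair carries its
#' textbook hydrogen bonds. Optional isotropic Gaussian coordinate noise
#' is re-drawn (bounded retries) until the planted pairs remain measurable
#' and no spurious pair appears, keeping the declared ground truth exact.
#'
#' The duplex is emitted as a single chain (resno 1..2n: strand 1 followed
#' by strand 2, 5' to 3'), pairing residue i with residue 2n+1-i, so the
#' single-chain annotation pipeline applies directly.
#'
#' @param sequence strand-1 sequence, 5' to 3' (A/C/G/U).
#' @param noise_sigma isotropic Gaussian coordinate noise, A (default 0).
#' @param seed RNG seed (used only when noise_sigma > 0).
#' @param fluoro_pyrimidines give pyrimidines a ribose 2'-F instead of the
#'   2'-OH (default FALSE).
#' @param chain chain id (default "A").
#' @param max_retries noise redraws allowed before failing (default 50).
#' @return list with \code{structure} and \code{truth}: \code{pairs}
#'   (res_i, res_j, pos_i, pos_j) covering all Watson-Crick pairs,
#'   \code{sequence}.
#' @export
build_aform_duplex <- function(sequence, noise_sigma = 0, seed = 1,
                               fluoro_pyrimidines = FALSE, chain = "A",
                               max_retries = 50) {
  seq1 <- valid_rna_sequence(sequence)
  n <- length(seq1)
  if (n < 2L) stop("duplex needs at least 2 base pairs")
  seq2 <- rev(unname(RNA_COMPLEMENT[seq1]))  # strand 2, 5' to 3'

  build_once <- function(jitter) {
    rows <- list()
    for (i in seq_len(n)) {
      fl <- fluoro_pyrimidines && seq1[i] %in% c("C", "U")
      rows[[length(rows) + 1L]] <- atom_rows(
        place_nucleotide(seq1[i], level = i, fluoro = fl),
        seq1[i], chain, i)
    }
    for (k in seq_len(n)) {
      lev <- n + 1L - k
      fl <- fluoro_pyrimidines && seq2[k] %in% c("C", "U")
      rows[[length(rows) + 1L]] <- atom_rows(
        place_nucleotide(seq2[k], level = lev, strand2 = TRUE,
                         fluoro = fl), seq2[k], chain, n + k)
    }
    rows <- do.call(rbind, rows)
    if (!is.null(jitter)) {
      rows[, c("x", "y", "z")] <- rows[, c("x", "y", "z")] +
        matrix(jitter(3L * nrow(rows)), ncol = 3)
    }
    finish_structure(paste0("duplex_", sequence), rows)
  }

  truth_pairs <- data.frame(
    res_i = paste0(chain, ":", seq_len(n)),
    res_j = paste0(chain, ":", (2L * n):(n + 1L)),
    pos_i = seq_len(n), pos_j = (2L * n):(n + 1L),
    stringsAsFactors = FALSE)

  if (noise_sigma <= 0) {
    s <- build_once(NULL)
    stopifnot(pairs_consistent(s, truth_pairs))
    return(list(structure = s,
                truth = list(pairs = truth_pairs, sequence = sequence)))
  }

  s <- with_seed(seed, {
    out <- NULL
    for (try in seq_len(max_retries)) {
      cand <- build_once(function(m) rnorm(m, 0, noise_sigma))
      if (pairs_consistent(cand, truth_pairs)) { out <- cand; break }
    }
    out
  })
  if (is.null(s)) {
    stop("could not generate a consistent noisy duplex after ",
         max_retries, " retries (sigma = ", noise_sigma, ")")
  }
  list(structure = s, truth = list(pairs = truth_pairs, sequence = sequence))
}

#' Build an RNA hairpin (stem + terminal loop) with known ground truth
#'
#' One chain: an A-form stem of \code{stem_len} Watson-Crick pairs closed
#' by an unpaired loop. Loop bases are placed on a spiral above the stem;
#' positions listed in \code{flipped_out} are extruded far from the
#' helical-axis extension (and laterally offset so they stack on neither
#' neighbour), the rest stay close to the axis.
#'
#' @param stem_seq 5'-side stem sequence (A/C/G/U).
#' @param loop_seq loop sequence (unpaired).
#' @param flipped_out integer positions *within the loop* (1-based) to
#'   extrude.
#' @param chain chain id (default "R").
#' @return list with \code{structure} and \code{truth}: \code{pairs},
#'   \code{loop_res}, \code{flipped_out} (residue keys), \code{sequence}.
#' @export
build_hairpin <- function(stem_seq, loop_seq, flipped_out = integer(),
                          chain = "R") {
  s1 <- valid_rna_sequence(stem_seq)
  lp <- valid_rna_sequence(loop_seq)
  n <- length(s1)
  L <- length(lp)
  if (n < 2L) stop("hairpin stem needs >= 2 pairs")
  if (L < 3L) stop("hairpin loop needs >= 3 nucleotides")
  stopifnot(all(flipped_out >= 1L & flipped_out <= L))
  s2 <- rev(unname(RNA_COMPLEMENT[s1]))
  total <- 2L * n + L

  rows <- list()
  for (i in seq_len(n)) {           # 5' strand of the stem
    rows[[length(rows) + 1L]] <- atom_rows(
      place_nucleotide(s1[i], level = i), s1[i], chain, i)
  }
  z_top <- (n - 1L) * AFORM_RISE
  for (k in seq_len(L)) {           # loop on a spiral above the stem
    base <- lp[k]
    xyz <- nucleotide_template(base)
    ring <- BASE_RING_ATOMS[[base]]
    ctr <- colMeans(xyz[rownames(xyz) %in% ring, , drop = FALSE])
    xyz <- sweep(xyz, 2, ctr)       # ring centroid at origin
    r_k <- if (k %in% flipped_out) 9.0 else 3.2
    th <- (n - 1L) * AFORM_TWIST + 40 * k
    target <- c(r_k * cos(th * pi / 180), r_k * sin(th * pi / 180),
                z_top + 3.2 + 3.0 * k)
    xyz <- xyz %*% t(rot_z(th))
    xyz <- sweep(xyz, 2, target, `+`)
    rows[[length(rows) + 1L]] <- atom_rows(xyz, base, chain, n + k)
  }
  for (k in seq_len(n)) {           # 3' strand of the stem
    lev <- n + 1L - k
    rows[[length(rows) + 1L]] <- atom_rows(
      place_nucleotide(s2[k], level = lev, strand2 = TRUE),
      s2[k], chain, n + L + k)
  }
  s <- finish_structure(paste0("hairpin_", stem_seq, "_", loop_seq),
                        do.call(rbind, rows))

  truth_pairs <- data.frame(
    res_i = paste0(chain, ":", seq_len(n)),
    res_j = paste0(chain, ":", total:(total - n + 1L)),
    pos_i = seq_len(n), pos_j = total:(total - n + 1L),
    stringsAsFactors = FALSE)
  stopifnot(pairs_consistent(s, truth_pairs))
  list(structure = s,
       truth = list(
         pairs = truth_pairs,
         loop_res = paste0(chain, ":", n + seq_len(L)),
         flipped_out = if (length(flipped_out))
           paste0(chain, ":", n + flipped_out) else character(0),
         sequence = paste0(stem_seq, loop_seq,
                           paste(s2, collapse = ""))))
}

#' Rotate one base out of a duplex (planted flipped-out perturbation)
#'
#' Rotates the base (ring + exocyclic) atoms of a nucleotide about the
#' vertical axis through its C1' atom, swinging the base out of the helix
#' into solvent; its former pairing partner stays in place. Intended for
#' structures built by \code{\link{build_aform_duplex}} (helix axis = z).
#'
#' @param s structure3d.
#' @param chain,resno the nucleotide to rotate.
#' @param angle_deg rotation angle (default 120).
#' @return structure3d with the base rotated.
#' @export
rotate_base_out <- function(s, chain, resno, angle_deg = 120) {
  a <- s$atom
  sel <- a$chain == chain & a$resno == resno &
    a$elety %in% c(NUCLEOBASE_ATOMS)
  if (!any(sel)) stop("no base atoms for ", chain, ":", resno)
  c1 <- a[a$chain == chain & a$resno == resno &
            a$elety %in% c("C1'", "C1*"), c("x", "y", "z")]
  if (nrow(c1) == 0L) stop("no C1' atom for ", chain, ":", resno)
  pivot <- as.numeric(c1[1, ])
  R <- rot_z(angle_deg)
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  xyz <- sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot, `+`)
  s$atom[sel, c("x", "y", "z")] <- xyz
  s
}

# --- toy protein-RNA complex ----------------------------------------------

# a short poly-alanine alpha-helix (backbone + CB), chain id `chain`,
# centred at `center`
poly_ala_helix <- function(n_res = 8, chain = "P", center = c(0, -30, 0)) {
  rows <- list()
  for (k in seq_len(n_res)) {
    th <- 100 * (k - 1) * pi / 180
    ca <- c(2.3 * cos(th), 2.3 * sin(th), 1.5 * (k - 1))
    xyz <- rbind(
      N = ca + c(-0.8, -0.9, -0.9),
      CA = ca,
      C = ca + c(0.9, 0.6, 1.0),
      O = ca + c(1.9, 0.3, 1.4),
      CB = ca + c(-1.2, 1.1, 0.6) * 1.2
    )
    xyz <- sweep(xyz, 2, center - c(0, 0, 1.5 * (n_res - 1) / 2), `+`)
    rows[[length(rows) + 1L]] <- atom_rows(xyz, "ALA", chain, k)
  }
  do.call(rbind, rows)
}

# serine-like probe residue whose OG sits exactly at `og_pos`, with CB/CA/
# N/C/O receding along `outward` so the donor-antecedent geometry is clean
probe_residue <- function(og_pos, outward, chain, resno) {
  outward <- outward / sqrt(sum(outward^2))
  perp <- if (abs(outward[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  perp <- perp - sum(perp * outward) * outward
  perp <- perp / sqrt(sum(perp^2))
  xyz <- rbind(
    OG = og_pos,
    CB = og_pos + 1.43 * outward,
    CA = og_pos + 2.9 * outward + 0.5 * perp,
    N = og_pos + 3.9 * outward + 1.3 * perp,
    C = og_pos + 4.1 * outward - 0.9 * perp,
    O = og_pos + 5.3 * outward - 1.1 * perp
  )
  atom_rows(xyz, "SER", chain, resno)
}

# phenylalanine-ring probe stacked on a base: hexagon parallel to the base
# plane at `offset` along its normal
phe_ring <- function(centroid, normal, chain, resno, offset = 3.4) {
  normal <- normal / sqrt(sum(normal^2))
  e1 <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- e1 - sum(e1 * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  ctr <- centroid + offset * normal
  ang <- seq(0, 300, by = 60) * pi / 180
  ring <- t(vapply(ang, function(a)
    ctr + 1.39 * (cos(a) * e1 + sin(a) * e2), numeric(3)))
  rownames(ring) <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  xyz <- rbind(ring, CB = ctr + 1.39 * 1.9 * e1 + 0.8 * normal)
  atom_rows(xyz, "PHE", chain, resno)
}

#' Build a toy protein-RNA complex with planted contacts
#'
#' A poly-alanine helix (chain P) and an RNA hairpin (chain R) placed far
#' apart, plus probe residues realising each planted contact exactly:
#' hydrogen bonds as serine hydroxyl probes at the requested donor-acceptor
#' distance (either direction), stacking contacts as phenylalanine rings
#' parallel to a chosen base, and water bridges as a water molecule with
#' both legs at the requested distance. The builder verifies that each
#' planted distance is realised to 0.01 A and that no unplanned polar pair
#' across the interface falls within the hydrogen-bond window, re-jittering
#' probe directions (bounded retries) if necessary.
#'
#' @param hbonds list of planted hydrogen bonds; each element
#'   \code{list(rna_res = resno, rna_atom = name, distance = d)}.
#' @param stacks list of planted stacking contacts; each
#'   \code{list(rna_res = resno, distance = d)} (distance along the base
#'   normal, default 3.4).
#' @param water_bridges list of planted bridges; each
#'   \code{list(rna_res = resno, rna_atom = name, distance = d)} (both
#'   legs at d).
#' @param flipped_out integer loop positions extruded in the hairpin.
#' @param stem_seq,loop_seq hairpin composition.
#' @param seed jitter seed for the retry loop.
#' @param max_retries bounded retries (default 100).
#' @return list with \code{structure} (chains P, R and waters W) and
#'   \code{truth}: \code{hbonds} (rna_atom key, protein_atom key,
#'   distance), \code{stacks}, \code{water_bridges}, \code{flipped_out},
#'   \code{pairs}.
#' @export
build_toy_complex <- function(hbonds = list(), stacks = list(),
                              water_bridges = list(),
                              flipped_out = integer(),
                              stem_seq = "GCGC", loop_seq = "AAUAA",
                              seed = 1, max_retries = 100) {
  for (hb in c(hbonds, water_bridges)) {
    if (!is.null(hb$distance) &&
        (hb$distance < 2.4 || hb$distance > 3.5)) {
      stop("planted hydrogen-bond distance outside [2.4, 3.5] A")
    }
  }
  hp <- build_hairpin(stem_seq, loop_seq, flipped_out = flipped_out,
                      chain = "R")
  rna_full <- hp$structure$atom
  rna <- rna_full[, ATOM_COLUMNS]
  rna_xyz <- as.matrix(rna[, c("x", "y", "z")])
  rna_centroid <- colMeans(rna_xyz)

  rna_atom_pos <- function(resno, name) {
    row <- rna[rna$resno == resno & rna$elety == name, , drop = FALSE]
    if (nrow(row) == 0L) stop("RNA atom ", resno, ":", name, " not found")
    as.numeric(row[1, c("x", "y", "z")])
  }

  # local exposure direction: away from the centroid of RNA atoms within
  # 8 A (more reliable than the global centroid for stem residues)
  outward_dir <- function(pos) {
    d <- sqrt(rowSums(sweep(rna_xyz, 2, pos)^2))
    near <- rna_xyz[d < 8, , drop = FALSE]
    v <- pos - colMeans(near)
    if (sqrt(sum(v^2)) < 1e-6) v <- pos - rna_centroid
    v / sqrt(sum(v^2))
  }

  cap_rna <- polar_capability(rna_full)
  rna_polar_xyz <- rna_xyz[cap_rna$donor | cap_rna$acceptor, , drop = FALSE]
  rna_polar_key <- atom_key(rna_full)[cap_rna$donor | cap_rna$acceptor]

  build_probes <- function(jitter_rot) {
    prows <- list()
    truth_hb <- list()
    truth_wb <- list()
    wrows <- list()
    placed_polar <- matrix(numeric(0), 0, 3)  # OG / water positions so far
    next_res <- 100L

    min_d <- function(p, m) if (nrow(m) == 0L) Inf else
      min(sqrt(rowSums(sweep(m, 2, p)^2)))

    # first direction with full clearance for a probe anchored at `pos`
    # (planted atom key excluded from the polar-clearance test); water
    # bridges additionally place a water halfway
    find_dir <- function(pos, planted_key, d_og, bridge = FALSE) {
      cands <- rbind(outward_dir(pos), fibonacci_sphere(120))
      if (!is.null(jitter_rot)) cands <- cands %*% t(jitter_rot)
      other_polar <- rna_polar_xyz[rna_polar_key != planted_key, ,
                                   drop = FALSE]
      for (t in seq_len(nrow(cands))) {
        u <- cands[t, ]
        og <- pos + (if (bridge) 2 * d_og else d_og) * u
        wat <- if (bridge) pos + d_og * u else NULL
        pts <- rbind(og, og + 3.9 * u, og + 5.3 * u)   # OG, probe N, O
        ok <- all(apply(pts, 1, min_d, m = other_polar) > 3.6) &&
          min_d(og, rna_xyz) >= min(d_og, 2.6) - 1e-9 &&
          min_d(og, placed_polar) > 3.8
        if (ok && bridge) {
          ok <- min_d(wat, other_polar) > 3.6 &&
            min_d(wat, placed_polar) > 3.8
        }
        if (ok) return(list(u = u, og = og, wat = wat))
      }
      NULL
    }

    for (q in seq_along(hbonds)) {
      hb <- hbonds[[q]]
      pos <- rna_atom_pos(hb$rna_res, hb$rna_atom)
      key <- paste("R", hb$rna_res, "", hb$rna_atom, sep = "|")
      hit <- find_dir(pos, key, hb$distance)
      if (is.null(hit)) return(NULL)
      prows[[length(prows) + 1L]] <- probe_residue(hit$og, hit$u, "P",
                                                  next_res)
      placed_polar <- rbind(placed_polar, hit$og)
      truth_hb[[length(truth_hb) + 1L]] <- data.frame(
        rna_atom = key,
        protein_atom = paste("P", next_res, "", "OG", sep = "|"),
        distance = hb$distance, stringsAsFactors = FALSE)
      next_res <- next_res + 1L
    }
    for (q in seq_along(water_bridges)) {
      wb <- water_bridges[[q]]
      pos <- rna_atom_pos(wb$rna_res, wb$rna_atom)
      key <- paste("R", wb$rna_res, "", wb$rna_atom, sep = "|")
      hit <- find_dir(pos, key, wb$distance, bridge = TRUE)
      if (is.null(hit)) return(NULL)
      wxyz <- matrix(hit$wat, 1, 3, dimnames = list("O", NULL))
      wrows[[length(wrows) + 1L]] <- atom_rows(wxyz, "HOH", "W",
                                               next_res, type = "HETATM")
      prows[[length(prows) + 1L]] <- probe_residue(hit$og, hit$u, "P",
                                                  next_res + 1L)
      placed_polar <- rbind(placed_polar, hit$og, hit$wat)
      truth_wb[[length(truth_wb) + 1L]] <- data.frame(
        rna_atom = key,
        protein_atom = paste("P", next_res + 1L, "", "OG", sep = "|"),
        water_res = paste0("W:", next_res),
        distance = wb$distance, stringsAsFactors = FALSE)
      next_res <- next_res + 2L
    }
    list(prows = prows, wrows = wrows,
         truth_hb = if (length(truth_hb)) do.call(rbind, truth_hb) else NULL,
         truth_wb = if (length(truth_wb)) do.call(rbind, truth_wb) else NULL)
  }

  stack_rows <- list()
  truth_st <- list()
  st_res <- 200L
  for (q in seq_along(stacks)) {
    st <- stacks[[q]]
    res_rows <- rna_full[rna_full$resno == st$rna_res, , drop = FALSE]
    pl <- base_plane(res_rows)
    d <- if (is.null(st$distance)) 3.4 else st$distance
    normal <- pl$normal
    if (normal[3] < 0) normal <- -normal   # stack above, into free space
    stack_rows[[length(stack_rows) + 1L]] <-
      phe_ring(pl$centroid, normal, "P", st_res, offset = d)
    truth_st[[length(truth_st) + 1L]] <- data.frame(
      rna_res = paste0("R:", st$rna_res),
      protein_res = paste0("P:", st_res),
      distance = d, stringsAsFactors = FALSE)
    st_res <- st_res + 1L
  }

  helix_rows <- poly_ala_helix(chain = "P",
                               center = rna_centroid + c(0, -40, 0))

  assembled <- with_seed(seed, {
    out <- NULL
    for (try in seq_len(max_retries)) {
      jr <- if (try == 1L) NULL else {
        # random small rotation applied to the candidate directions
        ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
        th <- runif(1, 0.1, 0.6)
        K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1],
                      -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
        diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
      }
      pr <- build_probes(jitter_rot = jr)
      if (is.null(pr)) next
      rows <- do.call(rbind, c(list(rna, helix_rows), pr$prows,
                               stack_rows, pr$wrows))
      cand <- finish_structure("toy_complex", rows)
      truth_st_df <- if (length(truth_st)) do.call(rbind, truth_st) else
        NULL
      if (toy_complex_consistent(cand, pr$truth_hb, pr$truth_wb,
                                 truth_st = truth_st_df)) {
        out <- list(s = cand, pr = pr)
        break
      }
    }
    out
  })
  if (is.null(assembled)) {
    stop("could not realise the planted contacts after ", max_retries,
         " retries")
  }
  list(structure = assembled$s,
       truth = list(
         hbonds = assembled$pr$truth_hb,
         water_bridges = assembled$pr$truth_wb,
         stacks = if (length(truth_st)) do.call(rbind, truth_st) else NULL,
         flipped_out = hp$truth$flipped_out,
         pairs = hp$truth$pairs))
}

# planted distances realised to 0.01 A; no unplanned cross-partition polar
# pair within the hydrogen-bond window (with a small safety margin)
toy_complex_consistent <- function(s, truth_hb, truth_wb, truth_st = NULL,
                                   margin = 0.05) {
  a <- s$atom
  keys <- atom_key(a)
  planted <- character()
  check <- function(k1, k2, d) {
    i <- match(k1, keys); j <- match(k2, keys)
    if (is.na(i) || is.na(j)) return(FALSE)
    abs(atom_distance(a[i, ], a[j, ]) - d) <= 0.01
  }
  if (!is.null(truth_hb)) {
    for (r in seq_len(nrow(truth_hb))) {
      if (!check(truth_hb$rna_atom[r], truth_hb$protein_atom[r],
                 truth_hb$distance[r])) return(FALSE)
      planted <- c(planted, paste(truth_hb$rna_atom[r],
                                  truth_hb$protein_atom[r]))
    }
  }
  cap <- polar_capability(a)
  polar <- cap$donor | cap$acceptor
  ia <- which(a$chain == "R" & polar)
  ib <- which(a$chain == "P" & polar)
  d <- cross_dist(as.matrix(a[ia, c("x", "y", "z")]),
                  as.matrix(a[ib, c("x", "y", "z")]))
  close <- which(d <= 3.5 + margin, arr.ind = TRUE)
  for (h in seq_len(nrow(close))) {
    pair <- paste(keys[ia[close[h, 1]]], keys[ib[close[h, 2]]])
    if (!(pair %in% planted)) return(FALSE)
  }
  # each planted bridging water must see exactly one polar atom per side
  if (!is.null(truth_wb)) {
    iw <- which(a$polymer == "water")
    for (r in seq_len(nrow(truth_wb))) {
      wi <- iw[res_key(a[iw, , drop = FALSE]) == truth_wb$water_res[r]]
      if (length(wi) != 1L) return(FALSE)
      dw_a <- cross_dist(as.matrix(a[wi, c("x", "y", "z"), drop = FALSE]),
                         as.matrix(a[ia, c("x", "y", "z")]))
      dw_b <- cross_dist(as.matrix(a[wi, c("x", "y", "z"), drop = FALSE]),
                         as.matrix(a[ib, c("x", "y", "z")]))
      if (sum(dw_a <= 3.5 + margin) != 1L ||
          sum(dw_b <= 3.5 + margin) != 1L) return(FALSE)
    }
  }
  # each planted ring must stack on its target base only (slightly wider
  # thresholds than the detector, so the detector finds no extras)
  if (!is.null(truth_st)) {
    rings <- collect_rings(a, which(a$chain == "P"))
    bases <- collect_rings(a, which(a$chain == "R"))
    for (r in seq_len(nrow(truth_st))) {
      ring <- Filter(function(x) x$res == truth_st$protein_res[r], rings)
      if (length(ring) != 1L) return(FALSE)
      ring <- ring[[1L]]
      for (b in bases) {
        d <- b$centroid - ring$centroid
        cd <- sqrt(sum(d^2))
        if (cd > 5.7) next
        ang <- plane_angle_deg(ring$normal, b$normal)
        nb <- if (sum(ring$normal * b$normal) < 0) -b$normal else b$normal
        nm <- ring$normal + nb
        nm <- nm / sqrt(sum(nm^2))
        offset <- sqrt(max(0, sum(d^2) - sum(d * nm)^2))
        is_stack <- ang <= 33 && offset <= 2.7
        planted_stack <- b$res == truth_st$rna_res[r]
        if (is_stack && !planted_stack) return(FALSE)
        if (planted_stack && !is_stack) return(FALSE)
      }
    }
  }
  TRUE
}

#' Build a synthetic poly-alanine helix structure
#'
#' A regular alpha-helical CA trace with schematic N, C, O, CB positions;
#' used as the protein partner in conformational-comparison fixtures.
#'
#' @param n_res number of residues.
#' @param chain chain id (default "P").
#' @return structure3d.
#' @export
build_protein_helix <- function(n_res = 30, chain = "P") {
  finish_structure(paste0("helix_", n_res),
                   poly_ala_helix(n_res, chain, center = c(0, 0, 0)))
}

# --- toy crystal ----------------------------------------------------------

#' Build a toy monoclinic crystal with one planted lattice contact
#'
#' A single elongated molecule (poly-glycine CA blobs joined by a spine) in
#' a P2(1) cell, positioned so that exactly one screw-axis mate makes
#' contact with the asymmetric unit. The generating operator and the mate
#' coordinates are returned so the interface can be recomputed directly.
#'
#' @param cell cell parameters (default c(30, 20, 30, 90, 90, 90)).
#' @return list with \code{structure} (chain A, cell + "P 21"),
#'   \code{truth}: \code{operator_index} (2), \code{shift} (c(0,0,0)),
#'   \code{mate_atoms} (data.frame of the contacting mate copy).
#' @export
build_toy_crystal <- function(cell = c(30, 20, 30, 90, 90, 90)) {
  blob <- function(center, spread = 1.1) {
    offs <- rbind(c(0, 0, 0), c(spread, 0, 0), c(-spread, 0, 0),
                  c(0, spread, 0), c(0, -spread, 0), c(0, 0, spread),
                  c(0, 0, -spread), c(spread, spread, -spread) / 1.6)
    sweep(offs, 2, center, `+`)
  }
  bottom <- blob(c(3, 1.5, 3))
  top <- blob(c(-1, 13.5, -1))
  spine <- t(vapply(seq(0, 1, length.out = 5), function(f)
    (1 - f) * c(3, 3.5, 3) + f * c(-1, 11.5, -1), numeric(3)))
  xyz <- rbind(bottom, spine, top)
  rownames(xyz) <- rep("CA", nrow(xyz))
  rows <- do.call(rbind, lapply(seq_len(nrow(xyz)), function(i)
    atom_rows(xyz[i, , drop = FALSE], "GLY", "A", i)))
  s <- finish_structure("toy_crystal", rows, cell = cell,
                        space_group = "P 21")
  # the contacting mate: operator 2 of P 21 = (-x, y + 1/2, -z)
  mate_xyz <- cbind(-xyz[, 1], xyz[, 2] + cell[2] / 2, -xyz[, 3])
  list(structure = s,
       truth = list(operator_index = 2L, shift = c(0, 0, 0),
                    mate_xyz = mate_xyz))
}

# --- planted-cluster ensembles --------------------------------------------

#' Build a conformational ensemble with planted clusters
#'
#' Draws k well-separated reference conformations (re-sampled until all
#' pairwise superposed RMSDs exceed \code{separation}), then populates each
#' cluster with Gaussian-jittered copies. Optionally adds high-energy decoy
#' members so that an energy filter keeping \code{survive_fraction} of the
#' ensemble retains exactly the planted members. Member order is shuffled
#' deterministically.
#'
#' @param sizes planted cluster sizes (length k), largest first or not;
#'   the ranking is recovered by the clustering, not assumed.
#' @param sigma per-coordinate Gaussian jitter (A).
#' @param separation minimum pairwise reference RMSD (A); must exceed
#'   4 * sigma for recoverability.
#' @param seed RNG seed.
#' @param n_atoms atoms per member (default 30).
#' @param survive_fraction energy-filter fraction that should keep exactly
#'   the planted members; 1 means no decoys (default 1).
#' @return list with \code{ensemble} (ensemble3d) and \code{truth}:
#'   \code{labels} (per member; 0 = decoy), \code{sizes}.
#' @export
build_planted_ensemble <- function(sizes, sigma = 0.5, separation = 20,
                                   seed = 1, n_atoms = 30,
                                   survive_fraction = 1) {
  k <- length(sizes)
  stopifnot(k >= 1L, all(sizes >= 1L), sigma >= 0,
            separation > 4 * sigma,
            survive_fraction > 0, survive_fraction <= 1)
  n_planted <- sum(sizes)
  n_total <- ceiling(n_planted / survive_fraction)
  n_decoy <- n_total - n_planted
  box <- max(40, separation * 2)

  with_seed(seed, {
    refs <- NULL
    for (try in seq_len(100L)) {
      cand <- lapply(seq_len(k), function(j)
        matrix(runif(n_atoms * 3, 0, box), ncol = 3))
      ok <- TRUE
      if (k > 1L) {
        for (a in seq_len(k - 1L)) for (b in (a + 1L):k) {
          if (superpose(cand[[b]], cand[[a]])$rmsd < separation) ok <- FALSE
        }
      }
      if (ok) { refs <- cand; break }
    }
    if (is.null(refs)) stop("could not draw references ", separation,
                            " A apart")
    coords <- list()
    labels <- integer()
    for (j in seq_len(k)) {
      for (m in seq_len(sizes[j])) {
        coords[[length(coords) + 1L]] <- refs[[j]] +
          matrix(rnorm(n_atoms * 3, 0, sigma), ncol = 3)
        labels <- c(labels, j)
      }
    }
    for (m in seq_len(n_decoy)) {
      coords[[length(coords) + 1L]] <-
        matrix(runif(n_atoms * 3, 0, box), ncol = 3)
      labels <- c(labels, 0L)
    }
    perm <- sample(length(coords))
    coords <- coords[perm]
    labels <- labels[perm]
    energy <- ifelse(labels > 0L, runif(length(labels), 0, 1),
                     runif(length(labels), 10, 11))
    e <- ensemble3d(coords, energy, model_index = seq_along(coords),
                    atom_selection = "synthetic")
    list(ensemble = e, truth = list(labels = labels, sizes = sizes))
  })
}
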