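# Heavy-atom hydrogen-bond and base-stacking detection. Deposited crystal
# structures carry no hydrogens, so a donor is a heavy atom known to bear a
# polar hydrogen and the directional test is the angle at the donor between
# its bonded heavy-atom antecedent and the acceptor (>= 90 deg), instead of
# a D-H...A angle. Ribose 2'-fluorine is admitted as an acceptor only.

# donor heavy atoms by residue (atoms carrying at least one polar H)
DONOR_ATOMS <- list(
  backbone_protein = "N",            # except proline
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG", ASN = "ND2",
  GLN = "NE2", TRP = "NE1",
  A = "N6", G = c("N1", "N2"), C = "N4", U = "N3", T = "N3",
  ribose = "O2'"
)
# acceptor heavy atoms by residue
ACCEPTOR_ATOMS <- list(
  backbone_protein = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD",
  A = c("N1", "N3", "N7"), G = c("O6", "N3", "N7"),
  C = c("O2", "N3"), U = c("O2", "O4"), T = c("O2", "O4"),
  ribose = c("O2'", "O4'", "O3'", "O5'"),
  phosphate = c("OP1", "OP2", "O1P", "O2P"),
  water = "O"
)

NUCLEOBASE_ATOMS <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9",
                      "N6", "O6", "N2", "N4", "O2", "O4", "C7", "C5M")
BACKBONE_NUC_ATOMS <- c("P", "OP1", "OP2", "OP3", "O1P", "O2P", "O5'", "O3'")
RIBOSE_ATOMS <- c("C1'", "C2'", "C3'", "C4'", "C5'", "O4'", "O2'", "F2'")

# classify a nucleotide atom into the nucleobase / backbone / ribose parts
nucleic_part_of <- function(elety) {
  ifelse(elety %in% NUCLEOBASE_ATOMS, "nucleobase",
    ifelse(elety %in% BACKBONE_NUC_ATOMS, "backbone",
      ifelse(elety %in% RIBOSE_ATOMS, "ribose", NA_character_)))
}

is_ribose_fluorine <- function(atom) {
  atom$elesy == "F" & grepl("2'|2\\*", atom$elety)
}

# per-atom donor / acceptor capability flags
polar_capability <- function(atom) {
  n <- nrow(atom)
  donor <- logical(n); acceptor <- logical(n)
  is_nuc <- atom$polymer %in% c("rna", "dna")
  is_prot <- atom$polymer == "protein"
  is_wat <- atom$polymer == "water"

  donor <- donor |
    (is_prot & atom$elety == "N" & atom$resid != "PRO") |
    (is_wat & atom$elesy == "O")
  acceptor <- acceptor |
    (is_prot & atom$elety %in% ACCEPTOR_ATOMS$backbone_protein) |
    (is_wat & atom$elesy == "O") |
    (is_nuc & atom$elety %in% ACCEPTOR_ATOMS$phosphate) |
    (is_nuc & atom$elety %in% ACCEPTOR_ATOMS$ribose) |
    is_ribose_fluorine(atom)
  donor <- donor | (is_nuc & atom$elety %in% DONOR_ATOMS$ribose)

  key <- ifelse(is_nuc & !is.na(atom$parent_base), atom$parent_base,
                atom$resid)
  for (res in unique(key)) {
    sel <- key == res
    if (res %in% names(DONOR_ATOMS)) {
      donor[sel] <- donor[sel] | atom$elety[sel] %in% DONOR_ATOMS[[res]]
    }
    if (res %in% names(ACCEPTOR_ATOMS)) {
      acceptor[sel] <- acceptor[sel] |
        atom$elety[sel] %in% ACCEPTOR_ATOMS[[res]]
    }
  }
  # fall back to an element heuristic for residues absent from the tables
  known <- key %in% c(names(DONOR_ATOMS), names(ACCEPTOR_ATOMS)) |
    is_prot | is_wat
  unk <- !known & atom$elesy %in% c("N", "O")
  donor[unk & atom$elesy == "N"] <- TRUE
  acceptor[unk] <- TRUE
  list(donor = donor, acceptor = acceptor)
}

# bonded heavy-atom antecedent of each polar atom: nearest heavy atom of the
# same residue within covalent range
donor_antecedent <- function(atom, idx) {
  xyz <- as.matrix(atom[, c("x", "y", "z")])
  rk <- paste(atom$chain, atom$resno, atom$insert)
  ante <- rep(NA_integer_, length(idx))
  for (q in seq_along(idx)) {
    i <- idx[q]
    same <- which(rk == rk[i])
    same <- same[same != i]
    if (length(same) == 0L) next
    d <- sqrt(rowSums(sweep(xyz[same, , drop = FALSE], 2, xyz[i, ])^2))
    ok <- same[d < 1.8]
    if (length(ok) == 0L) next
    ante[q] <- ok[which.min(d[d < 1.8])]
  }
  ante
}

angle_deg <- function(p1, p2, p3) {
  # angle at p2
  v1 <- p1 - p2; v2 <- p3 - p2
  c <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, c))) * 180 / pi
}

hbond_row <- function(atom, di, ai, dist, mediated_by = NA_character_) {
  da <- atom[di, ]; aa <- atom[ai, ]
  nuc_side <- if (da$polymer %in% c("rna", "dna")) da else
    if (aa$polymer %in% c("rna", "dna")) aa else NULL
  data.frame(
    donor = atom_key(da), acceptor = atom_key(aa),
    donor_res = res_key(da), acceptor_res = res_key(aa),
    donor_resid = da$resid, acceptor_resid = aa$resid,
    distance = dist, mediated_by = mediated_by,
    nucleic_part = if (is.null(nuc_side)) NA_character_
      else nucleic_part_of(nuc_side$elety),
    nucleic_res = if (is.null(nuc_side)) NA_character_
      else res_key(nuc_side),
    region = NA_character_,
    fluorine_acceptor = aa$elesy == "F",
    stringsAsFactors = FALSE
  )
}

empty_hbonds <- function() {
  data.frame(donor = character(), acceptor = character(),
             donor_res = character(), acceptor_res = character(),
             donor_resid = character(), acceptor_resid = character(),
             distance = numeric(), mediated_by = character(),
             nucleic_part = character(), nucleic_res = character(),
             region = character(), fluorine_acceptor = logical(),
             stringsAsFactors = FALSE)
}

# core pair finder over two atom tables (already subset); returns one row
# per unordered pair, direction chosen as the first capability-compatible
# orientation (a-side donating tried first)
find_polar_pairs <- function(atom, idx_a, idx_b, dmax, dmin) {
  if (length(idx_a) == 0L || length(idx_b) == 0L) return(empty_hbonds())
  cap <- polar_capability(atom)
  xyz <- as.matrix(atom[, c("x", "y", "z")])
  pa <- idx_a[cap$donor[idx_a] | cap$acceptor[idx_a]]
  pb <- idx_b[cap$donor[idx_b] | cap$acceptor[idx_b]]
  if (length(pa) == 0L || length(pb) == 0L) return(empty_hbonds())
  dmat <- cross_dist(xyz[pa, , drop = FALSE], xyz[pb, , drop = FALSE])
  hits <- which(dmat >= dmin & dmat <= dmax, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(empty_hbonds())
  cand <- data.frame(i = pa[hits[, 1]], j = pb[hits[, 2]],
                     dist = dmat[hits])
  ante <- donor_antecedent(atom, seq_len(nrow(atom)))
  ante_of <- function(i) ante[i]
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]; dd <- cand$dist[r]
    ok_dir <- function(d, a) {
      if (!cap$donor[d] || !cap$acceptor[a]) return(FALSE)
      if (atom$elesy[a] == "F" && !is_ribose_fluorine(atom[a, ])) {
        return(FALSE)
      }
      x <- ante_of(d)
      if (is.na(x)) return(TRUE)  # lone polar atom: no angle test possible
      angle_deg(xyz[x, ], xyz[d, ], xyz[a, ]) >= 90
    }
    if (ok_dir(i, j)) {
      rows[[length(rows) + 1L]] <- hbond_row(atom, i, j, dd)
    } else if (ok_dir(j, i)) {
      rows[[length(rows) + 1L]] <- hbond_row(atom, j, i, dd)
    }
  }
  if (length(rows) == 0L) return(empty_hbonds())
  do.call(rbind, rows)
}

#' Find direct hydrogen bonds across an interface
#'
#' Detects donor/acceptor heavy-atom pairs between two chain partitions
#' with \code{dmin <= |DA| <= dmax} and the donor-antecedent angle proxy
#' (angle antecedent-donor-acceptor >= 90 deg). Fluorine is accepted only
#' as a ribose 2'-F acceptor. Each bond is labelled with the nucleic-side
#' part (nucleobase / backbone / ribose).
#'
#' @param s structure3d.
#' @param partition_a,partition_b chain id vectors (disjoint).
#' @param dmax,dmin donor-acceptor distance window (default 3.5 / 2.4 A).
#' @return data.frame (possibly empty), one row per bond: donor, acceptor
#'   atom keys, residue keys, distance, nucleic_part, fluorine_acceptor.
#' @export
find_hbonds <- function(s, partition_a, partition_b, dmax = 3.5,
                        dmin = 2.4) {
  if (length(intersect(partition_a, partition_b)) > 0L) {
    stop("partitions overlap")
  }
  atom <- subset_structure(s, drop_hydrogens = TRUE)$atom
  idx_a <- which(atom$chain %in% partition_a & atom$polymer != "water")
  idx_b <- which(atom$chain %in% partition_b & atom$polymer != "water")
  find_polar_pairs(atom, idx_a, idx_b, dmax, dmin)
}

#' Find water-mediated hydrogen bonds across an interface
#'
#' One record per (partition-a polar atom, water oxygen, partition-b polar
#' atom) triple where both legs independently satisfy the direct
#' hydrogen-bond distance rule.
#'
#' @inheritParams find_hbonds
#' @return data.frame as \code{\link{find_hbonds}}, with \code{mediated_by}
#'   set to the water residue key and \code{distance} the longer leg;
#'   \code{distance_a}/\code{distance_b} carry both legs.
#' @export
find_water_bridges <- function(s, partition_a, partition_b, dmax = 3.5,
                               dmin = 2.4) {
  atom <- subset_structure(s, drop_hydrogens = TRUE)$atom
  wat <- which(atom$polymer == "water" & atom$elesy == "O")
  if (length(wat) == 0L) return(cbind(empty_hbonds(),
                                      distance_a = numeric(),
                                      distance_b = numeric()))
  idx_a <- which(atom$chain %in% partition_a & atom$polymer != "water")
  idx_b <- which(atom$chain %in% partition_b & atom$polymer != "water")
  legs_a <- find_polar_pairs(atom, idx_a, wat, dmax, dmin)
  legs_b <- find_polar_pairs(atom, idx_b, wat, dmax, dmin)
  if (nrow(legs_a) == 0L || nrow(legs_b) == 0L) {
    return(cbind(empty_hbonds(), distance_a = numeric(),
                 distance_b = numeric()))
  }
  wat_of <- function(legs) ifelse(startsWith(legs$donor_resid, "HOH") |
                                    legs$donor_resid %in% WATER_RESID,
                                  legs$donor_res, legs$acceptor_res)
  side_of <- function(legs) ifelse(legs$donor_resid %in% WATER_RESID,
                                   legs$acceptor, legs$donor)
  rows <- list()
  for (ra in seq_len(nrow(legs_a))) {
    for (rb in seq_len(nrow(legs_b))) {
      if (wat_of(legs_a[ra, ]) != wat_of(legs_b[rb, ])) next
      a_atom <- side_of(legs_a[ra, ])
      b_atom <- side_of(legs_b[rb, ])
      ai <- which(atom_key(atom) == a_atom)[1]
      bi <- which(atom_key(atom) == b_atom)[1]
      row <- hbond_row(atom, ai, bi,
                       max(legs_a$distance[ra], legs_b$distance[rb]),
                       mediated_by = wat_of(legs_a[ra, ]))
      row$distance_a <- legs_a$distance[ra]
      row$distance_b <- legs_b$distance[rb]
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) return(cbind(empty_hbonds(),
                                       distance_a = numeric(),
                                       distance_b = numeric()))
  do.call(rbind, rows)
}

# collect aromatic/planar rings of a partition: nucleobases plus
# Phe/Tyr/Trp/His side chains
collect_rings <- function(atom, idx) {
  sub <- atom[idx, , drop = FALSE]
  rk <- res_key(sub)
  out <- list()
  for (r in unique(rk)) {
    res <- sub[rk == r, , drop = FALSE]
    pb <- res$parent_base[1L]
    ok <- (!is.na(pb) && pb %in% names(BASE_RING_ATOMS)) ||
      res$resid[1L] %in% names(AA_RING_ATOMS)
    if (!ok) next
    pl <- tryCatch(base_plane(res), error = function(e) NULL)
    if (is.null(pl)) next
    out[[length(out) + 1L]] <- list(res = r, resid = res$resid[1L],
                                    normal = pl$normal,
                                    centroid = pl$centroid)
  }
  out
}

#' Find base/aromatic stacking contacts across an interface
#'
#' Ring pairs (nucleobase rings and Phe/Tyr/Trp/His side-chain rings)
#' satisfying three geometric thresholds: centroid distance, inter-plane
#' angle, and lateral offset of the centroids perpendicular to the mean
#' ring normal.
#'
#' @param s structure3d.
#' @param partition_a,partition_b chain id vectors.
#' @param centroid_max maximum centroid-centroid distance (A, default 5.5).
#' @param angle_max maximum inter-plane angle (degrees, default 30).
#' @param offset_max maximum lateral offset (A, default 2.5).
#' @return data.frame: ring_a, ring_b (residue keys), resid_a, resid_b,
#'   centroid_distance, plane_angle, lateral_offset.
#' @export
find_stacking <- function(s, partition_a, partition_b, centroid_max = 5.5,
                          angle_max = 30, offset_max = 2.5) {
  atom <- subset_structure(s, drop_hydrogens = TRUE)$atom
  rings_a <- collect_rings(atom, which(atom$chain %in% partition_a))
  rings_b <- collect_rings(atom, which(atom$chain %in% partition_b))
  rows <- list()
  for (ra in rings_a) {
    for (rb in rings_b) {
      d <- rb$centroid - ra$centroid
      cd <- sqrt(sum(d^2))
      if (cd > centroid_max) next
      ang <- plane_angle_deg(ra$normal, rb$normal)
      if (ang > angle_max) next
      # mean normal (sign-aligned)
      nb <- if (sum(ra$normal * rb$normal) < 0) -rb$normal else rb$normal
      nm <- ra$normal + nb
      nm <- nm / sqrt(sum(nm^2))
      offset <- sqrt(max(0, sum(d^2) - sum(d * nm)^2))
      if (offset > offset_max) next
      rows[[length(rows) + 1L]] <- data.frame(
        ring_a = ra$res, ring_b = rb$res, resid_a = ra$resid,
        resid_b = rb$resid, centroid_distance = cd, plane_angle = ang,
        lateral_offset = offset, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(ring_a = character(), ring_b = character(),
                      resid_a = character(), resid_b = character(),
                      centroid_distance = numeric(), plane_angle = numeric(),
                      lateral_offset = numeric(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Generic nonpolar contacts across an interface
#'
#' Any-heavy-atom contacts within a cutoff between apolar (carbon) groups;
#' complements the ring-stacking detector for contacts against non-aromatic
#' side chains such as alanine methyls.
#'
#' @param s structure3d.
#' @param partition_a,partition_b chain id vectors.
#' @param cutoff distance cutoff (A, default 4.5).
#' @return data.frame: atom_a, atom_b, res_a, res_b, distance.
#' @export
find_nonpolar_contacts <- function(s, partition_a, partition_b,
                                   cutoff = 4.5) {
  atom <- subset_structure(s, drop_hydrogens = TRUE)$atom
  ia <- which(atom$chain %in% partition_a & atom$elesy == "C")
  ib <- which(atom$chain %in% partition_b & atom$elesy == "C")
  if (length(ia) == 0L || length(ib) == 0L) {
    return(data.frame(atom_a = character(), atom_b = character(),
                      res_a = character(), res_b = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  dmat <- cross_dist(as.matrix(atom[ia, c("x", "y", "z")]),
                     as.matrix(atom[ib, c("x", "y", "z")]))
  hits <- which(dmat <= cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0L) {
    return(data.frame(atom_a = character(), atom_b = character(),
                      res_a = character(), res_b = character(),
                      distance = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(atom_a = atom_key(atom[ia[hits[, 1]], ]),
             atom_b = atom_key(atom[ib[hits[, 2]], ]),
             res_a = res_key(atom[ia[hits[, 1]], ]),
             res_b = res_key(atom[ib[hits[, 2]], ]),
             distance = dmat[hits], stringsAsFactors = FALSE)
}

#' Categorise interface hydrogen bonds
#'
#' Labels each bond's nucleic-side residue with its secondary-structure
#' region (helix for stem members, loop for loop members) and tallies the
#' interface: total, nucleobase, backbone (phosphate + ribose merged),
#' loop, helix, direct, water-mediated and fluorine-acceptor counts.
#'
#' @param bonds data.frame from \code{\link{find_hbonds}} and/or
#'   \code{\link{find_water_bridges}} (rbind of both is accepted; missing
#'   \code{distance_a/b} columns are tolerated).
#' @param ss \code{rna_ss} object covering every nucleotide in \code{bonds}.
#' @return list of class \code{contact_breakdown} with the count fields and
#'   the annotated bond table (\code{bonds}).
#' @export
categorize_hbonds <- function(bonds, ss) {
  stopifnot(inherits(ss, "rna_ss"))
  region_map <- ss_region_map(ss)
  if (nrow(bonds) > 0L) {
    nuc <- bonds$nucleic_res
    known <- is.na(nuc) | nuc %in% names(region_map)
    if (!all(known)) {
      stop("nucleotide(s) missing from the secondary structure: ",
           paste(unique(nuc[!known]), collapse = ", "))
    }
    bonds$region <- ifelse(is.na(nuc), "n/a", region_map[nuc])
  }
  mediated <- if (nrow(bonds) > 0L) !is.na(bonds$mediated_by) else logical()
  direct <- !mediated
  part <- if (nrow(bonds) > 0L) bonds$nucleic_part else character()
  out <- list(
    total = nrow(bonds),
    nucleobase = sum(direct & part %in% "nucleobase", na.rm = TRUE),
    backbone = sum(direct & part %in% c("backbone", "ribose"), na.rm = TRUE),
    loop = sum(bonds$region %in% "loop"),
    helix = sum(bonds$region %in% "helix"),
    direct = sum(direct),
    water_mediated = sum(mediated),
    fluorine = if (nrow(bonds) > 0L) sum(bonds$fluorine_acceptor) else 0L,
    bonds = bonds
  )
  class(out) <- "contact_breakdown"
  out
}

#' @export
print.contact_breakdown <- function(x, ...) {
  cat(sprintf(paste0("H-bond breakdown: %d total (%d direct, %d water-",
                     "mediated)\n  nucleobase %d / backbone %d; loop %d / ",
                     "helix %d; fluorine %d\n"),
              x$total, x$direct, x$water_mediated, x$nucleobase,
              x$backbone, x$loop, x$helix, x$fluorine))
  invisible(x)
}
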