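# Buried surface area, interface residues and crystal-contact enumeration.
# BSA follows the standard convention SASA(A) + SASA(B) - SASA(AB); the
# per-molecule interface fraction is the area each side loses on
# complexation divided by that side's free-state SASA.

#' Interface report for a two-partition complex
#'
#' Computes buried surface area, interface residue sets and per-side SASA
#' fractions for a complex split into two chain sets. Waters and ligands
#' are excluded from the SASA partitions.
#'
#' @param s structure3d containing both partitions.
#' @param partition_a,partition_b character vectors of chain ids (disjoint).
#' @param residue_criterion "delta_sasa" (residues losing > 0.1 A^2 of SASA
#'   on complexation) or "distance" (any heavy atom within
#'   \code{distance_cutoff} of the other partition).
#' @param distance_cutoff Angstrom, used in distance mode (default 5.0).
#' @param probe,n_points passed to \code{\link{compute_sasa}}.
#' @param delta_sasa_min ΔSASA threshold for an interface residue (A^2).
#' @return object of class \code{interface_report}: \code{bsa_combined},
#'   \code{interface_residues_a}, \code{interface_residues_b} (residue
#'   keys), \code{fraction_sasa_a}, \code{fraction_sasa_b},
#'   \code{criterion}, plus the three underlying SASA totals.
#' @export
interface_report <- function(s, partition_a, partition_b,
                             residue_criterion = c("delta_sasa", "distance"),
                             distance_cutoff = 5.0, probe = 1.4,
                             n_points = 960, delta_sasa_min = 0.1) {
  residue_criterion <- match.arg(residue_criterion)
  if (length(intersect(partition_a, partition_b)) > 0L) {
    stop("partitions share chains: ",
         paste(intersect(partition_a, partition_b), collapse = ", "))
  }
  sa <- subset_structure(s, chains = partition_a, drop_water = TRUE)
  sb <- subset_structure(s, chains = partition_b, drop_water = TRUE)
  sa <- subset_structure(sa, polymers = c("protein", "rna", "dna"))
  sb <- subset_structure(sb, polymers = c("protein", "rna", "dna"))
  if (nrow(sa$atom) == 0L || nrow(sb$atom) == 0L) {
    stop("empty partition (after dropping waters/ligands)")
  }
  sab <- s
  sab$atom <- rbind(sa$atom, sb$atom)

  res_a <- compute_sasa(sa, probe = probe, n_points = n_points)
  res_b <- compute_sasa(sb, probe = probe, n_points = n_points)
  res_ab <- compute_sasa(sab, probe = probe, n_points = n_points)

  bsa <- res_a$total + res_b$total - res_ab$total

  # area lost per side: free-state per-atom SASA minus complexed
  lost_side <- function(free, part_atoms) {
    keys <- atom_key(part_atoms)
    comp <- res_ab$per_atom[keys]
    comp[is.na(comp)] <- 0
    sum(free$per_atom[keys] - comp)
  }
  lost_a <- lost_side(res_a, sa$atom)
  lost_b <- lost_side(res_b, sb$atom)

  if (residue_criterion == "delta_sasa") {
    iface_res <- function(free, part_atoms) {
      rk <- res_key(part_atoms)
      comp <- tapply(res_ab$per_atom[atom_key(part_atoms)], rk, sum)
      dif <- free$per_residue[names(comp)] - as.numeric(comp)
      names(dif)[!is.na(dif) & dif > delta_sasa_min]
    }
    ira <- iface_res(res_a, sa$atom)
    irb <- iface_res(res_b, sb$atom)
  } else {
    xa <- coords3d(sa)
    xb <- coords3d(sb)
    dmat <- cross_dist(xa, xb)
    close_a <- apply(dmat, 1, min) <= distance_cutoff
    close_b <- apply(dmat, 2, min) <= distance_cutoff
    ira <- unique(res_key(sa$atom)[close_a])
    irb <- unique(res_key(sb$atom)[close_b])
  }

  out <- list(
    bsa_combined = max(0, bsa),
    interface_residues_a = ira,
    interface_residues_b = irb,
    fraction_sasa_a = max(0, min(1, lost_a / res_a$total)),
    fraction_sasa_b = max(0, min(1, lost_b / res_b$total)),
    criterion = if (residue_criterion == "delta_sasa")
      sprintf("delta_sasa > %.2f A^2", delta_sasa_min)
    else sprintf("heavy-atom distance <= %.1f A", distance_cutoff),
    sasa_a = res_a$total, sasa_b = res_b$total, sasa_ab = res_ab$total
  )
  class(out) <- "interface_report"
  out
}

#' @export
print.interface_report <- function(x, ...) {
  cat(sprintf("Interface: BSA %.0f A^2; %d + %d interface residues (%s)\n",
              x$bsa_combined, length(x$interface_residues_a),
              length(x$interface_residues_b), x$criterion))
  cat(sprintf("  side A: %.1f%% of free SASA buried; side B: %.1f%%\n",
              100 * x$fraction_sasa_a, 100 * x$fraction_sasa_b))
  invisible(x)
}

# pairwise distance matrix between two coordinate sets
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# crystallographic orthogonalisation matrix (fractional -> cartesian)
orth_matrix <- function(cell) {
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  v <- (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- c * sqrt(max(0, 1 - cos(be)^2 - v^2))
  matrix(c(a, b * cos(ga), c * cos(be),
           0, b * sin(ga), c * v,
           0, 0, cz), nrow = 3, byrow = TRUE)
}

# apply symmetry operator k (+ integer lattice shift) to a structure
apply_symop <- function(s, op, shift = c(0, 0, 0)) {
  xyz <- coords3d(s)
  if (identical(op$frame, "cartesian")) {
    M <- orth_matrix(s$cell)
    new <- t(op$R %*% t(xyz)) +
      matrix(rep(op$t + as.numeric(M %*% shift), each = nrow(xyz)), ncol = 3)
  } else {
    M <- orth_matrix(s$cell)
    Minv <- solve(M)
    frac <- t(Minv %*% t(xyz))
    frac <- t(op$R %*% t(frac)) +
      matrix(rep(op$t + shift, each = nrow(xyz)), ncol = 3)
    new <- t(M %*% t(frac))
  }
  out <- s
  out$atom$x <- new[, 1]
  out$atom$y <- new[, 2]
  out$atom$z <- new[, 3]
  out
}

is_identity_op <- function(op) {
  max(abs(op$R - diag(3))) < 1e-9 && max(abs(op$t %% 1)) < 1e-9
}

# canonical key of (op k, shift) under inversion, used to deduplicate the
# symmetric pair (ASU->mate vs mate->ASU)
canonical_pair_key <- function(ops, k, shift, chain_a, chain_b) {
  op <- ops[[k]]
  tt <- op$t + shift
  Rinv <- solve(op$R)
  tinv <- as.numeric(-Rinv %*% tt)
  kk <- NA_integer_; sh2 <- NULL
  for (j in seq_along(ops)) {
    if (max(abs(ops[[j]]$R - Rinv)) < 1e-6) {
      d <- tinv - ops[[j]]$t
      if (max(abs(d - round(d))) < 1e-6) { kk <- j; sh2 <- round(d); break }
    }
  }
  key1 <- paste(k, paste(shift, collapse = ","), chain_a, chain_b)
  if (is.na(kk)) return(key1)
  key2 <- paste(kk, paste(sh2, collapse = ","), chain_b, chain_a)
  min(key1, key2)
}

#' Enumerate crystal-symmetry interfaces
#'
#' Generates symmetry mates of the asymmetric unit within a range of unit
#' cell translations, computes the buried surface area for every contacting
#' asymmetric-unit/mate chain pairing, removes symmetric duplicates and
#' ranks interfaces by BSA.
#'
#' @param s structure3d with cell and symmetry operators.
#' @param max_lattice_shift integer; translations searched in
#'   \code{-max_lattice_shift..max_lattice_shift} along each axis.
#' @param min_bsa smallest reported interface (A^2, default 50).
#' @param contact_cutoff prefilter: a mate is considered only if some atom
#'   pair is within this distance (default 5 A).
#' @param n_points SASA quadrature points (default 240 for speed; interfaces
#'   are re-rankings, not absolute areas).
#' @return data.frame of class \code{crystal_interfaces}: columns
#'   \code{operator_index}, \code{shift_a/b/c}, \code{chain_asu},
#'   \code{chain_mate}, \code{bsa_combined}, ranked by BSA descending.
#' @export
enumerate_crystal_interfaces <- function(s, max_lattice_shift = 1,
                                         min_bsa = 50, contact_cutoff = 5.0,
                                         n_points = 240) {
  if (is.null(s$cell)) stop("structure carries no cell parameters")
  ops <- s$sym_ops
  if (is.null(ops) && !is.null(s$space_group)) {
    ops <- space_group_ops(s$space_group)
  }
  if (is.null(ops)) stop("structure carries no symmetry operators")

  asu <- subset_structure(s, polymers = c("protein", "rna", "dna"),
                          drop_water = TRUE, drop_hydrogens = TRUE)
  chains <- unique(asu$atom$chain)
  xyz_asu <- coords3d(asu)

  shifts <- expand.grid(a = -max_lattice_shift:max_lattice_shift,
                        b = -max_lattice_shift:max_lattice_shift,
                        c = -max_lattice_shift:max_lattice_shift)
  rows <- list()
  seen <- character()
  for (k in seq_along(ops)) {
    for (si in seq_len(nrow(shifts))) {
      shift <- as.numeric(shifts[si, ])
      if (is_identity_op(ops[[k]]) && all(shift == 0)) next
      mate <- apply_symop(asu, ops[[k]], shift)
      xyz_mate <- coords3d(mate)
      # bounding-box prefilter
      if (any(apply(xyz_mate, 2, min) - apply(xyz_asu, 2, max) >
              contact_cutoff) ||
          any(apply(xyz_asu, 2, min) - apply(xyz_mate, 2, max) >
              contact_cutoff)) next
      dmat <- cross_dist(xyz_asu, xyz_mate)
      if (min(dmat) > contact_cutoff) next
      for (ca in chains) {
        for (cb in chains) {
          ia <- asu$atom$chain == ca
          ib <- mate$atom$chain == cb
          if (min(dmat[ia, ib, drop = FALSE]) > contact_cutoff) next
          key <- canonical_pair_key(ops, k, shift, ca, cb)
          if (key %in% seen) next
          seen <- c(seen, key)
          # assemble a two-copy structure for the BSA computation
          pa <- asu$atom[ia, , drop = FALSE]
          pb <- mate$atom[ib, , drop = FALSE]
          pb$chain <- paste0(pb$chain, "_m")
          pair_s <- s
          pair_s$atom <- rbind(pa, pb)
          rep_ab <- interface_report(pair_s, unique(pa$chain),
                                     unique(pb$chain),
                                     residue_criterion = "distance",
                                     n_points = n_points)
          if (rep_ab$bsa_combined >= min_bsa) {
            rows[[length(rows) + 1L]] <- data.frame(
              operator_index = k, shift_a = shift[1], shift_b = shift[2],
              shift_c = shift[3], chain_asu = ca, chain_mate = cb,
              bsa_combined = rep_ab$bsa_combined,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(operator_index = integer(), shift_a = integer(),
               shift_b = integer(), shift_c = integer(),
               chain_asu = character(), chain_mate = character(),
               bsa_combined = numeric(), stringsAsFactors = FALSE)
  } else {
    d <- do.call(rbind, rows)
    d[order(-d$bsa_combined), , drop = FALSE]
  }
  rownames(out) <- NULL
  class(out) <- c("crystal_interfaces", "data.frame")
  out
}
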