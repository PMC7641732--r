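# Geometric primitives: least-squares rigid superposition (Kabsch),
# matched-atom RMSD, distances, least-squares planes through base rings.

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimising
#' \eqn{\sum_i \| R x_i + t - y_i \|^2} between matched point sets.
#' Reflections are excluded (det(R) = +1).
#'
#' @param mobile N x 3 matrix (moved onto the reference).
#' @param reference N x 3 matrix.
#' @return list with \code{rotation} (3x3), \code{translation} (3),
#'   \code{rmsd} after superposition, and \code{degenerate} (TRUE when the
#'   point set is rank-deficient, e.g. collinear; the minimiser is still
#'   returned).
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L)
  if (nrow(mobile) != nrow(reference)) stop("point sets differ in size")
  n <- nrow(mobile)
  if (n < 3L) stop("superposition needs at least 3 points, got ", n)
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  M <- sweep(mobile, 2, cm)
  Rf <- sweep(reference, 2, cr)
  H <- crossprod(M, Rf)          # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- as.numeric(cr - R %*% cm)
  fit <- M %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - Rf)^2)))
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  list(rotation = R, translation = t, rmsd = rmsd, degenerate = degenerate)
}

#' Apply a rigid transform to coordinates
#' @param x N x 3 matrix.
#' @param transform list(rotation, translation) as from \code{superpose}.
#' @return N x 3 matrix.
#' @export
apply_transform <- function(x, transform) {
  x <- as.matrix(x)
  sweep(x %*% t(transform$rotation), 2, -transform$translation)
}

#' RMSD between two coordinate sets (no superposition)
#' @param a,b N x 3 matrices.
#' @return numeric RMSD in Angstrom.
#' @export
rmsd_coords <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}

#' Distance between two atoms
#' @param a,b one-row atom data.frames (or any objects with x, y, z).
#' @return Euclidean distance in Angstrom.
#' @export
atom_distance <- function(a, b) {
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
}

# map chains of b onto chains of a; default: identity on shared ids, else
# pair the longest protein chains (and longest nucleic chains) by size
default_chain_map <- function(a, b) {
  ca <- chain_summary(a); cb <- chain_summary(b)
  shared <- intersect(ca$chain, cb$chain)
  map <- stats::setNames(shared, shared)
  for (cls in c("protein", "rna", "dna")) {
    ua <- ca[ca$polymer == cls & !(ca$chain %in% map), , drop = FALSE]
    ub <- cb[cb$polymer == cls & !(cb$chain %in% names(map)), , drop = FALSE]
    if (nrow(ua) > 0L && nrow(ub) > 0L) {
      ua <- ua[order(-ua$n_residues), , drop = FALSE]
      ub <- ub[order(-ub$n_residues), , drop = FALSE]
      k <- min(nrow(ua), nrow(ub))
      map <- c(map, stats::setNames(ua$chain[seq_len(k)], ub$chain[seq_len(k)]))
    }
  }
  map
}

match_atoms <- function(a, b, selection = c("calpha", "heavy", "custom"),
                        elety = NULL, residue_subset = NULL,
                        chain_map = NULL) {
  selection <- match.arg(selection)
  aa <- subset_structure(a, drop_water = TRUE, drop_hydrogens = TRUE)$atom
  ab <- subset_structure(b, drop_water = TRUE, drop_hydrogens = TRUE)$atom
  if (is.null(chain_map)) chain_map <- default_chain_map(a, b)
  ab <- ab[ab$chain %in% names(chain_map), , drop = FALSE]
  ab$chain <- unname(chain_map[ab$chain])
  label <- selection
  if (selection == "calpha") {
    aa <- aa[aa$elety == "CA" & aa$polymer == "protein", , drop = FALSE]
    ab <- ab[ab$elety == "CA" & ab$polymer == "protein", , drop = FALSE]
    label <- "Calpha"
  } else if (selection == "custom") {
    stopifnot(!is.null(elety))
    aa <- aa[aa$elety %in% elety, , drop = FALSE]
    ab <- ab[ab$elety %in% elety, , drop = FALSE]
    label <- paste(elety, collapse = ",")
  }
  if (!is.null(residue_subset)) {
    aa <- aa[res_key(aa) %in% residue_subset, , drop = FALSE]
    ab <- ab[res_key(ab) %in% residue_subset, , drop = FALSE]
  }
  ka <- atom_key(aa)
  kb <- atom_key(ab)
  common <- intersect(ka, kb)
  list(
    a = aa[match(common, ka), , drop = FALSE],
    b = ab[match(common, kb), , drop = FALSE],
    n_matched = length(common),
    n_unmatched_a = sum(!(ka %in% common)),
    n_unmatched_b = sum(!(kb %in% common)),
    selection_label = label
  )
}

#' Matched-atom RMSD between two structures
#'
#' Atoms are matched by (mapped chain, residue number, insertion code, atom
#' name); unmatched atoms are dropped and counted. By default, chains with
#' the same id are paired; across different entries the longest chains of
#' each polymer class are paired (override with \code{chain_map}).
#'
#' @param a,b structure3d.
#' @param selection "calpha", "heavy", or "custom" (then give \code{elety}).
#' @param elety atom names for selection = "custom".
#' @param residue_subset optional residue keys ("chain:resno") restricting
#'   the comparison (keys in a's frame).
#' @param superpose_first superpose b onto a before measuring (default TRUE).
#' @param chain_map named character vector mapping b's chain ids to a's.
#' @return list of class \code{rmsd_report}: \code{n_matched}, \code{rmsd},
#'   \code{selection_label}, \code{n_unmatched_a}, \code{n_unmatched_b}.
#' @export
rmsd_matched <- function(a, b, selection = c("calpha", "heavy", "custom"),
                         elety = NULL, residue_subset = NULL,
                         superpose_first = TRUE, chain_map = NULL) {
  m <- match_atoms(a, b, selection, elety, residue_subset, chain_map)
  if (m$n_matched < 3L) {
    stop("fewer than 3 matched atoms for selection '", m$selection_label, "'")
  }
  xa <- as.matrix(m$a[, c("x", "y", "z")])
  xb <- as.matrix(m$b[, c("x", "y", "z")])
  r <- if (superpose_first) superpose(xb, xa)$rmsd else rmsd_coords(xa, xb)
  out <- list(n_matched = m$n_matched, rmsd = r,
              selection_label = m$selection_label,
              n_unmatched_a = m$n_unmatched_a,
              n_unmatched_b = m$n_unmatched_b)
  class(out) <- "rmsd_report"
  out
}

#' @export
print.rmsd_report <- function(x, ...) {
  cat(sprintf("RMSD (%s): %.3f A over %d matched atoms (%d/%d unmatched)\n",
              x$selection_label, x$rmsd, x$n_matched,
              x$n_unmatched_a, x$n_unmatched_b))
  invisible(x)
}

# ring atom names per residue type
BASE_RING_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6"),
  G = c("N9", "C8", "N7", "C5", "C4", "N3", "C2", "N1", "C6"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6"),
  T = c("N1", "C2", "N3", "C4", "C5", "C6")
)
AA_RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
)

# least-squares plane through a point set: unit normal, centroid, rms residual
fit_plane <- function(xyz) {
  xyz <- as.matrix(xyz)
  stopifnot(nrow(xyz) >= 3L)
  ctr <- colMeans(xyz)
  sv <- svd(sweep(xyz, 2, ctr))
  normal <- sv$v[, 3]
  normal <- normal / sqrt(sum(normal^2))
  res <- sqrt(mean((sweep(xyz, 2, ctr) %*% normal)^2))
  list(normal = normal, centroid = ctr, residual = res)
}

#' Least-squares plane of a nucleotide base (or aromatic ring)
#'
#' Fits a plane through the heavy atoms of the base ring of a nucleotide
#' residue (parent-base ring atom names), or of an aromatic amino-acid
#' side-chain ring.
#'
#' @param residue_atoms data.frame of the residue's atoms (rows of a
#'   structure3d atom table).
#' @return list with \code{normal} (unit 3-vector), \code{centroid}
#'   (3-vector, Angstrom) and \code{residual} (rms out-of-plane distance).
#' @export
base_plane <- function(residue_atoms) {
  rn <- residue_atoms$resid[1L]
  pb <- residue_atoms$parent_base[1L]
  ring <- if (!is.na(pb) && pb %in% names(BASE_RING_ATOMS)) {
    BASE_RING_ATOMS[[pb]]
  } else if (rn %in% names(AA_RING_ATOMS)) {
    AA_RING_ATOMS[[rn]]
  } else {
    stop("residue ", rn, " has no known ring atom set")
  }
  sel <- residue_atoms$elety %in% ring
  if (sum(sel) < 3L) {
    stop("missing ring atoms for ", rn, ": ",
         paste(setdiff(ring, residue_atoms$elety), collapse = ", "))
  }
  fit_plane(residue_atoms[sel, c("x", "y", "z")])
}

# angle between two vectors in degrees, folded into [0, 90]
plane_angle_deg <- function(n1, n2) {
  c <- abs(sum(n1 * n2)) / sqrt(sum(n1^2) * sum(n2^2))
  acos(pmin(1, c)) * 180 / pi
}
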