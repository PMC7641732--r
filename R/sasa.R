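# Solvent-accessible surface area by the Shrake-Rupley method: a probe
# sphere is rolled over van der Waals spheres; accessibility is estimated by
# counting quadrature points on each expanded sphere not occluded by any
# neighbour. The point lattice is a deterministic Fibonacci spiral, so
# results are exactly reproducible for a fixed n_points (no RNG).

# near-uniform deterministic unit-sphere lattice (golden-angle spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- (i - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Computes per-atom, per-residue and total SASA for the heavy atoms of a
#' structure. Waters are excluded by default; ligands optionally. Radii are
#' element-based van der Waals radii (Bondi set) and can be overridden.
#'
#' @param s structure3d.
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points quadrature points per atom sphere (default 960).
#' @param radii named numeric vector of van der Waals radii by element
#'   symbol (default: built-in Bondi set).
#' @param include_waters include water atoms (default FALSE).
#' @param include_ligands include ligand/other atoms (default FALSE).
#' @param default_radius radius used for elements missing from \code{radii};
#'   \code{NULL} (default) makes an unknown element an error.
#' @return object of class \code{sasa_result}: list with \code{per_atom}
#'   (named by atom key "chain|resno|insert|name"), \code{per_residue}
#'   (named by residue key "chain:resno"), \code{total}, \code{probe_radius},
#'   \code{n_sphere_points}.
#' @export
compute_sasa <- function(s, probe = 1.4, n_points = 960, radii = VDW_RADII,
                         include_waters = FALSE, include_ligands = FALSE,
                         default_radius = NULL) {
  a <- s$atom
  keep <- !(a$elesy %in% c("H", "D"))
  if (!include_waters) keep <- keep & a$polymer != "water"
  if (!include_ligands) keep <- keep & !(a$polymer %in% c("ligand", "other"))
  a <- a[keep, , drop = FALSE]
  if (nrow(a) == 0L) stop("no atoms left for SASA computation")

  r <- unname(radii[a$elesy])
  if (any(is.na(r))) {
    if (is.null(default_radius)) {
      stop("no van der Waals radius for element(s): ",
           paste(unique(a$elesy[is.na(r)]), collapse = ", "),
           " (set default_radius to proceed)")
    }
    r[is.na(r)] <- default_radius
  }

  xyz <- as.matrix(a[, c("x", "y", "z")])
  n <- nrow(xyz)
  R <- r + probe                      # expanded radii
  pts <- fibonacci_sphere(n_points)
  Rmax <- max(R)

  # coarse spatial binning for neighbour lists
  cellw <- 2 * Rmax
  bin <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cellw)
  binkey <- bin[, 1] * 1e6 + bin[, 2] * 1e3 + bin[, 3]
  bins <- split(seq_len(n), binkey)
  binpos <- do.call(rbind, lapply(names(bins), function(k) {
    i <- bins[[k]][1L]
    bin[i, ]
  }))

  neighbour_cache <- lapply(seq_along(bins), function(bi) {
    near <- which(abs(binpos[, 1] - binpos[bi, 1]) <= 1 &
                  abs(binpos[, 2] - binpos[bi, 2]) <= 1 &
                  abs(binpos[, 3] - binpos[bi, 3]) <= 1)
    unlist(bins[near], use.names = FALSE)
  })
  atom_bin <- integer(n)
  for (bi in seq_along(bins)) atom_bin[bins[[bi]]] <- bi

  area <- numeric(n)
  for (i in seq_len(n)) {
    cand <- neighbour_cache[[atom_bin[i]]]
    cand <- cand[cand != i]
    if (length(cand) > 0L) {
      d2 <- rowSums(sweep(xyz[cand, , drop = FALSE], 2, xyz[i, ])^2)
      cand <- cand[d2 < (R[i] + R[cand])^2]
    }
    if (length(cand) == 0L) {
      area[i] <- 4 * pi * R[i]^2
      next
    }
    p <- sweep(pts * R[i], 2, xyz[i, ], `+`)     # points on sphere i
    acc <- rep(TRUE, n_points)
    # nearest occluders first prunes fastest
    d2 <- rowSums(sweep(xyz[cand, , drop = FALSE], 2, xyz[i, ])^2)
    for (j in cand[order(d2)]) {
      idx <- which(acc)
      if (length(idx) == 0L) break
      dj2 <- (p[idx, 1] - xyz[j, 1])^2 + (p[idx, 2] - xyz[j, 2])^2 +
             (p[idx, 3] - xyz[j, 3])^2
      acc[idx[dj2 < R[j]^2]] <- FALSE
    }
    area[i] <- 4 * pi * R[i]^2 * sum(acc) / n_points
  }

  per_atom <- stats::setNames(area, atom_key(a))
  rk <- res_key(a)
  per_residue <- tapply(area, rk, sum)
  per_residue <- stats::setNames(as.numeric(per_residue), names(per_residue))
  out <- list(per_atom = per_atom, per_residue = per_residue,
              total = sum(area), probe_radius = probe,
              n_sphere_points = n_points)
  class(out) <- "sasa_result"
  out
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("SASA: %.1f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total, length(x$per_atom), x$probe_radius,
              x$n_sphere_points))
  invisible(x)
}
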