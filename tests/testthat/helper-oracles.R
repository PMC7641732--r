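# Shared fixtures and independent oracles used across the test files.

fibonacci_sphere_test <- function(n) aptaface:::fibonacci_sphere(n)

# minimal one-atom structure row
atom_df <- function(elety, resid, chain, resno, x, y, z,
                    elesy = substr(elety, 1, 1), type = "ATOM") {
  data.frame(type = type, eleno = 0L, elety = elety, alt = "",
             resid = resid, chain = chain, resno = resno, insert = "",
             x = x, y = y, z = z, o = 1, b = 0, elesy = elesy,
             stringsAsFactors = FALSE)
}

make_structure <- function(id, ...) {
  rows <- do.call(rbind, list(...))
  rows$eleno <- seq_len(nrow(rows))
  structure3d(id, rows)
}

# hexagonal aromatic ring (PHE naming) with a given centre and unit normal
hexagon_residue <- function(center, normal, chain, resno, radius = 1.39) {
  normal <- normal / sqrt(sum(normal^2))
  e1 <- if (abs(normal[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- e1 - sum(e1 * normal) * normal
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(normal[2] * e1[3] - normal[3] * e1[2],
          normal[3] * e1[1] - normal[1] * e1[3],
          normal[1] * e1[2] - normal[2] * e1[1])
  nm <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  ang <- seq(0, 300, by = 60) * pi / 180
  rows <- do.call(rbind, lapply(seq_along(ang), function(i) {
    p <- center + radius * (cos(ang[i]) * e1 + sin(ang[i]) * e2)
    atom_df(nm[i], "PHE", chain, resno, p[1], p[2], p[3], "C")
  }))
  rows
}

# random proper rotation from a seed
random_rotation <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  th <- runif(1, 0.3, 2.8)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# independent brute-force minimum RMSD over rotations: coarse Euler grid
# followed by Nelder-Mead refinement (no SVD anywhere)
brute_force_rmsd <- function(mobile, reference) {
  M <- sweep(mobile, 2, colMeans(mobile))
  Rf <- sweep(reference, 2, colMeans(reference))
  euler <- function(p) {
    ca <- cos(p[1]); sa <- sin(p[1])
    cb <- cos(p[2]); sb <- sin(p[2])
    cg <- cos(p[3]); sg <- sin(p[3])
    Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
    Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  fcost <- function(p) sqrt(mean(rowSums((M %*% t(euler(p)) - Rf)^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  gridb <- seq(0, pi, length.out = 7)
  best <- NULL; bestv <- Inf
  for (a in grid) for (b in gridb) for (g in grid) {
    v <- fcost(c(a, b, g))
    if (v < bestv) { bestv <- v; best <- c(a, b, g) }
  }
  o <- stats::optim(best, fcost, method = "Nelder-Mead",
                    control = list(maxit = 2000, reltol = 1e-14))
  o$value
}

# independent neighbour-count clustering oracle: naive re-count of
# neighbours from scratch at every extraction step
oracle_clustering <- function(rmsd_mat, model_ids, threshold,
                              max_clusters = Inf) {
  k <- nrow(rmsd_mat)
  unassigned <- rep(TRUE, k)
  clusters <- list()
  while (any(unassigned) && length(clusters) < max_clusters) {
    best <- NA; best_n <- -1
    for (i in which(unassigned)) {
      n_i <- 0L
      for (j in which(unassigned)) {
        if (j != i && rmsd_mat[i, j] < threshold) n_i <- n_i + 1L
      }
      if (n_i > best_n ||
          (n_i == best_n && model_ids[i] < model_ids[best])) {
        best <- i; best_n <- n_i
      }
    }
    members <- best
    for (j in which(unassigned)) {
      if (j != best && rmsd_mat[best, j] < threshold) {
        members <- c(members, j)
      }
    }
    clusters[[length(clusters) + 1L]] <- sort(members)
    unassigned[members] <- FALSE
  }
  clusters
}

# reference SASA total via biotite (independent implementation), same
# element radii; returns the summed per-atom SASA
biotite_sasa_total <- function(s, n_points = 960) {
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  write_structure(s, tmp)
  py <- sprintf(paste0(
    "import biotite.structure.io.pdb as pdb\n",
    "import biotite.structure as struc\n",
    "import numpy as np\n",
    "f = pdb.PDBFile.read(%s)\n",
    "arr = f.get_structure(model=1)\n",
    "radii = {'C':1.70,'N':1.55,'O':1.52,'P':1.80,'S':1.80,'F':1.47,",
    "'H':1.20}\n",
    "vr = np.array([radii[e] for e in arr.element])\n",
    "sasa = struc.sasa(arr, probe_radius=1.4, point_number=%d, ",
    "vdw_radii=vr)\n",
    "print(float(np.nansum(sasa)))\n"), shQuote(tmp), n_points)
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE,
                 stderr = FALSE)
  as.numeric(out[length(out)])
}

# partition identity of an rna_ss object: every nucleotide in exactly one
# of stems / loops / unassigned
ss_partition_ok <- function(ss) {
  n <- length(ss$residues)
  count <- integer(n)
  for (st in ss$stems) count[c(st$pos_i, st$pos_j)] <-
    count[c(st$pos_i, st$pos_j)] + 1L
  for (lp in ss$loops) count[lp$members] <- count[lp$members] + 1L
  count[match(ss$unassigned, ss$residues)] <-
    count[match(ss$unassigned, ss$residues)] + 1L
  all(count == 1L)
}
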