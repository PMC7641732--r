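# RNA base-pair detection and secondary-structure annotation from 3D
# coordinates. Pairs are screened geometrically (base-centroid distance,
# inter-plane angle, an in-plane inter-base hydrogen bond) and classified by
# the Leontis-Westhof scheme: the interacting edge of each base
# (Watson-Crick / Hoogsteen / Sugar) and the glycosidic-bond orientation
# (cis / trans).

# edge atom groups per base (the polar atoms presenting each edge)
LW_EDGES <- list(
  A = list(WC = c("N1", "C2", "N6"), Hoogsteen = c("N7", "N6", "C8"),
           Sugar = c("N3", "C2", "O2'")),
  G = list(WC = c("N1", "N2", "O6"), Hoogsteen = c("N7", "O6", "C8"),
           Sugar = c("N3", "N2", "O2'")),
  C = list(WC = c("N3", "N4", "O2"), Hoogsteen = c("N4", "C5", "C6"),
           Sugar = c("O2", "O2'")),
  U = list(WC = c("N3", "O4", "O2"), Hoogsteen = c("O4", "C5", "C6"),
           Sugar = c("O2", "O2'"))
)
LW_EDGES$T <- LW_EDGES$U

# polar edge atoms capable of hydrogen bonding, per base
BASE_POLAR_ATOMS <- list(
  A = c("N1", "N3", "N6", "N7"),
  G = c("N1", "N2", "N3", "O6", "N7"),
  C = c("O2", "N3", "N4"),
  U = c("O2", "N3", "O4"),
  T = c("O2", "N3", "O4")
)

COMPLEMENT <- c(A = "U", U = "A", G = "C", C = "G", T = "A")

glycosidic_n <- function(parent_base) {
  ifelse(parent_base %in% c("A", "G"), "N9", "N1")
}

#' Detect base pairs in an RNA chain
#'
#' Geometric screening (base-centroid distance <= \code{centroid_max},
#' inter-plane angle <= \code{angle_max}, at least one inter-base polar
#' contact in the hydrogen-bond window whose direction lies roughly in the
#' base planes) followed by Leontis-Westhof edge and orientation
#' assignment. A pair is canonical when both edges are Watson-Crick, the
#' orientation is cis and the bases are complementary (A-U, G-C, and G-U
#' wobble when \code{wobble_canonical}).
#'
#' @param s structure3d.
#' @param chain RNA chain id.
#' @param centroid_max base-centroid screen (A, default 12).
#' @param angle_max inter-plane angle screen (degrees, default 40).
#' @param dmax,dmin inter-base hydrogen-bond window (A).
#' @param stagger_max maximum centroid offset along the mean base normal
#'   (A, default 2.0); separates coplanar pairing from stacking geometry.
#' @param in_plane_min minimum angle between an inter-base contact vector
#'   and the base normals (degrees, default 50); rejects
#'   stacked-neighbour polar contacts.
#' @param wobble_canonical count G-U wobble pairs as canonical
#'   (default TRUE).
#' @return data.frame, one row per pair (i-position < j-position):
#'   res_i, res_j (residue keys), pos_i, pos_j (1-based chain positions),
#'   base_i, base_j, edge_i, edge_j, orientation, canonical, n_hbonds.
#' @export
detect_base_pairs <- function(s, chain, centroid_max = 12, angle_max = 40,
                              dmax = 3.5, dmin = 2.4, stagger_max = 2.0,
                              in_plane_min = 50,
                              wobble_canonical = TRUE) {
  atom <- s$atom[s$atom$chain == chain, , drop = FALSE]
  if (nrow(atom) == 0L) stop("no atoms in chain ", chain)
  if (!all(atom$polymer %in% c("rna", "dna"))) {
    stop("chain ", chain, " is not a nucleic-acid chain")
  }
  res <- residue_table(atom)
  res <- res[!is.na(res$parent_base), , drop = FALSE]
  n <- nrow(res)
  empty <- data.frame(res_i = character(), res_j = character(),
                      pos_i = integer(), pos_j = integer(),
                      base_i = character(), base_j = character(),
                      edge_i = character(), edge_j = character(),
                      orientation = character(), canonical = logical(),
                      n_hbonds = integer(), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)

  rk_all <- res_key(atom)
  planes <- vector("list", n)
  for (i in seq_len(n)) {
    planes[[i]] <- tryCatch(
      base_plane(atom[rk_all == res$res_key[i], , drop = FALSE]),
      error = function(e) NULL)
  }
  centroids <- t(vapply(planes, function(p)
    if (is.null(p)) c(NA, NA, NA) else p$centroid, numeric(3)))

  rows <- list()
  for (i in seq_len(n - 1L)) {
    if (is.null(planes[[i]])) next
    for (j in (i + 1L):n) {
      if (is.null(planes[[j]])) next
      d <- centroids[j, ] - centroids[i, ]
      if (sqrt(sum(d^2)) > centroid_max) next
      ang <- plane_angle_deg(planes[[i]]$normal, planes[[j]]$normal)
      if (ang > angle_max) next
      if (pair_stagger(planes[[i]], planes[[j]]) > stagger_max) next
      hb <- interbase_hbonds(atom, rk_all, res, i, j, planes, dmax, dmin,
                             in_plane_min = in_plane_min)
      if (nrow(hb) == 0L) next
      lw <- lw_classify(atom, rk_all, res, i, j, hb)
      canonical <- lw$edge_i == "WC" && lw$edge_j == "WC" &&
        lw$orientation == "cis" &&
        is_complementary(res$parent_base[i], res$parent_base[j],
                         wobble_canonical)
      rows[[length(rows) + 1L]] <- data.frame(
        res_i = res$res_key[i], res_j = res$res_key[j],
        pos_i = i, pos_j = j,
        base_i = res$parent_base[i], base_j = res$parent_base[j],
        edge_i = lw$edge_i, edge_j = lw$edge_j,
        orientation = lw$orientation, canonical = canonical,
        n_hbonds = nrow(hb), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

is_complementary <- function(b1, b2, wobble = TRUE) {
  pair <- paste(sort(c(b1, b2)), collapse = "")
  pair %in% c("AU", "CG", "AT", if (wobble) "GU")
}

# centroid offset along the (sign-aligned) mean normal: ~0 for coplanar
# pairing, ~one rise (3 A) for stacking
pair_stagger <- function(pl_i, pl_j) {
  nb <- if (sum(pl_i$normal * pl_j$normal) < 0) -pl_j$normal else
    pl_j$normal
  nm <- pl_i$normal + nb
  nm <- nm / sqrt(sum(nm^2))
  abs(sum((pl_j$centroid - pl_i$centroid) * nm))
}

# inter-base polar contacts whose connecting vector lies roughly in both
# base planes (angle to the normals >= in_plane_min), which excludes
# stacked-neighbour artefacts
interbase_hbonds <- function(atom, rk_all, res, i, j, planes, dmax, dmin,
                             in_plane_min = 50) {
  ai <- atom[rk_all == res$res_key[i], , drop = FALSE]
  aj <- atom[rk_all == res$res_key[j], , drop = FALSE]
  pi_ <- ai[ai$elety %in% BASE_POLAR_ATOMS[[res$parent_base[i]]], ,
            drop = FALSE]
  pj <- aj[aj$elety %in% BASE_POLAR_ATOMS[[res$parent_base[j]]], ,
           drop = FALSE]
  # the sugar edge also presents the 2'-hydroxyl / O2
  pi_ <- rbind(pi_, ai[ai$elety %in% c("O2'"), , drop = FALSE])
  pj <- rbind(pj, aj[aj$elety %in% c("O2'"), , drop = FALSE])
  out <- data.frame(atom_i = character(), atom_j = character(),
                    distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(pi_) == 0L || nrow(pj) == 0L) return(out)
  dmat <- cross_dist(as.matrix(pi_[, c("x", "y", "z")]),
                     as.matrix(pj[, c("x", "y", "z")]))
  hits <- which(dmat >= dmin & dmat <= dmax, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(out)
  keep <- logical(nrow(hits))
  for (h in seq_len(nrow(hits))) {
    v <- as.numeric(pj[hits[h, 2], c("x", "y", "z")]) -
      as.numeric(pi_[hits[h, 1], c("x", "y", "z")])
    angs <- c(90 - plane_angle_deg(v, planes[[i]]$normal),
              90 - plane_angle_deg(v, planes[[j]]$normal))
    # plane_angle_deg folds to [0,90]; angle to the plane = 90 - (to normal)
    keep[h] <- all((90 - angs) >= in_plane_min)
  }
  hits <- hits[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(out)
  data.frame(atom_i = pi_$elety[hits[, 1]], atom_j = pj$elety[hits[, 2]],
             distance = dmat[cbind(hits[, 1], hits[, 2])],
             stringsAsFactors = FALSE)
}

# Leontis-Westhof edge + orientation for one candidate pair
lw_classify <- function(atom, rk_all, res, i, j, hb) {
  edge_for <- function(base, atoms) {
    tab <- LW_EDGES[[base]]
    score <- vapply(names(tab), function(e) sum(atoms %in% tab[[e]]), 0L)
    # ties resolved WC > Hoogsteen > Sugar (list order)
    names(tab)[which.max(score)]
  }
  edge_i <- edge_for(res$parent_base[i], hb$atom_i)
  edge_j <- edge_for(res$parent_base[j], hb$atom_j)

  gi <- glycosidic_n(res$parent_base[i])
  gj <- glycosidic_n(res$parent_base[j])
  ai <- atom[rk_all == res$res_key[i], , drop = FALSE]
  aj <- atom[rk_all == res$res_key[j], , drop = FALSE]
  ni <- as.numeric(ai[ai$elety == gi, c("x", "y", "z")][1, ])
  nj <- as.numeric(aj[aj$elety == gj, c("x", "y", "z")][1, ])
  c1i <- as.numeric(ai[ai$elety %in% c("C1'", "C1*"), c("x", "y", "z")][1, ])
  c1j <- as.numeric(aj[aj$elety %in% c("C1'", "C1*"), c("x", "y", "z")][1, ])
  ring_i <- ai[ai$elety %in% BASE_RING_ATOMS[[res$parent_base[i]]], ,
               drop = FALSE]
  ring_j <- aj[aj$elety %in% BASE_RING_ATOMS[[res$parent_base[j]]], ,
               drop = FALSE]
  orientation <- "cis"
  if (all(is.finite(c(ni, nj, c1i, c1j)))) {
    # pair axis between the glycosidic nitrogens; side vectors from the
    # ring centroids to C1' (long, hence robust to coordinate noise): in a
    # cis pair both sugars lie on the same side of the axis
    axis <- nj - ni
    axis <- axis / sqrt(sum(axis^2))
    ci <- colMeans(as.matrix(ring_i[, c("x", "y", "z")]))
    cj <- colMeans(as.matrix(ring_j[, c("x", "y", "z")]))
    vi <- (c1i - ci) - sum((c1i - ci) * axis) * axis
    vj <- (c1j - cj) - sum((c1j - cj) * axis) * axis
    orientation <- if (sum(vi * vj) >= 0) "cis" else "trans"
  }
  list(edge_i = edge_i, edge_j = edge_j, orientation = orientation)
}

#' Derive secondary structure from a base-pair list
#'
#' Builds stems (maximal antiparallel runs of consecutive pairs; an
#' isolated noncanonical pair sandwiched between canonical ones is absorbed
#' into its stem), classifies loops (hairpin / internal / bulge) from the
#' gap topology between stems, and emits a dot-bracket string (bracket
#' tiers for pseudoknots). Loop nucleotides are the unpaired residues
#' between stem boundary pairs; closing pairs belong to the stem.
#'
#' @param pairs data.frame from \code{\link{detect_base_pairs}}.
#' @param s structure3d (for the chain's residue order).
#' @param chain chain id.
#' @return object of class \code{rna_ss}: \code{stems} (list of pair
#'   data.frames), \code{loops} (list of \code{list(kind, members)}),
#'   \code{flipped_out} (empty; see \code{\link{detect_flipped_out}}),
#'   \code{unassigned}, \code{dotbracket}, \code{pseudoknot},
#'   \code{residues} (keys in chain order), \code{paired_pos}.
#' @export
derive_secondary_structure <- function(pairs, s, chain) {
  atom <- s$atom[s$atom$chain == chain, , drop = FALSE]
  res <- residue_table(atom)
  res <- res[!is.na(res$parent_base), , drop = FALSE]
  n <- nrow(res)

  # nesting-compatible pairing map from canonical pairs (first-come on
  # conflicts), then absorb sandwiched noncanonical pairs
  pmate <- rep(NA_integer_, n)
  cp <- pairs[pairs$canonical, , drop = FALSE]
  if (nrow(cp) > 0L) {
    cp <- cp[order(cp$pos_i), , drop = FALSE]
    for (r in seq_len(nrow(cp))) {
      i <- cp$pos_i[r]; j <- cp$pos_j[r]
      if (is.na(pmate[i]) && is.na(pmate[j])) {
        pmate[i] <- j; pmate[j] <- i
      }
    }
  }
  ncp <- pairs[!pairs$canonical, , drop = FALSE]
  if (nrow(ncp) > 0L) {
    for (r in seq_len(nrow(ncp))) {
      i <- ncp$pos_i[r]; j <- ncp$pos_j[r]
      if (i > 1L && j < n && !is.na(pmate[i - 1L]) &&
          pmate[i - 1L] == j + 1L &&
          !is.na(pmate[i + 1L]) && pmate[i + 1L] == j - 1L &&
          is.na(pmate[i]) && is.na(pmate[j])) {
        pmate[i] <- j; pmate[j] <- i
      }
    }
  }

  # stems: maximal runs of consecutive nested pairs
  stems <- list()
  i <- 1L
  while (i <= n) {
    j <- pmate[i]
    if (!is.na(j) && j > i) {
      run_i <- i
      while (i + 1L <= n && !is.na(pmate[i + 1L]) &&
             pmate[i + 1L] == pmate[i] - 1L && pmate[i + 1L] > i + 1L) {
        i <- i + 1L
      }
      stems[[length(stems) + 1L]] <- data.frame(
        pos_i = run_i:i, pos_j = pmate[run_i:i])
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(stems) >= 2L) {
    stems <- stems[order(vapply(stems, function(st) st$pos_i[1], 0))]
  }

  in_stem <- rep(FALSE, n)
  for (st in stems) in_stem[c(st$pos_i, st$pos_j)] <- TRUE

  # loop classification from stem gap topology
  loops <- list()
  claimed <- rep(FALSE, n)
  claimed[in_stem] <- TRUE
  for (st in stems) {
    ii <- st$pos_i[nrow(st)]   # innermost pair of this stem
    jj <- st$pos_j[nrow(st)]
    inner <- if (ii + 1L <= jj - 1L) (ii + 1L):(jj - 1L) else integer()
    if (length(inner) > 0L && !any(in_stem[inner])) {
      loops[[length(loops) + 1L]] <- list(kind = "hairpin", members = inner)
      claimed[inner] <- TRUE
    } else if (length(inner) > 0L) {
      # directly nested stem: internal loop or bulge
      inner_stems <- Filter(function(s2) s2$pos_i[1] > ii &&
                              s2$pos_j[1] < jj, stems)
      if (length(inner_stems) > 0L) {
        first_inner <- inner_stems[[which.min(vapply(inner_stems,
          function(s2) s2$pos_i[1], 0))]]
        k <- first_inner$pos_i[1]; l <- first_inner$pos_j[1]
        left <- if (ii + 1L <= k - 1L) (ii + 1L):(k - 1L) else integer()
        right <- if (l + 1L <= jj - 1L) (l + 1L):(jj - 1L) else integer()
        memb <- c(left, right)
        memb <- memb[!claimed[memb]]
        if (length(memb) > 0L) {
          kind <- if (length(left) > 0L && length(right) > 0L) "internal"
            else "bulge"
          loops[[length(loops) + 1L]] <- list(kind = kind, members = memb)
          claimed[memb] <- TRUE
        }
      }
    }
  }
  unassigned <- which(!claimed)

  db <- dot_bracket(pairs, n)

  out <- list(
    stems = stems, loops = loops,
    flipped_out = character(),
    unassigned = res$res_key[unassigned],
    dotbracket = db$string, pseudoknot = db$pseudoknot,
    residues = res$res_key, paired_pos = pmate, chain = chain
  )
  class(out) <- "rna_ss"
  out
}

# dot-bracket with bracket tiers for crossing (pseudoknotted) pairs
dot_bracket <- function(pairs, n) {
  open <- c("(", "[", "{", "<")
  close <- c(")", "]", "}", ">")
  s <- rep(".", n)
  tiers <- list()
  pk <- FALSE
  if (nrow(pairs) > 0L) {
    use <- pairs[pairs$canonical | TRUE, , drop = FALSE]  # all pairs drawn
    use <- use[order(use$pos_i), , drop = FALSE]
    taken <- rep(FALSE, n)
    for (r in seq_len(nrow(use))) {
      i <- use$pos_i[r]; j <- use$pos_j[r]
      if (taken[i] || taken[j]) next
      placed <- FALSE
      for (tnum in seq_len(4L)) {
        if (length(tiers) < tnum) tiers[[tnum]] <- matrix(0, 0, 2)
        tr <- tiers[[tnum]]
        crossing <- any((tr[, 1] < i & i < tr[, 2] & tr[, 2] < j) |
                          (i < tr[, 1] & tr[, 1] < j & j < tr[, 2]))
        if (!crossing) {
          tiers[[tnum]] <- rbind(tr, c(i, j))
          s[i] <- open[tnum]; s[j] <- close[tnum]
          taken[i] <- TRUE; taken[j] <- TRUE
          if (tnum > 1L) pk <- TRUE
          placed <- TRUE
          break
        }
      }
      if (!placed) pk <- TRUE
    }
  }
  list(string = paste(s, collapse = ""), pseudoknot = pk)
}

#' @export
print.rna_ss <- function(x, ...) {
  cat("RNA secondary structure (chain ", x$chain, "): ",
      length(x$stems), " stem(s), ", length(x$loops), " loop(s)\n",
      sep = "")
  for (st in x$stems) {
    cat("  stem: ", nrow(st), " bp (", x$residues[st$pos_i[1]], "..",
        x$residues[st$pos_i[nrow(st)]], " / ",
        x$residues[st$pos_j[nrow(st)]], "..", x$residues[st$pos_j[1]],
        ")\n", sep = "")
  }
  for (lp in x$loops) {
    cat("  ", lp$kind, " loop: ", length(lp$members), " nt\n", sep = "")
  }
  if (length(x$flipped_out) > 0L) {
    cat("  flipped out:", paste(x$flipped_out, collapse = ", "), "\n")
  }
  cat("  ", x$dotbracket, "\n", sep = "")
  invisible(x)
}

# residue key -> region ("helix" for stem members, "loop", "n/a")
ss_region_map <- function(ss) {
  n <- length(ss$residues)
  region <- rep("n/a", n)
  for (st in ss$stems) region[c(st$pos_i, st$pos_j)] <- "helix"
  for (lp in ss$loops) region[lp$members] <- "loop"
  # unassigned single-stranded stretches count as loops for interface
  # statistics only if flagged; keep "n/a"
  stats::setNames(region, ss$residues)
}

#' Detect flipped-out (extruded) bases
#'
#' A nucleotide is flipped out when it is unpaired, its base centroid lies
#' farther from the local helical axis than the mean paired-base centroid
#' distance plus \code{margin}, and it stacks on neither of its sequence
#' neighbours. The local axis is fitted through the C1' atoms of the
#' nearest \code{axis_window} stem pairs on each side; for a chain with no
#' stems every unpaired base is evaluated against the global C1' centroid
#' (with a warning).
#'
#' @param s structure3d.
#' @param chain chain id.
#' @param ss \code{rna_ss} for that chain.
#' @param axis_window stem pairs used on each side for the axis fit.
#' @param margin added to the mean paired-base axis distance (A).
#' @return character vector of flipped-out residue keys.
#' @export
detect_flipped_out <- function(s, chain, ss, axis_window = 2,
                               margin = 2.5) {
  atom <- s$atom[s$atom$chain == chain, , drop = FALSE]
  res <- residue_table(atom)
  res <- res[!is.na(res$parent_base), , drop = FALSE]
  n <- nrow(res)
  rk_all <- res_key(atom)

  centroid_of <- function(p) {
    pl <- tryCatch(base_plane(atom[rk_all == res$res_key[p], , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(pl)) return(rep(NA_real_, 3))
    pl$centroid
  }
  c1_of <- function(p) {
    a <- atom[rk_all == res$res_key[p] &
                atom$elety %in% c("C1'", "C1*"), , drop = FALSE]
    if (nrow(a) == 0L) return(rep(NA_real_, 3))
    as.numeric(a[1, c("x", "y", "z")])
  }

  paired <- !is.na(ss$paired_pos)
  stem_pairs <- do.call(rbind, lapply(ss$stems, function(st)
    cbind(st$pos_i, st$pos_j)))
  has_stems <- !is.null(stem_pairs) && nrow(stem_pairs) > 0L

  flipped <- character()
  unpaired <- which(!paired)
  if (length(unpaired) == 0L) return(flipped)
  if (!has_stems) {
    warning("chain ", chain, " has no stems; using the global C1' centroid")
    allc1 <- t(vapply(seq_len(n), c1_of, numeric(3)))
    gc <- colMeans(allc1, na.rm = TRUE)
    for (u in unpaired) {
      bc <- centroid_of(u)
      if (any(is.na(bc))) next
      d_u <- sqrt(sum((bc - gc)^2))
      ref <- mean(vapply(which(paired), function(p) {
        b <- centroid_of(p); sqrt(sum((b - gc)^2))
      }, 0), na.rm = TRUE)
      if (!is.finite(ref)) ref <- 0
      if (d_u > ref + margin && !stacks_on_neighbour(atom, rk_all, res, u)) {
        flipped <- c(flipped, res$res_key[u])
      }
    }
    return(flipped)
  }

  for (u in unpaired) {
    # nearest stem pairs by sequence distance, on each side
    d_seq <- pmin(abs(stem_pairs[, 1] - u), abs(stem_pairs[, 2] - u))
    before <- which(stem_pairs[, 1] < u | stem_pairs[, 2] < u)
    after <- which(stem_pairs[, 1] > u | stem_pairs[, 2] > u)
    pick <- function(side) {
      if (length(side) == 0L) return(integer())
      side[order(d_seq[side])][seq_len(min(axis_window, length(side)))]
    }
    sel <- unique(c(pick(before), pick(after)))
    if (length(sel) == 0L) next
    # one axis point per stem pair: the midpoint of the partners' base
    # ring centroids, which lies close to the helical axis (the C1'-C1'
    # midpoint does not: it is displaced toward the minor groove)
    pts <- do.call(rbind, lapply(sel, function(r) {
      p1 <- centroid_of(stem_pairs[r, 1]); p2 <- centroid_of(stem_pairs[r, 2])
      (p1 + p2) / 2
    }))
    pts <- pts[stats::complete.cases(pts), , drop = FALSE]
    if (nrow(pts) < 1L) next
    ctr <- colMeans(pts)
    axis <- if (nrow(pts) >= 3L) {
      sv <- svd(sweep(pts, 2, ctr))
      sv$v[, 1]
    } else {
      # too few axis points for a stable line fit: base planes are
      # perpendicular to the helix axis, so use the sign-aligned mean
      # base normal of the selected stem pairs as the direction
      normals <- list()
      for (r in sel) {
        for (p in stem_pairs[r, ]) {
          pl <- tryCatch(base_plane(atom[rk_all == res$res_key[p], ,
                                         drop = FALSE]),
                         error = function(e) NULL)
          if (!is.null(pl)) normals[[length(normals) + 1L]] <- pl$normal
        }
      }
      if (length(normals) == 0L) next
      ref_n <- normals[[1L]]
      nsum <- Reduce(`+`, lapply(normals, function(nv)
        if (sum(nv * ref_n) < 0) -nv else nv))
      nsum / sqrt(sum(nsum^2))
    }
    dist_axis <- function(x) {
      v <- x - ctr
      sqrt(max(0, sum(v^2) - sum(v * axis)^2))
    }
    bc <- centroid_of(u)
    if (any(is.na(bc))) next
    ref <- mean(vapply(sel, function(r) {
      mean(c(dist_axis(centroid_of(stem_pairs[r, 1])),
             dist_axis(centroid_of(stem_pairs[r, 2]))), na.rm = TRUE)
    }, 0), na.rm = TRUE)
    if (dist_axis(bc) > ref + margin &&
        !stacks_on_neighbour(atom, rk_all, res, u)) {
      flipped <- c(flipped, res$res_key[u])
    }
  }
  flipped
}

# does base at position u stack on either sequence neighbour?
stacks_on_neighbour <- function(atom, rk_all, res, u, centroid_max = 5.5,
                                angle_max = 30, offset_max = 2.5) {
  n <- nrow(res)
  pl_u <- tryCatch(base_plane(atom[rk_all == res$res_key[u], , drop = FALSE]),
                   error = function(e) NULL)
  if (is.null(pl_u)) return(FALSE)
  for (v in c(u - 1L, u + 1L)) {
    if (v < 1L || v > n) next
    pl_v <- tryCatch(base_plane(atom[rk_all == res$res_key[v], ,
                                     drop = FALSE]),
                     error = function(e) NULL)
    if (is.null(pl_v)) next
    d <- pl_v$centroid - pl_u$centroid
    cd <- sqrt(sum(d^2))
    if (cd > centroid_max) next
    if (plane_angle_deg(pl_u$normal, pl_v$normal) > angle_max) next
    nb <- if (sum(pl_u$normal * pl_v$normal) < 0) -pl_v$normal else
      pl_v$normal
    nm <- pl_u$normal + nb
    nm <- nm / sqrt(sum(nm^2))
    offset <- sqrt(max(0, sum(d^2) - sum(d * nm)^2))
    if (offset <= offset_max) return(TRUE)
  }
  FALSE
}

#' Full RNA annotation of one chain
#'
#' Convenience wrapper: base pairs, secondary structure, flipped-out bases.
#'
#' @param s structure3d.
#' @param chain RNA chain id.
#' @param ... passed to \code{\link{detect_base_pairs}}.
#' @return list with \code{pairs}, \code{ss} (with \code{flipped_out}
#'   filled in).
#' @export
annotate_rna <- function(s, chain, ...) {
  pairs <- detect_base_pairs(s, chain, ...)
  ss <- derive_secondary_structure(pairs, s, chain)
  ss$flipped_out <- detect_flipped_out(s, chain, ss)
  list(pairs = pairs, ss = ss)
}
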