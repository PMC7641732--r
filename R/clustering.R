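# Conformational-ensemble reduction by energy cutoff followed by
# neighbour-count centroid clustering: two members are neighbours when
# their pairwise RMSD (optionally after optimal superposition) is strictly
# below a threshold; the member with the most unassigned neighbours becomes
# the next cluster centroid, its neighbours its cluster, iterating over the
# remainder. Entirely deterministic.

#' Clustering configuration
#' @param energy_fraction fraction of lowest-energy members kept
#'   (default 0.10).
#' @param rmsd_threshold neighbour threshold in Angstrom (default 5.0;
#'   strict inequality).
#' @param max_clusters clusters extracted before remaining members are
#'   reported as singleton overflow (default 10; NULL = unlimited).
#' @param superpose superpose each member pair before the RMSD
#'   (default TRUE).
#' @return list of class \code{clustering_config}.
#' @export
clustering_config <- function(energy_fraction = 0.10, rmsd_threshold = 5.0,
                              max_clusters = 10, superpose = TRUE) {
  stopifnot(energy_fraction > 0, energy_fraction <= 1, rmsd_threshold > 0)
  out <- list(energy_fraction = energy_fraction,
              rmsd_threshold = rmsd_threshold,
              max_clusters = max_clusters, superpose = superpose)
  class(out) <- "clustering_config"
  out
}

#' Select the lowest-energy fraction of an ensemble
#'
#' Keeps the \code{ceiling(fraction * N)} members with the lowest energy;
#' ties at the cutoff are broken by the lower model index.
#'
#' @param e ensemble3d.
#' @param fraction in (0, 1].
#' @return integer vector of member positions (1-based, ascending).
#' @export
select_low_energy <- function(e, fraction = 0.10) {
  n <- length(e$coords)
  if (n == 0L) stop("empty ensemble")
  stopifnot(fraction > 0, fraction <= 1)
  m <- ceiling(fraction * n)
  ord <- order(e$energy, e$model_index)
  sort(ord[seq_len(m)])
}

# all-pairs RMSD over selected members
pairwise_rmsd_matrix <- function(e, sel, superpose_pairs = TRUE) {
  k <- length(sel)
  mat <- matrix(0, k, k)
  for (a in seq_len(k - 1L)) {
    xa <- e$coords[[sel[a]]]
    for (b in (a + 1L):k) {
      xb <- e$coords[[sel[b]]]
      r <- if (superpose_pairs) superpose(xb, xa)$rmsd else
        rmsd_coords(xa, xb)
      mat[a, b] <- r
      mat[b, a] <- r
    }
  }
  dimnames(mat) <- list(e$model_index[sel], e$model_index[sel])
  mat
}

#' Cluster a conformational ensemble by neighbour-count centroids
#'
#' Applies the energy filter, computes all-pairs RMSD over the selected
#' members, then repeatedly extracts the member with the largest number of
#' unassigned neighbours (RMSD strictly below the threshold; ties broken by
#' the lower model index) as a centroid, assigning the centroid plus its
#' unassigned neighbours to one cluster, until all members are assigned or
#' \code{max_clusters} is reached; leftovers are reported as singleton
#' overflow. A neighbour-free member forms a singleton cluster, so the
#' clusters partition the selection. Cluster sizes are non-increasing down
#' the ranking by construction.
#'
#' @param e ensemble3d.
#' @param cfg \code{\link{clustering_config}}.
#' @return list of class \code{cluster_result}: \code{clusters} (list of
#'   \code{list(centroid_model, centroid_pos, member_models, member_pos)}),
#'   \code{selected_pos}, \code{selected_models}, \code{pairwise_rmsd},
#'   \code{overflow_pos}, \code{config}.
#' @export
cluster_ensemble <- function(e, cfg = clustering_config()) {
  sel <- select_low_energy(e, cfg$energy_fraction)
  k <- length(sel)
  dims <- vapply(e$coords[sel], function(m) nrow(as.matrix(m)), 0L)
  if (length(unique(dims)) > 1L) stop("inconsistent member atom counts")
  rm_mat <- pairwise_rmsd_matrix(e, sel, cfg$superpose)
  thr <- cfg$rmsd_threshold

  neigh <- rm_mat < thr
  diag(neigh) <- FALSE            # a member is not its own neighbour
  unassigned <- rep(TRUE, k)
  model_ids <- e$model_index[sel]
  clusters <- list()
  max_c <- if (is.null(cfg$max_clusters)) Inf else cfg$max_clusters

  while (any(unassigned) && length(clusters) < max_c) {
    counts <- colSums(neigh & unassigned)      # unassigned neighbours
    counts[!unassigned] <- -1L
    best <- which(counts == max(counts))
    best <- best[which.min(model_ids[best])]   # tie: lower model index
    members <- which(unassigned & (neigh[, best] | seq_len(k) == best))
    clusters[[length(clusters) + 1L]] <- list(
      centroid_model = model_ids[best], centroid_pos = sel[best],
      member_models = model_ids[members], member_pos = sel[members])
    unassigned[members] <- FALSE
  }
  overflow <- sel[unassigned]

  out <- list(clusters = clusters, selected_pos = sel,
              selected_models = model_ids, pairwise_rmsd = rm_mat,
              overflow_pos = overflow, config = cfg)
  class(out) <- "cluster_result"
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$member_pos), 0L)
  cat(sprintf(
    "Ensemble clustering: %d selected members -> %d cluster(s)%s\n",
    length(x$selected_pos), length(x$clusters),
    if (length(x$overflow_pos) > 0L)
      sprintf(" + %d overflow singleton(s)", length(x$overflow_pos)) else ""))
  cat("  ranked sizes:", paste(sizes, collapse = ", "), "\n")
  cat("  centroid models:",
      paste(vapply(x$clusters, function(cl) cl$centroid_model, 0L),
            collapse = ", "), "\n")
  invisible(x)
}

#' Cluster sizes in ranked order
#' @param result cluster_result.
#' @return integer vector.
#' @export
cluster_sizes <- function(result) {
  vapply(result$clusters, function(cl) length(cl$member_pos), 0L)
}
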