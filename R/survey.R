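# Batch survey of protein-RNA complexes: per-complex interface, contact and
# RNA-annotation features, then aggregate statistics (mean hydrogen-bond
# counts, prevalence of helices, stem-loops, flipped-out bases, duplexes).

#' Analyse one protein-RNA complex
#'
#' Composes the interface report, direct + water-mediated hydrogen-bond
#' detection with categorisation, and RNA annotation into one per-complex
#' record. With several RNA chains, bonds are categorised against each
#' chain's secondary structure and annotation flags are ORed over chains.
#'
#' @param s structure3d.
#' @param protein_chains,rna_chains chain id vectors.
#' @param complex_id identifier (default: the structure id).
#' @param residue_criterion interface residue rule (see
#'   \code{\link{interface_report}}).
#' @param dmax hydrogen-bond distance cutoff (A).
#' @param n_points SASA quadrature points.
#' @return one-row data.frame (class \code{complex_record}): complex_id,
#'   n_hbonds_total, n_hbonds_nucleobase, n_hbonds_backbone, n_hbonds_loop,
#'   n_hbonds_helix, n_hbonds_direct, n_hbonds_water, has_helix,
#'   has_stem_loop, has_flipped_out, is_duplex, bsa_combined.
#' @export
analyze_complex <- function(s, protein_chains, rna_chains,
                            complex_id = s$id,
                            residue_criterion = "delta_sasa",
                            dmax = 3.5, n_points = 960) {
  have <- unique(s$atom$chain)
  if (!all(protein_chains %in% have) || !all(rna_chains %in% have)) {
    stop("complex ", complex_id, " lacks chains: ",
         paste(setdiff(c(protein_chains, rna_chains), have), collapse = ", "))
  }
  ir <- interface_report(s, protein_chains, rna_chains,
                         residue_criterion = residue_criterion,
                         n_points = n_points)
  direct <- find_hbonds(s, protein_chains, rna_chains, dmax = dmax)
  wb <- find_water_bridges(s, protein_chains, rna_chains, dmax = dmax)
  if (nrow(wb) > 0L) {
    wb <- wb[, names(direct), drop = FALSE]
  } else {
    wb <- direct[0, , drop = FALSE]
  }
  bonds <- rbind(direct, wb)

  has_helix <- FALSE; has_stem_loop <- FALSE
  has_flipped <- FALSE; is_duplex <- FALSE
  loop_n <- 0L; helix_n <- 0L
  for (ch in rna_chains) {
    ann <- annotate_rna(s, ch)
    ss <- ann$ss
    has_helix <- has_helix || length(ss$stems) > 0L
    has_stem_loop <- has_stem_loop ||
      any(vapply(ss$loops, function(l) l$kind == "hairpin", TRUE))
    has_flipped <- has_flipped || length(ss$flipped_out) > 0L
    is_duplex <- is_duplex || any(ann$pairs$canonical)
    mine <- bonds$nucleic_res %in% stats::setNames(
      nm = res_key(s$atom[s$atom$chain == ch, , drop = FALSE]))
    if (any(mine)) {
      br <- categorize_hbonds(bonds[mine, , drop = FALSE], ss)
      loop_n <- loop_n + br$loop
      helix_n <- helix_n + br$helix
    }
  }

  direct_nuc <- direct$nucleic_part
  rec <- data.frame(
    complex_id = complex_id,
    n_hbonds_total = nrow(bonds),
    n_hbonds_nucleobase = sum(direct_nuc %in% "nucleobase"),
    n_hbonds_backbone = sum(direct_nuc %in% c("backbone", "ribose")),
    n_hbonds_loop = loop_n,
    n_hbonds_helix = helix_n,
    n_hbonds_direct = nrow(direct),
    n_hbonds_water = nrow(wb),
    has_helix = has_helix, has_stem_loop = has_stem_loop,
    has_flipped_out = has_flipped, is_duplex = is_duplex,
    bsa_combined = ir$bsa_combined,
    stringsAsFactors = FALSE
  )
  class(rec) <- c("complex_record", "data.frame")
  rec
}

#' Aggregate survey statistics over complex records
#'
#' Arithmetic means of the per-complex hydrogen-bond counts and
#' percentage prevalence of the structural flags.
#'
#' @param records data.frame of rbind-ed \code{\link{analyze_complex}}
#'   records (or hand-built rows with the same columns).
#' @return list of class \code{survey_stats}: n_complexes,
#'   mean_hbonds_total, mean_hbonds_nucleobase, mean_hbonds_backbone,
#'   mean_hbonds_loop, mean_hbonds_helix, pct_helix, pct_stem_loop,
#'   pct_flipped_out, pct_duplex, mean_bsa.
#' @export
aggregate_survey <- function(records) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) stop("no records to aggregate")
  pct <- function(flag) 100 * mean(as.logical(records[[flag]]))
  out <- list(
    n_complexes = nrow(records),
    mean_hbonds_total = mean(records$n_hbonds_total),
    mean_hbonds_nucleobase = mean(records$n_hbonds_nucleobase),
    mean_hbonds_backbone = mean(records$n_hbonds_backbone),
    mean_hbonds_loop = mean(records$n_hbonds_loop),
    mean_hbonds_helix = mean(records$n_hbonds_helix),
    pct_helix = pct("has_helix"),
    pct_stem_loop = pct("has_stem_loop"),
    pct_flipped_out = pct("has_flipped_out"),
    pct_duplex = pct("is_duplex"),
    mean_bsa = if ("bsa_combined" %in% names(records))
      mean(records$bsa_combined) else NA_real_
  )
  class(out) <- "survey_stats"
  out
}

#' @export
print.survey_stats <- function(x, ...) {
  cat(sprintf("Survey over %d complexes:\n", x$n_complexes))
  cat(sprintf("  mean H-bonds: %.1f total (%.1f nucleobase / %.1f backbone;",
              x$mean_hbonds_total, x$mean_hbonds_nucleobase,
              x$mean_hbonds_backbone),
      sprintf(" %.1f loop / %.1f helix)\n", x$mean_hbonds_loop,
              x$mean_hbonds_helix))
  cat(sprintf("  prevalence: %.0f%% helices, %.0f%% stem-loops, %.0f%%",
              x$pct_helix, x$pct_stem_loop, x$pct_flipped_out),
      sprintf("flipped-out bases, %.0f%% duplexes\n", x$pct_duplex))
  invisible(x)
}

#' Run the survey over a manifest of complexes
#'
#' Reads structures from a directory and analyses each manifest entry.
#' Per-complex failures are logged and skipped, not fatal; entries with
#' several records (e.g. two aptamer copies per asymmetric unit analysed
#' as separate rows) should be pre-averaged by the caller.
#'
#' @param manifest data.frame with columns \code{id}, \code{file},
#'   \code{protein_chains}, \code{rna_chains} (chain ids "+"-separated),
#'   or a path to a TSV with those columns.
#' @param structures_dir directory prepended to relative \code{file} paths.
#' @param ... passed to \code{\link{analyze_complex}}.
#' @return list with \code{records} (data.frame), \code{stats}
#'   (\code{survey_stats} or NULL), \code{failures} (named character).
#' @export
run_survey <- function(manifest, structures_dir = ".", ...) {
  if (is.character(manifest)) {
    manifest <- utils::read.table(manifest, sep = "\t", header = TRUE,
                                  stringsAsFactors = FALSE)
  }
  records <- list()
  failures <- character()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$id[i]
    path <- manifest$file[i]
    if (!file.exists(path)) path <- file.path(structures_dir, path)
    rec <- tryCatch({
      s <- read_structure(path)
      analyze_complex(
        s,
        protein_chains = strsplit(manifest$protein_chains[i], "\\+")[[1]],
        rna_chains = strsplit(manifest$rna_chains[i], "\\+")[[1]],
        complex_id = id, ...)
    }, error = function(e) {
      failures[[id]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(rec)) records[[length(records) + 1L]] <- rec
  }
  records <- if (length(records) > 0L) do.call(rbind, records) else
    data.frame()
  stats <- if (nrow(records) > 0L) aggregate_survey(records) else NULL
  list(records = records, stats = stats, failures = failures)
}
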