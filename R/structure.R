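# Hierarchical structure container (flat atom table + crystal metadata).
# Residues are addressed by author numbering (chain, resno, insertion code),
# matching how interface residues are reported in crystallographic work.

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL"
)
RNA_RESID <- c("A", "C", "G", "U", "RA", "RC", "RG", "RU", "I")
DNA_RESID <- c("DA", "DC", "DG", "DT", "DU", "DI")
WATER_RESID <- c("HOH", "WAT", "DOD", "H2O")

# van der Waals radii (Bondi set, plus common ions), Angstrom
VDW_RADII <- c(
  H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
  S = 1.80, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, B = 1.92,
  MG = 1.73, ZN = 1.39, FE = 1.40, MN = 1.40, CU = 1.40, NI = 1.63,
  "NA" = 2.27, K = 2.75, CA = 2.31, CO = 1.40, CD = 1.58, HG = 1.55,
  LI = 1.82, AL = 1.84, SI = 2.10, AS = 1.85, MO = 1.75, W = 1.75
)

KNOWN_ELEMENTS <- names(VDW_RADII)

ATOM_COLUMNS <- c(
  "type", "eleno", "elety", "alt", "resid", "chain", "resno", "insert",
  "x", "y", "z", "o", "b", "elesy"
)

#' Construct a macromolecular structure object
#'
#' Builds the package's structure container from a flat atom table. Polymer
#' class is derived per chain from residue composition and modified
#' nucleotides (for example 2'-fluoro pyrimidines) are mapped to their parent
#' base so they take part in base-pair and hydrogen-bond analysis.
#'
#' @param id character identifier.
#' @param atom data.frame with columns \code{type, eleno, elety, alt, resid,
#'   chain, resno, insert, x, y, z, o, b, elesy}.
#' @param cell numeric(6) lattice parameters (a, b, c in Angstrom; alpha,
#'   beta, gamma in degrees) or \code{NULL}.
#' @param space_group Hermann-Mauguin symbol or \code{NULL}.
#' @param sym_ops list of symmetry operators, each
#'   \code{list(R = 3x3 matrix, t = numeric(3))} in fractional coordinates,
#'   or \code{NULL} (looked up from \code{space_group} when possible).
#' @param validate logical; run invariant checks (finite coordinates, unique
#'   atom keys, recognised elements).
#' @return object of class \code{structure3d}: list with elements
#'   \code{id}, \code{atom} (with added \code{polymer} and
#'   \code{parent_base} columns), \code{cell}, \code{space_group},
#'   \code{sym_ops}.
#' @export
structure3d <- function(id, atom, cell = NULL, space_group = NULL,
                        sym_ops = NULL, validate = TRUE) {
  stopifnot(is.data.frame(atom))
  missing_cols <- setdiff(ATOM_COLUMNS, names(atom))
  if (length(missing_cols) > 0L) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  atom <- as.data.frame(atom, stringsAsFactors = FALSE)
  atom$chain <- as.character(atom$chain)
  atom$chain[is.na(atom$chain) | atom$chain == ""] <- "A"
  atom$insert <- as.character(atom$insert)
  atom$insert[is.na(atom$insert)] <- ""
  atom$alt <- as.character(atom$alt)
  atom$alt[is.na(atom$alt)] <- ""
  atom$elesy <- toupper(trimws(as.character(atom$elesy)))
  atom$elety <- trimws(as.character(atom$elety))
  atom$resid <- toupper(trimws(as.character(atom$resid)))
  if (!is.numeric(atom$o) || all(is.na(atom$o))) atom$o <- 1
  atom$o[is.na(atom$o)] <- 1
  if (!is.numeric(atom$b) || all(is.na(atom$b))) atom$b <- 0

  # infer blank elements from the atom name
  blank <- atom$elesy == "" | is.na(atom$elesy)
  if (any(blank)) {
    atom$elesy[blank] <- infer_element(atom$elety[blank])
    warning(sum(blank), " atoms had no element; inferred from atom names")
  }
  unknown <- !(atom$elesy %in% KNOWN_ELEMENTS)
  if (any(unknown)) {
    guess <- infer_element(atom$elety[unknown])
    fixable <- guess %in% KNOWN_ELEMENTS
    atom$elesy[unknown][fixable] <- guess[fixable]
    if (any(!fixable) && validate) {
      stop("unrecognised chemical element(s): ",
           paste(unique(atom$elesy[unknown][!fixable]), collapse = ", "))
    }
    if (any(fixable)) {
      warning(sum(fixable),
              " atoms had unrecognised elements; inferred from atom names")
    }
  }

  atom <- resolve_altlocs(atom)
  atom$parent_base <- parent_base_of(atom)
  atom$polymer <- classify_polymer(atom)
  # parent_base only applies to nucleic-acid chains
  atom$parent_base[!(atom$polymer %in% c("rna", "dna"))] <- NA_character_

  if (validate) {
    xyz <- as.matrix(atom[, c("x", "y", "z")])
    if (!all(is.finite(xyz))) stop("non-finite atomic coordinates")
    key <- paste(atom$chain, atom$resno, atom$insert, atom$elety, atom$alt)
    if (anyDuplicated(key)) {
      stop("duplicate atom key(s): ",
           paste(head(key[duplicated(key)], 3L), collapse = "; "))
    }
    if (any(atom$o < 0 | atom$o > 1)) stop("occupancy outside [0, 1]")
  }

  if (!is.null(cell)) {
    cell <- as.numeric(cell)
    stopifnot(length(cell) == 6L, all(is.finite(cell)), all(cell > 0))
  }
  if (is.null(sym_ops) && !is.null(space_group)) {
    sym_ops <- tryCatch(space_group_ops(space_group), error = function(e) NULL)
  }

  out <- list(id = as.character(id), atom = atom, cell = cell,
              space_group = space_group, sym_ops = sym_ops)
  class(out) <- "structure3d"
  out
}

#' @export
print.structure3d <- function(x, ...) {
  ch <- chain_summary(x)
  cat("structure3d:", x$id, "-", nrow(x$atom), "atoms,",
      nrow(ch), "chains\n")
  for (i in seq_len(nrow(ch))) {
    cat("  chain", ch$chain[i], sprintf("(%s)", ch$polymer[i]),
        ch$n_residues[i], "residues\n")
  }
  if (!is.null(x$cell)) {
    cat("  cell:", paste(signif(x$cell, 6), collapse = " "),
        if (!is.null(x$space_group)) paste0("  [", x$space_group, "]") else "",
        "\n")
  }
  invisible(x)
}

# keep the highest-occupancy conformer per atom site (tie: first altloc
# alphabetically)
resolve_altlocs <- function(atom) {
  if (all(atom$alt == "")) return(atom)
  site <- paste(atom$chain, atom$resno, atom$insert, atom$elety)
  ord <- order(site, -atom$o, atom$alt)
  atom <- atom[ord, , drop = FALSE]
  keep <- !duplicated(paste(atom$chain, atom$resno, atom$insert, atom$elety))
  atom <- atom[keep, , drop = FALSE]
  atom[order(atom$eleno), , drop = FALSE]
}

infer_element <- function(elety) {
  nm <- toupper(gsub("[^A-Za-z]", "", elety))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% c("FE", "ZN", "MG", "CL", "BR", "SE", "NA", "MN", "CU",
                    "NI", "CO", "CD", "HG", "LI"),
         two, one)
}

# map modified nucleotides to their canonical parent base; recognises
# 2'-fluoro pyrimidines (ribose fluorine atom) and a configurable alias
# table (option "aptaface.base_aliases": named character vector code->base)
parent_base_of <- function(atom) {
  res_id <- paste(atom$chain, atom$resno, atom$insert)
  base <- rep(NA_character_, nrow(atom))
  aliases <- getOption("aptaface.base_aliases", character())
  canon <- c(A = "A", C = "C", G = "G", U = "U", I = "G",
             RA = "A", RC = "C", RG = "G", RU = "U",
             DA = "A", DC = "C", DG = "G", DT = "T", DU = "U", DI = "G")
  for (rid in unique(res_id)) {
    sel <- res_id == rid
    rn <- atom$resid[sel][1L]
    names_here <- atom$elety[sel]
    b <- NA_character_
    if (rn %in% names(canon)) {
      b <- canon[[rn]]
    } else if (rn %in% names(aliases)) {
      b <- aliases[[rn]]
    } else if (any(names_here %in% c("C1'", "C1*")) &&
               any(names_here %in% c("N9", "N1"))) {
      # unknown code: infer the parent base from the base atom names
      # (covers dialect-specific codes for 2'-F pyrimidines)
      if (all(c("N9", "N7") %in% names_here)) {
        b <- if ("O6" %in% names_here) "G" else "A"
      } else if ("N1" %in% names_here && "C6" %in% names_here) {
        if ("N4" %in% names_here) b <- "C"
        else if (any(c("C7", "C5M") %in% names_here)) b <- "T"
        else if ("O4" %in% names_here || "O2" %in% names_here) b <- "U"
      }
    }
    base[sel] <- b
  }
  base
}

classify_polymer <- function(atom) {
  res_first <- !duplicated(paste(atom$chain, atom$resno, atom$insert))
  cls <- rep(NA_character_, nrow(atom))
  for (ch in unique(atom$chain)) {
    sel <- atom$chain == ch
    rsel <- sel & res_first
    resn <- atom$resid[rsel]
    pb <- atom$parent_base[rsel]
    n <- length(resn)
    n_aa <- sum(resn %in% STANDARD_AA)
    n_wat <- sum(resn %in% WATER_RESID)
    has_sugar_f <- any(atom$elesy[sel] == "F" &
                         grepl("2'|2\\*", atom$elety[sel]))
    n_rna <- sum(resn %in% RNA_RESID | (!is.na(pb) & !(resn %in% DNA_RESID)))
    n_dna <- sum(resn %in% DNA_RESID)
    cls[sel] <- if (n_wat == n) "water"
      else if (n_aa >= 0.5 * n) "protein"
      else if (n_rna >= 0.5 * n || (has_sugar_f && n_rna > 0)) "rna"
      else if (n_dna >= 0.5 * n) "dna"
      else if (n == 1L) "ligand"
      else "other"
  }
  cls
}

# --- accessors -------------------------------------------------------------

atom_key <- function(atom) {
  paste(atom$chain, atom$resno, atom$insert, atom$elety, sep = "|")
}

res_key <- function(atom) {
  paste0(atom$chain, ":", atom$resno,
         ifelse(atom$insert == "", "", paste0(":", atom$insert)))
}

#' Extract atomic coordinates
#' @param s structure3d.
#' @param sel optional logical/integer index into the atom table.
#' @return N x 3 matrix of coordinates (Angstrom).
#' @export
coords3d <- function(s, sel = NULL) {
  a <- s$atom
  if (!is.null(sel)) a <- a[sel, , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- atom_key(a)
  m
}

#' Subset a structure by chains and polymer classes
#' @param s structure3d.
#' @param chains character vector of chain ids, or NULL for all.
#' @param polymers character vector of polymer classes to keep, or NULL.
#' @param drop_water drop water chains.
#' @param drop_hydrogens drop hydrogen/deuterium atoms.
#' @return structure3d.
#' @export
subset_structure <- function(s, chains = NULL, polymers = NULL,
                             drop_water = FALSE, drop_hydrogens = FALSE) {
  keep <- rep(TRUE, nrow(s$atom))
  if (!is.null(chains)) keep <- keep & s$atom$chain %in% chains
  if (!is.null(polymers)) keep <- keep & s$atom$polymer %in% polymers
  if (drop_water) keep <- keep & s$atom$polymer != "water"
  if (drop_hydrogens) keep <- keep & !(s$atom$elesy %in% c("H", "D"))
  out <- s
  out$atom <- s$atom[keep, , drop = FALSE]
  rownames(out$atom) <- NULL
  out
}

#' Summarise chains of a structure
#' @param s structure3d.
#' @return data.frame with chain, polymer, n_residues, n_atoms.
#' @export
chain_summary <- function(s) {
  a <- s$atom
  res_first <- !duplicated(paste(a$chain, a$resno, a$insert))
  chains <- unique(a$chain)
  data.frame(
    chain = chains,
    polymer = vapply(chains, function(ch) a$polymer[a$chain == ch][1L], ""),
    n_residues = vapply(chains, function(ch)
      sum(res_first & a$chain == ch), 0L),
    n_atoms = vapply(chains, function(ch) sum(a$chain == ch), 0L),
    stringsAsFactors = FALSE
  )
}

# residue-level view: one row per residue
residue_table <- function(atom) {
  first <- !duplicated(paste(atom$chain, atom$resno, atom$insert))
  r <- atom[first, c("chain", "resno", "insert", "resid", "parent_base",
                     "polymer")]
  r$res_key <- res_key(r)
  rownames(r) <- NULL
  r
}
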