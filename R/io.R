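# Reading and writing PDB / mmCIF structures and multi-model ensembles.
# Record parsing is delegated to bio3d; cell parameters and symmetry
# operators, which bio3d does not expose, are extracted here.

#' Read a macromolecular structure
#'
#' Parses a PDB or mmCIF file into a \code{\link{structure3d}}. Alternate
#' conformers are reduced to the highest-occupancy one (ties broken by the
#' alphabetically first altloc); modified nucleotides are assigned a parent
#' base; crystal cell and symmetry operators are read when present. For
#' multi-model files the first model is used (use
#' \code{\link{read_ensemble}} for conformational ensembles).
#'
#' @param path file path.
#' @param format one of "auto", "pdb", "mmcif".
#' @return structure3d.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") {
      # keep all alternate conformers; the occupancy-based policy is ours
      suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                       multi = FALSE, rm.alt = FALSE))
    } else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  atom <- pdb$atom
  # mmCIF quotes atom names containing primes; strip matched quote pairs
  # only (a trailing prime is part of the name)
  atom$elety <- sub("^\"(.*)\"$", "\\1", atom$elety)
  atom$elety <- sub("^'(.*)'$", "\\1", atom$elety)
  atom <- data.frame(
    type = atom$type, eleno = atom$eleno, elety = atom$elety,
    alt = ifelse(is.na(atom$alt), "", atom$alt),
    resid = atom$resid, chain = atom$chain, resno = atom$resno,
    insert = ifelse(is.na(atom$insert), "", atom$insert),
    x = atom$x, y = atom$y, z = atom$z,
    o = atom$o, b = atom$b,
    elesy = if ("elesy" %in% names(atom)) atom$elesy else "",
    stringsAsFactors = FALSE
  )
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    cellinfo <- parse_cryst1(lines)
    ops <- parse_remark290(lines)
  } else {
    cellinfo <- parse_cif_cell(lines)
    ops <- parse_cif_symops(lines)
  }
  structure3d(
    id = sub("\\.[^.]*$", "", basename(path)),
    atom = atom,
    cell = cellinfo$cell,
    space_group = cellinfo$space_group,
    sym_ops = ops
  )
}

parse_cryst1 <- function(lines) {
  ln <- grep("^CRYST1", lines, value = TRUE)
  if (length(ln) == 0L) return(list(cell = NULL, space_group = NULL))
  ln <- ln[1L]
  cell <- as.numeric(c(substr(ln, 7, 15), substr(ln, 16, 24),
                       substr(ln, 25, 33), substr(ln, 34, 40),
                       substr(ln, 41, 47), substr(ln, 48, 54)))
  sg <- trimws(substr(ln, 56, 66))
  if (any(is.na(cell))) return(list(cell = NULL, space_group = NULL))
  list(cell = cell, space_group = if (nzchar(sg)) sg else NULL)
}

parse_remark290 <- function(lines) {
  ln <- grep("^REMARK 290   SMTRY", lines, value = TRUE)
  if (length(ln) == 0L) return(NULL)
  rows <- do.call(rbind, lapply(ln, function(l) {
    f <- strsplit(trimws(sub("^REMARK 290", "", l)), "\\s+")[[1]]
    as.numeric(f[-1])  # n, op_index, r1 r2 r3 t
  }))
  ops <- lapply(split(as.data.frame(rows), rows[, 2]), function(d) {
    d <- d[order(d[, 1]), ]
    list(R = as.matrix(d[, 3:5]), t = as.numeric(d[, 6]))
  })
  names(ops) <- NULL
  # REMARK 290 translations are in Angstrom for SMTRY? They are fractional
  # applied after orthogonal rotation; treated as cartesian operators here
  lapply(ops, function(op) list(R = unname(op$R), t = op$t,
                                frame = "cartesian"))
}

parse_cif_cell <- function(lines) {
  getval <- function(tag) {
    ln <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (length(ln) == 0L) return(NA)
    trimws(sub(paste0("^", tag, "\\s+"), "", ln[1L]))
  }
  cell <- suppressWarnings(as.numeric(c(
    getval("_cell\\.length_a"), getval("_cell\\.length_b"),
    getval("_cell\\.length_c"), getval("_cell\\.angle_alpha"),
    getval("_cell\\.angle_beta"), getval("_cell\\.angle_gamma")
  )))
  sg <- getval("_symmetry\\.space_group_name_H-M")
  if (is.na(sg[1])) sg <- getval("_space_group\\.name_H-M_alt")
  sg <- if (is.na(sg[1])) NULL else gsub("['\"]", "", sg)
  if (any(is.na(cell))) cell <- NULL
  list(cell = cell, space_group = sg)
}

parse_cif_symops <- function(lines) {
  i <- grep("_symmetry_equiv_pos_as_xyz|_space_group_symop_operation_xyz",
            lines)
  if (length(i) == 0L) return(NULL)
  out <- character()
  j <- i[1L] + 1L
  while (j <= length(lines)) {
    l <- trimws(lines[j])
    if (l == "" || startsWith(l, "_") || startsWith(l, "loop_") ||
        startsWith(l, "#")) break
    l <- gsub("['\"]", "", l)
    l <- sub("^\\d+\\s+", "", l)  # optional leading operator id
    out <- c(out, l)
    j <- j + 1L
  }
  if (length(out) == 0L) return(NULL)
  lapply(out, parse_symop_xyz)
}

# parse an "x,y,z"-style operator string into R (3x3) + t (fractional)
parse_symop_xyz <- function(txt) {
  parts <- strsplit(tolower(gsub("\\s", "", txt)), ",")[[1]]
  stopifnot(length(parts) == 3L)
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (r in 1:3) {
    expr <- parts[r]
    for (k in 1:3) {
      v <- c("x", "y", "z")[k]
      if (grepl(paste0("-", v), expr, fixed = TRUE)) R[r, k] <- -1
      else if (grepl(v, expr, fixed = TRUE)) R[r, k] <- 1
      expr2 <- gsub(paste0("[+-]?", v), "", expr)
      expr <- expr2
    }
    expr <- gsub("^\\+", "", expr)
    if (nzchar(expr)) {
      if (grepl("/", expr)) {
        f <- as.numeric(strsplit(gsub("[+]", "", expr), "/")[[1]])
        t[r] <- f[1] / f[2]
      } else {
        t[r] <- as.numeric(expr)
      }
    }
  }
  list(R = R, t = t, frame = "fractional")
}

# built-in operator table for the space groups used in this package
# (toy crystals and the tetragonal group of the studied complex)
SPACE_GROUP_XYZ <- list(
  "P 1" = c("x,y,z"),
  "P 1 21 1" = c("x,y,z", "-x,y+1/2,-z"),
  "P 21" = c("x,y,z", "-x,y+1/2,-z"),
  "C 1 2 1" = c("x,y,z", "-x,y,-z", "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
  "P 21 21 21" = c("x,y,z", "-x+1/2,-y,z+1/2", "-x,y+1/2,-z+1/2",
                   "x+1/2,-y+1/2,-z"),
  "P 41 21 2" = c("x,y,z", "-x,-y,z+1/2", "-y+1/2,x+1/2,z+1/4",
                  "y+1/2,-x+1/2,z+3/4", "-x+1/2,y+1/2,-z+1/4",
                  "x+1/2,-y+1/2,-z+3/4", "y,x,-z", "-y,-x,-z+1/2"),
  "P 43 21 2" = c("x,y,z", "-x,-y,z+1/2", "-y+1/2,x+1/2,z+3/4",
                  "y+1/2,-x+1/2,z+1/4", "-x+1/2,y+1/2,-z+3/4",
                  "x+1/2,-y+1/2,-z+1/4", "y,x,-z", "-y,-x,-z+1/2")
)

#' Symmetry operators for a space group
#'
#' Returns the fractional-coordinate symmetry operators for a (small,
#' built-in) set of space groups. Operators parsed from the file itself
#' (mmCIF symop loop) take precedence in \code{\link{read_structure}}.
#'
#' @param symbol Hermann-Mauguin symbol, e.g. "P 21" or "P 41 21 2".
#' @return list of \code{list(R, t, frame = "fractional")}.
#' @export
space_group_ops <- function(symbol) {
  key <- toupper(gsub("\\s+", " ", trimws(symbol)))
  nosp <- gsub(" ", "", key)
  hit <- which(gsub(" ", "", toupper(names(SPACE_GROUP_XYZ))) == nosp)
  if (length(hit) == 0L) {
    stop("no operator table for space group '", symbol, "'")
  }
  lapply(SPACE_GROUP_XYZ[[hit[1L]]], parse_symop_xyz)
}

#' Write a structure to a PDB or mmCIF file
#'
#' Fixed-column PDB or a minimal atom_site mmCIF. Output re-parses to an
#' equal structure (atom identities exact, coordinates to 1e-3 Angstrom).
#'
#' @param s structure3d.
#' @param path output path.
#' @param format "pdb" or "mmcif".
#' @return invisibly, the path.
#' @export
write_structure <- function(s, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  a <- s$atom
  con_ok <- tryCatch({ file.create(path) }, warning = function(w) FALSE,
                     error = function(e) FALSE)
  if (!isTRUE(con_ok)) stop("cannot write to ", path)
  if (format == "pdb") {
    lines <- character()
    if (!is.null(s$cell)) {
      sg <- if (is.null(s$space_group)) "P 1" else s$space_group
      lines <- c(lines, sprintf(
        "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11sZ", s$cell[1], s$cell[2],
        s$cell[3], s$cell[4], s$cell[5], s$cell[6], sg))
    }
    if (nrow(a) > 0L) {
      nm <- ifelse(nchar(a$elety) < 4L & nchar(a$elesy) == 1L,
                   paste0(" ", a$elety), a$elety)
      lines <- c(lines, sprintf(
        "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        a$type, a$eleno %% 100000L, nm, a$alt, a$resid, substr(a$chain, 1, 1),
        a$resno, a$insert, a$x, a$y, a$z, a$o, a$b, a$elesy))
    }
    lines <- c(lines, "END")
    writeLines(lines, path)
  } else {
    hdr <- c(
      paste0("data_", gsub("\\s", "_", s$id)),
      "#",
      if (!is.null(s$cell)) c(
        sprintf("_cell.length_a    %.3f", s$cell[1]),
        sprintf("_cell.length_b    %.3f", s$cell[2]),
        sprintf("_cell.length_c    %.3f", s$cell[3]),
        sprintf("_cell.angle_alpha %.2f", s$cell[4]),
        sprintf("_cell.angle_beta  %.2f", s$cell[5]),
        sprintf("_cell.angle_gamma %.2f", s$cell[6]),
        if (!is.null(s$space_group))
          sprintf("_symmetry.space_group_name_H-M '%s'", s$space_group),
        "#"),
      "loop_", "_atom_site.group_PDB", "_atom_site.id",
      "_atom_site.type_symbol", "_atom_site.label_atom_id",
      "_atom_site.label_alt_id", "_atom_site.label_comp_id",
      "_atom_site.label_asym_id", "_atom_site.label_entity_id",
      "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
      "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
      "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
      "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
      "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
      "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num"
    )
    nm <- ifelse(grepl("'", a$elety), paste0("\"", a$elety, "\""), a$elety)
    body <- if (nrow(a) > 0L) sprintf(
      paste0("%-6s %d %s %s %s %s %s 1 %d %s ",
             "%.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1"),
      a$type, a$eleno, a$elesy, nm,
      ifelse(a$alt == "", ".", a$alt), a$resid, a$chain, a$resno,
      ifelse(a$insert == "", "?", a$insert), a$x, a$y, a$z, a$o, a$b,
      a$resno, a$resid, a$chain, nm
    ) else character()
    writeLines(c(hdr, body, "#"), path)
  }
  invisible(path)
}

#' Read a conformational ensemble
#'
#' Loads a multi-model PDB together with a per-model energy table and
#' restricts coordinates to an atom selection. One ensemble member is
#' created per energy-table row, in table order.
#'
#' @param model_path multi-model PDB (MODEL/ENDMDL records).
#' @param energy_path two-column TSV: \code{model_index<TAB>energy}
#'   (header optional).
#' @param selection atom selection: "all", "calpha", "heavy",
#'   or "name <ATOM>" (e.g. "name P").
#' @return object of class \code{ensemble3d}: list with \code{coords}
#'   (list of N x 3 matrices), \code{energy}, \code{model_index},
#'   \code{atom_selection}, \code{atom_names}.
#' @export
read_ensemble <- function(model_path, energy_path, selection = "all") {
  pdb <- tryCatch(bio3d::read.pdb(model_path, multi = TRUE, verbose = FALSE),
                  error = function(e) stop("parse error in ", model_path,
                                           ": ", conditionMessage(e),
                                           call. = FALSE))
  et <- utils::read.table(energy_path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (!is.numeric(et[[1]])) {  # header row present
    et <- utils::read.table(energy_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  }
  stopifnot(ncol(et) >= 2L)
  model_index <- as.integer(et[[1]])
  energy <- as.numeric(et[[2]])

  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n_models <- nrow(xyz)
  missing <- setdiff(model_index, seq_len(n_models))
  if (length(missing) > 0L) {
    stop("energy table lists model indices absent from the coordinate ",
         "file: ", paste(missing, collapse = ", "))
  }

  sel_idx <- parse_atom_selection(pdb$atom, selection)
  if (length(sel_idx) == 0L) stop("selection '", selection,
                                  "' matches zero atoms")
  atom_names <- paste(pdb$atom$chain[sel_idx], pdb$atom$resno[sel_idx],
                      pdb$atom$elety[sel_idx], sep = "|")
  coords <- lapply(model_index, function(m) {
    co <- matrix(xyz[m, ], ncol = 3L, byrow = TRUE)[sel_idx, , drop = FALSE]
    colnames(co) <- c("x", "y", "z")
    co
  })
  out <- list(coords = coords, energy = energy, model_index = model_index,
              atom_selection = selection, atom_names = atom_names)
  class(out) <- "ensemble3d"
  out
}

parse_atom_selection <- function(atom, selection) {
  selection <- trimws(selection)
  if (selection == "all") return(seq_len(nrow(atom)))
  if (selection == "calpha") return(which(atom$elety == "CA"))
  if (selection == "heavy") {
    el <- toupper(atom$elesy)
    el[el == "" | is.na(el)] <- infer_element(atom$elety[el == "" | is.na(el)])
    return(which(!(el %in% c("H", "D"))))
  }
  if (grepl("^name\\s+", selection)) {
    nm <- strsplit(sub("^name\\s+", "", selection), "\\s+")[[1]]
    return(which(atom$elety %in% nm))
  }
  stop("unsupported atom selection: '", selection, "'")
}

#' @export
print.ensemble3d <- function(x, ...) {
  cat("ensemble3d:", length(x$coords), "members,",
      nrow(x$coords[[1]]), "atoms each (selection: ",
      x$atom_selection, ")\n", sep = " ")
  cat("  energy range:", paste(signif(range(x$energy), 6), collapse = " .. "),
      "\n")
  invisible(x)
}

#' Construct an ensemble from in-memory coordinates
#' @param coords list of N x 3 matrices (identical dimensions).
#' @param energy numeric vector, one value per member.
#' @param model_index integer ids (default 1..n).
#' @param atom_selection descriptor string.
#' @return ensemble3d.
#' @export
ensemble3d <- function(coords, energy, model_index = seq_along(coords),
                       atom_selection = "all") {
  stopifnot(length(coords) == length(energy),
            length(coords) == length(model_index))
  dims <- vapply(coords, function(m) dim(as.matrix(m)), numeric(2))
  if (length(coords) > 0L &&
      (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != 3))) {
    stop("ensemble members must share one N x 3 atom selection")
  }
  out <- list(coords = lapply(coords, as.matrix), energy = as.numeric(energy),
              model_index = as.integer(model_index),
              atom_selection = atom_selection, atom_names = NULL)
  class(out) <- "ensemble3d"
  out
}

#' Write an ensemble as a multi-model PDB plus an energy TSV
#' @param e ensemble3d.
#' @param model_path output PDB path.
#' @param energy_path output TSV path.
#' @param atom_name atom name used for the pseudo-atoms (default "CA").
#' @return invisibly, model_path.
#' @export
write_ensemble <- function(e, model_path, energy_path, atom_name = "CA") {
  lines <- character()
  for (i in seq_along(e$coords)) {
    co <- e$coords[[i]]
    lines <- c(lines, sprintf("MODEL     %4d", i))
    lines <- c(lines, sprintf(
      "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(co)), atom_name, "GLY", "A", seq_len(nrow(co)),
      co[, 1], co[, 2], co[, 3], 1, 0,
      substr(atom_name, 1, 1)))
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), model_path)
  utils::write.table(
    data.frame(model_index = e$model_index, energy = e$energy),
    energy_path, sep = "\t", row.names = FALSE, col.names = FALSE,
    quote = FALSE)
  invisible(model_path)
}
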