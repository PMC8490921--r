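#' Read a PDB-format structure into a structure model
#'
#' Parses the ATOM records of a PDB file into a validated in-memory model.
#' Only the first MODEL block is read; HETATM records (waters, ligands, ions)
#' are excluded; alternate locations are resolved to the highest-occupancy
#' conformer (ties broken by file order). Hydrogens, when present, are kept:
#' hydrogen-bond detection can exploit them.
#'
#' @param path Path to a PDB-format text file.
#' @param id Identifier stored on the model (defaults to the file name).
#' @return A \code{StructureModel}: a list with elements \code{id} (character)
#'   and \code{atoms}, a data frame with one row per atom and columns
#'   \code{chain}, \code{resnum}, \code{icode}, \code{resname}, \code{atom},
#'   \code{element}, \code{x}, \code{y}, \code{z} (angstrom), \code{occ},
#'   \code{b}.
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' write_structure(make_helix(5), f)
#' m <- read_structure(f)
#' n_residues(m)
#' @export
read_structure <- function(path, id = basename(path)) {
  if (!file.exists(path)) {
    stop("cannot read structure file: ", path)
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("no ATOM records in '", path, "'")
  }
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$b[is.na(at$b)] <- 0
  # altloc policy: keep the highest-occupancy conformer per atom name,
  # first-encountered wins ties (stable order sort on -occupancy)
  key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(match(key, unique(key)), -at$o)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                               sep = "\r")), , drop = FALSE]
  }
  rkey <- paste(at$chain, at$resno, at$insert, sep = "\r")
  nm_per_res <- tapply(at$resid, rkey, function(v) length(unique(v)))
  if (any(nm_per_res > 1L)) {
    bad <- names(nm_per_res)[nm_per_res > 1L][1L]
    stop("conflicting residue names for residue ",
         gsub("\r", "/", bad), " in '", path, "'")
  }
  elem <- at$elesy
  elem[is.na(elem) | elem == ""] <- guess_element(at$elety[is.na(elem) | elem == ""])
  atoms <- data.frame(
    chain = at$chain, resnum = as.integer(at$resno), icode = at$insert,
    resname = at$resid, atom = at$elety, element = toupper(elem),
    x = at$x, y = at$y, z = at$z, occ = at$o, b = at$b,
    stringsAsFactors = FALSE
  )
  new_structure_model(id, atoms)
}

# element from the leading letter of an atom name (fallback only)
guess_element <- function(name) {
  e <- toupper(substr(gsub("^[0-9]+", "", name), 1L, 1L))
  e[e == ""] <- "C"
  e
}

new_structure_model <- function(id, atoms) {
  stopifnot(is.data.frame(atoms))
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite atom coordinates in structure model")
  }
  if (any(!nzchar(atoms$atom))) {
    stop("empty atom name in structure model")
  }
  m <- list(id = as.character(id), atoms = atoms)
  class(m) <- "StructureModel"
  m
}

#' @export
print.StructureModel <- function(x, ...) {
  res <- residue_table(x)
  cat("StructureModel '", x$id, "': ", length(unique(x$atoms$chain)),
      " chain(s), ", nrow(res), " residues, ", nrow(x$atoms), " atoms\n",
      sep = "")
  for (ch in unique(x$atoms$chain)) {
    r <- res[res$chain == ch, ]
    cat("  chain ", ch, ": ", nrow(r), " residues (",
        min(r$resnum), "-", max(r$resnum), ")\n", sep = "")
  }
  invisible(x)
}

#' Residue-level summary of a structure model
#'
#' @param model A \code{StructureModel}.
#' @return Data frame with one row per residue: \code{chain}, \code{resnum},
#'   \code{icode}, \code{resname}, in atom-record order.
#' @export
residue_table <- function(model) {
  at <- model$atoms
  keep <- !duplicated(paste(at$chain, at$resnum, at$icode, sep = "\r"))
  out <- at[keep, c("chain", "resnum", "icode", "resname")]
  rownames(out) <- NULL
  out
}

#' @rdname residue_table
#' @export
n_residues <- function(model) nrow(residue_table(model))

#' @rdname residue_table
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Alpha-carbon coordinates of a model
#'
#' @param model A \code{StructureModel}.
#' @return Data frame \code{chain}, \code{resnum}, \code{icode},
#'   \code{resname}, \code{x}, \code{y}, \code{z}: one row per residue that
#'   has a CA atom.
#' @export
ca_table <- function(model) {
  at <- model$atoms[model$atoms$atom == "CA", , drop = FALSE]
  out <- at[, c("chain", "resnum", "icode", "resname", "x", "y", "z")]
  rownames(out) <- NULL
  out
}

#' Write a structure model as a PDB file
#'
#' Emits standard fixed-column ATOM records (coordinates to 3 decimals), a
#' TER record after each chain and a terminating END. The writer is the exact
#' inverse of \code{\link{read_structure}} up to the 1e-3 angstrom coordinate
#' precision of the PDB format.
#'
#' @param model A \code{StructureModel}.
#' @param path Output file path.
#' @return Invisibly, \code{path}.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "StructureModel"))
  at <- model$atoms
  if (nrow(at) == 0L) stop("refusing to write a model with no atoms")
  if (any(nchar(at$atom) > 4L)) {
    stop("atom name longer than 4 characters: ",
         at$atom[which(nchar(at$atom) > 4L)[1L]])
  }
  # short atom names are indented one column per the wwPDB convention
  nm <- ifelse(nchar(at$atom) < 4L, sprintf(" %-3s", at$atom), at$atom)
  lines <- character(0)
  serial <- 0L
  for (ch in unique(at$chain)) {
    rows <- which(at$chain == ch)
    serial_seq <- serial + seq_along(rows)
    lines <- c(lines, sprintf(
      "ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial_seq, nm[rows], at$resname[rows], at$chain[rows],
      at$resnum[rows], ifelse(nzchar(at$icode[rows]), at$icode[rows], " "),
      at$x[rows], at$y[rows], at$z[rows], at$occ[rows], at$b[rows],
      at$element[rows]))
    serial <- serial + length(rows) + 1L
    last <- rows[length(rows)]
    lines <- c(lines, sprintf("TER   %5d      %-3s %1s%4d", serial,
                              at$resname[last], ch, at$resnum[last]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Declare the receptor/partner chain split of a complex
#'
#' @param receptor_chains Character vector of receptor chain identifiers.
#' @param partner_chains Character vector of partner chain identifiers.
#' @return A \code{ComplexSpec} (validated against a model only when used).
#' @export
complex_spec <- function(receptor_chains, partner_chains) {
  receptor_chains <- unique(as.character(receptor_chains))
  partner_chains <- unique(as.character(partner_chains))
  if (length(receptor_chains) == 0L || length(partner_chains) == 0L) {
    stop("receptor and partner chain sets must be non-empty")
  }
  if (length(intersect(receptor_chains, partner_chains)) > 0L) {
    stop("receptor and partner chain sets overlap: ",
         paste(intersect(receptor_chains, partner_chains), collapse = ", "))
  }
  structure(list(receptor_chains = receptor_chains,
                 partner_chains = partner_chains),
            class = "ComplexSpec")
}

validate_spec <- function(model, spec) {
  stopifnot(inherits(spec, "ComplexSpec"))
  have <- unique(model$atoms$chain)
  missing <- setdiff(c(spec$receptor_chains, spec$partner_chains), have)
  if (length(missing) > 0L) {
    stop("chain(s) not present in model '", model$id, "': ",
         paste(missing, collapse = ", "))
  }
  invisible(spec)
}

#' Split a complex into its receptor and partner halves
#'
#' Chains not named in the spec are dropped with a warning.
#'
#' @param model A \code{StructureModel} holding the complex.
#' @param spec A \code{\link{complex_spec}}.
#' @return List with elements \code{receptor} and \code{partner}, each a
#'   \code{StructureModel}.
#' @export
split_complex <- function(model, spec) {
  validate_spec(model, spec)
  selected <- c(spec$receptor_chains, spec$partner_chains)
  extra <- setdiff(unique(model$atoms$chain), selected)
  if (length(extra) > 0L) {
    warning("dropping chain(s) not named in complex spec: ",
            paste(extra, collapse = ", "))
  }
  take <- function(chains, tag) {
    new_structure_model(paste0(model$id, ":", tag),
                        model$atoms[model$atoms$chain %in% chains, ,
                                    drop = FALSE])
  }
  list(receptor = take(spec$receptor_chains, "receptor"),
       partner = take(spec$partner_chains, "partner"))
}
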