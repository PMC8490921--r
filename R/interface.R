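# one-letter codes via bio3d::aa321; non-standard residues come back "X"
aa_one <- function(resname) {
  suppressWarnings(bio3d::aa321(resname))
}

# amino-acid group partition used for interface composition; the four
# groups cover the 20 standard residues exactly once
aa_groups <- list(
  hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "P", "G"),
  polar       = c("S", "T", "C", "N", "Q", "Y"),
  positive    = c("K", "R", "H"),
  negative    = c("D", "E")
)

#' Find receptor-partner residue contacts
#'
#' A contact is a receptor residue / partner residue pair whose alpha-carbon
#' distance does not exceed \code{cutoff} (boundary inclusive). Residues
#' without a CA atom are skipped with a warning.
#'
#' @param model A \code{StructureModel} holding the complex.
#' @param spec A \code{\link{complex_spec}}.
#' @param cutoff Contact cutoff in angstrom (default 8).
#' @param mapping Optional \code{LabelMap}; when supplied, contacts carry
#'   generic labels, otherwise author labels \code{<chain>:<resnum>}.
#' @return A \code{ContactSet} data frame sorted by (receptor author number,
#'   partner author number), with columns \code{receptor_chain},
#'   \code{receptor_resnum}, \code{receptor_aa}, \code{receptor_label},
#'   the same four for the partner, \code{ca_distance}, \code{hbond},
#'   \code{saltbridge} (the last two \code{NA} until the detection passes
#'   run).
#' @examples
#' toy <- make_toy_complex(n = 12, separation = 6)
#' find_contacts(toy$model, toy$spec)
#' @export
find_contacts <- function(model, spec, cutoff = 8.0, mapping = NULL) {
  validate_spec(model, spec)
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  ca <- ca_table(model)
  res <- residue_table(model)
  sel <- res$chain %in% c(spec$receptor_chains, spec$partner_chains)
  no_ca <- !(paste(res$chain, res$resnum, res$icode) %in%
               paste(ca$chain, ca$resnum, ca$icode)) & sel
  if (any(no_ca)) {
    warning(sum(no_ca), " residue(s) without CA atom skipped")
  }
  rca <- ca[ca$chain %in% spec$receptor_chains, , drop = FALSE]
  pca <- ca[ca$chain %in% spec$partner_chains, , drop = FALSE]
  if (nrow(rca) == 0L || nrow(pca) == 0L) {
    stop("empty interface side: both receptor and partner need CA atoms")
  }
  # squared cross-distance matrix, receptor rows x partner columns
  d2 <- outer(rca$x, pca$x, "-")^2 + outer(rca$y, pca$y, "-")^2 +
    outer(rca$z, pca$z, "-")^2
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  lab <- function(tab, rows) {
    if (length(rows) == 0L) return(character(0))
    if (is.null(mapping)) {
      return(paste0(tab$chain[rows], ":", tab$resnum[rows], tab$icode[rows]))
    }
    idx <- match(paste(tab$chain[rows], tab$resnum[rows], tab$icode[rows]),
                 paste(mapping$chain, mapping$resnum, mapping$icode))
    ifelse(is.na(idx),
           paste0(tab$chain[rows], ":", tab$resnum[rows], tab$icode[rows]),
           mapping$label[idx])
  }
  out <- data.frame(
    receptor_chain = rca$chain[hit[, 1L]],
    receptor_resnum = rca$resnum[hit[, 1L]],
    receptor_icode = rca$icode[hit[, 1L]],
    receptor_aa = aa_one(rca$resname[hit[, 1L]]),
    receptor_label = lab(rca, hit[, 1L]),
    partner_chain = pca$chain[hit[, 2L]],
    partner_resnum = pca$resnum[hit[, 2L]],
    partner_icode = pca$icode[hit[, 2L]],
    partner_aa = aa_one(pca$resname[hit[, 2L]]),
    partner_label = lab(pca, hit[, 2L]),
    ca_distance = sqrt(d2[hit]),
    hbond = rep(NA, nrow(hit)), saltbridge = rep(NA, nrow(hit)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$receptor_chain, out$receptor_resnum,
                   out$partner_chain, out$partner_resnum), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ContactSet", "data.frame")
  out
}

# atoms of one residue, as a data frame subset
residue_atoms <- function(model, chain, resnum, icode = "") {
  at <- model$atoms
  at[at$chain == chain & at$resnum == resnum & at$icode == icode, ,
     drop = FALSE]
}

# hydrogen-bond donor / acceptor heavy atoms of a residue. With no
# hydrogens in the structure every N/O is a potential donor; acceptors are
# all oxygens plus the histidine ring nitrogens (lone-pair bearing).
hb_partners <- function(ratoms) {
  heavyNO <- ratoms[ratoms$element %in% c("N", "O"), , drop = FALSE]
  hyd <- ratoms[ratoms$element == "H", , drop = FALSE]
  donors <- heavyNO
  if (nrow(hyd) > 0L && nrow(heavyNO) > 0L) {
    # donor = N/O with a covalently attached hydrogen (<= 1.25 A)
    keep <- vapply(seq_len(nrow(heavyNO)), function(i) {
      d2 <- (hyd$x - heavyNO$x[i])^2 + (hyd$y - heavyNO$y[i])^2 +
        (hyd$z - heavyNO$z[i])^2
      any(d2 <= 1.25^2)
    }, logical(1L))
    donors <- heavyNO[keep, , drop = FALSE]
  }
  acceptors <- ratoms[ratoms$element == "O" |
                        (ratoms$resname == "HIS" &
                           ratoms$atom %in% c("ND1", "NE2")), , drop = FALSE]
  list(donors = donors, acceptors = acceptors, hydrogens = hyd)
}

# TRUE when some donor-acceptor pair across the two residues satisfies the
# geometric criterion
pair_has_hbond <- function(a, b, dist_cutoff, angle_min) {
  pa <- hb_partners(a)
  pb <- hb_partners(b)
  check <- function(don, hyd, acc) {
    if (nrow(don$donors) == 0L || nrow(acc$acceptors) == 0L) return(FALSE)
    for (i in seq_len(nrow(don$donors))) {
      D <- c(don$donors$x[i], don$donors$y[i], don$donors$z[i])
      for (j in seq_len(nrow(acc$acceptors))) {
        A <- c(acc$acceptors$x[j], acc$acceptors$y[j], acc$acceptors$z[j])
        if (sum((D - A)^2) > dist_cutoff^2) next
        if (nrow(hyd) == 0L) return(TRUE)
        # with explicit hydrogens additionally require D-H...A >= angle_min
        hd2 <- (hyd$x - D[1L])^2 + (hyd$y - D[2L])^2 + (hyd$z - D[3L])^2
        hs <- which(hd2 <= 1.25^2)
        if (length(hs) == 0L) return(TRUE)
        for (k in hs) {
          H <- c(hyd$x[k], hyd$y[k], hyd$z[k])
          v1 <- D - H
          v2 <- A - H
          ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                     sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
          if (ang >= angle_min) return(TRUE)
        }
      }
    }
    FALSE
  }
  check(pa, pa$hydrogens, pb) || check(pb, pb$hydrogens, pa)
}

#' Flag hydrogen-bonded contacts
#'
#' Sets the \code{hbond} flag of each contact using a geometric heavy-atom
#' criterion: a donor (N or O bearing a hydrogen; any N/O when the structure
#' has no hydrogens) within \code{dist_cutoff} of an acceptor (O, or a
#' histidine ring N) across the interface. When hydrogens are present the
#' D-H...A angle must additionally reach \code{angle_min} degrees.
#'
#' @param model The complex \code{StructureModel}.
#' @param spec The \code{\link{complex_spec}}.
#' @param contacts A \code{ContactSet} from \code{\link{find_contacts}}.
#' @param dist_cutoff Donor-acceptor heavy-atom distance cutoff (angstrom).
#' @param angle_min Minimum D-H...A angle in degrees (used only when
#'   hydrogens are present).
#' @return The contact set with \code{hbond} set.
#' @export
detect_hbonds <- function(model, spec, contacts, dist_cutoff = 3.5,
                          angle_min = 120) {
  contacts$hbond <- vapply(seq_len(nrow(contacts)), function(i) {
    a <- residue_atoms(model, contacts$receptor_chain[i],
                       contacts$receptor_resnum[i], contacts$receptor_icode[i])
    b <- residue_atoms(model, contacts$partner_chain[i],
                       contacts$partner_resnum[i], contacts$partner_icode[i])
    pair_has_hbond(a, b, dist_cutoff, angle_min)
  }, logical(1L))
  contacts
}

# side-chain charged-group heavy atoms
acidic_atoms <- function(ratoms) {
  ratoms[(ratoms$resname == "ASP" & ratoms$atom %in% c("OD1", "OD2")) |
           (ratoms$resname == "GLU" & ratoms$atom %in% c("OE1", "OE2")), ,
         drop = FALSE]
}

basic_atoms <- function(ratoms) {
  ratoms[(ratoms$resname == "LYS" & ratoms$atom == "NZ") |
           (ratoms$resname == "ARG" & ratoms$atom %in%
              c("NH1", "NH2", "NE")) |
           (ratoms$resname == "HIS" & ratoms$atom %in% c("ND1", "NE2")), ,
         drop = FALSE]
}

min_cross_dist2 <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(Inf)
  min(outer(a$x, b$x, "-")^2 + outer(a$y, b$y, "-")^2 +
        outer(a$z, b$z, "-")^2)
}

#' Flag salt-bridged contacts
#'
#' A contact is a salt bridge when an acidic side-chain oxygen (Asp OD1/OD2,
#' Glu OE1/OE2) on one side lies within \code{cutoff} of a basic side-chain
#' nitrogen (Lys NZ, Arg NH1/NH2/NE, His ND1/NE2) on the other, in either
#' direction. Histidine is counted as positively charged.
#'
#' @inheritParams detect_hbonds
#' @param cutoff Charged-group heavy-atom distance cutoff (angstrom).
#' @return The contact set with \code{saltbridge} set.
#' @export
detect_salt_bridges <- function(model, spec, contacts, cutoff = 4.0) {
  contacts$saltbridge <- vapply(seq_len(nrow(contacts)), function(i) {
    a <- residue_atoms(model, contacts$receptor_chain[i],
                       contacts$receptor_resnum[i], contacts$receptor_icode[i])
    b <- residue_atoms(model, contacts$partner_chain[i],
                       contacts$partner_resnum[i], contacts$partner_icode[i])
    min_cross_dist2(acidic_atoms(a), basic_atoms(b)) <= cutoff^2 ||
      min_cross_dist2(acidic_atoms(b), basic_atoms(a)) <= cutoff^2
  }, logical(1L))
  contacts
}

# van der Waals radii by element (angstrom); Bondi-style values
vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20, P = 1.80,
               F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)

# deterministic Fibonacci-sphere unit vectors: bit-stable across runs
fibonacci_sphere <- function(n) {
  i <- seq_len(n)
  z <- 1 - (2 * i - 1) / n
  phi <- (pi * (3 - sqrt(5))) * (i - 1)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom's sphere of radius r_vdw + probe is sampled with a deterministic
#' Fibonacci point set; the accessible area is the unoccluded point fraction
#' times the sphere area. Residue SASA is the sum over its atoms.
#'
#' @param model A \code{StructureModel}.
#' @param probe Probe (solvent) radius in angstrom, default 1.4 (water).
#' @param n_points Sphere sample points per atom (default 960; minimum 32).
#' @return Data frame \code{chain}, \code{resnum}, \code{icode},
#'   \code{resname}, \code{sasa} (angstrom squared), with the per-atom values
#'   in attribute \code{"atom_sasa"}.
#' @export
compute_sasa <- function(model, probe = 1.4, n_points = 960) {
  if (n_points < 32) stop("n_points must be at least 32")
  at <- model$atoms
  elem <- at$element
  r <- unname(vdw_radii[elem])
  if (anyNA(r)) {
    warning("unknown element(s) ", paste(unique(elem[is.na(r)]),
                                         collapse = ", "),
            ": using van der Waals radius 1.8 A")
    r[is.na(r)] <- 1.8
  }
  pts <- fibonacci_sphere(n_points)
  n <- nrow(at)
  xyz <- cbind(at$x, at$y, at$z)
  rexp <- r + probe
  atom_sasa <- numeric(n)
  for (i in seq_len(n)) {
    # neighbours whose expanded sphere can occlude points of sphere i
    d2 <- (xyz[, 1L] - xyz[i, 1L])^2 + (xyz[, 2L] - xyz[i, 2L])^2 +
      (xyz[, 3L] - xyz[i, 3L])^2
    nb <- which(d2 > 0 & d2 < (rexp[i] + rexp)^2)
    sp <- pts * rexp[i]
    sp[, 1L] <- sp[, 1L] + xyz[i, 1L]
    sp[, 2L] <- sp[, 2L] + xyz[i, 2L]
    sp[, 3L] <- sp[, 3L] + xyz[i, 3L]
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      occ <- (sp[free, 1L] - xyz[j, 1L])^2 + (sp[free, 2L] - xyz[j, 2L])^2 +
        (sp[free, 3L] - xyz[j, 3L])^2 < rexp[j]^2
      free[free] <- !occ
    }
    atom_sasa[i] <- sum(free) / n_points * 4 * pi * rexp[i]^2
  }
  rkey <- paste(at$chain, at$resnum, at$icode, sep = "\r")
  res <- residue_table(model)
  res$sasa <- as.numeric(tapply(atom_sasa, rkey, sum)[
    paste(res$chain, res$resnum, res$icode, sep = "\r")])
  attr(res, "atom_sasa") <- atom_sasa
  res
}

#' Buried interface surface area
#'
#' SASA(receptor alone) + SASA(partner alone) - SASA(complex), clamped at 0
#' (with a warning) if numerically negative.
#'
#' @inheritParams compute_sasa
#' @param spec A \code{\link{complex_spec}}.
#' @return Buried area in angstrom squared.
#' @export
buried_surface <- function(model, spec, probe = 1.4, n_points = 960) {
  halves <- split_complex(model, spec)
  total <- function(m) sum(compute_sasa(m, probe, n_points)$sasa)
  keep <- model$atoms$chain %in% c(spec$receptor_chains, spec$partner_chains)
  cplx <- new_structure_model(model$id, model$atoms[keep, , drop = FALSE])
  b <- total(halves$receptor) + total(halves$partner) - total(cplx)
  if (b < 0) {
    if (b < -1e-6) warning("negative buried surface clamped to 0")
    b <- 0
  }
  b
}

#' Interface residue composition
#'
#' Percentages of each amino acid and of the four physicochemical groups
#' (hydrophobic A,V,L,I,M,F,W,P,G; polar S,T,C,N,Q,Y; positive K,R,H;
#' negative D,E) among the unique interface residues of each side.
#'
#' @param contacts A \code{ContactSet} (or an \code{InterfaceProfile}).
#' @return List with elements \code{receptor} and \code{partner}, each a
#'   list of named numeric vectors \code{aa} and \code{group} summing to 100
#'   (empty sides give empty vectors).
#' @export
composition <- function(contacts) {
  if (inherits(contacts, "InterfaceProfile")) contacts <- contacts$contacts
  side <- function(prefix) {
    key <- paste(contacts[[paste0(prefix, "_chain")]],
                 contacts[[paste0(prefix, "_resnum")]],
                 contacts[[paste0(prefix, "_icode")]])
    aa <- contacts[[paste0(prefix, "_aa")]][!duplicated(key)]
    if (length(aa) == 0L) {
      return(list(aa = numeric(0), group = numeric(0)))
    }
    aa_pct <- 100 * table(aa) / length(aa)
    grp <- vapply(aa, function(a) {
      g <- names(aa_groups)[vapply(aa_groups, function(v) a %in% v,
                                   logical(1L))]
      if (length(g) == 0L) "other" else g
    }, character(1L))
    grp_pct <- 100 * table(grp) / length(grp)
    list(aa = c(unclass(aa_pct)), group = c(unclass(grp_pct)))
  }
  list(receptor = side("receptor"), partner = side("partner"))
}

#' Full interface profile of a complex
#'
#' Runs contact detection, hydrogen-bond and salt-bridge assignment, buried
#' surface area and composition in one pass.
#'
#' @param model The complex \code{StructureModel}.
#' @param spec The \code{\link{complex_spec}}.
#' @param mapping Optional \code{LabelMap} for generic labels.
#' @param complex_id Identifier stored on the profile.
#' @param config A \code{\link{run_config}} carrying the thresholds.
#' @return An \code{InterfaceProfile}: list with \code{complex_id},
#'   \code{contacts}, \code{n_hbonds}, \code{n_saltbridges},
#'   \code{buried_sasa}, \code{composition} and the \code{config} used.
#' @examples
#' toy <- make_toy_complex(n = 12, separation = 6)
#' map <- assign_labels(toy$model, toy$annotation)
#' interface_profile(toy$model, toy$spec, map, n_points = 120)
#' @export
interface_profile <- function(model, spec, mapping = NULL,
                              complex_id = model$id,
                              config = run_config(), n_points = NULL) {
  if (!is.null(n_points)) config$sasa_points <- n_points
  contacts <- find_contacts(model, spec, config$contact_cutoff, mapping)
  contacts <- detect_hbonds(model, spec, contacts, config$hbond_distance,
                            config$hbond_angle)
  contacts <- detect_salt_bridges(model, spec, contacts, config$sb_cutoff)
  prof <- list(
    complex_id = complex_id,
    contacts = contacts,
    n_hbonds = sum(contacts$hbond),
    n_saltbridges = sum(contacts$saltbridge),
    buried_sasa = buried_surface(model, spec, config$sasa_probe,
                                 config$sasa_points),
    composition = composition(contacts),
    config = config
  )
  class(prof) <- "InterfaceProfile"
  prof
}

#' @export
print.InterfaceProfile <- function(x, ...) {
  cat("InterfaceProfile '", x$complex_id, "': ", nrow(x$contacts),
      " contacts, ", x$n_hbonds, " H-bonds, ", x$n_saltbridges,
      " salt bridges, buried SASA ", sprintf("%.1f", x$buried_sasa),
      " A^2\n", sep = "")
  invisible(x)
}
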