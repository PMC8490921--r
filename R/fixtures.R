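# Synthetic-structure generators: geometric test articles, not physical
# models. Helices are ideal (rise 1.5 A/residue, 100 deg twist, CA radius
# 2.3 A); side chains beyond CB are synthesized only for charged residues,
# as idealized chains of atoms pointing radially away from the helix axis -
# enough to exercise salt-bridge / hydrogen-bond geometry without a rotamer
# library.

helix_rise <- 1.5      # A per residue along the axis
helix_twist <- 100     # degrees per residue
helix_radius <- 2.3    # CA distance from the axis

three_letter <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
                  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
                  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
                  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# charged side-chain atom chains grown outward from CB; (name, element,
# distance from CB along the outward radial, lateral offset in the
# tangential direction)
charged_sidechains <- list(
  ASP = list(c("CG", "C", 1.5, 0), c("OD1", "O", 2.4, 0.9),
             c("OD2", "O", 2.4, -0.9)),
  GLU = list(c("CG", "C", 1.5, 0), c("CD", "C", 2.9, 0),
             c("OE1", "O", 3.8, 0.9), c("OE2", "O", 3.8, -0.9)),
  LYS = list(c("CG", "C", 1.5, 0), c("CD", "C", 2.9, 0),
             c("CE", "C", 4.3, 0), c("NZ", "N", 5.7, 0)),
  ARG = list(c("CG", "C", 1.5, 0), c("CD", "C", 2.9, 0),
             c("NE", "N", 4.2, 0), c("CZ", "C", 5.4, 0),
             c("NH1", "N", 6.1, 1.0), c("NH2", "N", 6.1, -1.0)),
  HIS = list(c("CG", "C", 1.5, 0), c("ND1", "N", 2.7, 1.0),
             c("NE2", "N", 3.5, -0.5))
)

#' Generate an ideal poly-alanine helix
#'
#' Backbone atoms N, CA, C, O (plus CB for non-glycine) are placed on an
#' ideal alpha-helix: 1.5 angstrom rise and 100 degree twist per residue,
#' CA 2.3 angstrom from the axis, axis along z through the origin. Charged
#' residues (D, E, K, R, H) additionally receive idealized side-chain
#' atoms growing radially outward, so salt bridges form when two helices
#' face each other closely. Output is fully deterministic.
#'
#' @param n Number of residues (>= 1).
#' @param sequence Optional one-letter sequence of length \code{n}
#'   (default poly-Ala).
#' @param chain Chain identifier.
#' @param resnum_start First author residue number.
#' @param phase Rotation of the whole helix about its axis (degrees); use
#'   it to aim side chains of facing helices at each other.
#' @param origin 3-vector displacement applied to the whole helix.
#' @return A \code{StructureModel}.
#' @examples
#' h <- make_helix(10)
#' range(diff(ca_table(h)$z))  # ~1.5 A rise
#' @export
make_helix <- function(n, sequence = NULL, chain = "A", resnum_start = 1L,
                       phase = 0, origin = c(0, 0, 0)) {
  if (n < 1L) stop("n must be at least 1")
  if (is.null(sequence)) sequence <- strsplit(strrep("A", n), "")[[1L]]
  if (length(sequence) == 1L && nchar(sequence[1L]) > 1L) {
    sequence <- strsplit(sequence, "")[[1L]]
  }
  if (length(sequence) != n) stop("sequence length must equal n")
  bad <- setdiff(sequence, names(three_letter))
  if (length(bad) > 0L) {
    stop("invalid one-letter code(s): ", paste(unique(bad), collapse = ", "))
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    theta <- (phase + (i - 1L) * helix_twist) * pi / 180
    z0 <- (i - 1L) * helix_rise
    u <- c(cos(theta), sin(theta), 0)          # outward radial
    tg <- c(-sin(theta), cos(theta), 0)        # tangential
    ax <- c(0, 0, 1)
    ca <- helix_radius * u + c(0, 0, z0)
    resname <- three_letter[[sequence[i]]]
    atoms <- list(
      c("N", "N", list(ca - 0.9 * tg - 0.9 * ax - 0.5 * u)),
      c("CA", "C", list(ca)),
      c("C", "C", list(ca + 0.9 * tg + 0.7 * ax - 0.4 * u)),
      c("O", "O", list(ca + 0.9 * tg + 1.9 * ax - 0.5 * u))
    )
    if (resname != "GLY") {
      atoms <- c(atoms, list(c("CB", "C", list(ca + 1.45 * u + 0.5 * ax))))
    }
    sc <- charged_sidechains[[resname]]
    if (!is.null(sc)) {
      cb <- ca + 1.45 * u + 0.5 * ax
      for (a in sc) {
        p <- cb + as.numeric(a[[3L]]) * u + as.numeric(a[[4L]]) * tg
        atoms <- c(atoms, list(c(a[[1L]], a[[2L]], list(p))))
      }
    }
    rows[[i]] <- do.call(rbind, lapply(atoms, function(a) {
      p <- a[[3L]] + origin
      data.frame(chain = chain, resnum = resnum_start + i - 1L, icode = "",
                 resname = resname, atom = a[[1L]], element = a[[2L]],
                 x = p[1L], y = p[2L], z = p[3L], occ = 1, b = 0,
                 stringsAsFactors = FALSE)
    }))
  }
  new_structure_model(paste0("helix_", chain), do.call(rbind, rows))
}

# brute-force CA contact oracle used at construction time (independent of
# find_contacts): plain double loop over residues
brute_force_contacts <- function(model, spec, cutoff = 8.0) {
  ca <- ca_table(model)
  r <- ca[ca$chain %in% spec$receptor_chains, , drop = FALSE]
  p <- ca[ca$chain %in% spec$partner_chains, , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(r))) {
    for (j in seq_len(nrow(p))) {
      d <- sqrt((r$x[i] - p$x[j])^2 + (r$y[i] - p$y[j])^2 +
                  (r$z[i] - p$z[j])^2)
      if (d <= cutoff) {
        out <- rbind(out, data.frame(
          receptor_chain = r$chain[i], receptor_resnum = r$resnum[i],
          partner_chain = p$chain[j], partner_resnum = p$resnum[j],
          ca_distance = d, stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) {
    out <- data.frame(receptor_chain = character(0),
                      receptor_resnum = integer(0),
                      partner_chain = character(0),
                      partner_resnum = integer(0),
                      ca_distance = numeric(0), stringsAsFactors = FALSE)
  }
  out[order(out$receptor_resnum, out$partner_resnum), , drop = FALSE]
}

#' Generate a toy receptor-partner complex with known ground truth
#'
#' Two parallel ideal helices at a controlled axis separation: chain R (the
#' "receptor", annotated as a TM3 span with a central X.50 anchor) and chain
#' A (the "partner", annotated as an H5 span with positional numbering).
#' The expected contact set is computed at construction time by an
#' independent brute-force double loop, so the complex doubles as an oracle
#' for the interface module. With \code{sequence = "random"} both sequences
#' are drawn reproducibly from the seed, always including charged residues.
#'
#' @param n Residues per helix.
#' @param separation Axis-to-axis distance in angstrom (>= 0).
#' @param seed Integer seed for random sequences.
#' @param sequence \code{NULL} (poly-Ala), \code{"random"}, or a list with
#'   elements \code{receptor} and \code{partner} (one-letter strings).
#' @param cutoff Contact cutoff used for the ground-truth set.
#' @return List with \code{model} (two-chain \code{StructureModel}),
#'   \code{spec} (\code{ComplexSpec}), \code{annotation}
#'   (\code{AnnotationTable}), and \code{expected_contacts} (brute-force
#'   contact table).
#' @examples
#' toy <- make_toy_complex(n = 12, separation = 6)
#' nrow(toy$expected_contacts) > 0
#' @export
make_toy_complex <- function(n = 20L, separation = 8, seed = 1L,
                             sequence = NULL, cutoff = 8.0) {
  if (separation < 0) stop("separation must be non-negative")
  if (identical(sequence, "random")) {
    set.seed(seed)
    alphabet <- names(three_letter)
    sequence <- list(
      receptor = sample(alphabet, n, replace = TRUE),
      partner = sample(alphabet, n, replace = TRUE))
    # guarantee charged residues mid-helix so SB fixtures are exercised
    mid <- max(1L, n %/% 2L)
    sequence$receptor[mid] <- "D"
    sequence$partner[mid] <- "K"
  }
  seq_r <- if (is.list(sequence)) sequence$receptor else NULL
  seq_p <- if (is.list(sequence)) sequence$partner else NULL
  # facing phases: receptor side chains point +x, partner side chains -x
  receptor <- make_helix(n, seq_r, chain = "R", resnum_start = 101L,
                         phase = 0, origin = c(0, 0, 0))
  partner <- make_helix(n, seq_p, chain = "A", resnum_start = 301L,
                        phase = 180, origin = c(separation, 0, 0))
  model <- new_structure_model(
    sprintf("toy_n%d_sep%g_seed%d", n, separation, seed),
    rbind(receptor$atoms, partner$atoms))
  spec <- complex_spec("R", "A")
  anchor <- 101L + n %/% 2L
  annotation <- annotation_table(data.frame(
    chain = c("R", "A"), subdomain = c("TM3", "H5"),
    start = c(101L, 301L), end = c(101L + n - 1L, 301L + n - 1L),
    anchor = c(anchor, NA), stringsAsFactors = FALSE))
  list(model = model, spec = spec, annotation = annotation,
       expected_contacts = brute_force_contacts(model, spec, cutoff))
}

#' Generate a charged-pair fixture with exactly one salt bridge
#'
#' A single aspartate (chain R) facing a single lysine (chain A), with the
#' terminal charged atoms (OD1/OD2 vs NZ) separated by \code{gap} angstrom.
#'
#' @param gap Distance between the closest charged heavy atoms (angstrom).
#' @return List with \code{model} and \code{spec}.
#' @export
make_charged_pair <- function(gap = 3.0) {
  asp <- make_helix(1L, "D", chain = "R", resnum_start = 1L, phase = 0)
  # outward side-chain tips: ASP OD1/OD2 at radius + 1.45 + 2.4 (with a
  # 0.9 A lateral offset), LYS NZ at radius + 1.45 + 5.7 on axis
  asp_tip <- helix_radius + 1.45 + 2.4
  lys_tip <- helix_radius + 1.45 + 5.7
  lys <- make_helix(1L, "K", chain = "A", resnum_start = 1L, phase = 180,
                    origin = c(asp_tip + lys_tip + gap, 0, 0))
  model <- new_structure_model(sprintf("charged_pair_gap%g", gap),
                               rbind(asp$atoms, lys$atoms))
  # NZ sits on the x axis, OD1/OD2 are offset laterally by 0.9 A
  list(model = model, spec = complex_spec("R", "A"),
       charged_distance = sqrt(gap^2 + 0.9^2),
       ca_distance = asp_tip + lys_tip + gap - 2 * helix_radius)
}
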