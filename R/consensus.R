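#' Cross-complex interaction matrix
#'
#' Collects the labeled contact pairs of several interface profiles into one
#' presence matrix keyed by (receptor label, partner label). Unlabeled
#' residues participate under their author label.
#'
#' @param profiles List of \code{InterfaceProfile}s with distinct
#'   \code{complex_id}s, labeled on compatible schemes.
#' @return An \code{InteractionMatrix}: list with \code{complexes} (ordered
#'   ids) and \code{table}, a long data frame with one row per (cell,
#'   complex) where the interaction is present: \code{receptor_label},
#'   \code{partner_label}, \code{complex_id}, \code{receptor_aa},
#'   \code{partner_aa}.
#' @export
build_matrix <- function(profiles) {
  if (length(profiles) == 0L) stop("at least one profile required")
  ids <- vapply(profiles, function(p) p$complex_id, character(1L))
  if (anyDuplicated(ids)) {
    stop("duplicate complex id(s): ", paste(unique(ids[duplicated(ids)]),
                                            collapse = ", "))
  }
  rows <- lapply(profiles, function(p) {
    ct <- p$contacts
    if (nrow(ct) == 0L) return(NULL)
    df <- data.frame(receptor_label = ct$receptor_label,
                     partner_label = ct$partner_label,
                     complex_id = p$complex_id,
                     receptor_aa = ct$receptor_aa,
                     partner_aa = ct$partner_aa,
                     stringsAsFactors = FALSE)
    df[!duplicated(paste(df$receptor_label, df$partner_label, sep = "\r")), ,
       drop = FALSE]
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(receptor_label = character(0),
                      partner_label = character(0),
                      complex_id = character(0),
                      receptor_aa = character(0),
                      partner_aa = character(0), stringsAsFactors = FALSE)
  }
  rownames(tab) <- NULL
  structure(list(complexes = unname(ids), table = tab),
            class = "InteractionMatrix")
}

#' @export
print.InteractionMatrix <- function(x, ...) {
  ncell <- nrow(unique(x$table[, c("receptor_label", "partner_label")]))
  cat("InteractionMatrix: ", length(x$complexes), " complex(es), ",
      ncell, " labeled pair(s)\n", sep = "")
  invisible(x)
}

#' Filter to interactions common across complexes
#'
#' Keeps the cells present in at least \code{min_fraction} of the complexes.
#' The default 1.0 keeps only the interactions shared by every complex (the
#' usual consensus view across a receptor family).
#'
#' @param matrix An \code{InteractionMatrix}.
#' @param min_fraction Required presence fraction in (0, 1].
#' @return Filtered \code{InteractionMatrix} (same complexes).
#' @export
common_interactions <- function(matrix, min_fraction = 1.0) {
  stopifnot(inherits(matrix, "InteractionMatrix"))
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    stop("min_fraction must be in (0, 1]")
  }
  tab <- matrix$table
  cell <- paste(tab$receptor_label, tab$partner_label, sep = "\r")
  count <- tapply(tab$complex_id, cell, function(v) length(unique(v)))
  keep_cells <- names(count)[count / length(matrix$complexes) >=
                               min_fraction - 1e-12]
  matrix$table <- tab[cell %in% keep_cells, , drop = FALSE]
  rownames(matrix$table) <- NULL
  matrix
}

# split "34.50" / "H5.12" / "R:131" into subdomain prefix and position index
parse_label <- function(label) {
  m <- regmatches(label, regexec("^(.*)\\.([0-9]+)$", label))[[1L]]
  if (length(m) == 0L) return(NULL)
  list(prefix = m[2L], index = as.integer(m[3L]))
}

#' Per-position residue sets of one subdomain of an interaction matrix
#'
#' Walks the label positions of one subdomain (on the receptor or partner
#' side) between the first and last interacting position, collecting for
#' each position the residue alternatives observed across complexes (ordered
#' by first appearance in the complex ordering).
#'
#' @param matrix An \code{InteractionMatrix} (usually after
#'   \code{\link{common_interactions}}).
#' @param prefix Label prefix selecting the subdomain, e.g. \code{"34"}
#'   (intracellular loop 2) or \code{"H5"}.
#' @param side \code{"receptor"} or \code{"partner"}: which side of the pair
#'   the prefix refers to.
#' @return Data frame \code{label}, \code{index}, \code{residues}
#'   (slash-collapsed alternatives), \code{interacting} suitable for
#'   \code{\link{format_motif}}.
#' @export
motif_positions <- function(matrix, prefix, side = c("receptor", "partner")) {
  side <- match.arg(side)
  tab <- matrix$table
  lab_col <- paste0(side, "_label")
  aa_col <- paste0(side, "_aa")
  parsed <- lapply(tab[[lab_col]], parse_label)
  hit <- vapply(parsed, function(p) !is.null(p) && p$prefix == prefix,
                logical(1L))
  if (!any(hit)) {
    stop("no interacting positions with prefix '", prefix, "' on the ",
         side, " side")
  }
  idx <- vapply(parsed[hit], function(p) p$index, integer(1L))
  ord <- order(match(tab$complex_id[hit], matrix$complexes))
  aa_by_idx <- split(tab[[aa_col]][hit][ord], idx[ord])
  span <- seq(min(idx), max(idx))
  residues <- vapply(span, function(i) {
    v <- aa_by_idx[[as.character(i)]]
    if (is.null(v)) "" else paste(unique(v), collapse = "/")
  }, character(1L))
  # partner positional labels are zero-padded to two digits (H5.01 style)
  idx_txt <- if (grepl("^[0-9]+$", prefix)) as.character(span) else
    sprintf("%02d", span)
  data.frame(label = paste0(prefix, ".", idx_txt),
             index = span, residues = residues,
             interacting = nzchar(residues), stringsAsFactors = FALSE)
}

#' Render a consensus motif string
#'
#' Produces the compact wildcard notation used for interface motifs: the
#' walk runs from the first to the last interacting position; an interacting
#' position contributes its residue letter (alternatives across complexes
#' slash-joined in order of first appearance), a run of m interior
#' non-interacting positions contributes the wildcard \code{x} with
#' multiplicity m (\code{x2} for two skipped positions), adjacent
#' single-letter interacting positions fuse (\code{LD}), and the first and
#' last interacting positions carry their generic label. Tokens are joined
#' with an en dash, e.g. \code{P34.50-V/I-x2-LD34.55} (dashes rendered as
#' en dashes).
#'
#' @param positions Either a data frame with columns \code{label},
#'   \code{index}, \code{residues} (slash-joined alternatives, \code{""} if
#'   non-interacting) and \code{interacting}, as produced by
#'   \code{\link{motif_positions}}, or an \code{InteractionMatrix} (then
#'   \code{prefix} and \code{side} select the subdomain).
#' @param prefix,side Passed to \code{\link{motif_positions}} when
#'   \code{positions} is an \code{InteractionMatrix}.
#' @return A \code{MotifPattern}: list with \code{positions} and
#'   \code{rendered} (the motif string).
#' @export
format_motif <- function(positions, prefix = NULL,
                         side = c("receptor", "partner")) {
  if (inherits(positions, "InteractionMatrix")) {
    positions <- motif_positions(positions, prefix, side)
  }
  stopifnot(all(c("label", "index", "residues", "interacting") %in%
                  names(positions)))
  if (!any(positions$interacting)) {
    stop("motif range contains no interacting position")
  }
  first <- min(which(positions$interacting))
  last <- max(which(positions$interacting))
  pos <- positions[first:last, , drop = FALSE]
  # tokens: fused runs of single-letter interacting positions, slash groups,
  # and wildcard runs
  tokens <- character(0)
  token_first <- integer(0)   # row index of first position in token
  token_last <- integer(0)
  i <- 1L
  while (i <= nrow(pos)) {
    if (!pos$interacting[i]) {
      j <- i
      while (j < nrow(pos) && !pos$interacting[j + 1L]) j <- j + 1L
      m <- j - i + 1L
      tokens <- c(tokens, if (m == 1L) "x" else paste0("x", m))
      token_first <- c(token_first, NA_integer_)
      token_last <- c(token_last, NA_integer_)
      i <- j + 1L
    } else if (nchar(pos$residues[i]) == 1L) {
      j <- i
      while (j < nrow(pos) && pos$interacting[j + 1L] &&
             nchar(pos$residues[j + 1L]) == 1L) j <- j + 1L
      tokens <- c(tokens, paste(pos$residues[i:j], collapse = ""))
      token_first <- c(token_first, i)
      token_last <- c(token_last, j)
      i <- j + 1L
    } else {
      tokens <- c(tokens, pos$residues[i])
      token_first <- c(token_first, i)
      token_last <- c(token_last, i)
      i <- i + 1L
    }
  }
  # superscript labels on the first and last interacting positions; when a
  # single token spans the whole motif it carries the terminal label only
  tf <- which(!is.na(token_first))[1L]
  tl <- rev(which(!is.na(token_last)))[1L]
  tokens[tl] <- paste0(tokens[tl], pos$label[nrow(pos)])
  if (tf != tl) tokens[tf] <- paste0(tokens[tf], pos$label[1L])
  structure(list(positions = pos,
                 rendered = paste(tokens, collapse = "\u2013")),
            class = "MotifPattern")
}

#' @export
print.MotifPattern <- function(x, ...) {
  cat(x$rendered, "\n")
  invisible(x)
}

#' Long-format export of an interaction matrix
#'
#' One row per (cell, complex) including absent combinations, suitable for
#' heatmap plotting; deterministic row order (receptor label, partner label,
#' complex order).
#'
#' @param matrix An \code{InteractionMatrix}.
#' @return Data frame \code{receptor_label}, \code{partner_label},
#'   \code{complex_id}, \code{present}, \code{receptor_aa},
#'   \code{partner_aa} (empty strings when absent).
#' @export
export_heatmap_table <- function(matrix) {
  stopifnot(inherits(matrix, "InteractionMatrix"))
  tab <- matrix$table
  cells <- unique(tab[, c("receptor_label", "partner_label")])
  cells <- cells[order(cells$receptor_label, cells$partner_label), ,
                 drop = FALSE]
  if (nrow(cells) == 0L) {
    return(data.frame(receptor_label = character(0),
                      partner_label = character(0),
                      complex_id = character(0), present = logical(0),
                      receptor_aa = character(0),
                      partner_aa = character(0), stringsAsFactors = FALSE))
  }
  out <- merge(cbind(cells[rep(seq_len(nrow(cells)),
                               each = length(matrix$complexes)), ],
                     complex_id = rep(matrix$complexes, nrow(cells))),
               cbind(tab, present = TRUE),
               by = c("receptor_label", "partner_label", "complex_id"),
               all.x = TRUE, sort = FALSE)
  out$present[is.na(out$present)] <- FALSE
  out$receptor_aa[is.na(out$receptor_aa)] <- ""
  out$partner_aa[is.na(out$partner_aa)] <- ""
  out <- out[order(out$receptor_label, out$partner_label,
                   match(out$complex_id, matrix$complexes)),
             c("receptor_label", "partner_label", "complex_id", "present",
               "receptor_aa", "partner_aa")]
  rownames(out) <- NULL
  out
}

#' Rebuild an interaction matrix from its long-format export
#'
#' Exact inverse of \code{\link{export_heatmap_table}} (complex order taken
#' from first appearance unless given).
#'
#' @param table Data frame as produced by \code{\link{export_heatmap_table}}.
#' @param complexes Optional ordered complex ids.
#' @return An \code{InteractionMatrix}.
#' @export
import_heatmap_table <- function(table, complexes = unique(table$complex_id)) {
  tab <- table[table$present, c("receptor_label", "partner_label",
                                "complex_id", "receptor_aa", "partner_aa"),
               drop = FALSE]
  rownames(tab) <- NULL
  structure(list(complexes = complexes, table = tab),
            class = "InteractionMatrix")
}
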