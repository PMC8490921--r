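#' Interhelical / inter-subdomain distance
#'
#' Distance between two points of a receptor defined either by generic
#' residue labels (CA-CA distance, \code{mode = "residue_ca"}) or by
#' subdomain names (distance between the CA centroids of the two spans,
#' \code{mode = "span_centroid"}). Typical use: monitoring the cytosolic
#' opening between TM3 and TM6 (e.g. labels 3.50 and 6.30) that widens upon
#' receptor activation. The residue pair is always caller-specified.
#'
#' @param model A \code{StructureModel}.
#' @param mapping A \code{LabelMap} from \code{\link{assign_labels}}.
#' @param a,b Generic labels (\code{residue_ca}) or subdomain names
#'   (\code{span_centroid}).
#' @param mode \code{"residue_ca"} or \code{"span_centroid"}.
#' @return A \code{DistanceReport}: list with \code{pair}, \code{mode} and
#'   \code{value} (angstrom).
#' @export
interhelical_distance <- function(model, mapping, a, b,
                                  mode = c("residue_ca", "span_centroid")) {
  mode <- match.arg(mode)
  ca <- ca_table(model)
  point <- function(what) {
    if (mode == "residue_ca") {
      res <- label_lookup(mapping, what)
      if (is.null(res)) stop("label '", what, "' not found in mapping")
      hit <- ca$chain == res$chain & ca$resnum == res$resnum &
        ca$icode == res$icode
      if (!any(hit)) stop("residue for label '", what, "' has no CA atom")
      c(ca$x[hit][1L], ca$y[hit][1L], ca$z[hit][1L])
    } else {
      rows <- mapping[!is.na(mapping$subdomain) & mapping$subdomain == what, ]
      if (nrow(rows) == 0L) stop("subdomain '", what, "' not in mapping")
      hit <- paste(ca$chain, ca$resnum, ca$icode) %in%
        paste(rows$chain, rows$resnum, rows$icode)
      if (!any(hit)) stop("subdomain '", what, "' has no CA atoms")
      c(mean(ca$x[hit]), mean(ca$y[hit]), mean(ca$z[hit]))
    }
  }
  value <- sqrt(sum((point(a) - point(b))^2))
  structure(list(pair = c(a, b), mode = mode, value = value),
            class = "DistanceReport")
}

#' @export
print.DistanceReport <- function(x, ...) {
  cat(sprintf("%s [%s]: %.3f A\n", paste(x$pair, collapse = " - "),
              x$mode, x$value))
  invisible(x)
}

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' paired coordinate sets (reflections are corrected via the SVD determinant
#' sign). The fitted mobile set is \code{mobile \%*\% rotation + translation}
#' (row vectors).
#'
#' @param reference,mobile Numeric n x 3 matrices of paired coordinates,
#'   n >= 3, not collinear.
#' @return A \code{SuperpositionResult}: list with \code{rotation} (3 x 3,
#'   determinant +1), \code{translation} (length 3), \code{rmsd} (angstrom)
#'   and \code{n_atoms}.
#' @examples
#' x <- matrix(rnorm(30), ncol = 3)
#' superpose(x, x)$rmsd  # 0
#' @export
superpose <- function(reference, mobile) {
  reference <- as.matrix(reference)
  mobile <- as.matrix(mobile)
  if (ncol(reference) != 3L || ncol(mobile) != 3L) {
    stop("coordinate sets must be n x 3 matrices")
  }
  if (nrow(reference) != nrow(mobile)) {
    stop("coordinate sets must have equal length")
  }
  if (nrow(reference) < 3L) stop("at least 3 paired points required")
  cr <- colMeans(reference)
  cm <- colMeans(mobile)
  X <- sweep(mobile, 2L, cm)
  Y <- sweep(reference, 2L, cr)
  s <- svd(crossprod(X, Y))          # X^T Y = U D V^T
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1                 # degenerate (collinear) input
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- X %*% R
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(cr - cm %*% R),
                 rmsd = rmsd, n_atoms = nrow(reference)),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("Superposition over %d atoms: RMSD %.4f A\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a superposition to coordinates
#'
#' @param result A \code{SuperpositionResult}.
#' @param coords n x 3 matrix.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(result, coords) {
  sweep(as.matrix(coords) %*% result$rotation, 2L, -result$translation)
}
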