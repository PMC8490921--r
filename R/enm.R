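#' Build a C-alpha elastic network
#'
#' Nodes are the model's alpha-carbons; a harmonic spring of uniform force
#' constant \code{gamma} connects every node pair within \code{cutoff}
#' (anisotropic network model).
#'
#' @param model A \code{StructureModel} with at least 2 CA atoms.
#' @param cutoff Spring distance cutoff in angstrom (default 12).
#' @param gamma Uniform spring constant (arbitrary units, default 1).
#' @return An \code{ElasticNetwork}: list with \code{nodes} (data frame
#'   \code{chain}, \code{resnum}, \code{icode}, \code{x}, \code{y},
#'   \code{z}), \code{springs} (two-column index matrix i < j),
#'   \code{cutoff}, \code{gamma} and \code{connected} flag.
#' @export
build_network <- function(model, cutoff = 12.0, gamma = 1.0) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (gamma <= 0) stop("gamma must be positive")
  ca <- ca_table(model)
  n <- nrow(ca)
  if (n < 2L) stop("elastic network needs at least 2 CA atoms")
  xyz <- cbind(ca$x, ca$y, ca$z)
  d2 <- as.matrix(stats::dist(xyz))^2
  pair <- which(upper.tri(d2) & d2 <= cutoff^2, arr.ind = TRUE)
  net <- list(nodes = ca[, c("chain", "resnum", "icode", "x", "y", "z")],
              springs = unname(pair), cutoff = cutoff, gamma = gamma)
  net$connected <- length(network_components(n, pair)) == 1L
  if (!net$connected) {
    warning("elastic network is disconnected at cutoff ", cutoff, " A")
  }
  class(net) <- "ElasticNetwork"
  net
}

# connected components via breadth-first search over the spring list
network_components <- function(n, springs) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(springs))) {
    i <- springs[k, 1L]; j <- springs[k, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cid
      queue <- c(queue, new)
    }
  }
  split(seq_len(n), comp)
}

# 3N x 3N ANM Hessian: off-diagonal super-elements -gamma (d d^T)/|d|^2,
# diagonal blocks minus the sum of the row's off-diagonal blocks
anm_hessian <- function(network) {
  nodes <- network$nodes
  n <- nrow(nodes)
  H <- matrix(0, 3L * n, 3L * n)
  xyz <- cbind(nodes$x, nodes$y, nodes$z)
  for (k in seq_len(nrow(network$springs))) {
    i <- network$springs[k, 1L]; j <- network$springs[k, 2L]
    d <- xyz[j, ] - xyz[i, ]
    blk <- -network$gamma * tcrossprod(d) / sum(d^2)
    ii <- (3L * i - 2L):(3L * i)
    jj <- (3L * j - 2L):(3L * j)
    H[ii, jj] <- H[ii, jj] + blk
    H[jj, ii] <- H[jj, ii] + blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  H
}

#' Normal modes of an elastic network
#'
#' Assembles the anisotropic-network-model Hessian and diagonalizes it.
#' A connected three-dimensional network has exactly six zero-frequency
#' rigid-body modes; these are identified by an eigenvalue threshold of
#' 1e-6 relative to the largest eigenvalue, and their count is verified.
#'
#' @param network An \code{ElasticNetwork} from \code{\link{build_network}}.
#' @return A \code{ModeSet}: list with \code{values} (eigenvalues ascending,
#'   units of gamma), \code{vectors} (3N x 3N orthonormal columns, matching
#'   order), \code{rigid} (logical marking rigid-body modes) and the node
#'   table.
#' @export
compute_modes <- function(network) {
  stopifnot(inherits(network, "ElasticNetwork"))
  if (!network$connected) {
    comps <- network_components(nrow(network$nodes), network$springs)
    sizes <- vapply(comps, length, integer(1L))
    stop("elastic network is disconnected (component sizes: ",
         paste(sizes, collapse = ", "), "); increase the cutoff")
  }
  H <- anm_hessian(network)
  eig <- eigen(H, symmetric = TRUE)
  ord <- rev(seq_along(eig$values))
  values <- eig$values[ord]
  vectors <- eig$vectors[, ord, drop = FALSE]
  values[values < 0 & values > -1e-8] <- 0
  rigid <- values < 1e-6 * max(values)
  # a 3-D structure has 6 rigid-body modes; collinear point sets only 5
  # (rotation about the axis is trivial), a single point 3
  xyz <- cbind(network$nodes$x, network$nodes$y, network$nodes$z)
  sv <- svd(sweep(xyz, 2L, colMeans(xyz)))$d
  rank <- sum(sv > 1e-8 * max(sv, 1))
  expected <- c(3L, 5L, 6L, 6L)[rank + 1L]
  if (sum(rigid) != expected) {
    stop("expected ", expected, " rigid-body modes, found ", sum(rigid),
         " (near-degenerate spectrum?)")
  }
  structure(list(values = values, vectors = vectors, rigid = rigid,
                 nodes = network$nodes, gamma = network$gamma),
            class = "ModeSet")
}

#' @export
print.ModeSet <- function(x, ...) {
  nz <- x$values[!x$rigid]
  cat("ModeSet: ", length(x$values), " modes over ", nrow(x$nodes),
      " nodes; ", sum(x$rigid), " rigid-body; lowest internal eigenvalue ",
      sprintf("%.4g", nz[1L]), "\n", sep = "")
  invisible(x)
}

#' Per-residue mean-square fluctuations from a mode set
#'
#' MSF_i = sum over internal (non-rigid) modes k of (1/lambda_k) x the
#' squared norm of mode k restricted to node i - i.e. the per-node trace of
#' the Hessian pseudo-inverse. Units are 1/gamma (arbitrary).
#'
#' @param modes A \code{ModeSet}.
#' @return A \code{FluctuationProfile}: data frame \code{chain},
#'   \code{resnum}, \code{icode}, \code{msf}, \code{msf_norm} (msf divided
#'   by its mean).
#' @export
fluctuations <- function(modes) {
  stopifnot(inherits(modes, "ModeSet"))
  keep <- !modes$rigid
  v <- modes$vectors[, keep, drop = FALSE]
  w <- sweep(v^2, 2L, modes$values[keep], "/")
  per_coord <- rowSums(w)
  n <- nrow(modes$nodes)
  msf <- per_coord[3L * seq_len(n) - 2L] + per_coord[3L * seq_len(n) - 1L] +
    per_coord[3L * seq_len(n)]
  out <- modes$nodes[, c("chain", "resnum", "icode")]
  out$msf <- msf
  out$msf_norm <- msf / mean(msf)
  class(out) <- c("FluctuationProfile", "data.frame")
  out
}

#' Monomer-versus-complex fluctuation change
#'
#' Difference in mean-square fluctuation (complex minus monomer) over the
#' nodes shared by chain and residue number. Because absolute elastic-network
#' fluctuations are in arbitrary 1/gamma units, the delta is reported both
#' raw and after per-structure normalization (MSF / mean MSF).
#'
#' @param monomer_profile,complex_profile \code{FluctuationProfile}s.
#' @return Data frame \code{chain}, \code{resnum}, \code{icode},
#'   \code{msf_monomer}, \code{msf_complex}, \code{delta},
#'   \code{delta_norm}; unmatched nodes are listed in attribute
#'   \code{"unmatched"}.
#' @export
delta_fluctuations <- function(monomer_profile, complex_profile) {
  key <- function(p) paste(p$chain, p$resnum, p$icode, sep = "\r")
  km <- key(monomer_profile)
  kc <- key(complex_profile)
  shared <- intersect(km, kc)
  if (length(shared) == 0L) {
    stop("no shared (chain, resnum) nodes between the two profiles")
  }
  im <- match(shared, km)
  ic <- match(shared, kc)
  out <- monomer_profile[im, c("chain", "resnum", "icode")]
  out$msf_monomer <- monomer_profile$msf[im]
  out$msf_complex <- complex_profile$msf[ic]
  out$delta <- out$msf_complex - out$msf_monomer
  out$delta_norm <- complex_profile$msf_norm[ic] - monomer_profile$msf_norm[im]
  rownames(out) <- NULL
  attr(out, "unmatched") <- list(
    monomer_only = monomer_profile[!(km %in% shared),
                                   c("chain", "resnum", "icode")],
    complex_only = complex_profile[!(kc %in% shared),
                                   c("chain", "resnum", "icode")])
  out
}
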