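# Shared test fixtures and independent oracles. Oracles are deliberately
# written as plain loops so they share no code path with the package
# implementations they check.

# CA-only structure with residues scattered uniformly in a box
random_ca_structure <- function(n, seed, chains = "A", box = 30) {
  set.seed(seed)
  chain <- sample(chains, n, replace = TRUE)
  atoms <- data.frame(
    chain = chain, resnum = seq_len(n), icode = "",
    resname = sample(c("ALA", "GLY", "LEU", "SER", "ASP", "LYS"), n,
                     replace = TRUE),
    atom = "CA", element = "C",
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    occ = 1, b = 0, stringsAsFactors = FALSE)
  atoms <- atoms[order(atoms$chain, atoms$resnum), ]
  rownames(atoms) <- NULL
  gpcriface:::new_structure_model(paste0("rand", seed), atoms)
}

# plain-loop CA contact oracle
oracle_contacts <- function(model, spec, cutoff = 8) {
  ca <- ca_table(model)
  r <- ca[ca$chain %in% spec$receptor_chains, ]
  p <- ca[ca$chain %in% spec$partner_chains, ]
  pairs <- character(0)
  for (i in seq_len(nrow(r))) {
    for (j in seq_len(nrow(p))) {
      d <- sqrt((r$x[i] - p$x[j])^2 + (r$y[i] - p$y[j])^2 +
                  (r$z[i] - p$z[j])^2)
      if (d <= cutoff) {
        pairs <- c(pairs, paste(r$chain[i], r$resnum[i], "|",
                                p$chain[j], p$resnum[j]))
      }
    }
  }
  sort(pairs)
}

contact_keys <- function(contacts) {
  sort(paste(contacts$receptor_chain, contacts$receptor_resnum, "|",
             contacts$partner_chain, contacts$partner_resnum))
}

# uniformly random unit vectors (Monte Carlo sphere sampling for the SASA
# reference; independent of the deterministic Fibonacci set in the package)
random_sphere_points <- function(n, seed) {
  set.seed(seed)
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# two-sphere SASA reference by dense Monte Carlo sampling
mc_two_atom_sasa <- function(centers, radii, probe = 1.4, n = 100000,
                             seed = 42) {
  pts <- random_sphere_points(n, seed)
  total <- 0
  for (i in 1:2) {
    rexp <- radii[i] + probe
    sp <- sweep(pts * rexp, 2L, centers[i, ], "+")
    j <- 3L - i
    rj <- radii[j] + probe
    free <- rowSums(sweep(sp, 2L, centers[j, ])^2) >= rj^2
    total <- total + mean(free) * 4 * pi * rexp^2
  }
  total
}

# minimal single-atom model helper
atom_model <- function(df, id = "m") {
  defaults <- data.frame(chain = "A", resnum = 1L, icode = "",
                         resname = "ALA", atom = "CA", element = "C",
                         x = 0, y = 0, z = 0, occ = 1, b = 0,
                         stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    r <- defaults
    for (k in names(df)) r[[k]] <- df[[k]][i]
    r
  })
  gpcriface:::new_structure_model(id, do.call(rbind, rows))
}

# random interface profile (synthetic contacts only) for consensus tests
random_profile <- function(id, seed, labels_r = paste0("3.", 48:54),
                           labels_p = paste0("H5.", 20:26)) {
  set.seed(seed)
  n <- sample(3:8, 1L)
  contacts <- data.frame(
    receptor_chain = "R",
    receptor_resnum = sample(100:200, n),
    receptor_icode = "",
    receptor_aa = sample(c("A", "L", "D", "R", "T"), n, replace = TRUE),
    receptor_label = sample(labels_r, n, replace = TRUE),
    partner_chain = "A",
    partner_resnum = sample(300:400, n),
    partner_icode = "",
    partner_aa = sample(c("I", "K", "E", "S", "V"), n, replace = TRUE),
    partner_label = sample(labels_p, n, replace = TRUE),
    ca_distance = runif(n, 4, 8), hbond = FALSE, saltbridge = FALSE,
    stringsAsFactors = FALSE)
  structure(list(complex_id = id, contacts = contacts,
                 n_hbonds = 0L, n_saltbridges = 0L, buried_sasa = 0,
                 composition = composition(contacts),
                 config = run_config()),
            class = "InterfaceProfile")
}
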