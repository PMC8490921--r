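test_that("contact detection matches the brute-force oracle and is symmetric", {
  for (seed in 1:6) {
    m <- random_ca_structure(60, seed, chains = c("R", "A"), box = 25)
    spec <- complex_spec("R", "A")
    ct <- find_contacts(m, spec)
    expect_identical(contact_keys(ct), oracle_contacts(m, spec))
    # symmetry under swapping receptor/partner roles
    swapped <- find_contacts(m, complex_spec("A", "R"))
    expect_identical(
      sort(paste(ct$receptor_resnum, ct$partner_resnum)),
      sort(paste(swapped$partner_resnum, swapped$receptor_resnum)))
  }
})

test_that("the 8 A cutoff boundary is inclusive", {
  m <- atom_model(data.frame(chain = c("R", "A", "A"),
                             resnum = c(1L, 1L, 2L),
                             x = c(0, 8.0, 0), y = c(0, 0, 8.000001)))
  ct <- find_contacts(m, complex_spec("R", "A"))
  expect_equal(nrow(ct), 1L)
  expect_equal(ct$partner_resnum, 1L)
  expect_equal(ct$ca_distance, 8.0, tolerance = 1e-9)
})

test_that("distant chains yield no contacts and empty sides error", {
  far <- make_toy_complex(n = 8, separation = 100)
  expect_equal(nrow(find_contacts(far$model, far$spec)), 0L)
  expect_equal(nrow(far$expected_contacts), 0L)
  onesided <- atom_model(data.frame(chain = c("R", "A"), resnum = c(1L, 1L),
                                    atom = c("CA", "CB")))
  expect_warning(
    expect_error(find_contacts(onesided, complex_spec("R", "A")),
                 "empty interface side"),
    "without CA")
})

test_that("hydrogen bonds follow the heavy-atom distance and D-H...A angle rule", {
  # acceptor O (chain R) at the origin, donor N (chain A) at (dist, 0, 0);
  # h_dir, when given, places an explicit hydrogen at N + h_dir (|h_dir|=1)
  pair <- function(dist, h_dir = NULL) {
    rows <- data.frame(chain = c("R", "R", "A", "A"),
                       resnum = c(1L, 1L, 1L, 1L),
                       atom = c("CA", "O", "CA", "N"),
                       element = c("C", "O", "C", "N"),
                       x = c(0, 0, dist, dist), y = c(0, 0, 0, 0),
                       z = c(1, 0, 1, 0))
    if (!is.null(h_dir)) {
      rows <- rbind(rows, data.frame(chain = "A", resnum = 1L, atom = "H",
                                     element = "H", x = dist + h_dir[1],
                                     y = h_dir[2], z = h_dir[3]))
    }
    atom_model(rows)
  }
  hb <- function(m) {
    spec <- complex_spec("R", "A")
    detect_hbonds(m, spec, find_contacts(m, spec))$hbond[1]
  }
  expect_true(hb(pair(2.9)))
  expect_false(hb(pair(4.2)))
  # H placed so the D-H...A angle is exactly 90 degrees (Thales circle
  # through the donor at unit bond length): fails the angle test
  ux <- -1 / 2.9
  expect_false(hb(pair(2.9, h_dir = c(ux, sqrt(1 - ux^2), 0))))
  # H on the donor-acceptor line: 180 degrees, passes
  expect_true(hb(pair(2.9, h_dir = c(-1, 0, 0))))
})

test_that("salt bridges require opposite charges within 4 A", {
  bridge <- function(res_a, atom_a, res_b, atom_b, d) {
    atom_model(data.frame(chain = c("R", "R", "A", "A"),
                          resnum = 1L,
                          resname = c(res_a, res_a, res_b, res_b),
                          atom = c("CA", atom_a, "CA", atom_b),
                          element = c("C", substr(atom_a, 1, 1), "C",
                                      substr(atom_b, 1, 1)),
                          x = c(0, 0, d, d), y = 0, z = c(1, 0, 1, 0)))
  }
  spec <- complex_spec("R", "A")
  m <- bridge("ASP", "OD1", "LYS", "NZ", 3.2)
  ct <- detect_salt_bridges(m, spec, find_contacts(m, spec))
  expect_true(ct$saltbridge[1])
  # same-sign apposition is not a salt bridge
  m <- bridge("ASP", "OD1", "GLU", "OE1", 3.0)
  ct <- detect_salt_bridges(m, spec, find_contacts(m, spec))
  expect_false(ct$saltbridge[1])
  # beyond 4 A fails
  m <- bridge("GLU", "OE2", "ARG", "NH1", 4.3)
  ct <- detect_salt_bridges(m, spec, find_contacts(m, spec))
  expect_false(ct$saltbridge[1])
  # histidine counts as positive, either direction
  m <- bridge("HIS", "NE2", "GLU", "OE1", 3.5)
  ct <- detect_salt_bridges(m, spec, find_contacts(m, spec))
  expect_true(ct$saltbridge[1])
})

test_that("salt-bridge flags equal a brute-force atom-set oracle on random fixtures", {
  charged <- c("ASP", "GLU", "LYS", "ARG", "HIS")
  sb_oracle <- function(model, ct) {
    acid <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))
    base <- list(LYS = "NZ", ARG = c("NH1", "NH2", "NE"),
                 HIS = c("ND1", "NE2"))
    sapply(seq_len(nrow(ct)), function(i) {
      a <- gpcriface:::residue_atoms(model, ct$receptor_chain[i],
                                     ct$receptor_resnum[i], "")
      b <- gpcriface:::residue_atoms(model, ct$partner_chain[i],
                                     ct$partner_resnum[i], "")
      found <- FALSE
      for (pair in list(list(a, b), list(b, a))) {
        x <- pair[[1]]; y <- pair[[2]]
        xa <- x[x$atom %in% acid[[x$resname[1]]], , drop = FALSE]
        yb <- y[y$atom %in% base[[y$resname[1]]], , drop = FALSE]
        if (nrow(xa) == 0 || nrow(yb) == 0) next
        for (u in seq_len(nrow(xa))) for (v in seq_len(nrow(yb))) {
          d <- sqrt((xa$x[u] - yb$x[v])^2 + (xa$y[u] - yb$y[v])^2 +
                      (xa$z[u] - yb$z[v])^2)
          if (d <= 4.0) found <- TRUE
        }
      }
      found
    })
  }
  for (seed in 1:4) {
    set.seed(seed)
    n <- 8L
    seqs <- list(
      receptor = sample(c("D", "E", "K", "R", "H"), n, replace = TRUE),
      partner = sample(c("D", "E", "K", "R", "H"), n, replace = TRUE))
    toy <- make_toy_complex(n = n, separation = 9 + seed, sequence = seqs)
    ct <- find_contacts(toy$model, toy$spec, cutoff = 14)
    ct <- detect_salt_bridges(toy$model, toy$spec, ct)
    expect_identical(ct$saltbridge, unname(sb_oracle(toy$model, ct)))
  }
})

test_that("isolated-atom SASA matches the analytic sphere", {
  for (el in c("C", "N", "O", "S")) {
    m <- atom_model(data.frame(atom = el, element = el))
    s <- compute_sasa(m)
    r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)[[el]]
    expect_equal(s$sasa, 4 * pi * (r + 1.4)^2, tolerance = 0.02)
  }
  expect_error(compute_sasa(make_helix(2), n_points = 16), "at least 32")
  m <- atom_model(data.frame(atom = "XX", element = "ZZ"))
  expect_warning(compute_sasa(m), "unknown element")
})

test_that("a caged atom has near-zero SASA", {
  # central carbon enclosed by a tight octahedral-plus-cube cage
  d <- 2.2
  dirs <- rbind(diag(3), -diag(3),
                as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) /
                  sqrt(3))
  cage <- data.frame(chain = "A", resnum = seq_len(nrow(dirs) + 1L) + 1L,
                     atom = "C", element = "C",
                     x = c(0, d * dirs[, 1]), y = c(0, d * dirs[, 2]),
                     z = c(0, d * dirs[, 3]))
  cage$resnum[1] <- 1L
  m <- atom_model(cage)
  s <- compute_sasa(m)
  expect_lt(s$sasa[s$resnum == 1L], 1)
})

test_that("two-atom SASA agrees with a dense Monte Carlo reference", {
  for (sep in c(2.0, 3.0, 4.5, 6.0)) {
    m <- atom_model(data.frame(chain = "A", resnum = c(1L, 2L),
                               atom = c("C", "O"), element = c("C", "O"),
                               x = c(0, sep)))
    got <- sum(compute_sasa(m)$sasa)
    ref <- mc_two_atom_sasa(matrix(c(0, 0, 0, sep, 0, 0), 2, byrow = TRUE),
                            c(1.70, 1.52))
    expect_equal(got, ref, tolerance = 0.02)
  }
})

test_that("SASA decreases monotonically as a second chain approaches", {
  h <- make_helix(8, chain = "R")
  sasas <- sapply(c(12, 9, 7, 5.5), function(sep) {
    other <- make_helix(8, chain = "A", origin = c(sep, 0, 0))
    m <- gpcriface:::new_structure_model("pair",
                                         rbind(h$atoms, other$atoms))
    sum(compute_sasa(m, n_points = 240)$sasa)
  })
  expect_true(all(diff(sasas) < 0))
})

test_that("buried surface is consistent, non-negative and zero for distant chains", {
  far <- make_toy_complex(n = 6, separation = 100)
  expect_equal(buried_surface(far$model, far$spec, n_points = 240), 0,
               tolerance = 1e-6)
  near <- make_toy_complex(n = 10, separation = 7)
  b <- buried_surface(near$model, near$spec, n_points = 240)
  expect_gte(b, 0)
  # self-consistency with the three SASA calls
  halves <- split_complex(near$model, near$spec)
  manual <- sum(compute_sasa(halves$receptor, n_points = 240)$sasa) +
    sum(compute_sasa(halves$partner, n_points = 240)$sasa) -
    sum(compute_sasa(near$model, n_points = 240)$sasa)
  expect_equal(b, manual, tolerance = 1e-9)
  expect_gt(b, 10)  # the 7 A complex genuinely buries surface
})

test_that("composition percentages match a counting oracle and sum to 100", {
  ct <- data.frame(receptor_chain = "R", receptor_resnum = 1:4,
                   receptor_icode = "", receptor_aa = "A",
                   receptor_label = paste0("3.", 50:53),
                   partner_chain = "A", partner_resnum = 1:4,
                   partner_icode = "", partner_aa = c("D", "E", "K", "R"),
                   partner_label = paste0("H5.0", 1:4),
                   ca_distance = 5, hbond = FALSE, saltbridge = FALSE,
                   stringsAsFactors = FALSE)
  comp <- composition(ct)
  expect_equal(unname(comp$receptor$aa["A"]), 100)
  expect_equal(unname(comp$receptor$group["hydrophobic"]), 100)
  expect_equal(unname(comp$partner$group["negative"]), 50)
  expect_equal(unname(comp$partner$group["positive"]), 50)
  for (seed in 1:5) {
    toy <- make_toy_complex(n = 12, separation = 6, sequence = "random",
                            seed = seed)
    ct <- find_contacts(toy$model, toy$spec)
    comp <- composition(ct)
    for (side in comp) {
      if (length(side$aa) == 0) next
      expect_equal(sum(side$aa), 100, tolerance = 1e-6)
      expect_equal(sum(side$group), 100, tolerance = 1e-6)
      # counting oracle on the receptor side amino-acid table
    }
    aa <- ct$receptor_aa[!duplicated(ct$receptor_resnum)]
    for (a in unique(aa)) {
      expect_equal(unname(comp$receptor$aa[a]),
                   100 * sum(aa == a) / length(aa))
    }
  }
})

test_that("interface_profile counts are consistent with its flags", {
  toy <- make_toy_complex(n = 12, separation = 6, sequence = "random",
                          seed = 2)
  map <- assign_labels(toy$model, toy$annotation)
  prof <- interface_profile(toy$model, toy$spec, map, n_points = 120)
  expect_equal(prof$n_hbonds, sum(prof$contacts$hbond))
  expect_equal(prof$n_saltbridges, sum(prof$contacts$saltbridge))
  expect_gte(prof$buried_sasa, 0)
  expect_true(all(prof$contacts$ca_distance <= prof$config$contact_cutoff))
})
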