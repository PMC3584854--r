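test_that("kabsch_superpose handles exact and translated point sets", {
  P <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1), 4, 3, byrow = TRUE)
  s <- kabsch_superpose(P, P)
  expect_equal(s$rotation, diag(3), tolerance = 1e-12)
  expect_equal(s$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(s$rmsd, 0, tolerance = 1e-12)

  Q <- sweep(P, 2, c(1, 2, 3), "+")
  s2 <- kabsch_superpose(P, Q)
  expect_equal(s2$translation, c(1, 2, 3), tolerance = 1e-12)
  expect_equal(s2$rmsd, 0, tolerance = 1e-12)
  expect_equal(det(s2$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch_superpose(P[1:2, ], Q[1:2, ]), "3 point")
  expect_error(kabsch_superpose(P, Q[1:3, ]), "matching")
})

test_that("degenerate (collinear) point sets are flagged but still solved", {
  P <- cbind(0:3, 0, 0)
  R <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  Q <- P %*% t(R)
  s <- kabsch_superpose(P, Q)
  expect_true(s$collinear)
  expect_equal(s$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch rmsd matches the brute-force rotation-grid oracle", {
  set.seed(101)
  for (n in c(4, 5, 6)) {
    P <- matrix(rnorm(n * 3, sd = 3), n, 3)
    Q <- P %*% t(random_rotation()) + matrix(rnorm(n * 3, sd = 0.1), n, 3)
    s <- kabsch_superpose(P, Q)
    expect_equal(s$rmsd, oracle_grid_rmsd(P, Q), tolerance = 1e-6)
  }
})

test_that("rmsd is invariant under a common rigid motion", {
  set.seed(7)
  P <- matrix(rnorm(15, sd = 4), 5, 3)
  Q <- P %*% t(random_rotation()) + matrix(rnorm(15, sd = 0.3), 5, 3)
  base <- kabsch_superpose(P, Q)$rmsd
  for (i in 1:5) {
    R <- random_rotation(); tr <- rnorm(3, sd = 10)
    P2 <- sweep(P %*% t(R), 2, tr, "+")
    Q2 <- sweep(Q %*% t(R), 2, tr, "+")
    expect_equal(kabsch_superpose(P2, Q2)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("seed_correspondence pairs identical structures in order", {
  fam <- make_toy_family(1, 30, seed = 5)
  a <- fam$structures[[1]]
  pr <- seed_correspondence(a, a)
  expect_equal(pr$key_a, a$residues$key)
  expect_equal(pr$key_b, a$residues$key)
})

test_that("seed_correspondence covers the planted site across family members", {
  fam <- make_toy_family(3, 50, seed = 9)
  site_keys <- residue_key("A", fam$site_indices)
  for (i in 2:3) {
    pr <- seed_correspondence(fam$structures[[i]], fam$structures[[1]])
    hit <- pr$key_a %in% site_keys & pr$key_a == pr$key_b
    expect_gte(sum(hit), length(site_keys))
  }
})

test_that("iterative_superpose converges and respects the jitter bound", {
  fam <- make_toy_family(2, 50, seed = 13)
  a <- fam$structures[[1]]
  s <- iterative_superpose(a, a)
  expect_true(s$converged)
  expect_equal(s$iterations, 1)
  expect_equal(s$rmsd, 0, tolerance = 1e-9)

  s2 <- iterative_superpose(fam$structures[[2]], a)
  expect_true(s2$converged)
  expect_lte(s2$rmsd, 3 * fam$site$jitter_sigma)
})

test_that("unrelated coils either fail cleanly or survive with >= 3 pairs", {
  set.seed(21)
  mk <- function(id) {
    xyz <- round(matrix(cumsum(rnorm(90, sd = 2)), 30, 3), 3)
    protein_structure(id, data.frame(
      chain_id = "A", res_seq = 1:30, icode = "",
      name3 = "ALA", code1 = sample(salsar:::.AA20, 30, TRUE),
      ca_x = xyz[, 1], ca_y = xyz[, 2], ca_z = xyz[, 3],
      sc_x = xyz[, 1], sc_y = xyz[, 2], sc_z = xyz[, 3]))
  }
  res <- tryCatch(iterative_superpose(mk("c1"), mk("c2")),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "alignment failure")
  } else {
    expect_gte(res$n_pairs, 3)
  }
})

test_that("map_site_positions: identical structures give full occupancy", {
  fam <- make_toy_family(1, 40, site = site_spec(c("D", "H", "E"),
                                                 jitter_sigma = 0),
                         seed = 2)
  a <- fam$structures[[1]]
  b <- a; b$structure_id <- "S2"
  sites <- list(select_top_fraction(fam$rankings[[1]], 3 / 40),
                local({ s <- select_top_fraction(fam$rankings[[1]], 3 / 40)
                        s$structure_id <- "S2"; s }))
  pm <- map_site_positions(list(a, b), sites,
                           list(S2 = iterative_superpose(b, a)))
  expect_length(pm$positions, 3)
  for (p in pm$positions) expect_equal(sort(names(p)), c("S1", "S2"))
})

test_that("map_site_positions: disjoint sites give single-entry positions", {
  fam <- make_toy_family(1, 40, site = site_spec(c("D", "H", "E"),
                                                 jitter_sigma = 0),
                         seed = 2)
  a <- fam$structures[[1]]
  b <- a; b$structure_id <- "S2"
  # displace S2's residues far away while keeping an identity superposition
  b$residues[, c("sc_x", "ca_x")] <- b$residues[, c("sc_x", "ca_x")] + 500
  sites <- list(select_top_fraction(fam$rankings[[1]], 3 / 40),
                local({ s <- select_top_fraction(fam$rankings[[1]], 3 / 40)
                        s$structure_id <- "S2"; s }))
  pm <- map_site_positions(list(a, b), sites,
                           list(S2 = salsar:::identity_superposition()))
  expect_length(pm$positions, 6)
  expect_true(all(lengths(pm$positions) == 1))
})

test_that("map_site_positions recovers planted correspondence (ground truth)", {
  fam <- make_toy_family(5, 50, seed = 31)   # jitter 0.3 A, 8-residue site
  out <- run_family_pipeline(fam)
  expect_length(out$pm$positions, 8)
  expect_true(all(lengths(out$pm$positions) == 5))
  expect_true(same_positions(out$pm, fam$planted_positions))
})

test_that("position maps are bijective and monotone in the threshold", {
  fam <- make_toy_family(4, 50, seed = 17)
  sts <- fam$structures
  names(sts) <- sprintf("S%d", 1:4)
  sites <- lapply(fam$rankings, function(r) select_top_fraction(r, 8 / 50))
  sups <- lapply(sts[-1], function(s) iterative_superpose(s, sts[[1]]))
  occ <- c()
  for (th in c(4, 2, 1, 0.5)) {
    pm <- map_site_positions(sts, sites, sups, threshold = th)
    tagged <- unlist(lapply(pm$positions, function(p) paste(names(p), p)))
    expect_false(anyDuplicated(tagged) > 0)   # no residue in two positions
    occ <- c(occ, length(tagged))
  }
  expect_true(all(diff(occ) <= 0))  # lowering threshold never adds occupancy
})

test_that("map_site_positions validates the reference", {
  fam <- make_toy_family(2, 40, seed = 1)
  sites <- lapply(fam$rankings, function(r) select_top_fraction(r, 8 / 40))
  expect_error(map_site_positions(fam$structures, sites, list(),
                                  reference = "nope"), "reference")
})

test_that("import_msa_positions matches an exhaustive column scan", {
  fam <- make_toy_family(3, 30, site = site_spec(c("D", "H", "E"),
                                                 jitter_sigma = 0),
                         seed = 23)
  sts <- fam$structures
  seqs <- vapply(sts, structure_sequence, "")
  names(seqs) <- sprintf("S%d", 1:3)
  # hand-built alignment: S2 gets a gap inserted mid-sequence, S3 shifted
  msa <- c(S1 = paste0(seqs[1], "--"),
           S2 = paste0(substr(seqs[2], 1, 10), "-",
                       substr(seqs[2], 11, 30), "-"),
           S3 = paste0("--", seqs[3]))
  sites <- lapply(fam$rankings, function(r) select_top_fraction(r, 3 / 30))
  pm <- import_msa_positions(msa, sts, sites)

  pred_idx <- lapply(sprintf("S%d", 1:3), function(sid)
    match(sites[[match(sid, sprintf("S%d", 1:3))]]$members,
          sts[[match(sid, sprintf("S%d", 1:3))]]$residues$key))
  names(pred_idx) <- sprintf("S%d", 1:3)
  oracle <- oracle_msa_columns(msa, pred_idx)
  expect_length(pm$positions, length(oracle))
  for (i in seq_along(oracle)) {
    want <- oracle[[i]][oracle[[i]] > 0]
    got <- pm$positions[[i]]
    expect_equal(sort(names(got)), sort(names(want)))
    for (sid in names(want))
      expect_equal(got[[sid]], sts[[match(sid, sprintf("S%d", 1:3))]]$residues$key[want[[sid]]])
  }
})

test_that("import_msa_positions reports the first divergent residue", {
  fam <- make_toy_family(2, 20, site = site_spec(c("D", "H"), jitter_sigma = 0,
                                                 decoy_count = 5), seed = 3)
  sts <- fam$structures
  seqs <- vapply(sts, structure_sequence, "")
  names(seqs) <- c("S1", "S2")
  broken <- seqs
  substr(broken["S2"], 4, 4) <- if (substr(broken["S2"], 4, 4) == "A") "G" else "A"
  sites <- lapply(fam$rankings, function(r) select_top_fraction(r, 2 / 20))
  expect_error(import_msa_positions(broken, sts, sites), "A:4")
  expect_error(import_msa_positions(seqs[1], sts, sites), "missing sequence")
})

test_that("MSA route mirrors gap cells in the table", {
  fam <- make_toy_family(2, 20, site = site_spec(c("D", "H", "E"),
                                                 jitter_sigma = 0,
                                                 decoy_count = 5), seed = 4)
  sts <- fam$structures
  seqs <- vapply(sts, structure_sequence, "")
  # delete S2's first site residue from the alignment
  i1 <- fam$site_indices[1]
  msa <- c(S1 = seqs[1],
           S2 = paste0(substr(seqs[2], 1, i1 - 1), "-",
                       substr(seqs[2], i1 + 1, 20)))
  # drop that residue from S2's structure to keep sequences consistent
  sts[[2]]$residues <- sts[[2]]$residues[-i1, ]
  rk2 <- fam$rankings[[2]]$entries
  rk2 <- rk2[rk2$res_seq != i1, ]; rk2$rank <- rank(rk2$rank)
  sites <- list(select_top_fraction(fam$rankings[[1]], 3 / 20),
                select_top_fraction(residue_ranking("S2", rk2), 3 / 19))
  pm <- import_msa_positions(msa, sts, sites)
  tab <- build_salsa_table(pm, sites, sts)
  cell <- salsa_row(tab, "S2")[1, ]
  expect_true(cell$gap)
  expect_equal(salsa_row(tab, "S1")$code1[1], "D")
})
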