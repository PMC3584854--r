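# Synthetic structure families with known ground truth. The generator
# plants a conserved constellation of catalytic-type residues at a fixed
# geometry (with optional positional jitter and identity mutations) on an
# otherwise idealized helical CA trace, and emits rankings that place the
# planted residues at the top. This exercises parsing, correspondence,
# table construction and scoring end to end without any real structures;
# it does not emulate real folds, packing or electrostatics.

#' Specification of a planted site
#'
#' @param codes ordered one-letter codes of the site residues
#' @param geometry numeric `length(codes)` x 3 matrix of site coordinates
#'   in Angstrom; default places the residues on a 9-Angstrom ring, far
#'   enough apart that distinct positions never collide at realistic jitter
#' @param jitter_sigma per-coordinate Gaussian jitter, Angstrom (default
#'   0.3, the regime the recovery guarantees are stated for)
#' @param decoy_count residues placed on a 14-Angstrom shell around the
#'   site that compete with it in the rankings (default 10)
#' @return object of class `site_spec`
#' @export
site_spec <- function(codes, geometry = NULL, jitter_sigma = 0.3,
                      decoy_count = 10) {
  codes <- toupper(codes)
  if (!all(codes %in% .AA20)) stop("site codes must be standard amino acids")
  k <- length(codes)
  if (is.null(geometry)) {
    ang <- 2 * pi * (seq_len(k) - 1) / k
    geometry <- cbind(9 * cos(ang), 9 * sin(ang), 0)
  }
  geometry <- as.matrix(geometry)
  if (nrow(geometry) != k || ncol(geometry) != 3)
    stop("geometry must be a length(codes) x 3 matrix")
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  structure(list(codes = codes, geometry = geometry,
                 jitter_sigma = jitter_sigma, decoy_count = decoy_count),
            class = "site_spec")
}

#' Generate a toy structure family with a planted site
#'
#' Every member carries the site residues of `site` at the specified
#' geometry plus Gaussian jitter; all members share one background
#' sequence (family members are homologs, so the sequence-seeded
#' correspondence is exercised realistically). With probability
#' `mutation_rate` a site residue's identity is substituted uniformly by
#' another amino acid. Rankings place the site residues in the top ranks
#' (shuffled), then decoys and background by distance to the site.
#' Regeneration from the same seed is bit-identical.
#'
#' @param n_structures number of family members (ids `S1`, `S2`, ...)
#' @param n_residues residues per structure (>= site size + decoys)
#' @param site a [site_spec()]
#' @param mutation_rate per-residue identity substitution probability in
#'   `[0, 1)` (default 0)
#' @param seed integer RNG seed
#' @return object of class `family_truth`: `structures`, `rankings`,
#'   `planted_positions` (a ground-truth `position_map`), `site_indices`,
#'   `site`, `seed`
#' @export
make_toy_family <- function(n_structures, n_residues, site = site_spec(
                              c("D", "K", "D", "K", "D", "H", "P", "R")),
                            mutation_rate = 0, seed = 1) {
  if (n_structures < 1) stop("n_structures must be >= 1")
  k <- length(site$codes)
  if (n_residues < k + site$decoy_count)
    stop("n_residues must be at least site size + decoy_count")
  if (mutation_rate < 0 || mutation_rate >= 1)
    stop("mutation_rate must be in [0, 1)")

  with_seed(seed, {
    ids <- sprintf("S%d", seq_len(n_structures))
    # family-level layout: where site and decoy residues sit in the chain
    site_idx <- unique(round(seq(2, n_residues - 1, length.out = k)))
    if (length(site_idx) < k)
      stop("n_residues too small to place ", k, " distinct site residues")
    pool <- setdiff(seq_len(n_residues), site_idx)
    decoy_idx <- sort(sample(pool, site$decoy_count))
    bg_codes <- sample(.AA20, n_residues, replace = TRUE)

    centroid <- colMeans(site$geometry)
    ang <- runif(site$decoy_count, 0, 2 * pi)
    u <- runif(site$decoy_count, -1, 1)
    decoy_geom <- cbind(sqrt(1 - u^2) * cos(ang), sqrt(1 - u^2) * sin(ang), u) * 14
    decoy_geom <- sweep(decoy_geom, 2, centroid, "+")

    # idealized alpha-helical CA trace, displaced away from the site
    t_i <- seq_len(n_residues)
    helix <- cbind(2.3 * cos(t_i * 100 * pi / 180),
                   2.3 * sin(t_i * 100 * pi / 180),
                   1.5 * t_i)
    helix <- sweep(helix, 2, centroid + c(0, 0, 40), "+")

    structures <- list(); rankings <- list()
    for (s in seq_len(n_structures)) {
      codes <- bg_codes
      codes[site_idx] <- site$codes
      if (mutation_rate > 0) {
        mut <- runif(k) < mutation_rate
        for (j in which(mut))
          codes[site_idx[j]] <- sample(setdiff(.AA20, codes[site_idx[j]]), 1)
      }
      xyz <- helix
      xyz[site_idx, ] <- site$geometry
      xyz[decoy_idx, ] <- decoy_geom
      xyz <- xyz + matrix(rnorm(3 * n_residues, 0, site$jitter_sigma),
                          ncol = 3)
      xyz <- round(xyz, 3)  # PDB precision, so files round-trip exactly
      res <- data.frame(chain_id = "A", res_seq = t_i, icode = "",
                        name3 = unname(.AA1TO3[codes]), code1 = codes,
                        ca_x = xyz[, 1], ca_y = xyz[, 2], ca_z = xyz[, 3],
                        sc_x = xyz[, 1], sc_y = xyz[, 2], sc_z = xyz[, 3],
                        stringsAsFactors = FALSE)
      structures[[s]] <- protein_structure(ids[s], res)

      # ranks: site residues first (shuffled), then everything else by
      # distance to the site centroid
      site_rank <- sample(k)
      rest <- setdiff(t_i, site_idx)
      dc <- sqrt(rowSums(sweep(xyz[rest, , drop = FALSE], 2, centroid)^2))
      rest <- rest[order(dc, rest)]
      rank <- integer(n_residues)
      rank[site_idx] <- site_rank
      rank[rest] <- k + seq_along(rest)
      rankings[[s]] <- residue_ranking(ids[s], data.frame(
        chain_id = "A", res_seq = t_i, icode = "", code1 = codes,
        rank = rank, score = round(1 - (rank - 1) / n_residues, 6),
        stringsAsFactors = FALSE))
    }

    planted <- lapply(seq_len(k), function(a)
      stats::setNames(rep(residue_key("A", site_idx[a]), n_structures), ids))
    names(planted) <- sprintf("P%02d", seq_len(k))
    planted_positions <- structure(
      list(reference_id = ids[1], threshold = NA_real_,
           structure_ids = ids, positions = planted),
      class = "position_map")

    structure(list(structures = structures, rankings = rankings,
                   planted_positions = planted_positions,
                   site = site, site_indices = site_idx,
                   decoy_indices = decoy_idx, seed = seed),
              class = "family_truth")
  })
}

#' @export
print.family_truth <- function(x, ...) {
  cat("<family_truth>", length(x$structures), "structures, site of",
      length(x$site$codes), "residues, seed", x$seed, "\n")
  invisible(x)
}

#' Write a toy family to disk
#'
#' Emits one PDB file and one rankings TSV per member plus a ground-truth
#' position TSV; file contents are byte-identical across regenerations
#' from the same seed.
#'
#' @param family a `family_truth`
#' @param dir output directory (created if needed)
#' @return named list of file paths (`pdb`, `rankings`, `truth`), invisibly
#' @export
write_toy_family <- function(family, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pdb <- character(0); rnk <- character(0)
  for (i in seq_along(family$structures)) {
    sid <- family$structures[[i]]$structure_id
    pdb[sid] <- file.path(dir, paste0(sid, ".pdb"))
    write_pdb(family$structures[[i]], pdb[sid])
    rnk[sid] <- file.path(dir, paste0(sid, "_rankings.tsv"))
    write_rankings(family$rankings[[i]], rnk[sid])
  }
  truth <- file.path(dir, "planted_positions.tsv")
  sites <- lapply(family$rankings, function(r)
    select_top_fraction(r, length(family$site$codes) / nrow(r$entries)))
  write_position_map(family$planted_positions, family$structures, sites, truth)
  invisible(list(pdb = pdb, rankings = rnk, truth = truth))
}

#' Load a packaged worked-example SALSA table
#'
#' Four published local alignments ship with the package as plain-text
#' tables: `omdc_table2` (six orotidine 5'-monophosphate decarboxylases,
#' eight positions), `gh16_table3` (a glycoside hydrolase family 16
#' representative vs. a structural-genomics query, fourteen positions),
#' `ech_table4` (a rat enoyl-CoA hydratase vs. the same query protein,
#' nine positions) and `abdh_table5` (that query vs. a beta-diketone
#' hydrolase, seven positions ordered by the query's ranking). Cells keep
#' the published case (uppercase = predicted) and `-` gaps.
#'
#' @param name one of `"omdc_table2"`, `"gh16_table3"`, `"ech_table4"`,
#'   `"abdh_table5"`
#' @return a [salsa_table()]
#' @export
load_paper_fixture <- function(name = c("omdc_table2", "gh16_table3",
                                        "ech_table4", "abdh_table5")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "salsar")
  if (!nzchar(path)) stop("fixture not found: ", name)
  read_salsa_table(path)
}
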