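# Small in-code fixtures shared across test files.

# A hand-written PDB snippet: two residues with full backbones and side
# chains, one glycine, an altloc pair on the LYS CA, and an MSE HETATM.
write_tiny_pdb <- function(path) {
  writeLines(c(
    "HEADER    TEST",
    "ATOM      1  N   ASP A  11      11.000   0.500   0.000  1.00  0.00           N",
    "ATOM      2  CA  ASP A  11      12.000   1.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ASP A  11      13.000   1.500   0.000  1.00  0.00           C",
    "ATOM      4  O   ASP A  11      14.000   2.000   0.000  1.00  0.00           O",
    "ATOM      5  CB  ASP A  11      12.000   3.000   0.000  1.00  0.00           C",
    "ATOM      6  CG  ASP A  11      12.000   5.000   0.000  1.00  0.00           C",
    "ATOM      7  CA ALYS A  12      15.000   0.000   0.000  0.40  0.00           C",
    "ATOM      8  CA BLYS A  12      16.000   0.000   0.000  0.60  0.00           C",
    "ATOM      9  CA  GLY A  13      18.000   0.000   0.000  1.00  0.00           C",
    "HETATM   10  CA  MSE A  14      21.000   0.000   0.000  1.00  0.00           C",
    "HETATM   11  O   HOH A 101      30.000  30.000  30.000  1.00  0.00           O",
    "END"), path)
  path
}

# Build a salsa_table directly from a character matrix in published
# typography (rows = structures, "-" = gap, lowercase = unpredicted).
table_from_matrix <- function(m) {
  cells <- list()
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    cells[[length(cells) + 1L]] <- cbind(
      salsar:::parse_cell(m[i, j]),
      data.frame(structure_id = rownames(m)[i], position = colnames(m)[j],
                 stringsAsFactors = FALSE))
  }
  salsa_table(do.call(rbind, cells), structure_order = rownames(m),
              position_order = colnames(m))
}

# In-memory pipeline on a generated family: sites from exact top-k cut,
# star superposition onto S1, position map, table.
run_family_pipeline <- function(fam, threshold = 4.0) {
  sts <- fam$structures
  names(sts) <- vapply(sts, function(s) s$structure_id, "")
  k <- length(fam$site$codes)
  sites <- lapply(fam$rankings, function(r)
    select_top_fraction(r, k / nrow(r$entries)))
  names(sites) <- names(sts)
  sups <- list()
  for (sid in names(sts)[-1])
    sups[[sid]] <- iterative_superpose(sts[[sid]], sts[[1]])
  pm <- map_site_positions(sts, sites, sups, threshold = threshold)
  list(structures = sts, sites = sites, pm = pm,
       table = build_salsa_table(pm, sites, sts))
}

# Do two position maps describe the same residue clusters?
same_positions <- function(a, b) {
  norm <- function(pm) sort(vapply(pm$positions, function(p)
    paste(sort(paste(names(p), p)), collapse = ";"), ""))
  identical(norm(a), norm(b))
}

ompdc_ref_rows <- c("1dbt", "1dvj", "1dqw", "1l2u", "2za1")
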