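# Residue-level PDB ingestion. Only what local site matching needs is kept:
# author numbering, one-letter identity, the CA position and a side-chain
# centroid as the residue's representative point in space.

#' Construct a protein structure object
#'
#' A `protein_structure` is an ordered residue table plus an identifier.
#' Normally produced by [read_pdb()] or [make_toy_family()]; the constructor
#' is exported for programmatic assembly and testing.
#'
#' @param structure_id free-text identifier (e.g. a PDB ID)
#' @param residues data.frame with columns `chain_id`, `res_seq`, `icode`,
#'   `name3`, `code1`, `ca_x`, `ca_y`, `ca_z`, `sc_x`, `sc_y`, `sc_z`
#' @return object of class `protein_structure`
#' @export
protein_structure <- function(structure_id, residues) {
  need <- c("chain_id", "res_seq", "icode", "name3", "code1",
            "ca_x", "ca_y", "ca_z", "sc_x", "sc_y", "sc_z")
  miss <- setdiff(need, names(residues))
  if (length(miss)) stop("residues missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(residues) == 0) stop("empty structure: no residues")
  if (!all(residues$code1 %in% c(.AA20, "X")))
    stop("invalid one-letter code in residues")
  if (any(!is.finite(as.matrix(residues[, c("ca_x", "ca_y", "ca_z")]))))
    stop("non-finite CA coordinates")
  residues$key <- residue_key(residues$chain_id, residues$res_seq, residues$icode)
  if (anyDuplicated(residues$key))
    stop("duplicate residue identifier(s): ",
         paste(unique(residues$key[duplicated(residues$key)]), collapse = ", "))
  rownames(residues) <- NULL
  structure(list(structure_id = structure_id, residues = residues),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat("<protein_structure>", x$structure_id, "-", nrow(x$residues),
      "residues,", length(unique(x$residues$chain_id)), "chain(s)\n")
  invisible(x)
}

#' Amino-acid sequence of a structure
#'
#' @param structure a `protein_structure`
#' @param chain optional chain label; default concatenates all chains in
#'   file order
#' @return single character string of one-letter codes
#' @export
structure_sequence <- function(structure, chain = NULL) {
  r <- structure$residues
  if (!is.null(chain)) r <- r[r$chain_id %in% chain, , drop = FALSE]
  paste(r$code1, collapse = "")
}

# Representative (side-chain centroid) coordinates as an n x 3 matrix.
sc_coords <- function(structure, keys = NULL) {
  r <- structure$residues
  if (!is.null(keys)) r <- r[match(keys, r$key), , drop = FALSE]
  m <- as.matrix(r[, c("sc_x", "sc_y", "sc_z")])
  rownames(m) <- r$key
  m
}

ca_coords <- function(structure, keys = NULL) {
  r <- structure$residues
  if (!is.null(keys)) r <- r[match(keys, r$key), , drop = FALSE]
  m <- as.matrix(r[, c("ca_x", "ca_y", "ca_z")])
  rownames(m) <- r$key
  m
}

#' Read a protein structure from a PDB file
#'
#' Parses ATOM records of the first MODEL into a residue-level model.
#' Alternate locations are resolved by highest occupancy (ties: first
#' encountered); HETATM records are ignored except MSE, which is read as
#' methionine. Residues without a CA atom are dropped. The side-chain
#' centroid is the mean of side-chain heavy atoms and falls back to the CA
#' position for glycine or when no side-chain atoms are present.
#'
#' @param path PDB file path
#' @param chain_filter optional character vector of chain labels to keep
#' @return a [protein_structure()]
#' @export
read_pdb <- function(path, chain_filter = NULL) {
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)

  # first MODEL only
  mstart <- grep("^MODEL ", lines)
  if (length(mstart) >= 1) {
    mend <- grep("^ENDMDL", lines)
    end <- if (length(mend)) mend[1] else length(lines)
    lines <- lines[seq(mstart[1], end)]
  }

  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  "
  is_mse <- rec == "HETATM" & substr(lines, 18, 20) == "MSE"
  lines <- lines[is_atom | is_mse]
  if (!length(lines)) stop("empty structure: no usable ATOM records in ", path)

  at <- data.frame(
    name = trimws(substr(lines, 13, 16)),
    altloc = substr(lines, 17, 17),
    name3 = trimws(substr(lines, 18, 20)),
    chain_id = substr(lines, 22, 22),
    res_seq = as.integer(substr(lines, 23, 26)),
    icode = trimws(substr(lines, 27, 27)),
    x = as.numeric(substr(lines, 31, 38)),
    y = as.numeric(substr(lines, 39, 46)),
    z = as.numeric(substr(lines, 47, 54)),
    occ = suppressWarnings(as.numeric(substr(lines, 55, 60))),
    element = toupper(trimws(substr(lines, 77, 78))),
    stringsAsFactors = FALSE
  )
  at$occ[is.na(at$occ)] <- 1
  if (!is.null(chain_filter)) at <- at[at$chain_id %in% chain_filter, , drop = FALSE]
  if (!nrow(at)) stop("empty structure: no residues after chain filter")

  # altloc resolution per (residue, atom name): highest occupancy, then first
  akey <- paste(at$chain_id, at$res_seq, at$icode, at$name, sep = "\r")
  ord <- order(match(akey, unique(akey)), -at$occ, seq_len(nrow(at)))
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain_id, at$res_seq, at$icode, at$name,
                             sep = "\r")), , drop = FALSE]

  rkey <- paste(at$chain_id, at$res_seq, at$icode, sep = "\r")
  at <- at[order(match(rkey, unique(rkey))), , drop = FALSE]
  rkey <- paste(at$chain_id, at$res_seq, at$icode, sep = "\r")

  backbone <- c("N", "CA", "C", "O", "OXT")
  res_list <- lapply(split(seq_len(nrow(at)), factor(rkey, levels = unique(rkey))),
                     function(ix) {
    a <- at[ix, , drop = FALSE]
    ca <- a[a$name == "CA", , drop = FALSE]
    if (!nrow(ca)) return(NULL)            # residues lacking CA are excluded
    ca <- ca[1, ]
    name3 <- ca$name3
    code1 <- unname(.AA3TO1[name3])
    if (is.na(code1)) code1 <- "X"
    elem <- a$element
    guess_h <- grepl("^[0-9]*H", a$name)    # fall back when element blank
    is_h <- ifelse(elem != "", elem %in% c("H", "D"), guess_h)
    side <- a[!(a$name %in% backbone) & !is_h, , drop = FALSE]
    if (name3 == "GLY" || !nrow(side)) {
      sc <- c(ca$x, ca$y, ca$z)
    } else {
      sc <- c(mean(side$x), mean(side$y), mean(side$z))
    }
    data.frame(chain_id = ca$chain_id, res_seq = ca$res_seq, icode = ca$icode,
               name3 = name3, code1 = code1,
               ca_x = ca$x, ca_y = ca$y, ca_z = ca$z,
               sc_x = sc[1], sc_y = sc[2], sc_z = sc[3],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res_list)
  if (is.null(res) || !nrow(res))
    stop("empty structure: no residue with a CA atom in ", path)
  sid <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  protein_structure(sid, res)
}

#' Write a structure as a minimal PDB file
#'
#' Emits one CA ATOM record per residue (the representative-point model used
#' by the synthetic generator); output is byte-deterministic for a given
#' structure.
#'
#' @param structure a `protein_structure`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pdb <- function(structure, path) {
  r <- structure$residues
  lines <- sprintf(
    "ATOM  %5d  CA  %-3s %s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(r)), .AA1TO3[r$code1], r$chain_id, r$res_seq,
    ifelse(r$icode == "", " ", r$icode),
    r$ca_x, r$ca_y, r$ca_z, 1, 0)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
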