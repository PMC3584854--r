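# Rigid-body superposition and spatial correspondence of predicted-site
# residues across a protein family. Correspondence is seeded by global
# sequence alignment, refined by iterative Kabsch fitting with distance
# trimming, and site residues are clustered into spatial positions (the
# future SALSA table columns) by optimal one-to-one assignment against the
# reference site.

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' paired point sets. The transform maps mobile coordinates onto the
#' reference frame: `x %*% t(rotation) + translation`.
#'
#' @param mobile_coords,reference_coords numeric n x 3 matrices, n >= 3,
#'   row i of one paired with row i of the other
#' @return object of class `superposition` with `rotation` (3 x 3, det +1),
#'   `translation`, `rmsd` and a `collinear` flag set when the point set is
#'   rank-deficient (rotation about the degenerate axis is then arbitrary
#'   but a valid minimizer is still returned)
#' @export
kabsch_superpose <- function(mobile_coords, reference_coords) {
  P <- as.matrix(mobile_coords); Q <- as.matrix(reference_coords)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3)
    stop("coordinate sets must be matching n x 3 matrices")
  if (nrow(P) < 3) stop("at least 3 point pairs are required")
  if (any(!is.finite(P)) || any(!is.finite(Q))) stop("non-finite coordinates")
  cp <- colMeans(P); cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp); Q0 <- sweep(Q, 2, cq)
  H <- crossprod(P0, Q0)
  sv <- svd(H)
  s <- sign(det(sv$v %*% t(sv$u)))
  if (s == 0) s <- 1
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  rot <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((rot - Q0)^2)))
  # rank deficiency (collinear/coplanar-degenerate input)
  collinear <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)
  structure(list(rotation = R,
                 translation = as.numeric(cq - R %*% cp),
                 rmsd = rmsd,
                 pairs = NULL,
                 n_pairs = nrow(P),
                 collinear = collinear),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d pairs, rmsd %.3f A%s\n", x$n_pairs, x$rmsd,
              if (isTRUE(x$collinear)) " (degenerate point set)" else ""))
  invisible(x)
}

identity_superposition <- function() {
  structure(list(rotation = diag(3), translation = c(0, 0, 0), rmsd = 0,
                 pairs = NULL, n_pairs = 0L, collinear = FALSE),
            class = "superposition")
}

#' Apply a superposition to coordinates
#'
#' @param sup a `superposition`
#' @param coords n x 3 matrix
#' @return transformed n x 3 matrix
#' @export
apply_superposition <- function(sup, coords) {
  m <- as.matrix(coords)
  out <- m %*% t(sup$rotation)
  out <- sweep(out, 2, sup$translation, "+")
  rownames(out) <- rownames(m)
  out
}

#' Sequence-seeded residue correspondence between two structures
#'
#' Globally aligns the two amino-acid sequences (same parameters as
#' [pairwise_identity()]) and maps aligned non-gap columns back to residue
#' keys.
#'
#' @param a,b `protein_structure` objects
#' @return data.frame with columns `key_a`, `key_b`
#' @export
seed_correspondence <- function(a, b) {
  al <- nw_align(structure_sequence(a), structure_sequence(b))
  keep <- al$a_idx > 0 & al$b_idx > 0
  data.frame(key_a = a$residues$key[al$a_idx[keep]],
             key_b = b$residues$key[al$b_idx[keep]],
             stringsAsFactors = FALSE)
}

#' Iterative superposition with distance trimming
#'
#' Starts from the sequence-seeded correspondence, alternates a Kabsch fit
#' on the surviving pairs with rejection of pairs whose CA-CA distance
#' exceeds `trim_distance`, and stops when the pair set is stable or
#' `max_iter` is reached. Only the local, structurally conserved region
#' needs to align well for site matching, which is what the trimming
#' delivers.
#'
#' @param mobile,reference `protein_structure` objects; the result maps
#'   `mobile` onto `reference`
#' @param max_iter maximum refinement iterations (default 10)
#' @param trim_distance CA-CA rejection threshold in Angstrom (default 6)
#' @return a `superposition` with `pairs` (data.frame `key_mobile`,
#'   `key_reference`), `iterations` and `converged`
#' @export
iterative_superpose <- function(mobile, reference, max_iter = 10,
                                trim_distance = 6.0) {
  seed <- seed_correspondence(mobile, reference)
  if (nrow(seed) < 3)
    stop("alignment failure: fewer than 3 seed pairs between ",
         mobile$structure_id, " and ", reference$structure_id)
  mob_all <- ca_coords(mobile, seed$key_a)
  ref_all <- ca_coords(reference, seed$key_b)
  keep <- rep(TRUE, nrow(seed))
  sup <- NULL; converged <- FALSE; it <- 0
  repeat {
    it <- it + 1
    if (sum(keep) < 3)
      stop("alignment failure: fewer than 3 pairs within ", trim_distance,
           " A between ", mobile$structure_id, " and ", reference$structure_id)
    sup <- kabsch_superpose(mob_all[keep, , drop = FALSE],
                            ref_all[keep, , drop = FALSE])
    d <- sqrt(rowSums((apply_superposition(sup, mob_all) - ref_all)^2))
    keep_new <- unname(d <= trim_distance)
    if (identical(keep_new, keep)) { converged <- TRUE; break }
    if (it >= max_iter) break
    keep <- keep_new
  }
  sup$pairs <- data.frame(key_mobile = seed$key_a[keep],
                          key_reference = seed$key_b[keep],
                          stringsAsFactors = FALSE)
  sup$n_pairs <- sum(keep)
  sup$iterations <- it
  sup$converged <- converged
  sup
}

# Minimum-cost assignment of rows to distinct columns (shortest augmenting
# path Hungarian, n rows <= m columns). Forbidden cells carry cost ~1e12.
lap_min <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  INF <- 1e15
  u <- numeric(n); v <- numeric(m + 1)
  p <- integer(m + 1)          # p[j+1]: row assigned to column j (0 = free)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free_j <- which(!used[-1])
      cur <- cost[i0, free_j] - u[i0] - v[free_j + 1]
      upd <- cur < minv[free_j + 1]
      minv[free_j + 1][upd] <- cur[upd]
      way[free_j + 1][upd] <- j0
      jmin <- free_j[which.min(minv[free_j + 1])]
      delta <- minv[jmin + 1]
      us <- which(used)
      pos <- p[us]; rows <- pos > 0
      u[pos[rows]] <- u[pos[rows]] + delta
      v[us] <- v[us] - delta
      minv[-us] <- minv[-us] - delta
      j0 <- jmin
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0) assign[p[j + 1]] <- j
  assign
}

#' Map predicted-site residues to shared spatial positions
#'
#' Every predicted residue of the reference structure (plus any
#' `extra_residues`, used to admit literature-reported but unpredicted
#' residues) anchors a position. For each other structure, residues are
#' assigned one-to-one to anchors by minimum total side-chain-centroid
#' distance after superposition, accepting a match only within `threshold`;
#' exact distance ties are broken toward the earlier residue in the chain.
#' Predicted residues of non-reference structures matching no anchor are
#' agglomerated, closest pair first, into additional unanchored positions.
#'
#' @param structures list of `protein_structure` (the reference must be
#'   among them)
#' @param sites list of `predicted_site`, parallel to `structures`
#' @param superpositions named list (by structure id) of `superposition`
#'   onto the reference; the reference's own entry may be omitted
#' @param reference structure id of the reference; default first structure
#' @param threshold maximum centroid-centroid distance for two residues to
#'   share a position, Angstrom (default 4)
#' @param extra_residues optional named list (by structure id) of residue
#'   keys to treat as site members in addition to the predicted ones
#' @return object of class `position_map`
#' @export
map_site_positions <- function(structures, sites, superpositions,
                               reference = NULL, threshold = 4.0,
                               extra_residues = NULL) {
  ids <- unname(vapply(structures, function(s) s$structure_id, ""))
  names(structures) <- ids
  names(sites) <- vapply(sites, function(s) s$structure_id, "")
  if (!setequal(ids, names(sites)))
    stop("structures and sites refer to different identifiers")
  reference <- reference %||% ids[1]
  if (!reference %in% ids) stop("reference '", reference, "' not in structures")

  anchor_keys <- sites[[reference]]$members
  extra_ref <- extra_residues[[reference]] %||% character(0)
  anchor_keys <- unique(c(anchor_keys, extra_ref))
  # anchors in chain order of the reference
  anchor_keys <- anchor_keys[order(match(anchor_keys, structures[[reference]]$residues$key))]
  ref_xyz <- sc_coords(structures[[reference]], anchor_keys)
  k <- length(anchor_keys)

  members <- list()  # per position: named character structure_id -> key
  for (a in seq_len(k)) members[[a]] <- c(stats::setNames(anchor_keys[a], reference))

  leftover <- data.frame(structure_id = character(0), key = character(0),
                         x = numeric(0), y = numeric(0), z = numeric(0),
                         sorder = integer(0), rorder = integer(0))
  BIGF <- 1e12

  for (sid in setdiff(ids, reference)) {
    st <- structures[[sid]]
    sup <- superpositions[[sid]]
    if (is.null(sup)) stop("no superposition provided for ", sid)
    xyz <- apply_superposition(sup, sc_coords(st))
    site_keys <- unique(c(sites[[sid]]$members, extra_residues[[sid]] %||% character(0)))
    assigned <- character(0)
    if (k > 0) {
      n <- nrow(xyz)
      D <- sqrt(pmax(outer(rowSums(ref_xyz^2), rowSums(xyz^2), "+") -
                       2 * ref_xyz %*% t(xyz), 0))
      cost <- matrix(BIGF, k, n + k)
      ok <- D <= threshold
      # deterministic tie-break: earlier residue in the chain wins
      Dt <- D + outer(rep(1, k), seq_len(n)) * 1e-9
      cost[, seq_len(n)][ok] <- Dt[ok]
      gap_cost <- (k + 1) * threshold + 1
      cost[cbind(seq_len(k), n + seq_len(k))] <- gap_cost
      assign <- lap_min(cost)
      for (a in seq_len(k)) {
        j <- assign[a]
        if (j >= 1 && j <= n && D[a, j] <= threshold) {
          key <- rownames(xyz)[j]
          members[[a]] <- c(members[[a]], stats::setNames(key, sid))
          assigned <- c(assigned, key)
        }
      }
    }
    rest <- setdiff(site_keys, assigned)
    if (length(rest)) {
      ri <- match(rest, st$residues$key)
      leftover <- rbind(leftover, data.frame(
        structure_id = sid, key = rest,
        x = xyz[ri, 1], y = xyz[ri, 2], z = xyz[ri, 3],
        sorder = match(sid, ids), rorder = ri, stringsAsFactors = FALSE))
    }
  }

  # greedy agglomeration of unanchored predicted residues, closest first
  extra_positions <- list()
  if (nrow(leftover)) {
    cl <- integer(nrow(leftover))  # 0 = unclustered
    if (nrow(leftover) > 1) {
      cmb <- t(utils::combn(nrow(leftover), 2))
      xyzl <- as.matrix(leftover[, c("x", "y", "z")])
      dd <- sqrt(rowSums((xyzl[cmb[, 1], , drop = FALSE] -
                            xyzl[cmb[, 2], , drop = FALSE])^2))
      cross <- leftover$structure_id[cmb[, 1]] != leftover$structure_id[cmb[, 2]]
      okp <- which(cross & dd <= threshold)
      okp <- okp[order(dd[okp],
                       leftover$sorder[cmb[okp, 1]], leftover$rorder[cmb[okp, 1]],
                       leftover$sorder[cmb[okp, 2]], leftover$rorder[cmb[okp, 2]])]
      nextc <- 0L
      for (pidx in okp) {
        i <- cmb[pidx, 1]; j <- cmb[pidx, 2]
        ci <- cl[i]; cj <- cl[j]
        if (ci == 0 && cj == 0) {
          nextc <- nextc + 1L; cl[i] <- nextc; cl[j] <- nextc
        } else if (ci > 0 && cj == 0) {
          if (!leftover$structure_id[j] %in% leftover$structure_id[cl == ci])
            cl[j] <- ci
        } else if (ci == 0 && cj > 0) {
          if (!leftover$structure_id[i] %in% leftover$structure_id[cl == cj])
            cl[i] <- cj
        } else if (ci != cj) {
          if (!length(intersect(leftover$structure_id[cl == ci],
                                leftover$structure_id[cl == cj])))
            cl[cl == cj] <- ci
        }
      }
    }
    cl[cl == 0] <- max(cl, 0L) + seq_len(sum(cl == 0))
    for (g in split(seq_len(nrow(leftover)), cl)) {
      g <- g[order(leftover$sorder[g], leftover$rorder[g])]
      extra_positions[[length(extra_positions) + 1L]] <-
        stats::setNames(leftover$key[g], leftover$structure_id[g])
    }
    lkey <- paste(leftover$structure_id, leftover$key)
    ord <- order(vapply(extra_positions, function(p)
      match(names(p)[1], ids), 0L),
      vapply(extra_positions, function(p)
        leftover$rorder[match(paste(names(p)[1], p[1]), lkey)], 0L))
    extra_positions <- extra_positions[ord]
  }

  positions <- c(members, extra_positions)
  names(positions) <- sprintf("P%02d", seq_along(positions))
  structure(list(reference_id = reference, threshold = threshold,
                 structure_ids = ids, positions = positions),
            class = "position_map")
}

#' @export
print.position_map <- function(x, ...) {
  cat("<position_map>", length(x$positions), "positions x",
      length(x$structure_ids), "structures (reference", x$reference_id, ")\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path FASTA file of equal-length aligned sequences (`-` for gaps)
#' @return named character vector of aligned sequences
#' @export
read_msa_fasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || hdr[1] != TRUE) stop("not a FASTA file: ", path)
  id <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste, "", collapse = "")
  names(seqs) <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  if (length(unique(nchar(seqs))) != 1)
    stop("aligned FASTA sequences differ in length")
  toupper(seqs)
}

#' Positions from an externally produced multiple alignment
#'
#' Instead of the built-in superposition route, an aligned FASTA (sequence
#' names matching structure ids, ungapped sequences identical to the
#' structure sequences) can define the spatial positions directly: every
#' alignment column holding at least one predicted residue becomes a
#' position, and gap characters become gap cells.
#'
#' @param msa named character vector of aligned sequences (see
#'   [read_msa_fasta()]) or a path to an aligned FASTA file
#' @param structures list of `protein_structure`
#' @param sites list of `predicted_site`, parallel to `structures`
#' @return object of class `position_map`
#' @export
import_msa_positions <- function(msa, structures, sites) {
  if (is.character(msa) && length(msa) == 1 && file.exists(msa))
    msa <- read_msa_fasta(msa)
  ids <- unname(vapply(structures, function(s) s$structure_id, ""))
  names(structures) <- ids
  names(sites) <- vapply(sites, function(s) s$structure_id, "")
  miss <- setdiff(ids, names(msa))
  if (length(miss))
    stop("MSA is missing sequence(s): ", paste(miss, collapse = ", "))
  ncol_msa <- unique(nchar(msa))
  if (length(ncol_msa) != 1) stop("aligned sequences differ in length")

  colmap <- list()  # per structure: column -> residue index (0 = gap)
  for (sid in ids) {
    al <- strsplit(msa[[sid]], "")[[1]]
    res <- structures[[sid]]$residues
    ung <- al[al != "-"]
    sq <- strsplit(structure_sequence(structures[[sid]]), "")[[1]]
    if (length(ung) != length(sq) || any(ung != sq)) {
      bad <- if (length(ung) != length(sq)) min(length(ung), length(sq)) + 1L
             else which(ung != sq)[1]
      bad <- min(bad, length(sq))
      stop("MSA sequence for ", sid, " disagrees with the structure at ",
           "residue ", res$key[bad],
           " (structure has ", sq[bad], ")")
    }
    idx <- integer(ncol_msa)
    idx[al != "-"] <- seq_along(sq)
    colmap[[sid]] <- idx
  }

  keep_cols <- integer(0)
  for (col in seq_len(ncol_msa)) {
    has_pred <- any(vapply(ids, function(sid) {
      ri <- colmap[[sid]][col]
      ri > 0 && structures[[sid]]$residues$key[ri] %in% sites[[sid]]$members
    }, NA))
    if (has_pred) keep_cols <- c(keep_cols, col)
  }

  positions <- lapply(keep_cols, function(col) {
    mem <- character(0)
    for (sid in ids) {
      ri <- colmap[[sid]][col]
      if (ri > 0) mem[sid] <- structures[[sid]]$residues$key[ri]
    }
    mem
  })
  names(positions) <- sprintf("P%02d", seq_along(positions))
  structure(list(reference_id = ids[1], threshold = NA_real_,
                 structure_ids = ids, positions = positions),
            class = "position_map")
}

#' Export a position map as TSV
#'
#' Long format: one row per (position, structure) pair, gap rows included
#' with empty residue fields.
#'
#' @param pm a `position_map`
#' @param structures list of `protein_structure` backing the map
#' @param sites list of `predicted_site` (for the predicted flag)
#' @param path output file
#' @return `path`, invisibly
#' @export
write_position_map <- function(pm, structures, sites, path) {
  names(structures) <- vapply(structures, function(s) s$structure_id, "")
  names(sites) <- vapply(sites, function(s) s$structure_id, "")
  rows <- list()
  for (p in seq_along(pm$positions)) {
    mem <- pm$positions[[p]]
    for (sid in pm$structure_ids) {
      key <- if (sid %in% names(mem)) mem[[sid]] else NA_character_
      if (is.na(key)) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = names(pm$positions)[p], structure_id = sid,
          chain = "", res_seq = NA_integer_, icode = "", code1 = "",
          predicted = "gap", stringsAsFactors = FALSE)
      } else {
        r <- structures[[sid]]$residues
        ri <- match(key, r$key)
        rows[[length(rows) + 1L]] <- data.frame(
          position = names(pm$positions)[p], structure_id = sid,
          chain = r$chain_id[ri], res_seq = r$res_seq[ri],
          icode = r$icode[ri], code1 = r$code1[ri],
          predicted = if (key %in% sites[[sid]]$members) "predicted" else "unpredicted",
          stringsAsFactors = FALSE)
      }
    }
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
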