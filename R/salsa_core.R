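# SALSA tables and their scoring. A table's rows are structures, its
# columns spatially aligned positions; cells are residues carrying a
# predicted flag (rendered uppercase/lowercase in the TSV form) or gaps
# ("-"). A consensus signature summarises the predicted residue types of a
# functional subclass; queries are scored against it with BLOSUM62.
#
# Scoring convention (applied uniformly): an unpredicted residue cell is
# scored as the ambiguity code X, a gap cell costs a fixed penalty
# (default -3), and a signature's perfect-match maximum uses actual residue
# types regardless of predicted status.

#' Construct a SALSA table
#'
#' @param cells data.frame with one row per (structure, position) pair and
#'   columns `structure_id`, `position`, `code1`, `res_seq`, `icode`,
#'   `predicted`, `gap`
#' @param structure_order,position_order row and column display order
#' @param annotations optional named character vector of per-position labels
#'   (secondary-structure elements, notes)
#' @return object of class `salsa_table`
#' @export
salsa_table <- function(cells, structure_order = unique(cells$structure_id),
                        position_order = unique(cells$position),
                        annotations = NULL) {
  need <- c("structure_id", "position", "code1", "res_seq", "icode",
            "predicted", "gap")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stop("cells missing column(s): ", paste(miss, collapse = ", "))
  full <- expand.grid(structure_id = structure_order, position = position_order,
                      stringsAsFactors = FALSE)
  got <- paste(cells$structure_id, cells$position, sep = "\r")
  if (anyDuplicated(got)) stop("more than one cell for a (structure, position)")
  if (!setequal(got, paste(full$structure_id, full$position, sep = "\r")))
    stop("cells must cover every (structure, position) exactly once")
  ok <- cells$gap | cells$code1 %in% c(.AA20, "X")
  if (!all(ok)) stop("invalid one-letter code in non-gap cell")
  rownames(cells) <- NULL
  structure(list(structure_order = structure_order,
                 position_order = position_order,
                 cells = cells, annotations = annotations),
            class = "salsa_table")
}

#' Cells of one table row in column order
#'
#' @param table a `salsa_table`
#' @param structure_id row identifier
#' @param positions optional subset/order of position ids (default: table
#'   column order)
#' @return data.frame of cells ordered as requested
#' @export
salsa_row <- function(table, structure_id, positions = NULL) {
  if (!structure_id %in% table$structure_order)
    stop("no row '", structure_id, "' in table")
  positions <- positions %||% table$position_order
  miss <- setdiff(positions, table$position_order)
  if (length(miss)) stop("unknown position(s): ", paste(miss, collapse = ", "))
  cc <- table$cells[table$cells$structure_id == structure_id, , drop = FALSE]
  out <- cc[match(positions, cc$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

cell_text <- function(cells) {
  ifelse(cells$gap, "-",
         paste0(ifelse(cells$predicted, cells$code1, tolower(cells$code1)),
                cells$res_seq, cells$icode))
}

#' @export
print.salsa_table <- function(x, ...) {
  m <- do.call(rbind, lapply(x$structure_order, function(sid)
    cell_text(salsa_row(x, sid))))
  dimnames(m) <- list(x$structure_order, x$position_order)
  cat("<salsa_table>", length(x$structure_order), "structures x",
      length(x$position_order), "positions\n")
  print(m, quote = FALSE)
  invisible(x)
}

#' Build a SALSA table from a position map
#'
#' @param position_map a `position_map` from [map_site_positions()] or
#'   [import_msa_positions()]
#' @param sites list of `predicted_site` (provides the predicted flags)
#' @param structures list of `protein_structure`
#' @return a [salsa_table()]; rows follow the position map's structure
#'   order, columns its position order
#' @export
build_salsa_table <- function(position_map, sites, structures) {
  ids <- position_map$structure_ids
  names(structures) <- vapply(structures, function(s) s$structure_id, "")
  names(sites) <- vapply(sites, function(s) s$structure_id, "")
  if (!all(ids %in% names(structures)) || !all(ids %in% names(sites)))
    stop("position map refers to structures absent from inputs")
  rows <- list()
  for (p in seq_along(position_map$positions)) {
    pos <- names(position_map$positions)[p]
    mem <- position_map$positions[[p]]
    for (sid in ids) {
      if (sid %in% names(mem)) {
        r <- structures[[sid]]$residues
        ri <- match(mem[[sid]], r$key)
        if (is.na(ri))
          stop("integrity error: position ", pos, " refers to unknown residue ",
               mem[[sid]], " of ", sid)
        rows[[length(rows) + 1L]] <- data.frame(
          structure_id = sid, position = pos, code1 = r$code1[ri],
          res_seq = r$res_seq[ri], icode = r$icode[ri],
          predicted = mem[[sid]] %in% sites[[sid]]$members, gap = FALSE,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          structure_id = sid, position = pos, code1 = NA_character_,
          res_seq = NA_integer_, icode = "", predicted = FALSE, gap = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    cells <- data.frame(structure_id = character(0), position = character(0),
                        code1 = character(0), res_seq = integer(0),
                        icode = character(0), predicted = logical(0),
                        gap = logical(0))
    return(salsa_table(cells, structure_order = ids, position_order = character(0)))
  }
  salsa_table(do.call(rbind, rows), structure_order = ids,
              position_order = names(position_map$positions))
}

#' Write a SALSA table in the published typography
#'
#' TSV with one row per structure; cells are `<code><res_seq><icode>` with
#' uppercase for predicted residues, lowercase for unpredicted ones, and
#' `-` for gaps. An optional `#annotation` comment line carries per-position
#' labels.
#'
#' @param table a `salsa_table`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_salsa_table <- function(table, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(c("structure_id", table$position_order), collapse = "\t"), con)
  if (!is.null(table$annotations)) {
    ann <- table$annotations[table$position_order]
    ann[is.na(ann)] <- ""
    writeLines(paste(c("#annotation", ann), collapse = "\t"), con)
  }
  for (sid in table$structure_order) {
    writeLines(paste(c(sid, cell_text(salsa_row(table, sid))), collapse = "\t"), con)
  }
  invisible(path)
}

parse_cell <- function(txt) {
  if (txt == "-")
    return(data.frame(code1 = NA_character_, res_seq = NA_integer_, icode = "",
                      predicted = FALSE, gap = TRUE, stringsAsFactors = FALSE))
  m <- regmatches(txt, regexec("^([A-Za-z])([0-9]+)([A-Za-z]?)$", txt))[[1]]
  if (!length(m)) stop("cannot parse SALSA cell '", txt, "'")
  data.frame(code1 = toupper(m[2]), res_seq = as.integer(m[3]), icode = m[4],
             predicted = m[2] == toupper(m[2]), gap = FALSE,
             stringsAsFactors = FALSE)
}

#' Read a SALSA table written by [write_salsa_table()]
#'
#' @param path TSV file
#' @return a [salsa_table()]
#' @export
read_salsa_table <- function(path) {
  if (!file.exists(path)) stop("cannot read SALSA table: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (hdr[1] != "structure_id") stop("not a SALSA table TSV: ", path)
  positions <- hdr[-1]
  annotations <- NULL
  body <- lines[-1]
  ann_i <- grepl("^#annotation\t", body)
  if (any(ann_i)) {
    av <- strsplit(body[ann_i][1], "\t", fixed = TRUE)[[1]][-1]
    length(av) <- length(positions)
    annotations <- stats::setNames(av, positions)
  }
  body <- body[!grepl("^#", body)]
  rows <- list()
  sids <- character(0)
  for (ln in body) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) != length(positions) + 1)
      stop("row '", f[1], "' has ", length(f) - 1, " cells, expected ",
           length(positions))
    sids <- c(sids, f[1])
    for (j in seq_along(positions)) {
      cell <- parse_cell(f[j + 1])
      cell$structure_id <- f[1]; cell$position <- positions[j]
      rows[[length(rows) + 1L]] <- cell
    }
  }
  salsa_table(do.call(rbind, rows), structure_order = sids,
              position_order = positions, annotations = annotations)
}

# ---- signatures ------------------------------------------------------------

new_signature <- function(positions, majority_threshold = NA_real_,
                          source = "consensus") {
  structure(list(positions = positions,
                 majority_threshold = majority_threshold,
                 source = source),
            class = "consensus_signature")
}

#' @export
print.consensus_signature <- function(x, ...) {
  p <- x$positions
  cat("<consensus_signature> (", paste(p$code1, collapse = ", "), ") from ",
      x$source, "; maximum self-match ", max_score(x), "\n", sep = "")
  invisible(x)
}

#' Majority-rule consensus signature of a SALSA table
#'
#' For each column, the reference rows whose cell is a predicted residue of
#' the modal amino-acid type are counted; the column enters the signature
#' iff that count exceeds `majority_threshold` of the reference rows
#' (strictly greater). A tie for the modal type drops the column rather
#' than guessing. Retained columns keep table order.
#'
#' @param table a `salsa_table`
#' @param reference_rows structure ids of the previously characterized
#'   proteins defining the signature
#' @param majority_threshold fraction in `[0.5, 1)`; default 0.5
#' @return a `consensus_signature` whose positions carry the consensus
#'   type, its support count, and the number of reference rows
#' @export
derive_consensus <- function(table, reference_rows, majority_threshold = 0.5) {
  if (!length(reference_rows)) stop("reference_rows must be non-empty")
  miss <- setdiff(reference_rows, table$structure_order)
  if (length(miss)) stop("reference row(s) not in table: ", paste(miss, collapse = ", "))
  if (!is.numeric(majority_threshold) || majority_threshold < 0.5 ||
      majority_threshold >= 1)
    stop("majority_threshold must be in [0.5, 1)")
  n_ref <- length(reference_rows)
  keep <- list()
  for (pos in table$position_order) {
    cc <- table$cells[table$cells$position == pos &
                        table$cells$structure_id %in% reference_rows &
                        !table$cells$gap & table$cells$predicted, , drop = FALSE]
    if (!nrow(cc)) next
    tab <- table(cc$code1)
    top <- max(tab)
    if (sum(tab == top) > 1) next               # modal tie: drop the position
    if (top / n_ref <= majority_threshold) next
    keep[[length(keep) + 1L]] <- data.frame(
      position = pos, code1 = names(tab)[which.max(tab)], predicted = TRUE,
      support = as.integer(top), n_ref = n_ref, stringsAsFactors = FALSE)
  }
  if (!length(keep)) stop("no position passes the majority rule")
  new_signature(do.call(rbind, keep), majority_threshold, source = "consensus")
}

#' Signature defined by a single table row
#'
#' When too few characterized proteins exist for a consensus, a single
#' characterized structure's row can serve as the comparison target. Gap
#' cells are dropped; unpredicted (lowercase) residues stay in the
#' signature with their actual type — they count toward the perfect-match
#' maximum but are scored as `X` during comparison.
#'
#' @param table a `salsa_table`
#' @param structure_id row to take as the signature
#' @return a `consensus_signature`
#' @export
row_signature <- function(table, structure_id) {
  cc <- salsa_row(table, structure_id)
  cc <- cc[!cc$gap, , drop = FALSE]
  if (!nrow(cc)) stop("row '", structure_id, "' has no residue cells")
  new_signature(data.frame(position = cc$position, code1 = cc$code1,
                           predicted = cc$predicted, support = NA_integer_,
                           n_ref = NA_integer_, stringsAsFactors = FALSE),
                source = structure_id)
}

#' Perfect-match maximum of a signature
#'
#' The BLOSUM62 self-match score of the signature: the sum of diagonal
#' entries for the actual amino-acid types at every signature position,
#' regardless of predicted status. Match scores are reported as a
#' percentage of this value.
#'
#' @param signature a `consensus_signature`
#' @return integer maximum score
#' @export
max_score <- function(signature) {
  p <- signature$positions
  if (!nrow(p)) stop("empty signature")
  sum(blosum62(p$code1, p$code1))
}

#' Score a query site row against a signature
#'
#' Position by position, the effective code of a residue cell is its actual
#' type if predicted and `X` otherwise (on both the query and the signature
#' side); the contribution is the BLOSUM62 score of the two effective
#' codes. A gap cell in the query contributes `gap_penalty`. The raw sum is
#' also expressed as a nearest-integer percentage (ties away from zero) of
#' the signature's perfect self-match.
#'
#' @param query_row data.frame of cells aligned to the signature positions
#'   (columns `code1`, `predicted`, `gap`; e.g. from [salsa_row()])
#' @param signature a `consensus_signature`
#' @param gap_penalty score of a gap cell (default -3)
#' @return object of class `match_score` with `raw`, `max`, `percent` and
#'   `per_position`
#' @export
score_match <- function(query_row, signature, gap_penalty = -3) {
  p <- signature$positions
  if (nrow(query_row) != nrow(p))
    stop("query row has ", nrow(query_row), " cells but the signature has ",
         nrow(p), " positions")
  if (length(gap_penalty) != 1 || !is.finite(gap_penalty) ||
      gap_penalty != round(gap_penalty))
    stop("gap_penalty must be a single integer")
  gap_penalty <- as.integer(gap_penalty)
  sig_eff <- ifelse(p$predicted, p$code1, "X")
  q_eff <- ifelse(query_row$gap, NA, ifelse(query_row$predicted,
                                            query_row$code1, "X"))
  contrib <- integer(nrow(p))
  for (i in seq_len(nrow(p))) {
    contrib[i] <- if (query_row$gap[i]) gap_penalty
                  else blosum62(sig_eff[i], q_eff[i])
  }
  mx <- max_score(signature)
  if (mx == 0) stop("undefined percent: signature maximum is 0")
  raw <- sum(contrib)
  structure(list(
    raw = raw, max = mx,
    percent = as.integer(round_half_away(100 * raw / mx)),
    gap_penalty = gap_penalty,
    per_position = data.frame(
      position = p$position,
      query = ifelse(query_row$gap, "-",
                     ifelse(query_row$predicted, query_row$code1,
                            tolower(query_row$code1))),
      consensus = ifelse(p$predicted, p$code1, tolower(p$code1)),
      contribution = contrib, stringsAsFactors = FALSE)),
    class = "match_score")
}

#' @export
print.match_score <- function(x, ...) {
  cat(sprintf("<match_score> raw %d / max %d = %d%% of maximum\n",
              x$raw, x$max, x$percent))
  invisible(x)
}

#' Score a table row against a signature derived from the same table
#'
#' Convenience wrapper extracting the query cells at the signature's
#' positions before calling [score_match()].
#'
#' @inheritParams score_match
#' @param table a `salsa_table`
#' @param query_id row to score
#' @return a `match_score`
#' @export
score_table_row <- function(table, query_id, signature, gap_penalty = -3) {
  score_match(salsa_row(table, query_id, signature$positions$position),
              signature, gap_penalty)
}

#' Rank candidate signatures for a query
#'
#' Sorts match scores by percent of maximum (stable for ties, which are
#' reported explicitly) and flags negative-percent candidates as
#' incompatible. No hard acceptance threshold is imposed; the ranking is a
#' decision aid.
#'
#' @param scores list of `match_score`
#' @param labels candidate labels (default `names(scores)` or an index)
#' @return data.frame of class `match_report`, best candidate first
#' @export
classify_match <- function(scores, labels = NULL) {
  if (!length(scores)) stop("at least one match score is required")
  if (inherits(scores, "match_score")) scores <- list(scores)
  labels <- labels %||% names(scores) %||% as.character(seq_along(scores))
  if (is.null(names(scores)) && length(labels) != length(scores))
    stop("labels must match scores")
  pct <- vapply(scores, function(s) s$percent, 0L)
  ord <- order(-pct, seq_along(pct))   # stable: ties keep input order
  rep <- data.frame(
    label = labels[ord],
    raw = vapply(scores, function(s) s$raw, 0L)[ord],
    max = vapply(scores, function(s) s$max, 0L)[ord],
    percent = pct[ord],
    best = FALSE,
    tie_with_best = FALSE,
    incompatible = pct[ord] < 0,
    stringsAsFactors = FALSE)
  rep$best[1] <- TRUE
  rep$tie_with_best <- rep$percent == rep$percent[1]
  class(rep) <- c("match_report", "data.frame")
  rep
}

#' Write a match score as JSON
#'
#' @param score a `match_score`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_match_score <- function(score, path) {
  jsonlite::write_json(list(raw = score$raw, max = score$max,
                            percent = score$percent,
                            gap_penalty = score$gap_penalty,
                            per_position = score$per_position),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
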