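# Ingestion of per-residue functional-likelihood rankings (POOL-style) and
# extraction of the predicted site as the top fraction of the ranked list.
# The ranker itself (electrostatics, phylogeny, pocket geometry) is external;
# only its ordered output is consumed here.

#' Construct a residue ranking
#'
#' @param structure_id identifier matching the companion structure
#' @param entries data.frame with columns `chain_id`, `res_seq`, `icode`,
#'   `code1`, `rank` and optionally `score`; ranks must be a permutation of
#'   `1..N`
#' @return object of class `residue_ranking`, entries sorted by rank
#' @export
residue_ranking <- function(structure_id, entries) {
  need <- c("chain_id", "res_seq", "icode", "code1", "rank")
  miss <- setdiff(need, names(entries))
  if (length(miss)) stop("ranking missing column(s): ", paste(miss, collapse = ", "))
  n <- nrow(entries)
  if (n == 0) stop("empty ranking")
  r <- as.integer(entries$rank)
  if (anyDuplicated(r) || !setequal(r, seq_len(n)))
    stop("ranking format error: ranks must be a permutation of 1..", n)
  if (!all(entries$code1 %in% c(.AA20, "X")))
    stop("ranking format error: unknown amino-acid letter")
  entries <- entries[order(r), , drop = FALSE]
  entries$rank <- sort(r)
  entries$key <- residue_key(entries$chain_id, entries$res_seq, entries$icode)
  if (anyDuplicated(entries$key)) stop("ranking format error: duplicate residue")
  rownames(entries) <- NULL
  structure(list(structure_id = structure_id, entries = entries),
            class = "residue_ranking")
}

#' @export
print.residue_ranking <- function(x, ...) {
  cat("<residue_ranking>", x$structure_id, "-", nrow(x$entries), "residues\n")
  invisible(x)
}

#' Read a residue ranking from a tab-separated file
#'
#' Expected columns: `structure_id`, `chain`, `res_seq`, `icode`,
#' `resname1`, `rank` and optionally `score`. Ranks must form a permutation
#' of `1..N`.
#'
#' @param path TSV file with header
#' @return a [residue_ranking()]
#' @export
read_rankings <- function(path) {
  if (!file.exists(path)) stop("cannot read rankings file: ", path)
  d <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("structure_id", "chain", "res_seq", "icode", "resname1", "rank")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("ranking format error: missing column(s): ",
                         paste(miss, collapse = ", "))
  entries <- data.frame(
    chain_id = d$chain,
    res_seq = as.integer(d$res_seq),
    icode = ifelse(is.na(d$icode), "", d$icode),
    code1 = toupper(d$resname1),
    rank = as.integer(d$rank),
    stringsAsFactors = FALSE
  )
  if ("score" %in% names(d)) entries$score <- as.numeric(d$score)
  sid <- unique(d$structure_id)
  if (length(sid) != 1)
    stop("ranking format error: multiple structure_id values in one file")
  residue_ranking(sid, entries)
}

#' Write a residue ranking to the package's TSV dialect
#'
#' @param ranking a [residue_ranking()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_rankings <- function(ranking, path) {
  e <- ranking$entries
  d <- data.frame(structure_id = ranking$structure_id,
                  chain = e$chain_id, res_seq = e$res_seq, icode = e$icode,
                  resname1 = e$code1, rank = e$rank,
                  stringsAsFactors = FALSE)
  if (!is.null(e$score)) d$score <- format(e$score, digits = 6, trim = TRUE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Predicted site as the top fraction of a ranking
#'
#' The site comprises the `ceiling(fraction * N)` top-ranked residues, so
#' any nonzero fraction yields at least one residue. The cut-off fraction
#' is a per-run parameter; published analyses use values such as 0.08-0.09
#' depending on the protein family.
#'
#' @param ranking a [residue_ranking()]
#' @param fraction cut-off in `(0, 1]`
#' @return object of class `predicted_site` with `members` (residue keys in
#'   rank order), `cutoff_fraction` and `structure_id`
#' @export
select_top_fraction <- function(ranking, fraction) {
  if (!inherits(ranking, "residue_ranking")) stop("not a residue_ranking")
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      !is.finite(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  n <- nrow(ranking$entries)
  k <- as.integer(ceiling(fraction * n))
  structure(list(structure_id = ranking$structure_id,
                 cutoff_fraction = fraction,
                 members = ranking$entries$key[seq_len(k)]),
            class = "predicted_site")
}

#' @export
print.predicted_site <- function(x, ...) {
  cat("<predicted_site>", x$structure_id, "- top",
      sprintf("%.1f%%", 100 * x$cutoff_fraction), "=",
      length(x$members), "residues\n")
  invisible(x)
}
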