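# Data-level errors carry class "gklink_data_error" so callers (notably the
# CLI) can distinguish bad inputs from programming errors.
gk_data_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("gklink_data_error", "error")))
}

#' Read a miRNA-lncRNA interaction edge list
#'
#' Parses a delimited two-column edge list (miRNA identifier, lncRNA
#' identifier), one interaction per line. Lines starting with `#` are
#' comments. Duplicate pairs are dropped silently (the observed network is a
#' set of interactions, not a multiset); the number dropped is reported via
#' [message()].
#'
#' @param source path to the file, or a connection.
#' @param delimiter field delimiter, default tab.
#' @return A data.frame of class `gklink_interactions` with character columns
#'   `mirna_id` and `lncrna_id`, unique pairs in first-seen order.
#' @examples
#' tf <- tempfile()
#' writeLines(c("mir-1\tlnc-A", "mir-1\tlnc-B", "mir-2\tlnc-A"), tf)
#' read_interactions(tf)
#' @export
read_interactions <- function(source, delimiter = "\t") {
  lines <- readLines(source, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    gk_data_error("empty interaction input: no data lines found")
  }
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    bad <- line_no[which(nf < 2L)[1L]]
    gk_data_error("malformed interaction line ", bad,
                  ": expected at least 2 delimited fields")
  }
  mirna <- trimws(vapply(parts, `[[`, "", 1L))
  lncrna <- trimws(vapply(parts, `[[`, "", 2L))
  if (any(!nzchar(mirna)) || any(!nzchar(lncrna))) {
    bad <- line_no[which(!nzchar(mirna) | !nzchar(lncrna))[1L]]
    gk_data_error("empty identifier on interaction line ", bad)
  }
  dup <- duplicated(paste(mirna, lncrna, sep = "\r"))
  if (any(dup)) {
    message(sum(dup), " duplicate interaction pair(s) dropped")
  }
  out <- data.frame(mirna_id = mirna[!dup], lncrna_id = lncrna[!dup],
                    stringsAsFactors = FALSE)
  class(out) <- c("gklink_interactions", "data.frame")
  out
}

#' Build an indexed bipartite dataset from an interaction table
#'
#' Assigns row indices to miRNAs and column indices to lncRNAs in first-seen
#' order and materializes the binary adjacency matrix `adj` (1 = observed
#' interaction, 0 = unobserved pair).
#'
#' @param table a `gklink_interactions` data.frame (or any data.frame with
#'   columns `mirna_id`, `lncrna_id`).
#' @return An object of class `gklink_dataset`: a list with `mirna_ids`,
#'   `lncrna_ids` (character vectors) and `adj` (binary matrix, miRNAs in
#'   rows, lncRNAs in columns, dimnames set to the identifiers).
#' @export
build_dataset <- function(table) {
  if (NROW(table) == 0L) gk_data_error("empty interaction table")
  mirna_ids <- unique(as.character(table$mirna_id))
  lncrna_ids <- unique(as.character(table$lncrna_id))
  adj <- matrix(0, length(mirna_ids), length(lncrna_ids),
                dimnames = list(mirna_ids, lncrna_ids))
  adj[cbind(match(table$mirna_id, mirna_ids),
            match(table$lncrna_id, lncrna_ids))] <- 1
  new_dataset(mirna_ids, lncrna_ids, adj)
}

new_dataset <- function(mirna_ids, lncrna_ids, adj) {
  stopifnot(nrow(adj) == length(mirna_ids), ncol(adj) == length(lncrna_ids),
            all(adj %in% c(0, 1)))
  structure(list(mirna_ids = mirna_ids, lncrna_ids = lncrna_ids, adj = adj),
            class = "gklink_dataset")
}

#' @export
print.gklink_dataset <- function(x, ...) {
  cat("miRNA-lncRNA interaction dataset\n")
  cat(sprintf("  %d miRNAs x %d lncRNAs, %d interactions (density %.2f%%)\n",
              length(x$mirna_ids), length(x$lncrna_ids), sum(x$adj),
              100 * mean(x$adj)))
  invisible(x)
}

#' Read RNA sequences from a FASTA file
#'
#' The identifier is the header token up to the first whitespace. Sequences
#' are upper-cased and DNA-convention `T` is normalized to `U`, so only the
#' RNA alphabet `{A, C, G, U}` remains.
#'
#' @param source path to a FASTA file.
#' @return Named character vector of RNA sequences (class
#'   `gklink_sequences`).
#' @export
read_fasta <- function(source) {
  set <- Biostrings::readBStringSet(source)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    gk_data_error("duplicate FASTA identifier: ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    gk_data_error("empty sequence for record ", ids[!nzchar(seqs)][1L])
  }
  bad <- grepl("[^ACGTU]", seqs)
  if (any(bad)) {
    gk_data_error("sequence for record ", ids[bad][1L],
                  " contains symbols outside {A,C,G,U,T}")
  }
  seqs <- chartr("T", "U", seqs)
  names(seqs) <- ids
  structure(seqs, class = "gklink_sequences")
}

#' Read an expression matrix
#'
#' Expects a header row of condition labels and one row per RNA whose first
#' column is the identifier; all other cells must be numeric. All RNAs share
#' the same conditions, so every expression vector has the same length.
#'
#' @param source path or connection.
#' @param delimiter field delimiter, default comma.
#' @return A numeric matrix (RNAs in rows, conditions in columns) of class
#'   `gklink_expression`.
#' @export
read_expression <- function(source, delimiter = ",") {
  lines <- readLines(source, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) gk_data_error("expression input needs a header and at least one data row")
  header <- strsplit(lines[1L], delimiter, fixed = TRUE)[[1L]]
  conds <- trimws(header[-1L])
  if (length(conds) == 0L) gk_data_error("expression header has no condition columns")
  rows <- strsplit(lines[-1L], delimiter, fixed = TRUE)
  ids <- character(length(rows))
  vals <- matrix(NA_real_, length(rows), length(conds))
  for (i in seq_along(rows)) {
    r <- rows[[i]]
    if (length(r) != length(conds) + 1L) {
      gk_data_error("ragged expression row for '", trimws(r[1L]),
                    "': expected ", length(conds), " values, got ", length(r) - 1L)
    }
    ids[i] <- trimws(r[1L])
    v <- suppressWarnings(as.numeric(r[-1L]))
    if (anyNA(v)) gk_data_error("non-numeric expression value in row '", ids[i], "'")
    vals[i, ] <- v
  }
  if (anyDuplicated(ids)) gk_data_error("duplicate expression identifier: ",
                                        ids[duplicated(ids)][1L])
  dimnames(vals) <- list(ids, conds)
  structure(vals, class = c("gklink_expression", "matrix"))
}

#' Read functional annotations
#'
#' Two-column delimited input: RNA identifier, annotation-term identifier.
#' Terms are grouped into sets per RNA; duplicated (RNA, term) lines
#' collapse. Terms are opaque strings.
#'
#' @param source path or connection.
#' @param delimiter field delimiter, default tab.
#' @return A named list of character vectors (term sets), class
#'   `gklink_annotations`. Empty input yields an empty table.
#' @export
read_annotations <- function(source, delimiter = "\t") {
  lines <- readLines(source, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(structure(setNames(list(), character()), class = "gklink_annotations"))
  }
  parts <- strsplit(lines, delimiter, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2L)) {
    gk_data_error("malformed annotation line ", line_no[which(nf < 2L)[1L]],
                  ": expected 2 fields")
  }
  rna <- trimws(vapply(parts, `[[`, "", 1L))
  term <- trimws(vapply(parts, `[[`, "", 2L))
  sets <- lapply(split(term, factor(rna, levels = unique(rna))), unique)
  structure(sets, class = "gklink_annotations")
}

#' Write ranked prediction scores as TSV
#'
#' Emits one row per (miRNA, lncRNA) pair with columns `mirna_id`,
#' `lncrna_id`, `score`, `known` (the observed adjacency value) and a 1-based
#' `rank`. Rows are sorted by descending score; ties are broken by
#' lexicographic (mirna_id, lncrna_id) order so output is deterministic.
#'
#' @param scores numeric matrix, miRNAs x lncRNAs, matching `dataset`.
#' @param dataset a `gklink_dataset`.
#' @param sink output path or connection.
#' @return Invisibly, the written data.frame.
#' @export
write_scores <- function(scores, dataset, sink) {
  m <- length(dataset$mirna_ids); l <- length(dataset$lncrna_ids)
  if (!is.matrix(scores) || nrow(scores) != m || ncol(scores) != l) {
    gk_data_error("score matrix dimensions do not match the dataset (",
                  m, "x", l, ")")
  }
  df <- write_scores_df(scores, dataset)
  con <- if (is.character(sink)) file(sink, "w") else sink
  if (is.character(sink)) on.exit(close(con))
  writeLines(paste(c("mirna_id", "lncrna_id", "score", "known", "rank"),
                   collapse = "\t"), con)
  writeLines(sprintf("%s\t%s\t%.10g\t%d\t%d", df$mirna_id, df$lncrna_id,
                     df$score, df$known, df$rank), con)
  invisible(df)
}
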