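# RNA-RNA similarity constructions. Every function returns a square
# symmetric matrix with entries in [0, 1] and unit diagonal; downstream code
# relies on that contract when stacking similarities into the integrated
# adjacency.

check_similarity <- function(s, tol = 1e-10) {
  stopifnot(is.matrix(s), nrow(s) == ncol(s))
  if (any(!is.finite(s))) gk_data_error("non-finite similarity value")
  if (max(abs(s - t(s))) > tol) gk_data_error("similarity matrix not symmetric")
  if (min(s) < -tol || max(s) > 1 + tol) {
    gk_data_error("similarity values outside [0, 1]")
  }
  s
}

#' Gaussian interaction-profile kernel bandwidth
#'
#' The bandwidth is the reciprocal of the mean squared Euclidean row norm of
#' the profile matrix: `gamma = n / sum_i ||row_i||^2`. Normalizing this way
#' makes the kernel invariant to a common rescaling of all profiles.
#'
#' @param pf numeric profile matrix, one RNA per row.
#' @return A positive scalar.
#' @examples
#' gaussian_bandwidth(diag(2)) # 2 / (1 + 1) = 1
#' @export
gaussian_bandwidth <- function(pf) {
  pf <- as.matrix(pf)
  ss <- sum(pf^2)
  if (ss == 0) gk_data_error("degenerate profile: all rows are zero")
  nrow(pf) / ss
}

#' Gaussian kernel similarity between profile rows
#'
#' `K(i, j) = exp(-gamma * ||row_i - row_j||^2)` with the bandwidth from
#' [gaussian_bandwidth()]. Applied to rows of a 0/1 adjacency this is the
#' Gaussian interaction-profile (GIP) kernel: RNAs sharing partners come out
#' similar.
#'
#' @param pf numeric profile matrix, one RNA per row; rownames carried over.
#' @return Symmetric similarity matrix with unit diagonal, entries in (0, 1].
#' @export
gaussian_kernel <- function(pf) {
  pf <- as.matrix(pf)
  gamma <- gaussian_bandwidth(pf)
  sq <- rowSums(pf^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(pf)
  d2[d2 < 0] <- 0  # numerical noise from the expansion
  k <- exp(-gamma * d2)
  k <- (k + t(k)) / 2
  diag(k) <- 1
  dimnames(k) <- list(rownames(pf), rownames(pf))
  check_similarity(k)
}

#' Gaussian kernel similarities from the interaction network itself
#'
#' Computes the miRNA similarity from the rows of the bipartite adjacency
#' (each miRNA's interaction profile) and the lncRNA similarity from its
#' columns. This is the "network profile" mode: no side data needed beyond
#' the observed network.
#'
#' @param adj binary interaction matrix, miRNAs x lncRNAs.
#' @return List with elements `mirna` (m x m) and `lncrna` (l x l).
#' @export
network_similarities <- function(adj) {
  adj <- as.matrix(adj)
  if (sum(adj) == 0) gk_data_error("degenerate profile: adjacency has no interactions")
  list(mirna = gaussian_kernel(adj), lncrna = gaussian_kernel(t(adj)))
}

#' Alignment parameters for sequence similarity
#'
#' Scoring used by the global Needleman-Wunsch alignment: match 2, mismatch
#' 0, affine gaps where a gap of length L costs `gap_open + L * gap_extend`
#' (both penalties are non-positive reals, defaults -0.5 and -0.1).
#'
#' @param match_score score for an identical base pair (default 2).
#' @param mismatch_score score for a mismatched pair (default 0).
#' @param gap_open gap opening penalty, <= 0 (default -0.5).
#' @param gap_extend per-base gap extension penalty, <= 0 (default -0.1).
#' @return A list of class `gklink_alnparams`.
#' @export
alignment_params <- function(match_score = 2, mismatch_score = 0,
                             gap_open = -0.5, gap_extend = -0.1) {
  stopifnot(gap_open <= 0, gap_extend <= 0, match_score > mismatch_score)
  structure(list(match_score = match_score, mismatch_score = mismatch_score,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "gklink_alnparams")
}

#' Sequence similarity from global alignment scores
#'
#' All-vs-all Needleman-Wunsch global alignment with affine gaps; the raw
#' score `S(a, b)` is normalized by the geometric mean of the self-scores,
#' `max(0, S(a, b) / sqrt(S(a, a) * S(b, b)))`, which maps it into [0, 1]
#' with 1 for identical sequences. The diagonal is forced to 1.
#'
#' @param seqs named character vector of RNA sequences (see [read_fasta()]).
#' @param ids identifiers to include, in output order.
#' @param params scoring parameters from [alignment_params()].
#' @return Symmetric similarity matrix over `ids`.
#' @export
sequence_similarity <- function(seqs, ids = names(seqs),
                                params = alignment_params()) {
  missing <- setdiff(ids, names(seqs))
  if (length(missing)) gk_data_error("no sequence for identifier ", missing[1L])
  n <- length(ids)
  s <- unclass(seqs)[ids]
  sm <- matrix(params$mismatch_score, 4, 4,
               dimnames = list(c("A", "C", "G", "U"), c("A", "C", "G", "U")))
  diag(sm) <- params$match_score
  self <- vapply(s, function(x) {
    Biostrings::pairwiseAlignment(x, x, type = "global",
                                  substitutionMatrix = sm,
                                  gapOpening = -params$gap_open,
                                  gapExtension = -params$gap_extend,
                                  scoreOnly = TRUE)
  }, 0)
  if (any(self <= 0)) {
    gk_data_error("non-positive self-alignment score for ",
                  ids[self <= 0][1L])
  }
  out <- diag(1, n)
  for (i in seq_len(max(n - 1L, 0L))) {
    js <- seq.int(i + 1L, n)
    sc <- Biostrings::pairwiseAlignment(
      rep(s[i], length(js)), unname(s[js]), type = "global",
      substitutionMatrix = sm, gapOpening = -params$gap_open,
      gapExtension = -params$gap_extend, scoreOnly = TRUE)
    v <- pmax(0, sc / sqrt(self[i] * self[js]))
    out[i, js] <- v
    out[js, i] <- v
  }
  dimnames(out) <- list(ids, ids)
  check_similarity(pmin(out, 1))
}

#' Functional similarity from annotation sets
#'
#' Ochiai (cosine) set similarity between annotation sets:
#' `|A intersect B| / sqrt(|A| * |B|)`. RNAs with an empty annotation set get
#' 0 off-diagonal similarity; the diagonal is always 1.
#'
#' @param ann annotation table from [read_annotations()] (named list of term
#'   sets). Identifiers absent from `ann` are treated as unannotated.
#' @param ids identifiers to include, in output order.
#' @return Symmetric similarity matrix over `ids`.
#' @export
functional_similarity <- function(ann, ids = names(ann)) {
  sets <- lapply(ids, function(id) {
    if (id %in% names(ann)) unique(ann[[id]]) else character()
  })
  sizes <- lengths(sets)
  n <- length(ids)
  out <- diag(1, n)
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in seq.int(i + 1L, n)) {
      v <- if (sizes[i] == 0L || sizes[j] == 0L) 0 else
        length(intersect(sets[[i]], sets[[j]])) / sqrt(sizes[i] * sizes[j])
      out[i, j] <- out[j, i] <- v
    }
  }
  dimnames(out) <- list(ids, ids)
  check_similarity(out)
}

#' Expression similarity from Pearson correlation
#'
#' Pearson correlation between expression vectors, clipped at 0 so the
#' result lives in [0, 1] like the other similarities. Constant
#' (zero-variance) vectors correlate with nothing and get off-diagonal 0.
#'
#' @param expr expression matrix from [read_expression()] (RNAs in rows).
#' @param ids identifiers to include, in output order; all must be present.
#' @return Symmetric similarity matrix over `ids`.
#' @export
expression_similarity <- function(expr, ids = rownames(expr)) {
  missing <- setdiff(ids, rownames(expr))
  if (length(missing)) gk_data_error("no expression profile for ", missing[1L])
  x <- unclass(expr)[ids, , drop = FALSE]
  if (ncol(x) < 2L) gk_data_error("expression similarity needs >= 2 conditions")
  sds <- apply(x, 1L, stats::sd)
  cc <- suppressWarnings(stats::cor(t(x)))
  cc[sds == 0, ] <- 0
  cc[, sds == 0] <- 0
  cc <- pmin(pmax(cc, 0), 1)
  diag(cc) <- 1
  dimnames(cc) <- list(ids, ids)
  check_similarity((cc + t(cc)) / 2)
}

#' Expand a similarity matrix to RNAs without profiles
#'
#' Bio-profile collections are incomplete in practice: some RNAs in the
#' network have no sequence, expression or annotation record. Such RNAs get
#' an identity-like row (self-similarity 1, everything else 0), leaving the
#' model to rely on the interaction structure alone for them.
#'
#' @param sim similarity matrix over the `present` identifiers.
#' @param present identifiers covered by `sim` (defaults to its rownames).
#' @param all_ids full identifier list, superset of `present`, in output
#'   order.
#' @return Similarity matrix over `all_ids`.
#' @export
fill_missing <- function(sim, present = rownames(sim), all_ids) {
  if (!all(present %in% all_ids)) {
    gk_data_error("profile identifiers not in the dataset: ",
                  setdiff(present, all_ids)[1L])
  }
  out <- diag(1, length(all_ids))
  dimnames(out) <- list(all_ids, all_ids)
  idx <- match(present, all_ids)
  out[idx, idx] <- sim
  check_similarity(out)
}
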