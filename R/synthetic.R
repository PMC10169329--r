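# Seeded synthetic universe: a planted bipartite block model plus
# block-consistent side data. The model's inductive bias — RNAs with similar
# interaction profiles share partners — is exactly block structure, so a
# planted network is the natural testbed when the curated real network is
# not redistributable.

#' Specification of a planted bipartite block model
#'
#' RNAs of both classes are assigned to `n_blocks` communities round-robin
#' (deterministic block sizes); a (miRNA, lncRNA) pair interacts with
#' probability `p_in` when the two share a block and `p_out` otherwise. The
#' defaults (60 x 100, 5 blocks, 0.3 / 0.02) give a sparse network of about
#' 8% density at a size where a full CV harness runs in seconds.
#'
#' @param m,l number of miRNAs / lncRNAs.
#' @param n_blocks number of planted communities, `<= min(m, l)`.
#' @param p_in,p_out within/between-block interaction probabilities,
#'   `0 <= p_out < p_in <= 1`.
#' @param seed integer seed driving all generation.
#' @return A list of class `gklink_planted_spec`.
#' @export
planted_spec <- function(m = 60L, l = 100L, n_blocks = 5L, p_in = 0.3,
                         p_out = 0.02, seed = 1L) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1, n_blocks >= 1L,
            n_blocks <= min(m, l))
  structure(list(m = as.integer(m), l = as.integer(l),
                 n_blocks = as.integer(n_blocks), p_in = p_in, p_out = p_out,
                 seed = as.integer(seed)),
            class = "gklink_planted_spec")
}

block_assign <- function(n, n_blocks) ((seq_len(n) - 1L) %% n_blocks) + 1L

#' Generate a planted-block bipartite interaction network
#'
#' @param spec a [planted_spec()].
#' @return List with `dataset` (a `gklink_dataset` whose identifiers are
#'   `mir-001`, ..., `lnc-001`, ...) and `blocks` (list of integer block
#'   assignments `mirna`, `lncrna`, named by identifier). If a draw produces
#'   zero edges it is resampled once, then an error is raised.
#' @export
planted_block_network <- function(spec = planted_spec()) {
  stopifnot(inherits(spec, "gklink_planted_spec"))
  mirna_ids <- sprintf("mir-%03d", seq_len(spec$m))
  lncrna_ids <- sprintf("lnc-%03d", seq_len(spec$l))
  bm <- stats::setNames(block_assign(spec$m, spec$n_blocks), mirna_ids)
  bl <- stats::setNames(block_assign(spec$l, spec$n_blocks), lncrna_ids)
  p <- matrix(spec$p_out, spec$m, spec$l)
  p[outer(bm, bl, "==")] <- spec$p_in
  set.seed(spec$seed)
  adj <- matrix(as.numeric(stats::runif(spec$m * spec$l) < p), spec$m, spec$l)
  if (sum(adj) == 0) {
    adj <- matrix(as.numeric(stats::runif(spec$m * spec$l) < p), spec$m, spec$l)
    if (sum(adj) == 0) gk_data_error("planted network has zero edges after resampling")
  }
  dimnames(adj) <- list(mirna_ids, lncrna_ids)
  list(dataset = new_dataset(mirna_ids, lncrna_ids, adj),
       blocks = list(mirna = bm, lncrna = bl))
}

#' Synthesize block-consistent RNA sequences
#'
#' One random ancestor sequence per block; each RNA copies its block's
#' ancestor with independent per-site substitutions at `mutation_rate`. A
#' substitution always changes the base (uniform over the three
#' alternatives), so `mutation_rate = 1` leaves an expected per-site
#' identity of 1/3 between two within-block sequences.
#'
#' @param blocks named integer vector mapping identifier to block (combine
#'   the `mirna` and `lncrna` assignments to cover both classes).
#' @param length sequence length, >= 1 (default 60).
#' @param mutation_rate per-site substitution probability in \[0, 1\].
#' @param seed integer seed.
#' @return A `gklink_sequences` named character vector over `{A,C,G,U}`.
#' @export
synth_sequences <- function(blocks, length = 60L, mutation_rate = 0.05,
                            seed = 1L) {
  if (length < 1L) gk_data_error("sequence length must be >= 1")
  stopifnot(mutation_rate >= 0, mutation_rate <= 1)
  alphabet <- c("A", "C", "G", "U")
  set.seed(seed)
  n_blocks <- max(blocks)
  anc <- replicate(n_blocks,
                   sample(alphabet, length, replace = TRUE),
                   simplify = FALSE)
  seqs <- vapply(blocks, function(b) {
    s <- anc[[b]]
    hit <- stats::runif(length) < mutation_rate
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(base) {
        sample(setdiff(alphabet, base), 1L)
      }, "")
    }
    paste(s, collapse = "")
  }, "")
  structure(seqs, class = "gklink_sequences")
}

#' Synthesize block-consistent expression profiles
#'
#' One latent standard-normal condition profile per block; each RNA's vector
#' is its block profile plus i.i.d. Gaussian noise of standard deviation
#' `noise_sd`. With `noise_sd = 0` within-block Pearson similarity is
#' exactly 1; with large noise the correlations collapse toward 0.
#'
#' @inheritParams synth_sequences
#' @param n_conditions number of conditions, >= 2 (default 8).
#' @param noise_sd nonnegative noise standard deviation (default 0.3).
#' @return A `gklink_expression` matrix (RNAs x conditions).
#' @export
synth_expression <- function(blocks, n_conditions = 8L, noise_sd = 0.3,
                             seed = 1L) {
  if (n_conditions < 2L) gk_data_error("need at least 2 conditions")
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  n_blocks <- max(blocks)
  latent <- matrix(stats::rnorm(n_blocks * n_conditions), n_blocks)
  vals <- latent[blocks, , drop = FALSE] +
    matrix(stats::rnorm(length(blocks) * n_conditions, sd = noise_sd),
           length(blocks))
  dimnames(vals) <- list(names(blocks), sprintf("cond_%02d", seq_len(n_conditions)))
  structure(vals, class = c("gklink_expression", "matrix"))
}

#' Synthesize block-consistent functional annotations
#'
#' Each block owns a disjoint pool of `terms_per_block` terms; each RNA
#' keeps every term of its block's pool independently with probability
#' `shared_fraction` and additionally picks up each foreign term with
#' probability `p_foreign`. RNAs may end up unannotated (empty set), as in
#' real annotation collections.
#'
#' @inheritParams synth_sequences
#' @param terms_per_block pool size per block, >= 1 (default 6).
#' @param shared_fraction probability of inheriting each in-block term
#'   (default 0.8).
#' @param p_foreign probability of acquiring each out-of-block term
#'   (default 0.02).
#' @return A `gklink_annotations` named list of term sets.
#' @export
synth_annotations <- function(blocks, terms_per_block = 6L,
                              shared_fraction = 0.8, p_foreign = 0.02,
                              seed = 1L) {
  if (terms_per_block < 1L) gk_data_error("terms_per_block must be >= 1")
  stopifnot(shared_fraction >= 0, shared_fraction <= 1,
            p_foreign >= 0, p_foreign <= 1)
  set.seed(seed)
  n_blocks <- max(blocks)
  pools <- lapply(seq_len(n_blocks), function(b) {
    sprintf("term_b%d_%02d", b, seq_len(terms_per_block))
  })
  all_terms <- unlist(pools)
  sets <- lapply(blocks, function(b) {
    own <- pools[[b]][stats::runif(terms_per_block) < shared_fraction]
    foreign <- setdiff(all_terms, pools[[b]])
    extra <- foreign[stats::runif(length(foreign)) < p_foreign]
    c(own, extra)
  })
  names(sets) <- names(blocks)
  structure(sets, class = "gklink_annotations")
}

#' Write a complete synthetic study to disk
#'
#' Generates a planted-block network and its block-consistent side data and
#' writes the four input files the pipeline reads: `interactions.tsv`,
#' `sequences.fasta`, `expression.csv`, `annotations.tsv`.
#'
#' @param spec a [planted_spec()].
#' @param dir output directory (created if needed).
#' @param seq_length,mutation_rate,n_conditions,noise_sd,terms_per_block,shared_fraction
#'   forwarded to the side-data generators; their seeds are derived from
#'   `spec$seed`.
#' @return Invisibly, a named list of the written file paths.
#' @export
write_synthetic_study <- function(spec = planted_spec(), dir,
                                  seq_length = 60L, mutation_rate = 0.05,
                                  n_conditions = 8L, noise_sd = 0.3,
                                  terms_per_block = 6L,
                                  shared_fraction = 0.8) {
  net <- planted_block_network(spec)
  blocks <- c(net$blocks$mirna, net$blocks$lncrna)
  seqs <- synth_sequences(blocks, length = seq_length,
                          mutation_rate = mutation_rate, seed = spec$seed + 1L)
  expr <- synth_expression(blocks, n_conditions = n_conditions,
                           noise_sd = noise_sd, seed = spec$seed + 2L)
  ann <- synth_annotations(blocks, terms_per_block = terms_per_block,
                           shared_fraction = shared_fraction,
                           seed = spec$seed + 3L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(interactions = file.path(dir, "interactions.tsv"),
                sequences = file.path(dir, "sequences.fasta"),
                expression = file.path(dir, "expression.csv"),
                annotations = file.path(dir, "annotations.tsv"))
  pos <- which(net$dataset$adj == 1, arr.ind = TRUE)
  ord <- order(pos[, 1L], pos[, 2L])
  writeLines(paste(net$dataset$mirna_ids[pos[ord, 1L]],
                   net$dataset$lncrna_ids[pos[ord, 2L]], sep = "\t"),
             paths$interactions)
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unclass(seqs))),
             paths$sequences)
  writeLines(c(paste(c("id", colnames(expr)), collapse = ","),
               paste(rownames(expr),
                     apply(unclass(expr), 1L, function(v)
                       paste(sprintf("%.6g", v), collapse = ",")),
                     sep = ",")),
             paths$expression)
  ann_lines <- unlist(lapply(names(ann), function(id) {
    if (length(ann[[id]])) paste(id, ann[[id]], sep = "\t") else character()
  }))
  writeLines(ann_lines, paths$annotations)
  invisible(paths)
}

#' Degree-destroying shuffle of an interaction network
#'
#' Replaces the observed edges with the same number of edges placed
#' uniformly at random over the m x l grid, erasing the community structure
#' while keeping size and density. Used as the null control against which
#' planted-signal recovery is measured.
#'
#' @param dataset a `gklink_dataset`. @param seed integer seed.
#' @return A new `gklink_dataset` with the same identifiers.
#' @export
shuffle_network <- function(dataset, seed = 1L) {
  m <- length(dataset$mirna_ids); l <- length(dataset$lncrna_ids)
  n_edges <- sum(dataset$adj)
  set.seed(seed)
  adj <- matrix(0, m, l, dimnames = dimnames(dataset$adj))
  adj[sample.int(m * l, n_edges)] <- 1
  new_dataset(dataset$mirna_ids, dataset$lncrna_ids, adj)
}
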