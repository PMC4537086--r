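# Synthetic data generator: alignments with planted recombinant tracts of
# elevated divergence for the masking utility, and the small worked trees
# used throughout the tree-metric examples. The alignment model mutates
# columns independently (no linkage): sufficient to exercise masking and
# culling logic, not a sequence-evolution simulator.

#' Specification of a synthetic alignment fixture
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param length Alignment length in columns.
#' @param background Per-cell probability that a non-reference taxon
#'   carries a substitution relative to the reference row.
#' @param tracts Data frame with columns `taxon`, `begin`, `end`, `rate`:
#'   planted recombinant tracts in which the named taxon mutates at the
#'   elevated `rate` instead of `background`. May be `NULL`.
#' @param missing_prob Per-cell probability of an `N` (missing/ambiguous)
#'   character, applied anywhere in the alignment.
#' @param seed Integer seed; generation is fully deterministic.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_taxa = 6L, length = 400L, background = 0.01,
                         tracts = NULL, missing_prob = 0, seed = 1L) {
  n_taxa <- as.integer(n_taxa)
  length <- as.integer(length)
  if (n_taxa < 2L || length < 1L)
    stop("fixture needs at least 2 taxa and 1 column")
  probs <- c(background, missing_prob,
             if (!is.null(tracts)) tracts$rate)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (!is.null(tracts)) {
    stopifnot(all(c("taxon", "begin", "end", "rate") %in% names(tracts)))
    if (any(tracts$begin < 1L | tracts$end > length |
            tracts$begin > tracts$end))
      stop("planted tracts must lie within the alignment bounds")
  }
  structure(list(n_taxa = n_taxa, length = length,
                 background = background, tracts = tracts,
                 missing_prob = missing_prob, seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic alignment with planted recombinant tracts
#'
#' Draws a random reference sequence, copies it to every taxon, flips
#' cells to a different base at the background rate, applies the elevated
#' rate inside each planted tract for its taxon, then sprinkles `N`
#' characters at the missing-data probability. The ground-truth tract
#' intervals are returned alongside, in the same form
#' [mask_and_cull()] consumes.
#'
#' @param spec A [fixture_spec()].
#' @return List with `alignment` (character matrix, taxa `t1..tk`) and
#'   `intervals` (data frame `taxon`, `begin`, `end`).
#' @export
#' @examples
#' fx <- generate_alignment(fixture_spec(n_taxa = 4, length = 50,
#'   background = 0, tracts = data.frame(taxon = "t1", begin = 11,
#'   end = 20, rate = 0.5), seed = 7))
#' mask_and_cull(fx$alignment, fx$intervals)$report$n_kept  # 0
generate_alignment <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    L <- spec$length
    ref <- sample(.valid_bases, L, replace = TRUE)
    mat <- matrix(rep(ref, each = spec$n_taxa), spec$n_taxa, L)
    rownames(mat) <- paste0("t", seq_len(spec$n_taxa))
    mutate_cells <- function(mat, taxon, cols, rate) {
      hit <- cols[stats::runif(length(cols)) < rate]
      for (j in hit) {
        mat[taxon, j] <- sample(setdiff(.valid_bases, mat[taxon, j]), 1L)
      }
      mat
    }
    for (tx in rownames(mat)) {
      mat <- mutate_cells(mat, tx, seq_len(L), spec$background)
    }
    if (!is.null(spec$tracts)) {
      for (r in seq_len(nrow(spec$tracts))) {
        tr <- spec$tracts[r, ]
        mat <- mutate_cells(mat, as.character(tr$taxon),
                            tr$begin:tr$end, tr$rate)
      }
    }
    if (spec$missing_prob > 0) {
      miss <- stats::runif(length(mat)) < spec$missing_prob
      mat[matrix(miss, nrow(mat), L)] <- "N"
    }
    intervals <- if (is.null(spec$tracts)) {
      data.frame(taxon = character(0), begin = integer(0), end = integer(0))
    } else {
      data.frame(taxon = as.character(spec$tracts$taxon),
                 begin = as.integer(spec$tracts$begin),
                 end = as.integer(spec$tracts$end))
    }
    list(alignment = mat, intervals = intervals)
  })
}

#' Write a generated fixture to FASTA plus a truth-interval TSV
#'
#' @param fixture Result of [generate_alignment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two paths written (`alignment.fasta`,
#'   `intervals.tsv`).
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, "alignment.fasta")
  tsv <- file.path(dir, "intervals.tsv")
  seqs <- Biostrings::BStringSet(apply(fixture$alignment, 1L, paste,
                                       collapse = ""))
  names(seqs) <- rownames(fixture$alignment)
  Biostrings::writeXStringSet(seqs, fa)
  iv <- fixture$intervals
  utils::write.table(
    data.frame(Node = iv$taxon, Beg = iv$begin, End = iv$end),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, tsv))
}

#' Small worked genealogies with exact node ages
#'
#' Named fixture trees used in examples and tests: `cherry3` =
#' `((A:1,B:1):1,C:2)`, `ladder4` = `(((A:1,B:1):1,C:2):1,D:3)`, and
#' `para3` = `((X1:1,Y1:1):1,X2:2)` (a paraphyletic ingroup).
#'
#' @return Named list of `genealogy` objects.
#' @export
#' @examples
#' basal_node_age(worked_trees()$ladder4)  # 2
worked_trees <- function() {
  list(cherry3 = parse_newick("((A:1,B:1):1,C:2);"),
       ladder4 = parse_newick("(((A:1,B:1):1,C:2):1,D:3);"),
       para3 = parse_newick("((X1:1,Y1:1):1,X2:2);"))
}
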