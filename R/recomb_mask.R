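# Recombination masking and SNP-matrix extraction: remove alignment
# positions attributed to recombination (ClonalFrameML-style importation
# intervals), drop incomplete sites, and cull to variant positions.

.valid_bases <- c("A", "C", "G", "T")

#' Load a multi-FASTA whole-genome alignment
#'
#' @param path Path to a FASTA file of equal-length records.
#' @return A character matrix (taxa x positions, uppercase), rownames are
#'   the record names.
#' @export
load_alignment <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) < 1L) stop("empty alignment: no FASTA records in ", path)
  w <- Biostrings::width(seqs)
  if (length(unique(w)) != 1L) {
    bad <- names(seqs)[which(w != w[1L])[1L]]
    stop("ragged alignment: record '", bad, "' has length ",
         w[names(seqs) == bad][1L], " but '", names(seqs)[1L],
         "' has length ", w[1L])
  }
  labels <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(labels))
    stop("duplicate taxon labels in alignment: ",
         labels[duplicated(labels)][1L])
  mat <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(mat) <- labels
  mat
}

#' Load recombinant intervals in the ClonalFrameML importation dialect
#'
#' Reads a TSV with header `Node`, `Beg`, `End` (case-insensitive):
#' 1-based inclusive alignment coordinates of tracts attributed to
#' recombination on the named taxon or internal node.
#'
#' @param path Path to the TSV file.
#' @param alignment_length Optional alignment length for bounds checking.
#' @return Data frame with columns `taxon`, `begin`, `end`; zero rows for
#'   an empty interval file.
#' @export
load_intervals <- function(path, alignment_length = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L)
    return(data.frame(taxon = character(0), begin = integer(0),
                      end = integer(0)))
  nm <- tolower(names(df))
  need <- c("node", "beg", "end")
  if (!all(need %in% nm))
    stop("interval file must have columns Node, Beg, End; found: ",
         paste(names(df), collapse = ", "))
  out <- data.frame(taxon = as.character(df[[which(nm == "node")]]),
                    begin = as.integer(df[[which(nm == "beg")]]),
                    end = as.integer(df[[which(nm == "end")]]))
  for (r in seq_len(nrow(out))) {
    if (is.na(out$begin[r]) || is.na(out$end[r]) || out$begin[r] < 1L ||
        out$begin[r] > out$end[r])
      stop("invalid interval at row ", r, ": Beg=", df[r, which(nm == "beg")],
           " End=", df[r, which(nm == "end")])
    if (!is.null(alignment_length) && out$end[r] > alignment_length)
      stop("interval at row ", r, " ends at ", out$end[r],
           " beyond alignment length ", alignment_length)
  }
  out
}

#' Mask recombinant positions and cull to a SNP matrix
#'
#' Reproduces the post-recombination-detection cleanup applied before
#' molecular dating: (1) every alignment column intersecting a
#' recombinant interval is removed entirely (whole-column masking; a
#' per-taxon variant that only blanks the named taxon's characters is
#' available via `per_taxon = TRUE`); (2) with `drop_incomplete`, every
#' column containing a character outside A/C/G/T in any row (ambiguity
#' codes, N, gaps) is removed; (3) of the remainder, only columns with at
#' least 2 distinct valid states are kept, in original order.
#'
#' Intervals naming a taxon absent from the alignment (e.g. internal-node
#' labels emitted by recombination detectors) trigger a warning by
#' default and are applied as whole-column masks.
#'
#' @param aln Character matrix from [load_alignment()] or
#'   [generate_alignment()].
#' @param intervals Data frame from [load_intervals()] (columns `taxon`,
#'   `begin`, `end`, 1-based inclusive); may have zero rows.
#' @param drop_incomplete Drop columns with ambiguous/missing characters
#'   (default TRUE).
#' @param per_taxon Mask only the named taxon's characters (as missing)
#'   instead of the whole column.
#' @param unknown_taxon `"warn"` (default) or `"error"` for intervals
#'   whose taxon is not an alignment row.
#' @return Object of class `mask_result`: `matrix` (the SNP alignment),
#'   `coordinates` (1-based original positions of retained columns), and
#'   `report` — counts at each stage that reconcile exactly with the
#'   input length (`kept + masked_only + incomplete_only + invariant_only
#'   + multiply_flagged = n_input`), plus the fraction of positions
#'   attributed to recombination.
#' @export
#' @examples
#' aln <- rbind(taxonA = c("A","C","A","G","A","A","T","A","A","A"),
#'              taxonB = c("A","T","A","G","A","A","T","A","A","A"),
#'              taxonC = c("A","C","A","C","A","A","G","A","A","A"),
#'              taxonD = c("A","C","A","C","A","A","G","A","A","A"))
#' iv <- data.frame(taxon = "taxonA", begin = 3, end = 5)
#' mask_and_cull(aln, iv)$coordinates  # 2 and 7
mask_and_cull <- function(aln, intervals,
                          drop_incomplete = TRUE, per_taxon = FALSE,
                          unknown_taxon = c("warn", "error")) {
  unknown_taxon <- match.arg(unknown_taxon)
  if (is.null(dim(aln)) || nrow(aln) < 1L || ncol(aln) < 1L)
    stop("empty alignment")
  if (is.null(intervals) || nrow(intervals) == 0L)
    intervals <- data.frame(taxon = character(0), begin = integer(0),
                            end = integer(0))
  L <- ncol(aln)
  aln <- toupper(aln)
  masked <- logical(L)
  for (r in seq_len(nrow(intervals))) {
    b <- intervals$begin[r]
    e <- intervals$end[r]
    if (b < 1L || e > L || b > e)
      stop("interval at row ", r, " (", b, "-", e,
           ") outside alignment of length ", L)
    known <- intervals$taxon[r] %in% rownames(aln)
    if (!known) {
      msg <- paste0("interval taxon '", intervals$taxon[r],
                    "' is not an alignment row; masking whole columns ",
                    b, "-", e)
      if (unknown_taxon == "error") stop(msg) else warning(msg)
    }
    if (per_taxon && known) {
      aln[intervals$taxon[r], b:e] <- "N"
    } else {
      masked[b:e] <- TRUE
    }
  }
  incomplete <- apply(aln, 2L, function(col) any(!col %in% .valid_bases))
  variant <- apply(aln, 2L, function(col) {
    length(unique(col[col %in% .valid_bases])) >= 2L
  })
  f_mask <- masked
  f_inc <- if (drop_incomplete) incomplete else rep(FALSE, L)
  f_inv <- !variant
  nflags <- f_mask + f_inc + f_inv
  kept <- nflags == 0L
  report <- list(
    n_input = L,
    n_kept = sum(kept),
    n_masked = sum(f_mask),
    n_incomplete = sum(incomplete),
    n_invariant = sum(f_inv),
    masked_only = sum(f_mask & nflags == 1L),
    incomplete_only = sum(f_inc & nflags == 1L),
    invariant_only = sum(f_inv & nflags == 1L),
    multiply_flagged = sum(nflags >= 2L),
    recomb_fraction = mean(f_mask))
  structure(
    list(matrix = aln[, kept, drop = FALSE],
         coordinates = which(kept),
         report = report),
    class = "mask_result")
}

#' @export
print.mask_result <- function(x, ...) {
  r <- x$report
  cat("SNP matrix: ", nrow(x$matrix), " taxa x ", r$n_kept,
      " variant positions (from ", r$n_input, ")\n", sep = "")
  cat(sprintf("  masked (recombination): %d (%.1f%%); incomplete: %d; invariant: %d\n",
              r$n_masked, 100 * r$recomb_fraction, r$n_incomplete,
              r$n_invariant))
  invisible(x)
}

#' Write a SNP matrix with its retained-coordinate map
#'
#' Writes the culled alignment as FASTA, NEXUS or TSV plus a sidecar
#' `<out>.coords.tsv` mapping SNP index to the 1-based original alignment
#' position. A zero-column matrix produces a stub file with a warning.
#'
#' @param x A `mask_result` from [mask_and_cull()], or a character matrix
#'   (then `coordinates` defaults to 1..ncol).
#' @param path Output file path.
#' @param format `"fasta"`, `"nexus"` or `"tsv"`.
#' @return Invisibly, the main output path.
#' @export
write_snp_matrix <- function(x, path, format = c("fasta", "nexus", "tsv")) {
  format <- tryCatch(match.arg(format), error = function(e)
    stop("unknown format '", format[1L],
         "'; valid formats: fasta, nexus, tsv"))
  if (inherits(x, "mask_result")) {
    mat <- x$matrix
    coords <- x$coordinates
  } else {
    mat <- x
    coords <- seq_len(ncol(mat))
  }
  if (ncol(mat) == 0L)
    warning("SNP matrix has zero columns; writing an empty-alignment stub")
  switch(format,
    fasta = {
      seqs <- Biostrings::BStringSet(apply(mat, 1L, paste, collapse = ""))
      names(seqs) <- rownames(mat)
      Biostrings::writeXStringSet(seqs, path)
    },
    nexus = {
      if (ncol(mat) == 0L) {
        writeLines(c("#NEXUS", "BEGIN DATA;",
                     paste0("  DIMENSIONS NTAX=", nrow(mat), " NCHAR=0;"),
                     "  MATRIX", "  ;", "END;"), path)
      } else {
        ape::write.nexus.data(
          stats::setNames(lapply(seq_len(nrow(mat)),
                                 function(i) mat[i, ]), rownames(mat)),
          file = path, interleaved = FALSE)
      }
    },
    tsv = {
      df <- as.data.frame(mat, stringsAsFactors = FALSE)
      colnames(df) <- paste0("pos", coords)
      utils::write.table(cbind(taxon = rownames(mat), df), path,
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  utils::write.table(
    data.frame(snp_index = seq_along(coords), original_position = coords),
    paste0(path, ".coords.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}
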