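#' Parse an ms command string into a simulation configuration
#'
#' Accepts the supported ms flag subset `{-t, -I, -ej, -T, -seeds}` after
#' `ms nsam nreps` (the leading "ms" is optional). Tokenization is
#' whitespace-tolerant and repairs flag boundaries, so command strings
#' whose spacing was mangled by typesetting (e.g. `"ms 11 1-t 2.0-I 2 1
#' 10-ej 10 1 2 -T"`) parse correctly; en- and em-dash variants of "-" are
#' normalized. Any other ms flag (recombination, growth, migration, ...)
#' raises an unsupported-feature error naming the flag.
#'
#' @param text A single ms command string.
#' @return A [sim_config()] object. A `-seeds a b c` triple is folded
#'   deterministically into the single master seed.
#' @export
#' @examples
#' parse_ms_command("ms 11 1 -t 2.0 -I 2 1 10 -ej 10 1 2 -T")
parse_ms_command <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[–—]", "-", text)          # en/em dash -> hyphen
  s <- gsub("([0-9.])-([A-Za-z])", "\\1 -\\2", s) # "1-t" -> "1 -t"
  toks <- strsplit(trimws(s), "[[:space:]]+")[[1L]]
  if (length(toks) && tolower(toks[1L]) == "ms") toks <- toks[-1L]
  if (length(toks) < 2L)
    stop("ms parse error: expected 'ms nsam nreps [flags]'")
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) stop("ms parse error: non-numeric value for ", what,
                       ": '", paste(x[is.na(v)], collapse = " "), "'")
    v
  }
  nsam <- as.integer(num(toks[1L], "nsam"))
  nreps <- as.integer(num(toks[2L], "nreps"))
  i <- 3L
  theta <- 0
  pops <- NULL
  t_join <- NULL
  source_pop <- 1L
  dest_pop <- 2L
  emit_trees <- FALSE
  seed <- 1L
  take <- function(k, what) {
    if (i + k - 1L > length(toks))
      stop("ms parse error: flag ", what, " expects ", k, " value(s)")
    out <- toks[i:(i + k - 1L)]
    i <<- i + k
    out
  }
  while (i <= length(toks)) {
    tok <- toks[i]
    i <- i + 1L
    if (!startsWith(tok, "-"))
      stop("ms parse error: unexpected token '", tok, "'")
    switch(tok,
      "-t" = { theta <- num(take(1L, "-t"), "-t") },
      "-T" = { emit_trees <- TRUE },
      "-I" = {
        npop <- as.integer(num(take(1L, "-I"), "-I npop"))
        if (npop > 2L)
          stop("unsupported ms feature: -I with ", npop,
               " populations (at most 2 are supported)")
        pops <- as.integer(num(take(npop, "-I"), "-I sizes"))
      },
      "-ej" = {
        v <- num(take(3L, "-ej"), "-ej")
        t_join <- v[1L]
        source_pop <- as.integer(v[2L])
        dest_pop <- as.integer(v[3L])
      },
      "-seeds" = { seed <- fold_ms_seeds(num(take(3L, "-seeds"), "-seeds")) },
      stop("unsupported ms flag: ", tok)
    )
  }
  if (is.null(pops)) pops <- nsam
  if (sum(pops) != nsam)
    stop("ms parse error: -I population sizes sum to ", sum(pops),
         " but nsam is ", nsam)
  if (is.null(t_join)) {
    if (length(pops) == 2L)
      stop("ms parse error: two populations given but no -ej join event")
    t_join <- 0
  }
  sim_config(pop_sizes = pops, theta = theta, t_join = t_join,
             source_pop = source_pop, dest_pop = dest_pop,
             n_reps = nreps, seed = seed, emit_trees = emit_trees)
}

#' Render a configuration as a canonical ms command string
#'
#' Inverse of [parse_ms_command()] for the supported flag subset;
#' `parse -> render -> parse` is a fixed point.
#'
#' @param config A [sim_config()] object.
#' @return A single ms command string.
#' @export
render_ms_command <- function(config) {
  config <- as_sim_config(config)
  parts <- c("ms", sum(config$pop_sizes), config$n_reps)
  if (config$theta > 0) parts <- c(parts, "-t", format(config$theta))
  if (length(config$pop_sizes) == 2L)
    parts <- c(parts, "-I", 2, config$pop_sizes,
               "-ej", format(config$t_join), config$source_pop,
               config$dest_pop)
  if (config$emit_trees) parts <- c(parts, "-T")
  paste(parts, collapse = " ")
}

#' Write simulation output in the ms dialect
#'
#' Emits the familiar ms text stream: the command echo line, a seed line,
#' then per replicate a `//` separator, the Newick tree line (when the
#' configuration has tree emission on), `segsites: S`, a `positions:`
#' line with 4-decimal uniform marks (omitted when S = 0), and one 0/1
#' haplotype row per sample in label order.
#'
#' @param config The [sim_config()] the replicates came from.
#' @param trees List of `genealogy` objects.
#' @param haplotypes List of `haplotype_matrix` objects, same length.
#' @param file A connection, a file path, or `""` for stdout.
#' @return Invisibly, the character vector of lines written.
#' @export
write_ms_output <- function(config, trees, haplotypes, file = "") {
  config <- as_sim_config(config)
  if (length(trees) != length(haplotypes))
    stop("trees and haplotypes must have matching lengths")
  lines <- c(render_ms_command(config), as.character(config$seed), "")
  for (i in seq_along(trees)) {
    lines <- c(lines, "//")
    if (config$emit_trees) lines <- c(lines, write_newick(trees[[i]]))
    hap <- haplotypes[[i]]
    S <- ncol(hap$matrix)
    lines <- c(lines, paste0("segsites: ", S))
    if (S > 0L) {
      lines <- c(lines, paste0("positions: ",
                               paste(sprintf("%.4f", hap$positions),
                                     collapse = " ")),
                 apply(hap$matrix, 1L, paste, collapse = ""))
    }
    lines <- c(lines, "")
  }
  ok <- tryCatch({ writeLines(lines, con = file); TRUE },
                 error = function(e)
                   stop("I/O error writing ms output: ",
                        conditionMessage(e)))
  invisible(lines)
}

#' Read an ms-dialect stream written by this package
#'
#' Parses the command echo, the seed line and the per-replicate blocks
#' back into configuration, genealogies (when tree lines are present) and
#' haplotype matrices. The 0/1 matrix round-trips bit-exactly; position
#' marks are recovered at the 4 decimals printed.
#'
#' @param file A file path or connection, or `text` a character vector of
#'   lines.
#' @param text Optional character vector of lines (overrides `file`).
#' @return List with `config`, `seed`, and `replicates`: each replicate a
#'   list with `tree` (`genealogy` or `NULL`) and `haplotypes`
#'   (`haplotype_matrix`).
#' @export
read_ms_output <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("ms parse error: truncated stream")
  config <- parse_ms_command(lines[1L])
  seed <- as.integer(lines[2L])
  labels <- tip_labels_for(config$pop_sizes)
  breaks <- which(lines == "//")
  if (!length(breaks)) stop("ms parse error: no replicate blocks ('//')")
  bounds <- c(breaks, length(lines) + 1L)
  replicates <- vector("list", length(breaks))
  for (b in seq_along(breaks)) {
    block <- lines[(bounds[b] + 1L):(bounds[b + 1L] - 1L)]
    tree <- NULL
    j <- 1L
    if (length(block) >= j && startsWith(block[j], "(")) {
      tree <- parse_newick(block[j])
      j <- j + 1L
    }
    if (length(block) < j || !startsWith(block[j], "segsites:"))
      stop("ms parse error: missing 'segsites:' line in block ", b)
    S <- as.integer(sub("^segsites:\\s*", "", block[j]))
    j <- j + 1L
    if (S == 0L) {
      hap <- new_haplotype_matrix(labels, numeric(0),
                                  matrix(0L, length(labels), 0L,
                                         dimnames = list(labels, NULL)))
    } else {
      if (!startsWith(block[j], "positions:"))
        stop("ms parse error: missing 'positions:' line in block ", b)
      pos <- as.numeric(strsplit(trimws(sub("^positions:", "", block[j])),
                                 "\\s+")[[1L]])
      j <- j + 1L
      rows <- block[j:(j + length(labels) - 1L)]
      mat <- do.call(rbind, lapply(rows, function(r)
        as.integer(strsplit(r, "")[[1L]])))
      dimnames(mat) <- list(labels, NULL)
      hap <- new_haplotype_matrix(labels, pos, mat)
    }
    replicates[[b]] <- list(tree = tree, haplotypes = hap)
  }
  list(config = config, seed = seed, replicates = replicates)
}
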