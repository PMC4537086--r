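# Recombination masking, incomplete-site dropping and SNP culling.

worked_aln <- function() {
  # 4 taxa x 10 columns; variant columns 2, 4, 7
  rbind(taxonA = c("A","C","A","G","A","A","T","A","A","A"),
        taxonB = c("A","T","A","G","A","A","T","A","A","A"),
        taxonC = c("A","C","A","C","A","A","G","A","A","A"),
        taxonD = c("A","C","A","C","A","A","G","A","A","A"))
}

test_that("the hand-worked fixture keeps SNP columns 2 and 7", {
  iv <- data.frame(taxon = "taxonA", begin = 3L, end = 5L)
  res <- mask_and_cull(worked_aln(), iv)
  expect_equal(res$coordinates, c(2L, 7L))
  expect_equal(ncol(res$matrix), 2L)
  expect_equal(unname(res$matrix[, 1]), c("C", "T", "C", "C"))
  expect_equal(res$report$n_masked, 3L)
  expect_equal(res$report$recomb_fraction, 0.3)
})

test_that("column accounting reconciles exactly on random fixtures", {
  for (seed in 1:5) {
    fx <- generate_alignment(fixture_spec(
      n_taxa = 5, length = 300, background = 0.03,
      tracts = data.frame(taxon = c("t2", "t4"), begin = c(40L, 200L),
                          end = c(90L, 230L), rate = c(0.4, 0.5)),
      missing_prob = 0.01, seed = seed))
    res <- mask_and_cull(fx$alignment, fx$intervals)
    r <- res$report
    expect_equal(r$n_kept + r$masked_only + r$incomplete_only +
                   r$invariant_only + r$multiply_flagged, r$n_input)
    expect_equal(r$n_kept, length(res$coordinates))
    # planted tracts fully absent from the output
    tract_cols <- unlist(mapply(seq, fx$intervals$begin, fx$intervals$end))
    expect_length(intersect(res$coordinates, tract_cols), 0)
  }
})

test_that("masking rules match their statements", {
  aln <- worked_aln()
  # no intervals, identical rows -> 0 SNPs
  mono <- matrix("A", 3, 8, dimnames = list(paste0("s", 1:3), NULL))
  expect_equal(mask_and_cull(mono, NULL)$report$n_kept, 0L)
  # N column removed even if variant when drop_incomplete on, kept when off
  aln2 <- aln
  aln2["taxonC", 2] <- "N"
  expect_false(2L %in% mask_and_cull(aln2, NULL)$coordinates)
  keep <- mask_and_cull(aln2, NULL, drop_incomplete = FALSE)
  expect_true(2L %in% keep$coordinates)
  # gaps and IUPAC ambiguity count as incomplete
  aln3 <- aln
  aln3["taxonC", 7] <- "-"
  aln3["taxonD", 4] <- "R"
  expect_equal(mask_and_cull(aln3, NULL)$coordinates, 2L)
  expect_error(mask_and_cull(aln[, 0, drop = FALSE], NULL), "empty")
  expect_error(mask_and_cull(aln, data.frame(taxon = "taxonA", begin = 5L,
                                             end = 99L)),
               "outside alignment")
})

test_that("unknown interval taxa warn (or error) and mask whole columns", {
  iv <- data.frame(taxon = "NODE_12", begin = 2L, end = 2L)
  expect_warning(res <- mask_and_cull(worked_aln(), iv), "NODE_12")
  expect_false(2L %in% res$coordinates)
  expect_error(
    suppressWarnings(mask_and_cull(worked_aln(), iv,
                                   unknown_taxon = "error")),
    "NODE_12")
})

test_that("per-taxon masking blanks only the named taxon's tract", {
  iv <- data.frame(taxon = "taxonA", begin = 1L, end = 5L)
  res <- suppressWarnings(
    mask_and_cull(worked_aln(), iv, per_taxon = TRUE))
  # column 7 untouched by the tract survives; columns 2 and 4 now carry N
  expect_equal(res$coordinates, 7L)
  expect_equal(res$report$n_masked, 0L)
})

test_that("idempotence: re-culling the SNP output removes nothing", {
  iv <- data.frame(taxon = "taxonA", begin = 3L, end = 5L)
  res <- mask_and_cull(worked_aln(), iv)
  again <- mask_and_cull(res$matrix, NULL)
  expect_equal(again$report$n_kept, res$report$n_kept)
  expect_identical(again$matrix, res$matrix)
})

test_that("alignment and interval loaders validate their inputs", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "ACGT", ">b", "ACG"), fa)
  expect_error(load_alignment(fa), "ragged")
  writeLines(c(">a", "ACGT", ">b", "ACGA"), fa)
  aln <- load_alignment(fa)
  expect_equal(dim(aln), c(2L, 4L))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines("Node\tBeg\tEnd", tsv)
  expect_equal(nrow(load_intervals(tsv)), 0L)
  writeLines(c("Node\tBeg\tEnd", "a\t2\t9"), tsv)
  expect_error(load_intervals(tsv, alignment_length = 4), "row 1")
  writeLines(c("Node\tBeg\tEnd", "a\t3\t2"), tsv)
  expect_error(load_intervals(tsv), "invalid interval")
})

test_that("SNP matrices round-trip through fasta, nexus and tsv writers", {
  iv <- data.frame(taxon = "taxonA", begin = 3L, end = 5L)
  res <- mask_and_cull(worked_aln(), iv)
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_snp_matrix(res, fa, "fasta")
  expect_identical(unname(load_alignment(fa)), unname(res$matrix))
  coords <- utils::read.delim(paste0(fa, ".coords.tsv"))
  expect_equal(coords$original_position, c(2L, 7L))
  nx <- withr::local_tempfile(fileext = ".nex")
  write_snp_matrix(res, nx, "nexus")
  back <- ape::read.nexus.data(nx)
  expect_equal(length(back), 4L)
  expect_equal(toupper(back$taxonA), unname(res$matrix["taxonA", ]))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_snp_matrix(res, tsv, "tsv")
  df <- utils::read.delim(tsv)
  expect_equal(names(df), c("taxon", "pos2", "pos7"))
  expect_error(write_snp_matrix(res, tsv, "phylip"), "unknown format")
  # zero-column stub
  empty <- mask_and_cull(matrix("A", 2, 3,
                                dimnames = list(c("a", "b"), NULL)), NULL)
  expect_warning(write_snp_matrix(empty, fa, "fasta"), "zero columns")
})
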