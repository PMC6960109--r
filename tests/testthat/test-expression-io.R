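test_that("reading a delimited matrix marks sentinel and empty cells as missing", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2",
               "G1\t1.5\tNA",
               "G2\t2.25\t4"), f)
  rd <- read_matrix(f)
  expect_equal(dim(rd$matrix), c(2, 2))           # subjects x genes
  expect_equal(sum(rd$mask == 0), 1)
  expect_equal(rd$mask["S2", "G1"], 0)
  expect_equal(rd$matrix$values["S2", "G1"], 0)   # zero-filled
  expect_equal(rd$matrix$values["S1", "G2"], 2.25)
  expect_equal(rd$matrix$gene_ids, c("G1", "G2"))
  expect_equal(rd$matrix$sample_ids, c("S1", "S2"))

  # no sentinel -> mask all ones
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "G1\t1\t2", "G2\t3\t4"), f2)
  expect_true(all(read_matrix(f2)$mask == 1))
})

test_that("write_matrix round-trips values, ids and mask", {
  em <- expression_matrix(matrix(c(1.5, 2.25, 0.375, 4, 5, 6), 2, 3),
                          sample_ids = c("A", "B"),
                          gene_ids = c("g1", "g2", "g3"))
  mask <- matrix(1, 2, 3); mask[2, 1] <- 0
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(em, f, mask = mask, digits = 17)
  rd <- read_matrix(f)
  expect_equal(unname(rd$mask), mask)
  vals <- em$values; vals[2, 1] <- 0
  expect_equal(rd$matrix$values, vals)
  expect_equal(rd$matrix$sample_ids, em$sample_ids)
  expect_equal(rd$matrix$gene_ids, em$gene_ids)
})

test_that("malformed files are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "G1\t1\t2", "G2\t3"), f)   # ragged row
  expect_error(read_matrix(f), "parse error")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS1", "G1\t1\t2"), f2)           # duplicate samples
  expect_error(read_matrix(f2), "duplicate sample ids")
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1", "G1\tabc"), f3)                # non-numeric cell
  expect_error(read_matrix(f3), "non-numeric")
})

test_that("probe collapsing averages mapped probes per sample", {
  # P1 = [2, 6], P2 = [4, 2] both map to G -> G = [3, 4]
  em <- expression_matrix(matrix(c(2, 6, 4, 2, 9, 9), nrow = 2,
                                 dimnames = list(c("s1", "s2"),
                                                 c("P1", "P2", "P3"))))
  map <- data.frame(probe_id = c("P1", "P2", "P4"),
                    gene_symbol = c("G", "G", "H"))
  expect_message(cp <- collapse_probes(em, map), "dropped")
  expect_equal(unname(cp$matrix$values[, "G"]), c(3, 4))
  expect_equal(cp$matrix$gene_ids, "G")
  expect_equal(cp$matrix$sample_ids, em$sample_ids)       # samples preserved

  # single probe per gene -> identity
  map2 <- data.frame(probe_id = c("P1", "P2", "P3"),
                     gene_symbol = c("A", "B", "C"))
  cp2 <- collapse_probes(em, map2)
  expect_equal(unname(cp2$matrix$values), unname(em$values))

  # 5 probes -> 3 genes gives 3 gene columns
  em5 <- expression_matrix(matrix(1:10, nrow = 2,
                                  dimnames = list(NULL, paste0("P", 1:5))))
  map5 <- data.frame(probe_id = paste0("P", 1:5),
                     gene_symbol = c("g1", "g1", "g2", "g3", "g3"))
  expect_equal(ncol(collapse_probes(em5, map5)$matrix$values), 3)

  expect_error(collapse_probes(em, data.frame(probe_id = "ZZ",
                                              gene_symbol = "G")),
               "no probes")
})

test_that("probe collapsing is missing-aware", {
  em <- expression_matrix(matrix(c(2, 6, 4, 0), nrow = 2,
                                 dimnames = list(NULL, c("P1", "P2"))))
  mask <- matrix(c(1, 1, 1, 0), 2, 2)      # P2 missing at sample 2
  map <- data.frame(probe_id = c("P1", "P2"), gene_symbol = c("G", "G"))
  cp <- collapse_probes(em, map, mask)
  expect_equal(unname(cp$matrix$values[, 1]), c(3, 6))  # mean(2,4); only P1
  expect_equal(unname(cp$mask[, 1]), c(1, 1))
  # all probes missing at a sample -> output entry missing
  mask2 <- matrix(c(1, 0, 1, 0), 2, 2)
  cp2 <- collapse_probes(em, map, mask2)
  expect_equal(unname(cp2$mask[, 1]), c(1, 0))
  expect_equal(unname(cp2$matrix$values[2, 1]), 0)
})

test_that("log transform is log10(x + 1) with a scale-tag guard", {
  em <- expression_matrix(matrix(c(0, 999, 10^6 - 1, 9), 2, 2))
  lt <- log_transform(em)
  expect_equal(unname(lt$values), matrix(c(0, 3, 6, 1), 2, 2))
  expect_equal(lt$scale_tag, "log10p1")
  expect_error(log_transform(lt), "raw-scale")          # applying twice
  # strictly monotone entrywise
  x <- sort(stats::runif(50, 0, 1e5))
  lx <- log10(x + 1)
  expect_true(all(diff(lx) > 0))
  expect_error(expression_matrix(matrix(-1)), "non-negative")
})
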