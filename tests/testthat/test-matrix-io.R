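test_that("CountMatrix validates its invariants", {
  m <- matrix(c(1, 0, 2, 0, 3, 0, 4, 0, 0, 1, 0, 5), nrow = 4)
  cm <- toy_cm(m)
  expect_s3_class(cm, "CountMatrix")
  expect_equal(dim(cm), c(4L, 3L))
  m_neg <- m; m_neg[1, 1] <- -1
  expect_error(toy_cm(m_neg), "non-negative")
  m_frac <- m; m_frac[1, 1] <- 1.5
  expect_error(toy_cm(m_frac), "integral")
  bad_cells <- data.frame(cell_id = paste0("c", 1:4), tissue = c("t", "t", NA, "t"))
  expect_error(CountMatrix(m, bad_cells,
                           data.frame(gene_id = paste0("g", 1:3))),
               "tissue label")
})

test_that("write/read round trip is the identity, spike-ins flagged by prefix", {
  m <- matrix(rpois(12, 4), nrow = 4)
  cm <- CountMatrix(m,
                    cells = data.frame(cell_id = paste0("c", 1:4),
                                       tissue = c("a", "a", "b", "b")),
                    genes = data.frame(gene_id = c("Actb", "ERCC-00042", "Gapdh")))
  d <- withr::local_tempdir()
  write_counts(cm, d)
  back <- read_counts(file.path(d, "counts.mtx"), file.path(d, "cells.tsv"),
                      file.path(d, "genes.tsv"))
  expect_equal(as.matrix(back$counts), as.matrix(cm$counts))
  expect_equal(back$cells$tissue, cm$cells$tissue)
  expect_equal(back$genes$is_spikein, c(FALSE, TRUE, FALSE))
  expect_error(read_counts(file.path(d, "missing.mtx"),
                           file.path(d, "cells.tsv"),
                           file.path(d, "genes.tsv")),
               "not found")
})

test_that("FACS filter zeroes weak entries first, then drops by strict gene total", {
  # columns: (9,9) all below 10 -> zeroed, dropped; (100,401) total 501 kept;
  # (10,490) total 500 not > 500 dropped; (300,300) kept
  m <- matrix(c(9, 9, 100, 401, 10, 490, 300, 300), nrow = 2)
  cm <- toy_cm(m)
  f <- filter_facs(cm)
  expect_equal(f$genes$gene_id, c("g2", "g4"))
  expect_equal(attr(f, "filter_report")$genes_dropped, 2L)
  expect_equal(attr(f, "filter_report")$entries_zeroed, 2L)
  # zeroing happens before the total: (9, 495) would total 504 raw but 495 after
  m2 <- matrix(c(9, 495, 600, 1), nrow = 2)
  f2 <- filter_facs(toy_cm(m2))
  expect_equal(f2$genes$gene_id, "g2")
  expect_equal(as.numeric(f2$counts[, 1]), c(600, 0))   # the 1 was zeroed
})

test_that("FACS filter keeps spike-ins and is idempotent", {
  m <- matrix(c(9, 9, 700, 700, 5, 3), nrow = 2)
  cm <- toy_cm(m, spikein = c(FALSE, FALSE, TRUE))
  f <- filter_facs(cm)
  expect_true("g3" %in% f$genes$gene_id)      # spike-in exempt from drop
  expect_false("g1" %in% f$genes$gene_id)
  ff <- filter_facs(f)
  expect_equal(as.matrix(ff$counts), as.matrix(f$counts))
  expect_true(all(as.matrix(f$counts) <= as.matrix(cm$counts[, f$genes$gene_id])))
  expect_error(filter_facs(cm, min_gene_total = -1), "non-negative")
})

test_that("per-tissue FACS filtering zeroes a gene only where it fails", {
  m <- matrix(0, nrow = 4, ncol = 1)
  m[1:2, 1] <- c(300, 300)   # tissue a: total 600, passes
  m[3:4, 1] <- c(50, 60)     # tissue b: total 110, fails
  cm <- toy_cm(m, tissue = c("a", "a", "b", "b"))
  f <- filter_facs(cm, per_tissue = TRUE)
  expect_equal(as.numeric(f$counts[, 1]), c(300, 300, 0, 0))
  g <- filter_facs(cm, per_tissue = FALSE)   # global total 710 passes intact
  expect_equal(as.numeric(g$counts[, 1]), c(300, 300, 50, 60))
})

test_that("droplet filter applies inclusive per-cell thresholds", {
  n_genes <- 501
  m <- matrix(0, nrow = 3, ncol = n_genes)
  m[1, 1:500] <- 2                 # total 1000, 500 genes -> kept (boundary)
  m[2, 1:500] <- 2; m[2, 500] <- 1 # total 999 -> dropped
  m[3, 1:499] <- 3                 # 1497 reads but 499 genes -> dropped
  cm <- toy_cm(m)
  f <- filter_droplet(cm)
  expect_equal(f$cells$cell_id, "c1")
  expect_equal(attr(f, "filter_report")$cells_dropped, 2L)
  expect_equal(as.matrix(f$counts), as.matrix(cm$counts)[1, , drop = FALSE])
  # all cells passing leaves the matrix unchanged
  m_ok <- matrix(3, nrow = 2, ncol = n_genes)
  f_ok <- filter_droplet(toy_cm(m_ok))
  expect_equal(dim(f_ok), c(2L, n_genes))
  # spike-ins excluded from totals and detected-gene counts
  cm_sp <- toy_cm(cbind(m[1:2, ], 1000),
                  spikein = c(rep(FALSE, n_genes), TRUE))
  f_sp <- filter_droplet(cm_sp)
  expect_equal(f_sp$cells$cell_id, "c1")
  expect_error(filter_droplet(cm, min_genes = -5), "non-negative")
})
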