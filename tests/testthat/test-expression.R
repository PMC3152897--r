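test_that("dataset construction enforces the EF 40% rule and identifiers", {
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3", "s4")))
  ds <- expression_dataset(m, ef = c(41, 63, 40, 20))
  expect_equal(as.character(ds$labels), c("good", "good", "poor", "poor"))
  expect_error(expression_dataset(m, labels = rep("good", 4), ef = c(41, 63, 40, 20)),
               "inconsistent")
  expect_error(expression_dataset(m, labels = c("good", "bad", "good", "poor")),
               "good")
  m2 <- m; m2[1, 1] <- NA
  expect_error(expression_dataset(m2, ef = c(41, 63, 40, 20)), "missing values")
  m3 <- m; rownames(m3) <- c("g1", "g1", "g3")
  expect_error(expression_dataset(m3, ef = c(41, 63, 40, 20)), "duplicate gene")
})

test_that("expression files round-trip through matrix + phenotype tables", {
  ds <- small_expression(n_genes = 5, seed = 3)
  fm <- withr::local_tempfile(); fp <- withr::local_tempfile()
  write_expression(ds, fm, fp)
  back <- read_expression(fm, fp)
  expect_equal(back$matrix, ds$matrix, tolerance = 1e-9)
  expect_equal(back$labels, ds$labels)
  # phenotype with EF only derives labels by the 40% rule
  ph <- read.delim(fp)
  write.table(ph[, c("sample", "ef")], fp, sep = "\t", quote = FALSE,
              row.names = FALSE)
  back2 <- read_expression(fm, fp)
  expect_equal(back2$labels, ds$labels)
  # a sample missing from the phenotype file is an error
  write.table(ph[-1, ], fp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_expression(fm, fp), "absent")
})

test_that("Mann-Whitney U and exact p match enumeration and wilcox.test", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)     # 2/choose(6,3)
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # U(x,y) + U(y,x) = n1*n2
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(9)
    expect_equal(mann_whitney(x, y)$U + mann_whitney(y, x)$U, 54)
  }
  # exact p equals the full-enumeration oracle for n1+n2 <= 12
  set.seed(5)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- rnorm(n1); y <- rnorm(n2)
    expect_equal(mann_whitney(x, y, mode = "exact")$p, mw_oracle(x, y),
                 tolerance = 1e-12)
    wt <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mann_whitney(x, y)$U, unname(wt$statistic))
    expect_equal(mann_whitney(x, y)$p, wt$p.value, tolerance = 1e-12)
  }
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("exact and approximate Mann-Whitney p agree for moderate samples", {
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    pe <- mann_whitney(x, y, mode = "exact")$p
    pa <- mann_whitney(x, y, mode = "approx")$p
    expect_lt(abs(pe - pa), 0.02)
  }
  # ties force the corrected normal approximation; cross-check wilcox.test
  x <- c(1, 2, 2, 3, 5); y <- c(2, 3, 3, 6, 7, 7)
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(mann_whitney(x, y)$p, wt$p.value, tolerance = 1e-9)
})

test_that("gene DE scan finds planted shifts and is calibrated degenerately", {
  ds <- small_expression(n_genes = 50, seed = 7,
                         de_genes = c(G0001 = 2.0))
  de <- gene_de_scan(ds)
  expect_lt(de$p_nominal[de$unit == "G0001"], 0.01)
  expect_equal(de$direction[de$unit == "G0001"], 1)
  # constant gene: all ties, p = 1
  m <- ds$matrix; m["G0002", ] <- 5
  ds2 <- expression_dataset(m, labels = ds$labels)
  expect_equal(gene_de_scan(ds2, genes = "G0002")$p_nominal, 1)
  expect_error(gene_de_scan(ds, genes = c("G0001", "NOPE")), "NOPE")
})

test_that("module mean profiles average present genes and log dropped ones", {
  m <- rbind(g1 = c(1, 3), g2 = c(3, 1))
  colnames(m) <- c("s1", "s2")
  ds <- expression_dataset(m, labels = c("good", "poor"))
  expect_equal(as.numeric(module_mean_profile(ds, c("g1", "g2"))), c(2, 2))
  expect_equal(as.numeric(module_mean_profile(ds, "g1")),
               as.numeric(m["g1", ]))
  expect_message(prof <- module_mean_profile(ds, c("g1", "g2", "g3", "g4")),
                 "2 module gene")
  expect_equal(attr(prof, "n_dropped"), 2L)
  expect_error(module_mean_profile(ds, c("x1", "x2")), "no module gene")
  # invariant to gene order, linear in the matrix
  ds8 <- small_expression(n_genes = 8, seed = 8)
  g <- ds8$genes[1:4]
  expect_equal(module_mean_profile(ds8, g), module_mean_profile(ds8, rev(g)))
  ds8b <- expression_dataset(2 * ds8$matrix, labels = ds8$labels)
  expect_equal(as.numeric(module_mean_profile(ds8b, g)),
               2 * as.numeric(module_mean_profile(ds8, g)))
})

test_that("module-level DE ranks the planted module first", {
  genes <- sprintf("G%04d", 1:60)
  memb <- setNames(rep(1:6, each = 10), genes)
  ds <- synth_expression(60, seed = 9,
                         de_genes = setNames(rep(1.5, 10), genes[memb == 4]))
  md <- module_de(ds, memb)
  expect_equal(md$unit[which.min(md$p_adj)], "4")
  expect_lt(min(md$p_adj), 0.05)
  # single-module partition: correction is a no-op
  md1 <- module_de(ds, setNames(rep(1, 60), genes))
  expect_equal(md1$p_adj, md1$p_nominal)
})

test_that("module-level DE stays null on null data", {
  genes <- sprintf("G%04d", 1:60)
  memb <- setNames(rep(1:6, each = 10), genes)
  hits <- 0L
  for (s in 1:100) {
    ds <- synth_expression(60, seed = s + 1000)
    if (min(module_de(ds, memb)$p_adj) <= 0.05) hits <- hits + 1L
  }
  expect_gte(100L - hits, 90L)
})

test_that("Ct normalization follows the 2^(delta Ct) housekeeping formula", {
  ct <- ct_table(matrix(c(20, 23, 19, 20,
                          22, 22, 22, 22), nrow = 2, byrow = TRUE,
                        dimnames = list(c("p1", "p2"),
                                        c("REF", "TRAF2", "UBC", "SHKBP1"))),
                 reference_gene = "REF")
  ex <- pcr_normalize(ct)
  expect_equal(unname(ex[, "REF"]), c(1, 1))
  expect_equal(unname(ex["p1", "TRAF2"]), 2^-3)   # +3 cycles -> 0.125
  expect_equal(unname(ex["p1", "UBC"]), 2)        # -1 cycle -> 2.0
  expect_equal(unname(ex["p1", "SHKBP1"]), 1)
  # per-sample shift invariance
  ct2 <- ct_table(ct$ct + matrix(c(2, 0), 2, 4), "REF")
  expect_equal(pcr_normalize(ct2), pcr_normalize(ct))
  bad <- ct$ct; bad["p1", "REF"] <- NA
  expect_error(ct_table(bad, "REF"), "missing")
  expect_error(ct_table(ct$ct, "GAPDH"), "not measured")
})
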