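test_that("per-model means follow the log2(TPM + 1) convention", {
  expr <- cbind(M1_r1 = c(gA = 3, gB = 0), M1_r2 = c(7, 0),
                M2_r1 = c(1, 3), M2_r2 = c(3, 1))
  panel <- list(expression = expr,
                samples = data.frame(sample_id = colnames(expr),
                                     model = c("M1", "M1", "M2", "M2")))
  mm <- model_mean_log_expression(panel, c("gA", "gB"))
  expect_equal(mm["gA", "M1"], mean(c(log2(4), log2(8))))
  expect_equal(mm["gA", "M2"], mean(c(log2(2), log2(4))))  # TPM {1,3} -> 1.5
  expect_equal(mm["gA", "M2"], 1.5)
  expect_equal(mm["gB", "M1"], 0)  # all-zero gene
  expect_error(model_mean_log_expression(panel, c("gA", "gX")), "gX")
})

test_that("correlation with MVD reproduces exact linear relations", {
  mvd <- c(M1 = 10, M2 = 20, M3 = 30, M4 = 40)
  mm <- rbind(up = mvd / 5 + 2, down = -mvd, flat = rep(1, 4))
  colnames(mm) <- names(mvd)
  expect_warning(ct <- correlate_with_mvd(mm, mvd), "zero expression variance")
  expect_equal(ct$pearson_r[ct$gene == "up"], 1)
  expect_equal(ct$pearson_r[ct$gene == "down"], -1)
  expect_true(is.na(ct$pearson_r[ct$gene == "flat"]))
  expect_equal(ct$n_models, rep(4, 3))
  expect_error(correlate_with_mvd(mm[, 1:2], mvd[1:2]), ">= 3 models")
})

test_that("correlation r and p agree with cor.test", {
  set.seed(3)
  mm <- matrix(rnorm(8 * 10), nrow = 8,
               dimnames = list(paste0("g", 1:8), paste0("M", 1:10)))
  mvd <- rnorm(10)
  names(mvd) <- colnames(mm)
  ct <- correlate_with_mvd(mm, mvd)
  for (i in 1:8) {
    ref <- cor.test(mm[i, ], mvd)
    expect_equal(ct$pearson_r[i], unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ct$p_value[i], ref$p.value, tolerance = 1e-12)
  }
})

test_that("correlation is invariant to positive affine transforms of MVD", {
  set.seed(4)
  mm <- matrix(rnorm(5 * 6), nrow = 5,
               dimnames = list(paste0("g", 1:5), paste0("M", 1:6)))
  mvd <- setNames(runif(6, 10, 200), colnames(mm))
  a <- correlate_with_mvd(mm, mvd)
  b <- correlate_with_mvd(mm, 3.7 * mvd + 12)
  expect_equal(a$pearson_r, b$pearson_r, tolerance = 1e-12)
})

test_that("top_correlated ranks by signed r with deterministic ties", {
  ct <- data.frame(gene = c("A", "B", "C"), pearson_r = c(0.9, 0.8, 0.7))
  expect_equal(top_correlated(ct, 2)$gene, c("A", "B"))
  tie <- data.frame(gene = c("zz", "aa", "mm"), pearson_r = c(0.5, 0.5, 0.9))
  expect_equal(top_correlated(tie, 2)$gene, c("mm", "aa"))
  expect_warning(all3 <- top_correlated(tie, 10), "only 3")
  expect_equal(nrow(all3), 3)
})

test_that("specificity index spans exclusivity to uniformity", {
  # 14 equal clusters, one cell each; filler gene keeps library sizes equal
  m <- matrix(0, nrow = 3, ncol = 14,
              dimnames = list(c("uniform", "exclusive", "filler"),
                              sprintf("c%02d", 1:14)))
  m["uniform", ] <- 5
  m["exclusive", 1] <- 5
  m["filler", 2:14] <- 5
  ds <- structure(list(counts = m,
                       cell_cluster = factor(c("EC", sprintf("K%02d", 2:14))),
                       gene_ids = rownames(m), cell_ids = colnames(m)),
                  class = "sc_dataset")
  idx <- specificity_index(ds, c("uniform", "exclusive"), "EC")
  expect_equal(unname(idx["exclusive"]), 1)
  expect_equal(unname(idx["uniform"]), 1 / 14, tolerance = 1e-12)
})

test_that("planted EC markers are more specific than background genes", {
  pr <- tiny_profiles(n_clusters = 6, markers = 8)
  sc <- tiny_sc(cells = 80, n_clusters = 6, markers = 8)
  idx <- specificity_index(sc, sc$gene_ids, "EC")
  markers <- pr$marker_sets$EC
  non_markers <- setdiff(sc$gene_ids, unlist(pr$marker_sets))
  expect_gt(min(idx[markers]), median(idx[non_markers]))
})

test_that("build_signature filters, orders and truncates as declared", {
  sc <- tiny_sc()
  pr <- tiny_profiles()
  cand <- data.frame(gene = pr$marker_sets$EC[1:5],
                     pearson_r = c(0.9, 0.5, 0.7, 0.95, 0.6))
  # threshold 0: identity pool, ordered by descending r
  sig <- build_signature(cand, dataset = sc, target_cluster = "EC",
                         specificity_threshold = 0, size = 5)
  expect_s3_class(sig, "signature_def")
  expect_equal(sig$genes, cand$gene[order(-cand$pearson_r)])
  expect_equal(sig$transform, list(log_base = 2, pseudocount = 1,
                                   unit = "TPM"))
  # extra markers without r rank after correlated genes
  extra <- pr$marker_sets$EC[6]
  sig2 <- build_signature(cand, extra_markers = extra, dataset = sc,
                          target_cluster = "EC",
                          specificity_threshold = 0, size = 6)
  expect_equal(sig2$genes[6], extra)
  # impossible threshold: empty signature with warnings
  expect_warning(expect_warning(
    sig3 <- build_signature(cand, dataset = sc, target_cluster = "EC",
                            specificity_threshold = 1, size = 3),
    "smaller"), "no gene survives")
  expect_length(sig3$genes, 0)
})

test_that("signature definitions round-trip through YAML", {
  sig <- mvd_signature(c("Kdr", "Cdh5", "Tek"), name = "ec3",
                       weights = c(2, 1, 1))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_signature_yaml(sig, path)
  back <- read_signature_yaml(path)
  expect_equal(back$genes, sig$genes)
  expect_equal(back$transform, sig$transform)
  expect_equal(back$weights, sig$weights)
  expect_error(mvd_signature(character(0)), "non-empty")
  expect_error(mvd_signature(c("a", "a")), "duplicate")
})

test_that("ortholog mapping translates, deduplicates and warns", {
  sig <- mvd_signature(c("Kdr", "Cdh5", "Tek"), name = "ec3")
  map <- data.frame(from = c("Kdr", "Cdh5", "Pecam1"),
                    to = c("KDR", "CDH5", "PECAM1"))
  expect_warning(hs <- map_signature_genes(sig, map), "Tek")
  expect_equal(hs$genes, c("KDR", "CDH5"))
  expect_equal(hs$name, "ec3")
  expect_error(map_signature_genes(sig, map[0, ]), "no signature gene")
})
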