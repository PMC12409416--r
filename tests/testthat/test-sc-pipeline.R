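test_that("count_matrix validates and flags mito/ribo genes by symbol", {
  m <- matrix(0:5, nrow = 3)
  cm <- count_matrix(m,
                     gene_info = data.frame(gene = c("ACTB", "MT-CO1", "RPL13")),
                     cell_info = data.frame(cell_id = c("a", "b"), sample = "s",
                                            condition = "normoxia", genotype = "NTC"))
  expect_equal(cm$gene_info$mito, c(FALSE, TRUE, FALSE))
  expect_equal(cm$gene_info$ribo, c(FALSE, FALSE, TRUE))
  expect_error(count_matrix(matrix(c(1.5, 1), 2, 1),
                            data.frame(gene = c("A", "B")),
                            data.frame(cell_id = "a", sample = "s",
                                       condition = "n", genotype = "g")),
               "integers")
})

test_that("filter_cells removes exactly the intended cells at each stage", {
  res <- filter_cells(qc_fixture(), doublet_ids = "c05")
  rep <- res$report
  expect_equal(rep$stage, c("min_total_counts", "mad_outliers", "ribo_fraction",
                            "doublet_stub"))
  expect_equal(rep$cells_in, c(10, 9, 7, 6))
  expect_equal(rep$cells_out, c(9, 7, 6, 5))
  expect_true(all(rep$cells_out <= rep$cells_in))
  expect_setequal(res$counts$cell_info$cell_id, c("c06", "c07", "c08", "c09", "c10"))
})

test_that("filter_cells edge behavior: zero MAD, pass-through stub, emptiness", {
  # identical cells: MAD = 0 on every metric, nothing removed anywhere
  m <- matrix(rep(c(900, 50, 50), 6), nrow = 3)
  cm <- count_matrix(m, data.frame(gene = c("G1", "MT-1", "RPS1")),
                     data.frame(cell_id = paste0("c", 1:6), sample = "s",
                                condition = "n", genotype = "g"))
  res <- filter_cells(cm, filter_config(min_total_counts = 500))
  expect_equal(ncol(res$counts$counts), 6)
  # doublet stage is a pass-through without labels
  expect_equal(res$report$cells_out[4], 6)

  # threshold stages are idempotent on their own output
  res2 <- filter_cells(res$counts, filter_config(min_total_counts = 500))
  expect_equal(res2$report$cells_out[c(1, 3)], res2$report$cells_in[c(1, 3)])

  # removing everything raises an error that carries the report
  err <- tryCatch(filter_cells(cm, filter_config(min_total_counts = 1e7)),
                  schet_filter_error = identity)
  expect_s3_class(err, "schet_filter_error")
  expect_true(is.data.frame(err$report))
  expect_error(filter_cells(subset_empty <- count_matrix(
    matrix(integer(), nrow = 3, ncol = 0), data.frame(gene = c("a", "b", "c")),
    data.frame(cell_id = character(), sample = character(),
               condition = character(), genotype = character()))),
    "empty")
})

test_that("select_features ranks globally or intersects the panel", {
  m <- rbind(A = c(20, 20), B = c(10, 10), C = c(2, 2))
  cm <- count_matrix(m, data.frame(gene = c("A", "B", "C")),
                     data.frame(cell_id = c("x", "y"), sample = "s",
                                condition = "n", genotype = "g"))
  expect_equal(select_features(cm, "unsupervised", n = 1), "A")
  expect_setequal(select_features(cm, "unsupervised", n = 10), c("A", "B", "C"))
  expect_warning(f <- select_features(cm, "supervised", panel = c("A", "Z1", "Z2")),
                 "absent")
  expect_equal(f, "A")
  expect_error(
    suppressWarnings(select_features(cm, "supervised", panel = c("Z1", "Z2"))),
    "no panel gene")
})

test_that("embed_and_cluster separates disjoint marker blocks and is deterministic", {
  set.seed(2)
  n_per <- 40
  # population 1 expresses M1..M5, population 2 expresses M6..M10
  block <- function(on) {
    sapply(seq_len(n_per), function(i) {
      c(if (on == 1) rpois(5, 50) else rpois(5, 0.05),
        if (on == 2) rpois(5, 50) else rpois(5, 0.05),
        rpois(3, 20))  # shared genes keep totals sane
    })
  }
  m <- cbind(block(1), block(2))
  cm <- count_matrix(m, data.frame(gene = c(paste0("M", 1:10), paste0("S", 1:3))),
                     data.frame(cell_id = paste0("c", seq_len(2 * n_per)),
                                sample = rep(c("p1", "p2"), each = n_per),
                                condition = "n", genotype = "g"))
  ec <- embed_and_cluster(cm, cm$gene_info$gene, n_pcs = 5, k = 2, seed = 0)
  expect_equal(recovery_score(ec$cluster, cm$cell_info$sample)$ari, 1)
  ec2 <- embed_and_cluster(cm, cm$gene_info$gene, n_pcs = 5, k = 2, seed = 0)
  expect_identical(ec$cluster, ec2$cluster)

  # all-equal features are degenerate and flagged
  flat <- count_matrix(matrix(5L, 2, 10),
                       data.frame(gene = c("F1", "F2")),
                       data.frame(cell_id = paste0("c", 1:10), sample = "s",
                                  condition = "n", genotype = "g"))
  expect_error(embed_and_cluster(flat, c("F1", "F2"), n_pcs = 1, k = 2), "degenerate")
  expect_error(embed_and_cluster(cm, cm$gene_info$gene, n_pcs = 500, k = 2),
               "exceeds")
})

test_that("adjusted_rand_index matches the closed-form oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(1:6, rep(1, 6)), 0)  # singletons vs one cluster
  # contingency table [[2,1],[1,2]], n = 6: hand evaluation gives -1/9
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 1, 2, 2)
  expect_equal(adjusted_rand_index(a, b), -1 / 9)
  # both trivial partitions: identical, defined as 1
  expect_equal(adjusted_rand_index(rep(1, 5), rep("x", 5)), 1)
})

test_that("positive_cell_fraction counts cells with at least one read", {
  m <- rbind(G = c(0, 1, 2, 0), H = c(0, 0, 0, 0))
  cm <- count_matrix(m, data.frame(gene = c("G", "H")),
                     data.frame(cell_id = paste0("c", 1:4), sample = "s",
                                condition = "n", genotype = "g"))
  expect_equal(positive_cell_fraction(cm, "G"), 50)
  expect_equal(positive_cell_fraction(cm, "H"), 0)
  expect_equal(positive_cell_fraction(cm, "G", subset = c(2, 3)), 100)
  expect_error(positive_cell_fraction(cm, "G", subset = integer()), "empty")
  expect_error(positive_cell_fraction(cm, "Z"), "not present")
})

test_that("pseudobulk_deg applies thresholds exactly on the hand fixture", {
  fx <- deg_fixture()
  deg <- pseudobulk_deg(fx$cm, fx$groups)
  row <- function(g) deg[deg$gene == g, ]
  expect_equal(row("D1")$log2fc, log2(1501 / 101))
  expect_equal(row("D1")$base_mean, 800)
  expect_true(row("D1")$pass)
  expect_false(row("D2")$pass)                       # log2FC 1.58 < 2
  expect_false(row("D3")$pass)                       # base mean 55 < 350
  expect_false(row("D4")$prefilter)                  # total 30 <= 50
  expect_false(row("D4")$pass)
  expect_true(row("D5")$pass)                        # 2.807 / 351: just clears both
  expect_equal(row("D6")$base_mean, 350)
  expect_false(row("D6")$pass)                       # strict ">"
  expect_equal(row("D7")$log2fc, 2)
  expect_false(row("D7")$pass)                       # strict ">"

  sup <- pseudobulk_deg(fx$cm, fx$groups, deg_config(supervised = TRUE))
  expect_true(sup[sup$gene == "D3", "pass"])         # 3.20 / 55 clears 1.5 / 50
  expect_true(sup[sup$gene == "D2", "pass"])         # 1.58 / 400 clears 1.5 / 50

  # identical groups: all fold changes zero, nothing passes
  same <- pseudobulk_deg(fx$cm, factor(c("A", "B", "A", "B"), levels = c("A", "B")))
  expect_false(any(same$pass))
})

test_that("pseudobulk_deg is invariant to relabeling within groups and global depth", {
  fx <- deg_fixture()
  base <- pseudobulk_deg(fx$cm, fx$groups)
  shuffled <- subset_cells_for_test(fx$cm, c(2, 1, 4, 3))
  expect_equal(pseudobulk_deg(shuffled, fx$groups)$pass, base$pass)
  tripled <- count_matrix(fx$cm$counts * 3L, fx$cm$gene_info, fx$cm$cell_info)
  expect_equal(pseudobulk_deg(tripled, fx$groups)$pass, base$pass)
  expect_error(pseudobulk_deg(fx$cm, factor(rep("A", 4))), "two groups")
})
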