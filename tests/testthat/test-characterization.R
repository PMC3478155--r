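cluster_members <- function() {
  path <- system.file("extdata", "carp_cluster_members.tsv", package = "mirpipe")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

test_that("published cluster spans are reproduced by 1-based inclusive arithmetic", {
  cl <- find_clusters(cluster_members(), max_gap = 10000)
  expect_equal(nrow(cl), 5)
  expect_setequal(cl$length, c(392L, 362L, 515L, 901L, 274L))
})

test_that("clustering is single-linkage on one reference and strand", {
  two <- data.frame(id = c("miR-212", "miR-132"), reference_id = "r1",
                    start = c(200L, 430L), end = c(420L, 591L), strand = "-")
  cl <- find_clusters(two, max_gap = 10)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$length, 392L)   # gap of 9 chains them

  # same coordinates on opposite strands never cluster
  two$strand <- c("-", "+")
  expect_equal(nrow(find_clusters(two, max_gap = 10)), 0)

  # three precursors chained pairwise form one 3-member cluster;
  # oracle: exhaustive pairwise gap check
  three <- data.frame(id = paste0("m", 1:3), reference_id = "r1",
                      start = c(100L, 200L, 300L), end = c(150L, 250L, 350L),
                      strand = "+")
  cl3 <- find_clusters(three, max_gap = 49)
  expect_equal(cl3$n_members, 3)
  gaps <- three$start[-1] - three$end[-3] - 1L
  expect_true(all(gaps <= 49))
  # with a tighter gap nothing chains
  expect_equal(nrow(find_clusters(three, max_gap = 48)), 0)
})

test_that("phylogenetic grouping partitions the bundled presence matrix", {
  pm <- read_presence_matrix(system.file("extdata", "presence_matrix_synthetic.tsv",
                                         package = "mirpipe"))
  groups <- apply(pm$matrix, 1, assign_phylo_group, clades = pm$clades)
  expect_equal(unname(groups["let-7"]), "protostome+deuterostome-shared")
  expect_equal(unname(groups["mir-430"]), "fish-only")
  expect_equal(unname(groups["mir-727"]), "fish-only")
  expect_equal(unname(groups["mir-132"]), "vertebrate-only")
  # partition: every family gets exactly one of the three groups
  expect_true(all(groups %in% c("protostome+deuterostome-shared",
                                "vertebrate-only", "fish-only")))
  expect_equal(sum(groups == "protostome+deuterostome-shared"), 6)
  expect_equal(sum(groups == "fish-only"), 2)
})

test_that("a family present in hsa and dre only is vertebrate-only", {
  p <- c(hsa = TRUE, dre = TRUE, dme = FALSE, cel = FALSE)
  expect_equal(assign_phylo_group(p), "vertebrate-only")
  expect_error(assign_phylo_group(c(hsa = FALSE, dre = FALSE)), "absent")
})

test_that("exact Mann-Whitney matches full enumeration and handles ties", {
  res <- compare_expression(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)      # 2 * 1/20 over all 20 arrangements
  expect_equal(res$method, "exact")
  expect_equal(compare_expression(c(5, 5), c(5, 5))$p, 1.0)
  expect_error(compare_expression(numeric(0), 1), "at least one")
})

test_that("exact routine agrees with enumeration for all small inputs (property)", {
  set.seed(99)
  for (rep in 1:20) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(1:6, n1, replace = TRUE)
    y <- sample(1:6, n2, replace = TRUE)
    res <- compare_expression(x, y)
    # independent enumeration oracle
    pool <- c(x, y)
    u_obs <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    us <- apply(utils::combn(n1 + n2, n1), 2, function(idx) {
      a <- pool[idx]; b <- pool[-idx]
      sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    })
    p_oracle <- min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
    expect_equal(res$p, p_oracle)
  }
})

test_that("normal approximation tracks the exact p for moderate samples", {
  set.seed(100)
  diffs <- replicate(15, {
    x <- rnorm(10); y <- rnorm(10, 0.5)
    exact <- compare_expression(x, y, exact_limit = 20)$p
    approx <- compare_expression(x, y, exact_limit = 0)$p
    abs(exact - approx)
  })
  expect_lt(max(diffs), 0.02)
})

test_that("2^-ddCt yields 1 at the calibrator and the closed-form ratios", {
  ct <- expand.grid(sample = c("s0", "s1", "s2"), gene = c("mir", "U6"),
                    stringsAsFactors = FALSE)
  ct$ct <- c(20, 21, 18, 15, 15, 15)   # dCt = 5, 6, 3
  prof <- ddct_expression(ct, "mir", "U6", calibrator = "s0")
  expect_equal(prof$relative[prof$sample == "s0"], 1.0)
  expect_equal(prof$relative[prof$sample == "s1"], 0.5)   # ddCt = +1
  expect_equal(prof$relative[prof$sample == "s2"], 4.0)   # ddCt = -2
  expect_equal(prof$log2_rel, -prof$ddct)
  expect_true(all(prof$relative > 0))
  expect_error(ddct_expression(ct[-1, ], "mir", "U6", "s0"), "missing Ct")
})

test_that("miRNA-target correlation flags reciprocal patterns", {
  res <- mirna_target_correlation(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1))
  expect_equal(res$r, -1)
  expect_true(res$reciprocal)
  self <- mirna_target_correlation(c(1, 3, 2, 5, 4), c(1, 3, 2, 5, 4))
  expect_equal(self$r, 1)
  expect_false(self$reciprocal)
  # independent covariance-formula recomputation on random series
  set.seed(8)
  a <- rnorm(5); b <- rnorm(5)
  r_direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(mirna_target_correlation(a, b)$r, r_direct)
  expect_error(mirna_target_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("hierarchical clustering recovers well-separated planted groups", {
  set.seed(55)
  g1 <- matrix(rnorm(5 * 4, mean = 0, sd = 0.1), 5, 4)
  g2 <- matrix(rnorm(5 * 4, mean = 5, sd = 0.1), 5, 4)
  mat <- rbind(g1, g2)
  rownames(mat) <- paste0("m", 1:10)
  hc <- hierarchical_cluster(mat, k = 2)
  expect_equal(length(unique(hc$groups[1:5])), 1)
  expect_equal(length(unique(hc$groups[6:10])), 1)
  expect_false(hc$groups[[1]] == hc$groups[[10]])

  # identical rows merge first, at height 0
  m2 <- rbind(a = c(1, 2), b = c(1, 2), c = c(9, 9))
  hc2 <- hierarchical_cluster(m2)
  expect_equal(hc2$hclust$height[1], 0)
  expect_equal(hc2$groups[["a"]], hc2$groups[["b"]])

  # single row: trivial tree
  expect_equal(hierarchical_cluster(matrix(1:3, 1))$order, 1L)
  expect_error(hierarchical_cluster(matrix(c(1, NA), 1)), "missing")
})
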