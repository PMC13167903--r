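test_that("similarity matrix implements 1 - Hamming/n", {
  n <- 50
  g0 <- rep(0L, n)
  g5 <- g0; g5[1:5] <- 1L
  gc <- 1L - g0
  M <- rbind(g0, g0, g5, gc)
  S <- similarity_matrix(M)
  expect_equal(diag(S), rep(1, 4))
  expect_equal(S, t(S))
  expect_equal(S[1, 2], 1)        # identical genomes
  expect_equal(S[1, 3], 0.9)      # differ at 5 of 50 genes
  expect_equal(S[1, 4], 0)        # fully complementary
  expect_true(all(S >= 0 & S <= 1))
  expect_error(similarity_matrix(matrix(0, 0, 5)), "empty")
})

test_that("SVD entropy anchors: monoclonal zero, dissimilar clones log(b)", {
  # monoclonal populations of any size give exactly zero
  for (m in c(1, 4, 100)) {
    g <- rbinom(50, 1, 0.3)
    M <- matrix(rep(g, each = m), nrow = m)
    expect_identical(svd_entropy(similarity_matrix(M)), 0)
  }
  # two 2-cell clones with fully dissimilar genomes: singular values {2,2}
  M <- rbind(rep(0L, 50), rep(0L, 50), rep(1L, 50), rep(1L, 50))
  S <- similarity_matrix(M)
  expect_equal(sort(svd(S)$d, decreasing = TRUE), c(2, 2, 0, 0),
               tolerance = 1e-12)
  expect_equal(svd_entropy(S), log(2), tolerance = 1e-12)
  # block-ones S for b equal, mutually dissimilar clones: entropy log(b)
  for (b in 2:6) {
    S_b <- kronecker(diag(b), matrix(1, 10, 10))
    expect_equal(svd_entropy(S_b), log(b), tolerance = 1e-9)
  }
})

test_that("entropy is permutation invariant and detects added clones", {
  set.seed(5)
  M <- matrix(rbinom(30 * 50, 1, 0.2), 30, 50)
  S <- similarity_matrix(M)
  perm <- sample(30)
  expect_equal(svd_entropy(S[perm, perm]), svd_entropy(S), tolerance = 1e-10)
  # a fully dissimilar clone added to a monoclonal population raises entropy
  mono <- matrix(0L, 6, 50)
  mixed <- rbind(mono, matrix(1L, 2, 50))
  expect_gt(svd_entropy(similarity_matrix(mixed)),
            svd_entropy(similarity_matrix(mono)))
})

test_that("low-rank singular spectrum matches the dense SVD exactly", {
  set.seed(9)
  for (i in 1:5) {
    m <- sample(20:60, 1)
    M <- matrix(rbinom(m * 50, 1, runif(1, 0.05, 0.5)), m, 50)
    dense <- svd(similarity_matrix(M))$d
    dense <- dense[dense > 1e-9 * max(dense)]
    lowrank <- ithsim:::lowrank_singular_values(M)
    expect_equal(lowrank, dense, tolerance = 1e-8)
    expect_equal(ith_entropy(M, method = "exact"),
                 svd_entropy(similarity_matrix(M)), tolerance = 1e-9)
  }
})

test_that("sampled entropy estimates track the exact value", {
  set.seed(31)
  pop <- synthetic_clone_population(n_clones = 8, cells_per_clone = 150)
  exact <- ith_entropy(pop, method = "exact")
  est <- replicate(20, ith_entropy(pop, method = "sampled"))
  expect_lt(abs(mean(est) - exact) / exact, 0.10)
})

test_that("mean mutation count is the population average, bounded by n", {
  M0 <- matrix(0L, 7, 50)
  expect_equal(mean_mutation_count(M0), 0)
  M <- rbind(c(rep(1L, 1), rep(0L, 49)), c(rep(1L, 3), rep(0L, 47)))
  expect_equal(mean_mutation_count(M), 2)
  set.seed(2)
  Mr <- matrix(rbinom(500, 1, 0.5), 10, 50)
  expect_lte(mean_mutation_count(Mr), 50)
  expect_error(mean_mutation_count(matrix(integer(), 0, 0)), "no melanocytes")
})

test_that("subclone clustering partitions by driver profile", {
  braf <- genome_string(genome_with("BRAF"))
  pten <- genome_string(genome_with("PTEN"))
  cells <- rbind(cells_tbl(row = 1:6, col = 1, genome = braf),
                 cells_tbl(row = 1:6, col = 3, genome = pten))
  lab <- cluster_subclones(cells, k = 2)
  expect_equal(length(unique(lab)), 2L)
  expect_equal(length(unique(lab[1:6])), 1L)
  expect_equal(length(unique(lab[7:12])), 1L)
  expect_false(lab[1] == lab[7])
  # single shared profile collapses to one cluster
  expect_equal(unique(cluster_subclones(cells[1:6, ], k = 1)), 1L)
  # deterministic under a fixed seed even when k-means is engaged
  set.seed(77)
  many <- cells_tbl(row = rep(1:10, 4), col = rep(1:4, each = 10),
                    genome = braf)
  many$genome <- replicate(40, genome_string(mutate_genome(
    genome_with("BRAF"), r = 0.4)))
  set.seed(123); l1 <- cluster_subclones(many, k = 3)
  set.seed(123); l2 <- cluster_subclones(many, k = 3)
  expect_identical(l1, l2)
  expect_error(cluster_subclones(cells[1:3, ], k = 5), "fewer cells")
})

test_that("box counting recovers known dimensions", {
  expect_equal(box_counting_fd(matrix(TRUE, 128, 128)), 2, tolerance = 0.05)
  line <- matrix(FALSE, 128, 128); line[64, ] <- TRUE
  expect_equal(box_counting_fd(line), 1, tolerance = 0.05)
  expect_equal(box_counting_fd(sierpinski_carpet(5)), log(8) / log(3),
               tolerance = 0.05)
  expect_error(box_counting_fd(matrix(FALSE, 10, 10)), "empty")
  expect_true(is.na(box_counting_fd(matrix(TRUE, 4, 4))))
})

test_that("box counting is invariant under translation and rotation", {
  m <- sierpinski_carpet(4)
  fd <- box_counting_fd(m)
  shifted <- matrix(FALSE, nrow(m) + 13, ncol(m) + 7)
  shifted[13 + seq_len(nrow(m)), 7 + seq_len(ncol(m))] <- m
  expect_equal(box_counting_fd(shifted), fd, tolerance = 0.02)
  rotated <- t(m)[ncol(m):1, ]  # 90-degree rotation
  expect_equal(box_counting_fd(rotated), fd, tolerance = 0.02)
})

test_that("plateau trimming removes the point-count artifact", {
  # 3 isolated cells: the plain slope is ~0 purely because N(l) sticks at 3
  sparse <- matrix(FALSE, 64, 64)
  sparse[cbind(c(2, 30, 60), c(3, 40, 20))] <- TRUE
  expect_lt(abs(box_counting_fd(sparse)), 0.1)
  expect_true(is.na(box_counting_fd(sparse, plateau_trim = TRUE)))
  # dense masks are unaffected by trimming
  expect_equal(box_counting_fd(sierpinski_carpet(5), plateau_trim = TRUE),
               box_counting_fd(sierpinski_carpet(5)))
})

test_that("clustered FD averages per-subclone dimensions", {
  # monoclonal disk: one cluster, dimension of the disk (~2)
  occ <- which(disk_mask(25), arr.ind = TRUE)
  mono <- cells_tbl(row = occ[, 1], col = occ[, 2],
                    genome = genome_string(genome_with("BRAF")))
  v <- clustered_fd(mono, dims = c(70, 70))
  # coarse-box saturation keeps a finite disk slightly below 2
  expect_gt(as.numeric(v), 1.7)
  expect_lt(as.numeric(v), 2.05)
  expect_equal(nrow(attr(v, "clusters")), 1L)
  # two line-shaped subclones: mean dimension ~1
  two <- rbind(
    cells_tbl(row = 10, col = 1:64, genome = genome_string(genome_with("BRAF"))),
    cells_tbl(row = 40, col = 1:64, genome = genome_string(genome_with("PTEN"))))
  v2 <- clustered_fd(two, dims = c(70, 70))
  expect_equal(as.numeric(v2), 1, tolerance = 0.1)
  expect_error(clustered_fd(cells_tbl(1, 1, type = "NC",
                                      genome = genome_string(wild_genome())),
                            dims = c(10, 10)),
               "no melanoma")
})

test_that("ith_report assembles the metric row", {
  set.seed(4)
  pop <- synthetic_clone_population(n_clones = 4, cells_per_clone = 60)
  rep_row <- ith_report(pop, dims = c(120, 120), step = 7L)
  expect_equal(rep_row$step, 7L)
  expect_equal(rep_row$m, 240L)
  expect_gt(rep_row$epsilon, 0)
  expect_gt(rep_row$beta, 0)
  expect_true(is.finite(rep_row$clustered_fd))
  expect_gte(rep_row$k, 1L)
})
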