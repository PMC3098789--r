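test_that("exact rank-sum p-values match closed-form cases", {
  r1 <- binary_classification(c(1, 2, 3, 4, 5, 6),
                              c("A", "A", "A", "B", "B", "B"))
  expect_equal(r1$p, 0.1, tolerance = 1e-12)   # 2/20 labelings per tail
  r2 <- binary_classification(c(1:8, 9:16), rep(c("A", "B"), each = 8))
  expect_equal(r2$p, 2 / choose(16, 8), tolerance = 1e-12)
  expect_equal(r2$direction, -1)
  # identical multisets: ties force the corrected normal path, p = 1
  r3 <- binary_classification(c(1, 2, 3, 1, 2, 3),
                              rep(c("A", "B"), each = 3))
  expect_equal(r3$p, 1)
  expect_equal(binary_classification(rep(1, 6),
                                     rep(c("A", "B"), each = 3))$p, 1)
  expect_error(binary_classification(1:3, c("A", "B", "B")), "at least 2")
})

test_that("exact rank-sum equals the enumeration oracle", {
  set.seed(51)
  for (n1 in 2:5) for (n2 in n1:(10 - n1)) {
    if (n1 + n2 > 10) next
    x <- sample(100, n1); y <- sample(200, n2) + 0.5   # no ties
    got <- binary_classification(c(x, y),
                                 rep(c("A", "B"), c(n1, n2)))$p
    expect_equal(got, enumerate_ranksum_p(x, y), tolerance = 1e-12,
                 info = paste(n1, n2))
  }
})

test_that("Pearson correlation test matches hand calculations", {
  r <- linear_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r$statistic, 0.8, tolerance = 1e-12)
  expect_equal(r$p, 0.2, tolerance = 1e-10)
  expect_equal(linear_correlation(c(1, 2, 3), c(2, 4, 6))$statistic, 1)
  expect_equal(linear_correlation(c(1, 2, 3), c(2, 4, 6))$p, 0)
  expect_equal(linear_correlation(1:4, -(1:4))$statistic, -1)
  rz <- linear_correlation(c(1, 2, 3), c(5, 5, 5))
  expect_equal(rz$p, 1)
  expect_equal(rz$flag, "zero_variance")
  expect_error(linear_correlation(1:2, 1:2), "at least 3")
})

test_that("correlation test holds its nominal level under the null", {
  set.seed(53)
  rej <- mean(vapply(1:400, function(i)
    linear_correlation(rnorm(28), rnorm(28))$p < 0.05, logical(1)))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("1-D two-means split is the exact contiguous optimum", {
  s <- kmeans_split(c(0, 0.1, 0.9, 1.0), min_group_size = 2L)
  expect_equal(s$group, c(1L, 1L, 2L, 2L))
  # min_group_size forbids the natural 3|1 split
  s2 <- kmeans_split(c(0, 0, 0, 1), min_group_size = 2L)
  expect_equal(unname(c(table(s2$group))), c(2L, 2L))
  # mirror-symmetric data: documented tie-break toward the smaller
  # low-value group ({0}|{2,4} and {0,2}|{4} tie at SS = 2)
  s3 <- kmeans_split(c(0, 2, 4), min_group_size = 1L)
  expect_equal(s3$cut, 1L)
  expect_error(kmeans_split(rep(1, 10)), "constant")
  expect_error(kmeans_split(1:4, min_group_size = 3L), "at least")
})

test_that("two-means split matches naive exhaustive search", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    x <- rnorm(n)
    got <- kmeans_split(x, min_group_size = 2L)
    # independent oracle: recompute within-SS of every contiguous split
    xs <- sort(x)
    ss <- vapply(2:(n - 2), function(k) {
      g1 <- xs[1:k]; g2 <- xs[(k + 1):n]
      sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
    }, numeric(1))
    expect_equal(got$withinss, min(ss), tolerance = 1e-10)
    expect_equal(got$cut, (2:(n - 2))[which.min(ss)])
  }
})

test_that("Kaplan-Meier estimates match the product-limit by hand", {
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2/3, 1/3, 0), tolerance = 1e-12)
  km2 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  km3 <- kaplan_meier(c(5, 1, 2, 3), c(0, 0, 1, 0))
  expect_equal(km3$surv[km3$time == 2], 2/3)   # 3 at risk, 1 event
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
})

test_that("logrank chi-square matches the worked hypergeometric sum", {
  # deaths at 1,2 in group 1 and 3,4 in group 2: O1-E1 = 7/6, V = 17/36
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c(1, 1, 2, 2))
  expect_equal(lr$chisq, (7/6)^2 / (17/36), tolerance = 1e-3)
  expect_equal(round(lr$chisq, 3), 2.882)
  # symmetry under relabeling
  lr2 <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c(2, 2, 1, 1))
  expect_equal(lr2$chisq, lr$chisq, tolerance = 1e-12)
  # identical groups
  lr3 <- logrank_test(c(1, 2, 1, 2), rep(1, 4), c(1, 1, 2, 2))
  expect_lt(lr3$chisq, 1e-10)
  expect_equal(logrank_test(c(1, 2), c(0, 0), c(1, 2))$p, 1)
})

test_that("survival association composes split and logrank", {
  set.seed(57)
  scores <- c(rnorm(15, 0), rnorm(15, 5))
  high <- scores > 2.5
  times <- rexp(30, rate = ifelse(high, 0.5, 0.05))
  r <- survival_association(scores, times, rep(1, 30))
  expect_lt(r$p, 0.01)
  expect_equal(r$n1 + r$n2, 30L)
  expect_equal(r$direction, -1)   # high-score group dies faster
  rc <- survival_association(rep(1, 30), times, rep(1, 30))
  expect_equal(rc$flag, "constant")
})

test_that("planted doubled hazard is detected in most replicates", {
  set.seed(59)
  hits <- 0L
  for (i in 1:50) {
    scores <- c(rnorm(50, 0, 0.5), rnorm(50, 3, 0.5))
    high <- scores > 1.5
    times <- rexp(100, rate = 0.1 * ifelse(high, 2, 1))
    r <- survival_association(scores, times, rep(1, 100))
    hits <- hits + (r$p < 0.05)
  }
  expect_gte(hits, 45L)
})

test_that("per-sample hypergeometric tail matches enumeration", {
  # direct combinatorial case: N=10, K=4, n=5, k=4
  net <- toy_network()   # genes 101..106 -> use a custom small universe
  alt <- matrix(0L, 10, 1,
                dimnames = list(c("101", "102", "103", "104",
                                  as.character(1:6 + 900)), "s1"))
  alt[c("101", "102", "103", "104", "901"), 1] <- 1L   # k=4 of n=5 in K=4
  mols <- data.frame(molecule_id = c("a", "b"), label = c("a", "b"))
  mols$entrez_ids <- list(c("101", "102"), c("103", "104"))
  net4 <- pathway_network("pw", "pw", mols, list(
    list(interaction_id = "i", promoters = "a",
         inhibitors = character(0), outputs = "b")))
  r <- gene_hits(alt, net4)
  expect_equal(unname(r$per_sample), 6 / 252, tolerance = 1e-12)
  expect_equal(unname(r$per_sample), enumerate_hyper_p(10, 4, 5, 4),
               tolerance = 1e-12)
})

test_that("hypergeometric tails equal brute-force placement enumeration", {
  set.seed(61)
  for (i in 1:10) {
    N <- sample(6:12, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(1:(N - 1), 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 enumerate_hyper_p(N, K, n, k), tolerance = 1e-10,
                 info = paste(N, K, n, k))
  }
})

test_that("Fisher omnibus combination follows the even-df closed form", {
  set.seed(63)
  # craft two samples and verify against independent arithmetic
  genes <- as.character(1:10 + 100)
  mols <- data.frame(molecule_id = "a", label = "a")
  mols$entrez_ids <- list(genes[1:4])
  net <- pathway_network("pw", "pw", mols, list(
    list(interaction_id = "i", promoters = "a",
         inhibitors = character(0), outputs = "a")))
  alt <- matrix(0L, 10, 3, dimnames = list(genes, c("s1", "s2", "s3")))
  alt[1:5, 1] <- 1L          # k=4? genes[1:4] in pathway, gene 5 not
  alt[c(1, 6), 2] <- 1L      # k=1, n=2
  r <- gene_hits(alt, net)   # s3 has zero alterations: excluded
  expect_length(r$per_sample, 2L)
  X <- -2 * sum(log(r$per_sample))
  expect_equal(r$statistic, X, tolerance = 1e-12)
  # chi-square survival with 4 df: e^{-X/2} (1 + X/2)
  expect_equal(r$p, exp(-X / 2) * (1 + X / 2), tolerance = 1e-10)

  # all-zero alteration matrix: omnibus 0, p = 1
  r0 <- gene_hits(matrix(0L, 10, 2, dimnames = list(genes, c("a", "b"))),
                  net)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)

  # disjoint universe: not testable
  alt2 <- matrix(1L, 2, 1, dimnames = list(c("7777", "8888"), "s1"))
  expect_equal(gene_hits(alt2, net)$flag, "not_testable")
})

test_that("p-value adjustment caps, preserves order and nests", {
  expect_equal(adjust_pvalues(rep(0.001, 50))[1], 0.05)
  expect_equal(adjust_pvalues(c(0.5, rep(0.9, 9)))[1], 1.0)
  expect_equal(adjust_pvalues(0.37), 0.37)
  set.seed(65)
  p <- runif(40)
  adj <- adjust_pvalues(p)
  expect_true(all(which(adj < 0.05) %in% which(p < 0.05)))
  expect_true(all(adjust_pvalues(p, "bh") <= adj + 1e-15))
})

test_that("run_analysis builds a ranked hypothesis family", {
  spec <- synth_spec(seed = 67, n_pathways = 20)
  pw <- generate_pathways(spec)
  samples <- paste0("s", 1:12)
  probs <- random_prob_matrix(pw$mapping$probe_id, samples, seed = 68)
  sc <- score_pathways(probs, pw$nets, pw$mapping)
  y <- setNames(rnorm(12), samples)
  res <- run_analysis(sc, y, test = "correlation")
  expect_equal(nrow(res), 40L)   # 20 pathways x 2 metrics
  expect_false(is.unsorted(res$p_raw))
  expect_true(all(res$p_adjusted >= res$p_raw - 1e-15))

  # class restriction filters the sample set
  labels <- setNames(rep(c("t", "n"), each = 6), samples)
  res2 <- run_analysis(sc, y, test = "correlation", classes = labels,
                       class_restrict = "t")
  expect_equal(attr(res2, "n_samples"), 6L)
  expect_error(run_analysis(sc, y, test = "nope"))
  expect_error(run_analysis(sc, setNames(rnorm(3), c("x", "y", "z")),
                            test = "correlation"), "no samples")
})
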