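test_that("probe-to-gene aggregation averages posteriors", {
  probs <- matrix(c(0.2, 0.4, 0.7), 3, 1,
                  dimnames = list(c("pa", "pb", "pc"), "s1"))
  mapping <- data.frame(probe_id = c("pa", "pb", "pc"),
                        entrez_id = c("9", "9", "8"))
  expect_equal(gene_probability(probs, mapping, "9", "s1"), 0.3)
  expect_equal(gene_probability(probs, mapping, "8", "s1"), 0.7)
  expect_true(is.na(gene_probability(probs, mapping, "7", "s1")))
  gm <- gene_probability_matrix(probs, mapping)
  expect_equal(gm["9", "s1"], 0.3)
})

test_that("molecule probability multiplies measured member genes", {
  net <- toy_network()
  gp <- matrix(c(0.9, 0.8, 0.5), 3, 1,
               dimnames = list(c("104", "105", "101"), "s1"))
  expect_equal(unname(molecule_probability(net, gp, "m4")), 0.72)
  expect_equal(unname(molecule_probability(net, gp, "m1")), 0.5)
  expect_true(is.na(molecule_probability(net, gp, "m2")))
  expect_error(molecule_probability(net, gp, "m99"), "unknown")
})

test_that("interaction activity follows the promoter/inhibitor product", {
  expect_equal(interaction_activity(c(1, 1), 0), 1.0)
  expect_equal(interaction_activity(c(0.9, 0.5), 1.0), 0)
  expect_equal(interaction_activity(c(0.9, 0.8), 0.25), 0.54)
  # unmeasured inputs take 0.5 when anything is measured
  expect_equal(interaction_activity(c(0.8, NA)), 0.4)
  expect_true(is.na(interaction_activity(NA_real_, NA_real_)))
  expect_error(interaction_activity(numeric(0), numeric(0)), "no inputs")
})

test_that("consistency scores agreement between potential and outputs", {
  expect_equal(interaction_consistency(1, 1), 1.0)
  expect_equal(interaction_consistency(0.5, 0.123), 0.5)
  expect_equal(interaction_consistency(0.54, 0.7), 0.516)
  expect_true(is.na(interaction_consistency(0.5, NA_real_)))
  expect_equal(interaction_consistency(0.5, c(0.4, NA)),
               interaction_consistency(0.5, c(0.4, 0.5)))
})

test_that("activity is monotone in inputs and consistency is symmetric", {
  set.seed(21)
  for (i in 1:50) {
    p <- runif(3); q <- runif(2)
    a <- interaction_activity(p, q)
    expect_gte(a, 0); expect_lte(a, 1)
    # raising a promoter raises activity; raising an inhibitor lowers it
    p2 <- p; p2[1] <- min(1, p[1] + 0.1)
    expect_gte(interaction_activity(p2, q), a)
    q2 <- q; q2[1] <- min(1, q[1] + 0.1)
    expect_lte(interaction_activity(p, q2), a)
    # agreement symmetry
    po <- runif(1)
    expect_equal(interaction_consistency(a, po),
                 interaction_consistency(1 - a, 1 - po), tolerance = 1e-12)
  }
})

test_that("pathway scores average scoreable interactions", {
  net <- toy_network()
  mapping <- toy_mapping()
  # choose probe values so interaction activities are easy to follow
  probs <- matrix(
    c(0.9, 0.8, 0.25, 1.0, 1.0, 1.0, 0.7), 7, 1,
    dimnames = list(c("p1", "p2", "p3", "p4a", "p4b", "p5", "p6"), "s1"))
  sc <- score_pathways(probs, net, mapping)
  # i1: 0.9*0.8*(1-0.25) = 0.54 ; i2: promoter m4 = 1*1 -> activity 1
  expect_equal(unname(sc$activity["toy", "s1"]), mean(c(0.54, 1.0)))
  # i1 consistency: P_out = p(m4) = 1 -> 0.54 ; i2: P_out = 0.7 -> 0.7
  expect_equal(unname(sc$consistency["toy", "s1"]),
               mean(c(0.54 * 1 + 0.46 * 0, 1 * 0.7 + 0 * 0.3)))
})

test_that("unmapped pathways are flagged missing with a warning", {
  net <- toy_network()
  probs <- matrix(0.5, 1, 2, dimnames = list("zzz", c("s1", "s2")))
  mapping <- data.frame(probe_id = "zzz", entrez_id = "99999")
  expect_warning(sc <- score_pathways(probs, net, mapping),
                 "no scoreable")
  expect_true(all(is.na(sc$activity)))
})

test_that("a single interaction perturbation moves the mean by delta/n", {
  net <- toy_network()
  mapping <- toy_mapping()
  probs <- random_prob_matrix(toy_mapping()$probe_id, "s1", seed = 31)
  base <- score_pathways(probs, net, mapping)
  # push i2's promoter (m4 via its two genes) and compare
  delta_probe <- 0.05
  probs2 <- probs
  probs2["p5", ] <- probs["p5", ] + delta_probe
  pert <- score_pathways(probs2, net, mapping)
  # direct delta on interaction 2's activity
  m4_base <- mean(probs[c("p4a", "p4b"), 1]) * probs["p5", 1]
  m4_new <- mean(probs[c("p4a", "p4b"), 1]) * (probs["p5", 1] + delta_probe)
  delta_a2 <- m4_new - m4_base
  expect_equal(unname(pert$activity[1, 1] - base$activity[1, 1]),
               delta_a2 / 2, tolerance = 1e-12)
})

test_that("scoring matches the brute-force oracle on random networks", {
  set.seed(41)
  spec <- synth_spec(seed = 41, n_pathways = 10,
                     interactions_range = c(2L, 5L))
  pw <- generate_pathways(spec)
  samples <- paste0("s", 1:20)
  probs <- random_prob_matrix(pw$mapping$probe_id, samples, seed = 42)
  sc <- score_pathways(probs, pw$nets, pw$mapping)
  for (pid in names(pw$nets)) {
    oracle <- brute_force_scores(probs, pw$nets[[pid]], pw$mapping)
    expect_equal(unname(sc$activity[pid, ]), unname(oracle$activity),
                 tolerance = 1e-12)
    expect_equal(unname(sc$consistency[pid, ]), unname(oracle$consistency),
                 tolerance = 1e-12)
  }
})

test_that("sample permutation permutes score columns identically", {
  spec <- synth_spec(seed = 43, n_pathways = 3)
  pw <- generate_pathways(spec)
  samples <- paste0("s", 1:8)
  probs <- random_prob_matrix(pw$mapping$probe_id, samples, seed = 44)
  sc1 <- score_pathways(probs, pw$nets, pw$mapping)
  perm <- c(5, 3, 8, 1, 2, 7, 6, 4)
  sc2 <- score_pathways(probs[, perm], pw$nets, pw$mapping)
  expect_equal(sc2$activity, sc1$activity[, perm])
  expect_equal(sc2$consistency, sc1$consistency[, perm])
})

test_that("selection validates pathway and sample ids", {
  net <- toy_network()
  mapping <- toy_mapping()
  probs <- random_prob_matrix(mapping$probe_id, c("s1", "s2"), seed = 45)
  expect_error(score_pathways(probs, net, mapping,
                              pathway_ids = "nope"), "nope")
  expect_error(score_pathways(probs, net, mapping,
                              sample_ids = c("s1", "sX")), "sX")
  sub <- score_pathways(probs, net, mapping, sample_ids = "s2")
  expect_equal(colnames(sub$activity), "s2")
})

test_that("score matrices round-trip through the tsv writer", {
  net <- toy_network()
  mapping <- toy_mapping()
  probs <- random_prob_matrix(mapping$probe_id, c("s1", "s2"), seed = 46)
  sc <- score_pathways(probs, net, mapping, keep_interactions = TRUE)
  d <- tempfile()
  write_scores(sc, d)
  back <- read_scores(d)
  expect_equal(back$activity, sc$activity, tolerance = 1e-12)
  expect_equal(back$consistency, sc$consistency, tolerance = 1e-12)
  expect_true(file.exists(file.path(d, "interactions.tsv")))
})
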