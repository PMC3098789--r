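# Shared fixtures and independent oracles, all built in code.

# two-interaction toy network: i1 has promoters m1,m2 and inhibitor m3
# with output m4; i2 consumes m4 and produces m5
toy_network <- function() {
  mols <- data.frame(
    molecule_id = paste0("m", 1:5),
    label = paste0("gene", 1:5))
  mols$entrez_ids <- list("101", "102", "103", c("104", "105"), "106")
  pathway_network(
    "toy", "toy pathway (synthetic)",
    molecules = mols,
    interactions = list(
      list(interaction_id = "i1", promoters = c("m1", "m2"),
           inhibitors = "m3", outputs = "m4"),
      list(interaction_id = "i2", promoters = "m4",
           inhibitors = character(0), outputs = "m5")))
}

toy_pathway_file <- function(path = tempfile(fileext = ".txt")) {
  write_pathway_file(toy_network(), path)
  path
}

toy_mapping <- function() {
  m <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4a", "p4b", "p5", "p6"),
    entrez_id = c("101", "102", "103", "104", "104", "105", "106"))
  class(m) <- c("probe_mapping", "data.frame")
  m
}

# straight-line reimplementation of pathway scoring, kept deliberately
# independent of the package internals: nested loops, no vectorization
brute_force_scores <- function(probs, net, mapping) {
  samples <- colnames(probs)
  gene_p <- function(gene, s) {
    pr <- mapping$probe_id[mapping$entrez_id == gene]
    pr <- pr[pr %in% rownames(probs)]
    if (length(pr) == 0) return(NA)
    tot <- 0
    for (p in pr) tot <- tot + probs[p, s]
    tot / length(pr)
  }
  mol_p <- function(mol, s) {
    genes <- net$molecules$entrez_ids[[
      which(net$molecules$molecule_id == mol)]]
    vals <- c()
    for (g in genes) {
      v <- gene_p(g, s)
      if (!is.na(v)) vals <- c(vals, v)
    }
    if (length(vals) == 0) return(NA)
    out <- 1
    for (v in vals) out <- out * v
    out
  }
  act <- con <- numeric(length(samples))
  names(act) <- names(con) <- samples
  for (s in samples) {
    a_list <- c(); c_list <- c()
    for (ia in net$interactions) {
      inp <- c()
      for (m in ia$promoters) inp <- c(inp, mol_p(m, s))
      ninh <- length(ia$inhibitors)
      for (m in ia$inhibitors) inp <- c(inp, mol_p(m, s))
      if (all(is.na(inp))) next
      inp[is.na(inp)] <- 0.5
      a <- 1
      np <- length(ia$promoters)
      if (np > 0) for (v in inp[seq_len(np)]) a <- a * v
      if (ninh > 0) for (v in inp[np + seq_len(ninh)]) a <- a * (1 - v)
      a_list <- c(a_list, a)
      outp <- c()
      for (m in ia$outputs) outp <- c(outp, mol_p(m, s))
      if (!all(is.na(outp))) {
        outp[is.na(outp)] <- 0.5
        po <- 1
        for (v in outp) po <- po * v
        c_list <- c(c_list, a * po + (1 - a) * (1 - po))
      }
    }
    act[s] <- if (length(a_list)) mean(a_list) else NA
    con[s] <- if (length(c_list)) mean(c_list) else NA
  }
  list(activity = act, consistency = con)
}

# exact two-sided rank-sum p-value by enumeration of all labelings
enumerate_ranksum_p <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  r <- rank(all_v)
  w_obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(all_v), n1)
  w_all <- apply(combos, 2, function(idx) sum(r[idx]))
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# brute-force upper-tail hypergeometric by enumerating alteration placements
enumerate_hyper_p <- function(N, K, n, k) {
  combos <- utils::combn(N, n)
  in_pathway <- seq_len(K)   # wlog the first K genes form the pathway
  hits <- apply(combos, 2, function(idx) sum(idx %in% in_pathway))
  mean(hits >= k)
}

# random up-probability matrix for property tests
random_prob_matrix <- function(probes, samples, seed) {
  set.seed(seed)
  m <- matrix(runif(length(probes) * length(samples)),
              length(probes), length(samples),
              dimnames = list(probes, samples))
  m
}
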