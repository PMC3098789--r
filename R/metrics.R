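## Pathway metrics: per-interaction activity and consistency from
## up-probabilities, averaged into per-sample pathway scores.
##
## Activity  A = prod p(promoter) * prod (1 - p(inhibitor))
##   -- the probability that every positive regulator is up and every
##      inhibitor is down, i.e. the interaction's potential to occur.
## Consistency C = A * P_out + (1 - A) * (1 - P_out),  P_out = prod p(output)
##   -- the probability that the realized output state agrees with that
##      potential; 1 = outputs follow the network logic, 0 = they contradict.
##
## Unmeasured molecules inside a partially measured interaction take the
## neutral probability 0.5; interactions with no measured input at all are
## unscoreable and excluded from the pathway mean (no measured output drops
## only the consistency term).

#' Aggregate probeset up-probabilities to gene level
#'
#' Gene probability = mean of the posteriors of all probesets mapped to that
#' gene (posteriors share a unit scale, so averaging is meaningful). Genes
#' with no mapped measured probeset are absent from the result (unmeasured).
#'
#' @param probs Probeset x sample matrix of up-probabilities.
#' @param mapping A `probe_mapping` (see [load_probe_mapping()]).
#' @return Gene x sample matrix of probabilities; rownames are Entrez ids.
#' @export
gene_probability_matrix <- function(probs, mapping) {
  keep <- mapping$probe_id %in% rownames(probs)
  mp <- mapping[keep, , drop = FALSE]
  if (nrow(mp) == 0L)
    return(matrix(numeric(0), 0, ncol(probs),
                  dimnames = list(character(0), colnames(probs))))
  genes <- unique(mp$entrez_id)
  out <- matrix(NA_real_, length(genes), ncol(probs),
                dimnames = list(genes, colnames(probs)))
  for (g in genes) {
    pr <- mp$probe_id[mp$entrez_id == g]
    block <- probs[pr, , drop = FALSE]
    out[g, ] <- colMeans(block)
  }
  out
}

#' Up-probability of a single gene in a single sample
#'
#' Convenience scalar accessor over [gene_probability_matrix()].
#'
#' @param probs Probeset x sample up-probability matrix.
#' @param mapping A `probe_mapping`.
#' @param entrez_id Entrez gene id (character or integer).
#' @param sample Sample id.
#' @return Probability, or `NA` when no probeset maps to the gene
#'   ("unmeasured").
#' @export
gene_probability <- function(probs, mapping, entrez_id, sample) {
  entrez_id <- as.character(entrez_id)
  pr <- mapping$probe_id[mapping$entrez_id == entrez_id]
  pr <- pr[pr %in% rownames(probs)]
  if (length(pr) == 0L) return(NA_real_)
  mean(probs[pr, sample])
}

#' Up-probability of a pathway molecule
#'
#' A molecule (possibly a complex) is up when all its measured member genes
#' are up: the product of member-gene probabilities. `NA` ("unmeasured")
#' when the molecule has no measured member gene.
#'
#' @param net A `pathway_network`.
#' @param gene_probs Gene x sample probability matrix (or a named vector for
#'   one sample).
#' @param molecule_id Molecule id within `net`.
#' @return Numeric vector across samples (or scalar), `NA` if unmeasured.
#' @export
molecule_probability <- function(net, gene_probs, molecule_id) {
  i <- match(molecule_id, net$molecules$molecule_id)
  if (is.na(i)) stop("unknown molecule '", molecule_id, "'")
  eg <- net$molecules$entrez_ids[[i]]
  if (is.vector(gene_probs))
    gene_probs <- matrix(gene_probs, ncol = 1,
                         dimnames = list(names(gene_probs), "s"))
  eg <- eg[eg %in% rownames(gene_probs)]
  if (length(eg) == 0L) return(rep(NA_real_, ncol(gene_probs)))
  apply(gene_probs[eg, , drop = FALSE], 2L, prod)
}

#' Interaction activity from input probabilities
#'
#' `A = prod(p_promoter) * prod(1 - p_inhibitor)`. `NA` input probabilities
#' (unmeasured molecules) are replaced by 0.5 provided at least one input is
#' measured; with no measured input the interaction is unscoreable and `NA`
#' is returned.
#'
#' @param promoter_probs,inhibitor_probs Numeric vectors of probabilities
#'   (possibly containing `NA`); either may be empty but not both.
#' @return Activity in \[0, 1\], or `NA` when unscoreable.
#' @export
interaction_activity <- function(promoter_probs, inhibitor_probs = numeric(0)) {
  inputs <- c(promoter_probs, inhibitor_probs)
  if (length(inputs) == 0L) stop("interaction has no inputs")
  if (all(is.na(inputs))) return(NA_real_)
  p <- ifelse(is.na(promoter_probs), 0.5, promoter_probs)
  q <- ifelse(is.na(inhibitor_probs), 0.5, inhibitor_probs)
  prod(p) * prod(1 - q)
}

#' Interaction consistency from activity and output probabilities
#'
#' `C = A * P_out + (1 - A) * (1 - P_out)` with
#' `P_out = prod(p_output)`: the probability that the observed output state
#' agrees with the interaction's potential. `NA` outputs are replaced by 0.5
#' when at least one output is measured; with none measured, consistency is
#' `NA` (omitted from pathway averaging) while activity stands.
#'
#' @param activity Activity in \[0, 1\] (or `NA`).
#' @param output_probs Numeric vector of output probabilities (may contain
#'   `NA`).
#' @return Consistency in \[0, 1\], or `NA`.
#' @export
interaction_consistency <- function(activity, output_probs) {
  if (length(output_probs) == 0L) stop("interaction has no outputs")
  if (is.na(activity) || all(is.na(output_probs))) return(NA_real_)
  p_out <- prod(ifelse(is.na(output_probs), 0.5, output_probs))
  activity * p_out + (1 - activity) * (1 - p_out)
}

#' Score pathways across samples
#'
#' Computes per-interaction activity and consistency for every sample, then
#' averages over the pathway's scoreable interactions to give the pathway
#' score: activity = mean activity over interactions with at least one
#' measured input; consistency = mean consistency over interactions that
#' additionally have at least one measured output. A pathway with zero
#' scoreable interactions gets `NA` scores and a warning.
#'
#' @param probs Probeset x sample up-probability matrix (e.g.
#'   `updown_normalize(expr)$probs`).
#' @param nets List of `pathway_network` objects (or a single one).
#' @param mapping A `probe_mapping`.
#' @param pathway_ids,sample_ids Optional subsets to score; unknown ids are
#'   an error listing the offenders.
#' @param keep_interactions If `TRUE`, a long-format per-interaction score
#'   table is attached (used by the network exporter).
#' @return Object of class `pathway_scores`: matrices `activity` and
#'   `consistency` (pathways x samples), `config` snapshot, and optionally
#'   `interactions` (data frame with `pathway_id`, `interaction_id`,
#'   `sample_id`, `activity`, `consistency`).
#' @export
score_pathways <- function(probs, nets, mapping, pathway_ids = NULL,
                           sample_ids = NULL, keep_interactions = FALSE) {
  if (inherits(nets, "pathway_network")) nets <- list(nets)
  if (is.null(names(nets)) || any(!nzchar(names(nets))))
    names(nets) <- vapply(nets, `[[`, character(1), "pathway_id")
  if (!is.null(pathway_ids)) {
    unknown <- setdiff(pathway_ids, names(nets))
    if (length(unknown))
      stop("unknown pathway id(s): ", paste(unknown, collapse = ", "))
    nets <- nets[pathway_ids]
  }
  if (!is.null(sample_ids)) {
    unknown <- setdiff(sample_ids, colnames(probs))
    if (length(unknown))
      stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
    probs <- probs[, sample_ids, drop = FALSE]
  }
  if (length(nets) == 0L || ncol(probs) == 0L)
    stop("empty pathway or sample selection")

  gene_probs <- gene_probability_matrix(probs, mapping)
  n_s <- ncol(probs)
  samples <- colnames(probs)
  act <- matrix(NA_real_, length(nets), n_s,
                dimnames = list(names(nets), samples))
  con <- act
  inter_rows <- list()

  for (pw in names(nets)) {
    net <- nets[[pw]]
    mol_p <- lapply(net$molecules$molecule_id, function(m)
      molecule_probability(net, gene_probs, m))
    names(mol_p) <- net$molecules$molecule_id
    a_rows <- matrix(NA_real_, length(net$interactions), n_s)
    c_rows <- a_rows
    for (j in seq_along(net$interactions)) {
      ia <- net$interactions[[j]]
      pp <- do.call(rbind, mol_p[ia$promoters])
      ip <- do.call(rbind, mol_p[ia$inhibitors])
      op <- do.call(rbind, mol_p[ia$outputs])
      for (s in seq_len(n_s)) {
        a <- interaction_activity(
          if (is.null(pp)) numeric(0) else pp[, s],
          if (is.null(ip)) numeric(0) else ip[, s])
        a_rows[j, s] <- a
        c_rows[j, s] <- interaction_consistency(a, op[, s])
      }
      if (keep_interactions)
        inter_rows[[length(inter_rows) + 1L]] <- data.frame(
          pathway_id = pw, interaction_id = ia$interaction_id,
          sample_id = samples, activity = a_rows[j, ],
          consistency = c_rows[j, ])
    }
    act[pw, ] <- colMeans(a_rows, na.rm = TRUE)
    con[pw, ] <- colMeans(c_rows, na.rm = TRUE)
    if (all(is.na(a_rows)))
      warning("pathway '", pw, "' has no scoreable interactions")
  }
  act[is.nan(act)] <- NA_real_
  con[is.nan(con)] <- NA_real_
  structure(list(activity = act, consistency = con,
                 config = list(aggregation = "mean_of_posteriors",
                               complex_rule = "product",
                               unmeasured_input = 0.5,
                               combiner = "product"),
                 interactions = if (keep_interactions)
                   do.call(rbind, inter_rows)),
            class = "pathway_scores")
}

#' @export
print.pathway_scores <- function(x, ...) {
  cat("Pathway scores: ", nrow(x$activity), " pathways x ",
      ncol(x$activity), " samples\n", sep = "")
  cat("  activity    range: ",
      paste(signif(range(x$activity, na.rm = TRUE), 3), collapse = " - "),
      "\n  consistency range: ",
      paste(signif(range(x$consistency, na.rm = TRUE), 3), collapse = " - "),
      "\n", sep = "")
  cat("  unscoreable entries: ", sum(is.na(x$activity)), "\n", sep = "")
  invisible(x)
}

#' Write pathway score matrices as tab-delimited text
#'
#' Writes `activity.tsv` and `consistency.tsv` (pathways x samples) into
#' `dir`, each with a `# config:` header line recording the scoring
#' decisions.
#'
#' @param scores A `pathway_scores` object.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scores <- function(scores, dir) {
  stopifnot(inherits(scores, "pathway_scores"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- paste0("# config: ",
                paste(names(scores$config), unlist(scores$config),
                      sep = "=", collapse = " "))
  write_matrix_tsv(scores$activity, file.path(dir, "activity.tsv"),
                   id_col = "pathway_id", header_lines = hdr)
  write_matrix_tsv(scores$consistency, file.path(dir, "consistency.tsv"),
                   id_col = "pathway_id", header_lines = hdr)
  if (!is.null(scores$interactions))
    utils::write.table(scores$interactions,
                       file.path(dir, "interactions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read pathway score matrices written by [write_scores()]
#'
#' @param dir Directory containing `activity.tsv` and `consistency.tsv`.
#' @return A `pathway_scores` object (without per-interaction table).
#' @export
read_scores <- function(dir) {
  a <- read_matrix_tsv(file.path(dir, "activity.tsv"))
  co <- read_matrix_tsv(file.path(dir, "consistency.tsv"))
  structure(list(activity = a, consistency = co, config = list(),
                 interactions = NULL),
            class = "pathway_scores")
}
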