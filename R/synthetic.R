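## Seeded synthetic fixtures: expression matrices with known two-gamma
## mixture structure, random connected toy pathway collections, and
## clinical tables with planted effects, so the whole pipeline is testable
## without any external download.

#' Specification for a synthetic data bundle
#'
#' Collects the generator's parameters with their documented defaults. The
#' defaults describe a well-separated mixture (down Gamma(shape 2, scale 1),
#' up Gamma(shape 8, scale 1), half the samples up) measured on cell-line
#' scale cohorts.
#'
#' @param seed Integer RNG seed (every bundle is deterministic given it).
#' @param n_samples Number of samples (default 28, a typical cell-line
#'   panel size).
#' @param n_pathways Number of pathways including any signal target
#'   (default 21: one target plus 20 decoys).
#' @param interactions_range Integer range of interactions per pathway.
#' @param weight_down Mixing proportion of the "down" component.
#' @param shape_down,scale_down,shape_up,scale_up Gamma parameters of the
#'   two components.
#' @param probes_per_gene Probes measured per gene (default 4, typical of
#'   microarray platforms where one gene is covered by several probesets).
#' @param coverage Fraction of genes with measured probes.
#' @param complex_prob Probability a molecule is a 2-gene complex.
#' @param inhibitor_prob Probability an interaction carries an inhibitor.
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(seed = 1L, n_samples = 28L, n_pathways = 21L,
                       interactions_range = c(3L, 6L), weight_down = 0.5,
                       shape_down = 2, scale_down = 1,
                       shape_up = 8, scale_up = 1,
                       probes_per_gene = 4L, coverage = 1,
                       complex_prob = 0.15, inhibitor_prob = 0.3) {
  spec <- as.list(environment())
  stopifnot(n_samples > 0, n_pathways > 0, all(interactions_range > 0),
            weight_down >= 0, weight_down <= 1,
            shape_down > 0, scale_down > 0, shape_up > 0, scale_up > 0,
            coverage > 0, coverage <= 1)
  structure(spec, class = "synth_spec")
}

#' Generate a mixture-distributed expression matrix
#'
#' Each probeset's samples are drawn from the two-gamma mixture
#' `w * Gamma(shape_down, scale_down) + (1-w) * Gamma(shape_up, scale_up)`;
#' the true component label of every entry is retained, so recovery of the
#' up/down state by [updown_normalize()] can be checked against ground
#' truth.
#'
#' @param n_probes Number of probesets.
#' @param n_samples Number of samples.
#' @param weight_down,shape_down,scale_down,shape_up,scale_up Mixture
#'   parameters (defaults as in [synth_spec()]).
#' @param seed Optional seed (`set.seed` is called when non-NULL).
#' @return List: `expr` (matrix, probes x samples), `states` (logical
#'   matrix, `TRUE` = up).
#' @export
generate_expression <- function(n_probes, n_samples, weight_down = 0.5,
                                shape_down = 2, scale_down = 1,
                                shape_up = 8, scale_up = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  probe_ids <- paste0("p", seq_len(n_probes))
  sample_ids <- paste0("s", seq_len(n_samples))
  states <- matrix(stats::runif(n_probes * n_samples) > weight_down,
                   n_probes, n_samples,
                   dimnames = list(probe_ids, sample_ids))
  expr <- matrix(NA_real_, n_probes, n_samples,
                 dimnames = list(probe_ids, sample_ids))
  n_up <- sum(states)
  expr[states] <- stats::rgamma(n_up, shape = shape_up, scale = scale_up)
  expr[!states] <- stats::rgamma(length(expr) - n_up, shape = shape_down,
                                 scale = scale_down)
  list(expr = expr, states = states)
}

#' Generate a random collection of connected toy pathways
#'
#' Builds `n_pathways` random interaction networks over disjoint gene sets
#' (so decoy pathways are statistically independent of any planted effect).
#' Interactions are chained through shared molecules, guaranteeing the
#' connectedness invariant by construction; some molecules are 2-gene
#' complexes and some interactions carry inhibitors. A probe mapping
#' covering `coverage` of the genes is generated alongside.
#'
#' @param spec A [synth_spec()]. The caller controls the RNG state (used by
#'   [generate_bundle()]); call `set.seed()` first for standalone use.
#' @return List: `nets` (named list of `pathway_network`), `mapping`
#'   (`probe_mapping`), `genes` (character vector of all Entrez ids).
#' @export
generate_pathways <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  gene_counter <- 0L
  new_gene <- function() {
    gene_counter <<- gene_counter + 1L
    as.character(1000L + gene_counter)
  }
  nets <- list()
  for (pw in seq_len(spec$n_pathways)) {
    pid <- sprintf("pw%02d", pw)
    mols <- list()   # molecule_id -> entrez vector
    new_mol <- function() {
      n_genes <- if (stats::runif(1) < spec$complex_prob) 2L else 1L
      id <- sprintf("%s_m%02d", pid, length(mols) + 1L)
      mols[[id]] <<- vapply(seq_len(n_genes), function(i) new_gene(),
                            character(1))
      id
    }
    n_int <- sample(seq(spec$interactions_range[1],
                        spec$interactions_range[2]), 1L)
    interactions <- vector("list", n_int)
    carry <- NULL   # molecule shared with the previous interaction
    for (j in seq_len(n_int)) {
      promoters <- c(carry,
                     replicate(sample(1:2, 1L), new_mol()))
      inhibitors <- if (stats::runif(1) < spec$inhibitor_prob) new_mol()
                    else character(0)
      outputs <- replicate(sample(1:2, 1L), new_mol())
      interactions[[j]] <- list(interaction_id = sprintf("%s_i%02d", pid, j),
                                promoters = promoters,
                                inhibitors = inhibitors,
                                outputs = outputs)
      carry <- outputs[1]
    }
    mol_tab <- data.frame(molecule_id = names(mols),
                          label = names(mols))
    mol_tab$entrez_ids <- unname(mols)
    nets[[pid]] <- pathway_network(pid, paste0(pid, " (synthetic)"),
                                   molecules = mol_tab,
                                   interactions = interactions)
  }
  genes <- as.character(1000L + seq_len(gene_counter))
  measured <- if (spec$coverage >= 1) genes
              else sort(sample(genes, max(1L, round(spec$coverage *
                                                    length(genes)))))
  map_rows <- do.call(rbind, lapply(measured, function(g) {
    data.frame(probe_id = paste0("pr", g, "_", seq_len(spec$probes_per_gene)),
               entrez_id = g)
  }))
  rownames(map_rows) <- NULL
  class(map_rows) <- c("probe_mapping", "data.frame")
  list(nets = nets, mapping = map_rows, genes = genes)
}

#' Generate a full synthetic bundle
#'
#' Generates pathways, a probe mapping, gene-level true up/down states
#' (probes of the same gene share its state), and mixture-distributed
#' expression for every measured probe. Deterministic given `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @return List of class `synth_bundle`: `spec`, `nets`, `mapping`, `genes`,
#'   `expr` (probe x sample intensities), `states` (gene x sample logical,
#'   `TRUE` = up), `sample_ids`.
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  pw <- generate_pathways(spec)
  sample_ids <- paste0("s", seq_len(spec$n_samples))
  states <- matrix(stats::runif(length(pw$genes) * spec$n_samples) >
                     spec$weight_down,
                   length(pw$genes), spec$n_samples,
                   dimnames = list(pw$genes, sample_ids))
  bundle <- structure(
    list(spec = spec, nets = pw$nets, mapping = pw$mapping,
         genes = pw$genes, states = states, sample_ids = sample_ids,
         expr = NULL, clinical = NULL, target = NULL),
    class = "synth_bundle")
  bundle$expr <- .expression_from_states(bundle)
  bundle
}

## draw probe intensities given the gene-level state matrix
.expression_from_states <- function(bundle, genes = NULL) {
  spec <- bundle$spec
  map <- bundle$mapping
  if (!is.null(genes)) map <- map[map$entrez_id %in% genes, , drop = FALSE]
  n_s <- length(bundle$sample_ids)
  expr <- matrix(NA_real_, nrow(map), n_s,
                 dimnames = list(map$probe_id, bundle$sample_ids))
  for (i in seq_len(nrow(map))) {
    up <- bundle$states[map$entrez_id[i], ]
    expr[i, up] <- stats::rgamma(sum(up), shape = spec$shape_up,
                                 scale = spec$scale_up)
    expr[i, !up] <- stats::rgamma(sum(!up), shape = spec$shape_down,
                                  scale = spec$scale_down)
  }
  expr
}

#' True pathway scores implied by the generated states
#'
#' Scores pathways with the ground-truth 0/1 gene states in place of
#' estimated up-probabilities — the noise-free reference that planted
#' effects are tied to.
#'
#' @param bundle A `synth_bundle`.
#' @param pathway_ids Optional subset.
#' @return A `pathway_scores` object.
#' @export
true_pathway_scores <- function(bundle, pathway_ids = NULL) {
  gene_map <- data.frame(probe_id = bundle$genes,
                         entrez_id = bundle$genes)
  class(gene_map) <- c("probe_mapping", "data.frame")
  probs <- bundle$states * 1
  score_pathways(probs, bundle$nets, gene_map, pathway_ids = pathway_ids)
}

#' Plant a clinical signal tied to one pathway
#'
#' Adds a clinical table whose association with the target pathway is known
#' by construction:
#' * `class_shift` — input genes of the target pathway are re-drawn with
#'   up-state probability `p_up_shift` in class "B" samples (expression
#'   regenerated for their probes); labels written to
#'   `clinical$class`.
#' * `correlation` — continuous variable = true target activity plus
#'   Gaussian noise of SD `noise_sd`.
#' * `hazard_ratio` — exponential survival times with the hazard multiplied
#'   by `hazard_ratio` for the high-activity group of the exact two-means
#'   split of true target activity; all observations are events (no
#'   censoring).
#' * `alteration_enrichment` — logical gene x sample alteration matrix with
#'   baseline per-gene alteration probability `base_rate` and the target
#'   pathway's genes altered at `odds_multiplier` times the baseline odds.
#'
#' @param bundle A `synth_bundle`.
#' @param kind One of `"class_shift"`, `"correlation"`, `"hazard_ratio"`,
#'   `"alteration_enrichment"`.
#' @param target Target pathway id (default: the first pathway).
#' @param p_up_shift Up-state probability in class B (default 0.9).
#' @param noise_sd Noise SD for the correlation effect (default 0.05).
#' @param hazard_ratio Hazard multiplier for high-activity samples
#'   (default 6, a strongly prognostic marker).
#' @param base_hazard Baseline exponential hazard (default 0.1).
#' @param base_rate Baseline alteration probability (default 0.05).
#' @param odds_multiplier Odds multiplier for target genes (default 5).
#' @return The bundle with `clinical[[kind-specific name]]` and `target`
#'   filled in; for `class_shift`, `states` and `expr` are updated too.
#' @export
plant_signal <- function(bundle,
                         kind = c("class_shift", "correlation",
                                  "hazard_ratio", "alteration_enrichment"),
                         target = NULL, p_up_shift = 0.9, noise_sd = 0.05,
                         hazard_ratio = 6, base_hazard = 0.1,
                         base_rate = 0.05, odds_multiplier = 5) {
  kind <- match.arg(kind)
  stopifnot(inherits(bundle, "synth_bundle"))
  if (is.null(target)) target <- names(bundle$nets)[1]
  if (!target %in% names(bundle$nets))
    stop("unknown target pathway '", target, "'")
  net <- bundle$nets[[target]]
  n_s <- length(bundle$sample_ids)
  bundle$target <- target
  if (is.null(bundle$clinical)) bundle$clinical <- list()

  if (kind == "class_shift") {
    labels <- rep(c("A", "B"), length.out = n_s)
    names(labels) <- bundle$sample_ids
    input_mols <- unique(unlist(lapply(net$interactions,
                                       function(ia) ia$promoters)))
    genes <- unique(unlist(
      net$molecules$entrez_ids[match(input_mols,
                                     net$molecules$molecule_id)]))
    b <- labels == "B"
    bundle$states[genes, b] <-
      matrix(stats::runif(length(genes) * sum(b)) < p_up_shift,
             length(genes), sum(b))
    new_expr <- .expression_from_states(bundle, genes = genes)
    bundle$expr[rownames(new_expr), ] <- new_expr
    bundle$clinical$class <- labels
  } else if (kind == "correlation") {
    act <- true_pathway_scores(bundle, target)$activity[1, ]
    y <- act + stats::rnorm(n_s, sd = noise_sd)
    names(y) <- bundle$sample_ids
    bundle$clinical$continuous <- y
  } else if (kind == "hazard_ratio") {
    act <- true_pathway_scores(bundle, target)$activity[1, ]
    ## high-activity group = the exact two-means split of the true
    ## activity, i.e. the partition the survival test itself looks for
    high <- kmeans_split(act, min_group_size = 5L)$group == 2L
    rate <- base_hazard * ifelse(high, hazard_ratio, 1)
    bundle$clinical$survival <- data.frame(
      sample_id = bundle$sample_ids,
      time = stats::rexp(n_s, rate = rate),
      event = 1L)
  } else {
    genes <- bundle$genes
    base_odds <- base_rate / (1 - base_rate)
    hi_odds <- base_odds * odds_multiplier
    hi_rate <- hi_odds / (1 + hi_odds)
    rate <- ifelse(genes %in% network_genes(net), hi_rate, base_rate)
    alt <- matrix(stats::runif(length(genes) * n_s) <
                    rep(rate, times = n_s),
                  length(genes), n_s,
                  dimnames = list(genes, bundle$sample_ids))
    bundle$clinical$alterations <- alt * 1
  }
  bundle
}

#' Write a bundle's files in the formats the pipeline reads
#'
#' Writes `expression.tsv`, `mapping.tsv`, `pathways.txt`, and whichever
#' clinical tables the bundle carries (`class.tsv`, `continuous.tsv`,
#' `survival.tsv`, `alterations.tsv`). A `bundle.info` file records the
#' generator seed.
#'
#' @param bundle A `synth_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(bundle$expr, file.path(dir, "expression.tsv"),
                   id_col = "probeset_id")
  utils::write.table(as.data.frame(bundle$mapping),
                     file.path(dir, "mapping.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_pathway_file(bundle$nets, file.path(dir, "pathways.txt"))
  cl <- bundle$clinical
  if (!is.null(cl$class))
    utils::write.table(data.frame(names(cl$class), unname(cl$class)),
                       file.path(dir, "class.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(cl$continuous))
    utils::write.table(data.frame(names(cl$continuous),
                                  unname(cl$continuous)),
                       file.path(dir, "continuous.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(cl$survival))
    utils::write.table(cl$survival, file.path(dir, "survival.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cl$alterations))
    write_matrix_tsv(cl$alterations, file.path(dir, "alterations.tsv"),
                     id_col = "entrez_id")
  writeLines(c(paste0("seed\t", bundle$spec$seed),
               paste0("target\t",
                      if (is.null(bundle$target)) "-" else bundle$target)),
             file.path(dir, "bundle.info"))
  invisible(dir)
}
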