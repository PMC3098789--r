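## Association analyses: rank pathways by association of their activity or
## consistency scores with sample features. Four tests: binary class
## (Wilcoxon rank-sum), continuous variable (Pearson correlation),
## survival (exact 1-D two-cluster split + Kaplan-Meier/logrank), and
## gene-hit enrichment (per-sample hypergeometric + Fisher's omnibus).

#' Rank-sum test of pathway scores between two classes
#'
#' Two-sided Wilcoxon rank-sum test: exact by enumeration when
#' `min(n1, n2) <= 10` and there are no ties, normal approximation with tie
#' correction otherwise. Constant scores across both classes give p = 1.
#'
#' @param scores Numeric vector of pathway scores, one per sample.
#' @param labels Factor/character vector of two class labels, same length.
#' @return List: `statistic` (rank-sum W of the first class), `p`,
#'   `direction` (sign of median difference, first class minus second),
#'   `n1`, `n2`, `flag`.
#' @export
binary_classification <- function(scores, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L)
    stop("binary classification needs exactly 2 classes, got ",
         nlevels(labels))
  x <- scores[labels == levels(labels)[1]]
  y <- scores[labels == levels(labels)[2]]
  if (length(x) < 2L || length(y) < 2L)
    stop("each class needs at least 2 samples")
  if (stats::var(c(x, y)) == 0)
    return(list(statistic = NA_real_, p = 1, direction = 0,
                n1 = length(x), n2 = length(y), flag = "constant"))
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && min(length(x), length(y)) <= 10L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       direction = sign(stats::median(x) - stats::median(y)),
       n1 = length(x), n2 = length(y), flag = NA_character_)
}

#' Pearson correlation of pathway scores with a continuous variable
#'
#' Tests `rho = 0` with `t = rho * sqrt(n-2) / sqrt(1 - rho^2)` on `n - 2`
#' degrees of freedom (two-sided); `rho = +/-1` gives p = 0. Zero variance
#' in either vector leaves `rho` undefined and returns p = 1 with a flag.
#'
#' @param scores Numeric vector of pathway scores.
#' @param variable Numeric vector, same length (e.g. -log GI50).
#' @return List: `statistic` (rho), `p`, `n`, `flag`.
#' @export
linear_correlation <- function(scores, variable) {
  ok <- is.finite(scores) & is.finite(variable)
  x <- scores[ok]; y <- variable[ok]
  if (length(x) < 3L) stop("need at least 3 paired finite values")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(list(statistic = NA_real_, p = 1, n = length(x),
                flag = "zero_variance"))
  ct <- stats::cor.test(x, y, method = "pearson")
  list(statistic = unname(ct$estimate), p = ct$p.value, n = length(x),
       flag = NA_character_)
}

#' Exact one-dimensional two-cluster split
#'
#' Partitions values into the two groups minimizing the within-group sum of
#' squares (equivalently, the squared Euclidean distance to group
#' centroids). In one dimension the optimum is contiguous in sorted order,
#' so the split is found exactly by scanning all `n - 1` cut points;
#' candidate splits violating `min_group_size` are excluded. Ties are broken
#' toward the smaller low-value group. Deterministic.
#'
#' @param values Numeric vector, length `>= 2 * min_group_size`.
#' @param min_group_size Minimum samples per group (default 5).
#' @return List: `group` (integer vector in \{1, 2\}, 1 = low-value group,
#'   aligned with `values`), `cut` (boundary: low group has sorted ranks
#'   `1..cut`), `withinss`.
#' @export
kmeans_split <- function(values, min_group_size = 5L) {
  n <- length(values)
  if (n < 2L * min_group_size)
    stop("need at least ", 2L * min_group_size, " values, got ", n)
  if (stats::var(values) == 0)
    stop("constant values cannot be split into two clusters")
  o <- order(values)
  xs <- values[o]
  ## prefix sums give within-SS of every contiguous split in O(n)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  cuts <- seq.int(min_group_size, n - min_group_size)
  if (length(cuts) == 0L) stop("min_group_size leaves no feasible split")
  s1 <- cs[cuts]; q1 <- cs2[cuts]
  ss <- (q1 - s1^2 / cuts) +
    ((cs2[n] - q1) - (cs[n] - s1)^2 / (n - cuts))
  k <- cuts[which.min(ss)]   # which.min takes the first = smaller low group
  group <- integer(n)
  group[o] <- ifelse(seq_len(n) <= k, 1L, 2L)
  list(group = group, cut = k, withinss = min(ss))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function; right-censored
#' observations leave the risk set without contributing an event.
#'
#' @param times Nonnegative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return Data frame with columns `time`, `n_risk`, `n_event`, `surv`
#'   (one row per distinct observed time).
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  stopifnot(all(times >= 0), all(events %in% c(0, 1)))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             surv = sf$surv)
}

#' Two-group logrank test
#'
#' Standard logrank chi-square, `(O1 - E1)^2 / V`, accumulating observed
#' minus expected events with the hypergeometric variance at each distinct
#' event time; p from chi-square with 1 df. With no events at all, p = 1
#' (flagged).
#'
#' @param times Follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param group Two-level grouping vector.
#' @return List: `chisq`, `p`, `flag`.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2L)
  if (sum(events) == 0)
    return(list(chisq = NA_real_, p = 1, flag = "no_events"))
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       flag = NA_character_)
}

#' Survival association of a pathway score
#'
#' Splits samples into low/high score groups by [kmeans_split()], then
#' compares their Kaplan-Meier curves with a logrank test. Constant scores
#' cannot be split and yield a flagged, skipped result (p = NA).
#'
#' @param scores Numeric pathway scores, one per sample.
#' @param times,events Survival data aligned with `scores`.
#' @param min_group_size Minimum samples per score group (default 5).
#' @return List: `statistic` (logrank chi-square), `p`, `n1`, `n2`,
#'   `direction` (+1 when the high-score group has longer median survival),
#'   `flag`.
#' @export
survival_association <- function(scores, times, events,
                                 min_group_size = 5L) {
  if (stats::var(scores) == 0)
    return(list(statistic = NA_real_, p = NA_real_, n1 = NA_integer_,
                n2 = NA_integer_, direction = 0, flag = "constant"))
  sp <- kmeans_split(scores, min_group_size = min_group_size)
  lr <- logrank_test(times, events, sp$group)
  med <- function(g) stats::median(times[sp$group == g])
  list(statistic = lr$chisq, p = lr$p,
       n1 = sum(sp$group == 1L), n2 = sum(sp$group == 2L),
       direction = sign(med(2L) - med(1L)), flag = lr$flag)
}

#' Gene-hit enrichment of a pathway
#'
#' For each sample `s` with at least one altered gene, the upper-tail
#' hypergeometric probability that the pathway's genes are hit `k_s` or more
#' times given `n_s` alterations among `N` assayed genes, `K` of which lie
#' in the pathway: `p_s = P(X >= k_s)`, `X ~ Hypergeom(N, K, n_s)`. The
#' per-sample probabilities are combined by Fisher's omnibus statistic
#' `X = -2 * sum(log p_s)`, referred to chi-square with `2S` df (S = number
#' of contributing samples). Samples with zero alterations are excluded.
#'
#' @param alterations Logical/0-1 matrix, genes x samples; rownames are the
#'   Entrez ids of the assayed gene universe.
#' @param net A `pathway_network`.
#' @return List: `statistic` (omnibus X), `p`, `per_sample` (named vector of
#'   p_s), `n_pathway_genes`, `flag` (`"not_testable"` when the pathway
#'   shares no gene with the universe, with p = NA).
#' @export
gene_hits <- function(alterations, net) {
  stopifnot(is.matrix(alterations))
  alt <- alterations != 0
  universe <- rownames(alt)
  pw_genes <- intersect(network_genes(net), universe)
  if (length(pw_genes) == 0L)
    return(list(statistic = NA_real_, p = NA_real_,
                per_sample = numeric(0), n_pathway_genes = 0L,
                flag = "not_testable"))
  N <- length(universe)
  K <- length(pw_genes)
  n_alt <- colSums(alt)
  use <- n_alt > 0
  if (!any(use))
    return(list(statistic = 0, p = 1, per_sample = numeric(0),
                n_pathway_genes = K, flag = "no_alterations"))
  k_s <- colSums(alt[pw_genes, use, drop = FALSE])
  p_s <- stats::phyper(k_s - 1, K, N - K, n_alt[use], lower.tail = FALSE)
  p_s <- pmin(pmax(p_s, .Machine$double.xmin), 1)
  X <- -2 * sum(log(p_s))
  p <- stats::pchisq(X, df = 2 * length(p_s), lower.tail = FALSE)
  list(statistic = X, p = p, per_sample = p_s,
       n_pathway_genes = K, flag = NA_character_)
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni by default (matching the tool's reporting convention);
#' Benjamini-Hochberg available as `"bh"`. Order is preserved.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same order.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Run an association analysis over all pathways
#'
#' Applies one of the four per-pathway tests to every (pathway, metric) row
#' of a score matrix, adjusts p-values across all hypotheses in the run, and
#' returns the table sorted by raw p ascending.
#'
#' @param scores A `pathway_scores` object.
#' @param clinical For `test = "class"`: named vector/factor of class labels.
#'   For `"correlation"`: named numeric vector. For `"survival"`: data frame
#'   with columns `sample_id`, `time`, `event`. For `"genehits"`: logical
#'   gene x sample matrix with Entrez rownames.
#' @param test One of `"class"`, `"correlation"`, `"survival"`,
#'   `"genehits"`.
#' @param metric `"activity"`, `"consistency"`, or `"both"` (default): which
#'   score matrices enter the hypothesis family.
#' @param nets Pathway networks; required for `test = "genehits"`.
#' @param classes Optional class-label vector (named by sample) used to
#'   restrict the analysis to samples whose label is in `class_restrict`.
#' @param class_restrict Optional character vector of class labels to keep.
#' @param min_group_size Passed to the survival split (default 5).
#' @param adjust `"bonferroni"` (default) or `"bh"`.
#' @return Data frame of class `association_result`, columns `pathway_id`,
#'   `metric`, `statistic`, `p_raw`, `p_adjusted`, `flag`, plus test
#'   extras; sorted by `p_raw`.
#' @export
run_analysis <- function(scores, clinical,
                         test = c("class", "correlation", "survival",
                                  "genehits"),
                         metric = c("both", "activity", "consistency"),
                         nets = NULL, classes = NULL, class_restrict = NULL,
                         min_group_size = 5L,
                         adjust = c("bonferroni", "bh")) {
  test <- match.arg(test)
  metric <- match.arg(metric)
  adjust <- match.arg(adjust)
  stopifnot(inherits(scores, "pathway_scores"))
  metrics <- if (metric == "both") c("activity", "consistency") else metric

  samples <- colnames(scores$activity)
  if (!is.null(class_restrict)) {
    if (is.null(classes)) stop("class_restrict requires classes")
    samples <- intersect(samples,
                         names(classes)[classes %in% class_restrict])
  }

  ## align clinical data to score samples
  if (test %in% c("class", "correlation")) {
    if (is.null(names(clinical)))
      stop("clinical vector must be named by sample id")
    samples <- intersect(samples, names(clinical))
  } else if (test == "survival") {
    stopifnot(all(c("sample_id", "time", "event") %in% names(clinical)))
    samples <- intersect(samples, clinical$sample_id)
  } else if (test == "genehits") {
    if (is.null(nets)) stop("genehits test requires nets")
    samples <- intersect(samples, colnames(clinical))
  }
  if (length(samples) == 0L)
    stop("no samples shared between scores and clinical data")

  rows <- list()
  for (m in metrics) {
    mat <- scores[[m]][, samples, drop = FALSE]
    for (pw in rownames(mat)) {
      sc <- mat[pw, ]
      if (test != "genehits" && (any(is.na(sc)) || stats::var(sc) == 0)) {
        res <- list(statistic = NA_real_, p = NA_real_,
                    flag = if (any(is.na(sc))) "unscoreable" else "constant")
      } else {
        res <- switch(test,
          class = binary_classification(sc, clinical[samples]),
          correlation = linear_correlation(sc, clinical[samples]),
          survival = {
            cl <- clinical[match(samples, clinical$sample_id), ]
            survival_association(sc, cl$time, cl$event,
                                 min_group_size = min_group_size)
          },
          genehits = {
            if (is.null(nets[[pw]])) stop("no network for pathway ", pw)
            gene_hits(clinical[, samples, drop = FALSE], nets[[pw]])
          })
      }
      rows[[length(rows) + 1L]] <- data.frame(
        pathway_id = pw, metric = m,
        statistic = res$statistic, p_raw = res$p,
        flag = if (is.null(res$flag)) NA_character_ else res$flag)
    }
    if (test == "genehits") break   # alteration test does not use scores
  }
  out <- do.call(rbind, rows)
  if (test == "genehits") out$metric <- "genehits"
  out$p_adjusted <- adjust_pvalues(
    ifelse(is.na(out$p_raw), 1, out$p_raw), method = adjust)
  out$p_adjusted[is.na(out$p_raw)] <- NA_real_
  out <- out[order(out$p_raw), ]
  rownames(out) <- NULL
  attr(out, "n_hypotheses") <- sum(!is.na(out$p_raw))
  attr(out, "n_samples") <- length(samples)
  attr(out, "test") <- test
  class(out) <- c("association_result", "data.frame")
  out
}

#' @export
print.association_result <- function(x, n = 10L, ...) {
  cat("Association analysis (", attr(x, "test"), "): ",
      attr(x, "n_hypotheses"), " hypotheses over ",
      attr(x, "n_samples"), " samples\n", sep = "")
  print.data.frame(utils::head(x, n))
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more rows\n")
  invisible(x)
}
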