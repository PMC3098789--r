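## Exploration and export: bi-dimensional hierarchical clustering of score
## matrices, heatmap + reordered-text export, and per-sample network
## exports with score-scaled visual attributes.

#' Bi-dimensional hierarchical clustering of a score matrix
#'
#' Agglomerative clustering run independently on rows and columns.
#' Distances: `"euclidean"` or `"correlation"` (1 - Pearson r, the usual
#' choice for expression-style heatmaps); linkage: `"average"` (default) or
#' `"complete"`. Deterministic given input order (ties follow
#' `stats::hclust`'s fixed agglomeration rule). Rows containing missing
#' values are dropped with a warning; with fewer than 2 rows or columns the
#' identity ordering is returned with a warning.
#'
#' @param mat Numeric matrix (e.g. pathways x samples).
#' @param distance `"correlation"` (default) or `"euclidean"`.
#' @param linkage `"average"` (default) or `"complete"`.
#' @return List of class `bicluster_result`: `row_order`, `col_order`
#'   (permutations of the kept rows/columns), `row_tree`, `col_tree`
#'   (`hclust` objects or `NULL`), `kept_rows`.
#' @export
bicluster <- function(mat, distance = c("correlation", "euclidean"),
                      linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  stopifnot(is.matrix(mat))
  drop <- apply(mat, 1L, function(r) any(!is.finite(r)))
  if (any(drop)) {
    warning(sum(drop), " row(s) with missing scores dropped before ",
            "clustering")
    mat <- mat[!drop, , drop = FALSE]
  }
  dfun <- function(m) {
    if (distance == "euclidean") return(stats::dist(m))
    cc <- suppressWarnings(stats::cor(t(m)))
    cc[!is.finite(cc)] <- 0   # constant rows: treat as uncorrelated
    stats::as.dist(1 - cc)
  }
  cluster_dim <- function(m) {
    if (nrow(m) < 2L) {
      warning("fewer than 2 items; identity ordering returned")
      return(list(order = seq_len(nrow(m)), tree = NULL))
    }
    hc <- stats::hclust(dfun(m), method = linkage)
    list(order = hc$order, tree = hc)
  }
  rowc <- cluster_dim(mat)
  colc <- cluster_dim(t(mat))
  structure(list(row_order = rowc$order, col_order = colc$order,
                 row_tree = rowc$tree, col_tree = colc$tree,
                 kept_rows = rownames(mat)),
            class = "bicluster_result")
}

#' Export a clustered heatmap and its reordered matrix
#'
#' Writes a PNG heatmap of the matrix in clustered order plus the reordered
#' matrix as tab-delimited text (`<path>.ordered.tsv`) so the ordering can
#' be inspected and tested without pixel comparison. Optionally restricts to
#' the `top_variance` rows with the highest across-sample variance before
#' clustering, and draws a sample annotation bar.
#'
#' @param mat Numeric matrix (rows = pathway x metric, columns = samples).
#' @param path Output PNG path; the text export gets the additional
#'   extension `.ordered.tsv`.
#' @param cluster Optional precomputed [bicluster()] result for `mat`
#'   (computed here when `NULL`).
#' @param annotations Optional named character vector labelling samples;
#'   every name must be a column of `mat`.
#' @param top_variance Optional integer: keep only this many
#'   highest-variance rows.
#' @param ... Passed to [bicluster()].
#' @return Invisible list with the reordered matrix (`ordered`) and the two
#'   file paths.
#' @export
export_heatmap <- function(mat, path, cluster = NULL, annotations = NULL,
                           top_variance = NULL, ...) {
  stopifnot(is.matrix(mat))
  if (!is.null(annotations)) {
    unknown <- setdiff(names(annotations), colnames(mat))
    if (length(unknown))
      stop("annotation(s) for unknown sample(s): ",
           paste(unknown, collapse = ", "))
  }
  if (!is.null(top_variance) && top_variance < nrow(mat)) {
    v <- apply(mat, 1L, stats::var)
    keep <- order(v, decreasing = TRUE)[seq_len(top_variance)]
    mat <- mat[sort(keep), , drop = FALSE]
  }
  if (is.null(cluster)) cluster <- bicluster(mat, ...)
  mat <- mat[cluster$kept_rows, , drop = FALSE]
  ordered <- mat[cluster$row_order, cluster$col_order, drop = FALSE]
  tsv_path <- paste0(path, ".ordered.tsv")
  write_matrix_tsv(ordered, tsv_path, id_col = "row_id")

  grDevices::png(path, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(6, 1, 2, 8))
  on.exit(graphics::par(op), add = TRUE)
  pal <- grDevices::hcl.colors(64, "YlGnBu", rev = TRUE)
  graphics::image(t(ordered)[, rev(seq_len(nrow(ordered))), drop = FALSE],
                  col = pal, axes = FALSE, zlim = c(0, 1),
                  main = "Pathway scores (clustered)")
  graphics::axis(1, at = seq(0, 1, length.out = ncol(ordered)),
                 labels = colnames(ordered), las = 2, cex.axis = 0.7)
  graphics::axis(4, at = seq(0, 1, length.out = nrow(ordered)),
                 labels = rev(rownames(ordered)), las = 2, cex.axis = 0.5)
  if (!is.null(annotations)) {
    lab <- annotations[colnames(ordered)]
    cols <- grDevices::rainbow(length(unique(lab)))[as.integer(factor(lab))]
    graphics::points(x = seq(0, 1, length.out = ncol(ordered)),
                     y = rep(-0.08, ncol(ordered)), pch = 15, col = cols,
                     cex = 1.2, xpd = NA)
  }
  invisible(list(ordered = ordered, png = path, tsv = tsv_path))
}

## attribute scaling helpers shared by the two network writers
.node_fill <- function(p) {
  ## 0 -> white, 1 -> saturated turquoise
  p <- min(max(p, 0), 1)
  grDevices::rgb(1 - p * (1 - 64 / 255), 1 - p * (1 - 224 / 255), 1,
                 maxColorValue = 1)
}
.edge_color <- function(consistency) {
  ## low -> dark green, high -> bright blue
  if (is.na(consistency)) return("#888888")
  c0 <- grDevices::col2rgb("#1b5e20")
  c1 <- grDevices::col2rgb("#00b0ff")
  v <- (c0 + (c1 - c0) * min(max(consistency, 0), 1)) / 255
  grDevices::rgb(v[1], v[2], v[3])
}

#' Export a pathway network with per-sample score attributes
#'
#' Writes one node per molecule and one node per interaction. Molecule fill
#' encodes the up-probability (0 = white, 1 = saturated turquoise);
#' interaction node size encodes activity; edge color encodes consistency
#' (dark green = low, bright blue = high); genes flagged as altered are
#' outlined. Numeric attributes (`prob`, `activity`, `consistency`) are
#' written exactly so exported files are diffable.
#'
#' @param net A `pathway_network`.
#' @param molecule_probs Named numeric vector: up-probability per molecule
#'   id for one sample (`NA` allowed for unmeasured molecules).
#' @param interaction_scores Data frame with columns `interaction_id`,
#'   `activity`, `consistency` for the same sample.
#' @param path Output file path.
#' @param format `"dot"` or `"graphml"`.
#' @param altered Optional character vector of Entrez ids carrying an
#'   alteration (e.g. copy-number change); molecules containing one are
#'   outlined.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, molecule_probs, interaction_scores, path,
                           format = c("dot", "graphml"), altered = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(net, "pathway_network"))
  miss <- setdiff(net$molecules$molecule_id, names(molecule_probs))
  if (length(miss))
    stop("no probability for molecule(s): ", paste(miss, collapse = ", "))
  is_altered <- vapply(net$molecules$entrez_ids,
                       function(eg) any(eg %in% altered), logical(1))
  names(is_altered) <- net$molecules$molecule_id

  size_of <- function(a) if (is.na(a)) 0.3 else 0.3 + 1.2 * a
  num <- function(x) format(x, digits = 15, trim = TRUE, scientific = FALSE)

  mol_rows <- lapply(seq_len(nrow(net$molecules)), function(i) {
    id <- net$molecules$molecule_id[i]
    p <- unname(molecule_probs[id])
    list(id = id, label = net$molecules$label[i],
         prob = p, fill = .node_fill(if (is.na(p)) 0 else p),
         altered = is_altered[[id]])
  })
  ia_rows <- lapply(net$interactions, function(ia) {
    sc <- interaction_scores[
      interaction_scores$interaction_id == ia$interaction_id, , drop = FALSE]
    if (nrow(sc) == 0L)
      stop("no scores for interaction ", ia$interaction_id)
    list(id = ia$interaction_id, activity = sc$activity[1],
         consistency = sc$consistency[1], ia = ia)
  })

  edges <- list()
  for (r in ia_rows) {
    col <- .edge_color(r$consistency)
    for (m in r$ia$promoters)
      edges[[length(edges) + 1L]] <- list(from = m, to = r$id,
                                          role = "promoter", color = col,
                                          consistency = r$consistency)
    for (m in r$ia$inhibitors)
      edges[[length(edges) + 1L]] <- list(from = m, to = r$id,
                                          role = "inhibitor", color = col,
                                          consistency = r$consistency)
    for (m in r$ia$outputs)
      edges[[length(edges) + 1L]] <- list(from = r$id, to = m,
                                          role = "output", color = col,
                                          consistency = r$consistency)
  }

  q <- function(s) paste0("\"", gsub("\"", "\\\\\"", s), "\"")
  if (format == "dot") {
    out <- c(paste0("digraph ", q(net$pathway_id), " {"))
    for (m in mol_rows)
      out <- c(out, paste0("  ", q(m$id),
        " [shape=box, style=filled, fillcolor=", q(m$fill),
        ", label=", q(m$label),
        ", prob=", q(if (is.na(m$prob)) "NA" else num(m$prob)),
        if (m$altered) ", color=\"yellow\", penwidth=3" else "",
        "];"))
    for (r in ia_rows)
      out <- c(out, paste0("  ", q(r$id),
        " [shape=circle, width=", num(size_of(r$activity)),
        ", activity=", q(if (is.na(r$activity)) "NA" else num(r$activity)),
        ", consistency=",
        q(if (is.na(r$consistency)) "NA" else num(r$consistency)),
        "];"))
    for (e in edges)
      out <- c(out, paste0("  ", q(e$from), " -> ", q(e$to),
        " [color=", q(e$color), ", role=", q(e$role),
        if (e$role == "inhibitor") ", arrowhead=tee" else "",
        "];"))
    out <- c(out, "}")
    writeLines(out, path)
  } else {
    esc <- function(s) {
      s <- gsub("&", "&amp;", s, fixed = TRUE)
      s <- gsub("<", "&lt;", s, fixed = TRUE)
      gsub(">", "&gt;", s, fixed = TRUE)
    }
    out <- c('<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="d_kind" for="node" attr.name="kind" attr.type="string"/>',
      '  <key id="d_label" for="node" attr.name="label" attr.type="string"/>',
      '  <key id="d_prob" for="node" attr.name="prob" attr.type="double"/>',
      '  <key id="d_fill" for="node" attr.name="fill" attr.type="string"/>',
      paste0('  <key id="d_alt" for="node" attr.name="altered"',
             ' attr.type="boolean"/>'),
      paste0('  <key id="d_act" for="node" attr.name="activity"',
             ' attr.type="double"/>'),
      '  <key id="d_size" for="node" attr.name="size" attr.type="double"/>',
      paste0('  <key id="d_ncon" for="node" attr.name="consistency"',
             ' attr.type="double"/>'),
      paste0('  <key id="d_con" for="edge" attr.name="edge_consistency"',
             ' attr.type="double"/>'),
      '  <key id="d_color" for="edge" attr.name="color" attr.type="string"/>',
      '  <key id="d_role" for="edge" attr.name="role" attr.type="string"/>',
      paste0('  <graph id="', esc(net$pathway_id), '" edgedefault="directed">'))
    for (m in mol_rows)
      out <- c(out, paste0('    <node id="', esc(m$id), '">',
        '<data key="d_kind">molecule</data>',
        '<data key="d_label">', esc(m$label), '</data>',
        if (!is.na(m$prob))
          paste0('<data key="d_prob">', num(m$prob), '</data>') else "",
        '<data key="d_fill">', m$fill, '</data>',
        '<data key="d_alt">', tolower(as.character(m$altered)), '</data>',
        '</node>'))
    for (r in ia_rows)
      out <- c(out, paste0('    <node id="', esc(r$id), '">',
        '<data key="d_kind">interaction</data>',
        if (!is.na(r$activity))
          paste0('<data key="d_act">', num(r$activity), '</data>') else "",
        '<data key="d_size">', num(size_of(r$activity)), '</data>',
        if (!is.na(r$consistency))
          paste0('<data key="d_ncon">', num(r$consistency), '</data>')
        else "",
        '</node>'))
    for (i in seq_along(edges)) {
      e <- edges[[i]]
      out <- c(out, paste0('    <edge id="e', i, '" source="', esc(e$from),
        '" target="', esc(e$to), '">',
        '<data key="d_role">', e$role, '</data>',
        '<data key="d_color">', e$color, '</data>',
        if (!is.na(e$consistency))
          paste0('<data key="d_con">', num(e$consistency), '</data>')
        else "",
        '</edge>'))
    }
    out <- c(out, "  </graph>", "</graphml>")
    writeLines(out, path)
  }
  invisible(path)
}
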