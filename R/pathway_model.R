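## Pathway network data model ------------------------------------------------
##
## A pathway is a connected set of interactions; each interaction has one or
## more input molecules (promoters and/or inhibitors) and one or more output
## molecules. Molecules carry zero or more Entrez gene ids (zero for
## complexes/small molecules with no direct gene measurement).

#' Construct a pathway network object
#'
#' Builds a validated `pathway_network`: a table of molecules plus a list of
#' interactions over them. Each interaction names its promoters, inhibitors
#' and outputs by `molecule_id`.
#'
#' @param pathway_id Opaque pathway identifier.
#' @param name Display name (conventionally includes a source tag, e.g.
#'   `"(NCI/Nature)"`).
#' @param molecules Data frame with columns `molecule_id`, `entrez_ids`
#'   (list column of character vectors, possibly empty), `label`.
#' @param interactions List of lists, each with elements `interaction_id`,
#'   `promoters`, `inhibitors`, `outputs` (character vectors of molecule ids;
#'   `promoters`/`inhibitors` may be empty but not both, `outputs` must be
#'   nonempty).
#' @param check If `TRUE` (default), structural invariants are checked and
#'   violations raise an error (connectedness only warns; see
#'   [validate_network()]).
#' @return An object of class `pathway_network`.
#' @seealso [parse_pathway_file()], [validate_network()]
#' @export
pathway_network <- function(pathway_id, name, molecules, interactions,
                            check = TRUE) {
  stopifnot(is.character(pathway_id), length(pathway_id) == 1L,
            is.data.frame(molecules), is.list(interactions))
  if (!all(c("molecule_id", "entrez_ids", "label") %in% names(molecules)))
    stop("molecules must have columns molecule_id, entrez_ids, label")
  net <- structure(
    list(pathway_id = pathway_id, name = name,
         molecules = molecules, interactions = interactions),
    class = "pathway_network")
  if (check) {
    report <- validate_network(net)
    fatal <- report[report$severity == "error", , drop = FALSE]
    if (nrow(fatal) > 0L)
      stop("invalid pathway network '", pathway_id, "': ",
           paste(fatal$message, collapse = "; "))
    if (any(report$severity == "warning"))
      warning("pathway network '", pathway_id, "': ",
              paste(report$message[report$severity == "warning"],
                    collapse = "; "))
  }
  net
}

#' @export
print.pathway_network <- function(x, ...) {
  cat("Pathway network '", x$pathway_id, "' (", x$name, ")\n", sep = "")
  cat("  molecules:    ", nrow(x$molecules), "\n", sep = "")
  cat("  interactions: ", length(x$interactions), "\n", sep = "")
  n_genes <- length(unique(unlist(x$molecules$entrez_ids)))
  cat("  distinct Entrez genes: ", n_genes, "\n", sep = "")
  invisible(x)
}

#' Validate a pathway network
#'
#' Checks structural invariants and returns violations as data, not errors:
#' unique molecule ids, no duplicated Entrez ids within a molecule, nonempty
#' inputs/outputs per interaction, no molecule in more than one role or
#' listed twice in a role, no dangling molecule references, and connectedness
#' of the interaction graph (interactions are connected when they share a
#' molecule). Disconnectedness is reported with severity `"warning"` since
#' curated pathway boundaries are often ambiguous; everything else is
#' severity `"error"`.
#'
#' @param net A `pathway_network`.
#' @return Data frame with columns `severity`, `code`, `message`; zero rows
#'   when all invariants hold.
#' @export
validate_network <- function(net) {
  v <- list()
  add <- function(severity, code, message)
    v[[length(v) + 1L]] <<- data.frame(severity = severity, code = code,
                                       message = message)
  mol_ids <- net$molecules$molecule_id
  if (anyDuplicated(mol_ids))
    add("error", "dup_molecule",
        paste0("duplicated molecule_id: ",
               paste(unique(mol_ids[duplicated(mol_ids)]), collapse = ", ")))
  for (i in seq_len(nrow(net$molecules))) {
    eg <- net$molecules$entrez_ids[[i]]
    if (anyDuplicated(eg))
      add("error", "dup_entrez",
          paste0("molecule '", mol_ids[i], "' lists duplicate entrez ids"))
  }
  if (length(net$interactions) == 0L)
    add("error", "no_interactions", "pathway has no interactions")
  for (ia in net$interactions) {
    id <- ia$interaction_id
    if (length(ia$promoters) + length(ia$inhibitors) == 0L)
      add("error", "no_inputs",
          paste0("interaction '", id, "' has no promoters or inhibitors"))
    if (length(ia$outputs) == 0L)
      add("error", "no_outputs",
          paste0("interaction '", id, "' has no outputs"))
    for (role in c("promoters", "inhibitors", "outputs"))
      if (anyDuplicated(ia[[role]]))
        add("error", "dup_role",
            paste0("interaction '", id, "' repeats a molecule in ", role))
    both <- intersect(ia$promoters, ia$inhibitors)
    if (length(both))
      add("error", "promoter_and_inhibitor",
          paste0("interaction '", id, "' lists ",
                 paste(both, collapse = ", "),
                 " as both promoter and inhibitor"))
    dangling <- setdiff(c(ia$promoters, ia$inhibitors, ia$outputs), mol_ids)
    if (length(dangling))
      add("error", "dangling_molecule",
          paste0("interaction '", id, "' references undeclared molecule(s): ",
                 paste(dangling, collapse = ", ")))
  }
  ## connectedness of interactions via shared molecules
  k <- length(net$interactions)
  if (k > 1L) {
    members <- lapply(net$interactions,
                      function(ia) unique(c(ia$promoters, ia$inhibitors,
                                            ia$outputs)))
    comp <- seq_len(k)
    find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k))
      if (length(intersect(members[[i]], members[[j]])))
        comp[find(i)] <- find(j)
    roots <- vapply(seq_len(k), find, integer(1))
    if (length(unique(roots)) > 1L)
      add("warning", "disconnected",
          paste0("interaction graph is disconnected (",
                 length(unique(roots)), " components)"))
  }
  if (length(v) == 0L)
    return(data.frame(severity = character(), code = character(),
                      message = character()))
  do.call(rbind, v)
}

## Pathway interchange format -------------------------------------------------
## Tab-delimited blocks, one pathway per block, blank-line separated:
##   #PATHWAY <TAB> id <TAB> name
##   M <TAB> molecule_id <TAB> entrez1;entrez2;... (or "-") <TAB> label
##   I <TAB> interaction_id <TAB> promoters,csv <TAB> inhibitors,csv or "-"
##       <TAB> outputs,csv

#' Parse a pathway collection from its plain-text interchange format
#'
#' Reads tab-delimited pathway blocks (`#PATHWAY` header, `M` molecule lines,
#' `I` interaction lines, blank line between pathways) and returns validated
#' [pathway_network()] objects. Parsing is loss-free: serializing with
#' [write_pathway_file()] and re-parsing reproduces an equivalent structure.
#'
#' @param path Path to the pathway file (UTF-8, tab-delimited).
#' @return Named list of `pathway_network` objects (names = pathway ids).
#' @export
parse_pathway_file <- function(path) {
  if (!file.exists(path)) stop("pathway file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  nets <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (nrow(cur$molecules) == 0L && length(cur$interactions) == 0L)
      stop("empty pathway block '", cur$id, "'")
    pathway_network(cur$id, cur$name,
                    molecules = cur$molecules,
                    interactions = cur$interactions)
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(trimws(line))) {
      if (!is.null(cur)) { nets[[cur$id]] <- flush(cur); cur <- NULL }
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (f[1] == "#PATHWAY") {
      if (!is.null(cur)) nets[[cur$id]] <- flush(cur)
      if (length(f) < 3L)
        stop("malformed #PATHWAY line at line ", ln)
      cur <- list(id = f[2], name = f[3],
                  molecules = data.frame(molecule_id = character(),
                                         label = character()),
                  interactions = list())
      cur$molecules$entrez_ids <- list()
    } else if (f[1] == "M") {
      if (is.null(cur)) stop("molecule line before #PATHWAY at line ", ln)
      if (length(f) != 4L) stop("malformed molecule line at line ", ln)
      eg <- if (f[3] == "-" || !nzchar(f[3])) character(0)
            else strsplit(f[3], ";", fixed = TRUE)[[1]]
      if (length(eg) && !all(grepl("^[0-9]+$", eg)))
        stop("non-numeric entrez id in molecule line at line ", ln)
      row <- data.frame(molecule_id = f[2], label = f[4])
      row$entrez_ids <- list(eg)
      cur$molecules <- rbind(cur$molecules, row)
    } else if (f[1] == "I") {
      if (is.null(cur)) stop("interaction line before #PATHWAY at line ", ln)
      if (length(f) != 5L) stop("malformed interaction line at line ", ln)
      csv <- function(s) if (s == "-" || !nzchar(s)) character(0)
                         else strsplit(s, ",", fixed = TRUE)[[1]]
      cur$interactions[[length(cur$interactions) + 1L]] <-
        list(interaction_id = f[2], promoters = csv(f[3]),
             inhibitors = csv(f[4]), outputs = csv(f[5]))
    } else {
      stop("malformed line at line ", ln, ": unknown record type '",
           f[1], "'")
    }
  }
  if (!is.null(cur)) nets[[cur$id]] <- flush(cur)
  if (length(nets) == 0L) stop("no pathways found in ", path)
  nets
}

#' Serialize pathway networks to the interchange format
#'
#' @param nets A `pathway_network` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pathway_file <- function(nets, path) {
  if (inherits(nets, "pathway_network")) nets <- list(nets)
  out <- character(0)
  for (net in nets) {
    out <- c(out, paste("#PATHWAY", net$pathway_id, net$name, sep = "\t"))
    for (i in seq_len(nrow(net$molecules))) {
      eg <- net$molecules$entrez_ids[[i]]
      out <- c(out, paste("M", net$molecules$molecule_id[i],
                          if (length(eg)) paste(eg, collapse = ";") else "-",
                          net$molecules$label[i], sep = "\t"))
    }
    for (ia in net$interactions) {
      csv <- function(x) if (length(x)) paste(x, collapse = ",") else "-"
      out <- c(out, paste("I", ia$interaction_id, csv(ia$promoters),
                          csv(ia$inhibitors), csv(ia$outputs), sep = "\t"))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Load a probe-to-gene mapping file
#'
#' Reads a two-column tab-delimited file (`probe_id<TAB>entrez_id`, optional
#' header). Many-to-one and one-to-many mappings are both permitted;
#' duplicated pairs are collapsed; rows whose Entrez field is not a positive
#' integer are skipped with a warning reporting the count.
#'
#' @param path Path to the mapping file.
#' @return Data frame of class `probe_mapping` with columns `probe_id`,
#'   `entrez_id` (both character), one row per distinct pair.
#' @export
load_probe_mapping <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^(probe|probe_id)\t", lines[1],
                             ignore.case = TRUE))
    lines <- lines[-1]
  f <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(f, function(x) length(x) >= 2L && grepl("^[0-9]+$", x[2]),
               logical(1))
  n_bad <- sum(!ok)
  if (n_bad > 0L)
    warning(n_bad, " unparseable mapping row(s) skipped")
  if (!any(ok)) stop("no valid probe-to-gene rows in ", path)
  m <- data.frame(
    probe_id = vapply(f[ok], `[`, character(1), 1L),
    entrez_id = vapply(f[ok], `[`, character(1), 2L))
  m <- unique(m)
  rownames(m) <- NULL
  class(m) <- c("probe_mapping", "data.frame")
  m
}

#' Fraction of pathway molecules with at least one measured probe
#'
#' A molecule counts as measured when at least one of its Entrez genes has at
#' least one probe in `measured_probes` under `mapping`; molecules with no
#' Entrez ids (complexes, small molecules) count as unmeasured.
#'
#' @param net A `pathway_network` or list of them.
#' @param mapping A `probe_mapping`.
#' @param measured_probes Character vector of probe ids present in the
#'   expression data.
#' @return Data frame with columns `pathway_id`, `n_molecules`, `n_measured`,
#'   `coverage` (fraction in \[0, 1\]).
#' @export
coverage_report <- function(net, mapping, measured_probes) {
  if (inherits(net, "pathway_network")) net <- list(net)
  measured_genes <- unique(mapping$entrez_id[
    mapping$probe_id %in% measured_probes])
  rows <- lapply(net, function(n) {
    meas <- vapply(n$molecules$entrez_ids,
                   function(eg) length(eg) > 0L &&
                     any(eg %in% measured_genes),
                   logical(1))
    data.frame(pathway_id = n$pathway_id,
               n_molecules = length(meas),
               n_measured = sum(meas),
               coverage = if (length(meas)) mean(meas) else 0)
  })
  do.call(rbind, rows)
}

## internal: all Entrez ids used by a network
network_genes <- function(net) unique(unlist(net$molecules$entrez_ids))
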