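#' Read a GO ontology from an OBO 1.2 file
#'
#' Parses `[Term]` stanzas: id, name, namespace, obsolete flag, and lineage
#' relations. Both `is_a` and `part_of` (via `relationship:`) are treated as
#' parent links; other relationship types are ignored. Parent links that
#' cross namespaces are dropped, and the resulting relation graph must be
#' acyclic.
#'
#' @param path Path to an OBO file.
#' @return An object of class `go_dag` with `$terms` (data.frame: id, name,
#'   namespace, obsolete) and `$parents` (named list id -> parent ids).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0L) stopf("no [Term] stanzas found in %s", path)
  stanza_ends <- c(term_starts[-1] - 1L, length(lines))
  other_stanzas <- setdiff(grep("^\\[", lines), term_starts)

  ids <- names <- namespaces <- character(length(term_starts))
  obsolete <- logical(length(term_starts))
  parents <- vector("list", length(term_starts))
  for (k in seq_along(term_starts)) {
    block <- lines[term_starts[k]:stanza_ends[k]]
    cut <- which(block %in% lines[other_stanzas])
    if (length(cut)) block <- block[seq_len(min(cut) - 1L)]
    getval <- function(key) {
      hit <- grep(paste0("^", key, ": "), block, value = TRUE)
      if (length(hit) == 0L) return(character(0))
      sub("\\s*!.*$", "", sub(paste0("^", key, ": "), "", hit))
    }
    id <- getval("id")
    if (length(id) == 0L) stopf("[Term] stanza %d has no id", k)
    ids[k] <- trimws(id[[1]])
    nm <- getval("name")
    names[k] <- if (length(nm)) trimws(nm[[1]]) else ids[k]
    ns <- getval("namespace")
    namespaces[k] <- if (length(ns)) trimws(ns[[1]]) else ""
    obsolete[k] <- any(trimws(getval("is_obsolete")) == "true")
    isa <- trimws(getval("is_a"))
    rel <- getval("relationship")
    partof <- trimws(sub("^part_of\\s+", "", rel[grepl("^part_of\\s", rel)]))
    parents[[k]] <- unique(c(isa, partof))
  }
  if (anyDuplicated(ids)) stopf("duplicate term ids in %s", path)
  names(parents) <- ids
  ns_of <- stats::setNames(namespaces, ids)
  parents <- lapply(ids, function(id) {
    pp <- parents[[id]]
    pp[pp %in% ids & ns_of[pp] == ns_of[[id]]]
  })
  names(parents) <- ids
  dag <- structure(list(terms = data.frame(id = ids, name = names,
                                           namespace = namespaces,
                                           obsolete = obsolete,
                                           stringsAsFactors = FALSE),
                        parents = parents),
                   class = "go_dag")
  if (is.null(topo_order(dag))) stopf("ontology relation graph contains a cycle")
  dag
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("GO DAG: %d terms (%d obsolete); namespaces: %s\n",
              nrow(x$terms), sum(x$terms$obsolete),
              paste(sort(unique(x$terms$namespace)), collapse = ", ")))
  invisible(x)
}

# Kahn topological order, parents after children is NOT guaranteed here;
# returns terms ordered so that every parent appears after all its children
# (leaves first). NULL if the relation graph has a cycle.
topo_order <- function(dag) {
  ids <- dag$terms$id
  nchild <- stats::setNames(integer(length(ids)), ids)
  for (id in ids) {
    for (p in dag$parents[[id]]) nchild[[p]] <- nchild[[p]] + 1L
  }
  queue <- ids[nchild[ids] == 0L]
  out <- character(0)
  while (length(queue)) {
    t <- queue[[1]]
    queue <- queue[-1]
    out <- c(out, t)
    for (p in dag$parents[[t]]) {
      nchild[[p]] <- nchild[[p]] - 1L
      if (nchild[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (length(out) != length(ids)) return(NULL)
  out
}

# All ancestors (transitive parents) per term, as a named list.
ancestor_closure <- function(dag) {
  anc <- stats::setNames(vector("list", nrow(dag$terms)), dag$terms$id)
  for (t in rev(topo_order(dag))) {       # roots first
    ps <- dag$parents[[t]]
    anc[[t]] <- unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

# Longest-path depth from a root; descendants are always strictly deeper.
term_depths <- function(dag) {
  depth <- stats::setNames(integer(nrow(dag$terms)), dag$terms$id)
  for (t in rev(topo_order(dag))) {
    ps <- dag$parents[[t]]
    depth[[t]] <- if (length(ps)) max(depth[ps]) + 1L else 0L
  }
  depth
}

#' Read gene -> GO term annotations
#'
#' Accepts a two-column tab-delimited table (`gene<TAB>term`) or GAF 2.x
#' (comment lines start with `!`; column 2 is the gene id, column 5 the GO
#' term id).
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` (default) or `"gaf"`.
#' @return Named list: term id -> character vector of directly annotated
#'   genes.
#' @export
read_gene_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "tsv") {
    bad <- which(lengths(parts) < 2L)
    if (length(bad)) stopf("annotation line %d has fewer than 2 fields", bad[[1]])
    gene <- vapply(parts, `[[`, character(1), 1L)
    term <- vapply(parts, `[[`, character(1), 2L)
  } else {
    bad <- which(lengths(parts) < 5L)
    if (length(bad)) stopf("GAF line %d has fewer than 5 fields", bad[[1]])
    gene <- vapply(parts, `[[`, character(1), 2L)
    term <- vapply(parts, `[[`, character(1), 5L)
  }
  lapply(split(gene, term), unique)
}

#' Propagate annotations up the GO DAG
#'
#' True-path closure: each term's gene set becomes the union of its own
#' direct annotations and those of all its descendants, each gene counted
#' once per term. Annotations to unknown or obsolete terms are skipped with a
#' warning count.
#'
#' @param dag A [read_obo()] DAG.
#' @param direct Named list: term id -> genes (direct annotations).
#' @return Named list over all non-obsolete terms: term id -> sorted gene
#'   vector (possibly empty).
#' @export
propagate_annotations <- function(dag, direct) {
  valid <- dag$terms$id[!dag$terms$obsolete]
  unknown <- setdiff(names(direct), valid)
  if (length(unknown) > 0) {
    warnf("skipped annotations to %d unknown or obsolete term(s)",
          length(unknown))
    direct <- direct[setdiff(names(direct), unknown)]
  }
  genes <- stats::setNames(vector("list", length(valid)), valid)
  for (t in names(direct)) genes[[t]] <- unique(as.character(direct[[t]]))
  ord <- topo_order(dag)               # children before parents
  ord <- ord[ord %in% valid]
  for (t in ord) {
    for (p in intersect(dag$parents[[t]], valid)) {
      genes[[p]] <- unique(c(genes[[p]], genes[[t]]))
    }
  }
  lapply(genes, function(g) sort(as.character(if (is.null(g)) character(0) else g)))
}

#' Configuration for informative GO term filtering
#'
#' @param target_cardinality The preferred propagated annotation count;
#'   within each lineage the term closest to this value is retained.
#'   Default 50 (chosen in line with typical curated gene set sizes).
#' @param min_cardinality,max_cardinality Terms outside `[min, max]` are
#'   removed before the lineage comparison. Defaults 10 and 200.
#' @return An object of class `go_filter_config`.
#' @export
go_filter_config <- function(target_cardinality = 50, min_cardinality = 10,
                             max_cardinality = 200) {
  if (!(min_cardinality < target_cardinality &&
        target_cardinality < max_cardinality)) {
    stopf("need min_cardinality < target_cardinality < max_cardinality")
  }
  structure(list(target = target_cardinality, min = min_cardinality,
                 max = max_cardinality),
            class = "go_filter_config")
}

#' Select non-redundant informative GO terms
#'
#' Per namespace: (1) terms whose propagated cardinality lies outside
#' `[min, max]` are removed; (2) among the survivors, a term is retained only
#' if no surviving ancestor or descendant has a cardinality strictly closer
#' to the target, with ties broken in favor of the deeper (more specific)
#' term -- so no two retained terms are in an ancestor-descendant relation;
#' (3) retained terms with identical membership are merged. Lineage relations
#' follow the full DAG (they may pass through out-of-bounds terms), but only
#' surviving terms act as comparators.
#'
#' @param dag A [read_obo()] DAG.
#' @param term_genes Propagated annotations from [propagate_annotations()].
#' @param namespace One of `"biological_process"`, `"molecular_function"`,
#'   `"cellular_component"` (or any namespace present in the DAG).
#' @param config A [go_filter_config()].
#' @return A [gene_set_collection()] of the retained terms (id = term id,
#'   name = term name).
#' @export
filter_go_terms <- function(dag, term_genes, namespace,
                            config = go_filter_config()) {
  terms <- dag$terms[!dag$terms$obsolete & dag$terms$namespace == namespace, ,
                     drop = FALSE]
  if (nrow(terms) == 0L) {
    warnf("namespace '%s' has no terms; returning empty collection", namespace)
    return(gene_set_collection(list(), id = namespace))
  }
  card <- vapply(terms$id, function(t) {
    g <- term_genes[[t]]
    if (is.null(g)) 0L else length(g)
  }, integer(1))
  surv <- terms$id[card >= config$min & card <= config$max]
  if (length(surv) == 0L) {
    warnf("no terms within the cardinality bounds in namespace '%s'", namespace)
    return(gene_set_collection(list(), id = namespace))
  }
  close_of <- abs(vapply(surv, function(t) length(term_genes[[t]]), integer(1)) -
                    config$target)
  names(close_of) <- surv
  anc <- ancestor_closure(dag)
  depth <- term_depths(dag)

  surv_set <- surv
  # descendants among survivors, via the ancestor closure
  desc <- stats::setNames(vector("list", length(surv)), surv)
  for (t in surv) {
    for (p in intersect(anc[[t]], surv_set)) desc[[p]] <- c(desc[[p]], t)
  }
  retained <- vapply(surv, function(t) {
    related <- c(intersect(anc[[t]], surv_set), desc[[t]])
    if (length(related) == 0L) return(TRUE)
    cl <- close_of[related]
    !any(cl < close_of[[t]] |
           (cl == close_of[[t]] & depth[related] > depth[[t]]))
  }, logical(1))

  kept <- surv[retained]
  name_of <- stats::setNames(terms$name, terms$id)
  sets <- lapply(kept, function(t) gene_set(t, term_genes[[t]],
                                            name = name_of[[t]]))
  merge_identical_sets(gene_set_collection(sets, id = namespace))
}
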