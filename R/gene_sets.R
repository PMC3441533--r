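#' Create a gene set
#'
#' A gene set is a named collection of gene identifiers. Identifiers are
#' opaque strings (e.g. Entrez IDs); no identifier mapping is performed
#' anywhere in the package.
#'
#' @param id Unique (within a collection) non-empty identifier.
#' @param members Character vector of gene identifiers; duplicates are
#'   removed, order preserved.
#' @param name Human-readable name; defaults to `id`.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(id, members, name = id) {
  if (!is_string(id)) stopf("gene set id must be a non-empty string")
  members <- as.character(members)
  members <- members[!is.na(members) & nzchar(members)]
  members <- unique(members)
  if (length(members) == 0L) stopf("gene set '%s' has no members", id)
  structure(list(id = id, name = name, members = members),
            class = "gene_set")
}

#' Create a gene set collection
#'
#' The collection's gene universe is always the union of all member genes:
#' this union is the background for every co-membership and enrichment test.
#'
#' @param sets List of [gene_set()] objects (order preserved).
#' @param id Collection identifier.
#' @return An object of class `gene_set_collection` with fields `id`, `sets`
#'   and `universe` (sorted unique union of all members).
#' @export
gene_set_collection <- function(sets, id = "collection") {
  if (!is.list(sets)) stopf("sets must be a list of gene_set objects")
  ids <- vapply(sets, function(s) s$id, character(1))
  if (anyDuplicated(ids)) {
    stopf("duplicate gene set ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  universe <- sort(unique(unlist(lapply(sets, function(s) s$members),
                                 use.names = FALSE)))
  structure(list(id = id, sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene set collection '%s': %d sets over a universe of %d genes\n",
              x$id, length(x$sets), length(x$universe)))
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

set_ids <- function(collection) {
  vapply(collection$sets, function(s) s$id, character(1))
}

set_members <- function(collection) {
  stats::setNames(lapply(collection$sets, function(s) s$members),
                  set_ids(collection))
}

#' Read a GMT gene set file
#'
#' GMT is the de facto gene set exchange format: one set per line,
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate gene tokens within
#' a line are deduplicated. An empty file yields an empty collection so that
#' pipelines compose.
#'
#' @param path Path to a GMT file.
#' @param id Collection identifier (defaults to the file name).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, id = basename(path)) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) {
      stopf("malformed GMT line %d: fewer than 2 tab-separated fields", i)
    }
    genes <- fields[-(1:2)]
    genes <- unique(genes[nzchar(genes)])
    if (length(genes) == 0L) {
      stopf("malformed GMT line %d ('%s'): no gene members", i, fields[[1]])
    }
    sets[[i]] <- gene_set(fields[[1]], genes, name = fields[[2]])
  }
  gene_set_collection(sets, id = id)
}

#' Write a collection as a GMT file
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(collection$sets, function(s) {
    paste(c(s$id, s$name, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Merge gene sets with identical membership
#'
#' Sets whose memberships are exactly identical are combined into one set
#' whose id is the "+"-joined sorted ids of the merged sets. The universe is
#' unchanged. Applied before network construction so that trivially duplicate
#' sets do not inflate edge counts.
#'
#' @param collection A [gene_set_collection()].
#' @return A [gene_set_collection()] with no two sets of identical membership.
#' @export
merge_identical_sets <- function(collection) {
  keys <- vapply(collection$sets,
                 function(s) paste(sort(s$members), collapse = "\r"),
                 character(1))
  if (!anyDuplicated(keys)) return(collection)
  first_pos <- !duplicated(keys)
  groups <- split(seq_along(keys), keys)
  merged <- lapply(which(first_pos), function(i) {
    idx <- groups[[keys[[i]]]]
    if (length(idx) == 1L) return(collection$sets[[i]])
    ids <- sort(vapply(collection$sets[idx], function(s) s$id, character(1)))
    nms <- vapply(collection$sets[idx], function(s) s$name, character(1))
    gene_set(paste(ids, collapse = "+"), collection$sets[[i]]$members,
             name = paste(nms, collapse = " + "))
  })
  gene_set_collection(merged, id = collection$id)
}
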