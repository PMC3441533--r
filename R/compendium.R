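#' Create an experimentally derived gene list
#'
#' @param id Unique (within a compendium) identifier.
#' @param genes Character vector of gene ids; deduplicated, must be non-empty.
#' @param source Free-text provenance (e.g. a PubMed id).
#' @return An object of class `experiment_gene_list`.
#' @export
experiment_gene_list <- function(id, genes, source = "") {
  if (!is_string(id)) stopf("gene list id must be a non-empty string")
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stopf("gene list '%s' is empty", id)
  structure(list(id = id, source = source, genes = genes),
            class = "experiment_gene_list")
}

#' Create a gene list compendium
#'
#' A labeled collection of experimentally derived gene lists (e.g.
#' differentially expressed gene lists from many microarray studies), the
#' reference experiment set of the co-enrichment algorithm.
#'
#' @param lists List of [experiment_gene_list()] objects.
#' @param id Compendium identifier.
#' @return An object of class `gene_list_compendium`.
#' @export
gene_list_compendium <- function(lists, id = "compendium") {
  ids <- vapply(lists, function(l) l$id, character(1))
  if (anyDuplicated(ids)) {
    stopf("duplicate gene list ids: %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(id = id, lists = lists), class = "gene_list_compendium")
}

#' @export
print.gene_list_compendium <- function(x, ...) {
  cat(sprintf("Gene list compendium '%s': %d lists\n", x$id, length(x$lists)))
  invisible(x)
}

#' @export
length.gene_list_compendium <- function(x) length(x$lists)

#' Read a compendium of gene lists
#'
#' Accepts either a directory (one plain-text file per list, one gene per
#' line, list id = file name without extension) or a single two-column
#' tab-delimited table (`list_id<TAB>gene`).
#'
#' @param path Directory or file path.
#' @param id Compendium identifier.
#' @return A [gene_list_compendium()].
#' @export
read_gene_lists <- function(path, id = basename(path)) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE))
    files <- files[!dir.exists(files)]
    lists <- lapply(files, function(f) {
      genes <- readLines(f, warn = FALSE)
      genes <- genes[nzchar(trimws(genes))]
      experiment_gene_list(sub("\\.[^.]*$", "", basename(f)), trimws(genes),
                           source = basename(f))
    })
    return(gene_list_compendium(lists, id = id))
  }
  if (!file.exists(path)) stopf("file or directory not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          col.names = c("list_id", "gene"))
  groups <- split(df$gene, df$list_id)
  lists <- lapply(names(groups), function(nm) {
    experiment_gene_list(nm, groups[[nm]])
  })
  gene_list_compendium(lists, id = id)
}

#' Write a compendium as one file per list plus a manifest
#'
#' @param compendium A [gene_list_compendium()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_gene_lists <- function(compendium, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  manifest <- data.frame(list_id = character(0), file = character(0),
                         n_genes = integer(0), source = character(0),
                         stringsAsFactors = FALSE)
  for (l in compendium$lists) {
    f <- file.path(dir, paste0(l$id, ".txt"))
    writeLines(l$genes, f)
    manifest <- rbind(manifest,
                      data.frame(list_id = l$id, file = basename(f),
                                 n_genes = length(l$genes), source = l$source,
                                 stringsAsFactors = FALSE))
  }
  mpath <- file.path(dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(mpath)
}
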