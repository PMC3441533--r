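# Chromosome-locus statistics: pathway participation similarity, binned
# contact sums, and same-chromosome edge enrichment.

#' Pathway participation similarity of two gene sets
#'
#' Builds the pathway profile of each gene set (the union of pathways its
#' genes participate in) and returns the Jaccard similarity coefficient of
#' the two profiles. Returns 0 when both profiles are empty.
#'
#' @param genes_a,genes_b Character vectors of gene ids.
#' @param pathway_annot Named list: gene id -> character vector of pathway
#'   ids.
#' @return Jaccard coefficient in `[0, 1]`.
#' @export
jaccard_pathway_similarity <- function(genes_a, genes_b, pathway_annot) {
  profile <- function(g) {
    unique(unlist(pathway_annot[intersect(g, names(pathway_annot))],
                  use.names = FALSE))
  }
  kp_a <- profile(genes_a)
  kp_b <- profile(genes_b)
  u <- length(union(kp_a, kp_b))
  if (u == 0L) return(0)
  length(intersect(kp_a, kp_b)) / u
}

#' Parse a chromosome token from a cytogenetic locus name
#'
#' Strips a leading `chr` and takes the maximal prefix before the first `p`
#' or `q` arm letter (`"chr8p11"` -> `"8"`, `"Xq22"` -> `"X"`).
#'
#' @param x Character vector of locus names.
#' @return Character vector of chromosome tokens.
#' @export
parse_chromosome <- function(x) {
  rest <- sub("^chr", "", x, ignore.case = TRUE)
  tok <- sub("^([^pq]*).*$", "\\1", rest)
  bad <- !nzchar(tok)
  if (any(bad)) {
    stopf("cannot parse a chromosome from node name(s): %s",
          paste(x[bad], collapse = ", "))
  }
  tok
}

#' Same-chromosome edge enrichment of a locus network
#'
#' Tests whether network edges preferentially connect loci on the same
#' chromosome: over all `N(N-1)/2` node pairs, a 2x2 table (edge vs not x
#' same chromosome vs not) is evaluated with a one-sided Fisher's exact test.
#'
#' @param network A [gene_set_network()] whose nodes are loci.
#' @param locus_chrom Optional named character vector node -> chromosome;
#'   when missing, chromosomes are parsed from the node names with
#'   [parse_chromosome()].
#' @return List with `p_value`, `same_chromosome_edges`, `total_edges`,
#'   `same_chromosome_pairs`, `total_pairs`, and the `table`.
#' @export
same_chromosome_edge_enrichment <- function(network, locus_chrom = NULL) {
  nodes <- network$nodes
  if (is.null(locus_chrom)) {
    locus_chrom <- stats::setNames(parse_chromosome(nodes), nodes)
  }
  missing <- setdiff(nodes, names(locus_chrom))
  if (length(missing)) {
    stopf("no chromosome for node(s): %s", paste(missing, collapse = ", "))
  }
  n <- length(nodes)
  total_pairs <- n * (n - 1) / 2
  counts <- table(locus_chrom[nodes])
  same_pairs <- sum(counts * (counts - 1) / 2)
  e <- network$edges
  same_edges <- sum(locus_chrom[e$set_a] == locus_chrom[e$set_b])
  total_edges <- nrow(e)
  tab <- contingency_table(same_edges, total_edges - same_edges,
                           same_pairs - same_edges,
                           total_pairs - total_edges - same_pairs + same_edges)
  list(p_value = fisher_right_tail(tab),
       same_chromosome_edges = same_edges, total_edges = total_edges,
       same_chromosome_pairs = same_pairs, total_pairs = total_pairs,
       table = tab)
}

#' Read a binned contact-count table
#'
#' Three tab-delimited columns: `bin_i`, `bin_j`, `count`. Bin indices refer
#' to fixed-size bins (`bin k` covers `[k * bin_size, (k+1) * bin_size)`) on
#' a genome linearization defined by the caller.
#'
#' @param path Path to the TSV.
#' @param bin_size Bin width in bases.
#' @return A data.frame with attribute `bin_size`.
#' @export
read_contact_table <- function(path, bin_size) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("bin_i", "bin_j", "count"))
  attr(df, "bin_size") <- bin_size
  df
}

#' Sum binned contacts over locus pairs and compare groups
#'
#' For every unordered pair of loci, sums the contact counts over all bin
#' pairs covered by the two loci (the table is treated as symmetric), then
#' groups pairs by (same vs different chromosome) x (in-network vs not) and
#' compares the group contact sums with pairwise Wilcoxon-Mann-Whitney
#' rank-sum tests, BH-corrected.
#'
#' Locus coordinates are 0-based half-open; bins are half-open
#' `[k*bin_size, (k+1)*bin_size)`. Coordinates must live on the same
#' linearization as the contact-table bins: either supply pre-linearized
#' `start`/`end`, or per-chromosome coordinates plus `chrom_offsets` (named
#' base offsets added before binning).
#'
#' @param contacts data.frame with columns `bin_i`, `bin_j`, `count`.
#' @param bin_size Bin width in bases (taken from `attr(contacts,
#'   "bin_size")` when missing).
#' @param loci data.frame with columns `locus`, `chrom`, `start`, `end`.
#' @param pairs_in_network Locus pairs forming the network: a
#'   [gene_set_network()] or a two-column data.frame.
#' @param chrom_offsets Optional named numeric vector of per-chromosome base
#'   offsets.
#' @return List with `pair_sums` (data.frame: locus_a, locus_b,
#'   same_chromosome, in_network, contact_sum), `group_medians`, and
#'   `group_tests` (pairwise rank-sum results with BH q-values).
#' @export
loci_contact_analysis <- function(contacts, loci, pairs_in_network,
                                  bin_size = attr(contacts, "bin_size"),
                                  chrom_offsets = NULL) {
  if (is.null(bin_size)) stopf("bin_size must be supplied")
  key <- paste(pmin(contacts$bin_i, contacts$bin_j),
               pmax(contacts$bin_i, contacts$bin_j), sep = "\r")
  count_of <- tapply(contacts$count, key, sum)

  locus_bins <- lapply(seq_len(nrow(loci)), function(i) {
    s <- loci$start[i]
    e <- loci$end[i]
    if (!is.null(chrom_offsets)) {
      off <- unname(chrom_offsets[as.character(loci$chrom[i])])
      if (length(off) != 1L || is.na(off)) {
        stopf("no offset for chromosome '%s'", loci$chrom[i])
      }
      s <- s + off
      e <- e + off
    }
    if (e <= s) {
      warnf("locus '%s' covers no bin; contact sums will be 0", loci$locus[i])
      return(integer(0))
    }
    seq.int(floor(s / bin_size), floor((e - 1) / bin_size))
  })
  names(locus_bins) <- loci$locus
  chrom_of <- stats::setNames(as.character(loci$chrom), loci$locus)

  net_keys <- if (inherits(pairs_in_network, "gene_set_network")) {
    edge_keys(pairs_in_network)
  } else {
    pair_key(as.character(pairs_in_network[[1]]),
             as.character(pairs_in_network[[2]]))
  }

  n <- nrow(loci)
  if (n < 2L) stopf("need at least two loci")
  px <- pair_indices(n)
  sums <- vapply(seq_along(px$i), function(q) {
    ba <- locus_bins[[px$i[q]]]
    bb <- locus_bins[[px$j[q]]]
    if (length(ba) == 0L || length(bb) == 0L) return(0)
    g <- expand.grid(i = ba, j = bb)
    k <- paste(pmin(g$i, g$j), pmax(g$i, g$j), sep = "\r")
    sum(count_of[k], na.rm = TRUE)
  }, numeric(1))
  la <- loci$locus[px$i]
  lb <- loci$locus[px$j]
  pair_sums <- data.frame(
    locus_a = la, locus_b = lb,
    same_chromosome = chrom_of[la] == chrom_of[lb],
    in_network = pair_key(la, lb) %in% net_keys,
    contact_sum = sums, stringsAsFactors = FALSE)
  rownames(pair_sums) <- NULL

  grp <- interaction(ifelse(pair_sums$same_chromosome, "same_chrom", "diff_chrom"),
                     ifelse(pair_sums$in_network, "in_network", "not_in_network"),
                     sep = ":", drop = TRUE)
  groups <- split(pair_sums$contact_sum, grp)
  medians <- vapply(groups, stats::median, numeric(1))
  gnames <- names(groups)
  tests <- NULL
  if (length(gnames) >= 2L) {
    gp <- pair_indices(length(gnames))
    pvals <- vapply(seq_along(gp$i), function(q) {
      suppressWarnings(stats::wilcox.test(groups[[gp$i[q]]],
                                          groups[[gp$j[q]]])$p.value)
    }, numeric(1))
    pvals[is.na(pvals)] <- 1  # fully tied groups carry no evidence
    tests <- data.frame(group_a = gnames[gp$i], group_b = gnames[gp$j],
                        p_raw = pvals, q_bh = bh_adjust(pvals),
                        stringsAsFactors = FALSE)
  }
  list(pair_sums = pair_sums, group_medians = medians, group_tests = tests)
}
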