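# Hierarchical single-copy marker-set database and quality math.
#
# A marker hierarchy is a rooted taxon graph (root -> domains -> phyla -> ...).
# Each node carries its collocated marker sets (MSS): a list of marker sets
# (MS), each a character vector of marker accessions known to co-locate in
# genomes of that lineage. Presence of a set's genes estimates completeness;
# their copy numbers estimate purity.

.RANK_LEVELS <- c("domain", "phylum", "class", "order", "family", "genus",
                  "species")

.rank_index <- function(rank) {
  i <- match(rank, .RANK_LEVELS)
  if (anyNA(i)) stop("unknown rank(s): ", paste(rank[is.na(i)], collapse = ", "))
  i
}

#' Parse a bracketed marker-set serialization
#'
#' Converts strings like `[[m1,m2],[m3]]` (the dialect used in the marker
#' hierarchy table, a close relative of CheckM's `taxon_marker_sets.tsv`)
#' into a list of character vectors. Quotes and whitespace around accessions
#' are tolerated.
#'
#' @param x a single character string.
#' @return list of character vectors, one per collocated marker set.
#' @export
parse_marker_sets <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  s <- gsub("[\"' ]", "", trimws(x))
  if (!grepl("^\\[.*\\]$", s)) stop("malformed marker set serialization: ", x)
  s <- sub("^\\[", "", sub("\\]$", "", s))        # strip outer brackets
  if (s == "") return(list())
  parts <- strsplit(s, "],[", fixed = TRUE)[[1]]  # split set boundaries
  parts <- gsub("\\[|\\]", "", parts)
  sets <- lapply(parts, function(p) strsplit(p, ",", fixed = TRUE)[[1]])
  if (any(vapply(sets, length, 1L) == 0L) || any(unlist(sets) == ""))
    stop("empty marker set or accession in: ", x)
  sets
}

#' Load a taxon marker-set hierarchy
#'
#' Reads a tab-separated table with columns `rank`, `taxon`, `parent_taxon`,
#' `marker_sets` (serialized as `[[m1,m2],[m3]]`) into a rooted graph.
#' Domains must name `root` as their parent. Taxa listed in `excluded_taxa`
#' are dropped together with their entire subtrees; this mirrors the practice
#' of omitting marker sets that are too small to assess reliably.
#'
#' @param path path to the table (`#`-prefixed header allowed).
#' @param excluded_taxa character vector of taxon names to drop (with
#'   subtrees).
#' @return an object of class `marker_hierarchy`: a list with `nodes`
#'   (named list keyed by taxon; each node has `taxon`, `rank`, `parent`,
#'   `children`, `sets`) and `domains` (character vector of root children).
#' @export
load_marker_hierarchy <- function(path, excluded_taxa = character()) {
  tab <- read_tsv_hash(path, c("rank", "taxon", "parent_taxon", "marker_sets"))
  if (nrow(tab) == 0L) stop("empty marker hierarchy table: ", path)
  if (anyDuplicated(tab$taxon))
    stop("duplicate taxon in hierarchy: ",
         paste(unique(tab$taxon[duplicated(tab$taxon)]), collapse = ", "))
  .rank_index(tab$rank)  # validates rank names

  nodes <- vector("list", nrow(tab))
  names(nodes) <- tab$taxon
  for (i in seq_len(nrow(tab))) {
    sets <- parse_marker_sets(tab$marker_sets[i])
    if (length(sets) == 0L)
      stop("taxon without marker sets: ", tab$taxon[i])
    nodes[[i]] <- list(taxon = tab$taxon[i], rank = tab$rank[i],
                       parent = tab$parent_taxon[i],
                       children = character(), sets = sets)
  }
  # integrity: every non-domain parent must exist; domains hang off "root"
  for (nd in nodes) {
    if (identical(nd$parent, "root")) {
      if (nd$rank != "domain")
        stop("taxon ", nd$taxon, " has parent 'root' but rank ", nd$rank)
    } else if (!nd$parent %in% names(nodes)) {
      stop("orphan taxon (parent missing): ", nd$taxon)
    } else {
      pr <- nodes[[nd$parent]]$rank
      if (.rank_index(nd$rank) <= .rank_index(pr))
        stop("rank does not increase from ", nd$parent, " to ", nd$taxon)
    }
  }
  # drop excluded subtrees
  if (length(excluded_taxa)) {
    drop <- character()
    queue <- intersect(excluded_taxa, names(nodes))
    while (length(queue)) {
      t0 <- queue[[1]]; queue <- queue[-1]
      drop <- c(drop, t0)
      kids <- names(nodes)[vapply(nodes, function(n) identical(n$parent, t0),
                                  logical(1))]
      queue <- c(queue, kids)
    }
    nodes[drop] <- NULL
    if (length(nodes) == 0L) stop("all taxa excluded")
  }
  for (t0 in names(nodes)) {
    p <- nodes[[t0]]$parent
    if (p != "root") nodes[[p]]$children <- c(nodes[[p]]$children, t0)
  }
  domains <- sort(names(nodes)[vapply(nodes, function(n) n$parent == "root",
                                      logical(1))])
  if (length(domains) == 0L) stop("hierarchy has no domain-level nodes")
  structure(list(nodes = nodes, domains = domains),
            class = "marker_hierarchy")
}

#' @export
print.marker_hierarchy <- function(x, ...) {
  cat("marker_hierarchy:", length(x$nodes), "taxa;", length(x$domains),
      "domain(s):", paste(x$domains, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate marker-gene hit counts over a contig group
#'
#' @param contig_ids contigs forming the group; contigs without hits
#'   contribute nothing.
#' @param hit_table data.frame with columns `contig_id`, `orf_id`,
#'   `marker_accession` (one row per hit; see [read_marker_hits()]).
#' @return named integer vector: marker accession -> total hit multiplicity.
#' @export
marker_counts <- function(contig_ids, hit_table) {
  hits <- hit_table$marker_accession[hit_table$contig_id %in% contig_ids]
  if (length(hits) == 0L) return(setNames(integer(0), character(0)))
  tb <- table(hits)
  setNames(as.integer(tb), names(tb))
}

#' Parks-style completeness of a contig group for one taxon node
#'
#' Mean over the node's collocated marker sets of the fraction of each set's
#' genes present at least once in the group.
#'
#' @param counts named count vector from [marker_counts()].
#' @param node a node of a [load_marker_hierarchy()] graph.
#' @return fraction in \[0, 1\].
#' @export
marker_completeness <- function(counts, node) {
  present <- names(counts)[counts >= 1L]
  fr <- vapply(node$sets, function(ms) mean(ms %in% present), numeric(1))
  mean(fr)
}

#' Reciprocal-copy-number purity of a contig group for one taxon node
#'
#' For each marker set, the mean of 1/C_g over the set's genes present in the
#' group (C_g = copy number); the node's purity is the mean over marker sets
#' containing at least one present gene. Absent genes and empty sets are
#' excluded so that purity measures duplication only, not incompleteness.
#' A group without any of the node's markers is vacuously pure (1.0).
#'
#' @inheritParams marker_completeness
#' @return fraction in \[0, 1\].
#' @export
marker_purity <- function(counts, node) {
  per_set <- vapply(node$sets, function(ms) {
    cg <- counts[ms[ms %in% names(counts)]]
    cg <- cg[cg >= 1L]
    if (length(cg) == 0L) return(NA_real_)
    mean(1 / cg)
  }, numeric(1))
  per_set <- per_set[!is.na(per_set)]
  if (length(per_set) == 0L) return(1.0)
  mean(per_set)
}

.node_marker_size <- function(node) length(unique(unlist(node$sets)))

#' Assess a contig group against the marker hierarchy
#'
#' Starts at the domain level and picks the domain with the highest
#' completeness, then traverses that lineage one rank at a time down to
#' `max_rank`. For sub-domain nodes the reported completeness and purity are
#' the arithmetic mean of the node's own value and the chosen domain's value,
#' combining the generality of the domain set with the specificity of the
#' deeper set. A deeper taxon replaces the current best if its (averaged)
#' completeness is equal or higher; ties between siblings go to the
#' lexicographically smallest taxon name so runs are deterministic.
#'
#' @param counts named count vector from [marker_counts()].
#' @param hierarchy a `marker_hierarchy`.
#' @param max_rank deepest rank to evaluate (default `"class"`).
#' @return list of class `quality_estimate`: `taxon`, `rank`, `completeness`,
#'   `purity` (fractions in \[0,1\]), `marker_set_size`.
#' @export
assess_quality <- function(counts, hierarchy, max_rank = "class") {
  stopifnot(inherits(hierarchy, "marker_hierarchy"))
  max_depth <- .rank_index(max_rank)
  nodes <- hierarchy$nodes

  qual <- function(taxon) {
    nd <- nodes[[taxon]]
    c(comp = marker_completeness(counts, nd), pur = marker_purity(counts, nd))
  }
  pick_best <- function(taxa, comp) {
    # argmax completeness, lexicographic tie-break
    ord <- order(-comp, taxa)
    taxa[ord[1]]
  }

  if (length(counts) == 0L || sum(counts) == 0L) {
    # markerless group: report the (lexicographically first) domain with
    # completeness 0 rather than descending through vacuous ties
    d0 <- sort(hierarchy$domains)[1]
    return(structure(list(taxon = d0, rank = "domain", completeness = 0,
                          purity = 1.0,
                          marker_set_size = .node_marker_size(nodes[[d0]])),
                     class = "quality_estimate"))
  }
  dom_q <- vapply(hierarchy$domains, function(t0) qual(t0), numeric(2))
  best_dom <- pick_best(hierarchy$domains, dom_q["comp", ])
  dom_comp <- dom_q["comp", best_dom]
  dom_pur <- dom_q["pur", best_dom]

  best <- list(taxon = best_dom, rank = "domain",
               completeness = unname(dom_comp), purity = unname(dom_pur),
               marker_set_size = .node_marker_size(nodes[[best_dom]]))
  current <- best_dom
  while (.rank_index(nodes[[current]]$rank) < max_depth &&
         length(nodes[[current]]$children) > 0L) {
    kids <- sort(nodes[[current]]$children)
    kq <- vapply(kids, function(t0) qual(t0), numeric(2))
    avg_comp <- setNames((kq["comp", ] + dom_comp) / 2, kids)
    avg_pur <- setNames((kq["pur", ] + dom_pur) / 2, kids)
    sel <- pick_best(kids, avg_comp)
    if (avg_comp[sel] >= best$completeness) {
      best <- list(taxon = sel, rank = nodes[[sel]]$rank,
                   completeness = unname(avg_comp[sel]),
                   purity = unname(avg_pur[sel]),
                   marker_set_size = .node_marker_size(nodes[[sel]]))
    }
    current <- sel
  }
  structure(best, class = "quality_estimate")
}

#' @export
print.quality_estimate <- function(x, ...) {
  cat(sprintf("quality_estimate: %s (%s) completeness %.3f purity %.3f (%d markers)\n",
              x$taxon, x$rank, x$completeness, x$purity, x$marker_set_size))
  invisible(x)
}
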