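#' Preferred order of two dependent maturation events
#'
#' For a dependent pair, the relative abundance of the two maturation
#' intermediates reveals which event tends to happen first: if reads with
#' `event_a` mature and `event_b` immature (TF) outnumber the converse (FT),
#' `event_a` preferentially matures first. Only significant (dependent)
#' pairs are ordered; independent pairs return `"NONE"`.
#'
#' @param table a `pair_table` built from pooled replicates.
#' @param significant logical from the consensus rule.
#' @return `"A_FIRST"`, `"B_FIRST"`, `"TIE"` or `"NONE"`.
#' @export
pairwise_order <- function(table, significant) {
  if (!isTRUE(significant)) return("NONE")
  if (table$TF > table$FT) "A_FIRST"
  else if (table$FT > table$TF) "B_FIRST"
  else "TIE"
}

#' Infer the maturation chronology of one transcript
#'
#' Directed edges (earlier event -> later event) are taken from the ordered
#' significant pairs of the transcript; events are ranked by longest-path
#' depth from the sources of this graph, so an event downstream of several
#' chains receives the latest rank. Events with no significant edge to any
#' other event are reported as processed independently and excluded from
#' the order. Cycles - possible under noise - are collapsed into a single
#' rank group and flagged, never silently broken.
#'
#' @param network a `dependency_network` from [build_network()] (its pooled
#'   counts supply the intermediate abundances).
#' @param transcript_group restrict to the events of this transcript unit;
#'   default uses all events in the network.
#' @return a `chronology` list: `transcript_group`, `ranked_groups` (list of
#'   event-id character vectors, rank 1 = earliest), `ranks` (named integer
#'   vector), `independent` (event ids), `cyclic_warning` (logical).
#' @export
build_chronology <- function(network, transcript_group = NULL) {
  nodes <- network$nodes
  if (!is.null(transcript_group))
    nodes <- nodes[nodes$transcript_group == transcript_group, , drop = FALSE]
  ids <- nodes$event_id
  rep_ <- network$report
  rep_ <- rep_[rep_$event_a %in% ids & rep_$event_b %in% ids, , drop = FALSE]

  from <- character(0); to <- character(0); tied <- logical(0)
  linked <- character(0)
  for (i in seq_len(nrow(rep_))) {
    row <- rep_[i, ]
    if (!isTRUE(row$significant)) next
    linked <- union(linked, c(row$event_a, row$event_b))
    if (row$TF > row$FT) { from <- c(from, row$event_a); to <- c(to, row$event_b) }
    else if (row$FT > row$TF) { from <- c(from, row$event_b); to <- c(to, row$event_a) }
    # TIE: dependent but unordered; both events stay in the ranked set
  }
  independent <- setdiff(ids, linked)
  ranked_ids <- intersect(ids, linked)

  ranks <- integer(0)
  cyclic <- FALSE
  if (length(ranked_ids) > 0L) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = from, to = to, stringsAsFactors = FALSE),
      directed = TRUE,
      vertices = data.frame(name = ranked_ids, stringsAsFactors = FALSE))
    comp <- igraph::components(g, mode = "strong")
    cyclic <- any(comp$csize > 1L)
    # condensation: one vertex per strongly connected component (DAG)
    cond <- igraph::contract(g, comp$membership,
                             vertex.attr.comb = list(name = "concat"))
    cond <- igraph::simplify(cond, remove.loops = TRUE,
                             remove.multiple = TRUE)
    topo <- igraph::topo_sort(cond, mode = "out")
    depth <- integer(igraph::vcount(cond))
    for (v in as.integer(topo)) {
      preds <- as.integer(igraph::neighbors(cond, v, mode = "in"))
      depth[v] <- if (length(preds) == 0L) 1L else max(depth[preds]) + 1L
    }
    members <- igraph::vertex_attr(cond, "name")
    ranks <- integer(length(ranked_ids))
    names(ranks) <- ranked_ids
    for (v in seq_along(members)) ranks[unlist(members[[v]])] <- depth[v]
    # ranks contiguous from 1
    ranks[] <- match(ranks, sort(unique(ranks)))
  }

  ranked_groups <- if (length(ranks) > 0L)
    lapply(split(names(ranks), ranks), unname) else list()
  names(ranked_groups) <- NULL
  structure(list(transcript_group = transcript_group %||% "all",
                 ranked_groups = ranked_groups,
                 ranks = ranks,
                 independent = independent,
                 cyclic_warning = cyclic),
            class = "chronology")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.chronology <- function(x, ...) {
  cat(sprintf("chronology for %s%s\n", x$transcript_group,
              if (x$cyclic_warning) " [cycle collapsed]" else ""))
  for (r in seq_along(x$ranked_groups))
    cat(sprintf("  %d. %s\n", r, paste(x$ranked_groups[[r]], collapse = ", ")))
  if (length(x$independent) > 0)
    cat("  independent:", paste(x$independent, collapse = ", "), "\n")
  invisible(x)
}

#' Fraction of intermediate reads compatible with a chronology
#'
#' Restricts to reads informatively covering every ranked event of the
#' chronology (independent events are ignored), keeps the maturation
#' intermediates (reads neither fully mature nor fully immature over the
#' ranked events), and counts a read compatible when its matured event set
#' equals the union of the first complete ranks possibly plus a subset of
#' the next rank - the prefix rule for grouped ranks.
#'
#' @param matrix an `annotation_matrix` (typically pooled replicates).
#' @param chronology a `chronology` with at least 2 ranked events.
#' @return a `compatibility_result` list: `n_intermediate_reads`,
#'   `n_compatible`, `fraction` (`NA` with `undefined = TRUE` when no
#'   intermediate read exists).
#' @export
compatibility_fraction <- function(matrix, chronology) {
  groups <- chronology$ranked_groups
  ranked <- unlist(groups)
  if (length(ranked) < 2L)
    stop("chronology must rank at least 2 events")
  s <- as.matrix(as.data.frame(matrix)[, ranked, drop = FALSE])
  covered <- rowSums(s == "N") == 0L
  s <- s[covered, , drop = FALSE]
  mat <- s == "M"
  n_mat <- rowSums(mat)
  inter <- n_mat > 0L & n_mat < length(ranked)
  mat <- mat[inter, , drop = FALSE]
  n_inter <- nrow(mat)

  sizes <- lengths(groups)
  idx <- rep(seq_along(groups), sizes)[match(colnames(mat), ranked)]
  compatible <- vapply(seq_len(n_inter), function(i) {
    got <- tapply(mat[i, ], idx, sum)       # matured count per rank group
    full <- got == sizes
    r <- 0L
    while (r < length(sizes) && full[r + 1L]) r <- r + 1L
    extra <- sum(got) - sum(sizes[seq_len(r)])
    extra == 0L || (r < length(sizes) && got[r + 1L] == extra)
  }, logical(1))

  n_comp <- sum(compatible)
  structure(list(n_intermediate_reads = n_inter,
                 n_compatible = n_comp,
                 fraction = if (n_inter > 0L) n_comp / n_inter else NA_real_,
                 undefined = n_inter == 0L),
            class = "compatibility_result")
}

#' @export
print.compatibility_result <- function(x, ...) {
  if (x$undefined)
    cat("compatibility: no intermediate reads (fraction undefined)\n")
  else
    cat(sprintf("compatibility: %d / %d intermediate reads (%.1f%%)\n",
                x$n_compatible, x$n_intermediate_reads, 100 * x$fraction))
  invisible(x)
}

#' Expected fraction of error-free reads over k positions
#'
#' With a per-position error rate e, a read covering k maturation events is
#' expected to be error-free at all of them with probability (1 - e)^k;
#' e.g. 0.96^5 = 81.6% and 0.96^12 = 62% at a 4% nanopore error rate. This
#' bounds the compatibility fraction attainable under sequencing noise even
#' when the underlying molecules follow the chronology perfectly.
#'
#' @param error_rate per-position error probability in \[0, 1\].
#' @param k number of positions (>= 0).
#' @return (1 - error_rate)^k.
#' @export
error_free_fraction <- function(error_rate, k) {
  if (!is.numeric(error_rate) || any(error_rate < 0) || any(error_rate > 1))
    stop("error_rate must lie in [0, 1]")
  if (!is.numeric(k) || any(k < 0) || any(k != round(k)))
    stop("k must be a non-negative integer")
  (1 - error_rate)^k
}

#' Write a chronology (and optional compatibility result) to TSV
#'
#' One row per event with its rank or `"independent"`.
#'
#' @param chronology a `chronology`.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_chronology <- function(chronology, path) {
  df <- data.frame(
    transcript_group = chronology$transcript_group,
    event_id = c(names(chronology$ranks), chronology$independent),
    rank = c(as.character(chronology$ranks),
             rep("independent", length(chronology$independent))),
    cyclic_warning = chronology$cyclic_warning,
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
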