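#' Pairwise contingency table for two maturation events
#'
#' Reads where both events are called mature or immature are cross-tabulated
#' into the four configurations TT (both mature), TF (a mature / b
#' immature), FT (a immature / b mature) and FF (both immature); a `"N"`
#' (not read) on either event excludes the read. TF and FT are the
#' "maturation intermediates": under co-maturation both are observed less
#' often than the independence expectation, i.e. `delta_TF < 0` and
#' `delta_FT < 0`.
#'
#' @param matrix an `annotation_matrix` (single replicate or pooled).
#' @param event_a,event_b event ids (order defines the TF/FT orientation:
#'   TF = `event_a` mature, `event_b` immature).
#' @return a `pair_table` list: counts `TT`,`TF`,`FT`,`FF`, total `n`,
#'   independence expectations `expected_*`, `delta_TF`, `delta_FT`, and the
#'   two-sided Fisher `p_value` (`NA` when `n == 0`).
#' @export
joint_table <- function(matrix, event_a, event_b) {
  a <- matrix[[event_a]]
  b <- matrix[[event_b]]
  if (is.null(a) || is.null(b))
    stop("event not in annotation matrix: ",
         paste(setdiff(c(event_a, event_b), names(matrix)), collapse = ", "))
  ok <- a != "N" & b != "N"
  a <- a[ok] == "M"
  b <- b[ok] == "M"
  counts <- c(TT = sum(a & b), TF = sum(a & !b),
              FT = sum(!a & b), FF = sum(!a & !b))
  pair_table(event_a, event_b, counts)
}

#' @rdname joint_table
#' @param counts named integer vector with elements `TT`, `TF`, `FT`, `FF`.
#' @export
pair_table <- function(event_a, event_b, counts) {
  counts <- as.integer(counts[c("TT", "TF", "FT", "FF")])
  if (any(is.na(counts)) || any(counts < 0))
    stop("counts must be non-negative TT/TF/FT/FF")
  names(counts) <- c("TT", "TF", "FT", "FF")
  n <- sum(counts)
  a_mat <- counts[["TT"]] + counts[["TF"]]   # row margin: a mature
  b_mat <- counts[["TT"]] + counts[["FT"]]   # column margin: b mature
  if (n > 0) {
    expected <- c(TT = a_mat * b_mat,
                  TF = a_mat * (n - b_mat),
                  FT = (n - a_mat) * b_mat,
                  FF = (n - a_mat) * (n - b_mat)) / n
  } else {
    expected <- c(TT = NA_real_, TF = NA_real_, FT = NA_real_, FF = NA_real_)
  }
  structure(list(
    event_a = event_a, event_b = event_b,
    TT = counts[["TT"]], TF = counts[["TF"]],
    FT = counts[["FT"]], FF = counts[["FF"]],
    n = n,
    expected_TT = expected[["TT"]], expected_TF = expected[["TF"]],
    expected_FT = expected[["FT"]], expected_FF = expected[["FF"]],
    delta_TF = counts[["TF"]] - expected[["TF"]],
    delta_FT = counts[["FT"]] - expected[["FT"]],
    p_value = fisher_p(counts)), class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat(sprintf("pair_table %s x %s: TT=%d TF=%d FT=%d FF=%d (n=%d)\n",
              x$event_a, x$event_b, x$TT, x$TF, x$FT, x$FF, x$n))
  cat(sprintf("  delta_TF=%.2f delta_FT=%.2f p=%.3g\n",
              x$delta_TF, x$delta_FT, x$p_value))
  invisible(x)
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' The dependency of two maturation events is tested with the exact
#' conditional test on the TT/TF/FT/FF table. A table with an empty margin
#' carries no information about association and returns 1 by convention; an
#' empty table (`n == 0`) returns `NA` (the pair is skipped upstream).
#'
#' @param table a `pair_table`, a named `c(TT=,TF=,FT=,FF=)` vector, or a
#'   2x2 matrix (rows = event a mature/immature, columns = event b).
#' @return two-sided p-value in \[0, 1\].
#' @export
fisher_p <- function(table) {
  if (inherits(table, "pair_table"))
    table <- c(TT = table$TT, TF = table$TF, FT = table$FT, FF = table$FF)
  if (is.matrix(table)) {
    stopifnot(all(dim(table) == c(2L, 2L)))
    table <- c(TT = table[1, 1], TF = table[1, 2],
               FT = table[2, 1], FF = table[2, 2])
  }
  m <- matrix(as.integer(table[c("TT", "TF", "FT", "FF")]), nrow = 2L,
              byrow = TRUE)
  n <- sum(m)
  if (n == 0L) return(NA_real_)
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L)) return(1)
  stats::fisher.test(m)$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-preserving with the input vector. `NA`
#' entries (untested pairs) stay `NA` and do not enter the family size.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Replicate-consensus significance rule
#'
#' A pair of events is declared dependent when its adjusted p-value is below
#' `alpha_replicate` in at least `min_replicates` of the biological
#' replicates AND below `alpha_pooled` on the pool of all replicates.
#' Replicates where the pair was not observed (`NA`) count as not
#' significant.
#'
#' @param replicate_q adjusted p-values per replicate (NA allowed).
#' @param pooled_q adjusted p-value on the pooled reads.
#' @param alpha_replicate per-replicate threshold (default 0.1).
#' @param alpha_pooled pooled threshold (default 0.005).
#' @param min_replicates how many replicates must pass (default 2).
#' @return logical.
#' @export
consensus_significance <- function(replicate_q, pooled_q,
                                   alpha_replicate = 0.1,
                                   alpha_pooled = 0.005,
                                   min_replicates = 2L) {
  if (any(stats::na.omit(c(replicate_q, pooled_q)) < 0) ||
      any(stats::na.omit(c(replicate_q, pooled_q)) > 1))
    stop("adjusted p-values must lie in [0, 1]")
  n_pass <- sum(replicate_q < alpha_replicate, na.rm = TRUE)
  isTRUE(n_pass >= min_replicates && !is.na(pooled_q) &&
           pooled_q < alpha_pooled)
}

#' Pairwise dependency analysis across replicates
#'
#' Builds, for every pair of events jointly read at least once in the pooled
#' data, the TT/TF/FT/FF contingency tables per replicate and on the pool,
#' tests each with the two-sided Fisher exact test, adjusts p-values with
#' Benjamini-Hochberg within each replicate's detected-pair family (and
#' within the pooled family), and applies the replicate-consensus rule.
#' Significant pairs form the edges of the dependency network. The report
#' also flags, per significant pair, whether both intermediate classes are
#' depleted (`delta_TF < 0` and `delta_FT < 0`, the co-maturation
#' signature).
#'
#' @param matrices list of per-replicate `annotation_matrix` objects.
#' @param catalogue an [event_catalogue()]; defaults to the one attached to
#'   the first matrix.
#' @inheritParams consensus_significance
#' @return a `dependency_network` list with elements `report` (one row per
#'   detected pair: pooled counts, expectations, deltas, per-replicate and
#'   pooled q-values, `significant`, `comaturation_sign`), `edges`
#'   (significant pairs) and `nodes`.
#' @export
build_network <- function(matrices, catalogue = NULL,
                          alpha_replicate = 0.1, alpha_pooled = 0.005,
                          min_replicates = 2L) {
  if (inherits(matrices, "annotation_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1L)
  if (is.null(catalogue)) catalogue <- attr(matrices[[1L]], "catalogue")
  pooled <- pool_matrices(matrices)
  ids <- catalogue$event_id

  # logical state matrices per replicate: TRUE/FALSE mature, NA not read
  as_logical <- function(m) {
    s <- as.matrix(as.data.frame(m)[, ids, drop = FALSE])
    out <- s == "M"
    out[s == "N"] <- NA
    out
  }
  Lrep <- lapply(matrices, as_logical)
  Lpool <- as_logical(pooled)

  pairs <- utils::combn(length(ids), 2L)
  np <- ncol(pairs)
  count4 <- function(a, b) {
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    c(TT = sum(a & b), TF = sum(a & !b), FT = sum(!a & b), FF = sum(!a & !b))
  }

  pooled_counts <- matrix(0L, nrow = np, ncol = 4L,
                          dimnames = list(NULL, c("TT", "TF", "FT", "FF")))
  for (k in seq_len(np)) {
    pooled_counts[k, ] <- count4(Lpool[, pairs[1L, k]], Lpool[, pairs[2L, k]])
  }
  n_pool <- rowSums(pooled_counts)
  detected <- n_pool >= 1L
  det <- which(detected)

  report <- data.frame(
    event_a = ids[pairs[1L, det]],
    event_b = ids[pairs[2L, det]],
    stringsAsFactors = FALSE)

  # per-replicate q-values over each replicate's own detected family
  nrep <- length(matrices)
  qrep <- matrix(NA_real_, nrow = length(det), ncol = nrep)
  for (r in seq_len(nrep)) {
    prep <- rep(NA_real_, length(det))
    for (i in seq_along(det)) {
      k <- det[i]
      cc <- count4(Lrep[[r]][, pairs[1L, k]], Lrep[[r]][, pairs[2L, k]])
      if (sum(cc) >= 1L) prep[i] <- fisher_p(cc)
    }
    qrep[, r] <- bh_adjust(prep)
  }
  colnames(qrep) <- paste0("q_rep", seq_len(nrep))

  tabs <- lapply(det, function(k)
    pair_table(ids[pairs[1L, k]], ids[pairs[2L, k]], pooled_counts[k, ]))
  p_pool <- vapply(tabs, function(t) t$p_value, numeric(1))
  q_pool <- bh_adjust(p_pool)

  report$n <- n_pool[det]
  for (cn in c("TT", "TF", "FT", "FF"))
    report[[cn]] <- pooled_counts[det, cn]
  report$expected_TF <- vapply(tabs, function(t) t$expected_TF, numeric(1))
  report$expected_FT <- vapply(tabs, function(t) t$expected_FT, numeric(1))
  report$delta_TF <- vapply(tabs, function(t) t$delta_TF, numeric(1))
  report$delta_FT <- vapply(tabs, function(t) t$delta_FT, numeric(1))
  report <- cbind(report, as.data.frame(qrep))
  report$p_pooled <- p_pool
  report$q_pooled <- q_pool
  report$significant <- vapply(seq_along(det), function(i)
    consensus_significance(qrep[i, ], q_pool[i], alpha_replicate,
                           alpha_pooled, min_replicates), logical(1))
  report$comaturation_sign <- report$delta_TF < 0 & report$delta_FT < 0

  edges <- report[report$significant,
                  c("event_a", "event_b", "q_pooled", "delta_TF", "delta_FT",
                    "comaturation_sign")]
  rownames(edges) <- NULL
  nodes <- data.frame(event_id = ids, kind = catalogue$kind,
                      transcript_group = catalogue$transcript_group,
                      stringsAsFactors = FALSE)
  structure(list(report = report, edges = edges, nodes = nodes,
                 alpha_replicate = alpha_replicate,
                 alpha_pooled = alpha_pooled,
                 min_replicates = min_replicates,
                 n_replicates = nrep),
            class = "dependency_network")
}

#' @export
print.dependency_network <- function(x, ...) {
  cat(sprintf(paste0(
    "dependency_network: %d detected pairs, %d significant edges\n",
    "  consensus: q < %g in >= %d of %d replicates and pooled q < %g\n"),
    nrow(x$report), nrow(x$edges), x$alpha_replicate, x$min_replicates,
    x$n_replicates, x$alpha_pooled))
  if (nrow(x$edges) > 0) print.data.frame(utils::head(x$edges, 10))
  invisible(x)
}

#' Write the pair report and edge list to TSV
#'
#' The header line documents the orientation convention: TF counts reads
#' with `event_a` mature and `event_b` immature (a/b in catalogue order).
#'
#' @param network a `dependency_network`.
#' @param report_path path for the full pair report TSV.
#' @param edges_path optional path for the significant-edge TSV.
#' @return `report_path`, invisibly.
#' @export
write_network <- function(network, report_path, edges_path = NULL) {
  con <- file(report_path, "w")
  writeLines(paste("# TF = event_a mature & event_b immature;",
                   "FT = event_a immature & event_b mature"), con)
  utils::write.table(network$report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  if (!is.null(edges_path))
    utils::write.table(network$edges, edges_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(report_path)
}
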