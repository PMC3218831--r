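# ---------------------------------------------------------------------------
# Cross-experiment comparison: 2way summaries, 4way matching and quadrant
# classification, similarity matrices, ECDF curves and gene-set matrices.
# ---------------------------------------------------------------------------

#' Comparison summary of a change table
#'
#' Reduces a gene or event test table to the per-item statistics used by the
#' comparison tools: fold (or ratio) change, P-value and significance call.
#'
#' @param test_table A `gene_test_table` or `event_test_table` (or any
#'   data.frame with an id column, a fold/ratio change column, `p` and
#'   `call`).
#' @param name Comparison name.
#' @return data.frame `item_id`, `fold`, `p`, `call`, classed
#'   `comparison_summary`, with cutoffs carried over in attributes.
#' @export
comparison_summary <- function(test_table, name = "comparison") {
  id_col <- intersect(c("gene_id", "event_id", "item_id"),
                      names(test_table))[1L]
  fold_col <- intersect(c("fold_change", "ratio_change", "fold"),
                        names(test_table))[1L]
  if (is.na(id_col) || is.na(fold_col))
    stop("not a change table: need an id and a fold/ratio column")
  out <- data.frame(item_id = test_table[[id_col]],
                    fold = test_table[[fold_col]],
                    p = test_table$p, call = test_table$call,
                    stringsAsFactors = FALSE)
  attr(out, "name") <- name
  attr(out, "cutoffs") <- attr(test_table, "cutoffs")
  class(out) <- c("comparison_summary", "data.frame")
  out
}

#' Match items between two comparisons
#'
#' Joins two comparison summaries on item id, or through a many-to-many id
#' map (e.g. cross-species orthologs supplied as a two-column table). Items
#' missing from either side are omitted.
#'
#' @param summary_x,summary_y `comparison_summary` objects.
#' @param idmap Optional data.frame with columns `id_x`, `id_y`.
#' @return data.frame `id_x`, `id_y`, `fold_x`, `p_x`, `call_x`, `fold_y`,
#'   `p_y`, `call_y`.
#' @export
match_items <- function(summary_x, summary_y, idmap = NULL) {
  if (is.null(idmap)) {
    ids <- intersect(summary_x$item_id, summary_y$item_id)
    idmap <- data.frame(id_x = ids, id_y = ids, stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("id_x", "id_y") %in% names(idmap)))
    idmap <- unique(idmap[c("id_x", "id_y")])
    idmap <- idmap[idmap$id_x %in% summary_x$item_id &
                     idmap$id_y %in% summary_y$item_id, , drop = FALSE]
  }
  ix <- match(idmap$id_x, summary_x$item_id)
  iy <- match(idmap$id_y, summary_y$item_id)
  data.frame(id_x = idmap$id_x, id_y = idmap$id_y,
             fold_x = summary_x$fold[ix], p_x = summary_x$p[ix],
             call_x = summary_x$call[ix],
             fold_y = summary_y$fold[iy], p_y = summary_y$p[iy],
             call_y = summary_y$call[iy],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Quadrant classification of matched items
#'
#' Items significant in both comparisons land in a direction quadrant
#' (`UpUp`, `UpDown`, `DownUp`, `DownDown`, x-direction first); items
#' significant on one side only are `XOnly`/`YOnly`; the rest `Neither`.
#'
#' @param matched Output of [match_items()].
#' @param cutoffs_x,cutoffs_y Optional `c(p = , fold = )` cutoff pairs; when
#'   supplied, calls are recomputed per side with [call_changes()],
#'   otherwise the stored calls are used.
#' @return `matched` with a `quadrant` column appended.
#' @export
fourway_classify <- function(matched, cutoffs_x = NULL, cutoffs_y = NULL) {
  cx <- if (is.null(cutoffs_x)) matched$call_x else
    call_changes(matched$p_x, matched$fold_x, cutoffs_x[["p"]],
                 cutoffs_x[["fold"]])
  cy <- if (is.null(cutoffs_y)) matched$call_y else
    call_changes(matched$p_y, matched$fold_y, cutoffs_y[["p"]],
                 cutoffs_y[["fold"]])
  sx <- cx != "unchanged"; sy <- cy != "unchanged"
  q <- rep("Neither", nrow(matched))
  q[sx & !sy] <- "XOnly"
  q[!sx & sy] <- "YOnly"
  both <- sx & sy
  q[both] <- paste0(ifelse(cx[both] == "up", "Up", "Down"),
                    ifelse(cy[both] == "up", "Up", "Down"))
  matched$quadrant <- q
  matched
}

#' Empirical cumulative distribution curve
#'
#' @param values Numeric values; infinities are placed at the curve
#'   extremes; at least one finite value is required.
#' @param log2_axis Transform the x-axis values with `log2`?
#' @return data.frame `value`, `fraction` (nondecreasing, final value 1),
#'   one row per distinct value.
#' @export
ecdf_curve <- function(values, log2_axis = FALSE) {
  values <- values[!is.na(values)]
  if (!length(values) || !any(is.finite(values)))
    stop("need at least one finite value")
  if (log2_axis) values <- log2(values)
  s <- sort(values)
  u <- unique(s)
  data.frame(value = u,
             fraction = cumsum(tabulate(match(s, u))) / length(s))
}

#' Similarity matrix between two lists of comparisons
#'
#' `fold_corr` is the Pearson correlation of log2 fold changes over items
#' finite in both comparisons; `signed_overlap` counts concordant minus
#' discordant significant calls over items significant in both.
#'
#' @param comparisons_x,comparisons_y Named lists of `comparison_summary`
#'   objects.
#' @param statistic `"fold_corr"` or `"signed_overlap"`.
#' @return Numeric matrix (x comparisons as rows); cells without shared
#'   items (or without variation, for `fold_corr`) are `NA`.
#' @export
similarity_matrix <- function(comparisons_x, comparisons_y = comparisons_x,
                              statistic = c("fold_corr", "signed_overlap")) {
  statistic <- match.arg(statistic)
  m <- matrix(NA_real_, length(comparisons_x), length(comparisons_y),
              dimnames = list(names(comparisons_x), names(comparisons_y)))
  for (i in seq_along(comparisons_x)) {
    for (j in seq_along(comparisons_y)) {
      mt <- match_items(comparisons_x[[i]], comparisons_y[[j]])
      if (!nrow(mt)) next
      if (statistic == "fold_corr") {
        lx <- log2(mt$fold_x); ly <- log2(mt$fold_y)
        keep <- is.finite(lx) & is.finite(ly)
        if (sum(keep) >= 2 && stats::sd(lx[keep]) > 0 &&
            stats::sd(ly[keep]) > 0)
          m[i, j] <- stats::cor(lx[keep], ly[keep])
      } else {
        sig <- mt$call_x != "unchanged" & mt$call_y != "unchanged"
        if (any(sig)) {
          conc <- sum(mt$call_x[sig] == mt$call_y[sig])
          m[i, j] <- conc - (sum(sig) - conc)
        }
      }
    }
  }
  m
}

#' Fold-change matrix for a gene set across comparisons
#'
#' @param gene_ids Character vector (row order preserved).
#' @param comparisons Named list of `comparison_summary` objects.
#' @return Numeric matrix gene x comparison; genes absent from a comparison
#'   are `NA` (flagged missing).
#' @export
set_change_matrix <- function(gene_ids, comparisons) {
  stopifnot(length(gene_ids) >= 1)
  m <- matrix(NA_real_, length(gene_ids), length(comparisons),
              dimnames = list(gene_ids, names(comparisons)))
  for (j in seq_along(comparisons)) {
    idx <- match(gene_ids, comparisons[[j]]$item_id)
    m[, j] <- comparisons[[j]]$fold[idx]
  }
  m
}

#' Read a two-column id map (TSV)
#' @param path TSV with columns `id_x`, `id_y` (header optional; first two
#'   columns used).
#' @return data.frame `id_x`, `id_y`.
#' @export
read_idmap <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, header = FALSE,
                   comment.char = "#")
  if (identical(tolower(df[1, 1]), "id_x")) df <- df[-1, , drop = FALSE]
  setNames(df[1:2], c("id_x", "id_y"))
}

#' Write the 4way table (both sides' statistics plus quadrant)
#' @param fourway Output of [fourway_classify()].
#' @param path Output path.
#' @export
write_fourway <- function(fourway, path) {
  con <- file(path, "w")
  writeLines("# 4way comparison table", con)
  suppressWarnings(write.table(fourway, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)
  invisible(path)
}
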