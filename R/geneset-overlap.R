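# Trim and case-fold gene identifiers; no ortholog or symbol mapping.
normalize_ids <- function(x) tolower(trimws(as.character(x)))

#' Construct a gene set with normalized identifiers
#'
#' @param ids Character vector of gene identifiers.
#' @param label Set label.
#' @param direction Optional vector (aligned to `ids`) of `"up"`/`"down"`
#'   labels.
#' @return A `GeneSet`: character vector of unique normalized identifiers
#'   with attributes `label` and (optionally) `direction`.
#' @export
gene_set <- function(ids, label = "set", direction = NULL) {
  norm <- normalize_ids(ids)
  keep <- !duplicated(norm)
  out <- norm[keep]
  attr(out, "label") <- label
  if (!is.null(direction)) {
    stopifnot(length(direction) == length(ids))
    dir <- direction[keep]
    names(dir) <- out
    attr(out, "direction") <- dir
  }
  class(out) <- c("GeneSet", class(out))
  out
}

#' Filter a differential-expression table by the standard thresholds
#'
#' Keeps rows with `|log2FC| > min_abs_log2fc` AND `lfcSE < max_lfcse` AND
#' `padj < max_padj` (all strict inequalities; the fold-change threshold is
#' applied to the magnitude, so both up- and downregulated genes pass). Rows
#' with missing `padj` are excluded and counted. The sign of `log2FC` labels
#' each passing gene up or down.
#'
#' @param table Data frame with columns `gene_id`, `log2FC`, `lfcSE`,
#'   `padj`.
#' @param thresholds Named list `min_abs_log2fc`, `max_lfcse`, `max_padj`.
#' @param label Label for the resulting set.
#' @return A [gene_set()] with a `direction` attribute and an `n_missing`
#'   attribute counting rows dropped for missing `padj`.
#' @export
filter_degs <- function(table,
                        thresholds = list(min_abs_log2fc = 0.5,
                                          max_lfcse = 0.5,
                                          max_padj = 0.01),
                        label = "DEGs") {
  req <- c("gene_id", "log2FC", "lfcSE", "padj")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  has_p <- !is.na(table$padj)
  pass <- has_p &
    abs(table$log2FC) > thresholds$min_abs_log2fc &
    !is.na(table$lfcSE) & table$lfcSE < thresholds$max_lfcse &
    table$padj < thresholds$max_padj
  pass[is.na(pass)] <- FALSE
  out <- gene_set(table$gene_id[pass], label = label,
                  direction = ifelse(table$log2FC[pass] < 0, "down", "up"))
  attr(out, "n_missing") <- sum(!has_p)
  out
}

#' Venn partition of two gene sets
#'
#' @param a,b [gene_set()] objects (or character vectors, normalized on the
#'   fly).
#' @return An `OverlapReport`: list with `a_only`, `intersection`, `b_only`
#'   counts, `union`, the member identifiers of each partition, and the set
#'   labels.
#' @export
venn_partition <- function(a, b) {
  if (!inherits(a, "GeneSet")) a <- gene_set(a, label = "A")
  if (!inherits(b, "GeneSet")) b <- gene_set(b, label = "B")
  inter <- intersect(as.character(a), as.character(b))
  ao <- setdiff(as.character(a), inter)
  bo <- setdiff(as.character(b), inter)
  structure(list(a_only = length(ao), intersection = length(inter),
                 b_only = length(bo),
                 union = length(ao) + length(inter) + length(bo),
                 members = list(a_only = ao, intersection = inter,
                                b_only = bo),
                 labels = c(attr(a, "label") %||% "A",
                            attr(b, "label") %||% "B")),
            class = "OverlapReport")
}

# Round half up to the nearest integer (published-style percent reporting).
round_half_up <- function(x) floor(x + 0.5)

#' Overlap percentage of one set within another
#'
#' `100 * |A intersect B| / |B|`, reported both raw and rounded half-up to
#' the nearest integer. `numerator` may also be a precomputed intersection
#' count.
#'
#' @param numerator A [gene_set()] (intersected with `denominator`) or a
#'   single count.
#' @param denominator A [gene_set()] (nonempty) or a single count.
#' @return List with `percent` (raw), `percent_int` (round half up),
#'   `count`, `denominator`.
#' @export
overlap_percentage <- function(numerator, denominator) {
  n_den <- if (is.numeric(denominator) && length(denominator) == 1)
    denominator else length(gene_set(denominator))
  if (n_den == 0) stop("empty denominator set")
  n_num <- if (is.numeric(numerator) && length(numerator) == 1) numerator
  else {
    den_ids <- if (is.numeric(denominator)) NULL else
      as.character(gene_set(denominator))
    num_ids <- as.character(gene_set(numerator))
    if (is.null(den_ids)) length(num_ids)
    else length(intersect(num_ids, den_ids))
  }
  pct <- 100 * n_num / n_den
  list(percent = pct, percent_int = round_half_up(pct),
       count = n_num, denominator = n_den)
}

#' Overlap of a curated gene panel with a DEG set
#'
#' Intersects a literature panel (e.g. hair-bundle/stereocilia genes) with a
#' filtered DEG set after removing an explicit exclusion list (such as the
#' knocked-out gene itself, which would trivially overlap), and splits the
#' overlap by regulation direction when the DEG set carries direction
#' labels.
#'
#' @param panel A [gene_set()] (or character vector).
#' @param degs A [gene_set()] with an optional `direction` attribute (as
#'   produced by [filter_degs()]).
#' @param exclude Identifiers removed from the panel before comparison.
#' @return List with `panel_size` (after exclusion), `overlap_count`,
#'   `percent` (raw), `percent_int`, `n_down`, `n_up`, and the overlapping
#'   `members`.
#' @export
panel_overlap <- function(panel, degs, exclude = character(0)) {
  if (!inherits(panel, "GeneSet")) panel <- gene_set(panel, label = "panel")
  if (!inherits(degs, "GeneSet")) degs <- gene_set(degs, label = "DEGs")
  keep <- setdiff(as.character(panel), normalize_ids(exclude))
  inter <- intersect(keep, as.character(degs))
  dir <- attr(degs, "direction")
  n_down <- if (is.null(dir)) NA_integer_ else sum(dir[inter] == "down")
  n_up <- if (is.null(dir)) NA_integer_ else sum(dir[inter] == "up")
  pct <- overlap_percentage(length(inter), length(keep))
  list(panel_size = length(keep), overlap_count = length(inter),
       percent = pct$percent, percent_int = pct$percent_int,
       n_down = n_down, n_up = n_up, members = inter)
}
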