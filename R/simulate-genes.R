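# Draw effect-size columns for one differential-expression table.
# Members pass all three thresholds strictly; non-members fail at least one.
.deg_effects <- function(n, member, down, thr = list(lfc = 0.5, se = 0.5,
                                                     padj = 0.01)) {
  log2fc <- numeric(n); lfcse <- numeric(n); padj <- numeric(n)
  m <- which(member); o <- which(!member)
  if (length(m)) {
    sign <- ifelse(down[m], -1, 1)
    log2fc[m] <- sign * (thr$lfc + 0.05 + stats::rexp(length(m), 1))
    lfcse[m] <- stats::runif(length(m), 0.05, thr$se * 0.95)
    padj[m] <- stats::runif(length(m), 1e-12, thr$padj * 0.95)
  }
  if (length(o)) {
    # choose which threshold(s) each non-member fails
    fail <- sample(3, length(o), replace = TRUE)
    log2fc[o] <- stats::rnorm(length(o), 0, 1.2)
    lfcse[o] <- stats::runif(length(o), 0.05, 1.5)
    padj[o] <- stats::runif(length(o), 0, 1)
    i <- o[fail == 1]
    log2fc[i] <- stats::runif(length(i), -thr$lfc, thr$lfc)
    i <- o[fail == 2]
    lfcse[i] <- stats::runif(length(i), thr$se, 2)
    i <- o[fail == 3]
    padj[i] <- stats::runif(length(i), thr$padj, 1)
  }
  data.frame(log2FC = log2fc, lfcSE = lfcse, padj = padj)
}

#' Simulate differential-expression tables with known set structure
#'
#' Allocates gene identifiers to the named sets of the specification,
#' honouring the requested pairwise overlaps (overlap genes are assigned to
#' one pair at a time, so no triple intersections arise), then emits one
#' full-universe differential-expression table per contrast set. A gene's
#' row passes the standard thresholds (|log2FC| > 0.5, lfcSE < 0.5,
#' padj < 0.01, all strict) exactly when the gene belongs to that contrast's
#' ground-truth set; direction (sign of log2FC) honours any `n_down_*`
#' overlap constraints.
#'
#' @param spec A [gene_universe_spec()].
#' @param seed Integer seed.
#'
#' @return List with `tables` (named list of data frames `gene_id`,
#'   `log2FC`, `lfcSE`, `padj`), `sets` (named list of ground-truth
#'   identifier vectors), and `directions` (named list of logical
#'   "downregulated" vectors aligned to each table set).
#' @export
simulate_gene_tables <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "GeneUniverseSpec"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  universe <- sprintf("gene%05d", seq_len(spec$universe_size))
  pool <- sample(universe)          # randomized allocation order
  take <- function(n) {
    if (n == 0) return(character(0))
    if (n > length(pool)) stop("universe too small for the requested sets")
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }

  nm <- names(spec$set_sizes)
  sets <- stats::setNames(vector("list", length(nm)), nm)
  for (s in nm) sets[[s]] <- character(0)
  shared <- list()
  for (i in seq_along(spec$overlaps)) {
    ov <- spec$overlaps[[i]]
    g <- take(ov$n)
    shared[[i]] <- g
    sets[[ov$a]] <- c(sets[[ov$a]], g)
    sets[[ov$b]] <- c(sets[[ov$b]], g)
  }
  for (s in nm) {
    extra <- spec$set_sizes[[s]] - length(sets[[s]])
    if (extra < 0) stop("infeasible overlap specification for set ", s)
    sets[[s]] <- c(sets[[s]], take(extra))
  }

  # Direction (downregulated?) per set member, honouring overlap constraints.
  directions <- list()
  for (s in intersect(spec$tables, nm)) {
    g <- sets[[s]]
    down <- stats::runif(length(g)) < spec$down_frac
    names(down) <- g
    for (i in seq_along(spec$overlaps)) {
      ov <- spec$overlaps[[i]]
      key <- if (identical(ov$a, s)) "n_down_a"
             else if (identical(ov$b, s)) "n_down_b" else NA
      if (!is.na(key) && !is.null(ov[[key]])) {
        sg <- shared[[i]]
        stopifnot(ov[[key]] <= length(sg))
        down[sg] <- seq_along(sg) <= ov[[key]]
      }
    }
    directions[[s]] <- down
  }

  tables <- list()
  for (s in intersect(spec$tables, nm)) {
    member <- universe %in% sets[[s]]
    down <- rep(FALSE, spec$universe_size)
    down[match(names(directions[[s]]), universe)] <- directions[[s]]
    eff <- .deg_effects(spec$universe_size, member, down)
    tables[[s]] <- cbind(data.frame(gene_id = universe), eff)
  }

  list(tables = tables, sets = sets, directions = directions)
}
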