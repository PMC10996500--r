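#' Identify explicit and implicit founders, completing the pedigree
#'
#' Explicit founders are individuals with no parents in the pedigree
#' (in-degree 0). An individual with exactly one recorded parent implies
#' a missing co-parent: for each such individual a new implicit-founder
#' node is synthesized and wired as its second parent, so that after
#' completion every non-founder has exactly two parents. Implicit
#' founders receive ids with the reserved prefix `"IF_"`, letting
#' downstream genome export exclude them by id class. Their sex is the
#' complement of the known parent's sex (unknown when that is unknown).
#'
#' @param ped a [ped_dag].
#' @param profiles optional profile table; when given, rows for the new
#'   implicit founders are appended (generation ticks of implicit
#'   founders are left `NA` until [assign_generations()] is re-run).
#' @return list of class `founder_partition`:
#'   `explicit` (ids), `implicit` (ids of synthesized co-parents),
#'   `ped` (the completed pedigree), `profiles` (augmented, or `NULL`).
#' @export
identify_founders <- function(ped, profiles = NULL) {
  validate_ped(ped)
  pl <- parents_list(ped)
  explicit <- founder_ids(ped)
  single <- names(pl)[lengths(pl) == 1L]
  implicit <- character(0)
  newpar <- character(0); newch <- character(0); newsex <- character(0)
  if (length(single) > 0) {
    implicit <- paste0("IF_", seq_along(single))
    # avoid clashing with pre-existing ids carrying the reserved prefix
    while (any(implicit %in% ped$ids)) implicit <- paste0("IF_", implicit)
    newpar <- implicit
    newch <- single
    if (!is.null(profiles)) {
      sex <- stats::setNames(as.character(profiles$sex), profiles$id)
      known <- vapply(single, function(ch) {
        s <- sex[pl[[ch]][1]]
        if (is.na(s)) "unknown" else s
      }, character(1))
      newsex <- sex_complement(known)
    } else {
      newsex <- rep("unknown", length(single))
    }
  }
  completed <- ped_dag(parent = c(ped$edges[, 1], newpar),
                       child = c(ped$edges[, 2], newch),
                       ids = ped$ids)
  prof <- profiles
  if (!is.null(prof) && length(implicit) > 0) {
    prof <- rbind(prof[, c("id", "sex", "gen")],
                  profile_table(implicit, newsex))
  }
  structure(list(explicit = explicit, implicit = implicit,
                 ped = completed, profiles = prof),
            class = "founder_partition")
}

#' @export
print.founder_partition <- function(x, ...) {
  cat(sprintf("<founder_partition> %d explicit, %d implicit founders\n",
              length(x$explicit), length(x$implicit)))
  invisible(x)
}

#' Assign generation ticks to every individual
#'
#' Root founders (founders of minimal tick in their connected component)
#' receive tick 1 and every child's tick strictly exceeds all of its
#' parents' ticks. Ticks are computed in topological order as
#' `tick(child) = 1 + max(tick(parents))`; founders with children are
#' then pulled down to `min(tick(children)) - 1` (a founder marrying
#' into a later generation sits one tick above its children, not at the
#' root), and ticks are normalized per connected component so the
#' minimum is 1. Under consanguinity (several paths from an ancestor)
#' the max-over-parents rule guarantees the child's generation number
#' comes after every parent's.
#'
#' @param ped a non-empty [ped_dag].
#' @param profiles optional profile table whose sexes are carried over;
#'   its `gen` column is replaced.
#' @return a profile table (id, sex, gen) covering every individual.
#' @export
assign_generations <- function(ped, profiles = NULL) {
  validate_ped(ped)
  if (length(ped$ids) == 0) stop("empty pedigree")
  g <- as_ped_igraph(ped)
  ord <- ped$ids[igraph::topo_sort(g, mode = "out")]
  pl <- parents_list(ped)
  tick <- stats::setNames(rep(1L, length(ped$ids)), ped$ids)
  for (id in ord) {
    p <- pl[[id]]
    if (length(p) > 0) tick[id] <- 1L + max(tick[p])
  }
  # founders with children: one tick above their earliest child
  cl <- if (nrow(ped$edges) > 0) split(ped$edges[, 2], ped$edges[, 1]) else list()
  for (f in founder_ids(ped)) {
    ch <- cl[[f]]
    if (length(ch) > 0) tick[f] <- min(tick[ch]) - 1L
  }
  # normalize per connected component (undirected components)
  comp <- igraph::components(g, mode = "weak")$membership
  names(comp) <- ped$ids
  for (k in unique(comp)) {
    m <- names(comp)[comp == k]
    tick[m] <- tick[m] - min(tick[m]) + 1L
  }
  sex <- rep("unknown", length(ped$ids))
  if (!is.null(profiles)) {
    idx <- match(ped$ids, profiles$id)
    sex[!is.na(idx)] <- as.character(profiles$sex)[idx[!is.na(idx)]]
  }
  profile_table(id = ped$ids, sex = sex, gen = unname(tick[ped$ids]))
}
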