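#' Construct a pedigree DAG
#'
#' A pedigree is represented as a directed acyclic graph: nodes are
#' individuals, and a directed edge runs from a parent to a child
#' (genetic transmission). Individuals may appear as isolated nodes
#' (no edges) via the `ids` argument.
#'
#' @param parent character vector of parent ids (one per edge).
#' @param child character vector of child ids, same length as `parent`.
#' @param ids optional character vector of additional node ids; the node
#'   set is the union of `parent`, `child` and `ids`.
#' @param validate check DAG invariants (acyclicity, in-degree at most 2).
#'
#' @return An object of class `ped_dag` with elements `ids` (character)
#'   and `edges` (two-column character matrix, columns `parent`, `child`).
#' @export
#' @examples
#' trio <- ped_dag(parent = c("A", "B"), child = c("C", "C"))
#' trio
ped_dag <- function(parent = character(), child = character(),
                    ids = character(), validate = TRUE) {
  parent <- as.character(parent)
  child <- as.character(child)
  if (length(parent) != length(child)) {
    stop("`parent` and `child` must have the same length")
  }
  edges <- cbind(parent = parent, child = child)
  ids <- unique(c(parent, child, as.character(ids)))
  ped <- structure(list(ids = ids, edges = edges), class = "ped_dag")
  if (validate) validate_ped(ped)
  ped
}

#' @export
print.ped_dag <- function(x, ...) {
  cat(sprintf("<ped_dag> %d individuals, %d parent-child edges\n",
              length(x$ids), nrow(x$edges)))
  fp <- founder_ids(x)
  cat(sprintf("  founders (in-degree 0): %d\n", length(fp)))
  invisible(x)
}

#' Validate pedigree invariants
#'
#' Checks that a `ped_dag` is acyclic, has no duplicated edges or ids,
#' that every individual has at most two parents, and (when a profile
#' table is supplied) that co-parents of known sex are complementary
#' (one XX, one XY).
#'
#' @param ped a `ped_dag`.
#' @param profiles optional profile table (see [assign_generations()]);
#'   when given, parental sex complementarity is checked.
#' @return `ped`, invisibly. Errors describe the first violation found.
#' @export
validate_ped <- function(ped, profiles = NULL) {
  stopifnot(inherits(ped, "ped_dag"))
  if (anyDuplicated(ped$ids)) stop("duplicate individual ids in pedigree")
  if (nrow(ped$edges) > 0) {
    if (any(ped$edges[, 1] == ped$edges[, 2])) {
      stop("self-loop: an individual cannot be its own parent")
    }
    key <- paste(ped$edges[, 1], ped$edges[, 2], sep = "\r")
    if (anyDuplicated(key)) stop("duplicated parent-child edge")
    indeg <- table(ped$edges[, 2])
    if (any(indeg > 2)) {
      bad <- names(indeg)[which(indeg > 2)[1]]
      stop(sprintf("individual '%s' has more than two parents", bad))
    }
    g <- as_ped_igraph(ped)
    if (!igraph::is_dag(g)) {
      cyc <- find_one_cycle(ped)
      stop(sprintf("pedigree contains a cycle: %s",
                   paste(cyc, collapse = " -> ")))
    }
  }
  if (!is.null(profiles)) {
    check_parent_sexes(ped, profiles)
  }
  invisible(ped)
}

# locate one directed cycle for a readable error message
find_one_cycle <- function(ped) {
  g <- as_ped_igraph(ped)
  for (e in seq_len(nrow(ped$edges))) {
    from <- ped$edges[e, 2]
    to <- ped$edges[e, 1]
    sp <- suppressWarnings(
      igraph::shortest_paths(g, from = from, to = to, mode = "out")$vpath[[1]]
    )
    if (length(sp) > 0) {
      return(c(names(sp), from))
    }
  }
  "<cycle not localized>"
}

check_parent_sexes <- function(ped, profiles) {
  pl <- parents_list(ped)
  sex <- stats::setNames(as.character(profiles$sex), profiles$id)
  for (ch in names(pl)) {
    p <- pl[[ch]]
    if (length(p) == 2) {
      s <- sex[p]
      s <- s[!is.na(s) & s != "unknown"]
      if (length(s) == 2 && s[1] == s[2]) {
        stop(sprintf(
          "parents of '%s' (%s, %s) have the same sex", ch, p[1], p[2]))
      }
    }
  }
  invisible(TRUE)
}

#' @rdname ped_dag
#' @param x object to coerce/test.
#' @export
is_ped_dag <- function(x) inherits(x, "ped_dag")

as_ped_igraph <- function(ped) {
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(ped$ids), name = ped$ids)
  if (nrow(ped$edges) > 0) {
    g <- igraph::add_edges(g, rbind(match(ped$edges[, 1], ped$ids),
                                    match(ped$edges[, 2], ped$ids)))
  }
  g
}

#' List parents of every child
#'
#' @param ped a `ped_dag`.
#' @return named list: for every individual with at least one parent, the
#'   character vector of its parent ids.
#' @export
parents_list <- function(ped) {
  if (nrow(ped$edges) == 0) return(stats::setNames(list(), character()))
  split(ped$edges[, 1], ped$edges[, 2])
}

#' Ids with no parents (explicit founders)
#' @param ped a `ped_dag`.
#' @return character vector of ids with in-degree zero.
#' @export
founder_ids <- function(ped) {
  setdiff(ped$ids, unique(ped$edges[, 2]))
}

# directed shortest-path distance matrix (rows = from/ancestor,
# cols = to/descendant); Inf where unreachable
ped_distances <- function(ped, from = ped$ids, to = ped$ids) {
  g <- as_ped_igraph(ped)
  d <- igraph::distances(g, v = from, to = to, mode = "out")
  dimnames(d) <- list(from, to)
  d
}

#' Build a profile table
#'
#' One row per individual: id, sex (`"XX"`, `"XY"` or `"unknown"`), and
#' generation tick (positive integer, or `NA` when unassigned).
#'
#' @param id character vector of ids.
#' @param sex character vector, recycled, values in XX/XY/unknown.
#' @param gen integer vector of generation ticks, recycled; NA allowed.
#' @return a `data.frame` with columns `id`, `sex`, `gen`.
#' @export
profile_table <- function(id, sex = "unknown", gen = NA_integer_) {
  sex <- rep_len(as.character(sex), length(id))
  bad <- !sex %in% c("XX", "XY", "unknown")
  if (any(bad)) stop("sex must be one of 'XX', 'XY', 'unknown'")
  gen <- rep_len(as.integer(gen), length(id))
  if (any(!is.na(gen) & gen < 1)) stop("generation ticks must be >= 1")
  data.frame(id = as.character(id), sex = sex, gen = gen,
             stringsAsFactors = FALSE)
}

sex_complement <- function(sex) {
  ifelse(sex == "XX", "XY", ifelse(sex == "XY", "XX", "unknown"))
}
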