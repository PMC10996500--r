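#' Simulate misattributed-paternity (MAP) events on a pedigree
#'
#' Iterates over every eligible descendant (an individual with two
#' recorded parents of whom one is XY) and, independently with
#' probability `p_map`, replaces its father edge. With probability
#' `p_within` the replacement is drawn uniformly from existing fathers
#' at the same generation tick as the replaced father — excluding the
#' replaced father himself and any candidate whose adoption would
#' create a cycle (a descendant of the child). When the within-family
#' branch is selected but no eligible candidate exists, a new XY
#' individual at the father's tick is created instead. Mother edges are
#' never modified.
#'
#' @param ped a [ped_dag].
#' @param profiles profile table assigning sex and tick to every
#'   individual of `ped`.
#' @param p_map per-descendant probability of a MAP event, in [0, 1].
#' @param p_within probability a replacement father is sought within
#'   the existing same-tick fathers (vs created new), in [0, 1].
#' @param seed optional integer seed.
#' @return list of class `map_sim`: `ped` (rewired pedigree),
#'   `profiles` (augmented with any new fathers), `events` (data.frame
#'   with columns `child`, `old_father`, `new_father`, `origin`
#'   (`"within"` or `"new"`)).
#' @export
simulate_map <- function(ped, profiles, p_map, p_within, seed = NULL) {
  stopifnot(p_map >= 0, p_map <= 1, p_within >= 0, p_within <= 1)
  validate_ped(ped)
  if (any(!ped$ids %in% profiles$id)) {
    stop("profiles missing for some pedigree members")
  }
  if (!is.null(seed)) set.seed(seed)
  sex <- stats::setNames(as.character(profiles$sex), profiles$id)
  tick <- stats::setNames(profiles$gen, profiles$id)
  pl <- parents_list(ped)
  eligible <- names(pl)[vapply(pl, function(p)
    length(p) == 2 && sum(sex[p] == "XY", na.rm = TRUE) == 1, logical(1))]
  hit <- eligible[stats::runif(length(eligible)) < p_map]

  edges <- ped$edges
  prof <- profiles
  nnew <- 0L
  ev <- list()
  for (ch in hit) {
    p <- pl[[ch]]
    old_father <- p[sex[p] == "XY"][1]
    within <- stats::runif(1) < p_within
    new_father <- NA_character_
    origin <- "new"
    if (within) {
      # pool: current fathers (XY individuals with offspring) at the
      # same tick as the replaced father
      fathers <- unique(edges[, 1])
      fathers <- fathers[sex[fathers] == "XY" & !is.na(sex[fathers])]
      cand <- fathers[tick[fathers] == tick[old_father]]
      cand <- setdiff(cand, c(old_father, ch))
      if (length(cand) > 0) {
        # cycle safety: candidate must not be a descendant of the child
        cur <- ped_dag(edges[, 1], edges[, 2], ids = prof$id,
                       validate = FALSE)
        desc <- ped_distances(cur, from = ch, to = cand)
        cand <- cand[!is.finite(desc[1, ])]
      }
      if (length(cand) > 0) {
        new_father <- if (length(cand) == 1) cand else sample(cand, 1)
        origin <- "within"
      }
    }
    if (is.na(new_father)) {
      nnew <- nnew + 1L
      new_father <- paste0("MAPF_", nnew)
      while (new_father %in% prof$id) {
        nnew <- nnew + 1L
        new_father <- paste0("MAPF_", nnew)
      }
      prof <- rbind(prof[, c("id", "sex", "gen")],
                    profile_table(new_father, "XY", tick[old_father]))
      sex[new_father] <- "XY"
      tick[new_father] <- tick[old_father]
    }
    drop <- edges[, 1] == old_father & edges[, 2] == ch
    edges <- rbind(edges[!drop, , drop = FALSE],
                   c(new_father, ch))
    ev[[length(ev) + 1]] <- data.frame(
      child = ch, old_father = old_father, new_father = new_father,
      origin = origin, stringsAsFactors = FALSE)
  }
  out_ped <- ped_dag(edges[, 1], edges[, 2], ids = prof$id)
  events <- if (length(ev) > 0) do.call(rbind, ev) else
    data.frame(child = character(), old_father = character(),
               new_father = character(), origin = character(),
               stringsAsFactors = FALSE)
  structure(list(ped = out_ped, profiles = prof, events = events),
            class = "map_sim")
}

#' @export
print.map_sim <- function(x, ...) {
  cat(sprintf("<map_sim> %d MAP event(s), %d within-family, %d new fathers\n",
              nrow(x$events), sum(x$events$origin == "within"),
              sum(x$events$origin == "new")))
  invisible(x)
}
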