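#' Common ancestors of a pair with their distances
#'
#' All individuals ancestral to (or equal to) both `a` and `b`, each
#' with the shortest directed path lengths down to `a` and to `b`.
#'
#' @param ped a [ped_dag].
#' @param a,b distinct individual ids.
#' @return data.frame with columns `ancestor`, `dist_a`, `dist_b`;
#'   zero rows when the pair shares no ancestor.
#' @export
common_ancestors <- function(ped, a, b) {
  if (!all(c(a, b) %in% ped$ids)) stop("unknown individual id")
  if (a == b) stop("a and b must differ")
  g <- as_ped_igraph(ped)
  d <- igraph::distances(g, v = c(a, b), to = ped$ids, mode = "in")
  ok <- is.finite(d[1, ]) & is.finite(d[2, ])
  data.frame(ancestor = ped$ids[ok],
             dist_a = unname(d[1, ok]), dist_b = unname(d[2, ok]),
             stringsAsFactors = FALSE)
}

pair_metrics <- function(ped, a, b) {
  ca <- common_ancestors(ped, a, b)
  if (nrow(ca) == 0) {
    return(list(md = NA_integer_, gdd = NA_integer_, grt = NA_character_,
                n_mrca = 0L))
  }
  direct <- any(ca$ancestor %in% c(a, b))
  if (direct) {
    d <- ca[ca$ancestor %in% c(a, b), ]
    md <- as.integer(max(d$dist_a[1], d$dist_b[1]))
    return(list(md = md, gdd = md, grt = "direct", n_mrca = NA_integer_))
  }
  s <- ca$dist_a + ca$dist_b
  md <- min(s)
  atmin <- which(s == md)
  gdd <- min(abs(ca$dist_a[atmin] - ca$dist_b[atmin]))
  grt <- if (length(atmin) >= 2) "full" else "half"
  list(md = as.integer(md), gdd = as.integer(gdd), grt = grt,
       n_mrca = length(atmin))
}

#' Meiotic distance between two individuals
#'
#' For direct (ancestor-descendant) pairs, the length of the shortest
#' directed path; otherwise the minimum over common ancestors of the
#' summed distances to the pair; `NA` when no common ancestor exists.
#'
#' @inheritParams common_ancestors
#' @return non-negative integer or `NA`.
#' @export
meiotic_distance <- function(ped, a, b) pair_metrics(ped, a, b)$md

#' Generation depth difference between two individuals
#'
#' For direct pairs, the shortest directed path length; otherwise the
#' absolute difference of the two depths at the most recent common
#' ancestor used for the meiotic distance; `NA` when unrelated.
#'
#' @inheritParams common_ancestors
#' @return non-negative integer or `NA`.
#' @export
generation_depth_difference <- function(ped, a, b) pair_metrics(ped, a, b)$gdd

#' Genetic relationship type of a pair
#'
#' `"direct"` when one individual is an ancestor of the other;
#' otherwise the number of distinct most recent common ancestors at
#' minimal meiotic distance determines the type: one shared ancestor
#' gives `"half"`, two (a couple) give `"full"`. `NA` when the pair
#' shares no ancestor.
#'
#' @inheritParams common_ancestors
#' @return one of `"direct"`, `"full"`, `"half"`, `NA`.
#' @export
genetic_relationship_type <- function(ped, a, b) pair_metrics(ped, a, b)$grt

ordinal <- function(k) {
  suff <- ifelse(k %% 100 %in% 11:13, "th",
                 c("st", "nd", "rd", rep("th", 7))[pmin((k - 1) %% 10 + 1, 10)])
  paste0(k, suff)
}

#' Name a relationship from its metrics
#'
#' Deterministic lookup from (meiotic distance, generation depth
#' difference, relationship type) to the standard kinship nomenclature:
#' parent-child / grandparent / great-grandparent chains for direct
#' pairs; sibling, avuncular (grand-avuncular, ...), and Nth cousin
#' K-times-removed for collateral pairs, with a `half-` prefix for half
#' relatives. Unmatched metric combinations fall back to a generic
#' `"full relative, MD=m"` style label.
#'
#' @param md,gdd,grt equal-length vectors of metrics from the same
#'   pair(s); `grt` in direct/full/half/NA.
#' @return character vector of labels (`"unrelated"` for `NA` type).
#' @export
#' @examples
#' classify_relationship(3, 1, "full")  # avuncular
#' classify_relationship(2, 0, "half")  # half-sibling
classify_relationship <- function(md, gdd, grt) {
  n <- max(length(md), length(gdd), length(grt))
  md <- rep_len(as.integer(md), n)
  gdd <- rep_len(as.integer(gdd), n)
  grt <- rep_len(as.character(grt), n)
  if (any(grt == "direct" & md != gdd, na.rm = TRUE)) {
    stop("inconsistent metrics: direct relationships require md == gdd")
  }
  out <- rep("unrelated", n)
  dir <- which(!is.na(grt) & grt == "direct")
  if (length(dir) > 0) {
    m <- md[dir]
    out[dir] <- ifelse(m == 1, "parent-child",
                ifelse(m == 2, "grandparent",
                       paste0(strrep("great-", pmax(m - 2, 0)),
                              "grandparent")))
  }
  col <- which(!is.na(grt) & grt %in% c("full", "half"))
  if (length(col) > 0) {
    m <- md[col]; g <- gdd[col]
    d1 <- (m - g) / 2 # depth of the nearer individual to the MRCA
    lab <- character(length(col))
    bad <- d1 != floor(d1) | d1 < 1
    sib <- !bad & d1 == 1 & g == 0
    avc <- !bad & d1 == 1 & g >= 1
    cus <- !bad & d1 >= 2
    lab[sib] <- "sibling"
    lab[avc] <- ifelse(g[avc] == 1, "avuncular",
                       paste0(strrep("great-", pmax(g[avc] - 2, 0)),
                              "grand-avuncular"))
    rem <- ifelse(g == 0, "",
           ifelse(g == 1, " once-removed",
           ifelse(g == 2, " twice-removed", paste0(" ", g, "x-removed"))))
    lab[cus] <- paste0(ordinal(d1[cus] - 1), " cousin", rem[cus])
    lab[bad] <- paste0(grt[col][bad], " relative, MD=", m[bad])
    half <- grt[col] == "half" & !bad
    lab[half] <- paste0("half-", lab[half])
    out[col] <- lab
  }
  out
}

#' Expected kinship from path counting
#'
#' Wright path-counting kinship for non-inbred common ancestors: a
#' direct pair at meiotic distance m has kinship (1/2)^(m+1); a full
#' collateral pair (two shared most recent common ancestors) (1/2)^m;
#' a half pair (one shared ancestor) (1/2)^(m+1); an unrelated pair 0.
#'
#' @param md meiotic distance(s), integer >= 1 or `NA`.
#' @param grt relationship type(s): direct/full/half/NA.
#' @return numeric kinship coefficient(s) in [0, 0.5].
#' @export
#' @examples
#' expected_kinship(1, "direct") # parent-child, 0.25
#' expected_kinship(4, "full")   # 1st cousins, 0.0625
expected_kinship <- function(md, grt) {
  n <- max(length(md), length(grt))
  md <- rep_len(as.numeric(md), n)
  grt <- rep_len(as.character(grt), n)
  if (any(!is.na(md) & md < 1)) stop("md must be >= 1")
  out <- numeric(n)
  out[!is.na(grt) & grt == "full"] <- 0.5^md[!is.na(grt) & grt == "full"]
  dh <- !is.na(grt) & grt %in% c("direct", "half")
  out[dh] <- 0.5^(md[dh] + 1)
  out[is.na(grt) | is.na(md)] <- 0
  out
}

# Matrix engine: md / gdd / n-MRCA / direct over all pairs at once.
# Common ancestors are scanned row-by-row over individuals with
# offspring; O(ancestors * n^2) but fully vectorized per ancestor.
relationship_matrices <- function(ped) {
  n <- length(ped$ids)
  D <- ped_distances(ped)
  MD <- matrix(Inf, n, n)
  GDD <- matrix(Inf, n, n)
  NMR <- matrix(0L, n, n)
  anc <- which(ped$ids %in% unique(ped$edges[, 1]))
  for (k in anc) {
    dk <- D[k, ]
    r <- which(is.finite(dk))
    if (length(r) < 2) next
    s <- outer(dk[r], dk[r], "+")
    gd <- abs(outer(dk[r], dk[r], "-"))
    sub <- MD[r, r]
    less <- s < sub
    eqm <- s == sub
    sub[less] <- s[less]
    MD[r, r] <- sub
    Nr <- NMR[r, r]
    Nr[less] <- 1L
    Nr[eqm] <- Nr[eqm] + 1L
    NMR[r, r] <- Nr
    Gr <- GDD[r, r]
    Gr[less] <- gd[less]
    Gr[eqm] <- pmin(Gr[eqm], gd[eqm])
    GDD[r, r] <- Gr
  }
  # direct pairs override: metric is the directed shortest path
  dir <- is.finite(D) & D > 0
  dir <- dir | t(dir)
  Ddir <- pmin(D, t(D)) # the finite directed distance of the pair
  MD[dir] <- Ddir[dir]
  GDD[dir] <- Ddir[dir]
  dimnames(MD) <- dimnames(GDD) <- dimnames(NMR) <- list(ped$ids, ped$ids)
  list(md = MD, gdd = GDD, n_mrca = NMR, direct = dir)
}

#' All pairwise relationship records of a pedigree
#'
#' One record per unordered pair of individuals: meiotic distance,
#' generation depth difference, relationship type, the standard
#' relationship label, path-counting expected kinship, and the number
#' of distinct most recent common ancestors at minimal distance
#' (`n_mrca`; values above 2 flag extra ancestral paths through inbred
#' loops, which do not alter the label).
#'
#' @param ped a [ped_dag].
#' @return data.frame with `n(n-1)/2` rows and columns `id_a`, `id_b`,
#'   `md`, `gdd`, `grt`, `label`, `expected_kinship`, `n_mrca`.
#' @export
all_pairwise <- function(ped) {
  validate_ped(ped)
  n <- length(ped$ids)
  rel <- relationship_matrices(ped)
  ut <- which(upper.tri(rel$md), arr.ind = TRUE)
  md <- rel$md[ut]
  gdd <- rel$gdd[ut]
  nmr <- rel$n_mrca[ut]
  dir <- rel$direct[ut]
  grt <- rep(NA_character_, nrow(ut))
  grt[is.finite(md) & !dir & nmr == 1L] <- "half"
  grt[is.finite(md) & !dir & nmr >= 2L] <- "full"
  grt[dir] <- "direct"
  md[!is.finite(md)] <- NA
  gdd[!is.finite(gdd)] <- NA
  nmr[dir] <- NA_integer_
  data.frame(
    id_a = ped$ids[ut[, 1]],
    id_b = ped$ids[ut[, 2]],
    md = as.integer(md),
    gdd = as.integer(gdd),
    grt = grt,
    label = classify_relationship(md, gdd, grt),
    expected_kinship = expected_kinship(md, grt),
    n_mrca = as.integer(nmr),
    stringsAsFactors = FALSE
  )
}
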