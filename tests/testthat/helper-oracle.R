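# Brute-force genealogy-walking oracle, independent of the package's
# graph machinery: works directly on a two-column edge matrix.

oracle_parent_map <- function(edges) {
  if (nrow(edges) == 0) return(list())
  split(edges[, 1], edges[, 2])
}

# min distance from `id` up to each of its ancestors (including itself, 0)
oracle_ancestors <- function(edges, id) {
  pm <- oracle_parent_map(edges)
  dist <- c(stats::setNames(0, id))
  frontier <- id
  d <- 0
  while (length(frontier) > 0) {
    d <- d + 1
    nxt <- unique(unlist(pm[frontier], use.names = FALSE))
    nxt <- nxt[!nxt %in% names(dist)]
    if (length(nxt) == 0) break
    dist <- c(dist, stats::setNames(rep(d, length(nxt)), nxt))
    frontier <- nxt
  }
  dist
}

oracle_metrics <- function(edges, a, b) {
  da <- oracle_ancestors(edges, a)
  db <- oracle_ancestors(edges, b)
  common <- intersect(names(da), names(db))
  if (length(common) == 0) {
    return(list(md = NA, gdd = NA, grt = NA_character_))
  }
  if (b %in% names(da) || a %in% names(db)) {
    md <- if (b %in% names(da)) da[[b]] else db[[a]]
    return(list(md = md, gdd = md, grt = "direct"))
  }
  s <- da[common] + db[common]
  md <- min(s)
  at <- common[s == md]
  list(md = unname(md),
       gdd = unname(min(abs(da[at] - db[at]))),
       grt = if (length(at) >= 2) "full" else "half")
}

# Wright path-counting kinship: enumerate every directed path from each
# common ancestor down to a and b; path pairs may share only the
# ancestor itself. Assumes non-inbred common ancestors.
oracle_paths_down <- function(edges, from, to) {
  cm <- if (nrow(edges) == 0) list() else split(edges[, 2], edges[, 1])
  res <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == to) {
      res[[length(res) + 1]] <<- path
      return()
    }
    for (ch in cm[[last]]) walk(c(path, ch))
  }
  walk(from)
  res
}

oracle_kinship <- function(edges, a, b) {
  da <- oracle_ancestors(edges, a)
  db <- oracle_ancestors(edges, b)
  common <- intersect(names(da), names(db))
  total <- 0
  for (anc in common) {
    pa <- oracle_paths_down(edges, anc, a)
    pb <- oracle_paths_down(edges, anc, b)
    for (p in pa) {
      for (q in pb) {
        if (length(intersect(p[-1], q[-1])) == 0) {
          total <- total + 0.5^(length(p) - 1 + length(q) - 1 + 1)
        }
      }
    }
  }
  total
}

# small hand-built pedigrees used across relationship tests
hand_pedigrees <- function() {
  list(
    trio = rbind(c("A", "C"), c("B", "C")),
    chain = rbind(c("A", "B"), c("B", "C")),
    sibs = rbind(c("F", "S1"), c("M", "S1"), c("F", "S2"), c("M", "S2")),
    half_sibs = rbind(c("F", "H1"), c("M1", "H1"),
                      c("F", "H2"), c("M2", "H2")),
    avuncular = rbind(c("G1", "P"), c("G2", "P"), c("G1", "U"),
                      c("G2", "U"), c("P", "C"), c("S", "C")),
    cousins = rbind(c("G1", "P1"), c("G2", "P1"), c("G1", "P2"),
                    c("G2", "P2"), c("P1", "C1"), c("S1", "C1"),
                    c("P2", "C2"), c("S2", "C2")),
    # consanguineous: A is both parent and grandparent of E
    loop = rbind(c("A", "B"), c("M", "B"), c("A", "E"), c("B", "E")),
    second_cousins = rbind(
      c("G1", "P1"), c("G2", "P1"), c("G1", "P2"), c("G2", "P2"),
      c("P1", "Q1"), c("S1", "Q1"), c("P2", "Q2"), c("S2", "Q2"),
      c("Q1", "R1"), c("T1", "R1"), c("Q2", "R2"), c("T2", "R2"))
  )
}

edges_to_ped <- function(edges) {
  ped_dag(parent = edges[, 1], child = edges[, 2])
}

# deterministic two-child-model schedule
two_child_schedule <- function(rows = 3) {
  d <- data.frame(generation = paste0("g", seq_len(rows)),
                  mean = 2, sd = 0)
  class(d) <- c("sibship_schedule", "data.frame")
  d
}

# i.i.d. synthetic unrelated founder pool: `n` individuals, `s` sites
# with allele frequencies drawn from a U-shaped spectrum
synthetic_founder_pool <- function(n, s, L = 1e6, seed = NULL,
                                   ids = paste0("U", seq_len(n))) {
  if (!is.null(seed)) set.seed(seed)
  pos <- sort(sample.int(L, s)) - 1
  freq <- stats::rbeta(s, 0.4, 0.4)
  haps <- lapply(seq_len(n), function(i) {
    hap_pair(pos[stats::runif(s) < freq], pos[stats::runif(s) < freq], L)
  })
  names(haps) <- ids
  structure(list(haps = haps, L = L, config = genome_config(L)),
            class = "hap_genomes")
}

# round half away from zero (printing convention for kinship tables)
round_half_up <- function(x, digits = 3) {
  floor(abs(x) * 10^digits + 0.5) / 10^digits * sign(x)
}
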