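#' Genome simulation configuration
#'
#' @param sequence_length simulated sequence length L in bp (single
#'   contig; internal coordinates are 0-based half-open `[0, L)`).
#' @param mutation_rate per-bp per-generation mutation rate
#'   (default 1e-8).
#' @param recombination_rate per-bp per-generation crossover rate
#'   (default 1e-7).
#' @return list of class `genome_config`.
#' @export
genome_config <- function(sequence_length,
                          mutation_rate = 1e-8,
                          recombination_rate = 1e-7) {
  stopifnot(sequence_length >= 1, mutation_rate >= 0,
            recombination_rate >= 0)
  structure(list(sequence_length = as.numeric(sequence_length),
                 mutation_rate = mutation_rate,
                 recombination_rate = recombination_rate),
            class = "genome_config")
}

#' A phased haplotype pair
#'
#' Haplotypes are represented sparsely as sorted integer vectors of the
#' 0-based positions carrying a derived allele. Under the
#' infinite-sites approximation used throughout (collisions are
#' redrawn) a position identifies a unique mutation event, so the
#' position doubles as the allele id.
#'
#' @param h1,h2 sorted numeric vectors of derived-site positions in
#'   `[0, L)`; duplicates within one haplotype are forbidden.
#' @param L sequence length.
#' @return list of class `hap_pair`.
#' @export
hap_pair <- function(h1 = numeric(), h2 = numeric(), L = NULL) {
  h1 <- sort(unique(as.numeric(h1)))
  h2 <- sort(unique(as.numeric(h2)))
  if (!is.null(L) && (any(h1 >= L) || any(h2 >= L) ||
                      any(h1 < 0) || any(h2 < 0))) {
    stop("derived-site positions must lie in [0, L)")
  }
  structure(list(h1 = h1, h2 = h2), class = "hap_pair")
}

#' Simulate one meiosis
#'
#' The number of crossovers is Poisson with mean
#' `recombination_rate * L`; breakpoints fall uniformly on `[0, L)`;
#' the starting haplotype is a fair coin; the gamete is the alternating
#' mosaic of the two parental haplotypes. No crossover interference,
#' uniform genetic map.
#'
#' @param parent a [hap_pair].
#' @param config a [genome_config].
#' @return numeric vector: the gamete's derived-site positions.
#' @export
meiosis <- function(parent, config) {
  L <- config$sequence_length
  k <- stats::rpois(1, config$recombination_rate * L)
  start <- stats::rbinom(1, 1, 0.5) # 0 -> begin on h1
  if (k == 0) {
    return(if (start == 0) parent$h1 else parent$h2)
  }
  breaks <- sort(stats::runif(k, 0, L))
  seg1 <- (findInterval(parent$h1, breaks) + start) %% 2 == 0
  seg2 <- (findInterval(parent$h2, breaks) + start) %% 2 == 1
  sort(c(parent$h1[seg1], parent$h2[seg2]))
}

#' Add new mutations to a gamete
#'
#' Poisson(`mutation_rate * L`) new derived alleles at uniform integer
#' positions not already carried on the gamete (infinite-sites;
#' collisions are redrawn).
#'
#' @param gamete numeric vector of derived-site positions.
#' @param config a [genome_config].
#' @return the gamete with new mutation positions merged in, sorted.
#' @export
add_mutations <- function(gamete, config) {
  L <- config$sequence_length
  m <- stats::rpois(1, config$mutation_rate * L)
  if (m == 0) return(gamete)
  new <- floor(stats::runif(m, 0, L))
  repeat {
    clash <- new %in% gamete | duplicated(new)
    if (!any(clash)) break
    new[clash] <- floor(stats::runif(sum(clash), 0, L))
  }
  sort(c(gamete, new))
}

#' Gene-drop simulation of genomes down a fixed pedigree
#'
#' Individuals are processed in ascending generation-tick order; every
#' founder (explicit or implicit) must have an entry in
#' `founder_genomes`, and every non-founder receives one gamete per
#' parent via [meiosis()] followed by [add_mutations()].
#'
#' @param ped a completed [ped_dag] (every non-founder has two
#'   parents; see [identify_founders()]).
#' @param profiles profile table with generation ticks assigned.
#' @param founder_genomes named list of [hap_pair], one per founder.
#' @param config a [genome_config].
#' @param seed optional integer seed.
#' @return object of class `hap_genomes`: list with `haps` (named list
#'   of [hap_pair] covering every individual), `L`, and `config`.
#' @export
gene_drop <- function(ped, profiles, founder_genomes, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_ped(ped)
  fo <- founder_ids(ped)
  missing <- setdiff(fo, names(founder_genomes))
  if (length(missing) > 0) {
    stop(sprintf("missing founder genome(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  gen <- stats::setNames(profiles$gen, profiles$id)
  if (anyNA(gen[ped$ids])) stop("generation ticks must be assigned")
  pl <- parents_list(ped)
  haps <- vector("list", length(ped$ids))
  names(haps) <- ped$ids
  for (f in fo) haps[[f]] <- founder_genomes[[f]]
  for (id in ped$ids[order(gen[ped$ids])]) {
    p <- pl[[id]]
    if (length(p) == 0) next
    if (length(p) != 2) {
      stop(sprintf("'%s' has %d parent(s); run identify_founders() first",
                   id, length(p)))
    }
    if (is.null(haps[[p[1]]]) || is.null(haps[[p[2]]])) {
      stop(sprintf("parent of '%s' processed after child", id))
    }
    g1 <- add_mutations(meiosis(haps[[p[1]]], config), config)
    g2 <- add_mutations(meiosis(haps[[p[2]]], config), config)
    haps[[id]] <- hap_pair(g1, g2)
  }
  structure(list(haps = haps, L = config$sequence_length, config = config),
            class = "hap_genomes")
}

#' @export
print.hap_genomes <- function(x, ...) {
  ns <- length(unique(unlist(lapply(x$haps, function(h) c(h$h1, h$h2)))))
  cat(sprintf("<hap_genomes> %d individuals, %d derived sites, L = %g\n",
              length(x$haps), ns, x$L))
  invisible(x)
}

#' Neutral Wright-Fisher burn-in to generate founder genomes
#'
#' Simulates a randomly mating diploid population of constant size `ne`
#' for `burnin_generations` generations (default 10 * `ne`, enough to
#' approach mutation-drift equilibrium from an initially monomorphic
#' state) with mutation and crossover at the configured rates, then
#' samples `n_sample` individuals. The sampled genomes serve as
#' unrelated founder genomes for [gene_drop()] or can be written as a
#' phased VCF with [write_vcf()].
#'
#' @param n_sample number of individuals to sample (<= `ne`).
#' @param ne diploid population size.
#' @param config a [genome_config].
#' @param burnin_generations number of generations (default `10 * ne`).
#' @param seed optional integer seed.
#' @param sample_ids ids for the sampled individuals (default
#'   `S1..Sn`).
#' @return a `hap_genomes` object with `n_sample` individuals.
#' @export
simulate_founder_genomes <- function(n_sample, ne, config,
                                     burnin_generations = 10 * ne,
                                     seed = NULL,
                                     sample_ids = paste0("S", seq_len(n_sample))) {
  stopifnot(n_sample >= 1, ne >= 1)
  if (n_sample > ne) stop("n_sample must not exceed ne")
  if (!is.null(seed)) set.seed(seed)
  L <- config$sequence_length
  mu <- config$mutation_rate
  rr <- config$recombination_rate
  nh <- 2L * ne
  G <- matrix(integer(0), nrow = 0, ncol = nh) # sites x haplotypes, 0/1
  pos <- numeric(0)
  for (gen in seq_len(burnin_generations)) {
    # one gamete from a random mother, one from a random father
    par <- c(sample.int(ne, ne, replace = TRUE),
             sample.int(ne, ne, replace = TRUE))
    ncross <- stats::rpois(nh, rr * L)
    coin <- sample.int(2L, nh, replace = TRUE) # which parental hap first
    src <- 2L * (par - 1L) + coin
    if (nrow(G) > 0) {
      newG <- G[, src, drop = FALSE]
      xo <- which(ncross > 0)
      for (j in xo) {
        breaks <- sort(stats::runif(ncross[j], 0, L))
        pick_a <- (findInterval(pos, breaks) + coin[j] - 1L) %% 2L == 0L
        a <- G[, 2L * (par[j] - 1L) + 1L]
        b <- G[, 2L * (par[j] - 1L) + 2L]
        newG[, j] <- ifelse(pick_a, a, b)
      }
    } else {
      newG <- G
    }
    nmut <- stats::rpois(1, mu * L * nh)
    if (nmut > 0) {
      mp <- floor(stats::runif(nmut, 0, L))
      keep <- !mp %in% pos & !duplicated(mp)
      mp <- mp[keep]
      if (length(mp) > 0) {
        mc <- sample.int(nh, length(mp), replace = TRUE)
        add <- matrix(0L, nrow = length(mp), ncol = nh)
        add[cbind(seq_along(mp), mc)] <- 1L
        newG <- rbind(newG, add)
        pos <- c(pos, mp)
      }
    }
    G <- newG
    if (gen %% 25L == 0L && nrow(G) > 0) {
      rs <- rowSums(G)
      keep <- rs > 0L & rs < nh
      G <- G[keep, , drop = FALSE]
      pos <- pos[keep]
    }
  }
  if (nrow(G) > 0) {
    rs <- rowSums(G)
    keep <- rs > 0L & rs < nh
    G <- G[keep, , drop = FALSE]
    pos <- pos[keep]
  }
  take <- sample.int(ne, n_sample)
  haps <- vector("list", n_sample)
  names(haps) <- sample_ids
  for (i in seq_len(n_sample)) {
    c1 <- 2L * (take[i] - 1L) + 1L
    haps[[i]] <- hap_pair(pos[G[, c1] == 1L], pos[G[, c1 + 1L] == 1L], L)
  }
  structure(list(haps = haps, L = L, config = config),
            class = "hap_genomes")
}
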