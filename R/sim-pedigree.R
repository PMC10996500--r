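#' Load a sibship-size schedule from CSV
#'
#' The schedule drives the pedigree simulator: row k gives the mean and
#' standard deviation of the normal distribution from which sibship
#' sizes of generation-k couples are drawn (their children are
#' generation k + 1). Row order defines generation order; the
#' `generation` column is a label (census years in the packaged
#' default) and is never interpreted numerically.
#'
#' @param path CSV with columns `generation`, `mean`, `sd`.
#' @return data.frame of class `sibship_schedule` with those columns,
#'   rows in file order.
#' @export
#' @examples
#' sched <- load_sibship_schedule(
#'   system.file("extdata", "census_sibship.csv", package = "pedforge"))
#' sched
load_sibship_schedule <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("generation", "mean", "sd")
  if (!all(need %in% names(d))) {
    stop(sprintf("schedule must have columns %s; found: %s",
                 paste(need, collapse = ", "), paste(names(d), collapse = ", ")))
  }
  d <- d[, need]
  d$mean <- as.numeric(d$mean); d$sd <- as.numeric(d$sd)
  if (any(!is.finite(d$mean)) || any(!is.finite(d$sd))) {
    stop("schedule mean/sd must be finite")
  }
  if (any(d$sd < 0)) stop("schedule sd must be >= 0")
  if (any(d$mean < 0)) stop("schedule mean must be >= 0")
  class(d) <- c("sibship_schedule", "data.frame")
  d
}

#' The packaged census sibship schedule
#'
#' United States census sibship-size estimates for the years
#' 1850, 1880, 1910, 1940 and 1970 (mean and standard deviation of
#' children per couple), the default schedule of the pedigree
#' simulator.
#'
#' @return a `sibship_schedule` with five rows.
#' @export
census_sibship_schedule <- function() {
  load_sibship_schedule(
    system.file("extdata", "census_sibship.csv", package = "pedforge"))
}

#' Draw discrete sibship sizes from a normal distribution
#'
#' Continuous draws from N(mean, sd^2) are discretized by rounding to
#' the nearest integer and truncating below at zero. With `sd = 0` this
#' returns `round(mean)` always.
#'
#' @param mean,sd normal parameters (children per couple), `sd >= 0`.
#' @param n number of draws.
#' @return integer vector of non-negative sibship sizes.
#' @export
draw_sibship_size <- function(mean, sd, n = 1) {
  if (sd < 0) stop("sd must be >= 0")
  as.integer(pmax(0, round(stats::rnorm(n, mean, sd))))
}

#' Mean and sd of the discretized sibship-size distribution
#'
#' Numerical expectation of `max(0, round(X))` for X ~ N(mean, sd^2):
#' the distribution the simulator actually samples from, used as the
#' oracle for moment-recovery checks.
#'
#' @param mean,sd normal parameters.
#' @param kmax upper summation bound.
#' @return named numeric vector `c(mean =, sd =)`.
#' @export
discretized_sibship_moments <- function(mean, sd, kmax = 100) {
  if (sd == 0) return(c(mean = round(mean), sd = 0))
  k <- seq_len(kmax)
  p <- stats::pnorm(k + 0.5, mean, sd) - stats::pnorm(k - 0.5, mean, sd)
  m1 <- sum(k * p)
  m2 <- sum(k^2 * p)
  c(mean = m1, sd = sqrt(m2 - m1^2))
}

#' Forward-simulate a family pedigree under a sibship schedule
#'
#' Starts from `founder_couples` couples at generation tick 1. Each
#' couple of generation g draws a sibship size from schedule row g and
#' produces that many children at tick g + 1. Every child of a
#' non-final generation is paired with a newly created founder spouse
#' of complementary sex (monogamy; spouses are always new founders, so
#' no one reproduces with a relative), and the new couple reproduces
#' under the next schedule row. Children of the final generation do not
#' reproduce. The sex of each child, and of the first member of each
#' founder couple, is a fair Bernoulli draw; the partner gets the
#' complement.
#'
#' @param schedule a `sibship_schedule` (see [load_sibship_schedule()]).
#' @param n_generations number of reproducing generations (schedule
#'   rows consumed); individuals span ticks 1..`n_generations + 1`.
#' @param founder_couples number of unrelated root couples (default 1).
#' @param seed optional integer seed for reproducibility.
#' @param id_prefix prefix for generated individual ids.
#' @return list of class `ped_sim` with `ped` (a [ped_dag]) and
#'   `profiles` (profile table with sex and tick for everyone).
#' @export
#' @examples
#' sched <- data.frame(generation = c("g1", "g2"), mean = 2, sd = 0)
#' class(sched) <- c("sibship_schedule", "data.frame")
#' fam <- simulate_pedigree(sched, n_generations = 2, seed = 1)
#' fam$ped
simulate_pedigree <- function(schedule, n_generations,
                              founder_couples = 1, seed = NULL,
                              id_prefix = "I") {
  stopifnot(n_generations >= 1, founder_couples >= 1)
  if (n_generations > nrow(schedule)) {
    stop(sprintf("n_generations (%d) exceeds schedule length (%d)",
                 n_generations, nrow(schedule)))
  }
  if (!is.null(seed)) set.seed(seed)
  counter <- 0L
  new_ids <- function(n) {
    if (n == 0) return(character(0))
    out <- paste0(id_prefix, counter + seq_len(n))
    counter <<- counter + n
    out
  }
  all_id <- character(); all_sex <- character(); all_gen <- integer()
  e_par <- character(); e_ch <- character()
  sib_gen <- integer(); sib_size <- integer()

  # founder couples at tick 1
  s1 <- ifelse(stats::rbinom(founder_couples, 1, 0.5) == 1, "XY", "XX")
  p1 <- new_ids(founder_couples)
  p2 <- new_ids(founder_couples)
  all_id <- c(p1, p2)
  all_sex <- c(s1, sex_complement(s1))
  all_gen <- rep(1L, 2 * founder_couples)
  cp1 <- p1; cp2 <- p2

  for (g in seq_len(n_generations)) {
    nc <- length(cp1)
    sizes <- draw_sibship_size(schedule$mean[g], schedule$sd[g], nc)
    sib_gen <- c(sib_gen, rep(g, nc))
    sib_size <- c(sib_size, sizes)
    nk <- sum(sizes)
    kids <- new_ids(nk)
    ksex <- ifelse(stats::rbinom(nk, 1, 0.5) == 1, "XY", "XX")
    e_par <- c(e_par, rep(cp1, sizes), rep(cp2, sizes))
    e_ch <- c(e_ch, kids, kids)
    all_id <- c(all_id, kids)
    all_sex <- c(all_sex, ksex)
    all_gen <- c(all_gen, rep(g + 1L, nk))
    if (g < n_generations && nk > 0) {
      sp <- new_ids(nk)
      all_id <- c(all_id, sp)
      all_sex <- c(all_sex, sex_complement(ksex))
      all_gen <- c(all_gen, rep(g + 1L, nk))
      cp1 <- kids; cp2 <- sp
    } else if (nk == 0) {
      cp1 <- character(); cp2 <- character()
    }
  }
  # spouses whose couple stayed childless never enter the graph; they
  # carry no genetic information, so they are not retained (the couple
  # itself is still counted in the recorded sibship draws)
  connected <- unique(c(e_par, e_ch, p1, p2))
  keep <- all_id %in% connected
  all_id <- all_id[keep]; all_sex <- all_sex[keep]; all_gen <- all_gen[keep]
  ped <- ped_dag(parent = e_par, child = e_ch, ids = all_id,
                 validate = FALSE)
  structure(list(ped = ped,
                 profiles = profile_table(all_id, all_sex, all_gen),
                 sibships = data.frame(generation = sib_gen,
                                       size = sib_size)),
            class = "ped_sim")
}

#' @export
print.ped_sim <- function(x, ...) {
  cat(sprintf("<ped_sim> %d individuals over ticks 1..%d\n",
              length(x$ped$ids), max(x$profiles$gen)))
  invisible(x)
}

#' Realized sibship sizes of one or many pedigrees
#'
#' For pedigrees fresh from [simulate_pedigree()] the realized draws
#' recorded during simulation are used, so childless couples (sibship
#' size 0) are counted — they are invisible in the graph itself. For
#' any other pedigree, sibships are reconstructed by grouping children
#' by their (unordered) parent couple; a sibship's generation is its
#' parents' reproduction generation, i.e. the children's tick minus
#' one.
#'
#' @param peds a `ped_sim`, a list of `ped_sim`, or a list of
#'   `list(ped =, profiles =)`.
#' @return data.frame with one row per sibship: `generation` (integer
#'   reproduction generation), `size`.
#' @export
sibship_sizes <- function(peds) {
  if (inherits(peds, "ped_sim") ||
      (is.list(peds) && !is.null(peds$ped))) peds <- list(peds)
  if (length(peds) == 0) stop("empty input")
  res <- lapply(peds, function(x) {
    if (!is.null(x$sibships)) return(x$sibships)
    ed <- x$ped$edges
    if (nrow(ed) == 0) {
      return(data.frame(generation = integer(), size = integer()))
    }
    gen <- stats::setNames(x$profiles$gen, x$profiles$id)
    o <- order(ed[, 2], ed[, 1])
    pa <- ed[o, 1]; ch <- ed[o, 2]
    # couple key per child: its parents concatenated in sorted order
    key <- vapply(split(pa, ch), paste, character(1), collapse = "\r")
    chgen <- gen[names(key)]
    cup <- paste(key, chgen) # same couple reproducing at one tick
    tab <- table(cup)
    g <- as.integer(sub(".*[ ]", "", names(tab))) - 1L
    data.frame(generation = g, size = as.integer(tab))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-generation summary of realized sibship sizes
#'
#' One row per reproduction generation: how many couples reproduced and
#' the observed mean and standard deviation of their realized child
#' counts, the layout used to validate the simulator against the input
#' schedule.
#'
#' @inheritParams sibship_sizes
#' @param schedule optional schedule whose `generation` labels are
#'   attached to the rows.
#' @return data.frame with columns `generation`, `label` (if schedule
#'   given), `n_sibships`, `observed_mean`, `observed_sd`.
#' @export
sibship_summary <- function(peds, schedule = NULL) {
  s <- sibship_sizes(peds)
  if (nrow(s) == 0) stop("no sibships found")
  gens <- sort(unique(s$generation))
  out <- data.frame(
    generation = gens,
    n_sibships = vapply(gens, function(g) sum(s$generation == g), integer(1)),
    observed_mean = vapply(gens, function(g)
      mean(s$size[s$generation == g]), numeric(1)),
    observed_sd = vapply(gens, function(g) {
      v <- s$size[s$generation == g]
      if (length(v) < 2) 0 else stats::sd(v)
    }, numeric(1))
  )
  if (!is.null(schedule)) {
    out <- cbind(out[, "generation", drop = FALSE],
                 label = schedule$generation[out$generation],
                 out[, c("n_sibships", "observed_mean", "observed_sd")])
  }
  out
}
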