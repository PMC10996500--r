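#' Packaged example inputs
#'
#' Returns paths to small packaged fixtures:
#' \describe{
#'   \item{`census_sibship`}{the default five-row census sibship
#'     schedule (years 1850-1970), as used by the pedigree simulator.}
#'   \item{`avuncular_pedigree`}{a seven-individual pedigree containing the
#'     worked avuncular example (grandparents `G1`/`G2`, their children
#'     `P` and `U`, `P`'s child `C`) plus a half-sibling pair (`C` and
#'     `H` share only `S`).}
#'   \item{`toy_trio`}{a minimal trio `A -> C <- B`.}
#'   \item{`two_child_family`}{a deterministic 22-individual
#'     two-child-model family (three reproducing generations, sibship
#'     size fixed at 2), generated on the fly into `tempdir()`.}
#' }
#'
#' @param name one of the fixture names above.
#' @return named character vector of file paths (elements `nx` and,
#'   where applicable, `profiles` or `csv`).
#' @export
#' @examples
#' load_fixture("toy_trio")
load_fixture <- function(name = c("census_sibship", "avuncular_pedigree",
                                  "two_child_family", "toy_trio")) {
  name <- match.arg(name)
  ext <- function(f) system.file("extdata", f, package = "pedforge")
  switch(name,
    census_sibship = c(csv = ext("census_sibship.csv")),
    avuncular_pedigree = c(nx = ext("avuncular_pedigree.nx")),
    toy_trio = c(nx = ext("toy_trio.nx")),
    two_child_family = {
      sched <- data.frame(generation = c("g1", "g2", "g3"),
                          mean = 2, sd = 0)
      class(sched) <- c("sibship_schedule", "data.frame")
      fam <- simulate_pedigree(sched, n_generations = 3, seed = 42,
                               id_prefix = "T")
      nx <- file.path(tempdir(), "two_child_family.nx")
      pr <- file.path(tempdir(), "two_child_family_profiles.txt")
      write_nx(fam$ped, nx)
      write_profiles(fam$profiles, pr)
      c(nx = nx, profiles = pr)
    })
}
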