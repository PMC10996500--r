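#' One-call pedigree genome simulation
#'
#' Convenience pipeline: completes the pedigree (synthesizing implicit
#' founders for single-parent individuals), assigns generation ticks,
#' assigns founder genomes from a pool, and gene-drops genomes down the
#' pedigree. Implicit founders receive fresh random draws from the pool
#' (with replacement); their ids are returned so VCF export can exclude
#' them.
#'
#' @param ped a [ped_dag].
#' @param founder_pool a `hap_genomes` pool ([read_founder_vcf()] or
#'   [simulate_founder_genomes()]).
#' @param config a [genome_config]; defaults to the pool's.
#' @param profiles optional profile table (sexes carried into the
#'   completion); ticks are recomputed.
#' @param mode,mapping_path founder assignment, see [assign_founders()].
#' @param seed optional integer seed covering assignment and drop.
#' @return list of class `ped_genomes`: `genomes` (a `hap_genomes`
#'   covering everyone), `ped` (completed pedigree), `profiles`
#'   (with ticks), `founders` (the `founder_partition`),
#'   `released` (ids excluding implicit founders).
#' @export
simulate_pedigree_genomes <- function(ped, founder_pool, config = NULL,
                                      profiles = NULL,
                                      mode = "random", mapping_path = NULL,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(config)) config <- founder_pool$config
  fp <- identify_founders(ped, profiles)
  prof <- assign_generations(fp$ped, fp$profiles)
  fg <- assign_founders(fp, founder_pool, mode = mode,
                        mapping_path = mapping_path)
  genomes <- gene_drop(fp$ped, prof, fg, config)
  structure(list(genomes = genomes, ped = fp$ped, profiles = prof,
                 founders = fp,
                 released = setdiff(fp$ped$ids, fp$implicit)),
            class = "ped_genomes")
}

#' Validate gene-dropped genomes against pedigree expectations
#'
#' Runs the full validation loop on a `ped_genomes` result: builds the
#' dosage matrix over released individuals, estimates beta kinship,
#' computes all pairwise relationship records, and compares observed to
#' expected kinship.
#'
#' @param pg a `ped_genomes` from [simulate_pedigree_genomes()].
#' @param reference `"founders"` (default) anchors the estimator's zero
#'   point to the explicit-founder pairs — the generation on which
#'   path-counting expectations are defined — while `"all"` uses every
#'   released individual.
#' @param include_unrelated passed to [compare_observed_expected()].
#' @return a `kinship_validation` object.
#' @export
validate_kinship <- function(pg, reference = c("founders", "all"),
                             include_unrelated = FALSE) {
  reference <- match.arg(reference)
  X <- dosage_matrix(pg$genomes, samples = pg$released)
  ref <- if (reference == "founders") {
    intersect(pg$founders$explicit, pg$released)
  } else pg$released
  K <- kinship_matrix_beta(X, reference = ref)
  rel <- all_pairwise(pg$ped)
  compare_observed_expected(rel, K, include_unrelated = include_unrelated)
}
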