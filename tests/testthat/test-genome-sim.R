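test_that("meiosis without recombination returns a whole parental haplotype", {
  cfg <- genome_config(1e6, recombination_rate = 0)
  par <- hap_pair(c(10, 500), c(20, 30, 900), 1e6)
  set.seed(1)
  got1 <- 0; got2 <- 0
  for (i in 1:200) {
    g <- meiosis(par, cfg)
    expect_true(identical(g, par$h1) || identical(g, par$h2))
    if (identical(g, par$h1)) got1 <- got1 + 1 else got2 <- got2 + 1
  }
  # both haplotypes transmitted, roughly fairly
  expect_gt(stats::binom.test(got1, 200, 0.5)$p.value, 0.001)
})

test_that("Mendelian transmission of a heterozygous site is one half", {
  cfg <- genome_config(1e5, recombination_rate = 1e-7)
  par <- hap_pair(1234, numeric(), 1e5)
  set.seed(2)
  n <- 2e4
  carried <- sum(vapply(seq_len(n),
                        function(i) 1234 %in% meiosis(par, cfg), logical(1)))
  se <- sqrt(0.25 / n)
  expect_lt(abs(carried / n - 0.5), 3 * se)
})

test_that("crossover counts are Poisson distributed", {
  # parent heterozygous at many sites; count observed mosaic switches
  # indirectly through the configured rate: r * L = 2
  cfg <- genome_config(1e6, recombination_rate = 2e-6)
  set.seed(3)
  # count crossovers via the internal draw: simulate gametes from a
  # parent whose haplotypes tile the sequence densely, then count
  # switch points between consecutive informative sites
  pos <- seq(0, 1e6 - 1, by = 2000)
  par <- hap_pair(pos, numeric(), 1e6)
  n <- 4000
  counts <- integer(n)
  for (i in seq_len(n)) {
    g <- meiosis(par, cfg)
    carrier <- pos %in% g
    counts[i] <- sum(carrier[-1] != carrier[-length(carrier)])
  }
  # switches undercount true crossovers only when two fall within 2 kb
  lam <- 2
  brk <- c(0:5, Inf)
  obs <- table(cut(counts, brk, right = FALSE))
  p <- diff(c(ppois(-1:4, lam), 1))
  gof <- suppressWarnings(stats::chisq.test(as.integer(obs), p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("mutations are Poisson, never duplicated and rate-0 is a no-op", {
  cfg <- genome_config(1e6, mutation_rate = 0)
  g <- c(5, 10)
  expect_identical(add_mutations(g, cfg), g)

  cfg <- genome_config(1e6, mutation_rate = 1e-6) # mu * L = 1
  set.seed(4)
  n <- 2e4
  extra <- integer(n)
  for (i in seq_len(n)) {
    out <- add_mutations(g, cfg)
    expect_false(anyDuplicated(out) > 0)
    extra[i] <- length(out) - length(g)
  }
  expect_lt(abs(mean(extra) - 1), 3 * sqrt(1 / n))
})

test_that("gene drop conserves alleles when mutation and recombination are off", {
  fam <- simulate_pedigree(two_child_schedule(3), 3, seed = 5)
  fp <- identify_founders(fam$ped, fam$profiles)
  prof <- assign_generations(fp$ped, fp$profiles)
  cfg <- genome_config(1e6, mutation_rate = 0, recombination_rate = 0)
  pool <- synthetic_founder_pool(length(fp$explicit), 50, seed = 6)
  names(pool$haps) <- fp$explicit
  g <- gene_drop(fp$ped, prof, pool$haps, cfg, seed = 7)
  pl <- parents_list(fp$ped)
  for (id in names(pl)) {
    kid <- g$haps[[id]]
    par_alleles <- unlist(lapply(pl[[id]], function(p)
      c(g$haps[[p]]$h1, g$haps[[p]]$h2)))
    expect_true(all(c(kid$h1, kid$h2) %in% par_alleles))
    # each gamete is exactly one unrecombined parental haplotype
    for (hap in list(kid$h1, kid$h2)) {
      match_any <- any(vapply(pl[[id]], function(p)
        identical(hap, g$haps[[p]]$h1) || identical(hap, g$haps[[p]]$h2),
        logical(1)))
      expect_true(match_any)
    }
  }
})

test_that("trio with hom-derived father and hom-ancestral mother is het", {
  trio <- ped_dag(c("F", "M"), c("C", "C"))
  prof <- profile_table(c("F", "M", "C"), c("XY", "XX", "XX"), c(1, 1, 2))
  cfg <- genome_config(1000, mutation_rate = 0, recombination_rate = 1e-4)
  founders <- list(F = hap_pair(c(100, 600), c(100, 600), 1000),
                   M = hap_pair(numeric(), numeric(), 1000))
  for (seed in 1:5) {
    g <- gene_drop(trio, prof, founders, cfg, seed = seed)
    X <- dosage_matrix(g, polymorphic_only = FALSE)
    expect_equal(unname(X["C", ]), c(1L, 1L))
  }
})

test_that("a founder het allele reaches a grandchild a quarter of the time", {
  # chain: G founder, child P (with spouse), grandchild C
  ped <- ped_dag(c("G", "S1", "P", "S2"), c("P", "P", "C", "C"))
  prof <- assign_generations(ped)
  cfg <- genome_config(1e4, mutation_rate = 0, recombination_rate = 0)
  empty <- hap_pair(numeric(), numeric(), 1e4)
  founders <- list(G = hap_pair(42, numeric(), 1e4),
                   S1 = empty, S2 = empty)
  set.seed(8)
  n <- 4000
  hits <- 0
  for (i in seq_len(n)) {
    g <- gene_drop(ped, prof, founders, cfg)
    if (42 %in% c(g$haps$C$h1, g$haps$C$h2)) hits <- hits + 1
  }
  expect_lt(abs(hits / n - 0.25), 3 * sqrt(0.25 * 0.75 / n))
})

test_that("gene drop demands complete founder genomes and ticks", {
  trio <- ped_dag(c("A", "B"), c("C", "C"))
  prof <- assign_generations(trio)
  cfg <- genome_config(100)
  expect_error(gene_drop(trio, prof, list(A = hap_pair()), cfg),
               "missing founder genome")
  single <- ped_dag("A", "C")
  expect_error(
    gene_drop(single, assign_generations(single),
              list(A = hap_pair()), cfg),
    "identify_founders")
})

test_that("burn-in founder genomes behave neutrally", {
  cfg0 <- genome_config(1e5, mutation_rate = 0, recombination_rate = 1e-7)
  fg <- simulate_founder_genomes(5, 20, cfg0, burnin_generations = 50,
                                 seed = 9)
  expect_true(all(lengths(lapply(fg$haps, `[[`, "h1")) == 0))
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(fg, f)
  expect_length(grep("^[^#]", readLines(f)), 0)

  # mean pairwise diversity across replicates near 4*Ne*mu*L
  cfg <- genome_config(2e5, mutation_rate = 5e-7, recombination_rate = 1e-7)
  ne <- 30
  theta <- 4 * ne * cfg$mutation_rate * cfg$sequence_length
  set.seed(10)
  pis <- vapply(1:8, function(r) {
    fg <- simulate_founder_genomes(15, ne, cfg,
                                   burnin_generations = 10 * ne)
    X <- dosage_matrix(fg)
    n <- nrow(X)
    ac <- colSums(X); an <- 2 * n
    sum(2 * ac * (an - ac) / (an * (an - 1)))
  }, numeric(1))
  se <- stats::sd(pis) / sqrt(length(pis))
  expect_lt(abs(mean(pis) - theta), 4 * se + 0.15 * theta)
})

test_that("identical seeds give byte-identical VCF output", {
  fam <- simulate_pedigree(two_child_schedule(2), 2, seed = 11)
  cfg <- genome_config(1e5, 1e-6, 1e-6)
  run <- function() {
    pool <- simulate_founder_genomes(20, 30, cfg, burnin_generations = 100,
                                     seed = 12)
    pg <- simulate_pedigree_genomes(fam$ped, pool, config = cfg,
                                    profiles = fam$profiles, seed = 13)
    f <- tempfile(fileext = ".vcf")
    write_vcf(pg$genomes, f, samples = pg$released)
    on.exit(unlink(f))
    readLines(f)
  }
  expect_identical(run(), run())
})

test_that("VCF round trip preserves phased genotypes and coordinates", {
  pool <- synthetic_founder_pool(8, 40, seed = 14)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(pool, f)
  lines <- readLines(f)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  back <- read_founder_vcf(f)
  expect_equal(back$L, pool$L)
  X0 <- dosage_matrix(pool); X1 <- dosage_matrix(back)
  expect_identical(X1, X0[rownames(X1), colnames(X1), drop = FALSE])
  # phase preserved exactly for every segregating site
  seg <- as.numeric(colnames(X0)) - 1
  for (id in names(pool$haps)) {
    expect_identical(back$haps[[id]]$h1, intersect(pool$haps[[id]]$h1, seg))
    expect_identical(back$haps[[id]]$h2, intersect(pool$haps[[id]]$h2, seg))
  }

  # 1-based POS convention: hap1-only derived allele at internal 99
  g1 <- structure(list(haps = list(X = hap_pair(99, numeric(), 1000),
                                   Y = hap_pair(numeric(), numeric(), 1000)),
                       L = 1000, config = genome_config(1000)),
                  class = "hap_genomes")
  write_vcf(g1, f)
  rec <- grep("^[^#]", readLines(f), value = TRUE)
  expect_length(rec, 1)
  expect_equal(strsplit(rec, "\t")[[1]][2], "100")
  expect_equal(strsplit(rec, "\t")[[1]][10], "1|0")
  expect_equal(read_founder_vcf(f)$haps$X$h1, 99)

  # unphased input is rejected with a located error
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=1,length=1000>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tX",
               "1\t100\t.\tA\tT\t.\t.\t.\tGT\t0/1"), f)
  expect_error(read_founder_vcf(f), "unphased")
})

test_that("implicit founders are excluded from exported VCFs", {
  ped <- ped_dag("A", "C") # C's co-parent is implicit
  fp <- identify_founders(ped)
  prof <- assign_generations(fp$ped)
  cfg <- genome_config(1e4, 0, 0)
  pool <- synthetic_founder_pool(4, 10, L = 1e4, seed = 15)
  fg <- assign_founders(fp, pool, seed = 16)
  g <- gene_drop(fp$ped, prof, fg, cfg)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, f, samples = setdiff(fp$ped$ids, fp$implicit))
  hdr <- grep("^#CHROM", readLines(f), value = TRUE)
  expect_false(any(grepl("IF_", strsplit(hdr, "\t")[[1]])))
  expect_true(all(c("A", "C") %in% strsplit(hdr, "\t")[[1]]))
})

test_that("founder assignment is exact in mapped mode and safe in random", {
  ped <- ped_dag(c("A", "B"), c("C", "C"))
  fp <- identify_founders(ped)
  pool <- synthetic_founder_pool(3, 5, seed = 17)
  mapf <- withr::local_tempfile()
  writeLines(c("A U2", "B U3"), mapf)
  fg <- assign_founders(fp, pool, mode = "mapped", mapping_path = mapf)
  expect_identical(fg$A, pool$haps$U2)
  expect_identical(fg$B, pool$haps$U3)

  # random: deterministic under seed, no sample reused
  fg1 <- assign_founders(fp, pool, seed = 18)
  fg2 <- assign_founders(fp, pool, seed = 18)
  expect_identical(fg1, fg2)

  big <- ped_dag(c("A", "B", "D", "E"), c("C", "C", "F", "F"))
  fpb <- identify_founders(big)
  small <- synthetic_founder_pool(3, 5, seed = 19)
  expect_error(assign_founders(fpb, small), "more founders")
  writeLines(c("A U2"), mapf)
  expect_error(assign_founders(fp, pool, mode = "mapped",
                               mapping_path = mapf), "unassigned")
  writeLines(c("A U2", "B nope"), mapf)
  expect_error(assign_founders(fp, pool, mode = "mapped",
                               mapping_path = mapf), "unknown sample")
})
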