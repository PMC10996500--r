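#' Write phased genomes as a VCF 4.2 file
#'
#' One synthetic contig; positions are written 1-based; genotypes are
#' phased (`a|b`). Only sites segregating among the written samples are
#' emitted, in deterministic order by position. Because the simulation
#' model is abstract, REF/ALT are written as the fixed nucleotide
#' states `A`/`T`. Simulation parameters can be recorded as `##`
#' meta-lines.
#'
#' @param genomes a `hap_genomes` object (see [gene_drop()]).
#' @param path output path.
#' @param samples ids to write (default: all). Pedigree runs exclude
#'   implicit founders here: their genomes are simulated but withheld
#'   from output.
#' @param contig contig name (default `"1"`).
#' @param meta optional named character vector of extra header
#'   meta-fields, written as `##key=value`.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genomes, path, samples = names(genomes$haps),
                      contig = "1", meta = NULL) {
  haps <- genomes$haps[samples]
  if (any(vapply(haps, is.null, logical(1)))) {
    stop("unknown sample id(s) requested")
  }
  n <- length(haps)
  allpos <- sort(unique(unlist(lapply(haps, function(h) c(h$h1, h$h2)))))
  # keep segregating sites only (drop fixed-derived in this sample set)
  if (length(allpos) > 0) {
    cnt <- rep(0L, length(allpos))
    for (h in haps) {
      cnt <- cnt + (allpos %in% h$h1) + (allpos %in% h$h2)
    }
    allpos <- allpos[cnt > 0L & cnt < 2L * n]
  }
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", contig,
                   as.integer(genomes$L)),
           "##source=pedforge",
           if (!is.null(meta)) sprintf("##%s=%s", names(meta), meta),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", names(haps)), collapse = "\t"))
  if (length(allpos) == 0) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  gt <- matrix("", nrow = length(allpos), ncol = n)
  for (i in seq_len(n)) {
    a <- as.integer(allpos %in% haps[[i]]$h1)
    b <- as.integer(allpos %in% haps[[i]]$h2)
    gt[, i] <- paste0(a, "|", b)
  }
  body <- paste(contig, format(allpos + 1, scientific = FALSE, trim = TRUE),
                ".", "A", "T", ".", ".", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a phased founder VCF
#'
#' Reads a single-contig VCF with phased diploid genotypes and
#' reconstructs each sample's two haplotypes. Positions are converted
#' from the VCF's 1-based coordinates to the package's internal
#' 0-based convention; the ALT allele is taken as the derived state.
#'
#' @param path VCF path.
#' @param L sequence length; taken from the `##contig` header when
#'   omitted (required if the header lacks one).
#' @return a `hap_genomes` object.
#' @export
read_founder_vcf <- function(path, L = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(L)) {
    ctg <- grep("^##contig", v@meta, value = TRUE)
    lm <- regmatches(ctg, regexpr("length=[0-9]+", ctg))
    if (length(lm) == 0) stop("no ##contig length in header; supply L")
    L <- as.numeric(sub("length=", "", lm[1]))
  }
  samples <- colnames(v@gt)[-1]
  nvar <- nrow(v@fix)
  if (!is.null(nvar) && nvar > 0) {
    if (length(unique(v@fix[, "CHROM"])) > 1) {
      stop("founder VCF must contain a single contig")
    }
    alt <- v@fix[, "ALT"]
    if (any(grepl(",", alt, fixed = TRUE))) {
      stop("multiallelic sites are not supported; decompose first")
    }
    pos <- as.numeric(v@fix[, "POS"]) - 1
    gt <- v@gt[, -1, drop = FALSE]
    gt <- matrix(sub(":.*", "", gt), nrow = nvar,
                 dimnames = list(NULL, samples))
    bad <- grepl("/", gt, fixed = TRUE) | !grepl("|", gt, fixed = TRUE)
    if (any(bad)) {
      w <- which(matrix(bad, nrow = nvar), arr.ind = TRUE)[1, ]
      stop(sprintf("unphased genotype at record %d, sample %s",
                   w[1], samples[w[2]]))
    }
    a1 <- matrix(substr(gt, 1, 1) == "1", nrow = nvar)
    a2 <- matrix(substr(gt, 3, 3) == "1", nrow = nvar)
  } else {
    pos <- numeric(0)
    a1 <- a2 <- matrix(logical(0), nrow = 0, ncol = length(samples))
  }
  haps <- vector("list", length(samples))
  names(haps) <- samples
  for (i in seq_along(samples)) {
    haps[[i]] <- hap_pair(pos[a1[, i]], pos[a2[, i]], L)
  }
  structure(list(haps = haps, L = L,
                 config = genome_config(L)),
            class = "hap_genomes")
}

#' Assign founder genomes to pedigree founders
#'
#' In `"random"` mode each explicit founder is assigned a distinct VCF
#' sample uniformly at random (without replacement); in `"mapped"` mode
#' a two-column whitespace-separated file (founder id, sample id) is
#' applied verbatim. Implicit founders (reserved `IF_` prefix) are, by
#' default, given fresh random draws from the sample pool with
#' replacement: their genomes are needed for transmission but are
#' withheld from VCF output.
#'
#' @param founders a `founder_partition` from [identify_founders()].
#' @param genomes a `hap_genomes` pool (founder VCF or burn-in).
#' @param mode `"random"` or `"mapped"`.
#' @param mapping_path path to the two-column mapping file
#'   (mapped mode).
#' @param seed optional integer seed (random mode).
#' @return named list of [hap_pair], one entry per founder (explicit
#'   and implicit), suitable for [gene_drop()].
#' @export
assign_founders <- function(founders, genomes, mode = c("random", "mapped"),
                            mapping_path = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  pool <- names(genomes$haps)
  expl <- founders$explicit
  if (mode == "random") {
    if (length(expl) > length(pool)) {
      stop(sprintf("more founders (%d) than VCF samples (%d)",
                   length(expl), length(pool)))
    }
    picked <- sample(pool, length(expl))
    map <- stats::setNames(picked, expl)
  } else {
    if (is.null(mapping_path)) stop("mapped mode needs a mapping file")
    m <- utils::read.table(mapping_path, header = FALSE,
                           stringsAsFactors = FALSE)
    if (ncol(m) != 2) stop("mapping file must have two columns")
    map <- stats::setNames(as.character(m[[2]]), as.character(m[[1]]))
    if (any(!names(map) %in% expl)) {
      stop("mapping names an unknown founder id")
    }
    if (any(!map %in% pool)) stop("mapping names an unknown sample id")
    un <- setdiff(expl, names(map))
    if (length(un) > 0) {
      stop(sprintf("unassigned founder(s): %s",
                   paste(utils::head(un, 5), collapse = ", ")))
    }
  }
  out <- genomes$haps[map]
  names(out) <- names(map)
  impl <- founders$implicit
  if (length(impl) > 0) {
    extra <- sample(pool, length(impl), replace = TRUE)
    more <- genomes$haps[extra]
    names(more) <- impl
    out <- c(out, more)
  }
  out
}
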