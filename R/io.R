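#' Read a pedigree from a two-column edge-list (.nx) file
#'
#' Each non-empty line holds two whitespace-separated tokens:
#' parent first, then child.
#'
#' @param path path to an edge-list file.
#' @return a validated [ped_dag].
#' @export
read_nx <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)))
  toks <- strsplit(trimws(lines[keep]), "[[:space:]]+")
  nbad <- lengths(toks) != 2L
  if (any(nbad)) {
    stop(sprintf("malformed edge on line %d: expected two tokens, got %d",
                 keep[which(nbad)[1]], lengths(toks)[which(nbad)[1]]))
  }
  m <- do.call(rbind, toks)
  ped_dag(parent = m[, 1], child = m[, 2])
}

#' Write a pedigree as a two-column edge-list (.nx) file
#'
#' @param ped a [ped_dag]. Isolated nodes carry no edges and are not
#'   representable in this format; they are dropped with a warning.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_nx <- function(ped, path) {
  validate_ped(ped)
  iso <- setdiff(ped$ids, unique(as.vector(ped$edges)))
  if (length(iso) > 0) {
    warning(sprintf("%d isolated individual(s) not representable in .nx",
                    length(iso)))
  }
  writeLines(paste(ped$edges[, 1], ped$edges[, 2]), path)
  invisible(path)
}

#' Read a six-column PLINK-style .ped/.fam pedigree file
#'
#' Columns are FID, IID, P1, P2, Sex, Phenotype. A missing parent is
#' encoded `0`; sex codes are 1 = XY, 2 = XX, 0 = unknown. Edges are
#' created only for non-missing parents.
#'
#' @param path path to a .ped or .fam file.
#' @return list with elements `ped` (a [ped_dag]) and `profiles`
#'   (a profile table with `fid` column retained; `gen` is `NA` until
#'   [assign_generations()] is run).
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  nbad <- lengths(toks) != 6L
  if (any(nbad)) {
    stop(sprintf("line %d: expected 6 columns, got %d",
                 which(nbad)[1], lengths(toks)[which(nbad)[1]]))
  }
  m <- do.call(rbind, toks)
  colnames(m) <- c("fid", "iid", "p1", "p2", "sex", "phen")
  if (anyDuplicated(paste(m[, "fid"], m[, "iid"]))) {
    stop("duplicate IID within FID")
  }
  par <- character(); ch <- character()
  for (col in c("p1", "p2")) {
    has <- m[, col] != "0"
    par <- c(par, m[has, col])
    ch <- c(ch, m[has, "iid"])
  }
  sex <- c(`1` = "XY", `2` = "XX", `0` = "unknown")[m[, "sex"]]
  sex[is.na(sex)] <- "unknown"
  ped <- ped_dag(parent = par, child = ch, ids = m[, "iid"])
  prof <- profile_table(id = m[, "iid"], sex = unname(sex))
  # parents named in P1/P2 but absent as rows get an unknown-sex profile row
  extra <- setdiff(ped$ids, prof$id)
  if (length(extra) > 0) prof <- rbind(prof, profile_table(extra))
  prof$fid <- m[match(prof$id, m[, "iid"]), "fid"]
  prof$fid[is.na(prof$fid)] <- m[1, "fid"]
  list(ped = ped, profiles = prof)
}

#' Write a pedigree in six-column PLINK .ped/.fam layout
#'
#' @param ped a [ped_dag].
#' @param profiles profile table giving sex per individual.
#' @param path output path.
#' @param fid family id written in column 1 (single family), unless the
#'   profile table carries a `fid` column.
#' @param phenotype value for the sixth column (default `-9`, missing).
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, profiles, path, fid = "F1", phenotype = "-9") {
  validate_ped(ped)
  pl <- parents_list(ped)
  sexnum <- c(XY = "1", XX = "2", unknown = "0")
  sex <- stats::setNames(as.character(profiles$sex), profiles$id)
  fids <- if ("fid" %in% names(profiles)) {
    stats::setNames(as.character(profiles$fid), profiles$id)
  } else NULL
  rows <- vapply(ped$ids, function(id) {
    p <- pl[[id]]
    p1 <- if (length(p) >= 1) p[1] else "0"
    p2 <- if (length(p) >= 2) p[2] else "0"
    s <- sexnum[[if (id %in% names(sex)) sex[[id]] else "unknown"]]
    f <- if (!is.null(fids) && id %in% names(fids)) fids[[id]] else fid
    paste(f, id, p1, p2, s, phenotype)
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Write a generation-ordered four-column pedigree file
#'
#' Format consumed by forward genetic simulators that require founders
#' and descendants listed in the order their generation is created:
#' columns `[Gen, IID, P1, P2]`, rows sorted by ascending generation
#' tick then id; founders carry `0` in the parent columns.
#'
#' @param ped a [ped_dag].
#' @param profiles profile table; every individual must have an assigned
#'   generation tick.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_slim_pedigree <- function(ped, profiles, path) {
  validate_ped(ped)
  gen <- stats::setNames(profiles$gen, profiles$id)
  if (any(!ped$ids %in% profiles$id) || anyNA(gen[ped$ids])) {
    stop("every individual needs an assigned generation tick")
  }
  pl <- parents_list(ped)
  p1 <- vapply(ped$ids, function(i)
    if (length(pl[[i]]) >= 1) pl[[i]][1] else "0", character(1))
  p2 <- vapply(ped$ids, function(i)
    if (length(pl[[i]]) >= 2) pl[[i]][2] else "0", character(1))
  g <- gen[ped$ids]
  o <- order(g, ped$ids)
  writeLines(paste(g[o], ped$ids[o], p1[o], p2[o]), path)
  invisible(path)
}

#' Read back a generation-ordered four-column pedigree file
#'
#' @param path path written by [write_slim_pedigree()].
#' @return list with `ped` (a [ped_dag]) and `profiles` (id, sex =
#'   unknown, gen from column 1).
#' @export
read_slim_pedigree <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  if (any(lengths(toks) != 4L)) stop("expected 4 columns [Gen, IID, P1, P2]")
  m <- do.call(rbind, toks)
  par <- character(); ch <- character()
  for (col in 3:4) {
    has <- m[, col] != "0"
    par <- c(par, m[has, col])
    ch <- c(ch, m[has, 2])
  }
  ped <- ped_dag(parent = par, child = ch, ids = m[, 2])
  prof <- profile_table(id = m[, 2], gen = as.integer(m[, 1]))
  list(ped = ped, profiles = prof)
}

#' Read / write a profile file
#'
#' Three whitespace-separated columns `IID Sex GenerationTick` with a
#' header line; sex written as XX/XY/unknown.
#'
#' @param path file path.
#' @return for `read_profiles`, a profile table data.frame.
#' @export
read_profiles <- function(path) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "integer"))
  names(d) <- c("id", "sex", "gen")
  profile_table(d$id, d$sex, d$gen)
}

#' @rdname read_profiles
#' @param profiles profile table to write.
#' @export
write_profiles <- function(profiles, path) {
  d <- profiles[, c("id", "sex", "gen")]
  names(d) <- c("IID", "Sex", "GenerationTick")
  utils::write.table(d, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}
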