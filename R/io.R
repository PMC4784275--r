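#' Pedigree CSV reader and writer
#'
#' Columns `animal,sire,dam`, `0` = unknown parent.
#'
#' @param ped Pedigree tibble.
#' @param path File path.
#' @return `read_pedigree()` returns a tibble; the writer returns the path
#'   invisibly.
#' @export
write_pedigree <- function(ped, path) {
  out <- dplyr::mutate(ped[, c("animal", "sire", "dam")],
                       sire = dplyr::coalesce(.data$sire, 0L),
                       dam = dplyr::coalesce(.data$dam, 0L))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- readr::read_csv(path, col_types = "iii", progress = FALSE)
  check_parse_problems(ped, path)
  if (!all(c("animal", "sire", "dam") %in% names(ped)))
    abort(sprintf("%s: expected columns animal,sire,dam", path))
  ped_codes(ped) # validates ordering and parent references
  ped
}

#' Phenotype TSV reader and writer
#'
#' Columns `animal_id`, `trait_value`, `cg`, `age`. For simulated data,
#' `write_phenotypes()` also writes the truth side-channel (true breeding
#' values per animal) to `<path>.truth.tsv`.
#'
#' @param phen Phenotype tibble.
#' @param path File path.
#' @export
write_phenotypes <- function(phen, path) {
  readr::write_tsv(phen, path)
  truth <- attr(phen, "truth")
  if (!is.null(truth))
    readr::write_tsv(truth$values, paste0(path, ".truth.tsv"))
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  phen <- readr::read_tsv(path, col_types = readr::cols(
    animal_id = readr::col_integer(), trait_value = readr::col_double(),
    cg = readr::col_character(), age = readr::col_double()),
    progress = FALSE)
  check_parse_problems(phen, path)
  phen$cg <- factor(phen$cg)
  phen
}

#' Genotype readers and writers
#'
#' Two dialects. `count_tsv`: a pair of files `<stem>.counts.tsv`
#' (first column `animal_id`, one column per SNP holding allele counts,
#' `NA` = missing) and `<stem>.map.tsv` (`snp_id`, `chrom`, `pos_bp`);
#' round-trips bit-exactly. `plink_ped_map`: PLINK text `.ped`/`.map`;
#' calls are written with alleles `A`/`B` (`A` = counted allele,
#' `0 0` = missing) and read back as counts of the A1 allele, defined as
#' the alphabetically first allele observed at the SNP -- a SNP observed
#' with a single allele therefore cannot carry orientation through a
#' round trip.
#'
#' @param geno A [geno_matrix()].
#' @param stem Path stem (extensions are appended).
#' @param path,dialect For `read_genotypes()`: the path stem and which
#'   dialect to parse.
#' @return `read_genotypes()` returns a [geno_matrix()].
#' @export
write_genotypes_tsv <- function(geno, stem) {
  stopifnot(inherits(geno, "geno_matrix"))
  counts <- as_tibble(geno$calls)
  counts <- dplyr::bind_cols(tibble(animal_id = rownames(geno$calls)), counts)
  readr::write_tsv(counts, paste0(stem, ".counts.tsv"))
  readr::write_tsv(geno$map, paste0(stem, ".map.tsv"))
  invisible(stem)
}

#' @rdname write_genotypes_tsv
#' @export
write_plink <- function(geno, stem) {
  stopifnot(inherits(geno, "geno_matrix"))
  calls <- geno$calls
  code <- c(`0` = "B B", `1` = "A B", `2` = "A A")
  lines <- vapply(seq_len(nrow(calls)), function(i) {
    gg <- code[as.character(calls[i, ])]
    gg[is.na(gg)] <- "0 0"
    paste(rownames(calls)[i], rownames(calls)[i], "0", "0", "0", "-9",
          paste(gg, collapse = " "))
  }, character(1))
  writeLines(lines, paste0(stem, ".ped"))
  map_lines <- sprintf("%s\t%s\t0\t%d", geno$map$chrom, geno$map$snp_id,
                       geno$map$pos_bp)
  writeLines(map_lines, paste0(stem, ".map"))
  invisible(stem)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes <- function(path, dialect = c("count_tsv", "plink_ped_map")) {
  dialect <- match.arg(dialect)
  if (dialect == "count_tsv") read_genotypes_tsv(path) else read_plink(path)
}

read_genotypes_tsv <- function(stem) {
  cfile <- paste0(stem, ".counts.tsv")
  mfile <- paste0(stem, ".map.tsv")
  counts <- readr::read_tsv(cfile, col_types = readr::cols(
    animal_id = readr::col_character(), .default = readr::col_integer()),
    progress = FALSE)
  check_parse_problems(counts, cfile)
  map <- readr::read_tsv(mfile, col_types = "cci", progress = FALSE)
  check_parse_problems(map, mfile)
  calls <- as.matrix(counts[, -1L, drop = FALSE])
  rownames(calls) <- counts$animal_id
  if (!identical(colnames(calls), map$snp_id))
    abort(sprintf("%s and %s disagree on SNP ids/order", cfile, mfile))
  geno_matrix(calls, map)
}

read_plink <- function(stem) {
  pedfile <- paste0(stem, ".ped")
  mapfile <- paste0(stem, ".map")
  map_raw <- utils::read.table(mapfile, header = FALSE,
                               colClasses = c("character", "character",
                                              "character", "integer"))
  names(map_raw) <- c("chrom", "snp_id", "cm", "pos_bp")
  m <- nrow(map_raw)
  ped_lines <- readLines(pedfile)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  toks <- strsplit(trimws(ped_lines), "[ \t]+")
  expected <- 6L + 2L * m
  nb <- lengths(toks)
  if (any(nb != expected)) {
    bad <- which(nb != expected)
    abort(sprintf(
      ".ped/.map mismatch: %s line %d has %d fields, expected %d (6 + 2 x %d SNPs in %s)",
      pedfile, bad[1L], nb[bad[1L]], expected, m, mapfile))
  }
  ids <- vapply(toks, `[[`, character(1), 2L)
  al1 <- t(vapply(toks, function(tk) tk[6L + 2L * seq_len(m) - 1L], character(m)))
  al2 <- t(vapply(toks, function(tk) tk[6L + 2L * seq_len(m)], character(m)))
  if (m == 1L) { al1 <- matrix(al1, ncol = 1L); al2 <- matrix(al2, ncol = 1L) }
  calls <- matrix(NA_integer_, length(ids), m, dimnames = list(ids, NULL))
  for (j in seq_len(m)) {
    a <- al1[, j]; b <- al2[, j]
    miss <- a == "0" | b == "0"
    seen <- sort(unique(c(a[!miss], b[!miss])))
    if (length(seen) > 2L)
      abort(sprintf("SNP %s has more than two alleles in %s",
                    map_raw$snp_id[j], pedfile))
    if (length(seen) == 0L) next
    a1 <- seen[1L] # counted allele: alphabetically first observed
    calls[, j] <- (a == a1) + (b == a1)
    calls[miss, j] <- NA_integer_
  }
  geno_matrix(calls, map_raw[, c("snp_id", "chrom", "pos_bp")])
}

#' Write chain, posterior-summary and window tables
#'
#' Plain TSV writers for the fit and window results: the thinned chain
#' (`iteration`, `sigma2_a`, `sigma2_e`, `h2`), the posterior summary
#' (mean, median, SD, HPD bounds per parameter) and the per-window
#' variance table.
#'
#' @param fit An `ssgblup_fit`.
#' @param report A `window_report`.
#' @param path Output file.
#' @export
write_chain <- function(fit, path) {
  readr::write_tsv(fit$chains, path)
  invisible(path)
}

#' @rdname write_chain
#' @export
write_posterior_summary <- function(fit, path) {
  readr::write_tsv(tidy(fit), path)
  invisible(path)
}

#' @rdname write_chain
#' @export
write_windows <- function(report, path) {
  readr::write_tsv(as_tibble(report), path)
  invisible(path)
}

check_parse_problems <- function(df, path) {
  pr <- readr::problems(df)
  if (nrow(pr))
    abort(sprintf("%s: malformed row(s), e.g. line %d: %s", path,
                  pr$row[1L], pr$expected[1L]))
  invisible(df)
}
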